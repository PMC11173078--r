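#' Accessors for octanomaly containers
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param object an octanomaly S4 object.
#' @return the corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setGeneric("sourceId", function(object) standardGeneric("sourceId"))
#' @rdname accessors
#' @export
setGeneric("cropBox", function(object) standardGeneric("cropBox"))
#' @rdname accessors
#' @export
setGeneric("embeddings", function(object) standardGeneric("embeddings"))
#' @rdname accessors
#' @export
setGeneric("scores", function(object) standardGeneric("scores"))
#' @rdname accessors
#' @export
setGeneric("gridStride", function(object) standardGeneric("gridStride"))
#' @rdname accessors
#' @export
setGeneric("bankVectors", function(object) standardGeneric("bankVectors"))
#' @rdname accessors
#' @export
setGeneric("bankPositions", function(object) standardGeneric("bankPositions"))
#' @rdname accessors
#' @export
setGeneric("isCoreset", function(object) standardGeneric("isCoreset"))
#' @rdname accessors
#' @export
setGeneric("groundTruthMask", function(object) standardGeneric("groundTruthMask"))
#' @rdname accessors
#' @export
setGeneric("scanLabel", function(object) standardGeneric("scanLabel"))

#' @rdname accessors
#' @export
setMethod("pixels", "OCTScan", function(object) object@pixels)
#' @rdname accessors
#' @export
setMethod("pixels", "AnomalyMap", function(object) object@pixels)
#' @rdname accessors
#' @export
setMethod("pixels", "SynthScan", function(object) object@scan@pixels)
#' @rdname accessors
#' @export
setMethod("sourceId", "OCTScan", function(object) object@sourceId)
#' @rdname accessors
#' @export
setMethod("sourceId", "PreparedScan", function(object) object@sourceId)
#' @rdname accessors
#' @export
setMethod("sourceId", "RegionGrid", function(object) object@sourceId)
#' @rdname accessors
#' @export
setMethod("sourceId", "ScoreGrid", function(object) object@sourceId)
#' @rdname accessors
#' @export
setMethod("cropBox", "OCTScan", function(object) object@cropBox)
#' @rdname accessors
#' @export
setMethod("cropBox", "PreparedScan", function(object) object@cropBox)
#' @rdname accessors
#' @export
setMethod("embeddings", "RegionGrid", function(object) object@embeddings)
#' @rdname accessors
#' @export
setMethod("scores", "ScoreGrid", function(object) object@scores)
#' @rdname accessors
#' @export
setMethod("gridStride", "RegionGrid", function(object) object@gridStride)
#' @rdname accessors
#' @export
setMethod("gridStride", "ScoreGrid", function(object) object@gridStride)
#' @rdname accessors
#' @export
setMethod("bankVectors", "NominalBank", function(object) object@vectors)
#' @rdname accessors
#' @export
setMethod("bankPositions", "NominalBank", function(object) object@positions)
#' @rdname accessors
#' @export
setMethod("isCoreset", "NominalBank", function(object) object@isCoreset)
#' @rdname accessors
#' @export
setMethod("groundTruthMask", "SynthScan", function(object) object@mask)
#' @rdname accessors
#' @export
setMethod("scanLabel", "SynthScan", function(object) object@label)
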