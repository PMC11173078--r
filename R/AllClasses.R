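#' @import methods
#' @importFrom stats cov rnorm runif rgamma
NULL

#' OCTScan: a grayscale B-scan in [0,1]
#'
#' Container for a single 2-D grayscale OCT B-scan, before or after scanner
#' margin removal. Intensities are stored as a numeric matrix in `[0, 1]`
#' with rows indexing depth (axial direction) and columns the lateral
#' direction. `cropBox` records, in 0-based half-open coordinates of the
#' *original* image, the region this scan corresponds to; for a freshly
#' loaded scan it is the full frame.
#'
#' @slot pixels numeric matrix of intensities in `[0, 1]`.
#' @slot sourceId opaque identifier (usually the file path or stem).
#' @slot cropBox integer(4) `(row0, row1, col0, col1)`, 0-based half-open.
#' @export
setClass("OCTScan",
  representation(pixels = "matrix", sourceId = "character",
                 cropBox = "integer"))

setValidity("OCTScan", function(object) {
  p <- object@pixels
  if (!is.numeric(p) || length(dim(p)) != 2L)
    return("pixels must be a numeric matrix")
  if (nrow(p) < 1L || ncol(p) < 1L)
    return("scan must have height >= 1 and width >= 1")
  if (anyNA(p) || min(p) < 0 || max(p) > 1)
    return("all intensities must lie within [0, 1]")
  if (length(object@cropBox) != 4L)
    return("cropBox must be integer(4): (row0, row1, col0, col1)")
  b <- object@cropBox
  if (!anyNA(b) && (b[2] - b[1] != nrow(p) || b[4] - b[3] != ncol(p)))
    return("cropBox extent must match the pixel dimensions")
  TRUE
})

#' PreparedScan: normalized backbone input
#'
#' A scan after margin removal, bilinear resize to `targetSize` and
#' per-channel standardization, replicated to 3 channels so it matches the
#' input contract of ImageNet-style backbones.
#'
#' @slot tensor numeric array `(targetSize, targetSize, 3)` of standardized
#'   values.
#' @slot sourceId opaque identifier.
#' @slot cropBox integer(4) crop used before resizing, in original pixel
#'   coordinates (0-based, half-open).
#' @slot channelMeans,channelStds numeric(3) used for standardization, kept
#'   so the transform is invertible.
#' @export
setClass("PreparedScan",
  representation(tensor = "array", sourceId = "character",
                 cropBox = "integer", channelMeans = "numeric",
                 channelStds = "numeric"))

setValidity("PreparedScan", function(object) {
  d <- dim(object@tensor)
  if (length(d) != 3L || d[3] != 3L) return("tensor must be (S, S, 3)")
  if (d[1] != d[2]) return("prepared scans are square")
  if (any(!is.finite(object@tensor))) return("tensor must be finite")
  if (length(object@channelStds) != 3L || any(object@channelStds <= 0))
    return("channelStds must be 3 strictly positive numbers")
  TRUE
})

#' ToyBackbone: a small seeded convolutional feature extractor
#'
#' Four stages of (3x3 convolution, ReLU, 2x2 average pooling) with
#' 4/8/16/32 channels. Weights are a pure function of the seed, so feature
#' extraction is fully deterministic and needs no downloaded assets. The
#' same class carries adapted (fine-tuned) weights after [adaptBackbone()].
#'
#' @slot weights list of 4 stages, each `list(W, b)` with `W` a
#'   `(9*Cin) x Cout` matrix in im2col layout and `b` a length-`Cout` bias.
#' @slot spec list with `kind`, `seed`, `blocks` (pair of block indices used
#'   for region embeddings), `poolKernel` (local average-pooling kernel),
#'   and `channels`.
#' @export
setClass("ToyBackbone", representation(weights = "list", spec = "list"))

#' FeatureHierarchy: per-block feature grids plus the pooled image embedding
#'
#' @slot blocks list of 4 arrays `(H_b, W_b, C_b)` with strictly decreasing
#'   spatial size.
#' @slot pooled numeric vector: global-average-pooled final-block features,
#'   the image-level representation.
#' @slot sourceId identifier of the originating scan.
#' @export
setClass("FeatureHierarchy",
  representation(blocks = "list", pooled = "numeric", sourceId = "character"))

setValidity("FeatureHierarchy", function(object) {
  hs <- vapply(object@blocks, function(b) dim(b)[1], numeric(1))
  if (any(diff(hs) >= 0)) return("block spatial sizes must strictly decrease")
  last <- object@blocks[[length(object@blocks)]]
  if (length(object@pooled) != dim(last)[3])
    return("pooled vector length must equal final-block channels")
  TRUE
})

#' RegionGrid: the lattice of local-region embeddings of one scan
#'
#' Each grid cell holds a D-dimensional embedding describing one local
#' retinal region, built by concatenating two intermediate backbone blocks
#' after local average pooling.
#'
#' @slot embeddings numeric array `(H, W, D)`.
#' @slot sourceId identifier of the originating scan.
#' @slot gridStride pixels per grid cell in prepared-image coordinates.
#' @export
setClass("RegionGrid",
  representation(embeddings = "array", sourceId = "character",
                 gridStride = "numeric"))

setValidity("RegionGrid", function(object) {
  d <- dim(object@embeddings)
  if (length(d) != 3L) return("embeddings must be a (H, W, D) array")
  if (any(!is.finite(object@embeddings)))
    return("every cell must hold a finite vector")
  if (object@gridStride <= 0) return("gridStride must be positive")
  TRUE
})

#' NominalBank: healthy local-region embeddings
#'
#' The pool of local-region embeddings extracted from healthy training
#' scans, with the grid position of every vector retained so the bank can be
#' searched either globally (all positions) or position-aligned. A bank may
#' be compressed by [greedyCoreset()].
#'
#' @slot vectors numeric `N x D` matrix.
#' @slot positions integer `N x 2` matrix of 1-based `(row, col)` grid
#'   coordinates.
#' @slot gridDims integer(2) `(H, W)` of the source grids.
#' @slot isCoreset logical; `TRUE` after coreset compression.
#' @slot sourceFraction fraction of the original bank retained (1 if full).
#' @export
setClass("NominalBank",
  representation(vectors = "matrix", positions = "matrix",
                 gridDims = "integer", isCoreset = "logical",
                 sourceFraction = "numeric"))

setValidity("NominalBank", function(object) {
  if (nrow(object@vectors) != nrow(object@positions))
    return("vectors and positions must have one row per bank entry")
  if (nrow(object@vectors) < 1L) return("bank must be non-empty")
  if (any(object@positions < 1L) ||
      any(object@positions[, 1] > object@gridDims[1]) ||
      any(object@positions[, 2] > object@gridDims[2]))
    return("positions must lie inside gridDims")
  if (object@sourceFraction <= 0 || object@sourceFraction > 1)
    return("sourceFraction must lie in (0, 1]")
  TRUE
})

#' GaussianField: per-position Gaussian model of healthy regions
#'
#' For every grid position, the sample mean and regularized sample
#' covariance (denominator n-1, plus `epsilon * I`) of the healthy
#' embeddings observed at that position. Upper Cholesky factors are
#' precomputed for Mahalanobis scoring.
#'
#' @slot means numeric array `(H, W, D)`.
#' @slot covariances numeric array `(D, D, H*W)`, position index column-major.
#' @slot cholFactors numeric array `(D, D, H*W)` of upper Cholesky factors.
#' @slot epsilon ridge added to each covariance diagonal.
#' @slot nTrain number of training grids used.
#' @export
setClass("GaussianField",
  representation(means = "array", covariances = "array",
                 cholFactors = "array", epsilon = "numeric",
                 nTrain = "integer"))

#' ScoreGrid: per-region anomaly scores
#'
#' @slot scores numeric `(H, W)` matrix of non-negative anomaly scores, one
#'   per local region.
#' @slot sourceId identifier of the scored scan.
#' @slot gridStride pixels per grid cell in prepared-image coordinates.
#' @export
setClass("ScoreGrid",
  representation(scores = "matrix", sourceId = "character",
                 gridStride = "numeric"))

setValidity("ScoreGrid", function(object) {
  if (any(!is.finite(object@scores)) || any(object@scores < 0))
    return("scores must be finite and non-negative")
  TRUE
})

#' AnomalyMap: pixel-resolution heat map of region scores
#'
#' @slot pixels numeric `(S, S)` matrix at prepared-image resolution.
#' @slot sourceId identifier of the scored scan.
#' @slot smoothingSigma Gaussian smoothing std (pixels) applied after
#'   upsampling; 0 means none.
#' @export
setClass("AnomalyMap",
  representation(pixels = "matrix", sourceId = "character",
                 smoothingSigma = "numeric"))

#' CenterState: the frozen center of healthy image embeddings
#'
#' The arithmetic mean of the training-set image embeddings, computed once
#' from the pre-adaptation backbone and frozen: the center-loss objective
#' pulls embeddings toward this fixed vector (a moving center would admit
#' the trivial collapse of shifting the center instead of the features).
#'
#' @slot center numeric D-vector.
#' @export
setClass("CenterState", representation(center = "numeric"))

setValidity("CenterState", function(object) {
  if (length(object@center) < 1L || any(!is.finite(object@center)))
    return("center must be a non-empty finite vector")
  TRUE
})

#' FisherDiag: diagonal Fisher information weights
#'
#' Per-parameter non-negative weights (same layout as the backbone weights)
#' approximating the diagonal Fisher information at the initial parameters;
#' used by the elastic-weight-consolidation penalty during adaptation.
#'
#' @slot values list mirroring `ToyBackbone@weights`: per stage `list(W, b)`
#'   of non-negative entries.
#' @export
setClass("FisherDiag", representation(values = "list"))

#' SynthScan: a synthetic B-scan with label and ground-truth mask
#'
#' @slot scan an [OCTScan-class].
#' @slot label one of `"normal"`, `"cnv"`, `"dme"`, `"drusen"`.
#' @slot mask logical matrix marking injected anomalous pixels (all-`FALSE`
#'   matrix of dimension 0x0 for normal scans).
#' @slot seed the seed that fully determines the scan.
#' @export
setClass("SynthScan",
  representation(scan = "OCTScan", label = "character", mask = "matrix",
                 seed = "integer"))

setValidity("SynthScan", function(object) {
  if (!object@label %in% c("normal", "cnv", "dme", "drusen"))
    return("unknown label")
  if (object@label == "normal" && length(object@mask) > 0 && any(object@mask))
    return("normal scans must carry an empty mask")
  if (object@label != "normal" && (length(object@mask) == 0 || !any(object@mask)))
    return("anomalous scans must carry a nonempty mask")
  if (length(object@mask) > 0 &&
      !all(dim(object@mask) == dim(object@scan@pixels)))
    return("mask must match the image dimensions")
  TRUE
})

#' FittedModel: the artifacts of one fitted anomaly-detection run
#'
#' @slot backend one of `"global_knn"`, `"aligned_knn"`, `"gaussian"`,
#'   `"spade"`, `"image_level_knn"`.
#' @slot backbone the (possibly adapted) [ToyBackbone-class].
#' @slot bank a [NominalBank-class] or `NULL`.
#' @slot field a [GaussianField-class] or `NULL`.
#' @slot imageBank numeric matrix of training image embeddings (rows) or
#'   `NULL`.
#' @slot trainIds character vector of training scan identifiers.
#' @slot trainGrids list of training [RegionGrid-class]s (retained only for
#'   the gallery-retrieval backend) or `NULL`.
#' @slot center a [CenterState-class] or `NULL` (present when adapted).
#' @slot config the resolved run configuration list.
#' @export
setClass("FittedModel",
  representation(backend = "character", backbone = "ToyBackbone",
                 bank = "ANY", field = "ANY", imageBank = "ANY",
                 trainIds = "character", trainGrids = "ANY",
                 center = "ANY", config = "list"))

## ---- show methods -----------------------------------------------------

setMethod("show", "OCTScan", function(object) {
  cat(sprintf("OCTScan '%s': %d x %d, intensities [%.3f, %.3f]\n",
              object@sourceId, nrow(object@pixels), ncol(object@pixels),
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "PreparedScan", function(object) {
  d <- dim(object@tensor)
  cat(sprintf("PreparedScan '%s': %d x %d x %d (standardized)\n",
              object@sourceId, d[1], d[2], d[3]))
})

setMethod("show", "RegionGrid", function(object) {
  d <- dim(object@embeddings)
  cat(sprintf("RegionGrid '%s': %d x %d cells, D = %d, stride %.1f px\n",
              object@sourceId, d[1], d[2], d[3], object@gridStride))
})

setMethod("show", "NominalBank", function(object) {
  cat(sprintf("NominalBank: %d vectors, D = %d, grid %d x %d%s\n",
              nrow(object@vectors), ncol(object@vectors),
              object@gridDims[1], object@gridDims[2],
              if (object@isCoreset)
                sprintf(" (coreset, %.1f%% of source)",
                        100 * object@sourceFraction) else ""))
})

setMethod("show", "ScoreGrid", function(object) {
  cat(sprintf("ScoreGrid '%s': %d x %d, max score %.4f\n",
              object@sourceId, nrow(object@scores), ncol(object@scores),
              max(object@scores)))
})

setMethod("show", "GaussianField", function(object) {
  d <- dim(object@means)
  cat(sprintf(
    "GaussianField: %d x %d positions, D = %d, epsilon %.3g, n = %d\n",
    d[1], d[2], d[3], object@epsilon, object@nTrain))
})

setMethod("show", "ToyBackbone", function(object) {
  cat(sprintf("ToyBackbone (kind '%s', seed %d): channels %s\n",
              object@spec$kind, object@spec$seed,
              paste(object@spec$channels, collapse = "/")))
})

setMethod("show", "FittedModel", function(object) {
  cat(sprintf("FittedModel backend '%s', %d training scans%s\n",
              object@backend, length(object@trainIds),
              if (!is.null(object@center)) " (adapted)" else ""))
})

setMethod("show", "SynthScan", function(object) {
  cat(sprintf("SynthScan '%s' label '%s' (seed %d)%s\n",
              object@scan@sourceId, object@label, object@seed,
              if (length(object@mask) > 0)
                sprintf(", mask area %d px", sum(object@mask)) else ""))
})
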