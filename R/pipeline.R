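#' Default run configuration
#'
#' Nested configuration for a full fit / score / evaluate run. Blocks
#' mirror the module configurations ([prepConfig()], [backboneSpec()],
#' [knnConfig()], [coresetConfig()], [adaptConfig()]); the `backend`
#' selects the density model.
#'
#' @param backend one of `"global_knn"`, `"aligned_knn"`, `"gaussian"`,
#'   `"spade"`, `"image_level_knn"`.
#' @param targetSize prepared-image side length.
#' @param coresetFraction coreset fraction for the `global_knn` backend
#'   (1 disables compression; the aligned backend always uses the full
#'   bank so every position keeps its slice).
#' @param adapt logical: run center-loss feature adaptation before
#'   extracting the banks.
#' @param epochs adaptation epochs when `adapt` is `TRUE`.
#' @param seeds integer vector of run seeds (default `0:2`, the
#'   three-seed protocol).
#' @return a nested named list.
#' @export
defaultRunConfig <- function(backend = c("global_knn", "aligned_knn",
                                         "gaussian", "spade",
                                         "image_level_knn"),
                             targetSize = 224L, coresetFraction = 0.01,
                             adapt = FALSE, epochs = 40L,
                             seeds = c(0L, 1L, 2L)) {
  backend <- match.arg(backend)
  ac <- adaptConfig(epochs = epochs)
  list(
    prep = c(prepConfig(targetSize = targetSize),
             list(removeMargins = TRUE, margin = marginConfig())),
    backbone = list(kind = "toy_cnn", seed = 0L, blocks = c(2L, 3L),
                    localPoolKernel = 3L),
    knn = knnConfig(),
    coreset = list(fraction = coresetFraction, projectionDim = NULL),
    gaussian = list(epsilon = 0.01),
    spade = list(K = 5L),
    adapt = list(enabled = adapt, epochs = ac$epochs,
                 learningRate = ac$learningRate, ewcLambda = ac$ewcLambda,
                 fisherSamples = ac$fisherSamples,
                 batchSize = ac$batchSize),
    backend = backend, seeds = as.integer(seeds))
}

#' Read a run configuration from YAML
#'
#' Unspecified fields fall back to [defaultRunConfig()] values.
#'
#' @param path YAML file.
#' @return a nested named list.
#' @export
readRunConfig <- function(path) {
  user <- yaml::read_yaml(path)
  base <- defaultRunConfig(backend = user$backend %||% "global_knn")
  mergeList <- function(a, b) {
    for (nm in names(b))
      a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]]))
        mergeList(a[[nm]], b[[nm]]) else b[[nm]]
    a
  }
  mergeList(base, user)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# list image files under dir; with labelled = TRUE, one subdirectory per label
listScanFiles <- function(dir, labelled = FALSE) {
  if (!dir.exists(dir)) stopInput("directory '%s' does not exist", dir)
  if (!labelled) {
    f <- sort(list.files(dir, pattern = "\\.(png|jpe?g|tiff?)$",
                         full.names = TRUE, recursive = TRUE))
    if (!length(f)) stopInput("no images found under '%s'", dir)
    return(data.frame(path = f, label = "normal", stringsAsFactors = FALSE))
  }
  labs <- list.dirs(dir, full.names = FALSE, recursive = FALSE)
  if (!length(labs)) stopInput("no label subdirectories under '%s'", dir)
  do.call(rbind, lapply(sort(labs), function(l) {
    f <- sort(list.files(file.path(dir, l),
                         pattern = "\\.(png|jpe?g|tiff?)$",
                         full.names = TRUE))
    if (!length(f)) return(NULL)
    data.frame(path = f, label = l, stringsAsFactors = FALSE)
  }))
}

# load -> remove margins -> resize/standardize for a vector of paths
prepareFiles <- function(paths, prepCfg) {
  pc <- prepConfig(targetSize = prepCfg$targetSize,
                   channelMeans = prepCfg$channelMeans,
                   channelStds = prepCfg$channelStds)
  lapply(paths, function(p) {
    scan <- loadScan(p)
    if (isTRUE(prepCfg$removeMargins))
      scan <- removeMargins(scan, prepCfg$margin %||% marginConfig())
    prepareScan(scan, pc)
  })
}

#' Fit an anomaly-detection model on healthy scans
#'
#' Runs preprocessing, optional center-loss adaptation, feature extraction
#' and backend-specific model building on a directory of normal-only
#' training scans. The backbone weights are fixed by the `backbone` config
#' block (they stand in for a pretrained feature extractor, which a
#' multi-seed protocol would not re-initialize); the run `seed` drives the
#' stochastic pipeline stages — coreset shuffling and adaptation batching.
#'
#' @param trainDir directory of healthy scans (searched recursively).
#' @param config a [defaultRunConfig()]-style list.
#' @param seed integer run seed.
#' @return a [FittedModel-class].
#' @export
octFit <- function(trainDir, config = defaultRunConfig(), seed = 0L) {
  files <- listScanFiles(trainDir)
  prepared <- prepareFiles(files$path, config$prep)
  spec <- backboneSpec(kind = config$backbone$kind,
                       seed = config$backbone$seed %||% 0L,
                       blocks = config$backbone$blocks,
                       localPoolKernel = config$backbone$localPoolKernel)
  backbone <- makeBackbone(spec)
  center <- NULL
  if (isTRUE(config$adapt$enabled)) {
    acfg <- adaptConfig(epochs = config$adapt$epochs,
                        learningRate = config$adapt$learningRate,
                        ewcLambda = config$adapt$ewcLambda,
                        fisherSamples = config$adapt$fisherSamples,
                        batchSize = config$adapt$batchSize,
                        seed = deriveSeed(seed, 2L))
    ad <- adaptBackbone(backbone, prepared, acfg)
    backbone <- ad$backbone
    center <- ad$center
  }
  hier <- lapply(prepared, function(p) extractFeatureHierarchy(backbone, p))
  grids <- lapply(hier, localEmbeddings, spec = spec,
                  preparedSize = config$prep$targetSize)
  imageBank <- do.call(rbind, lapply(hier, imageEmbedding))
  bank <- NULL; field <- NULL; trainGrids <- NULL
  backend <- config$backend
  if (backend %in% c("global_knn", "aligned_knn")) {
    bank <- buildBank(grids)
    if (backend == "global_knn" && config$coreset$fraction < 1)
      bank <- greedyCoreset(bank, coresetConfig(
        fraction = config$coreset$fraction,
        seed = deriveSeed(seed, 1L),
        projectionDim = config$coreset$projectionDim))
  } else if (backend == "gaussian") {
    field <- fitGaussianField(grids, epsilon = config$gaussian$epsilon)
  } else if (backend == "spade") {
    trainGrids <- grids
  } else if (backend != "image_level_knn") {
    stopConfig("unknown backend '%s'", backend)
  }
  new("FittedModel", backend = backend, backbone = backbone, bank = bank,
      field = field, imageBank = imageBank,
      trainIds = vapply(prepared, sourceId, character(1)),
      trainGrids = trainGrids, center = center,
      config = c(config, list(seed = as.integer(seed))))
}

# region score grid for one prepared scan under the model's backend;
# NULL for the image-level backend
modelScoreGrid <- function(model, prepared) {
  spec <- model@backbone@spec
  h <- extractFeatureHierarchy(model@backbone, prepared)
  cfg <- model@config
  switch(model@backend,
    global_knn = scoreRegionsGlobal(
      localEmbeddings(h, spec, cfg$prep$targetSize), model@bank,
      knnConfig(cfg$knn$k)),
    aligned_knn = scoreRegionsAligned(
      localEmbeddings(h, spec, cfg$prep$targetSize), model@bank,
      knnConfig(cfg$knn$k)),
    gaussian = mahalanobisScores(
      localEmbeddings(h, spec, cfg$prep$targetSize), model@field),
    spade = {
      ret <- retrieveKnnImages(imageEmbedding(h), model@imageBank,
                               K = cfg$spade$K, ids = model@trainIds)
      spadePixelScores(localEmbeddings(h, spec, cfg$prep$targetSize),
                       model@trainGrids[ret$indices],
                       knnConfig(cfg$knn$k))
    },
    image_level_knn = NULL)
}

#' Score test scans with a fitted model
#'
#' For region backends, each scan's image score is the maximum of its
#' region score grid; the image-level backend scores the global-average-
#' pooled embedding by average kNN distance against the training image
#' embeddings and emits no grid or map.
#'
#' @param model a [FittedModel-class].
#' @param testDir labelled test directory (one subdirectory per label), or
#'   a flat directory.
#' @param labelled whether `testDir` has label subdirectories. Default
#'   `TRUE`.
#' @param withMaps also render an [anomalyHeatmap()] per scan.
#' @return list with `scores` (data.frame `sourceId`, `label`, `score`),
#'   `grids` (list of [ScoreGrid-class] or `NULL`), `maps`, and `prepared`.
#' @export
octScore <- function(model, testDir, labelled = TRUE, withMaps = FALSE) {
  files <- listScanFiles(testDir, labelled = labelled)
  prepared <- prepareFiles(files$path, model@config$prep)
  grids <- vector("list", length(prepared))
  maps <- vector("list", length(prepared))
  sc <- numeric(length(prepared))
  for (i in seq_along(prepared)) {
    if (model@backend == "image_level_knn") {
      h <- extractFeatureHierarchy(model@backbone, prepared[[i]])
      sc[i] <- knnAvgDistance(imageEmbedding(h), model@imageBank,
                              knnConfig(model@config$knn$k))
    } else {
      g <- modelScoreGrid(model, prepared[[i]])
      grids[[i]] <- g
      sc[i] <- imageScore(g)
      if (withMaps)
        maps[[i]] <- anomalyHeatmap(g, model@config$prep$targetSize)
    }
  }
  list(scores = data.frame(
         sourceId = vapply(prepared, sourceId, character(1)),
         label = files$label, score = sc, stringsAsFactors = FALSE),
       grids = grids, maps = maps, prepared = prepared)
}

#' Evaluate scored scans
#'
#' Pooled metrics (at the max-F1 threshold) plus per-pathology
#' one-vs-normal ROC-AUC.
#'
#' @param scoreDf data.frame with `label` and `score` (as produced by
#'   [octScore()]); `"normal"` is the negative class.
#' @return list with `pooled` ([classificationMetrics()] output) and
#'   `perPathology` (named AUC vector).
#' @export
octEvaluate <- function(scoreDf) {
  y <- as.integer(scoreDf$label != "normal")
  if (all(y == 1L) || all(y == 0L))
    stopInput("test set must contain both normal and anomalous scans")
  th <- selectThresholdMaxF1(scoreDf$score, y)
  pooled <- classificationMetrics(scoreDf$score, y, th)
  paths <- setdiff(unique(scoreDf$label), "normal")
  per <- vapply(paths, function(p) {
    keep <- scoreDf$label %in% c("normal", p)
    rocAuc(scoreDf$score[keep], y[keep])
  }, numeric(1))
  list(pooled = pooled, perPathology = per)
}

#' Run the full pipeline across seeds
#'
#' Fits, scores and evaluates once per seed in `config$seeds` and returns
#' per-seed results plus the mean and standard deviation of pooled AUC —
#' the multi-seed protocol for pipelines with stochastic stages.
#'
#' @param trainDir healthy training directory.
#' @param testDir labelled test directory.
#' @param config a [defaultRunConfig()]-style list.
#' @return list with `perSeed` (each: `scores`, `metrics`) and `summary`.
#' @export
runExperiment <- function(trainDir, testDir, config = defaultRunConfig()) {
  perSeed <- lapply(config$seeds, function(sd) {
    model <- octFit(trainDir, config, seed = sd)
    scored <- octScore(model, testDir)
    list(seed = sd, scores = scored$scores,
         metrics = octEvaluate(scored$scores))
  })
  aucs <- vapply(perSeed, function(r) r$metrics$pooled$rocAuc, numeric(1))
  perPath <- do.call(rbind, lapply(perSeed, function(r)
    r$metrics$perPathology))
  list(perSeed = perSeed,
       summary = list(aucMean = mean(aucs), aucSd = stats::sd(aucs),
                      perPathologyMean = colMeans(perPath)))
}

#' Persist / restore a fitted model
#'
#' The model artifacts are written as an RDS container next to a JSON
#' sidecar describing the run (backend, bank size, dimensions, seed).
#'
#' @param model a [FittedModel-class].
#' @param dir output directory.
#' @return `writeModel` returns the directory invisibly; `readModel`
#'   returns the [FittedModel-class].
#' @export
writeModel <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, file.path(dir, "model.rds"))
  side <- list(backend = model@backend,
               nTrain = length(model@trainIds),
               seed = model@config$seed,
               bankSize = if (!is.null(model@bank))
                 nrow(model@bank@vectors) else NULL,
               isCoreset = if (!is.null(model@bank))
                 model@bank@isCoreset else NULL)
  jsonlite::write_json(side, file.path(dir, "model.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(dir)
}

#' @rdname writeModel
#' @export
readModel <- function(dir) readRDS(file.path(dir, "model.rds"))
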