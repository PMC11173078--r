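# shared fixtures, all generated in code

rawScan <- function(px, id = "fx") {
  new("OCTScan", pixels = px, sourceId = id,
      cropBox = c(0L, nrow(px), 0L, ncol(px)))
}

randomGrid <- function(h, w, d, seed, id = "g", stride = 4) {
  set.seed(seed)
  new("RegionGrid", embeddings = array(rnorm(h * w * d), c(h, w, d)),
      sourceId = id, gridStride = stride)
}

# bank over explicit vectors at a single grid position
vectorBank <- function(m) {
  m <- as.matrix(m)
  new("NominalBank", vectors = m,
      positions = cbind(rep(1L, nrow(m)), rep(1L, nrow(m))),
      gridDims = c(1L, 1L), isCoreset = FALSE, sourceFraction = 1)
}

# brute-force mean distance to the k nearest bank rows (exhaustive oracle)
bruteKnnAvg <- function(q, x, k) {
  d <- sqrt(colSums((t(x) - q)^2))
  mean(sort(d)[seq_len(k)])
}

# brute-force pair-counting ROC-AUC oracle
bruteAuc <- function(scores, labels) {
  a <- scores[labels == 1]; n <- scores[labels == 0]
  wins <- 0
  for (x in a) for (y in n)
    wins <- wins + if (x > y) 1 else if (x == y) 0.5 else 0
  wins / (length(a) * length(n))
}

# covering radius of a selected subset (max over points of distance to set)
coverRadius <- function(x, sel) {
  max(apply(x, 1, function(p)
    min(sqrt(colSums((t(x[sel, , drop = FALSE]) - p)^2)))))
}

smallPrep <- function() prepConfig(targetSize = 64L)
smallSynth <- function(...) synthConfig(size = 64L, ...)

toyFixture <- function(seed = 7L) makeBackbone(backboneSpec(seed = seed))

preparedFromSynth <- function(ss, targetSize = 64L)
  prepareScan(ss@scan, prepConfig(targetSize = targetSize))
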