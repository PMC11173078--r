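#' kNN scoring configuration
#'
#' @param k number of nearest neighbours averaged into the anomaly score.
#'   Default 5.
#' @return a named list; the metric is Euclidean.
#' @export
knnConfig <- function(k = 5L) {
  stopifnot(k >= 1)
  list(k = as.integer(k), metric = "euclidean")
}

#' Coreset configuration
#'
#' Budget is `max(1, round(fraction * N))`. The default 1% matches the
#' profile used for large public training sets; a 10% profile suits smaller
#' clinical sets.
#'
#' @param fraction fraction of the bank to keep, in (0, 1]. Default 0.01.
#' @param seed seed for the initial shuffling (the greedy start point).
#' @param projectionDim optional dimension of a seeded Gaussian random
#'   projection used *only while selecting* (a speed knob); final distances
#'   are always computed in full dimension. `NULL` disables it.
#' @return a named list.
#' @export
coresetConfig <- function(fraction = 0.01, seed = 0L, projectionDim = NULL) {
  if (fraction <= 0 || fraction > 1)
    stopConfig("coreset fraction must lie in (0, 1]")
  list(fraction = fraction, seed = as.integer(seed),
       projectionDim = if (is.null(projectionDim)) NULL
                       else as.integer(projectionDim))
}

# row-major flattening of a (H, W, D) embedding array -> (H*W, D) matrix
# plus matching 1-based (row, col) positions
gridToMatrix <- function(emb) {
  h <- dim(emb)[1]; w <- dim(emb)[2]; d <- dim(emb)[3]
  m <- matrix(emb, h * w, d)              # column-major cell order
  ord <- as.vector(matrix(seq_len(h * w), h, w, byrow = FALSE) |> t())
  list(vectors = m[ord, , drop = FALSE],
       positions = cbind(rep(seq_len(h), each = w), rep(seq_len(w), h)))
}

#' Build the nominal bank of healthy local regions
#'
#' Stacks the region embeddings of all training grids into one pool,
#' recording each vector's grid position. Ordering is deterministic: grid
#' order, then row-major within each grid.
#'
#' @param trainGrids list of [RegionGrid-class]s sharing dimensions.
#' @return a [NominalBank-class] with `isCoreset = FALSE`.
#' @export
buildBank <- function(trainGrids) {
  if (length(trainGrids) < 1L) stopInput("need at least one training grid")
  dims <- dim(trainGrids[[1]]@embeddings)
  ok <- vapply(trainGrids,
               function(g) all(dim(g@embeddings) == dims), logical(1))
  if (!all(ok))
    stopInput("all training grids must share (H, W, D); grid %d differs",
              which(!ok)[1])
  parts <- lapply(trainGrids, function(g) gridToMatrix(g@embeddings))
  new("NominalBank",
      vectors = do.call(rbind, lapply(parts, `[[`, "vectors")),
      positions = do.call(rbind, lapply(parts, `[[`, "positions")),
      gridDims = as.integer(dims[1:2]), isCoreset = FALSE,
      sourceFraction = 1)
}

#' Compress a bank with greedy k-center selection
#'
#' Farthest-point greedy selection: after a seeded permutation of the bank,
#' the first vector seeds the selection and each step adds the vector
#' farthest from the current selection, until the budget
#' `max(1, round(fraction * N))` is reached. The covering radius of the
#' result is within a factor 2 of the optimal k-center radius. Positions
#' are preserved so the compressed bank still supports aligned search where
#' slices stay large enough.
#'
#' @param bank a full [NominalBank-class].
#' @param cfg a [coresetConfig()] list.
#' @return a [NominalBank-class] flagged `isCoreset`.
#' @export
greedyCoreset <- function(bank, cfg = coresetConfig()) {
  if (bank@isCoreset) stopConfig("bank is already a coreset")
  n <- nrow(bank@vectors)
  budget <- max(1L, as.integer(round(cfg$fraction * n)))
  perm <- withSeed(cfg$seed, sample.int(n))
  xsel <- bank@vectors[perm, , drop = FALSE]
  if (!is.null(cfg$projectionDim)) {
    d <- ncol(xsel)
    proj <- withSeed(deriveSeed(cfg$seed, 1L),
                     matrix(rnorm(d * cfg$projectionDim) /
                            sqrt(cfg$projectionDim), d))
    xsel <- xsel %*% proj
  }
  sel <- perm[cpp_greedy_coreset(xsel, budget)]
  new("NominalBank",
      vectors = bank@vectors[sel, , drop = FALSE],
      positions = bank@positions[sel, , drop = FALSE],
      gridDims = bank@gridDims, isCoreset = TRUE,
      sourceFraction = cfg$fraction)
}

#' Average distance to the k nearest bank vectors
#'
#' The anomaly score of a single local region: the mean Euclidean distance
#' between the query embedding and its k nearest vectors in the nominal
#' bank. Ties at the k-th neighbour do not affect the mean (tied vectors
#' are equidistant); neighbour identity ties are resolved by bank order.
#'
#' @param query numeric D-vector, or an `m x D` matrix of queries.
#' @param bank a [NominalBank-class] (or plain numeric matrix).
#' @param cfg a [knnConfig()] list.
#' @return non-negative score(s), one per query.
#' @export
knnAvgDistance <- function(query, bank, cfg = knnConfig()) {
  x <- if (is(bank, "NominalBank")) bank@vectors else bank
  q <- if (is.matrix(query)) query else matrix(query, 1L)
  if (ncol(q) != ncol(x))
    stopInput("query dimension %d does not match bank dimension %d",
              ncol(q), ncol(x))
  if (cfg$k > nrow(x))
    stopConfig("k = %d exceeds bank size %d", cfg$k, nrow(x))
  as.numeric(cpp_knn_avg_dist(q, x, cfg$k))
}

#' Score all regions against the full bank (global search)
#'
#' Every grid cell is scored by [knnAvgDistance()] against all bank vectors
#' regardless of spatial location, the search mode suited to unaligned,
#' uncentered scans.
#'
#' @param grid a [RegionGrid-class].
#' @param bank a [NominalBank-class].
#' @param cfg a [knnConfig()] list.
#' @return a [ScoreGrid-class].
#' @export
scoreRegionsGlobal <- function(grid, bank, cfg = knnConfig()) {
  emb <- grid@embeddings
  h <- dim(emb)[1]; w <- dim(emb)[2]; d <- dim(emb)[3]
  if (d != ncol(bank@vectors))
    stopInput("grid dimension %d does not match bank dimension %d",
              d, ncol(bank@vectors))
  if (cfg$k > nrow(bank@vectors))
    stopConfig("k = %d exceeds bank size %d", cfg$k, nrow(bank@vectors))
  sc <- cpp_knn_avg_dist(matrix(emb, h * w, d), bank@vectors, cfg$k)
  new("ScoreGrid", scores = matrix(sc, h, w), sourceId = grid@sourceId,
      gridStride = grid@gridStride)
}

#' Score regions against position-aligned bank slices
#'
#' Cell `(r, c)` is compared only with bank vectors recorded at grid
#' position `(r, c)` — the alignment-assuming search mode. Requires every
#' aligned slice to hold at least k vectors.
#'
#' @inheritParams scoreRegionsGlobal
#' @return a [ScoreGrid-class].
#' @export
scoreRegionsAligned <- function(grid, bank, cfg = knnConfig()) {
  emb <- grid@embeddings
  h <- dim(emb)[1]; w <- dim(emb)[2]; d <- dim(emb)[3]
  if (!all(bank@gridDims == c(h, w)))
    stopInput("grid is %d x %d but bank was built from %d x %d grids",
              h, w, bank@gridDims[1], bank@gridDims[2])
  pos <- (bank@positions[, 1] - 1L) * w + bank@positions[, 2]
  idx <- split(seq_len(nrow(bank@vectors)),
               factor(pos, levels = seq_len(h * w)))
  out <- matrix(0, h, w)
  k <- cfg$k
  for (r in seq_len(h)) for (cc in seq_len(w)) {
    rows <- idx[[(r - 1L) * w + cc]]
    if (length(rows) < k)
      stopConfig("aligned slice at position (%d, %d) has %d < k = %d vectors",
                 r, cc, length(rows), k)
    q <- emb[r, cc, ]
    d2 <- colSums((t(bank@vectors[rows, , drop = FALSE]) - q)^2)
    ks <- sort(d2, partial = k)[seq_len(k)]
    out[r, cc] <- mean(sqrt(pmax(ks, 0)))
  }
  new("ScoreGrid", scores = out, sourceId = grid@sourceId,
      gridStride = grid@gridStride)
}
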