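#' Fit a per-position Gaussian field to healthy region embeddings
#'
#' For every grid position, the sample mean and sample covariance
#' (denominator n-1) of the embeddings observed there across training
#' grids, regularized by `epsilon * I` so every covariance is symmetric
#' positive definite. The fit is invariant to the order of the training
#' grids.
#'
#' @param trainGrids list of at least two [RegionGrid-class]s sharing
#'   dimensions.
#' @param epsilon ridge added to each covariance diagonal. Default 0.01.
#' @return a [GaussianField-class].
#' @export
fitGaussianField <- function(trainGrids, epsilon = 0.01) {
  if (length(trainGrids) < 2L)
    stopInput("need at least 2 training grids for a sample covariance")
  stopifnot(epsilon > 0)
  dims <- dim(trainGrids[[1]]@embeddings)
  if (!all(vapply(trainGrids,
                  function(g) all(dim(g@embeddings) == dims), logical(1))))
    stopInput("all training grids must share (H, W, D)")
  h <- dims[1]; w <- dims[2]; d <- dims[3]; n <- length(trainGrids)
  # stack: (n, H*W, D), positions column-major as in R arrays
  stack <- array(0, c(n, h * w, d))
  for (g in seq_len(n))
    stack[g, , ] <- matrix(trainGrids[[g]]@embeddings, h * w, d)
  means <- array(0, c(h, w, d))
  covs <- array(0, c(d, d, h * w))
  chols <- array(0, c(d, d, h * w))
  eye <- diag(epsilon, d)
  for (p in seq_len(h * w)) {
    x <- stack[, p, , drop = TRUE]
    if (n == 2L) x <- matrix(x, n, d)
    s <- cov(x) + eye
    covs[, , p] <- s
    chols[, , p] <- chol(s)
    means[((p - 1L) %% h) + 1L, ((p - 1L) %/% h) + 1L, ] <- colMeans(x)
  }
  new("GaussianField", means = means, covariances = covs,
      cholFactors = chols, epsilon = epsilon, nTrain = as.integer(n))
}

#' Mahalanobis anomaly scores against a Gaussian field
#'
#' Cell `(r, c)` is scored by
#' `sqrt((x - mu)' solve(Sigma) (x - mu))` using the mean and regularized
#' covariance fitted at that same position.
#'
#' @param grid a [RegionGrid-class].
#' @param field a [GaussianField-class] with matching dimensions.
#' @return a [ScoreGrid-class].
#' @export
mahalanobisScores <- function(grid, field) {
  emb <- grid@embeddings
  if (!all(dim(emb) == dim(field@means)))
    stopInput("grid dimensions do not match the Gaussian field")
  h <- dim(emb)[1]; w <- dim(emb)[2]; d <- dim(emb)[3]
  q <- matrix(emb, h * w, d)
  mu <- matrix(field@means, h * w, d)
  out <- numeric(h * w)
  for (p in seq_len(h * w)) {
    z <- backsolve(field@cholFactors[, , p], q[p, ] - mu[p, ],
                   transpose = TRUE)
    out[p] <- sqrt(sum(z * z))
  }
  new("ScoreGrid", scores = matrix(out, h, w), sourceId = grid@sourceId,
      gridStride = grid@gridStride)
}

#' Retrieve the K nearest healthy scans by image embedding
#'
#' Euclidean nearest-neighbour retrieval on global-average-pooled image
#' embeddings; ties are resolved by training order.
#'
#' @param queryEmbedding numeric vector.
#' @param trainEmbeddings numeric matrix, one training scan per row.
#' @param K number of neighbours. Default 5.
#' @param ids optional character identifiers for the training scans.
#' @return list with `neighborIds` (ordered identifiers) and `indices`.
#' @export
retrieveKnnImages <- function(queryEmbedding, trainEmbeddings, K = 5L,
                              ids = NULL) {
  n <- nrow(trainEmbeddings)
  if (K > n) stopConfig("K = %d exceeds the number of training scans %d", K, n)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  d2 <- colSums((t(trainEmbeddings) - queryEmbedding)^2)
  ord <- order(d2, seq_len(n))[seq_len(K)]
  list(neighborIds = ids[ord], indices = ord)
}

#' Gallery-retrieval pixel-level scores
#'
#' The second stage of the retrieval backend: every query region is scored
#' by average kNN distance against the pooled set of *all* regions of the
#' retrieved gallery scans (all positions, retrieved scans only). With the
#' full training set as gallery this coincides with global bank search.
#'
#' @param queryGrid a [RegionGrid-class].
#' @param galleryGrids list of [RegionGrid-class]s (the retrieved scans).
#' @param cfg a [knnConfig()] list.
#' @return a [ScoreGrid-class].
#' @export
spadePixelScores <- function(queryGrid, galleryGrids, cfg = knnConfig()) {
  dims <- dim(queryGrid@embeddings)
  if (!all(vapply(galleryGrids,
                  function(g) all(dim(g@embeddings) == dims), logical(1))))
    stopInput("gallery grids must share (H, W, D) with the query")
  pool <- do.call(rbind, lapply(galleryGrids, function(g)
    matrix(g@embeddings, dims[1] * dims[2], dims[3])))
  if (cfg$k > nrow(pool))
    stopConfig("pooled gallery (%d regions) smaller than k = %d",
               nrow(pool), cfg$k)
  q <- matrix(queryGrid@embeddings, dims[1] * dims[2], dims[3])
  sc <- cpp_knn_avg_dist(q, pool, cfg$k)
  new("ScoreGrid", scores = matrix(sc, dims[1], dims[2]),
      sourceId = queryGrid@sourceId, gridStride = queryGrid@gridStride)
}
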