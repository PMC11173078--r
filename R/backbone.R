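#' Backbone specification
#'
#' Region embeddings are built from two intermediate blocks of a
#' convolutional backbone (default blocks 2 and 3), each locally
#' average-pooled (kernel `localPoolKernel`) so every grid cell summarizes
#' a true neighbourhood; the image-level embedding is the global average
#' pool of the final block. The `toy_cnn` kind is a small, fully seeded
#' 4-stage network that needs no downloaded weights; the pretrained ResNet
#' kinds require a locally available weights runtime and raise a resource
#' error when absent.
#'
#' @param kind one of `"toy_cnn"`, `"pretrained_resnet152"`,
#'   `"pretrained_resnet_small"`.
#' @param seed integer; fully determines `toy_cnn` weights.
#' @param blocks pair of distinct block indices in 1..4 used for region
#'   embeddings.
#' @param localPoolKernel odd positive integer; local average-pooling
#'   kernel applied to each block before concatenation. Default 3.
#' @return a named list.
#' @export
backboneSpec <- function(kind = c("toy_cnn", "pretrained_resnet152",
                                  "pretrained_resnet_small"),
                         seed = 0L, blocks = c(2L, 3L),
                         localPoolKernel = 3L) {
  kind <- match.arg(kind)
  if (length(blocks) != 2L || anyDuplicated(blocks) ||
      !all(blocks %in% 1:4))
    stopConfig("blocks must be two distinct indices in 1..4")
  if (localPoolKernel < 1 || localPoolKernel %% 2 == 0)
    stopConfig("localPoolKernel must be an odd positive integer")
  list(kind = kind, seed = as.integer(seed),
       blocks = as.integer(sort(blocks)),
       localPoolKernel = as.integer(localPoolKernel))
}

toyChannels <- c(4L, 8L, 16L, 32L)

#' Construct a backbone
#'
#' @param spec a [backboneSpec()] list.
#' @return a [ToyBackbone-class] ready for inference.
#' @export
makeBackbone <- function(spec = backboneSpec()) {
  if (spec$kind != "toy_cnn")
    stop(errorCondition(sprintf(
      paste0("backbone kind '%s' needs pretrained weights and a deep-",
             "learning runtime, neither of which is available here; ",
             "use kind = 'toy_cnn' for a self-contained seeded backbone"),
      spec$kind), class = c("octanomaly_resource_error", "error")))
  cins <- c(3L, toyChannels[-4])
  weights <- withSeed(spec$seed, lapply(seq_len(4L), function(s) {
    cin <- cins[s]; cout <- toyChannels[s]
    # He-normal initialization for ReLU stacks
    list(W = matrix(rnorm(9L * cin * cout, 0, sqrt(2 / (9 * cin))),
                    9L * cin, cout),
         b = numeric(cout))
  }))
  spec$channels <- toyChannels
  new("ToyBackbone", weights = weights, spec = spec)
}

## ---- forward primitives (im2col layout) --------------------------------

# (H, W, C) -> (H*W, 9C) with zero padding; column blocks ordered by the
# 3x3 offset (column-major over the kernel), channels within each offset.
# Positions are column-major over (H, W), matching R array vectorization.
im2col3 <- function(x) {
  h <- dim(x)[1]; w <- dim(x)[2]; C <- dim(x)[3]
  p <- array(0, c(h + 2L, w + 2L, C))
  p[2L:(h + 1L), 2L:(w + 1L), ] <- x
  cols <- vector("list", 9L)
  n <- 0L
  for (dj in 0:2) for (di in 0:2) {
    n <- n + 1L
    cols[[n]] <- matrix(p[di + seq_len(h), dj + seq_len(w), ], h * w, C)
  }
  do.call(cbind, cols)
}

# scatter-add adjoint of im2col3: (H*W, 9C) gradient -> (H, W, C)
col2im3 <- function(dM, h, w, C) {
  dP <- array(0, c(h + 2L, w + 2L, C))
  n <- 0L
  for (dj in 0:2) for (di in 0:2) {
    n <- n + 1L
    blk <- array(dM[, ((n - 1L) * C + 1L):(n * C)], c(h, w, C))
    dP[di + seq_len(h), dj + seq_len(w), ] <-
      dP[di + seq_len(h), dj + seq_len(w), ] + blk
  }
  dP[2L:(h + 1L), 2L:(w + 1L), , drop = FALSE]
}

# leaky ReLU: tiny random networks keep all channels informative (no dead
# units), which stabilizes feature quality across initialization seeds
leakySlope <- 0.1

avgPool2 <- function(x) {
  h <- dim(x)[1]; w <- dim(x)[2]
  (x[seq(1L, h, 2L), seq(1L, w, 2L), , drop = FALSE] +
   x[seq(2L, h, 2L), seq(1L, w, 2L), , drop = FALSE] +
   x[seq(1L, h, 2L), seq(2L, w, 2L), , drop = FALSE] +
   x[seq(2L, h, 2L), seq(2L, w, 2L), , drop = FALSE]) / 4
}

# full forward pass; keepCache retains per-stage intermediates for backprop
toyForward <- function(backbone, tensor, keepCache = FALSE) {
  x <- tensor
  blocks <- vector("list", 4L)
  cache <- if (keepCache) vector("list", 4L) else NULL
  for (s in seq_len(4L)) {
    h <- dim(x)[1]; w <- dim(x)[2]
    if (h %% 2L || w %% 2L)
      stopInput("input spatial size must be divisible by 16")
    wb <- backbone@weights[[s]]
    M <- im2col3(x)
    pre <- M %*% wb$W
    pre <- sweep(pre, 2L, wb$b, "+")
    act <- array(ifelse(pre > 0, pre, leakySlope * pre),
                 c(h, w, ncol(pre)))
    pooled <- avgPool2(act)
    if (keepCache)
      cache[[s]] <- list(M = M, preMask = pre > 0, inDim = dim(x))
    blocks[[s]] <- pooled
    x <- pooled
  }
  pooledVec <- colMeans(matrix(blocks[[4L]],
                               prod(dim(blocks[[4L]])[1:2]),
                               dim(blocks[[4L]])[3]))
  list(blocks = blocks, pooled = pooledVec, cache = cache)
}

#' Extract the per-block feature hierarchy of a prepared scan
#'
#' Runs the backbone in inference mode (a pure function of weights and
#' input) and returns the four block grids plus the global-average-pooled
#' final-block vector used as the image-level representation.
#'
#' @param backbone a [ToyBackbone-class].
#' @param scan a [PreparedScan-class].
#' @return a [FeatureHierarchy-class].
#' @export
extractFeatureHierarchy <- function(backbone, scan) {
  d <- dim(scan@tensor)
  if (d[3] != 3L || d[1] %% 16L != 0L)
    stopInput("scan tensor must be (S, S, 3) with S divisible by 16")
  fw <- toyForward(backbone, scan@tensor)
  new("FeatureHierarchy", blocks = fw$blocks, pooled = fw$pooled,
      sourceId = scan@sourceId)
}

#' Build the local-region embedding grid
#'
#' Applies local average pooling (kernel `localPoolKernel`, stride 1,
#' edge padding) to the two configured blocks, upsamples the coarser block
#' to the finer block's lattice by nearest neighbour (coarse vectors are
#' copied, never blended), and concatenates channel-wise, so each grid cell
#' holds a D = C_a + C_b embedding of one local retinal region.
#'
#' @param h a [FeatureHierarchy-class].
#' @param spec the [backboneSpec()] used (for blocks and pool kernel).
#' @param preparedSize side length of the prepared scan, used to record the
#'   grid stride.
#' @return a [RegionGrid-class].
#' @export
localEmbeddings <- function(h, spec = backboneSpec(), preparedSize = NULL) {
  if (!all(spec$blocks %in% seq_along(h@blocks)))
    stopConfig("block index out of range: %s",
               paste(spec$blocks, collapse = ", "))
  fine <- localAvgPool(h@blocks[[spec$blocks[1]]], spec$localPoolKernel)
  coarse <- localAvgPool(h@blocks[[spec$blocks[2]]], spec$localPoolKernel)
  fh <- dim(fine)[1]; fw <- dim(fine)[2]
  f <- fh / dim(coarse)[1]
  if (f != round(f) || fw / dim(coarse)[2] != f)
    stopConfig("finer block lattice must be an integer multiple of the coarser")
  up <- upsampleNearest(coarse, as.integer(f))
  emb <- array(c(fine, up), c(fh, fw, dim(fine)[3] + dim(up)[3]))
  if (is.null(preparedSize))
    preparedSize <- dim(h@blocks[[1]])[1] * 2L  # stage 1 halves the input
  new("RegionGrid", embeddings = emb, sourceId = h@sourceId,
      gridStride = preparedSize / fh)
}

#' Image-level embedding
#'
#' @param h a [FeatureHierarchy-class].
#' @return the global-average-pooled final-block vector.
#' @export
imageEmbedding <- function(h) h@pooled
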