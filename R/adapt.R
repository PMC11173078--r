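#' Adaptation configuration
#'
#' Center-loss fine-tuning of the backbone on healthy scans, regularized by
#' elastic weight consolidation (EWC) so the features do not drift far from
#' their informative initialization (catastrophic forgetting).
#'
#' @param epochs number of passes over the training scans. Default 40.
#' @param learningRate SGD step size (no momentum). Default 1e-4.
#' @param ewcLambda weight of the EWC quadratic penalty. Default 1e4.
#' @param fisherSamples number of scans used to estimate the Fisher
#'   diagonal. Default 32.
#' @param batchSize minibatch size. Default 8.
#' @param seed seed controlling batch shuffling and Fisher subsampling.
#' @return a named list.
#' @export
adaptConfig <- function(epochs = 40L, learningRate = 1e-4, ewcLambda = 1e4,
                        fisherSamples = 32L, batchSize = 8L, seed = 0L) {
  stopifnot(epochs >= 1, learningRate > 0, ewcLambda >= 0,
            fisherSamples >= 1, batchSize >= 1)
  list(epochs = as.integer(epochs), learningRate = learningRate,
       ewcLambda = ewcLambda, fisherSamples = as.integer(fisherSamples),
       batchSize = as.integer(batchSize), seed = as.integer(seed))
}

#' Compute the center of image embeddings
#'
#' The arithmetic mean of the training-set image embeddings; frozen once
#' computed, so the center loss cannot collapse by moving the target.
#'
#' @param embeddings numeric matrix (one embedding per row) or list of
#'   vectors.
#' @return a [CenterState-class].
#' @export
computeCenter <- function(embeddings) {
  if (is.list(embeddings)) embeddings <- do.call(rbind, embeddings)
  if (is.null(dim(embeddings))) embeddings <- matrix(embeddings, 1L)
  if (nrow(embeddings) < 1L) stopInput("need at least one embedding")
  new("CenterState", center = colMeans(embeddings))
}

# forward + backward of the center loss ||f(x) - c||^2 for one image;
# returns loss and per-stage gradients in the weight layout
centerLossGrad <- function(backbone, tensor, center) {
  fw <- toyForward(backbone, tensor, keepCache = TRUE)
  e <- fw$pooled
  diff <- e - center
  loss <- sum(diff * diff)
  # d loss / d block4 grid: GAP spreads the embedding gradient uniformly
  b4 <- fw$blocks[[4L]]
  h4 <- dim(b4)[1]; w4 <- dim(b4)[2]; c4 <- dim(b4)[3]
  dPool <- array(rep(2 * diff / (h4 * w4), each = h4 * w4), c(h4, w4, c4))
  grads <- vector("list", 4L)
  for (s in 4:1) {
    cache <- fw$cache[[s]]
    hh <- dim(dPool)[1] * 2L; ww <- dim(dPool)[2] * 2L
    cc <- dim(dPool)[3]
    # adjoint of 2x2 average pooling
    dAct <- array(0, c(hh, ww, cc))
    q <- dPool / 4
    dAct[seq(1L, hh, 2L), seq(1L, ww, 2L), ] <- q
    dAct[seq(2L, hh, 2L), seq(1L, ww, 2L), ] <- q
    dAct[seq(1L, hh, 2L), seq(2L, ww, 2L), ] <- q
    dAct[seq(2L, hh, 2L), seq(2L, ww, 2L), ] <- q
    dPre <- matrix(dAct, hh * ww, cc) *
      ifelse(cache$preMask, 1, leakySlope)
    grads[[s]] <- list(W = crossprod(cache$M, dPre), b = colSums(dPre))
    if (s > 1L) {
      dM <- dPre %*% t(backbone@weights[[s]]$W)
      dX <- col2im3(dM, hh, ww, cache$inDim[3])
      dPool <- dX
    }
  }
  list(loss = loss, grads = grads)
}

zeroGrads <- function(backbone) lapply(backbone@weights, function(wb)
  list(W = array(0, dim(wb$W)), b = numeric(length(wb$b))))

#' Estimate the diagonal Fisher information of the center loss
#'
#' Average of squared per-parameter gradients of the center loss
#' `||f(x) - c||^2` over a seeded subsample of the healthy training scans,
#' evaluated at the current (initial) weights. This anchors the EWC penalty
#' to the directions in which the one-class objective is locally sensitive.
#'
#' @param backbone a [ToyBackbone-class].
#' @param trainScans list of [PreparedScan-class]s.
#' @param state a [CenterState-class] (already computed).
#' @param cfg an [adaptConfig()] list.
#' @return a [FisherDiag-class].
#' @export
estimateFisherDiag <- function(backbone, trainScans, state,
                               cfg = adaptConfig()) {
  n <- length(trainScans)
  ns <- cfg$fisherSamples
  if (ns > n) {
    warning(sprintf("fisherSamples = %d clipped to the %d available scans",
                    ns, n))
    ns <- n
  }
  pick <- withSeed(cfg$seed, sample.int(n, ns))
  acc <- zeroGrads(backbone)
  for (i in pick) {
    g <- centerLossGrad(backbone, trainScans[[i]]@tensor,
                        state@center)$grads
    for (s in seq_len(4L)) {
      acc[[s]]$W <- acc[[s]]$W + g[[s]]$W^2
      acc[[s]]$b <- acc[[s]]$b + g[[s]]$b^2
    }
  }
  new("FisherDiag", values = lapply(acc, function(a)
    list(W = a$W / ns, b = a$b / ns)))
}

#' Adapt the backbone with a center loss under EWC regularization
#'
#' Minimizes `mean ||f(x) - c||^2 + lambda * sum_i F_i (theta_i - theta0_i)^2`
#' by seeded minibatch SGD. The center `c` is the frozen mean of the
#' initial image embeddings; `F` is the diagonal Fisher estimate at the
#' initial weights. The quadratic EWC term is applied as an exact proximal
#' (implicit) step, which is unconditionally stable in `lambda`: as
#' `lambda` grows, parameters are pinned ever closer to their initial
#' values instead of oscillating. The input backbone is left untouched.
#'
#' @param backbone a [ToyBackbone-class].
#' @param trainScans list of [PreparedScan-class]s (healthy only).
#' @param cfg an [adaptConfig()] list.
#' @return list with `backbone` (adapted), `history` (per-epoch mean center
#'   loss), `center` (the frozen [CenterState-class]) and `fisher`.
#' @export
adaptBackbone <- function(backbone, trainScans, cfg = adaptConfig()) {
  if (length(trainScans) < 1L) stopInput("need at least one training scan")
  emb <- t(vapply(trainScans, function(s)
    toyForward(backbone, s@tensor)$pooled,
    numeric(toyChannels[4L])))
  state <- computeCenter(emb)
  fisher <- if (cfg$ewcLambda > 0)
    estimateFisherDiag(backbone, trainScans, state, cfg)
  else NULL
  theta0 <- backbone@weights
  adapted <- backbone
  n <- length(trainScans)
  lr <- cfg$learningRate
  history <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    ord <- withSeed(deriveSeed(cfg$seed, ep), sample.int(n))
    epochLoss <- 0
    for (start in seq(1L, n, by = cfg$batchSize)) {
      batch <- ord[start:min(start + cfg$batchSize - 1L, n)]
      acc <- zeroGrads(adapted)
      for (i in batch) {
        g <- centerLossGrad(adapted, trainScans[[i]]@tensor, state@center)
        epochLoss <- epochLoss + g$loss
        for (s in seq_len(4L)) {
          acc[[s]]$W <- acc[[s]]$W + g$grads[[s]]$W
          acc[[s]]$b <- acc[[s]]$b + g$grads[[s]]$b
        }
      }
      m <- length(batch)
      w <- adapted@weights
      for (s in seq_len(4L)) {
        gW <- acc[[s]]$W / m
        gb <- acc[[s]]$b / m
        if (is.null(fisher)) {
          w[[s]]$W <- w[[s]]$W - lr * gW
          w[[s]]$b <- w[[s]]$b - lr * gb
        } else {
          # explicit step on the center loss, implicit (proximal) step on
          # the quadratic EWC penalty: exact in the lambda -> Inf limit
          aW <- 2 * lr * cfg$ewcLambda * fisher@values[[s]]$W
          ab <- 2 * lr * cfg$ewcLambda * fisher@values[[s]]$b
          w[[s]]$W <- (w[[s]]$W - lr * gW + aW * theta0[[s]]$W) / (1 + aW)
          w[[s]]$b <- (w[[s]]$b - lr * gb + ab * theta0[[s]]$b) / (1 + ab)
        }
      }
      adapted@weights <- w
    }
    history[ep] <- epochLoss / n
    if (!is.finite(history[ep]))
      stop(errorCondition(
        sprintf("adaptation diverged at epoch %d (non-finite loss)", ep),
        class = c("octanomaly_training_error", "error")))
  }
  list(backbone = adapted, history = history, center = state,
       fisher = fisher)
}
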