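# adaptation tests run on 64 px scans: small enough for analytic/finite-
# difference oracles while exercising all four backbone stages

adaptScans <- function(n, size = 64L, from = 1L)
  lapply(seq(from, length.out = n), function(i)
    preparedFromSynth(generateNormalScan(synthConfig(size = size), i), size))

test_that("computeCenter is the arithmetic mean", {
  expect_equal(computeCenter(list(c(0, 0), c(2, 2)))@center, c(1, 1))
  expect_equal(computeCenter(c(3, 1, 4))@center, c(3, 1, 4))
  set.seed(3)
  m <- matrix(rnorm(100 * 7), 100, 7)
  acc <- numeric(7)                      # independent running-sum oracle
  for (i in 1:100) acc <- acc + m[i, ]
  expect_equal(computeCenter(m)@center, acc / 100, tolerance = 1e-12)
  expect_error(computeCenter(matrix(0, 0, 3)),
               class = "octanomaly_input_error")
})

test_that("center-loss gradients match finite differences", {
  b <- toyFixture(seed = 2)
  set.seed(8)
  x <- array(rnorm(32 * 32 * 3), c(32, 32, 3))
  ctr <- rnorm(32)
  g <- octanomaly:::centerLossGrad(b, x, ctr)
  eps <- 1e-5
  for (s in 1:4) {
    set.seed(s)
    for (i in sample(length(b@weights[[s]]$W), 3)) {
      up <- b; up@weights[[s]]$W[i] <- up@weights[[s]]$W[i] + eps
      dn <- b; dn@weights[[s]]$W[i] <- dn@weights[[s]]$W[i] - eps
      fd <- (octanomaly:::centerLossGrad(up, x, ctr)$loss -
             octanomaly:::centerLossGrad(dn, x, ctr)$loss) / (2 * eps)
      expect_equal(g$grads[[s]]$W[i], fd, tolerance = 1e-5)
    }
    ib <- 1L
    up <- b; up@weights[[s]]$b[ib] <- up@weights[[s]]$b[ib] + eps
    dn <- b; dn@weights[[s]]$b[ib] <- dn@weights[[s]]$b[ib] - eps
    fd <- (octanomaly:::centerLossGrad(up, x, ctr)$loss -
           octanomaly:::centerLossGrad(dn, x, ctr)$loss) / (2 * eps)
    expect_equal(g$grads[[s]]$b[ib], fd, tolerance = 1e-5)
  }
})

test_that("Fisher diagonal is non-negative and vanishes for dead models", {
  b <- toyFixture(seed = 4)
  scans <- adaptScans(4)
  ctr <- computeCenter(t(vapply(scans, function(s)
    octanomaly:::toyForward(b, s@tensor)$pooled, numeric(32))))
  f <- estimateFisherDiag(b, scans, ctr, adaptConfig(fisherSamples = 4))
  expect_true(all(vapply(f@values, function(v)
    all(v$W >= 0) && all(v$b >= 0), logical(1))))

  # zero weights: the embedding is constant (zero) in the input and the
  # center loss gradient vanishes identically
  bz <- b
  for (s in 1:4) {
    bz@weights[[s]]$W[] <- 0
    bz@weights[[s]]$b[] <- 0
  }
  ctz <- computeCenter(t(vapply(scans, function(s)
    octanomaly:::toyForward(bz, s@tensor)$pooled, numeric(32))))
  fz <- estimateFisherDiag(bz, scans, ctz, adaptConfig(fisherSamples = 4))
  expect_true(all(vapply(fz@values, function(v)
    max(abs(v$W)) == 0 && max(abs(v$b)) == 0, logical(1))))

  expect_warning(estimateFisherDiag(b, scans, ctr,
                                    adaptConfig(fisherSamples = 10)),
                 "clipped")
})

test_that("adaptation reduces the center loss and honors the loop contract", {
  b <- toyFixture(seed = 1)
  scans <- adaptScans(16)
  evalLoss <- function(bk, ctr) mean(vapply(scans, function(s)
    sum((octanomaly:::toyForward(bk, s@tensor)$pooled - ctr)^2), numeric(1)))
  ad <- adaptBackbone(b, scans, adaptConfig(epochs = 5, batchSize = 8,
                                            fisherSamples = 8, seed = 3))
  expect_length(ad$history, 5L)
  expect_lt(evalLoss(ad$backbone, ad$center@center),
            evalLoss(b, ad$center@center))
  # the input backbone is untouched
  expect_identical(b@weights, makeBackbone(backboneSpec(seed = 1))@weights)
  # geometry is preserved
  p <- scans[[1]]
  expect_identical(dim(embeddings(localEmbeddings(
    extractFeatureHierarchy(ad$backbone, p), b@spec, 64))), c(16L, 16L, 24L))

  expect_error(adaptConfig(epochs = 0))
  one <- adaptBackbone(b, scans[1:4], adaptConfig(epochs = 1, batchSize = 4,
                                                  fisherSamples = 4))
  expect_length(one$history, 1L)
})

test_that("an extreme EWC penalty pins parameters at initialization", {
  b <- toyFixture(seed = 5)
  scans <- adaptScans(8)
  ad <- adaptBackbone(b, scans, adaptConfig(epochs = 3, ewcLambda = 1e12,
                                            batchSize = 4, fisherSamples = 4,
                                            seed = 1))
  drift <- max(vapply(1:4, function(s)
    max(abs(ad$backbone@weights[[s]]$W - b@weights[[s]]$W)), numeric(1)))
  expect_lt(drift, 1e-6)
  expect_lt(diff(range(ad$history)), 1e-6 * max(1, ad$history[1]))
})

test_that("with no EWC and a vanishing step the weights stay put", {
  b <- toyFixture(seed = 6)
  scans <- adaptScans(4)
  ad <- adaptBackbone(b, scans, adaptConfig(epochs = 2, learningRate = 1e-12,
                                            ewcLambda = 0, batchSize = 4))
  drift <- max(vapply(1:4, function(s)
    max(abs(ad$backbone@weights[[s]]$W - b@weights[[s]]$W)), numeric(1)))
  expect_lt(drift, 1e-8)
})
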