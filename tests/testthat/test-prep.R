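test_that("loadScan rescales integer bit depths and averages channels", {
  d <- withr::local_tempdir()
  # 8-bit PNG, all white
  p1 <- file.path(d, "white.png")
  png::writePNG(matrix(1, 6, 6), p1, dpi = NULL)
  s1 <- loadScan(p1)
  expect_equal(unname(pixels(s1)), matrix(1, 6, 6))
  # 3-channel image with identical channels stays at v/255
  p2 <- file.path(d, "rgb.png")
  v <- 100 / 255
  png::writePNG(array(v, c(5, 4, 3)), p2)
  s2 <- loadScan(p2)
  expect_equal(unname(pixels(s2)), matrix(v, 5, 4), tolerance = 1e-6)
  # 16-bit TIFF: stored intensity equals value / 65535
  p3 <- file.path(d, "deep.tif")
  tiff::writeTIFF(matrix(32768 / 65535, 4, 4), p3, bits.per.sample = 16L)
  s3 <- loadScan(p3)
  expect_equal(pixels(s3)[1, 1], 32768 / 65535, tolerance = 1e-9)
  expect_error(loadScan(file.path(d, "absent.png")),
               class = "octanomaly_input_error")
})

test_that("removeMargins strips corner-touching margin lines only", {
  # all-gray: no white/black pixels at all -> unchanged
  s <- rawScan(matrix(0.5, 10, 10))
  out <- removeMargins(s)
  expect_identical(pixels(out), pixels(s))
  expect_identical(cropBox(out), c(0L, 10L, 0L, 10L))

  # leftmost 2 columns white (touching corners): per-column fraction 1 > 0.25
  px <- matrix(0.5, 8, 8); px[, 1:2] <- 1
  out <- removeMargins(rawScan(px), marginConfig(minSize = 4))
  expect_identical(dim(pixels(out)), c(8L, 6L))
  expect_identical(cropBox(out), c(0L, 8L, 2L, 8L))
  expect_true(all(pixels(out) == 0.5))

  # same margins but detached from corners: no corner component, no strip
  px2 <- matrix(0.5, 8, 8); px2[3:6, 1:2] <- 1
  expect_identical(pixels(removeMargins(rawScan(px2), marginConfig(minSize = 4))),
                   px2)

  # entirely white -> everything is margin
  expect_error(removeMargins(rawScan(matrix(1, 8, 8))),
               class = "octanomaly_input_error")
})

test_that("removeMargins is idempotent and returns a contiguous crop", {
  set.seed(41)
  for (i in 1:20) {
    px <- matrix(runif(40 * 48, 0.2, 0.8), 40, 48)
    w <- sample(2:6, 4, replace = TRUE)
    on <- runif(4) < 0.7
    col <- sample(c(0, 1), 1)
    if (on[1]) px[seq_len(w[1]), ] <- col
    if (on[2]) px[(41 - w[2]):40, ] <- col
    if (on[3]) px[, seq_len(w[3])] <- col
    if (on[4]) px[, (49 - w[4]):48] <- col
    cfg <- marginConfig(minSize = 8)
    once <- removeMargins(rawScan(px), cfg)
    twice <- removeMargins(once, cfg)
    expect_identical(pixels(twice), pixels(once))
    expect_identical(cropBox(twice), cropBox(once))
    b <- cropBox(once)   # surviving pixels are an untouched contiguous crop
    expect_identical(pixels(once),
                     px[(b[1] + 1):b[2], (b[3] + 1):b[4], drop = FALSE])
  }
})

test_that("prepareScan resizes bilinearly, replicates channels, standardizes", {
  # identity resize + zero-mean/unit-sd normalization reproduces the input
  px <- matrix(runif(64 * 64), 64, 64)
  p <- prepareScan(rawScan(px), prepConfig(64, channelMeans = rep(0, 3),
                                           channelStds = rep(1, 3)))
  for (ch in 1:3) expect_equal(p@tensor[, , ch], px)

  # centering a constant image gives an all-zero tensor
  pc <- prepareScan(rawScan(matrix(0.3, 64, 64)),
                    prepConfig(64, channelMeans = rep(0.3, 3),
                               channelStds = rep(1, 3)))
  expect_equal(max(abs(pc@tensor)), 0)

  # factor-2 reduction equals the exact 2x2 block-average oracle
  set.seed(5)
  big <- matrix(runif(128 * 128), 128, 128)
  blk <- 0.25 * (big[seq(1, 128, 2), seq(1, 128, 2)] +
                 big[seq(2, 128, 2), seq(1, 128, 2)] +
                 big[seq(1, 128, 2), seq(2, 128, 2)] +
                 big[seq(2, 128, 2), seq(2, 128, 2)])
  p2 <- prepareScan(rawScan(big), prepConfig(64, channelMeans = rep(0, 3),
                                             channelStds = rep(1, 3)))
  expect_equal(p2@tensor[, , 1], blk, tolerance = 1e-12)

  # standardization is invertible from the recorded constants
  p3 <- prepareScan(rawScan(px), prepConfig(64))
  rec <- p3@tensor[, , 2] * p3@channelStds[2] + p3@channelMeans[2]
  expect_equal(rec, px, tolerance = 1e-12)
})

test_that("transformMask survives crop and nearest-neighbour resize", {
  mask <- matrix(FALSE, 40, 40); mask[11:18, 21:28] <- TRUE
  tm <- transformMask(mask, c(4L, 36L, 4L, 36L), 64L)
  expect_identical(dim(tm), c(64L, 64L))
  # area scales roughly with the squared zoom factor (64/32)^2 = 4
  expect_gt(sum(tm), 4 * sum(mask) * 0.7)
  expect_lt(sum(tm), 4 * sum(mask) * 1.3)
})
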