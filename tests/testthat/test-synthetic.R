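test_that("scan generation is seeded and seed-sensitive", {
  cfg <- smallSynth()
  a <- generateNormalScan(cfg, 5)
  b <- generateNormalScan(cfg, 5)
  c <- generateNormalScan(cfg, 6)
  expect_identical(pixels(a), pixels(b))
  expect_false(identical(pixels(a), pixels(c)))
  expect_identical(scanLabel(a), "normal")
  expect_identical(dim(groundTruthMask(a)), c(0L, 0L))
})

test_that("without speckle every column crosses the layered plateaus", {
  cfg <- smallSynth(speckleShape = 1e6)   # speckle effectively off
  px <- pixels(generateNormalScan(cfg, 3))
  nPlateaus <- apply(px, 2, function(col) length(rle(round(col, 6))$lengths))
  # background + every band + sub-retinal region: piecewise constant
  expect_true(all(nPlateaus >= cfg$nLayers))
})

test_that("anomalies stay local to their masks and match their phenotype", {
  cfg <- smallSynth()
  for (kind in c("drusen", "dme", "cnv")) {
    for (seed in c(2, 9, 23)) {
      nm <- generateNormalScan(cfg, seed)
      an <- generateAnomalousScan(cfg, kind, seed)
      mask <- groundTruthMask(an)
      expect_identical(scanLabel(an), kind)
      expect_gt(sum(mask), 20)            # non-trivial lesion area
      expect_lt(sum(mask), 0.5 * length(mask))
      # pixels beyond a one-cell dilation of the mask match the normal twin
      # up to the mask tolerance (sub-tolerance halo pixels are unmasked)
      dil <- EBImage::dilate(EBImage::Image(mask * 1),
                             EBImage::makeBrush(3, "box")) > 0
      out <- abs(pixels(an) - pixels(nm))[!dil]
      expect_lte(max(out), cfg$maskTol)
    }
  }
  # fluid cavities are darker than the twin tissue they replace
  an <- generateAnomalousScan(cfg, "dme", 4)
  nm <- generateNormalScan(cfg, 4)
  m <- groundTruthMask(an)
  expect_lt(mean(pixels(an)[m]), mean(pixels(nm)[m]))
  expect_error(generateAnomalousScan(cfg, "vitreomacular", 1))
})

test_that("class-conditional intensity statistics are separable", {
  cfg <- smallSynth()
  # lesion-region intensities shift measurably against the matched region
  # of the normal twin (paired location shift across scans)
  for (kind in c("dme", "drusen", "cnv")) {
    shift <- vapply(1:50, function(i) {
      an <- generateAnomalousScan(cfg, kind, 500 + i)
      nm <- generateNormalScan(cfg, 500 + i)
      m <- groundTruthMask(an)
      mean(pixels(an)[m]) - mean(pixels(nm)[m])
    }, numeric(1))
    p <- stats::wilcox.test(shift)$p.value
    expect_lt(p, 1e-4)
  }
  # the fluid phenotype also darkens whole-scan intensity distributions
  nrmMean <- vapply(1:50, function(i)
    mean(pixels(generateNormalScan(cfg, 600 + i))), numeric(1))
  dmeMean <- vapply(1:50, function(i)
    mean(pixels(generateAnomalousScan(cfg, "dme", 600 + i))), numeric(1))
  expect_lt(stats::wilcox.test(dmeMean, nrmMean)$p.value, 0.01)
})

test_that("generateDataset writes a reproducible labelled tree", {
  d1 <- file.path(withr::local_tempdir(), "a")
  d2 <- file.path(withr::local_tempdir(), "b")
  m1 <- generateDataset(d1, smallSynth(), nTrain = 4, nTestPerClass = 2,
                        seed = 9)
  m2 <- generateDataset(d2, smallSynth(), nTrain = 4, nTestPerClass = 2,
                        seed = 9)
  expect_identical(nrow(m1), 4L + 4L * 2L)
  expect_identical(m1$path, m2$path)
  expect_identical(m1$seed, m2$seed)
  # byte-identical image files under the same master seed
  for (p in m1$path[c(1, 6, 10)])
    expect_identical(readBin(file.path(d1, p), "raw", 1e6),
                     readBin(file.path(d2, p), "raw", 1e6))
  expect_true(all(file.exists(file.path(d1, na.omit(m1$mask_path)))))
  # margin-free by default
  expect_true(all(m1[, c("margin_top", "margin_bottom",
                         "margin_left", "margin_right")] == 0))
  expect_true(file.exists(file.path(d1, "config.yaml")))
})

test_that("injected margins are solid and recorded, and strip exactly", {
  d <- withr::local_tempdir()
  m <- generateDataset(d, smallSynth(), nTrain = 10, nTestPerClass = 2,
                       marginProb = 1, seed = 31)
  withMargin <- m[rowSums(m[, c("margin_top", "margin_bottom",
                                "margin_left", "margin_right")]) > 0, ]
  expect_gt(nrow(withMargin), 0)
  cfg <- marginConfig(minSize = 16)
  for (i in seq_len(nrow(withMargin))) {
    row <- withMargin[i, ]
    scan <- loadScan(file.path(d, row$path))
    out <- removeMargins(scan, cfg)
    h <- nrow(pixels(scan)); w <- ncol(pixels(scan))
    expect_identical(cropBox(out),
                     c(row$margin_top, h - row$margin_bottom,
                       row$margin_left, w - row$margin_right))
    # idempotent on real generator output
    expect_identical(pixels(removeMargins(out, cfg)), pixels(out))
  }
})
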