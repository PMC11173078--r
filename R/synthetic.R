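#' Synthetic OCT B-scan configuration
#'
#' Seeded generator of OCT-B-scan-like images: stacked horizontal retinal
#' bands with smooth curved boundaries (random vertical offset and tilt, so
#' scans are unaligned and uncentered), multiplicative gamma speckle, and
#' three anomaly phenotypes with exact ground-truth masks. All pixel-scale
#' parameters are expressed at the reference size 224 and scale linearly
#' with `size`.
#'
#' @param size image side length before any margin injection. Default 224.
#' @param nLayers number of retinal bands. Default 6.
#' @param layerContrast contrast between alternating bands in (0, 1].
#'   Default 0.5 (bands at 0.35 / 0.65 before jitter).
#' @param speckleShape gamma shape of the multiplicative speckle (mean 1);
#'   larger means weaker noise. Default 4, the heavy speckle regime.
#' @param curvatureAmplitude amplitude in pixels of the sinusoidal boundary
#'   curvature at size 224. Default 6.
#' @param marginProb probability that a dataset scan receives white/black
#'   scanner margins. Default 0.
#' @param anomalyParams per-kind size/intensity ranges (pixels at size 224);
#'   see Details.
#' @param maskTol intensity change that marks a pixel as part of the
#'   ground-truth mask. Default 0.02 (above speckle quantization, below
#'   anomaly contrast).
#'
#' @details Anomaly phenotypes: `drusen` lifts the top boundary of the
#' bright outer band by a Gaussian bump (localized elevation); `dme`
#' carves a dark elliptical fluid cavity (intensity times `dim`) inside
#' the band stack; `cnv` scrambles the layer boundaries inside a window
#' and overlays a bright irregular blob (structural disruption).
#'
#' @return a named list.
#' @export
synthConfig <- function(size = 224L, nLayers = 6L, layerContrast = 0.5,
                        speckleShape = 4, curvatureAmplitude = 6,
                        marginProb = 0,
                        anomalyParams = list(
                          drusen = list(height = c(18, 36), sigma = c(12, 22),
                                        fill = 0.5),
                          dme = list(rx = c(14, 26), ry = c(8, 16), dim = 0.2),
                          cnv = list(width = c(40, 72), jag = c(10, 16),
                                     brighten = c(0.3, 0.5))),
                        maskTol = 0.02) {
  stopifnot(size >= 32, nLayers >= 2, layerContrast > 0, layerContrast <= 1,
            speckleShape > 0, marginProb >= 0, marginProb <= 1)
  list(size = as.integer(size), nLayers = as.integer(nLayers),
       layerContrast = layerContrast, speckleShape = speckleShape,
       curvatureAmplitude = curvatureAmplitude, marginProb = marginProb,
       anomalyParams = anomalyParams, maskTol = maskTol)
}

# running mean with edge replication (keeps length, no NAs); k forced odd
smoothVec <- function(x, k) {
  n <- length(x)
  k <- as.integer(k)
  if (k %% 2L == 0L) k <- k + 1L
  r <- (k - 1L) %/% 2L
  xp <- c(rep(x[1], r), x, rep(x[n], r))
  as.numeric(stats::filter(xp, rep(1 / k, k), sides = 2))[(r + 1L):(r + n)]
}

# draws layer geometry from the current RNG stream
drawGeometry <- function(cfg) {
  s <- cfg$size
  sc <- s / 224
  x <- seq_len(s)
  y0 <- runif(1, 0.40, 0.60) * s
  tilt <- runif(1, -0.12, 0.12)
  freq <- runif(1, 0.5, 1.5)
  phase <- runif(1, 0, 2 * pi)
  walk <- smoothVec(cumsum(rnorm(s, 0, 0.4 * sc)), max(3L, round(15 * sc)))
  shape <- cfg$curvatureAmplitude * sc * sin(2 * pi * freq * x / s + phase) +
    tilt * (x - s / 2) + (walk - mean(walk))
  th <- s * runif(cfg$nLayers, 0.030, 0.055)
  hi <- 0.5 + 0.3 * cfg$layerContrast
  lo <- 0.5 - 0.3 * cfg$layerContrast
  vals <- ifelse(seq_len(cfg$nLayers) %% 2L == 1L, hi, lo) +
    runif(cfg$nLayers, -0.04, 0.04)
  vals[cfg$nLayers] <- 0.78 + runif(1, -0.03, 0.03)  # bright outer (RPE) band
  B <- matrix(0, cfg$nLayers + 1L, s)
  B[1, ] <- y0 - sum(th) / 2 + shape
  for (l in seq_len(cfg$nLayers)) B[l + 1L, ] <- B[l, ] + th[l]
  list(B = B, vals = vals, bg = 0.12, below = 0.22)
}

# renders the noise-free band image from a boundary matrix
rasterBase <- function(cfg, geom, B = geom$B) {
  s <- cfg$size
  R <- matrix(seq_len(s), s, s)
  base <- matrix(geom$bg, s, s)
  for (l in seq_len(cfg$nLayers)) {
    top <- matrix(B[l, ], s, s, byrow = TRUE)
    bot <- matrix(B[l + 1L, ], s, s, byrow = TRUE)
    base[R >= top & R < bot] <- geom$vals[l]
  }
  base[R >= matrix(B[cfg$nLayers + 1L, ], s, s, byrow = TRUE)] <- geom$below
  base
}

# injects one anomaly phenotype into the base image; draws continue the
# RNG stream after geometry and speckle, so the normal twin is untouched
injectAnomaly <- function(cfg, geom, base, kind) {
  s <- cfg$size
  sc <- s / 224
  ap <- cfg$anomalyParams
  R <- matrix(seq_len(s), s, s)
  Cm <- matrix(seq_len(s), s, s, byrow = TRUE)
  xa <- round(runif(1, 0.2, 0.8) * s)
  if (kind == "drusen") {
    p <- ap$drusen
    h <- runif(1, p$height[1], p$height[2]) * sc
    sg <- runif(1, p$sigma[1], p$sigma[2]) * sc
    bump <- h * exp(-((seq_len(s) - xa)^2) / (2 * sg^2))
    bump[bump < 0.05] <- 0              # exact locality away from the dome
    B2 <- geom$B
    # the bright outer (RPE) band rides over a dome; the space between the
    # lifted band and the flat original baseline fills with drusenoid
    # material of medium reflectivity
    B2[cfg$nLayers, ] <- B2[cfg$nLayers, ] - bump
    B2[cfg$nLayers + 1L, ] <- B2[cfg$nLayers + 1L, ] - bump
    out <- rasterBase(cfg, geom, B2)
    fill <- R >= matrix(B2[cfg$nLayers + 1L, ], s, s, byrow = TRUE) &
            R < matrix(geom$B[cfg$nLayers + 1L, ], s, s, byrow = TRUE)
    out[fill] <- p$fill
    out
  } else if (kind == "dme") {
    p <- ap$dme
    rx <- runif(1, p$rx[1], p$rx[2]) * sc
    ry <- runif(1, p$ry[1], p$ry[2]) * sc
    yc <- (geom$B[2, xa] + geom$B[cfg$nLayers, xa]) / 2
    ell <- ((Cm - xa) / rx)^2 + ((R - yc) / ry)^2 <= 1
    out <- base
    out[ell] <- out[ell] * p$dim            # dark fluid cavity
    out
  } else if (kind == "cnv") {
    p <- ap$cnv
    w <- round(runif(1, p$width[1], p$width[2]) * sc)
    jag <- runif(1, p$jag[1], p$jag[2]) * sc
    cols <- max(1L, xa - w %/% 2L):min(s, xa + w %/% 2L)
    B2 <- geom$B
    for (l in 2:(cfg$nLayers + 1L)) {
      pert <- smoothVec(rnorm(length(cols), 0, jag), max(3L, round(5 * sc)))
      # taper to zero at the window edges so boundaries stay continuous
      taper <- sin(pi * (seq_along(cols) - 0.5) / length(cols))
      B2[l, cols] <- B2[l, cols] + pert * taper
    }
    out <- rasterBase(cfg, geom, B2)
    yc <- (geom$B[2, xa] + geom$B[cfg$nLayers + 1L, xa]) / 2
    rb <- runif(1, 10, 18) * sc
    ell <- ((Cm - xa) / rb)^2 + ((R - yc) / (0.7 * rb))^2 <= 1
    blobNoise <- matrix(runif(s * s), s, s)
    blob <- ell & smoothVec2(blobNoise, max(3L, round(5 * sc))) > 0.45
    amp <- runif(1, p$brighten[1], p$brighten[2])
    out[blob] <- pmin(out[blob] + amp, 0.95)  # bright neovascular tissue
    out
  } else stopInput("unknown anomaly kind '%s'", kind)
}

# separable box smoothing of a matrix (used for irregular blob shapes)
smoothVec2 <- function(m, k) {
  t(apply(apply(m, 2, smoothVec, k = k), 1, smoothVec, k = k))
}

# scanner noise floor: real OCT exports never contain true zeros, so the
# black margin threshold (0.04) uniquely identifies injected margins
synthFloor <- 0.05

clampScan <- function(x) pmin(pmax(x, synthFloor), 1)

# shared deterministic core: geometry, speckle field, normal base
synthCore <- function(cfg, seed) {
  withSeed(seed, {
    geom <- drawGeometry(cfg)
    noise <- matrix(rgamma(cfg$size^2, shape = cfg$speckleShape,
                           rate = cfg$speckleShape), cfg$size, cfg$size)
    list(geom = geom, noise = noise, base = rasterBase(cfg, geom),
         rng = get(".Random.seed", envir = globalenv()))
  })
}

#' Generate a healthy synthetic B-scan
#'
#' Fully determined by `(cfg, seed)`: layered bands with curved, tilted,
#' vertically offset boundaries under multiplicative gamma speckle.
#'
#' @param cfg a [synthConfig()] list.
#' @param seed integer seed.
#' @param id optional source identifier.
#' @return a [SynthScan-class] with label `"normal"` and an empty mask.
#' @export
generateNormalScan <- function(cfg = synthConfig(), seed = 0L,
                               id = sprintf("normal_%06d", seed)) {
  core <- synthCore(cfg, seed)
  img <- clampScan(core$base * core$noise)
  new("SynthScan",
      scan = new("OCTScan", pixels = img, sourceId = id,
                 cropBox = c(0L, nrow(img), 0L, ncol(img))),
      label = "normal", mask = matrix(logical(0), 0L, 0L),
      seed = as.integer(seed))
}

#' Generate an anomalous synthetic B-scan with its ground-truth mask
#'
#' Starts from the normal twin of the same seed (identical geometry and
#' speckle field) and injects one phenotype; the mask marks pixels whose
#' intensity changed by more than `maskTol`, so the scan differs from its
#' twin only inside (a thin halo around) the mask.
#'
#' @param cfg a [synthConfig()] list.
#' @param kind `"drusen"`, `"dme"` or `"cnv"`.
#' @param seed integer seed.
#' @param id optional source identifier.
#' @return a [SynthScan-class].
#' @export
generateAnomalousScan <- function(cfg = synthConfig(),
                                  kind = c("drusen", "dme", "cnv"),
                                  seed = 0L,
                                  id = sprintf("%s_%06d", kind[1], seed)) {
  kind <- match.arg(kind)
  core <- synthCore(cfg, seed)
  base2 <- withSeed(seed, {
    assign(".Random.seed", core$rng, envir = globalenv())
    injectAnomaly(cfg, core$geom, core$base, kind)
  })
  img1 <- clampScan(core$base * core$noise)
  img2 <- clampScan(base2 * core$noise)
  mask <- abs(img2 - img1) > cfg$maskTol
  new("SynthScan",
      scan = new("OCTScan", pixels = img2, sourceId = id,
                 cropBox = c(0L, nrow(img2), 0L, ncol(img2))),
      label = kind, mask = mask, seed = as.integer(seed))
}

# overwrite border bands with a constant margin color; returns the new
# pixels and the injected widths (top, bottom, left, right)
applyMargins <- function(px, widths, color) {
  h <- nrow(px); w <- ncol(px)
  if (widths[1] > 0) px[seq_len(widths[1]), ] <- color
  if (widths[2] > 0) px[(h - widths[2] + 1L):h, ] <- color
  if (widths[3] > 0) px[, seq_len(widths[3])] <- color
  if (widths[4] > 0) px[, (w - widths[4] + 1L):w] <- color
  px
}

#' Generate a labelled synthetic dataset on disk
#'
#' Writes `train/normal/*.png`, `test/{normal,cnv,dme,drusen}/*.png`,
#' binary masks under `test_masks/`, a CSV manifest and a YAML echo of the
#' resolved configuration. Per-scan seeds are derived deterministically
#' from the master seed, so two runs with the same arguments are
#' byte-identical. With probability `marginProb` a scan's borders are
#' overwritten with solid white or black scanner margins (recorded in the
#' manifest), exercising margin removal downstream.
#'
#' @param outDir output directory (created if needed).
#' @param cfg a [synthConfig()] list.
#' @param nTrain number of healthy training scans.
#' @param nTestPerClass test scans per anomalous class.
#' @param nTestNormal normal test scans; defaults to `nTestPerClass`.
#' @param marginProb overrides `cfg$marginProb` when not `NULL`.
#' @param seed master seed.
#' @return the manifest `data.frame`, invisibly written to
#'   `manifest.csv`.
#' @export
generateDataset <- function(outDir, cfg = synthConfig(), nTrain = 10L,
                            nTestPerClass = 5L,
                            nTestNormal = nTestPerClass,
                            marginProb = NULL, seed = 0L) {
  stopifnot(nTrain >= 1, nTestPerClass >= 1, nTestNormal >= 1)
  if (is.null(marginProb)) marginProb <- cfg$marginProb
  classes <- c("normal", "cnv", "dme", "drusen")
  total <- nTrain + nTestNormal + 3L * nTestPerClass
  draws <- withSeed(seed, list(
    seeds = sample.int(2147483646L, total),
    margin = runif(total) < marginProb,
    color = sample(c(0, 1), total, replace = TRUE),
    sides = matrix(runif(total * 4) < 0.5, total, 4L),
    widths = matrix(sample(seq(8L, 16L), total * 4L, replace = TRUE),
                    total, 4L)))
  sc <- cfg$size / 224
  for (d in c(file.path(outDir, "train", "normal"),
              file.path(outDir, "test", classes),
              file.path(outDir, "test_masks")))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", total)
  idx <- 0L
  emit <- function(split, label, i) {
    idx <<- idx + 1L
    sd <- draws$seeds[idx]
    id <- sprintf("%s_%04d", label, i)
    ss <- if (label == "normal") generateNormalScan(cfg, sd, id)
          else generateAnomalousScan(cfg, label, sd, id)
    px <- pixels(ss)
    widths <- rep(0L, 4L)
    if (draws$margin[idx]) {
      on <- draws$sides[idx, ]
      if (!any(on)) on[1] <- TRUE
      widths <- as.integer(ifelse(on, pmax(2L, round(draws$widths[idx, ] * sc)),
                                  0L))
      px <- applyMargins(px, widths, draws$color[idx])
    }
    rel <- file.path(split, label, paste0(id, ".png"))
    png::writePNG(px, file.path(outDir, rel))
    maskRel <- NA_character_
    if (label != "normal") {
      maskRel <- file.path("test_masks", paste0(id, ".png"))
      png::writePNG(groundTruthMask(ss) * 1, file.path(outDir, maskRel))
    }
    rows[[idx]] <<- data.frame(
      path = rel, label = label, seed = sd, mask_path = maskRel,
      margin_top = widths[1], margin_bottom = widths[2],
      margin_left = widths[3], margin_right = widths[4],
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nTrain)) emit("train", "normal", i)
  for (cl in classes)
    for (i in seq_len(if (cl == "normal") nTestNormal else nTestPerClass))
      emit("test", cl, i)
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                   row.names = FALSE)
  yaml::write_yaml(cfg, file.path(outDir, "config.yaml"))
  invisible(manifest)
}
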