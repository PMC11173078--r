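#' Margin-removal configuration
#'
#' Scanner exports often frame the B-scan with solid white or black bands.
#' A pixel is called white when its intensity is at least `whiteThreshold`
#' and black when at most `blackThreshold`; a boundary row or column is
#' stripped when more than `lineFraction` of its pixels are white-or-black
#' (the "more than a quarter" rule at the default 0.25), and stripping is
#' attempted only when a white/black connected component touches an image
#' corner.
#'
#' @param whiteThreshold intensity in (0, 1] above which a pixel counts as
#'   white margin. Default 0.96.
#' @param blackThreshold intensity in [0, 1) below which a pixel counts as
#'   black margin. Default 0.04.
#' @param lineFraction fraction of margin pixels a boundary line must exceed
#'   to be stripped. Default 0.25.
#' @param maxPasses maximum alternations of re-binarize / strip. Default 4.
#' @param minSize smallest height/width allowed after cropping. Default 32.
#' @return a named list.
#' @export
marginConfig <- function(whiteThreshold = 0.96, blackThreshold = 0.04,
                         lineFraction = 0.25, maxPasses = 4L, minSize = 32L) {
  stopifnot(whiteThreshold > 0, whiteThreshold <= 1,
            blackThreshold >= 0, blackThreshold < whiteThreshold,
            lineFraction > 0, lineFraction < 1, maxPasses >= 1, minSize >= 1)
  list(whiteThreshold = whiteThreshold, blackThreshold = blackThreshold,
       lineFraction = lineFraction, maxPasses = as.integer(maxPasses),
       minSize = as.integer(minSize))
}

#' Preparation configuration
#'
#' @param targetSize side length of the square backbone input; must be a
#'   multiple of 16 so the four stride-2 backbone stages divide evenly.
#'   Default 224.
#' @param channelMeans,channelStds per-channel standardization constants;
#'   defaults are the ImageNet statistics used by pretrained backbones.
#' @param replicateChannels replicate the grayscale plane into 3 channels.
#' @return a named list.
#' @export
prepConfig <- function(targetSize = 224L,
                       channelMeans = c(0.485, 0.456, 0.406),
                       channelStds = c(0.229, 0.224, 0.225),
                       replicateChannels = TRUE) {
  stopifnot(targetSize >= 32, targetSize %% 16 == 0,
            length(channelMeans) == 3, length(channelStds) == 3,
            all(channelStds > 0))
  list(targetSize = as.integer(targetSize), channelMeans = channelMeans,
       channelStds = channelStds, replicateChannels = replicateChannels)
}

#' Load a grayscale scan from disk
#'
#' Reads PNG, JPEG or TIFF. Multi-channel images are converted to grayscale
#' by channel averaging; integer bit depths are rescaled to `[0, 1]` by the
#' full type range (the underlying readers already do this: 8-bit by 255,
#' 16-bit by 65535).
#'
#' @param path path to an image file.
#' @return an [OCTScan-class].
#' @export
loadScan <- function(path) {
  if (!file.exists(path) || file.size(path) == 0)
    stopInput("cannot read scan: '%s' is missing or empty", path)
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch(switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    jpg  = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stopInput("JPEG support requires the 'jpeg' package")
      jpeg::readJPEG(path)
    },
    stopInput("unsupported image format '%s' for '%s'", ext, path)),
    error = function(e) stopInput("cannot decode '%s': %s", path,
                                  conditionMessage(e)))
  if (length(dim(img)) == 3L) {
    # drop a pure alpha channel if present, then average the color channels
    if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
    img <- rowMeans(img, dims = 2L)
  }
  img <- clamp01(img)
  new("OCTScan", pixels = img,
      sourceId = tools::file_path_sans_ext(basename(path)),
      cropBox = c(0L, nrow(img), 0L, ncol(img)))
}

# fraction of white-or-black pixels per row / per column of a logical mask
marginMask <- function(px, cfg) px >= cfg$whiteThreshold | px <= cfg$blackThreshold

# length of the maximal contiguous run of TRUE at the start of a vector
leadingRun <- function(flag) {
  if (!length(flag) || !flag[1]) return(0L)
  w <- which(!flag)
  if (!length(w)) length(flag) else w[1] - 1L
}

#' Remove white/black scanner margins
#'
#' Binarizes the scan into white/black margin pixels, and, only when a
#' margin component touches an image corner (a connected component contains
#' a corner pixel exactly when that corner pixel is itself white or black),
#' repeatedly strips maximal contiguous boundary rows and columns whose
#' white-or-black fraction exceeds `lineFraction`. The mask is re-binarized
#' between passes, for at most `maxPasses` passes. Only boundary lines are
#' ever removed, so the output is a contiguous crop with all surviving
#' pixel values unchanged.
#'
#' @param scan an [OCTScan-class].
#' @param cfg a [marginConfig()] list.
#' @return the cropped [OCTScan-class] with an updated `cropBox`.
#' @export
removeMargins <- function(scan, cfg = marginConfig()) {
  px <- scan@pixels
  r0 <- 0L; c0 <- 0L                    # offset of current crop, 0-based
  for (pass in seq_len(cfg$maxPasses)) {
    m <- marginMask(px, cfg)
    h <- nrow(m); w <- ncol(m)
    corners <- m[1, 1] || m[1, w] || m[h, 1] || m[h, w]
    if (!corners) break
    rowFrac <- rowMeans(m); colFrac <- colMeans(m)
    top    <- leadingRun(rowFrac > cfg$lineFraction)
    bottom <- leadingRun(rev(rowFrac) > cfg$lineFraction)
    if (top + bottom >= h)
      stopInput("'%s': entire scan is margin", scan@sourceId)
    keepR <- (top + 1L):(h - bottom)
    colFrac <- colMeans(m[keepR, , drop = FALSE])
    left  <- leadingRun(colFrac > cfg$lineFraction)
    right <- leadingRun(rev(colFrac) > cfg$lineFraction)
    if (left + right >= w)
      stopInput("'%s': entire scan is margin", scan@sourceId)
    if (top + bottom + left + right == 0L) break
    px <- px[keepR, (left + 1L):(w - right), drop = FALSE]
    r0 <- r0 + top; c0 <- c0 + left
    if (nrow(px) < cfg$minSize || ncol(px) < cfg$minSize)
      stopInput("'%s': margin removal left %d x %d, below the minimum %d",
                scan@sourceId, nrow(px), ncol(px), cfg$minSize)
  }
  base <- scan@cropBox
  new("OCTScan", pixels = px, sourceId = scan@sourceId,
      cropBox = c(base[1] + r0, base[1] + r0 + nrow(px),
                  base[3] + c0, base[3] + c0 + ncol(px)))
}

#' Resize and standardize a scan for the backbone
#'
#' Bilinear resize to `targetSize` x `targetSize`, replication of the
#' grayscale plane into 3 channels, and per-channel standardization
#' `(x - mean) / std`. Margin removal is expected to have been applied
#' beforehand (or deliberately skipped).
#'
#' @param scan an [OCTScan-class].
#' @param cfg a [prepConfig()] list.
#' @return a [PreparedScan-class].
#' @export
prepareScan <- function(scan, cfg = prepConfig()) {
  s <- cfg$targetSize
  px <- scan@pixels
  if (nrow(px) != s || ncol(px) != s)
    px <- EBImage::imageData(EBImage::resize(EBImage::Image(px), w = s,
                                             h = s, filter = "bilinear"))
  nch <- if (cfg$replicateChannels) 3L else 3L  # backbone contract is 3-channel
  tensor <- array(0, c(s, s, nch))
  for (ch in seq_len(nch))
    tensor[, , ch] <- (px - cfg$channelMeans[ch]) / cfg$channelStds[ch]
  new("PreparedScan", tensor = tensor, sourceId = scan@sourceId,
      cropBox = scan@cropBox, channelMeans = cfg$channelMeans,
      channelStds = cfg$channelStds)
}

#' Map a pixel mask through crop and resize
#'
#' Transforms a ground-truth mask given in original image coordinates into
#' prepared-image coordinates (crop to `cropBox`, then nearest-neighbour
#' resize to `targetSize`), so localization can be evaluated against score
#' grids and heat maps.
#'
#' @param mask logical matrix in original coordinates.
#' @param cropBox integer(4) 0-based half-open crop box.
#' @param targetSize side length of the prepared image.
#' @return logical `(targetSize, targetSize)` matrix.
#' @export
transformMask <- function(mask, cropBox, targetSize) {
  sub <- mask[(cropBox[1] + 1L):cropBox[2], (cropBox[3] + 1L):cropBox[4],
              drop = FALSE]
  h <- nrow(sub); w <- ncol(sub)
  ri <- pmin(pmax(ceiling((seq_len(targetSize) - 0.5) * h / targetSize), 1L), h)
  ci <- pmin(pmax(ceiling((seq_len(targetSize) - 0.5) * w / targetSize), 1L), w)
  sub[ri, ci, drop = FALSE]
}
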