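# internal helpers shared across modules

# evaluate expr under a temporary RNG state seeded with `seed`;
# the caller's RNG stream is untouched
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# derive a child seed from a master seed; stays below 2^31
deriveSeed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 9973) %% 2147483629)
}

stopInput <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("octanomaly_input_error", "error")))
}

stopConfig <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("octanomaly_config_error", "error")))
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# nearest-neighbour upsampling of a (h, w, C) array by integer factor f:
# coarse vectors are copied, never blended
upsampleNearest <- function(x, f) {
  x[rep(seq_len(dim(x)[1]), each = f),
    rep(seq_len(dim(x)[2]), each = f), , drop = FALSE]
}

# edge-padded local average pooling with an odd kernel, stride 1
localAvgPool <- function(x, kernel) {
  if (kernel == 1L) return(x)
  stopifnot(kernel %% 2L == 1L)
  h <- dim(x)[1]; w <- dim(x)[2]
  r <- (kernel - 1L) %/% 2L
  out <- array(0, dim(x))
  for (di in -r:r) {
    ri <- pmin(pmax(seq_len(h) + di, 1L), h)
    for (dj in -r:r) {
      cj <- pmin(pmax(seq_len(w) + dj, 1L), w)
      out <- out + x[ri, cj, , drop = FALSE]
    }
  }
  out / (kernel * kernel)
}
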