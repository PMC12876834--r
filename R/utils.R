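# Shared internal helpers: seeded evaluation, image resampling, small hashes.
# Pixel conventions used throughout the package: images are numeric arrays
# dim c(H, W, 3) with values in [0, 1]; masks are logical H x W matrices.
# Continuous coordinates are 0-based and y-down: pixel (row r, col c) covers
# the square [c-1, c] x [r-1, r] and has center (c - 0.5, r - 0.5).

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a stream-specific 31-bit seed from a master seed and a label.
derive_seed <- function(seed, label) {
  h <- seed %% 2147483647
  for (b in utf8ToInt(as.character(label)))
    h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

# Stable small hash of a config (used to stamp output files).
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  h <- 17
  for (b in utf8ToInt(as.character(s)))
    h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Resample an image or matrix by bilinear interpolation
#'
#' Maps output pixel centers to input pixel-center coordinates (edge-clamped),
#' the standard convention for physical-scale resampling.
#'
#' @param img numeric matrix or H x W x C array.
#' @param oh,ow output height and width in pixels.
#' @return resampled matrix or array of dim `c(oh, ow, C)`.
#' @keywords internal
resize_bilinear <- function(img, oh, ow) {
  if (length(dim(img)) == 3L) {
    out <- array(0, c(oh, ow, dim(img)[3]))
    for (c in seq_len(dim(img)[3]))
      out[, , c] <- resize_bilinear(img[, , c], oh, ow)
    return(out)
  }
  ih <- nrow(img); iw <- ncol(img)
  if (ih == oh && iw == ow) return(img)
  sy <- (seq_len(oh) - 0.5) * ih / oh - 0.5
  sx <- (seq_len(ow) - 0.5) * iw / ow - 0.5
  y0 <- pmin(pmax(floor(sy), 0), ih - 1)
  x0 <- pmin(pmax(floor(sx), 0), iw - 1)
  y1 <- pmin(y0 + 1, ih - 1)
  x1 <- pmin(x0 + 1, iw - 1)
  wy <- pmin(pmax(sy - y0, 0), 1)
  wx <- pmin(pmax(sx - x0, 0), 1)
  outer(1 - wy, 1 - wx) * img[y0 + 1, x0 + 1, drop = FALSE] +
    outer(1 - wy, wx) * img[y0 + 1, x1 + 1, drop = FALSE] +
    outer(wy, 1 - wx) * img[y1 + 1, x0 + 1, drop = FALSE] +
    outer(wy, wx) * img[y1 + 1, x1 + 1, drop = FALSE]
}

# Nearest-neighbour resampling; keeps masks binary.
resize_nearest <- function(m, oh, ow) {
  if (length(dim(m)) == 3L) {
    out <- array(0, c(oh, ow, dim(m)[3]))
    for (c in seq_len(dim(m)[3])) out[, , c] <- resize_nearest(m[, , c], oh, ow)
    return(out)
  }
  ih <- nrow(m); iw <- ncol(m)
  ri <- pmin(pmax(ceiling((seq_len(oh) - 0.5) * ih / oh), 1), ih)
  ci <- pmin(pmax(ceiling((seq_len(ow) - 0.5) * iw / ow), 1), iw)
  m[ri, ci, drop = FALSE]
}

# Exact block averaging by an integer factor (f must divide both dims).
block_mean <- function(m, f) {
  h <- nrow(m); w <- ncol(m)
  stopifnot(h %% f == 0, w %% f == 0)
  m2 <- matrix(colMeans(matrix(m, nrow = f)), nrow = h %/% f)
  t(matrix(colMeans(matrix(t(m2), nrow = f)), nrow = w %/% f))
}

# Downsample an RGB array by block mean with integer factor.
block_mean_rgb <- function(img, f) {
  out <- array(0, c(nrow(img) %/% f, ncol(img) %/% f, dim(img)[3]))
  for (c in seq_len(dim(img)[3])) out[, , c] <- block_mean(img[, , c], f)
  out
}

# Resize an RGB tile to a square side `px`, averaging when shrinking by an
# exact integer factor (anti-aliased) and bilinear otherwise.
shrink_tile <- function(img, px) {
  h <- dim(img)[1]
  if (h == px) return(img)
  if (h %% px == 0) block_mean_rgb(img, h %/% px) else
    resize_bilinear(img, px, px)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

`%||%` <- function(a, b) if (is.null(a)) b else a
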