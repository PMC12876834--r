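# File I/O: 8-bit RGB PNG images, single-channel 0/255 mask PNGs, and CSV
# tables stamped with the run's config hash and seed.

#' Write an RGB image or binary mask as PNG
#'
#' Images (H x W x 3 in \[0,1\]) become 8-bit RGB; masks (logical/0-1
#' matrices) become single-channel 0/255.
#'
#' @param x image array or mask matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_image <- function(x, path) {
  if (is.logical(x) || is.matrix(x)) {
    png::writePNG(matrix(as.numeric(x != 0), nrow(x), ncol(x)), path)
  } else {
    png::writePNG(clamp01(x), path)
  }
  invisible(path)
}

#' Read a PNG image
#'
#' @param path PNG file.
#' @param as_mask threshold a single-channel image at 0.5 into a logical
#'   mask.
#' @return H x W x 3 array in \[0,1\], or a logical matrix when `as_mask`.
#' @export
read_image <- function(path, as_mask = FALSE) {
  x <- png::readPNG(path)
  if (as_mask) {
    if (length(dim(x)) == 3) x <- x[, , 1]
    return(x >= 0.5)
  }
  if (length(dim(x)) == 2) x <- array(rep(x, 3), c(dim(x), 3))
  if (dim(x)[3] > 3) x <- x[, , 1:3]
  x
}

# CSV with a "# zebrascore ..." stamp line; read back with
# read.csv(comment.char = "#").
write_stamped_csv <- function(df, path, stamp) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# zebrascore ", stamp), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}
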