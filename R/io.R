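# Image I/O: 8-bit grayscale PNG for images, 0/255 PNG for masks.

#' Write a grayscale image as 8-bit PNG
#'
#' @param image Numeric matrix with values in `[0, 1]`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_gray_png <- function(image, path) {
  stopifnot(is.matrix(image))
  png::writePNG(pmin(pmax(image, 0), 1), target = path)
  invisible(path)
}

#' Read a grayscale PNG (or the luminance of an RGB PNG)
#'
#' @param path PNG file path.
#' @return Numeric matrix in `[0, 1]`.
#' @export
read_gray_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) {
    # average color channels, drop alpha
    nc <- min(dim(x)[3], 3L)
    x <- apply(x[, , seq_len(nc), drop = FALSE], c(1, 2), mean)
  }
  x
}

#' Write a binary mask as 0/255 PNG
#'
#' @param mask Logical (or 0/1 numeric) matrix.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG((mask * 1) * 1.0, target = path)
  invisible(path)
}

#' Read a 0/255 mask PNG as a logical matrix
#'
#' @param path PNG file path.
#' @return Logical matrix.
#' @export
read_mask_png <- function(path) {
  read_gray_png(path) > 0.5
}

#' Write a region partition as a colored PNG
#'
#' Background is black; regions I..k ramp from cool to warm colors so the
#' nested structure is visible at a glance. Raw labels go in a companion CSV
#' if `csv_path` is given.
#'
#' @param partition A [segment_equal_areas()] result.
#' @param path Output PNG path.
#' @param csv_path Optional path for the raw integer label raster as CSV.
#' @return Invisibly, `path`.
#' @export
write_partition_png <- function(partition, path, csv_path = NULL) {
  labels <- partition$labels
  k <- max(labels)
  pal <- grDevices::col2rgb(c("black", grDevices::hcl.colors(k, "Zissou 1"))) / 255
  rgb <- array(0, c(nrow(labels), ncol(labels), 3))
  for (ch in 1:3) {
    rgb[, , ch] <- matrix(pal[ch, labels + 1L], nrow(labels), ncol(labels))
  }
  png::writePNG(rgb, target = path)
  if (!is.null(csv_path)) {
    utils::write.table(labels, csv_path, sep = ",",
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
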