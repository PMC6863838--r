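#' Single-channel image with physical pixel size
#'
#' The universal carrier for one channel of a 2-D fluorescence image:
#' a numeric intensity matrix (rows = y, columns = x) together with the
#' pixel size in micrometres per pixel.
#'
#' @param data Numeric matrix of intensities (arbitrary units).
#' @param pixel_size_um Pixel size in micrometres per pixel; must be > 0.
#' @param channel Optional channel name (e.g. `"ddr1"`, `"collagen"`, `"py"`).
#' @return An object of class `image_plane`: a list with elements `data`,
#'   `pixel_size_um` and `channel`.
#' @examples
#' img <- image_plane(matrix(rnorm(64 * 64), 64), pixel_size_um = 0.1)
#' dim(img)
#' @export
image_plane <- function(data, pixel_size_um, channel = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      is.na(pixel_size_um) || pixel_size_um <= 0) {
    stop("pixel_size_um must be a single positive number", call. = FALSE)
  }
  structure(
    list(data = data, pixel_size_um = pixel_size_um, channel = channel),
    class = "image_plane"
  )
}

#' @export
dim.image_plane <- function(x) dim(x$data)

#' @export
print.image_plane <- function(x, ...) {
  cat(sprintf(
    "<image_plane%s> %d x %d px, %.4g um/px, intensity range [%.4g, %.4g]\n",
    if (is.null(x$channel)) "" else paste0(" ", x$channel),
    nrow(x$data), ncol(x$data), x$pixel_size_um,
    min(x$data), max(x$data)
  ))
  invisible(x)
}
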