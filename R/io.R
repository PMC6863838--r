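#' Read a (multi-page) TIFF into image planes
#'
#' Intensities are returned as doubles on their native scale (the tiff
#' package's 0--1 scaling is undone for 8/16-bit data). Pixel size is taken
#' from a JSON sidecar (`<path>.json` or the file with `.tif(f)` replaced by
#' `.json`, key `pixel_size_um`), falling back to the `pixel_size_um`
#' argument; if neither is available the call fails.
#'
#' @param path TIFF file (single or multi-page; 8/16-bit or float).
#' @param pixel_size_um Fallback pixel size (um/px).
#' @param channels Optional channel names for the pages.
#' @return A named list of [image_plane()]s (single-page files return a
#'   one-element list).
#' @export
read_image <- function(path, pixel_size_um = NULL, channels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  sidecars <- c(paste0(path, ".json"),
                sub("\\.tiff?$", ".json", path, ignore.case = TRUE))
  meta <- NULL
  for (sc in unique(sidecars)) {
    if (file.exists(sc)) {
      meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
      break
    }
  }
  if (!is.null(meta) && !is.null(meta$pixel_size_um)) {
    pixel_size_um <- meta$pixel_size_um
  }
  if (is.null(pixel_size_um)) {
    stop("pixel size unknown: no sidecar metadata and no pixel_size_um ",
         "argument", call. = FALSE)
  }
  if (is.null(channels) && !is.null(meta) && !is.null(meta$channels)) {
    channels <- meta$channels
  }
  if (is.null(channels)) {
    channels <- if (length(pages) == 1) "channel1" else
      paste0("channel", seq_along(pages))
  }
  stopifnot(length(channels) == length(pages))
  scale <- if (!is.null(meta) && is.numeric(meta$intensity_scale)) {
    meta$intensity_scale
  } else {
    1
  }
  offset <- if (!is.null(meta) && is.numeric(meta$intensity_offset)) {
    meta$intensity_offset
  } else {
    0
  }
  out <- lapply(seq_along(pages), function(i) {
    p <- pages[[i]]
    bits <- attr(p, "bits.per.sample")
    attributes(p) <- list(dim = dim(p))   # drop TIFF tag attributes
    storage.mode(p) <- "double"
    v <- if (!is.null(meta) && is.numeric(meta$intensity_scale)) {
      p * scale + offset          # float data written by write_image()
    } else if (!is.null(bits) && bits %in% c(8L, 16L)) {
      round(p * (2^bits - 1))     # back to native integer counts
    } else {
      p
    }
    image_plane(v, pixel_size_um, channel = channels[i])
  })
  names(out) <- channels
  out
}

#' Write image planes as a (multi-page) TIFF with a JSON sidecar
#'
#' @param planes An [image_plane()] or list of them (one page each).
#' @param path Output TIFF path; a sidecar `<path>.json` records pixel size
#'   and channel names.
#' @param bits 16 (integer data, bit-exact round trip for values in
#'   0..65535) or 32 (IEEE float samples).
#' @return `path`, invisibly.
#' @export
write_image <- function(planes, path, bits = 16L) {
  if (inherits(planes, "image_plane")) planes <- list(planes)
  stopifnot(bits %in% c(16L, 32L))
  px <- planes[[1]]$pixel_size_um
  chans <- vapply(seq_along(planes), function(i) {
    nm <- planes[[i]]$channel
    if (is.null(nm)) paste0("channel", i) else nm
  }, character(1))
  # TIFF samples live on a 0-1 scale: 16-bit data are divided by 65535
  # (bit-exact for integer intensities); floats are affinely mapped with
  # the offset/scale recorded in the sidecar
  if (bits == 32L) {
    lo <- min(vapply(planes, function(p) min(p$data), numeric(1)))
    hi <- max(vapply(planes, function(p) max(p$data), numeric(1)))
    scale <- max(hi - lo, 1e-12)
    offset <- lo
  } else {
    scale <- 65535
    offset <- 0
  }
  pages <- lapply(planes, function(p) (p$data - offset) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = bits, reduce = FALSE)
  meta <- list(pixel_size_um = px, channels = chans)
  if (bits == 32L) {
    meta$intensity_scale <- scale
    meta$intensity_offset <- offset
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write a synthetic scene to disk
#'
#' Channels go to a multi-page float TIFF; the configuration and a truth
#' summary (texture class, characteristic length, centreline coordinate
#' lists) to a JSON sidecar.
#'
#' @param scene A `scene`.
#' @param dir Output directory (created if needed).
#' @param name Base file name (default `"scene"`).
#' @return Paths of the files written, invisibly.
#' @export
write_scene <- function(scene, dir, name = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tif <- file.path(dir, paste0(name, ".tif"))
  write_image(scene$channels, tif, bits = 32L)
  truth <- list(
    config = unclass(scene$config),
    char_length_um = scene$truth$char_length_um,
    cell_area_px = sum(scene$truth$cell_mask),
    centrelines = lapply(scene$truth$structure_centrelines, function(m) {
      list(row = m[, 1], col = m[, 2])
    })
  )
  js <- file.path(dir, paste0(name, "_truth.json"))
  jsonlite::write_json(truth, js, auto_unbox = TRUE, digits = NA)
  invisible(c(tif, js))
}
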