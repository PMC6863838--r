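# Binary morphology with a fixed 3x3 square structuring element and
# outside-the-frame treated as background — the ImageJ binary-process
# semantics the cell-mask pipeline is defined against.

dilate3_ <- function(m) {
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- out | shift_mat_(m, dr, dc, FALSE)
  }
  out
}

erode3_ <- function(m) {
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- out & shift_mat_(m, dr, dc, FALSE)
  }
  out
}

# Fill holes: background components (4-connected) not reachable from the
# frame border become foreground. Morphological reconstruction of the
# border-connected background by iterated 4-neighbour propagation.
fill_holes_ <- function(m) {
  bg <- !m
  reach <- matrix(FALSE, nrow(m), ncol(m))
  reach[1, ] <- bg[1, ]; reach[nrow(m), ] <- bg[nrow(m), ]
  reach[, 1] <- bg[, 1]; reach[, ncol(m)] <- bg[, ncol(m)]
  repeat {
    grown <- bg & (reach |
                     shift_mat_(reach, 1, 0, FALSE) |
                     shift_mat_(reach, -1, 0, FALSE) |
                     shift_mat_(reach, 0, 1, FALSE) |
                     shift_mat_(reach, 0, -1, FALSE))
    if (identical(grown, reach)) break
    reach <- grown
  }
  m | (bg & !reach)
}

#' Create a per-cell binary mask from an immunostain channel
#'
#' The ImageJ-equivalent mask pipeline: select pixels strictly brighter than
#' a pre-determined background level, then run two rounds of
#' dilate → fill holes → erode with a 3x3 structuring element so the whole
#' cell (including dim interior regions) is enclosed while the outline
#' returns close to the thresholded one. The largest connected component is
#' taken as the cell.
#'
#' @param image An [image_plane()] or numeric matrix.
#' @param background_level Intensity threshold; pixels strictly greater are
#'   selected. `NULL` uses an automatic estimate (intensity-histogram mode
#'   plus `3 * mad` of the sub-median pixels).
#' @param rounds Number of dilate/fill/erode rounds (default 2).
#' @param keep `"largest"` (default) keeps the largest connected component
#'   (ties broken by lowest centroid row, then column); `"all"` keeps every
#'   component.
#' @return A `cell_mask`: list with `grid` (logical), `source_channel`,
#'   `background_level`.
#' @export
make_cell_mask <- function(image, background_level = NULL, rounds = 2L,
                           keep = c("largest", "all")) {
  keep <- match.arg(keep)
  m <- as_matrix_(image)
  if (is.null(background_level)) background_level <- auto_background_(m)
  if (background_level < min(m) || background_level >= max(m)) {
    warning("background level outside the image intensity range: mask is ",
            if (background_level < min(m)) "full" else "empty", call. = FALSE)
  }
  mask <- m > background_level
  for (i in seq_len(rounds)) {
    mask <- erode3_(fill_holes_(dilate3_(mask)))
  }
  if (!any(mask)) stop("no cell detected", call. = FALSE)
  if (keep == "largest") {
    lab <- EBImage::bwlabel(mask)
    areas <- tabulate(lab[lab > 0])
    best <- which(areas == max(areas))
    if (length(best) > 1) {
      cent <- t(vapply(best, function(l) {
        w <- which(lab == l, arr.ind = TRUE)
        colMeans(w)
      }, numeric(2)))
      best <- best[order(cent[, 1], cent[, 2])][1]
    }
    mask <- lab == best[1]
  }
  structure(list(
    grid = mask,
    source_channel = if (inherits(image, "image_plane")) image$channel,
    background_level = background_level
  ), class = "cell_mask")
}

# Background estimate: histogram mode + 3 * mad of the sub-median pixels.
auto_background_ <- function(m) {
  d <- stats::density(m, n = 512)
  mode_int <- d$x[which.max(d$y)]
  mode_int + 3 * stats::mad(m[m <= stats::median(m)])
}

#' @export
print.cell_mask <- function(x, ...) {
  cat(sprintf("<cell_mask> %d px (%.1f%% of frame), background level %.4g\n",
              sum(x$grid), 100 * mean(x$grid), x$background_level))
  invisible(x)
}

#' Segment representative texture patches within a cell
#'
#' Finds the 1--4 regions of a cell carrying representative stain texture,
#' using Gaussian-gradient signatures at two scales: pixels are retained
#' where the fine-scale gradient response indicates texture, while areas
#' whose smoothed intensity is anomalously high at the ruffle scale (bright
#' membrane ruffles) or anomalously low at the coarse scale (out-of-focus
#' or empty regions) are excluded.
#' The retained region is morphologically closed, hole-filled, and reduced
#' to at most `max_patches` connected components of sufficient area.
#'
#' @param image [image_plane()] (or matrix with `pixel_size_um` supplied).
#' @param cell A `cell_mask` (or logical matrix).
#' @param sigma_small_um Fine texture scale (um), default 0.15.
#' @param sigma_large_um Coarse context scale (um), default 2.
#' @param pixel_size_um Pixel size if `image` is a bare matrix.
#' @param max_patches Maximum number of patches (default 4).
#' @param min_patch_area_um2 Minimum patch area in um^2 (default 2).
#' @param ruffle_quantile In-cell quantile of the ruffle-scale intensity
#'   above which pixels are excluded as ruffles (default 0.99); the excluded
#'   region is dilated by 0.5 um.
#' @param ruffle_sigma_um Smoothing scale for the ruffle-brightness
#'   criterion (default 0.5, matching the ~0.3 um size of membrane
#'   ruffles).
#' @param focus_quantile In-cell quantile below which the coarse-scale
#'   intensity marks out-of-focus/empty pixels (default 0.02).
#' @param texture_frac Fraction of the robust (95th-percentile) fine-scale
#'   gradient below which pixels carry no texture (default 0.1).
#' @return List of `texture_patch` objects (`grid`, `parent_cell`,
#'   `patch_id`, `area_px`, `area_um2`), largest first.
#' @export
segment_texture_patches <- function(image, cell,
                                    sigma_small_um = 0.15,
                                    sigma_large_um = 2,
                                    pixel_size_um = NULL,
                                    max_patches = 4L,
                                    min_patch_area_um2 = 2,
                                    ruffle_quantile = 0.99,
                                    ruffle_sigma_um = 0.5,
                                    focus_quantile = 0.02,
                                    texture_frac = 0.1) {
  if (sigma_small_um >= sigma_large_um) {
    stop("sigma_small_um must be smaller than sigma_large_um", call. = FALSE)
  }
  px <- pixel_size_of_(image, pixel_size_um)
  m <- as_matrix_(image)
  cm <- mask_grid_(cell)
  if (!any(cm)) stop("cell mask is empty", call. = FALSE)

  g_small <- gradient_magnitude_(gaussian_blur_(m, sigma_small_um / px))
  i_large <- gaussian_blur_(m, sigma_large_um / px)
  i_ruffle <- gaussian_blur_(m, ruffle_sigma_um / px)

  textured <- g_small > texture_frac *
    stats::quantile(g_small[cm], 0.95, names = FALSE)
  ruffled <- i_ruffle > stats::quantile(i_ruffle[cm], ruffle_quantile,
                                        names = FALSE)
  for (i in seq_len(max(1L, round(0.5 / px)))) ruffled <- dilate3_(ruffled)
  dark <- i_large < stats::quantile(i_large[cm], focus_quantile,
                                    names = FALSE)

  keep <- cm & textured & !ruffled & !dark
  # closing (radius ~2 px) bridges gaps between structures, then fill
  keep <- dilate3_(dilate3_(keep))
  keep <- erode3_(erode3_(keep))
  keep <- fill_holes_(keep) & cm & !ruffled
  lab <- EBImage::bwlabel(keep)
  if (max(lab) == 0) {
    stop("no texture patch: no pixels survive the two-scale criteria ",
         "(cell area ", sum(cm), " px, textured ", sum(textured & cm),
         " px, ruffle-excluded ", sum(ruffled & cm), " px)", call. = FALSE)
  }
  areas <- tabulate(lab[lab > 0])
  min_px <- min_patch_area_um2 / px^2
  ord <- order(areas, decreasing = TRUE)
  ord <- ord[areas[ord] >= min_px]
  if (length(ord) == 0) ord <- which.max(areas)
  ord <- ord[seq_len(min(length(ord), max_patches))]
  lapply(seq_along(ord), function(i) {
    structure(list(
      grid = lab == ord[i],
      parent_cell = 1L,
      patch_id = i,
      area_px = areas[ord[i]],
      area_um2 = areas[ord[i]] * px^2
    ), class = "texture_patch")
  })
}

#' @export
print.texture_patch <- function(x, ...) {
  cat(sprintf("<texture_patch #%d> %d px (%.2f um^2)\n",
              x$patch_id, x$area_px, x$area_um2))
  invisible(x)
}
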