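#' Extract a multi-channel line profile
#'
#' Samples every channel along the segment from `p0` to `p1` at 1-pixel
#' steps; each sample is the mean of bilinear samples taken across the
#' perpendicular line width (default 0.2 um, the convention for profiling
#' fine ridges), so exactly the same sampling geometry is applied to every
#' channel.
#'
#' @param channels A `scene`, a named list of [image_plane()]s, or a named
#'   list of matrices (then `pixel_size_um` is required).
#' @param p0,p1 Endpoints as (row, col) pixel coordinates (1-based), inside
#'   the frame.
#' @param line_width_um Averaging width perpendicular to the line (um).
#' @param pixel_size_um Pixel size for bare-matrix input.
#' @return A `line_profile`: `positions_um` (strictly increasing, from 0),
#'   `values` (named list of numeric vectors), `line_width_um`, `endpoints`.
#' @export
extract_profile <- function(channels, p0, p1, line_width_um = 0.2,
                            pixel_size_um = NULL) {
  if (inherits(channels, "scene")) channels <- channels$channels
  stopifnot(is.list(channels), length(channels) >= 1)
  first <- channels[[1]]
  px <- pixel_size_of_(first, pixel_size_um)
  mats <- lapply(channels, as_matrix_)
  nr <- nrow(mats[[1]]); nc <- ncol(mats[[1]])
  p0 <- as.numeric(p0); p1 <- as.numeric(p1)
  if (any(c(p0, p1) < 1) || p0[1] > nr || p1[1] > nr ||
      p0[2] > nc || p1[2] > nc) {
    stop("endpoints must lie inside the image frame", call. = FALSE)
  }
  d <- p1 - p0
  len <- sqrt(sum(d^2))
  if (len == 0) stop("zero-length segment", call. = FALSE)
  u <- d / len                      # along-line unit vector (row, col)
  v <- c(-u[2], u[1])               # perpendicular unit vector
  t <- seq(0, floor(len))           # 1-px steps
  w_px <- line_width_um / px
  k <- max(1L, round(w_px))
  offs <- if (k == 1L) 0 else seq(-(k - 1) / 2, (k - 1) / 2, length.out = k)
  vals <- lapply(mats, function(m) {
    acc <- numeric(length(t))
    for (o in offs) {
      acc <- acc + bilinear_(m, p0[1] + t * u[1] + o * v[1],
                             p0[2] + t * u[2] + o * v[2])
    }
    acc / length(offs)
  })
  structure(list(
    positions_um = t * px,
    values = vals,
    line_width_um = line_width_um,
    endpoints = rbind(p0 = p0, p1 = p1)
  ), class = "line_profile")
}

#' @export
print.line_profile <- function(x, ...) {
  cat(sprintf("<line_profile> %d samples over %.2f um, width %.2g um, channels: %s\n",
              length(x$positions_um), max(x$positions_um), x$line_width_um,
              paste(names(x$values), collapse = ", ")))
  invisible(x)
}

#' Min--max normalise a line profile to 0--100 A.U.
#'
#' Per channel, the lowest value maps to 0 and the highest to 100.
#'
#' @param profile A `line_profile`.
#' @return The profile with every channel rescaled.
#' @export
minmax_normalize <- function(profile) {
  stopifnot(inherits(profile, "line_profile"))
  nms <- names(profile$values)
  profile$values <- lapply(seq_along(profile$values), function(i) {
    x <- profile$values[[i]]
    rng <- max(x) - min(x)
    if (rng == 0) {
      stop("channel '", nms[i], "' is constant: min-max scale undefined",
           call. = FALSE)
    }
    100 * (x - min(x)) / rng
  })
  names(profile$values) <- nms
  profile
}

#' Full width at half maximum of a profile peak
#'
#' Baseline defaults to the profile minimum; the half level is
#' baseline + (peak - baseline)/2 and the width is the distance between the
#' two half-level crossings nearest the peak, linearly interpolated between
#' samples.
#'
#' @param values Numeric profile values (single dominant peak).
#' @param positions Positions (um), strictly increasing, same length.
#' @param baseline `"min"` (default) or `"zero"` (no background
#'   subtraction before the half level).
#' @return Width in the units of `positions`.
#' @export
fwhm <- function(values, positions, baseline = c("min", "zero")) {
  baseline <- match.arg(baseline)
  stopifnot(length(values) == length(positions), length(values) >= 3)
  base <- if (baseline == "min") min(values) else 0
  ipk <- which.max(values)
  half <- base + (values[ipk] - base) / 2
  cross_at_ <- function(i, j) {
    # linear interpolation of the half-level crossing between samples i, j
    positions[i] + (half - values[i]) * (positions[j] - positions[i]) /
      (values[j] - values[i])
  }
  left <- NA_real_
  if (ipk > 1) {
    for (i in ipk:2) {
      if (values[i - 1] <= half && values[i] >= half) {
        left <- cross_at_(i - 1, i)
        break
      }
    }
  }
  right <- NA_real_
  if (ipk < length(values)) {
    for (i in ipk:(length(values) - 1)) {
      if (values[i] >= half && values[i + 1] <= half) {
        right <- cross_at_(i, i + 1)
        break
      }
    }
  }
  if (is.na(left) || is.na(right)) {
    stop("no half-maximum crossing on ",
         if (is.na(left)) "the left" else "the right",
         " side: peak at the profile edge", call. = FALSE)
  }
  right - left
}

# Gaussian smoothing of a 1-D profile (sigma in samples, reflected ends).
smooth_profile_ <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- ceiling(3 * sigma)
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  xp <- c(rev(x[seq_len(min(r, length(x)))]), x,
          rev(x[seq(length(x) - min(r, length(x)) + 1, length(x))]))
  as.numeric(stats::filter(xp, k, sides = 2))[(r + 1):(r + length(x))]
}

# Indices of local maxima with prominence at least prom.
local_maxima_ <- function(x, prom) {
  n <- length(x)
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  if (length(cand) == 0) return(integer(0))
  keep <- vapply(cand, function(i) {
    lmin <- min(x[1:i]); rmin <- min(x[i:n])
    x[i] - max(lmin, rmin) >= prom
  }, logical(1))
  cand[keep]
}

#' Detect a double-walled structure on a wall/filler profile pair
#'
#' Tests whether the wall channel shows two local maxima flanking a trough
#' of sufficient depth, with the filler channel's maximum lying inside the
#' trough interval — the signature of paired receptor ridges whose gap is
#' filled by collagen and phospho-receptor signal.
#'
#' @param wall Wall-channel values (ideally normalised 0--100).
#' @param filler Filler-channel values on the same geometry.
#' @param positions Positions in um.
#' @param min_trough_frac Minimum trough depth as a fraction of the wall
#'   range (default 0.3).
#' @param smooth_sigma Gaussian pre-smoothing in samples (default 1).
#' @param prominence_frac Minimum peak prominence as a fraction of the wall
#'   range (default 0.1).
#' @return List: `detected`, `reason` (`"ok"`, `"single_peak"`,
#'   `"shallow_trough"` or `"filler_offset"`), `gap_um`,
#'   `trough_depth_frac`, `filler_offset_um`.
#' @export
detect_double_wall <- function(wall, filler, positions,
                               min_trough_frac = 0.3,
                               smooth_sigma = 1,
                               prominence_frac = 0.1) {
  stopifnot(length(wall) == length(positions),
            length(filler) == length(positions))
  ws <- smooth_profile_(wall, smooth_sigma)
  fs <- smooth_profile_(filler, smooth_sigma)
  rng <- max(ws) - min(ws)
  peaks <- local_maxima_(ws, prominence_frac * rng)
  if (length(peaks) < 2) {
    return(list(detected = FALSE, reason = "single_peak",
                gap_um = NA_real_, trough_depth_frac = NA_real_,
                filler_offset_um = NA_real_))
  }
  # the two most intense peaks, ordered along the line
  pk <- sort(peaks[order(ws[peaks], decreasing = TRUE)][1:2])
  trough_i <- pk[1] + which.min(ws[pk[1]:pk[2]]) - 1L
  depth <- (min(ws[pk]) - ws[trough_i]) / rng
  gap <- positions[pk[2]] - positions[pk[1]]
  if (depth < min_trough_frac) {
    return(list(detected = FALSE, reason = "shallow_trough",
                gap_um = gap, trough_depth_frac = depth,
                filler_offset_um = NA_real_))
  }
  fpk <- which.max(fs)
  offset <- positions[fpk] - positions[trough_i]
  if (fpk <= pk[1] || fpk >= pk[2]) {
    return(list(detected = FALSE, reason = "filler_offset",
                gap_um = gap, trough_depth_frac = depth,
                filler_offset_um = offset))
  }
  list(detected = TRUE, reason = "ok", gap_um = gap,
       trough_depth_frac = depth, filler_offset_um = offset)
}

#' Place a profile line perpendicular to a ground-truth centreline
#'
#' Test helper for generator scenes: chooses a centreline, takes its
#' midpoint and local tangent, and returns endpoints of a segment of length
#' `length_um` crossing the structure perpendicularly.
#'
#' @param scene A `scene` with polyline centrelines in its truth.
#' @param length_um Length of the profile line (default 2 um).
#' @param index Which centreline to use (default: the longest).
#' @return List with `p0`, `p1` (row, col), or NULL if no usable
#'   centreline exists or no candidate line fits inside the frame.
#' @export
place_profile_line <- function(scene, length_um = 2, index = NULL) {
  cls <- scene$truth$structure_centrelines
  cls <- Filter(function(p) nrow(p) >= 5, cls)
  if (length(cls) == 0) return(NULL)
  if (is.null(index)) {
    index <- which.max(vapply(cls, nrow, integer(1)))
  }
  pts <- cls[[index]]
  px <- scene$config$pixel_size_um
  half <- length_um / 2 / px
  dims <- dim(scene$channels[[1]]$data)
  n <- nrow(pts)
  # candidate interior anchor points, preferring the middle of the polyline
  cand <- unique(pmin(pmax(round(n * c(0.5, 0.4, 0.6, 0.3, 0.7)), 3L), n - 2L))
  for (mid in cand) {
    tang <- pts[min(mid + 2L, n), ] - pts[max(mid - 2L, 1L), ]
    tl <- sqrt(sum(tang^2))
    if (tl == 0) next
    tang <- tang / tl
    nrm <- c(-tang[2], tang[1])
    p0 <- pts[mid, ] - half * nrm
    p1 <- pts[mid, ] + half * nrm
    if (!(all(c(p0, p1) >= 1) && p0[1] <= dims[1] && p1[1] <= dims[1] &&
          p0[2] <= dims[2] && p1[2] <= dims[2])) next
    # avoid ruffle-contaminated sites (lines are drawn on clean structures)
    rm_ <- scene$truth$ruffle_mask
    if (!is.null(rm_) && any(rm_)) {
      tt <- seq(0, 1, length.out = 16)
      rr <- round(p0[1] + tt * (p1[1] - p0[1]))
      cc <- round(p0[2] + tt * (p1[2] - p0[2]))
      if (any(rm_[cbind(rr, cc)])) next
    }
    return(list(p0 = p0, p1 = p1))
  }
  NULL
}
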