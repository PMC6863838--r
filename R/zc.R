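#' Local-average subtraction: build the zero-mean reference image
#'
#' Subtracts a running local mean (square window, side `window_um`) from the
#' image inside a patch, renormalising at edges so the mean is taken over
#' in-patch pixels only, and recentres so the in-patch mean of the result is
#' exactly zero. Background variation from uneven staining or illumination
#' is removed and the remaining intensity variation is due to texture; zero
#' crossings are counted on this reference image.
#'
#' @param image [image_plane()] (or matrix with `pixel_size_um`).
#' @param patch `texture_patch`, `cell_mask` or logical matrix.
#' @param window_um Side of the local-averaging window in um (default 10).
#' @param pixel_size_um Pixel size if `image` is a bare matrix.
#' @return Numeric matrix, zero outside the patch, in-patch mean 0.
#' @export
local_average_subtract <- function(image, patch, window_um = 10,
                                   pixel_size_um = NULL) {
  px <- pixel_size_of_(image, pixel_size_um)
  m <- as_matrix_(image)
  p <- mask_grid_(patch)
  if (!any(p)) stop("patch is empty", call. = FALSE)
  w <- round(window_um / px)
  if (window_um < 3 * px || w < 3) {
    stop("window_um must cover at least 3 pixels", call. = FALSE)
  }
  h <- w %/% 2L
  pm <- p * 1.0
  s1 <- box_sum_(m * pm, h)
  s0 <- box_sum_(pm, h)
  mu <- matrix(0, nrow(m), ncol(m))
  ok <- s0 > 0
  mu[ok] <- s1[ok] / s0[ok]
  ref <- (m - mu) * pm
  ref[p] <- ref[p] - mean(ref[p])
  ref
}

#' Count zero crossings of an intensity profile
#'
#' Number of sign changes between consecutive non-zero samples. Exact zeros
#' carry the previous non-zero sign, so a profile that touches zero without
#' changing sign is not a crossing; leading zeros are skipped.
#'
#' @param values Numeric vector, length >= 2.
#' @return Integer crossing count (0 for an all-zero profile).
#' @examples
#' count_zero_crossings(c(1, -1, 1, -1)) # 3
#' count_zero_crossings(c(1, 0, -1))     # 1
#' count_zero_crossings(c(1, 0, 1))      # 0
#' @export
count_zero_crossings <- function(values) {
  if (length(values) < 2) stop("need at least 2 samples", call. = FALSE)
  s <- sign(values)
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  sum(s[-1] != s[-length(s)])
}

#' Sample one random line profile through a patch
#'
#' Picks a uniform random in-patch anchor pixel and a uniform random
#' direction in \eqn{[0, \pi)}, extends the line both ways until it leaves
#' the patch, and samples the reference image at 1-pixel steps with bilinear
#' interpolation. Only the contiguous in-patch segment through the anchor is
#' returned. Degenerate draws (fewer than `min_samples` samples) are
#' resampled up to `max_tries` times.
#'
#' @param patch Logical matrix or `texture_patch`.
#' @param reference Reference-image matrix (from
#'   [local_average_subtract()]).
#' @param pixel_size_um Pixel size, um/px.
#' @param min_samples Minimum samples for a valid line (default 3).
#' @param max_tries Resampling cap (default 25).
#' @return List: `positions_um` (relative to the first sample), `values`,
#'   `length_um`, `anchor` (row, col), `theta`.
#' @export
sample_random_line <- function(patch, reference, pixel_size_um,
                               min_samples = 3L, max_tries = 25L) {
  p <- mask_grid_(patch)
  inside <- which(p)
  if (length(inside) == 0) stop("patch is empty", call. = FALSE)
  nr <- nrow(p); nc <- ncol(p)
  tmax <- ceiling(sqrt(nr^2 + nc^2))
  tseq <- seq(-tmax, tmax)
  zero_at <- tmax + 1L
  for (try in seq_len(max_tries)) {
    a <- inside[sample.int(length(inside), 1L)]
    ar <- ((a - 1) %% nr) + 1
    ac <- ((a - 1) %/% nr) + 1
    theta <- runif(1, 0, pi)
    rr <- ar + tseq * sin(theta)
    cc <- ac + tseq * cos(theta)
    ri <- round(rr); ci <- round(cc)
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    ok[ok] <- p[(ci[ok] - 1) * nr + ri[ok]]
    # contiguous run through the anchor (t = 0)
    lo <- zero_at; hi <- zero_at
    while (lo > 1 && ok[lo - 1]) lo <- lo - 1
    while (hi < length(ok) && ok[hi + 1]) hi <- hi + 1
    n <- hi - lo + 1
    if (n < min_samples) next
    idx <- lo:hi
    vals <- bilinear_(reference, rr[idx], cc[idx])
    return(list(
      positions_um = (tseq[idx] - tseq[lo]) * pixel_size_um,
      values = vals,
      length_um = (n - 1) * pixel_size_um,
      anchor = c(ar, ac),
      theta = theta
    ))
  }
  stop("could not sample a valid line: patch too small or fragmented ",
       "(", max_tries, " attempts)", call. = FALSE)
}

#' ZC score: zero-crossing linear density of a texture patch
#'
#' The core texture statistic. The image is locally average-subtracted into
#' a zero-mean reference; intensity profiles along random lines across the
#' patch are drawn repeatedly (typically 2000 times); the number of
#' zero-level crossings per unit line length is averaged over lines. A
#' higher ZC score indicates a finer texture, a lower score a coarser,
#' denser signal; the score is insensitive to the signal's amplitude.
#'
#' @param image [image_plane()] (or matrix with `pixel_size_um`).
#' @param patch `texture_patch` or logical matrix.
#' @param n_lines Number of random lines (default 2000).
#' @param window_um Local-averaging window in um (default 10). `NULL`
#'   subtracts the in-patch global mean only — appropriate for stationary
#'   fields whose expected crossing density is compared with closed-form
#'   values, where a running-mean window would high-pass the signal.
#' @param seed Integer seed (recorded in the result) or NULL.
#' @param pixel_size_um Pixel size if `image` is a bare matrix.
#' @param aggregate `"mean_of_ratios"` (default): mean over lines of
#'   crossings/length. `"pooled"`: total crossings / total length.
#' @param patch_id Identifier copied into the result.
#' @return A `zc_result`: `zc_score` (crossings per um), `n_lines`,
#'   `per_line` (data.frame: length_um, crossings), `window_um`, `seed`,
#'   `mean_line_length_um`, `aggregate`, `patch_id`.
#' @export
zc_score <- function(image, patch, n_lines = 2000L, window_um = 10,
                     seed = NULL, pixel_size_um = NULL,
                     aggregate = c("mean_of_ratios", "pooled"),
                     patch_id = NULL) {
  aggregate <- match.arg(aggregate)
  if (n_lines < 1) stop("n_lines must be >= 1", call. = FALSE)
  px <- pixel_size_of_(image, pixel_size_um)
  p <- mask_grid_(patch)
  if (is.null(patch_id) && inherits(patch, "texture_patch")) {
    patch_id <- patch$patch_id
  }
  ref <- if (is.null(window_um)) {
    m <- as_matrix_(image)
    r <- m * p
    r[p] <- r[p] - mean(r[p])
    r
  } else {
    local_average_subtract(image, p, window_um = window_um,
                           pixel_size_um = px)
  }
  lens <- numeric(n_lines)
  crossings <- integer(n_lines)
  with_seed_(seed, {
    for (i in seq_len(n_lines)) {
      ln <- tryCatch(
        sample_random_line(p, ref, px),
        error = function(e) {
          stop("patch ", if (is.null(patch_id)) "" else patch_id, ": ",
               conditionMessage(e), call. = FALSE)
        }
      )
      lens[i] <- ln$length_um
      crossings[i] <- count_zero_crossings(ln$values)
    }
  })
  score <- if (aggregate == "mean_of_ratios") {
    mean(crossings / lens)
  } else {
    sum(crossings) / sum(lens)
  }
  structure(list(
    patch_id = patch_id,
    zc_score = score,
    n_lines = as.integer(n_lines),
    per_line = data.frame(length_um = lens, crossings = crossings),
    window_um = window_um,
    seed = seed,
    mean_line_length_um = mean(lens),
    aggregate = aggregate
  ), class = "zc_result")
}

#' @export
print.zc_result <- function(x, ...) {
  cat(sprintf(
    "<zc_result%s> ZC score %.4f crossings/um (%d lines, mean length %.2f um%s)\n",
    if (is.null(x$patch_id)) "" else paste0(" patch ", x$patch_id),
    x$zc_score, x$n_lines, x$mean_line_length_um,
    if (is.null(x$window_um)) ", global mean subtraction"
    else sprintf(", %g um window", x$window_um)
  ))
  invisible(x)
}

#' Mean ZC score of a whole cell
#'
#' Segments the cell into texture patches and averages their ZC scores,
#' weighting each patch equally.
#'
#' @inheritParams zc_score
#' @param cell A `cell_mask`.
#' @param ... Passed to [segment_texture_patches()].
#' @return List: `zc_score` (mean over patches), `per_patch` (list of
#'   `zc_result`), `n_patches`.
#' @export
cell_zc_score <- function(image, cell, n_lines = 2000L, window_um = 10,
                          seed = NULL, ...) {
  patches <- segment_texture_patches(image, cell, ...)
  results <- with_seed_(seed, {
    lapply(patches, function(p) {
      zc_score(image, p, n_lines = n_lines, window_um = window_um,
               seed = NULL)
    })
  })
  list(
    zc_score = mean(vapply(results, `[[`, numeric(1), "zc_score")),
    per_patch = results,
    n_patches = length(results)
  )
}
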