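#' Configuration for a synthetic fluorescence scene
#'
#' Describes one simulated cell: its texture class (the stages of
#' collagen-induced receptor redistribution seen by immunofluorescence),
#' characteristic structure scale, structure density, signal amplitude,
#' and the corruption model (uneven illumination, membrane ruffles,
#' Poisson/Gaussian noise).
#'
#' Texture classes:
#' \describe{
#'   \item{punctate}{isotropic Gaussian puncta (unstimulated receptor).}
#'   \item{linear_cidc}{connected linear clusters: random-walk polylines
#'     with a Gaussian cross-section (5--30 min of collagen stimulation).}
#'   \item{aggregate}{fewer, coarser blobs (>= 45 min stimulation).}
#'   \item{double_wall}{polylines rendered as two parallel ridges separated
#'     by `char_length_um` in the `ddr1` channel, with a single centred
#'     ridge in the `collagen` and `py` channels (the filler-in-gap
#'     geometry of dense aggregates seen by super-resolution imaging).}
#' }
#'
#' @param image_shape Integer (H, W) in pixels.
#' @param pixel_size_um Pixel size, um/px.
#' @param texture_class One of `"punctate"`, `"linear_cidc"`, `"aggregate"`,
#'   `"double_wall"`.
#' @param char_length_um Characteristic structure scale in um. For spot-like
#'   classes the full width at half maximum of a structure; for
#'   `double_wall` the wall-to-wall gap. Must be at least twice the pixel
#'   size so structures are resolvable.
#' @param density Structures per um^2 of cell area (spots or polylines).
#' @param amplitude Peak intensity of the `ddr1` texture (a.u.), > 0.
#' @param py_amplitude,collagen_amplitude Peak intensities of the `py`
#'   (phospho-receptor) and `collagen` channels; defaults scale with
#'   `amplitude`.
#' @param baseline_frac Diffuse in-cell stain level as a fraction of each
#'   channel's amplitude (default 0.15), added at scene assembly; this is
#'   the cytoplasmic background the cell-mask threshold keys on.
#' @param noise_gaussian_sd Additive Gaussian read-noise sd (a.u.).
#' @param noise_poisson Apply Poisson shot noise (intensities treated as
#'   expected photon counts after `photon_gain`)?
#' @param photon_gain Intensity units per photon for the Poisson model.
#' @param illumination_amplitude Fractional peak-to-trough amplitude of the
#'   smooth multiplicative illumination field (>= 0; 0 disables it).
#' @param ruffle_count Number of bright membrane-ruffle blobs placed within
#'   1 um of the cell boundary (3--5x the texture amplitude).
#' @param seed Integer seed; the whole scene is reproducible from it.
#' @return A `scene_config` list.
#' @export
scene_config <- function(image_shape = c(256L, 256L),
                         pixel_size_um = 0.1,
                         texture_class = c("punctate", "linear_cidc",
                                           "aggregate", "double_wall"),
                         char_length_um = 0.2,
                         density = NULL,
                         amplitude = 100,
                         py_amplitude = 0.3 * amplitude,
                         collagen_amplitude = 0.5 * amplitude,
                         baseline_frac = 0.15,
                         noise_gaussian_sd = 2,
                         noise_poisson = TRUE,
                         photon_gain = 1,
                         illumination_amplitude = 0.1,
                         ruffle_count = 2L,
                         seed = 1L) {
  texture_class <- match.arg(texture_class)
  if (is.null(density)) {
    density <- switch(texture_class,
      punctate = 3, linear_cidc = 0.4, aggregate = 0.3,
      double_wall = 0.02)
  }
  stopifnot(length(image_shape) == 2, all(image_shape >= 64))
  if (pixel_size_um <= 0) stop("pixel_size_um must be > 0", call. = FALSE)
  if (char_length_um < 2 * pixel_size_um) {
    stop("char_length_um must be >= 2 * pixel_size_um (structures must be ",
         "resolvable)", call. = FALSE)
  }
  if (amplitude <= 0) stop("amplitude must be > 0", call. = FALSE)
  if (noise_gaussian_sd < 0 || illumination_amplitude < 0 ||
      photon_gain <= 0 || ruffle_count < 0) {
    stop("noise/illumination parameters must be non-negative", call. = FALSE)
  }
  structure(list(
    image_shape = as.integer(image_shape), pixel_size_um = pixel_size_um,
    texture_class = texture_class, char_length_um = char_length_um,
    density = density, amplitude = amplitude,
    py_amplitude = py_amplitude, collagen_amplitude = collagen_amplitude,
    baseline_frac = baseline_frac,
    noise_gaussian_sd = noise_gaussian_sd, noise_poisson = noise_poisson,
    photon_gain = photon_gain,
    illumination_amplitude = illumination_amplitude,
    ruffle_count = as.integer(ruffle_count), seed = as.integer(seed)
  ), class = "scene_config")
}

#' Generate a random simply-connected cell silhouette
#'
#' Draws a star-convex blob (random low-order Fourier perturbation of a
#' circle) occupying 20--60% of the frame; the standard stand-in for a
#' manually cropped adherent cell.
#'
#' @param shape Integer (H, W), each >= 64.
#' @param seed Integer seed, or NULL to use the current RNG stream.
#' @return Logical H x W matrix, TRUE inside the cell.
#' @export
generate_cell_shape <- function(shape, seed = NULL) {
  if (length(shape) != 2 || any(shape < 64)) {
    stop("shape too small: the frame must be at least 64 x 64 pixels",
         call. = FALSE)
  }
  H <- as.integer(shape[1]); W <- as.integer(shape[2])
  with_seed_(seed, {
    cy <- H / 2 + runif(1, -0.05, 0.05) * H
    cx <- W / 2 + runif(1, -0.05, 0.05) * W
    r0 <- sqrt(0.33 * H * W / pi) * runif(1, 0.85, 1.1)
    amp <- runif(5, 0, 0.08)
    phs <- runif(5, 0, 2 * pi)
    yy <- matrix(seq_len(H), H, W)
    xx <- matrix(seq_len(W), H, W, byrow = TRUE)
    th <- atan2(yy - cy, xx - cx)
    rr <- sqrt((yy - cy)^2 + (xx - cx)^2)
    rad <- 1
    for (k in 1:5) rad <- rad + amp[k] * cos((k + 1) * th + phs[k])
    rad <- pmin(r0 * rad, 0.47 * min(H, W))
    rr <= rad
  })
}

# Accumulate weights w at continuous (r, c) positions into a matrix by
# bilinear splatting.
splat_ <- function(m, r, c, w) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  corners <- list(
    list(r0,     c0,     (1 - fr) * (1 - fc)),
    list(r0 + 1, c0,     fr * (1 - fc)),
    list(r0,     c0 + 1, (1 - fr) * fc),
    list(r0 + 1, c0 + 1, fr * fc)
  )
  mv <- as.vector(m)
  for (cr in corners) {
    ok <- cr[[1]] >= 1 & cr[[1]] <= nr & cr[[2]] >= 1 & cr[[2]] <= nc
    if (!any(ok)) next
    idx <- (cr[[2]][ok] - 1) * nr + cr[[1]][ok]
    agg <- rowsum(w[ok] * cr[[3]][ok], idx)
    mv[as.integer(rownames(agg))] <- mv[as.integer(rownames(agg))] + agg[, 1]
  }
  matrix(mv, nr, nc)
}

# Random-walk polyline inside a mask: unit-pixel steps with a persistent
# heading. Returns an n x 2 matrix of (row, col) positions.
walk_polyline_ <- function(mask, length_px, angle_sd) {
  nr <- nrow(mask); nc <- ncol(mask)
  inside <- which(mask)
  for (try in 1:20) {
    start <- inside[sample.int(length(inside), 1L)]
    r <- ((start - 1) %% nr) + 1 + runif(1, -0.5, 0.5)
    c <- ((start - 1) %/% nr) + 1 + runif(1, -0.5, 0.5)
    th <- runif(1, 0, 2 * pi)
    pts <- matrix(NA_real_, length_px, 2)
    pts[1, ] <- c(r, c)
    n <- 1L
    for (i in 2:length_px) {
      th <- th + rnorm(1, 0, angle_sd)
      r2 <- r + sin(th); c2 <- c + cos(th)
      ri <- round(r2); ci <- round(c2)
      if (ri < 1 || ri > nr || ci < 1 || ci > nc || !mask[ri, ci]) break
      r <- r2; c <- c2
      pts[i, ] <- c(r, c)
      n <- i
    }
    if (n >= 5L) return(pts[seq_len(n), , drop = FALSE])
  }
  NULL
}

#' Render the noiseless texture channels of a scene
#'
#' Draws the ground-truth structures for `config$texture_class` inside the
#' cell mask and returns noiseless per-channel intensity grids plus the
#' structure centrelines. Geometry is drawn at unit amplitude and scaled by
#' the channel amplitudes afterwards, so amplitude scaling is exactly linear.
#'
#' @param config A [scene_config()].
#' @param mask Logical cell mask (from [generate_cell_shape()]).
#' @param seed Integer seed or NULL (current stream).
#' @return List with `channels` (named list of noiseless matrices, always
#'   including `ddr1` and `py`, plus `collagen` for `double_wall`) and
#'   `centrelines` (list of n x 2 (row, col) matrices; empty for spot
#'   classes, which report centres as 1 x 2 matrices).
#' @export
render_texture <- function(config, mask, seed = NULL) {
  if (!any(mask)) stop("cell mask is empty", call. = FALSE)
  with_seed_(seed, {
    px <- config$pixel_size_um
    H <- nrow(mask); W <- ncol(mask)
    area_um2 <- sum(mask) * px^2
    sigma_px <- config$char_length_um / 2.355 / px
    pattern <- matrix(0, H, W)
    filler <- NULL
    centrelines <- list()

    if (config$texture_class %in% c("punctate", "aggregate")) {
      n <- rpois(1, config$density * area_um2)
      if (n > 0) {
        inside <- which(mask)
        pick <- inside[sample.int(length(inside), n, replace = TRUE)]
        r <- ((pick - 1) %% H) + 1 + runif(n, -0.5, 0.5)
        c <- ((pick - 1) %/% H) + 1 + runif(n, -0.5, 0.5)
        pattern <- splat_(pattern, r, c, rep(2 * pi * sigma_px^2, n))
        pattern <- gaussian_blur_(pattern, sigma_px)
        centrelines <- lapply(seq_len(n), function(i) {
          matrix(c(r[i], c[i]), 1, 2)
        })
      }
    } else if (config$texture_class == "linear_cidc") {
      n <- max(1L, rpois(1, config$density * area_um2))
      len_px <- max(10L, round(10 * config$char_length_um / px))
      step_w <- sqrt(2 * pi) * sigma_px  # unit peak after blurring
      for (i in seq_len(n)) {
        pts <- walk_polyline_(mask, len_px, angle_sd = 0.15)
        if (is.null(pts)) next
        pattern <- splat_(pattern, pts[, 1], pts[, 2],
                          rep(step_w, nrow(pts)))
        centrelines[[length(centrelines) + 1L]] <- pts
      }
      pattern <- gaussian_blur_(pattern, sigma_px)
    } else { # double_wall
      gap_px <- config$char_length_um / px
      wall_sigma <- gap_px / 5
      n <- max(1L, rpois(1, config$density * area_um2))
      len_px <- max(15L, round(15 * config$char_length_um / px))
      step_w <- sqrt(2 * pi) * wall_sigma
      filler <- matrix(0, H, W)
      # keep both walls inside the cell: walk on a mask eroded by the
      # wall offset plus the ridge width
      walk_mask <- mask
      for (k in seq_len(ceiling(gap_px / 2 + 2 * wall_sigma))) {
        walk_mask <- erode3_(walk_mask)
      }
      if (!any(walk_mask)) walk_mask <- mask
      for (i in seq_len(n)) {
        pts <- walk_polyline_(walk_mask, len_px, angle_sd = 0.02)
        if (is.null(pts) || nrow(pts) < 5) next
        m <- nrow(pts)
        tang <- rbind(pts[2, ] - pts[1, ],
                      (pts[3:m, , drop = FALSE] -
                         pts[1:(m - 2), , drop = FALSE]) / 2,
                      pts[m, ] - pts[m - 1, ])
        tl <- sqrt(rowSums(tang^2)); tl[tl == 0] <- 1
        nrm <- cbind(-tang[, 2], tang[, 1]) / tl
        off <- nrm * gap_px / 2
        pattern <- splat_(pattern, pts[, 1] + off[, 1], pts[, 2] + off[, 2],
                          rep(step_w, m))
        pattern <- splat_(pattern, pts[, 1] - off[, 1], pts[, 2] - off[, 2],
                          rep(step_w, m))
        filler <- splat_(filler, pts[, 1], pts[, 2], rep(step_w, m))
        centrelines[[length(centrelines) + 1L]] <- pts
      }
      pattern <- gaussian_blur_(pattern, wall_sigma)
      filler <- pmax(gaussian_blur_(filler, wall_sigma), 0)
      filler[!mask] <- 0
    }

    pattern <- pmax(pattern, 0)  # FFT blur can leave ~1e-16 ringing
    pattern[!mask] <- 0
    cover <- sum(pattern > 0.05) / sum(mask)
    if (cover > 0.95) {
      warning("structure density very high: texture covers >95% of the cell",
              call. = FALSE)
    }

    channels <- list(ddr1 = config$amplitude * pattern)
    if (config$texture_class == "double_wall") {
      channels$collagen <- config$collagen_amplitude * filler
      channels$py <- config$py_amplitude * filler
    } else {
      channels$py <- config$py_amplitude * pattern
    }
    list(channels = channels, centrelines = centrelines)
  })
}

# Smooth multiplicative illumination field: random low-order polynomial in
# normalised frame coordinates, rescaled so peak-to-trough = amplitude.
illumination_field_ <- function(H, W, amplitude) {
  if (amplitude <= 0) return(matrix(1, H, W))
  u <- matrix(seq(-1, 1, length.out = H), H, W)
  v <- matrix(seq(-1, 1, length.out = W), H, W, byrow = TRUE)
  cf <- runif(5, -1, 1)
  p <- cf[1] * u + cf[2] * v + cf[3] * u * v + cf[4] * u^2 + cf[5] * v^2
  rng <- max(p) - min(p)
  if (rng == 0) return(matrix(1, H, W))
  1 + amplitude * ((p - min(p)) / rng - 0.5)
}

# Bright ruffle blobs within 1 um of the cell boundary; returns the additive
# field and the truth mask (field above 25% of a single blob's peak).
ruffle_field_ <- function(mask, config) {
  H <- nrow(mask); W <- ncol(mask)
  field <- matrix(0, H, W)
  if (config$ruffle_count == 0) {
    return(list(field = field, mask = matrix(FALSE, H, W)))
  }
  px <- config$pixel_size_um
  boundary <- which(mask & !erode3_(mask))
  sig <- 0.3 / px
  amp0 <- 4 * config$amplitude
  for (i in seq_len(config$ruffle_count)) {
    b <- boundary[sample.int(length(boundary), 1L)]
    r <- ((b - 1) %% H) + 1 + runif(1, -1, 1) / px * runif(1, 0, 1)
    c <- ((b - 1) %/% H) + 1 + runif(1, -1, 1) / px * runif(1, 0, 1)
    amp <- amp0 * runif(1, 0.8, 1.2)
    field <- splat_(field, r, c, amp * 2 * pi * sig^2)
  }
  field <- pmax(gaussian_blur_(field, sig), 0)
  list(field = field, mask = field > 0.25 * amp0)
}

#' Corrupt a noiseless channel with illumination, ruffles and noise
#'
#' Applies, in order: a smooth multiplicative illumination field, additive
#' bright membrane-ruffle blobs near the cell boundary, Poisson shot noise
#' (intensities as expected photon counts after `photon_gain`) and additive
#' Gaussian read noise. With all corruptions disabled the output equals the
#' input exactly.
#'
#' @param noiseless Non-negative matrix (a noiseless truth channel).
#' @param config A [scene_config()].
#' @param seed Integer seed or NULL (current stream).
#' @param cell_mask Logical mask, required if `ruffle_count > 0` and no
#'   `ruffle` field is supplied.
#' @param illumination,ruffle Optional precomputed fields (as returned in
#'   this function's output) so several channels share one realisation.
#' @param add_ruffles Apply the ruffle field to this channel?
#' @return List: `plane` (corrupted matrix), `illumination_field`,
#'   `ruffle_field`, `ruffle_mask`.
#' @export
corrupt <- function(noiseless, config, seed = NULL, cell_mask = NULL,
                    illumination = NULL, ruffle = NULL, add_ruffles = TRUE) {
  if (min(noiseless) < 0) stop("noiseless must be >= 0", call. = FALSE)
  if (config$noise_gaussian_sd < 0 || config$illumination_amplitude < 0) {
    stop("negative noise parameters are not allowed", call. = FALSE)
  }
  with_seed_(seed, {
    H <- nrow(noiseless); W <- ncol(noiseless)
    if (is.null(illumination)) {
      illumination <- illumination_field_(H, W, config$illumination_amplitude)
    }
    if (is.null(ruffle)) {
      if (config$ruffle_count > 0) {
        if (is.null(cell_mask)) {
          stop("cell_mask needed to place ruffles", call. = FALSE)
        }
        ruffle <- ruffle_field_(cell_mask, config)
      } else {
        ruffle <- list(field = matrix(0, H, W), mask = matrix(FALSE, H, W))
      }
    }
    out <- noiseless
    if (add_ruffles && any(ruffle$field > 0)) out <- out + ruffle$field
    if (config$illumination_amplitude > 0) out <- out * illumination
    if (config$noise_poisson) {
      g <- config$photon_gain
      out <- g * matrix(rpois(H * W, pmax(out, 0) / g), H, W)
    }
    if (config$noise_gaussian_sd > 0) {
      out <- out + matrix(rnorm(H * W, 0, config$noise_gaussian_sd), H, W)
    }
    list(plane = out, illumination_field = illumination,
         ruffle_field = ruffle$field, ruffle_mask = ruffle$mask)
  })
}

#' Generate a complete synthetic scene
#'
#' Cell silhouette, noiseless texture channels (plus a diffuse in-cell
#' baseline of `baseline_frac` of each channel's amplitude), and
#' per-channel corruption, all reproducible from `config$seed`. Ruffles are added to the `ddr1`
#' channel only (they are the segmentation confound); the illumination field
#' and noise model apply to every channel.
#'
#' @param config A [scene_config()].
#' @return A `scene`: list with `channels` (named [image_plane()]s),
#'   `truth` (cell_mask, structure_centrelines, char_length_um, ruffle_mask,
#'   illumination_field, per_channel_truth) and `config`.
#' @export
generate_scene <- function(config) {
  with_seed_(config$seed, {
    mask <- generate_cell_shape(config$image_shape, seed = NULL)
    tex <- render_texture(config, mask, seed = NULL)
    H <- nrow(mask); W <- ncol(mask)
    illum <- illumination_field_(H, W, config$illumination_amplitude)
    ruffle <- if (config$ruffle_count > 0) {
      ruffle_field_(mask, config)
    } else {
      list(field = matrix(0, H, W), mask = matrix(FALSE, H, W))
    }
    amps <- c(ddr1 = config$amplitude, py = config$py_amplitude,
              collagen = config$collagen_amplitude)
    channels <- list()
    noiseless_channels <- list()
    for (nm in names(tex$channels)) {
      noiseless <- tex$channels[[nm]] +
        config$baseline_frac * amps[[nm]] * mask
      noiseless_channels[[nm]] <- noiseless
      cr <- corrupt(noiseless, config, seed = NULL,
                    illumination = illum, ruffle = ruffle,
                    add_ruffles = identical(nm, "ddr1"))
      channels[[nm]] <- image_plane(cr$plane, config$pixel_size_um,
                                    channel = nm)
    }
    truth <- structure(list(
      cell_mask = mask,
      structure_centrelines = tex$centrelines,
      char_length_um = config$char_length_um,
      ruffle_mask = ruffle$mask,
      illumination_field = illum,
      per_channel_truth = noiseless_channels
    ), class = "scene_truth")
    structure(list(channels = channels, truth = truth, config = config),
              class = "scene")
  })
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf(
    "<scene> %s, %d x %d px @ %.3g um/px, channels: %s, char length %.3g um\n",
    x$config$texture_class, x$config$image_shape[1], x$config$image_shape[2],
    x$config$pixel_size_um, paste(names(x$channels), collapse = ", "),
    x$config$char_length_um
  ))
  invisible(x)
}

# Stage of receptor redistribution emulated at a given stimulation time.
timepoint_class_ <- function(t) {
  if (t < 2.5) {
    list(texture_class = "punctate", char_length_um = 0.2, density = 3)
  } else if (t < 45) {
    list(texture_class = "linear_cidc", char_length_um = 0.4, density = 0.4)
  } else {
    list(texture_class = "aggregate", char_length_um = 0.8, density = 0.3)
  }
}

#' Generate a stimulation time course of scenes
#'
#' Maps stimulation time to texture class — 0 min: fine puncta; 5--30 min:
#' linear connected clusters; >= 45 min: coarse aggregates — with strictly
#' increasing characteristic length along that ordering, and a
#' phospho-channel amplitude that rises with stimulation time. Returns one
#' scene per requested time.
#'
#' @param times Numeric vector of stimulation times in minutes (non-empty).
#' @param seed Integer seed for the whole course.
#' @param ... Further arguments passed to [scene_config()] (e.g.
#'   `image_shape`, `noise_gaussian_sd`).
#' @return Named list of `scene` objects (names = times in minutes).
#' @export
generate_timecourse <- function(times, seed = 1L, ...) {
  if (length(times) == 0) stop("times must be non-empty", call. = FALSE)
  extra <- list(...)
  with_seed_(seed, {
    seeds <- sample.int(.Machine$integer.max - 1L, length(times))
    scenes <- vector("list", length(times))
    for (i in seq_along(times)) {
      cls <- timepoint_class_(times[i])
      amp <- if (!is.null(extra$amplitude)) extra$amplitude else 100
      args <- c(cls, list(
        seed = seeds[i],
        py_amplitude = amp * (0.02 + 0.9 * min(times[i], 60) / 60)
      ), extra)
      args <- args[!duplicated(names(args))]
      scenes[[i]] <- generate_scene(do.call(scene_config, args))
    }
    names(scenes) <- as.character(times)
    scenes
  })
}
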