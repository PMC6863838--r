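# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# seed = NULL means "use the current stream" (callers that are themselves
# seeded pass NULL down so one seed governs a whole generation).
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Shift a matrix by (dr, dc), filling vacated cells with `fill`.
shift_mat_ <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  if (length(rs) && length(cs)) out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Bilinear interpolation of matrix `m` at continuous 1-based (r, c)
# coordinates (pixel centres at integers). Out-of-frame points clamp to the
# frame edge; callers that need strict in-frame behaviour check beforehand.
bilinear_ <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  r <- pmin(pmax(r, 1), nr)
  c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  i00 <- (c0 - 1) * nr + r0
  v00 <- m[i00]; v10 <- m[i00 + 1]
  v01 <- m[i00 + nr]; v11 <- m[i00 + nr + 1]
  (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
    (1 - fr) * fc * v01 + fr * fc * v11
}

# Summed-area table; S[i+1, j+1] = sum of m[1:i, 1:j], zero-padded.
integral_image_ <- function(m) {
  s <- apply(m, 2, cumsum)
  s <- t(apply(s, 1, cumsum))
  rbind(0, cbind(0, s))
}

# Box sum of m over a (2h+1)-square window centred on each pixel, windows
# clipped at the frame.
box_sum_ <- function(m, h) {
  nr <- nrow(m); nc <- ncol(m)
  S <- integral_image_(m)
  r1 <- pmax(seq_len(nr) - h, 1L); r2 <- pmin(seq_len(nr) + h, nr)
  c1 <- pmax(seq_len(nc) - h, 1L); c2 <- pmin(seq_len(nc) + h, nc)
  S[r2 + 1, c2 + 1, drop = FALSE] - S[r1, c2 + 1, drop = FALSE] -
    S[r2 + 1, c1, drop = FALSE] + S[r1, c1, drop = FALSE]
}

# Gaussian smoothing (EBImage, reflective borders); sigma in pixels.
gaussian_blur_ <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  # gblur's kernel spans 2*ceil(3*sigma)+1 pixels and must fit the frame
  max_sigma <- (min(dim(m)) - 3) / 6.5
  matrix(EBImage::gblur(m, sigma = min(sigma_px, max_sigma)),
         nrow(m), ncol(m))
}

# Gradient magnitude by central differences (one-sided at the frame edge).
gradient_magnitude_ <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  gr <- (m[c(2:nr, nr), ] - m[c(1, 1:(nr - 1)), ]) / 2
  gc <- (m[, c(2:nc, nc)] - m[, c(1, 1:(nc - 1))]) / 2
  sqrt(gr^2 + gc^2)
}

as_matrix_ <- function(x) {
  if (inherits(x, "image_plane")) x$data else as.matrix(x)
}

mask_grid_ <- function(x) {
  if (inherits(x, c("cell_mask", "texture_patch"))) x <- x$grid
  if (!is.logical(x)) x <- x > 0
  x
}

pixel_size_of_ <- function(x, pixel_size_um = NULL) {
  if (inherits(x, "image_plane") && is.null(pixel_size_um)) {
    return(x$pixel_size_um)
  }
  if (is.null(pixel_size_um)) {
    stop("pixel_size_um must be given when the input is a bare matrix",
         call. = FALSE)
  }
  pixel_size_um
}
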