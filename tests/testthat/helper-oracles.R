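# Independent reference implementations used to validate the package's
# algorithms. These are deliberately written as direct pixel-by-pixel /
# element-by-element procedures, not shared with the package internals.

# 3x3 binary dilation, pixel by pixel; outside the frame is background.
oracle_dilate3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      out[i, j] <- any(m[max(1, i - 1):min(nr, i + 1),
                         max(1, j - 1):min(nc, j + 1)])
    }
  }
  out
}

# 3x3 binary erosion; neighbourhoods truncated at the frame behave as if
# padded with background, so border object pixels erode away.
oracle_erode3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      full <- (i > 1 && i < nr && j > 1 && j < nc)
      out[i, j] <- full && all(m[(i - 1):(i + 1), (j - 1):(j + 1)])
    }
  }
  out
}

# Fill holes by breadth-first search: background pixels 4-connected to the
# border stay background, all other background pixels become foreground.
oracle_fill_holes <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  visited <- matrix(FALSE, nr, nc)
  queue <- integer(0)
  push <- function(i, j) {
    if (i >= 1 && i <= nr && j >= 1 && j <= nc &&
        !visited[i, j] && !m[i, j]) {
      visited[i, j] <<- TRUE
      queue <<- c(queue, (j - 1L) * nr + i)
    }
  }
  for (i in seq_len(nr)) { push(i, 1L); push(i, nc) }
  for (j in seq_len(nc)) { push(1L, j); push(nr, j) }
  while (length(queue)) {
    p <- queue[1]; queue <- queue[-1]
    i <- ((p - 1L) %% nr) + 1L
    j <- ((p - 1L) %/% nr) + 1L
    push(i - 1L, j); push(i + 1L, j); push(i, j - 1L); push(i, j + 1L)
  }
  m | (!m & !visited)
}

# The full mask pipeline on a binary grid: n rounds of dilate/fill/erode.
oracle_mask_pipeline <- function(m, rounds = 2L) {
  for (r in seq_len(rounds)) {
    m <- oracle_erode3(oracle_fill_holes(oracle_dilate3(m)))
  }
  m
}

# Zero crossings by explicit scan with a carried sign.
oracle_count_crossings <- function(values) {
  carried <- 0
  n <- 0L
  for (v in values) {
    s <- sign(v)
    if (s == 0) next
    if (carried != 0 && s != carried) n <- n + 1L
    carried <- s
  }
  n
}

# Local-average-subtracted reference by direct per-pixel window means.
oracle_reference <- function(m, patch, w) {
  nr <- nrow(m); nc <- ncol(m)
  h <- w %/% 2L
  ref <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (!patch[i, j]) next
      ri <- max(1, i - h):min(nr, i + h)
      cj <- max(1, j - h):min(nc, j + h)
      sub <- patch[ri, cj]
      ref[i, j] <- m[i, j] - mean(m[ri, cj][sub])
    }
  }
  ref[patch] <- ref[patch] - mean(ref[patch])
  ref
}

# A scene with ordinary shot/read noise but no illumination or ruffle
# confounds.
clean_scene <- function(texture_class = "punctate", seed = 1, ...) {
  generate_scene(scene_config(
    texture_class = texture_class, seed = seed,
    illumination_amplitude = 0, ruffle_count = 0L, ...
  ))
}
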