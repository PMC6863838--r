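test_that("a constant image has an all-zero reference", {
  patch <- matrix(TRUE, 48, 48)
  ref <- local_average_subtract(matrix(7, 48, 48), patch, window_um = 1,
                                pixel_size_um = 0.1)
  expect_true(all(abs(ref) < 1e-12))
})

test_that("the reference image matches a per-pixel oracle and has zero mean", {
  set.seed(7)
  m <- matrix(runif(48 * 48, 0, 100), 48)
  patch <- generate_cell_shape(c(64, 64), seed = 3)[1:48, 1:48]
  ref <- local_average_subtract(m, patch, window_um = 15, pixel_size_um = 1)
  want <- oracle_reference(m, patch, w = 15)
  expect_equal(ref, want, tolerance = 1e-12)
  expect_lt(abs(mean(ref[patch])), 1e-6 * 100)
  expect_true(all(ref[!patch] == 0))
  expect_error(
    local_average_subtract(m, patch, window_um = 0.2, pixel_size_um = 0.1),
    "3 pixels"
  )
})

test_that("a fine sinusoid passes through local-average subtraction", {
  # grating period far below the window: the running mean attenuates the
  # sinusoid by |sin(pi w / P) / (w sin(pi / P))| < 5%, so the reference
  # approximately equals the sinusoid away from the patch edge
  n <- 96; w <- 31; P <- 6
  s <- sin(2 * pi * outer(rep(1, n), 1:n) / P)
  img <- 50 + s
  patch <- matrix(TRUE, n, n)
  ref <- local_average_subtract(img, patch, window_um = w, pixel_size_um = 1)
  interior <- (w %/% 2 + 1):(n - w %/% 2)
  expect_lt(max(abs(ref[interior, interior] - s[interior, interior])), 0.05)
})

test_that("zero-crossing counting follows the sign-change contract", {
  expect_identical(count_zero_crossings(c(1, 1, -1, -1)), 1L)
  expect_identical(count_zero_crossings(c(1, -1, 1, -1)), 3L)
  expect_identical(count_zero_crossings(c(1, 0, -1)), 1L)
  expect_identical(count_zero_crossings(c(1, 0, 1)), 0L)
  expect_identical(count_zero_crossings(c(0, 0, 0)), 0L)
  expect_identical(count_zero_crossings(c(0, 0, -2, 5)), 1L)
  expect_error(count_zero_crossings(1), "2 samples")

  set.seed(11)
  for (i in 1:200) {
    v <- sample(c(-1, 1), sample(2:12, 1), replace = TRUE)
    expect_identical(count_zero_crossings(v), oracle_count_crossings(v))
  }
})

test_that("random lines are seeded, in-patch, and rejected on tiny patches", {
  patch <- matrix(FALSE, 32, 32)
  patch[16, 16] <- TRUE
  expect_error(
    sample_random_line(patch, matrix(0, 32, 32), 0.1),
    "could not sample"
  )

  big <- matrix(TRUE, 64, 64)
  ref <- matrix(rnorm(64 * 64), 64)
  set.seed(5); a <- sample_random_line(big, ref, 0.1)
  set.seed(5); b <- sample_random_line(big, ref, 0.1)
  expect_identical(a, b)
  expect_gte(length(a$values), 3)
  expect_true(all(diff(a$positions_um) > 0))
})

test_that("line anchors are uniform over the patch", {
  patch <- matrix(TRUE, 64, 64)
  ref <- matrix(rnorm(64 * 64), 64)
  set.seed(17)
  anchors <- t(replicate(10000, sample_random_line(patch, ref, 1)$anchor))
  bins <- table(cut(anchors[, 1], seq(0.5, 64.5, length.out = 5)),
                cut(anchors[, 2], seq(0.5, 64.5, length.out = 5)))
  p <- suppressWarnings(chisq.test(as.vector(bins)))$p.value
  expect_gt(p, 0.001)
})

test_that("a constant image scores zero and the score is seed-stable", {
  patch <- matrix(TRUE, 48, 48)
  z <- zc_score(matrix(3, 48, 48), patch, n_lines = 50, window_um = 2,
                seed = 1, pixel_size_um = 0.1)
  expect_identical(z$zc_score, 0)
  expect_identical(z$n_lines, 50L)
  expect_identical(nrow(z$per_line), 50L)

  sc <- clean_scene("punctate", seed = 2)
  mask <- make_cell_mask(sc$channels$ddr1)
  p <- segment_texture_patches(sc$channels$ddr1, mask)[[1]]
  z1 <- zc_score(sc$channels$ddr1, p, n_lines = 100, seed = 9)
  z2 <- zc_score(sc$channels$ddr1, p, n_lines = 100, seed = 9)
  expect_identical(z1$zc_score, z2$zc_score)
})

test_that("the ZC score is exactly invariant to intensity scaling", {
  sc <- generate_scene(scene_config(texture_class = "linear_cidc",
                                    char_length_um = 0.4, seed = 31))
  mask <- make_cell_mask(sc$channels$ddr1)
  p <- segment_texture_patches(sc$channels$ddr1, mask)[[1]]
  base <- zc_score(sc$channels$ddr1, p, n_lines = 150, seed = 4)$zc_score
  for (c_ in c(0.25, 12)) {
    scaled <- image_plane(c_ * sc$channels$ddr1$data, 0.1)
    expect_identical(zc_score(scaled, p, n_lines = 150, seed = 4)$zc_score,
                     base)
  }
})

test_that("coarser textures score lower at fixed density", {
  zs <- vapply(c(0.2, 0.4, 0.8), function(cl) {
    mean(vapply(1:3, function(s) {
      sc <- suppressWarnings(generate_scene(scene_config(
        image_shape = c(160L, 160L), texture_class = "punctate",
        char_length_um = cl, density = 6, seed = s + 70
      )))
      mask <- make_cell_mask(sc$channels$ddr1)
      cell_zc_score(sc$channels$ddr1, mask, n_lines = 150,
                    seed = s)$zc_score
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(zs) < 0))
})

test_that("score precision improves as 1/sqrt(n_lines)", {
  sc <- clean_scene("linear_cidc", char_length_um = 0.4, seed = 8)
  mask <- make_cell_mask(sc$channels$ddr1)
  p <- segment_texture_patches(sc$channels$ddr1, mask)[[1]]
  z_lo <- vapply(1:8, function(s) {
    zc_score(sc$channels$ddr1, p, n_lines = 100, seed = s)$zc_score
  }, numeric(1))
  z_hi <- vapply(1:8, function(s) {
    zc_score(sc$channels$ddr1, p, n_lines = 400, seed = 100 + s)$zc_score
  }, numeric(1))
  ratio <- sd(z_lo) / sd(z_hi)           # expected ~ sqrt(4) = 2
  expect_gt(ratio, 1.2)
  expect_lt(ratio, 3.5)
  # quadrupling the line count moves the score by less than the spread of
  # the low-precision estimate
  expect_lt(abs(mean(z_hi) - mean(z_lo)), sd(z_lo))
})

test_that("pooled aggregation is available and close to mean-of-ratios", {
  sc <- clean_scene("punctate", seed = 12)
  mask <- make_cell_mask(sc$channels$ddr1)
  p <- segment_texture_patches(sc$channels$ddr1, mask)[[1]]
  zm <- zc_score(sc$channels$ddr1, p, n_lines = 300, seed = 2)
  zp <- zc_score(sc$channels$ddr1, p, n_lines = 300, seed = 2,
                 aggregate = "pooled")
  expect_identical(zp$aggregate, "pooled")
  expect_lt(abs(zp$zc_score / zm$zc_score - 1), 0.2)
})
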