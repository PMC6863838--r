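test_that("cell silhouettes are seeded, distinct, and sized like cells", {
  m1 <- generate_cell_shape(c(128, 128), seed = 1)
  m2 <- generate_cell_shape(c(128, 128), seed = 1)
  m3 <- generate_cell_shape(c(128, 128), seed = 2)
  expect_identical(m1, m2)
  expect_false(identical(m1, m3))
  expect_error(generate_cell_shape(c(32, 128)), "too small")

  fracs <- vapply(1:100, function(s) {
    mean(generate_cell_shape(c(128, 128), seed = s))
  }, numeric(1))
  expect_true(all(fracs >= 0.2 & fracs <= 0.6))
})

test_that("rendered texture is linear in amplitude and vanishes at zero density", {
  mask <- generate_cell_shape(c(96, 96), seed = 4)
  cfg0 <- scene_config(image_shape = c(96, 96), texture_class = "punctate",
                       density = 0, seed = 5)
  expect_true(all(render_texture(cfg0, mask, seed = 5)$channels$ddr1 == 0))

  cfg1 <- scene_config(image_shape = c(96, 96), texture_class = "linear_cidc",
                       char_length_um = 0.4, amplitude = 50, seed = 5)
  cfg2 <- scene_config(image_shape = c(96, 96), texture_class = "linear_cidc",
                       char_length_um = 0.4, amplitude = 100, seed = 5)
  t1 <- render_texture(cfg1, mask, seed = 9)$channels$ddr1
  t2 <- render_texture(cfg2, mask, seed = 9)$channels$ddr1
  expect_identical(2 * t1, t2)
})

test_that("double-wall truth has a trough between the walls with the filler centred", {
  cfg <- scene_config(image_shape = c(160, 160), pixel_size_um = 0.04,
                      texture_class = "double_wall", char_length_um = 0.3,
                      seed = 21)
  sc <- generate_scene(cfg)
  ddr1 <- sc$truth$per_channel_truth$ddr1
  coll <- sc$truth$per_channel_truth$collagen
  g_px <- cfg$char_length_um / cfg$pixel_size_um
  ok_centre <- ok_filler <- 0L
  n_pts <- 0L
  for (pts in sc$truth$structure_centrelines) {
    if (nrow(pts) < 9) next
    for (i in seq(5, nrow(pts) - 4, by = 4)) {
      tang <- pts[i + 2, ] - pts[i - 2, ]
      tang <- tang / sqrt(sum(tang^2))
      nrm <- c(-tang[2], tang[1])
      at <- function(m, p) m[round(p[1]), round(p[2])]
      centre <- pts[i, ]
      pp <- centre + nrm * g_px / 2
      pm <- centre - nrm * g_px / 2
      n_pts <- n_pts + 1L
      if (at(ddr1, centre) < at(ddr1, pp) &&
          at(ddr1, centre) < at(ddr1, pm)) ok_centre <- ok_centre + 1L
      if (at(coll, centre) > at(coll, pp) &&
          at(coll, centre) > at(coll, pm)) ok_filler <- ok_filler + 1L
    }
  }
  expect_gt(n_pts, 5)
  # walls flank a trough, and the filler peaks in it, at nearly every
  # interior centreline point
  expect_gt(ok_centre / n_pts, 0.9)
  expect_gt(ok_filler / n_pts, 0.9)
})

test_that("corruption is the identity when all confounds are off", {
  cfg <- scene_config(image_shape = c(96, 96), noise_gaussian_sd = 0,
                      noise_poisson = FALSE, illumination_amplitude = 0,
                      ruffle_count = 0L, seed = 2)
  x <- matrix(runif(96 * 96, 0, 50), 96)
  out <- corrupt(x, cfg, seed = 3)
  expect_identical(out$plane, x)
})

test_that("corruption is reproducible and Gaussian noise has the stated sd", {
  cfg <- scene_config(image_shape = c(128, 128), noise_gaussian_sd = 7,
                      noise_poisson = FALSE, illumination_amplitude = 0,
                      ruffle_count = 0L, seed = 2)
  zero <- matrix(0, 128, 128)
  a <- corrupt(zero, cfg, seed = 11)$plane
  b <- corrupt(zero, cfg, seed = 11)$plane
  expect_identical(a, b)
  expect_lt(abs(sd(a) / 7 - 1), 0.05)
  expect_error(corrupt(matrix(-1, 4, 4), cfg, seed = 1), ">= 0")
})

test_that("whole scenes are bit-reproducible from their seed", {
  cfg <- scene_config(image_shape = c(96, 96), seed = 13)
  s1 <- generate_scene(cfg)
  s2 <- generate_scene(cfg)
  expect_identical(s1$channels$ddr1$data, s2$channels$ddr1$data)
  expect_identical(s1$truth$cell_mask, s2$truth$cell_mask)
})

test_that("structure centrelines lie inside the cell mask", {
  for (s in 1:5) {
    sc <- generate_scene(scene_config(
      image_shape = c(128, 128), texture_class = "linear_cidc",
      char_length_um = 0.4, seed = s
    ))
    mask <- sc$truth$cell_mask
    for (pts in sc$truth$structure_centrelines) {
      expect_true(all(mask[cbind(round(pts[, 1]), round(pts[, 2]))]))
    }
  }
})

test_that("the time course maps to punctate, linear and aggregate textures", {
  single <- generate_timecourse(0, seed = 5, image_shape = c(96L, 96L))
  expect_length(single, 1)
  expect_identical(single[[1]]$config$texture_class, "punctate")

  scenes <- generate_timecourse(c(0, 10, 60), seed = 5,
                                image_shape = c(96L, 96L))
  classes <- vapply(scenes, function(s) s$config$texture_class, character(1))
  lens <- vapply(scenes, function(s) s$config$char_length_um, numeric(1))
  expect_identical(unname(classes),
                   c("punctate", "linear_cidc", "aggregate"))
  expect_true(all(diff(lens) > 0))

  again <- generate_timecourse(c(0, 10, 60), seed = 5,
                               image_shape = c(96L, 96L))
  expect_identical(scenes[[2]]$channels$ddr1$data,
                   again[[2]]$channels$ddr1$data)
  expect_error(generate_timecourse(numeric(0)), "non-empty")
})
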