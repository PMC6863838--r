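test_that("mean intensity is the in-mask arithmetic mean", {
  mask <- matrix(TRUE, 10, 10)
  expect_identical(mean_intensity(matrix(4.5, 10, 10), mask), 4.5)

  half <- matrix(c(rep(0, 50), rep(10, 50)), 10)
  expect_identical(mean_intensity(half, mask), 5)

  set.seed(3)
  img <- matrix(rnorm(400), 20)
  m <- matrix(runif(400) < 0.4, 20)
  naive <- {
    tot <- 0; n <- 0
    for (i in 1:20) for (j in 1:20) if (m[i, j]) {
      tot <- tot + img[i, j]; n <- n + 1
    }
    tot / n
  }
  expect_equal(mean_intensity(img, m), naive, tolerance = 1e-12)
  expect_error(mean_intensity(img, matrix(FALSE, 20, 20)), "empty")
})

test_that("colocalisation cropping intersects the mask with the crop", {
  g <- matrix(FALSE, 20, 20); g[5:15, 5:15] <- TRUE
  mask <- structure(list(grid = g, source_channel = "ddr1",
                         background_level = 1), class = "cell_mask")
  col <- matrix(1, 20, 20)
  full <- restrict_to_colocalized(col, mask, c(1, 20, 1, 20))
  expect_identical(full$grid, g)
  expect_warning(
    empty <- restrict_to_colocalized(col, mask, c(17, 20, 17, 20)),
    "zero-area"
  )
  expect_identical(sum(empty$grid), 0L)
  expect_error(restrict_to_colocalized(col, mask, c(0, 25, 1, 20)),
               "inside the image frame")
  # an extracellular aggregate (outside the receptor mask) is excluded
  agg <- matrix(FALSE, 20, 20); agg[1:3, 1:3] <- TRUE
  kept <- restrict_to_colocalized(col, mask, c(1, 20, 1, 20))
  expect_identical(sum(kept$grid & agg), 0L)
})

test_that("anchor normalisation maps anchor means to exactly 0 and 100", {
  vals <- c(5, 5, 15, 15, 10)
  cond <- c("un", "un", "st", "st", "mid")
  out <- anchor_normalize(vals, cond, "un", "st")
  expect_identical(out, c(0, 0, 100, 100, 50))
  expect_identical(anchor_normalize(c(2, 8, 1), c("a", "b", "c"),
                                    "a", "b")[3], -100 / 6)
  expect_error(anchor_normalize(c(1, 1), c("a", "b"), "a", "b"),
               "identical")
  expect_error(anchor_normalize(1:3, c("a", "b", "c"), "a", "z"),
               "present")
  # affine and order-preserving (with the high anchor above the low one)
  set.seed(1)
  v <- c(rnorm(10), rnorm(10, 5)); cn <- rep(c("a", "b"), each = 10)
  out <- anchor_normalize(v, cn, "a", "b")
  expect_identical(order(out), order(v))
})

test_that("positive-cell fractions and their binomial errors are correct", {
  expect_identical(fraction_positive(c(1, 2, 3), 10)$percent, 0)
  fp <- fraction_positive(c(rep(0, 9), 5), 1)
  expect_identical(fp$percent, 10)
  expect_equal(fp$se, 100 * sqrt(0.1 * 0.9 / 10), tolerance = 1e-12)

  set.seed(9)
  vals <- c(rnorm(140, 0, 1), rnorm(60, 6, 1))   # 30% true positives
  fp <- fraction_positive(vals, 3)
  expect_lt(abs(fp$percent - 30), 3 * 100 * sqrt(0.3 * 0.7 / 200))
})

test_that("densitometry fractions normalise per lane and sum to 100", {
  b <- data.frame(label = c("a", "b"), pY_intensity = c(2, 4),
                  total_intensity = c(1, 2))
  expect_equal(densitometry_fractions(b)$percent, c(50, 50))
  expect_equal(densitometry_fractions(
    data.frame(label = "x", pY_intensity = 3, total_intensity = 9)
  )$percent, 100)
  out <- densitometry_fractions(data.frame(
    label = letters[1:3], pY_intensity = 1:3, total_intensity = rep(1, 3)
  ))
  expect_equal(out$percent, c(100 / 6, 100 / 3, 50), tolerance = 1e-9)
  expect_lt(abs(sum(out$percent) - 100), 1e-9)
  expect_error(densitometry_fractions(data.frame(
    label = c("ok", "bad"), pY_intensity = c(1, 1),
    total_intensity = c(1, 0)
  )), "bad")
})

test_that("expression weighting is a scale-invariant ratio", {
  expect_identical(as.numeric(normalize_by_expression(10, 2)), 5)
  expect_identical(attr(normalize_by_expression(10, 2), "convention"),
                   "ratio")
  expect_identical(as.numeric(normalize_by_expression(20, 4)),
                   as.numeric(normalize_by_expression(10, 2)))
  # equal expression preserves the ordering of raw medians
  raw <- c(3, 9, 6)
  w <- as.numeric(normalize_by_expression(raw, 2))
  expect_identical(order(w), order(raw))
  expect_error(normalize_by_expression(5, 0), "> 0")
})

test_that("group comparison finds real separations and not identical groups", {
  y0 <- rep(c(1, 2, 3), 10)
  flat <- group_compare(c(y0, y0), rep(c("a", "b"), each = 30))
  expect_gt(flat$anova$p, 0.9)
  expect_false(any(flat$posthoc$significant))

  set.seed(2)
  y <- c(rnorm(50), rnorm(50, 5))
  g <- rep(c("ctrl", "stim"), each = 50)
  sep <- group_compare(y, g)
  expect_true(all(sep$posthoc$significant))
  expect_error(group_compare(1:5, rep("a", 5)), "2 groups")

  tk <- group_compare(c(rnorm(20), rnorm(20, 3), rnorm(20)),
                      rep(c("a", "b", "c"), each = 20), posthoc = "tukey")
  expect_identical(nrow(tk$posthoc), 3L)
  dn <- group_compare(c(rnorm(20), rnorm(20, 3), rnorm(20)),
                      rep(c("a", "b", "c"), each = 20),
                      posthoc = "dunnett", control = "a")
  expect_identical(nrow(dn$posthoc), 2L)
})

test_that("the ANOVA holds its nominal type-I error on null data", {
  set.seed(21)
  hits <- 0L
  reps <- 1000L
  y <- rnorm(30)
  for (i in seq_len(reps)) {
    g <- sample(rep(c("a", "b", "c"), each = 10))
    p <- group_compare(rnorm(30), g)$anova$p
    hits <- hits + (p < 0.05)
  }
  expect_lt(abs(hits / reps - 0.05), 0.02)
})
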