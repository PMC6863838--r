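#' Mean intensity within a cell mask
#'
#' @param image [image_plane()] or numeric matrix.
#' @param mask `cell_mask`, `texture_patch` or logical matrix.
#' @return Arithmetic mean of the in-mask pixel intensities.
#' @export
mean_intensity <- function(image, mask) {
  m <- as_matrix_(image)
  g <- mask_grid_(mask)
  if (!any(g)) stop("mask is empty", call. = FALSE)
  mean(m[g])
}

#' Restrict a DDR1 mask to a manually cropped colocalisation region
#'
#' Collagen is quantified only where it colocalises with the receptor
#' stain: the analysis region is the intersection of the cell (DDR1) mask
#' with a manually chosen crop, excluding e.g. extracellular collagen
#' aggregates.
#'
#' @param collagen [image_plane()] or matrix (used for dimension checks).
#' @param ddr1_mask `cell_mask` or logical matrix.
#' @param crop Either a logical matrix of the same shape or a list/vector
#'   `c(rmin, rmax, cmin, cmax)` of an axis-aligned crop rectangle.
#' @return A `cell_mask` restricted to the crop; a zero-area mask (with a
#'   warning) if the intersection is empty.
#' @export
restrict_to_colocalized <- function(collagen, ddr1_mask, crop) {
  m <- as_matrix_(collagen)
  g <- mask_grid_(ddr1_mask)
  stopifnot(all(dim(m) == dim(g)))
  if (is.matrix(crop)) {
    cg <- mask_grid_(crop)
    stopifnot(all(dim(cg) == dim(g)))
  } else {
    crop <- as.integer(unlist(crop))
    if (length(crop) != 4 || crop[1] < 1 || crop[3] < 1 ||
        crop[2] > nrow(g) || crop[4] > ncol(g) ||
        crop[1] > crop[2] || crop[3] > crop[4]) {
      stop("crop rectangle must lie inside the image frame", call. = FALSE)
    }
    cg <- matrix(FALSE, nrow(g), ncol(g))
    cg[crop[1]:crop[2], crop[3]:crop[4]] <- TRUE
  }
  out <- g & cg
  if (!any(out)) {
    warning("crop does not intersect the DDR1 mask: zero-area result",
            call. = FALSE)
  }
  structure(list(grid = out, source_channel = "ddr1",
                 background_level = NA_real_), class = "cell_mask")
}

#' Anchor normalisation of per-cell values to a 0--100 A.U. scale
#'
#' Affine rescaling so that the mean of the `low_condition` group maps to 0
#' and the mean of the `high_condition` group maps to 100:
#' \eqn{x \mapsto 100 (x - \bar{x}_{low}) / (\bar{x}_{high} - \bar{x}_{low})}.
#' Values outside the anchor range map below 0 or above 100.
#'
#' @param values Numeric vector of per-cell measurements.
#' @param condition Factor/character vector of condition labels.
#' @param low_condition,high_condition Labels of the anchor conditions.
#' @return Numeric vector of normalised values (A.U.).
#' @export
anchor_normalize <- function(values, condition, low_condition,
                             high_condition) {
  condition <- as.character(condition)
  if (!low_condition %in% condition || !high_condition %in% condition) {
    stop("both anchor conditions must be present", call. = FALSE)
  }
  lo <- mean(values[condition == low_condition])
  hi <- mean(values[condition == high_condition])
  if (hi == lo) {
    stop("anchor condition means are identical: normalisation scale is ",
         "undefined", call. = FALSE)
  }
  100 * (values - lo) / (hi - lo)
}

#' Fraction of cells with signal above a threshold
#'
#' @param values Per-cell mean intensities (e.g. phospho-stain).
#' @param threshold Positivity threshold (a.u.).
#' @return List: `percent`, `se` (binomial standard error, percentage
#'   points), `n_above`, `n`.
#' @export
fraction_positive <- function(values, threshold) {
  n <- length(values)
  if (n < 1) stop("need at least one value", call. = FALSE)
  k <- sum(values > threshold)
  p <- k / n
  list(percent = 100 * p, se = 100 * sqrt(p * (1 - p) / n),
       n_above = k, n = n)
}

#' Densitometry band fractions across a blot
#'
#' Each lane's phospho-band intensity is first normalised to its total
#' receptor band, and the per-lane ratios are expressed as percentages of
#' the sum of all ratios on the blot, so the outputs sum to 100.
#'
#' @param bands Data frame with columns `label`, `pY_intensity`,
#'   `total_intensity` (or a list of such lanes).
#' @return Data frame: `label`, `ratio`, `percent`.
#' @export
densitometry_fractions <- function(bands) {
  bands <- as.data.frame(bands)
  stopifnot(all(c("pY_intensity", "total_intensity") %in% names(bands)))
  if (any(bands$pY_intensity < 0)) {
    stop("band intensities must be >= 0", call. = FALSE)
  }
  bad <- which(bands$total_intensity <= 0)
  if (length(bad)) {
    stop("zero or negative total intensity in lane ",
         paste(if (!is.null(bands$label)) bands$label[bad] else bad,
               collapse = ", "), call. = FALSE)
  }
  r <- bands$pY_intensity / bands$total_intensity
  data.frame(
    label = if (!is.null(bands$label)) bands$label else seq_along(r),
    ratio = r,
    percent = 100 * r / sum(r)
  )
}

#' Expression-weighted median signal
#'
#' Weights a construct's median stain value by its median receptor
#' expression, as a ratio (`signal_median / expression_median`), so
#' constructs expressed at different levels are comparable. The ratio
#' convention is recorded in the result's `convention` attribute.
#'
#' @param signal_median Median stain value (a.u.).
#' @param expression_median Median receptor-expression value (> 0).
#' @return Weighted value with attribute `convention = "ratio"`.
#' @export
normalize_by_expression <- function(signal_median, expression_median) {
  if (any(expression_median <= 0)) {
    stop("expression_median must be > 0", call. = FALSE)
  }
  structure(signal_median / expression_median, convention = "ratio")
}

#' One-way group comparison with a chosen post-hoc test
#'
#' Delegates to a standard one-way ANOVA (`aov`) followed by the configured
#' post-hoc procedure: Bonferroni-adjusted pairwise t tests, Tukey HSD, or
#' Dunnett contrasts against a control group. Significance is declared at
#' adjusted p < 0.05.
#'
#' @param values Numeric measurements.
#' @param group Factor/character group labels (>= 2 groups).
#' @param posthoc `"bonferroni"`, `"tukey"` or `"dunnett"`.
#' @param control Control group label for Dunnett (default: first level).
#' @return List of class `group_comparison`: `anova` (data.frame with F and
#'   p), `posthoc` (data.frame: comparison, estimate, p_adj, significant),
#'   `method`.
#' @export
group_compare <- function(values, group,
                          posthoc = c("bonferroni", "tukey", "dunnett"),
                          control = NULL) {
  posthoc <- match.arg(posthoc)
  group <- factor(group)
  if (nlevels(group) < 2) stop("need at least 2 groups", call. = FALSE)
  dat <- data.frame(y = values, g = group)
  fit <- stats::aov(y ~ g, data = dat)
  an <- summary(fit)[[1]]
  anova_tab <- data.frame(
    statistic = an["g", "F value"],
    p = an["g", "Pr(>F)"]
  )
  tab <- switch(posthoc,
    tukey = {
      tk <- stats::TukeyHSD(fit)$g
      data.frame(
        comparison = rownames(tk),
        estimate = tk[, "diff"],
        p_adj = tk[, "p adj"],
        row.names = NULL
      )
    },
    bonferroni = {
      pt <- stats::pairwise.t.test(dat$y, dat$g,
                                   p.adjust.method = "bonferroni")
      pm <- pt$p.value
      means <- tapply(dat$y, dat$g, mean)
      idx <- which(!is.na(pm), arr.ind = TRUE)
      data.frame(
        comparison = paste(rownames(pm)[idx[, 1]], colnames(pm)[idx[, 2]],
                           sep = "-"),
        estimate = means[rownames(pm)[idx[, 1]]] -
          means[colnames(pm)[idx[, 2]]],
        p_adj = pm[idx],
        row.names = NULL
      )
    },
    dunnett = {
      if (!is.null(control)) dat$g <- stats::relevel(dat$g, ref = control)
      fit2 <- stats::aov(y ~ g, data = dat)
      gl <- multcomp::glht(fit2, linfct = multcomp::mcp(g = "Dunnett"))
      sm <- summary(gl)
      data.frame(
        comparison = names(sm$test$coefficients),
        estimate = as.numeric(sm$test$coefficients),
        p_adj = as.numeric(sm$test$pvalues),
        row.names = NULL
      )
    }
  )
  tab$significant <- tab$p_adj < 0.05
  structure(list(anova = anova_tab, posthoc = tab, method = posthoc),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> one-way ANOVA F = %.3g, p = %.3g; %s post hoc\n",
              x$anova$statistic, x$anova$p, x$method))
  print(x$posthoc, digits = 3)
  invisible(x)
}
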