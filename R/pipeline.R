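#' Build an analysis configuration for the time-course pipeline
#'
#' @param times Stimulation times in minutes (default `c(0, 10, 60)`).
#' @param n_experiments Number of pseudo-independent experiments.
#' @param cells_per_time Cells simulated per time point per experiment.
#' @param image_shape Scene frame in pixels.
#' @param pixel_size_um Pixel size (um/px).
#' @param n_lines Random lines per texture patch for the ZC score.
#' @param window_um Local-averaging window (um).
#' @param anchor_low,anchor_high Times whose per-experiment means anchor the
#'   0 and 100 A.U. normalisation of the phospho signal.
#' @param posthoc Post-hoc test for the ZC group comparison.
#' @param seed Master seed; every downstream random draw derives from it.
#' @param out_dir Output directory for CSVs and the summary plot, or NULL
#'   to skip writing.
#' @param scene_args Extra arguments forwarded to [scene_config()].
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(times = c(0, 10, 60),
                            n_experiments = 3L,
                            cells_per_time = 10L,
                            image_shape = c(192L, 192L),
                            pixel_size_um = 0.1,
                            n_lines = 300L,
                            window_um = 10,
                            anchor_low = 0,
                            anchor_high = max(times),
                            posthoc = "bonferroni",
                            seed = 1L,
                            out_dir = NULL,
                            scene_args = list()) {
  stopifnot(length(times) >= 1, n_experiments >= 1, cells_per_time >= 1)
  structure(list(
    times = times, n_experiments = as.integer(n_experiments),
    cells_per_time = as.integer(cells_per_time),
    image_shape = as.integer(image_shape), pixel_size_um = pixel_size_um,
    n_lines = as.integer(n_lines), window_um = window_um,
    anchor_low = anchor_low, anchor_high = anchor_high,
    posthoc = posthoc, seed = as.integer(seed), out_dir = out_dir,
    scene_args = scene_args
  ), class = "analysis_config")
}

#' Run the time-course analysis pipeline on a synthetic cohort
#'
#' For every experiment, cell and stimulation time: simulate a scene, build
#' the cell mask from the receptor channel, segment texture patches, compute
#' the mean ZC score and the mean phospho-channel intensity. Phospho means
#' are then anchor-normalised within each experiment (the low/high anchor
#' time means map to 0/100 A.U.), the positive-cell fraction is computed
#' against a mean + 2 sd threshold from the 0-min condition, and ZC scores
#' are compared across times with ANOVA plus the configured post-hoc test.
#' Per-cell failures are logged as exclusions and the pipeline continues.
#' Fully deterministic given `config$seed`.
#'
#' @param config An [analysis_config()].
#' @return A `timecourse_report`: `measurements` (per-cell data.frame),
#'   `summary` (per-time means, SEM, positive fraction), `comparison`
#'   (ZC group test), `exclusions` (data.frame of logged failures),
#'   `config`. If `config$out_dir` is set, writes `measurements.csv`,
#'   `summary.csv`, `comparisons.csv`, `exclusions.csv`, `summary.png` and
#'   a `run.json` provenance record there.
#' @export
run_timecourse_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  rows <- list()
  excl <- list()
  with_seed_(config$seed, {
    for (e in seq_len(config$n_experiments)) {
      for (cell in seq_len(config$cells_per_time)) {
        scene_seeds <- sample.int(.Machine$integer.max - 1L,
                                  length(config$times))
        zc_seeds <- sample.int(.Machine$integer.max - 1L,
                               length(config$times))
        for (ti in seq_along(config$times)) {
          t <- config$times[ti]
          res <- tryCatch({
            cls <- timepoint_class_(t)
            args <- c(cls, list(
              image_shape = config$image_shape,
              pixel_size_um = config$pixel_size_um,
              seed = scene_seeds[ti],
              py_amplitude = 100 * (0.02 + 0.9 * min(t, 60) / 60)
            ), config$scene_args)
            args <- args[!duplicated(names(args))]
            scene <- generate_scene(do.call(scene_config, args))
            mask <- make_cell_mask(scene$channels$ddr1)
            zc <- cell_zc_score(scene$channels$ddr1, mask,
                                n_lines = config$n_lines,
                                window_um = config$window_um,
                                seed = zc_seeds[ti])
            data.frame(
              experiment = e, cell_id = cell, time_min = t,
              zc_score = zc$zc_score, n_patches = zc$n_patches,
              py_mean = mean_intensity(scene$channels$py, mask),
              ddr1_mean = mean_intensity(scene$channels$ddr1, mask),
              mask_area_px = sum(mask$grid),
              seed = scene_seeds[ti]
            )
          }, error = function(err) err)
          if (inherits(res, "error")) {
            excl[[length(excl) + 1L]] <- data.frame(
              experiment = e, cell_id = cell, time_min = t,
              reason = conditionMessage(res)
            )
          } else {
            rows[[length(rows) + 1L]] <- res
          }
        }
      }
    }
  })
  if (length(rows) == 0) stop("no cell was analysed successfully",
                              call. = FALSE)
  meas <- do.call(rbind, rows)
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(experiment = integer(), cell_id = integer(),
               time_min = numeric(), reason = character())

  # within-experiment anchor normalisation of the phospho signal
  meas$py_norm <- NA_real_
  for (e in unique(meas$experiment)) {
    i <- meas$experiment == e
    meas$py_norm[i] <- anchor_normalize(
      meas$py_mean[i], meas$time_min[i],
      low_condition = config$anchor_low, high_condition = config$anchor_high
    )
  }

  thr <- {
    v0 <- meas$py_mean[meas$time_min == config$anchor_low]
    mean(v0) + 2 * stats::sd(v0)
  }
  sem_ <- function(x) stats::sd(x) / sqrt(length(x))
  agg <- lapply(split(meas, meas$time_min), function(d) {
    fp <- fraction_positive(d$py_mean, thr)
    data.frame(
      time_min = d$time_min[1], n_cells = nrow(d),
      zc_mean = mean(d$zc_score), zc_sem = sem_(d$zc_score),
      py_norm_mean = mean(d$py_norm), py_norm_sem = sem_(d$py_norm),
      positive_pct = fp$percent, positive_se = fp$se
    )
  })
  summary_tab <- do.call(rbind, agg)
  summary_tab <- summary_tab[order(summary_tab$time_min), ]
  rownames(summary_tab) <- NULL

  comparison <- if (length(unique(meas$time_min)) >= 2) {
    group_compare(meas$zc_score, factor(meas$time_min),
                  posthoc = config$posthoc)
  }

  report <- structure(list(
    measurements = meas, summary = summary_tab, comparison = comparison,
    exclusions = exclusions, positivity_threshold = thr, config = config
  ), class = "timecourse_report")

  if (!is.null(config$out_dir)) write_report_(report, config$out_dir)
  report
}

write_report_ <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$measurements,
                   file.path(dir, "measurements.csv"), row.names = FALSE)
  utils::write.csv(report$summary,
                   file.path(dir, "summary.csv"), row.names = FALSE)
  utils::write.csv(report$exclusions,
                   file.path(dir, "exclusions.csv"), row.names = FALSE)
  if (!is.null(report$comparison)) {
    utils::write.csv(report$comparison$posthoc,
                     file.path(dir, "comparisons.csv"), row.names = FALSE)
  }
  cfg <- report$config
  jsonlite::write_json(
    list(seed = cfg$seed, times = cfg$times,
         n_experiments = cfg$n_experiments,
         cells_per_time = cfg$cells_per_time, n_lines = cfg$n_lines,
         window_um = cfg$window_um,
         package_version = as.character(utils::packageVersion("zctexture"))),
    file.path(dir, "run.json"), auto_unbox = TRUE, digits = NA
  )
  grDevices::png(file.path(dir, "summary.png"), width = 900, height = 450)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, 2))
  s <- report$summary
  graphics::plot(s$time_min, s$zc_mean, type = "b", pch = 19,
                 ylim = range(c(s$zc_mean - s$zc_sem, s$zc_mean + s$zc_sem)),
                 xlab = "stimulation time (min)",
                 ylab = "mean ZC score (crossings/um)",
                 main = "Texture coarsening")
  graphics::arrows(s$time_min, s$zc_mean - s$zc_sem,
                   s$time_min, s$zc_mean + s$zc_sem,
                   angle = 90, code = 3, length = 0.04)
  graphics::plot(s$time_min, s$py_norm_mean, type = "b", pch = 19,
                 xlab = "stimulation time (min)",
                 ylab = "phospho signal (A.U., anchored 0-100)",
                 main = "Receptor phosphorylation")
  invisible(NULL)
}

#' @export
print.timecourse_report <- function(x, ...) {
  cat(sprintf(
    "<timecourse_report> %d cells analysed, %d excluded; times: %s min\n",
    nrow(x$measurements), nrow(x$exclusions),
    paste(sort(unique(x$measurements$time_min)), collapse = ", ")
  ))
  print(x$summary, digits = 4)
  invisible(x)
}
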