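# Downstream analyses: threshold sweeps and slopes, photostability count
# series, 2D-vs-3D count comparison, and two-condition knockdown comparison.

#' Spot counts across a range of detection thresholds
#'
#' Runs the full detection pipeline on every cell at every threshold and
#' summarises counts across cells.  The threshold dependence of the counts is
#' the robustness diagnostic: bright, uniform probes give a flat curve;
#' probes whose spots sit close to the autofluorescence background give a
#' steep one.
#'
#' @param frames List of image frames (one per cell).
#' @param masks List of cell masks (or `NULL` to count the whole frame).
#' @param psf A [psf_model()].
#' @param thresholds_db Increasing vector of thresholds in dB.
#' @param config A [detection_config()] (its `threshold_db` is overridden).
#' @return An object of class `threshold_sweep`: per-cell count matrix,
#'   per-threshold mean and sd, and central-difference slopes.
#' @export
threshold_sweep <- function(frames, masks = NULL, psf = psf_model(1.2),
                            thresholds_db = seq(25, 35, by = 2),
                            config = detection_config()) {
  if (!length(frames)) stop("need at least one frame", call. = FALSE)
  if (is.unsorted(thresholds_db, strictly = TRUE)) {
    stop("`thresholds_db` must be strictly increasing", call. = FALSE)
  }
  counts <- matrix(0L, length(frames), length(thresholds_db),
                   dimnames = list(NULL, paste0("db", thresholds_db)))
  for (ci in seq_along(frames)) {
    for (ti in seq_along(thresholds_db)) {
      cfg <- config
      cfg$threshold_db <- thresholds_db[ti]
      det <- detect_spots(frames[[ci]], psf, cfg)
      counts[ci, ti] <- if (is.null(masks)) {
        nrow(det$spots)
      } else {
        count_per_cell(det, masks[[ci]])
      }
    }
  }
  res <- structure(list(thresholds_db = thresholds_db,
                        per_cell_counts = counts,
                        mean_counts = colMeans(counts),
                        sd_counts = apply(counts, 2, stats::sd)),
                   class = "threshold_sweep")
  res$slopes <- sweep_slope(res)
  res
}

#' Slopes of the count-vs-threshold curve
#'
#' Finite differences of the mean count with respect to the threshold:
#' central differences at interior thresholds, one-sided at the ends (exact
#' for counts quadratic in the threshold on an even grid).  With a single
#' threshold the slope is undefined and returned as `NA` (flagged).
#'
#' @param sweep A [threshold_sweep()] result.
#' @return Numeric vector of slopes, one per threshold (counts per dB).
#' @export
sweep_slope <- function(sweep) {
  t <- sweep$thresholds_db
  m <- sweep$mean_counts
  k <- length(t)
  if (k < 2L) return(NA_real_)
  s <- numeric(k)
  s[1] <- (m[2] - m[1]) / (t[2] - t[1])
  s[k] <- (m[k] - m[k - 1]) / (t[k] - t[k - 1])
  if (k > 2L) {
    for (i in 2:(k - 1)) s[i] <- (m[i + 1] - m[i - 1]) / (t[i + 1] - t[i - 1])
  }
  unname(s)
}

#' @export
print.threshold_sweep <- function(x, ...) {
  cat(sprintf("threshold_sweep: %d cells x %d thresholds (%g-%g dB)\n",
              nrow(x$per_cell_counts), length(x$thresholds_db),
              min(x$thresholds_db), max(x$thresholds_db)))
  print(data.frame(threshold_db = x$thresholds_db, mean = x$mean_counts,
                   sd = x$sd_counts, slope = x$slopes, row.names = NULL))
  invisible(x)
}

#' @export
plot.threshold_sweep <- function(x, ...) {
  t <- x$thresholds_db
  graphics::plot(t, x$mean_counts, type = "b", pch = 19,
                 xlab = "threshold (dB)", ylab = "mean spot count",
                 ylim = range(c(x$mean_counts - x$sd_counts,
                                x$mean_counts + x$sd_counts)), ...)
  graphics::arrows(t, x$mean_counts - x$sd_counts,
                   t, x$mean_counts + x$sd_counts,
                   angle = 90, code = 3, length = 0.03, col = "grey50")
  invisible(x)
}

#' FISH counts over excitation time (photostability series)
#'
#' Detects spots at every time point of each cell's time-lapse and normalises
#' the mean count to the first time point.  Photostable probes hold a flat
#' series; bleaching probes lose counts as spots fall below threshold.
#'
#' @param stacks List of time-axis [image_stack()]s sharing one time grid.
#' @param masks Optional list of cell masks.
#' @param psf A [psf_model()].
#' @param config A [detection_config()].
#' @return An object of class `count_series`: `times_s`, per-cell count
#'   matrix, and `normalized_mean` (first element 1 by construction).
#' @export
photostability_series <- function(stacks, masks = NULL, psf = psf_model(1.2),
                                  config = detection_config()) {
  times <- stacks[[1]]$times_s
  for (s in stacks) {
    if (!inherits(s, "image_stack") || s$axis != "time") {
      stop("all stacks must be time-axis image_stacks", call. = FALSE)
    }
    if (!isTRUE(all.equal(s$times_s, times))) {
      stop("all stacks must share one time grid", call. = FALSE)
    }
  }
  counts <- matrix(0L, length(stacks), length(times))
  for (ci in seq_along(stacks)) {
    for (fi in seq_along(times)) {
      det <- detect_spots(stacks[[ci]]$frames[[fi]], psf, config)
      counts[ci, fi] <- if (is.null(masks)) nrow(det$spots)
                        else count_per_cell(det, masks[[ci]])
    }
  }
  m0 <- mean(counts[, 1])
  structure(list(times_s = times, per_cell_counts = counts,
                 mean_counts = colMeans(counts),
                 normalized_mean = colMeans(counts) / m0),
            class = "count_series")
}

#' @export
print.count_series <- function(x, ...) {
  print(data.frame(time_s = x$times_s, mean_count = x$mean_counts,
                   normalized = x$normalized_mean, row.names = NULL))
  invisible(x)
}

#' @export
plot.count_series <- function(x, ...) {
  graphics::plot(x$times_s, x$normalized_mean, type = "b", pch = 19,
                 xlab = "excitation time (s)", ylab = "normalized count",
                 ylim = c(0, max(1.05, x$normalized_mean)), ...)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}

#' Compare 2D (single focal plane) and 3D (z-stack) counts
#'
#' For each cell: a 2D count at the stated focal plane and a 3D count via
#' [detect_stack_3d()].  Returns the paired counts with the Pearson
#' correlation and the least-squares slope of 3D on 2D counts.
#'
#' @param stacks List of z-axis [image_stack()]s (one per cell).
#' @param focal_plane_index 0-based slice used for the 2D count.
#' @param masks Optional list of cell masks.
#' @param psf A [psf_model()].
#' @param config A [detection_config()].
#' @return An object of class `comparison_2d3d`: per-cell table, `slope`,
#'   `intercept`, `correlation` (`NA` with `degenerate = TRUE` when a group
#'   has zero variance).
#' @export
compare_2d_3d <- function(stacks, focal_plane_index = 0L, masks = NULL,
                          psf = psf_model(1.2), config = detection_config()) {
  if (length(stacks) < 2L) stop("need >= 2 cells for a correlation", call. = FALSE)
  c2d <- integer(length(stacks)); c3d <- integer(length(stacks))
  for (ci in seq_along(stacks)) {
    fr <- stacks[[ci]]$frames[[focal_plane_index + 1L]]
    det2 <- detect_spots(fr, psf, config)
    c2d[ci] <- if (is.null(masks)) nrow(det2$spots)
               else count_per_cell(det2, masks[[ci]])
    d3 <- detect_stack_3d(stacks[[ci]], psf, config)
    c3d[ci] <- if (is.null(masks) || d3$count == 0L) d3$count
               else sum(spots_in_mask(d3$spots3d$x_px, d3$spots3d$y_px,
                                      masks[[ci]]))
  }
  degenerate <- stats::var(c2d) == 0 || stats::var(c3d) == 0
  if (degenerate) {
    slope <- if (stats::var(c2d) > 0) 0 else NA_real_
    r <- NA_real_
    intercept <- NA_real_
  } else {
    fit <- stats::lm(c3d ~ c2d)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
    r <- stats::cor(c2d, c3d)
  }
  structure(list(table = data.frame(cell = seq_along(stacks),
                                    count_2d = c2d, count_3d = c3d),
                 slope = slope, intercept = intercept, correlation = r,
                 degenerate = degenerate),
            class = "comparison_2d3d")
}

#' @export
print.comparison_2d3d <- function(x, ...) {
  cat(sprintf("2D vs 3D counts over %d cells: slope %.3g, r = %.3f%s\n",
              nrow(x$table), x$slope, x$correlation,
              if (x$degenerate) " [degenerate: zero variance]" else ""))
  invisible(x)
}

#' Two-condition count comparison (knockdown quantification)
#'
#' Quantifies a treatment-induced change in per-cell transcript counts as the
#' percent change of the treated mean relative to the control mean, with a
#' percentile bootstrap confidence interval over cells and a Welch two-sample
#' t-test.
#'
#' @param counts_control,counts_treated Per-cell counts (n >= 2 each).
#' @param n_boot Bootstrap resamples (default 10000).
#' @param seed Optional integer seed for the bootstrap.
#' @param conf_level Confidence level of the percentile interval.
#' @return An object of class `condition_comparison` with `percent_change`
#'   (`100 * (1 - mean_treated / mean_control)`), `ci`, `t_statistic`,
#'   `p_value` and the group summaries.
#' @export
knockdown_fraction <- function(counts_control, counts_treated, n_boot = 10000L,
                               seed = NULL, conf_level = 0.95) {
  if (length(counts_control) < 2L || length(counts_treated) < 2L) {
    stop("both groups need at least two cells", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  pc <- function(ctrl, trt) 100 * (1 - mean(trt) / mean(ctrl))
  est <- pc(counts_control, counts_treated)
  boot <- replicate(n_boot, {
    pc(sample(counts_control, replace = TRUE),
       sample(counts_treated, replace = TRUE))
  })
  alpha <- (1 - conf_level) / 2
  ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha)))
  tt <- if (stats::var(counts_control) == 0 && stats::var(counts_treated) == 0) {
    list(statistic = c(t = if (est == 0) 0 else Inf),
         p.value = if (est == 0) 1 else 0)
  } else {
    stats::t.test(counts_control, counts_treated)
  }
  structure(list(percent_change = est, ci = ci, conf_level = conf_level,
                 t_statistic = unname(tt$statistic), p_value = tt$p.value,
                 mean_control = mean(counts_control),
                 mean_treated = mean(counts_treated),
                 n_control = length(counts_control),
                 n_treated = length(counts_treated),
                 n_boot = n_boot),
            class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf(paste0("Condition comparison: %.1f%% change ",
                     "(%d%% CI %.1f to %.1f), control mean %.1f (n=%d), ",
                     "treated mean %.1f (n=%d), Welch p = %.3g\n"),
              x$percent_change, round(100 * x$conf_level), x$ci[1], x$ci[2],
              x$mean_control, x$n_control, x$mean_treated, x$n_treated,
              x$p_value))
  invisible(x)
}
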