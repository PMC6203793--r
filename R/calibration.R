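# Single-fluorophore calibration from stepwise-photobleaching traces, and
# conversion of FISH spot intensities into fluorophores per transcript
# (labeling density).

#' Extract an intensity time-trace for one spot
#'
#' For each frame of a continuous-excitation video, the spot amplitude is
#' obtained by a linear (amplitude, background) least-squares fit of the PSF
#' at the fixed spot position over the analysis window; the returned values
#' are therefore background-subtracted integrated intensities.
#'
#' @param stack A time-axis [image_stack()].
#' @param spot One-row spot record (or list) with `x_px`, `y_px`.
#' @param psf A [psf_model()].
#' @return An object of class `intensity_trace` with `values` (one per
#'   frame), `times_s`, and the source position.
#' @export
extract_trace <- function(stack, spot, psf) {
  if (!inherits(stack, "image_stack") || stack$axis != "time") {
    stop("`stack` must be an image_stack with axis = \"time\"", call. = FALSE)
  }
  half <- psf$window_half
  cx <- as.integer(round(spot$x_px)); cy <- as.integer(round(spot$y_px))
  g <- as.numeric(psf_kernel(psf, spot$x_px - cx, spot$y_px - cy))
  gc <- g - mean(g)
  sgc2 <- sum(gc^2)
  gbar <- mean(g)
  vals <- vapply(stack$frames, function(fr) {
    fr <- as_pixel_matrix(fr)
    y <- as.numeric(fr[(cy - half):(cy + half) + 1L, (cx - half):(cx + half) + 1L])
    sum(gc * y) / sgc2
  }, 0)
  structure(list(values = vals,
                 times_s = stack$times_s %||% seq_along(vals) - 1,
                 x_px = spot$x_px, y_px = spot$y_px),
            class = "intensity_trace")
}

#' @export
print.intensity_trace <- function(x, ...) {
  cat(sprintf("intensity_trace: %d frames, mean %.3g at (%.2f, %.2f)\n",
              length(x$values), mean(x$values), x$x_px, x$y_px))
  invisible(x)
}

# Binary-segmentation changepoint detection on the mean.  A segment is split
# at the point minimising the two-part residual sum of squares; the split is
# kept when the information-criterion gain n*log(RSS/RSS_split) exceeds the
# penalty.  Splitting recurses into both parts.
binseg_changepoints <- function(x, penalty, min_seg = 2L) {
  n <- length(x)
  cps <- integer(0)
  segs <- list(c(1L, n))
  rss_of <- function(v) sum((v - mean(v))^2)
  while (length(segs)) {
    seg <- segs[[1L]]; segs <- segs[-1L]
    lo <- seg[1]; hi <- seg[2]
    len <- hi - lo + 1L
    if (len < 2L * min_seg) next
    v <- x[lo:hi]
    # candidate split after position k (within-segment index)
    ks <- min_seg:(len - min_seg)
    csum <- cumsum(v); csum2 <- cumsum(v^2)
    tot <- csum[len]; tot2 <- csum2[len]
    rss_l <- csum2[ks] - csum[ks]^2 / ks
    rss_r <- (tot2 - csum2[ks]) - (tot - csum[ks])^2 / (len - ks)
    rss_split <- rss_l + rss_r
    k <- ks[which.min(rss_split)]
    rss0 <- tot2 - tot^2 / len
    eps <- 1e-12 * max(abs(v))^2 + 1e-300
    gain <- len * log((rss0 + eps) / (min(rss_split) + eps))
    if (gain > penalty) {
      cps <- c(cps, lo + k - 1L)
      segs <- c(segs, list(c(lo, lo + k - 1L)), list(c(lo + k, hi)))
    }
  }
  sort(cps)
}

#' Detect intensity steps in a photobleaching trace
#'
#' Changepoint detection on the trace mean by binary segmentation with a
#' BIC-style penalty (default `3 * log(n)` on the `n log(RSS0/RSS1)` gain).
#' Single fluorophores bleach in one discrete downward step; only downward
#' steps are returned.
#'
#' @param trace An [extract_trace()] result or numeric vector (length >= 10).
#' @param penalty Penalty on the split gain; larger is more conservative.
#' @return Data frame with `frame` (0-based index of the first post-step
#'   frame) and `size` (post- minus pre-step mean, < 0), ordered by frame.
#'   A constant trace yields zero rows.
#' @export
detect_steps <- function(trace, penalty = NULL) {
  x <- if (inherits(trace, "intensity_trace")) trace$values else as.numeric(trace)
  n <- length(x)
  if (n < 10L) stop("trace must have at least 10 frames", call. = FALSE)
  if (!all(is.finite(x))) stop("trace values must be finite", call. = FALSE)
  penalty <- penalty %||% (3 * log(n))
  cps <- binseg_changepoints(x, penalty)
  if (!length(cps)) {
    return(data.frame(frame = integer(0), size = numeric(0)))
  }
  bounds <- c(0L, cps, n)
  means <- vapply(seq_len(length(bounds) - 1L),
                  function(i) mean(x[(bounds[i] + 1L):bounds[i + 1L]]), 0)
  steps <- data.frame(frame = cps,  # 0-based first frame of the new segment
                      size = diff(means))
  steps[steps$size < 0, , drop = FALSE]
}

#' Single-fluorophore intensity distribution from bleaching traces
#'
#' Classifies traces as single molecules -- exactly one downward step, a
#' post-step level indistinguishable from background, and a pre-step plateau
#' CV below `cv_max` -- and collects the pre-step plateau mean of each kept
#' trace as one single-fluorophore intensity sample.
#'
#' @param traces List of [extract_trace()] results or numeric vectors.
#' @param cv_max Maximum pre-step plateau coefficient of variation.
#' @param background_tol_sd Post-step mean must be within this many noise
#'   standard deviations (estimated from the post-step residuals) of zero.
#' @param penalty Step-detection penalty, passed to [detect_steps()].
#' @return An object of class `calibration_result`: the sample vector, its
#'   mean and CV, the number of molecules kept, and which traces were kept.
#' @export
single_fluorophore_distribution <- function(traces, cv_max = 0.5,
                                            background_tol_sd = 2,
                                            penalty = NULL) {
  if (!length(traces)) stop("need at least one trace", call. = FALSE)
  samples <- numeric(0)
  kept <- logical(length(traces))
  for (i in seq_along(traces)) {
    x <- traces[[i]]
    if (inherits(x, "intensity_trace")) x <- x$values
    steps <- detect_steps(x, penalty = penalty)
    if (nrow(steps) != 1L) next
    k <- steps$frame[1]
    pre <- x[seq_len(k)]
    post <- x[(k + 1L):length(x)]
    # post-step level must sit at background (within tol * noise sd)
    noise_sd <- max(stats::sd(post), 1e-12)
    if (abs(mean(post)) > background_tol_sd * noise_sd) next
    plateau <- mean(pre)
    if (plateau <= 0) next
    if (stats::sd(pre) / plateau > cv_max && length(pre) > 1L) next
    samples <- c(samples, plateau)
    kept[i] <- TRUE
  }
  if (!length(samples)) {
    stop(paste0("no trace classified as a single molecule; review the step ",
                "penalty and CV cutoff"), call. = FALSE)
  }
  structure(list(single_intensity_samples = samples,
                 mean_single_intensity = mean(samples),
                 cv = if (length(samples) > 1L)
                        stats::sd(samples) / mean(samples) else 0,
                 n_molecules = length(samples),
                 kept = kept,
                 method = "one-step photobleaching plateau"),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(paste0("Single-fluorophore calibration: mean intensity %.4g ",
                     "(cv %.3f) from %d molecules\n"),
              x$mean_single_intensity, x$cv, x$n_molecules))
  invisible(x)
}

#' Estimate labeling density (fluorophores per transcript)
#'
#' Divides each FISH spot's integrated intensity (the fitted amplitude, which
#' equals total collected photons under the unit-mass PSF convention) by the
#' calibrated mean single-fluorophore intensity.
#'
#' @param spot_amplitudes Numeric vector of spot amplitudes (one per spot), or
#'   a `fish_spots` object.
#' @param calib A [single_fluorophore_distribution()] result.
#' @return An object of class `labeling_density`: `per_spot_n` and `mean_n`.
#' @export
estimate_labeling_density <- function(spot_amplitudes, calib) {
  if (inherits(spot_amplitudes, "fish_spots")) {
    spot_amplitudes <- spot_amplitudes$spots$amplitude
  }
  if (!length(spot_amplitudes)) {
    stop("no spots supplied; labeling density undefined", call. = FALSE)
  }
  if (calib$mean_single_intensity <= 0) {
    stop("calibration mean single intensity must be > 0", call. = FALSE)
  }
  per_n <- spot_amplitudes / calib$mean_single_intensity
  structure(list(per_spot_n = per_n, mean_n = mean(per_n),
                 n_spots = length(per_n)),
            class = "labeling_density")
}

#' @export
print.labeling_density <- function(x, ...) {
  cat(sprintf("Labeling density: mean %.3g fluorophores/spot over %d spots\n",
              x$mean_n, x$n_spots))
  invisible(x)
}

#' @export
plot.labeling_density <- function(x, breaks = 30, ...) {
  graphics::hist(x$per_spot_n, breaks = breaks,
                 main = "Fluorophores per spot", xlab = "estimated n", ...)
  invisible(x)
}
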