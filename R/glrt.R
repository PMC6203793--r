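# Generalized likelihood ratio test (GLRT) for diffraction-limited spots.
#
# In each square analysis window the two hypotheses are
#   H0: y = b + e           (background only)
#   H1: y = a g + b + e     (one PSF-shaped spot plus background)
# with e iid Gaussian of unknown variance and g the unit-mass centre-sampled
# Gaussian kernel.  Both hypotheses are fitted by least squares (closed form)
# and the statistic is T = N log(SS0 / SS1) with N the number of window pixels.
# The test is one-sided: a fitted negative amplitude (a dark dip) gives T = 0.

#' GLRT statistic for one analysis window
#'
#' @param window Square numeric matrix (or vector) of pixel values whose size
#'   matches the PSF analysis window.
#' @param psf A [psf_model()].
#' @return The statistic T >= 0.  A constant window returns 0 (no spot
#'   evidence); a window fitted exactly by the spot model returns `Inf`.
#' @details T is invariant under affine rescaling `a * window + b` (a > 0) of
#'   the pixel values, which is what makes the dB threshold calibration
#'   transferable across illumination and camera-gain settings.
#' @export
glrt_statistic <- function(window, psf) {
  y <- as.numeric(window)
  n <- length(y)
  expect <- window_width(psf)^2
  if (n != expect) {
    stop(sprintf("window has %d pixels; PSF analysis window needs %d", n, expect),
         call. = FALSE)
  }
  g <- as.numeric(psf_kernel(psf))
  gc <- g - mean(g)
  sgc2 <- sum(gc^2)
  ybar <- mean(y)
  ss0 <- sum((y - ybar)^2)
  if (ss0 <= 0) return(0)
  a <- sum(gc * y) / sgc2
  if (a <= 0) return(0)
  ss1 <- ss0 - a^2 * sgc2
  if (ss1 <= 0) return(Inf)
  n * log(ss0 / ss1)
}

# 1D "valid" correlation of matrix M with kernel k along rows (dim 1) or
# columns (dim 2), by shift-and-add.  Used to evaluate the GLRT over every
# interior window of a frame with a separable kernel in O(width) passes.
corr1d <- function(m, k, dim) {
  wl <- length(k)
  if (dim == 1L) {
    h <- nrow(m)
    out <- matrix(0, h - wl + 1L, ncol(m))
    for (u in seq_len(wl)) {
      out <- out + k[u] * m[u:(h - wl + u), , drop = FALSE]
    }
  } else {
    w <- ncol(m)
    out <- matrix(0, nrow(m), w - wl + 1L)
    for (u in seq_len(wl)) {
      out <- out + k[u] * m[, u:(w - wl + u), drop = FALSE]
    }
  }
  out
}

corr_sep <- function(m, ky, kx) corr1d(corr1d(m, ky, 1L), kx, 2L)

#' GLRT score map of a frame
#'
#' Evaluates the window statistic at every fully interior window centre
#' (stride 1).  Because background is refitted in every window, detection
#' responds to local background, not global intensity.
#'
#' @param frame Numeric image matrix.
#' @param psf A [psf_model()].
#' @return A matrix the size of `frame` with the statistic at interior centres
#'   and `NA` in the border of width `window_half`.
#' @export
glrt_map <- function(frame, psf) {
  frame <- as_pixel_matrix(frame)
  h <- nrow(frame); w <- ncol(frame)
  half <- psf$window_half
  wl <- 2L * half + 1L
  n <- wl^2
  if (h < wl || w < wl) stop("frame smaller than the analysis window", call. = FALSE)

  # centre the data once: T is affine invariant and this avoids catastrophic
  # cancellation in SS0 = S2 - S1^2/n at large camera offsets
  fr <- frame - mean(frame)

  u <- seq.int(-half, half)
  gx <- gauss_profile_1d(u, 0, psf$sigma_px) / gauss_norm_1d(0, psf$sigma_px)
  g2 <- outer(gx, gx)
  gbar <- mean(g2)
  sgc2 <- sum((g2 - gbar)^2)
  ones <- rep(1, wl)

  s1 <- corr_sep(fr, ones, ones)
  s2 <- corr_sep(fr * fr, ones, ones)
  sg <- corr_sep(fr, gx, gx)
  sgc <- sg - gbar * s1

  ss0 <- s2 - s1 * s1 / n
  a <- sgc / sgc2
  apos <- pmax(a, 0)
  ss1 <- ss0 - apos * apos * sgc2

  tmap <- matrix(0, nrow(ss0), ncol(ss0))
  ok <- ss0 > 0
  pos <- ok & ss1 > 0
  tmap[pos] <- n * log(ss0[pos] / ss1[pos])
  tmap[ok & ss1 <= 0] <- Inf

  out <- matrix(NA_real_, h, w)
  out[(half + 1L):(h - half), (half + 1L):(w - half)] <- tmap
  out
}

#' Convert a dB detection threshold to a per-window false-alarm probability
#'
#' The detection threshold is expressed as the probability of false positives
#' per image on a decibel scale: `P_img = 10^(-threshold_db / 10)` (so 30 dB is
#' one false positive per thousand images).  The per-image probability is
#' spread over the fully interior sliding windows by Bonferroni division.
#'
#' @param threshold_db Positive threshold in decibels.
#' @param image_size Image size in pixels, one number or `c(rows, cols)`.
#' @param window_half Analysis window half-width (default 3, i.e. 7x7; a
#'   512x512 frame then holds 506^2 = 256,036 interior windows).
#' @return Per-window false-alarm probability.
#' @export
threshold_db_to_per_window_p <- function(threshold_db, image_size = c(512L, 512L),
                                         window_half = 3L) {
  if (!is.numeric(threshold_db) || any(threshold_db <= 0)) {
    stop("`threshold_db` must be positive", call. = FALSE)
  }
  if (length(image_size) == 1L) image_size <- rep(image_size, 2L)
  if (any(image_size <= 2L * window_half)) {
    stop("analysis window larger than the image", call. = FALSE)
  }
  nwin <- (image_size[1] - 2L * window_half) * (image_size[2] - 2L * window_half)
  10^(-threshold_db / 10) / nwin
}

# Draw m samples of the null GLRT statistic.  Under H0 the statistic depends
# on the noise only through two components of its orthogonal decomposition:
# with c the coefficient along the centred kernel direction (standard normal)
# and Q the residual sum of squares on the (N-2)-dimensional complement
# (chi-square, N - 2 df),  T = N log1p(c^2 / Q) when c > 0 and 0 otherwise.
# Sampling (c, Q) is distributionally identical to simulating full noise
# windows and evaluating glrt_statistic(), at a fraction of the cost; windows
# with c < 0 contribute exact zeros and are only counted, not drawn.
sample_null_glrt <- function(m, n_pixels = 49L) {
  npos <- stats::rbinom(1L, m, 0.5)
  z <- stats::rnorm(npos)
  q <- stats::rchisq(npos, df = n_pixels - 2L)
  c(n_pixels * log1p(z * z / q), numeric(m - npos))
}

# Exact null tail of the one-sided statistic (used for score reporting):
# P(T >= t) = 0.5 * P(F_{1, N-2} >= (exp(t/N) - 1) (N - 2)).
null_tail_prob <- function(t, n_pixels = 49L) {
  ifelse(t <= 0, 1,
         0.5 * stats::pf((exp(t / n_pixels) - 1) * (n_pixels - 2L),
                         1, n_pixels - 2L, lower.tail = FALSE))
}

#' Calibrate the GLRT cutoff for a per-window false-alarm probability
#'
#' Maps a per-window false-alarm probability `p` to a cutoff on the window
#' statistic.  `asymptotic` uses the chi-square(1) large-sample null of the
#' likelihood-ratio statistic (one extra linear parameter under H1).
#' `monte_carlo` uses the empirical (1 - p) quantile of the statistic over
#' `n_mc` simulated pure-noise windows, which captures the finite-sample
#' (49-pixel) tail that the asymptotic approximation misses at small `p`.
#'
#' @param psf A [psf_model()].
#' @param p Per-window false-alarm probability in (0, 1), usually from
#'   [threshold_db_to_per_window_p()].
#' @param mode `"asymptotic"` or `"monte_carlo"`.
#' @param n_mc Number of simulated noise windows; must be at least `100 / p`
#'   so that about 100 samples land beyond the estimated quantile.  Default
#'   `ceiling(100 / p)`.
#' @param seed Optional integer seed for the Monte-Carlo draw.
#' @return The statistic cutoff (monotone decreasing in `p`).
#' @export
calibrate_statistic_threshold <- function(psf, p,
                                          mode = c("asymptotic", "monte_carlo"),
                                          n_mc = NULL, seed = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1) {
    stop("`p` must be a single probability in (0, 1)", call. = FALSE)
  }
  if (mode == "asymptotic") {
    return(stats::qchisq(1 - p, df = 1))
  }
  n <- window_width(psf)^2
  if (is.null(n_mc)) n_mc <- ceiling(100 / p)
  n_mc <- as.numeric(n_mc)
  if (n_mc < 100 / p) {
    stop(sprintf(paste0("monte_carlo calibration at p = %.3g needs n_mc >= %.3g ",
                        "noise windows (got %.3g)"), p, 100 / p, n_mc),
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  k <- max(1, round(n_mc * p))  # cutoff = k-th largest => exceedance ~ p
  top <- numeric(0)
  batch <- 5e6
  remaining <- n_mc
  while (remaining > 0) {
    m <- min(batch, remaining)
    vals <- sample_null_glrt(m, n)
    thr <- if (length(top) >= k) top[k] else -Inf
    keep <- vals[vals > thr]
    top <- sort(c(top, keep), decreasing = TRUE)
    if (length(top) > k) top <- top[seq_len(k)]
    remaining <- remaining - m
  }
  top[k]
}
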