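# Shared test helpers: fixtures are built in code, never stored.

# Greedy one-to-one matching of ground-truth spots to detections, brightest
# truth first, within `radius` pixels.  Returns recall and precision.
match_truth <- function(truth, spots, radius = 2) {
  if (nrow(spots) == 0L) return(c(recall = 0, precision = NA_real_))
  matched <- rep(FALSE, nrow(truth))
  used <- rep(FALSE, nrow(spots))
  for (i in order(-truth$amplitude_photons)) {
    d2 <- (spots$x_px - truth$x_px[i])^2 + (spots$y_px - truth$y_px[i])^2
    d2[used] <- Inf
    j <- which.min(d2)
    if (length(j) && d2[j] <= radius^2) {
      matched[i] <- TRUE
      used[j] <- TRUE
    }
  }
  c(recall = mean(matched), precision = mean(used))
}

# Background noise s.d. (detector units) of a camera + autofluorescence
# configuration, at the mean autofluorescence level.
background_noise_sd <- function(config) {
  sqrt(config$autofluorescence$mean * config$camera$gain^2 +
         config$camera$read_noise_sd^2)
}

# Amplitude giving a stated peak signal-to-noise ratio for a spot at a pixel
# centre: peak pixel value = amplitude * g_peak.
amplitude_for_peak_snr <- function(snr, psf, noise_sd) {
  snr * noise_sd / max(psf_kernel(psf))
}

# A flat-background frame with rendered spots plus iid Gaussian noise -- the
# exact noise model assumed by the detection statistic.
render_noisy_frame <- function(psf, x, y, amplitude, size = 64L, bg = 100,
                               noise_sd = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  img <- matrix(bg, size, size)
  img <- qdfish:::add_spots(img, psf, x, y, amplitude)
  img + matrix(rnorm(size * size, 0, noise_sd), size, size)
}

# Independent GLRT oracle: brute-force likelihood maximization of both
# hypotheses by iterative grid refinement over the parameters (background b
# under H0; amplitude a >= 0 and background b under H1), never using the
# closed-form projections.
glrt_oracle <- function(window, psf, levels = 9L, grid_n = 41L) {
  y <- as.numeric(window)
  n <- length(y)
  g <- as.numeric(psf_kernel(psf))
  rng <- diff(range(y))
  if (rng == 0) return(0)

  ss_h0 <- function(b) vapply(b, function(bi) sum((y - bi)^2), 0)
  lo <- min(y); hi <- max(y)
  for (l in seq_len(levels)) {
    bs <- seq(lo, hi, length.out = grid_n)
    ss <- ss_h0(bs)
    i <- which.min(ss)
    step <- bs[2] - bs[1]
    lo <- bs[i] - 2 * step; hi <- bs[i] + 2 * step
  }
  ss0 <- min(ss)

  ss_h1 <- function(a, b) sum((y - a * g - b)^2)
  alo <- 0; ahi <- 4 * rng / max(g)
  blo <- min(y) - rng; bhi <- max(y) + rng
  for (l in seq_len(levels)) {
    as <- seq(alo, ahi, length.out = grid_n)
    bs <- seq(blo, bhi, length.out = grid_n)
    ss <- outer(as, bs, Vectorize(ss_h1))
    ij <- arrayInd(which.min(ss), dim(ss))
    astep <- as[2] - as[1]; bstep <- bs[2] - bs[1]
    alo <- max(0, as[ij[1]] - 2 * astep); ahi <- as[ij[1]] + 2 * astep
    blo <- bs[ij[2]] - 2 * bstep; bhi <- bs[ij[2]] + 2 * bstep
  }
  ss1 <- min(ss)
  if (ss1 <= 0) return(Inf)
  if (ss1 >= ss0) return(0)
  n * log(ss0 / ss1)
}
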