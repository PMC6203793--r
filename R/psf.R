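# Gaussian point-spread-function model and spot rendering.
#
# Coordinate convention used throughout the package: positions are 0-based,
# the centre of pixel (i, j) is at integer coordinate (x = j, y = i) with x
# running along image columns and y along rows.  All sub-pixel positions from
# simulation and fitting live in this frame.

#' Gaussian PSF model
#'
#' The microscope point spread function is modelled as a symmetric 2D Gaussian
#' sampled at pixel centres, normalised so that the full (untruncated) discrete
#' kernel sums to one.  With this convention a fitted spot amplitude equals the
#' total signal (photons) collected from the emitter, so amplitudes are
#' directly comparable to summed single-fluorophore intensities.
#'
#' @param sigma_px Gaussian standard deviation in pixels (from the emission
#'   wavelength and numerical aperture, or measured on sub-diffraction beads).
#' @param window_half Half-width of the square analysis window; the default 3
#'   gives the 7x7 window used for detection and fitting.
#' @return An object of class `psf_model`.
#' @examples
#' psf <- psf_model(1.2)
#' sum(psf_kernel(psf))  # close to, but below, 1 (7x7 truncation)
#' @export
psf_model <- function(sigma_px, window_half = 3L) {
  if (!is.numeric(sigma_px) || length(sigma_px) != 1L || !is.finite(sigma_px) ||
      sigma_px <= 0) {
    stop("`sigma_px` must be a single positive number", call. = FALSE)
  }
  window_half <- as.integer(window_half)
  if (length(window_half) != 1L || is.na(window_half) || window_half < 1L) {
    stop("`window_half` must be a positive integer", call. = FALSE)
  }
  structure(list(sigma_px = as.numeric(sigma_px), window_half = window_half),
            class = "psf_model")
}

#' @export
print.psf_model <- function(x, ...) {
  w <- 2L * x$window_half + 1L
  cat(sprintf("Gaussian PSF: sigma = %.4g px, %dx%d analysis window\n",
              x$sigma_px, w, w))
  invisible(x)
}

window_width <- function(psf) 2L * psf$window_half + 1L

# Lattice normalisation constant of the 1D sampled Gaussian: sum over all
# integers i of exp(-(i - x)^2 / (2 sigma^2)).  Depends on frac(x) only; the
# summation range is wide enough that the truncated tail is < 1e-15 relative.
gauss_norm_1d <- function(x, sigma) {
  k <- ceiling(10 * sigma) + 2L
  i <- seq.int(floor(x) - k, ceiling(x) + k)
  sum(exp(-((i - x)^2) / (2 * sigma^2)))
}

# Unnormalised 1D profile at integer offsets `idx` for a spot at coordinate x.
gauss_profile_1d <- function(idx, x, sigma) {
  exp(-((idx - x)^2) / (2 * sigma^2))
}

#' Discrete PSF kernel
#'
#' Kernel weights of a unit-amplitude spot over a square pixel window, for a
#' spot displaced by (`dx`, `dy`) from the window's central pixel.  Rows index
#' y (image rows), columns index x.
#'
#' @param psf A [psf_model()].
#' @param dx,dy Sub-pixel displacement of the spot from the window centre.
#' @param half Window half-width (defaults to the PSF analysis window).
#' @return A (2*half+1) square matrix; its sum is the fraction of the full
#'   kernel mass falling inside the window (< 1).
#' @export
psf_kernel <- function(psf, dx = 0, dy = 0, half = psf$window_half) {
  u <- seq.int(-half, half)
  wx <- gauss_profile_1d(u, dx, psf$sigma_px) / gauss_norm_1d(dx, psf$sigma_px)
  wy <- gauss_profile_1d(u, dy, psf$sigma_px) / gauss_norm_1d(dy, psf$sigma_px)
  outer(wy, wx)
}

#' Render one spot as an additive pixel patch
#'
#' Samples the normalised Gaussian PSF at pixel centres.  The returned patch is
#' the additive contribution of the spot to the image over the patch support;
#' because the kernel is normalised over the full lattice, the patch sum is at
#' most `amplitude` (truncation to the patch).
#'
#' @param psf A [psf_model()].
#' @param x,y Spot centre in 0-based pixel coordinates.
#' @param amplitude Total spot signal in photons (>= 0).
#' @param size Patch edge length in pixels; default the PSF analysis window.
#' @param origin Integer (x0, y0) of the patch's first pixel; default centres
#'   the patch on the pixel nearest the spot.
#' @return A `size` x `size` matrix with attribute `origin`.
#' @export
render_spot <- function(psf, x, y, amplitude, size = window_width(psf),
                        origin = NULL) {
  if (!is.numeric(amplitude) || length(amplitude) != 1L || amplitude < 0) {
    stop("`amplitude` must be a single non-negative number", call. = FALSE)
  }
  size <- as.integer(size)
  if (is.null(origin)) {
    origin <- c(round(x), round(y)) - (size - 1L) %/% 2L
  }
  sx <- psf$sigma_px
  ix <- origin[1] + seq_len(size) - 1L
  iy <- origin[2] + seq_len(size) - 1L
  wx <- gauss_profile_1d(ix, x, sx) / gauss_norm_1d(x, sx)
  wy <- gauss_profile_1d(iy, y, sx) / gauss_norm_1d(y, sx)
  patch <- amplitude * outer(wy, wx)
  attr(patch, "origin") <- as.integer(origin)
  patch
}

# Adds spots to an image matrix in place (functionally).  Each spot is rendered
# over a +/- ceil(8 sigma) support so the omitted tail mass is < 1e-14 of the
# amplitude, which keeps the photon-conservation identity exact to numerical
# precision.
add_spots <- function(img, psf, x, y, amplitude) {
  h <- nrow(img); w <- ncol(img)
  r <- ceiling(8 * psf$sigma_px)
  for (s in seq_along(x)) {
    if (amplitude[s] == 0) next
    cx <- round(x[s]); cy <- round(y[s])
    x0 <- max(0L, cx - r); x1 <- min(w - 1L, cx + r)
    y0 <- max(0L, cy - r); y1 <- min(h - 1L, cy + r)
    if (x0 > x1 || y0 > y1) next
    patch <- sign(amplitude[s]) *
      render_spot(psf, x[s], y[s], abs(amplitude[s]),
                  size = max(x1 - x0, y1 - y0) + 1L,
                  origin = c(x0, y0))
    rows <- (y0 + 1L):(y1 + 1L)
    cols <- (x0 + 1L):(x1 + 1L)
    img[rows, cols] <- img[rows, cols] +
      patch[seq_along(rows), seq_along(cols)]
  }
  img
}

# Kernel of a spot displaced by (dx, dy) from the centre of a square window,
# returned as a numeric vector in column-major window order.
gauss_shifted_window <- function(psf, dx, dy, half) {
  as.numeric(psf_kernel(psf, dx, dy, half = half))
}

# Fraction of a spot's full kernel mass falling inside an H x W image
# (separable product of 1D partial sums).
kernel_mass_in_image <- function(psf, x, y, h, w) {
  sx <- psf$sigma_px
  mx <- sum(gauss_profile_1d(0:(w - 1L), x, sx)) / gauss_norm_1d(x, sx)
  my <- sum(gauss_profile_1d(0:(h - 1L), y, sx)) / gauss_norm_1d(y, sx)
  mx * my
}
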