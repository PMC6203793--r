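# Fluorophore photophysics models, emission spectra and bandpass filters.

#' Fluorophore photophysics model
#'
#' Captures the contrast between organic dyes (dimmer, exponentially
#' photobleaching) and quantum dots (brighter, photostable, blinking) that
#' drives the simulated experiments.
#'
#' @param mean_intensity Mean photons emitted per fluorophore per frame (> 0).
#' @param intensity_cv Coefficient of variation of the per-fluorophore
#'   intensity (>= 0); intensities are drawn from a Gamma distribution with
#'   this mean and CV.
#' @param bleach_rate Photobleaching rate in 1/s; 0 for a photostable emitter.
#'   Each fluorophore's emitting lifetime under excitation is exponential with
#'   this rate.
#' @param blink_on_fraction Fraction of time a fluorophore is in its emitting
#'   state, in (0, 1]; 1 means no blinking.  Blinking is modelled as
#'   independent per-frame thinning.
#' @param emission_spectrum Optional two-column data frame
#'   (`wavelength_nm`, `intensity`) with non-negative intensities.
#' @return An object of class `fluorophore_model`.
#' @export
fluorophore_model <- function(mean_intensity, intensity_cv = 0.2,
                              bleach_rate = 0, blink_on_fraction = 1,
                              emission_spectrum = NULL) {
  if (!is.numeric(mean_intensity) || mean_intensity <= 0) {
    stop("`mean_intensity` must be > 0", call. = FALSE)
  }
  if (!is.numeric(intensity_cv) || intensity_cv < 0) {
    stop("`intensity_cv` must be >= 0", call. = FALSE)
  }
  if (!is.numeric(bleach_rate) || bleach_rate < 0) {
    stop("`bleach_rate` must be >= 0", call. = FALSE)
  }
  if (!is.numeric(blink_on_fraction) || blink_on_fraction <= 0 ||
      blink_on_fraction > 1) {
    stop("`blink_on_fraction` must be in (0, 1]", call. = FALSE)
  }
  if (!is.null(emission_spectrum)) {
    emission_spectrum <- validate_spectrum(emission_spectrum)
  }
  structure(list(mean_intensity = mean_intensity,
                 intensity_cv = intensity_cv,
                 bleach_rate = bleach_rate,
                 blink_on_fraction = blink_on_fraction,
                 emission_spectrum = emission_spectrum),
            class = "fluorophore_model")
}

#' @export
print.fluorophore_model <- function(x, ...) {
  cat(sprintf(paste0("Fluorophore: %.4g photons/frame (cv %.2f), bleach rate ",
                     "%.4g /s, on-fraction %.2f\n"),
              x$mean_intensity, x$intensity_cv, x$bleach_rate,
              x$blink_on_fraction))
  invisible(x)
}

validate_spectrum <- function(spec) {
  spec <- as.data.frame(spec)
  if (ncol(spec) < 2L) stop("spectrum needs wavelength and intensity columns",
                            call. = FALSE)
  names(spec)[1:2] <- c("wavelength_nm", "intensity")
  if (is.unsorted(spec$wavelength_nm, strictly = TRUE)) {
    spec <- spec[order(spec$wavelength_nm), ]
  }
  if (any(spec$intensity < 0)) stop("spectrum intensities must be >= 0",
                                    call. = FALSE)
  spec
}

# Gaussian emission line on a 1-nm grid; convenient synthetic stand-in for
# measured spectra.
gaussian_spectrum <- function(center_nm, sd_nm, range_nm = c(400, 950)) {
  wl <- seq(range_nm[1], range_nm[2], by = 1)
  data.frame(wavelength_nm = wl,
             intensity = exp(-((wl - center_nm)^2) / (2 * sd_nm^2)))
}

#' Per-fluorophore draw of frame intensities
#' @noRd
draw_fluor_intensity <- function(n, fluor) {
  if (n == 0L) return(numeric(0))
  cv <- fluor$intensity_cv
  if (cv == 0) return(rep(fluor$mean_intensity, n))
  shape <- 1 / cv^2
  stats::rgamma(n, shape = shape, scale = fluor$mean_intensity / shape)
}

#' Bandpass emission filter
#'
#' Specified the way filters are catalogued, centre/full-width: a 600/37
#' filter transmits 581.5-618.5 nm.
#'
#' @param center_nm Band centre in nm.
#' @param full_width_nm Full transmission width in nm (> 0).
#' @return An object of class `bandpass_filter` with the band limits.
#' @export
bandpass_filter <- function(center_nm, full_width_nm) {
  if (!is.numeric(full_width_nm) || full_width_nm <= 0) {
    stop("`full_width_nm` must be > 0", call. = FALSE)
  }
  structure(list(center_nm = center_nm, full_width_nm = full_width_nm,
                 band = c(center_nm - full_width_nm / 2,
                          center_nm + full_width_nm / 2)),
            class = "bandpass_filter")
}

#' @export
print.bandpass_filter <- function(x, ...) {
  cat(sprintf("Bandpass filter %g/%g nm (%.1f-%.1f nm)\n", x$center_nm,
              x$full_width_nm, x$band[1], x$band[2]))
  invisible(x)
}

#' Fraction of an emission spectrum transmitted by a bandpass filter
#'
#' Integrates the tabulated spectrum (trapezoidal rule, with interpolated
#' band-edge points) over the filter band and divides by the integral over all
#' tabulated wavelengths.  Used to split each simulated spot's photons across
#' imaging channels.
#'
#' @param spectrum Two-column spectrum (`wavelength_nm`, `intensity`).
#' @param filter A [bandpass_filter()].
#' @return The transmitted fraction, in `[0, 1]`.
#' @export
crosstalk_coefficient <- function(spectrum, filter) {
  spec <- validate_spectrum(spectrum)
  wl <- spec$wavelength_nm
  iv <- spec$intensity
  total <- trapz(wl, iv)
  if (total <= 0) stop("spectrum integrates to zero; transmitted fraction undefined",
                       call. = FALSE)
  lo <- max(filter$band[1], wl[1])
  hi <- min(filter$band[2], wl[length(wl)])
  if (lo >= hi) return(0)
  keep <- wl > lo & wl < hi
  bw <- c(lo, wl[keep], hi)
  bi <- c(stats::approx(wl, iv, lo)$y, iv[keep], stats::approx(wl, iv, hi)$y)
  min(max(trapz(bw, bi) / total, 0), 1)
}

trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' Synthetic quantum-dot emission spectra for the three multiplexing channels
#'
#' Gaussian emission lines centred at 608, 693, and 800 nm with widths typical
#' of alloyed HgCdSe/CdZnS quantum dots, matched to the 600/37, 698/70 and
#' 809/81 nm bandpass filters returned by [multiplex_filters()].
#'
#' @return Named list of three spectra (data frames).
#' @export
qd_emission_spectra <- function() {
  list(QD608 = gaussian_spectrum(608, 13),
       QD693 = gaussian_spectrum(693, 16),
       QD800 = gaussian_spectrum(800, 18))
}

#' Bandpass filter set for three-colour quantum-dot multiplexing
#' @return Named list of three [bandpass_filter()] objects.
#' @export
multiplex_filters <- function() {
  list(QD608 = bandpass_filter(600, 37),
       QD693 = bandpass_filter(698, 70),
       QD800 = bandpass_filter(809, 81))
}

#' Fluorophore presets
#'
#' Ships the photophysics regimes contrasted by the simulated experiments:
#' `"dye"` -- an organic dye, ~60 photons/frame per fluorophore, exponential
#' photobleaching (rate 0.006/s, i.e. a ~2.8 min mean emitting lifetime, so
#' spot counts decay over seconds-to-minutes of excitation); `"qd13"` -- a
#' compact quantum dot, ~300 photons/frame, photostable, blinking with 0.8
#' on-fraction; `"qd17"` -- a large quantum dot with the same photophysics as
#' `"qd13"` (its difference is steric: fewer probes bind, captured by the
#' labeling-density preset in [sim_preset()]).
#'
#' @param name One of `"dye"`, `"qd13"`, `"qd17"`.
#' @return A [fluorophore_model()].
#' @export
fluorophore_preset <- function(name = c("dye", "qd13", "qd17")) {
  name <- match.arg(name)
  switch(name,
    dye  = fluorophore_model(60, intensity_cv = 0.25, bleach_rate = 0.006,
                             blink_on_fraction = 1,
                             emission_spectrum = gaussian_spectrum(610, 20)),
    qd13 = fluorophore_model(300, intensity_cv = 0.15, bleach_rate = 0,
                             blink_on_fraction = 0.8,
                             emission_spectrum = gaussian_spectrum(608, 13)),
    qd17 = fluorophore_model(300, intensity_cv = 0.15, bleach_rate = 0,
                             blink_on_fraction = 0.8,
                             emission_spectrum = gaussian_spectrum(608, 13)))
}
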