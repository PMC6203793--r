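# Synthetic smFISH microscope-image generator.
#
# Emulates the statistical structure of single-molecule FISH data: a cell
# (elliptical mask) containing diffraction-limited spots, each a transcript
# carrying a random number of fluorophores; spatially correlated cellular
# autofluorescence; and EMCCD camera noise (Poisson shot noise, gain, Gaussian
# read noise, offset, quantization).  Every generator is deterministic given
# its seed, with per-cell/frame/channel sub-streams derived from one master
# seed.

#' Single image frame with physical metadata
#'
#' @param pixels Numeric matrix of non-negative detector units.
#' @param pixel_size_nm Pixel size in nm (default 160, a 16 um camera pixel
#'   behind a 100x objective).
#' @param time_s Acquisition time in seconds.
#' @param z_index 0-based slice index within a z-stack.
#' @param channel_id Channel label.
#' @param bit_depth 8 or 16.
#' @return An `image_frame`: the pixel matrix carrying metadata attributes.
#' @export
image_frame <- function(pixels, pixel_size_nm = 160, time_s = 0, z_index = 0L,
                        channel_id = "ch0", bit_depth = 16L) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix", call. = FALSE)
  if (any(pixels < 0)) stop("pixel values must be >= 0", call. = FALSE)
  if (!bit_depth %in% c(8L, 16L)) stop("`bit_depth` must be 8 or 16", call. = FALSE)
  structure(pixels,
            pixel_size_nm = pixel_size_nm, time_s = time_s,
            z_index = as.integer(z_index), channel_id = channel_id,
            bit_depth = as.integer(bit_depth),
            class = c("image_frame", class(pixels)))
}

#' @export
print.image_frame <- function(x, ...) {
  cat(sprintf("image_frame %dx%d px, %d-bit, pixel %g nm, t = %g s, z = %d\n",
              nrow(x), ncol(x), attr(x, "bit_depth"), attr(x, "pixel_size_nm"),
              attr(x, "time_s"), attr(x, "z_index")))
  invisible(x)
}

#' Ordered stack of frames along z or time
#'
#' @param frames List of [image_frame()]s (or matrices) of identical shape.
#' @param axis `"z"` or `"time"`.
#' @param z_step_um Slice spacing in um for z-stacks (default 0.22).
#' @param times_s Frame acquisition times in seconds for time stacks.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, axis = c("z", "time"), z_step_um = 0.22,
                        times_s = NULL) {
  axis <- match.arg(axis)
  dims <- unique(lapply(frames, dim))
  if (length(dims) != 1L) stop("all frames must share one shape", call. = FALSE)
  if (axis == "z" && z_step_um <= 0) stop("`z_step_um` must be > 0", call. = FALSE)
  structure(list(frames = frames, axis = axis,
                 z_step_um = if (axis == "z") z_step_um else NA_real_,
                 times_s = if (axis == "time") times_s else NULL),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("image_stack: %d frames of %dx%d px along %s\n",
              length(x$frames), d[1], d[2], x$axis))
  invisible(x)
}

#' @export
length.image_stack <- function(x) length(x$frames)

#' Simulation configuration for one cell
#'
#' @param image_size Image size in pixels, one number or `c(rows, cols)`.
#' @param pixel_size_nm Pixel size in nm.
#' @param n_spots List `(mean, dispersion)`: spots (transcripts) per cell.
#'   `dispersion = NULL` draws Poisson counts, `0` uses exactly `round(mean)`,
#'   otherwise negative-binomial with that size parameter.
#' @param labeling_density List `(mean)`: fluorophores per transcript, drawn
#'   from a zero-truncated Poisson parameterised by its (truncated) mean
#'   (> 1).  Every rendered spot carries at least one fluorophore.
#' @param cell_mask List `(center, semi_axes)` of an ellipse in pixel
#'   coordinates; spots are placed uniformly inside it.
#' @param autofluorescence List `(mean, amplitude, corr_length)`: expected
#'   autofluorescence photons per pixel inside the cell, the standard
#'   deviation of its spatial variation, and the correlation length in pixels
#'   of the Gaussian random field modelling the nonuniformity.
#' @param camera List `(offset, read_noise_sd, gain, bit_depth)` of EMCCD
#'   parameters in detector units.
#' @param seed Master integer seed.
#' @return An object of class `cell_sim_config`.
#' @export
cell_sim_config <- function(image_size = c(512L, 512L),
                            pixel_size_nm = 160,
                            n_spots = list(mean = 400, dispersion = NULL),
                            labeling_density = list(mean = 8),
                            cell_mask = list(center = c(255.5, 255.5),
                                             semi_axes = c(200, 170)),
                            autofluorescence = list(mean = 200, amplitude = 60,
                                                    corr_length = 40),
                            camera = list(offset = 100, read_noise_sd = 3,
                                          gain = 1, bit_depth = 16L),
                            seed = 1L) {
  if (length(image_size) == 1L) image_size <- rep(image_size, 2L)
  image_size <- as.integer(image_size)
  if (any(image_size < 7L)) stop("image smaller than the analysis window",
                                 call. = FALSE)
  if (autofluorescence$corr_length <= 0) {
    stop("autofluorescence correlation length must be > 0", call. = FALSE)
  }
  if (!camera$bit_depth %in% c(8L, 16L)) {
    stop("camera bit_depth must be 8 or 16", call. = FALSE)
  }
  cm <- cell_mask
  if (cm$center[1] + cm$semi_axes[1] > image_size[2] - 1 ||
      cm$center[1] - cm$semi_axes[1] < 0 ||
      cm$center[2] + cm$semi_axes[2] > image_size[1] - 1 ||
      cm$center[2] - cm$semi_axes[2] < 0) {
    stop("cell mask extends beyond the image", call. = FALSE)
  }
  if (labeling_density$mean <= 1) {
    stop("zero-truncated labeling density needs mean > 1", call. = FALSE)
  }
  structure(list(image_size = image_size, pixel_size_nm = pixel_size_nm,
                 n_spots = n_spots, labeling_density = labeling_density,
                 cell_mask = cell_mask, autofluorescence = autofluorescence,
                 camera = camera, seed = as.integer(seed)),
            class = "cell_sim_config")
}

#' Simulation presets for the three probe regimes
#'
#' Study conditions for a high-expression transcript (GAPDH-like) imaged on a
#' 512x512 EMCCD frame: `"dye"` -- 425 spots per cell, mean 8.0 fluorophores
#' per transcript, bleaching dye photophysics; `"qd13"` -- 487 spots, mean 10
#' compact quantum dots per transcript, photostable; `"qd17"` -- 75 spots,
#' mean 2.3 large quantum dots per transcript (sterically limited binding and
#' access), photostable.
#'
#' @param name One of `"dye"`, `"qd13"`, `"qd17"`.
#' @param seed Master seed stored in the config.
#' @param scale Linear size scale; `scale = 0.5` gives a 256x256 image with
#'   the cell and spot count scaled to preserve spot density (for quick
#'   analyses at reduced size).
#' @return List with elements `config` ([cell_sim_config()]) and `fluor`
#'   ([fluorophore_preset()]).
#' @export
sim_preset <- function(name = c("dye", "qd13", "qd17"), seed = 1L, scale = 1) {
  name <- match.arg(name)
  n0 <- switch(name, dye = 425, qd13 = 487, qd17 = 75)
  dens <- switch(name, dye = 8.0, qd13 = 10, qd17 = 2.3)
  sz <- as.integer(round(512 * scale))
  config <- cell_sim_config(
    image_size = c(sz, sz),
    n_spots = list(mean = n0 * scale^2, dispersion = NULL),
    labeling_density = list(mean = dens),
    cell_mask = list(center = c((sz - 1) / 2, (sz - 1) / 2),
                     semi_axes = c(200, 170) * scale),
    seed = seed)
  list(config = config, fluor = fluorophore_preset(name))
}

# --- distribution helpers -------------------------------------------------

draw_count <- function(spec) {
  disp <- spec$dispersion %||% NULL
  if (is.null(disp)) return(stats::rpois(1L, spec$mean))
  if (disp == 0) return(as.integer(round(spec$mean)))
  stats::rnbinom(1L, size = disp, mu = spec$mean)
}

# Rate of the zero-truncated Poisson whose truncated mean is m (> 1).
ztpois_lambda <- function(m) {
  stats::uniroot(function(l) l / (1 - exp(-l)) - m,
                 lower = 1e-8, upper = m, tol = 1e-12)$root
}

# Inverse-CDF draw (fixed RNG consumption, so sub-streams stay aligned).
rztpois <- function(n, mean) {
  lambda <- ztpois_lambda(mean)
  u <- stats::runif(n, stats::dpois(0, lambda), 1)
  pmax(stats::qpois(u, lambda), 1L)
}

# Uniform positions inside an ellipse.
runif_ellipse <- function(n, center, semi_axes) {
  r <- sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  cbind(x = center[1] + semi_axes[1] * r * cos(th),
        y = center[2] + semi_axes[2] * r * sin(th))
}

# Gaussian random field with unit variance and the given correlation length,
# generated by low-pass filtering white noise in Fourier space (periodic
# boundaries; the wrap-around is immaterial at correlation lengths well below
# the image size).
gaussian_random_field <- function(h, w, corr_length) {
  white <- matrix(stats::rnorm(h * w), h, w)
  fy <- c(0:(h %/% 2), -((h - h %/% 2 - 1):1)) / h
  fx <- c(0:(w %/% 2), -((w - w %/% 2 - 1):1)) / w
  # FT of a Gaussian kernel with spatial sd = corr_length
  ky <- exp(-2 * pi^2 * corr_length^2 * fy^2)
  kx <- exp(-2 * pi^2 * corr_length^2 * fx^2)
  filt <- outer(ky, kx)
  field <- Re(stats::fft(stats::fft(white) * filt, inverse = TRUE)) / (h * w)
  field / sqrt(mean(filt^2))  # Parseval: restores unit pixel variance
}

# Unit-DC-gain Gaussian blur (periodic boundaries).
gaussian_blur <- function(m, sigma) {
  h <- nrow(m); w <- ncol(m)
  fy <- c(0:(h %/% 2), -((h - h %/% 2 - 1):1)) / h
  fx <- c(0:(w %/% 2), -((w - w %/% 2 - 1):1)) / w
  filt <- outer(exp(-2 * pi^2 * sigma^2 * fy^2),
                exp(-2 * pi^2 * sigma^2 * fx^2))
  Re(stats::fft(stats::fft(m) * filt, inverse = TRUE)) / (h * w)
}

# Expected-photon autofluorescence surface, restricted to the cell mask.  The
# mask edge is tapered (`edge_softness`, px, Gaussian sigma): autofluorescence
# scales with cell body thickness, which falls off over roughly a micron near
# the adhesion edge (~6 px at 160 nm pixels), further blurred by the optics.
# An expected-photon step at the boundary would be unphysical.
autofluorescence_field <- function(config, mask) {
  af <- config$autofluorescence
  g <- gaussian_random_field(config$image_size[1], config$image_size[2],
                             af$corr_length)
  soft <- gaussian_blur(mask + 0, af$edge_softness %||% 6)
  pmax(af$mean + af$amplitude * g, 0) * pmin(pmax(soft, 0), 1)
}

#' Apply EMCCD camera noise to an expected-photon image
#'
#' Per pixel: Poisson shot noise on the expected photons, multiplied by the
#' camera gain, plus Gaussian read noise and a fixed offset, then rounded and
#' clipped to the bit depth.  The electron-multiplying register's excess noise
#' is absorbed into the Gaussian read-noise term, consistent with the Gaussian
#' noise model assumed by the detection statistic.
#'
#' @param clean Matrix of expected photons (>= 0).
#' @param camera List `(offset, read_noise_sd, gain, bit_depth)`.
#' @param seed Optional integer seed.
#' @return An [image_frame()] of quantized detector units.
#' @export
apply_camera_noise <- function(clean, camera, seed = NULL) {
  clean <- as_pixel_matrix(clean)
  if (any(clean < 0)) stop("expected photons must be >= 0", call. = FALSE)
  if (camera$gain < 0 || camera$read_noise_sd < 0) {
    stop("camera gain and read noise must be >= 0", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  h <- nrow(clean); w <- ncol(clean)
  counts <- matrix(stats::rpois(h * w, clean), h, w) * camera$gain +
    camera$offset
  if (camera$read_noise_sd > 0) {
    counts <- counts + matrix(stats::rnorm(h * w, 0, camera$read_noise_sd), h, w)
  }
  maxv <- 2^camera$bit_depth - 1
  image_frame(pmin(pmax(round(counts), 0), maxv), bit_depth = camera$bit_depth)
}

# Draw the spot population of one cell: positions, fluorophore loads, realised
# per-frame amplitudes (blinking-thinned sum of per-fluorophore intensities).
draw_spot_truth <- function(config, fluor, target_id, channel_id) {
  n <- draw_count(config$n_spots)
  if (n == 0L) {
    return(data.frame(spot_id = integer(0), x_px = numeric(0),
                      y_px = numeric(0), z_um = numeric(0),
                      n_fluorophores = integer(0), n_emitting = integer(0),
                      amplitude_photons = numeric(0),
                      target_id = character(0), channel_id = character(0),
                      stringsAsFactors = FALSE))
  }
  pos <- runif_ellipse(n, config$cell_mask$center, config$cell_mask$semi_axes)
  nf <- rztpois(n, config$labeling_density$mean)
  nem <- stats::rbinom(n, nf, fluor$blink_on_fraction)
  amp <- vapply(nem, function(k) sum(draw_fluor_intensity(k, fluor)), 0)
  data.frame(spot_id = seq_len(n) - 1L, x_px = pos[, "x"], y_px = pos[, "y"],
             z_um = 0, n_fluorophores = as.integer(nf),
             n_emitting = as.integer(nem), amplitude_photons = amp,
             target_id = target_id, channel_id = channel_id,
             stringsAsFactors = FALSE)
}

#' Generate one synthetic cell image with ground truth
#'
#' Draws the spot count, places transcripts uniformly inside the cell mask,
#' draws fluorophores per transcript from the zero-truncated labeling-density
#' distribution, sums per-fluorophore intensity draws into spot amplitudes,
#' renders the spots through the PSF on top of a spatially correlated
#' autofluorescence field, and applies camera noise.
#'
#' @param config A [cell_sim_config()].
#' @param fluor A [fluorophore_model()].
#' @param psf A [psf_model()] used for rendering (the simulator and detector
#'   share the pixel-centre-sampled Gaussian convention).
#' @param target_id,channel_id Labels stored in the truth table.
#' @return List with `frame` (noisy [image_frame()]), `clean` (expected-photon
#'   matrix before camera noise), `truth` (exact spot table), and `mask`
#'   (logical cell mask).
#' @export
generate_cell_field <- function(config, fluor, psf = psf_model(1.2),
                                target_id = "target", channel_id = "ch0") {
  set.seed(substream_seed(config$seed, 1L))
  truth <- draw_spot_truth(config, fluor, target_id, channel_id)
  mask <- ellipse_mask(config$image_size, config$cell_mask$center,
                       config$cell_mask$semi_axes)
  af <- autofluorescence_field(config, mask)
  clean <- add_spots(af, psf, truth$x_px, truth$y_px, truth$amplitude_photons)
  frame <- apply_camera_noise(clean, config$camera,
                              seed = substream_seed(config$seed, 2L))
  attr(frame, "pixel_size_nm") <- config$pixel_size_nm
  attr(frame, "channel_id") <- channel_id
  list(frame = frame, clean = clean, truth = truth, mask = mask)
}

#' Simulate a photobleaching time-lapse of a fixed spot field
#'
#' Each fluorophore draws an exposure-ordered emitting lifetime (exponential
#' with the model's bleach rate; infinite when photostable), so its survival
#' is monotone non-increasing across frames.  Surviving fluorophores are
#' further thinned per frame by the blinking on-fraction.  Frames are rendered
#' and camera-noised independently over a fixed autofluorescence field.
#'
#' @param truth Spot table from [generate_cell_field()] (positions and
#'   `n_fluorophores` are used).
#' @param fluor A [fluorophore_model()].
#' @param times Increasing vector of excitation times in seconds, starting at
#'   or after 0.
#' @param config A [cell_sim_config()].
#' @param psf A [psf_model()].
#' @param seed Integer seed (defaults to the config's).
#' @return List with `stack` (time-axis [image_stack()]) and `truth` (long
#'   table: one row per spot per frame with `n_alive`, `n_emitting`,
#'   `amplitude_photons`).
#' @export
simulate_timelapse <- function(truth, fluor, times, config, psf = psf_model(1.2),
                               seed = NULL) {
  if (is.unsorted(times, strictly = TRUE) || times[1] < 0) {
    stop("`times` must be strictly increasing and start at >= 0", call. = FALSE)
  }
  seed <- seed %||% config$seed
  set.seed(substream_seed(seed, 3L))
  nspots <- nrow(truth)
  nf <- truth$n_fluorophores
  # per-fluorophore brightness fixed over time; lifetime drawn once
  intens <- lapply(nf, function(k) draw_fluor_intensity(k, fluor))
  lifetimes <- lapply(nf, function(k) {
    if (fluor$bleach_rate == 0) rep(Inf, k) else stats::rexp(k, fluor$bleach_rate)
  })
  mask <- ellipse_mask(config$image_size, config$cell_mask$center,
                       config$cell_mask$semi_axes)
  af <- autofluorescence_field(config, mask)

  frames <- vector("list", length(times))
  rows <- vector("list", length(times))
  for (fi in seq_along(times)) {
    t <- times[fi]
    set.seed(substream_seed(seed, 4L, fi))
    amp <- numeric(nspots); nalive <- integer(nspots); nem <- integer(nspots)
    for (s in seq_len(nspots)) {
      alive <- lifetimes[[s]] > t
      on <- alive & (stats::runif(nf[s]) < fluor$blink_on_fraction)
      nalive[s] <- sum(alive); nem[s] <- sum(on)
      amp[s] <- sum(intens[[s]][on])
    }
    clean <- add_spots(af, psf, truth$x_px, truth$y_px, amp)
    fr <- apply_camera_noise(clean, config$camera,
                             seed = substream_seed(seed, 5L, fi))
    attr(fr, "time_s") <- t
    frames[[fi]] <- fr
    rows[[fi]] <- data.frame(time_s = t, spot_id = truth$spot_id,
                             n_alive = nalive, n_emitting = nem,
                             amplitude_photons = amp)
  }
  list(stack = image_stack(frames, axis = "time", times_s = times),
       truth = do.call(rbind, rows))
}

#' Simulate a z-stack of a 3D spot field
#'
#' Spots receive a z position (um) spanning the stack; each slice sees the
#' spot attenuated by a Gaussian axial profile, so a spot appears in a few
#' consecutive slices around its focal plane.
#'
#' @param config A [cell_sim_config()].
#' @param fluor A [fluorophore_model()].
#' @param psf A [psf_model()].
#' @param n_slices Number of z slices.
#' @param z_step_um Slice spacing in um (default 0.22).
#' @param axial_sigma_um Axial Gaussian sigma in um (default 0.35).
#' @return List with `stack` (z-axis [image_stack()]), `truth` (spot table
#'   with `z_um`), and `mask`.
#' @export
generate_zstack_field <- function(config, fluor, psf = psf_model(1.2),
                                  n_slices = 9L, z_step_um = 0.22,
                                  axial_sigma_um = 0.35) {
  set.seed(substream_seed(config$seed, 6L))
  truth <- draw_spot_truth(config, fluor, "target", "ch0")
  zmax <- (n_slices - 1) * z_step_um
  truth$z_um <- stats::runif(nrow(truth), 0.15 * zmax, 0.85 * zmax)
  mask <- ellipse_mask(config$image_size, config$cell_mask$center,
                       config$cell_mask$semi_axes)
  af <- autofluorescence_field(config, mask)
  frames <- vector("list", n_slices)
  for (k in seq_len(n_slices)) {
    zk <- (k - 1L) * z_step_um
    amp <- truth$amplitude_photons *
      exp(-((zk - truth$z_um)^2) / (2 * axial_sigma_um^2))
    clean <- add_spots(af, psf, truth$x_px, truth$y_px, amp)
    fr <- apply_camera_noise(clean, config$camera,
                             seed = substream_seed(config$seed, 7L, k))
    attr(fr, "z_index") <- k - 1L
    frames[[k]] <- fr
  }
  list(stack = image_stack(frames, axis = "z", z_step_um = z_step_um),
       truth = truth, mask = mask)
}

#' Simulate a multichannel (spectrally multiplexed) field
#'
#' Each target's spots emit with their fluorophore's spectrum; every imaging
#' channel (bandpass filter) receives the spot's photons scaled by the
#' transmitted fraction from [crosstalk_coefficient()].  Channels are rendered
#' and noised independently.
#'
#' @param config A [cell_sim_config()] (its `n_spots` is used per target
#'   unless `n_spots_per_target` is given).
#' @param fluors Named list of [fluorophore_model()]s with emission spectra,
#'   one per target.
#' @param filters Named list of [bandpass_filter()]s, one per channel.
#' @param psf A [psf_model()].
#' @param n_spots_per_target Optional named numeric vector of mean counts.
#' @return List with `frames` (named list of noisy [image_frame()]s, one per
#'   channel), `truth` (spot table with `target_id`), and `mask`.
#' @export
generate_multichannel_field <- function(config, fluors, filters,
                                        psf = psf_model(1.2),
                                        n_spots_per_target = NULL) {
  set.seed(substream_seed(config$seed, 8L))
  truths <- vector("list", length(fluors))
  for (i in seq_along(fluors)) {
    cfg <- config
    if (!is.null(n_spots_per_target)) {
      cfg$n_spots$mean <- n_spots_per_target[[names(fluors)[i]]]
    }
    truths[[i]] <- draw_spot_truth(cfg, fluors[[i]], names(fluors)[i], "mixed")
  }
  truth <- do.call(rbind, truths)
  truth$spot_id <- seq_len(nrow(truth)) - 1L
  mask <- ellipse_mask(config$image_size, config$cell_mask$center,
                       config$cell_mask$semi_axes)
  xtalk <- sapply(names(filters), function(ch) {
    sapply(names(fluors), function(tg) {
      crosstalk_coefficient(fluors[[tg]]$emission_spectrum, filters[[ch]])
    })
  })  # targets x channels
  frames <- vector("list", length(filters))
  names(frames) <- names(filters)
  for (ci in seq_along(filters)) {
    af <- autofluorescence_field(config, mask)
    amp <- truth$amplitude_photons * xtalk[truth$target_id, ci]
    clean <- add_spots(af, psf, truth$x_px, truth$y_px, amp)
    fr <- apply_camera_noise(clean, config$camera,
                             seed = substream_seed(config$seed, 9L, ci))
    attr(fr, "channel_id") <- names(filters)[ci]
    frames[[ci]] <- fr
  }
  list(frames = frames, truth = truth, mask = mask)
}
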