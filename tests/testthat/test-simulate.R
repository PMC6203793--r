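psf <- psf_model(1.2)

small_config <- function(seed = 1L, n_mean = 40, dens = 8, ...) {
  cell_sim_config(image_size = c(96L, 96L),
                  n_spots = list(mean = n_mean, dispersion = NULL),
                  labeling_density = list(mean = dens),
                  cell_mask = list(center = c(47.5, 47.5),
                                   semi_axes = c(38, 32)),
                  seed = seed, ...)
}

test_that("identical config and seed give bit-identical fields", {
  cfg <- small_config(seed = 9)
  fl <- fluorophore_preset("qd13")
  s1 <- generate_cell_field(cfg, fl, psf)
  s2 <- generate_cell_field(cfg, fl, psf)
  expect_identical(unclass(s1$frame), unclass(s2$frame))
  expect_identical(s1$truth, s2$truth)
  s3 <- generate_cell_field(small_config(seed = 10), fl, psf)
  expect_false(identical(unclass(s1$frame), unclass(s3$frame)))
})

test_that("a degenerate zero-spot distribution yields an empty truth list", {
  cfg <- small_config()
  cfg$n_spots <- list(mean = 0, dispersion = 0)
  sim <- generate_cell_field(cfg, fluorophore_preset("qd13"), psf)
  expect_equal(nrow(sim$truth), 0L)
  expect_true(all(unclass(sim$frame) >= 0))
})

test_that("spot truths sit inside the mask with at least one fluorophore", {
  sim <- generate_cell_field(small_config(seed = 3), fluorophore_preset("dye"),
                             psf)
  expect_true(all(sim$truth$n_fluorophores >= 1))
  inside <- qdfish:::spots_in_mask(sim$truth$x_px, sim$truth$y_px, sim$mask)
  expect_true(all(inside))
})

test_that("zero-truncated labeling density reproduces its configured mean", {
  set.seed(77)
  draws <- qdfish:::rztpois(4000, 8)
  expect_true(all(draws >= 1))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 8), 3 * se)
  # pooled over generated cells, as a field-level property
  cfg <- small_config(seed = 5, n_mean = 120)
  nf <- unlist(lapply(1:6, function(i) {
    cfg$seed <- 100L + i
    generate_cell_field(cfg, fluorophore_preset("dye"), psf)$truth$n_fluorophores
  }))
  expect_gt(length(nf), 500)
  expect_lt(abs(mean(nf) - 8), 3 * sd(nf) / sqrt(length(nf)))
})

test_that("camera noise has Poisson-gain moments", {
  cam <- list(offset = 10, read_noise_sd = 0, gain = 2, bit_depth = 16L)
  fr <- apply_camera_noise(matrix(7, 320, 320), cam, seed = 4)
  n <- length(fr)
  se <- sqrt(2^2 * 7) / sqrt(n)
  expect_lt(abs(mean(fr) - (2 * 7 + 10)), 4 * se)

  # offset + read noise only: variance close to read_noise_sd^2
  cam0 <- list(offset = 50, read_noise_sd = 3, gain = 1, bit_depth = 16L)
  fr0 <- apply_camera_noise(matrix(0, 320, 320), cam0, seed = 5)
  expect_lt(abs(var(as.numeric(fr0)) - 9), 0.35)  # + 1/12 quantization

  # zero everything -> zero frame
  camz <- list(offset = 0, read_noise_sd = 0, gain = 1, bit_depth = 8L)
  expect_true(all(apply_camera_noise(matrix(0, 10, 10), camz, seed = 1) == 0))
  expect_error(apply_camera_noise(matrix(1, 4, 4),
                                  list(offset = 0, read_noise_sd = -1,
                                       gain = 1, bit_depth = 8L)),
               ">= 0")
})

test_that("quantization respects the bit depth", {
  cam <- list(offset = 200, read_noise_sd = 0, gain = 1, bit_depth = 8L)
  fr <- apply_camera_noise(matrix(500, 12, 12), cam, seed = 2)
  expect_true(all(fr <= 255))
  expect_true(all(fr == round(fr)))
})

test_that("photostable timelapse amplitudes are constant, bleaching ones decay", {
  cfg <- small_config(seed = 21, n_mean = 30)
  stable <- fluorophore_model(300, intensity_cv = 0, bleach_rate = 0,
                              blink_on_fraction = 1)
  sim <- generate_cell_field(cfg, stable, psf)
  tl <- simulate_timelapse(sim$truth, stable, c(0, 10, 30), cfg, psf, seed = 8)
  amps <- split(tl$truth$amplitude_photons, tl$truth$spot_id)
  expect_true(all(vapply(amps, function(a) max(a) - min(a), 0) == 0))

  # per-fluorophore survival is monotone: n_alive never increases
  bleach <- fluorophore_model(300, bleach_rate = 0.02)
  tlb <- simulate_timelapse(sim$truth, bleach, c(0, 20, 50, 120), cfg, psf,
                            seed = 9)
  alive <- split(tlb$truth$n_alive, tlb$truth$spot_id)
  expect_true(all(vapply(alive, function(a) all(diff(a) <= 0), TRUE)))
})

test_that("pooled fluorophore survival matches the exponential law", {
  cfg <- small_config(seed = 31, n_mean = 900, dens = 12)
  bleach <- fluorophore_model(100, bleach_rate = 0.05)
  sim <- generate_cell_field(cfg, bleach, psf)
  tl <- simulate_timelapse(sim$truth, bleach, c(0, 1 / 0.05), cfg, psf,
                           seed = 12)
  tot <- tapply(tl$truth$n_alive, tl$truth$time_s, sum)
  nfl <- sum(sim$truth$n_fluorophores)
  expect_gte(nfl, 1e4)
  phat <- tot[[2]] / nfl
  se <- sqrt(exp(-1) * (1 - exp(-1)) / nfl)
  expect_lt(abs(phat - exp(-1)), 3 * se)
})

test_that("unsorted times are rejected", {
  cfg <- small_config()
  sim <- generate_cell_field(cfg, fluorophore_preset("qd13"), psf)
  expect_error(simulate_timelapse(sim$truth, fluorophore_preset("qd13"),
                                  c(0, 30, 20), cfg, psf),
               "increasing")
})

test_that("crosstalk coefficients integrate spectra over filter bands", {
  inside <- data.frame(wavelength_nm = 590:610, intensity = 1)
  expect_equal(crosstalk_coefficient(inside, bandpass_filter(600, 37)), 1)
  disjoint <- data.frame(wavelength_nm = 700:720, intensity = 1)
  expect_equal(crosstalk_coefficient(disjoint, bandpass_filter(600, 37)), 0)
  zero <- data.frame(wavelength_nm = 500:700, intensity = 0)
  expect_error(crosstalk_coefficient(zero, bandpass_filter(600, 37)),
               "zero")
  # Gaussian spectrum against the closed-form normal integral
  wl <- seq(500, 720, by = 0.2)
  spec <- data.frame(wavelength_nm = wl,
                     intensity = dnorm(wl, 608, 12))
  got <- crosstalk_coefficient(spec, bandpass_filter(600, 37))
  want <- (pnorm(618.5, 608, 12) - pnorm(581.5, 608, 12)) /
    (pnorm(720, 608, 12) - pnorm(500, 608, 12))
  expect_equal(got, want, tolerance = 1e-4)
})

test_that("crosstalk over disjoint filters sums to at most one", {
  filters <- multiplex_filters()
  for (spec in qd_emission_spectra()) {
    tot <- sum(vapply(filters, function(f) crosstalk_coefficient(spec, f), 0))
    expect_lte(tot, 1)
  }
  # each dot is captured mostly by its own filter
  x <- vapply(multiplex_filters(),
              function(f) crosstalk_coefficient(qd_emission_spectra()$QD693, f),
              0)
  expect_equal(unname(which.max(x)), 2L)
})

test_that("multichannel fields split photons by filter and stay deterministic", {
  cfg <- small_config(seed = 51, n_mean = 15)
  fluors <- list(
    GAPDH = fluorophore_model(300, emission_spectrum = gaussian_spectrum(608, 13)),
    PTEN = fluorophore_model(300, emission_spectrum = gaussian_spectrum(693, 16)))
  filters <- multiplex_filters()[1:2]
  mc1 <- generate_multichannel_field(cfg, fluors, filters, psf)
  mc2 <- generate_multichannel_field(cfg, fluors, filters, psf)
  expect_identical(lapply(mc1$frames, unclass), lapply(mc2$frames, unclass))
  expect_setequal(unique(mc1$truth$target_id), c("GAPDH", "PTEN"))
  expect_named(mc1$frames, names(filters))
})

test_that("z-stack spots span a few consecutive slices", {
  cfg <- small_config(seed = 61, n_mean = 10)
  zs <- generate_zstack_field(cfg, fluorophore_preset("qd13"), psf,
                              n_slices = 7L)
  expect_length(zs$stack$frames, 7L)
  expect_equal(zs$stack$axis, "z")
  expect_true(all(zs$truth$z_um >= 0 & zs$truth$z_um <= 6 * 0.22))
})

test_that("config invariants are enforced", {
  expect_error(cell_sim_config(image_size = 5), "window")
  expect_error(small_config(autofluorescence = list(mean = 10, amplitude = 1,
                                                    corr_length = 0)),
               "correlation")
  expect_error(small_config(camera = list(offset = 0, read_noise_sd = 1,
                                          gain = 1, bit_depth = 12L)),
               "bit_depth")
  expect_error(cell_sim_config(image_size = 64,
                               cell_mask = list(center = c(32, 32),
                                                semi_axes = c(60, 10))),
               "mask")
  expect_error(small_config(dens = 0.5), "mean > 1")
})
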