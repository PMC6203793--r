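psf <- psf_model(1.2)

constant_emitter_stack <- function(amp, n_frames = 20, bg = 30, noise_sd = 0,
                                   x = 15.3, y = 12.6, seed = 1) {
  set.seed(seed)
  frames <- lapply(seq_len(n_frames), function(i) {
    qdfish:::add_spots(matrix(bg, 32, 32), psf, x, y, amp) +
      if (noise_sd > 0) matrix(rnorm(32 * 32, 0, noise_sd), 32, 32) else 0
  })
  image_stack(frames, axis = "time", times_s = seq_len(n_frames) - 1)
}

test_that("traces recover a constant emitter's amplitude exactly", {
  st <- constant_emitter_stack(150, noise_sd = 0)
  tr <- extract_trace(st, list(x_px = 15.3, y_px = 12.6), psf)
  expect_equal(tr$values, rep(150, 20), tolerance = 1e-9)
})

test_that("an absent emitter gives a near-zero trace", {
  st <- constant_emitter_stack(0, noise_sd = 3, seed = 2)
  tr <- extract_trace(st, list(x_px = 15.3, y_px = 12.6), psf)
  expect_lt(abs(mean(tr$values)), 3 * 3 / sqrt(20) / sqrt(sum(
    (qdfish:::psf_kernel(psf) - mean(qdfish:::psf_kernel(psf)))^2)))
})

test_that("ensemble traces of bleaching emitters decay exponentially", {
  cfg <- cell_sim_config(image_size = c(96L, 96L),
                         n_spots = list(mean = 60, dispersion = 0),
                         labeling_density = list(mean = 8),
                         cell_mask = list(center = c(47.5, 47.5),
                                          semi_axes = c(38, 32)),
                         autofluorescence = list(mean = 30, amplitude = 0,
                                                 corr_length = 20),
                         camera = list(offset = 0, read_noise_sd = 1, gain = 1,
                                       bit_depth = 16L),
                         seed = 7L)
  k <- 0.05
  fl <- fluorophore_model(200, intensity_cv = 0, bleach_rate = k)
  sim <- generate_cell_field(cfg, fl, psf)
  times <- c(0, 10, 20, 40)
  tl <- simulate_timelapse(sim$truth, fl, times, cfg, psf, seed = 8)
  traces <- lapply(seq_len(nrow(sim$truth)), function(i) {
    extract_trace(tl$stack, sim$truth[i, c("x_px", "y_px")], psf)
  })
  mean_trace <- rowMeans(do.call(cbind, lapply(traces, function(t) t$values)))
  expected <- mean_trace[1] * exp(-k * times)
  expect_lt(max(abs(mean_trace - expected) / expected[1]), 0.1)
})

test_that("steps are found exactly in noiseless traces", {
  x <- c(rep(100, 50), rep(0, 50))
  st <- detect_steps(x)
  expect_equal(nrow(st), 1L)
  expect_equal(st$frame, 50L)
  expect_equal(st$size, -100)

  x2 <- c(rep(200, 30), rep(100, 30), rep(0, 30))
  st2 <- detect_steps(x2)
  expect_equal(nrow(st2), 2L)
  expect_equal(st2$frame, c(30L, 60L))
  expect_equal(st2$size, c(-100, -100))

  expect_equal(nrow(detect_steps(rep(5, 40))), 0L)
  expect_error(detect_steps(1:5), "10")
})

test_that("step detection is invariant to a constant offset", {
  set.seed(14)
  x <- c(rnorm(40, 120, 10), rnorm(60, 0, 10))
  expect_equal(detect_steps(x), detect_steps(x + 500))
})

test_that("noisy single steps are located within two frames", {
  ok <- vapply(1:200, function(i) {
    set.seed(600 + i)
    step <- 80
    x <- c(rnorm(50, step, step / 8), rnorm(50, 0, step / 8))
    st <- detect_steps(x)
    nrow(st) >= 1 && min(abs(st$frame - 50)) <= 2
  }, TRUE)
  expect_gte(mean(ok), 0.95)
})

test_that("single-molecule classification keeps one-step traces only", {
  one <- c(rep(100, 40), rep(0, 40))
  two <- c(rep(200, 25), rep(100, 25), rep(0, 30))
  calib <- single_fluorophore_distribution(list(one, one, two))
  expect_equal(calib$n_molecules, 2L)
  expect_equal(calib$mean_single_intensity, 100)
  expect_equal(calib$cv, 0)
  expect_equal(calib$kept, c(TRUE, TRUE, FALSE))

  flat <- rep(5, 40)
  expect_error(single_fluorophore_distribution(list(flat)), "single molecule")
})

test_that("simulated singles recover the plateau mean within 3 SE", {
  set.seed(33)
  mu <- 250
  traces <- lapply(1:300, function(i) {
    plateau <- rnorm(1, mu, 0.2 * mu)
    kstep <- sample(20:60, 1)
    c(rnorm(kstep, plateau, 12), rnorm(80 - kstep, 0, 12))
  })
  calib <- single_fluorophore_distribution(traces)
  expect_gt(calib$n_molecules, 200)
  se <- sd(calib$single_intensity_samples) / sqrt(calib$n_molecules)
  expect_lt(abs(calib$mean_single_intensity - mu), 3 * se)
  expect_equal(calib$cv, 0.2, tolerance = 0.05)
})

test_that("labeling density is spot intensity over single intensity", {
  calib <- single_fluorophore_distribution(list(c(rep(40, 30), rep(0, 30))))
  dens <- estimate_labeling_density(rep(200, 10), calib)
  expect_equal(dens$mean_n, 5)
  expect_equal(dens$per_spot_n, rep(5, 10))
  expect_error(estimate_labeling_density(numeric(0), calib), "no spots")
})

test_that("calibration is scale equivariant and density scale free", {
  set.seed(44)
  traces <- lapply(1:50, function(i) c(rnorm(40, 100, 5), rnorm(40, 0, 5)))
  c1 <- single_fluorophore_distribution(traces)
  c3 <- single_fluorophore_distribution(lapply(traces, function(t) 3 * t))
  expect_equal(c3$mean_single_intensity, 3 * c1$mean_single_intensity,
               tolerance = 1e-9)
  amps <- runif(100, 200, 2000)
  d1 <- estimate_labeling_density(amps, c1)
  d3 <- estimate_labeling_density(3 * amps, c3)
  expect_equal(d1$mean_n, d3$mean_n, tolerance = 1e-9)
})
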