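psf <- psf_model(1.2)

test_that("a noiseless rendered spot is recovered exactly once and exactly", {
  img <- qdfish:::add_spots(matrix(5, 64, 64), psf, 30.3, 40.7, 200)
  det <- detect_spots(img, psf, detection_config(threshold_db = 30))
  expect_equal(nrow(det$spots), 1L)
  expect_lt(abs(det$spots$x_px - 30.3), 0.02)
  expect_lt(abs(det$spots$y_px - 40.7), 0.02)
  expect_lt(abs(det$spots$amplitude - 200) / 200, 1e-6)
  expect_equal(det$spots$background, 5, tolerance = 1e-6)
})

test_that("a symmetric spot at a pixel centre fits exactly at that centre", {
  img <- qdfish:::add_spots(matrix(10, 48, 48), psf, 15, 22, 120)
  rec <- fit_spot(img, c(15, 22), psf)
  expect_equal(rec$x_px, 15, tolerance = 1e-8)
  expect_equal(rec$y_px, 22, tolerance = 1e-8)
  expect_equal(rec$amplitude, 120, tolerance = 1e-8)
  expect_true(rec$converged)
})

test_that("an all-zero or gradient-only frame yields no candidates", {
  cutoff <- calibrate_statistic_threshold(psf, threshold_db_to_per_window_p(30, 64))
  expect_equal(nrow(detect_candidates(matrix(0, 64, 64), psf, cutoff)), 0L)
  # a pure intensity plane: the symmetric kernel is orthogonal to the tilt,
  # so per-window background fitting leaves no spot evidence
  plane <- outer(seq(0, 50, length.out = 64), seq(0, 30, length.out = 64), "+")
  expect_equal(nrow(detect_candidates(plane, psf, cutoff)), 0L)
  det <- detect_spots(plane, psf, detection_config(threshold_db = 30))
  expect_equal(nrow(det$spots), 0L)
})

test_that("noisy localization error stays below 0.15 px on average", {
  errs <- vapply(1:60, function(i) {
    img <- render_noisy_frame(psf, 20 + (i %% 3) * 0.31, 20.47,
                              amplitude_for_peak_snr(10, psf, 5),
                              size = 40, bg = 50, noise_sd = 5, seed = 300 + i)
    rec <- fit_spot(img, c(20 + round((i %% 3) * 0.31), 20), psf)
    sqrt((rec$x_px - (20 + (i %% 3) * 0.31))^2 + (rec$y_px - 20.47)^2)
  }, 0)
  expect_lt(mean(errs), 0.15)
})

test_that("depletion separates close pairs", {
  hits <- vapply(1:20, function(i) {
    a <- amplitude_for_peak_snr(15, psf, 5)
    truth <- data.frame(x_px = c(20.2, 23.2), y_px = c(20.6, 20.6),
                        amplitude_photons = c(a, a))
    img <- render_noisy_frame(psf, truth$x_px, truth$y_px,
                              truth$amplitude_photons, size = 44, bg = 50,
                              noise_sd = 5, seed = 400 + i)
    det <- detect_spots(img, psf, detection_config(threshold_db = 25))
    ms <- match_truth(truth, det$spots, radius = 1)
    ms["recall"] == 1
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("re-detection on the depleted residual finds nothing new", {
  set.seed(71)
  img <- render_noisy_frame(psf, runif(25, 5, 90), runif(25, 5, 90),
                            amplitude_for_peak_snr(15, psf, 5) *
                              runif(25, 0.8, 1.4),
                            size = 96, bg = 80, noise_sd = 5, seed = 72)
  det <- detect_spots(img, psf, detection_config(threshold_db = 30))
  expect_gt(nrow(det$spots), 15)
  again <- detect_spots(residuals(det), psf, detection_config(threshold_db = 30))
  expect_equal(nrow(again$spots), 0L)
})

test_that("candidate counts never increase with the threshold", {
  set.seed(81)
  img <- render_noisy_frame(psf, runif(30, 5, 120), runif(30, 5, 120),
                            amplitude_for_peak_snr(6, psf, 5) *
                              runif(30, 0.3, 2),
                            size = 128, bg = 60, noise_sd = 5, seed = 82)
  tm <- glrt_map(img, psf)
  cutoffs <- vapply(seq(20, 36, by = 2), function(db) {
    calibrate_statistic_threshold(psf, threshold_db_to_per_window_p(db, 128))
  }, 0)
  counts <- vapply(cutoffs, function(cf) {
    nrow(detect_candidates(img, psf, cf, tmap = tm))
  }, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("detection output is deterministic and well-formed", {
  img <- render_noisy_frame(psf, c(12.3, 30.8), c(14.1, 25.5), c(800, 1200),
                            size = 48, bg = 40, noise_sd = 4, seed = 91)
  d1 <- detect_spots(img, psf, detection_config(threshold_db = 28))
  d2 <- detect_spots(img, psf, detection_config(threshold_db = 28))
  expect_identical(d1$spots, d2$spots)
  expect_true(all(d1$spots$glrt_score >= 0))
  expect_true(all(d1$spots$amplitude > 0))
  expect_s3_class(d1, "fish_spots")
  expect_output(print(d1), "fish_spots")
  expect_output(print(summary(d1)), "Spot detection")
  expect_equal(coef(d1), d1$spots)
  expect_equal(fitted(d1) + residuals(d1), d1$image, tolerance = 1e-12)
})

test_that("counting respects the cell mask", {
  spots <- data.frame(x_px = c(5, 20, 40), y_px = c(5, 20, 40))
  mask <- ellipse_mask(c(48, 48), c(20, 20), c(10, 10))
  expect_equal(count_per_cell(spots, mask), 1L)
  expect_equal(count_per_cell(spots[0, ], mask), 0L)
  allmask <- matrix(TRUE, 48, 48)
  expect_equal(count_per_cell(spots, allmask), 3L)
})

test_that("3D linking merges per-slice detections into single spots", {
  # one bright spot present in three consecutive slices at the same xy
  frames <- lapply(1:5, function(k) {
    a <- if (k %in% 2:4) 600 else 0
    render_noisy_frame(psf, 21.4, 17.8, a, size = 40, bg = 30, noise_sd = 3,
                       seed = 500 + k)
  })
  st <- image_stack(frames, axis = "z")
  res <- detect_stack_3d(st, psf, detection_config(threshold_db = 25))
  expect_equal(res$count, 1L)
  expect_equal(res$spots3d$n_slices, 3L)
  expect_lt(abs(res$spots3d$x_px - 21.4), 0.2)

  # a single-slice stack reduces to the 2D count
  st1 <- image_stack(frames[3], axis = "z")
  res1 <- detect_stack_3d(st1, psf, detection_config(threshold_db = 25))
  det2d <- detect_spots(frames[[3]], psf, detection_config(threshold_db = 25))
  expect_equal(res1$count, nrow(det2d$spots))

  cfg <- detection_config(threshold_db = 25)
  cfg$link_radius_px <- -1
  expect_error(detect_stack_3d(st, psf, cfg), "link_radius")
})

test_that("simulated 3D fields are counted within 5 percent", {
  # spot density low enough that chance xy collisions (which merge in z)
  # stay well below the tolerance
  cfg <- cell_sim_config(image_size = c(196L, 196L),
                         n_spots = list(mean = 40, dispersion = 0),
                         labeling_density = list(mean = 10),
                         cell_mask = list(center = c(97.5, 97.5),
                                          semi_axes = c(80, 70)),
                         seed = 19L)
  cfg$labeling_density <- list(mean = 12)
  # non-blinking bright emitters: this tests the slice linker, not the dim
  # tail of the labeling-density distribution
  fl <- fluorophore_model(300, intensity_cv = 0.1)
  zs <- generate_zstack_field(cfg, fl, psf, n_slices = 9L)
  res <- detect_stack_3d(zs$stack, psf, detection_config(threshold_db = 30))
  expect_lte(abs(res$count - nrow(zs$truth)) / nrow(zs$truth), 0.05)
})
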