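# Spot detection: GLRT candidates, sub-pixel PSF fitting, serial depletion.

#' Detection configuration
#'
#' @param threshold_db Detection stringency in decibels: the per-image
#'   false-positive probability is `10^(-threshold_db / 10)` (30 dB = one
#'   false positive per thousand 512x512 images).
#' @param max_depletion_rounds Maximum detect-subtract iterations.
#' @param max_spots Hard cap on accepted spots (truncation is flagged).
#' @param calibration_mode `"asymptotic"` (chi-square(1)) or `"monte_carlo"`
#'   (finite-sample empirical null); see
#'   [calibrate_statistic_threshold()].
#' @param n_mc Monte-Carlo sample size (windows) when calibrating empirically.
#' @param link_radius_px Radius for 3D slice linking; default `2 * sigma_px`.
#' @param min_amplitude Minimum fitted amplitude to accept a spot.
#' @param deblend Fit two spots jointly in a window when the single-spot fit
#'   residual still carries spot evidence at the detection cutoff (resolves
#'   pairs closer than about 3 px that a single-spot model would blend).
#' @param seed Seed used for Monte-Carlo calibration.
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(threshold_db = 30,
                             max_depletion_rounds = 10L,
                             max_spots = 100000L,
                             calibration_mode = c("asymptotic", "monte_carlo"),
                             n_mc = NULL,
                             link_radius_px = NULL,
                             min_amplitude = 0,
                             deblend = TRUE,
                             seed = 1L) {
  calibration_mode <- match.arg(calibration_mode)
  if (threshold_db <= 0) stop("`threshold_db` must be > 0", call. = FALSE)
  if (max_depletion_rounds < 1L) stop("`max_depletion_rounds` must be >= 1",
                                      call. = FALSE)
  if (!is.null(link_radius_px) && link_radius_px < 0) {
    stop("`link_radius_px` must be >= 0", call. = FALSE)
  }
  structure(list(threshold_db = threshold_db,
                 max_depletion_rounds = as.integer(max_depletion_rounds),
                 max_spots = as.integer(max_spots),
                 calibration_mode = calibration_mode,
                 n_mc = n_mc,
                 link_radius_px = link_radius_px,
                 min_amplitude = min_amplitude,
                 deblend = isTRUE(deblend),
                 seed = seed),
            class = "detection_config")
}

# Cutoff on the window statistic implied by a dB threshold for this frame size.
statistic_cutoff <- function(frame_dim, psf, config) {
  p <- threshold_db_to_per_window_p(config$threshold_db, frame_dim,
                                    psf$window_half)
  calibrate_statistic_threshold(psf, p, mode = config$calibration_mode,
                                n_mc = config$n_mc, seed = config$seed)
}

#' Detect candidate spot centres in a frame
#'
#' Evaluates the GLRT at every fully interior window centre and returns the
#' strict local maxima (8-neighbourhood) of the score map that reach the
#' cutoff, ordered by decreasing score (ties broken row-major).
#'
#' @param frame Image matrix or [image_frame()].
#' @param psf A [psf_model()].
#' @param cutoff Statistic cutoff from [calibrate_statistic_threshold()].
#' @param tmap Optional precomputed [glrt_map()] of `frame`.
#' @return Data frame with 0-based integer `x`, `y` and `score`.
#' @export
detect_candidates <- function(frame, psf, cutoff, tmap = NULL) {
  if (is.null(tmap)) tmap <- glrt_map(frame, psf)
  h <- nrow(tmap); w <- ncol(tmap)
  tm <- tmap
  tm[is.na(tm)] <- -Inf
  ctr <- tm[2:(h - 1), 2:(w - 1)]
  ismax <- ctr >= cutoff
  for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0) next
    ismax <- ismax & ctr > tm[(2 + dy):(h - 1 + dy), (2 + dx):(w - 1 + dx)]
  }
  idx <- which(ismax, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(data.frame(x = integer(0), y = integer(0), score = numeric(0)))
  }
  out <- data.frame(x = idx[, 2] + 1L - 1L,  # to 0-based full-frame coords
                    y = idx[, 1] + 1L - 1L,
                    score = ctr[idx])
  out[order(-out$score, out$y, out$x), , drop = FALSE]
}

#' Fit one spot with sub-pixel precision
#'
#' Nonlinear least squares of (x, y, amplitude, background) over the analysis
#' window centred on an integer candidate, with the PSF sigma fixed and the
#' position constrained within +/- 1 px of the candidate centre
#' (Levenberg-Marquardt).  If the optimizer fails, falls back to the integer
#' centre with a linear amplitude/background fit, flagged via
#' `converged = FALSE`.
#'
#' @param frame Image matrix or [image_frame()].
#' @param center Integer candidate centre, 0-based `c(x, y)`.
#' @param psf A [psf_model()].
#' @return One-row data frame: `x_px`, `y_px`, `amplitude`, `background`,
#'   `glrt_score`, `score_db`, `residual_var`, `converged`.
#' @export
fit_spot <- function(frame, center, psf) {
  frame <- as_pixel_matrix(frame)
  out <- fit_spot_window(frame, center, psf, cutoff = Inf)[1, , drop = FALSE]
  out$cond_score <- NULL
  rownames(out) <- NULL
  out
}

# Window fitter behind fit_spot() and detect_spots().  Fits one spot; when
# `cutoff` is finite and the single-spot fit residual itself still passes the
# GLRT at that cutoff, refits the window jointly with two spots (deblending).
# Returns a 1- or 2-row spot table.
fit_spot_window <- function(frame, center, psf, cutoff = Inf) {
  half <- psf$window_half
  wl <- 2L * half + 1L
  cx <- as.integer(round(center[1])); cy <- as.integer(round(center[2]))
  if (cx < half || cy < half || cx > ncol(frame) - 1L - half ||
      cy > nrow(frame) - 1L - half) {
    stop("candidate centre too close to the image border", call. = FALSE)
  }
  rows <- (cy - half):(cy + half) + 1L
  cols <- (cx - half):(cx + half) + 1L
  y <- as.numeric(frame[rows, cols])
  n <- length(y)

  kernel_at <- function(dx, dy) as.numeric(psf_kernel(psf, dx, dy))
  lin_fit <- function(g) {
    gc <- g - mean(g)
    a <- sum(gc * y) / sum(gc^2)
    b <- mean(y) - a * mean(g)
    c(a = a, b = b)
  }
  ctrl <- minpack.lm::nls.lm.control(maxiter = 100, ftol = 1e-14, ptol = 1e-14)

  resid1 <- function(par) y - (par[3] * kernel_at(par[1], par[2]) + par[4])
  g0 <- kernel_at(0, 0)
  ab0 <- lin_fit(g0)
  start <- c(0, 0, max(ab0["a"], 1e-6), ab0["b"])
  fit <- tryCatch(
    suppressWarnings(
      minpack.lm::nls.lm(par = start, fn = resid1,
                         lower = c(-1, -1, -Inf, -Inf),
                         upper = c(1, 1, Inf, Inf), control = ctrl)),
    error = function(e) NULL)
  if (!is.null(fit) && fit$info %in% 1:4) {
    par <- fit$par
    rss <- sum(fit$fvec^2)
    converged <- TRUE
  } else {
    par <- c(0, 0, ab0["a"], ab0["b"])
    rss <- sum(resid1(par)^2)
    converged <- FALSE
  }
  score <- glrt_statistic(matrix(y, wl), psf)
  rec <- function(p, a, b, sc, rv, conv, cond = sc) {
    data.frame(x_px = cx + p[1], y_px = cy + p[2], amplitude = a,
               background = b, glrt_score = sc,
               score_db = score_to_db(sc, dim(frame), half),
               residual_var = rv, converged = conv, cond_score = cond)
  }
  out1 <- rec(par[1:2], par[3], par[4], score, rss / max(n - 4L, 1L), converged)

  if (!is.finite(cutoff) || !converged || par[3] <= 0) return(out1)

  # Deblending.  A close pair fitted by a single spot leaves a structured
  # (two-lobe) residual.  Screen: GLRT of the in-window residual maximized
  # over integer kernel offsets (permissive; it only decides whether the
  # joint fit is attempted).  Acceptance of the split is decided below.
  yres <- y - par[3] * kernel_at(par[1], par[2])
  glrt_at_offset <- function(v, odx, ody, np) {
    s0 <- sum((v - mean(v))^2)
    if (s0 <= 0) return(0)
    g2 <- gauss_shifted_window(psf, odx, ody, half)
    gc2 <- g2 - mean(g2)
    a2 <- sum(gc2 * v) / sum(gc2^2)
    if (a2 <= 0) return(0)
    s1 <- s0 - a2^2 * sum(gc2^2)
    if (s1 <= 0) return(Inf)
    np * log(s0 / s1)
  }
  offs <- expand.grid(dx = (-half + 1L):(half - 1L),
                      dy = (-half + 1L):(half - 1L))
  screen <- mapply(function(odx, ody) {
    g2 <- kernel_at(odx, ody)
    gc2 <- g2 - mean(g2)
    a2 <- sum(gc2 * yres) / sum(gc2^2)
    if (a2 <= 0) return(0)
    s0 <- sum((yres - mean(yres))^2)
    s1 <- s0 - a2^2 * sum(gc2^2)
    if (s1 <= 0) return(Inf)
    n * log(s0 / s1)
  }, offs$dx, offs$dy)
  if (max(screen) < 2) return(out1)
  best <- which.max(screen)

  # joint two-spot fit on an enlarged patch so a partner up to ~half+2 px
  # away sits fully inside the fitted region
  half2 <- half + 2L
  half2 <- min(half2, cx, cy, ncol(frame) - 1L - cx, nrow(frame) - 1L - cy)
  wl2 <- 2L * half2 + 1L
  rows2 <- (cy - half2):(cy + half2) + 1L
  cols2 <- (cx - half2):(cx + half2) + 1L
  yb <- as.numeric(frame[rows2, cols2])
  u2 <- seq.int(-half2, half2)
  kernel_big <- function(dx, dy) {
    wx <- gauss_profile_1d(u2, dx, psf$sigma_px) /
      gauss_norm_1d(dx, psf$sigma_px)
    wy <- gauss_profile_1d(u2, dy, psf$sigma_px) /
      gauss_norm_1d(dy, psf$sigma_px)
    as.numeric(outer(wy, wx))
  }
  resid2 <- function(p) {
    yb - (p[3] * kernel_big(p[1], p[2]) + p[6] * kernel_big(p[4], p[5]) + p[7])
  }
  g2 <- kernel_at(offs$dx[best], offs$dy[best])
  gc2 <- g2 - mean(g2)
  a2_init <- max(sum(gc2 * yres) / sum(gc2^2), 1e-6)
  start2 <- c(par[1], par[2], par[3], offs$dx[best], offs$dy[best], a2_init,
              par[4])
  # maxiter exhaustion is tolerated here: the parameter vector is validated
  # below on fit quality, not on the optimizer's convergence code
  fit2 <- tryCatch(
    suppressWarnings(
      minpack.lm::nls.lm(par = start2, fn = resid2,
                         lower = c(-1, -1, -Inf, -half2, -half2, -Inf, -Inf),
                         upper = c(1, 1, Inf, half2, half2, Inf, Inf),
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300, ftol = 1e-12, ptol = 1e-12))),
    error = function(e) NULL)
  if (is.null(fit2)) return(out1)
  p2 <- fit2$par
  if (any(!is.finite(p2))) return(out1)
  rss2 <- sum(fit2$fvec^2)
  rss1_big <- sum((yb - (par[3] * kernel_big(par[1], par[2]) + par[4]))^2)
  # two Gaussians closer than ~2 sigma are indistinguishable from one; only
  # split when the components are optically resolvable
  sep <- sqrt((p2[1] - p2[4])^2 + (p2[2] - p2[5])^2)
  if (p2[3] <= 0 || p2[6] <= 0 || sep < 2 * psf$sigma_px || rss2 >= rss1_big) {
    return(out1)
  }
  # Conditional acceptance scores: each component must clear the ordinary
  # GLRT cutoff in its own analysis window after removal of the *other*
  # component's model -- the same statistical bar that depletion applies to
  # ordinary detections, evaluated within the window.
  cond_score <- function(px, py, qx, qy, qa) {
    cxi <- as.integer(round(cx + px)); cyi <- as.integer(round(cy + py))
    if (cxi < half || cyi < half || cxi > ncol(frame) - 1L - half ||
        cyi > nrow(frame) - 1L - half) {
      return(-Inf)
    }
    w <- frame[(cyi - half):(cyi + half) + 1L, (cxi - half):(cxi + half) + 1L]
    w <- as.numeric(w) -
      qa * gauss_shifted_window(psf, cx + qx - cxi, cy + qy - cyi, half)
    glrt_at_offset(w, cx + px - cxi, cy + py - cyi, n)
  }
  score2 <- cond_score(p2[4], p2[5], p2[1], p2[2], p2[3])
  if (score2 < cutoff) return(out1)
  score1c <- cond_score(p2[1], p2[2], p2[4], p2[5], p2[6])
  rv2 <- rss2 / max(wl2^2 - 7L, 1L)
  rbind(rec(p2[1:2], p2[3], p2[7], score, rv2, TRUE, cond = score1c),
        rec(p2[4:5], p2[6], p2[7], score2, rv2, TRUE, cond = score2))
}

# Report a window score on the per-image dB scale (asymptotic-null mapping).
score_to_db <- function(score, frame_dim, window_half) {
  nwin <- (frame_dim[1] - 2 * window_half) * (frame_dim[2] - 2 * window_half)
  p_img <- pmin(null_tail_prob(score, (2 * window_half + 1)^2) * nwin, 1)
  -10 * log10(pmax(p_img, 1e-300))
}

empty_spot_table <- function() {
  data.frame(x_px = numeric(0), y_px = numeric(0), z_index = integer(0),
             amplitude = numeric(0), background = numeric(0),
             glrt_score = numeric(0), score_db = numeric(0),
             depletion_round = integer(0), residual_var = numeric(0),
             converged = logical(0))
}

#' Detect all spots in one frame with serial depletion
#'
#' The core estimator.  Candidates are detected on the GLRT score map, fitted
#' brightest-first, and each fitted spot model is subtracted from a working
#' copy of the image; detection is then repeated on the depleted image until
#' no candidate passes the threshold (or the round limit is reached), which
#' recovers spots at high spatial density.  No two accepted spots lie within
#' 1 px of each other.
#'
#' @param frame Image matrix or [image_frame()].
#' @param psf A [psf_model()].
#' @param config A [detection_config()].
#' @param cutoff Optional precomputed statistic cutoff (e.g. one Monte-Carlo
#'   calibration shared across many frames of the same size); by default it
#'   is calibrated from `config$threshold_db` and the frame size.
#' @return An object of class `fish_spots`: the spot table plus the inputs,
#'   the calibrated cutoff, the depleted residual image and round count.
#'   Methods: `print`, `summary`, `plot`, `coef` (spot table), `fitted`
#'   (reconstructed spot image) and `residuals` (depleted image).
#' @examples
#' psf <- psf_model(1.2)
#' sim <- generate_cell_field(sim_preset("qd13", scale = 0.25)$config,
#'                            fluorophore_preset("qd13"), psf)
#' fit <- detect_spots(sim$frame, psf, detection_config(threshold_db = 30))
#' print(fit)
#' @export
detect_spots <- function(frame, psf, config = detection_config(),
                         cutoff = NULL) {
  frame <- as_pixel_matrix(frame)
  if (is.null(cutoff)) cutoff <- statistic_cutoff(dim(frame), psf, config)
  work <- frame
  half <- psf$window_half
  spots <- list()
  acc_x <- numeric(0); acc_y <- numeric(0)
  truncated <- FALSE
  rounds <- 0L

  # candidates are screened at half the cutoff when deblending: a near-equal
  # close pair depresses both members' window scores (each window holds the
  # other spot), but every accepted spot must still clear the full cutoff in
  # its own window conditional on the other fitted component being removed
  screen <- if (config$deblend) cutoff / 2 else cutoff

  for (round in seq_len(config$max_depletion_rounds)) {
    cands <- detect_candidates(work, psf, screen)
    if (nrow(cands) == 0L) break
    rounds <- round
    new_any <- FALSE
    for (ci in seq_len(nrow(cands))) {
      if (length(acc_x) &&
          any(abs(acc_x - cands$x[ci]) < 1 & abs(acc_y - cands$y[ci]) < 1)) {
        next  # duplicate suppression: within 1 px of an accepted spot
      }
      recs <- fit_spot_window(work, c(cands$x[ci], cands$y[ci]), psf,
                              cutoff = if (config$deblend) cutoff else Inf)
      for (ri in seq_len(nrow(recs))) {
        rec <- recs[ri, , drop = FALSE]
        if (max(rec$glrt_score, rec$cond_score) < cutoff) next
        if (rec$amplitude <= 0 || rec$amplitude < config$min_amplitude) next
        if (length(acc_x) &&
            any(abs(acc_x - rec$x_px) < 1 & abs(acc_y - rec$y_px) < 1)) {
          next
        }
        rec$z_index <- NA_integer_
        rec$depletion_round <- round
        spots[[length(spots) + 1L]] <- rec
        acc_x <- c(acc_x, rec$x_px); acc_y <- c(acc_y, rec$y_px)
        work <- subtract_spot(work, psf, rec$x_px, rec$y_px, rec$amplitude)
        new_any <- TRUE
        if (length(spots) >= config$max_spots) {
          truncated <- TRUE
          break
        }
      }
      if (truncated) break
    }
    if (!new_any || truncated) break
  }

  tab <- if (length(spots)) do.call(rbind, spots) else empty_spot_table()
  if (nrow(tab)) {
    tab <- tab[, c("x_px", "y_px", "z_index", "amplitude", "background",
                   "glrt_score", "score_db", "depletion_round",
                   "residual_var", "converged")]
    rownames(tab) <- NULL
  }
  structure(list(spots = tab, psf = psf, config = config, cutoff = cutoff,
                 image = frame, residual = work, rounds = rounds,
                 truncated = truncated),
            class = "fish_spots")
}

subtract_spot <- function(img, psf, x, y, amplitude) {
  add_spots(img, psf, x, y, -amplitude)
}

#' @export
print.fish_spots <- function(x, ...) {
  cat(sprintf("fish_spots: %d spots at %.3g dB (cutoff T = %.3f, %s), %d depletion round(s)%s\n",
              nrow(x$spots), x$config$threshold_db, x$cutoff,
              x$config$calibration_mode, x$rounds,
              if (x$truncated) " [truncated]" else ""))
  invisible(x)
}

#' @export
summary.fish_spots <- function(object, ...) {
  s <- object$spots
  out <- list(n = nrow(s), threshold_db = object$config$threshold_db,
              cutoff = object$cutoff, rounds = object$rounds,
              truncated = object$truncated,
              amplitude = if (nrow(s)) summary(s$amplitude) else NULL,
              background = if (nrow(s)) summary(s$background) else NULL,
              by_round = if (nrow(s)) table(s$depletion_round) else NULL)
  class(out) <- "summary.fish_spots"
  out
}

#' @export
print.summary.fish_spots <- function(x, ...) {
  cat(sprintf("Spot detection: %d spots (threshold %.3g dB, cutoff %.3f, %d rounds)\n",
              x$n, x$threshold_db, x$cutoff, x$rounds))
  if (!is.null(x$amplitude)) {
    cat("Amplitudes:\n"); print(x$amplitude)
    cat("Spots per depletion round:\n"); print(x$by_round)
  }
  invisible(x)
}

#' @export
coef.fish_spots <- function(object, ...) object$spots

#' @export
residuals.fish_spots <- function(object, ...) object$residual

#' @export
fitted.fish_spots <- function(object, ...) object$image - object$residual

#' @export
plot.fish_spots <- function(x, ...) {
  img <- x$image
  graphics::image(t(img)[, nrow(img):1], col = grDevices::gray.colors(256),
                  axes = FALSE, asp = nrow(img) / ncol(img), ...)
  if (nrow(x$spots)) {
    graphics::points(x$spots$x_px / (ncol(img) - 1),
                     1 - x$spots$y_px / (nrow(img) - 1),
                     col = "red", cex = 0.6)
  }
  invisible(x)
}

#' Count detected spots inside a cell mask
#'
#' @param spots A `fish_spots` object or its spot table.
#' @param cell_mask Logical/numeric matrix, nonzero inside the cell.
#' @return Number of accepted spots whose fitted centre lies in the mask.
#' @export
count_per_cell <- function(spots, cell_mask) {
  if (inherits(spots, "fish_spots")) spots <- spots$spots
  if (nrow(spots) == 0L) return(0L)
  sum(spots_in_mask(spots$x_px, spots$y_px, cell_mask))
}

#' Detect and count spots in a z-stack (3D counting)
#'
#' Runs 2D detection per slice, then merges spots in adjacent slices whose xy
#' distance is within `link_radius_px` (single-linkage through consecutive
#' slices).  Each merged cluster is one 3D spot, located at the
#' intensity-weighted centroid of its slice detections.
#'
#' @param stack A z-axis [image_stack()].
#' @param psf A [psf_model()].
#' @param config A [detection_config()]; `link_radius_px` defaults to
#'   `2 * sigma_px`.
#' @return List with `spots3d` (cluster table: centroid `x_px`, `y_px`,
#'   `z_index`, summed `amplitude`, `n_slices`), `count` (number of 3D
#'   spots), and `per_slice` (list of per-slice `fish_spots`).
#' @export
detect_stack_3d <- function(stack, psf, config = detection_config()) {
  if (!inherits(stack, "image_stack") || stack$axis != "z") {
    stop("`stack` must be an image_stack with axis = \"z\"", call. = FALSE)
  }
  link_r <- config$link_radius_px %||% (2 * psf$sigma_px)
  if (link_r < 0) stop("`link_radius_px` must be >= 0", call. = FALSE)

  per_slice <- lapply(seq_along(stack$frames), function(k) {
    det <- detect_spots(stack$frames[[k]], psf, config)
    if (nrow(det$spots)) det$spots$z_index <- k - 1L
    det
  })
  all_spots <- do.call(rbind, lapply(per_slice, function(d) d$spots))
  if (is.null(all_spots) || nrow(all_spots) == 0L) {
    return(list(spots3d = data.frame(), count = 0L, per_slice = per_slice))
  }

  # union-find over detections; link pairs in consecutive slices within link_r
  n <- nrow(all_spots)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union2 <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[rj] <<- ri }
  zvals <- sort(unique(all_spots$z_index))
  for (z in zvals) {
    i1 <- which(all_spots$z_index == z)
    i2 <- which(all_spots$z_index == z + 1L)
    if (!length(i1) || !length(i2)) next
    for (i in i1) {
      d2 <- (all_spots$x_px[i2] - all_spots$x_px[i])^2 +
            (all_spots$y_px[i2] - all_spots$y_px[i])^2
      for (j in i2[d2 <= link_r^2]) union2(i, j)
    }
  }
  root <- vapply(seq_len(n), find, 1L)
  groups <- split(seq_len(n), root)
  spots3d <- do.call(rbind, lapply(groups, function(ix) {
    w <- all_spots$amplitude[ix]
    w <- pmax(w, 1e-12)
    data.frame(x_px = sum(all_spots$x_px[ix] * w) / sum(w),
               y_px = sum(all_spots$y_px[ix] * w) / sum(w),
               z_index = sum(all_spots$z_index[ix] * w) / sum(w),
               amplitude = sum(all_spots$amplitude[ix]),
               n_slices = length(ix))
  }))
  rownames(spots3d) <- NULL
  list(spots3d = spots3d, count = nrow(spots3d), per_slice = per_slice)
}
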