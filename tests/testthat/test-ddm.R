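test_that("structure function matches the pure-noise closed form 2 sigma^2", {
  sigma <- 3
  sq <- noise_movie(n_frames = 24, n = 64, sigma = sigma, seed = 1)
  sf <- compute_structure_function(sq, max_lag_frames = 4)
  expect_equal(mean(sf$values), 2 * sigma^2, tolerance = 0.03)
  # every q-bin individually within sampling error
  expect_true(all(abs(sf$values / (2 * sigma^2) - 1) < 0.35))
})

test_that("structure function equals an independent double-loop evaluation", {
  sq <- noise_movie(n_frames = 10, n = 8, sigma = 2, seed = 2)
  sf <- compute_structure_function(sq, max_lag_frames = 6)
  oracle <- brute_force_sf(sq, max_lag = 6)
  expect_equal(sf$q_grid, oracle$q_grid, tolerance = 1e-12)
  expect_equal(sf$values, oracle$values, tolerance = 1e-10)

  # and with subsampled pairs (direct path) it is bit-identical
  sf_sub <- compute_structure_function(sq, max_lag_frames = 6,
                                       max_pairs_per_lag = 5)
  oracle_sub <- brute_force_sf(sq, max_lag = 6, max_pairs = 5)
  expect_identical(unname(sf_sub$values), unname(oracle_sub$values))
})

test_that("identical frames give a zero structure function", {
  sq <- tiny_sequence(3, 16, value = 5)
  sq$frames[, 3, 7] <- 100  # static texture, still identical across time
  # direct pair path: exact zero; fast autocorrelation path: zero up to
  # catastrophic-cancellation rounding of the static power (~1e-10 relative)
  sf_direct <- compute_structure_function(sq, max_lag_frames = 2,
                                          max_pairs_per_lag = 1)
  expect_true(all(sf_direct$values == 0))
  sf_fast <- compute_structure_function(sq, max_lag_frames = 2)
  expect_true(all(sf_fast$values < 1e-6))
})

test_that("a constant intensity offset leaves D(q, dt) unchanged for q > 0", {
  mov <- simulate_brownian_movie(brownian_movie_config(
    n_particles = 20, n_frames = 10, field_um = 10, pixel_size_um = 0.25,
    noise_sigma = 0, seed = 8))
  sf1 <- compute_structure_function(mov$sequence, max_lag_frames = 5)
  shifted <- mov$sequence
  shifted$frames <- shifted$frames + 123.4
  sf2 <- compute_structure_function(shifted, max_lag_frames = 5)
  expect_equal(sf1$values, sf2$values, tolerance = 1e-9)
})

test_that("structure function refuses movies that are too short", {
  expect_error(compute_structure_function(tiny_sequence(2, 8)),
               "insufficient frames")
})

test_that("noise floor fit recovers analytic tails", {
  sq <- noise_movie(n_frames = 24, n = 64, sigma = 3, seed = 3)
  sf <- compute_structure_function(sq, max_lag_frames = 2)
  cal <- estimate_noise_floor(sf, q_noise = max(sf$q_grid) / 2)
  expect_equal(cal$B, 18, tolerance = 0.05)

  # constant tail: B equals the constant
  sf2 <- sf
  sf2$values[] <- 5
  cal2 <- estimate_noise_floor(sf2, q_noise = max(sf$q_grid) / 2)
  expect_equal(cal2$B, 5, tolerance = 1e-8)

  # analytic exponential tail 2 + 7 exp(-q / 1.5)
  sf3 <- sf
  sf3$values[, 1] <- 2 + 7 * exp(-sf3$q_grid / 1.5)
  cal3 <- estimate_noise_floor(sf3, q_noise = 2)
  expect_equal(cal3$B, 2, tolerance = 1e-6)

  expect_error(estimate_noise_floor(sf, q_noise = max(sf$q_grid)),
               "fewer than 4")
})

test_that("amplitude fit recovers analytic plateaus and flags flat bins", {
  sq <- noise_movie(n_frames = 4, n = 32, sigma = 1, seed = 4)
  sf <- compute_structure_function(sq, max_lag_frames = 3)
  # build an analytic structure function on a custom lag grid
  sf$lag_grid <- seq(10, 1200, by = 10)
  sf$n_pairs <- rep(100L, length(sf$lag_grid))
  sf$values <- matrix(rep(10 * (1 - exp(-sf$lag_grid / 50)) + 2,
                          each = length(sf$q_grid)),
                      length(sf$q_grid), length(sf$lag_grid))
  cal <- suppressWarnings(estimate_amplitude(sf, 2, min_lag_s = 100))
  expect_equal(unname(cal$A_q), rep(10, length(sf$q_grid)), tolerance = 1e-4)
  expect_true(all(cal$A_fit_diagnostics$plateau_ok))

  # flat bin at B: amplitude ~ 0, flagged low confidence
  sf$values[1, ] <- 2
  cal2 <- suppressWarnings(estimate_amplitude(sf, 2, min_lag_s = 100))
  expect_true(is.na(cal2$A_q[1]) || cal2$A_q[1] < 1e-6 ||
                !cal2$A_fit_diagnostics$plateau_ok[1])

  expect_error(estimate_amplitude(sf, 2, min_lag_s = 2000), "min_lag_s")
})

test_that("ISF inversion handles the boundary cases and masks out of range", {
  sq <- noise_movie(n_frames = 4, n = 16, sigma = 1, seed = 5)
  sf <- compute_structure_function(sq, max_lag_frames = 2)
  nq <- length(sf$q_grid)
  cal <- structure(list(B = 2, A_q = rep(10, nq)), class = "DDMCalibration")

  sf$values[] <- 2            # D = B -> f = 1
  isf <- invert_to_isf(sf, cal)
  expect_true(all(isf$values == 1))

  sf$values[] <- 12           # D = A + B -> f = 0, masked
  isf0 <- tryCatch(invert_to_isf(sf, cal), error = function(e) e)
  expect_true(inherits(isf0, "error"))  # everything masked -> calibration failed

  sf$values[] <- 7            # f = 0.5 everywhere
  sf$values[1, 1] <- 0        # f = 1.2 there -> masked
  isf2 <- invert_to_isf(sf, cal)
  expect_true(is.na(isf2$values[1, 1]))
  expect_equal(isf2$values[2, 1], 0.5)

  cal_bad <- structure(list(B = 2, A_q = rep(NA_real_, nq)),
                       class = "DDMCalibration")
  expect_error(invert_to_isf(sf, cal_bad), "calibration failed")
})

test_that("MSD extrapolation is exact for constructed inputs", {
  q <- seq(0.2, 1, by = 0.1)
  lag <- c(10, 20, 30)
  # ideal Brownian: f = exp(-q^2 c dt) -> MSD_q = 4 c dt, intercept exact
  c0 <- 0.05
  f <- outer(q, lag, function(q, dt) exp(-q^2 * c0 * dt))
  isf <- structure(list(values = f, valid = f > 0, q_grid = q,
                        lag_grid = lag), class = "ISFMatrix")
  msd <- msd_from_isf(isf, q_band = c(0.2, 1))
  for (j in seq_along(lag)) {
    expect_equal(unique(round(msd$msd_q[, j], 12)), 4 * c0 * lag[j],
                 tolerance = 1e-10)
    expect_equal(msd$msd0[j], 4 * c0 * lag[j], tolerance = 1e-10)
  }

  # f = 1 somewhere -> MSD_q = 0 there
  f2 <- f; f2[3, 2] <- 1
  isf2 <- structure(list(values = f2, valid = f2 > 0, q_grid = q,
                         lag_grid = lag), class = "ISFMatrix")
  expect_equal(msd_from_isf(isf2, c(0.2, 1))$msd_q[3, 2], 0)

  # linear-in-q construction: slope 0.3, intercept 1.7
  msd_q_lin <- 1.7 + 0.3 * q
  f3 <- matrix(exp(-msd_q_lin * q^2 / 4), length(q), 1)
  isf3 <- structure(list(values = f3, valid = f3 > 0, q_grid = q,
                         lag_grid = 10), class = "ISFMatrix")
  expect_equal(msd_from_isf(isf3, c(0.2, 1))$msd0[1], 1.7,
               tolerance = 1e-10)
})

test_that("diffusion fit is exact on exact lines and safe on degenerate input", {
  lag <- seq(10, 100, by = 10)
  msd <- structure(list(lag_grid = lag, msd0 = 4 * 0.02 * lag,
                        msd0_se = rep(0.01, 10), q_band = c(0.4, 0.8),
                        D0 = NA, D0_se = NA), class = "MSDCurve")
  expect_equal(fit_diffusion(msd)$D0, 0.02, tolerance = 1e-12)

  msd$msd0 <- rep(0, 10)
  expect_equal(fit_diffusion(msd)$D0, 0)

  msd$msd0 <- -4 * 0.02 * lag
  expect_warning(res <- fit_diffusion(msd), "negative")
  expect_equal(res$D0, 0)

  msd$msd0 <- c(1, 2, rep(NA, 8))
  expect_error(fit_diffusion(msd), "fewer than 3")
})

test_that("ideal-Brownian ISF emerges from the noiseless simulator", {
  # statistics-friendly geometry: small field, high-q band, short decay times
  mov <- simulate_brownian_movie(brownian_movie_config(
    n_particles = 80, diffusion_um2_s = 0.05, field_um = 22,
    pixel_size_um = 0.22, frame_interval_s = 5, n_frames = 120,
    noise_sigma = 0, seed = 12))
  sf <- compute_structure_function(mov$sequence, max_lag_frames = 100)
  cal <- suppressWarnings(
    estimate_amplitude(sf, estimate_noise_floor(sf, q_noise = 10),
                       min_lag_s = 100))
  isf <- invert_to_isf(sf, cal)
  sel_q <- which(sf$q_grid > 0.8 & sf$q_grid < 1.6)
  for (i in sel_q) for (j in c(2, 5, 10)) {
    ideal <- exp(-sf$q_grid[i]^2 * 0.05 * sf$lag_grid[j])
    if (ideal < 0.1) next  # below the ISF resolvability mask
    expect_lt(abs(isf$values[i, j] - ideal), 0.06)
  }
})

test_that("end-to-end recovery and tracking-oracle agreement on Brownian input", {
  # scaled-down property sweep: D spanning 0.005-0.1 um^2/s, 5 seeds each.
  # Frame interval and extrapolation band are chosen per mobility so the
  # band ISF decays within the movie; the 10% / 15% checks are on the mean
  # over seeds (a single small movie carries ~30% intrinsic spread, see the
  # methods vignette).
  cases <- list(list(D = 0.005, dt = 20, band = c(0.8, 1.6)),
                list(D = 0.1, dt = 2, band = c(0.4, 0.9)))
  for (case in cases) {
    d0 <- msd_ratio <- numeric(0)
    for (seed in 1:5) {
      mov <- simulate_brownian_movie(brownian_movie_config(
        n_particles = 100, diffusion_um2_s = case$D, field_um = 28,
        pixel_size_um = 0.22, frame_interval_s = case$dt, n_frames = 120,
        noise_sigma = 1, seed = 100 + seed))
      sf <- compute_structure_function(mov$sequence, max_lag_frames = 100)
      cal <- suppressWarnings(
        estimate_amplitude(sf, estimate_noise_floor(sf, q_noise = 10),
                           min_lag_s = 0, gamma = 1))
      isf <- invert_to_isf(sf, cal)
      msd <- fit_diffusion(msd_from_isf(isf, q_band = case$band))
      d0[seed] <- msd$D0

      # tracking oracle: ground-truth unwrapped MSD at a mid lag
      k <- 5
      tr <- mov$trajectories
      msd_track <- mean(unlist(tapply(seq_len(nrow(tr)), tr$particle,
        function(i) (tr$x_um[i][-seq_len(k)] - utils::head(tr$x_um[i], -k))^2 +
                    (tr$y_um[i][-seq_len(k)] - utils::head(tr$y_um[i], -k))^2)))
      msd_ratio[seed] <- msd$msd0[k] / msd_track
    }
    expect_equal(mean(d0), case$D, tolerance = 0.10)
    expect_lt(abs(mean(msd_ratio) - 1), 0.15)
  }
})

test_that("MSD_0(dt) is linear in dt for Brownian input (R^2 >= 0.98)", {
  # Linearity is a statement about the underlying curve; a single movie
  # carries ~30% per-lag scatter at the stated geometry, so the test pools
  # the inverse-variance-weighted MSD_0 of three movies before fitting.
  n_lag <- 120L
  Y <- W <- matrix(NA_real_, 3, n_lag)
  for (seed in 1:3) {
    mov <- simulate_brownian_movie(brownian_movie_config(
      diffusion_um2_s = 0.023, seed = seed))
    sf <- compute_structure_function(mov$sequence, max_lag_frames = n_lag)
    cal <- suppressWarnings(
      estimate_amplitude(sf, estimate_noise_floor(sf), min_lag_s = 0,
                         gamma = 1))
    msd <- msd_from_isf(invert_to_isf(sf, cal))
    Y[seed, ] <- msd$msd0
    W[seed, ] <- 1 / msd$msd0_se^2
  }
  W[!is.finite(Y)] <- NA
  m <- colSums(Y * W, na.rm = TRUE) / colSums(W, na.rm = TRUE)
  w <- colSums(W, na.rm = TRUE)
  ok <- is.finite(m) & w > 0
  lag <- seq_len(n_lag) * 10
  fit <- stats::lm(m[ok] ~ lag[ok], weights = w[ok])
  r2 <- 1 - sum(w[ok] * stats::resid(fit)^2) /
    sum(w[ok] * (m[ok] - stats::weighted.mean(m[ok], w[ok]))^2)
  expect_gte(r2, 0.98)
  expect_equal(unname(stats::coef(fit)[2]) / 4, 0.023, tolerance = 0.3)
})

test_that("brownian structure function is non-decreasing in lag at fixed q", {
  mov <- simulate_brownian_movie(brownian_movie_config(
    n_particles = 60, diffusion_um2_s = 0.05, field_um = 15,
    pixel_size_um = 0.25, frame_interval_s = 5, n_frames = 60,
    noise_sigma = 0, seed = 31))
  sf <- compute_structure_function(mov$sequence, max_lag_frames = 30)
  sel <- sf$q_grid > 0.8 & sf$q_grid < 3
  smoothed <- t(apply(sf$values[sel, ], 1, function(v) stats::filter(v, rep(1/5, 5))))
  diffs <- t(apply(smoothed, 1, diff))
  # allow small sampling wiggles relative to the local level
  expect_true(mean(diffs > -0.05 * abs(smoothed[, -1]), na.rm = TRUE) > 0.95)
})
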