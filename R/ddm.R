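#' Differential dynamic microscopy
#'
#' Tracking-free measurement of granule mobility.  The chain is:
#' image structure function `D(q, dt)` from Fourier-space frame differences;
#' noise floor `B` from the high-q tail at the shortest lag; amplitude `A(q)`
#' from the large-lag plateau; intermediate scattering function
#' `f(q, dt) = 1 - (D - B)/A`; per-q mean square displacement
#' `MSD_q(dt) = -(4/q^2) ln f`; extrapolation to `q -> 0` at fixed lag; and a
#' linear fit `MSD_0(dt) = 4 D_0 dt` for the effective diffusion coefficient.
#'
#' @name ddm
NULL

#' Compute the image structure function
#'
#' For each lag `k * dt0` the squared modulus of the difference of frame
#' Fourier transforms is averaged over up to `max_pairs_per_lag` start times
#' (evenly subsampled when more are available) and then azimuthally over the
#' orientation of the wave vector.  The squared modulus is divided by the
#' pixel count, so for pure i.i.d. noise of variance `sigma^2` the expectation
#' is `2 sigma^2` at every q — the closed-form anchor the tests use.  Wave
#' vectors are physical: `q = 2 pi f` with `f` in cycles per micrometre.
#' Radial bins have width `2 pi / L` (`L` = ROI side in um) centered on
#' integer multiples; the zero-frequency bin is excluded.  Frames are
#' center-cropped to a square if needed.
#'
#' @param seq An [image_sequence()].
#' @param max_lag_frames Largest lag in frames (default 60).
#' @param max_pairs_per_lag Frame-pair census per lag (default 200).
#' @param window Apply a Hann window before the FFT (default `FALSE`; the
#'   plain periodogram preserves the amplitude calibration).
#' @return A `StructureFunction`: list with `q_grid` (um^-1), `lag_grid` (s),
#'   `values` (q x lag matrix), `n_pairs`, `roi_size_um`, `pixel_size_um`.
#' @export
compute_structure_function <- function(seq, max_lag_frames = 60L,
                                       max_pairs_per_lag = 200L,
                                       window = FALSE) {
  stopifnot(inherits(seq, "ImageSequence"))
  nf <- n_frames(seq)
  if (nf < 3L) stop("insufficient frames: DDM needs at least 3 frames")
  max_lag_frames <- min(as.integer(max_lag_frames), nf - 1L)
  d <- dim(seq$frames)
  n <- min(d[2], d[3])
  r0 <- floor((d[2] - n) / 2); c0 <- floor((d[3] - n) / 2)
  px <- seq$pixel_size_um
  L <- n * px

  win <- if (window) {
    h <- 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))
    h %o% h
  } else NULL

  ffts <- vector("list", nf)
  for (t in seq_len(nf)) {
    fr <- seq$frames[t, r0 + seq_len(n), c0 + seq_len(n)]
    if (!is.null(win)) fr <- fr * win
    ffts[[t]] <- stats::fft(fr)
  }

  # radial bin index per FFT pixel: frequencies wrap to [-1/2, 1/2)
  f_cyc <- (seq_len(n) - 1L) / n
  f_cyc[f_cyc >= 0.5] <- f_cyc[f_cyc >= 0.5] - 1
  qx <- 2 * pi * f_cyc / px
  qmag <- sqrt(outer(qx^2, qx^2, `+`))
  dq <- 2 * pi / L
  bin <- as.integer(round(qmag / dq))
  keep <- bin > 0L
  bin_f <- factor(bin[keep], levels = sort(unique(bin[keep])))
  bin_centers <- as.integer(levels(bin_f)) * dq

  lags <- seq_len(max_lag_frames)
  values <- matrix(NA_real_, length(bin_centers), length(lags))
  values_se <- matrix(NA_real_, length(bin_centers), length(lags))
  n_pairs <- integer(length(lags))
  npx <- n * n
  if (max_pairs_per_lag >= nf - 1L) {
    # all start times at every lag: the all-pairs average can be taken per
    # q-pixel with one temporal FFT (autocorrelation identity
    # sum |v_{t+k} - v_t|^2 = suffix_k + prefix_k - 2 Re sum v_{t+k} v_t*),
    # which is algebraically identical to the direct pair loop
    px_idx <- which(keep)
    bin_counts <- as.integer(table(bin_f))
    bin_sums <- matrix(0, length(bin_centers), length(lags))
    bin_sq <- matrix(0, length(bin_centers), length(lags))
    chunk <- max(1L, floor(8e5 / nf))  # small chunks keep mvfft in cache
    for (c0 in seq(1L, length(px_idx), by = chunk)) {
      sel_chunk <- c0:min(c0 + chunk - 1L, length(px_idx))
      cols <- px_idx[sel_chunk]
      bf_chunk <- bin_f[sel_chunk]
      P <- matrix(0i, nf, length(cols))
      for (t in seq_len(nf)) P[t, ] <- ffts[[t]][cols]
      sq <- Mod(P)^2
      cum <- apply(sq, 2, cumsum)
      Fz <- stats::mvfft(rbind(P, matrix(0i, nf, ncol(P))))
      ac <- Re(stats::mvfft(Mod(Fz)^2 + 0i, inverse = TRUE)) / (2 * nf)
      Dk <- matrix(0, length(lags), length(cols))
      for (li in seq_along(lags)) {
        k <- lags[li]
        prefix <- cum[nf - k, ]
        suffix <- cum[nf, ] - cum[k, ]
        Dk[li, ] <- (suffix + prefix - 2 * ac[k + 1L, ]) / (nf - k)
      }
      part <- rowsum(t(Dk), bf_chunk)  # (levels present) x lags
      rows <- match(rownames(part), levels(bin_f))
      bin_sums[rows, ] <- bin_sums[rows, ] + part
      part2 <- rowsum(t(Dk)^2, bf_chunk)
      bin_sq[rows, ] <- bin_sq[rows, ] + part2
    }
    values <- sweep(bin_sums, 1, bin_counts, `/`) / npx
    # pixel-to-pixel scatter of the time-averaged per-pixel value gives an
    # honest standard error of each azimuthal mean (pixels are independent)
    var_px <- sweep(bin_sq, 1, bin_counts, `/`) / npx^2 - values^2
    values_se <- sweep(sqrt(pmax(var_px, 0)), 1, sqrt(pmax(bin_counts - 1, 1)), `/`)
    n_pairs <- nf - lags
  } else {
    for (li in seq_along(lags)) {
      k <- lags[li]
      starts <- seq_len(nf - k)
      if (length(starts) > max_pairs_per_lag)
        starts <- starts[unique(round(seq(1, length(starts),
                                          length.out = max_pairs_per_lag)))]
      acc <- matrix(0, n, n)
      for (s in starts) acc <- acc + Mod(ffts[[s + k]] - ffts[[s]])^2
      acc <- acc / (length(starts) * npx)
      values[, li] <- as.numeric(tapply(acc[keep], bin_f, mean))
      values_se[, li] <- as.numeric(tapply(acc[keep], bin_f, stats::sd)) /
        sqrt(pmax(as.integer(table(bin_f)) - 1L, 1L))
      n_pairs[li] <- length(starts)
    }
  }
  structure(list(q_grid = bin_centers,
                 lag_grid = lags * seq$frame_interval_s,
                 values = values, values_se = values_se, n_pairs = n_pairs,
                 roi_size_um = L, pixel_size_um = px),
            class = "StructureFunction")
}

#' @export
print.StructureFunction <- function(x, ...) {
  cat(sprintf("StructureFunction: %d q-bins (%.3g-%.3g um^-1), %d lags (%g-%g s)\n",
              length(x$q_grid), min(x$q_grid), max(x$q_grid),
              length(x$lag_grid), min(x$lag_grid), max(x$lag_grid)))
  invisible(x)
}

#' Estimate the camera noise floor B
#'
#' Fits `D(q, dt0) = B + C exp(-q / lambda)` by least squares over the tail
#' `q > q_noise`, where the optical transfer function has vanished and only
#' delta-correlated detection noise remains.  The exact tail model is an
#' assumption (recorded as such); for a flat tail the fit degenerates
#' gracefully to `C = 0`, and on fit failure `B` falls back to the tail mean.
#'
#' @param sf A [compute_structure_function()] result.
#' @param q_noise Tail threshold in um^-1 (default 12).
#' @return A `DDMCalibration` with elements `B`, `noise_fit`
#'   (`C`, `lambda`, `rms`), later extended by [estimate_amplitude()].
#' @export
estimate_noise_floor <- function(sf, q_noise = 12) {
  stopifnot(inherits(sf, "StructureFunction"))
  tail_idx <- which(sf$q_grid > q_noise)
  if (length(tail_idx) < 4L)
    stop("fewer than 4 q-bins above q_noise = ", q_noise,
         "; use a smaller pixel size or lower q_noise")
  q <- sf$q_grid[tail_idx]
  y <- sf$values[tail_idx, 1]
  span <- diff(range(q))
  fit <- tryCatch({
    # lambda is capped at the tail span: beyond it the exponential is
    # indistinguishable from a constant and B + C become a degenerate ridge
    # (which would silently send B to zero while C absorbs the floor)
    m <- stats::nls(y ~ B + C * exp(-q / lambda),
                    start = list(B = stats::median(y),
                                 C = max(max(y) - min(y), 1e-9),
                                 lambda = span / 4),
                    lower = c(0, 0, 1e-6), upper = c(Inf, Inf, span),
                    algorithm = "port",
                    control = stats::nls.control(warnOnly = FALSE))
    cf <- stats::coef(m)
    out <- list(B = unname(cf["B"]), C = unname(cf["C"]),
                lambda = unname(cf["lambda"]),
                rms = sqrt(mean(stats::resid(m)^2)))
    if (out$lambda > 0.99 * span) NULL else out  # flat tail: use the mean
  }, error = function(e) NULL)
  if (is.null(fit))
    fit <- list(B = mean(y), C = 0, lambda = NA_real_,
                rms = stats::sd(y))
  structure(list(B = max(fit$B, 0),
                 noise_fit = fit[c("C", "lambda", "rms")],
                 A_q = NULL, A_fit_diagnostics = NULL),
            class = "DDMCalibration")
}

#' Estimate the amplitude A(q)
#'
#' With `B` fixed, each q-bin's lag dependence for `dt > min_lag_s` is fitted
#' by `D(q, dt) = A [1 - exp(-(dt/tau_q)^gamma)] + B` (gamma bounded to
#' 0.5 to 2); `A(q)` is the fitted plateau.  Bins where the ISF has not
#' decayed by the largest lag (fitted exponential term > 0.2) are flagged
#' low-confidence; non-converging bins are masked, not fatal.
#'
#' @param sf A `StructureFunction`.
#' @param calibration A `DDMCalibration` holding `B` (or a bare number).
#' @param min_lag_s Amplitude fit uses lags beyond this (default 100 s).
#' @param gamma `NULL` to fit the stretching exponent per bin (bounded to
#'   0.5 to 2), or a fixed value.  For data known to be homogeneously
#'   Brownian (e.g. the synthetic recovery experiments) `gamma = 1` is exact
#'   and removes a plateau/decay-time degeneracy that otherwise inflates the
#'   variance of `A(q)` at wave vectors whose ISF decays slowly.
#' @return The calibration with `A_q` (length of `q_grid`, `NA` where masked)
#'   and `A_fit_diagnostics` (data frame: `q, A, tau, gamma, plateau_ok,
#'   converged`).
#' @export
estimate_amplitude <- function(sf, calibration, min_lag_s = 100,
                               gamma = NULL) {
  stopifnot(inherits(sf, "StructureFunction"))
  B <- if (inherits(calibration, "DDMCalibration")) calibration$B
       else as.numeric(calibration)
  sel <- sf$lag_grid > min_lag_s  # min_lag_s = 0 fits the full lag range
  if (!any(sel)) stop("lag grid does not reach beyond min_lag_s = ", min_lag_s)
  lag <- sf$lag_grid[sel]
  # pair counts shrink with lag; weighting by them stabilises the plateau
  wts <- sf$n_pairs[sel] / max(sf$n_pairs[sel])
  max_lag <- max(sf$lag_grid)
  nq <- length(sf$q_grid)
  A_q <- rep(NA_real_, nq)
  diag <- data.frame(q = sf$q_grid, A = NA_real_, tau = NA_real_,
                     gamma = NA_real_, plateau_ok = FALSE, converged = FALSE)
  for (i in seq_len(nq)) {
    y <- sf$values[i, sel]
    if (all(!is.finite(y))) next
    plateau0 <- max(mean(y[order(lag, decreasing = TRUE)[seq_len(min(5, length(y)))]]) - B,
                    1e-12)
    # start tau where the rise reaches ~63% of the plateau; the lag median
    # can sit far beyond the decay and strand the optimizer
    rise <- which(y - B >= 0.63 * plateau0)
    tau0 <- if (length(rise)) max(lag[rise[1]] / 2, lag[1] / 2)
            else stats::median(lag) / 2
    fit <- tryCatch({
      if (is.null(gamma)) {
        m <- stats::nls(y ~ A * (1 - exp(-(lag / tau)^g)) + B,
                        start = list(A = plateau0, tau = tau0, g = 1),
                        weights = wts,
                        lower = c(0, 1e-6, 0.5), upper = c(Inf, Inf, 2),
                        algorithm = "port",
                        control = stats::nls.control(warnOnly = TRUE))
        as.list(stats::coef(m))
      } else {
        g0 <- gamma
        m <- stats::nls(y ~ A * (1 - exp(-(lag / tau)^g0)) + B,
                        start = list(A = plateau0, tau = tau0),
                        weights = wts,
                        lower = c(0, 1e-6), upper = c(Inf, Inf),
                        algorithm = "port",
                        control = stats::nls.control(warnOnly = TRUE))
        c(as.list(stats::coef(m)), list(g = g0))
      }
    }, error = function(e) NULL)
    if (is.null(fit)) next
    A_q[i] <- fit$A
    diag$A[i] <- fit$A; diag$tau[i] <- fit$tau; diag$gamma[i] <- fit$g
    diag$converged[i] <- TRUE
    diag$plateau_ok[i] <- exp(-(max_lag / fit$tau)^fit$g) <= 0.2
    # flat bin: no decorrelation signal at all
    if (fit$A <= 0 || !is.finite(fit$A)) diag$plateau_ok[i] <- FALSE
  }
  out <- if (inherits(calibration, "DDMCalibration")) calibration
         else structure(list(B = B, noise_fit = NULL), class = "DDMCalibration")
  out$A_q <- A_q
  out$A_fit_diagnostics <- diag
  out
}

#' Invert the structure function to the intermediate scattering function
#'
#' `f(q, dt) = 1 - (D(q, dt) - B) / A(q)`.  Entries with `f <= 0` or `f > 1`
#' (over-decayed or negative-excess bins at low signal) are masked invalid,
#' never clipped.  When the structure function carries pixel-scatter
#' standard errors, each ISF entry receives a propagated uncertainty
#' `se = values_se / A`, and entries whose relative uncertainty exceeds
#' `max_rel_se` are masked too: below that resolution the logarithm used for
#' the mean square displacement is dominated by survivorship noise.
#'
#' @param sf A `StructureFunction`.
#' @param calibration A `DDMCalibration` with `B` and `A_q`.
#' @param max_rel_se Mask entries with `se/f` at or above this (default 0.5).
#' @return An `ISFMatrix`: `values` (q x lag, `NA` where masked), `se`
#'   (propagated uncertainties, or `NULL`), `valid`, `q_grid`, `lag_grid`.
#' @export
invert_to_isf <- function(sf, calibration, max_rel_se = 0.5) {
  stopifnot(inherits(sf, "StructureFunction"),
            inherits(calibration, "DDMCalibration"),
            !is.null(calibration$A_q))
  A <- calibration$A_q
  usable <- which(is.finite(A) & A > 0)
  if (!length(usable)) stop("calibration failed: no q-bin has a positive amplitude")
  f <- matrix(NA_real_, length(sf$q_grid), length(sf$lag_grid))
  for (i in usable)
    f[i, ] <- 1 - (sf$values[i, ] - calibration$B) / A[i]
  valid <- is.finite(f) & f > 0 & f <= 1
  se <- NULL
  if (!is.null(sf$values_se)) {
    se <- sweep(sf$values_se, 1, A, `/`)
    valid <- valid & is.finite(se) & se < max_rel_se * f
  }
  f[!valid] <- NA_real_
  if (!any(valid)) stop("calibration failed: all ISF entries masked")
  structure(list(values = f, se = se, valid = valid, q_grid = sf$q_grid,
                 lag_grid = sf$lag_grid), class = "ISFMatrix")
}

#' Mean square displacement from the ISF
#'
#' Per-q MSD `MSD_q(dt) = -(4/q^2) ln f(q, dt)`; at each lag with at least 3
#' valid bins inside the extrapolation band, `MSD_0(dt)` is the intercept of
#' the least-squares line of `MSD_q` against `q` (linear in q, slope
#' unconstrained), with the intercept's standard error.  When the ISF
#' carries propagated uncertainties (see [invert_to_isf()]), the line is
#' fitted by weighted least squares with the known per-bin variances
#' `(4/q^2)^2 (se/f)^2` and the intercept's standard error is propagated
#' from them rather than estimated from the one-degree-of-freedom residual
#' scatter: external variances keep the weights independent of the
#' realized errors, which removes the weight-chasing bias a
#' scatter-estimated variance would introduce downstream.  Negative
#' intercepts (possible at noisy lags) are reported, not masked — the
#' physical non-negativity is enforced on the fitted diffusion coefficient,
#' because one-sided masking of noise excursions biases the curve upward.
#'
#' @param isf An `ISFMatrix`.
#' @param q_band Extrapolation band `c(q_lo, q_hi)` in um^-1
#'   (default `c(0.4, 0.8)`).
#' @return An `MSDCurve`: `lag_grid`, `msd_q` (matrix), `msd0`, `msd0_se`,
#'   `n_band_bins`, `q_band`; `D0` is filled by [fit_diffusion()].
#' @export
msd_from_isf <- function(isf, q_band = c(0.4, 0.8)) {
  stopifnot(inherits(isf, "ISFMatrix"), length(q_band) == 2L,
            q_band[1] < q_band[2])
  q <- isf$q_grid
  msd_q <- -sweep(log(isf$values), 1, 4 / q^2, `*`)
  msd_q_se <- if (!is.null(isf$se))
    sweep(isf$se / isf$values, 1, 4 / q^2, `*`) else NULL
  in_band <- q >= q_band[1] & q <= q_band[2]
  nl <- length(isf$lag_grid)
  msd0 <- rep(NA_real_, nl); se <- rep(NA_real_, nl); nb <- integer(nl)
  for (j in seq_len(nl)) {
    ok <- in_band & is.finite(msd_q[, j])
    nb[j] <- sum(ok)
    if (nb[j] < 3L) next
    x <- q[ok]; y <- msd_q[ok, j]
    if (is.null(msd_q_se)) {
      fit <- stats::lm(y ~ x)
      msd0[j] <- stats::coef(fit)[1]
      se[j] <- sqrt(stats::vcov(fit)[1, 1])
    } else {
      w <- 1 / msd_q_se[ok, j]^2
      sw <- sum(w); swx <- sum(w * x); swxx <- sum(w * x^2)
      det <- sw * swxx - swx^2
      msd0[j] <- (swxx * sum(w * y) - swx * sum(w * x * y)) / det
      se[j] <- sqrt(swxx / det)
    }
  }
  if (all(is.na(msd0)))
    stop("fewer than 3 valid band bins at every lag; cannot extrapolate")
  structure(list(lag_grid = isf$lag_grid, msd_q = msd_q, msd0 = msd0,
                 msd0_se = se, n_band_bins = nb, q_band = q_band,
                 D0 = NA_real_, D0_se = NA_real_, fit_lag_range = NULL),
            class = "MSDCurve")
}

#' Fit the effective diffusion coefficient
#'
#' Weighted least squares of `MSD_0(dt) = 4 D_0 dt` through the origin,
#' weights `1 / SE^2` (unit weights when standard errors are degenerate).
#' A negative fitted slope is reported as `D_0 = 0` with a warning.
#'
#' @param msd An `MSDCurve` from [msd_from_isf()].
#' @return The curve with `D0`, `D0_se` and `fit_lag_range` filled in.
#' @export
fit_diffusion <- function(msd) {
  stopifnot(inherits(msd, "MSDCurve"))
  ok <- is.finite(msd$msd0)
  if (sum(ok) < 3L) stop("fewer than 3 lags with a defined MSD_0")
  t <- msd$lag_grid[ok]; y <- msd$msd0[ok]; s <- msd$msd0_se[ok]
  w <- if (all(is.finite(s)) && all(s > 0)) 1 / s^2 else rep(1, length(y))
  slope <- sum(w * t * y) / sum(w * t^2)
  # dispersion-scaled uncertainty of the through-origin WLS slope
  dof <- max(length(y) - 1L, 1L)
  s2 <- sum(w * (y - slope * t)^2) / dof
  slope_se <- sqrt(s2 / sum(w * t^2))
  if (slope < 0) {
    warning("negative MSD_0 slope; reporting D0 = 0")
    slope <- 0
  }
  msd$D0 <- slope / 4
  msd$D0_se <- slope_se / 4
  msd$fit_lag_range <- range(t)
  msd
}

#' @export
print.MSDCurve <- function(x, ...) {
  cat(sprintf("MSDCurve: %d lags, band %.2f-%.2f um^-1, D0 = %s um^2/s\n",
              length(x$lag_grid), x$q_band[1], x$q_band[2],
              if (is.na(x$D0)) "unfitted"
              else sprintf("%.4g +/- %.2g", x$D0, x$D0_se)))
  invisible(x)
}

#' Run the full DDM chain
#'
#' Convenience wrapper: structure function, noise floor, amplitude, ISF,
#' MSD extrapolation, diffusion fit, driven by an [analysis_config()].
#'
#' @param seq An [image_sequence()].
#' @param config An [analysis_config()] (its `$ddm` section is used).
#' @return List with `structure_function`, `calibration`, `isf`, `msd`
#'   (the `MSDCurve` carries `D0`).
#' @export
ddm_pipeline <- function(seq, config = analysis_config()) {
  d <- config$ddm
  sf <- compute_structure_function(seq, d$max_lag_frames, d$max_pairs_per_lag,
                                   window = isTRUE(d$window))
  cal <- estimate_noise_floor(sf, q_noise = d$q_noise)
  cal <- estimate_amplitude(sf, cal, min_lag_s = d$min_lag_s,
                            gamma = d$gamma)
  isf <- invert_to_isf(sf, cal)
  msd <- msd_from_isf(isf, q_band = c(d$q_lo, d$q_hi))
  msd <- fit_diffusion(msd)
  list(structure_function = sf, calibration = cal, isf = isf, msd = msd)
}
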