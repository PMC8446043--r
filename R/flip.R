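#' FLIP exchange-rate quantification
#'
#' Fluorescence loss in photobleaching: one region is bleached repeatedly
#' while the loss of signal is monitored in granule and cytoplasm ROIs
#' elsewhere.  Traces are corrected by a constant background `I_B` (time
#' average of a corner ROI), normalized to their pre-bleach mean, and fitted
#' by a fixed-exponent stretched exponential `exp(-(t/tau)^beta)` with
#' `beta = 0.75`.  A background-perturbation sweep (+/-25% and random)
#' checks that group comparisons do not hinge on the background estimate.
#'
#' @name flip
NULL

#' ROI trace container
#'
#' @param t_grid Sample times in seconds, `t = 0` at the first bleach event
#'   (pre-bleach samples are negative).
#' @param traces Named list of numeric vectors `I_n(t)`, one per ROI, all of
#'   length `length(t_grid)`.
#' @param roles Named character vector (`bleach`, `granule`, `cytoplasm`)
#'   aligned with `traces`.
#' @param prebleach_mean Named numeric vector `I_{n,0}` per ROI.
#' @param background_trace Numeric vector `I_B(t)`; its time average is the
#'   constant background `I_B`.
#' @param reference_trace Numeric vector `I_R(t)`; stored and summarised but
#'   never used as a correction.
#' @param positions Optional named list (granule ROIs) of per-frame `(x, y)`
#'   centers.
#' @param frame_interval_s Sampling interval (s).
#' @param n_prebleach Number of pre-bleach samples at the start of `t_grid`.
#' @return A `ROITraceSet`.
#' @export
roi_trace_set <- function(t_grid, traces, roles, prebleach_mean,
                          background_trace, reference_trace = NULL,
                          positions = NULL, frame_interval_s = NULL,
                          n_prebleach = sum(t_grid < 0)) {
  nt <- length(t_grid)
  if (!all(vapply(traces, length, integer(1)) == nt))
    stop("every trace must span the full t_grid")
  if (length(background_trace) != nt)
    stop("background trace must span the full t_grid")
  structure(list(t_grid = t_grid, traces = traces,
                 roles = roles[names(traces)],
                 prebleach_mean = prebleach_mean[names(traces)],
                 background_trace = background_trace,
                 I_B = mean(background_trace),
                 reference_trace = reference_trace,
                 positions = positions,
                 frame_interval_s = frame_interval_s %||%
                   stats::median(diff(t_grid)),
                 n_prebleach = as.integer(n_prebleach)),
            class = "ROITraceSet")
}

#' @export
print.ROITraceSet <- function(x, ...) {
  cat(sprintf("ROITraceSet: %d ROIs (%s), %d samples, I_B = %.4g\n",
              length(x$traces),
              paste(sprintf("%d %s", table(x$roles), names(table(x$roles))),
                    collapse = ", "),
              length(x$t_grid), x$I_B))
  invisible(x)
}

#' Extract per-ROI intensity traces from a movie
#'
#' Per-frame mean intensity inside each ROI; the ROI list must contain
#' exactly one `background` and one `reference` ROI.  Granule ROIs may carry
#' per-frame positions (a named list of `(frame x 2)` matrices in pixels);
#' their area is kept constant while the mask follows the granule.  A granule
#' whose position leaves the frame has its trace truncated (`NA`) and is
#' flagged.
#'
#' @param seq An [image_sequence()] with `t0_index` at the first post-bleach
#'   frame.
#' @param rois List of [roi_spec()] with roles.
#' @param granule_positions Optional named list of per-frame `(x, y)`
#'   matrices for granule ROIs.
#' @param n_prebleach Pre-bleach frames used for `I_{n,0}` (default 5).
#' @return A [roi_trace_set()].
#' @export
extract_roi_traces <- function(seq, rois, granule_positions = NULL,
                               n_prebleach = 5L) {
  stopifnot(inherits(seq, "ImageSequence"))
  roles <- vapply(rois, `[[`, character(1), "role")
  labels <- vapply(rois, `[[`, character(1), "label")
  labels[labels == ""] <- paste0(roles[labels == ""], "_",
                                 seq_along(labels)[labels == ""])
  for (need in c("background", "reference"))
    if (sum(roles == need) != 1L)
      stop("ROI set must contain exactly one ROI with role '", need, "'")
  d <- dim(seq$frames)
  nf <- d[1]
  t0 <- seq$t0_index
  n_prebleach <- min(as.integer(n_prebleach), t0 - 1L)
  if (n_prebleach < 1L) stop("no pre-bleach frames before t0_index")

  trace_of <- function(roi, label) {
    pos <- if (!is.null(granule_positions)) granule_positions[[label]] else NULL
    if (is.null(pos)) {
      .roi_check_bounds(roi, d[2], d[3], paste0(" ('", label, "')"))
      m <- roi_mask(roi, d[2], d[3])
      vapply(seq_len(nf), function(t) mean(seq$frames[t, , ][m]), numeric(1))
    } else {
      vapply(seq_len(nf), function(t) {
        ctr <- pos[t, ]
        half <- max(roi$w, roi$h) / 2 + 1
        if (ctr[1] < half || ctr[1] > d[3] - 1 - half ||
            ctr[2] < half || ctr[2] > d[2] - 1 - half) return(NA_real_)
        m <- roi_mask(roi, d[2], d[3], center = ctr)
        mean(seq$frames[t, , ][m])
      }, numeric(1))
    }
  }

  traces <- list(); out_roles <- character(); pre <- numeric()
  bg_trace <- NULL; ref_trace <- NULL
  for (i in seq_along(rois)) {
    tr <- trace_of(rois[[i]], labels[i])
    if (roles[i] == "background") bg_trace <- tr
    else if (roles[i] == "reference") ref_trace <- tr
    else {
      traces[[labels[i]]] <- tr
      out_roles[labels[i]] <- roles[i]
      pre[labels[i]] <- mean(tr[(t0 - n_prebleach):(t0 - 1L)], na.rm = TRUE)
    }
  }
  t_grid <- (seq_len(nf) - t0) * seq$frame_interval_s
  roi_trace_set(t_grid = t_grid, traces = traces, roles = out_roles,
                prebleach_mean = pre, background_trace = bg_trace,
                reference_trace = ref_trace, positions = granule_positions,
                frame_interval_s = seq$frame_interval_s,
                n_prebleach = n_prebleach)
}

#' Background-corrected relative intensity
#'
#' `i_n(t) = (I_n(t) - I_B) / (I_n0 - I_B)`.  Values above 1 or below 0 are
#' preserved for diagnostics, never clipped.
#'
#' @param trace Numeric intensity trace `I_n(t)`.
#' @param I_B Constant background.
#' @param I_n0 Pre-bleach mean of the trace; must exceed `I_B`.
#' @param t_grid Optional sample times carried through.
#' @param role Optional role tag carried through.
#' @return A `NormalizedTrace`: list `t_grid`, `i` (relative intensity),
#'   `role`.
#' @export
normalize_trace <- function(trace, I_B, I_n0, t_grid = NULL, role = NA) {
  if (I_n0 <= I_B)
    stop("ROI indistinguishable from background (I_n0 <= I_B)")
  structure(list(t_grid = t_grid, i = (trace - I_B) / (I_n0 - I_B),
                 role = role), class = "NormalizedTrace")
}

#' Fit a fixed-exponent stretched-exponential decay
#'
#' One-parameter least squares of `exp(-(t/tau)^beta)` against the
#' normalized trace for `t >= 0`, amplitude fixed at 1, no offset.  `tau` is
#' searched on a log grid within `[frame_interval, 100 * duration]`; a fit
#' ending at a bound is flagged.
#'
#' @param norm A [normalize_trace()] result (needs `t_grid`).
#' @param beta Stretched exponent, fixed (default 0.75).
#' @param min_samples Minimum post-bleach samples (default 20).
#' @return List `tau` (s), `rms`, `converged`, `at_bound`, `beta`.
#' @export
fit_stretched_exponential <- function(norm, beta = 0.75, min_samples = 20L) {
  stopifnot(inherits(norm, "NormalizedTrace"), !is.null(norm$t_grid),
            beta > 0, beta <= 1)
  sel <- norm$t_grid >= 0 & is.finite(norm$i)
  if (sum(sel) < min_samples)
    stop("fewer than ", min_samples, " post-bleach samples")
  t <- norm$t_grid[sel]; y <- norm$i[sel]
  dt <- stats::median(diff(t))
  lo <- dt; hi <- 100 * max(t)
  obj <- function(log_tau) {
    m <- exp(-(t / exp(log_tau))^beta)
    sum((y - m)^2)
  }
  opt <- stats::optimize(obj, interval = log(c(lo, hi)), tol = 1e-12)
  tau <- exp(opt$minimum)
  at_bound <- tau / lo < 1.001 || tau / hi > 0.999
  list(tau = tau, rms = sqrt(opt$objective / length(y)),
       converged = !at_bound, at_bound = at_bound, beta = beta)
}

#' Fit all granule/cytoplasm traces of a set
#'
#' @param traces A [roi_trace_set()].
#' @param beta Stretched exponent (default 0.75).
#' @param I_B Background override (default: the set's constant `I_B`).
#' @return A `FlipResult`: data frame `fits` (roi, role, tau, rms,
#'   converged), `beta`, `summary` (mean +/- SD of tau per role).
#' @export
fit_flip_traces <- function(traces, beta = 0.75, I_B = NULL) {
  stopifnot(inherits(traces, "ROITraceSet"))
  I_B <- I_B %||% traces$I_B
  rows <- lapply(names(traces$traces), function(nm) {
    fit <- tryCatch({
      ntr <- normalize_trace(traces$traces[[nm]], I_B,
                             traces$prebleach_mean[[nm]],
                             t_grid = traces$t_grid,
                             role = traces$roles[[nm]])
      fit_stretched_exponential(ntr, beta = beta)
    }, error = function(e) NULL)
    if (is.null(fit))
      data.frame(roi = nm, role = unname(traces$roles[[nm]]), tau = NA_real_,
                 rms = NA_real_, converged = FALSE)
    else
      data.frame(roi = nm, role = unname(traces$roles[[nm]]), tau = fit$tau,
                 rms = fit$rms, converged = fit$converged)
  })
  fits <- do.call(rbind, rows)
  ok <- fits$converged
  summ <- stats::aggregate(tau ~ role, data = fits[ok, , drop = FALSE],
                           FUN = function(v) c(mean = mean(v), sd = stats::sd(v),
                                               n = length(v)))
  structure(list(fits = fits, beta = beta, I_B = I_B, summary = summ),
            class = "FlipResult")
}

#' @export
print.FlipResult <- function(x, ...) {
  cat(sprintf("FlipResult (beta = %g, I_B = %.4g):\n", x$beta, x$I_B))
  print(x$fits[, c("roi", "role", "tau", "converged")], row.names = FALSE)
  invisible(x)
}

#' Background-perturbation robustness sweep
#'
#' Re-runs normalization and fitting with `I_B` scaled by each perturbation
#' (default -25%, +25%, and uniform random between -25% and +25%); an ROI whose
#' perturbed background reaches its pre-bleach mean is dropped for that
#' condition.  When `groups` assigns ROIs to two labels, the ratio of
#' group-mean tau is reported per condition.
#'
#' @param traces A [roi_trace_set()] (or a named list of them, pooled).
#' @param beta Stretched exponent.
#' @param perturbations Relative changes of `I_B`; `NA` entries draw a
#'   uniform random perturbation between -25% and +25%.
#' @param groups Optional named vector mapping ROI names to two group labels.
#' @param seed Seed for the random perturbation.
#' @return List `table` (data frame: condition, roi, role, tau, converged)
#'   and `group_ratio` (data frame per condition) when `groups` is given.
#' @export
background_sensitivity <- function(traces, beta = 0.75,
                                   perturbations = c(-0.25, 0.25, NA),
                                   groups = NULL, seed = NULL) {
  .set_seed(seed)
  pert <- vapply(perturbations, function(p)
    if (is.na(p)) stats::runif(1, -0.25, 0.25) else p, numeric(1))
  pert <- c(baseline = 0, stats::setNames(pert, sprintf("pert_%+.3f", pert)))
  sets <- if (inherits(traces, "ROITraceSet")) list(set1 = traces) else traces
  rows <- list()
  for (cond in names(pert)) {
    for (snm in names(sets)) {
      s <- sets[[snm]]
      fr <- fit_flip_traces(s, beta = beta, I_B = s$I_B * (1 + pert[[cond]]))
      f <- fr$fits
      f$roi <- paste0(snm, ".", f$roi)
      f$condition <- cond
      f$perturbation <- pert[[cond]]
      rows[[length(rows) + 1L]] <- f
    }
  }
  tab <- do.call(rbind, rows)
  ratio <- NULL
  if (!is.null(groups)) {
    gl <- unique(stats::na.omit(groups))
    if (length(gl) != 2L) stop("groups must define exactly two labels")
    ratio <- do.call(rbind, lapply(unique(tab$condition), function(cond) {
      sub <- tab[tab$condition == cond & tab$converged, ]
      m <- tapply(sub$tau, groups[sub$roi], mean, na.rm = TRUE)
      data.frame(condition = cond,
                 mean_tau_1 = m[[gl[1]]], mean_tau_2 = m[[gl[2]]],
                 ratio = m[[gl[2]]] / m[[gl[1]]])
    }))
  }
  list(table = tab, group_ratio = ratio)
}

#' Run the full FLIP chain on a movie
#'
#' @param seq An [image_sequence()].
#' @param rois List of [roi_spec()] including one `background` and one
#'   `reference` ROI.
#' @param config An [analysis_config()] (its `$flip` section is used).
#' @param granule_positions Optional tracked granule ROI centers.
#' @return List with `traces` (a `ROITraceSet`), `result` (a `FlipResult`)
#'   and `robustness` (the perturbation sweep).
#' @export
flip_pipeline <- function(seq, rois, config = analysis_config(),
                          granule_positions = NULL) {
  fc <- config$flip
  traces <- extract_roi_traces(seq, rois, granule_positions,
                               n_prebleach = fc$n_prebleach)
  result <- fit_flip_traces(traces, beta = fc$beta)
  rob <- background_sensitivity(traces, beta = fc$beta,
                                perturbations = fc$perturbations, seed = 1L)
  list(traces = traces, result = result, robustness = rob)
}
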