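#' Synthetic-data generators
#'
#' Seeded generators with known ground truth emulating the statistical
#' structure of the confocal data the analysis pipelines were designed for:
#' Brownian granule movies for DDM, a diffusing Gaussian bleach deficit for
#' FRAP, stretched-exponential loss traces for FLIP, and polygonal shapes for
#' the morphometry oracles.  Identical configs and seeds reproduce outputs
#' exactly.
#'
#' @name synthetic-data
NULL

.set_seed <- function(seed) if (!is.null(seed)) set.seed(as.integer(seed))

#' Configuration for a Brownian granule movie
#'
#' Defaults emulate the DDM acquisitions: a 45 um square field imaged every
#' 10 s, a few hundred bright Gaussian-profiled granules diffusing at
#' ~0.02 um^2/s.  Granule density and spot intensity are not reported for the
#' real data; the defaults are chosen for numerical stability of the pipelines
#' and are not biological measurements.
#'
#' @param n_particles Number of granules.
#' @param diffusion_um2_s Ground-truth diffusion coefficient (>= 0).
#' @param field_um Field width (um); rounded to a whole number of pixels.
#' @param pixel_size_um Pixel size (um).
#' @param frame_interval_s Frame interval (s).
#' @param n_frames Number of frames (>= 2).
#' @param psf_sigma_um Gaussian spot width (um).
#' @param particle_intensity Integrated spot intensity (arbitrary units).
#' @param background_level Constant background offset.
#' @param noise_sigma SD of additive Gaussian detection noise (0 = none).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A `BrownianMovieConfig` list.
#' @export
brownian_movie_config <- function(n_particles = 150, diffusion_um2_s = 0.023,
                                  field_um = 45, pixel_size_um = 0.22,
                                  frame_interval_s = 10, n_frames = 180,
                                  psf_sigma_um = 0.4, particle_intensity = 500,
                                  background_level = 10, noise_sigma = 3,
                                  seed = NULL) {
  stopifnot(diffusion_um2_s >= 0, field_um > 0, pixel_size_um > 0,
            frame_interval_s > 0, n_frames >= 2, psf_sigma_um > 0,
            n_particles >= 0, noise_sigma >= 0)
  n_px <- round(field_um / pixel_size_um)
  if (n_px < ceiling(8 * psf_sigma_um / pixel_size_um))
    stop("field too small to hold the PSF")
  structure(list(n_particles = as.integer(n_particles),
                 diffusion_um2_s = diffusion_um2_s,
                 field_um = n_px * pixel_size_um, n_px = as.integer(n_px),
                 pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s,
                 n_frames = as.integer(n_frames),
                 psf_sigma_um = psf_sigma_um,
                 particle_intensity = particle_intensity,
                 background_level = background_level,
                 noise_sigma = noise_sigma, seed = seed),
            class = "BrownianMovieConfig")
}

#' Simulate a movie of Brownian granules
#'
#' Particles perform independent 2-D Gaussian random walks (per-axis step
#' variance `2 * D * frame_interval`) with periodic wrap at the field edges,
#' which keeps the density stationary as DDM assumes.  Spots are rendered by
#' analytically integrating the Gaussian profile over each pixel
#' (error-function differences), avoiding the aliasing that point sampling
#' would inject into the structure function at high q; rendering wraps
#' periodically so frames are consistent with the plain (unwindowed) FFT.
#'
#' @param cfg A [brownian_movie_config()].
#' @return A list of class `BrownianMovie` with elements `sequence` (an
#'   [image_sequence()]), `trajectories` (data frame `particle, frame, x_um,
#'   y_um, x_wrapped_um, y_wrapped_um`; the unwrapped columns are the oracle
#'   for MSD checks, the wrapped ones are what is rendered) and `config`.
#' @export
simulate_brownian_movie <- function(cfg) {
  stopifnot(inherits(cfg, "BrownianMovieConfig"))
  .set_seed(cfg$seed)
  n_px <- cfg$n_px; px <- cfg$pixel_size_um; L <- cfg$field_um
  np <- cfg$n_particles; nf <- cfg$n_frames
  step_sd <- sqrt(2 * cfg$diffusion_um2_s * cfg$frame_interval_s)

  x <- matrix(0, nf, max(np, 1)); y <- matrix(0, nf, max(np, 1))
  if (np > 0) {
    x[1, ] <- stats::runif(np, 0, L)
    y[1, ] <- stats::runif(np, 0, L)
    if (nf > 1) {
      dx <- matrix(stats::rnorm((nf - 1) * np, 0, step_sd), nf - 1, np)
      dy <- matrix(stats::rnorm((nf - 1) * np, 0, step_sd), nf - 1, np)
      x[-1, ] <- x[rep(1, nf - 1), ] + apply(dx, 2, cumsum)
      y[-1, ] <- y[rep(1, nf - 1), ] + apply(dy, 2, cumsum)
    }
  }
  sigma <- cfg$psf_sigma_um
  half <- ceiling(4 * sigma / px)
  frames <- array(cfg$background_level, c(nf, n_px, n_px))
  if (np > 0) {
    offs <- (-half):(half)
    for (t in seq_len(nf)) {
      fr <- matrix(0, n_px, n_px)
      xw <- x[t, ] %% L; yw <- y[t, ] %% L
      ic <- round(xw / px); jc <- round(yw / px)  # nearest pixel index (0-based)
      for (p in seq_len(np)) {
        cols <- (ic[p] + offs) %% n_px + 1L
        rows <- (jc[p] + offs) %% n_px + 1L
        edges <- ((ic[p] + offs[1]) : (ic[p] + offs[length(offs)] + 1L) - 0.5) * px
        gx <- diff(stats::pnorm(edges, mean = xw[p], sd = sigma))
        edges_y <- ((jc[p] + offs[1]) : (jc[p] + offs[length(offs)] + 1L) - 0.5) * px
        gy <- diff(stats::pnorm(edges_y, mean = yw[p], sd = sigma))
        fr[rows, cols] <- fr[rows, cols] +
          cfg$particle_intensity * (gy %o% gx)
      }
      frames[t, , ] <- frames[t, , ] + fr
    }
  }
  if (cfg$noise_sigma > 0)
    frames <- frames + array(stats::rnorm(length(frames), 0, cfg$noise_sigma),
                             dim(frames))
  frames[frames < 0] <- 0
  traj <- if (np > 0) data.frame(
    particle = rep(seq_len(np), each = nf),
    frame = rep(seq_len(nf), np),
    x_um = as.vector(x), y_um = as.vector(y),
    x_wrapped_um = as.vector(x %% L), y_wrapped_um = as.vector(y %% L)
  ) else data.frame(particle = integer(), frame = integer(), x_um = numeric(),
                    y_um = numeric(), x_wrapped_um = numeric(),
                    y_wrapped_um = numeric())
  structure(list(
    sequence = image_sequence(frames, px, cfg$frame_interval_s),
    trajectories = traj, config = cfg), class = "BrownianMovie")
}

#' Configuration for a synthetic FRAP sequence
#'
#' Defaults emulate the FRAP acquisitions: 66 ms frame interval, 15 pre-bleach
#' frames, an initially Gaussian bleach deficit of width `sigma0_um` that
#' broadens diffusively.
#'
#' @param diffusion_um2_s Ground-truth D (um^2/s).
#' @param sigma0_um Initial bleach-profile width (um).
#' @param bleach_depth Fraction of the field removed at the bleach center at
#'   t = 0, in (0, 1].
#' @param frame_interval_s Frame interval (s).
#' @param n_prebleach,n_postbleach Frame counts before/after the bleach.
#' @param noise_sigma SD of additive Gaussian noise (intensity units).
#' @param center Bleach center `(x, y)` in pixels; `NULL` = frame center.
#' @param field_um,pixel_size_um Field geometry.
#' @param field_level Uniform pre-bleach intensity.
#' @param seed Integer seed.
#' @return A `FrapSimConfig` list.
#' @export
frap_sim_config <- function(diffusion_um2_s = 0.24, sigma0_um = 1.5,
                            bleach_depth = 0.5, frame_interval_s = 0.066,
                            n_prebleach = 15L, n_postbleach = 460L,
                            noise_sigma = 0, center = NULL,
                            field_um = 40, pixel_size_um = 0.2,
                            field_level = 100, seed = NULL) {
  stopifnot(diffusion_um2_s >= 0, sigma0_um > 0,
            bleach_depth > 0, bleach_depth <= 1,
            frame_interval_s > 0, n_prebleach >= 1, n_postbleach >= 2,
            noise_sigma >= 0, field_level > 0)
  structure(list(diffusion_um2_s = diffusion_um2_s, sigma0_um = sigma0_um,
                 bleach_depth = bleach_depth,
                 frame_interval_s = frame_interval_s,
                 n_prebleach = as.integer(n_prebleach),
                 n_postbleach = as.integer(n_postbleach),
                 noise_sigma = noise_sigma, center = center,
                 field_um = field_um, pixel_size_um = pixel_size_um,
                 field_level = field_level, seed = seed),
            class = "FrapSimConfig")
}

#' Simulate a FRAP sequence with a diffusing Gaussian bleach deficit
#'
#' The post-bleach frame at time `t` after the bleach is
#' `field * (1 - depth * (sigma0^2 / sigma^2(t)) * exp(-r^2 / sigma^2(t)))`
#' with `sigma^2(t) = sigma0^2 + 4 D t` — the exact 2-D diffusion solution of
#' a Gaussian deficit under the `exp(-r^2/sigma^2)` width convention, with the
#' amplitude scaled so the integrated deficit is conserved.  The first
#' post-bleach frame sits at `t = frame_interval_s`.
#'
#' @param cfg A [frap_sim_config()].
#' @return An [image_sequence()] with `t0_index = n_prebleach + 1`.
#' @export
simulate_frap_sequence <- function(cfg) {
  stopifnot(inherits(cfg, "FrapSimConfig"))
  .set_seed(cfg$seed)
  px <- cfg$pixel_size_um
  n_px <- round(cfg$field_um / px)
  ctr <- cfg$center %||% c((n_px - 1) / 2, (n_px - 1) / 2)
  xs <- matrix(rep(0:(n_px - 1L), each = n_px), n_px)
  ys <- matrix(rep(0:(n_px - 1L), times = n_px), n_px)
  r2 <- ((xs - ctr[1])^2 + (ys - ctr[2])^2) * px^2
  nf <- cfg$n_prebleach + cfg$n_postbleach
  frames <- array(cfg$field_level, c(nf, n_px, n_px))
  s0sq <- cfg$sigma0_um^2
  for (j in seq_len(cfg$n_postbleach)) {
    t <- j * cfg$frame_interval_s
    ssq <- s0sq + 4 * cfg$diffusion_um2_s * t
    frames[cfg$n_prebleach + j, , ] <- cfg$field_level *
      (1 - cfg$bleach_depth * (s0sq / ssq) * exp(-r2 / ssq))
  }
  if (cfg$noise_sigma > 0)
    frames <- frames + array(stats::rnorm(length(frames), 0, cfg$noise_sigma),
                             dim(frames))
  frames[frames < 0] <- 0
  image_sequence(frames, px, cfg$frame_interval_s,
                 t0_index = cfg$n_prebleach + 1L)
}

#' Configuration for synthetic FLIP loss traces
#'
#' Defaults emulate the FLIP protocol: one bleach every 5 s for 100 events,
#' images every 2.5 s for 8 min, 5 pre-bleach frames, a ~0.5 relative drop in
#' the bleached ROI per exposure, and granule/cytoplasm exchange producing a
#' stretched-exponential loss with exponent `beta = 0.75`.
#'
#' @param tau_s Target granule decay time (s).
#' @param beta Stretched exponent in (0, 1].
#' @param bleach_period_s Time between bleach events (s).
#' @param n_bleach_events Number of bleach exposures.
#' @param frame_interval_s Sampling interval (s).
#' @param duration_s Post-bleach observation time (s).
#' @param per_event_drop Relative drop in the bleached ROI per exposure,
#'   in (0, 1).
#' @param cyto_tau_s Decay time of the fast-mixing cytoplasmic pool (s).
#' @param background_level Constant background intensity I_B.
#' @param n_rois Number of granule ROIs (an equal number of cytoplasm ROIs is
#'   generated).
#' @param noise_sigma Relative SD of multiplicative Gaussian noise.
#' @param mode `"stretched"` generates granule traces directly from the
#'   stretched-exponential law (the law the analysis asserts);
#'   `"exchange"` integrates a first-order granule/cytoplasm exchange model
#'   (`k_out` set from `tau_s`) and exists for property tests only.
#' @param seed Integer seed.
#' @return A `FlipSimConfig` list.
#' @export
flip_sim_config <- function(tau_s = 130, beta = 0.75, bleach_period_s = 5,
                            n_bleach_events = 100L, frame_interval_s = 2.5,
                            duration_s = 480, per_event_drop = 0.5,
                            cyto_tau_s = 40, background_level = 10,
                            n_rois = 4L, noise_sigma = 0,
                            mode = c("stretched", "exchange"), seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(tau_s > 0, beta > 0, beta <= 1, per_event_drop >= 0,
            per_event_drop < 1, frame_interval_s > 0, n_rois >= 1,
            noise_sigma >= 0, cyto_tau_s > 0)
  if (duration_s < bleach_period_s)
    stop("duration shorter than one bleach period")
  structure(list(tau_s = tau_s, beta = beta, bleach_period_s = bleach_period_s,
                 n_bleach_events = as.integer(n_bleach_events),
                 frame_interval_s = frame_interval_s, duration_s = duration_s,
                 per_event_drop = per_event_drop, cyto_tau_s = cyto_tau_s,
                 background_level = background_level, n_rois = as.integer(n_rois),
                 noise_sigma = noise_sigma, mode = mode, seed = seed),
            class = "FlipSimConfig")
}

#' Simulate FLIP loss traces
#'
#' Produces a [roi_trace_set()] whose granule traces are built so that their
#' background-corrected relative intensity follows `exp(-(t/tau)^beta)`
#' (multiplied by optional Gaussian noise), whose cytoplasm traces follow the
#' fast-mixing bleached pool, and whose bleached-ROI trace drops by
#' `per_event_drop` at each exposure and relaxes back toward the pool between
#' exposures.  A constant background and a stable reference trace are
#' included.  `t = 0` is the first bleach event.
#'
#' @param cfg A [flip_sim_config()].
#' @return A `ROITraceSet` (see [roi_trace_set()]).
#' @export
simulate_flip_traces <- function(cfg) {
  stopifnot(inherits(cfg, "FlipSimConfig"))
  .set_seed(cfg$seed)
  dt <- cfg$frame_interval_s
  n_pre <- 5L
  t_post <- seq(0, cfg$duration_s, by = dt)
  t_pre <- seq(-n_pre * dt, -dt, by = dt)
  t_grid <- c(t_pre, t_post)
  post <- t_grid >= 0
  nt <- length(t_grid)

  noisy <- function(x) {
    if (cfg$noise_sigma > 0)
      x * (1 + stats::rnorm(length(x), 0, cfg$noise_sigma)) else x
  }
  # cytoplasmic pool: fast first-order mixing with the bleached region;
  # with no bleaching (per_event_drop = 0) nothing decays anywhere
  bleaching <- cfg$per_event_drop > 0
  pool <- if (bleaching)
    ifelse(post, exp(-pmax(t_grid, 0) / cfg$cyto_tau_s), 1) else rep(1, nt)

  granule_rel <- function() {
    rel <- rep(1, nt)
    if (!bleaching) {
    } else if (cfg$mode == "stretched") {
      rel[post] <- exp(-(t_grid[post] / cfg$tau_s)^cfg$beta)
    } else {
      # dg/dt = -k_out g + k_out * pool(t), k_out = 1/tau
      k <- 1 / cfg$tau_s
      g <- 1
      idx <- which(post)
      for (i in seq_along(idx)) {
        if (i > 1) {
          h <- t_grid[idx[i]] - t_grid[idx[i - 1]]
          g <- g + h * k * (pool[idx[i - 1]] - g)
        }
        rel[idx[i]] <- g
      }
    }
    noisy(rel)
  }

  # bleached ROI: step down at each exposure, relax toward the pool between
  event_times <- cfg$bleach_period_s * (seq_len(cfg$n_bleach_events) - 1L)
  event_times <- event_times[event_times <= cfg$duration_s]
  mix_tau <- 2
  bleach_rel <- rep(1, nt)
  level <- 1
  last_event <- -Inf
  if (bleaching) for (i in which(post)) {
    t <- t_grid[i]
    ev <- event_times[event_times <= t & event_times > last_event]
    for (te in ev) {
      # relax up to the event, then apply the drop
      level <- pool_at(te, cfg) + (level - pool_at(te, cfg)) *
        exp(-(te - max(last_event, 0)) / mix_tau)
      level <- level * (1 - cfg$per_event_drop)
      last_event <- te
    }
    bleach_rel[i] <- pool[i] + (level - pool_at(last_event, cfg)) *
      exp(-(t - last_event) / mix_tau)
  }
  bleach_rel <- noisy(bleach_rel)

  I_B <- cfg$background_level
  traces <- list(); roles <- character(); pre_means <- numeric()
  add <- function(name, role, I0, rel) {
    traces[[name]] <<- I_B + (I0 - I_B) * rel
    roles[name] <<- role
    pre_means[name] <<- I0
  }
  add("bleach", "bleach", 200, bleach_rel)
  for (g in seq_len(cfg$n_rois))
    add(paste0("granule_", g), "granule", 150 + 10 * stats::runif(1),
        granule_rel())
  for (cidx in seq_len(cfg$n_rois))
    add(paste0("cyto_", cidx), "cytoplasm", 80 + 5 * stats::runif(1),
        noisy(pool))

  # slow granule wander for the tracked ROI positions (um, 45 um field)
  positions <- lapply(seq_len(cfg$n_rois), function(g) {
    p0 <- stats::runif(2, 10, 35)
    steps <- matrix(stats::rnorm(2 * nt, 0, 0.05), ncol = 2)
    sweep(apply(steps, 2, cumsum), 2, -p0)
  })
  names(positions) <- paste0("granule_", seq_len(cfg$n_rois))

  bg_trace <- I_B * (1 + if (cfg$noise_sigma > 0)
    stats::rnorm(nt, 0, 0.02) else rep(0, nt))
  ref_trace <- 120 * (1 + if (cfg$noise_sigma > 0)
    stats::rnorm(nt, 0, 0.01) else rep(0, nt))

  roi_trace_set(t_grid = t_grid, traces = traces, roles = roles,
                prebleach_mean = pre_means, background_trace = bg_trace,
                reference_trace = ref_trace, positions = positions,
                frame_interval_s = dt, n_prebleach = n_pre)
}

pool_at <- function(t, cfg) if (t <= 0) 1 else exp(-t / cfg$cyto_tau_s)

#' Shape specification and polygon generator
#'
#' Generates simple (star-shaped, hence non-self-intersecting) polygons for
#' shape-factor oracles: circles, ellipses and rough "blobs" whose radius is
#' modulated by low-order harmonics.
#'
#' @param family `"circle"`, `"ellipse"` or `"blob"`.
#' @param radius Circle/blob radius (also the ellipse semi-major axis if
#'   `axes` is missing).
#' @param axes Length-2 semi-axes `(a, b)` for an ellipse.
#' @param roughness Relative amplitude of the blob's radial modulation;
#'   0 degenerates to a circle.
#' @param n_vertices Polygon resolution (>= 16).
#' @param seed Integer seed for the blob harmonics.
#' @return A `ShapeSpec` list.
#' @export
shape_spec <- function(family = c("circle", "ellipse", "blob"), radius = 10,
                       axes = c(radius, radius), roughness = 0.2,
                       n_vertices = 256L, seed = NULL) {
  family <- match.arg(family)
  stopifnot(n_vertices >= 16, radius > 0, all(axes > 0), roughness >= 0)
  structure(list(family = family, radius = radius, axes = axes,
                 roughness = roughness, n_vertices = as.integer(n_vertices),
                 seed = seed), class = "ShapeSpec")
}

#' @rdname shape_spec
#' @param spec A [shape_spec()].
#' @param pixel_size Raster resolution for the mask (same units as the
#'   radius); `NULL` skips rasterization.
#' @return `generate_shape()`: list with `polygon` (n x 2 matrix of x, y
#'   vertices, counter-clockwise, centered on the origin), `mask` (logical
#'   matrix or `NULL`) and `mask_origin` (x, y of the mask's pixel (1,1)
#'   center).
#' @export
generate_shape <- function(spec, pixel_size = NULL) {
  stopifnot(inherits(spec, "ShapeSpec"))
  .set_seed(spec$seed)
  theta <- 2 * pi * (seq_len(spec$n_vertices) - 1L) / spec$n_vertices
  radius_fun <- switch(spec$family,
    circle = function(th) rep(spec$radius, length(th)),
    ellipse = function(th) {
      a <- spec$axes[1]; b <- spec$axes[2]
      a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)
    },
    blob = {
      k <- 2:6
      amp <- stats::rnorm(length(k), 0, 1) / k
      amp <- amp / max(sum(abs(amp)), 1e-12)
      phase <- stats::runif(length(k), 0, 2 * pi)
      function(th) {
        mod <- rowSums(vapply(seq_along(k), function(i)
          amp[i] * cos(k[i] * th + phase[i]), numeric(length(th))))
        spec$radius * (1 + spec$roughness * mod)
      }
    })
  r <- radius_fun(theta)
  if (any(r <= 0))
    stop("blob parameters produce a self-intersecting (negative-radius) outline")
  poly <- cbind(x = r * cos(theta), y = r * sin(theta))
  mask <- NULL; origin <- NULL
  if (!is.null(pixel_size)) {
    half <- max(abs(poly)) + 2 * pixel_size
    coords <- seq(-half, half, by = pixel_size)
    xs <- matrix(rep(coords, each = length(coords)), length(coords))
    ys <- matrix(rep(coords, times = length(coords)), length(coords))
    th_px <- atan2(ys, xs) %% (2 * pi)
    # star-shaped: pixel inside iff its radius is below the outline radius
    mask <- sqrt(xs^2 + ys^2) <= radius_fun(th_px)
    origin <- c(coords[1], coords[1])
  }
  list(polygon = poly, mask = mask, mask_origin = origin)
}
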