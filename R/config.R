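#' Analysis configuration
#'
#' One declarative object holds every tunable of the four pipelines; the
#' defaults reproduce the acquisition and analysis settings of the study the
#' package models: 10 s DDM frame delay, noise-floor fit above
#' `q_noise = 12` per um, amplitude fit for lags beyond 100 s, q -> 0
#' extrapolation band 0.4-0.8 per um, 30 s FRAP broadening window, FLIP
#' stretched exponent `beta = 0.75` with 5 pre-bleach frames.
#'
#' @param ddm,frap,flip,morph Named lists overriding individual fields (see
#'   the defaults in the function body).
#' @return An object of class `AnalysisConfig`.
#' @export
analysis_config <- function(ddm = list(), frap = list(), flip = list(),
                            morph = list()) {
  cfg <- list(
    ddm = list(
      max_lag_frames = 120L,      # lags k * frame_interval, k = 1..max
      max_pairs_per_lag = 200L,   # temporal averaging census per lag
      q_bin_width = NULL,         # NULL: 2*pi/L, the natural grid spacing
      q_noise = 12,               # um^-1; noise-floor tail starts here
      min_lag_s = 100,            # amplitude fit uses lags beyond this
      gamma = NULL,               # amplitude-fit exponent: NULL = per bin
      q_lo = 0.4, q_hi = 0.8,     # um^-1 extrapolation band
      window = FALSE              # optional Hann apodization (off: plain FFT)
    ),
    frap = list(
      fit_window_s = 30,
      bin_width_px = 1,
      n_prebleach = 15L
    ),
    flip = list(
      beta = 0.75,
      n_prebleach = 5L,
      perturbations = c(-0.25, 0.25, NA)  # NA: random in [-25%, +25%]
    ),
    morph = list(
      threshold = NULL,           # NULL: Otsu on first frame, then frozen
      min_area_px = 9L,
      max_link_distance_um = 2
    )
  )
  cfg$ddm[names(ddm)] <- ddm
  cfg$frap[names(frap)] <- frap
  cfg$flip[names(flip)] <- flip
  cfg$morph[names(morph)] <- morph
  validate_config(structure(cfg, class = "AnalysisConfig"))
}

#' @rdname analysis_config
#' @param cfg An `AnalysisConfig`.
#' @export
validate_config <- function(cfg) {
  d <- cfg$ddm
  if (!(d$q_lo < d$q_hi && d$q_hi <= d$q_noise))
    stop("config requires q_lo < q_hi <= q_noise")
  if (d$max_lag_frames < 1 || d$max_pairs_per_lag < 1 || d$min_lag_s < 0)
    stop("DDM lag settings must be positive")
  f <- cfg$flip
  if (!(f$beta > 0 && f$beta <= 1)) stop("beta must lie in (0, 1]")
  if (cfg$frap$fit_window_s <= 0 || cfg$frap$bin_width_px <= 0)
    stop("FRAP windows must be positive")
  if (cfg$morph$min_area_px < 1) stop("min_area_px must be >= 1")
  cfg
}

#' Read / write a configuration as JSON
#'
#' CLI flags override individual config fields; the JSON file is the single
#' declarative source.
#'
#' @param path JSON file path.
#' @return [read_config()]: an `AnalysisConfig`; [write_config()]: `path`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw <- lapply(raw, function(sec) {
    if (is.list(sec) && "perturbations" %in% names(sec))
      sec$perturbations <- as.numeric(sec$perturbations)
    sec
  })
  analysis_config(ddm = raw$ddm %||% list(), frap = raw$frap %||% list(),
                  flip = raw$flip %||% list(), morph = raw$morph %||% list())
}

#' @rdname read_config
#' @param cfg An `AnalysisConfig`.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
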