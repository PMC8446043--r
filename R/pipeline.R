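#' Pipeline driver and command-line interface
#'
#' `run_pipeline()` dispatches the five subcommands (`simulate`, `ddm`,
#' `frap`, `flip`, `morph`), writes tidy result tables (one row per
#' q-bin/frame/ROI/granule) plus a JSON run manifest recording config, seed
#' and package version, and propagates any stage error prefixed with the
#' stage name.  `rnpdyn_main()` is the CLI entry point used by the
#' `inst/cli/rnpdyn` script: subcommand plus `--seed`, `--config`, `--out`
#' and per-command flags; CLI flags override config fields.
#'
#' @name pipeline
NULL

.write_manifest <- function(out_dir, command, config, seed, extra = list()) {
  manifest <- c(list(
    command = command,
    package = "rnpdyn",
    version = as.character(utils::packageVersion("rnpdyn")),
    seed = seed,
    config = unclass(config),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")), extra)
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("[", name, "] ", conditionMessage(e), call. = FALSE))
}

#' Run an analysis pipeline end to end
#'
#' @param command One of `"simulate"`, `"ddm"`, `"frap"`, `"flip"`,
#'   `"morph"`.
#' @param out_dir Output directory (created if missing).
#' @param config An [analysis_config()].
#' @param input Path to the input TIFF stack (analysis commands).
#' @param rois Path to an ROI CSV (`flip`) or `NULL`.
#' @param pixel_size_um,frame_interval_s Calibration of the input stack.
#' @param t0_index First post-bleach frame (`frap`, `flip`).
#' @param seed Integer seed (`simulate`, robustness sweep).
#' @param simulate_what For `simulate`: `"brownian"`, `"frap"` or `"flip"`.
#' @param sim_args Named list of overrides passed to the simulator config.
#' @return Invisibly, the result object of the dispatched pipeline.
#' @export
run_pipeline <- function(command = c("simulate", "ddm", "frap", "flip", "morph"),
                         out_dir, config = analysis_config(), input = NULL,
                         rois = NULL, pixel_size_um = NULL,
                         frame_interval_s = NULL, t0_index = 1L, seed = NULL,
                         simulate_what = "brownian", sim_args = list()) {
  command <- match.arg(command)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  need_input <- function() {
    if (is.null(input)) stop("input TIFF path required")
    .stage(command, read_image_sequence(input, pixel_size_um,
                                        frame_interval_s, t0_index))
  }
  res <- switch(command,
    simulate = .stage("simulate", {
      sim_args$seed <- sim_args$seed %||% seed
      switch(simulate_what,
        brownian = {
          mov <- simulate_brownian_movie(do.call(brownian_movie_config, sim_args))
          write_image_sequence(mov$sequence, file.path(out_dir, "movie.tif"))
          utils::write.csv(mov$trajectories,
                           file.path(out_dir, "trajectories.csv"),
                           row.names = FALSE)
          mov
        },
        frap = {
          sq <- simulate_frap_sequence(do.call(frap_sim_config, sim_args))
          write_image_sequence(sq, file.path(out_dir, "frap.tif"))
          sq
        },
        flip = {
          tr <- simulate_flip_traces(do.call(flip_sim_config, sim_args))
          df <- data.frame(t = tr$t_grid)
          for (nm in names(tr$traces)) df[[nm]] <- tr$traces[[nm]]
          df$background <- tr$background_trace
          df$reference <- tr$reference_trace
          utils::write.csv(df, file.path(out_dir, "flip_traces.csv"),
                           row.names = FALSE)
          tr
        },
        stop("unknown simulation target: ", simulate_what))
    }),
    ddm = {
      sq <- need_input()
      r <- .stage("ddm", ddm_pipeline(sq, config))
      sf <- r$structure_function
      utils::write.csv(
        data.frame(q = rep(sf$q_grid, times = length(sf$lag_grid)),
                   lag = rep(sf$lag_grid, each = length(sf$q_grid)),
                   value = as.vector(sf$values),
                   n_pairs = rep(sf$n_pairs, each = length(sf$q_grid))),
        file.path(out_dir, "structure_function.csv"), row.names = FALSE)
      utils::write.csv(
        data.frame(q = rep(r$isf$q_grid, times = length(r$isf$lag_grid)),
                   lag = rep(r$isf$lag_grid, each = length(r$isf$q_grid)),
                   isf = as.vector(r$isf$values)),
        file.path(out_dir, "isf.csv"), row.names = FALSE)
      utils::write.csv(
        data.frame(lag = r$msd$lag_grid, msd0 = r$msd$msd0,
                   se = r$msd$msd0_se),
        file.path(out_dir, "msd.csv"), row.names = FALSE)
      jsonlite::write_json(
        list(B = r$calibration$B, D0 = r$msd$D0, D0_se = r$msd$D0_se,
             q_band = r$msd$q_band, config = unclass(config)$ddm),
        file.path(out_dir, "ddm_summary.json"), auto_unbox = TRUE,
        digits = NA, null = "null", na = "null", pretty = TRUE)
      r
    },
    frap = {
      sq <- need_input()
      r <- .stage("frap", frap_pipeline(sq, config))
      utils::write.csv(
        data.frame(r = rep(r$profiles$r_grid, times = length(r$profiles$t_grid)),
                   t = rep(r$profiles$t_grid, each = length(r$profiles$r_grid)),
                   depth = as.vector(r$profiles$profiles)),
        file.path(out_dir, "frap_profiles.csv"), row.names = FALSE)
      utils::write.csv(r$gaussian_fits$fits,
                       file.path(out_dir, "frap_gaussian_fits.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        list(D = r$result$D, D_se = r$result$D_se,
             sigma0_sq = r$result$sigma0_sq,
             window_s = r$result$fit_window_s),
        file.path(out_dir, "frap_summary.json"), auto_unbox = TRUE,
        digits = NA, pretty = TRUE)
      r
    },
    flip = {
      sq <- need_input()
      if (is.null(rois)) stop("[flip] ROI CSV required")
      roi_list <- .stage("flip", read_rois(rois, dim(sq$frames)[2:3]))
      r <- .stage("flip", flip_pipeline(sq, roi_list, config))
      tr <- r$traces
      long <- do.call(rbind, lapply(names(tr$traces), function(nm)
        data.frame(roi = nm, t = tr$t_grid, raw = tr$traces[[nm]],
                   normalized = (tr$traces[[nm]] - tr$I_B) /
                     (tr$prebleach_mean[[nm]] - tr$I_B))))
      utils::write.csv(long, file.path(out_dir, "flip_traces.csv"),
                       row.names = FALSE)
      utils::write.csv(r$result$fits, file.path(out_dir, "flip_fits.csv"),
                       row.names = FALSE)
      utils::write.csv(r$robustness$table,
                       file.path(out_dir, "flip_robustness.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        list(beta = r$result$beta, I_B = r$result$I_B,
             n_rois = nrow(r$result$fits)),
        file.path(out_dir, "flip_summary.json"), auto_unbox = TRUE,
        digits = NA, pretty = TRUE)
      r
    },
    morph = {
      sq <- need_input()
      m <- config$morph
      gr <- .stage("morph", segment_granules(sq, threshold = m$threshold,
                                             min_area_px = m$min_area_px))
      utils::write.csv(gr, file.path(out_dir, "granules.csv"),
                       row.names = FALSE)
      ts <- .stage("morph", link_tracks(gr, m$max_link_distance_um,
                                        sq$frame_interval_s))
      utils::write.csv(ts$tracks, file.path(out_dir, "tracks.csv"),
                       row.names = FALSE)
      list(granules = gr, tracks = ts)
    })
  .write_manifest(out_dir, command, config, seed)
  invisible(res)
}

#' Command-line entry point
#'
#' Parses `argv` (default: the process command line) as
#' `rnpdyn <command> [--seed N] [--config FILE] [--out DIR] [--input TIFF]
#' [--rois CSV] [--pixel-size UM] [--frame-interval S] [--t0 INDEX]
#' [--what brownian|frap|flip]` and dispatches [run_pipeline()].
#'
#' @param argv Character vector of arguments (excluding the program name).
#' @return The [run_pipeline()] result, invisibly.
#' @export
rnpdyn_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (!length(argv)) stop("usage: rnpdyn <simulate|ddm|frap|flip|morph> [options]")
  command <- argv[1]
  opts <- list(out = "rnpdyn_out", seed = NULL, config = NULL, input = NULL,
               rois = NULL, pixel_size = NULL, frame_interval = NULL,
               t0 = 1L, what = "brownian")
  i <- 2L
  while (i <= length(argv)) {
    key <- sub("^--", "", argv[i])
    if (!(i + 1L <= length(argv))) stop("missing value for --", key)
    val <- argv[i + 1L]
    switch(key,
      seed = { opts$seed <- as.integer(val) },
      config = { opts$config <- val },
      out = { opts$out <- val },
      input = { opts$input <- val },
      rois = { opts$rois <- val },
      `pixel-size` = { opts$pixel_size <- as.numeric(val) },
      `frame-interval` = { opts$frame_interval <- as.numeric(val) },
      t0 = { opts$t0 <- as.integer(val) },
      what = { opts$what <- val },
      stop("unknown option --", key))
    i <- i + 2L
  }
  cfg <- if (!is.null(opts$config)) read_config(opts$config)
         else analysis_config()
  run_pipeline(command, out_dir = opts$out, config = cfg,
               input = opts$input, rois = opts$rois,
               pixel_size_um = opts$pixel_size,
               frame_interval_s = opts$frame_interval,
               t0_index = opts$t0, seed = opts$seed,
               simulate_what = opts$what)
}
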