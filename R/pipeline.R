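#' Run the simulate/diffuse/force/register pipeline
#'
#' Executes the requested stages in order on a shared state and returns a
#' report of per-stage parameters, track counts through every filter, and
#' summary statistics. All configuration is validated (including filter
#' preset names) before any stage runs, and the seed is recorded so every
#' number in the report is reproducible from the config alone.
#'
#' Config fields:
#' * `stages`: character vector among `"simulate"`, `"diffuse"`, `"force"`,
#'   `"register"`.
#' * `seed`: integer, required.
#' * `temperature_K`: optional, default 298.
#' * `simulate`: arguments for [sim_config()] (minus `seed`) plus optional
#'   `needle = list(tip, F0, d0, p)`.
#' * `tracks_csv`: path to input tracks when not simulating.
#' * `diffuse`: optional list with `preset` ("spt" or "force") or explicit
#'   `min_length`/`D_min`/`min_displacement`, and `n_fit_lags`.
#' * `force`: optional list with `tip`, `window_len`, `step`, `preset`
#'   (filter applied before force estimation, default "force").
#' * `register`: optional list with `src`, `dst` (n x 2 matrices or paths
#'   to 2-column CSVs).
#' * `output_dir`: optional; when set, stage outputs (tracks, per-track D,
#'   window forces) are written there as CSV and the report as JSON.
#'
#' @param config Named list or path to a YAML/JSON config file.
#' @return The report, an S3 list of class `pipeline_report`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(is.list(config))
  if (is.null(config$seed)) stop("config must set an integer seed")
  stages <- config$stages %||% c("simulate", "diffuse")
  known <- c("simulate", "diffuse", "force", "register")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  resolve_filter <- function(cfg, default_preset) {
    preset <- cfg$preset %||% (if (is.null(cfg$min_length)) default_preset)
    if (!is.null(preset)) {
      if (!preset %in% c("spt", "force", "none")) {
        stop("unknown filter preset: ", preset)
      }
      switch(preset, spt = filter_spec_spt(), force = filter_spec_force(),
             none = NULL)
    } else {
      filter_spec(cfg$min_length, cfg$D_min,
                  cfg$min_displacement %||% NA_real_)
    }
  }
  # validate everything (preset names included) before any stage runs
  if ("diffuse" %in% stages) {
    diffuse_filter <- resolve_filter(config$diffuse %||% list(), "spt")
  }
  if ("force" %in% stages) {
    fcfg <- config$force %||% list()
    if (is.null(fcfg$tip) && is.null((config$simulate %||% list())$needle)) {
      stop("force stage needs a needle tip (config$force$tip)")
    }
    force_filter <- resolve_filter(fcfg, "force")
  }
  phys <- physical_params(config$temperature_K %||% 298)
  report <- list(seed = config$seed,
                 package = as.character(utils::packageVersion("fmnptrack")),
                 temperature_K = phys$T, stages = list())
  out_dir <- config$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  ts <- NULL
  Dtab <- NULL
  needle <- NULL
  scfg <- config$simulate %||% list()
  if (!is.null(scfg$needle)) {
    needle <- needle_geometry(unlist(scfg$needle$tip), scfg$needle$F0,
                              scfg$needle$d0, scfg$needle$p %||% 1)
  }
  for (stage in stages) {
    if (stage == "simulate") {
      args <- scfg[setdiff(names(scfg), "needle")]
      args$seed <- config$seed
      cfg <- do.call(sim_config, args)
      ts <- simulate_tracks(cfg, needle, phys)
      report$stages$simulate <- list(
        params = cfg[c("D_true", "dt", "n_frames", "n_tracks", "sigma_loc")],
        needle = if (is.null(needle)) NULL else unclass(needle),
        n_tracks = n_tracks(ts))
      if (!is.null(out_dir)) {
        write_tracks(ts, file.path(out_dir, "tracks.csv"))
      }
    } else if (stage == "diffuse") {
      if (is.null(ts)) ts <- read_tracks(config$tracks_csv)
      n_lags <- (config$diffuse %||% list())$n_fit_lags %||% 4
      Dtab <- track_diffusion(ts, n_fit_lags = n_lags)
      n_in <- n_tracks(ts)
      if (!is.null(diffuse_filter)) {
        ts <- apply_filters(ts, diffuse_filter,
                            setNames(Dtab$D, Dtab$track_id))
        Dtab <- Dtab[Dtab$track_id %in% unique(ts$tracks$track_id), ]
      }
      report$stages$diffuse <- list(
        n_fit_lags = n_lags,
        filter = if (is.null(diffuse_filter)) NULL else unclass(diffuse_filter),
        n_tracks_in = n_in, n_tracks_out = n_tracks(ts),
        D_summary = summarize_D(Dtab$D))
      if (!is.null(out_dir)) {
        utils::write.csv(Dtab, file.path(out_dir, "diffusion.csv"),
                         row.names = FALSE)
      }
    } else if (stage == "force") {
      if (is.null(ts)) ts <- read_tracks(config$tracks_csv)
      fcfg <- config$force %||% list()
      tip <- if (!is.null(fcfg$tip)) unlist(fcfg$tip) else needle$tip
      n_in <- n_tracks(ts)
      fts <- ts
      if (!is.null(force_filter)) {
        if (is.null(Dtab)) Dtab <- track_diffusion(ts)
        fts <- apply_filters(ts, force_filter,
                             setNames(Dtab$D, Dtab$track_id))
      }
      est <- trackset_forces(fts, tip,
                             window_len = fcfg$window_len %||% 50,
                             step = fcfg$step %||% 25, phys = phys)
      ptf <- per_track_forces(est)
      report$stages$force <- list(
        tip = tip, window_len = fcfg$window_len %||% 50,
        step = fcfg$step %||% 25,
        filter = if (is.null(force_filter)) NULL else unclass(force_filter),
        n_tracks_in = n_in, n_tracks_out = n_tracks(fts),
        ensemble = ensemble_force_stats(ptf))
      if (!is.null(out_dir)) {
        utils::write.csv(est, file.path(out_dir, "window_forces.csv"),
                         row.names = FALSE)
        utils::write.csv(data.frame(track_id = names(ptf), F_x = ptf),
                         file.path(out_dir, "track_forces.csv"),
                         row.names = FALSE)
      }
    } else if (stage == "register") {
      rcfg <- config$register
      if (is.null(rcfg$src) || is.null(rcfg$dst)) {
        stop("register stage needs src and dst point sets")
      }
      as_pts <- function(p) {
        if (is.character(p)) as.matrix(read.csv(p)) else as.matrix(p)
      }
      src <- as_pts(rcfg$src)
      dst <- as_pts(rcfg$dst)
      tf <- fit_similarity(src, dst)
      report$stages$register <- list(
        n_fiducials = nrow(src), transform = unclass(tf),
        rms_residual_um = registration_residual(tf, src, dst))
      if (!is.null(ts) && !is.null(out_dir)) {
        reg <- ts
        xy <- apply_transform(tf, cbind(ts$tracks$x_um, ts$tracks$y_um))
        reg$tracks$x_um <- xy[, 1]
        reg$tracks$y_um <- xy[, 2]
        write_tracks(reg, file.path(out_dir, "tracks_registered.csv"))
      }
    }
  }
  class(report) <- "pipeline_report"
  if (!is.null(out_dir)) {
    jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> seed %d, stages: %s\n", x$seed,
              paste(names(x$stages), collapse = ", ")))
  invisible(x)
}
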