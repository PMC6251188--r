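# End-to-end orchestration of the analysis chain and a small CLI.

#' Run the full analysis pipeline on a raw movie
#'
#' Conditioning (spatial bin, DF, zero-phase band-pass, drift removal,
#' normalization), phase computation, singularity detection/tracking with
#' rotor classification, isophase wavefront extraction with new-wavefront
#' classification, density maps, preferential sites, and the mechanism
#' label.
#'
#' @param movie a raw [voltage_movie()].
#' @param config a [run_config()].
#' @param condition logical; set `FALSE` if `movie` is already conditioned
#'   (a DF map is still computed for the phase window).
#' @return list of class `fibwave_run` with elements `conditioned`, `df`,
#'   `phase`, `detections`, `tracks`, `ps_maps`, `events`, `nwf_map`,
#'   `sites`, `report`, `mechanism`, `config`.
#' @export
run_pipeline <- function(movie, config = run_config(), condition = TRUE) {
  if (condition) {
    cond <- condition_movie(movie, config)
    m <- cond$movie; df <- cond$df
  } else {
    m <- movie
    band <- config$df_band_hz
    band[1] <- max(band[1], 2 / (dim(movie$data)[1] * movie$dt / 1000))
    df <- dominant_frequency(movie, band = band)
  }
  ph <- compute_phase(m, df$mean_df, config)
  det <- detect_ps_movie(ph, config$ps_tol_rad)
  tracks <- track_ps(det, config$track_link_px, config$track_gap_frames)
  tracks <- lapply(tracks, count_rotations, phase = ph, df_map = df)
  d <- dim(ph$phase)
  ps_maps <- ps_density_maps(tracks, dims = d[2:3], dt = ph$dt,
                             pitch = ph$pitch, n_frames = d[1])
  wu <- round(0.5 * config$extrema_window_frac * (1000 / df$mean_df) / ph$dt)
  events <- detect_wavefront_events(ph, config, warmup_frames = wu)
  nwf_map <- nwf_density_map(events)
  sites <- find_nwf_sites(nwf_map, events, mask = ph$mask)
  report <- activity_series(ph, tracks, events)
  mech <- classify_mechanism(report, events, sites)
  structure(list(conditioned = m, df = df, phase = ph, detections = det,
                 tracks = tracks, ps_maps = ps_maps, events = events,
                 nwf_map = nwf_map, sites = sites, report = report,
                 mechanism = mech, config = config),
            class = "fibwave_run")
}

#' @export
print.fibwave_run <- function(x, ...) {
  nwf <- sum(x$events$wf_class != "propagated")
  cat(sprintf("<fibwave_run> mean DF %.1f Hz | %d tracks (%d rotors) | %d NWF events | %d sites | mechanism: %s\n",
              x$df$mean_df, length(x$tracks),
              sum(vapply(x$tracks, function(tk) isTRUE(tk$is_rotor), logical(1))),
              nwf, length(x$sites), x$mechanism$label))
  invisible(x)
}

#' Command-line interface
#'
#' Subcommands: `simulate --regime {spiral,focal,two-layer} --seed N --out
#' dir` writes a movie (rds container) plus ground-truth JSON; `run
#' <movie> --out dir` executes the pipeline and writes the product tables,
#' maps and a JSON run manifest via [write_products()].
#'
#' @param args character vector (defaults to `commandArgs(TRUE)`).
#' @return exit status, invisibly.
#' @export
fibwave_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: fibwave {simulate|run} [options]\n  simulate --regime spiral|focal|two-layer --seed N --out DIR\n  run MOVIE.rds --out DIR [--seed N]"
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[[1L]]; rest <- args[-1L]
  opt <- function(name, default = NULL) {
    i <- which(rest == paste0("--", name))
    if (length(i) && i < length(rest)) rest[[i + 1L]] else default
  }
  if (cmd == "simulate") {
    regime <- opt("regime", "spiral")
    seed <- as.integer(opt("seed", "1"))
    outdir <- opt("out", ".")
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    g <- switch(regime,
                spiral = ,
                focal = synthesize_regime(if (regime == "spiral") "spiral" else "focal",
                                          seed = seed),
                `two-layer` = {
                  tl <- two_layer_simulate(two_layer_spec(seed = seed))
                  list(movie = tl$epi, truth = tl$truth, regime = "two_layer")
                },
                stop("unknown regime: ", regime, call. = FALSE))
    write_movie(g$movie, file.path(outdir, "movie.rds"))
    jsonlite::write_json(g$truth[c("regime", "params")],
                         file.path(outdir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    utils::write.csv(g$truth$focal_events,
                     file.path(outdir, "truth_focal_events.csv"),
                     row.names = FALSE)
    message("wrote ", outdir)
    return(invisible(0L))
  }
  if (cmd == "run") {
    if (!length(rest)) stop(usage, call. = FALSE)
    movie <- read_movie(rest[[1L]])
    outdir <- opt("out", "fibwave_out")
    cfg <- run_config(seed = as.integer(opt("seed", "1")))
    res <- run_pipeline(movie, cfg)
    write_products(res$tracks, res$events,
                   c(unname(res$ps_maps), list(res$nwf_map)),
                   outdir, config = cfg, dt = movie$dt)
    jsonlite::write_json(list(mean_df_hz = res$df$mean_df,
                              mechanism = res$mechanism,
                              n_tracks = length(res$tracks),
                              n_nwf_events = sum(res$events$wf_class != "propagated"),
                              n_sites = length(res$sites)),
                         file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    message("wrote ", outdir)
    return(invisible(0L))
  }
  message(usage)
  invisible(1L)
}
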