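#' Gridded optical-mapping voltage movie
#'
#' Core data carrier for the pipeline: a `T x H x W` array of voltage (or
#' fluorescence) samples with a valid-tissue mask and acquisition geometry.
#' All analyses restrict themselves to mask-true pixels; masked-out samples
#' are never read.
#'
#' @param data numeric `T x H x W` array, frames first.
#' @param dt frame interval in ms (default 1).
#' @param pitch pixel edge length in mm (default 0.44).
#' @param mask logical `H x W` valid-tissue map; defaults to all-true.
#' @param meta free-form provenance list.
#' @return an object of class `voltage_movie`.
#' @export
voltage_movie <- function(data, dt = 1, pitch = 0.44, mask = NULL, meta = list()) {
  d <- dim(data)
  if (length(d) != 3L) stop("`data` must be a T x H x W array", call. = FALSE)
  if (d[1] < 2L || d[2] < 3L || d[3] < 3L)
    stop("movie too small: need T >= 2, H >= 3, W >= 3", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("`dt` must be a positive scalar (ms)", call. = FALSE)
  if (!is.numeric(pitch) || length(pitch) != 1L || pitch <= 0)
    stop("`pitch` must be a positive scalar (mm)", call. = FALSE)
  if (is.null(mask)) mask <- matrix(TRUE, d[2], d[3])
  mask <- matrix(as.logical(mask), d[2], d[3])
  if (anyNA(mask)) stop("`mask` must not contain NA", call. = FALSE)
  structure(list(data = data, dt = dt, pitch = pitch, mask = mask, meta = meta),
            class = "voltage_movie")
}

#' @export
print.voltage_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voltage_movie> %d frames x %d x %d px | dt = %g ms | pitch = %g mm | %d/%d px in mask\n",
              d[1], d[2], d[3], x$dt, x$pitch, sum(x$mask), d[2] * d[3]))
  invisible(x)
}

#' @export
dim.voltage_movie <- function(x) dim(x$data)

#' Instantaneous-phase movie
#'
#' Same geometry as [voltage_movie()] but carrying phase angles strictly in
#' `(-pi, pi]`.
#'
#' @param phase numeric `T x H x W` array of radians in `(-pi, pi]`.
#' @inheritParams voltage_movie
#' @return an object of class `phase_movie`.
#' @export
phase_movie <- function(phase, dt = 1, pitch = 0.44, mask = NULL, meta = list()) {
  d <- dim(phase)
  if (length(d) != 3L) stop("`phase` must be a T x H x W array", call. = FALSE)
  if (is.null(mask)) mask <- matrix(TRUE, d[2], d[3])
  mask <- matrix(as.logical(mask), d[2], d[3])
  v <- matrix(phase, nrow = d[1])[, which(mask), drop = FALSE]
  rng <- suppressWarnings(range(v[is.finite(v)]))
  if (all(is.finite(rng)) && (rng[1] <= -pi - 1e-9 || rng[2] > pi + 1e-9))
    stop("phase values must lie in (-pi, pi]", call. = FALSE)
  structure(list(phase = phase, dt = dt, pitch = pitch, mask = mask, meta = meta),
            class = "phase_movie")
}

#' @export
print.phase_movie <- function(x, ...) {
  d <- dim(x$phase)
  cat(sprintf("<phase_movie> %d frames x %d x %d px | dt = %g ms\n", d[1], d[2], d[3], x$dt))
  invisible(x)
}

#' Pipeline run configuration
#'
#' Bundles every tunable of the analysis chain. The defaults reproduce the
#' published parameter set: 9 x 9 spatial bin, 2 Hz lower band edge, upper
#' edge at 125 % of the dominant frequency, extrema window at 90 % of the
#' mean cycle length, 15 % median-amplitude pair rejection, 3.0 rad
#' topological-charge tolerance, isophase value -pi/2 with band width 0.5.
#'
#' @param spatial_bin odd convolution bin (px).
#' @param band_low_hz lower band-pass edge (Hz).
#' @param band_high_frac upper band-pass edge as a multiple of the mean DF.
#' @param extrema_window_frac sliding-window length as a fraction of the
#'   mean cycle length.
#' @param amp_reject_frac extrema-pair rejection threshold as a fraction of
#'   the median pair amplitude.
#' @param ps_tol_rad tolerance (rad) around +-2*pi for candidate singularities.
#' @param iso_theta isophase value (rad) defining active pixels.
#' @param iso_band isophase band width (rad).
#' @param nwf_radius_px neighbourhood radius (px) for new-wavefront checks.
#' @param min_component_px minimum wavefront component size (px).
#' @param track_link_px maximum frame-to-frame link distance (px).
#' @param track_gap_frames frames a track survives unmatched.
#' @param df_band_hz dominant-frequency search band (Hz).
#' @param seed integer seed recorded in run manifests.
#' @return an object of class `run_config` (a named list).
#' @export
run_config <- function(spatial_bin = 9L,
                       band_low_hz = 2,
                       band_high_frac = 1.25,
                       extrema_window_frac = 0.9,
                       amp_reject_frac = 0.15,
                       ps_tol_rad = 3.0,
                       iso_theta = -pi / 2,
                       iso_band = 0.5,
                       nwf_radius_px = 3L,
                       min_component_px = 1L,
                       track_link_px = 5,
                       track_gap_frames = 0L,
                       df_band_hz = c(2, 50),
                       seed = 1L) {
  spatial_bin <- as.integer(spatial_bin)
  if (spatial_bin < 1L || spatial_bin %% 2L == 0L)
    stop("`spatial_bin` must be odd and >= 1", call. = FALSE)
  if (!(iso_band > 0 && iso_band < pi))
    stop("`iso_band` must be in (0, pi)", call. = FALSE)
  if (!(ps_tol_rad > 0 && ps_tol_rad < 2 * pi))
    stop("`ps_tol_rad` must be in (0, 2*pi)", call. = FALSE)
  structure(list(spatial_bin = spatial_bin, band_low_hz = band_low_hz,
                 band_high_frac = band_high_frac,
                 extrema_window_frac = extrema_window_frac,
                 amp_reject_frac = amp_reject_frac, ps_tol_rad = ps_tol_rad,
                 iso_theta = iso_theta, iso_band = iso_band,
                 nwf_radius_px = as.integer(nwf_radius_px),
                 min_component_px = as.integer(min_component_px),
                 track_link_px = track_link_px,
                 track_gap_frames = as.integer(track_gap_frames),
                 df_band_hz = df_band_hz, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a voltage movie from disk
#'
#' Two container formats are supported. `"rds"` is the native container (a
#' plain list serialized with [saveRDS()]). `"txt"` is a documented
#' plain-text container: line 1 is a JSON header with fields `T`, `H`, `W`,
#' `dt`, `pitch` and `version`; line 2 is the mask as `H*W` 0/1 integers in
#' row-major order; the following `T` lines each hold one frame as `H*W`
#' whitespace-separated samples in row-major order. Multi-page TIFF and HDF5
#' are not readable in this build (no offline reader); requesting them
#' raises an informative error.
#'
#' @param path file path.
#' @param fmt `"rds"` or `"txt"`; guessed from the extension when `NULL`.
#' @param dt,pitch optional overrides when the container lacks them.
#' @return a [voltage_movie()].
#' @export
read_movie <- function(path, fmt = NULL, dt = NULL, pitch = NULL) {
  if (!file.exists(path)) stop("cannot read movie: no such file: ", path, call. = FALSE)
  if (is.null(fmt)) {
    fmt <- switch(tolower(tools::file_ext(path)), rds = "rds", txt = "txt",
                  fwv = "txt", "rds")
  }
  if (fmt %in% c("tiff", "tif", "hdf5", "h5"))
    stop("format '", fmt, "' is not supported in this build; ",
         "convert to the documented text container or rds", call. = FALSE)
  if (fmt == "rds") {
    obj <- readRDS(path)
    if (!is.list(obj) || is.null(obj$data))
      stop("format error: rds container lacks `data`", call. = FALSE)
    dt2 <- dt %||% obj$dt
    pitch2 <- pitch %||% obj$pitch
    if (is.null(dt2)) stop("format error: no `dt` in container and no override", call. = FALSE)
    if (is.null(pitch2)) stop("format error: no `pitch` in container and no override", call. = FALSE)
    return(voltage_movie(obj$data, dt = dt2, pitch = pitch2, mask = obj$mask,
                         meta = obj$meta %||% list()))
  }
  lines <- readLines(path)
  if (length(lines) < 3L) stop("format error: truncated text container", call. = FALSE)
  hdr <- tryCatch(jsonlite::fromJSON(lines[[1L]]),
                  error = function(e) stop("format error: bad JSON header", call. = FALSE))
  Tn <- as.integer(hdr$T); H <- as.integer(hdr$H); W <- as.integer(hdr$W)
  if (anyNA(c(Tn, H, W))) stop("format error: header lacks T/H/W", call. = FALSE)
  dt2 <- dt %||% hdr$dt; pitch2 <- pitch %||% hdr$pitch
  if (is.null(dt2) || length(dt2) == 0L || is.na(dt2))
    stop("format error: no `dt` in header and no override", call. = FALSE)
  if (is.null(pitch2) || length(pitch2) == 0L || is.na(pitch2)) pitch2 <- 0.44
  if (length(lines) < 2L + Tn) stop("format error: expected ", Tn, " frame lines", call. = FALSE)
  mask_v <- as.integer(strsplit(trimws(lines[[2L]]), "\\s+")[[1L]])
  if (length(mask_v) != H * W) stop("format error: mask length mismatch", call. = FALSE)
  mask <- matrix(as.logical(mask_v), H, W, byrow = TRUE)
  dat <- array(NA_real_, c(Tn, H, W))
  for (t in seq_len(Tn)) {
    v <- as.numeric(strsplit(trimws(lines[[2L + t]]), "\\s+")[[1L]])
    if (length(v) != H * W) stop("format error: frame ", t, " length mismatch", call. = FALSE)
    dat[t, , ] <- matrix(v, H, W, byrow = TRUE)
  }
  voltage_movie(dat, dt = dt2, pitch = pitch2, mask = mask,
                meta = as.list(hdr[setdiff(names(hdr), c("T", "H", "W", "dt", "pitch"))]))
}

#' Write a voltage movie to disk
#'
#' @param movie a [voltage_movie()].
#' @param path destination path.
#' @param fmt `"rds"` (native) or `"txt"` (documented text container, see
#'   [read_movie()]).
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path, fmt = c("rds", "txt")) {
  fmt <- match.arg(fmt)
  stopifnot(inherits(movie, "voltage_movie"))
  if (fmt == "rds") {
    saveRDS(list(data = movie$data, dt = movie$dt, pitch = movie$pitch,
                 mask = movie$mask, meta = movie$meta, version = "fibwave-movie-1"),
            path)
    return(invisible(path))
  }
  d <- dim(movie$data)
  hdr <- jsonlite::toJSON(c(list(T = d[1], H = d[2], W = d[3], dt = movie$dt,
                                 pitch = movie$pitch, version = "fibwave-movie-1"),
                            movie$meta), auto_unbox = TRUE, digits = NA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(hdr), con)
  writeLines(paste(as.integer(t(movie$mask)), collapse = " "), con)
  for (t in seq_len(d[1])) {
    writeLines(paste(format(t(movie$data[t, , ]), digits = 17, trim = TRUE,
                            scientific = TRUE), collapse = " "), con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write derived products as delimited tables and gridded arrays
#'
#' Tables use 0-based `(frame, row, col)` coordinates and `time_ms =
#' frame * dt`, the package's export convention. Density maps are written as
#' plain whitespace `H x W` grids with a JSON metadata sidecar; a JSON run
#' manifest records the configuration and schema version.
#'
#' @param tracks list of `ps_track` objects (may be empty).
#' @param events wavefront event table (data.frame, may have 0 rows).
#' @param maps list of `density_map` objects.
#' @param path output directory (created if needed).
#' @param config optional [run_config()] recorded in the manifest.
#' @param dt frame interval in ms used for `time_ms` columns.
#' @return `path`, invisibly.
#' @export
write_products <- function(tracks = list(), events = NULL, maps = list(),
                           path, config = NULL, dt = 1) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  tr <- tracks_to_table(tracks, dt = dt)
  utils::write.csv(tr, file.path(path, "tracks.csv"), row.names = FALSE)
  ev <- if (is.null(events) || nrow(events) == 0L) {
    data.frame(frame = integer(), time_ms = numeric(), component_id = integer(),
               wf_class = character(), centroid_row = numeric(),
               centroid_col = numeric(), n_pixels = integer())
  } else {
    data.frame(frame = events$frame - 1L, time_ms = (events$frame - 1L) * dt,
               component_id = events$component_id, wf_class = events$wf_class,
               centroid_row = events$centroid_row - 1,
               centroid_col = events$centroid_col - 1,
               n_pixels = events$n_pixels)
  }
  utils::write.csv(ev, file.path(path, "events.csv"), row.names = FALSE)
  for (m in maps) {
    stopifnot(inherits(m, "density_map"))
    f <- file.path(path, paste0("map_", m$kind, ".txt"))
    utils::write.table(m$counts, f, row.names = FALSE, col.names = FALSE)
    jsonlite::write_json(list(kind = m$kind, duration_ms = m$duration_ms,
                              area_cm2 = m$area_cm2, schema = "fibwave-map-1"),
                         file.path(path, paste0("map_", m$kind, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  manifest <- list(schema = "fibwave-products-1", dt_ms = dt,
                   n_tracks = length(tracks),
                   n_events = if (is.null(events)) 0L else nrow(events),
                   maps = vapply(maps, function(m) m$kind, character(1)),
                   config = if (is.null(config)) NULL else unclass(config))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read back a density map written by [write_products()]
#'
#' @param path the products directory.
#' @param kind map kind (`"trajectory"`, `"initiation"`, `"annihilation"`,
#'   `"nwf_origin"`).
#' @return a `density_map`.
#' @export
read_density_map <- function(path, kind) {
  counts <- as.matrix(utils::read.table(file.path(path, paste0("map_", kind, ".txt"))))
  dimnames(counts) <- NULL
  meta <- jsonlite::fromJSON(file.path(path, paste0("map_", kind, ".json")))
  density_map(counts, kind = meta$kind, duration_ms = meta$duration_ms,
              area_cm2 = meta$area_cm2)
}

# 0-based track table used by exports.
tracks_to_table <- function(tracks, dt = 1) {
  if (length(tracks) == 0L) {
    return(data.frame(track_id = integer(), frame = integer(), time_ms = numeric(),
                      row = numeric(), col = numeric(), chirality = integer(),
                      rotations = numeric(), is_rotor = logical()))
  }
  do.call(rbind, lapply(seq_along(tracks), function(i) {
    tk <- tracks[[i]]
    data.frame(track_id = i, frame = tk$points$frame - 1L,
               time_ms = (tk$points$frame - 1L) * dt,
               row = tk$points$row - 1, col = tk$points$col - 1,
               chirality = tk$chirality,
               rotations = tk$rotations %||% NA_real_,
               is_rotor = tk$is_rotor %||% NA)
  }))
}
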