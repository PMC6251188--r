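# Phase-singularity detection by topological charge, nearest-neighbour
# tracking, rotor classification by cumulative rotations, and density maps.
#
# Charge orientation convention: the 8-neighbour ring is traversed in the
# order (r,c+1) -> (r+1,c+1) -> (r+1,c) -> (r+1,c-1) -> (r,c-1) ->
# (r-1,c-1) -> (r-1,c) -> (r-1,c+1) -> back. Under this orientation the
# vortex field theta = atan2(row - r0, col - c0) carries charge +2*pi and
# its mirror image -2*pi.

ps_ring_offsets <- function() {
  list(c(0, 1), c(1, 1), c(1, 0), c(1, -1),
       c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1))
}

#' Topological charge map of a phase frame
#'
#' For each interior pixel, the sum of phase differences - each wrapped to
#' `(-pi, pi]` - taken around the closed 8-neighbour ring centred on the
#' pixel. Boundary pixels, and pixels whose ring touches a masked-out
#' pixel, are 0.
#'
#' @param phase_frame `H x W` matrix of phase in `(-pi, pi]`.
#' @param mask optional logical `H x W` matrix.
#' @return `H x W` matrix of loop integrals (approximately 0 or +-2*pi).
#' @export
topological_charge <- function(phase_frame, mask = NULL) {
  H <- nrow(phase_frame); W <- ncol(phase_frame)
  if (is.null(mask)) mask <- matrix(TRUE, H, W)
  offs <- ps_ring_offsets()
  charge <- matrix(0, H, W)
  valid <- mask
  ring <- lapply(offs, function(o) shift_mat(phase_frame, -o[1], -o[2], fill = NA))
  for (o in offs) valid <- valid & shift_mat(mask, -o[1], -o[2], fill = FALSE)
  for (k in seq_along(offs)) {
    nxt <- ring[[if (k == length(offs)) 1L else k + 1L]]
    dphi <- wrap_pi(nxt - ring[[k]])
    dphi[is.na(dphi)] <- 0
    charge <- charge + dphi
  }
  charge[!valid] <- 0
  charge[1, ] <- 0; charge[H, ] <- 0; charge[, 1] <- 0; charge[, W] <- 0
  charge
}

#' Detect phase singularities in one frame
#'
#' A pixel is a candidate if its loop integral lies within `ps_tol_rad` of
#' `+2*pi` or `-2*pi`. It is an actual singularity if at least three of its
#' eight neighbours are candidates of the same sign and its residual
#' distance from `+-2*pi` is minimal among itself and those candidate
#' neighbours (row-major order breaks exact ties). Positions are refined
#' to sub-pixel accuracy by a residual-weighted centroid over the local
#' candidate cluster.
#'
#' @param phase_frame `H x W` phase matrix, or a precomputed charge map via
#'   `charge`.
#' @param ps_tol_rad candidate tolerance in radians (default 3.0).
#' @param mask optional logical matrix.
#' @param charge optional precomputed [topological_charge()] map.
#' @param refine logical; sub-pixel centroid refinement (default TRUE).
#' @return data.frame with columns `row`, `col` (sub-pixel), `px_row`,
#'   `px_col` (integer detection pixel), `chirality`, `charge_residual`.
#' @export
detect_ps <- function(phase_frame, ps_tol_rad = 3.0, mask = NULL,
                      charge = NULL, refine = TRUE) {
  if (is.null(charge)) charge <- topological_charge(phase_frame, mask)
  H <- nrow(charge); W <- ncol(charge)
  sgn <- ifelse(charge >= 0, 1L, -1L)
  resid <- abs(abs(charge) - 2 * pi)
  cand <- resid <= ps_tol_rad & abs(charge) > ps_tol_rad  # excludes charge ~ 0
  # candidate must actually be near +-2pi:
  cand <- abs(charge - sgn * 2 * pi) <= ps_tol_rad & abs(charge) > 1e-9
  out <- data.frame(row = numeric(), col = numeric(), px_row = integer(),
                    px_col = integer(), chirality = integer(),
                    charge_residual = numeric())
  if (!any(cand)) return(out)
  offs <- ps_ring_offsets()
  lin <- matrix(seq_len(H * W), H, W)          # column-major linear index
  rowmaj <- (row(lin) - 1L) * W + col(lin)     # row-major rank for tie-breaks
  n_same <- matrix(0L, H, W)
  beat_all <- matrix(TRUE, H, W)
  for (o in offs) {
    ncand <- shift_mat(cand + 0, -o[1], -o[2], fill = 0) > 0
    nsgn <- shift_mat(sgn, -o[1], -o[2], fill = 0)
    nres <- shift_mat(resid, -o[1], -o[2], fill = Inf)
    nrm <- shift_mat(rowmaj, -o[1], -o[2], fill = Inf)
    same <- ncand & nsgn == sgn
    n_same <- n_same + (same + 0L)
    # pixel must beat every same-sign candidate neighbour on residual,
    # with earlier row-major rank winning exact ties
    beats <- !same | (nres > resid) | (nres == resid & nrm > rowmaj)
    beat_all <- beat_all & beats
  }
  actual <- cand & n_same >= 3L & beat_all
  if (!any(actual)) return(out)
  ij <- which(actual, arr.ind = TRUE)
  ord <- order((ij[, 1] - 1L) * W + ij[, 2])
  ij <- ij[ord, , drop = FALSE]
  res_list <- lapply(seq_len(nrow(ij)), function(k) {
    r <- ij[k, 1]; c <- ij[k, 2]
    chir <- sgn[r, c]
    rr <- r; cc <- c; ww <- max(ps_tol_rad - resid[r, c], 1e-9)
    if (refine) {
      for (o in offs) {
        r2 <- r + o[1]; c2 <- c + o[2]
        if (r2 >= 1 && r2 <= H && c2 >= 1 && c2 <= W &&
            cand[r2, c2] && sgn[r2, c2] == chir) {
          w2 <- max(ps_tol_rad - resid[r2, c2], 1e-9)
          rr <- c(rr, r2); cc <- c(cc, c2); ww <- c(ww, w2)
        }
      }
    }
    data.frame(row = sum(rr * ww) / sum(ww), col = sum(cc * ww) / sum(ww),
               px_row = r, px_col = c, chirality = chir,
               charge_residual = resid[r, c])
  })
  do.call(rbind, res_list)
}

#' Detect phase singularities in every frame of a phase movie
#'
#' @param phase a [phase_movie()].
#' @param ps_tol_rad candidate tolerance (rad).
#' @param refine sub-pixel refinement flag.
#' @return data.frame of detections with a `frame` column.
#' @export
detect_ps_movie <- function(phase, ps_tol_rad = 3.0, refine = TRUE) {
  stopifnot(inherits(phase, "phase_movie"))
  Tn <- dim(phase$phase)[1]
  res <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    p <- detect_ps(phase$phase[t, , ], ps_tol_rad, mask = phase$mask,
                   refine = refine)
    if (nrow(p)) p$frame <- t
    res[[t]] <- p
  }
  out <- do.call(rbind, res[vapply(res, nrow, integer(1)) > 0])
  if (is.null(out)) out <- cbind(detect_ps(matrix(0, 3, 3) + pi), frame = integer())
  out
}

#' Track phase singularities over time
#'
#' Greedy frame-to-frame nearest-neighbour linking among same-chirality
#' detections: candidate (track, detection) pairs within `link_px` are
#' assigned in ascending order of distance; unmatched detections open new
#' tracks; tracks unmatched for more than `gap_frames` consecutive frames
#' die.
#'
#' @param detections data.frame from [detect_ps_movie()].
#' @param link_px maximum link distance in pixels (default 5).
#' @param gap_frames frames a track survives unmatched (default 0).
#' @return list of `ps_track` objects: `points` (data.frame `frame`, `row`,
#'   `col`, `charge_residual`), `chirality`, `birth_frame`, `death_frame`.
#' @export
track_ps <- function(detections, link_px = 5, gap_frames = 0L) {
  tracks <- list()
  open <- list()   # each: list(points = list of rows, chirality, last_frame, last_pos)
  if (is.null(detections) || nrow(detections) == 0L) return(tracks)
  frames <- sort(unique(detections$frame))
  finalize <- function(tr) {
    pts <- do.call(rbind, tr$points)
    structure(list(points = pts, chirality = tr$chirality,
                   birth_frame = pts$frame[1L],
                   death_frame = pts$frame[nrow(pts)],
                   rotations = NA_real_, is_rotor = NA),
              class = "ps_track")
  }
  for (f in frames) {
    det <- detections[detections$frame == f, , drop = FALSE]
    # retire tracks that exceeded the allowed gap
    if (length(open)) {
      expired <- vapply(open, function(tr) f - tr$last_frame > gap_frames + 1L,
                        logical(1))
      tracks <- c(tracks, lapply(open[expired], finalize))
      open <- open[!expired]
    }
    assigned_det <- rep(FALSE, nrow(det))
    if (length(open) && nrow(det)) {
      pairs <- do.call(rbind, lapply(seq_along(open), function(i) {
        tr <- open[[i]]
        ok <- det$chirality == tr$chirality
        if (!any(ok)) return(NULL)
        j <- which(ok)
        d <- sqrt((det$row[j] - tr$last_pos[1])^2 + (det$col[j] - tr$last_pos[2])^2)
        keep <- d <= link_px
        if (!any(keep)) return(NULL)
        data.frame(i = i, j = j[keep], d = d[keep])
      }))
      if (!is.null(pairs) && nrow(pairs)) {
        pairs <- pairs[order(pairs$d), , drop = FALSE]
        used_tr <- rep(FALSE, length(open))
        for (k in seq_len(nrow(pairs))) {
          i <- pairs$i[k]; j <- pairs$j[k]
          if (used_tr[i] || assigned_det[j]) next
          used_tr[i] <- TRUE; assigned_det[j] <- TRUE
          open[[i]]$points[[length(open[[i]]$points) + 1L]] <-
            data.frame(frame = f, row = det$row[j], col = det$col[j],
                       charge_residual = det$charge_residual[j])
          open[[i]]$last_frame <- f
          open[[i]]$last_pos <- c(det$row[j], det$col[j])
        }
      }
    }
    for (j in which(!assigned_det)) {
      open[[length(open) + 1L]] <- list(
        points = list(data.frame(frame = f, row = det$row[j], col = det$col[j],
                                 charge_residual = det$charge_residual[j])),
        chirality = det$chirality[j], last_frame = f,
        last_pos = c(det$row[j], det$col[j]))
    }
  }
  c(tracks, lapply(open, finalize))
}

#' @export
print.ps_track <- function(x, ...) {
  cat(sprintf("<ps_track> chirality %+d | frames %d-%d (%d points) | rotations %s\n",
              x$chirality, x$birth_frame, x$death_frame, nrow(x$points),
              if (is.na(x$rotations)) "?" else sprintf("%.2f", x$rotations)))
  invisible(x)
}

#' Count rotations of a tracked singularity
#'
#' Phase at a probe pixel offset `probe_px` from the per-frame core
#' position (offset direction fixed perpendicular to the track's mean
#' motion; +col for stationary tracks) is temporally unwrapped; rotations =
#' total absolute phase excursion / 2*pi. A track whose probes never land
#' on valid pixels falls back to lifetime x local dominant frequency and is
#' flagged (`attr(,"fallback")`).
#'
#' @param track a `ps_track`.
#' @param phase the [phase_movie()] the track was detected in.
#' @param probe_px probe offset in pixels (default 2).
#' @param df_map optional `df_map` used by the fallback.
#' @return the track with `rotations`, `is_rotor` and per-frame cumulative
#'   rotations (`points$cum_rotations`) filled in.
#' @export
count_rotations <- function(track, phase, probe_px = 2, df_map = NULL) {
  pts <- track$points
  d <- dim(phase$phase)
  n <- nrow(pts)
  # fixed probe direction: perpendicular to mean displacement
  if (n >= 2L) {
    v <- c(pts$row[n] - pts$row[1L], pts$col[n] - pts$col[1L])
  } else v <- c(0, 0)
  if (sqrt(sum(v^2)) < 1e-6) u <- c(0, 1) else {
    u <- c(-v[2], v[1]) / sqrt(sum(v^2))
  }
  pr <- pmin(pmax(round(pts$row + probe_px * u[1]), 1L), d[2])
  pc <- pmin(pmax(round(pts$col + probe_px * u[2]), 1L), d[3])
  valid <- phase$mask[cbind(pr, pc)]
  if (sum(valid) >= max(2L, n / 2)) {
    th <- phase$phase[cbind(pts$frame, pr, pc)]
    th[!valid] <- NA
    th <- th[!is.na(th)]
    fr <- pts$frame[valid]
    dth <- wrap_pi(diff(th))
    cum <- cumsum(abs(c(0, dth))) / (2 * pi)
    track$rotations <- cum[length(cum)]
    cumfull <- stats::approx(fr, cum, xout = pts$frame, rule = 2)$y
    track$points$cum_rotations <- cumfull
  } else {
    f_local <- if (!is.null(df_map)) {
      v <- df_map$values[cbind(pmin(pmax(round(pts$row), 1L), d[2]),
                               pmin(pmax(round(pts$col), 1L), d[3]))]
      mean(v, na.rm = TRUE)
    } else NA_real_
    lifetime_ms <- (pts$frame[n] - pts$frame[1L] + 1L) * phase$dt
    track$rotations <- lifetime_ms / 1000 * f_local
    track$points$cum_rotations <- if (is.na(track$rotations)) {
      rep(NA_real_, n)
    } else seq(0, track$rotations, length.out = n)
    attr(track, "fallback") <- TRUE
  }
  track$is_rotor <- isTRUE(track$rotations > 1)
  track
}

#' Density map container
#'
#' @param counts `H x W` non-negative matrix of event counts.
#' @param kind one of `"trajectory"`, `"initiation"`, `"annihilation"`,
#'   `"nwf_origin"`.
#' @param duration_ms recording duration covered.
#' @param area_cm2 mapped tissue area.
#' @return an object of class `density_map`.
#' @export
density_map <- function(counts, kind, duration_ms = NA_real_, area_cm2 = NA_real_) {
  stopifnot(all(counts >= 0))
  structure(list(counts = counts, kind = kind, duration_ms = duration_ms,
                 area_cm2 = area_cm2),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("<density_map:%s> %d x %d, total %g\n", x$kind,
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Trajectory / initiation / annihilation density maps from tracks
#'
#' The trajectory map increments every (frame, pixel) a singularity
#' occupies; initiation increments birth pixels; annihilation increments
#' death pixels.
#'
#' @param tracks list of `ps_track`.
#' @param dims `c(H, W)` grid size.
#' @param dt frame interval (ms), for metadata.
#' @param pitch pixel pitch (mm), for metadata.
#' @param n_frames total frames, for metadata.
#' @return named list of three `density_map`s: `trajectory`, `initiation`,
#'   `annihilation`.
#' @export
ps_density_maps <- function(tracks, dims, dt = 1, pitch = 0.44, n_frames = NA) {
  H <- dims[1]; W <- dims[2]
  traj <- matrix(0, H, W); init <- matrix(0, H, W); annih <- matrix(0, H, W)
  clamp <- function(r, c) cbind(pmin(pmax(round(r), 1L), H), pmin(pmax(round(c), 1L), W))
  for (tk in tracks) {
    ij <- clamp(tk$points$row, tk$points$col)
    for (k in seq_len(nrow(ij))) traj[ij[k, 1], ij[k, 2]] <- traj[ij[k, 1], ij[k, 2]] + 1
    b <- clamp(tk$points$row[1L], tk$points$col[1L])
    e <- clamp(tk$points$row[nrow(ij)], tk$points$col[nrow(ij)])
    init[b] <- init[b] + 1
    annih[e] <- annih[e] + 1
  }
  dur <- if (is.na(n_frames)) NA_real_ else n_frames * dt
  list(trajectory = density_map(traj, "trajectory", dur),
       initiation = density_map(init, "initiation", dur),
       annihilation = density_map(annih, "annihilation", dur))
}

#' Phase-singularity rate per unit area and time
#'
#' Mean count of coexisting singularities per frame divided by the mapped
#' area (cm^2) and the frame interval (ms), reported separately for tracks
#' lasting at most one rotation and for rotors (> 1 rotation).
#'
#' @param tracks list of `ps_track` with rotations filled in.
#' @param mask logical tissue mask.
#' @param n_frames number of frames in the recording.
#' @param dt frame interval (ms).
#' @param pitch pixel pitch (mm).
#' @return list with `rate_total`, `rate_short`, `rate_rotor`
#'   (PS / cm^2 / ms) and `area_cm2`.
#' @export
ps_rate <- function(tracks, mask, n_frames, dt = 1, pitch = 0.44) {
  area_cm2 <- sum(mask) * (pitch / 10)^2
  if (area_cm2 <= 0) stop("zero mapped area", call. = FALSE)
  if (n_frames <= 0) stop("duration must be positive", call. = FALSE)
  count_of <- function(sel) {
    tot <- 0
    for (tk in tracks[sel]) tot <- tot + nrow(tk$points)
    tot / n_frames
  }
  is_rot <- vapply(tracks, function(tk) isTRUE(tk$is_rotor), logical(1))
  list(rate_total = count_of(rep(TRUE, length(tracks))) / area_cm2 / dt,
       rate_short = count_of(!is_rot) / area_cm2 / dt,
       rate_rotor = count_of(is_rot) / area_cm2 / dt,
       area_cm2 = area_cm2)
}
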