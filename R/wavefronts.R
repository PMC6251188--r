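# Isophase wavefront extraction, new-wavefront (NWF) detection and
# three-way classification, NWF density maps and preferential sites.
#
# Active pixels sit on the isophase line of theta = -pi/2 (the upstroke):
# a pixel is active iff its phase lies in [theta - band, theta] and one to
# three of its four adjacent neighbours have phase greater than theta. A
# wavefront that cannot be explained by propagation from the previous frame
# is new; if the previous frame was globally quiescent it is a new
# wavefront following electrical quiescence.

#' Isophase active-pixel mask
#'
#' @param phase_frame `H x W` phase matrix in `(-pi, pi]`.
#' @param theta isophase value in radians (default `-pi/2`); must be at
#'   least `band` away from the branch cut at +-pi.
#' @param band band width in radians (default 0.5).
#' @param mask optional logical tissue mask; neighbours outside the mask are
#'   excluded from the neighbour count.
#' @return logical `H x W` matrix of active pixels.
#' @export
isophase_pixels <- function(phase_frame, theta = -pi / 2, band = 0.5, mask = NULL) {
  if (pi - abs(theta) < band)
    stop("`theta` must be at least `band` away from the +-pi branch cut",
         call. = FALSE)
  H <- nrow(phase_frame); W <- ncol(phase_frame)
  if (is.null(mask)) mask <- matrix(TRUE, H, W)
  inband <- phase_frame >= theta - band & phase_frame <= theta & mask
  gt <- (phase_frame > theta) & mask
  cnt <- matrix(0L, H, W)
  for (o in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
    cnt <- cnt + shift_mat(gt + 0L, -o[1], -o[2], fill = 0L)
  }
  inband & cnt >= 1L & cnt <= 3L
}

#' Label 8-connected wavefront components
#'
#' @param active logical `H x W` active-pixel mask.
#' @param min_component_px components smaller than this are discarded.
#' @return integer `H x W` label matrix (0 = background; labels 1..k in
#'   row-major order of first pixel).
#' @export
label_wavefronts <- function(active, min_component_px = 1L) {
  lab <- label_components(active)
  if (min_component_px > 1L && max(lab) > 0L) {
    sz <- tabulate(lab[lab > 0L])
    small <- which(sz < min_component_px)
    if (length(small)) {
      lab[lab %in% small] <- 0L
      ids <- sort(unique(lab[lab > 0L]))
      re <- integer(max(c(ids, 0L)))
      re[ids] <- seq_along(ids)
      lab[lab > 0L] <- re[lab[lab > 0L]]
    }
  }
  lab
}

#' Label active pixels as new or propagated
#'
#' An active pixel is propagated iff any active pixel of the previous frame
#' lies within the `(2 radius + 1)^2` square neighbourhood around it
#' (dilation of the previous mask by the square structuring element);
#' otherwise it is new.
#'
#' @param active_t logical active mask at frame t.
#' @param active_prev logical active mask at frame t-1 (same shape).
#' @return logical matrix: TRUE = new, FALSE = propagated; only meaningful
#'   at pixels active in `active_t`.
#' @param radius_px neighbourhood radius in pixels (default 3).
#' @export
detect_new_wavefronts <- function(active_t, active_prev, radius_px = 3L) {
  stopifnot(identical(dim(active_t), dim(active_prev)))
  dil <- box_sum_mat(active_prev + 0, 2L * as.integer(radius_px) + 1L) > 0
  active_t & !dil
}

#' Classify one wavefront component
#'
#' A component is new if the majority of its pixels are new (ties break
#' toward new). New components are `new_after_quiescence` iff the previous
#' frame had no active pixels anywhere in the mapping field, otherwise
#' `new_existing_AF`; components that are not new are `propagated`.
#'
#' @param component_pixels logical matrix or 2-column (row, col) index
#'   matrix of the component.
#' @param new_labels logical matrix from [detect_new_wavefronts()].
#' @param prev_frame_active_count total active pixels in the previous frame.
#' @return one of `"propagated"`, `"new_existing_AF"`,
#'   `"new_after_quiescence"`.
#' @export
classify_wavefront <- function(component_pixels, new_labels, prev_frame_active_count) {
  if (is.logical(component_pixels)) {
    nn <- sum(new_labels & component_pixels)
    np <- sum(component_pixels) - nn
  } else {
    v <- new_labels[component_pixels]
    nn <- sum(v); np <- length(v) - nn
  }
  if (nn >= np && nn > 0L) {
    if (prev_frame_active_count == 0L) "new_after_quiescence" else "new_existing_AF"
  } else "propagated"
}

#' Extract and classify wavefront components for a whole movie
#'
#' Runs the isophase rule on every frame, labels 8-connected components,
#' labels pixels new/propagated against the previous frame, and classifies
#' each component. Frame 1 has no predecessor: its components are recorded
#' with class `propagated` (no new-wavefront call can be made).
#'
#' @param phase a [phase_movie()].
#' @param config a [run_config()].
#' @param warmup_frames frames at each record edge in which no
#'   new-wavefront call is made (components are recorded as `propagated`).
#'   Phase values there lean on extrapolated envelopes and the analytic
#'   signal's edge transient; [run_pipeline()] sets this to half the
#'   extrema window.
#' @return object of class `wavefront_events`: data.frame with columns
#'   `frame`, `component_id`, `wf_class`, `centroid_row`, `centroid_col`,
#'   `n_pixels`, plus a list-column `pixels` of 2-column index matrices.
#'   Attribute `active_count` holds the per-frame active-pixel series.
#' @export
detect_wavefront_events <- function(phase, config = run_config(),
                                    warmup_frames = 0L) {
  stopifnot(inherits(phase, "phase_movie"))
  d <- dim(phase$phase)
  Tn <- d[1]
  rows <- list()
  prev_active <- matrix(FALSE, d[2], d[3])
  prev_count <- 0L
  active_count <- integer(Tn)
  for (t in seq_len(Tn)) {
    act <- isophase_pixels(phase$phase[t, , ], theta = config$iso_theta,
                           band = config$iso_band, mask = phase$mask)
    active_count[t] <- sum(act)
    if (any(act)) {
      lab <- label_wavefronts(act, config$min_component_px)
      if (max(lab) > 0L) {
        newlab <- if (t == 1L) act & FALSE else
          detect_new_wavefronts(act, prev_active, config$nwf_radius_px)
        edge <- t == 1L || t <= warmup_frames || t > Tn - warmup_frames
        comps <- lapply(seq_len(max(lab)), function(k) {
          ij <- which(lab == k, arr.ind = TRUE)
          cls <- if (edge) "propagated" else
            classify_wavefront(ij, newlab, prev_count)
          list(ij = ij, cls = cls)
        })
        # new components closer than the method's spatial resolution
        # (2 x neighbourhood radius) are indistinguishable from a single
        # new wavefront (e.g. one ring split into arcs): merge them
        comps <- merge_new_components(comps, 2L * config$nwf_radius_px)
        for (k in seq_along(comps)) {
          ij <- comps[[k]]$ij
          rows[[length(rows) + 1L]] <- list(
            frame = t, component_id = k, wf_class = comps[[k]]$cls,
            centroid_row = mean(ij[, 1]), centroid_col = mean(ij[, 2]),
            n_pixels = nrow(ij), pixels = ij)
        }
      }
    }
    prev_active <- act
    prev_count <- active_count[t]
  }
  ev <- if (length(rows)) {
    data.frame(frame = vapply(rows, `[[`, integer(1), "frame"),
               component_id = vapply(rows, `[[`, integer(1), "component_id"),
               wf_class = vapply(rows, `[[`, character(1), "wf_class"),
               centroid_row = vapply(rows, `[[`, numeric(1), "centroid_row"),
               centroid_col = vapply(rows, `[[`, numeric(1), "centroid_col"),
               n_pixels = vapply(rows, `[[`, integer(1), "n_pixels"))
  } else {
    data.frame(frame = integer(), component_id = integer(),
               wf_class = character(), centroid_row = numeric(),
               centroid_col = numeric(), n_pixels = integer())
  }
  ev$pixels <- lapply(rows, `[[`, "pixels")
  attr(ev, "active_count") <- active_count
  attr(ev, "dims") <- c(d[2], d[3])
  attr(ev, "dt") <- phase$dt
  class(ev) <- c("wavefront_events", class(ev))
  ev
}

# Merge new (non-propagated) components whose pixel sets are within
# Chebyshev distance `d_px` of each other; propagated components pass
# through untouched.
merge_new_components <- function(comps, d_px) {
  is_new <- vapply(comps, function(cp) cp$cls != "propagated", logical(1))
  ni <- which(is_new)
  if (length(ni) < 2L) return(comps)
  parent <- seq_along(ni)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (ai in seq_along(ni)) for (bi in seq_along(ni)) {
    if (bi <= ai) next
    A <- comps[[ni[ai]]]$ij; B <- comps[[ni[bi]]]$ij
    dmin <- min(pmax(abs(outer(A[, 1], B[, 1], `-`)),
                     abs(outer(A[, 2], B[, 2], `-`))))
    if (dmin <= d_px) {
      ra <- find(ai); rb <- find(bi)
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_along(ni), find, integer(1))
  merged <- lapply(unique(roots), function(r) {
    members <- ni[roots == r]
    list(ij = do.call(rbind, lapply(comps[members], `[[`, "ij")),
         cls = comps[[members[1L]]]$cls)
  })
  c(comps[!is_new], merged)
}

#' New-wavefront origin density map
#'
#' One count per new-wavefront event. By default the count is placed at the
#' event's pixels (spread as 1/n per pixel so each event contributes unit
#' mass); `at = "centroid"` places the whole count at the rounded centroid.
#'
#' @param events a `wavefront_events` table (or subset).
#' @param dims `c(H, W)`; taken from the events attribute when missing.
#' @param at `"pixels"` or `"centroid"`.
#' @return a `density_map` of kind `nwf_origin`.
#' @export
nwf_density_map <- function(events, dims = NULL, at = c("pixels", "centroid")) {
  at <- match.arg(at)
  if (is.null(dims)) dims <- attr(events, "dims")
  H <- dims[1]; W <- dims[2]
  counts <- matrix(0, H, W)
  nwf <- events[events$wf_class != "propagated", , drop = FALSE]
  for (i in seq_len(nrow(nwf))) {
    if (at == "centroid") {
      r <- min(max(round(nwf$centroid_row[i]), 1L), H)
      c <- min(max(round(nwf$centroid_col[i]), 1L), W)
      counts[r, c] <- counts[r, c] + 1
    } else {
      ij <- nwf$pixels[[i]]
      counts[ij] <- counts[ij] + 1 / nrow(ij)
    }
  }
  density_map(counts, "nwf_origin")
}

#' Preferential new-wavefront initiation sites
#'
#' The density map is smoothed with a mask-aware 3 x 3 mean, thresholded at
#' mean + `n_sd` standard deviations over the mask, and 8-connected
#' supra-threshold regions become sites. Events are assigned to a site when
#' their rounded origin centroid falls inside it.
#'
#' @param density a `density_map` (kind `nwf_origin`).
#' @param events the `wavefront_events` the map was built from.
#' @param mask optional logical mask.
#' @param n_sd threshold in SDs above the mask mean (default 2).
#' @param min_events minimum number of assigned events for a region to
#'   count as a preferential site (default 2: a site is a locus of
#'   *repeated* initiation; one stray event is not a site).
#' @return list of `nwf_site` objects: `pixels` (index matrix), `centroid`,
#'   `event_count`, `event_frames`, `cycle_lengths_ms`. Empty when no pixel
#'   passes the threshold.
#' @export
find_nwf_sites <- function(density, events, mask = NULL, n_sd = 2,
                           min_events = 2L) {
  counts <- density$counts
  H <- nrow(counts); W <- ncol(counts)
  if (is.null(mask)) mask <- matrix(TRUE, H, W)
  sm <- box_mean_masked(counts, mask, 3L)
  mu <- mean(sm[mask]); sdv <- stats::sd(sm[mask])
  thr <- mu + n_sd * sdv
  supra <- sm > thr & mask
  if (!any(supra)) return(list())
  lab <- label_components(supra)
  dt <- attr(events, "dt") %||% 1
  nwf <- events[events$wf_class != "propagated", , drop = FALSE]
  er <- pmin(pmax(round(nwf$centroid_row), 1L), H)
  ec <- pmin(pmax(round(nwf$centroid_col), 1L), W)
  # an event belongs to a site when its origin centroid falls inside it, or
  # failing that when any of its pixels do (a front detected a few frames
  # after onset is an annulus whose centroid carries no mass)
  event_site <- integer(nrow(nwf))
  if (nrow(nwf)) {
    event_site <- lab[cbind(er, ec)]
    for (i in which(event_site == 0L)) {
      hits <- lab[nwf$pixels[[i]]]
      hits <- hits[hits > 0L]
      if (length(hits)) event_site[i] <- as.integer(names(which.max(table(hits))))
    }
  }
  sites <- lapply(seq_len(max(lab)), function(k) {
    ij <- which(lab == k, arr.ind = TRUE)
    inside <- event_site == k
    fr <- sort(nwf$frame[inside])
    cls <- site_cycle_lengths_frames(fr, dt)
    structure(list(pixels = ij,
                   centroid = c(mean(ij[, 1]), mean(ij[, 2])),
                   event_count = sum(inside),
                   event_frames = fr,
                   cycle_lengths_ms = cls),
              class = "nwf_site")
  })
  sites[vapply(sites, function(s) s$event_count >= min_events, logical(1))]
}

#' @export
print.nwf_site <- function(x, ...) {
  cat(sprintf("<nwf_site> %d px at (%.1f, %.1f) | %d events | median CL %s ms\n",
              nrow(x$pixels), x$centroid[1], x$centroid[2], x$event_count,
              if (length(x$cycle_lengths_ms)) sprintf("%.0f", stats::median(x$cycle_lengths_ms)) else "-"))
  invisible(x)
}

#' Cycle lengths of new-wavefront events at a site
#'
#' Intervals (ms) between successive new-wavefront events whose origin lies
#' in the site. Fewer than two events yield an empty vector.
#'
#' @param site an `nwf_site` from [find_nwf_sites()].
#' @param events optional `wavefront_events`; when supplied, event origins
#'   are re-assigned to the site's pixels, otherwise the frames stored in
#'   the site are used.
#' @param dt frame interval in ms.
#' @return numeric vector of cycle lengths in ms.
#' @export
site_cycle_lengths <- function(site, events = NULL, dt = NULL) {
  if (is.null(events)) {
    return(site$cycle_lengths_ms)
  }
  if (is.null(dt)) dt <- attr(events, "dt") %||% 1
  H <- max(site$pixels[, 1]); W <- max(site$pixels[, 2])
  nwf <- events[events$wf_class != "propagated", , drop = FALSE]
  er <- round(nwf$centroid_row); ec <- round(nwf$centroid_col)
  keyset <- paste(site$pixels[, 1], site$pixels[, 2])
  inside <- paste(er, ec) %in% keyset
  site_cycle_lengths_frames(sort(nwf$frame[inside]), dt)
}

site_cycle_lengths_frames <- function(frames, dt) {
  if (length(frames) < 2L) return(numeric())
  diff(frames) * dt
}
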