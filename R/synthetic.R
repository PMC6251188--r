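# Ground-truth movie generators: analytic spiral phase films, a
# quiescence-guaranteeing focal source, a two-variable excitable-media
# reaction-diffusion solver (Aliev-Panfilov kinetics), a coupled two-layer
# breakthrough simulator, and an optical-noise model. All generators are
# deterministic given their seed.

#' Analytic spiral-wave movie with exact ground truth
#'
#' `phase(t, r, c) = wrap(2 pi f t + chirality * atan2(r - r0, c - c0)
#' - k * dist)`; voltage is `cos(phase)`. Under the package's charge
#' orientation the core carries winding number `+chirality` in every frame.
#'
#' @param freq rotation frequency in Hz (must be below Nyquist/4).
#' @param core length-2 `(row, col)` static core, or a `T x 2` matrix of
#'   per-frame core positions (e.g. a meander circle).
#' @param duration_ms movie duration in ms.
#' @param dims grid `c(H, W)` (default `c(128, 80)`).
#' @param dt frame interval in ms.
#' @param pitch pixel pitch in mm.
#' @param k radial wavenumber in rad/px (Archimedean arm tightness).
#' @param chirality +1 or -1.
#' @return list with `phase` ([phase_movie()]), `movie` ([voltage_movie()])
#'   and `truth` (list: `ps_trajectories` data.frame, `regime = "spiral"`,
#'   `params`).
#' @export
analytic_spiral_movie <- function(freq, core, duration_ms, dims = c(128, 80),
                                  dt = 1, pitch = 0.44, k = 0.2, chirality = 1L) {
  fs <- 1000 / dt
  if (freq >= fs / 8) stop("freq must be below Nyquist/4", call. = FALSE)
  Tn <- as.integer(round(duration_ms / dt))
  H <- dims[1]; W <- dims[2]
  if (is.null(dim(core))) core <- matrix(rep(core, each = Tn), Tn, 2)
  if (any(core[, 1] < 1 | core[, 1] > H | core[, 2] < 1 | core[, 2] > W))
    stop("core outside grid", call. = FALSE)
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  ph <- array(0, c(Tn, H, W))
  for (t in seq_len(Tn)) {
    dr <- rr - core[t, 1]; dc <- cc - core[t, 2]
    ph[t, , ] <- wrap_pi(2 * pi * freq * (t - 1) * dt / 1000 +
                           chirality * atan2(dr, dc) - k * sqrt(dr^2 + dc^2))
  }
  truth <- list(ps_trajectories = data.frame(frame = seq_len(Tn),
                                             row = core[, 1], col = core[, 2],
                                             chirality = as.integer(chirality)),
                focal_events = data.frame(frame = integer(), row = numeric(),
                                          col = numeric()),
                regime = "spiral",
                params = list(freq = freq, k = k, chirality = chirality,
                              dims = dims, dt = dt, duration_ms = duration_ms))
  list(phase = phase_movie(ph, dt = dt, pitch = pitch),
       movie = voltage_movie(cos(ph), dt = dt, pitch = pitch,
                             meta = list(generator = "analytic_spiral")),
       truth = truth)
}

# Stylized optical action potential: linear upstroke then cosine
# repolarization; tau in ms since activation.
ap_waveform <- function(tau, upstroke_ms = 2, apd_ms = 35) {
  v <- numeric(length(tau))
  up <- tau >= 0 & tau < upstroke_ms
  rep_ <- tau >= upstroke_ms & tau <= upstroke_ms + apd_ms
  v[up] <- tau[up] / upstroke_ms
  v[rep_] <- 0.5 * (1 + cos(pi * (tau[rep_] - upstroke_ms) / apd_ms))
  v
}

#' Focal-source movie with guaranteed inter-beat quiescence
#'
#' A stylized action potential (2 ms linear upstroke, cosine
#' repolarization of duration `apd_ms`) is launched from `origin` each
#' beat; activation time at a pixel is `beat time + distance / cv`. The
#' generator refuses parameter sets in which a beat would collide with the
#' previous wave's tail, so the mapped field fully repolarizes between
#' beats.
#'
#' @param origin `(row, col)` of the source (defaults to the grid centre).
#' @param cycle_ms basic cycle length in ms.
#' @param cv_mm_per_ms conduction velocity.
#' @param apd_ms action-potential duration.
#' @param n_beats number of beats.
#' @param dims grid `c(H, W)`.
#' @param dt frame interval (ms); `pitch` pixel pitch (mm).
#' @param pitch pixel pitch in mm.
#' @param jitter_sd_ms Gaussian jitter SD applied to each cycle (seeded).
#' @param start_ms time of the first beat; the default of one full cycle
#'   gives the phase estimator a quiescent baseline so record-edge
#'   transients do not contaminate the first beat.
#' @param seed RNG seed for the jitter.
#' @param duration_ms optional total duration; must be at least the time
#'   needed for the last wave to clear (a longer value appends quiescence).
#' @return list with `movie` ([voltage_movie()]) and `truth` (list:
#'   `focal_events` data.frame with 1-based frames, `regime = "focal"`,
#'   `params`).
#' @export
focal_movie <- function(origin = NULL, cycle_ms = 80, cv_mm_per_ms = 0.5,
                        apd_ms = 35, n_beats = 10, dims = c(64, 64), dt = 1,
                        pitch = 0.44, jitter_sd_ms = 0, start_ms = cycle_ms,
                        seed = NULL, duration_ms = NULL) {
  H <- dims[1]; W <- dims[2]
  if (is.null(origin)) origin <- c(round(H / 2), round(W / 2))
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  dist_mm <- sqrt((rr - origin[1])^2 + (cc - origin[2])^2) * pitch
  transit <- max(dist_mm) / cv_mm_per_ms
  upstroke_ms <- 2
  beat_times <- start_ms + (seq_len(n_beats) - 1) * cycle_ms
  if (jitter_sd_ms > 0) {
    jit <- with_seed(seed, stats::rnorm(n_beats, 0, jitter_sd_ms))
    beat_times <- beat_times + c(0, cumsum(jit[-1]))
  }
  gaps <- diff(beat_times)
  busy <- transit + upstroke_ms + apd_ms
  if (any(gaps <= busy))
    stop(sprintf("no quiescence: cycle %.0f ms <= transit+AP %.0f ms; shrink the grid, raise cv, or lengthen the cycle",
                 min(gaps), busy), call. = FALSE)
  need_ms <- beat_times[n_beats] + busy + 10
  if (is.null(duration_ms)) duration_ms <- need_ms
  if (duration_ms < need_ms)
    stop(sprintf("duration_ms must be >= %.0f for the last wave to clear", need_ms),
         call. = FALSE)
  Tn <- as.integer(ceiling(duration_ms / dt))
  dat <- array(0, c(Tn, H, W))
  tms <- (seq_len(Tn) - 1) * dt
  for (b in seq_len(n_beats)) {
    t_act <- beat_times[b] + dist_mm / cv_mm_per_ms
    fr <- which(tms >= beat_times[b] - dt & tms <= beat_times[b] + busy + dt)
    for (t in fr) {
      dat[t, , ] <- dat[t, , ] + ap_waveform(tms[t] - t_act,
                                             upstroke_ms = upstroke_ms,
                                             apd_ms = apd_ms)
    }
  }
  truth <- list(ps_trajectories = data.frame(frame = integer(), row = numeric(),
                                             col = numeric(), chirality = integer()),
                focal_events = data.frame(frame = as.integer(round(beat_times / dt)) + 1L,
                                          row = origin[1], col = origin[2]),
                regime = "focal",
                params = list(cycle_ms = cycle_ms, cv = cv_mm_per_ms,
                              apd_ms = apd_ms, n_beats = n_beats, dims = dims,
                              origin = origin, jitter_sd_ms = jitter_sd_ms,
                              seed = seed))
  list(movie = voltage_movie(dat, dt = dt, pitch = pitch,
                             meta = list(generator = "focal")),
       truth = truth)
}

#' Reaction-diffusion simulation spec
#'
#' Two-variable Aliev-Panfilov kinetics: `du/dt = D lap(u) - k u (u-a)(u-1)
#' - u v + I_stim`, `dv/dt = (eps0 + mu1 v / (u + mu2)) (-v - k u (u-a-1))`,
#' explicit Euler, 5-point Laplacian, no-flux boundaries. One model time
#' unit is mapped to `ms_per_tu` milliseconds; the default of 4 ms places
#' the model's spiral rotation period (~26 time units with the default
#' kinetics) near 100 ms, i.e. dominant frequencies in the atrial
#' fibrillation range.
#'
#' @param dims grid `c(H, W)`.
#' @param n_ms simulated duration in ms (one frame per ms).
#' @param a,k,eps0,mu1,mu2 kinetic parameters.
#' @param D diffusion coefficient (model units).
#' @param dx grid spacing (model units).
#' @param ms_per_tu milliseconds per model time unit.
#' @param dt_tu integration step in time units; `NULL` picks the largest
#'   stable step that divides a frame.
#' @param stimuli list of stimuli: each a list with `t_ms`, `type`
#'   (`"point"`, `"bar"`, `"half"`), and geometry (`row`, `col`,
#'   `radius_px` for point; `cols` for bar; `rows` for half).
#' @param pitch pixel pitch (mm) stamped on the output movie.
#' @return an object of class `rd_spec`.
#' @export
rd_spec <- function(dims = c(96, 64), n_ms = 500, a = 0.11, k = 8,
                    eps0 = 0.01, mu1 = 0.2, mu2 = 0.3, D = 1, dx = 1,
                    ms_per_tu = 4, dt_tu = NULL, stimuli = list(),
                    pitch = 0.44) {
  tu_per_frame <- 1 / ms_per_tu
  dt_max <- 0.9 * dx^2 / (4 * D)
  dt_max <- min(dt_max, 0.1)      # reaction stiffness bound
  if (is.null(dt_tu)) {
    n_sub <- max(1L, ceiling(tu_per_frame / dt_max))
    dt_tu <- tu_per_frame / n_sub
  } else {
    if (dt_tu > dt_max)
      stop(sprintf("unstable step: dt_tu = %.4f exceeds %.4f; use dt_tu <= %.4f",
                   dt_tu, dt_max, dt_max), call. = FALSE)
    n_sub <- max(1L, round(tu_per_frame / dt_tu))
    dt_tu <- tu_per_frame / n_sub
  }
  structure(list(dims = dims, n_ms = n_ms, a = a, k = k, eps0 = eps0,
                 mu1 = mu1, mu2 = mu2, D = D, dx = dx,
                 ms_per_tu = ms_per_tu, dt_tu = dt_tu, n_sub = n_sub,
                 stimuli = stimuli, pitch = pitch),
            class = "rd_spec")
}

# No-flux 5-point Laplacian (replicate-padded).
lap_noflux <- function(u, dx) {
  H <- nrow(u); W <- ncol(u)
  (u[c(1, 1:(H - 1)), ] + u[c(2:H, H), ] +
     u[, c(1, 1:(W - 1))] + u[, c(2:W, W)] - 4 * u) / dx^2
}

# Flux-form Laplacian with removable edges (fibrosis). eh: H x (W-1)
# horizontal-edge conductances; ev: (H-1) x W vertical.
lap_edges <- function(u, dx, eh, ev) {
  H <- nrow(u); W <- ncol(u)
  fr <- eh * (u[, 2:W, drop = FALSE] - u[, 1:(W - 1), drop = FALSE])
  fd <- ev * (u[2:H, , drop = FALSE] - u[1:(H - 1), , drop = FALSE])
  out <- matrix(0, H, W)
  out[, 1:(W - 1)] <- out[, 1:(W - 1)] + fr
  out[, 2:W] <- out[, 2:W] - fr
  out[1:(H - 1), ] <- out[1:(H - 1), ] + fd
  out[2:H, ] <- out[2:H, ] - fd
  out / dx^2
}

rd_apply_stim <- function(u, v, stim, dims) {
  H <- dims[1]; W <- dims[2]
  if (stim$type == "point") {
    rr <- matrix(seq_len(H), H, W); cc <- matrix(seq_len(W), H, W, byrow = TRUE)
    sel <- (rr - stim$row)^2 + (cc - stim$col)^2 <= (stim$radius_px %||% 3)^2
    u[sel] <- 1
  } else if (stim$type == "bar") {
    u[, intersect(stim$cols, seq_len(W))] <- 1
  } else if (stim$type == "half") {
    u[intersect(stim$rows, seq_len(H)), ] <- 1
  } else if (stim$type == "broken") {
    # broken plane wave: excited half-strip with a refractory block above
    # its free end; the end curls into a spiral as the block recovers
    r0 <- stim$row %||% (H %/% 2)
    u[r0:min(H, r0 + 4L), 1:(W %/% 2)] <- 1
    if (r0 > 1L) v[1:(r0 - 1L), ] <- pmax(v[1:(r0 - 1L), ], 1.5)
  }
  list(u = u, v = v)
}

#' Run an excitable-media reaction-diffusion simulation
#'
#' @param spec an [rd_spec()].
#' @param eps0_map optional `H x W` matrix overriding `eps0` pixel-wise
#'   (larger values shorten the action potential, emulating acetylcholine
#'   islands).
#' @param edges optional list `(eh, ev)` of edge conductances for fibrosis.
#' @param record_v logical; also return the recovery variable.
#' @return a [voltage_movie()] of the activator `u` (one frame per ms).
#' @export
rd_simulate <- function(spec, eps0_map = NULL, edges = NULL, record_v = FALSE) {
  stopifnot(inherits(spec, "rd_spec"))
  H <- spec$dims[1]; W <- spec$dims[2]
  u <- matrix(0, H, W); v <- matrix(0, H, W)
  e0 <- if (is.null(eps0_map)) matrix(spec$eps0, H, W) else eps0_map
  Tn <- as.integer(spec$n_ms)
  out <- array(0, c(Tn, H, W))
  stim_frame <- vapply(spec$stimuli, function(s) as.integer(round(s$t_ms)) + 1L,
                       integer(1))
  for (fr in seq_len(Tn)) {
    hit <- which(stim_frame == fr)
    for (s in hit) {
      st <- rd_apply_stim(u, v, spec$stimuli[[s]], spec$dims)
      u <- st$u; v <- st$v
    }
    for (sub in seq_len(spec$n_sub)) {
      lap <- if (is.null(edges)) lap_noflux(u, spec$dx)
             else lap_edges(u, spec$dx, edges$eh, edges$ev)
      eps <- e0 + spec$mu1 * v / (u + spec$mu2)
      du <- spec$D * lap - spec$k * u * (u - spec$a) * (u - 1) - u * v
      dv <- eps * (-v - spec$k * u * (u - spec$a - 1))
      u <- u + spec$dt_tu * du
      v <- v + spec$dt_tu * dv
      # explicit-scheme guards: physiological range of the kinetics
      u[u < 0] <- 0; u[u > 1.05] <- 1.05
      v[v < 0] <- 0; v[v > 3] <- 3
    }
    out[fr, , ] <- u
  }
  voltage_movie(out, dt = 1, pitch = spec$pitch,
                meta = list(generator = "rd", spec = unclass(spec)))
}

#' Convenience spec for a sustained spiral (broken-wave initiation)
#'
#' An excited half-strip with a refractory block above its free end; the
#' free end curls into a spiral as the block recovers, producing sustained
#' reentry from t = 0 without S1-S2 timing.
#'
#' @param dims grid size.
#' @param n_ms simulated duration in ms.
#' @param s2_ms retained for compatibility; ignored by the broken-wave
#'   protocol.
#' @param ... passed to [rd_spec()].
#' @return an [rd_spec()].
#' @export
rd_spiral_spec <- function(dims = c(96, 64), n_ms = 600, s2_ms = NULL, ...) {
  rd_spec(dims = dims, n_ms = n_ms,
          stimuli = list(list(t_ms = 0, type = "broken",
                              row = dims[1] %/% 2)),
          ...)
}

# Build fibrosis edge conductances: stochastic edge removal with a
# longitudinal (horizontal, fibre-direction) bias.
fibrosis_edges <- function(dims, fraction, longitudinal_bias = 4, seed = NULL) {
  H <- dims[1]; W <- dims[2]
  n_h <- H * (W - 1L); n_v <- (H - 1L) * W
  if (fraction <= 0) {
    return(list(eh = matrix(1, H, W - 1L), ev = matrix(1, H - 1L, W)))
  }
  p_t <- fraction * (n_h + n_v) / (longitudinal_bias * n_h + n_v)
  p_l <- min(1, longitudinal_bias * p_t)
  with_seed(seed, {
    eh <- matrix(as.numeric(stats::runif(n_h) >= p_l), H, W - 1L)
    ev <- matrix(as.numeric(stats::runif(n_v) >= p_t), H - 1L, W)
    list(eh = eh, ev = ev)
  })
}

# Random acetylcholine islands: eps0 scaled up inside circles (APD
# shortening).
island_eps0 <- function(dims, eps0, n_islands, radius_px, scale = 4, seed = NULL) {
  H <- dims[1]; W <- dims[2]
  e0 <- matrix(eps0, H, W)
  if (n_islands <= 0) return(e0)
  with_seed(seed, {
    rows <- stats::runif(n_islands, 1, H)
    cols <- stats::runif(n_islands, 1, W)
    rr <- matrix(seq_len(H), H, W); cc <- matrix(seq_len(W), H, W, byrow = TRUE)
    for (i in seq_len(n_islands)) {
      sel <- (rr - rows[i])^2 + (cc - cols[i])^2 <= radius_px^2
      e0[sel] <- eps0 * scale
    }
    e0
  })
}

#' Two-layer (endo/epi) simulation spec
#'
#' @param dims per-layer grid `c(H, W)`.
#' @param n_connections number of discrete inter-layer connection sites.
#' @param connection_sites optional explicit `n x 2` (row, col) matrix;
#'   random (seeded) when `NULL`. `n_connections = 0` decouples the layers.
#' @param fibrosis_fraction length-2 `(endo, epi)` edge-removal fractions
#'   in `[0, 0.166]`.
#' @param longitudinal_bias fibrotic-edge bias toward the fibre
#'   (horizontal) direction (default 4).
#' @param n_islands acetylcholine islands per surface (default 10).
#' @param island_radius_mm island radius in mm (default 2.4).
#' @param islands_on `"none"`, `"endo"`, `"epi"` or `"both"`.
#' @param apd_gradient logical; shorter action potential on the epicardium.
#' @param coupling inter-layer conductance at connection sites.
#' @param connection_radius_px footprint radius of each connection (px);
#'   connections are small discs, not single nodes.
#' @param n_ms duration; `seed` RNG seed; `pitch` pixel pitch (mm).
#' @param seed RNG seed for connections, fibrosis and islands.
#' @param pitch pixel pitch in mm.
#' @param s2_ms S2 timing for the endocardial spiral drive.
#' @return object of class `two_layer_spec`.
#' @export
two_layer_spec <- function(dims = c(96, 64), n_connections = 1,
                           connection_sites = NULL,
                           fibrosis_fraction = c(0, 0),
                           longitudinal_bias = 4, n_islands = 0,
                           island_radius_mm = 2.4, islands_on = "none",
                           apd_gradient = FALSE, coupling = 8, n_ms = 700,
                           connection_radius_px = 2.5,
                           seed = 1L, pitch = 0.44, s2_ms = 260) {
  stopifnot(all(fibrosis_fraction >= 0), all(fibrosis_fraction <= 0.166))
  H <- dims[1]; W <- dims[2]
  if (is.null(connection_sites) && n_connections > 0) {
    connection_sites <- with_seed(seed, {
      cbind(round(stats::runif(n_connections, 0.15 * H, 0.85 * H)),
            round(stats::runif(n_connections, 0.15 * W, 0.85 * W)))
    })
  }
  if (!is.null(connection_sites)) {
    connection_sites <- unique(connection_sites)
    stopifnot(all(connection_sites[, 1] >= 1), all(connection_sites[, 1] <= H),
              all(connection_sites[, 2] >= 1), all(connection_sites[, 2] <= W))
  }
  structure(list(dims = dims, n_connections = n_connections,
                 connection_sites = connection_sites,
                 fibrosis_fraction = fibrosis_fraction,
                 longitudinal_bias = longitudinal_bias,
                 n_islands = n_islands, island_radius_mm = island_radius_mm,
                 islands_on = islands_on, apd_gradient = apd_gradient,
                 coupling = coupling, n_ms = n_ms, seed = seed,
                 connection_radius_px = connection_radius_px,
                 pitch = pitch, s2_ms = s2_ms),
            class = "two_layer_spec")
}

#' Simulate a coupled endocardial/epicardial bilayer
#'
#' Two reaction-diffusion sheets coupled only at discrete connection sites
#' by a resistive current; the endocardial layer is driven into a spiral by
#' a cross-field protocol, the epicardial layer is initially quiescent and
#' can only be excited through the connections. Activity crossing a
#' connection (upward threshold crossing of the receiving-layer activator
#' at the site) is recorded as a ground-truth breakthrough event.
#'
#' @param spec a [two_layer_spec()].
#' @return list with `endo`, `epi` ([voltage_movie()]s) and `truth` (list:
#'   `focal_events` = breakthroughs on the epi layer, `regime =
#'   "two_layer"`, `params`).
#' @export
two_layer_simulate <- function(spec) {
  stopifnot(inherits(spec, "two_layer_spec"))
  H <- spec$dims[1]; W <- spec$dims[2]
  base <- rd_spiral_spec(dims = spec$dims, n_ms = spec$n_ms, s2_ms = spec$s2_ms)
  radius_px <- spec$island_radius_mm / spec$pitch
  mk_eps <- function(layer) {
    on <- spec$islands_on %in% c("both", layer)
    e0 <- if (on) island_eps0(spec$dims, base$eps0, spec$n_islands, radius_px,
                              seed = spec$seed + if (layer == "endo") 11L else 12L)
          else matrix(base$eps0, H, W)
    if (layer == "epi" && spec$apd_gradient) e0 <- e0 * 1.5
    e0
  }
  e0_endo <- mk_eps("endo"); e0_epi <- mk_eps("epi")
  edges_endo <- fibrosis_edges(spec$dims, spec$fibrosis_fraction[1],
                               spec$longitudinal_bias, seed = spec$seed + 21L)
  edges_epi <- fibrosis_edges(spec$dims, spec$fibrosis_fraction[2],
                              spec$longitudinal_bias, seed = spec$seed + 22L)
  conn <- spec$connection_sites
  # disc footprint per connection
  discs <- NULL
  if (!is.null(conn) && nrow(conn)) {
    rr <- matrix(seq_len(H), H, W); cc <- matrix(seq_len(W), H, W, byrow = TRUE)
    discs <- lapply(seq_len(nrow(conn)), function(i) {
      which((rr - conn[i, 1])^2 + (cc - conn[i, 2])^2 <=
              spec$connection_radius_px^2)
    })
  }
  cidx <- if (!is.null(discs)) unlist(discs) else NULL
  uA <- matrix(0, H, W); vA <- matrix(0, H, W)
  uB <- matrix(0, H, W); vB <- matrix(0, H, W)
  Tn <- as.integer(spec$n_ms)
  outA <- array(0, c(Tn, H, W)); outB <- array(0, c(Tn, H, W))
  stim_frame <- vapply(base$stimuli, function(s) as.integer(round(s$t_ms)) + 1L,
                       integer(1))
  bt_frames <- integer(); bt_rows <- integer(); bt_cols <- integer()
  armed <- rep(TRUE, if (is.null(discs)) 0 else length(discs))
  for (fr in seq_len(Tn)) {
    for (s in which(stim_frame == fr)) {
      st <- rd_apply_stim(uA, vA, base$stimuli[[s]], spec$dims)
      uA <- st$u; vA <- st$v
    }
    for (sub in seq_len(base$n_sub)) {
      Icpl_A <- matrix(0, H, W); Icpl_B <- matrix(0, H, W)
      if (!is.null(cidx)) {
        dAB <- uB[cidx] - uA[cidx]
        Icpl_A[cidx] <- spec$coupling * dAB
        Icpl_B[cidx] <- -spec$coupling * dAB
      }
      lapA <- lap_edges(uA, base$dx, edges_endo$eh, edges_endo$ev)
      lapB <- lap_edges(uB, base$dx, edges_epi$eh, edges_epi$ev)
      epsA <- e0_endo + base$mu1 * vA / (uA + base$mu2)
      epsB <- e0_epi + base$mu1 * vB / (uB + base$mu2)
      duA <- base$D * lapA - base$k * uA * (uA - base$a) * (uA - 1) - uA * vA + Icpl_A
      duB <- base$D * lapB - base$k * uB * (uB - base$a) * (uB - 1) - uB * vB + Icpl_B
      vA <- vA + base$dt_tu * epsA * (-vA - base$k * uA * (uA - base$a - 1))
      vB <- vB + base$dt_tu * epsB * (-vB - base$k * uB * (uB - base$a - 1))
      uA <- uA + base$dt_tu * duA
      uB <- uB + base$dt_tu * duB
      uA[uA < 0] <- 0; uA[uA > 1.05] <- 1.05
      uB[uB < 0] <- 0; uB[uB > 1.05] <- 1.05
      vA[vA < 0] <- 0; vA[vA > 3] <- 3
      vB[vB < 0] <- 0; vB[vB > 3] <- 3
    }
    outA[fr, , ] <- uA; outB[fr, , ] <- uB
    if (!is.null(discs)) {
      for (i in seq_along(discs)) {
        um <- mean(uB[discs[[i]]])
        if (armed[i] && um >= 0.5) {
          bt_frames <- c(bt_frames, fr)
          bt_rows <- c(bt_rows, conn[i, 1])
          bt_cols <- c(bt_cols, conn[i, 2])
          armed[i] <- FALSE
        } else if (!armed[i] && um < 0.2) {
          armed[i] <- TRUE
        }
      }
    }
  }
  if (is.null(cidx)) {
    stopifnot(all(outB == 0))  # decoupled layer is provably silent
  }
  truth <- list(focal_events = data.frame(frame = bt_frames, row = bt_rows,
                                          col = bt_cols),
                regime = "two_layer",
                params = unclass(spec))
  list(endo = voltage_movie(outA, dt = 1, pitch = spec$pitch,
                            meta = list(generator = "two_layer", layer = "endo")),
       epi = voltage_movie(outB, dt = 1, pitch = spec$pitch,
                           meta = list(generator = "two_layer", layer = "epi")),
       truth = truth)
}

#' Add optical-mapping noise and baseline drift
#'
#' Adds i.i.d. Gaussian noise scaled to the requested SNR (signal power =
#' variance over mask samples) plus a per-pixel sinusoidal baseline drift
#' with random phase.
#'
#' @param movie a [voltage_movie()].
#' @param snr_db signal-to-noise ratio in dB.
#' @param drift_amp drift amplitude (signal units; 0 disables drift).
#' @param drift_hz drift frequency in Hz.
#' @param seed RNG seed.
#' @return the noised [voltage_movie()].
#' @export
add_optical_noise <- function(movie, snr_db, drift_amp = 0, drift_hz = 0.5,
                              seed = NULL) {
  stopifnot(inherits(movie, "voltage_movie"), is.finite(snr_db))
  d <- dim(movie$data)
  Tn <- d[1]
  idx <- which(movie$mask)
  X <- matrix(movie$data[, , ], nrow = Tn)
  p_sig <- stats::var(as.vector(X[, idx]))
  sd_n <- sqrt(p_sig / 10^(snr_db / 10))
  with_seed(seed, {
    X <- X + matrix(stats::rnorm(length(X), 0, sd_n), Tn)
    if (drift_amp > 0) {
      phases <- stats::runif(ncol(X), 0, 2 * pi)
      tt <- (seq_len(Tn) - 1) * movie$dt / 1000
      drift <- drift_amp * sin(outer(2 * pi * drift_hz * tt, phases, `+`))
      X <- X + drift
    }
    voltage_movie(array(X, d), dt = movie$dt, pitch = movie$pitch,
                  mask = movie$mask,
                  meta = c(movie$meta, list(snr_db = snr_db,
                                            drift_amp = drift_amp)))
  })
}

#' Generate a seeded regime movie for mechanism benchmarking
#'
#' `"focal"`: jittered-cycle focal source with full inter-beat quiescence.
#' `"spiral"`: analytic spiral with a small circular meander. Both receive
#' 40 dB optical noise. Defaults are the package's stated test world:
#' focal cycle 120 +- 5 ms (jitter), spiral frequency drawn in 9-12 Hz.
#'
#' @param regime `"focal"` or `"spiral"`.
#' @param seed integer seed controlling all randomness.
#' @param dims grid size (default `c(64, 48)`).
#' @param duration_ms movie length (default 600).
#' @param snr_db optical SNR (default 40).
#' @return list with `movie`, `truth`, `regime`.
#' @export
synthesize_regime <- function(regime = c("focal", "spiral"), seed = 1L,
                              dims = c(64, 48), duration_ms = 600,
                              snr_db = 40) {
  regime <- match.arg(regime)
  if (regime == "focal") {
    org <- with_seed(seed, c(round(stats::runif(1, 0.35, 0.65) * dims[1]),
                             round(stats::runif(1, 0.35, 0.65) * dims[2])))
    cycle <- 120
    # recording ends shortly after the last wave clears: fibrillation does
    # not pause for hundreds of ms at the end of a real record
    n_beats <- max(3L, 1L + floor((duration_ms - cycle - 90) / cycle))
    g <- focal_movie(origin = org, cycle_ms = cycle, apd_ms = 40,
                     n_beats = n_beats, dims = dims,
                     jitter_sd_ms = 5, seed = seed + 1L)
  } else {
    freq <- with_seed(seed, stats::runif(1, 9, 12))
    Tn <- duration_ms
    ang <- 2 * pi * (seq_len(Tn) - 1) / 250
    core <- cbind(dims[1] / 2 + 2 * cos(ang), dims[2] / 2 + 2 * sin(ang))
    g <- analytic_spiral_movie(freq, core, duration_ms, dims = dims)
  }
  noisy <- add_optical_noise(g$movie, snr_db = snr_db, seed = seed + 2L)
  list(movie = noisy, truth = g$truth, regime = regime)
}
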