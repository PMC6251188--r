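# Generators: determinism, ground-truth fidelity, excitable-media
# behaviour, noise model.

test_that("generators are bitwise deterministic given their seed", {
  a <- focal_movie(n_beats = 3, dims = c(24, 24), jitter_sd_ms = 4, seed = 7)
  b <- focal_movie(n_beats = 3, dims = c(24, 24), jitter_sd_ms = 4, seed = 7)
  expect_identical(a$movie$data, b$movie$data)
  expect_identical(a$truth$focal_events, b$truth$focal_events)
  n1 <- add_optical_noise(a$movie, 30, drift_amp = 0.2, seed = 5)
  n2 <- add_optical_noise(b$movie, 30, drift_amp = 0.2, seed = 5)
  expect_identical(n1$data, n2$data)
  s1 <- synthesize_regime("spiral", seed = 3, dims = c(24, 24), duration_ms = 150)
  s2 <- synthesize_regime("spiral", seed = 3, dims = c(24, 24), duration_ms = 150)
  expect_identical(s1$movie$data, s2$movie$data)
})

test_that("analytic spiral: phase advance, meander truth, winding", {
  g <- analytic_spiral_movie(10, c(20, 25), 1000, dims = c(40, 50))
  # fixed pixel advances 2 pi per 100 ms
  ph <- g$phase$phase[, 10, 40]
  adv <- sum(wrap_oracle(diff(ph)))
  expect_equal(adv / (2 * pi), 9.99 * 0.1 * 10, tolerance = 0.05)
  # winding +1 at every sampled frame, by the loop-integral oracle
  for (t in c(1, 250, 700)) {
    ch <- brute_charge(g$phase$phase[t, , ])
    expect_equal(ch[20, 25], 2 * pi, tolerance = 1e-8)
  }
  # meander truth is the requested circle
  ang <- 2 * pi * (0:99) / 100
  core <- cbind(20 + 5 * cos(ang), 25 + 5 * sin(ang))
  gm <- analytic_spiral_movie(10, core, 100, dims = c(40, 50))
  expect_equal(gm$truth$ps_trajectories$row, core[, 1])
  expect_equal(gm$truth$ps_trajectories$col, core[, 2])
  expect_error(analytic_spiral_movie(10, c(90, 25), 50, dims = c(40, 50)),
               "outside")
  expect_error(analytic_spiral_movie(300, c(20, 25), 50, dims = c(40, 50)),
               "Nyquist")
})

test_that("focal generator: events, monotone activation, quiescence guard", {
  g <- focal_movie(cycle_ms = 80, n_beats = 10, dims = c(48, 48))
  expect_identical(nrow(g$truth$focal_events), 10L)
  expect_true(all(diff(g$truth$focal_events$frame) == 80))
  # activation time grows with distance from the origin
  dat <- g$movie$data
  act_time <- function(r, c) which(dat[, r, c] > 0.5)[1]
  o <- g$truth$params$origin
  t0 <- act_time(o[1], o[2]); t1 <- act_time(o[1], o[2] + 8)
  t2 <- act_time(o[1], o[2] + 16)
  expect_true(t0 < t1 && t1 < t2)
  # full quiescence between beats
  per_frame <- apply(dat > 0.01, 1, sum)
  expect_gt(sum(per_frame == 0), 50)
  # the guard refuses colliding parameters
  expect_error(focal_movie(cycle_ms = 40, n_beats = 3, dims = c(64, 64),
                           cv_mm_per_ms = 0.3), "quiescence")
})

test_that("reaction-diffusion: target wave, isochrones, stability guard", {
  spec <- rd_spec(dims = c(40, 40), n_ms = 260,
                  stimuli = list(list(t_ms = 5, type = "point",
                                      row = 20, col = 20, radius_px = 3)))
  mv <- rd_simulate(spec)
  act <- apply(mv$data > 0.5, c(2, 3), function(x) if (any(x)) which(x)[1] else NA)
  # concentric isochrones: activation time increases with radius
  expect_true(act[20, 30] > act[20, 24])
  expect_true(act[20, 36] > act[20, 30])
  # rough isotropy: same radius, similar time
  expect_lt(abs(act[20, 32] - act[32, 20]) / act[20, 32], 0.15)
  # plane-wave conduction speed constant to +-10% mid-domain
  spec2 <- rd_spec(dims = c(40, 60), n_ms = 400,
                   stimuli = list(list(t_ms = 0, type = "bar", cols = 1:3)))
  mv2 <- rd_simulate(spec2)
  act2 <- apply(mv2$data[, 20, ] > 0.5, 2, function(x) if (any(x)) which(x)[1] else NA)
  sp <- 1 / diff(act2[c(15, 25, 35, 45)]) * 10       # px per ms over 10-px spans
  expect_lt(max(abs(sp - mean(sp))) / mean(sp), 0.1)
  expect_error(rd_spec(dt_tu = 0.5), "unstable")
})

test_that("cross-field protocol sustains reentry that the pipeline calls a rotor", {
  spec <- rd_spiral_spec(dims = c(64, 48), n_ms = 700)
  mv <- rd_simulate(spec)
  # activity persists long after the stimuli
  expect_gt(mean(mv$data[650:700, , ] > 0.5), 0.005)
  res <- run_pipeline(mv)
  expect_gte(sum(vapply(res$tracks, function(tk) isTRUE(tk$is_rotor), logical(1))), 1)
})

test_that("two-layer: decoupled silence and breakthrough provenance", {
  spec0 <- two_layer_spec(n_connections = 0, dims = c(48, 40), n_ms = 400)
  tl0 <- two_layer_simulate(spec0)
  expect_equal(max(abs(tl0$epi$data)), 0)
  expect_identical(nrow(tl0$truth$focal_events), 0L)

  spec1 <- two_layer_spec(n_connections = 1, dims = c(64, 48), n_ms = 600, seed = 3)
  tl1 <- two_layer_simulate(spec1)
  bt <- tl1$truth$focal_events
  expect_gte(nrow(bt), 1)
  conn <- tl1$truth$params$connection_sites
  expect_true(all(bt$row == conn[1] & bt$col == conn[2]))
  # the epi sheet is actually captured (wave spreads beyond the footprint)
  expect_gt(max(apply(tl1$epi$data > 0.5, 1, mean)), 0.1)
})

test_that("fibrosis edges respect fraction and longitudinal bias", {
  set.seed(2)
  e <- fibwave:::fibrosis_edges(c(60, 60), fraction = 0.1,
                                longitudinal_bias = 4, seed = 10)
  f_h <- mean(e$eh == 0); f_v <- mean(e$ev == 0)
  tot <- (sum(e$eh == 0) + sum(e$ev == 0)) / (length(e$eh) + length(e$ev))
  expect_equal(tot, 0.1, tolerance = 0.02)
  expect_gt(f_h / f_v, 2.5)      # ~4x with sampling noise
  e0 <- fibwave:::fibrosis_edges(c(20, 20), fraction = 0)
  expect_true(all(e0$eh == 1) && all(e0$ev == 1))
})

test_that("optical noise hits the requested SNR and drift toggles off", {
  g <- analytic_spiral_movie(10, c(20, 25), 400, dims = c(40, 50))
  for (snr in c(20, 40)) {
    n <- add_optical_noise(g$movie, snr, seed = 9)
    resid <- n$data - g$movie$data
    got <- 10 * log10(var(as.vector(g$movie$data)) / var(as.vector(resid)))
    expect_lt(abs(got - snr), 1)
  }
  n0 <- add_optical_noise(g$movie, 30, drift_amp = 0, seed = 9)
  nd <- add_optical_noise(g$movie, 30, drift_amp = 0.5, drift_hz = 1, seed = 9)
  # drift adds low-frequency power: per-pixel means spread out
  expect_gt(sd(apply(nd$data, c(2, 3), mean)), 5 * sd(apply(n0$data, c(2, 3), mean)))
})
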