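# Topological charge, singularity detection, tracking, rotations, maps.

test_that("topological charge of analytic vortices has the right winding", {
  H <- 30; W <- 36
  rr <- matrix(seq_len(H), H, W); cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  th <- wrap_oracle(atan2(rr - 15, cc - 18))
  ch <- topological_charge(th)
  expect_equal(ch[15, 18], 2 * pi, tolerance = 1e-9)
  expect_lt(max(abs(ch[c(3, 27), c(3, 33)])), 1e-6)   # far field ~ 0
  ch2 <- topological_charge(wrap_oracle(-atan2(rr - 15, cc - 18)))
  expect_equal(ch2[15, 18], -2 * pi, tolerance = 1e-9)
})

test_that("charge map equals the loop-walk oracle on random smooth fields", {
  for (s in 1:10) {
    f <- random_smooth_phase(20, 18, seed = s)
    expect_equal(topological_charge(f), brute_charge(f), tolerance = 1e-10)
  }
  # and on fields that contain genuine vortices
  for (s in 1:5) {
    f <- random_vortex_phase(24, 22, seed = s)
    expect_equal(topological_charge(f), brute_charge(f), tolerance = 1e-10)
  }
})

test_that("detect_ps: single vortex, plane wave, opposite-chirality pair", {
  g <- analytic_spiral_movie(10, c(16, 20), 5, dims = c(32, 40))
  ps <- detect_ps(g$phase$phase[1, , ])
  expect_identical(nrow(ps), 1L)
  expect_lt(sqrt((ps$row - 16)^2 + (ps$col - 20)^2), 1)
  expect_identical(ps$chirality, 1L)

  pw <- wrap_oracle(outer(rep(0, 30), 0.25 * (1:40), "+"))
  expect_identical(nrow(detect_ps(pw)), 0L)

  # two opposite vortices 20 px apart (argument of a product of complex
  # vortices; cores off-lattice so no sample sits on the singular point)
  H <- 40; W <- 44
  rr <- matrix(seq_len(H), H, W); cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  z <- ((cc - 12.5) + 1i * (rr - 20.5)) * Conj((cc - 32.5) + 1i * (rr - 20.5))
  f <- matrix(Arg(z), H, W)
  ps2 <- detect_ps(wrap_oracle(f))
  expect_identical(nrow(ps2), 2L)
  expect_identical(sum(ps2$chirality), 0L)
  d1 <- min(sqrt((ps2$row - 20.5)^2 + (ps2$col - 12.5)^2))
  d2 <- min(sqrt((ps2$row - 20.5)^2 + (ps2$col - 32.5)^2))
  expect_lt(d1, 1); expect_lt(d2, 1)
})

test_that("detect_ps equals the brute-force rule on charged random fields", {
  for (s in 1:10) {
    f <- random_vortex_phase(26, 24, seed = 100 + s)
    ch <- topological_charge(f)
    got <- detect_ps(f, 3.0, refine = FALSE)
    want <- brute_detect_ps(ch, 3.0)
    if (is.null(want)) {
      expect_identical(nrow(got), 0L)
    } else {
      expect_identical(nrow(got), nrow(want))
      o1 <- order(got$px_row, got$px_col); o2 <- order(want[, 1], want[, 2])
      expect_identical(got$px_row[o1], as.integer(want[o2, 1]))
      expect_identical(got$px_col[o1], as.integer(want[o2, 2]))
      expect_identical(got$chirality[o1], as.integer(want[o2, 3]))
    }
  }
})

test_that("tracking: persistence, motion, and distance gating", {
  # stationary singularity for 100 frames
  det <- data.frame(row = 20, col = 20, px_row = 20L, px_col = 20L,
                    chirality = 1L, charge_residual = 0.1, frame = 1:100)
  tr <- track_ps(det)
  expect_length(tr, 1)
  expect_identical(nrow(tr[[1]]$points), 100L)

  # steady drift at 0.5 px/frame
  det2 <- data.frame(row = 10 + 0.5 * (0:59), col = 12, px_row = 10L,
                     px_col = 12L, chirality = -1L, charge_residual = 0.2,
                     frame = 1:60)
  tr2 <- track_ps(det2, link_px = 5)
  expect_length(tr2, 1)
  expect_equal(mean(diff(tr2[[1]]$points$row)), 0.5, tolerance = 1e-9)

  # two same-chirality singularities 30 px apart never cross-link
  det3 <- rbind(data.frame(row = 10, col = 10, px_row = 10L, px_col = 10L,
                           chirality = 1L, charge_residual = 0, frame = 1:50),
                data.frame(row = 40, col = 10, px_row = 40L, px_col = 10L,
                           chirality = 1L, charge_residual = 0, frame = 1:50))
  tr3 <- track_ps(det3, link_px = 5)
  expect_length(tr3, 2)
  expect_true(all(vapply(tr3, function(tk) sd(tk$points$row) == 0, logical(1))))

  # opposite chirality at same location -> separate tracks
  det4 <- rbind(data.frame(row = 10, col = 10, px_row = 10L, px_col = 10L,
                           chirality = 1L, charge_residual = 0, frame = 1:10),
                data.frame(row = 10.5, col = 10, px_row = 10L, px_col = 10L,
                           chirality = -1L, charge_residual = 0, frame = 1:10))
  expect_length(track_ps(det4), 2)

  # gap handling: a 1-frame dropout kills a track at gap 0, not at gap 1
  det5 <- data.frame(row = 20, col = 20, px_row = 20L, px_col = 20L,
                     chirality = 1L, charge_residual = 0, frame = c(1:10, 12:20))
  expect_length(track_ps(det5, gap_frames = 0L), 2)
  expect_length(track_ps(det5, gap_frames = 1L), 1)
})

test_that("rotation counting matches observation time x frequency", {
  # 10 Hz spiral watched for 3 periods -> ~3 rotations, a rotor
  g <- analytic_spiral_movie(10, c(20, 25), 300, dims = c(40, 50))
  tr <- track_ps(detect_ps_movie(g$phase))
  expect_length(tr, 1)
  tk <- count_rotations(tr[[1]], g$phase)
  expect_equal(tk$rotations, 3, tolerance = 0.1)
  expect_true(tk$is_rotor)
  # cumulative rotations are monotone and end at the total
  expect_true(all(diff(tk$points$cum_rotations) >= -1e-9))
  expect_equal(max(tk$points$cum_rotations), tk$rotations, tolerance = 1e-6)

  # 0.4 periods -> not a rotor
  g2 <- analytic_spiral_movie(10, c(20, 25), 40, dims = c(40, 50))
  tk2 <- count_rotations(track_ps(detect_ps_movie(g2$phase))[[1]], g2$phase)
  expect_equal(tk2$rotations, 0.4, tolerance = 0.1)
  expect_false(tk2$is_rotor)

  # static vortex field: a spatial singularity with no temporal advance
  H <- 40; W <- 50
  rr <- matrix(seq_len(H), H, W); cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  f <- wrap_oracle(atan2(rr - 20, cc - 25))
  ph <- phase_movie(array(rep(f, 50), c(H, W, 50)) |> aperm(c(3, 1, 2)))
  tk3 <- count_rotations(track_ps(detect_ps_movie(ph))[[1]], ph)
  expect_lt(tk3$rotations, 0.05)
})

test_that("density maps and rates follow their definitions", {
  pts <- data.frame(frame = 1:100, row = 15, col = 22, charge_residual = 0)
  tk <- structure(list(points = pts, chirality = 1L, birth_frame = 1L,
                       death_frame = 100L, rotations = 5, is_rotor = TRUE),
                  class = "ps_track")
  maps <- ps_density_maps(list(tk), dims = c(30, 30), n_frames = 100)
  expect_equal(maps$trajectory$counts[15, 22], 100)
  expect_equal(sum(maps$trajectory$counts), 100)
  expect_equal(maps$initiation$counts[15, 22], 1)
  expect_equal(maps$annihilation$counts[15, 22], 1)
  empty <- ps_density_maps(list(), dims = c(30, 30), n_frames = 100)
  expect_equal(sum(empty$trajectory$counts), 0)

  # one PS in every frame over exactly 1 cm^2, dt 1 ms
  mask <- matrix(TRUE, 20, 20)
  pitch <- 0.5                    # 400 px * (0.5 mm / 10)^2 = 1 cm^2
  r <- ps_rate(list(tk), mask, n_frames = 100, dt = 1, pitch = pitch)
  expect_equal(r$area_cm2, 1)
  expect_equal(r$rate_total, 1)
  expect_equal(r$rate_rotor, 1)
  expect_equal(r$rate_short, 0)
  expect_equal(ps_rate(list(), mask, 100, 1, 4.4)$rate_total, 0)
  expect_error(ps_rate(list(), matrix(FALSE, 3, 3), 100), "area")
})

test_that("meandering rotor trajectory mass concentrates on the true path", {
  Tn <- 400
  ang <- 2 * pi * (0:(Tn - 1)) / 200
  core <- cbind(24 + 5 * cos(ang), 20 + 5 * sin(ang))
  g <- analytic_spiral_movie(10, core, Tn, dims = c(48, 40))
  tr <- track_ps(detect_ps_movie(g$phase))
  maps <- ps_density_maps(tr, dims = c(48, 40), n_frames = Tn)
  ij <- which(maps$trajectory$counts > 0, arr.ind = TRUE)
  w <- maps$trajectory$counts[ij]
  d <- sqrt((ij[, 1] - 24)^2 + (ij[, 2] - 20)^2)
  # >= 90% of trajectory mass within 3 px of the radius-5 meander circle
  expect_gte(sum(w[abs(d - 5) <= 3]) / sum(w), 0.9)
})

test_that("chirality sum over a boundary-uniform field is zero", {
  for (s in 1:6) {
    f <- random_vortex_phase(28, 26, seed = 300 + s)
    ps <- detect_ps(f)
    if (nrow(ps)) expect_identical(sum(ps$chirality), 0L)
  }
})

test_that("detection is stable under phase noise after smoothing", {
  g <- analytic_spiral_movie(10, c(20, 25), 40, dims = c(40, 50))
  set.seed(17)
  hit <- 0L
  for (t in 1:40) {
    f <- wrap_oracle(g$phase$phase[t, , ] + matrix(rnorm(2000, 0, 0.2), 40, 50))
    sm <- smooth_phase(f, 9L)
    ps <- detect_ps(sm)
    if (nrow(ps) >= 1 &&
        min(sqrt((ps$row - 20)^2 + (ps$col - 25)^2)) <= 1) hit <- hit + 1L
  }
  expect_gte(hit / 40, 0.95)
})
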