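# Isophase activity, component labelling, new-wavefront detection and
# classification, density maps, preferential sites, cycle lengths.

test_that("isophase rule matches the brute-force oracle", {
  # plane wave: linear phase across columns
  pw <- wrap_oracle(outer(rep(0, 24), seq(-pi + 0.05, pi - 0.05, length.out = 30), "+"))
  got <- isophase_pixels(pw)
  expect_identical(got, brute_isophase(pw, -pi / 2, 0.5))
  ij <- which(got, arr.ind = TRUE)
  expect_gt(nrow(ij), 0)
  expect_lte(diff(range(ij[, 2])), 2)               # a 1-2 px wide band
  expect_true(all(pw[ij] >= -pi / 2 - 0.5 & pw[ij] <= -pi / 2))

  # uniform field exactly at theta: no qualifying neighbours
  u <- matrix(-pi / 2, 10, 10)
  expect_false(any(isophase_pixels(u)))

  # analytic spiral frame equals the oracle, with and without a mask
  g <- analytic_spiral_movie(10, c(16, 20), 3, dims = c(32, 40))
  f <- g$phase$phase[2, , ]
  expect_identical(isophase_pixels(f), brute_isophase(f, -pi / 2, 0.5))
  set.seed(31)
  mask <- matrix(runif(32 * 40) > 0.2, 32, 40)
  expect_identical(isophase_pixels(f, mask = mask),
                   brute_isophase(f, -pi / 2, 0.5, mask))

  # random fields
  for (s in 1:8) {
    fr <- random_smooth_phase(18, 16, seed = 40 + s, amp = 2.5)
    expect_identical(isophase_pixels(fr), brute_isophase(fr, -pi / 2, 0.5))
  }
  expect_error(isophase_pixels(f, theta = pi - 0.1), "branch cut")
})

test_that("wavefront labelling equals flood fill and filters small parts", {
  set.seed(12)
  for (s in 1:6) {
    a <- matrix(runif(30 * 28) < 0.3, 30, 28)
    expect_identical(label_wavefronts(a), brute_flood_fill(a))
  }
  two <- matrix(FALSE, 10, 20); two[3, 2:6] <- TRUE; two[8, 12:17] <- TRUE
  expect_identical(max(label_wavefronts(two)), 2L)
  expect_identical(max(label_wavefronts(matrix(FALSE, 5, 5))), 0L)
  one_px <- matrix(FALSE, 8, 8); one_px[2, 2] <- TRUE; one_px[6, 4:7] <- TRUE
  lab <- label_wavefronts(one_px, min_component_px = 2L)
  expect_identical(max(lab), 1L)
  expect_identical(lab[2, 2], 0L)
})

test_that("new/propagated labelling follows the dilation rule", {
  H <- 20; W <- 30
  empty <- matrix(FALSE, H, W)
  onset <- empty; onset[10, 14:16] <- TRUE
  # focal onset after total quiescence: everything new
  expect_true(all(detect_new_wavefronts(onset, empty, 3L)[onset]))

  # plane wave advancing 1 px/frame: all propagated
  prev <- empty; prev[, 10] <- TRUE
  cur <- empty; cur[, 11] <- TRUE
  expect_false(any(detect_new_wavefronts(cur, prev, 3L)))

  # an existing front plus a distant second front
  far <- cur; far[10, 25] <- TRUE
  nl <- detect_new_wavefronts(far, prev, 3L)
  expect_true(nl[10, 25])
  expect_false(any(nl[, 11]))

  # equals the per-pixel neighbourhood oracle on random masks, and
  # monotone in radius
  set.seed(77)
  for (s in 1:5) {
    a1 <- matrix(runif(H * W) < 0.15, H, W)
    a0 <- matrix(runif(H * W) < 0.15, H, W)
    for (rad in c(1L, 3L)) {
      got <- detect_new_wavefronts(a1, a0, rad)
      want <- matrix(FALSE, H, W)
      for (r in 1:H) for (c in 1:W) {
        if (!a1[r, c]) next
        any_prev <- FALSE
        for (dr in -rad:rad) for (dc in -rad:rad) {
          r2 <- r + dr; c2 <- c + dc
          if (r2 >= 1 && r2 <= H && c2 >= 1 && c2 <= W && a0[r2, c2])
            any_prev <- TRUE
        }
        want[r, c] <- !any_prev
      }
      expect_identical(got & a1, want)
    }
    n1 <- sum(detect_new_wavefronts(a1, a0, 1L))
    n5 <- sum(detect_new_wavefronts(a1, a0, 5L))
    expect_lte(n5, n1)
  }
})

test_that("three-way classification matches the published scenarios", {
  H <- 12; W <- 12
  comp <- matrix(FALSE, H, W); comp[6, 5:7] <- TRUE
  all_new <- matrix(TRUE, H, W)
  # other fronts existed in the previous frame -> new during existing AF
  expect_identical(classify_wavefront(comp, all_new, prev_frame_active_count = 8L),
                   "new_existing_AF")
  # empty previous frame -> new after quiescence
  expect_identical(classify_wavefront(comp, all_new, prev_frame_active_count = 0L),
                   "new_after_quiescence")
  # continuation of a prior band -> propagated
  expect_identical(classify_wavefront(comp, !all_new, prev_frame_active_count = 5L),
                   "propagated")
  # pixel-majority with tie toward new
  half <- matrix(FALSE, H, W); half[6, 5] <- TRUE
  mixed <- comp & FALSE; mixed[6, 5] <- TRUE; mixed[6, 6] <- TRUE
  labels <- matrix(FALSE, H, W); labels[6, 5] <- TRUE
  expect_identical(classify_wavefront(mixed, labels, 3L), "new_existing_AF")
})

test_that("every active pixel is labeled exactly once (new xor propagated)", {
  g <- analytic_spiral_movie(10, c(16, 20), 30, dims = c(32, 40))
  for (t in 2:5) {
    a1 <- isophase_pixels(g$phase$phase[t, , ])
    a0 <- isophase_pixels(g$phase$phase[t - 1, , ])
    nl <- detect_new_wavefronts(a1, a0, 3L)
    expect_true(all(xor(nl[a1], !nl[a1])))   # partition of the active set
    expect_false(any(nl & !a1))
  }
})

test_that("density maps count one unit of mass per event", {
  ev <- data.frame(frame = 1:20, component_id = 1L, wf_class = "new_existing_AF",
                   centroid_row = 7, centroid_col = 9, n_pixels = 1L)
  ev$pixels <- replicate(20, cbind(7L, 9L), simplify = FALSE)
  attr(ev, "dims") <- c(16L, 16L)
  m <- nwf_density_map(ev)
  expect_equal(sum(m$counts), 20)
  expect_equal(m$counts[7, 9], 20)
  m2 <- nwf_density_map(ev[0, ], dims = c(16, 16))
  expect_equal(sum(m2$counts), 0)
  # propagated events contribute nothing
  ev$wf_class <- "propagated"
  expect_equal(sum(nwf_density_map(ev)$counts), 0)
})

test_that("site finding: cluster, uniform control, two clusters", {
  H <- 96; W <- 96
  mk_events <- function(rows, cols) {
    ev <- data.frame(frame = seq_along(rows) * 10, component_id = 1L,
                     wf_class = "new_after_quiescence",
                     centroid_row = rows, centroid_col = cols,
                     n_pixels = 1L)
    ev$pixels <- lapply(seq_along(rows),
                        function(i) cbind(as.integer(round(rows[i])),
                                          as.integer(round(cols[i]))))
    attr(ev, "dims") <- c(H, W); attr(ev, "dt") <- 1
    ev
  }
  set.seed(55)
  ev1 <- mk_events(rnorm(50, 20, 1.2), rnorm(50, 24, 1.2))
  s1 <- find_nwf_sites(nwf_density_map(ev1), ev1)
  expect_length(s1, 1)
  expect_lt(sqrt((s1[[1]]$centroid[1] - 20)^2 + (s1[[1]]$centroid[2] - 24)^2), 1.5)
  expect_gte(s1[[1]]$event_count, 45)

  # spatially uniform random events (no two sharing a neighbourhood by
  # chance at this density): no preferential site at the stated threshold
  set.seed(5)
  ev2 <- mk_events(runif(20, 3, 94), runif(20, 3, 94))
  expect_length(find_nwf_sites(nwf_density_map(ev2), ev2), 0)

  set.seed(57)
  ev3 <- mk_events(c(rnorm(30, 20, 1), rnorm(30, 70, 1)),
                   c(rnorm(30, 20, 1), rnorm(30, 70, 1)))
  expect_length(find_nwf_sites(nwf_density_map(ev3), ev3), 2)
})

test_that("site cycle lengths include harmonic gaps", {
  site <- structure(list(pixels = cbind(5L, 5L), centroid = c(5, 5),
                         event_count = 4L, event_frames = c(1L, 81L, 161L, 241L),
                         cycle_lengths_ms = c(80, 80, 80)),
                    class = "nwf_site")
  expect_equal(site_cycle_lengths(site), c(80, 80, 80))
  # a skipped initiation shows as a harmonic of the base cycle length
  ev <- data.frame(frame = c(1L, 81L, 241L), component_id = 1L,
                   wf_class = "new_after_quiescence",
                   centroid_row = 5, centroid_col = 5, n_pixels = 1L)
  ev$pixels <- replicate(3, cbind(5L, 5L), simplify = FALSE)
  attr(ev, "dt") <- 1
  expect_equal(site_cycle_lengths(site, ev), c(80, 160))
  one <- ev[1, , drop = FALSE]
  expect_length(site_cycle_lengths(site, one), 0)
})
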