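# Instantaneous phase: pseudo-empirical-mean envelope normalization,
# Hilbert-transform phase, and circular spatial smoothing.
#
# Sign convention (fixed by tests): phase 0 at signal maxima, +-pi at
# minima, -pi/2 mid-upstroke. For cos(w t) the phase is w t, so a
# depolarization wavefront sits near the -pi/2 isophase line.

#' Detect sliding-window extrema with amplitude-pair rejection
#'
#' A sample is a local maximum (minimum) if it is the extremum of the
#' centred window; flat runs collapse to their middle sample. Consecutive
#' (maximum, minimum) pairs whose amplitude falls below
#' `amp_reject_frac` times the median pair amplitude are deleted (both
#' members), and alternation is restored by keeping the more extreme member
#' of any same-type run.
#'
#' @param trace numeric vector (one pixel's signal).
#' @param window_frames centred window length in frames (>= 3).
#' @param amp_reject_frac rejection threshold as a fraction of the median
#'   pair amplitude (default 0.15).
#' @return an `extrema_set`: list with `maxima` and `minima` data frames
#'   (`frame`, `value`), `window_frames`, `amp_threshold`.
#' @export
detect_extrema <- function(trace, window_frames, amp_reject_frac = 0.15) {
  window_frames <- as.integer(window_frames)
  if (window_frames < 3L) stop("`window_frames` must be >= 3", call. = FALSE)
  X <- matrix(trace, ncol = 1L)
  rmax <- rolling_extreme_mat(X, window_frames, "max")[, 1L]
  rmin <- rolling_extreme_mat(X, window_frames, "min")[, 1L]
  ex <- pair_extrema(trace, which(trace == rmax & local_peak(trace, "max")),
                     which(trace == rmin & local_peak(trace, "min")),
                     window_frames, amp_reject_frac)
  structure(ex, class = "extrema_set")
}

# TRUE where a sample is also a 3-point local extremum (both neighbours
# defined and not exceeding it). Filters out record endpoints sitting on
# monotone segments, which the truncated centred window would otherwise
# flag as extrema.
local_peak <- function(x, what) {
  Tn <- length(x)
  ok <- logical(Tn)
  if (Tn < 3L) return(ok)
  i <- 2:(Tn - 1L)
  ok[i] <- if (what == "max") x[i] >= x[i - 1L] & x[i] >= x[i + 1L]
           else x[i] <= x[i - 1L] & x[i] <= x[i + 1L]
  ok
}

# Collapse runs of consecutive indices to their middle element.
collapse_runs <- function(idx) {
  if (length(idx) == 0L) return(integer())
  brk <- c(0L, which(diff(idx) > 1L), length(idx))
  vapply(seq_len(length(brk) - 1L), function(i) {
    run <- idx[(brk[i] + 1L):brk[i + 1L]]
    run[(length(run) + 1L) %/% 2L]
  }, integer(1))
}

# Keep the more extreme member of any same-type run so maxima and minima
# alternate in time.
enforce_alternation <- function(ev) {
  if (nrow(ev) < 2L) return(ev)
  keep <- rep(TRUE, nrow(ev))
  i <- 1L
  while (i < nrow(ev)) {
    j <- i
    while (j < nrow(ev) && ev$type[j + 1L] == ev$type[i]) j <- j + 1L
    if (j > i) {
      run <- i:j
      best <- if (ev$type[i] == 1L) run[which.max(ev$value[run])]
              else run[which.min(ev$value[run])]
      keep[setdiff(run, best)] <- FALSE
    }
    i <- j + 1L
  }
  ev <- ev[keep, , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Envelope-normalize a trace to approximately [-1, 1]
#'
#' Upper and lower envelopes are natural cubic splines through the maxima
#' and minima respectively, held constant beyond the end extrema. Output is
#' `2 (s - L) / (U - L) - 1`; samples where `U - L` degenerates (below
#' 1e-6 of the trace range) are set to 0.
#'
#' @param trace numeric vector.
#' @param extrema an `extrema_set` from [detect_extrema()].
#' @return zero-centred normalized trace.
#' @export
envelope_normalize <- function(trace, extrema) {
  if (nrow(extrema$maxima) < 2L || nrow(extrema$minima) < 2L)
    stop("pixel excluded: need >= 2 maxima and >= 2 minima", call. = FALSE)
  Tn <- length(trace)
  U <- spline_env(extrema$maxima$frame, extrema$maxima$value, Tn)
  L <- spline_env(extrema$minima$frame, extrema$minima$value, Tn)
  span <- U - L
  eps <- 1e-6 * diff(range(trace))
  out <- ifelse(span < eps, 0, 2 * (trace - L) / span - 1)
  out
}

spline_env <- function(xk, yk, Tn) {
  f <- stats::splinefun(xk, yk, method = "natural")
  t <- seq_len(Tn)
  v <- f(pmin(pmax(t, min(xk)), max(xk)))  # constant extension past end knots
  v
}

#' Instantaneous phase via the Hilbert transform
#'
#' Computes the analytic signal `s + i H{s}` by the FFT half-spectrum
#' method and returns its argument wrapped to `(-pi, pi]`. The trace is
#' demeaned first (the method presupposes a zero-mean signal).
#'
#' @param trace numeric vector, all samples finite.
#' @return phase series in `(-pi, pi]`.
#' @export
hilbert_phase <- function(trace) {
  if (any(!is.finite(trace))) stop("non-finite samples in trace", call. = FALSE)
  z <- analytic_signal_mat(matrix(trace - mean(trace), ncol = 1L))[, 1L]
  wrap_pi(Arg(z))
}

# Analytic signal of each column of a real T x N matrix (FFT method).
analytic_signal_mat <- function(X) {
  Tn <- nrow(X)
  F <- stats::mvfft(X)
  w <- numeric(Tn)
  if (Tn %% 2L == 0L) {
    w[1L] <- 1; w[Tn / 2 + 1L] <- 1; w[2:(Tn / 2)] <- 2
  } else {
    w[1L] <- 1; w[2:((Tn + 1L) / 2)] <- 2
  }
  stats::mvfft(F * w, inverse = TRUE) / Tn
}

#' Smooth a phase field across the branch cut
#'
#' The phase is mapped to its exponential form `exp(i theta)`, averaged
#' with a mask-aware `bin x bin` uniform window, and the argument of the
#' complex mean is returned (the magnitude is discarded). This is the
#' circular mean, so values straddling +-pi never average toward 0.
#'
#' @param phase `phase_movie`, or a bare `H x W` matrix (single frame).
#' @param bin odd window size (default 9).
#' @param mask optional mask when `phase` is a matrix.
#' @return same type as the input, smoothed.
#' @export
smooth_phase <- function(phase, bin = 9L, mask = NULL) {
  bin <- as.integer(bin)
  if (bin %% 2L == 0L || bin < 1L) stop("`bin` must be odd and >= 1", call. = FALSE)
  if (inherits(phase, "phase_movie")) {
    out <- phase$phase
    for (t in seq_len(dim(out)[1])) {
      out[t, , ] <- smooth_phase_frame(phase$phase[t, , ], bin, phase$mask)
    }
    return(phase_movie(out, dt = phase$dt, pitch = phase$pitch,
                       mask = phase$mask, meta = phase$meta))
  }
  if (is.null(mask)) mask <- matrix(TRUE, nrow(phase), ncol(phase))
  smooth_phase_frame(phase, bin, mask)
}

smooth_phase_frame <- function(ph, bin, mask) {
  if (bin == 1L) return(ph)
  re <- box_mean_masked(cos(ph), mask, bin)
  im <- box_mean_masked(sin(ph), mask, bin)
  out <- wrap_pi(atan2(im, re))
  out[!mask] <- ph[!mask]
  out
}

#' Compute a smoothed phase movie from a conditioned voltage movie
#'
#' Per-pixel: sliding-window extrema (window = `extrema_window_frac` of the
#' mean cycle length), envelope normalization, Hilbert phase; then spatial
#' circular smoothing with the configured bin. Pixels with too few extrema
#' are dropped from the mask.
#'
#' @param movie conditioned [voltage_movie()].
#' @param mean_df_hz mean dominant frequency (Hz), defining the cycle length.
#' @param config a [run_config()].
#' @return a [phase_movie()] (mask possibly shrunken); per-pixel QC counts
#'   in `meta$qc`.
#' @export
compute_phase <- function(movie, mean_df_hz, config = run_config()) {
  d <- dim(movie$data)
  Tn <- d[1]
  cl_frames <- (1000 / mean_df_hz) / movie$dt
  w <- max(3L, round(config$extrema_window_frac * cl_frames))
  idx <- which(movie$mask)
  X <- matrix(movie$data[, , ], nrow = Tn)[, idx, drop = FALSE]
  # vectorized rolling extrema across all pixels, then per-pixel pairing
  rmax <- rolling_extreme_mat(X, w, "max")
  rmin <- rolling_extreme_mat(X, w, "min")
  Z <- matrix(NA_real_, Tn, length(idx))
  ok <- logical(length(idx))
  n_max <- integer(length(idx))
  for (j in seq_along(idx)) {
    x <- X[, j]
    ex <- pair_extrema(x, which(x == rmax[, j] & local_peak(x, "max")),
                       which(x == rmin[, j] & local_peak(x, "min")),
                       w, config$amp_reject_frac)
    n_max[j] <- nrow(ex$maxima)
    if (nrow(ex$maxima) < 2L || nrow(ex$minima) < 2L) next
    Z[, j] <- envelope_normalize(x, ex)
    ok[j] <- TRUE
  }
  mask <- movie$mask
  mask[idx[!ok]] <- FALSE
  ph <- matrix(pi, Tn, length(idx))
  if (any(ok)) {
    A <- analytic_signal_mat(Z[, ok, drop = FALSE] -
                               matrix(colMeans(Z[, ok, drop = FALSE]),
                                      Tn, sum(ok), byrow = TRUE))
    ph[, ok] <- wrap_pi(Arg(A))
  }
  M <- matrix(pi, Tn, d[2] * d[3])
  M[, idx] <- ph
  pm <- phase_movie(array(M, d), dt = movie$dt, pitch = movie$pitch, mask = mask,
                    meta = c(movie$meta, list(qc = list(n_maxima = n_max,
                                                        excluded = sum(!ok)))))
  smooth_phase(pm, bin = config$spatial_bin)
}

# Same pairing/rejection logic as detect_extrema, reusing precomputed
# rolling-extrema hits (pipeline fast path; vector-based for speed).
pair_extrema <- function(x, hit_max, hit_min, window_frames, amp_reject_frac) {
  mx <- collapse_runs(hit_max)
  mn <- collapse_runs(hit_min)
  fr <- c(mx, mn)
  ty <- c(rep(1L, length(mx)), rep(-1L, length(mn)))
  o <- order(fr)
  fr <- fr[o]; ty <- ty[o]; vl <- x[fr]
  alt <- alternate_vec(fr, vl, ty)
  fr <- alt$fr; vl <- alt$vl; ty <- alt$ty
  thr <- 0
  n <- length(fr)
  if (n >= 2L) {
    pr <- which(ty[-n] == 1L & ty[-1L] == -1L)
    if (length(pr)) {
      amps <- abs(vl[pr] - vl[pr + 1L])
      thr <- amp_reject_frac * stats::median(amps)
      drop <- pr[amps < thr]
      if (length(drop)) {
        keep <- setdiff(seq_len(n), c(drop, drop + 1L))
        alt <- alternate_vec(fr[keep], vl[keep], ty[keep])
        fr <- alt$fr; vl <- alt$vl; ty <- alt$ty
      }
    }
  }
  list(maxima = data.frame(frame = fr[ty == 1L], value = vl[ty == 1L]),
       minima = data.frame(frame = fr[ty == -1L], value = vl[ty == -1L]),
       window_frames = window_frames, amp_threshold = thr)
}

# Vector version of enforce_alternation.
alternate_vec <- function(fr, vl, ty) {
  n <- length(fr)
  if (n < 2L) return(list(fr = fr, vl = vl, ty = ty))
  grp <- cumsum(c(1L, diff(ty) != 0L))
  keep <- logical(n)
  for (g in unique(grp)) {
    run <- which(grp == g)
    best <- if (ty[run[1L]] == 1L) run[which.max(vl[run])] else run[which.min(vl[run])]
    keep[best] <- TRUE
  }
  list(fr = fr[keep], vl = vl[keep], ty = ty[keep])
}
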