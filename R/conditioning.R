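# Signal conditioning: mask-aware spatial binning, dominant-frequency
# estimation, zero-phase FIR band-pass filtering, drift removal and
# normalization. Movies are T x H x W with frames first; per-pixel traces
# are handled as columns of a T x N matrix (N = mask pixels).

#' Mask-aware spatial uniform filter
#'
#' Replaces each frame by the uniform mean over a `bin x bin` window.
#' Windows are renormalized by the count of valid in-window pixels, so
#' tissue borders do not bleed zeros in; masked-out pixels are excluded
#' from neighbours' averages and pass through unchanged.
#'
#' @param movie a [voltage_movie()].
#' @param bin odd window size in pixels (default 9).
#' @return a filtered [voltage_movie()].
#' @export
spatial_filter <- function(movie, bin = 9L) {
  stopifnot(inherits(movie, "voltage_movie"))
  bin <- as.integer(bin)
  if (bin < 1L || bin %% 2L == 0L) stop("`bin` must be odd and >= 1", call. = FALSE)
  if (bin == 1L) return(movie)
  out <- movie$data
  for (t in seq_len(dim(out)[1])) {
    out[t, , ] <- box_mean_masked(movie$data[t, , ], movie$mask, bin)
  }
  voltage_movie(out, dt = movie$dt, pitch = movie$pitch, mask = movie$mask,
                meta = c(movie$meta, list(spatial_bin = bin)))
}

#' Per-pixel dominant frequency map
#'
#' The dominant frequency (DF) of a pixel is the frequency of maximal
#' power-spectral density within the search band, estimated from the
#' demeaned, Hann-tapered trace zero-padded to at least 4x the record
#' length (spectral bin well under 1 Hz for 1 s records at 1 kHz).
#'
#' @param movie a [voltage_movie()].
#' @param band length-2 numeric, search band in Hz (default `c(2, 50)`).
#' @return an object of class `df_map` with fields `values` (H x W, Hz; NA
#'   outside the mask), `band`, and `mean_df` (mask-restricted mean).
#' @export
dominant_frequency <- function(movie, band = c(2, 50)) {
  stopifnot(inherits(movie, "voltage_movie"))
  d <- dim(movie$data)
  fs <- 1000 / movie$dt
  if (band[1] <= 0 || band[2] <= band[1] || band[2] >= fs / 2)
    stop("search band must satisfy 0 < low < high < Nyquist", call. = FALSE)
  dur_s <- d[1] * movie$dt / 1000
  if (dur_s < 2 / band[1])
    stop("movie duration must cover >= 2 cycles of the band's low edge", call. = FALSE)
  Tn <- d[1]
  nfft <- next_pow2(4L * Tn)
  freqs <- (seq_len(nfft) - 1L) * fs / nfft
  sel <- which(freqs >= band[1] & freqs <= band[2])
  taper <- 0.5 * (1 - cos(2 * pi * seq_len(Tn) / (Tn + 1)))
  vals <- matrix(NA_real_, d[2], d[3])
  idx <- which(movie$mask)
  X <- matrix(movie$data[, , ], nrow = Tn)[, idx, drop = FALSE]
  chunk <- max(1L, floor(2^26 / nfft))
  starts <- seq(1L, ncol(X), by = chunk)
  df_pix <- numeric(ncol(X))
  for (s in starts) {
    cols <- s:min(s + chunk - 1L, ncol(X))
    B <- X[, cols, drop = FALSE]
    B <- sweep(B, 2L, colMeans(B)) * taper
    B <- rbind(B, matrix(0, nfft - Tn, length(cols)))
    P <- Mod(stats::mvfft(B))^2
    df_pix[cols] <- freqs[sel[max.col(t(P[sel, , drop = FALSE]))]]
  }
  vals[idx] <- df_pix
  structure(list(values = vals, band = band, mean_df = mean(df_pix)),
            class = "df_map")
}

#' @export
print.df_map <- function(x, ...) {
  cat(sprintf("<df_map> mean DF %.2f Hz over band [%g, %g] Hz\n",
              x$mean_df, x$band[1], x$band[2]))
  invisible(x)
}

#' Design a linear-phase FIR band-pass filter
#'
#' Kaiser windowed-sinc design. The -6 dB cut-offs sit mid-transition:
#' the lower stop-band edge is at `low/2` and the upper at `high + trans_hi`
#' by default, so that forward-backward application attenuates a `low/2`
#' component by well over 20 dB. The impulse response is symmetric, hence
#' exactly linear-phase.
#'
#' @param low,high pass-band edges in Hz.
#' @param fs sampling rate in Hz.
#' @param n_taps odd filter length; derived from the transition width and
#'   `atten_db` when `NULL`.
#' @param atten_db single-pass stop-band attenuation target in dB.
#' @return numeric vector of taps (odd length), class `fir_filter` with
#'   attributes `fs`, `low`, `high`.
#' @export
design_fir_bandpass <- function(low, high, fs, n_taps = NULL, atten_db = 30) {
  if (!(low > 0 && high > low && high < fs / 2))
    stop("need 0 < low < high < Nyquist", call. = FALSE)
  trans_lo <- low / 2            # stop-band edge at low/2
  trans_hi <- max(high / 2, trans_lo)
  if (is.null(n_taps)) {
    dw <- 2 * pi * trans_lo / fs
    n_taps <- ceiling((atten_db - 7.95) / (2.285 * dw))
    if (n_taps %% 2L == 0L) n_taps <- n_taps + 1L
  }
  n_taps <- as.integer(n_taps)
  if (n_taps %% 2L == 0L) n_taps <- n_taps + 1L
  A <- atten_db
  beta <- if (A > 50) 0.1102 * (A - 8.7)
          else if (A >= 21) 0.5842 * (A - 21)^0.4 + 0.07886 * (A - 21)
          else 0
  M <- n_taps - 1L
  n <- seq(0L, M) - M / 2
  fc1 <- low - trans_lo / 2      # -6 dB points mid-transition
  fc2 <- high + trans_hi / 2
  sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))
  h <- 2 * fc2 / fs * sinc(2 * fc2 * n / fs) - 2 * fc1 / fs * sinc(2 * fc1 * n / fs)
  w <- besselI(beta * sqrt(pmax(0, 1 - (2 * n / M)^2)), 0) / besselI(beta, 0)
  h <- h * w
  # unit gain at band centre (geometric mean frequency)
  f0 <- sqrt(fc1 * fc2)
  g <- Mod(fir_response(h, f0, fs))
  structure(h / g, class = "fir_filter", fs = fs, low = low, high = high)
}

#' Evaluate the complex frequency response of an FIR filter
#'
#' @param h filter taps.
#' @param f frequencies in Hz (vector).
#' @param fs sampling rate in Hz.
#' @return complex response at each frequency. For forward-backward (zero
#'   phase) application the effective magnitude response is `Mod(...)^2`.
#' @export
fir_response <- function(h, f, fs) {
  k <- seq_along(h) - 1L
  vapply(f, function(fi) sum(h * exp(-2i * pi * fi * k / fs)), complex(1))
}

# Forward-backward (zero-phase) FIR filtering of the columns of X,
# with odd reflection padding; FFT-based convolution, chunked over columns.
zero_phase_filter_mat <- function(X, h) {
  Tn <- nrow(X)
  P <- length(h)
  g <- stats::convolve(h, rev(h), type = "open")  # h conv h, length 2P-1, centre P
  pad <- min(P, Tn - 1L)
  nfull <- Tn + 2L * pad
  nf <- next_pow2(nfull + 2L * P)
  G <- stats::fft(c(g, rep(0, nf - length(g))))
  out <- X
  chunk <- max(1L, floor(2^25 / nf))
  for (s in seq(1L, ncol(X), by = chunk)) {
    cols <- s:min(s + chunk - 1L, ncol(X))
    B <- X[, cols, drop = FALSE]
    top <- 2 * B[rep(1L, pad), , drop = FALSE] - B[pad + 1L - seq_len(pad) + 1L, , drop = FALSE]
    bot <- 2 * B[rep(Tn, pad), , drop = FALSE] - B[Tn - seq_len(pad), , drop = FALSE]
    Bp <- rbind(top, B, bot, matrix(0, nf - nfull, length(cols)))
    Y <- Re(stats::mvfft(stats::mvfft(Bp) * G, inverse = TRUE)) / nf
    # conv centre offset: g is centred at index P
    out[, cols] <- Y[pad + seq_len(Tn) + (P - 1L), , drop = FALSE]
  }
  out
}

#' Zero-phase temporal band-pass filter
#'
#' Applies a linear-phase FIR band-pass (see [design_fir_bandpass()])
#' forward and backward to every in-mask pixel trace, yielding exactly zero
#' group delay. Edges are odd-reflection padded.
#'
#' @param movie a [voltage_movie()].
#' @param low,high band edges in Hz.
#' @param n_taps optional explicit filter length. When `NULL` the design
#'   length is used but capped at `floor(T/3)` (odd) for short records,
#'   with a warning (the transition band widens accordingly). An explicit
#'   `n_taps` longer than `T/3` is an error.
#' @return a filtered [voltage_movie()]; the filter taps are attached as
#'   attribute `"fir"`.
#' @export
temporal_bandpass <- function(movie, low, high, n_taps = NULL) {
  stopifnot(inherits(movie, "voltage_movie"))
  d <- dim(movie$data)
  fs <- 1000 / movie$dt
  if (!(low > 0 && high > low && high < fs / 2))
    stop("need 0 < low < high < Nyquist", call. = FALSE)
  if (!is.null(n_taps) && d[1] < 3L * n_taps)
    stop("movie shorter than 3x the filter length", call. = FALSE)
  h <- design_fir_bandpass(low, high, fs, n_taps = n_taps)
  cap <- max(5L, (d[1] %/% 3L) - (1L - (d[1] %/% 3L) %% 2L))
  if (is.null(n_taps) && length(h) > cap) {
    warning(sprintf("record too short for the %d-tap design; capping at %d taps (wider transition)",
                    length(h), cap), call. = FALSE)
    h <- design_fir_bandpass(low, high, fs, n_taps = cap)
  }
  idx <- which(movie$mask)
  Tn <- d[1]
  X <- matrix(movie$data[, , ], nrow = Tn)[, idx, drop = FALSE]
  Y <- zero_phase_filter_mat(X, unclass(h))
  M <- matrix(movie$data[, , ], nrow = Tn)
  M[, idx] <- Y
  out <- array(M, d)
  res <- voltage_movie(out, dt = movie$dt, pitch = movie$pitch, mask = movie$mask,
                       meta = c(movie$meta, list(band_hz = c(low, high))))
  attr(res, "fir") <- h
  res
}

#' Remove baseline drift and normalize to [0, 1]
#'
#' Per pixel: subtract a centred moving-mean trend whose window spans two
#' mean cycle lengths, then min-max rescale to `[0, 1]`. Pixels with a
#' constant trace are removed from the mask with a warning rather than
#' propagating NaN.
#'
#' @param movie a [voltage_movie()].
#' @param mean_df_hz mean dominant frequency (Hz) defining the cycle length;
#'   required unless `window_frames` is given.
#' @param window_frames explicit trend window in frames (overrides
#'   `mean_df_hz`).
#' @return a [voltage_movie()] with data in `[0, 1]` (possibly shrunken mask).
#' @export
remove_baseline_normalize <- function(movie, mean_df_hz = NULL, window_frames = NULL) {
  stopifnot(inherits(movie, "voltage_movie"))
  d <- dim(movie$data)
  Tn <- d[1]
  if (is.null(window_frames)) {
    if (is.null(mean_df_hz)) stop("supply `mean_df_hz` or `window_frames`", call. = FALSE)
    window_frames <- round(2 * (1000 / mean_df_hz) / movie$dt)
  }
  w <- max(3L, min(as.integer(window_frames), Tn))
  hb <- (w - 1L) %/% 2L
  idx <- which(movie$mask)
  X <- matrix(movie$data[, , ], nrow = Tn)[, idx, drop = FALSE]
  cs <- apply(rbind(0, X), 2L, cumsum)
  lo <- pmax(seq_len(Tn) - hb, 1L)
  hi <- pmin(seq_len(Tn) + hb, Tn)
  trend <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1L)
  Y <- X - trend
  rng_lo <- apply(Y, 2L, min)
  rng_hi <- apply(Y, 2L, max)
  span <- rng_hi - rng_lo
  const <- span <= 1e-12 * pmax(1, abs(rng_hi) + abs(rng_lo))
  mask <- movie$mask
  if (any(const)) {
    warning(sum(const), " constant trace(s) removed from mask", call. = FALSE)
    mask[idx[const]] <- FALSE
  }
  keep <- !const
  Y[, keep] <- sweep(sweep(Y[, keep, drop = FALSE], 2L, rng_lo[keep]), 2L,
                     span[keep], "/")
  Y[, const] <- 0
  M <- matrix(movie$data[, , ], nrow = Tn)
  M[, idx] <- Y
  out <- array(M, d)
  voltage_movie(out, dt = movie$dt, pitch = movie$pitch, mask = mask,
                meta = c(movie$meta, list(normalized = TRUE)))
}

#' Full conditioning chain
#'
#' Spatial filter, provisional DF estimate (drift-insensitive thanks to
#' demeaning + taper), drift removal with a window of two mean cycle
#' lengths, final DF map, band-pass from `band_low_hz` to
#' `band_high_frac x mean DF`, then normalization.
#'
#' @param movie a raw [voltage_movie()].
#' @param config a [run_config()].
#' @return list with elements `movie` (conditioned), `df` (final `df_map`),
#'   and `fir` (taps used).
#' @export
condition_movie <- function(movie, config = run_config()) {
  m <- spatial_filter(movie, config$spatial_bin)
  # a record of duration D can only resolve frequencies >= 2 cycles / D;
  # raise the search floor accordingly for short records
  dur_s <- dim(movie$data)[1] * movie$dt / 1000
  band <- config$df_band_hz
  band[1] <- max(band[1], 2 / dur_s)
  df0 <- dominant_frequency(m, band = band)
  m <- remove_baseline_normalize(m, mean_df_hz = df0$mean_df)
  df <- dominant_frequency(m, band = band)
  high <- min(config$band_high_frac * df$mean_df, 0.95 * (500 / movie$dt))
  m <- suppressWarnings(temporal_bandpass(m, config$band_low_hz, high))
  fir <- attr(m, "fir")
  m <- remove_baseline_normalize(m, mean_df_hz = df$mean_df)
  list(movie = m, df = df, fir = fir)
}
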