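# Independent brute-force oracles and small field builders used across the
# suite. Oracles deliberately use naive loop implementations so they share
# no code path with the package internals they check.

wrap_oracle <- function(x) {
  y <- x
  while (any(y > pi)) y[y > pi] <- y[y > pi] - 2 * pi
  while (any(y <= -pi)) y[y <= -pi] <- y[y <= -pi] + 2 * pi
  y
}

# Loop-walk topological charge: explicit path integral around the
# 8-neighbour ring of each interior pixel.
brute_charge <- function(ph, mask = NULL) {
  H <- nrow(ph); W <- ncol(ph)
  if (is.null(mask)) mask <- matrix(TRUE, H, W)
  path <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1),
               c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1))
  out <- matrix(0, H, W)
  for (r in 2:(H - 1)) for (c in 2:(W - 1)) {
    ok <- mask[r, c]
    for (o in path) ok <- ok && mask[r + o[1], c + o[2]]
    if (!ok) next
    s <- 0
    for (k in seq_along(path)) {
      o1 <- path[[k]]; o2 <- path[[if (k == 8) 1 else k + 1]]
      s <- s + wrap_oracle(ph[r + o2[1], c + o2[2]] - ph[r + o1[1], c + o1[2]])
    }
    out[r, c] <- s
  }
  out
}

# Brute-force per-pixel application of the candidate / actual-singularity
# rules on a charge map.
brute_detect_ps <- function(charge, tol) {
  H <- nrow(charge); W <- ncol(charge)
  sgn <- ifelse(charge >= 0, 1L, -1L)
  resid <- abs(abs(charge) - 2 * pi)
  cand <- matrix(FALSE, H, W)
  for (r in 1:H) for (c in 1:W) {
    cand[r, c] <- abs(charge[r, c]) > 1e-9 &&
      abs(charge[r, c] - sgn[r, c] * 2 * pi) <= tol
  }
  hits <- NULL
  for (r in 1:H) for (c in 1:W) {
    if (!cand[r, c]) next
    n_same <- 0L; best <- TRUE
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > H || c2 < 1 || c2 > W) next
      if (cand[r2, c2] && sgn[r2, c2] == sgn[r, c]) {
        n_same <- n_same + 1L
        rm1 <- (r - 1) * W + c; rm2 <- (r2 - 1) * W + c2
        if (resid[r2, c2] < resid[r, c] ||
            (resid[r2, c2] == resid[r, c] && rm2 < rm1)) best <- FALSE
      }
    }
    if (n_same >= 3L && best) hits <- rbind(hits, c(r, c, sgn[r, c]))
  }
  hits
}

# Brute-force isophase rule: in-band + 1..3 of the four adjacent
# neighbours strictly greater than theta.
brute_isophase <- function(ph, theta, band, mask = NULL) {
  H <- nrow(ph); W <- ncol(ph)
  if (is.null(mask)) mask <- matrix(TRUE, H, W)
  out <- matrix(FALSE, H, W)
  for (r in 1:H) for (c in 1:W) {
    if (!mask[r, c]) next
    if (ph[r, c] < theta - band || ph[r, c] > theta) next
    cnt <- 0L
    for (o in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      r2 <- r + o[1]; c2 <- c + o[2]
      if (r2 < 1 || r2 > H || c2 < 1 || c2 > W) next
      if (mask[r2, c2] && ph[r2, c2] > theta) cnt <- cnt + 1L
    }
    out[r, c] <- cnt >= 1L && cnt <= 3L
  }
  out
}

# Naive O(H W bin^2) mask-aware windowed mean.
brute_box_mean <- function(m, mask, bin) {
  H <- nrow(m); W <- ncol(m); h <- (bin - 1) %/% 2
  out <- m
  for (r in 1:H) for (c in 1:W) {
    if (!mask[r, c]) next
    s <- 0; n <- 0L
    for (dr in -h:h) for (dc in -h:h) {
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > H || c2 < 1 || c2 > W) next
      if (mask[r2, c2]) { s <- s + m[r2, c2]; n <- n + 1L }
    }
    out[r, c] <- s / n
  }
  out
}

# Brute-force flood-fill 8-connected labelling.
brute_flood_fill <- function(active) {
  H <- nrow(active); W <- ncol(active)
  lab <- matrix(0L, H, W); k <- 0L
  for (r in 1:H) for (c in 1:W) {
    if (!active[r, c] || lab[r, c] > 0L) next
    k <- k + 1L
    queue <- list(c(r, c)); lab[r, c] <- k
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      for (dr in -1:1) for (dc in -1:1) {
        r2 <- p[1] + dr; c2 <- p[2] + dc
        if (r2 >= 1 && r2 <= H && c2 >= 1 && c2 <= W &&
            active[r2, c2] && lab[r2, c2] == 0L) {
          lab[r2, c2] <- k
          queue[[length(queue) + 1L]] <- c(r2, c2)
        }
      }
    }
  }
  lab
}

# Frequency-domain analytic signal built independently (explicit loop over
# DFT bins rather than the packaged half-spectrum weighting).
oracle_phase <- function(x) {
  n <- length(x)
  X <- stats::fft(x - mean(x))
  Y <- complex(real = numeric(n), imaginary = numeric(n))
  for (k in 0:(n - 1)) {
    if (k == 0) Y[k + 1] <- X[k + 1]
    else if (n %% 2 == 0 && k == n / 2) Y[k + 1] <- X[k + 1]
    else if (k < n / 2) Y[k + 1] <- 2 * X[k + 1]
    else Y[k + 1] <- 0
  }
  z <- stats::fft(Y, inverse = TRUE) / n
  atan2(Im(z), Re(z))
}

# Smooth random phase field: a few 2-D Fourier modes, wrapped.
random_smooth_phase <- function(H, W, seed, n_modes = 4, amp = 1.2) {
  set.seed(seed)
  f <- matrix(0, H, W)
  rr <- matrix(seq_len(H), H, W); cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  for (i in seq_len(n_modes)) {
    kx <- runif(1, -0.25, 0.25); ky <- runif(1, -0.25, 0.25)
    f <- f + runif(1, 0.3, amp) * sin(kx * cc + ky * rr + runif(1, 0, 2 * pi))
  }
  wrap_oracle(f)
}

# Random phase field containing a deliberate vortex pair plus smooth
# background (exercises nonzero charges).
random_vortex_phase <- function(H, W, seed) {
  set.seed(seed)
  r1 <- runif(1, 0.25 * H, 0.45 * H); c1 <- runif(1, 0.25 * W, 0.75 * W)
  r2 <- runif(1, 0.55 * H, 0.75 * H); c2 <- runif(1, 0.25 * W, 0.75 * W)
  rr <- matrix(seq_len(H), H, W); cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  f <- atan2(rr - r1, cc - c1) - atan2(rr - r2, cc - c2) +
    0.4 * sin(0.11 * cc + 0.07 * rr)
  wrap_oracle(f)
}

# Pearson correlation by the direct covariance sums.
brute_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  (n * sum(x * y) - sx * sy) /
    sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2))
}

# Exact Mood p-value by full enumeration of 2x2 tables with fixed margins.
brute_mood_exact <- function(x, y) {
  m <- stats::median(c(x, y))
  ax <- sum(x > m); ay <- sum(y > m)
  nx <- sum(x != m); ny <- sum(y != m)
  N <- nx + ny; R1 <- ax + ay
  if (N == 0 || R1 == 0 || R1 == N || nx == 0 || ny == 0) return(list(stat = 0, p = 1))
  chi <- function(a) {
    O <- c(a, nx - a, R1 - a, ny - R1 + a)
    E <- c(R1 * nx, (N - R1) * nx, R1 * ny, (N - R1) * ny) / N
    sum((O - E)^2 / E)
  }
  obs <- chi(ax)
  tot <- choose(N, R1)
  p <- 0
  for (a in max(0, R1 - ny):min(nx, R1)) {
    if (chi(a) >= obs - 1e-12) {
      p <- p + choose(nx, a) * choose(ny, R1 - a) / tot
    }
  }
  list(stat = obs, p = p)
}
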