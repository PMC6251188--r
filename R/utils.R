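# Internal numerical helpers shared across modules.

#' Wrap angles to (-pi, pi]
#'
#' @param x numeric vector/array of angles in radians.
#' @return angles wrapped to the half-open interval (-pi, pi].
#' @keywords internal
wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  # %% maps to [-pi, pi); fold the lower endpoint onto +pi
  y[y <= -pi] <- pi
  y
}

# Shift a matrix by (dr, dc); vacated cells take `fill`.
shift_mat <- function(m, dr, dc, fill = 0) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  rs <- max(1, 1 + dr):min(H, H + dr)
  cs <- max(1, 1 + dc):min(W, W + dc)
  if (length(rs) && length(cs)) {
    out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  }
  out
}

# Windowed box sum with truncated windows at the borders (integral image).
# Window is bin x bin centred on each pixel, bin odd.
box_sum_mat <- function(m, bin) {
  h <- (bin - 1L) %/% 2L
  H <- nrow(m); W <- ncol(m)
  S <- matrix(0, H + 1L, W + 1L)
  S[-1L, -1L] <- apply(apply(m, 2L, cumsum), 1L, cumsum) |> t()
  r1 <- pmax(seq_len(H) - h - 1L, 0L) + 1L
  r2 <- pmin(seq_len(H) + h, H) + 1L
  c1 <- pmax(seq_len(W) - h - 1L, 0L) + 1L
  c2 <- pmin(seq_len(W) + h, W) + 1L
  S[r2, c2] - S[r1, c2] - S[r2, c1] + S[r1, c1]
}

# Mask-aware uniform mean: masked-out pixels are excluded from neighbours'
# averages and returned unchanged themselves.
box_mean_masked <- function(m, mask, bin) {
  if (bin == 1L) return(m)
  mm <- m
  mm[!mask] <- 0
  s <- box_sum_mat(mm, bin)
  n <- box_sum_mat(mask + 0, bin)
  out <- m
  ok <- mask & n > 0
  out[ok] <- s[ok] / n[ok]
  out
}

# Centred rolling max/min over time for a T x N matrix, via doubling spans
# (sparse-table style: O(log w) pmax passes). Truncates at record ends.
rolling_extreme_mat <- function(X, window, what = c("max", "min")) {
  what <- match.arg(what)
  Tn <- nrow(X)
  w <- min(window, Tn)
  hb <- (w - 1L) %/% 2L         # back half
  hf <- w - 1L - hb             # forward half
  cmb <- if (what == "max") pmax else pmin
  pad <- if (what == "max") -Inf else Inf
  shift_rows <- function(M, k) {
    # shift forward in time by k rows (k>0: value from t-k)
    out <- matrix(pad, nrow(M), ncol(M))
    if (k >= 0) {
      if (k < nrow(M)) out[(k + 1L):nrow(M), ] <- M[1L:(nrow(M) - k), , drop = FALSE]
    } else {
      k <- -k
      if (k < nrow(M)) out[1L:(nrow(M) - k), ] <- M[(k + 1L):nrow(M), , drop = FALSE]
    }
    out
  }
  # suffix-style doubling: R[t] = extreme over [t, t+span-1]
  span <- 1L
  Rm <- X
  while (span < w) {
    step <- min(span, w - span)
    Rm <- cmb(Rm, shift_rows(Rm, -step))
    span <- span + step
  }
  # Rm[t] = extreme over [t, min(t+w-1, T)]; centred window starts at t-hb
  out <- shift_rows(Rm, hb)
  # top rows: window truncated at start; recompute from spans anchored at 1
  if (hb > 0L) {
    for (t in seq_len(min(hb, Tn))) {
      out[t, ] <- apply(X[1L:min(t + hf, Tn), , drop = FALSE], 2L,
                        if (what == "max") max else min)
    }
  }
  out
}

# 8-connected component labelling of a logical matrix: two-pass union-find
# over row runs. Returns an integer matrix (0 = background, components
# numbered 1..k in row-major order of their first pixel).
label_components <- function(active) {
  H <- nrow(active); W <- ncol(active)
  out <- matrix(0L, H, W)
  if (!any(active)) return(out)
  parent <- integer(0)
  uf_find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  run_row <- integer(0); run_s <- integer(0); run_e <- integer(0)
  prev_ids <- integer(0)
  for (r in seq_len(H)) {
    v <- active[r, ]
    cur_ids <- integer(0)
    if (any(v)) {
      rl <- rle(v)
      ends <- cumsum(rl$lengths)
      starts <- ends - rl$lengths + 1L
      ts <- starts[rl$values]; te <- ends[rl$values]
      for (k in seq_along(ts)) {
        id <- length(parent) + 1L
        parent[id] <- id
        run_row[id] <- r; run_s[id] <- ts[k]; run_e[id] <- te[k]
        # 8-connectivity: overlap with previous-row runs extended by 1
        for (p in prev_ids) {
          if (run_e[p] >= ts[k] - 1L && run_s[p] <= te[k] + 1L) {
            rp <- uf_find(p); rc <- uf_find(id)
            if (rp != rc) parent[max(rp, rc)] <- min(rp, rc)
          }
        }
        cur_ids <- c(cur_ids, id)
      }
    }
    prev_ids <- cur_ids
  }
  roots <- vapply(seq_along(parent), uf_find, integer(1))
  # renumber roots in row-major order of first run (runs were created in
  # (row, start-col) order, i.e. row-major)
  first <- !duplicated(roots)
  renum <- integer(length(parent))
  renum[roots[first]] <- seq_len(sum(first))
  lab_of_run <- renum[roots]
  for (id in seq_along(parent)) {
    out[run_row[id], run_s[id]:run_e[id]] <- lab_of_run[id]
  }
  out
}

# Evaluate a seeded expression without disturbing the global RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Next power of two >= n (FFT sizing).
next_pow2 <- function(n) 2^ceiling(log2(max(n, 1)))
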