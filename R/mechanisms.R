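# Mechanism inference: per-frame activity summaries, the rotor-sustained
# vs new-wavefront-sustained classification rule, density-map stability
# correlation, and Mood's median test for cycle-length comparisons.

#' Per-frame activity series
#'
#' Counts, per frame: detected singularities, rotors (tracks alive whose
#' cumulative rotation already exceeds one), and active isophase pixels.
#' Quiescent frames are frames with zero active pixels.
#'
#' @param phase a [phase_movie()].
#' @param tracks list of `ps_track` with per-frame cumulative rotations
#'   (see [count_rotations()]).
#' @param events a `wavefront_events` table (carries the active-pixel
#'   series as an attribute).
#' @return object of class `mechanism_report`: list with `n_ps`, `n_rotor`,
#'   `active_px` (integer series), `quiescent_frames`, `dt`.
#' @export
activity_series <- function(phase, tracks, events) {
  Tn <- dim(phase$phase)[1]
  n_ps <- integer(Tn)
  n_rotor <- integer(Tn)
  for (tk in tracks) {
    fr <- tk$points$frame
    n_ps[fr] <- n_ps[fr] + 1L
    cum <- tk$points$cum_rotations
    if (!is.null(cum)) {
      n_rotor[fr[cum > 1]] <- n_rotor[fr[cum > 1]] + 1L
    } else if (isTRUE(tk$is_rotor)) {
      n_rotor[fr] <- n_rotor[fr] + 1L
    }
  }
  active <- attr(events, "active_count")
  if (is.null(active)) active <- integer(Tn)
  structure(list(n_ps = n_ps, n_rotor = n_rotor, active_px = active,
                 quiescent_frames = which(active == 0L), dt = phase$dt),
            class = "mechanism_report")
}

#' @export
print.mechanism_report <- function(x, ...) {
  cat(sprintf("<mechanism_report> %d frames | mean PS %.2f | rotor frames %.0f%% | quiescent %.1f%%\n",
              length(x$n_ps), mean(x$n_ps), 100 * mean(x$n_rotor > 0),
              100 * length(x$quiescent_frames) / length(x$n_ps)))
  invisible(x)
}

#' Classify the sustaining mechanism of a recording
#'
#' Formalizes the activity-trace reasoning: fibrillation is
#' `nwf_sustained` when episodes of electrical quiescence occur (quiescent
#' fraction above `quiesc_frac`) and at least `site_frac` of quiescence
#' exits are initiated by a new wavefront from a detected preferential site
#' (first new event within `attr_ms` of the exit); `rotor_sustained` when a
#' rotor is present in at least `rotor_frac` of frames and quiescence is
#' absent (fraction at most `quiesc_frac`); otherwise `mixed`.
#'
#' @param report a `mechanism_report`.
#' @param events the `wavefront_events` table.
#' @param sites list of `nwf_site` from [find_nwf_sites()].
#' @param site_frac,attr_ms,rotor_frac,quiesc_frac rule thresholds
#'   (defaults 0.5, 20 ms, 0.8, 0.01).
#' @return list with `label` (`"rotor_sustained"`, `"nwf_sustained"`,
#'   `"mixed"`), `restart_attributions` (per-site fractions of quiescence
#'   exits), `n_exits`, `rotor_fraction`, `quiescent_fraction`.
#' @export
classify_mechanism <- function(report, events, sites,
                               site_frac = 0.5, attr_ms = 20,
                               rotor_frac = 0.8, quiesc_frac = 0.01) {
  Tn <- length(report$active_px)
  dt <- report$dt
  q <- report$active_px == 0L
  quiescent_fraction <- mean(q)
  rotor_fraction <- mean(report$n_rotor > 0)
  # quiescence exits: first active frame after a quiescent frame
  exits <- which(!q & c(FALSE, q[-Tn]))
  nwf <- events[events$wf_class != "propagated", , drop = FALSE]
  site_attr <- numeric(length(sites))
  attributed <- 0L
  if (length(exits) && length(sites)) {
    site_keys <- lapply(sites, function(s) paste(s$pixels[, 1], s$pixels[, 2]))
    for (e in exits) {
      win <- nwf[nwf$frame >= e & (nwf$frame - e) * dt <= attr_ms, , drop = FALSE]
      if (!nrow(win)) next
      first <- win[which.min(win$frame), , drop = FALSE]
      # centroid hit, else any-pixel overlap (annular fronts)
      keys <- c(paste(round(first$centroid_row), round(first$centroid_col)),
                paste(first$pixels[[1]][, 1], first$pixels[[1]][, 2]))
      for (k in seq_along(sites)) {
        if (any(keys %in% site_keys[[k]])) {
          site_attr[k] <- site_attr[k] + 1
          attributed <- attributed + 1L
          break
        }
      }
    }
  }
  n_exits <- length(exits)
  restart_attributions <- if (n_exits > 0) site_attr / n_exits else site_attr
  label <- if (n_exits > 0 && quiescent_fraction > quiesc_frac &&
               attributed / n_exits >= site_frac) {
    "nwf_sustained"
  } else if (rotor_fraction >= rotor_frac && quiescent_fraction <= quiesc_frac) {
    "rotor_sustained"
  } else "mixed"
  list(label = label, restart_attributions = restart_attributions,
       n_exits = n_exits, rotor_fraction = rotor_fraction,
       quiescent_fraction = quiescent_fraction)
}

#' Pearson correlation between two density maps
#'
#' Computed over mask-true pixels on raw counts (no smoothing).
#'
#' @param mapA,mapB `density_map`s of identical shape.
#' @param mask optional logical mask.
#' @return Pearson r; `NA` with attribute `flagged = TRUE` when either map
#'   has zero variance over the mask.
#' @export
map_correlation <- function(mapA, mapB, mask = NULL) {
  a <- mapA$counts; b <- mapB$counts
  stopifnot(identical(dim(a), dim(b)))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(a), ncol(a))
  x <- a[mask]; y <- b[mask]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance over mask; correlation undefined", call. = FALSE)
    return(structure(NA_real_, flagged = TRUE))
  }
  stats::cor(x, y)
}

#' Mood's median test
#'
#' Tests equality of medians of two samples: counts above vs not-above the
#' grand median of the pooled data form a 2 x 2 table (values equal to the
#' grand median are dropped); the chi-square statistic (1 df, no continuity
#' correction) is computed, and the p-value comes from exact enumeration of
#' all tables with the observed margins (hypergeometric) whenever any
#' expected cell count is below 5, otherwise from the chi-square
#' distribution.
#'
#' @param x,y numeric samples (nonempty).
#' @return list of class `htest`-like: `statistic`, `p.value`, `table`,
#'   `grand_median`, `method`.
#' @export
moods_median_test <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be nonempty", call. = FALSE)
  m <- stats::median(c(x, y))
  ax <- sum(x > m); ay <- sum(y > m)
  nx <- sum(x != m); ny <- sum(y != m)
  tab <- matrix(c(ax, nx - ax, ay, ny - ay), 2L, 2L,
                dimnames = list(c("above", "not_above"), c("x", "y")))
  R1 <- ax + ay; N <- nx + ny
  if (N == 0L || R1 == 0L || R1 == N || nx == 0L || ny == 0L) {
    return(structure(list(statistic = 0, p.value = 1, table = tab,
                          grand_median = m, method = "degenerate"),
                     class = "moods_test"))
  }
  chi_of <- function(a) {
    E <- outer(c(R1, N - R1), c(nx, ny)) / N
    O <- matrix(c(a, nx - a, R1 - a, ny - R1 + a), 2L, 2L)
    sum((O - E)^2 / E)
  }
  stat <- chi_of(ax)
  E <- outer(c(R1, N - R1), c(nx, ny)) / N
  # exact enumeration whenever it is cheap (small pooled sample) or the
  # chi-square approximation is unsafe (any expected cell < 5)
  if (any(E < 5) || N <= 40) {
    lo <- max(0L, R1 - ny); hi <- min(nx, R1)
    a_all <- lo:hi
    pr <- stats::dhyper(a_all, nx, ny, R1)
    stats <- vapply(a_all, chi_of, numeric(1))
    p <- sum(pr[stats >= stat - 1e-12])
    method <- "exact enumeration"
  } else {
    p <- stats::pchisq(stat, df = 1L, lower.tail = FALSE)
    method <- "chi-square approximation"
  }
  structure(list(statistic = stat, p.value = min(p, 1), table = tab,
                 grand_median = m, method = method),
            class = "moods_test")
}

#' @export
print.moods_test <- function(x, ...) {
  cat(sprintf("Mood's median test: chi-square = %.4f, p = %.4g (%s)\n",
              x$statistic, x$p.value, x$method))
  print(x$table)
  invisible(x)
}
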