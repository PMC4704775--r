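#' Delay-embedding parameters
#'
#' Phase-space reconstruction uses `m` lagged copies of the signal at delay
#' `tau` samples.  The defaults (`m = 4`, `tau = 8`) are the values found to
#' work well for 9-second VF segments; `tau` must be large enough that the
#' lagged sample carries new information, but not so large that the system
#' appears memoryless.
#'
#' @param m Embedding dimension (default 4).
#' @param tau Delay in samples (default 8).
#' @return An `embedding_params` list.
#' @export
embedding_params <- function(m = 4, tau = 8) {
  m <- as.integer(m); tau <- as.integer(tau)
  if (m < 1L || tau < 1L) stop("m and tau must be >= 1", call. = FALSE)
  structure(list(m = m, tau = tau), class = "embedding_params")
}

#' Reconstruct a delay-coordinate trajectory
#'
#' Point `k` of the trajectory has coordinates
#' `(p[k + (m-1)*tau], p[k + (m-2)*tau], ..., p[k])`, i.e. the most recent
#' sample first; the trajectory has `N - (m-1)*tau` points for an `N`-sample
#' segment.
#'
#' @param seg A [signal_segment()].
#' @param params An [embedding_params()].
#' @return A `trajectory`: list with `points` (matrix, one row per point),
#'   `m`, `tau`, `source_rate`.
#' @export
#' @examples
#' seg <- signal_segment(rnorm(100), 250)
#' nrow(embed_delay(seg)$points)  # 100 - 3 * 8 = 76
embed_delay <- function(seg, params = embedding_params()) {
  stopifnot(inherits(seg, "vf_segment"), inherits(params, "embedding_params"))
  p <- seg$samples
  n <- length(p)
  m <- params$m; tau <- params$tau
  span <- (m - 1L) * tau
  if (n <= span) {
    stop(sprintf("segment too short to embed: need > %d samples, have %d",
                 span, n), call. = FALSE)
  }
  npts <- n - span
  pts <- vapply(seq_len(m), function(d) p[seq_len(npts) + (m - d) * tau],
                numeric(npts))
  if (npts == 1L) pts <- matrix(pts, nrow = 1L)
  structure(list(points = pts, m = m, tau = tau,
                 source_rate = seg$sampling_rate),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d points in %d dims (tau = %d, rate = %g Hz)\n",
              nrow(x$points), x$m, x$tau, x$source_rate))
  invisible(x)
}

# Bounding-box diagonal of the reconstructed attractor: O(N) and scale-aware.
attractor_diameter <- function(traj) {
  rngs <- apply(traj$points, 2L, function(col) diff(range(col)))
  sqrt(sum(rngs^2))
}

# Nearest neighbour (Euclidean, temporal exclusion window, distance > 0)
# for each trajectory point, computed in row blocks to bound memory.
nearest_neighbours <- function(X, min_separation, block = 512L) {
  n <- nrow(X)
  sq <- rowSums(X^2)
  nn <- integer(n)
  nn_d2 <- numeric(n)
  for (lo in seq(1L, n, by = block)) {
    hi <- min(lo + block - 1L, n)
    idx <- lo:hi
    d2 <- outer(sq[idx], sq, `+`) - 2 * tcrossprod(X[idx, , drop = FALSE], X)
    d2[d2 < 0] <- 0
    rel <- outer(idx, seq_len(n), function(i, j) abs(i - j) <= min_separation)
    d2[rel | d2 == 0] <- Inf
    nn[idx] <- max.col(-d2, ties.method = "first")
    nn_d2[idx] <- d2[cbind(seq_along(idx), nn[idx])]
  }
  list(index = nn, dist2 = nn_d2)
}

#' Maximal Lyapunov exponent of a trajectory
#'
#' Rosenstein-style estimator, suited to short noisy series: every point is
#' paired with its nearest neighbour outside a temporal exclusion window, the
#' mean log divergence of the pairs is tracked over `fit_range` steps, and
#' the exponent is the least-squares slope of that curve converted to 1/s via
#' the source rate.  A positive value indicates exponential divergence of
#' nearby states, the operational signature of chaos; periodic signals give
#' values near zero.
#'
#' @param traj A [embed_delay()] trajectory with at least 50 points.
#' @param min_separation Temporal exclusion window in samples when picking
#'   nearest neighbours (default `m * tau`).
#' @param fit_range Number of divergence steps used for the slope fit
#'   (default 50).
#' @param fit_start First divergence step of the fit window (default 0).
#'   Skipping the earliest steps avoids the initial neighbour transient on
#'   long, clean series; the default fits from the origin, which suits
#'   short noisy segments.
#' @return The exponent in 1/s, with the per-step mean log-divergence curve
#'   attached as attribute `divergence`.
#' @export
max_lyapunov <- function(traj, min_separation = traj$m * traj$tau,
                         fit_range = 50, fit_start = 0) {
  stopifnot(inherits(traj, "trajectory"))
  X <- traj$points
  n <- nrow(X)
  if (n < 50L) stop("need at least 50 trajectory points", call. = FALSE)
  if (attractor_diameter(traj) == 0) {
    stop("degenerate trajectory: all points identical", call. = FALSE)
  }
  nn <- nearest_neighbours(X, min_separation)
  usable <- which(is.finite(nn$dist2))
  if (length(usable) < 10L) {
    stop("degenerate trajectory: no usable neighbour pairs", call. = FALSE)
  }
  fit_range <- min(as.integer(fit_range), n - 2L)
  fit_start <- max(0L, min(as.integer(fit_start), fit_range - 2L))
  # fixed pair set over the whole window: pairs dropping out mid-window
  # would drift the composition of the mean and bias the slope
  usable <- usable[usable + fit_range <= n &
                     nn$index[usable] + fit_range <= n]
  if (length(usable) < 10L) {
    stop("too few neighbour pairs survive the fit window", call. = FALSE)
  }
  ks <- fit_start:fit_range
  mean_log_d <- vapply(ks, function(k) {
    d2 <- rowSums((X[usable + k, , drop = FALSE] -
                     X[nn$index[usable] + k, , drop = FALSE])^2)
    d2 <- pmax(d2, .Machine$double.xmin)
    mean(0.5 * log(d2))
  }, 0)
  ok <- is.finite(mean_log_d)
  slope <- stats::coef(stats::lm.fit(cbind(1, ks[ok]),
                                     mean_log_d[ok]))[2L]
  lam <- unname(slope) * traj$source_rate
  attr(lam, "divergence") <- tibble::tibble(step = ks, mean_log_dist = mean_log_d)
  lam
}

#' Quasi-period sample from phase-space recurrences
#'
#' The quasi-period of a reconstructed trajectory is the time between
#' successive returns into a small neighbourhood of a reference state.  For
#' each reference point, the trajectory's visits to the eps-ball around it
#' (radius `eps_fraction` of the attractor's bounding-box diagonal) are
#' found; visits separated by excursions shorter than the Theiler window are
#' merged (they are one sojourn, not a recurrence), and the times between
#' successive visit onsets are recorded.  Durations are pooled over all
#' reference points.
#'
#' @param traj A [embed_delay()] trajectory.
#' @param eps_fraction Ball radius as a fraction of the attractor diameter
#'   (default 0.15).
#' @param theiler Exclusion window in samples (default `m * tau`).
#' @param ref_stride Stride over reference points (default 1 = every point);
#'   larger strides trade recurrence-count for speed.
#' @return A `quasi_period_sample`: list with `durations` (seconds), `rate`,
#'   `eps`, `n_ref`, and logical `empty` when no recurrences were found (a
#'   warning is raised in that case).
#' @export
quasi_periods <- function(traj, eps_fraction = 0.15,
                          theiler = traj$m * traj$tau, ref_stride = 1) {
  stopifnot(inherits(traj, "trajectory"))
  if (eps_fraction <= 0 || eps_fraction >= 1) {
    stop("eps_fraction must lie in (0, 1)", call. = FALSE)
  }
  if (theiler < 1) stop("theiler must be >= 1", call. = FALSE)
  X <- traj$points
  n <- nrow(X)
  diam <- attractor_diameter(traj)
  if (diam == 0) stop("degenerate trajectory: zero attractor diameter", call. = FALSE)
  eps2 <- (eps_fraction * diam)^2
  refs <- seq(1L, n, by = as.integer(ref_stride))
  rate <- traj$source_rate
  durations <- vector("list", length(refs))
  for (j in seq_along(refs)) {
    ref <- refs[j]
    d2 <- rowSums((X - rep(X[ref, ], each = n))^2)
    inball <- d2 <= eps2
    r <- rle(inball)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    vs <- starts[r$values]
    ve <- ends[r$values]
    if (length(vs) >= 1L && vs[1L] == 1L) {  # truncated visit: onset unseen
      vs <- vs[-1L]; ve <- ve[-1L]
    }
    if (length(vs) >= 2L) {
      gaps <- vs[-1L] - ve[-length(ve)]
      keep <- c(TRUE, gaps >= theiler)
      vs <- vs[keep]
      if (length(vs) >= 2L) durations[[j]] <- diff(vs) / rate
    }
  }
  durations <- unlist(durations)
  empty <- length(durations) == 0L
  if (empty) {
    warning("no recurrences found at this eps_fraction", call. = FALSE)
    durations <- numeric(0)
  }
  structure(list(durations = durations, rate = rate,
                 eps = sqrt(eps2), n_ref = length(refs), empty = empty),
            class = "quasi_period_sample")
}

#' @export
print.quasi_period_sample <- function(x, ...) {
  cat(sprintf("<quasi_period_sample> %d durations from %d reference points\n",
              length(x$durations), x$n_ref))
  invisible(x)
}
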