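#' Filter configuration for the adaptive two-stage ECG filter
#'
#' Stage 1 smooths high-frequency noise with a Savitzky-Golay filter
#' (degree-11 polynomials over 25-sample frames).  Stage 2 estimates the
#' baseline by repeatedly smoothing with a much wider, low-order
#' Savitzky-Golay filter (degree 3 over 499-sample frames, or the largest odd
#' frame that fits the segment) until the estimate stabilizes, then subtracts
#' it.  Frames must be odd; polynomial order must be below the frame length.
#'
#' @param sg_order,sg_frame Stage-1 polynomial degree and odd frame length.
#' @param base_order,base_frame Stage-2 (baseline) degree and odd frame length;
#'   `base_frame` is clipped to the largest odd value not exceeding the
#'   segment length at filter time.
#' @param base_passes_max Maximum number of baseline smoothing passes.
#' @param base_tol Convergence tolerance for the baseline iteration, mV:
#'   stop once the maximum absolute change between passes falls below it.
#' @return A `filter_config` list.
#' @export
filter_config <- function(sg_order = 11, sg_frame = 25,
                          base_order = 3, base_frame = 499,
                          base_passes_max = 10, base_tol = 1e-3) {
  cfg <- list(sg_order = as.integer(sg_order), sg_frame = as.integer(sg_frame),
              base_order = as.integer(base_order),
              base_frame = as.integer(base_frame),
              base_passes_max = as.integer(base_passes_max),
              base_tol = as.numeric(base_tol))
  for (nm in c("sg_frame", "base_frame")) {
    if (cfg[[nm]] %% 2L == 0L) stop(nm, " must be odd", call. = FALSE)
  }
  if (cfg$sg_order >= cfg$sg_frame || cfg$base_order >= cfg$base_frame) {
    stop("polynomial order must be smaller than the frame length", call. = FALSE)
  }
  if (cfg$base_tol <= 0) stop("base_tol must be positive", call. = FALSE)
  structure(cfg, class = "filter_config")
}

# Savitzky-Golay weight vectors.  Interior: projection of the centred frame
# onto polynomials of the given degree, evaluated at the centre.  Edge rows
# use one-sided windows anchored at the boundary.  Cached per parameter set.
.sg_cache <- new.env(parent = emptyenv())

sg_weights <- function(order, frame, edge_order = order,
                       edge_frame = frame) {
  key <- paste0(order, "_", frame, "_", edge_order, "_", edge_frame)
  if (!is.null(.sg_cache[[key]])) return(.sg_cache[[key]])
  h <- (frame - 1L) %/% 2L
  # hat-matrix row for a degree-`ord` fit over positions x, evaluated at
  # position `at`; orthogonal polynomial basis keeps this well conditioned
  proj_row <- function(x, at, ord) {
    P <- cbind(1, stats::poly(x, degree = ord))
    Q <- qr.Q(qr(P))
    drop(Q[at, , drop = FALSE] %*% t(Q))
  }
  center <- proj_row(seq(-h, h), h + 1L, order)
  # boundary rows: the frame cannot extend past the signal edge, so it is
  # anchored there at full width and the fit is evaluated at the offset
  # position; keeps exactness on degree <= edge_order polynomials without
  # the transients a shrinking window would introduce.  Wide baseline
  # frames use edge_order = 1 because high-degree one-sided fits have
  # large endpoint leverage and leak oscillatory content into the edges.
  left <- lapply(seq_len(h),
                 function(i) proj_row(seq_len(edge_frame), i, edge_order))
  .sg_cache[[key]] <- list(center = center, left = left, h = h)
  .sg_cache[[key]]
}

sg_apply <- function(y, order, frame, edge_order = order,
                     edge_frame = frame) {
  n <- length(y)
  if (frame > n) stop("frame exceeds signal length", call. = FALSE)
  edge_frame <- min(edge_frame, n)
  w <- sg_weights(order, frame, edge_order, edge_frame)
  h <- w$h
  out <- as.numeric(stats::filter(y, w$center, sides = 2))
  for (i in seq_len(h)) {
    out[i] <- sum(w$left[[i]] * y[seq_len(edge_frame)])
    # right edge: mirror of the left-edge fit
    out[n - i + 1L] <- sum(w$left[[i]] * y[n + 1L - seq_len(edge_frame)])
  }
  out
}

# Detect sustained baseline step shifts ("sudden jumps"): the contrast of
# adjacent w-sample window means is a matched filter for a step; locations
# where it exceeds k robust SDs of its own background are corrected by the
# step coefficient of a local linear-plus-step regression.  Oscillatory VF
# content averages out of the window means, so physiologic morphology does
# not trigger the detector.
jump_shift <- function(x, w = 250L, k = 5, guard = 13L, max_jumps = 4L) {
  n <- length(x)
  if (n < 4L * w) return(numeric(n))
  cs <- cumsum(c(0, x))
  core <- (w + 1L):(n - w)
  d_core <- (cs[core + w + 1L] - cs[core + 1L]) / w -
    (cs[core + 1L] - cs[core - w + 1L]) / w
  dc <- d_core - stats::median(d_core)
  th <- k * stats::mad(d_core)
  shift <- numeric(n)
  if (th <= 0) return(shift)
  dca <- rep(0, n)
  dca[core] <- abs(dc)
  cand <- core[abs(dc) > th]
  found <- 0L
  while (length(cand) > 0L && found < max_jumps) {
    i0 <- cand[which.max(dca[cand])]
    idx <- c(max(1L, i0 - w):(i0 - guard), (i0 + guard):min(n, i0 + w))
    fit <- stats::lm.fit(cbind(1, idx - i0, as.numeric(idx > i0)),
                         x[idx] - shift[idx])
    shift[(i0 + 1L):n] <- shift[(i0 + 1L):n] + stats::coef(fit)[3L]
    cand <- cand[abs(cand - i0) > 2L * w]   # step response spans 2w
    found <- found + 1L
  }
  shift
}

#' Savitzky-Golay smoothing of a segment
#'
#' Least-squares local-polynomial smoothing: within every frame a polynomial
#' of the given degree is fitted and evaluated at the frame centre, which
#' preserves low-degree polynomial content exactly while attenuating
#' high-frequency noise.
#'
#' @param seg A [signal_segment()].
#' @param order Polynomial degree (default 11).
#' @param frame Odd frame length in samples (default 25).
#' @return A [signal_segment()] of the same length and rate.
#' @export
sg_smooth <- function(seg, order = 11, frame = 25) {
  stopifnot(inherits(seg, "vf_segment"))
  if (frame %% 2L == 0L) stop("frame must be odd", call. = FALSE)
  if (order >= frame) stop("order must be smaller than frame", call. = FALSE)
  seg_with_samples(seg, sg_apply(seg$samples, order, frame))
}

#' Estimate the slow baseline of a segment
#'
#' Captures the baseline in two parts.  Sudden sustained shifts (electrode
#' or motion steps) are detected by a window-mean contrast statistic and
#' recorded as an explicit step component — these are exactly the "baseline
#' shifts" the stage must retain, and no smooth low-order filter can follow
#' them sharply.  The remaining drift is estimated by repeatedly applying a
#' wide low-order Savitzky-Golay smoother until the estimate stabilizes:
#' iteration stops when the maximum absolute change between successive
#' passes drops below `tol`, or after `passes_max` passes (in which case a
#' `converged = FALSE` flag is attached to the result's `baseline_info`
#' attribute rather than raising an error).  The returned baseline is the
#' sum of both parts.
#'
#' @param seg A [signal_segment()].
#' @param order Baseline polynomial degree (default 3).
#' @param frame Odd frame length in samples (default 499); clipped to the
#'   largest odd value not exceeding the segment length.
#' @param passes_max Maximum smoothing passes (default 10).
#' @param tol Convergence tolerance in mV (default 1e-3).
#' @return A [signal_segment()] holding the baseline, with attribute
#'   `baseline_info` (list: `passes`, `converged`, `last_change`).
#' @export
estimate_baseline <- function(seg, order = 3, frame = 499,
                              passes_max = 10, tol = 1e-3) {
  stopifnot(inherits(seg, "vf_segment"))
  n <- length(seg$samples)
  frame <- min(frame, if (n %% 2L == 1L) n else n - 1L)
  if (frame %% 2L == 0L) frame <- frame - 1L
  if (order >= frame) stop("order must be smaller than frame", call. = FALSE)
  shift <- jump_shift(seg$samples)
  h <- (frame - 1L) %/% 2L
  w_center <- sg_weights(order, frame)$center
  # one smoothing application: interior convolution; edge values are linear
  # extrapolations of the smoothed interior (the baseline is slow, and
  # extrapolating it keeps oscillatory signal content out of the edges)
  smooth_once <- function(y) {
    out <- as.numeric(stats::filter(y, w_center, sides = 2))
    span <- (h + 1L):min(h + frame, n - h)
    fit_l <- stats::lm.fit(cbind(1, span), out[span])
    out[seq_len(h)] <- stats::coef(fit_l)[1L] +
      stats::coef(fit_l)[2L] * seq_len(h)
    span_r <- max(h + 1L, n - h - frame + 1L):(n - h)
    fit_r <- stats::lm.fit(cbind(1, span_r), out[span_r])
    out[(n - h + 1L):n] <- stats::coef(fit_r)[1L] +
      stats::coef(fit_r)[2L] * ((n - h + 1L):n)
    out
  }
  # double application per pass: squares the stopband so oscillatory
  # content cannot accumulate into the baseline over the refinement
  smooth2 <- function(y) smooth_once(smooth_once(y))
  # successive refinement: each pass smooths what is not yet explained and
  # adds it to the baseline, until the estimate stabilizes
  b <- numeric(n)
  passes <- 0L
  change <- Inf
  while (passes < passes_max) {
    delta <- smooth2(seg$samples - shift - b)
    passes <- passes + 1L
    change <- max(abs(delta))
    b <- b + delta
    if (change < tol) break
  }
  out <- seg_with_samples(seg, b + shift)
  attr(out, "baseline_info") <- list(passes = passes,
                                     converged = change < tol,
                                     last_change = change)
  out
}

#' Adaptive two-stage de-trending filter
#'
#' Smooths the segment (stage 1), estimates its baseline from the smoothed
#' signal (stage 2a) and subtracts it (stage 2b), yielding a signal that
#' keeps VF morphology but is free of baseline wander and step offsets.
#'
#' @param seg A [signal_segment()].
#' @param config A [filter_config()].
#' @return A de-trended [signal_segment()]; the `baseline_info` attribute of
#'   the baseline stage is carried over.
#' @export
#' @examples
#' t <- (0:2249) / 250
#' raw <- signal_segment(sin(2 * pi * 5 * t) + 0.5 * t, 250)
#' flat <- detrend(raw)
detrend <- function(seg, config = filter_config()) {
  stopifnot(inherits(seg, "vf_segment"), inherits(config, "filter_config"))
  smoothed <- sg_smooth(seg, config$sg_order, config$sg_frame)
  baseline <- estimate_baseline(smoothed, config$base_order, config$base_frame,
                                config$base_passes_max, config$base_tol)
  out <- seg_with_samples(seg, smoothed$samples - baseline$samples)
  attr(out, "baseline_info") <- attr(baseline, "baseline_info")
  out
}
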