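# Dual-tree complex wavelet transform (1-D).
#
# Two parallel perfect-reconstruction filter-bank trees offset by one
# sample at the first level and by half a sample (a quarter-delay filter
# and its time reverse) at every deeper level.  Detail coefficients of the two trees form the real and
# imaginary parts of approximately analytic complex coefficients, whose
# magnitudes are nearly invariant to small shifts of the input — the
# property that makes windowed segments comparable.  Both trees are PR, so
# the inverse (average of the two tree inverses) reconstructs exactly.

# Filter bank construction ---------------------------------------------------

# A bank is a list of taps plus the index of each filter's first tap.
# The first level uses a classical spline biorthogonal pair (lengths 5/11)
# built in closed form from the maxflat halfband product
# P = ((1+z)(1+1/z)/4)^L * Q_L(y), y = (2 - z - 1/z)/4.  Highpass filters
# follow the standard alias-cancelling modulation
# h1[n] = (-1)^(n-1) g0[n-1], g1[n] = (-1)^(n+1) h0[n+1].
make_bank <- function(h0, h0_first, g0, g0_first, normalize = TRUE) {
  if (normalize) {                 # DC gain sqrt(2) on both sides
    h0 <- h0 * sqrt(2) / sum(h0)
    g0 <- g0 / (sum(g0) / sqrt(2))
  }
  n_h1 <- (g0_first + seq_along(g0) - 1) + 1          # indices of h1 taps
  h1 <- (-1)^(n_h1 - 1) * g0
  n_g1 <- (h0_first + seq_along(h0) - 1) - 1
  g1 <- (-1)^(n_g1 + 1) * h0
  list(h0 = h0, h0_first = h0_first,
       h1 = h1, h1_first = g0_first + 1,
       g0 = g0, g0_first = g0_first,
       g1 = g1, g1_first = h0_first - 1)
}

make_spline_pair <- function(h_zeros, L) {
  conv0 <- function(a, b) stats::convolve(a, rev(b), type = "open")
  y <- c(-1, 2, -1) / 4
  QL <- 0
  yj <- 1
  for (j in 0:(L - 1)) {
    pad <- (length(yj) - length(QL)) / 2
    if (pad > 0) QL <- c(rep(0, pad), QL, rep(0, pad))
    QL <- QL + choose(L - 1 + j, j) * yj
    yj <- conv0(yj, y)
  }
  g_zeros <- 2L * L - h_zeros
  h0 <- choose(h_zeros, 0:h_zeros) / 2^h_zeros
  g0 <- 2 * conv0(choose(g_zeros, 0:g_zeros) / 2^g_zeros, QL)
  list(h0 = h0, g0 = g0)
}

# Quarter-sample-delay orthonormal lowpass for the deeper levels, designed
# once by least squares on a delayed-lowpass frequency target under a
# paraunitary lattice parametrization (orthonormality is exact by
# construction; passband group delay (L-1)/2 - 1/4, stopband < 0.05).
# Tree B uses the time reverse, so the two trees differ by exactly half an
# input sample at every level the pair is used.
qshift_taps <- c(
  -0.0014114307639769, -0.0079668511406816, 0.0159254803606601,
  -0.0230359772535870, -0.1152145723526691, 0.2609831907157974,
  0.7688158594888904, 0.5629032014039835, 0.0039221569612949,
  -0.0941356092847831, 0.0284914275593058, 0.0100042607423476,
  0.0059938281717053, -0.0010618842157521)

dt_banks <- local({
  banks <- NULL
  function() {
    if (is.null(banks)) {
      op <- make_spline_pair(4L, 4L)    # lengths 5 / 11, odd, delay 0
      q <- qshift_taps
      L <- length(q)
      # orthonormal banks: synthesis lowpass is the analysis time-reverse,
      # so the halfband product |H0|^2 comes from paraunitarity
      banks <<- list(
        odd = make_bank(op$h0, -2L, op$g0, -5L),
        # exact paraunitary taps: do not renormalize (sum is sqrt(2) to
        # within the design fit; rescaling would break perfect
        # reconstruction at the 1e-6 level)
        qa = make_bank(q, -6L, rev(q), -7L, normalize = FALSE),
        qb = make_bank(rev(q), -7L, q, -6L, normalize = FALSE)
      )
    }
    banks
  }
})

# circular convolution of x with taps (first tap index `first`), via FFT
circ_conv <- function(x, taps, first) {
  N <- length(x)
  hpad <- numeric(N)
  idx <- ((first + seq_along(taps) - 1) %% N) + 1
  for (k in seq_along(taps)) hpad[idx[k]] <- hpad[idx[k]] + taps[k]
  Re(stats::fft(stats::fft(x) * stats::fft(hpad), inverse = TRUE)) / N
}

analysis_step <- function(x, bank, phase = 0L) {
  keep <- seq(1L + phase, length(x), by = 2L)
  list(a = circ_conv(x, bank$h0, bank$h0_first)[keep],
       d = circ_conv(x, bank$h1, bank$h1_first)[keep])
}

synthesis_step <- function(a, d, bank, phase = 0L, N = 2L * length(a)) {
  ua <- numeric(N); ud <- numeric(N)
  keep <- seq(1L + phase, N, by = 2L)
  ua[keep] <- a; ud[keep] <- d
  circ_conv(ua, bank$g0, bank$g0_first) + circ_conv(ud, bank$g1, bank$g1_first)
}

# Level scheme: at level 1 both trees use the odd spline bank with
# downsampling phases offset by one sample (the required one-sample delay
# difference); at every deeper level the trees use the q-shift filter and
# its time reverse, giving exactly half a sample of relative delay at that
# level's input rate — the condition for near-analytic coefficients.
tree_plan <- function(tree, levels) {
  if (tree == "a") {
    list(bank = c("odd", rep("qa", max(0L, levels - 1L))),
         phase = rep(0L, levels))
  } else {
    list(bank = c("odd", rep("qb", max(0L, levels - 1L))),
         phase = c(1L, rep(0L, max(0L, levels - 1L))))
  }
}

#' Dual-tree complex wavelet decomposition
#'
#' Decomposes a segment into `levels` octave subbands of approximately
#' analytic complex coefficients (tree-A detail as real part, tree-B detail
#' as imaginary part) plus the two trees' final scaling coefficients.  The
#' segment is closed into a circle with a smooth cubic bridge (padding it
#' to a multiple of `2^levels`); the transform is exactly invertible via
#' [dtcwt_reconstruct()].
#'
#' @param seg A [signal_segment()] (or numeric vector) of length at least
#'   `2^levels`.
#' @param levels Decomposition depth (default 5).
#' @return A `dtcwt` object: list with `coeffs` (list of complex vectors,
#'   level 1 = finest), `lowpass` (list `a`, `b`), `levels`, `n` (original
#'   length), `rate`.
#' @export
dtcwt_decompose <- function(seg, levels = 5) {
  x <- if (inherits(seg, "vf_segment")) seg$samples else as.numeric(seg)
  rate <- if (inherits(seg, "vf_segment")) seg$sampling_rate else NA_real_
  n <- length(x)
  levels <- as.integer(levels)
  if (n < 2^levels) {
    stop(sprintf("segment too short: need >= %d samples for %d levels",
                 2^levels, levels), call. = FALSE)
  }
  # The filters run circularly, so the segment is closed with a smooth
  # C1 cubic bridge from its last sample back to its first: a plain wrap
  # (or a mirrored copy, whose seam kinks) would inject a shift-dependent
  # broadband burst into every subband.
  block <- 2L^levels
  n_bridge <- max(block, 256L)
  n_pad <- ceiling((n + n_bridge) / block) * block
  nb <- n_pad - n
  tt <- seq_len(nb) / (nb + 1)
  p0 <- x[n]; p1 <- x[1L]
  # end tangents from local least-squares slopes (robust to sample noise)
  k <- min(25L, n %/% 2L)
  sl <- function(y) unname(stats::coef(stats::lm.fit(
    cbind(1, seq_along(y)), y))[2L])
  m0 <- sl(x[(n - k + 1L):n]) * (nb + 1)
  m1 <- sl(x[1L:k]) * (nb + 1)
  bridge <- (2 * tt^3 - 3 * tt^2 + 1) * p0 + (tt^3 - 2 * tt^2 + tt) * m0 +
    (-2 * tt^3 + 3 * tt^2) * p1 + (tt^3 - tt^2) * m1
  x <- c(x, bridge)
  banks <- dt_banks()
  plan_a <- tree_plan("a", levels)
  plan_b <- tree_plan("b", levels)
  xa <- x; xb <- x
  coeffs <- vector("list", levels)
  for (l in seq_len(levels)) {
    sa <- analysis_step(xa, banks[[plan_a$bank[l]]], plan_a$phase[l])
    sb <- analysis_step(xb, banks[[plan_b$bank[l]]], plan_b$phase[l])
    coeffs[[l]] <- complex(real = sa$d, imaginary = sb$d)
    xa <- sa$a; xb <- sb$a
  }
  structure(list(coeffs = coeffs, lowpass = list(a = xa, b = xb),
                 levels = levels, n = n, n_pad = n_pad, rate = rate),
            class = "dtcwt")
}

#' @export
print.dtcwt <- function(x, ...) {
  cat(sprintf("<dtcwt> %d levels over %d samples; subband sizes: %s\n",
              x$levels, x$n, paste(lengths(x$coeffs), collapse = ", ")))
  invisible(x)
}

#' Inverse dual-tree complex wavelet transform
#'
#' Each tree is a perfect-reconstruction filter bank; the signal is the
#' average of the two tree inverses, truncated to the original length.
#'
#' @param dt A [dtcwt_decompose()] object.
#' @return Numeric vector of reconstructed samples.
#' @export
dtcwt_reconstruct <- function(dt) {
  stopifnot(inherits(dt, "dtcwt"))
  banks <- dt_banks()
  plan_a <- tree_plan("a", dt$levels)
  plan_b <- tree_plan("b", dt$levels)
  xa <- dt$lowpass$a; xb <- dt$lowpass$b
  for (l in rev(seq_len(dt$levels))) {
    xa <- synthesis_step(xa, Re(dt$coeffs[[l]]), banks[[plan_a$bank[l]]],
                         plan_a$phase[l])
    xb <- synthesis_step(xb, Im(dt$coeffs[[l]]), banks[[plan_b$bank[l]]],
                         plan_b$phase[l])
  }
  ((xa + xb) / 2)[seq_len(dt$n)]
}

#' Per-subband statistics of a dual-tree decomposition
#'
#' For every level: coefficient magnitude energy, mean magnitude, magnitude
#' standard deviation, and log-energy entropy (`sum(log(m^2))` over nonzero
#' magnitudes, 0 for an all-zero subband).  Deterministic names
#' `dtcwt_L{k}_{stat}`.
#'
#' @param coeffs A [dtcwt_decompose()] object.
#' @return Named numeric vector of `4 * levels` features.
#' @export
subband_features <- function(coeffs) {
  stopifnot(inherits(coeffs, "dtcwt"))
  out <- lapply(seq_len(coeffs$levels), function(l) {
    m <- Mod(coeffs$coeffs[[l]])
    # log-energy entropy with a relative magnitude floor: near-zero
    # coefficients would otherwise make the sum of logs ill-conditioned
    logen <- if (max(m) == 0) 0 else sum(log(pmax(m, 1e-9 * max(m))^2))
    stats::setNames(
      c(sum(m^2), mean(m), stats::sd(m), logen),
      paste0("dtcwt_L", l, "_", c("energy", "mag_mean", "mag_sd", "logen")))
  })
  unlist(out)
}

#' Time-domain descriptors of a segment
#'
#' Mean absolute amplitude (mV), root-mean-square amplitude (mV),
#' peak-to-peak amplitude (mV), zero-crossing rate (crossings per second)
#' and median absolute slope (mV/s).  Computed on de-trended segments these
#' are offset-free summaries of VF coarseness and amplitude.
#'
#' @param seg A [signal_segment()].
#' @return Named numeric vector of 5 features.
#' @export
time_features <- function(seg) {
  stopifnot(inherits(seg, "vf_segment"))
  x <- seg$samples
  rate <- seg$sampling_rate
  s <- sign(x)
  s <- s[s != 0]
  zc <- if (length(s) > 1L) sum(diff(s) != 0) else 0L
  c(td_mean_abs = mean(abs(x)),
    td_rms = sqrt(mean(x^2)),
    td_p2p = diff(range(x)),
    td_zcr = zc / (length(x) / rate),
    td_med_slope = stats::median(abs(diff(x))) * rate)
}
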