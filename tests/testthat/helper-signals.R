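# shared fixtures: analytic signals and small synthetic cohorts, all built
# in code at test time

sine_segment <- function(freq = 5, rate = 250, duration = 9, amp = 1,
                         phase = 0) {
  t <- (seq_len(round(duration * rate)) - 1) / rate
  signal_segment(amp * sin(2 * pi * freq * t + phase), rate)
}

# small feature tibble with a known class structure for ML-level tests
toy_features <- function(n = 60, p = 6, delta = 0, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(c(0, 1), length.out = n)
    X <- matrix(rnorm(n * p), n, p)
    X[, 1] <- X[, 1] + delta * y
    colnames(X) <- paste0("f", seq_len(p))
    out <- tibble::as_tibble(as.data.frame(X))
    out$outcome <- y
    out
  })
}

lorenz_rhs <- function(t, s, p) {
  list(c(10 * (s[2] - s[1]), s[1] * (28 - s[3]) - s[2],
         s[1] * s[2] - (8 / 3) * s[3]))
}

# Lorenz x-coordinate via deSolve, the independent chaotic test signal
lorenz_x <- function(n = 5000, dt = 0.01, x0 = c(1, 1, 20), burn = 500) {
  times <- seq(0, (n + burn) * dt, by = dt)
  out <- deSolve::ode(x0, times, lorenz_rhs, NULL, method = "rk4")
  as.numeric(out[(burn + 1):(burn + n), 2])
}

# independent two-trajectory divergence oracle for the Lorenz exponent:
# perturb several base states along the attractor by 1e-8, integrate both
# copies, fit the global log-separation growth, and average
lorenz_lyap_oracle <- function(n_base = 8, horizon = 16, dt = 0.01) {
  times <- seq(0, horizon, by = dt)
  base_run <- deSolve::ode(c(1, 1, 20), seq(0, 40, by = 0.01), lorenz_rhs,
                           NULL, method = "rk4")
  bases <- base_run[1001 + 250 * (seq_len(n_base) - 1), 2:4]
  slopes <- apply(bases, 1, function(s0) {
    o1 <- deSolve::ode(unname(s0), times, lorenz_rhs, NULL, method = "rk4")
    o2 <- deSolve::ode(unname(s0) + c(1e-8, 0, 0), times, lorenz_rhs, NULL,
                       method = "rk4")
    d <- sqrt(rowSums((o1[, 2:4] - o2[, 2:4])^2))
    keep <- times >= 1          # past the alignment transient
    unname(stats::coef(stats::lm(log(d[keep]) ~ times[keep]))[2])
  })
  mean(slopes)
}
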