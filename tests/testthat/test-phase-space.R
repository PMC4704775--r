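test_that("embedding has the stated geometry and point count", {
  withr::with_seed(1, seg <- signal_segment(rnorm(100), 250))
  traj <- embed_delay(seg, embedding_params(4, 8))
  expect_equal(nrow(traj$points), 76)       # 100 - 3 * 8
  # point k holds (p[k + 3 tau], ..., p[k]): most recent coordinate first
  expect_equal(traj$points[1, ], seg$samples[c(25, 17, 9, 1)])
  expect_equal(traj$points[76, ], seg$samples[c(100, 92, 84, 76)])
  # m = 1 reproduces the signal
  tr1 <- embed_delay(seg, embedding_params(1, 3))
  expect_equal(drop(tr1$points), seg$samples)
  # constant signal embeds to identical points
  trc <- embed_delay(signal_segment(rep(2, 50), 250), embedding_params(3, 4))
  expect_true(all(apply(trc$points, 2, function(c) diff(range(c))) == 0))
  expect_error(embed_delay(signal_segment(rnorm(20), 250),
                           embedding_params(4, 8)), "too short")
})

test_that("embedding point count holds over randomized (N, m, tau)", {
  withr::with_seed(42, {
    for (i in 1:25) {
      m <- sample(1:6, 1); tau <- sample(1:12, 1)
      N <- (m - 1) * tau + sample(2:300, 1)
      traj <- embed_delay(signal_segment(rnorm(N), 100),
                          embedding_params(m, tau))
      expect_equal(nrow(traj$points), N - (m - 1) * tau)
    }
  })
})

test_that("defaults are m = 4 dimensions, tau = 8 samples", {
  ep <- embedding_params()
  expect_equal(ep$m, 4L)
  expect_equal(ep$tau, 8L)
})

test_that("periodic signals have near-zero maximal Lyapunov exponent", {
  n <- round(10 / 5.3 * 250)                       # 10 periods at 5.3 Hz
  seg <- signal_segment(sin(2 * pi * 5.3 * (0:(n - 1)) / 250), 250)
  lam <- max_lyapunov(embed_delay(seg), min_separation = 60, fit_range = 100)
  expect_lt(abs(lam), 0.1 * 5.3)
})

test_that("degenerate trajectories are rejected", {
  trc <- embed_delay(signal_segment(rep(1, 200), 250))
  expect_error(max_lyapunov(trc), "degenerate")
  expect_error(quasi_periods(trc), "degenerate")
})

test_that("the exponent is invariant under amplitude scaling", {
  seg <- generate_vf(seed = 4, drift_amp = 0, step_prob = 0)
  tr1 <- embed_delay(seg)
  tr2 <- embed_delay(seg_scaled <- signal_segment(seg$samples * 7.3, 250))
  l1 <- max_lyapunov(tr1, fit_range = 40)
  l2 <- max_lyapunov(tr2, fit_range = 40)
  expect_lt(abs(l1 - l2), 1e-6)
})

test_that("Lorenz-x exponent matches a two-trajectory divergence oracle within 25%", {
  skip_if_not_installed("deSolve")
  x <- lorenz_x(n = 5000, dt = 0.01)
  traj <- embed_delay(signal_segment(x, 100), embedding_params(3, 10))
  lam <- max_lyapunov(traj, min_separation = 100, fit_range = 250,
                      fit_start = 50)
  oracle <- lorenz_lyap_oracle()
  expect_lt(abs(lam - oracle) / oracle, 0.25)
})

test_that("quasi-periods of a sinusoid equal its period", {
  seg <- sine_segment(freq = 5)
  qp <- quasi_periods(embed_delay(seg), eps_fraction = 0.1)
  expect_gt(length(qp$durations), 100)
  expect_true(all(abs(qp$durations - 0.2) <= 2 / 250 + 1e-12))
})

test_that("a two-frequency flow yields a multi-modal quasi-period sample", {
  t <- (0:2249) / 250
  seg <- signal_segment(sin(2 * pi * 4 * t) + sin(2 * pi * 6.5 * t), 250)
  qp <- quasi_periods(embed_delay(seg), eps_fraction = 0.1)
  h <- graphics::hist(qp$durations,
                      breaks = seq(0, max(qp$durations) + 0.02, by = 0.02),
                      plot = FALSE)
  dens <- h$counts / sum(h$counts)
  peaks <- sum(diff(sign(diff(c(-1, dens, -1)))) == -2 & dens > 0.03)
  expect_gte(peaks, 2)
})

test_that("recurrence-free settings return an empty flagged sample", {
  seg <- sine_segment(freq = 5, duration = 1)
  expect_warning(
    qp <- quasi_periods(embed_delay(seg), eps_fraction = 0.01, theiler = 200),
    "no recurrences")
  expect_true(qp$empty)
  expect_length(qp$durations, 0)
})

test_that("eps_fraction and theiler are validated", {
  traj <- embed_delay(sine_segment(duration = 1))
  expect_error(quasi_periods(traj, eps_fraction = 1.2), "eps_fraction")
  expect_error(quasi_periods(traj, theiler = 0), "theiler")
})
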