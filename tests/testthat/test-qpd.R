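# helper: density object on an explicit grid (for distance tests)
grid_density <- function(pdf, grid, params = qpd_params()) {
  structure(list(bin_edges = range(grid), mass = 1,
                 pdf_grid = pdf / trapz(grid, pdf), grid = grid,
                 params = params),
            class = "qpd_density")
}
trapz <- function(x, y) sum((y[-1] + y[-length(y)]) * diff(x)) / 2

test_that("the quasi-period histogram is a normalized density with overflow bin", {
  d <- qpd_histogram(rep(0.2, 50), bin_width = 0.05, t_max = 1)
  expect_equal(sum(d$mass), 1, tolerance = 1e-12)
  expect_equal(max(d$mass), 1)
  # overflow: durations beyond t_max land in the last bin
  d2 <- qpd_histogram(c(rep(0.2, 5), 3, 7), bin_width = 0.05, t_max = 1)
  expect_equal(d2$mass[length(d2$mass)], 2 / 7)
  expect_error(qpd_histogram(numeric(0)), "empty")
})

test_that("uniform durations fill bins uniformly within binomial bounds", {
  withr::with_seed(11, u <- runif(100))
  d <- qpd_histogram(u, bin_width = 0.1, t_max = 1)
  ci <- stats::qbinom(c(0.005, 0.995), 100, 0.1) / 100
  expect_true(all(d$mass >= ci[1] & d$mass <= ci[2]))
})

test_that("exponential smoothing of a point mass gives the analytic causal tail", {
  d <- qpd_histogram(rep(2.02, 10), bin_width = 0.04, t_max = 4,
                     params = qpd_params(bin_width = 0.04, t_max = 4))
  sm <- smooth_pdf(d, grid_step = 0.01, kernel_scale = 4)
  center <- d$bin_edges[which(d$mass == 1)] + 0.02
  expected <- ifelse(sm$grid >= center, exp(-(sm$grid - center) / 4), 0)
  expected <- expected / trapz(sm$grid, expected)
  expect_lt(max(abs(sm$pdf_grid - expected)), 1e-6)
  expect_equal(sm$grid[which.max(sm$pdf_grid)], center, tolerance = 1e-9)
})

test_that("smoothing is linear: a two-point mixture is the mixture of tails", {
  d <- qpd_histogram(c(rep(1.01, 5), rep(3.01, 5)), bin_width = 0.02,
                     t_max = 4)
  sm <- smooth_pdf(d, grid_step = 0.01, kernel_scale = 4)
  c1 <- 1.01; c2 <- 3.01                     # the occupied bin centres
  mix <- 0.5 * ifelse(sm$grid >= c1, exp(-(sm$grid - c1) / 4), 0) +
    0.5 * ifelse(sm$grid >= c2, exp(-(sm$grid - c2) / 4), 0)
  mix <- mix / trapz(sm$grid, mix)
  expect_lt(max(abs(sm$pdf_grid - mix)), 1e-6)
})

test_that("smoothed uniform density matches direct quadrature of the convolution", {
  b <- 1 / 400
  centers <- b / 2 + (0:399) * b
  d <- qpd_histogram(centers, bin_width = b, t_max = 1)
  sm <- smooth_pdf(d, grid_step = 0.005, kernel_scale = 4)
  # continuous-uniform oracle: int_0^min(t,1) e^{-(t-u)/4} du
  oracle <- ifelse(sm$grid <= 1, 4 * (1 - exp(-sm$grid / 4)),
                   4 * (exp((1 - sm$grid) / 4) - exp(-sm$grid / 4)))
  oracle <- oracle / trapz(sm$grid, oracle)
  expect_lt(max(abs(sm$pdf_grid - oracle)), 1e-4 * max(oracle))
})

test_that("the smoothed output is a proper density for arbitrary inputs", {
  withr::with_seed(13, {
    for (i in 1:10) {
      durs <- rexp(sample(5:200, 1), rate = 5) + 0.01
      sm <- smooth_pdf(qpd_histogram(durs, bin_width = 0.025, t_max = 1))
      expect_true(all(sm$pdf_grid >= 0))
      expect_equal(trapz(sm$grid, sm$pdf_grid), 1, tolerance = 1e-6)
    }
  })
})

test_that("the prototype distance is a symmetric divergence, zero at identity", {
  withr::with_seed(21, {
    grid <- seq(0, 1, by = 0.01)
    p <- grid_density(dexp(grid, 3) + 0.1, grid)
    q <- grid_density(dgamma(grid + 0.01, 2, 8) + 0.1, grid)
  })
  expect_equal(kd_distance(p, p), 0)
  expect_equal(kd_distance(p, q), kd_distance(q, p))
  expect_gt(kd_distance(p, q), 0)
  short <- grid_density(rep(1, 51), seq(0, 1, by = 0.02))
  expect_error(kd_distance(p, short), "grids")
})

test_that("the distance between discretized Gaussians matches the Jeffreys closed form", {
  grid <- seq(0, 1.2, by = 0.002)
  a <- grid_density(stats::dnorm(grid, 0.3, 0.05), grid)
  b <- grid_density(stats::dnorm(grid, 0.6, 0.05), grid)
  # Jeffreys divergence of equal-variance Gaussians: (mu1 - mu2)^2 / sigma^2
  expect_equal(kd_distance(a, b, method = "jeffreys"),
               (0.3 / 0.05)^2, tolerance = 0.02)
  # Wasserstein-1 between shifted equal-shape densities: the shift itself
  expect_equal(kd_distance(a, b), 0.3, tolerance = 0.01)
})

test_that("sep matches an independent direct-summation oracle to 1e-12", {
  withr::with_seed(31, {
    L <- 8
    labels <- rep(c(1, 0), each = 4)
    kd <- matrix(0, L, L)
    for (i in 1:(L - 1)) for (j in (i + 1):L) {
      base <- if (labels[i] == labels[j]) 1 else 3
      kd[i, j] <- kd[j, i] <- base + rnorm(1, 0, 0.01)
    }
  })
  got <- sep_criterion(kd, labels)
  # brute-force re-implementation, straight from the definition
  oracle <- 0
  for (i in 1:8) {
    own <- setdiff(which(labels == labels[i]), i)
    opp <- which(labels != labels[i])
    kdB <- kd[i, opp]; kdW <- kd[i, own]
    oracle <- oracle + (mean(kdB) - mean(kdW)) /
      max(sum((kdB - mean(kdB))^2) / length(kdB),
          sum((kdW - mean(kdW))^2) / length(kdW))
  }
  expect_equal(got$value, oracle, tolerance = 1e-12)
  expect_equal(sum(got$per_signal_terms), got$value)
})

test_that("sep is zero when between- and within-class distances share means", {
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 1; W[3, 4] <- W[4, 3] <- 1
  W[1, 3] <- W[3, 1] <- 2; W[2, 4] <- W[4, 2] <- 2
  W[1, 4] <- W[4, 1] <- 3; W[2, 3] <- W[3, 2] <- 3
  B <- rbind(c(1, 2, 3, 2), c(2, 1, 2, 3), c(3, 2, 1, 2), c(2, 3, 2, 1))
  kd <- rbind(cbind(W, B), cbind(t(B), W))
  got <- sep_criterion(kd, rep(c(1, 0), each = 4))
  expect_equal(got$value, 0, tolerance = 1e-12)
  expect_true(all(abs(got$per_signal_terms) < 1e-12))
})

test_that("distances without spread raise a degenerate-variance error", {
  kd <- matrix(3, 8, 8)
  kd[1:4, 1:4] <- 1; kd[5:8, 5:8] <- 1
  diag(kd) <- 0
  expect_error(sep_criterion(kd, rep(c(1, 0), each = 4)), "degenerate")
})

test_that("sep scales as 1/s under a common scaling of all distances", {
  withr::with_seed(32, {
    kd <- matrix(0, 8, 8)
    labels <- rep(c(1, 0), each = 4)
    for (i in 1:7) for (j in (i + 1):8) {
      kd[i, j] <- kd[j, i] <- runif(1, 1, 4)
    }
  })
  s1 <- sep_criterion(kd, labels)$value
  s5 <- sep_criterion(5 * kd, labels)$value
  expect_equal(s5, s1 / 5, tolerance = 1e-9)
})

test_that("prototype features are distances to the 8-signal prototype set", {
  co <- generate_cohort(cohort_spec(n_patients = 10, n_shocks = 20,
                                    success_rate = 0.5, seed = 41))
  qp <- qpd_params(ref_stride = 8)
  dens <- lapply(co$records, function(r) qpd_density_of(r$ecg, qp))
  names(dens) <- vapply(co$records, function(r) r$shock_id, "")
  outcomes <- vapply(co$records, outcome_code, 0L)
  ps <- prototype_set(dens, outcomes, C = 4)
  expect_length(ps$entries, 8)
  expect_equal(sum(ps$classes == 1), 4)
  fx <- prototype_features(dens[[ps$ids[1]]], ps)
  expect_length(fx, 8)
  expect_equal(unname(fx[1]), 0)              # distance to itself
  expect_identical(names(fx),
                   c(paste0("kd_s", 1:4), paste0("kd_u", 1:4)))
  # mismatched parameterization is refused
  other <- qpd_density_of(co$records[[1]]$ecg, qpd_params(bin_width = 0.05))
  expect_error(prototype_features(other, ps), "parameterization")
})

test_that("segments lie closer to their own class prototypes on average", {
  co <- generate_cohort(cohort_spec(n_patients = 20, n_shocks = 40,
                                    success_rate = 0.5, seed = 43))
  qp <- qpd_params(ref_stride = 8)
  dens <- lapply(co$records, function(r) qpd_density_of(r$ecg, qp))
  names(dens) <- vapply(co$records, function(r) r$shock_id, "")
  outcomes <- vapply(co$records, outcome_code, 0L)
  ps <- prototype_set(dens, outcomes, C = 4)
  own_closer <- vapply(which(outcomes == 1), function(i) {
    fx <- prototype_features(dens[[i]], ps)
    mean(fx[1:4]) < mean(fx[5:8])
  }, TRUE)
  expect_gte(mean(own_closer), 0.8)
})

test_that("parameter selection maximizes sep over the grid deterministically", {
  co <- generate_cohort(cohort_spec(n_patients = 8, n_shocks = 16,
                                    success_rate = 0.5, seed = 45))
  grid <- list(qpd_params(eps_fraction = 0.1, ref_stride = 8),
               qpd_params(eps_fraction = 0.15, ref_stride = 8),
               qpd_params(eps_fraction = 0.15, bin_width = 0.05,
                          ref_stride = 8))
  sel <- select_parameters(co$records, grid)
  expect_false(any(is.na(sel$trace$sep[!sel$trace$skipped])))
  expect_equal(sel$best_sep, max(sel$trace$sep, na.rm = TRUE))
  expect_length(sel$prototype_ids, 8)
  # grid of one returns that parameterization
  one <- select_parameters(co$records, grid[2])
  expect_equal(one$best_params$eps_fraction, 0.15)
  # determinism
  sel2 <- select_parameters(co$records, grid)
  expect_equal(sel$trace$sep, sel2$trace$sep)
  expect_identical(sel$best_params, sel2$best_params)
})

test_that("shuffling prototype class labels lowers the attainable sep", {
  co <- generate_cohort(cohort_spec(n_patients = 8, n_shocks = 16,
                                    success_rate = 0.5, seed = 47))
  grid <- list(qpd_params(ref_stride = 8))
  sel <- select_parameters(co$records, grid)
  shuffled <- withr::with_seed(7, {
    recs <- co$records
    perm <- sample(length(recs))
    for (i in seq_along(recs)) {
      recs[[i]]$outcome <- co$records[[perm[i]]]$outcome
    }
    recs
  })
  sel_sh <- select_parameters(shuffled, grid)
  expect_lt(sel_sh$best_sep, sel$best_sep)
})
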