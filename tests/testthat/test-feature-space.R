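random_features <- function(n, p, seed = 1, delta = 0) {
  withr::with_seed(seed, {
    y <- rep(c(0, 1), length.out = n)
    X <- matrix(rnorm(n * p), n, p)
    X[, 1] <- X[, 1] + delta * y
    out <- tibble::as_tibble(as.data.frame(X))
    names(out) <- paste0("f", seq_len(p))
    out$outcome <- y
    out
  })
}

test_that("orthogonalization preserves variance and decorrelates columns", {
  m <- random_features(50, 12, seed = 3)
  proj <- orthogonalize(m, standardize = FALSE)
  X <- as.matrix(m[paste0("f", 1:12)])
  expect_equal(sum(proj$eigenvalues), sum(apply(X, 2, stats::var)),
               tolerance = 1e-9)
  S <- as.matrix(proj$scores[, seq_along(proj$eigenvalues)])
  cc <- stats::cor(S)
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-8)
  expect_true(all(diff(proj$eigenvalues) <= 1e-12))
  # loadings orthonormal
  R <- proj$rotation
  expect_lt(max(abs(crossprod(R) - diag(ncol(R)))), 1e-9)
})

test_that("already-orthogonal data returns its column variances as eigenvalues", {
  withr::with_seed(5, {
    X <- cbind(rnorm(2000, sd = 3), rnorm(2000, sd = 1), rnorm(2000, sd = 0.2))
    X <- scale(X, scale = FALSE)
    # exact orthogonalization of the sample
    X <- qr.Q(qr(X)) %*% diag(sqrt(colSums(scale(X, scale = FALSE)^2)))
  })
  m <- tibble::as_tibble(as.data.frame(X))
  names(m) <- c("a", "b", "c")
  m$outcome <- rep(c(0, 1), 1000)
  proj <- orthogonalize(m, standardize = FALSE)
  expect_equal(proj$eigenvalues,
               sort(apply(X, 2, stats::var), decreasing = TRUE),
               tolerance = 1e-6)
})

test_that("rank-1 data yields exactly one nonzero eigenvalue", {
  withr::with_seed(6, v <- rnorm(30))
  m <- tibble::tibble(a = v, b = 2 * v, c = -0.5 * v,
                      outcome = rep(c(0, 1), 15))
  proj <- orthogonalize(m, standardize = FALSE)
  expect_gt(proj$eigenvalues[1], 0)
  expect_lt(proj$eigenvalues[2] / proj$eigenvalues[1], 1e-12)
})

test_that("constant columns are refused under standardization, by name", {
  m <- tibble::tibble(good = rnorm(10), flat = rep(1, 10),
                      outcome = rep(c(0, 1), 5))
  expect_error(orthogonalize(m, standardize = TRUE), "flat")
})

test_that("reduction keeps the smallest k reaching the variance threshold", {
  fake <- structure(
    list(eigenvalues = c(98, 1.5, 0.5),
         scores = tibble::tibble(PC1 = rnorm(10), PC2 = rnorm(10),
                                 PC3 = rnorm(10),
                                 outcome = rep(c(0, 1), 5))),
    class = "vf_projection")
  red <- reduce_dimensions(fake, 0.99)
  expect_equal(attr(red, "retained_k"), 2)
  red_all <- reduce_dimensions(fake, 1.0)
  expect_equal(attr(red_all, "retained_k"), 3)
})

test_that("retained variance at the default threshold is at least 99%", {
  m <- random_features(80, 15, seed = 9)
  proj <- orthogonalize(m)
  red <- reduce_dimensions(proj)
  k <- attr(red, "retained_k")
  # independent recomputation from standardized data
  X <- scale(as.matrix(m[paste0("f", 1:15)]))
  ev <- sort(eigen(stats::cov(X), symmetric = TRUE)$values,
             decreasing = TRUE)
  expect_gte(sum(ev[1:k]) / sum(ev), 0.99)
  expect_equal(attr(red, "retained_variance"), sum(ev[1:k]) / sum(ev),
               tolerance = 1e-9)
})

test_that("two-class ANOVA per feature equals the squared pooled t", {
  m <- random_features(40, 5, seed = 12, delta = 1)
  an <- anova_per_feature(m)
  expect_equal(nrow(an), 5)
  tt <- stats::t.test(m$f1[m$outcome == 1], m$f1[m$outcome == 0],
                      var.equal = TRUE)
  expect_equal(an$F[1], unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(an$p[1], tt$p.value, tolerance = 1e-9)
  # direct between/within mean-square oracle
  g1 <- c(1, 2, 3); g2 <- c(4, 5, 6)
  m2 <- tibble::tibble(f = c(g1, g2), outcome = rep(c(0, 1), each = 3))
  F_oracle <- {
    gm <- mean(c(g1, g2))
    ssb <- 3 * (mean(g1) - gm)^2 + 3 * (mean(g2) - gm)^2
    ssw <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)
    (ssb / 1) / (ssw / 4)
  }
  expect_equal(anova_per_feature(m2)$F, F_oracle, tolerance = 1e-9)
  expect_error(anova_per_feature(tibble::tibble(f = 1:4,
                                                outcome = rep(1, 4))),
               "classes")
})

test_that("Kruskal-Wallis per feature matches the rank-formula oracle", {
  m <- tibble::tibble(f = c(1, 2, 3, 4), outcome = c(0, 0, 1, 1))
  kw <- kw_per_feature(m)
  # direct rank formula, no ties
  r <- rank(m$f)
  H_oracle <- 12 / (4 * 5) * (sum(r[1:2])^2 / 2 + sum(r[3:4])^2 / 2) - 3 * 5
  expect_equal(kw$H, H_oracle, tolerance = 1e-9)
  # identical samples in both groups: H = 0 with tie correction, p in the 1 region
  m0 <- tibble::tibble(f = rep(c(5, 7), 4), outcome = rep(c(0, 1), each = 4))
  kw0 <- kw_per_feature(m0)
  expect_equal(kw0$H, 0, tolerance = 1e-9)
  expect_gt(kw0$p, 0.99)
  # invariance under monotone transforms
  m3 <- random_features(30, 3, seed = 17, delta = 0.8)
  h1 <- kw_per_feature(m3)$H
  m3e <- m3
  for (f in paste0("f", 1:3)) m3e[[f]] <- exp(m3e[[f]])
  expect_equal(kw_per_feature(m3e)$H, h1, tolerance = 1e-9)
})

test_that("Hotelling T-squared reduces to ANOVA in one dimension", {
  m <- random_features(40, 1, seed = 19, delta = 1)
  mv <- manova_features(m)
  an <- anova_per_feature(m)
  expect_equal(mv$F, an$F[1], tolerance = 1e-9)
  expect_equal(mv$p, an$p[1], tolerance = 1e-9)
})

test_that("Hotelling T-squared is calibrated under equal means and detects shifts", {
  m0 <- random_features(100, 4, seed = 21, delta = 0)
  mv0 <- manova_features(m0)
  expect_gt(mv0$p, 0.05)
  m1 <- random_features(100, 4, seed = 21, delta = 1.5)
  expect_lt(manova_features(m1)$p, 1e-6)
  # cross-check against stats::manova (Pillai = Hotelling for 2 groups)
  X <- as.matrix(m1[paste0("f", 1:4)])
  fit <- summary(stats::manova(X ~ factor(m1$outcome)), test = "Hotelling-Lawley")
  F_ref <- fit$stats[1, "approx F"]
  expect_equal(manova_features(m1)$F, unname(F_ref), tolerance = 1e-6)
})

test_that("the accumulated false-positive curve follows its closed form", {
  expect_equal(accumulate_fp(c(0, 0, 0))$cum_fp, c(0, 0, 0))
  one <- accumulate_fp(0.05)
  expect_equal(one$cum_fp, 0.05)
  expect_equal(one$cum_fp_scaled, 0.5)
  two <- accumulate_fp(c(0.01, 0.02))
  expect_equal(two$cum_fp[2], 1 - 0.99 * 0.98, tolerance = 1e-12)
  expect_error(accumulate_fp(c(0.5, 1.2)), "p_values")
})
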