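test_that("ROC handles perfect, reversed and degenerate rankings", {
  expect_equal(roc_curve(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_curve(c(0.9, 0.8, 0.2, 0.1), c(0, 0, 1, 1))$auc, 0)
  expect_equal(roc_curve(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_error(roc_curve(1:4, rep(1, 4)), "classes")
})

test_that("trapezoid AUC equals exhaustive pairwise concordance", {
  withr::with_seed(23, {
    for (i in 1:5) {
      n <- 20
      y <- rbinom(n, 1, 0.5)
      if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
      s <- round(runif(n), 2)            # force ties
      auc <- roc_curve(s, y)$auc
      pos <- s[y == 1]; neg <- s[y == 0]
      conc <- mean(outer(pos, neg, function(a, b)
        (a > b) + 0.5 * (a == b)))
      expect_equal(auc, conc, tolerance = 1e-9)
    }
  })
})

test_that("AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(29, {
    y <- rbinom(40, 1, 0.4); y[1:2] <- c(0, 1)
    s <- rnorm(40) + y
  })
  ours <- roc_curve(s, y)$auc
  ref <- as.numeric(suppressMessages(pROC::auc(pROC::roc(y, s, quiet = TRUE))))
  expect_equal(ours, ref, tolerance = 1e-9)
})

test_that("operating points match an exhaustive threshold sweep", {
  withr::with_seed(31, {
    y <- rbinom(50, 1, 0.4); y[1:2] <- c(0, 1)
    s <- round(runif(50), 2)
  })
  roc <- roc_curve(s, y)
  got <- metrics_at_sensitivity(roc, c(0.8, 0.9))
  for (r in seq_len(nrow(got))) {
    tg <- got$target[r]
    # oracle: sweep all candidate thresholds, keep the largest with sens >= tg
    cand <- sort(unique(c(s, Inf)), decreasing = TRUE)
    best <- NULL
    for (th in cand) {
      sens <- sum(s >= th & y == 1) / sum(y == 1)
      if (sens >= tg) { best <- th; break }
    }
    sens_o <- sum(s >= best & y == 1) / sum(y == 1)
    spec_o <- sum(s < best & y == 0) / sum(y == 0)
    acc_o <- mean((s >= best) == (y == 1))
    expect_equal(got$threshold[r], best)
    expect_equal(got$sens[r], sens_o)
    expect_equal(got$spec[r], spec_o)
    expect_equal(got$acc[r], acc_o)
  }
  # degenerate score sets
  deg <- roc_curve(rep(0.3, 10), rep(c(0, 1), 5))
  md <- metrics_at_sensitivity(deg, 0.8)
  expect_equal(md$sens, 1)
  expect_equal(md$spec, 0)
})

test_that("the Table-1 hyperparameter defaults are encoded in the specs", {
  rf <- model_spec("RANDOM_FOREST")
  expect_equal(rf$grid$trees, 100L)
  expect_equal(rf$grid$feature_fraction, 0.8)
  nn <- model_spec("BACKPROP_NN")
  expect_equal(nn$grid$iterations, 500L)
  expect_equal(nn$grid$learning_rate, 0.3)
  expect_equal(nn$grid$momentum, 0.4)
  ab <- model_spec("ADABOOST_TREES")
  expect_equal(ab$grid$iterations, 100L)
  bl <- model_spec("BAYES_LOGISTIC")
  expect_equal(bl$grid$prior, "gaussian")
  al <- model_spec("ADDITIVE_LOGISTIC")
  expect_equal(al$max_features, 20L)
})

test_that("every classifier fits and predicts calibrated-side probabilities", {
  m <- toy_features(n = 80, p = 4, delta = 3, seed = 33)
  X <- as.matrix(m[paste0("f", 1:4)])
  for (alg in c("ADDITIVE_LOGISTIC", "RANDOM_FOREST", "BAYES_LOGISTIC",
                "BACKPROP_NN", "ADABOOST_TREES")) {
    hyper <- vfmdi:::grid_rows(vfmdi:::default_grid(alg))[[1]]
    fit <- vfmdi:::fit_classifier(alg, X, m$outcome, hyper, seed = 5)
    p <- vfmdi:::predict_prob(fit, X)
    expect_true(all(p >= 0 & p <= 1))
    expect_gt(roc_curve(p, m$outcome)$auc, 0.9)
  }
})

test_that("stratified folds balance sizes and classes", {
  withr::with_seed(35, y <- rbinom(83, 1, 0.4))
  folds <- vfmdi:::make_folds(y, 10, seed = 2)
  sizes <- table(folds)
  expect_lte(max(sizes) - min(sizes), 1)
  per_fold_pos <- tapply(y, folds, sum)
  expect_lte(max(per_fold_pos) - min(per_fold_pos), 2)
})

test_that("a single separating feature is selected in every fold with AUC 1", {
  m <- toy_features(n = 60, p = 5, delta = 0, seed = 37)
  m$f3 <- m$outcome * 10 + rnorm(60, 0, 0.01)
  rep <- nested_cv(m, model_spec(grid = list(iterations = 10L),
                                 max_features = 3),
                   k = 5, seed = 3, inner_k = 4)
  expect_equal(rep$auc, 1)
  expect_true(all(vapply(rep$fold_info,
                         function(fi) "f3" %in% fi$features, TRUE)))
  expect_true(all(!is.na(rep$oof$prob)))
  expect_equal(sort(unique(rep$oof$fold)), 1:5)
})

test_that("training-fold models ignore test-fold labels entirely", {
  m <- toy_features(n = 60, p = 4, delta = 1.5, seed = 39)
  spec <- model_spec(grid = list(iterations = 10L), max_features = 3)
  folds <- vfmdi:::make_folds(m$outcome, 5, seed = 11)
  r1 <- nested_cv(m, spec, seed = 7, inner_k = 4, folds = folds)
  corrupted <- m
  corrupted$outcome[folds == 2] <- 1 - corrupted$outcome[folds == 2]
  # both classes must survive in fold 2 for the report to build
  if (length(unique(corrupted$outcome[folds == 2])) < 2) {
    corrupted$outcome[which(folds == 2)[1]] <-
      1 - corrupted$outcome[which(folds == 2)[1]]
  }
  r2 <- nested_cv(corrupted, spec, seed = 7, inner_k = 4, folds = folds)
  expect_identical(r1$oof$prob[folds == 2], r2$oof$prob[folds == 2])
})

test_that("the final model is deterministic, serializable and fast to apply", {
  m <- toy_features(n = 80, p = 5, delta = 3, seed = 41)
  fit1 <- train_final(m, model_spec(grid = list(iterations = 20L),
                                    max_features = 4), seed = 9, inner_k = 4)
  fit2 <- train_final(m, model_spec(grid = list(iterations = 20L),
                                    max_features = 4), seed = 9, inner_k = 4)
  newx <- toy_features(n = 100, p = 5, delta = 3, seed = 43)
  p1 <- predict(fit1, newx)
  expect_identical(p1, predict(fit2, newx))
  # serialization round-trip
  path <- withr::local_tempfile(fileext = ".rds")
  saveRDS(fit1, path)
  expect_identical(predict(readRDS(path), newx), p1)
  # separable training rows land on the correct side of 0.5
  ptr <- predict(fit1, m)
  expect_gt(mean((ptr > 0.5) == (m$outcome == 1)), 0.95)
  # single-vector latency budget
  one <- newx[1, ]
  elapsed <- system.time(for (i in 1:20) predict(fit1, one))[["elapsed"]] / 20
  expect_lt(elapsed, 0.08)
})

test_that("schema mismatches are refused at prediction time", {
  m <- toy_features(n = 40, p = 3, delta = 2, seed = 45)
  fit <- train_final(m, model_spec(grid = list(iterations = 10L),
                                   max_features = 2), seed = 1, inner_k = 3)
  bad <- toy_features(n = 5, p = 3, seed = 46)
  names(bad)[1] <- "other"
  expect_error(predict(fit, bad), "exist|schema")
})
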