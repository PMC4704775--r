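# Classifier suite behind the nested cross-validation.  The additive
# logistic regression (LogitBoost with depth-1 weighted-least-squares
# stumps) is the primary model; random forest, Gaussian-prior (ridge)
# logistic regression, a momentum back-propagation network and AdaBoost
# over entropy-split trees are the comparison paradigms.

# evaluate code with a private, restored-afterwards RNG stream
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Model specification for the classification stage
#'
#' Fixes the learning algorithm, its hyperparameter grid (tuned by the inner
#' cross-validation level) and the cap on wrapper-selected features.
#' Algorithm defaults mirror the comparison suite: random forest with 100
#' trees on 80% of features, Gaussian-prior Bayesian logistic regression,
#' a 500-iteration back-propagation network with learning rate 0.3 and
#' momentum 0.4, 100 rounds of AdaBoost over entropy-split trees, and the
#' default additive logistic regression (LogitBoost) with up to 20 features.
#'
#' @param algorithm One of `"ADDITIVE_LOGISTIC"`, `"RANDOM_FOREST"`,
#'   `"BAYES_LOGISTIC"`, `"BACKPROP_NN"`, `"ADABOOST_TREES"`.
#' @param grid Named list of hyperparameter vectors; the cartesian product
#'   is searched at tuning level.  `NULL` takes the algorithm default.
#' @param max_features Wrapper feature-selection cap (default 20).
#' @return A `model_spec`.
#' @export
model_spec <- function(algorithm = c("ADDITIVE_LOGISTIC", "RANDOM_FOREST",
                                     "BAYES_LOGISTIC", "BACKPROP_NN",
                                     "ADABOOST_TREES"),
                       grid = NULL, max_features = 20) {
  algorithm <- match.arg(algorithm)
  if (is.null(grid)) grid <- default_grid(algorithm)
  stopifnot(is.list(grid), length(grid) >= 1L, max_features >= 1)
  structure(list(algorithm = algorithm, grid = grid,
                 max_features = as.integer(max_features)),
            class = "model_spec")
}

default_grid <- function(algorithm) {
  switch(algorithm,
    ADDITIVE_LOGISTIC = list(iterations = c(20L, 50L)),
    RANDOM_FOREST = list(trees = 100L, feature_fraction = 0.8),
    BAYES_LOGISTIC = list(prior = "gaussian", lambda = c(0.01, 0.1)),
    BACKPROP_NN = list(iterations = 500L, learning_rate = 0.3,
                       momentum = 0.4, hidden = c(3L, 6L)),
    ADABOOST_TREES = list(iterations = 100L, max_depth = c(1L, 2L)))
}

grid_rows <- function(grid) {
  df <- expand.grid(grid, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s, %d grid point(s), max %d features\n",
              x$algorithm, length(grid_rows(x$grid)), x$max_features))
  invisible(x)
}

# -- fitting ------------------------------------------------------------------

fit_classifier <- function(algorithm, X, y, hyper, seed) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.integer(y)
  fit <- with_local_seed(seed, switch(algorithm,
    ADDITIVE_LOGISTIC = fit_logitboost(X, y,
      iterations = hyper$iterations %||% 50L),
    RANDOM_FOREST = randomForest::randomForest(
      x = X, y = factor(y, levels = c(0, 1)),
      ntree = hyper$trees %||% 100L,
      mtry = max(1L, floor((hyper$feature_fraction %||% 0.8) * ncol(X)))),
    BAYES_LOGISTIC = fit_ridge_logistic(X, y, lambda = hyper$lambda %||% 0.1),
    BACKPROP_NN = fit_backprop_nn(X, y,
      iterations = hyper$iterations %||% 500L,
      learning_rate = hyper$learning_rate %||% 0.3,
      momentum = hyper$momentum %||% 0.4,
      hidden = hyper$hidden %||% 3L),
    ADABOOST_TREES = fit_adaboost(X, y,
      iterations = hyper$iterations %||% 100L,
      max_depth = hyper$max_depth %||% 1L)))
  structure(list(algorithm = algorithm, fit = fit, hyper = hyper,
                 features = colnames(X), seed = seed),
            class = "vf_classifier")
}

predict_prob <- function(model, X) {
  stopifnot(inherits(model, "vf_classifier"))
  X <- as.matrix(X)
  if (!is.null(model$features) && !is.null(colnames(X))) {
    if (!all(model$features %in% colnames(X))) {
      stop("feature schema mismatch: missing ",
           paste(setdiff(model$features, colnames(X)), collapse = ", "),
           call. = FALSE)
    }
    X <- X[, model$features, drop = FALSE]
  } else if (ncol(X) != length(model$features)) {
    stop("feature schema mismatch: expected ", length(model$features),
         " columns", call. = FALSE)
  }
  storage.mode(X) <- "double"
  p <- switch(model$algorithm,
    ADDITIVE_LOGISTIC = predict_logitboost(model$fit, X),
    RANDOM_FOREST = unname(
      stats::predict(model$fit, newdata = X, type = "prob")[, "1"]),
    BAYES_LOGISTIC = predict_ridge_logistic(model$fit, X),
    BACKPROP_NN = predict_backprop_nn(model$fit, X),
    ADABOOST_TREES = predict_adaboost(model$fit, X))
  pmin(pmax(as.numeric(p), 0), 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# -- additive logistic regression (LogitBoost, depth-1 WLS stumps) -----------

# Stagewise additive modelling of the logistic log-likelihood: at each round
# the working response z = (y - p) / (p (1 - p)) is fitted by the best
# weighted-least-squares stump (weights p (1 - p)), and half of the fit is
# added to the score F; p = 1 / (1 + exp(-2 F)).
fit_logitboost <- function(X, y, iterations = 50L, z_max = 4) {
  n <- nrow(X)
  ord <- lapply(seq_len(ncol(X)), function(j) order(X[, j]))
  Fx <- numeric(n)
  stumps <- vector("list", iterations)
  for (m in seq_len(iterations)) {
    p <- 1 / (1 + exp(-2 * Fx))
    w <- pmax(p * (1 - p), 1e-10)
    z <- pmin(pmax((y - p) / w, -z_max), z_max)
    best <- NULL
    for (j in seq_len(ncol(X))) {
      o <- ord[[j]]
      xs <- X[o, j]; ws <- w[o]; zs <- z[o]
      cw <- cumsum(ws); cwz <- cumsum(ws * zs)
      W <- cw[n]; WZ <- cwz[n]
      valid <- which(diff(xs) > 0)
      if (length(valid) == 0L) next
      gain <- cwz[valid]^2 / cw[valid] +
        (WZ - cwz[valid])^2 / (W - cw[valid])
      b <- which.max(gain)
      i <- valid[b]
      cand <- list(feature = j,
                   threshold = (xs[i] + xs[i + 1L]) / 2,
                   left = cwz[i] / cw[i],
                   right = (WZ - cwz[i]) / (W - cw[i]),
                   gain = gain[b])
      if (is.null(best) || cand$gain > best$gain) best <- cand
    }
    if (is.null(best)) {             # all features constant: intercept fit
      mu <- sum(w * z) / sum(w)
      best <- list(feature = 1L, threshold = Inf, left = mu, right = mu,
                   gain = 0)
    }
    fx <- ifelse(X[, best$feature] <= best$threshold, best$left, best$right)
    Fx <- Fx + 0.5 * fx
    stumps[[m]] <- best
  }
  list(stumps = stumps)
}

predict_logitboost <- function(fit, X) {
  Fx <- numeric(nrow(X))
  for (s in fit$stumps) {
    Fx <- Fx + 0.5 * ifelse(X[, s$feature] <= s$threshold, s$left, s$right)
  }
  1 / (1 + exp(-2 * Fx))
}

# -- Gaussian-prior (ridge) logistic regression ------------------------------

fit_ridge_logistic <- function(X, y, lambda = 0.1) {
  pad <- ncol(X) < 2L                 # glmnet requires >= 2 columns
  Xg <- if (pad) cbind(X, .pad = 0) else X
  fit <- glmnet::glmnet(Xg, factor(y, levels = c(0, 1)), family = "binomial",
                        alpha = 0, lambda = lambda, standardize = TRUE)
  list(glmnet = fit, lambda = lambda, pad = pad)
}

predict_ridge_logistic <- function(fit, X) {
  Xg <- if (fit$pad) cbind(X, .pad = 0) else X
  as.numeric(stats::predict(fit$glmnet, newx = Xg, s = fit$lambda,
                            type = "response"))
}

# -- back-propagation neural network -----------------------------------------

# One sigmoid hidden layer, sigmoid output, cross-entropy loss, full-batch
# gradient descent with a fixed learning rate and momentum term.
fit_backprop_nn <- function(X, y, iterations = 500L, learning_rate = 0.3,
                            momentum = 0.4, hidden = 3L) {
  center <- colMeans(X)
  scale <- pmax(apply(X, 2L, stats::sd), 1e-8)
  Xs <- sweep(sweep(X, 2L, center), 2L, scale, `/`)
  n <- nrow(Xs); p <- ncol(Xs)
  W1 <- matrix(stats::runif((p + 1L) * hidden, -0.5, 0.5), p + 1L, hidden)
  W2 <- matrix(stats::runif(hidden + 1L, -0.5, 0.5), hidden + 1L, 1L)
  V1 <- W1 * 0; V2 <- W2 * 0
  X1 <- cbind(1, Xs)
  sig <- function(u) 1 / (1 + exp(-u))
  for (it in seq_len(iterations)) {
    H <- sig(X1 %*% W1)
    H1 <- cbind(1, H)
    out <- sig(H1 %*% W2)
    delta_out <- (out - y) / n                  # dL/du for cross-entropy
    g2 <- crossprod(H1, delta_out)
    delta_h <- (delta_out %*% t(W2[-1L, , drop = FALSE])) * H * (1 - H)
    g1 <- crossprod(X1, delta_h)
    V2 <- momentum * V2 - learning_rate * g2
    V1 <- momentum * V1 - learning_rate * g1
    W2 <- W2 + V2; W1 <- W1 + V1
  }
  list(W1 = W1, W2 = W2, center = center, scale = scale)
}

predict_backprop_nn <- function(fit, X) {
  Xs <- sweep(sweep(X, 2L, fit$center), 2L, fit$scale, `/`)
  sig <- function(u) 1 / (1 + exp(-u))
  H <- sig(cbind(1, Xs) %*% fit$W1)
  as.numeric(sig(cbind(1, H) %*% fit$W2))
}

# -- AdaBoost over entropy-split trees ---------------------------------------

fit_adaboost <- function(X, y, iterations = 100L, max_depth = 1L) {
  n <- nrow(X)
  df <- as.data.frame(X)
  df$.y <- factor(y, levels = c(0, 1))
  w <- rep(1 / n, n)
  trees <- list(); alphas <- numeric(0)
  for (m in seq_len(iterations)) {
    tr <- rpart::rpart(.y ~ ., data = df, weights = w,
                       method = "class",
                       parms = list(split = "information"),
                       control = rpart::rpart.control(
                         maxdepth = max_depth, cp = 0, minsplit = 4L,
                         xval = 0L))
    pred <- as.integer(as.character(stats::predict(tr, df, type = "class")))
    err <- sum(w * (pred != y))
    if (err <= 1e-10) { trees <- c(trees, list(tr)); alphas <- c(alphas, 10); break }
    if (err >= 0.5) break
    a <- 0.5 * log((1 - err) / err)
    w <- w * exp(a * ifelse(pred != y, 1, -1))
    w <- w / sum(w)
    trees <- c(trees, list(tr)); alphas <- c(alphas, a)
  }
  if (length(trees) == 0L) {          # unlearnable: constant score
    return(list(trees = list(), alphas = numeric(0), base = mean(y)))
  }
  list(trees = trees, alphas = alphas, base = mean(y))
}

predict_adaboost <- function(fit, X) {
  if (length(fit$trees) == 0L) return(rep(fit$base, nrow(X)))
  df <- as.data.frame(X)
  score <- numeric(nrow(X))
  for (m in seq_along(fit$trees)) {
    pred <- as.integer(as.character(
      stats::predict(fit$trees[[m]], df, type = "class")))
    score <- score + fit$alphas[m] * ifelse(pred == 1, 1, -1)
  }
  1 / (1 + exp(-2 * score / max(sum(fit$alphas), 1e-12) * 3))
}
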