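# Twice-nested cross-validation with wrapper feature selection, ROC and
# threshold reporting.  Outer folds estimate generalization; inside each
# outer training set, one inner level (L2) greedily selects features by
# mean inner-fold AUC and a second (L1) tunes hyperparameters on the
# selected subset.  All preprocessing statistics (standardization,
# projection, prototype selection) are fitted on outer-training data only.

#' ROC curve and area under the curve
#'
#' Sweeps every distinct score as a decision threshold (predict success when
#' `score >= threshold`) and records sensitivity/specificity; the AUC is the
#' trapezoidal area, which equals the Mann-Whitney concordance probability
#' (ties counted half).
#'
#' @param scores Numeric scores, larger = more likely successful.
#' @param outcomes Binary outcomes (1 = successful).
#' @return A `vf_roc`: list with `points` (tibble: `threshold`, `tp`, `fp`,
#'   `sens`, `spec`), `auc`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, outcomes) {
  stopifnot(length(scores) == length(outcomes), all(outcomes %in% c(0, 1)))
  n_pos <- sum(outcomes == 1); n_neg <- sum(outcomes == 0)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both outcome classes are required for ROC analysis", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- outcomes[ord]
  cum_tp <- cumsum(y == 1); cum_fp <- cumsum(y == 0)
  last <- c(s[-1L] != s[-length(s)], TRUE)   # last row of each tied block
  pts <- tibble::tibble(
    threshold = c(Inf, s[last]),
    tp = c(0L, cum_tp[last]), fp = c(0L, cum_fp[last]))
  pts$sens <- pts$tp / n_pos
  pts$spec <- 1 - pts$fp / n_neg
  fpr <- pts$fp / n_neg
  auc <- sum(diff(fpr) * (pts$sens[-1L] + pts$sens[-nrow(pts)]) / 2)
  structure(list(points = pts, auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "vf_roc")
}

#' @export
print.vf_roc <- function(x, ...) {
  cat(sprintf("<vf_roc> AUC %.3f (%d positives, %d negatives)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

best_accuracy <- function(roc) {
  with(roc, max((points$tp + (n_neg - points$fp)) / (n_pos + n_neg)))
}

#' Operating points at requested sensitivity levels
#'
#' For each target, picks the largest threshold whose sensitivity reaches
#' the target and reports the achieved sensitivity, specificity and
#' accuracy there (achieved values can exceed the target on finite data).
#'
#' @param roc A [roc_curve()] result.
#' @param targets Sensitivity targets in (0, 1); default 0.80 and 0.90.
#' @return Tibble with `target`, `threshold`, `sens`, `spec`, `acc`.
#' @export
metrics_at_sensitivity <- function(roc, targets = c(0.8, 0.9)) {
  stopifnot(inherits(roc, "vf_roc"), all(targets > 0 & targets < 1))
  pts <- roc$points
  purrr::map_dfr(targets, function(tg) {
    i <- which(pts$sens >= tg)[1L]          # sens nondecreasing down the sweep
    tibble::tibble(
      target = tg, threshold = pts$threshold[i], sens = pts$sens[i],
      spec = pts$spec[i],
      acc = (pts$tp[i] + (roc$n_neg - pts$fp[i])) / (roc$n_pos + roc$n_neg))
  })
}

# stratified fold assignment; class-wise round-robin keeps fold sizes within
# one of each other.  With a grouping vector, whole groups are dealt to
# folds (stratified on the group's majority outcome).
make_folds <- function(y, k, seed, groups = NULL) {
  with_local_seed(seed, {
    if (is.null(groups)) {
      fold <- integer(length(y))
      counter <- 0L
      for (cls in sort(unique(y), decreasing = TRUE)) {
        idx <- sample(which(y == cls))
        fold[idx] <- ((counter + seq_along(idx) - 1L) %% k) + 1L
        counter <- counter + length(idx)
      }
      fold
    } else {
      gl <- split(seq_along(y), groups)
      g_out <- vapply(gl, function(i) round(mean(y[i])), 0)
      g_fold <- integer(length(gl))
      counter <- 0L
      for (cls in sort(unique(g_out), decreasing = TRUE)) {
        gi <- sample(which(g_out == cls))
        g_fold[gi] <- ((counter + seq_along(gi) - 1L) %% k) + 1L
        counter <- counter + length(gi)
      }
      fold <- integer(length(y))
      for (j in seq_along(gl)) fold[gl[[j]]] <- g_fold[j]
      fold
    }
  })
}

mean_inner_auc <- function(X, y, feats, algorithm, hyper, inner_folds, seed) {
  aucs <- c()
  for (f in sort(unique(inner_folds))) {
    tr <- inner_folds != f; te <- !tr
    if (length(unique(y[te])) < 2L || length(unique(y[tr])) < 2L) next
    m <- fit_classifier(algorithm, X[tr, feats, drop = FALSE], y[tr], hyper,
                        seed + f)
    p <- predict_prob(m, X[te, feats, drop = FALSE])
    aucs <- c(aucs, roc_curve(p, y[te])$auc)
  }
  if (length(aucs) == 0L) return(NA_real_)
  mean(aucs)
}

# greedy forward selection by mean inner AUC; ties break to the lower
# feature index; stops when no candidate improves or the cap is reached
forward_select <- function(X, y, algorithm, hyper, max_features, inner_k,
                           seed) {
  feats <- colnames(X)
  inner_folds <- make_folds(y, inner_k, seed)
  selected <- character(0)
  best_auc <- -Inf
  while (length(selected) < min(max_features, ncol(X))) {
    cand <- setdiff(feats, selected)
    scores <- vapply(cand, function(f) {
      mean_inner_auc(X, y, c(selected, f), algorithm, hyper, inner_folds,
                     seed)
    }, 0)
    j <- which.max(scores)            # first max = lowest feature index
    if (!is.finite(scores[j]) || scores[j] <= best_auc + 1e-9) break
    best_auc <- scores[j]
    selected <- c(selected, cand[j])
  }
  if (length(selected) == 0L) selected <- feats[1L]
  list(features = selected, inner_auc = best_auc)
}

tune_hyper <- function(X, y, feats, spec, inner_k, seed) {
  rows <- grid_rows(spec$grid)
  if (length(rows) == 1L) return(list(hyper = rows[[1L]], inner_auc = NA_real_))
  inner_folds <- make_folds(y, inner_k, seed)
  aucs <- vapply(rows, function(h) {
    mean_inner_auc(X, y, feats, spec$algorithm, h, inner_folds, seed)
  }, 0)
  j <- which.max(aucs)
  list(hyper = rows[[j]], inner_auc = aucs[j])
}

#' Twice-nested cross-validated evaluation
#'
#' Outer stratified k-fold cross-validation around per-fold wrapper feature
#' selection (level 2) and hyperparameter tuning (level 1).  Every shock is
#' predicted exactly once, out of fold; preprocessing fitted through
#' `transform` sees only the outer-training rows.
#'
#' @param matrix Feature tibble with an `outcome` column; optional
#'   `patient_id` column for patient-grouped folds; list-columns are passed
#'   through to `transform`.
#' @param spec A [model_spec()].
#' @param k Outer folds (default 10).
#' @param seed Master seed; all fold and fit seeds derive from it.
#' @param inner_k Inner folds for both nested levels (default 10).
#' @param transform Per-fold preprocessing: `function(train, test)` returning
#'   `list(train =, test =)` numeric feature tibbles (both with `outcome`).
#'   Default passes features through unchanged; see [mdi_fold_transform()].
#' @param group_by_patient Deal whole patients to folds when a `patient_id`
#'   column is present (default `TRUE`), preventing within-patient leakage.
#' @param folds Optional precomputed outer fold assignment (length
#'   `nrow(matrix)`), overriding internal fold construction.
#' @param sens_targets Sensitivity levels for the operating-point table.
#' @return A `cv_report`: out-of-fold predictions, ROC, AUC, accuracy at the
#'   best threshold, operating points, and per-fold selection details.
#' @export
nested_cv <- function(matrix, spec, k = 10, seed = 1, inner_k = 10,
                      transform = NULL, group_by_patient = TRUE,
                      folds = NULL, sens_targets = c(0.8, 0.9)) {
  check_feature_matrix_schema(matrix)
  stopifnot(inherits(spec, "model_spec"))
  y <- matrix$outcome
  stopifnot(all(y %in% c(0, 1)))
  if (is.null(folds)) {
    groups <- if (group_by_patient && "patient_id" %in% names(matrix))
      matrix$patient_id else NULL
    folds <- make_folds(y, k, seed, groups)
  }
  if (is.null(transform)) {
    transform <- function(train, test) {
      fc <- feature_columns(train)
      list(train = train[c(fc, "outcome")], test = test[c(fc, "outcome")])
    }
  }
  oof <- rep(NA_real_, length(y))
  fold_info <- vector("list", max(folds))
  for (f in sort(unique(folds))) {
    tr_idx <- which(folds != f); te_idx <- which(folds == f)
    if (length(unique(y[tr_idx])) < 2L) {
      stop("outcome class absent from a training fold", call. = FALSE)
    }
    tt <- transform(matrix[tr_idx, , drop = FALSE],
                    matrix[te_idx, , drop = FALSE])
    fc <- feature_columns(tt$train)
    Xtr <- as.matrix(tt$train[fc]); Xte <- as.matrix(tt$test[fc])
    if (!all(is.finite(Xtr)) || !all(is.finite(Xte))) {
      stop("non-finite feature after fold transform", call. = FALSE)
    }
    fs_seed <- seed * 1000L + f * 13L
    hyper0 <- grid_rows(spec$grid)[[1L]]
    sel <- forward_select(Xtr, y[tr_idx], spec$algorithm, hyper0,
                          spec$max_features, inner_k, fs_seed)
    tuned <- tune_hyper(Xtr, y[tr_idx], sel$features, spec, inner_k,
                        fs_seed + 7L)
    model <- fit_classifier(spec$algorithm,
                            Xtr[, sel$features, drop = FALSE], y[tr_idx],
                            tuned$hyper, fs_seed + 91L)
    oof[te_idx] <- predict_prob(model, Xte[, sel$features, drop = FALSE])
    fold_info[[f]] <- list(fold = f, features = sel$features,
                           hyper = tuned$hyper,
                           inner_auc = sel$inner_auc)
  }
  roc <- roc_curve(oof, y)
  structure(
    list(oof = tibble::tibble(
           row = seq_along(y),
           shock_id = if ("shock_id" %in% names(matrix)) matrix$shock_id
                      else as.character(seq_along(y)),
           fold = folds, outcome = y, prob = oof),
         roc = roc, auc = roc$auc, accuracy = best_accuracy(roc),
         at_sensitivity = metrics_at_sensitivity(roc, sens_targets),
         fold_info = fold_info, spec = spec, seed = seed, k = k),
    class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s, %d-fold: AUC %.3f, accuracy %.3f\n",
              x$spec$algorithm, x$k, x$auc, x$accuracy))
  print(x$at_sensitivity)
  invisible(x)
}

#' Per-fold preprocessing for the multi-domain feature set
#'
#' Returns a fold transform for [nested_cv()] that, using outer-training
#' rows only: (1) builds the quasi-period prototype set (per-class medoids
#' of the `qpd_density` list-column) and emits prototype-distance features
#' for both partitions, (2) drops identifier and list columns, and (3)
#' optionally z-scores and projects onto orthogonal axes retaining the
#' requested cumulative variance.
#'
#' @param C Prototypes per class (default 4).
#' @param var_threshold Retained cumulative variance (default 0.99);
#'   `NULL` skips projection.
#' @param standardize Z-score before projection (default `TRUE`).
#' @return A `function(train, test)` suitable for `nested_cv(transform =)`.
#' @export
mdi_fold_transform <- function(C = 4, var_threshold = 0.99,
                               standardize = TRUE) {
  function(train, test) {
    add_kd <- function(tbl, ps) {
      kd <- t(vapply(tbl$qpd_density,
                     function(d) prototype_features(d, ps),
                     numeric(2L * C)))
      dplyr::bind_cols(tbl[setdiff(names(tbl), "qpd_density")],
                       tibble::as_tibble(kd))
    }
    if ("qpd_density" %in% names(train)) {
      ps <- prototype_set(train$qpd_density, train$outcome, C = C)
      train <- add_kd(train, ps); test <- add_kd(test, ps)
    }
    fc <- feature_columns(train)
    train <- train[c(fc, "outcome")]; test <- test[c(fc, "outcome")]
    if (!is.null(var_threshold)) {
      proj <- orthogonalize(train, standardize = standardize)
      red_tr <- reduce_dimensions(proj, var_threshold)
      keep <- setdiff(names(red_tr), "outcome")
      red_te <- stats::predict(proj, test)[c(keep, "outcome")]
      train <- red_tr; test <- red_te
    }
    list(train = train, test = test)
  }
}

#' Train the deployable model on a full feature matrix
#'
#' Fits the fold transform and classifier on all rows (hyperparameters tuned
#' by one inner cross-validation) and returns a self-describing model whose
#' `predict()` maps a new feature row to a success probability.  Prediction
#' on an assembled feature vector is microseconds-to-milliseconds work,
#' comfortably inside a real-time budget.
#'
#' @param matrix Feature tibble as for [nested_cv()].
#' @param spec A [model_spec()].
#' @param seed Master seed.
#' @param inner_k Folds for hyperparameter tuning (default 10).
#' @param transform Preprocessing as in [nested_cv()]; default
#'   [mdi_fold_transform()] when a `qpd_density` column is present, identity
#'   otherwise.
#' @return A `vf_final_model` with elements `model`, `features`, `hyper`,
#'   `schema`, `seed`.  `predict()` expects rows in the transformed feature
#'   schema.
#' @export
train_final <- function(matrix, spec, seed = 1, inner_k = 10,
                        transform = NULL) {
  check_feature_matrix_schema(matrix)
  if (is.null(transform) && "qpd_density" %in% names(matrix)) {
    transform <- mdi_fold_transform()
  }
  if (!is.null(transform)) {
    tt <- transform(matrix, matrix)
    train <- tt$train
  } else {
    fc <- feature_columns(matrix)
    train <- matrix[c(fc, "outcome")]
  }
  fc <- feature_columns(train)
  X <- as.matrix(train[fc]); y <- train$outcome
  sel <- forward_select(X, y, spec$algorithm, grid_rows(spec$grid)[[1L]],
                        spec$max_features, inner_k, seed)
  tuned <- tune_hyper(X, y, sel$features, spec, inner_k, seed + 7L)
  model <- fit_classifier(spec$algorithm, X[, sel$features, drop = FALSE], y,
                          tuned$hyper, seed + 91L)
  structure(list(model = model, features = sel$features,
                 hyper = tuned$hyper, schema = fc, seed = seed),
            class = "vf_final_model")
}

#' @export
print.vf_final_model <- function(x, ...) {
  cat(sprintf("<vf_final_model> %s on %d selected features (seed %d)\n",
              x$model$algorithm, length(x$features), x$seed))
  invisible(x)
}

#' Predict success probability for assembled feature rows
#' @param object A [train_final()] model.
#' @param newdata Tibble/matrix containing the model's schema columns
#'   (already transformed features).
#' @param ... Unused.
#' @return Numeric vector of probabilities.
#' @export
predict.vf_final_model <- function(object, newdata, ...) {
  X <- as.matrix(tibble::as_tibble(newdata)[object$schema])
  predict_prob(object$model, X[, object$features, drop = FALSE])
}
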