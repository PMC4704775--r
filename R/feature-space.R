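# Feature-space validation and reduction: orthogonal projection to ~99%
# cumulative variance, per-feature ANOVA / Kruskal-Wallis screening, a
# two-sample Hotelling T^2 on the reduced set, and the accumulated
# false-positive curve used to compare parameterizations.

feature_columns <- function(matrix) {
  drop_cols <- c("outcome", "patient_id", "shock_id")
  is_num <- vapply(matrix, is.numeric, TRUE)
  setdiff(names(matrix)[is_num], drop_cols)
}

#' Project a feature matrix onto orthogonal axes
#'
#' Centres (and by default z-scores — the prototype-distance, wavelet-energy
#' and time-domain features live on incommensurate scales) the feature
#' columns and rotates them onto principal axes.  The projected columns are
#' uncorrelated and total variance is preserved; each axis carries an
#' eigenvalue giving its share of the total variance.
#'
#' @param matrix Feature tibble with an `outcome` column (id columns and
#'   list-columns are ignored).
#' @param standardize Z-score before rotation (default `TRUE`).
#' @return A `vf_projection`: list with `center`, `scale`, `rotation`,
#'   `eigenvalues`, `scores` (tibble of projected columns plus `outcome`)
#'   and `input_features`.
#' @export
orthogonalize <- function(matrix, standardize = TRUE) {
  check_feature_matrix_schema(matrix)
  feats <- feature_columns(matrix)
  if (length(feats) < 1L || nrow(matrix) < 2L) {
    stop("need at least 2 rows and 1 feature column", call. = FALSE)
  }
  X <- as.matrix(matrix[feats])
  if (!all(is.finite(X))) stop("non-finite feature values", call. = FALSE)
  if (standardize) {
    sds <- apply(X, 2L, stats::sd)
    if (any(sds == 0)) {
      stop("constant column cannot be standardized: ",
           paste(feats[sds == 0], collapse = ", "), call. = FALSE)
    }
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = standardize)
  scores <- tibble::as_tibble(as.data.frame(pc$x))
  scores$outcome <- matrix$outcome
  structure(
    list(center = pc$center,
         scale = if (standardize) pc$scale else NULL,
         rotation = pc$rotation,
         eigenvalues = pc$sdev^2,
         scores = scores,
         input_features = feats),
    class = "vf_projection")
}

#' @export
print.vf_projection <- function(x, ...) {
  cat(sprintf("<vf_projection> %d features -> %d components; top eigenvalue share %.1f%%\n",
              length(x$input_features), length(x$eigenvalues),
              100 * x$eigenvalues[1L] / sum(x$eigenvalues)))
  invisible(x)
}

#' Apply a fitted projection to new data
#' @param object A [orthogonalize()] projection.
#' @param newdata Feature tibble with the projection's input columns.
#' @param ... Unused.
#' @return Tibble of projected columns (plus `outcome` if present).
#' @export
predict.vf_projection <- function(object, newdata, ...) {
  X <- as.matrix(newdata[object$input_features])
  X <- sweep(X, 2L, object$center)
  if (!is.null(object$scale)) X <- sweep(X, 2L, object$scale, `/`)
  out <- tibble::as_tibble(as.data.frame(X %*% object$rotation))
  if ("outcome" %in% names(newdata)) out$outcome <- newdata$outcome
  out
}

#' Retain components up to a cumulative-variance threshold
#'
#' Keeps the smallest number of leading components whose cumulative
#' eigenvalue fraction reaches the threshold (default 99%); the remaining
#' variance is treated as spurious and discarded.
#'
#' @param projection A [orthogonalize()] result.
#' @param var_threshold Cumulative variance fraction in (0, 1] (default
#'   0.99).  At 1.0 all components with nonzero eigenvalue are kept.
#' @return Tibble of the retained score columns plus `outcome`, with
#'   attributes `retained_k`, `retained_variance` and `discarded_fraction`
#'   (share of original columns dropped).
#' @export
reduce_dimensions <- function(projection, var_threshold = 0.99) {
  stopifnot(inherits(projection, "vf_projection"),
            var_threshold > 0, var_threshold <= 1)
  ev <- projection$eigenvalues
  frac <- cumsum(ev) / sum(ev)
  k <- if (var_threshold == 1) sum(ev > 1e-12 * ev[1L])
       else which(frac >= var_threshold - 1e-12)[1L]
  out <- projection$scores[, c(seq_len(k),
                               match("outcome", names(projection$scores)))]
  attr(out, "retained_k") <- k
  attr(out, "retained_variance") <- frac[k]
  attr(out, "discarded_fraction") <- 1 - k / length(ev)
  out
}

#' Per-feature two-class ANOVA
#'
#' One-way fixed-effects ANOVA of each feature against the binary outcome
#' (equal-variance F test; with two classes the F statistic is the square of
#' the pooled two-sample t statistic).
#'
#' @param matrix Feature tibble with an `outcome` column, both classes with
#'   at least 2 rows.
#' @return Tibble with `feature`, `F`, `p`.
#' @export
anova_per_feature <- function(matrix) {
  check_two_classes(matrix)
  g <- factor(matrix$outcome)
  purrr::map_dfr(feature_columns(matrix), function(f) {
    ow <- stats::oneway.test(matrix[[f]] ~ g, var.equal = TRUE)
    tibble::tibble(feature = f, F = unname(ow$statistic), p = ow$p.value)
  })
}

#' Per-feature Kruskal-Wallis test
#'
#' Rank-based analogue of [anova_per_feature()] (with two classes it is the
#' Mann-Whitney-Wilcoxon rank-sum test); tie correction applied.
#'
#' @inheritParams anova_per_feature
#' @return Tibble with `feature`, `H`, `p`.
#' @export
kw_per_feature <- function(matrix) {
  check_two_classes(matrix)
  g <- factor(matrix$outcome)
  purrr::map_dfr(feature_columns(matrix), function(f) {
    kw <- stats::kruskal.test(matrix[[f]], g)
    tibble::tibble(feature = f, H = unname(kw$statistic), p = kw$p.value)
  })
}

check_two_classes <- function(matrix) {
  check_feature_matrix_schema(matrix)
  tab <- table(matrix$outcome)
  if (length(tab) != 2L || any(tab < 2L)) {
    stop("need both outcome classes with at least 2 rows each", call. = FALSE)
  }
  invisible(matrix)
}

#' Two-sample Hotelling T-squared on the reduced feature set
#'
#' Multivariate test of whether the class mean vectors differ; for two
#' factor levels the multivariate analysis of variance reduces to this
#' T-squared, reported with its exact F transform.  With one response
#' column the F statistic equals the per-feature ANOVA F.
#'
#' @param matrix Reduced feature tibble (columns preferably uncorrelated)
#'   with an `outcome` column; needs more rows than retained dimensions + 2.
#' @return List with `T2`, `F`, `df1`, `df2`, `p`.
#' @export
manova_features <- function(matrix) {
  check_two_classes(matrix)
  feats <- feature_columns(matrix)
  X <- as.matrix(matrix[feats])
  p <- ncol(X)
  y <- matrix$outcome
  n1 <- sum(y == 1); n2 <- sum(y == 0)
  if (n1 + n2 <= p + 2L) stop("too few rows for the retained dimensionality",
                              call. = FALSE)
  d <- colMeans(X[y == 1, , drop = FALSE]) - colMeans(X[y == 0, , drop = FALSE])
  S <- ((n1 - 1) * stats::cov(X[y == 1, , drop = FALSE]) +
          (n2 - 1) * stats::cov(X[y == 0, , drop = FALSE])) / (n1 + n2 - 2)
  qr_S <- qr(S)
  if (qr_S$rank < p) stop("singular pooled covariance", call. = FALSE)
  T2 <- (n1 * n2 / (n1 + n2)) * drop(t(d) %*% solve(qr_S, d))
  Fstat <- (n1 + n2 - p - 1) / ((n1 + n2 - 2) * p) * T2
  df1 <- p; df2 <- n1 + n2 - p - 1
  list(T2 = T2, F = Fstat, df1 = df1, df2 = df2,
       p = stats::pf(Fstat, df1, df2, lower.tail = FALSE))
}

#' Accumulated false-positive probability over repeated tests
#'
#' Running probability of at least one false positive after testing each
#' successive feature, under independence: `1 - prod(1 - p_i)`.  The
#' optional scale factor (default 10) eases plotting the curve alongside
#' raw statistic values.
#'
#' @param p_values Numeric p-values in `[0, 1]`, in testing order.
#' @param scale Multiplier for the plotted curve (default 10).
#' @return Tibble with `index`, `cum_fp` and `cum_fp_scaled`.
#' @export
accumulate_fp <- function(p_values, scale = 10) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  cum <- 1 - cumprod(1 - p_values)
  tibble::tibble(index = seq_along(p_values), cum_fp = cum,
                 cum_fp_scaled = scale * cum)
}
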