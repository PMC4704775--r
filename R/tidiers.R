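# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a cross-validation report
#'
#' One row per outer fold: test-fold size, selected feature count and the
#' features themselves, and the inner-CV AUC reached during selection.
#'
#' @param x A `cv_report` from [nested_cv()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy cv_report
#' @export
tidy.cv_report <- function(x, ...) {
  purrr::map_dfr(x$fold_info, function(fi) {
    tibble::tibble(fold = fi$fold,
                   n_test = sum(x$oof$fold == fi$fold),
                   n_features = length(fi$features),
                   features = paste(fi$features, collapse = ";"),
                   inner_auc = fi$inner_auc)
  })
}

#' One-row summary of a cross-validation report
#' @inheritParams tidy.cv_report
#' @return Tibble with algorithm, folds, n, AUC, accuracy and the 80%/90%
#'   sensitivity operating points.
#' @method glance cv_report
#' @export
glance.cv_report <- function(x, ...) {
  at <- x$at_sensitivity
  row <- tibble::tibble(algorithm = x$spec$algorithm, k = x$k,
                        n = nrow(x$oof), auc = x$auc, accuracy = x$accuracy)
  for (i in seq_len(nrow(at))) {
    row[[sprintf("spec_at_sens%.0f", 100 * at$target[i])]] <- at$spec[i]
    row[[sprintf("acc_at_sens%.0f", 100 * at$target[i])]] <- at$acc[i]
  }
  row
}

#' Tidy an orthogonal projection
#' @param x A [orthogonalize()] projection.
#' @param ... Unused.
#' @return Tibble with `component`, `eigenvalue`, `prop_variance`,
#'   `cum_variance`.
#' @method tidy vf_projection
#' @export
tidy.vf_projection <- function(x, ...) {
  ev <- x$eigenvalues
  tibble::tibble(component = seq_along(ev), eigenvalue = ev,
                 prop_variance = ev / sum(ev),
                 cum_variance = cumsum(ev) / sum(ev))
}

#' @rdname tidy.vf_projection
#' @method glance vf_projection
#' @export
glance.vf_projection <- function(x, ...) {
  tibble::tibble(n_features = length(x$input_features),
                 n_components = length(x$eigenvalues),
                 k99 = which(cumsum(x$eigenvalues) / sum(x$eigenvalues) >=
                               0.99)[1L])
}

#' Tidy a separation-criterion value
#' @param x A [sep_criterion()] result.
#' @param ... Unused.
#' @return Tibble with `signal` and per-signal `term`.
#' @method tidy sep_value
#' @export
tidy.sep_value <- function(x, ...) {
  tibble::tibble(signal = seq_along(x$per_signal_terms),
                 term = x$per_signal_terms)
}

#' ROC curve plot for a cross-validation report
#'
#' Sensitivity against 1 - specificity, colour encoding the decision
#' threshold from 0 to 1.
#'
#' @param object A `cv_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cv_report
#' @export
autoplot.cv_report <- function(object, ...) {
  pts <- object$roc$points
  pts$thr <- pmin(pmax(pts$threshold, 0), 1)
  ggplot2::ggplot(pts, ggplot2::aes(x = 1 - spec, y = sens, colour = thr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3,
                         colour = "grey60") +
    ggplot2::geom_path(linewidth = 0.8) +
    ggplot2::scale_colour_gradient(low = "orange", high = "blue",
                                   name = "threshold") +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Quasi-period density plot
#'
#' Bars: normalized quasi-period histogram; line: the exponential-kernel
#' smoothed PDF (scaled to the bar heights for display).
#'
#' @param object A `qpd_density`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot qpd_density
#' @export
autoplot.qpd_density <- function(object, ...) {
  centers <- (object$bin_edges[-1L] +
                object$bin_edges[-length(object$bin_edges)]) / 2
  bars <- tibble::tibble(t = centers, mass = object$mass)
  p <- ggplot2::ggplot(bars, ggplot2::aes(x = t, y = mass)) +
    ggplot2::geom_col(width = diff(object$bin_edges)[1L] * 0.9,
                      fill = "grey65") +
    ggplot2::labs(x = "quasi-period (s)", y = "normalized mass") +
    ggplot2::theme_minimal()
  if (!is.null(object$pdf_grid)) {
    sc <- max(bars$mass) / max(object$pdf_grid)
    line <- tibble::tibble(t = object$grid, y = object$pdf_grid * sc)
    p <- p + ggplot2::geom_line(data = line, ggplot2::aes(x = t, y = y),
                                colour = "firebrick", linewidth = 0.8)
  }
  p
}

#' Segment trace plot
#' @param object A [signal_segment()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot vf_segment
#' @export
autoplot.vf_segment <- function(object, ...) {
  df <- tibble::tibble(
    t = object$start_time + (seq_along(object$samples) - 1L) /
      object$sampling_rate,
    value = object$samples)
  ggplot2::ggplot(df, ggplot2::aes(x = t, y = value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)",
                  y = if (object$channel == "ECG") "mV" else "mmHg") +
    ggplot2::theme_minimal()
}

#' Parameter-selection trace plot
#'
#' Separation criterion across the candidate parameter grid, with skipped
#' (degenerate) grid points marked.
#'
#' @param trace The `trace` tibble from [select_parameters()].
#' @return A ggplot.
#' @export
plot_sep_trace <- function(trace) {
  ggplot2::ggplot(trace, ggplot2::aes(x = grid_index, y = sep)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = skipped)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "violetred",
                                            `TRUE` = "grey40"),
                                 guide = "none") +
    ggplot2::labs(x = "parameter combination", y = "sep") +
    ggplot2::theme_minimal()
}
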