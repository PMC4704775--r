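#' Parameterization of the quasi-period density
#'
#' One `qpd_params` object fixes everything that shapes a segment's
#' quasi-period density: the recurrence neighbourhood (`eps_fraction`,
#' `theiler`, `ref_stride` — see [quasi_periods()]), the histogram binning
#' (`bin_width`, `t_max`, seconds) and the exponential smoothing kernel
#' (`grid_step`, `kernel_scale`, seconds).  These are exactly the knobs later
#' selected by maximizing the class-separation criterion [sep_criterion()].
#'
#' @param eps_fraction Recurrence ball radius as a fraction of attractor
#'   diameter.
#' @param theiler Theiler exclusion window in samples; `NULL` defers to
#'   `m * tau` of the embedding at use time.
#' @param ref_stride Reference-point stride for recurrence extraction.
#' @param bin_width Histogram bin width, seconds.
#' @param t_max Histogram upper edge, seconds; longer durations accumulate in
#'   the last bin.
#' @param grid_step Step of the uniform grid carrying the smoothed PDF,
#'   seconds.
#' @param kernel_scale Time constant of the causal exponential kernel
#'   `exp(-t / kernel_scale)`, seconds.  The default, `4 * bin_width`,
#'   reads the kernel's printed decay constant in histogram-bin units: on
#'   the sub-second quasi-period support a seconds-scaled 4 s kernel is
#'   nearly flat and erases exactly the mass-concentration differences the
#'   prototype distances must see.
#' @return A `qpd_params` list.
#' @export
qpd_params <- function(eps_fraction = 0.15, theiler = NULL, ref_stride = 1,
                       bin_width = 0.025, t_max = 1, grid_step = 0.01,
                       kernel_scale = NULL) {
  if (is.null(kernel_scale)) kernel_scale <- 4 * bin_width
  stopifnot(bin_width > 0, t_max > bin_width, grid_step > 0, kernel_scale > 0)
  structure(list(eps_fraction = eps_fraction, theiler = theiler,
                 ref_stride = ref_stride, bin_width = bin_width,
                 t_max = t_max, grid_step = grid_step,
                 kernel_scale = kernel_scale),
            class = "qpd_params")
}

params_key <- function(p) {
  paste(sprintf("%.10g", c(p$eps_fraction,
                           if (is.null(p$theiler)) -1 else p$theiler,
                           p$ref_stride, p$bin_width, p$t_max, p$grid_step,
                           p$kernel_scale)), collapse = "|")
}

#' Normalized quasi-period histogram
#'
#' Bins the pooled recurrence durations on `[0, t_max]`; durations beyond
#' `t_max` accumulate in the last bin; bin mass is normalized to sum to one.
#'
#' @param sample A [quasi_periods()] sample (nonempty).
#' @param bin_width Bin width, seconds.
#' @param t_max Upper edge, seconds.
#' @param params Optionally, the full [qpd_params()] to stamp on the result
#'   (defaults to one built from `bin_width`/`t_max`).
#' @return A `qpd_density` with `bin_edges`, `mass` and an empty `pdf_grid`
#'   (filled by [smooth_pdf()]).
#' @export
qpd_histogram <- function(sample, bin_width = 0.025, t_max = 1, params = NULL) {
  if (inherits(sample, "quasi_period_sample")) sample <- sample$durations
  sample <- as.numeric(sample)
  if (length(sample) == 0L) {
    stop("empty quasi-period sample: no density to build", call. = FALSE)
  }
  stopifnot(bin_width > 0, all(sample > 0))
  edges <- seq(0, t_max, by = bin_width)
  if (edges[length(edges)] < t_max) edges <- c(edges, t_max)
  idx <- findInterval(pmin(sample, t_max), edges, rightmost.closed = TRUE,
                      left.open = TRUE)
  idx[idx < 1L] <- 1L                     # durations in (0, first edge]
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  if (is.null(params)) params <- qpd_params(bin_width = bin_width, t_max = t_max)
  structure(list(bin_edges = edges, mass = counts / sum(counts),
                 pdf_grid = NULL, grid = NULL, params = params),
            class = "qpd_density")
}

#' @export
print.qpd_density <- function(x, ...) {
  cat(sprintf("<qpd_density> %d bins on [0, %g] s%s\n",
              length(x$mass), max(x$bin_edges),
              if (is.null(x$pdf_grid)) "" else
                sprintf(", PDF on %d-point grid", length(x$pdf_grid))))
  invisible(x)
}

#' Exponential-kernel smoothing of a quasi-period density
#'
#' Convolves the binned quasi-period density with the causal exponential
#' kernel `exp(-t / kernel_scale)` (time in seconds, scale 4 s by default):
#' each bin's mass launches a decaying exponential at the bin centre, and the
#' superposition — renormalized to unit integral on the grid — is the
#' smoothed PDF.  When most quasi-periods cluster in a narrow range the
#' convolution concentrates correspondingly, which is the property the
#' prototype distances exploit.
#'
#' @param density A [qpd_histogram()] result.
#' @param grid_step Grid step in seconds (default from the density's params).
#' @param kernel_scale Kernel time constant in seconds (default from params).
#' @return The density with `pdf_grid` (nonnegative, unit trapezoidal
#'   integral) and `grid` filled.
#' @export
smooth_pdf <- function(density, grid_step = NULL, kernel_scale = NULL) {
  stopifnot(inherits(density, "qpd_density"))
  if (abs(sum(density$mass) - 1) > 1e-9) {
    stop("density mass must sum to 1", call. = FALSE)
  }
  p <- density$params
  if (!is.null(grid_step)) p$grid_step <- grid_step
  if (!is.null(kernel_scale)) p$kernel_scale <- kernel_scale
  grid <- seq(0, max(density$bin_edges), by = p$grid_step)
  centers <- (density$bin_edges[-1L] + density$bin_edges[-length(density$bin_edges)]) / 2
  keep <- density$mass > 0
  pdf <- numeric(length(grid))
  for (b in which(keep)) {
    dt <- grid - centers[b]
    pdf <- pdf + density$mass[b] * ifelse(dt >= 0, exp(-dt / p$kernel_scale), 0)
  }
  z <- trapz_integral(grid, pdf)
  if (z <= 0) stop("degenerate smoothed density", call. = FALSE)
  density$pdf_grid <- pdf / z
  density$grid <- grid
  density$params <- p
  density
}

trapz_integral <- function(x, y) {
  n <- length(x)
  sum((y[-1L] + y[-n]) * diff(x)) / 2
}

#' Prototype distance between two smoothed quasi-period densities
#'
#' Default measure: the 1-Wasserstein (earth-mover) distance between the
#' two PDFs on their common grid — the integrated absolute difference of
#' their CDFs, in seconds.  It responds linearly to shifts of the
#' quasi-period mass and smoothly to concentration differences, where
#' log-ratio divergences are dominated by near-empty tails when densities
#' are sharply peaked.  The measure is pluggable: `"jeffreys"` gives the
#' symmetrized Kullback-Leibler divergence on floor-regularized PDFs and
#' `"sup_cdf"` the Kolmogorov-style sup distance between the CDFs.
#' All variants are symmetric, nonnegative and zero exactly when the
#' (floored) grids coincide.
#'
#' @param a,b [smooth_pdf()]-completed densities on identical grids.
#' @param method `"wasserstein"` (default), `"jeffreys"` or `"sup_cdf"`.
#' @param floor Regularization floor for the PDF values (Jeffreys only).
#' @return Nonnegative scalar distance.
#' @export
kd_distance <- function(a, b, method = c("wasserstein", "jeffreys",
                                         "sup_cdf"),
                        floor = 1e-12) {
  method <- match.arg(method)
  stopifnot(inherits(a, "qpd_density"), inherits(b, "qpd_density"))
  if (is.null(a$pdf_grid) || is.null(b$pdf_grid)) {
    stop("densities must be smoothed first (smooth_pdf)", call. = FALSE)
  }
  if (length(a$grid) != length(b$grid) ||
      max(abs(a$grid - b$grid)) > 1e-12) {
    stop("densities live on different grids", call. = FALSE)
  }
  p <- pmax(a$pdf_grid, floor)
  q <- pmax(b$pdf_grid, floor)
  if (method != "jeffreys") {
    step <- diff(a$grid)
    cp <- cumsum((p[-1L] + p[-length(p)]) / 2 * step)
    cq <- cumsum((q[-1L] + q[-length(q)]) / 2 * step)
    if (method == "sup_cdf") return(max(abs(cp - cq)))
    return(sum(abs(cp - cq)) * mean(step))
  }
  sum((p - q) * (log(p) - log(q))) * mean(diff(a$grid))
}

#' Class-separation criterion over a prototype distance matrix
#'
#' For each prototype signal `i`, the criterion contrasts its mean distance
#' to opposite-class prototypes with its mean distance to same-class
#' prototypes, normalized by the larger of the two population variances
#' (divisors `C^B` and `C^W`, where `C^B` counts opposite-class prototypes
#' and `C^W` is one less than the own-class count); the criterion is the sum
#' of the per-signal terms.  Large values mean the two prototype classes are
#' far apart and internally tight — the quantity maximized when selecting
#' the quasi-period density parameters.
#'
#' Note the printed form is not scale-invariant: scaling every distance by
#' `s` scales the criterion by `1/s` (numerators scale by `s`, variance
#' denominators by `s^2`).  It is implemented exactly as defined.
#'
#' @param kd_matrix Symmetric `L x L` matrix of pairwise prototype distances
#'   (diagonal ignored).
#' @param labels Length-`L` class labels (two classes).
#' @param var_floor Degeneracy floor: if for any signal both variances fall
#'   below it, a degenerate-variance error is raised.
#' @return A `sep_value`: list with `value` and `per_signal_terms`.
#' @export
sep_criterion <- function(kd_matrix, labels, var_floor = 1e-12) {
  kd_matrix <- as.matrix(kd_matrix)
  L <- nrow(kd_matrix)
  stopifnot(ncol(kd_matrix) == L, length(labels) == L)
  labels <- as.character(labels)
  if (length(unique(labels)) != 2L) {
    stop("labels must contain exactly two classes", call. = FALSE)
  }
  terms <- vapply(seq_len(L), function(i) {
    own <- setdiff(which(labels == labels[i]), i)
    opp <- which(labels != labels[i])
    if (length(own) < 1L || length(opp) < 1L) {
      stop("each prototype needs own-class and opposite-class companions",
           call. = FALSE)
    }
    kdB <- kd_matrix[i, opp]
    kdW <- kd_matrix[i, own]
    varB <- mean((kdB - mean(kdB))^2)
    varW <- mean((kdW - mean(kdW))^2)
    denom <- max(varB, varW)
    if (denom < var_floor) {
      stop("degenerate variance: prototype distances carry no spread",
           call. = FALSE)
    }
    (mean(kdB) - mean(kdW)) / denom
  }, 0)
  structure(list(value = sum(terms), per_signal_terms = terms),
            class = "sep_value")
}

#' @export
print.sep_value <- function(x, ...) {
  cat(sprintf("<sep_value> %.6g over %d prototype signals\n",
              x$value, length(x$per_signal_terms)))
  invisible(x)
}

#' Quasi-period density of a raw or preprocessed ECG segment
#'
#' Pipeline helper: de-trend (optional), delay-embed, extract phase-space
#' recurrence durations, bin them and smooth with the exponential kernel —
#' everything governed by one [qpd_params()].
#'
#' @param seg A [signal_segment()].
#' @param params A [qpd_params()].
#' @param embed An [embedding_params()].
#' @param config A [filter_config()] (used when `preprocess = TRUE`).
#' @param preprocess De-trend before embedding? Default `TRUE`.
#' @return A smoothed `qpd_density`, or `NULL` when the segment yields no
#'   recurrences at these parameters.
#' @export
qpd_density_of <- function(seg, params = qpd_params(),
                           embed = embedding_params(),
                           config = filter_config(), preprocess = TRUE) {
  stopifnot(inherits(seg, "vf_segment"))
  if (preprocess) seg <- detrend(seg, config)
  traj <- embed_delay(seg, embed)
  theiler <- if (is.null(params$theiler)) embed$m * embed$tau else params$theiler
  qp <- suppressWarnings(
    quasi_periods(traj, params$eps_fraction, theiler, params$ref_stride)
  )
  if (qp$empty) return(NULL)
  smooth_pdf(qpd_histogram(qp, params$bin_width, params$t_max, params = params))
}

#' Build a prototype set
#'
#' The prototype set holds `C` smoothed quasi-period densities per class,
#' all under one parameterization.  By default the per-class medoids —
#' the `C` signals minimizing summed within-class distance — are used, a
#' leakage-free automated stand-in for clinically chosen prototypes;
#' explicit `prototype_ids` override the automation.
#'
#' @param densities Named list of smoothed `qpd_density` objects (one per
#'   training-fold shock; `NULL` entries are dropped).
#' @param outcomes Numeric 0/1 outcomes aligned with `densities`.
#' @param C Prototypes per class (default 4, giving the canonical 8-signal
#'   set).
#' @param prototype_ids Optional character vector of entry names to use
#'   verbatim (must cover both classes, `C` per class).
#' @return A `prototype_set`: list with `entries`, `classes`, `ids`, `params`.
#' @export
prototype_set <- function(densities, outcomes, C = 4, prototype_ids = NULL) {
  keep <- !vapply(densities, is.null, TRUE)
  densities <- densities[keep]
  outcomes <- outcomes[keep]
  if (is.null(names(densities))) names(densities) <- as.character(seq_along(densities))
  stopifnot(length(densities) == length(outcomes))
  if (!is.null(prototype_ids)) {
    miss <- setdiff(prototype_ids, names(densities))
    if (length(miss)) stop("unknown prototype ids: ", paste(miss, collapse = ", "),
                           call. = FALSE)
    ids <- prototype_ids
  } else {
    ids <- unlist(lapply(c(1, 0), function(cls) {
      cand <- names(densities)[outcomes == cls]
      if (length(cand) < C) {
        stop(sprintf("class %d has %d candidates, need %d prototypes",
                     cls, length(cand), C), call. = FALSE)
      }
      dd <- kd_matrix_of(densities[cand])
      cand[order(rowSums(dd))[seq_len(C)]]
    }))
  }
  classes <- outcomes[match(ids, names(densities))]
  if (length(unique(classes)) != 2L) {
    stop("prototype set must represent both classes", call. = FALSE)
  }
  ord <- order(-classes, match(ids, names(densities)))  # class then id
  ids <- ids[ord]; classes <- classes[ord]
  structure(list(entries = densities[ids], classes = classes, ids = ids,
                 params = densities[[1L]]$params),
            class = "prototype_set")
}

#' @export
print.prototype_set <- function(x, ...) {
  cat(sprintf("<prototype_set> %d prototypes (%d successful, %d unsuccessful)\n",
              length(x$entries), sum(x$classes == 1), sum(x$classes == 0)))
  invisible(x)
}

# pairwise KD matrix of a list of densities
kd_matrix_of <- function(densities) {
  L <- length(densities)
  out <- matrix(0, L, L, dimnames = list(names(densities), names(densities)))
  if (L < 2L) return(out)
  for (i in seq_len(L - 1L)) {
    for (j in (i + 1L):L) {
      out[i, j] <- out[j, i] <- kd_distance(densities[[i]], densities[[j]])
    }
  }
  out
}

#' Prototype-distance features of one segment density
#'
#' Distances from the segment's smoothed quasi-period density to every
#' prototype density, in deterministic order (successful class first, then
#' training order), named `kd_s1..kd_sC, kd_u1..kd_uC`.
#'
#' @param seg_density A smoothed `qpd_density` (same parameterization as the
#'   prototype set), or `NULL` for a recurrence-free segment (features fall
#'   back to the maximum observed prototype spacing).
#' @param ps A [prototype_set()].
#' @return Named numeric vector of `2 * C` features.
#' @export
prototype_features <- function(seg_density, ps) {
  stopifnot(inherits(ps, "prototype_set"))
  nm <- paste0("kd_", ifelse(ps$classes == 1, "s", "u"),
               stats::ave(seq_along(ps$classes), ps$classes, FUN = seq_along))
  if (is.null(seg_density)) {
    fallback <- max(kd_matrix_of(ps$entries))
    return(stats::setNames(rep(fallback, length(ps$entries)), nm))
  }
  if (!identical(params_key(seg_density$params), params_key(ps$params))) {
    stop("density parameterization does not match the prototype set",
         call. = FALSE)
  }
  stats::setNames(
    vapply(ps$entries, function(e) kd_distance(seg_density, e), 0), nm)
}

#' Select quasi-period density parameters by separation maximization
#'
#' Evaluates [sep_criterion()] on the prototype signals for every candidate
#' parameterization and returns the maximizer (ties break to the first grid
#' entry; grid order is deterministic).  Grid points whose distances are
#' degenerate are skipped and logged in the trace.
#'
#' @param train_records List of [shock_record()]s (the training fold).
#' @param param_grid List of [qpd_params()] candidates.
#' @param prototype_ids Optional explicit prototype record ids (shock ids);
#'   default: per-class medoids under the first grid entry.
#' @param C Prototypes per class.
#' @param embed,config Embedding and filter settings shared by all grid
#'   points.
#' @return List with `best_params`, `best_sep`, `prototype_ids`, and `trace`
#'   (tibble: one row per grid point with the parameter values, `sep`, and a
#'   `skipped` flag).
#' @export
select_parameters <- function(train_records, param_grid, prototype_ids = NULL,
                              C = 4, embed = embedding_params(),
                              config = filter_config()) {
  stopifnot(length(param_grid) >= 1L)
  outcomes <- vapply(train_records, outcome_code, 0L)
  ids <- vapply(train_records, function(r) r$shock_id, "")
  if (any(!nzchar(ids))) ids <- as.character(seq_along(train_records))
  segs <- lapply(train_records, function(r) detrend(r$ecg, config))
  dens_at <- function(p) {
    d <- lapply(segs, qpd_density_of, params = p, embed = embed,
                preprocess = FALSE)
    names(d) <- ids
    d
  }
  d1 <- dens_at(param_grid[[1L]])
  ps_ids <- if (is.null(prototype_ids)) {
    prototype_set(d1, outcomes, C = C)$ids
  } else prototype_ids
  proto_idx <- match(ps_ids, ids)
  rows <- vector("list", length(param_grid))
  best <- NULL
  for (g in seq_along(param_grid)) {
    p <- param_grid[[g]]
    dg <- if (g == 1L) d1 else dens_at(param_grid[[g]])
    pd <- dg[proto_idx]
    sep_g <- tryCatch({
      if (any(vapply(pd, is.null, TRUE))) stop("prototype without recurrences")
      sep_criterion(kd_matrix_of(pd), outcomes[proto_idx])
    }, error = function(e) e)
    skipped <- inherits(sep_g, "error")
    rows[[g]] <- tibble::tibble(
      grid_index = g, eps_fraction = p$eps_fraction, bin_width = p$bin_width,
      t_max = p$t_max, kernel_scale = p$kernel_scale,
      sep = if (skipped) NA_real_ else sep_g$value, skipped = skipped)
    if (!skipped && (is.null(best) || sep_g$value > best$sep)) {
      best <- list(params = p, sep = sep_g$value, index = g)
    }
  }
  if (is.null(best)) {
    stop("all grid points degenerate: no parameterization selectable",
         call. = FALSE)
  }
  list(best_params = best$params, best_sep = best$sep,
       prototype_ids = ps_ids, trace = dplyr::bind_rows(rows))
}
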