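# Assembly of the multi-domain feature matrix: quasi-period densities
# (carried as a list-column until fold-level prototypes exist),
# dual-tree wavelet subband statistics, time-domain descriptors, AMSA and
# optional PetCO2 summaries.

petco2_features <- function(seg) {
  if (is.null(seg)) {
    return(c(petco2_mean = NA_real_, petco2_slope = NA_real_,
             petco2_last = NA_real_))
  }
  tt <- (seq_along(seg$samples) - 1L) / seg$sampling_rate
  fit <- stats::lm.fit(cbind(1, tt), seg$samples)
  c(petco2_mean = mean(seg$samples),
    petco2_slope = unname(stats::coef(fit)[2L]),
    petco2_last = seg$samples[length(seg$samples)])
}

#' Assemble the multi-domain feature matrix for a set of shock records
#'
#' For every record the ECG is de-trended once, then characterized in three
#' domains: the phase-space quasi-period density (kept as a list-column —
#' prototype distances are computed per training fold by
#' [mdi_fold_transform()] to avoid leakage), dual-tree complex wavelet
#' subband statistics plus time-domain descriptors, and the AMSA value.
#' PetCO2 summaries (mean level, linear trend, final value) join for
#' records that carry capnography; `has_petco2` flags them.
#'
#' @param records List of [shock_record()]s.
#' @param qp [qpd_params()] governing the quasi-period density.
#' @param embed [embedding_params()].
#' @param config [filter_config()] for preprocessing.
#' @param wavelet_levels Dual-tree decomposition depth (default 5).
#' @param amsa_band AMSA band in Hz.
#' @return Tibble: `patient_id`, `shock_id`, `outcome`, `qpd_density`
#'   (list-column), `amsa`, wavelet/time features, PetCO2 columns,
#'   `has_petco2`.
#' @export
mdi_features <- function(records, qp = qpd_params(),
                         embed = embedding_params(),
                         config = filter_config(),
                         wavelet_levels = 5, amsa_band = c(4, 48)) {
  rows <- purrr::map(records, function(rec) {
    clean <- detrend(rec$ecg, config)
    dens <- qpd_density_of(clean, qp, embed, preprocess = FALSE)
    wf <- subband_features(dtcwt_decompose(clean, wavelet_levels))
    tf <- time_features(clean)
    pf <- petco2_features(rec$petco2)
    tibble::tibble(
      patient_id = rec$patient_id, shock_id = rec$shock_id,
      outcome = outcome_code(rec),
      qpd_density = list(dens),
      amsa = compute_amsa(rec$ecg, amsa_band),
      !!!as.list(c(wf, tf, pf)),
      has_petco2 = !is.null(rec$petco2))
  })
  dplyr::bind_rows(rows)
}

#' Restrict a feature matrix to the ECG-only feature set
#'
#' Drops the PetCO2 columns (which are undefined for shocks without
#' capnography), leaving the full-cohort ECG feature set.
#'
#' @param features A [mdi_features()] tibble.
#' @return The tibble without `petco2_*`/`has_petco2` columns.
#' @export
ecg_only <- function(features) {
  features[setdiff(names(features),
                   c("petco2_mean", "petco2_slope", "petco2_last",
                     "has_petco2"))]
}

#' Restrict a feature matrix to shocks with usable PetCO2
#'
#' @param features A [mdi_features()] tibble.
#' @return Rows with capnography, PetCO2 columns retained.
#' @export
petco2_subset <- function(features) {
  out <- features[features$has_petco2, , drop = FALSE]
  out[setdiff(names(out), "has_petco2")]
}
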