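# One-stop pipeline runners and the YAML configuration surface.

#' Default pipeline configuration
#'
#' Nested list mirroring the pipeline stages; serializable to YAML with
#' [save_config()] and consumed by [run_mdi()] and the command-line
#' wrapper.
#'
#' @return Named list with sections `preprocessing`, `phase_space`,
#'   `qpd_pd`, `wavelet`, `amsa`, `model`, `cv`.
#' @export
default_config <- function() {
  list(
    preprocessing = list(sg_order = 11, sg_frame = 25, base_order = 3,
                         base_frame = 499, base_passes_max = 10,
                         base_tol = 1e-3),
    phase_space = list(m = 4, tau = 8, eps_fraction = 0.15, theiler = NULL,
                       ref_stride = 4),
    qpd_pd = list(bin_width = 0.025, t_max = 1, grid_step = 0.01,
                  kernel_scale = 4, prototypes_per_class = 4,
                  prototype_ids = NULL),
    wavelet = list(levels = 5),
    amsa = list(band = c(4, 48)),
    model = list(algorithm = "ADDITIVE_LOGISTIC", max_features = 20),
    cv = list(k = 10, inner_k = 10, group_by_patient = TRUE,
              var_threshold = 0.99, seed = 1)
  )
}

#' Read / write a pipeline configuration
#' @param path YAML file path.
#' @param config Configuration list as from [default_config()]; missing
#'   sections are filled from the defaults on read.
#' @return `load_config()` returns the configuration list; `save_config()`
#'   returns `path` invisibly.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- default_config()
  for (sec in names(user)) {
    base[[sec]] <- utils::modifyList(base[[sec]] %||% list(), user[[sec]])
  }
  base
}

#' @rdname load_config
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

config_objects <- function(config) {
  pp <- config$preprocessing
  ps <- config$phase_space
  qp <- config$qpd_pd
  list(
    filter = filter_config(pp$sg_order, pp$sg_frame, pp$base_order,
                           pp$base_frame, pp$base_passes_max, pp$base_tol),
    embed = embedding_params(ps$m, ps$tau),
    qp = qpd_params(eps_fraction = ps$eps_fraction, theiler = ps$theiler,
                    ref_stride = ps$ref_stride, bin_width = qp$bin_width,
                    t_max = qp$t_max, grid_step = qp$grid_step,
                    kernel_scale = qp$kernel_scale))
}

#' Run the full prediction pipeline on a cohort of shock records
#'
#' Assembles the multi-domain feature matrix, evaluates the classifier by
#' twice-nested cross-validation (prototype selection, standardization and
#' projection all inside outer-training folds), and scores the AMSA
#' baseline on the same shocks.
#'
#' @param records List of [shock_record()]s.
#' @param config Pipeline configuration (see [default_config()]).
#' @param seed Master seed (overrides `config$cv$seed` when given).
#' @param features Optional precomputed [mdi_features()] tibble (skips
#'   extraction).
#' @return List with `features`, `mdi` (a `cv_report`), `amsa`
#'   (see [amsa_threshold_metrics()]).
#' @export
run_mdi <- function(records, config = default_config(), seed = NULL,
                    features = NULL) {
  obj <- config_objects(config)
  if (is.null(features)) {
    features <- mdi_features(records, obj$qp, obj$embed, obj$filter,
                             config$wavelet$levels, config$amsa$band)
  }
  seed <- seed %||% config$cv$seed
  spec <- model_spec(config$model$algorithm,
                     max_features = config$model$max_features)
  mdi <- nested_cv(ecg_only(features), spec, k = config$cv$k, seed = seed,
                   inner_k = config$cv$inner_k,
                   transform = mdi_fold_transform(
                     C = config$qpd_pd$prototypes_per_class,
                     var_threshold = config$cv$var_threshold),
                   group_by_patient = config$cv$group_by_patient)
  amsa <- amsa_threshold_metrics(features$amsa, features$outcome)
  list(features = features, mdi = mdi, amsa = amsa)
}

# percentile bootstrap CI of an oof AUC (resampling shocks)
boot_auc_ci <- function(probs, outcomes, B = 200, seed = 1, level = 0.95) {
  n <- length(probs)
  with_local_seed(seed, {
    reps <- vapply(seq_len(B), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      if (length(unique(outcomes[i])) < 2L) return(NA_real_)
      roc_curve(probs[i], outcomes[i])$auc
    }, 0)
    stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                    na.rm = TRUE, names = FALSE)
  })
}

#' End-to-end recovery experiment on a synthetic cohort
#'
#' Generates a cohort, runs the full pipeline, scores AMSA on the same
#' shocks, optionally repeats the cross-validation with permuted labels
#' (the null reference), and runs the paired PetCO2 sub-analysis
#' (ECG-only vs PetCO2-augmented on the capnography subset, same folds).
#' Bootstrap confidence intervals over out-of-fold predictions accompany
#' the separable-vs-null AUC comparison.
#'
#' @param spec A [cohort_spec()] (default: [separable_cohort_spec()]).
#' @param config Pipeline configuration.
#' @param seed Master seed.
#' @param include_null Run the label-permuted reference? (default `TRUE`)
#' @param include_petco2 Run the PetCO2 sub-analysis? (default `TRUE`)
#' @param n_boot Bootstrap replicates for the AUC intervals.
#' @return An `mdi_recovery` list: `mdi_auc`, `amsa_auc`, `null_auc`,
#'   intervals, PetCO2 sub-analysis AUCs, the underlying reports and the
#'   generating truth table.
#' @export
parameter_recovery_suite <- function(spec = separable_cohort_spec(),
                                     config = default_config(), seed = 1,
                                     include_null = TRUE,
                                     include_petco2 = TRUE, n_boot = 200) {
  cohort <- generate_cohort(spec)
  res <- run_mdi(cohort$records, config, seed = seed)
  out <- list(
    mdi_auc = res$mdi$auc, mdi_accuracy = res$mdi$accuracy,
    amsa_auc = res$amsa$auc,
    mdi_auc_ci = boot_auc_ci(res$mdi$oof$prob, res$mdi$oof$outcome,
                             B = n_boot, seed = seed + 1L),
    at_sensitivity = res$mdi$at_sensitivity,
    mdi = res$mdi, amsa = res$amsa, features = res$features,
    truth = cohort$truth)
  feats <- res$features
  if (include_null) {
    null_feats <- feats
    null_feats$outcome <- with_local_seed(seed + 2L, sample(feats$outcome))
    null_run <- run_mdi(NULL, config, seed = seed, features = null_feats)
    out$null_auc <- null_run$mdi$auc
    out$null_auc_ci <- boot_auc_ci(null_run$mdi$oof$prob,
                                   null_run$mdi$oof$outcome,
                                   B = n_boot, seed = seed + 3L)
  }
  if (include_petco2 && any(feats$has_petco2)) {
    sub <- petco2_subset(feats)
    if (length(unique(sub$outcome)) == 2L && nrow(sub) >= 10L) {
      k_sub <- max(2L, min(5L, min(table(sub$outcome))))
      folds <- make_folds(sub$outcome, k_sub, seed + 4L)
      spec_m <- model_spec(config$model$algorithm,
                           max_features = config$model$max_features)
      tf <- mdi_fold_transform(C = min(config$qpd_pd$prototypes_per_class,
                                       floor(min(table(sub$outcome)) / 2)),
                               var_threshold = config$cv$var_threshold)
      ecg_run <- nested_cv(ecg_only(sub), spec_m, k = k_sub, seed = seed,
                           inner_k = max(3L, min(5L, config$cv$inner_k)),
                           transform = tf, folds = folds)
      aug_run <- nested_cv(sub, spec_m, k = k_sub, seed = seed,
                           inner_k = max(3L, min(5L, config$cv$inner_k)),
                           transform = tf, folds = folds)
      out$petco2_ecg_only_auc <- ecg_run$auc
      out$petco2_augmented_auc <- aug_run$auc
      out$petco2_n <- nrow(sub)
    }
  }
  structure(out, class = "mdi_recovery")
}

#' @export
print.mdi_recovery <- function(x, ...) {
  cat(sprintf("<mdi_recovery> MDI AUC %.3f (acc %.3f), AMSA AUC %.3f",
              x$mdi_auc, x$mdi_accuracy, x$amsa_auc))
  if (!is.null(x$null_auc)) cat(sprintf(", null AUC %.3f", x$null_auc))
  if (!is.null(x$petco2_augmented_auc)) {
    cat(sprintf("\n  PetCO2 subset (n=%d): ECG-only %.3f, augmented %.3f",
                x$petco2_n, x$petco2_ecg_only_auc, x$petco2_augmented_auc))
  }
  cat("\n")
  invisible(x)
}
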