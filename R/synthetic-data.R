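# Synthetic VF cohort generator.  Segments are frequency-modulated
# oscillations whose instantaneous frequency is driven by a chaotic
# (logistic-map) signal, dressed with pink noise, baseline drift and
# occasional step artifacts; class-conditional parameters encode the
# empirical picture that shocks converting to a perfusing rhythm are
# preceded by coarser (higher-amplitude), faster and more organized VF.
# The generator is a pure function of its spec (master seed included).

#' Per-class VF waveform parameters
#'
#' @param f0_mean,f0_sd Dominant frequency of the VF oscillation, Hz.
#' @param amp_mean,amp_sd Waveform amplitude, mV.
#' @param chaos_gain Frequency-modulation depth of the chaotic drive, Hz:
#'   larger values give broader, less organized spectra.
#' @param organization Index in (0, 1]: higher = shallower amplitude
#'   modulation and stronger harmonic regularity.
#' @param petco2_level_mean,petco2_level_sd End-tidal CO2 level, mmHg.
#' @param petco2_slope Linear PetCO2 trend over the window, mmHg/s.
#' @return A list of class parameters.
#' @export
vf_class_params <- function(f0_mean, f0_sd = 0.5, amp_mean, amp_sd = 0.15,
                            chaos_gain = 1, organization = 0.5,
                            petco2_level_mean = 20, petco2_level_sd = 6,
                            petco2_slope = 0) {
  list(f0_mean = f0_mean, f0_sd = f0_sd, amp_mean = amp_mean,
       amp_sd = amp_sd, chaos_gain = chaos_gain, organization = organization,
       petco2_level_mean = petco2_level_mean,
       petco2_level_sd = petco2_level_sd, petco2_slope = petco2_slope)
}

#' Cohort specification for the synthetic generator
#'
#' Defaults emulate the scale and class balance of a retrospective
#' out-of-hospital cardiac-arrest series: 153 patients contributing 358
#' shocks, 39.1% successful, ECG at 250 Hz, and capnography available for
#' 48/358 of shocks.  Successful-class VF defaults to higher dominant
#' frequency (5.2 vs 4.2 Hz), markedly narrower chaotic frequency
#' modulation and higher organization, slightly higher but strongly
#' overlapping amplitude (0.60 vs 0.50 mV, SD 0.2), and higher, rising
#' PetCO2.  The class gradient is deliberately organization-dominant:
#' waveform organization rather than raw amplitude carries most of the
#' outcome signal, which is the premise the multi-domain model rests on.
#'
#' @param n_patients Number of patients.
#' @param n_shocks Total shocks in the cohort (default 358).
#' @param shocks_per_patient Integer range; per-patient counts are drawn
#'   uniformly then trimmed to `n_shocks`.
#' @param success_rate P(successful shock) (default 140/358).
#' @param sampling_rate ECG rate, Hz.
#' @param duration Segment duration, s.
#' @param successful,unsuccessful [vf_class_params()] per class.
#' @param noise_sd Pink-noise amplitude, mV.
#' @param drift_amp Baseline drift amplitude, mV.
#' @param step_prob,step_size Probability and size (mV) of a step artifact.
#' @param petco2_rate PetCO2 sampling rate, Hz.
#' @param petco2_fraction Fraction of shocks with usable PetCO2.
#' @param petco2_noise_sd PetCO2 noise, mmHg.
#' @param seed Master seed: the cohort is a pure function of the spec.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 153, n_shocks = 358,
                        shocks_per_patient = c(1, 5),
                        success_rate = 140 / 358,
                        sampling_rate = 250, duration = 9,
                        successful = vf_class_params(
                          f0_mean = 5.2, amp_mean = 0.60, amp_sd = 0.2,
                          chaos_gain = 0.6, organization = 0.75,
                          petco2_level_mean = 32,
                          petco2_level_sd = 7, petco2_slope = 0.25),
                        unsuccessful = vf_class_params(
                          f0_mean = 4.2, amp_mean = 0.50, amp_sd = 0.2,
                          chaos_gain = 1.8, organization = 0.35,
                          petco2_level_mean = 14,
                          petco2_level_sd = 6, petco2_slope = -0.05),
                        noise_sd = 0.04, drift_amp = 0.3,
                        step_prob = 0.1, step_size = 0.8,
                        petco2_rate = 25, petco2_fraction = 48 / 358,
                        petco2_noise_sd = 1.5, seed = 181803) {
  stopifnot(sampling_rate > 0, duration > 0,
            success_rate >= 0, success_rate <= 1,
            petco2_fraction >= 0, petco2_fraction <= 1,
            step_prob >= 0, step_prob <= 1)
  structure(list(n_patients = as.integer(n_patients),
                 n_shocks = as.integer(n_shocks),
                 shocks_per_patient = as.integer(shocks_per_patient),
                 success_rate = success_rate, sampling_rate = sampling_rate,
                 duration = duration, successful = successful,
                 unsuccessful = unsuccessful, noise_sd = noise_sd,
                 drift_amp = drift_amp, step_prob = step_prob,
                 step_size = step_size, petco2_rate = petco2_rate,
                 petco2_fraction = petco2_fraction,
                 petco2_noise_sd = petco2_noise_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' A strongly separable cohort specification
#'
#' Convenience spec for recovery experiments: widens the class gap in
#' dominant frequency and amplitude while keeping everything else at the
#' defaults.
#'
#' @param delta_f0 Class gap in dominant frequency, Hz (default 2).
#' @param delta_amp Class gap in amplitude, mV (default 0.3).
#' @param ... Passed to [cohort_spec()].
#' @return A `cohort_spec`.
#' @export
separable_cohort_spec <- function(delta_f0 = 2, delta_amp = 0.3, ...) {
  cohort_spec(
    successful = vf_class_params(
      f0_mean = 4.2 + delta_f0, amp_mean = 0.50 + delta_amp, amp_sd = 0.2,
      chaos_gain = 0.6, organization = 0.75,
      petco2_level_mean = 32, petco2_level_sd = 7, petco2_slope = 0.25),
    ...)
}

# pink (1/f amplitude) noise via spectral shaping of seeded white noise
pink_noise <- function(n, sd) {
  if (sd <= 0) return(numeric(n))
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)                   # fold to two-sided frequency
  W <- W / sqrt(f)
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  x * sd / stats::sd(x)
}

# chaotic frequency drive: logistic map at 25 Hz, spline-interpolated
logistic_drive <- function(n, rate, drive_rate = 25, r = 3.99) {
  m <- ceiling(n / rate * drive_rate) + 3L
  x <- numeric(m)
  x[1L] <- stats::runif(1, 0.2, 0.8)
  for (i in seq_len(m - 1L)) x[i + 1L] <- r * x[i] * (1 - x[i])
  tt <- (seq_len(m) - 1L) / drive_rate
  t_out <- (seq_len(n) - 1L) / rate
  stats::spline(tt, (x - 0.5) * 2, xout = t_out)$y
}

#' Generate one synthetic VF segment
#'
#' A 9-second (by default) VF-like waveform: a sinusoid whose instantaneous
#' frequency wanders chaotically around the dominant frequency, with a
#' class-dependent harmonic, amplitude modulation set by the organization
#' index, pink noise, slow baseline drift and (optionally) a step artifact.
#' Deterministic for a given seed.
#'
#' @param f0 Dominant frequency, Hz.
#' @param amp Amplitude, mV.
#' @param chaos_gain FM depth of the chaotic drive, Hz.
#' @param organization Organization index in (0, 1].
#' @param noise_sd,drift_amp,step_prob,step_size Artifact levels (mV).
#' @param rate Sampling rate, Hz.
#' @param duration Duration, s.
#' @param seed Integer seed.
#' @return An ECG [signal_segment()].
#' @export
generate_vf <- function(f0 = 4.5, amp = 0.6, chaos_gain = 1,
                        organization = 0.5, noise_sd = 0.04,
                        drift_amp = 0.3, step_prob = 0.1, step_size = 0.8,
                        rate = 250, duration = 9, seed = 1) {
  n <- round(duration * rate)
  with_local_seed(seed, {
    drive <- logistic_drive(n, rate)
    f_inst <- pmax(f0 + chaos_gain * drive, 0.5)
    phase <- 2 * pi * cumsum(f_inst) / rate + stats::runif(1, 0, 2 * pi)
    am_depth <- 1 - organization
    slow <- sin(2 * pi * stats::runif(1, 0.1, 0.3) * (seq_len(n) - 1L) / rate +
                  stats::runif(1, 0, 2 * pi))
    envelope <- amp * (1 - am_depth / 2 + (am_depth / 2) * slow)
    x <- envelope * sin(phase) +
      0.2 * organization * amp * sin(2 * phase + stats::runif(1, 0, 2 * pi))
    x <- x + pink_noise(n, noise_sd)
    if (drift_amp > 0) {
      fd <- stats::runif(1, 0.05, 0.2)
      x <- x + drift_amp * sin(2 * pi * fd * (seq_len(n) - 1L) / rate +
                                 stats::runif(1, 0, 2 * pi)) +
        stats::runif(1, -0.3, 0.3) * (seq_len(n) - 1L) / n
    }
    if (stats::runif(1) < step_prob) {
      at <- floor(n * stats::runif(1, 0.3, 0.8))
      x[(at + 1L):n] <- x[(at + 1L):n] + step_size * sample(c(-1, 1), 1L)
    }
    signal_segment(x, rate, "ECG")
  })
}

generate_petco2 <- function(level, slope, noise_sd, rate, duration, seed) {
  n <- round(duration * rate)
  with_local_seed(seed, {
    tt <- (seq_len(n) - 1L) / rate
    breath <- 0.08 * level * sin(2 * pi * 0.25 * tt + stats::runif(1, 0, 2 * pi))
    x <- pmax(level + slope * tt + breath + stats::rnorm(n, 0, noise_sd), 0.1)
    signal_segment(x, rate, "PETCO2")
  })
}

#' Generate a labelled synthetic cohort
#'
#' Draws outcomes, per-shock waveform parameters and artifact realizations
#' per the spec, returning ready-cut pre-shock records together with the
#' ground-truth parameter table used to generate them (for recovery tests).
#'
#' @param spec A [cohort_spec()].
#' @return List with `records` (list of [shock_record()]s) and `truth`
#'   (tibble of drawn per-shock parameters).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_local_seed(spec$seed, {
    counts <- sample(seq(spec$shocks_per_patient[1L],
                         spec$shocks_per_patient[2L]),
                     spec$n_patients, replace = TRUE)
    patient <- rep(seq_len(spec$n_patients), counts)
    while (length(patient) < spec$n_shocks) {
      patient <- c(patient, sample(spec$n_patients, 1L))
    }
    patient <- sort(patient[seq_len(spec$n_shocks)])
    n <- spec$n_shocks
    outcome <- stats::rbinom(n, 1L, spec$success_rate)
    seeds <- sample.int(.Machine$integer.max - 1L, 3L * n)
    has_pet <- stats::runif(n) < spec$petco2_fraction
    truth <- tibble::tibble(
      patient_id = sprintf("P%03d", patient),
      shock_id = sprintf("S%04d", seq_len(n)),
      outcome = outcome,
      f0 = NA_real_, amp = NA_real_, chaos_gain = NA_real_,
      organization = NA_real_, petco2_level = NA_real_,
      petco2_slope = NA_real_, has_petco2 = has_pet)
    records <- vector("list", n)
    for (i in seq_len(n)) {
      cp <- if (outcome[i] == 1L) spec$successful else spec$unsuccessful
      par_seed <- seeds[i]
      drawn <- with_local_seed(par_seed, list(
        f0 = max(stats::rnorm(1, cp$f0_mean, cp$f0_sd), 1.5),
        amp = max(stats::rnorm(1, cp$amp_mean, cp$amp_sd), 0.05),
        level = max(stats::rnorm(1, cp$petco2_level_mean,
                                 cp$petco2_level_sd), 2)))
      ecg <- generate_vf(drawn$f0, drawn$amp, cp$chaos_gain, cp$organization,
                         spec$noise_sd, spec$drift_amp, spec$step_prob,
                         spec$step_size, spec$sampling_rate, spec$duration,
                         seed = seeds[n + i])
      ecg$segment_id <- sprintf("S%04d_ecg", i)
      pet <- NULL
      if (has_pet[i]) {
        pet <- generate_petco2(drawn$level, cp$petco2_slope,
                               spec$petco2_noise_sd, spec$petco2_rate,
                               spec$duration, seed = seeds[2L * n + i])
      }
      records[[i]] <- shock_record(
        ecg, outcome[i], petco2 = pet,
        patient_id = truth$patient_id[i], shock_id = truth$shock_id[i],
        shock_time = spec$duration)
      truth$f0[i] <- drawn$f0; truth$amp[i] <- drawn$amp
      truth$chaos_gain[i] <- cp$chaos_gain
      truth$organization[i] <- cp$organization
      truth$petco2_level[i] <- if (has_pet[i]) drawn$level else NA_real_
      truth$petco2_slope[i] <- if (has_pet[i]) cp$petco2_slope else NA_real_
    }
    list(records = records, truth = truth)
  })
}

#' Write a synthetic cohort to disk
#'
#' One recording per shock (CSV dialect or WFDB) plus a cohort-level
#' annotation CSV (`shocks.csv`: `patient_id`, `shock_id`, `shock_time_s`,
#' `outcome`) and the ground-truth table (`truth.csv`).
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @param format `"CSV"` or `"WFDB"`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("CSV", "WFDB")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in cohort$records) {
    chans <- list(ECG = rec$ecg)
    if (!is.null(rec$petco2) && format == "CSV") chans$PETCO2 <- rec$petco2
    r <- structure(list(channels = chans, annotations = NULL),
                   class = "vf_recording")
    ext <- if (format == "CSV") ".csv" else ".hea"
    write_recording(r, file.path(dir, paste0(rec$shock_id, ext)), format)
    if (!is.null(rec$petco2) && format == "WFDB") {
      write_recording(rec$petco2,
                      file.path(dir, paste0(rec$shock_id, "_petco2.hea")),
                      "WFDB")
    }
  }
  ann <- tibble::tibble(
    patient_id = vapply(cohort$records, function(r) r$patient_id, ""),
    shock_id = vapply(cohort$records, function(r) r$shock_id, ""),
    shock_time_s = vapply(cohort$records, function(r) r$shock_time, 0),
    outcome = vapply(cohort$records, outcome_code, 0L))
  utils::write.csv(ann, file.path(dir, "shocks.csv"), row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
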