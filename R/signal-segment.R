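#' Construct a uniformly sampled signal segment
#'
#' A `signal_segment` is the basic carrier for a slice of one physiologic
#' channel: ECG in millivolts or end-tidal CO2 (PetCO2) in mmHg, sampled
#' uniformly at `sampling_rate` Hz.  The sampling rate always travels with the
#' data; downstream operations never assume a rate.
#'
#' @param samples Numeric vector of samples (mV for ECG, mmHg for PetCO2).
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param channel Channel label, one of `"ECG"` or `"PETCO2"`.
#' @param start_time Time of the first sample on the recording clock, seconds.
#' @param segment_id Opaque identifier string.
#'
#' @return An object of class `vf_segment` with fields `samples`,
#'   `sampling_rate`, `channel`, `start_time`, `segment_id`.
#' @export
#' @examples
#' seg <- signal_segment(sin(2 * pi * 5 * (0:499) / 250), 250)
#' seg
signal_segment <- function(samples, sampling_rate, channel = c("ECG", "PETCO2"),
                           start_time = 0, segment_id = "") {
  channel <- match.arg(channel)
  samples <- as.numeric(samples)
  if (length(samples) < 2L) {
    stop("signal segment must contain at least 2 samples", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    bad <- which(!is.finite(samples))[1L]
    stop(sprintf("non-finite sample at index %d", bad), call. = FALSE)
  }
  if (!is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be a positive number", call. = FALSE)
  }
  structure(
    list(
      samples = samples,
      sampling_rate = as.numeric(sampling_rate),
      channel = channel,
      start_time = as.numeric(start_time),
      segment_id = as.character(segment_id)
    ),
    class = "vf_segment"
  )
}

#' @export
print.vf_segment <- function(x, ...) {
  cat(sprintf(
    "<vf_segment> %s: %d samples @ %g Hz (%.2f s), start %.2f s%s\n",
    x$channel, length(x$samples), x$sampling_rate,
    length(x$samples) / x$sampling_rate, x$start_time,
    if (nzchar(x$segment_id)) paste0(", id=", x$segment_id) else ""
  ))
  invisible(x)
}

#' @export
length.vf_segment <- function(x) length(x$samples)

#' Duration of a segment in seconds
#' @param seg A [signal_segment()].
#' @return Duration in seconds.
#' @export
segment_duration <- function(seg) {
  stopifnot(inherits(seg, "vf_segment"))
  length(seg$samples) / seg$sampling_rate
}

# internal: clone a segment with new samples, preserving metadata
seg_with_samples <- function(seg, samples, id_suffix = NULL) {
  out <- seg
  out$samples <- as.numeric(samples)
  if (!is.null(id_suffix) && nzchar(seg$segment_id)) {
    out$segment_id <- paste0(seg$segment_id, id_suffix)
  }
  out
}

#' Construct a shock record
#'
#' Binds the pre-countershock ECG segment (and, when available, a PetCO2
#' segment) to the adjudicated binary countershock outcome.  A successful
#' shock is one followed by return of spontaneous circulation (a sustained
#' period of narrow QRS complexes under 150 beats per minute); adjudication
#' itself is upstream of this package — the outcome arrives as 0/1.
#'
#' @param ecg Pre-shock ECG [signal_segment()].
#' @param outcome `"SUCCESSFUL"`/`"UNSUCCESSFUL"`, or 1/0.
#' @param petco2 Optional PetCO2 [signal_segment()].
#' @param patient_id,shock_id Opaque identifier strings.
#' @param shock_time Countershock time on the recording clock, seconds.
#'
#' @return An object of class `shock_record`.
#' @export
shock_record <- function(ecg, outcome, petco2 = NULL,
                         patient_id = "", shock_id = "", shock_time = NA_real_) {
  stopifnot(inherits(ecg, "vf_segment"))
  if (!is.null(petco2)) stopifnot(inherits(petco2, "vf_segment"))
  if (is.numeric(outcome)) {
    stopifnot(outcome %in% c(0, 1))
    outcome <- if (outcome == 1) "SUCCESSFUL" else "UNSUCCESSFUL"
  }
  outcome <- match.arg(outcome, c("SUCCESSFUL", "UNSUCCESSFUL"))
  if (is.finite(shock_time)) {
    seg_end <- ecg$start_time + length(ecg$samples) / ecg$sampling_rate
    if (seg_end > shock_time + 1e-9) {
      stop("ECG segment extends past shock_time", call. = FALSE)
    }
  }
  structure(
    list(
      ecg = ecg, petco2 = petco2, outcome = outcome,
      patient_id = as.character(patient_id),
      shock_id = as.character(shock_id),
      shock_time = as.numeric(shock_time)
    ),
    class = "shock_record"
  )
}

#' @export
print.shock_record <- function(x, ...) {
  cat(sprintf(
    "<shock_record> patient=%s shock=%s outcome=%s petco2=%s\n",
    x$patient_id, x$shock_id, x$outcome,
    if (is.null(x$petco2)) "absent" else "present"
  ))
  invisible(x)
}

#' Numeric outcome of a shock record
#' @param record A [shock_record()].
#' @return 1 for a successful shock, 0 otherwise.
#' @export
outcome_code <- function(record) {
  stopifnot(inherits(record, "shock_record"))
  as.integer(record$outcome == "SUCCESSFUL")
}
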