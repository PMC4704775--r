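#' Read a multichannel recording from disk
#'
#' Two on-disk formats are supported:
#'
#' * `"CSV"` — the package's delimited dialect: line 1 holds comma-separated
#'   `key=value` pairs (at minimum `ecg_rate_hz`; optionally `petco2_rate_hz`
#'   and `start_time_s`), line 2 the column names (`t`, `ecg`, optionally
#'   `petco2`), then the data rows with `.` decimals.  Channels sampled at
#'   different rates occupy the same table; the shorter column is blank-padded.
#' * `"WFDB"` — a minimal WFDB reader for format-16 records (`.hea` plus
#'   16-bit little-endian `.dat`), all signals at the record sampling rate.
#'
#' If a sibling file `<stem>_shocks.csv` exists (columns `patient_id`,
#' `shock_id`, `shock_time_s`, `outcome` with outcome coded 0/1) it is read as
#' the shock annotation table.
#'
#' @param path Path to the `.csv` file or to the WFDB `.hea` header.
#' @param format `"CSV"` or `"WFDB"`.
#' @return A `vf_recording`: list with `channels` (named list of
#'   [signal_segment()]s) and `annotations` (tibble or `NULL`).
#' @seealso [write_recording()], [extract_pre_shock()]
#' @export
read_recording <- function(path, format = c("CSV", "WFDB")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  rec <- if (format == "CSV") read_recording_csv(path) else read_recording_wfdb(path)
  ann_path <- paste0(sub("\\.(csv|hea)$", "", path), "_shocks.csv")
  if (file.exists(ann_path)) {
    ann <- utils::read.csv(ann_path, stringsAsFactors = FALSE)
    need <- c("patient_id", "shock_id", "shock_time_s", "outcome")
    if (!all(need %in% names(ann))) {
      stop("annotation file lacks required columns", call. = FALSE)
    }
    rec$annotations <- tibble::as_tibble(ann)
  }
  rec
}

#' @export
print.vf_recording <- function(x, ...) {
  cat(sprintf("<vf_recording> channels: %s; %s shock annotations\n",
              paste(names(x$channels), collapse = ", "),
              if (is.null(x$annotations)) "no" else nrow(x$annotations)))
  invisible(x)
}

read_recording_csv <- function(path) {
  lines <- readLines(path, n = 2L, warn = FALSE)
  if (length(lines) < 2L || !grepl("=", lines[1L], fixed = TRUE)) {
    stop("malformed CSV recording header in ", path, call. = FALSE)
  }
  kv <- strsplit(strsplit(lines[1L], ",", fixed = TRUE)[[1L]], "=", fixed = TRUE)
  if (any(lengths(kv) != 2L)) stop("malformed key=value header", call. = FALSE)
  meta <- stats::setNames(
    as.numeric(vapply(kv, `[`, "", 2L)),
    trimws(vapply(kv, `[`, "", 1L))
  )
  if (!"ecg_rate_hz" %in% names(meta) || !is.finite(meta[["ecg_rate_hz"]])) {
    stop("CSV header must declare ecg_rate_hz", call. = FALSE)
  }
  dat <- utils::read.csv(path, skip = 1L, stringsAsFactors = FALSE)
  if (!"ecg" %in% names(dat)) stop("CSV recording lacks an 'ecg' column", call. = FALSE)
  start_time <- if ("start_time_s" %in% names(meta)) meta[["start_time_s"]] else 0
  check_finite_column <- function(x, name) {
    x <- x[!is.na(x)]
    if (!all(is.finite(x))) {
      stop(sprintf("non-finite sample at index %d of channel %s",
                   which(!is.finite(x))[1L], name), call. = FALSE)
    }
    x
  }
  channels <- list(
    ECG = signal_segment(check_finite_column(dat$ecg, "ecg"),
                         meta[["ecg_rate_hz"]], "ECG", start_time = start_time)
  )
  if ("petco2" %in% names(dat)) {
    if (!"petco2_rate_hz" %in% names(meta)) {
      stop("CSV header must declare petco2_rate_hz for a petco2 column",
           call. = FALSE)
    }
    channels$PETCO2 <- signal_segment(check_finite_column(dat$petco2, "petco2"),
                                      meta[["petco2_rate_hz"]], "PETCO2",
                                      start_time = start_time)
  }
  structure(list(channels = channels, annotations = NULL),
            class = "vf_recording")
}

# Minimal WFDB format-16 support: one .dat per record, signals interleaved,
# two's-complement 16-bit little-endian, amplitude = (adc - baseline) / gain.
read_recording_wfdb <- function(path) {
  hea <- readLines(path, warn = FALSE)
  hea <- hea[!grepl("^\\s*#", hea) & nzchar(trimws(hea))]
  if (length(hea) < 2L) stop("malformed WFDB header: ", path, call. = FALSE)
  rec_line <- strsplit(trimws(hea[1L]), "\\s+")[[1L]]
  if (length(rec_line) < 4L) stop("malformed WFDB record line", call. = FALSE)
  nsig <- as.integer(rec_line[2L])
  fs <- as.numeric(rec_line[3L])
  nsamp <- as.integer(rec_line[4L])
  if (!is.finite(nsig) || nsig < 1L) stop("WFDB record has no signals", call. = FALSE)
  sig <- lapply(hea[2L:(1L + nsig)], function(line) {
    tok <- strsplit(trimws(line), "\\s+")[[1L]]
    if (length(tok) < 3L || tok[2L] != "16") {
      stop("only WFDB format 16 is supported", call. = FALSE)
    }
    gain_tok <- tok[3L]
    units <- "mV"
    baseline <- 0
    if (grepl("/", gain_tok, fixed = TRUE)) {
      units <- sub("^[^/]*/", "", gain_tok)
      gain_tok <- sub("/.*$", "", gain_tok)
    }
    if (grepl("\\(", gain_tok)) {
      baseline <- as.numeric(sub("^.*\\(([^)]*)\\).*$", "\\1", gain_tok))
      gain_tok <- sub("\\(.*$", "", gain_tok)
    }
    list(file = tok[1L], gain = as.numeric(gain_tok), baseline = baseline,
         units = units, name = if (length(tok) >= 9L) tok[length(tok)] else "ECG")
  })
  dat_path <- file.path(dirname(path), sig[[1L]]$file)
  raw <- readBin(dat_path, "integer", n = nsig * nsamp, size = 2L,
                 signed = TRUE, endian = "little")
  channels <- list()
  for (i in seq_len(nsig)) {
    adc <- raw[seq(i, length(raw), by = nsig)]
    phys <- (adc - sig[[i]]$baseline) / sig[[i]]$gain
    if (!all(is.finite(phys))) {
      stop(sprintf("non-finite sample at index %d of signal %d",
                   which(!is.finite(phys))[1L], i), call. = FALSE)
    }
    ch <- if (identical(sig[[i]]$units, "mmHg")) "PETCO2" else "ECG"
    channels[[ch]] <- signal_segment(phys, fs, ch)
  }
  structure(list(channels = channels, annotations = NULL),
            class = "vf_recording")
}

#' Write a recording to disk
#'
#' Inverse of [read_recording()].  For WFDB the ECG is quantized with a gain
#' of 1000 ADC units per mV (PetCO2: 100 per mmHg); the CSV dialect stores
#' samples at 17 significant digits.  Annotations, when supplied, go to
#' `<stem>_shocks.csv`.
#'
#' @param recording A `vf_recording` (or a bare ECG [signal_segment()]).
#' @param path Output path: `.csv` file or WFDB `.hea` path.
#' @param format `"CSV"` or `"WFDB"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path, format = c("CSV", "WFDB")) {
  format <- match.arg(format)
  if (inherits(recording, "vf_segment")) {
    recording <- structure(
      list(channels = stats::setNames(list(recording), recording$channel),
           annotations = NULL),
      class = "vf_recording")
  }
  stopifnot(inherits(recording, "vf_recording"))
  if (format == "CSV") write_recording_csv(recording, path)
  else write_recording_wfdb(recording, path)
  if (!is.null(recording$annotations)) {
    ann_path <- paste0(sub("\\.(csv|hea)$", "", path), "_shocks.csv")
    utils::write.csv(recording$annotations, ann_path, row.names = FALSE)
  }
  invisible(path)
}

write_recording_csv <- function(recording, path) {
  ecg <- recording$channels$ECG
  pet <- recording$channels$PETCO2
  meta <- sprintf("ecg_rate_hz=%.10g,start_time_s=%.10g",
                  ecg$sampling_rate, ecg$start_time)
  if (!is.null(pet)) {
    meta <- paste0(meta, sprintf(",petco2_rate_hz=%.10g", pet$sampling_rate))
  }
  n <- max(length(ecg$samples), if (is.null(pet)) 0L else length(pet$samples))
  pad <- function(x) c(sprintf("%.17g", x), rep("", n - length(x)))
  cols <- list(t = pad(ecg$start_time + (seq_along(ecg$samples) - 1) / ecg$sampling_rate),
               ecg = pad(ecg$samples))
  if (!is.null(pet)) cols$petco2 <- pad(pet$samples)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  writeLines(paste(names(cols), collapse = ","), con)
  writeLines(do.call(paste, c(unname(cols), sep = ",")), con)
}

write_recording_wfdb <- function(recording, path) {
  chans <- recording$channels
  rates <- vapply(chans, function(s) s$sampling_rate, 0)
  if (length(unique(rates)) != 1L) {
    stop("WFDB writer requires all channels at one sampling rate", call. = FALSE)
  }
  lens <- vapply(chans, function(s) length(s$samples), 0L)
  if (length(unique(lens)) != 1L) {
    stop("WFDB writer requires equal-length channels", call. = FALSE)
  }
  rec_name <- sub("\\.hea$", "", basename(path))
  dat_name <- paste0(rec_name, ".dat")
  gains <- vapply(chans, function(s) if (s$channel == "PETCO2") 100 else 1000, 0)
  units <- vapply(chans, function(s) if (s$channel == "PETCO2") "mmHg" else "mV", "")
  adc <- mapply(function(s, g) {
    q <- as.integer(round(s$samples * g))
    if (any(abs(q) > 32767L)) stop("sample exceeds 16-bit range", call. = FALSE)
    q
  }, chans, gains, SIMPLIFY = FALSE)
  inter <- as.integer(t(do.call(cbind, adc)))
  writeBin(inter, file.path(dirname(path), dat_name), size = 2L, endian = "little")
  hea <- c(
    sprintf("%s %d %.10g %d", rec_name, length(chans), rates[[1L]], lens[[1L]]),
    vapply(seq_along(chans), function(i) {
      sprintf("%s 16 %g(0)/%s 16 0 %d 0 0 %s",
              dat_name, gains[[i]], units[[i]], adc[[i]][1L], names(chans)[i])
    }, "")
  )
  writeLines(hea, path)
}

#' Cut the fixed-duration pre-countershock window
#'
#' Returns the window `[shock_time - duration, shock_time)` of the ECG
#' channel: exactly `round(duration * rate)` samples ending at the last sample
#' strictly before the shock.  The window is half-open so no post-shock sample
#' can leak into the predictor.
#'
#' @param recording A `vf_recording` or a [signal_segment()].
#' @param shock_time Shock time on the recording clock, seconds.
#' @param duration Window length in seconds (default 9).
#' @return A [signal_segment()] of the pre-shock ECG.
#' @export
extract_pre_shock <- function(recording, shock_time, duration = 9) {
  seg <- if (inherits(recording, "vf_recording")) recording$channels$ECG else recording
  stopifnot(inherits(seg, "vf_segment"))
  rate <- seg$sampling_rate
  n_take <- as.integer(round(duration * rate))
  # last 1-based index with sample time strictly before shock_time
  k <- (shock_time - seg$start_time) * rate
  i_end <- as.integer(ceiling(k - 1e-9))
  i_start <- i_end - n_take + 1L
  if (i_start < 1L || i_end > length(seg$samples)) {
    stop(sprintf("insufficient history: need samples %d..%d of %d",
                 i_start, i_end, length(seg$samples)), call. = FALSE)
  }
  signal_segment(seg$samples[i_start:i_end], rate, seg$channel,
                 start_time = seg$start_time + (i_start - 1L) / rate,
                 segment_id = seg$segment_id)
}

#' Persist / load a feature matrix
#'
#' Feature tables are written as plain CSV with values rendered at 17
#' significant digits, so `read_features(write_features(x))` returns values
#' bit-identical to the originals.  The table must contain exactly one
#' `outcome` column and unique column names.
#'
#' @param matrix A tibble/data frame of per-shock features with an `outcome`
#'   column (0/1).
#' @param path Output CSV path.
#' @return `write_features()` returns `path` invisibly; `read_features()`
#'   returns a tibble.
#' @export
write_features <- function(matrix, path) {
  check_feature_matrix_schema(matrix)
  is_num <- vapply(matrix, is.numeric, TRUE)
  cols <- lapply(seq_along(matrix), function(i) {
    if (is_num[i]) sprintf("%.17g", matrix[[i]]) else as.character(matrix[[i]])
  })
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(matrix), collapse = ","), con)
  if (nrow(matrix) > 0L) writeLines(do.call(paste, c(cols, sep = ",")), con)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  out <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                           check.names = FALSE))
  # numeric columns come back as double regardless of printed form
  out <- dplyr::mutate(out, dplyr::across(dplyr::where(is.integer),
                                          as.numeric))
  check_feature_matrix_schema(out)
  out
}

check_feature_matrix_schema <- function(matrix) {
  if (anyDuplicated(names(matrix))) {
    stop("duplicate feature column names: ",
         paste(unique(names(matrix)[duplicated(names(matrix))]), collapse = ", "),
         call. = FALSE)
  }
  if (sum(names(matrix) == "outcome") != 1L) {
    stop("feature matrix must contain exactly one 'outcome' column", call. = FALSE)
  }
  invisible(matrix)
}
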