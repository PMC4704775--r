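test_that("CSV recordings round-trip losslessly, with annotations", {
  withr::with_seed(4, {
    ecg <- signal_segment(rnorm(500), 250, "ECG")
    pet <- signal_segment(runif(50, 10, 40), 25, "PETCO2")
  })
  rec <- structure(
    list(channels = list(ECG = ecg, PETCO2 = pet),
         annotations = tibble::tibble(patient_id = "P1", shock_id = "S1",
                                      shock_time_s = 1.5, outcome = 1L)),
    class = "vf_recording")
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, path, "CSV")
  back <- read_recording(path, "CSV")
  expect_identical(back$channels$ECG$samples, ecg$samples)
  expect_identical(back$channels$PETCO2$samples, pet$samples)
  expect_equal(back$channels$ECG$sampling_rate, 250)
  expect_equal(back$channels$PETCO2$sampling_rate, 25)
  expect_equal(back$annotations$shock_time_s, 1.5)
  expect_equal(back$annotations$outcome, 1L)
})

test_that("WFDB records written by the generator are recovered within ADC precision", {
  seg <- generate_vf(seed = 10)
  path <- file.path(withr::local_tempdir(), "rec01.hea")
  write_recording(seg, path, "WFDB")
  back <- read_recording(path, "WFDB")
  # gain 1000 ADC units per mV: half-LSB quantization
  expect_lt(max(abs(back$channels$ECG$samples - seg$samples)), 5e-4 + 1e-12)
  expect_equal(back$channels$ECG$sampling_rate, 250)
})

test_that("malformed recordings raise format errors", {
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(0), empty)
  expect_error(read_recording(empty, "CSV"), "header|malformed")
  noheader <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,ecg", "0,0.1"), noheader)
  expect_error(read_recording(noheader, "CSV"), "malformed")
  expect_error(read_recording(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("pre-shock extraction takes exactly the half-open window before the shock", {
  withr::with_seed(5, x <- rnorm(60 * 250))
  seg <- signal_segment(x, 250, "ECG")
  cut <- extract_pre_shock(seg, shock_time = 30, duration = 9)
  expect_length(cut$samples, 2250)
  # 0-based indices [5250, 7500): last sample strictly before the shock
  expect_identical(cut$samples, x[5251:7500])
  expect_equal(cut$start_time, 21)
  expect_error(extract_pre_shock(seg, shock_time = 5, duration = 9),
               "insufficient history")
})

test_that("pre-shock length is round(duration * rate) across rates", {
  for (rate in c(125, 250, 500)) {
    seg <- signal_segment(rnorm(15 * rate), rate, "ECG")
    cut <- extract_pre_shock(seg, shock_time = 14, duration = 9)
    expect_length(cut$samples, round(9 * rate))
  }
})

test_that("feature tables round-trip bit-identically and enforce schema", {
  withr::with_seed(6, {
    tab <- tibble::tibble(a = rnorm(3), b = rexp(3), c = runif(3),
                          outcome = c(0, 1, 0))
  })
  path <- withr::local_tempfile(fileext = ".csv")
  write_features(tab, path)
  back <- read_features(path)
  expect_identical(back$a, tab$a)
  expect_identical(back$b, tab$b)
  expect_identical(back$outcome, tab$outcome)
  expect_error(write_features(tibble::tibble(a = 1), tempfile()), "outcome")
  dup <- tibble::tibble(a = 1, outcome = 0)
  names(dup) <- c("a", "a")
  expect_error(write_features(dup, tempfile()), "duplicate|outcome")
})

test_that("a generated cohort written to disk round-trips through read_recording", {
  co <- generate_cohort(cohort_spec(n_patients = 3, n_shocks = 5,
                                    petco2_fraction = 1, seed = 2))
  dir <- withr::local_tempdir()
  write_cohort(co, dir, "CSV")
  ann <- utils::read.csv(file.path(dir, "shocks.csv"))
  expect_equal(nrow(ann), 5)
  back <- read_recording(file.path(dir, paste0(co$records[[1]]$shock_id, ".csv")))
  expect_identical(back$channels$ECG$samples, co$records[[1]]$ecg$samples)
  expect_identical(back$channels$PETCO2$samples,
                   co$records[[1]]$petco2$samples)
})

test_that("segment and record invariants are enforced", {
  expect_error(signal_segment(c(1, NA, 3), 250), "non-finite")
  expect_error(signal_segment(1, 250), "at least 2")
  expect_error(signal_segment(c(1, 2), -1), "positive")
  seg <- sine_segment(duration = 1)
  expect_error(shock_record(seg, 1, shock_time = 0.5), "past shock_time")
  rec <- shock_record(seg, "SUCCESSFUL", shock_time = 1)
  expect_identical(outcome_code(rec), 1L)
})
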