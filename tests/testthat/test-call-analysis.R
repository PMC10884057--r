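test_that("call segments validate their inputs", {
  expect_error(call_segment(numeric(100), 16000), "0.05 s")
  expect_error(call_segment(c(rep(0, 1000), NA), 16000), "finite")
  seg <- call_segment(sin(2 * pi * 200 * (1:1600) / 16000), 16000,
                      airflow = "egressive")
  expect_identical(seg$airflow, "egressive")
})

test_that("autocorrelation f0 tracks the synthesis fundamental", {
  w100 <- synthesize_vowel(synthesis_spec(c(358.75, 896.25), f0 = 100,
                                          duration = 0.5))
  expect_lt(abs(estimate_f0(call_segment(w100$samples, 16000)) - 100), 2)

  w300 <- synthesize_vowel(synthesis_spec(c(358.75, 896.25), f0 = 300,
                                          duration = 0.5))
  expect_lt(abs(estimate_f0(call_segment(w300$samples, 16000)) - 300), 6)
})

test_that("aperiodic input yields no f0", {
  set.seed(1)
  noise <- call_segment(stats::rnorm(8000), 16000)
  expect_true(is.na(estimate_f0(noise)))
})

test_that("a pure tone yields a partial single-peak estimate with a warning", {
  tone <- call_segment(sin(2 * pi * 500 * (0:7999) / 16000), 16000)
  expect_warning(est <- estimate_formants(tone, n_formants = 2), "1 of 2")
  expect_true("partial" %in% est$flags)
  fs <- formant_frequencies(est)
  expect_length(fs, 1L)
  expect_lt(abs(fs[1] - 500), 10)
})

test_that("formants of a synthesized chimp-range vowel are recovered", {
  seg <- make_vowel_segment(358.75, 896.25, f0 = 100)
  est <- estimate_formants(seg)
  expect_identical(est$provenance, "audio")
  fs <- formant_frequencies(est)
  expect_true(all(abs(fs[1:2] - c(358.75, 896.25)) /
                    c(358.75, 896.25) < 0.05))
})

test_that("an F1 lying on the fundamental is reported and flagged", {
  seg <- make_vowel_segment(300, 900, f0 = 300)
  est <- suppressWarnings(estimate_formants(seg))
  expect_true("f0_coincident" %in% est$flags)
  expect_lt(abs(est$f1 - 300), 45)  # within 15%: only harmonics 300 Hz apart
})

test_that("unvoiced input falls back to the cepstral envelope", {
  set.seed(2)
  # formant-shaped noise: no periodicity, but clear spectral peaks
  noise <- stats::rnorm(16000)
  shaped <- tractsim:::resonator_filter(noise, 500, 150, 16000)
  seg <- call_segment(shaped / max(abs(shaped)), 16000)
  est <- suppressWarnings(estimate_formants(seg, n_formants = 1))
  expect_true("no_f0" %in% est$flags)
  expect_lt(abs(est$f1 - 500), 150)
})

test_that("median round-trip error stays within the harmonic-sampling limits", {
  set.seed(77)
  one_err <- function(f0) {
    f1 <- runif(1, 250, 500)
    f2 <- runif(1, 700, 1200)
    est <- quiet_f1f2(make_vowel_segment(f1, f2, f0 = f0, duration = 0.4))
    abs(est - c(f1, f2)) / c(f1, f2)
  }
  err100 <- replicate(25, one_err(100))
  err300 <- replicate(25, one_err(300))
  expect_lt(median(err100[1, ], na.rm = TRUE), 0.05)
  expect_lt(median(err100[2, ], na.rm = TRUE), 0.05)
  expect_lt(median(err300[1, ], na.rm = TRUE), 0.10)
  expect_lt(median(err300[2, ], na.rm = TRUE), 0.10)
})

test_that("formant estimation is deterministic for fixed audio", {
  seg <- make_vowel_segment(380, 950, f0 = 220)
  expect_identical(formant_frequencies(estimate_formants(seg)),
                   formant_frequencies(estimate_formants(seg)))
})

test_that("the spectral envelope export has matched grids and an f0", {
  seg <- make_vowel_segment(358.75, 896.25, f0 = 100)
  env <- spectral_envelope(seg)
  expect_length(env$level_db, length(env$frequencies))
  expect_lt(abs(env$f0_estimate - 100), 2)
  expect_equal(max(env$level_db), 0)
})

test_that("spectrogram CSV export is frame-by-bin with a time column", {
  seg <- make_vowel_segment(358.75, 896.25, duration = 0.2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrogram_csv(seg, path)
  mat <- read.csv(path, check.names = FALSE)
  expect_identical(names(mat)[1], "time_s")
  expect_gt(nrow(mat), 10)
  expect_true(all(is.finite(as.matrix(mat))))
})
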