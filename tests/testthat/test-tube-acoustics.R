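test_that("uniform-tube resonance closed form gives the quarter-wave series", {
  expect_equal(uniform_tube_resonances(18, 35000, 3),
               c(486.1111, 1458.3333, 2430.5556), tolerance = 1e-6)
  expect_equal(uniform_tube_resonances(22, 35000, 2),
               c(397.7273, 1193.1818), tolerance = 1e-6)
  # linear in the speed of sound
  expect_equal(uniform_tube_resonances(18, 70000, 1),
               2 * uniform_tube_resonances(18, 35000, 1))
})

test_that("chain-matrix formants match the analytic oracle for uniform tubes", {
  for (L in c(5, 9, 14, 18, 22.5, 30)) {
    for (cc in c(34300, 35000)) {
      tf <- transfer_function(tube_sequence(L, 1),
                              acoustic_constants(speed_of_sound = cc),
                              f_min = 50, f_max = 5000, f_step = 1)
      n <- min(3L, sum(uniform_tube_resonances(L, cc, 5) < 4900))
      got <- formant_frequencies(find_formants(tf, n))
      expect_equal(got, uniform_tube_resonances(L, cc, n), tolerance = 1 / 400,
                   label = sprintf("formants of %g cm tube at c = %g", L, cc))
      expect_true(all(abs(got - uniform_tube_resonances(L, cc, n)) <= 1))
    }
  }
})

test_that("subdividing segments leaves the transfer function unchanged", {
  const <- acoustic_constants()
  shapes <- list(list(l = 18, a = 1),
                 list(l = c(2, 18, 3, 0.2), a = c(25, 1, 1, 0.3)))
  for (sh in shapes) {
    whole <- transfer_function(tube_sequence(sh$l, sh$a), const)
    for (k in c(2, 5)) {
      split_l <- rep(sh$l / k, each = k)
      split_a <- rep(sh$a, each = k)
      split_tf <- transfer_function(tube_sequence(split_l, split_a), const)
      expect_lt(max(abs(whole$magnitude_db - split_tf$magnitude_db)), 1e-6)
      f_whole <- formant_frequencies(find_formants(whole, 2))
      f_split <- formant_frequencies(find_formants(split_tf, 2))
      expect_true(all(abs(f_whole - f_split) <= 0.5))
    }
  }
})

test_that("scaling all areas preserves resonance frequencies", {
  lens <- c(2, 18, 3, 0.2)
  areas <- c(25, 1, 1, 0.3)
  for (damping in c(0, 0.005)) {
    const <- acoustic_constants(damping_fraction = damping)
    base <- formant_frequencies(
      find_formants(transfer_function(tube_sequence(lens, areas), const), 2))
    scaled <- formant_frequencies(
      find_formants(transfer_function(tube_sequence(lens, 3 * areas), const), 2))
    expect_true(all(abs(base - scaled) <= 0.5))
  }
})

test_that("elongating a uniform tube lowers every resonance", {
  const <- acoustic_constants()
  prev <- NULL
  for (L in seq(10, 26, by = 4)) {
    f <- formant_frequencies(
      find_formants(transfer_function(tube_sequence(L, 1), const), 3))
    expect_true(!is.unsorted(f, strictly = TRUE))
    expect_true(all(f > 0))
    if (!is.null(prev)) expect_true(all(f < prev))
    prev <- f
  }
})

test_that("transfer function is normalized and finite", {
  tf <- transfer_function(tube_sequence(18, 1), acoustic_constants())
  expect_identical(tf$magnitude_db[1], 0)
  expect_true(all(is.finite(tf$magnitude_db)))
  expect_true(!is.unsorted(tf$frequencies, strictly = TRUE))
  expect_length(tf$magnitude_db, length(tf$frequencies))
})

test_that("piston radiation load lowers resonances relative to the open end", {
  const <- acoustic_constants()
  open_f <- formant_frequencies(
    find_formants(transfer_function(tube_sequence(18, 1), const), 2))
  rad_f <- formant_frequencies(
    find_formants(transfer_function(tube_sequence(18, 1), const,
                                    lip_termination = "piston"), 2))
  expect_true(all(rad_f < open_f))  # end correction acts as extra length
})

test_that("degenerate tube and peak-picking inputs are rejected", {
  expect_error(tube_segment(0, 1), "length")
  expect_error(tube_segment(1, -2), "area")
  expect_error(tube_sequence(numeric(), numeric()), "at least one")
  expect_error(tube_sequence(c(1, 2), 1), "equal length")
  expect_error(transfer_function(tube_sequence(18, 1), f_min = 0.5), "f_min")
  expect_error(acoustic_constants(damping_fraction = 0.5), "damping")
  # monotone, peakless curve
  tf <- fake_tf(seq(50, 500, 1), seq(0, -40, length.out = 451))
  expect_error(find_formants(tf, 1), "0 peaks")
  # fewer qualifying peaks than requested reports the count found
  tf2 <- transfer_function(tube_sequence(18, 1), acoustic_constants(),
                           f_max = 1000)
  expect_error(find_formants(tf2, 5), "found")
})

test_that("formant estimates enforce ordering and provenance", {
  fe <- formant_estimate(c(300, 900, 2500), provenance = "audio")
  expect_identical(formant_frequencies(fe), c(300, 900, 2500))
  expect_identical(fe$provenance, "audio")
  expect_error(formant_estimate(c(900, 300)), "increasing")
  expect_error(formant_estimate(-1), "positive")
})

test_that("transfer functions export as two-column CSV", {
  tf <- transfer_function(tube_sequence(18, 1), acoustic_constants(),
                          f_max = 600)
  path <- withr::local_tempfile(fileext = ".csv")
  write_transfer_function(tf, path)
  got <- read.csv(path)
  expect_identical(names(got), c("frequency_hz", "magnitude_db"))
  expect_equal(got$frequency_hz, tf$frequencies)
})

test_that("acoustic constants load from YAML with defaults filled in", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines("speed_of_sound: 34300", path)
  const <- read_acoustic_constants(path)
  expect_identical(const$speed_of_sound, 34300)
  expect_identical(const$damping_fraction, acoustic_constants()$damping_fraction)
})
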