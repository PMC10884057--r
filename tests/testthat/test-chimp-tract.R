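test_that("the five-segment tract is assembled glottis to lips", {
  p <- tract_params(sac_length = 2, sac_area = 30, protrusion_length = 3.8,
                    lip_opening_area = 0.2)
  tb <- build_tract(p)
  expect_equal(nrow(tb), 5L)
  expect_equal(tb$length, c(0.125, 2, 18, 3.8, 0.2))
  expect_equal(tb$area, c(0.125, 30, 1, 1, 0.2))
  expect_equal(total_length(tb), 24.125)

  no_con <- build_tract(tract_params(sac_length = 1, sac_area = 5,
                                     protrusion_length = 1,
                                     lip_opening_area = 0.5,
                                     constriction_enabled = FALSE))
  expect_equal(nrow(no_con), 4L)
  expect_equal(total_length(no_con), 18 + 1 + 1 + 0.2)
})

test_that("all-uniform parameters reduce to a single-tube resonator", {
  p <- tract_params(sac_length = 1, sac_area = 1, protrusion_length = 1,
                    lip_opening_area = 1, constriction_enabled = FALSE)
  fe <- find_formants(transfer_function(build_tract(p)), 2)
  oracle <- uniform_tube_resonances(20.2, 35000, 2)
  expect_true(all(abs(formant_frequencies(fe) - oracle) <= 1))
})

test_that("invalid tract parameters are rejected by field name", {
  expect_error(tract_params(sac_length = 1, sac_area = 1,
                            protrusion_length = 0, lip_opening_area = 1),
               "protrusion_length")
  expect_error(tract_params(sac_length = -1, sac_area = 1,
                            protrusion_length = 1, lip_opening_area = 1),
               "sac_length")
})

test_that("grid enumeration covers the Cartesian product in documented order", {
  expect_length(enumerate_grid(), 19L * 3L * 30L * 5L)

  g <- param_grid(protrusion_lengths = c(1, 2), sac_lengths = 1,
                  sac_areas = c(5, 10), lip_opening_areas = c(0.2, 0.4))
  configs <- enumerate_grid(g, default_fixed_params())
  expect_length(configs, 8L)
  # lip-opening area varies fastest, protrusion length slowest
  expect_equal(vapply(configs, `[[`, numeric(1), "lip_opening_area"),
               rep(c(0.2, 0.4), 4))
  expect_equal(vapply(configs, `[[`, numeric(1), "protrusion_length"),
               rep(c(1, 2), each = 4))

  single <- param_grid(protrusion_lengths = 1, sac_lengths = 1,
                       sac_areas = 1, lip_opening_areas = 1)
  expect_length(enumerate_grid(single, default_fixed_params()), 1L)

  expect_error(param_grid(sac_areas = numeric()), "sac_areas")
  expect_error(param_grid(sac_areas = c(1, -3)), "sac_areas")
})

test_that("a reduced sweep emits ordered rows with sensible formants", {
  g <- param_grid(protrusion_lengths = c(0.2, 2), sac_lengths = 1,
                  sac_areas = c(1, 15, 30), lip_opening_areas = c(0.2, 1))
  sw <- run_sweep(g)
  expect_s3_class(sw, "sweep_result")
  expect_equal(nrow(sw), 12L)
  expect_true(all(sw$status == "ok"))
  expect_true(all(sw$f1_hz < sw$f2_hz))
  expect_equal(sw$total_length_cm,
               0.125 + sw$sac_length_cm + 18 + sw$protrusion_length_cm + 0.2)
  # F2 falls as the air sac grows, other parameters held fixed
  for (pl in unique(sw$protrusion_length_cm)) {
    for (la in unique(sw$lip_area_cm2)) {
      slice <- sw[sw$protrusion_length_cm == pl & sw$lip_area_cm2 == la, ]
      expect_true(all(diff(slice$f2_hz[order(slice$sac_area_cm2)]) <= 1e-9))
    }
  }
})

test_that("sweep failures are flagged rows, not dropped rows", {
  g <- param_grid(protrusion_lengths = 1, sac_lengths = 1,
                  sac_areas = c(1, 10), lip_opening_areas = 1)
  sw <- run_sweep(g, min_prominence_db = 90)  # nothing can qualify
  expect_equal(nrow(sw), 2L)
  expect_true(all(sw$status != "ok"))
  expect_true(all(is.na(sw$f1_hz)))
})

test_that("sweep CSV round-trips and repeated runs are byte-identical", {
  g <- param_grid(protrusion_lengths = c(0.2, 3.8), sac_lengths = 1.5,
                  sac_areas = c(1, 30), lip_opening_areas = 0.2)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_sweep_csv(run_sweep(g), p1)
  write_sweep_csv(run_sweep(g), p2)
  expect_identical(readBin(p1, raw(), file.size(p1)),
                   readBin(p2, raw(), file.size(p2)))
  back <- read_sweep_csv(p1)
  expect_s3_class(back, "sweep_result")
  expect_equal(back$f1_hz, run_sweep(g)$f1_hz)
})

test_that("parameter grids load from YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("protrusion_lengths: [1, 2]", "sac_areas: [3]"), path)
  g <- read_param_grid(path)
  expect_equal(g$protrusion_lengths, c(1, 2))
  expect_equal(g$sac_areas, 3)
  expect_equal(g$sac_lengths, seq(1, 2, 0.5))
})
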