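test_that("air kerma matches the hand formula for a single bin", {
  mu <- read_mu_en_table()
  sp <- new_spectrum(25, 1.5e7, 0.025)
  k <- air_kerma(sp, 1, mu)
  mu25 <- mu$mu_en_over_rho_m2_per_kg[mu$energy_keV == 25]
  expected <- 25e3 * 1.602176634e-19 * 1.5e7 * 1e6 * mu25 * 1e3
  expect_equal(k$total_mGy, expected, tolerance = 1e-12)
  expect_equal(nrow(k$per_bin), 1L)
})

test_that("kerma is linear in exposure time and fluence", {
  sp <- mono_spectrum()
  expect_equal(air_kerma(sp, 4)$total_mGy, 4 * air_kerma(sp, 1)$total_mGy,
               tolerance = 1e-12)
  expect_equal(air_kerma(mono_spectrum(3e7), 1)$total_mGy,
               2 * air_kerma(mono_spectrum(1.5e7), 1)$total_mGy,
               tolerance = 1e-12)
})

test_that("energy lookups refuse to extrapolate", {
  mu <- read_mu_en_table()
  expect_error(air_kerma(new_spectrum(45, 1e6, 1), 1, mu),
               class = "phasemammo_range_error")
  expect_error(air_kerma(new_spectrum(5, 1e6, 1), 1, mu),
               class = "phasemammo_range_error")
})

test_that("MGD equals kerma times 0.114 times DgN at a grid node", {
  dgn <- read_dgn_table()
  d25 <- dgn_lookup(dgn, 25, 4.5, 0.5)
  expect_equal(d25, 0.60, tolerance = 1e-9) # exact grid node of the table
  expect_equal(mean_glandular_dose(1, 25, 4.5, 0.5, dgn),
               1 * 0.114 * 0.60, tolerance = 1e-9)
})

test_that("MGD is additive over spectrum bins", {
  dgn <- read_dgn_table()
  k <- c(0.3, 0.5, 0.2)
  e <- c(20, 25, 30)
  total <- mean_glandular_dose(k, e, 4.5, 0.5, dgn)
  parts <- vapply(1:3, function(i) {
    mean_glandular_dose(k[i], e[i], 4.5, 0.5, dgn)
  }, numeric(1))
  expect_equal(total, sum(parts), tolerance = 1e-12)
})

test_that("trilinear DgN interpolation is exact at nodes and bounded between", {
  dgn <- read_dgn_table()
  # exact reproduction at grid nodes
  expect_equal(dgn_lookup(dgn, 20, 4, 0.25),
               0.42 * (4.5 / 4)^0.6 * (1 - 0.25 * (0.25 - 0.5)),
               tolerance = 1e-6)
  # interpolated value lies between neighbouring nodes
  mid <- dgn_lookup(dgn, 22.5, 4.25, 0.4)
  lo <- min(dgn_lookup(dgn, 20, 4, 0.25), dgn_lookup(dgn, 25, 4.5, 0.5))
  hi <- max(dgn_lookup(dgn, 20, 4, 0.25), dgn_lookup(dgn, 25, 4.5, 0.5))
  expect_gte(mid, lo)
  expect_lte(mid, hi)
  expect_error(dgn_lookup(dgn, 25, 10, 0.5), class = "phasemammo_range_error")
  expect_error(dgn_lookup(dgn, 25, 4.5, 1.5), class = "phasemammo_range_error")
  expect_error(dgn_lookup(dgn, 40, 4.5, 0.5), class = "phasemammo_range_error")
})

test_that("exposure planning round-trips through the dose report", {
  sp <- mono_spectrum()
  for (target in c(0.7, 1.0, 2.0)) {
    t_exp <- exposure_time_for_mgd(target, sp)
    rep <- dose_report(sp, t_exp)
    expect_equal(rep$mgd_mGy, target, tolerance = 1e-9)
  }
})

test_that("default study dose rate sits near 0.1 mGy/s", {
  # default source: ~1-2 mGy in 10-20 s of exposure
  rep <- dose_report(mono_spectrum(), 1)
  expect_gt(rep$mgd_mGy, 0.05)
  expect_lt(rep$mgd_mGy, 0.2)
})

test_that("thickness correction is directional and identity at truth", {
  expect_equal(thickness_correction_factor(0.5, 4.5, 4.5), 1,
               tolerance = 1e-12)
  # DgN falls with thickness: true thicker than assumed -> factor < 1
  expect_lt(thickness_correction_factor(0.5, 4.5, 6), 1)
  expect_gt(thickness_correction_factor(0.5, 4.5, 3), 1)
  expect_error(thickness_correction_factor(50, 4.5, 5),
               class = "phasemammo_range_error")
})

test_that("counter calibration round-trips counts to kerma", {
  cal <- calibrate_counter(2e5, 1.6)
  expect_equal(kerma_from_counts(cal, 2e5), 1.6, tolerance = 1e-12)
  expect_equal(kerma_from_counts(cal, c(0, 1e5)), c(0, 0.8),
               tolerance = 1e-12)
  expect_error(kerma_from_counts(cal, -1), class = "phasemammo_invalid_input")
  expect_error(calibrate_counter(0, 1), class = "phasemammo_invalid_input")
})

test_that("table readers validate their inputs", {
  expect_s3_class(read_mu_en_table(), "mu_en_table")
  expect_s3_class(read_dgn_table(), "dgn_table")
  expect_true(all(diff(read_al_hvl_table()$hvl_mm) > 0))
  bad <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(energy_keV = c(10, 10),
                              mu_en_over_rho_m2_per_kg = c(1, 1)),
                   bad, row.names = FALSE)
  expect_error(read_mu_en_table(bad), class = "phasemammo_invalid_input")
})

test_that("make_dgn_table rejects non-positive or unordered grids", {
  expect_error(make_dgn_table(c(20, 15), 4.5, 0.5, c(1, 1)),
               class = "phasemammo_invalid_input")
  expect_error(make_dgn_table(c(15, 20), 4.5, 0.5, c(1, -1)),
               class = "phasemammo_invalid_input")
})
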