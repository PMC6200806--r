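test_that("Talbot distance follows the fractional-order formulas", {
  cfg <- interferometer_config()
  lambda <- xray_wavelength(25)
  expect_equal(talbot_distance(cfg), (4.9e-6)^2 / (2 * lambda),
               tolerance = 1e-12)
  cfg_pi <- interferometer_config(phase_shift = "pi")
  expect_equal(talbot_distance(cfg_pi), talbot_distance(cfg) / 4,
               tolerance = 1e-12)
  cfg_m3 <- interferometer_config(talbot_order = 3)
  expect_equal(talbot_distance(cfg_m3), 3 * talbot_distance(cfg),
               tolerance = 1e-12)
})

test_that("angular sensitivity is 2 pi d / p2", {
  cfg <- interferometer_config(inter_grating_distance_m = 0.25, p2_um = 5)
  expect_equal(angular_sensitivity(cfg), 2 * pi * 0.25 / 5e-6,
               tolerance = 1e-12)
})

test_that("noiseless flat reference matches the closed-form stepping curve", {
  ph <- flat_phantom(16, 16)
  cfg <- interferometer_config(n_steps = 8, reference_visibility = 0.45)
  sp <- mono_spectrum()
  st <- simulate_stepping_stack(ph, cfg, sp, exposure_s = 2,
                                with_sample = FALSE, noise = FALSE)
  f <- 1.5e7 * 0.071^2 * 2
  theta <- 2 * pi * (0:7) / 8
  for (s in 1:8) {
    expect_equal(st$counts[, , s],
                 matrix((f / 8) * (1 + 0.45 * cos(theta[s])), 16, 16),
                 tolerance = 1e-12)
  }
})

test_that("energy bins contribute additively", {
  ph <- flat_phantom(8, 8, att = 1)
  cfg <- interferometer_config()
  two <- new_spectrum(c(24, 26), c(5e6, 7e6), 2)
  one_a <- new_spectrum(24, 5e6, 2)
  one_b <- new_spectrum(26, 7e6, 2)
  s_two <- simulate_stepping_stack(ph, cfg, two, 1, noise = FALSE)
  s_a <- simulate_stepping_stack(ph, cfg, one_a, 1, noise = FALSE)
  s_b <- simulate_stepping_stack(ph, cfg, one_b, 1, noise = FALSE)
  expect_equal(s_two$counts, s_a$counts + s_b$counts, tolerance = 1e-10)
})

test_that("Poisson noise is seed-reproducible and mean-preserving", {
  ph <- flat_phantom(32, 32)
  cfg <- interferometer_config()
  sp <- mono_spectrum()
  a <- simulate_stepping_stack(ph, cfg, sp, 1, seed = 7)
  b <- simulate_stepping_stack(ph, cfg, sp, 1, seed = 7)
  expect_identical(a$counts, b$counts)
  expect_true(all(a$counts == round(a$counts)))
  noiseless <- simulate_stepping_stack(ph, cfg, sp, 1, noise = FALSE)
  expect_equal(mean(a$counts), mean(noiseless$counts), tolerance = 0.01)
})

test_that("plain radiograph equals fluence times transmission", {
  ph <- flat_phantom(8, 8, att = 2.25)
  img <- simulate_plain_radiograph(ph, mono_spectrum(), 1, noise = FALSE)
  f <- 1.5e7 * 0.071^2
  expect_equal(img[1, 1], f * exp(-2.25), tolerance = 1e-10)
  expect_equal(attr(img, "pixel_pitch_mm"), 0.071)
})

test_that("gaussian blur preserves constants and reduces variance", {
  m <- matrix(5, 32, 32)
  expect_equal(gaussian_blur(m, 1.5), m, tolerance = 1e-12)
  set.seed(1)
  n <- matrix(rnorm(32 * 32), 32, 32)
  expect_lt(stats::sd(gaussian_blur(n, 1.5)), stats::sd(n))
})

test_that("stepping stack constructor validates the step grid", {
  counts <- array(1, c(4, 4, 3))
  expect_error(new_stepping_stack(counts, c(0, 1), 1, 0.071),
               class = "phasemammo_invalid_input")
  expect_error(new_stepping_stack(counts, c(0, 2, 1), 1, 0.071),
               class = "phasemammo_invalid_input")
  expect_error(new_stepping_stack(counts, c(0, 1, 2 * pi), 1, 0.071),
               class = "phasemammo_invalid_input")
  counts[1] <- -1
  expect_error(new_stepping_stack(counts, c(0, 1, 2), 1, 0.071),
               class = "phasemammo_invalid_input")
})

test_that("interferometer config rejects bad parameters", {
  expect_error(interferometer_config(n_steps = 2),
               class = "phasemammo_invalid_input")
  expect_error(interferometer_config(reference_visibility = 0),
               class = "phasemammo_invalid_input")
  expect_error(interferometer_config(reference_visibility = 1.2),
               class = "phasemammo_invalid_input")
  expect_error(interferometer_config(talbot_order = 0.5),
               class = "phasemammo_invalid_input")
})
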