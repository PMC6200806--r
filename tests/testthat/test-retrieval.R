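test_that("wrap_phase maps into (-pi, pi] and is idempotent", {
  x <- seq(-10, 10, by = 0.37)
  w <- wrap_phase(x)
  expect_true(all(w > -pi & w <= pi))
  expect_equal(wrap_phase(w), w, tolerance = 1e-12)
  expect_equal(wrap_phase(pi), pi)
  expect_equal(wrap_phase(-pi), pi)
  expect_equal(wrap_phase(3 * pi), pi)
  expect_equal(wrap_phase(0.3), 0.3)
  # wrapped differences agree modulo 2 pi
  expect_equal(sin(w), sin(x), tolerance = 1e-12)
  expect_equal(cos(w), cos(x), tolerance = 1e-12)
})

test_that("stepping-curve fit is exact for synthetic sinusoids", {
  set.seed(3)
  for (n_steps in c(3, 4, 5, 8)) {
    a0 <- matrix(runif(16, 50, 150), 4, 4)
    v <- 0.37
    phi <- matrix(runif(16, -3, 3), 4, 4)
    st <- sine_stack(a0, v, phi, n_steps)
    fit <- fit_stepping_curve(st)
    expect_equal(fit$a0, a0, tolerance = 1e-10)
    expect_equal(fit$a1, v * a0, tolerance = 1e-10)
    expect_equal(wrap_phase(fit$phi1 - wrap_phase(phi)),
                 matrix(0, 4, 4), tolerance = 1e-10)
    expect_true(all(fit$valid))
  }
})

test_that("DFT estimator coincides with the least-squares sinusoid fit", {
  set.seed(11)
  n_steps <- 8
  theta <- 2 * pi * (seq_len(n_steps) - 1) / n_steps
  for (k in 1:25) {
    a0 <- runif(1, 10, 1e4)
    v <- runif(1, 0.05, 0.9)
    phi <- runif(1, -pi, pi)
    y <- a0 * (1 + v * cos(theta + phi)) + rnorm(n_steps, sd = 0.01 * a0)
    st <- new_stepping_stack(array(y, c(1, 1, n_steps)), theta, 1, 0.071)
    fit <- fit_stepping_curve(st)
    ls <- stats::lm(y ~ cos(theta) + sin(theta))
    cf <- stats::coef(ls)
    expect_equal(fit$a0[1, 1], unname(cf[1]), tolerance = 1e-9)
    expect_equal(fit$a1[1, 1], unname(sqrt(cf[2]^2 + cf[3]^2)),
                 tolerance = 1e-9)
    expect_equal(fit$phi1[1, 1], unname(atan2(-cf[3], cf[2])),
                 tolerance = 1e-9)
  }
})

test_that("median visibility of a noiseless reference equals the setting", {
  ph <- flat_phantom(16, 16)
  for (v in c(0.25, 0.45, 0.6)) {
    cfg <- interferometer_config(reference_visibility = v)
    st <- simulate_stepping_stack(ph, cfg, mono_spectrum(), 1,
                                  with_sample = FALSE, noise = FALSE)
    expect_equal(median_visibility(st), v, tolerance = 1e-12)
  }
})

test_that("multimodal retrieval enforces matching stacks", {
  ph <- flat_phantom(8, 8)
  cfg <- interferometer_config()
  sp <- mono_spectrum()
  smp <- simulate_stepping_stack(ph, cfg, sp, 1, noise = FALSE)
  ref8 <- simulate_stepping_stack(flat_phantom(8, 9), cfg, sp, 1,
                                  with_sample = FALSE, noise = FALSE)
  expect_error(multimodal_retrieve(smp, ref8),
               class = "phasemammo_invalid_input")
  cfg6 <- interferometer_config(n_steps = 6)
  ref6 <- simulate_stepping_stack(ph, cfg6, sp, 1, with_sample = FALSE,
                                  noise = FALSE)
  expect_error(multimodal_retrieve(smp, ref6),
               class = "phasemammo_invalid_input")
})

test_that("degenerate pixels are masked, not fabricated", {
  n_steps <- 8
  theta <- 2 * pi * (seq_len(n_steps) - 1) / n_steps
  # sample pixel [1,1] has zero modulation -> fringe phase undefined
  smp_counts <- array(100, c(1, 2, n_steps))
  for (s in seq_len(n_steps)) {
    smp_counts[1, 2, s] <- 100 * (1 + 0.4 * cos(theta[s]))
  }
  ref_counts <- array(0, c(1, 2, n_steps))
  for (s in seq_len(n_steps)) {
    ref_counts[1, , s] <- 120 * (1 + 0.45 * cos(theta[s]))
  }
  smp <- new_stepping_stack(smp_counts, theta, 1, 0.071)
  ref <- new_stepping_stack(ref_counts, theta, 1, 0.071,
                            with_sample = FALSE)
  mm <- multimodal_retrieve(smp, ref)
  expect_false(mm$valid[1, 1])
  expect_true(mm$valid[1, 2])
  expect_true(is.na(mm$transmission[1, 1]))
  expect_true(is.na(mm$differential_phase[1, 1]))
  expect_true(is.na(mm$dark_field[1, 1]))
  expect_equal(mm$transmission[1, 2], 100 / 120, tolerance = 1e-10)
  expect_equal(mm$dark_field[1, 2], 0.4 / 0.45, tolerance = 1e-10)
})

test_that("dark_field_log is the negative log of the visibility ratio", {
  img <- new_multimodal_image(matrix(0.8, 2, 2), matrix(0, 2, 2),
                              matrix(exp(-0.3), 2, 2))
  expect_equal(dark_field_log(img), matrix(0.3, 2, 2), tolerance = 1e-12)
})
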