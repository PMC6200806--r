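test_that("cnr matches a direct two-pass oracle exactly", {
  set.seed(21)
  img <- matrix(rnorm(64 * 64, mean = 100, sd = 5), 64, 64)
  r1 <- roi(5, 10, 5, 10)
  r2 <- roi(20, 25, 5, 10)
  bg <- roi(40, 60, 10, 50)
  res <- cnr(img, r1, r2, bg)
  m1 <- mean(img[5:10, 5:10])
  m2 <- mean(img[20:25, 5:10])
  v <- as.vector(img[40:60, 10:50])
  s <- sqrt(sum((v - mean(v))^2) / (length(v) - 1))
  expect_identical(res$cnr, (m1 - m2) / s)
  expect_identical(res$sigma_bg, s)
})

test_that("cnr validates geometry and refuses zero-variance noise", {
  img <- matrix(1, 32, 32)
  expect_error(cnr(img, roi(1, 4, 1, 4), roi(6, 9, 1, 4), roi(30, 33, 1, 4)),
               class = "phasemammo_invalid_input") # out of bounds
  expect_error(cnr(img, roi(1, 10, 1, 10), roi(12, 21, 1, 10),
                   roi(25, 28, 1, 4)),
               class = "phasemammo_invalid_input") # background too small
  expect_error(cnr(img, roi(1, 4, 1, 4), roi(6, 9, 1, 4), roi(15, 30, 1, 30)),
               class = "phasemammo_undetermined") # constant background
})

test_that("acr_score counts resolved objects per category", {
  tab <- tibble::tibble(
    category = c(rep("fiber", 6), rep("calcification_group", 5),
                 rep("mass", 5)),
    rank = c(1:6, 1:5, 1:5),
    cnr = c(4.7, 3.1, 2.1, 1.4, 0.9, 0.6, 44, 27, 17, 10, 6.4,
            12, 8.3, 5.7, 3.9, -2.7)
  )
  sc <- acr_score(tab)
  expect_equal(sc$counts$resolved[sc$counts$category == "fiber"], 4L)
  expect_equal(sc$counts$resolved[sc$counts$category ==
                                    "calcification_group"], 5L)
  # negative CNR counts by magnitude (polarity-free detectability)
  expect_equal(sc$counts$resolved[sc$counts$category == "mass"], 5L)
  expect_true(sc$pass)
  tab$cnr[1:3] <- 0.5
  expect_false(acr_score(tab)$pass)
})

test_that("acr_score rejects malformed tables", {
  bad <- tibble::tibble(category = c("fiber", "fiber"), rank = c(1, 1),
                        cnr = c(1, 2))
  expect_error(acr_score(bad), class = "phasemammo_invalid_input")
  expect_error(acr_score(tibble::tibble(a = 1)),
               class = "phasemammo_invalid_input")
})

test_that("resolution estimator returns undetermined on degenerate input", {
  expect_true(power_spectrum_resolution(matrix(7, 128, 128),
                                        0.071)$undetermined)
  set.seed(5)
  noise <- matrix(rnorm(128 * 128), 128, 128)
  r <- power_spectrum_resolution(noise, 0.071)
  expect_true(r$undetermined)
  expect_true(is.na(r$resolution_lp_mm))
  expect_error(power_spectrum_resolution(matrix(0, 32, 32), 0.071),
               class = "phasemammo_invalid_input")
})

test_that("resolution estimate respects the Nyquist invariant", {
  img <- band_limited_field(128, 0.071, 2.0, seed = 9)
  r <- power_spectrum_resolution(img, 0.071)
  expect_false(r$undetermined)
  expect_gt(r$resolution_lp_mm, 0)
  expect_lte(r$resolution_lp_mm, 1 / (2 * 0.071))
  expect_gte(r$uncertainty_lp_mm, 0)
  expect_s3_class(r$profile, "tbl_df")
})

test_that("quality table covers every layout object and both channels", {
  ph <- gammex_like_phantom()
  sp <- mono_spectrum()
  te <- exposure_time_for_mgd(1.0, sp)
  img <- simulate_plain_radiograph(ph, sp, te, seed = 31)
  q <- phantom_quality_table(list(mAC = img), ph, mgd_mgy = 1.0,
                             include_resolution = FALSE)
  expect_equal(nrow(q$cnr), 16L)
  expect_true(all(q$cnr$cnr >= 0)) # reported as magnitudes
  expect_equal(unique(q$cnr$mgd_mgy), 1.0)
  expect_equal(unique(q$cnr$modality), "mAC")

  # multimodal images expand into AC and DFC channels
  cfg <- interferometer_config()
  smp <- simulate_stepping_stack(ph, cfg, sp, te, seed = 32)
  ref <- simulate_stepping_stack(ph, cfg, sp, te, seed = 33,
                                 with_sample = FALSE)
  mm <- multimodal_retrieve(smp, ref)
  q2 <- phantom_quality_table(list(mgb = mm), ph,
                              include_resolution = FALSE)
  expect_setequal(unique(q2$cnr$modality), c("mgbAC", "mgbDFC"))
  expect_equal(nrow(q2$cnr), 32L)
})

test_that("quality table validates its inputs", {
  ph <- gammex_like_phantom()
  expect_error(phantom_quality_table(list(matrix(0, 2, 2)), ph),
               class = "phasemammo_invalid_input") # unnamed list
  expect_error(phantom_quality_table(list(a = matrix(0, 2, 2)), ph,
                                     include_resolution = FALSE),
               class = "phasemammo_invalid_input") # dimension mismatch
})
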