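test_that("roi arithmetic and validation behave", {
  r <- roi(3, 10, 5, 20)
  expect_s3_class(r, "roi")
  expect_equal(roi_area(r), 8 * 16)
  expect_error(roi(5, 3, 1, 2), class = "phasemammo_invalid_input")
  expect_error(roi(0, 3, 1, 2), class = "phasemammo_invalid_input")
  expect_error(roi(1.5, 3, 1, 2), class = "phasemammo_invalid_input")
  # regression: named scalar inputs must not corrupt the names
  named <- c(row1 = 3L)
  r2 <- roi(named, 10, 5, 20)
  expect_identical(unclass(r2), unclass(r))
})

test_that("gammex phantom has the expected structure", {
  ph <- gammex_like_phantom()
  expect_s3_class(ph, "phantom_model")
  expect_equal(dim(ph), c(192L, 192L))
  lay <- ph$layout
  expect_equal(nrow(lay), 16L)
  expect_equal(sum(lay$category == "fiber"), 6L)
  expect_equal(sum(lay$category == "calcification_group"), 5L)
  expect_equal(sum(lay$category == "mass"), 5L)
  # attenuation contrasts decrease with rank within each category
  for (cat in unique(lay$category)) {
    sub <- lay[lay$category == cat, ]
    sub <- sub[order(sub$rank), ]
    deltas <- vapply(seq_len(nrow(sub)), function(i) {
      r1 <- roi(sub$roi1_row1[i], sub$roi1_row2[i],
                sub$roi1_col1[i], sub$roi1_col2[i])
      mean(ph$attenuation[r1[1]:r1[2], r1[3]:r1[4]]) -
        0.5 * ph$compressed_thickness_cm
    }, numeric(1))
    expect_true(all(diff(deltas) < 0))
  }
})

test_that("gammex phantom is deterministic", {
  expect_identical(gammex_like_phantom(), gammex_like_phantom())
})

test_that("gammex phantom rejects absurd contrast scales", {
  expect_error(gammex_like_phantom(contrast_scale = 1e5),
               class = "phasemammo_invalid_input")
  expect_error(gammex_like_phantom(pixel_pitch_mm = 0.5),
               class = "phasemammo_invalid_input")
})

test_that("breast texture phantom is seed-reproducible", {
  a <- breast_texture_phantom(shape = c(64, 64), seed = 5)
  b <- breast_texture_phantom(shape = c(64, 64), seed = 5)
  expect_identical(a, b)
  c <- breast_texture_phantom(shape = c(64, 64), seed = 6)
  expect_false(identical(a$attenuation, c$attenuation))
})

test_that("breast background attenuation rises with glandularity", {
  lo <- breast_texture_phantom(shape = c(64, 64), glandularity = 0,
                               seed = 1, texture_rms = 0)
  hi <- breast_texture_phantom(shape = c(64, 64), glandularity = 1,
                               seed = 1, texture_rms = 0)
  expect_equal(mean(lo$attenuation), 0.44 * 4.5, tolerance = 1e-12)
  expect_equal(mean(hi$attenuation), 0.57 * 4.5, tolerance = 1e-12)
})

test_that("lesion insertion adds layout rows with legal ROIs", {
  les <- list(calc_cluster = list(n = 6, region_px = 48),
              mass = list(radius_px = 15))
  ph <- breast_texture_phantom(shape = c(256, 256), lesion_spec = les,
                               seed = 2)
  expect_equal(nrow(ph$layout), 2L)
  expect_setequal(ph$layout$category, c("calcification_group", "mass"))
  # constructor validation implies ROIs are in bounds and non-overlapping
  expect_s3_class(ph, "phantom_model")
})

test_that("phantom constructor rejects inconsistent maps", {
  m <- matrix(0, 8, 8)
  expect_error(new_phantom_model(m, matrix(0, 8, 9), m, 0.071, 4.5),
               class = "phasemammo_invalid_input")
  expect_error(new_phantom_model(m - 1, m, m, 0.071, 4.5),
               class = "phasemammo_invalid_input")
  expect_error(new_phantom_model(m, m, m, -1, 4.5),
               class = "phasemammo_invalid_input")
})

test_that("project_phantom scales maps and refuses extrapolation", {
  ph <- flat_phantom(8, 8, att = 2, phase = 10, scatter = 0.3)
  same <- project_phantom(ph, 25)
  expect_equal(same$attenuation, ph$attenuation, tolerance = 1e-12)
  expect_equal(same$phase, ph$phase, tolerance = 1e-12)
  lo <- project_phantom(ph, 20)
  expect_true(all(lo$attenuation > ph$attenuation))
  expect_equal(lo$phase, ph$phase * 25 / 20, tolerance = 1e-12)
  expect_equal(lo$scatter, ph$scatter * (25 / 20)^2, tolerance = 1e-12)
  expect_error(project_phantom(ph, 40), class = "phasemammo_range_error")
  expect_error(project_phantom(ph, 10), class = "phasemammo_range_error")
})

test_that("layout validation rejects overlapping or out-of-bounds ROIs", {
  lay <- gammex_like_phantom()$layout[1, ]
  lay$roi2_row1 <- lay$roi1_row1 # overlap roi1
  lay$roi2_row2 <- lay$roi1_row2
  lay$roi2_col1 <- lay$roi1_col1
  lay$roi2_col2 <- lay$roi1_col2
  m <- matrix(0, 192, 192)
  expect_error(new_phantom_model(m, m, m, 0.071, 4.5, layout = lay),
               class = "phasemammo_invalid_input")
})
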