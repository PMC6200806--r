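small_cfg <- function(mods) {
  cfg <- default_study_config()
  cfg$modalities <- mods
  cfg$analysis$resolution <- FALSE
  cfg
}

test_that("empty modality list yields an empty but well-formed study", {
  st <- run_dose_study(small_cfg(list()))
  expect_s3_class(st, "dose_study")
  expect_equal(nrow(st$cnr), 0L)
  expect_equal(nrow(st$acr), 0L)
  expect_equal(nrow(st$dose), 0L)
})

test_that("an absorption run produces CNR and accreditation tables", {
  st <- run_dose_study(small_cfg(list(list(name = "mAC", mgd_mgy = 2.0))))
  expect_equal(nrow(st$cnr), 16L)
  expect_equal(unique(st$cnr$modality), "mAC")
  expect_equal(unique(st$cnr$mgd_mgy), 2.0)
  expect_equal(nrow(st$acr), 1L)
  expect_equal(nrow(st$dose), 1L)
  expect_gt(st$dose$exposure_s, 0)
  # consistency with the standalone dosimetry chain
  expect_equal(st$dose$exposure_s,
               exposure_time_for_mgd(2.0, mono_spectrum()),
               tolerance = 1e-9)
})

test_that("grating runs expand into AC and DFC channels", {
  st <- run_dose_study(small_cfg(list(list(name = "mgb", mgd_mgy = 1.8))))
  expect_setequal(unique(st$cnr$modality), c("mgbAC", "mgbDFC"))
  expect_equal(nrow(st$cnr), 32L)
  expect_equal(nrow(st$acr), 2L)
})

test_that("reruns with the same config are bit-identical", {
  cfg <- small_cfg(list(list(name = "mAC", mgd_mgy = 1.0)))
  a <- run_dose_study(cfg)
  b <- run_dose_study(cfg)
  expect_identical(a$cnr, b$cnr)
  expect_identical(a$acr, b$acr)
  expect_identical(a$seeds, b$seeds)
})

test_that("changing the master seed changes the realization", {
  cfg1 <- small_cfg(list(list(name = "mAC", mgd_mgy = 1.0)))
  cfg2 <- cfg1
  cfg2$seed <- 2L
  a <- run_dose_study(cfg1)
  b <- run_dose_study(cfg2)
  expect_false(identical(a$cnr$cnr, b$cnr$cnr))
})

test_that("output directory receives tables, summary, config and log", {
  out <- file.path(tempdir(), "study_out")
  st <- run_dose_study(small_cfg(list(list(name = "mAC", mgd_mgy = 1.0))),
                       output_dir = out)
  for (f in c("cnr.csv", "resolution.csv", "acr.csv", "dose.csv",
              "summary.json", "config.yaml", "run.log")) {
    expect_true(file.exists(file.path(out, f)), info = f)
  }
  back <- utils::read.csv(file.path(out, "cnr.csv"))
  expect_equal(nrow(back), nrow(st$cnr))
  expect_equal(back$cnr, st$cnr$cnr, tolerance = 1e-9)
  cfg_back <- yaml::read_yaml(file.path(out, "config.yaml"))
  expect_equal(cfg_back$seed, 1L)
  unlink(out, recursive = TRUE)
})

test_that("study config files merge over the defaults", {
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(seed = 99L,
                        source = list(peak_energy_keV = 24)), f)
  cfg <- read_study_config(f)
  expect_equal(cfg$seed, 99L)
  expect_equal(cfg$source$peak_energy_keV, 24)
  # untouched defaults survive the merge
  expect_equal(cfg$source$fluence_rate_per_mm2_s, 1.5e7)
  expect_equal(length(cfg$modalities), 5L)
  fj <- tempfile(fileext = ".json")
  jsonlite::write_json(list(seed = 7), fj, auto_unbox = TRUE)
  expect_equal(read_study_config(fj)$seed, 7)
})

test_that("unknown phantom generators are rejected", {
  cfg <- small_cfg(list(list(name = "mAC", mgd_mgy = 1.0)))
  cfg$phantom$generator <- "nope"
  expect_error(run_dose_study(cfg), class = "phasemammo_invalid_input")
})
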