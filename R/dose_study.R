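# End-to-end dose-study driver: for each (modality, MGD) pair, compute the
# exposure, simulate the tiled acquisition, retrieve (for grating modes),
# stitch, and run the CNR / resolution / accreditation analyses.

#' Default dose-study configuration
#'
#' Mirrors the accreditation-phantom study: a monochromatic 25 keV beam,
#' plain absorption acquisitions at 1.0 / 1.6 / 2.0 mGy and grating-based
#' trimodal acquisitions at 0.7 / 1.8 mGy, each stitched from a 2 x 2 tile
#' grid.
#'
#' @return A nested configuration list.
#' @export
default_study_config <- function() {
  list(
    seed = 1L,
    source = list(peak_energy_keV = 25, relative_bandwidth = 0, n_bins = 1,
                  fluence_rate_per_mm2_s = 1.5e7),
    phantom = list(generator = "gammex", pixel_pitch_mm = 0.071),
    interferometer = list(p1_um = 4.9, p2_um = 5.0, design_energy_keV = 25,
                          phase_shift = "pi_half", talbot_order = 1,
                          n_steps = 8, reference_visibility = 0.45),
    acquisition = list(grid = c(2, 2), overlap_px = 16, blur_sigma_px = 0,
                       noise = TRUE),
    dosimetry = list(thickness_cm = 4.5, glandularity = 0.5),
    modalities = list(
      list(name = "mAC", mgd_mgy = 1.0),
      list(name = "mAC", mgd_mgy = 1.6),
      list(name = "mAC", mgd_mgy = 2.0),
      list(name = "mgb", mgd_mgy = 0.7),
      list(name = "mgb", mgd_mgy = 1.8)
    ),
    analysis = list(cnr_threshold = 1, resolution = TRUE)
  )
}

#' Read a study configuration from YAML or JSON
#'
#' Values present in the file override the defaults of
#' [default_study_config()]; everything else keeps its default.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return The merged configuration list.
#' @export
read_study_config <- function(path) {
  user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  merge_study_config(user)
}

# modifyList merges lists recursively, which is right for the named blocks
# but wrong for `modalities` (an unnamed list of runs that must be replaced
# wholesale when the user supplies one).
merge_study_config <- function(user) {
  cfg <- utils::modifyList(default_study_config(), user)
  if ("modalities" %in% names(user)) cfg$modalities <- user$modalities
  cfg
}

build_study_phantom <- function(cfg) {
  gen <- cfg$phantom$generator %||% "gammex"
  switch(gen,
    gammex = gammex_like_phantom(
      pixel_pitch_mm = cfg$phantom$pixel_pitch_mm %||% 0.071),
    breast_texture = do.call(breast_texture_phantom,
                             cfg$phantom[setdiff(names(cfg$phantom),
                                                 "generator")]),
    abort_invalid(sprintf("unknown phantom generator '%s'.", gen))
  )
}

# Simulate one tiled acquisition and return stitched image(s).
acquire_tiled <- function(phantom, spectrum, exposure_s, cfg, seed, grating,
                          icfg = NULL) {
  layout <- tile_layout(dim(phantom), grid = unlist(cfg$acquisition$grid),
                        overlap_px = cfg$acquisition$overlap_px %||% 0)
  noise <- isTRUE(cfg$acquisition$noise %||% TRUE)
  blur <- cfg$acquisition$blur_sigma_px %||% 0
  set.seed(seed)
  tile_seeds <- sample.int(.Machine$integer.max - 1L, prod(layout$grid) * 2L)
  t_tiles <- list(); df_tiles <- list(); dphi_tiles <- list()
  plain_tiles <- list()
  idx <- 0L
  for (i in seq_along(layout$row_starts)) {
    for (j in seq_along(layout$col_starts)) {
      idx <- idx + 1L
      r0 <- layout$row_starts[i]; c0 <- layout$col_starts[j]
      sub <- subset_phantom(phantom,
                            r0:(r0 + layout$tile_dim[1] - 1L),
                            c0:(c0 + layout$tile_dim[2] - 1L))
      if (grating) {
        smp <- simulate_stepping_stack(sub, icfg, spectrum, exposure_s,
                                       seed = tile_seeds[2 * idx - 1L],
                                       with_sample = TRUE, noise = noise,
                                       blur_sigma_px = blur)
        ref <- simulate_stepping_stack(sub, icfg, spectrum, exposure_s,
                                       seed = tile_seeds[2 * idx],
                                       with_sample = FALSE, noise = noise,
                                       blur_sigma_px = blur)
        mm <- multimodal_retrieve(smp, ref)
        t_tiles[[idx]] <- mm$transmission
        df_tiles[[idx]] <- mm$dark_field
        dphi_tiles[[idx]] <- mm$differential_phase
      } else {
        plain_tiles[[idx]] <- simulate_plain_radiograph(
          sub, spectrum, exposure_s, seed = tile_seeds[2 * idx - 1L],
          noise = noise, blur_sigma_px = blur)
      }
    }
  }
  if (grating) {
    new_multimodal_image(
      stitch(t_tiles, layout),
      stitch_phase(dphi_tiles, layout),
      stitch(df_tiles, layout),
      pixel_pitch_mm = phantom$pixel_pitch_mm,
      provenance = list(exposure_s = exposure_s, tiles = layout$grid)
    )
  } else {
    out <- stitch(plain_tiles, layout)
    attr(out, "pixel_pitch_mm") <- phantom$pixel_pitch_mm
    out
  }
}

#' Run the full dose study
#'
#' For every requested (modality, MGD) pair: compute the exposure time from
#' the dosimetry chain, simulate the tiled acquisition (phase stepping plus
#' reference scan for grating modes), retrieve and stitch, then compute the
#' per-object CNR table, the power-spectrum resolution and the accreditation
#' score. One master seed fans out deterministically to per-stage seeds, so
#' identical configurations reproduce identical outputs.
#'
#' @param config Configuration list; see [default_study_config()].
#' @param output_dir Optional directory; when given, CSV tables, a JSON
#'   summary, the resolved configuration and a run log are written there.
#' @return An object of class `dose_study` with tibbles `cnr`, `resolution`,
#'   `acr` and `dose`, plus the resolved `config` and the per-run `seeds`.
#' @export
run_dose_study <- function(config = default_study_config(),
                           output_dir = NULL) {
  cfg <- merge_study_config(config)
  spectrum <- make_spectrum(cfg$source$peak_energy_keV,
                            cfg$source$fluence_rate_per_mm2_s,
                            cfg$source$relative_bandwidth,
                            cfg$source$n_bins)
  mu_en <- read_mu_en_table()
  dgn <- read_dgn_table()
  phantom <- build_study_phantom(cfg)
  icfg <- do.call(interferometer_config, cfg$interferometer)

  set.seed(cfg$seed)
  n_mod <- length(cfg$modalities)
  run_seeds <- if (n_mod > 0) {
    sample.int(.Machine$integer.max - 1L, n_mod)
  } else integer(0)

  cnr_tbl <- tibble::tibble()
  res_tbl <- tibble::tibble()
  acr_tbl <- tibble::tibble()
  dose_tbl <- tibble::tibble()
  log_lines <- character()

  for (m in seq_len(n_mod)) {
    mod <- cfg$modalities[[m]]
    grating <- identical(mod$name, "mgb")
    t_exp <- exposure_time_for_mgd(mod$mgd_mgy, spectrum,
                                   cfg$dosimetry$thickness_cm,
                                   cfg$dosimetry$glandularity, mu_en, dgn)
    t0 <- Sys.time()
    img <- acquire_tiled(phantom, spectrum, t_exp, cfg, run_seeds[m],
                         grating, icfg)
    q <- phantom_quality_table(stats::setNames(list(img), mod$name), phantom,
                               mgd_mgy = mod$mgd_mgy,
                               include_resolution =
                                 isTRUE(cfg$analysis$resolution))
    cnr_tbl <- dplyr::bind_rows(cnr_tbl, q$cnr)
    res_tbl <- dplyr::bind_rows(res_tbl, q$resolution)
    for (mod_name in unique(q$cnr$modality)) {
      sc <- acr_score(q$cnr[q$cnr$modality == mod_name, ],
                      threshold = cfg$analysis$cnr_threshold %||% 1)
      acr_tbl <- dplyr::bind_rows(acr_tbl, tibble::tibble(
        modality = mod_name, mgd_mgy = mod$mgd_mgy,
        fibers = sc$counts$resolved[sc$counts$category == "fiber"],
        calcification_groups =
          sc$counts$resolved[sc$counts$category == "calcification_group"],
        masses = sc$counts$resolved[sc$counts$category == "mass"],
        pass = sc$pass))
    }
    dose_tbl <- dplyr::bind_rows(dose_tbl, tibble::tibble(
      modality = mod$name, mgd_mgy = mod$mgd_mgy, exposure_s = t_exp,
      seed = run_seeds[m]))
    log_lines <- c(log_lines, sprintf(
      "%s mgd=%.3g mGy exposure=%.4g s seed=%d elapsed=%.2f s",
      mod$name, mod$mgd_mgy, t_exp, run_seeds[m],
      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }

  study <- structure(
    list(cnr = cnr_tbl, resolution = res_tbl, acr = acr_tbl, dose = dose_tbl,
         config = cfg, seeds = run_seeds, log = log_lines),
    class = "dose_study"
  )
  if (!is.null(output_dir)) write_dose_study(study, output_dir)
  study
}

#' Write dose-study outputs to a directory
#'
#' @param study A `dose_study`.
#' @param output_dir Directory (created if missing).
#' @return `output_dir`, invisibly.
#' @export
write_dose_study <- function(study, output_dir) {
  stopifnot(inherits(study, "dose_study"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(study$cnr, file.path(output_dir, "cnr.csv"),
                   row.names = FALSE)
  utils::write.csv(study$resolution, file.path(output_dir, "resolution.csv"),
                   row.names = FALSE)
  utils::write.csv(study$acr, file.path(output_dir, "acr.csv"),
                   row.names = FALSE)
  utils::write.csv(study$dose, file.path(output_dir, "dose.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(acr = study$acr, dose = study$dose, seeds = study$seeds),
    file.path(output_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  yaml::write_yaml(study$config, file.path(output_dir, "config.yaml"))
  writeLines(study$log, file.path(output_dir, "run.log"))
  invisible(output_dir)
}
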