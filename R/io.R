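# Serialization: spectra as CSV, image planes as normalized 32-bit float
# TIFF with a JSON sidecar carrying the affine scale/offset and metadata.
#
# TIFF writers in this toolchain store values in [0, 1], so every plane is
# min/max normalized on write; the sidecar records `offset` and `scale` such
# that `values = offset + scale * stored`. Round trips are exact to float32
# precision.

norm_plane <- function(m) {
  m[!is.finite(m)] <- 0
  lo <- min(m); hi <- max(m)
  scale <- hi - lo
  if (scale <= 0) scale <- 1
  list(data = (m - lo) / scale, offset = lo, scale = scale)
}

write_plane_tiff <- function(m, path) {
  nz <- norm_plane(m)
  tiff::writeTIFF(nz$data, path, bits.per.sample = 32L)
  list(offset = nz$offset, scale = nz$scale)
}

read_plane_tiff <- function(path, offset, scale) {
  m <- tiff::readTIFF(path)
  offset + scale * m
}

#' Write / read an x-ray spectrum as CSV
#'
#' The CSV has columns `energy_keV` and `fluence_rate_per_mm2_s`; the bin
#' width is stored in a `# bin_width_keV:` header comment.
#'
#' @param spectrum An `xray_spectrum`.
#' @param path CSV file path.
#' @return `path` invisibly (writer); the spectrum (reader).
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "xray_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# bin_width_keV: %.17g",
                     attr(spectrum, "bin_width_keV")), con)
  utils::write.csv(as.data.frame(spectrum), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  first <- readLines(path, n = 1)
  bw <- suppressWarnings(as.numeric(sub("^#\\s*bin_width_keV:\\s*", "", first)))
  if (!is.finite(bw)) abort_invalid("missing bin_width_keV header comment.")
  d <- utils::read.csv(path, comment.char = "#")
  if (!all(c("energy_keV", "fluence_rate_per_mm2_s") %in% names(d))) {
    abort_invalid(
      "spectrum CSV needs columns energy_keV and fluence_rate_per_mm2_s.")
  }
  new_spectrum(d$energy_keV, d$fluence_rate_per_mm2_s, bw)
}

#' Write / read a phantom model directory
#'
#' The directory holds `attenuation.tif`, `phase.tif` and `scatter.tif`
#' (normalized float32), the object layout as `layout.csv` and the scalar
#' metadata plus normalization constants in `meta.json`.
#'
#' @param phantom A `phantom_model`.
#' @param dir Output directory (created if missing).
#' @return `dir` invisibly (writer); the phantom (reader).
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "phantom_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  planes <- c("attenuation", "phase", "scatter")
  norm <- lapply(planes, function(p) {
    write_plane_tiff(phantom[[p]], file.path(dir, paste0(p, ".tif")))
  })
  names(norm) <- planes
  utils::write.csv(as.data.frame(phantom$layout),
                   file.path(dir, "layout.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(pixel_pitch_mm = phantom$pixel_pitch_mm,
         compressed_thickness_cm = phantom$compressed_thickness_cm,
         reference_energy_keV = phantom$reference_energy_keV,
         glandularity = phantom$glandularity,
         planes = norm),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  planes <- lapply(c("attenuation", "phase", "scatter"), function(p) {
    read_plane_tiff(file.path(dir, paste0(p, ".tif")),
                    meta$planes[[p]]$offset, meta$planes[[p]]$scale)
  })
  layout <- tibble::as_tibble(utils::read.csv(file.path(dir, "layout.csv"),
                                              stringsAsFactors = FALSE))
  if (nrow(layout) == 0) layout <- empty_layout()
  new_phantom_model(planes[[1]], planes[[2]], planes[[3]],
                    pixel_pitch_mm = meta$pixel_pitch_mm,
                    compressed_thickness_cm = meta$compressed_thickness_cm,
                    layout = layout,
                    reference_energy_keV = meta$reference_energy_keV,
                    glandularity = meta$glandularity)
}

#' Write / read a phase-stepping stack
#'
#' The count planes go to a multi-page `counts.tif` (one page per step,
#' normalized jointly so relative counts across steps survive the round
#' trip); step phases, exposure, pitch and the normalization constants go to
#' `meta.json`.
#'
#' @param stack A `stepping_stack`.
#' @param dir Output directory (created if missing).
#' @return `dir` invisibly (writer); the stack (reader).
#' @export
write_stepping_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "stepping_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lo <- min(stack$counts); hi <- max(stack$counts)
  scale <- hi - lo
  if (scale <= 0) scale <- 1
  pages <- lapply(seq_len(dim(stack)[3]), function(s) {
    (stack$counts[, , s] - lo) / scale
  })
  tiff::writeTIFF(pages, file.path(dir, "counts.tif"), bits.per.sample = 32L)
  jsonlite::write_json(
    list(step_phases = stack$step_phases, exposure_s = stack$exposure_s,
         pixel_pitch_mm = stack$pixel_pitch_mm,
         with_sample = stack$with_sample,
         offset = lo, scale = scale),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_stepping_stack
#' @export
read_stepping_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  pages <- tiff::readTIFF(file.path(dir, "counts.tif"), all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  counts <- array(0, c(dim(pages[[1]]), length(pages)))
  for (s in seq_along(pages)) {
    counts[, , s] <- meta$offset + meta$scale * pages[[s]]
  }
  new_stepping_stack(counts, meta$step_phases, meta$exposure_s,
                     meta$pixel_pitch_mm, meta$with_sample)
}

#' Write / read a multimodal image directory
#'
#' Channels go to `transmission.tif` (`_T`), `differential_phase.tif`
#' (`_dphi`) and `dark_field.tif` (`_df`) plus the validity mask
#' `valid.tif`; invalid pixels are stored as 0 and restored to `NA` on read
#' via the mask. Normalization constants and metadata live in `meta.json`.
#'
#' @param image A `multimodal_image`.
#' @param dir Output directory (created if missing).
#' @return `dir` invisibly (writer); the image (reader).
#' @export
write_multimodal <- function(image, dir) {
  stopifnot(inherits(image, "multimodal_image"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  chans <- c(transmission = "transmission",
             differential_phase = "differential_phase",
             dark_field = "dark_field")
  norm <- lapply(chans, function(ch) {
    write_plane_tiff(image[[ch]], file.path(dir, paste0(ch, ".tif")))
  })
  tiff::writeTIFF(image$valid * 1, file.path(dir, "valid.tif"),
                  bits.per.sample = 32L)
  jsonlite::write_json(
    list(pixel_pitch_mm = image$pixel_pitch_mm,
         provenance = image$provenance, channels = norm),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_multimodal
#' @export
read_multimodal <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  get <- function(ch) {
    read_plane_tiff(file.path(dir, paste0(ch, ".tif")),
                    meta$channels[[ch]]$offset, meta$channels[[ch]]$scale)
  }
  valid <- tiff::readTIFF(file.path(dir, "valid.tif")) > 0.5
  tr <- get("transmission"); dp <- get("differential_phase")
  df <- get("dark_field")
  tr[!valid] <- NA_real_; dp[!valid] <- NA_real_; df[!valid] <- NA_real_
  prov <- meta$provenance
  if (is.null(prov)) prov <- list()
  new_multimodal_image(tr, dp, df, valid, meta$pixel_pitch_mm,
                       provenance = as.list(prov))
}
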