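# Digital phantoms expressed as projected attenuation / phase / scatter maps
# with a ground-truth test-object layout.

LAYOUT_COLS <- c(
  "object_id", "category", "rank",
  "roi1_row1", "roi1_row2", "roi1_col1", "roi1_col2",
  "roi2_row1", "roi2_row2", "roi2_col1", "roi2_col2",
  "bg_row1", "bg_row2", "bg_col1", "bg_col2"
)

PHANTOM_CATEGORIES <- c("fiber", "calcification_group", "mass")

#' Low-level phantom constructor
#'
#' A phantom is a set of per-pixel projected line integrals:
#' `attenuation` (dimensionless, integral of mu dz), `phase` (radians at the
#' reference energy, -(2 pi / lambda) integral of delta dz) and `scatter`
#' (dimensionless, the log of the dark-field visibility extinction), plus a
#' layout of test objects. ROIs in the layout are 1-based and inclusive.
#'
#' @param attenuation,phase,scatter Numeric matrices of equal dimension.
#' @param pixel_pitch_mm Pixel pitch (mm).
#' @param compressed_thickness_cm Compressed breast-equivalent thickness (cm).
#' @param layout Tibble of test objects; one row per object with columns
#'   `object_id`, `category` (fiber / calcification_group / mass), `rank`
#'   (1 = largest) and ROI bounds `roi1_*` (object), `roi2_*` (paired
#'   background for the CNR numerator) and `bg_*` (larger background region
#'   for the CNR denominator).
#' @param reference_energy_keV Energy at which the maps are stored.
#' @param glandularity Glandular fraction assumed for dosimetry coupling.
#' @return An object of class `phantom_model`.
#' @export
new_phantom_model <- function(attenuation, phase, scatter, pixel_pitch_mm,
                              compressed_thickness_cm,
                              layout = empty_layout(),
                              reference_energy_keV = 25,
                              glandularity = 0.5) {
  if (!is.matrix(attenuation) || !is.matrix(phase) || !is.matrix(scatter)) {
    abort_invalid("phantom maps must be matrices.")
  }
  if (!identical(dim(attenuation), dim(phase)) ||
      !identical(dim(attenuation), dim(scatter))) {
    abort_invalid("phantom maps must share the same dimensions.")
  }
  if (any(!is.finite(attenuation)) || any(attenuation < 0)) {
    abort_invalid("projected attenuation must be finite and non-negative.")
  }
  if (any(!is.finite(scatter)) || any(scatter < 0)) {
    abort_invalid("projected scatter must be finite and non-negative.")
  }
  if (any(!is.finite(phase))) abort_invalid("projected phase must be finite.")
  check_positive_scalar(pixel_pitch_mm, "pixel_pitch_mm")
  check_positive_scalar(compressed_thickness_cm, "compressed_thickness_cm")
  validate_layout(layout, dim(attenuation))
  structure(
    list(
      attenuation = attenuation, phase = phase, scatter = scatter,
      pixel_pitch_mm = pixel_pitch_mm,
      compressed_thickness_cm = compressed_thickness_cm,
      layout = layout,
      reference_energy_keV = reference_energy_keV,
      glandularity = glandularity
    ),
    class = "phantom_model"
  )
}

#' @export
dim.phantom_model <- function(x) dim(x$attenuation)

empty_layout <- function() {
  out <- lapply(LAYOUT_COLS, function(x) {
    if (x == "category") character() else if (x == "object_id") character()
    else integer()
  })
  names(out) <- LAYOUT_COLS
  tibble::as_tibble(out)
}

validate_layout <- function(layout, img_dim) {
  if (!tibble::is_tibble(layout) && !is.data.frame(layout)) {
    abort_invalid("`layout` must be a data frame.")
  }
  missing <- setdiff(LAYOUT_COLS, names(layout))
  if (length(missing) > 0) {
    abort_invalid(paste("layout is missing columns:",
                        paste(missing, collapse = ", ")))
  }
  if (nrow(layout) == 0) return(invisible(layout))
  if (!all(layout$category %in% PHANTOM_CATEGORIES)) {
    abort_invalid("layout categories must be fiber, calcification_group or mass.")
  }
  if (any(layout$rank < 1)) abort_invalid("object ranks must be >= 1.")
  if (anyDuplicated(layout[c("category", "rank")]) > 0) {
    abort_invalid("duplicate (category, rank) entries in layout.")
  }
  for (i in seq_len(nrow(layout))) {
    row <- layout[i, ]
    r1 <- layout_roi(row, "roi1")
    r2 <- layout_roi(row, "roi2")
    bg <- layout_roi(row, "bg")
    if (!roi_in_bounds(r1, img_dim) || !roi_in_bounds(r2, img_dim) ||
        !roi_in_bounds(bg, img_dim)) {
      abort_invalid(sprintf("ROIs of object '%s' exceed the image bounds.",
                            row$object_id))
    }
    if (roi_overlaps(r1, r2) || roi_overlaps(r1, bg)) {
      abort_invalid(sprintf(
        "object ROI of '%s' overlaps its paired background ROI.",
        row$object_id))
    }
  }
  invisible(layout)
}

# Background photon count per 71 um pixel behind the slab for the reference
# acquisition (2.0 mGy mean glandular dose with the package's default source,
# spectrum and dosimetry settings). Used only as a calibration anchor for the
# default object contrasts; see the methods vignette for the derivation.
GAMMEX_REFERENCE_COUNTS <- 1.435533e5

# CNR anchors at the 2.0 mGy reference acquisition, by category and rank
# (1 = largest object). Chosen so the absorption image passes accreditation
# scoring with the minimum required margin for fibers (ranks 5-6 sit below
# the CNR = 1 detectability limit) while all speck groups and masses remain
# detectable and the smallest mass approaches the limit.
GAMMEX_CNR_ANCHORS <- list(
  fiber = c(4.71, 3.13, 2.08, 1.38, 0.92, 0.61),
  calcification_group = c(44.1, 27.3, 16.9, 10.4, 6.4),
  mass = c(12.2, 8.3, 5.7, 3.9, 2.67)
)

#' Digital accreditation phantom
#'
#' Builds a breast-equivalent slab phantom modelled after a mammography
#' accreditation phantom: 6 fibers, 5 microcalcification speck groups
#' (6 specks each) and 5 masses, each category with size and contrast
#' decreasing by rank. Object attenuation contrasts default to values
#' calibrated against per-object CNR anchors at a 2.0 mGy reference
#' acquisition (see `Details`); phase and scatter contrasts give the masses
#' and speck groups a scatter-dominant dark-field signature.
#'
#' @details The projected-attenuation increment of an object with anchor CNR
#'   `c` is `-log(1 - c / sqrt(N))` where `N` is the background photon count
#'   per pixel of the reference acquisition (for speck groups the increment is
#'   additionally divided by the speck fill fraction of the object ROI), so
#'   that the expected measured CNR at the reference dose equals the anchor.
#'   The generator is deterministic; `seed` is accepted for interface
#'   symmetry with the other generators.
#'
#' @param pixel_pitch_mm Pixel pitch in mm, in (0.01, 0.2).
#' @param seed Unused; the layout is deterministic.
#' @param contrast_scale Multiplies all CNR anchors.
#' @param background_mu_per_cm Linear attenuation coefficient of the
#'   breast-equivalent slab at the reference energy (1/cm).
#' @param compressed_thickness_cm Slab thickness (cm).
#' @param reference_counts Calibration anchor; see `Details`.
#' @return A `phantom_model` (192 x 192 pixels) with 16 layout objects.
#' @export
gammex_like_phantom <- function(pixel_pitch_mm = 0.071, seed = NULL,
                                contrast_scale = 1,
                                background_mu_per_cm = 0.5,
                                compressed_thickness_cm = 4.5,
                                reference_counts = GAMMEX_REFERENCE_COUNTS) {
  if (!is_scalar_number(pixel_pitch_mm) ||
      pixel_pitch_mm <= 0.01 || pixel_pitch_mm >= 0.2) {
    abort_invalid("`pixel_pitch_mm` must lie in (0.01, 0.2).")
  }
  check_positive_scalar(contrast_scale, "contrast_scale")
  cell <- 48L
  n <- 4L * cell
  bg_att <- background_mu_per_cm * compressed_thickness_cm
  att <- matrix(bg_att, n, n)
  phase <- matrix(0, n, n)
  scatter <- matrix(0, n, n)
  sqrt_n <- sqrt(reference_counts)

  anchor_to_delta <- function(cnr, fill = 1) {
    x <- contrast_scale * cnr / sqrt_n / fill
    if (any(x >= 1)) {
      abort_invalid("contrast_scale too large: implied contrast exceeds full absorption.")
    }
    -log1p(-x)
  }

  fiber_width <- c(8L, 6L, 5L, 4L, 3L, 2L)
  mass_radius <- c(10, 8, 7, 6, 5)
  speck_offsets <- rbind(
    c(-5L, 0L), c(5L, 0L), c(-2L, 4L), c(2L, 4L), c(-2L, -4L), c(2L, -4L)
  )

  rows <- list()
  add_object <- function(id, category, rank, r1, r2, bg) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      object_id = id, category = category, rank = rank,
      roi1_row1 = r1[1], roi1_row2 = r1[2], roi1_col1 = r1[3], roi1_col2 = r1[4],
      roi2_row1 = r2[1], roi2_row2 = r2[2], roi2_col1 = r2[3], roi2_col2 = r2[4],
      bg_row1 = bg[1], bg_row2 = bg[2], bg_col1 = bg[3], bg_col2 = bg[4]
    )
  }

  cell_origin <- function(k) {
    # cells are laid out row-major on a 4 x 4 grid
    c(((k - 1L) %/% 4L) * cell, ((k - 1L) %% 4L) * cell)
  }

  k <- 0L
  for (r in 1:6) { # fibers
    k <- k + 1L
    o <- cell_origin(k)
    w <- fiber_width[r]
    row1 <- 25L - w %/% 2L
    r1 <- roi_shift(roi(row1, row1 + w - 1L, 10L, 39L), o[1], o[2])
    delta <- anchor_to_delta(GAMMEX_CNR_ANCHORS$fiber[r])
    att[r1[1]:r1[2], r1[3]:r1[4]] <- att[r1[1]:r1[2], r1[3]:r1[4]] + delta
    phase[r1[1]:r1[2], r1[3]:r1[4]] <- phase[r1[1]:r1[2], r1[3]:r1[4]] +
      4 * 0.8^(r - 1)
    scatter[r1[1]:r1[2], r1[3]:r1[4]] <- scatter[r1[1]:r1[2], r1[3]:r1[4]] +
      0.06 * 0.8^(r - 1)
    add_object(paste0("fiber_", r), "fiber", r, r1,
               roi_shift(roi(3L, 10L, 10L, 39L), o[1], o[2]),
               roi_shift(roi(36L, 46L, 3L, 46L), o[1], o[2]))
  }

  for (r in 1:5) { # microcalcification speck groups
    k <- k + 1L
    o <- cell_origin(k)
    r1 <- roi_shift(roi(17L, 31L, 17L, 31L), o[1], o[2])
    fill <- (6 * 9) / roi_area(roi(17L, 31L, 17L, 31L))
    delta <- anchor_to_delta(GAMMEX_CNR_ANCHORS$calcification_group[r], fill)
    for (s in seq_len(nrow(speck_offsets))) {
      cr <- 24L + speck_offsets[s, 1] + o[1]
      cc <- 24L + speck_offsets[s, 2] + o[2]
      idx_r <- (cr - 1L):(cr + 1L)
      idx_c <- (cc - 1L):(cc + 1L)
      att[idx_r, idx_c] <- att[idx_r, idx_c] + delta
      phase[idx_r, idx_c] <- phase[idx_r, idx_c] + 2
      scatter[idx_r, idx_c] <- scatter[idx_r, idx_c] + 0.5 * 0.8^(r - 1)
    }
    add_object(paste0("calc_group_", r), "calcification_group", r, r1,
               roi_shift(roi(3L, 10L, 10L, 39L), o[1], o[2]),
               roi_shift(roi(36L, 46L, 3L, 46L), o[1], o[2]))
  }

  for (r in 1:5) { # masses
    k <- k + 1L
    o <- cell_origin(k)
    rad <- mass_radius[r]
    ctr <- 24.5
    rows_idx <- matrix(seq_len(cell), cell, cell)
    cols_idx <- matrix(seq_len(cell), cell, cell, byrow = TRUE)
    disk <- (rows_idx - ctr)^2 + (cols_idx - ctr)^2 <= rad^2
    delta <- anchor_to_delta(GAMMEX_CNR_ANCHORS$mass[r])
    sub_r <- (o[1] + 1L):(o[1] + cell)
    sub_c <- (o[2] + 1L):(o[2] + cell)
    blk <- att[sub_r, sub_c]; blk[disk] <- blk[disk] + delta
    att[sub_r, sub_c] <- blk
    blk <- phase[sub_r, sub_c]; blk[disk] <- blk[disk] + 8 * 0.75^(r - 1)
    phase[sub_r, sub_c] <- blk
    blk <- scatter[sub_r, sub_c]; blk[disk] <- blk[disk] + 0.12 * 0.85^(r - 1)
    scatter[sub_r, sub_c] <- blk
    h <- floor(rad / sqrt(2))
    r1 <- roi_shift(roi(25L - h, 24L + h, 25L - h, 24L + h), o[1], o[2])
    add_object(paste0("mass_", r), "mass", r, r1,
               roi_shift(roi(3L, 10L, 10L, 39L), o[1], o[2]),
               roi_shift(roi(36L, 46L, 3L, 46L), o[1], o[2]))
  }

  layout <- dplyr::bind_rows(rows)
  new_phantom_model(att, phase, scatter, pixel_pitch_mm,
                    compressed_thickness_cm, layout,
                    reference_energy_keV = 25, glandularity = 0.5)
}

#' Breast-texture phantom with optional lesions
#'
#' Generates a power-law (1/f^beta) textured projected-attenuation map that
#' mimics the anatomical background of a compressed breast, with an optional
#' inserted microcalcification cluster (Gaussian-profile specks with elevated
#' scatter) and an optional spiculated mass (disk plus a radial line bundle).
#'
#' @param shape Image dimensions `c(rows, cols)`.
#' @param glandularity Glandular tissue fraction in \[0, 1\]; sets the
#'   background attenuation.
#' @param lesion_spec `NULL` (no lesions) or a list with optional elements
#'   `calc_cluster` (fields `n`, `radius_px`, `contrast`, `scatter`,
#'   `center`, `region_px`) and `mass` (fields `radius_px`, `contrast`,
#'   `scatter`, `n_spicules`, `spicule_len_px`, `center`).
#' @param seed Integer RNG seed; identical seeds give bit-identical phantoms.
#' @param pixel_pitch_mm Pixel pitch (mm).
#' @param compressed_thickness_cm Compressed thickness (cm).
#' @param texture_rms Relative RMS amplitude of the attenuation texture.
#' @param spectral_index Exponent beta of the 1/f^beta texture power law.
#' @param phase_scale Amplitude (radians) of the correlated phase texture.
#' @return A `phantom_model`.
#' @export
breast_texture_phantom <- function(shape = c(256, 256), glandularity = 0.5,
                                   lesion_spec = NULL, seed = NULL,
                                   pixel_pitch_mm = 0.071,
                                   compressed_thickness_cm = 4.5,
                                   texture_rms = 0.05, spectral_index = 3,
                                   phase_scale = 30) {
  if (length(shape) != 2L || any(shape < 32) || any(shape != round(shape))) {
    abort_invalid("`shape` must be two integer dimensions >= 32.")
  }
  if (!is_scalar_number(glandularity) || glandularity < 0 || glandularity > 1) {
    abort_invalid("`glandularity` must lie in [0, 1].")
  }
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  if (!is.null(seed)) set.seed(seed)

  tex <- matrix(0, nr, nc)
  if (texture_rms > 0) {
    w <- matrix(stats::rnorm(nr * nc), nr, nc)
    fr <- freq_radius(nr, nc, pitch = 1) # cycles per pixel
    filt <- ifelse(fr > 0, fr^(-spectral_index / 2), 0)
    tex <- Re(stats::fft(stats::fft(w) * filt, inverse = TRUE)) / (nr * nc)
    tex <- tex - mean(tex)
    tex <- tex * texture_rms / stats::sd(tex)
  }

  mu <- 0.44 + 0.13 * glandularity # 1/cm at the 25 keV reference energy
  bg <- mu * compressed_thickness_cm
  att <- pmax(bg * (1 + tex), 0)
  phase <- phase_scale * tex
  scatter <- matrix(0, nr, nc)
  layout <- empty_layout()

  if (!is.null(lesion_spec)) {
    rows_idx <- matrix(seq_len(nr), nr, nc)
    cols_idx <- matrix(seq_len(nc), nr, nc, byrow = TRUE)

    if (!is.null(lesion_spec$calc_cluster)) {
      cc <- utils::modifyList(
        list(n = 12, radius_px = 1.5, contrast = 0.8, scatter = 0.5,
             center = NULL, region_px = 64),
        lesion_spec$calc_cluster
      )
      ctr <- cc$center %||% c(round(nr / 2), round(nc * 0.35))
      half <- cc$region_px / 2
      centers <- sample_points(cc$n, ctr, half - 2 * cc$radius_px,
                               min_dist = 4 * cc$radius_px + 1)
      sig <- cc$radius_px / 2
      for (s in seq_len(nrow(centers))) {
        d2 <- (rows_idx - centers[s, 1])^2 + (cols_idx - centers[s, 2])^2
        prof <- exp(-d2 / (2 * sig^2))
        prof[d2 > (3 * cc$radius_px)^2] <- 0
        att <- att + cc$contrast * prof
        scatter <- scatter + cc$scatter * prof
      }
      r1 <- roi(max(1, ctr[1] - half), min(nr, ctr[1] + half),
                max(1, ctr[2] - half), min(nc, ctr[2] + half))
      layout <- dplyr::bind_rows(layout, lesion_layout_row(
        "calc_cluster", "calcification_group", r1, nr, nc))
    }

    if (!is.null(lesion_spec$mass)) {
      ms <- utils::modifyList(
        list(radius_px = 20, contrast = 0.05, scatter = 0.1,
             n_spicules = 8, spicule_len_px = 25, center = NULL),
        lesion_spec$mass
      )
      ctr <- ms$center %||% c(round(nr / 2), round(nc * 0.7))
      d2 <- (rows_idx - ctr[1])^2 + (cols_idx - ctr[2])^2
      disk <- d2 <= ms$radius_px^2
      att[disk] <- att[disk] + ms$contrast
      scatter[disk] <- scatter[disk] + ms$scatter
      if (ms$n_spicules > 0) {
        angles <- stats::runif(ms$n_spicules, 0, 2 * pi)
        for (a in angles) {
          t_seq <- seq(ms$radius_px, ms$radius_px + ms$spicule_len_px, by = 0.5)
          pr <- round(ctr[1] + t_seq * sin(a))
          pc <- round(ctr[2] + t_seq * cos(a))
          keep <- pr >= 1 & pr <= nr & pc >= 1 & pc <= nc
          idx <- unique(cbind(pr[keep], pc[keep]))
          att[idx] <- att[idx] + ms$contrast / 2
          scatter[idx] <- scatter[idx] + ms$scatter / 2
        }
      }
      h <- floor(ms$radius_px / sqrt(2))
      r1 <- roi(max(1, ctr[1] - h), min(nr, ctr[1] + h),
                max(1, ctr[2] - h), min(nc, ctr[2] + h))
      layout <- dplyr::bind_rows(layout, lesion_layout_row(
        "mass_lesion", "mass", r1, nr, nc))
    }
  }

  new_phantom_model(att, phase, scatter, pixel_pitch_mm,
                    compressed_thickness_cm, layout,
                    reference_energy_keV = 25, glandularity = glandularity)
}

# Place n points uniformly in a square of half-width `half` around `center`
# with a minimum pairwise distance, by rejection sampling.
sample_points <- function(n, center, half, min_dist, max_tries = 10000) {
  pts <- matrix(numeric(0), 0, 2)
  tries <- 0
  while (nrow(pts) < n && tries < max_tries) {
    tries <- tries + 1
    cand <- center + stats::runif(2, -half, half)
    if (nrow(pts) == 0 ||
        all(sqrt((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2) >= min_dist)) {
      pts <- rbind(pts, cand)
    }
  }
  if (nrow(pts) < n) abort_invalid("could not place lesion specks; region too small.")
  pts
}

# Background ROIs for an inserted lesion: a paired strip above the object
# and a larger sigma region below it (falls back to the other side if the
# object sits close to an edge).
lesion_layout_row <- function(id, category, r1, nr, nc) {
  h2 <- 12L
  above_ok <- r1[1] - h2 - 2L >= 1L
  r2 <- if (above_ok) {
    roi(r1[1] - h2 - 1L, r1[1] - 2L, r1[3], r1[4])
  } else {
    roi(r1[2] + 2L, r1[2] + h2 + 1L, r1[3], r1[4])
  }
  hbg <- 20L
  bg <- if (r1[2] + hbg + 2L <= nr && above_ok) {
    roi(r1[2] + 2L, r1[2] + hbg + 1L, max(1L, r1[3] - 10L),
        min(nc, r1[4] + 10L))
  } else {
    roi(max(1L, r1[1] - hbg - h2 - 3L), r1[1] - h2 - 3L,
        max(1L, r1[3] - 10L), min(nc, r1[4] + 10L))
  }
  tibble::tibble(
    object_id = id, category = category, rank = 1L,
    roi1_row1 = r1[1], roi1_row2 = r1[2], roi1_col1 = r1[3], roi1_col2 = r1[4],
    roi2_row1 = r2[1], roi2_row2 = r2[2], roi2_col1 = r2[3], roi2_col2 = r2[4],
    bg_row1 = bg[1], bg_row2 = bg[2], bg_col1 = bg[3], bg_col2 = bg[4]
  )
}

# Soft-tissue linear-attenuation energy scaling relative to 25 keV.
TISSUE_MU_RATIO <- list(
  energy_keV = c(15, 20, 25, 30, 35),
  ratio = c(2.40, 1.45, 1.00, 0.78, 0.65)
)

#' Project phantom maps to a requested energy
#'
#' Rescales the stored reference-energy maps: attenuation by the soft-tissue
#' mu(E)/mu(E_ref) ratio, phase by lambda(E)/lambda(E_ref) = E_ref/E, and
#' scatter by a (E_ref/E)^p power law (small-angle scattering strengthens
#' with wavelength).
#'
#' @param phantom A `phantom_model`.
#' @param energy_keV Requested energy; must lie within the tissue table range
#'   (15-35 keV).
#' @param scatter_power Exponent p of the scatter energy scaling.
#' @return A list with matrices `attenuation`, `phase` and `scatter`.
#' @export
project_phantom <- function(phantom, energy_keV, scatter_power = 2) {
  stopifnot(inherits(phantom, "phantom_model"))
  rng <- range(TISSUE_MU_RATIO$energy_keV)
  if (!is_scalar_number(energy_keV) ||
      energy_keV < rng[1] || energy_keV > rng[2]) {
    abort_range(sprintf("energy %.3g keV outside the supported range [%g, %g].",
                        energy_keV, rng[1], rng[2]))
  }
  e0 <- phantom$reference_energy_keV
  mu_ratio <- stats::approx(TISSUE_MU_RATIO$energy_keV, TISSUE_MU_RATIO$ratio,
                            xout = energy_keV)$y /
    stats::approx(TISSUE_MU_RATIO$energy_keV, TISSUE_MU_RATIO$ratio,
                  xout = e0)$y
  list(
    attenuation = phantom$attenuation * mu_ratio,
    phase = phantom$phase * (e0 / energy_keV),
    scatter = phantom$scatter * (e0 / energy_keV)^scatter_power
  )
}

# Crop a phantom to a row/column window (layout is dropped; used for tiled
# acquisition where quality analysis runs on the stitched full image).
subset_phantom <- function(phantom, rows, cols) {
  new_phantom_model(
    phantom$attenuation[rows, cols, drop = FALSE],
    phantom$phase[rows, cols, drop = FALSE],
    phantom$scatter[rows, cols, drop = FALSE],
    phantom$pixel_pitch_mm, phantom$compressed_thickness_cm,
    empty_layout(), phantom$reference_energy_keV, phantom$glandularity
  )
}

# Radial spatial-frequency grid (unshifted FFT layout) in cycles per unit,
# where `pitch` is the sample spacing.
freq_radius <- function(nr, nc, pitch) {
  fx <- fft_freq(nr, pitch)
  fy <- fft_freq(nc, pitch)
  sqrt(outer(fx^2, fy^2, `+`))
}

fft_freq <- function(n, pitch) {
  k <- c(seq(0, floor(n / 2)), seq(-(ceiling(n / 2) - 1), -1))
  k / (n * pitch)
}
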