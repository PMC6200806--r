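# Image-quality analyses: contrast-to-noise ratio, power-spectrum resolution
# with the 2x noise-baseline criterion, accreditation scoring and batch
# quality tables.

#' Contrast-to-noise ratio between two regions of interest
#'
#' `CNR = (S1 - S2) / sigma_BG`: the difference of the sample means of two
#' ROIs divided by the sample standard deviation (denominator n - 1) of a
#' larger background ROI.
#'
#' @param image Numeric matrix.
#' @param roi1,roi2 ROIs to compare (see [roi()]).
#' @param roi_bg Background ROI for the noise estimate; must be larger than
#'   both object ROIs.
#' @return An object of class `cnr_result`.
#' @export
cnr <- function(image, roi1, roi2, roi_bg) {
  roi1 <- as_roi(roi1); roi2 <- as_roi(roi2); roi_bg <- as_roi(roi_bg)
  d <- dim(image)
  for (r in list(roi1, roi2, roi_bg)) {
    if (!roi_in_bounds(r, d)) abort_invalid("ROI exceeds the image bounds.")
  }
  if (roi_area(roi_bg) <= max(roi_area(roi1), roi_area(roi2))) {
    abort_invalid("background ROI must be larger than the object ROIs.")
  }
  m1 <- mean(roi_values(image, roi1))
  m2 <- mean(roi_values(image, roi2))
  s <- stats::sd(roi_values(image, roi_bg))
  if (!is.finite(s) || s == 0) {
    abort_undetermined("background ROI has zero variance; CNR undefined.")
  }
  structure(
    list(cnr = (m1 - m2) / s, mean_roi1 = m1, mean_roi2 = m2, sigma_bg = s,
         roi1 = roi1, roi2 = roi2, roi_bg = roi_bg),
    class = "cnr_result"
  )
}

#' Image resolution from the radially averaged power spectrum
#'
#' The image is Fourier transformed, the squared modulus smoothed with a
#' Gaussian filter (circular convolution, the spectrum being periodic) and
#' radially averaged. The noise baseline is the median smoothed power in the
#' top `baseline_frac` of frequencies below Nyquist. The resolution is the
#' maximal spatial frequency at which the radial power crosses down through
#' `threshold` times the baseline (log-linear interpolation between bins).
#' The quoted uncertainty is the standard deviation of the estimate over the
#' four image quadrants.
#'
#' @param image Numeric matrix, at least 64 x 64.
#' @param pixel_pitch_mm Pixel pitch (mm).
#' @param filter_sigma_bins Gaussian filter width in frequency bins. Kept
#'   narrow by default: wide filters smear sharp spectral edges upward in
#'   frequency when the signal-to-noise-floor power ratio is large, biasing
#'   the crossing estimate.
#' @param baseline_frac Fraction of the band below Nyquist used for the
#'   noise baseline.
#' @param threshold Signal-to-baseline power ratio defining the crossing.
#' @return An object of class `resolution_result` with fields
#'   `resolution_lp_mm` (`NA` when undetermined), `undetermined`,
#'   `uncertainty_lp_mm`, the radial `profile` tibble, the `baseline` power
#'   and the parameters used. A constant image or pure noise, whose spectrum
#'   never rises above the threshold, yields an undetermined result rather
#'   than a fabricated number.
#' @export
power_spectrum_resolution <- function(image, pixel_pitch_mm,
                                      filter_sigma_bins = 0.5,
                                      baseline_frac = 0.1,
                                      threshold = 2) {
  if (!is.matrix(image) || min(dim(image)) < 64) {
    abort_invalid("image must be a matrix of at least 64 x 64 pixels.")
  }
  check_positive_scalar(pixel_pitch_mm, "pixel_pitch_mm")
  est <- psd_resolution_core(image, pixel_pitch_mm, filter_sigma_bins,
                             baseline_frac, threshold)
  # quadrant spread
  nr <- nrow(image); nc <- ncol(image)
  hr <- nr %/% 2L; hc <- nc %/% 2L
  quads <- list(image[1:hr, 1:hc], image[1:hr, (hc + 1L):nc],
                image[(hr + 1L):nr, 1:hc], image[(hr + 1L):nr, (hc + 1L):nc])
  qest <- vapply(quads, function(q) {
    psd_resolution_core(q, pixel_pitch_mm, filter_sigma_bins,
                        baseline_frac, threshold)$resolution
  }, numeric(1))
  qest <- qest[is.finite(qest)]
  structure(
    list(resolution_lp_mm = est$resolution,
         undetermined = !is.finite(est$resolution),
         uncertainty_lp_mm = if (length(qest) >= 2) stats::sd(qest) else NA_real_,
         quadrant_estimates = qest,
         profile = est$profile, baseline = est$baseline,
         params = list(filter_sigma_bins = filter_sigma_bins,
                       baseline_frac = baseline_frac, threshold = threshold,
                       pixel_pitch_mm = pixel_pitch_mm,
                       nyquist_lp_mm = 1 / (2 * pixel_pitch_mm))),
    class = "resolution_result"
  )
}

psd_resolution_core <- function(image, pitch, sigma_bins, baseline_frac,
                                threshold) {
  nr <- nrow(image); nc <- ncol(image)
  x <- image - mean(image)
  p <- Mod(stats::fft(x))^2
  if (sigma_bins > 0) {
    r <- max(1L, ceiling(4 * sigma_bins))
    k <- stats::dnorm(-r:r, sd = sigma_bins)
    k <- k / sum(k)
    p <- circ_blur_axis(p, k, rows = TRUE)
    p <- circ_blur_axis(p, k, rows = FALSE)
  }
  fr <- freq_radius(nr, nc, pitch)
  nyq <- 1 / (2 * pitch)
  df <- 1 / (min(nr, nc) * pitch)
  bin <- floor(fr / df)
  keep <- fr <= nyq
  prof <- tapply(p[keep], bin[keep], mean)
  f_mid <- (as.numeric(names(prof)) + 0.5) * df
  baseline_band <- f_mid >= (1 - baseline_frac) * nyq
  baseline <- stats::median(prof[baseline_band])
  profile <- tibble::tibble(frequency_lp_mm = f_mid, power = as.numeric(prof))
  if (!is.finite(baseline) || baseline <= 0) {
    return(list(resolution = NA_real_, profile = profile, baseline = baseline))
  }
  ratio <- as.numeric(prof) / baseline
  ratio <- ratio[order(f_mid)]
  f_ord <- sort(f_mid)
  # drop the DC bin, search only below Nyquist
  use <- f_ord > 0 & f_ord <= nyq
  ratio <- ratio[use]; f_ord <- f_ord[use]
  if (length(ratio) < 3 || max(ratio) < threshold || ratio[1] < threshold) {
    return(list(resolution = NA_real_, profile = profile, baseline = baseline))
  }
  idx <- which(ratio[-length(ratio)] >= threshold &
                 ratio[-1] < threshold)
  if (length(idx) == 0) {
    return(list(resolution = NA_real_, profile = profile, baseline = baseline))
  }
  i <- max(idx)
  # log-linear interpolation of the crossing
  l1 <- log(ratio[i]); l2 <- log(max(ratio[i + 1], .Machine$double.xmin))
  frac <- if (l1 == l2) 0.5 else (l1 - log(threshold)) / (l1 - l2)
  res <- f_ord[i] + frac * (f_ord[i + 1] - f_ord[i])
  list(resolution = min(res, nyq), profile = profile, baseline = baseline)
}

circ_blur_axis <- function(m, k, rows) {
  r <- (length(k) - 1L) / 2L
  n <- if (rows) nrow(m) else ncol(m)
  out <- matrix(0, nrow(m), ncol(m))
  base <- seq_len(n)
  for (j in -r:r) {
    idx <- ((base + j - 1L) %% n) + 1L
    w <- k[j + r + 1L]
    if (rows) out <- out + w * m[idx, , drop = FALSE]
    else out <- out + w * m[, idx, drop = FALSE]
  }
  out
}

#' Accreditation-phantom scoring
#'
#' An object counts as resolved when its CNR (magnitude) reaches the Rose-style
#' detectability threshold of 1; the image passes when at least 4 fibers,
#' 3 microcalcification groups and 3 masses are resolved.
#'
#' @param cnr_table Tibble with columns `category`, `rank` and `cnr`, one row
#'   per test object. Duplicate (category, rank) pairs are an error.
#' @param threshold Detectability threshold on CNR.
#' @param required Named minimum resolved counts per category.
#' @return An object of class `acr_result`: a counts tibble and a `pass`
#'   flag.
#' @export
acr_score <- function(cnr_table,
                      threshold = 1,
                      required = c(fiber = 4, calcification_group = 3,
                                   mass = 3)) {
  need <- c("category", "rank", "cnr")
  if (!all(need %in% names(cnr_table))) {
    abort_invalid("cnr_table needs columns category, rank and cnr.")
  }
  if (anyDuplicated(cnr_table[c("category", "rank")]) > 0) {
    abort_invalid("duplicate (category, rank) entries.")
  }
  counts <- vapply(names(required), function(cat) {
    sub <- cnr_table[cnr_table$category == cat, ]
    sum(abs(sub$cnr) >= threshold)
  }, numeric(1))
  structure(
    list(
      counts = tibble::tibble(category = names(required),
                              resolved = as.integer(counts),
                              required = as.integer(required)),
      pass = all(counts >= required),
      threshold = threshold
    ),
    class = "acr_result"
  )
}

#' Per-object CNR and per-image resolution tables for a phantom
#'
#' Applies [cnr()] to every layout object of the phantom (object ROI vs its
#' paired background ROI, noise from the larger background ROI) on each
#' supplied image, and [power_spectrum_resolution()] to each image. The CNR
#' is reported as a magnitude, since the accreditation criterion concerns
#' detectability regardless of contrast polarity.
#'
#' @param images Named list. Each element is either a numeric matrix (an
#'   absorption-type image) or a `multimodal_image`, which is expanded into
#'   its transmission (`<name>AC`) and dark-field (`<name>DFC`) channels.
#' @param phantom The `phantom_model` whose layout matches the images.
#' @param mgd_mgy Optional named/recycled vector of mean glandular doses to
#'   annotate the rows with.
#' @param include_resolution Compute the resolution table as well.
#' @return A list of class `quality_tables` with tibbles `cnr`
#'   (`modality, mgd_mgy, category, rank, cnr`) and `resolution`
#'   (`modality, resolution_lp_mm, uncertainty_lp_mm`).
#' @export
phantom_quality_table <- function(images, phantom, mgd_mgy = NA_real_,
                                  include_resolution = TRUE) {
  stopifnot(inherits(phantom, "phantom_model"))
  if (!is.list(images) || is.null(names(images)) || any(names(images) == "")) {
    abort_invalid("`images` must be a named list.")
  }
  flat <- list()
  for (nm in names(images)) {
    img <- images[[nm]]
    if (inherits(img, "multimodal_image")) {
      flat[[paste0(nm, "AC")]] <- img$transmission
      flat[[paste0(nm, "DFC")]] <- img$dark_field
    } else if (is.matrix(img)) {
      flat[[nm]] <- img
    } else {
      abort_invalid("images must be matrices or multimodal_image objects.")
    }
  }
  mgd_mgy <- rep_len(mgd_mgy, length(flat))
  layout <- phantom$layout
  if (nrow(layout) == 0) abort_invalid("phantom layout is empty.")

  cnr_rows <- purrr::imap(flat, function(img, nm) {
    if (!identical(dim(img), dim(phantom))) {
      abort_invalid("image dimensions do not match the phantom layout.")
    }
    vals <- purrr::map_dbl(seq_len(nrow(layout)), function(i) {
      row <- layout[i, ]
      abs(cnr(img, layout_roi(row, "roi1"), layout_roi(row, "roi2"),
              layout_roi(row, "bg"))$cnr)
    })
    tibble::tibble(modality = nm,
                   mgd_mgy = mgd_mgy[match(nm, names(flat))],
                   category = layout$category, rank = layout$rank,
                   cnr = vals)
  })
  cnr_tbl <- dplyr::bind_rows(cnr_rows)

  res_tbl <- tibble::tibble(modality = character(),
                            resolution_lp_mm = numeric(),
                            uncertainty_lp_mm = numeric())
  if (include_resolution) {
    res_tbl <- dplyr::bind_rows(purrr::imap(flat, function(img, nm) {
      r <- power_spectrum_resolution(img, phantom$pixel_pitch_mm)
      tibble::tibble(modality = nm,
                     resolution_lp_mm = r$resolution_lp_mm,
                     uncertainty_lp_mm = r$uncertainty_lp_mm)
    }))
  }
  structure(list(cnr = cnr_tbl, resolution = res_tbl),
            class = "quality_tables")
}
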