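# print / tidy / glance / autoplot methods for the package's S3 classes.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

matrix_to_long <- function(m, value_name = "value") {
  tibble::tibble(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    !!value_name := as.vector(m)
  )
}

# ---- dose_report -----------------------------------------------------------

#' @export
print.dose_report <- function(x, ...) {
  cat("<dose_report>\n")
  cat(sprintf("  exposure      : %.4g s\n", x$exposure_s))
  cat(sprintf("  air kerma     : %.4g mGy over %d bin(s)\n",
              x$total_kerma_mGy, nrow(x$kerma_per_bin)))
  cat(sprintf("  MGD           : %.4g mGy (t = %g cm, g = %g)\n",
              x$mgd_mGy, x$settings$thickness_cm, x$settings$glandularity))
  invisible(x)
}

#' Tidy a dose report into its per-bin kerma table
#' @param x A `dose_report`.
#' @param ... Unused.
#' @return Tibble with `energy_keV` and `kerma_mGy`.
#' @export
tidy.dose_report <- function(x, ...) x$kerma_per_bin

#' One-row dose-report summary
#' @param x A `dose_report`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.dose_report <- function(x, ...) {
  tibble::tibble(exposure_s = x$exposure_s,
                 total_kerma_mGy = x$total_kerma_mGy,
                 mgd_mGy = x$mgd_mGy,
                 thickness_cm = x$settings$thickness_cm,
                 glandularity = x$settings$glandularity)
}

# ---- cnr_result ------------------------------------------------------------

#' @export
print.cnr_result <- function(x, ...) {
  cat(sprintf("<cnr_result> CNR = %.4g (means %.4g vs %.4g, sigma_bg %.4g)\n",
              x$cnr, x$mean_roi1, x$mean_roi2, x$sigma_bg))
  invisible(x)
}

#' Tidy a CNR result
#' @param x A `cnr_result`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
tidy.cnr_result <- function(x, ...) {
  tibble::tibble(cnr = x$cnr, mean_roi1 = x$mean_roi1,
                 mean_roi2 = x$mean_roi2, sigma_bg = x$sigma_bg)
}

#' @rdname tidy.cnr_result
#' @export
glance.cnr_result <- function(x, ...) tidy.cnr_result(x)

# ---- acr_result ------------------------------------------------------------

#' @export
print.acr_result <- function(x, ...) {
  cat(sprintf("<acr_result> %s (CNR threshold %g)\n",
              if (x$pass) "PASS" else "FAIL", x$threshold))
  print(x$counts)
  invisible(x)
}

#' Tidy an accreditation score into its counts table
#' @param x An `acr_result`.
#' @param ... Unused.
#' @return Tibble with `category`, `resolved`, `required`.
#' @export
tidy.acr_result <- function(x, ...) x$counts

#' One-row accreditation summary
#' @param x An `acr_result`.
#' @param ... Unused.
#' @return One-row tibble with per-category counts and the pass flag.
#' @export
glance.acr_result <- function(x, ...) {
  out <- as.list(stats::setNames(x$counts$resolved, x$counts$category))
  out$pass <- x$pass
  tibble::as_tibble(out)
}

# ---- resolution_result -----------------------------------------------------

#' @export
print.resolution_result <- function(x, ...) {
  if (x$undetermined) {
    cat("<resolution_result> undetermined (no spectral crossing)\n")
  } else {
    cat(sprintf("<resolution_result> %.3g +/- %.2g LP/mm (Nyquist %.3g)\n",
                x$resolution_lp_mm, x$uncertainty_lp_mm,
                x$params$nyquist_lp_mm))
  }
  invisible(x)
}

#' Tidy a resolution result into its radial power profile
#' @param x A `resolution_result`.
#' @param ... Unused.
#' @return Tibble with `frequency_lp_mm` and `power`.
#' @export
tidy.resolution_result <- function(x, ...) x$profile

#' One-row resolution summary
#' @param x A `resolution_result`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.resolution_result <- function(x, ...) {
  tibble::tibble(resolution_lp_mm = x$resolution_lp_mm,
                 uncertainty_lp_mm = x$uncertainty_lp_mm,
                 undetermined = x$undetermined,
                 baseline = x$baseline,
                 nyquist_lp_mm = x$params$nyquist_lp_mm)
}

#' Plot the radial power profile and resolution crossing
#' @param object A `resolution_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.resolution_result <- function(object, ...) {
  p <- ggplot2::ggplot(object$profile,
                       ggplot2::aes(x = .data$frequency_lp_mm,
                                    y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "spatial frequency (LP/mm)",
                  y = "radially averaged power")
  if (is.finite(object$baseline) && object$baseline > 0) {
    p <- p + ggplot2::geom_hline(
      yintercept = object$params$threshold * object$baseline,
      linetype = "dashed")
  }
  if (!object$undetermined) {
    p <- p + ggplot2::geom_vline(xintercept = object$resolution_lp_mm,
                                 colour = "red")
  }
  p
}

# ---- quality_tables --------------------------------------------------------

#' @export
print.quality_tables <- function(x, ...) {
  cat("<quality_tables>\n$cnr\n")
  print(x$cnr)
  cat("$resolution\n")
  print(x$resolution)
  invisible(x)
}

#' Tidy quality tables into the CNR table
#' @param x A `quality_tables`.
#' @param ... Unused.
#' @return The per-object CNR tibble.
#' @export
tidy.quality_tables <- function(x, ...) x$cnr

#' Per-modality quality summary
#' @param x A `quality_tables`.
#' @param ... Unused.
#' @return One row per modality with mean CNR and resolution.
#' @export
glance.quality_tables <- function(x, ...) {
  agg <- dplyr::summarise(dplyr::group_by(x$cnr, .data$modality),
                          mean_cnr = mean(.data$cnr), .groups = "drop")
  dplyr::left_join(agg, x$resolution, by = "modality")
}

# ---- multimodal_image ------------------------------------------------------

#' @export
print.multimodal_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<multimodal_image> %d x %d px (pitch %.3g mm), %.1f%% valid\n",
    d[1], d[2], x$pixel_pitch_mm, 100 * mean(x$valid)))
  invisible(x)
}

#' Tidy a multimodal image into long pixel form
#' @param x A `multimodal_image`.
#' @param ... Unused.
#' @return Tibble with `row`, `col`, `channel`, `value`.
#' @export
tidy.multimodal_image <- function(x, ...) {
  dplyr::bind_rows(lapply(
    c("transmission", "differential_phase", "dark_field"),
    function(ch) {
      d <- matrix_to_long(x[[ch]])
      d$channel <- ch
      d
    }))
}

#' Plot the three multimodal channels side by side
#' @param object A `multimodal_image`.
#' @param ... Unused.
#' @return A ggplot with one facet per channel.
#' @export
autoplot.multimodal_image <- function(object, ...) {
  d <- tidy.multimodal_image(object)
  d$channel <- factor(d$channel, levels = c("transmission",
                                            "differential_phase",
                                            "dark_field"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(ggplot2::vars(.data$channel), scales = "free") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL)
}

# ---- phantom_model ---------------------------------------------------------

#' @export
print.phantom_model <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<phantom_model> %d x %d px (pitch %.3g mm, thickness %g cm), %d objects\n",
    d[1], d[2], x$pixel_pitch_mm, x$compressed_thickness_cm, nrow(x$layout)))
  invisible(x)
}

#' Tidy a phantom into its object layout
#' @param x A `phantom_model`.
#' @param ... Unused.
#' @return The layout tibble.
#' @export
tidy.phantom_model <- function(x, ...) x$layout

#' Plot the phantom attenuation map with object ROIs
#' @param object A `phantom_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.phantom_model <- function(object, ...) {
  d <- matrix_to_long(object$attenuation)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                       fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "attenuation")
  if (nrow(object$layout) > 0) {
    lay <- object$layout
    rects <- tibble::tibble(
      xmin = lay$roi1_col1 - 0.5, xmax = lay$roi1_col2 + 0.5,
      ymin = lay$roi1_row1 - 0.5, ymax = lay$roi1_row2 + 0.5,
      category = lay$category)
    p <- p + ggplot2::geom_rect(
      data = rects, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = .data$ymin, ymax = .data$ymax,
                   colour = .data$category),
      fill = NA, linewidth = 0.3)
  }
  p
}

# ---- stepping_stack --------------------------------------------------------

#' @export
print.stepping_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<stepping_stack> %d x %d px, %d steps, %.4g s, %s scan\n",
    d[1], d[2], d[3], x$exposure_s,
    if (x$with_sample) "sample" else "reference"))
  invisible(x)
}

# ---- dose_study ------------------------------------------------------------

#' @export
print.dose_study <- function(x, ...) {
  cat(sprintf("<dose_study> %d acquisition(s)\n", nrow(x$dose)))
  if (nrow(x$acr) > 0) print(x$acr)
  invisible(x)
}

#' Tidy a dose study into its per-object CNR table
#' @param x A `dose_study`.
#' @param ... Unused.
#' @return The CNR tibble across all modalities and dose levels.
#' @export
tidy.dose_study <- function(x, ...) x$cnr

#' Per-acquisition dose-study summary
#' @param x A `dose_study`.
#' @param ... Unused.
#' @return The accreditation table joined with exposure times.
#' @export
glance.dose_study <- function(x, ...) {
  if (nrow(x$acr) == 0) return(x$acr)
  dplyr::left_join(x$acr,
                   x$dose[c("modality", "mgd_mgy", "exposure_s")],
                   by = c("mgd_mgy"),
                   suffix = c("", "_dose"),
                   relationship = "many-to-many")
}

#' Plot CNR against mean glandular dose
#'
#' Log-log CNR versus MGD per object category; Poisson-limited imaging gives
#' slope 1/2.
#'
#' @param object A `dose_study`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dose_study <- function(object, ...) {
  agg <- dplyr::summarise(
    dplyr::group_by(object$cnr, .data$modality, .data$mgd_mgy,
                    .data$category),
    mean_cnr = mean(.data$cnr), .groups = "drop")
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$mgd_mgy, y = .data$mean_cnr,
                                    colour = .data$category,
                                    shape = .data$modality)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(group = interaction(.data$category,
                                                        .data$modality))) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "mean glandular dose (mGy)", y = "mean CNR")
}
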