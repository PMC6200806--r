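# Per-pixel phase-stepping analysis: transmission, differential phase and
# dark-field retrieval from sample and reference stepping stacks.

#' Fit the per-pixel stepping curve
#'
#' First-harmonic analysis of the stepping curve: the mean `a0`, the
#' first-harmonic amplitude `a1` and phase `phi1` are taken from the discrete
#' Fourier transform over the steps. For uniform steps covering one full
#' analyzer period this estimator is exact for a pure sinusoid and coincides
#' with the least-squares three-parameter fit.
#'
#' @param stack A `stepping_stack` with at least 3 uniform steps.
#' @param visibility_floor Pixels whose fitted visibility `a1 / a0` falls
#'   below this value are flagged invalid (their fringe phase is undefined).
#' @return A list of class `stepping_fit` with matrices `a0`, `a1`, `phi1`
#'   and a logical `valid` mask.
#' @export
fit_stepping_curve <- function(stack, visibility_floor = 1e-9) {
  stopifnot(inherits(stack, "stepping_stack"))
  n <- dim(stack)[3]
  theta <- stack$step_phases
  a0 <- matrix(0, dim(stack)[1], dim(stack)[2])
  comp <- matrix(0 + 0i, dim(stack)[1], dim(stack)[2])
  for (s in seq_len(n)) {
    a0 <- a0 + stack$counts[, , s]
    comp <- comp + stack$counts[, , s] * exp(-1i * theta[s])
  }
  a0 <- a0 / n
  comp <- comp / n
  a1 <- 2 * Mod(comp)
  phi1 <- Arg(comp)
  valid <- a0 > 0 & a1 > visibility_floor * a0
  structure(list(a0 = a0, a1 = a1, phi1 = phi1, valid = valid, n_steps = n),
            class = "stepping_fit")
}

#' Wrap phase values into (-pi, pi]
#'
#' @param x Phase values (radians).
#' @return Wrapped values; wrapping is idempotent.
#' @export
wrap_phase <- function(x) {
  pi - ((pi - x) %% (2 * pi))
}

#' Multimodal retrieval from sample and reference stacks
#'
#' Channel definitions: transmission `T = a0_s / a0_r`; differential phase
#' `wrap(phi1_s - phi1_r)` in (-pi, pi\] (positive values correspond to
#' refraction toward increasing column index); dark field
#' `D = (a1_s / a0_s) / (a1_r / a0_r)`, the sample/reference visibility
#' ratio. Pixels where either fit is degenerate are flagged in the mask and
#' set `NA` in the channels.
#'
#' @param sample,reference `stepping_stack`s with matching shapes and step
#'   grids.
#' @return An object of class `multimodal_image` with matrices
#'   `transmission`, `differential_phase`, `dark_field`, a logical `valid`
#'   mask, and acquisition metadata.
#' @export
multimodal_retrieve <- function(sample, reference) {
  stopifnot(inherits(sample, "stepping_stack"),
            inherits(reference, "stepping_stack"))
  if (!identical(dim(sample), dim(reference))) {
    abort_invalid("sample and reference stacks must have identical shapes.")
  }
  if (!isTRUE(all.equal(sample$step_phases, reference$step_phases))) {
    abort_invalid("sample and reference stacks must share the step grid.")
  }
  fs <- fit_stepping_curve(sample)
  fr <- fit_stepping_curve(reference)
  valid <- fs$valid & fr$valid
  trans <- fs$a0 / fr$a0
  dphi <- wrap_phase(fs$phi1 - fr$phi1)
  df <- (fs$a1 / fs$a0) / (fr$a1 / fr$a0)
  trans[!valid] <- NA_real_
  dphi[!valid] <- NA_real_
  df[!valid] <- NA_real_
  new_multimodal_image(trans, dphi, df, valid, sample$pixel_pitch_mm,
                       provenance = list(
                         n_steps = dim(sample)[3],
                         exposure_s = sample$exposure_s
                       ))
}

#' Low-level multimodal image constructor
#'
#' @param transmission,differential_phase,dark_field Channel matrices.
#' @param valid Logical validity mask.
#' @param pixel_pitch_mm Pixel pitch (mm).
#' @param provenance Optional acquisition metadata list.
#' @return A `multimodal_image`.
#' @export
new_multimodal_image <- function(transmission, differential_phase, dark_field,
                                 valid = NULL, pixel_pitch_mm = 0.071,
                                 provenance = list()) {
  if (!identical(dim(transmission), dim(differential_phase)) ||
      !identical(dim(transmission), dim(dark_field))) {
    abort_invalid("multimodal channels must share dimensions.")
  }
  if (is.null(valid)) valid <- !is.na(transmission)
  ok <- valid & !is.na(transmission) & !is.na(dark_field)
  if (any(transmission[ok] <= 0) || any(dark_field[ok] <= 0)) {
    abort_invalid("transmission and dark field must be positive where valid.")
  }
  structure(
    list(transmission = transmission,
         differential_phase = differential_phase,
         dark_field = dark_field, valid = valid,
         pixel_pitch_mm = pixel_pitch_mm, provenance = provenance),
    class = "multimodal_image"
  )
}

#' @export
dim.multimodal_image <- function(x) dim(x$transmission)

#' Per-pixel fringe visibility of a stepping stack
#'
#' @param stack A `stepping_stack`.
#' @return Matrix of `a1 / a0`; `NA` where the fit is degenerate.
#' @export
visibility_map <- function(stack) {
  fit <- fit_stepping_curve(stack)
  v <- fit$a1 / fit$a0
  v[!fit$valid] <- NA_real_
  v
}

#' Scalar visibility summary
#'
#' @param stack A `stepping_stack`.
#' @return Median fringe visibility over valid pixels.
#' @export
median_visibility <- function(stack) {
  stats::median(visibility_map(stack), na.rm = TRUE)
}

#' Logarithmic dark-field channel
#'
#' @param image A `multimodal_image`.
#' @return Matrix `-log(dark_field)`, i.e. the retrieved projected scatter.
#' @export
dark_field_log <- function(image) {
  stopifnot(inherits(image, "multimodal_image"))
  -log(image$dark_field)
}
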