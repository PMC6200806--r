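# Forward model of a two-grating Talbot interferometer: design distances,
# phase-stepping stack synthesis with Poisson noise, and plain radiographs.

#' Configure a two-grating Talbot interferometer
#'
#' @param p1_um Phase-grating period (micrometres).
#' @param p2_um Analyzer-grating period (micrometres).
#' @param design_energy_keV Design energy (keV).
#' @param phase_shift Phase grating type: `"pi_half"` or `"pi"`.
#' @param talbot_order Fractional Talbot order (positive integer).
#' @param inter_grating_distance_m Distance between the gratings (m); defaults
#'   to the fractional Talbot distance for the given design.
#' @param n_steps Number of phase steps over one analyzer period (>= 3).
#' @param reference_visibility Fringe visibility of the empty interferometer,
#'   in (0, 1\].
#' @param reference_phase Reference fringe phase (radians): a scalar or a
#'   matrix matching the simulated image (models a non-flat reference).
#' @return An object of class `interferometer_config`.
#' @export
interferometer_config <- function(p1_um = 4.9, p2_um = 5.0,
                                  design_energy_keV = 25,
                                  phase_shift = c("pi_half", "pi"),
                                  talbot_order = 1,
                                  inter_grating_distance_m = NULL,
                                  n_steps = 8,
                                  reference_visibility = 0.45,
                                  reference_phase = 0) {
  phase_shift <- match.arg(phase_shift)
  check_positive_scalar(p1_um, "p1_um")
  check_positive_scalar(p2_um, "p2_um")
  check_positive_scalar(design_energy_keV, "design_energy_keV")
  if (!is_scalar_number(talbot_order) || talbot_order < 1 ||
      talbot_order != round(talbot_order)) {
    abort_invalid("`talbot_order` must be a positive integer.")
  }
  if (!is_scalar_number(n_steps) || n_steps < 3 || n_steps != round(n_steps)) {
    abort_invalid("`n_steps` must be an integer >= 3.")
  }
  if (!is_scalar_number(reference_visibility) ||
      reference_visibility <= 0 || reference_visibility > 1) {
    abort_invalid("`reference_visibility` must lie in (0, 1].")
  }
  cfg <- structure(
    list(
      p1_um = p1_um, p2_um = p2_um,
      design_energy_keV = design_energy_keV,
      phase_shift = phase_shift, talbot_order = as.integer(talbot_order),
      inter_grating_distance_m = inter_grating_distance_m,
      n_steps = as.integer(n_steps),
      reference_visibility = reference_visibility,
      reference_phase = reference_phase
    ),
    class = "interferometer_config"
  )
  if (is.null(cfg$inter_grating_distance_m)) {
    cfg$inter_grating_distance_m <- talbot_distance(cfg)
  }
  check_positive_scalar(cfg$inter_grating_distance_m, "inter_grating_distance_m")
  cfg
}

#' Fractional Talbot distance of the interferometer design
#'
#' For a pi/2-shifting phase grating of period `p1` at order `m` the
#' fringe-contrast maximum sits at `m * p1^2 / (2 * lambda)`; for a
#' pi-shifting grating at `m * p1^2 / (8 * lambda)`.
#'
#' @param config An [interferometer_config()].
#' @return Distance in metres.
#' @examples
#' talbot_distance(interferometer_config()) # ~0.242 m for 4.9 um at 25 keV
#' @export
talbot_distance <- function(config) {
  stopifnot(inherits(config, "interferometer_config"))
  lambda <- xray_wavelength(config$design_energy_keV)
  p1 <- config$p1_um * 1e-6
  denom <- if (config$phase_shift == "pi_half") 2 else 8
  config$talbot_order * p1^2 / (denom * lambda)
}

#' Angular sensitivity of the interferometer
#'
#' Stepping-phase shift per radian of refraction angle:
#' `2 * pi * d / p2`, with `d` the inter-grating distance.
#'
#' @param config An [interferometer_config()].
#' @return Sensitivity in radians of stepping phase per radian of refraction.
#' @export
angular_sensitivity <- function(config) {
  stopifnot(inherits(config, "interferometer_config"))
  2 * pi * config$inter_grating_distance_m / (config$p2_um * 1e-6)
}

# Stepping-phase shift map for a projected-phase map at a given energy:
# refraction angle alpha = (lambda / 2 pi) * dPhi/dx (x = column direction,
# central differences, one-sided at the borders), then Delta phi =
# angular_sensitivity * alpha. Positive shifts correspond to refraction
# toward increasing column index.
stepping_phase_shift <- function(phase_map, config, energy_keV,
                                 pixel_pitch_mm) {
  lambda <- xray_wavelength(energy_keV)
  dx <- pixel_pitch_mm * 1e-3
  nc <- ncol(phase_map)
  grad <- matrix(0, nrow(phase_map), nc)
  if (nc >= 3) {
    grad[, 2:(nc - 1)] <- (phase_map[, 3:nc] - phase_map[, 1:(nc - 2)]) / (2 * dx)
  }
  if (nc >= 2) {
    grad[, 1] <- (phase_map[, 2] - phase_map[, 1]) / dx
    grad[, nc] <- (phase_map[, nc] - phase_map[, nc - 1]) / dx
  }
  alpha <- (lambda / (2 * pi)) * grad
  angular_sensitivity(config) * alpha
}

#' Low-level stepping-stack constructor
#'
#' @param counts Non-negative array `rows x cols x n_steps` of photon counts.
#' @param step_phases Strictly increasing step phases in \[0, 2 pi).
#' @param exposure_s Total exposure time (s) across all steps.
#' @param pixel_pitch_mm Pixel pitch (mm).
#' @param with_sample Whether a sample was in the beam.
#' @return An object of class `stepping_stack`.
#' @export
new_stepping_stack <- function(counts, step_phases, exposure_s,
                               pixel_pitch_mm, with_sample = TRUE) {
  if (!is.array(counts) || length(dim(counts)) != 3L) {
    abort_invalid("`counts` must be a rows x cols x steps array.")
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    abort_invalid("counts must be finite and non-negative.")
  }
  n <- dim(counts)[3]
  if (length(step_phases) != n) {
    abort_invalid("`step_phases` must have one entry per step.")
  }
  if (any(step_phases < 0) || any(step_phases >= 2 * pi) ||
      (n > 1 && any(diff(step_phases) <= 0))) {
    abort_invalid("`step_phases` must be strictly increasing within [0, 2 pi).")
  }
  check_positive_scalar(exposure_s, "exposure_s")
  check_positive_scalar(pixel_pitch_mm, "pixel_pitch_mm")
  structure(
    list(counts = counts, step_phases = step_phases, exposure_s = exposure_s,
         pixel_pitch_mm = pixel_pitch_mm, with_sample = isTRUE(with_sample)),
    class = "stepping_stack"
  )
}

#' @export
dim.stepping_stack <- function(x) dim(x$counts)

#' Simulate a phase-stepping acquisition
#'
#' Per pixel and step `s`, the expected count is
#' `(F / n) * T * (1 + V_r * D * cos(theta_s + phi_0 + dphi))`
#' where `F` is the fluence per pixel over the whole exposure,
#' `T = exp(-attenuation)`, `D = exp(-scatter)` (multiplicative dark-field
#' visibility reduction) and `dphi` the stepping-phase shift from the
#' projected-phase gradient. Energy bins of the spectrum are simulated
#' independently and the counts summed; a one-bin spectrum reproduces the
#' monochromatic closed form. With `noise = TRUE` counts are Poisson draws.
#'
#' @param phantom A `phantom_model` (defines geometry; ignored as an object
#'   when `with_sample = FALSE`, where a flat reference scan of the same
#'   shape is produced).
#' @param config An [interferometer_config()].
#' @param spectrum An `xray_spectrum` (sample-plane fluence rate).
#' @param exposure_s Total exposure time (s), shared uniformly by the steps.
#' @param seed Integer seed for the Poisson draws.
#' @param with_sample `FALSE` produces the reference (empty-beam) scan.
#' @param noise `FALSE` returns the noiseless expectation.
#' @param blur_sigma_px Optional Gaussian detector blur (pixels) applied to
#'   the expected counts of each step before noise.
#' @return A `stepping_stack`.
#' @export
simulate_stepping_stack <- function(phantom, config, spectrum, exposure_s,
                                    seed = NULL, with_sample = TRUE,
                                    noise = TRUE, blur_sigma_px = 0) {
  stopifnot(inherits(phantom, "phantom_model"),
            inherits(config, "interferometer_config"),
            inherits(spectrum, "xray_spectrum"))
  check_positive_scalar(exposure_s, "exposure_s")
  d <- dim(phantom)
  n <- config$n_steps
  theta <- 2 * pi * (seq_len(n) - 1) / n
  pitch <- phantom$pixel_pitch_mm
  px_area <- pitch^2
  phi0 <- config$reference_phase
  expected <- array(0, c(d[1], d[2], n))
  for (b in seq_len(nrow(spectrum))) {
    e_b <- spectrum$energy_keV[b]
    f_b <- spectrum$fluence_rate_per_mm2_s[b] * px_area * exposure_s
    if (f_b == 0) next
    if (with_sample) {
      maps <- project_phantom(phantom, e_b)
      trans <- exp(-maps$attenuation)
      df <- exp(-maps$scatter)
      dphi <- stepping_phase_shift(maps$phase, config, e_b, pitch)
    } else {
      trans <- matrix(1, d[1], d[2])
      df <- trans
      dphi <- matrix(0, d[1], d[2])
    }
    for (s in seq_len(n)) {
      expected[, , s] <- expected[, , s] + (f_b / n) * trans *
        (1 + config$reference_visibility * df * cos(theta[s] + phi0 + dphi))
    }
  }
  if (blur_sigma_px > 0) {
    for (s in seq_len(n)) {
      expected[, , s] <- gaussian_blur(expected[, , s], blur_sigma_px)
    }
  }
  counts <- expected
  if (noise) {
    if (!is.null(seed)) set.seed(seed)
    counts <- array(stats::rpois(length(expected), expected), dim(expected))
  }
  new_stepping_stack(counts, theta, exposure_s, pitch,
                     with_sample = with_sample)
}

#' Simulate a plain (grating-free) radiograph
#'
#' Expected counts are `F * T` per pixel, summed over energy bins and
#' optionally Poisson sampled. This is the monochromatic absorption-contrast
#' acquisition arm of the dose study.
#'
#' @inheritParams simulate_stepping_stack
#' @return A numeric matrix of photon counts with a `pixel_pitch_mm`
#'   attribute.
#' @export
simulate_plain_radiograph <- function(phantom, spectrum, exposure_s,
                                      seed = NULL, noise = TRUE,
                                      blur_sigma_px = 0) {
  stopifnot(inherits(phantom, "phantom_model"),
            inherits(spectrum, "xray_spectrum"))
  check_positive_scalar(exposure_s, "exposure_s")
  d <- dim(phantom)
  px_area <- phantom$pixel_pitch_mm^2
  expected <- matrix(0, d[1], d[2])
  for (b in seq_len(nrow(spectrum))) {
    f_b <- spectrum$fluence_rate_per_mm2_s[b] * px_area * exposure_s
    if (f_b == 0) next
    maps <- project_phantom(phantom, spectrum$energy_keV[b])
    expected <- expected + f_b * exp(-maps$attenuation)
  }
  if (blur_sigma_px > 0) expected <- gaussian_blur(expected, blur_sigma_px)
  out <- expected
  if (noise) {
    if (!is.null(seed)) set.seed(seed)
    out <- matrix(stats::rpois(length(expected), expected), d[1], d[2])
  }
  attr(out, "pixel_pitch_mm") <- phantom$pixel_pitch_mm
  out
}

#' Separable Gaussian blur with replicated edges
#'
#' @param m Numeric matrix.
#' @param sigma_px Standard deviation in pixels; `<= 0` returns `m`.
#' @return Blurred matrix.
#' @export
gaussian_blur <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  r <- max(1L, ceiling(4 * sigma_px))
  k <- stats::dnorm(-r:r, sd = sigma_px)
  k <- k / sum(k)
  m <- blur_axis(m, k, rows = TRUE)
  blur_axis(m, k, rows = FALSE)
}

blur_axis <- function(m, k, rows) {
  r <- (length(k) - 1L) / 2L
  n <- if (rows) nrow(m) else ncol(m)
  out <- matrix(0, nrow(m), ncol(m))
  base <- seq_len(n)
  for (j in -r:r) {
    idx <- pmin(pmax(base + j, 1L), n)
    w <- k[j + r + 1L]
    if (rows) out <- out + w * m[idx, , drop = FALSE]
    else out <- out + w * m[, idx, drop = FALSE]
  }
  out
}
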