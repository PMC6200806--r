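# Inverse-Compton source model: x-ray energy relation, quasi-monochromatic
# spectrum, beam footprint and sample-plane fluence rate.

#' Configure an inverse-Compton x-ray source
#'
#' Describes a compact synchrotron source in which relativistic electrons
#' backscatter laser photons. The emitted x-ray energy follows
#' \eqn{E_x = 4 \gamma^2 E_L} with \eqn{\gamma = E_e / E_0}.
#'
#' @param electron_total_energy_mev Total electron energy \eqn{E_e} (MeV).
#' @param laser_photon_energy_ev Laser photon energy \eqn{E_L} (eV).
#' @param cone_angle_mrad Collimation cone opening angle (mrad). Either a
#'   single value (circular beam) or two values (width, height) for an
#'   elliptic beam. Must not exceed 10 mrad.
#' @param sample_distance_m Distance from the interaction point to the sample
#'   plane (m).
#' @param electron_rest_energy_mev Electron rest energy \eqn{E_0} (MeV).
#' @return An object of class `source_config`.
#' @examples
#' src <- source_config(36.9, 1.2)
#' compton_xray_energy(src)
#' @export
source_config <- function(electron_total_energy_mev,
                          laser_photon_energy_ev,
                          cone_angle_mrad = 4,
                          sample_distance_m = 16,
                          electron_rest_energy_mev = 0.511) {
  check_positive_scalar(electron_total_energy_mev, "electron_total_energy_mev")
  check_positive_scalar(laser_photon_energy_ev, "laser_photon_energy_ev")
  check_positive_scalar(sample_distance_m, "sample_distance_m")
  check_positive_scalar(electron_rest_energy_mev, "electron_rest_energy_mev")
  if (!is.numeric(cone_angle_mrad) || !length(cone_angle_mrad) %in% 1:2 ||
      any(!is.finite(cone_angle_mrad)) || any(cone_angle_mrad < 0)) {
    abort_invalid("`cone_angle_mrad` must be one or two non-negative angles.")
  }
  if (any(cone_angle_mrad > 10)) {
    abort_invalid("`cone_angle_mrad` must not exceed 10 mrad.")
  }
  if (electron_total_energy_mev <= electron_rest_energy_mev) {
    abort_invalid("`electron_total_energy_mev` must exceed the rest energy.")
  }
  structure(
    list(
      electron_total_energy_mev = electron_total_energy_mev,
      electron_rest_energy_mev = electron_rest_energy_mev,
      laser_photon_energy_ev = laser_photon_energy_ev,
      cone_angle_mrad = cone_angle_mrad,
      sample_distance_m = sample_distance_m
    ),
    class = "source_config"
  )
}

#' X-ray energy of an inverse-Compton source
#'
#' Head-on backscattering relation \eqn{E_x = 4 \gamma^2 E_L},
#' \eqn{\gamma = E_e / E_0}.
#'
#' @param source A [source_config()].
#' @return X-ray energy in keV.
#' @export
compton_xray_energy <- function(source) {
  stopifnot(inherits(source, "source_config"))
  gamma <- source$electron_total_energy_mev / source$electron_rest_energy_mev
  4 * gamma^2 * source$laser_photon_energy_ev / 1e3
}

#' Electron energy required for a target x-ray energy
#'
#' Inverts the inverse-Compton energy relation: the source is tuned by
#' adjusting the electron energy.
#'
#' @param target_xray_kev Desired x-ray energy (keV).
#' @param laser_photon_energy_ev Laser photon energy (eV).
#' @param electron_rest_energy_mev Electron rest energy (MeV).
#' @return Total electron energy in MeV.
#' @export
electron_energy_for <- function(target_xray_kev, laser_photon_energy_ev,
                                electron_rest_energy_mev = 0.511) {
  check_positive_scalar(target_xray_kev, "target_xray_kev")
  check_positive_scalar(laser_photon_energy_ev, "laser_photon_energy_ev")
  gamma <- sqrt(target_xray_kev * 1e3 / (4 * laser_photon_energy_ev))
  gamma * electron_rest_energy_mev
}

#' Construct a quasi-monochromatic binned spectrum
#'
#' Builds a Gaussian-shaped fluence-rate profile centred at `peak_kev`,
#' truncated at three standard deviations, whose bin sum equals
#' `total_fluence_rate`. The spectrum is expressed as sample-plane fluence
#' rate so that dosimetry can consume it directly. With `n_bins = 1` (or zero
#' bandwidth) the strictly monochromatic limit is recovered.
#'
#' @param peak_kev Peak (central) energy in keV.
#' @param total_fluence_rate Total photon fluence rate at the sample plane
#'   (photons / mm^2 / s), summed over all bins.
#' @param relative_bandwidth Fractional bandwidth (sigma / peak), in
#'   \[0, 0.2\].
#' @param n_bins Number of energy bins (>= 1).
#' @return A tibble of class `xray_spectrum` with columns `energy_keV`
#'   (strictly ascending bin centres) and `fluence_rate_per_mm2_s`, plus a
#'   `bin_width_keV` attribute.
#' @examples
#' make_spectrum(25, 1.5e7)                      # monochromatic
#' make_spectrum(25, 1.5e7, 0.03, n_bins = 11)   # 3% bandwidth
#' @export
make_spectrum <- function(peak_kev, total_fluence_rate,
                          relative_bandwidth = 0, n_bins = 1) {
  check_positive_scalar(peak_kev, "peak_kev")
  check_nonnegative_scalar(total_fluence_rate, "total_fluence_rate")
  if (!is_scalar_number(relative_bandwidth) ||
      relative_bandwidth < 0 || relative_bandwidth > 0.2) {
    abort_invalid("`relative_bandwidth` must lie in [0, 0.2].")
  }
  if (!is_scalar_number(n_bins) || n_bins < 1 || n_bins != round(n_bins)) {
    abort_invalid("`n_bins` must be a positive integer.")
  }
  n_bins <- as.integer(n_bins)
  sigma <- peak_kev * relative_bandwidth
  if (n_bins == 1L || sigma == 0) {
    centers <- peak_kev
    width <- if (sigma > 0) 6 * sigma else 1e-3 * peak_kev
    rate <- total_fluence_rate
    if (n_bins > 1L) {
      # zero bandwidth with several bins: all fluence in the central bin
      centers <- peak_kev + width * (seq_len(n_bins) - (n_bins + 1) / 2)
      rate <- rep(0, n_bins)
      rate[(n_bins + 1L) %/% 2L] <- total_fluence_rate
    }
  } else {
    centers <- seq(peak_kev - 3 * sigma, peak_kev + 3 * sigma,
                   length.out = n_bins)
    width <- centers[2] - centers[1]
    w <- stats::dnorm(centers, mean = peak_kev, sd = sigma)
    rate <- total_fluence_rate * w / sum(w)
  }
  new_spectrum(centers, rate, width)
}

#' Low-level spectrum constructor
#'
#' @param energy_keV Strictly ascending bin centres (keV).
#' @param fluence_rate_per_mm2_s Non-negative fluence rate per bin.
#' @param bin_width_keV Positive common bin width (keV).
#' @return An `xray_spectrum` tibble.
#' @export
new_spectrum <- function(energy_keV, fluence_rate_per_mm2_s, bin_width_keV) {
  if (length(energy_keV) < 1L || any(!is.finite(energy_keV))) {
    abort_invalid("spectrum needs at least one finite energy bin.")
  }
  if (length(energy_keV) > 1L && any(diff(energy_keV) <= 0)) {
    abort_invalid("spectrum bin centres must be strictly ascending.")
  }
  if (length(fluence_rate_per_mm2_s) != length(energy_keV) ||
      any(!is.finite(fluence_rate_per_mm2_s)) ||
      any(fluence_rate_per_mm2_s < 0)) {
    abort_invalid("fluence rates must be non-negative, one per bin.")
  }
  check_positive_scalar(bin_width_keV, "bin_width_keV")
  out <- tibble::tibble(
    energy_keV = as.numeric(energy_keV),
    fluence_rate_per_mm2_s = as.numeric(fluence_rate_per_mm2_s)
  )
  attr(out, "bin_width_keV") <- bin_width_keV
  class(out) <- c("xray_spectrum", class(out))
  out
}

#' Total fluence rate of a spectrum
#' @param spectrum An `xray_spectrum`.
#' @return Photons / mm^2 / s summed over bins.
#' @export
total_fluence_rate <- function(spectrum) {
  stopifnot(inherits(spectrum, "xray_spectrum"))
  sum(spectrum$fluence_rate_per_mm2_s)
}

#' Beam footprint at the sample plane
#'
#' Small-angle geometry: footprint extent = distance x cone angle per axis
#' (m x mrad = mm). A single cone angle gives a circular footprint.
#'
#' @param source A [source_config()].
#' @return A tibble with `width_mm` and `height_mm`.
#' @examples
#' beam_footprint(source_config(36.9, 1.2, cone_angle_mrad = 4,
#'                              sample_distance_m = 16)) # 64 mm
#' @export
beam_footprint <- function(source) {
  stopifnot(inherits(source, "source_config"))
  ang <- source$cone_angle_mrad
  if (length(ang) == 1L) ang <- c(ang, ang)
  tibble::tibble(
    width_mm = source$sample_distance_m * ang[1],
    height_mm = source$sample_distance_m * ang[2]
  )
}
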