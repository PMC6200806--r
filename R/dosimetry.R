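# Dose chain: air kerma from a binned spectrum, mean glandular dose via
# monoenergetic normalized glandular dose coefficients, HVL-based thickness
# correction, exposure planning and counter calibration.

#' Read a mass energy-absorption coefficient table for air
#'
#' CSV with columns `energy_keV` and `mu_en_over_rho_m2_per_kg` on a strictly
#' ascending energy grid. The packaged default is a synthetic stand-in table
#' (see `tools/generate_tables.R`) suitable for testing and simulation.
#'
#' @param path CSV path; defaults to the packaged stand-in table.
#' @return A tibble of class `mu_en_table`.
#' @export
read_mu_en_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "mu_en_air_synthetic.csv",
                                package = "phasemammo", mustWork = TRUE)
  tab <- utils::read.csv(path)
  if (!all(c("energy_keV", "mu_en_over_rho_m2_per_kg") %in% names(tab))) {
    abort_invalid("mu_en table must have energy_keV and mu_en_over_rho_m2_per_kg.")
  }
  if (any(diff(tab$energy_keV) <= 0) || any(tab$mu_en_over_rho_m2_per_kg <= 0)) {
    abort_invalid("mu_en table must be strictly ascending with positive values.")
  }
  out <- tibble::as_tibble(tab)
  class(out) <- c("mu_en_table", class(out))
  out
}

mu_en_lookup <- function(table, energy_keV) {
  rng <- range(table$energy_keV)
  if (any(energy_keV < rng[1]) || any(energy_keV > rng[2])) {
    abort_range(sprintf(
      "energy outside the mu_en table range [%g, %g] keV; refusing to extrapolate.",
      rng[1], rng[2]))
  }
  stats::approx(table$energy_keV, table$mu_en_over_rho_m2_per_kg,
                xout = energy_keV)$y
}

#' Construct a DgN coefficient grid
#'
#' Normalized glandular dose coefficients DgN(E, thickness, glandularity) in
#' mGy per roentgen of entrance exposure, on a full rectangular grid.
#'
#' @param energy_keV,thickness_cm,glandularity Strictly ascending grid axes.
#' @param values Numeric array `length(energy) x length(thickness) x
#'   length(glandularity)` of positive coefficients.
#' @return An object of class `dgn_table`.
#' @export
make_dgn_table <- function(energy_keV, thickness_cm, glandularity, values) {
  values <- array(values, c(length(energy_keV), length(thickness_cm),
                            length(glandularity)))
  if (any(diff(energy_keV) <= 0) ||
      (length(thickness_cm) > 1 && any(diff(thickness_cm) <= 0)) ||
      (length(glandularity) > 1 && any(diff(glandularity) <= 0))) {
    abort_invalid("DgN grid axes must be strictly ascending.")
  }
  if (any(!is.finite(values)) || any(values <= 0)) {
    abort_invalid("DgN values must be positive and finite.")
  }
  structure(list(energy_keV = energy_keV, thickness_cm = thickness_cm,
                 glandularity = glandularity, values = values),
            class = "dgn_table")
}

#' Read a DgN coefficient table
#'
#' Long CSV with columns `energy_keV`, `thickness_cm`, `glandularity`,
#' `dgn_mgy_per_r` covering a full rectangular grid. The packaged default is
#' a synthetic stand-in grid.
#'
#' @param path CSV path; defaults to the packaged stand-in table.
#' @return A `dgn_table`.
#' @export
read_dgn_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "dgn_synthetic.csv",
                                package = "phasemammo", mustWork = TRUE)
  tab <- utils::read.csv(path)
  need <- c("energy_keV", "thickness_cm", "glandularity", "dgn_mgy_per_r")
  if (!all(need %in% names(tab))) {
    abort_invalid(paste("DgN table must have columns:", paste(need, collapse = ", ")))
  }
  e <- sort(unique(tab$energy_keV))
  t <- sort(unique(tab$thickness_cm))
  g <- sort(unique(tab$glandularity))
  if (nrow(tab) != length(e) * length(t) * length(g)) {
    abort_invalid("DgN table must cover a full rectangular grid.")
  }
  o <- order(match(tab$glandularity, g), match(tab$thickness_cm, t),
             match(tab$energy_keV, e))
  make_dgn_table(e, t, g, tab$dgn_mgy_per_r[o])
}

# Linear interpolation weights of x within grid axis g (error outside).
axis_weights <- function(g, x, what) {
  if (x < g[1] || x > g[length(g)]) {
    abort_range(sprintf(
      "%s = %g outside the DgN grid range [%g, %g]; refusing to extrapolate.",
      what, x, g[1], g[length(g)]))
  }
  if (length(g) == 1L) return(list(i = c(1L, 1L), w = c(1, 0)))
  i <- findInterval(x, g, rightmost.closed = TRUE)
  i <- min(max(i, 1L), length(g) - 1L)
  w2 <- (x - g[i]) / (g[i + 1] - g[i])
  list(i = c(i, i + 1L), w = c(1 - w2, w2))
}

#' Interpolate a DgN coefficient
#'
#' Multilinear interpolation inside the grid; querying outside any axis range
#' raises a range error (no extrapolation, because silent dose
#' under-reporting is the failure mode that matters).
#'
#' @param dgn A `dgn_table`.
#' @param energy_keV,thickness_cm,glandularity Query point; `energy_keV` may
#'   be a vector.
#' @return DgN in mGy/R.
#' @export
dgn_lookup <- function(dgn, energy_keV, thickness_cm, glandularity) {
  stopifnot(inherits(dgn, "dgn_table"))
  wt <- axis_weights(dgn$thickness_cm, thickness_cm, "thickness_cm")
  wg <- axis_weights(dgn$glandularity, glandularity, "glandularity")
  vapply(energy_keV, function(e) {
    we <- axis_weights(dgn$energy_keV, e, "energy_keV")
    acc <- 0
    for (a in 1:2) for (b in 1:2) for (c in 1:2) {
      acc <- acc + we$w[a] * wt$w[b] * wg$w[c] *
        dgn$values[we$i[a], wt$i[b], wg$i[c]]
    }
    acc
  }, numeric(1))
}

#' Air kerma from a binned spectrum
#'
#' Per bin, `K(E) = E * Phi(E) * t * (mu_en / rho)_air(E)` with the photon
#' energy converted to joules and the fluence to per square metre, giving
#' kerma in mGy.
#'
#' @param spectrum An `xray_spectrum` (fluence rate per mm^2 per s).
#' @param exposure_s Exposure time (s).
#' @param mu_en A `mu_en_table`; all spectrum bins must lie inside its range.
#' @return A list with `per_bin` (tibble `energy_keV`, `kerma_mGy`) and
#'   `total_mGy`.
#' @export
air_kerma <- function(spectrum, exposure_s, mu_en = read_mu_en_table()) {
  stopifnot(inherits(spectrum, "xray_spectrum"))
  check_nonnegative_scalar(exposure_s, "exposure_s")
  mu <- mu_en_lookup(mu_en, spectrum$energy_keV)
  e_joule <- spectrum$energy_keV * 1e3 * EV_TO_JOULE
  fluence_m2 <- spectrum$fluence_rate_per_mm2_s * exposure_s * 1e6
  kerma_mgy <- e_joule * fluence_m2 * mu * 1e3
  list(
    per_bin = tibble::tibble(energy_keV = spectrum$energy_keV,
                             kerma_mGy = kerma_mgy),
    total_mGy = sum(kerma_mgy)
  )
}

#' Mean glandular dose from per-bin air kerma
#'
#' `MGD = sum_E K(E) * 0.114 * DgN(E, thickness, glandularity)`, where
#' 0.114 R/mGy converts air kerma to entrance exposure and DgN is the
#' monoenergetic normalized glandular dose coefficient.
#'
#' @param kerma_mgy Per-bin air kerma (mGy).
#' @param energy_keV Bin energies (keV), same length.
#' @param thickness_cm Compressed breast thickness (cm).
#' @param glandularity Glandular fraction.
#' @param dgn A `dgn_table`.
#' @return Mean glandular dose in mGy.
#' @export
mean_glandular_dose <- function(kerma_mgy, energy_keV, thickness_cm,
                                glandularity = 0.5, dgn = read_dgn_table()) {
  if (length(kerma_mgy) != length(energy_keV)) {
    abort_invalid("`kerma_mgy` and `energy_keV` must have the same length.")
  }
  if (any(kerma_mgy < 0)) abort_invalid("kerma must be non-negative.")
  coeff <- dgn_lookup(dgn, energy_keV, thickness_cm, glandularity)
  sum(kerma_mgy * KERMA_TO_EXPOSURE_R_PER_MGY * coeff)
}

#' Full dose report for an acquisition
#'
#' Runs the kerma and mean-glandular-dose chain for one exposure.
#'
#' @inheritParams air_kerma
#' @inheritParams mean_glandular_dose
#' @param spectrum An `xray_spectrum`.
#' @return An object of class `dose_report` with per-bin kerma, total kerma,
#'   MGD, exposure time and a settings snapshot.
#' @export
dose_report <- function(spectrum, exposure_s, thickness_cm = 4.5,
                        glandularity = 0.5, mu_en = read_mu_en_table(),
                        dgn = read_dgn_table()) {
  k <- air_kerma(spectrum, exposure_s, mu_en)
  mgd <- mean_glandular_dose(k$per_bin$kerma_mGy, k$per_bin$energy_keV,
                             thickness_cm, glandularity, dgn)
  structure(
    list(kerma_per_bin = k$per_bin, total_kerma_mGy = k$total_mGy,
         mgd_mGy = mgd, exposure_s = exposure_s,
         settings = list(thickness_cm = thickness_cm,
                         glandularity = glandularity,
                         total_fluence_rate = total_fluence_rate(spectrum))),
    class = "dose_report"
  )
}

#' Exposure time delivering a target mean glandular dose
#'
#' The dose chain is linear in exposure time, so the answer is
#' `target / rate` with `rate` the MGD at one second.
#'
#' @param target_mgd_mgy Target MGD (mGy).
#' @param spectrum An `xray_spectrum`.
#' @inheritParams mean_glandular_dose
#' @inheritParams air_kerma
#' @return Exposure time in seconds.
#' @export
exposure_time_for_mgd <- function(target_mgd_mgy, spectrum, thickness_cm = 4.5,
                                  glandularity = 0.5,
                                  mu_en = read_mu_en_table(),
                                  dgn = read_dgn_table()) {
  check_nonnegative_scalar(target_mgd_mgy, "target_mgd_mgy")
  rate <- dose_report(spectrum, 1, thickness_cm, glandularity,
                      mu_en, dgn)$mgd_mGy
  if (rate <= 0) {
    abort_invalid("dose rate is zero (empty spectrum); exposure time undefined.")
  }
  target_mgd_mgy / rate
}

#' Thickness correction factor for a reported dose
#'
#' When a dose monitor assumed the wrong compressed thickness, the reported
#' MGD is corrected by the ratio of DgN coefficients at the true and assumed
#' thicknesses, evaluated at the effective monoenergy matching the beam's
#' aluminium half value layer: `factor = DgN(E_eq, t_true) / DgN(E_eq,
#' t_assumed)`, with `corrected = reported * factor`.
#'
#' @param hvl_al_mm Half value layer of aluminium (mm).
#' @param t_assumed_cm,t_true_cm Assumed and true compressed thickness (cm).
#' @param glandularity Glandular fraction.
#' @param dgn A `dgn_table`.
#' @param hvl_table Tibble mapping `energy_keV` to `hvl_mm` (monotone
#'   increasing); defaults to the packaged stand-in aluminium table.
#' @return Dimensionless correction factor.
#' @export
thickness_correction_factor <- function(hvl_al_mm, t_assumed_cm, t_true_cm,
                                        glandularity = 0.5,
                                        dgn = read_dgn_table(),
                                        hvl_table = read_al_hvl_table()) {
  check_positive_scalar(hvl_al_mm, "hvl_al_mm")
  rng <- range(hvl_table$hvl_mm)
  if (hvl_al_mm < rng[1] || hvl_al_mm > rng[2]) {
    abort_range(sprintf("HVL %.3g mm outside the table range [%g, %g] mm.",
                        hvl_al_mm, rng[1], rng[2]))
  }
  e_eq <- stats::approx(hvl_table$hvl_mm, hvl_table$energy_keV,
                        xout = hvl_al_mm)$y
  dgn_lookup(dgn, e_eq, t_true_cm, glandularity) /
    dgn_lookup(dgn, e_eq, t_assumed_cm, glandularity)
}

#' Read an aluminium half-value-layer table
#'
#' CSV with columns `energy_keV` and `hvl_mm` (monotone increasing in
#' energy). The packaged default is a synthetic stand-in table.
#'
#' @param path CSV path; defaults to the packaged table.
#' @return A tibble.
#' @export
read_al_hvl_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "al_hvl_synthetic.csv",
                                package = "phasemammo", mustWork = TRUE)
  tab <- tibble::as_tibble(utils::read.csv(path))
  if (any(diff(tab$energy_keV) <= 0) || any(diff(tab$hvl_mm) <= 0)) {
    abort_invalid("HVL table must be monotone increasing.")
  }
  tab
}

#' Calibrate a scintillation counter against a computed kerma rate
#'
#' @param counter_rate_cps Counter rate (counts/s) observed while the beam
#'   delivers `kerma_rate_mgy_s`.
#' @param kerma_rate_mgy_s Computed air-kerma rate (mGy/s).
#' @return An object of class `counter_calibration` holding the calibration
#'   constant in counts per mGy.
#' @export
calibrate_counter <- function(counter_rate_cps, kerma_rate_mgy_s) {
  check_positive_scalar(counter_rate_cps, "counter_rate_cps")
  check_positive_scalar(kerma_rate_mgy_s, "kerma_rate_mgy_s")
  structure(list(counts_per_mgy = counter_rate_cps / kerma_rate_mgy_s),
            class = "counter_calibration")
}

#' Convert logged counter counts to air kerma
#'
#' @param calibration A `counter_calibration`.
#' @param counts Counts per frame (vector allowed).
#' @return Air kerma per frame in mGy.
#' @export
kerma_from_counts <- function(calibration, counts) {
  stopifnot(inherits(calibration, "counter_calibration"))
  if (any(counts < 0)) abort_invalid("counts must be non-negative.")
  counts / calibration$counts_per_mgy
}
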