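# Physical constants and unit helpers shared across the package.

# Elementary charge in Joule per eV (exact, SI 2019).
EV_TO_JOULE <- 1.602176634e-19

# h*c in eV*m; lambda [m] = HC_EV_M / E [eV].
HC_EV_M <- 1.23984198e-6

# Air-kerma -> exposure conversion used in the mean-glandular-dose sum:
# 0.114 R per mGy of air kerma (reciprocal of 8.76 mGy air kerma per roentgen).
KERMA_TO_EXPOSURE_R_PER_MGY <- 0.114

#' X-ray wavelength for a photon energy
#'
#' @param energy_keV Photon energy in keV.
#' @return Wavelength in metres.
#' @examples
#' xray_wavelength(25) # ~4.96e-11 m
#' @export
xray_wavelength <- function(energy_keV) {
  if (any(!is.finite(energy_keV)) || any(energy_keV <= 0)) {
    abort_invalid("`energy_keV` must be positive and finite.")
  }
  HC_EV_M / (energy_keV * 1e3)
}

abort_invalid <- function(msg) {
  rlang::abort(msg, class = "phasemammo_invalid_input")
}

abort_range <- function(msg) {
  rlang::abort(msg, class = "phasemammo_range_error")
}

abort_undetermined <- function(msg) {
  rlang::abort(msg, class = "phasemammo_undetermined")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

check_positive_scalar <- function(x, name) {
  if (!is_scalar_number(x) || x <= 0) {
    abort_invalid(sprintf("`%s` must be a single positive finite number.", name))
  }
  invisible(x)
}

check_nonnegative_scalar <- function(x, name) {
  if (!is_scalar_number(x) || x < 0) {
    abort_invalid(sprintf("`%s` must be a single non-negative finite number.", name))
  }
  invisible(x)
}
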