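# Shared fixtures for the test suite.

# Uniform slab phantom with optional constant maps.
flat_phantom <- function(nr = 64, nc = 64, att = 0, phase = 0, scatter = 0,
                         pitch = 0.071, thickness = 4.5) {
  new_phantom_model(matrix(att, nr, nc), matrix(phase, nr, nc),
                    matrix(scatter, nr, nc), pitch, thickness)
}

# Default monochromatic 25 keV study spectrum.
mono_spectrum <- function(rate = 1.5e7) make_spectrum(25, rate)

# Manually built stepping stack: one sinusoid per pixel,
# y_s = a0 * (1 + v * cos(theta_s + phi)).
sine_stack <- function(a0, v, phi, n_steps = 8, pitch = 0.071,
                       exposure_s = 1) {
  nr <- nrow(a0); nc <- ncol(a0)
  theta <- 2 * pi * (seq_len(n_steps) - 1) / n_steps
  counts <- array(0, c(nr, nc, n_steps))
  for (s in seq_len(n_steps)) {
    counts[, , s] <- a0 * (1 + v * cos(theta[s] + phi))
  }
  new_stepping_stack(counts, theta, exposure_s, pitch)
}

# Band-limited random field: flat isotropic spectrum with a hard cutoff
# (cycles/mm) plus 1% white noise; unit variance before the noise.
band_limited_field <- function(n, pitch, cutoff, seed) {
  set.seed(seed)
  half <- c(0:(n / 2), (n / 2 - 1):1)
  fr <- sqrt(outer(half^2, half^2, "+")) / (n * pitch)
  amp <- matrix(0, n, n)
  amp[fr <= cutoff] <- 1
  ph <- matrix(stats::runif(n * n, 0, 2 * pi), n, n)
  x <- Re(stats::fft(amp * exp(1i * ph), inverse = TRUE)) / (n * n)
  x <- x / stats::sd(x)
  x + 0.01 * matrix(stats::rnorm(n * n), n, n)
}

# Frozen clinical resolution-study conditions (see the methods vignette):
# textured breast phantom with a 12-speck microcalcification cluster,
# detector blur of 1.4 px, 2.0 mGy absorption acquisition.
clinical_resolution_image <- function(seed) {
  spec <- mono_spectrum()
  te <- exposure_time_for_mgd(2.0, spec)
  les <- list(calc_cluster = list(n = 12, radius_px = 1.5, contrast = 0.8,
                                  scatter = 0.5, region_px = 64))
  bt <- breast_texture_phantom(shape = c(256, 256), lesion_spec = les,
                               seed = seed)
  list(image = simulate_plain_radiograph(bt, spec, te, seed = seed + 1,
                                         blur_sigma_px = 1.4),
       pitch = bt$pixel_pitch_mm)
}
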