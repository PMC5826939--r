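# Independent oracles, kept deliberately separate from the package's own
# implementations.

# Brute-force discrete-Fourier-ratio phasor: complex first-harmonic
# coefficient of the spectrum divided by its total, term by term.
dft_phasor_oracle <- function(intensity, harmonic = 1) {
  n <- length(intensity)
  z <- 0 + 0i
  for (k in 0:(n - 1))
    z <- z + intensity[k + 1] * exp(2i * pi * harmonic * k / n)
  z <- z / sum(intensity)
  c(g = Re(z), s = Im(z))
}

# Textbook paired two-tailed t-test.
paired_t_oracle <- function(x, y) {
  d <- y - x
  n <- length(d)
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 1))
}

# Analytic area of a Gaussian peak of given height and sigma.
gaussian_area <- function(height, sigma) height * sigma * sqrt(2 * pi)

# Numeric trapezoid integration.
trapz_area <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

# Run the full imaging pipeline on one phantom spec and return the
# recovered percentage steatosis and the droplet table.
run_imaging_pipeline <- function(spec, gates = default_gates()) {
  ph <- generate_phantom(spec)
  seg <- segment_by_gates(phasor_transform(ph$stack), gates)
  list(truth = ph$truth,
       stack = ph$stack,
       seg = seg,
       composition = percentage_steatosis(seg),
       droplets = detect_droplets(seg, spec$pixel_size))
}

# Small phantom spec for fast unit tests.
small_phantom <- function(mode = "nash", seed = 1, ...) {
  tissue_phantom_spec(mode, height_px = 96, width_px = 96, seed = seed, ...)
}
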