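# Shared small fixtures, built in code at test time.

uniform_field <- function(value, dims = c(11, 11, 11), spacing = 0.01,
                          kind = "generic") {
  voxel_field(array(value, dims), spacing, kind = kind)
}

uniform_rf_config <- function(b1 = 2e-6, sar = 3, dims = c(11, 11, 11),
                              spacing = 0.01) {
  rf_configuration(
    b1_map = uniform_field(complex(real = b1), dims, spacing, "b1_plus"),
    sar_map = uniform_field(sar, dims, spacing, "sar_nominal"),
    density_map = uniform_field(1000, dims, spacing, "density"),
    body_mask = uniform_field(1, dims, spacing, "mask")
  )
}

small_sphere <- function(radius = 0.008, nvox = 12, anatomy = "hip") {
  make_implant("sphere", radius = radius, spacing = 2 * radius / nvox,
               anatomy = anatomy)
}

# single-tone spectrum helper (peak phasors)
tone_spectrum <- function(freqs, coefs) {
  co <- matrix(0 + 0i, length(freqs), 3,
               dimnames = list(NULL, c("x", "y", "z")))
  for (i in seq_along(freqs)) co[i, ] <- coefs[[i]]
  structure(list(frequencies = freqs, coefficients = co, tr = 1 / min(freqs)),
            class = "gradient_spectrum")
}

# random pulse train under a fixed seed, mixing shapes
random_pulse_train <- function(seed, n = 4) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    shape <- sample(c("hard", "rect_window", "apodized_sinc"), 1)
    rf_pulse(stats::runif(1, 0.1, pi), stats::runif(1, 0.5e-3, 3e-3),
             shape,
             time_bandwidth = sample(2:6, 1),
             window_fraction = stats::runif(1, 0.3, 1))
  })
}
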