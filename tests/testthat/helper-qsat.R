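# Shared fixtures, built in code.

# default acquisition constants used across tests
acq <- acq_params()

# small phantom geometry for fast end-to-end checks
small_params <- function(tissue, ...) {
  phantom_params(tissue, fov_um = c(400, 400), step_um = 5, ...)
}

# a cached noiseless eWAT phantom + single-channel cube (built once per run)
.fixtures <- new.env(parent = emptyenv())
fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

noiseless_ewat_cube <- function() {
  fixture("noiseless_ewat_cube", function() {
    ph <- generate_phantom(small_params("eWAT", noise_sd = 0, seed = 3))
    list(phantom = ph,
         cube = render_hypercube(ph, c(2856, 1550), seed = 3))
  })
}

# closed-form analytic signal of a sum of sinusoids: the independent oracle
# for the envelope operation
sinusoid_mixture <- function(n, freqs_cycles, amps, phases) {
  t <- seq_len(n) - 1
  sig <- rep(0, n)
  env_re <- env_im <- rep(0, n)
  for (k in seq_along(freqs_cycles)) {
    arg <- 2 * pi * freqs_cycles[k] * t + phases[k]
    sig <- sig + amps[k] * cos(arg)
    env_re <- env_re + amps[k] * cos(arg)
    env_im <- env_im + amps[k] * sin(arg)
  }
  list(signal = sig, envelope = sqrt(env_re^2 + env_im^2))
}
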