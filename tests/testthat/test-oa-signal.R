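test_that("cubic interpolation is exact on cubics and averages a linear ramp", {
  x <- seq_len(16)
  cubic <- 0.5 * x^3 - 2 * x^2 + x - 4
  t <- oa_transient(cubic, 200e6)
  expect_identical(interpolate_transient(t, 1L), t)
  t4 <- interpolate_transient(t, 4L)
  xf <- seq(1, 16, by = 0.25)
  expect_equal(t4$samples, 0.5 * xf^3 - 2 * xf^2 + xf - 4, tolerance = 1e-8)
  expect_equal(t4$fs_hz, 800e6)
  ramp <- interpolate_transient(oa_transient(seq_len(10), 200e6), 2L)
  mids <- ramp$samples[seq(2, 18, by = 2)]
  expect_equal(mids, seq_len(9) + 0.5, tolerance = 1e-10)
  expect_error(interpolate_transient(t, 0), "factor")
})

test_that("envelope equals the closed-form analytic magnitude of sinusoid mixtures", {
  # oracle: a band-limited signal built from sinusoids at exact DFT bins has
  # analytic signal sum A_k exp(i(w_k t + phi_k)); magnitudes must agree to
  # 1e-9 relative
  set.seed(42)
  for (rep in 1:5) {
    n <- 256
    bins <- sample(5:60, 4)
    mix <- sinusoid_mixture(n, bins / n, runif(4, 0.5, 2), runif(4, 0, 2 * pi))
    env <- envelope(oa_transient(mix$signal, 200e6))
    expect_lt(max(abs(env$magnitude - mix$envelope)) / max(mix$envelope),
              1e-9)
    # envelope dominates the raw signal
    expect_true(all(env$magnitude >= abs(mix$signal) - 1e-9))
  }
})

test_that("envelope of a pure cosine is flat and of zero input is zero", {
  n <- 512
  s <- 1.7 * cos(2 * pi * 32 * (0:(n - 1)) / n)
  env <- envelope(oa_transient(s, 200e6))
  interior <- env$magnitude[33:(n - 32)]
  expect_true(all(abs(interior - 1.7) / 1.7 < 0.01))
  z <- envelope(oa_transient(rep(0, 16), 200e6))
  expect_true(all(z$magnitude == 0))
  expect_error(envelope(oa_transient(rep(2, 16), 200e6)), "constant")
  expect_error(envelope(oa_transient(c(1, NA, 3, 4), 200e6)), "finite")
})

test_that("envelope peak of a Gaussian-modulated sinusoid sits at the modulation center", {
  t0 <- 100.3
  i <- 0:255
  s <- sin(2 * pi * 0.1 * (i - t0)) * exp(-(i - t0)^2 / (2 * 3^2))
  env <- envelope(oa_transient(s, 200e6))
  expect_lte(abs(which.max(env$magnitude) - 1 - t0), 1)
})

test_that("peak-to-peak is max minus min", {
  expect_equal(peak_to_peak(oa_transient(c(-1, 2), 200e6)), 3)
  expect_equal(peak_to_peak(oa_transient(rep(1.5, 8), 200e6)), 0)
  # monotone in the synthesized amplitude
  p <- vapply(c(0.5, 1, 2), function(a)
    peak_to_peak(synthesize_transient(a, 150)), 1)
  expect_true(all(diff(p) > 0))
  expect_equal(p[3] / p[1], 4, tolerance = 1e-9)
})

test_that("window location finds the reference peak and breaks ties early", {
  mag <- rep(0, 64); mag[20] <- 1
  env <- structure(list(magnitude = mag, fs_hz = 200e6, interp_factor = 1L,
                        source = NULL), class = "envelope_signal")
  w <- locate_window(env, 7.5)
  expect_equal(w$start_sample, 20 - 1)  # half-width 1 sample at minimum gate
  expect_true(w$start_sample <= 20 && w$end_sample > 20)
  mag2 <- rep(0, 64); mag2[c(25, 40)] <- 1
  env2 <- structure(list(magnitude = mag2, fs_hz = 200e6, interp_factor = 1L,
                         source = NULL), class = "envelope_signal")
  w2 <- locate_window(env2, 7.5)
  expect_true(w2$start_sample <= 25 && w2$end_sample > 25)
  expect_error(locate_window(env, 5), "below the minimum")
})

test_that("window on a synthesized pulse centers at the true depth", {
  for (depth in c(75, 150, 300)) {
    t <- synthesize_transient(1, depth)
    env <- envelope(interpolate_transient(t, 4L))
    w <- locate_window(env, 45)
    center <- (w$start_sample + w$end_sample - 1) / 2
    expect_lte(abs((center - 1) / 4 - sample_of_depth(depth)), 1)
  }
})

test_that("gated intensity is a trapezoid with additive adjacent windows", {
  mag <- abs(sin(seq(0, 6, length.out = 128))) + 0.2
  env <- structure(list(magnitude = mag, fs_hz = 800e6, interp_factor = 4L,
                        source = NULL), class = "envelope_signal")
  full <- gated_intensity(env, depth_window(1, 129))
  expect_equal(full, sum((mag[-1] + mag[-128]) / 2) / 4)
  a <- gated_intensity(env, depth_window(1, 60))
  b <- gated_intensity(env, depth_window(60, 129))
  expect_equal(a + b, full, tolerance = 1e-12)
  # constant envelope: c * (n - 1) * dt
  cmag <- rep(2, 40)
  cenv <- structure(list(magnitude = cmag, fs_hz = 200e6, interp_factor = 1L,
                         source = NULL), class = "envelope_signal")
  expect_equal(gated_intensity(cenv, depth_window(1, 41)), 2 * 39)
  zenv <- structure(list(magnitude = rep(0, 40), fs_hz = 200e6,
                         interp_factor = 1L, source = NULL),
                    class = "envelope_signal")
  expect_equal(gated_intensity(zenv, depth_window(5, 20)), 0)
  expect_error(gated_intensity(cenv, depth_window(30, 60)), "record")
})

test_that("averaging transients is the sample-wise mean with accumulated counts", {
  t1 <- oa_transient(c(1, 2, 3, 4), 200e6, n_averaged = 2L)
  expect_equal(average_transients(list(t1, t1))$samples, t1$samples)
  expect_equal(average_transients(list(t1, t1))$n_averaged, 4L)
  t2 <- oa_transient(-c(1, 2, 3, 4), 200e6)
  expect_equal(average_transients(list(t1, t2))$samples, rep(0, 4))
  expect_error(average_transients(list(t1, oa_transient(1:3, 200e6))),
               "length")
  expect_error(average_transients(list(t1, oa_transient(1:4, 100e6))),
               "sampling")
})

test_that("averaging 50 unit-noise pulses leaves residual SD near 1/sqrt(50)", {
  set.seed(7)
  n <- 4000
  ts <- lapply(1:50, function(i) oa_transient(rnorm(n), 200e6))
  avg <- average_transients(ts)
  expect_equal(sd(avg$samples), 1 / sqrt(50), tolerance = 0.05)
  # the same law through the synthesizer
  t <- synthesize_transient(0, 150, noise_sd = 1, pulses = 50, seed = 11)
  expect_equal(sd(t$samples), 1 / sqrt(50), tolerance = 0.35)
})
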