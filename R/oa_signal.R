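#' Optoacoustic transient (A-line)
#'
#' One time-resolved pressure record from a single scan position.  Arrival
#' time encodes absorber depth (one-way propagation toward the transducer).
#'
#' @param samples Numeric vector of pressure amplitudes (a.u.).
#' @param fs_hz Sampling rate in Hz (after any interpolation).
#' @param n_averaged Number of raw pulses averaged into this record.
#' @param interp_factor Integer >= 1; 1 for a raw record.
#' @return An object of class `oa_transient`.
#' @export
oa_transient <- function(samples, fs_hz, n_averaged = 1L, interp_factor = 1L) {
  samples <- as.numeric(samples)
  if (length(samples) < 2) stop("a transient needs at least 2 samples")
  if (!is.finite(fs_hz) || fs_hz <= 0) stop("fs_hz must be positive")
  if (interp_factor < 1 || interp_factor != round(interp_factor))
    stop("interp_factor must be an integer >= 1")
  structure(list(samples = samples, fs_hz = fs_hz,
                 n_averaged = as.integer(n_averaged),
                 interp_factor = as.integer(interp_factor)),
            class = "oa_transient")
}

#' @export
print.oa_transient <- function(x, ...) {
  cat(sprintf("<oa_transient> %d samples @ %.0f MS/s (x%d interp, %d averaged)\n",
              length(x$samples), x$fs_hz / 1e6, x$interp_factor, x$n_averaged))
  invisible(x)
}

# Dense cubic-spline interpolation expressed as a linear operator: row i of
# the returned matrix holds the spline weights mapping n input samples to the
# i-th output node.  Cubic spline interpolation is linear in the data, so the
# matrix applied to many A-lines at once reproduces per-column stats::spline.
interp_operator <- function(n, factor) {
  n_out <- (n - 1L) * factor + 1L
  xout <- seq(1, n, length.out = n_out)
  M <- matrix(0, n_out, n)
  for (j in seq_len(n)) {
    e <- numeric(n); e[j] <- 1
    M[, j] <- stats::spline(seq_len(n), e, xout = xout, method = "fmm")$y
  }
  M
}

#' Cubic interpolation of a transient
#'
#' Resamples the record onto a grid `factor` times denser using cubic spline
#' interpolation; `factor = 1` returns the input unchanged.
#'
#' @param t An [oa_transient()].
#' @param factor Integer interpolation factor >= 1.
#' @return An interpolated `oa_transient` with updated `fs_hz` and
#'   `interp_factor`.
#' @export
interpolate_transient <- function(t, factor = 4L) {
  stopifnot(inherits(t, "oa_transient"))
  if (factor < 1 || factor != round(factor))
    stop("interpolation factor must be an integer >= 1")
  if (factor == 1L) return(t)
  n <- length(t$samples)
  xout <- seq(1, n, length.out = (n - 1L) * factor + 1L)
  y <- stats::spline(seq_len(n), t$samples, xout = xout, method = "fmm")$y
  oa_transient(y, t$fs_hz * factor, t$n_averaged,
               t$interp_factor * as.integer(factor))
}

# Analytic-signal magnitude of one or more columns.  Standard frequency-domain
# construction: double positive frequencies, zero negative ones, keep DC (and
# Nyquist for even lengths), inverse transform, take the modulus.
analytic_envelope_matrix <- function(S) {
  n <- nrow(S)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  F <- stats::mvfft(S) * h
  Mod(stats::mvfft(F, inverse = TRUE)) / n
}

#' Envelope of a transient
#'
#' Magnitude of the analytic signal (Hilbert-transform quadrature) of the
#' A-line.  The envelope is nonnegative and, for band-limited signals, bounds
#' the raw pressure amplitude away from the record edges.
#'
#' @param t An [oa_transient()] with at least 4 samples.
#' @return An object of class `envelope_signal` with fields `magnitude`,
#'   `fs_hz`, `interp_factor` and `source`.
#' @export
envelope <- function(t) {
  stopifnot(inherits(t, "oa_transient"))
  s <- t$samples
  if (length(s) < 4) stop("envelope needs at least 4 samples")
  if (any(!is.finite(s))) stop("transient contains non-finite samples")
  if (stats::sd(s) == 0 && any(s != 0))
    stop("constant non-zero transient has no meaningful envelope")
  mag <- analytic_envelope_matrix(matrix(s, ncol = 1))[, 1]
  structure(list(magnitude = mag, fs_hz = t$fs_hz,
                 interp_factor = t$interp_factor, source = t),
            class = "envelope_signal")
}

#' Peak-to-peak intensity (MAP)
#'
#' The maximum-amplitude-projection intensity of a transient:
#' `max(samples) - min(samples)`.
#'
#' @param t An [oa_transient()].
#' @return Intensity in a.u.
#' @export
peak_to_peak <- function(t) {
  stopifnot(inherits(t, "oa_transient"))
  max(t$samples) - min(t$samples)
}

#' Depth window on an interpolated record
#'
#' Half-open interval `[start, end)` of interpolated sample indices (1-based
#' start, exclusive end) selecting one depth range of the record.
#'
#' @param start_sample,end_sample 1-based window bounds, `start < end`.
#' @param center_depth_um,width_um Physical provenance of the window.
#' @return An object of class `depth_window`.
#' @export
depth_window <- function(start_sample, end_sample,
                         center_depth_um = NA_real_, width_um = NA_real_) {
  if (start_sample < 1 || end_sample <= start_sample)
    stop("need 1 <= start < end")
  structure(list(start_sample = as.integer(start_sample),
                 end_sample = as.integer(end_sample),
                 center_depth_um = center_depth_um, width_um = width_um),
            class = "depth_window")
}

# Minimum gate width: one raw sampling interval (7.5 um at the defaults).
min_gate_width_um <- function(acq) acq$sound_speed_m_s / acq$fs_hz * 1e6

#' Locate the intracellular depth window
#'
#' Centers a window of physical width `width_um` on the maximum-amplitude
#' depth of a reference envelope (in practice the 2856 cm^-1 lipid channel),
#' clips it to the record, and breaks ties toward the earliest (shallowest)
#' sample.  Samples within `edge_exclude` positions of either record edge are
#' excluded from the argmax to avoid Hilbert edge artifacts.
#'
#' @param ref_envelope An `envelope_signal` from the reference channel.
#' @param width_um Gate width in micrometers; must be at least one raw
#'   sampling interval (7.5 um at the defaults).
#' @param acq An [acq_params()] object.
#' @param edge_exclude Number of samples excluded at each record edge.
#' @return A [depth_window()].
#' @export
locate_window <- function(ref_envelope, width_um = 45,
                          acq = acq_params(), edge_exclude = 3L) {
  stopifnot(inherits(ref_envelope, "envelope_signal"))
  if (width_um < min_gate_width_um(acq) - 1e-9)
    stop(sprintf("gate width %.3g um is below the minimum of %.3g um",
                 width_um, min_gate_width_um(acq)))
  mag <- ref_envelope$magnitude
  n <- length(mag)
  lo <- edge_exclude + 1L
  hi <- n - edge_exclude
  if (lo >= hi) { lo <- 1L; hi <- n }
  k <- lo - 1L + which.max(mag[lo:hi])   # which.max takes the earliest tie
  # interpolated sample spacing in um
  spacing_um <- acq$sound_speed_m_s / ref_envelope$fs_hz * 1e6
  half <- max(1L, round(width_um / spacing_um / 2))
  start <- max(1L, k - half)
  end <- min(n + 1L, k + half + 1L)
  depth_um <- (k - 1L) * spacing_um
  depth_window(start, end, center_depth_um = depth_um, width_um = width_um)
}

#' Depth-gated intensity
#'
#' Trapezoidal area under the envelope magnitude over the half-open window
#' `[start, end)`, integrating the sample segments from `start` up to `end`
#' (clipped to the record), in raw sample units: sample spacing counts as
#' `1 / interp_factor` so the value does not grow with the interpolation
#' factor.  With this convention the intensities of two adjacent disjoint
#' windows sum exactly to the intensity of their union.
#'
#' @param env An `envelope_signal`.
#' @param w A [depth_window()].
#' @return Intensity in a.u.
#' @export
gated_intensity <- function(env, w) {
  stopifnot(inherits(env, "envelope_signal"), inherits(w, "depth_window"))
  n <- length(env$magnitude)
  if (w$start_sample > n || w$end_sample > n + 1L)
    stop("window exceeds the record")
  idx <- seq.int(w$start_sample, min(w$end_sample, n))
  if (length(idx) < 1) stop("empty window")
  m <- env$magnitude[idx]
  if (length(m) == 1) return(0)
  sum((m[-1] + m[-length(m)]) / 2) / env$interp_factor
}

#' Average transients
#'
#' Sample-wise mean of a list of equal-length, equal-rate transients; the
#' averaging counts accumulate.
#'
#' @param ts A list of [oa_transient()] objects.
#' @return An `oa_transient`.
#' @export
average_transients <- function(ts) {
  stopifnot(length(ts) >= 1, all(vapply(ts, inherits, TRUE, "oa_transient")))
  lens <- vapply(ts, function(t) length(t$samples), 1L)
  fss <- vapply(ts, function(t) t$fs_hz, 1)
  if (length(unique(lens)) != 1) stop("transients have mismatched lengths")
  if (length(unique(fss)) != 1) stop("transients have mismatched sampling rates")
  m <- rowMeans(vapply(ts, function(t) t$samples, numeric(lens[1])))
  oa_transient(m, fss[1],
               n_averaged = sum(vapply(ts, function(t) t$n_averaged, 1L)),
               interp_factor = ts[[1]]$interp_factor)
}
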