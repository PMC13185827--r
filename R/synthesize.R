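# Simulated MiROM acquisition: bipolar optoacoustic pulses with additive
# per-pulse Gaussian noise, averaged per pixel, plus a synthetic QCL
# reference emission profile.

# Axial pulse width: the Gaussian envelope FWHM is matched to the 42 um
# axial resolution of the instrument (FWHM in samples = 42 um / 7.5 um).
axial_fwhm_um <- 42

# Unit-amplitude bipolar pulse (Gaussian-modulated sinusoid at the
# transducer center frequency) arriving from depth_um; 0-based sample i is
# at time i / fs, one-way propagation (depth = t * c).
unit_pulse <- function(depth_um, acq = acq_params()) {
  n <- acq$record_len_samples
  t0 <- sample_of_depth(depth_um, acq)           # fractional sample index
  if (t0 > n - 1) stop(sprintf("depth %.1f um beyond the %d-sample record",
                               depth_um, n))
  i <- seq_len(n) - 1
  spacing_um <- acq$sound_speed_m_s / acq$fs_hz * 1e6
  sigma <- axial_fwhm_um / spacing_um / (2 * sqrt(2 * log(2)))
  f_rel <- acq$pulse_center_freq_hz / acq$fs_hz   # cycles per sample
  sin(2 * pi * f_rel * (i - t0)) * exp(-(i - t0)^2 / (2 * sigma^2))
}

#' Synthesize an averaged optoacoustic transient
#'
#' One pixel's A-line: a bipolar Gaussian-modulated sinusoid of amplitude
#' proportional to the absorption, centered at the sample index matching the
#' one-way arrival time `depth / c`, plus additive zero-mean Gaussian noise
#' on each of `pulses` single-shot records, returned as their mean.
#'
#' @param absorption Absorption strength (a.u.); scales the pulse.
#' @param depth_um Absorber depth in micrometers (within the record).
#' @param acq An [acq_params()] object.
#' @param noise_sd Additive noise SD per single pulse (a.u.).
#' @param pulses Number of pulses averaged (default from `acq`).
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return An [oa_transient()] with `n_averaged = pulses`.
#' @export
synthesize_transient <- function(absorption, depth_um, acq = acq_params(),
                                 noise_sd = 0, pulses = acq$pulses_per_pixel,
                                 seed = NULL) {
  clean <- absorption * unit_pulse(depth_um, acq)
  n <- length(clean)
  s <- with_seed(seed, {
    if (noise_sd > 0) {
      clean + rowMeans(matrix(stats::rnorm(n * pulses, 0, noise_sd),
                              n, pulses))
    } else clean
  })
  oa_transient(s, acq$fs_hz, n_averaged = pulses)
}

#' Synthetic QCL reference emission profile
#'
#' Smooth, strictly positive emission envelope of the excitation laser over
#' a wavenumber grid, as measured on a broadband carbon-tape absorber; the
#' divisor of the reference correction.  A sum of low-order cosines with
#' seeded random coefficients, passed through `exp()` so the profile stays
#' positive; `flat = TRUE` returns all ones.
#'
#' @param wavenumbers Nonempty wavenumber grid (cm^-1).
#' @param seed Integer seed for the envelope shape.
#' @param flat Return a constant unit envelope.
#' @return A [spectrum()] in state `"raw"`.
#' @export
reference_emission <- function(wavenumbers, seed = 0L, flat = FALSE) {
  if (length(wavenumbers) < 1) stop("wavenumber grid is empty")
  if (flat) return(spectrum(wavenumbers, rep(1, length(wavenumbers)),
                            state = "raw"))
  u <- seq(0, 1, length.out = length(wavenumbers))
  y <- with_seed(seed, {
    a <- stats::runif(4, -1, 1)
    ph <- stats::runif(4, 0, 2 * pi)
    z <- rep(0, length(u))
    for (k in 1:4) z <- z + a[k] * cos(2 * pi * k * u + ph[k]) / k
    exp(0.35 * z)
  })
  spectrum(wavenumbers, y, state = "raw")
}

# Depth-gated intensity of a unit-absorption, noiseless pulse through the
# standard gate (interpolation -> envelope -> window at the envelope peak).
# This is the scale factor linking template absorption values to gated
# image/spectrum intensities.
gated_unit_intensity <- function(acq = acq_params(), depth_um = 150,
                                 gate_width_um = 45, interp_factor = 4L) {
  t <- oa_transient(unit_pulse(depth_um, acq), acq$fs_hz)
  env <- envelope(interpolate_transient(t, interp_factor))
  w <- locate_window(env, gate_width_um, acq)
  gated_intensity(env, w)
}

#' Hyperspectral optoacoustic cube
#'
#' Container for a rendered raster scan: depth-gated and peak-to-peak (MAP)
#' intensity planes over `(y, x, wavenumber)`, the scan geometry, gating
#' provenance and (optionally) the raw transients.
#' @name hypercube
NULL

#' Render a hypercube from a phantom
#'
#' Simulates the full raster acquisition of a phantom: for every pixel and
#' wavenumber an averaged transient is synthesized (absorption = class
#' template value at that wavenumber), cubic-interpolated, enveloped, and
#' depth-gated through one intracellular window per field, centered on the
#' maximum-amplitude depth of the mean envelope of the reference
#' (2856 cm^-1 lipid) channel.  Averaged noise is drawn
#' directly as N(0, noise_sd / sqrt(pulses)) per sample, the exact
#' distribution of the mean of `pulses` single-shot noises.
#'
#' @param phantom A [generate_phantom()] result.
#' @param wavenumbers Wavenumbers to acquire; must lie on the canonical grid.
#' @param acq An [acq_params()] object.
#' @param keep_raw Keep the raw averaged transients (memory-hungry).
#' @param seed Integer seed for the acquisition noise.
#' @param gate_width_um Depth-gate width in micrometers.
#' @param interp_factor Cubic interpolation factor.
#' @param reference_wavenumber Channel used to locate the per-pixel gate.
#' @return An object of class `hypercube` with `gated` and `map` arrays of
#'   shape `(ny, nx, n_wavenumbers)`.
#' @export
render_hypercube <- function(phantom, wavenumbers = qsat_wavenumbers_10,
                             acq = acq_params(), keep_raw = FALSE,
                             seed = phantom$params$seed,
                             gate_width_um = 45, interp_factor = 4L,
                             reference_wavenumber = 2856) {
  stopifnot(inherits(phantom, "phantom"))
  grid <- canonical_wavenumbers()
  bad <- setdiff(wavenumbers, grid)
  if (length(bad))
    stop("wavenumbers not on the canonical grid: ",
         paste(bad, collapse = ", "))
  lab <- phantom$label_map
  ny <- nrow(lab); nx <- ncol(lab); npx <- ny * nx
  cls <- as.vector(lab)
  depth <- as.vector(phantom$depth_map)
  noise_sd <- phantom$params$noise_sd
  sd_avg <- noise_sd / sqrt(acq$pulses_per_pixel)
  templates <- phantom$params$class_templates %||% tissue_templates(grid)

  # absorption per pixel per wavenumber from the class templates
  wl_idx <- match(wavenumbers, grid)
  tmpl <- vapply(phantom_classes,
                 function(cl) templates[[cl]][wl_idx],
                 numeric(length(wl_idx)))
  tmpl <- matrix(tmpl, nrow = length(wl_idx))   # n_wn x n_class

  # pulses grouped by unique depth (usually one)
  u_depth <- unique(depth)
  pulse_by_depth <- lapply(u_depth, unit_pulse, acq = acq)
  n_rec <- acq$record_len_samples
  M <- interp_operator(n_rec, interp_factor)
  n_i <- nrow(M)

  env_of <- function(S) {
    E <- matrix(0, n_i, ncol(S))
    chunk <- 8192L
    for (j0 in seq(1L, ncol(S), by = chunk)) {
      j1 <- min(j0 + chunk - 1L, ncol(S))
      E[, j0:j1] <- analytic_envelope_matrix(M %*% S[, j0:j1])
    }
    E
  }

  gated_cols <- function(E, start, end) {
    # trapezoid over [start, end) per column, spacing 1/interp_factor
    out <- numeric(ncol(E))
    key <- paste(start, end)
    for (k in unique(key)) {
      jj <- which(key == k)
      s <- start[jj[1]]; e <- end[jj[1]]
      idx <- s:min(e, nrow(E))   # same convention as gated_intensity()
      block <- E[idx, jj, drop = FALSE]
      out[jj] <- (colSums(block) -
                    (block[1, ] + block[nrow(block), ]) / 2) / interp_factor
    }
    out
  }

  gated <- array(NA_real_, c(ny, nx, length(wavenumbers)))
  mapint <- array(NA_real_, c(ny, nx, length(wavenumbers)))
  raw <- if (keep_raw) vector("list", length(wavenumbers)) else NULL

  with_seed(seed, {
    ref_in_set <- reference_wavenumber %in% wavenumbers
    ref_tmpl_row <- match(reference_wavenumber, grid)
    # render the reference channel first to locate gates
    A_ref <- vapply(phantom_classes,
                    function(cl) templates[[cl]][ref_tmpl_row], 1)[cls]
    S <- matrix(0, n_rec, npx)
    for (di in seq_along(u_depth)) {
      sel <- depth == u_depth[di]
      S[, sel] <- outer(pulse_by_depth[[di]], A_ref[sel])
    }
    if (noise_sd > 0)
      S <- S + matrix(stats::rnorm(n_rec * npx, 0, sd_avg), n_rec, npx)
    E_ref <- env_of(S)
    # one intracellular window per field, centered on the maximum-amplitude
    # depth of the mean reference-channel envelope (robust for pixels whose
    # 2856 cm^-1 signal is near the noise floor)
    ref_env <- structure(list(magnitude = rowMeans(E_ref),
                              fs_hz = acq$fs_hz * interp_factor,
                              interp_factor = interp_factor, source = NULL),
                         class = "envelope_signal")
    w <- locate_window(ref_env, gate_width_um, acq)
    start <- rep(w$start_sample, npx)
    end <- rep(w$end_sample, npx)
    if (ref_in_set) {
      i_ref <- match(reference_wavenumber, wavenumbers)
      gated[, , i_ref] <- gated_cols(E_ref, start, end)
      mapint[, , i_ref] <- apply(S, 2, max) - apply(S, 2, min)
      if (keep_raw) raw[[i_ref]] <- S
    }
    for (i in seq_along(wavenumbers)) {
      if (ref_in_set && wavenumbers[i] == reference_wavenumber) next
      A <- tmpl[i, cls]
      S <- matrix(0, n_rec, npx)
      for (di in seq_along(u_depth)) {
        sel <- depth == u_depth[di]
        S[, sel] <- outer(pulse_by_depth[[di]], A[sel])
      }
      if (noise_sd > 0)
        S <- S + matrix(stats::rnorm(n_rec * npx, 0, sd_avg), n_rec, npx)
      E <- env_of(S)
      gated[, , i] <- gated_cols(E, start, end)
      mapint[, , i] <- apply(S, 2, max) - apply(S, 2, min)
      if (keep_raw) raw[[i]] <- S
    }
    invisible(NULL)
  })

  structure(list(
    gated = gated, map = mapint, wavenumbers = wavenumbers,
    step_um = phantom$params$step_um, acq = acq,
    gate = list(width_um = gate_width_um, interp_factor = interp_factor,
                reference_wavenumber = reference_wavenumber),
    raw = raw, phantom = phantom
  ), class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  cat(sprintf("<hypercube> %d x %d px, %d wavenumbers @ %g um step%s\n",
              dim(x$gated)[1], dim(x$gated)[2], dim(x$gated)[3], x$step_um,
              if (!is.null(x$raw)) " (raw-backed)" else ""))
  invisible(x)
}

#' Simulate localized adipocyte spectra
#'
#' Draws single-cell depth-gated spectra of one structure class over a
#' wavenumber grid: the class template scaled by a lognormal cell-to-cell
#' amplitude factor and the QCL emission profile, with additive gated-noise
#' reflecting `n_transients`-fold pulse averaging.  The gated scale factor
#' is the unit-pulse gated intensity of the standard signal path.
#'
#' @param class Structure class name.
#' @param n Number of spectra (cells).
#' @param wavenumbers Wavenumber grid.
#' @param reference The QCL [reference_emission()] spectrum on this grid.
#' @param noise_sd Single-pulse noise SD.
#' @param n_transients Number of averaged transients per wavenumber.
#' @param cell_cv Lognormal SD of the per-cell amplitude factor.
#' @param acq,gate_width_um,interp_factor Signal-path parameters.
#' @param seed Integer seed.
#' @return Matrix `n x length(wavenumbers)` of raw (uncorrected) spectra.
#' @export
simulate_spectra <- function(class, n, wavenumbers = canonical_wavenumbers(),
                             reference = reference_emission(wavenumbers),
                             noise_sd = 0.15, n_transients = 10000,
                             cell_cv = 0.1, acq = acq_params(),
                             gate_width_um = 45, interp_factor = 4L,
                             seed = 0L) {
  tmpl <- class_template(class, wavenumbers)
  K <- gated_unit_intensity(acq, 150, gate_width_um, interp_factor)
  sd_gate <- gated_noise_sd(noise_sd / sqrt(n_transients), acq,
                            gate_width_um, interp_factor)
  with_seed(seed, {
    amp <- exp(stats::rnorm(n, 0, cell_cv))
    X <- outer(amp, tmpl * reference$intensities * K)
    X + matrix(stats::rnorm(n * length(tmpl), 0, sd_gate), n)
  })
}

# Empirical SD of the gated intensity of pure averaged noise at the standard
# gate; memoised per parameter set (Monte-Carlo, fixed internal seed).
gated_noise_cache <- new.env(parent = emptyenv())
gated_noise_sd <- function(sd_avg, acq = acq_params(), gate_width_um = 45,
                           interp_factor = 4L, n_mc = 400L) {
  if (sd_avg == 0) return(0)
  key <- paste(signif(sd_avg, 6), acq$record_len_samples, gate_width_um,
               interp_factor, sep = "|")
  if (!is.null(gated_noise_cache[[key]])) return(gated_noise_cache[[key]])
  val <- with_seed(987654L, {
    n <- acq$record_len_samples
    M <- interp_operator(n, interp_factor)
    S <- matrix(stats::rnorm(n * n_mc, 0, sd_avg), n, n_mc)
    E <- analytic_envelope_matrix(M %*% S)
    # gate at a fixed interior position (signal-dominated pixels have their
    # gate pinned by the pulse, so noise enters at a fixed window)
    spacing_um <- acq$sound_speed_m_s / (acq$fs_hz * interp_factor) * 1e6
    half <- max(1L, round(gate_width_um / spacing_um / 2))
    k <- round(nrow(E) / 2)
    idx <- (k - half):(k + half)
    vals <- (colSums(E[idx, , drop = FALSE]) -
               (E[idx[1], ] + E[idx[length(idx)], ]) / 2) / interp_factor
    stats::sd(vals)
  })
  gated_noise_cache[[key]] <- val
  val
}
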