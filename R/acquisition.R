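#' Acquisition parameters for a MiROM scan
#'
#' Bundles the fixed instrument constants used throughout the pipeline: the
#' DAQ sampling rate, laser pulse repetition rate, number of averaged pulses
#' per pixel, the assumed speed of sound in soft tissue, the transducer
#' center frequency, the transient record length and the per-wavenumber
#' frame time for a 1 x 1 mm^2, 5 um-step raster.
#'
#' @param fs_hz Sampling rate of the digitizer in Hz.
#' @param prf_hz Pulse repetition rate of the excitation laser in Hz.
#' @param pulses_per_pixel Number of transients averaged per pixel.
#' @param sound_speed_m_s Assumed acoustic speed in soft tissue (m/s).
#' @param pulse_center_freq_hz Transducer band center frequency in Hz.
#' @param record_len_samples Length of one recorded transient in raw samples.
#' @param frame_time_min_per_wavenumber Minutes to raster one wavenumber
#'   frame (1 x 1 mm^2 field at 5 um step).
#' @return An object of class `acq_params`.
#' @export
acq_params <- function(fs_hz = 200e6,
                       prf_hz = 100e3,
                       pulses_per_pixel = 50,
                       sound_speed_m_s = 1500,
                       pulse_center_freq_hz = 20e6,
                       record_len_samples = 64,
                       frame_time_min_per_wavenumber = 8) {
  vals <- c(fs_hz, prf_hz, pulses_per_pixel, sound_speed_m_s,
            pulse_center_freq_hz, record_len_samples,
            frame_time_min_per_wavenumber)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all acquisition parameters must be positive and finite")
  structure(list(
    fs_hz = fs_hz, prf_hz = prf_hz,
    pulses_per_pixel = as.integer(pulses_per_pixel),
    sound_speed_m_s = sound_speed_m_s,
    pulse_center_freq_hz = pulse_center_freq_hz,
    record_len_samples = as.integer(record_len_samples),
    frame_time_min_per_wavenumber = frame_time_min_per_wavenumber
  ), class = "acq_params")
}

#' Depth corresponding to a raw sample index
#'
#' One-way conversion: the absorber emits toward the transducer, so depth is
#' arrival time times sound speed, `index * c / fs`.  At the defaults
#' (200 MS/s, 1500 m/s) one sampling interval is 7.5 um.
#'
#' @param index Raw (non-interpolated) sample index, 0-based; may be a vector.
#' @param acq An [acq_params()] object.
#' @return Depth in micrometers.
#' @export
depth_of_sample <- function(index, acq = acq_params()) {
  if (any(index < 0)) stop("sample index must be >= 0")
  index * acq$sound_speed_m_s / acq$fs_hz * 1e6
}

#' Raw sample index corresponding to a depth
#'
#' Inverse of [depth_of_sample()]; fractional indices are returned as-is.
#'
#' @param depth_um Depth in micrometers.
#' @param acq An [acq_params()] object.
#' @return 0-based (possibly fractional) raw sample index.
#' @export
sample_of_depth <- function(depth_um, acq = acq_params()) {
  if (any(depth_um < 0)) stop("depth must be >= 0")
  depth_um * 1e-6 * acq$fs_hz / acq$sound_speed_m_s
}

#' Pixel acquisition time
#'
#' Time to fire `pulses` laser pulses at the repetition rate: `pulses / prf`.
#' 50 pulses at 100 kHz give 500 us.
#'
#' @param pulses Number of pulses averaged at one pixel (>= 1).
#' @param acq An [acq_params()] object.
#' @return Seconds.
#' @export
pixel_time <- function(pulses, acq = acq_params()) {
  if (any(pulses < 1)) stop("pulses must be >= 1")
  pulses / acq$prf_hz
}

#' Hyperspectral acquisition time
#'
#' Raster time for `n_wavenumbers` frames at the per-wavenumber frame time;
#' with the 8 min default, 10 wavenumbers take 80 min and a full 502-frame
#' sweep about 67 h.
#'
#' @param n_wavenumbers Number of wavenumber frames (>= 1).
#' @param acq An [acq_params()] object.
#' @return Minutes.
#' @export
acquisition_time <- function(n_wavenumbers, acq = acq_params()) {
  if (any(n_wavenumbers < 1)) stop("n_wavenumbers must be >= 1")
  n_wavenumbers * acq$frame_time_min_per_wavenumber
}

#' Canonical QCL wavenumber grid
#'
#' Union of the two tuning ranges 2932 -> 2770 and 1738 -> 910 cm^-1 at a
#' 2 cm^-1 step, stored descending (acquisition order); 497 points.
#'
#' @param step Grid step in cm^-1.
#' @return Numeric vector of wavenumbers in cm^-1, descending.
#' @export
canonical_wavenumbers <- function(step = 2) {
  c(seq(2932, 2770, by = -step), seq(1738, 910, by = -step))
}

# The 10 wavenumbers used by the reduced Q-SAT feature set, and the two
# 2-wavenumber variants studied as fast alternatives.
#' Q-SAT reduced wavenumber sets
#'
#' `qsat_wavenumbers_10` is the 10-feature set used by the pixel scorer;
#' `qsat_wavenumber_pairs` the two 2-feature variants.
#' @format Numeric vector / list of numeric pairs (cm^-1).
#' @export
qsat_wavenumbers_10 <- c(2856, 1632, 1550, 1454, 1376, 1238, 1134, 1086,
                         1046, 990)

#' @rdname qsat_wavenumbers_10
#' @export
qsat_wavenumber_pairs <- list(c(990, 1238), c(1550, 2856))
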