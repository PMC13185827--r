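# Spectrum-level processing: carbon-reference correction, band areas,
# vector normalization, standardization, PCA, KDE and correlation.

spectrum_states <- c("raw", "corrected", "l2_normalized", "standardized")

#' Optoacoustic spectrum
#'
#' Intensity over a wavenumber grid with an explicit processing-state flag,
#' so that downstream operations can insist on the preprocessing they need.
#'
#' @param wavenumbers Strictly monotone wavenumber grid (cm^-1); the
#'   acquisition order (descending) is kept as given.
#' @param intensities Intensities (a.u.), same length as the grid.
#' @param state One of `"raw"`, `"corrected"`, `"l2_normalized"`,
#'   `"standardized"`.
#' @param n_transients Averaging count behind each intensity (default 10000,
#'   the localized single-cell acquisition).
#' @return An object of class `spectrum`.
#' @export
spectrum <- function(wavenumbers, intensities, state = "raw",
                     n_transients = 10000L) {
  state <- match.arg(state, spectrum_states)
  if (length(wavenumbers) != length(intensities))
    stop("grid and intensities differ in length")
  d <- diff(wavenumbers)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    stop("wavenumber grid must be strictly monotone")
  if (state == "l2_normalized" &&
      abs(sum(intensities^2) - 1) > 1e-9)
    stop("l2_normalized spectrum must have unit sum of squares")
  structure(list(wavenumbers = as.numeric(wavenumbers),
                 intensities = as.numeric(intensities),
                 state = state, n_transients = as.integer(n_transients)),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d points, %g..%g cm^-1 (%s)\n",
              length(x$wavenumbers), x$wavenumbers[1],
              x$wavenumbers[length(x$wavenumbers)], x$state))
  invisible(x)
}

#' Carbon-reference correction
#'
#' Divides a sample spectrum (depth-selective intensity) element-wise by the
#' reference emission profile (peak-to-peak intensity of the carbon-tape
#' absorber), canceling the wavelength-dependent laser output.
#'
#' @param sample Raw [spectrum()].
#' @param reference Reference [spectrum()] on the identical grid, strictly
#'   positive.
#' @return A `spectrum` in state `"corrected"`.
#' @export
reference_correct <- function(sample, reference) {
  stopifnot(inherits(sample, "spectrum"), inherits(reference, "spectrum"))
  if (!isTRUE(all.equal(sample$wavenumbers, reference$wavenumbers)))
    stop("sample and reference grids differ")
  if (any(reference$intensities <= 0))
    stop("reference emission must be strictly positive everywhere")
  spectrum(sample$wavenumbers, sample$intensities / reference$intensities,
           state = "corrected", n_transients = sample$n_transients)
}

#' Band area under the curve
#'
#' Trapezoidal area of intensity versus wavenumber over a closed band
#' `[lo, hi]`.  Band endpoints are snapped to the nearest grid points (with
#' a warning when not exact).
#'
#' @param s A [spectrum()].
#' @param band Numeric `c(lo, hi)` in cm^-1, within the grid span.
#' @return Area in a.u. * cm^-1 (nonnegative orientation).
#' @export
band_auc <- function(s, band) {
  stopifnot(inherits(s, "spectrum"), length(band) == 2)
  band <- sort(band)
  wn <- s$wavenumbers
  if (band[1] < min(wn) - 1e-9 || band[2] > max(wn) + 1e-9)
    stop("band lies outside the spectral grid")
  snap <- function(target) {
    i <- which.min(abs(wn - target))
    if (abs(wn[i] - target) > 1e-9)
      warning(sprintf("band endpoint %g snapped to grid point %g",
                      target, wn[i]))
    i
  }
  i1 <- snap(band[1]); i2 <- snap(band[2])
  idx <- seq(min(i1, i2), max(i1, i2))
  x <- wn[idx]; y <- s$intensities[idx]
  o <- order(x)
  x <- x[o]; y <- y[o]
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

#' L2 vector normalization
#'
#' Divides the spectrum by its L2 norm so only the spectral shape remains;
#' removes global intensity drifts.
#'
#' @param s A [spectrum()] with nonzero norm.
#' @return A `spectrum` in state `"l2_normalized"`.
#' @export
l2_normalize <- function(s) {
  stopifnot(inherits(s, "spectrum"))
  nrm <- sqrt(sum(s$intensities^2))
  if (nrm == 0) stop("cannot normalize an all-zero spectrum")
  spectrum(s$wavenumbers, s$intensities / nrm, state = "l2_normalized",
           n_transients = s$n_transients)
}

# L2-normalize the rows of a plain feature matrix
l2_normalize_rows <- function(X) {
  nrm <- sqrt(rowSums(X^2))
  if (any(nrm == 0)) stop("cannot normalize an all-zero feature row")
  X / nrm
}

#' Feature standardization
#'
#' Per-wavenumber standardization `(I - mu) / sigma` with population SD
#' (denominator n).  In fit mode the statistics are estimated from the
#' given collection and returned; in apply mode the training statistics are
#' reused unchanged for unseen data.
#'
#' @param X Matrix of spectra, rows = observations, columns = wavenumbers
#'   (column names carry the wavenumbers when available).
#' @param stats `NULL` to fit on `X`, or a `standardizer_stats` object from
#'   a previous fit.
#' @return A list with `X` (transformed matrix) and `stats`
#'   (`standardizer_stats`: fields `mean`, `sd`).
#' @export
standardize <- function(X, stats = NULL) {
  X <- as.matrix(X)
  if (is.null(stats)) {
    mu <- colMeans(X)
    sdv <- sqrt(colMeans(sweep(X, 2, mu)^2))   # population SD
    zero <- sdv == 0
    if (any(zero)) {
      nm <- colnames(X)[zero] %||% which(zero)
      stop("zero-variance feature(s) in fit: ",
           paste(nm, collapse = ", "))
    }
    stats <- structure(list(mean = mu, sd = sdv),
                       class = "standardizer_stats")
  }
  if (any(stats$sd <= 0)) stop("standardizer has non-positive SDs")
  Z <- sweep(sweep(X, 2, stats$mean), 2, stats$sd, "/")
  list(X = Z, stats = stats)
}

#' Principal component analysis of spectra
#'
#' Centered PCA of a collection of (typically L2-normalized) spectra, with a
#' fixed sign convention: each loading's largest-magnitude coefficient is
#' positive.
#'
#' @param X Matrix of spectra, rows = observations.
#' @param k Number of components (at most the matrix rank).
#' @return A list of class `pca_model`: `loadings` (columns = components),
#'   `explained` (variance fractions), `center`, `scores` (n x k).
#' @export
pca_fit_project <- function(X, k = 2L) {
  X <- as.matrix(X)
  if (nrow(X) < k + 1) stop("need at least k + 1 spectra")
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  rank <- sum(p$sdev > max(p$sdev) * 1e-12)
  if (k > rank) stop(sprintf("k = %d exceeds the data rank %d", k, rank))
  L <- p$rotation[, seq_len(k), drop = FALSE]
  S <- p$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) { L[, j] <- -L[, j]; S[, j] <- -S[, j] }
  }
  structure(list(loadings = L,
                 explained = p$sdev^2 / sum(p$sdev^2),
                 center = p$center, scores = S),
            class = "pca_model")
}

#' Gaussian kernel density estimate
#'
#' KDE of a set of scores (e.g. PC1 projections) with Silverman's
#' rule-of-thumb bandwidth by default.  Kernels are evaluated exactly (no
#' binning) on a grid extending 6 bandwidths past the data, so the curve
#' integrates to 1 up to the ~1e-9 kernel tail mass.
#'
#' @param values Numeric vector, length >= 2.
#' @param bandwidth `"silverman"` or a positive number.
#' @param n Number of evaluation points.
#' @return A `data.frame` with columns `x` and `density`.
#' @export
kde_curve <- function(values, bandwidth = "silverman", n = 1024L) {
  if (length(values) < 2) stop("need at least 2 values")
  if (identical(bandwidth, "silverman")) {
    if (stats::sd(values) == 0)
      stop("all values equal: rule-based bandwidth undefined")
    bw <- stats::bw.nrd0(values)
  } else {
    bw <- as.numeric(bandwidth)
    if (!is.finite(bw) || bw <= 0) stop("bandwidth must be positive")
  }
  x <- seq(min(values) - 6 * bw, max(values) + 6 * bw, length.out = n)
  dens <- rowMeans(outer(x, values, function(a, b) stats::dnorm(a, b, bw)))
  data.frame(x = x, density = dens)
}

#' Pearson correlation
#'
#' Sample Pearson correlation coefficient between two equal-length vectors.
#'
#' @param x,y Numeric vectors, length >= 3, nonzero variance.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) < 3) stop("need at least 3 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(x, y, method = "pearson")
}
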