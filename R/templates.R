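# Class spectral templates for the tissue-phantom generator.
#
# Each structure class is a sum of Gaussian vibrational bands (center cm^-1,
# height a.u., sigma cm^-1) plus an optional flat baseline, evaluated on the
# canonical grid.  Heights are in units where the eWAT adipocyte CH2 peak at
# 2856 cm^-1 equals 1.  Adipocyte band amplitudes are calibrated so that the
# digitally isolated contrast ratios and band-area ratios reproduce the
# relations measured on real tissue: eWAT/iBAT = 1.7 at 2856 cm^-1,
# iBAT/eWAT = 3.4 at 1550 cm^-1, amide-band (1700-1500 cm^-1) mean-spectrum
# AUC ratio iBAT/eWAT = 2.8, and roughly 2x higher CH2- and CO-region areas
# for eWAT.  Non-adipocyte classes (ECM, lymph node, connective tissue,
# water, void) carry plausible protein / nucleic-acid / water signatures and
# are shaped to stay distinguishable even when only two wavenumbers
# (990, 1238) or (1550, 2856) are acquired.

phantom_classes <- c("WAT_adipocyte", "BAT_adipocyte", "ECM", "lymph_node",
                     "connective", "water", "void")

# height of the eWAT amide II band; the iBAT one is 3.4x by calibration
.h_w1550 <- 0.105
# iBAT amide I height; calibrated so the 1700-1500 cm^-1 AUC ratio is 2.8
.h_b1652 <- 0.52589

template_bands <- function() {
  b <- function(center, height, sigma) cbind(center, height, sigma)
  list(
    WAT_adipocyte = rbind(
      b(2920, 0.75, 18), b(2856, 1.00, 14),          # CH2 stretches
      b(1740, 0.50, 16),                             # ester C=O
      b(1650, 0.30, 14),                             # C=C (narrow)
      b(1550, .h_w1550, 12),                         # weak amide II
      b(1460, 0.30, 14), b(1376, 0.16, 12),          # CH2/CH3 bending
      b(1238, 0.055, 12), b(1160, 0.30, 16),
      b(1116, 0.45, 12), b(1086, 0.30, 12),          # C-O
      b(990, 0.192, 14)),
    BAT_adipocyte = rbind(
      b(2920, 0.28, 16), b(2856, 1 / 1.7, 13),
      b(1740, 0.22, 16),
      b(1652, .h_b1652, 20),                         # amide I
      b(1550, 3.4 * .h_w1550, 14),                   # amide II
      b(1460, 0.20, 14), b(1376, 0.11, 12),
      b(1238, 0.199, 14),
      b(1116, 0.22, 12), b(1086, 0.18, 12),
      b(990, 0.021, 12)),
    ECM = rbind(
      b(2920, 0.10, 18), b(2856, 0.139, 14),
      b(1652, 0.48, 18), b(1550, 0.428, 14),
      b(1454, 0.22, 14), b(1238, 0.284, 14),         # amide III
      b(1086, 0.10, 12), b(1030, 0.15, 14),
      b(990, 0.098, 12)),
    lymph_node = rbind(
      b(2920, 0.18, 16), b(2856, 0.218, 14),
      b(1740, 0.10, 14), b(1652, 0.40, 18),
      b(1550, 0.335, 14), b(1454, 0.18, 14),
      b(1238, 0.145, 12), b(1116, 0.15, 12),
      b(1086, 0.26, 12),                             # PO2- symmetric
      b(990, 0.262, 12)),                            # ribose-phosphate
    connective = rbind(
      b(2920, 0.08, 16), b(2856, 0.087, 14),
      b(1660, 0.52, 18), b(1550, 0.494, 14),
      b(1454, 0.26, 14), b(1238, 0.382, 14),
      b(1046, 0.30, 14), b(990, 0.238, 12)),
    water = rbind(
      b(1640, 0.50, 60),                             # bending
      b(909, 0.35, 120)),                            # libration tail
    void = NULL)
}

template_baselines <- c(WAT_adipocyte = 0, BAT_adipocyte = 0, ECM = 0,
                        lymph_node = 0, connective = 0, water = 0.01,
                        void = 0.057)

#' Evaluate a class template spectrum
#'
#' Sum-of-Gaussian-band model spectrum of one phantom structure class on an
#' arbitrary wavenumber grid.
#'
#' @param class One of `"WAT_adipocyte"`, `"BAT_adipocyte"`, `"ECM"`,
#'   `"lymph_node"`, `"connective"`, `"water"`, `"void"`.
#' @param wavenumbers Wavenumber grid in cm^-1.
#' @return Numeric vector of template intensities (a.u.).
#' @export
class_template <- function(class, wavenumbers = canonical_wavenumbers()) {
  class <- match.arg(class, phantom_classes)
  bands <- template_bands()[[class]]
  y <- rep(template_baselines[[class]], length(wavenumbers))
  if (!is.null(bands)) {
    for (i in seq_len(nrow(bands))) {
      y <- y + bands[i, "height"] *
        exp(-(wavenumbers - bands[i, "center"])^2 / (2 * bands[i, "sigma"]^2))
    }
  }
  y
}

#' Template spectra for all structure classes
#'
#' @param wavenumbers Wavenumber grid in cm^-1.
#' @return Named list mapping class to its template spectrum.
#' @export
tissue_templates <- function(wavenumbers = canonical_wavenumbers()) {
  stats::setNames(lapply(phantom_classes, class_template,
                         wavenumbers = wavenumbers), phantom_classes)
}
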