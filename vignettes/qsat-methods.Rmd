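---
title: "Depth-gated optoacoustic micrographs and Q-SAT digital scoring: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-gated optoacoustic micrographs and Q-SAT digital scoring: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement model

Mid-infrared optoacoustic microscopy (MiROM) excites tissue with a pulsed
quantum cascade laser and records the resulting ultrasound transient (the
A-line) with a focused transducer.  Because sound arrives later from deeper
absorbers, the arrival time of the pressure pulse encodes depth: at the
instrument constants used throughout (200 MS/s digitization, 1500 m/s sound
speed in soft tissue, one-way propagation toward the transducer) a single
raw sampling interval corresponds to 7.5 µm of depth.  `qsat` implements
this chain explicitly:

* `interpolate_transient()` — cubic-spline resampling of the A-line
  (default factor 4; the interpolation factor is not dictated by the
  measurement and is exposed as configuration),
* `envelope()` — the magnitude of the analytic signal, computed by the
  standard frequency-domain quadrature construction,
* `locate_window()` / `gated_intensity()` — a depth window centered on the
  maximum-amplitude depth of the 2856 cm⁻¹ (lipid CH₂) reference channel,
  and the trapezoidal area of the envelope over that window.

The depth-gated intensity of the lipid channel is the quantitative
per-pixel signal everywhere in the package.  Two post-processing steps,
min–max normalized squared intensity (`noas_squared()`) and CLAHE
(`clahe_micrograph()`), exist for display only; every quantitative
operation refuses images carrying those intensity kinds.

Numerical conventions worth stating once:

* The gate integrates the half-open window *[start, end)* by trapezoid
  with sample spacing 1/interp_factor, clipped to the record; adjacent
  disjoint windows therefore sum exactly to the gate over their union.
* Envelope argmax searches exclude three samples at each record edge,
  where the discrete Hilbert transform is unreliable.
* Ties in the argmax resolve to the earliest (shallowest) sample.
* The default gate width is 45 µm — six raw samples, on the order of the
  42 µm axial resolution of the instrument; the minimum admissible width
  is one raw sample (7.5 µm).
* One window is located per field (from the mean reference-channel
  envelope), not per pixel.  A per-pixel argmax fails for structures that
  are dark at 2856 cm⁻¹ (water, void): their gate would lock onto noise
  peaks at arbitrary depths and the extracted features would be
  meaningless.  A single intracellular window per field matches how a
  depth range of interest is selected in practice and behaves identically
  for bright pixels.

# The synthetic tissue phantom

No instrument data ships with the package; instead `generate_phantom()` and
`render_hypercube()` produce ground-truthed inputs for every stage.

**Geometry.** Adipocytes are non-overlapping disks with diameters drawn
from tissue-specific normal distributions — eWAT 50 ± 15 µm, iBAT
16 ± 6 µm, truncated below at 6 µm (a minimal lipid droplet; the
truncation keeps rasterization meaningful at a 5 µm step).  The full
diameter list is drawn *before* placement and cells are placed largest
first with per-cell retries, so the placed population follows the
requested distribution exactly (naive dart throwing would preferentially
reject large cells and bias the sizes low).  Cells keep a minimum ECM gap
of 1.5 pixels; with 8-connected labeling a 1-pixel gap would still allow
diagonal pixel adjacency across the gap (7.07 µm > 5 µm) and merge
neighboring cells.

**Densities.** Absolute adipocyte densities are not published for these
tissues; the defaults (eWAT 82 /mm², iBAT 697 /mm²) were fixed once at the
measured 8.5× iBAT:eWAT density relation while staying safely below the
jamming limit of gap-separated random disk packing, so phantom generation
succeeds for any seed.

**Spectra.** Each structure class (WAT adipocyte, BAT adipocyte, ECM,
lymph node, connective tissue, water, void) carries a template spectrum
built from Gaussian vibrational bands (CH₂ 2856/2920, ester C=O 1740,
amide I ~1650, amide II 1550, CH bending 1454/1376, amide III 1238, C–O
1160–1086, and low-wavenumber bands near 1046/990 cm⁻¹).  Absolute band
amplitudes are not recoverable from published data — only ratios are — so
the adipocyte templates are calibrated so that the *pipeline outputs*
reproduce the measured relations: eWAT 1.7× brighter than iBAT at
2856 cm⁻¹, iBAT 3.4× brighter at 1550 cm⁻¹, a 2.8× iBAT:eWAT amide-band
(1700–1500 cm⁻¹) area ratio, and roughly 2× CH₂- and CO-region areas for
eWAT.  Non-adipocyte templates are plausible protein / nucleic-acid /
water signatures, shaped so all seven classes remain distinguishable even
when only two wavenumbers are acquired.  Water carries its 1640 cm⁻¹
bending band and a libration tail rising toward 909 cm⁻¹; void (bare
dish) a weak flat response.

**Acquisition.** A pixel's transient is a Gaussian-modulated sinusoid at
the 20 MHz transducer center frequency, envelope FWHM matched to the 42 µm
axial resolution, amplitude proportional to the class template value at
the acquired wavenumber, arriving from 150 µm depth, plus zero-mean
Gaussian noise per pulse, averaged over 50 pulses.  The default
single-pulse noise SD (0.15 of the eWAT CH₂ peak) corresponds to a
single-shot SNR of ~7 — a level at which the instrument's 50-fold pulse
averaging is actually necessary, as it is in practice.
`render_hypercube()` draws the averaged noise directly from its exact
distribution N(0, σ/√50) per sample; `synthesize_transient()` performs the
literal 50-pulse average, and the two are verified equivalent.  Localized
single-cell spectra (`simulate_spectra()`) emulate 10 000-transient
averaging with a 10 % lognormal cell-to-cell amplitude factor, times a
smooth seeded QCL emission profile that the carbon-reference correction
must cancel.

**What the phantom does not emulate.** No acoustic wave equation, no
transducer focusing, no depth-dependent attenuation, no mid-IR water
attenuation, no partial-volume mixing at cell boundaries, and real
adipose tissue is wall-to-wall adipocytes whereas gapped packing caps
coverage near 20 %.  Passing recovery tests therefore demonstrates that
the *processing* is correct and unbiased under controlled conditions, not
that the instrument model is complete.

# Segmentation and morphometry

Masks threshold the 2856 cm⁻¹ micrograph at the first quartile (linear
interpolation between order statistics, `stats::quantile` type 7) of an
iBAT calibration image.  That rule presumes adipocytes dominate the
calibration field — true in real brown fat, but unreachable by gapped
disk packing at a 5 µm step (the gap alone caps coverage near 25 % for
16 µm cells).  The calibration reference is therefore generated in a
*dense* packing mode (overlapping darts to ~80 % coverage); it is used
only for its intensity histogram, never for morphometry.  With a quarter
of the calibration pixels below threshold, the threshold lands just below
the iBAT adipocyte intensity mode: all eWAT cell pixels (1.7× brighter)
pass, ~94 % of iBAT cell pixels pass, and ECM (≈0.14 of the eWAT cell
level, ~45 noise SDs below threshold) is excluded essentially everywhere.

Components are labeled 8-connected; components smaller than the area of a
5 µm disk are discarded as speckle; equivalent diameter is 2·√(area/π);
density is surviving count over FOV area.  Touching cells are not split
(phantoms guarantee gaps); a watershed step would only matter for real
data and is deliberately out of scope.

# Spectral processing and scoring

Spectra move through carbon-reference correction (depth-gated sample
intensity divided by the *peak-to-peak* reference intensity — the stated
asymmetry of the acquisition), L2 normalization (shape only, gain
removed), and standardization `(I − μ)/σ` with statistics always taken
from the training set.  The population SD (denominator n) is used; the
formula itself fixes no convention, and fixing one keeps worked examples
deterministic.  PCA operates on L2-normalized spectra (whether the
published scatter used standardized features is not stated; a switch
covers both), with the sign convention that each loading's
largest-magnitude coefficient is positive.

Both scorers are ridge-penalized logistic models fit by `glmnet`
(`alpha = 0`, penalty `reg/n` with `reg = 1` — the weakly-informative
unit-strength default; the fit is deterministic, the stored seed only
governs callers that subsample).  The multiclass pixel scorer is a single
multinomial softmax over all structure classes rather than one-vs-rest,
so pixel probabilities cohere (sum to one) by construction.  Features for
the pixel scorer are the per-pixel intensities at the 10 scoring
wavenumbers (2856, 1632, 1550, 1454, 1376, 1238, 1134, 1086, 1046,
990 cm⁻¹), L2-normalized per pixel over those features.  The published
selection procedure for that set is not fully specified;
`select_wavenumbers()` defaults to the printed constants and offers a
reproducible PCA-loading heuristic (components weighted by explained
variance × class-separation F statistic, greedy top-k with 20 cm⁻¹
minimum spacing) as the documented alternative.

Normalized tissue scores are
`S_WAT = ΣWAT(x,y) / Σ(WAT(x,y) + BAT(x,y))` and its BAT counterpart —
the second published formula is typeset with the same label as the first
but its numerator (ΣBAT) makes the intent unambiguous.  The sums run over
all pixels without masking: non-adipocyte probability mass cancels in the
ratio, and S_WAT + S_BAT = 1 identically.  Tile heterogeneity partitions
the map into a 10×10 grid (remainder pixels to the last row/column),
computes the normalized scores per tile, and reports the coefficient of
variation (population SD over mean) of the tile scores.

Feature attributions use the exact closed form of Shapley values for
linear models — `w_i (x_i − mean(x_i))` in margin space against the
supplied background — so local accuracy holds to machine precision and no
sampling approximation is involved.  ROC AUCs are midrank Mann–Whitney
statistics.

# Validation harnesses and problem sizes

The package validates itself end-to-end on phantom studies sized to run
comfortably on a single CPU:

* `morphometry_study()` — 5 eWAT + 5 iBAT phantoms, 1×1 mm² at 5 µm
  (200×200 pixels), two wavenumbers each, one dense calibration field;
  recovers the 3.1× diameter and 8.5× density ratios and the 1.7×/3.4×
  isolated contrasts (~1 min).
* `spectral_band_study()` — 200 simulated single-cell spectra per tissue
  over the full 497-point grid; recovers the 2.8× amide-band area ratio.
* `classifier_study()` — pixel features from one eWAT, one iBAT and one
  iWAT phantom (≥500 pixels per class after balancing to 1000), 70/30
  split, models for the 10-wavenumber set and both 2-wavenumber variants;
  held-out macro one-vs-rest AUC ≥ 0.95 for all three, ~0.99+ for the
  10-wavenumber model (~1 min).
* `week_series_study()` — iWAT phantoms for postnatal weeks 2–6 at BAT-like
  mixing fractions 0.15/0.45/0.80/0.50/0.20 (monotone browning weeks 2→4,
  whitening 4→6; the fractions themselves are generator conventions, not
  published values), three seeded replicates, 500×500 µm fields; S_BAT
  rises then falls in every replicate.  The scored fields contain
  adipocytes and ECM only — the extra structure classes exist for
  training the scorer, and at 500 µm they would crowd out the cells.

# Known limitations

* The published wavenumber count (502) cannot be reconciled with the
  stated tuning ranges and 2 cm⁻¹ step, which give 497 points; the grid
  length is configurable and 497 is the default.  Timing arithmetic uses
  whatever count is requested.
* iWAT week mixing fractions and absolute class amplitudes are package
  conventions (only trends and ratios are published).
* The 2-wavenumber scorers sit just above the 0.95 AUC floor by design of
  the class templates; on real tissue their margin would depend on
  biochemistry the phantom only sketches.
* Hypercubes are stored as long-format CSV with hex-float intensities
  plus a YAML sidecar rather than a binary container; bit-exact and
  inspectable, but not compact for very large scans.
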