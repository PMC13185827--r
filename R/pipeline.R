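# High-level analysis harnesses composing the modules into the standard
# phantom -> signal -> segmentation -> scoring workflows, plus the `qsat`
# command-line pipeline.

#' iBAT calibration micrograph
#'
#' Renders the 2856 cm^-1 depth-gated micrograph of a dense (near-confluent)
#' iBAT reference phantom.  Its 25% intensity quantile is the segmentation
#' threshold; the dense packing emulates the adipocyte-dominated fields of
#' real brown fat on which the quantile rule is calibrated.
#'
#' @param seed Integer seed.
#' @param acq An [acq_params()] object.
#' @param fov_um,step_um Calibration field geometry.
#' @return A depth-gated [micrograph()] at 2856 cm^-1.
#' @export
ibat_reference_micrograph <- function(seed = 1000L, acq = acq_params(),
                                      fov_um = c(1000, 1000), step_um = 5) {
  ph <- generate_phantom(phantom_params("iBAT", packing = "dense",
                                        fov_um = fov_um, step_um = step_um,
                                        seed = seed))
  assemble_micrograph(render_hypercube(ph, 2856, acq = acq, seed = seed),
                      2856)
}

#' Morphometry and contrast recovery study
#'
#' Full parameter-recovery harness: generates eWAT and iBAT phantoms at the
#' tissue defaults for a set of seeds, renders the 2856 and 1550 cm^-1
#' depth-gated channels, segments with the 25%-quantile iBAT calibration
#' threshold, sizes the cells, and pools per-cell equivalent diameters,
#' densities and digitally isolated contrasts per tissue.
#'
#' @param seeds Integer vector of phantom seeds.
#' @param calibration_seed Seed of the dense calibration phantom.
#' @param acq An [acq_params()] object.
#' @return A list: per-tissue pooled vectors and the derived ratios
#'   (`diameter_ratio` eWAT:iBAT, `density_ratio` iBAT:eWAT,
#'   `contrast_ratio_2856` eWAT:iBAT, `contrast_ratio_1550` iBAT:eWAT).
#' @export
morphometry_study <- function(seeds = 0:4, calibration_seed = 1000L,
                              acq = acq_params()) {
  cal <- ibat_reference_micrograph(calibration_seed, acq)
  thr <- stats::quantile(cal$image, 0.25, names = FALSE)
  out <- list(eWAT = NULL, iBAT = NULL)
  for (tt in c("eWAT", "iBAT")) {
    diam <- dens <- c2856 <- c1550 <- numeric(0)
    for (s in seeds) {
      ph <- generate_phantom(phantom_params(tt, seed = s))
      cube <- render_hypercube(ph, c(2856, 1550), acq = acq, seed = s)
      m2856 <- assemble_micrograph(cube, 2856)
      m1550 <- assemble_micrograph(cube, 1550)
      mask <- adipocyte_mask(m2856, threshold = thr)
      tab <- label_and_measure(mask, m2856)
      diam <- c(diam, tab$equivalent_diameter_um)
      dens <- c(dens, attr(tab, "density_per_mm2"))
      c2856 <- c(c2856, isolated_contrast(m2856, mask))
      c1550 <- c(c1550, isolated_contrast(m1550, mask))
    }
    out[[tt]] <- list(diameters_um = diam, density_per_mm2 = dens,
                      contrast_2856 = c2856, contrast_1550 = c1550)
  }
  out$threshold <- thr
  out$diameter_ratio <- mean(out$eWAT$diameters_um) /
    mean(out$iBAT$diameters_um)
  out$density_ratio <- mean(out$iBAT$density_per_mm2) /
    mean(out$eWAT$density_per_mm2)
  out$contrast_ratio_2856 <- mean(out$eWAT$contrast_2856) /
    mean(out$iBAT$contrast_2856)
  out$contrast_ratio_1550 <- mean(out$iBAT$contrast_1550) /
    mean(out$eWAT$contrast_1550)
  out
}

#' Spectral band-area recovery study
#'
#' Simulates localized adipocyte spectra for eWAT and iBAT, applies the
#' carbon-reference correction, averages per tissue and reports the
#' amide-band (1700-1500 cm^-1), CH2 (2932-2778) and CO (1128-1080)
#' area ratios of the mean spectra.
#'
#' @param n_per_tissue Number of simulated adipocyte spectra per tissue.
#' @param seed Integer seed.
#' @param noise_sd Single-pulse noise SD.
#' @return A list with the mean corrected spectra and the three ratios.
#' @export
spectral_band_study <- function(n_per_tissue = 200, seed = 0L,
                                noise_sd = 0.15) {
  wn <- canonical_wavenumbers()
  ref_emit <- reference_emission(wn, seed = seed + 1L)
  # reference profile as measured on carbon tape: peak-to-peak of the unit
  # pulse times the emission envelope
  p2p <- peak_to_peak(oa_transient(unit_pulse(150), acq_params()$fs_hz))
  ref_spec <- spectrum(wn, ref_emit$intensities * p2p)
  means <- list()
  for (tt in c("eWAT", "iBAT")) {
    cls <- if (tt == "eWAT") "WAT_adipocyte" else "BAT_adipocyte"
    X <- simulate_spectra(cls, n_per_tissue, wn, reference = ref_emit,
                          noise_sd = noise_sd,
                          seed = seed + match(tt, c("eWAT", "iBAT")))
    raw_mean <- spectrum(wn, colMeans(X))
    means[[tt]] <- reference_correct(raw_mean, ref_spec)
  }
  ratio <- function(band, top, bottom)
    band_auc(means[[top]], band) / band_auc(means[[bottom]], band)
  list(mean_spectra = means,
       amide_ratio_ibat_ewat = ratio(c(1500, 1700), "iBAT", "eWAT"),
       ch2_ratio_ewat_ibat = ratio(c(2778, 2932), "eWAT", "iBAT"),
       co_ratio_ewat_ibat = ratio(c(1080, 1128), "eWAT", "iBAT"))
}

#' Labeled per-pixel training features from default phantoms
#'
#' Generates one eWAT, one iBAT and one iWAT phantom, renders them at the
#' 10 scoring wavenumbers, and collects raw per-pixel intensities with
#' their ground-truth class labels (balanced up to `max_per_class`).
#'
#' @param seed Integer seed (phantom seeds derive from it).
#' @param max_per_class Cap on pixels kept per class.
#' @param fov_um,step_um Phantom geometry.
#' @param acq An [acq_params()] object.
#' @return A list: `features` (n x 10 matrix), `labels`, `wavenumbers`.
#' @export
pixel_training_set <- function(seed = 0L, max_per_class = 1000L,
                               fov_um = c(1000, 1000), step_um = 5,
                               acq = acq_params()) {
  wns <- qsat_wavenumbers_10
  feats <- NULL; labs <- character(0)
  keep_classes <- phantom_classes
  i <- 0L
  for (tt in c("eWAT", "iBAT", "iWAT")) {
    i <- i + 1L
    ph <- generate_phantom(phantom_params(tt, week = 4, fov_um = fov_um,
                                          step_um = step_um,
                                          seed = seed + i))
    cube <- render_hypercube(ph, wns, acq = acq, seed = seed + i)
    X <- vapply(seq_along(wns), function(k) as.vector(cube$gated[, , k]),
                numeric(length(ph$label_map)))
    lab <- phantom_classes[as.vector(ph$label_map)]
    # one tissue contributes each class, so labels stay unambiguous:
    use <- switch(tt,
                  eWAT = lab == "WAT_adipocyte",
                  iBAT = lab == "BAT_adipocyte" | lab == "ECM",
                  iWAT = !(lab %in% c("WAT_adipocyte", "BAT_adipocyte",
                                      "ECM")))
    feats <- rbind(feats, X[use, , drop = FALSE])
    labs <- c(labs, lab[use])
  }
  keep <- with_seed(seed + 17L, {
    unlist(lapply(split(seq_along(labs), labs), function(ix) {
      if (length(ix) > max_per_class) sample(ix, max_per_class) else ix
    }), use.names = FALSE)
  })
  list(features = feats[keep, , drop = FALSE], labels = labs[keep],
       wavenumbers = wns)
}

#' Held-out classifier evaluation over the reduced feature sets
#'
#' Splits labeled pixel features 70/30, trains the multinomial pixel scorer
#' on the 10-wavenumber set and on both 2-wavenumber variants, and reports
#' the held-out macro one-vs-rest ROC AUC of each model.
#'
#' @param seed Integer seed for data generation and the split.
#' @param train_frac Training fraction.
#' @param reg Ridge regularization strength.
#' @param ... Passed to [pixel_training_set()].
#' @return A list: `auc` (named: `wn10`, `pair_990_1238`,
#'   `pair_1550_2856`), `models`, `split` sizes.
#' @export
classifier_study <- function(seed = 0L, train_frac = 0.7, reg = 1, ...) {
  ts <- pixel_training_set(seed = seed, ...)
  n <- nrow(ts$features)
  idx_train <- with_seed(seed + 31L, sample(n, round(train_frac * n)))
  idx_test <- setdiff(seq_len(n), idx_train)
  sets <- list(wn10 = qsat_wavenumbers_10,
               pair_990_1238 = qsat_wavenumber_pairs[[1]],
               pair_1550_2856 = qsat_wavenumber_pairs[[2]])
  models <- list(); auc <- c()
  for (nm in names(sets)) {
    cols <- match(sets[[nm]], ts$wavenumbers)
    model <- train_pixel_scorer(ts$features[idx_train, cols, drop = FALSE],
                                ts$labels[idx_train], sets[[nm]],
                                reg = reg, seed = seed)
    P <- predict_scorer(model,
                        l2_normalize_rows(
                          ts$features[idx_test, cols, drop = FALSE]))
    auc[nm] <- macro_auc(P, ts$labels[idx_test])
    models[[nm]] <- model
  }
  list(auc = auc, models = models,
       split = c(train = length(idx_train), test = length(idx_test)))
}

#' Postnatal week-series scoring study
#'
#' Scores synthetic iWAT phantoms for postnatal weeks 2-6 (browning then
#' whitening mixing fractions) with a pixel scorer trained on independent
#' phantoms, and reports the normalized tissue scores per week and seed.
#'
#' @param seeds Phantom seeds (one replicate per seed).
#' @param weeks Postnatal weeks to simulate.
#' @param fov_um,step_um Geometry of the scored phantoms.
#' @param model A trained multiclass `scorer_model`; by default one is
#'   trained on phantoms at `training_seed`.
#' @param training_seed Seed for the training phantoms.
#' @return A list with matrices `s_bat` and `s_wat` (rows = seeds,
#'   columns = weeks) and the model used.
#' @export
week_series_study <- function(seeds = 0:2, weeks = 2:6,
                              fov_um = c(500, 500), step_um = 5,
                              model = NULL, training_seed = 5000L) {
  if (is.null(model)) {
    ts <- pixel_training_set(seed = training_seed)
    model <- train_pixel_scorer(ts$features, ts$labels, ts$wavenumbers,
                                seed = training_seed)
  }
  s_bat <- s_wat <- matrix(NA_real_, length(seeds), length(weeks),
                           dimnames = list(paste0("seed", seeds),
                                           paste0("week", weeks)))
  for (i in seq_along(seeds)) for (j in seq_along(weeks)) {
    # scored fields carry adipocytes + ECM only; the structure classes are
    # needed for training, not for the remodeling read-out
    ph <- generate_phantom(phantom_params("iWAT", week = weeks[j],
                                          fov_um = fov_um,
                                          step_um = step_um,
                                          include_structures = FALSE,
                                          seed = seeds[i] + 100L * weeks[j]))
    cube <- render_hypercube(ph, model$wavenumbers,
                             seed = seeds[i] + 100L * weeks[j])
    sc <- normalized_scores(score_map(model, cube))
    s_bat[i, j] <- sc$S_BAT
    s_wat[i, j] <- sc$S_WAT
  }
  list(s_bat = s_bat, s_wat = s_wat, model = model)
}
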