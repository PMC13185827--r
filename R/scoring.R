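# Q-SAT core: linear (multinomial logistic) spectral and pixel scorers,
# probability score maps, normalized tissue scores, tile heterogeneity,
# exact linear SHAP attributions and rank-based ROC AUC.

new_scorer_model <- function(mode, class_names, wavenumbers, weights,
                             intercepts, stats, reg, seed) {
  dimnames(weights) <- list(class_names, as.character(wavenumbers))
  names(intercepts) <- class_names
  names(stats$mean) <- names(stats$sd) <- as.character(wavenumbers)
  structure(list(mode = mode, class_names = class_names,
                 wavenumbers = wavenumbers, weights = weights,
                 intercepts = intercepts, stats = stats,
                 reg = reg, seed = seed),
            class = "scorer_model")
}

#' @export
print.scorer_model <- function(x, ...) {
  cat(sprintf("<scorer_model> %s: %d classes (%s), %d features\n",
              x$mode, length(x$class_names),
              paste(x$class_names, collapse = ", "),
              ncol(x$weights)))
  invisible(x)
}

# Ridge-penalized multinomial logistic fit (glmnet).  `reg` plays the role
# of an inverse-C: the glmnet penalty is lambda = reg / n.  Deterministic
# for fixed inputs; the seed is provenance (and used by callers that
# subsample).
fit_multinomial <- function(X, labels, reg = 1, seed = 0L) {
  y <- factor(labels)
  classes <- levels(y)
  if (any(table(y) < 2))
    stop("every class needs at least 2 training examples")
  if (length(classes) < 2) stop("need at least 2 classes")
  lam <- reg / nrow(X)
  # decreasing lambda path for warm starts; coefficients read at the target
  path <- exp(seq(log(max(1, lam * 1e4)), log(lam), length.out = 25))
  fit <- glmnet::glmnet(X, y, family = "multinomial", alpha = 0,
                        lambda = path, standardize = FALSE, maxit = 3e5)
  co <- glmnet::coef.glmnet(fit, s = lam, exact = FALSE)
  W <- t(vapply(co, function(b) as.numeric(b)[-1], numeric(ncol(X))))
  b <- vapply(co, function(b) as.numeric(b)[1], 1)
  rownames(W) <- classes
  list(weights = W, intercepts = b, classes = classes)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Class probabilities for raw (L2-normalized) feature rows: standardize
# with the training statistics, then softmax of the linear margins.
predict_scorer <- function(model, X) {
  Z <- standardize(as.matrix(X), model$stats)$X
  M <- Z %*% t(model$weights)
  M <- sweep(M, 2, model$intercepts, "+")
  P <- softmax_rows(M)
  colnames(P) <- model$class_names
  P
}

# Coerce a collection of spectra (list of `spectrum` or a matrix) into a
# feature matrix on the expected grid.
spectra_matrix <- function(spectra, wavenumbers = NULL,
                           require_state = NULL) {
  if (is.matrix(spectra)) return(spectra)
  stopifnot(length(spectra) >= 1,
            all(vapply(spectra, inherits, TRUE, "spectrum")))
  wn <- spectra[[1]]$wavenumbers
  if (!is.null(wavenumbers) && !isTRUE(all.equal(wn, wavenumbers)))
    stop("spectra grid does not match the model's wavenumbers")
  for (s in spectra) {
    if (!isTRUE(all.equal(s$wavenumbers, wn)))
      stop("spectra lie on different grids")
    if (!is.null(require_state) && s$state != require_state)
      stop(sprintf("spectra must be %s (got %s)", require_state, s$state))
  }
  t(vapply(spectra, function(s) s$intensities, numeric(length(wn))))
}

#' Train the binary WAT/BAT spectral scorer
#'
#' L2-regularized logistic regression on labeled, L2-normalized adipocyte
#' reference spectra from eWAT and iBAT; features are standardized with
#' statistics fit on the training set and stored in the model.
#'
#' @param spectra Matrix (rows = spectra) of L2-normalized intensities, or a
#'   list of [spectrum()] objects in state `"l2_normalized"`.
#' @param labels Class labels (two levels, e.g. `"WAT"`/`"BAT"`), >= 2
#'   examples each.
#' @param wavenumbers Feature wavenumbers (defaults to the canonical grid
#'   for matrix input, or the spectra's own grid).
#' @param reg Ridge regularization strength (inverse-C; glmnet lambda =
#'   `reg / n`).
#' @param seed Stored training seed.
#' @return A `scorer_model` of mode `"binary_spectral"`.
#' @export
train_binary_scorer <- function(spectra, labels, wavenumbers = NULL,
                                reg = 1, seed = 0L) {
  X <- spectra_matrix(spectra, require_state = "l2_normalized")
  if (is.null(wavenumbers))
    wavenumbers <- if (is.matrix(spectra)) seq_len(ncol(X)) * NA_real_
                   else spectra[[1]]$wavenumbers
  if (length(unique(labels)) != 2)
    stop("binary scorer needs exactly 2 classes")
  st <- standardize(X)
  f <- fit_multinomial(st$X, labels, reg = reg, seed = seed)
  new_scorer_model("binary_spectral", f$classes, wavenumbers,
                   f$weights, f$intercepts, st$stats, reg, seed)
}

#' Score adipocyte spectra
#'
#' Applies a binary spectral scorer to a collection of spectra, returning
#' the per-spectrum WAT- and BAT-probabilities (each row sums to 1) and the
#' argmax class assignment.
#'
#' @param model A binary `scorer_model`.
#' @param spectra Matrix or list of L2-normalized [spectrum()] objects on
#'   the model's grid.
#' @return A `data.frame` with one probability column per class plus an
#'   `assigned` column.
#' @export
score_adipocytes <- function(model, spectra) {
  stopifnot(inherits(model, "scorer_model"))
  if (model$mode != "binary_spectral")
    stop("score_adipocytes expects a binary spectral scorer")
  X <- spectra_matrix(spectra, wavenumbers = model$wavenumbers)
  if (ncol(X) != ncol(model$weights))
    stop("feature count does not match the model")
  P <- predict_scorer(model, X)
  out <- as.data.frame(P)
  out$assigned <- model$class_names[max.col(P, ties.method = "first")]
  out
}

#' Select scoring wavenumbers
#'
#' In `"default"` mode returns the fixed reduced feature sets used for
#' digital staining: the 10-wavenumber set for `k = 10`, or one of the two
#' 2-wavenumber variants for `k = 2`.  In `"pca"` mode ranks grid points by
#' the aggregate absolute PCA-loading magnitude on class-discriminating
#' components (components weighted by explained variance times the one-way
#' ANOVA F statistic of their scores against the labels) and greedily picks
#' the top `k` subject to a minimum spacing.
#'
#' @param spectra Labeled spectra matrix (rows = spectra), `"pca"` mode.
#' @param labels Class labels, `"pca"` mode.
#' @param wavenumbers Grid for the columns of `spectra`.
#' @param k Number of wavenumbers (>= 2).
#' @param mode `"default"` or `"pca"`.
#' @param pair For `mode = "default"`, `k = 2`: `1` for (990, 1238) or `2`
#'   for (1550, 2856).
#' @param min_spacing_cm1 Minimum spacing between selected points.
#' @return Numeric vector of k wavenumbers (cm^-1).
#' @export
select_wavenumbers <- function(spectra = NULL, labels = NULL,
                               wavenumbers = canonical_wavenumbers(),
                               k = 10, mode = c("default", "pca"),
                               pair = 1, min_spacing_cm1 = 20) {
  mode <- match.arg(mode)
  if (k < 2) stop("k must be >= 2")
  if (mode == "default") {
    if (k == 10) return(qsat_wavenumbers_10)
    if (k == 2) return(qsat_wavenumber_pairs[[pair]])
    stop("default mode provides only the k = 10 and k = 2 sets; use mode = 'pca'")
  }
  if (is.null(spectra) || is.null(labels))
    stop("pca mode needs labeled spectra")
  X <- as.matrix(spectra)
  if (k > ncol(X)) stop("k exceeds the number of grid points")
  p <- pca_fit_project(X, k = min(10L, nrow(X) - 1L, ncol(X)))
  y <- factor(labels)
  wts <- vapply(seq_len(ncol(p$scores)), function(j) {
    f <- tryCatch(summary(stats::aov(p$scores[, j] ~ y))[[1]]$`F value`[1],
                  error = function(e) 0)
    if (!is.finite(f)) f <- 0
    p$explained[j] * f
  }, 1)
  score <- as.numeric(abs(p$loadings) %*% wts)
  ord <- order(score, decreasing = TRUE)
  chosen <- numeric(0)
  for (i in ord) {
    if (all(abs(wavenumbers[i] - chosen) >= min_spacing_cm1)) {
      chosen <- c(chosen, wavenumbers[i])
      if (length(chosen) == k) break
    }
  }
  if (length(chosen) < k)
    stop("could not select k wavenumbers at the requested spacing")
  chosen
}

#' Train the multiclass pixel scorer
#'
#' Multinomial logistic regression over all labeled structure classes
#' (adipocytes plus ECM, lymph node, connective tissue, water, void) on
#' per-pixel intensities at the selected wavenumbers.  Features are
#' L2-normalized per pixel over the selected wavenumbers, then standardized
#' with training statistics stored in the model.
#'
#' @param features Matrix of raw per-pixel intensities, rows = pixels,
#'   columns = `wavenumbers`.
#' @param labels Per-pixel class labels (>= 2 classes, >= 2 examples each).
#' @param wavenumbers Feature wavenumbers (cm^-1).
#' @param reg Ridge regularization strength.
#' @param seed Stored training seed.
#' @return A `scorer_model` of mode `"multiclass_pixel"`.
#' @export
train_pixel_scorer <- function(features, labels, wavenumbers,
                               reg = 1, seed = 0L) {
  X <- as.matrix(features)
  if (ncol(X) != length(wavenumbers))
    stop("feature columns must match the wavenumber list")
  Xn <- l2_normalize_rows(X)
  st <- standardize(Xn)
  f <- fit_multinomial(st$X, labels, reg = reg, seed = seed)
  colnames(f$weights) <- as.character(wavenumbers)
  new_scorer_model("multiclass_pixel", f$classes, wavenumbers,
                   f$weights, f$intercepts, st$stats, reg, seed)
}

#' Pixel-wise probability score map
#'
#' Applies a multiclass pixel scorer to a hypercube restricted to the
#' model's wavenumbers, producing one probability plane per class (digital
#' staining).  Per-pixel preprocessing (L2 normalization over the model
#' wavenumbers, then standardization with the training statistics) is
#' applied internally.
#'
#' @param model A `scorer_model` of mode `"multiclass_pixel"`.
#' @param cube A `hypercube` containing every model wavenumber.
#' @return An object of class `score_map`: `probs` array
#'   `(ny, nx, n_classes)`, `class_names`, `step_um`, `provenance`.
#' @export
score_map <- function(model, cube) {
  stopifnot(inherits(model, "scorer_model"), inherits(cube, "hypercube"))
  if (model$mode != "multiclass_pixel")
    stop("score_map expects a multiclass pixel scorer")
  idx <- match(model$wavenumbers, cube$wavenumbers)
  if (anyNA(idx))
    stop("cube is missing model wavenumber plane(s): ",
         paste(model$wavenumbers[is.na(idx)], collapse = ", "))
  ny <- dim(cube$gated)[1]; nx <- dim(cube$gated)[2]
  X <- vapply(idx, function(i) as.vector(cube$gated[, , i]),
              numeric(ny * nx))
  P <- predict_scorer(model, l2_normalize_rows(X))
  probs <- array(P, c(ny, nx, ncol(P)))
  structure(list(probs = probs, class_names = model$class_names,
                 step_um = cube$step_um,
                 provenance = list(wavenumbers = model$wavenumbers,
                                   mode = model$mode)),
            class = "score_map")
}

#' @export
print.score_map <- function(x, ...) {
  cat(sprintf("<score_map> %d x %d px, classes: %s\n",
              dim(x$probs)[1], dim(x$probs)[2],
              paste(x$class_names, collapse = ", ")))
  invisible(x)
}

# find the WAT / BAT probability plane of a score map
plane_of <- function(map, which = c("WAT", "BAT")) {
  which <- match.arg(which)
  cand <- if (which == "WAT") c("WAT_adipocyte", "WAT") else
    c("BAT_adipocyte", "BAT")
  i <- match(cand, map$class_names)
  i <- i[!is.na(i)][1]
  if (is.na(i)) stop("score map has no ", which, " plane")
  map$probs[, , i]
}

#' Normalized tissue scores
#'
#' S_WAT = sum(WAT) / sum(WAT + BAT) and S_BAT = sum(BAT) / sum(WAT + BAT)
#' over all pixels of a score map: the WAT/BAT probability mass relative to
#' the total adipocyte probability mass, so the two scores always sum to 1.
#'
#' @param map A [score_map()] result.
#' @return A list of class `tissue_scores`: `S_WAT`, `S_BAT`, `n_pixels`.
#' @export
normalized_scores <- function(map) {
  stopifnot(inherits(map, "score_map"))
  W <- plane_of(map, "WAT"); B <- plane_of(map, "BAT")
  denom <- sum(W) + sum(B)
  if (denom <= 0) stop("zero adipocyte probability mass")
  structure(list(S_WAT = sum(W) / denom, S_BAT = sum(B) / denom,
                 n_pixels = length(W)),
            class = "tissue_scores")
}

#' @export
print.tissue_scores <- function(x, ...) {
  cat(sprintf("S_WAT = %.4f, S_BAT = %.4f (%d px)\n",
              x$S_WAT, x$S_BAT, x$n_pixels))
  invisible(x)
}

#' Tile-based spatial heterogeneity
#'
#' Partitions the score map into a near-equal grid of tiles (remainder
#' pixels going to the last row/column), computes the normalized WAT and
#' BAT scores per tile, and summarizes spatial patchiness as the
#' coefficient of variation (population SD / mean) of the tile scores.
#'
#' @param map A [score_map()] result.
#' @param grid Tile grid `(rows, cols)`, default 10 x 10.
#' @return A list of class `heterogeneity_result`: `tile_nwat`, `tile_nbat`
#'   matrices, `cv_nwat`, `cv_nbat`, `grid`.
#' @export
tile_cv <- function(map, grid = c(10, 10)) {
  stopifnot(inherits(map, "score_map"))
  W <- plane_of(map, "WAT"); B <- plane_of(map, "BAT")
  ny <- nrow(W); nx <- ncol(W)
  if (ny < grid[1] || nx < grid[2])
    stop("score map smaller than the tile grid")
  cuts <- function(n, g) {
    base <- n %/% g
    sizes <- rep(base, g); sizes[g] <- sizes[g] + n %% g
    cumsum(c(0, sizes))
  }
  ry <- cuts(ny, grid[1]); rx <- cuts(nx, grid[2])
  tw <- tb <- matrix(NA_real_, grid[1], grid[2])
  for (i in seq_len(grid[1])) for (j in seq_len(grid[2])) {
    w <- W[(ry[i] + 1):ry[i + 1], (rx[j] + 1):rx[j + 1]]
    b <- B[(ry[i] + 1):ry[i + 1], (rx[j] + 1):rx[j + 1]]
    denom <- sum(w) + sum(b)
    if (denom <= 0) stop("tile with zero adipocyte probability mass")
    tw[i, j] <- sum(w) / denom
    tb[i, j] <- sum(b) / denom
  }
  cv <- function(x) {
    mu <- mean(x)
    if (mu == 0) stop("mean tile score is zero: CV undefined")
    sqrt(mean((x - mu)^2)) / mu   # population SD
  }
  structure(list(tile_nwat = tw, tile_nbat = tb,
                 cv_nwat = cv(tw), cv_nbat = cv(tb), grid = grid),
            class = "heterogeneity_result")
}

#' Exact linear SHAP feature attributions
#'
#' For a linear scorer the Shapley value of feature i on sample x is
#' `w_i * (x_i - mean(x_i))` in margin (log-odds) space, computed against
#' the mean of the supplied background/evaluation set; per-sample
#' contributions sum exactly to the margin minus the mean margin (local
#' accuracy).  The summary is the mean absolute contribution per feature
#' and class.
#'
#' @param model A linear `scorer_model`.
#' @param X Feature matrix in the model's input space (L2-normalized rows,
#'   pre-standardization).
#' @return A list of class `shap_attribution`: `contributions` array
#'   `(n, features, classes)` and `summary` matrix `(features, classes)`.
#' @export
feature_importance <- function(model, X) {
  stopifnot(inherits(model, "scorer_model"))
  if (is.null(model$weights))
    stop("feature_importance requires a linear model")
  Z <- standardize(as.matrix(X), model$stats)$X
  Zc <- sweep(Z, 2, colMeans(Z))
  nC <- length(model$class_names); nF <- ncol(Z)
  contrib <- array(NA_real_, c(nrow(Z), nF, nC),
                   dimnames = list(NULL, colnames(model$weights),
                                   model$class_names))
  for (c_i in seq_len(nC))
    contrib[, , c_i] <- sweep(Zc, 2, model$weights[c_i, ], "*")
  summ <- apply(abs(contrib), c(2, 3), mean)
  structure(list(contributions = contrib, summary = summ),
            class = "shap_attribution")
}

#' Rank-based ROC AUC
#'
#' Mann-Whitney AUC of continuous scores against binary labels, with
#' midranks for ties.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels (logical, 0/1, or a 2-level factor whose
#'   second level is positive).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  if (is.factor(labels) || is.character(labels)) {
    f <- factor(labels)
    if (nlevels(f) != 2) stop("labels must have exactly 2 levels")
    pos <- f == levels(f)[2]
  } else pos <- as.logical(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Macro one-vs-rest AUC
#'
#' Mean over classes of the one-vs-rest [roc_auc()] of each class's
#' predicted probability.
#'
#' @param probs Matrix of class probabilities (columns named by class).
#' @param labels True class labels.
#' @return Macro-averaged AUC.
#' @export
macro_auc <- function(probs, labels) {
  classes <- colnames(probs)
  mean(vapply(classes, function(cl) {
    roc_auc(probs[, cl], labels == cl)
  }, 1))
}
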