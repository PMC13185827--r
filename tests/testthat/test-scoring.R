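# toy helpers ---------------------------------------------------------------

toy_binary <- function(n = 20, sd = 0.2, seed = 1) {
  # two clusters at distinct angles so they stay separable after the
  # per-row L2 normalization
  set.seed(seed)
  X <- rbind(cbind(rnorm(n, 3, sd), rnorm(n, 0.3, sd)),
             cbind(rnorm(n, 0.3, sd), rnorm(n, 3, sd)))
  X <- X / sqrt(rowSums(X^2))
  list(X = X, y = rep(c("WAT", "BAT"), each = n))
}

test_that("the binary scorer separates separable toys and outputs probabilities", {
  d <- toy_binary()
  m <- train_binary_scorer(d$X, d$y)
  expect_s3_class(m, "scorer_model")
  sc <- score_adipocytes(m, d$X)
  P <- as.matrix(sc[, m$class_names])
  expect_true(all(abs(rowSums(P) - 1) < 1e-9))
  expect_equal(roc_auc(P[, "BAT"], d$y == "BAT"), 1.0)
  expect_error(train_binary_scorer(d$X, rep("WAT", nrow(d$X))), "2 classes")
})

test_that("permuted labels yield chance-level held-out AUC", {
  d <- toy_binary(n = 40, sd = 0.6, seed = 2)
  aucs <- replicate(100, {
    y <- sample(d$y)
    tr <- sample(80, 56)
    m <- train_binary_scorer(d$X[tr, ], y[tr])
    P <- score_adipocytes(m, d$X[-tr, ])
    roc_auc(P[, "BAT"], y[-tr] == "BAT")
  })
  expect_equal(mean(aucs), 0.5, tolerance = 0.1)
})

test_that("synthetic adipocyte spectra are scored almost perfectly held-out", {
  wn <- canonical_wavenumbers()
  XW <- simulate_spectra("WAT_adipocyte", 80, wn, seed = 11)
  XB <- simulate_spectra("BAT_adipocyte", 80, wn, seed = 12)
  X <- rbind(XW, XB) |> (\(A) A / sqrt(rowSums(A^2)))()
  y <- rep(c("WAT", "BAT"), each = 80)
  set.seed(13)
  tr <- sample(160, 112)
  m <- train_binary_scorer(X[tr, ], y[tr], wavenumbers = wn)
  P <- score_adipocytes(m, X[-tr, ])
  expect_gt(roc_auc(P[, "BAT"], y[-tr] == "BAT"), 0.99)
  # a training BAT-template spectrum scores BAT > 0.5
  tb <- class_template("BAT_adipocyte", wn)
  Pb <- score_adipocytes(m, matrix(tb / sqrt(sum(tb^2)), 1))
  expect_gt(Pb[1, "BAT"], 0.5)
  expect_error(score_adipocytes(m, X[, 1:10]), "feature count")
})

test_that("wavenumber selection returns the fixed sets and honors forced features", {
  expect_equal(select_wavenumbers(k = 10),
               c(2856, 1632, 1550, 1454, 1376, 1238, 1134, 1086, 1046, 990))
  expect_equal(select_wavenumbers(k = 2, pair = 1), c(990, 1238))
  expect_equal(select_wavenumbers(k = 2, pair = 2), c(1550, 2856))
  expect_error(select_wavenumbers(k = 5), "pca")
  # two-class data varying at a single grid point -> that point ranks first
  wn <- canonical_wavenumbers()
  set.seed(21)
  X <- matrix(rnorm(60 * length(wn), sd = 0.01), 60)
  j <- match(1376, wn)
  X[31:60, j] <- X[31:60, j] + 5
  sel <- select_wavenumbers(X, rep(c("a", "b"), each = 30),
                            wavenumbers = wn, k = 2, mode = "pca")
  expect_equal(sel[1], 1376)
  expect_error(select_wavenumbers(X, rep(c("a", "b"), each = 30),
                                  wavenumbers = wn, k = length(wn) + 1,
                                  mode = "pca"), "exceeds")
})

test_that("the pixel scorer is exact on separable toys and drops absent classes", {
  set.seed(5)
  mk <- function(center, n = 30) sweep(matrix(abs(rnorm(2 * n, sd = 0.05)),
                                              n, 2), 2, center, "+")
  X <- rbind(mk(c(1, 0.1)), mk(c(0.1, 1)), mk(c(0.7, 0.7)))
  y <- rep(c("WAT_adipocyte", "ECM", "connective"), each = 30)
  m <- train_pixel_scorer(X, y, c(2856, 1550))
  P <- qsat:::predict_scorer(m, qsat:::l2_normalize_rows(X))
  expect_equal(mean(m$class_names[max.col(P)] == y), 1.0)
  m2 <- train_pixel_scorer(X[y != "connective", ], y[y != "connective"],
                           c(2856, 1550))
  expect_false("connective" %in% m2$class_names)
  expect_error(train_pixel_scorer(X[c(1, 31:90), ], y[c(1, 31:90)],
                                  c(2856, 1550)), "at least 2")
})

test_that("score maps are probability fields consistent with the spectrum path", {
  ph <- generate_phantom(phantom_params("eWAT", fov_um = c(200, 200),
                                        step_um = 5, seed = 31))
  cube <- render_hypercube(ph, qsat_wavenumbers_10, seed = 31)
  ts <- pixel_training_set(seed = 91, max_per_class = 150,
                           fov_um = c(300, 300))
  model <- train_pixel_scorer(ts$features, ts$labels, ts$wavenumbers)
  sm <- score_map(model, cube)
  expect_equal(dim(sm$probs)[1:2], dim(ph$label_map))
  sums <- apply(sm$probs, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # pure-WAT phantom: WAT plane dominates BAT plane on average
  expect_gt(mean(qsat:::plane_of(sm, "WAT")), mean(qsat:::plane_of(sm, "BAT")))
  # identical to pushing the flattened features through the predictor
  X <- vapply(seq_along(model$wavenumbers),
              function(k) as.vector(cube$gated[, , k]),
              numeric(length(ph$label_map)))
  P <- qsat:::predict_scorer(model, qsat:::l2_normalize_rows(X))
  expect_equal(as.vector(sm$probs), as.vector(P))
  cube2 <- cube; cube2$wavenumbers <- cube$wavenumbers + 2
  expect_error(score_map(model, cube2), "missing model wavenumber")
})

test_that("normalized tissue scores follow the summed-probability formula", {
  mk_map <- function(W, B) {
    probs <- array(c(W, B), c(dim(W), 2))
    structure(list(probs = probs, class_names = c("WAT", "BAT"),
                   step_um = 5, provenance = list()), class = "score_map")
  }
  eq <- mk_map(matrix(0.4, 3, 3), matrix(0.4, 3, 3))
  expect_equal(normalized_scores(eq)$S_WAT, 0.5)
  allw <- mk_map(matrix(0.9, 3, 3), matrix(0, 3, 3))
  expect_equal(normalized_scores(allw)$S_WAT, 1)
  two <- mk_map(matrix(c(0.8, 0.2), 1), matrix(c(0.1, 0.6), 1))
  expect_equal(normalized_scores(two)$S_WAT, 1.0 / 1.7)
  expect_error(normalized_scores(mk_map(matrix(0, 2, 2), matrix(0, 2, 2))),
               "zero adipocyte")
})

test_that("S_WAT + S_BAT is identically 1 over random score maps", {
  set.seed(6)
  for (r in 1:1000) {
    W <- matrix(runif(16), 4); B <- matrix(runif(16), 4)
    probs <- array(c(W, B), c(4, 4, 2))
    map <- structure(list(probs = probs, class_names = c("WAT", "BAT"),
                          step_um = 5, provenance = list()),
                     class = "score_map")
    sc <- normalized_scores(map)
    expect_identical(sc$S_WAT + sc$S_BAT, 1)
  }
})

test_that("tile CV matches hand computation, scale invariance and permutation", {
  mk_map <- function(W, B) {
    structure(list(probs = array(c(W, B), c(dim(W), 2)),
                   class_names = c("WAT", "BAT"), step_um = 5,
                   provenance = list()), class = "score_map")
  }
  # 2x2 tiles with per-tile S_WAT {0.2, 0.2, 0.6, 0.6}
  w <- rbind(cbind(matrix(0.2, 5, 5), matrix(0.2, 5, 5)),
             cbind(matrix(0.6, 5, 5), matrix(0.6, 5, 5)))
  het <- tile_cv(mk_map(w, 1 - w), grid = c(2, 2))
  expect_equal(as.vector(het$tile_nwat), c(0.2, 0.6, 0.2, 0.6))
  expect_equal(het$cv_nwat, 0.2 / 0.4)   # population SD / mean
  uni <- tile_cv(mk_map(matrix(0.3, 20, 20), matrix(0.7, 20, 20)),
                 grid = c(4, 4))
  expect_equal(uni$cv_nwat, 0)
  set.seed(8)
  W <- matrix(runif(400), 20); B <- matrix(runif(400), 20)
  h1 <- tile_cv(mk_map(W, B), grid = c(4, 4))
  h2 <- tile_cv(mk_map(3 * W, 3 * B), grid = c(4, 4))
  expect_equal(h1$cv_nwat, h2$cv_nwat, tolerance = 1e-12)
  expect_equal(h1$cv_nbat, h2$cv_nbat, tolerance = 1e-12)
  # permuting tiles leaves the CV unchanged
  cvp <- function(x) sqrt(mean((x - mean(x))^2)) / mean(x)
  perm <- sample(16)
  expect_equal(cvp(as.vector(h1$tile_nwat)[perm]), h1$cv_nwat)
  expect_error(tile_cv(mk_map(W, B), grid = c(30, 4)), "smaller")
})

test_that("linear SHAP satisfies local accuracy and matches brute-force Shapley", {
  d <- toy_binary(n = 15, seed = 3)
  m <- train_binary_scorer(d$X, d$y)
  fi <- feature_importance(m, d$X)
  Z <- qsat:::standardize(d$X, m$stats)$X
  for (ci in seq_along(m$class_names)) {
    margin <- as.numeric(Z %*% m$weights[ci, ]) + m$intercepts[ci]
    expect_equal(rowSums(fi$contributions[, , ci]),
                 margin - mean(margin), tolerance = 1e-12)
  }
  # zero-weight feature gets zero attribution
  m0 <- m; m0$weights[, 2] <- 0
  fi0 <- feature_importance(m0, d$X)
  expect_true(all(fi0$contributions[, 2, ] == 0))
  # brute-force Shapley for a linear value function, 3 features
  set.seed(4)
  w <- c(0.7, -1.2, 0.4)
  X3 <- matrix(rnorm(30), 10, 3)
  mu <- colMeans(X3)
  brute_shap <- function(x) {
    perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
    phi <- numeric(3)
    val <- function(S) sum(w[S] * x[S]) + sum(w[setdiff(1:3, S)] * mu[setdiff(1:3, S)])
    for (p in perms) {
      S <- integer(0)
      for (f in p) {
        phi[f] <- phi[f] + (val(c(S, f)) - val(S)) / length(perms)
        S <- c(S, f)
      }
    }
    phi
  }
  lin_shap <- sweep(sweep(X3, 2, mu), 2, w, "*")
  for (i in 1:10) expect_equal(brute_shap(X3[i, ]), lin_shap[i, ],
                               tolerance = 1e-12)
})

test_that("rank AUC handles ties, perfect separation and chance", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(c(10, 20), c(FALSE, TRUE)), 1)
  expect_equal(roc_auc(c(1, 1, 2), c(0, 1, 1)), 0.75)  # midrank tie
  set.seed(10)
  expect_equal(roc_auc(rnorm(4000), rbinom(4000, 1, 0.5)), 0.5,
               tolerance = 0.03)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
  # agrees with the reference implementation
  sc <- rnorm(200); y <- rbinom(200, 1, 0.4)
  ref <- as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(sc, y), ref, tolerance = 1e-12)
})

test_that("attribution rankings are stable across training seeds", {
  ts <- pixel_training_set(seed = 201, max_per_class = 200,
                           fov_um = c(300, 300))
  n <- nrow(ts$features)
  ranks <- lapply(c(301, 302), function(s) {
    set.seed(s)
    idx <- sample(n, round(0.8 * n))
    m <- train_pixel_scorer(ts$features[idx, ], ts$labels[idx],
                            ts$wavenumbers, seed = s)
    fi <- feature_importance(m, qsat:::l2_normalize_rows(ts$features[idx, ]))
    rowMeans(fi$summary)
  })
  expect_gt(cor(ranks[[1]], ranks[[2]], method = "spearman"), 0.9)
})
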