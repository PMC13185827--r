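test_that("micrograph assembly extracts the requested plane in scan order", {
  fx <- noiseless_ewat_cube()
  m <- assemble_micrograph(fx$cube, 2856)
  expect_equal(m$image, fx$cube$gated[, , 1])
  expect_equal(m$step_um, 5)
  mm <- assemble_micrograph(fx$cube, 1550, kind = "MAP")
  expect_equal(mm$image, fx$cube$map[, , 2])
  expect_error(assemble_micrograph(fx$cube, 1046), "not present")
})

test_that("NOAS^2 maps the FOV extremes to 0 and 1 and the midpoint to 0.25", {
  m <- micrograph(matrix(c(0, 1, 2, 2), 2), 2856, 5, "depth_gated")
  n <- noas_squared(m)
  expect_equal(sort(unique(as.vector(n$image))), c(0, 0.25, 1))
  expect_equal(n$intensity_kind, "NOAS2")
  expect_error(noas_squared(micrograph(matrix(3, 2, 2), 2856, 5,
                                       "depth_gated")),
               "zero dynamic range")
  # min-max normalization is idempotent before squaring
  mm <- matrix(runif(64, 2, 9), 8)
  norm1 <- (mm - min(mm)) / diff(range(mm))
  norm2 <- (norm1 - min(norm1)) / diff(range(norm1))
  expect_equal(norm1, norm2)
  expect_equal(noas_squared(micrograph(mm, 2856, 5, "depth_gated"))$image,
               norm1^2)
})

test_that("CLAHE is display-only, bounded, and near-monotone on smooth ramps", {
  ramp <- matrix(rep(seq(0, 1, length.out = 64), each = 64), 64)
  m <- noas_squared(micrograph(ramp, 2856, 5, "depth_gated"))
  cl <- clahe_micrograph(m)
  expect_equal(cl$intensity_kind, "CLAHE")
  expect_true(all(cl$image >= 0 & cl$image <= 1))
  expect_gt(cor(as.vector(m$image), as.vector(cl$image),
                method = "spearman"), 0.99)
  const <- micrograph(matrix(0.5, 16, 16), 2856, 5, "NOAS2")
  expect_equal(clahe_micrograph(const)$image, const$image)
  # display kinds are refused downstream
  expect_error(adipocyte_mask(cl, threshold = 0.5), "display-only")
  expect_error(isolated_contrast(cl, matrix(TRUE, 64, 64)), "display-only")
})

test_that("quantile threshold masks follow the linear-interpolation Q25", {
  cal <- micrograph(matrix(c(1, 2, 3, 4), 2), 2856, 5, "depth_gated")
  expect_equal(stats::quantile(cal$image, 0.25, names = FALSE), 1.75)
  tgt <- micrograph(matrix(c(1.5, 2.0, 0.2, 3.1), 2), 2856, 5, "depth_gated")
  mask <- adipocyte_mask(tgt, calibration = cal)
  expect_equal(as.vector(mask), c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(attr(mask, "threshold"), 1.75)
  # a field identical to the calibration masks ~75% of its pixels
  big <- micrograph(matrix(runif(1e4), 100), 2856, 5, "depth_gated")
  self_mask <- adipocyte_mask(big, calibration = big)
  expect_equal(mean(self_mask), 0.75, tolerance = 0.01)
  z <- micrograph(matrix(0, 10, 10), 2856, 5, "depth_gated")
  expect_false(any(adipocyte_mask(z, calibration = big)))
  expect_error(adipocyte_mask(tgt), "calibration")
  # monotonicity: raising the threshold never adds pixels
  m1 <- adipocyte_mask(big, threshold = 0.3)
  m2 <- adipocyte_mask(big, threshold = 0.6)
  expect_true(all(m1[m2]))
})

test_that("morphometry is exact on synthetic disks", {
  img <- matrix(0, 60, 60)
  # disk of diameter 20 px at 5 um step -> equivalent diameter ~100 um
  cx <- 25; cy <- 25
  img[(row(img) - cy)^2 + (col(img) - cx)^2 <= 10^2] <- 1
  img[50:52, 50:52] <- 1   # second small blob (3x3)
  m <- micrograph(img, 2856, 5, "depth_gated")
  mask <- adipocyte_mask(m, threshold = 0.5)
  tab <- label_and_measure(mask, m, channels = list(self = m))
  expect_equal(nrow(tab), 2)
  big <- tab[which.max(tab$area_um2), ]
  expect_equal(big$equivalent_diameter_um, 100, tolerance = 5 / 100)
  expect_equal(big$mean_self, 1)
  expect_equal(attr(tab, "density_per_mm2") * attr(tab, "fov_area_mm2"),
               nrow(tab))
  # min-area filter removes the small blob
  tab2 <- label_and_measure(mask, m, min_area_um2 = 9 * 25 + 1)
  expect_equal(nrow(tab2), 1)
  # empty mask
  tab0 <- label_and_measure(matrix(FALSE, 60, 60), m)
  expect_equal(nrow(tab0), 0)
  expect_equal(attr(tab0, "density_per_mm2"), 0)
})

test_that("8-connected labeling agrees with the reference labeler on gapped masks", {
  set.seed(9)
  mask <- matrix(FALSE, 40, 40)
  for (k in 1:6) {
    r <- sample(3:36, 1); c <- sample(3:36, 1)
    mask[r + (-1:1), c + (-1:1)] <- TRUE
  }
  ours <- max(qsat:::label_components8(mask))
  ref <- max(EBImage::bwlabel(mask))  # 4-connected; equal on gapped blobs
  expect_equal(ours, ref)
  # diagonal-only touch merges under 8-connectivity
  diagm <- matrix(FALSE, 4, 4); diagm[1, 1] <- diagm[2, 2] <- TRUE
  expect_equal(max(qsat:::label_components8(diagm)), 1)
})

test_that("noiseless phantom morphometry recovers generator truth within 5%", {
  fx <- noiseless_ewat_cube()
  m <- assemble_micrograph(fx$cube, 2856)
  lab <- phantom_classes[fx$phantom$label_map]
  thr <- (max(m$image[lab == "ECM"]) + min(m$image[lab == "WAT_adipocyte"])) / 2
  tab <- label_and_measure(adipocyte_mask(m, threshold = thr), m)
  expect_equal(nrow(tab), nrow(fx$phantom$cell_table))
  expect_equal(mean(tab$equivalent_diameter_um),
               mean(fx$phantom$cell_table$true_diameter_um),
               tolerance = 0.05)
})

test_that("isolated contrast is the masked mean", {
  m <- micrograph(matrix(c(2, 4, 6, 8), 2), 2856, 5, "depth_gated")
  one <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2)
  expect_equal(isolated_contrast(m, one), 2)
  expect_equal(isolated_contrast(m, matrix(TRUE, 2, 2)), 5)
  u <- micrograph(matrix(3.3, 4, 4), 2856, 5, "depth_gated")
  expect_equal(isolated_contrast(u, matrix(TRUE, 4, 4)), 3.3)
  expect_error(isolated_contrast(m, matrix(FALSE, 2, 2)), "empty mask")
})
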