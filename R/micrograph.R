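# Per-wavenumber micrographs: assembly from a hypercube, display-only
# contrast post-processing (NOAS^2, CLAHE), quantile-threshold adipocyte
# segmentation and connected-component morphometry.

#' Micrograph container
#'
#' A single-wavenumber intensity image with its scan geometry and
#' provenance.  `intensity_kind` tracks what the pixel values are; the
#' display-only kinds (`"NOAS2"`, `"CLAHE"`) are refused by every
#' quantitative operation.
#'
#' @param image Numeric matrix of intensities (rows = y, cols = x).
#' @param wavenumber_cm1 Excitation wavenumber.
#' @param step_um Scan step in micrometers.
#' @param intensity_kind One of `"MAP"`, `"depth_gated"`, `"NOAS2"`,
#'   `"CLAHE"`.
#' @param provenance Optional list of gate/processing parameters.
#' @return An object of class `micrograph`.
#' @export
micrograph <- function(image, wavenumber_cm1, step_um,
                       intensity_kind = c("depth_gated", "MAP", "NOAS2",
                                          "CLAHE"),
                       provenance = list()) {
  intensity_kind <- match.arg(intensity_kind)
  if (!is.matrix(image) || !all(is.finite(image)))
    stop("image must be a finite numeric matrix")
  if (step_um <= 0) stop("step_um must be positive")
  if (intensity_kind == "NOAS2" &&
      (min(image) < 0 || max(image) > 1))
    stop("NOAS2 images must lie in [0, 1]")
  structure(list(image = image, wavenumber_cm1 = wavenumber_cm1,
                 step_um = step_um, intensity_kind = intensity_kind,
                 provenance = provenance),
            class = "micrograph")
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf("<micrograph> %d x %d px @ %g um, %g cm^-1 (%s)\n",
              nrow(x$image), ncol(x$image), x$step_um, x$wavenumber_cm1,
              x$intensity_kind))
  invisible(x)
}

display_kinds <- c("NOAS2", "CLAHE")

assert_quantitative <- function(m, what) {
  if (m$intensity_kind %in% display_kinds)
    stop(sprintf("%s requires raw MAP or depth-gated intensities, not %s (display-only)",
                 what, m$intensity_kind))
}

#' Assemble a micrograph from a hypercube
#'
#' Extracts the requested intensity plane (depth-gated or peak-to-peak MAP)
#' at one wavenumber, in raster scan order.
#'
#' @param cube A [render_hypercube()] result (or compatible `hypercube`).
#' @param wavenumber Wavenumber in cm^-1; must be present in the cube.
#' @param kind `"depth_gated"` or `"MAP"`.
#' @return A [micrograph()].
#' @export
assemble_micrograph <- function(cube, wavenumber,
                                kind = c("depth_gated", "MAP")) {
  kind <- match.arg(kind)
  stopifnot(inherits(cube, "hypercube"))
  i <- match(wavenumber, cube$wavenumbers)
  if (is.na(i))
    stop(sprintf("wavenumber %g cm^-1 not present in the cube", wavenumber))
  img <- if (kind == "depth_gated") cube$gated[, , i] else cube$map[, , i]
  micrograph(img, wavenumber, cube$step_um, intensity_kind = kind,
             provenance = cube$gate)
}

#' Normalized squared OA intensity (NOAS^2)
#'
#' Min-max normalizes the image over the field of view and squares it:
#' `((I - min) / (max - min))^2`, mapping the FOV minimum to 0 and maximum
#' to 1.  A display-only contrast enhancement; the result is refused by the
#' quantitative operations.
#'
#' @param m A [micrograph()] with nonzero dynamic range.
#' @return A `micrograph` of kind `"NOAS2"` with values in `[0, 1]`.
#' @export
noas_squared <- function(m) {
  stopifnot(inherits(m, "micrograph"))
  rng <- range(m$image)
  if (diff(rng) == 0)
    stop("constant image: zero dynamic range, NOAS^2 undefined")
  img <- ((m$image - rng[1]) / diff(rng))^2
  micrograph(img, m$wavenumber_cm1, m$step_um, "NOAS2",
             provenance = c(m$provenance, list(noas_from = m$intensity_kind)))
}

#' Contrast-limited adaptive histogram equalization
#'
#' Standard CLAHE (via EBImage) on a NOAS^2 image; display-only.
#'
#' @param m A `micrograph` of kind `"NOAS2"`.
#' @param tiles Tile grid `(nx, ny)`.
#' @param clip Clip limit as a fraction of the per-tile histogram (scaled
#'   onto EBImage's `limit = clip * bins` convention).
#' @param bins Number of histogram bins.
#' @return A `micrograph` of kind `"CLAHE"` with values in `[0, 1]`.
#' @export
clahe_micrograph <- function(m, tiles = c(8, 8), clip = 0.01, bins = 256L) {
  stopifnot(inherits(m, "micrograph"))
  if (m$intensity_kind != "NOAS2")
    stop("CLAHE is applied to NOAS2 images")
  if (diff(range(m$image)) == 0) {
    img <- m$image
  } else {
    # EBImage needs dimensions divisible by the tile grid: pad by edge
    # replication, equalize, crop back
    ny <- nrow(m$image); nx <- ncol(m$image)
    py <- (tiles[2] - ny %% tiles[2]) %% tiles[2]
    px <- (tiles[1] - nx %% tiles[1]) %% tiles[1]
    padded <- m$image[c(seq_len(ny), rep(ny, py)),
                      c(seq_len(nx), rep(nx, px)), drop = FALSE]
    img <- EBImage::clahe(padded, nx = tiles[1], ny = tiles[2],
                          bins = bins, limit = max(1, clip * bins),
                          keep.range = TRUE)
    img <- matrix(pmin(1, pmax(0, img[seq_len(ny), seq_len(nx)])), ny)
  }
  micrograph(img, m$wavenumber_cm1, m$step_um, "CLAHE",
             provenance = c(m$provenance,
                            list(clahe_tiles = tiles, clahe_clip = clip)))
}

#' Adipocyte segmentation mask by quantile thresholding
#'
#' Masks the pixels brighter than the first quartile (25% quantile, linear
#' interpolation between order statistics) of a calibration iBAT micrograph
#' at 2856 cm^-1, or brighter than an explicit threshold.  Presumes the
#' calibration field is dominated by adipocytes, as real brown fat is.
#'
#' @param m Target [micrograph()] (MAP or depth-gated).
#' @param calibration Calibration `micrograph` of the same intensity kind.
#' @param threshold Explicit threshold overriding the calibration.
#' @return Logical matrix with attributes `threshold` and `step_um`.
#' @export
adipocyte_mask <- function(m, calibration = NULL, threshold = NULL) {
  stopifnot(inherits(m, "micrograph"))
  assert_quantitative(m, "adipocyte_mask")
  if (is.null(threshold)) {
    if (is.null(calibration))
      stop("provide either a calibration micrograph or an explicit threshold")
    stopifnot(inherits(calibration, "micrograph"))
    if (calibration$intensity_kind != m$intensity_kind)
      stop("calibration and target must share the same intensity kind")
    threshold <- stats::quantile(calibration$image, 0.25, names = FALSE,
                                 type = 7)
  }
  mask <- m$image > threshold
  attr(mask, "threshold") <- threshold
  attr(mask, "step_um") <- m$step_um
  mask
}

# 8-connected labeling of a logical mask via graph components.
label_components8 <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  idx <- which(mask)
  if (!length(idx)) return(lab)
  r <- (idx - 1L) %% ny + 1L
  c <- (idx - 1L) %/% ny + 1L
  pos <- matrix(0L, ny, nx); pos[idx] <- seq_along(idx)
  edges <- integer(0)
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- r + d[1]; c2 <- c + d[2]
    ok <- r2 >= 1L & r2 <= ny & c2 >= 1L & c2 <= nx
    ok[ok] <- mask[cbind(r2[ok], c2[ok])]
    if (any(ok))
      edges <- c(edges, rbind(pos[cbind(r[ok], c[ok])],
                              pos[cbind(r2[ok], c2[ok])]))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  lab[idx] <- comp
  lab
}

#' Label and measure adipocytes
#'
#' 8-connected components of the segmentation mask, filtered by a minimum
#' area, with per-cell morphometry: centroid, pixel area, equivalent
#' diameter `2 * sqrt(area / pi)`, and the mean intensity in any supplied
#' channel micrographs (the digitally isolated per-cell contrast).
#'
#' @param mask Logical matrix from [adipocyte_mask()].
#' @param m The micrograph the mask was derived from (for geometry).
#' @param min_area_um2 Components below this area are discarded (default:
#'   the area of a 5 um disk, suppressing single-pixel speckle).
#' @param channels Optional named list of micrographs to average per cell.
#' @return A `data.frame` (class `adipocyte_table`) with one row per cell
#'   and attributes `density_per_mm2`, `fov_area_mm2`, `masked_fraction`,
#'   `threshold`.
#' @export
label_and_measure <- function(mask, m, min_area_um2 = pi * 2.5^2,
                              channels = list()) {
  stopifnot(inherits(m, "micrograph"))
  assert_quantitative(m, "label_and_measure")
  if (!all(dim(mask) == dim(m$image)))
    stop("mask and micrograph dimensions differ")
  step <- m$step_um
  px_area <- step^2
  fov_area_mm2 <- prod(dim(mask)) * px_area / 1e6
  lab <- label_components8(mask)
  empty <- data.frame(id = integer(0), centroid_x_um = numeric(0),
                      centroid_y_um = numeric(0), area_um2 = numeric(0),
                      equivalent_diameter_um = numeric(0))
  for (nm in names(channels)) empty[[paste0("mean_", nm)]] <- numeric(0)
  if (max(lab) == 0L) {
    tab <- empty
  } else {
    areas <- tabulate(lab)
    keep <- which(areas * px_area >= min_area_um2)
    if (!length(keep)) {
      tab <- empty
    } else {
      idx <- which(lab > 0L & matrix(lab %in% keep, nrow(lab)))
      comp <- match(lab[idx], keep)
      ny <- nrow(lab)
      rr <- (idx - 1L) %% ny + 1L
      cc <- (idx - 1L) %/% ny + 1L
      area_px <- tabulate(comp)
      tab <- data.frame(
        id = seq_along(keep),
        centroid_x_um = tapply((cc - 1) * step, comp, mean),
        centroid_y_um = tapply((rr - 1) * step, comp, mean),
        area_um2 = area_px * px_area,
        equivalent_diameter_um = 2 * sqrt(area_px * px_area / pi)
      )
      for (nm in names(channels)) {
        ch <- channels[[nm]]
        stopifnot(inherits(ch, "micrograph"))
        assert_quantitative(ch, "label_and_measure channel")
        tab[[paste0("mean_", nm)]] <-
          as.numeric(tapply(ch$image[idx], comp, mean))
      }
      rownames(tab) <- NULL
    }
  }
  attr(tab, "density_per_mm2") <- nrow(tab) / fov_area_mm2
  attr(tab, "fov_area_mm2") <- fov_area_mm2
  attr(tab, "masked_fraction") <- mean(mask)
  attr(tab, "threshold") <- attr(mask, "threshold")
  class(tab) <- c("adipocyte_table", "data.frame")
  tab
}

#' Digitally isolated contrast
#'
#' Mean intensity of a micrograph over the masked (adipocyte) pixels.
#'
#' @param m A quantitative [micrograph()].
#' @param mask Logical matrix; must contain at least one `TRUE` pixel.
#' @return Mean masked intensity (a.u.).
#' @export
isolated_contrast <- function(m, mask) {
  stopifnot(inherits(m, "micrograph"))
  assert_quantitative(m, "isolated_contrast")
  if (!any(mask)) stop("empty mask: no pixels to isolate")
  mean(m$image[mask])
}
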