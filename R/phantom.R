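# Tissue phantom generator: ground-truthed adipose phantoms whose adipocyte
# size distributions, densities and class spectra emulate epididymal white
# (eWAT), interscapular brown (iBAT) and postnatally remodeling inguinal
# white (iWAT) fat.

# per-tissue adipocyte defaults: diameter mean/SD (um) and density (/mm^2).
# eWAT 50 +/- 15 um and iBAT 16 +/- 6 um reproduce the measured size
# distributions; absolute densities are chosen at an 8.5x iBAT:eWAT ratio
# with packing fractions safely below the jamming limit of gapped disks.
tissue_defaults <- list(
  eWAT = list(diam = c(50, 15), density = 82, class = "WAT_adipocyte"),
  iBAT = list(diam = c(16, 6), density = 697, class = "BAT_adipocyte"),
  iWAT = list(diam_wat = c(45, 12), diam_bat = c(18, 6), density = 180)
)

# fraction of BAT-like adipocytes in iWAT by postnatal week: browning
# (weeks 2-4) then whitening (weeks 4-6)
iwat_mixing_fraction <- function(week) {
  f <- c(`2` = 0.15, `3` = 0.45, `4` = 0.80, `5` = 0.50, `6` = 0.20)
  key <- as.character(week)
  if (!key %in% names(f)) stop("week must be one of 2..6")
  unname(f[key])
}

#' Phantom generation parameters
#'
#' Describes one synthetic adipose-tissue phantom: field of view, scan step,
#' tissue type, adipocyte diameter distribution and target density, class
#' template spectra, absorber depths, per-pulse noise level and packing mode.
#'
#' @param tissue_type `"eWAT"`, `"iBAT"` or `"iWAT"`.
#' @param week Postnatal week (2-6), used only for `"iWAT"` phantoms to set
#'   the BAT-like mixing fraction.
#' @param fov_um Field of view `(height, width)` in micrometers.
#' @param step_um Scan step in micrometers.
#' @param cell_diameter_mean_um,cell_diameter_sd_um Adipocyte diameter
#'   distribution; defaults are tissue-specific.  For iWAT these are
#'   2-vectors `(WAT-like, BAT-like)`.
#' @param cell_density_per_mm2 Target adipocyte count per mm^2 (>= 0).
#' @param bat_fraction Fraction of BAT-like adipocytes (iWAT only; defaults
#'   to the week-dependent browning/whitening schedule).
#' @param class_templates Named list of class template spectra over
#'   `wavenumbers` (defaults to [tissue_templates()]).
#' @param depth_profile Named per-class absorber depth in micrometers.
#' @param noise_sd Additive Gaussian noise SD per single pulse (a.u.).
#' @param packing `"gapped"` (non-overlapping disks with an ECM gap of
#'   `gap_px` pixels; exact ground truth) or `"dense"` (overlapping darts up
#'   to `coverage_target`; emulates the near-confluent adipocyte coverage of
#'   real fat for threshold calibration).
#' @param gap_px Minimum ECM gap between disks, in pixels (gapped mode).
#' @param coverage_target Adipocyte pixel coverage to reach in dense mode.
#' @param diameter_min_um Lower truncation of the diameter distribution.
#' @param include_structures Add lymph-node / connective / water / void
#'   regions (default `TRUE` for iWAT, `FALSE` otherwise).
#' @param seed Integer seed; phantoms are bit-reproducible for a fixed seed.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(tissue_type = c("eWAT", "iBAT", "iWAT"),
                           week = 4,
                           fov_um = c(1000, 1000),
                           step_um = 5,
                           cell_diameter_mean_um = NULL,
                           cell_diameter_sd_um = NULL,
                           cell_density_per_mm2 = NULL,
                           bat_fraction = NULL,
                           class_templates = NULL,
                           depth_profile = NULL,
                           noise_sd = 0.15,
                           packing = c("gapped", "dense"),
                           gap_px = 1.5,
                           coverage_target = 0.8,
                           diameter_min_um = 6,
                           include_structures = NULL,
                           seed = 0L) {
  tissue_type <- match.arg(tissue_type)
  packing <- match.arg(packing)
  def <- tissue_defaults[[tissue_type]]
  if (tissue_type == "iWAT") {
    dm <- cell_diameter_mean_um %||% c(def$diam_wat[1], def$diam_bat[1])
    ds <- cell_diameter_sd_um %||% c(def$diam_wat[2], def$diam_bat[2])
    bf <- bat_fraction %||% iwat_mixing_fraction(week)
    incl <- include_structures %||% TRUE
  } else {
    dm <- cell_diameter_mean_um %||% def$diam[1]
    ds <- cell_diameter_sd_um %||% def$diam[2]
    bf <- if (tissue_type == "iBAT") 1 else 0
    incl <- include_structures %||% FALSE
  }
  dens <- cell_density_per_mm2 %||% def$density
  if (any(fov_um <= 0) || step_um <= 0) stop("fov and step must be positive")
  if (any(ds >= dm)) stop("diameter SD must be smaller than the mean")
  if (dens < 0) stop("density must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  depth_profile <- depth_profile %||%
    stats::setNames(rep(150, length(phantom_classes)), phantom_classes)
  structure(list(
    tissue_type = tissue_type, week = week, fov_um = fov_um,
    step_um = step_um,
    cell_diameter_mean_um = dm, cell_diameter_sd_um = ds,
    cell_density_per_mm2 = dens, bat_fraction = bf,
    class_templates = class_templates,
    depth_profile = depth_profile, noise_sd = noise_sd,
    packing = packing, gap_px = gap_px, coverage_target = coverage_target,
    diameter_min_um = diameter_min_um, include_structures = incl,
    seed = as.integer(seed)
  ), class = "phantom_params")
}

# deterministic structure regions for iWAT phantoms, in fractional FOV
# coordinates; returns an integer matrix of class codes (0 = ECM base)
structure_regions <- function(ny, nx) {
  lab <- matrix(0L, ny, nx)
  ri <- (row(lab) - 0.5) / ny
  ci <- (col(lab) - 0.5) / nx
  code <- function(cls) match(cls, phantom_classes)
  # connective ribbons: one diagonal, one shallow band
  lab[abs(ri - (0.15 + 0.55 * ci)) < 0.022] <- code("connective")
  lab[abs(ri - (0.85 - 0.25 * ci)) < 0.022] <- code("connective")
  # lymph node: ellipse
  el <- ((ri - 0.30) / 0.13)^2 + ((ci - 0.68) / 0.11)^2 <= 1
  lab[el] <- code("lymph_node")
  # water strip along the bottom, void corner top-left
  lab[ri > 0.92] <- code("water")
  lab[ri < 0.15 & ci < 0.15] <- code("void")
  lab
}

#' Generate a ground-truthed tissue phantom
#'
#' Places adipocyte disks sampled from the tissue's diameter distribution by
#' dart throwing.  In `"gapped"` mode disks are rejected unless separated
#' from all accepted disks by at least `gap_px` pixels of ECM, giving exact
#' per-cell ground truth; placement stops when the target density is reached
#' and fails loudly if it cannot be.  In `"dense"` mode darts may overlap
#' and placement stops at the requested pixel coverage (used to calibrate
#' segmentation thresholds on a near-confluent reference, as in real brown
#' fat).  Remaining pixels are ECM; iWAT phantoms optionally carry lymph
#' node, connective tissue, water and void regions.
#'
#' @param params A [phantom_params()] object.
#' @return An object of class `phantom`: `label_map` (integer matrix of
#'   class codes with levels `phantom_classes`), `cell_table` (one row per
#'   placed adipocyte: id, class, centroid in um, true diameter, pixel
#'   count), `depth_map` (um) and `params`.
#' @export
generate_phantom <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  step <- params$step_um
  ny <- round(params$fov_um[1] / step)
  nx <- round(params$fov_um[2] / step)
  ecm_code <- match("ECM", phantom_classes)
  lab <- matrix(ecm_code, ny, nx)
  if (params$include_structures) {
    sr <- structure_regions(ny, nx)
    lab[sr > 0] <- sr[sr > 0]
  }
  forbidden <- lab != ecm_code
  area_mm2 <- prod(params$fov_um) / 1e6
  n_target <- round(params$cell_density_per_mm2 * area_mm2)
  # pixel center coordinates in um (0-based convention: index * step)
  px_y <- (seq_len(ny) - 1) * step
  px_x <- (seq_len(nx) - 1) * step
  gap_um <- params$gap_px * step

  res <- with_seed(params$seed, {
    acc_x <- acc_y <- acc_r <- numeric(0)
    acc_cls <- acc_npx <- integer(0)
    dense <- params$packing == "dense"
    covered <- 0L
    n_px <- ny * nx
    lab_work <- lab

    draw_cell <- function() {
      is_bat <- stats::runif(1) < params$bat_fraction
      dm <- params$cell_diameter_mean_um
      ds <- params$cell_diameter_sd_um
      if (length(dm) == 2) {  # iWAT mixture
        mu <- if (is_bat) dm[2] else dm[1]
        sg <- if (is_bat) ds[2] else ds[1]
      } else {
        mu <- dm; sg <- ds
      }
      d <- rtrunc_norm(1, mu, sg, params$diameter_min_um, mu + 3.5 * sg)
      cls <- match(if (is_bat) "BAT_adipocyte" else "WAT_adipocyte",
                   phantom_classes)
      c(d = d, cls = cls)
    }

    # rasterize a disk, claiming only unclaimed ECM pixels; returns count
    claim <- function(cx, cy, r, cls) {
      rows <- which(abs(px_y - cy) <= r)
      cols <- which(abs(px_x - cx) <= r)
      claimed <- 0L
      if (length(rows) && length(cols)) {
        inside <- outer((px_y[rows] - cy)^2, (px_x[cols] - cx)^2, "+") <= r^2
        if (any(inside)) {
          sel <- cbind(rep(rows, times = ncol(inside))[as.vector(inside)],
                       rep(cols, each = nrow(inside))[as.vector(inside)])
          fresh <- lab_work[sel] == ecm_code
          claimed <- sum(fresh)
          lab_work[sel[fresh, , drop = FALSE]] <<- cls
        }
      }
      if (claimed == 0L && !dense) {
        # tiny disk missed every pixel center: claim the nearest pixel so
        # every ground-truth cell remains visible in the label map
        rr <- which.min(abs(px_y - cy)); cc <- which.min(abs(px_x - cx))
        if (lab_work[rr, cc] == ecm_code) {
          lab_work[rr, cc] <<- cls
          claimed <- 1L
        }
      }
      claimed
    }

    hits_structure <- function(cx, cy, r) {
      if (!params$include_structures) return(FALSE)
      mrows <- which(abs(px_y - cy) <= r + 2 * step)
      mcols <- which(abs(px_x - cx) <= r + 2 * step)
      length(mrows) > 0 && length(mcols) > 0 &&
        any(forbidden[mrows, mcols])
    }

    if (!dense) {
      # draw the full ground-truth diameter list first so the placed-cell
      # size distribution is exactly the requested one, then place largest
      # first (sequential packing with per-cell retries)
      cells <- if (n_target > 0)
        t(vapply(seq_len(n_target), function(i) draw_cell(), c(d = 1, cls = 1)))
      else matrix(numeric(0), 0, 2, dimnames = list(NULL, c("d", "cls")))
      ord <- order(cells[, "d"], decreasing = TRUE)
      cells <- cells[ord, , drop = FALSE]
      per_cell_attempts <- 4000L
      for (i in seq_len(nrow(cells))) {
        r <- cells[i, "d"] / 2
        placed <- FALSE
        for (a in seq_len(per_cell_attempts)) {
          cx <- stats::runif(1, r, params$fov_um[2] - r)
          cy <- stats::runif(1, r, params$fov_um[1] - r)
          if (length(acc_r) &&
              any((acc_x - cx)^2 + (acc_y - cy)^2 <
                  (acc_r + r + gap_um)^2)) next
          if (hits_structure(cx, cy, r)) next
          placed <- TRUE
          break
        }
        if (!placed) {
          stop(sprintf(paste0("packing failure: placed %d of %d cells ",
                              "(achieved density %.1f of %.1f per mm^2)"),
                       length(acc_r), n_target, length(acc_r) / area_mm2,
                       params$cell_density_per_mm2))
        }
        covered <- covered + (npx_i <- claim(cx, cy, r, cells[i, "cls"]))
        acc_x <- c(acc_x, cx); acc_y <- c(acc_y, cy); acc_r <- c(acc_r, r)
        acc_cls <- c(acc_cls, cells[i, "cls"]); acc_npx <- c(acc_npx, npx_i)
      }
    } else {
      max_attempts <- 200000L
      attempts <- 0L
      while (covered / n_px < params$coverage_target &&
             attempts < max_attempts) {
        attempts <- attempts + 1L
        cell <- draw_cell()
        r <- cell["d"] / 2
        cx <- stats::runif(1, r, params$fov_um[2] - r)
        cy <- stats::runif(1, r, params$fov_um[1] - r)
        if (hits_structure(cx, cy, r)) next
        npx_i <- claim(cx, cy, r, cell["cls"])
        if (npx_i == 0L) next  # fully covered dart: not a cell
        covered <- covered + npx_i
        acc_x <- c(acc_x, cx); acc_y <- c(acc_y, cy); acc_r <- c(acc_r, r)
        acc_cls <- c(acc_cls, cell["cls"]); acc_npx <- c(acc_npx, npx_i)
      }
      if (covered / n_px < params$coverage_target)
        stop(sprintf("dense packing failure: coverage %.2f of %.2f",
                     covered / n_px, params$coverage_target))
    }
    list(lab = lab_work, x = acc_x, y = acc_y, r = acc_r, cls = acc_cls,
         npx = acc_npx)
  })

  lab <- res$lab
  storage.mode(lab) <- "integer"
  n_cells <- length(res$r)
  cell_table <- data.frame(
    id = seq_len(n_cells),
    class = phantom_classes[res$cls],
    center_x_um = res$x, center_y_um = res$y,
    true_diameter_um = 2 * res$r,
    n_pixels = res$npx,
    stringsAsFactors = FALSE
  )
  depth_map <- matrix(params$depth_profile[phantom_classes[lab]], ny, nx)
  structure(list(label_map = structure(lab, classes = phantom_classes),
                 cell_table = cell_table, depth_map = depth_map,
                 params = params),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %s, %dx%d px @ %g um, %d cells (seed %d)\n",
              x$params$tissue_type, nrow(x$label_map), ncol(x$label_map),
              x$params$step_um, nrow(x$cell_table), x$params$seed))
  invisible(x)
}
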