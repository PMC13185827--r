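# Standard, inspectable on-disk formats: hypercubes as long-format CSV with
# a YAML sidecar (lossless double round-trip via readr), micrographs and
# score maps as 32-bit TIFF, tables as CSV, scorer models as YAML with
# hex-float weights, run configuration and records as YAML.

#' Write / read a hypercube
#'
#' `write_hypercube()` stores the gated and MAP planes as a long-format CSV
#' (`row`, `col`, `wavenumber_cm1`, `gated`, `map`; 0-based pixel indices)
#' next to a YAML sidecar (`<base>.yaml`) holding the scan geometry, gate
#' provenance and, when present, the raw transients in a third file
#' (`<base>_raw.csv`).  `read_hypercube()` restores the object; arrays
#' round-trip bit-identically.
#'
#' @param cube A `hypercube`.
#' @param base Path base name (without extension).
#' @return `write_hypercube` returns `base` invisibly; `read_hypercube`
#'   returns a `hypercube`.
#' @export
write_hypercube <- function(cube, base) {
  stopifnot(inherits(cube, "hypercube"))
  ny <- dim(cube$gated)[1]; nx <- dim(cube$gated)[2]
  nw <- dim(cube$gated)[3]
  # intensities as C99 hex-float strings: plain text, bit-exact round trip
  df <- data.frame(
    row = rep(rep(seq_len(ny) - 1L, nx), nw),
    col = rep(rep(seq_len(nx) - 1L, each = ny), nw),
    wavenumber_cm1 = rep(cube$wavenumbers, each = ny * nx),
    gated = sprintf("%a", as.vector(cube$gated)),
    map = sprintf("%a", as.vector(cube$map))
  )
  readr::write_csv(df, paste0(base, ".csv"), progress = FALSE)
  meta <- list(
    shape = c(ny, nx, nw),
    wavenumbers = cube$wavenumbers,
    step_um = cube$step_um,
    gate = cube$gate,
    has_raw = !is.null(cube$raw),
    acq = unclass(cube$acq)
  )
  yaml::write_yaml(meta, paste0(base, ".yaml"))
  if (!is.null(cube$raw)) {
    raw_df <- do.call(rbind, lapply(seq_len(nw), function(i) {
      R <- cube$raw[[i]]
      data.frame(wavenumber_cm1 = cube$wavenumbers[i],
                 pixel = rep(seq_len(ncol(R)) - 1L, each = nrow(R)),
                 sample = rep(seq_len(nrow(R)) - 1L, ncol(R)),
                 value = sprintf("%a", as.vector(R)))
    }))
    readr::write_csv(raw_df, paste0(base, "_raw.csv"), progress = FALSE)
  }
  invisible(base)
}

#' @rdname write_hypercube
#' @export
read_hypercube <- function(base) {
  yml <- paste0(base, ".yaml")
  csv <- paste0(base, ".csv")
  if (!file.exists(yml)) stop("missing hypercube sidecar: ", yml)
  if (!file.exists(csv)) stop("missing hypercube data: ", csv)
  meta <- yaml::read_yaml(yml)
  need <- c("shape", "wavenumbers", "step_um")
  if (!all(need %in% names(meta)))
    stop("corrupt hypercube sidecar: missing ",
         paste(setdiff(need, names(meta)), collapse = ", "))
  shape <- as.integer(unlist(meta$shape))
  wn <- as.numeric(unlist(meta$wavenumbers))
  df <- readr::read_csv(csv, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) != prod(shape))
    stop(sprintf("hypercube shape mismatch: sidecar %d pixels, file %d rows",
                 prod(shape), nrow(df)))
  gated <- array(as.numeric(df$gated), shape)
  mapint <- array(as.numeric(df$map), shape)
  raw <- NULL
  if (isTRUE(meta$has_raw) && file.exists(paste0(base, "_raw.csv"))) {
    raw_df <- readr::read_csv(paste0(base, "_raw.csv"),
                              show_col_types = FALSE, progress = FALSE)
    raw <- lapply(seq_along(wn), function(i) {
      v <- as.numeric(raw_df$value[raw_df$wavenumber_cm1 == wn[i]])
      matrix(v, ncol = shape[1] * shape[2])
    })
  }
  acq <- do.call(acq_params, meta$acq[c("fs_hz", "prf_hz",
                                        "pulses_per_pixel",
                                        "sound_speed_m_s",
                                        "pulse_center_freq_hz",
                                        "record_len_samples",
                                        "frame_time_min_per_wavenumber")])
  structure(list(gated = gated, map = mapint, wavenumbers = wn,
                 step_um = meta$step_um, acq = acq, gate = meta$gate,
                 raw = raw, phantom = NULL),
            class = "hypercube")
}

#' Write / read a micrograph as 32-bit TIFF
#'
#' Stores the intensity image as a single-plane 32-bit float TIFF; step
#' size, wavenumber and intensity kind travel in a YAML sidecar (TIFF tag
#' support in R writers is too limited for arbitrary metadata).  Values are
#' stored as single-precision floats.
#'
#' @param m A [micrograph()].
#' @param path TIFF path; the sidecar is `<path>.yaml`.
#' @return `write_micrograph` returns `path` invisibly.
#' @export
write_micrograph <- function(m, path) {
  stopifnot(inherits(m, "micrograph"))
  lo <- min(m$image); hi <- max(m$image)
  img01 <- if (hi > lo) (m$image - lo) / (hi - lo) else m$image * 0
  tiff::writeTIFF(img01, path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  yaml::write_yaml(list(wavenumber_cm1 = m$wavenumber_cm1,
                        step_um = m$step_um,
                        intensity_kind = m$intensity_kind,
                        range = c(lo, hi),   # TIFF stores (I - lo)/(hi - lo)
                        provenance = m$provenance),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_micrograph
#' @export
read_micrograph <- function(path) {
  img <- tiff::readTIFF(path, as.is = FALSE)
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  rng <- as.numeric(unlist(meta$range %||% c(0, 1)))
  img <- img * (rng[2] - rng[1]) + rng[1]
  micrograph(matrix(as.numeric(img), nrow(img)),
             meta$wavenumber_cm1, meta$step_um,
             intensity_kind = meta$intensity_kind,
             provenance = meta$provenance %||% list())
}

#' Serialize / load a scorer model
#'
#' YAML bundle holding the mode, classes, wavenumbers, regularization,
#' seed, standardizer statistics and weights; all doubles are written as
#' C99 hex-float strings (`sprintf("%a")`) for bit-exact round trips.
#'
#' @param model A `scorer_model`.
#' @param path YAML file path.
#' @return `write_scorer_model` returns `path` invisibly;
#'   `read_scorer_model` the restored `scorer_model`.
#' @export
write_scorer_model <- function(model, path) {
  stopifnot(inherits(model, "scorer_model"))
  hx <- function(x) sprintf("%a", as.numeric(x))
  obj <- list(
    mode = model$mode,
    class_names = as.character(model$class_names),
    wavenumbers = hx(model$wavenumbers),
    weights = lapply(seq_len(nrow(model$weights)),
                     function(i) hx(model$weights[i, ])),
    intercepts = hx(model$intercepts),
    standardizer = list(mean = hx(model$stats$mean),
                        sd = hx(model$stats$sd)),
    reg = hx(model$reg),
    seed = model$seed
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_scorer_model
#' @export
read_scorer_model <- function(path) {
  obj <- yaml::read_yaml(path)
  unhx <- function(s) vapply(s, function(v) as.numeric(v), 1, USE.NAMES = FALSE)
  W <- do.call(rbind, lapply(obj$weights, unhx))
  rownames(W) <- obj$class_names
  new_scorer_model(obj$mode, obj$class_names, unhx(obj$wavenumbers),
                   W, unhx(obj$intercepts),
                   structure(list(mean = unhx(obj$standardizer$mean),
                                  sd = unhx(obj$standardizer$sd)),
                             class = "standardizer_stats"),
                   unhx(obj$reg), obj$seed)
}

#' Write an adipocyte table (with its per-image summary) to CSV
#'
#' @param tab An `adipocyte_table` from [label_and_measure()].
#' @param path CSV path; a `<path>.yaml` sidecar stores the density,
#'   FOV area, mask fraction and threshold.
#' @export
write_adipocyte_table <- function(tab, path) {
  readr::write_csv(as.data.frame(tab), path, progress = FALSE)
  yaml::write_yaml(list(density_per_mm2 = attr(tab, "density_per_mm2"),
                        fov_area_mm2 = attr(tab, "fov_area_mm2"),
                        masked_fraction = attr(tab, "masked_fraction"),
                        threshold = attr(tab, "threshold")),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' Write / read phantom ground truth
#'
#' Label map and depth map as long CSV, the cell table as CSV, and the
#' generator parameters echoed into a YAML sidecar for provenance.
#'
#' @param phantom A `phantom`.
#' @param base Path base name.
#' @export
write_phantom <- function(phantom, base) {
  stopifnot(inherits(phantom, "phantom"))
  lab <- phantom$label_map
  df <- data.frame(row = rep(seq_len(nrow(lab)) - 1L, ncol(lab)),
                   col = rep(seq_len(ncol(lab)) - 1L, each = nrow(lab)),
                   class = phantom_classes[as.vector(lab)],
                   depth_um = as.vector(phantom$depth_map))
  readr::write_csv(df, paste0(base, "_labels.csv"), progress = FALSE)
  readr::write_csv(phantom$cell_table, paste0(base, "_cells.csv"),
                   progress = FALSE)
  p <- phantom$params
  p$class_templates <- NULL  # regenerated from code; keep the sidecar small
  yaml::write_yaml(unclass(p), paste0(base, "_params.yaml"))
  invisible(base)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(base) {
  df <- readr::read_csv(paste0(base, "_labels.csv"),
                        show_col_types = FALSE, progress = FALSE)
  cells <- as.data.frame(readr::read_csv(paste0(base, "_cells.csv"),
                                         show_col_types = FALSE,
                                         progress = FALSE))
  p <- yaml::read_yaml(paste0(base, "_params.yaml"))
  ny <- max(df$row) + 1L; nx <- max(df$col) + 1L
  lab <- matrix(match(df$class, phantom_classes), ny, nx)
  depth <- matrix(df$depth_um, ny, nx)
  params <- phantom_params(
    tissue_type = p$tissue_type, week = p$week,
    fov_um = as.numeric(unlist(p$fov_um)), step_um = p$step_um,
    cell_diameter_mean_um = as.numeric(unlist(p$cell_diameter_mean_um)),
    cell_diameter_sd_um = as.numeric(unlist(p$cell_diameter_sd_um)),
    cell_density_per_mm2 = p$cell_density_per_mm2,
    bat_fraction = p$bat_fraction, noise_sd = p$noise_sd,
    packing = p$packing, gap_px = p$gap_px,
    coverage_target = p$coverage_target,
    diameter_min_um = p$diameter_min_um,
    include_structures = p$include_structures, seed = p$seed)
  structure(list(label_map = structure(lab, classes = phantom_classes),
                 cell_table = cells, depth_map = depth, params = params),
            class = "phantom")
}
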