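# Cell/bead morphometry: spherocylinder volume, image segmentation and
# per-object length/width measurement, population summaries.

#' Spherocylinder (capped-cylinder) volume of a rod-shaped cell
#'
#' The cell is modeled as a cylinder of width `w` capped by two
#' half-spheres, giving
#' \deqn{V = \pi w^2 (l - w/3) / 4}
#' with length `l` and width `w` in um and V in fl (1 fl = 1 um^3).
#' At `l = w` this reduces to the sphere volume \eqn{\pi w^3 / 6}.
#'
#' @param length_um cell length(s), um; must satisfy `length_um >= width_um`.
#' @param width_um cell width(s), um; strictly positive. Recycled.
#' @return volume(s) in fl.
#' @examples
#' capped_cylinder_volume(3.0, 1.26)  # ~3.2 fl (glucose-grown cells)
#' @export
capped_cylinder_volume <- function(length_um, width_um) {
  n <- max(length(length_um), length(width_um))
  l <- rep_len(length_um, n); w <- rep_len(width_um, n)
  if (any(!is.finite(l)) || any(!is.finite(w)) || any(w <= 0) || any(l <= 0))
    stop("length and width must be finite and positive", call. = FALSE)
  if (any(l < w))
    stop("length < width: the capped-cylinder formula assumes a rod ",
         "(l >= w)", call. = FALSE)
  pi * w^2 * (l - w / 3) / 4
}

#' Segment a fluorescence image and measure object dimensions
#'
#' Pipeline: automatic (Otsu) threshold, 8-connected component labeling,
#' area filter, optional exclusion of border-touching objects (their full
#' length cannot be measured), then per-object length and width as the
#' extents along the principal axes of the object's pixel cloud, converted
#' to um.
#'
#' An image whose foreground fraction after thresholding exceeds
#' `max_foreground_frac` is treated as containing no objects (a blank,
#' noise-only image splits roughly in half at the Otsu threshold); a
#' constant image is an error.
#'
#' @param image single-channel numeric/integer matrix.
#' @param pixel_um um per pixel (> 0).
#' @param min_area_px discard components smaller than this (noise specks).
#' @param exclude_border discard objects touching the image border
#'   (default TRUE).
#' @param max_foreground_frac sanity cap on the foreground fraction.
#' @return data.frame with one row per retained object: `object_id`,
#'   `length_um`, `width_um`, `centroid_x_px`, `centroid_y_px`, `area_px`.
#'   Empty (zero rows) for images without measurable objects.
#' @examples
#' out <- render_cells(image_spec(n_cells = 2, seed = 11))
#' segment_and_measure(out$image, 0.092)
#' @export
segment_and_measure <- function(image, pixel_um, min_area_px = 25L,
                                exclude_border = TRUE,
                                max_foreground_frac = 0.35) {
  stopifnot(is.matrix(image), is.numeric(image) || is.integer(image),
            pixel_um > 0)
  empty <- data.frame(object_id = integer(0), length_um = numeric(0),
                      width_um = numeric(0), centroid_x_px = numeric(0),
                      centroid_y_px = numeric(0), area_px = integer(0))
  thr <- otsu_threshold(image)  # errors on constant image
  fg <- image > thr
  if (mean(fg) > max_foreground_frac || !any(fg)) return(empty)
  labels <- label_components(fg)
  nlab <- max(labels)
  rows_list <- vector("list", nlab)
  idx <- which(labels > 0L)
  if (length(idx) == 0L) return(empty)
  rr <- ((idx - 1L) %% nrow(labels)) + 1L
  cc <- ((idx - 1L) %/% nrow(labels)) + 1L
  lab <- labels[idx]
  out <- empty
  for (id in seq_len(nlab)) {
    sel <- lab == id
    r <- rr[sel]; c <- cc[sel]
    if (length(r) < min_area_px) next
    if (exclude_border &&
        (min(r) == 1L || min(c) == 1L ||
         max(r) == nrow(image) || max(c) == ncol(image))) next
    ax <- axis_extents(r, c)
    out <- rbind(out, data.frame(
      object_id = id,
      length_um = ax[1] * pixel_um,
      width_um = ax[2] * pixel_um,
      centroid_x_px = ax[3], centroid_y_px = ax[4],
      area_px = length(r)))
  }
  rownames(out) <- NULL
  out
}

#' Summarize a cell population's dimensions and volume
#'
#' Computes mean and SD of length and width and the per-cell
#' spherocylinder volumes. The default width policy uses the fixed
#' population-average width of 1.26 um for every cell — cell width is
#' condition-independent within measurement error, so the per-condition
#' volume is driven by length alone. `"per_cell_width"` uses each cell's
#' own measured width instead (sensitivity analysis).
#'
#' With the fixed-width policy, a measured length below the fixed width is
#' clamped to it (sphere limit) so the formula's `l >= w` precondition
#' holds; this matters only for near-spherical stationary-phase cells.
#'
#' @param measurements data.frame from [segment_and_measure()] (columns
#'   `length_um`, `width_um`).
#' @param volume_width_policy `"fixed_mean_width"` (default) or
#'   `"per_cell_width"`.
#' @param min_cells minimum population size (default 200, the measurement
#'   protocol's floor); fewer cells is an error unless
#'   `allow_below_min = TRUE`.
#' @param allow_below_min override the minimum with an explicit flag.
#' @param fixed_width_um width used by the fixed policy.
#' @return list of class `population_summary`: `n_cells`, `length_mean`,
#'   `length_sd`, `width_mean`, `width_sd`, `volume_mean`, `volume_sd`,
#'   `policy`.
#' @export
summarize_population <- function(measurements,
                                 volume_width_policy = c("fixed_mean_width",
                                                         "per_cell_width"),
                                 min_cells = 200L, allow_below_min = FALSE,
                                 fixed_width_um = od_constants()$mean_width_um) {
  volume_width_policy <- match.arg(volume_width_policy)
  stopifnot(is.data.frame(measurements),
            all(c("length_um", "width_um") %in% names(measurements)))
  n <- nrow(measurements)
  if (n < min_cells && !allow_below_min)
    stop("only ", n, " cells measured; the protocol requires at least ",
         min_cells, " cells per condition (set allow_below_min = TRUE to ",
         "override)", call. = FALSE)
  if (n == 0L) stop("no measurements", call. = FALSE)
  l <- measurements$length_um; w <- measurements$width_um
  vol <- if (volume_width_policy == "fixed_mean_width") {
    capped_cylinder_volume(pmax(l, fixed_width_um), fixed_width_um)
  } else {
    capped_cylinder_volume(pmax(l, w), w)
  }
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  structure(list(n_cells = n,
                 length_mean = mean(l), length_sd = sd0(l),
                 width_mean = mean(w), width_sd = sd0(w),
                 volume_mean = mean(vol), volume_sd = sd0(vol),
                 policy = volume_width_policy),
            class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf("Population summary (n = %d, policy = %s)\n",
              x$n_cells, x$policy))
  cat(sprintf("  length: %.2f +/- %.2f um\n", x$length_mean, x$length_sd))
  cat(sprintf("  width:  %.2f +/- %.2f um\n", x$width_mean, x$width_sd))
  cat(sprintf("  volume: %.2f +/- %.2f fl\n", x$volume_mean, x$volume_sd))
  invisible(x)
}
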