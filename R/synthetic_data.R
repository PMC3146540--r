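# Seeded synthetic-data generators.
#
# Every generator is a pure function of its spec (seed included): same spec,
# same output, bit for bit. Each artifact is returned together with its
# ground truth so the measurement pipeline can be validated without the
# truth ever entering the pipeline under test.

#' Specify a synthetic fluorescence-microscopy image
#'
#' Cells are rendered as "stadium" shapes, the 2-D projection of a rod
#' modeled as a cylinder capped by two half-spheres; beads as disks. The
#' virtual microscope applies a Gaussian point-spread function and additive
#' Gaussian read noise on a constant background, at the reference imaging
#' resolution of 0.092 um/pixel.
#'
#' @param pixel_um resolution, um per pixel.
#' @param shape image size, `c(rows, cols)` in pixels.
#' @param n_cells number of objects to place.
#' @param length_dist `c(mean, sd)` of cell length, um (normal; resampled
#'   so that length >= width > 0).
#' @param width_dist `c(mean, sd)` of cell width, um.
#' @param bead_diameter_um if non-`NULL`, objects are beads (disks) of this
#'   diameter instead of rods.
#' @param psf_sigma_um Gaussian PSF sigma, um.
#' @param foreground fluorescence level of object interiors (16-bit counts).
#' @param background background level (counts).
#' @param noise_sd SD of additive Gaussian noise (counts).
#' @param min_separation_um minimum gap between object outlines; touching
#'   objects are never rendered unless `allow_touching = TRUE` (robustness
#'   tests only — real adjacent cells had to be separated manually and the
#'   measurement pipeline does not split them).
#' @param allow_touching disable the separation guarantee.
#' @param seed RNG seed.
#' @return object of class `image_spec`.
#' @export
image_spec <- function(pixel_um = 0.092, shape = c(512L, 512L), n_cells = 20L,
                       length_dist = c(3.0, 0.7), width_dist = c(1.26, 0.16),
                       bead_diameter_um = NULL, psf_sigma_um = 0.1,
                       foreground = 20000, background = 800, noise_sd = 60,
                       min_separation_um = 0.5, allow_touching = FALSE,
                       seed = 1L) {
  stopifnot(pixel_um > 0, length(shape) == 2L, all(shape >= 16L),
            n_cells >= 0L, psf_sigma_um >= 0, noise_sd >= 0,
            foreground > background, background >= 0)
  if (min_separation_um < pixel_um && !allow_touching)
    min_separation_um <- pixel_um  # at least one pixel of clearance
  spec <- list(pixel_um = pixel_um, shape = as.integer(shape),
               n_cells = as.integer(n_cells),
               length_dist = length_dist, width_dist = width_dist,
               bead_diameter_um = bead_diameter_um,
               psf_sigma_um = psf_sigma_um, foreground = foreground,
               background = background, noise_sd = noise_sd,
               min_separation_um = min_separation_um,
               allow_touching = allow_touching, seed = as.integer(seed))
  class(spec) <- "image_spec"
  spec
}

# place n object centers s.t. bounding circles (radius r_i) plus the
# separation gap do not overlap; bounded retries.
.place_objects <- function(n, shape, radii_px, sep_px, margin_px, allow_touching) {
  xs <- numeric(0); ys <- numeric(0)
  max_tries <- 400L * max(n, 1L)
  tries <- 0L
  for (i in seq_len(n)) {
    repeat {
      tries <- tries + 1L
      if (tries > max_tries)
        stop("could not place ", n, " objects with the requested separation; ",
             "object density exceeds what the image can hold", call. = FALSE)
      x <- stats::runif(1, margin_px[i] + 1, shape[2] - margin_px[i])
      y <- stats::runif(1, margin_px[i] + 1, shape[1] - margin_px[i])
      if (allow_touching || length(xs) == 0L ||
          all(sqrt((xs - x)^2 + (ys - y)^2) >=
              radii_px[seq_along(xs)] + radii_px[i] + sep_px)) break
    }
    xs <- c(xs, x); ys <- c(ys, y)
  }
  cbind(x = xs, y = ys)
}

# draw one stadium (half-width r px around the segment p1-p2) into img and
# mask with label `id`; anti-aliased edge on img, hard edge on mask.
.draw_stadium <- function(img, mask, id, cx, cy, theta, len_px, r_px, level) {
  h <- max((len_px - 2 * r_px) / 2, 0)   # half length of the cylinder axis
  dx <- cos(theta) * h; dy <- sin(theta) * h
  p1 <- c(cx - dx, cy - dy); p2 <- c(cx + dx, cy + dy)
  pad <- ceiling(r_px + 2)
  x0 <- max(1L, floor(min(p1[1], p2[1]) - pad))
  x1 <- min(ncol(img), ceiling(max(p1[1], p2[1]) + pad))
  y0 <- max(1L, floor(min(p1[2], p2[2]) - pad))
  y1 <- min(nrow(img), ceiling(max(p1[2], p2[2]) + pad))
  xs <- x0:x1; ys <- y0:y1
  px <- matrix(rep(xs, each = length(ys)), nrow = length(ys))
  py <- matrix(rep(ys, times = length(xs)), nrow = length(ys))
  # distance from each pixel center to the segment
  vx <- p2[1] - p1[1]; vy <- p2[2] - p1[2]
  L2 <- vx^2 + vy^2
  if (L2 == 0) {
    d <- sqrt((px - p1[1])^2 + (py - p1[2])^2)
  } else {
    t <- pmin(pmax(((px - p1[1]) * vx + (py - p1[2]) * vy) / L2, 0), 1)
    d <- sqrt((px - (p1[1] + t * vx))^2 + (py - (p1[2] + t * vy))^2)
  }
  cov <- pmin(pmax(r_px - d + 0.5, 0), 1)  # linear edge anti-aliasing
  img[ys, xs] <- img[ys, xs] + level * cov
  mask[ys, xs][d <= r_px] <- id
  list(img = img, mask = mask)
}

.render <- function(spec, beads) {
  with_seed(spec$seed, {
    n <- spec$n_cells
    if (beads) {
      if (is.null(spec$bead_diameter_um))
        stop("bead_diameter_um must be set to render beads", call. = FALSE)
      if (spec$bead_diameter_um <= 2 * spec$pixel_um)
        warning("bead diameter at or below the resolvable size (",
                signif(2 * spec$pixel_um, 3), " um)")
      lens <- rep(spec$bead_diameter_um, n)
      wids <- lens
    } else if (n > 0L) {
      lens <- numeric(n); wids <- numeric(n)
      for (i in seq_len(n)) {
        for (k in 1:200) {
          l <- stats::rnorm(1, spec$length_dist[1], spec$length_dist[2])
          w <- stats::rnorm(1, spec$width_dist[1], spec$width_dist[2])
          if (l >= w && w > 0) break
          if (k == 200) stop("could not sample length >= width > 0")
        }
        lens[i] <- l; wids[i] <- w
      }
    } else {
      lens <- wids <- numeric(0)
    }
    len_px <- lens / spec$pixel_um
    rad_px <- wids / spec$pixel_um / 2
    sep_px <- spec$min_separation_um / spec$pixel_um
    half_ext <- pmax(len_px / 2, rad_px)
    pos <- if (n > 0L)
      .place_objects(n, spec$shape, half_ext, sep_px,
                     margin_px = half_ext + 2, spec$allow_touching)
    else cbind(x = numeric(0), y = numeric(0))
    theta <- if (beads) rep(0, n) else stats::runif(n, 0, pi)

    img <- matrix(0, spec$shape[1], spec$shape[2])
    mask <- matrix(0L, spec$shape[1], spec$shape[2])
    for (i in seq_len(n)) {
      dr <- .draw_stadium(img, mask, i, pos[i, 1], pos[i, 2], theta[i],
                          len_px[i], rad_px[i],
                          spec$foreground - spec$background)
      img <- dr$img; mask <- dr$mask
    }
    img <- gaussian_blur(img, spec$psf_sigma_um / spec$pixel_um)
    img <- img + spec$background +
      stats::rnorm(length(img), 0, spec$noise_sd)
    img <- matrix(pmin(pmax(round(img), 0), 65535), spec$shape[1])
    storage.mode(img) <- "integer"
    truth <- data.frame(object_id = seq_len(n),
                        length_um = lens, width_um = wids,
                        x_px = pos[, 1], y_px = pos[, 2],
                        theta = theta)
    if (beads) truth$diameter_um <- truth$length_um
    list(image = img, truth = truth, mask = mask)
  })
}

#' Render a synthetic image of rod-shaped cells
#'
#' @param spec an [image_spec()].
#' @return list with `image` (16-bit integer matrix), `truth` (data.frame of
#'   true per-object dimensions and poses) and `mask` (integer matrix of
#'   pre-blur object labels, the oracle for sub-pixel-free extents; never
#'   consumed by the measurement pipeline).
#' @examples
#' out <- render_cells(image_spec(n_cells = 3, seed = 7))
#' dim(out$image)
#' @export
render_cells <- function(spec) .render(spec, beads = FALSE)

#' Render a synthetic image of spherical beads
#'
#' @param spec an [image_spec()] with `bead_diameter_um` set.
#' @return as [render_cells()]; `truth` gains a `diameter_um` column.
#' @export
render_beads <- function(spec) .render(spec, beads = TRUE)

.default_channel_models <- function() {
  # (log10 location, log10 scale) per channel; classes are separated by
  # >= 3 log-SD in their gating projections so threshold gating is
  # unambiguous (the real gates were drawn manually; absolute scales are
  # instrument-dependent and arbitrary here).
  list(
    cell   = list(FSC = c(2.0, 0.12), SSC = c(1.8, 0.12), FL1 = c(2.6, 0.15)),
    bead   = list(FSC = c(4.0, 0.04), SSC = c(3.5, 0.04), FL1 = c(4.0, 0.05)),
    debris = list(FSC = c(0.8, 0.25), SSC = c(0.9, 0.25), FL1 = c(0.6, 0.25))
  )
}

#' Specify a synthetic flow-cytometry acquisition
#'
#' Emulates the bead-referenced counting setup: a tube holding 380 ul of
#' diluted cell suspension plus a 20 ul aliquot of counting beads, from
#' which the virtual instrument draws a fixed volume. Event counts per
#' class are Poisson in the analyzed volume; channel values are per-class
#' log-normal.
#'
#' @param true_cell_conc_per_ml true cell concentration in the measurement
#'   tube (cells/ml).
#' @param beads_total total number of beads spiked into the tube.
#' @param tube_volume_ul total tube volume (default 400 = 380 + 20).
#' @param analyzed_volume_ul volume the instrument draws.
#' @param channel_models per-class list of `c(log10 location, log10 scale)`
#'   for FSC/SSC/FL1; see `odcell:::.default_channel_models`.
#' @param debris_rate_per_ml concentration of debris events.
#' @param seed RNG seed.
#' @return object of class `event_spec`.
#' @export
event_spec <- function(true_cell_conc_per_ml = 1e6, beads_total = 20000,
                       tube_volume_ul = 400, analyzed_volume_ul = 30,
                       channel_models = .default_channel_models(),
                       debris_rate_per_ml = 1e5, seed = 1L) {
  stopifnot(true_cell_conc_per_ml >= 0, beads_total >= 0,
            tube_volume_ul > 0, analyzed_volume_ul > 0,
            analyzed_volume_ul <= tube_volume_ul, debris_rate_per_ml >= 0)
  spec <- list(true_cell_conc_per_ml = true_cell_conc_per_ml,
               beads_total = beads_total, tube_volume_ul = tube_volume_ul,
               analyzed_volume_ul = analyzed_volume_ul,
               channel_models = channel_models,
               debris_rate_per_ml = debris_rate_per_ml, seed = as.integer(seed))
  class(spec) <- "event_spec"
  spec
}

#' Generate a synthetic cytometry event table
#'
#' @param spec an [event_spec()].
#' @return list with `events` (data.frame with positive columns
#'   `FSC`, `SSC`, `FL1`, rows shuffled) and `truth` (list with `class`,
#'   a per-row factor aligned with `events`, the true
#'   `analyzed_volume_ul`, and per-class counts).
#' @examples
#' ev <- generate_events(event_spec(seed = 3))
#' table(ev$truth$class)
#' @export
generate_events <- function(spec) {
  stopifnot(inherits(spec, "event_spec"))
  vol_ml <- spec$analyzed_volume_ul * 1e-3
  lam <- c(cell = spec$true_cell_conc_per_ml * vol_ml,
           bead = spec$beads_total * spec$analyzed_volume_ul / spec$tube_volume_ul,
           debris = spec$debris_rate_per_ml * vol_ml)
  if (any(lam > 1e7))
    stop("expected event count exceeds 1e7; reduce concentration or volume",
         call. = FALSE)
  with_seed(spec$seed, {
    counts <- stats::rpois(3, lam)
    names(counts) <- names(lam)
    cls <- rep(names(counts), counts)
    draw <- function(class, channel) {
      m <- spec$channel_models[[class]][[channel]]
      10^stats::rnorm(counts[[class]], m[1], m[2])
    }
    events <- data.frame(
      FSC = unlist(lapply(names(counts), draw, channel = "FSC")),
      SSC = unlist(lapply(names(counts), draw, channel = "SSC")),
      FL1 = unlist(lapply(names(counts), draw, channel = "FL1"))
    )
    ord <- sample.int(nrow(events))
    events <- events[ord, , drop = FALSE]
    rownames(events) <- NULL
    list(events = events,
         truth = list(class = cls[ord],
                      analyzed_volume_ul = spec$analyzed_volume_ul,
                      counts = counts))
  })
}

#' Generate paired (true OD, device OD) calibration data
#'
#' Models a plate-reader-style saturating non-linearity: the device reading
#' follows the true OD at low density and saturates at high density,
#' remaining strictly monotone.
#'
#' @param n number of pairs (>= 3).
#' @param device_model list with `type` (`"saturating"` or `"identity"`),
#'   `od_sat` (saturation scale, default 2), `noise_cv` (multiplicative
#'   noise CV, default 0.01), or an element `fn`, a custom monotone
#'   function mapping true OD to device OD (checked on a grid).
#' @param od_range range of true ODs, default `c(0.001, 10)` (log-spaced).
#' @param seed RNG seed.
#' @return data.frame with columns `od_true`, `od_device`, sorted by
#'   `od_true` and monotone in it.
#' @export
generate_od_pairs <- function(n = 20L,
                              device_model = list(type = "saturating",
                                                  od_sat = 2, noise_cv = 0.01),
                              od_range = c(0.001, 10), seed = 1L) {
  if (n < 3L) stop("need at least 3 OD pairs", call. = FALSE)
  stopifnot(od_range[1] > 0, od_range[2] > od_range[1])
  fn <- if (!is.null(device_model$fn)) {
    device_model$fn
  } else if (identical(device_model$type, "identity")) {
    identity
  } else {
    K <- if (is.null(device_model$od_sat)) 2 else device_model$od_sat
    function(x) K * x / (K + x)
  }
  grid <- exp(seq(log(od_range[1]), log(od_range[2]), length.out = 101))
  if (any(diff(fn(grid)) <= 0))
    stop("device_model is not strictly monotone over the OD range",
         call. = FALSE)
  cv <- if (is.null(device_model$noise_cv)) 0.01 else device_model$noise_cv
  with_seed(seed, {
    od_true <- exp(seq(log(od_range[1]), log(od_range[2]), length.out = n))
    dev <- fn(od_true) * exp(stats::rnorm(n, 0, cv))
    dev <- cummax(dev)  # enforce the generator's monotonicity contract
    data.frame(od_true = od_true, od_device = dev)
  })
}

#' Generate a synthetic OD-normalized omics table with known truth
#'
#' Amounts are log-uniform over `amount_range`; the ground-truth copies per
#' cell and molar concentrations are computed from the reference table's
#' printed OD-specific cell concentration and total cell volume for the
#' chosen condition.
#'
#' @param n_analytes number of analytes (0 allowed).
#' @param condition_id condition label resolvable by [get_condition()].
#' @param amount_range range of amounts, mol/ml/OD.
#' @param seed RNG seed.
#' @return list with `omics` (data.frame: `analyte_id`, `amount_per_ml_od`,
#'   `amount_sd`, `unit`) and `truth` (data.frame with true
#'   `copies_per_cell` and `conc_molar`, plus the factors used).
#' @export
generate_omics_table <- function(n_analytes, condition_id = "glucose",
                                 amount_range = c(1e-12, 1e-8), seed = 1L) {
  rec <- get_condition(condition_id)  # errors on unknown condition
  stopifnot(n_analytes >= 0, amount_range[1] > 0,
            amount_range[2] >= amount_range[1])
  with_seed(seed, {
    amt <- exp(stats::runif(n_analytes, log(amount_range[1]),
                            log(amount_range[2])))
    omics <- data.frame(
      analyte_id = sprintf("analyte_%03d", seq_len(n_analytes)),
      amount_per_ml_od = amt,
      amount_sd = rep(NA_real_, n_analytes),
      unit = rep("mol_per_ml_od", n_analytes),
      stringsAsFactors = FALSE
    )
    n_cells <- rec$conc_e8 * 1e8
    truth <- data.frame(
      analyte_id = omics$analyte_id,
      copies_per_cell = amt * od_constants()$avogadro / n_cells,
      conc_molar = amt / (rec$vtot_ul * 1e-6),
      n_cells_per_ml_od = rep(n_cells, n_analytes),
      vtot_ul = rep(rec$vtot_ul, n_analytes),
      stringsAsFactors = FALSE
    )
    list(omics = omics, truth = truth)
  })
}
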