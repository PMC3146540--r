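# Bead-referenced absolute cell counting from cytometry event tables,
# and scatter-to-volume calibration.
#
# Counting scheme: (i) cells gated in the FL1 x SSC projection,
# (ii) beads gated in the FSC x SSC projection, (iii) the analyzed volume
# inferred from the bead count and the known number of beads spiked into
# the tube, (iv) cell concentration = cell count / analyzed volume. The
# suspension concentration additionally undoes the dilution by the 20 ul
# bead aliquot (factor tube/sample = 400/380, ~5%).

#' Rectangular gates for cells and beads
#'
#' Gates are axis-aligned rectangles in log10 channel units, matching how
#' the two populations are separated on log-scale dotplots: cells in
#' (FL1, SSC), beads in (FSC, SSC). The defaults are tuned to the synthetic
#' generator's channel models (real gates are instrument-specific and were
#' drawn manually).
#'
#' @param cells list with `fl1` and `ssc`, each `c(lo, hi)` in log10 units.
#' @param beads list with `fsc` and `ssc`, each `c(lo, hi)`.
#' @return object of class `gate_spec`.
#' @export
gate_spec <- function(cells = list(fl1 = c(1.8, 3.4), ssc = c(1.2, 2.6)),
                      beads = list(fsc = c(3.6, 4.4), ssc = c(3.1, 3.9))) {
  ok <- function(g) is.numeric(g) && length(g) == 2L && g[1] < g[2]
  stopifnot(ok(cells$fl1), ok(cells$ssc), ok(beads$fsc), ok(beads$ssc))
  structure(list(cells = cells, beads = beads), class = "gate_spec")
}

#' Count cells and beads by threshold gating
#'
#' Each class is counted in its own projection, so events may in principle
#' fall into both gates (they do not with the default synthetic channel
#' models).
#'
#' @param events data.frame with positive columns `FSC`, `SSC`, `FL1`.
#' @param gates a [gate_spec()].
#' @return list with `cell_count` and `bead_count` (non-negative integers).
#' @export
gate_events <- function(events, gates = gate_spec()) {
  stopifnot(inherits(gates, "gate_spec"))
  if (!is.data.frame(events) || nrow(events) == 0L)
    stop("empty event table", call. = FALSE)
  if (!all(c("FSC", "SSC", "FL1") %in% names(events)))
    stop("event table must have FSC, SSC and FL1 columns", call. = FALSE)
  if (any(events$FSC <= 0 | events$SSC <= 0 | events$FL1 <= 0))
    stop("channel values must be positive (log-scale acquisition)",
         call. = FALSE)
  within <- function(x, g) log10(x) >= g[1] & log10(x) <= g[2]
  cell_count <- sum(within(events$FL1, gates$cells$fl1) &
                    within(events$SSC, gates$cells$ssc))
  bead_count <- sum(within(events$FSC, gates$beads$fsc) &
                    within(events$SSC, gates$beads$ssc))
  if (cell_count == 0L) warning("cell gate contains no events")
  if (bead_count == 0L) warning("bead gate contains no events")
  list(cell_count = as.integer(cell_count), bead_count = as.integer(bead_count))
}

#' Absolute cell concentration from bead-referenced counts
#'
#' @param cell_count gated cell events.
#' @param bead_count gated bead events (>= 1; the analyzed volume is
#'   undeterminable otherwise).
#' @param beads_total_in_tube number of beads spiked into the tube
#'   (bead lot concentration x bead aliquot volume); no default is
#'   shipped because it is lot-specific.
#' @param tube_volume_ul total tube volume (sample + bead aliquot).
#' @param sample_aliquot_ul volume of cell suspension in the tube.
#' @param dilution_factor dilution of the culture into the suspension
#'   (>= 1).
#' @param od culture OD600, for the OD-specific output (optional).
#' @param aliquot_correction undo the bead-aliquot dilution
#'   (tube/sample, ~5%); disable only for sensitivity analysis.
#' @return list of class `count_result` with `cell_count`, `bead_count`,
#'   `analyzed_volume_ml`, `conc_tube_per_ml`, `conc_suspension_per_ml`,
#'   `conc_culture_per_ml`, `od_specific_conc` (cells/ml/OD, `NA` without
#'   `od`), and relative/absolute Poisson standard errors (`rel_se`,
#'   `conc_culture_se`; `NA` when `cell_count` is 0).
#' @examples
#' absolute_concentration(30000, 10000, beads_total_in_tube = 20000)
#' @export
absolute_concentration <- function(cell_count, bead_count,
                                   beads_total_in_tube,
                                   tube_volume_ul = 400,
                                   sample_aliquot_ul = 380,
                                   dilution_factor = 1,
                                   od = NULL,
                                   aliquot_correction = TRUE) {
  stopifnot(cell_count >= 0, cell_count == round(cell_count),
            bead_count == round(bead_count),
            tube_volume_ul > 0, sample_aliquot_ul > 0,
            sample_aliquot_ul <= tube_volume_ul, dilution_factor >= 1)
  if (bead_count < 1)
    stop("bead_count must be >= 1: the analyzed volume cannot be determined ",
         "without beads", call. = FALSE)
  if (beads_total_in_tube < bead_count)
    stop("beads_total_in_tube must be >= bead_count", call. = FALSE)
  if (!is.null(od) && od <= 0) stop("od must be > 0", call. = FALSE)

  analyzed_ml <- (bead_count / beads_total_in_tube) * tube_volume_ul * 1e-3
  conc_tube <- cell_count / analyzed_ml
  conc_susp <- conc_tube *
    if (aliquot_correction) tube_volume_ul / sample_aliquot_ul else 1
  conc_culture <- conc_susp * dilution_factor
  rel_se <- if (cell_count > 0) sqrt(1 / cell_count + 1 / bead_count)
            else NA_real_
  structure(list(
    cell_count = as.integer(cell_count),
    bead_count = as.integer(bead_count),
    analyzed_volume_ml = analyzed_ml,
    conc_tube_per_ml = conc_tube,
    conc_suspension_per_ml = conc_susp,
    conc_culture_per_ml = conc_culture,
    od_specific_conc = if (is.null(od)) NA_real_ else conc_culture / od,
    rel_se = rel_se,
    conc_culture_se = if (is.na(rel_se)) NA_real_ else conc_culture * rel_se,
    aliquot_correction = aliquot_correction
  ), class = "count_result")
}

#' Calibrate a scatter channel against cell volume
#'
#' Fits `volume = a * scatter + b` by least squares. Scatter readings are
#' instrument-setting dependent, so the calibration must be re-derived for
#' every setup from conditions with known volumes. Known problem rows can
#' be excluded and are logged in the model: stationary cells sit near the
#' FSC detection limit, and chemostat-grown cells show altered granularity
#' in SSC.
#'
#' @param scatter numeric scatter values (FSC or SSC).
#' @param volume_fl matching single-cell volumes, fl.
#' @param channel `"FSC"` or `"SSC"` (bookkeeping only).
#' @param exclude logical vector (or integer indices) of points to drop.
#' @return list of class `scatter_volume_model`: `fit` (the `lm`),
#'   `slope`, `intercept`, `r_squared`, `sigma` (residual SD), `range`
#'   (fitted scatter range), `channel`, `n`, `excluded`.
#' @export
calibrate_scatter_to_volume <- function(scatter, volume_fl,
                                        channel = c("FSC", "SSC"),
                                        exclude = NULL) {
  channel <- match.arg(channel)
  stopifnot(length(scatter) == length(volume_fl))
  keep <- rep(TRUE, length(scatter))
  if (!is.null(exclude)) {
    if (is.logical(exclude)) keep <- !exclude else keep[exclude] <- FALSE
  }
  s <- scatter[keep]; v <- volume_fl[keep]
  if (length(s) < 3L)
    stop("need at least 3 (scatter, volume) pairs after exclusions",
         call. = FALSE)
  if (stats::var(s) == 0)
    stop("scatter values have zero variance", call. = FALSE)
  fit <- stats::lm(v ~ s, data = data.frame(s = s, v = v))
  sm <- suppressWarnings(summary(fit))  # exact lines are legitimate input
  structure(list(fit = fit,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 sigma = sm$sigma,
                 range = range(s),
                 channel = channel,
                 n = length(s),
                 excluded = which(!keep)),
            class = "scatter_volume_model")
}

#' Predict cell volume from a scatter reading
#'
#' @param model a [calibrate_scatter_to_volume()] model.
#' @param scatter scatter value(s); outside the fitted range the point
#'   prediction is still returned but flagged with an extrapolation
#'   warning.
#' @param level prediction-interval coverage (default 0.95).
#' @return data.frame with `volume_fl`, `lwr`, `upr` (prediction interval
#'   from the residual SD).
#' @export
predict_volume_from_scatter <- function(model, scatter, level = 0.95) {
  if (!inherits(model, "scatter_volume_model"))
    stop("model must come from calibrate_scatter_to_volume()", call. = FALSE)
  if (any(scatter < model$range[1] | scatter > model$range[2]))
    warning("scatter outside the fitted range [",
            signif(model$range[1], 4), ", ", signif(model$range[2], 4),
            "]: extrapolating")
  p <- stats::predict(model$fit, newdata = data.frame(s = scatter),
                      interval = "prediction", level = level)
  data.frame(volume_fl = p[, "fit"], lwr = p[, "lwr"], upr = p[, "upr"])
}
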