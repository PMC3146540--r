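# Conversion of OD-normalized omics quantities into copies per cell and
# intracellular molar concentration, with uncertainty propagation and OD
# calibration.
#
# Given an amount A in mol per ml of culture per OD unit:
#   copies/cell = A * N_Avogadro / N        (N = cells/ml/OD)
#   molarity    = A / (V_tot * 1e-6 L)      (V_tot = ul cell volume /ml/OD)
# Both are exactly linear in A. When condition-consistent factors are used
# (V_tot = V_cell x N), the two outputs agree:
# copies / (V_cell[L] * N_A) = molarity.

.check_omics <- function(record) {
  stopifnot(is.data.frame(record))
  need <- c("analyte_id", "amount_per_ml_od", "unit")
  if (!all(need %in% names(record)))
    stop("omics table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(record) > 0 && !all(record$unit == "mol_per_ml_od"))
    stop("refusing untagged/mistagged amounts: unit must be ",
         "'mol_per_ml_od' for every row", call. = FALSE)
  if (any(record$amount_per_ml_od < 0))
    stop("amounts must be >= 0", call. = FALSE)
  invisible(record)
}

#' Build an OD-normalized omics table
#'
#' Convenience constructor attaching the mandatory unit tag.
#'
#' @param analyte_id character vector of analyte identifiers.
#' @param amount_per_ml_od amounts, mol/ml/OD600 (>= 0).
#' @param amount_sd optional one-sigma SDs (NA when unknown).
#' @return data.frame with the schema expected by the conversion
#'   operations.
#' @export
omics_records <- function(analyte_id, amount_per_ml_od, amount_sd = NA_real_) {
  data.frame(analyte_id = as.character(analyte_id),
             amount_per_ml_od = amount_per_ml_od,
             amount_sd = rep_len(amount_sd, length(amount_per_ml_od)),
             unit = rep_len("mol_per_ml_od", length(amount_per_ml_od)),
             stringsAsFactors = FALSE)
}

#' Convert OD-normalized amounts to copies per cell
#'
#' @param record omics table (see [omics_records()]); the unit tag is
#'   mandatory.
#' @param n_cells_per_ml_od OD-specific cell concentration N, cells/ml/OD
#'   (> 0), e.g. `get_condition("glucose")$conc_e8 * 1e8`.
#' @return numeric vector of copies per cell.
#' @examples
#' rec <- omics_records("atp", 1e-9)
#' to_copies_per_cell(rec, 11.1e8)  # ~5.4e5 copies/cell
#' @export
to_copies_per_cell <- function(record, n_cells_per_ml_od) {
  .check_omics(record)
  stopifnot(length(n_cells_per_ml_od) == 1L, n_cells_per_ml_od > 0)
  record$amount_per_ml_od * od_constants()$avogadro / n_cells_per_ml_od
}

#' Convert OD-normalized amounts to intracellular molar concentration
#'
#' @param record omics table (see [omics_records()]).
#' @param vtot_ul_per_ml_od OD-specific total cell volume V_tot, ul/ml/OD
#'   (> 0); ~3.6 for any growth condition.
#' @return numeric vector, mol/L (concentration within total cell volume).
#' @examples
#' to_molar(omics_records("atp", 1e-9), 3.6)  # ~2.8e-4 M
#' @export
to_molar <- function(record, vtot_ul_per_ml_od) {
  .check_omics(record)
  stopifnot(length(vtot_ul_per_ml_od) == 1L, vtot_ul_per_ml_od > 0)
  record$amount_per_ml_od / (vtot_ul_per_ml_od * 1e-6)
}

# lognormal (meanlog, sdlog) for a printed "m +/- s": the printed central
# value is taken as the median (symmetric-reporting convention) and the
# log-scale spread matches the printed CV
.lnorm_pars <- function(m, s) {
  c(meanlog = log(m), sdlog = sqrt(log(1 + (s / m)^2)))
}

#' Convert an omics table with condition-resolved factors and uncertainty
#'
#' Resolves the conversion factors N (cells/ml/OD) and V_tot (ul/ml/OD)
#' for a growth condition (from the reference table) or an arbitrary
#' growth rate (from the fitted models), converts every analyte, and
#' propagates uncertainty either by Monte Carlo over independent
#' log-normals for N and the single-cell volume V (truncation at zero is
#' implicit in the log-normal) or by the first-order delta method.
#'
#' `vtot_source` picks the total volume entering the molar conversion:
#' `"printed"` (the condition's measured V_tot column; default),
#' `"product"` (V x N, self-consistent with the copies output by
#' construction), or `"global"` (the 3.6 ul constant).
#'
#' @param omics omics table (see [omics_records()]).
#' @param condition condition label (mutually exclusive with `mu`).
#' @param mu growth rate, 1/h; factors then come from the fitted models.
#' @param vtot_source `"printed"`, `"product"` or `"global"`.
#' @param uncertainty `"mc"` (default), `"delta"` or `"none"`.
#' @param mc_samples Monte Carlo sample count (default 10000; < 100 warns).
#' @param seed Monte Carlo seed.
#' @param table reference table.
#' @return data.frame with one row per analyte: `analyte_id`,
#'   `copies_per_cell`, `copies_sd`, `conc_molar`, `molar_sd`. Attribute
#'   `"factors"` records N, V, V_tot, their SDs, source and seed.
#' @examples
#' tab <- generate_omics_table(3, "glucose", seed = 2)
#' convert_table(tab$omics, condition = "glucose", uncertainty = "delta")
#' @export
convert_table <- function(omics, condition = NULL, mu = NULL,
                          vtot_source = c("printed", "product", "global"),
                          uncertainty = c("mc", "delta", "none"),
                          mc_samples = 10000L, seed = 1L,
                          table = load_reference_table()) {
  vtot_source <- match.arg(vtot_source)
  uncertainty <- match.arg(uncertainty)
  .check_omics(omics)
  if (is.null(mu) == is.null(condition))
    stop("supply exactly one of condition or mu", call. = FALSE)

  if (!is.null(condition)) {
    rec <- get_condition(condition)
    n_od <- rec$conc_e8 * 1e8; n_sd <- rec$conc_sd_e8 * 1e8
    v <- rec$volume_fl; v_sd <- rec$volume_sd_fl
    vtot_printed <- rec$vtot_ul
    src <- "table"
  } else {
    vm <- fit_volume_vs_mu(table)
    pv <- predict_volume(mu = mu, model = vm)
    pc <- predict_cell_concentration(mu = mu, od = 1, table = table,
                                     volume_model = vm)
    v <- pv$volume_fl; v_sd <- pv$sd
    n_od <- pc$od_specific_conc; n_sd <- pc$sd
    vtot_printed <- fit_total_volume(table)$vtot_ul
    src <- "model"
  }
  vtot <- switch(vtot_source,
                 printed = vtot_printed,
                 product = v * n_od * 1e-9,   # fl*cells -> ul
                 global = od_constants()$vtot_global_ul)

  amt <- omics$amount_per_ml_od
  amt_sd <- if ("amount_sd" %in% names(omics)) omics$amount_sd else NA_real_
  amt_sd <- ifelse(is.na(amt_sd), 0, amt_sd)
  copies <- amt * od_constants()$avogadro / n_od
  molar <- amt / (vtot * 1e-6)

  rel_amt <- ifelse(amt > 0, amt_sd / amt, 0)
  rel_n <- n_sd / n_od
  rel_v <- v_sd / v
  copies_sd <- molar_sd <- rep(NA_real_, length(amt))
  if (uncertainty == "delta") {
    copies_sd <- copies * sqrt(rel_amt^2 + rel_n^2)
    # molar uncertainty: V_tot fluctuations follow the V x N product
    molar_sd <- molar * sqrt(rel_amt^2 + rel_n^2 + rel_v^2)
  } else if (uncertainty == "mc") {
    if (mc_samples < 100L)
      warning("mc_samples < 100: Monte Carlo SDs will be unreliable")
    mc <- with_seed(seed, {
      pn <- .lnorm_pars(n_od, n_sd)
      pvl <- .lnorm_pars(v, v_sd)
      n_mc <- stats::rlnorm(mc_samples, pn[1], pn[2])
      v_mc <- stats::rlnorm(mc_samples, pvl[1], pvl[2])
      # scale the chosen point V_tot by the relative V x N fluctuation
      vtot_mc <- vtot * (v_mc * n_mc) / (v * n_od)
      list(n = n_mc, vtot = vtot_mc)
    })
    for (i in seq_along(amt)) {
      a_mc <- if (rel_amt[i] > 0)
        with_seed(seed + i, {
          p <- .lnorm_pars(amt[i], amt_sd[i])
          stats::rlnorm(mc_samples, p[1], p[2])
        })
      else amt[i]
      copies_sd[i] <- stats::sd(a_mc * od_constants()$avogadro / mc$n)
      molar_sd[i] <- stats::sd(a_mc / (mc$vtot * 1e-6))
    }
  }
  out <- data.frame(analyte_id = omics$analyte_id,
                    copies_per_cell = copies, copies_sd = copies_sd,
                    conc_molar = molar, molar_sd = molar_sd,
                    stringsAsFactors = FALSE)
  attr(out, "factors") <- list(n_cells_per_ml_od = n_od, n_sd = n_sd,
                               volume_fl = v, volume_sd = v_sd,
                               vtot_ul = vtot, vtot_source = vtot_source,
                               source = src,
                               condition = condition, mu = mu,
                               uncertainty = uncertainty,
                               seed = if (uncertainty == "mc") seed else NULL)
  out
}

#' Calibrate a non-linear OD-measuring device against reference ODs
#'
#' Builds a monotone correction mapping device readings to reference
#' (spectrophotometer) ODs from paired calibration samples spanning the
#' working range (the protocol used known ODs from 0.001 to 10). The
#' interpolant is a shape-preserving monotone piecewise cubic in log-log
#' space; outside the calibrated device range the map is clamped to the
#' boundary correction factor, with a warning.
#'
#' @param pairs data.frame with columns `od_device` and `od_reference`
#'   (>= 4 rows; both strictly increasing after sorting by device OD).
#' @return function mapping device OD(s) to corrected OD(s); attribute
#'   `"device_range"` holds the calibrated range.
#' @examples
#' cal <- calibrate_od(data.frame(od_device = c(0.01, 0.1, 0.5, 1),
#'                                od_reference = c(0.01, 0.11, 0.7, 1.8)))
#' cal(0.3)
#' @export
calibrate_od <- function(pairs) {
  stopifnot(is.data.frame(pairs),
            all(c("od_device", "od_reference") %in% names(pairs)))
  if (nrow(pairs) < 4L)
    stop("need at least 4 calibration pairs", call. = FALSE)
  if (any(pairs$od_device <= 0 | pairs$od_reference <= 0))
    stop("OD values must be positive", call. = FALSE)
  p <- pairs[order(pairs$od_device), ]
  if (any(diff(p$od_device) <= 0) || any(diff(p$od_reference) <= 0))
    stop("calibration pairs are not strictly monotone", call. = FALSE)
  sf <- stats::splinefun(log(p$od_device), log(p$od_reference),
                         method = "hyman")
  rng <- range(p$od_device)
  f <- function(od_device) {
    stopifnot(all(od_device > 0))
    out_of_range <- od_device < rng[1] | od_device > rng[2]
    if (any(out_of_range))
      warning("device OD outside calibrated range [", rng[1], ", ", rng[2],
              "]: correction clamped to the boundary factor")
    x <- pmin(pmax(od_device, rng[1]), rng[2])
    # clamped: apply the boundary multiplicative correction beyond range
    exp(sf(log(x))) * od_device / x
  }
  attr(f, "device_range") <- rng
  class(f) <- c("od_calibration", class(f))
  f
}
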