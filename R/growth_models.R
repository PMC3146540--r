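# Growth-rate-dependent models: cell volume V(mu), OD-specific cell
# concentration N(mu), and the near-constant OD-specific total cell volume.
#
# V(mu) is a low-order polynomial in log10(mu) (degree 2 by default: the
# smallest degree that captures the curvature of volume against growth rate
# on a log axis). N(mu) is the reciprocal model
#   N(mu) = vtot_hat * 1e9 / V(mu)   [cells/ml/OD, V in fl, vtot in ul]
# i.e. a fixed total cell volume divided by the condition-dependent
# single-cell volume. Stationary cells (mu = 0) are placed at a pseudo
# growth rate of 0.1/h on the log axis for the volume fit, but excluded
# from the concentration model's domain, where "growth rate" is undefined.

.mu_for_fit <- function(mu, pseudo_mu) ifelse(mu <= 0, pseudo_mu, mu)

#' Fit the cell-volume vs growth-rate model
#'
#' Least-squares polynomial of `volume_fl` against `log10(mu)`.
#'
#' @param table a reference table (default: embedded).
#' @param degree polynomial degree (default 2).
#' @param include_stationary include stationary rows at the pseudo growth
#'   rate (default TRUE).
#' @param pseudo_mu growth rate substituted for mu = 0 rows.
#' @return object of class `volume_model`: `coefficients` (increasing
#'   powers of log10(mu)), `degree`, `sigma` (residual SD, 0 for an exact
#'   fit), `mu_range` (domain of growing conditions), `pseudo_mu`, `n`.
#'   A numerically non-monotone fit over the observed range triggers a
#'   warning.
#' @examples
#' m <- fit_volume_vs_mu()
#' predict_volume(mu = 0.6, model = m)
#' @export
fit_volume_vs_mu <- function(table = load_reference_table(), degree = 2L,
                             include_stationary = TRUE,
                             pseudo_mu = od_constants()$stationary_pseudo_mu) {
  stopifnot(is.data.frame(table), degree >= 1L)
  df <- data.frame(mu = table$mu, v = table$volume_fl)
  if (!include_stationary) df <- df[df$mu > 0, , drop = FALSE]
  if (any(df$mu <= 0) && (is.null(pseudo_mu) || pseudo_mu <= 0))
    stop("non-positive growth rates present and no positive pseudo_mu given",
         call. = FALSE)
  df$x <- log10(.mu_for_fit(df$mu, pseudo_mu))
  if (nrow(df) < degree + 1L)
    stop("need at least degree + 1 = ", degree + 1L, " records", call. = FALSE)
  fit <- stats::lm(v ~ poly(x, degree, raw = TRUE), data = df)
  sigma <- suppressWarnings(summary(fit)$sigma)  # NaN-safe for exact fits
  if (!is.finite(sigma)) sigma <- 0  # saturated (exact) fit
  coefs <- unname(stats::coef(fit))
  mu_obs <- df$mu[df$mu > 0]
  model <- structure(list(coefficients = coefs, degree = degree,
                          sigma = sigma,
                          mu_range = range(mu_obs),
                          pseudo_mu = pseudo_mu, n = nrow(df)),
                     class = "volume_model")
  grid <- exp(seq(log(model$mu_range[1]), log(model$mu_range[2]),
                  length.out = 101))
  if (any(diff(.eval_poly(model, log10(grid))) < 0))
    warning("fitted volume model is not monotone non-decreasing over the ",
            "observed growth-rate range")
  model
}

.eval_poly <- function(model, x) {
  drop(outer(x, 0:model$degree, `^`) %*% model$coefficients)
}

#' Mean OD-specific total cell volume
#'
#' The estimator is the unweighted mean across conditions (no replicate
#' weights are available for most rows); the spread across conditions is
#' reported as its SD.
#'
#' @param table a reference table.
#' @return list with `vtot_ul` (mean), `sd` (`NA` for a single row), `n`.
#' @examples
#' round(fit_total_volume()$vtot_ul, 1)  # 3.6
#' @export
fit_total_volume <- function(table = load_reference_table()) {
  if (!is.data.frame(table) || nrow(table) == 0L)
    stop("'table' must be a non-empty reference table", call. = FALSE)
  v <- table$vtot_ul
  list(vtot_ul = mean(v),
       sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
       n = length(v))
}

.check_domain <- function(mu, model, force) {
  if (mu <= 0) stop("growth rate must be positive", call. = FALSE)
  if (!force && (mu < model$mu_range[1] || mu > model$mu_range[2]))
    stop("mu = ", mu, " outside the fitted growth-rate range [",
         model$mu_range[1], ", ", model$mu_range[2],
         "]; set force = TRUE to extrapolate", call. = FALSE)
}

#' Predict single-cell volume for a condition or growth rate
#'
#' A known condition label returns the measured volume directly (with its
#' SD); a growth rate goes through the fitted V(mu) model, whose residual
#' SD serves as the uncertainty.
#'
#' @param mu growth rate, 1/h (mutually exclusive with `condition`).
#' @param condition condition label resolvable by [get_condition()].
#' @param model a [fit_volume_vs_mu()] model; fitted on the embedded table
#'   when `NULL`.
#' @param force allow extrapolation outside the fitted mu range.
#' @return list with `volume_fl`, `sd`, `source` (`"table"` or `"model"`).
#' @export
predict_volume <- function(mu = NULL, condition = NULL, model = NULL,
                           force = FALSE) {
  if (is.null(mu) == is.null(condition))
    stop("supply exactly one of mu or condition", call. = FALSE)
  if (!is.null(condition)) {
    rec <- get_condition(condition)
    return(list(volume_fl = rec$volume_fl, sd = rec$volume_sd_fl,
                source = "table"))
  }
  if (is.null(model)) model <- fit_volume_vs_mu()
  .check_domain(mu, model, force)
  v <- .eval_poly(model, log10(mu))
  if (v <= 0) stop("model predicts non-positive volume at mu = ", mu,
                   call. = FALSE)
  list(volume_fl = v, sd = model$sigma, source = "model")
}

#' Predict the cell concentration of a culture from OD and growth rate
#'
#' For a known condition the measured OD-specific concentration is used
#' directly; for an arbitrary growth rate the reciprocal model
#' `N(mu) = vtot_hat * 1e9 / V(mu)` is evaluated with the fitted total
#' volume and volume model. Cells/ml = N x OD.
#'
#' @param mu growth rate, 1/h (mutually exclusive with `condition`).
#' @param condition condition label.
#' @param od culture OD600 (> 0).
#' @param table reference table used for lookups and fits.
#' @param volume_model optional pre-fitted [fit_volume_vs_mu()] model.
#' @param force allow extrapolation outside the fitted mu range.
#' @return list with `cells_per_ml`, `sd`, `od_specific_conc`
#'   (cells/ml/OD), `source`.
#' @examples
#' predict_cell_concentration(condition = "glucose", od = 1)$cells_per_ml
#' @export
predict_cell_concentration <- function(mu = NULL, condition = NULL, od,
                                       table = load_reference_table(),
                                       volume_model = NULL, force = FALSE) {
  if (missing(od) || is.null(od) || od <= 0)
    stop("od must be > 0", call. = FALSE)
  if (is.null(mu) == is.null(condition))
    stop("supply exactly one of mu or condition", call. = FALSE)
  if (!is.null(condition)) {
    rec <- get_condition(condition)
    n_od <- rec$conc_e8 * 1e8
    sd_od <- rec$conc_sd_e8 * 1e8
    return(list(cells_per_ml = n_od * od, sd = sd_od * od,
                od_specific_conc = n_od, source = "table"))
  }
  if (is.null(volume_model))
    volume_model <- fit_volume_vs_mu(table)
  .check_domain(mu, volume_model, force)
  vt <- fit_total_volume(table)
  v <- predict_volume(mu = mu, model = volume_model, force = force)
  n_od <- vt$vtot_ul * 1e9 / v$volume_fl  # ul -> fl: 1e9
  # first-order propagation of the vtot spread and the volume fit residual
  rel <- sqrt((if (is.na(vt$sd)) 0 else vt$sd / vt$vtot_ul)^2 +
              (v$sd / v$volume_fl)^2)
  list(cells_per_ml = n_od * od, sd = n_od * od * rel,
       od_specific_conc = n_od, source = "model")
}
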