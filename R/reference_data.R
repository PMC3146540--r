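# Curated reference table of E. coli BW25113 / MG1655 cell parameters across
# 24 growth conditions (22 BW25113 conditions + 2 MG1655 comparisons),
# together with the physical constants used throughout the package.
#
# Units as measured/printed:
#   mu        growth rate, 1/h (0 for stationary rows)
#   length/width  um; volume fl (1 fl = 1 um^3)
#   conc_e8   OD-specific cell concentration, 1e8 cells/ml/OD600
#   vtot_ul   OD-specific total cell volume, ul/ml/OD600
# SDs are one sigma; NA marks "not determined" (chemostat mu was set by the
# dilution rate, and the total-volume column carries no SD).

# condition_id, category, strain, mu, mu_sd, length, length_sd, width,
# width_sd, volume, volume_sd, conc, conc_sd, vtot
.ref_rows <- list(
  # complex medium
  list("LB",               "complex",      "BW25113", 1.61, 0.05, 3.9, 0.9, 1.3, 0.2, 4.4, 1.1,  7.8, 0.8, 3.4),
  list("LB_MG1655",        "complex",      "MG1655",  1.62, 0.04, 3.5, 0.9, 1.4, 0.1, 3.9, 1.2,  7.5, 0.8, 2.9),
  list("glucose_AA",       "complex",      "BW25113", 1.49, 0.05, 3.5, 1.0, 1.5, 0.1, 4.0, 1.3,  5.9, 0.6, 2.4),
  list("mannose_AA",       "complex",      "BW25113", 1.28, 0.07, 3.7, 0.9, 1.5, 0.2, 4.1, 1.2,  6.3, 0.6, 2.5),
  list("glycerol_AA",      "complex",      "BW25113", 1.26, 0.04, 3.5, 0.9, 1.5, 0.1, 3.9, 1.2,  8.2, 0.8, 3.2),
  # minimal medium carbon sources
  list("acetate",          "carbon_source","BW25113", 0.29, 0.02, 2.3, 0.6, 1.2, 0.1, 2.4, 1.3, 16.8, 1.7, 4.0),
  list("fumarate",         "carbon_source","BW25113", 0.47, 0.03, 2.4, 0.6, 1.1, 0.1, 2.4, 1.2, 17.0, 1.7, 4.1),
  list("galactose",        "carbon_source","BW25113", 0.17, 0.02, 2.0, 0.5, 1.1, 0.1, 1.9, 1.2, 19.9, 2.0, 3.8),
  list("glucose",          "carbon_source","BW25113", 0.60, 0.05, 3.0, 0.7, 1.4, 0.2, 3.2, 1.2, 11.1, 1.1, 3.6),
  list("glucose_MG1655",   "carbon_source","MG1655",  0.67, 0.05, 2.8, 0.7, 1.4, 0.2, 3.0, 1.3, 11.0, 1.1, 3.3),
  list("glucosamine",      "carbon_source","BW25113", 0.39, 0.03, 2.7, 0.7, 1.3, 0.1, 2.9, 1.3, 12.2, 1.2, 3.5),
  list("glycerol",         "carbon_source","BW25113", 0.47, 0.03, 2.3, 0.6, 1.2, 0.1, 2.3, 1.3, 19.6, 2.0, 4.5),
  list("pyruvate",         "carbon_source","BW25113", 0.40, 0.03, 2.2, 0.6, 1.0, 0.1, 2.1, 1.2, 21.0, 2.1, 4.5),
  list("succinate",        "carbon_source","BW25113", 0.49, 0.02, 2.4, 0.6, 1.1, 0.2, 2.4, 1.3, 16.7, 1.7, 4.1),
  # stress conditions on glucose
  list("anaerobic",        "stress",       "BW25113", 0.55, 0.01, 2.8, 0.7, 1.3, 0.2, 2.9, 1.2, 10.4, 1.0, 3.1),
  list("NaCl_50mM",        "stress",       "BW25113", 0.65, 0.02, 2.6, 0.7, 1.3, 0.2, 2.8, 1.2, 11.3, 1.1, 3.1),
  list("pH_6",             "stress",       "BW25113", 0.50, 0.11, 2.9, 0.8, 1.3, 0.2, 3.1, 1.3, 10.5, 1.1, 3.3),
  list("42C",              "stress",       "BW25113", 0.65, 0.02, 2.7, 0.7, 1.3, 0.2, 2.8, 1.2, 11.0, 1.1, 3.1),
  # glucose-limited chemostat, mu fixed by the dilution rate (no SD)
  list("chemostat_0.50",   "chemostat",    "BW25113", 0.50, NA,   2.5, 1.2, 1.2, 0.2, 2.6, 1.9, 13.4, 1.3, 3.5),
  list("chemostat_0.35",   "chemostat",    "BW25113", 0.35, NA,   2.4, 1.0, 1.0, 0.1, 2.4, 1.7, 19.7, 2.0, 4.8),
  list("chemostat_0.20",   "chemostat",    "BW25113", 0.20, NA,   2.2, 1.0, 1.0, 0.1, 2.2, 1.8, 20.6, 2.1, 4.5),
  list("chemostat_0.12",   "chemostat",    "BW25113", 0.12, NA,   2.1, 1.1, 1.1, 0.1, 2.1, 1.9, 23.0, 2.3, 4.9),
  # starved cells
  list("stationary_1_day", "stationary",   "BW25113", 0.00, NA,   1.6, 0.4, 1.1, 0.2, 1.5, 1.2, 21.9, 2.2, 3.3),
  list("stationary_3_days","stationary",   "BW25113", 0.00, NA,   1.7, 0.3, 1.4, 0.1, 1.6, 1.1, 22.9, 2.3, 3.7)
)

.build_ref_table <- function() {
  df <- do.call(rbind, lapply(.ref_rows, function(r) {
    data.frame(condition_id = r[[1]], category = r[[2]], strain = r[[3]],
               mu = r[[4]], mu_sd = r[[5]],
               length_um = r[[6]], length_sd_um = r[[7]],
               width_um = r[[8]], width_sd_um = r[[9]],
               volume_fl = r[[10]], volume_sd_fl = r[[11]],
               conc_e8 = r[[12]], conc_sd_e8 = r[[13]],
               vtot_ul = r[[14]],
               stringsAsFactors = FALSE)
  }))
  rownames(df) <- df$condition_id
  class(df) <- c("ref_table", "data.frame")
  df
}

.ref_table_cache <- .build_ref_table()

#' Physical constants and unit conventions
#'
#' Fixed constants used across the package: the population-average cell
#' width (condition independent within measurement error), the global
#' OD-specific total cell volume, imaging resolution, counting-bead
#' geometry and aliquot volumes, replicate-level variability, and the
#' pseudo growth rate at which non-growing stationary cells are placed on
#' logarithmic growth-rate axes.
#'
#' @return A named list of constants:
#' \describe{
#'   \item{mean_width_um, width_sd_um}{population-average cell width, um
#'     (1.26 +/- 0.16 across all conditions).}
#'   \item{vtot_global_ul}{global OD-specific total cell volume,
#'     ul/ml/OD600 (approx. 3.6 for every condition measured).}
#'   \item{avogadro}{Avogadro constant, 1/mol.}
#'   \item{pixel_um}{microscope resolution, um/pixel (0.092).}
#'   \item{bead_diameter_um}{nominal counting-bead diameter, um (7.0).}
#'   \item{bead_aliquot_ul, sample_aliquot_ul}{bead and sample aliquot
#'     volumes mixed into the counting tube (20 + 380 ul).}
#'   \item{daytoday_cv}{day-to-day coefficient of variation of the
#'     concentration measurement (<= 0.10).}
#'   \item{stationary_pseudo_mu}{growth rate at which stationary cells are
#'     plotted/fitted on a log axis (0.1/h).}
#' }
#' @examples
#' od_constants()$mean_width_um
#' @export
od_constants <- function() {
  list(
    mean_width_um       = 1.26,
    width_sd_um         = 0.16,
    vtot_global_ul      = 3.6,
    avogadro            = 6.02214076e23,
    pixel_um            = 0.092,
    bead_diameter_um    = 7.0,
    bead_aliquot_ul     = 20,
    sample_aliquot_ul   = 380,
    daytoday_cv         = 0.10,
    stationary_pseudo_mu = 0.1
  )
}

#' Load the reference table of condition-dependent cell parameters
#'
#' Returns the embedded reference dataset: one row per growth condition
#' with growth rate, cell length and width, single-cell volume,
#' OD-specific cell concentration and OD-specific total cell volume.
#' The data are stored in the package source (no file access) exactly as
#' measured; means come with one-sigma SDs where available and `NA` where
#' not (chemostat growth rates are set by the dilution rate; the
#' total-volume column carries no SD).
#'
#' @return A `ref_table` (a `data.frame`) with 24 rows and columns
#'   `condition_id`, `category` (one of `complex`, `carbon_source`,
#'   `stress`, `chemostat`, `stationary`), `strain` (`BW25113` or
#'   `MG1655`), `mu`, `mu_sd` (1/h), `length_um`, `length_sd_um`,
#'   `width_um`, `width_sd_um` (um), `volume_fl`, `volume_sd_fl` (fl),
#'   `conc_e8`, `conc_sd_e8` (1e8 cells/ml/OD), `vtot_ul` (ul/ml/OD).
#' @examples
#' tab <- load_reference_table()
#' tab["LB", "volume_fl"]
#' @seealso [get_condition()], [tabulate_total_volume()]
#' @export
load_reference_table <- function() {
  .ref_table_cache
}

# canonical key: lower-case, non-alphanumerics collapsed to "_"
.normalize_id <- function(x) {
  x <- gsub("[^a-z0-9]+", "_", tolower(x))
  gsub("^_+|_+$", "", x)
}

# aliases mapping normalized user input -> canonical condition_id
.ref_aliases <- c(
  "stationary_1d"   = "stationary_1_day",
  "stationary_3d"   = "stationary_3_days",
  "stationary"      = "stationary_1_day",
  "42_c"            = "42C",
  "42c"             = "42C",
  "ph6"             = "pH_6",
  "nacl"            = "NaCl_50mM",
  "50_mm_nacl"      = "NaCl_50mM",
  "lb_mg"           = "LB_MG1655",
  "glucose_mg"      = "glucose_MG1655"
)

#' Look up one growth condition in the reference table
#'
#' Matching is case-insensitive and tolerant of punctuation
#' (`"42°C"`, `"42C"` and `"42_c"` all resolve to the 42C row); a few
#' documented aliases are accepted (e.g. `"stationary_1d"`).
#'
#' @param condition_id condition label, e.g. `"glucose"`, `"LB"`,
#'   `"chemostat_0.12"`.
#' @return A one-row `data.frame` (classes `condition_record`,
#'   `data.frame`) with the columns of [load_reference_table()].
#' @examples
#' get_condition("acetate")$mu
#' get_condition("ACETATE")$condition_id
#' @export
get_condition <- function(condition_id) {
  stopifnot(is.character(condition_id), length(condition_id) == 1L)
  tab <- load_reference_table()
  key <- .normalize_id(condition_id)
  if (key %in% names(.ref_aliases)) key <- .normalize_id(.ref_aliases[[key]])
  hit <- match(key, .normalize_id(tab$condition_id))
  if (is.na(hit)) {
    stop("unknown condition '", condition_id, "'; valid labels: ",
         paste(tab$condition_id, collapse = ", "), call. = FALSE)
  }
  rec <- tab[hit, , drop = FALSE]
  class(rec) <- c("condition_record", "data.frame")
  rec
}

#' Summarize the OD-specific total cell volume column
#'
#' The central empirical observation served by this package is that the
#' total cell volume per ml of culture per OD unit is nearly constant
#' across growth conditions (~3.6 ul/ml/OD, extremes differing only by a
#' factor of about two). This helper computes that summary from a
#' reference table.
#'
#' @param table a `ref_table`, by default the embedded one.
#' @return list with `n`, `mean`, `sd`, `min`, `max` and `ratio`
#'   (max/min) of the `vtot_ul` column. For a single-row table `sd` is
#'   `NA` (undefined by convention).
#' @examples
#' round(tabulate_total_volume()$mean, 1)
#' @export
tabulate_total_volume <- function(table = load_reference_table()) {
  if (!is.data.frame(table) || nrow(table) == 0L)
    stop("'table' must be a non-empty reference table", call. = FALSE)
  v <- table$vtot_ul
  list(n = length(v),
       mean = mean(v),
       sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
       min = min(v), max = max(v),
       ratio = max(v) / min(v))
}

#' Export the reference table as CSV
#'
#' Writes one row per condition, columns in measurement-table order,
#' UTF-8 with a header row.
#'
#' @param path output file path.
#' @param table table to write (default: embedded reference table).
#' @return `path`, invisibly.
#' @export
write_reference_csv <- function(path, table = load_reference_table()) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
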