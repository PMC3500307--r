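## Accessors for the small published-value tables shipped with the package.
## These are inputs for audits and cross-checks (printed interval rates,
## detected shift times, soft-bound calibration estimates), not results
## computed here.

extdataPath <- function(name) {
  p <- system.file("extdata", name, package = "primdiv")
  if (p == "") stop("bundled file not found: ", name)
  p
}

#' Published per-interval diversification rates for Cenozoic primates
#'
#' Net diversification rates (speciation minus extinction, per lineage per
#' Myr) for eleven consecutive 5-Myr intervals from 55 to 0 Ma, from fossil
#' range-through counts and from four molecular timetrees (autocorrelated/
#' independent rates crossed with hard/soft calibration bounds). Used to
#' cross-check [compareRateSeries()] against reported correlations.
#'
#' @return data.frame with columns `start_ma`, `end_ma`, `fossil`,
#'   `autohard`, `autosoft`, `irhard`, `irsoft`.
#' @export
primateIntervalRates <- function() {
  utils::read.csv(extdataPath("primate_interval_rates.csv"))
}

#' Published diversification-rate shifts for primates
#'
#' Shift times (Ma) and directions detected on four primate timetrees under
#' three taxonomies. Eleven of the twelve tree-taxonomy combinations
#' support a late Miocene/Pliocene rate increase.
#'
#' @return data.frame with columns `timetree`, `taxonomy`, `time_ma`,
#'   `direction`.
#' @export
primateRateShifts <- function() {
  utils::read.csv(extdataPath("primate_rate_shifts.csv"),
                  stringsAsFactors = FALSE)
}

#' Soft-bound calibration audit inputs for primate timetrees
#'
#' The node-age estimates from soft-bounded dating analyses that conflict
#' with their fossil calibration bounds, with the violated bound on each
#' row (the unconstrained side is NA). Feeding the table to
#' [auditViolations()] reproduces the six-violation audit.
#'
#' @return data.frame with columns `clade`, `analysis`, `age_ma`, `min_ma`,
#'   `max_ma`.
#' @export
primateCalibrationAudit <- function() {
  utils::read.csv(extdataPath("primate_calibration_audit.csv"),
                  stringsAsFactors = FALSE)
}

#' Mean age of late Miocene/Pliocene rate increases
#'
#' Filters a shift table to increases within an age window (default the
#' late Miocene plus Pliocene, 2.6-11.6 Ma, excluding Pleistocene and
#' early/middle Miocene shifts) and averages their times.
#'
#' @param shifts a data.frame as returned by [primateRateShifts()].
#' @param window numeric `(young, old)` ages in Ma.
#' @return list with `times` (the selected shift ages) and `mean`.
#' @export
summarizeIncreaseTimes <- function(shifts = primateRateShifts(),
                                   window = c(2.6, 11.6)) {
  sel <- shifts$direction == "increase" & shifts$time_ma > window[1] &
    shifts$time_ma <= window[2]
  list(times = shifts$time_ma[sel], mean = mean(shifts$time_ma[sel]))
}
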