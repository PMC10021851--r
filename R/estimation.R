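#' Maternal mortality ratio from reported counts
#'
#' Standard ratio estimator: maternal deaths per 100,000 live births over the
#' analysis window (counts are cumulative, not annualised).
#'
#' @param maternal_deaths Non-negative integer count(s) of maternal deaths.
#' @param live_births Positive integer count(s) of live births.
#' @return Numeric MMR, deaths per 100,000 live births.
#' @examples
#' compute_mmr(61169, 61982623)  # national HMIS 2017-19 counts -> 98.69
#' @export
compute_mmr <- function(maternal_deaths, live_births) {
  .check_rate_inputs(maternal_deaths, live_births, "maternal_deaths")
  maternal_deaths / live_births * 1e5
}

#' Infant mortality rate from reported counts
#'
#' Infant deaths per 1,000 live births; used as a calibration proxy for
#' states whose reference MMR is unavailable.
#'
#' @param infant_deaths Non-negative integer count(s).
#' @param live_births Positive integer count(s).
#' @return Numeric IMR, deaths per 1,000 live births.
#' @export
compute_imr <- function(infant_deaths, live_births) {
  .check_rate_inputs(infant_deaths, live_births, "infant_deaths")
  infant_deaths / live_births * 1e3
}

.check_rate_inputs <- function(deaths, births, what) {
  if (any(!is.finite(deaths)) || any(!is.finite(births)))
    stop("non-finite counts supplied")
  if (any(births == 0))
    stop("live_births is zero: rate undefined (distinct from a zero rate)")
  if (any(births < 0)) stop("live_births must be non-negative")
  if (any(deaths < 0)) stop(what, " must be non-negative")
  if (any(deaths > births)) stop(what, " exceeds live_births")
  invisible(TRUE)
}

#' Pooled state-level rate from district counts
#'
#' State rates are computed from summed numerator and denominator counts,
#' never as an average of district rates (the two differ whenever district
#' denominators differ).
#'
#' @param districts Data frame with columns `state_id`, `live_births` and
#'   `maternal_deaths` (for `which = "mmr"`) or `infant_deaths`
#'   (for `which = "imr"`).
#' @param which `"mmr"` (per 100,000) or `"imr"` (per 1,000).
#' @return Data frame with `state_id` and `rate`, one row per state.
#' @export
state_hmis_rate <- function(districts, which = c("mmr", "imr")) {
  which <- match.arg(which)
  num_col <- if (which == "mmr") "maternal_deaths" else "infant_deaths"
  need <- c("state_id", "live_births", num_col)
  miss <- setdiff(need, names(districts))
  if (length(miss)) stop("districts table lacks columns: ",
                         paste(miss, collapse = ", "))
  births <- tapply(districts$live_births, districts$state_id, sum)
  deaths <- tapply(districts[[num_col]], districts$state_id, sum)
  zero <- names(births)[births == 0]
  if (length(zero))
    stop("state(s) with zero live births, rate undefined: ",
         paste(zero, collapse = ", "))
  rate <- if (which == "mmr") compute_mmr(deaths, births)
          else compute_imr(deaths, births)
  data.frame(state_id = names(births), rate = as.numeric(rate),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-state calibration factor against a reference system
#'
#' The calibration factor is the ratio of the gold-standard reference rate to
#' the facility-reported (HMIS-style) rate for the same state. When the
#' reference MMR is available it always wins; otherwise the IMR ratio stands
#' in as a proxy. The provenance of each factor is recorded.
#'
#' @param ref_mmr Reference MMR (per 100,000) or `NA` if unavailable.
#' @param ref_imr Reference IMR (per 1,000) or `NA`.
#' @param hmis_mmr Facility-reported state MMR (pooled counts).
#' @param hmis_imr Facility-reported state IMR (pooled counts).
#' @param allow_imr_fallback_on_degenerate Fall back to the IMR-proxy path
#'   when the reference MMR is present but the facility MMR is zero (which
#'   would make the factor infinite). Off by default: such a state is an
#'   error the analyst should see.
#' @return List with elements `cf` (positive multiplier) and `source`
#'   (`"mmr_based"` or `"imr_proxy"`).
#' @export
calibration_factor <- function(ref_mmr, ref_imr, hmis_mmr, hmis_imr,
                               allow_imr_fallback_on_degenerate = FALSE) {
  mmr_ok <- !is.na(ref_mmr)
  if (mmr_ok && hmis_mmr == 0 && allow_imr_fallback_on_degenerate &&
      !is.na(ref_imr))
    mmr_ok <- FALSE
  if (mmr_ok) {
    if (hmis_mmr == 0)
      stop("degenerate calibration: facility MMR is zero with a positive ",
           "reference MMR (set allow_imr_fallback_on_degenerate = TRUE to ",
           "use the IMR proxy)")
    return(list(cf = ref_mmr / hmis_mmr, source = "mmr_based"))
  }
  if (is.na(ref_imr))
    stop("no reference rate available: both ref_mmr and ref_imr missing")
  if (hmis_imr == 0)
    stop("degenerate calibration: facility IMR is zero on the proxy path")
  list(cf = ref_imr / hmis_imr, source = "imr_proxy")
}

#' Apply state calibration factors to district MMRs
#'
#' Element-wise multiplication of each district's unadjusted MMR by its
#' state's calibration factor; a zero unadjusted rate stays zero.
#'
#' @param mmr_unadjusted Numeric vector of district MMRs.
#' @param state_id Character vector of state assignments, same length.
#' @param cf_table Data frame with `state_id` and `cf`.
#' @return Numeric vector of adjusted district MMRs.
#' @export
adjust_districts <- function(mmr_unadjusted, state_id, cf_table) {
  idx <- match(state_id, cf_table$state_id)
  if (anyNA(idx))
    stop("no calibration factor for state(s): ",
         paste(unique(state_id[is.na(idx)]), collapse = ", "))
  mmr_unadjusted * cf_table$cf[idx]
}

#' District population weights within states
#'
#' Each district's share of its state's female population aged 15-49; used
#' to aggregate adjusted district MMRs to the state level.
#'
#' @param female_pop Numeric vector of district female-population counts.
#' @param state_id State assignment per district.
#' @return Numeric vector of weights in `[0, 1]` summing to 1 within each
#'   state.
#' @export
population_weights <- function(female_pop, state_id) {
  if (any(female_pop < 0)) stop("negative population counts")
  tot <- tapply(female_pop, state_id, sum)
  zero <- names(tot)[tot == 0]
  if (length(zero))
    stop("state(s) with zero female population: ",
         paste(zero, collapse = ", "))
  as.numeric(female_pop / tot[match(state_id, names(tot))])
}

#' Population-weighted state aggregation of adjusted district MMRs
#'
#' @param mmr_adjusted Adjusted district MMRs.
#' @param pw Population weights from [population_weights()].
#' @param state_id State assignment per district.
#' @return Data frame with `state_id` and `mmr_adjusted`.
#' @export
aggregate_states <- function(mmr_adjusted, pw, state_id) {
  if (length(mmr_adjusted) != length(pw) ||
      length(mmr_adjusted) != length(state_id))
    stop("mmr_adjusted, pw and state_id must have equal length")
  s <- tapply(mmr_adjusted * pw, state_id, sum)
  data.frame(state_id = names(s), mmr_adjusted = as.numeric(s),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' SDG-3.1 classification of an MMR value
#'
#' Bins follow the SDG target cut-offs: below 70 (the 2030 target), 70-139,
#' 140-209 and at-or-above 210 deaths per 100,000 live births. Bins are
#' half-open: 70 falls in the second bin, 210 in the fourth.
#'
#' @param mmr Numeric vector of finite, non-negative MMRs.
#' @return Factor with levels `below_70`, `70_139`, `140_209`, `ge_210`.
#' @export
classify_sdg <- function(mmr) {
  if (any(!is.finite(mmr)) || any(mmr < 0))
    stop("MMR must be finite and non-negative for classification")
  cut(mmr, breaks = c(-Inf, 70, 140, 210, Inf), right = FALSE,
      labels = c("below_70", "70_139", "140_209", "ge_210"))
}

#' Registration completeness percentage
#'
#' Share of demographically expected live births captured by the reporting
#' system, as a percentage.
#'
#' @param reported_births Births recorded by the facility system.
#' @param estimated_births Independently estimated births (must be > 0).
#' @return Percentage `100 * reported / estimated`.
#' @examples
#' completeness(62e6, 81e6)  # ~76.5, rounds to 77
#' @export
completeness <- function(reported_births, estimated_births) {
  if (any(estimated_births <= 0)) stop("estimated_births must be positive")
  if (any(reported_births < 0)) stop("reported_births must be non-negative")
  100 * reported_births / estimated_births
}
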