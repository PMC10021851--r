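#' Fit a calibrated district MMR model
#'
#' The central estimator: computes raw district MMRs from facility-reported
#' counts, derives one calibration factor per state as the ratio of the
#' reference (gold-standard) rate to the pooled facility rate — using the
#' IMR-proxy path where the reference MMR is missing — rescales every
#' district by its state's factor, and aggregates back to states with
#' female-population (15-49) weights.
#'
#' Districts with zero live births have undefined MMR: they are kept in the
#' output with `NA` estimates, flagged, and excluded from classification and
#' state aggregation.
#'
#' @param districts Data frame with columns `district_id`, `state_id`,
#'   `live_births`, `maternal_deaths`, `infant_deaths`, `female_pop_15_49`.
#' @param states Data frame with columns `state_id`, `ref_mmr` (per 100,000,
#'   `NA` allowed) and `ref_imr` (per 1,000, `NA` allowed); at least one of
#'   the two must be present for every state.
#' @param allow_imr_fallback_on_degenerate Passed to
#'   [calibration_factor()]: permit the proxy path when a state's facility
#'   MMR is zero against a positive reference.
#' @return An object of class `mmr_calibration` with components
#'   \describe{
#'     \item{districts}{per-district table: unadjusted and adjusted MMR,
#'       population weight `pw`, SDG category, `undefined` flag.}
#'     \item{states}{per-state table: calibration factor `cf`, its
#'       provenance `cf_source`, facility rates and the adjusted state MMR.}
#'     \item{call}{the matched call.}
#'   }
#' @seealso [classify_sdg()], [summarize_classification()]
#' @examples
#' sys <- generate_system(synthetic_config(n_states = 4,
#'   districts_per_state = 5, lattice_rows = 4, lattice_cols = 5, seed = 1))
#' fit <- mmr_calibrate(sys$districts, sys$states)
#' fit
#' head(coef(fit))
#' @export
mmr_calibrate <- function(districts, states,
                          allow_imr_fallback_on_degenerate = FALSE) {
  need_d <- c("district_id", "state_id", "live_births", "maternal_deaths",
              "infant_deaths", "female_pop_15_49")
  miss <- setdiff(need_d, names(districts))
  if (length(miss)) stop("districts table lacks columns: ",
                         paste(miss, collapse = ", "))
  need_s <- c("state_id", "ref_mmr", "ref_imr")
  miss <- setdiff(need_s, names(states))
  if (length(miss)) stop("states table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(districts$district_id))
    stop("duplicated district_id values")
  unknown <- setdiff(districts$state_id, states$state_id)
  if (length(unknown))
    stop("district state_id not in states table: ",
         paste(unknown, collapse = ", "))
  both_na <- is.na(states$ref_mmr) & is.na(states$ref_imr)
  if (any(both_na))
    stop("state(s) with neither ref_mmr nor ref_imr: ",
         paste(states$state_id[both_na], collapse = ", "))

  d <- districts
  undef <- d$live_births == 0
  if (any(d$maternal_deaths[undef] > 0))
    stop("district(s) with maternal deaths but zero live births")
  mmr_un <- rep(NA_real_, nrow(d))
  mmr_un[!undef] <- compute_mmr(d$maternal_deaths[!undef],
                                d$live_births[!undef])

  # pooled facility rates per state (zero-birth districts contribute 0/0)
  hmis_mmr <- state_hmis_rate(d, "mmr")
  hmis_imr <- state_hmis_rate(d, "imr")
  s <- states[, need_s]
  s$hmis_mmr <- hmis_mmr$rate[match(s$state_id, hmis_mmr$state_id)]
  s$hmis_imr <- hmis_imr$rate[match(s$state_id, hmis_imr$state_id)]

  cf <- vector("list", nrow(s))
  for (i in seq_len(nrow(s))) {
    cf[[i]] <- tryCatch(
      calibration_factor(s$ref_mmr[i], s$ref_imr[i],
                         s$hmis_mmr[i], s$hmis_imr[i],
                         allow_imr_fallback_on_degenerate),
      error = function(e) stop("state ", s$state_id[i], ": ",
                               conditionMessage(e), call. = FALSE))
  }
  s$cf <- vapply(cf, `[[`, numeric(1), "cf")
  s$cf_source <- vapply(cf, `[[`, character(1), "source")

  d$mmr_unadjusted <- mmr_un
  d$mmr_adjusted <- adjust_districts(ifelse(undef, NA_real_, mmr_un),
                                     d$state_id,
                                     s[, c("state_id", "cf")])
  d$pw <- population_weights(d$female_pop_15_49, d$state_id)
  d$undefined <- undef
  d$sdg_category <- factor(NA, levels = levels(classify_sdg(0)))
  d$sdg_category[!undef] <- classify_sdg(d$mmr_adjusted[!undef])

  # aggregate over defined districts, renormalising weights within state
  dd <- d[!undef, ]
  pw_def <- population_weights(dd$female_pop_15_49, dd$state_id)
  agg <- aggregate_states(dd$mmr_adjusted, pw_def, dd$state_id)
  s$mmr_adjusted <- agg$mmr_adjusted[match(s$state_id, agg$state_id)]

  structure(list(districts = d, states = s, call = match.call()),
            class = "mmr_calibration")
}

#' @export
print.mmr_calibration <- function(x, ...) {
  cat("Calibrated district MMR estimates\n")
  cat(sprintf("  %d districts in %d states (%d with undefined MMR)\n",
              nrow(x$districts), nrow(x$states), sum(x$districts$undefined)))
  src <- table(x$states$cf_source)
  cat("  calibration: ",
      paste(sprintf("%s x%d", names(src), as.integer(src)), collapse = ", "),
      "\n", sep = "")
  ok <- !x$districts$undefined
  cat(sprintf("  adjusted district MMR: min %.1f, median %.1f, max %.1f\n",
              min(x$districts$mmr_adjusted[ok]),
              stats::median(x$districts$mmr_adjusted[ok]),
              max(x$districts$mmr_adjusted[ok])))
  invisible(x)
}

#' @export
summary.mmr_calibration <- function(object, ...) {
  out <- list(
    n_districts = nrow(object$districts),
    n_undefined = sum(object$districts$undefined),
    cf = object$states[, c("state_id", "cf", "cf_source")],
    state_mmr = object$states[, c("state_id", "mmr_adjusted")],
    sdg_districts = table(object$districts$sdg_category),
    sdg_states = table(classify_sdg(object$states$mmr_adjusted)))
  class(out) <- "summary.mmr_calibration"
  out
}

#' @export
print.summary.mmr_calibration <- function(x, ...) {
  cat("Calibrated district MMR estimates\n\n")
  cat(sprintf("Districts: %d (%d undefined MMR excluded from bins)\n",
              x$n_districts, x$n_undefined))
  cat("\nCalibration factors:\n")
  print(x$cf, row.names = FALSE)
  cat("\nSDG-3.1 classification (districts):\n")
  print(x$sdg_districts)
  cat("\nSDG-3.1 classification (states):\n")
  print(x$sdg_states)
  invisible(x)
}

#' @describeIn mmr_calibrate Named vector of state calibration factors.
#' @param object,x A fitted `mmr_calibration` object.
#' @param ... Unused.
#' @export
coef.mmr_calibration <- function(object, ...) {
  stats::setNames(object$states$cf, object$states$state_id)
}

#' @describeIn mmr_calibrate Adjusted district MMRs, named by district.
#' @export
fitted.mmr_calibration <- function(object, ...) {
  stats::setNames(object$districts$mmr_adjusted,
                  object$districts$district_id)
}

#' @describeIn mmr_calibrate Apply the fitted calibration factors to a new
#'   district table (same schema as `districts`).
#' @param newdata District table to adjust with the stored factors.
#' @export
predict.mmr_calibration <- function(object, newdata, ...) {
  if (missing(newdata)) return(fitted(object))
  undef <- newdata$live_births == 0
  raw <- rep(NA_real_, nrow(newdata))
  raw[!undef] <- compute_mmr(newdata$maternal_deaths[!undef],
                             newdata$live_births[!undef])
  stats::setNames(
    adjust_districts(raw, newdata$state_id,
                     object$states[, c("state_id", "cf")]),
    newdata$district_id)
}

#' @describeIn mmr_calibrate Histogram of adjusted district MMRs with the
#'   SDG cut-offs marked.
#' @export
plot.mmr_calibration <- function(x, ...) {
  ok <- !x$districts$undefined
  graphics::hist(x$districts$mmr_adjusted[ok], breaks = 30,
                 main = "Adjusted district MMR",
                 xlab = "deaths per 100,000 live births", ...)
  graphics::abline(v = c(70, 140, 210), lty = 2)
  invisible(x)
}
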