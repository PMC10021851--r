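#' HDI-style dimension index
#'
#' Min-max normalisation of an indicator onto `[0, 1]` between goalposts,
#' clamping values outside the goalposts.
#'
#' @param value Numeric indicator value(s).
#' @param goal_min,goal_max Goalposts with `goal_max > goal_min`.
#' @return Value(s) in `[0, 1]`.
#' @export
dimension_index <- function(value, goal_min, goal_max) {
  if (any(goal_max <= goal_min))
    stop("degenerate goalposts: goal_max must exceed goal_min")
  pmin(pmax((value - goal_min) / (goal_max - goal_min), 0), 1)
}

#' Aggregate dimension indices into a raw index
#'
#' @param indices Numeric vector (or row-wise matrix) of dimension indices.
#' @param method `"arithmetic"` (default) or `"geometric"` mean.
#' @return Scalar (or per-row) raw index.
#' @export
aggregate_hii <- function(indices, method = c("arithmetic", "geometric")) {
  method <- match.arg(method)
  if (is.matrix(indices)) {
    if (ncol(indices) == 0) stop("no dimension indices supplied")
    return(apply(indices, 1, aggregate_hii, method = method))
  }
  if (length(indices) == 0) stop("no dimension indices supplied")
  if (method == "arithmetic") mean(indices)
  else exp(mean(log(pmax(indices, .Machine$double.eps))))
}

#' Urban-share adjustment of the raw index
#'
#' Convex combination of the raw index with an urban component imputed at
#' the upper goalpost: `(1 - share) * raw + share * 1`. This gives weight
#' to urban (largely private) infrastructure not captured by the rural
#' indicators; the adjusted value is never below the raw one.
#'
#' @param raw_hii Raw index value(s) in `[0, 1]`.
#' @param urban_share Urban population share(s) in `[0, 1]`.
#' @return Adjusted index value(s).
#' @export
urban_adjust <- function(raw_hii, urban_share) {
  if (any(urban_share < 0 | urban_share > 1))
    stop("urban_share must lie in [0, 1]")
  (1 - urban_share) * raw_hii + urban_share
}

#' Health Infrastructure Index for a district table
#'
#' Normalises each per-1,000-population facility/personnel indicator into a
#' dimension index (goalposts default to the observed cross-district
#' min/max), aggregates the indices, and applies the urban-share
#' adjustment.
#'
#' @param data Data frame with `district_id`, one column per indicator, and
#'   `urban_share`.
#' @param indicators Character vector of indicator column names (default:
#'   all numeric columns except `urban_share`).
#' @param goalposts `"observed"` or a data frame with columns `indicator`,
#'   `goal_min`, `goal_max`.
#' @param aggregation `"arithmetic"` or `"geometric"`.
#' @return Data frame `district_id`, one `idx_*` column per indicator,
#'   `raw_hii`, `adjusted_hii`.
#' @export
compute_hii <- function(data, indicators = NULL, goalposts = "observed",
                        aggregation = c("arithmetic", "geometric")) {
  aggregation <- match.arg(aggregation)
  if (!"urban_share" %in% names(data)) stop("data lacks 'urban_share'")
  if (is.null(indicators))
    indicators <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                          "urban_share")
  if (!length(indicators)) stop("no indicator columns")
  if (any(vapply(data[indicators], function(x) any(x < 0), logical(1))))
    stop("indicators must be non-negative")
  gp <- if (identical(goalposts, "observed")) {
    data.frame(indicator = indicators,
               goal_min = vapply(data[indicators], min, numeric(1)),
               goal_max = vapply(data[indicators], max, numeric(1)))
  } else {
    stopifnot(all(c("indicator", "goal_min", "goal_max") %in%
                    names(goalposts)))
    goalposts[match(indicators, goalposts$indicator), ]
  }
  idx <- mapply(function(col, lo, hi) dimension_index(data[[col]], lo, hi),
                gp$indicator, gp$goal_min, gp$goal_max)
  idx <- matrix(idx, nrow = nrow(data),
                dimnames = list(NULL, paste0("idx_", gp$indicator)))
  raw <- aggregate_hii(idx, method = aggregation)
  data.frame(district_id = data$district_id, idx,
             raw_hii = raw,
             adjusted_hii = urban_adjust(raw, data$urban_share),
             stringsAsFactors = FALSE)
}
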