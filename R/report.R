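#' Classification summary over adjusted estimates
#'
#' Counts districts and states per SDG-3.1 bin and reports the extremes.
#' Undefined (zero-birth) districts are excluded; the bin counts always sum
#' to the number of districts with a defined MMR.
#'
#' @param fit A [mmr_calibrate()] result, or a list with `districts`
#'   (`district_id`, `mmr_adjusted`) and optionally `states`.
#' @param bin_edges Increasing internal cut-offs (default `c(70, 140,
#'   210)`, the SDG-based bins).
#' @return List of class `classification_summary`: `district_counts`,
#'   `state_counts`, `extremes`.
#' @export
summarize_classification <- function(fit, bin_edges = c(70, 140, 210)) {
  if (any(diff(bin_edges) <= 0)) stop("bin edges must be increasing")
  d <- fit$districts
  ok <- if ("undefined" %in% names(d)) !d$undefined else
    is.finite(d$mmr_adjusted)
  labs <- c(paste0("below_", bin_edges[1]),
            paste0(bin_edges[-length(bin_edges)], "_",
                   bin_edges[-1] - 1),
            paste0("ge_", bin_edges[length(bin_edges)]))
  cl <- cut(d$mmr_adjusted[ok], c(-Inf, bin_edges, Inf), right = FALSE,
            labels = labs)
  dmax <- which.max(ifelse(ok, d$mmr_adjusted, -Inf))
  dmin <- which.min(ifelse(ok, d$mmr_adjusted, Inf))
  out <- list(district_counts = table(cl),
              extremes = list(
                district_max = list(id = d$district_id[dmax],
                                    mmr = d$mmr_adjusted[dmax]),
                district_min = list(id = d$district_id[dmin],
                                    mmr = d$mmr_adjusted[dmin])))
  if (!is.null(fit$states) && "mmr_adjusted" %in% names(fit$states)) {
    s <- fit$states
    scl <- cut(s$mmr_adjusted, c(-Inf, bin_edges, Inf), right = FALSE,
               labels = labs)
    out$state_counts <- table(scl)
    smax <- which.max(s$mmr_adjusted); smin <- which.min(s$mmr_adjusted)
    out$extremes$state_max <- list(id = s$state_id[smax],
                                   mmr = s$mmr_adjusted[smax])
    out$extremes$state_min <- list(id = s$state_id[smin],
                                   mmr = s$mmr_adjusted[smin])
  }
  class(out) <- "classification_summary"
  out
}

#' @export
print.classification_summary <- function(x, ...) {
  cat("SDG-3.1 classification\n\nDistricts:\n")
  print(x$district_counts)
  if (!is.null(x$state_counts)) { cat("\nStates:\n"); print(x$state_counts) }
  e <- x$extremes
  cat(sprintf("\nHighest district: %s (%.0f)\n",
              e$district_max$id, e$district_max$mmr))
  if (!is.null(e$state_max))
    cat(sprintf("Highest state: %s (%.0f)\n", e$state_max$id,
                e$state_max$mmr))
  invisible(x)
}

#' Compare two rate series
#'
#' Pearson correlation between paired rates from two sources (e.g. the
#' reference system's IMR against facility-based MMR), with the paired
#' table used for source-comparison reporting.
#'
#' @param a,b Numeric rate vectors (paired by position or by shared names).
#' @param labels Length-2 names for the table columns.
#' @return List: `r` (Pearson correlation on complete pairs), `n_pairs`,
#'   `table`.
#' @export
compare_sources <- function(a, b, labels = c("a", "b")) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    common <- intersect(names(a), names(b))
    a <- a[common]; b <- b[common]
  }
  if (length(a) != length(b)) stop("series lengths differ")
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0)
    stop("zero variance in a series")
  tab <- data.frame(id = if (is.null(names(a))) seq_along(a) else names(a),
                    a = as.numeric(a), b = as.numeric(b))
  names(tab)[2:3] <- labels
  list(r = stats::cor(a[ok], b[ok]), n_pairs = sum(ok), table = tab[ok, ])
}

#' Run the full pipeline and write its artifacts
#'
#' Orchestrates the stages — calibration, optional health-infrastructure
#' index, spatial clustering, regression suite — over CSV inputs and
#' writes every stage output plus a run-metadata file. Deterministic
#' given the seed; rerunning the same configuration reproduces the
#' outputs byte for byte. Each stochastic stage derives its own seed from
#' the master seed so stages can be rerun independently.
#'
#' @param districts,states District and state tables (data frames) or
#'   paths to CSVs with the documented schemas.
#' @param adjacency Optional adjacency edge list (data frame or CSV path)
#'   enabling the spatial stage.
#' @param hii_inputs Optional indicator table for [compute_hii()].
#' @param covariates Covariate column names for the regression stage
#'   (default: numeric district columns beyond the count schema).
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @param n_permutations,alpha Spatial-inference settings.
#' @param bin_edges Classification cut-offs.
#' @param zero_policy Outcome zero handling for the regression stage.
#' @param stages Character subset of `c("estimate", "hii", "spatial",
#'   "regress")` to run; `estimate` is always required.
#' @return Invisibly, a list of the stage results and written paths.
#' @export
run_pipeline <- function(districts, states, adjacency = NULL,
                         hii_inputs = NULL, covariates = NULL,
                         out_dir = "mmrcal-out", seed = 1L,
                         n_permutations = 999, alpha = 0.05,
                         bin_edges = c(70, 140, 210),
                         zero_policy = "drop",
                         stages = c("estimate", "hii", "spatial",
                                    "regress")) {
  rd <- function(x) if (is.character(x))
    utils::read.csv(x, stringsAsFactors = FALSE) else x
  districts <- rd(districts); states <- rd(states)
  adjacency <- rd(adjacency); hii_inputs <- rd(hii_inputs)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list(); paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }

  fit <- tryCatch(mmr_calibrate(districts, states),
                  error = function(e) stop("stage estimate: ",
                                           conditionMessage(e),
                                           call. = FALSE))
  res$fit <- fit
  wr(fit$districts[, c("district_id", "state_id", "mmr_unadjusted",
                       "mmr_adjusted", "pw", "sdg_category")],
     "adjusted_districts.csv")
  wr(fit$states[, c("state_id", "cf", "cf_source", "mmr_adjusted")],
     "adjusted_states.csv")
  res$classification <- summarize_classification(fit, bin_edges)

  if ("hii" %in% stages && !is.null(hii_inputs)) {
    res$hii <- tryCatch(compute_hii(hii_inputs),
                        error = function(e) stop("stage hii: ",
                                                 conditionMessage(e),
                                                 call. = FALSE))
    wr(res$hii[, c("district_id", "raw_hii", "adjusted_hii")], "hii.csv")
  }

  if ("spatial" %in% stages && !is.null(adjacency)) {
    sp <- tryCatch({
      w <- build_weights(adjacency, ids = fit$districts$district_id)
      v <- stats::setNames(fit$districts$mmr_adjusted,
                           fit$districts$district_id)
      v <- v[!fit$districts$undefined]
      keep <- names(v)
      wk <- build_weights(adjacency[
        adjacency[[1]] %in% keep & adjacency[[2]] %in% keep, ],
        ids = keep)
      g <- moran_permutation_p(v, wk, n_permutations, seed = seed + 1L)
      l <- lisa_permutation(v, wk, n_permutations, seed = seed + 2L,
                            alpha = alpha)
      list(weights = wk, global = g, lisa = l)
    }, error = function(e) stop("stage spatial: ", conditionMessage(e),
                                call. = FALSE))
    res$spatial <- sp
    wr(data.frame(I = sp$global$I, expected_I = sp$global$expected_I,
                  pseudo_p = sp$global$pseudo_p,
                  n_permutations = sp$global$n_permutations,
                  seed = sp$global$seed), "moran_global.csv")
    wr(as.data.frame(sp$lisa), "lisa.csv")
  }

  if ("regress" %in% stages) {
    d <- fit$districts
    if (is.null(covariates))
      covariates <- setdiff(
        names(d)[vapply(d, is.numeric, logical(1))],
        c("live_births", "maternal_deaths", "infant_deaths",
          "female_pop_15_49", "mmr_unadjusted", "mmr_adjusted", "pw"))
    if (length(covariates)) {
      tab <- data.frame(district_id = d$district_id,
                        state_id = d$state_id,
                        mmr = d$mmr_adjusted,
                        d[, covariates, drop = FALSE])
      res$screen <- screen_collinearity(tab[, covariates, drop = FALSE])
      res$regression <- tryCatch(
        model_suite(tab,
                    specs = list(combined = model_spec(covariates,
                                                       label = "combined")),
                    univariate = covariates, zero_policy = zero_policy,
                    screen = res$screen),
        error = function(e) stop("stage regress: ", conditionMessage(e),
                                 call. = FALSE))
      wr(res$regression, "regression_table.csv")
    }
  }

  meta <- data.frame(
    key = c("seed", "n_permutations", "alpha", "bin_edges", "zero_policy",
            "stages", "n_districts", "n_states", "package_version"),
    value = c(seed, n_permutations, alpha,
              paste(bin_edges, collapse = "|"), zero_policy,
              paste(stages, collapse = "|"), nrow(fit$districts),
              nrow(fit$states),
              as.character(utils::packageVersion("mmrcal"))))
  wr(meta, "run_metadata.csv")
  res$paths <- paths
  invisible(res)
}
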