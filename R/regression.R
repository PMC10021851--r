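#' Log-transform the MMR outcome with an explicit zero policy
#'
#' The log-linear models use `log(MMR)`, which is undefined at zero.
#' Zero-MMR districts are dropped by default (each drop is reported);
#' alternatively a fixed offset is added before the log.
#'
#' @param mmr Non-negative district MMRs (names taken as district ids).
#' @param zero_policy `"drop"` or `"offset"`.
#' @param offset Offset added under the `"offset"` policy.
#' @return List: `log_mmr` (transformed values), `dropped` (data frame of
#'   excluded units with reasons).
#' @export
prepare_outcome <- function(mmr, zero_policy = c("drop", "offset"),
                            offset = 1) {
  zero_policy <- match.arg(zero_policy)
  if (any(mmr < 0, na.rm = TRUE)) stop("negative MMR values")
  ids <- if (is.null(names(mmr))) as.character(seq_along(mmr))
         else names(mmr)
  bad_na <- is.na(mmr)
  drop_zero <- !bad_na & mmr == 0 & zero_policy == "drop"
  keep <- !bad_na & !drop_zero
  y <- if (zero_policy == "offset") log(mmr[keep] + offset)
       else log(mmr[keep])
  dropped <- data.frame(
    district_id = ids[!keep],
    reason = ifelse(bad_na[!keep], "missing MMR", "zero MMR"),
    stringsAsFactors = FALSE)
  list(log_mmr = stats::setNames(y, ids[keep]), dropped = dropped)
}

#' Pairwise-correlation collinearity screen
#'
#' Pearson correlations between covariates on complete cases; pairs whose
#' absolute correlation exceeds the threshold are flagged and must not
#' enter the same model.
#'
#' @param covariates Data frame (numeric columns) with at least 2
#'   covariates and 3 rows.
#' @param threshold Flagging threshold on `|r|` (default 0.60).
#' @return Object of class `collinearity_screen`: correlation `matrix`,
#'   `flagged` pair table, `threshold`, `constant` (undefined-correlation
#'   columns).
#' @export
screen_collinearity <- function(covariates, threshold = 0.60) {
  covariates <- covariates[vapply(covariates, is.numeric, logical(1))]
  if (ncol(covariates) < 2) stop("need at least 2 covariates")
  cc <- stats::complete.cases(covariates)
  if (sum(cc) < 3) stop("need at least 3 complete rows")
  x <- covariates[cc, ]
  constant <- names(x)[vapply(x, function(v) stats::sd(v) == 0, logical(1))]
  m <- suppressWarnings(stats::cor(x))
  ut <- which(upper.tri(m) & abs(m) > threshold & !is.na(m), arr.ind = TRUE)
  flagged <- data.frame(var1 = rownames(m)[ut[, 1]],
                        var2 = colnames(m)[ut[, 2]],
                        r = m[ut], stringsAsFactors = FALSE)
  structure(list(matrix = m, flagged = flagged, threshold = threshold,
                 constant = constant),
            class = "collinearity_screen")
}

#' @export
print.collinearity_screen <- function(x, ...) {
  cat(sprintf("Collinearity screen (|r| > %.2f): %d flagged pair(s)\n",
              x$threshold, nrow(x$flagged)))
  if (nrow(x$flagged)) print(x$flagged, row.names = FALSE)
  if (length(x$constant))
    cat("constant covariate(s), correlation undefined: ",
        paste(x$constant, collapse = ", "), "\n")
  invisible(x)
}

#' Specify one log-linear OLS model
#'
#' @param covariates Character vector of covariate names, in order.
#' @param log_covariates Covariates entered as `log(x)`; defaults to none
#'   here, while [model_suite()] logs all strictly positive continuous
#'   covariates unless told otherwise.
#' @param state_effects Include state fixed effects (the interpretation
#'   used for area-level dummies).
#' @param label Model label for tables.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(covariates, log_covariates = character(0),
                       state_effects = FALSE, label = NULL) {
  if (anyDuplicated(covariates)) stop("duplicated covariate in model spec")
  bad <- setdiff(log_covariates, covariates)
  if (length(bad)) stop("log_covariates not in covariates: ",
                        paste(bad, collapse = ", "))
  structure(list(covariates = covariates, log_covariates = log_covariates,
                 state_effects = state_effects,
                 label = if (is.null(label))
                   paste(covariates, collapse = "+") else label),
            class = "model_spec")
}

#' Fit a log-linear OLS model with robust standard errors
#'
#' Ordinary least squares of `log(MMR)` on the specified covariates with
#' listwise deletion of incomplete rows and heteroskedasticity-robust
#' (sandwich) standard errors, HC1 by default. A model containing a
#' covariate pair flagged by [screen_collinearity()] fails validation
#' unless `allow_collinear = TRUE`.
#'
#' @param spec A [model_spec()].
#' @param data Data frame with column `mmr` (or `log_mmr`), the covariates,
#'   and `state_id` when `state_effects` is set.
#' @param zero_policy,offset Passed to [prepare_outcome()] when the
#'   outcome arrives as `mmr`.
#' @param robust Sandwich estimator flavour, `"HC0"`-`"HC3"`.
#' @param screen Optional `collinearity_screen` to validate against.
#' @param allow_collinear Override a failed collinearity validation.
#' @return Object of class `mmr_ols`: the underlying `lm` fit, `coefs`
#'   table (estimate, robust SE, t, p), `r_squared`, `n`, `dropped` report,
#'   `robust` flavour, `spec`.
#' @export
fit_ols <- function(spec, data, zero_policy = c("drop", "offset"),
                    offset = 1, robust = "HC1", screen = NULL,
                    allow_collinear = FALSE) {
  stopifnot(inherits(spec, "model_spec"))
  zero_policy <- match.arg(zero_policy)
  miss <- setdiff(spec$covariates, names(data))
  if (length(miss)) stop("covariate(s) not in data: ",
                         paste(miss, collapse = ", "))
  if (!is.null(screen) && !allow_collinear && nrow(screen$flagged)) {
    inmodel <- screen$flagged$var1 %in% spec$covariates &
      screen$flagged$var2 %in% spec$covariates
    if (any(inmodel)) {
      p <- screen$flagged[which(inmodel)[1], ]
      stop(sprintf(
        "collinear pair in model '%s': %s and %s (r = %.2f > %.2f)",
        spec$label, p$var1, p$var2, p$r, screen$threshold))
    }
  }

  ids <- if ("district_id" %in% names(data)) as.character(data$district_id)
         else as.character(seq_len(nrow(data)))
  if ("log_mmr" %in% names(data)) {
    y <- stats::setNames(data$log_mmr, ids)
    dropped <- data.frame(district_id = character(0), reason = character(0))
  } else {
    if (!"mmr" %in% names(data)) stop("data lacks 'mmr' or 'log_mmr'")
    prep <- prepare_outcome(stats::setNames(data$mmr, ids),
                            zero_policy, offset)
    y <- prep$log_mmr
    dropped <- prep$dropped
  }
  rows <- match(names(y), ids)
  X <- data[rows, spec$covariates, drop = FALSE]
  for (v in spec$log_covariates) {
    if (any(X[[v]] <= 0, na.rm = TRUE))
      stop("cannot log-transform non-positive covariate '", v, "'")
    X[[v]] <- log(X[[v]])
    names(X)[names(X) == v] <- paste0("log_", v)
  }
  df <- data.frame(log_mmr = as.numeric(y), X, check.names = FALSE)
  if (spec$state_effects) {
    if (!"state_id" %in% names(data)) stop("state_effects need 'state_id'")
    df$state_id <- factor(data$state_id[rows])
  }
  cc <- stats::complete.cases(df)
  if (any(!cc))
    dropped <- rbind(dropped,
                     data.frame(district_id = names(y)[!cc],
                                reason = "missing covariate",
                                stringsAsFactors = FALSE))
  df <- df[cc, , drop = FALSE]
  if (nrow(df) <= ncol(df)) stop("fewer rows than parameters")

  fml <- stats::as.formula(paste(
    "log_mmr ~",
    paste(c(sprintf("`%s`", setdiff(names(df), c("log_mmr", "state_id"))),
            if (spec$state_effects) "state_id"), collapse = " + ")))
  fit <- stats::lm(fml, data = df)
  if (anyNA(stats::coef(fit))) {
    nd <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; dependent column(s): ",
         paste(nd, collapse = ", "))
  }
  vc <- sandwich::vcovHC(fit, type = robust)
  ct <- lmtest::coeftest(fit, vcov. = vc)
  coefs <- data.frame(term = rownames(ct), estimate = ct[, 1],
                      robust_se = ct[, 2], t = ct[, 3], p = ct[, 4],
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(fit = fit, coefs = coefs,
                 r_squared = summary(fit)$r.squared,
                 n = nrow(df), dropped = dropped, robust = robust,
                 spec = spec),
            class = "mmr_ols")
}

#' @export
print.mmr_ols <- function(x, ...) {
  cat(sprintf("Log-linear OLS '%s' (n = %d, R^2 = %.3f, %s robust SE)\n",
              x$spec$label, x$n, x$r_squared, x$robust))
  print(transform(x$coefs, stars = .p_stars(p)), row.names = FALSE,
        digits = 4)
  if (nrow(x$dropped))
    cat(sprintf("dropped %d row(s): %s\n", nrow(x$dropped),
                paste(unique(x$dropped$reason), collapse = ", ")))
  invisible(x)
}

#' @export
coef.mmr_ols <- function(object, ...) stats::coef(object$fit)

#' @export
residuals.mmr_ols <- function(object, ...) stats::residuals(object$fit)

.p_stars <- function(p) {
  ifelse(p < 0.01, "***", ifelse(p < 0.05, "**", ifelse(p < 0.1, "*", "")))
}

#' Run a suite of log-linear models
#'
#' Mirrors the usual correlates-table layout: a univariate pass fitting
#' each covariate alone, then the configured grouped multivariable models.
#' Returns a long table (one row per model term) ready for reshaping into
#' a coefficient matrix.
#'
#' @param data Analysis table (see [fit_ols()]).
#' @param specs Named list of [model_spec()]s for the multivariable models.
#' @param univariate Covariates fitted one at a time as the first column;
#'   `NULL` skips the pass.
#' @param ... Passed to [fit_ols()].
#' @return Data frame `model`, `term`, `estimate`, `robust_se`, `p`,
#'   `stars`, `n`, `r2`, with the fitted `mmr_ols` objects in attribute
#'   `"fits"`.
#' @export
model_suite <- function(data, specs, univariate = NULL, ...) {
  out <- list(); fits <- list()
  if (!is.null(univariate)) {
    for (v in univariate) {
      f <- fit_ols(model_spec(v, label = "univariate"), data, ...)
      row <- f$coefs[f$coefs$term != "(Intercept)", ]
      out[[length(out) + 1]] <- data.frame(
        model = "univariate", term = row$term, estimate = row$estimate,
        robust_se = row$robust_se, p = row$p, stars = .p_stars(row$p),
        n = f$n, r2 = f$r_squared, stringsAsFactors = FALSE)
      fits[[paste0("univariate_", v)]] <- f
    }
  }
  for (nm in names(specs)) {
    f <- fit_ols(specs[[nm]], data, ...)
    out[[length(out) + 1]] <- data.frame(
      model = nm, term = f$coefs$term, estimate = f$coefs$estimate,
      robust_se = f$coefs$robust_se, p = f$coefs$p,
      stars = .p_stars(f$coefs$p), n = f$n, r2 = f$r_squared,
      stringsAsFactors = FALSE)
    fits[[nm]] <- f
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "fits") <- fits
  res
}
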