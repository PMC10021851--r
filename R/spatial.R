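#' Build queen-contiguity spatial weights from an edge list
#'
#' Constructs binary and row-standardised weight matrices from a (possibly
#' one-directional) adjacency edge list. Edges are symmetrised; self-edges
#' are dropped. Units with no neighbours (islands) are retained and
#' flagged: their row-standardised row is zero and they are excluded from
#' autocorrelation statistics with a warning.
#'
#' @param edges Data frame whose first two columns are unit ids of adjacent
#'   pairs (e.g. `district_id`, `neighbor_id`).
#' @param ids Optional complete unit id vector; its order fixes the unit
#'   ordering of the matrices and of positional (unnamed) value vectors.
#'   When omitted, ids are the sorted unique ids appearing in `edges`.
#'   Permutation engines draw per-unit samples in sorted-id order, so
#'   pseudo p-values are invariant to relabelling given the seed.
#' @return Object of class `spatial_weights`: `ids`, binary matrix `W`,
#'   row-standardised `W_star`, `degree`, `islands` (ids), and `S0`
#'   (sum of row-standardised weights).
#' @export
build_weights <- function(edges, ids = NULL) {
  a <- as.character(edges[[1]]); b <- as.character(edges[[2]])
  if (is.null(ids)) ids <- sort(unique(c(a, b))) else {
    ids <- as.character(ids)
    unknown <- setdiff(c(a, b), ids)
    if (length(unknown))
      stop("edge list references unknown id(s): ",
           paste(unique(unknown), collapse = ", "))
  }
  if (anyDuplicated(ids)) stop("unit ids must be unique")
  n <- length(ids)
  if (n < 2) stop("need at least 2 units")
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  i <- match(a, ids); j <- match(b, ids)
  keep <- i != j
  W[cbind(i[keep], j[keep])] <- 1
  W[cbind(j[keep], i[keep])] <- 1
  deg <- rowSums(W)
  W_star <- W / ifelse(deg == 0, 1, deg)
  structure(list(ids = ids, W = W, W_star = W_star, degree = deg,
                 islands = ids[deg == 0], S0 = sum(W_star)),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("Queen/adjacency spatial weights: %d units, %d links",
              length(x$ids), sum(x$W) / 2), "\n")
  cat(sprintf("  degree: min %d, mean %.2f, max %d; islands: %d\n",
              min(x$degree), mean(x$degree), max(x$degree),
              length(x$islands)))
  invisible(x)
}

# align a named/ordered value vector with weights, drop islands with warning
.moran_prep <- function(values, weights) {
  stopifnot(inherits(weights, "spatial_weights"))
  n <- length(weights$ids)
  if (length(values) != n)
    stop("values length (", length(values), ") != number of units (", n, ")")
  if (!is.null(names(values))) values <- values[weights$ids]
  if (any(!is.finite(values)))
    stop("non-finite values for unit(s): ",
         paste(weights$ids[!is.finite(values)], collapse = ", "))
  keep <- weights$degree > 0
  if (any(!keep))
    warning("excluding island unit(s) from spatial statistics: ",
            paste(weights$ids[!keep], collapse = ", "))
  list(values = values[keep], ids = weights$ids[keep],
       W_star = weights$W_star[keep, keep, drop = FALSE])
}

#' Global Moran's I
#'
#' Classical global spatial autocorrelation statistic on row-standardised
#' weights: with deviations `z = x - mean(x)`,
#' `I = (n / S0) * sum_ij w*_ij z_i z_j / sum_i z_i^2`. Its expectation
#' under no autocorrelation is `-1/(n-1)`.
#'
#' @param values Numeric vector, one value per unit (names matched to
#'   weight ids when present).
#' @param weights A [build_weights()] object.
#' @return Object of class `moran`: `I`, `expected_I`, `n`.
#' @export
global_moran <- function(values, weights) {
  p <- .moran_prep(values, weights)
  n <- length(p$values)
  if (n < 3) stop("need at least 3 non-island units")
  z <- p$values - mean(p$values)
  if (sum(z^2) == 0) stop("constant field: Moran's I undefined")
  S0 <- sum(p$W_star)
  I <- (n / S0) * drop(z %*% p$W_star %*% z) / sum(z^2)
  structure(list(I = I, expected_I = -1 / (n - 1), n = n), class = "moran")
}

#' @export
print.moran <- function(x, ...) {
  cat(sprintf("Global Moran's I = %.4f (E[I] = %.4f, n = %d)\n",
              x$I, x$expected_I, x$n))
  if (!is.null(x$pseudo_p))
    cat(sprintf("  pseudo p = %.4g (%d permutations, seed %d)\n",
                x$pseudo_p, x$n_permutations, x$seed))
  invisible(x)
}

#' Permutation pseudo p-value for global Moran's I
#'
#' Values are randomly reassigned across units `n_permutations` times and
#' the statistic recomputed; the pseudo p-value is
#' `(count{at least as extreme toward the observed sign} + 1) /
#' (n_permutations + 1)`, one-sided toward the sign of the observed
#' departure from `E[I]`, with ties counted as extreme. Its floor is
#' `1/(n_permutations + 1)` — 0.001 at the default 999 permutations.
#'
#' @inheritParams global_moran
#' @param n_permutations Number of random permutations (default 999).
#' @param seed Integer seed making the draw deterministic.
#' @return A `moran` object with `pseudo_p`, `n_permutations`, `seed`.
#' @export
moran_permutation_p <- function(values, weights, n_permutations = 999,
                                seed = 1L) {
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  obs <- global_moran(values, weights)
  p <- .moran_prep(values, weights)
  n <- length(p$values)
  z <- p$values - mean(p$values)
  S0 <- sum(p$W_star)
  denom_fac <- n / S0
  set.seed(seed)
  I_perm <- vapply(seq_len(n_permutations), function(b) {
    zz <- z[sample.int(n)]
    denom_fac * drop(zz %*% p$W_star %*% zz) / sum(zz^2)
  }, numeric(1))
  upper <- obs$I >= obs$expected_I
  extreme <- if (upper) sum(I_perm >= obs$I) else sum(I_perm <= obs$I)
  obs$pseudo_p <- (extreme + 1) / (n_permutations + 1)
  obs$n_permutations <- n_permutations
  obs$seed <- as.integer(seed)
  obs
}

#' Local Moran's I (LISA) statistics and cluster quadrants
#'
#' Per-unit local autocorrelation `I_i = (z_i / m2) * sum_j w*_ij z_j` with
#' `m2 = sum z^2 / n`. Quadrants follow the usual cluster-map convention
#' from the signs of `z_i` and its spatial lag: HH (hot spot), LL (cold
#' spot), HL and LH (spatial outliers). Under row standardisation the mean
#' of the local statistics equals global I.
#'
#' @inheritParams global_moran
#' @return Data frame of class `lisa`: `district_id`, `local_i`,
#'   `quadrant`.
#' @export
local_moran <- function(values, weights) {
  p <- .moran_prep(values, weights)
  n <- length(p$values)
  if (n < 3) stop("need at least 3 non-island units")
  z <- p$values - mean(p$values)
  if (sum(z^2) == 0) stop("constant field: local Moran undefined")
  m2 <- sum(z^2) / n
  lag <- drop(p$W_star %*% z)
  Ii <- z / m2 * lag
  quadrant <- ifelse(z >= 0,
                     ifelse(lag >= 0, "HH", "HL"),
                     ifelse(lag >= 0, "LH", "LL"))
  out <- data.frame(district_id = p$ids, local_i = Ii, quadrant = quadrant,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("lisa", "data.frame")
  out
}

# Conditional permutation engine shared by uni- and bivariate LISA.
# For unit i the focal term (z_i or zx_i) is held fixed and the permuted
# field supplies neighbour values drawn without replacement from the other
# units. Per-unit draws are made in sorted-id order from one seeded stream,
# so results are invariant to unit relabelling given the seed.
# Extremeness is magnitude exceedance: a tail chosen from the observed sign
# would roughly double the nominal rejection rate.
.lisa_perm <- function(z_focal, z_field, W_star, n_permutations, seed,
                       obs_Ii, m2, ids = NULL) {
  n <- length(z_focal)
  set.seed(seed)
  pseudo_p <- numeric(n)
  unit_order <- if (is.null(ids)) seq_len(n) else order(ids)
  for (i in unit_order) {
    others <- z_field[-i]
    k <- sum(W_star[i, ] > 0)
    if (k == 0) { pseudo_p[i] <- NA_real_; next }
    # row-standardised weight of each neighbour is 1/k
    sims <- vapply(seq_len(n_permutations), function(b) {
      lag <- sum(others[sample.int(n - 1L, k)]) / k
      z_focal[i] / m2 * lag
    }, numeric(1))
    # magnitude exceedance (two-sided), ties counted as extreme: the
    # pseudo p is uniform under an i.i.d. field, so flagging at alpha
    # rejects the nominal share; direction is carried by the quadrant
    pseudo_p[i] <- (sum(abs(sims) >= abs(obs_Ii[i])) + 1) /
      (n_permutations + 1)
  }
  pseudo_p
}

#' Conditional-permutation significance for local Moran's I
#'
#' For each unit the focal value is held fixed while the remaining values
#' are permuted among the other units; the local statistic is recomputed
#' each time and the pseudo p-value is `(count{|I_perm| >= |I_obs|} + 1) /
#' (n_permutations + 1)`, with ties counted as extreme. Magnitude
#' exceedance keeps the flagged share at the nominal level under an
#' independent field (a tail picked from the observed sign would double
#' it); the cluster direction is carried by the quadrant. No
#' multiple-testing correction is applied by default (matching standard
#' LISA cluster maps); `fdr = TRUE` applies Benjamini-Hochberg before
#' flagging.
#'
#' @inheritParams moran_permutation_p
#' @param alpha Significance level for the `significant` flag.
#' @param fdr Apply a Benjamini-Hochberg correction before flagging.
#' @return The [local_moran()] data frame with `pseudo_p` and `significant`
#'   columns added.
#' @export
lisa_permutation <- function(values, weights, n_permutations = 999,
                             seed = 1L, alpha = 0.05, fdr = FALSE) {
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  res <- local_moran(values, weights)
  p <- .moran_prep(values, weights)
  z <- p$values - mean(p$values)
  m2 <- sum(z^2) / length(z)
  res$pseudo_p <- .lisa_perm(z, z, p$W_star, n_permutations, seed,
                             res$local_i, m2, ids = p$ids)
  padj <- if (fdr) stats::p.adjust(res$pseudo_p, "BH") else res$pseudo_p
  res$significant <- !is.na(padj) & padj < alpha
  attr(res, "n_permutations") <- n_permutations
  attr(res, "seed") <- as.integer(seed)
  attr(res, "alpha") <- alpha
  res
}

#' Bivariate local Moran's I
#'
#' Spatial association between a focal field `x` and the neighbourhood of a
#' second field `y`: `I_i^xy = (zx_i / m2x) * sum_j w*_ij zy_j`. With
#' `y = x` it reduces to the univariate local Moran. Conditional
#' permutation holds `x_i` fixed and permutes `y` among the other units.
#'
#' @param x,y Numeric fields, one value per unit.
#' @inheritParams lisa_permutation
#' @param n_permutations Permutations for pseudo p-values; `0` skips
#'   inference and returns statistics and quadrants only.
#' @return Data frame `district_id`, `local_i`, `quadrant` (from signs of
#'   `zx_i` and the lag of `zy`), plus `pseudo_p`/`significant` when
#'   permutations are requested.
#' @export
bivariate_local_moran <- function(x, y, weights, n_permutations = 999,
                                  seed = 1L, alpha = 0.05) {
  p <- .moran_prep(x, weights)
  py <- .moran_prep(y, weights)
  zx <- p$values - mean(p$values)
  zy <- py$values - mean(py$values)
  if (sum(zx^2) == 0 || sum(zy^2) == 0)
    stop("constant field: bivariate local Moran undefined")
  n <- length(zx)
  m2x <- sum(zx^2) / n
  lag_y <- drop(p$W_star %*% zy)
  Ii <- zx / m2x * lag_y
  quadrant <- ifelse(zx >= 0,
                     ifelse(lag_y >= 0, "HH", "HL"),
                     ifelse(lag_y >= 0, "LH", "LL"))
  out <- data.frame(district_id = p$ids, local_i = Ii, quadrant = quadrant,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (n_permutations >= 1) {
    out$pseudo_p <- .lisa_perm(zx, zy, p$W_star, n_permutations, seed,
                               Ii, m2x, ids = p$ids)
    out$significant <- !is.na(out$pseudo_p) & out$pseudo_p < alpha
  }
  class(out) <- c("lisa", "data.frame")
  out
}
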