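#' Configuration for the synthetic district system
#'
#' Describes a multi-state district system laid out on a rectangular
#' lattice, with a spatially autocorrelated true-MMR surface, binomially
#' sampled deaths, state-level under-reporting of deaths, covariates linked
#' to log-MMR through known coefficients, and a reference table that is
#' missing MMR for a configurable share of states (forcing the IMR-proxy
#' calibration path).
#'
#' Default sizes mirror the real system the package targets: 640 districts
#' in 32 states on a 20 x 32 lattice, state base MMRs spanning roughly the
#' published state range, and reference MMR withheld for half the states
#' (the reference registration system publishes MMR for only about half of
#' India's states/UTs).
#'
#' @param n_states Number of states.
#' @param districts_per_state Districts per state; states are contiguous
#'   row-major blocks of lattice cells, so neighbouring districts tend to
#'   share a state and the surface inherits state-level structure.
#' @param lattice_rows,lattice_cols Lattice dimensions; their product must
#'   equal `n_states * districts_per_state`.
#' @param base_mmr_range State base MMR interval (per 100,000 live births).
#' @param spatial_rho Neighbour-smoothing strength in `[0, 1)` for the true
#'   log-MMR surface.
#' @param reporting_fraction_range Interval in `(0, 1]` from which each
#'   state's death-reporting fraction is drawn (applied to maternal and
#'   infant deaths; births are fully reported).
#' @param births_per_district_range Integer interval of cumulative live
#'   births per district over the analysis window.
#' @param missing_reference_fraction Share of states whose reference MMR is
#'   withheld.
#' @param covariate_effects Named coefficients on log true MMR; one
#'   standard-normal covariate is generated per name.
#' @param noise_sd SD of the white-noise term on log true MMR.
#' @param true_imr_range State base IMR interval (per 1,000 live births) for
#'   the proxy surface.
#' @param pop_per_birth Female population aged 15-49 per cumulative live
#'   birth (population is proportional to births).
#' @param reference_noise_sd Lognormal SD of optional noise on the reference
#'   rates; 0 (default) sets the reference exactly to the truth.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_states = 32L,
                             districts_per_state = 20L,
                             lattice_rows = 20L,
                             lattice_cols = 32L,
                             base_mmr_range = c(60, 250),
                             spatial_rho = 0.5,
                             reporting_fraction_range = c(0.5, 1.0),
                             births_per_district_range = c(5e4, 1.5e5),
                             missing_reference_fraction = 0.5,
                             covariate_effects = c(anc4 = -0.3,
                                                   pnc = -0.2,
                                                   children_ever_born = 0.3,
                                                   schooling = -0.25,
                                                   poor_households = 0.2),
                             noise_sd = 0.15,
                             true_imr_range = c(15, 50),
                             pop_per_birth = 10,
                             reference_noise_sd = 0,
                             seed = 1L) {
  cfg <- list(n_states = as.integer(n_states),
              districts_per_state = as.integer(districts_per_state),
              lattice_rows = as.integer(lattice_rows),
              lattice_cols = as.integer(lattice_cols),
              base_mmr_range = as.numeric(base_mmr_range),
              spatial_rho = spatial_rho,
              reporting_fraction_range = as.numeric(reporting_fraction_range),
              births_per_district_range = as.numeric(births_per_district_range),
              missing_reference_fraction = missing_reference_fraction,
              covariate_effects = covariate_effects,
              noise_sd = noise_sd,
              true_imr_range = as.numeric(true_imr_range),
              pop_per_birth = pop_per_birth,
              reference_noise_sd = reference_noise_sd,
              seed = as.integer(seed))
  .validate_config(cfg)
  structure(cfg, class = "synthetic_config")
}

.validate_config <- function(cfg) {
  chk_range <- function(r, nm, lo = -Inf, hi = Inf) {
    if (length(r) != 2 || any(!is.finite(r)) || r[1] > r[2] ||
        r[1] < lo || r[2] > hi)
      stop("invalid field '", nm, "': must be a non-empty interval",
           if (is.finite(lo) || is.finite(hi))
             sprintf(" within [%s, %s]", lo, hi))
  }
  if (cfg$n_states < 1) stop("invalid field 'n_states'")
  if (cfg$districts_per_state < 1) stop("invalid field 'districts_per_state'")
  if (cfg$lattice_rows * cfg$lattice_cols !=
      cfg$n_states * cfg$districts_per_state)
    stop("invalid field 'lattice_rows/lattice_cols': lattice size must ",
         "equal n_states * districts_per_state")
  chk_range(cfg$base_mmr_range, "base_mmr_range", lo = 0)
  if (!is.finite(cfg$spatial_rho) || cfg$spatial_rho < 0 ||
      cfg$spatial_rho >= 1)
    stop("invalid field 'spatial_rho': must lie in [0, 1)")
  chk_range(cfg$reporting_fraction_range, "reporting_fraction_range",
            lo = 0, hi = 1)
  if (cfg$reporting_fraction_range[1] <= 0)
    stop("invalid field 'reporting_fraction_range': must lie in (0, 1]")
  chk_range(cfg$births_per_district_range, "births_per_district_range",
            lo = 1)
  if (cfg$missing_reference_fraction < 0 ||
      cfg$missing_reference_fraction > 1)
    stop("invalid field 'missing_reference_fraction': must lie in [0, 1]")
  if (length(cfg$covariate_effects) &&
      is.null(names(cfg$covariate_effects)))
    stop("invalid field 'covariate_effects': must be named")
  if (cfg$noise_sd < 0) stop("invalid field 'noise_sd'")
  chk_range(cfg$true_imr_range, "true_imr_range", lo = 0)
  if (cfg$pop_per_birth <= 0) stop("invalid field 'pop_per_birth'")
  if (cfg$reference_noise_sd < 0) stop("invalid field 'reference_noise_sd'")
  invisible(TRUE)
}

#' Queen-contiguity edge list of a rectangular lattice
#'
#' @param rows,cols Lattice dimensions.
#' @param ids Optional unit ids in row-major order (default: cell indices,
#'   zero-padded so lexicographic and lattice order coincide).
#' @return Data frame `district_id`, `neighbor_id` holding each undirected
#'   queen edge once in each direction (symmetric edge list).
#' @export
queen_lattice_edges <- function(rows, cols, ids = NULL) {
  n <- rows * cols
  if (is.null(ids))
    ids <- formatC(seq_len(n), width = nchar(n), flag = "0")
  if (length(ids) != n) stop("ids length must equal rows * cols")
  cell <- function(r, c) (r - 1L) * cols + c
  from <- integer(0); to <- integer(0)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    r <- rep(seq_len(rows), each = cols); c <- rep(seq_len(cols), rows)
    keep <- r + dr >= 1 & r + dr <= rows & c + dc >= 1 & c + dc <= cols
    from <- c(from, cell(r[keep], c[keep]))
    to <- c(to, cell(r[keep] + dr, c[keep] + dc))
  }
  data.frame(district_id = ids[from], neighbor_id = ids[to],
             stringsAsFactors = FALSE)
}

#' Generate a synthetic multi-state district system
#'
#' Builds the full input set for the calibration pipeline with known ground
#' truth: a district table (births, maternal/infant deaths, female
#' population, covariates), a state reference table (reference MMR withheld
#' for a configured share of states), a queen-contiguity adjacency list for
#' the lattice, and the truth tables.
#'
#' The true log-MMR surface is a state base effect plus an iterated
#' rho-weighted neighbour average of white noise (an approximate spatial
#' autoregressive field), plus covariate effects and independent noise.
#' Observed maternal deaths are `Binomial(births, trueMMR/1e5)` thinned
#' binomially by the state's reporting fraction, so deaths never exceed
#' births and the observed state rate is `r_s` times the true rate in
#' expectation. Infant deaths are generated the same way from the true-IMR
#' surface and thinned by the same fraction.
#'
#' @param config A [synthetic_config()].
#' @return List with elements `districts`, `states`, `adjacency`, `truth`
#'   (per-district) and `truth_states` (per-state true MMR and reporting
#'   fraction), plus the `config`.
#' @export
generate_system <- function(config = synthetic_config()) {
  if (!inherits(config, "synthetic_config")) .validate_config(config)
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_states * cfg$districts_per_state
  ids <- sprintf("d%03d", seq_len(n))
  state_ids <- sprintf("s%02d", seq_len(cfg$n_states))
  # contiguous row-major blocks keep states spatially compact
  state_of <- rep(state_ids, each = cfg$districts_per_state)

  edges <- queen_lattice_edges(cfg$lattice_rows, cfg$lattice_cols, ids)
  nbr <- split(match(edges$neighbor_id, ids), match(edges$district_id, ids))
  nbr <- nbr[order(as.integer(names(nbr)))]

  # spatial field: iterate u <- rho * mean(neighbour u) + e
  e <- stats::rnorm(n, 0, 1)
  u <- e
  for (it in 1:10) {
    lag <- vapply(seq_len(n), function(i) mean(u[nbr[[i]]]), numeric(1))
    u <- cfg$spatial_rho * lag + e
  }
  u <- (u - mean(u)) / stats::sd(u) * 0.25  # moderate district-level spread

  base_mmr <- stats::runif(cfg$n_states, cfg$base_mmr_range[1],
                           cfg$base_mmr_range[2])
  base_imr <- stats::runif(cfg$n_states, cfg$true_imr_range[1],
                           cfg$true_imr_range[2])

  k <- length(cfg$covariate_effects)
  X <- matrix(stats::rnorm(n * max(k, 1)), nrow = n)[, seq_len(k),
                                                     drop = FALSE]
  colnames(X) <- names(cfg$covariate_effects)
  xb <- if (k) drop(X %*% cfg$covariate_effects) else rep(0, n)
  eps <- stats::rnorm(n, 0, cfg$noise_sd)

  log_true_mmr <- log(base_mmr)[match(state_of, state_ids)] + u + xb + eps
  true_mmr <- exp(log_true_mmr)
  true_imr <- exp(log(base_imr)[match(state_of, state_ids)] + u)

  births <- as.integer(round(stats::runif(
    n, cfg$births_per_district_range[1], cfg$births_per_district_range[2])))
  rfrac <- stats::runif(cfg$n_states, cfg$reporting_fraction_range[1],
                        cfg$reporting_fraction_range[2])
  r_d <- rfrac[match(state_of, state_ids)]

  true_deaths <- stats::rbinom(n, births, pmin(true_mmr / 1e5, 1))
  obs_deaths <- stats::rbinom(n, true_deaths, r_d)
  true_ideaths <- stats::rbinom(n, births, pmin(true_imr / 1e3, 1))
  obs_ideaths <- stats::rbinom(n, true_ideaths, r_d)

  pop <- as.integer(round(births * cfg$pop_per_birth))

  districts <- data.frame(district_id = ids, state_id = state_of,
                          live_births = births,
                          maternal_deaths = obs_deaths,
                          infant_deaths = obs_ideaths,
                          female_pop_15_49 = pop,
                          stringsAsFactors = FALSE)
  if (k) districts <- cbind(districts, as.data.frame(X))

  # truth at state level: births-weighted true rates
  st_births <- tapply(births, state_of, sum)[state_ids]
  st_true_mmr <- tapply(true_mmr * births, state_of, sum)[state_ids] /
    st_births
  st_true_imr <- tapply(true_imr * births, state_of, sum)[state_ids] /
    st_births

  ref_mmr <- as.numeric(st_true_mmr)
  ref_imr <- as.numeric(st_true_imr)
  if (cfg$reference_noise_sd > 0) {
    ref_mmr <- ref_mmr * exp(stats::rnorm(cfg$n_states, 0,
                                          cfg$reference_noise_sd))
    ref_imr <- ref_imr * exp(stats::rnorm(cfg$n_states, 0,
                                          cfg$reference_noise_sd))
  }
  n_missing <- floor(cfg$missing_reference_fraction * cfg$n_states)
  missing_states <- sample(state_ids, n_missing)
  ref_mmr[state_ids %in% missing_states] <- NA_real_

  states <- data.frame(state_id = state_ids, ref_mmr = ref_mmr,
                       ref_imr = ref_imr, stringsAsFactors = FALSE)
  truth <- data.frame(district_id = ids, true_mmr = true_mmr,
                      true_imr = true_imr, stringsAsFactors = FALSE)
  truth_states <- data.frame(state_id = state_ids,
                             true_mmr = as.numeric(st_true_mmr),
                             true_imr = as.numeric(st_true_imr),
                             reporting_fraction = rfrac,
                             stringsAsFactors = FALSE)

  list(districts = districts, states = states, adjacency = edges,
       truth = truth, truth_states = truth_states, config = cfg)
}

#' Write a generated system to CSV fixtures
#'
#' Writes `districts.csv`, `states.csv`, `adjacency.csv` and `truth.csv`
#' under `directory` with the documented schemas; the files round-trip
#' losslessly through [read_system()].
#'
#' @param system Output of [generate_system()].
#' @param directory Target directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_fixture <- function(system, directory) {
  if (nrow(system$districts) == 0) stop("empty district table")
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("unwritable path: ", directory)
  paths <- file.path(directory,
                     c("districts.csv", "states.csv", "adjacency.csv",
                       "truth.csv"))
  utils::write.csv(system$districts, paths[1], row.names = FALSE)
  utils::write.csv(system$states, paths[2], row.names = FALSE)
  utils::write.csv(system$adjacency, paths[3], row.names = FALSE)
  utils::write.csv(system$truth, paths[4], row.names = FALSE)
  invisible(paths)
}

#' Read district/state/adjacency tables from a fixture directory
#'
#' @param directory Directory holding `districts.csv`, `states.csv` and
#'   `adjacency.csv` (and optionally `truth.csv`).
#' @return List with `districts`, `states`, `adjacency` and, when present,
#'   `truth`.
#' @export
read_system <- function(directory) {
  rd <- function(f) utils::read.csv(file.path(directory, f),
                                    stringsAsFactors = FALSE)
  out <- list(districts = rd("districts.csv"), states = rd("states.csv"),
              adjacency = rd("adjacency.csv"))
  tf <- file.path(directory, "truth.csv")
  if (file.exists(tf)) out$truth <- utils::read.csv(tf,
                                                    stringsAsFactors = FALSE)
  out
}
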