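# shared fixtures and independent oracles

# independent brute-force global Moran: explicit O(n^2) double sum on the
# row-standardised matrix, no reuse of package internals beyond the matrix
moran_brute <- function(values, weights) {
  keep <- weights$degree > 0
  if (!is.null(names(values))) values <- values[weights$ids]
  x <- values[keep]
  W <- weights$W_star[keep, keep]
  n <- length(x)
  z <- x - mean(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    num <- num + W[i, j] * z[i] * z[j]
  (n / sum(W)) * num / sum(z^2)
}

# minimal hand-built two-state, four-district system
tiny_districts <- function() {
  data.frame(
    district_id = c("d1", "d2", "d3", "d4"),
    state_id = c("A", "A", "B", "B"),
    live_births = c(10000L, 10000L, 20000L, 5000L),
    maternal_deaths = c(10L, 30L, 20L, 10L),
    infant_deaths = c(200L, 300L, 500L, 100L),
    female_pop_15_49 = c(30000L, 70000L, 160000L, 40000L),
    stringsAsFactors = FALSE)
}

tiny_states <- function(ref_mmr = c(300, NA), ref_imr = c(30, 25)) {
  data.frame(state_id = c("A", "B"), ref_mmr = ref_mmr, ref_imr = ref_imr,
             stringsAsFactors = FALSE)
}

small_config <- function(...) {
  synthetic_config(n_states = 4L, districts_per_state = 6L,
                   lattice_rows = 4L, lattice_cols = 6L, seed = 42L, ...)
}
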