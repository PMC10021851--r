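#' Published state-level adjusted MMR estimates for India, 2017-19
#'
#' Calibrated facility-based (HMIS) MMR estimates for 29 states and 7
#' union territories of India over 2017-19, as published alongside the
#' calibration method this package implements. Useful for classification
#' and reporting examples; the district-level table behind the national
#' analysis was released only as a PDF supplement and is not bundled.
#'
#' @return Data frame with columns `state` and `mmr_adjusted` (deaths per
#'   100,000 live births), 36 rows.
#' @examples
#' s <- india_state_mmr()
#' table(classify_sdg(s$mmr_adjusted))
#' @export
india_state_mmr <- function() {
  utils::read.csv(system.file("extdata", "india_state_mmr.csv",
                              package = "mmrcal", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}
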