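test_that("MMR and IMR are exact ratio arithmetic on counts", {
  # national facility counts and the reference-sample counts
  expect_equal(round(compute_mmr(61169, 61982623), 2), 98.69)
  expect_equal(round(compute_mmr(525, 429173), 2), 122.33)
  expect_equal(compute_mmr(0, 1000), 0)
  expect_equal(compute_imr(32, 1000), 32)
  expect_equal(compute_imr(0, 500), 0)
  expect_error(compute_mmr(1, 0), "undefined")
  expect_error(compute_mmr(11, 10), "exceeds")
  expect_error(compute_imr(-1, 10), "non-negative")
})

test_that("state rates pool counts, never average district rates", {
  d <- data.frame(state_id = "A", live_births = c(10000, 10000),
                  maternal_deaths = c(10, 30), infant_deaths = c(1, 1))
  expect_equal(state_hmis_rate(d, "mmr")$rate, 200)
  # unequal denominators: pooled differs from the unweighted mean
  d2 <- data.frame(state_id = "A", live_births = c(1000, 100000),
                   maternal_deaths = c(10, 10), infant_deaths = c(1, 1))
  pooled <- state_hmis_rate(d2, "mmr")$rate
  unweighted <- mean(compute_mmr(d2$maternal_deaths, d2$live_births))
  expect_equal(pooled, 20 / 101000 * 1e5)
  expect_false(isTRUE(all.equal(pooled, unweighted)))
  # single-district state equals its own rate
  d3 <- tiny_districts()[3, ]
  expect_equal(state_hmis_rate(d3, "mmr")$rate,
               compute_mmr(20, 20000))
  d3$live_births <- 0; d3$maternal_deaths <- 0
  expect_error(state_hmis_rate(d3, "mmr"), "B")
})

test_that("calibration factor prefers the reference MMR, proxies by IMR", {
  expect_equal(calibration_factor(150, NA, 150, 10),
               list(cf = 1, source = "mmr_based"))
  cf <- calibration_factor(NA, 32, 100, 26.2)
  expect_equal(cf$source, "imr_proxy")
  expect_equal(round(cf$cf, 3), 1.221)
  expect_equal(round(calibration_factor(130, NA, 98.69, NA)$cf, 3), 1.317)
  # MMR path wins even when the IMR ratio disagrees
  expect_equal(calibration_factor(100, 99, 50, 10)$cf, 2)
  expect_error(calibration_factor(NA, NA, 10, 10), "both")
  expect_error(calibration_factor(100, NA, 0, 10), "degenerate")
  fb <- calibration_factor(100, 30, 0, 15,
                           allow_imr_fallback_on_degenerate = TRUE)
  expect_equal(fb, list(cf = 2, source = "imr_proxy"))
  expect_error(calibration_factor(NA, 30, 10, 0), "degenerate")
})

test_that("district adjustment is element-wise with zero preserved", {
  cf_tab <- data.frame(state_id = c("A", "B"), cf = c(1.3, 1.0))
  expect_equal(adjust_districts(c(200, 0), c("A", "A"), cf_tab),
               c(260, 0))
  expect_equal(adjust_districts(c(5, 7), c("B", "B"), cf_tab), c(5, 7))
  expect_error(adjust_districts(1, "C", cf_tab), "C")
})

test_that("population weights are within-state proportions summing to 1", {
  expect_equal(population_weights(c(30000, 70000), c("A", "A")),
               c(0.3, 0.7))
  expect_equal(population_weights(5, "A"), 1)
  set.seed(9)
  pop <- runif(60, 1e4, 1e6)
  st <- sample(letters[1:5], 60, replace = TRUE)
  pw <- population_weights(pop, st)
  expect_true(all(pw >= 0 & pw <= 1))
  expect_equal(as.numeric(tapply(pw, st, sum)), rep(1, 5), tolerance = 1e-9)
  expect_error(population_weights(c(0, 0), c("A", "A")), "zero")
})

test_that("state aggregation is the weighted sum, order-invariant", {
  expect_equal(aggregate_states(c(100, 300), c(0.5, 0.5),
                                c("A", "A"))$mmr_adjusted, 200)
  expect_equal(aggregate_states(c(100, 300), c(0.25, 0.75),
                                c("A", "A"))$mmr_adjusted, 250)
  expect_equal(aggregate_states(rep(55, 4), rep(0.25, 4),
                                rep("A", 4))$mmr_adjusted, 55)
  m <- c(10, 20, 30); w <- c(0.2, 0.3, 0.5); s <- c("A", "B", "A")
  o <- c(3, 1, 2)
  expect_equal(aggregate_states(m, w, s), aggregate_states(m[o], w[o], s[o]))
  expect_error(aggregate_states(1:3, 1:2, c("A", "A")), "length")
})

test_that("SDG bins are half-open at 70/140/210", {
  expect_equal(as.character(classify_sdg(c(0, 69.99, 70, 139.99, 140,
                                           209.99, 210, 5000))),
               c("below_70", "below_70", "70_139", "70_139", "140_209",
                 "140_209", "ge_210", "ge_210"))
  mmr <- runif(200, 0, 400)
  expect_equal(sum(table(classify_sdg(mmr))), 200)  # bins partition
  expect_error(classify_sdg(-1), "non-negative")
  expect_error(classify_sdg(NaN), "finite")
})

test_that("registration completeness is a simple coverage percentage", {
  expect_equal(round(completeness(62e6, 81e6), 1), 76.5)
  expect_equal(round(completeness(62e6, 81e6)), 77)
  expect_equal(completeness(123, 123), 100)
  expect_equal(completeness(0, 10), 0)
  expect_error(completeness(1, 0), "positive")
})
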