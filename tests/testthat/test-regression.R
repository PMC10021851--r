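test_that("outcome preparation logs MMR and reports zero drops", {
  p <- prepare_outcome(c(a = 100, b = 0, c = 250))
  expect_equal(p$log_mmr, c(a = log(100), c = log(250)))
  expect_equal(p$dropped$district_id, "b")
  expect_equal(p$dropped$reason, "zero MMR")
  po <- prepare_outcome(c(a = 100, b = 0), zero_policy = "offset",
                        offset = 1)
  expect_equal(unname(po$log_mmr), log(c(101, 1)))
  expect_error(prepare_outcome(c(1, -2)), "negative")
  # one zero among 640 leaves 639 observations
  mmr <- runif(640, 10, 400); mmr[17] <- 0
  expect_length(prepare_outcome(mmr)$log_mmr, 639)
})

test_that("collinearity screen flags |r| above threshold and gates models", {
  set.seed(1)
  x <- rnorm(100)
  dat <- data.frame(x = x, y = 2 * x, z = rnorm(100))
  sc <- screen_collinearity(dat)
  expect_equal(nrow(sc$flagged), 1)
  expect_setequal(unlist(sc$flagged[1, c("var1", "var2")]), c("x", "y"))
  expect_equal(sc$flagged$r, 1)
  expect_true(isSymmetric(sc$matrix))
  expect_equal(unname(diag(sc$matrix)), rep(1, 3))

  # independent covariates at large n: nothing flagged
  set.seed(2)
  ind <- as.data.frame(matrix(rnorm(5000), ncol = 5))
  expect_equal(nrow(screen_collinearity(ind)$flagged), 0)

  # constant column is reported as undefined
  datc <- data.frame(x = x, k = rep(1, 100))
  expect_equal(screen_collinearity(datc)$constant, "k")

  # a flagged pair in a model spec fails validation, naming the pair
  set.seed(3)
  a <- rnorm(200); b <- 0.8 * a + rnorm(200, 0, 0.5)
  dd <- data.frame(mmr = exp(rnorm(200, 5, 0.3)), a = a, b = b)
  scr <- screen_collinearity(dd[, c("a", "b")])
  expect_gt(abs(scr$flagged$r[1]), 0.6)
  expect_error(fit_ols(model_spec(c("a", "b")), dd, screen = scr),
               "a and b")
  expect_s3_class(fit_ols(model_spec(c("a", "b")), dd, screen = scr,
                          allow_collinear = TRUE), "mmr_ols")
})

test_that("noiseless generative data is recovered exactly", {
  set.seed(4)
  n <- 200
  x1 <- rnorm(n); x2 <- rnorm(n)
  log_mmr <- 4.2 - 0.5 * x1 + 0.3 * x2
  dat <- data.frame(mmr = exp(log_mmr), x1 = x1, x2 = x2)
  # summary.lm warns about the (intentionally) perfect fit
  f <- suppressWarnings(fit_ols(model_spec(c("x1", "x2")), dat))
  expect_equal(unname(coef(f)), c(4.2, -0.5, 0.3), tolerance = 1e-8)
  expect_equal(f$n, n)
  expect_equal(f$r_squared, 1, tolerance = 1e-8)
})

test_that("estimates are order-invariant and R^2 never drops with a column", {
  set.seed(5)
  n <- 150
  dat <- data.frame(mmr = exp(rnorm(n, 5, 0.4)), x = rnorm(n),
                    junk = rnorm(n))
  f1 <- fit_ols(model_spec("x"), dat)
  f2 <- fit_ols(model_spec("x"), dat[sample(n), ])
  expect_equal(coef(f1), coef(f2), tolerance = 1e-10)
  f3 <- fit_ols(model_spec(c("x", "junk")), dat)
  expect_gte(f3$r_squared, f1$r_squared)
  # affine rescaling of an unlogged covariate rescales its coefficient
  dat$x100 <- dat$x * 100
  f4 <- fit_ols(model_spec("x100"), dat)
  expect_equal(unname(coef(f4)["x100"] * 100), unname(coef(f1)["x"]),
               tolerance = 1e-10)
})

test_that("robust SEs track classical ones under homoskedasticity", {
  set.seed(6)
  n <- 640
  x <- rnorm(n)
  dat <- data.frame(mmr = exp(3 + 0.4 * x + rnorm(n, 0, 0.3)), x = x)
  f <- fit_ols(model_spec("x"), dat)
  classical <- summary(f$fit)$coefficients[, 2]
  expect_equal(unname(f$coefs$robust_se), unname(classical),
               tolerance = 0.2)
})

test_that("listwise deletion, rank checks and transforms behave", {
  set.seed(7)
  n <- 60
  dat <- data.frame(district_id = sprintf("d%02d", 1:n),
                    mmr = exp(rnorm(n, 5, 0.3)),
                    x = rnorm(n), w = runif(n, 1, 9))
  dat$x[c(3, 9)] <- NA
  f <- fit_ols(model_spec("x"), dat)
  expect_equal(f$n, 58)
  expect_setequal(f$dropped$district_id, c("d03", "d09"))
  # log-transformed covariate enters as log
  fl <- fit_ols(model_spec("w", log_covariates = "w"), dat)
  expect_true("log_w" %in% fl$coefs$term)
  dat$neg <- dat$x
  expect_error(fit_ols(model_spec("neg", log_covariates = "neg"), dat),
               "non-positive")
  dat$dup <- dat$w * 3
  expect_error(fit_ols(model_spec(c("w", "dup")), dat), "rank-deficient")
})

test_that("the model suite reproduces standalone fits and recovers signs", {
  cfg <- synthetic_config(n_states = 4L, districts_per_state = 40L,
                          lattice_rows = 8L, lattice_cols = 20L,
                          births_per_district_range = c(5e5, 1e6),
                          covariate_effects = c(anc4 = -0.4, poor = 0.4),
                          noise_sd = 0.1, seed = 8L)
  sys <- generate_system(cfg)
  fit <- mmr_calibrate(sys$districts, sys$states)
  dat <- data.frame(district_id = sys$districts$district_id,
                    state_id = sys$districts$state_id,
                    mmr = fit$districts$mmr_adjusted,
                    anc4 = sys$districts$anc4, poor = sys$districts$poor)
  suite <- model_suite(dat,
                       specs = list(both = model_spec(c("anc4", "poor"))),
                       univariate = c("anc4", "poor"))
  expect_setequal(unique(suite$model), c("univariate", "both"))
  standalone <- fit_ols(model_spec("anc4"), dat)
  expect_equal(suite$estimate[suite$model == "univariate" &
                                suite$term == "anc4"],
               unname(coef(standalone)["anc4"]))
  both <- suite[suite$model == "both", ]
  expect_lt(both$estimate[both$term == "anc4"], 0)
  expect_gt(both$estimate[both$term == "poor"], 0)
  # state fixed effects are accepted as the area-dummy interpretation
  fs <- fit_ols(model_spec(c("anc4", "poor"), state_effects = TRUE), dat)
  expect_true(any(grepl("^state_id", fs$coefs$term)))
})
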