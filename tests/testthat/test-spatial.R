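test_that("weights build symmetric zero-diagonal matrices from edges", {
  w <- build_weights(data.frame(a = "a", b = "b"), ids = c("a", "b", "c"))
  expect_equal(w$W["a", "b"], 1)
  expect_equal(w$W["b", "a"], 1)
  expect_equal(diag(w$W), c(a = 0, b = 0, c = 0))
  expect_equal(w$islands, "c")

  w22 <- build_weights(queen_lattice_edges(2, 2))
  expect_true(all(w22$W[upper.tri(w22$W)] == 1))  # complete on 4
  w33 <- build_weights(queen_lattice_edges(3, 3))
  expect_identical(w33$W, t(w33$W))
  expect_equal(unname(w33$degree["5"]), 8)
  rs <- rowSums(w33$W_star)
  expect_equal(unname(rs), rep(1, 9), tolerance = 1e-12)
  expect_error(build_weights(data.frame(a = "a", b = "x"), ids = c("a", "b")),
               "unknown")
  expect_error(build_weights(data.frame(a = "a", b = "a")), "2 units")
})

test_that("global Moran matches the closed form and brute-force oracle", {
  w4 <- build_weights(queen_lattice_edges(2, 2))
  set.seed(1)
  for (rep in 1:5) {
    v <- rnorm(4)
    expect_equal(global_moran(v, w4)$I, -1 / 3, tolerance = 1e-12)
  }
  # random sparse fixtures against the O(n^2) double sum
  set.seed(2)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    m <- matrix(rbinom(n * n, 1, 0.2), n)
    m[lower.tri(m, diag = TRUE)] <- 0
    edges <- which(m == 1, arr.ind = TRUE)
    if (nrow(edges) < 2) next
    ids <- sprintf("u%02d", 1:n)
    w <- build_weights(data.frame(a = ids[edges[, 1]], b = ids[edges[, 2]]),
                       ids = ids)
    v <- rnorm(n)
    if (length(w$islands) == length(ids) - 1) next
    expect_equal(suppressWarnings(global_moran(v, w)$I),
                 suppressWarnings(moran_brute(v, w)), tolerance = 1e-12)
  }
  expect_error(global_moran(rep(1, 4), w4), "constant")
})

test_that("local Moran averages to global I and follows the sign rules", {
  w <- build_weights(queen_lattice_edges(5, 5))
  set.seed(3)
  v <- rnorm(25)
  l <- local_moran(v, w)
  g <- global_moran(v, w)
  expect_equal(mean(l$local_i), g$I, tolerance = 1e-10)
  # a unit placed at the mean of the others is at the overall mean too,
  # so its local statistic is exactly zero
  v2 <- v; v2[13] <- mean(v2[-13])
  l2 <- local_moran(v2, w)
  expect_equal(l2$local_i[13], 0, tolerance = 1e-12)
  # a high island of values among high neighbours is HH, low among low LL
  v3 <- rep(0, 25); v3[c(7, 8, 9, 12, 13, 14, 17, 18, 19)] <- 10
  l3 <- local_moran(v3, w)
  expect_equal(l3$quadrant[13], "HH")
  v4 <- -v3
  expect_equal(local_moran(v4, w)$quadrant[13], "LL")
  # high value among low neighbours is an HL outlier
  v5 <- rep(0, 25); v5[13] <- 10
  expect_equal(local_moran(v5, w)$quadrant[13], "HL")
})

test_that("permutation p-values hit their floor and are seed-deterministic", {
  w <- build_weights(queen_lattice_edges(6, 6))
  # strongly clustered gradient field: observed I beats every permutation
  v <- rep(1:6, each = 6) + rep(1:6, times = 6)
  g <- moran_permutation_p(v, w, n_permutations = 999, seed = 4)
  expect_equal(g$pseudo_p, 0.001)
  g2 <- moran_permutation_p(v, w, n_permutations = 999, seed = 4)
  expect_identical(g$pseudo_p, g2$pseudo_p)
  g1 <- moran_permutation_p(v, w, n_permutations = 1, seed = 4)
  expect_true(g1$pseudo_p %in% c(0.5, 1.0))
  l <- lisa_permutation(v, w, n_permutations = 99, seed = 4)
  expect_true(all(l$pseudo_p >= 1 / 100))
  l2 <- lisa_permutation(v, w, n_permutations = 99, seed = 4)
  expect_identical(l$pseudo_p, l2$pseudo_p)
})

test_that("islands are excluded from statistics with a warning", {
  edges <- queen_lattice_edges(3, 3)
  ids <- c(as.character(1:9), "iso")
  w <- build_weights(edges, ids = ids)
  expect_equal(w$islands, "iso")
  set.seed(5)
  v <- setNames(rnorm(10), ids)
  expect_warning(g <- global_moran(v, w), "iso")
  expect_equal(g$n, 9)
})

test_that("bivariate local Moran generalises the univariate statistic", {
  w <- build_weights(queen_lattice_edges(5, 5))
  set.seed(6)
  x <- rnorm(25)
  uni <- local_moran(x, w)
  biv <- bivariate_local_moran(x, x, w, n_permutations = 0)
  expect_equal(biv$local_i, uni$local_i, tolerance = 1e-12)
  expect_equal(biv$quadrant, uni$quadrant)

  # planted positive cross-correlation: y is the smoothed x
  x2 <- rep(1:5, each = 5) + rnorm(25, 0, 0.1)
  y2 <- drop(w$W_star %*% x2)
  bp <- bivariate_local_moran(x2, y2, w, n_permutations = 0)
  expect_gt(mean(bp$local_i), 0)
  # independent fields: mean statistic near zero across replicates
  set.seed(7)
  ms <- replicate(40, {
    mean(bivariate_local_moran(rnorm(25), rnorm(25), w,
                               n_permutations = 0)$local_i)
  })
  expect_lt(abs(mean(ms)), 0.05)
})
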