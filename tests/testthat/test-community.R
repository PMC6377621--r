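test_that("bray_curtis matches hand values and the incidence identity", {
  m <- rbind(a = c(1, 1, 0), b = c(0, 1, 1))
  d <- bray_curtis(m)
  expect_equal(d["a", "b"], 0.5)                 # 2/4
  expect_equal(diag(d), c(a = 0, b = 0))

  expect_equal(bray_curtis(rbind(c(2, 3), c(2, 3)))[1, 2], 0)   # identical
  expect_equal(bray_curtis(rbind(c(1, 0), c(0, 1)))[1, 2], 1)   # disjoint

  ## incidence special case: 1 - 2a / (2a + b + c); checked against vegan
  set.seed(21)
  for (rep in 1:20) {
    m <- matrix(rbinom(20, 1, 0.6), 2, 10)
    if (any(rowSums(m) == 0)) next
    a <- sum(m[1, ] & m[2, ])
    b <- sum(m[1, ] & !m[2, ]); cc <- sum(!m[1, ] & m[2, ])
    expect_equal(bray_curtis(m)[1, 2], 1 - 2 * a / (2 * a + b + cc))
  }
  big <- matrix(rexp(60), 6, 10)
  expect_equal(unname(bray_curtis(big)[lower.tri(diag(6))]),
               as.numeric(vegan::vegdist(big, "bray")), tolerance = 1e-12)

  expect_error(bray_curtis(rbind(s1 = c(0, 0), s2 = c(1, 0))), "s1")
})

test_that("nmds recovers embeddable configurations", {
  ## three equidistant sites embed exactly
  d3 <- matrix(0.7, 3, 3); diag(d3) <- 0
  o <- nmds(d3, n_starts = 5, seed = 1)
  expect_lt(o$stress, 1e-4)

  ## points on a plane with Euclidean distances: near-zero stress
  set.seed(22)
  xy <- matrix(runif(40), 20, 2)
  o <- nmds(as.matrix(dist(xy)), n_starts = 10, seed = 2)
  expect_lt(o$stress, 0.05)
  ## scores centred at the origin
  expect_lt(max(abs(colMeans(o$scores))), 1e-8)
})

test_that("nestedness temperature is 0 for perfect nesting and matches the
           reference implementation", {
  ## staircase matrices are perfectly nested
  tri <- rbind(c(1, 1, 1), c(1, 1, 0), c(1, 0, 0))
  expect_equal(nestedness_temperature(tri)$temperature, 0)
  m <- generate_community_matrix(c(3, 2, 1), 3, 1, seed = 1)
  expect_equal(unname(m), unname(tri))
  expect_equal(nestedness_temperature(m)$temperature, 0)

  ## row/column permutation invariance (packing canonicalises order)
  set.seed(23)
  x <- matrix(rbinom(48, 1, 0.5), 6, 8)
  t1 <- nestedness_temperature(x)$temperature
  t2 <- nestedness_temperature(x[sample(6), sample(8)])$temperature
  expect_equal(t1, t2, tolerance = 1e-9)

  ## cross-implementation check against the reference estimator under a
  ## shared tie-breaking RNG state
  for (i in 1:40) {
    set.seed(400 + i)
    repeat {
      m <- matrix(rbinom(35, 1, runif(1, 0.3, 0.7)), 5, 7)
      if (all(rowSums(m) > 0) && all(colSums(m) > 0)) break
    }
    set.seed(i); ref <- unname(vegan::nestedtemp(m)$statistic)
    set.seed(i); got <- nestedness_temperature(m, ties = "random")$temperature
    expect_lt(abs(got - ref), 0.5)
  }

  expect_warning(nestedness_temperature(matrix(1, 3, 3)), "degenerate")
})

test_that("permutation p-values behave at the boundaries", {
  set.seed(24)
  nested <- generate_community_matrix(10:1, 10, 1, seed = 2)
  r <- nestedness_test(nested, n_perm = 99, seed = 3)
  expect_equal(r$temperature, 0)
  expect_equal(r$p_value, 1 / 100)     # minimum attainable p
  expect_true(all(r$null_temperatures >= 0))

  ## granularity with 99 permutations
  expect_true(r$p_value %in% ((1:100) / 100))
  expect_error(nestedness_test(nested, n_perm = 50), "99")
  expect_error(nestedness_test(nested, null_model = "bogus"))
})

test_that("curveball null preserves row and column sums", {
  set.seed(25)
  x <- matrix(rbinom(80, 1, 0.4), 8, 10)
  nl <- polarscape:::null_matrix(x, "curveball")
  expect_equal(rowSums(nl), rowSums(x))
  expect_equal(colSums(nl), colSums(x))
})

test_that("richness-axis correlation has the documented conventions", {
  set.seed(26)
  scores <- cbind(rnorm(60), rnorm(60))
  ord <- list(scores = scores)
  ## richness equal to axis-1 scores: |r| = 1, reported negative by the
  ## sign convention
  r <- richness_axis_correlation(scores[, 1], ord, n_perm = 199, seed = 1)
  expect_equal(r$r[1], -1, tolerance = 1e-12)
  expect_lt(r$p_value[1], 0.02)

  ## independent richness: small r, non-significant usually
  r2 <- richness_axis_correlation(rnorm(60), ord, n_perm = 199, seed = 2)
  expect_true(all(abs(r2$r) < 0.5))
  expect_error(richness_axis_correlation(rep(1, 60), ord), "variance")

  ## nested communities force a strong richness gradient on axis 1
  rich <- rep(1:12, each = 4)
  comm <- generate_community_matrix(rich, 15, 0.95, seed = 5)
  ord2 <- nmds(bray_curtis(comm), n_starts = 5, seed = 6)
  r3 <- richness_axis_correlation(rich, ord2, n_perm = 199, seed = 7)
  expect_gt(abs(r3$r[1]), 0.9)
  expect_lte(r3$r[1], 0)               # axis oriented against richness
})
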