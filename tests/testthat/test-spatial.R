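test_that("pcnm basis has sinusoidal structure on a regular transect", {
  x <- cbind(seq(0, 1900, by = 100), 0)
  b <- pcnm_basis(x)
  L <- 1900
  pos <- x[, 1]
  for (k in 1:3) {
    target <- cos(k * pi * pos / L)
    ## leading vectors are sinusoid-like (near-degenerate eigenvalues mix
    ## adjacent frequencies slightly; the reference implementation returns
    ## the same vectors) with the right number of sign changes
    expect_gt(abs(cor(b$vectors[, k], target)), 0.85)
    expect_equal(sum(diff(sign(b$vectors[, k])) != 0), k)
  }
  ## identical to the reference implementation on the transect
  ref <- vegan::pcnm(dist(x))
  for (k in 1:3)
    expect_equal(abs(cor(b$vectors[, k], ref$vectors[, k])), 1,
                 tolerance = 1e-9)
  ## orthogonality and centring
  g <- crossprod(b$vectors)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
  expect_lt(max(abs(colMeans(b$vectors))), 1e-10)
})

test_that("pcnm matches the dense eigendecomposition oracle up to sign", {
  set.seed(31)
  xy <- matrix(runif(60, 0, 500), 30, 2)
  b <- pcnm_basis(xy)
  ## independent oracle: truncate, Gower-centre, eigen-decompose from
  ## scratch (vegan's implementation)
  ref <- vegan::pcnm(dist(xy))
  nref <- sum(ref$values > 1e-9 * max(ref$values))
  expect_equal(ncol(b$vectors), nref)
  expect_equal(b$values, ref$values[seq_len(nref)], tolerance = 1e-8)
  expect_equal(b$truncation, ref$threshold, tolerance = 1e-10)
  sc <- sweep(ref$vectors[, seq_len(nref)], 2,
              sqrt(ref$values[seq_len(nref)]), `*`)
  for (k in seq_len(nref))
    expect_equal(abs(cor(b$vectors[, k], sc[, k])), 1, tolerance = 1e-7)

  ## translation/rotation invariance of the eigenvalues (truncation fixed
  ## with a margin so rotation round-off cannot flip threshold-boundary
  ## pairs)
  t0 <- b$truncation * 1.05
  b1 <- pcnm_basis(xy, truncation = t0)
  th <- 0.7
  rot <- xy %*% matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2) + 100
  b2 <- pcnm_basis(rot, truncation = t0)
  expect_equal(b2$values, b1$values, tolerance = 1e-8)

  expect_error(pcnm_basis(matrix(1, 5, 2)), "distinct")
})

test_that("residualization is an exact projection", {
  set.seed(32)
  xy <- matrix(runif(80, 0, 1000), 40, 2)
  b <- pcnm_basis(xy)
  env <- cbind(rnorm(40), rnorm(40), rnorm(40))
  rb <- residualize(b, env)
  ## residuals orthogonal to the environment (and intercept)
  expect_lt(max(abs(crossprod(cbind(1, env), rb$vectors))), 1e-9)
  ## env containing a PCNM column: that column residualises to ~0
  rb2 <- residualize(b, cbind(env, b$vectors[, 1]))
  expect_lt(max(abs(rb2$vectors[, 1])), 1e-9)
  ## collinear env columns dropped with a warning
  expect_warning(residualize(b, cbind(env, env[, 1])), "collinear")
})

test_that("spatial components summarise a shared field", {
  set.seed(33)
  dem <- generate_dem(20, 20, 100, 600, 0.5, seed = 33)
  tab <- generate_sample_table(dem, 150, default_truth(), seed = 33)
  b <- pcnm_basis(tab[c("x", "y")])
  env <- as.matrix(tab[c("elevation", "slope", "aspect", "dist_coast",
                         "wetness", "temperature")])
  rb <- residualize(b, env)
  ## one shared spatial field + independent noise: s1 dominates
  shared <- tab$s1
  rich <- cbind(shared + rnorm(150, sd = 0.4),
                shared + rnorm(150, sd = 0.4),
                shared + rnorm(150, sd = 0.4))
  sc <- spatial_components(rb, rich)
  expect_gt(sc$variance_explained[1], 0.8)
  expect_lt(abs(sum(sc$s1 * sc$s2)), 1e-6)            # s1 orthogonal to s2
  expect_equal(sum(sc$variance_explained), 1, tolerance = 1e-9)

  ## richness with no spatial component: PCA normalisation still holds
  rich0 <- matrix(rnorm(450), 150, 3)
  sc0 <- spatial_components(rb, rich0)
  expect_equal(sum(sc0$variance_explained), 1, tolerance = 1e-9)
})

test_that("moran_forward selection returns a subset of the basis", {
  set.seed(34)
  xy <- matrix(runif(60, 0, 800), 30, 2)
  b <- pcnm_basis(xy)
  resp <- b$vectors[, 1] * 2 + rnorm(30, sd = 0.3)
  sel <- select_pcnm(b, xy, response = matrix(resp), method = "moran_forward",
                     n_perm = 99, seed = 1)
  expect_lte(ncol(sel$vectors), ncol(b$vectors))
  expect_gte(ncol(sel$vectors), 1)
  ## "all" is the identity
  expect_identical(select_pcnm(b, xy), b)
})

test_that("s1 association with richness grows with spatial_sd", {
  dem <- generate_dem(20, 20, 100, 600, 0.5, seed = 35)
  partials <- sapply(c(0.5, 2), function(ssd) {
    tab <- generate_sample_table(dem, 160, default_truth(spatial_sd = ssd),
                                 seed = 35)
    b <- residualize(pcnm_basis(tab[c("x", "y")]),
                     as.matrix(tab[c("elevation", "slope", "aspect",
                                     "dist_coast", "wetness",
                                     "temperature", "ph", "water",
                                     "nitrogen")]))
    sc <- spatial_components(b, as.matrix(tab[c("cyano_s", "fungal_s",
                                                "multi_s")]))
    ## partial correlation of s1 with cyano richness given abiotic columns
    ab <- as.matrix(tab[c("elevation", "slope", "aspect", "dist_coast",
                          "wetness", "temperature")])
    ry <- lm.fit(cbind(1, ab), tab$cyano_s)$residuals
    rs <- lm.fit(cbind(1, ab), sc$s1)$residuals
    abs(cor(ry, rs))
  })
  expect_gt(partials[2], partials[1])
})
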