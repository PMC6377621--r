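test_that("generate_dem satisfies its contract", {
  dem <- generate_dem(32, 32, 100, 800, 0.8, seed = 1)
  ## coast edge (southern row) contains at least one zero cell
  expect_true(any(dem$elev[32, ] == 0))
  expect_true(all(dem$elev >= 0))
  ## determinism
  dem2 <- generate_dem(32, 32, 100, 800, 0.8, seed = 7)
  dem3 <- generate_dem(32, 32, 100, 800, 0.8, seed = 7)
  expect_identical(dem2$elev, dem3$elev)
  expect_false(identical(dem$elev, dem2$elev))
  ## semivariogram rises with lag for a smooth surface
  demr <- generate_dem(64, 64, 50, 1500, 0.2, seed = 3)
  sv <- semivariogram(demr$elev, c(1, 2, 4, 8))
  expect_true(all(diff(sv) > 0))
  expect_error(generate_dem(4, 4, 100, 800), "8 x 8")
  expect_error(generate_dem(16, 16, 100, -5), "positive")
})

test_that("sample tables honour the ground truth", {
  dem <- generate_dem(24, 24, 100, 800, 0.5, seed = 2)
  truth <- default_truth()
  tab <- generate_sample_table(dem, 300, truth, seed = 2)
  expect_equal(nrow(tab), 300)
  ## sites inside the DEM extent
  expect_true(all(tab$x > 0 & tab$x < 2400 & tab$y > 0 & tab$y < 2400))
  ## multicellular richness in 0..9
  expect_true(all(tab$multi_richness >= 0 & tab$multi_richness <= 9))
  ## ATP independent of everything (inside the 95% sampling band at n=300)
  others <- c("elevation", "cyano_richness", "fungal_richness", "ph",
              "water", "nitrogen", "temperature")
  rs <- sapply(others, function(v) abs(cor(tab$atp, tab[[v]])))
  expect_true(mean(rs < 1.96 / sqrt(300)) >= 6 / 7)
  ## discretization is rank-preserving
  expect_true(all(diff(tab$cyano_richness[order(tab$cyano_s)]) >= 0))
  ## rejected inputs
  expect_error(generate_sample_table(dem, 1e6), "exceeds")
  bad <- data.frame(effect = c("a", "b"), cause = c("b", "a"),
                    coef = c(0.5, 0.5))
  expect_error(ground_truth(bad, c(a = 1, b = 1)), "cycle")
})

test_that("generated covariance converges to the truth-implied covariance", {
  dem <- generate_dem(24, 24, 100, 800, 0.5, seed = 5)
  truth <- default_truth()
  vars <- c("elevation", "slope", "aspect", "dist_coast", "wetness",
            "temperature", "s1", "s2", "ph", "nitrogen", "water",
            "cyano_s", "fungal_s", "multi_s")
  nrep <- 40
  acc <- 0
  exo_emp <- 0
  for (r in seq_len(nrep)) {
    tab <- generate_sample_table(dem, 500, truth, seed = 600 + r)
    zt <- scale(as.matrix(tab[vars]))
    acc <- acc + cov(zt) / nrep
    exo_emp <- exo_emp + cov(zt[, 1:8]) / nrep
  }
  ## truth-implied covariance via the independent path-tracing construction
  ## (I - B)^-1 S0 (I - B)^-T with the empirical exogenous block
  dimnames(exo_emp) <- list(vars[1:8], vars[1:8])
  imp <- truth_implied_cov(truth, exo_cov = exo_emp)
  imp <- imp[vars, vars]
  ## endogenous variables are z-scored in the table; rescale implied to
  ## correlation-like units for comparison
  dsc <- sqrt(diag(imp))
  imp_std <- imp / outer(dsc, dsc)
  acc_d <- sqrt(diag(acc))
  acc_std <- acc / outer(acc_d, acc_d)
  expect_lt(max(abs(imp_std - acc_std)), 4 / sqrt(nrep * 500))
})

test_that("community matrices conserve richness and order by nestedness", {
  rich <- c(3, 2, 1)
  m <- generate_community_matrix(rich, 3, 1, seed = 1)
  expect_equal(unname(rowSums(m)), rich)
  expect_equal(nestedness_temperature(m)$temperature, 0)

  set.seed(6)
  rich <- sample(1:15, 30, replace = TRUE)
  for (s in c(0, 0.5, 1)) {
    m <- generate_community_matrix(rich, 20, s, seed = s * 10 + 1)
    expect_equal(unname(rowSums(m)), rich)
  }
  expect_error(generate_community_matrix(c(5, 30), 20, 1), "pool")

  ## monotonicity: strength 1 is colder than strength 0 in >= 95% of seeds
  wins <- 0
  for (s in 1:60) {
    rich <- sample(1:15, 25, replace = TRUE)
    t1 <- nestedness_temperature(
      generate_community_matrix(rich, 20, 1, seed = s))$temperature
    t0 <- nestedness_temperature(
      generate_community_matrix(rich, 20, 0, seed = s))$temperature
    if (t1 < t0) wins <- wins + 1
  }
  expect_gte(wins, 57)
})

test_that("electropherograms round-trip through the peak caller", {
  ## zero richness: all peaks designed to fail
  e0 <- generate_electropherogram(0, c(100, 1200), seed = 1,
                                  noise_peaks = 10)
  expect_equal(nrow(call_true_peaks(e0, "cyanobacteria")), 0)

  ## richness 25 in the cyanobacterial window
  e25 <- generate_electropherogram(25, c(100, 1200), seed = 2)
  expect_equal(arisa_richness(call_true_peaks(e25, "cyanobacteria")), 25)

  ## determinism
  ea <- generate_electropherogram(12, c(100, 1400), seed = 5)
  eb <- generate_electropherogram(12, c(100, 1400), seed = 5)
  expect_identical(ea$peaks, eb$peaks)

  expect_error(generate_electropherogram(300, c(100, 140)), "narrow")
  expect_error(generate_electropherogram(-1, c(100, 1200)), ">= 0")
})

test_that("bundles are internally consistent", {
  b <- generate_bundle(n_sites = 40, nrows = 16, ncols = 16, seed = 9)
  ## richness columns equal community row sums
  expect_equal(unname(rowSums(b$communities$cyanobacteria)),
               b$samples$cyano_richness)
  expect_equal(unname(rowSums(b$communities$multicellular)),
               b$samples$multi_richness)
  expect_true(all(b$samples$multi_richness <= 9))
  ## ARISA round-trip on the bundle, exactly
  called <- vapply(b$electropherograms$cyanobacteria, function(e)
    arisa_richness(call_true_peaks(e, "cyanobacteria")), 0L)
  expect_equal(unname(called), b$samples$cyano_richness)
  called_f <- vapply(b$electropherograms$fungi, function(e)
    arisa_richness(call_true_peaks(e, "fungi")), 0L)
  expect_equal(unname(called_f), b$samples$fungal_richness)
})
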