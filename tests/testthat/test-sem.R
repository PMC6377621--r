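test_that("parse_model handles paths, composites, covariances and errors", {
  m <- parse_model("y <- x")
  expect_equal(nrow(m$paths), 1)
  expect_equal(m$endogenous, "y")
  ## p = 2 moments 3: path + disturbance + exo variance = 3 free, df 0
  expect_equal(model_df(m)$df, 0)

  expect_error(parse_model("y <- x; x <- y"), "cycle")
  expect_error(parse_model("y <- x\ny <- x"), "duplicate")
  expect_error(parse_model("what is this"), "parse")

  m2 <- parse_model("y <- x1 + 0.5*x2\ncomposite C <= x1 + x2\nz <- C")
  expect_equal(names(m2$composites), "C")
  expect_equal(m2$composites$C$fixed, c(1, NA))   # first weight auto-fixed
  expect_equal(sum(is.finite(m2$paths$fixed)), 1)

  ## the built-in final model matches the published degrees of freedom
  mf <- parse_model("final_2019")
  expect_equal(model_df(mf)$df, 35)
  expect_equal(length(mf$observed), 14)
})

test_that("single-path model has the closed-form OLS/correlation solution", {
  set.seed(41)
  x <- rnorm(200)
  y <- 0.6 * x + rnorm(200, sd = 0.8)
  d <- data.frame(x = x, y = y)
  fit <- fit_ml("y <- x", d)
  expect_equal(fit$estimates$estimate[fit$estimates$label == "y<-x"],
               unname(coef(lm(y ~ x, d))[2]), tolerance = 1e-6)
  expect_equal(fit$standardized$std[1], cor(x, y), tolerance = 1e-6)
  expect_lt(fit$chi2, 1e-8)            # saturated: df 0, perfect fit
})

test_that("saturated models reach F_ML = 0 and analytic gradients are exact", {
  set.seed(42)
  case <- random_recursive_case(7, n = 150)
  model <- path_model(case$paths)
  fit <- fit_ml(model, case$data)
  ## finite-difference check of the analytic gradient at a generic point
  skel <- fit$skeleton
  S <- cov(case$data[, model$observed])
  S <- S / outer(sqrt(diag(S)), sqrt(diag(S)))
  logdet <- determinant(S)$modulus
  th <- fit$theta * 0 + seq(0.1, 0.3, length.out = length(fit$theta))
  g <- polarscape:::fml_gradient(skel, th, S)
  fd <- sapply(seq_along(th), function(k) {
    h <- 1e-6
    tp <- th; tp[k] <- tp[k] + h
    tm <- th; tm[k] <- tm[k] - h
    (polarscape:::fml_value(skel, tp, S, logdet) -
       polarscape:::fml_value(skel, tm, S, logdet)) / (2 * h)
  })
  expect_equal(g, fd, tolerance = 1e-5)
})

test_that("chi-square equals the closed-form oracle from cold starts", {
  for (s in 1:8) {
    case <- random_recursive_case(100 + s, n = 250)
    fit <- fit_ml(path_model(case$paths), case$data, start = "null",
                  se = FALSE)
    ref <- oracle_sem_chi2(case$paths, case$data)
    expect_lt(abs(fit$chi2 - ref$chi2), 0.01)
  }
})

test_that("fit indices follow their definitions", {
  set.seed(43)
  case <- random_recursive_case(17, n = 400)
  fit <- fit_ml(path_model(case$paths), case$data, se = FALSE)
  fi <- fit_indices(fit)
  expect_equal(fi$df, model_df(fit$model)$df)
  expect_equal(fi$p_value, pchisq(fi$chi2, fi$df, lower.tail = FALSE))
  if (fi$chi2 <= fi$df) expect_equal(fi$cfi, 1)
  expect_gte(fi$cfi, 0); expect_lte(fi$cfi, 1)
  expect_gt(fi$baseline_chi2, fi$chi2)
})

test_that("standardization: pre-standardized data leaves estimates alone", {
  set.seed(44)
  x <- scale(rnorm(300)); m <- 0.5 * x + rnorm(300, sd = 0.6)
  y <- 0.4 * m + rnorm(300, sd = 0.7)
  d <- data.frame(x = as.numeric(scale(x)), m = as.numeric(scale(m)),
                  y = as.numeric(scale(y)))
  fit <- fit_ml("m <- x; y <- m", d, se = FALSE)
  std <- fit$standardized
  ## estimates on unit-variance data differ from standardized only through
  ## the implied (vs sample) SD ratio, which converges; check closeness
  expect_equal(std$std, std$estimate, tolerance = 0.02)
})

test_that("total effects match brute-force path enumeration", {
  ## hand-checkable chain with a direct shortcut
  set.seed(45)
  x <- rnorm(400)
  m <- 0.5 * x + rnorm(400, 0.7)
  y <- 0.3 * m + 0.2 * x + rnorm(400, 0.6)
  fit <- fit_ml("m <- x\ny <- m + x", data.frame(x = x, m = m, y = y),
                se = FALSE)
  te <- total_effects(fit)
  B <- te$direct
  a <- B["m", "x"]; b <- B["y", "m"]; cc <- B["y", "x"]
  expect_equal(te$total["y", "x"], cc + a * b, tolerance = 1e-10)
  expect_equal(diag(te$total), setNames(rep(0, 3), rownames(B)))

  ## random DAGs vs the enumeration oracle
  for (s in 1:25) {
    case <- random_recursive_case(200 + s, n = 120)
    fit <- fit_ml(path_model(case$paths), case$data, se = FALSE)
    te <- total_effects(fit)
    B <- te$direct
    for (src in colnames(B)) for (out in rownames(B)) {
      if (src == out) next
      ref <- oracle_total_effect(B, src, out)
      expect_equal(te$total[out, src], ref, tolerance = 1e-10)
    }
    ## conservation: total = direct + indirect identically
    expect_equal(te$total, te$direct + te$indirect, tolerance = 1e-12)
  }
})

test_that("net effects collapse constructs correctly", {
  dem <- generate_dem(20, 20, 100, 700, 0.5, seed = 46)
  tab <- generate_sample_table(dem, 300, seed = 46)
  fit <- fit_ml("final_2019", tab, se = FALSE)
  ne <- net_effects(fit)
  expect_equal(dim(ne), c(3, 3))
  ## no biotic paths into cyanobacterial richness: structurally zero
  expect_equal(ne["cyano_s", "biotic"], 0)
  expect_true(all(ne >= 0 & ne <= 1))
  ## single-cause construct equals that cause's |standardized path|
  std <- fit$standardized
  w <- std$std[std$effect == "fungal_s" & std$cause == "cyano_s"]
  expect_equal(ne["fungal_s", "biotic"], abs(w), tolerance = 1e-10)
  expect_error(net_effects(fit, groups = list(), outcomes = "nope"))
})

test_that("residual covariance flags a missing strong path", {
  ## truth: m <- x (0.8); y <- 0.2 x + 0.7 m. Fit a model that omits the
  ## strong m -> y path: the (y, m) pair should carry the largest
  ## standardized residual in >= 90% of replicates.
  hits <- 0
  nrep <- 50
  for (s in seq_len(nrep)) {
    set.seed(1300 + s)
    n <- 500
    x <- rnorm(n)
    m <- 0.8 * x + rnorm(n, sd = 0.6)
    y <- 0.2 * x + 0.7 * m + rnorm(n, sd = 0.6)
    d <- data.frame(x = x, m = m, y = y)
    fit2 <- fit_ml("m <- x\ny <- x", d, se = FALSE)
    rc <- residual_covariance(fit2)
    expect_equal(rc$raw, t(rc$raw), tolerance = 1e-9)
    top_pair <- sort(c(rc$largest$v1[1], rc$largest$v2[1]))
    if (identical(top_pair, c("m", "y"))) hits <- hits + 1
  }
  expect_gte(hits, 0.9 * nrep)

  ## saturated model: residuals vanish
  set.seed(47)
  d <- data.frame(x = rnorm(100))
  d$y <- 0.5 * d$x + rnorm(100)
  fit <- fit_ml("y <- x", d, se = FALSE)
  expect_lt(max(abs(residual_covariance(fit)$raw)), 1e-6)
})

test_that("prediction reproduces the reduced form", {
  dem <- generate_dem(20, 20, 100, 700, 0.5, seed = 48)
  tab <- generate_sample_table(dem, 250, seed = 48)
  fit <- fit_ml("final_2019", tab, se = FALSE)
  pred <- predict_richness(fit, tab)
  ## in-sample: cyano richness has only exogenous parents, so its squared
  ## correlation with the observed values equals the structural R2
  psi <- fit$estimates$estimate[fit$estimates$label == "psi(cyano_s)"]
  v <- diag(fit$C)[match("cyano_s", fit$skeleton$nodes)]
  r2_model <- 1 - psi / v
  expect_equal(cor(pred$cyano_s, tab$cyano_s)^2, unname(r2_model),
               tolerance = 0.02)

  ## noise-free limit: per-equation OLS recovers the generator exactly
  truth0 <- default_truth()
  truth0$disturbance_sds[] <- 0
  tab0 <- generate_sample_table(dem, 250, truth0, seed = 48)
  co <- coef(lm(cyano_s ~ scale(elevation) + scale(dist_coast) +
                  scale(wetness) + scale(aspect) + scale(slope) + s1 + s2,
                tab0))
  expect_equal(unname(co[-1]), c(0.30, 0.25, 0.30, -0.20, -0.20,
                                 0.30, 0.25), tolerance = 1e-9)

  expect_error(predict_richness(fit, tab["elevation"]), "lacks")

  ## predictive (remote-sensing-only) variant runs on terrain alone
  fit_p <- fit_ml("predictive", tab, se = FALSE)
  grid_tab <- tab[c("elevation", "slope", "aspect", "dist_coast",
                    "wetness", "temperature")]
  pred_p <- predict_richness(fit_p, grid_tab)
  expect_equal(names(pred_p), c("cyano_s", "fungal_s", "multi_s"))
  expect_gt(cor(pred_p$cyano_s, tab$cyano_s), 0.3)
})
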