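## Independent oracles used across the suite. These deliberately take
## different computational routes from the package code they check.

## ---- SEM oracle -----------------------------------------------------------
## For a recursive path model with a saturated exogenous block and diagonal
## disturbances, the ML solution has a closed form: equation-wise OLS
## computed from the sample covariance, exogenous moments taken directly
## from S. Returns the minimised F_ML and chi-square. No numerical
## optimisation anywhere.
oracle_sem_chi2 <- function(paths, data) {
  vars <- unique(c(paths$effect, paths$cause))
  S <- cov(data[, vars, drop = FALSE])
  n <- nrow(data)
  endo <- unique(paths$effect)
  exo <- setdiff(vars, endo)
  p <- length(vars)
  ## implied covariance assembled by the reduced form Sigma = B S0 B'
  A <- matrix(0, p, p, dimnames = list(vars, vars))
  S0 <- matrix(0, p, p, dimnames = list(vars, vars))
  S0[exo, exo] <- S[exo, exo]
  for (y in endo) {
    pa <- paths$cause[paths$effect == y]
    beta <- solve(S[pa, pa, drop = FALSE], S[pa, y])
    A[y, pa] <- beta
    S0[y, y] <- S[y, y] - sum(beta * S[pa, y])
  }
  B <- solve(diag(p) - A)
  sigma <- B %*% S0 %*% t(B)
  f <- determinant(sigma)$modulus + sum(diag(solve(sigma, S))) -
    determinant(S)$modulus - p
  list(F = as.numeric(f), chi2 = as.numeric((n - 1) * f), sigma = sigma)
}

## Random recursive model + simulated data for the oracle-equivalence
## sweeps: 3-8 variables, random DAG over a random topological order,
## correlated exogenous block.
random_recursive_case <- function(seed, n = 300) {
  set.seed(seed)
  p <- sample(3:8, 1)
  vars <- paste0("v", seq_len(p))
  edges <- NULL
  for (j in 2:p) for (i in 1:(j - 1))
    if (runif(1) < 0.45)
      edges <- rbind(edges, data.frame(effect = vars[j], cause = vars[i]))
  if (is.null(edges))
    edges <- data.frame(effect = vars[2], cause = vars[1])
  endo <- unique(edges$effect)
  exo <- setdiff(vars, endo)
  ## simulate: correlated exogenous, linear equations + normal noise
  q <- length(exo)
  R <- crossprod(matrix(rnorm(q * q), q)) / q + diag(q) * 0.5
  X <- matrix(rnorm(n * q), n, q) %*% chol(R)
  colnames(X) <- exo
  dat <- as.data.frame(X)
  for (y in vars[vars %in% endo]) {     # vars order is topological
    pa <- edges$cause[edges$effect == y]
    b <- runif(length(pa), 0.2, 0.6) * sample(c(-1, 1), length(pa), TRUE)
    dat[[y]] <- as.matrix(dat[pa]) %*% b + rnorm(n, sd = runif(1, 0.6, 1.2))
  }
  list(paths = edges, data = dat[vars])
}

## ---- total-effects oracle -------------------------------------------------
## Brute-force enumeration of every directed path source -> outcome with
## product-summing, on a coefficient matrix B (effect x cause).
oracle_total_effect <- function(B, source, outcome) {
  if (is.character(source)) source <- match(source, colnames(B))
  if (is.character(outcome)) outcome <- match(outcome, rownames(B))
  children_of <- function(v) which(B[, v] != 0)
  total <- 0
  walk <- function(v, prod) {
    for (w in children_of(v)) {
      contrib <- prod * B[w, v]
      if (w == outcome) total <<- total + contrib
      walk(w, contrib)
    }
  }
  walk(source, 1)
  total
}

## ---- ARISA oracle ---------------------------------------------------------
## Applies the three acceptance predicates independently, peak by peak.
oracle_true_peaks <- function(size, rfu, window, floor = 30, rel = 0.003) {
  in_window <- size >= window[1] & size <= window[2]
  over_floor <- rfu > floor
  denom <- sum(rfu[over_floor])
  rel_ok <- if (denom > 0) rfu / denom > rel else rep(FALSE, length(rfu))
  which(in_window & over_floor & rel_ok)
}

## ---- geometry helpers -----------------------------------------------------
## Empirical semivariogram of a grid along rows/columns at integer lags.
semivariogram <- function(z, lags) {
  vapply(lags, function(h) {
    dx <- (z[, seq_len(ncol(z) - h)] - z[, seq_len(ncol(z) - h) + h])^2
    dy <- (z[seq_len(nrow(z) - h), ] - z[seq_len(nrow(z) - h) + h, ])^2
    mean(c(dx, dy)) / 2
  }, numeric(1))
}

## A tilted plane DEM: z = g * (dx * x_east + dy * y_north), on cell centres.
plane_dem <- function(n = 12, cellsize = 10, gx = 0, gy = 0, z0 = 100) {
  ## row 1 = north; y decreases with row index
  x <- (seq_len(n) - 0.5) * cellsize
  y <- rev(seq_len(n) - 0.5) * cellsize
  z <- z0 + outer(y, x, function(yy, xx) gx * xx + gy * yy)
  dem_grid(z, cellsize)
}
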