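## Maximum-likelihood estimation of recursive path models on the sample
## covariance matrix, via the RAM parameterisation
## Sigma = F (I - A)^-1 S0 (I - A)^-T F^T.

## Build parameter bookkeeping for a model: node order, fixed pattern of the
## A (paths/weights) and S0 (variances/covariances) matrices, and the index
## table of free parameters.
ram_skeleton <- function(model) {
  nodes <- c(model$observed, names(model$composites))
  m <- length(nodes)
  idx <- function(v) match(v, nodes)
  A <- matrix(0, m, m, dimnames = list(nodes, nodes))
  free <- NULL
  add_free <- function(type, i, j, label)
    rbind(free, data.frame(type = type, i = i, j = j, label = label))
  for (k in seq_len(nrow(model$paths))) {
    i <- idx(model$paths$effect[k]); j <- idx(model$paths$cause[k])
    if (is.finite(model$paths$fixed[k])) A[i, j] <- model$paths$fixed[k]
    else free <- add_free("A", i, j,
                          sprintf("%s<-%s", nodes[i], nodes[j]))
  }
  for (nm in names(model$composites)) {
    cdf <- model$composites[[nm]]
    i <- idx(nm)
    for (k in seq_len(nrow(cdf))) {
      j <- idx(cdf$cause[k])
      if (is.finite(cdf$fixed[k])) A[i, j] <- cdf$fixed[k]
      else free <- add_free("A", i, j,
                            sprintf("%s<=%s", nm, nodes[j]))
    }
  }
  exo <- idx(model$exogenous)
  if (length(exo)) {
    for (a in seq_along(exo)) for (b in seq_len(a)) {
      lbl <- if (a == b) sprintf("var(%s)", nodes[exo[a]])
             else sprintf("cov(%s,%s)", nodes[exo[a]], nodes[exo[b]])
      free <- add_free("S", exo[a], exo[b], lbl)
    }
  }
  for (v in model$endogenous)
    free <- add_free("S", idx(v), idx(v), sprintf("psi(%s)", v))
  if (!is.null(model$covariances)) {
    for (k in seq_len(nrow(model$covariances)))
      free <- add_free("S", idx(model$covariances$v1[k]),
                       idx(model$covariances$v2[k]),
                       sprintf("cov(%s,%s)", model$covariances$v1[k],
                               model$covariances$v2[k]))
  }
  list(nodes = nodes, m = m, A0 = A, free = free,
       obs_idx = idx(model$observed))
}

ram_matrices <- function(skel, theta) {
  A <- skel$A0
  S <- matrix(0, skel$m, skel$m, dimnames = dimnames(A))
  for (k in seq_len(nrow(skel$free))) {
    i <- skel$free$i[k]; j <- skel$free$j[k]
    if (skel$free$type[k] == "A") A[i, j] <- theta[k]
    else { S[i, j] <- theta[k]; S[j, i] <- theta[k] }
  }
  list(A = A, S = S)
}

implied_cov <- function(skel, theta) {
  ms <- ram_matrices(skel, theta)
  B <- solve(diag(skel$m) - ms$A)
  C <- B %*% ms$S %*% t(B)
  list(sigma = C[skel$obs_idx, skel$obs_idx, drop = FALSE], C = C, B = B,
       A = ms$A, S = ms$S)
}

fml_value <- function(skel, theta, S_samp, logdet_S) {
  sig <- implied_cov(skel, theta)$sigma
  ev <- eigen(sig, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-12) return(1e10 + abs(min(ev)))
  sum(log(ev)) + sum(diag(solve(sig, S_samp))) - logdet_S - nrow(S_samp)
}

fml_gradient <- function(skel, theta, S_samp) {
  ic <- implied_cov(skel, theta)
  sig_inv <- solve(ic$sigma)
  W <- sig_inv - sig_inv %*% S_samp %*% sig_inv
  G <- matrix(0, skel$m, skel$m)
  G[skel$obs_idx, skel$obs_idx] <- W
  B <- ic$B
  BtGB <- t(B) %*% G %*% B
  M <- (B %*% ic$S %*% t(B)) %*% G %*% B    # C G B
  g <- numeric(nrow(skel$free))
  for (k in seq_len(nrow(skel$free))) {
    i <- skel$free$i[k]; j <- skel$free$j[k]
    g[k] <- if (skel$free$type[k] == "A") 2 * M[j, i]
            else if (i == j) BtGB[i, i]
            else 2 * BtGB[i, j]
  }
  g
}

## OLS-informed starting values: equation-wise regressions computed from the
## sample covariance, exogenous moments taken from S directly. Falls back to
## small generic values where composites make equations latent.
start_values <- function(skel, model, S_samp, kind = "ols") {
  th <- numeric(nrow(skel$free))
  nodes <- skel$nodes
  obs <- model$observed
  for (k in seq_len(nrow(skel$free))) {
    i <- skel$free$i[k]; j <- skel$free$j[k]
    if (skel$free$type[k] == "S") {
      vi <- nodes[i]; vj <- nodes[j]
      if (vi %in% obs && vj %in% obs) {
        th[k] <- if (i == j && vi %in% model$endogenous)
          0.5 * S_samp[vi, vi] else S_samp[vi, vj]
      } else th[k] <- 0.05
    } else th[k] <- 0.1
  }
  if (kind == "null") return(ifelse(skel$free$type == "A", 0, th))
  ## per-equation OLS for endogenous observed with fully observed parents
  for (eff in model$endogenous) {
    parents <- model$paths$cause[model$paths$effect == eff]
    if (!all(parents %in% obs)) next
    Sp <- S_samp[parents, parents, drop = FALSE]
    sy <- S_samp[parents, eff]
    beta <- tryCatch(solve(Sp, sy), error = function(e) NULL)
    if (is.null(beta)) next
    for (q in seq_along(parents)) {
      k <- which(skel$free$type == "A" &
                   skel$free$i == match(eff, nodes) &
                   skel$free$j == match(parents[q], nodes))
      if (length(k) == 1) th[k] <- beta[q]
    }
    kpsi <- which(skel$free$type == "S" &
                    skel$free$i == match(eff, nodes) &
                    skel$free$j == match(eff, nodes))
    resid_var <- S_samp[eff, eff] - sum(beta * sy)
    if (length(kpsi) == 1 && resid_var > 0) th[kpsi] <- resid_var
  }
  th
}

#' Fit a path model by maximum likelihood
#'
#' Minimises the ML discrepancy
#' `F(theta) = log det Sigma + tr(S Sigma^-1) - log det S - p`
#' over the free parameters with analytic gradients (BFGS, jittered
#' restarts on failure). The chi-square statistic is `(n - 1) F` at the
#' minimum; standard errors come from the inverse observed information.
#'
#' @param model a [path_model()] or built-in model name.
#' @param data data.frame/matrix containing the model's observed variables
#'   (rows = sites; listwise-complete).
#' @param columns optional named character vector mapping model variable
#'   names to data column names.
#' @param start `"ols"` (default) or `"null"` (cold start: all paths zero).
#' @param se compute standard errors (numeric Hessian), default TRUE.
#' @param maxit BFGS iteration cap.
#' @param grad_tol convergence threshold on the gradient infinity norm.
#' @return object of class `sem_fit`: estimates, implied covariance, sample
#'   covariance, `chi2`, `df`, `p_value`, standardized solution, standard
#'   errors, convergence information.
#' @export
fit_ml <- function(model, data, columns = NULL, start = "ols", se = TRUE,
                   maxit = 500, grad_tol = 1e-6) {
  if (is.character(model)) model <- parse_model(model)
  dat <- as.data.frame(data)
  cols <- model$observed
  if (!is.null(columns)) {
    cols <- unname(columns[model$observed])
    if (any(is.na(cols)))
      stop_ps("columns mapping misses: %s",
              paste(model$observed[is.na(cols)], collapse = ", "))
  }
  missing_cols <- setdiff(cols, names(dat))
  if (length(missing_cols))
    stop_ps("data lacks column(s): %s", paste(missing_cols, collapse = ", "))
  X <- as.matrix(dat[, cols, drop = FALSE])
  colnames(X) <- model$observed
  X <- X[stats::complete.cases(X), , drop = FALSE]
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop_ps("need more rows (%d) than variables (%d)", n, p)
  S_samp <- stats::cov(X)
  ev_s <- eigen(S_samp, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev_s) <= 0 || min(ev_s) / max(ev_s) < 1e-14)
    stop_ps("sample covariance is not positive definite")
  skel <- ram_skeleton(model)
  dfs <- model_df(model)
  if (dfs$df < 0)
    stop_ps("model not identified: %d parameters for %d moments",
            dfs$t, p * (p + 1) / 2)

  ## Optimize on the SD-scaled covariance (condition ~ 1) and map estimates
  ## back to raw units afterwards; F_ML and chi2 are scale-invariant.
  sd_data <- sqrt(diag(S_samp))
  node_sd <- rep(1, skel$m)
  node_sd[skel$obs_idx] <- sd_data
  S_work <- S_samp / outer(sd_data, sd_data)
  logdet_S <- sum(log(eigen(S_work, symmetric = TRUE,
                            only.values = TRUE)$values))
  ## raw = scaled * theta_scale, per free parameter
  theta_scale <- vapply(seq_len(nrow(skel$free)), function(k) {
    i <- skel$free$i[k]; j <- skel$free$j[k]
    if (skel$free$type[k] == "A") node_sd[i] / node_sd[j]
    else node_sd[i] * node_sd[j]
  }, numeric(1))

  obj <- function(th) fml_value(skel, th, S_work, logdet_S)
  grd <- function(th) {
    if (obj(th) >= 1e10) return(rep(0, length(th)))
    fml_gradient(skel, th, S_work)
  }
  th0 <- start_values(skel, model, S_work, kind = start)
  best <- NULL
  for (attempt in 0:3) {
    th_try <- if (attempt == 0) th0 else
      with_seed(1000 + attempt,
                th0 + stats::rnorm(length(th0), sd = 0.1 * (1 + abs(th0))))
    opt <- stats::optim(th_try, obj, grd, method = "BFGS",
                        control = list(maxit = maxit, reltol = 1e-14))
    gn <- max(abs(grd(opt$par)))
    cand <- list(par = opt$par, value = opt$value, grad_norm = gn)
    if (is.null(best) || cand$value < best$value) best <- cand
    if (best$grad_norm < grad_tol) break
  }
  converged <- best$grad_norm < grad_tol
  if (!converged)
    warning(sprintf("fit_ml did not fully converge: gradient norm %.3g",
                    best$grad_norm))
  theta <- best$par * theta_scale       # back to raw units
  ic <- implied_cov(skel, theta)
  fmin <- best$value
  chi2 <- (n - 1) * fmin
  est <- data.frame(label = skel$free$label, type = skel$free$type,
                    estimate = theta)
  ses <- rep(NA_real_, length(theta))
  if (se) {
    H <- numeric_hessian(grd, best$par)
    covm <- tryCatch(2 / (n - 1) * solve((H + t(H)) / 2),
                     error = function(e) NULL)
    if (!is.null(covm)) {
      dg <- diag(covm)
      ses[dg > 0] <- sqrt(dg[dg > 0])
      ses <- ses * abs(theta_scale)
    }
  }
  est$se <- ses
  fit <- structure(list(
    model = model, skeleton = skel, theta = theta, estimates = est,
    A = ic$A, S0 = ic$S, C = ic$C, sigma = ic$sigma,
    sample_cov = S_samp, n = n, means = colMeans(X),
    F_ml = fmin, chi2 = chi2, df = dfs$df,
    p_value = stats::pchisq(chi2, dfs$df, lower.tail = FALSE),
    converged = converged, grad_norm = best$grad_norm,
    data_columns = cols), class = "sem_fit")
  fit$standardized <- standardize(fit)
  fit
}

numeric_hessian <- function(grad_fn, theta, eps = 1e-5) {
  k <- length(theta)
  H <- matrix(0, k, k)
  for (q in seq_len(k)) {
    tp <- theta; tm <- theta
    h <- eps * (1 + abs(theta[q]))
    tp[q] <- tp[q] + h; tm[q] <- tm[q] - h
    H[, q] <- (grad_fn(tp) - grad_fn(tm)) / (2 * h)
  }
  H
}

#' Fit indices
#'
#' Chi-square, degrees of freedom, p-value, and the comparative fit index
#' `CFI = 1 - max(chi2_M - df_M, 0) / max(chi2_M - df_M, chi2_B - df_B, 0)`
#' against the independence baseline (all variances free, covariances
#' zero), which has a closed-form discrepancy.
#'
#' @param fit a `sem_fit`.
#' @return list `chi2`, `df`, `p_value`, `cfi`, `baseline_chi2`,
#'   `baseline_df`.
#' @export
fit_indices <- function(fit) {
  S <- fit$sample_cov
  p <- ncol(S)
  f_b <- sum(log(diag(S))) -
    sum(log(eigen(S, symmetric = TRUE, only.values = TRUE)$values))
  chi2_b <- (fit$n - 1) * f_b
  df_b <- p * (p - 1) / 2
  num <- max(fit$chi2 - fit$df, 0)
  den <- max(fit$chi2 - fit$df, chi2_b - df_b, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  if (cfi < 0 || cfi > 1) {
    warning("CFI outside [0, 1]; clamped")
    cfi <- min(max(cfi, 0), 1)
  }
  list(chi2 = fit$chi2, df = fit$df, p_value = fit$p_value, cfi = cfi,
       baseline_chi2 = chi2_b, baseline_df = df_b)
}

#' Standardized solution
#'
#' Path coefficients rescaled by SD(cause)/SD(effect) under the implied
#' covariance (composites included via their implied variances).
#'
#' @param fit a `sem_fit`.
#' @return data.frame of standardized paths/weights with columns `label`,
#'   `effect`, `cause`, `estimate`, `std`.
#' @export
standardize <- function(fit) {
  skel <- fit$skeleton
  sds <- sqrt(pmax(diag(fit$C), 0))
  if (any(sds == 0 & rowSums(abs(fit$A)) > 0))
    stop_ps("zero implied variance; cannot standardize")
  rows <- which(skel$free$type == "A")
  out <- lapply(rows, function(k) {
    i <- skel$free$i[k]; j <- skel$free$j[k]
    data.frame(label = skel$free$label[k],
               effect = skel$nodes[i], cause = skel$nodes[j],
               estimate = fit$theta[k],
               std = fit$theta[k] * sds[j] / sds[i])
  })
  do.call(rbind, out)
}

#' Residual covariance matrix
#'
#' `S - Sigma(theta_hat)`, plus a standardized version (residuals divided by
#' the product of implied SDs) and the largest-magnitude entries, the usual
#' starting point for respecification.
#'
#' @param fit a `sem_fit`.
#' @param top number of largest standardized residuals to list.
#' @return list `raw`, `standardized`, `largest`.
#' @export
residual_covariance <- function(fit, top = 10) {
  res <- fit$sample_cov - fit$sigma
  sds <- sqrt(diag(fit$sigma))
  stdres <- res / outer(sds, sds)
  ut <- which(upper.tri(stdres, diag = TRUE), arr.ind = TRUE)
  ord <- order(abs(stdres[ut]), decreasing = TRUE)
  sel <- ut[ord[seq_len(min(top, nrow(ut)))], , drop = FALSE]
  largest <- data.frame(
    v1 = rownames(stdres)[sel[, 1]], v2 = colnames(stdres)[sel[, 2]],
    residual = res[sel], standardized = stdres[sel])
  list(raw = res, standardized = stdres, largest = largest)
}

#' @export
print.sem_fit <- function(x, ...) {
  fi <- fit_indices(x)
  cat(sprintf(
    "<sem_fit> '%s': n = %d, chi2 = %.3f, df = %d, p = %.4f, CFI = %.3f%s\n",
    x$model$name, x$n, x$chi2, x$df, x$p_value, fi$cfi,
    if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}
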