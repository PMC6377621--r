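## Environment-independent spatial predictors: PCNM eigenvector basis,
## residualization against environmental variables, and PCA summarisation of
## spatially predicted richness into the components s1 and s2.

## Longest edge of the minimum spanning tree of the site distance graph
## (Prim's algorithm) - the classical automatic PCNM truncation distance.
mst_longest_edge <- function(d) {
  n <- nrow(d)
  in_tree <- logical(n)
  in_tree[1] <- TRUE
  best <- d[1, ]
  longest <- 0
  for (k in seq_len(n - 1)) {
    cand <- which(!in_tree)
    j <- cand[which.min(best[cand])]
    longest <- max(longest, best[j])
    in_tree[j] <- TRUE
    best <- pmin(best, d[j, ])
  }
  longest
}

#' PCNM spatial eigenvector basis
#'
#' Principal coordinates of neighbour matrices: pairwise Euclidean distances
#' are truncated (entries beyond the threshold replaced by four times the
#' threshold), the squared distances are double-centred, and the positive
#' eigenvectors of the resulting matrix - each scaled by the square root of
#' its eigenvalue - form spatial predictors ordered from broad to fine
#' scale.
#'
#' @param coords sites x 2 matrix/data.frame of coordinates (m).
#' @param truncation threshold distance in metres, or `"auto"` (longest
#'   minimum-spanning-tree edge).
#' @param positive_tol eigenvalues below this fraction of the largest are
#'   dropped as numerically zero.
#' @return list with `vectors` (sites x m, scaled by sqrt(eigenvalue)),
#'   `values` (positive eigenvalues), `truncation`.
#' @export
pcnm_basis <- function(coords, truncation = "auto", positive_tol = 1e-9) {
  coords <- as.matrix(coords)
  if (nrow(unique(coords)) < 3)
    stop_ps("need at least 3 distinct sites for a PCNM basis")
  d <- as.matrix(stats::dist(coords))
  if (identical(truncation, "auto")) truncation <- mst_longest_edge(d)
  dt <- d
  dt[dt > truncation] <- 4 * truncation
  n <- nrow(dt)
  g <- -0.5 * dt^2
  j <- diag(n) - matrix(1 / n, n, n)
  g <- j %*% g %*% j
  e <- eigen((g + t(g)) / 2, symmetric = TRUE)
  keep <- e$values > positive_tol * max(e$values)
  vals <- e$values[keep]
  vecs <- e$vectors[, keep, drop = FALSE]
  vecs <- sweep(vecs, 2, sqrt(vals), `*`)
  colnames(vecs) <- paste0("PCNM", seq_len(ncol(vecs)))
  list(vectors = vecs, values = vals, truncation = truncation)
}

## Moran's I of v under binary connectivity within the truncation distance.
morans_i <- function(v, w) {
  v <- v - mean(v)
  n <- length(v)
  (n / sum(w)) * as.numeric(t(v) %*% w %*% v) / sum(v^2)
}

#' Select PCNM eigenvectors
#'
#' Either keeps the full positive basis (default) or screens for vectors
#' with significantly positive spatial autocorrelation (Moran's I above its
#' expectation, permutation test) followed by forward selection on adjusted
#' R-squared against a response matrix.
#'
#' @param basis output of [pcnm_basis()].
#' @param coords site coordinates used to build the basis.
#' @param response optional sites x k response matrix for forward selection.
#' @param method `"all"` or `"moran_forward"`.
#' @param alpha significance level, `n_perm` permutations.
#' @param n_perm permutations for the Moran and forward-selection tests.
#' @param seed integer seed.
#' @return the basis restricted to the selected columns.
#' @export
select_pcnm <- function(basis, coords, response = NULL,
                        method = c("all", "moran_forward"), alpha = 0.05,
                        n_perm = 199, seed = 1) {
  method <- match.arg(method)
  if (method == "all") return(basis)
  coords <- as.matrix(coords)
  d <- as.matrix(stats::dist(coords))
  w <- (d <= basis$truncation) & d > 0
  storage.mode(w) <- "double"
  keep <- with_seed(seed, {
    vapply(seq_len(ncol(basis$vectors)), function(k) {
      v <- basis$vectors[, k]
      obs <- morans_i(v, w)
      null <- vapply(seq_len(n_perm), function(i)
        morans_i(sample(v), w), numeric(1))
      (1 + sum(null >= obs)) / (1 + n_perm) <= alpha
    }, logical(1))
  })
  vecs <- basis$vectors[, keep, drop = FALSE]
  vals <- basis$values[keep]
  if (!is.null(response) && ncol(vecs) > 1) {
    y <- scale(as.matrix(response), center = TRUE, scale = FALSE)
    sel <- integer(0)
    remaining <- seq_len(ncol(vecs))
    r2 <- function(cols) {
      f <- stats::lm.fit(cbind(1, vecs[, cols, drop = FALSE]), y)
      1 - sum(f$residuals^2) / sum(y^2)
    }
    adj <- function(R2, q) 1 - (1 - R2) * (nrow(y) - 1) / (nrow(y) - q - 1)
    global_adj <- adj(r2(remaining), length(remaining))
    with_seed(seed + 1, {
      repeat {
        if (!length(remaining)) break
        gains <- vapply(remaining, function(k) r2(c(sel, k)), numeric(1))
        k_best <- remaining[which.max(gains)]
        ## permutation test of the candidate's marginal contribution
        base_r2 <- if (length(sel)) r2(sel) else 0
        obs_gain <- max(gains) - base_r2
        null_gain <- vapply(seq_len(n_perm), function(i) {
          perm <- sample(nrow(y))
          f <- stats::lm.fit(cbind(1, vecs[, sel, drop = FALSE],
                                   vecs[perm, k_best]), y)
          (1 - sum(f$residuals^2) / sum(y^2)) - base_r2
        }, numeric(1))
        p <- (1 + sum(null_gain >= obs_gain)) / (1 + n_perm)
        if (p > alpha) break
        sel <- c(sel, k_best)
        remaining <- setdiff(remaining, k_best)
        if (adj(r2(sel), length(sel)) >= global_adj) break
      }
    })
    if (length(sel)) {
      vecs <- vecs[, sort(sel), drop = FALSE]
      vals <- vals[sort(sel)]
    }
  }
  list(vectors = vecs, values = vals, truncation = basis$truncation)
}

#' Residualize a spatial basis against environmental predictors
#'
#' Replaces every PCNM column with its least-squares residual on the
#' environmental matrix (plus intercept), yielding "spatial residuals" that
#' are exactly orthogonal to the measured environment. Collinear
#' environmental columns are dropped with a warning.
#'
#' @param basis output of [pcnm_basis()] / [select_pcnm()].
#' @param env sites x q numeric matrix of environmental predictors.
#' @return the basis with residualized `vectors`.
#' @export
residualize <- function(basis, env) {
  env <- as.matrix(env)
  v <- basis$vectors
  if (nrow(env) != nrow(v))
    stop_ps("env rows (%d) do not match basis rows (%d)", nrow(env), nrow(v))
  if (ncol(env) >= nrow(env))
    stop_ps("more environmental columns than sites")
  x <- cbind(1, env)
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    drop_idx <- qx$pivot[(qx$rank + 1):ncol(x)]
    warning(sprintf("dropping %d collinear environmental column(s)",
                    length(drop_idx)))
    x <- x[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    qx <- qr(x)
  }
  res <- qr.resid(qx, v)
  out <- basis
  out$vectors <- res
  out
}

#' Spatial components s1 and s2
#'
#' Regresses each richness variable on the (residualized) spatial basis,
#' then runs a covariance-based PCA on the three fitted-value columns. The
#' first two component scores, s1 and s2, summarise the environment-
#' independent spatial pattern shared by the richness variables.
#'
#' @param residual_basis output of [residualize()].
#' @param richness sites x k (typically 3) richness matrix.
#' @return list with `s1`, `s2`, `variance_explained` (per component),
#'   `loadings`, `fitted` (the spatially predicted richness), `r_squared`
#'   per richness variable.
#' @export
spatial_components <- function(residual_basis, richness) {
  v <- residual_basis$vectors
  y <- as.matrix(richness)
  if (nrow(y) != nrow(v))
    stop_ps("richness rows (%d) do not match basis rows (%d)",
            nrow(y), nrow(v))
  if (ncol(v) < 2) stop_ps("need at least 2 residual spatial columns")
  fit <- stats::lm.fit(cbind(1, v), y)
  pred <- y - fit$residuals
  if (any(apply(pred, 2, stats::sd) < .Machine$double.eps^0.5))
    stop_ps("a spatially predicted richness column is constant: no spatial signal")
  r2 <- 1 - colSums(fit$residuals^2) /
    colSums(scale(y, scale = FALSE)^2)
  pca <- stats::prcomp(pred, center = TRUE, scale. = FALSE)
  ve <- pca$sdev^2 / sum(pca$sdev^2)
  list(s1 = pca$x[, 1], s2 = pca$x[, 2],
       variance_explained = ve,
       loadings = pca$rotation[, 1:2, drop = FALSE],
       fitted = pred, r_squared = r2)
}
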