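## Community-structure statistics: Bray-Curtis dissimilarity, non-metric
## multidimensional scaling, nestedness temperature with permutation nulls,
## and richness-axis correlations.

#' Bray-Curtis dissimilarity
#'
#' `d(i, j) = sum |x_i - x_j| / sum (x_i + x_j)` over taxa. For incidence
#' data this reduces to `1 - 2a / (2a + b + c)` with `a` shared and `b`,
#' `c` unshared taxon counts.
#'
#' @param m sites x taxa matrix, non-negative entries, no all-zero rows.
#' @return symmetric dissimilarity matrix with zero diagonal, entries in
#'   `[0, 1]`.
#' @export
bray_curtis <- function(m) {
  m <- as.matrix(m)
  if (any(m < 0)) stop_ps("community matrix has negative entries")
  rs <- rowSums(m)
  if (any(rs == 0)) {
    bad <- rownames(m)[rs == 0] %||% which(rs == 0)
    stop_ps("all-zero site rows: %s", paste(bad, collapse = ", "))
  }
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <-
      sum(abs(m[i, ] - m[j, ])) / (rs[i] + rs[j])
  }
  d
}

## Kruskal stress-1 for a configuration given target disparities.
kruskal_stress <- function(d, dhat) sqrt(sum((d - dhat)^2) / sum(d^2))

#' Non-metric multidimensional scaling
#'
#' Minimises Kruskal stress-1 by alternating isotonic regression of
#' configuration distances on the rank order of the dissimilarities with
#' Guttman-transform configuration updates, keeping an update only when it
#' lowers stress (so stress is non-increasing within a start). The best of
#' `n_starts` starts (classical-scaling start plus random starts) is
#' returned with scores centred and rotated to principal axes.
#'
#' @param d symmetric dissimilarity matrix (e.g. from [bray_curtis()]).
#' @param k number of axes, default 2.
#' @param n_starts number of starts, default 20.
#' @param seed integer seed for the random starts.
#' @param maxit maximum iterations per start.
#' @param tol convergence threshold on the stress decrease.
#' @return list with `scores` (sites x k), `stress`, `converged`,
#'   `n_starts`, `seed`.
#' @export
nmds <- function(d, k = 2, n_starts = 20, seed = 1, maxit = 200,
                 tol = 1e-6) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) stop_ps("need at least 3 sites for ordination")
  ij <- which(upper.tri(d))
  delta <- d[ij]
  ord <- order(delta)

  run_start <- function(x0) {
    x <- x0
    dd <- as.matrix(stats::dist(x))
    dv <- dd[ij]
    stress <- Inf
    converged <- FALSE
    for (it in seq_len(maxit)) {
      ## isotonic regression of distances on dissimilarity ranks
      iso <- stats::isoreg(dv[ord])
      dhat <- numeric(length(dv)); dhat[ord] <- iso$yf
      s_now <- kruskal_stress(dv, dhat)
      if (is.finite(stress) && stress - s_now < tol && s_now <= stress) {
        stress <- s_now; converged <- TRUE; break
      }
      if (s_now < stress) stress <- s_now
      ## Guttman transform towards the disparities
      dhat_m <- matrix(0, n, n)
      dhat_m[ij] <- dhat; dhat_m <- dhat_m + t(dhat_m)
      ratio <- ifelse(dd > 0, dhat_m / dd, 0)
      bmat <- -ratio
      diag(bmat) <- 0
      diag(bmat) <- -rowSums(bmat)
      x_new <- bmat %*% x / n
      dd_new <- as.matrix(stats::dist(x_new))
      dv_new <- dd_new[ij]
      iso2 <- stats::isoreg(dv_new[ord])
      dhat2 <- numeric(length(dv_new)); dhat2[ord] <- iso2$yf
      s_new <- kruskal_stress(dv_new, dhat2)
      if (s_new <= stress + 1e-12) {
        x <- x_new; dd <- dd_new; dv <- dv_new
      } else {
        converged <- TRUE; break      # no admissible downhill move left
      }
      if (stress - s_new < tol && it > 1) {
        stress <- min(stress, s_new); converged <- TRUE; break
      }
      stress <- min(stress, s_new)
    }
    list(x = x, stress = stress, converged = converged)
  }

  with_seed(seed, {
    ## start 1: classical scaling; remaining: random Gaussian configurations
    starts <- vector("list", n_starts)
    cm <- try(stats::cmdscale(d, k = k), silent = TRUE)
    starts[[1]] <- if (inherits(cm, "try-error") || ncol(cm) < k)
      matrix(stats::rnorm(n * k), n, k) else {
        cm <- cbind(cm, matrix(0, n, k - ncol(cm)))
        cm + matrix(stats::rnorm(n * k, sd = 1e-4), n, k)
      }
    if (n_starts > 1)
      for (s in 2:n_starts)
        starts[[s]] <- matrix(stats::rnorm(n * k), n, k)
    best <- NULL
    for (s in seq_len(n_starts)) {
      res <- run_start(starts[[s]])
      if (is.null(best) || res$stress < best$stress) best <- res
    }
    x <- scale(best$x, center = TRUE, scale = FALSE)
    ## rotate to principal axes
    pc <- svd(x)
    x <- x %*% pc$v
    dimnames(x) <- list(rownames(d), paste0("NMDS", seq_len(k)))
    list(scores = x, stress = best$stress, converged = best$converged,
         n_starts = n_starts, seed = seed)
  })
}

## Pack a binary matrix to maximal nestedness: rows and columns reordered by
## a joint criterion iterated a few times (the published temperature
## estimator's packing), with deterministic tie-breaking.
pack_matrix <- function(x, ties = "canonical") {
  ## canonical mode breaks rank ties by the row/column incidence pattern,
  ## so packing depends only on matrix content (permutation invariant);
  ## "random" reproduces the reference implementation's tie policy.
  rank2 <- function(key, patterns) {
    if (ties == "random") return(rank(key, ties.method = "random"))
    o <- order(key, patterns)
    r <- integer(length(key)); r[o] <- seq_along(key)
    r
  }
  col_pat <- function(x) apply(x, 2, paste, collapse = "")
  row_pat <- function(x) apply(x, 1, paste, collapse = "")
  colpack <- function(x, rr) {
    ind <- matrix(rep(rr, ncol(x)), nrow = nrow(x))
    s <- -colSums((x * ind)^2)
    t <- -colSums((nrow(x) - (1 - x) * ind + 1)^2)
    rank2(s + t, col_pat(x))
  }
  rowpack <- function(x, cr) {
    ind <- matrix(rep(cr, each = nrow(x)), nrow = nrow(x))
    s <- -rowSums((x * ind)^2)
    t <- -rowSums((ncol(x) - (1 - x) * ind + 1)^2)
    rank2(s + t, row_pat(x))
  }
  ## the initial marginal-total rank uses average ties (as published)
  if (ncol(x) >= nrow(x)) {
    i <- rank(-rowSums(x), ties.method = "average")
  } else {
    j <- rank(-colSums(x), ties.method = "average")
    i <- rowpack(x, j)
  }
  for (k in seq_len(8)) {
    j <- colpack(x, i)
    i <- rowpack(x, j)
  }
  if (ncol(x) < nrow(x)) j <- colpack(x, i)
  x[order(i), order(j), drop = FALSE]
}

#' Nestedness temperature of an incidence matrix
#'
#' Implements the matrix-temperature estimator: the matrix is packed by a
#' joint row/column criterion, an isocline of perfect nestedness is fitted
#' to the observed fill, and the temperature is the normalised sum of
#' squared relative distances of unexpected presences (below/right of the
#' isocline) and unexpected absences (above/left) from the isocline, scaled
#' to 0-100. Perfectly nested matrices score 0.
#'
#' @param m incidence (or abundance, binarised internally) matrix with at
#'   least 2 rows and 2 columns.
#' @param ties tie-breaking in the packing ranks: `"canonical"`
#'   (content-based, deterministic and permutation-invariant, default) or
#'   `"random"` (the reference implementation's policy; makes the statistic
#'   depend on the RNG state for tied matrices).
#' @return list with `temperature`, the packed matrix `comm`, and the
#'   surprise matrix `u`.
#' @export
nestedness_temperature <- function(m, ties = c("canonical", "random")) {
  ties <- match.arg(ties)
  m <- as.matrix(m)
  if (nrow(m) < 2 || ncol(m) < 2)
    stop_ps("need at least a 2 x 2 incidence matrix")
  x <- ifelse(m > 0, 1, 0)
  fill <- sum(x) / length(x)
  if (fill == 0 || fill == 1) {
    warning("degenerate (all-zero or all-one) matrix: temperature 0")
    return(list(temperature = 0, comm = x, u = x * 0))
  }
  x <- pack_matrix(x, ties = ties)
  r <- stats::ppoints(nrow(x), a = 0.5)
  cpts <- stats::ppoints(ncol(x), a = 0.5)
  dis <- matrix(rep(r, ncol(x)), nrow = nrow(x))
  totdis <- 1 - abs(outer(r, cpts, "-"))
  ## isocline x + y-offset through the unit square matching the fill
  fillfun <- function(p_, p) 1 - (1 - (1 - p_)^p)^(1 / p)
  intfun <- function(p, fill)
    stats::integrate(fillfun, lower = 0, upper = 1, p = p)$value - fill
  p <- stats::uniroot(intfun, c(0, 20), fill = fill,
                      extendInt = "downX")$root
  iso <- matrix(0, nrow = length(r), ncol = length(cpts))
  for (i in seq_along(r)) for (j in seq_along(cpts)) {
    a <- cpts[j] - r[i]
    iso[i, j] <- stats::uniroot(function(z) fillfun(z, p) - a - z,
                                c(0, 1))$root
  }
  u <- (dis - iso) / totdis
  u[u < 0 & x == 1] <- 0
  u[u > 0 & x == 0] <- 0
  u <- u^2
  temp <- 100 * sum(u) / length(x) / 0.04145
  list(temperature = temp, comm = x, u = u)
}

## Null-model generators for incidence matrices.
null_matrix <- function(x, model = c("r00", "curveball", "quasiswap"),
                        n_iter = 1000) {
  model <- match.arg(model)
  if (model == "r00") {
    out <- matrix(0, nrow(x), ncol(x))
    out[sample.int(length(x), sum(x))] <- 1
    return(out)
  }
  ## curveball: fixed row and column sums via repeated pair trades
  rows <- lapply(seq_len(nrow(x)), function(i) which(x[i, ] > 0))
  nr <- nrow(x)
  for (it in seq_len(n_iter)) {
    ab <- sample.int(nr, 2)
    a <- rows[[ab[1]]]; b <- rows[[ab[2]]]
    shared <- intersect(a, b)
    only_a <- setdiff(a, shared); only_b <- setdiff(b, shared)
    tot <- c(only_a, only_b)
    if (length(only_a) == 0 || length(only_b) == 0) next
    pick <- sample(tot, length(only_a))
    rows[[ab[1]]] <- c(shared, pick)
    rows[[ab[2]]] <- c(shared, setdiff(tot, pick))
  }
  out <- matrix(0, nrow(x), ncol(x))
  for (i in seq_len(nr)) out[i, rows[[i]]] <- 1
  out
}

#' Permutation test of nestedness
#'
#' Compares the observed temperature with temperatures of null matrices
#' (lower temperature = more nested), with
#' `p = (1 + #\{null <= observed\}) / (1 + n_perm)`.
#'
#' @param m incidence matrix.
#' @param null_model `"r00"` (equiprobable fill preserving total fill,
#'   default), or `"curveball"`/`"quasiswap"` (fixed row and column sums).
#' @param n_perm number of null matrices, at least 99.
#' @param seed integer seed.
#' @return list with `temperature`, `null_temperatures`, `p_value`.
#' @export
nestedness_test <- function(m, null_model = "r00", n_perm = 999, seed = 1) {
  if (n_perm < 99) stop_ps("n_perm must be at least 99")
  null_model <- match.arg(null_model, c("r00", "curveball", "quasiswap"))
  x <- ifelse(as.matrix(m) > 0, 1, 0)
  obs <- nestedness_temperature(x)$temperature
  nulls <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    nestedness_temperature(null_matrix(x, null_model))$temperature
  }, numeric(1)))
  p <- (1 + sum(nulls <= obs)) / (1 + n_perm)
  list(temperature = obs, null_temperatures = nulls, p_value = p)
}

#' Correlation of richness with ordination axes
#'
#' Pearson correlation of a site richness vector with each ordination axis,
#' with permutation p-values. By convention each axis is reported with the
#' sign that makes its richness correlation non-positive (ordination axis
#' signs are arbitrary).
#'
#' @param richness numeric vector, one value per site.
#' @param ord an ordination from [nmds()] (or any list with `scores`).
#' @param n_perm permutations for the p-value.
#' @param seed integer seed.
#' @return data.frame with one row per axis: `axis`, `r`, `p_value`.
#' @export
richness_axis_correlation <- function(richness, ord, n_perm = 999,
                                      seed = 1) {
  scores <- if (is.list(ord)) ord$scores else as.matrix(ord)
  if (length(richness) != nrow(scores))
    stop_ps("richness length %d does not match %d sites",
            length(richness), nrow(scores))
  if (stats::sd(richness) == 0)
    stop_ps("richness has zero variance")
  res <- with_seed(seed, {
    lapply(seq_len(ncol(scores)), function(a) {
      v <- scores[, a]
      r_obs <- stats::cor(richness, v)
      if (r_obs > 0) { v <- -v; r_obs <- -r_obs }  # sign convention
      null_r <- vapply(seq_len(n_perm), function(i)
        abs(stats::cor(sample(richness), v)), numeric(1))
      p <- (1 + sum(null_r >= abs(r_obs))) / (1 + n_perm)
      data.frame(axis = a, r = r_obs, p_value = p)
    })
  })
  do.call(rbind, res)
}
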