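## Effect decompositions on a fitted recursive model: total/indirect
## effects, construct-level net effects, and reduced-form prediction.

## Standardized path matrix over all nodes (B[i, j] = std coefficient of
## cause j in the equation of effect i).
std_B <- function(fit) {
  sds <- sqrt(pmax(diag(fit$C), .Machine$double.xmin))
  fit$A * outer(1 / sds, sds)
}

#' Total, direct and indirect effects
#'
#' For a recursive model with standardized path matrix `B`, the total
#' effects are `(I - B)^-1 - I`: the sum over every directed path of the
#' product of its standardized coefficients. Direct effects are the `B`
#' entries; indirect effects the remainder.
#'
#' @param fit a `sem_fit`.
#' @return list with matrices `total`, `direct`, `indirect`
#'   (rows = outcome, columns = source) and a long data.frame `table` for
#'   pairs with any nonzero effect.
#' @export
total_effects <- function(fit) {
  B <- std_B(fit)
  m <- nrow(B)
  total <- solve(diag(m) - B) - diag(m)
  direct <- B
  indirect <- total - direct
  nz <- which(abs(total) > 1e-12 | abs(direct) > 1e-12, arr.ind = TRUE)
  tab <- data.frame(
    source = colnames(B)[nz[, 2]], outcome = rownames(B)[nz[, 1]],
    direct = direct[nz], indirect = indirect[nz], total = total[nz])
  list(total = total, direct = direct, indirect = indirect,
       table = tab[order(tab$outcome, -abs(tab$total)), ])
}

#' Net effects of abiotic, spatial and biotic constructs
#'
#' For each focal outcome, the direct parents are partitioned into the
#' three constructs and each construct is collapsed into a composite (the
#' weighted sum of its parents with the fitted path coefficients as
#' weights). The net effect is the absolute standardized path coefficient
#' of that composite: `sqrt(b' Sigma_PP b) / sd(outcome)` under the implied
#' covariance. Constructs with no path into an outcome report 0.
#'
#' @param fit a `sem_fit` whose model carries `groups` and `outcomes`
#'   (the built-in models do), or supply them explicitly.
#' @param groups named list of character vectors classifying variables.
#' @param outcomes character vector of outcome variables.
#' @return matrix outcomes x constructs of net effects in `[0, 1]`.
#' @export
net_effects <- function(fit, groups = NULL, outcomes = NULL) {
  groups <- groups %||% fit$model$groups
  outcomes <- outcomes %||% fit$model$outcomes
  if (is.null(groups) || is.null(outcomes))
    stop_ps("model has no construct groups/outcomes; supply them")
  nodes <- fit$skeleton$nodes
  sds <- sqrt(diag(fit$C))
  out <- matrix(0, length(outcomes), length(groups),
                dimnames = list(outcomes, names(groups)))
  for (y in outcomes) {
    iy <- match(y, nodes)
    if (is.na(iy)) stop_ps("outcome '%s' not in the model", y)
    b_row <- fit$A[iy, ]
    for (g in names(groups)) {
      members <- intersect(groups[[g]], nodes[b_row != 0])
      members <- setdiff(members, y)
      if (!length(members)) next
      jj <- match(members, nodes)
      b <- b_row[jj]
      v <- as.numeric(t(b) %*% fit$C[jj, jj, drop = FALSE] %*% b)
      out[y, g] <- sqrt(max(v, 0)) / sds[iy]
    }
  }
  out
}

## Topological order of nodes under the path/weight graph.
topo_order <- function(fit) {
  A <- fit$A != 0
  m <- nrow(A)
  indeg <- rowSums(A)
  ord <- integer(0)
  done <- logical(m)
  while (length(ord) < m) {
    ready <- which(!done & indeg == 0)
    if (!length(ready)) stop_ps("model is not recursive")
    ord <- c(ord, ready)
    done[ready] <- TRUE
    indeg <- indeg - rowSums(A[, ready, drop = FALSE])
  }
  ord
}

#' Predict richness (and other endogenous variables) for new data
#'
#' Reduced-form expected values: exogenous columns are taken from
#' `newdata`, centred at the training means, and propagated through the
#' fitted equations in topological order (endogenous mediators are replaced
#' by their predicted values), then re-centred at the training means of
#' each outcome.
#'
#' @param fit a `sem_fit`.
#' @param newdata data.frame with every exogenous predictor of the model
#'   (model variable names, or the original data columns used at fit time).
#' @param outcomes variables to return; default the model's focal outcomes
#'   (or all endogenous).
#' @return data.frame of predicted values, one column per outcome.
#' @export
predict_richness <- function(fit, newdata, outcomes = NULL) {
  model <- fit$model
  outcomes <- outcomes %||% model$outcomes %||% model$endogenous
  nd <- as.data.frame(newdata)
  ## accept either model names or the mapped original column names
  for (q in seq_along(model$observed)) {
    mv <- model$observed[q]; cv <- fit$data_columns[q]
    if (!mv %in% names(nd) && cv %in% names(nd)) nd[[mv]] <- nd[[cv]]
  }
  missing_exo <- setdiff(model$exogenous, names(nd))
  if (length(missing_exo))
    stop_ps("newdata lacks exogenous predictor(s): %s",
            paste(missing_exo, collapse = ", "))
  nodes <- fit$skeleton$nodes
  n <- nrow(nd)
  vals <- matrix(0, n, length(nodes), dimnames = list(NULL, nodes))
  mu <- stats::setNames(rep(0, length(nodes)), nodes)
  mu[model$observed] <- fit$means[model$observed]
  for (v in model$exogenous) vals[, v] <- nd[[v]] - mu[v]
  for (i in topo_order(fit)) {
    v <- nodes[i]
    if (v %in% model$exogenous) next
    vals[, i] <- vals %*% fit$A[i, ]
  }
  out <- as.data.frame(vals[, outcomes, drop = FALSE])
  for (v in outcomes) out[[v]] <- out[[v]] + mu[v]
  out
}
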