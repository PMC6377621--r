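## Recursive path models with composite variables: specification, parsing,
## validation, and the built-in landscape model.

#' Construct a path model
#'
#' A path model is a directed acyclic graph of observed variables plus
#' optional composite (emergent, zero-disturbance) variables defined as
#' weighted sums of their causes. Exogenous observed variables get a
#' saturated free covariance block; every endogenous observed variable gets
#' a free disturbance variance; additional disturbance covariances can be
#' declared explicitly.
#'
#' @param paths data.frame with columns `effect`, `cause` and optionally
#'   `fixed` (numeric fixed coefficient, `NA` = free).
#' @param composites named list; each element a data.frame with columns
#'   `cause` and `fixed` (first weight fixed to 1 for identification when
#'   none is fixed).
#' @param covariances optional data.frame with columns `v1`, `v2` declaring
#'   free disturbance covariances between endogenous variables.
#' @param groups optional named list classifying variables into constructs
#'   (e.g. abiotic/spatial/biotic) for [net_effects()].
#' @param outcomes optional character vector of focal outcome variables.
#' @param name optional model name.
#' @return object of class `path_model`.
#' @export
path_model <- function(paths, composites = list(), covariances = NULL,
                       groups = NULL, outcomes = NULL, name = "model") {
  paths <- as.data.frame(paths)
  if (!all(c("effect", "cause") %in% names(paths)))
    stop_ps("paths needs columns effect, cause")
  if (is.null(paths$fixed)) paths$fixed <- NA_real_
  if (anyDuplicated(paths[c("effect", "cause")]))
    stop_ps("duplicate path: %s",
            paste(paths[duplicated(paths[c("effect", "cause")]),
                        c("cause")], collapse = ", "))
  comp_names <- names(composites)
  for (nm in comp_names) {
    cdf <- as.data.frame(composites[[nm]])
    if (is.null(cdf$fixed)) cdf$fixed <- NA_real_
    if (!any(is.finite(cdf$fixed))) cdf$fixed[1] <- 1
    composites[[nm]] <- cdf
  }
  vars <- unique(c(paths$effect, paths$cause,
                   unlist(lapply(composites, `[[`, "cause")), comp_names))
  ## full edge list (paths + composite weights) for cycle detection
  edges <- rbind(
    paths[c("effect", "cause")],
    do.call(rbind, lapply(comp_names, function(nm)
      data.frame(effect = nm, cause = composites[[nm]]$cause))))
  if (has_cycle(vars, edges))
    stop_ps("path graph contains a cycle")
  observed <- setdiff(vars, comp_names)
  endo <- intersect(unique(edges$effect), observed)
  exo <- setdiff(observed, endo)
  if (!is.null(covariances)) {
    covariances <- as.data.frame(covariances)
    bad <- !(covariances$v1 %in% vars & covariances$v2 %in% vars)
    if (any(bad))
      stop_ps("covariance references unknown variable(s): %s",
              paste(unlist(covariances[bad, ]), collapse = ", "))
  }
  structure(list(vars = vars, observed = observed, composites = composites,
                 exogenous = exo, endogenous = endo, paths = paths,
                 covariances = covariances, groups = groups,
                 outcomes = outcomes, name = name),
            class = "path_model")
}

has_cycle <- function(vars, edges) {
  indeg <- stats::setNames(integer(length(vars)), vars)
  tab <- table(edges$effect)
  indeg[names(tab)] <- as.integer(tab)
  queue <- names(indeg)[indeg == 0]
  seen <- 0L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
    out <- edges$effect[edges$cause == v]
    for (w in out) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  seen < length(vars)
}

#' Number of free parameters and degrees of freedom
#'
#' Free parameters: free paths and composite weights, exogenous variances
#' and all exogenous covariances (saturated block), one disturbance variance
#' per endogenous variable, plus declared disturbance covariances. Model
#' degrees of freedom are `p(p+1)/2 - t` over the `p` observed variables.
#'
#' @param model a [path_model()].
#' @return list with `t` (free parameter count), `p`, `df`.
#' @export
model_df <- function(model) {
  n_paths <- sum(!is.finite(model$paths$fixed))
  n_w <- sum(vapply(model$composites,
                    function(c) sum(!is.finite(c$fixed)), 0L))
  n_exo <- length(model$exogenous)
  n_cov <- if (is.null(model$covariances)) 0L else nrow(model$covariances)
  t <- n_paths + n_w + n_exo * (n_exo + 1) / 2 +
    length(model$endogenous) + n_cov
  p <- length(model$observed)
  list(t = t, p = p, df = p * (p + 1) / 2 - t)
}

#' @export
print.path_model <- function(x, ...) {
  d <- model_df(x)
  cat(sprintf(
    "<path_model> '%s': %d observed (%d exogenous), %d composites, %d paths, df = %d\n",
    x$name, length(x$observed), length(x$exogenous),
    length(x$composites), nrow(x$paths), d$df))
  invisible(x)
}

#' Parse a path-model specification
#'
#' Lines (separated by newlines or `;`) of the forms
#' `effect <- cause1 + 0.5*cause2` (structural paths; a numeric multiplier
#' fixes the coefficient), `composite C <= 1*x1 + x2` (composite definition;
#' the first weight is fixed to 1 when none is fixed explicitly), and
#' `x ~~ y` (free disturbance covariance). `#` starts a comment. The names
#' `"final_2019"` and `"predictive"` return the built-in landscape models.
#'
#' @param text model specification text, or a built-in model name.
#' @return a [path_model()].
#' @export
parse_model <- function(text) {
  if (length(text) == 1 && text %in% c("final_2019", "predictive"))
    return(builtin_model(text))
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "[\n;]"))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  paths <- NULL; comps <- list(); covs <- NULL
  parse_terms <- function(rhs, where) {
    terms <- trimws(strsplit(rhs, "+", fixed = TRUE)[[1]])
    out <- lapply(terms, function(tm) {
      if (grepl("*", tm, fixed = TRUE)) {
        parts <- trimws(strsplit(tm, "*", fixed = TRUE)[[1]])
        if (length(parts) != 2)
          stop_ps("cannot parse term '%s' (line: %s)", tm, where)
        w <- suppressWarnings(as.numeric(parts[1]))
        data.frame(cause = parts[2],
                   fixed = if (is.finite(w)) w else NA_real_)
      } else data.frame(cause = tm, fixed = NA_real_)
    })
    do.call(rbind, out)
  }
  for (ln in lines) {
    if (grepl("^composite\\s+", ln)) {
      body <- sub("^composite\\s+", "", ln)
      if (!grepl("<=", body, fixed = TRUE))
        stop_ps("composite line without '<=': %s", ln)
      parts <- strsplit(body, "<=", fixed = TRUE)[[1]]
      nm <- trimws(parts[1])
      if (nm %in% names(comps)) stop_ps("composite '%s' redefined", nm)
      comps[[nm]] <- parse_terms(parts[2], ln)
    } else if (grepl("~~", ln, fixed = TRUE)) {
      parts <- trimws(strsplit(ln, "~~", fixed = TRUE)[[1]])
      if (length(parts) != 2) stop_ps("cannot parse covariance line: %s", ln)
      covs <- rbind(covs, data.frame(v1 = parts[1], v2 = parts[2]))
    } else if (grepl("<-", ln, fixed = TRUE)) {
      parts <- strsplit(ln, "<-", fixed = TRUE)[[1]]
      if (length(parts) != 2) stop_ps("cannot parse path line: %s", ln)
      eff <- trimws(parts[1])
      tms <- parse_terms(parts[2], ln)
      paths <- rbind(paths, data.frame(effect = eff, cause = tms$cause,
                                       fixed = tms$fixed))
    } else stop_ps("cannot parse line: %s", ln)
  }
  if (is.null(paths)) stop_ps("model has no structural paths")
  path_model(paths, composites = comps, covariances = covs,
             name = "parsed")
}

## The built-in landscape models. `final_2019` is the full model: terrain,
## temperature and the two environment-independent spatial components drive
## soil chemistry and the richness of cyanobacteria, fungi and multicellular
## taxa; pH and total N are endogenous children of terrain so that soil
## properties partially mediate topography, and the three richness variables
## are linked cyano -> fungi -> multicellular. 14 observed variables,
## 28 paths, saturated 8-variable exogenous block: df = 35.
## `predictive` keeps only remote-sensing-derivable predictors.
builtin_model <- function(name) {
  p <- function(effect, cause) data.frame(effect = effect, cause = cause,
                                          fixed = NA_real_)
  groups <- list(
    abiotic = c("elevation", "slope", "aspect", "dist_coast", "wetness",
                "temperature", "ph", "nitrogen", "water"),
    spatial = c("s1", "s2"),
    biotic = c("cyano_s", "fungal_s", "multi_s"))
  outcomes <- c("cyano_s", "fungal_s", "multi_s")
  if (name == "final_2019") {
    paths <- rbind(
      p("ph", c("dist_coast", "elevation")),
      p("nitrogen", c("wetness", "dist_coast", "elevation")),
      p("water", "temperature"),
      p("cyano_s", c("elevation", "dist_coast", "wetness", "aspect",
                     "slope", "s1", "s2")),
      p("fungal_s", c("dist_coast", "water", "cyano_s", "ph",
                      "temperature", "s1", "s2")),
      p("multi_s", c("cyano_s", "fungal_s", "nitrogen", "dist_coast",
                     "elevation", "aspect", "s1", "s2")))
    return(path_model(paths, groups = groups, outcomes = outcomes,
                      name = "final_2019"))
  }
  if (name == "predictive") {
    paths <- rbind(
      p("cyano_s", c("elevation", "dist_coast", "wetness", "aspect",
                     "slope")),
      p("fungal_s", c("dist_coast", "temperature", "cyano_s")),
      p("multi_s", c("cyano_s", "fungal_s", "dist_coast", "elevation",
                     "aspect")))
    return(path_model(paths, groups = groups, outcomes = outcomes,
                      name = "predictive"))
  }
  stop_ps("unknown built-in model '%s'", name)
}
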