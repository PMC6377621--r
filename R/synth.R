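## Synthetic landscapes, sample tables, community matrices and
## electropherograms with a known ground-truth path model.

#' Ground truth for the synthetic generator
#'
#' The recursive structural equations used to generate biotic and soil
#' variables, with their disturbance SDs and the spatial-field parameters.
#' Coefficients apply to in-sample z-scored parent variables, so they are
#' standardized-scale quantities. The default truth mirrors the built-in
#' `final_2019` model topology: signed magnitudes 0.12-0.35 matching the
#' documented signs (richness rising with elevation, coast distance and
#' wetness, falling with aspect deviation and slope; fungi tracking soil
#' water, pH and temperature plus cyanobacterial richness; multicellular
#' richness tracking both microbial groups plus soil N), with disturbance
#' SDs sized so each richness equation explains roughly a third of the
#' variance.
#'
#' @param paths data.frame with columns `effect`, `cause`, `coef`.
#' @param disturbance_sds named numeric vector, one per endogenous variable
#'   (zero allowed for the noise-free limit).
#' @param spatial_sd multiplier on the two spatial-field path coefficients.
#' @param spatial_range exponential-covariance range of the spatial fields,
#'   metres.
#' @return object of class `ground_truth`.
#' @export
ground_truth <- function(paths, disturbance_sds, spatial_sd = 1,
                         spatial_range = 500) {
  paths <- as.data.frame(paths)
  stopifnot(all(c("effect", "cause", "coef") %in% names(paths)))
  vars <- unique(c(paths$effect, paths$cause))
  if (has_cycle(vars, paths[c("effect", "cause")]))
    stop_ps("ground-truth path graph contains a cycle")
  endo <- unique(paths$effect)
  miss <- setdiff(endo, names(disturbance_sds))
  if (length(miss))
    stop_ps("disturbance_sds missing for: %s", paste(miss, collapse = ", "))
  if (any(disturbance_sds < 0)) stop_ps("disturbance SDs must be >= 0")
  structure(list(paths = paths, disturbance_sds = disturbance_sds,
                 spatial_sd = spatial_sd, spatial_range = spatial_range,
                 vars = vars, endogenous = endo,
                 exogenous = setdiff(vars, endo)),
            class = "ground_truth")
}

#' @rdname ground_truth
#' @export
default_truth <- function(spatial_sd = 1, spatial_range = 500) {
  tr <- function(effect, cause, coef)
    data.frame(effect = effect, cause = cause, coef = coef)
  paths <- rbind(
    tr("ph", c("dist_coast", "elevation"), c(0.25, -0.20)),
    tr("nitrogen", c("wetness", "dist_coast", "elevation"),
       c(0.30, 0.20, 0.20)),
    tr("water", "temperature", -0.35),
    tr("cyano_s", c("elevation", "dist_coast", "wetness", "aspect",
                    "slope", "s1", "s2"),
       c(0.30, 0.25, 0.30, -0.20, -0.20, 0.30, 0.25)),
    tr("fungal_s", c("dist_coast", "water", "cyano_s", "ph",
                     "temperature", "s1", "s2"),
       c(0.20, 0.25, 0.20, -0.25, -0.25, 0.25, 0.20)),
    tr("multi_s", c("cyano_s", "fungal_s", "nitrogen", "dist_coast",
                    "elevation", "aspect", "s1", "s2"),
       c(0.22, 0.22, 0.25, 0.20, 0.20, -0.20, 0.15, 0.12)))
  sds <- c(ph = 0.95, nitrogen = 0.90, water = 0.94,
           cyano_s = 1.20, fungal_s = 0.95, multi_s = 1.20)
  ground_truth(paths, sds, spatial_sd = spatial_sd,
               spatial_range = spatial_range)
}

## B matrix (effect x cause) and topological order of the truth equations.
truth_matrices <- function(truth) {
  vars <- truth$vars
  B <- matrix(0, length(vars), length(vars), dimnames = list(vars, vars))
  for (k in seq_len(nrow(truth$paths)))
    B[truth$paths$effect[k], truth$paths$cause[k]] <- truth$paths$coef[k]
  sp <- intersect(c("s1", "s2"), vars)
  if (length(sp)) B[, sp] <- B[, sp] * truth$spatial_sd
  B
}

#' Truth-implied covariance matrix
#'
#' `Sigma = (I - B)^-1 S0 (I - B)^-T` with the exogenous block supplied
#' (identity by default) and squared disturbance SDs on the endogenous
#' diagonal of `S0`.
#'
#' @param truth a [ground_truth()].
#' @param exo_cov covariance matrix of the exogenous variables (named), or
#'   `NULL` for the identity.
#' @return covariance matrix over all truth variables.
#' @export
truth_implied_cov <- function(truth, exo_cov = NULL) {
  B <- truth_matrices(truth)
  vars <- truth$vars
  S0 <- matrix(0, length(vars), length(vars), dimnames = dimnames(B))
  if (is.null(exo_cov)) {
    diag(S0)[truth$exogenous] <- 1
  } else {
    S0[truth$exogenous, truth$exogenous] <-
      exo_cov[truth$exogenous, truth$exogenous]
  }
  diag(S0)[truth$endogenous] <- truth$disturbance_sds[truth$endogenous]^2
  Binv <- solve(diag(length(vars)) - B)
  Binv %*% S0 %*% t(Binv)
}

## Separable Gaussian smoothing of a matrix (reflected edges).
smooth_gauss <- function(m, sd_cells) {
  if (sd_cells <= 0) return(m)
  half <- max(1L, ceiling(3 * sd_cells))
  kern <- stats::dnorm(seq(-half, half), sd = sd_cells)
  kern <- kern / sum(kern)
  smooth_vec <- function(v) {
    ext <- c(rev(v[seq_len(half)]), v, rev(v[length(v) - seq_len(half) + 1]))
    stats::filter(ext, kern, sides = 2)[half + seq_along(v)]
  }
  m <- apply(m, 2, smooth_vec)
  t(apply(t(m), 2, smooth_vec))
}

#' Generate a synthetic DEM
#'
#' A smooth random elevation surface rising inland from a "coast" edge (the
#' southern grid edge), guaranteed to contain at least one zero-elevation
#' coast cell. Reproducible for a fixed seed.
#'
#' @param nrows,ncols grid dimensions (>= 8).
#' @param cellsize cell size in metres.
#' @param relief approximate total relief in metres (> 0).
#' @param smoothness in (0, 1]: fraction controlling the Gaussian smoothing
#'   radius (higher = smoother terrain).
#' @param seed integer seed.
#' @return a [dem_grid()].
#' @export
generate_dem <- function(nrows, ncols, cellsize = 100, relief = 800,
                         smoothness = 0.5, seed = 1) {
  if (nrows < 8 || ncols < 8)
    stop_ps("DEM must be at least 8 x 8, got %d x %d", nrows, ncols)
  if (relief <= 0 || cellsize <= 0)
    stop_ps("relief and cellsize must be positive")
  with_seed(seed, {
    noise <- matrix(stats::rnorm(nrows * ncols), nrows, ncols)
    sd_cells <- max(0.75, smoothness * min(nrows, ncols) / 4)
    field <- smooth_gauss(noise, sd_cells)
    field <- (field - mean(field)) / stats::sd(field)
    ## inland trend: row `nrows` (south) is the coast, elevation rises north
    trend <- matrix(rep((nrows - seq_len(nrows)) / (nrows - 1), ncols),
                    nrows, ncols)
    z <- relief * trend + 0.25 * relief * field
    z <- z - min(z[nrows, ])          # pin the coast edge minimum to zero
    z <- pmax(z, 0)
    dem_grid(z, cellsize)
  })
}

## Draw k spatially autocorrelated unit-variance fields at the given
## coordinates (exponential covariance, shared Cholesky factor).
gp_fields <- function(coords, range_m, k = 2) {
  d <- as.matrix(stats::dist(coords))
  cv <- exp(-d / range_m)
  diag(cv) <- diag(cv) + 1e-8
  L <- chol(cv)
  sapply(seq_len(k), function(i) as.numeric(t(L) %*% stats::rnorm(nrow(d))))
}

zscore <- function(v) as.numeric(scale(v))

#' Generate a synthetic sample table
#'
#' Samples `n_sites` land cells from the DEM, derives terrain covariates
#' (slope, aspect deviation, wetness index, distance to coast), draws two
#' spatially autocorrelated fields (`s1`, `s2`) plus independent soil
#' chemistry, and propagates the ground-truth structural equations to
#' produce latent richness scores (`cyano_s`, `fungal_s`, `multi_s`) and
#' monotone-discretized integer richness columns (microbial 0-120,
#' multicellular 0-9). Soil ATP is generated independently of everything
#' else. All structural equations operate on in-sample z-scores.
#'
#' @param dem a [dem_grid()] (see [generate_dem()]).
#' @param n_sites number of sites (at most the number of land cells).
#' @param truth a [ground_truth()].
#' @param seed integer seed.
#' @return data.frame with one row per site; the truth is attached as
#'   attribute `"truth"`.
#' @export
generate_sample_table <- function(dem, n_sites, truth = default_truth(),
                                  seed = 1) {
  if (!inherits(truth, "ground_truth")) stop_ps("truth must be ground_truth")
  land <- which(dem$elev > 0)
  if (n_sites > length(land))
    stop_ps("n_sites (%d) exceeds available land cells (%d)",
            n_sites, length(land))
  st <- terrain_stack(dem)
  with_seed(seed, {
    cells <- sample(land, n_sites)
    nr <- nrow(dem$elev)
    rows <- ((cells - 1L) %% nr) + 1L
    cols <- ((cells - 1L) %/% nr) + 1L
    cc <- dem_coords(dem, rows, cols)
    d <- data.frame(site_id = sprintf("site%04d", seq_len(n_sites)),
                    x = cc$x, y = cc$y,
                    elevation = dem$elev[cells],
                    slope = st$slope[cells],
                    aspect = st$aspect_dev[cells],
                    dist_coast = st$dist_coast[cells],
                    wetness = st$cti[cells])
    z <- list(elevation = zscore(d$elevation), slope = zscore(d$slope),
              aspect = zscore(d$aspect), dist_coast = zscore(d$dist_coast),
              wetness = zscore(d$wetness))
    ## surface temperature: lapse with elevation plus independent noise
    temp_z <- zscore(-0.55 * z$elevation +
                       sqrt(1 - 0.55^2) * stats::rnorm(n_sites))
    d$temperature <- 2 + 6 * temp_z
    z$temperature <- temp_z
    ## environment-independent spatial fields, recorded as ground truth
    sp <- gp_fields(cbind(d$x, d$y), truth$spatial_range, k = 2)
    z$s1 <- zscore(sp[, 1]); z$s2 <- zscore(sp[, 2])
    d$s1 <- z$s1; d$s2 <- z$s2
    ## independent soil measures (not part of the path model)
    d$conductivity <- exp(stats::rnorm(n_sites, 4.5, 0.8))  # uS/cm
    d$carbon <- exp(stats::rnorm(n_sites, -2.2, 0.6))       # % organic C
    d$atp <- exp(stats::rnorm(n_sites, 1.5, 0.9))           # pmol/g
    ## propagate the structural equations in topological order
    B <- truth_matrices(truth)
    order_vars <- truth_topo_order(truth)
    for (v in order_vars) {
      if (v %in% names(z)) next
      parents <- colnames(B)[B[v, ] != 0]
      sdv <- truth$disturbance_sds[[v]]
      val <- as.numeric(vapply(parents, function(p2) B[v, p2] * z[[p2]],
                               numeric(n_sites)) |>
                          matrix(nrow = n_sites) |> rowSums())
      z[[v]] <- val + (if (sdv > 0) stats::rnorm(n_sites, sd = sdv) else 0)
    }
    ## natural units (linear transforms preserve the path structure)
    d$ph <- 8.2 + 0.45 * z$ph
    d$nitrogen <- 0.045 + 0.018 * z$nitrogen    # total N, %
    d$water <- 2.2 + 0.9 * z$water              # gravimetric moisture, %
    d$cyano_s <- z$cyano_s
    d$fungal_s <- z$fungal_s
    d$multi_s <- z$multi_s
    ## monotone quantile discretization of latent scores to counts
    disc <- function(score, size, prob) {
      p2 <- stats::pnorm(score / max(stats::sd(score), 1e-12))
      as.integer(stats::qbinom(p2, size, prob))
    }
    d$cyano_richness <- disc(z$cyano_s, 120, 0.25)
    d$fungal_richness <- disc(z$fungal_s, 120, 0.30)
    d$multi_richness <- disc(z$multi_s, 9, 0.45)
    attr(d, "truth") <- truth
    ## linear transforms from the structural (z) metric to natural units,
    ## recorded so fits can be run in the exact generating metric
    attr(d, "transforms") <- data.frame(
      variable = c("ph", "nitrogen", "water"),
      center = c(8.2, 0.045, 2.2),
      scale = c(0.45, 0.018, 0.9))
    d
  })
}

truth_topo_order <- function(truth) {
  remaining <- truth$endogenous
  done <- truth$exogenous
  ord <- character(0)
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(v) {
      all(truth$paths$cause[truth$paths$effect == v] %in% done)
    }, logical(1))]
    if (!length(ready)) stop_ps("truth graph is not recursive")
    ord <- c(ord, ready)
    done <- c(done, ready)
    remaining <- setdiff(remaining, ready)
  }
  ord
}

#' Generate a community incidence matrix with tunable nestedness
#'
#' Row sums equal the supplied richness vector exactly. At
#' `nestedness_strength = 1` every site holds the top-ranked taxa (a
#' perfectly nested matrix); at 0 taxa are sampled uniformly from the pool;
#' in between, a fraction `strength` of each site's taxa come from the top
#' ranks and the rest are sampled uniformly.
#'
#' @param richness integer vector of site richness values.
#' @param pool_size taxon pool size (>= max richness).
#' @param nestedness_strength in `[0, 1]`.
#' @param seed integer seed.
#' @return sites x taxa incidence matrix.
#' @export
generate_community_matrix <- function(richness, pool_size,
                                      nestedness_strength = 1, seed = 1) {
  if (max(richness) > pool_size)
    stop_ps("richness (max %d) exceeds pool size %d", max(richness),
            pool_size)
  if (nestedness_strength < 0 || nestedness_strength > 1)
    stop_ps("nestedness_strength must be in [0, 1]")
  with_seed(seed, {
    m <- matrix(0L, length(richness), pool_size,
                dimnames = list(sprintf("site%04d", seq_along(richness)),
                                sprintf("t%03d", seq_len(pool_size))))
    for (i in seq_along(richness)) {
      r <- richness[i]
      if (r == 0) next
      k_top <- round(nestedness_strength * r)
      taxa <- seq_len(k_top)
      if (r > k_top)
        taxa <- c(taxa, sample(setdiff(seq_len(pool_size), taxa),
                               r - k_top))
      m[i, taxa] <- 1L
    }
    m
  })
}

#' Generate a synthetic ARISA electropherogram
#'
#' Builds a peak list containing exactly `true_richness` peaks that pass
#' the true-peak acceptance rule for a window equal to `size_range`
#' (inside the window, > 30 RFU, > 0.3% of the summed fluorescence of
#' peaks over 30 RFU) plus `noise_peaks` peaks that each fail at least one
#' criterion (below the RFU floor, outside the window, or below the
#' relative threshold).
#'
#' @param true_richness number of true peaks (>= 0).
#' @param size_range numeric length-2 window in bp, within `[50, 1500]`.
#' @param seed integer seed.
#' @param noise_peaks number of failing peaks to add.
#' @param rfu_scale base fluorescence scale of true peaks (true peaks are
#'   drawn between 1 and 3 times this value).
#' @return an [electropherogram()].
#' @export
generate_electropherogram <- function(true_richness, size_range = c(100, 1200),
                                      seed = 1, noise_peaks = 10,
                                      rfu_scale = 1000) {
  if (true_richness < 0) stop_ps("true_richness must be >= 0")
  if (size_range[1] < 50 || size_range[2] > 1500 ||
      size_range[1] >= size_range[2])
    stop_ps("size_range must be increasing and within [50, 1500]")
  lo <- size_range[1]; hi <- size_range[2]
  slots <- seq(lo + 1, hi - 1, by = 2.5)
  if (true_richness > length(slots))
    stop_ps("size_range too narrow for %d separated peaks", true_richness)
  with_seed(seed, {
    true_size <- sort(sample(slots, true_richness)) +
      stats::runif(true_richness, -0.2, 0.2)
    true_rfu <- stats::runif(true_richness, 1, 3) * rfu_scale
    ## noise classes cycle: below-floor, out-of-window, below-relative
    cls <- rep_len(c("floor", "window", "relative"),
                   max(noise_peaks, 0))
    n_fl <- sum(cls == "floor"); n_wi <- sum(cls == "window")
    n_re <- sum(cls == "relative")
    fl_size <- stats::runif(n_fl, lo + 0.3, hi - 0.3)
    fl_rfu <- stats::runif(n_fl, 1, 29)
    wi_size <- stats::runif(n_wi, max(50, lo - 45), lo - 4)
    wi_rfu <- stats::runif(n_wi, 35, 300)
    t0 <- sum(true_rfu) + sum(wi_rfu)
    if (0.0029 * t0 > 31) {
      re_rfu <- stats::runif(n_re, 31, 0.0029 * t0)
    } else {
      re_rfu <- stats::runif(n_re, 1, 29)   # fall back to floor failures
    }
    re_size <- stats::runif(n_re, lo + 0.3, hi - 0.3)
    size <- c(true_size, fl_size, wi_size, re_size)
    rfu <- c(true_rfu, fl_rfu, wi_rfu, re_rfu)
    ## nudge near-duplicate sizes apart so the profile is strictly increasing
    o <- order(size)
    size <- size[o]; rfu <- rfu[o]
    while (any(diff(size) < 1e-3))
      size[which(diff(size) < 1e-3) + 1] <-
        size[which(diff(size) < 1e-3) + 1] + 1e-3
    prof <- electropherogram("synthetic", size, rfu)
    ## verify the round-trip contract before returning
    called <- call_true_peaks(prof, window = size_range)
    if (nrow(called) != true_richness)
      stop_ps("internal error: generated profile calls %d peaks, expected %d",
              nrow(called), true_richness)
    prof
  })
}

#' Generate a full synthetic bundle
#'
#' DEM, sample table, community matrices (cyanobacteria, fungi,
#' multicellular taxa) and per-site electropherograms for the two ARISA
#' groups, with the ground truth attached.
#'
#' @param n_sites number of sites.
#' @param truth a [ground_truth()].
#' @param nrows,ncols,cellsize,relief,smoothness DEM parameters.
#' @param nestedness_strength community nestedness (default 0.8).
#' @param electropherograms generate per-site peak lists (slow for large
#'   `n_sites`), default TRUE.
#' @param seed integer seed.
#' @return list with `dem`, `samples`, `communities`, `electropherograms`,
#'   `truth`.
#' @export
generate_bundle <- function(n_sites = 490, truth = default_truth(),
                            nrows = 32, ncols = 32, cellsize = 100,
                            relief = 800, smoothness = 0.5,
                            nestedness_strength = 0.8,
                            electropherograms = TRUE, seed = 1) {
  dem <- generate_dem(nrows, ncols, cellsize, relief, smoothness,
                      seed = seed)
  samples <- generate_sample_table(dem, n_sites, truth, seed = seed + 1)
  communities <- list(
    cyanobacteria = generate_community_matrix(
      samples$cyano_richness, 140, nestedness_strength, seed = seed + 2),
    fungi = generate_community_matrix(
      samples$fungal_richness, 160, nestedness_strength, seed = seed + 3),
    multicellular = generate_community_matrix(
      samples$multi_richness, 9, nestedness_strength, seed = seed + 4))
  colnames(communities$multicellular) <-
    c("nematodes", "rotifers", "tardigrades", "springtails", "mites",
      "cyano_mats", "mosses", "lichens", "hypoliths")
  eph <- NULL
  if (electropherograms) {
    eph <- list(
      cyanobacteria = lapply(seq_len(n_sites), function(i)
        generate_electropherogram(samples$cyano_richness[i],
                                  c(100, 1200), seed = seed * 1000 + i)),
      fungi = lapply(seq_len(n_sites), function(i)
        generate_electropherogram(samples$fungal_richness[i],
                                  c(100, 1400), seed = seed * 2000 + i)))
    for (g in names(eph)) names(eph[[g]]) <- samples$site_id
  }
  list(dem = dem, samples = samples, communities = communities,
       electropherograms = eph, truth = truth)
}
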