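## Terrain covariates from a DEM: Horn slope/aspect, D8 flow accumulation,
## compound topographic wetness index, distance to coast.

## Pad a matrix by replicating its edges (used by the 3x3 gradient stencil).
pad_edges <- function(m) {
  m2 <- m[c(1, seq_len(nrow(m)), nrow(m)), c(1, seq_len(ncol(m)), ncol(m))]
  m2
}

#' Slope and aspect deviation from north
#'
#' Computes slope (radians) and aspect on every cell using Horn's 3x3
#' finite-difference stencil. Aspect is reported as the absolute angular
#' deviation of the downslope direction from north, in degrees 0-180, so a
#' north-facing cell scores 0 and a south-facing cell 180. Flat cells get
#' aspect deviation 0 by convention.
#'
#' @param dem a [dem_grid()].
#' @return list with matrices `slope` (radians) and `aspect_dev` (degrees).
#' @export
slope_aspect <- function(dem) {
  z <- dem$elev
  if (!any(is.finite(z))) stop_ps("DEM is all nodata")
  zp <- pad_edges(z)
  nr <- nrow(z); nc <- ncol(z)
  ri <- seq_len(nr) + 1L; ci <- seq_len(nc) + 1L
  a <- zp[ri - 1L, ci - 1L]; b <- zp[ri - 1L, ci]; cc <- zp[ri - 1L, ci + 1L]
  d <- zp[ri,      ci - 1L];                       f <- zp[ri,      ci + 1L]
  g <- zp[ri + 1L, ci - 1L]; h <- zp[ri + 1L, ci]; i <- zp[ri + 1L, ci + 1L]
  cs <- dem$cellsize
  ## p = dz/dx (east), q = dz/dy (north); row index increases southward.
  p <- ((cc + 2 * f + i) - (a + 2 * d + g)) / (8 * cs)
  q <- ((a + 2 * b + cc) - (g + 2 * h + i)) / (8 * cs)
  slope <- atan(sqrt(p^2 + q^2))
  ## Downslope direction is (-p, -q) in (east, north); azimuth from north.
  az <- atan2(-p, -q) * 180 / pi
  aspect_dev <- abs(az)
  aspect_dev[slope == 0] <- 0
  list(slope = slope, aspect_dev = aspect_dev)
}

## D8 receiver index for every cell: the steepest-descent neighbour
## (distance-weighted drop), ties broken by first neighbour in row-major
## order. Flats drain towards the nearest lower ground by breadth-first
## assignment; cells with no resolvable receiver are sinks (receiver 0).
d8_receivers <- function(dem) {
  z <- dem$elev
  nr <- nrow(z); nc <- ncol(z); n <- nr * nc
  cs <- dem$cellsize
  ## neighbour offsets in row-major scan order
  dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  dist <- cs * sqrt(dr^2 + dc^2)
  recv <- integer(n)              # 0 = sink / unresolved
  flat <- logical(n)
  for (col in seq_len(nc)) for (row in seq_len(nr)) {
    k <- row + (col - 1L) * nr
    if (!is.finite(z[k])) next
    best <- 0; best_j <- 0L; has_equal <- FALSE
    for (t in 1:8) {
      r2 <- row + dr[t]; c2 <- col + dc[t]
      if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
      j <- r2 + (c2 - 1L) * nr
      if (!is.finite(z[j])) next
      drop <- (z[k] - z[j]) / dist[t]
      if (drop > best + 1e-15) { best <- drop; best_j <- j }
      else if (z[j] == z[k]) has_equal <- TRUE
    }
    if (best_j > 0L) recv[k] <- best_j
    else if (has_equal) flat[k] <- TRUE
  }
  ## resolve flats: BFS from flat cells that touch resolved/lower ground
  if (any(flat)) {
    queue <- integer(0)
    for (k in which(flat)) {
      row <- ((k - 1L) %% nr) + 1L; col <- ((k - 1L) %/% nr) + 1L
      for (t in 1:8) {
        r2 <- row + dr[t]; c2 <- col + dc[t]
        if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
        j <- r2 + (c2 - 1L) * nr
        if (!is.finite(z[j])) next
        if (z[j] < z[k]) { recv[k] <- j; flat[k] <- FALSE; break }
      }
      if (!flat[k]) queue <- c(queue, k)
    }
    while (length(queue)) {
      k <- queue[1]; queue <- queue[-1]
      row <- ((k - 1L) %% nr) + 1L; col <- ((k - 1L) %/% nr) + 1L
      for (t in 1:8) {
        r2 <- row + dr[t]; c2 <- col + dc[t]
        if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
        j <- r2 + (c2 - 1L) * nr
        if (flat[j] && is.finite(z[j]) && z[j] == z[k]) {
          recv[j] <- k; flat[j] <- FALSE; queue <- c(queue, j)
        }
      }
    }
  }
  recv
}

#' D8 flow accumulation
#'
#' Routes flow to the steepest downslope of the eight neighbours and
#' accumulates source weights downstream. Each cell contributes its own
#' weight times the cell area; the result is expressed per unit contour
#' width (divided by cellsize), i.e. in m^2 per metre, the `A_s` of the
#' wetness index. Uniform unit weights give every cell at least one
#' cell-area of accumulation.
#'
#' @param dem a [dem_grid()].
#' @param source_weights optional non-negative weight matrix (e.g. a probable
#'   water-source raster) of the same shape; default uniform 1.
#' @return matrix of accumulation values (m^2 per unit contour width).
#' @export
flow_accumulation <- function(dem, source_weights = NULL) {
  z <- dem$elev
  nr <- nrow(z); nc <- ncol(z)
  if (is.null(source_weights)) source_weights <- matrix(1, nr, nc)
  if (!all(dim(source_weights) == dim(z)))
    stop_ps("source_weights shape %dx%d does not match DEM %dx%d",
            nrow(source_weights), ncol(source_weights), nr, nc)
  if (any(source_weights < 0, na.rm = TRUE))
    stop_ps("source_weights must be non-negative")
  recv <- d8_receivers(dem)
  acc <- as.vector(source_weights) * dem$cellsize^2
  acc[!is.finite(as.vector(z))] <- 0
  ## Kahn topological pass over the receiver graph (acyclic by construction):
  ## every donor is fully accumulated before it is added to its receiver.
  n <- length(acc)
  indeg <- tabulate(recv[recv > 0L], nbins = n)
  queue <- which(indeg == 0L)
  head <- 1L
  queue <- c(queue, integer(n))   # preallocated ring
  tail <- sum(indeg == 0L)
  while (head <= tail) {
    k <- queue[head]; head <- head + 1L
    j <- recv[k]
    if (j > 0L) {
      acc[j] <- acc[j] + acc[k]
      indeg[j] <- indeg[j] - 1L
      if (indeg[j] == 0L) { tail <- tail + 1L; queue[tail] <- j }
    }
  }
  matrix(acc / dem$cellsize, nr, nc)
}

#' Compound topographic wetness index
#'
#' `CTI = ln(A_s / tan(beta))` where `A_s` is the upslope contributing area
#' per unit contour width (from [flow_accumulation()], optionally weighted by
#' a water-source raster) and `beta` the slope angle in radians. `tan(beta)`
#' is floored to keep the index finite on flat cells.
#'
#' @inheritParams flow_accumulation
#' @param min_tanb floor for `tan(beta)`; default `tan(0.1 degrees)`.
#' @return matrix of CTI values.
#' @export
cti <- function(dem, source_weights = NULL, min_tanb = tan(0.1 * pi / 180)) {
  sa <- slope_aspect(dem)
  acc <- flow_accumulation(dem, source_weights)
  tanb <- pmax(tan(sa$slope), min_tanb)
  log(pmax(acc, .Machine$double.xmin) / tanb)
}

#' Euclidean distance to the coast
#'
#' The coastline is the set of zero-elevation DEM cells; the distance for
#' each query point is the minimum Euclidean distance to any coast cell
#' centre.
#'
#' @param dem a [dem_grid()].
#' @param points matrix or data.frame with columns `x`, `y` (metres).
#' @param tol absolute elevation tolerance for "zero" cells.
#' @return numeric vector of distances (m), one per point.
#' @export
distance_to_coast <- function(dem, points, tol = 1e-9) {
  z <- dem$elev
  coast <- which(abs(z) <= tol)
  if (!length(coast))
    stop_ps("DEM contains no zero-elevation cells: coastline undefined")
  nr <- nrow(z)
  rows <- ((coast - 1L) %% nr) + 1L
  cols <- ((coast - 1L) %/% nr) + 1L
  cc <- dem_coords(dem, rows, cols)
  pts <- as.data.frame(points)
  if (!all(c("x", "y") %in% names(pts))) {
    pts <- data.frame(x = points[, 1], y = points[, 2])
  }
  vapply(seq_len(nrow(pts)), function(i) {
    sqrt(min((cc$x - pts$x[i])^2 + (cc$y - pts$y[i])^2))
  }, numeric(1))
}

#' All terrain covariates in one pass
#'
#' @inheritParams cti
#' @return list of matrices: `slope`, `aspect_dev`, `accumulation`, `cti`,
#'   `dist_coast`.
#' @export
terrain_stack <- function(dem, source_weights = NULL,
                          min_tanb = tan(0.1 * pi / 180)) {
  sa <- slope_aspect(dem)
  acc <- flow_accumulation(dem, source_weights)
  tanb <- pmax(tan(sa$slope), min_tanb)
  cti_g <- log(pmax(acc, .Machine$double.xmin) / tanb)
  cc <- dem_coords(dem)
  dc <- distance_to_coast(dem, cc)
  list(slope = sa$slope, aspect_dev = sa$aspect_dev, accumulation = acc,
       cti = cti_g,
       dist_coast = matrix(dc, nrow(dem$elev), ncol(dem$elev)))
}
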