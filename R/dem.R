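#' Digital elevation model grid
#'
#' A light container for a regular elevation raster. Elevations are stored as
#' a numeric matrix with row 1 at the northern edge; `cellsize` is the cell
#' edge length in metres. Cell-centre coordinates are metres east (`x`) and
#' metres north (`y`), with the lower-left grid corner at
#' (`xll`, `yll`).
#'
#' @param elevations numeric matrix of elevations (m a.s.l.), row 1 = north.
#' @param cellsize cell edge length in metres (> 0).
#' @param xll,yll coordinates of the lower-left corner of the grid (m).
#' @param nodata value marking missing cells (stored as `NA` internally).
#' @return an object of class `dem_grid`.
#' @export
dem_grid <- function(elevations, cellsize, xll = 0, yll = 0, nodata = -9999) {
  if (!is.matrix(elevations) || !is.numeric(elevations))
    stop_ps("elevations must be a numeric matrix")
  if (!is.numeric(cellsize) || length(cellsize) != 1 || cellsize <= 0)
    stop_ps("cellsize must be a single positive number, got %s",
            format(cellsize))
  elevations[elevations == nodata] <- NA_real_
  if (!any(is.finite(elevations)))
    stop_ps("DEM has no finite cells")
  structure(
    list(elev = elevations, cellsize = cellsize, xll = xll, yll = yll,
         nodata = nodata),
    class = "dem_grid")
}

#' @export
print.dem_grid <- function(x, ...) {
  cat(sprintf("<dem_grid> %d x %d cells, cellsize %g m, elev [%g, %g] m\n",
              nrow(x$elev), ncol(x$elev), x$cellsize,
              min(x$elev, na.rm = TRUE), max(x$elev, na.rm = TRUE)))
  invisible(x)
}

#' @export
dim.dem_grid <- function(x) dim(x$elev)

#' Cell-centre coordinates of a DEM grid
#'
#' @param dem a [dem_grid()].
#' @param rows,cols optional 1-based row/column indices (row 1 = north);
#'   defaults to all cells in row-major order.
#' @return data.frame with columns `row`, `col`, `x`, `y`.
#' @export
dem_coords <- function(dem, rows = NULL, cols = NULL) {
  nr <- nrow(dem$elev); nc <- ncol(dem$elev)
  if (is.null(rows)) {
    idx <- expand.grid(row = seq_len(nr), col = seq_len(nc))
    rows <- idx$row; cols <- idx$col
  }
  data.frame(
    row = rows, col = cols,
    x = dem$xll + (cols - 0.5) * dem$cellsize,
    y = dem$yll + (nr - rows + 0.5) * dem$cellsize)
}

#' Read an ESRI ASCII grid
#'
#' @param path file path to an ESRI ASCII (`.asc`) raster.
#' @return a [dem_grid()].
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path, n = 6L)
  hdr <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop_ps("not an ESRI ASCII grid: missing header fields in %s", path)
  vals <- scan(path, skip = 6, quiet = TRUE)
  if (length(vals) != hdr$nrows * hdr$ncols)
    stop_ps("grid body has %d values, expected %d", length(vals),
            hdr$nrows * hdr$ncols)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  xll <- hdr$xllcorner %||% 0
  yll <- hdr$yllcorner %||% 0
  dem_grid(m, hdr$cellsize, xll = xll, yll = yll,
           nodata = hdr$nodata_value %||% -9999)
}

#' Write an ESRI ASCII grid
#'
#' @param x a [dem_grid()] or a numeric matrix (row 1 = north).
#' @param path output file path.
#' @param cellsize,xll,yll grid registration, ignored when `x` is a
#'   [dem_grid()].
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(x, path, cellsize = 1, xll = 0, yll = 0) {
  if (inherits(x, "dem_grid")) {
    m <- x$elev; cellsize <- x$cellsize; xll <- x$xll; yll <- x$yll
    nodata <- x$nodata
  } else {
    m <- x; nodata <- -9999
  }
  m[!is.finite(m)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10g", xll),
    sprintf("yllcorner %.10g", yll),
    sprintf("cellsize %.10g", cellsize),
    sprintf("NODATA_value %g", nodata)), con)
  utils::write.table(format(m, trim = TRUE, digits = 10), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
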