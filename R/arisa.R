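## ARISA fingerprint processing: true-peak calling, richness, fragment
## binning across samples.

#' ARISA electropherogram
#'
#' A per-sample peak list from automated ribosomal intergenic spacer
#' analysis: fragment sizes in base pairs (possibly fractional, as sized
#' against a ladder) and peak heights in relative fluorescence units.
#'
#' @param sample_id sample identifier.
#' @param size numeric vector of fragment sizes (bp), strictly increasing.
#' @param rfu numeric vector of peak heights (RFU), non-negative.
#' @return object of class `electropherogram`.
#' @export
electropherogram <- function(sample_id, size, rfu) {
  size <- as.numeric(size); rfu <- as.numeric(rfu)
  if (length(size) != length(rfu))
    stop_ps("size and rfu lengths differ (%d vs %d)", length(size), length(rfu))
  if (any(size < 0)) stop_ps("negative fragment sizes are invalid")
  if (any(rfu < 0)) stop_ps("negative fluorescence values are invalid")
  if (length(size) > 1 && is.unsorted(size, strictly = TRUE)) {
    o <- order(size)
    size <- size[o]; rfu <- rfu[o]
  }
  if (anyDuplicated(size)) stop_ps("duplicate fragment sizes in profile")
  structure(list(sample_id = as.character(sample_id),
                 peaks = data.frame(size = size, rfu = rfu)),
            class = "electropherogram")
}

## Size windows (bp) per fingerprinted group. The total-bacterial window is
## not separately documented; the cyanobacterial window is assumed
## (config-exposed via the `window` argument of call_true_peaks).
arisa_windows <- function() {
  list(cyanobacteria = c(100, 1200),
       fungi = c(100, 1400),
       bacteria_total = c(100, 1200))
}

#' Call true peaks from an electropherogram
#'
#' A peak is accepted as a true peak when (i) its size lies inside the
#' group's window (inclusive bounds; 100-1200 bp for cyanobacteria and total
#' bacteria, 100-1400 bp for fungi), (ii) its height exceeds 30 RFU
#' (strict), and (iii) its height exceeds 0.3% of the summed height of all
#' peaks over 30 RFU in that electropherogram. The denominator convention
#' follows standard ARISA practice (fluorescence proportion); set
#' `relative_to = "count"` to read the relative rule against the peak count
#' instead.
#'
#' @param profile an [electropherogram()].
#' @param group one of `"cyanobacteria"`, `"fungi"`, `"bacteria_total"`.
#' @param window optional numeric length-2 override of the size window (bp).
#' @param rfu_floor minimum height (exclusive), default 30 RFU.
#' @param rel_threshold relative threshold (exclusive), default 0.003.
#' @param relative_to denominator for the relative rule: `"fluorescence"`
#'   (default, summed RFU of peaks over the floor) or `"count"`.
#' @return a `peak_table`: data.frame of accepted peaks with columns
#'   `size`, `rfu`, `relative_fluorescence`, plus attributes `sample_id`
#'   and `group`.
#' @export
call_true_peaks <- function(profile, group = c("cyanobacteria", "fungi",
                                               "bacteria_total"),
                            window = NULL, rfu_floor = 30,
                            rel_threshold = 0.003,
                            relative_to = c("fluorescence", "count")) {
  group <- match.arg(group)
  relative_to <- match.arg(relative_to)
  if (!inherits(profile, "electropherogram"))
    stop_ps("profile must be an electropherogram")
  if (is.null(window)) window <- arisa_windows()[[group]]
  pk <- profile$peaks
  over_floor <- pk$rfu > rfu_floor
  denom <- if (relative_to == "fluorescence") sum(pk$rfu[over_floor])
           else sum(over_floor)
  rel <- if (denom > 0) pk$rfu / denom else rep(0, nrow(pk))
  keep <- pk$size >= window[1] & pk$size <= window[2] &
    over_floor & rel > rel_threshold
  out <- data.frame(size = pk$size[keep], rfu = pk$rfu[keep],
                    relative_fluorescence = rel[keep])
  structure(out, sample_id = profile$sample_id, group = group,
            class = c("peak_table", "data.frame"))
}

#' Taxon richness of a peak table
#'
#' The number of accepted true peaks, used as the richness estimate for the
#' fingerprinted community.
#'
#' @param table a `peak_table` from [call_true_peaks()].
#' @return integer count.
#' @export
arisa_richness <- function(table) {
  if (!inherits(table, "peak_table"))
    stop_ps("table must be a peak_table from call_true_peaks()")
  nrow(table)
}

#' Bin accepted peaks across samples
#'
#' Pools accepted fragment sizes over all samples and merges peaks within
#' one base pair of one another by single-linkage clustering (sorted sizes
#' are chained while consecutive gaps are <= the linkage threshold). Returns
#' the bin map and a sites x bins community matrix whose entries are summed
#' relative fluorescence (use `m > 0` for the incidence view).
#'
#' @param tables list of `peak_table` objects of the same group.
#' @param linkage merge threshold in bp, default 1.
#' @return list with `bins` (data.frame `bin_id`, `low`, `high`) and
#'   `matrix` (sites x bins, summed relative fluorescence).
#' @export
bin_peaks <- function(tables, linkage = 1) {
  if (!length(tables)) stop_ps("no peak tables supplied")
  groups <- unique(vapply(tables, attr, "", "group"))
  if (length(groups) != 1)
    stop_ps("peak tables mix groups: %s", paste(groups, collapse = ", "))
  ids <- vapply(tables, attr, "", "sample_id")
  pooled <- do.call(rbind, lapply(seq_along(tables), function(i) {
    t <- tables[[i]]
    if (!nrow(t)) return(NULL)
    data.frame(sample = rep(ids[i], nrow(t)), size = t$size,
               rel = t$relative_fluorescence, row.names = NULL)
  }))
  if (is.null(pooled) || !nrow(pooled)) {
    return(list(bins = data.frame(bin_id = integer(), low = numeric(),
                                  high = numeric()),
                matrix = matrix(0, length(ids), 0,
                                dimnames = list(ids, NULL))))
  }
  o <- order(pooled$size)
  s <- pooled$size[o]
  new_bin <- c(TRUE, diff(s) > linkage)
  bin_of_sorted <- cumsum(new_bin)
  bin <- integer(nrow(pooled))
  bin[o] <- bin_of_sorted
  nb <- max(bin)
  bins <- data.frame(
    bin_id = seq_len(nb),
    low = vapply(seq_len(nb), function(b) min(pooled$size[bin == b]), 0),
    high = vapply(seq_len(nb), function(b) max(pooled$size[bin == b]), 0))
  m <- matrix(0, nrow = length(ids), ncol = nb,
              dimnames = list(ids, sprintf("bin%03d", seq_len(nb))))
  for (k in seq_len(nrow(pooled))) {
    i <- match(pooled$sample[k], ids)
    m[i, bin[k]] <- m[i, bin[k]] + pooled$rel[k]
  }
  list(bins = bins, matrix = m)
}

#' Read peak-scanner style CSV exports
#'
#' Expects columns `sample_id`, `size_bp`, `rfu`; returns one
#' [electropherogram()] per sample.
#'
#' @param path CSV file path.
#' @return named list of electropherograms.
#' @export
read_peak_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("sample_id", "size_bp", "rfu")
  if (!all(need %in% names(d)))
    stop_ps("%s must have columns %s", path, paste(need, collapse = ", "))
  lapply(split(d, d$sample_id), function(s) {
    s <- s[order(s$size_bp), ]
    electropherogram(s$sample_id[1], s$size_bp, s$rfu)
  })
}
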