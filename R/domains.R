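#' Ordered sets of TAD-like domains
#'
#' A `DomainSet` is an ordered list of non-overlapping half-open bin
#' intervals `[start_bin, end_bin)` on one chromosome. Bin indices are
#' 0-based, so the genomic span of a domain is
#' `[start_bin * binsize, end_bin * binsize)`. Bins covered by no domain
#' form the gaps ("intermediate windows"). A boundary bin is the first bin
#' of a domain other than the chromosome start.
#'
#' @param starts,ends Integer vectors of domain start/end bins (0-based,
#'   half-open).
#' @param n_bins Total number of bins on the chromosome.
#' @param chrom Chromosome name.
#' @param binsize Bin size in base pairs.
#' @return An object of class `DomainSet`.
#' @examples
#' d <- domain_set(c(0, 5), c(5, 10), n_bins = 12)
#' boundaries(d)
#' @export
domain_set <- function(starts, ends, n_bins, chrom = "chr1",
                       binsize = 40000L) {
  starts <- as.integer(starts); ends <- as.integer(ends)
  stopifnot(length(starts) == length(ends))
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  if (any(ends <= starts)) stopf("empty domain")
  if (length(starts) > 1 && any(starts[-1] < ends[-length(ends)]))
    stopf("domains overlap")
  if (length(starts) && (min(starts) < 0 || max(ends) > n_bins))
    stopf("domain outside [0, n_bins)")
  structure(list(chrom = chrom, binsize = as.integer(binsize),
                 n_bins = as.integer(n_bins),
                 starts = starts, ends = ends),
            class = "DomainSet")
}

#' @export
print.DomainSet <- function(x, ...) {
  cat(sprintf("DomainSet: %s, %d domains over %d bins @ %d bp (%d gap bins)\n",
              x$chrom, length(x$starts), x$n_bins, x$binsize,
              x$n_bins - sum(x$ends - x$starts)))
  invisible(x)
}

#' @export
length.DomainSet <- function(x) length(x$starts)

#' Boundary bins of a DomainSet
#'
#' Domain start bins, excluding a domain that starts at the chromosome
#' start (bin 0 marks no transition).
#'
#' @param d A `DomainSet`.
#' @return Sorted integer vector of 0-based boundary bins.
#' @export
boundaries <- function(d) {
  b <- d$starts
  b[b > 0]
}

#' Build a DomainSet from boundary bins
#'
#' Partitions `[0, n_bins)` at the given boundary bins; each boundary is
#' the first bin of the downstream domain. Gap intervals (e.g. no-call
#' regions) can be punched out afterwards with `gaps`.
#'
#' @param bounds 0-based boundary bins.
#' @param n_bins Total number of bins.
#' @param chrom,binsize Passed to [domain_set()].
#' @param gaps Optional two-column matrix of half-open `[start, end)` bin
#'   intervals to exclude from every domain.
#' @return A `DomainSet`.
#' @export
domains_from_boundaries <- function(bounds, n_bins, chrom = "chr1",
                                    binsize = 40000L, gaps = NULL) {
  bounds <- sort(unique(as.integer(bounds)))
  bounds <- bounds[bounds > 0 & bounds < n_bins]
  cuts <- c(0L, bounds, n_bins)
  starts <- cuts[-length(cuts)]
  ends <- cuts[-1]
  if (!is.null(gaps) && nrow(gaps) > 0) {
    covered <- rep(TRUE, n_bins)
    for (g in seq_len(nrow(gaps))) {
      lo <- max(0L, gaps[g, 1]); hi <- min(n_bins, gaps[g, 2])
      if (hi > lo) covered[(lo + 1):hi] <- FALSE
    }
    # re-derive maximal covered runs within each domain
    ns <- integer(0); ne <- integer(0)
    for (k in seq_along(starts)) {
      bins <- starts[k]:(ends[k] - 1L)
      ok <- covered[bins + 1L]
      if (!any(ok)) next
      r <- rle(ok)
      pos <- cumsum(c(0L, r$lengths))
      for (j in seq_along(r$values)) {
        if (r$values[j]) {
          ns <- c(ns, starts[k] + pos[j])
          ne <- c(ne, starts[k] + pos[j + 1])
        }
      }
    }
    starts <- ns; ends <- ne
  }
  domain_set(starts, ends, n_bins, chrom, binsize)
}

#' Gap intervals of a DomainSet
#' @param d A `DomainSet`.
#' @return Two-column matrix of half-open `[start, end)` gap intervals.
#' @export
domain_gaps <- function(d) {
  covered <- rep(FALSE, d$n_bins)
  for (k in seq_along(d$starts))
    covered[(d$starts[k] + 1):d$ends[k]] <- TRUE
  r <- rle(covered)
  pos <- cumsum(c(0L, r$lengths))
  idx <- which(!r$values)
  cbind(start = pos[idx], end = pos[idx + 1])
}

#' Per-bin partition labels of a DomainSet
#'
#' Converts domains to an integer label per bin. Gap bins are labelled
#' either per contiguous gap (`gap_mode = "per_gap"`, the default: each
#' intermediate window is its own cluster) or as one shared cluster
#' (`"single"`), or dropped (`"exclude"`, returning `NA` there).
#'
#' @param d A `DomainSet`.
#' @param gap_mode `"per_gap"`, `"single"`, or `"exclude"`.
#' @return Integer vector of length `n_bins` (element `i` labels bin
#'   `i - 1`); `NA` for excluded gap bins.
#' @export
domain_labels <- function(d, gap_mode = c("per_gap", "single", "exclude")) {
  gap_mode <- match.arg(gap_mode)
  lab <- rep(NA_integer_, d$n_bins)
  for (k in seq_along(d$starts))
    lab[(d$starts[k] + 1):d$ends[k]] <- k
  if (gap_mode != "exclude" && anyNA(lab)) {
    g <- domain_gaps(d)
    for (k in seq_len(nrow(g))) {
      id <- if (gap_mode == "per_gap") length(d$starts) + k
            else length(d$starts) + 1L
      lab[(g[k, 1] + 1):g[k, 2]] <- id
    }
  }
  # contiguous ids
  keep <- !is.na(lab)
  lab[keep] <- as.integer(factor(lab[keep]))
  lab
}

#' Write a DomainSet as BED
#'
#' One BED3 row per domain, 0-based half-open genomic coordinates
#' (`start_bin * binsize`, `end_bin * binsize`).
#'
#' @param d A `DomainSet`.
#' @param path Output path.
#' @export
write_domains_bed <- function(d, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = rep(d$chrom, length(d$starts)),
    ranges = IRanges::IRanges(start = d$starts * d$binsize + 1,
                              end = d$ends * d$binsize))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a DomainSet from BED
#'
#' @param path BED file of domain intervals.
#' @param binsize Bin size in base pairs; intervals must align to it.
#' @param n_bins Total number of bins; defaults to the last domain end.
#' @param chrom Chromosome to keep (default: first seqname in the file).
#' @return A `DomainSet`.
#' @export
read_domains_bed <- function(path, binsize = 40000L, n_bins = NULL,
                             chrom = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  if (length(gr) == 0) {
    if (is.null(n_bins)) stopf("empty BED and no n_bins given")
    return(domain_set(integer(0), integer(0), n_bins,
                      chrom = chrom %||% "chr1", binsize = binsize))
  }
  if (is.null(chrom)) chrom <- as.character(GenomicRanges::seqnames(gr)[1])
  gr <- gr[GenomicRanges::seqnames(gr) == chrom]
  s <- GenomicRanges::start(gr) - 1L
  e <- GenomicRanges::end(gr)
  if (any(s %% binsize != 0) || any(e %% binsize != 0))
    stopf("BED intervals not aligned to binsize %d", binsize)
  starts <- s %/% binsize
  ends <- e %/% binsize
  if (is.null(n_bins)) n_bins <- max(ends)
  domain_set(starts, ends, n_bins, chrom = chrom, binsize = binsize)
}

#' Read peak intervals from BED or narrowPeak
#'
#' @param path BED or ENCODE narrowPeak file.
#' @return A `GRanges` of peaks.
#' @export
read_peaks <- function(path) {
  if (grepl("\\.narrowPeak$", path, ignore.case = TRUE)) {
    rtracklayer::import(path, format = "BED",
      extraCols = c(signalValue = "numeric", pValue = "numeric",
                    qValue = "numeric", peak = "integer"))
  } else {
    rtracklayer::import(path, format = "BED")
  }
}
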