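#' Classify ensemble domains by their fate in a single cell
#'
#' Compares each ensemble domain against a cell's domain set using
#' boundary regions of +/- `flank_bp` around boundary bins (boundaries
#' align when their genomic positions differ by at most `flank_bp`).
#' Classes:
#' \itemize{
#'   \item `matched`: both domain boundaries align to cell boundaries;
#'   \item `merged`: the domain lies inside one cell domain together with
#'     at least one other ensemble domain (its internal boundary is lost);
#'   \item `split`: one boundary aligns, the other falls strictly inside a
#'     cell domain;
#'   \item `shifted`: the two boundaries fall strictly inside two
#'     different cell domains;
#'   \item `other`: none of the rules apply (e.g. a boundary in a gap).
#' }
#'
#' @param ensemble,cell `DomainSet`s on the same chromosome and binning.
#' @param flank_bp Boundary-region half width in base pairs
#'   (default 1e5).
#' @return Character vector, one class per ensemble domain.
#' @export
classify_variation <- function(ensemble, cell, flank_bp = 1e5) {
  stopifnot(inherits(ensemble, "DomainSet"), inherits(cell, "DomainSet"))
  if (ensemble$binsize != cell$binsize || ensemble$n_bins != cell$n_bins)
    stopf("domain sets on different binnings")
  if (length(ensemble$starts) == 0 || length(cell$starts) == 0)
    stopf("empty domain set")
  bs <- ensemble$binsize
  tol <- flank_bp / bs
  cb <- unique(c(cell$starts, cell$ends))        # cell boundary bins
  aligns <- function(b) any(abs(b - cb) <= tol)
  # index of the cell domain strictly containing bin position b (boundary
  # coordinate), NA if none or if b aligns to a cell boundary region
  inside_of <- function(b) {
    if (aligns(b)) return(NA_integer_)
    hit <- which(cell$starts < b & b < cell$ends)
    if (length(hit)) hit[1] else NA_integer_
  }
  ns <- length(ensemble$starts)
  # which cell domain fully contains an ensemble domain (for merges)
  container <- vapply(seq_len(ns), function(k) {
    hit <- which(cell$starts <= ensemble$starts[k] &
                 ensemble$ends[k] <= cell$ends)
    if (length(hit)) hit[1] else NA_integer_
  }, integer(1))
  container_count <- table(container[!is.na(container)])
  vapply(seq_len(ns), function(k) {
    b1 <- ensemble$starts[k]; b2 <- ensemble$ends[k]
    a1 <- aligns(b1); a2 <- aligns(b2)
    if (a1 && a2) return("matched")
    cont <- container[k]
    if (!is.na(cont) && container_count[as.character(cont)] >= 2)
      return("merged")
    in1 <- inside_of(b1); in2 <- inside_of(b2)
    if ((a1 && !is.na(in2)) || (a2 && !is.na(in1))) return("split")
    if (!is.na(in1) && !is.na(in2) && in1 != in2) return("shifted")
    "other"
  }, character(1))
}

#' Build a boundary catalog from per-cell domain sets
#'
#' @param cell_domains List of `DomainSet`s (one per cell) on the same
#'   binning.
#' @return Object of class `BoundaryCatalog`: list with `n_bins`,
#'   `n_cells`, `per_cell` (list of 0-based boundary-bin vectors) and
#'   `counts` (per-bin number of carrying cells).
#' @export
boundary_catalog <- function(cell_domains) {
  stopifnot(length(cell_domains) >= 1)
  n <- cell_domains[[1]]$n_bins
  per_cell <- lapply(cell_domains, boundaries)
  counts <- integer(n)
  for (b in per_cell) counts[b + 1L] <- counts[b + 1L] + 1L
  structure(list(n_bins = n, n_cells = length(cell_domains),
                 per_cell = per_cell, counts = counts),
            class = "BoundaryCatalog")
}

#' Over- and under-represented boundaries in a cell population
#'
#' Models the number of cells carrying a given boundary as binomial
#' `B(n_cells, p_hat)` with `p_hat` the mean per-cell occurrence
#' frequency of the catalog's boundaries. Boundaries carried by more than
#' `hi` cells are "popular", by fewer than `lo` cells "unpopular"
#' (defaults 12 and 6, the conventional thresholds for a 150-cell
#' population). A Monte-Carlo p-value tests whether the observed number
#' of tail boundaries deviates from the binomial null.
#'
#' @param catalog A `BoundaryCatalog`.
#' @param hi,lo Popularity thresholds (counts strictly above `hi` /
#'   strictly below `lo`).
#' @param n_sim Monte-Carlo draws (default 10,000).
#' @param seed Optional seed.
#' @return List with `popular` and `unpopular` 0-based bins, `p_hat`, the
#'   observed tail count `observed`, and `p_value`.
#' @export
boundary_popularity <- function(catalog, hi = 12L, lo = 6L, n_sim = 10000L,
                                seed = NULL) {
  stopifnot(inherits(catalog, "BoundaryCatalog"), catalog$n_cells >= 2)
  occ <- catalog$counts[catalog$counts > 0]
  m <- length(occ)
  p_hat <- mean(occ) / catalog$n_cells
  obs <- sum(occ > hi) + sum(occ < lo)
  null <- with_seed(seed, {
    vapply(seq_len(n_sim), function(r) {
      x <- stats::rbinom(m, catalog$n_cells, p_hat)
      sum(x > hi) + sum(x < lo)
    }, numeric(1))
  })
  list(popular = which(catalog$counts > hi) - 1L,
       unpopular = which(catalog$counts > 0 & catalog$counts < lo) - 1L,
       p_hat = p_hat, observed = obs,
       p_value = (1 + sum(null >= obs)) / (n_sim + 1))
}

#' Classify single-cell-specific boundaries (scSB)
#'
#' A cell boundary is an scSB when its bin is not an ensemble boundary bin
#' (same-bin identity; a +/- `tol_bins` tolerant mode can be enabled).
#' scSBs are grouped by the number of carrying cells into `scSB-1`,
#' `scSB-2`, and `scSB-m` (> 2); mappable bins never used as a boundary in
#' any cell are `absent`. A permutation control repositions each cell's
#' boundaries uniformly over mappable bins (preserving per-cell counts)
#' and re-tabulates the classes.
#'
#' @param catalog A `BoundaryCatalog`.
#' @param ensemble_bounds 0-based ensemble boundary bins.
#' @param mappable Logical vector of mappable bins (default: all).
#' @param tol_bins Boundary-identity tolerance in bins (default 0).
#' @param n_perm Permutation replicates for the control (default 100).
#' @param seed Optional seed.
#' @return List with `classes` (named counts), `bins` (list of 0-based
#'   bins per class), and `control` (n_perm x 4 matrix of permuted
#'   counts).
#' @export
classify_scsb <- function(catalog, ensemble_bounds, mappable = NULL,
                          tol_bins = 0L, n_perm = 100L, seed = NULL) {
  stopifnot(inherits(catalog, "BoundaryCatalog"))
  n <- catalog$n_bins
  mappable <- mappable %||% rep(TRUE, n)
  ens <- sort(unique(as.integer(ensemble_bounds)))
  is_sc <- function(b) {
    if (length(ens) == 0) return(rep(TRUE, length(b)))
    vapply(b, function(x) min(abs(x - ens)) > tol_bins, logical(1))
  }
  tab_classes <- function(per_cell) {
    counts <- integer(n)
    for (b in per_cell) {
      sc <- b[is_sc(b)]
      counts[sc + 1L] <- counts[sc + 1L] + 1L
    }
    used <- integer(n)
    for (b in per_cell) used[b + 1L] <- used[b + 1L] + 1L
    c(`scSB-1` = sum(counts == 1), `scSB-2` = sum(counts == 2),
      `scSB-m` = sum(counts > 2),
      absent = sum(mappable & used == 0))
  }
  obs <- tab_classes(catalog$per_cell)
  counts <- integer(n)
  for (b in catalog$per_cell) {
    sc <- b[is_sc(b)]
    counts[sc + 1L] <- counts[sc + 1L] + 1L
  }
  used <- integer(n)
  for (b in catalog$per_cell) used[b + 1L] <- used[b + 1L] + 1L
  bins <- list(`scSB-1` = which(counts == 1) - 1L,
               `scSB-2` = which(counts == 2) - 1L,
               `scSB-m` = which(counts > 2) - 1L,
               absent = which(mappable & used == 0) - 1L)
  pool <- which(mappable) - 1L
  control <- with_seed(seed, {
    t(vapply(seq_len(n_perm), function(r) {
      perm <- lapply(catalog$per_cell, function(b)
        sample(pool, min(length(b), length(pool)), replace = FALSE))
      tab_classes(perm)
    }, numeric(4)))
  })
  list(classes = obs, bins = bins, control = control)
}

#' Nested and unnested ensemble boundaries
#'
#' Ranks boundaries by the contact count between their upstream and
#' downstream `flank_bp` regions (cross-boundary contacts). The `n_drop`
#' lowest-ranked boundaries are removed first (they typically sit in
#' unmappable regions); of the rest, the `n_top` highest are "nested" and
#' the `n_top` lowest "unnested".
#'
#' @param ensemble A `DomainSet`.
#' @param m A `ContactMatrix`.
#' @param n_top Number of boundaries per class (default 20).
#' @param n_drop Boundaries discarded from the bottom first (default 20).
#' @param flank_bp Cross-boundary region span (default 4e5).
#' @return List with 0-based `nested` and `unnested` bins and the full
#'   ranking table `cross` (bin, cross_contacts).
#' @export
nested_unnested <- function(ensemble, m, n_top = 20L, n_drop = 20L,
                            flank_bp = 4e5) {
  stopifnot(inherits(ensemble, "DomainSet"), inherits(m, "ContactMatrix"))
  fb <- as.integer(round(flank_bp / m$binsize))
  if (fb < 1) stopf("flank smaller than one bin")
  b <- boundaries(ensemble)
  if (length(b) < 2 * n_top + n_drop)
    stopf("need at least %d boundaries, have %d", 2 * n_top + n_drop,
          length(b))
  n <- n_bins(m)
  cross <- vapply(b, function(bb) {
    up <- max(0L, bb - fb):(bb - 1L)
    dn <- bb:min(n - 1L, bb + fb - 1L)
    up <- up[up >= 0]; dn <- dn[dn < n]
    if (length(up) == 0 || length(dn) == 0) return(0)
    sum(m$counts[up + 1L, dn + 1L])
  }, numeric(1))
  o <- order(cross)
  keep <- o[-seq_len(n_drop)]
  ranked <- keep[order(cross[keep], decreasing = TRUE)]
  list(nested = sort(b[ranked[seq_len(n_top)]]),
       unnested = sort(b[ranked[(length(ranked) - n_top + 1):length(ranked)]]),
       cross = data.frame(bin = b, cross_contacts = cross))
}

#' Condition-specific boundary bins between two cell groups
#'
#' The bias of a bin is the difference between the fractions of group-A
#' and group-B cells whose domain calls place a boundary there. The
#' `n_select` most A-biased bins are A-specific, the `n_select` most
#' B-biased are B-specific.
#'
#' @param catalog_a,catalog_b `BoundaryCatalog`s of the two groups on the
#'   same binning.
#' @param n_select Bins per condition (default 400).
#' @return List with 0-based `a_specific` and `b_specific` bins and the
#'   per-bin `bias` vector.
#' @export
condition_specific_boundaries <- function(catalog_a, catalog_b,
                                          n_select = 400L) {
  stopifnot(catalog_a$n_bins == catalog_b$n_bins)
  bias <- catalog_a$counts / catalog_a$n_cells -
    catalog_b$counts / catalog_b$n_cells
  if (all(bias == 0)) {
    warnf("biases all zero: no condition-specific boundaries")
    return(list(a_specific = integer(0), b_specific = integer(0),
                bias = bias))
  }
  n_select <- min(n_select, floor(catalog_a$n_bins / 2))
  o <- order(bias, decreasing = TRUE)
  a_spec <- o[seq_len(n_select)]
  b_spec <- rev(o)[seq_len(n_select)]
  if (length(intersect(a_spec, b_spec)) > 0)
    stopf("top and bottom selections overlap: genome too small for n_select")
  list(a_specific = sort(a_spec - 1L), b_specific = sort(b_spec - 1L),
       bias = bias)
}

#' Compartment-domain boundaries
#'
#' Boundaries whose two flanking bins (last upstream bin and first
#' downstream bin) carry compartment scores of opposite sign. Boundaries
#' with a missing score at either flank are skipped with a warning.
#'
#' @param ensemble A `DomainSet`.
#' @param score Per-bin compartment score (length `n_bins`; `NA` allowed).
#' @return 0-based boundary bins at compartment sign flips.
#' @export
compartment_domain_boundaries <- function(ensemble, score) {
  stopifnot(inherits(ensemble, "DomainSet"),
            length(score) == ensemble$n_bins)
  b <- boundaries(ensemble)
  b <- b[b >= 1 & b < ensemble$n_bins]
  up <- score[b]        # bin b-1 (1-based index b)
  dn <- score[b + 1L]   # bin b
  miss <- is.na(up) | is.na(dn)
  if (any(miss))
    warnf("%d boundaries skipped for missing compartment score", sum(miss))
  b[!miss & sign(up) * sign(dn) < 0]
}
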