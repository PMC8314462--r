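#' Sliding windows over a chromosome
#'
#' Tiles the chromosome with windows of length `L` base pairs overlapping
#' by `L/2`. Each window carries a *report interval*: the middle half
#' `[start + L/4, start + 3L/4)`, extended so the first window reports
#' from the chromosome start, the last to the chromosome end, and
#' consecutive report intervals tile the chromosome exactly once. Windows
#' with fewer than `min_contacts` intra-window contacts are flagged
#' no-call. A chromosome shorter than `L` yields a single whole-chromosome
#' window.
#'
#' @param m A `ContactMatrix`.
#' @param L Window length in base pairs (default 8e6); must be a multiple
#'   of `2 * binsize`.
#' @param min_contacts Minimum intra-window contact count (default 100).
#' @return Data frame with 0-based bin columns `start`, `end`,
#'   `report_start`, `report_end`, plus `contacts` and `no_call`.
#' @export
make_windows <- function(m, L = 8e6, min_contacts = 100) {
  n <- n_bins(m)
  wl <- as.integer(round(L / m$binsize))
  if (L %% (2 * m$binsize) != 0)
    stopf("window length must be a multiple of 2 * binsize")
  if (wl >= n) {
    starts <- 0L; wl <- n
  } else {
    stride <- wl %/% 2L
    starts <- seq.int(0L, n - wl, by = stride)
    if (starts[length(starts)] + wl < n) starts <- c(starts, n - wl)
  }
  ends <- pmin.int(starts + wl, n)
  k <- length(starts)
  rs <- starts + wl %/% 4L
  re <- starts + (3L * wl) %/% 4L
  rs[1] <- 0L
  re[k] <- n
  if (k > 1) rs[2:k] <- re[1:(k - 1)]  # seamless tiling
  contacts <- vapply(seq_len(k), function(t) {
    idx <- (starts[t] + 1):ends[t]
    sub <- m$counts[idx, idx]
    sum(sub[upper.tri(sub, diag = TRUE)])
  }, numeric(1))
  data.frame(start = starts, end = ends,
             report_start = rs, report_end = re,
             contacts = contacts, no_call = contacts < min_contacts)
}

#' Consensus co-clustering map over repeated NMF runs
#'
#' Runs [nmf_cluster_once()] `k` times with seeds `seed_base + 0 .. k-1`
#' and records, for each bin pair, the fraction of runs in which the two
#' bins received the same label.
#'
#' @param sub Non-negative symmetric contact submatrix.
#' @param n_components Factorization rank.
#' @param k Number of runs (default 10).
#' @param seed_base First seed; runs use consecutive seeds (default 0).
#' @inheritParams nmf_fit
#' @return Symmetric matrix `C` with entries in `[0, 1]` and unit
#'   diagonal.
#' @export
consensus_map <- function(sub, n_components, k = 10L, seed_base = 0L,
                          max_iter = 200L, tol = 1e-4) {
  stopifnot(k >= 1)
  n <- nrow(sub)
  cmap <- matrix(0, n, n)
  for (s in seq_len(k) - 1L) {
    lab <- nmf_cluster_once(sub, n_components, seed = seed_base + s,
                            max_iter = max_iter, tol = tol)
    cmap <- cmap + outer(lab, lab, "==")
  }
  cmap / k
}

#' Cluster-rate profile of a consensus map
#'
#' The cluster rate of bin `i` is the mean of the consensus map over a
#' `w x w` diagonal square at bin `i`, truncated at the window edges. With
#' the default `"center"` anchoring the square spans bins
#' `[i - ceiling(w/2), i + floor(w/2) - 1]`, so bin `i` is the first bin of
#' the downstream half and a dip in the profile indexes the first bin of a
#' downstream domain. `"corner"` places the top-left corner of the square
#' at `(i, i)` (a variant retained for sensitivity checks; it dips about
#' `ceiling(w/2)` bins upstream of a domain junction).
#'
#' @param cmap Consensus map from [consensus_map()].
#' @param w Side of the diagonal square in bins (default 11).
#' @param anchor `"center"` (default) or `"corner"`.
#' @return Numeric cluster-rate profile, one value per bin.
#' @export
cluster_rate_profile <- function(cmap, w = 11L, anchor = c("center", "corner")) {
  anchor <- match.arg(anchor)
  n <- nrow(cmap)
  stopifnot(w >= 1)
  off_lo <- if (anchor == "center") -as.integer(ceiling(w / 2)) else 0L
  off_hi <- off_lo + as.integer(w) - 1L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i + off_lo)
    hi <- min(n, i + off_hi)
    mean(cmap[lo:hi, lo:hi])
  }, numeric(1))
}

#' Local minima of a cluster-rate profile
#'
#' Bin `i` (1-based) is a local minimum when
#' `sum(CR[i..i+2]) - sum(CR[i-3..i-1]) < 0 <= sum(CR[i+1..i+3]) - sum(CR[i-2..i])`,
#' i.e. the smoothed profile switches from falling to rising at `i`. The
#' strength of a minimum is the largest CR value between its neighbouring
#' minima (sentinels: first and last bin of the profile) minus its own CR.
#'
#' @param cr Cluster-rate profile (length >= 7).
#' @return Data frame with columns `bin` (1-based, window-local) and
#'   `strength`, ordered by position.
#' @export
find_local_minima <- function(cr) {
  n <- length(cr)
  if (n < 7) return(data.frame(bin = integer(0), strength = numeric(0)))
  idx <- 4:(n - 3)
  left <- vapply(idx, function(i)
    sum(cr[i:(i + 2)]) - sum(cr[(i - 3):(i - 1)]), numeric(1))
  right <- vapply(idx, function(i)
    sum(cr[(i + 1):(i + 3)]) - sum(cr[(i - 2):i]), numeric(1))
  mins <- idx[left < 0 & right >= 0]
  m <- length(mins)
  if (m == 0) return(data.frame(bin = integer(0), strength = numeric(0)))
  anchors <- c(1L, mins, n)
  strength <- vapply(seq_len(m), function(t)
    max(cr[anchors[t]:anchors[t + 2]]) - cr[mins[t]], numeric(1))
  data.frame(bin = mins, strength = strength)
}

#' Select boundary calls from cluster-rate minima
#'
#' Keeps the union of the `n_components - 1` strongest minima (rank calls)
#' and every minimum with strength above `strength_cutoff` (threshold
#' calls). With fewer minima than requested, all are kept.
#'
#' @param minima Data frame from [find_local_minima()].
#' @param n_components The factorization rank whose boundaries are sought.
#' @param strength_cutoff Strength threshold (default 0.3).
#' @return `minima` subset ordered by position, with a `source` column
#'   (`"rank"` or `"threshold"` for calls admitted only by the cutoff).
#' @export
select_boundaries <- function(minima, n_components, strength_cutoff = 0.3) {
  if (nrow(minima) == 0) return(cbind(minima, source = character(0)))
  o <- order(-minima$strength, minima$bin)
  n_rank <- min(nrow(minima), max(0L, n_components - 1L))
  rank_rows <- o[seq_len(n_rank)]
  thr_rows <- which(minima$strength > strength_cutoff)
  keep <- sort(union(rank_rows, thr_rows))
  out <- minima[keep, , drop = FALSE]
  out$source <- ifelse(keep %in% rank_rows, "rank", "threshold")
  rownames(out) <- NULL
  out
}

#' Silhouette score of a boundary partition on a consensus map
#'
#' Evaluates, on the dissimilarity `D = 1 - C`, the mean silhouette of the
#' window bins under the segmentation induced by the boundaries: for each
#' bin the between-segment mean dissimilarity minus the within-segment
#' mean, over their maximum, summed and divided by the window length. A
#' bin whose segment is the whole window (no between set) contributes 0.
#'
#' @param cmap Consensus map.
#' @param bounds 1-based window-local boundary bins (each the first bin of
#'   its downstream segment).
#' @return Silhouette score in `[-1, 1]`.
#' @export
silhouette_for_partition <- function(cmap, bounds) {
  n <- nrow(cmap)
  d <- 1 - cmap
  cuts <- c(1L, sort(unique(as.integer(bounds))), n + 1L)
  total <- 0
  for (k in seq_len(length(cuts) - 1L)) {
    seg <- cuts[k]:(cuts[k + 1L] - 1L)
    out <- setdiff(seq_len(n), seg)
    if (length(out) == 0) next  # single cluster: terms are 0
    for (a in seg) {
      win <- mean(d[a, seg])
      btw <- mean(d[a, out])
      mx <- max(win, btw)
      if (mx > 0) total <- total + (btw - win) / mx
    }
  }
  total / n
}

#' Detect TAD-like domains within one window
#'
#' For each candidate rank in `n_range`, builds the consensus map over `k`
#' seeded NMF runs, extracts cluster-rate minima, selects boundaries, and
#' scores the partition by its silhouette on that rank's consensus map.
#' The rank with the largest silhouette wins; ties go to the smaller rank.
#'
#' @param sub Non-negative symmetric contact submatrix of the window.
#' @param n_range Candidate ranks (default `8:13`, suited to mammalian
#'   TAD sizes in 8-Mb windows at 40 kb).
#' @param k NMF runs per rank (default 10).
#' @param strength_cutoff Boundary strength threshold (default 0.3).
#' @param cr_width Side of the cluster-rate square (default 11).
#' @param cr_anchor Anchoring of the cluster-rate square, see
#'   [cluster_rate_profile()].
#' @param seed_base Base seed for the NMF runs (default 0).
#' @inheritParams nmf_fit
#' @return List with `bounds` (1-based window-local boundary bins),
#'   `n_selected`, and `silhouettes` (named by rank).
#' @export
detect_window <- function(sub, n_range = 8:13, k = 10L,
                          strength_cutoff = 0.3, cr_width = 11L,
                          cr_anchor = c("center", "corner"),
                          seed_base = 0L, max_iter = 200L, tol = 1e-4) {
  cr_anchor <- match.arg(cr_anchor)
  n_range <- n_range[n_range < nrow(sub)]
  if (length(n_range) == 0) stopf("no admissible rank below window size")
  best <- NULL
  sils <- stats::setNames(numeric(length(n_range)), n_range)
  for (ni in seq_along(n_range)) {
    nc <- n_range[ni]
    cmap <- consensus_map(sub, nc, k = k, seed_base = seed_base,
                          max_iter = max_iter, tol = tol)
    cr <- cluster_rate_profile(cmap, w = cr_width, anchor = cr_anchor)
    minima <- find_local_minima(cr)
    calls <- select_boundaries(minima, nc, strength_cutoff)
    sil <- silhouette_for_partition(cmap, calls$bin)
    sils[ni] <- sil
    if (is.null(best) || sil > best$sil + 1e-12) {
      best <- list(sil = sil, bounds = calls$bin, n = nc)
    }
  }
  list(bounds = best$bounds, n_selected = best$n, silhouettes = sils)
}

#' Detect TAD-like domains on a whole chromosome
#'
#' Slides 8-Mb (by default) windows over the chromosome, detects
#' boundaries in each with [detect_window()], keeps only the calls falling
#' in each window's report interval (middle half, extended at the
#' chromosome ends), and stitches them into one `DomainSet`. Report
#' intervals of no-call windows (too few contacts) become gaps.
#'
#' @param m A `ContactMatrix`.
#' @param L Window length in bp (default 8e6).
#' @param min_contacts No-call threshold on intra-window contacts
#'   (default 100).
#' @param verbose Log per-window rank selection and silhouettes.
#' @inheritParams detect_window
#' @return A `DomainSet`; attribute `"window_log"` holds the per-window
#'   selection log.
#' @export
detect_chromosome <- function(m, L = 8e6, min_contacts = 100,
                              n_range = 8:13, k = 10L,
                              strength_cutoff = 0.3, cr_width = 11L,
                              cr_anchor = c("center", "corner"),
                              seed_base = 0L, max_iter = 200L, tol = 1e-4,
                              verbose = FALSE) {
  cr_anchor <- match.arg(cr_anchor)
  win <- make_windows(m, L = L, min_contacts = min_contacts)
  n <- n_bins(m)
  all_bounds <- integer(0)
  gaps <- NULL
  log <- vector("list", nrow(win))
  for (t in seq_len(nrow(win))) {
    if (win$no_call[t]) {
      gaps <- rbind(gaps, c(win$report_start[t], win$report_end[t]))
      log[[t]] <- data.frame(window = t, n_selected = NA_integer_,
                             silhouette = NA_real_, n_boundaries = 0L)
      next
    }
    idx <- (win$start[t] + 1):win$end[t]
    res <- detect_window(m$counts[idx, idx], n_range = n_range, k = k,
                         strength_cutoff = strength_cutoff,
                         cr_width = cr_width, cr_anchor = cr_anchor,
                         seed_base = seed_base, max_iter = max_iter,
                         tol = tol)
    abs_b <- win$start[t] + res$bounds - 1L  # 0-based absolute bins
    inside <- abs_b >= win$report_start[t] & abs_b < win$report_end[t]
    all_bounds <- c(all_bounds, abs_b[inside])
    log[[t]] <- data.frame(window = t, n_selected = res$n_selected,
                           silhouette = max(res$silhouettes),
                           n_boundaries = sum(inside))
    if (verbose)
      message(sprintf("window %d [%d,%d): n = %d, silhouette = %.3f, %d boundaries",
                      t, win$start[t], win$end[t], res$n_selected,
                      max(res$silhouettes), sum(inside)))
  }
  if (all(win$no_call)) {
    warnf("all windows no-call: empty DomainSet")
    out <- domain_set(integer(0), integer(0), n, m$chrom, m$binsize)
  } else {
    out <- domains_from_boundaries(unique(all_bounds), n, m$chrom,
                                   m$binsize, gaps = gaps)
  }
  attr(out, "window_log") <- do.call(rbind, log)
  out
}
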