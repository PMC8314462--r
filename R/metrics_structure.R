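#' Structure entropy of a domain partition on a contact network
#'
#' Two-term entropy of the partition induced by the domain boundaries on
#' the contact graph; *lower* values indicate better-insulated domains.
#' With sentinels at the first bin and `N + 1`, the boundaries partition
#' all `N` bins into segments. For segment `i` with total degree `g_i`
#' (contacts of its bins to anywhere, both directions) and intra-segment
#' sum `v_i`:
#' `SE = -sum_i (g_i - v_i)/Num * log(g_i/Num) / log N`
#' `     - sum_i sum_{j in seg i} deg_j/Num * log(deg_j/g_i) / log N`,
#' where `Num` is the total off-diagonal contact mass and `deg_j` the
#' off-diagonal degree of bin `j`. Degenerate `0 * log(0)` terms are 0.
#' (Both terms carry the conventional leading minus of an entropy, making
#' SE non-negative; a well-insulated partition has zero cut mass in the
#' first term and tight segment degrees in the second.)
#'
#' @param t_dom A `DomainSet` (its boundaries define the segments) or a
#'   vector of 0-based boundary bins.
#' @param m A `ContactMatrix` (or plain symmetric matrix).
#' @return Structure entropy (dimensionless).
#' @export
structure_entropy <- function(t_dom, m) {
  f <- if (inherits(m, "ContactMatrix")) m$counts else as.matrix(m)
  n <- nrow(f)
  b <- if (inherits(t_dom, "DomainSet")) boundaries(t_dom)
       else sort(unique(as.integer(t_dom)))
  f0 <- f
  diag(f0) <- 0
  num <- sum(f0)
  if (num == 0) stopf("empty matrix")
  deg <- rowSums(f0)
  cuts <- c(0L, b[b > 0 & b < n], n)  # 0-based segment starts + sentinel
  se <- 0
  for (k in seq_len(length(cuts) - 1L)) {
    seg <- (cuts[k] + 1):cuts[k + 1]
    g <- sum(deg[seg])
    v <- sum(f0[seg, seg])
    if (g > 0) se <- se - (g - v) / num * log(g / num) / log(n)
    dj <- deg[seg]
    ok <- dj > 0
    if (any(ok))
      se <- se - sum(dj[ok] / num * log(dj[ok] / g) / log(n))
  }
  se
}

#' Modularity index of a domain partition
#'
#' Splits the chromosome into 6-Mb non-overlapping windows, drops windows
#' with fewer than `min_contacts` intra-window raw contacts, and on each
#' retained window computes a modularity over the log-transformed,
#' diagonal-removed contact matrix `E = log(1 + counts)`:
#' `M_xy = (E_xy - rowsum_x * rowsum_y / S) / S` with
#' `S = sum_{i != j} E_ij`, summed over intra-domain bin pairs
#' (`x != y`, both in the same domain). The per-window values are
#' averaged. Higher is better.
#'
#' @param t_dom A `DomainSet`.
#' @param m A `ContactMatrix` with raw counts.
#' @param window_bp Window span in base pairs (default 6e6).
#' @param min_contacts Window retention threshold (default 100).
#' @return Mean per-window modularity.
#' @export
modularity <- function(t_dom, m, window_bp = 6e6, min_contacts = 100) {
  stopifnot(inherits(t_dom, "DomainSet"), inherits(m, "ContactMatrix"))
  n <- n_bins(m)
  wl <- max(2L, as.integer(round(window_bp / m$binsize)))
  lab <- domain_labels(t_dom, gap_mode = "exclude")
  starts <- seq.int(0L, n - 1L, by = wl)
  vals <- numeric(0)
  for (st in starts) {
    en <- min(n, st + wl)
    if (en - st < 2) next
    idx <- (st + 1):en
    raw <- m$counts[idx, idx]
    diag(raw) <- 0
    if (sum(raw[upper.tri(raw)]) < min_contacts) next
    e <- log1p(raw)
    diag(e) <- 0
    s <- sum(e)
    if (s == 0) next
    rs <- rowSums(e)
    wlab <- lab[idx]
    mod <- 0
    for (d in unique(wlab[!is.na(wlab)])) {
      dd <- which(wlab == d)
      if (length(dd) < 2) next
      em <- e[dd, dd]
      expm <- outer(rs[dd], rs[dd]) / s
      mm <- (em - expm) / s
      diag(mm) <- 0
      mod <- mod + sum(mm)
    }
    vals <- c(vals, mod)
  }
  if (length(vals) == 0) stopf("all windows filtered: modularity undefined")
  mean(vals)
}
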