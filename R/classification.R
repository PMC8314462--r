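#' Unsupervised classification of cells from TAD-like domain structure
#'
#' For each chromosome `k`, builds the cell-by-cell weighted-similarity
#' matrix `M[i, j] = WS(domains of cell i, domains of cell j)`, its
#' row-wise Spearman correlation matrix `C`, and the first principal
#' component `V` of `C`; each cell is reduced to the sign `S[i, k]` of its
#' PC1 entry (0 when the chromosome is missing for that cell). Cell pairs
#' are then scored by the sign-agreement ratio
#' `T[i, j] = sum_k S[i,k] S[j,k] / sum_k |S[i,k] S[j,k]|` (0 when no
#' chromosome informs the pair), and the per-cell classification index is
#' the first principal component of `T`. When labels are supplied the
#' index is scored by the area under the ROC curve; since the PC sign is
#' arbitrary, `max(auc, 1 - auc)` is reported for unordered labels.
#'
#' @param collection List over chromosomes; each element a list over cells
#'   of `DomainSet` or `NULL` (missing chromosome). A plain list of
#'   `DomainSet`s is treated as a single chromosome.
#' @param labels Optional two-level factor (or coercible) of cell labels.
#' @return List with `index` (per-cell classification index), `signs`
#'   (cells x chromosomes sign matrix), `T` (pairwise agreement), and
#'   `auc` (or `NA` without labels).
#' @export
cell_classification <- function(collection, labels = NULL) {
  if (length(collection) && inherits(collection[[1]], "DomainSet"))
    collection <- list(collection)
  n_chr <- length(collection)
  n_cell <- length(collection[[1]])
  stopifnot(n_cell >= 2)
  signs <- matrix(0, n_cell, n_chr)
  for (k in seq_len(n_chr)) {
    doms <- collection[[k]]
    have <- !vapply(doms, is.null, logical(1))
    idx <- which(have)
    if (length(idx) < 2) next
    nm <- length(idx)
    mws <- matrix(1, nm, nm)
    for (a in seq_len(nm)) {
      for (b in seq_len(nm)) {
        if (a == b) next
        mws[a, b] <- tryCatch(ws(doms[[idx[a]]], doms[[idx[b]]]),
                              error = function(e) 0)
      }
    }
    cc <- matrix(0, nm, nm)
    for (a in seq_len(nm)) {
      for (b in seq_len(nm)) {
        if (stats::sd(mws[a, ]) == 0 || stats::sd(mws[b, ]) == 0) {
          cc[a, b] <- 0
          if (a == b) cc[a, b] <- 1
        } else {
          cc[a, b] <- stats::cor(mws[a, ], mws[b, ], method = "spearman")
        }
      }
    }
    v <- .pc1(cc)
    signs[idx, k] <- sign(v)
  }
  tmat <- matrix(0, n_cell, n_cell)
  for (i in seq_len(n_cell)) {
    for (j in seq_len(n_cell)) {
      prod <- signs[i, ] * signs[j, ]
      den <- sum(abs(prod))
      tmat[i, j] <- if (den > 0) sum(prod) / den else 0
    }
  }
  index <- .pc1(tmat)
  auc <- NA_real_
  if (!is.null(labels)) {
    labels <- factor(labels)
    stopifnot(nlevels(labels) == 2, length(labels) == n_cell)
    roc <- pROC::roc(labels, index, quiet = TRUE, direction = "<",
                     levels = levels(labels))
    auc <- as.numeric(pROC::auc(roc))
    auc <- max(auc, 1 - auc)
  }
  list(index = index, signs = signs, T = tmat, auc = auc)
}

# first principal component scores of a symmetric matrix, with the global
# sign fixed so the first nonzero loading is positive
.pc1 <- function(x) {
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  load <- pc$rotation[, 1]
  nz <- which(abs(load) > 1e-12)
  s <- if (length(nz)) sign(load[nz[1]]) else 1
  as.numeric(pc$x[, 1]) * s
}

#' Intra- vs inter-domain correlation of a per-bin signal
#'
#' For every bin pair at a fixed genomic separation (default 240 kb),
#' computes the Pearson correlation of the signal across cells (pairs
#' with fewer than `min_obs` complete observations are skipped), then
#' compares the mean correlation of intra-domain pairs (both bins in the
#' same domain) against inter-domain pairs (bins separated by at least
#' one boundary) with Fisher's z-test. Pairs are classified intra/inter
#' per cell and assigned by majority vote across cells with data (ties
#' are dropped); alternatively a single `DomainSet` fixes the
#' classification for all cells.
#'
#' @param domains A single `DomainSet` or a list of per-cell
#'   `DomainSet`s.
#' @param signal Numeric matrix, bins x cells (`NA` = missing).
#' @param sep_bp Pair separation in base pairs (default 2.4e5).
#' @param binsize Bin size in base pairs (default 4e4).
#' @param min_obs Minimum complete observations per pair (default 3).
#' @param pool With `pool = TRUE`, correlations are computed on all
#'   pooled (pair, cell) observations per group instead of per pair.
#' @return List with `r_intra`, `r_inter`, per-group pair counts, `z`,
#'   and `p_value`.
#' @export
inter_intra_correlation <- function(domains, signal, sep_bp = 2.4e5,
                                    binsize = 4e4, min_obs = 3L,
                                    pool = FALSE) {
  sep <- as.integer(round(sep_bp / binsize))
  stopifnot(sep >= 1)
  if (inherits(domains, "DomainSet")) domains <- list(domains)
  n <- nrow(signal)
  n_cells <- ncol(signal)
  lab_list <- lapply(domains, domain_labels, gap_mode = "exclude")
  classify_pair <- function(i) {
    votes <- vapply(seq_along(lab_list), function(c) {
      lab <- lab_list[[if (length(lab_list) == 1) 1 else c]]
      l1 <- lab[i]; l2 <- lab[i + sep]
      if (is.na(l1) || is.na(l2)) return(NA)
      l1 == l2
    }, logical(1))
    votes <- votes[!is.na(votes)]
    if (length(votes) == 0) return(NA)
    f <- mean(votes)
    if (f == 0.5) return(NA)
    f > 0.5
  }
  r_intra <- c(); r_inter <- c()
  pool_intra <- list(); pool_inter <- list()
  for (i in seq_len(n - sep)) {
    cls <- classify_pair(i)
    if (is.na(cls)) next
    x <- signal[i, ]; y <- signal[i + sep, ]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < min_obs) next
    if (pool) {
      dst <- cbind(x[ok], y[ok])
      if (cls) pool_intra[[length(pool_intra) + 1]] <- dst
      else pool_inter[[length(pool_inter) + 1]] <- dst
    } else {
      if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next
      r <- stats::cor(x[ok], y[ok])
      if (cls) r_intra <- c(r_intra, r) else r_inter <- c(r_inter, r)
    }
  }
  if (pool) {
    pcor <- function(lst) {
      m <- do.call(rbind, lst)
      stats::cor(m[, 1], m[, 2])
    }
    if (length(pool_intra) == 0 || length(pool_inter) == 0)
      stopf("one of the groups is empty")
    r1 <- pcor(pool_intra); r2 <- pcor(pool_inter)
    n1 <- sum(vapply(pool_intra, nrow, numeric(1)))
    n2 <- sum(vapply(pool_inter, nrow, numeric(1)))
  } else {
    if (length(r_intra) == 0 || length(r_inter) == 0)
      stopf("one of the groups is empty")
    r1 <- mean(r_intra); r2 <- mean(r_inter)
    n1 <- length(r_intra); n2 <- length(r_inter)
  }
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(r_intra = r1, r_inter = r2, n_intra = n1, n_inter = n2,
       z = z, p_value = 2 * stats::pnorm(-abs(z)))
}
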