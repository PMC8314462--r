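#' Contact matrices for one chromosome
#'
#' A `ContactMatrix` holds the symmetric, non-negative bin-by-bin contact
#' counts of a single chromosome at a fixed bin size. Bin `b` (0-based)
#' covers the genomic interval `[b * binsize, (b + 1) * binsize)`; row and
#' column `i` of the count matrix correspond to bin `i - 1`.
#'
#' @param counts Square numeric matrix of contact counts (symmetrized if
#'   only one triangle is filled is *not* done automatically: the matrix
#'   must already be symmetric).
#' @param chrom Chromosome name.
#' @param binsize Bin size in base pairs.
#' @return An object of class `ContactMatrix`.
#' @examples
#' m <- contact_matrix(diag(3), chrom = "chr1", binsize = 40000)
#' n_bins(m)
#' @export
contact_matrix <- function(counts, chrom = "chr1", binsize = 40000L) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stopf("contact matrix must be square")
  if (any(counts < 0)) stopf("negative contact counts are not allowed")
  if (max(abs(counts - t(counts))) > 1e-8 * max(1, max(abs(counts))))
    stopf("contact matrix must be symmetric")
  dimnames(counts) <- NULL
  structure(list(chrom = chrom, binsize = as.integer(binsize),
                 counts = counts),
            class = "ContactMatrix")
}

#' @export
print.ContactMatrix <- function(x, ...) {
  cat(sprintf("ContactMatrix: %s, %d bins @ %d bp, %.0f total contacts, sparsity %.3f\n",
              x$chrom, n_bins(x), x$binsize, total_contacts(x),
              tryCatch(sparsity(x), error = function(e) NA_real_)))
  invisible(x)
}

#' Number of bins of a ContactMatrix
#' @param m A `ContactMatrix`.
#' @export
n_bins <- function(m) nrow(m$counts)

#' Total contact count (upper triangle including the diagonal)
#' @param m A `ContactMatrix`.
#' @export
total_contacts <- function(m) {
  ut <- upper.tri(m$counts, diag = TRUE)
  sum(m$counts[ut])
}

#' Mappable bins of a ContactMatrix
#'
#' A bin is mappable when its marginal (row sum) is positive. An explicit
#' logical mask can be supplied to override this, e.g. a mask derived from
#' the densest available matrix of the same chromosome.
#'
#' @param m A `ContactMatrix`.
#' @param mask Optional logical vector of length `n_bins(m)`.
#' @return Logical vector flagging mappable bins.
#' @export
mappable_bins <- function(m, mask = NULL) {
  if (!is.null(mask)) {
    stopifnot(is.logical(mask), length(mask) == n_bins(m))
    return(mask)
  }
  rowSums(m$counts) > 0
}

#' Read a contact matrix from text
#'
#' Supports two plain-text formats: `triplet` (`bin_i bin_j count` or
#' `pos_i pos_j count` rows; duplicated pairs are summed) and `dense`
#' (whitespace-separated square matrix). Triplet coordinates may be 0-based
#' bin indices or base-pair positions; with `coords = "auto"` positions are
#' assumed when every coordinate is a multiple of `binsize` and some
#' coordinate is at least `binsize`.
#'
#' @param path Path to the text file.
#' @param format `"triplet"` or `"dense"`.
#' @param chrom Chromosome name to attach.
#' @param binsize Bin size in base pairs.
#' @param n_bins Number of bins (required for `triplet`; inferred for
#'   `dense`).
#' @param coords Coordinate convention for triplet rows: `"auto"`, `"bin"`,
#'   or `"bp"`.
#' @return A [contact_matrix()].
#' @export
read_contact_matrix <- function(path, format = c("triplet", "dense"),
                                chrom = "chr1", binsize = 40000L,
                                n_bins = NULL, coords = c("auto", "bin", "bp")) {
  format <- match.arg(format)
  coords <- match.arg(coords)
  if (format == "dense") {
    mat <- as.matrix(utils::read.table(path, header = FALSE))
    return(contact_matrix(mat, chrom = chrom, binsize = binsize))
  }
  tri <- utils::read.table(path, header = FALSE,
                           col.names = c("i", "j", "count"))
  if (nrow(tri) > 0 && any(tri$count < 0)) stopf("negative counts in %s", path)
  if (coords == "auto") {
    cc <- c(tri$i, tri$j)
    coords <- if (length(cc) && all(cc %% binsize == 0) && any(cc >= binsize))
      "bp" else "bin"
  }
  if (coords == "bp") {
    tri$i <- tri$i %/% binsize
    tri$j <- tri$j %/% binsize
  }
  if (is.null(n_bins)) n_bins <- max(tri$i, tri$j) + 1L
  if (nrow(tri) > 0 && max(tri$i, tri$j) >= n_bins)
    stopf("bin index beyond declared n_bins = %d", n_bins)
  mat <- matrix(0, n_bins, n_bins)
  for (r in seq_len(nrow(tri))) {
    i <- tri$i[r] + 1L; j <- tri$j[r] + 1L
    mat[i, j] <- mat[i, j] + tri$count[r]
    if (i != j) mat[j, i] <- mat[j, i] + tri$count[r]
  }
  contact_matrix(mat, chrom = chrom, binsize = binsize)
}

#' Write a contact matrix as sparse triplet text
#'
#' Writes the upper triangle (including the diagonal) as 0-based
#' `bin_i bin_j count` rows.
#'
#' @param m A `ContactMatrix`.
#' @param path Output path.
#' @export
write_contact_matrix <- function(m, path) {
  ut <- which(upper.tri(m$counts, diag = TRUE) & m$counts != 0, arr.ind = TRUE)
  df <- data.frame(i = ut[, 1] - 1L, j = ut[, 2] - 1L,
                   count = m$counts[ut])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Iterative correction (ICE) of a contact matrix
#'
#' Balances the matrix so that the marginals of mappable bins are equal,
#' by iteratively dividing rows and columns by their relative marginal.
#' Unmappable bins (zero marginal, or masked out) are zeroed. The total
#' count mass is rescaled to the input total after convergence.
#'
#' @param m A `ContactMatrix`.
#' @param max_iter Maximum number of iterations (default 200).
#' @param tol Convergence tolerance on the relative change of the bias
#'   vector (default 1e-5).
#' @param mask Optional mappability mask passed to [mappable_bins()].
#' @return A balanced `ContactMatrix`.
#' @export
ice_normalize <- function(m, max_iter = 200L, tol = 1e-5, mask = NULL) {
  cm <- m$counts
  if (sum(cm) == 0) stopf("empty matrix")
  keep <- mappable_bins(m, mask)
  cm[!keep, ] <- 0
  cm[, !keep] <- 0
  tot0 <- sum(cm)
  for (it in seq_len(max_iter)) {
    marg <- rowSums(cm)
    s <- marg / mean(marg[keep])
    s[!keep | s == 0] <- 1
    cm <- cm / outer(s, s)
    if (max(abs(s[keep] - 1)) < tol) break
  }
  cm <- cm * (tot0 / sum(cm))
  out <- m
  out$counts <- cm
  out
}

#' Binomial thinning of contact counts
#'
#' Retains each read independently with probability `rate`, mimicking a
#' shallow-sequenced library; the characteristic single-cell regime in this
#' package is `rate = 1/800` applied to deep bulk data. Counts must be raw
#' integers: thinning is applied before any normalization.
#'
#' @param m A `ContactMatrix` with integer counts.
#' @param rate Retention probability in (0, 1].
#' @param seed Optional integer seed for reproducibility.
#' @return A thinned `ContactMatrix`.
#' @export
downsample_contacts <- function(m, rate, seed = NULL) {
  stopifnot(rate > 0, rate <= 1)
  if (max(abs(m$counts - round(m$counts))) > 1e-9)
    stopf("downsampling requires raw integer counts (normalize after, not before)")
  if (rate == 1) return(m)
  cm <- round(m$counts)
  ut <- which(upper.tri(cm, diag = TRUE) & cm > 0)
  new <- with_seed(seed, stats::rbinom(length(ut), cm[ut], rate))
  cm[] <- 0
  cm[ut] <- new
  cm <- cm + t(cm)
  diag(cm) <- diag(cm) / 2
  out <- m
  out$counts <- cm
  out
}

#' Aggregate a contact matrix into coarser bins
#'
#' Sums counts over unique bin pairs: the coarse count for pair `(I, J)`
#' is the sum of the fine counts over all pairs `i <= j` mapping into it,
#' so contacts falling within one coarse bin land on the diagonal once and
#' [total_contacts()] is conserved exactly. The trailing partial block
#' (when `n_bins` is not a multiple of `factor`) is kept as a smaller
#' bin. The bin size is multiplied by `factor`.
#'
#' @param m A `ContactMatrix`.
#' @param factor Integer aggregation factor (>= 1).
#' @return A `ContactMatrix` at `binsize * factor`.
#' @export
rebin_matrix <- function(m, factor) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1)
  if (factor == 1) return(m)
  n <- n_bins(m)
  grp <- (seq_len(n) - 1L) %/% factor + 1L
  up <- m$counts
  up[lower.tri(up)] <- 0                   # unique pairs i <= j
  agg <- rowsum(up, grp)
  agg <- t(rowsum(t(agg), grp))            # coarse upper triangle
  out <- agg + t(agg)
  diag(out) <- diag(agg)
  contact_matrix(out, chrom = m$chrom, binsize = m$binsize * factor)
}

#' Sparsity of a contact matrix
#'
#' Fraction of zero entries among bin pairs of the mappable submatrix.
#' Counted over the upper triangle; the diagonal is included by default
#' (the convention is configurable because published definitions leave it
#' unstated).
#'
#' @param m A `ContactMatrix`.
#' @param include_diagonal Count diagonal entries as pairs (default TRUE).
#' @param mask Optional mappability mask passed to [mappable_bins()].
#' @return Fraction of zero entries in `[0, 1]`.
#' @export
sparsity <- function(m, include_diagonal = TRUE, mask = NULL) {
  keep <- mappable_bins(m, mask)
  if (!any(keep)) stopf("no mappable bins")
  sub <- m$counts[keep, keep, drop = FALSE]
  ut <- upper.tri(sub, diag = include_diagonal)
  mean(sub[ut] == 0)
}
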