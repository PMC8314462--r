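#' Synthetic block-structured 3D chromatin conformations
#'
#' Generates an ordered chain of particles (one per fine bin, conventionally
#' 10 kb) whose consecutive blocks form spatial globules: each block's
#' centre takes a random-walk step of per-coordinate standard deviation
#' `inter_scale` from the previous centre, and particles scatter
#' isotropically around their block centre with standard deviation
#' `intra_scale`. With `inter_scale > intra_scale` the blocks are spatially
#' segregated and play the role of ground-truth domains; with equal scales
#' the chain has no block structure and downstream detection is at chance.
#'
#' @param n_particles Number of particles (fine bins).
#' @param block_lengths Integer block lengths in particles; must sum to
#'   `n_particles`.
#' @param intra_scale Within-block scatter (model units, default 1).
#' @param inter_scale Between-block centre step (default 5).
#' @param seed Optional integer seed.
#' @return Object of class `Structure3D`: list with `coords`
#'   (`n_particles` x 3 matrix) and `block_lengths`.
#' @export
generate_synthetic_structure <- function(n_particles, block_lengths,
                                         intra_scale = 1, inter_scale = 5,
                                         seed = NULL) {
  block_lengths <- as.integer(block_lengths)
  if (sum(block_lengths) != n_particles)
    stopf("block lengths must sum to n_particles")
  nb <- length(block_lengths)
  coords <- with_seed(seed, {
    steps <- matrix(stats::rnorm(nb * 3, sd = inter_scale), nb, 3)
    centers <- apply(steps, 2, cumsum)
    if (nb == 1) centers <- matrix(centers, 1, 3)
    jitter <- matrix(stats::rnorm(n_particles * 3, sd = intra_scale),
                     n_particles, 3)
    centers[rep(seq_len(nb), block_lengths), , drop = FALSE] + jitter
  })
  structure(list(coords = coords, block_lengths = block_lengths),
            class = "Structure3D")
}

#' @export
print.Structure3D <- function(x, ...) {
  cat(sprintf("Structure3D: %d particles in %d blocks\n",
              nrow(x$coords), length(x$block_lengths)))
  invisible(x)
}

#' Read particle coordinates from an xyz table
#'
#' Plain whitespace-separated table `particle_index x y z` (index sorted or
#' not; rows are reordered by index).
#'
#' @param path Path to the table.
#' @param block_lengths Optional ground-truth block lengths to attach.
#' @return A `Structure3D`.
#' @export
read_structure_xyz <- function(path, block_lengths = NULL) {
  df <- utils::read.table(path, header = FALSE,
                          col.names = c("index", "x", "y", "z"))
  df <- df[order(df$index), ]
  coords <- as.matrix(df[, c("x", "y", "z")])
  dimnames(coords) <- NULL
  structure(list(coords = coords,
                 block_lengths = block_lengths %||% nrow(coords)),
            class = "Structure3D")
}

#' Distance quantile of a structure
#'
#' The `q`-quantile of all pairwise Euclidean distances between particles;
#' used to pick the single-cell contact threshold `D` (e.g. `q` of 0.2,
#' 0.4, 0.6).
#'
#' @param s A `Structure3D`.
#' @param q Quantile in (0, 1).
#' @return Distance threshold `D`.
#' @export
distance_quantile_threshold <- function(s, q) {
  stopifnot(q > 0, q < 1)
  stats::quantile(stats::dist(s$coords), probs = q, names = FALSE)
}

# pairwise index/distance table over i < j
.pair_distances <- function(s) {
  d <- as.matrix(stats::dist(s$coords))
  n <- nrow(d)
  ut <- which(upper.tri(d), arr.ind = TRUE)
  list(i = ut[, 1], j = ut[, 2], d = d[upper.tri(d)], n = n)
}

.counts_to_matrix <- function(pairs, counts, n) {
  mat <- matrix(0, n, n)
  idx <- cbind(pairs$i, pairs$j)
  mat[idx] <- counts
  mat[idx[, c(2, 1), drop = FALSE]] <- counts
  mat
}

#' Simulate deep reference Hi-C from a 3D structure
#'
#' Every particle pair (self pairs excluded) gets weight `1/distance`,
#' weights are normalized to sum to one, and the pair's count is drawn as
#' Poisson with mean `weight * reads`. The default budget is the
#' deep-coverage convention of 0.35 M reads per 5-Mb region, scaled to the
#' structure length.
#'
#' @param s A `Structure3D` with no coincident particles.
#' @param reads Total expected read count (default scales 0.35 M per 500
#'   fine bins).
#' @param fine_binsize Base pairs per particle (default 10 kb).
#' @param chrom Chromosome name for the output matrix.
#' @param seed Optional integer seed.
#' @return A `ContactMatrix` at `fine_binsize` resolution.
#' @export
simulate_reference_hic <- function(s, reads = NULL, fine_binsize = 10000L,
                                   chrom = "chr1", seed = NULL) {
  p <- .pair_distances(s)
  if (any(p$d == 0)) stopf("coincident particles")
  if (is.null(reads)) reads <- 350000 * nrow(s$coords) / 500
  w <- (1 / p$d) / sum(1 / p$d)
  counts <- with_seed(seed, stats::rpois(length(w), w * reads))
  contact_matrix(.counts_to_matrix(p, counts, p$n),
                 chrom = chrom, binsize = fine_binsize)
}

#' Simulate sparse single-cell Hi-C from a 3D structure
#'
#' Only particle pairs closer than the contact threshold `D` can ligate;
#' their weights are `D - distance`, normalized over contacting pairs. In
#' the default `"multinomial"` mode the fixed read budget is partitioned
#' over pairs by a single multinomial draw (each pair marginally binomial,
#' totals exact); `"binomial"` mode draws each pair independently as
#' `Binomial(reads, weight)` so totals fluctuate.
#'
#' @param s A `Structure3D`.
#' @param D Contact distance threshold (model units).
#' @param reads Read budget (default scales 1,000 per 500 fine bins,
#'   i.e. per 5 Mb at 10 kb).
#' @param mode `"multinomial"` (default) or `"binomial"`.
#' @inheritParams simulate_reference_hic
#' @return A `ContactMatrix` at `fine_binsize` resolution; zero outside
#'   the contact radius.
#' @export
simulate_single_cell_hic <- function(s, D, reads = NULL,
                                     mode = c("multinomial", "binomial"),
                                     fine_binsize = 10000L, chrom = "chr1",
                                     seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(D > 0)
  p <- .pair_distances(s)
  if (any(p$d == 0)) stopf("coincident particles")
  if (is.null(reads)) reads <- 1000 * nrow(s$coords) / 500
  w <- pmax(D - p$d, 0)
  if (all(w == 0)) stopf("no contacts at this threshold")
  w <- w / sum(w)
  counts <- with_seed(seed, {
    if (mode == "multinomial")
      as.numeric(stats::rmultinom(1, round(reads), w))
    else stats::rbinom(length(w), round(reads), w)
  })
  contact_matrix(.counts_to_matrix(p, counts, p$n),
                 chrom = chrom, binsize = fine_binsize)
}

#' Simulate a population of single cells with ground truth
#'
#' Draws `n_cells` independent conformations of the same planted block
#' layout, samples a sparse single-cell contact matrix from each (and
#' optionally a deep per-cell reference), aggregates fine bins into the
#' output bin size, and attaches the planted domains as a ground-truth
#' `DomainSet` at the output resolution.
#'
#' @param block_lengths Planted block lengths in fine bins; each must be a
#'   multiple of `out_binsize / fine_binsize`.
#' @param n_cells Number of cells (default 100).
#' @param D Contact threshold; `NULL` (default) uses the 0.2 distance
#'   quantile of each cell's conformation.
#' @param reads_cell Single-cell read budget (default 1,000 per 5 Mb).
#' @param reads_reference Reference budget (default 0.35 M per 5 Mb).
#' @param intra_scale,inter_scale Passed to
#'   [generate_synthetic_structure()].
#' @param fine_binsize,out_binsize Fine and output bin sizes (defaults
#'   10 kb and 40 kb).
#' @param with_reference Also simulate a deep reference per cell.
#' @param chrom Chromosome name.
#' @param seed Master seed; each cell derives its own sub-seed.
#' @return List with `cells` (list of `ContactMatrix` at `out_binsize`),
#'   `truth` (`DomainSet`), and if requested `references`.
#' @export
simulate_cell_population <- function(block_lengths, n_cells = 100L, D = NULL,
                                     reads_cell = NULL, reads_reference = NULL,
                                     intra_scale = 1, inter_scale = 5,
                                     fine_binsize = 10000L, out_binsize = 40000L,
                                     with_reference = FALSE, chrom = "chr1",
                                     seed = NULL) {
  factor <- out_binsize %/% fine_binsize
  if (any(block_lengths %% factor != 0))
    stopf("block lengths must be multiples of the rebinning factor %d", factor)
  n_part <- sum(block_lengths)
  cells <- vector("list", n_cells)
  refs <- if (with_reference) vector("list", n_cells) else NULL
  for (c in seq_len(n_cells)) {
    s_seed <- sub_seed(seed, paste0("structure", c))
    s <- generate_synthetic_structure(n_part, block_lengths,
                                      intra_scale, inter_scale, seed = s_seed)
    Dc <- D %||% distance_quantile_threshold(s, 0.2)
    sc <- simulate_single_cell_hic(s, Dc, reads = reads_cell,
                                   fine_binsize = fine_binsize, chrom = chrom,
                                   seed = sub_seed(seed, paste0("cell", c)))
    cells[[c]] <- rebin_matrix(sc, factor)
    if (with_reference) {
      rf <- simulate_reference_hic(s, reads = reads_reference,
                                   fine_binsize = fine_binsize, chrom = chrom,
                                   seed = sub_seed(seed, paste0("ref", c)))
      refs[[c]] <- rebin_matrix(rf, factor)
    }
  }
  ends <- cumsum(block_lengths) %/% factor
  starts <- c(0L, ends[-length(ends)])
  truth <- domain_set(starts, ends, n_part %/% factor, chrom, out_binsize)
  out <- list(cells = cells, truth = truth)
  if (with_reference) out$references <- refs
  out
}
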