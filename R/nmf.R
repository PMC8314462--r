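#' Non-negative matrix factorization by multiplicative updates
#'
#' Minimizes the Frobenius loss ||V - WH||_F over non-negative factors
#' W (n x r) and H (r x n) with Lee-Seung multiplicative updates. Factors
#' are initialized from seeded half-normal noise scaled to the data mean
#' (the usual "random" initialization), so a fixed seed gives a
#' reproducible factorization.
#'
#' @param v Non-negative numeric matrix.
#' @param rank Factorization rank (number of components).
#' @param seed Integer seed for the random initialization.
#' @param max_iter Maximum update iterations (default 200).
#' @param tol Relative decrease of the loss below which iteration stops,
#'   checked every 10 iterations (default 1e-4).
#' @return List with `w`, `h`, and the final Frobenius loss `loss`.
#' @export
nmf_fit <- function(v, rank, seed = 0L, max_iter = 200L, tol = 1e-4) {
  stopifnot(all(v >= 0), rank >= 1, rank < nrow(v))
  n <- nrow(v); p <- ncol(v)
  eps <- 1e-10
  scale0 <- sqrt(mean(v) / rank)
  init <- with_seed(seed, list(w = matrix(abs(stats::rnorm(n * rank)), n, rank),
                               h = matrix(abs(stats::rnorm(rank * p)), rank, p)))
  w <- init$w * scale0
  h <- init$h * scale0
  prev <- Inf
  for (it in seq_len(max_iter)) {
    h <- h * (crossprod(w, v) / (crossprod(w, w %*% h) + eps))
    w <- w * (v %*% t(h)) / (w %*% tcrossprod(h, h) + eps)
    if (it %% 10L == 0L) {
      loss <- sqrt(sum((v - w %*% h)^2))
      if (is.finite(prev) && (prev - loss) <= tol * max(prev, eps)) break
      prev <- loss
    }
  }
  list(w = w, h = h, loss = sqrt(sum((v - w %*% h)^2)))
}

#' Cluster bins by one NMF run
#'
#' Factorizes the contact submatrix at the given rank and assigns bin `j`
#' the index of the largest entry in column `j` of the coefficient matrix
#' H; ties go to the lowest row index. Bins sharing a label form one
#' spatial cluster. If the factorization degenerates (non-finite factors),
#' it is retried with the next seed offsets.
#'
#' @param sub Non-negative symmetric contact submatrix.
#' @param n_components Factorization rank.
#' @param seed Integer seed.
#' @param max_retry Retries with incremented seed on failure (default 3).
#' @inheritParams nmf_fit
#' @return Integer vector of per-bin labels in `1..n_components`.
#' @export
nmf_cluster_once <- function(sub, n_components, seed = 0L,
                             max_iter = 200L, tol = 1e-4, max_retry = 3L) {
  for (try in 0:max_retry) {
    fit <- nmf_fit(sub, n_components, seed = seed + try * 1000003L,
                   max_iter = max_iter, tol = tol)
    if (all(is.finite(fit$h))) {
      if (try > 0) message(sprintf("NMF retried with seed offset %d", try))
      return(max.col(t(fit$h), ties.method = "first"))
    }
  }
  stopf("NMF failed to produce finite factors after %d retries", max_retry)
}
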