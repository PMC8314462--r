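# Independent brute-force evaluators used as oracles. These deliberately
# take the most literal route (explicit loops, closed-form distributions)
# and share no code with the package implementations they check.

# block-diagonal contact matrix: blocks of ones, optional within-block
# exponential distance decay
block_matrix <- function(block_sizes, decay = NULL) {
  blk <- rep(seq_along(block_sizes), block_sizes)
  v <- outer(blk, blk, "==") * 1.0
  if (!is.null(decay)) {
    pos <- seq_along(blk)
    v <- v * exp(-abs(outer(pos, pos, "-")) / decay)
  }
  v
}

random_labels <- function(n, max_k) {
  k <- sample(2:max_k, 1)
  sample(seq_len(k), n, replace = TRUE)
}

# random non-overlapping DomainSet, optionally with gaps
random_domain_set <- function(n_bins, n_domains, with_gaps = FALSE,
                              binsize = 40000L) {
  cuts <- sort(sample(1:(n_bins - 1), min(n_domains * 2, n_bins - 1)))
  cuts <- unique(c(0L, cuts, n_bins))
  starts <- cuts[-length(cuts)]
  ends <- cuts[-1]
  if (with_gaps && length(starts) > 2) {
    drop <- sample(seq_along(starts), max(1, length(starts) %/% 4))
    starts <- starts[-drop]; ends <- ends[-drop]
  }
  domain_set(starts, ends, n_bins, binsize = binsize)
}

# --- brute-force partition metrics on label vectors ---------------------

bf_entropy <- function(lab) {
  h <- 0
  for (cl in unique(lab)) {
    p <- sum(lab == cl) / length(lab)
    h <- h - p * log(p)
  }
  h
}

bf_mi <- function(t_lab, k_lab) {
  n <- length(t_lab)
  total <- 0
  for (ti in unique(t_lab)) {
    for (kj in unique(k_lab)) {
      nij <- sum(t_lab == ti & k_lab == kj)
      if (nij == 0) next
      pij <- nij / n
      total <- total + pij * log(pij / ((sum(t_lab == ti) / n) *
                                          (sum(k_lab == kj) / n)))
    }
  }
  total
}

# expected MI via the hypergeometric pmf (dhyper), a different route than
# the package's lgamma expression
bf_emi <- function(t_lab, k_lab) {
  n <- length(t_lab)
  a <- as.numeric(table(t_lab)); b <- as.numeric(table(k_lab))
  total <- 0
  for (ai in a) for (bj in b) {
    for (nij in max(1, ai + bj - n):min(ai, bj)) {
      pr <- stats::dhyper(nij, ai, n - ai, bj)
      total <- total + pr * nij / n * log(n * nij / (ai * bj))
    }
  }
  total
}

bf_ami <- function(t_lab, k_lab) {
  ht <- bf_entropy(t_lab); hk <- bf_entropy(k_lab)
  if (ht == 0 && hk == 0) return(1)
  emi <- bf_emi(t_lab, k_lab)
  (bf_mi(t_lab, k_lab) - emi) / (max(ht, hk) - emi)
}

bf_vi <- function(t_lab, k_lab) {
  bf_entropy(t_lab) + bf_entropy(k_lab) - 2 * bf_mi(t_lab, k_lab)
}

# brute-force WS on two DomainSets: literal double loop over domains
bf_ws <- function(t_dom, k_dom) {
  num <- 0; den <- 0
  for (j in seq_along(k_dom$starts)) {
    kbins <- k_dom$starts[j]:(k_dom$ends[j] - 1)
    best <- 0
    for (i in seq_along(t_dom$starts)) {
      tbins <- t_dom$starts[i]:(t_dom$ends[i] - 1)
      ov <- length(intersect(tbins, kbins))
      s <- ov / sqrt(length(tbins) * length(kbins))
      if (s > best) best <- s
    }
    num <- num + best * length(kbins)
    den <- den + length(kbins)
  }
  num / den
}

# brute-force structure entropy: literal translation of the two entropy
# sums (leading minus restored) with explicit bin loops (1-based
# positions, sentinels 1 and N+1)
bf_structure_entropy <- function(bound_bins0, f) {
  n <- nrow(f)
  cuts <- sort(unique(c(1, bound_bins0 + 1, n + 1)))  # 1-based starts
  num <- 0
  for (i in 1:n) for (j in 1:n) if (i != j) num <- num + f[i, j]
  se <- 0
  for (k in seq_len(length(cuts) - 1)) {
    seg <- cuts[k]:(cuts[k + 1] - 1)
    g <- 0
    for (a in seg) for (b in 1:n) if (b != a) g <- g + f[a, b]
    v <- 0
    for (a in seg) for (b in seg) if (b != a) v <- v + f[a, b]
    if (g > 0) se <- se - (g - v) / num * log(g / num) / log(n)
    for (j in seg) {
      dj <- 0
      for (b in 1:n) if (b != j) dj <- dj + f[j, b]
      if (dj > 0) se <- se - dj / num * log(dj / g) / log(n)
    }
  }
  se
}

# exhaustive local-minimum scan used as the detector oracle
bf_local_minima <- function(cr) {
  n <- length(cr)
  mins <- integer(0)
  for (i in seq_len(n)) {
    if (i < 4 || i > n - 3) next
    left <- sum(cr[i:(i + 2)]) - sum(cr[(i - 3):(i - 1)])
    right <- sum(cr[(i + 1):(i + 3)]) - sum(cr[(i - 2):i])
    if (left < 0 && right >= 0) mins <- c(mins, i)
  }
  mins
}

# naive insulation-minimum TAD caller (baseline for thinning stability):
# boundaries at strict local minima of the square insulation profile
insulation_baseline <- function(m, span = 10L) {
  cm <- if (inherits(m, "ContactMatrix")) m$counts else m
  n <- nrow(cm)
  ins <- rep(NA_real_, n)
  for (b in (span + 1):(n - span + 1)) {
    up <- (b - span):(b - 1)
    dn <- b:(b + span - 1)
    ins[b] <- mean(cm[up, dn])
  }
  bounds <- integer(0)
  for (b in 2:(n - 1)) {
    if (!is.na(ins[b]) && !is.na(ins[b - 1]) && !is.na(ins[b + 1]) &&
        ins[b] < ins[b - 1] && ins[b] < ins[b + 1])
      bounds <- c(bounds, b - 1L)  # 0-based
  }
  bounds
}
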