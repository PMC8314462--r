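test_that("mutual information matches its identities and a hand-evaluated sum", {
  lab <- rep(1:3, times = c(4, 3, 3))
  expect_equal(mutual_information(lab, lab), bf_entropy(lab))
  # T = {1..5}{6..10}, K = {1..4}{5..10}: hand evaluation of the double sum
  t_lab <- rep(1:2, each = 5)
  k_lab <- rep(1:2, times = c(4, 6))
  hand <- 4 / 10 * log((4 / 10) / (0.5 * 0.4)) +
    1 / 10 * log((1 / 10) / (0.5 * 0.6)) +
    5 / 10 * log((5 / 10) / (0.5 * 0.6))
  expect_equal(mutual_information(t_lab, k_lab), hand)
  expect_error(mutual_information(1:3, 1:4), "differ")
})

test_that("partition metrics satisfy their exact identities", {
  set.seed(21)
  for (r in 1:20) {
    n <- sample(10:40, 1)
    lab <- random_labels(n, 6)
    expect_equal(ami(lab, lab), 1)
    expect_equal(vi(lab, lab), 0)
    d <- random_domain_set(n, 4)
    expect_equal(ws(d, d), 1)
    expect_equal(bp_score(d, d), 0)
  }
  # VI of single cluster vs b equal blocks = log b
  for (b in c(2, 4, 5)) {
    one <- rep(1L, 20)
    blocks <- rep(seq_len(b), each = 20 / b)
    expect_equal(vi(one, blocks), log(b))
  }
  # VI = H + H - 2 MI on arbitrary pairs
  t_lab <- random_labels(30, 5); k_lab <- random_labels(30, 5)
  expect_equal(vi(t_lab, k_lab),
               bf_entropy(t_lab) + bf_entropy(k_lab) -
                 2 * mutual_information(t_lab, k_lab))
})

test_that("AMI is near zero for independent partitions and handles edge cases", {
  set.seed(22)
  vals <- replicate(100, {
    ami(random_labels(60, 4), random_labels(60, 4))
  })
  expect_lt(abs(mean(vals)), 0.05)
  expect_equal(ami(rep(1, 10), rep(1, 10)), 1)  # single cluster both
})

test_that("AMI agrees with the sklearn reference implementation", {
  set.seed(23)
  pairs <- lapply(1:5, function(i)
    list(t = random_labels(40, 5), k = random_labels(40, 5)))
  lines <- vapply(pairs, function(p)
    paste(c(p$t, p$k), collapse = ","), character(1))
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(lines, f)
  py <- paste(
    "import sys",
    "from sklearn.metrics import adjusted_mutual_info_score",
    "for line in open(sys.argv[1]):",
    "    v = [int(x) for x in line.split(',')]",
    "    n = len(v)//2",
    "    print(repr(adjusted_mutual_info_score(v[:n], v[n:], average_method='max')))",
    sep = "\n")
  out <- system2("python", c("-c", shQuote(py), f), stdout = TRUE)
  expect_length(out, 5)
  ref <- as.numeric(out)
  ours <- vapply(pairs, function(p) ami(p$t, p$k), numeric(1))
  expect_equal(ours, ref, tolerance = 1e-8)
})

test_that("WS follows its overlap formula, asymmetrically", {
  n <- 8
  t1 <- domain_set(0, 4, n)          # one 4-bin domain
  k1 <- domain_set(c(0, 2), c(2, 4), n)  # split in halves
  expect_equal(ws(t1, k1), 2 / sqrt(8))  # each S = 2/sqrt(8) -> 1/sqrt(2)
  expect_equal(ws(t1, k1), 1 / sqrt(2))
  expect_equal(ws(k1, t1), 2 / sqrt(8))  # equal here despite asymmetry
  # zero overlap
  t2 <- domain_set(0, 3, 10)
  k2 <- domain_set(5, 8, 10)
  expect_equal(ws(t2, k2), 0)
  expect_error(ws(t2, domain_set(integer(0), integer(0), 10)), "empty")
})

test_that("WS of a nested refinement differs by direction", {
  n <- 12
  coarse <- domain_set(0, 12, n)
  fine <- domain_set(c(0, 4, 8), c(4, 8, 12), n)
  # evaluated = fine: every K_j scores 4/sqrt(48)
  expect_equal(ws(coarse, fine), 4 / sqrt(48))
  # evaluated = coarse: single K scores max_i 4/sqrt(48)
  expect_equal(ws(fine, coarse), 4 / sqrt(48))
  # a genuinely asymmetric case
  t3 <- domain_set(c(0, 6), c(6, 12), n)
  expect_false(isTRUE(all.equal(ws(t3, fine), ws(fine, t3))))
})

test_that("BP distance is zero iff boundary sets coincide and is label-invariant", {
  a <- domain_set(c(0, 5), c(5, 10), 10)
  b <- domain_set(c(0, 5), c(5, 10), 10)
  expect_equal(bp_score(a, b), 0)
  c1 <- domain_set(c(0, 6), c(6, 10), 10)
  expect_gt(bp_score(a, c1), 0)
  expect_equal(bp_score(a, c1), bp_score(c1, a))
  # brute-force check of the implemented formula on boundary vectors
  bt <- c(3, 7); bk <- c(2, 9)
  exp_val <- (mean(c(1, 2)) + mean(c(1, 2))) / (2 * 12)
  expect_equal(bp_score(bt, bk, n_bins = 12), exp_val)
})

test_that("metric brute-force equivalence on random partition pairs", {
  set.seed(24)
  for (r in 1:15) {
    n <- sample(15:40, 1)
    t_lab <- random_labels(n, 5)
    k_lab <- random_labels(n, 5)
    expect_equal(mutual_information(t_lab, k_lab), bf_mi(t_lab, k_lab),
                 tolerance = 1e-12)
    expect_equal(ami(t_lab, k_lab), bf_ami(t_lab, k_lab), tolerance = 1e-10)
    expect_equal(vi(t_lab, k_lab), bf_vi(t_lab, k_lab), tolerance = 1e-12)
    td <- random_domain_set(n, 3)
    kd <- random_domain_set(n, 3)
    expect_equal(ws(td, kd), bf_ws(td, kd), tolerance = 1e-12)
  }
})

test_that("structure entropy matches brute force and prefers true partitions", {
  set.seed(25)
  f <- matrix(runif(900), 30); f <- f + t(f)
  m <- contact_matrix(f)
  b <- c(8, 17, 24)
  expect_equal(structure_entropy(b, m), bf_structure_entropy(b, f),
               tolerance = 1e-12)
  # zero-cut first term: contacts only inside one domain
  f2 <- matrix(0, 20, 20); f2[1:10, 1:10] <- 1; diag(f2) <- 0
  m2 <- contact_matrix(f2)
  se <- structure_entropy(c(10), m2)
  expect_equal(se, bf_structure_entropy(10, f2), tolerance = 1e-12)

  v <- block_matrix(rep(10, 4), decay = 5) * 20
  mb <- contact_matrix(v)
  truth <- c(10, 20, 30)
  expect_lt(structure_entropy(truth, mb),
            structure_entropy(c(5, 15, 25), mb))
})

test_that("structure entropy of a planted partition beats matched random ones", {
  set.seed(26)
  v <- block_matrix(rep(10, 4), decay = 5) * 20
  mb <- contact_matrix(v)
  se_true <- structure_entropy(c(10, 20, 30), mb)
  se_rand <- replicate(50, structure_entropy(sort(sample(1:39, 3)), mb))
  expect_gt(mean(se_true < se_rand), 0.95)
})

test_that("modularity is positive for true blocks, near zero for shuffles", {
  v <- block_matrix(rep(25, 6)) * 30  # 150 bins = one 6-Mb window at 40 kb
  m <- contact_matrix(v, binsize = 40000)
  truth <- domain_set(seq(0, 125, 25), seq(25, 150, 25), 150)
  expect_gt(modularity(truth, m), 0)
  set.seed(27)
  shuf <- replicate(100, {
    b <- sort(sample(1:149, 5))
    modularity(domains_from_boundaries(b, 150), m)
  })
  expect_gt(modularity(truth, m), max(shuf))
  expect_lt(median(shuf), modularity(truth, m) / 1.5)
  # uniform matrix: null-model cancellation
  mu <- contact_matrix(matrix(200, 150, 150), binsize = 40000)
  expect_lt(abs(modularity(truth, mu)), 5e-3)
  # window threshold: sparse matrix has no retained window
  ms <- contact_matrix(diag(0, 150), binsize = 40000)
  expect_error(modularity(truth, ms), "filtered|empty")
})

test_that("SE and modularity rank planted truth above matched-size shuffles", {
  set.seed(28)
  v <- block_matrix(rep(25, 6), decay = 10) * 30
  m <- contact_matrix(v, binsize = 40000)
  truth_b <- seq(25, 125, 25)
  mod_true <- modularity(domains_from_boundaries(truth_b, 150), m)
  mod_rand <- replicate(50, {
    b <- sort(sample(1:149, 5))
    modularity(domains_from_boundaries(b, 150), m)
  })
  expect_gt(mean(mod_true > mod_rand), 0.95)
})
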