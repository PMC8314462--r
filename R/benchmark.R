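#' Run configuration
#'
#' Bundles the detector, simulator and metric defaults used throughout
#' the package, so every run can be reproduced from its serialized
#' configuration. Defaults: 8-Mb windows at 40-kb bins, 10 NMF runs per
#' rank over ranks 8..13, boundary-strength cutoff 0.3, cluster-rate
#' width 11, 100-contact no-call threshold, 10,000 permutations.
#'
#' @param ... Overrides of the named defaults.
#' @return Object of class `RunConfig` (a named list).
#' @export
run_config <- function(...) {
  cfg <- list(L = 8e6, binsize = 40000L, k = 10L, n_range = 8:13,
              strength_cutoff = 0.3, cr_width = 11L, cr_anchor = "center",
              min_contacts = 100L, n_perm = 10000L,
              reads_cell = 1000, reads_reference = 350000,
              fine_binsize = 10000L, intra_scale = 1, inter_scale = 5,
              seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stopf("unknown config fields: %s",
                             paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "RunConfig")
}

#' Serialize a RunConfig as key=value lines
#' @param cfg A `RunConfig`.
#' @param path Output path (or `NULL` to return the lines).
#' @export
write_config <- function(cfg, path = NULL) {
  lines <- vapply(names(cfg), function(k)
    paste0(k, "=", paste(cfg[[k]], collapse = ",")), character(1))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(path)
}

#' Read a key=value configuration file
#' @param path Path to the file written by [write_config()].
#' @return A `RunConfig`.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- lapply(kv, function(x) {
    v <- strsplit(x[2], ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(v))
    if (!anyNA(num)) num else v
  })
  do.call(run_config, stats::setNames(vals, vapply(kv, `[[`, "", 1)))
}

#' End-to-end synthetic benchmark
#'
#' Simulates a population of single cells over a planted block layout,
#' detects TAD-like domains per cell, scores the calls against the
#' planted truth (AMI, WS, VI, BP) and against the per-cell deep
#' reference call, evaluates structure entropy and modularity of the
#' per-cell calls, and (when a second layout is given) classifies the two
#' planted populations and reports the AUC. All randomness derives from
#' `cfg$seed` via named substreams.
#'
#' @param cfg A [run_config()].
#' @param block_lengths Planted block lengths in fine bins (default five
#'   1.0-Mb domains in a 5-Mb region).
#' @param block_lengths_b Optional second layout for the classification
#'   arm (same total length).
#' @param n_cells Cells per population (default 20).
#' @return List with `per_cell` (data frame of per-cell scores),
#'   `summary` (medians), `auc` (or `NA`), and the `config`.
#' @export
run_benchmark <- function(cfg = run_config(), block_lengths = NULL,
                          block_lengths_b = NULL, n_cells = 20L) {
  block_lengths <- block_lengths %||% c(80L, 120L, 100L, 80L, 120L)
  pop <- simulate_cell_population(
    block_lengths, n_cells = n_cells,
    reads_cell = cfg$reads_cell * sum(block_lengths) / 500,
    reads_reference = cfg$reads_reference * sum(block_lengths) / 500,
    intra_scale = cfg$intra_scale, inter_scale = cfg$inter_scale,
    fine_binsize = cfg$fine_binsize, out_binsize = cfg$binsize,
    with_reference = TRUE, seed = sub_seed(cfg$seed, "simulate"))
  truth <- pop$truth
  det <- function(m) detect_chromosome(
    m, L = cfg$L, min_contacts = cfg$min_contacts, n_range = cfg$n_range,
    k = cfg$k, strength_cutoff = cfg$strength_cutoff,
    cr_width = cfg$cr_width, cr_anchor = cfg$cr_anchor,
    seed_base = sub_seed(cfg$seed, "nmf"))
  rows <- vector("list", n_cells)
  for (c in seq_len(n_cells)) {
    call_c <- det(pop$cells[[c]])
    call_r <- det(pop$references[[c]])
    rows[[c]] <- data.frame(
      cell = c,
      n_domains = length(call_c),
      ami_truth = ami(truth, call_c),
      ws_truth = ws(truth, call_c),
      vi_truth = vi(truth, call_c),
      bp_truth = bp_score(truth, call_c),
      ami_reference = ami(call_r, call_c),
      se = structure_entropy(call_c, pop$cells[[c]]),
      modularity = tryCatch(
        modularity(call_c, pop$cells[[c]],
                   min_contacts = cfg$min_contacts),
        error = function(e) NA_real_))
  }
  per_cell <- do.call(rbind, rows)
  auc <- NA_real_
  if (!is.null(block_lengths_b)) {
    pop_b <- simulate_cell_population(
      block_lengths_b, n_cells = n_cells,
      reads_cell = cfg$reads_cell * sum(block_lengths_b) / 500,
      intra_scale = cfg$intra_scale, inter_scale = cfg$inter_scale,
      fine_binsize = cfg$fine_binsize, out_binsize = cfg$binsize,
      seed = sub_seed(cfg$seed, "simulate-b"))
    calls <- c(lapply(pop$cells, det), lapply(pop_b$cells, det))
    labels <- rep(c("A", "B"), each = n_cells)
    auc <- cell_classification(calls, labels = labels)$auc
  }
  list(per_cell = per_cell,
       summary = c(ami_truth_median = stats::median(per_cell$ami_truth),
                   ws_truth_median = stats::median(per_cell$ws_truth),
                   vi_truth_median = stats::median(per_cell$vi_truth),
                   bp_truth_median = stats::median(per_cell$bp_truth),
                   ami_reference_median = stats::median(per_cell$ami_reference)),
       auc = auc, config = cfg)
}
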