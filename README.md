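# sctad

Detection and analysis of **TAD-like domains in ultra-sparse single-cell
Hi-C** contact matrices.

In a single cell every locus exists in at most two copies, so a
single-cell Hi-C library yields on the order of 1,000 contacts per 5-Mb
region — a 40-kb-bin contact matrix that is >90% zeros, far below what
insulation- or segmentation-based TAD callers tolerate. `sctad` detects
domain boundaries in this regime by **consensus clustering over repeated
non-negative matrix factorizations** (NMF) of 8-Mb sliding windows:

1. For each candidate rank *n* (default 8..13), factorize the window's
   contact submatrix *k* = 10 times with seeded random initializations;
   bin *j* joins the component maximizing column *j* of the coefficient
   matrix.
2. Summarize the runs in a consensus map *C* (fraction of runs
   co-clustering each bin pair) and its **cluster-rate profile** (mean
   of *C* over an 11-bin diagonal square), whose local minima — scored
   by a strength rule (top *n* − 1 plus all minima above 0.3) — are the
   candidate boundaries.
3. Pick the rank whose segmentation maximizes a silhouette on
   *D* = 1 − *C*; report calls from the middle half of each window and
   stitch windows into the chromosome-wide domain set.

The package also provides:

* a **single-cell Hi-C simulator** driven by 3D particle chains
  (reference Hi-C: Poisson sampling with 1/distance weights, 0.35 M
  reads per 5 Mb; single cells: multinomial sampling with
  max(D − distance, 0) weights, 1,000 reads per 5 Mb), plus a
  block-globule conformation generator with planted ground-truth
  domains;
* **partition-similarity metrics** — mutual information, adjusted
  mutual information (AMI), weighted similarity (WS), variation of
  information (VI), boundary-point distance (BP);
* **structure-quality indices** — structure entropy (lower = better)
  and contact-network modularity (higher = better);
* **boundary enrichment** — aggregate peak profiles (MNPPB) with
  bootstrap bands and permutation tests;
* **boundary dynamics across cells** — matched/merged/split/shifted
  classes, binomial boundary popularity, single-cell-specific boundary
  (scSB) classes with permutation controls, nested/unnested and
  condition-specific boundaries, unsupervised cell classification from
  domain structure alone, and intra- vs inter-domain signal
  correlation.

See `vignettes/domain-detection-methods.Rmd` for the model, parameter
and design details.

## Worked example

Simulate ten single cells of a 5-Mb region with planted domains of
0.4–1.2 Mb, detect domains in one cell, and score the call:

```r
library(sctad)

pop <- simulate_cell_population(
  block_lengths = c(60, 100, 40, 120, 80, 100),  # fine 10-kb bins
  n_cells = 10, reads_cell = 1000, inter_scale = 5, seed = 7)
pop$cells[[1]]
#> ContactMatrix: chr1, 125 bins @ 40000 bp, 1000 total contacts, sparsity 0.900
boundaries(pop$truth)
#> [1]  15  40  50  80 100

call <- detect_chromosome(pop$cells[[1]])
boundaries(call)
#> [1]  19  30  39  52  79 103 110
round(c(AMI = ami(pop$truth, call), WS = ws(pop$truth, call),
        VI = vi(pop$truth, call), BP = bp_score(pop$truth, call)), 3)
#>   AMI    WS    VI    BP
#> 0.723 0.831 0.761 0.027
```

From 1,000 contacts (90% of matrix entries zero) the detector places
boundaries at or within a bin or two of most planted positions
(15/40/50/80/100): AMI 0.72 and WS 0.83 against the truth, versus ≈0.65
for a size-matched random boundary set. Bin indices are 0-based; bin
*b* covers `[b*binsize, (b+1)*binsize)`, and `write_domains_bed()`
emits standard BED3.

A thin command-line front end wrapping these functions ships in
`inst/cli/sctad.R`
(`Rscript inst/cli/sctad.R detect --matrix m.txt --out domains.bed`,
plus `simulate`, `compare`, `quality`, `enrich`, `benchmark`
subcommands).

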