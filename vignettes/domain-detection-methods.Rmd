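---
title: "Detecting TAD-like domains in ultra-sparse single-cell Hi-C"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting TAD-like domains in ultra-sparse single-cell Hi-C}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sctad)
```

## The problem

Topologically associating domains (TADs) are contiguous genomic intervals
whose loci contact each other more than they contact flanking sequence;
on a bulk Hi-C map they appear as blocks along the diagonal. In a single
cell, each locus exists in at most two copies, so a single-cell Hi-C
library carries on the order of 1,000 contacts per 5-Mb region — a
matrix at 40-kb bins that is more than 90% zeros. Insulation- and
segmentation-style callers degrade badly in this regime. This package
detects *TAD-like domains* (the single-cell counterpart of TADs, which
need not coincide with the population consensus) directly from such
ultra-sparse matrices, and provides the simulation and evaluation
machinery needed to study their cell-to-cell dynamics.

## The detector

The chromosome is tiled with 8-Mb windows overlapping by 4 Mb; windows
with fewer than 100 intra-window contacts are flagged no-call. Within a
window of $m$ bins the contact submatrix $V$ is factorized as
$V \approx WH$ by non-negative matrix factorization (NMF) at rank $n$;
bin $j$ is assigned to the component with the largest entry in column
$j$ of the coefficient matrix $H$ (ties to the lowest index). Because a
single factorization of sparse data is unstable, the assignment is
repeated $k = 10$ times with seeds $0..k-1$, and summarized by the
consensus map
$$C_{ij} = \frac{\#\{\text{runs co-clustering } i, j\}}{k},$$
whose low-rank averaging is what recovers signal from the sparse input.

The *cluster rate* $CR_i$ is the mean of $C$ over a $w \times w$
diagonal square at bin $i$ ($w = 11$); it is near 1 deep inside a
domain and dips where cluster membership changes. Candidate boundaries
are bins satisfying the smoothed falling-to-rising condition
$$\sum_{j=i}^{i+2} CR_j - \sum_{j=i-3}^{i-1} CR_j < 0 \le
  \sum_{j=i+1}^{i+3} CR_j - \sum_{j=i-2}^{i} CR_j,$$
and each minimum's *strength* is the largest $CR$ between its
neighbouring minima minus its own $CR$. The called boundaries are the
union of the $n - 1$ strongest minima and all minima with strength
above 0.3.

The rank $n$ is not known in advance. For each candidate in 8..13 (a
range matched to mammalian TAD sizes in an 8-Mb window at 40 kb), the
induced segmentation is scored by a silhouette on the dissimilarity
$D = 1 - C$: per bin, the between-segment mean minus the within-segment
mean over their maximum, summed and divided by the window length. The
rank with the largest silhouette wins (ties to the smaller rank), and
the winning boundary calls in the middle half of each window are
stitched into the chromosome-wide call, with the terminal windows
extending their report intervals to the chromosome ends.

### Numerical choices

* **NMF solver.** Frobenius loss with Lee–Seung multiplicative updates,
  at most 200 iterations, stopping when the loss decreases by less than
  a relative $10^{-4}$ (checked every 10 iterations). Initialization is
  half-normal noise scaled by $\sqrt{\bar V / n}$, seeded, so a fixed
  seed base makes the whole detection bit-reproducible.
* **Cluster-rate anchoring.** The $w \times w$ square at bin $i$ spans
  bins $[i - \lceil w/2 \rceil,\, i + \lfloor w/2 \rfloor - 1]$, i.e.
  bin $i$ is the first bin of the downstream half. With this centring a
  dip indexes exactly the first bin of the downstream domain: on an
  exact two-block consensus map the minimum lands on the junction bin.
  Anchoring the square's top-left corner at $(i, i)$ instead (available
  as `cr_anchor = "corner"` for sensitivity analysis) shifts every
  minimum about $\lceil w/2 \rceil$ bins upstream of the junction, which
  is why it is not the default.
* **Degenerate silhouettes.** A bin whose segment spans the whole window
  has no between set; its term is defined as 0.
* **Saturation in the noiseless limit.** On an exactly block-diagonal
  matrix, every rank at or below the true block count yields perfect
  within-block consensus, so the silhouette equals exactly 1 for all of
  them and the tie rule returns the smallest candidate rank. The
  *boundaries* are unaffected (they are recovered exactly for any such
  rank); only the reported rank is conservative. Real matrices are never
  noiseless, so the silhouette discriminates in practice.
* **Seams.** Report intervals partition the chromosome exactly once, so
  a boundary can only be claimed by one window; duplicates cannot arise
  except at interval edges, where calls are de-duplicated by bin.

## The simulator

Contact maps are sampled from 3D particle chains (one particle per
10-kb fine bin):

* **Reference (deep) Hi-C:** pair weights $1/d_{ij}$, normalized;
  counts are Poisson with mean $w_{ij} \times R$, with
  $R = 0.35\,\mathrm{M}$ reads per 5 Mb — deep-coverage bulk.
* **Single-cell Hi-C:** only pairs with $d_{ij} < D$ can ligate, with
  weight $D - d_{ij}$, normalized; the read budget (1,000 per 5 Mb) is
  partitioned over pairs by a single multinomial draw, so each pair is
  marginally binomial and the total is exact. A strict per-pair
  independent binomial mode is available (`mode = "binomial"`); it
  differs only in letting the total fluctuate. The threshold $D$ is
  taken as a quantile (0.2/0.4/0.6) of the pairwise distance
  distribution. Self pairs are excluded from both schemes, and
  coincident particles are rejected rather than given infinite weight.

Fine-bin matrices are aggregated 4-fold to 40-kb bins by summing unique
pairs (upper triangle including the diagonal), which conserves the read
total exactly at every resolution.

The synthetic conformation generator plants ground-truth domains as
spatial globules: block centres take random-walk steps with
per-coordinate standard deviation `inter_scale` and particles scatter
isotropically (`intra_scale`) around their centre. The
`inter_scale/intra_scale` ratio is the single knob controlling domain
strength; at ratio 1 the chain has no block structure and detection
falls to chance, at ratio 5 domains are well separated. A literal
stepwise random walk with variance contrast does *not* make blocks
spatially compact (a block's end-to-end spread grows with its length
and swamps the junction steps), which is why the globule construction
is used. What the generator does **not** emulate: distance-dependent
contact decay within domains beyond what the globule geometry induces,
nested or hierarchical domains, compartment-scale checkerboards,
unmappable regions, and PCR duplication noise. Passing tests on this
generator therefore demonstrate recovery of planted segmentation
structure under realistic sparsity, not performance on every feature of
experimental data.

## Metrics

Partition agreement: mutual information and adjusted mutual information
(AMI; expected MI under the hypergeometric permutation model,
max-entropy normalization), variation of information
($VI = H_T + H_K - 2\,MI$), the asymmetric weighted similarity
$$WS(T, K) = \frac{\sum_j \max_i \frac{|T_i \cap K_j|}
{\sqrt{|T_i||K_j|}}\,|K_j|}{\sum_j |K_j|},$$
with the reference in $T$ and gaps excluded, and a boundary-point
distance (BP) — reconstructed from its benchmarking citation as the
symmetrized mean nearest-boundary distance normalized by the bin count;
its contract is the brute-force self-consistency test shipped with the
package. AMI/MI/VI include gap bins, each contiguous gap as its own
cluster by default (`gap_mode` switches to a single shared gap
cluster). Natural logarithms are used throughout; the base cancels in
AMI.

Structural quality: *structure entropy* (two-term partition entropy of
the contact graph; the conventional leading minus is kept so that lower
values mean better-insulated domains) and *modularity* (per 6-Mb
window, on the log-transformed, diagonal-removed matrix
$E = \log(1 + \text{counts})$, summed over intra-domain pairs and
averaged over windows with at least 100 contacts). On strong planted
blocks both rank the true partition ahead of matched-size random
partitions; on a uniform matrix modularity cancels to ~0.

Boundary enrichment: the MNPPB profile (mean number of peaks per bin at
offsets −10..10 from boundaries; peaks are assigned to bins by their
midpoints) with a 1,000-replicate bootstrap band, and a permutation
test of the central three bins against uniformly repositioned
boundaries (default 10,000 permutations, add-one p-value).

## Dynamics across cells

Ensemble domains are classified per cell as matched / merged / split /
shifted using ±100-kb boundary regions; boundary identity across cells
is same-bin by default (a ±1-bin tolerant mode exists). Boundary
popularity is modelled as $B(n_\text{cells}, \hat p)$ with $\hat p$ the
mean per-cell occurrence frequency; with the conventional thresholds
for a 150-cell population, boundaries in more than 12 cells are
popular and fewer than 6 unpopular, and tail-count deviation from the
binomial null is assessed by Monte Carlo. Note the fitted null uses
$\hat p$ from the data: a catalog where every boundary is in every cell
saturates the null and shows no deviation — the test detects
*overdispersion*, not high frequency per se. Cell-specific boundaries
(scSBs, absent from the ensemble) are classed by carrying-cell count
(1 / 2 / >2) against a permutation control that repositions each
cell's boundaries over mappable bins. Nested vs unnested ensemble
boundaries are the top/bottom 20 by cross-boundary contacts over
±400 kb after dropping the 20 lowest (unmappable artifacts);
condition-specific boundaries are the top/bottom 400 bins by
occurrence-frequency bias between two groups.

Cell classification reduces each cell and chromosome to the sign of its
loading on the first principal component of the Spearman-correlated WS
similarity matrix, scores cell pairs by sign agreement across
chromosomes (missing chromosomes contribute 0 and drop from the
denominator), and takes the first principal component of that agreement
matrix as the classification index; with labels, performance is the ROC
AUC, reported as $\max(\text{AUC}, 1-\text{AUC})$ because the PC sign
is arbitrary. Signal coupling across boundaries (e.g. DNA methylation)
is measured as the mean across-cell Pearson correlation of bin pairs at
a fixed 240-kb separation, split into intra- and inter-domain groups
(per-cell majority vote when per-cell domain sets are supplied) and
compared by Fisher's z with the number of contributing pairs as the
variance unit.

## Problem sizes used in the shipped checks

The package's tests and the acceptance script run entirely on synthetic
data sized for a desktop: 5-Mb regions (125 bins at 40 kb) with 50
cells for detection accuracy, a 20-Mb bulk region for thinning
stability, 30 replicates of two 8- and 5-cell populations for
classification, and 100 replicates for null calibrations. These sizes
were chosen so the whole suite completes in tens of minutes on one
core while keeping every statistical check adequately powered.

## Known limitations

* The silhouette cannot distinguish ranks below the true block count on
  exactly noiseless input (see above); the reported rank is then the
  smallest tied candidate.
* BP is a reconstruction from a citation, not a re-implementation of a
  published formula.
* The simulator's single-conformation-per-cell assumption ignores the
  two homologous copies of each locus in a diploid cell.
* No imputation is provided; externally imputed matrices can be fed in
  as ordinary dense/triplet input.
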