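# nitramp

Processing-method sensitivity analysis for protein-coding functional-gene
amplicons.

## The problem

Amplicon surveys of nitrogen-cycle genes (*amoA*, *nxrB*, *nirS*, *nirK*,
*nrfA*) must turn raw reads into countable features before any ecology can
be done, and the field has no consensus on how: OTU clustering is used at
thresholds anywhere from 97% down to 82% identity depending on the gene,
while exact-variant (ASV) denoising drops the threshold entirely. Because
the markers are protein-coding, a further screen is available that 16S
pipelines lack: a feature whose translation contains a stop codon, has the
wrong length, or no longer aligns to the target enzyme is an artifact and
should be removed. `nitramp` implements this whole decision space as a
tested pipeline so that the sensitivity of downstream conclusions — alpha
and beta diversity, PERMANOVA group effects, Mantel agreement between
methods, CCA driver selection, tree congruence, taxonomy — to the
processing choices can be measured on communities with known ground truth.

For whom: microbial ecologists who want to know whether a reported
ridge-vs-runnel (or any two-group) effect would survive a different
clustering threshold, and method developers who need a controlled test bed
for functional-gene pipelines.

## What is inside

* **Synthetic communities** with planted truth: stop-free coding genes,
  taxa at controlled identities, a two-group abundance effect, per-base
  substitution/indel errors, single-breakpoint chimeras, paired reads
  with quality strings (`make_reference_panel()`, `derive_taxa()`,
  `assign_abundances()`, `simulate_amplicons()`, `write_fixture()`).
* **Protein QC** (`qc_feature_set()`): six-frame detection, translation,
  stop-codon screen, length gate, Smith–Waterman enzyme verification
  (BLOSUM62, identity ≥ 0.5 over coverage ≥ 0.7), table curation and a
  Table-style summary (% wrong features, % reads retained, size
  histogram).
* **Two reconstruction routes**: greedy centroid clustering at any
  identity threshold, and an abundance-skew exact-variant denoiser
  (merge when `abund(child)/abund(parent) ≤ 2^-(2d+1)` at edit distance
  d), plus quality trimming, pair merging, dereplication, singleton
  discard and de novo bimera flagging.
* **Diversity & inference**: rarefaction (analytic expectation +
  hypergeometric draws), Shannon/Gini–Simpson, Bray–Curtis, JC69 + NJ
  trees, unweighted/weighted UniFrac, Mantel (9,999 permutations,
  two-sided), PERMANOVA (pseudo-F, R², 999 permutations), Hellinger +
  CCA with both-direction stepwise driver selection.
* **Tree congruence**: features added one at a time in descending
  abundance to reference-anchored NJ trees for two methods, normalized
  Robinson–Foulds at each step, and the fit `RF = a·ln(n) + b`.
* **Taxonomy**: an RDP-style naive Bayesian 8-mer classifier and a
  BLCA-style alignment + lowest-common-ancestor classifier, with a
  near/distant synthetic reference-database contrast.

The model statistics: PERMANOVA partitions distance-based sums of squares,
`F = (SS_B/(g-1))/(SS_W/(n-g))`, `R² = SS_B/SS_T`, with label-permutation
p-values under the +1 convention; Mantel correlates lower-triangle
distances with the same convention; weighted UniFrac is
`Σ_b l_b |A_b - B_b| / Σ_b l_b (A_b + B_b)` over branches b with
descendant read fractions A, B.

## Worked example

```r
library(nitramp)

cfg <- run_config(aa_length = 80, n_taxa = 14, target_identity = 0.92,
                  n_reads_per_sample = 1500, rarefaction_depth = 1000,
                  effect_fold = 4, effect_frac = 0.25, seed = 1)
rep <- run_pipeline(cfg)
rep$feature_summary
#> # A tibble: 5 × 5
#>   method  n_features n_chimeric pct_wrong_features pct_reads_retained
#>   <chr>        <int>      <int>              <dbl>              <dbl>
#> 1 ASV             14          1                  0                100
#> 2 OTU-97%         14          1                  0                100
#> 3 OTU-95%         14          0                  0                100
#> 4 OTU-90%         14          0                  0                100
#> 5 OTU-85%          1          0                  0                100
```

Reading this: the exact-variant route resolves all 14 planted taxa, and
because the community was generated at ~92% mean identity to its
reference gene, clustering anywhere above that keeps them apart too —
but OTU-85% collapses the entire community into a single feature.
Resolution lost this way is exactly what makes a planted two-group
effect detectable at fine resolution and invisible at OTU-85% (whose
one-feature table supports no distance at all here):

```r
subset(rep$permanova, metric == "WU")
#>    method metric pseudo_F        R2     p
#>       ASV     WU 67.31330 0.9439095 0.099
#>   OTU-97%     WU 83.23775 0.9541483 0.099
#>   OTU-95%     WU 84.08581 0.9545897 0.099
#>   OTU-90%     WU 84.92511 0.9550183 0.099
```

(with 3 replicates per group the attainable permutation p floors at
~0.1; the bundled tests use 6 replicates per group to demonstrate the
significant/non-significant contrast at p ≤ 0.01 vs p > 0.05). `rep$mantel` holds
the between-method distance-matrix correlations, `rep$cca_drivers` the
stepwise-selected covariates per method, `rep$congruence` the
Robinson–Foulds curve and its log fit, and `rep$taxonomy` the
near/distant database contrast for the two classifiers.

Plot helpers: `plot_permanova_grid()`, `plot_mantel_grid()`,
`plot_qc_sizes()`, `plot_rarefaction()`, `autoplot()` on congruence
curves. `tidy()`/`glance()` methods cover the fitted result objects.

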