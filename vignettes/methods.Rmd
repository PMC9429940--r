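---
title: "How amplicon processing choices move ecological conclusions: the nitramp methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How amplicon processing choices move ecological conclusions: the nitramp methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitramp)
```

## The question the package addresses

Functional-gene amplicon surveys (nitrogen-cycle markers such as *amoA*,
*nxrB*, *nirS*, *nirK* and *nrfA*) have no agreed identity threshold for
building OTUs, and exact-variant (ASV) denoising removes the threshold
altogether. Because these genes are protein-coding, a second axis of choice
appears: how aggressively to remove features whose translation is not a
plausible fragment of the target enzyme. `nitramp` implements both
reconstruction routes, the protein-verification quality check, the full
beta-diversity/inference layer, an incremental tree-congruence procedure,
and two taxonomy classifiers, all driven by a seeded synthetic community
generator so that every claim in the package is checkable against planted
ground truth.

## The synthetic community generator

`make_reference_panel()` draws stop-free coding genes (random non-stop
codons); `derive_taxa()` places substitutions at third codon positions
(frame-preserving mode) so derived taxa still translate cleanly, or at
uniform positions when frame-breaking divergence is wanted. Realised
identity to the reference is exact (`1 - round((1-t)L)/L`) because
divergence is substitution-only.

`assign_abundances()` draws one lognormal base profile (default
`sigma = 1`, a typical skew for amplicon communities) and multiplies a
fraction of taxa in group 2 by a fold factor before renormalising; the
two-group layout mirrors a paired sedimentary-structure contrast (e.g.
ridges vs runnels) with replicate cores per group.
`simulate_amplicons()` draws reads multinomially, applies per-base
substitutions and single-base indels, and with a configurable probability
replaces a read by a single-breakpoint chimera of two profile-sampled
parents; the breakpoint is uniform in the middle 60% of the amplicon so
both parents contribute detectable segments. Paired mode emits
overlapping read pairs with constant-Q37 Phred+33 strings plus an
optional linear 3' decay -- enough structure to exercise trimming and
merging without pretending to model a sequencer. Every event is recorded
in a truth table, one row per read.

What the generator deliberately does not emulate: PCR amplification bias,
polymerase error spectra, flow-cell artifacts, or position-dependent
error models. Passing tests therefore demonstrate correctness of the
algorithms under controlled noise, not robustness to every real-data
pathology.

## Protein quality check

The decision tree is: detect the reading frame (all six frames, best
local BLOSUM62 alignment against a reference protein panel; ties broken
by fewest stops, then forward strand, then smallest offset); translate;
reject any feature whose translation contains a stop codon anywhere --
the amplicon is internal to the ORF, so no terminal-stop exception is
made; accept stop-free proteins of exactly the expected length
(`floor(expected_nt/3)`, tolerance configurable, default 0); and submit
length-anomalous proteins to Smith-Waterman verification (gap open 11 /
extend 1), passing them when identity is at least 0.5 over at least 0.7
of the query. The verification stage replaces a manual BLASTp-vs-nr check
with a deterministic alignment against a bundled panel; the contract --
"does this still encode the expected enzyme?" -- is the same, and the
cutoffs are configuration, not biology. Frame detection is per-feature
rather than per-gene: strictly safer with mixed-orientation reads, and
identical on clean data.

A deliberately constructed test shows why the length gate cannot work
alone: an in-frame codon deletion and a frameshift can produce proteins
of similar (wrong) lengths, and only the alignment step separates them.

## Feature reconstruction

Both routes start from pooled exact dereplication (decreasing abundance,
lexicographic ties) and singleton discard, in that order, followed by
clustering/denoising and then de novo bimera flagging.

**OTU route.** `greedy_cluster()` scans uniques in decreasing-abundance
order; a sequence founds a centroid exactly when its identity to every
earlier centroid is below the threshold, otherwise it joins the eligible
centroid of maximal identity. Identity everywhere is global alignment
(match +2, mismatch -3, gap open 5 / extend 2, a length-L gap costing
open + L*extend) with terminal-gap columns excluded from the denominator.
Centroid discovery is exact; the maximal-identity assignment restricts
candidates to the `screen_top = 4` centroids sharing most 5-mers (plus
the centroid that proved the sequence clusterable), the standard
prefilter trick of threshold-clustering tools. With at most four eligible
centroids the assignment is exact; beyond that, a sequence is guaranteed
an assignment satisfying the >= t invariant, and only the "maximal"
part is heuristic. Read-to-feature mapping reuses the clustering
threshold (the upstream tools do not state a separate mapping identity).

**Variant route.** `denoise()` is an abundance-skew caller: candidate c
merges into the nearest accepted variant v at edit distance d >= 1 when
`abund(c)/abund(v) <= 2^-(alpha*d + 1)` (default `alpha = 2`), otherwise
it becomes a new variant. This is a UNOISE-style stand-in for per-run
error-model denoisers: it keeps the contract that matters for the
comparisons here -- single-nucleotide resolution whenever both variants
are abundant, no similarity threshold -- while remaining deterministic
and desk-scale. It is documented as a stand-in, not a reimplementation
of any specific tool.

**Bimeras.** For each candidate, parents are uniques at least `abskew = 2`
times more abundant; over all parent pairs and breakpoints the best
two-segment model is assembled from per-parent match profiles, and the
candidate is flagged when the model reaches 0.99 identity and beats the
best single parent by 0.02. Reference-based chimera filtering is out of
scope; only the de novo step is implemented.

## Diversity and inference

Alpha diversity: analytic rarefaction richness (hypergeometric
expectation, via `vegan::rarefy`), Shannon (nats) and Gini-Simpson on a
single seeded rarefied draw at depth 10,000 by default; samples under
depth are excluded, never an error. Using the analytic expectation for
richness and one draw for the entropies mirrors common practice when a
single rarefied table is carried forward; averaging draws would shrink
the entropies' variance but not their centre.

Beta diversity: Bray-Curtis (vegan), and UniFrac computed on
neighbor-joining trees built from JC69-corrected alignment p-distances
(saturated pairs, p >= 0.749, are capped at a configurable maximum,
default 5 substitutions/site). The NJ + JC69 combination replaces an
aligner + approximate-ML tool: it is deterministic, dependency-free and
sufficient for distance-based beta diversity at this scale. The weighted
UniFrac default is the normalized form so values are comparable with the
unweighted variant ([0,1]); the raw form is available because upstream
conventions differ.

`mantel_test()` (default 9,999 permutations, two-sided) and
`permanova()` (default 999 permutations, the convention of the usual
implementation) both use the +1 permutation convention, so p-values lie
in `[1/(n_perm+1), 1]`; note that with few samples, relabelings that
reproduce the same partition keep the attainable minimum slightly above
the floor. Both are vectorised over permutations and cross-checked in
the tests against `vegan::mantel` and `vegan::adonis2`.

CCA operates on Hellinger-transformed tables with centred/scaled
covariates via `vegan::cca`, and `stepwise_select()` wraps
`vegan::ordistep(direction = "both")` with `p_in = 0.05`,
`p_out = 0.10` and 199 permutations per marginal test -- the one-factor
-at-a-time permutation scheme, chosen for reproducibility under a fixed
seed.

## Tree congruence

`incremental_congruence()` adds features one at a time in descending
abundance to reference-anchored NJ trees for each method, rebuilding the
tree from scratch at every step, and reports the normalized
Robinson-Foulds distance at each size. Because the two methods' feature
labels can never match, RF is computed on the induced topologies over
the shared reference tips after pruning the added features -- the only
reading under which an equal-tip-set RF is well defined; the curve stops
at the size of the smaller feature set. Normalization divides by the
total number of non-trivial bipartitions in both trees, which stays in
[0,1] for non-binary trees too. `fit_log_curve()` fits
`rf = a ln(n) + b` by ordinary least squares.

## Taxonomy classifiers

`nbc_classify()` is an RDP-style naive Bayesian 8-mer classifier: word
priors `(n(w)+0.5)/(N+1)`, species conditionals `(m(w,s)+P(w))/(M_s+1)`,
100 bootstraps each drawing one eighth of the query's distinct words,
per-rank confidence as bootstrap agreement with the modal lineage, 0.8
assignment cutoff. Duplicate (lineage, sequence) entries are collapsed
before modelling so that depositing the same reference twice cannot
change a call. `blca_classify()` aligns the query against the database,
keeps hits at >= 0.80 identity within 0.02 of the best hit, bootstraps
alignment columns, spreads one unit of weight per bootstrap across hits
proportionally to resampled score, and assigns the modal taxon at each
rank reaching 0.80 confidence -- the lowest-common-ancestor behaviour
with per-rank confidences. The published tools' exact internals are not
reproduced; parameters follow their documented conventions and are all
configuration keys.

`build_synthetic_db()` creates the near/distant database contrast:
genus 1 / species 1 sits exactly at the configured divergence from the
reference gene and further lineages are staggered a full divergence step
apart, so query-generating taxa always have one clearly nearest lineage.
On the distant database the LCA route finds no qualifying hits and
reports UNASSIGNED, while the k-mer route still commits to the nearest
species -- the qualitative pattern that motivates recommending an
environment-relevant database for LCA classification.

## Numerical choices and degenerate inputs

* Identity is `pid` type 1 on the global alignment: matches over
  alignment columns excluding terminal gaps; internal gap columns count
  against identity. Ends-free scoring was rejected because it clips
  divergent pairs to short high-identity cores.
* NJ breaks Q-criterion ties by label order and clamps negative branch
  estimates to zero, transferring the deficit to the sibling so the pair
  path length is preserved; additive matrices are recovered exactly.
* Pair merging requires a best ungapped overlap of at least
  `min_overlap` (20 by default, 4 for genes whose reads barely overlap)
  *and* at least 0.75 identity across the overlap, so random abutments
  are not merged; the 0.75 floor is this package's own guard, stated
  here because upstream descriptions leave "qualifying overlap"
  implicit.
* Single-feature tables rarefy trivially (each kept sample becomes the
  depth) and are excluded from tree-based metrics, which need three
  features; the pipeline reports such routes with Bray-Curtis only.
* A constant distance matrix makes the Mantel correlation undefined and
  is an error; `run_pipeline()` skips such pairs rather than aborting
  the whole comparison.
* All randomness flows from one master seed; `run_pipeline()` expands it
  into per-stage seeds by a fixed affine map, so any stage can be re-run
  in isolation.

## Problem sizes

The bundled experiment sizes are chosen so the whole package exercises
in minutes on one core: communities of 8-20 taxa over amplicons of
150-300 nt, 6-12 samples of 400-2,500 reads, permutation tests at their
conventional counts (999 / 9,999), null-calibration batteries of a few
hundred replicates, and Monte-Carlo rarefaction checks at depth 1,000.
These sizes are statements about the fixtures, not about the method:
every routine accepts full-scale inputs.

## Known limitations

* The denoiser is an abundance-skew rule, not a fitted error model; it
  will under-split when genuine variants are very rare and over-split
  under heavy-tailed error processes the generator does not produce.
* The maximal-identity cluster assignment is k-mer-prescreened (exact
  for up to four eligible centroids); pathological communities with many
  near-tied centroids could see a member assigned to its second-best
  centroid, though never in violation of the threshold invariant.
* UniFrac is computed on the rooted representation of the `phylo`
  object; unweighted UniFrac on trees rooted elsewhere can differ
  slightly, as it does across published implementations.
* The classifiers operate on nucleotides only; amino-acid-level
  classification and phylogenetic placement are out of scope.
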