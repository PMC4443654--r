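---
title: "Methods: recovering higher-order chromatin organisation from contact maps and chromatin features"
author: "chromarch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recovering higher-order chromatin organisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromarch)
```

# Overview

Interphase chromosomes organise at several scales. At the megabase scale,
Hi-C contact maps partition the genome into two alternating classes of
regions — the transcriptionally active, more centrally positioned **A
compartment** and the repressive, more peripheral **B compartment** —
visible as a checkerboard of enriched/depleted long-range contacts. At the
sub-megabase scale, **topologically associating domains (TADs)** are
stretches of preferentially self-interacting chromatin whose boundaries act
as insulation points. `chromarch` implements an end-to-end analysis linking
these higher-order structures to locus-level chromatin features (ChIP-seq
fold-change tracks, DNase hypersensitivity, GC content):

1. iterative correction (ICE) of binned intrachromosomal contact maps;
2. per-arm A/B compartment eigenvectors and calls;
3. compartment-boundary detection with a two-state hidden Markov model, and
   TAD-boundary detection with the directionality index;
4. feature meta-profiles around boundaries with Mann-Whitney
   enrichment/depletion tests under Bonferroni control;
5. random-forest regression of the compartment eigenvector on chromatin
   features, with out-of-bag (OOB) evaluation, permutation variable
   importance, cross-cell-type transfer and coarse-to-fine application;
6. structural-variability analysis across cell types (MAD tertiles, altered
   compartments, enhancer annotation enrichment, A-contact fractions); and
7. clustering of TADs into active / heterochromatic ("null") / polycomb
   (PcG) classes.

Because raw Hi-C and ENCODE-scale ChIP-seq compendia are far beyond what a
package test suite can process, every stage is validated against a
**synthetic-genome generator** that plants known compartments, TADs,
feature effects, biases and annotations, so each method has a quantitative
recovery test with known truth.

# The synthetic generator

`simConfig()` + `simulateChromatin()` emulate, per chromosome arm:

* **Compartment states.** A two-state Markov chain with symmetric
  persistence $p$ (default 0.98) gives geometric state runs of mean
  $1/(1-p) = 50$ bins — tens of megabases at the default 1-Mb bins, the
  scale at which compartments alternate in mammalian genomes. A fraction
  (`switchFraction`, default 5%) of bins, in contiguous runs of mean 5
  bins, is flipped in exactly one cell type, creating planted *altered
  open/closed* regions.
* **TAD partitions.** Shared breakpoints with geometric lengths (mean
  `tadMeanLen`) unioned, per cell type, with that cell type's compartment
  state-change points, so every compartment boundary is also a TAD boundary
  and the ground truth is unambiguous.
* **Feature tracks.** value = state mean + boundary kernel + Gaussian
  noise, floored at zero. The default panel of 12 features contains 8
  compartment-informative tracks (mean higher in A), two boundary-peaked
  tracks with no compartment effect (CTCF/POL2-like), one boundary-dipped
  track anticorrelated with A (H3K9me3-like) and one flat control. The
  boundary kernel is triangular — the exact smooth shape of real boundary
  peaks is immaterial to any conclusion drawn here, so the simplest
  compactly supported kernel is used — and is centred on the first bin of
  the new domain, the same bin every boundary-position convention in the
  package refers to.
* **Contact maps.** $\lambda_{ij} \propto |i-j|^{-\alpha}\,
  (1+\varepsilon\,[s_i=s_j])\,(1+\tau\,[\mathrm{tad}_i=\mathrm{tad}_j])\,
  b_i b_j$ with $\alpha = 1$, same-compartment affinity $\varepsilon=0.3$,
  same-TAD boost $\tau=0.5$ and log-normal visibility biases $b$
  (sd 0.3), scaled so each arm map's expected total is `depth` (default
  $5\times10^6$ counts — roughly the per-arm coverage of a published 1-Mb
  map), then Poisson-sampled with a zero diagonal.
* **Annotations.** Enhancer intervals planted at rate 3/bin in
  altered-open bins (cell-type-specific), 0.5/bin in all A bins
  (specific baseline), and 1/bin shared across cell types in
  constitutively-A bins.

A single global seed deterministically derives one sub-seed per stage, so
stages can be re-run independently and the whole object is reproducible
from `(cfg, seed)`.

**What the generator does not emulate** — and hence what passing tests do
*not* demonstrate about real data: read-level noise structure and mapping
artefacts, trans-chromosomal contacts, copy-number variation, fragment-level
ChIP-seq chemistry, correlated noise between features, and nested
(hierarchical) TADs. Recovery rates on this generator are best-case
figures for data whose generative structure matches the model.

# Hi-C processing

**Masking.** Bins with zero total contacts or totals in the bottom 2% of
nonzero bins are masked before correction. (Real pipelines delegate this
to their processing software; a concrete, reproducible rule is stated
here.)

**Iterative correction.** `iceCorrect()` alternately divides by row/column
scalings until the coefficient of variation of unmasked row sums falls
below `tol` = 1e-5 (at most 200 iterations; non-convergence flags the
result and raises a warning). The returned per-bin factors satisfy
`raw = corrected * outer(b, b)`.

*An identifiability note.* On a finite arm, the bias-free decay structure
itself balances to non-uniform per-bin factors $e_i$ (the harmonic decay
sum is smaller near arm ends), so *any* balancing estimator reports
$b_i e_i$, not the planted visibility $b_i$ alone. With $\alpha = 1$ and
1000 bins, $\mathrm{sd}(\log e) \approx 0.044$, which caps the correlation
with raw visibility at about 0.99 regardless of sequencing depth.
`plantedEffectiveBiases()` therefore exposes the identifiable quantity
$b_i e_i$, and bias-recovery checks compare against it; the correlation
with raw $b$ is reported alongside for transparency.

**Eigenvectors.** The compartment pipeline is fixed as: corrected map
$\to$ observed/expected (per-separation arithmetic means over unmasked
pairs; separations with fewer than 3 pairs inherit the nearest smaller
separation's value) $\to$ Pearson correlation of O/E columns $\to$ leading
eigenvector of the symmetric eigendecomposition, unit norm. This is the
canonical compartment recipe; it is stated explicitly because published
analyses typically delegate it to processing software without detail.
Undefined O/E entries (the diagonal) are set to the neutral value 1 before
the correlation — a single entry per column — because pairwise-complete
correlation is quadratically slower and numerically indistinguishable
here. The sign is oriented so the eigenvector correlates non-negatively
with an anchor track — GC content by default, A being GC-rich; the anchor
is a parameter. Compartment calls threshold at zero with **A at
eigenvector ≥ 0**, including exactly 0.

# Boundary detection

**Compartment boundaries.** A two-state Gaussian HMM is trained by
Baum-Welch on the (unmasked) eigenvector, initialised from the sign split
(state means = mean of positive/negative values, self-transition 0.95),
stopping when the log-likelihood gain is below 1e-6 or after 500
iterations. The state with the larger mean is A. The Viterbi path bridges
masked bins on the transition structure alone (their emission term is
omitted), and a boundary is recorded at every A/B transition of the path.
A boundary between bins $k-1$ and $k$ is recorded as $k$ — the first bin
of the new domain — everywhere in the package.

**Directionality index.** For each bin, with $A$/$B$ the contact sums to
bins within a 2-Mb window upstream/downstream (the cited tool's
recommended window) and $E = (A+B)/2$:
$$\mathrm{DI} = \mathrm{sign}(B-A)\left[\frac{(A-E)^2}{E} +
\frac{(B-E)^2}{E}\right],$$
zero when $A=B$ or $A+B=0$; windows truncated by arm ends are used as-is
and flagged.

**TAD boundaries.** The DI is a signed chi-square-like statistic; its heavy
tails defeat Gaussian emissions on the raw scale (one state absorbs both
tails). The three-state (upstream-biased / unbiased / downstream-biased)
HMM is therefore fitted to the variance-stabilised
$\mathrm{sign}(\mathrm{DI})\sqrt{|\mathrm{DI}|}$, initialised from the DI
tertiles. Boundaries are recorded where a downstream-biased run begins
after an upstream-biased or unbiased run, and additionally at any one-bin
negative-to-positive DI flip of magnitude at least 0.75 times the fitted
up-to-down state separation: Viterbi smoothing structurally erases domains
shorter than a few bins, and the strong flip is the same transition
signature at one-bin resolution. Calls are snapped within ±2 bins to the
steepest upward DI change and merged with a minimum 3-bin gap (keeping the
stronger |DI|). Note the generator's geometric TAD lengths put roughly 10%
of planted boundaries closer than the merge gap allows, capping attainable
recall near 88%; the observed 75–87% should be read against that ceiling.

**Concordance.** The matched fraction is the share of X boundaries with a
Y boundary within ±`toleranceBins`. The null model re-places |Y|
boundaries uniformly over valid positions (respecting the min-gap rule) —
the simplest count-preserving null — and the Kolmogorov-Smirnov statistic
compares observed distance-to-nearest-Y values against the pooled null
distances.

# Boundary feature profiles and enrichment tests

Profiles average each feature into bins centred on the boundary bin: 25
columns of 40 kb for TAD boundaries (±480 kb) and 31 columns of 100 kb for
compartment boundaries (±1.5 Mb). Boundaries whose flanks leave the arm
are dropped and counted. The enrichment test compares the centre-bin
values against the ten outermost bins (five per side), pooled across
boundaries by default (a per-boundary-mean variant is exposed as an
option), with a two-tailed Mann-Whitney test (normal approximation with
tie correction; the exact distribution is used for small untied samples
elsewhere). Significance is Bonferroni-controlled at $\alpha = 0.01$
across the features tested; direction is the sign of the centre-minus-
peripheral mean difference, and the effect size is its absolute value.

Boundary subsets by architectural-protein occupancy (`a_only`, `b_only`,
`both`, `neither`) require, for `both`, an a-peak and b-peak that mutually
overlap; co-occurring but disjoint peaks are reported separately as
`both_non_overlapping` rather than forced into either class.

# Compartment modelling

A random-forest regression predicts the eigenvector from the feature
matrix (chromatin tracks + GC) with `ntree = 200` and
`mtry = floor(n/3)` — 12 for the canonical 36-feature panel; the algorithm
is insensitive to these within broad ranges. Metrics: PCC and RMSE on the
continuous values (OOB for the native model), classification accuracy and
AUROC after thresholding at 0 (A ≥ 0); the AUROC scores *continuous*
predictions against thresholded truth with a fixed direction, so an
anti-correlated predictor scores below 0.5. Permutation importance is
reported as %IncMSE = 100 × (permuted OOB MSE − OOB MSE)/OOB MSE, averaged
over trees and permutation repetitions. Cross-cell-type transfer applies
a trained model to another cell type without refitting and reports the
relative PCC decline against the native OOB PCC. Baselines (ordinary
least squares and PLS with 1–15 components) have no OOB notion, so both
are scored on 10-fold cross-validated predictions, with the PLS component
count chosen by cross-validated RMSE. Coarse-to-fine transfer applies a
model trained at coarse bins directly to fine-resolution rows with the
same feature columns.

# Structural variability

Per-bin variability across ≥3 cell types is the raw median absolute
deviation of the eigenvector values (no consistency constant), ranked and
split into tertiles of equal size ±1. A bin A in exactly one cell type
and B in the others is an *altered open* compartment in that cell type
(conversely *altered closed*). For cross-cell-type state assignment the
package uses the HMM/Viterbi state path rather than the raw eigenvector
sign: when an arm's A/B proportions are unbalanced the compartment signal
splits across the top two eigenvectors and isolated sign errors fabricate
single-bin "altered" regions; the smoothed path removes these without
moving true multi-bin altered runs. Annotation counting classifies a
record as *shared* if any same-label record of another cell type overlaps
it by ≥1 bp, else *specific*; the enrichment ratio compares per-bin
specific densities in altered-open versus unaltered regions, with a
1000-replicate bootstrap CI over regions (counts plus a CI, not a p-value,
matching how such enrichments are conventionally reported). The A-contact
fraction of a region is the share of its corrected contacts at separation
≥ 2 bins (a "long-range" focus; the threshold is a documented convention)
landing in A-called bins, computed in each cell type.

# TAD clustering

Per-TAD coverage-weighted feature means are standardised and clustered by
k-means (k = 3, 25 restarts, fixed seed). Clusters map to classes by
which signature feature attains the highest standardised centre: DNase →
active, H3K9me3 → null (repressed heterochromatin), H3K27me3 → PcG; a
non-bijective mapping is an error with diagnostics, not silently
re-assigned. TADs are assigned to A or B by majority of their bins' calls
(ties → A, counted), and class-by-compartment composition is reported as
counts and row proportions. Clustering can be run per cell type or on
TADs pooled across cell types; pooled is the default.

# Numerical and design choices

* Coordinates are 0-based half-open on disk (BED/bedGraph native) and
  1-based closed in `GRanges` in memory; boundary positions are bin
  indices.
* Bins without signal records score 0 (fold-change tracks are dense;
  missingness is carried only by the mask).
* Contact files store the upper triangle once under a
  `# resolution=... chrom=... arm=...` header; symmetry is materialised on
  load.
* HMMs fix state identity by initialisation (sign split / DI tertiles), so
  no label-switching heuristics are needed; relabelling invariance is
  tested.
* `stats::wilcox.test` provides the Mann-Whitney machinery (exact for
  small untied samples, normal approximation with tie correction
  otherwise); the implementation is checked against an exhaustive
  enumeration oracle for group sizes ≤ 8.
* All randomness flows through explicit seeds; forest training, k-means
  and the simulator are bit-reproducible given their seed arguments.

## Problem sizes used in validation

The test suite and the acceptance script run, as the package's standard
validation conditions: two arms × 1000 bins at 1 Mb (3 cell types,
12 features) for compartment, variability and transfer analyses; one arm
× 1000 bins at 40 kb with 25-bin mean TADs and persistence 0.995 (1-Mb
TADs, multi-Mb compartment runs — the defaults re-expressed at the finer
bin size) for TAD calling; 200 null datasets of 300 bins × 36 features for
the calibration study and 30 replicates of 2600 bins for power; and 2000
× 16 feature matrices for forest validation. These sizes give stable
Monte-Carlo estimates while keeping the full validation run in the order
of a minute.

# Known limitations

* The compartment eigenvector is a single leading component; arms whose
  A/B split is strongly unbalanced can split the compartment signal over
  two eigenvectors, lowering the value-wise correlation with the planted
  state even when sign calls remain accurate.
* The TAD caller targets non-nested domains at a single window scale.
* The enrichment test's pooled peripheral sample treats boundary windows
  as exchangeable; strongly autocorrelated tracks violate this mildly.
* The PLS baseline requires the `mixOmics` package and is skipped (with a
  NULL result) when unavailable.
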