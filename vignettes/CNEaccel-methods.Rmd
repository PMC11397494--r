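---
title: "Detecting conserved noncoding elements and their lineage-specific acceleration"
author: "CNEaccel authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting conserved noncoding elements and their lineage-specific acceleration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CNEaccel)
library(GenomicRanges)
```

## The scientific problem

Self-fertile hermaphroditism (androdioecy) evolved independently on three
terminal lineages of *Caenorhabditis* — *C. elegans*, *C. briggsae* and
*C. tropicalis* — from dioecious ancestors. One route by which such
convergent phenotypic change can arise is the rewiring of gene
*regulation*: conserved noncoding elements (CNEs), which sit under strong
purifying selection across the genus, can undergo bursts of
lineage-specific substitution ("accelerated evolution") on exactly the
branches where the phenotype changed. CNEaccel implements the
computational core of that analysis on reference-anchored whole-genome
alignments:

1. detect CNEs with a two-state phylogenetic hidden Markov model
   (phastCons-style segmentation) and catalog filters;
2. test each CNE for acceleration on designated target branches with a
   branch-scale likelihood-ratio test (phyloP-style), either jointly on
   all three hermaphrodite branches or per branch;
3. quantify within-species constraint via nucleotide diversity from a
   population variant panel;
4. relate accelerated-CNE neighborhood to cross-species transitions in
   sex-biased gene expression.

A seeded synthetic-data module generates every input with known ground
truth, so each stage is verifiable at desk scale.

## Substitution model and likelihood

All likelihood computation uses an HKY85 model: stationary frequencies
$\pi$ over $\{A,C,G,T\}$ and transition/transversion rate ratio
$\kappa$, with the rate matrix normalised to one expected substitution
per site at stationarity, so branch lengths are expected substitutions
per site. HKY is the smallest model that separates transitions from
transversions; richer models (GTR+$\Gamma$) are out of scope and the
model sits behind the `NucModel` class so it could be swapped. Column
likelihoods come from Felsenstein's pruning algorithm, vectorised across
columns, with per-node rescaling of partial likelihoods (accumulated in
log space) so long elements cannot underflow. `N` and `-` are treated as
missing data — a leaf contributes a partial vector of ones — which makes
a fully missing column contribute exactly zero log-likelihood, the
convention the HMM relies on to bridge alignment gaps. Transition
matrices are computed from the eigendecomposition of the
$\pi^{1/2}$-symmetrised rate matrix, which keeps detailed balance exact
to machine precision.

The default base composition for simulation,
$\pi = (0.32, 0.18, 0.18, 0.32)$ with $\kappa = 2$, reflects the AT-rich
noncoding sequence typical of *Caenorhabditis*; `estimateHky()` fits
$\kappa$ and empirical frequencies from putatively neutral columns when
a fitted neutral model is preferred over a configured one.

## The conservation HMM

Segmentation uses a two-state (conserved / nonconserved) phylo-HMM over
alignment columns. The conserved state emits columns under the tree with
every branch multiplied by $\rho \in (0,1]$; the nonconserved state uses
the unscaled tree. Transition probabilities follow the phastCons
parameterisation from two interpretable tunables, the expected conserved
segment length $\omega$ (columns) and the target coverage $\gamma$:

$$\mu = 1/\omega, \qquad \nu = \mu\,\gamma/(1-\gamma),$$

with defaults $\omega = 12$ and $\gamma = 0.3$ — the parameter choice
used for CNE detection in this genus, where conserved elements are short.
The initial state distribution is the stationary one
$(\gamma, 1-\gamma)$, so $\gamma$ really is the expected conserved
coverage. Elements are called as maximal conserved runs of the *Viterbi*
path rather than by posterior thresholding: the call is deterministic and
matches the "most conserved elements" convention; posterior probabilities
are still computed (`posteriorDecode()`) and reported per segment as a
diagnostic. Ties in the Viterbi recursion are resolved toward the
nonconserved state, a conservative and deterministic rule. $\rho$ is
estimated once per dataset by maximising the total forward likelihood
over a coarse grid on $(0,1]$ refined by golden-section search; on
synthetic data with true $\rho = 0.3$ the estimate lands in
$[0.2, 0.4]$ in over 90% of seeded replicates, and on purely neutral
data the profile is flat near 1.

## From segments to the CNE catalog

Conserved segments become CNEs through four steps, all on 0-based
half-open intervals internally (the BED convention; GFF input is
converted on read by `rtracklayer`):

- **Coding subtraction** — every base overlapping a CDS is removed;
  each surviving piece remains a sub-interval of exactly one input
  segment (adjacent segments are never merged).
- **Length rule** — only intervals *strictly longer than 10 bp* on the
  reference are kept: an 11 bp element passes, a 10 bp element does not.
  The boundary is pinned by tests.
- **Projection** — each element is mapped through the alignment blocks
  onto every subject species. Deletions shrink the projection;
  insertion columns (reference gaps inside the projected window)
  lengthen it; species absent from all covering blocks are unaligned.
- **Species filters** — a projection that splits into two or more
  disjoint genomic intervals is flagged `dropped_redundant`
  (redundantly aligned), and a single-interval projection *strictly
  longer than twice* the reference length is flagged
  `dropped_length_ratio` (24 bp against a 12 bp reference is kept; 25 bp
  is dropped). The reference record itself is never dropped by these
  rules.

Nearest-gene assignment uses gene *bodies*, ignores strand, and defines
distance as the base gap (0 for overlap or adjacency), signed positive
when the gene lies at higher coordinates; ties go to the leftmost gene
start, then to the lexicographically smaller id. Gene bodies rather than
transcription start sites were chosen because the neighbor relation in
the underlying workflow is body-based; the choice is isolated inside
`nearestGene()`. Annotation-overlap enrichment of an accelerated set
against the full kept catalog uses one-sided Fisher's exact tests
(enrichment direction) per feature class with Benjamini–Hochberg
correction across classes.

## The acceleration test

For each element alignment the null model fits one free global scale
$r$ applied to every branch; the alternative adds a single shared
acceleration scale $\lambda \ge 1$ applied multiplicatively to the
target branches (the three hermaphrodite terminal branches in the joint
analysis, or one terminal branch in the per-species analysis — with one
target the two modes coincide exactly). The free $r$ in both models
absorbs element-wide rate variation, so the test is specific to excess
substitution *on the targets*. The statistic is
$2(\ln L_1 - \ln L_0)$ and, because $\lambda$ is tested at the boundary
of its parameter space, the p-value uses the one-sided mixture
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$:
$p = \tfrac12 P(\chi^2_1 \ge \mathrm{stat})$ when $\hat\lambda > 1$,
else $p = 1$. On at least 1000 simulated null elements (30–100 columns,
11 taxa, $\rho = 0.3$) the empirical type-I error at $\alpha = 0.05$
sits within three binomial standard errors of 0.05, which is the
calibration the convention is pinned by.

Optimisation is deterministic: a coarse log-spaced grid followed by
Brent's method for the null, and for the alternative a $\lambda$-grid at
the null's $\hat r$ followed by three rounds of coordinate descent
(Brent in $\log r$ and $\log\lambda$ alternately). The boundary
$\lambda = 1$ always remains admissible — if the alternative search ends
below the null likelihood the fit collapses to the null — so
$\ln L_1 \ge \ln L_0$ holds by construction. Elements are called
accelerated at BH $q < 0.05$, with the correction applied within each
run (the joint run, and each species' run separately), mirroring the
separate FDR statements of the two analyses. Convergence across species
is summarised at the orthogroup level: a group qualifies when CNEs
accelerated in at least two species neighbor genes of that group and the
contributing elements are not all the same CNE.

## Nucleotide diversity

Per-element diversity uses the unbiased per-site estimator

$$\pi = \frac{1}{L}\sum_{s} 2 p_s (1-p_s)\,\frac{n_s}{n_s - 1},$$

summing over segregating sites inside the element, with $p_s$ the
alternate-allele frequency among the $n_s$ non-missing haplotypes at
site $s$ — algebraically identical to the mean pairwise difference among
haplotypes, which the tests assert numerically. Sites with fewer than
two called haplotypes are skipped and logged; multiallelic and non-SNP
records are dropped on read (logged), matching biallelic SNP-panel
handling. The denominator is the full element length by default; a
callable-regions mask can be supplied to switch the denominator to
callable length, since which convention the field uses varies. Class
summaries use only elements strictly longer than 50 bp (short elements
give unstable per-element estimates) and report the median with a
low-count flag for classes with fewer than 10 elements.

## Sex-biased expression transitions

The differential-expression caller is deliberately a simple, fully
self-contained stand-in for the TCC/edgeR route: median-of-ratios size
factors (upper-quartile fallback when no gene is nonzero everywhere), a
per-gene method-of-moments negative-binomial dispersion *shrunk toward
the common across-gene value* (prior weight equivalent to 20 residual
degrees of freedom, floored at 0.01), and a conditional double-tail
exact-style test on the rounded normalised group sums. The shrinkage is
essential, not cosmetic: raw moment estimates from four replicates are
so noisy that genes with chance-small sample variance would be tested
at the floor and the null would be anti-conservative (empirical
$P(p<0.05) \approx 0.095$); with moderation the test calibrates to
0.05–0.06 at dispersions 0.05–0.3 while retaining >90% recall of
planted four-fold changes at $q < 0.01$. Externally computed bias calls
can be supplied as TSV (`readBiasCalls()`) to bypass the stand-in
entirely. Genes are classed `XX-biased` / `XO-biased` / `Non` at
$q < 0.01$.

The cross-species analysis places each one-to-one ortholog in a
3×3 cell by its class in the two species and asks, per cell, whether
accelerated-CNE-neighbor genes are enriched (2×2 Fisher, in-cell vs not
× neighbor vs not; two-sided by default with a one-sided switch, since
the directionality convention is not fixed; BH across the nine cells).
Odds ratios are sample odds ratios with 0.5 added to every cell when any
cell is zero — deterministic and finite — while p-values always come
from the uncorrected exact test. A one-sided discordance test (class
differs between species vs neighbor status) is also emitted. The
2×3 per-comparison class-proportion contrast uses the exact test up to a
configurable table total (default 400) and the chi-squared
approximation above it.

## What the synthetic data do and do not emulate

`simulateAlignment()` lays out non-overlapping CDS and noncoding
conserved elements on a reference chromosome and evolves sequences down
the packaged 11-taxon tree with the same HKY machinery the inference
uses: neutral background at scale 1, conserved features (both CDS and
CNEs) at $\rho = 0.3$, accelerated elements additionally at
$\lambda = 5$ on the three hermaphrodite terminal branches. Reusing one
substitution-model implementation for simulation and inference makes
self-consistency itself a test. The packaged tree mimics the accepted
clade structure of the genus with *C. niphades* as outgroup/reference;
its branch lengths are round numbers chosen for test power, not
empirical estimates. Alignments are simulated gap-free with optional
uniform gap masking; there is no indel evolution, so projection-filter
behaviour on real, indel-rich alignments is exercised only by the
hand-built fixture. `simulatePopulation()` places variants
site-independently (no linkage or coalescent genealogy) with
probability $\theta a_n$ per base, five-fold reduced inside CNEs, and
neutral-prior derived-allele counts ($P(i) \propto 1/i$); defaults are
$\theta = 0.005$/site and 30 haplotypes, a realistic scale for a wild
nematode isolate panel. `simulateExpression()` plants class fractions
(15% XX-, 15% XO-biased), two-fold expression bias, negative-binomial
counts (mean lognormal around 100, dispersion 0.1, four replicates —
the replicate structure of the motivating design) and a neighbor flag
enriched at odds ratio 3 in one configurable transition cell, solving
the baseline neighbor rate so the overall neighbor fraction (5%,
roughly the fraction of genes neighboring accelerated CNEs) is
preserved.

Passing tests on these data therefore demonstrate correctness of the
algorithms and calibration of the statistics under the stated generative
assumptions; they do not demonstrate robustness to alignment error,
indels, linkage, demography or expression batch effects, which real
data contain.

## Numerical and design choices

- All optimisers are deterministic (grids + Brent/golden-section, fixed
  tolerances: $10^{-3}$ on log-scales for the LRT, $5 \times 10^{-3}$
  for $\rho$); identical inputs give identical results.
- Search bounds: $r \in [1/32, 32]$, $\lambda \in [1, 64]$. Invariant
  elements drive $\hat r$ to the lower bound, which is the correct
  boundary behaviour.
- Degenerate inputs: all-missing columns emit 0; empty blocks,
  all-missing elements and empty neighbor sets raise informative errors
  or logged skips rather than propagating NaN.
- The fixture regression pins every boundary rule (>10 bp, strict 2×,
  adjacency distance 0, tie-breaks) byte-identically against
  hand-computed expected files.
- Problem sizes in the tests (20 kb alignments, 300–1000 element LRTs,
  10,000 orthologs) were chosen as the smallest sizes at which the
  statistical criteria are sharp.

## Known limitations

- The neutral model is HKY without rate variation among sites; phyloP's
  score-based modes and conservation (deceleration) calling are not
  implemented.
- The HMM has exactly two states and no full EM over all free
  parameters; only $\rho$ is estimated, with $\omega$ and $\gamma$
  fixed by configuration.
- "Redundant alignment" is operationalised as a split projection (two or
  more disjoint intervals), the natural reading of duplicated alignment
  semantics; other definitions (e.g. coverage-depth based) would need
  alignment-level information this pipeline does not retain.
- π uses the full element length as denominator by default; with sparse
  callable regions the callable-mask mode should be preferred.
- The DE stand-in is not TCC/edgeR; when exact reproduction of an
  external DE pipeline matters, import its calls via `readBiasCalls()`.
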