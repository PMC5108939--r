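---
title: "Community phylogenetics and trait divergence: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community phylogenetics and trait divergence: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barbetdiv)
```

`barbetdiv` asks three questions about assemblages of co-occurring related
species — developed around sympatric Asian barbet (Megalaimidae) communities,
but applicable to any clade with occurrence records, morphometrics, a dated
phylogeny and recorded vocalizations:

1. Are co-occurring species a random draw from the regional phylogeny, or
   are communities phylogenetically clustered / overdispersed?
2. Are co-occurring species more divergent in trait space (morphology, vocal
   frequency) than a random draw?
3. Does trait evolution depart from the Brownian-motion expectation
   (Blomberg's K), and in which direction?

This vignette documents the statistical machinery, the tunable parameters,
the synthetic-data generator used by the test suite, and the design choices
made where the procedure was genuinely open.

## Co-occurrence and phylogenetic structure

Occurrence records (species, latitude, longitude in decimal degrees; WGS84
assumed, never reprojected) are binned on a regular grid of square cells,
0.2° on a side by default. Cells are half-open `[a, a + cell)`; a record on
a boundary belongs to the higher-index cell, with a 1e-9-cell tolerance
absorbing floating-point division error. Only cells containing at least one
record become sites, and repeated records collapse to a single presence —
the analysis is presence/absence throughout, which makes the co-occurrence
index robust to unequal recording effort across species. The grid origin is
not identifiable from the method itself, so it defaults to the region's
minimum coordinates floored to the cell size and is exposed as a parameter
for sensitivity analysis.

For each unordered species pair the **DO index** is

$$DO_{ij} = \frac{P_{ij} - P_i P_j}{P_i P_j},$$

with $P_i$, $P_j$ the proportions of sites holding each species and $P_{ij}$
the proportion holding both. Independent distributions give $DO \approx 0$,
mutual exclusion gives the minimum $-1$, and positive association grows
without bound ($(1-P)/P$ for a pair always found together). Pairs in which a
species occupies no site are flagged undefined rather than given a number.

**Phylogenetic structure** is the Pearson correlation $r$ between $DO_{ij}$
and the cophenetic (tip-to-tip path-length) distance, over all defined
pairs, after pruning the phylogeny to the species in the matrix. A negative
$r$ means relatives co-occur preferentially (clustering); a positive $r$
means co-occurring species are more distantly related than expected
(overdispersion). Significance comes from two places:

* a parametric two-tailed p from the t distribution of $r$ (pairs are not
  independent, so this is indicative only), and
* an **independent-swap randomization**: the observed matrix is randomized
  by 2×2 checkerboard swaps — a `[[1,0],[0,1]]` or `[[0,1],[1,0]]` submatrix
  replaced by its complement — which preserve every site's richness and
  every species' occurrence frequency exactly. Each null replicate performs
  10× (number of presences) successful swaps (a mixing default, exposed as
  `n_swaps`), recomputes DO and $r$, and the test reports the lower-tail p
  (fraction of null $r \le$ observed, small under clustering), the upper
  tail, and the two-tailed value $2\min(\text{lower}, \text{upper})$ capped
  at 1. No add-one correction is applied, so 0 and 1 are attainable, and
  replicates with undefined $r$ are dropped and counted. 999 replicates is
  the default.

**Calibration design.** The swap null conditions on the matrix margins: its
hypothesis is that the observed matrix is a random member of the
fixed-margin ensemble. The package's type-I calibration therefore draws each
"observed" matrix from that ensemble (one long swap walk from an arbitrary
binary matrix) before testing; at $\alpha = 0.05$ the measured rejection
rate is nominal. Feeding the test raw i.i.d. Bernoulli matrices instead —
whose margins are themselves random — measures a slightly anticonservative
rate (up to ~0.08 in our experiments), which is a property of that
mismatched generator, not of the test.

## Morphospace

Specimen-level tables carry seven strictly positive linear measurements in
millimetres (beak length, width, depth; tail, tarsus, body, wing). Each
measurement is log-transformed — linearizing allometric scaling and pulling
the joint distribution toward multivariate normality — and the matrix is
ordinated by **covariance PCA via SVD**: columns are mean-centred, not
scaled (all columns share the log scale, and standardizing would discard
the size signal that dominates these data), and eigenvalue $k$ equals
$s_k^2/(n-1)$, the variance of score $k$. Loadings are sign-fixed so each
vector's largest-magnitude element is positive. Rank-deficient input yields
trailing zero eigenvalues rather than an error. The log base is
configurable (natural log by default) and provably irrelevant to
percent-variance output, since changing base rescales every column by one
common factor; raw eigenvalues do scale with the base, so they should only
be compared under a stated base.

Species are sorted into size classes along PC1 by 1-D k-means (k = 3, best
of 50 restarts, seeded), labelled I < II < III by ascending mean PC1. This
is an algorithmic stand-in for what is otherwise a visual grouping of the
PC1–PC2 scatter; the class boundaries are reported so the assignment can be
audited.

## Trait overlap and community dispersion

Pairwise overlap uses **Cohen's d**, $|\bar x_i - \bar x_j| / s_p$ with the
pooled standard deviation from $n-1$ sample variances. Two species overlap
when $d < 2$ on *every* axis considered (PC1 and PC2 for morphology, peak
frequency alone for acoustics); the comparison is strict, so $d = 1.98$
counts as overlap and $d = 2.00$ does not. Species with fewer than three
specimens are never given a numeric verdict — their comparisons are flagged
qualitative-only.

The **dispersion Z-score** asks whether a community's members are more
spread out in trait space than a random draw from the family-wide pool. The
statistic is the mean pairwise Cohen's d over community members. Each null
build draws 10,000 pseudo-communities of the same species count from the
pool, and $Z = (\text{obs} - \text{mean(null)})/\text{sd(null)}$; the whole
null build is repeated 100 times (all defaults overridable) and the mean Z
reported, with the empirical p the fraction of all null statistics at or
above the observed (overdispersion = large observed dispersion).

Two decisions here were genuinely open. First, the *unit of the null draw*:
the default draws whole species (each bringing its specimen values), because
the statistic requires within-species variance and "community size" is a
species count; an alternative mode (`unit = "values"`) draws individual
values into pseudo-species matching the observed sample sizes, for
sensitivity analysis. Second, species below the three-specimen floor are
excluded from members *and* pool, keeping observed and null statistics
comparable. Z is invariant to affine transformation of the trait axis
(shifts and scalings cancel in d).

## Acoustics

Each annotated vocal element (onset/offset seconds within a recording) is
windowed (Hann), zero-padded to 4× the next power of two, and
Fourier-transformed; the **peak frequency** is the largest-magnitude bin
refined by three-point parabolic interpolation. On a pure tone this is
accurate to well under 2 Hz. The analysis band is `[fmin, Nyquist]`:
`peak_frequency()` itself defaults to `fmin = 0` (a constant segment
legitimately peaks at 0 Hz), while the annotation-driven extractor defaults
to `fmin = 100` Hz to suppress recording rumble; synthetic round-trip tests
switch it off. All spectrum parameters are attached to the result.

Two analysis units follow field practice: for *within-community* frequency
comparisons each recording contributes one sample (the mean of its element
peaks), avoiding pseudo-replication across elements of one singer; for
*chorus* comparisons — several species audible in one recording — each
element is one unit, elements must not overlap in time (enforced), and the
test is per recording: a two-tailed Mann–Whitney U for two species (exact
when the combined tie-free sample is ≤ 20, tie-corrected normal
approximation otherwise) or a one-way fixed-effects ANOVA followed by all
pairwise pooled-variance t tests with Bonferroni correction (multiplier =
number of pairs, capped at 1) for more. Species with fewer than two usable
elements are excluded with a warning.

## Phylogenetic signal

**Independent contrasts** are computed by Felsenstein pruning: at each
internal node, contrast $= (x_1 - x_2)/\sqrt{v_1 + v_2}$, ancestral value
$=$ the $1/v$-weighted mean, and the parent branch is lengthened by
$v_1 v_2/(v_1+v_2)$. A bifurcating n-tip tree yields n − 1 contrasts;
polytomies are resolved arbitrarily with zero-length branches under a
warning (the sum of squared contrasts, and hence K, is invariant to the
resolution order).

**Blomberg's K** is the ratio of mean squared errors
$\mathrm{MSE0}/\mathrm{MSE}$ — deviations of tip values from the GLS
phylogenetic mean $\hat a = (\mathbf 1^\top V^{-1}x)/(\mathbf 1^\top V^{-1}
\mathbf 1)$, over the $V^{-1}$-standardized deviations — divided by its
Brownian expectation $(\mathrm{tr}(V) - n/\mathbf 1^\top V^{-1}\mathbf 1)/(n-1)$,
where $V$ is the shared-path-length covariance matrix. K = 1 under Brownian
motion (exactly 1 on a star phylogeny, a closed form the tests assert);
K < 1 means relatives are more divergent than Brownian motion predicts.
K is invariant to affine trait transforms and to rescaling all branch
lengths.

Significance uses a **tip shuffle**: the trait-to-tip assignment is permuted
(1000 times by default), the variance of the standardized contrasts is
recomputed, and $p = (1 + \#\{\text{null} \le \text{obs}\})/(1 + n)$ —
one-tailed, because signal means *smaller* contrast variance than a random
tree, with the add-one correction making $1/(1+n)$ the attainable floor
(reported "≤ 0.001" at 1000 shuffles). Whether the null statistic should be
the variance or the mean square of contrasts is not fully determined by the
method's description; variance is the default and `stat = "meansq"` is
exposed. Species means are the expected trait input; subspecies are treated
as ordinary tips.

## The synthetic study system

The generator exists so that every stage can be tested against known truth
without any external download. It emulates, with deliberate simplifications:

* **Phylogeny**: forward-time pure-birth (Yule) trees, exponential waiting
  times, ultrametric by construction. No extinction.
* **Traits**: Brownian motion along branches (rate σ²); a `lambda`-style
  transform scaling the covariance off-diagonals, and a white-noise mode
  (i.i.d. tips with Brownian marginal variances) to produce zero-signal
  traits.
* **Specimens**: a one-factor size model — every log measurement is a trait
  baseline plus the specimen's size score (species value + within-species
  noise, default sd 0.1) plus independent per-trait noise (default sd 0.05).
  This is the simplest model under which "PC1 = body size" is true, which is
  how the morphospace axis is interpreted; it does *not* emulate
  trait-specific evolution, sexual dimorphism, allometric curvature or
  measurement error structure, so passing tests say nothing about those.
* **Communities**: random draws; overdispersed (greedy max–min trait
  spacing, which dominates random spacing by construction); clustered
  (nearest trait neighbours of a random focal species — with a Brownian
  trait this is also phylogenetically clustered). Members leave occurrence
  records in a block of grid cells with a detection probability; one anchor
  cell records all members so every community is observable.
* **Choruses**: pure sine tones with 5 ms cosine ramps at species-specific
  peak frequencies, optional frequency/onset jitter, and a guaranteed
  non-overlapping slot layout for chorus statistics. Real barbet phrases are
  harmonically richer and amplitude-modulated; pure tones keep the
  peak-frequency oracle exact, which is the point.

Every generator takes an explicit seed and is bit-reproducible under it.

## Numerical choices and degenerate inputs

* Zero pooled sd in Cohen's d: equal means give d = 0, unequal give an
  infinite-d flag.
* Zero-variance vectors in the structure correlation: flagged undefined,
  never silently 0.
* A matrix with no checkerboard cannot be swap-randomized: returned
  unchanged with a warning flag.
* Constant traits: all contrasts zero; shuffle p degenerates to 1 with a
  flag.
* Singular phylogenetic covariance (duplicate zero-length tips): an error.
* Rank-deficient morphometrics: trailing zero eigenvalues, reported.
* WAV input: integer PCM (8/16/24/32-bit) and IEEE float accepted,
  normalized to [−1, 1]; multi-channel averaged to mono; anything
  compressed is an unsupported-format error.

## Problem sizes used by the tests

The test suite and the acceptance script run everything on synthetic data
at sizes chosen to make Monte-Carlo assertions stable: 30-species trees and
300-specimen tables for the ordination; 500 simulations × 99 swap
replicates for the type-I calibration; 100 Brownian simulations on 30-tip
trees for the K benchmark; exhaustive enumeration for the DO, Mann–Whitney
and dispersion-Z oracles (≤ 6 sites, ≤ 4 elements per group, 5-species
pools); 12 simulated communities per assembly regime for the end-to-end
recovery checks. The acceptance script (`scripts/acceptance.R`) recomputes
all of these from scratch under a caller-supplied seed.

## Limitations

* Reproducing the published barbet numbers requires the original
  329-specimen morphometric supplement and the published consensus tree;
  neither is redistributable here, so the corresponding checks run against
  a documented `inst/extdata` path and fail loudly when the files are
  absent. All other guarantees are against synthetic known truth.
* The grid origin and the swap count per null draw are not identifiable
  from the method description; both are parameters with documented
  defaults.
* The parametric p for the structure correlation ignores the
  non-independence of species pairs; the randomization p is the one to
  trust.
* Dispersion Z excludes under-sampled species from observed and null
  alike; communities reduced below two usable members cannot be tested.
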