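---
title: "Methods: core-anchored partitioning and QC for UCE phylogenomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: core-anchored partitioning and QC for UCE phylogenomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`corepart` implements the bespoke computational stages of a
target-enrichment (UCE) phylogenomic workflow between the standard external
tools: it starts from per-locus multiple sequence alignments and specimen
metadata, and it prepares inputs for — and consumes newick outputs of —
external inference engines. Alignment computation, read processing and the
tree searches themselves are out of scope.

The package covers six analysis stages plus a synthetic-data generator and
a pipeline driver:

1. **Locus I/O and summaries** — cleaning, completeness filtering,
   parsimony-informative-site (PIS) statistics, concatenation.
2. **Core/flank character sets** — the central 160 bp bait core and five
   mirrored flank bins per locus.
3. **Model selection** — a GTR+Γ pruning likelihood engine and greedy AICc
   search over groupings of a locus's character sets.
4. **Gene-tree QC** — bootstrap-support filtering, saturation regression,
   burn-in removal, split-frequency convergence (ASDSF), and maximum clade
   credibility topologies.
5. **Tree comparison** — Robinson–Foulds, path, and approximate SPR
   distances.
6. **Museum capture statistics** — Welch tests, capture GLMs, and the
   common-slope likelihood-ratio test on logit capture fractions.

# Alignment cleaning and summaries

A locus alignment is a character matrix over `{A,C,G,T,-,N,?}`. Cleaning
removes exactly the columns in which *every* taxon carries one of `-`, `N`,
`?` (case-insensitive). Other IUPAC ambiguity codes are treated as missing
data by every downstream statistic (PIS, distances, likelihood) but do
**not** trigger column removal; the cleanup rule names only those three
symbols, and widening it would silently change matrix coordinates.

A site is parsimony-informative when at least two distinct unambiguous
nucleotides each occur in at least two taxa. Completeness filtering keeps a
locus when its taxon count reaches `ceiling(p × T)` for the study taxon set
of size `T`; with the usual `p = 0.70` and `T = 33` this requires 24 taxa.
`ceiling` is a documented choice — the threshold is stated in the
literature as "≥ 70 % complete" without a rounding rule — so results under
`floor` can be compared by passing a slightly smaller `p`.

Concatenation writes loci in lexicographic id order, pads absent taxa with
`?`, and emits RAxML-style (`DNA, locus = start-end`) and NEXUS `sets`
blocks with 1-based inclusive coordinates. Internally all site coordinates
are 0-based half-open; only the writers convert.

# Core/flank character sets

Captured UCE loci are least variable in the central bait region and
increasingly variable outward. Each locus of length `L ≥ 160` receives a
central core of 160 sites with left offset `floor((L−160)/2)` — the extra
column of an odd flank total goes to the right flank. Each flank is divided
independently into five contiguous bins of width `floor(F/5)`; the
remainder is distributed one site to each of the *outermost* bins, because
the variability profile changes fastest next to the core, so inner bins
should stay homogeneous. Bin `k` of the left flank is unioned with bin `k`
of the right flank into charset `flank_k`, with `k = 1` adjacent to the
core. Charset numbering direction is a labelling convention only; the
grouping content is invariant to it. Loci shorter than 160 sites become
single-charset (`core_only`) loci rather than errors — they simply cannot
be split.

# Likelihood engine

The engine evaluates the GTR+Γ log-likelihood of an alignment on a fixed
tree by Felsenstein pruning over compressed site patterns (C++ core), with:

* exchangeabilities relative to `r_GT ≡ 1`; the rate matrix normalized to
  one expected substitution per site per unit branch length;
* discrete gamma rates as the means of four equal-probability slices of
  `Gamma(α, α)` — the de-facto standard discretization;
* missing data as all-ones partial likelihoods;
* per-node, per-pattern rescaling against underflow;
* a subset-relative rate multiplier applied to branch lengths.

The pruning recursion is validated in the test suite against brute-force
summation over all internal ancestral states (4-taxon instances, 1e-8),
the closed-form two-sequence Jukes–Cantor likelihood, and the
sum-to-one identity over all site columns for three taxa.

## Subset fitting

`fit_subset_model()` maximizes the likelihood over the five free
exchangeabilities, three free base-frequency weights, the gamma shape and
(optionally) the rate multiplier by coordinate ascent with bounded scalar
optimization on a log scale (rates `1e-6..100`, alpha `0.02..100`,
multiplier `1e-3..100`); convergence when a sweep improves lnL by less
than `1e-6`, capped at 200 sweeps (then a warning and a `converged = FALSE`
flag, returning the best point found). Two implementation details matter
for speed and do not change the optimum: scalar searches bracket locally
around the current value and re-expand to the full bounds when the optimum
lands on a bracket edge, and one extra ascent direction jointly rescales
the five free exchangeabilities, cutting through the ridge between the
relative rates and the GT-anchored scale. Merged subsets warm-start from
the largest member's fit; the warm start is a deterministic function of
the subset so greedy and exhaustive searches score identical subsets
identically.

## Scheme search and AICc

The guide tree is estimated once per locus — neighbor joining on
Jukes–Cantor distances (p-distances clamped at 0.74 before correction,
negative NJ branch lengths clamped to zero) followed by GTR+Γ
branch-length optimization — and held fixed across subsets. Subsets differ
by model parameters and a rate multiplier. This avoids AICc degeneracy:
with 33 taxa the 63 branch lengths would otherwise be counted per subset
and could exceed the sites of a small charset. Scheme-level
`K = (2T−3) + 9S + (S−1)`: shared branch lengths once, nine base
parameters per subset, and `S−1` free multipliers under the mean-rate-1
convention (each subset's multiplier is fitted freely against the fixed
branch lengths; the constraint is a counting convention absorbed by the
shared branch scale). AICc uses `n =` number of sites, not patterns — the
literature is split and sites is the choice made here.

The greedy search starts with every charset alone, evaluates all pairwise
merges, accepts the merge that most decreases scheme AICc, and stops when
none does; ties break lexicographically on merged charset names. The
exhaustive search scores every set-partition (≤ 6 charsets, Bell(6) = 203
schemes) and is the oracle the greedy result is compared against in the
acceptance suite: greedy AICc must never be lower than the exhaustive
optimum, homogeneous simulations must merge to one subset and strongly
heterogeneous ones must stay separate in at least 95 of 100 seeded
replicates each.

# Gene-tree quality control

* **Support filtering.** Mean bootstrap support is the arithmetic mean over
  internal-edge supports (trivial splits excluded; the root label is not
  attached to an edge and is ignored; the scale is auto-detected and
  normalized to 0–100; support is averaged over all internal edges, not
  only the resolved ones). Loci
  strictly below the type-7 linear-interpolation 0.10 quantile of mean
  support are flagged.
* **Saturation.** Per locus, uncorrected p-distances are regressed (OLS
  with intercept) on patristic distances from the locus tree; a shallow
  slope means multiple hits are flattening observed divergence. "Departure
  from the regression" is operationalized as the lower Tukey fence
  (`Q1 − 1.5·IQR`) on the slope distribution — there is no canonical
  outlier rule for this diagnostic, so a standard, configurable fence is
  used.
  On the packaged benchmark (loci simulated at branch scale ×10 against
  unsaturated loci) the fence detects ≥ 95 % of saturated loci with ≤ 5 %
  false flags.
* **Burn-in and convergence.** `apply_burnin()` drops the first
  `floor(0.25 N)` samples by default. Split frequencies are keyed by the
  bipartition side not containing the lexicographically first taxon; ASDSF
  averages the `n−1`-denominator standard deviation of per-run frequencies
  over splits reaching 0.10 in at least one run (the convention of the
  usual Bayesian MCMC tooling).
* **MCCT.** The maximum clade credibility topology is chosen among the
  *sampled* trees — not built as a consensus — by the sum of log clade
  frequencies from the full post-burn-in sample, ties broken by first
  occurrence, nodes annotated with clade frequencies.

# Tree distances

All metrics are topological: branch lengths are ignored and
multifurcations are allowed (non-trivial bipartitions only). RF is the
symmetric difference of bipartition sets; path distance is the Euclidean
norm of the difference of tip-pair edge-count vectors. The approximate SPR
distance kernelizes (iteratively collapsing pendant cherries shared by
both trees) and then greedily deletes the leaf whose removal most reduces
RF, one move per deletion. Published approximate-SPR heuristics differ;
this one is validated against an exact breadth-first-search oracle over
SPR neighborhoods (≤ 10 leaves) rather than against any specific
implementation — it equals the exact distance on single-move pairs and
never undercuts it on the small-tree suite. The SPR neighborhood
enumeration itself is checked against the closed-form neighborhood size
`2(n−3)(2n−7)`.

# Museum capture statistics

Preservation groups are compared with Welch's two-sample t-test. The
capture GLM is `loci_count ~ age_years + preservation` with ethanol as the
reference level; "GLM" is interpreted as Gaussian identity link (the
reported statistics are coefficient p-values with no family stated) with
Poisson log link available as an option.

Cross-study decay uses the fraction of loci captured relative to the
within-study maximum. The maximum specimen has fraction 1, whose logit is
infinite, so the Smithson–Verkuilen squeeze `p' = (p(n−1)+0.5)/n` is
applied before the logit. The common-slope test fits per-study intercepts
with per-study slopes (full) versus per-study intercepts with one shared
slope (reduced) by Gaussian maximum likelihood and refers
`2(lnL_full − lnL_reduced)` to χ² with `#studies − 1` degrees of freedom.
Ages are `sequencing_year − year_collected` with the sequencing year
configurable.

# Synthetic data

The generator emulates the study conditions end-to-end so every stage runs
without downloads: 33 taxa and 231–802-site loci by default, a 160 bp
core, and a per-charset rate profile rising from 0.2 (core) to 1.5
(outermost flank), chosen to reproduce the qualitative U-shaped
variability profile of captured loci — not fitted to any real data.
Sequences evolve by eigendecomposition of the GTR rate matrix with
i.i.d. per-site gamma-category assignment; trees are Yule topologies with
exponential branch lengths rescaled so the mean root-to-tip path equals
`tree_height` (default 0.3 substitutions/site at rate 1, giving shallow
core divergences comparable to closely related genera).

Museum degradation retains each specimen × locus with probability
`plogis(a + b·age)` (so `b < 0` gives the decline of capture with age) and
truncates surviving pinned sequences from both ends — flanks lost first —
each end by a `Uniform(0, truncation_rate)` fraction, mirroring the
shorter contigs assembled from degraded DNA.

Capture tables draw `logit fraction = intercept + slope·age + N(0, sd)`
per specimen and map fractions to counts through the study's maximum-locus
constant. Each study also contains one fresh reference specimen captured
at the study maximum: in real tables the within-clade maximum is attained
by construction, and anchoring it keeps the fraction denominator constant.
Without the anchor the denominator is a random sample maximum, which
biases the common-slope estimate and couples the per-study transformation
to the intercepts; with it, the likelihood-ratio calibrations hold at the
packaged conditions (three studies, 30 aged specimens each, ages uniform
on 0–60 years, intercepts 2.5/2/3, slope −0.04 per year, residual sd 0.5).

What passing the synthetic suites does *not* show: robustness to alignment
error, indels, model misspecification (the generator and the engine share
the GTR+Γ family), non-uniform taxon sampling, or the linkage structure of
real capture data. The suites demonstrate internal correctness and
statistical calibration under the stated model, not field performance.

# Numerical choices and problem sizes

* Likelihood oracle agreement asserted at 1e-8 (brute force) and 1e-10
  (closed forms); scalar optimizer tolerance 1e-3 on the log scale;
  coordinate-ascent convergence 1e-6 lnL.
* Guide-tree branch lengths: two optimization sweeps at tolerance 0.01 lnL
  — branch lengths are nuisance parameters here and further sweeps do not
  change scheme selection in the suites.
* The packaged suites use 6–12 taxa and 300–10 000-site loci: merge
  calibration at 6 taxa × 450–600 sites (100 replicates per condition),
  parameter recovery at 8 taxa × 10 kb, QC benchmarks at 40 loci, LRT
  size at 500 replicates. These sizes make the full suite reproducible in
  minutes on a single core while keeping every assertion at the stated
  tolerance.
* Degenerate inputs: empty post-cleaning alignments, star trees,
  zero-overlap taxon pairs and all-missing columns raise errors naming the
  locus; loci shorter than the core become single-charset loci; invariant
  subsets drive the rate multiplier to its lower bound rather than failing.

# Known limitations

* The guide tree is NJ-based and fixed; scheme selection inherits any
  gross topology error (mitigated by the branch-length refit, and
  acceptable because subsets share the tree).
* Exact SPR is exponential and capped at 10 leaves; the approximate SPR is
  an upper bound with no approximation-ratio guarantee.
* The AICc sample size uses sites; pattern-count conventions would shift
  absolute AICc values (not usually the ranking).
* The capture models are Gaussian on the logit scale; counts near zero or
  the maximum are handled by the squeeze, not by a binomial likelihood.
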