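---
title: "Asymmetry indices for replication-origin analysis: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Asymmetry indices for replication-origin analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Replication forks copy the two DNA strands asymmetrically, and the
leading- and lagging-strand substitution spectra differ. At
mutational equilibrium without strand asymmetry a single strand
satisfies G = C and T = A; replication perturbs this so that, in
budding yeasts, the leading strand is enriched in adenines and
cytosines. A strand's composition therefore switches regime at
replication origins and at fork-convergence (termination) points, with
the deviation measured by the GC and TA skews (G−C)/(G+C) and
(T−A)/(T+A), or the affinely equivalent simple forms G/(G+C) and
T/(T+A) (`simple = (1 + full)/2`, exact).

Because eukaryotic origins fire stochastically, a locus is sometimes
replicated as leading and sometimes as lagging strand, diluting the
skew in proportion to the locus's *net* leading/lagging exposure. The
package's locus statistic handles this by contrasting the four strand
segments around a position `x` with window length `L`: segment 1 =
upper strand `[x−L, x)`, segment 2 = upper strand `(x, x+L]`, segments
3/4 = lower strand over the same intervals. Writing s(i) for the
simple skew of segment i, computed over third codon positions on
coding strands only,

* `I_GC,cod = [s(1) + s(4)] − [s(2) + s(3)]` (TA analogous),
* `I_GC,int = s(1) − s(2)` for intergenes (TA analogous),
* `I_GC,TA` = unweighted sum of the four components.

At an efficient origin segments 1 and 4 are both lagging-synthesized
and 2 and 3 leading, so the indices peak positive (with the A/C-leading
sign convention); at termination sites the roles invert and the indices
dip; far from both they are centred on zero. Restricting the coding
components to coding-strand reads means the constant
transcription-associated skew contributes equally to s(1)..s(4) and
cancels — the construction is insensitive to the local mix of coding
and template strands, which would otherwise distort windowed skews.

## Key parameters

* `L` (window length, bp): scoring default 20000, profile default
  10000. With ~40 kb between origins, L = 20 kb spans a locus's full
  replication domain without reaching the next origin's; smaller L
  trades bias for variance.
* `window`/`step` for skew profiles: 10 kb / 500 bp defaults (1.5 kb /
  200 bp is the conventional choice for fine-scale centromere-region
  profiles). A step-function composition change produces a linear ramp
  of width `window` in the profile, so extrema sit half a window from
  the switch point.
* Skew direction (`skew_direction()`): which pair of bases is enriched
  on the leading strand; `{A,C}` by default. Every index sign flows
  from it, and it must be established (from timing data or known
  origins) before interpreting signs in a naive genome.
* Intergene scoring rule: intergenes shorter than 1.5 kb are evaluated
  at their midpoint; longer ones on a 1-kb grid centred on the midpoint
  (all points inside the intergene, positions closer than `L` to a
  chromosome end dropped), keeping the maximum. The grid anchoring is a
  package choice; the boundary length 1500 uses the multi-point branch
  ("less than 1.5 kb" read strictly).
* CAI: iterative self-consistent reference set, starting from all
  genes, reference size `max(30, ceiling(0.01 n))`, weights normalized
  per synonymous family with zero counts replaced by 0.5, geometric
  mean excluding ATG, TGG and stops; `cai_filter()` removes the top
  20% (ties at the cut-off all removed).

## Statistical components

Count pooling, not curve averaging: anchor-averaged profiles and
fractional interorigin bins pool base *counts* across anchors/intervals
before computing skews. This keeps sparse classes (intergenic sites in
small windows) computable and is the variance-minimizing estimator;
windows with zero denominator are missing, never zero. Minus-oriented
anchors are mirrored (offset axis flipped, G/C and T/A counts swapped)
so all anchors point the same way.

Left/right significance around anchors uses the Wilcoxon signed-rank
test on per-anchor |skew| pairs at ±d (values for one anchor are
paired); an unpaired rank-sum option exists. Group and correlation
analyses use the rank-sum test and Spearman's rho. Top-k enrichment
uses the exact binomial tail with the origin-containing prevalence as
null. The component combination is a maximum-likelihood logistic
regression with explicit separation and aliasing diagnostics. Skew
trends across fractional interorigin position use a binomial GLM with
multiplicative overdispersion (quasibinomial), weighted by per-bin
denominators — per-bin counts are pooled over heterogeneous intervals,
so extra-binomial scatter is expected and the quasi fit widens the
slope's standard error accordingly.

ROC curves group tied scores into single threshold steps and integrate
by trapezoid, which equals the concordance-pair (Mann-Whitney)
estimator and is invariant under strictly increasing score transforms;
the test suite cross-checks it against an independent implementation
(pROC) and a brute-force pair count.

## The synthetic generator

`synthetic_spec()`/`generate_genome()` build genomes whose composition
carries the causal structure the indices assume. Origins sit every
`origin_spacing` (default 40 kb, the mean yeast interorigin distance;
the first half a spacing from the chromosome start). Firing is
simulated per replication round as independent Bernoulli draws with
per-origin efficiency; each position's leading/lagging state per round
is set by its nearest fired origin, so passive replication emerges
from fork convergence, and `f_lag` is the per-position net exposure
averaged over `n_rounds` (default 100). Upper-strand bases are drawn
with `P(G)/(P(G)+P(C)) = (1 + f_lag·s_rep·σ + g·s_txn)/2` (TA
analogous), where `s_rep = 0.1` is the replication-skew amplitude (the
order of the observed yeast skew jumps), `s_txn = 0.05` the
coding-strand transcription skew, σ the direction sign and g = ±1/0 the
gene-strand indicator. Genes (1.5 kb, giving ~70% coding) alternate
with intergenes (0.6 kb) at genomic G+C 0.38, yeast-like values.
`generate_timing()` adds triangular efficiency-scaled peaks at the true
origins sampled every 50 bp with Gaussian noise. With all efficiencies
1 the exposure is an exact square wave: at an origin the expected
coding GC index equals `2·s_rep`, the anchor-averaged 10-kb-window skew
curve has its extrema 5 kb either side of the origin, and the curve
returns to the genome-average skew at half the origin spacing (~20 kb),
the average fork-convergence point. These closed forms are what the
acceptance checks measure. An option `snap_origins_to_intergenes`
relocates each origin to its nearest intergene midpoint, emulating the
intergenic localization of yeast origins for end-to-end
prediction tests; the default keeps the regular grid.

What the generator does *not* emulate: evolutionary substitution
dynamics (bases are drawn at equilibrium probabilities rather than
mutated over time), indels and repeats, variable gene/intergene
lengths, ancient or relocated origins, and selection heterogeneity
among sites. Passing tests on synthetic data therefore validates the
estimators and their geometry, not the biological effect sizes in any
real genome.

## Numerical and convention choices

* Coordinates are 0-based half-open internally; GFF3 and tabular
  origin files are read/written 1-based inclusive, BED 0-based
  half-open. A base "at position p" occupies `[p, p+1)`; position `x`
  itself belongs to neither window of a segment pair.
* Windows are half-open `[x − w/2, x + w/2)`; profile grids start at 0.
* Terminal regions before the first and after the last gene are not
  intergenes; overlapping genes are merged before gap extraction;
  genes whose length is not a codon multiple are excluded with a
  warning (no splice model); N bases are skipped everywhere.
* Missing index components contribute 0 to the global sum with a
  recorded `n_missing`; a locus is dropped only when all four are
  undefined. Rationale: in compact genomes all-defined is the norm and
  dropping loci would bias prediction denominators.
* Timing peaks are strict local maxima of the 500-bp binned profile
  (`rep(x−500) < rep(x) > rep(x+500)`): plateaus and chromosome ends
  are never called, and calls are invariant under affine rescaling of
  the timing values; `invert = TRUE` accommodates datasets where early
  replication means small values.
* One-to-one colocalization is resolved by smallest midpoint distance
  (ties leftmost); the 10-kb midpoint threshold is strict.
* Ties at the CAI exclusion cut-off are all removed; the reference-set
  iteration caps at 20 rounds.

## Design decisions taken where the construction was open

* The figure-level index formulas are reconstructed from the segment
  description as sums/differences of simple skews; using full skews
  instead is affinely equivalent (factor 2, offset-free) and changes no
  ranking, test or ROC.
* Coding-mean subtraction in anchor profiles subtracts a single
  genome-wide scalar per skew type (the pooled coding-strand skew of
  the same site class) — the minimal reading of subtracting the
  protein-coding contribution.
* Interorigin bins run left origin → right origin on the upper strand
  with no reorientation by firing time, and a site exactly at the
  right origin belongs to the next interval.
* The exact binomial tail is used for enrichment; published analyses
  of this kind sometimes use normal-approximation proportion tests,
  whose p-values can differ by orders of magnitude in the far tail, so
  printed significance levels are comparable only in sign and rough
  magnitude.

## Problem sizes used in the checks

The test suite and the acceptance script run on seeded synthetic
genomes of 0.4–2 Mb (10–50 origins; the skew-geometry check uses
1.64 Mb, i.e. 41 origins of which 39 are far enough from chromosome
ends to be pooled), chosen so that pooled-count standard errors are an
order of magnitude below the effects being measured while the whole
suite stays fast on one CPU.

## Known limitations

* With strongly mixed origin efficiencies, the replicate-to-replicate
  fluctuation of origin usage is shared by all four index components,
  so the global index's advantage over the *best* single component —
  clear for efficient origins, where independent sampling noise
  dominates — can vanish in any given replicate, although it still at
  least matches the component average. The same sharing means longer
  exposure averaging (more `n_rounds`) sharpens all components
  together.
* Index geometry assumes roughly regular origin spacing; near
  telomeres (positions closer than `L` to an end) indices are not
  computed at all rather than computed asymmetrically.
* Skew-based prediction sees the *historical* replication program:
  recently born or recently inactivated origins are mislabelled by
  construction, a property of the method, not of the implementation.
* The CAI reference fraction and the timing-peak rule operate on
  whatever profile they are given; no smoothing is applied, so noisy
  timing data will over-call peaks unless pre-filtered (the strict
  three-point rule calls every local bump).
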