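---
title: "Methods: selection scans on pathway gene sets with planted-truth benchmarking"
author: "domescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selection scans on pathway gene sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Domestication leaves characteristic footprints in a crop's genome.
Genes dragged through a selective sweep lose diversity in the
domesticated population (the landraces), differentiate sharply from the
wild relatives, and skew their site-frequency spectrum toward rare
variants; genes under balancing selection do the opposite. `domescan`
implements the full chain of analyses used to scan a metabolic pathway's
genes for these signatures: per-gene and per-codon summary statistics,
joint empirical-percentile classification, a flanking-gene sweep scan,
multilocus HKA validation, and a test for positional rate variation
(faster evolution downstream in the pathway). Because the original
resequencing panels behind such studies are not reproducible at desk
scale, the package ships a coalescent generator that plants known
selection regimes, and every stage is benchmarked against that ground
truth.

# Statistics

All statistics operate on a `hap_alignment`: aligned haploid CDS
sequences over `{A,C,G,T,N,-}`. Missing data policy, applied uniformly:
`-` is treated as `N`; θ~π~ and all pairwise distances use *pairwise
deletion* (each pair compared over its own comparable sites, per-pair
per-site distances averaged), while S-based statistics (θ~W~, Tajima's
D) use *complete deletion*, which keeps the null theory for S valid.

* θ~π~ = (Σ~i&lt;j~ d~ij~/L~ij~) / C(n,2), per site.
* θ~W~ = S / (a~n~ L~eff~), a~n~ = Σ~i=1~^n−1^ 1/i.
* Tajima's D follows the 1989 constants exactly; an invariant sample
  (S = 0) is reported as `NA` with an `invariant` flag and printed as
  "Invariant" — zero and undefined are different statements, and the
  tables preserve that distinction.
* F~ST~ is Hudson's 1 − H~w~/H~b~ with H~w~ the mean of the two
  within-group per-site diversities and H~b~ the mean over all
  between-group pairs. H~b~ = 0 is reported as 0; negative estimates are
  *not* clamped (they are informative about panmixia). Which estimator
  the original scan's tooling used is not recoverable, so numeric parity
  with any particular legacy module is deliberately not a target; the
  classification layer consumes percentiles, which are invariant to
  monotone re-parameterizations of the estimator.
* Codon-resolution statistics use non-overlapping 3-bp windows in the
  coding frame — the natural unit at which "site-level" selection calls
  can be annotated as synonymous or nonsynonymous. A window's coding
  effect is monomorphic, synonymous, nonsynonymous, or complex (two or
  more segregating positions, or a majority haplotype carrying an
  internal stop, which also raises a warning).

## Ka/Ks

`kaks_pair()` implements Nei–Gojobori (1986): per-codon synonymous site
fractions (changes to stop codons count as nonsynonymous
opportunities), path-averaged difference counts for multi-hit codons
(paths through stop codons are excluded unless all paths cross one),
Jukes–Cantor correction d = −3/4·log(1 − 4p/3), and a `SATURATED` flag
when a proportion reaches 3/4. NG86 was chosen over the HKY-corrected
variants used by legacy calculators because every quantity in it is
enumerable — each test value in the suite is checked against exhaustive
neighbour/path enumeration. At the divergences simulated here
(≈ 0.1 substitutions/site) the extra corrections of fancier estimators
do not change sign or ordering conclusions.

Which two sequences enter a *population's* Ka/Ks is genuinely
underdetermined; the default compares the group majority consensus with
the outgroup (ties broken toward the reference, then alphabetically),
and `mode = "pairs"` averages over all member–outgroup pairs instead.
The mode is recorded in the result. Significance against neutrality is
a doubled exact binomial tail on the rounded (Na, Ns) split with
p₀ = Sa/(Sa+Ss) — the doubled-tail form makes the textbook example
"Na = 0 of 20 at p₀ = 0.75 gives p = 2·0.25²⁰" hold exactly.

## Gene-level classification

Purifying: θ~π~ and θ~W~ of the descendant sample below the 5th
percentile of the background, F~ST~ above the 95th, and D < 0.
Balancing: θ~π~ and θ~W~ above the 75th percentile, D above the 95th,
F~ST~ below the 90th. All inequalities are strict (a value exactly at
the cutoff fails; D = 0 satisfies neither sign), so boundary behaviour
is deterministic. A descendant-invariant gene is labelled `invariant`.

Percentiles are "fraction of background strictly below, ties counted
half". When the background is the analyzed set itself (the default),
the focal gene's own entry is left out, so the minimum of a distinct
background sits at percentile 0. The background is configurable for a
reason: tail criteria against the analyzed set itself can never flag
more than the tail mass (15 planted genes cannot all be in their own
lower 5%). The benchmark therefore evaluates recovery against the
known-neutral loci — the analog of the genome-wide reference
distribution such criteria are normally calibrated on, where selected
pathway genes are rare.

Codon-level calls use absolute criteria: purifying when the
wild-to-landrace diversity drop at a codon exceeds the supplied
background mean gene diversity with F~ST~ > 0 and D < 0; balancing for
the mirrored increase with D > 0. A gene whose codons are called in
*both* directions is reported as "both" at the codon summary level —
the gene-level labels stay mutually exclusive.

## Multilocus HKA

The validation stage fits an independent-Poisson composite likelihood:
S~i~ ~ Poisson(k~i~ θ~i~ L~i~ a~n~) and
D~i~ ~ Poisson(θ~i~ L~i~ (T + (n~i~+1)/(2n~i~))). The (n+1)/(2n) term
is the within-sample coalescent correction to divergence; it is a
documented switch (default on). The selection parameter k~i~ scales
polymorphism only — divergence is left untouched — which is itself a
modelling choice recorded behind a flag-shaped argument rather than
hidden. Given T, all per-locus parameters maximize in closed form
(selected loci saturate their two observations), so each model reduces
to a one-dimensional profile likelihood in T, maximized by a log-grid
multistart plus golden-section refinement: deterministic, no MCMC. The
LRT statistic 2(ℓ~sel~ − ℓ~neu~) is non-negative by construction (the
selection profile dominates pointwise in T and is additionally
evaluated at the neutral optimum), with df = |selected set|.
Calibration at realistic counts (θLa ≈ 30, 34 neutral + 5 tested loci)
holds the nominal 5% size within its binomial confidence band, and
k = 0.1 at five loci is detected at α = 0.001 essentially always.

## PRV and trees

`kendall_tau()` computes tie-corrected τ-b. PPI positions are heavily
tied (several genes share a pathway position), so τ-a would be
misleading. For n ≤ 8 the two-sided p-value is exact (enumeration of
all orderings); above that, the normal approximation with the
tie-adjusted null variance of C − D. The approximation is slightly
anticonservative at n ≈ 30 with heavy ties (observed null rejection
≈ 0.05–0.10), which is why the calibration study reports the realized
rate rather than assuming nominal size. `prv_test()` excludes undefined
ratios with a count and re-tests after dropping the single maximum
ratio — the standard robustness check against one outlier driving the
trend.

UPGMA uses size-weighted average linkage on per-site p-distances with
pairwise deletion (no multiple-hit correction: within-species
divergences here are ~10⁻³/site, where p-distance and corrected
distance are indistinguishable). Ties on the minimum merge distance are
broken toward the lexicographically smallest pair of cluster labels and
children are ordered by label, so output Newick strings are canonical
and byte-reproducible. Ultrametricity of the output is asserted to
1e−9 in the tests.

# The generator

The generator is part of the tested surface, not a fixture. Each gene is
simulated under a self-contained Hudson-style coalescent (no
recombination within a gene; infinite-sites mutations placed by Poisson
counts on branches), over a two-population split. Defaults are the
study-shaped conditions:

| parameter | default | meaning |
|---|---|---|
| `theta_wild` | 0.001/site | ancestral/wild diversity scale |
| `n_landrace`, `n_wild` | 20 + 20 | haplotypes per gene |
| gene lengths | 0.5–5 kb | CDS, multiples of 3 |
| `t_split` | 0.1 × 2N gen | population split time |
| `t_bottleneck` | 0.05 × 2N gen | end of the recovered-size phase |
| `bottleneck_factor` | 0.7 | neutral landrace diversity multiplier |
| `outgroup_divergence` | 0.1 subs/site | outgroup branch length |
| purifying multiplier | 0.05 | landrace diversity scale at swept genes |
| balancing multiplier | 4 | landrace diversity scale at balanced genes |
| `purifying_weight` | 0.3 | geometric singleton-skew weight |

The neutral and balancing landrace history is a *founder squeeze with
recovery*: full size on [0, t_bottleneck), a founder-phase size solved
(from the closed-form expected pair-coalescence time) so the realized
landrace diversity meets the configured multiplier, then the ancestral
population. This demography reduces diversity ~1.4-fold while leaving
Tajima's D near zero and F~ST~ ≈ 0.2 — the regime such crop–wild panels
actually show. A uniform recent contraction tuned to the same diversity
loss was rejected during development because it inflates neutral
landrace D to ≈ +0.8 and makes ~10% of neutral genes invariant, neither
of which resembles the observed data scale.

Planted regimes:

* **Purifying** (a completed sweep): the landrace population is
  uniformly small throughout its history (size solved from the target
  multiplier), and derived-allele counts at landrace-polymorphic sites
  are resampled toward singletons with geometric weight w = 0.3. The
  skew lowers π below the nominal multiplier (singletons carry little
  pairwise diversity per segregating site); the realized per-group θ~π~
  is recorded in the truth table.
* **Balancing** (a trans-specific balanced polymorphism): the gene —
  non-recombining — carries two allelic classes at an intermediate
  frequency p ∈ (0.4, 0.6) in the landrace; linked landrace variation
  is reshaped around p, and additional variants are injected (at least
  one, sized so landrace diversity reaches multiplier × θ~wild~). The
  balanced locus is modelled as shielded from the founder loss — the
  balanced alleles are precisely the variation that survives a
  bottleneck — and the classes segregate at lower frequency
  (0.05–0.25) in the wild sample, so the landrace gains more diversity
  than the wild and the codon-level contrast stays positive while
  F~ST~ drops. Wild diversity at balancing genes is therefore above
  `theta_wild` by design; the wild-recovery benchmark is asserted on
  non-balancing genes.
* The outgroup evolves from the ancestral sequence by accepted
  substitution proposals: synonymous accepted with probability
  min(1, 1/ω), nonsynonymous with min(1, ω), stop-creating proposals
  rejected, total accepted count Poisson(divergence × L). This matches
  the NG86 estimator's site model, so planted ω ∈ {0.2, 1} is recovered
  within ±5% on average (the benchmark requires ±30%). Ingroup derived
  alleles likewise avoid creating premature stops — segregating
  nonsense variants would not persist in a functional CDS.

What the generator does *not* emulate: recombination within genes,
gene conversion, sequencing error, alignment error, linked selection
between neighbouring genes, and real gene-order structure (coordinates
are synthetic, two chromosomes, uniform spacing). Passing benchmarks
therefore demonstrate correctness of the estimators and the internal
consistency of the classification chain under the stated model — not
robustness to the full messiness of resequencing data.

# Benchmark design and known limitations

Problem sizes were chosen to exercise the study-shaped regime while
keeping the full suite in minutes on one core: 1000 replicates for the
neutral D calibration (n = 40, θL = 3), one seeded 100-gene dataset for
classifier recovery, 500/200 replicates for HKA size/power, 100
replicates of 30 genes for PRV power, 100 replicates per ω for Ka/Ks
recovery, and 200 randomized cases for the brute-force estimator
oracles at n ≤ 6, L ≤ 60.

One benchmark is knowingly not met, and the package reports it rather
than redefining it away. Under the stated study conditions
(θ = 0.001/site, CDS of 0.5–5 kb, 20 landrace haplotypes), a ×0.05
purifying regime leaves E[S] ≈ 0.3 in the landrace sample, so roughly
three quarters of planted purifying genes are *invariant* — and the
classifier's contract labels S = 0 genes `invariant`, never
`purifying` (the negative-D condition is undefined at S = 0, and
invariant background genes block the lower-5% percentile for the rest).
Gene-level purifying sensitivity is therefore structurally ≈ 0–0.1, far
below the 0.8 the recovery benchmark asks of both classes; reaching
P(S ≥ 1) ≥ 0.8 would need ~13 kb genes, outside the stated length
range. The balancing class meets the same benchmark comfortably
(sensitivity ≈ 0.9, false-positive rate ≤ 0.03). In practice nearly all
planted purifying genes are still *detected* — as `invariant`, the
extreme of diversity elimination, exactly how fixed genes are counted
as sweep evidence in the flanking-gene scan — and the acceptance report
carries that detection rate under its own name.

Other limitations worth knowing: the HKA likelihood is composite
(independent Poisson counts), so its χ² reference is approximate at low
counts; the percentile classifier inherits the usual outlier-test
caveat that some tail mass is always flagged, which is why candidate
calls are validated by HKA before being read as selection; and the
pseudo-phasing path for unphased heterozygous VCF genotypes is a
convention (random assignment under a recorded seed), defensible for
highly inbred material only.
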