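# domescan

Selection scans for domestication candidates in pathway gene sets.

`domescan` re-implements, as a reusable and fully tested R pipeline, the
population-genetic analysis used to contrast a domesticated crop
population ("landraces", the descendant) against its wild and weedy
ancestral relatives across the genes of a metabolic pathway — the kind of
scan used to find starch-synthesis genes under selection during cereal
domestication. It is aimed at population geneticists who want each stage
of such a scan as an auditable, composable function, benchmarked against
ground truth from a built-in coalescent simulator rather than against an
unreproducible external resequencing panel.

## What it computes

For each gene (aligned haploid CDS sequences for the two groups plus an
outgroup):

* **Diversity statistics** — nucleotide diversity per site
  θ<sub>π</sub> = (Σ<sub>i&lt;j</sub> d<sub>ij</sub>/L<sub>ij</sub>) / C(n,2),
  Watterson's θ<sub>W</sub> = S/(a<sub>n</sub>L) with
  a<sub>n</sub> = Σ<sub>i=1</sub><sup>n−1</sup> 1/i, Tajima's
  D = (Π − S/a₁)/√(e₁S + e₂S(S−1)), and Hudson's
  F<sub>ST</sub> = 1 − H<sub>w</sub>/H<sub>b</sub>, at gene and
  per-codon resolution. Genes with S = 0 are reported as *Invariant*,
  never as D = 0.
* **Ka/Ks** — Nei–Gojobori (1986) site and path-averaged difference
  counting with Jukes–Cantor correction, group consensus versus the
  outgroup, plus a doubled exact binomial test of the Na:Ns split
  against the Sa:Ss neutral expectation.
* **Selection classification** — the joint empirical-percentile
  criteria: *purifying* = θ<sub>π</sub> and θ<sub>W</sub> in the lower
  5% of the descendant distribution, F<sub>ST</sub> above the 95th
  percentile and D < 0; *balancing* = θ<sub>π</sub> and θ<sub>W</sub> in
  the upper 25%, D in the upper 5% and F<sub>ST</sub> below the 90th
  percentile; plus per-codon sign criteria and a flanking-gene sweep
  scan (up to ten gene models each side).
* **Multilocus HKA validation** — maximum-likelihood fit of
  S<sub>i</sub> ~ Poisson(k<sub>i</sub>θ<sub>i</sub>L<sub>i</sub>a<sub>n</sub>),
  D<sub>i</sub> ~ Poisson(θ<sub>i</sub>L<sub>i</sub>(T + (n+1)/2n)), with a
  likelihood-ratio test of free k<sub>i</sub> at candidate loci
  (χ² with df = number of candidates).
* **Positional rate variation (PRV)** — Kendall's τ-b between pathway
  position (PPI) and Ka/Ks, with a leave-one-out re-test dropping the
  maximum ratio, and UPGMA trees from pairwise p-distances.

The built-in generator (`sim_config()`, `simulate_gene()`,
`generate_dataset()`) simulates a Hudson-style structured coalescent over
a two-population split with a domestication founder bottleneck, plants
per-gene selection regimes (diversity loss + singleton skew; balanced
polymorphism with trans-specific intermediate-frequency variants), and
evolves an outgroup with codon-aware, ω-filtered substitutions — so every
downstream stage has ground truth.

## Worked example

```r
library(domescan)

genes <- data.frame(gene_id = c("sweep1", "bal1", "neu1"), length = 3000,
                    regime = c("purifying", "balancing", "neutral"),
                    multiplier = c(0.05, 4, 1), omega = 0.3)
cfg <- sim_config(genes, seed = 11)
sim <- simulate_gene(cfg, "bal1")
lr  <- names(sim$partition)[sim$partition == "landrace"]

theta_pi(sim$alignment, lr)
#> [1] 0.004887719
tajimas_d(sim$alignment, lr)
#> [1] 3.104691
hudson_fst(sim$alignment, sim$partition)
#> [1] 0.2978252
```

The balancing gene shows elevated landrace diversity (θ<sub>π</sub> ≈
0.0049 against the simulated neutral wild scale of 0.001), strongly
positive Tajima's D (+3.10, intermediate-frequency variants) and modest
F<sub>ST</sub> (0.30) — exactly the joint signature the gene-level
classifier requires before labelling a gene *balancing*.

The `analysis/` directory holds the full workflow as numbered drivers:

```sh
Rscript analysis/01_simulate.R       # 100-gene study-shaped dataset
Rscript analysis/02_gene_stats.R     # per-gene statistics tables
Rscript analysis/03_kaks_prv.R       # Ka/Ks ~ pathway position
Rscript analysis/04_selection_scan.R # gene/codon calls + sweep scan
Rscript analysis/05_hka_trees.R      # HKA validation + UPGMA trees
```

Each prints what it found and writes its tables under `results/`.

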