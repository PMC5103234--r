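#!/usr/bin/env Rscript
# Per-gene population-genetic statistics for both groups: theta-pi,
# Watterson's theta, Tajima's D (with the Invariant marker), Hudson FST
# and NG86 Ka/Ks of each group consensus against the outgroup.
# Writes results/gene_stats.tsv.

library(domescan)

data <- read_dataset("results/data")
stats <- gene_stats_table(data)
write_gene_stats(stats, "results/gene_stats.tsv")

lr <- stats[stats$group == "landrace", ]
wd <- stats[stats$group == "wild", ]
ssp1 <- data$pathway$gene_id[data$pathway$pathway == "SSP1"]

cat("Mean theta-pi, SSP1, wild:      ",
    signif(mean(wd$theta_pi[wd$gene %in% ssp1]), 4), "\n")
cat("Mean theta-pi, all genes:  landrace",
    signif(mean(lr$theta_pi), 4), " wild",
    signif(mean(wd$theta_pi), 4), "\n")
cat("Mean Tajima's D (landrace):",
    signif(mean(lr$tajimas_d, na.rm = TRUE), 3), "with",
    sum(lr$invariant), "invariant gene(s)\n")
cat("Highest FST:", signif(max(lr$fst), 3), "at gene",
    lr$gene[which.max(lr$fst)], "\n")
cat("Fraction of SSP1 genes with Ka/Ks < 1 (landrace):",
    mean(lr$KaKs[lr$gene %in% ssp1] < 1, na.rm = TRUE), "\n")
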