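#!/usr/bin/env Rscript
# Positional rate variation: Kendall's tau-b between pathway position
# (PPI) and Ka/Ks per pathway and group, with the leave-one-out
# robustness re-test dropping the maximum-ratio gene.
# Writes results/prv.tsv.

library(domescan)

data <- read_dataset("results/data")
stats <- read_gene_stats("results/gene_stats.tsv")

rows <- list()
for (pw in unique(data$pathway$pathway)) {
  for (grp in c("landrace", "wild")) {
    kt <- stats[stats$group == grp, c("gene", "KaKs")]
    names(kt)[2] <- "ratio"
    res <- tryCatch(prv_test(kt, data$pathway, pw),
                    error = function(e) NULL)
    if (is.null(res)) next
    rows[[paste(pw, grp)]] <- data.frame(
      pathway = pw, group = grp, tau = res$tau, p_value = res$p_value,
      n_genes = res$n_genes, loo_dropped = res$leave_one_out$dropped,
      loo_tau = res$leave_one_out$tau, loo_p = res$leave_one_out$p_value)
  }
}
prv <- do.call(rbind, rows)
write.table(prv, "results/prv.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("PRV results (tau between PPI and Ka/Ks):\n")
print(prv[, c("pathway", "group", "tau", "p_value", "loo_tau")],
      row.names = FALSE, digits = 3)
cat("\nSSP1 carries the planted omega gradient (0.1 -> 0.8 with PPI);",
    "\nthe other pathways have constant omega and should show no trend.\n")
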