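#!/usr/bin/env Rscript
# Multilocus HKA validation of the called candidates against neutral
# loci, and UPGMA trees for the strongest purifying and balancing
# candidates. Writes results/hka.tsv and results/trees/*.nwk.

library(domescan)

data <- read_dataset("results/data")
calls <- read.delim("results/calls_gene.tsv")

set.seed(20260920)
none_ids <- calls$gene[calls$label == "none"]
neutral <- sort(sample(none_ids, min(34, length(none_ids))))

rows <- list()
for (side in c("purifying", "balancing")) {
  cand <- calls$gene[calls$label == side]
  if (side == "purifying") {
    cand <- union(cand, calls$gene[calls$label == "invariant"])
  }
  cand <- head(cand, if (side == "purifying") 5 else 9)
  if (!length(cand)) next
  ds <- hka_dataset_from_alignments(data$alignments, data$partition,
                                    genes = c(neutral, cand),
                                    selected = cand)
  h <- hka_lrt(ds)
  rows[[side]] <- data.frame(candidate_set = side,
                             n_selected = h$df,
                             n_neutral = length(neutral),
                             statistic = h$statistic, df = h$df,
                             p_value = h$p_value,
                             T_hat = h$selection$T)
}
hka <- do.call(rbind, rows)
write.table(hka, "results/hka.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Multilocus HKA validation (candidates vs", length(neutral),
    "neutral loci):\n")
print(hka, row.names = FALSE, digits = 4)

# trees for the top-FST purifying candidate and a balancing candidate
dir.create("results/trees", showWarnings = FALSE, recursive = TRUE)
pick <- c(calls$gene[calls$label %in% c("purifying", "invariant")][1],
          calls$gene[calls$label == "balancing"][1])
pick <- pick[!is.na(pick)]
for (gid in pick) {
  aln <- data$alignments[[gid]]
  ingroup <- setdiff(aln$sample_ids, "outgroup_1")
  tr <- upgma(pairwise_distance_matrix(subset_alignment(aln, ingroup)))
  write_newick(tr, file.path("results/trees", paste0(gid, ".nwk")))
  cat("Wrote UPGMA tree for", gid, "(root height",
      signif(tr$height, 3), ")\n")
}
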