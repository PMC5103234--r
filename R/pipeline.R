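# End-to-end orchestration: expression screen -> per-gene statistics ->
# gene/codon classification -> flanking sweep scan -> HKA validation ->
# PRV -> UPGMA trees, with TSV/JSON/Newick artifacts.

#' Pipeline configuration
#'
#' @param dataset_dir directory written by \code{generate_dataset} (or
#'   hand-assembled in the same layout)
#' @param out_dir output directory for report artifacts
#' @param cutoffs percentile cutoffs for \code{classify_genes}
#' @param expression_threshold day-average FPKM strictly above which a
#'   gene is analyzed (default 0)
#' @param sweep_radius flanking genes per side for the sweep scan
#' @param hka_neutral gene ids to use as HKA neutral loci (default:
#'   genes classified "none", capped at 34)
#' @param background optional external background stats table for
#'   percentiles (default: the analyzed gene set itself)
#' @param mean_diversity background mean gene diversity for the
#'   codon-level criteria (default: mean landrace theta-pi of the
#'   analyzed set)
#' @param allow_genes genes to retain even if the expression screen
#'   would drop them
#' @param tree_genes genes to emit UPGMA trees for (default: strongest
#'   purifying and balancing call)
#' @param seed integer seed (pseudo-phasing, neutral-locus subsampling)
#' @return a \code{pipeline_config} list
#' @export
pipeline_config <- function(dataset_dir, out_dir,
                            cutoffs = default_cutoffs(),
                            expression_threshold = 0,
                            sweep_radius = 10,
                            hka_neutral = NULL,
                            background = NULL,
                            mean_diversity = NULL,
                            allow_genes = character(0),
                            tree_genes = NULL,
                            seed = 1L) {
  stopifnot(sweep_radius >= 1,
            all(unlist(cutoffs) > 0), all(unlist(cutoffs) < 100))
  structure(list(dataset_dir = dataset_dir, out_dir = out_dir,
                 cutoffs = cutoffs,
                 expression_threshold = expression_threshold,
                 sweep_radius = sweep_radius, hka_neutral = hka_neutral,
                 background = background, mean_diversity = mean_diversity,
                 allow_genes = allow_genes, tree_genes = tree_genes,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Expression-presence screen
#'
#' "Day average" = mean of the available FPKM timepoint columns per
#' gene; genes with day average strictly above the threshold are
#' analyzed.
#'
#' @param expression data.frame with \code{gene_id} and one or more
#'   numeric FPKM columns
#' @param threshold inclusion threshold (strict >, default 0)
#' @return character vector of included gene ids; excluded ids in
#'   attribute \code{"excluded"}
#' @export
expression_screen <- function(expression, threshold = 0) {
  num <- vapply(expression, is.numeric, logical(1))
  num["gene_id"] <- FALSE
  if (!any(num)) stop("expression table has no numeric FPKM column")
  day_avg <- rowMeans(expression[, num, drop = FALSE], na.rm = TRUE)
  keep <- day_avg > threshold
  included <- expression$gene_id[keep]
  attr(included, "excluded") <- expression$gene_id[!keep]
  included
}

#' Merged per-gene statistics table for a dataset
#'
#' Landrace and wild summary statistics per gene, cross-group Hudson
#' FST, and Ka/Ks of each group's consensus against the outgroup.
#'
#' @param data dataset list from \code{read_dataset} (or equivalent)
#' @param genes genes to analyze (default: all alignments)
#' @return data.frame with one row per gene x group
#' @export
gene_stats_table <- function(data, genes = names(data$alignments)) {
  rows <- lapply(genes, function(gid) {
    aln <- data$alignments[[gid]]
    fst <- hudson_fst(aln, data$partition)
    og <- group_samples(aln, data$partition, "outgroup")
    ref <- data$references[[gid]]
    out <- lapply(c("landrace", "wild"), function(grp) {
      rec <- gene_stat_record(aln, data$partition, grp)
      rec$fst <- fst
      if (length(og)) {
        ogseq <- alignment_strings(aln)[[og[1]]]
        kk <- kaks_group(aln, data$partition, grp, ogseq, reference = ref)
        rec$Ka <- kk$Ka
        rec$Ks <- kk$Ks
        rec$KaKs <- kk$ratio
        rec$kaks_p <- kk$p_vs_1
        rec$kaks_status <- kk$status
      }
      rec
    })
    do.call(rbind, out)
  })
  do.call(rbind, rows)
}

# wide landrace-side table used by the classifier
landrace_class_table <- function(stats) {
  lr <- stats[stats$group == "landrace", ]
  data.frame(gene = lr$gene, theta_pi = lr$theta_pi, theta_w = lr$theta_w,
             tajimas_d = lr$tajimas_d, S = lr$S, fst = lr$fst,
             stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Deterministic given the config seed; writes gene_stats.tsv,
#' calls_gene.tsv, calls_codon.tsv, sweep.tsv, hka.tsv, prv.tsv,
#' trees/<gene>.nwk, run_manifest.json and (when the dataset carries a
#' truth table) confusion.tsv under \code{config$out_dir}.
#'
#' @param config a \code{pipeline_config}
#' @return invisible list of all result tables
#' @export
run_pipeline <- function(config) {
  data <- read_dataset(config$dataset_dir)
  dir.create(file.path(config$out_dir, "trees"), recursive = TRUE,
             showWarnings = FALSE)

  # stage 1: expression screen
  genes <- names(data$alignments)
  if (!is.null(data$expression)) {
    included <- expression_screen(data$expression,
                                  config$expression_threshold)
    if (!length(intersect(included, data$pathway$gene_id))) {
      stop("expression screen left no gene overlapping the pathway map")
    }
    genes <- intersect(genes, union(included, config$allow_genes))
  }
  if (!length(genes)) stop("no genes to analyze after screening")

  # stage 2: per-gene statistics
  stats <- gene_stats_table(data, genes)
  write_gene_stats(stats, file.path(config$out_dir, "gene_stats.tsv"))

  # stage 3: gene-level classification
  lrt_tab <- landrace_class_table(stats)
  gene_calls <- classify_genes(lrt_tab, background = config$background,
                               cutoffs = config$cutoffs)
  utils::write.table(gene_calls, file.path(config$out_dir,
                                           "calls_gene.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # stage 4: codon-level classification
  mean_div <- config$mean_diversity %||% mean(lrt_tab$theta_pi)
  codon_calls <- do.call(rbind, lapply(genes, function(gid) {
    classify_codons(codon_stats(data$alignments[[gid]], data$partition),
                    mean_div)
  }))
  utils::write.table(codon_calls[codon_calls$label != "none", ],
                     file.path(config$out_dir, "calls_codon.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  both <- genes_with_both(codon_calls)

  # stage 5: flanking sweep scan over the selected/invariant genes
  focal <- gene_calls$gene[gene_calls$label != "none"]
  sweep <- if (length(focal)) {
    do.call(rbind, lapply(focal, flanking_sweep_scan,
                          gene_order = data$gene_order,
                          calls = gene_calls,
                          radius = config$sweep_radius))
  } else {
    data.frame()
  }
  utils::write.table(sweep, file.path(config$out_dir, "sweep.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # stage 6: HKA validation of candidate sets
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(sub_seed(config$seed, 424243L))
  neutral <- config$hka_neutral %||% {
    none <- gene_calls$gene[gene_calls$label == "none"]
    if (length(none) > 34) sort(sample(none, 34)) else none
  }
  hka <- list()
  for (set_name in c("purifying", "balancing")) {
    cand <- gene_calls$gene[gene_calls$label == set_name]
    if (!length(cand) || length(neutral) < 1) next
    ds <- hka_dataset_from_alignments(data$alignments, data$partition,
                                      genes = c(neutral, cand),
                                      selected = cand)
    hka[[set_name]] <- hka_lrt(ds)
  }
  hka_tab <- do.call(rbind, lapply(names(hka), function(nm) {
    h <- hka[[nm]]
    data.frame(candidate_set = nm, n_selected = h$df,
               n_neutral = length(neutral), statistic = h$statistic,
               df = h$df, p_value = h$p_value, T_hat = h$selection$T,
               stringsAsFactors = FALSE)
  }))
  if (is.null(hka_tab)) hka_tab <- data.frame()
  utils::write.table(hka_tab, file.path(config$out_dir, "hka.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # stage 7: PRV per pathway per group
  prv_rows <- list()
  for (pw in unique(data$pathway$pathway)) {
    for (grp in c("landrace", "wild")) {
      kt <- stats[stats$group == grp, c("gene", "KaKs")]
      names(kt)[2] <- "ratio"
      res <- tryCatch(prv_test(kt, data$pathway, pw),
                      error = function(e) NULL)
      if (is.null(res)) next
      prv_rows[[paste(pw, grp)]] <- data.frame(
        pathway = pw, group = grp, tau = res$tau, p_value = res$p_value,
        n_genes = res$n_genes, n_excluded = res$n_excluded,
        loo_dropped = res$leave_one_out$dropped,
        loo_tau = res$leave_one_out$tau,
        loo_p = res$leave_one_out$p_value,
        stringsAsFactors = FALSE)
    }
  }
  prv_tab <- do.call(rbind, prv_rows)
  if (is.null(prv_tab)) prv_tab <- data.frame()
  utils::write.table(prv_tab, file.path(config$out_dir, "prv.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # stage 8: UPGMA trees
  tree_genes <- config$tree_genes %||% {
    pick <- function(lbl, decreasing) {
      cand <- gene_calls[gene_calls$label == lbl, ]
      if (!nrow(cand)) return(character(0))
      cand$gene[order(cand$pct_fst, decreasing = decreasing)][1]
    }
    c(pick("purifying", TRUE), pick("balancing", FALSE))
  }
  for (gid in tree_genes) {
    aln <- data$alignments[[gid]]
    ingroup <- setdiff(aln$sample_ids,
                       group_samples(aln, data$partition, "outgroup"))
    tr <- upgma(pairwise_distance_matrix(subset_alignment(aln, ingroup)))
    write_newick(tr, file.path(config$out_dir, "trees",
                               paste0(gid, ".nwk")))
  }

  # confusion matrix against truth, when available
  confusion <- NULL
  if (!is.null(data$truth)) {
    tr <- data$truth[match(gene_calls$gene, data$truth$gene_id), ]
    confusion <- as.data.frame(table(truth = tr$regime,
                                     call = gene_calls$label))
    utils::write.table(confusion, file.path(config$out_dir,
                                            "confusion.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    seed = config$seed,
    n_genes_analyzed = length(genes),
    expression_threshold = config$expression_threshold,
    sweep_radius = config$sweep_radius,
    cutoffs = config$cutoffs,
    hka_neutral = neutral,
    dataset_manifest_seed = data$manifest$seed)
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(genes = genes, stats = stats, gene_calls = gene_calls,
                 codon_calls = codon_calls, both = both, sweep = sweep,
                 hka = hka, prv = prv_tab, confusion = confusion))
}

#' Classifier recovery against planted truth
#'
#' Sensitivity and false-positive rate per planted class, judged gene
#' by gene against the generator's truth table.
#'
#' @param gene_calls data.frame from \code{classify_genes}
#' @param truth truth table with \code{gene_id} and \code{regime}
#' @return data.frame with one row per class
#' @export
classifier_recovery <- function(gene_calls, truth) {
  regime <- truth$regime[match(gene_calls$gene, truth$gene_id)]
  out <- lapply(c("purifying", "balancing"), function(cls) {
    planted <- regime == cls
    called <- gene_calls$label == cls
    data.frame(
      class = cls,
      n_planted = sum(planted),
      sensitivity = if (any(planted)) mean(called[planted]) else NA_real_,
      fpr = if (any(!planted)) mean(called[!planted]) else NA_real_)
  })
  do.call(rbind, out)
}
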