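# Gene- and codon-level selection classification and the flanking-gene
# sweep scan.

#' Empirical percentile of a value against a background
#'
#' Fraction of background values strictly less than x, times 100, with
#' ties counted half. When x is itself a member of the background, drop
#' its own entry first (as \code{classify_genes} does) so that e.g. the
#' minimum of a distinct background sits at percentile 0.
#'
#' @param values background values (non-empty)
#' @param x query value
#' @return percentile in [0, 100]
#' @export
empirical_percentile <- function(values, x) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("empty background distribution")
  if (length(values) < 20) {
    warning("background of ", length(values),
            " values; 5% tail thresholds are unreliable below 20")
  }
  100 * (sum(values < x) + 0.5 * sum(values == x)) / length(values)
}

default_cutoffs <- function() {
  list(purifying_diversity = 5,    # theta-pi and theta-w below this percentile
       purifying_fst = 95,         # FST above this percentile
       balancing_diversity = 75,   # theta-pi and theta-w above this (upper 25%)
       balancing_d = 95,           # Tajima's D above this (upper 5%)
       balancing_fst = 90)         # FST below this percentile
}

#' Classify genes as under purifying or balancing selection
#'
#' Joint empirical-percentile criteria on the descendant (landrace)
#' sample:
#' purifying = theta-pi and theta-w in the lower tail
#' (< \code{purifying_diversity} percentile), FST above
#' \code{purifying_fst}, and negative Tajima's D; balancing = theta-pi
#' and theta-w in the upper tail (> \code{balancing_diversity}), Tajima's
#' D above the \code{balancing_d} percentile, and FST below
#' \code{balancing_fst}. All inequalities are strict. Genes invariant in
#' the descendant sample are labelled "invariant".
#'
#' Percentiles are taken against \code{background}; by default the
#' analyzed gene set itself, in which case the focal gene's own row is
#' left out of its background. Supplying an external (e.g. genome-wide
#' or known-neutral) background reproduces the situation where selected
#' genes are rare in the reference distribution.
#'
#' @param stats data.frame with one row per gene: \code{gene},
#'   \code{theta_pi}, \code{theta_w}, \code{tajimas_d} (NA = invariant),
#'   \code{S}, \code{fst} -- descendant-population statistics plus the
#'   cross-population FST
#' @param background background table with the same columns (default:
#'   \code{stats})
#' @param cutoffs percentile cutoffs, see \code{default_cutoffs()}
#' @return data.frame of selection calls with evidence percentiles
#' @export
classify_genes <- function(stats, background = NULL,
                           cutoffs = default_cutoffs()) {
  self_bg <- is.null(background)
  if (self_bg) background <- stats
  if (any(is.na(stats$fst))) stop("missing FST for gene(s): ",
                                  paste(stats$gene[is.na(stats$fst)],
                                        collapse = ", "))
  out <- lapply(seq_len(nrow(stats)), function(i) {
    g <- stats[i, ]
    bg <- if (self_bg) background[-i, ] else background
    p_pi <- empirical_percentile(bg$theta_pi, g$theta_pi)
    p_w <- empirical_percentile(bg$theta_w, g$theta_w)
    p_fst <- empirical_percentile(bg$fst, g$fst)
    p_d <- if (is.na(g$tajimas_d)) NA_real_ else {
      empirical_percentile(bg$tajimas_d, g$tajimas_d)
    }
    label <- if (g$S == 0) {
      "invariant"
    } else if (p_pi < cutoffs$purifying_diversity &&
               p_w < cutoffs$purifying_diversity &&
               p_fst > cutoffs$purifying_fst &&
               !is.na(g$tajimas_d) && g$tajimas_d < 0) {
      "purifying"
    } else if (p_pi > cutoffs$balancing_diversity &&
               p_w > cutoffs$balancing_diversity &&
               !is.na(p_d) && p_d > cutoffs$balancing_d &&
               p_fst < cutoffs$balancing_fst) {
      "balancing"
    } else {
      "none"
    }
    data.frame(gene = g$gene, level = "gene", label = label,
               pct_theta_pi = p_pi, pct_theta_w = p_w, pct_fst = p_fst,
               pct_tajimas_d = p_d, tajimas_d = g$tajimas_d,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Classify codons as under purifying or balancing selection
#'
#' Site-level criteria on a per-codon track: purifying when the
#' ancestor-to-descendant diversity reduction (pi_wild - pi_landrace)
#' exceeds the supplied mean gene diversity, FST > 0 and Tajima's D < 0;
#' balancing when the diversity increase exceeds the same threshold,
#' FST > 0 and D > 0. Strict signs: D = 0 (or invariant) satisfies
#' neither. Monomorphic codons get no call. Calls are annotated with the
#' codon's coding effect.
#'
#' @param codon_track data.frame from \code{codon_stats}
#' @param mean_diversity genome/background mean per-site gene diversity
#' @return data.frame of codon-level calls (label "none" rows included)
#' @export
classify_codons <- function(codon_track, mean_diversity) {
  delta <- codon_track$pi_wild - codon_track$pi_landrace
  d <- codon_track$tajd_landrace
  fst <- codon_track$fst
  label <- rep("none", nrow(codon_track))
  pur <- delta > mean_diversity & fst > 0 & !is.na(d) & d < 0
  bal <- (-delta) > mean_diversity & fst > 0 & !is.na(d) & d > 0
  label[pur] <- "purifying"
  label[bal] <- "balancing"
  label[codon_track$effect == "monomorphic"] <- "none"
  data.frame(gene = codon_track$gene, codon = codon_track$codon,
             level = "codon", label = label,
             effect = codon_track$effect,
             delta_pi = delta, fst = fst, tajimas_d = d,
             stringsAsFactors = FALSE)
}

#' Genes with disjoint codon sets under each selection type
#'
#' The gene-level criteria are mutually exclusive; a gene is "both" when
#' distinct codons within it are called purifying and balancing.
#'
#' @param codon_calls data.frame from \code{classify_codons} (possibly
#'   row-bound over genes)
#' @return character vector of gene ids
#' @export
genes_with_both <- function(codon_calls) {
  tab <- table(codon_calls$gene, codon_calls$label)
  labs <- colnames(tab)
  if (!all(c("purifying", "balancing") %in% labs)) return(character(0))
  rownames(tab)[tab[, "purifying"] > 0 & tab[, "balancing"] > 0]
}

#' Flanking-gene sweep scan
#'
#' For a focal gene, counts the selection labels of up to \code{radius}
#' consecutive gene models on each side (same chromosome; windows
#' truncate at chromosome ends) and flags a putative sweep when at least
#' one flanking gene carries a non-"none" label (selected or invariant).
#'
#' @param focal_gene gene id
#' @param gene_order data.frame with columns \code{gene}, \code{chrom},
#'   \code{start} (genes are ordered by chromosome and start)
#' @param calls data.frame with columns \code{gene}, \code{label}
#' @param radius flanking genes per side (default 10)
#' @return one-row data.frame of counts and the sweep flag
#' @export
flanking_sweep_scan <- function(focal_gene, gene_order, calls, radius = 10) {
  ord <- gene_order[order(gene_order$chrom, gene_order$start), ]
  i <- match(focal_gene, ord$gene)
  if (is.na(i)) stop("focal gene '", focal_gene, "' not in gene order")
  chrom <- ord$chrom[i]
  same <- which(ord$chrom == chrom)
  pos <- match(i, same)
  lo <- max(1, pos - radius)
  hi <- min(length(same), pos + radius)
  flank <- ord$gene[same[setdiff(lo:hi, pos)]]
  labels <- calls$label[match(flank, calls$gene)]
  labels[is.na(labels)] <- "none"
  data.frame(
    gene = focal_gene, n_flanking = length(flank),
    n_purifying = sum(labels == "purifying"),
    n_balancing = sum(labels == "balancing"),
    n_invariant = sum(labels == "invariant"),
    n_none = sum(labels == "none"),
    sweep = any(labels != "none"),
    stringsAsFactors = FALSE)
}
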