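# Within- and between-population summary statistics.
#
# Missing data policy (documented, applied consistently):
#   * theta_pi and all pairwise distances use pairwise deletion -- each
#     pair (i, j) is compared over the sites where both carry a base, and
#     the per-pair per-site distances are averaged;
#   * S-based statistics (theta_W, Tajima's D) use complete deletion --
#     only sites with no missing base in the analyzed subset enter, which
#     keeps the null theory for S valid;
#   * alignment gaps "-" are treated exactly like N.

# columns with no missing data in the coded matrix
complete_sites <- function(codes) which(colSums(is.na(codes)) == 0)

count_segregating <- function(codes, sites) {
  if (!length(sites)) return(0L)
  sub <- codes[, sites, drop = FALSE]
  sum(apply(sub, 2, function(col) length(unique(col)) > 1L))
}

#' Nucleotide diversity per site (theta-pi)
#'
#' Mean over sample pairs of the per-site difference proportion, with
#' pairwise deletion of missing data:
#' (sum_{i<j} d_ij / L_ij) / C(n, 2), where d_ij counts differing
#' comparable sites and L_ij the comparable sites for the pair.
#'
#' @param aln a \code{hap_alignment}
#' @param subset sample ids (default all); at least 2 required
#' @return per-site nucleotide diversity
#' @export
theta_pi <- function(aln, subset = aln$sample_ids) {
  if (length(subset) < 2) stop("theta_pi needs at least 2 sequences")
  codes <- alignment_codes(aln)[subset, , drop = FALSE]
  n <- nrow(codes)
  if (!anyNA(codes)) {
    # site-frequency shortcut, identical to the pair average when no data
    # are missing
    diffs <- 0
    for (b in 1:4) {
      k <- colSums(codes == b)
      diffs <- diffs + sum(k * (n - k))
    }
    return((diffs / 2) / (ncol(codes) * choose(n, 2)))
  }
  tot <- 0
  npairs <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(codes[i, ]) & !is.na(codes[j, ])
      lij <- sum(ok)
      npairs <- npairs + 1L
      if (lij > 0) tot <- tot + sum(codes[i, ok] != codes[j, ok]) / lij
    }
  }
  tot / npairs
}

#' Watterson's estimator of theta per site
#'
#' S / (a_n * L_effective) over complete-deletion sites, with
#' a_n = sum_{i=1}^{n-1} 1/i.
#'
#' @inheritParams theta_pi
#' @return per-site Watterson estimate (0 when no site segregates)
#' @export
watterson_theta <- function(aln, subset = aln$sample_ids) {
  if (length(subset) < 2) stop("watterson_theta needs at least 2 sequences")
  codes <- alignment_codes(aln)[subset, , drop = FALSE]
  sites <- complete_sites(codes)
  if (!length(sites)) return(0)
  s <- count_segregating(codes, sites)
  s / (harmonic_number(nrow(codes)) * length(sites))
}

#' Tajima's D
#'
#' D = (Pi - S/a1) / sqrt(e1 S + e2 S (S-1)) with Pi the mean pairwise
#' difference count and the Tajima (1989) constants. Computed over
#' complete-deletion sites so Pi and S see the same data. An invariant
#' sample (S = 0) returns NA ("Invariant"), never 0: zero and
#' undefined are different statements about a gene.
#'
#' @inheritParams theta_pi
#' @return Tajima's D, or NA_real_ when the sample is invariant
#' @export
tajimas_d <- function(aln, subset = aln$sample_ids) {
  n <- length(subset)
  if (n < 2) stop("tajimas_d needs at least 2 sequences")
  codes <- alignment_codes(aln)[subset, , drop = FALSE]
  sites <- complete_sites(codes)
  if (!length(sites)) return(NA_real_)
  sub <- codes[, sites, drop = FALSE]
  s <- count_segregating(codes, sites)
  if (s == 0) return(NA_real_)
  diffs <- 0
  for (b in 1:4) {
    k <- colSums(sub == b)
    diffs <- diffs + sum(k * (n - k))
  }
  pi_count <- (diffs / 2) / choose(n, 2)
  tajd_from_counts(n, s, pi_count)
}

# Tajima's D from sample size, segregating sites and the mean pairwise
# difference count (Tajima 1989 constants)
tajd_from_counts <- function(n, s, pi_count) {
  if (s == 0) return(NA_real_)
  a1 <- harmonic_number(n)
  a2 <- harmonic_number2(n)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_count - s / a1) / sqrt(e1 * s + e2 * s * (s - 1))
}

#' Hudson's FST between landrace and wild samples
#'
#' FST = 1 - Hw/Hb, where Hw is the mean of the two within-group per-site
#' diversities (pairwise deletion) and Hb the mean per-site difference
#' over all between-group pairs. Hb = 0 is reported as FST = 0; negative
#' estimates are returned unclamped.
#'
#' @param aln a \code{hap_alignment}
#' @param partition a \code{population_partition}
#' @return Hudson FST estimate (<= 1)
#' @export
hudson_fst <- function(aln, partition) {
  g1 <- group_samples(aln, partition, "landrace")
  g2 <- group_samples(aln, partition, "wild")
  if (length(g1) < 2 || length(g2) < 2) {
    stop("hudson_fst needs >= 2 samples in each of landrace and wild")
  }
  hw <- (theta_pi(aln, g1) + theta_pi(aln, g2)) / 2
  codes <- alignment_codes(aln)
  c1 <- codes[g1, , drop = FALSE]
  c2 <- codes[g2, , drop = FALSE]
  if (!anyNA(c1) && !anyNA(c2)) {
    n1 <- nrow(c1); n2 <- nrow(c2)
    same <- 0
    for (b in 1:4) same <- same + colSums(c1 == b) * colSums(c2 == b)
    hb <- sum(n1 * n2 - same) / (ncol(codes) * n1 * n2)
  } else {
    tot <- 0; npairs <- 0L
    for (i in seq_len(nrow(c1))) {
      for (j in seq_len(nrow(c2))) {
        ok <- !is.na(c1[i, ]) & !is.na(c2[j, ])
        npairs <- npairs + 1L
        if (any(ok)) tot <- tot + sum(c1[i, ok] != c2[j, ok]) / sum(ok)
      }
    }
    hb <- tot / npairs
  }
  if (hb == 0) return(0)
  1 - hw / hb
}

#' Per-gene summary statistic record for one group
#'
#' @param aln a \code{hap_alignment}
#' @param partition a \code{population_partition}
#' @param group group label
#' @return one-row data.frame: gene, group, n, L_effective, S, theta_pi,
#'   theta_w, tajimas_d (NA when invariant), invariant flag
#' @export
gene_stat_record <- function(aln, partition, group) {
  samples <- group_samples(aln, partition, group)
  if (length(samples) < 2) stop("group '", group, "' has < 2 samples")
  codes <- alignment_codes(aln)[samples, , drop = FALSE]
  sites <- complete_sites(codes)
  s <- count_segregating(codes, sites)
  data.frame(
    gene = aln$gene_id, group = group, n = length(samples),
    L_effective = length(sites), S = s,
    theta_pi = theta_pi(aln, samples),
    theta_w = watterson_theta(aln, samples),
    tajimas_d = tajimas_d(aln, samples),
    invariant = s == 0L,
    stringsAsFactors = FALSE)
}

#' Per-codon statistic track
#'
#' Computes, over non-overlapping 3-bp codon windows, the per-site
#' diversity of each group, Hudson FST, Tajima's D in the descendant
#' (landrace) sample (NA when the window is invariant there), and the
#' coding effect of the window's variation: monomorphic, synonymous,
#' nonsynonymous, or complex (>= 2 segregating sites, or a stop in the
#' majority codon, which also raises a warning).
#'
#' @param aln a \code{hap_alignment} with known frame
#' @param partition a \code{population_partition}
#' @return data.frame with one row per codon: codon, pi_landrace,
#'   pi_wild, fst, tajd_landrace, effect
#' @export
codon_stats <- function(aln, partition) {
  if (aln$L < 3) stop("alignment shorter than one codon")
  tab <- codon_tables()
  g1 <- group_samples(aln, partition, "landrace")
  g2 <- group_samples(aln, partition, "wild")
  ingroup <- c(g1, g2)
  start <- aln$frame_offset + 1L
  ncod <- (aln$L - aln$frame_offset) %/% 3L
  codes <- alignment_codes(aln)
  c1m <- codes[g1, , drop = FALSE]
  c2m <- codes[g2, , drop = FALSE]
  n1 <- length(g1)
  n2 <- length(g2)

  # per-site allele counts per group (fast path; sites with missing data
  # fall back to the pairwise-deletion window computation)
  cnt1 <- vapply(1:4, function(b) colSums(c1m == b, na.rm = TRUE),
                 numeric(aln$L))
  cnt2 <- vapply(1:4, function(b) colSums(c2m == b, na.rm = TRUE),
                 numeric(aln$L))
  has_na <- colSums(is.na(codes[ingroup, , drop = FALSE])) > 0
  pd1 <- (n1^2 - rowSums(cnt1^2)) / 2     # differing pairs per site
  pd2 <- (n2^2 - rowSums(cnt2^2)) / 2
  hb_site <- (n1 * n2 - rowSums(cnt1 * cnt2)) / (n1 * n2)
  seg1 <- rowSums(cnt1 > 0) > 1
  seg_in <- rowSums(cnt1 + cnt2 > 0) > 1

  # per-sample codon indices for effect classification
  cidx <- matrix(NA_integer_, nrow = length(ingroup), ncol = ncod)
  cA <- codes[ingroup, start + 3L * (seq_len(ncod) - 1L), drop = FALSE]
  cB <- codes[ingroup, start + 3L * (seq_len(ncod) - 1L) + 1L, drop = FALSE]
  cC <- codes[ingroup, start + 3L * (seq_len(ncod) - 1L) + 2L, drop = FALSE]
  cidx <- 16L * (cA - 1L) + 4L * (cB - 1L) + cC

  out <- vector("list", ncod)
  for (k in seq_len(ncod)) {
    cols <- start + 3L * (k - 1L) + 0:2
    if (any(has_na[cols])) {
      win <- hap_alignment(aln$gene_id, ingroup,
                           aln$seq[ingroup, cols, drop = FALSE])
      wcodes <- alignment_codes(win)
      nseg <- count_segregating(wcodes, complete_sites(wcodes))
      pi1 <- theta_pi(win, g1)
      pi2 <- theta_pi(win, g2)
      fst <- if (nseg == 0) 0 else hudson_fst(win, partition)
      d1 <- tajimas_d(win, g1)
    } else {
      nseg <- sum(seg_in[cols])
      pi1 <- sum(pd1[cols]) / (3 * choose(n1, 2))
      pi2 <- sum(pd2[cols]) / (3 * choose(n2, 2))
      hb <- mean(hb_site[cols])
      fst <- if (hb == 0) 0 else 1 - ((pi1 + pi2) / 2) / hb
      d1 <- tajd_from_counts(n1, sum(seg1[cols]),
                             sum(pd1[cols]) / choose(n1, 2))
    }
    obs <- unique(cidx[, k])
    obs <- obs[!is.na(obs)]
    effect <- if (nseg == 0) {
      "monomorphic"
    } else if (nseg >= 2) {
      "complex"
    } else {
      aas <- unique(tab$aa[obs])
      if (length(aas) == 1L) "synonymous" else "nonsynonymous"
    }
    if (nseg > 0 && length(obs) && k < ncod) {
      major <- obs[which.max(tabulate(match(cidx[, k], obs)))]
      if (tab$is_stop[major]) {
        warning("stop codon in majority haplotype at codon ", k,
                " of gene ", aln$gene_id)
        effect <- "complex"
      }
    }
    out[[k]] <- list(codon = k, pi_landrace = pi1, pi_wild = pi2,
                     fst = fst, tajd_landrace = d1, effect = effect)
  }
  res <- data.frame(
    gene = aln$gene_id,
    codon = vapply(out, `[[`, numeric(1), "codon"),
    pi_landrace = vapply(out, `[[`, numeric(1), "pi_landrace"),
    pi_wild = vapply(out, `[[`, numeric(1), "pi_wild"),
    fst = vapply(out, `[[`, numeric(1), "fst"),
    tajd_landrace = vapply(out, `[[`, numeric(1), "tajd_landrace"),
    effect = vapply(out, `[[`, character(1), "effect"),
    stringsAsFactors = FALSE)
  res
}
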