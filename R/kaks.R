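#' Majority-rule consensus sequence of a sample
#'
#' Per-site majority allele over the non-missing bases. Ties are broken
#' toward the reference allele when one is supplied and is among the tied
#' bases, otherwise alphabetically. Sites with no data become "N"
#' (or the reference base when given).
#'
#' @param aln a \code{hap_alignment}
#' @param subset sample ids to use (default: all)
#' @param reference optional reference DNA string of the same length
#' @return a DNA string of length \code{aln$L}
#' @export
consensus_sequence <- function(aln, subset = aln$sample_ids, reference = NULL) {
  sub <- subset_alignment(aln, subset)
  refv <- if (!is.null(reference)) strsplit(toupper(reference), "")[[1]] else NULL
  if (!is.null(refv) && length(refv) != sub$L) {
    stop("reference length ", length(refv), " != alignment length ", sub$L)
  }
  codes <- alignment_codes(sub)
  cnt <- vapply(1:4, function(b) colSums(codes == b, na.rm = TRUE),
                numeric(sub$L))
  vmax <- do.call(pmax, as.data.frame(cnt))
  n_at_max <- rowSums(cnt == vmax)
  out <- character(sub$L)
  clear <- vmax > 0 & n_at_max == 1L
  out[clear] <- DNA_BASES4[max.col(cnt[clear, , drop = FALSE],
                                   ties.method = "first")]
  for (j in which(!clear)) {
    if (vmax[j] == 0) {
      out[j] <- if (is.null(refv)) "N" else refv[j]
      next
    }
    best <- DNA_BASES4[cnt[j, ] == vmax[j]]
    out[j] <- if (!is.null(refv) && refv[j] %in% best) refv[j] else
      sort(best)[1]
  }
  paste(out, collapse = "")
}

#' NG86 synonymous and nonsynonymous site counts
#'
#' Nei-Gojobori (1986) site counting: each codon position contributes to
#' the synonymous site total the fraction of its three possible
#' single-nucleotide changes that preserve the encoded amino acid; the
#' remainder (including changes to stop codons) is nonsynonymous. Codons
#' containing missing data (N or -) are skipped.
#'
#' @param codon_seq DNA string with length a multiple of 3 (in frame)
#' @return named numeric vector \code{c(Sa = ..., Ss = ...)}
#' @export
ng86_sites <- function(codon_seq) {
  tab <- codon_tables()
  cods <- split_codons(codon_seq)
  if (nchar(codon_seq) %% 3 != 0) stop("sequence length not a multiple of 3")
  idx <- codon_index(cods)
  keep <- !is.na(idx)
  stops <- which(tab$is_stop[idx[keep]])
  # a terminal stop codon is legitimate; internal stops are not
  internal_stop <- stops[stops < sum(keep)]
  if (length(internal_stop)) {
    stop("internal stop codon at codon index ",
         which(keep)[internal_stop[1]], " of in-frame sequence")
  }
  use <- idx[keep & !tab$is_stop[replace(idx, is.na(idx), 1L)]]
  c(Sa = sum(tab$sa[use]), Ss = sum(tab$ss[use]))
}

#' NG86 difference counts between two codons
#'
#' Zero differences give (0, 0); one difference is classified by
#' translation; two or three differences are averaged over all minimal
#' substitution paths, excluding paths that pass through a stop codon
#' (all paths are used when every one passes through a stop).
#'
#' @param codon_a,codon_b 3-base DNA strings
#' @return named numeric vector \code{c(na = ..., ns = ...)}
#' @export
ng86_differences <- function(codon_a, codon_b) {
  tab <- codon_tables()
  i <- codon_index(codon_a)
  j <- codon_index(codon_b)
  if (is.na(i) || is.na(j)) stop("invalid codon: ", codon_a, " / ", codon_b)
  c(na = tab$na[i, j], ns = tab$ns[i, j])
}

#' Pairwise Ka/Ks by the Nei-Gojobori (1986) method
#'
#' Counts synonymous/nonsynonymous sites (averaged over the two
#' sequences) and path-averaged differences per codon, converts the
#' proportions with the Jukes-Cantor correction
#' d = -3/4 log(1 - 4/3 p), and reports Ka, Ks and their ratio. Codons
#' with missing data in either sequence are excluded.
#'
#' @param seq_a,seq_b equal-length in-frame DNA strings
#' @return list with \code{Ka}, \code{Ks}, \code{ratio}, \code{Na},
#'   \code{Ns}, \code{Sa}, \code{Ss}, \code{status} (one of "OK",
#'   "UNDEFINED" when Ks = 0, "SATURATED" when a proportion exceeds 3/4)
#' @export
kaks_pair <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) stop("sequences differ in length")
  if (nchar(seq_a) %% 3 != 0) stop("sequence length not a multiple of 3")
  tab <- codon_tables()
  ca <- split_codons(seq_a)
  cb <- split_codons(seq_b)
  ia <- codon_index(ca)
  ib <- codon_index(cb)
  keep <- !is.na(ia) & !is.na(ib) & !tab$is_stop[replace(ia, is.na(ia), 1L)] &
    !tab$is_stop[replace(ib, is.na(ib), 1L)]
  ia <- ia[keep]; ib <- ib[keep]
  if (!length(ia)) stop("no comparable codons")
  Sa <- (sum(tab$sa[ia]) + sum(tab$sa[ib])) / 2
  Ss <- (sum(tab$ss[ia]) + sum(tab$ss[ib])) / 2
  diff <- ia != ib
  Na <- sum(tab$na[cbind(ia[diff], ib[diff])])
  Ns <- sum(tab$ns[cbind(ia[diff], ib[diff])])
  pa <- Na / Sa
  ps <- Ns / Ss
  jc <- function(p) -0.75 * log(1 - 4 * p / 3)
  status <- "OK"
  if (pa >= 0.75 || ps >= 0.75) {
    return(list(Ka = NA_real_, Ks = NA_real_, ratio = NA_real_,
                Na = Na, Ns = Ns, Sa = Sa, Ss = Ss, status = "SATURATED"))
  }
  Ka <- jc(pa)
  Ks <- jc(ps)
  ratio <- if (Ns == 0) { status <- "UNDEFINED"; NA_real_ } else Ka / Ks
  list(Ka = Ka, Ks = Ks, ratio = ratio, Na = Na, Ns = Ns,
       Sa = Sa, Ss = Ss, status = status)
}

#' Exact binomial test of Ka/Ks against neutrality
#'
#' Under neutrality the observed nonsynonymous/synonymous difference
#' counts split in proportion to the available site counts. The doubled
#' exact binomial tail tests Na successes in Na+Ns trials against
#' p0 = Sa/(Sa+Ss); fractional NG86 counts are rounded to the nearest
#' integer before the tail is evaluated.
#'
#' @param result a \code{kaks_pair()} result (or any list with Na, Ns, Sa, Ss)
#' @return two-sided p-value in [0, 1]
#' @export
kaks_significance <- function(result) {
  if (result$Sa + result$Ss <= 0) stop("zero synonymous+nonsynonymous sites")
  na <- round(result$Na)
  ns <- round(result$Ns)
  if (na + ns == 0) stop("no observed differences to test")
  p0 <- result$Sa / (result$Sa + result$Ss)
  lower <- stats::pbinom(na, na + ns, p0)
  upper <- stats::pbinom(na - 1, na + ns, p0, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

#' Per-group Ka/Ks against an outgroup sequence
#'
#' Default mode compares the group majority consensus with the outgroup;
#' \code{mode = "pairs"} instead averages the NG86 quantities over all
#' (group member, outgroup) pairs. Which two sequences enter the
#' comparison is not uniquely defined for population samples, so the mode
#' used is recorded in the result.
#'
#' @param aln a \code{hap_alignment}
#' @param partition a \code{population_partition} over the samples
#' @param group group label to estimate for
#' @param outgroup_seq outgroup DNA string aligned to the gene
#' @param mode "consensus" (default) or "pairs"
#' @param reference optional reference string for consensus tie-breaks
#' @return \code{kaks_pair}-shaped list plus \code{gene_id}, \code{group},
#'   \code{mode} and \code{p_vs_1}
#' @export
kaks_group <- function(aln, partition, group, outgroup_seq,
                       mode = c("consensus", "pairs"), reference = NULL) {
  mode <- match.arg(mode)
  samples <- group_samples(aln, partition, group)
  if (!length(samples)) stop("no samples of group '", group, "' in alignment")
  if (mode == "consensus") {
    cons <- consensus_sequence(aln, samples, reference)
    res <- kaks_pair(cons, outgroup_seq)
  } else {
    strs <- alignment_strings(subset_alignment(aln, samples))
    per <- lapply(strs, kaks_pair, seq_b = outgroup_seq)
    ok <- vapply(per, function(r) r$status != "SATURATED", logical(1))
    if (!any(ok)) {
      res <- per[[1]]
    } else {
      agg <- function(f) mean(vapply(per[ok], `[[`, numeric(1), f))
      Na <- agg("Na"); Ns <- agg("Ns"); Sa <- agg("Sa"); Ss <- agg("Ss")
      Ka <- agg("Ka"); Ks <- agg("Ks")
      res <- list(Ka = Ka, Ks = Ks,
                  ratio = if (Ks > 0) Ka / Ks else NA_real_,
                  Na = Na, Ns = Ns, Sa = Sa, Ss = Ss,
                  status = if (Ks > 0) "OK" else "UNDEFINED")
    }
  }
  res$p_vs_1 <- if (round(res$Na) + round(res$Ns) > 0) {
    kaks_significance(res)
  } else {
    NA_real_
  }
  res$gene_id <- aln$gene_id
  res$group <- group
  res$mode <- mode
  res
}
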