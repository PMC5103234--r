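#' Haplotype alignment container
#'
#' An aligned set of haploid CDS sequences for one gene, the unit every
#' statistic in the package operates on. Sequences are stored as a
#' character matrix (one row per haplotype, one column per site) over the
#' alphabet {A, C, G, T, N, -}; "N" and "-" are treated as missing data
#' throughout.
#'
#' @param gene_id gene identifier
#' @param sample_ids character vector of haplotype identifiers (length n)
#' @param sequences character vector of equal-length DNA strings, or an
#'   n x L single-character matrix
#' @param frame_offset 0-based offset of the first complete codon (0, 1 or 2)
#' @return an object of class \code{hap_alignment} with elements
#'   \code{gene_id}, \code{sample_ids}, \code{seq} (character matrix),
#'   \code{L}, \code{n}, \code{frame_offset}
#' @export
hap_alignment <- function(gene_id, sample_ids, sequences, frame_offset = 0L) {
  if (is.matrix(sequences)) {
    mat <- sequences
  } else {
    if (length(sequences) != length(sample_ids)) {
      stop("number of sequences (", length(sequences),
           ") != number of sample ids (", length(sample_ids), ")")
    }
    lens <- nchar(sequences)
    if (length(unique(lens)) != 1L) {
      bad <- which(lens != lens[1])[1]
      stop("ragged alignment for gene '", gene_id, "': record ", bad,
           " ('", sample_ids[bad], "') has length ", lens[bad],
           " but record 1 has length ", lens[1])
    }
    mat <- do.call(rbind, strsplit(toupper(sequences), "", fixed = TRUE))
  }
  if (nrow(mat) < 1L || ncol(mat) < 1L) stop("empty alignment for gene '", gene_id, "'")
  if (anyDuplicated(sample_ids)) stop("duplicated sample ids in alignment '", gene_id, "'")
  bad <- !(mat %in% c("A", "C", "G", "T", "N", "-"))
  if (any(bad)) {
    mat[bad] <- "N"
  }
  if (!frame_offset %in% 0:2) stop("frame_offset must be 0, 1 or 2")
  rownames(mat) <- sample_ids
  structure(
    list(gene_id = gene_id, sample_ids = as.character(sample_ids),
         seq = mat, n = nrow(mat), L = ncol(mat),
         frame_offset = as.integer(frame_offset)),
    class = "hap_alignment")
}

#' @export
print.hap_alignment <- function(x, ...) {
  cat("<hap_alignment> gene", x$gene_id, ":", x$n, "haplotypes x", x$L, "bp\n")
  invisible(x)
}

#' Subset an alignment to a set of samples
#'
#' @param aln a \code{hap_alignment}
#' @param samples character vector of sample ids (order preserved)
#' @return a \code{hap_alignment} over the requested samples
#' @export
subset_alignment <- function(aln, samples) {
  missing <- setdiff(samples, aln$sample_ids)
  if (length(missing)) {
    stop("samples not in alignment '", aln$gene_id, "': ",
         paste(missing, collapse = ", "))
  }
  hap_alignment(aln$gene_id, samples, aln$seq[samples, , drop = FALSE],
                aln$frame_offset)
}

#' Sequences of an alignment as strings
#'
#' @param aln a \code{hap_alignment}
#' @return named character vector of sequences
#' @export
alignment_strings <- function(aln) {
  stats::setNames(apply(aln$seq, 1, paste, collapse = ""), aln$sample_ids)
}

# integer-coded view: A=1 C=2 G=3 T=4, missing (N,-) = NA
alignment_codes <- function(aln) {
  m <- matrix(match(aln$seq, DNA_BASES4), nrow = aln$n)
  rownames(m) <- aln$sample_ids
  m
}

#' Population partition (sample to group map)
#'
#' @param sample_ids character vector
#' @param groups character vector over {landrace, wild, outgroup}
#' @return named character vector mapping sample id to group
#' @export
population_partition <- function(sample_ids, groups) {
  if (anyDuplicated(sample_ids)) {
    dup <- sample_ids[duplicated(sample_ids)][1]
    stop("duplicated sample id in partition: '", dup, "'")
  }
  bad <- setdiff(unique(groups), c("landrace", "wild", "outgroup"))
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  stats::setNames(as.character(groups), sample_ids)
}

# samples of an alignment belonging to one group of a partition
group_samples <- function(aln, partition, group) {
  intersect(aln$sample_ids, names(partition)[partition == group])
}
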