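# External formats: FASTA via Biostrings, VCF reading via vcfR, TSV via
# base utils. Everything downstream operates on in-memory domain types.

#' Read a FASTA alignment for one gene
#'
#' @param path FASTA file of equal-length aligned records
#' @param gene_id gene identifier to attach (default: file stem)
#' @param frame_offset 0-based codon frame start
#' @return a \code{hap_alignment}; record order preserved, sequences
#'   uppercased
#' @export
read_fasta_alignment <- function(path, gene_id = NULL, frame_offset = 0L) {
  if (!file.exists(path)) stop("no such file: ", path)
  gene_id <- gene_id %||% sub("\\.(fa|fasta|fna)$", "", basename(path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty FASTA file: ", path)
  lens <- Biostrings::width(set)
  if (length(unique(lens)) != 1L) {
    bad <- which(lens != lens[1])[1]
    stop("ragged alignment in ", path, ": record ", bad, " ('",
         names(set)[bad], "') has length ", lens[bad],
         " but record 1 has length ", lens[1])
  }
  hap_alignment(gene_id, names(set), toupper(as.character(set)),
                frame_offset)
}

#' Write an alignment as FASTA
#'
#' @param aln a \code{hap_alignment}
#' @param path output path
#' @export
write_fasta_alignment <- function(aln, path) {
  strs <- alignment_strings(aln)
  writeLines(as.vector(rbind(paste0(">", names(strs)), unname(strs))), path)
}

#' Reconstruct a haplotype alignment from a reference CDS and a VCF
#'
#' Each sample haplotype is the reference with ALT alleles substituted
#' at its variant sites; missing genotypes become N. Haploid genotypes
#' give one haplotype per sample; phased diploid genotypes are split
#' into \code{<sample>_1} and \code{<sample>_2}. Indels and multiallelic
#' records are skipped (count reported in attribute
#' \code{"skipped_records"}); unphased heterozygotes are an error unless
#' \code{pseudo_phase = TRUE} assigns alleles randomly under
#' \code{seed}.
#'
#' @param reference_cds DNA string
#' @param vcf_path VCF v4.2 file
#' @param region contig (gene) name to extract
#' @param pseudo_phase randomly phase unphased heterozygotes
#' @param seed seed for pseudo-phasing
#' @return a \code{hap_alignment}
#' @export
alignment_from_vcf <- function(reference_cds, vcf_path, region,
                               pseudo_phase = FALSE, seed = 1L) {
  ref <- strsplit(toupper(reference_cds), "", fixed = TRUE)[[1]]
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fixm <- vcfR::getFIX(vcf)
  if (is.null(dim(fixm))) fixm <- t(fixm)   # single-record VCF
  fix <- as.data.frame(fixm, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf)
  keep <- fix$CHROM == region
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  samples <- colnames(gt)
  skipped <- 0L

  # determine ploidy from the first non-missing genotype
  gtv <- as.vector(gt)
  gtv <- gtv[!is.na(gtv)]
  diploid <- length(gtv) > 0 && grepl("[|/]", gtv[1])
  hap_ids <- if (diploid) {
    as.vector(rbind(paste0(samples, "_1"), paste0(samples, "_2")))
  } else samples
  mat <- matrix(rep(ref, each = length(hap_ids)), nrow = length(hap_ids))
  rownames(mat) <- hap_ids

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (r in seq_len(nrow(fix))) {
    refa <- fix$REF[r]
    alta <- fix$ALT[r]
    pos <- as.integer(fix$POS[r])
    if (nchar(refa) != 1 || nchar(alta) != 1 || grepl(",", alta)) {
      skipped <- skipped + 1L
      next
    }
    if (pos < 1 || pos > length(ref)) {
      stop("VCF position ", pos, " outside reference length ", length(ref),
           " for region ", region)
    }
    for (s in seq_along(samples)) {
      g <- gt[r, s]
      if (is.na(g) || g %in% c(".", "./.", ".|.")) {
        rows <- if (diploid) 2 * s - 1:0 else s
        mat[rows, pos] <- "N"
        next
      }
      if (diploid) {
        alleles <- strsplit(g, "[|/]")[[1]]
        phased <- grepl("\\|", g)
        if (!phased && length(unique(alleles)) > 1) {
          if (!pseudo_phase) {
            stop("unphased heterozygote ", g, " for sample ", samples[s],
                 " at ", region, ":", pos,
                 "; set pseudo_phase = TRUE to randomize")
          }
          alleles <- sample(alleles)
        }
        for (h in 1:2) {
          a <- alleles[h]
          mat[2 * s - 2 + h, pos] <-
            if (a == ".") "N" else if (a == "0") refa else alta
        }
      } else {
        mat[s, pos] <- if (g == ".") "N" else if (g == "0") refa else alta
      }
    }
  }
  aln <- hap_alignment(region, hap_ids, mat)
  attr(aln, "skipped_records") <- skipped
  aln
}

# write a merged VCF of the ingroup haplotypes of simulated genes
# against their reference sequences (one contig per gene, haploid GTs)
write_dataset_vcf <- function(sims, ingroup, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=domescan",
    sprintf("##contig=<ID=%s,length=%d>", names(sims),
            vapply(sims, function(s) nchar(s$reference), integer(1))),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ingroup), collapse = "\t")), con)
  for (gid in names(sims)) {
    sim <- sims[[gid]]
    refc <- strsplit(sim$reference, "", fixed = TRUE)[[1]]
    sub <- sim$alignment$seq[ingroup, , drop = FALSE]
    for (pos in seq_along(refc)) {
      col <- sub[, pos]
      alts <- setdiff(unique(col), c(refc[pos], "N", "-"))
      if (!length(alts)) next
      for (alt in sort(alts)) {
        gts <- ifelse(col == alt, "1", ifelse(is_missing_base(col), ".", "0"))
        writeLines(paste(c(gid, pos, ".", refc[pos], alt, ".", "PASS", ".",
                           "GT", gts), collapse = "\t"), con)
      }
    }
  }
  invisible(path)
}

#' Read partition, pathway-map and optional expression tables
#'
#' All are UTF-8 TSV with a header row. The partition table needs
#' columns \code{sample_id} and \code{group}; the pathway map
#' \code{gene_id}, \code{pathway} and integer \code{ppi}; the expression
#' table \code{gene_id} plus one column per timepoint.
#'
#' @param partition_path,pathway_path,expression_path file paths
#'   (expression optional)
#' @return list(partition, pathway, expression)
#' @export
read_tables <- function(partition_path, pathway_path,
                        expression_path = NULL) {
  pt <- utils::read.delim(partition_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(pt))) {
    stop("partition table needs columns sample_id, group")
  }
  partition <- population_partition(pt$sample_id, pt$group)

  pw <- utils::read.delim(pathway_path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "pathway", "ppi") %in% names(pw))) {
    stop("pathway table needs columns gene_id, pathway, ppi")
  }
  if (any(pw$ppi != as.integer(pw$ppi)) || any(is.na(as.integer(pw$ppi)))) {
    stop("PPI column must be integer")
  }
  pw$ppi <- as.integer(pw$ppi)

  expr <- NULL
  if (!is.null(expression_path)) {
    expr <- utils::read.delim(expression_path, stringsAsFactors = FALSE)
    if (!"gene_id" %in% names(expr)) {
      stop("expression table needs a gene_id column")
    }
    unknown <- setdiff(expr$gene_id, pw$gene_id)
    if (length(unknown)) {
      warning(length(unknown),
              " expression gene(s) not in the pathway map (retained)")
    }
  }
  list(partition = partition, pathway = pw, expression = expr)
}

#' Write a per-gene statistics table
#'
#' Stable column order (gene, group, n, L_effective, S, theta_pi,
#' theta_w, tajimas_d, fst, Ka, Ks, KaKs, call); invariant genes print
#' "Invariant" in the Tajima's D column rather than a number, and reading
#' the table back restores the NA + invariant flag representation.
#'
#' @param records data.frame of per-gene records
#' @param path output TSV path
#' @export
write_gene_stats <- function(records, path) {
  if (!nrow(records)) stop("no records to write")
  cols <- c("gene", "group", "n", "L_effective", "S", "theta_pi", "theta_w",
            "tajimas_d", "fst", "Ka", "Ks", "KaKs", "call")
  out <- records
  for (cc in setdiff(cols, names(out))) out[[cc]] <- NA
  out <- out[, cols]
  num <- vapply(out, is.numeric, logical(1))
  for (cc in names(out)[num]) {
    out[[cc]] <- formatC(out[[cc]], digits = 10, format = "g")
  }
  if ("invariant" %in% names(records)) {
    out$tajimas_d[records$invariant] <- "Invariant"
  }
  out$tajimas_d[out$tajimas_d %in% c("NA", NA)] <- "Invariant"
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read back a gene statistics table
#'
#' @param path TSV written by \code{write_gene_stats}
#' @return data.frame with numeric columns restored and an
#'   \code{invariant} logical column
#' @export
read_gene_stats <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  df$invariant <- df$tajimas_d == "Invariant"
  df$tajimas_d[df$invariant] <- NA
  for (cc in c("n", "L_effective", "S", "theta_pi", "theta_w", "tajimas_d",
               "fst", "Ka", "Ks", "KaKs")) {
    df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
  }
  df
}

#' Write a tree in Newick format
#'
#' @param tree an \code{upgma} result or a Newick string
#' @param path output path
#' @export
write_newick <- function(tree, path) {
  nwk <- if (is.list(tree)) tree$newick else tree
  if (!grepl(";$", nwk)) nwk <- paste0(nwk, ";")
  writeLines(nwk, path)
  invisible(path)
}

#' Load a generated dataset directory
#'
#' @param dir directory written by \code{generate_dataset}
#' @return list with alignments (named list of \code{hap_alignment}),
#'   partition, pathway, expression, references (named character),
#'   gene_order (data.frame from the BED file), truth (if present),
#'   manifest
#' @export
read_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  tabs <- read_tables(file.path(dir, "samples.tsv"),
                      file.path(dir, "pathway.tsv"),
                      file.path(dir, "expression.tsv"))
  files <- list.files(file.path(dir, "alignments"), full.names = TRUE)
  alignments <- lapply(files, read_fasta_alignment)
  names(alignments) <- vapply(alignments, `[[`, character(1), "gene_id")
  refs <- Biostrings::readBStringSet(file.path(dir, "reference.fasta"))
  references <- stats::setNames(toupper(as.character(refs)), names(refs))
  bed <- utils::read.delim(file.path(dir, "genes.bed"), header = FALSE,
                           stringsAsFactors = FALSE)
  names(bed) <- c("chrom", "start", "end", "gene", "score", "strand")
  truth <- NULL
  tpath <- file.path(dir, "truth.tsv")
  if (file.exists(tpath)) truth <- utils::read.delim(tpath,
                                                     stringsAsFactors = FALSE)
  list(alignments = alignments, partition = tabs$partition,
       pathway = tabs$pathway, expression = tabs$expression,
       references = references, gene_order = bed, truth = truth,
       manifest = manifest)
}
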