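#' Simulation configuration for study-shaped datasets
#'
#' Defines the two-population sampling design, the per-site mutation
#' scale, the split model, the planted selection regimes and the
#' outgroup. Regimes act on the landrace (descendant) sample:
#' \describe{
#'   \item{neutral}{landrace diversity = \code{theta_wild *
#'     bottleneck_factor}, realized through a reduced relative
#'     population size under the split model.}
#'   \item{purifying}{diversity additionally scaled by the regime
#'     multiplier (default 0.05), and landrace derived-allele counts are
#'     resampled toward singletons with geometric weight
#'     \code{purifying_weight}, skewing Tajima's D negative.}
#'   \item{balancing}{K >= 1 intermediate-frequency (0.4-0.6) variants
#'     are injected, shared at matched frequency in both populations
#'     (trans-specific balanced polymorphism), K sized so landrace
#'     diversity reaches \code{bottleneck_factor * multiplier} (default
#'     multiplier 4): Tajima's D skews positive and FST drops.}
#' }
#'
#' @param genes data.frame with columns \code{gene_id}, \code{length}
#'   (bp, multiple of 3), \code{pathway}, \code{ppi}, \code{regime}
#'   (neutral/purifying/balancing), \code{multiplier} (regime diversity
#'   multiplier; 1 for neutral), \code{omega} (dN/dS on the outgroup
#'   branch)
#' @param n_landrace,n_wild haplotype counts (>= 2)
#' @param theta_wild per-site population mutation rate of the
#'   wild/ancestral population
#' @param bottleneck_factor multiplier on landrace diversity for neutral
#'   genes
#' @param t_split population split time in units of 2N generations
#' @param t_bottleneck end (backwards in time) of the recovered-size
#'   phase; the founder squeeze occupies [t_bottleneck, t_split)
#' @param outgroup_divergence expected substitutions/site on the
#'   outgroup branch
#' @param purifying_weight geometric weight w of the singleton skew
#'   (P(count = k) proportional to w^(k-1))
#' @param seed integer seed; every gene derives its own sub-seed
#' @return a \code{sim_config} list
#' @export
sim_config <- function(genes, n_landrace = 20, n_wild = 20,
                       theta_wild = 0.001, bottleneck_factor = 0.7,
                       t_split = 0.1, t_bottleneck = 0.05,
                       outgroup_divergence = 0.1,
                       purifying_weight = 0.3, seed = 1L) {
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "length", "regime", "multiplier", "omega")
                %in% names(genes)),
            n_landrace >= 2, n_wild >= 2,
            theta_wild > 0, bottleneck_factor > 0, t_split > 0,
            t_bottleneck > 0, t_bottleneck < t_split,
            outgroup_divergence > 0,
            all(genes$length %% 3 == 0), all(genes$length > 0),
            all(genes$multiplier > 0), all(genes$omega > 0),
            all(genes$regime %in% c("neutral", "purifying", "balancing")))
  if (anyDuplicated(genes$gene_id)) stop("duplicated gene_id in config")
  if (is.null(genes$pathway)) genes$pathway <- "SSP1"
  if (is.null(genes$ppi)) genes$ppi <- 1L
  structure(list(genes = genes, n_landrace = n_landrace, n_wild = n_wild,
                 theta_wild = theta_wild,
                 bottleneck_factor = bottleneck_factor, t_split = t_split,
                 t_bottleneck = t_bottleneck,
                 outgroup_divergence = outgroup_divergence,
                 purifying_weight = purifying_weight,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default study-shaped configuration
#'
#' One hundred genes across three pathway routes: 30 genes in SSP1 at
#' PPI positions 1-6 (five per position) with omega rising linearly from
#' 0.1 upstream to 0.8 downstream (the planted positional-rate-variation
#' signal), and 35 genes in each of SSP2/SSP3 with omega 0.3. Fifteen
#' genes are planted purifying (x0.05), fifteen balancing (x4), seventy
#' neutral; CDS lengths are drawn uniformly on 0.5-5 kb (multiples of 3).
#'
#' @param seed integer seed
#' @param n_purifying,n_balancing planted gene counts
#' @param length_range CDS length range in bp
#' @param ... passed to \code{sim_config}
#' @return a \code{sim_config}
#' @export
default_sim_config <- function(seed = 1L, n_purifying = 15, n_balancing = 15,
                               length_range = c(501, 4998), ...) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(sub_seed(seed, 999983L))
  n_genes <- 100L
  ssp1_ppi <- rep(1:6, each = 5)
  omega_by_ppi <- seq(0.1, 0.8, length.out = 6)
  genes <- data.frame(
    gene_id = sprintf("gene%03d", seq_len(n_genes)),
    length = 3 * sample(ceiling(length_range[1] / 3):floor(length_range[2] / 3),
                        n_genes, replace = TRUE),
    pathway = c(rep("SSP1", 30), rep("SSP2", 35), rep("SSP3", 35)),
    ppi = c(ssp1_ppi, sample(1:6, 70, replace = TRUE)),
    stringsAsFactors = FALSE)
  genes$omega <- ifelse(genes$pathway == "SSP1",
                        omega_by_ppi[genes$ppi], 0.3)
  regime <- rep("neutral", n_genes)
  planted <- sample(n_genes, n_purifying + n_balancing)
  regime[planted[seq_len(n_purifying)]] <- "purifying"
  regime[planted[n_purifying + seq_len(n_balancing)]] <- "balancing"
  genes$regime <- regime
  genes$multiplier <- c(neutral = 1, purifying = 0.05, balancing = 4)[regime]
  sim_config(genes, seed = seed, ...)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# random in-frame CDS of sense codons
random_reference <- function(length) {
  tab <- codon_tables()
  sense <- which(!tab$is_stop)
  paste(tab$codons[sample(sense, length %/% 3, replace = TRUE)],
        collapse = "")
}

# evolve an outgroup sequence from `ref` with ~divergence*L accepted
# substitutions; nonsynonymous changes accepted with probability
# proportional to omega, proposals creating stops rejected
evolve_outgroup <- function(ref, divergence, omega) {
  tab <- codon_tables()
  chars <- strsplit(ref, "", fixed = TRUE)[[1]]
  L <- length(chars)
  target <- stats::rpois(1, divergence * L)
  acc_n <- omega / max(1, omega)
  acc_s <- 1 / max(1, omega)
  n_nonsyn <- 0L
  n_syn <- 0L
  accepted <- 0L
  guard <- 0L
  while (accepted < target && guard < 1000L * (target + 10L)) {
    guard <- guard + 1L
    site <- sample.int(L, 1)
    old <- chars[site]
    alt <- sample(setdiff(DNA_BASES4, old), 1)
    cod_i <- (site - 1L) %/% 3L
    cpos <- site - 3L * cod_i
    cod <- chars[3L * cod_i + 1:3]
    new_cod <- cod
    new_cod[cpos] <- alt
    aa_old <- tab$aa[codon_index(paste(cod, collapse = ""))]
    aa_new <- tab$aa[codon_index(paste(new_cod, collapse = ""))]
    if (aa_new == "*") next
    syn <- aa_old == aa_new
    if (stats::runif(1) < (if (syn) acc_s else acc_n)) {
      chars[site] <- alt
      accepted <- accepted + 1L
      if (syn) n_syn <- n_syn + 1L else n_nonsyn <- n_nonsyn + 1L
    }
  }
  list(seq = paste(chars, collapse = ""), n_nonsyn = n_nonsyn, n_syn = n_syn)
}

# geometric-weight resampling of landrace derived-allele counts toward 1
resample_singleton <- function(n, w) {
  k <- seq_len(n - 1)
  sample(k, 1, prob = w^(k - 1))
}

#' Simulate one gene under the configured regime
#'
#' Runs the structured coalescent over the two-population split, drops
#' infinite-sites mutations, applies the regime's site-frequency skew,
#' and evolves one outgroup sequence with codon-aware, omega-filtered
#' substitution placement. The returned alignment contains the landrace
#' and wild haplotypes plus the outgroup sequence (sample id
#' \code{"outgroup_1"}).
#'
#' @param config a \code{sim_config}
#' @param gene_id a gene listed in \code{config$genes}
#' @return list with \code{alignment} (a \code{hap_alignment}),
#'   \code{partition}, \code{reference} (ancestral/root CDS string) and
#'   \code{truth} (one-row data.frame: regime, target multiplier,
#'   realized per-group theta-pi, realized omega on the outgroup branch)
#' @export
simulate_gene <- function(config, gene_id) {
  gi <- match(gene_id, config$genes$gene_id)
  if (is.na(gi)) stop("unknown gene_id '", gene_id, "'")
  g <- config$genes[gi, ]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(sub_seed(config$seed, gi))

  n1 <- config$n_landrace
  n2 <- config$n_wild
  L <- g$length
  theta <- config$theta_wild
  target_mult <- config$bottleneck_factor *
    (if (g$regime == "purifying") g$multiplier else 1)
  gen <- if (g$regime == "purifying") {
    # a completed sweep: diversity suppressed throughout the landrace
    # history, realized as a uniformly small population size
    b <- solve_relative_size(target_mult, config$t_split)
    sim_genealogy(n1, n2, b = b, t_split = config$t_split)
  } else {
    # founder squeeze followed by full recovery: reduces diversity with
    # only mild site-frequency distortion (Tajima's D near zero)
    b_f <- solve_founder_size(target_mult, config$t_bottleneck,
                              config$t_split)
    sim_genealogy(n1, n2, b = 1, t_split = config$t_split,
                  t_bottleneck = config$t_bottleneck, b_founder = b_f)
  }
  pool <- seq_len(L)
  dm <- drop_mutations(gen, rate_per_time = theta / 2 * L, site_pool = pool)
  muts <- dm$muts
  pool <- dm$pool

  landrace_tips <- seq_len(n1)
  if (g$regime == "purifying" && length(muts)) {
    w <- config$purifying_weight
    for (m in seq_along(muts)) {
      carriers_l <- intersect(muts[[m]]$carriers, landrace_tips)
      kl <- length(carriers_l)
      if (kl >= 1 && kl <= n1 - 1) {
        kl_new <- resample_singleton(n1, w)
        muts[[m]]$carriers <- c(setdiff(muts[[m]]$carriers, landrace_tips),
                                sample(landrace_tips, kl_new))
      }
    }
  }
  if (g$regime == "balancing") {
    # a gene-wide balanced polymorphism: the non-recombining gene
    # carries two allelic classes held at intermediate frequency in the
    # landrace (the balanced locus is shielded from the founder
    # bottleneck), so linked landrace variation is reshaped around the
    # class frequency and additional variants are injected; the classes
    # are trans-specific but segregate at lower frequency in the wild
    # sample, so the landrace gains more diversity than the wild
    p_land <- stats::runif(1, 0.4, 0.6)
    p_wild <- stats::runif(1, 0.05, 0.25)
    draw_count <- function(n, p) min(max(stats::rbinom(1, n, p), 1L),
                                     n - 1L)
    for (m in seq_along(muts)) {
      carriers_l <- intersect(muts[[m]]$carriers, landrace_tips)
      kl <- length(carriers_l)
      if (kl >= 1 && kl <= n1 - 1) {
        muts[[m]]$carriers <- c(setdiff(muts[[m]]$carriers, landrace_tips),
                                sample(landrace_tips, draw_count(n1, p_land)))
      }
    }
    per_site_gain <- 2 * 0.5 * 0.5 * n1 / (n1 - 1)
    baseline_pi_factor <- config$bottleneck_factor *
      harmonic_number(n1) * per_site_gain
    lambda <- max(0, (g$multiplier - baseline_pi_factor) *
                    theta * L / per_site_gain)
    k_inj <- max(1L, stats::rpois(1, lambda))
    k_inj <- min(k_inj, length(pool))
    inj_sites <- pool[sample.int(length(pool), k_inj)]
    pool <- setdiff(pool, inj_sites)
    for (s in inj_sites) {
      muts[[length(muts) + 1L]] <- list(
        site = s,
        carriers = c(sample(landrace_tips, draw_count(n1, p_land)),
                     n1 + sample(n2, draw_count(n2, p_wild))))
    }
  }

  ref <- random_reference(L)
  refc <- strsplit(ref, "", fixed = TRUE)[[1]]
  tab <- codon_tables()
  # derived alleles avoid creating stop codons in the reference frame
  # (a segregating premature stop would not persist in a functional CDS)
  safe_alts <- function(site) {
    ci <- (site - 1L) %/% 3L
    cpos <- site - 3L * ci
    cod <- refc[3L * ci + 1:3]
    alts <- setdiff(DNA_BASES4, refc[site])
    ok <- vapply(alts, function(a) {
      mut <- cod
      mut[cpos] <- a
      tab$aa[codon_index(paste(mut, collapse = ""))] != "*"
    }, logical(1))
    if (any(ok)) alts[ok] else alts
  }
  seqmat <- matrix(rep(refc, each = n1 + n2), nrow = n1 + n2)
  for (m in muts) {
    alts <- safe_alts(m$site)
    derived <- alts[sample.int(length(alts), 1)]
    seqmat[m$carriers, m$site] <- derived
  }

  og <- evolve_outgroup(ref, config$outgroup_divergence, g$omega)
  sample_ids <- c(sprintf("landrace_%02d", seq_len(n1)),
                  sprintf("wild_%02d", seq_len(n2)), "outgroup_1")
  seqmat <- rbind(seqmat, strsplit(og$seq, "", fixed = TRUE)[[1]])
  rownames(seqmat) <- sample_ids
  aln <- hap_alignment(gene_id, sample_ids, seqmat)
  partition <- population_partition(
    sample_ids, c(rep("landrace", n1), rep("wild", n2), "outgroup"))

  sites <- ng86_sites(ref)
  omega_real <- if (og$n_syn > 0) {
    (og$n_nonsyn / sites[["Sa"]]) / (og$n_syn / sites[["Ss"]])
  } else NA_real_
  truth <- data.frame(
    gene_id = gene_id, regime = g$regime, multiplier = g$multiplier,
    omega = g$omega, length = L,
    theta_pi_landrace = theta_pi(aln, sample_ids[seq_len(n1)]),
    theta_pi_wild = theta_pi(aln, sample_ids[n1 + seq_len(n2)]),
    omega_realized = omega_real,
    stringsAsFactors = FALSE)
  list(alignment = aln, partition = partition, reference = ref,
       truth = truth)
}

#' Generate a complete study-shaped dataset on disk
#'
#' Writes per-gene FASTA alignments (including the outgroup), a
#' reference CDS FASTA, a merged VCF of the ingroup haplotypes against
#' the reference (one contig per gene), sample partition, pathway map,
#' a two-timepoint FPKM expression table, a BED6 gene-order file (genes
#' interleaved over two chromosomes for the flanking sweep scan), the
#' ground-truth table and a JSON manifest with per-file MD5 hashes.
#' Identical seeds produce byte-identical outputs.
#'
#' @param config a \code{sim_config}
#' @param out_dir output directory
#' @param force overwrite an existing manifest
#' @return the manifest, invisibly
#' @export
generate_dataset <- function(config, out_dir, force = FALSE) {
  manifest_path <- file.path(out_dir, "manifest.json")
  if (file.exists(manifest_path) && !force) {
    stop("dataset manifest already exists at ", manifest_path,
         "; use force = TRUE to overwrite")
  }
  dir.create(file.path(out_dir, "alignments"), recursive = TRUE,
             showWarnings = FALSE)
  genes <- config$genes
  sims <- lapply(genes$gene_id, function(gid) simulate_gene(config, gid))
  names(sims) <- genes$gene_id

  for (gid in genes$gene_id) {
    write_fasta_alignment(sims[[gid]]$alignment,
                          file.path(out_dir, "alignments",
                                    paste0(gid, ".fasta")))
  }
  refs <- vapply(sims, `[[`, character(1), "reference")
  writeLines(as.vector(rbind(paste0(">", genes$gene_id), refs)),
             file.path(out_dir, "reference.fasta"))

  part <- sims[[1]]$partition
  utils::write.table(
    data.frame(sample_id = names(part), group = unname(part)),
    file.path(out_dir, "samples.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    genes[, c("gene_id", "pathway", "ppi")],
    file.path(out_dir, "pathway.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(sub_seed(config$seed, 999979L))
  n_genes <- nrow(genes)
  expr <- data.frame(
    gene_id = genes$gene_id,
    fpkm_midday = round(stats::rlnorm(n_genes, meanlog = 3, sdlog = 1), 3),
    fpkm_midnight = round(stats::rlnorm(n_genes, meanlog = 2.5, sdlog = 1), 3))
  utils::write.table(expr, file.path(out_dir, "expression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ord <- sample(n_genes)
  chrom <- rep(c("chr1", "chr2"), length.out = n_genes)
  pos <- integer(n_genes)
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    pos[idx] <- 50000L * (seq_along(idx) - 1L)
  }
  bed <- data.frame(chrom = chrom, start = pos,
                    end = pos + genes$length[ord],
                    gene = genes$gene_id[ord], score = 0L, strand = "+")
  bed <- bed[order(bed$chrom, bed$start), ]
  utils::write.table(bed, file.path(out_dir, "genes.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)

  truth <- do.call(rbind, lapply(sims, `[[`, "truth"))
  truth_out <- truth
  for (col in c("theta_pi_landrace", "theta_pi_wild", "omega_realized")) {
    truth_out[[col]] <- formatC(truth_out[[col]], digits = 10, format = "g")
  }
  utils::write.table(truth_out, file.path(out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ingroup <- names(part)[part != "outgroup"]
  write_dataset_vcf(sims, ingroup, file.path(out_dir, "variants.vcf"))

  files <- setdiff(list.files(out_dir, recursive = TRUE), "manifest.json")
  manifest <- list(
    seed = config$seed,
    n_landrace = config$n_landrace, n_wild = config$n_wild,
    theta_wild = config$theta_wild,
    bottleneck_factor = config$bottleneck_factor,
    t_split = config$t_split,
    outgroup_divergence = config$outgroup_divergence,
    n_genes = n_genes,
    regimes = as.list(table(genes$regime)),
    files = as.list(tools::md5sum(file.path(out_dir, files))))
  names(manifest$files) <- files
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
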