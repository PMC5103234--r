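# Independent brute-force oracles and fixture builders. These are kept
# deliberately naive (explicit loops over pairs, paths and permutations)
# so they share no code path with the package implementations they
# check.

make_alignment <- function(seqs, ids = sprintf("s%d", seq_along(seqs)),
                           gene = "toy") {
  hap_alignment(gene, ids, seqs)
}

# random alignment as character strings, optionally with missing data
random_seqs <- function(n, L, p_var = 0.15, p_missing = 0) {
  base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  seqs <- matrix(rep(base, each = n), nrow = n)
  var_sites <- which(stats::runif(L) < p_var)
  for (s in var_sites) {
    alt <- sample(setdiff(c("A", "C", "G", "T"), base[s]), 1)
    carriers <- which(stats::runif(n) < 0.5)
    seqs[carriers, s] <- alt
  }
  if (p_missing > 0) {
    miss <- which(matrix(stats::runif(n * L) < p_missing, n, L))
    seqs[miss] <- "N"
  }
  apply(seqs, 1, paste, collapse = "")
}

# mean over pairs of per-site differences, pairwise deletion
pi_oracle <- function(seqs) {
  mat <- do.call(rbind, strsplit(seqs, ""))
  n <- nrow(mat)
  tot <- 0
  np <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- mat[i, ]
      b <- mat[j, ]
      ok <- !(a %in% c("N", "-")) & !(b %in% c("N", "-"))
      np <- np + 1
      if (any(ok)) tot <- tot + sum(a[ok] != b[ok]) / sum(ok)
    }
  }
  tot / np
}

fst_oracle <- function(seqs1, seqs2) {
  hw <- (pi_oracle(seqs1) + pi_oracle(seqs2)) / 2
  mat1 <- do.call(rbind, strsplit(seqs1, ""))
  mat2 <- do.call(rbind, strsplit(seqs2, ""))
  tot <- 0
  np <- 0
  for (i in seq_len(nrow(mat1))) {
    for (j in seq_len(nrow(mat2))) {
      a <- mat1[i, ]
      b <- mat2[j, ]
      ok <- !(a %in% c("N", "-")) & !(b %in% c("N", "-"))
      np <- np + 1
      if (any(ok)) tot <- tot + sum(a[ok] != b[ok]) / sum(ok)
    }
  }
  hb <- tot / np
  if (hb == 0) 0 else 1 - hw / hb
}

GC <- Biostrings::GENETIC_CODE

# NG86 site counts by exhaustive single-base neighbour enumeration
ng86_sites_oracle <- function(codon) {
  cod <- strsplit(codon, "")[[1]]
  ss <- 0
  for (pos in 1:3) {
    for (alt in setdiff(c("A", "C", "G", "T"), cod[pos])) {
      mut <- cod
      mut[pos] <- alt
      if (GC[paste(mut, collapse = "")] == GC[codon] &&
          GC[codon] != "*") {
        ss <- ss + 1 / 3
      }
    }
  }
  c(Sa = 3 - ss, Ss = ss)
}

# NG86 difference counts by explicit path enumeration
ng86_diff_oracle <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  pos <- which(ca != cb)
  if (!length(pos)) return(c(na = 0, ns = 0))
  perms <- if (length(pos) == 1) list(pos) else {
    if (length(pos) == 2) list(pos, rev(pos)) else {
      idx <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                  c(3, 1, 2), c(3, 2, 1))
      lapply(idx, function(o) pos[o])
    }
  }
  res <- lapply(perms, function(ord) {
    cur <- ca
    syn <- 0
    nonsyn <- 0
    stop_hit <- FALSE
    for (s in seq_along(ord)) {
      nxt <- cur
      nxt[ord[s]] <- cb[ord[s]]
      if (GC[paste(cur, collapse = "")] == GC[paste(nxt, collapse = "")]) {
        syn <- syn + 1
      } else nonsyn <- nonsyn + 1
      if (s < length(ord) && GC[paste(nxt, collapse = "")] == "*") {
        stop_hit <- TRUE
      }
      cur <- nxt
    }
    c(syn = syn, nonsyn = nonsyn, stop = stop_hit)
  })
  ok <- !vapply(res, function(r) as.logical(r["stop"]), logical(1))
  if (!any(ok)) ok <- rep(TRUE, length(res))
  use <- res[ok]
  c(na = mean(vapply(use, `[[`, numeric(1), "nonsyn")),
    ns = mean(vapply(use, `[[`, numeric(1), "syn")))
}

# Tajima's D by direct evaluation of the 1989 formula on a complete
# (no missing data) alignment
tajd_oracle <- function(seqs) {
  mat <- do.call(rbind, strsplit(seqs, ""))
  n <- nrow(mat)
  seg <- apply(mat, 2, function(col) length(unique(col)) > 1)
  s <- sum(seg)
  if (s == 0) return(NA_real_)
  pi_tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) pi_tot <- pi_tot + sum(mat[i, ] != mat[j, ])
  }
  pi_bar <- pi_tot / choose(n, 2)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (pi_bar - s / a1) /
    sqrt(c1 / a1 * s + c2 / (a1^2 + a2) * s * (s - 1))
}

# Kendall tau-b by explicit concordant/discordant pair counting
kendall_oracle <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- x[j] - x[i]
      dy <- y[j] - y[i]
      if (dx == 0 && dy == 0) next
      if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (sign(dx) == sign(dy)) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  t1 <- sum(sapply(table(x), function(t) t * (t - 1) / 2))
  t2 <- sum(sapply(table(y), function(t) t * (t - 1) / 2))
  (conc - disc) / sqrt((n0 - t1) * (n0 - t2))
}

random_codon <- function(sense_only = TRUE) {
  repeat {
    cod <- paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE),
                 collapse = "")
    if (!sense_only || GC[cod] != "*") return(cod)
  }
}

# small two-population dataset on disk for pipeline tests
make_test_dataset <- function(dir, n_genes = 10, n = 6, L = 600, seed = 9,
                              regimes = NULL) {
  if (is.null(regimes)) regimes <- rep("neutral", n_genes)
  mult <- c(neutral = 1, purifying = 0.05, balancing = 4)[regimes]
  genes <- data.frame(gene_id = sprintf("tg%02d", seq_len(n_genes)),
                      length = L,
                      pathway = rep(c("SSP1", "SSP2"),
                                    length.out = n_genes),
                      ppi = rep(1:5, length.out = n_genes),
                      regime = regimes, multiplier = unname(mult),
                      omega = 0.3, stringsAsFactors = FALSE)
  cfg <- sim_config(genes, n_landrace = n, n_wild = n, seed = seed)
  generate_dataset(cfg, dir, force = TRUE)
  cfg
}
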