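# Precomputed codon machinery for the NG86 estimator.
#
# Codons are indexed 1..64 with base order A,C,G,T:
#   index = 16*(b1-1) + 4*(b2-1) + b3.
# All tables are built once per session from Biostrings::GENETIC_CODE
# (standard code) and cached in the package namespace environment.

.codon_cache <- new.env(parent = emptyenv())

codon_index <- function(codons) {
  m <- matrix(match(unlist(strsplit(codons, "", fixed = TRUE)), DNA_BASES4),
              nrow = 3)
  if (anyNA(m)) return(ifelse(colSums(is.na(m)) > 0, NA_integer_,
                              16L * (m[1, ] - 1L) + 4L * (m[2, ] - 1L) + m[3, ]))
  16L * (m[1, ] - 1L) + 4L * (m[2, ] - 1L) + m[3, ]
}

codon_tables <- function() {
  if (!is.null(.codon_cache$tab)) return(.codon_cache$tab)
  b <- expand.grid(b3 = DNA_BASES4, b2 = DNA_BASES4, b1 = DNA_BASES4,
                   stringsAsFactors = FALSE)
  codons <- paste0(b$b1, b$b2, b$b3)          # in index order
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  is_stop <- aa == "*"

  # NG86 site fractions: each position contributes (#synonymous among its
  # 3 single-base changes)/3 to Ss; everything else (incl. changes to
  # stops) is nonsynonymous.
  ss <- numeric(64)
  for (ci in seq_len(64)) {
    cod <- strsplit(codons[ci], "")[[1]]
    nsyn <- 0
    for (pos in 1:3) {
      for (alt in setdiff(DNA_BASES4, cod[pos])) {
        mut <- cod
        mut[pos] <- alt
        if (gc[paste(mut, collapse = "")] == aa[ci] && !is_stop[ci]) {
          nsyn <- nsyn + 1
        }
      }
    }
    ss[ci] <- nsyn / 3
  }
  sa <- 3 - ss

  # Pairwise NG86 difference counts (path-averaged).
  na_mat <- matrix(0, 64, 64)
  ns_mat <- matrix(0, 64, 64)
  stop_path_mat <- matrix(FALSE, 64, 64)   # TRUE where only stop-crossing paths exist
  for (i in seq_len(64)) {
    ci <- strsplit(codons[i], "")[[1]]
    for (j in seq_len(64)) {
      if (i == j) next
      cj <- strsplit(codons[j], "")[[1]]
      pos <- which(ci != cj)
      res <- ng86_path_average(ci, cj, pos, gc)
      na_mat[i, j] <- res$na
      ns_mat[i, j] <- res$ns
      stop_path_mat[i, j] <- res$stop_only
    }
  }
  .codon_cache$tab <- list(codons = codons, aa = aa, is_stop = is_stop,
                           sa = sa, ss = ss, na = na_mat, ns = ns_mat,
                           stop_only = stop_path_mat)
  .codon_cache$tab
}

# Average synonymous/nonsynonymous step counts over all minimal mutation
# paths between two codons, excluding paths through stop intermediates
# (unless no path avoids one, in which case all paths are used).
ng86_path_average <- function(ci, cj, pos, gc) {
  orders <- switch(as.character(length(pos)),
                   "1" = list(pos),
                   "2" = list(pos, rev(pos)),
                   "3" = lapply(asplit(rbind(
                     c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                     c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)), 1),
                     function(o) pos[o]))
  paths <- lapply(orders, function(ord) {
    cur <- ci
    syn <- 0; nonsyn <- 0; through_stop <- FALSE
    for (step in seq_along(ord)) {
      nxt <- cur
      nxt[ord[step]] <- cj[ord[step]]
      a1 <- gc[paste(cur, collapse = "")]
      a2 <- gc[paste(nxt, collapse = "")]
      if (a1 == a2) syn <- syn + 1 else nonsyn <- nonsyn + 1
      if (step < length(ord) && a2 == "*") through_stop <- TRUE
      cur <- nxt
    }
    list(syn = syn, nonsyn = nonsyn, through_stop = through_stop)
  })
  ok <- !vapply(paths, `[[`, logical(1), "through_stop")
  stop_only <- !any(ok)
  if (stop_only) ok <- rep(TRUE, length(paths))
  use <- paths[ok]
  list(na = mean(vapply(use, `[[`, numeric(1), "nonsyn")),
       ns = mean(vapply(use, `[[`, numeric(1), "syn")),
       stop_only = stop_only)
}

# split a DNA string into complete codons (character vector); trailing
# partial codon dropped
split_codons <- function(seq, frame_offset = 0L) {
  chars <- if (length(seq) > 1L) seq else strsplit(seq, "", fixed = TRUE)[[1]]
  if (frame_offset > 0) chars <- chars[-seq_len(frame_offset)]
  ncod <- length(chars) %/% 3
  if (ncod == 0) return(character(0))
  chars <- chars[seq_len(3 * ncod)]
  m <- matrix(chars, nrow = 3)
  paste0(m[1, ], m[2, ], m[3, ])
}
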