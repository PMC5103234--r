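# Positional rate variation: Kendall rank correlation of Ka/Ks with
# pathway position, plus per-gene UPGMA trees.

#' Kendall's tau-b rank correlation with significance
#'
#' Tie-corrected tau-b: (C - D) / sqrt((n0 - n1)(n0 - n2)). The
#' two-sided p-value is computed by exact enumeration of all n!
#' orderings for n <= 8 and by the normal approximation with the
#' tie-adjusted null variance of C - D otherwise.
#'
#' @param x,y numeric vectors of equal length >= 3 (ties permitted)
#' @return list with \code{tau}, \code{p_value}, \code{n},
#'   \code{method} ("exact" or "normal")
#' @export
kendall_tau <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y differ in length")
  if (n < 3) stop("kendall_tau needs n >= 3")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop("kendall_tau undefined for an all-tied vector")
  }
  s_obs <- kendall_s(x, y)
  tau <- s_obs / kendall_denom(x, y)
  if (n <= 8) {
    perms <- all_permutations(n)
    s_null <- apply(perms, 1, function(p) kendall_s(x, y[p]))
    p <- mean(abs(s_null) >= abs(s_obs) - 1e-9)
    method <- "exact"
  } else {
    v <- kendall_null_var(x, y)
    z <- s_obs / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  list(tau = tau, p_value = p, n = n, method = method)
}

# concordant-minus-discordant pair count
kendall_s <- function(x, y) {
  s <- 0
  n <- length(x)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- s + sign(x[j] - x[i]) * sign(y[j] - y[i])
    }
  }
  s
}

kendall_denom <- function(x, y) {
  n <- length(x)
  n0 <- n * (n - 1) / 2
  tie_sum <- function(v) {
    t <- table(v)
    sum(t * (t - 1) / 2)
  }
  sqrt((n0 - tie_sum(x)) * (n0 - tie_sum(y)))
}

# tie-adjusted null variance of C - D (Kendall 1970)
kendall_null_var <- function(x, y) {
  n <- length(x)
  tx <- as.numeric(table(x))
  ty <- as.numeric(table(y))
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(tx * (tx - 1) * (2 * tx + 5))
  vu <- sum(ty * (ty - 1) * (2 * ty + 5))
  v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
  v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
    (9 * n * (n - 1) * (n - 2))
  (v0 - vt - vu) / 18 + v1 + v2
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (pos in seq_len(n)) {
    right <- if (pos <= n - 1) sub[, pos:(n - 1), drop = FALSE] else
      sub[, integer(0), drop = FALSE]
    block <- cbind(sub[, seq_len(pos - 1), drop = FALSE], n, right)
    out[r + seq_len(nrow(sub)), ] <- as.matrix(block)
    r <- r + nrow(sub)
  }
  out
}

#' Positional-rate-variation test for one pathway
#'
#' Kendall's tau-b between pathway position (PPI) and the Ka/Ks ratio
#' across the genes of a pathway, with a leave-one-out re-test dropping
#' the single maximum-ratio gene (robustness to one outlier driving the
#' trend). Genes with undefined (NA) ratios are excluded and counted.
#'
#' @param kaks_table data.frame with columns \code{gene} and
#'   \code{ratio}
#' @param pathway_map data.frame with columns \code{gene_id},
#'   \code{pathway}, \code{ppi}
#' @param pathway pathway to test
#' @return list with \code{pathway}, \code{tau}, \code{p_value},
#'   \code{n_genes}, \code{n_excluded}, and \code{leave_one_out}
#'   (dropped gene, tau, p)
#' @export
prv_test <- function(kaks_table, pathway_map, pathway) {
  pm <- pathway_map[pathway_map$pathway == pathway, ]
  df <- merge(pm, kaks_table, by.x = "gene_id",
              by.y = if ("gene" %in% names(kaks_table)) "gene" else "gene_id")
  n_excluded <- sum(is.na(df$ratio))
  df <- df[!is.na(df$ratio), ]
  if (nrow(df) < 3) {
    stop("prv_test needs >= 3 genes with a defined Ka/Ks ratio in ",
         pathway, " (", nrow(df), " available)")
  }
  kt <- kendall_tau(df$ppi, df$ratio)
  drop_i <- which.max(df$ratio)
  loo <- if (nrow(df) - 1 >= 3) {
    kt2 <- kendall_tau(df$ppi[-drop_i], df$ratio[-drop_i])
    list(dropped = df$gene_id[drop_i], tau = kt2$tau,
         p_value = kt2$p_value)
  } else {
    list(dropped = df$gene_id[drop_i], tau = NA_real_, p_value = NA_real_)
  }
  list(pathway = pathway, tau = kt$tau, p_value = kt$p_value,
       n_genes = nrow(df), n_excluded = n_excluded, leave_one_out = loo)
}

#' Pairwise p-distance matrix of an alignment
#'
#' Per-site difference proportions with pairwise deletion; diagonal 0.
#'
#' @param aln a \code{hap_alignment}
#' @return symmetric n x n matrix with sample ids as dimnames
#' @export
pairwise_distance_matrix <- function(aln) {
  codes <- alignment_codes(aln)
  n <- nrow(codes)
  d <- matrix(0, n, n, dimnames = list(aln$sample_ids, aln$sample_ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(codes[i, ]) & !is.na(codes[j, ])
      d[i, j] <- d[j, i] <-
        if (any(ok)) sum(codes[i, ok] != codes[j, ok]) / sum(ok) else NA_real_
    }
  }
  d
}

#' UPGMA clustering to a rooted ultrametric tree
#'
#' Iterative closest-pair merging with size-weighted average linkage;
#' node height = half the merge distance, branch length = height minus
#' child height. Ties on the minimum distance are broken toward the
#' lexicographically smallest pair of cluster labels (a cluster is
#' labelled by its smallest member).
#'
#' @param d symmetric non-negative distance matrix with labelled dimnames
#' @param labels leaf labels (default: rownames of d)
#' @return list of class \code{upgma_tree} with \code{newick} (string,
#'   ";"-terminated) and \code{height} of the root
#' @export
upgma <- function(d, labels = rownames(d)) {
  if (!isSymmetric(unname(as.matrix(d)), tol = 1e-12)) {
    stop("upgma requires a symmetric distance matrix")
  }
  d <- as.matrix(d)
  if (any(d < 0)) stop("negative distances")
  n <- nrow(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  active <- seq_len(n)
  newick <- labels
  height <- rep(0, n)
  size <- rep(1L, n)
  minlab <- labels
  dm <- d
  next_id <- n
  while (length(active) > 1) {
    # closest active pair, ties broken by smallest label pair
    best <- NULL
    for (ii in seq_along(active)[-length(active)]) {
      for (jj in (ii + 1):length(active)) {
        a <- active[ii]; b <- active[jj]
        dist_ab <- dm[a, b]
        lab <- sort(c(minlab[a], minlab[b]))
        cand <- list(a = a, b = b, d = dist_ab, lab = lab)
        if (is.null(best) || dist_ab < best$d - 1e-15 ||
            (abs(dist_ab - best$d) <= 1e-15 &&
             (lab[1] < best$lab[1] ||
              (lab[1] == best$lab[1] && lab[2] < best$lab[2])))) {
          best <- cand
        }
      }
    }
    a <- best$a; b <- best$b
    if (minlab[b] < minlab[a]) { tmp <- a; a <- b; b <- tmp }
    h <- best$d / 2
    next_id <- next_id + 1L
    newick[next_id] <- sprintf("(%s:%.10g,%s:%.10g)",
                               newick[a], h - height[a],
                               newick[b], h - height[b])
    height[next_id] <- h
    size[next_id] <- size[a] + size[b]
    minlab[next_id] <- min(minlab[a], minlab[b])
    # size-weighted average linkage update
    dm <- rbind(cbind(dm, 0), 0)
    for (k in setdiff(active, c(a, b))) {
      dm[next_id, k] <- dm[k, next_id] <-
        (size[a] * dm[a, k] + size[b] * dm[b, k]) / (size[a] + size[b])
    }
    active <- c(setdiff(active, c(a, b)), next_id)
  }
  root <- active[1]
  structure(list(newick = paste0(newick[root], ";"),
                 height = height[root]),
            class = "upgma_tree")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat("<upgma_tree> height", x$height, "\n", x$newick, "\n")
  invisible(x)
}
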