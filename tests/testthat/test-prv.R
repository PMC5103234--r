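test_that("kendall_tau matches the pair-counting oracle and cor.test", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(kendall_tau(x, x)$tau, 1)
  expect_equal(kendall_tau(x, rev(x))$tau, -1)

  # tied example against the explicit oracle
  xt <- c(1, 1, 2, 3)
  yt <- c(0.2, 0.4, 0.3, 0.5)
  kt <- kendall_tau(xt, yt)
  expect_equal(kt$tau, kendall_oracle(xt, yt), tolerance = 1e-12)
  expect_equal(kt$method, "exact")

  # symmetry in the arguments
  expect_equal(kendall_tau(xt, yt)$tau, kendall_tau(yt, xt)$tau,
               tolerance = 1e-12)

  # agreement with stats::cor.test where both are exact (no ties)
  set.seed(71)
  for (i in 1:5) {
    x <- sample(100, 7)
    y <- sample(100, 7)
    kt <- kendall_tau(x, y)
    ct <- stats::cor.test(x, y, method = "kendall", exact = TRUE)
    expect_equal(kt$tau, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(kt$p_value, ct$p.value, tolerance = 1e-10)
  }

  # large-n normal approximation with heavy ties stays calibrated
  set.seed(72)
  x <- rep(1:6, each = 5)
  y <- stats::rnorm(30)
  kt <- kendall_tau(x, y)
  expect_equal(kt$method, "normal")
  expect_equal(kt$tau, kendall_oracle(x, y), tolerance = 1e-12)
  expect_true(kt$p_value > 0 && kt$p_value <= 1)

  # invariance under strictly monotone transforms
  expect_equal(kendall_tau(x, y)$tau, kendall_tau(x^3, exp(y))$tau,
               tolerance = 1e-12)

  expect_error(kendall_tau(c(1, 1, 1), c(1, 2, 3)), "all-tied")
  expect_error(kendall_tau(1:2, 1:2), "n >= 3")
})

test_that("prv_test correlates Ka/Ks with pathway position", {
  pm <- data.frame(gene_id = sprintf("g%d", 1:12),
                   pathway = "SSP1", ppi = rep(1:6, 2))
  kk <- data.frame(gene = pm$gene_id,
                   ratio = 0.1 * pm$ppi + 0.001 * (1:12))
  res <- prv_test(kk, pm, "SSP1")
  expect_gt(res$tau, 0.8)
  expect_lt(res$p_value, 0.01)
  expect_equal(res$n_genes, 12)

  # leave-one-out drops exactly the maximum ratio and reports both
  expect_equal(res$leave_one_out$dropped, "g12")
  expect_false(is.na(res$leave_one_out$tau))

  # undefined ratios excluded with a count
  kk$ratio[1:2] <- NA
  res2 <- prv_test(kk, pm, "SSP1")
  expect_equal(res2$n_excluded, 2)
  expect_equal(res2$n_genes, 10)

  expect_error(prv_test(kk[1:4, ], pm, "SSP1"), ">= 3 genes")
})

test_that("pairwise distances match the brute-force loop and ape", {
  aln <- make_alignment(c("AAAA", "AAAA"))
  d0 <- pairwise_distance_matrix(aln)
  expect_equal(d0[1, 2], 0)

  set.seed(73)
  seqs <- random_seqs(6, 50, p_missing = 0.05)
  aln2 <- make_alignment(seqs)
  d <- pairwise_distance_matrix(aln2)
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  for (i in 1:5) {
    for (j in (i + 1):6) {
      a <- strsplit(seqs[i], "")[[1]]
      b <- strsplit(seqs[j], "")[[1]]
      ok <- !(a %in% c("N", "-")) & !(b %in% c("N", "-"))
      expect_equal(d[i, j], sum(a[ok] != b[ok]) / sum(ok),
                   tolerance = 1e-12)
    }
  }

  # cross-check against ape raw distances with pairwise deletion
  seqs2 <- random_seqs(5, 80)
  aln3 <- make_alignment(seqs2)
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(seqs2), "")))
  dd <- as.matrix(ape::dist.dna(bin, model = "raw",
                                pairwise.deletion = TRUE))
  expect_equal(unname(pairwise_distance_matrix(aln3)), unname(dd),
               tolerance = 1e-12)
})

test_that("upgma builds ultrametric trees with deterministic tie-breaks", {
  # two leaves at distance d: both branches d/2
  d2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("A", "B"),
                                                 c("A", "B")))
  expect_equal(upgma(d2)$newick, "(A:1.5,B:1.5);")

  # three leaves, hand-executed merge order
  d3 <- matrix(c(0, 2, 6,
                 2, 0, 6,
                 6, 6, 0), 3, byrow = TRUE,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_equal(upgma(d3)$newick, "((A:1,B:1):2,C:3);")

  # ultrametricity on random distance matrices (via ape path lengths)
  set.seed(74)
  for (i in 1:5) {
    n <- 7
    pts <- matrix(stats::rnorm(n * 3), n)
    dm <- as.matrix(stats::dist(pts))
    dimnames(dm) <- list(letters[1:n], letters[1:n])
    tr <- upgma(dm)
    ph <- ape::read.tree(text = tr$newick)
    depths <- ape::node.depth.edgelength(ph)[seq_len(n)]
    expect_lt(max(depths) - min(depths), 1e-9)
    # root height agrees with hclust average linkage
    hc <- stats::hclust(stats::as.dist(dm), method = "average")
    expect_equal(tr$height, max(hc$height) / 2, tolerance = 1e-9)
  }

  # deterministic lexicographic tie-break
  dt <- matrix(c(0, 1, 1,
                 1, 0, 1,
                 1, 1, 0), 3, byrow = TRUE,
               dimnames = list(c("B", "A", "C"), c("B", "A", "C")))
  expect_equal(upgma(dt)$newick, "((A:0.5,B:0.5):0,C:0.5);")

  expect_error(upgma(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("divergent populations form disjoint UPGMA clades", {
  cfg <- sim_config(data.frame(gene_id = "g", length = 1200,
                               regime = "purifying", multiplier = 0.05,
                               omega = 0.3),
                    n_landrace = 6, n_wild = 6, seed = 29)
  sim <- simulate_gene(cfg, "g")
  ingroup <- setdiff(sim$alignment$sample_ids, "outgroup_1")
  sub <- subset_alignment(sim$alignment, ingroup)
  tr <- upgma(pairwise_distance_matrix(sub))
  ph <- ape::read.tree(text = tr$newick)
  lr <- grep("landrace", ingroup, value = TRUE)
  expect_true(ape::is.monophyletic(ph, lr))
})
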