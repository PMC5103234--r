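test_that("theta_pi matches its definition and the brute-force oracle", {
  a <- make_alignment(c(paste(rep("A", 100), collapse = ""),
                        paste(c(rep("A", 99), "G"), collapse = "")))
  expect_equal(theta_pi(a), 0.01)

  b <- make_alignment(rep(paste(rep("ACGT", 10), collapse = ""), 4))
  expect_equal(theta_pi(b), 0)
  expect_error(theta_pi(b, "s1"), "at least 2")

  set.seed(101)
  for (i in 1:20) {
    seqs <- random_seqs(5, 60, p_missing = if (i > 10) 0.05 else 0)
    aln <- make_alignment(seqs)
    expect_equal(theta_pi(aln), pi_oracle(seqs), tolerance = 1e-12)
  }
})

test_that("watterson_theta follows S / (a_n L)", {
  a <- make_alignment(c(paste(rep("A", 100), collapse = ""),
                        paste(c(rep("A", 99), "G"), collapse = "")))
  expect_equal(watterson_theta(a), 0.01)

  # n = 4, S = 11 over L = 1000: a_4 = 1 + 1/2 + 1/3
  set.seed(7)
  base <- sample(c("A", "C", "G", "T"), 1000, replace = TRUE)
  m <- matrix(rep(base, each = 4), nrow = 4)
  sites <- sample(1000, 11)
  for (s in sites) m[sample(4, 1), s] <- setdiff(c("A", "C", "G", "T"),
                                                 base[s])[1]
  aln <- make_alignment(apply(m, 1, paste, collapse = ""))
  expect_equal(watterson_theta(aln), 11 / ((1 + 1 / 2 + 1 / 3) * 1000),
               tolerance = 1e-12)
})

test_that("tajimas_d reproduces the 1989 formula and marks invariance", {
  inv <- make_alignment(rep(paste(rep("ACG", 20), collapse = ""), 6))
  expect_true(is.na(tajimas_d(inv)))

  # every variant a singleton: D must be negative
  set.seed(11)
  base <- sample(c("A", "C", "G", "T"), 200, replace = TRUE)
  m <- matrix(rep(base, each = 10), nrow = 10)
  for (s in sample(200, 5)) {
    m[sample(10, 1), s] <- setdiff(c("A", "C", "G", "T"), base[s])[1]
  }
  aln <- make_alignment(apply(m, 1, paste, collapse = ""))
  expect_lt(tajimas_d(aln), 0)

  # agreement with direct formula evaluation on random alignments
  set.seed(12)
  for (i in 1:10) {
    seqs <- random_seqs(8, 120)
    aln <- make_alignment(seqs)
    if (watterson_theta(aln) == 0) next
    expect_equal(tajimas_d(aln), tajd_oracle(seqs), tolerance = 1e-12)
  }
})

test_that("hudson_fst handles fixed differences, panmixia and hand cases", {
  part <- population_partition(sprintf("s%d", 1:4),
                               c("landrace", "landrace", "wild", "wild"))

  # groups fixed for different alleles at every variable site
  aln <- make_alignment(c("AAAA", "AAAA", "GGGG", "GGGG"))
  expect_equal(hudson_fst(aln, part), 1)

  # invariant alignment (no variation anywhere): exactly 0, not NaN
  aln0 <- make_alignment(rep("ACGT", 4))
  expect_identical(hudson_fst(aln0, part), 0)

  # hand-built Hw = 0.005, Hb = 0.01 over L = 200: derived-site sets
  # A = {}, B = {1}, C = {2}, D = {2,3} give within-group differences
  # (1, 1) and cross differences (1, 2, 2, 3), mean 2
  L <- 200
  chars <- rep("A", L)
  mk <- function(sites, alts) {
    x <- chars
    x[sites] <- alts
    paste(x, collapse = "")
  }
  aln2 <- make_alignment(c(mk(integer(0), character(0)),
                           mk(1, "C"), mk(2, "G"), mk(2:3, c("G", "T"))))
  expect_equal(theta_pi(aln2, c("s1", "s2")), 1 / L)
  expect_equal(theta_pi(aln2, c("s3", "s4")), 1 / L)
  expect_equal(hudson_fst(aln2, part), 0.5, tolerance = 1e-12)

  # random alignments vs oracle
  set.seed(21)
  for (i in 1:15) {
    seqs <- random_seqs(6, 60, p_missing = if (i > 8) 0.05 else 0)
    part6 <- population_partition(sprintf("s%d", 1:6),
                                  rep(c("landrace", "wild"), each = 3))
    aln <- make_alignment(seqs)
    expect_equal(hudson_fst(aln, part6),
                 fst_oracle(seqs[1:3], seqs[4:6]), tolerance = 1e-12)
    expect_lte(hudson_fst(aln, part6), 1)
  }

  # panmictic draws straddle zero
  set.seed(22)
  fsts <- replicate(60, {
    seqs <- random_seqs(8, 80)
    part8 <- population_partition(sprintf("s%d", 1:8),
                                  rep(c("landrace", "wild"), each = 4))
    hudson_fst(make_alignment(seqs), part8)
  })
  expect_lt(abs(mean(fsts)), 0.12)
  expect_true(any(fsts < 0) && any(fsts > 0))
})

test_that("codon_stats classifies coding effects and conserves diversity", {
  part <- population_partition(sprintf("s%d", 1:6),
                               rep(c("landrace", "wild"), each = 3))

  # monomorphic codon, one synonymous (GGG/GGA) and one complex codon
  seqs <- c("ATGGGGTTTAAA",
            "ATGGGATTCACC",
            "ATGGGGTTTAAA",
            "ATGGGGTTTAAA",
            "ATGGGATTTAAA",
            "ATGGGGTTTAAA")
  aln <- make_alignment(seqs)
  cs <- codon_stats(aln, part)
  expect_equal(cs$effect, c("monomorphic", "synonymous", "synonymous",
                            "complex"))
  expect_equal(cs$fst[1], 0)
  expect_true(is.na(cs$tajd_landrace[1]))
  expect_equal(nrow(cs), 4)

  # nonsynonymous change
  seqs2 <- c("ATGAAA", "ATGGAA", "ATGAAA", "ATGAAA", "ATGAAA", "ATGAAA")
  cs2 <- codon_stats(make_alignment(seqs2), part)
  expect_equal(cs2$effect[2], "nonsynonymous")

  # per-codon diversity sums to the gene-level pairwise diversity
  set.seed(31)
  cfg <- sim_config(data.frame(gene_id = "g", length = 300,
                               regime = "neutral", multiplier = 1,
                               omega = 0.3),
                    n_landrace = 6, n_wild = 6, theta_wild = 0.01,
                    seed = 3)
  sim <- simulate_gene(cfg, "g")
  cs3 <- codon_stats(sim$alignment, sim$partition)
  lr <- names(sim$partition)[sim$partition == "landrace"]
  expect_equal(sum(cs3$pi_landrace * 3),
               theta_pi(sim$alignment, lr) * sim$alignment$L,
               tolerance = 1e-9)
})
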