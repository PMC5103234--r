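test_that("consensus_sequence takes majorities with deterministic ties", {
  aln1 <- make_alignment("ACGTAC", ids = "only")
  expect_equal(consensus_sequence(aln1), "ACGTAC")

  aln2 <- make_alignment(c("AAA", "AAA", "GAA"))
  expect_equal(consensus_sequence(aln2), "AAA")

  # 2-way tie broken toward the reference, else alphabetically
  aln3 <- make_alignment(c("ATT", "GTT"))
  expect_equal(consensus_sequence(aln3, reference = "GTT"), "GTT")
  expect_equal(consensus_sequence(aln3), "ATT")
})

test_that("NG86 site counts match exhaustive neighbour enumeration", {
  expect_equal(ng86_sites("TTT"), c(Sa = 8 / 3, Ss = 1 / 3))
  expect_equal(ng86_sites("ATG"), c(Sa = 3, Ss = 0))

  # additivity over concatenation
  expect_equal(ng86_sites("TTTATG"),
               ng86_sites("TTT") + ng86_sites("ATG"))

  set.seed(41)
  for (i in 1:30) {
    cod <- random_codon()
    expect_equal(ng86_sites(cod), ng86_sites_oracle(cod),
                 tolerance = 1e-12)
  }

  # every sense codon partitions its 9 neighbours: Sa + Ss = 3
  for (cod in names(GC)[GC != "*"]) {
    s <- ng86_sites(cod)
    expect_equal(unname(s["Sa"] + s["Ss"]), 3, tolerance = 1e-12)
  }

  expect_error(ng86_sites("ATGTAAAAA"), "codon index 2")
})

test_that("NG86 differences average over minimal substitution paths", {
  expect_equal(ng86_differences("GGG", "GGA"), c(na = 0, ns = 1))
  expect_equal(ng86_differences("AAA", "AAA"), c(na = 0, ns = 0))
  expect_equal(ng86_differences("TTT", "GTA"),
               ng86_diff_oracle("TTT", "GTA"), tolerance = 1e-12)

  set.seed(42)
  for (i in 1:50) {
    a <- random_codon()
    b <- random_codon()
    expect_equal(ng86_differences(a, b), ng86_diff_oracle(a, b),
                 tolerance = 1e-12)
    # symmetry of the path average
    got <- ng86_differences(b, a)
    expect_equal(unname(got), unname(ng86_differences(a, b)),
                 tolerance = 1e-12)
  }
})

test_that("kaks_pair computes the Jukes-Cantor-corrected NG86 estimate", {
  s <- paste(rep("ATGGCT", 20), collapse = "")
  r0 <- kaks_pair(s, s)
  expect_equal(r0$Ka, 0)
  expect_equal(r0$Ks, 0)
  expect_true(is.na(r0$ratio))
  expect_equal(r0$status, "UNDEFINED")

  # one synonymous difference only: Ka = 0, ratio 0
  s2 <- sub("GCT", "GCC", s)
  r1 <- kaks_pair(s, s2)
  expect_equal(r1$Ka, 0)
  expect_equal(r1$ratio, 0)

  # two-codon toy pair against full hand enumeration
  a <- "TTTGGG"
  b <- "GTAGGG"
  r2 <- kaks_pair(a, b)
  d1 <- ng86_diff_oracle("TTT", "GTA")
  d2 <- ng86_diff_oracle("GGG", "GGG")
  sa <- (ng86_sites_oracle("TTT") + ng86_sites_oracle("GGG") +
           ng86_sites_oracle("GTA") + ng86_sites_oracle("GGG")) / 2
  na <- d1["na"] + d2["na"]
  ns <- d1["ns"] + d2["ns"]
  jc <- function(p) -3 / 4 * log(1 - 4 * p / 3)
  expect_equal(r2$Na, unname(na), tolerance = 1e-12)
  expect_equal(r2$Ns, unname(ns), tolerance = 1e-12)
  expect_equal(r2$Ka, unname(jc(na / sa["Sa"])), tolerance = 1e-12)
  expect_equal(r2$Ks, unname(jc(ns / sa["Ss"])), tolerance = 1e-12)

  # symmetry
  r3 <- kaks_pair(b, a)
  expect_equal(r3$Ka, r2$Ka, tolerance = 1e-12)
  expect_equal(r3$Ks, r2$Ks, tolerance = 1e-12)

  # saturation flag when a proportion reaches 3/4
  many_a <- paste(rep("AAA", 10), collapse = "")
  many_c <- paste(rep("CCC", 10), collapse = "")
  expect_equal(kaks_pair(many_a, many_c)$status, "SATURATED")
})

test_that("kaks_significance is a doubled exact binomial tail", {
  # proportional split sits at the null: maximal p
  res <- list(Na = 30, Ns = 10, Sa = 75, Ss = 25)
  expect_equal(kaks_significance(res), 1)

  # Na = 0 of 20 with p0 = 0.75
  res2 <- list(Na = 0, Ns = 20, Sa = 75, Ss = 25)
  expect_equal(kaks_significance(res2), 2 * 0.25^20, tolerance = 1e-12)

  # more extreme splits never increase p
  p_seq <- vapply(0:10, function(na) {
    kaks_significance(list(Na = na, Ns = 20 - na, Sa = 50, Ss = 50))
  }, numeric(1))
  expect_true(all(diff(p_seq) >= -1e-12))

  expect_error(kaks_significance(list(Na = 0, Ns = 0, Sa = 10, Ss = 5)),
               "no observed differences")
})

test_that("kaks_group modes agree in direction on simulated genes", {
  cfg <- sim_config(data.frame(gene_id = "g", length = 1500,
                               regime = "neutral", multiplier = 1,
                               omega = 0.2),
                    n_landrace = 4, n_wild = 4, seed = 17)
  sim <- simulate_gene(cfg, "g")
  og <- alignment_strings(sim$alignment)[["outgroup_1"]]
  k1 <- kaks_group(sim$alignment, sim$partition, "wild", og,
                   reference = sim$reference)
  k2 <- kaks_group(sim$alignment, sim$partition, "wild", og,
                   mode = "pairs", reference = sim$reference)
  expect_lt(k1$ratio, 1)
  expect_lt(k2$ratio, 1)
  expect_equal(k1$mode, "consensus")
  expect_equal(k2$mode, "pairs")
})
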