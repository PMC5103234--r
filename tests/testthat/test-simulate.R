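test_that("zero mutation rate produces an invariant ingroup", {
  cfg <- sim_config(data.frame(gene_id = "g", length = 300,
                               regime = "neutral", multiplier = 1,
                               omega = 0.5),
                    n_landrace = 4, n_wild = 4, theta_wild = 1e-12,
                    seed = 2)
  sim <- simulate_gene(cfg, "g")
  ingroup <- setdiff(sim$alignment$sample_ids, "outgroup_1")
  strs <- alignment_strings(sim$alignment)[ingroup]
  expect_equal(length(unique(strs)), 1L)
  expect_equal(watterson_theta(sim$alignment, ingroup), 0)
  expect_equal(unique(unname(strs)), sim$reference)
})

test_that("neutral segregating sites match the coalescent expectation", {
  # E[S] = theta * L * a_n for the wild (panmictic) sample
  n <- 40
  L <- 3000
  theta <- 0.001
  cfg <- sim_config(data.frame(gene_id = "g", length = L,
                               regime = "neutral", multiplier = 1,
                               omega = 0.5),
                    n_landrace = 2, n_wild = n, theta_wild = theta,
                    seed = 77)
  reps <- 400
  s_obs <- numeric(reps)
  for (r in seq_len(reps)) {
    cfg$seed <- sub_seed(77, 100000 + r)
    sim <- simulate_gene(cfg, "g")
    wild <- grep("wild", sim$alignment$sample_ids, value = TRUE)
    codes <- domescan:::alignment_codes(sim$alignment)[wild, ]
    s_obs[r] <- domescan:::count_segregating(codes, seq_len(L))
  }
  expected <- theta * L * harmonic_number(n)
  se <- stats::sd(s_obs) / sqrt(reps)
  expect_lt(abs(mean(s_obs) - expected), 3 * se)
})

test_that("wild diversity recovers theta and regimes order landrace diversity", {
  genes <- data.frame(gene_id = sprintf("g%03d", 1:200), length = 1500,
                      regime = "neutral", multiplier = 1, omega = 0.3)
  cfg <- sim_config(genes, n_landrace = 6, n_wild = 10, seed = 81)
  truths <- do.call(rbind, lapply(genes$gene_id, function(g) {
    simulate_gene(cfg, g)$truth
  }))
  expect_lt(abs(mean(truths$theta_pi_wild) - cfg$theta_wild) /
              cfg$theta_wild, 0.1)

  # purifying regime: landrace diversity below wild in nearly all draws
  genes2 <- data.frame(gene_id = sprintf("p%03d", 1:200), length = 1500,
                       regime = "purifying", multiplier = 0.1,
                       omega = 0.3)
  cfg2 <- sim_config(genes2, n_landrace = 10, n_wild = 10, seed = 82)
  tr2 <- do.call(rbind, lapply(genes2$gene_id, function(g) {
    simulate_gene(cfg2, g)$truth
  }))
  expect_gte(mean(tr2$theta_pi_landrace < tr2$theta_pi_wild), 0.95)

  # balancing regime: landrace diversity above wild-neutral scale,
  # Tajima's D skewed positive
  genes3 <- data.frame(gene_id = sprintf("b%03d", 1:50), length = 1500,
                       regime = "balancing", multiplier = 4, omega = 0.3)
  cfg3 <- sim_config(genes3, n_landrace = 10, n_wild = 10, seed = 83)
  sims3 <- lapply(genes3$gene_id, function(g) simulate_gene(cfg3, g))
  tr3 <- do.call(rbind, lapply(sims3, `[[`, "truth"))
  expect_gt(mean(tr3$theta_pi_landrace), 2 * cfg3$theta_wild)
  d3 <- vapply(sims3, function(s) {
    lr <- names(s$partition)[s$partition == "landrace"]
    tajimas_d(s$alignment, lr)
  }, numeric(1))
  expect_gt(mean(d3, na.rm = TRUE), 0.5)
})

test_that("planted omega governs the outgroup substitution spectrum", {
  genes <- data.frame(gene_id = c("lo", "hi"), length = 3000,
                      regime = "neutral", multiplier = 1,
                      omega = c(0.2, 1.0))
  cfg <- sim_config(genes, n_landrace = 2, n_wild = 2, seed = 84)
  lo <- simulate_gene(cfg, "lo")$truth$omega_realized
  hi <- simulate_gene(cfg, "hi")$truth$omega_realized
  expect_lt(lo, hi)
  expect_lt(lo, 0.5)
})

test_that("generate_dataset is deterministic and refuses overwrites", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- make_test_dataset(d1, n_genes = 6, n = 4, L = 300, seed = 7,
                           regimes = rep(c("neutral", "purifying",
                                           "balancing"), 2))
  make_test_dataset(d2, n_genes = 6, n = 4, L = 300, seed = 7,
                    regimes = rep(c("neutral", "purifying",
                                    "balancing"), 2))
  files <- setdiff(list.files(d1, recursive = TRUE), "manifest.json")
  h1 <- tools::md5sum(file.path(d1, files))
  h2 <- tools::md5sum(file.path(d2, files))
  expect_identical(unname(h1), unname(h2))

  # refuse to clobber an existing dataset without force
  expect_error(generate_dataset(cfg, d1), "force")

  # manifest counts match the planted regimes
  data <- read_dataset(d1)
  expect_equal(nrow(data$truth), 6)
  expect_equal(sum(data$truth$regime == "purifying"), 2)
  expect_equal(sum(data$truth$regime == "balancing"), 2)
  expect_length(data$alignments, 6)
  expect_equal(data$manifest$regimes$balancing, 2)
})
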