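test_that("empirical_percentile follows the strictly-less + half-tie rule", {
  expect_error(empirical_percentile(numeric(0), 1), "empty")

  set.seed(51)
  vals <- sort(stats::rnorm(100))
  # minimum queried against the remaining 99 distinct values
  expect_equal(empirical_percentile(vals[-1], vals[1]), 0)

  vals101 <- sort(stats::rnorm(101))
  med <- vals101[51]
  expect_equal(empirical_percentile(vals101[-51], med), 50)

  # all-tied background: every comparison is a half-counted tie
  expect_equal(suppressWarnings(empirical_percentile(c(1, 1), 1)), 50)

  expect_warning(empirical_percentile(1:5, 3), "unreliable")
})

test_that("classify_genes applies the joint percentile criteria", {
  set.seed(52)
  bg <- data.frame(gene = sprintf("b%03d", 1:200),
                   theta_pi = stats::rlnorm(200, log(1e-3), 0.5),
                   theta_w = stats::rlnorm(200, log(1.1e-3), 0.5),
                   tajimas_d = stats::rnorm(200, 0, 0.8),
                   S = 10L, fst = stats::runif(200, 0, 0.5))

  at_pct <- function(v, p) stats::quantile(v, p / 100, names = FALSE)
  focal <- data.frame(
    gene = c("pur", "med", "bal", "inv"),
    theta_pi = c(at_pct(bg$theta_pi, 2), stats::median(bg$theta_pi),
                 at_pct(bg$theta_pi, 85), 0),
    theta_w = c(at_pct(bg$theta_w, 3), stats::median(bg$theta_w),
                at_pct(bg$theta_w, 85), 0),
    tajimas_d = c(-1.2, 0.1, at_pct(bg$tajimas_d, 97), NA),
    S = c(5L, 5L, 9L, 0L),
    fst = c(at_pct(bg$fst, 97), stats::median(bg$fst),
            at_pct(bg$fst, 50), 0.3))
  calls <- classify_genes(focal, background = bg)
  expect_equal(calls$label, c("purifying", "none", "balancing",
                              "invariant"))
  expect_true(all(!is.na(calls$pct_theta_pi)))

  # boundary determinism: exactly the 5th percentile fails "< 5%"
  cut <- default_cutoffs()
  b0 <- data.frame(gene = sprintf("x%d", 1:100), theta_pi = 1:100,
                   theta_w = 1:100, tajimas_d = rep(-1, 100), S = 5L,
                   fst = 1:100 / 100)
  focal5 <- data.frame(gene = "q", theta_pi = 5.5, theta_w = 5.5,
                       tajimas_d = -1, S = 5L, fst = 0.999)
  # theta percentile is exactly 5 -> purifying must NOT fire
  expect_equal(empirical_percentile(b0$theta_pi, 5.5), 5)
  expect_equal(classify_genes(focal5, background = b0)$label, "none")

  expect_error(classify_genes(transform(focal5, fst = NA),
                              background = b0), "missing FST")
})

test_that("classify_genes is invariant to monotone rescaling of backgrounds", {
  set.seed(53)
  stats_df <- data.frame(gene = sprintf("g%d", 1:60),
                         theta_pi = stats::rlnorm(60, -7, 0.8),
                         theta_w = stats::rlnorm(60, -7, 0.8),
                         tajimas_d = stats::rnorm(60),
                         S = rpois(60, 8),
                         fst = stats::runif(60))
  stats_df$S[stats_df$S == 0] <- 1L
  calls1 <- classify_genes(stats_df)
  rescaled <- transform(stats_df,
                        theta_pi = 1000 * theta_pi^3,
                        theta_w = 50 * theta_w,
                        fst = fst^5)
  calls2 <- classify_genes(rescaled)
  expect_equal(calls1$label, calls2$label)
  expect_equal(calls1$pct_theta_pi, calls2$pct_theta_pi)
})

test_that("classify_codons applies the site-level sign criteria", {
  track <- data.frame(
    gene = "g", codon = 1:5,
    pi_landrace = c(0, 0, 0.02, 0.001, 0.001),
    pi_wild = c(0, 0.02, 0, 0.001, 0.001),
    fst = c(0, 0.4, 0.4, 0.4, 0.4),
    tajd_landrace = c(NA, -0.9, 0.9, 0, 0.5),
    effect = c("monomorphic", "nonsynonymous", "synonymous",
               "synonymous", "synonymous"))
  calls <- classify_codons(track, mean_diversity = 0.001)
  expect_equal(calls$label,
               c("none", "purifying", "balancing", "none", "none"))
  expect_equal(calls$effect[2], "nonsynonymous")
})

test_that("genes_with_both needs disjoint codon sets of each type", {
  cc <- data.frame(gene = c("a", "a", "b", "b", "c"),
                   codon = c(1, 9, 2, 3, 1), level = "codon",
                   label = c("purifying", "balancing", "purifying",
                             "purifying", "balancing"))
  expect_equal(genes_with_both(cc), "a")
})

test_that("flanking_sweep_scan counts labelled neighbours within the radius", {
  ord <- data.frame(gene = sprintf("g%02d", 1:30),
                    chrom = rep(c("chr1", "chr2"), each = 15),
                    start = rep(seq(0, by = 1000, length.out = 15), 2))
  calls <- data.frame(gene = ord$gene, label = "none")

  s0 <- flanking_sweep_scan("g05", ord, calls, radius = 10)
  expect_false(s0$sweep)
  expect_equal(s0$n_purifying + s0$n_balancing + s0$n_invariant, 0)

  # chromosome end: only 3 downstream neighbours exist
  s1 <- flanking_sweep_scan("g12", ord, calls, radius = 10)
  expect_equal(s1$n_flanking, 10 + 3)

  # planted cluster: 4 balancing + 2 purifying neighbours
  calls2 <- calls
  calls2$label[calls2$gene %in% c("g18", "g19", "g21", "g22")] <- "balancing"
  calls2$label[calls2$gene %in% c("g17", "g23")] <- "purifying"
  s2 <- flanking_sweep_scan("g20", ord, calls2, radius = 10)
  expect_equal(s2$n_balancing, 4)
  expect_equal(s2$n_purifying, 2)
  expect_true(s2$sweep)

  expect_error(flanking_sweep_scan("nope", ord, calls), "not in gene order")
})
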