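# Hudson-style coalescent machinery (no recombination within a gene).
#
# Time is measured in units of 2N generations of the wild/ancestral
# population; a lineage pair in a population of relative size b coalesces
# at rate 1/b, and mutations fall on branches as a Poisson process with
# rate (theta/2) * L per unit time (so E[pairwise differences per site]
# equals theta in a panmictic population).

# Genealogy of n1 landrace + n2 wild haplotypes under a clean split at
# t_split: landrace lineages coalesce among themselves until t_split,
# wild lineages likewise (size 1), then all surviving lineages enter the
# ancestral population (size 1) and coalesce to the root. The landrace
# population size is piecewise constant backwards in time: `b` on
# [0, t_bottleneck) (recent/recovered size) and `b_founder` on
# [t_bottleneck, t_split) (the domestication founder squeeze). Returns
# node times, parent pointers and per-node tip descendants.
sim_genealogy <- function(n1, n2, b = 1, t_split = 0,
                          t_bottleneck = t_split, b_founder = b) {
  n <- n1 + n2
  max_nodes <- 2L * n - 1L
  node_time <- numeric(max_nodes)
  parent <- integer(max_nodes)
  children <- vector("list", max_nodes)
  active <- seq_len(n)
  pop <- c(rep("L", n1), rep("W", n2))
  nxt <- n + 1L
  t <- 0

  coalesce_pair <- function(ids) {
    node_time[nxt] <<- t
    parent[ids] <<- nxt
    children[nxt] <<- list(ids)
    nxt <<- nxt + 1L
  }

  # phase 1: within-population coalescence until the split time
  while (length(active) > 1 && t < t_split) {
    kl <- sum(pop == "L")
    kw <- sum(pop == "W")
    size_l <- if (t < t_bottleneck) b else b_founder
    rl <- if (kl >= 2) choose(kl, 2) / size_l else 0
    rw <- if (kw >= 2) choose(kw, 2) else 0
    boundary <- if (t < t_bottleneck) t_bottleneck else t_split
    if (rl + rw == 0) { t <- t_split; break }
    dt <- stats::rexp(1, rl + rw)
    if (t + dt >= boundary) { t <- boundary; next }
    t <- t + dt
    which_pop <- if (stats::runif(1) < rl / (rl + rw)) "L" else "W"
    idx <- which(pop == which_pop)
    pair <- sample(idx, 2)
    new_id <- nxt
    coalesce_pair(active[pair])
    active <- c(active[-pair], new_id)
    pop <- c(pop[-pair], which_pop)
  }

  # phase 2: ancestral panmictic population
  while (length(active) > 1) {
    k <- length(active)
    t <- t + stats::rexp(1, choose(k, 2))
    pair <- sample(seq_len(k), 2)
    new_id <- nxt
    coalesce_pair(active[pair])
    active <- c(active[-pair], new_id)
  }
  root <- active[1]

  # tip descendant sets, children before parents (ids are time-ordered)
  desc <- vector("list", nxt - 1L)
  for (i in seq_len(n)) desc[[i]] <- i
  if (nxt - 1L > n) {
    for (i in (n + 1L):(nxt - 1L)) {
      desc[[i]] <- unlist(desc[children[[i]]], use.names = FALSE)
    }
  }
  list(n = n, n1 = n1, n2 = n2, root = root,
       node_time = node_time[seq_len(nxt - 1L)],
       parent = parent[seq_len(nxt - 1L)], desc = desc)
}

# Drop infinite-sites mutations on a genealogy. Returns a list of
# mutations, each with the site index and the tip set carrying the
# derived allele. `site_pool` supplies unused site indices.
drop_mutations <- function(gen, rate_per_time, site_pool) {
  nodes <- seq_along(gen$node_time)
  nodes <- nodes[nodes != gen$root]
  blen <- gen$node_time[gen$parent[nodes]] - gen$node_time[nodes]
  counts <- stats::rpois(length(nodes), blen * rate_per_time)
  total <- sum(counts)
  if (total == 0) return(list(muts = list(), pool = site_pool))
  if (total > length(site_pool)) {
    stop("mutation count ", total, " exceeds available sites; ",
         "theta or divergence too large for gene length")
  }
  sites <- site_pool[sample.int(length(site_pool), total)]
  muts <- vector("list", total)
  m <- 0L
  for (e in seq_along(nodes)) {
    if (counts[e] == 0) next
    for (r in seq_len(counts[e])) {
      m <- m + 1L
      muts[[m]] <- list(site = sites[m], carriers = gen$desc[[nodes[e]]])
    }
  }
  list(muts = muts, pool = setdiff(site_pool, sites))
}

# Relative landrace population size b realizing a target expected
# pairwise-coalescence multiplier m under the split model with a
# *uniform* landrace size on [0, t_split]:
# m(b) = b + (1 - b) * exp(-t_split / b), increasing in b on (0, 1 + t).
solve_relative_size <- function(m, t_split) {
  stopifnot(m > 0)
  if (m >= 1 + t_split) {
    stop("diversity multiplier ", m, " is unreachable through population ",
         "size under a split at t = ", t_split,
         " (bound ", 1 + t_split, "); use the balancing regime mechanism")
  }
  f <- function(b) b + (1 - b) * exp(-t_split / b) - m
  stats::uniroot(f, lower = 1e-8, upper = 1e8, tol = 1e-12)$root
}

# Expected pairwise coalescence time for a landrace pair under the
# bottleneck-with-recovery demography: recent size 1 on [0, t_b),
# founder size b_f on [t_b, t_split), ancestral size 1 afterwards.
bottleneck_pair_time <- function(b_f, t_b, t_split) {
  d <- t_split - t_b
  e1 <- exp(-t_b)
  e2 <- exp(-d / b_f)
  phase1 <- 1 - (1 + t_b) * e1
  phase2 <- t_b * (1 - e2) + b_f - (d + b_f) * e2
  phase1 + e1 * (phase2 + e2 * (t_split + 1))
}

# Founder-phase size b_f realizing a target multiplier m under the
# bottleneck-with-recovery demography (neutral/balancing landrace
# history: a founder squeeze followed by full recovery, which reduces
# diversity without the strong site-frequency distortion a permanent
# contraction would impose).
solve_founder_size <- function(m, t_b, t_split) {
  lo_m <- bottleneck_pair_time(1e-9, t_b, t_split)
  hi_m <- bottleneck_pair_time(1e9, t_b, t_split)
  if (m <= lo_m || m >= hi_m) {
    stop("bottleneck multiplier ", m, " outside the reachable range (",
         signif(lo_m, 3), ", ", signif(hi_m, 3), ") for t_bottleneck = ",
         t_b, ", t_split = ", t_split)
  }
  f <- function(b_f) bottleneck_pair_time(b_f, t_b, t_split) - m
  stats::uniroot(f, lower = 1e-9, upper = 1e9, tol = 1e-12)$root
}
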