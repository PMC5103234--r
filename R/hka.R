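# Multilocus HKA test as a maximum-likelihood fit with a likelihood-
# ratio test.
#
# Model (independent-Poisson composite likelihood, locus i):
#   S_i ~ Poisson(k_i * theta_i * L_i * a_{n_i})          polymorphism
#   D_i ~ Poisson(theta_i * L_i * (T + (n_i+1)/(2 n_i)))  divergence
# with a_n the harmonic number, T the divergence time in 2N units, and
# k_i a selection parameter scaling polymorphism only (k_i = 1 at
# neutral loci). The (n+1)/(2n) term is the within-sample coalescent
# correction to divergence; it can be switched off. Under the neutral
# model every k_i = 1; the selection model frees k_i on the selected
# set. Given T, the per-locus parameters maximize in closed form, so
# each model fit is a 1-D profile-likelihood optimization in T
# (log-grid multistart + golden-section refinement), deterministic.

#' Build an HKA dataset
#'
#' @param S segregating sites per locus (descendant sample)
#' @param D fixed differences to the outgroup per locus
#' @param L sites per locus
#' @param n sample sizes per locus
#' @param selected indices of loci allowed a free selection parameter
#' @param locus optional locus names
#' @return an \code{hka_dataset} list
#' @export
hka_dataset <- function(S, D, L, n, selected = integer(0), locus = NULL) {
  m <- length(S)
  stopifnot(length(D) == m, length(L) == m, length(n) == m,
            all(S >= 0), all(D >= 0), all(L > 0), all(n >= 2))
  selected <- sort(unique(as.integer(selected)))
  if (length(selected) && (min(selected) < 1 || max(selected) > m)) {
    stop("selected_set indices outside 1..", m)
  }
  structure(list(S = as.numeric(S), D = as.numeric(D), L = as.numeric(L),
                 n = as.integer(n), selected = selected,
                 locus = locus %||% paste0("locus", seq_len(m))),
            class = "hka_dataset")
}

hka_div_const <- function(n, divergence_correction = TRUE) {
  if (divergence_correction) (n + 1) / (2 * n) else rep(0, length(n))
}

#' HKA composite log-likelihood
#'
#' @param dataset an \code{hka_dataset}
#' @param theta per-locus theta (> 0)
#' @param T divergence time parameter (> 0)
#' @param k per-locus selection parameters (k = 1 off the selected set)
#' @param divergence_correction include the within-sample coalescent
#'   term in expected divergence (default TRUE)
#' @return log-likelihood
#' @export
hka_loglik <- function(dataset, theta, T, k = rep(1, length(dataset$S)),
                       divergence_correction = TRUE) {
  if (any(theta <= 0) || T <= 0 || any(k <= 0)) {
    stop("hka_loglik requires theta > 0, T > 0, k > 0")
  }
  a <- harmonic_number(dataset$n)
  cc <- hka_div_const(dataset$n, divergence_correction)
  mu_s <- k * theta * dataset$L * a
  mu_d <- theta * dataset$L * (T + cc)
  sum(stats::dpois(dataset$S, mu_s, log = TRUE)) +
    sum(stats::dpois(dataset$D, mu_d, log = TRUE))
}

# profile log-likelihood over T: per-locus parameters maximized in
# closed form. Selected loci saturate both observations (theta from D,
# k from S), so they contribute a T-free constant; neutral loci give
# theta_hat = (S + D) / (L (a + T + c)).
hka_profile <- function(dataset, T, free_k, divergence_correction = TRUE) {
  a <- harmonic_number(dataset$n)
  cc <- hka_div_const(dataset$n, divergence_correction)
  S <- dataset$S; D <- dataset$D; L <- dataset$L
  m <- length(S)
  theta <- numeric(m)
  k <- rep(1, m)
  ll <- 0
  pois <- function(x, mu) {
    # dpois with the mu -> 0 limit handled (0 observations only)
    ifelse(mu == 0, ifelse(x == 0, 0, -Inf), stats::dpois(x, mu, log = TRUE))
  }
  sel <- seq_len(m) %in% free_k
  # neutral loci
  theta[!sel] <- (S[!sel] + D[!sel]) / (L[!sel] * (a[!sel] + T + cc[!sel]))
  ll <- ll + sum(pois(S[!sel], theta[!sel] * L[!sel] * a[!sel])) +
    sum(pois(D[!sel], theta[!sel] * L[!sel] * (T + cc[!sel])))
  # selected loci: saturated fit
  if (any(sel)) {
    theta[sel] <- D[sel] / (L[sel] * (T + cc[sel]))
    k[sel] <- ifelse(theta[sel] > 0,
                     S[sel] / (theta[sel] * L[sel] * a[sel]), NA_real_)
    ll <- ll + sum(pois(S[sel], S[sel])) + sum(pois(D[sel], D[sel]))
  }
  list(loglik = ll, theta = theta, k = k, T = T)
}

#' Fit the HKA model by profile maximum likelihood
#'
#' @param dataset an \code{hka_dataset}
#' @param model "neutral" (all k = 1) or "selection" (free k on the
#'   selected set)
#' @param divergence_correction see \code{hka_loglik}
#' @return list with \code{loglik}, \code{T}, \code{theta}, \code{k}
#' @export
hka_fit <- function(dataset, model = c("neutral", "selection"),
                    divergence_correction = TRUE) {
  model <- match.arg(model)
  free_k <- if (model == "selection") dataset$selected else integer(0)
  if (length(free_k) == length(dataset$S)) {
    stop("at least one neutral locus is required to fit T")
  }
  obj <- function(logT) {
    hka_profile(dataset, exp(logT), free_k, divergence_correction)$loglik
  }
  grid <- seq(log(1e-4), log(1e4), length.out = 33)
  vals <- vapply(grid, obj, numeric(1))
  best <- which.max(vals)
  lo <- grid[max(1, best - 1)]
  hi <- grid[min(length(grid), best + 1)]
  opt <- stats::optimize(obj, c(lo, hi), maximum = TRUE,
                         tol = .Machine$double.eps^0.5)
  if (!is.finite(opt$objective)) {
    stop("HKA optimization failed to find a finite likelihood; ",
         "best grid value ", max(vals))
  }
  res <- hka_profile(dataset, exp(opt$maximum), free_k,
                     divergence_correction)
  res$model <- model
  res
}

#' Multilocus HKA likelihood-ratio test
#'
#' statistic = 2 (l_selection - l_neutral) >= 0 (the selection model
#' nests the neutral one); p from chi-squared with df = number of
#' selected loci. An empty selected set gives statistic exactly 0.
#'
#' @param dataset an \code{hka_dataset} with >= 2 loci and at least one
#'   neutral locus
#' @param divergence_correction see \code{hka_loglik}
#' @return list with \code{statistic}, \code{df}, \code{p_value} and the
#'   two fits
#' @export
hka_lrt <- function(dataset, divergence_correction = TRUE) {
  if (length(dataset$S) < 2) stop("hka_lrt needs at least 2 loci")
  fit0 <- hka_fit(dataset, "neutral", divergence_correction)
  if (!length(dataset$selected)) {
    return(list(statistic = 0, df = 0L, p_value = 1,
                neutral = fit0, selection = fit0))
  }
  fit1 <- hka_fit(dataset, "selection", divergence_correction)
  # the selection profile dominates the neutral profile pointwise in T;
  # evaluating it at the neutral optimum guarantees a non-negative LRT
  at0 <- hka_profile(dataset, fit0$T, dataset$selected,
                     divergence_correction)
  if (at0$loglik > fit1$loglik) fit1 <- c(at0, model = "selection")
  stat <- 2 * (fit1$loglik - fit0$loglik)
  df <- length(dataset$selected)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       neutral = fit0, selection = fit1)
}

#' Simulate HKA counts from the model
#'
#' Draws S and D from the independent-Poisson HKA model, for
#' calibration and power studies of \code{hka_lrt}.
#'
#' @param theta,T,k,L,n model parameters (recycled to a common length)
#' @param selected selected-set indices for the returned dataset
#' @param divergence_correction see \code{hka_loglik}
#' @return an \code{hka_dataset}
#' @export
hka_simulate <- function(theta, T, L, n, k = 1, selected = integer(0),
                         divergence_correction = TRUE) {
  m <- max(length(theta), length(L), length(n), length(k))
  theta <- rep_len(theta, m); L <- rep_len(L, m)
  n <- rep_len(n, m); k <- rep_len(k, m)
  a <- harmonic_number(n)
  cc <- hka_div_const(n, divergence_correction)
  S <- stats::rpois(m, k * theta * L * a)
  D <- stats::rpois(m, theta * L * (T + cc))
  hka_dataset(S, D, L, n, selected)
}

#' Build an HKA dataset from alignments and an outgroup
#'
#' S_i = segregating sites in the descendant (landrace) sample over
#' complete-deletion sites; D_i = sites at which the outgroup base
#' differs from every landrace base (fixed differences), over sites
#' complete in landrace + outgroup; L_i = those comparable sites.
#'
#' @param alignments named list of \code{hap_alignment} (outgroup row
#'   included)
#' @param partition a \code{population_partition}
#' @param genes gene ids to include (default: all)
#' @param selected gene ids forming the selected set
#' @return an \code{hka_dataset}
#' @export
hka_dataset_from_alignments <- function(alignments, partition,
                                        genes = names(alignments),
                                        selected = character(0)) {
  rows <- lapply(genes, function(gid) {
    aln <- alignments[[gid]]
    lr <- group_samples(aln, partition, "landrace")
    og <- group_samples(aln, partition, "outgroup")
    if (!length(og)) stop("no outgroup sample for gene ", gid)
    codes <- alignment_codes(aln)
    lrc <- codes[lr, , drop = FALSE]
    ogc <- codes[og[1], ]
    ok <- colSums(is.na(lrc)) == 0 & !is.na(ogc)
    s <- count_segregating(lrc, which(ok))
    fixed_diff <- sum(vapply(which(ok), function(j) {
      all(lrc[, j] != ogc[j])
    }, logical(1)))
    c(S = s, D = fixed_diff, L = sum(ok), n = length(lr))
  })
  m <- do.call(rbind, rows)
  hka_dataset(m[, "S"], m[, "D"], m[, "L"], m[, "n"],
              selected = match(selected, genes), locus = genes)
}
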