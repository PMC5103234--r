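#' Harmonic number a_n = sum_{i=1}^{n-1} 1/i
#'
#' The sample-size constant used by Watterson's estimator and the HKA
#' likelihood (expected number of segregating sites is theta * L * a_n).
#'
#' @param n number of sampled haplotypes (>= 1)
#' @return sum of 1/i for i in 1..(n-1); 0 for n = 1
#' @export
harmonic_number <- function(n) {
  stopifnot(is.numeric(n), n >= 1)
  vapply(n, function(k) if (k < 2) 0 else sum(1 / seq_len(k - 1)), numeric(1))
}

# second-order harmonic sum_{i=1}^{n-1} 1/i^2 (Tajima's a2)
harmonic_number2 <- function(n) {
  vapply(n, function(k) if (k < 2) 0 else sum(1 / seq_len(k - 1)^2), numeric(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed
#'
#' Deterministically maps a base seed and an index to a new seed below
#' 2^31, so that per-gene simulations are independent but reproducible.
#'
#' @param seed base integer seed
#' @param index positive integer stream index
#' @return integer seed
#' @export
sub_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 30269) %% 2147483587)
}

DNA_BASES4 <- c("A", "C", "G", "T")

is_missing_base <- function(x) x == "N" | x == "-"
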