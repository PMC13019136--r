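#' Randomized-response keep probability
#'
#' The local differential privacy mechanism keeps a ternary dosage value
#' with probability `p = exp(epsilon) / (exp(epsilon) + 2)` and otherwise
#' replaces it uniformly at random by one of the two alternative values.
#' This yields pure epsilon-DP (delta = 0): the likelihood ratio any output
#' induces between two input values is `p / ((1 - p)/2) = exp(epsilon)`.
#'
#' `epsilon = 0` is accepted and gives the uniform limit `p = 1/3`;
#' `epsilon = Inf` gives `p = 1` (no perturbation).
#'
#' @param epsilon Privacy budget, `>= 0` or `Inf`.
#' @return The keep probability in `[1/3, 1]`.
#' @examples
#' keep_probability(3)   # ~0.909
#' @export
keep_probability <- function(epsilon) {
  if (!is.numeric(epsilon) || length(epsilon) != 1 || is.na(epsilon) || epsilon < 0) {
    abort("epsilon must be a single number >= 0 (Inf allowed)")
  }
  if (is.infinite(epsilon)) return(1)
  exp(epsilon) / (exp(epsilon) + 2)
}

#' Randomized-response transition matrix
#'
#' The 3x3 row-stochastic matrix of the mechanism over dosage values
#' \{0, 1, 2\}: diagonal `p`, off-diagonal `(1 - p)/2`.
#'
#' @inheritParams keep_probability
#' @return 3x3 matrix with dimnames `c("0","1","2")`; rows are input values.
#' @export
ldp_transition_matrix <- function(epsilon) {
  p <- keep_probability(epsilon)
  T3 <- matrix((1 - p) / 2, 3, 3)
  diag(T3) <- p
  dimnames(T3) <- list(input = c("0", "1", "2"), output = c("0", "1", "2"))
  T3
}

#' Apply randomized response to a genotype table
#'
#' Each dosage entry is independently kept with probability
#' [keep_probability()] and otherwise replaced uniformly by one of the two
#' other ternary values.  This is the only operation in the site protocol
#' that reads unperturbed data; everything downstream (preprocessing, model
#' training, explanation) is post-processing of the private release.
#'
#' @param g Genotype tibble with entries in \{0, 1, 2\}.
#' @param epsilon Privacy budget (`Inf` returns the input unchanged).
#' @param seed Integer seed.
#' @return Genotype tibble of the same shape with ternary entries.
#' @export
perturb_genotypes <- function(g, epsilon, seed = 1) {
  validate_genotypes(g, ternary = TRUE)
  if (is.infinite(epsilon)) return(g)
  p <- keep_probability(epsilon)
  M <- geno_matrix(g)
  withr::with_seed(seed, {
    keep <- runif(length(M)) < p
    shift <- 1 + rbinom(length(M), 1L, 0.5)   # +1 or +2 mod 3: uniform over the two alternatives
    M[] <- ifelse(keep, M, (M + shift) %% 3)
  })
  genotype_tbl(M, sample_ids = g$sample_id, locus_ids = locus_ids(g))
}
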