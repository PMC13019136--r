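#' Specify a synthetic cohort
#'
#' Bundles the parameters of the synthetic-data generator.  The generator
#' emulates the cohort shapes used throughout the verification study: a
#' samples-by-loci dosage matrix with Hardy-Weinberg genotypes at
#' independently drawn allele frequencies, a binary phenotype from a
#' logistic model with a calibrated intercept, and optional injection of
#' duplicate records and distance outliers so that the duplicate-removal and
#' outlier-filtering preprocessing steps have real work to do.
#'
#' @param n_samples Number of individuals.
#' @param n_loci Number of biallelic loci.
#' @param maf_low,maf_high Bounds of the uniform distribution the per-locus
#'   allele frequency is drawn from.  The default `[0.05, 0.5]` keeps every
#'   generated locus comfortably above the conventional 0.01
#'   minor-allele-frequency cut; use `n_monomorphic` to add loci that the
#'   cut removes.
#' @param n_causal Number of loci with a phenotype effect.
#' @param effect_size Log-odds increase per alternate-allele dosage unit at
#'   each causal locus.
#' @param prevalence Target case fraction of the binary phenotype.
#' @param dup_fraction Fraction of duplicate records appended by
#'   [inject_duplicates()].
#' @param outlier_fraction Fraction of rows replaced by distance outliers by
#'   [inject_outliers()].
#' @param n_monomorphic Number of all-zero (monomorphic) loci appended after
#'   the polymorphic ones, for exercising [filter_maf()].
#' @param seed Integer seed; the generator is fully deterministic given the
#'   spec.
#' @return An object of class `cohort_spec`.
#' @examples
#' spec <- cohort_spec(n_samples = 100, n_loci = 20, seed = 1)
#' g <- sample_genotypes(spec)
#' y <- sample_phenotypes(g, spec)
#' @export
cohort_spec <- function(n_samples, n_loci,
                        maf_low = 0.05, maf_high = 0.5,
                        n_causal = 5, effect_size = 1,
                        prevalence = 0.3,
                        dup_fraction = 0.05, outlier_fraction = 0.02,
                        n_monomorphic = 0,
                        seed = 1) {
  spec <- list(
    n_samples = as.integer(n_samples), n_loci = as.integer(n_loci),
    maf_low = maf_low, maf_high = maf_high,
    n_causal = as.integer(min(n_causal, n_loci)),
    effect_size = effect_size, prevalence = prevalence,
    dup_fraction = dup_fraction, outlier_fraction = outlier_fraction,
    n_monomorphic = as.integer(n_monomorphic),
    seed = as.integer(seed)
  )
  if (spec$n_samples < 1 || spec$n_loci < 1) abort("n_samples and n_loci must be positive")
  if (!(maf_low >= 0 && maf_low <= maf_high && maf_high <= 0.5)) {
    abort("require 0 <= maf_low <= maf_high <= 0.5")
  }
  if (dup_fraction < 0 || dup_fraction >= 0.5 ||
      outlier_fraction < 0 || outlier_fraction >= 0.5) {
    abort("dup_fraction and outlier_fraction must be in [0, 0.5)")
  }
  structure(spec, class = "cohort_spec")
}

#' Sample Hardy-Weinberg genotype dosages
#'
#' Draws a per-locus allele frequency `f_j ~ Uniform(maf_low, maf_high)` and
#' dosages as the sum of two independent Bernoulli(`f_j`) allele draws, i.e.
#' Hardy-Weinberg genotype frequencies `(1-f)^2, 2f(1-f), f^2`.  Loci are
#' independent (no linkage disequilibrium).  The drawn allele frequencies
#' are attached as the `allele_freqs` attribute.
#'
#' @param spec A [cohort_spec()].
#' @return Genotype tibble of dimension `n_samples` x
#'   (`n_loci` + `n_monomorphic`).
#' @export
sample_genotypes <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  seeds <- split_seed(spec$seed, 2)
  n <- spec$n_samples
  m <- spec$n_loci
  withr::with_seed(seeds[1], {
    f <- runif(m, spec$maf_low, spec$maf_high)
    M <- vapply(seq_len(m), function(j) rbinom(n, 2L, f[j]), numeric(n))
    M <- matrix(M, nrow = n)
  })
  if (spec$n_monomorphic > 0) {
    M <- cbind(M, matrix(0, n, spec$n_monomorphic))
    f <- c(f, rep(0, spec$n_monomorphic))
  }
  g <- genotype_tbl(M)
  attr(g, "allele_freqs") <- setNames(f, locus_ids(g))
  g
}

# internal: bisection for the logistic intercept giving the target prevalence
calibrate_intercept <- function(eta, prevalence, tol = 1e-4) {
  lo <- -40; hi <- 40
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    p <- mean(plogis(mid + eta))
    if (abs(p - prevalence) <= tol) return(mid)
    if (p < prevalence) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Sample binary phenotypes from a logistic model
#'
#' Labels follow `logit P(y = 1) = alpha + effect_size * sum(g_j)` over
#' `n_causal` randomly chosen causal loci; the intercept `alpha` is
#' calibrated by bisection so that the expected case fraction matches
#' `prevalence`.  The chosen causal loci and intercept are attached as
#' attributes `causal_loci` and `intercept`.
#'
#' @param g Genotype tibble from [sample_genotypes()].
#' @param spec The same [cohort_spec()].
#' @return Phenotype tibble aligned to `g`.
#' @export
sample_phenotypes <- function(g, spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$prevalence <= 0 || spec$prevalence >= 1) {
    abort("prevalence must be strictly between 0 and 1")
  }
  seeds <- split_seed(spec$seed, 3)
  M <- geno_matrix(g)
  withr::with_seed(seeds[2], {
    causal <- sample(ncol(M), spec$n_causal)
    eta <- as.numeric(M[, causal, drop = FALSE] %*% rep(spec$effect_size, length(causal)))
    alpha <- calibrate_intercept(eta, spec$prevalence)
    y <- rbinom(nrow(M), 1L, plogis(alpha + eta))
  })
  out <- phenotype_tbl(y, sample_ids(g))
  attr(out, "causal_loci") <- locus_ids(g)[causal]
  attr(out, "intercept") <- alpha
  out
}

#' Append exact duplicate records
#'
#' Appends `ceiling(fraction * n)` exact copies of randomly chosen existing
#' rows (genotype and label) under fresh sample ids, creating work for the
#' duplicate-removal preprocessing step.
#'
#' @param g,y Aligned genotype and phenotype tibbles.
#' @param fraction Duplicate fraction in `[0, 0.5)`.
#' @param seed Integer seed.
#' @return List with elements `genotypes` and `phenotypes`.
#' @export
inject_duplicates <- function(g, y, fraction, seed = 1) {
  check_aligned(g, y)
  if (fraction < 0 || fraction >= 0.5) abort("fraction must be in [0, 0.5)")
  n <- nrow(g)
  n_dup <- ceiling(fraction * n)
  if (n_dup == 0) return(list(genotypes = g, phenotypes = y))
  src <- withr::with_seed(seed, sample(n, n_dup, replace = TRUE))
  dup_g <- g[src, ]
  dup_g$sample_id <- sprintf("%s_dup%03d", g$sample_id[src], seq_len(n_dup))
  dup_y <- y[src, ]
  dup_y$sample_id <- dup_g$sample_id
  list(genotypes = dplyr::bind_rows(g, dup_g),
       phenotypes = dplyr::bind_rows(y, dup_y))
}

#' Replace rows with Euclidean-distance outliers
#'
#' Replaces `ceiling(fraction * n)` randomly chosen rows by rows built from
#' the extreme dosages \{0, 2\}, constructed so that their Euclidean distance
#' to the pre-injection cohort mean exceeds the pre-injection maximum row
#' distance by at least `magnitude`.  Injected rows remain valid ternary
#' dosage vectors, and the guaranteed margin makes the downstream outlier
#' filter's behaviour deterministic and testable.
#'
#' @param g Genotype tibble.
#' @param fraction Outlier fraction in `[0, 0.5)`.
#' @param magnitude Required distance margin (> 0) beyond the most extreme
#'   original row.
#' @param seed Integer seed.
#' @return Genotype tibble with the same dimensions and sample ids.
#' @export
inject_outliers <- function(g, fraction, magnitude = 2, seed = 1) {
  if (fraction < 0 || fraction >= 0.5) abort("fraction must be in [0, 0.5)")
  if (magnitude <= 0) abort("magnitude must be positive")
  n_out <- ceiling(fraction * nrow(g))
  if (n_out == 0) return(g)
  M <- geno_matrix(g)
  mu <- colMeans(M)
  d <- sqrt(rowSums(sweep(M, 2, mu)^2))
  target_d <- max(d) + magnitude
  far <- ifelse(mu < 1, 2, 0)            # per-locus extreme farthest from the mean
  d_max_possible <- sqrt(sum(pmax(mu, 2 - mu)^2))
  if (d_max_possible < target_d) {
    abort("cannot construct outliers: required distance margin exceeds the dosage range")
  }
  withr::with_seed(seed, {
    rows <- sample(nrow(M), n_out)
    for (i in rows) {
      for (try in 1:25) {
        cand <- ifelse(runif(ncol(M)) < 0.9, far, 2 - far)
        if (sqrt(sum((cand - mu)^2)) >= target_d) break
        cand <- far
      }
      M[i, ] <- cand
    }
  })
  genotype_tbl(M, sample_ids = g$sample_id, locus_ids = locus_ids(g))
}

#' Filter loci by minor allele frequency
#'
#' Retains exactly the loci whose minor allele frequency, `min(f, 1 - f)`
#' with `f = mean(dosage) / 2`, strictly exceeds `threshold`.  Locus order
#' is preserved.
#'
#' @param g Genotype tibble with ternary dosages.
#' @param threshold MAF threshold in `[0, 0.5)`; the conventional cut is
#'   0.01.
#' @return Genotype tibble containing the retained loci.
#' @export
filter_maf <- function(g, threshold = 0.01) {
  if (threshold < 0 || threshold >= 0.5) abort("threshold must be in [0, 0.5)")
  M <- geno_matrix(g)
  f <- colMeans(M) / 2
  maf <- pmin(f, 1 - f)
  keep <- maf > threshold
  if (!any(keep)) abort("all loci removed by the MAF filter")
  g[, c("sample_id", locus_ids(g)[keep])]
}

#' Partition a cohort across sites
#'
#' Random, disjoint, exhaustive partition into `k` near-equal parts (sizes
#' differ by at most one).  All parts share the full locus set in identical
#' order; within each part the original row order is preserved.
#'
#' @param g,y Aligned genotype and phenotype tibbles.
#' @param k Number of sites (>= 2).
#' @param seed Integer seed.
#' @return List of `k` lists, each with elements `genotypes` and
#'   `phenotypes`.
#' @export
partition_sites <- function(g, y, k = 3, seed = 1) {
  check_aligned(g, y)
  n <- nrow(g)
  if (k < 2) abort("k must be at least 2")
  if (k > n) abort("more sites than samples")
  perm <- withr::with_seed(seed, sample(n))
  sizes <- rep(n %/% k, k) + c(rep(1, n %% k), rep(0, k - n %% k))
  idx <- split(perm, rep(seq_len(k), sizes))
  lapply(idx, function(i) {
    i <- sort(i)
    list(genotypes = g[i, ], phenotypes = y[i, ])
  })
}
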