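#' Enumerate the preprocessing fingerprint space
#'
#' Four optional preprocessing operations are monitored, always applied in
#' the fixed order duplicate removal -> outlier filtering -> z-score scaling
#' -> SMOTE resampling.  Including or excluding each yields `2^4 - 1 = 15`
#' valid fingerprints (the all-off combination is excluded).  The label of a
#' configuration is its binary encoding
#' `dedupe*8 + outlier*4 + scale*2 + resample*1`, so labels run 1..15 and the
#' resample-only configuration has label 1.
#'
#' @return Tibble with columns `label`, `dedupe`, `outlier`, `scale`,
#'   `resample`; one row per configuration, in increasing label order.
#' @examples
#' enumerate_configs()
#' @export
enumerate_configs <- function() {
  label <- 1:15
  tibble(
    label = label,
    dedupe = bitwAnd(label, 8L) > 0,
    outlier = bitwAnd(label, 4L) > 0,
    scale = bitwAnd(label, 2L) > 0,
    resample = bitwAnd(label, 1L) > 0
  )
}

#' Build a preprocessing configuration
#'
#' @param dedupe,outlier,scale,resample Logical flags for the four optional
#'   operations.  At least one must be set.
#' @return One-row tibble as in [enumerate_configs()].
#' @export
preproc_config <- function(dedupe = FALSE, outlier = FALSE,
                           scale = FALSE, resample = FALSE) {
  label <- dedupe * 8L + outlier * 4L + scale * 2L + resample * 1L
  if (label == 0) abort("at least one preprocessing flag must be set")
  tibble(label = as.integer(label), dedupe = dedupe, outlier = outlier,
         scale = scale, resample = resample)
}

# internal: accept a label (1..15) or a one-row config tibble
resolve_config <- function(config) {
  if (is.numeric(config) && length(config) == 1) {
    if (!(config %in% 1:15)) abort("config label must be in 1..15")
    return(enumerate_configs()[config, ])
  }
  if (is.data.frame(config) && nrow(config) == 1 &&
      all(c("dedupe", "outlier", "scale", "resample") %in% names(config))) {
    cfg <- preproc_config(config$dedupe, config$outlier, config$scale, config$resample)
    return(cfg)
  }
  abort("config must be a label in 1..15 or a one-row configuration tibble")
}

#' Remove duplicate genotype records
#'
#' Keeps the first occurrence of each distinct genotype row (labels are
#' ignored when deciding identity, matching "repeated genotype records");
#' the phenotype table is filtered to the kept rows.  Idempotent.
#'
#' @param g,y Aligned genotype and phenotype tibbles.
#' @return List with elements `genotypes` and `phenotypes`.
#' @export
remove_duplicates <- function(g, y) {
  check_aligned(g, y)
  keep <- !duplicated(geno_matrix(g))
  list(genotypes = g[keep, ], phenotypes = y[keep, ])
}

#' Filter Euclidean-distance outliers
#'
#' Computes each row's Euclidean distance `d_i` to the column-mean vector
#' and removes rows with `d_i > mean(d) + k_sigma * sd(d)`.  With the
#' default `k_sigma = 3` this is a scale-free three-sigma rule on the
#' distance distribution.  If every distance is identical (`sd(d) = 0`)
#' nothing is removed; the filter refuses to empty the cohort.
#'
#' @param g,y Aligned genotype and phenotype tibbles (`n >= 3`).
#' @param k_sigma Threshold multiplier; `Inf` disables the filter.
#' @return List with elements `genotypes` and `phenotypes`.
#' @export
filter_outliers <- function(g, y, k_sigma = 3) {
  check_aligned(g, y)
  if (nrow(g) < 3) abort("outlier filtering needs at least 3 samples")
  M <- geno_matrix(g)
  d <- sqrt(rowSums(sweep(M, 2, colMeans(M))^2))
  s <- sd(d)
  keep <- if (!is.finite(k_sigma) || s == 0) rep(TRUE, nrow(M)) else d <= mean(d) + k_sigma * s
  if (!any(keep)) abort("outlier filtering would remove every sample")
  list(genotypes = g[keep, ], phenotypes = y[keep, ])
}

#' Z-score scale each locus
#'
#' Standardizes every locus column to mean 0 and population standard
#' deviation 1.  Zero-variance columns are mapped to all-zeros so that the
#' feature dimension (and hence the explanation-vector dimension) is
#' preserved.
#'
#' @param g Genotype tibble (`n >= 2`).
#' @return Genotype tibble with real-valued entries.
#' @export
scale_features <- function(g) {
  if (nrow(g) < 2) abort("scaling needs at least 2 samples")
  M <- geno_matrix(g)
  mu <- colMeans(M)
  sdp <- sqrt(colMeans(sweep(M, 2, mu)^2))   # population sd
  Z <- sweep(M, 2, mu)
  Z <- sweep(Z, 2, ifelse(sdp == 0, 1, sdp), "/")
  Z[, sdp == 0] <- 0
  genotype_tbl(Z, sample_ids = g$sample_id, locus_ids = locus_ids(g))
}

#' Balance classes with SMOTE
#'
#' Synthetic Minority Over-sampling: until class counts are equal, pick a
#' random minority sample `x`, find its nearest minority neighbour `x_nn`
#' in Euclidean distance (ties broken by lowest row index; `k_neighbors = 1`
#' uses the single nearest neighbour), draw one `lambda ~ Uniform(0, 1)` per
#' synthetic row, and append `x + lambda * (x_nn - x)` with a generated
#' sample id and the minority label.
#'
#' @param g,y Aligned genotype and phenotype tibbles; the minority class
#'   must have at least `k_neighbors + 1` samples.
#' @param k_neighbors Number of nearest minority neighbours to draw the
#'   interpolation partner from (default 1).
#' @param seed Integer seed.
#' @return List with elements `genotypes` and `phenotypes`, class-balanced.
#' @export
resample_smote <- function(g, y, k_neighbors = 1, seed = 1) {
  check_aligned(g, y)
  counts <- table(factor(y$label, levels = c(0, 1)))
  if (counts[1] == counts[2]) return(list(genotypes = g, phenotypes = y))
  minority <- as.integer(names(which.min(counts)))
  n_syn <- as.integer(abs(counts[1] - counts[2]))
  min_idx <- which(y$label == minority)
  if (length(min_idx) < k_neighbors + 1) {
    abort(sprintf("SMOTE with k_neighbors = %d needs at least %d minority samples",
                  k_neighbors, k_neighbors + 1))
  }
  M <- geno_matrix(g)
  Mmin <- M[min_idx, , drop = FALSE]
  D <- as.matrix(dist(Mmin))
  diag(D) <- Inf
  syn <- withr::with_seed(seed, {
    t(vapply(seq_len(n_syn), function(s) {
      i <- sample(length(min_idx), 1)
      nn_pool <- order(D[i, ])[seq_len(k_neighbors)]   # order() breaks ties by lowest index
      j <- if (k_neighbors == 1) nn_pool else nn_pool[sample(k_neighbors, 1)]
      lambda <- runif(1)
      Mmin[i, ] + lambda * (Mmin[j, ] - Mmin[i, ])
    }, numeric(ncol(M))))
  })
  syn_ids <- sprintf("syn_%05d", seq_len(n_syn))
  g_syn <- genotype_tbl(syn, sample_ids = syn_ids, locus_ids = locus_ids(g))
  list(genotypes = dplyr::bind_rows(g, g_syn),
       phenotypes = dplyr::bind_rows(y, phenotype_tbl(rep(minority, n_syn), syn_ids)))
}

#' Mode-impute missing dosages
#'
#' Replaces `NA` entries by the per-locus mode of the observed values (ties
#' broken toward the smaller dosage).  Part of the mandatory preprocessing
#' every site applies; generator output is complete, so this only matters
#' for imported data with missing genotypes.
#'
#' @param g Genotype tibble, possibly with `NA` entries.
#' @return Complete genotype tibble.
#' @export
impute_mode <- function(g) {
  M <- geno_matrix(g)
  if (!anyNA(M)) return(g)
  for (j in seq_len(ncol(M))) {
    nas <- is.na(M[, j])
    if (any(nas)) {
      obs <- M[!nas, j]
      if (!length(obs)) abort(sprintf("locus '%s' has no observed genotypes", colnames(M)[j]))
      tab <- table(obs)
      M[nas, j] <- as.numeric(names(tab)[which.max(tab)])  # which.max: first = smallest value
    }
  }
  genotype_tbl(M, sample_ids = g$sample_id, locus_ids = locus_ids(g))
}

#' Apply a preprocessing pipeline
#'
#' Runs the enabled operations in the fixed order
#' dedupe -> outlier -> scale -> resample; disabled operations are skipped.
#' Mandatory mode imputation runs first whenever missing values are present.
#' A row-count ledger records each step's input and output sizes.
#'
#' @param g,y Aligned genotype and phenotype tibbles.
#' @param config A label in 1..15 or a one-row tibble from
#'   [preproc_config()] / [enumerate_configs()].
#' @param seed Integer seed (consumed by SMOTE).
#' @param k_sigma Outlier-filter threshold multiplier.
#' @param k_neighbors SMOTE neighbour count.
#' @return List with elements `genotypes`, `phenotypes`, `config`, and
#'   `ledger` (tibble with columns `step`, `enabled`, `n_in`, `n_out`).
#' @export
apply_pipeline <- function(g, y, config, seed = 1, k_sigma = 3, k_neighbors = 1) {
  check_aligned(g, y)
  cfg <- resolve_config(config)
  g <- impute_mode(g)
  ledger <- list()
  note <- function(step, enabled, n_in, n_out) {
    tibble(step = step, enabled = enabled, n_in = n_in, n_out = n_out)
  }
  n0 <- nrow(g)
  if (cfg$dedupe) {
    res <- remove_duplicates(g, y); g <- res$genotypes; y <- res$phenotypes
  }
  ledger[[1]] <- note("dedupe", cfg$dedupe, n0, nrow(g))
  n1 <- nrow(g)
  if (cfg$outlier) {
    res <- filter_outliers(g, y, k_sigma = k_sigma); g <- res$genotypes; y <- res$phenotypes
  }
  ledger[[2]] <- note("outlier", cfg$outlier, n1, nrow(g))
  n2 <- nrow(g)
  if (cfg$scale) g <- scale_features(g)
  ledger[[3]] <- note("scale", cfg$scale, n2, nrow(g))
  n3 <- nrow(g)
  if (cfg$resample) {
    res <- resample_smote(g, y, k_neighbors = k_neighbors, seed = seed)
    g <- res$genotypes; y <- res$phenotypes
  }
  ledger[[4]] <- note("resample", cfg$resample, n3, nrow(g))
  list(genotypes = g, phenotypes = y, config = cfg, ledger = dplyr::bind_rows(ledger))
}
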