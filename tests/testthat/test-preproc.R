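test_that("the fingerprint space has exactly 15 distinct configurations", {
  cfgs <- enumerate_configs()
  expect_equal(nrow(cfgs), 15)
  flags <- cfgs[, c("dedupe", "outlier", "scale", "resample")]
  expect_equal(nrow(dplyr::distinct(flags)), 15)
  expect_false(any(rowSums(as.matrix(flags)) == 0))
  # binary encoding: resample-only is label 1, dedupe-only is label 8
  expect_equal(cfgs$label[cfgs$resample & !cfgs$dedupe & !cfgs$outlier & !cfgs$scale], 1L)
  expect_equal(cfgs$label[cfgs$dedupe & !cfgs$outlier & !cfgs$scale & !cfgs$resample], 8L)
  expect_error(preproc_config(), "at least one")
})

test_that("duplicate removal restores injected cohorts and is idempotent", {
  messy <- make_messy_cohort(n = 100, m = 30, seed = 5, dup_fraction = 0.1,
                             outlier_fraction = 0)
  out <- remove_duplicates(messy$genotypes, messy$phenotypes)
  expect_equal(nrow(out$genotypes), 100)
  again <- remove_duplicates(out$genotypes, out$phenotypes)
  expect_identical(again$genotypes, out$genotypes)

  co <- make_cohort(n = 50, m = 30, seed = 6)
  none <- remove_duplicates(co$genotypes, co$phenotypes)
  expect_identical(none$genotypes, co$genotypes)
})

test_that("outlier filter removes exactly the constructed outliers", {
  co <- make_cohort(n = 120, m = 30, seed = 7, maf_high = 0.2)
  g2 <- inject_outliers(co$genotypes, 1 / 120, magnitude = 3, seed = 8)
  out <- filter_outliers(g2, co$phenotypes, k_sigma = 3)
  changed <- co$genotypes$sample_id[rowSums(geno_matrix(g2) !=
                                            geno_matrix(co$genotypes)) > 0]
  expect_length(changed, 1)
  expect_false(changed %in% out$genotypes$sample_id)
  expect_equal(nrow(out$genotypes), 119)

  # all rows identical: sd(d) = 0, nothing removed
  gid <- genotype_tbl(matrix(1, 5, 4))
  yid <- phenotype_tbl(c(1, 0, 0, 1, 0), gid$sample_id)
  expect_equal(nrow(filter_outliers(gid, yid)$genotypes), 5)

  # k_sigma = Inf disables the filter
  expect_equal(nrow(filter_outliers(g2, co$phenotypes, k_sigma = Inf)$genotypes), 120)
})

test_that("z-score scaling gives population-sd columns and zeroes constants", {
  g <- genotype_tbl(cbind(a = c(0, 1, 2), b = c(1, 1, 1)))
  s <- scale_features(g)
  expect_equal(unname(geno_matrix(s)[, "a"]),
               c(-sqrt(3 / 2), 0, sqrt(3 / 2)), tolerance = 1e-12)
  expect_equal(unname(geno_matrix(s)[, "b"]), c(0, 0, 0))

  co <- make_cohort(n = 80, m = 20, seed = 9)
  S <- geno_matrix(scale_features(co$genotypes))
  expect_true(all(abs(colMeans(S)) < 1e-9))
  sds <- sqrt(colMeans(sweep(S, 2, colMeans(S))^2))
  expect_true(all(abs(sds - 1) < 1e-9))
})

test_that("SMOTE equalizes classes with on-segment synthetic rows", {
  co <- make_cohort(n = 100, m = 20, seed = 10, prevalence = 0.1)
  n1 <- sum(co$phenotypes$label)
  out <- resample_smote(co$genotypes, co$phenotypes, seed = 4)
  tab <- table(out$phenotypes$label)
  expect_equal(unname(tab["0"]), unname(tab["1"]))

  # synthetic coordinates lie between the two parents coordinate-wise
  M <- geno_matrix(co$genotypes)
  minority <- M[co$phenotypes$label == 1, , drop = FALSE]
  syn <- geno_matrix(out$genotypes)[-seq_len(100), , drop = FALSE]
  lo <- apply(minority, 2, min); hi <- apply(minority, 2, max)
  expect_true(all(sweep(syn, 2, lo, ">=") & sweep(syn, 2, hi, "<=")))

  # already balanced input is returned unchanged
  gb <- genotype_tbl(matrix(rep(0:2, 20), 10, 6))
  yb <- phenotype_tbl(rep(c(0, 1), 5), gb$sample_id)
  expect_identical(resample_smote(gb, yb, seed = 1)$genotypes, gb)

  y1 <- phenotype_tbl(c(1, rep(0, 9)), gb$sample_id)
  expect_error(resample_smote(gb, y1, seed = 1), "minority")
})

test_that("pipeline applies enabled steps in the fixed order with a row ledger", {
  messy <- make_messy_cohort(n = 150, m = 30, seed = 12, dup_fraction = 0.1,
                             outlier_fraction = 0.04)
  res <- apply_pipeline(messy$genotypes, messy$phenotypes,
                        preproc_config(dedupe = TRUE, outlier = TRUE,
                                       scale = TRUE, resample = TRUE),
                        seed = 3)
  led <- res$ledger
  expect_equal(led$step, c("dedupe", "outlier", "scale", "resample"))
  expect_equal(led$n_in[-1], led$n_out[-4])
  expect_equal(led$n_out[4], nrow(res$genotypes))
  expect_lte(led$n_out[1], led$n_in[1])           # dedupe removes
  expect_equal(led$n_out[3], led$n_in[3])         # scale preserves rows
  expect_gte(led$n_out[4], led$n_in[4])           # resample appends
  expect_equal(sum(res$phenotypes$label == 0), sum(res$phenotypes$label == 1))

  # dedupe-only config is exactly remove_duplicates
  one <- apply_pipeline(messy$genotypes, messy$phenotypes, 8, seed = 3)
  expect_identical(one$genotypes,
                   remove_duplicates(messy$genotypes, messy$phenotypes)$genotypes)

  expect_error(apply_pipeline(messy$genotypes, messy$phenotypes, 0), "1..15")
})

test_that("the fixed dedupe-before-outlier order matters on constructed data", {
  # a duplicated outlier row: dedupe->outlier removes both copies' influence
  # differently from outlier->dedupe
  co <- make_cohort(n = 60, m = 30, seed = 13, maf_high = 0.2)
  g2 <- inject_outliers(co$genotypes, 1 / 60, magnitude = 3, seed = 14)
  out_row <- which(rowSums(geno_matrix(g2) != geno_matrix(co$genotypes)) > 0)
  dup <- g2[c(seq_len(60), rep(out_row, 8)), ]
  dup$sample_id <- sprintf("r%03d", seq_len(nrow(dup)))
  yd <- phenotype_tbl(c(co$phenotypes$label, rep(0, 8)), dup$sample_id)

  fixed <- filter_outliers(remove_duplicates(dup, yd)$genotypes,
                           remove_duplicates(dup, yd)$phenotypes)$genotypes
  swapped_step1 <- filter_outliers(dup, yd)
  swapped <- remove_duplicates(swapped_step1$genotypes,
                               swapped_step1$phenotypes)$genotypes
  expect_false(identical(dim(fixed), dim(swapped)) &&
               identical(geno_matrix(fixed), geno_matrix(swapped)))
})

test_that("all 15 pipelines run on a default messy cohort", {
  messy <- make_messy_cohort(n = 120, m = 25, seed = 15)
  for (label in 1:15) {
    res <- apply_pipeline(messy$genotypes, messy$phenotypes, label, seed = label)
    expect_gt(nrow(res$genotypes), 0)
    expect_identical(res$genotypes$sample_id, res$phenotypes$sample_id)
  }
})

test_that("missing dosages are mode-imputed per locus before the pipeline", {
  g <- genotype_tbl(cbind(a = c(0, 0, 1, NA), b = c(2, NA, 2, 1)))
  imp <- impute_mode(g)
  expect_equal(unname(geno_matrix(imp)[4, "a"]), 0)   # mode of (0,0,1)
  expect_equal(unname(geno_matrix(imp)[2, "b"]), 2)   # mode of (2,2,1)
  y <- phenotype_tbl(c(0, 1, 0, 1), g$sample_id)
  res <- apply_pipeline(g, y, preproc_config(scale = TRUE), seed = 1)
  expect_false(anyNA(geno_matrix(res$genotypes)))
})
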