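# a small messy cohort shared by the protocol tests
proto_cohort <- local({
  co <- make_cohort(n = 240, m = 20, seed = 51, prevalence = 0.3)
  inj <- inject_duplicates(co$genotypes, co$phenotypes, 0.05, seed = 52)
  list(genotypes = inj$genotypes, phenotypes = inj$phenotypes)
})

small_site <- function(config = 3, epsilon = 3, seed = 61, id = "siteA") {
  run_site(proto_cohort$genotypes, proto_cohort$phenotypes, config,
           epsilon = epsilon, seed = seed, site_id = id,
           n_trees = 40, n_instances = 6, n_samples = 150)
}

test_that("the site protocol emits a structurally valid artifact", {
  a <- small_site()
  expect_s3_class(a, "site_artifact")
  expect_true(all(geno_matrix(a$genotypes) %in% c(0, 1, 2)))
  expect_length(a$explanation$coefficients, 20)
  expect_true(all(is.finite(a$explanation$coefficients)))
  expect_identical(a$locus_ids, locus_ids(a$genotypes))
  expect_identical(names(a$explanation$coefficients), a$locus_ids)
  # no raw data, config, or model in the artifact
  expect_null(a$config)
  expect_null(a$model)
})

test_that("at epsilon = Inf with a no-op pipeline the release equals the input", {
  co <- make_cohort(n = 60, m = 15, seed = 53)   # no injected duplicates
  a <- run_site(co$genotypes, co$phenotypes, preproc_config(dedupe = TRUE),
                epsilon = Inf, seed = 1, n_trees = 30, n_instances = 4,
                n_samples = 100)
  expect_identical(geno_matrix(a$genotypes), geno_matrix(co$genotypes))
})

test_that("alignment validation reports mismatches and bad cells precisely", {
  a1 <- small_site(id = "s1", seed = 71)
  a2 <- small_site(id = "s2", seed = 72)
  expect_true(validate_alignment(list(a1, a2))$ok)

  swapped <- a2
  ids <- swapped$locus_ids
  ids[c(3, 4)] <- ids[c(4, 3)]
  swapped$locus_ids <- ids
  chk <- validate_alignment(list(a1, swapped))
  expect_false(chk$ok)
  expect_match(chk$detail, "position 3")

  bad <- a2
  M <- geno_matrix(bad$genotypes)
  M[2, 5] <- 3
  bad$genotypes <- genotype_tbl(M, sample_ids = rownames(M),
                                locus_ids = colnames(M))
  chk2 <- validate_alignment(list(a1, bad))
  expect_false(chk2$ok)
  expect_match(chk2$detail, "non-ternary value 3")
  expect_error(build_reference(list(a1, bad)), "alignment")
})

test_that("reference concatenation preserves rows and uniquifies sample ids", {
  arts <- lapply(1:3, function(i) small_site(id = paste0("site", i), seed = 80 + i))
  ref <- build_reference(arts)
  expect_equal(nrow(ref$genotypes), 3 * nrow(proto_cohort$genotypes))
  expect_equal(anyDuplicated(ref$genotypes$sample_id), 0L)
  expect_true(all(grepl("^site[123]:", ref$genotypes$sample_id)))
  expect_identical(ref$genotypes$sample_id, ref$phenotypes$sample_id)

  one <- build_reference(arts[1])
  expect_equal(geno_matrix(one$genotypes),
               geno_matrix(arts[[1]]$genotypes), ignore_attr = "dimnames")
})

test_that("reference simulation produces one labelled vector per config and replicate", {
  lib <- simulate_references(proto_cohort$genotypes, proto_cohort$phenotypes,
                             n_replicates = 1, seed = 90, subsample = 150,
                             n_trees = 30, n_instances = 4, n_samples = 120)
  expect_s3_class(lib, "reference_library")
  expect_equal(nrow(lib), 15)
  expect_setequal(lib$label, 1:15)
  expect_true(all(vapply(lib$coefficients, length, integer(1)) == 20))
})

test_that("the verifier validates cluster counts and produces usable maps", {
  lib <- simulate_references(proto_cohort$genotypes, proto_cohort$phenotypes,
                             n_replicates = 3, seed = 91, subsample = 150,
                             n_trees = 30, n_instances = 4, n_samples = 120)
  expect_error(train_verifier(lib, n_clusters = 7), "15, 5, 4, 3, 2")

  v15 <- train_verifier(lib, n_clusters = 15, seed = 2)
  expect_equal(v15$cluster_map$cluster, 1:15)

  v2 <- train_verifier(lib, n_clusters = 2, seed = 2)
  expect_equal(sort(unique(v2$cluster_map$cluster)), 1:2)
  expect_true(all(table(v2$cluster_map$cluster) >= 1))

  # resubstitution sanity: training predictions at least as good as chance
  X <- do.call(rbind, lib$coefficients)
  expect_gt(mean(predict(v15, X) == lib$label), 1 / 15)
})

test_that("the verdict rule is exactly the cluster-equality predicate", {
  cm15 <- tibble::tibble(label = 1:15, cluster = 1:15)
  set.seed(99)
  for (i in 1:50) {
    labels <- sample(15, sample(2:5, 1), replace = TRUE)
    v <- prepverify:::verdict_from_labels(labels, cm15)
    expect_equal(v$verdict == "COMPATIBLE", length(unique(labels)) == 1)
  }
  # coarse map: distinct labels in one cluster are compatible
  cm2 <- tibble::tibble(label = 1:15, cluster = rep(c(1, 2), c(8, 7)))
  for (i in 1:50) {
    labels <- sample(15, 3, replace = TRUE)
    v <- prepverify:::verdict_from_labels(labels, cm2)
    expect_equal(v$verdict == "COMPATIBLE",
                 length(unique(cm2$cluster[labels])) == 1)
  }
})

test_that("verification reports carry flags and differ-summaries", {
  lib <- simulate_references(proto_cohort$genotypes, proto_cohort$phenotypes,
                             n_replicates = 3, seed = 92, subsample = 150,
                             n_trees = 30, n_instances = 4, n_samples = 120)
  v <- train_verifier(lib, n_clusters = 15, seed = 3)
  a1 <- small_site(id = "s1", seed = 95)
  rep1 <- verify_sites(list(a1), v)
  expect_equal(rep1$verdict, "COMPATIBLE")      # single artifact, trivially
  expect_equal(nrow(rep1$per_site), 1)

  rep2 <- verify_sites(list(a1, small_site(id = "s2", seed = 96)), v)
  expect_true(rep2$verdict %in% c("COMPATIBLE", "INCOMPATIBLE"))
  expect_equal(names(rep2$differing_flags),
               c("dedupe", "outlier", "scale", "resample"))
  if (rep2$verdict == "INCOMPATIBLE" && rep2$n_clusters == 15) {
    labs <- rep2$per_site$label
    ec <- enumerate_configs()
    for (op in names(rep2$differing_flags)) {
      expect_equal(rep2$differing_flags[[op]],
                   length(unique(ec[[op]][labs])) > 1)
    }
  }
  expect_s3_class(glance(rep2), "tbl_df")
})

test_that("federated trials score verdicts against scenario ground truth", {
  co <- make_cohort(n = 360, m = 15, seed = 55)
  tr <- run_federated_experiment(co$genotypes, co$phenotypes, epsilon = Inf,
                                 scenario = "one-differs", seed = 7, k = 3,
                                 n_replicates = 2, subsample = 100,
                                 n_trees = 30, n_instances = 4,
                                 n_samples = 120, verifier_trees = 150)
  expect_equal(tr$truth, "INCOMPATIBLE")
  expect_equal(length(unique(tr$configs)), 2)
  expect_equal(tr$correct, tr$verdict == tr$truth)

  tr2 <- run_federated_experiment(co$genotypes, co$phenotypes, epsilon = Inf,
                                  scenario = "all-same", seed = 8, k = 3,
                                  n_replicates = 2, subsample = 100,
                                  n_trees = 30, n_instances = 4,
                                  n_samples = 120, verifier_trees = 150)
  expect_equal(tr2$truth, "COMPATIBLE")
  expect_equal(length(unique(tr2$configs)), 1)
})
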