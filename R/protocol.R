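#' Execute the site-side protocol
#'
#' Runs the full site pipeline in the protocol's fixed order: LDP
#' perturbation of the raw dosage matrix, the site's preprocessing pipeline
#' on the perturbed data, random-forest training, and extraction of the
#' aggregated explanation vector.  The returned artifact contains only what
#' the site uploads: the perturbed (pre-preprocessing) matrix, the phenotype
#' vector, the explanation vector, and metadata — never raw genotypes, the
#' preprocessing configuration, or model parameters.
#'
#' @param g,y Aligned raw genotype (ternary) and phenotype tibbles.
#' @param config Preprocessing configuration (label 1..15 or one-row
#'   tibble).
#' @param epsilon Privacy budget for the randomized response.
#' @param seed Integer seed; split internally across the four stages.
#' @param site_id Identifier carried in the artifact.
#' @param n_trees,n_instances,n_samples,kernel_width,k_sigma Settings passed
#'   through to [train_classifier()], [site_explanation_vector()] and
#'   [apply_pipeline()].
#' @return An object of class `site_artifact`.
#' @export
run_site <- function(g, y, config, epsilon, seed = 1, site_id = "site1",
                     n_trees = 100, n_instances = 50, n_samples = 1000,
                     kernel_width = NULL, k_sigma = 3) {
  check_aligned(g, y)
  cfg <- resolve_config(config)
  seeds <- split_seed(seed, 4)
  g_ldp <- perturb_genotypes(g, epsilon, seed = seeds[1])
  pp <- apply_pipeline(g_ldp, y, cfg, seed = seeds[2], k_sigma = k_sigma)
  model <- train_classifier(pp$genotypes, pp$phenotypes,
                            n_trees = n_trees, seed = seeds[3])
  ev <- site_explanation_vector(model, pp$genotypes,
                                n_instances = n_instances,
                                n_samples = n_samples,
                                kernel_width = kernel_width, seed = seeds[4])
  structure(list(
    site_id = site_id,
    genotypes = g_ldp,          # the perturbed, pre-preprocessing release
    phenotypes = y,
    explanation = ev,
    epsilon = epsilon,
    locus_ids = locus_ids(g_ldp)
  ), class = "site_artifact")
}

#' @export
print.site_artifact <- function(x, ...) {
  cat(sprintf("<site_artifact> %s: %d samples x %d loci, epsilon = %s\n",
              x$site_id, nrow(x$genotypes), length(x$locus_ids),
              format(x$epsilon)))
  invisible(x)
}

#' Check allele coding and locus ordering across artifacts
#'
#' Server-side stage-2 check: all artifacts must share identical ordered
#' locus id lists and every matrix entry must be a valid ternary dosage.
#' Failures are reported as results (with the first mismatching locus
#' position or cell named), not exceptions.
#'
#' @param artifacts List of `site_artifact` objects.
#' @return List of class `alignment_check` with fields `ok` (logical) and
#'   `detail` (character).
#' @export
validate_alignment <- function(artifacts) {
  stopifnot(length(artifacts) >= 1)
  ref <- artifacts[[1]]$locus_ids
  for (a in artifacts[-1]) {
    ids <- a$locus_ids
    if (!identical(ids, ref)) {
      pos <- which(ids != ref | is.na(ids != ref))[1]
      if (is.na(pos)) pos <- min(length(ids), length(ref)) + 1
      return(structure(list(ok = FALSE, detail = sprintf(
        "site '%s': locus mismatch at position %d ('%s' vs '%s')",
        a$site_id, pos,
        if (pos <= length(ids)) ids[pos] else "<absent>",
        if (pos <= length(ref)) ref[pos] else "<absent>")),
        class = "alignment_check"))
    }
  }
  for (a in artifacts) {
    M <- geno_matrix(a$genotypes)
    bad <- which(!(M %in% c(0, 1, 2)))
    if (length(bad)) {
      idx <- arrayInd(bad[1], dim(M))
      return(structure(list(ok = FALSE, detail = sprintf(
        "site '%s': non-ternary value %g at sample '%s', locus '%s'",
        a$site_id, M[bad[1]], rownames(M)[idx[1]], colnames(M)[idx[2]])),
        class = "alignment_check"))
    }
  }
  structure(list(ok = TRUE, detail = "aligned"), class = "alignment_check")
}

#' Concatenate site uploads into the server reference dataset
#'
#' Row-wise concatenation of the perturbed matrices and phenotype vectors in
#' site order, with sample ids uniquified by a site prefix.  Alignment is
#' (re-)validated first.
#'
#' @param artifacts List of `site_artifact` objects.
#' @return List with elements `genotypes` and `phenotypes`.
#' @export
build_reference <- function(artifacts) {
  chk <- validate_alignment(artifacts)
  if (!chk$ok) abort(paste0("alignment check failed: ", chk$detail))
  gs <- lapply(artifacts, function(a) {
    g <- a$genotypes
    g$sample_id <- paste0(a$site_id, ":", g$sample_id)
    g
  })
  ys <- lapply(artifacts, function(a) {
    y <- a$phenotypes
    y$sample_id <- paste0(a$site_id, ":", y$sample_id)
    y
  })
  list(genotypes = dplyr::bind_rows(gs), phenotypes = dplyr::bind_rows(ys))
}

#' Simulate reference explanation vectors for all 15 configurations
#'
#' For each of the 15 preprocessing fingerprints and each of `n_replicates`
#' replicates, bootstrap-resamples the reference rows (with replacement, so
#' duplicate records exist for the dedupe step to act on), applies the
#' configuration's pipeline, trains a classifier, and extracts the
#' aggregated explanation vector.  The labelled vectors are the training
#' corpus of the verification classifier.
#'
#' @param g,y Reference genotype/phenotype tibbles from [build_reference()];
#'   both classes must be present.
#' @param n_replicates Replicates per configuration (default 20).
#' @param seed Integer seed.
#' @param subsample Rows per bootstrap replicate (default: `nrow(g)`).
#' @param n_trees,n_instances,n_samples,kernel_width,k_sigma Passed through
#'   to the pipeline, classifier and surrogate.
#' @return A tibble of class `reference_library` with columns `label`,
#'   `replicate` and list-column `coefficients`.
#' @export
simulate_references <- function(g, y, n_replicates = 20, seed = 1,
                                subsample = NULL, n_trees = 100,
                                n_instances = 50, n_samples = 1000,
                                kernel_width = NULL, k_sigma = 3) {
  check_aligned(g, y)
  if (length(unique(y$label)) < 2) abort("reference phenotypes must contain both classes")
  n <- nrow(g)
  if (is.null(subsample)) subsample <- n
  base_seeds <- split_seed(seed, 15 * n_replicates)
  rows <- vector("list", 15 * n_replicates)
  k <- 0
  for (label in 1:15) {
    for (r in seq_len(n_replicates)) {
      k <- k + 1
      ss <- split_seed(base_seeds[k], 4)
      res <- tryCatch({
        idx <- withr::with_seed(ss[1], {
          for (try in 1:10) {
            cand <- sample(n, subsample, replace = TRUE)
            if (length(unique(y$label[cand])) == 2) break
          }
          cand
        })
        gb <- g[idx, ]
        gb$sample_id <- sprintf("b%05d", seq_along(idx))
        yb <- y[idx, ]
        yb$sample_id <- gb$sample_id
        pp <- apply_pipeline(gb, yb, label, seed = ss[2], k_sigma = k_sigma)
        model <- train_classifier(pp$genotypes, pp$phenotypes,
                                  n_trees = n_trees, seed = ss[3])
        ev <- site_explanation_vector(model, pp$genotypes,
                                      n_instances = n_instances,
                                      n_samples = n_samples,
                                      kernel_width = kernel_width,
                                      seed = ss[4])
        ev$coefficients
      }, error = function(e) {
        abort(sprintf("reference simulation failed for config %d replicate %d: %s",
                      label, r, conditionMessage(e)))
      })
      rows[[k]] <- tibble(label = label, replicate = r, coefficients = list(res))
    }
  }
  lib <- dplyr::bind_rows(rows)
  attr(lib, "locus_ids") <- locus_ids(g)
  class(lib) <- c("reference_library", class(lib))
  lib
}

# internal: stack a library's coefficient vectors into a matrix
library_matrix <- function(library) {
  do.call(rbind, library$coefficients)
}

#' Train the verification classifier with optional label clustering
#'
#' The verifier learns to map explanation vectors to the four binary
#' preprocessing flags: one probability random forest per flag, trained on
#' the labelled reference vectors.  A 15-class label prediction is obtained
#' by scoring all 15 valid flag combinations with the product of the
#' per-flag probabilities and taking the arg-max, which also keeps the
#' invalid all-off combination out of the prediction space.
#'
#' When `n_clusters < 15`, the 15 per-config mean reference vectors are
#' clustered with seeded K-means (10 restarts, best inertia) and each label
#' is mapped to its cluster; compatibility is then judged at cluster
#' granularity.  `n_clusters = 15` uses the identity mapping.
#'
#' @param library A `reference_library`; all 15 labels must be present.
#' @param n_clusters Cluster count, one of 15, 5, 4, 3, 2.
#' @param n_trees Trees in each per-flag forest (default 500).
#' @param seed Integer seed.
#' @return An object of class `verifier` with fields `flag_forests` (one
#'   per operation), `cluster_map` (tibble `label`, `cluster`),
#'   `n_clusters`, `locus_ids`.
#' @export
train_verifier <- function(library, n_clusters = 15, n_trees = 500, seed = 1) {
  if (!n_clusters %in% c(15, 5, 4, 3, 2)) {
    abort("n_clusters must be one of 15, 5, 4, 3, 2")
  }
  if (!all(1:15 %in% library$label)) abort("reference library must cover all 15 labels")
  X <- library_matrix(library)
  cfg <- enumerate_configs()[library$label, ]
  ops <- c("dedupe", "outlier", "scale", "resample")
  seeds <- split_seed(seed, length(ops) + 1)
  flag_forests <- setNames(lapply(seq_along(ops), function(i) {
    ranger::ranger(x = X, y = factor(cfg[[ops[i]]], levels = c(FALSE, TRUE)),
                   num.trees = n_trees, probability = TRUE,
                   seed = seeds[i], num.threads = 1)
  }), ops)
  means <- t(vapply(1:15, function(l) {
    colMeans(X[library$label == l, , drop = FALSE])
  }, numeric(ncol(X))))
  if (n_clusters == 15) {
    cluster_map <- tibble(label = 1:15, cluster = 1:15)
  } else {
    km <- withr::with_seed(seeds[5], kmeans(means, centers = n_clusters, nstart = 10))
    cluster_map <- tibble(label = 1:15, cluster = as.integer(km$cluster))
  }
  structure(list(flag_forests = flag_forests, cluster_map = cluster_map,
                 n_clusters = n_clusters,
                 locus_ids = attr(library, "locus_ids"),
                 n_trees = n_trees, seed = seed),
            class = "verifier")
}

#' @describeIn train_verifier Predict configuration labels for a matrix (or
#'   list) of explanation vectors.
#' @param object A `verifier`.
#' @param newdata Numeric matrix of explanation vectors (rows), a single
#'   vector, or an `explanation_vector`.
#' @param ... Unused.
#' @export
predict.verifier <- function(object, newdata, ...) {
  if (inherits(newdata, "explanation_vector")) newdata <- newdata$coefficients
  X <- if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1)
  f1 <- object$flag_forests[[1]]
  if (ncol(X) != f1$num.independent.variables) {
    abort("explanation-vector dimension does not match the verifier")
  }
  colnames(X) <- f1$forest$independent.variable.names
  probs <- lapply(object$flag_forests, function(f) {
    predict(f, data = X, num.threads = 1)$predictions[, "TRUE"]
  })
  ec <- enumerate_configs()
  score <- vapply(1:15, function(l) {
    s <- rep(1, nrow(X))
    for (op in names(probs)) {
      s <- s * if (ec[[op]][l]) probs[[op]] else 1 - probs[[op]]
    }
    s
  }, numeric(nrow(X)))
  score <- matrix(score, nrow = nrow(X))
  as.integer(apply(score, 1, which.max))
}

# internal: the verdict rule — compatible iff all cluster ids are equal
verdict_from_labels <- function(labels, cluster_map) {
  clusters <- cluster_map$cluster[match(labels, cluster_map$label)]
  verdict <- if (length(unique(clusters)) == 1) "COMPATIBLE" else "INCOMPATIBLE"
  list(verdict = verdict, clusters = clusters)
}

#' Held-out verification accuracy over a reference library
#'
#' Estimates how well the verifier identifies preprocessing configurations
#' from explanation vectors: for each evaluation seed, the library is split
#' into training and held-out replicates (stratified by label), a verifier
#' is trained on the training part, and the held-out vectors are scored.
#' With `n_clusters = 15` a prediction is correct when the exact label
#' matches; with coarser granularity it is correct when the predicted
#' label's cluster matches the true label's cluster (the compatibility
#' criterion).
#'
#' @param library A `reference_library` with at least 2 replicates per
#'   label.
#' @param n_clusters Cluster granularity (15, 5, 4, 3, 2).
#' @param n_seeds Number of independent split/training seeds (default 5).
#' @param holdout Fraction of replicates per label held out (default 0.25).
#' @param seed Integer seed.
#' @param n_trees Trees per flag forest.
#' @return List with `mean_accuracy` and `accuracies` (one per seed).
#' @export
verification_accuracy <- function(library, n_clusters = 15, n_seeds = 5,
                                  holdout = 0.25, seed = 1, n_trees = 500) {
  R <- max(library$replicate)
  n_test <- max(1, round(R * holdout))
  if (R - n_test < 1) abort("library too small for a held-out split")
  seeds <- split_seed(seed, n_seeds)
  accuracies <- vapply(seeds, function(s) {
    test_reps <- withr::with_seed(s, sample(R, n_test))
    test <- library$replicate %in% test_reps
    verifier <- train_verifier(library[!test, ], n_clusters = n_clusters,
                               n_trees = n_trees, seed = s)
    X <- do.call(rbind, library$coefficients[test])
    pred <- predict(verifier, X)
    truth <- library$label[test]
    if (n_clusters == 15) {
      mean(pred == truth)
    } else {
      cm <- verifier$cluster_map$cluster
      mean(cm[pred] == cm[truth])
    }
  }, numeric(1))
  list(mean_accuracy = mean(accuracies), accuracies = accuracies)
}

#' Verify site compatibility from released artifacts
#'
#' Predicts each site's preprocessing label from its explanation vector and
#' returns COMPATIBLE exactly when all predicted labels fall in the same
#' cluster of the verifier's label map.  The report includes each label's
#' flag vector and, on incompatibility, which of the four operations the
#' predictions disagree on.
#'
#' @param artifacts List of `site_artifact` objects (a single artifact is
#'   trivially compatible).
#' @param verifier A trained [train_verifier()] model.
#' @return An object of class `verification_report` with fields `verdict`,
#'   `per_site` (tibble: `site`, `label`, `cluster`, four flag columns) and
#'   `differing_flags` (named logical over the four operations).
#' @export
verify_sites <- function(artifacts, verifier) {
  stopifnot(length(artifacts) >= 1)
  chk <- validate_alignment(artifacts)
  if (!chk$ok) abort(paste0("alignment check failed: ", chk$detail))
  E <- do.call(rbind, lapply(artifacts, function(a) a$explanation$coefficients))
  labels <- predict(verifier, E)
  v <- verdict_from_labels(labels, verifier$cluster_map)
  flags <- enumerate_configs()[labels, c("dedupe", "outlier", "scale", "resample")]
  per_site <- dplyr::bind_cols(
    tibble(site = vapply(artifacts, function(a) a$site_id, character(1)),
           label = labels, cluster = v$clusters),
    flags
  )
  differing <- vapply(c("dedupe", "outlier", "scale", "resample"),
                      function(op) length(unique(per_site[[op]])) > 1, logical(1))
  structure(list(verdict = v$verdict, per_site = per_site,
                 differing_flags = differing,
                 n_clusters = verifier$n_clusters),
            class = "verification_report")
}

#' @export
print.verification_report <- function(x, ...) {
  cat(sprintf("<verification_report> %s (C = %d)\n", x$verdict, x$n_clusters))
  print(x$per_site)
  if (x$verdict == "INCOMPATIBLE") {
    cat("differing flags:", paste(names(which(x$differing_flags)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Run one end-to-end federated verification trial
#'
#' Partitions a cohort across `k` sites, assigns preprocessing
#' configurations according to the scenario (`"all-same"`: one random
#' configuration for every site; `"one-differs"`: one randomly chosen site
#' gets a different random configuration), executes the site protocol at
#' each site, then the full server protocol (alignment check, reference
#' concatenation, 15-configuration simulation, verifier training,
#' prediction), and scores the verdict against the scenario's ground truth.
#'
#' @param g,y Aligned cohort tibbles.
#' @param epsilon Privacy budget used by every site.
#' @param scenario `"all-same"` or `"one-differs"`.
#' @param seed Integer seed (split across partitioning, config assignment,
#'   sites, and server stages).
#' @param k Number of sites (default 3).
#' @param n_clusters Verifier cluster granularity (default 15: strict label
#'   equality).
#' @param n_replicates Reference replicates per configuration.
#' @param subsample Rows per reference bootstrap replicate.
#' @param n_trees,n_instances,n_samples,verifier_trees Size knobs passed to
#'   the component stages.
#' @return An object of class `federated_trial`: list with `scenario`,
#'   `truth`, `verdict`, `correct`, `configs` (true per-site labels), and
#'   the full `report`.
#' @export
run_federated_experiment <- function(g, y, epsilon, scenario = c("all-same", "one-differs"),
                                     seed = 1, k = 3, n_clusters = 15,
                                     n_replicates = 5, subsample = NULL,
                                     n_trees = 100, n_instances = 50,
                                     n_samples = 1000, verifier_trees = 500) {
  scenario <- match.arg(scenario)
  seeds <- split_seed(seed, 5 + k)
  parts <- partition_sites(g, y, k = k, seed = seeds[1])
  configs <- withr::with_seed(seeds[2], {
    c0 <- sample(15, 1)
    cf <- rep(c0, k)
    if (scenario == "one-differs") {
      cf[sample(k, 1)] <- sample(setdiff(1:15, c0), 1)
    }
    cf
  })
  artifacts <- lapply(seq_len(k), function(i) {
    run_site(parts[[i]]$genotypes, parts[[i]]$phenotypes,
             config = configs[i], epsilon = epsilon, seed = seeds[2 + i],
             site_id = sprintf("site%d", i), n_trees = n_trees,
             n_instances = n_instances, n_samples = n_samples)
  })
  ref <- build_reference(artifacts)
  lib <- simulate_references(ref$genotypes, ref$phenotypes,
                             n_replicates = n_replicates, seed = seeds[k + 3],
                             subsample = subsample, n_trees = n_trees,
                             n_instances = n_instances, n_samples = n_samples)
  verifier <- train_verifier(lib, n_clusters = n_clusters,
                             n_trees = verifier_trees, seed = seeds[k + 4])
  report <- verify_sites(artifacts, verifier)
  truth <- if (scenario == "all-same") "COMPATIBLE" else "INCOMPATIBLE"
  structure(list(scenario = scenario, truth = truth, verdict = report$verdict,
                 correct = report$verdict == truth, configs = configs,
                 report = report),
            class = "federated_trial")
}

#' Binary compatibility-detection accuracy over repeated trials
#'
#' Runs `n_trials` federated trials, alternating the `"all-same"` and
#' `"one-differs"` scenarios (half each), and reports the fraction of trials
#' whose COMPATIBLE/INCOMPATIBLE verdict matched the ground truth.
#'
#' @inheritParams run_federated_experiment
#' @param n_trials Total trials (even; default 10 = 5 repetitions x 2
#'   scenarios).
#' @return List with `accuracy` and a `trials` tibble (`trial`, `scenario`,
#'   `truth`, `verdict`, `correct`).
#' @export
compatibility_trials <- function(g, y, epsilon, n_trials = 10, seed = 1,
                                 k = 3, n_clusters = 15, n_replicates = 5,
                                 subsample = NULL, n_trees = 100,
                                 n_instances = 50, n_samples = 1000,
                                 verifier_trees = 500) {
  stopifnot(n_trials >= 2, n_trials %% 2 == 0)
  seeds <- split_seed(seed, n_trials)
  scen <- rep(c("all-same", "one-differs"), n_trials / 2)
  trials <- purrr::map2(seq_len(n_trials), scen, function(i, s) {
    tr <- run_federated_experiment(g, y, epsilon = epsilon, scenario = s,
                                   seed = seeds[i], k = k,
                                   n_clusters = n_clusters,
                                   n_replicates = n_replicates,
                                   subsample = subsample, n_trees = n_trees,
                                   n_instances = n_instances,
                                   n_samples = n_samples,
                                   verifier_trees = verifier_trees)
    tibble(trial = i, scenario = s, truth = tr$truth,
           verdict = tr$verdict, correct = tr$correct)
  }) |> dplyr::bind_rows()
  list(accuracy = mean(trials$correct), trials = trials)
}
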