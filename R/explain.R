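#' Train the site phenotype classifier
#'
#' Fits a bagged-tree ensemble (random forest via \pkg{ranger}) predicting
#' the binary phenotype from the preprocessed dosage matrix.  Deterministic
#' under the seed (single-threaded).
#'
#' @param g,y Aligned genotype and phenotype tibbles; both classes must be
#'   present and `n >= 10`.
#' @param n_trees Number of trees (default 100).
#' @param seed Integer seed.
#' @return An object of class `site_model`.
#' @export
train_classifier <- function(g, y, n_trees = 100, seed = 1) {
  check_aligned(g, y)
  if (nrow(g) < 10) abort("classifier training needs at least 10 samples")
  if (length(unique(y$label)) < 2) abort("classifier training needs both phenotype classes")
  M <- geno_matrix(g)
  fit <- ranger::ranger(
    x = M, y = factor(y$label, levels = c(0, 1)),
    num.trees = n_trees, probability = TRUE,
    seed = seed, num.threads = 1
  )
  structure(list(forest = fit, locus_ids = locus_ids(g),
                 n_trees = n_trees, seed = seed),
            class = "site_model")
}

#' @describeIn train_classifier Predict class probabilities; rows of the
#'   returned matrix (columns `0` and `1`) sum to one.
#' @param object A `site_model`.
#' @param newdata Genotype tibble or numeric matrix in the model's locus
#'   order.
#' @param ... Unused.
#' @export
predict.site_model <- function(object, newdata, ...) {
  X <- if (is.data.frame(newdata)) geno_matrix(newdata) else as.matrix(newdata)
  if (ncol(X) != length(object$locus_ids)) {
    abort("newdata does not match the model's locus count")
  }
  colnames(X) <- object$locus_ids
  P <- predict(object$forest, data = X, num.threads = 1)$predictions
  P[, c("0", "1"), drop = FALSE]
}

# internal: class-1 probability for a site_model or a bare probability function
prob1 <- function(model, X) {
  if (is.function(model)) return(as.numeric(model(X)))
  predict(model, X)[, "1"]
}

# internal: batched local-surrogate explanation.
# One shared perturbation design (mask Z and background resamples S) is drawn
# per call and reused for every explained instance: common random numbers
# make per-instance coefficients a deterministic function of the instance,
# so aggregation is invariant to duplicated explain sets, and one model
# prediction call covers all instances.
lime_batch <- function(model, Xq, background, n_samples = 1000,
                       kernel_width = NULL, ridge_lambda = 1e-3, seed = 1) {
  B <- if (is.data.frame(background)) geno_matrix(background) else as.matrix(background)
  if (nrow(B) < 1) abort("background must be non-empty")
  m <- ncol(B)
  if (ncol(Xq) != m) abort("instances and background have different locus counts")
  if (is.null(kernel_width)) kernel_width <- 0.75 * sqrt(m)
  if (n_samples < m + 1) {
    warn(sprintf("n_samples (%d) < n_features + 1 (%d); ridge regularization compensates",
                 n_samples, m + 1))
  }
  mu <- colMeans(B)
  sdev <- sqrt(colMeans(sweep(B, 2, mu)^2))
  if (all(sdev == 0)) abort("degenerate background: every locus is constant")
  sdev[sdev == 0] <- 1
  design <- withr::with_seed(seed, {
    Z <- matrix(rbinom(n_samples * m, 1L, 0.5), n_samples, m)
    Z[1, ] <- 1L                      # first perturbed point is the instance itself
    S <- vapply(seq_len(m), function(j) {
      B[sample.int(nrow(B), n_samples, replace = TRUE), j]
    }, numeric(n_samples))
    list(Z = Z, S = matrix(S, nrow = n_samples))
  })
  Z <- design$Z; S <- design$S
  q <- nrow(Xq)
  big <- matrix(0, q * n_samples, m)
  for (i in seq_len(q)) {
    xi <- Xq[i, ]
    big[((i - 1) * n_samples + 1):(i * n_samples), ] <-
      Z * matrix(xi, n_samples, m, byrow = TRUE) + (1 - Z) * S
  }
  colnames(big) <- colnames(B)
  yhat <- prob1(model, big)
  coefs <- matrix(0, q, m, dimnames = list(NULL, colnames(B)))
  lam <- diag(ridge_lambda, m)
  for (i in seq_len(q)) {
    rows <- ((i - 1) * n_samples + 1):(i * n_samples)
    Xp <- big[rows, , drop = FALSE]
    yi <- yhat[rows]
    d2 <- rowSums(sweep(sweep(Xp, 2, Xq[i, ]), 2, sdev, "/")^2)
    w <- exp(-d2 / kernel_width^2)
    w <- w / sum(w)
    wmx <- colSums(Xp * w)
    wmy <- sum(yi * w)
    Xc <- sweep(Xp, 2, wmx)
    A <- crossprod(Xc, Xc * w) + lam
    coefs[i, ] <- solve(A, crossprod(Xc, w * (yi - wmy)))
  }
  coefs
}

#' Explain one prediction with a local linear surrogate
#'
#' LIME-style explanation: draws `n_samples` perturbed points by keeping
#' each feature of the instance with probability 0.5 and otherwise
#' resampling it from the background's empirical distribution, weights each
#' point by `exp(-d^2 / kernel_width^2)` with `d` the Euclidean distance to
#' the instance in background-standardized feature space, and fits a
#' weighted ridge regression of the model's class-1 probability on the
#' perturbed features.  The signed slope vector is the explanation.
#'
#' @param model A `site_model`, or a function mapping a feature matrix to
#'   class-1 probabilities (useful for testing).
#' @param x Numeric feature vector (the instance to explain).
#' @param background Genotype tibble or matrix the perturbations are drawn
#'   from; conventionally the model's own training matrix.
#' @param n_samples Number of perturbed points (default 1000).
#' @param kernel_width Locality kernel width in standardized space; default
#'   `0.75 * sqrt(n_features)`.
#' @param ridge_lambda Ridge penalty (small, for numerical stability;
#'   sparsity is not sought because the full vector is the artifact).
#' @param seed Integer seed.
#' @return Named numeric coefficient vector of length `n_features`.
#' @export
lime_explain_instance <- function(model, x, background, n_samples = 1000,
                                  kernel_width = NULL, ridge_lambda = 1e-3,
                                  seed = 1) {
  co <- lime_batch(model, matrix(as.numeric(x), nrow = 1), background,
                   n_samples = n_samples, kernel_width = kernel_width,
                   ridge_lambda = ridge_lambda, seed = seed)
  co[1, ]
}

#' Aggregate per-instance explanations into the site explanation vector
#'
#' Explains `min(n_instances, n)` instances (default 50) drawn
#' deterministically under the seed from `g_explain` and returns the
#' element-wise mean of the per-instance surrogate coefficient vectors.
#' This single aggregated vector is the only model-derived artifact a site
#' releases.
#'
#' @param model A `site_model` (or probability function).
#' @param g_explain Genotype tibble of candidate instances (non-empty).
#' @param n_instances Number of instances to explain (default 50).
#' @param background Background for the surrogate; defaults to `g_explain`.
#' @inheritParams lime_explain_instance
#' @return An object of class `explanation_vector` with fields
#'   `coefficients` (named, length = locus count), `locus_ids`,
#'   `n_instances_explained`, and `settings`.
#' @export
site_explanation_vector <- function(model, g_explain, n_instances = 50,
                                    n_samples = 1000, kernel_width = NULL,
                                    ridge_lambda = 1e-3, seed = 1,
                                    background = g_explain) {
  n <- nrow(g_explain)
  if (n < 1) abort("explain set is empty")
  seeds <- split_seed(seed, 2)
  Xall <- geno_matrix(g_explain)
  idx <- if (n_instances >= n) seq_len(n) else
    withr::with_seed(seeds[1], sample(n, n_instances))
  co <- lime_batch(model, Xall[idx, , drop = FALSE], background,
                   n_samples = n_samples, kernel_width = kernel_width,
                   ridge_lambda = ridge_lambda, seed = seeds[2])
  structure(list(
    coefficients = colMeans(co),
    locus_ids = locus_ids(g_explain),
    n_instances_explained = length(idx),
    settings = list(n_samples = n_samples,
                    kernel_width = if (is.null(kernel_width))
                      0.75 * sqrt(ncol(Xall)) else kernel_width,
                    ridge_lambda = ridge_lambda, seed = seed)
  ), class = "explanation_vector")
}

#' @export
print.explanation_vector <- function(x, ...) {
  cat(sprintf("<explanation_vector> %d loci, mean of %d instances\n",
              length(x$coefficients), x$n_instances_explained))
  cat(sprintf("  |coef| range [%.3g, %.3g]\n",
              min(abs(x$coefficients)), max(abs(x$coefficients))))
  invisible(x)
}
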