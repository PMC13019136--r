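#' Tidy an explanation vector
#'
#' @param x An `explanation_vector`.
#' @param ... Unused.
#' @return Tibble with columns `locus` and `coefficient`.
#' @export
tidy.explanation_vector <- function(x, ...) {
  tibble(locus = names(x$coefficients), coefficient = unname(x$coefficients))
}

#' Tidy a reference library into long form
#'
#' @param x A `reference_library`.
#' @param ... Unused.
#' @return Tibble with columns `label`, `replicate`, `locus`, `coefficient`.
#' @export
tidy.reference_library <- function(x, ...) {
  loci <- attr(x, "locus_ids")
  tidyr::unnest(
    mutate(as_tibble(x),
           locus = list(loci),
           coefficient = lapply(.data$coefficients, unname),
           coefficients = NULL),
    c("locus", "coefficient"))
}

#' Tidy a verification report
#'
#' @param x A `verification_report`.
#' @param ... Unused.
#' @return The per-site tibble (`site`, `label`, `cluster`, flag columns).
#' @export
tidy.verification_report <- function(x, ...) x$per_site

#' @rdname tidy.verification_report
#' @return For `glance()`: one row with `verdict`, `compatible`,
#'   `n_sites`, `n_clusters`, `n_differing_flags`.
#' @export
glance.verification_report <- function(x, ...) {
  tibble(verdict = x$verdict, compatible = x$verdict == "COMPATIBLE",
         n_sites = nrow(x$per_site), n_clusters = x$n_clusters,
         n_differing_flags = sum(x$differing_flags))
}

#' Tidy a membership-inference attack result
#'
#' @param x An `mi_attack`.
#' @param ... Unused.
#' @return Tibble with one row per repetition: `repetition`, `power`,
#'   `fpr`, `threshold`.
#' @export
tidy.mi_attack <- function(x, ...) {
  tibble(repetition = seq_along(x$powers), power = x$powers,
         fpr = x$fprs, threshold = x$thresholds)
}

#' @rdname tidy.mi_attack
#' @return For `glance()`: one row with the mean power, CI bounds, and
#'   attack parameters.
#' @export
glance.mi_attack <- function(x, ...) {
  tibble(power = x$power, ci_low = x$ci[1], ci_high = x$ci[2],
         fpr_target = x$fpr_target, epsilon = x$epsilon,
         n_loci = x$n_loci, reps = x$reps)
}

#' Tidy a verifier's label-to-cluster map
#'
#' @param x A `verifier`.
#' @param ... Unused.
#' @return The cluster-map tibble joined with the configuration flags.
#' @export
tidy.verifier <- function(x, ...) {
  left_join(x$cluster_map, enumerate_configs(), by = "label")
}

#' @rdname tidy.verifier
#' @return For `glance()`: one row with `n_clusters`, `n_trees`, and each
#'   per-flag forest's out-of-bag Brier error.
#' @export
glance.verifier <- function(x, ...) {
  oob <- vapply(x$flag_forests, function(f) f$prediction.error, numeric(1))
  dplyr::bind_cols(
    tibble(n_clusters = x$n_clusters, n_trees = x$n_trees),
    as_tibble(as.list(setNames(oob, paste0("oob_", names(oob))))))
}

#' Plot the power distribution of a membership-inference attack
#'
#' Histogram of per-repetition powers with the mean and bootstrap 95%
#' confidence interval marked.
#'
#' @param object An `mi_attack`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mi_attack <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$power)) +
    ggplot2::geom_histogram(bins = 20, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$power, colour = "firebrick") +
    ggplot2::geom_vline(xintercept = object$ci, colour = "firebrick",
                        linetype = "dashed") +
    ggplot2::labs(
      x = "attack power per repetition", y = "repetitions",
      title = sprintf("MI attack power: mean %.3f at epsilon = %s, %d loci",
                      object$power, format(object$epsilon), object$n_loci)) +
    ggplot2::theme_minimal()
}

#' Plot an explanation vector as a coefficient profile
#'
#' @param object An `explanation_vector`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.explanation_vector <- function(object, ...) {
  df <- tidy(object)
  df$index <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$coefficient)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$index, yend = 0)) +
    ggplot2::labs(x = "locus index", y = "surrogate coefficient",
                  title = "Aggregated local-surrogate explanation vector") +
    ggplot2::theme_minimal()
}

#' Plot a reference library in principal-component space
#'
#' Projects all replicate reference vectors onto their first two principal
#' components, coloured by configuration label: a visual check of how
#' separable the 15 preprocessing fingerprints are.
#'
#' @param object A `reference_library`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reference_library <- function(object, ...) {
  X <- library_matrix(object)
  pc <- prcomp(X, scale. = FALSE)
  df <- tibble(PC1 = pc$x[, 1], PC2 = pc$x[, 2],
               label = factor(object$label))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                   colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(title = "Reference explanation vectors by configuration",
                  colour = "config") +
    ggplot2::theme_minimal()
}
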