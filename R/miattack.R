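# internal: minimum Hamming distance of each query row to any released row.
# Counted via match-indicator matrix products: matches(v) = (Q==v) %*% t(R==v).
hamming_min <- function(Q, Rm) {
  m <- ncol(Q)
  stopifnot(ncol(Rm) == m)
  matches <- matrix(0, nrow(Q), nrow(Rm))
  for (v in c(0, 1, 2)) {
    matches <- matches + (Q == v) %*% t(Rm == v)
  }
  apply(m - matches, 1, min)
}

#' Minimum Hamming distance of a genome to a released matrix
#'
#' The membership-inference test statistic: the number of positions at which
#' a target genome differs from its closest row in the released (perturbed)
#' matrix.  A true member whose record survived perturbation mostly intact
#' scores low; population non-members score higher.
#'
#' @param genome Numeric dosage vector.
#' @param released Genotype tibble or matrix (the LDP release).
#' @return Integer minimum Hamming distance.
#' @export
hamming_statistic <- function(genome, released) {
  Rm <- if (is.data.frame(released)) geno_matrix(released) else as.matrix(released)
  if (length(genome) != ncol(Rm)) {
    abort("genome length does not match the released locus count")
  }
  as.integer(hamming_min(matrix(as.numeric(genome), nrow = 1), Rm))
}

#' Estimate membership-inference attack power against an LDP release
#'
#' Perturbs the member rows of `pool` at budget `epsilon` to form the
#' release, then repeatedly (default 50 repetitions) samples `n_case` true
#' members and `n_ctrl` non-members, computes each genome's minimum Hamming
#' distance to the release, calibrates a per-repetition decision threshold
#' as the largest distance at which at most `fpr` of the non-members are
#' flagged, and records the fraction of members flagged (the attack power).
#' The mean power over repetitions with a bootstrap 95% confidence interval
#' summarizes the residual re-identification risk.
#'
#' @param pool Genotype tibble containing members and non-members drawn from
#'   the same population.
#' @param member_ids Sample ids of the rows that enter the release.
#' @param epsilon Privacy budget of the release.
#' @param n_case,n_ctrl Members / non-members tested per repetition
#'   (default 25 each).
#' @param reps Repetitions (default 50).
#' @param fpr Target false-positive rate for threshold calibration
#'   (default 0.05).
#' @param seed Integer seed.
#' @param n_boot Bootstrap resamples for the confidence interval.
#' @return An object of class `mi_attack` with fields `power` (mean),
#'   `powers`, `fprs`, `thresholds` (per repetition), `ci` (95% bootstrap),
#'   and the attack parameters.
#' @export
mi_attack_power <- function(pool, member_ids, epsilon,
                            n_case = 25, n_ctrl = 25, reps = 50,
                            fpr = 0.05, seed = 1, n_boot = 1000) {
  validate_genotypes(pool, ternary = TRUE)
  is_member <- pool$sample_id %in% member_ids
  if (sum(is_member) < n_case) abort("pool has fewer members than n_case")
  if (sum(!is_member) < n_ctrl) abort("pool has fewer non-members than n_ctrl")
  seeds <- split_seed(seed, reps + 2)
  members <- pool[is_member, ]
  controls_pool <- geno_matrix(pool[!is_member, ])
  members_mat <- geno_matrix(members)
  release <- geno_matrix(perturb_genotypes(members, epsilon, seed = seeds[1]))
  m <- ncol(release)
  powers <- fprs <- thresholds <- numeric(reps)
  for (r in seq_len(reps)) {
    draw <- withr::with_seed(seeds[r + 1], {
      list(case = sample(nrow(members_mat), n_case),
           ctrl = sample(nrow(controls_pool), n_ctrl))
    })
    case_stat <- hamming_min(members_mat[draw$case, , drop = FALSE], release)
    ctrl_stat <- hamming_min(controls_pool[draw$ctrl, , drop = FALSE], release)
    cand <- seq.int(-1L, m)   # any integer distance is a possible threshold
    ok <- vapply(cand, function(t) mean(ctrl_stat <= t) <= fpr, logical(1))
    thr <- max(cand[ok])
    powers[r] <- mean(case_stat <= thr)
    fprs[r] <- mean(ctrl_stat <= thr)
    thresholds[r] <- thr
  }
  ci <- withr::with_seed(seeds[reps + 2], {
    boots <- vapply(seq_len(n_boot), function(b) {
      mean(powers[sample.int(reps, reps, replace = TRUE)])
    }, numeric(1))
    unname(quantile(boots, c(0.025, 0.975)))
  })
  structure(list(power = mean(powers), powers = powers, fprs = fprs,
                 thresholds = thresholds, ci = ci, fpr_target = fpr,
                 epsilon = epsilon, n_loci = m, n_case = n_case,
                 n_ctrl = n_ctrl, reps = reps, seed = seed),
            class = "mi_attack")
}

#' @export
print.mi_attack <- function(x, ...) {
  cat(sprintf(
    "<mi_attack> epsilon = %s, %d loci: mean power %.3f (95%% CI %.3f-%.3f) at FPR <= %.2f\n",
    format(x$epsilon), x$n_loci, x$power, x$ci[1], x$ci[2], x$fpr_target))
  invisible(x)
}
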