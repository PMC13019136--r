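# shared fixture builders: small cohorts generated in code

make_cohort <- function(n = 200, m = 30, seed = 101, prevalence = 0.3,
                        effect_size = 1, ...) {
  spec <- cohort_spec(n_samples = n, n_loci = m, seed = seed,
                      prevalence = prevalence, effect_size = effect_size, ...)
  g <- sample_genotypes(spec)
  y <- sample_phenotypes(g, spec)
  list(spec = spec, genotypes = g, phenotypes = y)
}

# cohort with injected duplicates and outliers, as a site would hold it
make_messy_cohort <- function(n = 200, m = 30, seed = 101,
                              dup_fraction = 0.1, outlier_fraction = 0.05) {
  co <- make_cohort(n, m, seed)
  inj <- inject_duplicates(co$genotypes, co$phenotypes, dup_fraction,
                           seed = seed + 1)
  g <- inject_outliers(inj$genotypes, outlier_fraction, seed = seed + 2)
  list(genotypes = g, phenotypes = inj$phenotypes,
       n_dup = nrow(inj$genotypes) - n)
}

# brute-force minimum Hamming distance, the independent oracle
brute_hamming <- function(genome, M) {
  min(apply(M, 1, function(r) sum(r != genome)))
}

# stratified split of a reference library: last `k` replicates per label
lib_split <- function(lib, k_test) {
  R <- max(lib$replicate)
  lib$replicate > R - k_test
}
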