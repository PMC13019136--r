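Package: prepverify
Title: Privacy-Preserving Verification of Preprocessing Pipelines in
    Federated Genomic Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Verifies that the sites of a federated genomic study applied
    identical preprocessing pipelines without ever exchanging raw genotypes.
    Each site perturbs its SNP dosage matrix with an epsilon-local
    differential privacy randomized-response mechanism, trains a random
    forest phenotype classifier, and releases a single aggregated
    local-surrogate (LIME-style) explanation vector.  A coordinating server
    simulates the 15 possible combinations of four optional preprocessing
    operations (duplicate removal, outlier filtering, z-score scaling, SMOTE
    resampling) on the pooled perturbed data, trains a verification
    classifier over reference explanation vectors, predicts each site's
    preprocessing fingerprint, and returns a compatibility verdict.  Also
    included are a synthetic cohort generator (Hardy-Weinberg genotypes,
    logistic phenotypes, injected duplicates and outliers) and a
    Hamming-distance membership-inference attack for quantifying the
    residual privacy risk of the released artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
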