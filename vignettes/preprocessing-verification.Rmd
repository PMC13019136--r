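---
title: "Verifying preprocessing pipelines in federated genomic studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Verifying preprocessing pipelines in federated genomic studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prepverify)
```

## The problem

Multi-institutional genomic studies pool statistical strength across sites
that cannot share raw genotypes. Each site preprocesses its own data, and
seemingly minor differences — whether duplicates were dropped, whether
distance outliers were filtered, whether dosages were z-scored, whether the
class imbalance was SMOTE-corrected — shift downstream effect estimates
enough to matter clinically. Sites can *claim* a common pipeline; nothing in
a standard federated workflow *verifies* it.

`prepverify` implements a verification protocol in which each site releases
only two privacy-protected artifacts: a locally differentially private (LDP)
copy of its SNP dosage matrix and a single aggregated local-surrogate
(LIME-style) explanation vector of a random-forest phenotype classifier
trained on its preprocessed data. A coordinating server re-simulates all 15
possible pipelines on the pooled perturbed data, learns what each pipeline
does to an explanation vector, predicts every site's preprocessing
fingerprint, and returns a COMPATIBLE/INCOMPATIBLE verdict. A
Hamming-distance membership-inference (MI) attack quantifies the residual
privacy risk of the released matrix.

## The mechanism, step by step

**Randomized response.** Each dosage value $v \in \{0,1,2\}$ is kept with
probability

$$p = \frac{e^{\varepsilon}}{e^{\varepsilon} + 2}$$

and otherwise replaced uniformly by one of the two alternative values. The
induced $3\times 3$ transition matrix has diagonal $p$ and off-diagonal
$(1-p)/2$, so the worst-case likelihood ratio between two inputs is exactly
$p / \tfrac{1-p}{2} = e^{\varepsilon}$: pure $\varepsilon$-DP with
$\delta = 0$. `keep_probability()`, `ldp_transition_matrix()` and
`perturb_genotypes()` expose the analytic structure and the sampler
separately so the mechanism can be tested against its own law.
Perturbation happens *before* preprocessing; everything downstream is
post-processing and inherits the guarantee. Phenotype labels are uploaded
in clear: the server must train surrogate models on $(X_{\mathrm{ref}}, Y)$
and the protocol does not specify a label mechanism; this is a known gap of
the artifact set and is documented rather than hidden.

**The fingerprint space.** Four optional operations in fixed order —
duplicate removal, outlier filtering (rows whose Euclidean distance to the
cohort mean exceeds $\bar d + k\sigma_d$, default $k = 3$), per-locus
z-scoring (population SD; zero-variance loci map to zeros so the feature
dimension never changes), and SMOTE resampling with one nearest neighbour —
give $2^4 - 1 = 15$ valid configurations. The label of a configuration is
its binary encoding `dedupe*8 + outlier*4 + scale*2 + resample*1`. The
all-off combination is excluded; we read the count $2^4-1$ as excluding
exactly that combination, the only reading under which the label map is
canonical.

**Local surrogate explanations.** For an instance $x$, we draw perturbed
points by keeping each feature with probability $1/2$ and otherwise
resampling it from the background's empirical marginal, weight each point by
$\exp(-d^2/w^2)$ (with $d$ the Euclidean distance to $x$ in
background-standardized space and $w = 0.75\sqrt{m}$ by default), and fit a
weighted ridge regression of the forest's class-1 probability on the
perturbed features. The signed slopes are the explanation. One shared
perturbation design is drawn per call and reused across instances: common
random numbers make each instance's coefficients a deterministic function of
the instance, so the site-level aggregate (the element-wise mean over 50
explained instances by default) is invariant to duplicated explain sets and
can be computed with a single batched forest prediction. Ridge rather than
lasso: the full vector is the artifact, sparsity is not wanted, and the
ridge solve is deterministic and cheap.

**The verifier.** The server concatenates the perturbed site matrices into
$X_{\mathrm{ref}}$ and, for each configuration and replicate,
bootstrap-resamples rows (with replacement — deliberately, since this is the
only stage at which exact duplicate rows can exist post-LDP, giving the
dedupe flag something to act on), applies the pipeline, trains a forest, and
extracts a reference explanation vector. One probability forest per
preprocessing flag is trained on the labelled reference vectors; a 15-class
prediction scores all 15 valid flag combinations by the product of per-flag
probabilities and takes the arg-max. We chose the flag-wise architecture
over a flat 15-way forest because the label space is a product space: the
four binary tasks share evidence across labels and the product scoring
excludes the invalid all-off combination by construction.

With cluster granularity $C < 15$, seeded K-means (10 restarts) clusters the
15 per-configuration *mean* reference vectors — not the raw replicate cloud
— so the label-to-cluster map is deterministic and auditable. Sites are
compatible exactly when their predicted labels share a cluster; the verdict
rule is the cluster-equality predicate and nothing else.

## What the synthetic generator emulates — and what it does not

The generator reproduces the statistical shape the protocol is evaluated
on: $n$ individuals at $m$ loci (the study's primary operating points are
$n = 2504$ or $400$ with $m = 100$, and $m \in \{50, 200, 500\}$ for
dimensionality sweeps), Hardy-Weinberg dosages at per-locus allele
frequencies drawn Uniform(0.05, 0.5) (all loci clear the conventional
MAF > 0.01 cut; monomorphic loci can be added explicitly to exercise
`filter_maf()`), a binary phenotype from a logistic model over 5 causal loci
with a bisection-calibrated intercept (default prevalence 0.3, so the
resampling step has real work), 5% injected exact-duplicate records, and 2%
injected distance outliers constructed with a guaranteed margin beyond the
most extreme genuine row, so the outlier filter's behaviour is
deterministic.

Deliberate non-goals: no linkage disequilibrium (loci independent), no
population structure or admixture, no quantitative phenotypes, no
GAN-trained genome synthesis. The verification signal concerns what
*preprocessing* does to explanation vectors, not haplotype structure; but a
green test suite here says nothing about cohorts whose duplicate records are
near- rather than exact copies, or whose outliers are subtler than the
injected ones.

The phenotype model is a stand-in choice, not an inference about the
original cohorts, whose phenotype definitions are unstated.

## Numerical and design choices

* **Seeds.** Every stochastic operation takes one integer seed;
  composite operations split theirs via `split_seed()` (a fixed two-round
  multiplicative hash mod $2^{31}-1$), so no two stages share an RNG stream
  and every stage is individually reproducible.
* **Outlier threshold.** The distance rule needs a threshold; we use
  $\bar d + 3\,\mathrm{sd}(d)$ — scale-free, standard, and parameter-light.
  If every distance is equal the filter removes nothing, and it refuses to
  empty a cohort.
* **SMOTE details.** Nearest-neighbour ties break toward the lowest row
  index; one interpolation weight $\lambda \sim U(0,1)$ per synthetic row
  (shared across coordinates, so synthetic rows lie on the parent segment).
* **Mode imputation** (mandatory step) breaks ties toward the smaller
  dosage; generator data is complete, so this path is exercised by
  dedicated fixtures with masked entries.
* **Ridge penalty** $10^{-3}$ on centred features; weights normalised to
  sum to one. With fewer perturbation samples than features the fit warns
  and proceeds (the ridge keeps it well-posed).
* **K-means** is run on 15 mean vectors only; with 10 restarts the
  partition is stable across seeds in practice.
* **Degenerate inputs.** Scaling maps zero-variance columns to zeros rather
  than dropping them (the explanation-vector dimension must equal the locus
  count); `epsilon = 0` is accepted as the uniform-noise limit even though
  operating budgets are $\varepsilon \in [0.1, 3]$.

## Problem sizes used by the shipped studies

The acceptance script and the heavier tests run the full protocol at the
study's cohort shapes ($n = 2504$, $m \in \{100, 200, 500\}$) but scale the
Monte-Carlo knobs of the *estimators* — reference replicates per
configuration, bootstrap subsample size, trees, explained instances,
surrogate sample counts — to sizes chosen once for statistical adequacy at
tractable cost: centralized reference libraries use 20 replicates per
configuration with bootstrap subsamples of 1500 rows, 80-tree forests, and
20 explained instances at 300 surrogate samples; federated trials use
3-replicate reference libraries on 500-row subsamples with 60-tree forests
and 6-8 instances at 300-520 surrogate samples. These are estimator
settings, not study conditions; the cohort parameters above are never
varied per experiment.

## Known limitations

* After randomized response at any finite $\varepsilon$, exact duplicate
  rows essentially never survive into the released matrix, so the
  duplicate-removal flag is observable only through the bootstrap-replicate
  device, and weakly; the same holds for the outlier flag, whose 2% of
  removed rows barely move an aggregated surrogate. The package's measured
  15-class verification accuracy is therefore dominated by the scaling and
  resampling flags, and falls well short of separating all 15
  configurations at high accuracy. Coarse cluster granularities
  ($C = 2$) recover robust compatibility decisions, which is the
  operating mode we would recommend to a consortium.
* The MI attack is the minimum-Hamming-distance variant — the strongest
  natural matching rule, hence conservative for privacy claims; other
  attacks (likelihood-ratio, kinship) are out of scope. Be aware of what
  the conservative rule implies on *unstructured* cohorts: a member's raw
  genome differs from its released row at an expected fraction $1-p$ of
  loci (about 9 of 100 SNPs at $\varepsilon = 3$), while an unrelated
  non-member's nearest release row is far more distant, so the calibrated
  attack separates members almost perfectly at moderate budgets and long
  slices. Per-allele randomized response composes over loci; it does not,
  by itself, make a released 100-SNP slice safe against record linkage
  when non-members have no near-duplicates inside the release. Cohorts
  with strong internal similarity (relatives, LD, near-duplicate synthetic
  genomes) blunt the attack because non-members also find close matches;
  the generator's unrelated, LD-free cohorts are the worst case for
  privacy, and the attack results the package reports should be read that
  way.
* All sites use the same classifier family (random forest); heterogeneous
  site models would change the explanation-vector geometry.
* Federation is simulated in-process with exactly the protocol's message
  contents; no network transport is included.
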