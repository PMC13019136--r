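#' Read and write genotype matrices as delimited text
#'
#' The on-disk format is tab-separated text with a header: first column
#' `sample_id`, remaining columns one per locus (the header carries the
#' locus ids, whose order is significant).  The round trip is loss-free for
#' integer dosages and repr-exact for real-valued (scaled) matrices.
#'
#' @param g Genotype tibble.
#' @param path File path.
#' @return `write_genotypes()` returns `path` invisibly; `read_genotypes()`
#'   returns a genotype tibble.
#' @export
write_genotypes <- function(g, path) {
  readr::write_tsv(g, path)
  invisible(path)
}

#' @rdname write_genotypes
#' @param ternary Validate that all entries are ternary dosages on read.
#' @export
read_genotypes <- function(path, ternary = FALSE) {
  g <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  probs <- readr::problems(g)
  if (nrow(probs) > 0) {
    abort(sprintf("malformed genotype file '%s': line %d (%s)",
                  path, probs$row[1], probs$expected[1]))
  }
  if (names(g)[1] != "sample_id") abort("genotype file must start with a sample_id column")
  g$sample_id <- as.character(g$sample_id)
  validate_genotypes(g, ternary = ternary, allow_missing = TRUE)
  g
}

#' Read and write phenotype tables
#'
#' Two-column tab-separated text: `sample_id`, `label`.
#'
#' @param y Phenotype tibble.
#' @param path File path.
#' @export
write_phenotypes <- function(y, path) {
  readr::write_tsv(y, path)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  y <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample_id", "label") %in% names(y))) {
    abort("phenotype file must have sample_id and label columns")
  }
  phenotype_tbl(y$label, as.character(y$sample_id))
}

#' Import genotype dosages from a VCF
#'
#' Converts GT fields of biallelic records to alternate-allele dosages
#' (0/0 -> 0, 0/1 -> 1, 1/1 -> 2); missing genotypes become `NA` for
#' downstream mode imputation.  Multiallelic records are skipped with a
#' warning stating how many were dropped.  Locus ids are
#' `CHROM:POS:REF:ALT` for traceability; coordinates and strand play no
#' further role.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param samples Optional character vector restricting the imported
#'   samples.
#' @return Genotype tibble (samples x loci), possibly containing `NA`.
#' @export
import_vcf <- function(path, samples = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(vcf)
  if (!any(bi)) abort("VCF contains no biallelic records")
  if (any(!bi)) {
    warn(sprintf("skipped %d multiallelic record(s)", sum(!bi)))
    vcf <- vcf[bi, ]
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  fix <- vcfR::getFIX(vcf)
  ids <- paste(fix[, "CHROM"], fix[, "POS"], fix[, "REF"], fix[, "ALT"], sep = ":")
  dosage <- function(s) {
    if (is.na(s)) return(NA_real_)
    al <- strsplit(s, "[/|]")[[1]]
    if (any(al == ".")) return(NA_real_)
    sum(al == "1")
  }
  D <- matrix(vapply(gt, dosage, numeric(1)), nrow = nrow(gt))
  M <- t(D)                             # loci x samples -> samples x loci
  rownames(M) <- colnames(gt)
  if (!is.null(samples)) {
    missing <- setdiff(samples, rownames(M))
    if (length(missing)) abort(paste0("sample not in VCF: ", missing[1]))
    M <- M[samples, , drop = FALSE]
  }
  genotype_tbl(M, sample_ids = rownames(M), locus_ids = ids)
}

#' Serialize and restore site artifacts
#'
#' The wire format of a site upload: a tab-separated perturbed matrix
#' (`<site>_matrix.tsv`), a phenotype file (`<site>_phenotypes.tsv`), and a
#' JSON explanation file (`<site>_explanation.json`) carrying the
#' coefficient vector, locus ids, surrogate settings, and epsilon.
#'
#' @param artifact A `site_artifact`.
#' @param dir Directory to write into (created if needed).
#' @return `write_artifact()` returns the directory invisibly;
#'   `read_artifact()` returns a `site_artifact`.
#' @export
write_artifact <- function(artifact, dir) {
  stopifnot(inherits(artifact, "site_artifact"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  id <- artifact$site_id
  write_genotypes(artifact$genotypes, file.path(dir, paste0(id, "_matrix.tsv")))
  write_phenotypes(artifact$phenotypes, file.path(dir, paste0(id, "_phenotypes.tsv")))
  ev <- artifact$explanation
  jsonlite::write_json(
    list(site_id = id, epsilon = artifact$epsilon,
         locus_ids = artifact$locus_ids,
         coefficients = unname(ev$coefficients),
         n_instances_explained = ev$n_instances_explained,
         settings = ev$settings),
    file.path(dir, paste0(id, "_explanation.json")),
    auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_artifact
#' @param site_id Site identifier used in the file names.
#' @export
read_artifact <- function(dir, site_id) {
  g <- read_genotypes(file.path(dir, paste0(site_id, "_matrix.tsv")), ternary = TRUE)
  y <- read_phenotypes(file.path(dir, paste0(site_id, "_phenotypes.tsv")))
  js <- jsonlite::read_json(file.path(dir, paste0(site_id, "_explanation.json")),
                            simplifyVector = TRUE)
  ev <- structure(list(
    coefficients = setNames(as.numeric(js$coefficients), js$locus_ids),
    locus_ids = js$locus_ids,
    n_instances_explained = js$n_instances_explained,
    settings = js$settings
  ), class = "explanation_vector")
  structure(list(site_id = js$site_id, genotypes = g, phenotypes = y,
                 explanation = ev, epsilon = js$epsilon,
                 locus_ids = js$locus_ids),
            class = "site_artifact")
}

#' Write a verification report as JSON
#'
#' @param report A `verification_report`.
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "verification_report"))
  jsonlite::write_json(
    list(verdict = report$verdict, n_clusters = report$n_clusters,
         per_site = report$per_site,
         differing_flags = as.list(report$differing_flags)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
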