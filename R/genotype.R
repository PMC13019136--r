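#' Construct a genotype table
#'
#' The package represents a SNP dosage matrix as a tibble whose first column
#' is `sample_id` and whose remaining columns are one numeric dosage column
#' per locus.  Dosages are counts of the alternate (or minor) allele per
#' individual and locus, in \{0, 1, 2\} for raw data; preprocessing steps
#' such as z-score scaling or SMOTE interpolation may make them real-valued.
#' Column order is the canonical locus order for every downstream vector
#' (explanation vectors, verifier features).
#'
#' @param values Numeric matrix, samples in rows and loci in columns.
#' @param sample_ids Character vector of unique sample identifiers; defaults
#'   to `S0001`, `S0002`, ...
#' @param locus_ids Character vector of unique locus identifiers; defaults to
#'   `L0001`, `L0002`, ...
#' @return A tibble with a `sample_id` column followed by one column per
#'   locus.
#' @examples
#' genotype_tbl(matrix(c(0, 1, 2, 1), 2, 2))
#' @export
genotype_tbl <- function(values, sample_ids = NULL, locus_ids = NULL) {
  values <- as.matrix(values)
  n <- nrow(values)
  m <- ncol(values)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%04d", seq_len(n))
  if (is.null(locus_ids)) {
    locus_ids <- colnames(values)
    if (is.null(locus_ids) || !all(nzchar(locus_ids))) {
      locus_ids <- sprintf("L%04d", seq_len(m))
    }
  }
  if (length(sample_ids) != n) abort("sample_ids length must equal the row count")
  if (length(locus_ids) != m) abort("locus_ids length must equal the column count")
  if (anyDuplicated(sample_ids)) {
    abort(paste0("duplicate sample_id: ", sample_ids[duplicated(sample_ids)][1]))
  }
  if (anyDuplicated(locus_ids)) {
    abort(paste0("duplicate locus_id: ", locus_ids[duplicated(locus_ids)][1]))
  }
  colnames(values) <- locus_ids
  out <- as_tibble(values)
  out <- tibble(sample_id = as.character(sample_ids)) |> dplyr::bind_cols(out)
  out
}

#' Construct a phenotype table
#'
#' Binary phenotypes aligned to a genotype table by `sample_id` (and by row
#' order, which all package operations preserve).
#'
#' @param labels Vector of 0/1 phenotype labels.
#' @param sample_ids Character vector of sample identifiers.
#' @return A tibble with columns `sample_id` and `label`.
#' @export
phenotype_tbl <- function(labels, sample_ids) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) abort("phenotype labels must be 0 or 1")
  if (length(labels) != length(sample_ids)) {
    abort("labels and sample_ids must have equal length")
  }
  tibble(sample_id = as.character(sample_ids), label = labels)
}

#' Extract the dosage matrix from a genotype table
#'
#' @param g Genotype tibble (see [genotype_tbl()]).
#' @return Numeric matrix with sample ids as row names and locus ids as
#'   column names.
#' @export
geno_matrix <- function(g) {
  M <- as.matrix(g[, setdiff(names(g), "sample_id"), drop = FALSE])
  storage.mode(M) <- "double"
  rownames(M) <- g$sample_id
  M
}

#' @rdname geno_matrix
#' @export
locus_ids <- function(g) setdiff(names(g), "sample_id")

#' @rdname geno_matrix
#' @export
sample_ids <- function(g) g$sample_id

#' Validate a genotype table
#'
#' Checks structural invariants: a unique `sample_id` column, numeric locus
#' columns, and (optionally) that every entry is a valid ternary dosage.
#' On a ternary violation the error names the offending sample and locus.
#'
#' @param g Genotype tibble.
#' @param ternary Require entries in \{0, 1, 2\}? Set `FALSE` after scaling
#'   or resampling.
#' @param allow_missing Tolerate `NA` entries (e.g. fresh VCF imports before
#'   imputation)?
#' @return `g`, invisibly.
#' @export
validate_genotypes <- function(g, ternary = TRUE, allow_missing = FALSE) {
  if (!is.data.frame(g) || names(g)[1] != "sample_id") {
    abort("a genotype table must have sample_id as its first column")
  }
  if (anyDuplicated(g$sample_id)) {
    abort(paste0("duplicate sample_id: ", g$sample_id[duplicated(g$sample_id)][1]))
  }
  M <- geno_matrix(g)
  if (!allow_missing && anyNA(M)) {
    idx <- which(is.na(M), arr.ind = TRUE)[1, ]
    abort(sprintf("missing dosage at sample '%s', locus '%s'",
                  rownames(M)[idx[1]], colnames(M)[idx[2]]))
  }
  if (ternary) {
    bad <- which(!(M %in% c(0, 1, 2) | is.na(M)))
    if (length(bad)) {
      idx <- arrayInd(bad[1], dim(M))
      abort(sprintf(
        "non-ternary dosage %g at sample '%s', locus '%s'",
        M[bad[1]], rownames(M)[idx[1]], colnames(M)[idx[2]]))
    }
  }
  invisible(g)
}

# internal: check genotype/phenotype alignment
check_aligned <- function(g, y) {
  if (nrow(g) != nrow(y)) {
    abort("genotype and phenotype tables have different numbers of samples")
  }
  if (!identical(g$sample_id, y$sample_id)) {
    abort("genotype and phenotype sample_ids are not aligned")
  }
  invisible(TRUE)
}
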