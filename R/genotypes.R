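#' Construct a genotype dataset
#'
#' Holds an individuals-by-SNPs dosage matrix, the binary phenotype, and an
#' optional severity stratum for cases. Dosage `d[i, j]` counts copies
#' (0/1/2) of the panel's `counted_allele` for SNP `j` in individual `i`;
#' missing genotypes are `NA`. Column order and orientation always follow the
#' panel, so datasets from different files are directly comparable.
#'
#' @param dosage integer matrix, individuals x SNPs, values in `{0,1,2,NA}`;
#'   column names must be panel snp_ids.
#' @param panel the [variant_panel()] the columns map to (subset allowed,
#'   same order as columns).
#' @param phenotype 0 = control, 1 = case; `NA` if unknown.
#' @param severity per-individual label, one of `"none"`, `"mild"`,
#'   `"moderate_severe"`; controls are `"none"`.
#' @param sample_id character vector of unique sample identifiers.
#' @param absent_snps panel SNPs that could not be resolved in the source
#'   file (kept so they are reported, never silently dropped).
#' @return A `genotype_dataset` list.
#' @export
genotype_dataset <- function(dosage, panel, phenotype = NULL, severity = NULL,
                             sample_id = NULL, absent_snps = character(0)) {
  dosage <- as.matrix(dosage)
  n <- nrow(dosage)
  if (is.null(sample_id)) sample_id <- sprintf("S%04d", seq_len(n))
  if (is.null(phenotype)) phenotype <- rep(NA_integer_, n)
  if (is.null(severity)) severity <- rep("none", n)
  phenotype <- as.integer(phenotype)
  if (anyDuplicated(sample_id)) stop("sample_ids must be unique")
  if (length(phenotype) != n || length(severity) != n || length(sample_id) != n) {
    stop("sample_id, phenotype and severity must match nrow(dosage)")
  }
  if (!all(phenotype %in% c(0L, 1L, NA_integer_))) {
    stop("phenotype must be 0 (control), 1 (case) or NA")
  }
  if (!all(severity %in% c("none", "mild", "moderate_severe"))) {
    stop("severity must be one of none, mild, moderate_severe")
  }
  bad <- !(dosage %in% c(0L, 1L, 2L)) & !is.na(dosage)
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  if (is.null(colnames(dosage))) colnames(dosage) <- panel$snp_id
  if (!identical(colnames(dosage), panel$snp_id)) {
    stop("dosage columns must match the panel snp_ids (same order)")
  }
  rownames(dosage) <- NULL
  structure(
    list(sample_id = as.character(sample_id),
         dosage = dosage,
         phenotype = phenotype,
         severity = as.character(severity),
         panel = panel,
         absent_snps = as.character(absent_snps)),
    class = "genotype_dataset"
  )
}

#' @export
print.genotype_dataset <- function(x, ...) {
  n_case <- sum(x$phenotype == 1L, na.rm = TRUE)
  n_ctrl <- sum(x$phenotype == 0L, na.rm = TRUE)
  cat(sprintf("genotype_dataset: %d individuals x %d SNPs (%d cases, %d controls)\n",
              nrow(x$dosage), ncol(x$dosage), n_case, n_ctrl))
  if (length(x$absent_snps)) {
    cat("  absent panel SNPs:", paste(x$absent_snps, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of individuals in a genotype dataset
#' @param dataset a `genotype_dataset`.
#' @return integer count.
#' @export
n_individuals <- function(dataset) nrow(dataset$dosage)

#' Flip the counted allele of selected SNP columns
#'
#' Replaces dosage `g` with `2 - g` and swaps counted/other alleles in the
#' panel for the given SNPs. Applying the same flip twice restores the
#' original dataset exactly (missing stays missing).
#'
#' @param dataset a `genotype_dataset`.
#' @param snp_ids SNPs to flip (default: all).
#' @return The re-oriented `genotype_dataset`.
#' @export
flip_counted_allele <- function(dataset, snp_ids = dataset$panel$snp_id) {
  j <- match(snp_ids, dataset$panel$snp_id)
  if (anyNA(j)) stop("unknown snp_id(s): ",
                     paste(snp_ids[is.na(j)], collapse = ", "))
  dataset$dosage[, j] <- 2L - dataset$dosage[, j]
  tmp <- dataset$panel$counted_allele[j]
  dataset$panel$counted_allele[j] <- dataset$panel$other_allele[j]
  dataset$panel$other_allele[j] <- tmp
  dataset
}

#' Restrict a dataset to a subset of individuals
#' @param dataset a `genotype_dataset`.
#' @param idx logical or integer index over individuals.
#' @return The subset `genotype_dataset`.
#' @export
subset_individuals <- function(dataset, idx) {
  genotype_dataset(
    dosage = dataset$dosage[idx, , drop = FALSE],
    panel = dataset$panel,
    phenotype = dataset$phenotype[idx],
    severity = dataset$severity[idx],
    sample_id = dataset$sample_id[idx],
    absent_snps = dataset$absent_snps
  )
}
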