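#' Read genotypes into a panel-oriented dataset
#'
#' Reads a genotype file and orients every resolved SNP to the panel's
#' counted allele: when the file counts the other allele the stored dosage is
#' `2 - g` and the alleles are effectively swapped. SNPs the file does not
#' contain are recorded in `absent_snps`, never silently dropped. Alleles are
#' compared literally; a SNP matching the panel in neither orientation is a
#' hard error (no strand-flip guessing, which would corrupt weights for
#' ambiguous A/T and C/G variants).
#'
#' @param path genotype file. For `dialect = "vcf"` a VCF 4.x file with GT
#'   genotypes; for `dialect = "plink_raw"` a PLINK `--recode A` style text
#'   file (header `FID IID PAT MAT SEX PHENOTYPE` then one `rsid_ALLELE`
#'   column per SNP, the allele suffix being the counted allele; `NA` marks
#'   missing).
#' @param panel the [variant_panel()] to orient against.
#' @param dialect `"vcf"` or `"plink_raw"`.
#' @param phenotype optional phenotype TSV path (columns `sample_id`,
#'   `phenotype`, optional `severity`) or a data frame with those columns.
#'   For `plink_raw`, the file's own PHENOTYPE column (1 = control,
#'   2 = case) is used when no explicit phenotype is supplied.
#' @return A [genotype_dataset()].
#' @export
read_genotypes <- function(path, panel, dialect = c("vcf", "plink_raw"),
                           phenotype = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  ds <- switch(dialect,
    vcf = read_genotypes_vcf(path, panel),
    plink_raw = read_genotypes_plink_raw(path, panel)
  )
  if (!is.null(phenotype)) ds <- attach_phenotype(ds, phenotype)
  ds
}

read_genotypes_vcf <- function(path, panel) {
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("failed to parse VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ids <- fix[, "ID"]
  locus <- paste(fix[, "CHROM"], fix[, "POS"], sep = ":")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  samples <- colnames(gt)
  n <- length(samples)

  dosage <- matrix(NA_integer_, nrow = n, ncol = nrow(panel),
                   dimnames = list(NULL, panel$snp_id))
  absent <- character(0)
  for (j in seq_len(nrow(panel))) {
    row <- match(panel$snp_id[j], ids)
    if (is.na(row)) {
      row <- match(paste(panel$chrom[j], panel$pos[j], sep = ":"), locus)
    }
    if (is.na(row)) {
      absent <- c(absent, panel$snp_id[j])
      next
    }
    ref <- toupper(unname(fix[row, "REF"]))
    alt <- toupper(unname(fix[row, "ALT"]))
    g <- parse_gt_calls(gt[row, ], panel$snp_id[j])
    if (alt == panel$counted_allele[j] && ref == panel$other_allele[j]) {
      dosage[, j] <- g
    } else if (ref == panel$counted_allele[j] && alt == panel$other_allele[j]) {
      dosage[, j] <- 2L - g
    } else {
      stop("allele mismatch for ", panel$snp_id[j], ": file REF/ALT = ",
           ref, "/", alt, ", panel alleles = ", panel$counted_allele[j],
           "/", panel$other_allele[j])
    }
  }
  keep <- !(panel$snp_id %in% absent)
  genotype_dataset(
    dosage = dosage[, keep, drop = FALSE],
    panel = panel[keep, , drop = FALSE],
    sample_id = samples,
    absent_snps = absent
  )
}

# ALT-allele copy count from a vector of GT strings ("0/1", "1|1", "./.")
parse_gt_calls <- function(calls, snp_id) {
  vapply(calls, function(x) {
    if (is.na(x) || x %in% c(".", "./.", ".|.")) return(NA_integer_)
    alleles <- strsplit(x, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_integer_)
    av <- suppressWarnings(as.integer(alleles))
    if (anyNA(av) || any(av > 1L) || length(av) != 2L) {
      stop("unsupported GT '", x, "' at ", snp_id,
           " (only biallelic diploid 0/1 calls are handled)")
    }
    sum(av)
  }, integer(1), USE.NAMES = FALSE)
}

read_genotypes_plink_raw <- function(path, panel) {
  raw <- tryCatch(
    utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                      check.names = FALSE, na.strings = "NA"),
    error = function(e) stop("failed to parse plink_raw '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  meta_cols <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  snp_cols <- setdiff(names(raw), meta_cols)
  m <- regmatches(snp_cols, regexec("^(.+)_([ACGT]+)$", snp_cols))
  bad <- lengths(m) != 3L
  if (any(bad)) {
    stop("cannot parse counted allele from column(s): ",
         paste(snp_cols[bad], collapse = ", "))
  }
  file_ids <- vapply(m, `[`, "", 2L)
  file_alleles <- vapply(m, `[`, "", 3L)

  n <- nrow(raw)
  dosage <- matrix(NA_integer_, nrow = n, ncol = nrow(panel),
                   dimnames = list(NULL, panel$snp_id))
  absent <- character(0)
  for (j in seq_len(nrow(panel))) {
    k <- match(panel$snp_id[j], file_ids)
    if (is.na(k)) {
      absent <- c(absent, panel$snp_id[j])
      next
    }
    g <- as.integer(raw[[snp_cols[k]]])
    if (any(!is.na(g) & !(g %in% 0:2))) {
      stop("non 0/1/2 dosage for ", panel$snp_id[j], " in ", path)
    }
    if (file_alleles[k] == panel$counted_allele[j]) {
      dosage[, j] <- g
    } else if (file_alleles[k] == panel$other_allele[j]) {
      dosage[, j] <- 2L - g
    } else {
      stop("allele mismatch for ", panel$snp_id[j], ": file counts ",
           file_alleles[k], ", panel alleles = ", panel$counted_allele[j],
           "/", panel$other_allele[j])
    }
  }
  pheno <- rep(NA_integer_, n)
  if ("PHENOTYPE" %in% names(raw)) {
    pheno <- ifelse(raw$PHENOTYPE %in% c(1, 2), as.integer(raw$PHENOTYPE) - 1L,
                    NA_integer_)
  }
  keep <- !(panel$snp_id %in% absent)
  genotype_dataset(
    dosage = dosage[, keep, drop = FALSE],
    panel = panel[keep, , drop = FALSE],
    phenotype = pheno,
    sample_id = if ("IID" %in% names(raw)) as.character(raw$IID) else NULL,
    absent_snps = absent
  )
}

attach_phenotype <- function(dataset, phenotype) {
  tab <- if (is.character(phenotype)) read_phenotypes(phenotype) else phenotype
  idx <- match(dataset$sample_id, tab$sample_id)
  if (anyNA(idx)) {
    stop("phenotype table missing sample(s): ",
         paste(utils::head(dataset$sample_id[is.na(idx)], 5), collapse = ", "))
  }
  dataset$phenotype <- as.integer(tab$phenotype[idx])
  if (!is.null(tab$severity)) dataset$severity <- as.character(tab$severity[idx])
  genotype_dataset(dataset$dosage, dataset$panel, dataset$phenotype,
                   dataset$severity, dataset$sample_id, dataset$absent_snps)
}

#' Read a phenotype table
#'
#' TSV with header `sample_id`, `phenotype` (0 = control, 1 = case) and
#' optionally `severity` (`none`/`mild`/`moderate_severe`).
#'
#' @param path TSV path.
#' @return A data frame.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("sample_id", "phenotype") %in% names(tab))) {
    stop("phenotype file needs columns sample_id, phenotype")
  }
  tab$sample_id <- as.character(tab$sample_id)
  tab
}

#' Write a genotype dataset
#'
#' `dialect = "vcf"` writes an uncompressed VCF 4.2 with GT genotypes,
#' REF = other allele and ALT = counted allele, missing as `./.`;
#' `dialect = "plink_raw"` writes a PLINK additive-recode text table with
#' `NA` for missing and PHENOTYPE coded 1/2 (control/case, -9 unknown).
#' Output is deterministic: rewriting the same dataset is byte-identical.
#'
#' @param dataset a [genotype_dataset()].
#' @param path output file path.
#' @param dialect `"vcf"` or `"plink_raw"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(dataset, path, dialect = c("vcf", "plink_raw")) {
  dialect <- match.arg(dialect)
  panel <- dataset$panel
  if (dialect == "vcf") {
    gt_codes <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    lines <- c(
      "##fileformat=VCFv4.2",
      "##source=drugpgs",
      '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              "FORMAT", dataset$sample_id), collapse = "\t")
    )
    body <- vapply(seq_len(nrow(panel)), function(j) {
      g <- dataset$dosage[, j]
      calls <- ifelse(is.na(g), "./.", gt_codes[as.character(g)])
      paste(c(panel$chrom[j], panel$pos[j], panel$snp_id[j],
              panel$other_allele[j], panel$counted_allele[j],
              ".", "PASS", ".", "GT", calls), collapse = "\t")
    }, character(1))
    writeLines(c(lines, body), path)
  } else {
    pheno <- ifelse(is.na(dataset$phenotype), -9L, dataset$phenotype + 1L)
    header <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE",
                paste0(panel$snp_id, "_", panel$counted_allele))
    rows <- vapply(seq_len(nrow(dataset$dosage)), function(i) {
      g <- dataset$dosage[i, ]
      paste(c(dataset$sample_id[i], dataset$sample_id[i], "0", "0", "0",
              pheno[i], ifelse(is.na(g), "NA", as.character(g))),
            collapse = " ")
    }, character(1))
    writeLines(c(paste(header, collapse = " "), rows), path)
  }
  invisible(path)
}

#' Write a phenotype table alongside a genotype file
#'
#' @param dataset a [genotype_dataset()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(dataset, path) {
  tab <- data.frame(sample_id = dataset$sample_id,
                    phenotype = dataset$phenotype,
                    severity = dataset$severity,
                    stringsAsFactors = FALSE)
  write_tsv_deterministic(tab, path)
}
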