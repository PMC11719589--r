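#' Construct a variant panel
#'
#' A variant panel is the fixed set of SNPs a polygenic score is built over:
#' identifiers, coordinates, the allele whose copies are counted in dosages,
#' the other allele, and a reference minor-allele frequency (a fraction, not
#' a percentage). Positions are 1-based (VCF convention) and are treated as
#' build-agnostic labels: genotype files are matched by rsID first and by
#' chrom:pos only as a fallback.
#'
#' @param snp_id character vector of unique rsIDs.
#' @param chrom chromosome labels.
#' @param pos 1-based positions (positive integers).
#' @param counted_allele allele whose copies the dosage counts (A/C/G/T or
#'   multi-base).
#' @param other_allele the other allele; must differ from `counted_allele`.
#' @param maf_reference reference MAF as a fraction in `[0, 0.5]`.
#' @param gene optional gene symbol, carried as annotation only.
#' @return A `variant_panel`: a data frame with one row per SNP.
#' @export
variant_panel <- function(snp_id, chrom, pos, counted_allele, other_allele,
                          maf_reference, gene = NA_character_) {
  panel <- data.frame(
    snp_id = as.character(snp_id),
    chrom = as.character(chrom),
    pos = as.integer(pos),
    counted_allele = toupper(as.character(counted_allele)),
    other_allele = toupper(as.character(other_allele)),
    maf_reference = as.numeric(maf_reference),
    gene = as.character(gene),
    stringsAsFactors = FALSE
  )
  validate_panel(panel)
  class(panel) <- c("variant_panel", "data.frame")
  panel
}

validate_panel <- function(panel) {
  if (anyDuplicated(panel$snp_id)) {
    stop("panel snp_ids must be unique: ",
         paste(unique(panel$snp_id[duplicated(panel$snp_id)]), collapse = ", "))
  }
  if (any(panel$counted_allele == panel$other_allele)) {
    bad <- panel$snp_id[panel$counted_allele == panel$other_allele]
    stop("counted_allele equals other_allele for: ", paste(bad, collapse = ", "))
  }
  if (any(is.na(panel$pos)) || any(panel$pos <= 0)) {
    stop("panel positions must be positive integers")
  }
  if (any(is.na(panel$maf_reference)) ||
      any(panel$maf_reference < 0) || any(panel$maf_reference > 0.5)) {
    stop("maf_reference must lie in [0, 0.5]")
  }
  invisible(panel)
}

#' Read a variant panel from TSV
#'
#' Expects a tab-separated file with header columns `snp_id`, `chrom`, `pos`,
#' `counted_allele`, `other_allele`, `maf_reference` and optionally `gene`.
#'
#' @param path path to the TSV file.
#' @return A [variant_panel()].
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, colClasses = "character")
  required <- c("snp_id", "chrom", "pos", "counted_allele", "other_allele",
                "maf_reference")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("panel file missing column(s): ", paste(missing, collapse = ", "))
  }
  variant_panel(
    snp_id = tab$snp_id, chrom = tab$chrom, pos = as.integer(tab$pos),
    counted_allele = tab$counted_allele, other_allele = tab$other_allele,
    maf_reference = as.numeric(tab$maf_reference),
    gene = if ("gene" %in% names(tab)) tab$gene else NA_character_
  )
}

#' The built-in 26-SNP asthma drug-pathway panel
#'
#' The default panel of 26 biallelic SNPs in genes involved in the metabolism
#' of anti-asthmatic drugs (glucocorticosteroids, beta-2-agonists,
#' antihistamines, antileukotrienes) or implicated in treatment response by
#' GWAS. `maf_reference` holds the control-group MAF of the Volga-Ural study
#' sample the panel was characterised in; the simulator uses these as its
#' default allele frequencies. Metadata are taken as published, including the
#' gene label "TFT" for rs2305089 and two distinct ARG2 loci.
#'
#' @return A [variant_panel()] with 26 rows.
#' @export
default_panel <- function() {
  read_panel(system.file("extdata", "asthma_panel.tsv", package = "drugpgs",
                         mustWork = TRUE))
}

#' The built-in LD-proxy map for panel SNPs absent from TAGC summary statistics
#'
#' Seven panel SNPs are not present in the external GWAS summary statistics;
#' for each, a published LD proxy supplies the weight instead. The pairwise
#' r-squared values were established externally (1000 Genomes LD lookups) and
#' are not re-derivable here, so the `r2` column is `NA`: the map itself is
#' the assertion of admissible LD. [build_weight_set()] accepts `NA` r2 as
#' user-asserted with a note; supply numeric r2 to enforce the threshold.
#'
#' @return A data frame with columns `missing_snp`, `proxy_snp`, `r2`.
#' @export
default_proxy_map <- function() {
  tab <- utils::read.table(
    system.file("extdata", "tagc_proxy_map.tsv", package = "drugpgs",
                mustWork = TRUE),
    header = TRUE, sep = "\t", stringsAsFactors = FALSE,
    na.strings = "NA",
    colClasses = c("character", "character", "numeric")
  )
  tab
}
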