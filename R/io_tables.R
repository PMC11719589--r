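#' Read GWAS summary statistics
#'
#' TSV with header columns `snp_id`, `effect_allele`, `other_allele`,
#' `beta` (log-odds per effect allele), `se` and optionally `n`. Alleles are
#' upper-cased; duplicate snp_ids and non-positive standard errors are
#' rejected. A header-only file yields an empty table.
#'
#' @param path TSV path.
#' @return A `summary_stats` data frame.
#' @export
read_summary_stats <- function(path) {
  if (!file.exists(path)) stop("summary statistics file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  required <- c("snp_id", "effect_allele", "other_allele", "beta", "se")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("summary statistics missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (!"n" %in% names(tab)) tab$n <- NA_real_
  tab <- tab[, c(required, "n")]
  tab$snp_id <- as.character(tab$snp_id)
  tab$effect_allele <- toupper(as.character(tab$effect_allele))
  tab$other_allele <- toupper(as.character(tab$other_allele))
  tab$beta <- as.numeric(tab$beta)
  tab$se <- as.numeric(tab$se)
  if (nrow(tab)) {
    if (anyDuplicated(tab$snp_id)) {
      stop("duplicated snp_id in summary statistics: ",
           paste(unique(tab$snp_id[duplicated(tab$snp_id)]), collapse = ", "))
    }
    if (anyNA(tab$se) || any(tab$se <= 0)) {
      stop("summary statistics require se > 0 for every row")
    }
    if (anyNA(tab$beta)) stop("summary statistics contain non-numeric beta")
  }
  class(tab) <- c("summary_stats", "data.frame")
  tab
}

#' Read a weight set from TSV
#'
#' @param path TSV with columns `snp_id`, `risk_allele`, `weight`, `source`,
#'   `beta_origin`.
#' @return A `weight_set` data frame (see [build_weight_set()]).
#' @export
read_weight_set <- function(path) {
  if (!file.exists(path)) stop("weight file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  required <- c("snp_id", "risk_allele", "weight", "source", "beta_origin")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("weight file missing column(s): ", paste(missing, collapse = ", "))
  }
  new_weight_set(tab[, required])
}

# Deterministic TSV writer: numerics formatted to 8 significant digits so a
# rewrite of identical results is byte-identical.
write_tsv_deterministic <- function(tab, path) {
  out <- tab
  for (k in seq_along(out)) {
    if (is.double(out[[k]])) {
      v <- sprintf("%.8g", out[[k]])
      v[is.na(out[[k]])] <- "NA"
      out[[k]] <- v
    }
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "NA")
    TRUE
  }, error = function(e) {
    stop("cannot write '", path, "': ", conditionMessage(e), call. = FALSE)
  })
  invisible(path)
}

#' Write a set of result tables to a directory
#'
#' Writes each table in `tables` as `<name>.tsv` under `out_dir` with
#' deterministic column order and numeric formatting (8 significant digits),
#' so identical results produce byte-identical files.
#'
#' @param tables named list of data frames.
#' @param out_dir output directory (created if needed).
#' @return Character vector of file paths written, invisibly.
#' @export
write_results <- function(tables, out_dir) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    write_tsv_deterministic(as.data.frame(tables[[nm]]), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
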