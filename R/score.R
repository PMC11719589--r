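#' Compute the weighted polygenic score per individual
#'
#' The raw score is `sum_j weight_j * riskdosage_ij`, where the risk dosage
#' is the stored dosage `g` when the risk allele is the panel's counted
#' allele and `2 - g` otherwise — so the score is invariant to how each SNP
#' happens to be oriented on disk. Missing genotypes are handled by
#' `missing_policy`: `"mean_impute"` (default) replaces a missing risk
#' dosage by `2 * q_risk` with `q_risk` the control-sample risk-allele
#' frequency; `"skip_rescale"` omits missing SNPs and rescales the partial
#' sum by total/used weight.
#'
#' @param dataset a [genotype_dataset()] containing every weight-set SNP.
#' @param weight_set a `weight_set` from [build_weight_set()].
#' @param missing_policy `"mean_impute"` or `"skip_rescale"`.
#' @return A `pgs_vector` data frame: `sample_id`, `raw_score`, `z_score`
#'   (standardized over this dataset), `n_snps_used`, `n_imputed`.
#' @export
compute_pgs <- function(dataset, weight_set,
                        missing_policy = c("mean_impute", "skip_rescale")) {
  missing_policy <- match.arg(missing_policy)
  panel <- dataset$panel
  j <- match(weight_set$snp_id, panel$snp_id)
  if (anyNA(j)) {
    stop("weight-set SNP(s) absent from dataset: ",
         paste(weight_set$snp_id[is.na(j)], collapse = ", "),
         " (scores over a silently shrunken panel are not comparable)")
  }
  # risk-allele orientation per weight entry
  risk_is_counted <- weight_set$risk_allele == panel$counted_allele[j]
  risk_is_other <- weight_set$risk_allele == panel$other_allele[j]
  if (any(!risk_is_counted & !risk_is_other)) {
    bad <- weight_set$snp_id[!risk_is_counted & !risk_is_other]
    stop("risk allele matches neither panel allele for: ",
         paste(bad, collapse = ", "))
  }
  g <- dataset$dosage[, j, drop = FALSE]
  rd <- sweep(g, 2, ifelse(risk_is_counted, 0, 2), function(x, a) abs(a - x))
  w <- weight_set$weight

  miss <- is.na(rd)
  n_imputed <- rowSums(miss)
  n_used <- ncol(rd) - n_imputed
  if (missing_policy == "mean_impute") {
    is_ctrl <- !is.na(dataset$phenotype) & dataset$phenotype == 0L
    ref <- if (any(is_ctrl)) rd[is_ctrl, , drop = FALSE] else {
      warning("no controls in dataset; imputing from the full sample")
      rd
    }
    q_risk <- colMeans(ref, na.rm = TRUE) / 2
    if (anyNA(q_risk)) stop("cannot impute: a SNP is entirely missing in the reference stratum")
    for (k in which(colSums(miss) > 0)) rd[miss[, k], k] <- 2 * q_risk[k]
    raw <- as.vector(rd %*% w)
  } else {
    rd0 <- rd
    rd0[miss] <- 0
    used_w <- as.vector((!miss) %*% w)
    raw <- as.vector(rd0 %*% w)
    scale <- ifelse(used_w > 0, sum(w) / used_w, NA_real_)
    raw <- raw * scale
    if (sum(w) == 0) raw[] <- 0   # all-zero weights: score is identically 0
  }
  sd_raw <- stats::sd(raw)
  z <- if (!is.na(sd_raw) && sd_raw > 0) (raw - mean(raw)) / sd_raw else
    rep(0, length(raw))
  out <- data.frame(sample_id = dataset$sample_id, raw_score = raw,
                    z_score = z, n_snps_used = n_used, n_imputed = n_imputed,
                    stringsAsFactors = FALSE)
  class(out) <- c("pgs_vector", "data.frame")
  out
}

#' Association of the polygenic score with disease status
#'
#' Logistic regression of case status on the standardized score within the
#' analysed stratum: `stratum = "all_cases"` uses every case against every
#' control; `stratum = "moderate_severe"` uses only cases with that severity
#' label against all controls. The score is re-standardized over the pooled
#' individuals of the stratum analysed, so the odds ratio is per standard
#' deviation of the PGS in that analysis sample (the per-SD unit is a
#' reporting convention, echoed in the output).
#'
#' @param pgs a `pgs_vector` from [compute_pgs()] (aligned with `dataset`).
#' @param dataset the [genotype_dataset()] supplying phenotype and severity.
#' @param stratum `"all_cases"` or `"moderate_severe"`.
#' @return A one-row `score_association` data frame: `stratum`, `or_per_sd`,
#'   `ci_low`, `ci_high`, `p`, `n_cases`, `n_controls`, `scale`.
#' @export
score_association <- function(pgs, dataset,
                              stratum = c("all_cases", "moderate_severe")) {
  stratum <- match.arg(stratum)
  y <- dataset$phenotype
  keep <- !is.na(y) & (y == 0L |
    (y == 1L & (stratum == "all_cases" |
                  dataset$severity == "moderate_severe")))
  raw <- pgs$raw_score[keep]
  yy <- y[keep]
  if (sum(yy == 1L) < 2 || sum(yy == 0L) < 2) {
    stop("need at least 2 cases and 2 controls in stratum ", stratum)
  }
  if (stats::sd(raw) == 0) stop("score variance is zero; association undefined")
  z <- (raw - mean(raw)) / stats::sd(raw)
  fit <- stats::glm(yy ~ z, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-12, maxit = 50))
  co <- summary(fit)$coefficients
  b <- co["z", "Estimate"]
  se <- co["z", "Std. Error"]
  out <- data.frame(
    stratum = stratum,
    or_per_sd = exp(b),
    ci_low = exp(b - 1.96 * se),
    ci_high = exp(b + 1.96 * se),
    p = 2 * stats::pnorm(-abs(b / se)),
    n_cases = sum(yy == 1L),
    n_controls = sum(yy == 0L),
    scale = "per_sd",
    stringsAsFactors = FALSE
  )
  class(out) <- c("score_association", "data.frame")
  out
}
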