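#' Counted-allele frequency and MAF of one SNP column
#'
#' @param dosages vector of dosages in `{0,1,2,NA}`.
#' @return List with `freq` (counted-allele frequency, `sum(d) / (2 n)` over
#'   non-missing calls) and `maf = min(freq, 1 - freq)`.
#' @export
compute_maf <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  if (!length(d)) stop("cannot compute MAF: all dosages missing")
  freq <- sum(d) / (2 * length(d))
  list(freq = freq, maf = min(freq, 1 - freq))
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test: given the observed allele counts, every possible
#' heterozygote count has probability proportional to
#' `n! / (n_AA! n_Aa! n_aa!) * 2^n_het`; the p-value is the total probability
#' of configurations no more likely than the observed one. A monomorphic SNP
#' has a single configuration and p = 1.
#'
#' @param n_hom_minor,n_het,n_hom_major non-negative genotype counts.
#' @return The exact p-value in `(0, 1]`.
#' @export
hwe_exact_test <- function(n_hom_minor, n_het, n_hom_major) {
  counts <- c(n_hom_minor, n_het, n_hom_major)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("genotype counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n < 1) stop("need at least one genotyped individual")
  na <- 2 * n_hom_minor + n_het          # copies of the minor allele
  hets <- seq(na %% 2, min(na, 2 * n - na), by = 2)
  logw <- lgamma(n + 1) - lgamma((na - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma((2 * n - na - hets) / 2 + 1) + hets * log(2)
  w <- exp(logw - max(logw))
  p_obs <- w[match(n_het, hets)]
  sum(w[w <= p_obs * (1 + 1e-10)]) / sum(w)
}

#' Squared dosage correlation (LD r-squared) between two SNPs
#'
#' Squared Pearson correlation of dosages over pairwise-complete
#' individuals.
#'
#' @param dosages_a,dosages_b dosage vectors of equal length.
#' @return r-squared in `[0, 1]`.
#' @export
ld_r2 <- function(dosages_a, dosages_b) {
  ok <- !is.na(dosages_a) & !is.na(dosages_b)
  if (sum(ok) < 2) stop("need at least 2 pairwise-complete individuals")
  a <- dosages_a[ok]
  b <- dosages_b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    stop("r2 undefined: zero dosage variance")
  }
  stats::cor(a, b)^2
}

#' Log-additive logistic association of one SNP
#'
#' Maximum-likelihood fit of `logit P(case) = alpha + beta * g` by
#' iteratively reweighted least squares (via [stats::glm()], tolerance 1e-12,
#' at most 50 iterations). `beta` is the log-odds per copy of the counted
#' allele, SE comes from the observed information, and the p-value is the
#' two-sided Wald normal tail of `z = beta / se`. Individuals with missing
#' dosage are excluded (`n_used` reports the complete cases). Non-convergence
#' or (quasi-)complete separation yields `converged = FALSE` with `NA`
#' statistics, never a silent number.
#'
#' @param dosages dosage vector in `{0,1,2,NA}`.
#' @param phenotype 0/1 vector.
#' @param snp_id,counted_allele identifiers carried into the result.
#' @return One-row `association_result` data frame with columns `snp_id`,
#'   `counted_allele`, `beta`, `se`, `z`, `p`, `n_used`, `converged`.
#' @export
fit_logistic_logadditive <- function(dosages, phenotype,
                                     snp_id = NA_character_,
                                     counted_allele = NA_character_) {
  ok <- !is.na(dosages) & !is.na(phenotype)
  g <- as.numeric(dosages[ok])
  y <- as.integer(phenotype[ok])
  if (length(unique(y)) < 2) stop("both cases and controls are required")
  if (stats::var(g) == 0) stop("SNP is monomorphic among non-missing individuals")

  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ g, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-12, maxit = 50)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separated <<- TRUE
      }
      invokeRestart("muffleWarning")
    }
  )
  converged <- isTRUE(fit$converged) && !separated
  if (converged) {
    # Newton polish from the IRLS solution: quadratic convergence puts the
    # MLE and its observed-information SE at machine precision.
    X <- cbind(1, g)
    th <- stats::coef(fit)
    info <- NULL
    for (it in 1:3) {
      mu <- stats::plogis(as.vector(X %*% th))
      info <- crossprod(X, X * (mu * (1 - mu)))
      step <- tryCatch(solve(info, crossprod(X, y - mu)),
                       error = function(e) NULL)
      if (is.null(step)) break
      th <- th + as.vector(step)
    }
    beta <- unname(th[2])
    se <- unname(sqrt(diag(solve(info)))[2])
    z <- beta / se
    p <- 2 * stats::pnorm(-abs(z))
    p <- max(p, .Machine$double.xmin)   # keep p in (0, 1]
  } else {
    beta <- se <- z <- p <- NA_real_
  }
  out <- data.frame(snp_id = snp_id, counted_allele = counted_allele,
                    beta = beta, se = se, z = z, p = p,
                    n_used = length(y), converged = converged,
                    stringsAsFactors = FALSE)
  class(out) <- c("association_result", "data.frame")
  out
}

#' Per-SNP association scan over a dataset
#'
#' Fits [fit_logistic_logadditive()] for every panel SNP. SNPs that are
#' monomorphic in the analysed sample are reported with `converged = FALSE`
#' and `NA` statistics rather than aborting the scan.
#'
#' @param dataset a [genotype_dataset()] with phenotype.
#' @return An `association_result` data frame, one row per panel SNP.
#' @export
assoc_scan <- function(dataset) {
  panel <- dataset$panel
  rows <- lapply(seq_len(nrow(panel)), function(j) {
    tryCatch(
      fit_logistic_logadditive(dataset$dosage[, j], dataset$phenotype,
                               snp_id = panel$snp_id[j],
                               counted_allele = panel$counted_allele[j]),
      error = function(e) {
        data.frame(snp_id = panel$snp_id[j],
                   counted_allele = panel$counted_allele[j],
                   beta = NA_real_, se = NA_real_, z = NA_real_, p = NA_real_,
                   n_used = sum(!is.na(dataset$dosage[, j]) &
                                  !is.na(dataset$phenotype)),
                   converged = FALSE, stringsAsFactors = FALSE)
      }
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("association_result", "data.frame")
  out
}

#' Per-SNP quality-control report
#'
#' MAF in controls and overall, HWE exact p (on controls by default, the
#' standard QC stratum; set `hwe_stratum = "all"` for the combined sample)
#' and call rate.
#'
#' @param dataset a [genotype_dataset()].
#' @param hwe_stratum `"controls"` or `"all"`.
#' @return A `qc_report` data frame, one row per panel SNP.
#' @export
qc_report <- function(dataset, hwe_stratum = c("controls", "all")) {
  hwe_stratum <- match.arg(hwe_stratum)
  panel <- dataset$panel
  is_ctrl <- !is.na(dataset$phenotype) & dataset$phenotype == 0L
  if (hwe_stratum == "controls" && !any(is_ctrl)) {
    stop("no controls available for HWE testing; use hwe_stratum = 'all'")
  }
  rows <- lapply(seq_len(nrow(panel)), function(j) {
    d_all <- dataset$dosage[, j]
    d_ctrl <- d_all[is_ctrl]
    d_hwe <- if (hwe_stratum == "controls") d_ctrl else d_all
    d_hwe <- d_hwe[!is.na(d_hwe)]
    hwe_p <- if (length(d_hwe)) {
      hwe_exact_test(sum(d_hwe == 2L), sum(d_hwe == 1L), sum(d_hwe == 0L))
    } else NA_real_
    data.frame(
      snp_id = panel$snp_id[j],
      maf_controls = if (any(!is.na(d_ctrl))) compute_maf(d_ctrl)$maf else NA_real_,
      maf_all = if (any(!is.na(d_all))) compute_maf(d_all)$maf else NA_real_,
      hwe_p = hwe_p,
      call_rate = mean(!is.na(d_all)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("qc_report", "data.frame")
  out
}

#' Greedy LD pruning ordered by association p-value
#'
#' SNPs are visited in order of ascending association p-value (ties and
#' missing p after, in panel order); a SNP is kept iff its dosage r-squared
#' with every already-kept SNP is at or below `threshold`. Each removal is
#' recorded with the kept SNP and the r-squared that triggered it.
#'
#' @param dataset a [genotype_dataset()].
#' @param assoc optional precomputed [assoc_scan()] result.
#' @param threshold r-squared above which a SNP is pruned (default 0.2).
#' @return List with `keep` (snp_ids retained) and `removed` (data frame
#'   `snp_id`, `blocked_by`, `r2`).
#' @export
prune_by_ld <- function(dataset, assoc = NULL, threshold = 0.2) {
  if (is.null(assoc)) assoc <- assoc_scan(dataset)
  panel_ids <- dataset$panel$snp_id
  p <- assoc$p[match(panel_ids, assoc$snp_id)]
  ord <- order(ifelse(is.na(p), Inf, p), seq_along(panel_ids))
  keep <- integer(0)
  removed <- list()
  for (j in ord) {
    blocked <- NA_integer_
    r2_hit <- NA_real_
    for (k in keep) {
      r2 <- tryCatch(ld_r2(dataset$dosage[, j], dataset$dosage[, k]),
                     error = function(e) NA_real_)
      if (!is.na(r2) && r2 > threshold) {
        blocked <- k
        r2_hit <- r2
        break
      }
    }
    if (is.na(blocked)) {
      keep <- c(keep, j)
    } else {
      removed[[length(removed) + 1L]] <- data.frame(
        snp_id = panel_ids[j], blocked_by = panel_ids[blocked], r2 = r2_hit,
        stringsAsFactors = FALSE)
    }
  }
  removed <- if (length(removed)) do.call(rbind, removed) else
    data.frame(snp_id = character(0), blocked_by = character(0),
               r2 = numeric(0), stringsAsFactors = FALSE)
  list(keep = panel_ids[sort(keep)], removed = removed)
}
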