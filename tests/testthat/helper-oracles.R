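# Small fixture builders and independent oracles used across test files.

# A minimal panel with given counted-allele frequencies.
tiny_panel <- function(q, ids = sprintf("rs%d", seq_along(q))) {
  variant_panel(
    snp_id = ids, chrom = rep("1", length(q)),
    pos = seq_along(q) * 1000L,
    counted_allele = rep("A", length(q)), other_allele = rep("G", length(q)),
    maf_reference = pmin(q, 1 - q)
  )
}

# Dataset straight from a dosage matrix and phenotype.
make_dataset <- function(dosage, phenotype, severity = NULL, q = NULL) {
  m <- ncol(dosage)
  panel <- tiny_panel(if (is.null(q)) rep(0.3, m) else q)
  colnames(dosage) <- panel$snp_id
  genotype_dataset(dosage, panel, phenotype = phenotype, severity = severity)
}

# HWE exact-test oracle: Wigginton-style recurrence over heterozygote counts
# (independent of the package's direct log-multinomial summation).
hwe_oracle <- function(n_hom_minor, n_het, n_hom_major) {
  n <- n_hom_minor + n_het + n_hom_major
  na <- 2 * n_hom_minor + n_het
  hets <- seq(na %% 2, min(na, 2 * n - na), by = 2)
  probs <- numeric(length(hets))
  probs[1] <- 1
  if (length(hets) > 1) {
    for (k in seq_len(length(hets) - 1)) {
      h <- hets[k]
      hom_r <- (na - h) / 2
      hom_c <- (2 * n - na - h) / 2
      # P(h + 2) / P(h) = 4 * hom_r * hom_c / ((h + 2) * (h + 1))
      probs[k + 1] <- probs[k] * 4 * hom_r * hom_c / ((h + 2) * (h + 1))
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, hets)]
  sum(probs[probs <= p_obs * (1 + 1e-10)])
}

# Pairwise Mann-Whitney AUC oracle (brute force over all case/control pairs).
auc_bruteforce <- function(scores, labels) {
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  cmp <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Generic ML logistic fit via optim (independent of glm's IRLS).
logistic_ml_oracle <- function(g, y) {
  nll <- function(par) {
    eta <- par[1] + par[2] * g
    -sum(y * eta - log1p(exp(eta)))
  }
  fit <- stats::optim(c(0, 0), nll, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 1000))
  fit$par[2]
}
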