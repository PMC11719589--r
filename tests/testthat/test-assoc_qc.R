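test_that("counted-allele frequency and MAF follow the dosage arithmetic", {
  expect_equal(compute_maf(c(0, 1, 1, 2)), list(freq = 0.5, maf = 0.5))
  expect_equal(compute_maf(c(0, 0, 0))$maf, 0)
  expect_equal(compute_maf(c(2, 2, NA))$freq, 1)   # missing excluded
  expect_error(compute_maf(c(NA, NA)), "missing")
})

test_that("MAF of simulated controls recovers the generating frequency", {
  cfg <- sim_config(panel = tiny_panel(0.3783), n_cases = 200L,
                    n_controls = 2000L, seed = 21)
  ds <- simulate_case_control(cfg)
  maf <- compute_maf(ds$dosage[ds$phenotype == 0L, 1])$maf
  se <- sqrt(0.3783 * (1 - 0.3783) / (2 * 2000))
  expect_lt(abs(maf - 0.3783), 3 * se)
})

test_that("HWE exact test matches hand enumeration and boundaries", {
  expect_equal(hwe_exact_test(0, 0, 25), 1)
  expect_equal(hwe_exact_test(1, 0, 1), 1 / 3, tolerance = 1e-12)
  set.seed(1)
  for (i in 1:50) {
    n <- sample(1:50, 1)
    a <- sample(0:n, 1)
    h <- sample(0:(n - a), 1)
    expect_equal(hwe_exact_test(a, h, n - a - h), hwe_oracle(a, h, n - a - h),
                 tolerance = 1e-12)
  }
  expect_error(hwe_exact_test(-1, 0, 1), "non-negative")
})

test_that("dosage r2 matches hand-computed values and detects degeneracy", {
  a <- c(0, 1, 2, 0)
  expect_equal(ld_r2(a, a), 1)
  expect_equal(ld_r2(a, c(0, 1, 2, 2)), (1.25 / 2.75)^2, tolerance = 1e-12)
  expect_error(ld_r2(c(1, 1, 1), c(0, 1, 2)), "variance")
  # missing handled pairwise-complete
  expect_equal(ld_r2(c(0, 1, 2, NA), c(0, 1, 2, 0)), 1)
})

test_that("independent SNPs show near-zero r2", {
  set.seed(8)
  hits <- replicate(100, {
    a <- rbinom(5000, 2, 0.3)
    b <- rbinom(5000, 2, 0.3)
    ld_r2(a, b) < 0.01
  })
  expect_gte(mean(hits), 0.99)
})

test_that("logistic fit reproduces the 2x2 closed form for binary dosages", {
  g <- rep(c(1, 1, 0, 0), c(30, 70, 10, 90))
  y <- rep(c(1, 0, 1, 0), c(30, 70, 10, 90))
  fit <- fit_logistic_logadditive(g, y)
  expect_equal(fit$beta, log(30 * 90 / (70 * 10)), tolerance = 1e-6)
  expect_equal(fit$se, sqrt(1 / 30 + 1 / 70 + 1 / 10 + 1 / 90),
               tolerance = 1e-6)
  expect_equal(fit$p, 2 * pnorm(-abs(fit$beta / fit$se)), tolerance = 1e-12)
  expect_equal(fit$n_used, 200)
})

test_that("logistic fit agrees with an independent ML optimizer", {
  set.seed(17)
  for (i in 1:10) {
    n <- sample(50:500, 1)
    g <- rbinom(n, 2, runif(1, 0.1, 0.5))
    y <- rbinom(n, 1, plogis(-0.3 + 0.4 * g))
    if (length(unique(y)) < 2 || var(g) == 0) next
    fit <- fit_logistic_logadditive(g, y)
    expect_equal(fit$beta, logistic_ml_oracle(g, y), tolerance = 1e-6)
  }
})

test_that("beta is antisymmetric under allele flip with unchanged SE", {
  set.seed(23)
  g <- rbinom(300, 2, 0.4)
  y <- rbinom(300, 1, plogis(-0.5 + 0.3 * g))
  a <- fit_logistic_logadditive(g, y)
  b <- fit_logistic_logadditive(2 - g, y)
  expect_equal(b$beta, -a$beta, tolerance = 1e-9)
  expect_equal(b$se, a$se, tolerance = 1e-9)
})

test_that("degenerate fits are flagged, never silent numbers", {
  expect_error(fit_logistic_logadditive(rep(1, 10), rep(c(0, 1), 5)),
               "monomorphic")
  expect_error(fit_logistic_logadditive(rbinom(10, 2, 0.5), rep(1, 10)),
               "both cases and controls")
  # complete separation
  g <- rep(c(0, 2), each = 20)
  y <- rep(c(0, 1), each = 20)
  fit <- fit_logistic_logadditive(g, y)
  expect_false(fit$converged)
  expect_true(is.na(fit$p))
})

test_that("greedy LD pruning keeps the most significant of correlated sets", {
  set.seed(31)
  n <- 400
  base <- rbinom(n, 2, 0.4)
  # three mutually near-duplicate SNPs + one independent
  d <- cbind(base,
             ifelse(rbinom(n, 1, 0.95) == 1, base, rbinom(n, 2, 0.4)),
             base,
             rbinom(n, 2, 0.3))
  y <- rbinom(n, 1, plogis(-0.2 + 0.5 * base))
  ds <- make_dataset(d, phenotype = y)
  assoc <- assoc_scan(ds)
  pr <- prune_by_ld(ds, assoc, threshold = 0.2)
  expect_length(intersect(pr$keep, c("rs1", "rs2", "rs3")), 1)
  expect_true("rs4" %in% pr$keep)
  # the kept one is the smallest p of the correlated trio
  trio_p <- assoc$p[assoc$snp_id %in% c("rs1", "rs2", "rs3")]
  kept_p <- assoc$p[assoc$snp_id == intersect(pr$keep, c("rs1", "rs2", "rs3"))]
  expect_equal(kept_p, min(trio_p))
  expect_true(all(pr$removed$r2 > 0.2))
})

test_that("uncorrelated panels survive pruning intact", {
  ds <- simulate_case_control(sim_config(seed = 12))
  pr <- prune_by_ld(ds, threshold = 0.2)
  expect_length(pr$keep, 26)
  expect_equal(nrow(pr$removed), 0)
})

test_that("QC report covers MAF, HWE stratum and call rate", {
  set.seed(41)
  cfg <- sim_config(panel = tiny_panel(c(0.2, 0.4)), n_cases = 300L,
                    n_controls = 300L, missing_rate = 0.1, seed = 41)
  ds <- simulate_case_control(cfg)
  qc <- qc_report(ds)
  expect_equal(nrow(qc), 2)
  expect_true(all(qc$hwe_p > 0 & qc$hwe_p <= 1))
  expect_true(all(qc$maf_controls <= 0.5))
  expect_true(all(qc$call_rate > 0.8 & qc$call_rate < 1))
  # combined-sample stratum is available as a flag
  qc_all <- qc_report(ds, hwe_stratum = "all")
  expect_false(identical(qc$hwe_p, qc_all$hwe_p))
})
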