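make_ws <- function(snp_id, risk_allele, weight) {
  drugpgs:::new_weight_set(data.frame(
    snp_id = snp_id, risk_allele = risk_allele, weight = weight,
    source = "local", beta_origin = weight, stringsAsFactors = FALSE))
}

test_that("the raw score is the weighted sum of risk-allele dosages", {
  d <- matrix(c(2L, 0L,   # individual 1: rs1 = 2, rs2 = 0 (counted allele)
                0L, 1L), 2, 2, byrow = TRUE)
  ds <- make_dataset(d, phenotype = c(1L, 0L))
  # rs2's risk allele is the OTHER allele: risk dosage = 2 - g
  ws <- make_ws(c("rs1", "rs2"), c("A", "G"), c(0.5, 1.0))
  pgs <- compute_pgs(ds, ws)
  expect_equal(pgs$raw_score[1], 0.5 * 2 + 1.0 * (2 - 0))   # = 3
  expect_equal(pgs$raw_score[2], 0.5 * 0 + 1.0 * (2 - 1))   # = 1
  expect_equal(pgs$n_imputed, c(0, 0))
})

test_that("mean imputation contributes 2 q w from the control frequency", {
  # controls have risk-allele frequency 0.25 at rs1
  d <- matrix(c(NA, 1L, 0L, 0L, 1L), 5, 1)
  ds <- make_dataset(d, phenotype = c(1L, 0L, 0L, 0L, 0L))
  ws <- make_ws("rs1", "A", 1.0)
  pgs <- compute_pgs(ds, ws, missing_policy = "mean_impute")
  expect_equal(pgs$raw_score[1], 0.5)   # 2 * 0.25 * 1.0
  expect_equal(pgs$n_imputed[1], 1)
})

test_that("skip_rescale omits missing SNPs and rescales by total weight", {
  d <- matrix(c(2L, NA,
                2L, 2L), 2, 2, byrow = TRUE)
  ds <- make_dataset(d, phenotype = c(1L, 0L))
  ws <- make_ws(c("rs1", "rs2"), c("A", "A"), c(1, 3))
  pgs <- compute_pgs(ds, ws, missing_policy = "skip_rescale")
  expect_equal(pgs$raw_score[1], 2 * 1 * (4 / 1))   # used weight 1 of 4
  expect_equal(pgs$raw_score[2], 8)
})

test_that("scores are invariant to stored orientation", {
  set.seed(3)
  cfg <- sim_config(panel = tiny_panel(c(0.2, 0.4, 0.3)),
                    n_cases = 100L, n_controls = 100L, seed = 3)
  ds <- simulate_case_control(cfg)
  ws <- make_ws(c("rs1", "rs2", "rs3"), c("A", "G", "A"), c(0.4, 0.3, 0.2))
  flipped <- flip_counted_allele(ds)   # dosage 2 - g, alleles swapped
  expect_equal(compute_pgs(ds, ws)$raw_score,
               compute_pgs(flipped, ws)$raw_score)
})

test_that("a weight-set SNP absent from the dataset is a hard error", {
  ds <- make_dataset(matrix(0:1, 2, 1), phenotype = c(0L, 1L))
  ws <- make_ws(c("rs1", "rs_missing"), c("A", "A"), c(0.5, 0.5))
  expect_error(compute_pgs(ds, ws), "rs_missing")
})

test_that("all-zero weights give identically zero scores", {
  ds <- make_dataset(matrix(rbinom(20, 2, 0.3), 10, 2),
                     phenotype = rep(c(0L, 1L), 5))
  ws <- make_ws(c("rs1", "rs2"), c("A", "A"), c(0, 0))
  expect_true(all(compute_pgs(ds, ws)$raw_score == 0))
})

test_that("score-disease OR is null when distributions coincide", {
  set.seed(5)
  cfg <- sim_config(panel = tiny_panel(c(0.3, 0.4)), n_cases = 500L,
                    n_controls = 500L, seed = 5)
  ds <- simulate_case_control(cfg)
  ws <- make_ws(c("rs1", "rs2"), c("A", "A"), c(0.3, 0.2))
  pgs <- compute_pgs(ds, ws)
  sa <- score_association(pgs, ds)
  expect_lt(sa$ci_low, 1.25)
  expect_gt(sa$ci_high, 0.8)
})

test_that("OR per SD matches an independent ML fit on the same draws", {
  set.seed(7)
  n <- 50000
  raw <- c(rnorm(n, 0.5, 1), rnorm(n, 0, 1))
  y <- rep(c(1L, 0L), each = n)
  ds <- make_dataset(matrix(rep(0:1, n), 2 * n, 1), phenotype = y)
  pgs <- data.frame(sample_id = ds$sample_id, raw_score = raw,
                    z_score = scale(raw)[, 1], n_snps_used = 1, n_imputed = 0)
  sa <- score_association(pgs, ds)
  z <- (raw - mean(raw)) / sd(raw)
  b_oracle <- logistic_ml_oracle(z, y)
  expect_equal(log(sa$or_per_sd), b_oracle, tolerance = 0.03 * abs(b_oracle))
})

test_that("severity stratum uses moderate-severe cases against all controls", {
  ds <- simulate_case_control(sim_config(seed = 15))
  assoc <- assoc_scan(ds)
  ws <- build_weight_set(ds$panel, assoc, mode = "local")
  pgs <- compute_pgs(ds, ws)
  sa <- score_association(pgs, ds, stratum = "moderate_severe")
  expect_equal(sa$n_cases, 174)
  expect_equal(sa$n_controls, 504)
})

test_that("OR per SD and AUC are invariant to weight rescaling and null SNPs", {
  set.seed(9)
  cfg <- sim_config(panel = tiny_panel(c(0.3, 0.4, 0)), n_cases = 200L,
                    n_controls = 200L, seed = 9)
  ds <- simulate_case_control(cfg)   # rs3 is monomorphic (zero variance)
  ws1 <- make_ws(c("rs1", "rs2"), c("A", "A"), c(0.4, 0.2))
  ws2 <- make_ws(c("rs1", "rs2"), c("A", "A"), 10 * c(0.4, 0.2))
  ws3 <- make_ws(c("rs1", "rs2", "rs3"), c("A", "A", "A"), c(0.4, 0.2, 0.7))
  p1 <- compute_pgs(ds, ws1); p2 <- compute_pgs(ds, ws2)
  p3 <- compute_pgs(ds, ws3)
  a1 <- score_association(p1, ds); a2 <- score_association(p2, ds)
  a3 <- score_association(p3, ds)
  expect_equal(a1$or_per_sd, a2$or_per_sd, tolerance = 1e-8)
  expect_equal(a1$or_per_sd, a3$or_per_sd, tolerance = 1e-8)
  y <- ds$phenotype
  expect_equal(roc_auc(p1$raw_score, y)$auc, roc_auc(p2$raw_score, y)$auc)
  expect_equal(roc_auc(p1$raw_score, y)$auc, roc_auc(p3$raw_score, y)$auc)
})
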