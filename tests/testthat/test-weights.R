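test_that("fixed-effect meta-analysis pools by inverse variance", {
  one <- meta_fixed_effect(list(study_effect(0.3, 0.15)))
  expect_equal(one$beta, 0.3)
  expect_equal(one$se, 0.15)

  m <- meta_fixed_effect(list(study_effect(0.2, 0.1), study_effect(0.4, 0.2)))
  expect_equal(m$beta, 0.24, tolerance = 1e-12)          # weights 100 and 25
  expect_equal(m$se, sqrt(1 / 125), tolerance = 1e-12)   # 0.089443

  k <- 7
  rep7 <- meta_fixed_effect(replicate(k, study_effect(0.3, 0.12),
                                      simplify = FALSE))
  expect_equal(rep7$beta, 0.3, tolerance = 1e-12)
  expect_equal(rep7$se, 0.12 / sqrt(k), tolerance = 1e-12)

  expect_error(meta_fixed_effect(list()), "at least one")
})

test_that("leave-one-study-out inversion undoes the pooling", {
  m <- meta_fixed_effect(list(study_effect(0.2, 0.1), study_effect(0.4, 0.2)))
  loo <- remove_study_from_meta(m, study_effect(0.4, 0.2))
  expect_equal(loo$beta, 0.2, tolerance = 1e-10)
  expect_equal(loo$se, 0.1, tolerance = 1e-10)

  # zero-weight limit: a removed study with enormous SE changes nothing
  loo0 <- remove_study_from_meta(m, study_effect(5, 1e8))
  expect_equal(loo0$beta, m$beta, tolerance = 1e-8)
  expect_equal(loo0$se, m$se, tolerance = 1e-8)

  # removing at least the whole pooled precision is non-invertible
  expect_error(remove_study_from_meta(study_effect(0.2, 0.1),
                                      study_effect(0.2, 0.1)), "invert")
  expect_error(remove_study_from_meta(study_effect(0.2, 0.1),
                                      study_effect(0.2, 0.05)), "invert")
})

test_that("removal equals re-pooling the remaining studies (property)", {
  set.seed(19)
  for (i in 1:50) {
    k <- sample(3:10, 1)
    studies <- lapply(seq_len(k), function(j)
      study_effect(runif(1, -1, 1), runif(1, 0.01, 1)))
    full <- meta_fixed_effect(studies)
    drop_k <- sample(k, 1)
    loo <- remove_study_from_meta(full, studies[[drop_k]])
    rest <- meta_fixed_effect(studies[-drop_k])
    expect_equal(loo$beta, rest$beta, tolerance = 1e-10)
    expect_equal(loo$se, rest$se, tolerance = 1e-10)
  }
})

test_that("fixed-effect pooling agrees with metafor", {
  skip_if_not_installed("metafor")
  set.seed(29)
  beta <- rnorm(5); se <- runif(5, 0.05, 0.5)
  ours <- meta_fixed_effect(Map(study_effect, beta, se))
  ref <- metafor::rma(yi = beta, sei = se, method = "FE")
  expect_equal(ours$beta, as.numeric(ref$beta), tolerance = 1e-8)
  expect_equal(ours$se, as.numeric(ref$se), tolerance = 1e-8)
})

test_that("risk alleles follow the sign of the local association", {
  panel <- tiny_panel(c(0.3, 0.3, 0.3))  # counted A, other G
  row <- function(id, b) data.frame(snp_id = id, counted_allele = "A",
                                    beta = b, se = 0.1, z = b / 0.1, p = 0.5,
                                    n_used = 100, converged = TRUE)
  pos <- assign_risk_allele(row("rs1", 0.4707), panel)
  expect_equal(pos$risk_allele, "A")
  expect_equal(pos$weight, 0.4707)

  neg <- assign_risk_allele(row("rs2", -0.3), panel)
  expect_equal(neg$risk_allele, "G")
  expect_equal(neg$weight, 0.3)

  tie <- assign_risk_allele(row("rs3", 0), panel)
  expect_equal(tie$risk_allele, "A")
  expect_equal(tie$weight, 0)

  bad <- row("rs1", 0.2); bad$converged <- FALSE
  expect_error(assign_risk_allele(bad, panel), "converge")
})

# Local associations for a panel, fabricated with known betas.
fake_assoc <- function(panel, beta) {
  data.frame(snp_id = panel$snp_id, counted_allele = panel$counted_allele,
             beta = beta, se = 0.1, z = beta / 0.1, p = 0.5,
             n_used = 100, converged = TRUE, stringsAsFactors = FALSE)
}

test_that("local weight sets take |beta| with local provenance", {
  panel <- tiny_panel(c(0.2, 0.3))
  ws <- build_weight_set(panel, fake_assoc(panel, c(0.5, -0.2)), mode = "local")
  expect_equal(ws$weight, c(0.5, 0.2))
  expect_equal(ws$source, c("local", "local"))
  expect_equal(ws$risk_allele, c("A", "G"))
})

test_that("GWAS-corrected weights invert the meta-analysis per SNP", {
  panel <- tiny_panel(c(0.2, 0.3, 0.4))
  local <- fake_assoc(panel, c(0.3, -0.2, 0.1))
  # external meta = pooled {cohortA, cohortB}; removing B must recover |betaA|
  betaA <- c(0.25, -0.15, 0.05); seA <- c(0.05, 0.06, 0.07)
  betaB <- c(0.4, 0.1, -0.2); seB <- c(0.1, 0.12, 0.09)
  pooled <- Map(function(a, sa, b, sb)
    meta_fixed_effect(list(study_effect(a, sa), study_effect(b, sb))),
    betaA, seA, betaB, seB)
  ss <- data.frame(snp_id = panel$snp_id, effect_allele = "A",
                   other_allele = "G",
                   beta = vapply(pooled, `[[`, 0, "beta"),
                   se = vapply(pooled, `[[`, 0, "se"), n = NA_real_)
  removed <- data.frame(snp_id = panel$snp_id, beta = betaB, se = seB)
  ws <- build_weight_set(panel, local, summary_stats = ss,
                         removed_cohort = removed, mode = "gwas_corrected")
  expect_equal(ws$weight, abs(betaA), tolerance = 1e-10)
  expect_equal(ws$source, rep("gwas_corrected", 3))
  # orientation still follows the local sign
  expect_equal(ws$risk_allele, c("A", "G", "A"))
})

test_that("external effects with swapped alleles are sign-flipped, others rejected", {
  panel <- tiny_panel(0.3)
  local <- fake_assoc(panel, 0.3)
  ss_swap <- data.frame(snp_id = "rs1", effect_allele = "G",
                        other_allele = "A", beta = -0.25, se = 0.05,
                        n = NA_real_)
  ws <- build_weight_set(panel, local, summary_stats = ss_swap,
                         mode = "gwas_corrected")
  expect_equal(ws$beta_origin, 0.25)   # flipped to the counted allele
  ss_bad <- transform(ss_swap, effect_allele = "C", other_allele = "T")
  expect_error(build_weight_set(panel, local, summary_stats = ss_bad,
                                mode = "gwas_corrected"), "mismatch")
})

test_that("absent SNPs borrow admissible proxies; others are dropped and counted", {
  panel <- tiny_panel(c(0.2, 0.3, 0.4))
  local <- fake_assoc(panel, c(0.3, -0.2, 0.1))
  # rs2 and rs3 absent; rs2 has a strong proxy, rs3's proxy is too weak
  ss <- data.frame(snp_id = c("rs1", "rsP2", "rsP3"),
                   effect_allele = c("A", "T", "T"),
                   other_allele = c("G", "C", "C"),
                   beta = c(0.2, 0.6, 0.9), se = c(0.05, 0.04, 0.04),
                   n = NA_real_)
  pm <- data.frame(missing_snp = c("rs2", "rs3"),
                   proxy_snp = c("rsP2", "rsP3"), r2 = c(0.9, 0.3))
  expect_warning(
    ws <- build_weight_set(panel, local, summary_stats = ss, proxy_map = pm,
                           mode = "gwas_corrected", proxy_r2 = 0.8),
    "rs3")
  expect_equal(ws$source[ws$snp_id == "rs2"], "proxy:rsP2")
  expect_equal(ws$weight[ws$snp_id == "rs2"], 0.6)
  # local orientation preserved for the proxied SNP (local beta < 0)
  expect_equal(ws$risk_allele[ws$snp_id == "rs2"], "G")
  expect_identical(attr(ws, "dropped"), "rs3")
  expect_equal(nrow(ws) + length(attr(ws, "dropped")), nrow(panel))
})

test_that("the shipped proxy map covers the seven SNPs absent from TAGC", {
  pm <- default_proxy_map()
  expect_setequal(pm$missing_snp,
                  c("rs13182402", "rs41423247", "rs2781667", "rs37973",
                    "rs1049793", "rs7140310", "rs11000016"))
  panel <- default_panel()
  expect_true(all(pm$missing_snp %in% panel$snp_id))
  # full-panel accounting: 19 typed + 7 proxied when the proxies are present
  local <- fake_assoc(panel, rep(0.1, 26))
  local$counted_allele <- panel$counted_allele
  typed <- setdiff(panel$snp_id, pm$missing_snp)
  ss <- data.frame(
    snp_id = c(typed, pm$proxy_snp),
    effect_allele = c(panel$counted_allele[match(typed, panel$snp_id)],
                      rep("A", 7)),
    other_allele = c(panel$other_allele[match(typed, panel$snp_id)],
                     rep("G", 7)),
    beta = 0.1, se = 0.05, n = NA_real_)
  ws <- suppressMessages(
    build_weight_set(panel, local, summary_stats = ss, proxy_map = pm,
                     mode = "gwas_corrected"))
  expect_equal(sum(ws$source == "gwas_corrected"), 19)
  expect_equal(sum(startsWith(ws$source, "proxy:")), 7)
  expect_length(attr(ws, "dropped"), 0)
})
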