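#' A study effect (log-odds and standard error)
#'
#' @param beta log-odds effect estimate.
#' @param se standard error, finite and positive.
#' @return A `study_effect` list.
#' @export
study_effect <- function(beta, se) {
  if (!is.finite(beta)) stop("beta must be finite")
  if (!is.finite(se) || se <= 0) stop("se must be finite and positive")
  structure(list(beta = beta, se = se), class = "study_effect")
}

#' Fixed-effect inverse-variance meta-analysis
#'
#' Pools study effects with precision weights `1/se^2`:
#' `beta_meta = sum(beta_k / se_k^2) / sum(1 / se_k^2)` and
#' `se_meta = sqrt(1 / sum(1 / se_k^2))`.
#'
#' @param effects list of [study_effect()] objects (at least one).
#' @return The pooled [study_effect()].
#' @export
meta_fixed_effect <- function(effects) {
  if (!length(effects)) stop("meta-analysis requires at least one study")
  if (inherits(effects, "study_effect")) effects <- list(effects)
  beta <- vapply(effects, function(e) e$beta, numeric(1))
  se <- vapply(effects, function(e) e$se, numeric(1))
  if (any(se <= 0)) stop("all standard errors must be positive")
  w <- 1 / se^2
  study_effect(sum(w * beta) / sum(w), sqrt(1 / sum(w)))
}

#' Remove one study from a fixed-effect meta-analysis result
#'
#' Inverts the inverse-variance pooling formula to subtract one study's
#' contribution: with precisions `W = 1/se_meta^2` and `w = 1/se_removed^2`,
#' `beta_loo = (W * beta_meta - w * beta_removed) / (W - w)` and
#' `se_loo = sqrt(1 / (W - w))`. This is the leave-one-cohort-out
#' correction applied to external GWAS effects when one contributing cohort
#' overlaps the analysis sample.
#'
#' @param meta the pooled [study_effect()].
#' @param removed the [study_effect()] of the study to remove; its precision
#'   must be strictly smaller than the pooled precision.
#' @return The [study_effect()] of the remaining studies.
#' @export
remove_study_from_meta <- function(meta, removed) {
  W <- 1 / meta$se^2
  w <- 1 / removed$se^2
  if (w >= W) {
    stop("cannot invert meta-analysis: removed study's precision (",
         format(w), ") is not strictly below the pooled precision (",
         format(W), ")")
  }
  study_effect((W * meta$beta - w * removed$beta) / (W - w), sqrt(1 / (W - w)))
}

#' Orient a weight entry by the sign of a local association
#'
#' The risk allele is the allele associated with increased disease odds in
#' the local (in-sample) regression: the counted allele when `beta > 0`,
#' otherwise the other allele (risk dosage `2 - g`). The weight is `|beta|`.
#' `beta = 0` keeps the counted allele with weight 0 (documented tie rule).
#'
#' @param assoc one row of an `association_result` (must have converged).
#' @param panel the [variant_panel()] (supplies the other allele).
#' @param weight_beta optional externally derived log-odds (e.g. a corrected
#'   GWAS effect, oriented to the counted allele) to use as `beta_origin`
#'   instead of the local beta; the risk allele still follows the local sign.
#' @param source provenance label.
#' @return One-row weight-set data frame.
#' @export
assign_risk_allele <- function(assoc, panel, weight_beta = NULL,
                               source = "local") {
  if (!isTRUE(assoc$converged)) {
    stop("cannot orient ", assoc$snp_id, ": association did not converge")
  }
  j <- match(assoc$snp_id, panel$snp_id)
  if (is.na(j)) stop("SNP not in panel: ", assoc$snp_id)
  risk <- if (assoc$beta >= 0) panel$counted_allele[j] else panel$other_allele[j]
  beta_origin <- if (is.null(weight_beta)) assoc$beta else weight_beta
  data.frame(snp_id = assoc$snp_id, risk_allele = risk,
             weight = abs(beta_origin), source = source,
             beta_origin = beta_origin, stringsAsFactors = FALSE)
}

new_weight_set <- function(tab, dropped = character(0)) {
  if (!nrow(tab)) stop("weight set is empty")
  if (any(tab$weight < 0)) stop("weights must be non-negative")
  rownames(tab) <- NULL
  structure(tab, dropped = dropped, class = c("weight_set", "data.frame"))
}

#' Build the per-SNP weight set for scoring
#'
#' Two weighting designs are supported. `mode = "local"` takes each panel
#' SNP's weight from the in-sample association (`|beta|`). In
#' `mode = "gwas_corrected"` weights come from external GWAS summary
#' statistics: the external beta is sign-aligned to the panel's counted
#' allele (literal allele match required), corrected by
#' [remove_study_from_meta()] when the overlapping cohort's effect for that
#' SNP is supplied, and otherwise used as-is. Panel SNPs absent from the
#' summary statistics borrow the (corrected) beta of an LD proxy from
#' `proxy_map`, provided the proxy's r-squared meets `proxy_r2` (an `NA`
#' r-squared is accepted as user-asserted LD, with a message); SNPs with no
#' admissible proxy are dropped with a warning and listed in the `dropped`
#' attribute. Risk alleles are always oriented by the local association, in
#' both designs.
#'
#' @param panel the [variant_panel()].
#' @param local_assoc [assoc_scan()] result on the analysis sample.
#' @param summary_stats [read_summary_stats()] table
#'   (required for `mode = "gwas_corrected"`).
#' @param removed_cohort optional data frame (`snp_id`, `beta`, `se`) of the
#'   overlapping cohort's per-SNP effects, oriented to the summary-stats
#'   effect allele.
#' @param proxy_map optional data frame (`missing_snp`, `proxy_snp`, `r2`).
#' @param mode `"local"` or `"gwas_corrected"`.
#' @param proxy_r2 minimum proxy r-squared (default 0.8).
#' @return A `weight_set` data frame (`snp_id`, `risk_allele`, `weight`,
#'   `source`, `beta_origin`) with attribute `dropped`.
#' @export
build_weight_set <- function(panel, local_assoc, summary_stats = NULL,
                             removed_cohort = NULL, proxy_map = NULL,
                             mode = c("local", "gwas_corrected"),
                             proxy_r2 = 0.8) {
  mode <- match.arg(mode)
  rows <- list()
  dropped <- character(0)

  for (j in seq_len(nrow(panel))) {
    sid <- panel$snp_id[j]
    la <- local_assoc[local_assoc$snp_id == sid, , drop = FALSE]
    if (nrow(la) != 1) stop("local association missing for panel SNP ", sid)
    if (!isTRUE(la$converged)) {
      warning("dropping ", sid, ": local association did not converge")
      dropped <- c(dropped, sid)
      next
    }
    if (mode == "local") {
      rows[[sid]] <- assign_risk_allele(la, panel, source = "local")
      next
    }
    # gwas_corrected
    if (is.null(summary_stats)) stop("mode 'gwas_corrected' needs summary_stats")
    ss <- summary_stats[summary_stats$snp_id == sid, , drop = FALSE]
    if (nrow(ss) == 1) {
      eff <- align_external_effect(ss, panel[j, ])
      eff <- correct_for_cohort(eff, sid, removed_cohort,
                                flip = attr(eff, "flipped"))
      rows[[sid]] <- assign_risk_allele(la, panel, weight_beta = eff$beta,
                                        source = "gwas_corrected")
    } else {
      pr <- if (is.null(proxy_map)) NULL else
        proxy_map[proxy_map$missing_snp == sid, , drop = FALSE]
      if (is.null(pr) || nrow(pr) == 0) {
        warning("dropping ", sid, ": absent from summary stats and no proxy")
        dropped <- c(dropped, sid)
        next
      }
      pr <- pr[1, ]
      admissible <- if (is.na(pr$r2)) {
        message("proxy ", pr$proxy_snp, " for ", sid,
                ": r2 not supplied, accepted as user-asserted LD")
        TRUE
      } else pr$r2 >= proxy_r2
      ssp <- summary_stats[summary_stats$snp_id == pr$proxy_snp, , drop = FALSE]
      if (!admissible || nrow(ssp) != 1) {
        warning("dropping ", sid, ": proxy ", pr$proxy_snp,
                if (!admissible) paste0(" below r2 threshold ", proxy_r2)
                else " absent from summary stats")
        dropped <- c(dropped, sid)
        next
      }
      eff <- study_effect(ssp$beta, ssp$se)
      eff <- correct_for_cohort(eff, pr$proxy_snp, removed_cohort, flip = FALSE)
      # proxy beta magnitude used unmodified (no r2 attenuation); the sign
      # orientation of an untyped SNP is taken from the local regression
      beta_origin <- sign_or_pos(la$beta) * abs(eff$beta)
      rows[[sid]] <- assign_risk_allele(la, panel, weight_beta = beta_origin,
                                        source = paste0("proxy:", pr$proxy_snp))
    }
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab) || !nrow(tab)) stop("resulting weight set is empty")
  new_weight_set(tab, dropped = dropped)
}

sign_or_pos <- function(x) if (x < 0) -1 else 1

# Orient an external effect to the panel's counted allele; literal allele
# match required, no strand inference.
align_external_effect <- function(ss, panel_row) {
  if (ss$effect_allele == panel_row$counted_allele &&
      ss$other_allele == panel_row$other_allele) {
    out <- study_effect(ss$beta, ss$se)
    attr(out, "flipped") <- FALSE
  } else if (ss$effect_allele == panel_row$other_allele &&
             ss$other_allele == panel_row$counted_allele) {
    out <- study_effect(-ss$beta, ss$se)
    attr(out, "flipped") <- TRUE
  } else {
    stop("allele mismatch for ", panel_row$snp_id, ": summary stats ",
         ss$effect_allele, "/", ss$other_allele, " vs panel ",
         panel_row$counted_allele, "/", panel_row$other_allele)
  }
  out
}

# Leave-one-cohort-out correction when the removed cohort reports the SNP;
# otherwise the meta value passes through with a note.
correct_for_cohort <- function(eff, sid, removed_cohort, flip = FALSE) {
  if (is.null(removed_cohort)) return(eff)
  rc <- removed_cohort[removed_cohort$snp_id == sid, , drop = FALSE]
  if (nrow(rc) != 1) {
    message("no overlapping-cohort effect for ", sid,
            "; using the uncorrected meta value")
    return(eff)
  }
  b <- if (flip) -rc$beta else rc$beta
  remove_study_from_meta(eff, study_effect(b, rc$se))
}

#' @export
print.weight_set <- function(x, ...) {
  cat(sprintf("weight_set: %d SNPs (%d proxy, %d dropped)\n", nrow(x),
              sum(startsWith(x$source, "proxy:")),
              length(attr(x, "dropped"))))
  print.data.frame(x, ...)
  invisible(x)
}
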