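#' ROC curve and AUC (Mann-Whitney, ties count one half)
#'
#' AUC is the probability a random case scores above a random control, with
#' tied pairs counted 1/2 — computed from midranks, which is exactly the
#' pairwise Mann-Whitney statistic. The curve holds one point per distinct
#' threshold (classify case when `score >= threshold`), from (0,0) at
#' `threshold = Inf` to (1,1); higher score means more case-like.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels (1 = case).
#' @return List with `auc` and `curve` (data frame `threshold`, `fpr`,
#'   `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  ok <- !is.na(scores) & !is.na(labels)
  s <- scores[ok]
  y <- as.integer(labels[ok])
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(s)
  auc <- (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  thr <- sort(unique(s), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(s >= t & y == 1L), numeric(1))
  fp <- vapply(thr, function(t) sum(s >= t & y == 0L), numeric(1))
  curve <- data.frame(threshold = c(Inf, thr),
                      fpr = c(0, fp / n0),
                      tpr = c(0, tp / n1))
  list(auc = auc, curve = curve)
}

# DeLong placement values via midranks (handles ties, O(n log n)).
delong_placements <- function(s, y) {
  r_all <- rank(s)
  v10 <- (r_all[y == 1L] - rank(s[y == 1L])) / sum(y == 0L)
  v01 <- 1 - (r_all[y == 0L] - rank(s[y == 0L])) / sum(y == 1L)
  list(v10 = v10, v01 = v01)
}

#' Confidence interval for the AUC
#'
#' `method = "delong"` uses the DeLong variance from placement values with a
#' normal 95% interval truncated to `[0, 1]`; `method = "bootstrap"` uses a
#' stratified percentile bootstrap. A degenerate variance with AUC 0 or 1
#' collapses the interval to the point, with a warning.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels (1 = case).
#' @param method `"delong"` or `"bootstrap"`.
#' @param boot_reps bootstrap replicates (default 2000).
#' @param seed optional RNG seed for the bootstrap.
#' @return Numeric `c(ci_low, ci_high)`.
#' @export
auc_ci <- function(scores, labels, method = c("delong", "bootstrap"),
                   boot_reps = 2000L, seed = NULL) {
  method <- match.arg(method)
  ok <- !is.na(scores) & !is.na(labels)
  s <- scores[ok]
  y <- as.integer(labels[ok])
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 < 2 || n0 < 2) stop("need at least 2 cases and 2 controls")
  auc <- roc_auc(s, y)$auc

  if (method == "delong") {
    pl <- delong_placements(s, y)
    v <- stats::var(pl$v10) / n1 + stats::var(pl$v01) / n0
    if (v <= 0) {
      if (auc %in% c(0, 1)) {
        warning("degenerate AUC variance; interval collapsed to the point")
        return(c(auc, auc))
      }
      v <- 0
    }
    half <- stats::qnorm(0.975) * sqrt(v)
    return(c(max(0, auc - half), min(1, auc + half)))
  }
  if (!is.null(seed)) set.seed(seed)
  i1 <- which(y == 1L)
  i0 <- which(y == 0L)
  reps <- vapply(seq_len(boot_reps), function(b) {
    idx <- c(sample(i1, n1, replace = TRUE), sample(i0, n0, replace = TRUE))
    roc_auc(s[idx], y[idx])$auc
  }, numeric(1))
  if (stats::var(reps) == 0 && auc %in% c(0, 1)) {
    warning("degenerate AUC variance; interval collapsed to the point")
    return(c(auc, auc))
  }
  unname(stats::quantile(reps, c(0.025, 0.975), type = 7))
}

#' Operating point of an ROC curve
#'
#' With `rule = "youden"`, picks the threshold maximizing
#' `J = sensitivity + specificity - 1` (classify case when
#' `score >= threshold`); ties are broken toward the lower threshold, i.e.
#' the higher sensitivity.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels (1 = case).
#' @param rule operating-point rule; only `"youden"` is implemented.
#' @return List with `threshold`, `sensitivity`, `specificity`, `rule`.
#' @export
operating_point <- function(scores, labels, rule = c("youden")) {
  rule <- match.arg(rule)
  ok <- !is.na(scores) & !is.na(labels)
  s <- scores[ok]
  y <- as.integer(labels[ok])
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  thr <- sort(unique(s))
  sens <- vapply(thr, function(t) sum(s >= t & y == 1L) / n1, numeric(1))
  spec <- vapply(thr, function(t) sum(s < t & y == 0L) / n0, numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))[1]   # thr ascending: first max = lowest threshold
  list(threshold = thr[best], sensitivity = sens[best],
       specificity = spec[best], rule = rule)
}

#' Full ROC summary of a score against labels
#'
#' Bundles [roc_auc()], [auc_ci()] and [operating_point()] into one record.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels (1 = case).
#' @param ci_method `"delong"` (default) or `"bootstrap"`.
#' @param boot_reps,seed passed to [auc_ci()] for the bootstrap.
#' @return A `roc_summary` list: `auc`, `ci_low`, `ci_high`, `threshold`,
#'   `sensitivity`, `specificity`, `rule`, `ci_method`, `n_cases`,
#'   `n_controls`, `curve`.
#' @export
roc_summary <- function(scores, labels, ci_method = c("delong", "bootstrap"),
                        boot_reps = 2000L, seed = NULL) {
  ci_method <- match.arg(ci_method)
  ra <- roc_auc(scores, labels)
  ci <- auc_ci(scores, labels, method = ci_method, boot_reps = boot_reps,
               seed = seed)
  op <- operating_point(scores, labels)
  structure(
    list(auc = ra$auc, ci_low = ci[1], ci_high = ci[2],
         threshold = op$threshold, sensitivity = op$sensitivity,
         specificity = op$specificity, rule = op$rule, ci_method = ci_method,
         n_cases = sum(labels == 1L, na.rm = TRUE),
         n_controls = sum(labels == 0L, na.rm = TRUE),
         curve = ra$curve),
    class = "roc_summary"
  )
}

#' @export
print.roc_summary <- function(x, ...) {
  cat(sprintf("AUC %.4f (95%% CI [%.4f; %.4f], %s)\n", x$auc, x$ci_low,
              x$ci_high, x$ci_method))
  cat(sprintf("%s threshold %.4g: sensitivity %.3f, specificity %.3f (%d cases / %d controls)\n",
              x$rule, x$threshold, x$sensitivity, x$specificity,
              x$n_cases, x$n_controls))
  invisible(x)
}
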