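#' Configure an end-to-end PGS analysis
#'
#' One configuration drives the whole pipeline: data acquisition (simulated
#' or from files), per-SNP QC and association, weight building in one or
#' more designs, scoring, score-disease association per stratum, and ROC
#' evaluation — the two weighting designs by two strata layout of a
#' case-control PGS study.
#'
#' Weight modes: `"local"` estimates weights in the analysis sample itself
#' (the in-sample design; optimistically biased, and flagged as such in the
#' manifest); `"replicate"` draws an independent simulated replicate and
#' takes weights from it (the unbiased out-of-sample design; simulated input
#' only); `"gwas_corrected"` uses external summary statistics with optional
#' leave-one-cohort-out correction and LD-proxy substitution.
#'
#' @param input either a [sim_config()] or a list
#'   `list(genotypes =, dialect =, phenotype =, panel =)` of file paths.
#' @param modes subset of `c("local", "replicate", "gwas_corrected")`.
#' @param strata subset of `c("all_cases", "moderate_severe")`.
#' @param summary_stats,removed_cohort,proxy_map inputs for
#'   `"gwas_corrected"` (paths or data frames; see [build_weight_set()]).
#' @param hwe_alpha HWE flagging level (default 0.05).
#' @param exclude_hwe_failures drop SNPs failing HWE from scoring
#'   (default `FALSE`: flag only).
#' @param ld_prune r-squared pruning threshold (default 0.2).
#' @param proxy_r2 minimum proxy r-squared (default 0.8).
#' @param missing_policy passed to [compute_pgs()].
#' @param ci_method passed to [roc_summary()].
#' @param seed seed for stages beyond simulation (replicate draw, bootstrap).
#' @param out_dir output directory, or `NULL` to skip writing.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input,
                            modes = c("local"),
                            strata = c("all_cases", "moderate_severe"),
                            summary_stats = NULL, removed_cohort = NULL,
                            proxy_map = NULL,
                            hwe_alpha = 0.05, exclude_hwe_failures = FALSE,
                            ld_prune = 0.2, proxy_r2 = 0.8,
                            missing_policy = "mean_impute",
                            ci_method = "delong", seed = 1L, out_dir = NULL) {
  modes <- match.arg(modes, c("local", "replicate", "gwas_corrected"),
                     several.ok = TRUE)
  strata <- match.arg(strata, c("all_cases", "moderate_severe"),
                      several.ok = TRUE)
  if (!length(modes) || !length(strata)) {
    stop("need at least one weight mode and one stratum")
  }
  stopifnot(hwe_alpha > 0, hwe_alpha < 1, ld_prune >= 0, ld_prune <= 1,
            proxy_r2 >= 0, proxy_r2 <= 1)
  if ("gwas_corrected" %in% modes && is.null(summary_stats)) {
    stop("mode 'gwas_corrected' requires summary_stats")
  }
  if ("replicate" %in% modes && !inherits(input, "sim_config")) {
    stop("mode 'replicate' requires simulated input")
  }
  structure(
    list(input = input, modes = modes, strata = strata,
         summary_stats = summary_stats, removed_cohort = removed_cohort,
         proxy_map = proxy_map, hwe_alpha = hwe_alpha,
         exclude_hwe_failures = exclude_hwe_failures, ld_prune = ld_prune,
         proxy_r2 = proxy_r2, missing_policy = missing_policy,
         ci_method = ci_method, seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config"
  )
}

as_table <- function(x) {
  if (is.character(x) && length(x) == 1) return(x)  # path; resolved later
  x
}

resolve_summary_stats <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.character(x)) read_summary_stats(x) else x
}

resolve_tsv <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.character(x)) {
    utils::read.table(x, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  } else x
}

#' Run the full PGS pipeline
#'
#' Executes every configured (weight mode, stratum) cell: QC report, LD
#' pruning, per-SNP association, weight building, scoring, score-disease
#' odds ratios, and ROC summaries. When `out_dir` is set, writes
#' deterministic TSV outputs plus a `manifest.yaml` recording the seed,
#' thresholds, package version, and every dropped or proxied SNP; identical
#' config and seed reproduce the bundle byte for byte.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a result bundle: `dataset`, `qc`, `assoc`, `pruning`,
#'   `weights` (per mode), `scores` (per mode), `score_association` and
#'   `roc` tables, `roc_summaries` (full objects per cell), `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }

  dataset <- stage("input", {
    if (inherits(config$input, "sim_config")) {
      simulate_case_control(config$input)
    } else {
      read_genotypes(config$input$genotypes,
                     panel = if (is.character(config$input$panel))
                       read_panel(config$input$panel) else config$input$panel,
                     dialect = config$input$dialect,
                     phenotype = config$input$phenotype)
    }
  })

  qc <- stage("qc", qc_report(dataset))
  qc$hwe_fail <- !is.na(qc$hwe_p) & qc$hwe_p < config$hwe_alpha
  assoc <- stage("assoc", assoc_scan(dataset))
  pruning <- stage("ld_prune", prune_by_ld(dataset, assoc,
                                           threshold = config$ld_prune))
  keep_ids <- pruning$keep
  if (config$exclude_hwe_failures) {
    keep_ids <- setdiff(keep_ids, qc$snp_id[qc$hwe_fail])
  }
  panel_used <- dataset$panel[dataset$panel$snp_id %in% keep_ids, , drop = FALSE]

  summary_stats <- resolve_summary_stats(config$summary_stats)
  removed_cohort <- resolve_tsv(config$removed_cohort)
  proxy_map <- resolve_tsv(config$proxy_map)

  weights <- list()
  for (mode in config$modes) {
    weights[[mode]] <- stage(paste0("weights_", mode), {
      if (mode == "local") {
        build_weight_set(panel_used, assoc, mode = "local")
      } else if (mode == "gwas_corrected") {
        build_weight_set(panel_used, assoc, summary_stats = summary_stats,
                         removed_cohort = removed_cohort,
                         proxy_map = proxy_map, mode = "gwas_corrected",
                         proxy_r2 = config$proxy_r2)
      } else { # replicate: weights from an independent draw of the same design
        rep_cfg <- config$input
        rep_cfg$seed <- (config$input$seed + 104729L) %% .Machine$integer.max
        rep_ds <- simulate_case_control(rep_cfg)
        rep_assoc <- assoc_scan(rep_ds)
        ws <- build_weight_set(panel_used, rep_assoc, mode = "local")
        ws$source <- "replicate"
        ws
      }
    })
  }

  scores <- list()
  assoc_rows <- list()
  roc_rows <- list()
  roc_objects <- list()
  for (mode in names(weights)) {
    pgs <- stage(paste0("score_", mode),
                 compute_pgs(dataset, weights[[mode]],
                             missing_policy = config$missing_policy))
    scores[[mode]] <- pgs
    for (stratum in config$strata) {
      cell <- paste(mode, stratum, sep = ".")
      sa <- stage(paste0("associate_", cell),
                  score_association(pgs, dataset, stratum = stratum))
      sa <- cbind(mode = mode, sa)
      assoc_rows[[cell]] <- sa
      keep <- !is.na(dataset$phenotype) & (dataset$phenotype == 0L |
        (stratum == "all_cases" | dataset$severity == "moderate_severe"))
      rs <- stage(paste0("roc_", cell),
                  roc_summary(pgs$raw_score[keep], dataset$phenotype[keep],
                              ci_method = config$ci_method,
                              seed = config$seed))
      roc_objects[[cell]] <- rs
      roc_rows[[cell]] <- data.frame(
        mode = mode, stratum = stratum, auc = rs$auc, ci_low = rs$ci_low,
        ci_high = rs$ci_high, threshold = rs$threshold,
        sensitivity = rs$sensitivity, specificity = rs$specificity,
        rule = rs$rule, ci_method = rs$ci_method, n_cases = rs$n_cases,
        n_controls = rs$n_controls, stringsAsFactors = FALSE)
    }
  }
  score_assoc_tab <- do.call(rbind, c(assoc_rows, list(make.row.names = FALSE)))
  roc_tab <- do.call(rbind, c(roc_rows, list(make.row.names = FALSE)))

  manifest <- list(
    package_version = as.character(utils::packageVersion("drugpgs")),
    seed = config$seed,
    input = if (inherits(config$input, "sim_config")) {
      list(type = "simulate", seed = config$input$seed,
           n_cases = config$input$n_cases, n_controls = config$input$n_controls,
           severity_fraction = config$input$severity_fraction,
           missing_rate = config$input$missing_rate)
    } else c(list(type = "files"), config$input),
    thresholds = list(hwe_alpha = config$hwe_alpha,
                      exclude_hwe_failures = config$exclude_hwe_failures,
                      ld_prune = config$ld_prune, proxy_r2 = config$proxy_r2),
    missing_policy = config$missing_policy,
    ci_method = config$ci_method,
    snps_pruned = pruning$removed$snp_id,
    snps_hwe_flagged = qc$snp_id[qc$hwe_fail],
    snps_dropped = lapply(weights, function(w) attr(w, "dropped")),
    snps_proxied = lapply(weights, function(w)
      w$snp_id[startsWith(w$source, "proxy:")]),
    notes = if ("local" %in% names(weights))
      "mode 'local': weights estimated in-sample; AUC/OR optimistically biased"
    else character(0)
  )

  bundle <- list(dataset = dataset, qc = qc, assoc = assoc, pruning = pruning,
                 weights = weights, scores = scores,
                 score_association = score_assoc_tab, roc = roc_tab,
                 roc_summaries = roc_objects, manifest = manifest)

  if (!is.null(config$out_dir)) {
    tables <- list(association = assoc, qc_report = qc,
                   ld_pruning = pruning$removed,
                   score_association = score_assoc_tab,
                   roc_summary = roc_tab)
    for (mode in names(weights)) {
      tables[[paste0("weights_", mode)]] <- as.data.frame(weights[[mode]])
      tables[[paste0("scores_", mode)]] <- scores[[mode]]
    }
    for (cell in names(roc_objects)) {
      tables[[paste0("roc_curve_", gsub("\\.", "_", cell))]] <-
        roc_objects[[cell]]$curve
    }
    stage("write", {
      write_results(tables, config$out_dir)
      yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
    })
  }
  invisible(bundle)
}

#' Read a pipeline configuration from YAML
#'
#' Maps a YAML document onto [pipeline_config()]. Recognised keys: `seed`,
#' `out_dir`, `modes`, `strata`, `missing_policy`, `ci_method`,
#' `thresholds: {hwe_alpha, exclude_hwe_failures, ld_prune, proxy_r2}`,
#' `summary_stats`, `removed_cohort`, `proxy_map` (file paths), and `input`
#' with `type: simulate` (fields of [sim_config()]; `effects` as an
#' rsID-to-beta map) or `type: files` (`genotypes`, `dialect`, `phenotype`,
#' `panel`).
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  input <- y$input
  if (is.null(input$type)) stop("config input needs a 'type'")
  if (input$type == "simulate") {
    panel <- if (!is.null(input$panel)) read_panel(input$panel) else default_panel()
    input <- sim_config(
      panel = panel,
      effects = if (!is.null(input$effects)) unlist(input$effects) else NULL,
      intercept = input$intercept,
      n_cases = input$n_cases %||% 378L,
      n_controls = input$n_controls %||% 504L,
      severity_fraction = input$severity_fraction %||% (174 / 378),
      missing_rate = input$missing_rate %||% 0,
      seed = input$seed %||% 26L
    )
  } else if (input$type == "files") {
    input <- list(genotypes = input$genotypes,
                  dialect = input$dialect %||% "vcf",
                  phenotype = input$phenotype, panel = input$panel)
  } else stop("unknown input type: ", input$type)
  th <- y$thresholds %||% list()
  pipeline_config(
    input = input,
    modes = y$modes %||% "local",
    strata = y$strata %||% c("all_cases", "moderate_severe"),
    summary_stats = y$summary_stats, removed_cohort = y$removed_cohort,
    proxy_map = y$proxy_map,
    hwe_alpha = th$hwe_alpha %||% 0.05,
    exclude_hwe_failures = isTRUE(th$exclude_hwe_failures),
    ld_prune = th$ld_prune %||% 0.2,
    proxy_r2 = th$proxy_r2 %||% 0.8,
    missing_policy = y$missing_policy %||% "mean_impute",
    ci_method = y$ci_method %||% "delong",
    seed = y$seed %||% 1L,
    out_dir = y$out_dir
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
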