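#' Pipeline run configuration
#'
#' Collects every tunable threshold of the pipeline in one object. Defaults
#' mirror the analysis conventions: 10% missing tolerance, CV quartile
#' tails, |r| > 0.5 co-expression edges, raw p < 0.05 screens, fivefold
#' stratified cross-validation.
#'
#' @param cv_quantile_low,cv_quantile_high CV two-tail quantile bounds.
#' @param corr_threshold absolute Pearson correlation for network edges.
#' @param alpha significance level shared by the ANOVA, Tukey, Fisher and
#'   pathway screens.
#' @param missing_fraction_max missing-value tolerance per gene/sample.
#' @param cv_folds cross-validation folds.
#' @param rfe_step features eliminated per RFE iteration.
#' @param control_stage baseline stage.
#' @return object of class `run_config`.
#' @export
run_config <- function(cv_quantile_low = 0.25, cv_quantile_high = 0.75,
                       corr_threshold = 0.5, alpha = 0.05,
                       missing_fraction_max = 0.10, cv_folds = 5L,
                       rfe_step = 1L, control_stage = "I") {
  stopifnot(cv_quantile_low > 0, cv_quantile_low < cv_quantile_high,
            cv_quantile_high < 1, alpha > 0, alpha < 1)
  structure(list(cv_quantile_low = cv_quantile_low,
                 cv_quantile_high = cv_quantile_high,
                 corr_threshold = corr_threshold,
                 alpha = alpha,
                 missing_fraction_max = missing_fraction_max,
                 cv_folds = as.integer(cv_folds),
                 rfe_step = as.integer(rfe_step),
                 control_stage = control_stage),
            class = "run_config")
}

#' Run the full stage-stratified pathway analysis
#'
#' Executes, in order: missing-value filtering, mean imputation,
#' control-anchored z-scoring, the CV two-tail filter, the four-group ANOVA
#' + Tukey HSD stage feature sets, per-stage and global co-expression
#' networks, Fisher enrichment per stage, pathway imbalance scoring with
#' global-network degree weights, the pathway ANOVA screen, recursive
#' feature elimination and the cross-validated SVM. Per-stage networks are
#' built from that stage's samples and feature genes; the global network
#' (all feature genes, all samples) supplies the score weights so that
#' scoring a sample never needs its stage label.
#'
#' All randomness derives from `seed`; identical inputs and seed give an
#' identical manifest.
#'
#' @param expression expression tibble (raw; may contain `NA`).
#' @param cohort cohort tibble.
#' @param gene_sets gene-set tibble (`pathway`, `gene`).
#' @param config a [run_config()].
#' @param seed integer root seed.
#' @return object of class `stage_pipeline`: list with `config`, `seed`,
#'   `counts` (named list summarising every step) and `results` (the
#'   intermediate objects).
#' @export
run_pipeline <- function(expression, cohort, gene_sets,
                         config = run_config(), seed = 1L) {
  stopifnot(inherits(config, "run_config"))
  validate_inputs(expression, cohort, gene_sets)

  filtered <- filter_missing(expression, config$missing_fraction_max)
  kept_samples <- setdiff(names(filtered), "gene_id")
  cohort <- cohort[cohort$sample_id %in% kept_samples, , drop = FALSE]
  imputed <- impute_mean(filtered)
  normalized <- zscore_to_control(imputed, cohort, config$control_stage)

  cv_stats <- compute_cv(normalized)
  candidates <- two_tail_filter(cv_stats, config$cv_quantile_low,
                                config$cv_quantile_high)

  anova <- anova_screen(normalized, cohort, genes = candidates$gene_id,
                        alpha = config$alpha)
  sig_genes <- anova$gene_id[anova$selected]
  if (!length(sig_genes)) abort("feature_selection: no ANOVA-significant genes")
  feature_sets <- tukey_assign(normalized, cohort, sig_genes, config$alpha)
  features <- feature_union(feature_sets)

  stage_networks <- lapply(stage_levels, function(st) {
    smp <- cohort$sample_id[as.character(cohort$stage) == st]
    gs <- feature_sets$per_stage[[st]]
    if (length(gs) < 2L || length(smp) < 3L) return(NULL)
    build_network(normalized, genes = gs, samples = smp,
                  threshold = config$corr_threshold)
  })
  names(stage_networks) <- stage_levels
  global_network <- build_network(normalized, genes = features,
                                  threshold = config$corr_threshold)
  weights <- degree_weights(global_network, all_genes = features)

  enrich <- lapply(stage_levels, function(st) {
    fg <- feature_sets$per_stage[[st]]
    if (!length(fg)) return(NULL)
    fisher_enrich(fg, gene_sets, background = candidates$gene_id,
                  alpha = config$alpha) |>
      mutate(stage = st, .before = 1L)
  })
  enrich <- bind_rows(enrich)
  sel_pathways <- unique(enrich$pathway[enrich$selected])
  if (!length(sel_pathways)) abort("enrichment: no pathway passed the Fisher screen")

  directions <- assign_directions(
    normalized, cohort,
    gene_sets[gene_sets$pathway %in% sel_pathways, , drop = FALSE],
    feature_genes = features, weights = weights,
    control_stage = config$control_stage)
  scores <- score_matrix(normalized, directions)
  screen <- screen_pathways(scores, cohort, config$alpha)
  screened <- screen$pathway[screen$selected]
  if (!length(screened)) abort("pathway_score: no pathway passed the ANOVA screen")

  classes <- make_binary(cohort)
  feat_scores <- scores[scores$pathway %in% screened, , drop = FALSE]
  rfe <- if (nrow(feat_scores) >= 2L) {
    rfe_select(feat_scores, classes, step_k = config$rfe_step,
               folds = config$cv_folds, seed = seed + 11L)
  } else NULL
  svm_features <- if (is.null(rfe)) feat_scores$pathway else rfe$selected
  report <- train_and_evaluate(feat_scores, classes, features = svm_features,
                               folds = config$cv_folds, seed = seed + 23L)

  counts <- list(
    n_genes_input = nrow(expression),
    n_samples_input = ncol(expression) - 1L,
    n_genes_after_missing_filter = nrow(filtered),
    n_samples_after_missing_filter = length(kept_samples),
    n_genes_normalized = nrow(normalized),
    n_cv_candidates = nrow(candidates),
    n_anova_significant = length(sig_genes),
    n_feature_genes_per_stage = vapply(feature_sets$per_stage, length, 0L),
    n_shared_feature_genes = length(feature_sets$shared),
    n_feature_genes_union = length(features),
    edges_per_stage_network = vapply(stage_networks, function(n)
      if (is.null(n)) NA_integer_ else nrow(n$edges), 0L),
    edges_global_network = nrow(global_network$edges),
    n_enriched_pathways = length(sel_pathways),
    n_scorable_pathways = nrow(scores),
    n_screened_pathways = length(screened),
    n_rfe_selected = length(svm_features),
    mean_cv_accuracy = report$mean_accuracy,
    mean_cv_auc = report$mean_auc
  )

  structure(list(
    config = config, seed = as.integer(seed), counts = counts,
    results = list(normalized = normalized, cv_stats = cv_stats,
                   candidates = candidates, anova = anova,
                   feature_sets = feature_sets,
                   stage_networks = stage_networks,
                   global_network = global_network, weights = weights,
                   enrichment = enrich, directions = directions,
                   scores = scores, screen = screen, rfe = rfe,
                   report = report)
  ), class = "stage_pipeline")
}

#' @export
print.stage_pipeline <- function(x, ...) {
  c <- x$counts
  cat("<stage_pipeline>  seed =", x$seed, "\n")
  cat("  genes: input", c$n_genes_input, "-> normalized", c$n_genes_normalized,
      "-> CV candidates", c$n_cv_candidates,
      "-> ANOVA", c$n_anova_significant, "\n")
  cat("  feature genes per stage:",
      paste(c$n_feature_genes_per_stage, collapse = "/"),
      " shared:", c$n_shared_feature_genes, "\n")
  cat("  global network edges:", c$edges_global_network, "\n")
  cat("  pathways: enriched", c$n_enriched_pathways,
      "-> screened", c$n_screened_pathways,
      "-> RFE selected", c$n_rfe_selected, "\n")
  cat(sprintf("  SVM: mean CV accuracy %.3f, mean AUC %.3f\n",
              c$mean_cv_accuracy, c$mean_cv_auc))
  invisible(x)
}

#' Serializable manifest of a pipeline run
#'
#' Flattens the run's configuration, seed and per-step counts into a plain
#' named list, suitable for JSON serialization and byte-level comparison of
#' reruns.
#'
#' @param pipeline a `stage_pipeline`.
#' @return named list.
#' @export
pipeline_manifest <- function(pipeline) {
  stopifnot(inherits(pipeline, "stage_pipeline"))
  list(config = unclass(pipeline$config),
       seed = pipeline$seed,
       counts = pipeline$counts,
       selected_features = pipeline$results$report$selected_features,
       fold_metrics = as.data.frame(pipeline$results$report$folds))
}
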