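#' Density of the signed CV statistic with the two-tail cutoffs
#'
#' @param cv_stats tibble from [compute_cv()].
#' @param q_low,q_high the quantile bounds used by [two_tail_filter()].
#' @return a ggplot.
#' @export
plot_cv_distribution <- function(cv_stats, q_low = 0.25, q_high = 0.75) {
  ok <- cv_stats[!is.na(cv_stats$cv), , drop = FALSE]
  qs <- quantile(ok$cv, c(q_low, q_high), type = 7, names = FALSE)
  ggplot(ok, aes(x = .data$cv)) +
    geom_density() +
    geom_vline(xintercept = qs, linetype = "dashed", colour = c("darkgreen", "red")) +
    labs(x = "signed CV (mean / sd)", y = "density",
         title = "CV distribution with two-tail selection cutoffs") +
    theme_minimal()
}

#' Boxplots of pathway imbalance scores by stage
#'
#' One panel per pathway, scores grouped by tumor stage — the visual check
#' that a screened pathway's imbalance drifts with stage.
#'
#' @param scores pathway-by-sample score tibble from [score_matrix()].
#' @param cohort cohort tibble.
#' @param pathways optional subset of pathways to draw.
#' @return a ggplot.
#' @export
plot_score_by_stage <- function(scores, cohort, pathways = NULL) {
  long <- scores |>
    pivot_longer(-"pathway", names_to = "sample_id", values_to = "score") |>
    inner_join(cohort, by = "sample_id")
  if (!is.null(pathways)) long <- long[long$pathway %in% pathways, , drop = FALSE]
  ggplot(long, aes(x = .data$stage, y = .data$score, fill = .data$stage)) +
    geom_boxplot(outlier.size = 0.5) +
    facet_wrap(~pathway, scales = "free_y") +
    labs(x = "stage", y = "imbalance score A(P)") +
    theme_minimal()
}

#' @rdname topology
#' @param object a `topology_summary`.
#' @param ... unused.
#' @export
autoplot.topology_summary <- function(object, ...) {
  ggplot(object$degree_distribution, aes(x = .data$degree, y = .data$count)) +
    geom_point() +
    geom_line(alpha = 0.4) +
    labs(x = "degree", y = "number of genes",
         title = "Co-expression network degree distribution") +
    theme_minimal()
}

#' @rdname train_and_evaluate
#' @param object a `stage_svm_report`.
#' @export
autoplot.stage_svm_report <- function(object, ...) {
  ggplot(object$roc_points,
         aes(x = .data$fpr, y = .data$tpr, colour = factor(.data$fold))) +
    geom_line() +
    geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    labs(x = "false positive rate", y = "true positive rate",
         colour = "fold",
         title = sprintf("Cross-validated ROC (mean AUC %.3f)",
                         object$mean_auc)) +
    theme_minimal()
}

#' @rdname rfe_select
#' @param object an `rfe_result`.
#' @export
autoplot.rfe_result <- function(object, ...) {
  ggplot(object$history, aes(x = .data$n_features, y = .data$accuracy)) +
    geom_line() +
    geom_point() +
    labs(x = "features retained", y = "mean CV accuracy",
         title = "Recursive feature elimination path") +
    theme_minimal()
}
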