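#' Signed coefficient of variation per gene
#'
#' On the control-anchored z scale the conventional CV is inverted: the
#' fluctuation statistic is `mean / sd` over all samples, so a gene whose
#' expression drifts upward in tumors has a large positive value, a
#' downward-drifting gene a large negative one, and a gene that merely
#' fluctuates around the control baseline sits near zero. Genes with zero
#' SD get `NA` and are flagged.
#'
#' @param x expression tibble (normalized, no missing values).
#' @return tibble `gene_id`, `mean`, `sd`, `cv` ordered as the input.
#' @export
compute_cv <- function(x) {
  check_expr_tbl(x)
  m <- expr_values(x)
  if (anyNA(m)) abort("missing values present")
  mu <- rowMeans(m)
  s <- apply(m, 1L, sd)
  tibble(gene_id = rownames(m), mean = unname(mu), sd = unname(s),
         cv = unname(ifelse(s > 0, mu / s, NA_real_)))
}

#' Keep genes in the two tails of the CV distribution
#'
#' Retains genes whose CV lies strictly below the `q_low` empirical quantile
#' or strictly above the `q_high` quantile (type-7 quantiles). With the
#' default quartiles the middle half of genes — those fluctuating tightly
#' around the control baseline — is discarded.
#'
#' @param cv_stats tibble from [compute_cv()].
#' @param q_low,q_high quantile bounds (defaults 0.25 and 0.75).
#' @return `cv_stats` rows for the retained genes.
#' @export
two_tail_filter <- function(cv_stats, q_low = 0.25, q_high = 0.75) {
  stopifnot(q_low < q_high, q_low >= 0, q_high <= 1)
  ok <- cv_stats[!is.na(cv_stats$cv), , drop = FALSE]
  if (nrow(ok) < 4L) abort("fewer than 4 genes with a defined CV")
  qs <- quantile(ok$cv, c(q_low, q_high), type = 7, names = FALSE)
  ok[ok$cv < qs[1] | ok$cv > qs[2], , drop = FALSE]
}

#' Four-group one-way ANOVA screen
#'
#' Tests each gene for any difference in mean expression across the four
#' stage groups (fixed-effects F test, equal-variance pooling). No
#' multiple-testing correction is applied; the raw `p < alpha` rule defines
#' the candidate differential set.
#'
#' @param x expression tibble.
#' @param cohort cohort tibble; every stage needs at least 2 samples.
#' @param genes optional character vector restricting the tested genes.
#' @param alpha significance level (default 0.05).
#' @return tibble `gene_id`, `f`, `p`, `selected`.
#' @export
anova_screen <- function(x, cohort, genes = NULL, alpha = 0.05) {
  check_expr_tbl(x)
  check_cohort(cohort, x, min_per_stage = 2L)
  present <- table(factor(cohort$stage, levels = stage_levels))
  if (any(present < 2L)) abort("each of the four stages needs >= 2 samples")
  m <- expr_values(x)[, cohort$sample_id, drop = FALSE]
  if (!is.null(genes)) m <- m[intersect(rownames(m), genes), , drop = FALSE]
  grp <- factor(as.character(cohort$stage), levels = stage_levels)
  res <- apply(m, 1L, function(v) {
    if (sd(v) == 0) return(c(NA_real_, NA_real_))
    ht <- tryCatch(oneway.test(v ~ grp, var.equal = TRUE),
                   error = function(e) NULL)
    if (is.null(ht)) c(NA_real_, NA_real_)
    else c(unname(ht$statistic), unname(ht$p.value))
  })
  tibble(gene_id = rownames(m), f = unname(res[1L, ]), p = unname(res[2L, ]),
         selected = unname(!is.na(res[2L, ]) & res[2L, ] < alpha))
}

#' Assign ANOVA-significant genes to stage feature sets via Tukey HSD
#'
#' For each gene surviving the ANOVA screen, all six pairwise stage
#' comparisons are tested with Tukey's honestly-significant-difference
#' procedure (Tukey-Kramer for the unequal group sizes typical of staged
#' cohorts). A gene joins stage k's feature set when at least one
#' significant pair involves stage k; the shared set is the intersection of
#' the four per-stage sets.
#'
#' @param x expression tibble.
#' @param cohort cohort tibble.
#' @param anova_genes character vector of genes to assign (typically the
#'   `selected` genes of [anova_screen()]).
#' @param alpha significance level for the adjusted pairwise p-values.
#' @return object of class `stage_feature_sets`: list with `per_stage`
#'   (named list of gene-id vectors), `shared`, `tukey` (tibble `gene_id`,
#'   `pair`, `diff`, `p_adj`), `alpha`.
#' @export
tukey_assign <- function(x, cohort, anova_genes, alpha = 0.05) {
  check_expr_tbl(x)
  check_cohort(cohort, x, min_per_stage = 2L)
  if (!length(anova_genes)) abort("anova_genes is empty")
  m <- expr_values(x)[intersect(rownames(expr_values(x)), anova_genes), ,
                      drop = FALSE]
  m <- m[, cohort$sample_id, drop = FALSE]
  grp <- factor(as.character(cohort$stage), levels = stage_levels)

  tk <- map(seq_len(nrow(m)), function(i) {
    fit <- aov(m[i, ] ~ grp)
    tt <- TukeyHSD(fit)$grp
    tibble(gene_id = rownames(m)[i], pair = rownames(tt),
           diff = tt[, "diff"], p_adj = tt[, "p adj"])
  })
  tk <- bind_rows(tk)

  sig <- tk[!is.na(tk$p_adj) & tk$p_adj < alpha, , drop = FALSE]
  pair_stages <- strsplit(sig$pair, "-", fixed = TRUE)
  per_stage <- lapply(stage_levels, function(st) {
    hit <- vapply(pair_stages, function(p) st %in% p, logical(1))
    sort(unique(sig$gene_id[hit]))
  })
  names(per_stage) <- stage_levels
  shared <- Reduce(intersect, per_stage)

  structure(list(per_stage = per_stage, shared = shared,
                 tukey = tk, alpha = alpha),
            class = "stage_feature_sets")
}

#' @export
print.stage_feature_sets <- function(x, ...) {
  cat("<stage_feature_sets>  alpha =", x$alpha, "\n")
  for (st in names(x$per_stage)) {
    cat(sprintf("  stage %-3s: %d genes\n", st, length(x$per_stage[[st]])))
  }
  cat("  shared   :", length(x$shared), "genes\n")
  invisible(x)
}

#' @rdname tukey_assign
#' @param x a `stage_feature_sets` object.
#' @param ... unused.
#' @export
tidy.stage_feature_sets <- function(x, ...) x$tukey

#' All genes appearing in at least one stage feature set
#'
#' @param feature_sets a `stage_feature_sets` object.
#' @return character vector of gene ids.
#' @export
feature_union <- function(feature_sets) {
  sort(unique(unlist(feature_sets$per_stage, use.names = FALSE)))
}
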