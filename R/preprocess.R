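#' Drop genes and samples with excessive missing values
#'
#' Genes whose missing fraction strictly exceeds `max_fraction` are removed
#' first; samples are then re-assessed on the surviving genes and removed by
#' the same rule. Every removal is recorded in the [drop_log()].
#'
#' @param x expression tibble (may contain `NA`).
#' @param max_fraction maximum tolerated missing fraction (default 0.10).
#' @return filtered expression tibble with a `drop_log` attribute.
#' @export
filter_missing <- function(x, max_fraction = 0.10) {
  check_expr_tbl(x)
  m <- expr_values(x)
  log <- new_drop_log()

  gene_frac <- rowMeans(is.na(m))
  drop_g <- gene_frac > max_fraction
  log <- append_drop_log(log, rownames(m)[drop_g], "gene",
                         "missing_fraction", gene_frac[drop_g])
  m <- m[!drop_g, , drop = FALSE]
  if (nrow(m) == 0L) abort("all genes removed by missing-value filter")

  smp_frac <- colMeans(is.na(m))
  drop_s <- smp_frac > max_fraction
  log <- append_drop_log(log, colnames(m)[drop_s], "sample",
                         "missing_fraction", smp_frac[drop_s])
  m <- m[, !drop_s, drop = FALSE]
  if (ncol(m) == 0L) abort("all samples removed by missing-value filter")

  set_drop_log(as_expr_tbl(m), log)
}

#' Impute missing cells with the gene's observed mean
#'
#' Each `NA` cell is replaced by the mean of that gene's observed values
#' across the remaining samples. Run after [filter_missing()], which
#' guarantees every gene retains observed values.
#'
#' @param x expression tibble.
#' @return expression tibble without missing values.
#' @export
impute_mean <- function(x) {
  check_expr_tbl(x)
  m <- expr_values(x)
  if (!anyNA(m)) return(as_expr_tbl(m))
  obs <- rowSums(!is.na(m))
  if (any(obs == 0L)) {
    abort(paste0("gene with no observed values: ",
                 paste(rownames(m)[obs == 0L], collapse = ", ")))
  }
  gm <- rowMeans(m, na.rm = TRUE)
  idx <- which(is.na(m), arr.ind = TRUE)
  m[idx] <- gm[idx[, 1L]]
  as_expr_tbl(m)
}

#' Z-score all samples against the control stage
#'
#' Per gene, the mean and sample standard deviation (n - 1 denominator) are
#' computed over the control-stage samples; every value is transformed to
#' `(x - mu) / sigma`. On the resulting scale the control group of each gene
#' has mean 0 and SD 1 exactly. Genes whose control SD is zero cannot be
#' scaled and are dropped with a logged reason.
#'
#' @param x expression tibble with no missing values.
#' @param cohort cohort tibble (`sample_id`, `stage`).
#' @param control_stage stage used as baseline (default `"I"`).
#' @return normalized expression tibble; attributes `norm_params` (tibble
#'   `gene_id`, `mu`, `sigma`) and `drop_log`.
#' @export
zscore_to_control <- function(x, cohort, control_stage = "I") {
  check_expr_tbl(x)
  check_cohort(cohort, x)
  m <- expr_values(x)
  if (anyNA(m)) abort("missing values present; run filter_missing()/impute_mean() first")
  ctrl <- cohort$sample_id[as.character(cohort$stage) == control_stage]
  if (length(ctrl) < 2L) abort("control stage must have at least 2 samples")
  mc <- m[, ctrl, drop = FALSE]
  mu <- rowMeans(mc)
  sigma <- apply(mc, 1L, sd)

  log <- new_drop_log()
  zero <- sigma <= 0 | !is.finite(sigma)
  log <- append_drop_log(log, rownames(m)[zero], "gene",
                         "zero_control_variance", sigma[zero])
  if (all(zero)) abort("all genes have zero control variance")
  m <- (m[!zero, , drop = FALSE] - mu[!zero]) / sigma[!zero]

  out <- as_expr_tbl(m)
  attr(out, "norm_params") <- tibble(gene_id = rownames(m),
                                     mu = unname(mu[!zero]),
                                     sigma = unname(sigma[!zero]))
  set_drop_log(out, log)
}

#' Retrieve control-anchored normalization parameters
#'
#' @param x result of [zscore_to_control()].
#' @return tibble `gene_id`, `mu`, `sigma`.
#' @export
norm_params <- function(x) {
  attr(x, "norm_params") %||%
    abort("no norm_params attribute; was the object produced by zscore_to_control()?")
}
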