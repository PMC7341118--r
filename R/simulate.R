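#' Specification of a synthetic staged cohort
#'
#' Defines the statistical structure of a simulated four-stage expression
#' cohort with planted ground truth. Control-stage (stage I) expression is
#' standard normal; genes of "planted" pathways shift their means linearly
#' with stage index and share an equicorrelated co-expression block, so every
#' downstream step (feature selection, network recovery, enrichment, pathway
#' imbalance, classification) has a known target.
#'
#' Up-regulated planted genes gain `effect_size` standard deviations per
#' stage step; down-regulated planted genes move in the opposite direction
#' attenuated by `balance_drift`, so the up/down balance of a planted
#' pathway drifts with stage and its imbalance score has a monotone trend.
#'
#' @param n_genes total number of genes.
#' @param n_samples_per_stage integer vector of length 4 (stages I-IV).
#' @param n_pathways number of gene sets in the collection.
#' @param genes_per_pathway genes per set (disjoint sets).
#' @param n_planted_pathways number of pathways carrying signal.
#' @param effect_size mean shift per stage step, in SD units.
#' @param balance_drift attenuation of the down-regulated shift relative to
#'   the up-regulated shift (0 = down genes stay flat, 1 = symmetric drift,
#'   which keeps the pathway balanced).
#' @param coexpr_block_rho pairwise correlation within a planted block.
#' @param noise_sd residual standard deviation.
#' @param missing_rate fraction of cells masked as missing.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 1000L,
                           n_samples_per_stage = c(50L, 50L, 50L, 50L),
                           n_pathways = 20L,
                           genes_per_pathway = 25L,
                           n_planted_pathways = 4L,
                           effect_size = 1.5,
                           balance_drift = 0.5,
                           coexpr_block_rho = 0.7,
                           noise_sd = 1,
                           missing_rate = 0.02) {
  spec <- list(n_genes = as.integer(n_genes),
               n_samples_per_stage = as.integer(n_samples_per_stage),
               n_pathways = as.integer(n_pathways),
               genes_per_pathway = as.integer(genes_per_pathway),
               n_planted_pathways = as.integer(n_planted_pathways),
               effect_size = effect_size,
               balance_drift = balance_drift,
               coexpr_block_rho = coexpr_block_rho,
               noise_sd = noise_sd,
               missing_rate = missing_rate)
  if (length(spec$n_samples_per_stage) != 4L || any(spec$n_samples_per_stage < 1L)) {
    abort("n_samples_per_stage must be 4 positive integers")
  }
  if (spec$n_planted_pathways > spec$n_pathways) {
    abort("n_planted_pathways must not exceed n_pathways")
  }
  if (spec$n_pathways * spec$genes_per_pathway > spec$n_genes) {
    abort("n_pathways * genes_per_pathway must not exceed n_genes")
  }
  if (spec$coexpr_block_rho <= 0 || spec$coexpr_block_rho >= 1) {
    abort("coexpr_block_rho must lie in (0, 1)")
  }
  if (spec$missing_rate < 0 || spec$missing_rate >= 1) {
    abort("missing_rate must lie in [0, 1)")
  }
  structure(spec, class = "synthetic_spec")
}

make_truth <- function(spec, seed) {
  set.seed(seed)
  gene_id <- sprintf("g%04d", seq_len(spec$n_genes))
  pw_names <- sprintf("PW%02d", seq_len(spec$n_pathways))
  pathway <- rep(NA_character_, spec$n_genes)
  idx <- seq_len(spec$n_pathways * spec$genes_per_pathway)
  pathway[idx] <- rep(pw_names, each = spec$genes_per_pathway)
  planted_pw <- pw_names[seq_len(spec$n_planted_pathways)]
  planted <- !is.na(pathway) & pathway %in% planted_pw

  direction <- integer(spec$n_genes)
  for (pw in planted_pw) {
    g <- which(pathway %in% pw)
    d <- sample(c(-1L, 1L), length(g), replace = TRUE)
    # every planted pathway must carry both directions so its imbalance
    # score is finite and informative
    if (all(d == 1L)) d[1] <- -1L
    if (all(d == -1L)) d[1] <- 1L
    direction[g] <- d
  }

  shifts <- matrix(0, spec$n_genes, 4, dimnames = list(gene_id, stage_levels))
  step <- 0:3
  up <- direction == 1L
  dn <- direction == -1L
  shifts[up, ] <- rep(spec$effect_size * step, each = sum(up))
  shifts[dn, ] <- rep(-spec$balance_drift * spec$effect_size * step,
                      each = sum(dn))

  structure(list(
    genes = tibble(gene_id = gene_id, pathway = pathway,
                   planted = planted, direction = direction),
    shifts = shifts,
    planted_pathways = planted_pw,
    pathway_names = pw_names,
    spec = spec
  ), class = "synthetic_truth")
}

#' Override a planted pathway's per-stage imbalance profile
#'
#' Rewrites the mean-shift schedule of one pathway so the expected sign of
#' its imbalance score per stage follows `profile`: positive entries inflate
#' the up-regulated genes by that many SD units, negative entries inflate
#' the down-regulated genes, zero leaves the stage balanced.
#'
#' @param truth a `synthetic_truth` (from [generate_cohort()]'s `truth`
#'   element or [make_truth] via `generate_cohort(..., return_truth_only =
#'   TRUE)`).
#' @param pathway pathway name present in the truth.
#' @param profile numeric length 4 (stages I-IV), in SD units.
#' @return modified `synthetic_truth`.
#' @export
plant_balance_profile <- function(truth, pathway, profile) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (length(profile) != 4L || !is.numeric(profile)) {
    abort("profile must be numeric of length 4")
  }
  g <- truth$genes
  in_pw <- !is.na(g$pathway) & g$pathway == pathway
  if (!any(in_pw)) abort(paste0("pathway not present in truth: ", pathway))
  up <- in_pw & g$direction == 1L
  dn <- in_pw & g$direction == -1L
  truth$shifts[up, ] <- rep(pmax(profile, 0), each = sum(up))
  truth$shifts[dn, ] <- rep(-pmax(-profile, 0), each = sum(dn))
  truth
}

#' Generate a synthetic staged expression cohort
#'
#' Realises an expression matrix, stage labels, gene-set collection and the
#' planted truth from a [synthetic_spec()]. Fully reproducible from `seed`.
#'
#' @param spec a `synthetic_spec`.
#' @param seed integer RNG seed.
#' @param truth optional `synthetic_truth` to realise (e.g. after
#'   [plant_balance_profile()]); defaults to the truth implied by `spec`.
#' @param return_truth_only if `TRUE`, return only the `synthetic_truth`
#'   (no matrix realised), for editing before generation.
#' @return list of class `synthetic_cohort` with elements `expression`
#'   (expression tibble), `cohort` (sample_id/stage tibble), `gene_sets`
#'   (pathway/description/gene tibble) and `truth`.
#' @export
generate_cohort <- function(spec = synthetic_spec(), seed = 1L, truth = NULL,
                            return_truth_only = FALSE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(truth)) truth <- make_truth(spec, seed)
  if (return_truth_only) return(truth)

  set.seed(seed + 1L)
  n_s <- spec$n_samples_per_stage
  n_samples <- sum(n_s)
  stage <- factor(rep(stage_levels, times = n_s), levels = stage_levels)
  sample_id <- sprintf("s%03d", seq_len(n_samples))
  gene_id <- truth$genes$gene_id

  m <- matrix(rnorm(spec$n_genes * n_samples), spec$n_genes, n_samples,
              dimnames = list(gene_id, sample_id))
  # equicorrelated block per planted pathway: shared factor + residual
  rho <- spec$coexpr_block_rho
  for (pw in truth$planted_pathways) {
    g <- which(!is.na(truth$genes$pathway) & truth$genes$pathway == pw)
    z <- rnorm(n_samples)
    m[g, ] <- sqrt(rho) * rep(z, each = length(g)) + sqrt(1 - rho) * m[g, , drop = FALSE]
  }
  m <- m * spec$noise_sd
  m <- m + truth$shifts[, as.integer(stage), drop = FALSE]

  if (spec$missing_rate > 0) {
    mask <- runif(length(m)) < spec$missing_rate
    m[mask] <- NA_real_
  }

  gene_sets <- truth$genes |>
    filter(!is.na(.data$pathway)) |>
    mutate(description = ifelse(.data$pathway %in% truth$planted_pathways,
                                "planted", "null")) |>
    select(pathway = "pathway", description = "description", gene = "gene_id")

  structure(list(
    expression = as_expr_tbl(m),
    cohort = tibble(sample_id = sample_id, stage = stage),
    gene_sets = gene_sets,
    truth = truth
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>\n")
  cat("  genes:   ", nrow(x$expression), "\n")
  cat("  samples: ", nrow(x$cohort), " (",
      paste(table(x$cohort$stage), collapse = "/"), " by stage)\n", sep = "")
  cat("  pathways:", length(unique(x$gene_sets$pathway)),
      "(", length(x$truth$planted_pathways), "planted )\n")
  invisible(x)
}
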