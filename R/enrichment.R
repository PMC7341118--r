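#' Fisher exact over-representation test of a gene list against gene sets
#'
#' For each pathway, a 2x2 table (in/out of the feature list by in/out of
#' the pathway) is formed over the background universe and tested one-sided
#' for enrichment with Fisher's exact test. Pathways are intersected with
#' the background before testing; feature genes outside the background are
#' an error. Raw p-values are compared with `alpha` — no multiple-testing
#' correction, so the selected flag is a screening device, not a
#' family-wise claim.
#'
#' @param feature_genes character vector (the gene list to test).
#' @param gene_sets long tibble (`pathway`, `gene`; `description` optional).
#' @param background character vector: the gene universe the features were
#'   drawn from (typically the CV-filtered candidate genes).
#' @param alpha significance level (default 0.05).
#' @return tibble `pathway`, `overlap`, `feature_size`, `pathway_size`,
#'   `background_size`, `p`, `selected`, ordered by `p`.
#' @export
fisher_enrich <- function(feature_genes, gene_sets, background, alpha = 0.05) {
  background <- unique(background)
  if (!length(background)) abort("empty background universe")
  feature_genes <- unique(feature_genes)
  if (!all(feature_genes %in% background)) {
    abort("feature_genes must be a subset of the background")
  }
  n_f <- length(feature_genes)
  n_bg <- length(background)

  sets <- split(gene_sets$gene, gene_sets$pathway)
  res <- imap(sets, function(genes, pw) {
    pw_genes <- intersect(unique(genes), background)
    k <- length(intersect(pw_genes, feature_genes))
    K <- length(pw_genes)
    tab <- matrix(c(k, K - k, n_f - k, n_bg - K - n_f + k), nrow = 2L)
    p <- if (K == 0L) 1 else fisher.test(tab, alternative = "greater")$p.value
    tibble(pathway = pw, overlap = k, feature_size = n_f,
           pathway_size = K, background_size = n_bg, p = p)
  })
  bind_rows(res) |>
    mutate(selected = .data$p < alpha) |>
    arrange(.data$p)
}
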