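#' Assign up/down directions, weights and baselines to pathway genes
#'
#' Builds the direction table underlying the pathway imbalance score. For
#' each pathway, the member genes are its genes present in the matrix,
#' optionally restricted to a feature-gene universe (the union of the stage
#' feature sets). Each member gene's baseline `mu` is its mean over the
#' control-stage samples (0 on the control-anchored z scale); its direction
#' is `up` when its mean deviation from `mu` over all non-control samples is
#' positive, `down` when negative, and the gene is excluded (logged) in the
#' measure-zero case of an exactly zero mean deviation. Weights come from a
#' co-expression network's sigmoid degree weights; genes without a weight
#' entry get the minimum 0.5.
#'
#' Pathways ending up with an empty up or down side cannot form the score
#' ratio; they are excluded and logged as unscorable.
#'
#' @param x expression tibble (normalized).
#' @param cohort cohort tibble.
#' @param gene_sets long tibble (`pathway`, `gene`), typically pre-filtered
#'   to the enrichment-selected pathways.
#' @param feature_genes optional character vector restricting member genes
#'   (use [feature_union()] of the stage feature sets); `NULL` keeps all
#'   pathway genes present in the matrix.
#' @param weights optional tibble from [degree_weights()] (`gene_id`,
#'   `weight`); `NULL` gives every gene weight 0.5.
#' @param control_stage baseline stage (default `"I"`).
#' @return tibble `pathway`, `gene_id`, `direction` ("up"/"down"),
#'   `weight`, `mu`, with a `drop_log` attribute listing excluded genes and
#'   unscorable pathways.
#' @export
assign_directions <- function(x, cohort, gene_sets, feature_genes = NULL,
                              weights = NULL, control_stage = "I") {
  check_expr_tbl(x)
  check_cohort(cohort, x)
  m <- expr_values(x)
  ctrl <- cohort$sample_id[as.character(cohort$stage) == control_stage]
  noncontrol <- cohort$sample_id[as.character(cohort$stage) != control_stage]
  if (length(ctrl) < 1L || length(noncontrol) < 1L) {
    abort("need both control and non-control samples")
  }
  universe <- rownames(m)
  if (!is.null(feature_genes)) universe <- intersect(universe, feature_genes)

  mu <- rowMeans(m[, ctrl, drop = FALSE])
  dev <- rowMeans(m[, noncontrol, drop = FALSE]) - mu

  members <- gene_sets |>
    select(pathway = "pathway", gene_id = "gene") |>
    distinct() |>
    filter(.data$gene_id %in% universe) |>
    mutate(mu = mu[.data$gene_id],
           mean_dev = dev[.data$gene_id],
           direction = dplyr::case_when(.data$mean_dev > 0 ~ "up",
                                        .data$mean_dev < 0 ~ "down",
                                        TRUE ~ NA_character_))

  log <- new_drop_log()
  zero <- is.na(members$direction)
  log <- append_drop_log(log, members$gene_id[zero], "gene",
                         "zero_mean_deviation", 0)
  members <- members[!zero, , drop = FALSE]

  w <- if (is.null(weights)) {
    tibble(gene_id = unique(members$gene_id), weight = 0.5)
  } else {
    weights[, c("gene_id", "weight")]
  }
  members <- members |>
    left_join(w, by = "gene_id") |>
    mutate(weight = ifelse(is.na(.data$weight), 0.5, .data$weight))

  sides <- members |>
    group_by(.data$pathway) |>
    summarise(n_up = sum(.data$direction == "up"),
              n_down = sum(.data$direction == "down"), .groups = "drop")
  bad <- sides$pathway[sides$n_up == 0L | sides$n_down == 0L]
  log <- append_drop_log(log, bad, "pathway", "unscorable_one_sided",
                         NA_real_)
  missing_pw <- setdiff(unique(gene_sets$pathway), sides$pathway)
  log <- append_drop_log(log, missing_pw, "pathway", "no_member_genes",
                         NA_real_)

  out <- members |>
    filter(!(.data$pathway %in% bad)) |>
    select("pathway", "gene_id", "direction", "weight", "mu") |>
    arrange(.data$pathway, .data$gene_id)
  set_drop_log(out, log)
}

#' Pathway imbalance score of one sample
#'
#' `A(P) = log2( sum_up w_i (x_i - mu_i)^2 / sum_down w_j (x_j - mu_j)^2 )`:
#' the log2 ratio of the weighted sums of squared deviations from the
#' control baseline over the pathway's up- versus down-regulated genes.
#' Zero means the two sides are balanced; positive values mean the
#' up-regulated genes dominate, negative the down-regulated ones. Numerator
#' and denominator are floored at `eps` so a vanishing side yields a large
#' finite score rather than an infinity.
#'
#' @param sample_values named numeric vector of the sample's expression
#'   (names = gene ids; must cover the entry's genes).
#' @param entry direction-table rows of a single pathway (from
#'   [assign_directions()]).
#' @param eps floor applied to each side (default 1e-8).
#' @return scalar A(P).
#' @export
imbalance_score <- function(sample_values, entry, eps = 1e-8) {
  if (!nrow(entry)) abort("empty direction entry")
  if (length(unique(entry$pathway)) != 1L) abort("entry must cover one pathway")
  up <- entry[entry$direction == "up", , drop = FALSE]
  dn <- entry[entry$direction == "down", , drop = FALSE]
  if (!nrow(up) || !nrow(dn)) abort("unscorable entry: one side is empty")
  miss <- setdiff(entry$gene_id, names(sample_values))
  if (length(miss)) abort(paste0("sample lacks genes: ",
                                 paste(head(miss, 5), collapse = ", ")))
  num <- sum(up$weight * (sample_values[up$gene_id] - up$mu)^2)
  den <- sum(dn$weight * (sample_values[dn$gene_id] - dn$mu)^2)
  log2(max(num, eps) / max(den, eps))
}

#' Pathway-by-sample matrix of imbalance scores
#'
#' Applies [imbalance_score()] to every scorable pathway and every sample
#' of the matrix; column order follows the matrix's sample order.
#'
#' @param x expression tibble (normalized).
#' @param direction_table tibble from [assign_directions()].
#' @param eps floor for either side of the ratio.
#' @return tibble: first column `pathway`, one numeric column per sample.
#' @export
score_matrix <- function(x, direction_table, eps = 1e-8) {
  check_expr_tbl(x)
  if (!nrow(direction_table)) abort("empty direction table")
  m <- expr_values(x)
  pws <- unique(direction_table$pathway)
  rows <- map(pws, function(pw) {
    e <- direction_table[direction_table$pathway == pw, , drop = FALSE]
    up <- e[e$direction == "up", , drop = FALSE]
    dn <- e[e$direction == "down", , drop = FALSE]
    num <- colSums(up$weight * (m[up$gene_id, , drop = FALSE] - up$mu)^2)
    den <- colSums(dn$weight * (m[dn$gene_id, , drop = FALSE] - dn$mu)^2)
    log2(pmax(num, eps) / pmax(den, eps))
  })
  sm <- do.call(rbind, rows)
  dimnames(sm) <- list(pws, colnames(m))
  out <- bind_cols(tibble(pathway = pws), as_tibble(sm))
  out
}

score_values <- function(scores) {
  m <- as.matrix(scores[, setdiff(names(scores), "pathway"), drop = FALSE])
  rownames(m) <- scores$pathway
  m
}

#' Screen pathways whose imbalance score differs across stages
#'
#' One-way fixed-effects ANOVA of each pathway's per-sample score across
#' the four stage groups; pathways with raw `p < alpha` are flagged.
#'
#' @param scores pathway-by-sample score tibble from [score_matrix()].
#' @param cohort cohort tibble (every stage needs >= 2 samples).
#' @param alpha significance level (default 0.05).
#' @return tibble `pathway`, `f`, `p`, `selected`, ordered by `p`.
#' @export
screen_pathways <- function(scores, cohort, alpha = 0.05) {
  check_cohort(cohort, min_per_stage = 2L)
  sm <- score_values(scores)[, cohort$sample_id, drop = FALSE]
  grp <- factor(as.character(cohort$stage), levels = stage_levels)
  res <- apply(sm, 1L, function(v) {
    if (sd(v) == 0) return(c(NA_real_, NA_real_))
    ht <- tryCatch(oneway.test(v ~ grp, var.equal = TRUE),
                   error = function(e) NULL)
    if (is.null(ht)) c(NA_real_, NA_real_)
    else c(unname(ht$statistic), unname(ht$p.value))
  })
  tibble(pathway = rownames(sm), f = unname(res[1L, ]), p = unname(res[2L, ]),
         selected = unname(!is.na(res[2L, ]) & res[2L, ] < alpha)) |>
    arrange(.data$p)
}
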