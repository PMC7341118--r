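test_that("the same seed reproduces the cohort exactly", {
  spec <- synthetic_spec(n_genes = 100, n_samples_per_stage = rep(10L, 4),
                         n_pathways = 5, genes_per_pathway = 10,
                         n_planted_pathways = 2)
  a <- generate_cohort(spec, seed = 3)
  b <- generate_cohort(spec, seed = 3)
  expect_identical(a$expression, b$expression)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$truth$shifts, b$truth$shifts)
  c <- generate_cohort(spec, seed = 4)
  expect_false(identical(a$expression, c$expression))
})

test_that("infeasible specs are rejected", {
  expect_error(synthetic_spec(n_pathways = 10, genes_per_pathway = 20,
                              n_genes = 100), "must not exceed")
  expect_error(synthetic_spec(n_planted_pathways = 5, n_pathways = 4),
               "must not exceed")
  expect_error(synthetic_spec(coexpr_block_rho = 1), "in \\(0, 1\\)")
})

test_that("a zero-effect cohort is null: ANOVA hits stay near alpha", {
  spec <- synthetic_spec(n_genes = 2000, n_samples_per_stage = rep(25L, 4),
                         n_pathways = 10, genes_per_pathway = 10,
                         n_planted_pathways = 0, effect_size = 0,
                         missing_rate = 0)
  sc <- generate_cohort(spec, seed = 11)
  an <- anova_screen(sc$expression, sc$cohort, alpha = 0.05)
  se <- sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(mean(an$selected) - 0.05), 2 * se)
})

test_that("planted genes realise the prescribed stage-IV minus stage-I shift", {
  spec <- synthetic_spec(n_genes = 300, n_samples_per_stage = rep(50L, 4),
                         n_pathways = 4, genes_per_pathway = 25,
                         n_planted_pathways = 2, effect_size = 1.5,
                         balance_drift = 1, missing_rate = 0)
  sc <- generate_cohort(spec, seed = 5)
  m <- expr_values(sc$expression)
  g <- sc$truth$genes
  s1 <- sc$cohort$sample_id[sc$cohort$stage == "I"]
  s4 <- sc$cohort$sample_id[sc$cohort$stage == "IV"]
  diff <- rowMeans(m[, s4]) - rowMeans(m[, s1])
  planted <- g$planted
  # expected gap: direction * effect * 3 stage steps; sampling error of a
  # mean difference at n=50/stage is ~0.2 SD, so 0.8 is a 4-sigma band
  expect_true(all(abs(diff[planted] - 4.5 * g$direction[planted]) < 0.8))
  expect_true(all(abs(diff[!planted]) < 0.8))
})

test_that("control-group margins converge to mean 0, sd 1", {
  spec <- synthetic_spec(n_genes = 200, n_samples_per_stage = c(500L, 2L, 2L, 2L),
                         n_pathways = 4, genes_per_pathway = 10,
                         n_planted_pathways = 2, missing_rate = 0)
  sc <- generate_cohort(spec, seed = 9)
  m <- expr_values(sc$expression)
  ctrl <- sc$cohort$sample_id[sc$cohort$stage == "I"]
  mu <- rowMeans(m[, ctrl])
  s <- apply(m[, ctrl], 1, sd)
  expect_lt(mean(abs(mu)), 0.1)
  expect_lt(mean(abs(s - 1)), 0.1)
})

test_that("planted blocks reach the requested pairwise correlation", {
  spec <- synthetic_spec(n_genes = 100, n_samples_per_stage = c(200L, 2L, 2L, 2L),
                         n_pathways = 4, genes_per_pathway = 15,
                         n_planted_pathways = 2, effect_size = 0,
                         coexpr_block_rho = 0.7, missing_rate = 0)
  sc <- generate_cohort(spec, seed = 13)
  m <- expr_values(sc$expression)
  ctrl <- sc$cohort$sample_id[sc$cohort$stage == "I"]
  g <- sc$truth$genes
  for (pw in sc$truth$planted_pathways) {
    block <- m[g$gene_id[!is.na(g$pathway) & g$pathway == pw], ctrl]
    cm <- cor(t(block))
    expect_lt(abs(mean(cm[upper.tri(cm)]) - 0.7), 0.1)
  }
})

test_that("missing cells appear at close to the requested rate", {
  spec <- synthetic_spec(n_genes = 500, n_samples_per_stage = rep(25L, 4),
                         n_pathways = 5, genes_per_pathway = 10,
                         n_planted_pathways = 2, missing_rate = 0.05)
  sc <- generate_cohort(spec, seed = 2)
  frac <- mean(is.na(expr_values(sc$expression)))
  expect_lt(abs(frac - 0.05), 0.005)
})

test_that("balance profiles steer the expected imbalance trajectory", {
  spec <- synthetic_spec(n_genes = 60, n_samples_per_stage = rep(200L, 4),
                         n_pathways = 3, genes_per_pathway = 20,
                         n_planted_pathways = 3, effect_size = 1.5,
                         missing_rate = 0)
  truth <- generate_cohort(spec, seed = 21, return_truth_only = TRUE)
  truth <- plant_balance_profile(truth, "PW01", c(0, 0, 0, 0))
  truth <- plant_balance_profile(truth, "PW02", c(0, 0.5, 1, 1.5))
  truth <- plant_balance_profile(truth, "PW03", c(0, -0.5, -1, -1.5))
  sc <- generate_cohort(spec, seed = 21, truth = truth)

  # score with the known directions, unit baseline, flat weights
  dirs <- subset(merge(sc$truth$genes, data.frame(weight = 0.5, mu = 0)),
                 direction != 0)
  dirs <- tibble::tibble(pathway = dirs$pathway, gene_id = dirs$gene_id,
                         direction = ifelse(dirs$direction > 0, "up", "down"),
                         weight = dirs$weight, mu = dirs$mu)
  scores <- score_matrix(sc$expression, dirs)
  stage_means <- function(pw) {
    v <- unlist(scores[scores$pathway == pw, -1])
    tapply(v[sc$cohort$sample_id], sc$cohort$stage, mean)
  }
  flat <- stage_means("PW01")
  expect_true(all(abs(flat) < 0.15))
  up <- stage_means("PW02")
  expect_true(all(diff(up) > 0))
  down <- stage_means("PW03")
  expect_true(all(diff(down) < 0))

  expect_error(plant_balance_profile(truth, "PW01", c(0, 1)), "length 4")
  expect_error(plant_balance_profile(truth, "nope", rep(0, 4)), "not present")
})
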