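entry_tbl <- function(genes, directions, weights = 0.5, mu = 0,
                      pathway = "P") {
  tibble::tibble(pathway = pathway, gene_id = genes, direction = directions,
                 weight = rep_len(weights, length(genes)),
                 mu = rep_len(mu, length(genes)))
}

test_that("direction assignment labels planted genes by their shift", {
  spec <- synthetic_spec(n_genes = 60, n_samples_per_stage = rep(25L, 4),
                         n_pathways = 2, genes_per_pathway = 25,
                         n_planted_pathways = 2, effect_size = 1.5,
                         missing_rate = 0)
  sc <- generate_cohort(spec, seed = 19)
  pre <- zscore_to_control(sc$expression, sc$cohort)
  dirs <- assign_directions(pre, sc$cohort, sc$gene_sets)
  merged <- merge(dirs, sc$truth$genes, by = "gene_id")
  expect_gte(mean((merged$direction.x == "up") == (merged$direction.y == 1)),
             0.99)
  expect_true(all(abs(dirs$mu) < 1e-12))  # control-anchored z scale
})

test_that("pathways without scorable genes are excluded and logged", {
  x <- tiny_expr(matrix(rnorm(40), 2, 20), genes = c("gA", "gB"))
  cohort <- tiny_cohort(x, per_stage = rep(5, 4))
  sets <- tibble::tibble(pathway = c("present", "present", "ghost"),
                         gene = c("gA", "gB", "gZ"))
  dirs <- assign_directions(x, cohort, sets)
  expect_false("ghost" %in% dirs$pathway)
  log <- drop_log(dirs)
  expect_true("ghost" %in% log$item[log$reason == "no_member_genes"])

  # restricting to a feature universe that empties one side is unscorable
  dirs2 <- assign_directions(x, cohort, sets, feature_genes = "gA")
  expect_equal(nrow(dirs2), 0L)
  expect_true("present" %in%
                drop_log(dirs2)$item[drop_log(dirs2)$reason ==
                                       "unscorable_one_sided"])
})

test_that("imbalance score reproduces hand-computed values", {
  e <- entry_tbl(c("u", "d"), c("up", "down"))
  # equal weighted sums: log2(1) = 0
  expect_equal(imbalance_score(c(u = 1, d = 1), e), 0)
  # up deviation 2, down deviation 1, both weights 0.5: log2(4) = 2
  expect_equal(imbalance_score(c(u = 2, d = 1), e), 2)
  # doubling the down-side deviation shifts the score by exactly -2
  s1 <- imbalance_score(c(u = 3, d = 1.3), e)
  s2 <- imbalance_score(c(u = 3, d = 2.6), e)
  expect_equal(s2 - s1, -2)
  expect_error(imbalance_score(c(u = 1), e), "lacks genes")
  expect_error(imbalance_score(c(u = 1, d = 1),
                               entry_tbl("u", "up")), "unscorable")
})

test_that("score is antisymmetric under up/down swap and scale-equivariant", {
  set.seed(77)
  genes <- sprintf("g%d", 1:10)
  e <- entry_tbl(genes, rep(c("up", "down"), 5),
                 weights = runif(10, 0.5, 1), mu = rnorm(10, 0, 0.2))
  v <- setNames(rnorm(10, 0, 2), genes)
  swapped <- e
  swapped$direction <- ifelse(e$direction == "up", "down", "up")
  expect_equal(imbalance_score(v, swapped), -imbalance_score(v, e),
               tolerance = 1e-12)

  # multiplying every up deviation by c multiplies the ratio by c^2
  up_ids <- e$gene_id[e$direction == "up"]
  v2 <- v
  v2[up_ids] <- e$mu[match(up_ids, e$gene_id)] +
    3 * (v[up_ids] - e$mu[match(up_ids, e$gene_id)])
  expect_equal(imbalance_score(v2, e) - imbalance_score(v, e), 2 * log2(3),
               tolerance = 1e-12)
})

test_that("scores match an explicit summation loop to 1e-12", {
  set.seed(78)
  genes <- sprintf("g%02d", 1:20)
  e <- entry_tbl(genes, sample(c("up", "down"), 20, TRUE, prob = c(.6, .4)),
                 weights = runif(20, 0.5, 1), mu = rnorm(20, 0, 0.1))
  for (r in 1:20) {
    v <- setNames(rnorm(20), genes)
    expect_equal(imbalance_score(v, e), oracle_imbalance(v, e),
                 tolerance = 1e-12)
  }
})

test_that("a sample sitting exactly at baseline scores zero via the floor", {
  e <- entry_tbl(c("u", "d"), c("up", "down"), mu = c(1.5, -2))
  expect_equal(imbalance_score(c(u = 1.5, d = -2), e), 0)
})

test_that("score_matrix is a column-wise application of the score", {
  set.seed(79)
  m <- matrix(rnorm(5 * 8), 5, 8,
              dimnames = list(sprintf("g%d", 1:5), sprintf("s%d", 1:8)))
  x <- as_expr_tbl(m)
  e <- entry_tbl(sprintf("g%d", 1:5), c("up", "up", "down", "down", "up"),
                 weights = c(0.9, 0.5, 0.6, 0.8, 0.7))
  sm <- score_matrix(x, e)
  expect_equal(setdiff(names(sm), "pathway"), colnames(m))
  for (j in seq_len(8)) {
    expect_equal(sm[[colnames(m)[j]]], oracle_imbalance(m[, j], e),
                 tolerance = 1e-12)
  }
  # permuting sample order permutes columns identically
  perm <- c(3, 1, 2, 8, 5, 4, 7, 6)
  sm_perm <- score_matrix(as_expr_tbl(m[, perm]), e)
  expect_equal(sm_perm, sm[, c(1, 1 + perm)])
})

test_that("pathway screen is calibrated at the boundary and under signal", {
  spec <- synthetic_spec(n_genes = 500, n_samples_per_stage = rep(50L, 4),
                         n_pathways = 10, genes_per_pathway = 25,
                         n_planted_pathways = 3, effect_size = 1.5,
                         missing_rate = 0)
  sc <- generate_cohort(spec, seed = 23)
  pre <- zscore_to_control(sc$expression, sc$cohort)
  dirs <- assign_directions(pre, sc$cohort, sc$gene_sets)
  scores <- score_matrix(pre, dirs)
  screen <- screen_pathways(scores, sc$cohort)
  planted <- sc$truth$planted_pathways
  expect_true(all(planted %in% screen$pathway[screen$selected]))

  # alpha = 1 selects every scorable pathway
  all_sel <- screen_pathways(scores, sc$cohort, alpha = 1)
  expect_true(all(all_sel$selected))
})
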