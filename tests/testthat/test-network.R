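test_that("edges require strictly exceeding the correlation threshold", {
  # constructed pair with Pearson r exactly 0.5
  m <- rbind(a = c(-1, 0, 1), b = c(0, -2, 2))
  colnames(m) <- sprintf("s%d", 1:3)
  expect_equal(cor(m["a", ], m["b", ]), 0.5)
  net <- build_network(as_expr_tbl(m), threshold = 0.5)
  expect_equal(nrow(net$edges), 0L)
  net2 <- build_network(as_expr_tbl(m), threshold = 0.49)
  expect_equal(nrow(net2$edges), 1L)
  expect_equal(net2$edges$sign, "positive")
})

test_that("identical vectors give r = 1 and a positive edge", {
  m <- rbind(a = c(1, 3, 2, 5), b = c(1, 3, 2, 5))
  colnames(m) <- sprintf("s%d", 1:4)
  net <- build_network(as_expr_tbl(m), threshold = 0.5)
  expect_equal(net$edges$r, 1)
  expect_equal(net$edges$sign, "positive")
  expect_error(build_network(as_expr_tbl(m[, 1:2])), "at least 3 samples")
})

test_that("a 30-gene edge set equals the all-pairs correlation loop", {
  set.seed(50)
  m <- matrix(rnorm(30 * 12), 30, 12,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:12)))
  net <- build_network(as_expr_tbl(m), threshold = 0.5)
  ref <- oracle_edges(m, 0.5)
  ref <- ref[order(ref$gene_a, ref$gene_b), ]
  expect_equal(net$edges$gene_a, ref$gene_a)
  expect_equal(net$edges$gene_b, ref$gene_b)
  expect_equal(net$edges$r, ref$r, tolerance = 1e-12)
  expect_equal(net$edges$sign, ref$sign)
})

test_that("edge sign tallies match the edge list", {
  m <- matrix(rnorm(9), 3, 3,
              dimnames = list(sprintf("g%d", 1:3), sprintf("s%d", 1:3)))
  empty <- build_network(as_expr_tbl(m), threshold = 1.1)
  expect_equal(count_edge_signs(empty),
               tibble::tibble(n_positive = 0L, n_negative = 0L, n_total = 0L))

  # perfect triangle: three collinear genes
  base <- c(1, 2, 4, 8)
  tri <- rbind(a = base, b = 2 * base + 1, c = -0.5 * base)
  colnames(tri) <- sprintf("s%d", 1:4)
  net <- build_network(as_expr_tbl(tri), threshold = 0.5)
  counts <- count_edge_signs(net)
  expect_equal(counts$n_total, 3L)
  expect_equal(counts$n_positive, 1L)  # a-b; a-c and b-c are anticorrelated
  expect_equal(counts$n_negative, 2L)

  # planted anticorrelated pair among independent noise
  set.seed(51)
  noise <- matrix(rnorm(4 * 50), 4, 50)
  sig <- rnorm(50)
  m2 <- rbind(noise, up = sig, dn = -sig + rnorm(50, sd = 0.05))
  rownames(m2)[1:4] <- sprintf("n%d", 1:4)
  colnames(m2) <- sprintf("s%02d", 1:50)
  counts2 <- count_edge_signs(build_network(as_expr_tbl(m2), threshold = 0.5))
  expect_equal(counts2$n_negative, 1L)
})

test_that("path-graph and triangle topology match hand computation", {
  # 3-node path a-b-c: a and c orthogonal, b their sum, so r(a,b) =
  # r(b,c) = 1/sqrt(2) > 0.5 and r(a,c) = 0
  a <- c(1, -1, 1, -1)
  c_ <- c(1, 1, -1, -1)
  m <- rbind(a = a, b = a + c_, c = c_)
  colnames(m) <- sprintf("s%d", 1:4)
  net <- build_network(as_expr_tbl(m), threshold = 0.5)
  expect_setequal(paste(net$edges$gene_a, net$edges$gene_b),
                  c("a b", "b c"))
  topo <- topology(net)
  expect_equal(topo$average_shortest_path, 4 / 3)
  expect_equal(topo$nodes$closeness[topo$nodes$gene_id == "b"], 1.0)
  expect_equal(topo$nodes$closeness[topo$nodes$gene_id == "a"], 2 / 3)

  base <- c(1, 2, 4, 8)
  tri <- rbind(a = base, b = 2 * base, c = base + 0.001 * rnorm(4))
  colnames(tri) <- sprintf("s%d", 1:4)
  topo_tri <- topology(build_network(as_expr_tbl(tri), threshold = 0.5))
  expect_true(all(topo_tri$nodes$clustering == 1))
  expect_equal(topo_tri$average_shortest_path, 1)
})

test_that("topology equals the BFS/triple-count oracle on random graphs", {
  for (seed in 1:5) {
    set.seed(seed)
    n_genes <- sample(20:50, 1)
    m <- matrix(rnorm(n_genes * 8), n_genes, 8,
                dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                sprintf("s%d", 1:8)))
    net <- build_network(as_expr_tbl(m), threshold = 0.6)
    topo <- topology(net)
    ref <- oracle_topology(net$nodes, net$edges)
    expect_equal(topo$average_shortest_path, ref$asp, tolerance = 1e-10)
    expect_equal(setNames(topo$nodes$closeness, topo$nodes$gene_id),
                 ref$closeness[topo$nodes$gene_id], tolerance = 1e-10)
    expect_equal(setNames(topo$nodes$clustering, topo$nodes$gene_id),
                 ref$clustering[topo$nodes$gene_id], tolerance = 1e-10)
    expect_equal(setNames(as.double(topo$nodes$degree), topo$nodes$gene_id),
                 ref$degree[topo$nodes$gene_id])
  }
})

test_that("degree weights follow the sigmoid with 0.5 floor for absentees", {
  base <- c(1, 2, 4, 8, 16)
  m <- rbind(hub = base, x = 2 * base, y = 3 * base + 0.001 * c(1, -1, 0, 1, -1))
  colnames(m) <- sprintf("s%d", 1:5)
  net <- build_network(as_expr_tbl(m), threshold = 0.9)
  w <- degree_weights(net, all_genes = c("hub", "x", "y", "ghost"))
  expect_equal(w$weight[w$gene_id == "ghost"], 0.5)
  expect_false(w$in_network[w$gene_id == "ghost"])
  expect_equal(w$weight[w$gene_id == "hub"], 1 / (1 + exp(-2)),
               tolerance = 1e-12)
  # closed form for every observed degree, and monotone in degree
  expect_equal(w$weight, 1 / (1 + exp(-w$degree)), tolerance = 1e-12)
  expect_true(all(diff(w$weight[order(w$degree)]) >= 0))
})

test_that("within-block edges are recovered from planted correlation", {
  spec <- synthetic_spec(n_genes = 60, n_samples_per_stage = c(200L, 2L, 2L, 2L),
                         n_pathways = 2, genes_per_pathway = 20,
                         n_planted_pathways = 2, effect_size = 0,
                         coexpr_block_rho = 0.8, missing_rate = 0)
  sc <- generate_cohort(spec, seed = 17)
  ctrl <- sc$cohort$sample_id[sc$cohort$stage == "I"]
  net <- build_network(sc$expression, samples = ctrl, threshold = 0.5)
  g <- sc$truth$genes
  for (pw in sc$truth$planted_pathways) {
    members <- g$gene_id[!is.na(g$pathway) & g$pathway == pw]
    within <- net$edges$gene_a %in% members & net$edges$gene_b %in% members
    possible <- choose(length(members), 2)
    expect_gte(sum(within) / possible, 0.95)
  }
})
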