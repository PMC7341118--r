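# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use naive loops and first-principles formulas, never
# the code paths they validate.

# upper-tail hypergeometric probability P(X >= k) by exhaustive summation
oracle_hyper_tail <- function(k, K, n, N) {
  if (K == 0) return(1)
  js <- max(k, 0, n + K - N):min(n, K)
  js <- js[js >= k]
  if (!length(js)) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# all-pairs thresholded correlation edges by explicit double loop
oracle_edges <- function(m, threshold) {
  genes <- rownames(m)
  out <- list()
  for (i in seq_len(nrow(m) - 1L)) {
    for (j in (i + 1L):nrow(m)) {
      r <- cor(m[i, ], m[j, ])
      if (!is.na(r) && abs(r) > threshold) {
        out[[length(out) + 1L]] <- data.frame(
          gene_a = genes[i], gene_b = genes[j], r = r,
          sign = if (r > 0) "positive" else "negative")
      }
    }
  }
  if (!length(out)) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      r = double(), sign = character()))
  }
  do.call(rbind, out)
}

# BFS all-pairs distances over an undirected edge list
oracle_distances <- function(nodes, edges) {
  n <- length(nodes)
  adj <- setNames(vector("list", n), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges$gene_a[i]; b <- edges$gene_b[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  for (s in nodes) {
    frontier <- s
    dist <- 0
    while (length(frontier)) {
      nxt <- character()
      for (v in frontier) {
        for (w in adj[[v]]) {
          if (is.infinite(d[s, w])) {
            d[s, w] <- dist + 1
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- unique(nxt)
      dist <- dist + 1
    }
  }
  d
}

# ASP / closeness / clustering from first principles
oracle_topology <- function(nodes, edges) {
  d <- oracle_distances(nodes, edges)
  off <- d[row(d) != col(d)]
  asp <- if (any(is.finite(off))) mean(off[is.finite(off)]) else NaN

  closeness <- vapply(nodes, function(s) {
    ds <- d[s, setdiff(nodes, s)]
    reach <- sum(is.finite(ds))
    if (reach == 0) 0 else reach / sum(ds[is.finite(ds)])
  }, 0)

  adj <- matrix(0L, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    adj[edges$gene_a[i], edges$gene_b[i]] <- 1L
    adj[edges$gene_b[i], edges$gene_a[i]] <- 1L
  }
  clustering <- vapply(nodes, function(s) {
    nb <- nodes[adj[s, ] == 1L]
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0L
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) links <- links + adj[nb[i], nb[j]]
    }
    2 * links / (k * (k - 1))
  }, 0)

  list(asp = asp, closeness = closeness, clustering = clustering,
       degree = rowSums(adj))
}

# weighted squared-deviation ratio score by explicit loop
oracle_imbalance <- function(sample_values, entry, eps = 1e-8) {
  num <- 0; den <- 0
  for (i in seq_len(nrow(entry))) {
    term <- entry$weight[i] * (sample_values[[entry$gene_id[i]]] - entry$mu[i])^2
    if (entry$direction[i] == "up") num <- num + term else den <- den + term
  }
  log2(max(num, eps) / max(den, eps))
}

# sort-and-cut reimplementation of the two-tail CV filter
oracle_two_tail <- function(cv, q_low, q_high) {
  cv <- cv[!is.na(cv)]
  qs <- quantile(cv, c(q_low, q_high), type = 7, names = FALSE)
  names(cv)[cv < qs[1] | cv > qs[2]]
}

# small deterministic expression tibble from a matrix-like definition
tiny_expr <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- genes %||% sprintf("g%d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%d", seq_len(ncol(m)))
  as_expr_tbl(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# balanced four-stage cohort over the samples of an expression tibble
tiny_cohort <- function(x, per_stage = NULL) {
  smp <- setdiff(names(x), "gene_id")
  if (is.null(per_stage)) per_stage <- rep(length(smp) %/% 4, 4)
  tibble::tibble(
    sample_id = smp[seq_len(sum(per_stage))],
    stage = factor(rep(c("I", "II", "III", "IV"), times = per_stage),
                   levels = c("I", "II", "III", "IV")))
}
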