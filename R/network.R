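#' Build a thresholded Pearson co-expression network
#'
#' Nodes are the requested genes; an edge joins two genes whose Pearson
#' correlation over the chosen samples is strictly greater than `threshold`
#' (positive edge) or strictly less than `-threshold` (negative edge).
#' Correlations exactly at the threshold do not form edges.
#'
#' @param x expression tibble (normalized).
#' @param genes character vector of genes to include (default: all).
#' @param samples character vector of samples to correlate over (default:
#'   all); at least 3 required.
#' @param threshold absolute-correlation cutoff (default 0.5).
#' @return object of class `coexpr_network`: list with `nodes`, `edges`
#'   (tibble `gene_a`, `gene_b`, `r`, `sign`), `threshold`, `n_samples`.
#' @export
build_network <- function(x, genes = NULL, samples = NULL, threshold = 0.5) {
  check_expr_tbl(x)
  m <- expr_values(x)
  if (!is.null(genes)) m <- m[rownames(m)[rownames(m) %in% genes], , drop = FALSE]
  if (!is.null(samples)) m <- m[, colnames(m)[colnames(m) %in% samples], drop = FALSE]
  if (ncol(m) < 3L) abort("need at least 3 samples to correlate")
  if (nrow(m) < 2L) {
    return(structure(list(nodes = rownames(m),
                          edges = tibble(gene_a = character(), gene_b = character(),
                                         r = double(), sign = character()),
                          threshold = threshold, n_samples = ncol(m)),
                     class = "coexpr_network"))
  }
  cm <- suppressWarnings(cor(t(m)))
  cm[is.na(cm)] <- 0            # constant genes correlate with nothing
  ut <- upper.tri(cm)
  hit <- ut & (cm > threshold | cm < -threshold)
  idx <- which(hit, arr.ind = TRUE)
  edges <- tibble(
    gene_a = rownames(cm)[idx[, 1L]],
    gene_b = colnames(cm)[idx[, 2L]],
    r = cm[hit],
    sign = ifelse(cm[hit] > 0, "positive", "negative")
  ) |> arrange(.data$gene_a, .data$gene_b)
  structure(list(nodes = rownames(m), edges = edges,
                 threshold = threshold, n_samples = ncol(m)),
            class = "coexpr_network")
}

#' @export
print.coexpr_network <- function(x, ...) {
  cat("<coexpr_network> ", length(x$nodes), "nodes,", nrow(x$edges),
      "edges (|r| >", x$threshold, "over", x$n_samples, "samples)\n")
  invisible(x)
}

#' Tally positive and negative co-expression edges
#'
#' @param network a `coexpr_network`.
#' @return one-row tibble `n_positive`, `n_negative`, `n_total`.
#' @export
count_edge_signs <- function(network) {
  stopifnot(inherits(network, "coexpr_network"))
  tibble(n_positive = sum(network$edges$sign == "positive"),
         n_negative = sum(network$edges$sign == "negative"),
         n_total = nrow(network$edges))
}

as_igraph <- function(network) {
  igraph::graph_from_data_frame(
    network$edges[, c("gene_a", "gene_b")],
    directed = FALSE,
    vertices = data.frame(name = network$nodes)
  )
}

#' Topology summary of a co-expression network
#'
#' Computes the average shortest path (ASP; mean geodesic distance over all
#' connected ordered pairs — unreachable pairs are excluded, not infinite),
#' per-node closeness centrality (number of reachable nodes divided by the
#' sum of distances to them; isolated nodes get 0), the local clustering
#' coefficient (closed triplets over possible triplets; nodes with degree
#' < 2 get 0) and the degree distribution.
#'
#' @param network a `coexpr_network`.
#' @return object of class `topology_summary`: list with
#'   `average_shortest_path`, `nodes` (tibble `gene_id`, `degree`,
#'   `closeness`, `clustering`) and `degree_distribution` (tibble `degree`,
#'   `count`).
#' @export
topology <- function(network) {
  stopifnot(inherits(network, "coexpr_network"))
  g <- as_igraph(network)
  n <- igraph::vcount(g)
  if (n == 0L) {
    return(structure(list(average_shortest_path = NaN,
                          nodes = tibble(gene_id = character(), degree = integer(),
                                         closeness = double(), clustering = double()),
                          degree_distribution = tibble(degree = integer(),
                                                       count = integer())),
                     class = "topology_summary"))
  }
  d <- igraph::distances(g)
  off <- d[row(d) != col(d)]
  finite <- off[is.finite(off)]
  asp <- if (length(finite)) mean(finite) else NaN

  reach <- rowSums(is.finite(d)) - 1L
  dsum <- apply(d, 1L, function(v) sum(v[is.finite(v)]))
  closeness <- ifelse(reach > 0, reach / dsum, 0)

  clust <- igraph::transitivity(g, type = "local", isolates = "zero")
  clust[is.na(clust)] <- 0
  deg <- igraph::degree(g)

  nodes <- tibble(gene_id = igraph::V(g)$name,
                  degree = as.integer(deg),
                  closeness = unname(closeness),
                  clustering = clust)
  dist_tbl <- nodes |> count(.data$degree, name = "count") |> arrange(.data$degree)

  structure(list(average_shortest_path = asp, nodes = nodes,
                 degree_distribution = dist_tbl),
            class = "topology_summary")
}

#' @export
print.topology_summary <- function(x, ...) {
  cat("<topology_summary>\n")
  cat("  ASP:", format(x$average_shortest_path), "\n")
  cat("  nodes:", nrow(x$nodes),
      " mean degree:", format(mean(x$nodes$degree)), "\n")
  invisible(x)
}

#' Sigmoid degree weights for pathway scoring
#'
#' Converts node degree into a gene importance weight
#' `omega = 1 / (1 + exp(-degree))`, mapping connectivity into (0.5, 1).
#' Genes absent from the network (or isolated in it) take the minimum
#' weight 0.5 = sigmoid(0).
#'
#' @param network a `coexpr_network`.
#' @param all_genes character vector of genes to weight (defaults to the
#'   network's nodes).
#' @return tibble `gene_id`, `degree`, `in_network`, `weight`.
#' @export
degree_weights <- function(network, all_genes = NULL) {
  stopifnot(inherits(network, "coexpr_network"))
  all_genes <- all_genes %||% network$nodes
  deg <- setNames(integer(length(all_genes)), all_genes)
  tab <- table(c(network$edges$gene_a, network$edges$gene_b))
  hit <- intersect(names(tab), all_genes)
  deg[hit] <- as.integer(tab[hit])
  tibble(gene_id = all_genes,
         degree = unname(deg),
         in_network = all_genes %in% network$nodes,
         weight = plogis(unname(deg)))
}
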