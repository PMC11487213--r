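## Structural network metrics, weighted PageRank importance, node-removal
## experiments, and abundant-connection comparison between subgroup networks.

#' Structural summary of a comorbidity network
#'
#' Computes, on the unweighted thresholded graph: density
#' `2E / (N (N - 1))`, per-node degree, average neighbor degree (mean degree
#' over each node's neighbors; `NA` for isolated nodes), unnormalized
#' betweenness centrality (shortest-path counts), weighted PageRank, mean
#' degree `2E / N`, and median/IQR summaries of degree and neighbor degree
#' for table-style reporting.
#'
#' @param net A [pcn] object (or an `igraph` graph).
#' @param damping PageRank damping factor (default 0.85).
#' @return List of class `pcn_summary`: `node_count`, `edge_count`,
#'   `density`, `mean_degree`, `degree_median`, `degree_iqr`,
#'   `neighbor_degree_median`, `neighbor_degree_iqr`, `node_metrics` (per
#'   node: degree, avg_neighbor_degree, betweenness, pagerank).
#' @export
summarize_network <- function(net, damping = 0.85) {
  g <- if (inherits(net, "pcn")) net$graph else net
  nv <- igraph::vcount(g)
  ne <- igraph::ecount(g)
  if (nv < 2L) {
    pcnet_error("pcnet_degenerate_network",
                "density undefined for a network with fewer than 2 nodes")
  }
  deg <- igraph::degree(g)
  knn <- suppressWarnings(igraph::knn(g, weights = NA)$knn)
  knn[deg == 0] <- NA_real_
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA,
                             normalized = FALSE)
  pr <- pagerank_scores(g, damping = damping)
  qs <- function(x) quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
  dq <- qs(deg)
  kq <- if (all(is.na(knn))) c(NA, NA, NA) else qs(knn)
  structure(list(
    node_count = nv, edge_count = ne,
    density = 2 * ne / (nv * (nv - 1)),
    mean_degree = 2 * ne / nv,
    degree_median = dq[2], degree_iqr = c(dq[1], dq[3]),
    neighbor_degree_median = kq[2], neighbor_degree_iqr = c(kq[1], kq[3]),
    node_metrics = data.frame(code = igraph::V(g)$name, degree = deg,
                              avg_neighbor_degree = knn, betweenness = btw,
                              pagerank = pr, stringsAsFactors = FALSE,
                              row.names = NULL)
  ), class = "pcn_summary")
}

#' Density and mean degree from node/edge counts
#'
#' The count-based arithmetic behind table-style network summaries:
#' `density = 2E / (N (N - 1))` and `mean_degree = 2E / N` for an undirected
#' simple graph with `N` nodes and `E` edges.
#'
#' @param node_count,edge_count Counts.
#' @return List with `density` and `mean_degree`.
#' @examples
#' summarize_counts(72, 492)   # density 0.192, mean degree 13.7
#' @export
summarize_counts <- function(node_count, edge_count) {
  stopifnot(node_count >= 2, edge_count >= 0)
  list(density = 2 * edge_count / (node_count * (node_count - 1)),
       mean_degree = 2 * edge_count / node_count)
}

#' @export
print.pcn_summary <- function(x, ...) {
  cat(sprintf("Nodes: %d  Edges: %d  Density: %.3f  Mean degree: %.1f\n",
              x$node_count, x$edge_count, x$density, x$mean_degree))
  cat(sprintf("Degree: median %.1f (IQR %.1f-%.1f)\n", x$degree_median,
              x$degree_iqr[1], x$degree_iqr[2]))
  cat(sprintf("Neighbor degree: median %.1f (IQR %.1f-%.1f)\n",
              x$neighbor_degree_median, x$neighbor_degree_iqr[1],
              x$neighbor_degree_iqr[2]))
  invisible(x)
}

#' @export
summary.pcn <- function(object, damping = 0.85, ...) {
  summarize_network(object, damping = damping)
}

pagerank_scores <- function(g, damping = 0.85) {
  if (igraph::vcount(g) == 0L) return(numeric(0))
  w <- if (igraph::ecount(g) > 0L && "weight" %in%
             igraph::edge_attr_names(g)) igraph::E(g)$weight else NA
  igraph::page_rank(g, damping = damping, weights = w)$vector
}

#' Rank comorbidities by weighted PageRank
#'
#' Weighted PageRank on the undirected network: each edge acts as two
#' directed edges with transition probability proportional to its cosine
#' weight; dangling (isolated) nodes teleport uniformly. Scores sum to 1.
#' Ties in score are broken lexicographically by code and flagged.
#'
#' @param net A [pcn] object.
#' @param damping Damping factor (default 0.85).
#' @param top_k Number of top comorbidities to mark (default 5).
#' @return Data frame ranked by decreasing score: `rank`, `code`,
#'   `pagerank`, `top`, `tied`.
#' @export
pagerank_importance <- function(net, damping = 0.85, top_k = 5) {
  g <- if (inherits(net, "pcn")) net$graph else net
  if (igraph::vcount(g) == 0L) {
    return(data.frame(rank = integer(0), code = character(0),
                      pagerank = numeric(0), top = logical(0),
                      tied = logical(0)))
  }
  pr <- pagerank_scores(g, damping = damping)
  code <- igraph::V(g)$name
  ord <- order(-pr, code)
  pr <- pr[ord]; code <- code[ord]
  tied <- duplicated(signif(pr, 12)) | rev(duplicated(rev(signif(pr, 12))))
  data.frame(rank = seq_along(pr), code = code, pagerank = pr,
             top = seq_along(pr) <= top_k, tied = tied,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Remove nodes and measure the network contraction
#'
#' Removes either named nodes or the top-k by degree or betweenness and
#' reports the share of edges lost, the style of hub-knockout experiment
#' used to show how much of a comorbidity network hangs on a few hub
#' diseases.
#'
#' @param net A [pcn] object.
#' @param nodes Character vector of codes to remove; when `NULL`, the top
#'   `k` by `by` are removed.
#' @param by `"degree"` or `"betweenness"` (used when `nodes` is `NULL`).
#' @param k Number of top nodes to remove (default 5).
#' @return List: `removed` (codes), `edges_before`, `edges_after`,
#'   `edges_removed`, `edge_drop_fraction`, `graph` (reduced igraph).
#' @export
remove_top_nodes <- function(net, nodes = NULL, by = c("degree", "betweenness"),
                             k = 5) {
  g <- if (inherits(net, "pcn")) net$graph else net
  by <- match.arg(by)
  if (is.null(nodes)) {
    if (k >= igraph::vcount(g)) {
      pcnet_error("pcnet_config_error", "k must be smaller than the node count")
    }
    score <- switch(by,
                    degree = igraph::degree(g),
                    betweenness = igraph::betweenness(g, directed = FALSE,
                                                      weights = NA))
    nodes <- igraph::V(g)$name[order(-score, igraph::V(g)$name)][seq_len(k)]
  }
  nodes <- intersect(nodes, igraph::V(g)$name)
  e0 <- igraph::ecount(g)
  g2 <- igraph::delete_vertices(g, nodes)
  e1 <- igraph::ecount(g2)
  list(removed = nodes, edges_before = e0, edges_after = e1,
       edges_removed = e0 - e1,
       edge_drop_fraction = if (e0 > 0) (e0 - e1) / e0 else 0,
       graph = g2)
}

#' Abundant connections between two subgroup networks
#'
#' Every edge present in either network is classified: `shared` when present
#' in both with cosine weights within `threshold` of each other;
#' `abundant_in_a` / `abundant_in_b` when unique to one network
#' (`mode = "unique"`) or present in both with a weight at least `threshold`
#' higher on one side (`mode = "enriched"`).
#'
#' @param net_a,net_b [pcn] objects built with the same universe policy.
#' @param threshold Minimum cosine difference for enrichment (default 0.05).
#' @return Data frame: `code_a`, `code_b`, `cosine_in_a`, `cosine_in_b`
#'   (`NA` when absent), `status`, `mode`.
#' @export
abundant_connections <- function(net_a, net_b, threshold = 0.05) {
  stopifnot(inherits(net_a, "pcn"), inherits(net_b, "pcn"))
  if (net_a$include_td != net_b$include_td) {
    pcnet_error("pcnet_universe_mismatch",
                "networks were built with different node-universe policies")
  }
  ea <- net_a$edges; eb <- net_b$edges
  key <- function(e) paste(e$code_a, e$code_b, sep = "|")
  all_keys <- union(key(ea), key(eb))
  if (length(all_keys) == 0L) {
    return(data.frame(code_a = character(0), code_b = character(0),
                      cosine_in_a = numeric(0), cosine_in_b = numeric(0),
                      status = character(0), mode = character(0)))
  }
  ca <- setNames(ea$cosine, key(ea))[all_keys]
  cb <- setNames(eb$cosine, key(eb))[all_keys]
  parts <- do.call(rbind, strsplit(all_keys, "|", fixed = TRUE))
  status <- mode <- character(length(all_keys))
  for (i in seq_along(all_keys)) {
    a <- ca[i]; b <- cb[i]
    if (is.na(b)) { status[i] <- "abundant_in_a"; mode[i] <- "unique" }
    else if (is.na(a)) { status[i] <- "abundant_in_b"; mode[i] <- "unique" }
    else if (a - b >= threshold) { status[i] <- "abundant_in_a"; mode[i] <- "enriched" }
    else if (b - a >= threshold) { status[i] <- "abundant_in_b"; mode[i] <- "enriched" }
    else { status[i] <- "shared"; mode[i] <- "shared" }
  }
  out <- data.frame(code_a = parts[, 1], code_b = parts[, 2],
                    cosine_in_a = unname(ca), cosine_in_b = unname(cb),
                    status = status, mode = mode,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$code_a, out$code_b), , drop = FALSE]
}
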