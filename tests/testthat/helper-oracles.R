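# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately avoid the package's own computational paths.

# cosine of two 0/1 indicator vectors, straight from the definition
oracle_cosine <- function(a, b) {
  sum(a * b) / sqrt(sum(a * a) * sum(b * b))
}

# Pearson correlation of the raw 0/1 vectors
oracle_phi <- function(a, b) {
  suppressWarnings(cor(a, b))
}

# pair counts by brute-force double loop over records
oracle_pair_counts <- function(code_sets, code_a, code_b) {
  n_a <- n_b <- n_ab <- 0L
  for (cs in code_sets) {
    ia <- code_a %in% cs; ib <- code_b %in% cs
    n_a <- n_a + ia; n_b <- n_b + ib; n_ab <- n_ab + (ia && ib)
  }
  c(n_a = n_a, n_b = n_b, n_ab = n_ab)
}

# unnormalized betweenness by explicit shortest-path counting:
# BFS distances from every source, then sigma (path counts) by dynamic
# programming over distance levels; each unordered pair counted once.
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  dist_from <- function(s) {
    d <- rep(Inf, n); d[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(adj[v, ] == 1)) {
          if (is.infinite(d[w])) { d[w] <- d[v] + 1; nxt <- c(nxt, w) }
        }
      }
      frontier <- unique(nxt)
    }
    d
  }
  D <- t(vapply(seq_len(n), dist_from, numeric(n)))
  sigma <- function(s, t) {   # number of shortest s-t paths
    if (is.infinite(D[s, t])) return(0)
    if (s == t) return(1)
    sum(vapply(which(adj[, t] == 1), function(w) {
      if (D[s, w] == D[s, t] - 1) sigma(s, w) else 0
    }, 0))
  }
  btw <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (is.infinite(D[s, t])) next
    sst <- sigma(s, t)
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (D[s, v] + D[v, t] == D[s, t]) {
        btw[v] <- btw[v] + sigma(s, v) * sigma(v, t) / sst
      }
    }
  }
  btw
}

# random small cohort: n records over given codes, each code iid present
random_code_sets <- function(n, codes, p = 0.4) {
  lapply(seq_len(n), function(i) codes[runif(length(codes)) < p])
}

make_cohort <- function(codes_list, age = NULL, sex = NULL, ids = NULL) {
  n <- length(codes_list)
  new_cohort(ids %||% sprintf("e%03d", seq_len(n)),
             age %||% rep(50L, n),
             sex %||% rep(c("male", "female"), length.out = n),
             codes_list)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small ready-made analysis cohort: every record adult with a TD code
toy_filtered_cohort <- function() {
  make_cohort(list(
    c("E04", "I10", "E11"),
    c("E04", "I10"),
    c("E03", "E11", "K29"),
    c("C73", "I10", "K29"),
    c("E04", "E11", "I10"),
    c("E03", "I10", "K29")
  ), age = c(45L, 60L, 70L, 38L, 55L, 65L))
}

# igraph from an edge list over named nodes (test-side construction)
make_pcn_from_edges <- function(nodes, edges_df, N = 100L) {
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = edges_df$code_a, to = edges_df$code_b,
                   weight = edges_df$cosine),
    directed = FALSE,
    vertices = data.frame(name = nodes, prevalence = 0.1))
  structure(list(
    nodes = data.frame(code = nodes, label = nodes, n = 10L,
                       prevalence = 0.1, stringsAsFactors = FALSE),
    edges = if (nrow(edges_df)) {
      data.frame(code_a = edges_df$code_a, code_b = edges_df$code_b,
                 N = N, n_a = 10L, n_b = 10L, n_ab = 5L,
                 cosine = edges_df$cosine, phi = 0.2, t = 2,
                 p_value = 0.01, significant = TRUE,
                 stringsAsFactors = FALSE)
    } else cbind(edges_df, data.frame(N = integer(0), n_a = integer(0),
                                      n_b = integer(0), n_ab = integer(0),
                                      phi = numeric(0), t = numeric(0),
                                      p_value = numeric(0),
                                      significant = logical(0))),
    pairs = NULL,
    cutoff = if (nrow(edges_df)) min(edges_df$cosine) else Inf,
    K = nrow(edges_df),
    tie_broadened = FALSE, alpha = 0.05, N = N, include_td = TRUE,
    label = NULL, universe = nodes, graph = g), class = "pcn")
}
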