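## Phenotypic comorbidity network construction: pairwise co-occurrence
## statistics, Pearson-matched cutoff calibration, and the pcn() fit.

#' Binary disease incidence matrix
#'
#' @param cohort An `emr_cohort`.
#' @param codes Column universe.
#' @return Logical matrix, records x codes.
#' @export
incidence_matrix <- function(cohort, codes) {
  n <- length(cohort)
  M <- matrix(FALSE, n, length(codes), dimnames = list(NULL, codes))
  if (n == 0L || length(codes) == 0L) return(M)
  k <- lengths(cohort$codes)
  rec <- rep.int(seq_len(n), k)
  code <- unlist(cohort$codes, use.names = FALSE)
  keep <- code %in% codes
  M[cbind(rec[keep], match(code[keep], codes))] <- TRUE
  M
}

#' Cosine co-occurrence index
#'
#' `n_ab / sqrt(n_a * n_b)`: the cosine of the angle between the two binary
#' disease indicator vectors. Nonnegative, 1 for identical incidence, 0 iff
#' the diseases never co-occur.
#'
#' @param n_ab Joint count.
#' @param n_a,n_b Marginal counts (> 0).
#' @return Cosine index in \[0, 1\].
#' @export
cosine_index <- function(n_ab, n_a, n_b) {
  if (any(n_a <= 0) || any(n_b <= 0)) {
    pcnet_error("pcnet_undefined_pair",
                "cosine index undefined for zero marginal counts")
  }
  n_ab / sqrt(n_a * n_b)
}

#' Phi coefficient of two binary diseases
#'
#' The Pearson correlation of the 0/1 indicator vectors, computed from the
#' 2x2 contingency counts:
#' `(N*n_ab - n_a*n_b) / sqrt(n_a*n_b*(N-n_a)*(N-n_b))`.
#'
#' @param N Cohort size.
#' @param n_a,n_b Marginal counts, strictly between 0 and N.
#' @param n_ab Joint count.
#' @return Correlation in \[-1, 1\].
#' @export
phi_coefficient <- function(N, n_a, n_b, n_ab) {
  if (any(n_a <= 0) || any(n_b <= 0) || any(n_a >= N) || any(n_b >= N)) {
    pcnet_error("pcnet_undefined_correlation",
                "phi undefined for degenerate marginals (0 or N)")
  }
  (N * n_ab - n_a * n_b) / sqrt(n_a * n_b * (N - n_a) * (N - n_b))
}

#' t-test for a correlation coefficient
#'
#' `t = r * sqrt((N - 2) / (1 - r^2))`, two-tailed p from Student's t with
#' N - 2 degrees of freedom. For |r| = 1 the statistic is infinite; p = 0 is
#' returned with `infinite = TRUE`.
#'
#' @param r Correlation (phi coefficient).
#' @param N Sample size (> 2).
#' @return List with `t`, `p_value`, `infinite`.
#' @export
correlation_t_test <- function(r, N) {
  stopifnot(all(N > 2))
  infinite <- abs(r) >= 1
  t <- ifelse(infinite, sign(r) * Inf, r * sqrt((N - 2) / (1 - r^2)))
  p <- ifelse(infinite, 0, 2 * pt(-abs(t), df = N - 2))
  list(t = t, p_value = p, infinite = infinite)
}

#' Pairwise co-occurrence statistics for a cohort
#'
#' Exact contingency counts for every unordered code pair from the record
#' code-sets, plus cosine index, phi coefficient, and the correlation
#' t-test. Pairs where either disease has a zero marginal count are skipped
#' (not zero-filled); pairs with a degenerate marginal (count = N) carry
#' `NA` phi and are never significant.
#'
#' @param cohort An `emr_cohort`.
#' @param universe Codes to consider (default: comorbidity universe plus
#'   thyroid codes present when `include_td`).
#' @param include_td Include thyroid-disease codes as nodes (default TRUE).
#' @param alpha Significance level for the `significant` flag (default 0.05).
#' @return Data frame, one row per pair (`code_a < code_b`): `code_a`,
#'   `code_b`, `N`, `n_a`, `n_b`, `n_ab`, `cosine`, `phi`, `t`, `p_value`,
#'   `significant`.
#' @export
pair_statistics <- function(cohort, universe = NULL, include_td = TRUE,
                            alpha = 0.05) {
  if (is.null(universe)) {
    universe <- comorbidity_universe(cohort)
    if (include_td) {
      present <- sort(unique(unlist(cohort$codes)))
      universe <- sort(c(universe, present[is_td_code(present)]))
    }
  }
  universe <- sort(unique(universe))
  if (length(universe) < 2L) {
    pcnet_error("pcnet_config_error", "need at least 2 codes for pair statistics")
  }
  M <- incidence_matrix(cohort, universe)
  N <- nrow(M)
  n <- colSums(M)
  keep <- n > 0           # zero-marginal codes are skipped entirely
  M <- M[, keep, drop = FALSE]
  n <- n[keep]
  codes <- colnames(M)
  D <- length(codes)
  if (D < 2L) {
    return(empty_pair_table())
  }
  C <- crossprod(M * 1)   # D x D joint counts
  ia <- rep(seq_len(D - 1L), times = (D - 1L):1L)
  ib <- unlist(lapply(seq_len(D - 1L), function(i) (i + 1L):D))
  n_a <- n[ia]; n_b <- n[ib]
  n_ab <- C[cbind(ia, ib)]
  cosine <- n_ab / sqrt(n_a * n_b)
  degen <- n_a >= N | n_b >= N
  phi <- rep(NA_real_, length(ia))
  phi[!degen] <- (N * n_ab[!degen] - n_a[!degen] * n_b[!degen]) /
    sqrt(n_a[!degen] * n_b[!degen] * (N - n_a[!degen]) * (N - n_b[!degen]))
  tt <- correlation_t_test(ifelse(is.na(phi), 0, phi), max(N, 3))
  t_stat <- ifelse(is.na(phi), NA_real_, tt$t)
  p <- ifelse(is.na(phi), NA_real_, tt$p_value)
  data.frame(code_a = codes[ia], code_b = codes[ib],
             N = N, n_a = unname(n_a), n_b = unname(n_b), n_ab = unname(n_ab),
             cosine = unname(cosine), phi = unname(phi), t = unname(t_stat),
             p_value = unname(p),
             significant = !is.na(phi) & phi > 0 & !is.na(p) & p < alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}

empty_pair_table <- function() {
  data.frame(code_a = character(0), code_b = character(0), N = integer(0),
             n_a = integer(0), n_b = integer(0), n_ab = integer(0),
             cosine = numeric(0), phi = numeric(0), t = numeric(0),
             p_value = numeric(0), significant = logical(0),
             stringsAsFactors = FALSE)
}

#' Calibrate the cosine cutoff against the Pearson significance count
#'
#' Let K be the number of pairs with positive phi coefficient significant at
#' `alpha` (two-tailed). The cutoff is the K-th largest cosine index among
#' all pairs, so the cosine-thresholded network has as many edges as there
#' are significantly correlated pairs; ties at the cutoff value are all
#' included (and noted). K = 0 yields an infinite cutoff and an empty edge
#' set.
#'
#' @param pairs Pair table from [pair_statistics()].
#' @param alpha Significance level (default 0.05).
#' @return List: `cutoff`, `K`, `n_edges` (after ties), `tie_broadened`
#'   (TRUE when ties pushed the edge count above K).
#' @export
calibrate_cutoff <- function(pairs, alpha = 0.05) {
  K <- sum(!is.na(pairs$phi) & pairs$phi > 0 &
             !is.na(pairs$p_value) & pairs$p_value < alpha)
  if (K == 0L) {
    return(list(cutoff = Inf, K = 0L, n_edges = 0L, tie_broadened = FALSE))
  }
  cs <- sort(pairs$cosine, decreasing = TRUE)
  cutoff <- cs[K]
  n_edges <- sum(pairs$cosine >= cutoff)
  list(cutoff = cutoff, K = K, n_edges = n_edges,
       tie_broadened = n_edges > K)
}

#' Fit a phenotypic comorbidity network
#'
#' The central model object of the package. From a cleaned cohort (or any
#' subgroup of it), computes all pairwise co-occurrence statistics, calibrates
#' the cosine cutoff so the network has as many edges as there are
#' significantly Pearson-correlated pairs, and returns the weighted
#' undirected network: nodes are diseases (sized by prevalence), edges carry
#' the cosine index as weight. Deterministic in its inputs and invariant to
#' record and code order.
#'
#' @param cohort A cleaned `emr_cohort` (see [filter_cohort()]).
#' @param universe Node universe; default the cohort's comorbidity universe,
#'   plus its thyroid codes when `include_td`.
#' @param include_td Keep thyroid-disease codes as network nodes (default
#'   TRUE; they are always excluded from comorbidity prevalence tables).
#' @param alpha Two-tailed significance level for the Pearson calibration
#'   (default 0.05; only positive correlations count, since edges represent
#'   coexistence).
#' @param label Optional provenance label (e.g. `"male"`).
#' @return Object of class `pcn`: list with `nodes` (code, label,
#'   n, prevalence), `edges` (pair statistics of retained edges), `pairs`
#'   (all pair statistics), `cutoff`, `K`, `alpha`, `N`, `label`, `universe`,
#'   and `graph` (the igraph representation, edge attribute `weight` =
#'   cosine).
#' @examples
#' cfg <- sim_config(n_records = 2000, seed = 7,
#'                   diseases = data.frame(code = c("I10", "E11", "K29"),
#'                                         base_prevalence = c(0.3, 0.2, 0.15)),
#'                   planted_pairs = data.frame(code_a = "I10", code_b = "E11",
#'                                              target_cosine = 0.45))
#' net <- pcn(filter_cohort(simulate_cohort(cfg)))
#' print(net)
#' @export
pcn <- function(cohort, universe = NULL, include_td = TRUE, alpha = 0.05,
                label = NULL) {
  if (length(cohort) < 3L) {
    warning("fewer than 3 records; network is degenerate")
  }
  pairs <- pair_statistics(cohort, universe = universe,
                           include_td = include_td, alpha = alpha)
  cal <- calibrate_cutoff(pairs, alpha = alpha)
  edges <- pairs[pairs$cosine >= cal$cutoff & pairs$cosine > 0, , drop = FALSE]
  node_codes <- if (is.null(universe)) {
    sort(unique(c(pairs$code_a, pairs$code_b)))
  } else sort(unique(universe))
  prev <- code_prevalence(cohort, node_codes)
  nodes <- data.frame(code = prev$code, label = prev$code, n = prev$n,
                      prevalence = prev$prevalence, stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    d = if (nrow(edges)) data.frame(from = edges$code_a, to = edges$code_b,
                                    weight = edges$cosine,
                                    stringsAsFactors = FALSE)
        else data.frame(from = character(0), to = character(0),
                        weight = numeric(0)),
    directed = FALSE,
    vertices = data.frame(name = nodes$code, prevalence = nodes$prevalence)
  )
  structure(list(nodes = nodes, edges = edges, pairs = pairs,
                 cutoff = cal$cutoff, K = cal$K,
                 tie_broadened = cal$tie_broadened,
                 alpha = alpha, N = pairs$N[1] %||% length(cohort),
                 include_td = include_td,
                 label = label, universe = node_codes, graph = g),
            class = "pcn")
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a[1])) b else a

#' @export
print.pcn <- function(x, ...) {
  cat(sprintf("Phenotypic comorbidity network%s\n",
              if (is.null(x$label)) "" else sprintf(" [%s]", x$label)))
  cat(sprintf("  cohort: %d records; nodes: %d; edges: %d\n",
              x$N, nrow(x$nodes), nrow(x$edges)))
  cat(sprintf("  cosine cutoff: %s (K = %d significant Pearson pairs%s, alpha = %g)\n",
              if (is.finite(x$cutoff)) sprintf("%.4f", x$cutoff) else "Inf",
              x$K, if (x$tie_broadened) "; ties broadened the edge set" else "",
              x$alpha))
  invisible(x)
}

#' Plot a comorbidity network
#'
#' Basic igraph rendering: node size proportional to prevalence, edge width
#' to the cosine index.
#'
#' @param x A `pcn` object.
#' @param ... Passed to [igraph::plot.igraph()].
#' @export
plot.pcn <- function(x, ...) {
  if (nrow(x$edges) == 0L && nrow(x$nodes) == 0L) {
    pcnet_error("pcnet_empty_network", "nothing to plot")
  }
  sz <- 3 + 25 * igraph::V(x$graph)$prevalence
  ew <- if (igraph::ecount(x$graph)) 1 + 6 * igraph::E(x$graph)$weight else NULL
  igraph::plot.igraph(x$graph, vertex.size = sz, edge.width = ew,
                      vertex.label.cex = 0.6, ...)
  invisible(x)
}
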