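## End-to-end pipeline: clean -> prevalence -> networks -> metrics ->
## subgroup comparison, written out as one reproducible report bundle.

#' Build a pipeline configuration
#'
#' @param input Path to a long-format diagnosis CSV, or `NULL` when
#'   `simulation` is given.
#' @param simulation Optional [sim_config()] used instead of `input`.
#' @param min_codes,min_prevalence Cleaning parameters (see
#'   [filter_cohort()]).
#' @param rare_rule_per_subgroup Apply the rare-disease rule per declared
#'   subgroup instead of overall (default FALSE).
#' @param subgroups Stratification axes to analyze (default sex and disease
#'   type).
#' @param alpha Significance level for the network calibration and
#'   difference tests.
#' @param d_threshold,fold Enrichment thresholds (see
#'   [classify_enrichment()]).
#' @param abundance_threshold Cosine difference for abundant connections.
#' @param top_k PageRank top list size.
#' @param seed Seed recorded in the manifest (drives clustering restarts).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, simulation = NULL,
                            min_codes = 2, min_prevalence = 0.02,
                            rare_rule_per_subgroup = FALSE,
                            subgroups = c("sex", "disease_type"),
                            alpha = 0.05, d_threshold = 0.1, fold = 1.5,
                            abundance_threshold = 0.05, top_k = 5,
                            seed = 1) {
  if (is.null(input) && is.null(simulation)) {
    pcnet_error("pcnet_config_error", "either input or simulation is required")
  }
  stopifnot(is.null(subgroups) ||
              all(subgroups %in% c("sex", "disease_type", "td_subtype",
                                   "age_bin")))
  structure(list(input = input, simulation = simulation,
                 min_codes = min_codes, min_prevalence = min_prevalence,
                 rare_rule_per_subgroup = rare_rule_per_subgroup,
                 subgroups = subgroups, alpha = alpha,
                 d_threshold = d_threshold, fold = fold,
                 abundance_threshold = abundance_threshold,
                 top_k = top_k, seed = as.integer(seed)),
            class = "pipeline_config")
}

quantile_iqr <- function(x) {
  # linear-interpolation quantiles (type 7), the R default
  q <- quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
  sprintf("%.0f (%.0f-%.0f)", q[2], q[1], q[3])
}

cohort_characteristics <- function(cohorts) {
  rows <- lapply(names(cohorts), function(nm) {
    ch <- cohorts[[nm]]
    cc <- vapply(ch$codes, function(cs) sum(!is_td_code(cs)), 0L)
    data.frame(subgroup = nm, n = length(ch),
               age_median_iqr = quantile_iqr(ch$age),
               comorbidities_median_iqr = quantile_iqr(cc),
               mean_comorbidities = mean(cc),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full comorbidity-network pipeline
#'
#' Cleans the cohort, computes prevalence and subgroup difference tables,
#' age-profile trends and clusters, builds the overall and per-subgroup
#' comorbidity networks with their structural summaries and PageRank
#' rankings, classifies abundant connections between paired subgroup
#' networks, and (optionally) writes everything to `outdir` together with a
#' JSON manifest. The whole run is a pure function of (input bytes, config,
#' seed): rerunning writes byte-identical tables.
#'
#' Written files: `cohort_characteristics.csv`, `prevalence.csv`,
#' `difference_<axis>.csv`, `age_clusters.csv`, `network_summary.csv`,
#' `pagerank.csv`, `abundant_<axis>.csv`, per-network
#' `net_<label>_{nodes,edges}.csv` + `net_<label>.graphml`, and
#' `manifest.json`.
#'
#' @param cfg A [pipeline_config()].
#' @param outdir Output directory (`NULL` to skip writing).
#' @return Invisible list with all computed tables and `pcn` objects.
#' @export
run_pipeline <- function(cfg, outdir = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  stage <- "read"
  result <- tryCatch({
    raw <- if (!is.null(cfg$simulation)) simulate_cohort(cfg$simulation)
           else read_cohort(cfg$input)

    stage <- "filter"
    filtered <- filter_cohort(raw, min_codes = cfg$min_codes,
                              min_prevalence = cfg$min_prevalence,
                              subgroups = if (cfg$rare_rule_per_subgroup)
                                cfg$subgroups else NULL)
    universe <- comorbidity_universe(filtered)

    strata <- list()
    for (ax in cfg$subgroups) strata[[ax]] <- stratify(filtered, ax)
    cohorts <- c(list(all = filtered),
                 unlist(strata, recursive = FALSE, use.names = TRUE))

    stage <- "characteristics"
    chars <- cohort_characteristics(cohorts)
    # male vs female comorbidity-count contrast (Mann-Whitney U)
    mw_p <- NA_real_
    if ("sex" %in% names(strata)) {
      cc <- function(ch) vapply(ch$codes, function(cs) sum(!is_td_code(cs)), 0L)
      mw_p <- suppressWarnings(
        wilcox.test(cc(strata$sex$male), cc(strata$sex$female))$p.value)
    }

    stage <- "prevalence"
    prev <- cohort_prevalence(filtered, codes = universe)
    diffs <- list()
    for (ax in intersect(names(strata), c("sex", "disease_type"))) {
      pair <- strata[[ax]][1:2]
      diffs[[ax]] <- compare_prevalence(pair[[1]], pair[[2]],
                                        codes = universe,
                                        d_threshold = cfg$d_threshold,
                                        fold = cfg$fold, alpha = cfg$alpha)
    }

    stage <- "age_profiles"
    prof <- age_profiles(filtered, codes = universe)
    clus <- cluster_age_profiles(prof, seed = cfg$seed)
    age_tab <- data.frame(code = rownames(prof$profiles),
                          prof$profiles, check.names = FALSE,
                          rho = prof$trend$rho, p_value = prof$trend$p_value,
                          cluster = clus$cluster[rownames(prof$profiles)],
                          row.names = NULL, stringsAsFactors = FALSE)

    stage <- "networks"
    nets <- list(all = pcn(filtered, include_td = TRUE, alpha = cfg$alpha,
                           label = "all"))
    for (ax in names(strata)) {
      for (nm in names(strata[[ax]])) {
        lb <- paste(ax, nm, sep = ".")
        ch <- strata[[ax]][[nm]]
        if (length(ch) >= 3L &&
            length(unique(unlist(ch$codes))) >= 2L) {
          nets[[lb]] <- pcn(ch, include_td = TRUE, alpha = cfg$alpha,
                            label = lb)
        }
      }
    }

    stage <- "metrics"
    net_rows <- lapply(names(nets), function(nm) {
      s <- summarize_network(nets[[nm]])
      data.frame(network = nm, nodes = s$node_count, edges = s$edge_count,
                 density = s$density, mean_degree = s$mean_degree,
                 degree_median = s$degree_median,
                 degree_q1 = s$degree_iqr[1], degree_q3 = s$degree_iqr[2],
                 neighbor_degree_median = s$neighbor_degree_median,
                 neighbor_degree_q1 = s$neighbor_degree_iqr[1],
                 neighbor_degree_q3 = s$neighbor_degree_iqr[2],
                 cutoff = nets[[nm]]$cutoff, K = nets[[nm]]$K,
                 stringsAsFactors = FALSE)
    })
    net_summary <- do.call(rbind, net_rows)
    pr_rows <- lapply(names(nets), function(nm) {
      pr <- pagerank_importance(nets[[nm]], top_k = cfg$top_k)
      if (nrow(pr) == 0L) return(NULL)
      cbind(network = nm, pr[pr$top, , drop = FALSE])
    })
    pagerank_tab <- do.call(rbind, pr_rows)

    stage <- "compare"
    abundant <- list()
    for (ax in names(strata)) {
      nms <- paste(ax, names(strata[[ax]])[1:2], sep = ".")
      if (all(nms %in% names(nets))) {
        abundant[[ax]] <- abundant_connections(nets[[nms[1]]], nets[[nms[2]]],
                                               threshold = cfg$abundance_threshold)
      }
    }

    list(config = cfg, cohort = filtered, strata = strata,
         characteristics = chars, male_female_comorbidity_p = mw_p,
         prevalence = prev, differences = diffs,
         age_profiles = prof, age_clusters = clus, age_table = age_tab,
         networks = nets, network_summary = net_summary,
         pagerank = pagerank_tab, abundant = abundant)
  }, pcnet_error = function(e) {
    pcnet_error("pcnet_pipeline_error",
                sprintf("pipeline failed at stage '%s': %s", stage,
                        conditionMessage(e)))
  })

  if (!is.null(outdir)) write_report(result, outdir)
  invisible(result)
}

write_report <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(outdir, ...)
  write.csv(result$characteristics, fp("cohort_characteristics.csv"),
            row.names = FALSE)
  write.csv(result$prevalence, fp("prevalence.csv"), row.names = FALSE)
  for (ax in names(result$differences)) {
    write.csv(result$differences[[ax]], fp(sprintf("difference_%s.csv", ax)),
              row.names = FALSE)
  }
  write.csv(result$age_table, fp("age_clusters.csv"), row.names = FALSE)
  write.csv(result$network_summary, fp("network_summary.csv"),
            row.names = FALSE)
  if (!is.null(result$pagerank)) {
    write.csv(result$pagerank, fp("pagerank.csv"), row.names = FALSE)
  }
  for (ax in names(result$abundant)) {
    write.csv(result$abundant[[ax]], fp(sprintf("abundant_%s.csv", ax)),
              row.names = FALSE)
  }
  for (nm in names(result$networks)) {
    safe <- gsub("[^A-Za-z0-9._-]", "_", nm)
    write_network(result$networks[[nm]],
                  node_path = fp(sprintf("net_%s_nodes.csv", safe)),
                  edge_path = fp(sprintf("net_%s_edges.csv", safe)),
                  graphml_path = fp(sprintf("net_%s.graphml", safe)))
  }
  cfg <- result$config
  manifest <- list(
    package = "pcnet",
    version = as.character(utils::packageVersion("pcnet")),
    seed = cfg$seed,
    parameters = cfg[c("min_codes", "min_prevalence",
                       "rare_rule_per_subgroup", "alpha", "d_threshold",
                       "fold", "abundance_threshold", "top_k")],
    subgroups = cfg$subgroups,
    input = if (is.null(cfg$input)) "simulated" else cfg$input,
    filter_log = result$cohort$filter_log,
    networks = names(result$networks)
  )
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(outdir)
}
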