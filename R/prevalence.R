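## Prevalence estimation, subgroup difference/enrichment statistics, and
## age-profile trends and clustering.

#' Prevalence with a binomial confidence interval
#'
#' Default is the Wald interval p +/- z * sqrt(p(1-p)/N), clamped to
#' \[0, 1\]; a Wilson score interval is available behind `method`.
#'
#' @param n Affected count.
#' @param N Denominator count (> 0).
#' @param level Confidence level (default 0.95).
#' @param method `"wald"` (default) or `"wilson"`.
#' @return Data frame row: `n`, `N`, `prevalence`, `ci_low`, `ci_high`.
#' @examples
#' prevalence_with_ci(6435, 18311)   # 35.14% (34.5, 35.8)
#' @export
prevalence_with_ci <- function(n, N, level = 0.95,
                               method = c("wald", "wilson")) {
  method <- match.arg(method)
  if (any(N <= 0)) {
    pcnet_error("pcnet_undefined_prevalence", "denominator N must be > 0")
  }
  stopifnot(all(n >= 0), all(n <= N))
  p <- n / N
  z <- qnorm(1 - (1 - level) / 2)
  if (method == "wald") {
    se <- sqrt(p * (1 - p) / N)
    lo <- pmax(0, p - z * se)
    hi <- pmin(1, p + z * se)
  } else {
    den <- 1 + z^2 / N
    ctr <- (p + z^2 / (2 * N)) / den
    hw <- z * sqrt(p * (1 - p) / N + z^2 / (4 * N^2)) / den
    lo <- pmax(0, ctr - hw)
    hi <- pmin(1, ctr + hw)
  }
  data.frame(n = n, N = N, prevalence = p, ci_low = lo, ci_high = hi)
}

#' Prevalence table with confidence intervals for a cohort
#'
#' @param cohort An `emr_cohort`.
#' @param codes Code subset (default: comorbidity universe plus thyroid codes
#'   present).
#' @inheritParams prevalence_with_ci
#' @return Data frame: `code`, `n`, `N`, `prevalence`, `ci_low`, `ci_high`.
#' @export
cohort_prevalence <- function(cohort, codes = NULL, level = 0.95,
                              method = c("wald", "wilson")) {
  cp <- code_prevalence(cohort, codes)
  ci <- prevalence_with_ci(cp$n, cp$N, level = level, method = method)
  cbind(cp[, "code", drop = FALSE], ci)
}

#' Relative difference between two prevalences
#'
#' `d = (p_a - p_b) / ((p_a + p_b) / 2)`, a symmetric scale-free contrast
#' with range \[-2, 2\]; antisymmetric in its arguments.
#'
#' @param p_a,p_b Prevalences (fractions), not both zero.
#' @return Numeric vector of relative differences.
#' @export
relative_difference <- function(p_a, p_b) {
  if (any(p_a + p_b <= 0)) {
    pcnet_error("pcnet_undefined_difference",
                "both prevalences are zero; relative difference undefined")
  }
  2 * (p_a - p_b) / (p_a + p_b)
}

#' Pooled two-proportion z-test
#'
#' Two-sided test of p_a = p_b using the pooled standard error. Equivalent
#' to the chi-square test without continuity correction (z^2 = X^2).
#'
#' @param n_a,N_a Count and denominator in group a.
#' @param n_b,N_b Count and denominator in group b.
#' @return List with `z` and `p_value`; a `low_count` flag marks strata with
#'   fewer than 5 expected events.
#' @export
two_proportion_ztest <- function(n_a, N_a, n_b, N_b) {
  if (any(N_a <= 0) || any(N_b <= 0)) {
    pcnet_error("pcnet_undefined_prevalence", "denominators must be > 0")
  }
  p_pool <- (n_a + n_b) / (N_a + N_b)
  if (any(p_pool <= 0) || any(p_pool >= 1)) {
    pcnet_error("pcnet_degenerate_test",
                "pooled proportion is 0 or 1; z-test degenerate")
  }
  se <- sqrt(p_pool * (1 - p_pool) * (1 / N_a + 1 / N_b))
  z <- (n_a / N_a - n_b / N_b) / se
  low <- pmin(N_a, N_b) * pmin(p_pool, 1 - p_pool) < 5
  list(z = z, p_value = 2 * pnorm(-abs(z)), low_count = low)
}

#' Classify a subgroup prevalence difference
#'
#' A comorbidity is *different* between subgroups when the absolute relative
#' difference exceeds `d_threshold` and the z-test is significant at `alpha`;
#' among different comorbidities, those with a prevalence ratio of at least
#' `fold` are *enriched* in the higher-prevalence subgroup. With
#' `fold_as_relative_difference = TRUE` the enrichment bar is instead
#' `|d| >= fold - 1` on the relative-difference scale.
#'
#' @param p_a,p_b Prevalences in subgroups a and b.
#' @param d Relative difference (from [relative_difference()]).
#' @param p_value Two-proportion z-test p-value.
#' @param d_threshold Relative-difference threshold (default 0.1).
#' @param fold Enrichment fold threshold (default 1.5, i.e. a >= 0.5-fold
#'   increase).
#' @param alpha Significance level (default 0.05).
#' @param fold_as_relative_difference Alternative enrichment reading.
#' @return One of `"not_different"`, `"different"`, `"enriched_in_a"`,
#'   `"enriched_in_b"`.
#' @export
classify_enrichment <- function(p_a, p_b, d, p_value, d_threshold = 0.1,
                                fold = 1.5, alpha = 0.05,
                                fold_as_relative_difference = FALSE) {
  different <- abs(d) > d_threshold & p_value < alpha
  if (!different) return("not_different")
  if (fold_as_relative_difference) {
    enr_a <- d >= (fold - 1)
    enr_b <- -d >= (fold - 1)
  } else {
    # p_b = 0 with p_a > 0: infinite ratio counts as enriched in a
    enr_a <- p_a > p_b && (p_b == 0 || p_a / p_b >= fold)
    enr_b <- p_b > p_a && (p_a == 0 || p_b / p_a >= fold)
  }
  if (enr_a) "enriched_in_a" else if (enr_b) "enriched_in_b" else "different"
}

#' Compare comorbidity prevalences between two cohorts
#'
#' Produces a per-code difference table: prevalences, absolute and relative
#' differences, pooled z-test, and the enrichment classification of
#' [classify_enrichment()]. Codes with zero prevalence in both cohorts are
#' skipped. No multiple-testing correction is applied by default;
#' `p_adjust = "BH"` applies Benjamini-Hochberg to the z-test p-values
#' before classification.
#'
#' @param cohort_a,cohort_b `emr_cohort` objects (e.g. male/female strata).
#' @param codes Codes to compare (default: union of comorbidity universes).
#' @param p_adjust `"none"` (default) or a method for [stats::p.adjust()].
#' @inheritParams classify_enrichment
#' @return Data frame, one row per code.
#' @export
compare_prevalence <- function(cohort_a, cohort_b, codes = NULL,
                               d_threshold = 0.1, fold = 1.5, alpha = 0.05,
                               p_adjust = "none",
                               fold_as_relative_difference = FALSE) {
  if (is.null(codes)) {
    codes <- sort(union(comorbidity_universe(cohort_a),
                        comorbidity_universe(cohort_b)))
  }
  a <- code_prevalence(cohort_a, codes)
  b <- code_prevalence(cohort_b, codes)
  keep <- a$n + b$n > 0
  a <- a[keep, ]; b <- b[keep, ]
  zt <- two_proportion_ztest(a$n, a$N, b$n, b$N)
  p <- if (identical(p_adjust, "none")) zt$p_value else
    stats::p.adjust(zt$p_value, method = p_adjust)
  d <- relative_difference(a$prevalence, b$prevalence)
  cls <- vapply(seq_along(d), function(i) {
    classify_enrichment(a$prevalence[i], b$prevalence[i], d[i], p[i],
                        d_threshold = d_threshold, fold = fold, alpha = alpha,
                        fold_as_relative_difference = fold_as_relative_difference)
  }, "")
  data.frame(code = a$code,
             n_a = a$n, N_a = a$N, p_a = a$prevalence,
             n_b = b$n, N_b = b$N, p_b = b$prevalence,
             absolute_difference = a$prevalence - b$prevalence,
             relative_difference = d,
             z = zt$z, p_value = p, low_count = zt$low_count,
             classification = cls,
             stringsAsFactors = FALSE, row.names = NULL)
}

## age profiles ----------------------------------------------------------

#' Age-specific prevalence profiles and trends
#'
#' For every code, the prevalence in each age bin plus the Spearman rank
#' correlation between bin order and prevalence; also the mean comorbidity
#' count (non-thyroid codes per record) per bin and its Spearman trend.
#' Spearman uses the bin *ordinals* as the x variable, so results do not
#' depend on bin widths. Empty bins are dropped with a warning.
#'
#' @param cohort An `emr_cohort` (ages >= 18).
#' @param codes Codes to profile (default: comorbidity universe).
#' @return List of class `age_profiles`: `profiles` (code x bin prevalence
#'   matrix), `trend` (per-code rho and p), `mean_comorbidities` (per-bin
#'   means), `mean_trend` (rho, p), `bin_sizes`.
#' @export
age_profiles <- function(cohort, codes = NULL) {
  if (is.null(codes)) codes <- comorbidity_universe(cohort)
  bins <- age_bins(cohort$age)
  sizes <- table(bins)
  if (any(sizes == 0)) {
    warning(sprintf("empty age bin(s) dropped: %s",
                    paste(names(sizes)[sizes == 0], collapse = ", ")))
  }
  keep_bins <- names(sizes)[sizes > 0]
  M <- incidence_matrix(cohort, codes)
  comorb_count <- vapply(cohort$codes, function(cs) sum(!is_td_code(cs)), 0L)
  prof <- sapply(keep_bins, function(b) {
    idx <- !is.na(bins) & bins == b
    colMeans(M[idx, , drop = FALSE])
  })
  prof <- matrix(prof, nrow = length(codes),
                 dimnames = list(codes, keep_bins))
  ord <- seq_along(keep_bins)
  trend <- t(vapply(codes, function(cd) {
    spearman_trend(ord, prof[cd, ])
  }, c(rho = 0, p_value = 0)))
  mean_cc <- vapply(keep_bins, function(b) {
    mean(comorb_count[!is.na(bins) & bins == b])
  }, 0)
  structure(list(profiles = prof,
                 trend = data.frame(code = codes, rho = trend[, "rho"],
                                    p_value = trend[, "p_value"],
                                    row.names = NULL),
                 mean_comorbidities = mean_cc,
                 mean_trend = as.list(spearman_trend(ord, mean_cc)),
                 bin_sizes = sizes),
            class = "age_profiles")
}

spearman_trend <- function(x, y) {
  if (length(unique(y)) == 1L) {
    return(c(rho = 0, p_value = 1))  # constant profile: no trend
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  c(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' @export
print.age_profiles <- function(x, ...) {
  cat(sprintf("Age profiles: %d codes x %d bins (bin sizes: %s)\n",
              nrow(x$profiles), ncol(x$profiles),
              paste(x$bin_sizes, collapse = ", ")))
  cat(sprintf("Mean comorbidity count per bin: %s (Spearman rho %.3f, p %.3g)\n",
              paste(sprintf("%.2f", x$mean_comorbidities), collapse = ", "),
              x$mean_trend$rho, x$mean_trend$p_value))
  invisible(x)
}

#' Cluster age-specific prevalence profiles with K-means
#'
#' K-means on the raw (unscaled) per-bin prevalence vectors, so clusters
#' separate by prevalence magnitude as well as shape. When `k` is missing it
#' is chosen by the elbow of the total within-cluster sum of squares over
#' `k = 1..k_max`: the k with the largest second difference of the curve.
#'
#' @param profiles An `age_profiles` object or a numeric matrix (codes x
#'   bins).
#' @param k Number of clusters; `NULL` (default) picks by elbow.
#' @param k_max Largest k scanned for the elbow (default 10, capped at the
#'   number of profiles).
#' @param nstart Random restarts per k (default 50).
#' @param seed RNG seed for restarts (default 1).
#' @return List: `cluster` (named assignment vector), `k`, `wss` (inertia
#'   curve), `centers`.
#' @export
cluster_age_profiles <- function(profiles, k = NULL, k_max = 10, nstart = 50,
                                 seed = 1) {
  X <- if (inherits(profiles, "age_profiles")) profiles$profiles else profiles
  X <- as.matrix(X)
  if (nrow(X) < 2L) {
    pcnet_error("pcnet_config_error", "need at least 2 profiles to cluster")
  }
  if (!is.null(k) && k > nrow(X)) {
    pcnet_error("pcnet_config_error", "k exceeds the number of profiles")
  }
  k_max <- min(k_max, nrow(X) - 1L)
  set.seed(seed)
  wss <- vapply(seq_len(max(k_max, if (is.null(k)) 2 else k)), function(kk) {
    if (kk == 1) sum(scale(X, scale = FALSE)^2)
    else kmeans(X, centers = kk, nstart = nstart, iter.max = 100)$tot.withinss
  }, 0)
  if (is.null(k)) {
    if (k_max >= 3) {
      d2 <- wss[seq_len(k_max - 2)] - 2 * wss[seq(2, k_max - 1)] +
        wss[seq(3, k_max)]
      k <- which.max(d2) + 1L
    } else k <- k_max
  }
  set.seed(seed)
  fit <- if (k == 1) {
    list(cluster = rep(1L, nrow(X)), centers = colMeans(X))
  } else {
    kmeans(X, centers = k, nstart = nstart, iter.max = 100)
  }
  list(cluster = setNames(fit$cluster, rownames(X)), k = k,
       wss = wss, centers = fit$centers)
}
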