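test_that("Wald interval matches hand-computed bounds and clamps at zero", {
  est <- prevalence_with_ci(140, 700)
  p <- 0.2; se <- sqrt(p * 0.8 / 700)
  expect_equal(est$prevalence, p)
  expect_equal(est$ci_low, p - qnorm(0.975) * se, tolerance = 1e-12)
  expect_equal(est$ci_high, p + qnorm(0.975) * se, tolerance = 1e-12)
  zero <- prevalence_with_ci(0, 100)
  expect_equal(zero$prevalence, 0)
  expect_equal(zero$ci_low, 0)
  expect_gt(prevalence_with_ci(0, 100, method = "wilson")$ci_high, 0)
  expect_error(prevalence_with_ci(1, 0), class = "pcnet_undefined_prevalence")
})

test_that("Wald 95% interval has nominal coverage over simulated binomials", {
  set.seed(404)
  n <- rbinom(1000, 500, 0.2)
  est <- prevalence_with_ci(n, 500)
  covered <- mean(est$ci_low <= 0.2 & 0.2 <= est$ci_high)
  expect_gte(covered, 0.93)
  expect_lte(covered, 0.97)
})

test_that("relative difference follows its closed form and is antisymmetric", {
  expect_equal(relative_difference(0.1, 0.1), 0)
  expect_equal(relative_difference(0.20, 0.10), 2 / 3, tolerance = 1e-9)
  expect_equal(relative_difference(0.10, 0), 2)      # one-sided extreme
  expect_error(relative_difference(0, 0), class = "pcnet_undefined_difference")
  set.seed(1)
  pa <- runif(50); pb <- runif(50)
  expect_equal(relative_difference(pa, pb), -relative_difference(pb, pa))
  expect_true(all(abs(relative_difference(pa, pb)) <= 2))
})

test_that("pooled z-test matches its closed form and prop.test", {
  zt <- two_proportion_ztest(200, 1000, 100, 1000)
  expect_equal(zt$z, 6.26, tolerance = 1e-2)   # pooled-variance hand value
  # chi-square without continuity correction is z^2
  pt <- prop.test(c(200, 100), c(1000, 1000), correct = FALSE)
  expect_equal(zt$z^2, unname(pt$statistic), tolerance = 1e-10)
  expect_equal(zt$p_value, pt$p.value, tolerance = 1e-10)
  eq <- two_proportion_ztest(50, 500, 50, 500)
  expect_equal(eq$z, 0)
  expect_equal(eq$p_value, 1)
  expect_error(two_proportion_ztest(0, 10, 0, 10),
               class = "pcnet_degenerate_test")
  expect_true(two_proportion_ztest(1, 3, 2, 3)$low_count)
})

test_that("enrichment classification applies the d, p and fold rules", {
  # d ~ 0.857, ratio 2.5, z-test p << 0.05 -> enriched in a
  zt <- two_proportion_ztest(500, 5000, 200, 5000)
  d <- relative_difference(0.10, 0.04)
  expect_equal(classify_enrichment(0.10, 0.04, d, zt$p_value),
               "enriched_in_a")
  # |d| below the 0.1 bar despite huge n -> not different
  d2 <- relative_difference(0.105, 0.100)
  expect_lt(abs(d2), 0.1)
  expect_equal(classify_enrichment(0.105, 0.100, d2, 1e-6), "not_different")
  expect_equal(classify_enrichment(0.1, 0.1, 0, 1), "not_different")
  # different but under the 1.5x ratio
  d3 <- relative_difference(0.14, 0.10)
  expect_equal(classify_enrichment(0.14, 0.10, d3, 1e-6), "different")
  # zero denominator counts as infinite ratio
  expect_equal(classify_enrichment(0.1, 0, 2, 1e-6), "enriched_in_a")
  # alternative reading: |d| >= 0.5 on the relative-difference scale
  expect_equal(classify_enrichment(0.14, 0.10, d3, 1e-6,
                                   fold_as_relative_difference = TRUE),
               "different")
  expect_equal(classify_enrichment(0.2, 0.1, relative_difference(0.2, 0.1),
                                   1e-6, fold_as_relative_difference = TRUE),
               "enriched_in_a")
})

test_that("enrichment is monotone in the first prevalence", {
  labels <- vapply(seq(0.04, 0.20, by = 0.02), function(pa) {
    zt <- two_proportion_ztest(round(pa * 5000), 5000, 200, 5000)
    classify_enrichment(pa, 0.04, relative_difference(pa, 0.04), zt$p_value)
  }, "")
  rank <- c(not_different = 0, different = 1, enriched_in_a = 2)
  expect_true(all(diff(rank[labels]) >= 0))
})

test_that("subgroup comparison table flags planted sex enrichment", {
  ds <- data.frame(code = c("N40", "D25", "I10"),
                   base_prevalence = c(0.08, 0.06, 0.30),
                   sex_log_odds_shift = c(2.5, -2.5, 0))
  cfg <- sim_config(n_records = 20000, seed = 17, diseases = ds)
  ch <- simulate_cohort(cfg)
  sx <- stratify(ch, "sex")
  cmp <- compare_prevalence(sx$male, sx$female, codes = ds$code)
  expect_equal(cmp$classification[cmp$code == "N40"], "enriched_in_a")
  expect_equal(cmp$classification[cmp$code == "D25"], "enriched_in_b")
  expect_equal(cmp$classification[cmp$code == "I10"], "not_different")
})

test_that("age profiles recover monotone trends", {
  # deterministic strictly increasing prevalence over the 5 bins
  ages <- rep(c(25L, 45L, 55L, 65L, 80L), each = 40)
  sets <- lapply(seq_along(ages), function(i) {
    bin <- (i - 1) %/% 40 + 1
    c("E04", if ((i - 1) %% 40 < bin * 5) "I10", "K29")
  })
  ch <- make_cohort(sets, age = ages)
  ap <- age_profiles(ch, codes = c("I10", "K29"))
  expect_equal(dim(ap$profiles), c(2L, 5L))
  expect_equal(unname(ap$trend$rho[ap$trend$code == "I10"]), 1)
  # constant prevalence -> no trend under the tie convention
  expect_equal(unname(ap$trend$rho[ap$trend$code == "K29"]), 0)
})

test_that("generator age slopes surface as positive Spearman trends", {
  ds <- data.frame(code = c("I70", "G47"), base_prevalence = c(0.15, 0.10),
                   age_slope_per_decade = c(0.8, 0))
  cfg <- sim_config(n_records = 20000, seed = 23, diseases = ds)
  ch <- simulate_cohort(cfg)
  ap <- age_profiles(ch, codes = ds$code)
  expect_gt(ap$trend$rho[ap$trend$code == "I70"], 0.8)
  expect_lt(ap$trend$p_value[ap$trend$code == "I70"], 0.05)
  # mean comorbidity count per bin also rises with the slope present
  expect_gt(ap$mean_trend$rho, 0)
})

test_that("k-means separates planted prevalence levels and picks k by elbow", {
  set.seed(99)
  low <- matrix(0.02 + rnorm(40 * 5, sd = 0.002), 40, 5,
                dimnames = list(sprintf("L%02d", 1:40), NULL))
  high <- matrix(0.40 + rnorm(8 * 5, sd = 0.002), 8, 5,
                 dimnames = list(sprintf("H%02d", 1:8), NULL))
  X <- rbind(low, high)
  cl <- cluster_age_profiles(X, k = 2, seed = 7)
  expect_length(unique(cl$cluster[1:40]), 1L)
  expect_length(unique(cl$cluster[41:48]), 1L)
  expect_false(cl$cluster[1] == cl$cluster[41])
  # elbow selection lands on the planted k
  cl2 <- cluster_age_profiles(X, seed = 7)
  expect_equal(cl2$k, 2L)
  # k = 1 puts everything together; duplicates co-cluster
  expect_length(unique(cluster_age_profiles(X, k = 1, seed = 7)$cluster), 1L)
  dup <- rbind(low, low[1:5, ])
  cl3 <- cluster_age_profiles(dup, k = 2, seed = 7)
  expect_equal(unname(cl3$cluster[1:5]), unname(cl3$cluster[41:45]))
  expect_error(cluster_age_profiles(X, k = 100), class = "pcnet_config_error")
})

test_that("k-means assignments are invariant to profile order at fixed seed", {
  set.seed(31)
  X <- rbind(matrix(0.10, 10, 5), matrix(0.50, 10, 5), matrix(0.90, 10, 5)) +
    matrix(rnorm(30 * 5, sd = 0.03), 30, 5)
  rownames(X) <- sprintf("P%02d", 1:30)
  cl1 <- cluster_age_profiles(X, k = 3, seed = 5)$cluster
  perm <- sample(30)
  cl2 <- cluster_age_profiles(X[perm, ], k = 3, seed = 5)$cluster
  # same partition up to label renaming
  tab <- table(cl1[rownames(X)[perm]], cl2)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})
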