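test_that("pair counts enumerate exact contingency tables", {
  ch <- make_cohort(list(c("A10", "B20", "E04"), c("A10", "E04"),
                         c("B20", "E04")), age = c(50L, 50L, 50L))
  ps <- pair_statistics(ch, universe = c("A10", "B20"))
  expect_equal(ps$n_a, 2L)
  expect_equal(ps$n_b, 2L)
  expect_equal(ps$n_ab, 1L)
  expect_equal(ps$N, 3L)
  # disjoint diseases -> n_ab = 0 and cosine 0
  ch2 <- make_cohort(list(c("A10", "E04"), c("B20", "E04")))
  ps2 <- pair_statistics(ch2, universe = c("A10", "B20"))
  expect_equal(ps2$n_ab, 0L)
  expect_equal(ps2$cosine, 0)
})

test_that("cosine and phi follow their closed forms", {
  expect_equal(cosine_index(0, 10, 20), 0)
  expect_equal(cosine_index(7, 7, 7), 1)          # identical incidence
  expect_equal(cosine_index(35, 100, 50), 0.4950, tolerance = 1e-4)
  expect_error(cosine_index(0, 0, 5), class = "pcnet_undefined_pair")
  expect_equal(phi_coefficient(100, 30, 40, 20), 0.3564, tolerance = 2e-4)
  # independence expectation n_ab = n_a n_b / N -> phi 0
  expect_equal(phi_coefficient(100, 20, 50, 10), 0)
  # perfect co-occurrence with equal marginals -> phi 1
  expect_equal(phi_coefficient(100, 30, 30, 30), 1)
  expect_error(phi_coefficient(100, 0, 40, 0),
               class = "pcnet_undefined_correlation")
  expect_error(phi_coefficient(100, 100, 40, 40),
               class = "pcnet_undefined_correlation")
})

test_that("cosine and phi agree with brute-force vector oracles", {
  set.seed(111)
  for (rep in 1:1000) {
    n <- sample(6:16, 1)
    a <- rbinom(n, 1, 0.5); b <- rbinom(n, 1, 0.5)
    if (sum(a) %in% c(0, n) || sum(b) %in% c(0, n)) next
    n_a <- sum(a); n_b <- sum(b); n_ab <- sum(a & b)
    expect_equal(cosine_index(n_ab, n_a, n_b), oracle_cosine(a, b),
                 tolerance = 1e-12)
    expect_equal(phi_coefficient(n, n_a, n_b, n_ab), oracle_phi(a, b),
                 tolerance = 1e-12)
  }
})

test_that("pair counts match a brute-force double loop on random cohorts", {
  set.seed(222)
  codes <- c("A10", "B20", "C40", "D64", "I10")
  for (rep in 1:25) {
    sets <- random_code_sets(20, codes, p = 0.45)
    sets <- lapply(sets, function(cs) c(cs, "E04"))  # TD indication
    ch <- make_cohort(sets)
    ps <- pair_statistics(ch, universe = codes)
    for (i in seq_len(nrow(ps))) {
      o <- oracle_pair_counts(ch$codes, ps$code_a[i], ps$code_b[i])
      expect_equal(unname(c(ps$n_a[i], ps$n_b[i], ps$n_ab[i])), unname(o))
    }
  }
})

test_that("correlation t-test matches the closed form and cor.test", {
  t0 <- correlation_t_test(0, 100)
  expect_equal(t0$t, 0)
  expect_equal(t0$p_value, 1)
  tt <- correlation_t_test(0.3564, 100)
  expect_equal(tt$t, 3.776, tolerance = 1e-3)
  # oracle: cor.test on raw vectors gives the same t and p
  set.seed(9)
  a <- rbinom(60, 1, 0.5); b <- ifelse(runif(60) < 0.3, a, rbinom(60, 1, 0.5))
  r <- cor(a, b)
  ct <- cor.test(a, b)
  ours <- correlation_t_test(r, 60)
  expect_equal(ours$t, unname(ct$statistic), tolerance = 1e-10)
  expect_equal(ours$p_value, ct$p.value, tolerance = 1e-10)
  # |t| grows with N at fixed r
  ts <- vapply(c(10, 50, 200, 1000),
               function(N) correlation_t_test(0.2, N)$t, 0)
  expect_true(all(diff(ts) > 0))
  inf <- correlation_t_test(1, 50)
  expect_true(inf$infinite)
  expect_equal(inf$p_value, 0)
})

test_that("cutoff calibration picks the K-th largest cosine, ties included", {
  pairs <- data.frame(cosine = c(0.9, 0.5, 0.3, 0.1),
                      phi = c(0.5, 0.4, -0.2, 0.1),
                      p_value = c(0.001, 0.01, 0.001, 0.5))
  cal <- calibrate_cutoff(pairs)
  expect_equal(cal$K, 2L)            # two positive significant phis
  expect_equal(cal$cutoff, 0.5)
  expect_equal(cal$n_edges, 2L)
  # K = 0 -> empty network sentinel
  none <- calibrate_cutoff(data.frame(cosine = 0.4, phi = 0.2, p_value = 0.9))
  expect_equal(none$K, 0L)
  expect_equal(none$cutoff, Inf)
  # ties at the cutoff are all included and flagged
  tied <- calibrate_cutoff(data.frame(cosine = c(0.6, 0.5, 0.5, 0.2),
                                      phi = c(0.5, 0.5, 0.2, 0.1),
                                      p_value = c(0.001, 0.001, 0.2, 0.9)))
  expect_equal(tied$K, 2L)
  expect_equal(tied$n_edges, 3L)
  expect_true(tied$tie_broadened)
  # all pairs significant -> cutoff is the smallest cosine
  all_sig <- calibrate_cutoff(data.frame(cosine = c(0.7, 0.4, 0.2),
                                         phi = c(0.6, 0.5, 0.3),
                                         p_value = c(1e-4, 1e-3, 1e-2)))
  expect_equal(all_sig$cutoff, 0.2)
})

test_that("planted strong pairs surface as network edges", {
  ds <- data.frame(code = sprintf("%s%02d", rep(c("I", "K", "N", "J"), 5),
                                  10 + 1:20),
                   base_prevalence = rep(c(0.25, 0.20, 0.15, 0.10, 0.05), 4))
  planted <- data.frame(code_a = ds$code[c(1, 3, 6)],
                        code_b = ds$code[c(2, 4, 7)],
                        target_cosine = c(0.55, 0.50, 0.45))
  cfg <- sim_config(n_records = 20000, seed = 13, diseases = ds,
                    planted_pairs = planted)
  net <- pcn(filter_cohort(simulate_cohort(cfg)), include_td = FALSE)
  ekey <- paste(net$edges$code_a, net$edges$code_b)
  pkey <- paste(pmin(planted$code_a, planted$code_b),
                pmax(planted$code_a, planted$code_b))
  expect_true(all(pkey %in% ekey))
  # the planted edges dominate the weight ranking
  top3 <- net$edges[order(-net$edges$cosine), ][1:3, ]
  expect_setequal(paste(top3$code_a, top3$code_b), pkey)
})

test_that("edge set obeys the calibration count and cutoff bound", {
  cfg <- paper_like_config(n_records = 8000, seed = 29)
  net <- pcn(filter_cohort(simulate_cohort(cfg)))
  expect_gte(nrow(net$edges), net$K)
  expect_true(all(net$edges$cosine >= net$cutoff))
  excluded <- net$pairs[!(paste(net$pairs$code_a, net$pairs$code_b) %in%
                            paste(net$edges$code_a, net$edges$code_b)), ]
  expect_true(all(excluded$cosine < net$cutoff))
  if (!net$tie_broadened) expect_equal(nrow(net$edges), net$K)
  # no self loops, each pair once, ordered codes
  expect_true(all(net$edges$code_a < net$edges$code_b))
  expect_false(any(duplicated(paste(net$edges$code_a, net$edges$code_b))))
})

test_that("network construction is permutation invariant and deterministic", {
  cfg <- sim_config(n_records = 2000, seed = 19,
                    diseases = data.frame(code = c("I10", "E11", "K29", "D64"),
                                          base_prevalence = c(0.3, 0.2, 0.15, 0.1)),
                    planted_pairs = data.frame(code_a = "I10", code_b = "E11",
                                               target_cosine = 0.4))
  ch <- filter_cohort(simulate_cohort(cfg))
  n1 <- pcn(ch)
  n2 <- pcn(ch)
  expect_identical(n1$edges, n2$edges)
  set.seed(77)
  n3 <- pcn(subset_cohort(ch, sample(length(ch))))
  expect_equal(n1$edges[order(n1$edges$code_a, n1$edges$code_b), ],
               n3$edges[order(n3$edges$code_a, n3$edges$code_b), ])
  expect_equal(n1$cutoff, n3$cutoff)
})

test_that("independence-only cohorts yield ~alpha/2 significant pairs", {
  ds <- data.frame(code = sprintf("X%02d", 10:39),
                   base_prevalence = rep(0.12, 30))
  frac <- vapply(1:3, function(r) {
    cfg <- sim_config(n_records = 5000, seed = 100 + r, diseases = ds)
    ps <- pair_statistics(simulate_cohort(cfg), universe = ds$code)
    mean(ps$significant)
  }, 0)
  n_pairs <- choose(30, 2) * 3
  se <- sqrt(0.025 * 0.975 / n_pairs)
  expect_lt(abs(mean(frac) - 0.025), 3 * se + 0.005)
})

test_that("degenerate subgroups warn instead of failing", {
  ch <- make_cohort(list(c("E04", "I10", "K29"), c("E04", "I10", "K29")))
  expect_warning(net <- pcn(ch), "fewer than 3")
  expect_s3_class(net, "pcn")
})
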