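## Synthetic EMR cohort generator with known ground truth: configured
## marginal prevalences, sex- and age-dependent shifts, and planted pairwise
## co-occurrence with target cosine indices.

#' Build a simulation configuration
#'
#' Defines a synthetic inpatient cohort: every record is an adult encounter
#' carrying exactly one thyroid-disease indication code (drawn from
#' `td_mix`) plus comorbidity codes. Comorbidity `i` enters a record with
#' probability `plogis(qlogis(base_prevalence) + sex_log_odds_shift * male +
#' age_slope_per_decade * (age - 18)/10)`. Pairwise co-occurrence is planted
#' through a shared latent Bernoulli component per pair whose rate is solved
#' so the population cosine index equals `target_cosine` in expectation
#' while marginal prevalences are preserved.
#'
#' @param n_records Number of encounters.
#' @param seed Integer RNG seed; the cohort is a deterministic function of
#'   the configuration including the seed.
#' @param diseases Data frame with columns `code`, `base_prevalence`
#'   (in (0,1)) and optional `sex_log_odds_shift`, `age_slope_per_decade`
#'   (default 0). Thyroid codes (`E00`--`E07`, `C73`) are not allowed here;
#'   they come from `td_mix`.
#' @param planted_pairs Optional data frame `code_a`, `code_b`,
#'   `target_cosine` (in \[0, 1)). Both codes must appear in `diseases`; a
#'   pair may be planted once, a disease may take part in several pairs.
#'   Targets at or below the independence cosine `sqrt(p_a p_b)` are treated
#'   as independence; targets above the marginal-feasibility bound
#'   `sqrt(min(p)/max(p))` raise an infeasible-co-occurrence error.
#' @param td_mix Named probability vector over thyroid codes; default
#'   mirrors a goiter-dominant hospital case mix.
#' @param age_mean,age_sd Normal age distribution, truncated to
#'   `[age_min, age_max]` (defaults 58/14, bounds 18/95).
#' @param age_min,age_max Age bounds.
#' @param sex_ratio Fraction of female records (default 0.6).
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_records, seed = 1, diseases,
                       planted_pairs = NULL,
                       td_mix = c(E04 = 0.62, E03 = 0.17, E05 = 0.10,
                                  C73 = 0.065, E06 = 0.03, E02 = 0.015),
                       age_mean = 58, age_sd = 14,
                       age_min = 18, age_max = 95,
                       sex_ratio = 0.6) {
  stopifnot(n_records >= 1, sex_ratio > 0, sex_ratio < 1,
            age_min >= 18, age_max > age_min)
  diseases <- as.data.frame(diseases)
  stopifnot(all(c("code", "base_prevalence") %in% names(diseases)))
  if (is.null(diseases$sex_log_odds_shift)) diseases$sex_log_odds_shift <- 0
  if (is.null(diseases$age_slope_per_decade)) diseases$age_slope_per_decade <- 0
  diseases$sex_log_odds_shift[is.na(diseases$sex_log_odds_shift)] <- 0
  diseases$age_slope_per_decade[is.na(diseases$age_slope_per_decade)] <- 0
  if (any(duplicated(diseases$code))) {
    pcnet_error("pcnet_config_error", "duplicated disease codes in config")
  }
  if (any(is_td_code(diseases$code))) {
    pcnet_error("pcnet_config_error",
                "thyroid codes belong in td_mix, not in diseases")
  }
  stopifnot(all(diseases$base_prevalence > 0),
            all(diseases$base_prevalence < 1))
  if (!all(is_td_code(names(td_mix))) || abs(sum(td_mix) - 1) > 1e-8) {
    pcnet_error("pcnet_config_error",
                "td_mix must be a probability vector over E00-E07/C73 codes")
  }
  cfg <- structure(list(n_records = as.integer(n_records),
                        seed = as.integer(seed),
                        diseases = diseases, planted_pairs = NULL,
                        td_mix = td_mix, age_mean = age_mean, age_sd = age_sd,
                        age_min = age_min, age_max = age_max,
                        sex_ratio = sex_ratio),
                   class = "sim_config")
  if (!is.null(planted_pairs) && nrow(as.data.frame(planted_pairs)) > 0) {
    pp <- as.data.frame(planted_pairs)
    stopifnot(all(c("code_a", "code_b", "target_cosine") %in% names(pp)))
    miss <- setdiff(c(pp$code_a, pp$code_b), diseases$code)
    if (length(miss)) {
      pcnet_error("pcnet_config_error",
                  sprintf("planted-pair codes not in diseases: %s",
                          paste(miss, collapse = ", ")))
    }
    key <- paste(pmin(pp$code_a, pp$code_b), pmax(pp$code_a, pp$code_b))
    if (any(duplicated(key))) {
      pcnet_error("pcnet_config_error", "a pair may be planted only once")
    }
    stopifnot(all(pp$target_cosine >= 0), all(pp$target_cosine < 1))
    cfg$planted_pairs <- pp
    cfg$latent_rates <- solve_latent_rates(cfg)  # validates feasibility
  }
  cfg
}

## Closed form used to invert the target cosine:
## with a shared latent component L ~ Bern(s) OR-ed into both diseases and
## marginals held at (p_a, p_b),  P(ab) = p_a + p_b - 1 + (1-p_a)(1-p_b)/(1-s),
## exact also when a disease carries latents from several planted pairs.
planted_joint_prob <- function(s, p_a, p_b) {
  p_a + p_b - 1 + (1 - p_a) * (1 - p_b) / (1 - s)
}

solve_latent_rates <- function(cfg) {
  pp <- cfg$planted_pairs
  p <- setNames(cfg$diseases$base_prevalence, cfg$diseases$code)
  s <- numeric(nrow(pp))
  for (i in seq_len(nrow(pp))) {
    pa <- p[[pp$code_a[i]]]; pb <- p[[pp$code_b[i]]]
    target <- pp$target_cosine[i]
    c_indep <- sqrt(pa * pb)
    c_max <- sqrt(min(pa, pb) / max(pa, pb))
    if (target > c_max + 1e-12) {
      pcnet_error("pcnet_infeasible_cosine",
                  sprintf("target cosine %.3f for pair %s-%s exceeds the bound %.3f implied by marginals %.3f/%.3f",
                          target, pp$code_a[i], pp$code_b[i], c_max, pa, pb))
    }
    if (target <= c_indep) { s[i] <- 0; next }
    f <- function(ss) planted_joint_prob(ss, pa, pb) / sqrt(pa * pb) - target
    s_hi <- min(pa, pb) - 1e-12
    s[i] <- stats::uniroot(f, c(0, s_hi), tol = 1e-12)$root
  }
  # base rates must stay nonnegative once all latents are accounted for
  for (cd in unique(c(pp$code_a, pp$code_b))) {
    in_pair <- pp$code_a == cd | pp$code_b == cd
    keep_prob <- prod(1 - s[in_pair])
    if (1 - p[[cd]] > keep_prob + 1e-12) {
      pcnet_error("pcnet_infeasible_cosine",
                  sprintf("disease %s cannot satisfy all planted cosines jointly: combined latent mass exceeds its prevalence %.3f",
                          cd, p[[cd]]))
    }
  }
  s
}

#' Simulate a synthetic EMR cohort
#'
#' Draws `n_records` adult encounters per the configuration: truncated-normal
#' ages, Bernoulli sex, exactly one thyroid code from `td_mix`, and
#' comorbidity codes from the logistic marginal model with planted latent
#' co-occurrence (see [sim_config()]). Byte-identical across runs for a
#' fixed configuration.
#'
#' @param cfg A `sim_config`.
#' @return An `emr_cohort`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_records
  sex <- ifelse(runif(n) < cfg$sex_ratio, "female", "male")
  # inverse-CDF truncated normal, then rounded to whole years
  lo <- pnorm(cfg$age_min, cfg$age_mean, cfg$age_sd)
  hi <- pnorm(cfg$age_max, cfg$age_mean, cfg$age_sd)
  age <- as.integer(round(qnorm(runif(n, lo, hi), cfg$age_mean, cfg$age_sd)))
  age <- pmin(pmax(age, cfg$age_min), cfg$age_max)
  td <- sample(names(cfg$td_mix), n, replace = TRUE, prob = cfg$td_mix)

  ds <- cfg$diseases
  D <- nrow(ds)
  male <- as.numeric(sex == "male")
  dec <- (age - 18) / 10
  # per-record inclusion probability per disease (logistic marginal model)
  eta <- outer(rep(1, n), qlogis(ds$base_prevalence)) +
    outer(male, ds$sex_log_odds_shift) +
    outer(dec, ds$age_slope_per_decade)
  prob <- plogis(eta)

  pp <- cfg$planted_pairs
  if (!is.null(pp)) {
    s <- cfg$latent_rates
    # deflate base rates so marginals survive the OR with the latents
    keep <- rep(1, D)
    for (j in seq_len(D)) {
      in_pair <- pp$code_a == ds$code[j] | pp$code_b == ds$code[j]
      if (any(in_pair)) keep[j] <- prod(1 - s[in_pair])
    }
    qprob <- 1 - sweep(1 - prob, 2, keep, "/")
    qprob <- pmin(pmax(qprob, 0), 1)
    X <- matrix(runif(n * D), n, D) < qprob
    for (i in seq_len(nrow(pp))) {
      if (s[i] <= 0) next
      L <- runif(n) < s[i]
      ja <- match(pp$code_a[i], ds$code)
      jb <- match(pp$code_b[i], ds$code)
      X[, ja] <- X[, ja] | L
      X[, jb] <- X[, jb] | L
    }
  } else {
    X <- matrix(runif(n * D), n, D) < prob
  }
  colnames(X) <- ds$code

  codes <- lapply(seq_len(n), function(i) c(td[i], ds$code[X[i, ]]))
  cohort <- new_cohort(sprintf("S%07d", seq_len(n)), age, sex, codes)
  log_filter(cohort, sprintf("simulated (seed %d)", cfg$seed), n, n)
}

#' A bundled realistic configuration
#'
#' Mimics the headline structure of a goiter-dominant thyroid-disease
#' inpatient cohort: ~55 comorbidities with marginal prevalences spanning
#' 2%--35% (hypertension ~35%, liver disease ~22%, diabetes ~17%,
#' lipoprotein disorders ~15%), male- and female-enriched diseases,
#' age-increasing cardiometabolic prevalences, and a handful of strong
#' planted cardiometabolic co-occurrences.
#'
#' @param n_records Cohort size (default 20000).
#' @param seed RNG seed.
#' @return A `sim_config`.
#' @export
paper_like_config <- function(n_records = 20000, seed = 1) {
  d <- function(code, p, sex = 0, age = 0) {
    data.frame(code = code, base_prevalence = p, sex_log_odds_shift = sex,
               age_slope_per_decade = age, stringsAsFactors = FALSE)
  }
  diseases <- rbind(
    d("I10", 0.35, 0.15, 0.55), d("K76", 0.22, 0.10, 0.25),
    d("E11", 0.17, 0.45, 0.45), d("I70", 0.16, 0.10, 0.75),
    d("E78", 0.15, 0.00, 0.30), d("I25", 0.15, 0.55, 0.55),
    d("K29", 0.135, 0.05, 0.20), d("N28", 0.12, 0.50, 0.15),
    d("J15", 0.115, 0.30, 0.35), d("I11", 0.093, 0.45, 0.45),
    d("I63", 0.093, 0.45, 0.50), d("C77", 0.092, 0.40, -0.10),
    d("J18", 0.092, 0.20, 0.30), d("K80", 0.092, 0.10, 0.25),
    d("D64", 0.085, 0.05, 0.20), d("C34", 0.078, 0.45, 0.15),
    d("N40", 0.075, 4.00, 0.60), d("I50", 0.074, 0.60, 0.45),
    d("M81", 0.071, -0.65, 0.60), d("E87", 0.069, 0.10, 0.15),
    d("C78", 0.064, 0.20, 0.00), d("N18", 0.055, 0.70, 0.25),
    d("E79", 0.054, 0.60, 0.10), d("N20", 0.054, 0.50, 0.10),
    d("I49", 0.053, 0.05, 0.25), d("C79", 0.053, 0.45, 0.00),
    d("E55", 0.048, 0.05, 0.20), d("M48", 0.048, -0.40, 0.35),
    d("E77", 0.044, 0.05, 0.10), d("I20", 0.042, 0.70, 0.40),
    d("I67", 0.042, 0.10, 0.45), d("J43", 0.041, 0.95, 0.40),
    d("J94", 0.041, 0.15, 0.10), d("N08", 0.041, 0.10, 0.10),
    d("M51", 0.040, 0.00, 0.20), d("I79", 0.036, 0.10, 0.25),
    d("B66", 0.034, 0.90, 0.10), d("E27", 0.033, 0.55, 0.05),
    d("K82", 0.033, 0.05, 0.15), d("G63", 0.033, 0.05, 0.15),
    d("D25", 0.033, -4.00, -0.30), d("I48", 0.031, 0.45, 0.40),
    d("D18", 0.031, 0.00, 0.00), d("N04", 0.030, 0.70, 0.00),
    d("I65", 0.030, 0.10, 0.40), d("J32", 0.030, 0.45, -0.05),
    d("K31", 0.029, 0.05, 0.10), d("I69", 0.029, 0.60, 0.40),
    d("A49", 0.027, 0.05, 0.15), d("G47", 0.026, 0.05, 0.05),
    d("K63", 0.026, 0.05, 0.10), d("C50", 0.024, -3.50, -0.10),
    d("M10", 0.024, 1.10, 0.15), d("M50", 0.024, -0.40, 0.10),
    d("G31", 0.023, 0.30, 0.45), d("K74", 0.023, 0.45, 0.15)
  )
  planted <- data.frame(
    code_a = c("I10", "I10", "I10", "E11", "I25", "J15", "I63", "N18"),
    code_b = c("I25", "E11", "I70", "E78", "I50", "J18", "I69", "N28"),
    target_cosine = c(0.42, 0.36, 0.40, 0.30, 0.32, 0.26, 0.24, 0.30),
    stringsAsFactors = FALSE
  )
  sim_config(n_records = n_records, seed = seed, diseases = diseases,
             planted_pairs = planted)
}
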