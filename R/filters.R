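## Cohort cleaning and subgroup stratification.
##
## The cleaning pipeline mirrors the standard EMR study design for
## thyroid-disease comorbidity work: keep adult encounters with a thyroid
## indication, drop obstetric/perinatal/symptom/external-cause chapters,
## require a minimum diagnosis count, and remove rare diseases.

## ICD-10 chapters XV-XXII start with these letters (O: pregnancy/childbirth,
## P: perinatal, Q: congenital, R: symptoms/signs, S/T: injury, U: special,
## V-Y: external causes, Z: factors influencing health status)
excluded_chapter_letters <- c("O", "P", "Q", "R", "S", "T", "U",
                              "V", "W", "X", "Y", "Z")

#' Disease prevalence table of a cohort
#'
#' @param cohort An `emr_cohort`.
#' @param codes Optional code subset; default all codes present.
#' @return Data frame with `code`, `n`, `N`, `prevalence`, sorted by code.
#' @export
code_prevalence <- function(cohort, codes = NULL) {
  N <- length(cohort)
  tab <- table(unlist(cohort$codes))
  if (is.null(codes)) codes <- sort(names(tab))
  n <- as.integer(tab[codes])
  n[is.na(n)] <- 0L
  data.frame(code = codes, n = n, N = N, prevalence = n / N,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Apply the cohort cleaning pipeline
#'
#' Steps, in order, each logged with before/after record counts:
#' \enumerate{
#'   \item keep records with age >= 18 **and** at least one thyroid-disease
#'     code (`E00`--`E07` or `C73`);
#'   \item drop diagnosis codes whose leading letter is in `O`--`Z`
#'     (ICD-10 chapters XV--XXII: pregnancy, perinatal, congenital,
#'     symptoms, injury, external causes, health-status factors);
#'   \item drop records left with fewer than `min_codes` codes;
#'   \item drop diseases whose prevalence in the cleaned cohort (and, when
#'     `subgroups` are declared, in every declared subgroup) is below
#'     `min_prevalence`.
#' }
#'
#' @param raw An `emr_cohort`.
#' @param min_codes Minimum diagnosis codes per record after the chapter
#'   exclusion (default 2).
#' @param min_prevalence Rare-disease threshold as a fraction (default 0.02).
#' @param subgroups Optional character vector of stratification axes (any of
#'   `"sex"`, `"disease_type"`, `"td_subtype"`, `"age_bin"`); when given, a
#'   disease must reach `min_prevalence` in at least one declared subgroup to
#'   be kept (it is dropped when rare in *all* of them), matching the
#'   per-subgroup reading of the rare-disease rule. Default `NULL` applies
#'   the rule to the overall cohort only.
#' @return Cleaned `emr_cohort` with updated `filter_log`.
#' @export
filter_cohort <- function(raw, min_codes = 2, min_prevalence = 0.02,
                          subgroups = NULL) {
  if (length(raw) == 0L) {
    pcnet_error("pcnet_empty_cohort", "input cohort is empty")
  }
  x <- raw

  ## (a) adults with a thyroid indication
  keep <- !is.na(x$age) & x$age >= 18 &
    vapply(x$codes, function(cs) any(is_td_code(cs)), TRUE)
  y <- subset_cohort(x, keep)
  y <- log_filter(y, "adult_with_td_code", length(x), length(y))
  check_nonempty(y, "adult_with_td_code")

  ## (b) chapter XV-XXII code exclusion
  before <- length(y)
  y$codes <- lapply(y$codes, function(cs) {
    cs[!substr(cs, 1L, 1L) %in% excluded_chapter_letters]
  })
  y <- log_filter(y, "drop_chapters_XV_XXII", before, length(y))

  ## (c) minimum code count
  keep <- lengths(y$codes) >= min_codes
  z <- subset_cohort(y, keep)
  z$filter_log <- y$filter_log
  z <- log_filter(z, sprintf("min_%d_codes", min_codes), length(y), length(z))
  check_nonempty(z, "min_codes")

  ## (d) rare-disease removal
  prev <- code_prevalence(z)
  rare_overall <- prev$code[prev$prevalence < min_prevalence]
  if (is.null(subgroups)) {
    rare <- rare_overall
  } else {
    # per-subgroup reading: keep a disease if any declared subgroup reaches
    # the threshold
    reaches <- setNames(prev$prevalence >= min_prevalence, prev$code)
    for (ax in subgroups) {
      strata <- stratify(z, ax)
      for (s in strata) {
        ps <- code_prevalence(s, codes = prev$code)
        reaches <- reaches | setNames(ps$prevalence >= min_prevalence, ps$code)
      }
    }
    rare <- names(reaches)[!reaches]
  }
  before <- length(z)
  z$codes <- lapply(z$codes, function(cs) setdiff(cs, rare))
  z <- log_filter(z, sprintf("drop_rare_diseases_(%d_codes)", length(rare)),
                  before, length(z))
  check_nonempty(z, "drop_rare_diseases")
  z
}

check_nonempty <- function(cohort, step) {
  if (length(cohort) == 0L) {
    pcnet_error("pcnet_empty_cohort",
                sprintf("no records remain after step '%s'", step))
  }
  invisible(cohort)
}

#' Comorbidity code universe of a filtered cohort
#'
#' All surviving disease codes minus the thyroid-disease indication codes
#' (`C73` and the whole `E00`--`E07` block), in lexicographic order.
#'
#' @param filtered A cleaned `emr_cohort` (see [filter_cohort()]).
#' @return Character vector of comorbidity codes.
#' @export
comorbidity_universe <- function(filtered) {
  codes <- sort(unique(unlist(filtered$codes)))
  codes[!is_td_code(codes)]
}

## age bins used throughout: 18-39, 40-49, 50-59, 60-69, >=70
age_bin_breaks <- c(18, 40, 50, 60, 70, Inf)
age_bin_labels <- c("18-39", "40-49", "50-59", "60-69", ">=70")

#' Assign age bins
#' @param age Integer vector of ages (>= 18).
#' @return Factor with levels `18-39`, `40-49`, `50-59`, `60-69`, `>=70`.
#' @export
age_bins <- function(age) {
  cut(age, breaks = age_bin_breaks, labels = age_bin_labels, right = FALSE)
}

#' Stratify a cohort into subgroups
#'
#' Axes:
#' \describe{
#'   \item{sex}{`male` / `female`; records with unknown sex are excluded.}
#'   \item{disease_type}{`TC` (thyroid cancer, C73 present) vs `BTD` (benign
#'     thyroid disease). Records carrying both C73 and benign E-codes go to
#'     `TC`: the malignancy is taken as the dominant label so the strata are
#'     disjoint (override with `tc_dominant = FALSE` to assign such records
#'     to both strata).}
#'   \item{td_subtype}{`nontoxic_goiter` (E04), `hypothyroidism` (E02 or
#'     E03), `hyperthyroidism` (E05). These strata may overlap, since a
#'     record can carry several thyroid codes.}
#'   \item{age_bin}{18-39, 40-49, 50-59, 60-69, >=70; a partition.}
#' }
#'
#' @param cohort An `emr_cohort`.
#' @param axis One of `"sex"`, `"disease_type"`, `"td_subtype"`, `"age_bin"`.
#' @param tc_dominant Logical; see `disease_type` above.
#' @return Named list of `emr_cohort` objects.
#' @export
stratify <- function(cohort, axis = c("sex", "disease_type", "td_subtype",
                                      "age_bin"),
                     tc_dominant = TRUE) {
  if (!is.character(axis) || !axis[1] %in% c("sex", "disease_type",
                                             "td_subtype", "age_bin")) {
    pcnet_error("pcnet_config_error",
                sprintf("unknown stratification axis '%s'", axis[1]))
  }
  axis <- match.arg(axis)
  out <- switch(
    axis,
    sex = {
      list(male = subset_cohort(cohort, !is.na(cohort$sex) & cohort$sex == "male"),
           female = subset_cohort(cohort, !is.na(cohort$sex) & cohort$sex == "female"))
    },
    disease_type = {
      has_tc <- vapply(cohort$codes, function(cs) "C73" %in% cs, TRUE)
      has_btd <- vapply(cohort$codes,
                        function(cs) any(grepl("^E0[0-7]$", cs)), TRUE)
      if (tc_dominant) {
        list(TC = subset_cohort(cohort, has_tc),
             BTD = subset_cohort(cohort, has_btd & !has_tc))
      } else {
        list(TC = subset_cohort(cohort, has_tc),
             BTD = subset_cohort(cohort, has_btd))
      }
    },
    td_subtype = {
      lapply(td_group_codes[c("nontoxic_goiter", "hypothyroidism",
                              "hyperthyroidism")],
             function(grp) {
               subset_cohort(cohort, vapply(cohort$codes,
                                            function(cs) any(grp %in% cs), TRUE))
             })
    },
    age_bin = {
      bins <- age_bins(cohort$age)
      setNames(lapply(levels(bins), function(b) {
        subset_cohort(cohort, !is.na(bins) & bins == b)
      }), levels(bins))
    }
  )
  out
}
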