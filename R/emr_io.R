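#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor cor.test kmeans median pnorm pt qlogis qnorm quantile
#'   rbinom runif setNames plogis wilcox.test
#' @importFrom utils read.csv write.csv head modifyList
NULL

## condition helpers -----------------------------------------------------

pcnet_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "pcnet_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

## thyroid-disease code helpers ------------------------------------------

#' Thyroid-disease indication codes
#'
#' A 3-character code counts as a thyroid-disease (TD) indication when it is
#' `C73` (thyroid cancer, TC) or falls in `E00`--`E07` (benign thyroid
#' disease, BTD).
#'
#' @param code Character vector of 3-character ICD-10 codes.
#' @return Logical vector.
#' @export
is_td_code <- function(code) {
  grepl("^E0[0-7]$", code) | code == "C73"
}

## TD subtype groups used for stratification and comorbidity exclusion.
## E02+E03 = hypothyroidism, E04 = nontoxic goiter, E05 = hyperthyroidism,
## E06 = other benign thyroid disease (thyroiditis), C73 = thyroid cancer.
td_group_codes <- list(
  tc              = "C73",
  nontoxic_goiter = "E04",
  hypothyroidism  = c("E02", "E03"),
  hyperthyroidism = "E05",
  other_btd       = "E06"
)

## code normalization ----------------------------------------------------

#' Normalize raw diagnosis codes to 3-character ICD-10 codes
#'
#' Codes are uppercased, separators stripped, and truncated to the
#' 3-character ICD-10 category (letter + two digits), e.g. `"E04.1"` becomes
#' `"E04"`. ICD-9-shaped inputs (leading digit, or ICD-9-style E/V codes such
#' as `"E950"` with three digits) are first translated through a user-supplied
#' ICD-9 to ICD-10 map and then truncated; without a map entry they raise an
#' `pcnet_unmapped_code` error carrying the offending value. Inputs that fit
#' neither shape raise `pcnet_malformed_code`.
#'
#' The operation is idempotent: a valid 3-character code passes through
#' unchanged.
#'
#' @param x Character vector of raw codes.
#' @param icd9_map Optional named character vector or two-column data frame
#'   (`icd9`, `icd10`) mapping ICD-9 codes (with or without dot) to ICD-10
#'   codes. See [read_icd9_map()].
#' @return Character vector of 3-character ICD-10 codes.
#' @examples
#' normalize_icd10(c("E04.1", "c73"))
#' normalize_icd10("244.9", icd9_map = c("244.9" = "E03.9"))
#' @export
normalize_icd10 <- function(x, icd9_map = NULL) {
  if (length(x) == 0L) return(character(0))
  if (any(is.na(x) | !nzchar(x))) {
    pcnet_error("pcnet_malformed_code", "empty or missing diagnosis code")
  }
  raw <- toupper(trimws(as.character(x)))
  map <- icd9_map_lookup(icd9_map)
  out <- character(length(raw))
  for (i in seq_along(raw)) {
    out[i] <- normalize_one(raw[i], map)
  }
  out
}

icd9_map_lookup <- function(icd9_map) {
  if (is.null(icd9_map)) return(NULL)
  if (is.data.frame(icd9_map)) {
    if (!all(c("icd9", "icd10") %in% names(icd9_map))) {
      pcnet_error("pcnet_schema_error",
                  "icd9_map needs columns 'icd9' and 'icd10'")
    }
    icd9_map <- setNames(as.character(icd9_map$icd10),
                         as.character(icd9_map$icd9))
  }
  keys <- toupper(trimws(names(icd9_map)))
  vals <- toupper(trimws(as.character(icd9_map)))
  # index under both dotted and dotless spellings
  setNames(c(vals, vals), c(keys, gsub(".", "", keys, fixed = TRUE)))
}

normalize_one <- function(code, map) {
  dotless <- gsub("[^A-Z0-9]", "", code)
  # ICD-9 shapes: purely numeric (e.g. 244.9) or ICD-9-style external-cause
  # codes (E + three digits before the dot); ICD-10 E codes carry two digits
  # before the dot, so the shape test runs on the raw dotted form
  if (grepl("^[0-9]", dotless) || grepl("^E[0-9]{3}", code)) {
    mapped <- if (!is.null(map)) map[match(code, names(map))] else NA_character_
    if (is.na(mapped)) mapped <- if (!is.null(map)) map[match(dotless, names(map))] else NA_character_
    if (is.na(mapped)) {
      pcnet_error("pcnet_unmapped_code",
                  sprintf("ICD-9-shaped code '%s' has no entry in icd9_map", code),
                  raw = code)
    }
    return(normalize_one(toupper(trimws(mapped)), NULL))
  }
  # V codes: prefer a user map entry (ICD-9 supplementary), else treat as ICD-10
  if (grepl("^V[0-9]+$", dotless) && !is.null(map)) {
    mapped <- map[match(code, names(map))]
    if (is.na(mapped)) mapped <- map[match(dotless, names(map))]
    if (!is.na(mapped)) {
      return(normalize_one(toupper(trimws(mapped)), NULL))
    }
  }
  if (!grepl("^[A-Z][0-9]{2}", dotless)) {
    pcnet_error("pcnet_malformed_code",
                sprintf("cannot interpret diagnosis code '%s'", code),
                raw = code)
  }
  substr(dotless, 1L, 3L)
}

#' Read an ICD-9 to ICD-10 mapping file
#'
#' Two-column CSV with header `icd9,icd10`. The package ships no mapping;
#' general-equivalence tables are versioned artifacts the user supplies.
#'
#' @param path CSV path.
#' @return Named character vector usable as `icd9_map`.
#' @export
read_icd9_map <- function(path) {
  m <- read.csv(path, colClasses = "character")
  if (!all(c("icd9", "icd10") %in% names(m))) {
    pcnet_error("pcnet_schema_error",
                "icd9 map file needs columns 'icd9' and 'icd10'")
  }
  setNames(m$icd10, m$icd9)
}

## cohort container ------------------------------------------------------

#' Construct an EMR cohort object
#'
#' The analysis unit is one hospitalization record (encounter): an id, age in
#' whole years, sex, and a *set* of 3-character ICD-10 codes (duplicates
#' collapse). Repeat hospitalizations are treated as independent records.
#'
#' @param encounter_id Character vector of encounter ids.
#' @param age Integer vector of ages in years (>= 0).
#' @param sex Character vector, `"male"`/`"female"` (NA allowed; such records
#'   are kept overall but excluded from sex-stratified analyses).
#' @param codes List of character vectors of normalized ICD-10 codes, one per
#'   encounter.
#' @param filter_log Data frame logging filter steps (internal).
#' @return An object of class `emr_cohort`.
#' @export
new_cohort <- function(encounter_id, age, sex, codes,
                       filter_log = empty_filter_log()) {
  n <- length(encounter_id)
  stopifnot(length(age) == n, length(sex) == n, length(codes) == n)
  age <- as.integer(age)
  if (any(!is.na(age) & age < 0)) {
    pcnet_error("pcnet_invalid_record", "negative age in cohort")
  }
  sex <- as.character(sex)
  sex[!sex %in% c("male", "female")] <- NA_character_
  codes <- lapply(codes, function(cs) sort(unique(as.character(cs))))
  bad <- !vapply(codes, function(cs) all(grepl("^[A-Z][0-9]{2}$", cs)), TRUE)
  if (any(bad)) {
    pcnet_error("pcnet_malformed_code",
                sprintf("non-normalized codes in %d record(s); run normalize_icd10() first",
                        sum(bad)))
  }
  structure(
    list(encounter_id = as.character(encounter_id),
         age = age, sex = sex, codes = codes,
         filter_log = filter_log),
    class = "emr_cohort"
  )
}

empty_filter_log <- function() {
  data.frame(step = character(0), records_before = integer(0),
             records_after = integer(0), stringsAsFactors = FALSE)
}

log_filter <- function(cohort, step, before, after) {
  cohort$filter_log <- rbind(
    cohort$filter_log,
    data.frame(step = step, records_before = before, records_after = after,
               stringsAsFactors = FALSE)
  )
  cohort
}

#' @export
length.emr_cohort <- function(x) length(x$encounter_id)

#' @export
print.emr_cohort <- function(x, ...) {
  cat(sprintf("EMR cohort: %d encounters, %d distinct codes\n",
              length(x), length(unique(unlist(x$codes)))))
  cat(sprintf("  age: median %s; sex: %d male / %d female / %d unknown\n",
              stats::median(x$age, na.rm = TRUE),
              sum(x$sex == "male", na.rm = TRUE),
              sum(x$sex == "female", na.rm = TRUE),
              sum(is.na(x$sex))))
  if (nrow(x$filter_log)) {
    cat("  filters applied:\n")
    for (i in seq_len(nrow(x$filter_log))) {
      cat(sprintf("    %-28s %d -> %d\n", x$filter_log$step[i],
                  x$filter_log$records_before[i], x$filter_log$records_after[i]))
    }
  }
  invisible(x)
}

#' Subset a cohort by record index
#'
#' Filter provenance is carried over unchanged; callers append their own log
#' entries.
#'
#' @param cohort An `emr_cohort`.
#' @param idx Integer or logical index of records to keep.
#' @return An `emr_cohort`.
#' @export
subset_cohort <- function(cohort, idx) {
  new_cohort(cohort$encounter_id[idx], cohort$age[idx], cohort$sex[idx],
             cohort$codes[idx], filter_log = cohort$filter_log)
}

## readers / writers -----------------------------------------------------

default_sex_recode <- c(M = "male", F = "female", male = "male",
                        female = "female", MALE = "male", FEMALE = "female",
                        m = "male", f = "female")

#' Read a diagnosis table into a cohort
#'
#' The canonical input is a long (tidy) CSV with one row per
#' encounter-diagnosis and columns `encounter_id`, `age`, `sex`, `icd_code`
#' (names configurable through `columns`). A wide dialect — one row per
#' encounter with any number of code columns whose names start with `code` —
#' is accepted with `format = "wide"`. Codes are normalized with
#' [normalize_icd10()] and de-duplicated within an encounter; the number of
#' duplicate diagnosis rows collapsed is recorded in the filter log so that
#' rows in = codes kept + duplicates dropped.
#'
#' @param path CSV path (UTF-8, header row).
#' @param format `"long"` (default) or `"wide"`.
#' @param columns Named list overriding column names, e.g.
#'   `list(encounter_id = "hadm_id")`.
#' @param sex_recode Named character vector mapping raw sex values to
#'   `"male"`/`"female"`; unmapped values become `NA`.
#' @param icd9_map Optional ICD-9 map passed to [normalize_icd10()].
#' @return An `emr_cohort`.
#' @export
read_cohort <- function(path, format = c("long", "wide"),
                        columns = list(), sex_recode = default_sex_recode,
                        icd9_map = NULL) {
  format <- match.arg(format)
  df <- read.csv(path, colClasses = "character", check.names = FALSE)
  if (nrow(df) == 0L) {
    pcnet_error("pcnet_empty_cohort", sprintf("no rows in '%s'", path))
  }
  cols <- modifyList(list(encounter_id = "encounter_id", age = "age",
                          sex = "sex", icd_code = "icd_code"), columns)
  need <- if (format == "long") unlist(cols) else unlist(cols[c("encounter_id", "age", "sex")])
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    pcnet_error("pcnet_schema_error",
                sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  }
  if (format == "long") {
    long <- data.frame(id = df[[cols$encounter_id]],
                       age = df[[cols$age]],
                       sex = df[[cols$sex]],
                       code = df[[cols$icd_code]],
                       stringsAsFactors = FALSE)
  } else {
    code_cols <- grep("^code", names(df), value = TRUE)
    if (!length(code_cols)) {
      pcnet_error("pcnet_schema_error", "wide format needs columns starting with 'code'")
    }
    long <- do.call(rbind, lapply(code_cols, function(cc) {
      data.frame(id = df[[cols$encounter_id]], age = df[[cols$age]],
                 sex = df[[cols$sex]], code = df[[cc]],
                 stringsAsFactors = FALSE)
    }))
    long <- long[!is.na(long$code) & nzchar(trimws(long$code)), , drop = FALSE]
  }
  long$code <- normalize_icd10(long$code, icd9_map = icd9_map)
  ids <- unique(long$id)
  first <- match(ids, long$id)
  codes <- split(long$code, factor(long$id, levels = ids))
  n_dup <- nrow(long) - sum(vapply(codes, function(cs) length(unique(cs)), 0L))
  sex <- unname(sex_recode[long$sex[first]])
  cohort <- new_cohort(ids, as.integer(round(as.numeric(long$age[first]))),
                       sex, unname(codes))
  cohort <- log_filter(cohort, sprintf("read (%d rows, %d duplicate diagnoses collapsed)",
                                       nrow(long), n_dup),
                       length(ids), length(ids))
  cohort
}

#' Write a cohort to long CSV
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(x))` reproduces the
#' cohort up to record order.
#'
#' @param cohort An `emr_cohort`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  k <- lengths(cohort$codes)
  df <- data.frame(encounter_id = rep(cohort$encounter_id, k),
                   age = rep(cohort$age, k),
                   sex = rep(cohort$sex, k),
                   icd_code = unlist(cohort$codes),
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

## network export --------------------------------------------------------

#' Write a comorbidity network to node/edge CSVs and GraphML
#'
#' Node table columns: `code`, `label`, `prevalence`, `degree`,
#' `betweenness`, `pagerank`. Edge table columns: `code_a`, `code_b`,
#' `n_ab`, `cosine`, `phi`, `p`. Isolated nodes appear in the node table
#' only. The GraphML export round-trips through [read_network()] with the
#' edge multiset and weights intact.
#'
#' @param net A [pcn] object.
#' @param node_path,edge_path,graphml_path Output paths (`NULL` to skip one).
#' @return Invisible list of written paths.
#' @export
write_network <- function(net, node_path = NULL, edge_path = NULL,
                          graphml_path = NULL) {
  stopifnot(inherits(net, "pcn"))
  if (nrow(net$nodes) < 1L) {
    pcnet_error("pcnet_empty_network", "network has no nodes")
  }
  s <- summarize_network(net)
  nodes <- data.frame(code = net$nodes$code,
                      label = net$nodes$label,
                      prevalence = net$nodes$prevalence,
                      degree = s$node_metrics$degree,
                      betweenness = s$node_metrics$betweenness,
                      pagerank = s$node_metrics$pagerank,
                      stringsAsFactors = FALSE)
  edges <- net$edges[, c("code_a", "code_b", "n_ab", "cosine", "phi", "p_value")]
  names(edges)[names(edges) == "p_value"] <- "p"
  if (!is.null(node_path)) write.csv(nodes, node_path, row.names = FALSE)
  if (!is.null(edge_path)) write.csv(edges, edge_path, row.names = FALSE)
  if (!is.null(graphml_path)) {
    igraph::write_graph(net$graph, graphml_path, format = "graphml")
  }
  invisible(list(node_path = node_path, edge_path = edge_path,
                 graphml_path = graphml_path))
}

#' Read a GraphML network export
#'
#' @param graphml_path Path written by [write_network()].
#' @return An `igraph` graph with `weight` edge attribute (cosine index).
#' @export
read_network <- function(graphml_path) {
  igraph::read_graph(graphml_path, format = "graphml")
}
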