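corpus_columns <- function() {
  c("study_id", "disorder_id", "subtype_id", "costing_year", "currency",
    cost_columns(), "basis", "indirect_basis", "quality_high",
    "excluded_outlier")
}

#' Build a validated cost-observation corpus
#'
#' One row per article x disorder/subtype: per-patient yearly amounts for up
#' to three cost categories, exactly as stated in the source article
#' (original currency at costing-year prices). A missing category is `NA`
#' (not reported); an explicit `0` is a reported zero cost — the pooling
#' rules treat the two differently.
#'
#' @param x A data frame with the corpus schema (see [read_corpus()]).
#' @param year_range Admissible costing years.
#' @return A tibble of class `coi_corpus`.
#' @export
as_coi_corpus <- function(x, year_range = c(1995L, 2012L)) {
  x <- as_tibble(x)
  missing_cols <- setdiff(corpus_columns(), names(x))
  if (length(missing_cols)) {
    abort(paste0("Corpus is missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "coi_schema_error")
  }
  x <- x[corpus_columns()]
  x <- mutate(x,
              costing_year = as.integer(.data$costing_year),
              across(dplyr::all_of(cost_columns()), as.numeric),
              quality_high = as.logical(.data$quality_high),
              excluded_outlier = as.logical(.data$excluded_outlier))
  problems <- corpus_row_problems(x, year_range)
  if (nrow(problems)) {
    msg <- paste0("row ", problems$row, ": ", problems$problem)
    abort(c("Invalid corpus rows:", setNames(msg, rep("x", length(msg)))),
          class = problems$class[1])
  }
  structure(x, class = c("coi_corpus", class(x)))
}

corpus_row_problems <- function(x, year_range) {
  amounts <- as.matrix(x[cost_columns()])
  neg <- which(apply(amounts, 1, function(a) any(!is.na(a) & a < 0)))
  none <- which(apply(amounts, 1, function(a) all(is.na(a))))
  bad_dis <- which(!x$disorder_id %in% brain_disorders()$disorder_id)
  bad_year <- which(is.na(x$costing_year) |
                      x$costing_year < year_range[1] |
                      x$costing_year > year_range[2])
  bad_basis <- which(!x$basis %in% c("prevalence", "incidence"))
  bad_ib <- which(!x$indirect_basis %in% c("working_age", "all_ages"))
  bind_rows(
    tibble(row = neg, problem = "negative cost amount",
           class = "coi_validation_error"),
    tibble(row = none, problem = "no cost category reported",
           class = "coi_validation_error"),
    tibble(row = bad_dis,
           problem = paste0("unknown disorder_id '", x$disorder_id[bad_dis], "'"),
           class = "coi_vocabulary_error"),
    tibble(row = bad_year, problem = "costing_year outside admissible range",
           class = "coi_validation_error"),
    tibble(row = bad_basis, problem = "basis must be prevalence or incidence",
           class = "coi_validation_error"),
    tibble(row = bad_ib,
           problem = "indirect_basis must be working_age or all_ages",
           class = "coi_validation_error")) %>%
    arrange(.data$row)
}

#' Read a cost-observation corpus from a delimited file
#'
#' Expects a UTF-8, comma-separated table with header columns `study_id`,
#' `disorder_id`, `subtype_id`, `costing_year`, `currency`,
#' `cost_healthcare`, `cost_nonmedical`, `cost_indirect`, `basis`,
#' `indirect_basis`, `quality_high`, `excluded_outlier`. Empty cells are
#' missing values. Rows that violate the schema invariants are reported with
#' their row numbers.
#'
#' @param path Path to the CSV file.
#' @param year_range Admissible costing years, default 1995–2012.
#' @return A `coi_corpus` tibble (possibly with zero rows).
#' @export
read_corpus <- function(path, year_range = c(1995L, 2012L)) {
  if (!file.exists(path)) {
    abort(paste0("Corpus file not found: ", path), class = "coi_schema_error")
  }
  x <- readr::read_csv(
    path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      study_id = "c", disorder_id = "c", subtype_id = "c",
      costing_year = "i", currency = "c",
      cost_healthcare = "d", cost_nonmedical = "d", cost_indirect = "d",
      basis = "c", indirect_basis = "c",
      quality_high = "l", excluded_outlier = "l", .default = "c"))
  as_coi_corpus(x, year_range = year_range)
}

#' Write a corpus back to CSV
#'
#' Round-trips through [read_corpus()] field by field.
#' @param corpus A `coi_corpus`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  readr::write_csv(as_tibble(corpus), path, na = "")
  invisible(path)
}

#' @export
print.coi_corpus <- function(x, ...) {
  cat("<coi_corpus> ", nrow(x), " observations, ",
      length(unique(x$disorder_id)), " disorders; ",
      sum(x$excluded_outlier), " excluded as outliers, ",
      sum(x$basis == "incidence"), " incidence-based\n", sep = "")
  NextMethod()
}

#' Summarise corpus coverage against the disorder vocabulary
#'
#' A reporting-only check: per-disorder observation counts, the categories
#' covered by at least one non-excluded observation, the categories that will
#' need European-median imputation, and the rows excluded from pooling.
#' Never mutates or drops data.
#'
#' @param corpus A `coi_corpus`.
#' @param refs Optional [read_references()] set; when given, the report also
#'   lists the (currency, year) pairs required but absent from the
#'   exchange-rate table.
#' @param config Optional [coi_config()] (controls incidence handling).
#' @return A list of class `coi_validation` with elements `by_disorder`,
#'   `disorders_without_observations`, `disorders_fully_imputed`,
#'   `rows_excluded` and `fx_gaps`.
#' @export
validate_corpus <- function(corpus, refs = NULL, config = NULL) {
  config <- as_coi_config(config)
  long <- corpus_long(corpus)
  pooled <- pooled_rows(corpus, config)
  covered <- corpus_long(pooled) %>%
    distinct(.data$disorder_id, .data$category)
  by_disorder <- brain_disorders() %>%
    left_join(corpus %>% group_by(.data$disorder_id) %>%
                summarise(n_obs = n(), .groups = "drop"),
              by = "disorder_id") %>%
    mutate(n_obs = if_else(is.na(.data$n_obs), 0L, .data$n_obs)) %>%
    left_join(covered %>% group_by(.data$disorder_id) %>%
                summarise(categories_observed =
                            paste(sort(unique(.data$category)), collapse = ","),
                          .groups = "drop"),
              by = "disorder_id") %>%
    mutate(categories_imputed = purrr::map_chr(
      .data$categories_observed,
      ~ paste(setdiff(cost_categories(),
                      if (is.na(.x)) character() else strsplit(.x, ",")[[1]]),
              collapse = ",")))
  fx_gaps <- if (!is.null(refs)) fx_coverage_gaps(corpus, refs) else tibble()
  structure(
    list(by_disorder = by_disorder,
         disorders_without_observations =
           by_disorder$disorder_id[by_disorder$n_obs == 0L],
         disorders_fully_imputed =
           setdiff(brain_disorders()$disorder_id, unique(pooled$disorder_id)),
         rows_excluded = which(corpus$excluded_outlier |
                                 (!config$include_incidence &
                                    corpus$basis == "incidence")),
         fx_gaps = fx_gaps),
    class = "coi_validation")
}

#' @export
print.coi_validation <- function(x, ...) {
  cat("<coi_validation>\n")
  cat("  disorders with observations: ",
      sum(x$by_disorder$n_obs > 0), "/19\n", sep = "")
  cat("  fully imputed after exclusions: ",
      length(x$disorders_fully_imputed), "\n", sep = "")
  cat("  rows excluded from pooling: ", length(x$rows_excluded), "\n", sep = "")
  if (nrow(x$fx_gaps)) {
    cat("  MISSING fx coverage:\n")
    print(x$fx_gaps)
  }
  invisible(x)
}

# long view of the three cost columns; absent categories dropped
corpus_long <- function(corpus) {
  as_tibble(corpus) %>%
    mutate(.row = row_number()) %>%
    tidyr::pivot_longer(dplyr::all_of(cost_columns()),
                        names_to = "category", values_to = "amount",
                        names_prefix = "cost_") %>%
    filter(!is.na(.data$amount))
}

# rows entering the pooled means under the given config
pooled_rows <- function(corpus, config) {
  out <- filter(corpus, !.data$excluded_outlier)
  if (!config$include_incidence) out <- filter(out, .data$basis == "prevalence")
  out
}
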