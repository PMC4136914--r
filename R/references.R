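#' Assemble the reference set for harmonization and scaling
#'
#' Bundles the consumer price index series, the annual nominal exchange
#' rates, the European median per-patient costs (already expressed in EUR at
#' the target-year price level), the prevalence-based patient counts, the
#' disorder configuration and, optionally, subtype prevalence weights.
#'
#' Each argument accepts a data frame or a CSV path with the documented
#' schema: `cpi` (`year`, `index`), `fx` (`currency`, `year`,
#' `eur_per_unit`), `eu_medians` (`disorder_id`, `subtype_id`, `category`,
#' `amount_eur2010`, `source`), `prevalence` (`disorder_id`, `n_patients`
#' and/or `proportion`, `working_age_fraction`), `disorders` (`disorder_id`,
#' `group`, `indirect_forced_zero`), `subtype_weights` (`disorder_id`,
#' `subtype_id`, `weight`).
#'
#' @param cpi,fx,eu_medians,prevalence,disorders,subtype_weights Tables or
#'   CSV paths; `subtype_weights` may be `NULL` (no subtype weighting).
#' @param population National inhabitant count used to turn prevalence
#'   proportions into patient counts. When omitted the default of
#'   46,000,000 is used and a message is emitted.
#' @return A list of class `coi_references`.
#' @export
read_references <- function(cpi, fx, eu_medians, prevalence, disorders,
                            subtype_weights = NULL, population = NULL) {
  if (is.null(population)) {
    population <- default_population()
    message("population not supplied; using default ",
            format(population, big.mark = ",", scientific = FALSE))
  }
  refs <- list(
    cpi = load_table(cpi, c("year", "index")),
    fx = load_table(fx, c("currency", "year", "eur_per_unit")),
    eu_medians = load_table(eu_medians,
                            c("disorder_id", "category", "amount_eur2010")),
    prevalence = load_table(prevalence, "disorder_id"),
    disorders = load_table(disorders,
                           c("disorder_id", "group", "indirect_forced_zero")),
    subtype_weights = if (is.null(subtype_weights)) {
      tibble(disorder_id = character(), subtype_id = character(),
             weight = numeric())
    } else load_table(subtype_weights,
                      c("disorder_id", "subtype_id", "weight")),
    population = population)
  if (!"subtype_id" %in% names(refs$eu_medians)) {
    refs$eu_medians$subtype_id <- NA_character_
  }
  if (!"working_age_fraction" %in% names(refs$prevalence)) {
    refs$prevalence$working_age_fraction <- 1
  }
  if (!"n_patients" %in% names(refs$prevalence)) {
    refs$prevalence$n_patients <- NA_real_
  }
  validate_references(refs)
  structure(refs, class = "coi_references")
}

load_table <- function(x, required) {
  if (is.character(x) && length(x) == 1) {
    x <- readr::read_csv(x, show_col_types = FALSE, progress = FALSE)
  }
  x <- as_tibble(x)
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    abort(paste0("Reference table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "coi_schema_error")
  }
  x
}

validate_references <- function(refs) {
  stopifnot(all(refs$cpi$index > 0), all(refs$fx$eur_per_unit > 0),
            all(refs$eu_medians$amount_eur2010 >= 0),
            all(refs$prevalence$working_age_fraction >= 0 &
                  refs$prevalence$working_age_fraction <= 1),
            refs$population > 0)
  w <- refs$subtype_weights
  if (nrow(w)) {
    bad <- w %>% group_by(.data$disorder_id) %>%
      summarise(s = sum(.data$weight), .groups = "drop") %>%
      filter(abs(.data$s - 1) > 1e-8)
    if (nrow(bad)) {
      abort(paste0("Subtype weights must sum to 1; offending disorder(s): ",
                   paste(bad$disorder_id, collapse = ", ")),
            class = "coi_config_error")
    }
    if (any(w$weight < 0)) {
      abort("Subtype weights must be non-negative", class = "coi_config_error")
    }
  }
  invisible(refs)
}

#' @export
print.coi_references <- function(x, ...) {
  cat("<coi_references>\n",
      "  cpi: ", nrow(x$cpi), " years (", min(x$cpi$year), "-",
      max(x$cpi$year), ")\n",
      "  fx: ", nrow(x$fx), " currency-year rates\n",
      "  eu_medians: ", nrow(x$eu_medians), " cells\n",
      "  prevalence: ", nrow(x$prevalence), " disorders; population ",
      format(x$population, big.mark = ","), "\n", sep = "")
  invisible(x)
}

# (currency, year) pairs required by the corpus but absent from fx
fx_coverage_gaps <- function(corpus, refs) {
  needed <- as_tibble(corpus) %>%
    filter(.data$currency != "EUR") %>%
    distinct(.data$currency, year = .data$costing_year)
  anti_join(needed, refs$fx, by = c("currency", "year"))
}

check_reference_coverage <- function(corpus, refs, target_year) {
  gaps <- fx_coverage_gaps(corpus, refs)
  if (nrow(gaps)) {
    abort(c("Exchange-rate coverage missing for:",
            setNames(paste0(gaps$currency, " ", gaps$year),
                     rep("x", nrow(gaps)))),
          class = "coi_coverage_error")
  }
  need_years <- unique(c(corpus$costing_year, target_year))
  miss <- setdiff(need_years, refs$cpi$year)
  if (length(miss)) {
    abort(paste0("CPI series lacks year(s): ", paste(miss, collapse = ", ")),
          class = "coi_coverage_error")
  }
  invisible(TRUE)
}

#' Prevalence-based patient count
#'
#' Direct counts pass through unchanged; proportions are multiplied by the
#' population and rounded to the nearest integer.
#'
#' @param n_patients Direct patient count, or `NA`.
#' @param proportion Prevalence proportion in `[0, 1]`, used when
#'   `n_patients` is `NA`.
#' @param population Inhabitant count.
#' @return Integer-valued patient count.
#' @examples
#' patient_count(608711)
#' patient_count(NA, proportion = 0.01, population = 1e6)
#' @export
patient_count <- function(n_patients, proportion = NA_real_,
                          population = default_population()) {
  if (!is.na(n_patients)) return(as.numeric(n_patients))
  stopifnot(!is.na(proportion), proportion >= 0, proportion <= 1)
  round(proportion * population)
}

extdata <- function(file) {
  path <- system.file("extdata", file, package = "braincost", mustWork = TRUE)
  path
}

#' Bundled Spanish cost-observation corpus
#'
#' The packaged corpus of Spanish per-patient cost studies published
#' 2004–2012 (42 observations over 11 disorders), with amounts exactly as
#' stated in the source articles, incidence-basis flags, outlier-exclusion
#' flags and quality labels.
#'
#' @return A `coi_corpus`.
#' @export
bundled_corpus <- function() read_corpus(extdata("corpus_es.csv"))

#' Bundled reference tables
#'
#' The Spanish all-items CPI (annual averages rebased to 2010 = 100), ECB
#' annual average exchange rates, the European median imputation values
#' (printed disorder-level values, plus reconstructed subtype-level
#' stand-ins calibrated against the published pooled estimates — see the
#' `source` column and the methods vignette), prevalence-based patient
#' counts, disorder configuration and subtype prevalence weights.
#'
#' @return A `coi_references` object.
#' @export
bundled_references <- function() {
  suppressMessages(read_references(
    cpi = extdata("cpi_es.csv"),
    fx = extdata("fx.csv"),
    eu_medians = extdata("eu_medians.csv"),
    prevalence = extdata("prevalence.csv"),
    disorders = extdata("disorders.csv"),
    subtype_weights = extdata("subtype_weights.csv"),
    population = default_population()))
}

#' Published per-patient cost table
#'
#' The published pooled per-patient costs (EUR, 2010 prices) and patient
#' counts for the 19 disorders, as printed in the reference analysis. Used
#' for validation and for arithmetic reproduction of the published societal
#' totals.
#'
#' @return A tibble with `disorder_id`, `n_patients` and the three category
#'   columns.
#' @export
published_per_patient <- function() {
  readr::read_csv(extdata("published_per_patient_2010.csv"),
                  show_col_types = FALSE, progress = FALSE)
}
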