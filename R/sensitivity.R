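#' Restrict a corpus by a row predicate
#'
#' Default predicate keeps the rows labelled as providing high-quality
#' information. Rows failing the predicate are dropped; the fallback for
#' disorders (or cells) left without observations happens downstream in
#' [quality_sensitivity()], which reverts them to the baseline estimate.
#'
#' @param corpus A `coi_corpus`.
#' @param predicate A function of the corpus tibble returning a logical
#'   vector; default `quality_high`.
#' @return The filtered corpus.
#' @export
restrict_corpus <- function(corpus, predicate = function(x) x$quality_high) {
  keep <- predicate(as_tibble(corpus))
  stopifnot(is.logical(keep), length(keep) == nrow(corpus))
  corpus[keep, , drop = FALSE]
}

#' Derive a quality label from the five appraisal items
#'
#' The appraisal questionnaire asks whether the study perspective is
#' specified, the design justified, all relevant costs included, measured
#' adequately, and uncertainty assessed. The label is applied by reviewers;
#' this helper only encodes a reproducible default cut-off: all unambiguous
#' (non-`NA`) answers must be positive, with at least `min_answered`
#' answered.
#'
#' @param answers Logical vector of length 5 (`NA` = ambiguous).
#' @param min_answered Minimum number of non-`NA` answers, default 3.
#' @return `TRUE`/`FALSE`.
#' @export
derive_quality <- function(answers, min_answered = 3L) {
  stopifnot(is.logical(answers), length(answers) == 5L)
  sum(!is.na(answers)) >= min_answered && all(answers[!is.na(answers)])
}

#' Quality-restricted re-analysis
#'
#' Re-runs the full pipeline using only high-quality observations and
#' reports per-disorder and overall deltas against the baseline, on
#' unrounded values. Any disorder/subtype/category cell left without a
#' high-quality observation keeps its baseline value and the disorder is
#' flagged as a fallback — so fully-imputed disorders are unaffected by
#' construction, and a restriction that drops nothing yields exactly zero
#' deltas.
#'
#' @param corpus A `coi_corpus` with `quality_high` labels.
#' @param refs A `coi_references` set.
#' @param config A [coi_config()].
#' @param predicate Row predicate passed to [restrict_corpus()].
#' @return A list of class `coi_sensitivity`: `by_disorder` (baseline and
#'   restricted societal totals in EUR million, deltas, per-patient deltas,
#'   fallback flag), `overall_delta` (EUR million), `overall_delta_pct`,
#'   and the two societal tables.
#' @export
quality_sensitivity <- function(corpus, refs, config = NULL,
                                predicate = function(x) x$quality_high) {
  config <- as_coi_config(config)
  h <- ensure_harmonized(corpus, refs, config)
  base_cells <- observed_cell_means(h, refs, config)
  hq_cells <- observed_cell_means(restrict_corpus(h, predicate), refs, config)
  # high-quality cell means where available, baseline cells elsewhere
  fallback <- anti_join(base_cells, hq_cells,
                        by = c("disorder_id", "subtype_id", "category"))
  restricted_cells <- bind_rows(hq_cells, fallback)

  finish <- function(cells) {
    completed <- impute_missing(cells, refs, config)
    long <- combine_subtypes(completed, refs$subtype_weights)
    pp <- per_patient_from_long(long, h, refs, config)
    societal_cost(pp, refs)
  }
  base_soc <- finish(base_cells)
  restr_soc <- finish(restricted_cells)

  by_disorder <- tibble(
    disorder_id = base_soc$disorder_id,
    baseline = base_soc$soc_total,
    restricted = restr_soc$soc_total[match(base_soc$disorder_id,
                                           restr_soc$disorder_id)],
    n_patients = base_soc$n_patients) %>%
    mutate(delta = .data$restricted - .data$baseline,
           delta_per_patient = 1e6 * .data$delta / .data$n_patients,
           fallback = .data$disorder_id %in% unique(fallback$disorder_id))
  structure(
    list(by_disorder = by_disorder,
         overall_delta = sum(by_disorder$delta),
         overall_delta_pct = 100 * sum(by_disorder$delta) /
           sum(by_disorder$baseline),
         baseline = base_soc, restricted = restr_soc),
    class = "coi_sensitivity")
}

# shared tail of per_patient_costs(), reusable with substituted cell means
per_patient_from_long <- function(disorder_long, harmonized, refs, config) {
  wide <- tidyr::pivot_wider(
    select(disorder_long, "disorder_id", "category", "amount"),
    names_from = "category", values_from = "amount") %>%
    left_join(tidyr::pivot_wider(
      select(disorder_long, "disorder_id", "category", "provenance"),
      names_from = "category", values_from = "provenance",
      names_prefix = "prov_"), by = "disorder_id") %>%
    left_join(tidyr::pivot_wider(
      select(disorder_long, "disorder_id", "category", "n_obs"),
      names_from = "category", values_from = "n_obs",
      names_prefix = "n_obs_"), by = "disorder_id") %>%
    mutate(total = .data$healthcare + .data$nonmedical + .data$indirect)
  ib <- pooled_rows(harmonized, config) %>%
    filter(!is.na(.data$cost_indirect)) %>%
    group_by(.data$disorder_id) %>%
    summarise(indirect_basis = if (all(.data$indirect_basis == "all_ages"))
      "all_ages" else "working_age", .groups = "drop")
  out <- wide %>%
    left_join(ib, by = "disorder_id") %>%
    mutate(indirect_basis = dplyr::coalesce(.data$indirect_basis,
                                            "working_age")) %>%
    select("disorder_id", "healthcare", "nonmedical", "indirect", "total",
           "prov_healthcare", "prov_nonmedical", "prov_indirect",
           "n_obs_healthcare", "n_obs_nonmedical", "n_obs_indirect",
           "indirect_basis") %>%
    arrange(.data$disorder_id)
  structure(out, class = c("coi_per_patient", class(out)))
}

#' @export
print.coi_sensitivity <- function(x, ...) {
  cat("<coi_sensitivity> overall delta ",
      sprintf("%+.0f EUR million (%+.1f%%)\n", x$overall_delta,
              x$overall_delta_pct), sep = "")
  print(x$by_disorder)
  invisible(x)
}
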