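#' Un-weighted pooled mean of one disorder/category cell
#'
#' The arithmetic mean over the harmonized observations that report the
#' category, after dropping outlier-excluded rows and (by default)
#' incidence-based rows. Explicit zeros participate; absent values are
#' skipped, not zero-filled. Returns `NA` when no included row reports the
#' category.
#'
#' @param harmonized A harmonized `coi_corpus` (see [harmonize()]).
#' @param disorder_id,category Cell to pool (`category` one of
#'   `"healthcare"`, `"nonmedical"`, `"indirect"`).
#' @param subtype_id Optional subtype restriction.
#' @param include_incidence Pool incidence-based rows too?
#' @return A single pooled amount, or `NA`.
#' @export
category_mean <- function(harmonized, disorder_id, category,
                          subtype_id = NULL, include_incidence = FALSE) {
  stopifnot(category %in% cost_categories())
  d <- filter(as_tibble(harmonized),
              .data$disorder_id == !!disorder_id, !.data$excluded_outlier)
  if (!include_incidence) d <- filter(d, .data$basis == "prevalence")
  if (!is.null(subtype_id)) d <- filter(d, .data$subtype_id == !!subtype_id)
  v <- d[[paste0("cost_", category)]]
  v <- v[!is.na(v)]
  if (!length(v)) return(NA_real_)
  mean(v)
}

# observed cell means at the granularity the subtype weights dictate:
# subtype level for weighted disorders, disorder level (all rows pooled,
# each subtype row an ordinary observation) otherwise
observed_cell_means <- function(harmonized, refs, config) {
  pooled <- pooled_rows(harmonized, config)
  w <- refs$subtype_weights
  weighted_dis <- unique(w$disorder_id)
  long <- corpus_long(pooled)
  means_sub <- long %>%
    filter(.data$disorder_id %in% weighted_dis) %>%
    group_by(.data$disorder_id, .data$subtype_id, .data$category) %>%
    summarise(observed = mean(.data$amount), n_obs = n(), .groups = "drop")
  stray <- anti_join(distinct(means_sub, .data$disorder_id, .data$subtype_id),
                     w, by = c("disorder_id", "subtype_id"))
  if (nrow(stray)) {
    abort(c("Corpus subtypes without a configured weight:",
            setNames(paste0(stray$disorder_id, "/", stray$subtype_id),
                     rep("x", nrow(stray)))),
          class = "coi_config_error")
  }
  means_dis <- long %>%
    filter(!.data$disorder_id %in% weighted_dis) %>%
    group_by(.data$disorder_id, .data$category) %>%
    summarise(observed = mean(.data$amount), n_obs = n(), .groups = "drop") %>%
    mutate(subtype_id = NA_character_)
  bind_rows(means_sub, means_dis)
}

#' Complete the cell table with European-median imputation
#'
#' Fills the missing-category hierarchy: an observed pooled mean is kept; a
#' missing cell takes the European median (subtype-level entry first, then
#' the disorder-level entry); a cell with neither becomes zero with
#' provenance `unavailable_zero`. Disorders configured with
#' `indirect_forced_zero` (dementia, childhood/adolescence disorders, whose
#' patients are assumed outside the working population) get indirect cost 0
#' with provenance `forced_zero` regardless of other evidence.
#'
#' @param means Observed cell means (`disorder_id`, `subtype_id`,
#'   `category`, `observed`, `n_obs`), e.g. the internal output of the
#'   pooling step; missing cells may simply be absent rows.
#' @param refs A `coi_references` set.
#' @param config A [coi_config()]; `impute = FALSE` disables the
#'   European-median step.
#' @return A long tibble with one row per disorder (x subtype) x category:
#'   `amount`, `provenance`, `n_obs`.
#' @export
impute_missing <- function(means, refs, config = NULL) {
  config <- as_coi_config(config)
  w <- refs$subtype_weights
  weighted_dis <- unique(w$disorder_id)
  grid <- bind_rows(
    select(w, "disorder_id", "subtype_id"),
    tibble(disorder_id = setdiff(refs$disorders$disorder_id, weighted_dis),
           subtype_id = NA_character_)) %>%
    tidyr::crossing(category = cost_categories())
  eu <- refs$eu_medians
  eu_sub <- filter(eu, !is.na(.data$subtype_id)) %>%
    select("disorder_id", "subtype_id", "category", eu_sub = "amount_eur2010")
  eu_dis <- filter(eu, is.na(.data$subtype_id)) %>%
    select("disorder_id", "category", eu_dis = "amount_eur2010")
  out <- grid %>%
    left_join(means, by = c("disorder_id", "subtype_id", "category")) %>%
    left_join(eu_sub, by = c("disorder_id", "subtype_id", "category")) %>%
    left_join(eu_dis, by = c("disorder_id", "category")) %>%
    mutate(
      eu_value = dplyr::coalesce(.data$eu_sub, .data$eu_dis),
      amount = case_when(
        !is.na(.data$observed) ~ .data$observed,
        config$impute & !is.na(.data$eu_value) ~ .data$eu_value,
        TRUE ~ 0),
      provenance = case_when(
        !is.na(.data$observed) ~ "observed_mean",
        config$impute & !is.na(.data$eu_value) ~ "imputed_eu_median",
        TRUE ~ "unavailable_zero"),
      n_obs = if_else(is.na(.data$n_obs), 0L, .data$n_obs)) %>%
    select(-"eu_sub", -"eu_dis", -"eu_value", -"observed")
  forced <- refs$disorders$disorder_id[refs$disorders$indirect_forced_zero]
  out %>%
    mutate(
      provenance = if_else(.data$disorder_id %in% forced &
                             .data$category == "indirect",
                           "forced_zero", .data$provenance),
      amount = if_else(.data$provenance == "forced_zero", 0, .data$amount))
}

#' Combine subtype costs into disorder-level costs
#'
#' Weighted average per category under the configured subtype prevalence
#' weights; disorders without configured subtypes pass through (their cells
#' were already pooled over all rows, i.e. each subtype row treated as an
#' ordinary observation). Category provenance is the strongest of the
#' component provenances (observed over imputed over forced/unavailable
#' zero).
#'
#' @param completed Long cell table from [impute_missing()].
#' @param weights Subtype weight table (`disorder_id`, `subtype_id`,
#'   `weight`); weights must cover exactly the subtypes present.
#' @return A long disorder-level tibble (`disorder_id`, `category`,
#'   `amount`, `provenance`, `n_obs`).
#' @export
combine_subtypes <- function(completed, weights) {
  plain <- filter(completed, is.na(.data$subtype_id)) %>%
    select("disorder_id", "category", "amount", "provenance", "n_obs")
  sub <- filter(completed, !is.na(.data$subtype_id))
  if (!nrow(sub)) return(plain)
  mism <- dplyr::full_join(distinct(sub, .data$disorder_id, .data$subtype_id),
                           weights, by = c("disorder_id", "subtype_id"))
  if (anyNA(mism$weight)) {
    abort("Subtype/weight mismatch between cost table and weight table",
          class = "coi_config_error")
  }
  prov_rank <- c(observed_mean = 1, imputed_eu_median = 2, forced_zero = 3,
                 unavailable_zero = 4)
  combined <- sub %>%
    left_join(weights, by = c("disorder_id", "subtype_id")) %>%
    group_by(.data$disorder_id, .data$category) %>%
    summarise(amount = sum(.data$weight * .data$amount),
              provenance = names(prov_rank)[min(prov_rank[.data$provenance])],
              n_obs = sum(.data$n_obs), .groups = "drop")
  bind_rows(plain, combined)
}

#' Pooled per-patient costs per disorder
#'
#' The full pooling stage: harmonize (if needed), drop excluded and
#' incidence-based rows, take un-weighted category means, impute missing
#' cells from the European medians, apply forced zeros and subtype weights,
#' and total the three categories.
#'
#' @param corpus A `coi_corpus` (raw or harmonized).
#' @param refs A `coi_references` set.
#' @param config A [coi_config()].
#' @return A tibble of class `coi_per_patient`: one row per disorder with
#'   `healthcare`, `nonmedical`, `indirect`, `total` (EUR per patient per
#'   year at target-year prices), provenance columns `prov_*`, observation
#'   counts `n_obs_*` and the disorder-level `indirect_basis`.
#' @export
per_patient_costs <- function(corpus, refs, config = NULL) {
  config <- as_coi_config(config)
  h <- ensure_harmonized(corpus, refs, config)
  observed <- observed_cell_means(h, refs, config)
  completed <- impute_missing(observed, refs, config)
  disorder_long <- combine_subtypes(completed, refs$subtype_weights)
  per_patient_from_long(disorder_long, h, refs, config)
}

#' @export
print.coi_per_patient <- function(x, ...) {
  cat("<coi_per_patient> EUR per patient per year;",
      nrow(x), "disorders\n")
  NextMethod()
}

#' Scale per-patient costs to societal costs
#'
#' Multiplies each category by the prevalence-based patient count. Direct
#' healthcare and non-medical costs scale by the full count; indirect costs
#' scale by `n * working_age_fraction` unless the pooled indirect estimates
#' were presented as an all-ages average, in which case the full count is
#' used.
#'
#' @param per_patient A `coi_per_patient` table.
#' @param refs A `coi_references` set (prevalence and population).
#' @return A tibble of class `coi_societal`: per disorder, `n_patients` and
#'   category/total societal costs in EUR million.
#' @export
societal_cost <- function(per_patient, refs) {
  prev <- refs$prevalence
  if (!"proportion" %in% names(prev)) prev$proportion <- NA_real_
  out <- as_tibble(per_patient) %>%
    left_join(select(prev, "disorder_id", "n_patients", "proportion",
                     "working_age_fraction"),
              by = "disorder_id")
  if (anyNA(out$n_patients) && anyNA(out$proportion)) {
    miss <- out$disorder_id[is.na(out$n_patients) & is.na(out$proportion)]
    abort(c("No prevalence entry for:", setNames(miss, rep("x", length(miss)))),
          class = "coi_coverage_error")
  }
  out <- out %>%
    mutate(
      n_patients = purrr::map2_dbl(.data$n_patients, .data$proportion,
                                   patient_count,
                                   population = refs$population),
      n_indirect = .data$n_patients *
        if_else(.data$indirect_basis == "all_ages", 1,
                .data$working_age_fraction),
      soc_healthcare = .data$healthcare * .data$n_patients / 1e6,
      soc_nonmedical = .data$nonmedical * .data$n_patients / 1e6,
      soc_indirect = .data$indirect * .data$n_indirect / 1e6,
      soc_total = .data$soc_healthcare + .data$soc_nonmedical +
        .data$soc_indirect) %>%
    select("disorder_id", "n_patients", dplyr::starts_with("soc_"),
           "healthcare", "nonmedical", "indirect", "total",
           dplyr::starts_with("prov_"))
  structure(out, class = c("coi_societal", class(out)))
}

#' @export
print.coi_societal <- function(x, ...) {
  cat("<coi_societal> EUR million;",
      "grand total", format(round(sum(x$soc_total)), big.mark = ","), "\n")
  NextMethod()
}

#' Roll up societal costs into group totals and cost-type shares
#'
#' Sums the societal costs over all 19 disorders and by diagnostic group
#' (mental / neurological), computes mean per-patient costs as group
#' societal total over group patient total, the per-inhabitant cost, and
#' the distribution of the three cost types. Because headache is a low-cost,
#' highly prevalent disorder that dominates the neurological patient count,
#' a `neurological_excl_headache` stratum is reported as well.
#'
#' @param societal A `coi_societal` table covering all 19 disorders.
#' @param refs A `coi_references` set.
#' @return A list of class `coi_rollup` with `groups` (patients, societal
#'   EUR million, mean per-patient EUR), `shares` (percent of societal cost
#'   per category, per stratum), `grand_total` (EUR million) and
#'   `per_inhabitant` (EUR).
#' @export
rollup <- function(societal, refs) {
  missing_dis <- setdiff(brain_disorders()$disorder_id, societal$disorder_id)
  if (length(missing_dis)) {
    abort(c("Societal table incomplete; missing:",
            setNames(missing_dis, rep("x", length(missing_dis)))),
          class = "coi_completeness_error")
  }
  x <- as_tibble(societal) %>%
    left_join(select(brain_disorders(), "disorder_id", "group"),
              by = "disorder_id")
  strata <- list(
    all = x,
    mental = filter(x, .data$group == "mental"),
    neurological = filter(x, .data$group == "neurological"),
    neurological_excl_headache = filter(x, .data$group == "neurological",
                                        .data$disorder_id != "headache"))
  groups <- purrr::imap(strata, function(d, nm) {
    tibble(group = nm,
           n_patients = sum(d$n_patients),
           soc_total = sum(d$soc_total),
           mean_per_patient = 1e6 * sum(d$soc_total) / sum(d$n_patients))
  }) %>% bind_rows()
  shares <- purrr::imap(strata[c("all", "mental", "neurological")],
                        function(d, nm) {
    s <- c(healthcare = sum(d$soc_healthcare),
           nonmedical = sum(d$soc_nonmedical),
           indirect = sum(d$soc_indirect))
    tibble(group = nm, category = names(s), soc = unname(s),
           share_pct = 100 * unname(s) / sum(s))
  }) %>% bind_rows()
  structure(
    list(groups = groups, shares = shares,
         grand_total = sum(x$soc_total),
         per_inhabitant = 1e6 * sum(x$soc_total) / refs$population),
    class = "coi_rollup")
}

#' @export
print.coi_rollup <- function(x, ...) {
  cat("<coi_rollup> grand total ",
      format(round(x$grand_total), big.mark = ","), " EUR million (",
      format(round(x$per_inhabitant), big.mark = ","),
      " EUR per inhabitant)\n", sep = "")
  print(x$groups)
  print(x$shares)
  invisible(x)
}
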