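#' Configuration for the synthetic-corpus generator
#'
#' Describes a ground-truth costing world: true per-patient category means
#' in EUR at 2010 prices, between-study noise, structured missingness,
#' currency/year heterogeneity and quality labelling. Defaults emulate the
#' bundled Spanish corpus: true means equal to the published pooled
#' per-patient costs, three articles per disorder, log-normal between-study
#' noise at CV 0.5, category missingness matching the observed reporting
#' rates, and a mix of costing years and currencies.
#'
#' @param truth Tibble with `disorder_id` (vocabulary ids), optional
#'   `subtype_id` and `weight` (subtype prevalence shares summing to 1
#'   within a disorder), and true means `healthcare`, `nonmedical`,
#'   `indirect` (EUR-2010, >= 0). Default: the published per-patient table.
#' @param n_articles Articles generated per truth row.
#' @param cv Between-study coefficient of variation of the log-normal
#'   study-level noise; `0` makes every observation equal its true mean.
#' @param missingness Named probabilities (per category) that an article
#'   does not report the category. If all three categories would be
#'   dropped, the pattern is redrawn so every article reports something.
#' @param quality_prob Probability an article is labelled high quality.
#' @param currencies Tibble (`currency`, `prob`) of costing currencies.
#' @param years Candidate costing years.
#' @param cpi_growth Annual inflation rate of the synthetic CPI series.
#' @param fx_rates Named vector of EUR per unit for the non-EUR currencies.
#' @param eu_medians Optional imputation table (`disorder_id`, `category`,
#'   `amount_eur2010`); defaults to the true means so that fully-missing
#'   categories are imputed back to truth.
#' @param n_patients Named patient counts per disorder; defaults to the
#'   published counts.
#' @param population Inhabitant count.
#' @return A list of class `coi_synth_config`.
#' @export
synthetic_config <- function(truth = NULL,
                             n_articles = 3L,
                             cv = 0.5,
                             missingness = c(healthcare = 0.10,
                                             nonmedical = 0.45,
                                             indirect = 0.35),
                             quality_prob = 0.45,
                             currencies = tibble(
                               currency = c("EUR", "USD", "GBP"),
                               prob = c(0.90, 0.05, 0.05)),
                             years = 2001:2010,
                             cpi_growth = 0.03,
                             fx_rates = c(USD = 0.78, GBP = 1.25),
                             eu_medians = NULL,
                             n_patients = NULL,
                             population = default_population()) {
  if (is.null(truth)) {
    pub <- published_per_patient()
    truth <- tibble(disorder_id = pub$disorder_id,
                    subtype_id = NA_character_, weight = 1,
                    healthcare = pub$cost_healthcare,
                    nonmedical = pub$cost_nonmedical,
                    indirect = pub$cost_indirect)
    if (is.null(n_patients)) {
      n_patients <- setNames(pub$n_patients, pub$disorder_id)
    }
  }
  truth <- as_tibble(truth)
  if (!"subtype_id" %in% names(truth)) truth$subtype_id <- NA_character_
  if (!"weight" %in% names(truth)) truth$weight <- 1
  stopifnot(all(truth$disorder_id %in% brain_disorders()$disorder_id),
            all(truth$healthcare >= 0), all(truth$nonmedical >= 0),
            all(truth$indirect >= 0), n_articles >= 0, cv >= 0,
            all(missingness >= 0 & missingness <= 1),
            any(missingness < 1),  # every article must report something
            quality_prob >= 0, quality_prob <= 1,
            abs(sum(currencies$prob) - 1) < 1e-8)
  wsum <- truth %>% group_by(.data$disorder_id) %>%
    summarise(s = sum(.data$weight), .groups = "drop")
  stopifnot(all(abs(wsum$s - 1) < 1e-8))
  if (is.null(n_patients)) {
    n_patients <- setNames(rep(1e5, length(unique(truth$disorder_id))),
                           unique(truth$disorder_id))
  }
  if (is.null(eu_medians)) {
    eu_medians <- truth %>%
      tidyr::pivot_longer(dplyr::all_of(cost_categories()),
                          names_to = "category",
                          values_to = "amount_eur2010") %>%
      group_by(.data$disorder_id, .data$category) %>%
      summarise(amount_eur2010 = sum(.data$weight * .data$amount_eur2010),
                .groups = "drop") %>%
      mutate(subtype_id = NA_character_, source = "synthetic_truth")
  }
  structure(
    list(truth = truth, n_articles = as.integer(n_articles), cv = cv,
         missingness = missingness[cost_categories()],
         quality_prob = quality_prob, currencies = currencies,
         years = as.integer(years), cpi_growth = cpi_growth,
         fx_rates = fx_rates, eu_medians = as_tibble(eu_medians),
         n_patients = n_patients, population = population),
    class = "coi_synth_config")
}

# log-normal draw with mean m and coefficient of variation cv
rlnorm_cv <- function(n, m, cv) {
  if (cv == 0 || m == 0) return(rep(m, n))
  s2 <- log(1 + cv^2)
  rlnorm(n, meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
}

#' Generate a synthetic corpus with known ground truth
#'
#' Draws article-level per-patient amounts around the configured true means
#' (log-normal noise at the configured CV), expresses each article in a
#' randomly assigned costing currency and year by inverting the CPI and
#' exchange-rate maps (so harmonization recovers the EUR-2010 amounts
#' exactly), applies per-category missingness and quality labels, and
#' returns matching reference tables plus the analytically expected
#' pipeline outputs.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @return A list with `corpus` (a `coi_corpus`), `references`
#'   (a `coi_references`) and `truth` (list with `per_patient`, `societal`,
#'   `grand_total`; noise-free expectations satisfying the aggregation
#'   invariants by construction).
#' @export
generate_corpus <- function(config, seed = 1L) {
  stopifnot(inherits(config, "coi_synth_config"))
  set.seed(seed)
  years <- config$years
  target <- 2010L
  cpi <- tibble(year = sort(unique(c(years, target)))) %>%
    mutate(index = 100 / (1 + config$cpi_growth)^(target - .data$year))
  fx <- tidyr::crossing(
    currency = setdiff(config$currencies$currency, "EUR"),
    year = sort(unique(c(years, target)))) %>%
    mutate(eur_per_unit = unname(config$fx_rates[.data$currency]))
  idx <- setNames(cpi$index, cpi$year)

  rows <- purrr::pmap(config$truth, function(disorder_id, subtype_id, weight,
                                             healthcare, nonmedical,
                                             indirect, ...) {
    means <- c(healthcare = healthcare, nonmedical = nonmedical,
               indirect = indirect)
    purrr::map(seq_len(config$n_articles), function(j) {
      yr <- if (length(years) == 1) years else sample(years, 1)
      cur <- sample(config$currencies$currency, 1,
                    prob = config$currencies$prob)
      rate <- if (cur == "EUR") 1 else unname(config$fx_rates[cur])
      cpi_factor <- unname(idx[as.character(target)] / idx[as.character(yr)])
      vals <- vapply(cost_categories(),
                     function(cc) rlnorm_cv(1, means[[cc]], config$cv),
                     numeric(1))
      repeat {
        present <- runif(3) >= config$missingness
        if (any(present)) break
      }
      vals[!present] <- NA_real_
      tibble(study_id = sprintf("SYN-%s%s-%02d", disorder_id,
                                if (is.na(subtype_id)) ""
                                else paste0("-", subtype_id), j),
             disorder_id = disorder_id, subtype_id = subtype_id,
             costing_year = as.integer(yr), currency = cur,
             cost_healthcare = vals[["healthcare"]] / (rate * cpi_factor),
             cost_nonmedical = vals[["nonmedical"]] / (rate * cpi_factor),
             cost_indirect = vals[["indirect"]] / (rate * cpi_factor),
             basis = "prevalence", indirect_basis = "working_age",
             quality_high = runif(1) < config$quality_prob,
             excluded_outlier = FALSE)
    }) %>% bind_rows()
  }) %>% bind_rows()
  corpus <- as_coi_corpus(rows, year_range = range(c(years, target)))

  dis_ids <- unique(config$truth$disorder_id)
  weights <- config$truth %>%
    filter(!is.na(.data$subtype_id)) %>%
    select("disorder_id", "subtype_id", "weight")
  refs <- suppressMessages(read_references(
    cpi = cpi, fx = fx, eu_medians = config$eu_medians,
    prevalence = tibble(disorder_id = dis_ids,
                        n_patients = unname(config$n_patients[dis_ids]),
                        working_age_fraction = 1),
    disorders = brain_disorders() %>%
      filter(.data$disorder_id %in% dis_ids) %>%
      transmute(.data$disorder_id, .data$group,
                indirect_forced_zero = FALSE),
    subtype_weights = if (nrow(weights)) weights else NULL,
    population = config$population))

  list(corpus = corpus, references = refs,
       truth = synthetic_truth(config))
}

# noise-free expected pipeline outputs; exact when cv = 0 and each
# missingness probability is 0 or 1
synthetic_truth <- function(config) {
  eu <- config$eu_medians
  long <- config$truth %>%
    tidyr::pivot_longer(dplyr::all_of(cost_categories()),
                        names_to = "category", values_to = "true_mean") %>%
    left_join(select(eu, "disorder_id", "category",
                     eu_value = "amount_eur2010"),
              by = c("disorder_id", "category")) %>%
    mutate(expected = if_else(config$missingness[.data$category] >= 1,
                              dplyr::coalesce(.data$eu_value, 0),
                              .data$true_mean))
  per_patient <- long %>%
    group_by(.data$disorder_id, .data$category) %>%
    summarise(amount = sum(.data$weight * .data$expected), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "category", values_from = "amount") %>%
    mutate(total = .data$healthcare + .data$nonmedical + .data$indirect) %>%
    arrange(.data$disorder_id)
  societal <- per_patient %>%
    mutate(n_patients = unname(config$n_patients[.data$disorder_id]),
           soc_total = .data$total * .data$n_patients / 1e6)
  list(per_patient = per_patient, societal = societal,
       grand_total = sum(societal$soc_total))
}
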