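# Shared fixture builders and independent (brute-force) oracles.

# minimal reference set: flat CPI except one inflation step, one USD rate,
# no medians unless supplied
tiny_refs <- function(eu_medians = NULL, n_patients = NULL,
                      disorder_ids = c("epilepsy", "dementia"),
                      forced_zero = character(),
                      subtype_weights = NULL) {
  if (is.null(eu_medians)) {
    eu_medians <- tibble::tibble(disorder_id = character(),
                                 subtype_id = character(),
                                 category = character(),
                                 amount_eur2010 = numeric())
  }
  if (is.null(n_patients)) {
    n_patients <- stats::setNames(rep(1000, length(disorder_ids)),
                                  disorder_ids)
  }
  suppressMessages(read_references(
    cpi = tibble::tibble(year = 2000:2012,
                         index = 100 * 1.02^(2000:2012 - 2010)),
    fx = tibble::tibble(currency = "USD", year = 2000:2012,
                        eur_per_unit = 0.8),
    eu_medians = eu_medians,
    prevalence = tibble::tibble(disorder_id = disorder_ids,
                                n_patients = unname(n_patients[disorder_ids]),
                                working_age_fraction = 1),
    disorders = tibble::tibble(
      disorder_id = disorder_ids,
      group = ifelse(disorder_ids %in%
                       brain_disorders()$disorder_id[
                         brain_disorders()$group == "mental"],
                     "mental", "neurological"),
      indirect_forced_zero = disorder_ids %in% forced_zero),
    subtype_weights = subtype_weights,
    population = 1e6))
}

tiny_obs <- function(disorder_id, h = NA, nm = NA, ind = NA,
                     year = 2010, currency = "EUR", study = "S1",
                     subtype = NA_character_, basis = "prevalence",
                     quality = FALSE, excluded = FALSE) {
  tibble::tibble(study_id = study, disorder_id = disorder_id,
                 subtype_id = subtype, costing_year = as.integer(year),
                 currency = currency,
                 cost_healthcare = h, cost_nonmedical = nm,
                 cost_indirect = ind, basis = basis,
                 indirect_basis = "working_age", quality_high = quality,
                 excluded_outlier = excluded)
}

# brute-force pooled means + societal totals computed with plain loops,
# independently of the package's dplyr pipeline
brute_force_estimate <- function(corpus, refs) {
  cats <- c("healthcare", "nonmedical", "indirect")
  disorders <- refs$disorders$disorder_id
  idx <- stats::setNames(refs$cpi$index, refs$cpi$year)
  out <- list()
  for (d in disorders) {
    amounts <- numeric(3); names(amounts) <- cats
    for (cc in cats) {
      vals <- c()
      for (i in seq_len(nrow(corpus))) {
        row <- corpus[i, ]
        if (row$disorder_id != d || row$excluded_outlier ||
            row$basis != "prevalence") next
        v <- row[[paste0("cost_", cc)]]
        if (is.na(v)) next
        rate <- if (row$currency == "EUR") 1 else
          refs$fx$eur_per_unit[refs$fx$currency == row$currency &
                                 refs$fx$year == row$costing_year]
        vals <- c(vals, v * rate * idx["2010"] /
                    idx[as.character(row$costing_year)])
      }
      if (length(vals)) {
        amounts[cc] <- mean(vals)
      } else {
        eu <- refs$eu_medians
        m <- eu$amount_eur2010[eu$disorder_id == d & eu$category == cc &
                                 is.na(eu$subtype_id)]
        amounts[cc] <- if (length(m)) m[1] else 0
      }
    }
    if (refs$disorders$indirect_forced_zero[refs$disorders$disorder_id == d]) {
      amounts["indirect"] <- 0
    }
    n <- refs$prevalence$n_patients[refs$prevalence$disorder_id == d]
    out[[d]] <- list(per_patient = amounts, total = sum(amounts),
                     societal = sum(amounts) * n / 1e6)
  }
  out
}

# replicate parameter-recovery study; returns fraction of disorder x
# category cells whose pooled estimate lies within 2 SE of the true mean
recovery_coverage <- function(n_articles, cv, n_reps, seed) {
  cfg <- synthetic_config(n_articles = n_articles, cv = cv,
                          missingness = c(healthcare = 0, nonmedical = 0,
                                          indirect = 0))
  truth <- cfg$truth
  hits <- total <- 0
  for (r in seq_len(n_reps)) {
    gen <- generate_corpus(cfg, seed = seed + r)
    pp <- per_patient_costs(gen$corpus, gen$references)
    for (cc in c("healthcare", "nonmedical", "indirect")) {
      m <- truth[[cc]][match(pp$disorder_id, truth$disorder_id)]
      se <- m * cv / sqrt(n_articles)
      hits <- hits + sum(abs(pp[[cc]] - m) <= 2 * se + 1e-9)
      total <- total + length(m)
    }
  }
  hits / total
}
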