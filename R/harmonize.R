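#' Convert an amount to EUR at same-year prices
#'
#' Multiplies by the annual nominal exchange rate (EUR per unit of the
#' source currency) for the costing year. EUR amounts pass through
#' unchanged.
#'
#' @param amount Money amount in the source currency (vectorised).
#' @param currency ISO-4217 code.
#' @param year Costing year.
#' @param fx Exchange-rate table (`currency`, `year`, `eur_per_unit`).
#' @return Amount in EUR at `year` prices.
#' @export
convert_currency <- function(amount, currency, year, fx) {
  if (currency == "EUR") return(amount)
  rate <- fx$eur_per_unit[fx$currency == currency & fx$year == year]
  if (length(rate) != 1) {
    abort(paste0("No exchange rate for ", currency, " ", year),
          class = "coi_coverage_error")
  }
  amount * rate
}

#' Restate an EUR amount at another year's price level
#'
#' `amount * cpi(to_year) / cpi(from_year)`, using the all-items consumer
#' price index series.
#'
#' @param amount Money amount in EUR at `from_year` prices (vectorised).
#' @param from_year,to_year Calendar years, both covered by `cpi`.
#' @param cpi CPI table (`year`, `index`).
#' @return Amount at `to_year` prices.
#' @export
inflate <- function(amount, from_year, to_year, cpi) {
  if (from_year == to_year) return(amount)
  i_from <- cpi$index[cpi$year == from_year]
  i_to <- cpi$index[cpi$year == to_year]
  if (length(i_from) != 1 || length(i_to) != 1) {
    abort(paste0("CPI series lacks year ",
                 paste(setdiff(c(from_year, to_year), cpi$year),
                       collapse = ", ")),
          class = "coi_coverage_error")
  }
  amount * i_to / i_from
}

#' Harmonize a corpus to EUR at target-year prices
#'
#' Each present cost category is first converted to EUR at the costing-year
#' annual nominal rate, then inflated to the target year with the national
#' all-items CPI. Absent categories stay absent; explicit zeros stay exactly
#' zero; all flags are preserved. Two audit columns record the exchange rate
#' and CPI factor applied, and `harmonized` marks the restated rows, which
#' makes the operation idempotent: harmonizing EUR/target-year data (or an
#' already-harmonized corpus) is the identity.
#'
#' @param corpus A `coi_corpus`.
#' @param refs A `coi_references` set covering the corpus.
#' @param target_year Price-level year, default 2010.
#' @return The corpus with amounts in EUR at `target_year` prices plus audit
#'   columns `fx_rate`, `cpi_factor`, `harmonized`.
#' @export
harmonize <- function(corpus, refs, target_year = 2010) {
  if (isTRUE(attr(corpus, "target_year") == target_year) ||
      ("harmonized" %in% names(corpus) && all(corpus$harmonized))) {
    return(corpus)
  }
  check_reference_coverage(corpus, refs, target_year)
  fx_rate <- vapply(seq_len(nrow(corpus)), function(i) {
    if (corpus$currency[i] == "EUR") 1
    else refs$fx$eur_per_unit[refs$fx$currency == corpus$currency[i] &
                                refs$fx$year == corpus$costing_year[i]]
  }, numeric(1))
  idx <- setNames(refs$cpi$index, refs$cpi$year)
  cpi_factor <- unname(idx[as.character(target_year)] /
                         idx[as.character(corpus$costing_year)])
  out <- corpus
  for (col in cost_columns()) {
    out[[col]] <- out[[col]] * fx_rate * cpi_factor
  }
  out$currency <- "EUR"
  out$costing_year <- as.integer(target_year)
  out$fx_rate <- fx_rate
  out$cpi_factor <- cpi_factor
  out$harmonized <- TRUE
  attr(out, "target_year") <- as.integer(target_year)
  out
}

ensure_harmonized <- function(corpus, refs, config) {
  harmonize(corpus, refs, target_year = config$target_year)
}
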