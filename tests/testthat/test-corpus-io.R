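test_that("bundled corpus matches the documented study inventory", {
  corpus <- bundled_corpus()
  expect_s3_class(corpus, "coi_corpus")
  expect_identical(nrow(corpus), 42L)
  expect_identical(sum(corpus$excluded_outlier), 3L)
  expect_identical(sum(corpus$basis == "incidence"), 2L)
  expect_identical(length(unique(corpus$disorder_id)), 11L)
  ms <- corpus[corpus$disorder_id == "multiple_sclerosis", ]
  expect_identical(nrow(ms), 4L)
  expect_setequal(ms$study_id, c("Kobelt 2006", "Arroyo 2011",
                                 "Casado 2006", "Karampampa 2012"))
  mar_stroke <- corpus[corpus$study_id == "Mar 2011" &
                         corpus$disorder_id == "stroke", ]
  expect_true(mar_stroke$excluded_outlier)
  # amounts stored exactly as stated in the articles
  sancho <- corpus[corpus$study_id == "Sancho 2008", ]
  expect_equal(unlist(sancho[, c("cost_healthcare", "cost_nonmedical",
                                 "cost_indirect")], use.names = FALSE),
               c(4982, 255, 1618))
  # explicit zero (reported zero cost) distinct from absent
  other_headache <- corpus[corpus$subtype_id %in% "other_headache", ]
  expect_identical(other_headache$cost_indirect, 0)
  expect_true(is.na(other_headache$cost_nonmedical))
})

test_that("corpus round-trips through CSV unchanged", {
  corpus <- bundled_corpus()
  path <- withr::local_tempfile(fileext = ".csv")
  write_corpus(corpus, path)
  back <- read_corpus(path)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(corpus))
})

test_that("an empty corpus file with a valid header loads without error", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste(c("study_id", "disorder_id", "subtype_id", "costing_year",
                     "currency", "cost_healthcare", "cost_nonmedical",
                     "cost_indirect", "basis", "indirect_basis",
                     "quality_high", "excluded_outlier"), collapse = ","),
             path)
  corpus <- read_corpus(path)
  expect_identical(nrow(corpus), 0L)
})

test_that("schema and row-level validation errors name the problem", {
  bad <- tiny_obs("epilepsy", h = -5)
  expect_error(as_coi_corpus(bad), class = "coi_validation_error")
  expect_error(as_coi_corpus(bad), "row 1.*negative")

  expect_error(as_coi_corpus(tiny_obs("not_a_disorder", h = 10)),
               class = "coi_vocabulary_error")
  expect_error(as_coi_corpus(tiny_obs("epilepsy")),  # all categories absent
               class = "coi_validation_error")
  expect_error(as_coi_corpus(tiny_obs("epilepsy", h = 1, year = 1901)),
               class = "coi_validation_error")
  expect_error(as_coi_corpus(tiny_obs("epilepsy", h = 1)[, -1]),
               class = "coi_schema_error")
  expect_error(read_corpus(file.path(tempdir(), "nope.csv")),
               class = "coi_schema_error")
})

test_that("validation reports coverage without mutating the corpus", {
  corpus <- bundled_corpus()
  refs <- bundled_references()
  before <- tibble::as_tibble(corpus)
  report <- validate_corpus(corpus, refs)
  expect_identical(tibble::as_tibble(corpus), before)
  expect_length(report$disorders_without_observations, 8L)
  # traumatic brain injury has one (excluded) observation, so after
  # exclusions one more disorder is fully imputed
  expect_length(report$disorders_fully_imputed, 9L)
  expect_length(report$rows_excluded, 5L)  # 3 outliers + 2 incidence rows
  expect_identical(nrow(report$fx_gaps), 0L)

  dem_only <- as_coi_corpus(corpus[corpus$disorder_id == "dementia", ])
  rep2 <- validate_corpus(dem_only)
  expect_length(rep2$disorders_without_observations, 18L)

  all_excl <- tibble::as_tibble(corpus)
  all_excl$excluded_outlier <- TRUE
  rep3 <- validate_corpus(as_coi_corpus(all_excl))
  expect_length(rep3$disorders_fully_imputed, 19L)
})

test_that("missing exchange-rate coverage is reported as a gap", {
  refs <- bundled_references()
  refs$fx <- refs$fx[!(refs$fx$currency == "USD" & refs$fx$year == 2005), ]
  report <- validate_corpus(bundled_corpus(), refs)
  expect_identical(report$fx_gaps$currency, "USD")
  expect_identical(report$fx_gaps$year, 2005L)
  expect_error(harmonize(bundled_corpus(), refs),
               class = "coi_coverage_error")
})

test_that("omitted population falls back to the national default with a message", {
  expect_message(
    refs <- read_references(
      cpi = tibble::tibble(year = 2010, index = 100),
      fx = tibble::tibble(currency = character(), year = integer(),
                          eur_per_unit = numeric()),
      eu_medians = tibble::tibble(disorder_id = character(),
                                  subtype_id = character(),
                                  category = character(),
                                  amount_eur2010 = numeric()),
      prevalence = tibble::tibble(disorder_id = "epilepsy",
                                  n_patients = 1000),
      disorders = tibble::tibble(disorder_id = "epilepsy",
                                 group = "neurological",
                                 indirect_forced_zero = FALSE)),
    "46,000,000")
  expect_identical(refs$population, 46e6)
})
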