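test_that("zero-noise, zero-missingness corpora are recovered exactly", {
  truth <- tibble::tibble(
    disorder_id = c("epilepsy", "dementia", "mood", "mood"),
    subtype_id = c(NA, NA, "unipolar", "bipolar"),
    weight = c(1, 1, 0.8, 0.2),
    healthcare = c(4000, 6000, 1500, 300),
    nonmedical = c(600, 20000, 0, 0),
    indirect = c(1800, 4500, 1300, 3000))
  cfg <- synthetic_config(
    truth = truth, n_articles = 4, cv = 0,
    missingness = c(healthcare = 0, nonmedical = 0, indirect = 0),
    n_patients = c(epilepsy = 225346, dementia = 608711, mood = 3002725))
  gen <- generate_corpus(cfg, seed = 42)
  # currency/year heterogeneity is present yet inverts exactly
  expect_gt(length(unique(gen$corpus$costing_year)), 1)
  pp <- per_patient_costs(gen$corpus, gen$references)
  expect_equal(pp$healthcare,
               gen$truth$per_patient$healthcare[
                 match(pp$disorder_id, gen$truth$per_patient$disorder_id)])
  expect_equal(pp$total,
               gen$truth$per_patient$total[
                 match(pp$disorder_id, gen$truth$per_patient$disorder_id)])
  soc <- societal_cost(pp, gen$references)
  expect_equal(sum(soc$soc_total), gen$truth$grand_total)
  # mood combines the subtype structure with its prevalence weights
  expect_equal(pp$healthcare[pp$disorder_id == "mood"],
               0.8 * 1500 + 0.2 * 300)
})

test_that("certain missingness routes a category through the medians", {
  truth <- tibble::tibble(disorder_id = c("epilepsy", "stroke"),
                          healthcare = c(4000, 3000),
                          nonmedical = c(600, 5000), indirect = c(1800, 800))
  cfg <- synthetic_config(
    truth = truth, n_articles = 3, cv = 0,
    missingness = c(healthcare = 0, nonmedical = 1, indirect = 0),
    n_patients = c(epilepsy = 1e5, stroke = 2e5))
  gen <- generate_corpus(cfg, seed = 7)
  expect_true(all(is.na(gen$corpus$cost_nonmedical)))
  pp <- per_patient_costs(gen$corpus, gen$references)
  expect_identical(unique(pp$prov_nonmedical), "imputed_eu_median")
  # default medians are the true means, so truth is still recovered
  expect_equal(pp$nonmedical[pp$disorder_id == "epilepsy"], 600)
  expect_equal(pp$total,
               gen$truth$per_patient$total[
                 match(pp$disorder_id, gen$truth$per_patient$disorder_id)])
})

test_that("synthetic corpora round-trip through the corpus file format", {
  gen <- generate_corpus(synthetic_config(n_articles = 2), seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_corpus(gen$corpus, path)
  expect_equal(tibble::as_tibble(read_corpus(path)),
               tibble::as_tibble(gen$corpus))
})

test_that("pooled means recover the true means within sampling error", {
  # 10 articles per disorder at CV 0.2, 100 replicates: at least 95% of
  # disorder x category cells within 2 standard errors of the truth
  coverage <- recovery_coverage(n_articles = 10, cv = 0.2, n_reps = 100,
                                seed = 500)
  expect_gte(coverage, 0.95)
})

test_that("estimation error shrinks as articles accumulate", {
  truth <- tibble::tibble(disorder_id = c("epilepsy", "stroke", "dementia"),
                          healthcare = c(4000, 3000, 6000),
                          nonmedical = c(600, 5000, 20000),
                          indirect = c(1800, 800, 4500))
  rmse_for <- function(n_articles) {
    errs <- c()
    for (r in 1:20) {
      cfg <- synthetic_config(truth = truth, n_articles = n_articles,
                              cv = 0.4,
                              missingness = c(healthcare = 0,
                                              nonmedical = 0, indirect = 0),
                              n_patients = c(epilepsy = 1, stroke = 1,
                                             dementia = 1))
      gen <- generate_corpus(cfg, seed = 9000 + 100 * n_articles + r)
      pp <- per_patient_costs(gen$corpus, gen$references)
      tt <- gen$truth$per_patient
      m <- match(pp$disorder_id, tt$disorder_id)
      errs <- c(errs, (pp$healthcare - tt$healthcare[m]) / tt$healthcare[m],
                (pp$nonmedical - tt$nonmedical[m]) / tt$nonmedical[m],
                (pp$indirect - tt$indirect[m]) / tt$indirect[m])
    }
    sqrt(mean(errs^2))
  }
  r5 <- rmse_for(5)
  r20 <- rmse_for(20)
  r80 <- rmse_for(80)
  expect_gt(r5, r20)
  expect_gt(r20, r80)
})
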