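refs <- bundled_references()
corpus <- bundled_corpus()
h <- harmonize(corpus, refs)

test_that("epilepsy pooling reproduces the published row within 1%", {
  # healthcare: mean of two reporting articles; indirect: single article,
  # absence skipped rather than zero-filled
  expect_equal(category_mean(h, "epilepsy", "healthcare"), 4721.7761,
               tolerance = 1e-6)
  expect_equal(category_mean(h, "epilepsy", "healthcare") / 4734, 1,
               tolerance = 0.01)
  expect_equal(category_mean(h, "epilepsy", "indirect"), 1818.8867,
               tolerance = 1e-6)
  expect_equal(category_mean(h, "epilepsy", "indirect") / 1827, 1,
               tolerance = 0.01)
  pp <- per_patient_costs(corpus, refs)
  epi <- pp[pp$disorder_id == "epilepsy", ]
  expect_equal(epi$total / 7180, 1, tolerance = 0.01)
  expect_identical(epi$prov_healthcare, "observed_mean")
})

test_that("a single observation pools to itself", {
  one <- as_coi_corpus(tiny_obs("epilepsy", h = 5000))
  expect_identical(category_mean(harmonize(one, tiny_refs()), "epilepsy",
                                 "healthcare"), 5000)
})

test_that("imputation follows observed > European median > zero, with provenance", {
  eu <- tibble::tibble(
    disorder_id = c("eating", "eating", "dementia"),
    subtype_id = NA_character_,
    category = c("healthcare", "indirect", "indirect"),
    amount_eur2010 = c(364, 90, 5000))
  refs2 <- tiny_refs(eu_medians = eu,
                     disorder_ids = c("eating", "dementia"),
                     forced_zero = "dementia")
  cor2 <- as_coi_corpus(dplyr::bind_rows(
    tiny_obs("dementia", h = 1000, ind = 700)))
  pp <- per_patient_costs(cor2, refs2)
  eating <- pp[pp$disorder_id == "eating", ]
  expect_identical(eating$prov_healthcare, "imputed_eu_median")
  expect_identical(eating$healthcare, 364)
  expect_identical(eating$prov_nonmedical, "unavailable_zero")
  expect_identical(eating$nonmedical, 0)
  dem <- pp[pp$disorder_id == "dementia", ]
  # observed mean kept, never overwritten by the median ...
  expect_identical(dem$healthcare, 1000)
  # ... but the forced zero overrides even observed/median indirect values
  expect_identical(dem$indirect, 0)
  expect_identical(dem$prov_indirect, "forced_zero")
})

test_that("toggling imputation off only decreases or preserves totals", {
  on <- suppressWarnings(run_estimate(coi_config()))
  off <- suppressWarnings(run_estimate(coi_config(impute = FALSE)))
  expect_true(all(off$per_patient$total <= on$per_patient$total + 1e-9))
  expect_lt(off$rollup$grand_total, on$rollup$grand_total)
})

test_that("subtype combination is a weighted average with safeguards", {
  cells <- tibble::tibble(
    disorder_id = "mood", subtype_id = c("unipolar", "bipolar"),
    category = "healthcare", amount = c(100, 300),
    provenance = "observed_mean", n_obs = 1L)
  w50 <- tibble::tibble(disorder_id = "mood",
                        subtype_id = c("unipolar", "bipolar"),
                        weight = c(0.5, 0.5))
  out <- combine_subtypes(cells, w50)
  expect_equal(out$amount, 200)
  # one subtype with weight 1 is the identity
  one <- combine_subtypes(cells[1, ],
                          tibble::tibble(disorder_id = "mood",
                                         subtype_id = "unipolar", weight = 1))
  expect_equal(one$amount, 100)
  expect_error(combine_subtypes(cells, w50[1, ]),
               class = "coi_config_error")
})

test_that("patient counts use direct counts or proportion x population", {
  expect_identical(patient_count(608711), 608711)
  expect_identical(patient_count(NA, proportion = 0.01, population = 1e6),
                   10000)
  expect_identical(patient_count(NA, proportion = 0, population = 1e6), 0)
})

test_that("societal scaling reproduces published products and handles n = 0", {
  pub <- published_per_patient()
  pp <- tibble::tibble(
    disorder_id = pub$disorder_id,
    healthcare = pub$cost_healthcare, nonmedical = pub$cost_nonmedical,
    indirect = pub$cost_indirect,
    total = pub$cost_healthcare + pub$cost_nonmedical + pub$cost_indirect,
    indirect_basis = "working_age")
  soc <- societal_cost(pp, refs)
  expect_equal(soc$soc_total[soc$disorder_id == "dementia"], 15402,
               tolerance = 1e-3)
  expect_equal(soc$soc_total[soc$disorder_id == "eating"], 65,
               tolerance = 1e-2)
  refs0 <- refs
  refs0$prevalence$n_patients <- 0
  soc0 <- societal_cost(pp, refs0)
  expect_true(all(soc0$soc_total == 0))
})

test_that("indirect costs scale by the working-age fraction unless all-ages based", {
  refs2 <- tiny_refs(disorder_ids = "stroke")
  refs2$prevalence$working_age_fraction <- 0.6
  pp <- tibble::tibble(disorder_id = "stroke", healthcare = 100,
                       nonmedical = 0, indirect = 1000, total = 1100,
                       indirect_basis = "working_age")
  soc <- societal_cost(pp, refs2)
  expect_equal(soc$soc_indirect, 1000 * 1000 * 0.6 / 1e6)
  pp$indirect_basis <- "all_ages"
  expect_equal(societal_cost(pp, refs2)$soc_indirect, 1000 * 1000 / 1e6)
})

test_that("aggregation equals a brute-force oracle on small corpora", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(2:5, 1)
    rows <- lapply(seq_len(n), function(i) {
      tiny_obs(sample(c("epilepsy", "dementia"), 1),
               h = if (runif(1) < 0.8) round(runif(1, 0, 9000), 2) else NA,
               nm = if (runif(1) < 0.6) round(runif(1, 0, 9000), 2) else NA,
               ind = if (runif(1) < 0.6) round(runif(1, 0, 9000), 2) else NA,
               year = sample(2004:2010, 1),
               currency = sample(c("EUR", "USD"), 1),
               study = paste0("S", i))
    })
    rows <- dplyr::bind_rows(rows)
    keep <- !(is.na(rows$cost_healthcare) & is.na(rows$cost_nonmedical) &
                is.na(rows$cost_indirect))
    rows <- rows[keep, ]
    if (!nrow(rows)) next
    eu <- tibble::tibble(disorder_id = "dementia", subtype_id = NA_character_,
                         category = "indirect", amount_eur2010 = 1234)
    refs2 <- tiny_refs(eu_medians = eu)
    oracle <- brute_force_estimate(rows, refs2)
    pp <- per_patient_costs(as_coi_corpus(rows), refs2)
    soc <- societal_cost(pp, refs2)
    for (d in names(oracle)) {
      got <- pp[pp$disorder_id == d, ]
      expect_equal(unname(unlist(got[, c("healthcare", "nonmedical",
                                         "indirect")])),
                   unname(oracle[[d]]$per_patient), tolerance = 1e-10)
      expect_equal(soc$soc_total[soc$disorder_id == d],
                   oracle[[d]]$societal, tolerance = 1e-10)
    }
  }
})

test_that("societal costs are additive and monotone in the observations", {
  est <- suppressWarnings(run_estimate())
  soc <- est$societal
  expect_equal(soc$soc_healthcare + soc$soc_nonmedical + soc$soc_indirect,
               soc$soc_total)
  expect_equal(sum(soc$soc_total), est$rollup$grand_total)
  g <- est$rollup$groups
  expect_equal(g$soc_total[g$group == "mental"] +
                 g$soc_total[g$group == "neurological"],
               g$soc_total[g$group == "all"])
  # shares normalise to 100% before rounding
  sh <- est$rollup$shares
  tot <- tapply(sh$share_pct, sh$group, sum)
  expect_equal(as.vector(tot), rep(100, 3))

  # raising one observation's amount weakly increases everything downstream
  bumped <- tibble::as_tibble(corpus)
  i <- which(bumped$study_id == "Sancho 2008")
  bumped$cost_healthcare[i] <- bumped$cost_healthcare[i] + 1000
  est2 <- suppressWarnings(run_estimate(corpus = as_coi_corpus(bumped)))
  expect_gt(est2$per_patient$total[est2$per_patient$disorder_id == "epilepsy"],
            est$per_patient$total[est$per_patient$disorder_id == "epilepsy"])
  expect_gt(est2$rollup$grand_total, est$rollup$grand_total)
  expect_true(all(est2$per_patient$total >= est$per_patient$total - 1e-9))
})

test_that("rollup demands all 19 disorders", {
  est <- suppressWarnings(run_estimate())
  soc <- est$societal[est$societal$disorder_id != "stroke", ]
  expect_error(rollup(soc, refs), class = "coi_completeness_error")
})
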