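test_that("triangular fitting uses article extremes with the mean as mode", {
  tri <- fit_triangular(c(2, 3, 7))
  expect_equal(c(tri$min, tri$mode, tri$max), c(2, 4, 7))
  expect_false(tri$degenerate)
  one <- fit_triangular(5000)
  expect_true(one$degenerate)
  expect_equal(one$min, 5000)
  two <- fit_triangular(c(10, 30))
  expect_equal(tri_mean <- (two$min + two$mode + two$max) / 3, 20)
  expect_equal(two$mode, 20)  # symmetric for two values
  m <- fit_triangular(c(2, 3, 7), mode_stat = "median")
  expect_equal(m$mode, 3)
  expect_error(fit_triangular(numeric(0)), class = "coi_validation_error")
})

test_that("sampler matches the closed-form triangular moments and quantiles", {
  set.seed(99)
  x <- rtriangular(1e5, 0, 5, 10)
  expect_true(all(x >= 0 & x <= 10))
  # mean 5, sd sqrt(75/18); 3 standard errors of the mean
  expect_equal(mean(x), 5, tolerance = 3 * sqrt(75 / 18) / sqrt(1e5) / 5)
  # 90% central quantiles vs closed form F(x) = x^2/50 on the lower half
  q_true <- c(sqrt(0.05 * 50), 10 - sqrt(0.05 * 50))
  dens <- 2 * q_true[1] / 50
  se_q <- sqrt(0.05 * 0.95 / 1e5) / dens
  emp <- unname(quantile(x, c(0.05, 0.95)))
  expect_lt(abs(emp[1] - q_true[1]), 3 * se_q)
  expect_lt(abs(emp[2] - q_true[2]), 3 * se_q)
  # quantile function inverts the CDF
  p <- seq(0.01, 0.99, by = 0.07)
  expect_equal(ptriangular(qtriangular(p, 0, 5, 10), 0, 5, 10), p)
  # asymmetric case too
  expect_equal(ptriangular(qtriangular(p, 1, 2, 9), 1, 2, 9), p)
})

test_that("degenerate components contribute constants", {
  dists <- list(degenerate_h = fit_triangular(10),
                degenerate_n = fit_triangular(20),
                degenerate_i = fit_triangular(30))
  s <- sample_disorder(dists, n_iter = 50, seed = 1)
  expect_identical(s, rep(60, 50))
  expect_equal(summarize_samples(s), c(mean = 60, lower = 60, upper = 60))
})

test_that("sample summaries use linear order-statistic interpolation", {
  s <- summarize_samples(as.numeric(1:1000), level = 0.90)
  expect_equal(unname(s["lower"]), 50.95)
  expect_equal(unname(s["upper"]), 950.05)
  expect_equal(unname(s["mean"]), 500.5)
})

test_that("pooled medians behave for constant disorders", {
  two <- cbind(a = rep(100, 20), b = rep(300, 20))
  ps <- pooled_median_stats(two, threshold = 150)
  expect_true(all(ps$medians == 200))
  expect_identical(ps$exceedance, 1)
  # seven degenerate disorders: the median is the 4th order statistic
  seven <- t(replicate(10, c(10, 20, 30, 40, 50, 60, 70)))
  expect_true(all(pooled_median_stats(seven, threshold = 0)$medians == 40))
  expect_error(pooled_median_stats(list(a = 1:3, b = 1:4), threshold = 0),
               class = "coi_validation_error")
  expect_error(pooled_median_stats(cbind(a = 1:3), threshold = 0),
               class = "coi_validation_error")
})

test_that("simulation is seed-reproducible with samples inside the support", {
  cfg <- coi_config(seed = 11, n_iter = 400)
  sim1 <- run_simulate(cfg)
  sim2 <- run_simulate(cfg)
  expect_identical(sim1$samples, sim2$samples)
  expect_identical(sim1$summary, sim2$summary)

  # support containment per disorder: totals within [sum mins, sum maxs]
  refs <- bundled_references()
  corpus <- bundled_corpus()
  h <- harmonize(corpus, refs)
  epi <- sim1$samples[, "epilepsy"]
  lo <- 3843 + min(h$cost_nonmedical[h$disorder_id == "epilepsy"],
                   na.rm = TRUE) +
    category_mean(h, "epilepsy", "indirect")
  hi <- max(h$cost_healthcare[h$disorder_id == "epilepsy"], na.rm = TRUE) +
    max(h$cost_nonmedical[h$disorder_id == "epilepsy"], na.rm = TRUE) +
    category_mean(h, "epilepsy", "indirect")
  expect_true(all(epi >= lo - 1e-9 & epi <= hi + 1e-9))
  expect_true(all(sim1$summary$lower <= sim1$summary$upper))
})

test_that("disorders with single-article categories have zero-width intervals", {
  refs <- tiny_refs()
  corpus <- as_coi_corpus(dplyr::bind_rows(
    tiny_obs("epilepsy", h = 4000, nm = 300, ind = 1500),
    tiny_obs("dementia", h = 5000, study = "S2"),
    tiny_obs("dementia", h = 7000, study = "S3")))
  cfg <- coi_config(seed = 3, n_iter = 100,
                    simulate_disorders = c("epilepsy", "dementia"))
  sim <- simulate_costs(corpus, refs, cfg)
  epi <- sim$summary[sim$summary$disorder_id == "epilepsy", ]
  expect_equal(epi$lower, epi$upper)
  expect_equal(epi$sim_mean, 5800)
  dem <- sim$summary[sim$summary$disorder_id == "dementia", ]
  expect_lt(dem$lower, dem$upper)
})

test_that("right-skewed article sets push simulated means above observed", {
  expect_equal(simulated_vs_observed(c(110, 220), c(100, 200)), 0.1)
  # symmetric triangulars: analytic mean equals the mode, difference ~ 0
  refs <- tiny_refs()
  corpus <- as_coi_corpus(dplyr::bind_rows(
    tiny_obs("epilepsy", h = 1000, study = "A"),
    tiny_obs("epilepsy", h = 3000, study = "B")))
  cfg <- coi_config(seed = 5, n_iter = 4000,
                    simulate_disorders = "epilepsy")
  sim <- simulate_costs(corpus, refs, cfg)
  expect_equal(sim$summary$sim_mean, 2000, tolerance = 0.02)
  # right-skewed: {1000, 1000, 7000} has mean 3000 < (1000 + 3000 + 7000)/3
  corpus2 <- as_coi_corpus(dplyr::bind_rows(
    tiny_obs("epilepsy", h = 1000, study = "A"),
    tiny_obs("epilepsy", h = 1000, study = "B"),
    tiny_obs("epilepsy", h = 7000, study = "C")))
  sim2 <- simulate_costs(corpus2, refs, cfg)
  expect_gt(sim2$rel_diff_vs_observed, 0)
  expect_equal(sim2$summary$sim_mean, (1000 + 3000 + 7000) / 3,
               tolerance = 0.03)
})

test_that("simulation of the bundled corpus tracks the pooled baseline", {
  sim <- run_simulate(coi_config(seed = 2024))
  expect_identical(nrow(sim$summary), 7L)  # one row per eligible disorder
  pk <- sim$summary[sim$summary$disorder_id == "parkinson", ]
  # non-medical is a symmetric two-article triangular, healthcare and
  # indirect are single-article constants: simulated mean ~ pooled total
  expect_equal(pk$sim_mean, 22992.5, tolerance = 0.005)
  expect_gt(sim$rel_diff_vs_observed, 0)
})
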