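#' Draw per-patient total samples for one disorder
#'
#' One independent draw per category component per iteration, summed (with
#' optional weights for subtype components). Degenerate components
#' contribute their constant.
#'
#' @param dists List of `coi_triangular` components (1–3 per category, or
#'   more when subtypes are weighted).
#' @param n_iter Number of iterations (>= 1).
#' @param seed Optional seed set before drawing.
#' @param weights Optional numeric vector of component weights (default all
#'   1, i.e. a plain sum across categories).
#' @return Numeric vector of length `n_iter`.
#' @export
sample_disorder <- function(dists, n_iter, seed = NULL, weights = NULL) {
  stopifnot(n_iter >= 1, length(dists) >= 1)
  if (is.null(weights)) weights <- rep(1, length(dists))
  stopifnot(length(weights) == length(dists))
  if (!is.null(seed)) set.seed(seed)
  draws <- vapply(dists, function(tri) {
    if (tri$degenerate) rep(tri$min, n_iter)
    else rtriangular(n_iter, tri$min, tri$mode, tri$max)
  }, numeric(n_iter))
  draws <- matrix(draws, nrow = n_iter)
  as.vector(draws %*% weights)
}

#' Summarise simulation samples
#'
#' Empirical mean and the central interval at the requested level, with
#' quantiles computed by linear interpolation of order statistics
#' (`stats::quantile()` type 7).
#'
#' @param samples Numeric vector.
#' @param level Central interval level in (0, 1), default 0.90.
#' @return Named numeric vector `(mean, lower, upper)`.
#' @export
summarize_samples <- function(samples, level = 0.90) {
  stopifnot(length(samples) >= 1, level > 0, level < 1)
  qs <- quantile(samples, probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                 names = FALSE, type = 7)
  c(mean = mean(samples), lower = qs[1], upper = qs[2])
}

#' Pooled per-iteration median across disorders
#'
#' For each iteration, the median of the disorders' per-patient totals; the
#' function reports its central interval and the fraction of iterations in
#' which that median exceeds a threshold.
#'
#' @param samples A matrix (iterations x disorders) or a list of
#'   equal-length sample vectors from >= 2 disorders.
#' @param threshold Per-patient cost threshold in EUR.
#' @param level Central interval level.
#' @return A list with `medians`, `interval` (named lower/upper),
#'   `exceedance` (probability in `[0, 1]`) and `threshold`.
#' @export
pooled_median_stats <- function(samples, threshold, level = 0.90) {
  if (is.list(samples)) {
    lens <- lengths(samples)
    if (length(unique(lens)) != 1) {
      abort("All disorders must have the same number of iterations",
            class = "coi_validation_error")
    }
    samples <- do.call(cbind, samples)
  }
  stopifnot(is.matrix(samples))
  if (ncol(samples) < 2) {
    abort("Pooled statistics need at least two disorders",
          class = "coi_validation_error")
  }
  med <- apply(samples, 1, median)
  qs <- quantile(med, probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                 names = FALSE, type = 7)
  list(medians = med,
       interval = c(lower = qs[1], upper = qs[2]),
       exceedance = mean(med > threshold),
       threshold = threshold)
}

#' Relative difference between simulated and observed per-patient costs
#'
#' `(mean of simulated means - mean of observed totals) / mean of observed
#' totals` over the simulated disorders. Positive when the fitted
#' triangulars are right-skewed (article maxima further from the mean than
#' the minima), since the triangular mean `(min + mode + max) / 3` then
#' exceeds the mode.
#'
#' @param simulated_means Numeric vector of simulated mean totals.
#' @param observed_totals Matching vector of pooled (baseline) totals.
#' @return A single relative difference.
#' @export
simulated_vs_observed <- function(simulated_means, observed_totals) {
  stopifnot(length(simulated_means) == length(observed_totals))
  (mean(simulated_means) - mean(observed_totals)) / mean(observed_totals)
}

# triangular components (per subtype x category for weighted disorders,
# per category otherwise); degenerate at the completed cell value where a
# cell has no article observations
disorder_components <- function(disorder, harmonized, refs, config,
                                completed) {
  w <- filter(refs$subtype_weights, .data$disorder_id == disorder)
  long <- corpus_long(pooled_rows(harmonized, config)) %>%
    filter(.data$disorder_id == disorder)
  cells <- filter(completed, .data$disorder_id == disorder)
  if (nrow(w)) {
    grid <- tidyr::crossing(w, category = cost_categories())
  } else {
    grid <- tidyr::crossing(tibble(subtype_id = NA_character_, weight = 1),
                            category = cost_categories())
  }
  purrr::pmap(grid[c("subtype_id", "weight", "category")],
              function(subtype_id, weight, category) {
    vals <- if (nrow(w)) {
      long$amount[long$subtype_id %in% subtype_id &
                    long$category == category]
    } else {
      long$amount[long$category == category]
    }
    sub_match <- if (is.na(subtype_id)) is.na(cells$subtype_id)
                 else cells$subtype_id %in% subtype_id
    cell <- cells[sub_match & cells$category == category, ]
    forced <- nrow(cell) && cell$provenance[1] %in% "forced_zero"
    tri <- if (length(vals) && !forced) {
      fit_triangular(vals, mode_stat = config$mode_stat)
    } else {
      degenerate_triangular(if (nrow(cell)) cell$amount[1] else 0)
    }
    list(weight = weight, tri = tri)
  })
}

#' Monte Carlo simulation of per-patient costs
#'
#' Propagates between-article uncertainty: for every eligible disorder and
#' cost category a triangular distribution is fitted to the harmonized
#' article values (bounds at the article extremes, most probable value at
#' the article mean); cells without multiple observations enter as
#' degenerate constants at their pooled/imputed baseline value, so the
#' simulated totals remain comparable to the baseline table. Draws are
#' independent across categories and disorders. The pooled statistic is the
#' per-iteration median of the eligible disorders' per-patient totals.
#'
#' @param corpus A `coi_corpus` (raw or harmonized).
#' @param refs A `coi_references` set.
#' @param config A [coi_config()]; uses `n_iter`, `seed`, `level`,
#'   `threshold`, `mode_stat` and `simulate_disorders`.
#' @return A list of class `coi_simulation`: `samples` (n_iter x disorders
#'   matrix), `summary` (per-disorder mean and interval bounds plus the
#'   baseline total), `pooled` (see [pooled_median_stats()]),
#'   `rel_diff_vs_observed`, `n_iter`, `seed`, `level`.
#' @export
simulate_costs <- function(corpus, refs, config = NULL) {
  config <- as_coi_config(config)
  h <- ensure_harmonized(corpus, refs, config)
  observed <- observed_cell_means(h, refs, config)
  completed <- impute_missing(observed, refs, config)
  baseline <- per_patient_from_long(
    combine_subtypes(completed, refs$subtype_weights), h, refs, config)
  eligible <- intersect(config$simulate_disorders, baseline$disorder_id)
  if (length(eligible) < 1) {
    abort("No eligible disorders to simulate", class = "coi_config_error")
  }
  set.seed(config$seed)
  samples <- vapply(eligible, function(d) {
    comp <- disorder_components(d, h, refs, config, completed)
    sample_disorder(purrr::map(comp, "tri"), config$n_iter,
                    weights = purrr::map_dbl(comp, "weight"))
  }, numeric(config$n_iter))
  samples <- matrix(samples, nrow = config$n_iter,
                    dimnames = list(NULL, eligible))
  sums <- t(apply(samples, 2, summarize_samples, level = config$level))
  obs_totals <- baseline$total[match(eligible, baseline$disorder_id)]
  summary_tbl <- tibble(
    disorder_id = eligible,
    sim_mean = unname(sums[, "mean"]), lower = unname(sums[, "lower"]),
    upper = unname(sums[, "upper"]), observed_total = obs_totals)
  pooled <- if (length(eligible) >= 2) {
    pooled_median_stats(samples, threshold = config$threshold,
                        level = config$level)
  } else NULL
  structure(
    list(samples = samples, summary = summary_tbl, pooled = pooled,
         rel_diff_vs_observed = simulated_vs_observed(summary_tbl$sim_mean,
                                                      obs_totals),
         n_iter = config$n_iter, seed = config$seed, level = config$level),
    class = "coi_simulation")
}

#' @export
print.coi_simulation <- function(x, ...) {
  cat("<coi_simulation> ", x$n_iter, " iterations, seed ", x$seed, ", ",
      round(100 * x$level), "% intervals\n", sep = "")
  print(x$summary)
  if (!is.null(x$pooled)) {
    cat(sprintf("pooled median interval: %.0f - %.0f EUR;  P(median > %.0f) = %.3f\n",
                x$pooled$interval["lower"], x$pooled$interval["upper"],
                x$pooled$threshold, x$pooled$exceedance))
  }
  cat(sprintf("simulated vs observed: %+.1f%%\n",
              100 * x$rel_diff_vs_observed))
  invisible(x)
}
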