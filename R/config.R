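#' Analysis configuration
#'
#' Collects the tunable switches of the pipeline in one validated object.
#' Defaults reproduce the reference analysis: costs restated at 2010 prices,
#' incidence-based observations excluded from pooling, European-median
#' imputation on, triangular mode at the article mean, 1000 simulation
#' iterations summarised at the 90% level.
#'
#' @param target_year Calendar year whose price level all costs are restated
#'   to. Must be covered by the CPI series.
#' @param include_incidence Include observations whose costs are incidence
#'   (not prevalence) based in the pooled means? Default `FALSE`.
#' @param impute Impute missing disorder/category cells from the European
#'   medians? When `FALSE`, unobserved cells are zero (with a warning
#'   downstream).
#' @param n_iter Monte Carlo iterations (>= 1).
#' @param seed Integer seed for all simulation randomness.
#' @param level Central interval level for simulation summaries, in (0, 1).
#' @param threshold Per-patient cost threshold (EUR) for the pooled
#'   exceedance probability.
#' @param mode_stat Statistic used as the most probable value of the fitted
#'   triangular distributions: `"mean"` (default) or `"median"` of the
#'   article values.
#' @param simulate_disorders Disorders eligible for simulation; defaults to
#'   the seven with more than one pooled article.
#' @param year_range Admissible costing years for corpus validation.
#' @param output_dir Optional directory where `run_*()` functions write their
#'   result tables and manifest.
#'
#' @return A list of class `coi_config`.
#' @export
coi_config <- function(target_year = 2010,
                       include_incidence = FALSE,
                       impute = TRUE,
                       n_iter = 1000,
                       seed = 1L,
                       level = 0.90,
                       threshold = 3000,
                       mode_stat = c("mean", "median"),
                       simulate_disorders = default_simulation_disorders(),
                       year_range = c(1995L, 2012L),
                       output_dir = NULL) {
  mode_stat <- match.arg(mode_stat)
  stopifnot(n_iter >= 1, level > 0, level < 1, threshold >= 0,
            length(year_range) == 2, year_range[1] <= year_range[2])
  structure(
    list(target_year = as.integer(target_year),
         include_incidence = isTRUE(include_incidence),
         impute = isTRUE(impute),
         n_iter = as.integer(n_iter),
         seed = as.integer(seed),
         level = level,
         threshold = threshold,
         mode_stat = mode_stat,
         simulate_disorders = simulate_disorders,
         year_range = as.integer(year_range),
         output_dir = output_dir),
    class = "coi_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Keys mirror the arguments of [coi_config()]; unknown keys are rejected.
#' Two extra keys, `corpus` and `references`, may carry input paths and are
#' returned as attributes for the command-line wrapper.
#'
#' @param path Path to a YAML file.
#' @return A `coi_config` object.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  paths <- raw[intersect(names(raw), c("corpus", "references"))]
  raw <- raw[setdiff(names(raw), c("corpus", "references"))]
  known <- names(formals(coi_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    abort(paste0("Unknown configuration keys: ", paste(bad, collapse = ", ")),
          class = "coi_config_error")
  }
  cfg <- do.call(coi_config, raw)
  attr(cfg, "paths") <- paths
  cfg
}

as_coi_config <- function(config) {
  if (is.null(config)) return(coi_config())
  if (inherits(config, "coi_config")) return(config)
  abort("`config` must be NULL or a coi_config object", class = "coi_config_error")
}
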