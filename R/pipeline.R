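resolve_corpus <- function(corpus) {
  if (is.null(corpus)) return(bundled_corpus())
  if (is.character(corpus)) return(read_corpus(corpus))
  if (inherits(corpus, "coi_corpus")) return(corpus)
  as_coi_corpus(corpus)
}

resolve_references <- function(references) {
  if (is.null(references)) return(bundled_references())
  if (inherits(references, "coi_references")) return(references)
  if (is.character(references) && length(references) == 1 &&
      dir.exists(references)) {
    p <- function(f) file.path(references, f)
    sw <- if (file.exists(p("subtype_weights.csv"))) p("subtype_weights.csv")
    return(suppressMessages(read_references(
      cpi = p("cpi_es.csv"), fx = p("fx.csv"),
      eu_medians = p("eu_medians.csv"), prevalence = p("prevalence.csv"),
      disorders = p("disorders.csv"), subtype_weights = sw,
      population = default_population())))
  }
  abort("`references` must be NULL, a coi_references object or a directory",
        class = "coi_config_error")
}

run_manifest <- function(config, corpus, refs, stage) {
  list(package = "braincost",
       version = as.character(utils::packageVersion("braincost")),
       stage = stage,
       config = config[setdiff(names(config), "output_dir")],
       corpus_hash = rlang::hash(as_tibble(corpus)),
       references_hash = rlang::hash(unclass(refs)),
       n_observations = nrow(corpus))
}

write_output <- function(x, dir, file) {
  if (is.null(dir)) return(invisible(NULL))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, file)
  if (is.data.frame(x)) {
    readr::write_csv(as_tibble(x), path, na = "")
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Run the full cost estimation
#'
#' End-to-end composition: read/validate inputs, harmonize to EUR at the
#' target-year price level, pool un-weighted category means, impute missing
#' cells, scale by patient counts, and roll the societal costs up by
#' diagnostic group and cost type. Categories that remain zero because no
#' estimate exists anywhere (`unavailable_zero`) are reported with a
#' warning — they understate the true totals.
#'
#' @param config A [coi_config()] (or `NULL` for defaults).
#' @param corpus A `coi_corpus`, a CSV path, or `NULL` for the bundled
#'   Spanish corpus.
#' @param references A `coi_references`, a directory of reference CSVs, or
#'   `NULL` for the bundled set.
#' @return A list of class `coi_estimate` with `per_patient`, `societal`,
#'   `rollup` (`NULL` when the corpus does not cover all 19 disorders) and
#'   a deterministic run `manifest`. When `config$output_dir` is set, the
#'   tables are written there as CSV plus `manifest.json`, at full
#'   precision, schema-stable, and byte-identical across reruns with the
#'   same inputs.
#' @export
run_estimate <- function(config = NULL, corpus = NULL, references = NULL) {
  config <- as_coi_config(config)
  corpus <- resolve_corpus(corpus)
  refs <- resolve_references(references)
  check_reference_coverage(corpus, refs, config$target_year)
  pp <- per_patient_costs(corpus, refs, config)
  unavailable <- purrr::map(cost_categories(), function(cc) {
    pp$disorder_id[pp[[paste0("prov_", cc)]] == "unavailable_zero"]
  })
  names(unavailable) <- cost_categories()
  unavailable <- purrr::compact(purrr::map(unavailable, unique))
  unavailable <- unavailable[lengths(unavailable) > 0]
  if (length(unavailable)) {
    warn(c("No estimate anywhere for some categories; counted as zero (totals understated):",
           setNames(purrr::imap_chr(unavailable, ~ paste0(
             .y, ": ", paste(.x, collapse = ", "))),
             rep("!", length(unavailable)))),
         class = "coi_unavailable_warning")
  }
  soc <- societal_cost(pp, refs)
  roll <- if (all(brain_disorders()$disorder_id %in% soc$disorder_id)) {
    rollup(soc, refs)
  } else {
    message("corpus does not cover all 19 disorders; rollup skipped")
    NULL
  }
  out <- structure(
    list(per_patient = pp, societal = soc, rollup = roll,
         manifest = run_manifest(config, corpus, refs, "estimate")),
    class = "coi_estimate")
  write_output(pp, config$output_dir, "per_patient.csv")
  write_output(soc, config$output_dir, "societal.csv")
  if (!is.null(roll)) {
    write_output(roll$groups, config$output_dir, "rollup_groups.csv")
    write_output(roll$shares, config$output_dir, "rollup_shares.csv")
  }
  write_output(out$manifest, config$output_dir, "manifest.json")
  out
}

#' @export
print.coi_estimate <- function(x, ...) {
  cat("<coi_estimate>\n")
  print(x$societal)
  if (!is.null(x$rollup)) print(x$rollup)
  invisible(x)
}

#' Run the Monte Carlo simulation
#'
#' Seeded triangular simulation of per-patient totals for the eligible
#' disorders (see [simulate_costs()]); writes a per-disorder summary table
#' and the pooled statistics when an output directory is configured.
#'
#' @inheritParams run_estimate
#' @return A `coi_simulation` (with the run manifest attached as
#'   `manifest`).
#' @export
run_simulate <- function(config = NULL, corpus = NULL, references = NULL) {
  config <- as_coi_config(config)
  corpus <- resolve_corpus(corpus)
  refs <- resolve_references(references)
  check_reference_coverage(corpus, refs, config$target_year)
  sim <- simulate_costs(corpus, refs, config)
  sim$manifest <- run_manifest(config, corpus, refs, "simulate")
  write_output(sim$summary, config$output_dir, "simulation_summary.csv")
  if (!is.null(sim$pooled)) {
    write_output(list(interval = as.list(sim$pooled$interval),
                      exceedance = sim$pooled$exceedance,
                      threshold = sim$pooled$threshold,
                      rel_diff_vs_observed = sim$rel_diff_vs_observed,
                      n_iter = sim$n_iter, seed = sim$seed),
                 config$output_dir, "pooled_stats.json")
  }
  write_output(sim$manifest, config$output_dir, "manifest_simulate.json")
  sim
}

#' Run the quality-restricted sensitivity analysis
#'
#' @inheritParams run_estimate
#' @return A `coi_sensitivity` (with `manifest` attached); the delta table
#'   is written as `sensitivity.csv` when an output directory is
#'   configured.
#' @export
run_sensitivity <- function(config = NULL, corpus = NULL, references = NULL) {
  config <- as_coi_config(config)
  corpus <- resolve_corpus(corpus)
  refs <- resolve_references(references)
  check_reference_coverage(corpus, refs, config$target_year)
  sens <- quality_sensitivity(corpus, refs, config)
  sens$manifest <- run_manifest(config, corpus, refs, "sensitivity")
  write_output(sens$by_disorder, config$output_dir, "sensitivity.csv")
  write_output(sens$manifest, config$output_dir, "manifest_sensitivity.json")
  sens
}
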