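#' Controlled vocabulary of the 19 brain disorders
#'
#' The diagnostic groups covered by the costing model: 10 mental and 9
#' neurological/neurosurgical disorders. All corpus and reference tables key
#' on `disorder_id`.
#'
#' @return A tibble with columns `disorder_id`, `label` and `group`
#'   (`"mental"` or `"neurological"`).
#' @examples
#' brain_disorders()
#' @export
brain_disorders <- function() {
  tibble::tribble(
    ~disorder_id, ~label, ~group,
    "addiction",               "Addiction",                      "mental",
    "anxiety",                 "Anxiety disorders",              "mental",
    "child_adolescent",        "Childhood/adolescence disorders","mental",
    "eating",                  "Eating disorders",               "mental",
    "intellectual_disability", "Intellectual disability",        "mental",
    "mood",                    "Mood disorders",                 "mental",
    "personality",             "Personality disorders",          "mental",
    "psychotic",               "Psychotic disorders",            "mental",
    "sleep",                   "Sleep disorders",                "mental",
    "somatoform",              "Somatoform disorders",           "mental",
    "brain_tumor",             "Brain tumor",                    "neurological",
    "dementia",                "Dementia",                       "neurological",
    "epilepsy",                "Epilepsy",                       "neurological",
    "headache",                "Headache",                       "neurological",
    "multiple_sclerosis",      "Multiple sclerosis",             "neurological",
    "neuromuscular",           "Neuromuscular disorders",        "neurological",
    "parkinson",               "Parkinson's disease",            "neurological",
    "stroke",                  "Stroke",                         "neurological",
    "tbi",                     "Traumatic brain injury",         "neurological")
}

# cost categories, in fixed reporting order
cost_categories <- function() c("healthcare", "nonmedical", "indirect")

cost_columns <- function() paste0("cost_", cost_categories())

#' @keywords internal
default_population <- function() 46e6

# default simulation eligibility: disorders with more than one pooled article
default_simulation_disorders <- function() {
  c("dementia", "epilepsy", "headache", "mood", "multiple_sclerosis",
    "parkinson", "stroke")
}
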