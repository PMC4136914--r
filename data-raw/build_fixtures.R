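# Builds inst/extdata fixtures and prints oracle values for tests.
# Run from repo root: Rscript data-raw/build_fixtures.R
suppressPackageStartupMessages({library(dplyr); library(tidyr); library(readr); library(tibble)})

out <- "inst/extdata"

## ---- Spanish all-items CPI, annual averages (INE), rebased 2010 = 100 ----
infl <- c(`1996` = 3.6, `1997` = 2.0, `1998` = 1.8, `1999` = 2.3, `2000` = 3.4,
          `2001` = 3.6, `2002` = 3.5, `2003` = 3.0, `2004` = 3.0, `2005` = 3.4,
          `2006` = 3.5, `2007` = 2.8, `2008` = 4.1, `2009` = -0.3, `2010` = 1.8,
          `2011` = 3.2, `2012` = 2.4)
years <- 1995:2012
idx <- numeric(length(years)); names(idx) <- years
idx["1995"] <- 1
for (y in 1996:2012) idx[as.character(y)] <- idx[as.character(y - 1)] * (1 + infl[as.character(y)] / 100)
idx <- idx / idx["2010"] * 100
cpi <- tibble(year = years, index = round(unname(idx), 6))
write_csv(cpi, file.path(out, "cpi_es.csv"))

cpi_f <- function(from, to = 2010) idx[as.character(to)] / idx[as.character(from)]

## ---- ECB annual average exchange rates (units of currency per EUR -> eur_per_unit) ----
usd_per_eur <- c(`2004` = 1.2439, `2005` = 1.2441, `2006` = 1.2556, `2007` = 1.3705,
                 `2008` = 1.4708, `2009` = 1.3948, `2010` = 1.3257)
gbp_per_eur <- c(`2004` = 0.67866, `2005` = 0.68380, `2006` = 0.68173, `2007` = 0.68434,
                 `2008` = 0.79628, `2009` = 0.89094, `2010` = 0.85784)
fx <- bind_rows(
  tibble(currency = "USD", year = as.integer(names(usd_per_eur)), eur_per_unit = round(1 / usd_per_eur, 6)),
  tibble(currency = "GBP", year = as.integer(names(gbp_per_eur)), eur_per_unit = round(1 / gbp_per_eur, 6)))
write_csv(fx, file.path(out, "fx.csv"))

fx_rate <- function(cur, yr) {
  if (cur == "EUR") return(1)
  fx$eur_per_unit[fx$currency == cur & fx$year == yr]
}

## ---- Corpus (the published article inventory, amounts exactly as printed) ----
r <- function(study, dis, sub, yr, cur, h, nm, ind, basis = "prevalence",
              hq = FALSE, excl = FALSE)
  tibble(study_id = study, disorder_id = dis, subtype_id = sub, costing_year = yr,
         currency = cur, cost_healthcare = h, cost_nonmedical = nm, cost_indirect = ind,
         basis = basis, indirect_basis = "working_age", quality_high = hq,
         excluded_outlier = excl)

corpus <- bind_rows(
  r("Rovira 2012",          "anxiety",   "gad",       2006, "EUR", 1206,  162,  4451),
  r("Coduras 2010",         "dementia",  "alzheimer", 2006, "EUR", 4272, 12708,   NA, hq = TRUE),
  r("Lopez-Bastida 2006",   "dementia",  "alzheimer", 2001, "EUR", 3289, 24281,  628, hq = TRUE),
  r("Lopez-Pousa 2004",     "dementia",  "alzheimer", 2001, "EUR",   NA,    NA, 6649),
  r("Sicras 2005",          "dementia",  "alzheimer", 2003, "EUR", 5706, 15444,   NA),
  r("Turro-Garriga 2010",   "dementia",  "alzheimer", 2006, "EUR", 8212,    NA,   NA),
  r("Gustavsson 2011",      "dementia",  "alzheimer", 2007, "GBP", 4189, 18504,   NA),
  r("Sicras 2005",          "dementia",  "vascular",  2003, "EUR", 6090, 20034,   NA),
  r("Oliva 2007",           "dementia",  "alzheimer", 2002, "EUR",   NA, 11110,   NA, hq = TRUE),
  r("Wimo 2007",            "dementia",  "alzheimer", 2005, "USD", 6219, 14989,   NA),
  r("Sancho 2008",          "epilepsy",  NA,          2005, "EUR", 4982,  255,  1618, hq = TRUE),
  r("Villanueva 2012",      "epilepsy",  NA,          2010, "EUR", 3843,  951,    NA, hq = TRUE),
  r("Badia 2004",           "headache",  "migraine",  2001, "EUR",  198,   NA,    54, hq = TRUE),
  r("Bloudek 2012",         "headache",  "migraine",  2010, "EUR", 1217,   NA,    NA),
  r("Linde 2012",           "headache",  "migraine",  2010, "EUR",  130,   NA,   257, hq = TRUE),
  r("Linde 2012",           "headache",  "tension_type", 2010, "EUR", 19,  NA,    26, hq = TRUE),
  r("Linde 2012",           "headache",  "medication_overuse", 2010, "EUR", 404, NA, 873, hq = TRUE),
  r("Linde 2012",           "headache",  "other_headache", 2010, "EUR", 22, NA,    0, hq = TRUE),
  r("Salvador-Carulla 2011","mood",      "unipolar",  2006, "EUR", 4002,   NA,  1346, hq = TRUE),
  r("Sicras-Mainar 2012",   "mood",      "unipolar",  2009, "EUR",  620,   NA,  1275),
  r("Sicras-Mainar 2010",   "mood",      "unipolar",  2006, "EUR", 1579,   NA,  1810),
  r("Serna 2007",           "mood",      "unipolar",  2004, "EUR",  335,   NA,   268),
  r("Gonzalez-Pinto 2010",  "mood",      "bipolar",   2003, "EUR",  283,   NA,    NA),
  r("Kobelt 2006",          "multiple_sclerosis", NA, 2005, "EUR", 12142, 12540, 8145, hq = TRUE),
  r("Arroyo 2011",          "multiple_sclerosis", NA, 2009, "EUR",  9895,  5510,   NA),
  r("Casado 2006",          "multiple_sclerosis", NA, 2004, "EUR",  7775, 21297, 16618, hq = TRUE),
  r("Karampampa 2012",      "multiple_sclerosis", NA, 2009, "EUR", 15958,  5235,  7732, hq = TRUE),
  r("Cubo 2009",            "parkinson", NA,          2004, "EUR",  7380,  3817,  8235),
  r("Oliva 2007",           "parkinson", NA,          2002, "EUR",    NA,  4255,    NA, hq = TRUE),
  r("Olivares 2008",        "psychotic", NA,          2005, "EUR",  5569,    NA,    NA),
  r("Vazquez-Polo 2005",    "psychotic", NA,          1999, "EUR",  3989,    NA,    NA),
  r("Beguiristain 2005",    "stroke",    NA,          2002, "EUR",  5048,    NA,    NA, hq = TRUE),
  r("Hervas-Angulo 2006",   "stroke",    NA,          2004, "EUR",  2271,  1863,   426, hq = TRUE),
  r("Mar 2011",             "stroke",    NA,          2008, "EUR", 16341, 10932,    NA, excl = TRUE),
  r("Sicras 2008",          "stroke",    NA,          2006, "EUR",  1591,    NA,    NA),
  r("Oliva 2007",           "stroke",    NA,          2002, "EUR",    NA,  4478,    NA, hq = TRUE),
  r("Hervas 2007",          "stroke",    NA,          2004, "EUR",    NA, 21551,    NA, excl = TRUE),
  r("Navarrete-Navarro 2007","stroke",   NA,          2004, "EUR",  1425,  5537,   741, hq = TRUE),
  r("Hervas-Angulo 2006",   "stroke",    NA,          2004, "EUR",  4470,  1289,   572, basis = "incidence", hq = TRUE),
  r("Navarrete-Navarro 2007","stroke",   NA,          2004, "EUR",  5173,  6420,  2347, basis = "incidence", hq = TRUE),
  r("Lopez-Bastida 2009",   "neuromuscular", "als",   2004, "EUR",  8018, 19602,  8575, hq = TRUE),
  r("Mar 2011",             "tbi",       NA,          2008, "EUR", 11109,  8914,    NA, excl = TRUE))
stopifnot(nrow(corpus) == 42L)
write_csv(corpus, file.path(out, "corpus_es.csv"))

## ---- Prevalence (published patient counts) and disorder config ----
prev <- tribble(
  ~disorder_id, ~n_patients,
  "addiction",      1437560, "anxiety",   6238499, "brain_tumor",   20695,
  "child_adolescent", 480074, "dementia",  608711, "eating",       131049,
  "epilepsy",        225346, "headache", 13909125, "intellectual_disability", 376777,
  "mood",           3002725, "multiple_sclerosis", 36193, "neuromuscular", 23003,
  "parkinson",        79789, "personality", 396532, "psychotic",    453650,
  "sleep",          4072265, "somatoform", 1852405, "stroke",       644025,
  "tbi",             335260) |>
  mutate(working_age_fraction = 1)
write_csv(prev, file.path(out, "prevalence.csv"))

mental <- c("addiction", "anxiety", "child_adolescent", "eating", "intellectual_disability",
            "mood", "personality", "psychotic", "sleep", "somatoform")
disorders <- prev |>
  transmute(disorder_id,
            group = ifelse(disorder_id %in% mental, "mental", "neurological"),
            indirect_forced_zero = disorder_id %in% c("dementia", "child_adolescent"))
write_csv(disorders, file.path(out, "disorders.csv"))

## ---- Harmonize observed rows (convert at costing-year rate, then Spanish CPI) ----
h <- corpus |>
  rowwise() |>
  mutate(across(starts_with("cost_"),
                ~ .x * fx_rate(currency, costing_year) * cpi_f(costing_year))) |>
  ungroup()

cat_mean <- function(dis, cat, sub = NULL, data = h, incl_incidence = FALSE) {
  d <- data |> filter(disorder_id == dis, !excluded_outlier)
  if (!incl_incidence) d <- d |> filter(basis == "prevalence")
  if (!is.null(sub)) d <- d |> filter(subtype_id == sub)
  v <- d[[paste0("cost_", cat)]]
  v <- v[!is.na(v)]
  if (!length(v)) return(NA_real_)
  mean(v)
}

## Published per-patient values (targets for back-solving unprinted inputs)
t3 <- tribble(
  ~disorder_id, ~hc, ~nm, ~ind,
  "addiction", 1335, 867, 1315, "anxiety", 689, 24, 948, "brain_tumor", 12428, 0, 6826,
  "child_adolescent", 392, 3021, 0, "dementia", 5830, 19473, 0, "eating", 364, 45, 90,
  "epilepsy", 4734, 619, 1827, "headache", 233, 0, 168, "intellectual_disability", 6409, 3203, 0,
  "mood", 1514, 469, 1601, "multiple_sclerosis", 12291, 12495, 12160,
  "neuromuscular", 4605, 3227, 14185, "parkinson", 8614, 4866, 9612,
  "personality", 697, 583, 3979, "psychotic", 5870, 0, 11705, "sleep", 396, 0, 284,
  "somatoform", 426, 0, 465, "stroke", 3461, 9032, 835, "tbi", 2412, 830, 4183)

## ---- Back-solve subtype weights + reconstructed medians ----
# anxiety: GAD observed; choose w_gad so the weighted non-medical matches the printed 24
# with the non-GAD median at 0 (no non-medical estimate outside the GAD article).
gad <- c(hc = cat_mean("anxiety", "healthcare", "gad"),
         nm = cat_mean("anxiety", "nonmedical", "gad"),
         ind = cat_mean("anxiety", "indirect", "gad"))
w_gad <- 24 / gad[["nm"]]
anx_other <- c(hc = (689 - w_gad * gad[["hc"]]) / (1 - w_gad), nm = 0,
               ind = (948 - w_gad * gad[["ind"]]) / (1 - w_gad))

# mood: unipolar means observed for hc/ind; bipolar hc observed; back-solve the bipolar
# weight from the printed healthcare value, then the bipolar indirect median.
uni <- c(hc = cat_mean("mood", "healthcare", "unipolar"),
         ind = cat_mean("mood", "indirect", "unipolar"))
bip_hc <- cat_mean("mood", "healthcare", "bipolar")
w_bip <- (uni[["hc"]] - 1514) / (uni[["hc"]] - bip_hc)
bip_ind <- (1601 - (1 - w_bip) * uni[["ind"]]) / w_bip
mood_nm <- 469  # printed disorder-level imputation, same median for both subtypes

# headache: four subtypes; fix the 'other headaches' share at 0.02 and solve the
# remaining two equations (printed hc 233, ind 168) for migraine/tension/MOH shares.
mig <- c(hc = cat_mean("headache", "healthcare", "migraine"),
         ind = cat_mean("headache", "indirect", "migraine"))
ten <- c(hc = cat_mean("headache", "healthcare", "tension_type"),
         ind = cat_mean("headache", "indirect", "tension_type"))
moh <- c(hc = cat_mean("headache", "healthcare", "medication_overuse"),
         ind = cat_mean("headache", "indirect", "medication_overuse"))
oth <- c(hc = cat_mean("headache", "healthcare", "other_headache"),
         ind = cat_mean("headache", "indirect", "other_headache"))
w_oth <- 0.02
A <- rbind(c(mig[["hc"]] - ten[["hc"]], moh[["hc"]] - ten[["hc"]]),
           c(mig[["ind"]] - ten[["ind"]], moh[["ind"]] - ten[["ind"]]))
b <- c(233 - w_oth * oth[["hc"]] - (1 - w_oth) * ten[["hc"]],
       168 - w_oth * oth[["ind"]] - (1 - w_oth) * ten[["ind"]])
wm <- solve(A, b)
w_head <- c(migraine = wm[1], medication_overuse = wm[2],
            tension_type = 1 - w_oth - sum(wm), other_headache = w_oth)
stopifnot(all(w_head > 0))

# neuromuscular: ALS observed; ALS share fixed at 0.10 (rare disease); solve the
# non-ALS medians from the printed disorder-level values.
als <- c(hc = cat_mean("neuromuscular", "healthcare", "als"),
         nm = cat_mean("neuromuscular", "nonmedical", "als"),
         ind = cat_mean("neuromuscular", "indirect", "als"))
w_als <- 0.10
nmd_other <- (c(hc = 4605, nm = 3227, ind = 14185) - w_als * als) / (1 - w_als)

subw <- bind_rows(
  tibble(disorder_id = "anxiety", subtype_id = c("gad", "other_anxiety"),
         weight = c(w_gad, 1 - w_gad)),
  tibble(disorder_id = "mood", subtype_id = c("unipolar", "bipolar"),
         weight = c(1 - w_bip, w_bip)),
  tibble(disorder_id = "headache",
         subtype_id = c("migraine", "tension_type", "medication_overuse", "other_headache"),
         weight = unname(w_head[c("migraine", "tension_type", "medication_overuse", "other_headache")])),
  tibble(disorder_id = "neuromuscular", subtype_id = c("als", "other_nmd"),
         weight = c(w_als, 1 - w_als))) |>
  mutate(weight = round(weight, 8))
write_csv(subw, file.path(out, "subtype_weights.csv"))

## ---- European medians: printed imputations + reconstructed subtype-level stand-ins ----
med <- function(dis, sub, cat, amt, src)
  tibble(disorder_id = dis, subtype_id = sub, category = cat,
         amount_eur2010 = round(amt, 4), source = src)
full_imp <- c("addiction", "brain_tumor", "child_adolescent", "eating",
              "intellectual_disability", "personality", "sleep", "somatoform", "tbi")
eu <- bind_rows(lapply(full_imp, function(d) {
  row <- t3[t3$disorder_id == d, ]
  keep <- list()
  # published zeros for these disorders mean "no estimate anywhere" (unavailable) or
  # forced-zero indirect; neither is a median -> only positive cells are medians here
  if (row$hc > 0) keep <- c(keep, list(med(d, NA, "healthcare", row$hc, "printed")))
  if (row$nm > 0) keep <- c(keep, list(med(d, NA, "nonmedical", row$nm, "printed")))
  if (row$ind > 0 && !d %in% c("child_adolescent")) keep <- c(keep, list(med(d, NA, "indirect", row$ind, "printed")))
  bind_rows(keep)
}))
eu <- bind_rows(
  eu,
  med("psychotic", NA, "indirect", 11705, "printed"),
  med("anxiety", "other_anxiety", "healthcare", anx_other[["hc"]], "reconstructed"),
  med("anxiety", "other_anxiety", "indirect", anx_other[["ind"]], "reconstructed"),
  med("mood", "unipolar", "nonmedical", mood_nm, "printed"),
  med("mood", "bipolar", "nonmedical", mood_nm, "printed"),
  med("mood", "bipolar", "indirect", bip_ind, "reconstructed"),
  med("neuromuscular", "other_nmd", "healthcare", nmd_other[["hc"]], "reconstructed"),
  med("neuromuscular", "other_nmd", "nonmedical", nmd_other[["nm"]], "reconstructed"),
  med("neuromuscular", "other_nmd", "indirect", nmd_other[["ind"]], "reconstructed"))
write_csv(eu, file.path(out, "eu_medians.csv"))

## ---- Published per-patient comparison table ----
pub <- t3 |> left_join(prev |> select(disorder_id, n_patients), by = "disorder_id") |>
  select(disorder_id, n_patients, cost_healthcare = hc, cost_nonmedical = nm, cost_indirect = ind)
write_csv(pub, file.path(out, "published_per_patient_2010.csv"))

## ================= ORACLE VALUES (frozen into tests) =================
fmt <- function(x) formatC(x, format = "f", digits = 4)
cat("\n--- CPI factors ---\n")
for (y in c(1999, 2001:2009)) cat(y, "->2010:", fmt(cpi_f(y)), "\n")
cat("USD2005 eur_per_unit:", fx_rate("USD", 2005), " GBP2007:", fx_rate("GBP", 2007), "\n")
cat("Wimo 21208 USD 2005 -> EUR2010:", fmt(21208 * fx_rate("USD", 2005) * cpi_f(2005)), "\n")
cat("Wimo 21208 USD 2005 -> EUR same-year:", fmt(21208 * fx_rate("USD", 2005)), "\n")

cat("\n--- Pooled (unweighted) per-patient means, EUR-2010 ---\n")
for (d in c("dementia", "epilepsy", "multiple_sclerosis", "parkinson", "psychotic", "stroke")) {
  v <- c(cat_mean(d, "healthcare"), cat_mean(d, "nonmedical"), cat_mean(d, "indirect"))
  cat(sprintf("%-20s hc %10s nm %10s ind %10s\n", d, fmt(v[1]), fmt(v[2]), fmt(v[3])))
}
cat("epilepsy total:", fmt(cat_mean("epilepsy", "healthcare") + cat_mean("epilepsy", "nonmedical") +
                          cat_mean("epilepsy", "indirect")), "\n")

cat("\n--- Back-solved weights/medians ---\n")
cat("w_gad:", w_gad, " anx_other:", paste(fmt(anx_other), collapse = "/"), "\n")
cat("w_bip:", w_bip, " bip_ind:", fmt(bip_ind), " uni hc/ind:", fmt(uni[["hc"]]), fmt(uni[["ind"]]), "\n")
cat("headache weights:", paste(names(w_head), fmt(w_head), collapse = " "), "\n")
cat("nmd_other:", paste(fmt(nmd_other), collapse = "/"), "\n")

## Full pipeline by hand -> per-disorder per-patient + societal (€ million)
per_pat <- t3 |> select(disorder_id) |> rowwise() |> mutate(hc = NA_real_, nm = NA_real_, ind = NA_real_) |> ungroup()
setpp <- function(d, v) { per_pat[per_pat$disorder_id == d, c("hc","nm","ind")] <<- as.list(v) }
for (d in full_imp) {
  row <- t3[t3$disorder_id == d, ]
  setpp(d, c(row$hc, row$nm, row$ind))
}
setpp("anxiety", w_gad * gad + (1 - w_gad) * anx_other)
setpp("mood", c((1 - w_bip) * uni[["hc"]] + w_bip * bip_hc,
                mood_nm,
                (1 - w_bip) * uni[["ind"]] + w_bip * bip_ind))
hw <- w_head
setpp("headache", c(hw[["migraine"]] * mig[["hc"]] + hw[["tension_type"]] * ten[["hc"]] +
                      hw[["medication_overuse"]] * moh[["hc"]] + hw[["other_headache"]] * oth[["hc"]],
                    0,
                    hw[["migraine"]] * mig[["ind"]] + hw[["tension_type"]] * ten[["ind"]] +
                      hw[["medication_overuse"]] * moh[["ind"]] + hw[["other_headache"]] * oth[["ind"]]))
setpp("neuromuscular", w_als * als + (1 - w_als) * nmd_other)
setpp("dementia", c(cat_mean("dementia", "healthcare"), cat_mean("dementia", "nonmedical"), 0))
setpp("epilepsy", c(cat_mean("epilepsy", "healthcare"), cat_mean("epilepsy", "nonmedical"), cat_mean("epilepsy", "indirect")))
setpp("multiple_sclerosis", c(cat_mean("multiple_sclerosis", "healthcare"), cat_mean("multiple_sclerosis", "nonmedical"), cat_mean("multiple_sclerosis", "indirect")))
setpp("parkinson", c(cat_mean("parkinson", "healthcare"), cat_mean("parkinson", "nonmedical"), cat_mean("parkinson", "indirect")))
setpp("psychotic", c(cat_mean("psychotic", "healthcare"), 0, 11705))
setpp("stroke", c(cat_mean("stroke", "healthcare"), cat_mean("stroke", "nonmedical"), cat_mean("stroke", "indirect")))

res <- per_pat |> left_join(prev, by = "disorder_id") |>
  mutate(total = hc + nm + ind, societal = total * n_patients / 1e6)
cat("\n--- Pipeline per-patient totals and societal (EUR million) ---\n")
print(res |> mutate(across(where(is.numeric), ~round(.x, 2))), n = 25)
cat("GRAND TOTAL (pipeline):", fmt(sum(res$societal)), " vs printed 83,749;  rel diff ",
    fmt(100 * (sum(res$societal) / 83749 - 1)), "%\n")

## Criterion-1 arithmetic from printed values
pub2 <- t3 |> left_join(prev, by = "disorder_id") |>
  mutate(total = hc + nm + ind, societal = total * n_patients / 1e6,
         group = ifelse(disorder_id %in% mental, "mental", "neurological"))
cat("\n--- Printed-value arithmetic ---\n")
cat("grand total:", fmt(sum(pub2$societal)), "\n")
gm <- pub2 |> group_by(group) |> summarise(soc = sum(societal), n = sum(n_patients), mean_pp = 1e6 * soc / n)
print(gm)
neh <- pub2 |> filter(group == "neurological", disorder_id != "headache")
cat("neuro excl headache mean pp:", fmt(1e6 * sum(neh$societal) / sum(neh$n_patients)), "\n")
cat("overall mean pp:", fmt(1e6 * sum(pub2$societal) / sum(pub2$n_patients)), "\n")
catshares <- c(hc = sum(pub2$hc * pub2$n_patients), nm = sum(pub2$nm * pub2$n_patients),
               ind = sum(pub2$ind * pub2$n_patients))
cat("shares %:", paste(fmt(100 * catshares / sum(catshares)), collapse = " / "), "\n")

## Monte Carlo analytics
tri_mean <- function(v) (min(v) + max(v) + mean(v)) / 3
cat("\n--- Simulation analytics ---\n")
pd_nm <- c(cat_mean("parkinson", "nonmedical", data = h |> filter(study_id == "Cubo 2009")),
           cat_mean("parkinson", "nonmedical", data = h |> filter(study_id == "Oliva 2007", disorder_id == "parkinson")))
cat("parkinson sim mean (analytic):",
    fmt(cat_mean("parkinson", "healthcare") + tri_mean(pd_nm) + cat_mean("parkinson", "indirect")), "\n")
cat("parkinson nm article values:", fmt(pd_nm), "\n")

## Quality-restricted (category-level fallback to baseline)
hq <- h |> filter(quality_high)
cmq <- function(d, cat, sub = NULL) cat_mean(d, cat, sub, data = hq)
cat("\n--- Quality-restricted means ---\n")
dem_r <- c(cmq("dementia", "healthcare"), cmq("dementia", "nonmedical"), 0)
cat("dementia restricted:", paste(fmt(dem_r), collapse = "/"),
    " delta societal:", fmt((sum(dem_r) - res$total[res$disorder_id == "dementia"]) * prev$n_patients[prev$disorder_id == "dementia"] / 1e6), "\n")
mig_r <- c(cmq("headache", "healthcare", "migraine"), cmq("headache", "indirect", "migraine"))
head_r_hc <- hw[["migraine"]] * mig_r[1] + hw[["tension_type"]] * ten[["hc"]] +
  hw[["medication_overuse"]] * moh[["hc"]] + hw[["other_headache"]] * oth[["hc"]]
head_r_ind <- hw[["migraine"]] * mig_r[2] + hw[["tension_type"]] * ten[["ind"]] +
  hw[["medication_overuse"]] * moh[["ind"]] + hw[["other_headache"]] * oth[["ind"]]
cat("headache restricted hc/ind:", fmt(head_r_hc), fmt(head_r_ind),
    " delta societal:", fmt((head_r_hc + head_r_ind - res$total[res$disorder_id == "headache"]) * prev$n_patients[prev$disorder_id == "headache"] / 1e6), "\n")
uni_r <- c(cmq("mood", "healthcare", "unipolar"), cmq("mood", "indirect", "unipolar"))
mood_r <- (1 - w_bip) * (uni_r[1] + mood_nm + uni_r[2]) + w_bip * (bip_hc + mood_nm + bip_ind)
cat("mood restricted total:", fmt(mood_r), " delta societal:",
    fmt((mood_r - res$total[res$disorder_id == "mood"]) * prev$n_patients[prev$disorder_id == "mood"] / 1e6), "\n")
ms_r <- c(cmq("multiple_sclerosis", "healthcare"), cmq("multiple_sclerosis", "nonmedical"), cmq("multiple_sclerosis", "indirect"))
cat("MS restricted:", paste(fmt(ms_r), collapse = "/"), " delta societal:",
    fmt((sum(ms_r) - res$total[res$disorder_id == "multiple_sclerosis"]) * prev$n_patients[prev$disorder_id == "multiple_sclerosis"] / 1e6), "\n")
pd_r_nm <- cmq("parkinson", "nonmedical")
cat("parkinson restricted nm:", fmt(pd_r_nm), " delta societal:",
    fmt((pd_r_nm - res$nm[res$disorder_id == "parkinson"]) * prev$n_patients[prev$disorder_id == "parkinson"] / 1e6), "\n")
st_r <- c(cmq("stroke", "healthcare"), cmq("stroke", "nonmedical"), cmq("stroke", "indirect"))
cat("stroke restricted:", paste(fmt(st_r), collapse = "/"), " delta societal:",
    fmt((sum(st_r) - res$total[res$disorder_id == "stroke"]) * prev$n_patients[prev$disorder_id == "stroke"] / 1e6), "\n")
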