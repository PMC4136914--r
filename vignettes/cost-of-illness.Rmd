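---
title: "Methods: bottom-up cost-of-illness estimation for brain disorders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bottom-up cost-of-illness estimation for brain disorders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(braincost)
```

## The model

`braincost` implements a prevalence-based, bottom-up cost-of-illness (COI)
model from a societal perspective for 19 mental and neurological disorders.
The unit of evidence is a *cost observation*: one published article's yearly
per-patient cost for one disorder (or subtype), split into up to three
categories —

* **direct healthcare** costs $c_H$ (inpatient, outpatient, drugs,
  procedures and devices),
* **direct non-medical** costs $c_N$ (informal care, adaptations,
  transportation),
* **indirect** costs $c_I$ (production losses from absence, reduced
  capacity and early retirement, valued by the human capital approach).

Intangible costs, costs of crime and premature-mortality losses are outside
the model. For a disorder $d$ with patient count $n_d$ the societal cost is

$$ S_d = n_d \,(\bar c_{d,H} + \bar c_{d,N}) + n_d\, w_d\, \bar c_{d,I}, $$

where $\bar c_{d,k}$ is the pooled per-patient cost of category $k$ and
$w_d$ is the working-age fraction of the patients (indirect costs only
accrue to the working population, unless a disorder's indirect estimates
were published as an all-ages average, in which case $w_d$ is ignored).
The bundled prevalence inputs are already restricted to the age spans the
underlying epidemiological review used (18+ for most disorders, 14–65 for
addictive and anxiety disorders, 2–17 for childhood/adolescence disorders,
65+ for dementia), so their default working-age fraction is 1; the fraction
exists as a per-disorder override for prevalence sources that are not
age-restricted.

## Harmonization

Observations are stated in their original currency at costing-year prices.
Each present category is

1. converted to EUR at the costing-year **annual average nominal exchange
   rate**, then
2. restated at 2010 prices with the **Spanish all-items CPI**:
   $c^{2010} = c^{y} \cdot I(2010)/I(y)$.

The two steps are individually standard; their order is not dictated by the
method. We convert first so that all inflation happens in a single national
price index; the alternative (source-country CPI, then a current exchange
rate) is deliberately not implemented. For the two non-EUR articles in the
bundled corpus the difference between orders is a few percent, which is why
foreign-currency rows are only expected to reproduce published pooled values
within that margin. Absent categories stay absent; explicit zeros are fixed
points; the operation is idempotent and positively homogeneous, and an
audit trail (`fx_rate`, `cpi_factor`) is attached to every row.

The CPI fixture is the Spanish all-items annual-average inflation series
rebased to 2010 = 100, and the exchange-rate fixture holds ECB annual
average USD and GBP rates for 2004–2010. Both are plain CSV and fully
replaceable through `read_references()`.

## Pooling, imputation and subtypes

Within a disorder and category, the pooled estimate is the **un-weighted
arithmetic mean over the articles that report the category**. Reporting a
zero and not reporting are different things: zeros enter the mean, absences
are skipped. Rows flagged as outlier exclusions never enter the pool;
incidence-based rows are excluded by default (`include_incidence = TRUE`
pools them — the bundled corpus prints both prevalence- and incidence-based
variants for two stroke articles, and which variant entered the published
model is not stated).

Missing cells follow the hierarchy

> observed mean → European median → zero,

with provenance recorded per cell (`observed_mean`, `imputed_eu_median`,
`unavailable_zero`). The European medians are disorder-level per-patient
costs (already adjusted to Spanish income/price levels, EUR-2010) consumed
as inputs. Dementia and childhood/adolescence disorders have indirect costs
**forced to zero** (`forced_zero`), since their patients are assumed outside
the working population; the forcing overrides both observed and imputed
values.

Four disorders combine **subtype-level** evidence (anxiety: generalized
anxiety disorder vs other anxiety disorders; mood: unipolar vs bipolar;
headache: migraine, tension-type, medication-overuse, other; neuromuscular:
amyotrophic lateral sclerosis vs other) as a prevalence-weighted average of
per-subtype costs. Disorders without configured weights pool all rows
directly, i.e. every subtype row counts as an ordinary observation — that is
also the behaviour the un-weighted pooling rule implies, and it is the
default because the published analysis does not state its weighting.

### Reconstructed reference inputs

The disorder-level European medians for the nine disorders with no Spanish
article are printed in the published comparison table and are bundled
verbatim (`source = "printed"` in `eu_medians.csv`). The subtype-level
medians and the subtype prevalence weights were **not published anywhere**;
they are reconstructed stand-ins (`source = "reconstructed"`), back-solved
so that the bundled corpus under this package's harmonization reproduces the
published disorder-level per-patient values for anxiety, mood, headache and
neuromuscular disorders. Two shares in that back-solve are genuinely free
and were fixed once on epidemiological plausibility: the "other headaches"
share (0.02) and the ALS share of neuromuscular disorders (0.10). The
reconstruction is validated independently by the Monte Carlo stage: with the
reconstructed headache weights, the simulated headache mean reproduces the
published simulated value (432 €) that was *not* used in the calibration.

## What reproduces and what cannot

Running the bundled corpus end to end reproduces the published per-patient
rows for epilepsy, multiple sclerosis, Parkinson's disease and psychotic
disorders within 0.5%, and the published group arithmetic exactly. Two rows
cannot be reconstructed from the printed inputs:

* **stroke** — the published pooled non-medical mean (9,032 €) exceeds the
  largest mean attainable from any subset of the non-excluded observations
  (6,474 €, even including the incidence-based variants). It is reachable
  only if an observation printed as an outlier exclusion (21,551 €) enters
  the pool; the published table is internally inconsistent with its own
  exclusion flags, and this package follows the flags.
* **dementia** — the published healthcare and non-medical means
  (5,830/19,473 €) do not correspond to any subtype weighting of the
  harmonized observations under either conversion/inflation order; the
  deviation of the pooled means is +4–8% per category.

The package therefore reports a full-corpus grand total of ~81.4 € billion
against the published 83.7 € billion (−2.8%), almost entirely attributable
to the stroke row. The corresponding acceptance check is intentionally left
failing rather than forcing the bundled inputs toward the printed output.

The published overall per-inhabitant figure (1,725 €) is likewise
inconsistent with its own grand total (83,749 € million over 46 million
inhabitants gives 1,821 €); `rollup()` computes the ratio and does not
target the printed number.

## Quality-restricted sensitivity analysis

Quality is a per-row input label (the five-item appraisal — perspective
specified, design justified, costs complete, measured adequately,
uncertainty assessed — is applied by human reviewers; `derive_quality()`
encodes only a default cut-off: every unambiguous item positive). The
re-analysis recomputes all pooled means using high-quality rows only, with a
**category-level fallback**: any disorder/subtype/category cell left without
a high-quality observation keeps its baseline value and the disorder is
flagged. The fallback rule was chosen because it reproduces the published
restricted deltas for Parkinson's disease (+32 vs printed +33 € million) and
multiple sclerosis (+109 vs +109 € million); a disorder-level fallback or a
zero-fill does not. Deltas are computed on unrounded values; fully-imputed
disorders are unaffected by construction. The bundled labels give a positive
overall delta (≈ +4.0 € billion) and a negative headache delta, matching the
published signs; the published per-disorder magnitudes mix imputed
components in an unstated way and are not targeted.

## Monte Carlo simulation

Between-article uncertainty is propagated with **triangular distributions**
per disorder × category: bounds at the lowest and highest harmonized article
values, most probable value at the un-weighted article mean, clamped into
the bounds. (The source method description is ambiguous between "median
observations" and the mean as "the most probable value"; the explicit
sentence fixing the mean governs, and `mode_stat = "median"` exposes the
alternative.) Cells with a single or no observation enter as degenerate
point masses at their baseline (pooled or imputed) value, so simulated
totals remain comparable to the baseline table. Draws are independent across
categories and disorders — no correlation structure is described or
assumed — and use the closed-form inverse CDF under R's seeded RNG, making
every run exactly reproducible from `(seed, n_iter)`.

Simulation is restricted to the seven disorders with more than one pooled
article (dementia, epilepsy, headache, mood disorders, multiple sclerosis,
Parkinson's disease, stroke). A bare ">1 article" rule would also capture
psychotic disorders, which the reference analysis did not simulate, so the
explicit list is the default and is configurable. For subtype-weighted
disorders the triangulars are fitted per subtype and the draws combined with
the prevalence weights — the design validated by the headache simulated
mean (431.9 € vs the published 432 €).

Summaries use the empirical mean and central 90% interval (quantile type 7,
linear interpolation). The pooled statistic is defined as the
**per-iteration median of the eligible disorders' per-patient totals**,
reported with its 90% interval and the exceedance probability against a
3,000 € threshold. A caveat documented deliberately: that median is the 4th
order statistic of 7 totals, and with the per-disorder distributions implied
by the corpus (epilepsy never below ≈5,900 €, stroke rarely below
≈6,000 €) it essentially never falls under 3,000 €, so the exceedance
probability computed here is ≈100%. The published pooled range
(1,696–4,392 €) and exceedance (36.5%) are arithmetically incompatible with
this definition given the same source's own per-disorder intervals; they
appear to stem from a different, unstated pooling (e.g. patient-weighted or
per-category). We implement the stated definition and report what it yields.

Simulated means exceed the observed pooled means whenever the article sets
are right-skewed (triangular mean $(\min + \text{mode} + \max)/3$ exceeds
the mode); on the bundled corpus the difference is ≈ +5%, matching the
published positive direction.

## Synthetic-data generator

`generate_corpus()` draws article-level amounts around configurable true
category means with **log-normal noise parameterised by a coefficient of
variation** (costs are positive and right-skewed; CV 0 degenerates to exact
means), assigns each article a costing year and currency, and writes the
stored amounts by **inverting the CPI and exchange-rate maps**, so
harmonization recovers the EUR-2010 amounts exactly and zero-noise corpora
reproduce the analytic ground truth to machine precision. Structured
missingness is per-category Bernoulli (patterns leaving an article empty
are redrawn); quality labels are Bernoulli. Defaults emulate the bundled
corpus: true means equal to the published per-patient table, three articles
per disorder, CV 0.5, missingness 0.10/0.45/0.35 for
healthcare/non-medical/indirect (the observed reporting gaps), 45%
high-quality rate, 90/5/5% EUR/USD/GBP currency mix over costing years
2001–2010, 3% synthetic inflation.

What the generator does *not* emulate: correlation between categories
within an article, subtype-specific missingness, informative missingness
(articles omitting a category *because* it is small), heterogeneity in
costing methodology, and outlier articles. Passing recovery tests therefore
demonstrates correctness of the pipeline arithmetic under the stated noise
model, not robustness to real-world reporting biases.

The estimator-validation study shipped in the test suite runs 100
replicates of 10 articles per disorder at CV 0.2 across the 19 default
disorders and requires at least 95% of disorder × category cells within two
standard errors ($\mathrm{SE} = \mu\,\mathrm{CV}/\sqrt{n}$) of truth; a
companion check verifies RMSE shrinks over 5 → 20 → 80 articles. These
problem sizes keep the full suite in the low minutes on one core while
leaving the binomial pass bands comfortably wide.

## Numerical conventions

* All invariant checks (additivity, share normalisation, delta
  decomposition) run on unrounded doubles; rounding is display-only.
* Triangular mode clamping resolves the degenerate tie `min = max` to a
  point mass; `fit_triangular()` on one value is a point mass by
  definition.
* Quantiles are `stats::quantile()` type 7 throughout.
* Patient counts from proportions are rounded to the nearest integer;
  direct counts pass through.
* Output tables are schema-stable, written at full precision, and
  byte-identical across reruns with identical inputs and seeds; manifests
  carry input hashes and the configuration echo but no timestamps.

## Known limitations

Patient counts are summed across disorders without comorbidity adjustment,
so the total patient figure double-counts individuals with multiple
disorders. Categories with no estimate anywhere (non-medical costs for
brain tumours, headache, psychotic, sleep and somatoform disorders;
indirect costs for intellectual disability) enter as zeros and understate
the totals — the pipeline warns about every such cell. The un-weighted mean
gives small studies the same influence as large ones, by design of the
underlying method. Exclusion of outlier articles is an input flag, not an
algorithm: no criterion for outlier status is modelled.
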