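---
title: "Validating hospital discharge ascertainment of pregnancy-associated cancer"
author: "pacvalid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating hospital discharge ascertainment of pregnancy-associated cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pacvalid)
```

## The problem

A pregnancy-associated cancer is a cancer newly diagnosed during pregnancy or
within 12 months of delivery. Population cancer registries are the reliable
("gold standard") source of incident cancers, but their quality-assurance
pipelines delay data availability; hospital discharge abstracts are timely but
were never designed for incidence estimation. `pacvalid` implements the
diagnostic-accuracy framework for asking how well hospital inpatient data
ascertain incident pregnancy-associated cancers when a linked registry is
available as the reference, and ships a seeded synthetic generator of linked
maternity / hospital / registry collections so the whole pipeline is testable
without access to identifiable health data.

The unit of analysis is the *maternity* (one delivery of one woman; a woman
may contribute several), crossed with 13 clinical cancer groups. Two hospital
ascertainment definitions are compared against the registry:

* **index cancer hospitalisation** — the earliest cancer admission per
  (maternity, cancer group), emulating data where individuals are
  identifiable; and
* **all cancer hospitalisations** — every admission carrying a cancer
  diagnosis, record as unit, emulating data where individuals cannot be
  distinguished from admissions.

## The procedure

### Exposure windows

For each maternity the exposure window is
$[\,d - 7g,\; d + 365\,]$ days, where $d$ is the delivery date and $g$ the
completed weeks of gestation (20–44; the birth data do not cover earlier
pregnancy losses). Both endpoints are inclusive: a cancer dated on the
delivery day or on the 365th day after it is pregnancy-associated under any
reading of the definition. "Within 12 months" is implemented as a fixed
+365 days rather than calendar-month arithmetic; this is unambiguous and
reproducible, and it is a package constant, not a tunable. Dates are ISO-8601
in all files and integer day offsets internally, removing timezone and locale
ambiguity.

When consecutive windows of one woman overlap (a conception within 12 months
of a delivery) and an event falls in both, the maternity with the earliest
delivery date wins. This is a genuinely open design point — the containment
rule when windows overlap has no canonical answer — so the rule is explicit
and switchable (`rule = "all"` returns every containing maternity).

### Code phenotyping

Hospital diagnoses are ICD-10-AM codes; up to 22 diagnosis fields per
admission are scanned. Malignant neoplasms are C00–C96; admissions whose
codes are all outside that range (including in-situ/benign D codes) never
enter the analysis, and C77–C79 (secondary/metastatic sites) are recognised
but excluded from candidacy, realising the "incident primary only" filter
purely at code level. C44 (non-melanoma skin) is out of scope because
population registries do not register it.

The 13 clinical groups follow ICD-10 chapter blocks (see
`default_code_map()`); registry clinical groupings are not published at code
level, so the mapping is a documented approximation and fully replaceable via
a YAML file (`read_code_map()`). Stems unused by ICD-10 inside the range
(C27–C29, C35–C36, C42, C59) are folded into the adjacent block so that the
map provably covers C00–C96; these stems never occur in coded data, so the
folding is cosmetic but lets the package assert exhaustiveness.

A record with several eligible codes takes the group of the *first-listed*
eligible code. This is the package's choice (the field order encodes coding
priority); it is consistent with per-group admission counts summing exactly
to the "any" total, which implies one group per record.

### Case sets

* *Registry cases*: registry records whose diagnosis date attributes to a
  window and whose earliest notification of that group equals the diagnosis
  date (incident, not prevalent — the lookback semantics are carried by a
  single `first_notification_date` field). Duplicates of one group within a
  maternity collapse to the earliest; distinct groups are distinct cases, so
  multiple primaries in one pregnancy are preserved.
* *Hospital index cases*: per (maternity, group), the qualifying admission
  with the earliest admission date, ties broken by smallest record id (a
  deterministic, documented tie-break).
* *Hospital all cases*: one case per qualifying record.

The hospital side is attributed by admission date (the natural analogue of
the registry diagnosis date for timing comparison).

## The statistics

Cross-classification is on (maternity × group) units: per group,
$\mathrm{TP}$ are pairs in both sources, $\mathrm{FP}$ hospital-only,
$\mathrm{FN}$ registry-only, and
$\mathrm{TN} = N - \mathrm{TP} - \mathrm{FP} - \mathrm{FN}$ with $N$ the
number of maternities — all four metrics are proportions *of maternities*.
The "any" row is the element-wise sum of the 13 group rows (not a collapse
to distinct maternities), so a maternity with two primary cancers
contributes two units.

$$
\mathrm{Sn} = \frac{TP}{TP+FN},\quad
\mathrm{PPV} = \frac{TP}{TP+FP},\quad
\mathrm{Sp} = \frac{TN}{TN+FP},\quad
\mathrm{NPV} = \frac{TN}{TN+FN}
$$

each with an exact (Clopper–Pearson) binomial interval from the Beta
quantile closed form: with $\alpha = 1 - \text{level}$,

$$
\mathrm{low} = B^{-1}(\alpha/2;\, x,\, n-x+1), \qquad
\mathrm{high} = B^{-1}(1-\alpha/2;\, x+1,\, n-x),
$$

with the conventions $\mathrm{low}=0$ at $x=0$ and $\mathrm{high}=1$ at
$x=n$. Exact intervals are conservative (their coverage is at least the
nominal level), which matters for the parameter-recovery tests below. A
metric with a zero denominator is *undefined* and surfaces as `NA` plus a
flag — never as a silent zero.

Crude incidence is $10^5 \cdot \text{cases} / N$ per 100,000 maternities,
and each hospital source's incidence rate ratio (IRR) is its rate over the
registry rate, computed on unrounded values. All percentages and rates are
rounded half-up to one decimal *only* at the presentation layer
(`round_half_up()`; base `round()` would round half to even), and every
comparison and interval uses unrounded values.

In the reference count set shipped with the package
(`nsw_reference_counts()`, 679,736 maternities), the overall registry count
of 988 gives 145.35 per 100,000 — the source tables print both 145.0 and
145.4 for this quantity; the package follows the arithmetic and reports the
unrounded value. Similarly, the reference TP+FP totals (746) do not equal
the index-hospitalisation totals (770), an artefact of the source data the
package neither reproduces nor hides: the pipeline itself always satisfies
$TP + FP = $ index count.

### False-positive adjudication and timing

Each false positive is adjudicated by lookback, with precedence
*prevalent* > *misclassified type*:

1. **prevalent** — the woman has a same-group registry notification first
   notified before the window start;
2. **misclassified type** — otherwise, the same maternity has an incident
   registry cancer of a different group;
3. **unexplained** — neither.

Among true positives, the calendar-month difference (registry month minus
admission month) is binned as 0 / 1–2 / 3–5 / ≥6 months prior, or negative
(admission after registration). Calendar months, not 30-day blocks, are used
because registries effectively record month-level diagnosis dates.

## The synthetic generator

`simulate_cohort()` emulates the statistical structure the analysis assumes:

* women with 1–4 maternities (mean ≈ 1.45, matching the reference cohort's
  maternities-per-woman ratio), delivery dates uniform over 2001–2008 with
  inter-pregnancy gaps of 400–1,100 days, and a realistic gestational-age
  distribution concentrated at 38–41 weeks;
* incident cancers drawn independently per (maternity, group) at the
  reference per-group incidence (so multiple primaries can co-occur),
  diagnosis dates uniform in the window;
* hospital capture of each incident cancer with the reference per-group
  sensitivities as capture probabilities; the index admission precedes the
  registry date by a whole-calendar-month offset drawn from the 66/28/5/1
  percent mixture (day uniform within the target month, not after the
  registry day when the offset is 0), clamped to the window start with the
  realized bin recorded; extra same-group admissions (Poisson, per-group
  mean equal to the reference all/index ratio minus one) drawn between the
  index admission and the window end, so the index admission remains the
  earliest;
* the three false-positive mechanisms: prevalent cancers (registry history
  strictly before the woman's earliest window, plus an in-window admission),
  miscoded types (a planted true cancer whose admission code is replaced via
  a confusion map: colorectal→upper-GI, gynaecological→upper-GI,
  melanoma→breast/bone, others uniform), and uncorroborated noise
  admissions; their rates are the reference decomposition 86/22/58 per
  679,736 maternities, with partially published group profiles completed by
  uniform/proportional spreading — a documented approximation;
* optional linkage noise at 5/1,000 missed links (a woman's registry records
  detached) and 3/1,000 false links (a record reassigned to a random woman);
* a delivery admission (obstetric codes only) per maternity, so code
  filtering is always exercised.

The truth ledger records every planted event and computes the expected
per-group TP/FP/FN *after* window attribution, i.e. exactly what a correct
pipeline must recover when linkage noise is off — including the rare case
where an event planted in one maternity's window attributes to an earlier
overlapping maternity of the same woman.

What the generator does **not** emulate: demographic covariates, survival
and death, seasonality, gestational-age error, outpatient management (the
mechanism behind much of the real melanoma under-ascertainment appears here
only as a capture probability), and record-linkage internals (only its error
rates). Passing tests therefore demonstrate the *pipeline's* correctness and
calibration under the stated structure, not the clinical generalisability of
any particular estimate. One structural consequence worth knowing: extra
admissions attach only to captured true cancers, so the synthetic
all-to-index admission ratio sits somewhat below the reference 2.23.

## Numerical and testing choices

* Degenerate inputs: empty hospital files are legal (sensitivity 0, PPV
  undefined); empty code lists, gestations outside 20–44, malformed codes,
  non-ISO dates and unknown group labels fail fast with row-level
  diagnostics.
* Determinism: the analysis draws no random numbers; the generator is fully
  reproducible under a seed (the global RNG state is saved and restored),
  and identical inputs yield byte-identical JSON summaries.
* Test problem sizes are chosen to keep the suite fast while leaving
  Monte-Carlo error far from the asserted bounds: randomized-oracle
  equivalence uses cohorts of ≤50 women where brute-force set construction
  is feasible; end-to-end ledger recovery runs 20 seeds at ~50,000
  maternities; the incidence-profile check uses ~690,000 maternities (about
  1,000 expected cancers, binomial SE ≈ 1.5% on the melanoma share);
  stochastic tolerances are stated inline as multiples of the binomial
  standard error.
* Parameter-recovery experiments switch miscoding and linkage noise off so
  that per-group sensitivity estimates exactly the capture probability;
  degenerate-limit and multiplicity experiments use one maternity per woman
  so that overlapping sibling windows cannot reattribute events. Both are
  design-time choices about what each experiment isolates.

## Known limitations

* The code-to-group mapping is an approximation of unpublished registry
  clinical groupings (e.g. whether eye C69 belongs with neurological is not
  recoverable); it is config-overridable.
* Prevalent/miscode/noise group profiles are only partially identified by
  the reference decomposition; the remainder is spread by assumption.
* The false-negative side is modelled only as non-capture; causes of
  missingness (death-certificate notification, outpatient diagnosis) are
  not distinguished.
* Inferential comparison of IRRs (significance testing) is out of scope.
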