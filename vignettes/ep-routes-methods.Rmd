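---
title: "Methods: classifying and analysing emergency presentations to cancer diagnosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying and analysing emergency presentations to cancer diagnosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eproutes)
library(dplyr)
```

## The problem

A substantial share of cancers are first diagnosed in the days after an
emergency hospital admission. This "emergency presentation" (EP) route is a
strong non-stage prognosticator — emergency presenters die sooner than
otherwise comparable patients — and jurisdictions differ widely in how
often it occurs, so it is a candidate explanation for international
differences in cancer survival. Measuring it requires only two linked
administrative tables per jurisdiction: tumour registrations (diagnosis
date, site, demographics, stage, vital status) and inpatient admissions
(date, emergency/elective type). Because patient-level registry data cannot
cross borders, the analysis is federated: each jurisdiction runs the same
pipeline locally and shares only aggregates, which a central stage pools.

`eproutes` implements that pipeline end to end: cohort eligibility, EP
classification under two operational definitions, stratified description
with Wilson intervals, logistic EP-risk and EP–mortality models,
random-effects meta-analysis with a definition-type moderator, and the
jurisdiction-level ecological regression against 1-year net survival. A
synthetic linked-registry generator stands in for the non-shareable data so
every stage is testable.

## Operational definitions of emergency presentation

A diagnosis is **broad-EP** when at least one *emergency* inpatient
admission occurred within `window_days` (default 30) days before the
diagnosis date, both bounds inclusive. It is **narrow-EP** when, in
addition, some qualifying emergency admission has no *elective* admission
dated strictly between it and the diagnosis. Narrow therefore implies
broad, and enlarging the window can only add broad labels.

Three boundary conventions are deliberate:

* An emergency admission on the diagnosis day itself (offset 0) counts:
  many cancers are diagnosed during the index admission.
* An elective admission on the same calendar day as the emergency
  admission, or as the diagnosis, is *not* intervening. Day-granularity
  data cannot order same-day events, so strict inequalities are used.
* The anchor is the *admission* date of the latest qualifying emergency
  admission (not the discharge date, which the source datasets do not
  consistently carry).

The definitions are contextual, not clinical: only dates and the
emergency/elective flag are used, never the coded reason for admission.
This makes them robust to coding variation across health systems, at the
price of counting some admissions unrelated to the cancer.

## Cohort eligibility

Eight sites are analysed, mapped from ICD-10 topography: oesophageal
(C15), stomach (C16), colon (C18–C19), rectal (C20), liver (C22),
pancreatic (C25), lung (C34), and ovarian including peritoneal and
fallopian-tube cancers (C48.1, C48.2, C56, C57.0 — the C48/C57 members at
four-character precision). Both dotted and undotted code forms are
accepted, since registries differ. Records are kept when the site is
mappable, age is 15–99 years (evaluated on the grouped bands 15–64, 65–74,
75–84, ≥85; a raw age is banded first), behaviour is invasive (code 3),
the diagnosis year falls in the study period (default 2012–2017), and —
for ovarian cancer — the ICD-O-3 morphology is not one of the borderline
codes 8442, 8451, 8462, 8472, 8473.

Exclusion reasons are tallied under a fixed precedence (missing diagnosis
date, unmappable site, age, behaviour, borderline morphology, year). The
precedence is a reporting convention only: the included set is identical
under any ordering, which the tests assert.

## Statistical methods

**Proportions.** EP percentages are `100·k/n` per stratum with 95% Wilson
score intervals — centre $(\hat p + z^2/2n)/(1+z^2/n)$, half-width
$z\sqrt{\hat p(1-\hat p)/n + z^2/4n^2}/(1+z^2/n)$ — with
$z = \Phi^{-1}(0.975) = 1.959964$ and no continuity correction. Wilson
intervals never leave $[0,1]$ and behave sensibly at $k = 0$; the suite
cross-checks them against `prop.test(correct = FALSE)`. Values are kept at
full precision internally; rounding to one decimal is presentation-layer
only.

**Concordance of site ordering.** Pairwise Pearson correlations between
one reference jurisdiction's eight site-level EP percentages and every
other jurisdiction's. Whether "ordering" should mean ranks was open;
Pearson on percentages is the default and Spearman is available via
`method = "spearman"`.

**Odds ratios.** Crude ORs come from the 2×2 closed form
$ad/bc$ with $\mathrm{se}(\log OR) = \sqrt{1/a+1/b+1/c+1/d}$; a zero cell
is an error, not a silent continuity correction. Adjusted ORs come from
maximum-likelihood logistic regression with categorical covariates
dummy-coded against fixed references: colon for site, 15–64 for age,
male for sex, the earliest year (year is categorical throughout — no
linearity is assumed), and the least advanced stage. Wald standard errors
and symmetric log-scale CIs match how such tables are printed. Two
EP-risk models are fitted (site+age+sex+year, then +stage) and three
EP–mortality models (crude, adjusted without stage, stage-adjusted) at
each horizon. Missing stage is an explicit `"missing"` category, which
preserves the cohort; jurisdictions with a site entirely missing stage get
their stage-adjusted models skipped and flagged rather than silently
refitted.

**Mortality.** All-cause mortality at fixed horizons: 1 month = 30 days,
3 months = 91 days, 12 months = 365 days (registry conventions; the
horizons' day counts are not standardised elsewhere). A record is dead at
a horizon iff its death date is within the horizon of diagnosis; patients
censored earlier are assumed to have survived, which is appropriate when
registry follow-up is near-complete. Logistic rather than time-to-event
models are used throughout: with essentially complete 12-month
ascertainment the binary model answers the same question more simply.

**Meta-analysis.** Jurisdiction log-ORs are pooled by inverse-variance
random-effects meta-analysis (weights $1/(se_i^2+\tau^2)$), by default with
REML estimation of $\tau^2$ (DerSimonian–Laird and fixed-effect are
options) and no Knapp–Hartung adjustment. The definition type enters as a
narrow-indicator moderator; per-definition pooled ORs are the fitted
values at each level. Pooling printed tables is supported by back-deriving
$se = (\ln U - \ln L)/(2z)$ from published CIs. Heterogeneity is reported
two ways, because they answer different questions: the Cochran-Q form
$I^2 = \max(0,(Q-\mathrm{df})/Q)\cdot 100$ for the fitted (possibly
moderated) model and for the unmoderated model, plus the $\tau^2$-based
$I^2$ of the REML fit. The implementation delegates the fit to `metafor`,
the standard tool for this model; the test suite holds it to the
DerSimonian–Laird closed form and the fixed-effect closed form computed by
direct arithmetic.

**Ecological regression.** Per cancer site, unweighted OLS of
jurisdiction-level 1-year net survival on the jurisdiction's EP percentage
plus a narrow-definition indicator, with t-based inference; the slope is
reported per 10 percentage points of EP. Net survival is an external
input, not something this package estimates. Because the real
17-jurisdiction EP-percentage/net-survival pairs are not bundled, this
stage is validated by synthetic recovery: exact recovery on noiseless
collinear fixtures, and nominal CI coverage over repeated noisy
17-jurisdiction tables.

## The synthetic registry generator

The generator emulates the linked two-table structure under the study
conditions: diagnoses uniform over 2012–2017; covariates (site, age band,
sex, 3-level stage plus an 8% missing fraction) drawn independently from
configurable mixes; a latent EP indicator from a logistic model whose
defaults give a marginal broad-EP fraction near 32%, highest for
pancreatic and liver cancer, lowest for rectal, rising with age and
stage; and a 12-month death indicator from a second logistic model with a
conditional EP log-OR of $\ln 3$, so that the *crude* EP–mortality OR is
confounded upward (to about 4.0, computable exactly via
`implied_marginal_mortality_or()`) the way real registry data are.

Admission histories are built backward from the latent labels. A broad-EP
case receives one emergency admission 0–30 days (inclusive) before
diagnosis, exercising both window boundaries. With probability
`narrow_discordance` (default 0.15) the case is broad-but-not-narrow: its
emergency admission is drawn 2–30 days out and an elective admission is
placed strictly between admission and diagnosis. The 2-day floor exists
because a strictly intervening elective needs at least one free day; had
discordant cases drawn offsets 0–30 like the rest, the realised
broad-minus-narrow gap would fall short of
$\text{broad} \times \texttt{narrow\_discordance}$, which is the
calibration the generator promises (≈ 32% × 0.15 ≈ 5 percentage points,
matching the gap observed where both definitions were computed on the same
patients). Small fractions of non-EP patients receive an in-window
elective admission (1%) or an emergency admission 45–365 days before
diagnosis (2%), so the emergency/elective and in/out-of-window distinctions
are exercised by data, not only by fixtures. Deaths within 12 months get a
death date uniform in (diagnosis, diagnosis+365]; survivors are censored
at diagnosis+400 days. A full survival-time model is unnecessary because
the analysis consumes only binary mortality at fixed horizons.

What the generator does *not* emulate: correlated covariates (real
registries have strong site–age–sex dependence; treating them as
independent is a modelling convenience, and parameter-recovery results
should be read accordingly), realistic multi-admission histories,
comorbidity, screening detection, between-jurisdiction coding differences,
or true between-jurisdiction heterogeneity in effect sizes. Passing tests
therefore demonstrate that the *machinery* is correct under the stated
model, not that real data meet the model.

## Federated aggregate exchange

`run_jurisdiction()` executes eligibility → classification → description →
models and emits an aggregate bundle: stratum summaries, tidy model
estimates, an eligibility report, a schema version and a provenance hash.
No patient-level field may appear in a bundle (enforced by a schema scan
at both construction and serialisation). Counts below the suppression
threshold (default 5, the common registry disclosure floor; 0 is sensible
for synthetic data) are masked — the numerator, denominator and derived
values are all withheld, and masked cells are flagged and excluded from
collated sums. Bundles are one directory of CSVs plus a JSON manifest,
and round-trip byte-identically. `collate()` refuses to pool bundles built
with different windows, checks each bundle's site-stratum sums against its
total, and emits the jurisdiction-by-site percentage matrix, the mortality
OR table, and a meta-analysis-ready estimate table. The suite asserts that
the federated path and a direct pooled-data run produce identical
estimates.

There is no networking: "federated" here is the data contract — aggregates
only — not an execution model.

## Problem sizes and numerical choices

The bundled analysis scripts simulate 3 jurisdictions × 20,000 patients.
The test suite checks marginal-convergence invariants on a single 100,000
patient cohort (tolerance: 3 Monte-Carlo standard errors), parameter
recovery over 200 replicates of 1,500 patients for the conditional models
and 200 replicates of 4 × 700 patients for pooled crude ORs (coverage
asserted within a 3σ binomial band of the nominal 95%), and ecological
coverage over 200 replicates of 17 jurisdictions. These sizes keep each
property on the right side of Monte-Carlo noise while running in minutes.

Other numerical conventions: day arithmetic on calendar dates with no
time-of-day component; deterministic generation given the configuration
seed; logistic fits reject rank-deficient designs and flag perfect
separation rather than returning degenerate Wald intervals; the ecological
fit reports $R^2 = 0$ (not NaN) for a constant outcome; and
`pool_random_effects()` requires at least two studies (three with the
moderator) unless the caller explicitly relaxes `min_k`, as the
single-study identity check does.

## Known limitations

* Published jurisdiction-level percentages are shipped rounded to one
  decimal, so quantities recomputed from them (e.g. the minimum site-order
  concordance) are exact only to the printed precision of the original
  values.
* The narrow definition is evaluated against elective admissions only;
  other admission categories (day cases, transfers) are out of scope, as
  are clinically enriched definitions (e.g. emergency-laparotomy-based),
  which trade robustness for sensitivity.
* No socioeconomic, comorbidity or rurality adjustment; no
  multiple-primary deduplication; no estimation of net survival.
* Ecological associations are population-level: they say nothing causal
  about individual patients.
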