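---
title: "Disproportionality and time-to-onset methods in pvfaers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality and time-to-onset methods in pvfaers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvfaers)
```

pvfaers implements the standard spontaneous-report screen for a
drug–event association — here tuned to immune-checkpoint-inhibitor
(ICI) related pancreatitis in FAERS-style data — as a tested pipeline:
read and deduplicate quarterly report tables, normalize drug names,
select event cases by MedDRA preferred term (PT), and quantify
disproportionate co-reporting with four algorithms plus subgroup,
descriptive and time-to-onset analyses. This vignette records the
model, the parameter choices, and the design decisions that were
genuinely open.

## The data model and deduplication

A FAERS quarter is five `$`-delimited tables keyed by `primaryid`:
DEMO (demographics and receipt date `fda_dt`), DRUG (one row per drug
with role code PS/SS/C/I — primary suspect, secondary suspect,
concomitant, interacting), REAC (MedDRA PTs), THER (therapy start/end
dates) and OUTC (outcome codes, `DE` = death). Because cases are
re-submitted as follow-ups, one patient case (`caseid`) appears under
several `primaryid`s; the convention implemented in `dedup_reports()`
keeps, per case, the record with the latest receipt date. Receipt-date
ties are broken toward the largest numeric `primaryid` — the
later-assigned identifier — which makes the rule deterministic and
idempotent. Dates may be partial (`YYYYMM` or `YYYY`); they are kept as
(year, month, day) components rather than forced into full dates, and
each consumer owns its completion policy (see time-to-onset below).

Age and weight arrive as value/unit pairs; the conversion constants
are fixed (decades ×10, years ×1, months ÷12, weeks ÷52.143, days
÷365.25; pounds ×0.45359237, grams ÷1000). Unknown units or
out-of-range results (age outside 0–120 years, weight outside 0–500
kg) yield missing values; the row is never dropped for a bad field.

Drug mapping is deliberately simple: case-insensitive,
punctuation-stripped substring matching of dictionary synonyms (generic
plus brand names) inside the verbatim `drugname`, consulting the
active-ingredient field only when the name fails. Fuzzy edit-distance
matching is out of scope; the bundled dictionary covers the seven
marketed checkpoint inhibitors and is user-extensible. Selection
defaults to primary-suspect (PS) roles only — the conservative choice
for causal attribution — and a report listing two ICIs as PS
contributes one case per drug (flagged `multi_ici`), so each drug's
2×2 table counts the report once.

The default pancreatitis event definition is the nine pancreatitis PTs
commonly reported in checkpoint-inhibitor screens (Pancreatitis,
acute, chronic, immune-mediated, autoimmune, obstructive, necrotising,
oedematous, haemorrhagic). Published screens differ in their exact PT
panels, so the list is fully overridable through
`event_definition()`/YAML config.

## The four disproportionality algorithms

All four compare observed co-reporting of (drug, event) with the
expectation under independence of the report margins. With cells
a (drug & event), b (event, other drugs), c (drug, other events),
d (neither), N = a+b+c+d:

* ROR = ad/bc; 95% CI = exp(log ROR ± 1.96·√(1/a+1/b+1/c+1/d))
  (Wald on the log scale). Criterion: lower bound > 1 and a ≥ 3.
* PRR = [a/(a+c)]/[b/(b+d)]; χ² is the full four-cell Pearson
  statistic with expecteds from the margins. Criterion: PRR ≥ 2,
  χ² ≥ 4, a ≥ 3 (boundaries inclusive).
* IC = log₂[aN/((a+c)(a+b))]; IC025 = IC − 3.3·a^(−1/2) − 2.0·a^(−3/2),
  the Norén closed-form lower credibility bound on the observed count.
  Criterion: IC025 > 0 (strict).
* EBGM = aN/((a+c)(a+b)) — the observed/expected relative reporting
  ratio, identically 2^IC; EBGM05 = exp(log EBGM − 1.645/√a), a
  one-sided 95% lognormal lower bound with observed-count variance
  1/a. Criterion: EBGM05 > 2 (strict) and a > 0.

Design decisions where conventions differ:

* **Cell semantics.** `d` is the *remaining* cell (N − a − b − c).
  Loose verbal definitions of d as "all reports" are internally
  inconsistent with ROR = (a/b)/(c/d); only the four-cell partition
  makes the four formulas coherent, and it is standard practice.
* **χ² correction.** No Yates continuity correction by default (the
  plain Σ(O−E)²/E form); Yates is available by flag since some screens
  report it.
* **Zero cells.** Ratio estimates on a table with any zero cell use
  the Haldane–Anscombe +0.5 on all four cells and are flagged
  `corrected`; the χ² always uses the raw counts. a = 0 leaves IC and
  EBGM undefined (flagged non-signal) rather than corrected.
* **Interval formulas.** Screens of this type typically print point
  estimates and lower bounds without stating their interval formulas;
  the choices above (Wald ROR CI, Norén IC025, lognormal EBGM05) are
  the common closed forms. The full five-parameter DuMouchel
  empirical-Bayes fit — a two-component gamma mixture prior over
  relative reporting rates, fitted by marginal (negative-binomial
  mixture) likelihood, giving shrunk EBGM and EB05 per table — is
  implemented in `fit_mgps_eb()` for panels of ≥ 50 tables. It shrinks
  sparse cells toward the null and converges to the raw ratio as
  counts grow; the simple ratio form remains the default because it is
  what the printed tables use.
* **Subgroups.** Sex and age (<65 / ≥65 years) panels restrict *both*
  the drug margin and the background to the stratum, i.e. N is re-based
  to the stratum. Keeping the global background instead would mix
  between-stratum reporting differences into every within-stratum
  estimate.

The composite "positive signal" requires all four criteria — the
consistency standard screens use before calling an association.

## Descriptive analyses

`case_table()` reproduces the clinical-characteristics layout: counts
per category and drug with an explicit Missing row and percentages of
the per-drug event-case total at one decimal (age bins <18 / 18–64.9 /
65–85 / >85 years; weight <50 / 50–100 / >100 kg). Homogeneity across
drugs uses Pearson's chi-square without continuity correction;
the Missing row is *excluded* from the test by default because
structural missingness reflects reporting practice, not demography (a
flag reverses this; degenerate all-zero rows or columns are dropped
and reported, and the fraction of cells with expected count < 5 is
returned as a quality flag). Death proportions divide by event cases
*with any outcome recorded* — published per-drug mortality fractions
(e.g. 3 deaths of 11 evaluable) imply that restricted denominator —
and a zero-denominator drug reports `NA`, never 0%.

## Time to onset

For each event case, onset is the event date minus the *earliest*
therapy start among THER rows linked to the matched drug's sequence
numbers ("drug initiation" means first exposure). Partial-date policy:
a missing day imputes to the 1st of the month (biasing a record's
onset upward by at most 30 days; `complete_dates` records imputation so
sensitivity analyses can drop such records); a missing month excludes
the record; negative intervals are excluded. Every event case ends as
either a record or exactly one exclusion reason — the exclusion log
partitions the failures.

Summaries are medians and IQRs with linearly interpolated quartiles
(R's default type-7 convention). Kaplan–Meier curves of the
event-free fraction use the product-limit estimator (with all onsets
observed it equals one minus the empirical CDF; censoring is supported
structurally). Groups are compared with the k-group log-rank test
referred to χ²(k−1), with Kruskal–Wallis on raw onset days emitted as
a secondary, rank-based comparison. Kaplan–Meier and log-rank
computations are delegated to the survival package; the package's own
tests check them against enumeration and permutation references.

A calibration note: the χ² reference for the k-group log-rank
converges slowly when there are many groups — in our simulations with
7 uncensored Weibull groups it rejects a true null at ≈ 9% with 20
observations per group and still ≈ 6% at 40–100 per group, reaching
its nominal 5% only around 250 per group. The package's
null-calibration simulations therefore use 7 × 250; interpret log-rank
p-values near 0.05 cautiously when per-drug onset groups are small
(they often are for low-volume drugs).

## The synthetic generator

`generate_faers()` emulates the FAERS schema with known ground truth
so that every downstream stage is testable without external data. One
primary-suspect drug is assigned per report — a categorical draw over
the configured exposure probabilities, with the remainder drawn from a
background-drug pool — and the event PT occurs with probability
min(1, background_rate × planted_rrr) given exposure. The
single-suspect design keeps planted null drugs uncontaminated by
co-exposure to elevated drugs while matching how primary-suspect
attribution works in practice; multi-suspect reports are exercised in
tests through hand-built fixtures. Reports are spread over configured
quarters; onset intervals are Weibull (shape 0.85 by default — the
right skew of published onset IQRs; scale set per drug so the Weibull
median matches the published per-drug medians, 39.5–146.5 days);
receipt follows the event by a 7–120-day reporting lag. A configured
fraction of cases receives a duplicate DEMO record with a new
`primaryid` and a strictly earlier receipt date, so "keep latest" has
a unique right answer; dates are truncated to YYYYMM (¾ of
truncations) or YYYY with the configured partial-date rate; death
outcomes are Bernoulli per event case at per-drug probabilities, other
outcome codes sampled from the remaining FAERS codes.

Default study conditions: 200,000 reports, background event rate
0.005, the seven checkpoint inhibitors with exposure shares
proportional to their report volumes (0.04–1.8%), planted relative
rates 2.18–3.35, demographic mixes near published case tables (54%
male, mean age 63, ~60% missing weight, country mix led by US and
Japan), 10% duplicate injection, 15% partial dates, 30% missing event
dates. What the generator does *not* emulate: secular reporting
trends, drug–drug interactions, correlated missingness, PT
co-occurrence structure, and real free-text noise beyond brand/generic
variants and dose suffixes — so passing tests demonstrate correctness
of the machinery under the stated model, not robustness to every
real-data pathology.

## Validation design

Two validation experiments are bundled (used by the test suite and
`scripts/acceptance.R`):

* **Planted recovery** (`planted_recovery()`): datasets of 200,000
  reports with several drugs planted at one relative rate (40, 20, 14
  and 8 drugs at rates 1, 2, 3, 5, each at 1% exposure) are pushed
  through the full pipeline and the pooled drug-set EBGM is compared
  with the EBGM of the *expected* 2×2 table under the generative
  model. Pooling brings the expected drug–event count to ≈ 400, so the
  Monte-Carlo error (≈ 5% on the log scale) sits well inside the 15%
  acceptance band. The expected-table truth matters: with a
  non-negligible exposed fraction the planted signal itself inflates
  the database-wide event rate, so the attainable EBGM is slightly
  below the planted rate (e.g. 1.67 rather than 2 when 20% of reports
  carry a rate-2 drug) — exactly what the expected table predicts, and
  a real property of relative-reporting statistics, not an estimator
  bias. The null dataset additionally checks that no planted-null drug
  is flagged by the composite criteria.
* **Log-rank behaviour**: 500 null panels (7 Weibull groups × 40)
  for the type-I error, and a scale-40 vs scale-160 Weibull pair
  (n = 200 each) for power, cross-checked in the tests against a
  10,000-shuffle permutation reference implemented independently.

Problem sizes throughout (200,000-report recovery datasets, 500-panel
calibrations, 1,000-table oracle-equivalence sweeps) were chosen so the
statistical claims are sharp while a full run of the suite and the
acceptance script completes in a couple of minutes on one CPU.

## Known limitations

Signal detection on spontaneous reports measures reporting
disproportionality, not incidence or risk; the package inherits every
caveat of that design (reporting biases, confounding by indication,
duplicate reports beyond the modelled follow-up pattern). The drug
matcher is substring-based and will miss heavily misspelled names. The
PT matcher is exact (case-insensitive) with no MedDRA hierarchy
traversal. No multiplicity adjustment is applied across the PT panel
or the descriptive tests, matching field practice for
hypothesis-generating screens.
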