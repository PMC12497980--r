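# pvfaers

Pharmacovigilance signal detection and time-to-onset analysis for
FAERS-style spontaneous report data, built for drug–event screens such
as immune-checkpoint-inhibitor (ICI) related pancreatitis.

Spontaneous-report databases like the FDA Adverse Event Reporting
System (FAERS) hold millions of voluntary reports, each listing a
patient's demographics, suspect and concomitant drugs, MedDRA-coded
reactions, therapy dates and outcomes. Whether a drug is
disproportionately co-reported with an event is assessed against the
database's own background: for a target drug and target event, reports
are partitioned into a 2×2 table

|              | target drug | other drugs |
|--------------|-------------|-------------|
| target event | a           | b           |
| other events | c           | d           |

and four standard statistics are computed with their conventional
positivity criteria:

* **ROR** (reporting odds ratio) = ad/bc, Wald 95% CI on the log scale;
  positive when the lower bound exceeds 1 and a ≥ 3.
* **PRR** (proportional reporting ratio) = [a/(a+c)] / [b/(b+d)] with the
  four-cell Pearson χ²; positive when PRR ≥ 2, χ² ≥ 4 and a ≥ 3.
* **IC** (BCPNN information component) = log₂[aN/((a+c)(a+b))] with the
  Norén closed-form lower bound; positive when IC025 > 0.
* **EBGM** (gamma-Poisson relative reporting ratio) = aN/((a+c)(a+b)),
  identically 2^IC, with a one-sided lognormal lower bound; positive
  when EBGM05 > 2 and a > 0. A full DuMouchel-style empirical-Bayes fit
  across a panel of tables is available via `fit_mgps_eb()`.

A composite signal requires all four.

Around that core the package provides the full working pipeline:
readers for the FAERS quarterly `$`-delimited ASCII tables with
case-level deduplication ("keep the latest receipt per case"),
free-text drug-name normalization against a bundled ICI dictionary,
event selection by MedDRA preferred-term lists,
clinical-characteristics tables with chi-square homogeneity tests,
per-drug death summaries, sex and age subgroup panels, time-to-onset
(TTO) medians/IQRs with Kaplan–Meier curves and log-rank comparisons,
and a synthetic FAERS generator with planted ground truth (association
strengths, Weibull onset distributions, duplicate injection,
missingness) so every stage is testable without external data.

## Worked example

```r
library(pvfaers)

cfg   <- synthetic_config(n_reports = 50000, seed = 42)
x     <- generate_faers(cfg)       # five FAERS-dialect tables + truth
cases <- select_cases(x)           # dedup, drug mapping, PT matching
cases
#> spontaneous-report case selection ('pancreatitis')
#>   roles kept: PS | duplicates removed: 5000
#>                                step     n
#>                       raw demo rows 55000
#>                deduplicated reports 50000
#>  reports with dictionary drug as PS  2571
#>         event reports (target drug)    33
#>               cases (report x drug)  2571
#>         event cases (report x drug)    33

pv_signal(cases)
#> disproportionality panel (10 rows)
#>  group           event        stratum N(a) ROR (95% CI)      PRR (chi2)   EBGM (EBGM05) IC (IC025)
#>  Total           pancreatitis overall 33   2.62 (1.82-3.78)  2.60 (28.67) 2.40 (1.81)   1.27 (0.68)
#>  PD-L1 inhibitor pancreatitis overall 10   3.27 (1.73-6.19)  3.24 (14.95) 3.15 (1.87)   1.66 (0.55)
#>  ...
```

The `Total` row reads: 33 co-reports of a checkpoint inhibitor (as
primary suspect) with a pancreatitis preferred term; the drug class is
co-reported with pancreatitis about 2.4–2.6 times more often than the
database background, with the ROR confidence interval excluding 1. The
generator planted per-drug relative rates between 2.2 and 3.3, so the
panel recovers the built-in truth. Onset analysis:

```r
tt <- tto_analysis(cases, x$ther)
tt$overall
#>   group  n median q1     q3 small_group
#> 1   all 24   77.5 10 167.75       FALSE
```

24 event cases carry resolvable therapy-start and event dates; the
median onset is 77.5 days (IQR 10–167.75) — the right-skewed Weibull
onset profile the generator plants. Single tables work directly too:

```r
signal_scores(pv_2x2(10, 20, 30, 240))
#>   ror ror_lo95 ror_hi95  prr   chi2    ic ebgm ebgm05
#> 1   4    1.712    9.346 3.25 11.538 1.322  2.5  1.486
```

Real FAERS quarters are read with `read_faers(dir)` (files named like
`DEMO24Q1.txt`), and `run_pipeline(run_config(...))` drives every stage
from one configuration, writing CSV tables, a log and a JSON manifest
with attrition counts and content hashes.

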