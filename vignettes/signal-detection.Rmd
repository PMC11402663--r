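---
title: "Disproportionality and time-to-onset methods in faersdpa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality and time-to-onset methods in faersdpa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersdpa)
```

## The problem

Spontaneous adverse-event reporting systems such as FAERS collect reports in
which a reporter names one or more suspect drugs and one or more MedDRA-coded
reactions. Because there is no denominator of exposed patients, the standard
analysis is *disproportionality*: for a drug–event pair, compare how often
the pair is reported against how often it would be reported if drug and event
were mentioned independently across the database. `faersdpa` implements that
analysis end-to-end for a single target event (by default the preferred term
"CONSTIPATION"), together with a Weibull time-to-onset (TTO) analysis and a
synthetic data generator that makes every stage testable offline.

A disproportionality signal is a *reporting* association. It is affected by
under- and over-reporting, channeling, and notoriety effects, and is a
hypothesis to investigate, never a causal estimate.

## From raw files to cases

FAERS quarters are `$`-delimited ASCII tables. The package reads DEMO, DRUG,
REAC and THER (INDI/OUTC/RPSR parse but are unused), maps legacy `ISR`/`CASE`
headers onto `primaryid`/`caseid`, and treats lines with a wrong field count
as malformed (counted, dropped, never fatal — the dialect cannot escape an
embedded delimiter).

One patient case (`caseid`) accrues several report versions (`primaryid`).
`dedup_cases()` keeps, per case, the version with the latest `fda_dt`,
breaking ties by the largest `primaryid` (numeric when both sides parse,
lexicographic otherwise). The source data dictionary only says duplicates
are removed; this particular rule is the widely used community convention,
and it is deterministic and idempotent, which the tests rely on.

Only drug mentions with role code `PS` (primary suspect) are analyzed;
secondary-suspect, concomitant and interacting mentions are dropped and
counted. All drop counts reconcile: rows in equal rows retained plus rows
dropped per named reason.

Dates (`FDA_DT`, `EVENT_DT`, `START_DT`) carry 4, 6 or 8 digits; precision
is derived from digit count alone, and an 8-digit string that is not a real
calendar date becomes an `invalid` marker rather than an error.

Ages are converted to years with the FAERS unit codes
(`DEC`×10, `YR`×1, `MON`/12, `WK`/52, `DY`/365.25, `HR`/8766); the age bands
are fixed to `<18`, `[18,40)`, `[40,65)`, `>=65`, unknown. Counting is
case-level everywhere by default (`dedup = FALSE` gives a report-level
sensitivity mode, since published tables are sometimes ambiguous about which
denominator was used).

## The 2×2 table and the four statistics

For a drug–event pair over `N` deduplicated cases:

|              | event | no event |
|--------------|-------|----------|
| drug (PS)    | a     | b        |
| no drug      | c     | d        |

* **ROR** `= ad/bc`, with the Woolf 95% CI
  `exp(ln ROR ± 1.96 √(1/a+1/b+1/c+1/d))`.
* **PRR** `= [a/(a+b)] / [c/(c+d)]`, reported with the uncorrected Pearson
  χ² of the table (a Yates-corrected variant sits behind `yates = TRUE`).
* **RRR** `= aN / ((a+b)(a+c))`, the observed/expected ratio; it underlies
  both MGPS and the information component.
* **MGPS / EBGM** and **BCPNN / IC**, described below.

Zero cells make some of these undefined. The package returns a typed
`NA`-plus-reason marker instead of silently adding 0.5 continuity
corrections; a correction exists only as the explicit Yates χ² option.
Ratios are computed in log space (sums of logs) so the large products
(`ad` with `N` in the tens of millions) keep full double precision.

Signal criteria (`signal_criteria()`) are the community standards: ROR
signals when `a ≥ 3` and the lower CI bound exceeds 1; PRR when `a ≥ 3`,
`PRR ≥ 2` and `χ² ≥ 4`; MGPS when `EB05 > 2`; BCPNN when `IC025 > 0`; a
drug is "any-signal" under the union. An undefined statistic never signals.

### Table-compatibility modes

Published signal tables do not always use the textbook estimators. Internal
consistency of the study table this package replicates shows:

* `EB05/EBGM = exp(−1.64 √(1/a+1/b+1/c+1/d))` in every row — i.e. EBGM was
  the *unshrunk* RRR with a one-sided log-normal 5% bound, not a posterior
  quantile. `ebgm_estimate(mode = "simplified")` reproduces exactly that.
* `IC − IC025 = 1.67` in every row — a constant-width bound matching no
  standard credible interval we know of. `bcpnn_ic(mode = "table_compat")`
  reproduces it verbatim (`IC = log2 RRR`, `IC025 = IC − 1.67`); its
  provenance is unknown, so it is quarantined behind the mode flag.

The principled alternatives are the defaults for new analyses:
`mode = "full"` MGPS (below) and the Norén-style IC,
`IC = log2((a+0.5)/(E+0.5))` with
`IC025 = IC − 3.3(a+0.5)^{−1/2} − 2.4(a+0.5)^{−1}`, `E = (a+b)(a+c)/N`.
`run_pipeline()` defaults to the compatibility modes because its purpose is
replication of published tables; both switches are exposed.

### Full MGPS

`mgps_fit_prior()` fits the two-component gamma mixture prior on the
reporting ratio λ by maximizing the negative-binomial mixture marginal
likelihood of all cells' observed counts given their expected counts, over
the five hyperparameters (two shape/rate pairs and the weight), from three
fixed starting points plus seeded jitters (deterministic given the seed).
`ebgm_estimate(mode = "full")` then uses the conjugate posterior — again a
two-component gamma mixture — to report `EBGM = exp(E[ln λ | a])` and EB05
as the posterior 5th percentile, root-found on the mixture CDF to 1e−8.

One subtlety the tests encode: EBGM is a posterior *geometric* mean, so with
no data it sits at the prior's geometric mean, which is below 1 even when
the prior's arithmetic mean is exactly 1 (for Gamma(2,2),
`exp(ψ(2) − ln 2) ≈ 0.76`). Shrinkage therefore pulls elevated cells into
the interval between the prior geometric mean and the raw RRR — not between
1 and the RRR, which a first reading might suggest.

## Time-to-onset and the Weibull shape test

TTO is `EVENT_DT − START_DT` in days, per target-event case and
primary-suspect drug, using the earliest day-precision therapy start
attached to that drug's sequence (when several therapy episodes exist the
first start is used; the alternative — last start — is not distinguishable
from the published description). Pairs are excluded, under named reasons
that reconcile with the candidate count, when the event precedes the start,
a date is missing or invalid, or either date has only month/year precision.

Same-day onsets would contribute `ln 0 = −∞` to the Weibull log-likelihood,
so they are retained as 0.5 day for fitting; descriptive medians and
quartiles count them as 0. Quartiles use linear interpolation between order
statistics (R's default type 7) — the convention is not identifiable from
published medians alone, so the common software default was fixed.

`weibull_fit()` maximizes the two-parameter Weibull likelihood (no
censoring) by damped Newton iterations on `(ln α, ln β)`, stopping when the
step norm falls below 1e−10 (Gumbel moment start, step-halving if a step
would reduce the likelihood). 95% CIs are Wald intervals from the observed
information on the log scale, back-transformed — so bounds are always
positive, unlike natural-scale Wald intervals which can dip below zero for
small samples; a percentile bootstrap (`ci = "bootstrap"`, fixed seed,
1000 resamples) is available for small `n`. Degenerate samples (n < 3,
non-positive values, all values equal — the shape diverges) are errors.

The failure classification reads the shape CI: entirely below 1 → `early`
(hazard decreasing with time on drug), entirely above 1 → `wear-out`,
covering 1 → `random`, anything non-finite → `indeterminate`.

## The synthetic generator

`synthetic_config()` defaults describe the study conditions this package is
built around: a 0.34% background target-event rate (the constipation share
of all ADEs in the full database), drugs spanning association strengths from
RRR ≈ 80 down to a slightly protective 0.9, early-failure Weibull onsets
(shapes 0.46–0.6, scales from ~9 to ~175 days), 5% duplicated case
versions, a few percent corrupted dates, and study-like sex/age/country
margins. The default of 50,000 reports keeps every listed drug's expected
event cell in the tens-to-hundreds, which is the regime the recovery
contracts address; tests that exercise bookkeeping rather than statistics
use smaller runs (500–20,000 reports) for speed.

Each report draws one PS drug from the marginal shares; the target event
fires with probability `min(1, background_rate × rrr_target)`; onsets are
drawn from the drug's Weibull and written as `START_DT`/`EVENT_DT` around a
report date inside the configured quarter. Duplicates get a fresh
`primaryid`, a later `fda_dt` and the same `caseid`. Corruption blanks,
truncates, or inverts the TTO dates of event reports at the configured
rates. A concomitant-role drug row is attached to ~30% of reports so the PS
filter is always exercised. The ground-truth ledger records the realized
2×2 cells per drug (exactly recoverable after deduplication, by
construction) and the true Weibull parameters; `ledger_check()` compares a
pipeline run against it.

One definitional point: `rrr_target` multiplies the *background* event
rate, while the RRR statistic compares a drug against the *database
average*, which the strong drugs themselves inflate. The ledger therefore
also records `implied_rrr` — the drug's event probability over the
share-weighted average event probability — and recovery tests compare the
estimate against that, within 3 standard errors of `ln RRR` (≈ `1/√a`).

What the generator deliberately does not emulate: misspelled or compound
drug names (the synonym map is exercised by fixtures instead), MedDRA
hierarchy structure, country- or time-varying reporting propensities, and
report-level covariate dependence. Passing recovery tests therefore shows
the estimators and bookkeeping are correct under the stated generative
model — not that real FAERS data are free of the biases disproportionality
is known to suffer.

## Replication from printed statistics

Raw FAERS-scale margins (`b`, `d`) are rarely printed, so the package ships
the published 30-drug statistic table (`published_signal_table()`) and
`replicate_from_printed()` applies the signal criteria directly to it,
reproducing the published per-algorithm counts (26/15/15/11, union 26) and
the per-drug significance marks without any raw data. For the
strongest-signal drug the full 2×2 table *is* recoverable:
`reconstruct_table_from_ror()` solves the drug-only cell from
`a`, `N`, the event margin and the printed ROR
(`b = a(N−a−c)/(ROR·c + a)`, rounded to a count), and the recomputed PRR,
χ², EBGM and EB05 agree with the printed row to well within 0.1%.

```{r replicate}
rep <- replicate_from_printed(published_signal_table())
rep$counts

t <- reconstruct_table_from_ror(a = 2369, n_total = 50659288,
                                event_total = 169897, ror = 115.51)
c(prr = prr_estimate(t)$prr, ebgm = ebgm_estimate(t, "simplified")$ebgm)
```

The shipped drug-class letters (`atc_classes()`) are static user-editable
data; two letters in the published ranking (duloxetine, capecitabine) appear
transposed relative to the ATC system, and the shipped map follows ATC
rather than replicating the transposition.

## Numerical and design choices, in one place

* Dedup key and tie-break: caseid → max `fda_dt` → max `primaryid`.
* Percentages for display: round half away from zero (2 dp in rankings and
  trends, 1 dp in demographics), matching published table conventions;
  full precision is kept in the JSON manifest.
* Rare-event agreement: ROR and PRR agree within 1% whenever the drug's
  event share and the event's drug share are both below 1% — a property
  test, and a useful sanity check on any new data.
* MGPS optimization: BFGS on log/logit-transformed hyperparameters,
  relative tolerance 1e−12, three fixed starts plus five seeded jitters;
  non-convergence from every start is an error carrying the best prior.
* Weibull Newton tolerance 1e−10 on the step norm; EB05 root-find tolerance
  1e−8; all statistics exact to double precision against direct formula
  evaluation (tested at 1e−10 relative on random tables).
* Problem sizes in the shipped tests: 1,000 random tables for oracle
  equivalence; Weibull recovery at n = 5,000 and CI coverage over 200
  replicates at n = 500; synthetic pipelines of 3,000–50,000 reports.

## Limitations

* Single-event design: no multiple-testing control across events, and no
  age/sex/period-stratified MGPS.
* No censoring or competing-risk model for TTO; only observed onsets are
  fitted, as in the replicated analysis.
* PT matching is exact string equality after normalization; no MedDRA
  SMQ/HLT expansion and no multi-ingredient product decomposition.
* The compatibility modes reproduce published numbers whose exact
  derivation is partly unknown (the constant 1.67 IC offset); they should
  not be used for new analyses.
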