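---
title: "Signal detection, risk modelling and onset analysis for spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal detection, risk modelling and onset analysis for spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
library(dplyr)
```

## The problem

Spontaneous adverse-event reporting systems such as FAERS collect
unverified safety reports: each report names one or more suspect drugs,
the coded adverse reactions (MedDRA Preferred Terms), sparse
demographics, outcomes, and — sometimes — therapy and event dates.
Signal detection asks whether a particular drug–event pair is reported
*disproportionately* often relative to everything else in the database.
`faersignal` implements the full desk workflow for one target event
(here the PT "hepatotoxicity" in reports on anti-neoplastic agents):
case extraction, four disproportionality statistics with their
conventional signal criteria, a screened LASSO → logistic risk-factor
model, and Weibull characterization of time-to-onset.

Because raw FAERS extracts are large and unversioned, the package pairs
every stage with a seeded synthetic-corpus generator whose ground truth
(injected reporting odds ratios, onset laws, duplicate and missingness
rates) is known exactly, so the whole pipeline is testable end to end.

## Case extraction

Reports are read from the "$"-delimited quarterly ASCII tables (DEMO,
DRUG, REAC, THER, OUTC, INDI) against an explicit per-table schema; the
modern post-2014 column set is the default, since silently sniffing
dialects is how reports get lost. Malformed lines are skipped *and
counted*; every log is attached to its result so the flow accounting
`raw = retained + excluded` can be asserted at each stage.

De-duplication follows FDA practice: among reports sharing a `caseid`,
keep the one with the latest FDA receipt date. The receipt-date rule
needs a tie-break, which the convention leaves open; we use the maximal
`primaryid` under zero-padded numeric comparison, which picks the
highest case version in FAERS numbering.

A report is a **case** iff the target PT matches one of its reaction
PTs (case-insensitive, exact — a single PT, not an SMQ or hierarchy
expansion) *and* it carries at least one Primary Suspect (PS) drug.
Only PS drugs attribute exposure; secondary-suspect and concomitant
roles never count. Drug names are free text, so a user-supplied lookup
maps case-folded names (trailing periods stripped, a common FAERS
artifact) to a normalized name and ATC code; unmapped names stay `NA`
and are tallied, never guessed.

Two harmonization choices are ours: ages in codes other than years are
converted (DEC ×10, MON /12, WK /52, DY /365.25) and implausible values
(> 120 y) set missing, both needed for the demographic strata; and the
reporter country is upper-cased but not otherwise recoded.

## Disproportionality statistics

Every drug gets a 2×2 table against the target event over de-duplicated
reports: `a` drug∧event, `b` drug∧other, `c` other∧event, `d` the rest.
The four classical measures are, with `N = a+b+c+d`:

* **ROR** = (a/c)/(b/d) — signal if the 95% CI lower bound > 1 and `a ≥ 3`;
* **PRR** = (a/(a+b))/(c/(c+d)) with Pearson's χ² (no continuity
  correction) — signal if PRR ≥ 2, χ² ≥ 4, `a ≥ 3`;
* **EBGM** = aN/((a+b)(a+c)) — the observed/expected relative reporting
  ratio. Note this is the *unshrunk* quantity, not DuMouchel's
  gamma-Poisson–shrunk MGPS; we implement the ratio as conventionally
  printed and document the difference here. Signal if EBGM05 > 2;
* **IC** = log2(EBGM) — signal if IC025 > 0 with `a > 0`. IC and EBGM
  share one computation, so `ic == log2(ebgm)` holds identically.

Interval bounds all share the variance term `v = 1/a + 1/b + 1/c + 1/d`:
`ROR CI95 = exp(ln ROR ± 1.96√v)`, `EBGM05 = exp(ln EBGM − 1.645√v)`
(one-sided 95%), `IC025 = IC − 1.96√v/ln 2`. These conventions were
chosen by internal consistency with published top-30 tables (a single
`v` reproduces both the printed EBGM→EBGM05 and IC→IC025 gaps to within
0.02), and the validation suite asserts exactly that.

Zero cells make the odds-scale estimates degenerate, so such tables
return `NA` scores with a structured reason and all flags `FALSE` —
never ±∞. No continuity correction is applied by default (an optional
`haldane = TRUE` adds 0.5 per cell). Ranking uses the ROR criterion as
the primary measure; the other three flags are reported alongside, not
intersected, since no intersection rule is standard.

```{r}
signal_scores(tibble::tibble(a = 10, b = 90, c = 100, d = 9900)) |>
  dplyr::select(ror, ror_lo, ror_hi, prr, chi2, ebgm, ic) |>
  as.data.frame()
```

## Risk-factor modelling

The unit of analysis is one row per de-duplicated report, outcome = the
case flag — the case/non-case design. The procedure is a three-stage
funnel:

1. **Univariate screen**: per drug, a single-predictor logistic fit
   (whose OR equals the 2×2 ROR). A drug passes iff its OR 95% CI lower
   bound exceeds 1, it has more than 100 target-event reports, and the
   Bonferroni-adjusted Wald p-value is below 0.01. We use the Wald
   logistic p (rather than a χ² test p); the two agree closely at these
   counts.
2. **LASSO selection** over the screened indicators, penalty chosen by
   10-fold cross-validated binomial deviance at `lambda.min` (the 1-SE
   rule is a flag), folds fixed by seed — the selected set is fully
   deterministic. Demographic covariates are *not* penalized; they
   enter only at the next stage, following the stated order of the
   procedure (drugs selected first, characteristics added after).
3. **Multivariate logistic** on the selected drugs plus age group, sex
   and weight group. Missing demographics are explicit `"Missing"`
   factor levels, not deleted rows — published strata tables report
   Missing categories, so those reports were evidently retained.
   Reference levels are the largest stratum. Terms are Bonferroni
   corrected over all reported coefficients; significance means
   adjusted p < 0.01.

Separation is detected by runaway coefficients (|β̂| or SE > 15) and
flagged rather than reported as a spurious huge OR.

## Time to onset

TTO = event date − therapy start date, in whole days, for PS drug
entries where both dates are complete valid 8-digit dates and the event
does not precede the start. Partial (year or year-month), missing,
invalid and negative-interval rows are excluded with per-reason
tallies. Same-day onsets are floored at 1 day rather than excluded:
published onset tables show per-drug medians of 1 day, so same-day
events were evidently retained, and the Weibull support requires
positivity. Quartiles use linear interpolation between order statistics
(hence fractional values like 9.25 days).

The two-parameter Weibull is fit by maximum likelihood via profile
likelihood: for fixed shape β the scale MLE is closed-form,
`α̂(β) = (mean(tᵢ^β))^{1/β}`, leaving a monotone one-dimensional score
equation solved to 1e−10 on geometric-mean-scaled data. Wald 95% CIs
come from the inverse observed information **on the natural scale**.
Log-scale intervals would be invariant-positive, but the natural-scale
convention is the one under which published tables print negative lower
scale bounds and under which the failure-type rule is stated, so it is
the default and only convention here. Failure type is read off the
shape CI: entirely below 1 → *early* (decreasing hazard), entirely
above 1 → *wear-out* (increasing hazard), else *random*. Degenerate
samples (all onsets equal, β → ∞) are rejected with a boundary flag;
per-drug fits require a minimum sample (default 10) below which only
the quartiles are reported.

Subgroup contrasts (e.g. fatal vs non-fatal) use the two-sided Wilcoxon
rank-sum test: exhaustive enumeration of rank assignments (mid-ranks
under ties) when both groups have ≤ 8 observations, the tie-corrected
normal approximation otherwise.

```{r}
onsets <- withr::with_seed(1, rweibull(300, shape = 0.7, scale = 45))
fit <- fit_weibull(onsets)
tidy(fit)
glance(fit)
```

## The synthetic corpus

The generator emulates the statistical structure the pipeline consumes,
with every injected quantity recorded in a truth ledger:

* Each report draws one PS drug: a profile drug by its use probability,
  else a background null drug. One PS drug per report keeps the 2×2
  counts unambiguous; multi-drug reports are a documented extension.
* The event probability for a profile solves
  `p_d/(1−p_d) = ROR_true · p₀/(1−p₀)` against the baseline rate `p₀`,
  so the drug's population reporting odds ratio against all other
  drugs equals its target. When several elevated drugs coexist the
  comparator arm is mildly contaminated and empirical 2×2 RORs sit
  slightly below target; the *conditional* logistic coefficients
  against the background reference recover the injected log-OR
  exactly, which is what the recovery tests measure.
* Onsets are continuous Weibull draws, ceiling-rounded to days with a
  1-day floor — matching how the pipeline's floor convention arises.
* Demographics use a mixture age distribution with most mass in
  18–64.9 y, lognormal weight, and missingness rates (40% age, 82%
  weight, 26% sex) mirroring published FAERS hepatotoxicity strata;
  duplicates (default 10%) are older versions of existing caseids;
  a configured fraction of reports gets corrupted dates (missing,
  partial, invalid, reversed).
* A fixed seed makes the corpus byte-identical; writing and re-reading
  it through the ASCII dialect reproduces the in-memory reports
  field-for-field.

What the generator does **not** emulate: free-text drug-name
misspellings beyond case/punctuation noise, multi-drug polypharmacy
reports, reporter-level correlation, secular trends in reporting rates,
and real MedDRA coding variability. Passing recovery tests therefore
demonstrates the pipeline's correctness under the stated reporting
model, not robustness to every pathology of real FAERS data.

## Descriptive outputs

`demographics_table()` reproduces the conventional strata layout. Each
report contributes one outcome by severity precedence Death >
Life-Threatening > Disability > Hospitalization > other; precedence
makes the outcome strata a partition (published tables sum to 100%),
and the specific order is our documented choice. Display percentages
round half-up at 2 decimals. Annual counts use the FDA receipt year by
default (event year by flag) — receipt year is the recency key already
used for de-duplication.

## Numerical and testing choices

* Problem sizes in the test-suite recovery experiments: 30,000-report
  corpora for screening/recovery properties (5 seeds), one
  50,000-report corpus with 5 injected (OR 5–10) and 15 null drugs for
  the end-to-end check, 20 seeds × n = 500 per shape for Weibull CI
  coverage. These sizes put Monte-Carlo bands comfortably inside the
  asserted tolerances.
* The null false-flag band for 15 null drugs allows ≤ 2 flags: the
  one-sided ROR criterion has a ~2.5% nominal rate, so ≥ 3 false flags
  has probability < 1% under the binomial.
* Weibull solver tolerances: score root to 1e−10, equivariance under
  day-unit rescaling holds to 1e−6.
* The χ² statistic is computed by the rank-1 shortcut
  `N(ad−bc)²/((a+b)(c+d)(a+c)(b+d))`; the suite checks it against the
  literal `Σ(O−E)²/E` form and `chisq.test(correct = FALSE)` to 1e−12.

## Known limitations

Disproportionality measures are associative, not causal; nothing here
adjudicates causality (e.g. RUCAM scoring), phenotypes liver injury
from laboratory values, or corrects for under-reporting. The EBGM
implemented is the unshrunk ratio, so small-count tables are noisier
than under a true gamma-Poisson shrinker. TTO treats onset as fully
observed — no censoring or competing risks.
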