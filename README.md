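# faersignal

Pharmacovigilance signal detection, risk-factor modelling and
time-to-onset analysis for FAERS-style spontaneous adverse-event
reports, as a tidy R pipeline.

Spontaneous reporting databases (such as the FDA Adverse Event
Reporting System) are the workhorse of post-marketing drug safety, but
they are messy: multiple versions of the same case, free-text drug
names, heavily missing demographics, partial dates. `faersignal`
implements the standard desk workflow for one target adverse event —
built and validated around hepatotoxicity of anti-neoplastic agents —
for pharmacoepidemiologists and safety scientists:

* **Ingestion** — reads the "$"-delimited quarterly ASCII tables
  (DEMO/DRUG/REAC/THER/OUTC/INDI) against explicit schemas,
  de-duplicates case versions (latest FDA receipt date per `caseid`),
  normalizes drug names to ATC via a lookup table, and flags cases by
  MedDRA Preferred Term with Primary-Suspect-only exposure attribution.
  Every step logs its row accounting; nothing is dropped silently.
* **Disproportionality** — per-drug 2×2 tables and the four classical
  statistics with their signal criteria:
  ROR = (a/c)/(b/d) (signal: CI95 lower > 1, a ≥ 3),
  PRR = (a/(a+b))/(c/(c+d)) with Pearson χ² (signal: PRR ≥ 2, χ² ≥ 4,
  a ≥ 3), EBGM = aN/((a+b)(a+c)) with one-sided EBGM05 (signal:
  EBGM05 > 2), and IC = log2(EBGM) with IC025 (signal: IC025 > 0).
* **Risk factors** — univariate logistic screen (OR CI lower > 1,
  > 100 cases, Bonferroni p < 0.01) → 10-fold cross-validated LASSO
  selection → multivariate logistic regression with age/sex/weight
  covariates (explicit Missing levels) and Bonferroni-corrected terms.
* **Time to onset** — per-drug onset days from therapy start to event
  date with reasoned exclusions, median/IQR, two-parameter Weibull MLE
  (profile likelihood; natural-scale Wald CIs) and failure-type
  classification from the shape CI: β CI < 1 *early*, CI ∋ 1 *random*,
  CI > 1 *wear-out*; Wilcoxon rank-sum subgroup comparison (exact by
  enumeration for small groups).
* **Synthetic corpus** — a seeded generator of FAERS-shaped corpora
  with known injected reporting odds ratios, Weibull onset laws,
  duplicates, missingness and corrupted dates, so the whole pipeline
  is testable without the live database.

## Worked example

Generate a 20,000-report synthetic corpus with three injected
hepatotoxicity signals and run the full pipeline:

```r
library(faersignal)

profiles <- dplyr::bind_rows(
  synth_profile("MERCAPTOPURINE", "L01BB02", 0.03, 12, 200, 0.5),
  synth_profile("LETROZOLE",      "L02BG04", 0.05,  8,  85, 0.9),
  synth_profile("PACLITAXEL",     "L01CD01", 0.05,  5,  55, 1.8)
)
cfg <- synth_config(n_reports = 20000, drug_profiles = profiles,
                    baseline_event_rate = 0.02, seed = 42)
res <- run_pipeline(list(synth = cfg))

signal_table(res$ranked)
#>             drug cases           ror_ci      prr_chi2 ebgm_ebgm05
#> 1 mercaptopurine   120 7.60 (6.13-9.43) 6.34 (464.03) 5.43 (4.53)
#> 2      letrozole   140 5.44 (4.46-6.62) 4.80 (350.30) 4.05 (3.43)
#> 3     paclitaxel    77 2.44 (1.91-3.12)  2.33 (53.95) 2.18 (1.78)
```

All three injected drugs are flagged by the ROR criterion. The
empirical RORs sit below the injected 12/8/5 because each drug's 2×2
comparator ("all other reports") contains the other elevated drugs;
the conditional odds ratios from the multivariate model recover the
injected values against the clean background reference:

```r
res$forest[1:2, c("term", "odds_ratio", "ci_lo", "ci_hi", "significant")]
#>             term odds_ratio ci_lo ci_hi significant
#> 1      letrozole       6.76  5.52  8.28        TRUE
#> 2 mercaptopurine       9.60  7.70 11.96        TRUE
```

Onset analysis recovers each drug's generating hazard regime from the
fitted Weibull shape and its 95% CI:

```r
res$tto_by_drug[1:3, c("drug", "n", "median", "beta", "failure_type")]
#>             drug   n median  beta failure_type
#> 1      letrozole 137     49 0.980       random
#> 2 mercaptopurine 118    126 0.536        early
#> 3     paclitaxel  75     50 1.731     wear_out
```

The run log carries the flow accounting (`22000` raw rows → `2000`
duplicate versions removed → `705` cases), and passing `out_dir =`
writes `signals.csv`, `forest.csv`, `tto.csv`, `demographics.csv`,
`annual.csv` and `run_log.json`, byte-identical on rerun with the same
seed.

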