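# citscore

Statistical scoring and three-way judgment for the **Concealed
Information Test (CIT)** — the memory-detection polygraph paradigm in
which an examinee's autonomic responses to one crime-relevant item are
compared with responses to several matched irrelevant items. `citscore`
is for psychophysiologists and forensic examiners who already have
per-presentation scalar responses (after signal preprocessing) and need
objective, explainable statistics and decisions on top of them.

## What it computes

For a session with $k$ items presented $r$ times each, on up to four
measures (SCR, HR, RLL, NPV, or any custom measure with a declared
response direction):

* **Effect size d** — the standardized mean difference between relevant
  and irrelevant responses,
  $d = \mathrm{dir}\cdot(\bar{x}_\mathrm{rel} - \bar{x}_\mathrm{irr})/s_p$
  with the pooled SD
  $s_p = \sqrt{((n_1-1)s_1^2 + (n_2-1)s_2^2)/(n_1+n_2-2)}$ from the
  unbiased group variances; the direction flip ($-1$ for HR, RLL, NPV)
  makes positive d always mean "responded like a recognizer". Measures
  are integrated by averaging, skipping any that are missing.
* **Randomization-test p** — the real mean difference is ranked among B
  (default 1000) differences generated by randomly relabeling which
  response cells are "relevant" (the 50th largest of 1000 ⇒ p = 0.05);
  per-measure p-values are multiplied across measures and the product is
  calibrated against its own permutation null, yielding an integrated p
  that is valid under cross-measure dependence. Small designs switch to
  exact exhaustive enumeration automatically.
* **Lykken score** — the traditional 2/1-points-per-block comparator.
* **Three-way judgments** — *recognized / inconclusive / unrecognized*
  at the published threshold presets, for known-solution CITs
  (d: 0.4/0, lenient 0.3/0.1; p: 0.025/0.6, lenient 0.05/0.4) and
  searching CITs where every item is scored and the max-d / min-p item
  is judged (d: 0.6/0.2; p: 0.01/0.2), including the two searching
  false-positive types.
* **Cohort evaluation** — inconclusive/hit/correct-rejection rates,
  trapezoidal ROC AUC, published-bin score tables, and a synthetic
  cohort generator emulating the 80-recognizing / 72-unrecognizing
  laboratory study design the thresholds come from.

## A worked example

```r
library(citscore)

cfg <- cit_synthetic_config(seed = 11)          # 5 items x 5 reps, 4 measures
s   <- simulate_cit_session(cfg, recognizing = TRUE, seed = 3)
fit <- cit_score(s, B = 1000, seed = 42)
summary(fit)
#> Per-measure CIT scores, session 'sim':
#>  measure     d     p lykken
#>      SCR 0.761 0.068      7
#>       HR 0.714 0.080      5
#>      RLL 0.625 0.112      6
#>      NPV 1.351 0.002      8
#> integrated:
#>      d      p lykken
#>  0.863  0.002  6.500
judge_cit(fit, cit_preset("known_d"))
#> CIT judgment: RECOGNIZED (basis: d)
```

Each measure responds in its expected direction (all per-measure d > 0);
the integrated d = 0.863 clears the strict 0.4 cutoff and the integrated
p = 0.002 is far below 0.025, so both statistics agree the (simulated)
examinee recognizes the relevant item. A cohort run:

```r
res <- run_cit_pipeline(list(n_recognizing = 30, n_unrecognizing = 30,
                             B = 500, seed = 5), out_dir = NULL)
res$evaluation$d$rates
#> $inconclusive_rate        33.3
#> $hit_rate                 86.4
#> $correct_rejection_rate   83.3
res$evaluation$d$auc
#> [1] 0.853
```

i.e. a third of this small noisy cohort lands in the inconclusive band;
among conclusive cases 86% of recognizers and 83% of non-recognizers are
judged correctly.

Real sessions are read from plain long-format CSV
(`read_cit_session()`; one row per measure/item/repetition plus a small
metadata header), and the same pipeline is scriptable from a shell via
`inst/cli/cit.R` (`simulate`, `score`, `judge`, `run` subcommands; item
positions in output are 1-based).

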