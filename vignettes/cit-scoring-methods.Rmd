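---
title: "Statistical scoring of the Concealed Information Test: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical scoring of the Concealed Information Test: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(citscore)
```

## The problem

The Concealed Information Test (CIT) probes recognition memory rather than
deception: an examinee is shown one crime-relevant item (say, the stolen
*ring*) embedded among several plausible foils, each presented several
times, while autonomic activity is recorded. An examinee who recognizes the
relevant item tends to show a larger skin conductance response (SCR) to it,
together with a slower heart rate (HR), suppressed respiration (summarized
as respiration line length, RLL) and peripheral vasoconstriction
(normalized pulse volume, NPV). Someone without the crime knowledge cannot
distinguish the items, so responses are exchangeable across them.

`citscore` implements the statistical layer that turns per-presentation
scalar responses into a three-way judgment -- *recognized*, *inconclusive*,
or *unrecognized* -- using two complementary statistics designed for field
use: an effect size `d` and a randomization-test `p`. Both are simple to
explain, need no normative database, and tolerate missing measures. The
package deliberately does **not** process raw signals (ECG, pulse waves,
respiration belts); its unit of input is a `cit_session`: one scalar per
(measure, item, repetition) cell.

## The effect size d

For one measure, let the relevant item have $n_1$ responses (one per
repetition; $n_1 = 5$ in the standard 5-item, 5-repetition design) and the
irrelevant items $n_2 = n_1 (k - 1)$ responses for $k$ items. With unbiased
group variances $s_1^2, s_2^2$, the pooled standard deviation is

$$ s_p = \sqrt{\frac{(n_1 - 1)s_1^2 + (n_2 - 1)s_2^2}{n_1 + n_2 - 2}}, $$

and $d$ is the standardized mean difference
$(\bar{x}_\text{rel} - \bar{x}_\text{irr}) / s_p$, multiplied by the
measure's expected direction ($+1$ for SCR, $-1$ for HR, RLL and NPV) so
that positive $d$ always means "responded as a recognizing examinee
would". Per-measure $d$ values are integrated by an arithmetic mean;
missing measures (about a quarter of examinees are electrodermal
non-responders) are simply skipped.

Two deliberate strictness choices: the unbiased ($n-1$) variances require
at least two responses per group, so single-repetition sessions are
rejected for $d$ (Lykken scoring still works); and a zero pooled SD makes
$d$ undefined -- `cit_d()` raises an error, `cit_score()` records the
session as degenerate, and judgment treats it as inconclusive rather than
inventing $\pm\infty$. Responses are used exactly as supplied: no
within-session standardization is applied before computing $d$, matching
the published formula.

## The randomization test p

The randomization test asks how often a response difference as extreme as
the observed one arises by randomly relabeling which cells are "relevant".
One relabeling draws $n_1$ of the $n_1 + n_2$ cells (uniformly, without
regard to items) and computes the same mean difference. With $B$
relabelings (default $B = 1000$), the per-measure p-value is $x/B$ where
the real difference is the $x$-th largest generated difference for SCR, or
the $x$-th smallest for HR/RLL/NPV.

Implementation details that the bare description leaves open:

* **Rank and tie rule.** $x = 1 + \#\{\text{generated differences at
  least as extreme as the real one}\}$, clipped to $[1, B]$. Ties count
  against significance, so fully constant data give $p = 1$, while a real
  difference beating every generated one gives $p = 1/B$, never 0. For
  tie-free data this is exactly the published "$x$-th largest" rule
  ($x = 50 \Rightarrow p = 0.05$).
* **The observed labeling is not added** to the generated set in
  Monte-Carlo mode; the $+1$ in the rank plays the equivalent anti-zero
  role. In exhaustive mode the true labeling is necessarily part of the
  enumeration, so the $+1$ is dropped.
* **Exhaustive enumeration** replaces sampling automatically when
  $\binom{n_1+n_2}{n_1} \le 10{,}000$ (configurable); small designs are
  then exact.
* **Arithmetic path.** The real difference is computed through the same
  vectorized sum formula as the generated ones, so in exhaustive mode the
  observed subset ties itself exactly in floating point.

**Integration across measures.** The per-measure p-values from the *same*
relabelings are multiplied ("original multiplied p"). Because the
measures are dependent and a product of p-values is not itself a p-value,
the product is calibrated against its own permutation null: each
relabeling $b$ receives a pseudo-p per measure (the self-inclusive rank of
its generated difference among all $B$, in the measure's direction), the
pseudo-p's are multiplied across measures, and the integrated p is the
rank of the original product among the $B$ generated products, divided by
$B$. Sharing one set of relabelings across measures is essential: it
preserves the cross-measure correlation under the null, which is what
makes the calibrated product valid. A session's relabelings are also
shared across the items of a searching CIT, making the five per-item
p-values comparable.

The pseudo-p of relabeling $b$ ranks $b$ among all $B$ generated
differences including itself; ranking among the other $B - 1$ would change
results by at most $1/B$.

## Lykken scoring

The traditional comparator: within each repetition block the
(direction-adjusted) largest response scores 2 and the second largest 1;
the relevant item's points are summed over blocks, giving a score in
$[0, 2 n_\text{reps}]$, then averaged across measures. Under exchangeable
items a 5-item block contributes $(2+1)/5 = 0.6$ on average. The score is
rank-based, hence invariant to monotone transforms, but it always awards
points -- even when no response stands out -- which is why it lacks an
inconclusive band and why no decision thresholds are published for it.
Ties (measure zero for continuous data) share the contested rank by a
random draw, reproducible under a seed.

## Decision thresholds

`cit_preset()` ships the published threshold pairs verbatim:

| preset | recognized | unrecognized |
|---|---|---|
| `known_d` | d > 0.4 | d < 0 |
| `known_d_lenient` | d > 0.3 | d < 0.1 |
| `known_p` | p < 0.025 | p > 0.6 |
| `known_p_lenient` | p < 0.05 | p > 0.4 |
| `searching_d` | max d > 0.6 | max d < 0.2 |
| `searching_p` | min p < 0.01 | min p > 0.2 |

Everything between the two cutoffs is inconclusive. The published bands
are strict inequalities on both sides, leaving the cutoff values
themselves undefined; this package assigns boundaries to the inconclusive
band, the conservative choice (for continuous scores the event has
probability zero; for the lattice-valued p it matters and stays
conservative). In a searching CIT every item is scored as if relevant and
the extreme statistic (max d or min p) is judged; the per-item p-values
are *not* multiplicity-corrected -- the stricter searching thresholds are
the published instrument for family-wise control, and the two resulting
false-positive types are reported separately by
`searching_error_decomposition()`. An optional conjunctive rule
(`judge_both()`) demands agreement of d and p and is otherwise
inconclusive; single-statistic judgment remains the default because the
published thresholds are per statistic.

## The synthetic cohort generator

No public CIT dataset accompanies the published thresholds, so testing
and demonstration rest on a simulator that mirrors the laboratory study
behind them: 80 recognizing and 72 unrecognizing examinees, five items by
five repetitions, four measures with the conventional directions, and a
25% electrodermal non-responder rate (`nonresponder_mode = "drop"`
removes SCR entirely, exercising the missing-measure paths; `"noise"`
keeps it present but effect-free).

Responses are Gaussian with unit baseline SD -- the simplest model
consistent with what is known -- with these tunables:

* `delta`: per-measure shift of the relevant item's expected response, in
  SD units, applied in the measure's direction. The default reference
  profile (SCR 0.85, HR 0.45, RLL 0.60, NPV 0.45) keeps SCR the most
  diagnostic channel and was scaled **once**, on a 24,000-session cohort,
  so that the default cohort's integrated-d AUC lands near the published
  0.92 (we obtained 0.9198). That is a tuning target for realism, not a
  claim that the simulator reproduces the real data's distributions.
* `rho` (default 0.3): equicorrelation of the noise across measures
  within a cell, implemented as a shared cell factor
  ($\sqrt{\rho}\, z_\text{cell} + \sqrt{1-\rho}\, z_m$). The real
  within-examinee measure correlations are unpublished; 0.3 is a moderate
  default and a free parameter for sensitivity analysis.
* `habituation` (default 0): geometric decay of the effect,
  $\delta (1 - h)^{r-1}$ at repetition $r$, reflecting that reactivity
  declines over a session.

What the simulator does *not* emulate: non-Gaussian response shapes,
item-specific salience differences, inter-individual reactivity
differences beyond the non-responder dichotomy, habituation of the
baseline noise, or countermeasures. Passing tests on synthetic cohorts
therefore validate the *statistical machinery* (calibration, recovery,
monotonicity, rates), not field performance; the published real-data
AUCs (0.92 for d and p, 0.90 for Lykken) and hit/correct-rejection rates
cannot be reproduced without the original dataset and are treated as
external context only.

A useful consequence of the design worth knowing when interpreting
recovered effects: the pooled-SD estimator at $n_1 = 5$, $n_2 = 20$ is
slightly biased, so the mean recovered $d$ for a true unit shift is not 1
but $\sqrt{df/2}\,\Gamma(\frac{df-1}{2})/\Gamma(\frac{df}{2}) \approx
1.0342$ at $df = 23$ (the reciprocal of the usual small-sample bias
correction). The parameter-recovery tests check against this value, not
against 1.

## Numerical and interface choices

* Item positions are 1-based everywhere, as native to R; files mark an
  unknown relevant item as `"unknown"`.
* Sessions are stored as plain long-format CSV with a commented metadata
  header (item order, relevant item, measure directions); values are
  written with 17 significant digits so a write/read round trip is
  bit-identical. Measure directions are data, not code: any measure name
  may be declared with a direction, the four standard ones are presets.
* A measure must be entirely present or absent; partial grids are
  rejected rather than imputed (the missing-measure rules cover whole
  measures only).
* Binned cohort summaries use the published bin edges (d:
  $<-0.2, -0.2..0, 0..0.2, 0.2..0.4, 0.4..0.6, >0.6$; p: $0..0.025,
  0.025..0.05, 0.05..0.1, 0.1..0.2, 0.2..0.4, 0.4..0.6, 0.6..0.8,
  0.8..1$), left-closed right-open with the last bin absorbing its upper
  boundary; any convention matches for continuous scores.
* Rates with empty denominators (e.g. correct rejection in an
  all-recognizing cohort) are reported as `NA`, never as 0 or 100.
* Degenerate (constant-response) sessions are counted as inconclusive by
  the cohort evaluation and flagged via `cit_score()$degenerate`.
* Analyses use every provided repetition; discarding a warm-up first
  presentation, where practiced, belongs to upstream preprocessing.

## Problem sizes used in the shipped checks

The test-suite simulations are sized for tight Monte-Carlo error at
interactive runtimes: 2,000 sessions for null calibration of the
integrated p ($B = 1000$), 2,000 recognizing sessions for parameter
recovery, 12,000 blocks for the Lykken null mean, $B = 10{,}000$ against
exhaustive enumeration on the 15- and 220-labeling designs, and 400 + 400
sessions per point of the effect-size/AUC monotonicity grid. All
tolerance bands are 3--4 Monte-Carlo standard errors, fixed before the
runs by the binomial or empirical variance of the quantity checked.

## A worked example

```{r example}
cfg <- cit_synthetic_config(seed = 11)
s <- simulate_cit_session(cfg, recognizing = TRUE, seed = 3)
fit <- cit_score(s, B = 1000, seed = 42)
summary(fit)
judge_cit(fit, cit_preset("known_d"))
judge_cit(fit, cit_preset("known_p"))
```

And a small cohort evaluation:

```{r cohort}
res <- run_cit_pipeline(list(n_recognizing = 30, n_unrecognizing = 30,
                             B = 500, seed = 5), out_dir = NULL)
res$evaluation$d$rates
res$evaluation$d$auc
```

## Known limitations

Judgments apply to a single CIT question; combining several questions
into a case-level verdict is out of scope, as are raw-signal
preprocessing, facial/thermal/ocular measures, and machine-learning
classifiers (which published comparisons found no better than d and p on
the reference dataset, while requiring a training database). The
thresholds shipped here were derived from one laboratory dataset;
applying them to field data without revalidation is the user's
responsibility.
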