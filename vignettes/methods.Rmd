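---
title: "Statistical methods for forum-based pharmacovigilance signal detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for forum-based pharmacovigilance signal detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
library(dplyr)
```

## The data model

pvsignal works on *annotation corpora*: tables with one row per annotation
line extracted from a web-forum post. A line can describe a drug mention, an
adverse-drug-event (ADE) mention, or both at once; only a line that carries
**both** a normalized MedDRA preferred-term (PT) code and an ATC level-5
code is a *drug–ADE couple*, the unit on which signal detection operates.
Couples are never inferred by joining separate lines of one post: the
annotator asserts the relationship by emitting both entities on one line.
Partial lines (a verbatim without a normalized code, or a PT without an ATC
code) are ordinary, expected data and are kept — they contribute to
descriptive statistics and to the per-post universe, but not to couple
counts.

Absent values are empty CSV cells (an em-dash placeholder on input is also
accepted and normalized to absent). Dates are canonically ISO 8601; the
reader also accepts English "October 8, 2018"-style dates because published
excerpts use them. Text is UTF-8 with French diacritics preserved verbatim.

MedDRA is licensed and cannot be redistributed, so the package bundles a
*synthetic toy vocabulary* (50 PTs with HLT/HLGT/SOC assignments, 40 ATC
codes) sufficient for simulations, examples and tests. Any real vocabulary
with the same columns can be supplied through `pv_vocabulary()`.

## Descriptive statistics

`corpus_summary()` separates post-level counts (distinct post ids) from
annotation-level counts (lines), because a post routinely carries several
annotations. Reported percentages are rounded half-up to 2 decimals, the
precision used in published per-forum tables; ranked distributions
(`rank_by()`) sort by decreasing count with a lexicographic tie-break so
output is deterministic, and compute cumulative percentages on the full
total *before* any top-n truncation. `f1_from_pr()` returns the harmonic
mean at full precision rather than pre-rounded: rounding inside the function
would break the bound `min(P, R) <= F1 <= max(P, R)` at the boundaries, so
rounding to the 3 printed decimals happens at report time.

## Disproportionality: PRR and ROR

With exposure denominators unknown in spontaneous-report-like data,
disproportionality compares reporting rates inside the corpus. For a 2×2
table of couple *events* (a: drug and ADE of interest; b: drug, other ADE;
c: other drug, ADE; d: neither),

$$\mathrm{PRR} = \frac{a/(a+b)}{c/(c+d)}, \qquad \mathrm{ROR} = \frac{ad}{bc},$$

both 1 under independence. Events are counted with multiplicity: a pair
annotated three times in one post contributes three events. Confidence
intervals are standard Wald intervals on the log scale,

$$\ln \mathrm{PRR} \pm 1.96\sqrt{\tfrac1a - \tfrac1{a+b} + \tfrac1c - \tfrac1{c+d}},
\qquad
\ln \mathrm{ROR} \pm 1.96\sqrt{\tfrac1a + \tfrac1b + \tfrac1c + \tfrac1d},$$

the field's default when no interval formula is otherwise specified. A
*signal* is flagged when the lower bound of the 95% CI of the log estimate
exceeds 0.

Zero cells: the default `strict` policy returns an explicit not-computable
row rather than a silent infinity whenever a defining cell is zero (`a` or
`c` for PRR; any cell for ROR). The Haldane–Anscombe continuity correction
(+0.5 to every cell) is available as `zero_cell = "haldane"` for sparse
early months of cumulative series. `cumulative_prr_series()` interprets the
monthly evolution as *cumulative-from-start* windows — each month's estimate
uses all events up to that month's end — which is the natural reading for a
monitoring dashboard; a rolling window is a conceivable alternative but is
not implemented.

```{r prr-example}
prr(c(10, 90, 100, 9900))
```

## The class-imbalanced subsampling lasso

Disproportionality is univariate and can be confounded by co-reported
drugs. The multivariate detector regresses per-post ADE presence on the
presence indicators of all $N_m$ drugs in the corpus with an L1 penalty:

$$\mathrm{logit}\, P(\mathrm{ADE}=1 \mid X) = \alpha + \sum_{i=1}^{N_m} \beta_i\,\mathrm{Drug}_i .$$

Because posts without the ADE dominate, each of $B = 250$ draws resamples,
with replacement, $n_1$ posts from the case set and
$R = \max(4 n_1,\, 4 N_m)$ posts from the non-case set (a case-control-like
ratio, with the $4 N_m$ floor guaranteeing enough observations for the
predictor count). Within a draw the penalty follows the glmnet path from
the largest $\lambda$ downward; path points whose active set exceeds
`max_predictors` (default 50) drugs are inadmissible, and among the
admissible ones $\lambda$ is chosen by BIC. When many drugs compete the
cap binds and the choice is the smallest admissible $\lambda$, the direct
reading of the model-size constraint; when the corpus holds fewer drugs
than the cap the constraint cannot bind, and without the BIC choice the
path would run to an essentially unpenalized fit — sign noise then inflates
per-drug false retention under the null to 7–10%, where the BIC-penalized
fit keeps it at the nominal level while leaving genuine effects (designed
odds multiplier 5) retained. A per-draw cross-validated $\lambda$ is
available behind `lambda_rule = "cv"` for sensitivity analyses. The
intercept is never penalized. Binary indicators share a scale already, so
predictors are not standardized.

Retention uses the distribution, across draws, of each drug's coefficient
(0 when the drug is absent from a draw's model): drug $i$ is retained when
the $q$-th percentile (linear interpolation between order statistics,
`quantile(..., type = 7)`) of that collection is strictly positive, with
$q \in \{5, 10, 15\}$. Smaller $q$ demands positivity deeper into the left
tail and is therefore the *stricter* rule, giving nested retained sets
$q{=}5 \subseteq q{=}10 \subseteq q{=}15$. The phrase "number of times the
drug was selected" admits a second reading — the 0/1 selection indicators
rather than the coefficients — which is exposed as `mode = "selection"`
(retention then means selection in at least roughly $100-q$ percent of
draws). The two modes can genuinely differ: a drug with many small positive
and a few negative coefficients may pass the selection-count rule yet fail
the coefficient rule.

Draw-level reproducibility comes from deriving each draw's seed
deterministically from the master seed. A draw that fails to fit is redrawn
once with a derived seed and otherwise recorded as all-zero with a warning
counter — a conservative choice that can only push percentiles toward
non-retention.

## Change-point detection on monthly series

For a monthly count series the CUSUM path accumulates deviations from the
segment mean, $S_0 = 0,\ S_i = S_{i-1} + (x_i - \bar x)$; a sustained mean
shift produces a V-shaped path whose extremal range
$s_{\mathrm{diff}} = \max S - \min S$ carries the evidence, and the largest
$|S_i|$ marks the last point of the pre-shift regime. Significance is
assessed by a permutation bootstrap: the segment's values are reordered
(sampling without replacement) `n_bootstrap = 1000` times, and the
confidence of a change is the fraction of permutations with a strictly
smaller range. Under an i.i.d. null this confidence is approximately
uniform, so the 0.95 threshold controls the per-segment false-detection
rate near 5%. Detection recurses on the sub-segments before and after each
accepted breakpoint until none is found.

Two placement details are deliberate. The breakpoint locator in
`detect_breakpoints()` restricts candidates to positions at least
`min_segment_length` (default 6) months from either segment edge: this
guarantees that emitted breakpoints are pairwise separated by at least one
minimum segment and avoids unstable edge placements, at the cost of never
flagging a shift in the first or last few months of a segment
(`cusum_path()` exposes the unrestricted argmax). Ties in $|S_i|$ break to
the earliest index. The statistic analyzed is the raw monthly count; no
smoothing is applied.

## The synthetic corpus generator

Real scraped corpora cannot be redistributed, so validation uses a
generator whose defaults define the package's reference study conditions.
Per post it draws a forum (configured mixture), a month (uniform unless a
volume shift applies), independent Bernoulli drug mentions, and ADE
mentions from the logistic model above with designed odds multipliers
$\rho$ — `rho = 1` everywhere is exact independence, and a designed pair
$(\rho \ge 5,\ 2000$ posts$)$ is comfortably recoverable. Temporal
structure is injected as a step multiplier from month $\tau$ onward on
post volume, one drug's mention odds, or one pair's association odds.

One generator choice matters statistically: posts whose draws produce no
catalog mention still emit a single *unnormalized* complaint line (verbatim
only, no codes), as real annotator output does. Dropping those posts
entirely would condition the corpus on "at least one normalized mention" —
a collider that measurably attenuates designed odds ratios (an effect
designed at $\rho = 5$ shrank to an observed odds ratio of about 1.4 in a
2000-post corpus) and would bias the lasso's baseline. With the complete
post universe retained, per-post models see the designed effects.

What the generator does *not* emulate: linguistic content (verbatims are
lowercase label variants), duplicate or fraudulent posts, per-forum topic
differences beyond the mixture weights, annotation errors, or
within-thread correlation between posts. Passing recovery tests therefore
demonstrates correctness of the statistical machinery under the designed
model, not robustness to NLP noise or dependent posts.

`scenario_levothyrox()` packages a 50-month scenario tuned to the shape of
a real thyroid-drug episode: one community forum carrying 82% of posts, a
fivefold mention surge for an ATC H03AA01 drug at month 25, and a designed
association ($\rho = 4$) between that drug and the tiredness PT. At the
default 6000 posts (~120/month) the surge is a recoverable change point
and the pair's cumulative PRR signal is on from the surge month onward.

```{r scenario, fig.width = 6, fig.height = 3}
sc <- scenario_levothyrox(seed = 1)
ser <- monthly_series(sc$corpus, unit = "couples",
                      atc = "H03AA01", meddra = "10016256")
bp <- detect_breakpoints(ser, seed = 1)
bp
plot_monthly_series(ser, breakpoints = bp)
```

## Problem sizes and numerical choices

Validation suites run the generator at sizes chosen to balance statistical
resolution against desk-scale runtimes: calibration of mention frequencies
at 20,000 posts (3-standard-error tolerance), disproportionality
calibration on 3 × 64 designed-independent pairs at 20,000 posts, lasso
recovery at 2000 posts × 30 drugs × 20 replicates with the full $B = 250$,
null-retention at 100 replicates of a single-drug design, and change-point
recovery on 48-month series with 1000 permutations. Percentile convention,
rounding rules, tie-breaks and zero-cell policies are fixed and documented
above so that identical inputs and seeds reproduce identical outputs
byte-for-byte.

## Known limitations

* Wald intervals are first-order; for very sparse tables the `haldane`
  policy changes estimates materially, and neither matches exact or
  Bayesian intervals.
* The lasso assumes drug mentions imply intake and adjusts only for
  co-mentioned drugs; age, sex and indication are unobserved in forum data.
* The change-point locator's edge restriction trades sensitivity at the
  series boundaries for placement stability.
* The generator's independence across posts ignores thread dynamics
  (bursts of correlated posts), which in real data inflate both
  disproportionality variance and change-point false alarms relative to
  the i.i.d. calibration shown here.
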