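---
title: "Sequential likelihood-ratio diagnosis of coronary occlusion: model, catalog, and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequential likelihood-ratio diagnosis of coronary occlusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omibayes)
```

## The diagnostic model

`omibayes` treats the diagnosis of occlusion myocardial infarction (OMI) as a
running probability rather than a binary ECG rule. The engine is Bayes'
theorem in its odds–likelihood-ratio form: a pre-test probability $P$ is
converted to odds $O = P/(1-P)$, multiplied by the likelihood ratio of each
new finding, and converted back, $P' = O'/(1+O')$. Because LRs multiply,
findings can be layered in any order at full precision; the posterior depends
only on the product of the applied LRs (`chain_update()` verifies this
*collapsibility* to $10^{-12}$ in the test suite).

The model's assumptions are worth stating plainly:

* **Conditional independence.** Each LR is applied as if the finding were
  independent of the others given disease status. Clinically co-linear
  findings (two anterior-lead occlusion signs, say) violate this, and serial
  multiplication then double-counts evidence. This is not a footnote — it is
  the framework's main failure mode, and the cohort simulator below exists to
  make it measurable.
* **Transportability of published LRs.** The catalog's symptom LRs were
  pooled across acute-coronary-syndrome populations, not OMI specifically;
  the ECG tier accuracies come from occlusion-verified series. Users with
  better local estimates should edit the catalog, not the code.
* **A probability is never 0 or 1.** Degenerate priors are rejected
  (`prob_to_odds(0)` is an error, not 0): the state must remain updatable,
  and a "pathognomonic" result (specificity 1, infinite LR+) is flagged as a
  boundary rather than applied as a multiplier.

## The evidence catalog

All numbers ship in one human-editable YAML file with three sections.

**Anchors.** Baseline OMI prevalence among ED chest-pain patients by age
band, for women, derived as: STEMI ED-visit rate per 10,000 encounters ÷
the ~5% chest-pain share of ED visits × 1.7 (the OMI:STEMI prevalence
ratio, since ~30% of NSTEMIs hide an occluded culprit). Male sex multiplies
the *odds* by 1.3 at any age. The oldest band (≥ 85) is capped at 25%,
rounded down deliberately for very frail populations. `catalog_validate()`
re-derives every band; one published value (the 35–44 STEMI prevalence,
0.82% versus the pipeline's 0.80%) disagrees with its own derivation and is
carried as an explicit whitelist entry — reproduced verbatim, never silently
corrected. Band boundaries are closed–open on integer years ([18, 35), …);
patients under 18 fall back to the youngest band with a warning, because the
surveillance data contain no pediatric stratum but the engine still needs an
anchor (the first shipped case is a 17-year-old).

**Clinical features.** Pre-ECG LR+/LR− pairs for fifteen chest-pain
descriptors, with 95% CIs. Some source rows report only a span of
individual-study estimates ("worse with exertion, 1.5–1.8") with no pooled
point; the catalog stores the midpoint as the point value and the span as
the interval, marked `range: true`. The midpoint convention is this
package's choice, declared rather than silent.

**Tests.** ECG tiers (ST-elevation-only; comprehensive occlusion-sign
reading; an AI classifier at its published operating point of Sn 0.80 /
Sp 0.98) and troponin entries. Entries carrying sensitivity and specificity
have `LR+ = Sn/(1-Sp)` and `LR- = (1-Sn)/Sp` derived at load time; the
initial-troponin entry instead states its published LRs (1.4 / 0.28)
directly, exactly as the case walkthroughs apply them. The serial-rise entry
(Sn 1.0, Sp 0.837) has LR− = 0 — a boundary the lookup refuses to apply as
a finite multiplier.

## Rounding: two deliberate arithmetic modes

The published case walkthroughs round intermediate probabilities to bedside
precision and chain *from the rounded value*: the printed 0.8% pre-ECG
probability feeds the printed 9.2% post-ECG probability, which unrounded
chaining would put at 9.5%. The engine therefore supports two policies:

* `full_precision()` — machine precision throughout; order-invariant;
  what you want for computation.
* `printed_checkpoint()` — after each step the probability is rounded
  **half-up on the percent scale** to a declared number of decimals before
  the next LR applies; what you need to reproduce published or bedside
  arithmetic. Half-up (not banker's rounding) matches how people round.

`replay_case()` goes one step further for the five shipped fixtures: at each
printed checkpoint it compares the recomputed value against the published one
(tolerances: ±0.1 percentage points for one-decimal checkpoints, ±1.0 for
integer ones, and a tighter ±0.02 for the single two-decimal checkpoint) and
then continues from the printed value, mirroring the source's own sequencing.
One checkpoint ("17%", where exact recomputation gives 16.4%) is a nomogram
read-off imprecision in the source; the tolerance policy absorbs it, and the
fixture annotates it. Across all five cases the full-precision and
printed-checkpoint posteriors differ by under two percentage points — the
test suite quantifies this rather than assuming it.

## Decision thresholds

`recommend()` maps a posterior to `surveillance`, `activate_cath`
(posterior strictly above 10%), or `activate_cath_and_lysis_eligible`
(strictly above 75%). Whether a posterior of exactly 10% should activate is
genuinely unspecified in the source; this package chose strict inequality
(the boundary falls to the lower tier) and documents it here and in the
function help. The pragmatic cut-points approximate the classical
test/treatment threshold calculus; `pauker_kassirer_thresholds()` implements
the standard textbook expressions — reconstructed, since the source cites
but does not print them — so users can check how the 10%/75% landmarks
relate to explicit benefit/harm ratios. The tier strings deliberately avoid
prescriptive verbs, and every assessment report embeds a non-optional
disclaimer: the framework is didactic decision support, not a device.

## Nomogram geometry

The Fagan nomogram is implemented as geometry, not as a picture: left axis
ordinate $-\log_{10}(\text{pre-test odds})$, right axis
$+\log_{10}(\text{post-test odds})$, middle axis $\log_{10}(LR)/2$. With the
axes equally spaced, $\log O' = \log O + \log LR$ *is* the collinearity of
the three anchor points; the half-span middle axis is forced by that
identity, and `nomogram_read_off()` recovers the posterior purely by line
intersection (agreeing with `apply_lr()` to $10^{-9}$ over random grids —
the geometry is the arithmetic). Axis ranges are 0.1%–99.9% for
probabilities and 0.001–1000 for LRs; out-of-range inputs are clipped with a
warning, never silently. SVG output is plain text, timestamp-free, and
byte-identical for identical inputs, so figures can be golden-file tested;
chained updates render as a ladder of lines on one canvas, each step's
posterior becoming the next prior.

## The cohort simulator: what it emulates, and what it does not

`simulate_cohort()` generates patients under the framework's *own* generative
assumptions: disease ~ Bernoulli(prevalence); each finding positive with
probability Sn in the diseased and 1 − Sp in the healthy; findings
conditionally independent at `rho = 0`. Under these conditions the chained
posterior is exactly the Bayes-correct conditional probability — the test
suite proves this by exhaustive enumeration of all findings-patterns for
three findings (`enumerate_posteriors()`, the independent oracle) and by
logistic calibration regression on simulated cohorts (slope ≈ 1,
intercept ≈ 0 at n = 100,000, the size chosen so binomial error bars are
tight while the whole suite stays fast on one CPU).

Setting `rho > 0` couples the findings through an equicorrelated Gaussian
copula within each disease class: marginal Sn/Sp are preserved, but findings
co-occur, so serial multiplication over-counts shared evidence. At
`rho = 0.5` with three duplicated ECG-grade findings the calibration slope's
95% CI already excludes 1 at n = 100,000 — the quantitative face of the
independence caveat. The copula is a deliberately simple mechanism: the goal
is to demonstrate and measure the failure mode, not to model any specific
clinical correlation structure.

What the simulator does *not* emulate: real symptom prevalence patterns,
age-mixed cohorts (a demographic-mix mode would need a target composition
the evidence base does not supply), measurement timing, or repeat testing.
Passing calibration here shows the arithmetic is self-consistent — it says
nothing about how well the catalog's LRs transport to any real service line.
Findings specified only by LRs are converted to (Sn, Sp) either exactly
(from an LR+/LR− pair) or by fixing the false-positive rate (LR+ only), and
the solved values are logged, never assumed silently.

## Numerical choices, degenerate inputs, tie-breaks

* Probabilities are fractions everywhere internally; percent appears only at
  I/O boundaries (reports print one decimal). This prevents 9.2-vs-0.092
  scale bugs by construction.
* Round trips `odds_to_prob(prob_to_odds(p))` reproduce `p` to $10^{-12}$;
  an LR of exactly 1 is an exact no-op rather than a floating-point round
  trip, so neutrality is exact.
* Half-up rounding uses `floor(x * 10^d + 0.5 + 1e-9)`; the epsilon guards
  values that are exact halves in decimal but sit one ulp below in binary.
* Rounding inside `printed_checkpoint()` can land on 0% or 100%; the result
  is clamped one part in $10^{12}$ inside the open interval so the chain
  stays updatable.
* Monte-Carlo interval propagation draws each LR independently log-normally,
  centered on the *point value* with the spread implied by the CI width
  (`sd = (log hi - log lo) / (2 * 1.96)`). For CIs asymmetric about the
  point on the log scale this is an approximation, consistent with the
  independence approximation the whole chain already makes. Draws are seeded
  and reproducible.
* Ties at decision thresholds fall to the lower tier (strict `>`), and
  `policy_sweep()` uses the same convention, so the two never disagree at a
  boundary.

## Problem sizes

The shipped tests replay all five cases (milliseconds), check geometry and
arithmetic properties on grids of a few hundred points, propagate intervals
at up to 100,000 draws, and run calibration cohorts of 100,000 patients
(seconds each). These sizes were chosen to make binomial and Monte-Carlo
error bars small relative to the effects being asserted.

## Known limitations

* The serial-multiplication model is only as good as conditional
  independence; the simulator quantifies the breakdown but the engine does
  not correct for it (no multivariable adjustment is attempted).
* Catalog LRs are point estimates from heterogeneous sources; interval
  propagation expresses their sampling uncertainty but not their
  transportability.
* The anchor table has no pediatric stratum, no demographic mix other than
  age band and sex, and inherits one internal inconsistency from its source
  (whitelisted, see above).
* Bedside subtleties — gestalt, symptom topography, comorbidity context —
  carry no published LRs and therefore no representation here; the catalog
  format exists so they can be added when estimates appear.
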