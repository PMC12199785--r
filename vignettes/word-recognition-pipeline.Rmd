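---
title: "Scoring infant word recognition from gaze and pupil data: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring infant word recognition from gaze and pupil data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

wordgaze implements a complete analysis pipeline for longitudinal infant
word-recognition studies that combine two eye-tracking paradigms with
parent-reported vocabulary. This vignette explains the measurement models,
the preprocessing rules and their exact boundary conventions, the
statistical stage, the synthetic-data generator that stands in for real
recordings, and the design decisions that were genuinely open.

## The two eye-tracking measures

**Preferential looking (looking-while-listening).** On each test trial a
spoken sentence labels one of two pictures; the labelled target and the
distractor then appear side by side for 2500 ms. Word recognition shows up
as more looking at the named picture. Looking times are accumulated inside
an analysis window from 367 to 2500 ms after picture onset — the lower edge
discounts the latency infants need to program an eye movement in response
to speech. Gaze samples are classified into two areas of interest (AOIs) of
11° × 13.6° of visual angle, one per picture.

The outcome corrects for picture-level attractiveness biases. For a picture
$X$ of a pair, let $P(X \mid X\ \text{target})$ be the mean proportion of
AOI looking directed at $X$ on valid trials where $X$ was labelled, and
$P(X \mid X\ \text{distractor})$ the corresponding proportion when the
other picture was labelled. The picture-level difference is

$$ d_X = P(X \mid X\ \text{target}) - P(X \mid X\ \text{distractor}), $$

and the pair score is the mean of the two picture-level differences. A
picture that attracts gaze regardless of the label contributes the same
proportion in both roles, so any fixed bias cancels exactly; a label-blind
looker scores 0 in expectation, a perfect recognizer scores 1. The
participant's wave score is the mean over valid pairs.

Two proportions conventions were possible and the source text does not
choose between them: proportions here use **target + distractor AOI time**
as the denominator (the looking-while-listening convention), not window
duration; trials with no AOI looking contribute no proportion at all.
Validity rules: a trial needs valid on-screen gaze in at least 30% of the
window (about 640 ms); a pair needs the subtraction to be computable
(each role observed for at least one picture); a participant needs at least
4 of the 8 pairs, otherwise the wave score is missing and flows into the
imputation stage.

The units question — "mean score across valid trials" versus "a single
score per item pair" — is resolved as *pair-then-mean*: proportions are
pooled to one score per pair, and the participant score averages pair
scores. The subtraction that defines the score is a pair-level quantity, so
averaging anything finer would mix items with different bias corrections.

**Mismatch pupillometry.** A label is spoken, an occluder rises (motion
onset 360 ms after the experimenter's button press, offset at 760 ms), and
the revealed object either matches (congruent) or violates (incongruent)
the label. Mismatch detection is indexed by pupil dilation. Each trial's
left-eye pupil trace is baseline-corrected subtractively with the 360 ms
interval before occluder motion, and summarized by the mean corrected
dilation over the 1200 ms window that starts at motion offset. The
participant score is

$$ \Delta = \bar{p}_{\text{incongruent}} - \bar{p}_{\text{congruent}}, $$

so a positive score means a larger pupil on incongruent trials. The source
description of the subtraction order contradicts its own sign convention;
the sign convention wins here (it is the interpretable statement), and the
opposite order is available via
`analysis.mm_sign_convention: congruent_minus_incongruent`.

## Preprocessing rules and boundary conventions

The pipeline freezes the following stage order for pupil data, and tests
guard it, because the median filter and the interpolation do not commute
next to spike-adjacent gaps:

1. range filter → 2. moving median → 3. gap interpolation →
4. baseline correction → 5. window mean.

Exact conventions, each configurable but defaulting to the published value:

| rule | default | boundary convention |
|---|---|---|
| gaze gap interpolation | < 14 samples (≈117 ms at 120 Hz) | strictly shorter: a 13-sample gap is filled, a 14-sample gap is not |
| pupil gap interpolation | ≤ 14 samples | inclusive: a 14-sample gap is filled, 15 is not |
| pupil keep-range | 1.5–9 mm | inclusive: exactly 1.5 or 9 mm is kept ("outside the range" is discarded) |
| moving median | 14 samples | left-biased centre for the even window; edges truncated; missing samples skipped, never invented |
| PLP trial validity | ≥ 30% valid on-screen gaze in the window | applied after interpolation |
| MM trial validity | ≤ 50% missing over baseline ∪ window | *more than* 50% excludes, exactly 50% is kept |
| MM inclusion | ≥ 5 valid trials per condition | both conditions |
| CDI inclusion | ≥ 90% of 90 items answered | 81 items exactly (⌈0.9·90⌉) |

The "14-sample moving median average filter" of the source is not a
standard single filter; it is implemented as a plain moving median of
window 14, which is the robust interpretation that actually removes
single-sample blink artifacts. Gaps are always represented as in-grid
invalid samples rather than dropped rows, so gap lengths are countable in
samples and the two interpolation rules are well defined. Interpolation
never changes an originally valid sample and never extrapolates into edge
gaps.

Coordinates use the screen's top-left origin in pixels, and AOIs are
half-open rectangles $[x_0, x_1) \times [y_0, y_1)$, so every point on
screen belongs to at most one AOI and edge behaviour is unambiguous. Visual
angles convert through $w = 2D\tan(\theta/2)$ at viewing distance
$D = 600$ mm. The horizontal placement of the AOI centres is not printed in
the source ("off-center"); the default of ±8° is configurable
(`aoi.center_offset_deg`) and keeps the default AOIs fully on a 22-inch
1920×1080 screen without overlap.

Event clocks differ by paradigm and follow each paradigm's natural anchor:
preferential-looking streams are timed from picture onset, mismatch streams
from the experimenter's button press.

## The statistical stage

Because CDI and pupil measures are skewed and outlier-prone, associations
use **Spearman's rho**: the Pearson correlation of mid-ranks (tie-aware),
with two-sided p-values from the $t$ approximation on $n-2$ df. Partial
correlations follow the standard nonparametric-partial convention:
rank-transform the continuous variables, keep binary covariates as 0/1,
residualize on the covariate matrix, correlate residuals, with
$df = n - k - 2$. With an empty covariate set this reduces exactly to the
zero-order statistic. P-values are reported two-sided and uncorrected; the
report objects carry a multiplicity note rather than an adjustment, since
the analysis plan applies none.

**Missing data.** Wave-by-measure outcome scores (13 variables: 8 CDI, 3
preferential-looking, 2 mismatch) are imputed once by
expectation-maximization under a multivariate normal model: E-step
conditional moments per missingness pattern, M-step mean and ML (1/n)
covariance, iterated until the relative change in the observed-data
log-likelihood falls below 1e-6 (cap 500 iterations; non-convergence is
flagged and the last iterate returned). Imputed cells are conditional means
— single deterministic imputation, no residual draws — and are deliberately
**not clipped** to observed ranges, so a 0–90 checklist score can receive a
negative imputation; that is a property of the method, not a bug.
Imputation happens at the outcome level, not the CDI item level, matching
how the scores enter the analysis. Which variables enter the EM model
jointly is configurable; the default is the 13 outcomes.

**Little's MCAR test** uses the same ML estimates: for each missingness
pattern $j$ with $n_j$ rows and observed set $o_j$,

$$ d^2 = \sum_j n_j\,(\bar{y}_{j,o_j} - \hat\mu_{o_j})^\top
   \hat\Sigma_{o_j}^{-1} (\bar{y}_{j,o_j} - \hat\mu_{o_j}),
   \qquad df = \sum_j |o_j| - p, $$

referred to a χ². Calibration was verified by simulation (1000 MCAR
replicates at n = 300, three variables, 10% missingness: rejection rate
0.04–0.044 at α = 0.05) together with near-complete power against strongly
MAR missingness at n = 500.

**Sensitivity analysis.** `min_detectable_r()` root-finds the smallest
population correlation reaching a target power for the two-sided test of
zero correlation. Two routes are implemented: the Fisher-z approximation
(closed form $\tanh[(z_{1-\alpha/2}+z_{\text{power}})/\sqrt{n-3}]$) and the
exact bivariate-normal route, which integrates the exact density of the
sample correlation (Gauss hypergeometric series; the integral of the
density was verified to be 1 and the power at the root was verified by
Monte Carlo). At n = 70, α = 0.05, power 0.80 the exact route gives
0.3273 and Fisher-z 0.3295 — both round to 0.33. The quadrature is
restricted to |ρ| ≤ 0.999; beyond that the density is too concentrated for
reliable numerical integration, and no practical sensitivity analysis
lives there.

Descriptives report median, SD (n−1), adjusted Fisher–Pearson skewness G1
and sample excess kurtosis G2 (the SPSS/SAS "type 2" conventions, via
e1071), so rows are directly comparable with published descriptive tables.
The reading-habits covariate is the mean of the two item z-scores
(frequency and duration of reading, each coded 0–3), not re-standardized:
its sample mean is 0 by construction and its SD is below 1 unless the
items correlate perfectly — matching the published mean of 0.00 with SD
below 1.

## The synthetic cohort

No real recordings ship with the package; the generator produces complete
studies with known ground truth so every stage is testable end to end.

* **Design generators** reproduce the published task structures: 4 warm-up
  trials (single picture alternating L, R, L, R) plus 32 test trials from 8
  pairs with each picture labelled twice, no pair on consecutive trials,
  and no three consecutive same-side targets; 64 mismatch trials from 16
  words × 4 presentations (2 congruent / 2 incongruent), congruency runs of
  at most 2, no word three times in a row; attention getters after every
  8th (preferential looking) or 4th (mismatch) trial. The side-constraint
  wording is ambiguous ("not … on the same side for more than one trial");
  the default reads it as *no three in a row*, with the stricter
  alternation reading behind `strict_side = TRUE`. Sequencing uses
  randomized greedy construction with a feasibility guard and restarts, so
  every seed yields a valid sequence (checked over 1000 seeds in the
  tests).
* **Gaze micro-model:** within a trial the eye produces a sequence of
  fixations with exponential dwell times (mean 400 ms, floor 80 ms). Each
  fixation lands away from the AOIs with a wave-specific probability
  (0.30/0.22/0.08 at 10/11.5/18 months — attentiveness grows with age, and
  40% of away fixations leave the screen entirely), otherwise on the target
  with probability $0.5 + \text{preference} + (b_T - b_D)$, where the $b$'s
  are per-picture attractiveness biases (SD 0.05). This is the simplest
  model whose looking proportions are directly controllable, which is what
  the recovery tests need. A per-sample track-loss hazard of 0.07 with
  geometric mean gap length 12 samples yields roughly 26 valid trials of 32
  at the first wave and realistic exclusion rates in both tasks — chosen to
  mirror the published valid-trial counts.
* **Pupil micro-model:** participant baseline (4 ± 0.3 mm) plus
  trial-level variation (0.1 mm) and a random linear drift (0.1 mm/s SD),
  an event-evoked rise after occluder motion offset with time constant
  75 ms whose *sample-grid mean over the analysis window is normalized to
  1*, amplitude 0.1 mm plus the participant's true congruency effect δ on
  incongruent trials, white noise (0.05 mm), the same gap process, and rare
  out-of-range artifacts (rate 0.001) that exercise the 1.5–9 mm filter.
  Normalizing the kernel's window mean makes the injected amplitude
  recoverable as the corrected window mean without a shape-dependent
  correction factor.
* **Participant model:** one latent ability per child (standard normal)
  drives the looking preference (0.03 + 0.15·ability), the per-wave pupil
  congruency effect (group means −0.05/+0.05 mm at 10/11.5 months with
  ability slopes +0.02/−0.05 — emulating the observed developmental sign
  reversal), and CDI growth: scores are
  $\mathrm{round}(90\,\sigma(\eta))$ with per-wave intercepts set so the
  expected trajectories rise from near floor (production at 10 months) to
  near the 90-item ceiling (comprehension at 24 months), ability slope 0.8
  and noise 0.6 on the logit scale. Covariate marginals (70% university
  education, 76% monolingual households, 16% family history) follow the
  published sample description.
* **Missingness** is MCAR at the measure level by default (CDI 5%,
  eye-tracking technical loss 10–17% per wave, matching the reported
  technical losses of 7 and 12 participants), with an MAR mode (missingness
  loaded on ability) for the MCAR-test power checks.

What the generator does **not** emulate: saccade dynamics and smooth
pursuit, pupil foreshortening with gaze angle, autocorrelated measurement
noise, luminance responses, item-level CDI responses, or attrition that
depends on temperament. Passing recovery tests therefore demonstrates that
the scoring and inference machinery is correct and unbiased under a
controlled data-generating process — not that the paradigms themselves are
valid measures in real infants.

## Problem sizes used in the checks

The property suite runs at the sizes that make its tolerances meaningful,
chosen once: design constraints over 1000 seeds; null preferential-looking
cohort of 10,000 simulated participants (|mean score| < 0.01); mismatch
effect recovery at 200 trials per condition × 100 replicates per
δ ∈ {−0.07, 0, +0.07} mm (±0.01 mm); EM correlation recovery at n = 2000
with 20% MCAR (±0.05); MCAR-test calibration over 1000 replicates
(0.05 ± 0.02); and a full 70-participant pipeline run repeated to verify
byte-identical determinism under a fixed seed.

## Known limitations

* The exact-power quadrature limit (|ρ| ≤ 0.999) is irrelevant in practice
  but means `min_detectable_r()` cannot chase absurd targets (e.g. power
  0.999999 at n = 5).
* The EM stage assumes joint normality of the 13 outcomes; with integer,
  ceilinged CDI scores this is an approximation — the same one the
  published analysis makes — and out-of-range imputations are its visible
  symptom.
* Little's test, like all omnibus MCAR tests, has limited power against
  weak MAR mechanisms; a non-significant result supports but does not prove
  MCAR.
* The pair-score denominator excludes non-AOI looking; cohorts differing in
  overall attentiveness can have equal scores with very different amounts
  of usable gaze, which is why the exploratory attentiveness summary
  (total looking per trial, paired t-tests between waves) is part of the
  report bundle.
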