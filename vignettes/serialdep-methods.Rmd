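---
title: "Methods: serial-dependence psychophysics, decoding, and brain-behavior linking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: serial-dependence psychophysics, decoding, and brain-behavior linking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serialdep)
```

## The problem

Serial dependence is the attractive perceptual bias that makes a current
stimulus appear more similar to recently seen ones. In magnitude perception
it can be probed with an inducer–reference–probe paradigm: a task-irrelevant
*inducer* dot array (modulated in numerosity, duration and dot size)
precedes a constant *reference* (16 dots, 200 ms, 6 px), which the observer
compares against a variable *probe*. If the inducer attracts the perceived
reference magnitude, the point of subjective equality (PSE) shifts with the
inducer level. The electrophysiological counterpart is that the magnitude of
the *previous* stimulus can be decoded from the multichannel evoked response
to the *current* one, and the strength of that neural signature may predict
the behavioral bias across subjects.

`serialdep` implements this full analysis chain — psychometric estimation,
time-resolved multivariate decoding with an empirical shuffled-label null,
and a per-window mixed-model brain–behavior regression protected by a
cluster permutation test — together with a synthetic-data generator that
emulates both an active discrimination experiment and a passive
magnitude-stream experiment with known ground truth, so every stage is
testable by parameter recovery.

## Synthetic data generator

**Designs.** `generate_design_exp1()` builds the full 2×2×2 factorial of
inducer numerosity (12/24 dots), duration (140/280 ms) and dot size
(4/8 px), crossed with five task-specific probe levels ({8,12,16,24,32}
dots, {100,140,200,280,400} ms, or {3,4,6,8,12} px), each cell repeated
`n_reps_per_cell` times (default 10, i.e. the canonical 400-trial session in
10 blocks of 40). The stated session total of 400 trials is only consistent
with the full 8×5 crossing at 10 repetitions per cell, which is what the
generator produces. Whether the three inducer dimensions were fully crossed
or independently randomized in the original paradigm is not derivable from
the design counts; the full crossing is assumed because it preserves both
balance and the total. `generate_design_exp2()` builds the 3×3×3 passive
stream (levels bracketing the reference on each dimension), 80 repetitions
per combination in 8 blocks of 270 trials, with 10 low-contrast catch trials
per block (contrast 0.7 of standard, a 3.7% catch rate) drawn from the
standard combinations so the 80-per-combination count is preserved. Each
stream trial carries the previous trial's magnitudes as its past labels;
the first trial of each block has no usable past (blocks are separated by
breaks, so carrying labels across them would be wrong for real sessions).

**Observer.** Responses are Bernoulli draws from a lapse-corrected
cumulative Gaussian,
$$P(\text{"probe greater"}) = \lambda/2 + (1-\lambda)\,
\Phi\!\left(\frac{x - \mathrm{PSE}_{trial}}{\sigma}\right),$$
with $\mathrm{PSE}_{trial} = \mathrm{PSE}_{base} + \sum_d s_d\, b_d/2$,
where $s_d = \pm 1$ for a high/low inducer level on dimension $d$ and
$b_d$ is that dimension's full PSE separation in probe units. Positive
$b_d$ is attractive. Defaults: $\sigma = 2$ probe units, $\lambda = 0.05$.

**Epochs.** `simulate_epochs()` builds trials × channels × time arrays on
an exact $-200..700$ ms grid. Defaults are desk-scale: 250 Hz and 32
channels (a typical laboratory recording at 2048 Hz would be decimated to
a similar rate before windowed decoding anyway); tests use even smaller
grids. Each epoch is the sum of

* a class-independent evoked template (damped Gaussian deflections after
  stimulus onset) scaled by fixed per-channel gains,
* per dimension, $s_d \cdot A_{subj} \cdot a_w \cdot \mathbf{w}_d$ inside
  each configured signal window ($A_{subj}$ the subject amplitude, $a_w$
  the window amplitude, $\mathbf{w}_d$ a unit-norm topography vector), and
* AR(1) noise (lag-1 autocorrelation 0.9, marginal SD 1) mixed across
  channels by a random unit-row matrix per subject.

The AR(1)-plus-spatial-mixing noise is the minimal structure that makes
channel selection and window averaging non-trivial; it does not attempt
blinks, drifts, or a forward head model, and passing tests on it says
nothing about artifact robustness on real recordings.

**Coupling.** `simulate_cohort()` draws a per-subject amplitude
$A_i \sim \mathcal N(\mu_A, \sigma_A)$ truncated at 0, sets the true
behavioral effect to $\beta_0 + \beta_1 A_i + \varepsilon_i$ (percent), and
converts it into the observer's bias on the task dimension via the exact
inverse of the effect index, so the generative effect is recovered by the
downstream formula without approximation.

## Psychometric estimation

`fit_psychometric()` maximizes the binomial log-likelihood of the
lapse-corrected cumulative Gaussian over $(\mu, \log\sigma)$ (Nelder–Mead,
relative tolerance 1e-10). Choices worth stating:

* **Lapse** is fixed at $\lambda = 0.05$, split equally between floor and
  ceiling, the standard symmetric finger-error model; it is not estimated.
* **Axis.** Fits are on the linear magnitude axis, since PSEs are reported
  in raw stimulus units.
* **PSE** is $\mu$, the median of the cumulative Gaussian. **JND** is read
  off the lapse-corrected curve: the probe distance between the 50% and
  75% response points, $\sigma \cdot z^*$ with
  $\Phi(z^*) = (0.75 - \lambda/2)/(1-\lambda)$. **WF** is JND/PSE.
* **Degenerate data** (all responses one way) are flagged non-converged
  with a boundary estimate, never a silent success; a PSE outside the probe
  range sets a boundary flag.

The effect index is $\mathrm{Eff} = (\mathrm{PSE}_{high} -
\mathrm{PSE}_{low})/\mathrm{PSE}_{low} \times 100$, computed from fits
split by the low/high level of one inducer dimension with the others
marginalized. One 400-trial session estimates the PSE separation with a
sampling SD of roughly 0.8 probe units (most probes sit far from the PSE),
so recovery tests average over simulated observers rather than asserting
tight bands on single sessions.

The "nonlinear regression" of per-trial responses is realized as a binomial
GLM with logit link — the canonical model for 0/1 responses — with the
response recoded so 1 = "reference greater" and all predictors (probe and
the three inducer magnitudes) coded as ratios to the reference magnitude;
the probe is ratio-coded too for scale comparability. Positive inducer
coefficients then mean attraction. Perfect separation is reported as
non-convergence.

## Time-resolved decoding

Per subject and dimension, epochs are split by the binarized past level
(12 vs 24 dots, 140 vs 280 ms, 4 vs 8 px; intermediate past levels of the
passive stream are dropped, not pooled). The decoding protocol per
iteration (default 30, final accuracy = mean over iterations; iteration
$i$ reseeds at `seed + i` so each is independently reproducible):

1. average activity in 100 ms windows stepped by 20 ms (windows indexed by
   start time; a window covers $[t, t+100)$ ms);
2. randomly partition each class into disjoint groups of `pseudo_k` trials
   (default rule: `min(20, floor(n/10))` clipped to \[10, 20\], emulating
   a 10–20 trial average adapted to the available data; remainder
   discarded) and average each group into a pseudo-trial (10 per class);
3. leave-one-pseudo-trial-out (one per class per fold): on the training
   fold only, rank channels by one-way ANOVA F and keep the top 5 (ties to
   the lower index), z-score features with training statistics, train a
   linear SVM with C = 1, and classify the two held-out pseudo-trials.

The SVM kernel, regularization and scaling are not uniquely determined by
the protocol's verbal description; linear kernel with C = 1 and
training-fold z-scoring is the standard configuration of the toolboxes
used for this kind of analysis and is fixed here. The empirical chance
level comes from the identical pipeline with training labels shuffled
within every fold (`null_decode_timecourse()`); latency-window summaries
(early 50–200 ms, late 500–650 ms) average the windows *fully contained*
in the interval — the conservative, unambiguous reading — and group tests
compare subjects' actual accuracies against the null mean with one-sample
t tests, FDR-adjusted within each latency window. Temporal generalization
trains at one window and tests at all others with the same folds, channel
selection and scaling as the diagonal, so its diagonal reproduces the
timecourse decoding exactly.

## Brain-behavior linking

The specified model is `Eff ~ CA + (1 | Subj)`. With one effect index and
one accuracy per subject — the design's situation — the random-intercept
variance is unidentifiable, and the only well-defined reading is the fit
that the mixed model profiles to: the ordinary least-squares solution.
`fit_effect_ca_lme()` therefore returns the OLS slope, t, p and R² in that
case (verified against the closed form to 6 decimals), and an actual
`lmer` fit with marginal R² (fixed-effect variance over total variance,
labeled as such) when subjects repeat.

The per-window regression is applied across the whole epoch; windows with
zero accuracy variance (saturated decoding) yield NA records rather than
aborting the timecourse. Clusters are maximal runs of at least two
consecutive windows with p < 0.05. Each cluster is then evaluated by
permutation: effects are shuffled across subjects, accuracies are shuffled
independently across subjects at each window *within the cluster*, the
regression is refit per cluster window (via the closed-form t, identical
to the model fit in this design), and a permutation succeeds if it shows
at least the cluster's length of contiguous windows with |t| at or above
the cluster's own minimum |t|. The p value uses the add-one estimator
$(s+1)/(n_{perm}+1)$ — the raw proportion can return an exact zero, which
misstates the resolution of a finite permutation test.

### A calibration caveat, and why it is left visible

This cluster test, exactly as described, is a *per-cluster robustness
quantification*, not a selection-corrected significance test. The
permutation is confined to the cluster's own windows and thresholds at the
cluster's own minimum |t| — but the cluster was found by scanning the whole
timecourse for extreme excursions. The shuffled data are never subjected to
that selection step, so the permutation p approximates the joint local p of
the cluster's windows, which is small for essentially any cluster that
forms, including clusters arising from smooth noise under a true null. The
package's calibration test simulates null cohorts (coupling slope 0,
temporally smooth accuracy fields) and quantifies this: the fraction of
null clusters declared significant far exceeds the nominal level, under
either reading of the within-cluster shuffle (independent per window, as
implemented following the procedure's description, or one joint subject
permutation across windows). A calibrated alternative would permute at the
whole-timecourse level and compare maximum run lengths, but that is a
different procedure from the one this package sets out to implement.
Users should read `perm_p` as "how unlikely is an excursion of this height
and length at these windows under re-pairing", not as a family-wise error
rate. The calibration test is kept failing-by-design in the acceptance
suite as an explicit record of this property.

## Inferential utilities

One-sample and paired t tests report Cohen's d (mean difference over the
SD of the sample or of the pairwise differences); behavioral batteries
default to two-tailed tests, while the power analysis is one-tailed (the
direction of the attractive effect is hypothesized). FDR adjustment is
Benjamini–Hochberg step-up, applied within explicitly configured batteries
(here: within each latency window), never implicitly.
`min_sample_size()` scans n over the exact noncentral-t power
$1 - F_{t,\nu,\delta\sqrt n}(t_{crit})$ and returns the smallest n
reaching the target; at d = 0.55, one-tailed α = 0.05 and power 0.9 it
returns 30, the design's sample-size basis. (At d = 1 the exact power at
n = 10 is just below 0.9, so the answer is 11 — rounding the asymptotic
approximation down to 10 would overstate the power.)

## Problem sizes used by the tests

The test and acceptance suites choose sizes that keep the full run in the
minutes range while leaving every assertion statistically meaningful: unit
tests decode 4–8-channel epochs at 100 Hz with 2–6 iterations; the
chance-level calibration uses 10 subjects at the full 8-channel, 250 Hz,
30-iteration configuration; effect-recovery runs use 100 simulated
observers; the cluster-permutation calibration uses 200 reduced cohorts
(20 subjects, 20 windows, 500 permutations) with simulated accuracy fields
— the permutation machinery is exercised exactly, only the SVM front end
is bypassed there, since its output under the null is already
characterized by the chance-level calibration; the end-to-end coupling
recovery runs 16 subjects with 6 decoding iterations and 1,000
permutations.

## Known limitations

* The generator's epochs contain no artifacts, eye movements, or realistic
  volume conduction; channel-selection behavior on real data may differ.
* Decoding is binary only (low vs high past level); no multiclass or
  continuous-magnitude decoding.
* The cluster permutation inherits the calibration caveat above.
* Reaction times are not modeled; behavioral summaries are
  choice-probability based.
* With one observation per subject the "mixed model" is OLS by necessity;
  repeated-measures designs engage the true random-intercept fit but have
  no special support beyond it (no random slopes).
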