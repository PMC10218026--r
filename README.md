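# serialdep

An R package for analyzing **serial dependence** — the attractive
perceptual bias that makes a current stimulus look more similar to
recently seen ones — in magnitude perception (numerosity, duration, size),
together with its electrophysiological signature. It is aimed at
psychophysicists and cognitive neuroscientists who want a tested,
reproducible pipeline from trial tables and multichannel evoked epochs to
group-level brain–behavior statistics, and it ships a synthetic-data
generator with known ground truth so every stage can be validated by
parameter recovery before touching real data.

## What it computes

**Behavior.** Binary choices are fit with a lapse-corrected cumulative
Gaussian by maximum likelihood,

&nbsp;&nbsp;&nbsp;&nbsp;ψ(x) = λ/2 + (1 − λ) Φ((x − μ)/σ),&nbsp;&nbsp;λ = 0.05,

giving the PSE (μ), the JND (probe distance between the 50% and 75%
points of ψ), and the Weber fraction (JND/PSE). The history bias is
summarized per inducer dimension by the serial-dependence index

&nbsp;&nbsp;&nbsp;&nbsp;Eff = (PSE_high − PSE_low) / PSE_low × 100,

positive = attractive, plus a trial-level binomial GLM of responses on the
probe and the three inducer magnitudes (ratio-coded to the reference).

**Decoding.** Past-stimulus magnitude (low vs high) is decoded from
trials × channels × time epochs with a sliding-window protocol: 100 ms
windows stepped by 20 ms, random pseudo-trial averaging (10–20 trials
each), top-5 channel selection by training-set ANOVA, training-fold
z-scoring, linear SVM (C = 1) under leave-one-pseudo-trial-out, 30
resampling iterations. An identical run with shuffled training labels
provides the empirical chance level; temporal generalization matrices and
early/late latency-window summaries (50–200, 500–650 ms) are included.

**Linking.** Per time window, the behavioral effect is regressed on
classification accuracy, `Eff ~ CA + (1 | Subj)` (which reduces to OLS
with one observation per subject); runs of ≥ 2 consecutive significant
windows form clusters that are evaluated by a within-cluster permutation
test with the add-one p estimator. Supporting utilities: t tests with
Cohen's d, Benjamini–Hochberg FDR, Pearson correlation, and exact
noncentral-t power analysis (d = 0.55, one-tailed α = 0.05, power 0.9 →
n = 30).

See `vignette("serialdep-methods")` for the model details, parameter
defaults, and an honest discussion of what the cluster permutation does
and does not control.

## Worked example

Simulate one subject with a known attractive numerosity bias
(PSE separation 1.5 dots ≈ +9.7%) and a past-numerosity signal at
100–300 ms, then recover both:

```r
library(serialdep)

tab <- generate_design_exp1("numerosity", n_reps_per_cell = 10, seed = 1)
obs <- observer_params(pse_base = 16, sigma = 2, lapse = 0.05,
                       bias_numerosity = 1.5)
tab <- simulate_responses(tab, obs, seed = 2)
eb  <- effects_by_inducer(tab, "numerosity")
eb$fit_low; eb$fit_high
sprintf("serial dependence effect: %.2f%%", eb$effect$eff)

eeg <- eeg_sim_params(n_channels = 8, sampling_rate = 250,
                      signal_windows = list(list(start = 100, end = 300,
                                                 amplitude = c(numerosity = 1))),
                      seed = 3)
ep  <- simulate_epochs(tab, eeg, subject_amplitude = 0.6)
cls <- sort_epochs_by_past(ep, "numerosity")
dp  <- decoding_params(pseudo_k = 10, n_pseudo_per_class = 10,
                       n_iterations = 10, seed = 4)
dec <- decode_timecourse(cls$low, cls$high, grid_for_epochs(ep), dp)
nul <- null_decode_timecourse(cls$low, cls$high, grid_for_epochs(ep), dp)
window_mean_ca(dec, 50, 200); window_mean_ca(nul, 50, 200)
```

Output:

```
Psychometric fit (200 trials): PSE = 14.872, sigma = 2.033, JND = 1.457, WF = 0.0980
Psychometric fit (200 trials): PSE = 16.273, sigma = 1.021, JND = 0.732, WF = 0.0450
[1] "serial dependence effect: 9.42%"
[1] 0.9222222
[1] 0.5148148
```

The two split fits straddle the baseline PSE of 16 and the index recovers
the generative +9.7% bias within single-session noise; decoding in the
early latency window is far above the shuffled-label chance level of
~0.51, while prestimulus windows stay at chance.

`run_pipeline(run_config(...), out_dir)` chains all stages for a whole
cohort — per-subject trial tables and fits, actual/null decoding
timecourses, latency-window tests against the empirical null (FDR within
window), the per-window regression, and the cluster permutation — writing
CSV/JSON stage outputs plus a seed-complete manifest, summarized by
`make_report(out_dir)`. A thin command-line wrapper lives at
`inst/cli/serialdep.R` (`run-all`, `simulate`, `report`).

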