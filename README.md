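# tunedrift

Analysis pipeline for quantifying **orientation tuning and its
day-to-day stability ("representational drift")** from two-photon
calcium imaging, together with the behavioral plasticity scores and
immunostaining ensemble quantification that typically accompany such
studies of activity-dependent plasticity in mouse visual cortex and
nucleus accumbens. A synthetic-data generator with recorded ground
truth drives verification of every stage, so the whole pipeline is
testable without any in-house raw data.

## What it computes

**Trace processing.** Per-cell fluorescence traces are decontaminated
by subtracting a scaled neuropil trace, with the scale `a` chosen on a
grid in [0, 1] to maximize the skewness of `cell − a·neuropil`
(somatic signals are sparse and skewed; neuropil is smooth and
symmetric). Trial-evoked responses are means of dF/F =
(F − F0)/F0 over the 2 s stimulus window, with F0 the mean of the 1 s
pre-onset baseline.

**Tuning.** Responses to opposite drift directions are averaged and
the orientation profile is fit by bounded least squares with

    f(θ) = B + R·exp(κ(cos 2(θ − μ) − 1))

where μ is the preferred orientation (mod 180°) and κ the
concentration, reported as a width σ = (180/π)·√(1/κ) degrees. A cell
is *responsive* if any condition passes a Bonferroni-corrected paired
t-test (baseline vs stimulus window); the fit's *reliability* is the
nearest-rank 90th percentile of circular deviations |μ_boot − μ| over
trial-resampled refits; cells with reliability < 22.5° are *tuned*.

**Drift.** For cells tuned on the reference day and matched across
sessions, the change in preferred orientation is the circular
difference folded to [0, 90]°, summarized as the fraction of cells
below 10° and the median change.

**Behavior.** CPP score `(t_cocaine − t_saline)/(t_cocaine +
t_saline)`; percent PPI `(pulse_alone − prepulse_pulse)/pulse_alone ×
100` per prepulse level; NOR preference `(t_novel −
t_familiar)/(t_novel + t_familiar)`.

**Ensemble quantification.** Threshold segmentation inside an
infected-region mask, 8-connected particle labeling filtered by area
and circularity (4πA/P²), per-cell integrated densities, counts
normalized by mask area, and two-sample Kolmogorov–Smirnov comparison
of intensity distributions between conditions.

## Worked example

The numbered scripts under `analysis/` run one simulated experiment end
to end: 150 cells (10% untuned) imaged on simulated days D1, D3 and D7
with 7°/step drift of preferred orientation, 70% neuropil
contamination and dF/F noise of 0.05.

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_extract_responses.R
Rscript analysis/03_fit_tuning.R
Rscript analysis/04_drift.R
Rscript analysis/05_behavior.R
Rscript analysis/06_ensemble.R
```

Output from one run (summary tables land under `results/`):

```
D1: 160 trials x 150 cells; median neuropil scale 0.70 (true 0.70); 0 invalid trials
neuropil scale error: median |a_hat - a_true| = 0.010 over 450 cell-sessions
D1: 145/150 responsive, 136 tuned; median reliability 0.2 deg; median |mu error| 0.09 deg
D1-D3: n = 136 tuned matched cells; 85% below 10 deg; median change 4.6 deg
D1-D7: n = 136 tuned matched cells; 72% below 10 deg; median change 6.2 deg
CPP: cocaine group mean score 0.22, saline group -0.00 (n = 12 each)
PPI by prepulse level: +4 dB: 28.5%  +8 dB: 51.1%  +12 dB: 66.7%
NOR: training preference 0.09, STM preference 0.41 (paired t p = 0.001)
integrated density KS: D = 0.173, p = 2.21e-02 (n = 150 vs 150 cells)
```

Reading this: the skew-maximization recovers the planted neuropil scale
to ±0.01; essentially all planted tuned cells are recovered as tuned
with sub-degree preferred-orientation error; two days of 7° drift steps
leave 85% of tuned cells within 10° (one step) and 72% (two steps) —
drift accumulates across the longer interval; the behavioral scores
recover their generating effects (a conditioned group near its 0.25
expected CPP score against a null saline group, percent PPI near
100×attenuation per level, novel-object preference emerging at the
short-term test); and the knockdown-like image set shows a downward
shift of per-cell integrated density detected by the KS test.

In code, the core loop is three calls:

```r
library(tunedrift)
pop  <- gen_population(150, frac_untuned = 0.1, seed = 1)
sess <- gen_session(pop, trial_design(), noise_sd = 0.05, a_true = 0.7, seed = 2)
resp <- session_responses(sess)                  # neuropil + dF/F + evoked means
fits <- fit_tuning_session(resp, n_boot = 200, seed = 3)
head(fits[, c("cell", "mu_deg", "sigma_deg", "reliability_deg", "tuned")])
```

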