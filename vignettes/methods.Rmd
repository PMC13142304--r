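---
title: "Methods: orientation tuning, drift, and plasticity scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: orientation tuning, drift, and plasticity scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tunedrift)
```

# What this package computes

`tunedrift` is the analysis machinery of a two-photon orientation-tuning
study, rebuilt as a tested pipeline and driven by a synthetic-data
generator with recorded ground truth. Five analysis stages sit on top of
the generator:

1. **Trace processing** — neuropil decontamination by skew maximization
   and reduction of fluorescence traces to trial-evoked dF/F.
2. **Tuning** — responsiveness testing, Von Mises fits, and bootstrap
   reliability of the preferred orientation.
3. **Drift** — change in preferred orientation for matched cells across
   imaging days, on the folded 0–90° orientation-difference domain.
4. **Behavior** — conditioned place preference (CPP), percent prepulse
   inhibition (PPI), and novel object recognition (NOR) scores.
5. **Ensemble quantification** — threshold segmentation with
   size/circularity particle filtering, per-cell integrated densities,
   area-normalized counts, and Kolmogorov–Smirnov comparison of
   intensity distributions.

The numbered scripts under `analysis/` run these stages in order over
one simulated experiment and write small summary tables under
`results/`.

# The tuning model

Evoked responses are means of dF/F over the stimulus window, with
`F0` the mean of the 1 s window immediately preceding each onset
(`(f - F0) / F0`, so the measure is invariant to overall gain).
Responses to opposite drift directions are averaged, and the
orientation profile is fit with a Von Mises function

$$ f(\theta) = B + R\,e^{\kappa(\cos 2(\theta-\mu) - 1)} $$

where $B$ is the baseline response, $R$ the modulation at the preferred
orientation $\mu$, and $\kappa$ the concentration. The doubled angle
makes the curve 180°-periodic. $\kappa$ corresponds to a variance of
$1/\kappa$ and is reported as a width
$\sigma = (180/\pi)\sqrt{1/\kappa}$ degrees.

**Fitting.** Bounded Levenberg–Marquardt least squares with
multi-start: $\mu$ is initialized at every circular local peak of the
observed profile and $\kappa$ at each of $\{0.5, 2, 8\}$, with
$B = \min$ and $R = \max - \min$ of the responses; the lowest-SSE
converged solution wins. Bounds are $R \ge 0$ and
$\kappa \in (0, 50]$ — $\kappa = 50$ is a width of about 8°, already
below one stimulus step, so sharper fits carry no extra information at
this stimulus resolution. A flat profile fits with $R \approx 0$ and an
arbitrary $\mu$; such cells are not special-cased because the
reliability screen removes them. The fitted SSE is verified in the test
suite against a dense brute-force $(\mu, \kappa)$ grid with closed-form
$(B, R)$ at every grid point.

**Responsiveness.** A cell is visually responsive if at least one
stimulus condition shows a significant two-sided paired t-test between
per-trial baseline-window and stimulus-window dF/F, Bonferroni-corrected
across the 16 conditions (`min p < alpha / 16`, `alpha = 0.05`). The
paired form was chosen over a one-sample test against zero because the
protocol explicitly pairs each stimulus value with its own pre-stimulus
baseline; with the package's F0 convention the baseline-window means are
near zero, so the two readings coincide in practice. Degenerate inputs
follow a fixed contract: all-zero paired differences give p = 1;
zero-variance nonzero differences skip the condition with a warning.

**Reliability.** The fit is repeated on trial-resampled data: trials
are resampled with replacement *within each stimulus condition*
(preserving the design and per-condition sample sizes — the natural
reading of trial resampling for a balanced protocol), condition means
recomputed, directions collapsed, and the multi-start fit rerun.
Deliberately, replicates are **not** warm-started from the original
parameters: a warm start anchors weakly tuned cells near the original
$\mu$ and understates their variability (we observed exactly this
failure mode for untuned cells). The deviation of a replicate is the
circular orientation difference $\min(|\Delta|, 180 - |\Delta|) \in
[0, 90]$ from the original $\mu$; linear differences would exceed 90°
artifactually on the orientation circle. Reliability is the
**nearest-rank** 90th percentile (the value at index
$\lceil 0.9 n \rceil$ of the ascending sort), so a reliability of 20
means exactly that 90% of bootstraps fall within 20° of the original
fit. The default is 1000 replicates; the analysis scripts and the
heavier verification runs use 200, which leaves the nearest-rank
statistic unchanged in definition and was chosen purely as a
problem-size economy. Cells with reliability strictly below 22.5° (the
stimulus-set interval) are classified tuned; tuned cells must also be
responsive with a successful fit.

# Neuropil subtraction

Somatic calcium signals are sparse and positively skewed; the neuropil
contaminant is smoother and nearly symmetric. Subtracting the correctly
scaled contaminant from the measured trace therefore maximizes the
skewness of the residual: for independent signals, adding a symmetric
component only dilutes the third moment, so the adjusted Fisher–Pearson
sample skewness of `cell - a * neuropil` peaks at the true scale. The
scale is searched on the grid $a \in \{0, 0.01, \ldots, 1\}$ — the
protocol gives no bounds, and a unit upper limit reflects physical
contamination of at most 100%. Ties break toward the smallest $a$;
candidates with zero-variance residuals are excluded; if all are
excluded the estimate is 0 with a warning flag. The bias-corrected
(adjusted Fisher–Pearson) skewness estimator is used because "skew"
alone does not pin down an estimator; the choice is documented here and
in the function's help.

# The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions every verification run uses.

* **Protocol**: 16 directions at 22.5° increments, 2 s stimulus, 4 s
  ITI, 15 Hz sampling, 1 s baseline window. The protocol does not fix
  the trial count per condition; the generator defaults to 10 and
  exposes it.
* **Population**: $B \sim U(0, 0.2)$, $R \sim U(0.5, 1.5)$,
  $\kappa \sim U(1, 4)$ (widths of roughly 29–57°), $\mu \sim U[0,
  180)$ — typical dF/F magnitudes and widths for mouse V1. Untuned
  cells have $R = 0$.
* **Traces**: `F_base * (1 + kernel) + a_true * neuropil + noise` with
  `F_base = 100`. The kernel is a boxcar over the stimulus window at
  the cell's Von Mises response — the analysis only uses window means,
  so a calcium-decay convolution would not change any downstream
  quantity, and the boxcar keeps the noiseless pipeline exactly
  invertible (the conservation test recovers the generating parameters
  to machine precision). The baseline window carries only `F_base`, so
  the evoked dF/F at angle $\theta$ equals the full Von Mises value
  including $B$.
* **Neuropil**: an AR(1) process with coefficient 0.98 (correlation
  time ≈ 3 s at 15 Hz), rescaled to mean 50 and SD 30 fluorescence
  units. The SD — about 30% of baseline fluorescence — makes the
  contaminant's variance comparable to the signal's, which is both
  realistic for somatic neuropil contamination and what makes the skew
  objective well-curved: with a much weaker contaminant the skew
  profile is nearly flat and the grid argmax wanders.
* **Drift**: session $k > 1$ perturbs each cell's $\mu$ by an
  independent $N(0, \text{drift\_sd}^2)$ step wrapped onto $[0, 180)$ —
  a random walk on the orientation circle. The demonstration analysis
  uses 7°/step, which places the between-session stability fractions in
  the range such studies report (a large majority of cells under 10°
  change after one step).
* **Behavior**: CPP and NOR times are built from a Beta-distributed
  side proportion with mean $(1 + \text{effect})/2$, so the expected
  score equals `effect` *exactly* (not just approximately) for any
  effect size, including the null. PPI startle amplitudes are
  Gamma-distributed with per-level mean `(1 - attenuation) *
  pulse_mean`, so expected percent PPI is `100 * attenuation`.
* **Images**: non-overlapping disks of known center, radius and
  intensity on a constant low background inside an infected-region
  mask, with the exact rasterized pixel count and intensity sum
  recorded per cell.

All randomness flows from one user seed through a splitting function;
each sub-stream's seed is recorded in the session object.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: calcium indicator kinetics and
nonlinearity, motion artifacts, correlated (shared) noise across cells,
eye movements and behavioral-state covariates, cell-matching errors
across days, anisotropic or overlapping nuclei, and stained-tissue
background structure. Recovery results here certify the *analysis
machinery*, not robustness to those real-world effects.

# Drift quantification

Cross-session matching itself (typically done by eye against fiduciary
landmarks) is an input — a two-column map of cell indices.
For each matched pair with successful fits (and, by default, tuned on
the reference session), the drift record is the circular orientation
difference of the fitted $\mu$s, in $[0, 90]$. Summaries report the
fraction of cells strictly below a 10° stability threshold, the median
(mean of central order statistics for even n), and n.

# Ensemble quantification

Where interactive imaging workflows use a hand-trained pixel
classifier to mark positive nuclei, this package uses a global
intensity threshold — a trained classifier is inherently
irreproducible, while the downstream particle chain is the substantive
computation and is preserved exactly: binarize
within the mask, label 8-connected components, filter by area
(default 30–5000 px) and circularity $4\pi A / P^2 \ge 0.3$. The
perimeter $P$ counts boundary pixel edges (4-neighbor edges facing the
exterior), matching the intent of the FIJI definition; on a digitized
disk this yields circularity ≈ 0.62, comfortably above the cutoff,
while a 1-px-wide bar scores ≈ 0.07 and is rejected. Circularity is
clipped at 1. The size/circularity cutoffs are exposed parameters with
pragmatic defaults, not canonical values. An
optional distance-transform watershed stage (off by default) can split
touching nuclei; the generator plants non-overlapping cells so
correctness tests do not depend on it. Counts are normalized by the
mask pixel count; per-cell expression is the intensity sum over the
ROI; conditions are compared with a two-sample two-sided
Kolmogorov–Smirnov test (asymptotic p).

# Behavioral scores

* CPP: $(t_{\text{cocaine}} - t_{\text{saline}}) / (t_{\text{cocaine}} +
  t_{\text{saline}})$, −1 to +1.
* PPI: $(\text{pulse alone} - \text{prepulse+pulse}) / \text{pulse
  alone} \times 100$ per prepulse level, computed on mean amplitudes
  per trial type, unclipped (negative values = facilitation). Per-level
  values are primary; averaging across levels is on request only.
* NOR: $(t_{\text{novel}} - t_{\text{familiar}}) / (t_{\text{novel}} +
  t_{\text{familiar}})$. The sign convention is *positive = novel
  preference*, consistent with how recognition memory is plotted; the
  opposite subtraction order is available via `novel_positive = FALSE`
  because written task descriptions sometimes state it that way.

# Numerical conventions and degenerate inputs

* Frames are 0-indexed in trial tables; windows are
  `round(duration * rate)` frames; the onset frame opens the stimulus
  window and the baseline is strictly pre-onset.
* Trials with non-positive F0 are flagged invalid, counted, and
  excluded downstream.
* Orientation differences are always folded to $[0, 90]$.
* The tuned threshold is a strict inequality (22.5 is not tuned).
* Bootstrap replicates whose refit fails are dropped and counted; more
  than 20% failures flags the cell's reliability as unreliable.
* `which.max` tie-breaking plus an ascending grid gives the documented
  smallest-$a$ tie rule for the neuropil scale.

# Problem sizes

Verification runs use sizes chosen to make the statistical assertions
sharp while staying desk-scale: 250 cells (20% untuned) at 200
bootstrap replicates for tuning recovery; 50 traces per contamination
level for the neuropil scale; 1000 null cells for the type-I check;
1000 cells for the drifted-fraction law (against a $10^6$-draw
Monte-Carlo reference); 20 seeded images for ensemble recovery. The
demonstration workflow under `analysis/` simulates 150 cells across
three sessions.

# Known limitations

* The skew-maximization scale estimate assumes the contaminant is less
  skewed than the cell signal; for near-silent cells (rare transients,
  low R) the objective flattens and the estimate degrades.
* Reliability at 200 replicates has coarser percentile resolution than
  at 1000; both are supported, 1000 is the default.
* The responsiveness test treats trials as exchangeable; slow drifts in
  F0 within a session are not modeled.
* Group-level inference (ANOVAs, mixed models over animals) is out of
  scope; the package stops at per-cell and per-session quantities.
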