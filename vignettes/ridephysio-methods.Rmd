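---
title: "Methods: physiological indices of passenger experience and their synthetic test bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: physiological indices of passenger experience and their synthetic test bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ridephysio)
```

## What this package computes

`ridephysio` analyses passenger psychophysiology during a ride with two
unexpected road events (a deer-shaped dummy at about 50% of the route and a
child-shaped pedestrian dummy at about 90%), experienced once with a human
driver and once in self-driving mode. Four measure families are derived per
subject, condition, and route event:

* **Affectivity** — frontal alpha asymmetry (FAA),
  $\mathrm{FAA} = \log_{10} P_\alpha(F4) - \log_{10} P_\alpha(F3)$,
  where $P_\alpha$ is the 8–12 Hz Welch band power. Higher values index
  approach/positive affect.
* **Arousal** — $(\bar P_\beta + \bar P_\gamma) / \bar P_\alpha$ with each
  band power averaged over F3 and F4 (13–30 Hz beta, 30–45 Hz gamma).
* **Multifractal spectrum width (MFSW)** — $\Delta\alpha$ of the
  Chhabra–Jensen singularity spectrum of eye- and head-displacement series,
  per event window.
* **Spontaneous blink frequency** — blink counts per event window, a blink
  being a binocular, equal-extent measurement-error interval.

Inference is a 2 (Condition: Human / SelfDriving) × 3 (Route event: Smooth /
Deer / Kid) fully within-subject ANOVA per measure, with generalized
eta-squared ($\eta^2_G$) effect sizes, Tukey-adjusted pairwise post hocs,
and mean ± 95% CI summaries.

## The preprocessing chains and their assumptions

### EEG

1. Band-pass 7–48 Hz, 9th-order Butterworth. Filtering is **zero-phase**:
   the squared analog Butterworth magnitude is applied in the frequency
   domain with mirror padding, which is exactly the gain of one forward and
   one backward pass and introduces no latency shift into epoch anchoring.
   The effective attenuation is therefore that of the order-18 magnitude;
   a 2 Hz tone leaves less than 10% residual, a 10 Hz tone is preserved
   within 10%. An optional `correct` hook before filtering is the seat for
   an external artifact correction (e.g. ICA), which this package does not
   perform itself.
2. 2 s epochs advancing by 1 s; the count is $\lfloor (N-L)/S \rfloor + 1$
   in samples and a trailing partial window is dropped.
3. Epochs with any sample outside ±100 µV on any channel are rejected; the
   mask is monotone and idempotent.
4. Welch PSD with 1 s Hann windows, 50% overlap (1 Hz resolution — enough
   to resolve the 8 Hz alpha edge); band power is the PSD integral over the
   closed band, bins assigned by center frequency. The alpha band sits just
   inside the 7 Hz passband edge; no edge correction is applied.
5. Per participant and measure, epochs deviating from the individual mean
   by ≥ 3 SD are removed in a **single pass** (the rule is not re-iterated).
6. Epoch values are averaged into four route segments: ride start →
   deer − 5 s, deer − 5 s → 60% of the ride, 60% → pedestrian − 5 s, and
   pedestrian − 5 s → ride end; segments 1/3 are "smooth", 2/4
   "unexpected". The 5 s anticipation window corresponds to 1000 samples at
   200 Hz, roughly when a dummy enters the visual field. For the 2 × 3
   design, Smooth is the mean of segments 1 and 3, Deer is segment 2, Kid
   is segment 4.

Whether arousal averages PSD across F3/F4 before or after forming the
ratio is ambiguous in the source description; this package averages each
band across electrodes first (mean-before-ratio). Both readings are scale
invariant; they differ only when the electrodes' band profiles differ
strongly.

### Gaze and head movement

Pupil-boundary points are fitted with a direct least-squares ellipse
(Fitzgibbon's constrained conic); pixel centers are converted to degrees
through a spherical eyeball model, $yaw = \arcsin(\Delta x / r)$,
$pitch = \arcsin(\Delta y / r)$, after roll-correcting by the camera axis
through the horizontal rectus landmarks. Points outside the bulbus disk are
invalid. Then:

* consecutive valid samples implying a total angular speed
  $\sqrt{\Delta yaw^2 + \Delta pitch^2} \cdot f_s$ above 500 °/s invalidate
  the later sample, repeated to a fixed point;
* invalid runs ≤ 20 ms (about 2 frames at 120 Hz) are linearly
  interpolated; longer runs, and runs touching the series edge, are
  measurement errors;
* error intervals with equal extent in both eyes (± one sample — exact
  sample equality is fragile under independent per-eye processing) are
  blinks;
* a final 2nd-order Butterworth low-pass, nominally 60 Hz. At the 120 Hz
  camera rate 60 Hz **is** Nyquist; the package refuses an explicit 60 Hz
  request at 120 Hz and the default falls back to 50 Hz with a warning
  rather than silently reproducing an unrealizable setting.

The cleaning wrapper iterates the velocity filter and gap interpolation
together, because interpolating across a removed saccade sample creates a
half-sized step that can itself exceed 500 °/s; steps shrink geometrically
so a fixed point is reached in a few rounds, with grown gaps ending up as
error runs.

Head displacement arrives already in degrees at 30 Hz and goes straight to
segmentation and multifractal analysis: its upstream validity handling is
video processing outside this package's scope.

### Multifractal spectrum (Chhabra–Jensen)

For box size $\varepsilon$ the measure is
$P_i(\varepsilon) = \sum_{t \in \mathrm{box}\ i} w_t / \sum_t w_t$ with
weights $w_t$ the absolute first differences of the displacement series
(for gaze, the 2-D increment magnitudes $\sqrt{\Delta yaw^2 + \Delta
pitch^2}$, so both components feed one spectrum per eye). For each moment
order $q$:

$$\mu_i(q,\varepsilon) = \frac{P_i^q}{\sum_j P_j^q}, \qquad
\alpha(q) = \lim_{\varepsilon \to 0}
\frac{\sum_i \mu_i \log P_i}{\log \varepsilon}, \qquad
f(q) = \lim_{\varepsilon \to 0}
\frac{\sum_i \mu_i \log \mu_i}{\log \varepsilon},$$

estimated by OLS across dyadic scales (default 8 samples to $N/8$, so every
scale has ≥ 8 boxes), with the width $\Delta\alpha = \max_q \alpha(q) -
\min_q \alpha(q)$ over $q \in [-5, 5]$ in steps of 0.25. Numerical choices:

* $q$-th powers are formed in the log domain with max-subtraction, so
  extreme $q$ never overflow and are never clipped;
* zero-mass boxes are excluded (they contribute nothing for $q > 0$ and
  would be singular for $q < 0$ — the $q<0$ flank is the part sensitive to
  this, hence it is documented);
* the series is truncated to the largest length divisible by the maximal
  scale, avoiding partial boxes;
* per-$q$ regression $R^2$ is reported as a diagnostic but never used to
  censor (a single width per segment is reported, with no censoring rule);
* increments touching invalid samples (blinks, error runs) are **dropped**
  from the measure rather than bridged: a linear bridge injects box mass
  proportional to the blink count, confounding the width with the blink
  rate.

The estimator is validated against the closed-form binomial-cascade
spectrum
$\alpha(q) = -\frac{p^q \ln p + (1-p)^q \ln(1-p)}{(p^q + (1-p)^q)\ln 2}$,
$f(q) = q\alpha(q) + \log_2(p^q + (1-p)^q)$: on an exact depth-14 cascade
the estimate agrees to machine precision and the $p = 0.3$ width on this
$q$ grid is 1.1875. No $q$ range, scale range, or measure construction is
canonical for displacement data, so all three are configurable
(`mf_config()`); the defaults above are the package's own choices.

### Statistics

The ANOVA uses the classical within-subject decomposition; each effect is
tested against its interaction with subjects
($F_A = MS_A / MS_{A \times S}$, etc.), with uncorrected dfs by default (a
Greenhouse–Geisser option exists but is off, matching how this design's
results are conventionally reported). Subjects with any missing cell are
dropped listwise; no imputation. Effect size is
$\eta^2_G = SS_\mathrm{eff} / (SS_\mathrm{eff} + SS_S + SS_{A\times S} +
SS_{B\times S} + SS_{AB\times S})$ — the observed-vs-manipulated
convention with subjects as the only measured factor. Post hocs collapse
over the non-tested factor to one mean per subject and level, form paired
$t$ statistics with $df = n - 1$, and adjust through the studentized range
with $q = |t|\sqrt{2}$ and $k$ = number of levels; at $k = 2$ this reduces
to the plain paired $t$. Summaries are mean ± $t_{0.975,n-1}\,SD/\sqrt n$.

One published inconsistency is deliberately not reproduced: a blink-rate
ANOVA reported with denominator df 128, which cannot arise from a
subject-level 2 × 3 within design at the study's n. This package implements
the subject-level design only.

## The synthetic cohort: what it emulates, and what it does not

`gen_cohort()` generates the full input bundle with known ground truth:

* **EEG** (200 Hz, F3/F4/FPz/Oz): sums of band-limited noise carriers
  (brick-wall filtered white noise, unit RMS) scaled per channel — default
  alpha 10, beta 5, gamma 2 µV RMS, giving a baseline arousal near 0.3.
  F3 and F4 share the alpha carrier, so a planted FAA is realized *exactly*
  as the amplitude ratio $10^{\mathrm{FAA}/2}$, piecewise over the four EEG
  segments. Artifacts are 0.25 s in-band square bursts (a DC pulse would be
  removed by the band-pass before rejection could see it).
* **Displacement** (gaze 120 Hz ×2 eyes, head 30 Hz ×2 axes):
  cascade-modulated Gaussian noise — binomial-cascade cells act as local
  variances and positions are their running sum, so the pipeline's
  $|\Delta x|$ measure recovers noisy cascade weights. Each analysis window
  is its own cascade aligned to the window start (a window cut mid-cascade
  inherits coarse-scale mass imbalance that biases its width upward). The
  planted event effect is a width *difference* on the closed-form scale,
  inverted to a multiplier $p$ (baseline width 0.5 → $p \approx 0.39$);
  the elevation is planted in the deer window only, matching the designed
  contrast (deer > smooth, deer > kid, smooth ≈ kid).
* **Blinks**: a thinned Poisson schedule at 15/min (a standard resting
  spontaneous blink rate), multiplied by the planted factor inside event
  windows, injected into both eye traces as invalid runs so the pipeline
  has to re-detect them.
* **Design noise**: per-subject FAA intercepts (SD 0.1), per-cell FAA noise
  (`noise_sd`), lognormal subject blink-rate factors (SD 0.2). Default ride:
  180 s, events at 50% and 90%, 5 s pre-windows, 20 s event windows.

What a green test does *not* establish: the generator has no volume
conduction, no 1/f background or non-stationarity in the EEG, no real
saccade/fixation dynamics (fixational jitter is a random walk), no video
noise, and the cascade model is only one way multifractality arises in
movement data. Estimated widths of the cleaned, low-passed traces are
systematically attenuated relative to the planted closed-form widths —
which is why the end-to-end acceptance check asserts the qualitative
post-hoc pattern, not width values. Conversely, the estimator itself *is*
held to exact closed forms on pure cascade measures.

## Worked example

```{r example, eval = FALSE}
co <- gen_cohort(24, condition_effect_faa = 0.3, event_effect_mfsw = 0.4,
                 event_effect_blink = 0.5, noise_sd = 0.2, seed = 1)
res <- run_pipeline(co)
res$anova$faa          # Condition main effect on FAA
res$posthoc$mfsw_eye_left  # Deer vs Smooth / Kid contrasts
head(res$summary)      # mean +/- 95% CI per measure x condition x event
```

## Known limitations

* ICA-based artifact correction is out of scope; only amplitude rejection
  handles artifacts (a `correct` hook is provided).
* Pupil segmentation from video and head-motion estimation from scene video
  are out of scope; the pipeline starts from boundary points / coordinate
  series.
* The event-window length is a required parameter: the source description
  of "equal in length" windows does not determine a value.
* Estimated MFSW depends on the measure construction and $q$ range;
  comparisons are only meaningful within one configuration.
* The ANOVA requires a complete balanced table after listwise deletion;
  unbalanced designs are out of scope.
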