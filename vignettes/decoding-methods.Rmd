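---
title: "Information-based analysis of multi-scale electrophysiology with mvdecode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information-based analysis of multi-scale electrophysiology with mvdecode}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvdecode)
```

## The analysis problem

Rapid streams of colored random-dot stimuli vary in two circular
features — color hue and motion direction — drawn uniformly from 8 or 12
equally spaced classes. Neural signals recorded at several scales
(single units, analog multi-unit activity, local field potentials, EEG
electrodes, MEG sensors) carry information about these features, and the
scientific questions are *when* that information appears, *where* it
sits along the cortical hierarchy, and *how similar* the underlying
stimulus representations are across areas, measurement scales and
recording modalities.

`mvdecode` implements the full chain of analyses for these questions
and pairs it with a seeded synthetic-data generator, so that every
stage can be validated end to end against known ground truth without
any recorded data.

## Decoding model

At each time point $t$ of the epoch grid, a multi-class linear
discriminant analysis (LDA) is trained on the channel activity of the
training trials and applied to held-out trials. LDA models each class
$k$ as a Gaussian with mean $\mu_k$ and a shared covariance $\Sigma$,
estimated as the pooled within-class covariance shrunk toward a scaled
identity,

$$\hat\Sigma = (1-s)\,S + s\,\overline{\mathrm{diag}(S)}\,I,$$

with shrinkage weight $s$ (default 0.1, configurable). Shrinkage keeps
the estimate invertible when channels outnumber trials (hundreds of MEG
sensors, few thousand trials) and is the standard remedy preserving the
LDA form. Posterior probabilities are the softmax of the Gaussian
log-discriminants with uniform priors — uniform because the design is
balanced by stratification; with a shared covariance this equals the
exact Gaussian-Bayes posterior, which the test suite verifies against
an independently coded density-evaluation oracle to $10^{-8}$.

Held-out posteriors are averaged per true class, giving a
time-resolved **confusion tensor**: entry $[t, i, j]$ is the mean
predicted probability of class $j$ for trials of true class $i$. Every
row is a probability vector at every time point; this invariant is
asserted throughout. The **hit rate** (mean of the diagonal) summarizes
performance, with chance $1/K$.

### Cross-validation and stratification

Sensor-level analyses use 10-fold cross-validation; sparse invasive
recordings use 2-fold. Before folding, trials are subsampled so every
color x motion combination occurs equally often (decoding one feature
must not be confounded by the other). For sequence paradigms, each
stimulus x sequence-position cell is additionally balanced by
oversampling *within* each fold — duplicated indices never cross folds,
so oversampling cannot leak information; a dedicated test decodes pure
noise with oversampling active and confirms chance-level output.

Fold assignment and cell subsampling derive their RNG streams from the
member indices of each class rather than from the label values. This
makes the whole pipeline exactly equivariant under class relabeling (a
property test permutes the class labels and checks that confusion rows
and columns permute identically) while remaining fully deterministic
given the scheme seed.

### Unit subsampling and class-grid interpolation

To compare areas with different unit counts on an equal footing,
decoding can be restricted to 5 units at a time and averaged over all
or at most 40 seeded distinct combinations. Twelve-class recordings are
brought onto the common 8-class grid by bilinear interpolation on the
torus of true x predicted angles (the minimal interpolation respecting
the circular geometry), followed by row renormalization to restore the
probability invariant.

## Group statistics

**Cluster sign permutation.** After subtracting chance, temporally
contiguous clusters are formed where a one-tailed t-test over sessions
is significant at $p < 0.01$. The null multiplies each session's
timecourse with random signs (10,000 draws by default) and records the
strongest cluster mass per draw; observed clusters get
$p = (b+1)/(m+1)$. Cluster mass is the sum of t-values over the
cluster — the field-standard choice. A 500-dataset null simulation
keeps the family-wise false-positive rate in $[0.02, 0.075]$ at
nominal 0.05.

**Latency.** Sessions are normalized to $(x - \mathrm{chance}) /
(\mathrm{peak} - \mathrm{chance})$ and included only if the
post-stimulus peak is at least 1.5x the largest absolute baseline
deviation (absolute value, as deviations below chance are equally
diagnostic of noise). The peak is the first post-stimulus local maximum
reaching 75% of the global maximum; the latency is the first half-peak
crossing, linearly interpolated between the bracketing 10 ms samples.
The group statistic is the latency of the session-mean normalized
timecourse — more robust than averaging noisy per-session latencies.
Bootstrap CIs resample sessions; group contrasts permute group labels,
with inclusion masks held fixed across permutations (recomputing them
per permutation would change the hypothesis being tested). All
permutation p-values use the $(b+1)/(m+1)$ convention.

## Representational similarity and tuning

Confusion matrices averaged over 50-250 ms (the window where stimulus
information is available) act as representational similarity
structures. Two entities are compared by the Pearson correlation of
their off-diagonal entries — both triangles, since confusions need not
be symmetric. Significance comes from reassigning stimulus labels to
rows and columns of one matrix simultaneously (10,000 draws), two-sided
on $|r|$; shuffling one matrix is statistically equivalent to shuffling
both under exchangeability.

Collapsing a confusion matrix over stimuli gives a tuning curve:
prediction probability as a function of signed circular distance
(offsets in $(-180, 180]$). The **bimodality index**

$$\mathrm{BI} = \frac{P(180^\circ) - \tfrac12\left(P(135^\circ) + P(-135^\circ)\right)}{P_{\max} - P_{\min}}$$

is positive when stimuli are confused with their opposites (axis
tuning) and zero or negative for unimodal tuning; a flat curve is
assigned 0 by convention. Where the two next-to-opposite offsets
differ, their mean is used. Group significance is a one-sided t-test of
per-session indices against 0, and a linear regression of pairwise
similarities on $|\Delta \mathrm{BI}|$ quantifies how much of the
similarity structure tuning shape explains.

Single-channel tuning screens channels with a one-way ANOVA
($p < 0.05$) on mean response amplitude in a configurable window
(default 50-250 ms, matching the RSA window; the response summary uses
mean squared amplitude when `power = TRUE`, appropriate for
LFP-like signals), aligns each curve to its preferred stimulus (ties
broken toward the lowest class angle, for determinism), and averages.

## Controls

**Luminance cross-classification.** Color decoding could reflect
residual luminance differences. Training and testing are split by
luminance level: within-level, cross-level, and a half-space scheme
that trains on high-luminance stimuli from one half of the color circle
plus low-luminance stimuli from the other half and tests on the
complement, averaging confusion matrices over all possible split axes
before extracting accuracies. Classes exactly on a split axis go to
half A by the lower-angle rule. A pure luminance confound drives the
half-space accuracy *below* chance (the classifier systematically picks
the trained, wrong, half); a level-invariant color signal keeps
cross-level accuracy at the within-level value. Significance uses
exactly 100 label shuffles with the $(b+1)/(m+1)$ convention.

**Minimum-motion equiluminance.** Probe gratings at 19 luminance
levels elicit vertical eye drift whose curvature (second
time-derivative of vertical position; summarized as the mean second
difference over the stimulus period, scaled by $1/\Delta t^2$ — the
stencil is exact on quadratics) is proportional to the luminance offset
from true equiluminance, with opposite sign in the two motion-direction
conditions. The condition difference regressed on luminance crosses
zero at the perceptually equiluminant level, returned as $-a/b$.

## Source space

A linear forward model (gain matrix) mixes source activity into
sensors. The inverse uses linearly constrained minimum-variance (LCMV)
filters $w = C^{-1}\ell / (\ell^\top C^{-1}\ell)$ with the sensor
covariance regularized by $\lambda\,\overline{\mathrm{diag}(C)}\,I$
(default $\lambda = 0.05$); the unit-gain constraint
$w^\top \ell = 1$ holds exactly. Searchlight decoding repeats the
cross-validated analysis per source using that source and its
`group_size - 1` nearest neighbors along the occipito-frontal
coordinate as features (default group size 1; the analysis drivers use
2, since a single tuned scalar cannot separate classes symmetric about
its preferred angle).

## The synthetic-data generator

The generator is first-class, tested code defining the study
conditions:

* **Stimuli.** Configuration A: 12 classes, 150 ms stimuli, 50 ms ISI,
  sequences of 6. Configuration B: 8 classes, 100 ms stimuli, 20 ms
  ISI, sequences of 8. Color and motion labels are independent and
  uniform; both configurations are exposed through
  `stimulus_config()`.
* **Tuning.** Unimodal tuning is a von-Mises-shaped bump
  $b + a\,e^{\kappa(\cos\Delta - 1)}$; axis (bimodal) tuning evaluates
  the same bump on the doubled angle, giving exact 180°
  periodicity. Defaults: $\kappa = 2$ (a realistic tuning width on the
  8-class grid), baseline 0.5, amplitude 2, noise SD 0.25 per 10 ms
  sample, 8 units per area with preferred angles spread over the
  circle.
* **Temporal kernel.** A half-sine bump of width 60 ms starting at the
  population's onset latency. The kernel's half-maximum sits at
  onset + width/6 = 10 ms, one step of the 10 ms analysis grid; with
  the default amplitude the information timecourse saturates, which
  pulls its half-maximum crossing to within one grid step of the true
  onset. This is deliberate: it makes the half-max latency estimator's
  target analytically predictable, so onset-latency recovery can be
  tested sharply (80 vs 120 ms recovered within ±10 ms).
* **Sampling.** 100 Hz (10 ms steps) on the −250..500 ms window — the
  decoding grid itself, 76 points, with t = 0 on the grid.
* **Sensors and eye traces.** A gain matrix mixes sources to sensors
  with additive Gaussian sensor noise. Eye traces are parabolic drifts
  whose curvature is `gain · (L − L_eq)` (gain 50 curvature units per
  luminance unit), sign-flipped in condition 2, with position noise
  SD 0.01 — small relative to stimulus-driven drift, as for an
  infrared eye tracker.

What the generator does *not* emulate: temporally correlated (1/f)
noise, cross-channel noise correlations, trial-to-trial gain
fluctuations, overlapping responses from adjacent sequence stimuli,
eye-movement artifacts in neural channels, or fixation breaks
(sequences are always complete). Passing tests therefore demonstrate
the correctness of the analysis chain, not the expected effect sizes on
recorded data — real information timecourses peak far below the
near-ceiling accuracies seen here.

## Numerical choices

* Filters: Butterworth designs applied forward-reverse (zero phase;
  the effective order doubles, matching the "2-pass" convention), with
  reflect padding of three time constants of the slowest corner before
  filtering to suppress edge transients on short synthetic recordings.
  Down-sampling low-passes at 0.8x the new Nyquist before
  interpolating onto the new grid (the anti-alias filter is applied
  even though the analysis band ends well below the new Nyquist).
* All angles are in degrees, classes at bin centers, circular
  differences mapped to $(-180, 180]$.
* Degenerate inputs have defined behavior: flat tuning curves get
  BI = 0; sessions with no qualifying peak are flagged and excluded
  from group latency statistics; a zero-variance bimodality sample is
  reported as degenerate rather than producing a spurious t-test.
* Every stochastic step takes an explicit seed, applied through local
  RNG state that never disturbs the caller's random stream; per-class
  draws are seeded from member indices so results are invariant to
  relabeling and to session ordering.
* Where the printed grid is coarse (10 ms), half-max crossings are
  linearly interpolated between samples; reported latencies are
  therefore continuous.

## Problem sizes

The packaged tests and analysis drivers run the study at reduced but
structurally identical sizes, chosen so the complete chain remains
comfortably reproducible on a laptop: 200-2,000 stimuli per session,
6-10 sessions, 8-12 units per population, permutation counts of
500-1,000 in simulation loops (the statistical definitions are
unchanged; `default_config(fast_factor = )` scales the counts without
touching the procedures). The chance-calibration analysis uses the full
2,000-trial, 10-fold design. The interfaces default to the full
10,000-permutation counts.

## Known limitations

* The LDA covariance shrinkage weight is fixed, not analytically
  optimized (Ledoit-Wolf style); 0.1 is conservative for the simulated
  regime and configurable everywhere.
* The torus-bilinear 12-to-8 interpolation is exact only for
  band-limited confusion structure; sharp circulant kernels incur a
  few percent interpolation error (tested at that tolerance).
* The epochs container stores numeric payloads as text CSV: robust and
  diff-able, but roughly 3x larger and slower than a binary format;
  fine at the simulation scales above.
* The searchlight geometry is one-dimensional (an occipito-frontal
  coordinate); extending neighborhoods to a 2-D cortical mesh would
  only change the neighbor lookup.
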