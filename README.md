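# mvdecode

Time-resolved multivariate decoding of circular stimulus features from
multi-scale electrophysiology, with the group statistics and
representational analyses that turn decoder output into scientific
claims — plus a fully seeded synthetic-data generator so the entire
chain is verifiable against ground truth.

## Who this is for

Researchers analyzing rapid-stream visual experiments in which stimuli
vary along circular features (color hue, motion direction, 8 or 12
uniformly spaced classes) and neural activity is recorded at one or
several scales: single/multi-unit activity and LFP from
microelectrodes, or EEG/MEG sensors. The package answers *when*
stimulus information appears in a signal, *where* it sits along the
cortical hierarchy, and *how similar* stimulus representations are
across areas, scales and modalities.

## What it computes

At the core is time-resolved multi-class **LDA with shrinkage
covariance** and probabilistic outputs. For each time point $t$ of the
−250..500 ms epoch grid (10 ms steps, 76 points), held-out posterior
probabilities are averaged per true class into a confusion tensor
$C[t,i,j]$ = mean predicted probability of class $j$ for trials of
class $i$; the hit rate is $\mathrm{mean}(\mathrm{diag}\,C[t])$ with
chance $1/K$. Around this core:

* cross-validation (10-fold, or 2-fold for sparse invasive data) with
  joint color x motion balancing and within-fold oversampling of
  stimulus x sequence-position cells;
* 5-unit subsampling (≤ 40 combinations) and torus-bilinear 12→8 class
  interpolation for cross-area and cross-configuration comparability;
* cluster-based **sign-permutation inference** on information
  timecourses (cluster-forming p < 0.01, mass = summed t, max-mass
  null);
* **half-maximum latency** estimation (first local maximum ≥ 75% of
  the global max; 1.5x-baseline session inclusion; interpolated
  half-peak crossing) with bootstrap CIs and label-permutation
  contrasts;
* confusion-matrix **RSA** (off-diagonal Pearson r over 50–250 ms
  averages; joint row/column label-permutation null);
* circular tuning curves, the **bimodality index**
  $(P_{180} - \bar P_{135})/(P_{\max}-P_{\min})$ for detecting axis
  tuning, and the similarity-vs-bimodality regression;
* **LCMV** unit-gain spatial filters and searchlight decoding along an
  occipito-frontal source coordinate, with latency–position
  correlation;
* luminance cross-classification and minimum-motion equiluminance
  controls;
* preprocessing chains: MUA envelope extraction (500–6000 Hz,
  rectify, 250 Hz low-pass, 1 kHz), bipolar LFP, 0.1–10 Hz analysis
  band-pass (zero-phase Butterworth), resampling with average
  reference, and epoching.

The synthetic-data module generates stimulus streams for both paradigm
configurations, von-Mises-tuned (unimodal or axis-tuned) populations
with controlled onset latencies, linear source-to-sensor mixtures, and
eye traces for the equiluminance control. See
`vignettes/decoding-methods.Rmd` for the model details and design
choices.

## Worked example

Simulate one session of an 8-class color-tuned population, decode it,
and test for information:

```r
library(mvdecode)

trials <- generate_stimulus_stream(stimulus_config("B"), 400, seed = 1)
pop    <- population_config("V4", n_units = 8, tuned_feature = "color",
                            tuning_shape = "unimodal")
ep     <- simulate_tuned_responses(trials, pop, seed = 2)
conf   <- crossvalidated_confusion(ep, "color", cv_scheme(n_folds = 2, seed = 3))
tc     <- accuracy_timecourse(conf)
tc
#> <info_timecourse> 76 points, chance 0.125, peak 0.9992 at 110 ms
```

Accuracy rises from chance (0.125) to near ceiling at 110 ms: the population's
80 ms onset latency plus the rise of its 60 ms response kernel. The
half-max latency recovers the onset:

```r
ns <- normalize_and_select(list(tc))
estimate_latency(ns$sessions[[1]])$latency_ms
#> [1] 86.30928
```

The full multi-session study, with cluster statistics, RSA and
bimodality analysis, is one call:

```r
run <- run_pipeline(default_config(seed = 1))
report(run, "results")
```

The numbered scripts under `analysis/` walk through the complete
workflow stage by stage (simulation → preprocessing → decoding → group
statistics → RSA/tuning → controls → searchlight) and write their
tables under `results/`. For example, `analysis/07_searchlight.R`
prints

```
information peaks at occipital-like coordinates (max tuned 0.39 vs max
silent 0.15); latency-position r = 0.988, p = 3.17e-05 over 7
significant sources
```

— the feed-forward-like latency gradient built into the simulated
sources (80→130 ms across positions 1–6) is recovered through the
sensor mixture, LCMV inversion and searchlight decoding.

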