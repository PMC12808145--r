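---
title: "Laminar CSD analysis of reversal learning: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Laminar CSD analysis of reversal learning: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lamcsd)
```

`lamcsd` analyses laminar local field potentials (LFP) recorded across the
depth of a cortical column while an animal performs an auditory Go/NoGo
task whose stimulus--response contingencies are repeatedly reversed. This
vignette explains the models the package implements, the tunable
parameters, the choices made where the methodology left room, and what the
synthetic data generator can and cannot show.

## The analysis chain

1. **Behavior.** Each trial presents a CS+ (Go) or CS- (NoGo) tone; a
   compartment change within the observation window is a *hit* (CS+) or
   *false alarm* (CS-), withholding is a *miss* or *correct rejection*.
   Session sensitivity is the signal-detection index
   $d' = \Phi^{-1}(\text{hit rate}) - \Phi^{-1}(\text{FA rate})$.
   Sessions are binned into three performance phases: early reversal
   ($d' < 0$), learning ($0 \le d' < 1$) and retrieval ($d' \ge 1$).
2. **Current source density.** The one-dimensional CSD is the negative
   second spatial derivative of the depth profile of the LFP,
   $\mathrm{CSD}(z) = -[\Phi(z+n\Delta z) - 2\Phi(z) +
   \Phi(z-n\Delta z)]/(n\Delta z)^2$, after depth-smoothing the LFP with a
   unit-sum 9-channel Hamming window (about 400 µm at 50 µm contact
   spacing). Sinks (net inward current, mostly excitatory synaptic input)
   are negative. AVREC, the depth mean of $|\mathrm{CSD}_i(t)|$, summarises
   overall columnar current flow.
3. **Features.** Per trial and cortical layer (I/II, III/IV, Va, Vb, VI),
   the root-mean-square of the layer-representative CSD trace over a
   half-open 500 ms window anchored at a CS onset, z-scored across trials
   within session and feature.
4. **Spectra.** A continuous wavelet transform with the analytic Morse
   wavelet (5--100 Hz, L1 normalization) turns layer CSD traces into
   time--frequency power maps, annotated with six bands (theta 4--7,
   alpha 8--12, low beta 13--18, high beta 19--30, low gamma 31--60, high
   gamma 61--100 Hz).
5. **Cluster statistics.** Two conditions are compared bin-wise with
   two-sample t tests ($\alpha = 0.05$, two-tailed); significant bins are
   grouped into 8-connected clusters split by t sign; the maximum cluster
   size under label permutation builds a null distribution whose 95th
   percentile must be exceeded; retained clusters must additionally cover
   at least $5 \times 5 = 25$ bins and have mean $|d| > 0.4$ (Cohen's d).
6. **Models.** A repeated-measures ANOVA stage (subject as the repeated
   unit, Holm-adjusted paired post-hocs, generalized eta-squared) and a
   mixed-logistic stage: the binary choice contrast is predicted from the
   z-scored layer RMS with per-subject random intercepts and slopes, and
   summarised by the marginal/conditional coefficients of determination
   $R^2_m = \sigma^2_f / (\sigma^2_f + \sigma^2_r + \pi^2/3)$,
   $R^2_c = (\sigma^2_f + \sigma^2_r) / (\sigma^2_f + \sigma^2_r +
   \pi^2/3)$, tracked across the CS positions preceding the decision.

## The synthetic generator

Real laminar recordings of this kind are not freely downloadable, so every
stage is exercised against a generator whose defaults state the study
conditions: 60 trials per session (30 CS+, 30 CS-), 200 ms tones with a
1.5 s inter-stimulus interval inside a 6 s observation window (hence four
CS onsets at 0/1.7/3.4/5.1 s), LFP sampled at 2 kHz on a 32-channel probe
with 50 µm spacing. The behavioral agent relaxes exponentially towards
asymptotic rates of 0.8 (hit) and 0.2 (FA); at each scheduled reversal the
hit rate drops by 0.65 (to ~0.15, below 20 %) and the FA rate jumps by
0.25 (to ~0.45), matching the perseverative signature of reversal
learning, with recovery past $d' = 1$ within 3--4 sessions.

The electrophysiology is built from three parts:

* **Evoked dipoles.** Each layer receives, at every CS onset, a potential
  bump that is Gaussian in depth (centred on the layer) and Gaussian in
  time (15 ms width, layer-specific onset latency of 12--28 ms); its
  second spatial derivative is a sink at the layer centre flanked by
  balancing sources, so the injected current closes across the column. The
  deepest/earliest sinks sit in the granular (III/IV) and infragranular
  (Vb) input layers, at 200--220 µV; supragranular amplitudes are weaker.
* **Oscillatory bursts.** Band-limited sinusoids under a Gaussian envelope
  tied to each CS onset, by default a 25 Hz high-beta burst in Vb and a
  40 Hz low-gamma burst in III/IV at 30 µV, with a random phase per trial
  (induced, not phase-locked, activity). A burst's *power gain* may depend
  on the trial's choice label -- that is how condition effects are
  injected for recovery tests.
* **Noise.** White Gaussian noise, 50 µV SD per sample.

Amplitudes, latencies, the layer map (channels 2--6, 7--12, 13--17,
18--24, 25--30 superficial to deep) and the noise floor are plausible for
awake rodent auditory cortex but are conventions of this package, not
published measurements. The generator deliberately omits 1/f background
structure, volume-conducted far fields, spiking, behavior-correlated
movement artifacts and across-session drift. Passing tests therefore
demonstrate that the *algorithms* recover what was injected under
realistic geometry and SNR -- they do not validate neurobiological claims
about real recordings.

Artifact positives are injected explicitly: channel-gain events for the
bad-channel screen and rail-saturation blocks for the clipping detector.

## Numerical and design choices

* **Degenerate hit/FA rates.** Rates of 0 or 1 are replaced by $1/(2N)$
  and $1 - 1/(2N)$ so $d'$ stays finite (standard correction; the
  methodology itself is silent).
* **Phase boundaries.** The published inequalities are strict on both
  sides and leave $d' = 0$ and $d' = 1$ unassigned; the package uses
  half-open bins $[-\infty, 0)$, $[0, 1)$, $[1, \infty)$ so the partition
  is total. $d' = 0$ is *learning*, $d' = 1$ is *retrieval*.
* **Bad-channel statistic.** Per channel, the median across trials of the
  per-trial peak-to-peak amplitude, flagged when strictly above the
  across-channel mean + 3 SD of that statistic. The reference distribution
  had to be fixed here; the median across trials makes the screen robust
  to single-trial transients.
* **Smoothing order and boundary.** Spatial smoothing is applied to the
  LFP before differencing. The Hamming kernel length (9 channels) is taken
  as normative rather than the quoted ~400 µm (9 × 50 µm = 450 µm). The
  boundary uses half-sample reflection, which keeps the kernel unit-sum at
  the edges and conserves the depth sum exactly.
* **Edge channels.** The second difference is undefined at the outermost
  channels; they are trimmed by default. Vaknin-style padding (duplicating
  the edge channels) is available (`csd_config(vaknin = TRUE)`) and has
  the useful property that the depth sum of the CSD telescopes to exactly
  zero, which is how the dipole-closure test is phrased.
* **RMS source.** Whether RMS was taken on single-trial or trial-averaged
  CSD is ambiguous in the source description; the package computes the
  depth mean of the layer's channels per single trial, then RMS -- the
  variant that keeps trial-level variance for the GLMM stage.
* **Windows after a response.** CS presentations at or after the reaction
  time are excluded (the CS ends at the response); for the pre-reaction
  anchor the last CS *starting* before the reaction is used and its full
  500 ms window is kept.
* **Morse parameters.** Only "analytic Morse" is specified; the package
  uses $\gamma = 3$, $\beta = 20$ (time-bandwidth 60, the common toolbox
  default), 12 voices per octave on a log grid including both endpoints.
  L1 normalization is implemented so a unit-amplitude sinusoid has ridge
  magnitude ~1 at any frequency.
* **Cone of influence.** The wavelet time spread at unit scale,
  $\sigma_t$, is computed in closed form from the frequency-domain
  derivative (for $\gamma=3, \beta=20$: $\sigma_t = 2.92$ cycles of the
  peak frequency); bins within $\sqrt{2}\,\sigma_t$ scaled samples of an
  edge (the amplitude e-folding) are flagged and excluded from cluster
  statistics by default. This matters most below ~10 Hz, where the
  wavelet spans hundreds of milliseconds.
* **Trial averaging.** The default averages complex coefficients before
  taking magnitude (evoked, phase-locked emphasis, matching the stated
  formula); per-trial magnitude averaging (total power) is kept as an
  option because the intent is not fully determinable. Cluster statistics
  always operate on per-trial *power* maps, so this choice does not
  affect inference.
* **Cluster machinery.** Connectivity is 8-neighbour (the default of the
  boundary-tracing routine the method cites), 4-neighbour available. The
  null statistic is the per-permutation *maximum* cluster size, which
  controls family-wise error; pooling all null sizes is exposed as an
  option. The cluster statistic itself is size (bin count); cluster mass
  $\sum |t|$ is computed and reported but not thresholded. The mean-d gate
  uses mean $|d|$; clusters are sign-coherent by construction. All gates
  are strict as printed: size $\ge 25$, mean $|d| > 0.4$, size strictly
  above the null 95th percentile. Degenerate bins (zero variance, zero
  pooled SD) yield $t = 0, p = 1$ and $d = 0$.
* **Permutation unit.** Trials, matching the trial-pooled design of the
  comparisons; subject-level exchangeability is a known limitation.
* **GLMM direction.** The methodology describes both "z-scored RMS
  modeled as a function of choice" and "compare binary outcome classes";
  the package predicts the binary choice contrast from the z-scored RMS
  (logistic link), which is the direction the effect-size series over
  stimulus positions requires. Significance flags use the Wald test of
  the fixed slope; non-converging or single-class fits become logged gaps.
* **$R^2$ components.** $\sigma^2_f$ is the variance of the fixed-effect
  linear predictor; $\sigma^2_r$ is the mean per-observation random-effect
  variance $\mathrm{diag}(Z \Sigma Z^\top)$ summed over grouping factors;
  the logistic link variance is $\pi^2/3$. Labels: small $\le 0.1$ <
  medium < 0.25 $\le$ large, for both $R^2_m$ and $\eta^2_{gen}$.
* **Trial-length scheduling.** Trials are described as 12--15 s with a 6 s
  observation window and CS/US continuing on misses; the generator exposes
  the window length as configuration and records only the observation
  window, with trial time zero at the first CS onset.

## Problem sizes in the test suite

The statistical suites run at sizes chosen to finish quickly while keeping
their inferential content: calibration of the gated cluster test uses 100
null data sets with 200 permutations each (the analysis default is 1000
permutations); power uses a 1-SD block effect at 40 observations per
group; the GLMM recovery suite uses 20 seeds with 6 subjects x 30 trials
at two stimulus positions; the end-to-end injection suite runs 10 seeds of
two 60-trial sessions with one CS per trial and a hit-vs-miss low-gamma
power gain of 3 in layer VI. The uninjected layers of that suite double as
an end-to-end null check and are held to the generator's null-fidelity
bound (significant-cluster frequency at most 0.10); a calibrated 5 %-level
procedure cannot promise literally zero false positives over repeated null
comparisons.

## Known limitations

* The generator's dipoles are phenomenological (Gaussian bumps), not
  biophysical forward solutions; absolute CSD magnitudes are arbitrary.
* One pipeline run simulates one animal; the orchestrated GLMM stage uses
  sessions as the random-effect grouping unit, whereas the scientific
  design would use animals. The standalone `fit_choice_glmm()` /
  `effect_size_series()` accept any subject column.
* Recordings and scalograms are (de)serialized via R's own binary format
  at run time; interchange formats are CSV/TSV/JSON for tables, configs
  and cluster results.
* The ANOVA stage implements the one-way repeated-measures design on
  subject-by-condition cell means; unbalanced subjects are dropped
  listwise and counted.
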