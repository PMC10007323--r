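---
title: "Crosstalk in facial EMG and its reduction with infomax ICA"
author: "emgica"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crosstalk in facial EMG and its reduction with infomax ICA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Surface EMG over the corrugator supercilii (frowning) and zygomatic major
(smiling) muscles is the workhorse measure of affective valence in
psychophysiology. Both electrodes sit on a face crowded with other
muscles, and volume conduction spreads every muscle's electrical activity
instantaneously through the tissue. When a participant chews or speaks,
the jaw muscles (masseter, suprahyoid) fire vigorously a few centimetres
from the zygomatic electrode, so part of what the zygomatic channel
records is not smiling at all — it is crosstalk. Because crosstalk falls
off roughly with the square of the distance to the source, the corrugator
electrode on the brow should be far less affected.

`emgica` implements, end to end and fully seeded, a pipeline to study
this contamination and its removal: a generative simulator with a known
mixing matrix, preprocessing to amplitude envelopes, per-participant
infomax independent component analysis (ICA), partial back-projection
reconstruction, and the statistical battery that compares original and
reconstructed signals across a cohort.

## Signal model and pipeline

**Mixing model.** Observed channels are an instantaneous linear mixture
of muscle sources: `x(t) = A s(t) + noise`, with `A[c, c] = 1` and
`A[c, s] = min(1, (d0 / d_cs)^2)` for source `s` at distance `d_cs` from
electrode `c` (`d0` = 1.6 cm by default). Zero conduction delay is
assumed throughout: at the conduction velocities relevant for surface
EMG, inter-electrode delays are orders of magnitude smaller than the
100 ms envelope bins, which is also the premise that justifies applying
ICA to envelope data.

**Preprocessing.** The pipeline is fixed as bandpass (20–400 Hz,
zero-phase Butterworth) → full-wave rectification → 10 Hz
average-rectified-value (ARV) envelope by non-overlapping 100 ms bin
means → epoching into 55-point windows (5 baseline points covering the
500 ms before action onset, 50 points covering the 5 s action) →
concatenation of all 64 trials into one channels × 3520 matrix per
participant. Rectification must precede downsampling — bin-averaging a
zero-mean carrier first would cancel it. Bin means (not decimation with
an anti-alias filter) are the standard ARV amplitude estimator; an RMS
variant is available via `downsample_envelope(..., method = "rms")`.
Zero-phase filtering avoids group delay that would shift trial onsets;
epoching happens after enveloping the continuous signal so that trial
edges carry no filter transients.

**Decomposition.** `fit_infomax()` is plain (non-extended) logistic
infomax: centered, ZCA-sphered data are unmixed by stochastic
natural-gradient ascent on the joint entropy of logistic-transformed
outputs, `W <- W + lr (I + (1 - 2 g(u)) u') W` over shuffled blocks.
Centered rectified envelopes are strongly super-Gaussian, which the
logistic score matches; the extended variant's sub-Gaussian branch is
unnecessary here. Components are always 4 (= channels); no dimension
reduction is applied.

**Reconstruction.** `variance_shares()` attributes back-projected
variance to channels: `V[c, k] = var(A_hat[c, k] S_k) / sum_j
var(A_hat[c, j] S_j)`. The component with the highest share on the
corrugator row and the component with the highest share on the zygomatic
row are kept (ties break to the lower index; if both rows pick the same
component the second target takes its next-best distinct one), and all
four channels are rebuilt from those two components plus channel means.
Reconstructions of the masseter and suprahyoid channels are therefore
purged too, which is what the paired comparisons quantify. Reconstructed
envelopes may go negative; no clipping is applied because the subsequent
baseline correction and averaging tolerate sign.

**Statistics.** Per trial and channel, the envelope is baseline-corrected
by the mean of the 5 pre-stimulus points and averaged over the 50 action
points; trial scalars are averaged within condition. Across participants,
each muscle × condition cell gets a two-tailed one-sample t-test of the
original amplitudes against zero (crosstalk detection) and a paired
t-test of original vs reconstructed (reduction), with Cohen's d as
`mean/sd` (one-sample) and `mean(diff)/sd(diff)` (paired) — the
convention under which `d = t / sqrt(n)`. Wilcoxon signed-rank tests
accompany every t-test; they are exact (full sign-assignment
distribution, computed by convolution over doubled midranks, hence valid
under ties) up to n = 25 and use a normal approximation with continuity
and tie corrections beyond. Holm's step-down correction is applied within
each muscle's 8 conditions, separately per table and per test family —
never across muscles. `required_sample_size()` inverts exact
noncentral-t power; at d = 0.8, α = 0.05, power 0.80 it returns 15.

## What the simulator emulates — and what it does not

`simulate_cohort()` reproduces the study conditions the pipeline targets:
29 participants, 8 facial-action conditions (frown, smile, chew, speak,
and the four frown/smile × speak/chew combinations) × 8 trials in blocked
pseudorandom order, 4 channels at 1000 Hz band-limited to 20–400 Hz,
with 500 ms baseline + 5000 ms action epochs.

Per muscle, the source envelope is a tonic resting level (default 1,
unitless) times a slow lognormal drift (sd 0.1, < 0.2 Hz — baseline
wander), plus condition-dependent activation: frown → corrugator (amp 3),
smile → zygomatic (amp 3), chew → masseter + suprahyoid (amps 4 and 3,
1.5 Hz rhythm), speak → masseter + suprahyoid (amps 2 and 2.5, 3 Hz
rhythm, weaker and faster than chewing); combinations take the union.
Three variability choices matter and are deliberate:

* jaw openers and closers alternate, so the masseter and suprahyoid
  rhythms are in antiphase;
* rhythm phase is redrawn uniformly on every trial — actions are not
  locked to stimulus onset;
* voluntary expressive intensity varies widely, as per-trial lognormal
  amplitude jitter (sdlog 0.55) on top of per-participant per-muscle
  lognormal scaling (sdlog 0.4); sustained holds additionally wax and
  wane (modulation depth 0.4 at 0.6 Hz) rather than staying flat.

Without this variability the disjoint trial structure (frown-type and
smile-type trials never co-occur) would itself induce source-envelope
correlations near −0.45, violating the approximate independence that any
ICA-recovery test must be able to presuppose; with it, all pairwise
envelope correlations stay below 0.3. The default electrode geometry
(zygomatic 3 cm from masseter and 5 cm from suprahyoid; corrugator 7, 10
and 13 cm from zygomatic, masseter and suprahyoid) uses anatomically
plausible distances and is calibrated so that the simulated cohort
reproduces the qualitative significance pattern the pipeline is designed
to detect — strong mouth-action crosstalk on the zygomatic channel, none
detectable on the corrugator. Only that ordering, and the inverse-square
law behind it, is scientifically motivated; absolute amplitudes and
distances are configuration, not measurement.

The raw-signal mode multiplies envelopes with independent band-limited
Gaussian carriers and mixes the *raw* signals — the physically correct
model, under which envelope-domain ICA is only approximately linear
(RMS amplitudes of independent carriers add in quadrature, not
linearly). The `envelope_domain = TRUE` mode instead mixes nonnegative
envelopes linearly — the exact generative model ICA assumes — and adds
ARV-estimator sampling noise (sd `0.603 σ / sqrt(100)` per bin, the
exact statistics of a rectified Gaussian averaged over 100 samples).
The two modes separate algorithm-correctness tests from realism tests.

Not modelled: motor-unit action-potential trains, electrode lift or
motion artifacts, ocular/cardiac contamination, conduction delays, and
any amplitude calibration to real microvolts. Passing tests on this
generator therefore show that the pipeline's inferences are correct
*under its stated mixing model*, not that the model captures every
property of real facial EMG.

## Numerical choices

* **ICA defaults**: `lr_init = 1e-3 / ln(channels)`, `tol = 1e-6` on the
  per-pass max weight change, `max_iter = 512` passes, block size 128,
  identity initialization, required seed (shuffling is the only
  stochastic element). The learning rate halves when successive per-pass
  updates point in opposing directions *or* when the change has not
  shrunk for 10 consecutive passes — block-stochastic updates otherwise
  plateau at a noise floor proportional to the rate and never reach a
  strict tolerance. Non-convergence is reported in the result and as a
  warning, never silently ignored; weight explosion raises an error
  advising a smaller rate.
* **Identifiability**: all-near-Gaussian components (excess kurtosis
  < 0.2 on every component) set a `gaussian_warning` flag, since any
  rotation then fits equally well.
* **Sign convention**: each component is flipped so its loading on its
  dominant (max variance share) channel is positive, making
  reconstructions comparable across runs.
* **Degenerate inputs**: rank-deficient channel matrices are rejected
  before sphering; zero-variance cells in the report tables are flagged
  `degenerate` with NA statistics rather than failing the whole table;
  an empty keep-set in `partial_reconstruct()` returns channel means
  with a warning.
* **Wilcoxon boundary**: exact enumeration up to n = 25, approximation
  beyond; at the boundary the two differ by well under 0.02 in p.
  Exact zeros are dropped and counted, the common convention.

## Problem sizes in the tests

The test suite exercises the full cohort analysis at n = 29 participants
(the default) for the headline-pattern check, n = 10 for the
cohort-level reduction invariants, and 200 replicates of n = 10
envelope-domain null cohorts for type-I calibration of the report — the
envelope-domain generator is used there because the null battery tests
the statistics, not the raw-signal physics. ICA recovery is checked on
3520-point envelope matrices and a 10 000-point 2 × 2 mixture, the
latter also against an independent reference infomax implementation.

## Known limitations

* With 4 channels and 2 retained components, reconstruction removes
  *all* variance of the discarded components, including any genuine
  zygomatic/corrugator activity they carry; the paired comparisons can
  therefore slightly overshoot (reconstructed mouth-condition zygomatic
  amplitudes can dip below zero after baseline correction).
* Envelope-domain ICA on raw-mixed data is an approximation; recovery
  correlations of ~0.95–0.99 on simulated participants should not be
  read as a guarantee on real recordings, where the mixing model itself
  is an idealization.
* The Holm families follow the design (8 conditions within a muscle);
  nothing corrects across muscles or across the two tables.
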