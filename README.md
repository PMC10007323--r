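# emgica — crosstalk simulation and reduction in facial EMG using infomax ICA

Facial surface EMG from the corrugator supercilii (frowning) and
zygomatic major (smiling) muscles is widely used to read out affective
valence. But surface electrodes also pick up volume-conducted activity
from nearby muscles: when a person chews or speaks, the masseter and
suprahyoid fire a few centimetres from the zygomatic electrode, and part
of the "smiling" signal is crosstalk. `emgica` is an R package for
psychophysiologists who want to study and remove that contamination. It
provides:

* a **seeded cohort simulator** producing four-channel facial EMG
  (corrugator, zygomatic, masseter, suprahyoid; 1000 Hz, 20–400 Hz band,
  8 facial-action conditions × 8 trials) mixed through a known
  distance-dependent crosstalk matrix `A[c,s] = min(1, (d0/d_cs)^2)`;
* **preprocessing** to 10 Hz rectified (average-rectified-value)
  envelope epochs: zero-phase bandpass → rectify → 100 ms bin means →
  55-point epochs (0.5 s baseline + 5 s action) → per-participant
  concatenation;
* **infomax ICA** (`fit_infomax()`): logistic-infomax unmixing by
  stochastic natural-gradient ascent with annealed learning rate,
  variance-share attribution of components to channels, and
  ground-truth matching utilities;
* **crosstalk removal**: keep the two components with the highest
  variance share on the corrugator and zygomatic channels, rebuild all
  channels from them by partial back-projection;
* the **statistical battery**: one-sample and paired t-tests with
  Cohen's *d* (`d = t/sqrt(n)` convention), exact/approximate Wilcoxon
  signed-rank tests, Holm step-down correction within each muscle's 8
  conditions, and exact noncentral-t power analysis.

## Worked example

```r
library(emgica)

# a priori power analysis: paired two-tailed t, d = 0.8, alpha .05, power .80
required_sample_size(d = 0.8, alpha = 0.05, power = 0.80)
#> [1] 15

# one simulated participant with known ground truth
sim <- simulate_participant(seed = 1)
sim$recording
#> <emg_recording> participant P01
#>   4 channels x 384000 samples @ 1000 Hz; 64 trial markers

# preprocess -> infomax ICA -> select 2 components -> reconstruct -> summarize
res <- analyze_participant(sim$recording, ica_seed = 1)
res$ica
#> <emg_ica> 4 components, 3520 timepoints
#>   converged: TRUE after 155 passes (delta 8.72e-07 ), seed 1
round(res$ica$V, 3)       # variance share of each component per channel
#>       [,1]  [,2]  [,3] [,4]
#> [1,] 0.991 0.009 0.000    0   # corrugator   <- component 1
#> [2,] 0.013 0.913 0.074    0   # zygomatic    <- component 2
#> [3,] 0.001 0.021 0.979    0   # masseter     <- component 3
#> [4,] 0.000 0.000 0.000    1   # suprahyoid   <- component 4
res$selection             # components kept for reconstruction
#> [1] 1 2

subset(res$summary, channel == "zygomatic" & condition %in% c("smile", "chew"))
#>    participant condition   channel       version mean_amplitude
#> 12         P01     smile zygomatic      original     1.06987224
#> 14         P01      chew zygomatic      original     0.32958595
#> 44         P01     smile zygomatic reconstructed     1.09530760
#> 46         P01      chew zygomatic reconstructed     0.06928081
```

The numbers tell the story: chewing (which never activates the simulated
zygomatic source) raises the observed zygomatic amplitude by 0.33
envelope units — pure crosstalk — and the two-component reconstruction
cuts that to 0.07 while leaving the genuine smiling amplitude intact
(1.07 → 1.10).

At cohort scale (`run_study(n_participants = 29, master_seed = 1)`,
about 90 s), the report tables reproduce the qualitative pattern the
pipeline is designed to detect — mouth actions drive significant
zygomatic but not corrugator activity, and reconstruction removes it
(excerpt; Holm-corrected within each muscle):

```text
table1 (original vs zero):          table2 (original vs reconstructed):
 muscle     condition    t  p_holm   sig     t  p_holm   sig
 corrugator chew      2.39 9.6e-02 FALSE  0.35 1.0e+00 FALSE
 corrugator speak    -0.97 3.4e-01 FALSE  0.51 1.0e+00 FALSE
 zygomatic  smile    13.27 9.3e-13  TRUE -2.89 1.5e-02  TRUE
 zygomatic  chew      7.85 4.4e-08  TRUE 11.10 3.8e-11  TRUE
 zygomatic  speak     8.34 1.8e-08  TRUE 11.48 3.0e-11  TRUE
```

A thin command-line wrapper ships in `inst/cli/emgx.R`
(`Rscript inst/cli/emgx.R run --config cfg.yaml --out out/`,
`simulate`, `power`); `run_pipeline()` writes condition summaries, both
report tables and a JSON manifest, bit-identically for a fixed
configuration.

## Package layout

* `R/conditions.R`, `R/recording.R` — condition/channel vocabulary, the
  `emg_recording`/`emg_epochs` containers and their CSV + JSON-sidecar
  round-trip I/O.
* `R/synthetic.R` — geometry, mixing matrix, source specification and
  the raw- and envelope-domain simulators (`simulate_cohort()`).
* `R/preprocess.R` — `bandpass()`, `rectify()`,
  `downsample_envelope()`, `epoch_envelope()`, `concatenate_trials()`.
* `R/infomax.R` — `center_and_sphere()`, `fit_infomax()`,
  `variance_shares()`, `match_components()`.
* `R/reconstruct.R` — `select_target_components()`,
  `partial_reconstruct()`, `summarize_conditions()`.
* `R/stats.R` — `one_sample_t()`, `paired_t()`,
  `wilcoxon_signed_rank()`, `holm_adjust()`, `required_sample_size()`,
  `build_report()`.
* `R/pipeline.R` — `analyze_participant()`, `run_study()`,
  `run_pipeline()`.
* `vignettes/facial-emg-crosstalk.Rmd` — the methods vignette: model,
  assumptions, simulator rationale, numerical choices, limitations.
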