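# restqc

Quantitative quality control for resting-state fMRI.

Resting-state functional connectivity is estimated from temporal
correlations between brain regions, so anything that correlates signals for
non-neuronal reasons — head motion, RF coil artifacts, misregistration —
corrupts it directly. `restqc` is for analysts assembling multi-subject
resting-state studies (especially multi-site ones) who need reproducible,
scriptable answers to: how much did this subject move, how much usable data
is left after censoring, are the images smooth/noisy/flipped/misaligned,
and does residual motion still leak into the connectivity estimates at the
cohort level?

## What it computes

* **Motion**: the volume-to-volume motion series
  `E_t = sqrt(sum_i (p_{t,i} - p_{t-1,i})^2)` over the six realignment
  parameters (rotations in degrees and translations in mm at unit weight —
  1° ≈ 1 mm at a 57 mm radius), censoring of every violation and its
  preceding time point, and the mean/max/good-time summaries.
* **Denoising with exact dof accounting**: censored least-squares
  projection of polynomial drift (order 2), tissue and motion regressors
  with temporal derivatives, and band-pass via stop-band sine/cosine
  regressors at the DFT frequencies outside the pass band;
  `dof = retained rows − rank(design on retained rows)`.
* **Image QC**: temporal SNR, spatial smoothness (Gaussian-autocorrelation
  first-difference estimator, per direction), iterative blur-to-target
  (default 8 mm), Dice mask overlap, left-right flip detection, and
  functional connectivity strength (FCS) via the scaled-global-signal
  identity.
* **Connectivity QC**: seed correlation maps, parcellated FC matrices with
  Fisher-Z, group means in Z space, per-subject similarity/dissimilarity to
  the group mean, QC-FC (per-edge correlation of connectivity with mean
  motion across subjects) with histogram and distance dependence, and a
  censoring-threshold / band-pass sweep.
* **Inclusion criteria**: strict cutoffs for residual degrees of freedom
  (< 15 fails) and retained data (< 240 s fails); review flags for maximum
  motion > 3 mm and suspected flips; site-grouped robust outlier screening
  (4 MAD) on TSNR/FCS for coil artifacts; qualitative criteria carried as
  explicit not-evaluable entries.
* **Synthetic cohorts**: a phantom generator (networks with shared
  low-frequency time courses, thermal noise, global coil spikes, motion
  with controllable mean/spikes/drift, optional motion-coupled edges with
  known slope) so the whole pipeline is testable with known ground truth.

See `vignettes/restqc-methods.Rmd` for the models, conventions and design
decisions.

## Worked example

```r
library(restqc)

# a synthetic subject: 150 volumes at TR 2 s, three networks, a couple of
# motion spikes of 0.6 mm
spec <- phantom_spec(n_timepoints = 150, tr_s = 2, seed = 42,
                     motion_spike_times = c(60, 61, 100),
                     motion_spike_amp_mm = 0.6)
bundle <- simulate_subject(spec)

config <- run_config(tr_s = 2, censor_threshold_mm = 0.4)
masks <- list(global = bundle$brain_mask, wm = bundle$wm_mask,
              csf = bundle$csf_mask)
sq <- subject_qc(bundle$volume, bundle$motion, masks, config,
                 subject_id = "phantom-42",
                 parcellation = bundle$parcellation)
sq$qc[, c("mean_enorm_mm", "max_enorm_mm", "n_good", "good_seconds",
          "dof", "tsnr_mean", "fcs_mean")]
#>   mean_enorm_mm max_enorm_mm n_good good_seconds dof tsnr_mean fcs_mean
#> 1        0.0614        0.633    145          290  31      35.7   0.0554

evaluate_criteria(sq$qc, config)
#>   criterion status
#> 1 A         pass
#> 2 B         pass
#> 3 C         pass
#> 4 D         not-evaluable   (no T1 supplied for the flip check)
#> ...
```

Reading the numbers: the three injected 0.6 mm excursions exceed the 0.4 mm
threshold, so 5 of 150 volumes are censored (`n_good = 145`, 290 s of good
data). The 0.01–0.1 Hz stop-band projection plus 21 nuisance/drift columns
leaves `dof = 31` independent samples — above the exclusion cutoff of 15,
so criterion A passes; 290 s ≥ 240 s passes B; max motion 0.63 mm ≤ 3 mm
passes C. TSNR (~36) and mean FCS (~0.06) would be compared against the
subject's site group.

Cohort-level: `threshold_sweep()` + `sweep_summary()` re-run the pipeline
across censoring thresholds and band options and report, per cell, the
similarity-vs-motion R², mean QC-FC, and exclusion counts; `qcfc()` gives
the per-edge motion correlations and their distance dependence.

A thin CLI over these functions is installed at `inst/cli/restqc`
(`simulate`, `subject-qc`, `group-qc`, `sweep`).

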