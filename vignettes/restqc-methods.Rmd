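---
title: "Quality control for resting-state fMRI: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality control for resting-state fMRI: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(restqc)
```

## What the package computes

Resting-state functional connectivity is measured from the temporal
correlation of fMRI signals, which makes it exquisitely sensitive to
anything that correlates signals for non-neuronal reasons: head motion, coil
artifacts, registration failures. `restqc` implements the quantitative side
of a subject-level and cohort-level quality-control workflow:

* **Motion.** The volume-to-volume motion at time $t$ is the Euclidean norm
  of the backward differences of the six rigid-body realignment parameters,
  $E_t = \sqrt{\sum_{i=1}^6 (p_{t,i}-p_{t-1,i})^2}$, rotations in degrees
  and translations in mm combined at unit weight. The justification for the
  unit weight is geometric: a 1° rotation displaces tissue by about 1 mm at
  a radius of 57 mm ($57 \cdot \pi/180 = 0.995$ mm), roughly the distance
  from the centre of the head to the cortical surface. Time points whose
  $E_t$ strictly exceeds a threshold are censored together with the
  preceding point (both volumes of the offending difference are suspect).
  A point exactly at the threshold is kept, matching the strict ">" with
  which such criteria are normally stated. The mean and maximum of $E_t$
  are computed over all defined differences, deliberately ignoring the
  censoring mask, so a subject's motion summary does not depend on which
  threshold was chosen.

* **Denoising with exact degrees-of-freedom accounting.** Nuisance signals
  (whole-brain mean, eroded white matter, CSF, the six motion parameters,
  and the backward-difference derivative of each) are projected out by
  least squares, together with polynomial drift terms of order 2 and — when
  a pass band is requested — a sine and cosine regressor at every DFT
  frequency $k/(T \cdot \mathrm{TR})$, $1 \le k \le T/2$, lying *outside*
  the band. Regressing out stop-band sinusoids is algebraically a band-pass
  filter on uncensored data, but unlike a frequency-domain filter it remains
  well-defined under censoring and makes the cost in degrees of freedom
  explicit: $\mathrm{dof} = (\text{retained rows}) - \mathrm{rank}(X_{\text{retained}})$.
  "2 polynomials" of drift is implemented as polynomial *order* 2 (constant,
  linear, quadratic — 3 columns): with 9 nuisance series, 9 derivatives and
  3 polynomial columns the design has 21 columns, and the two arithmetic
  anchors the engine is tested against — 140 uncensored points leaving 119
  dof and 720 leaving 699, with no band — hold only under this reading.
  Band limits are inclusive (a frequency exactly at either edge is
  retained). Censored rows are excluded from the fit, never interpolated,
  and residuals are reported only on retained rows so that no downstream
  correlation ever sees a censored sample.

* **Image-quality metrics.** TSNR (per-voxel mean over sd across time, on
  the *original* series, sd with denominator $T-1$); spatial smoothness per
  direction from the variance of first spatial differences under a Gaussian
  autocorrelation model,
  $\mathrm{FWHM}_d = \Delta_d \sqrt{-2\ln 2 / \ln(1-\sigma_\Delta^2/2\sigma^2)}$,
  combined as a geometric mean; iterative blur-to-target smoothing that
  closes the quadrature gap $\sigma_{target}^2 - \sigma_{cur}^2$ per
  iteration (default target 8 mm, tolerance 5%, at most 10 iterations);
  Dice overlap $2|A\cap B|/(|A|+|B|)$ of whole-brain masks as an alignment
  audit; a left-right flip check comparing the EPI-to-T1 match cost with
  and against a mid-sagittal mirror of the T1; and functional connectivity
  strength (FCS), each voxel's average correlation with the whole brain,
  computed through its identity with the correlation against the scaled
  global signal.

* **Connectivity-level QC.** Seed correlation maps from 4 mm spheres
  (voxel membership by centre-to-centre distance in mm); parcellated FC
  matrices (Pearson over retained time points, Fisher-Z with $r$ clipped to
  $\pm(1-10^{-7})$); group averaging in Z space; per-subject similarity to
  the group mean (Pearson over the upper-triangle edge vector) and its
  Euclidean counterpart, the dissimilarity; QC-FC (per-edge correlation of
  Fisher-Z connectivity with mean motion across subjects) with its
  histogram and distance dependence; and a threshold/band sweep that
  re-runs censoring, design, projection, FC and similarity per cell.

* **Inclusion criteria.** The quantitative criteria are strict: fewer than
  15 residual degrees of freedom (A), fewer than 240 s of retained data
  (B). Maximum motion above 3 mm (C) flags the subject for review rather
  than excluding — a single large excursion at the end of a run can simply
  be censored — with a switch to make it exclusionary. The flip check
  drives criterion D (uncertain, review). Coil-artifact screening (E) is
  operationalised as a site-grouped robust rule, |value − site median| >
  4·MAD on mean TSNR or mean FCS, because no portable absolute cutoff
  exists for either metric. Qualitative criteria (field-of-view coverage,
  anatomical abnormality, unfixable misalignment) are carried as explicit
  "not-evaluable" placeholders so the summary table is complete and
  auditable rather than silently partial.

## The synthetic cohort generator

Every metric above is exercised end-to-end on synthetic subjects with known
ground truth, so the test suite needs no data downloads. A phantom subject
is an ellipsoidal brain containing a central white-matter sphere and a CSF
shell, with the remaining "cortical" voxels partitioned into regions
(nearest seeded centre). Regions belong to networks round-robin; each
network has a time course built from four sinusoids with frequencies drawn
in 0.01–0.08 Hz — low enough to survive a 0.01–0.1 Hz pass band, where
resting-state fluctuations of interest live — and each region mixes the
network course with a private band-limited component
(`network_weight = 0.8` by default, i.e. true within-network correlation
0.8). The 4D signal is baseline 100 plus amplitude-4 fluctuations plus
white Gaussian thermal noise (default sd 1); coil spikes multiply all
in-mask voxels by $1+\text{gain}$ at chosen volumes, reproducing the
simultaneous global excursions that inflate FCS. Motion traces are Gaussian
random walks whose volume-to-volume norm has a requested mean (the exact
chi-6 factor 0.959 converts between the per-axis sd and the mean norm),
plus optional single-axis translation steps that appear in the motion
series *exactly*, so injected excursions are recoverable to machine
precision.

Motion-coupled connectivity, used to validate QC-FC recovery, is injected
at the time-course level: a coupled edge's region courses are mixed so
their true correlation equals `slope ×` (subject's target mean motion).
This gives an analytic target without simulating image-space motion
artifacts — which the phantom deliberately does not attempt, along with all
EPI physics (B0 distortion, slice timing, spin history). Passing tests
therefore demonstrate that the *estimators and bookkeeping* are correct,
not that real motion artifacts look like the injected ones.

One integer seed drives every stream through fixed offsets (+1 motion, +2
anatomy, +3 time courses, +4 noise; subject $i$ of a cohort uses
`seed + 101·i`, and the whole cohort shares one anatomy seed so regions
correspond across subjects, as they would in template space). Identical
specs give bit-identical bundles.

## The reduced-scale mechanism study

The cohort-level claim the package reproduces is a *mechanism*: when
censoring is aggressive and band-pass regression is on, high-motion
subjects lose so many degrees of freedom that their connectivity estimates
become noisy and drift away from the group mean — the similarity-to-group
correlates with motion because of dof starvation, not artifact. The bundled
study conditions are 40 subjects, 16×16×12 voxels, 150 time points at
TR = 2 s, low baseline motion (0.03 mm) plus 0–24 motion spikes of
0.28 mm: the spikes are censored at a 0.2 mm threshold (two frames each)
but survive 0.4 and 1.0 mm. With the 0.01–0.1 Hz stop-band projection the
uncensored design has 114 columns, so each censored pair eats directly into
the ~36 available dof. Under these conditions the similarity-vs-motion
$R^2$ is around 0.3 at a 0.2 mm threshold and below 0.1 at 0.4/1.0 mm, and
dropping the band-pass (which returns ~93 dof) raises similarity most for
high-motion subjects — the qualitative pattern reported at full scale,
reproduced from its cause. A separate 40-subject null cohort (motion
varying 0.02–0.25 mm, no coupling) verifies that mean QC-FC stays within
±0.1 of zero and the distance-dependence CI covers zero. These problem
sizes keep the entire suite and the acceptance script in seconds while
leaving the mechanism comfortably detectable.

## Numerical choices and edge cases

* Rank and dof use a pivoted QR with tolerance $10^{-9}$; rank-deficient
  designs are projected anyway (residuals are unique even when coefficients
  are not) and the effective rank is reported. A design that saturates the
  retained rows yields dof 0 with an `over_determined` flag — the "not
  enough degrees of freedom" condition.
* At the Nyquist frequency only the cosine regressor exists (the sine is
  identically zero on the grid); the zero frequency is the polynomial
  constant.
* The smoothness estimator clamps a direction to 0 when the first-difference
  variance reaches that of independent noise ($\sigma_\Delta^2 \ge 2\sigma^2$);
  estimates below about one voxel are not meaningful, and the estimator is
  validated instead on recovery of known ≥ 2-voxel kernels (within ±10% at
  64³). Masked Gaussian smoothing is separable FFT convolution renormalised
  by the blurred mask, so signal does not bleed across the boundary;
  wrap-around is irrelevant for interior masks.
* FCS includes the self-correlation term, which is what makes the
  scaled-global identity exact; the difference from "all other voxels" is
  $O(1/V)$. The identity is tested against the brute-force pairwise mean to
  $10^{-10}$.
* The flip check performs only an exhaustive integer-voxel translation
  search (±10 mm) around pre-aligned inputs; full registration is out of
  scope, and ties go to "not flipped". The mirror axis is whichever grid
  axis the orientation code maps to left-right, not blindly the first array
  axis.
* Zero-variance voxels, regions and edges are excluded and counted at every
  stage, never silently zeroed.
* The QC-FC distance-dependence CI uses the Fisher interval with $n$ = the
  number of edges. Edges are not independent, so the interval is
  anti-conservative; it is reported in this conventional form and labelled
  as such.

## Open design choices

Where the procedure admitted more than one reading, the package fixes one
and records why:

* Group-mean FC includes each subject in its own mean by default ("the
  group average" read literally); a leave-one-out variant is provided, and
  at $n = 40$ the two orderings of subjects correlate above 0.99, so the
  choice is immaterial at cohort scale.
* QC-FC operates on Fisher-Z edges (the variance-stabilised companion of
  Z-space group averaging); at the small edge correlations involved,
  $z \approx r$ and the choice is cosmetic.
* Motion-file column order is a declared convention (rotations first by
  default) because realignment tools disagree and the files carry no
  header.
* Seed coordinates are interpreted on signed world axes (+R, +A, +S), with
  signs mappable per configuration, since printed coordinate triplets are
  ambiguous across template conventions.

## Limitations

The phantom's noise is white in space and time; real fMRI noise is neither,
so absolute metric values (TSNR, smoothness) on real data will differ from
phantom values even when the pipeline is identical. The package consumes
realignment parameters and pre-aligned images; it does not estimate motion,
register images, or segment tissue. Qualitative review — scrolling
concatenated volumes, judging anatomy — is supported only by static montage
export with a cohort-fixed intensity window.
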