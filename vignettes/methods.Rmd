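---
title: "Methods: regional DOT analysis of cerebral oxygenation during head-up tilt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regional DOT analysis of cerebral oxygenation during head-up tilt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(huttdot)
```

## The problem

During a head-up tilt table test (HUTT) a supine subject is tilted to 70
degrees, held there, and returned supine. In Parkinson's disease (PD),
autonomic degeneration can impair the compensatory response that normally
maintains cerebral perfusion against the orthostatic challenge. Continuous-
wave diffuse optical tomography (DOT) over the forehead measures prefrontal
oxyhemoglobin (HbO) changes throughout the tilt with enough spatial
resolution to assign them to individual frontal gyri. Two signatures matter:

* the **rate of HbO change** from the dynamic tilt into the early static
  tilt (the 15-60 s window after tilt onset) per gyrus — healthy controls
  and one PD subgroup dip and then recover (positive rate), while PD
  patients with orthostatic hypotension (OH) and a second PD subgroup rise
  during the tilt and then decline without recovery (negative rate);
* **laterality** — the deficit groups show asymmetric reoxygenation with a
  stronger right-hemisphere involvement.

The package implements the full chain from raw channel intensities to these
statistics plus a bagged decision-tree classifier of the patient subgroups,
together with a calibrated synthetic cohort generator so that every stage is
testable without patient data (none were deposited by the underlying study).

## Processing chain and its assumptions

Channel preprocessing runs in a fixed order: optical-density conversion,
0.2 Hz low-pass, 5-point moving average, wavelet despiking, modified
Beer-Lambert inversion, baseline correction. The measurement literature
lists these steps without fixing their order; we fix it for reproducibility
and document each stage's tunables.

* **Optical density**: $\Delta OD(t) = -\log_{10}(I(t)/\bar I_{\rm ref})$
  per channel and wavelength, with $\bar I_{\rm ref}$ the *geometric* mean
  intensity over the 20-s pre-tilt baseline, so the OD baseline average is
  exactly zero.
* **Low-pass** (`cutoff = 0.2` Hz): 4th-order Butterworth applied forward
  and backward for zero phase. The forward-backward pass is computed
  explicitly over a mirror-padded series so filter transients decay inside
  the pads; DC gain is 1 to $10^{-10}$.
* **Moving average** (`window = 5` samples at 5 Hz): centered mean with
  shrinking windows at the edges, preserving series length.
* **Wavelet despiking** (`alpha = 1.5`): full-depth Daubechies-5
  maximal-overlap discrete wavelet transform (MODWT, implemented in the
  package); per level, detail coefficients farther than `alpha` interquartile
  ranges from the level median are zeroed, and the series is reconstructed.
  The MODWT is shift-invariant and energy-conserving, so despiking can only
  remove energy. The endpoint-connecting line is subtracted first so the
  circular transform sees no wrap-around jump. Because the MODWT is
  redundant, re-analysis of a despiked series slightly redistributes
  coefficient mass: a second application changes the series RMS by well
  under 1% but is not an exact no-op. The decomposition depth, threshold
  statistic, and the chain position of despiking are explicit package
  choices (the measurement literature leaves them open).
* **MBLL** (`dpf = 1`): per channel the 2x2 extinction system is solved
  with base-10 coefficients at 760/830 nm (0.5864/1.5485 and 0.9740/0.6930
  (mM cm)^-1 for HbO/Hb, the standard compiled tabulation, shipped as
  `inst/extdata/extinction_coefficients.csv` and overridable). With DPF = 1
  concentrations are reported per differential pathlength factor (mM/DPF),
  matching the reporting unit of the calibration targets.
* **Quality control**: a channel is dropped when its mean intensity falls
  below `min_intensity` or any sample saturates; a subject is flagged when
  more than half the channels drop. The thresholds are package defaults,
  not measured device properties.

## Image reconstruction

The probe is modelled from a channel table (midpoint, in-plane axis,
nominal separation); per-channel source/detector positions are synthesized
as midpoint ± (separation/2)·axis. The study hardware's optode coordinates
were never published, so no attempt is made to reconstruct a globally
consistent optode layout — only per-channel geometry enters the forward
model. The default fixture reproduces the published separation multiset
(40/20/32/16 channels at 15/30/36/45 mm) over a 120 x 40 mm forehead patch.

The forward model is a first-order Rytov row per channel on a
24 x 12 x 8 voxel grid at 5 mm spacing,
$A_{cv} = G(r_s, r_v) G(r_v, r_d) / G(r_s, r_d) \cdot \Delta V / \ln 10$,
with $G$ the semi-infinite-medium diffusion Green's function with an
extrapolated-boundary image source ($\mu_s' = 1.0$ mm^-1, $\mu_a = 0.017$ /
$0.019$ mm^-1 at 760/830 nm, all overridable). This analytic model replaces
Monte-Carlo photon transport on a template head: it is deterministic,
desk-scale, and standard for CW-DOT prototyping, at the cost of ignoring
scalp/skull layering and curvature.

The inverse uses Tikhonov regularization with a spatially variant diagonal
$L = \mathrm{diag}(\sqrt{\mathrm{diag}(A^TA)} + \beta \max \sqrt{\mathrm{diag}(A^TA)})$:

$$x = L^{-1} \tilde A^T (\tilde A \tilde A^T + \lambda\,\max \mathrm{diag}(\tilde A \tilde A^T) I)^{-1} y,
\qquad \tilde A = A L^{-1},$$

with defaults $\lambda = 0.01$, $\beta = 0.1$. The named depth-compensation
technique has no unique published formula; this sensitivity-normalizing
family is one standard realization. Reconstructed chromophore images are
averaged (unweighted) over six axis-aligned boxes at 12.5-22.5 mm depth
standing in for the AAL left/right superior, middle and medial frontal
gyri; the boxes are mirror-symmetric across the midline and sit under the
probe patch.

**Depth resolution caveat.** Single-voxel perturbations at the shallowest
gyral slab (12.5 mm) are localized to within one voxel; deeper
perturbations are pulled toward the surface, as expected for CW reflectance
DOT even with depth compensation. Region averaging over the full slab is
correspondingly depth-blurred; region *time courses* are nevertheless
recovered with correlation above 0.95 in noiseless inverse-crime tests.

## Features and statistics

Phases follow the tilt events: 20-s baseline, dynamic tilt (0-15 s), static
tilt (15 s to the per-subject tilt-down time), post-tilt. The rate feature
is the OLS slope of gyrus-averaged HbO over 15-60 s. The published unit
(1e-4 mM/DPF) carries no time denominator; the package reports slopes **per
minute**, and the generator and extractor share this convention, so the
calibration is self-consistent whatever the original study's denominator
was.

PD subjects with normal tilt results are split by the sign of the *global*
rate (arithmetic mean of the six gyrus slopes; exactly zero — a
measure-zero event — goes to the positive group). Which aggregate the
original analysis used is unstated; the whole-prefrontal average of the
precursor study motivates the mean-of-gyri default, and a single-region
rule is available in configuration.

Group trajectory comparisons use Welch's unequal-variance two-tailed t-test
per region per time sample, and laterality uses a paired t-test of the
within-subject left-minus-right difference per gyrus pair (the original
report says only "two-tailed t-test"; Welch is the safer unpaired choice
and pairing is natural for a within-subject contrast). Flags are per
timepoint at p < 0.05 with **no multiplicity correction**, mirroring
per-timepoint significance bars; they are descriptive, not inferential.
When both groups have zero variance at a sample, p is defined as 1.

## Classification

The classifier is a bagged ensemble (default 1000 trees) of CART trees
grown to purity with Gini impurity, `m_try = ceiling(sqrt(p))` random
features per split (the MATLAB classification default of the tool named in
the study), and deterministic tie-breaks (lowest feature index, lowest
threshold, lowest class index) so every ensemble is exactly reproducible
from its seed. Out-of-bag (OOB) accuracy votes each subject only through
trees whose bootstrap excluded it. Importance is permuted-delta-error:
per tree and feature, the feature is permuted among that tree's OOB rows
(OOB-only permutation, the standard semantics of the named implementation)
and the change in tree OOB error recorded; a feature's importance is
mean/sd of these deltas over trees, then the vector is normalized by its
maximum absolute value. Features are the six gyrus rates plus clinical
covariates; healthy controls carry no PD metrics and are excluded from
classification. The three trials are tilt-normal vs OH, the
positive-vs-negative subgroups, and the three-class problem. Accuracy is
reported as mean ± sd over independently seeded replicate cohorts.

## The synthetic cohort

`region_direct` mode draws, per subject, six gyrus slopes from an
equicorrelated multivariate normal with the published group mean and sd
(HC 7 ± 8.1, PD-OH −5.6 ± 6.7, PD-POS 8.5 ± 6.3, PD-NEG −9.9 ± 9.9, in
1e-4 mM/DPF per min) and builds piecewise trajectories: zero baseline, a
smooth dynamic-tilt transient (dip for HC/PD-POS, rise for PD-OH/PD-NEG,
amplitude 2), the linear rate segment over 15-60 s, a plateau through the
rest of the static tilt, and an exponential post-tilt return (time constant
20 s). The realized fit-window slope equals the stored truth exactly, which
the noise-free recovery tests exploit. Clinical covariates are truncated
normals / Bernoullis at the published group values; motor and non-motor
symptom flags have no published prevalences and are non-discriminative
stand-ins (0.4/0.6 in all PD groups).

Choices the published summaries do not determine, fixed once here:

* **Inter-region correlation** of the six slopes, ρ = 0.8 — gyrus-averaged
  signals from one compact cortical patch are strongly shared.
* **Right-hemisphere deficit multiplier** 1.3 in PD-OH/PD-NEG. It is
  applied mean-preservingly (left mean $2m/(1+k)$, right mean $2mk/(1+k)$),
  so the group's global mean still equals the published value — otherwise
  the deficit would bias the calibration the rate-recovery checks compare
  against.
* **Timing**: baseline 20 s, dynamic 15 s, static 180 ± 30 s uniform
  per-subject jitter (static durations varied between subjects), post-tilt
  60 s, at 5 Hz.
* **Noise**: cardiac (1.1 Hz, amp 0.1), respiratory (0.25 Hz, 0.2), Mayer
  (0.1 Hz, 0.3) sinusoids with random phases, white noise (sd 0.3),
  random-walk drift (step sd 0.02), all in 1e-4 mM/DPF; motion spikes are
  channel-level (OD scale) and appear only in `full_optical` mode.
* Hb is generated as −0.3 × HbO plus noise, a typical anticorrelation; the
  published figures show Hb but do not quantify it.

`full_optical` mode paints the region trajectories into the atlas voxels,
composes absorption perturbations through the extinction coefficients,
applies the sensitivity matrix, adds channel noise, and exponentiates
around a reference intensity — the same forward model the inverse uses.
This *inverse crime* is deliberate: it isolates pipeline correctness from
model mismatch. A mismatch mode (perturbed optical properties) exists for
exploration but is not part of the acceptance checks. Because subgroup
labels in the synthetic cohorts are deterministically the sign of the mean
of the same six features the classifier sees, the synthetic subgroup
classification task is somewhat *easier* than the real one (where
subgrouping came from a separate whole-prefrontal rate estimate), and its
accuracy runs a few points above the published 89.4%. Passing tests
demonstrate pipeline correctness under these stated conditions, not
real-data performance.

## Problem sizes and determinism

The package's own verification runs use: 2,000-subject single-group
cohorts for rate-calibration recovery; 50 replicate cohorts at the analyzed
sample sizes (10/17/12) with 1000 trees per ensemble for classification;
100-subject-per-group cohorts for the laterality pattern checks; and a
24 x 12 x 8 grid with 108 channels for reconstruction. Every stochastic
step (cohort draws, bootstraps, permutations) is seeded explicitly, and a
fixed configuration reproduces byte-identical outputs.

## Known limitations

* The probe fixture and region boxes are stated stand-ins: the study's true
  optode layout and channel-to-gyrus sensitivity pattern are not
  recoverable from its text.
* The analytic semi-infinite forward model ignores tissue layering and head
  curvature; depth localization is limited as described above.
* Laterality and subgroup structure of the synthetic cohorts rest on the
  invented ρ and deficit multiplier; only the per-group global-rate and
  covariate distributions are calibrated to published values.
* Pointwise significance flags are uncorrected for multiplicity by design.
* No blood-pressure waveforms are simulated; OH group membership is a
  generator label, not a diagnosis.
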