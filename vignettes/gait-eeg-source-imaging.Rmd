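---
title: "Gait-cycle-resolved EEG source imaging: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gait-cycle-resolved EEG source imaging: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitsource)
```

## What the pipeline computes

Walking EEG from a 19-channel 10–20 montage is segmented into full
strides anchored at right heel strikes, each stride is time-warped onto a
common gait-phase axis (heel strikes pinned to 0, 50 and 100% of the
cycle), and the warped sensor data are inverted through a combined
cortical + cerebellar source model. The result is a per-vertex z-score
map for each gait-cycle quartile (0–25, 25–50, 50–75, 75–100%),
normalized to the 1-s pre-stride baseline, with family-wise inference by
maximal-statistic sign-flip permutation. A second, sensor-level branch
quantifies phase coupling between the occipital electrodes (O1/O2, the
scalp locations closest to the cerebellum) and the rest of the montage:
phase-locking values (PLV) and the imaginary part of coherency (ImCoh)
from a Morlet decomposition of consecutive 2-s epochs, and the difference
between the PLV of the original O1/O2 and of their spherical-spline
reconstruction from the other electrodes.

Every stage is testable against ground truth because the package ships a
generator that plants dipolar sources, gated to chosen gait-cycle
quartiles, and forward-projects them through the same head model.

## Head model and source spaces

Template anatomy and a boundary-element forward solution are replaced by
a three-shell concentric spherical head model (brain/skull/scalp radii
0.087/0.092/0.100 m, conductivities 0.33/0.0042/0.33 S/m). The potential
of a current dipole is evaluated by the Legendre-series solution of the
concentric-shell boundary-value problem; with equal conductivities the
series reduces to the homogeneous-sphere closed form, which serves as an
independent oracle in the tests (agreement to 1e-8 relative). The
spherical model keeps every algorithmic property under test — linearity,
common-average consistency, depth attenuation — while being exactly
computable, at the cost of anatomical realism (no folded cortex, no
skull holes, no individual geometry).

The cortical source space is a Fibonacci lattice on the upper cap of a
0.070 m sphere; the cerebellar space is an inferior–posterior patch at
0.055 m — deeper and lower, so cerebellar lead-field columns are weak
and posterior-dominant at the scalp (O1/O2/T5/T6), which is exactly the
low-SNR regime that motivates stride averaging. Dipole orientations are
fixed to the surface normals (radial). Cortical vertices are labelled by
the nearest ROI seed direction using the montage itself (frontal
F3/F4/Fz, central C3/C4/Cz, parietal P3/P4, temporal T3/T4, occipital
O1/O2; hemisphere from the winning electrode, midline seeds split by the
vertex's own left/right position). FCz appears in some ROI conventions
but is not part of the 19-channel montage, so it is not used. Cerebellar
parcellation finer than left/right is not attempted: 19 channels cannot
resolve it.

## Inverse solutions

Both estimators are linear kernels on common-average-referenced data.

* **wMNE** — depth weights `w_v = ||l_v||^gamma` (default `gamma = 1`),
  kernel `W^-1 L' (L W^-1 L' + lambda^2 I)^+`.
* **eLORETA** — weights from the fixed-point iteration
  `w_v = sqrt(l_v' (L W^-1 L' + lambda^2 H)^+ l_v)` with `H` the
  common-average projector, iterated to a relative change below 1e-6.

`reg_lambda` is dimensionless: `lambda^2` multiplies the mean diagonal of
`L W^-1 L'`, which makes kernels scale-covariant (scaling the lead field
by `c` scales the kernel by `1/c`). The defining contrast, verified
exhaustively in the tests: in the noiseless small-`lambda` limit eLORETA
localizes a single dipole at *every* vertex of the 600-vertex combined
space with zero error, while wMNE mislocalizes the deep cerebellar
vertices. This is why the weighted family matters for cerebellar EEG.

## Gait epoching, warping, quartiles

Strides are right-heel-strike to right-heel-strike with exactly one
interior left heel strike; durations outside 0.5–2.5 s are discarded
(freezing episodes, sensor dropouts), and each stride carries the 1 s of
data before its onset as baseline. The warp is the two-segment linear
map `[RHS0, LHS] -> [0, 50]%`, `[LHS, RHS1] -> [50, 100]%`, resampled at
`G` uniform phase points `100 (j-1)/G` (default `G = 200`, i.e. 0.5%
resolution — finer than the 25% reporting granularity by a wide margin).
The grid covers `[0, 100)`; phase 100% is the next cycle's 0%, so the
three heel strikes sit at grid point 1, grid point `G/2 + 1`, and the
first grid point of the following stride. Quartile bins are half-open
(`[0,25) ... [75,100)`), so the four slices partition the grid exactly.

Resampling uses vectorized linear interpolation by default (cubic
splines optional). At 512 Hz with analysis content below ~45 Hz the
linear-interpolation error is orders of magnitude below every tolerance
used here (the jittered phase-locked-sinusoid test bounds the
across-stride variance at each phase point by 1% of the squared
amplitude; the observed value is ~1e-6).

## Baseline z-scores: the convention decision

The z-score convention for "normalized to baseline" was genuinely open.
Implemented default: per vertex and quartile,
`z = (m_active - m_base) / (s_base / sqrt(n))`, where `m_active` is the
across-epoch mean of the quartile-mean amplitude, and `m_base`, `s_base`
are the mean and sd across epochs of the per-epoch baseline mean. This
"sem" convention makes z grow with evidence (hundreds of strides give
large z for stable activations, consistent with gait studies reporting
z-scores far beyond single-epoch variability). The alternative
(`convention = "sd"`, dividing by `s_base` alone) is config-selectable;
amplitudes enter as absolute values by default (`summary = "abs"`) since
orientation-signed estimates would otherwise cancel.

Two caveats the tests make explicit. First, on matched inputs the maps
are unbiased (pure-noise maps center on zero). Second, in the full
pipeline the active samples pass through interpolation while the raw
baseline does not; interpolation slightly reduces noise variance, so at
very low SNR all vertices share a common negative offset that the `sem`
convention amplifies. Quantities that compare quartiles or subjects —
the arg-max quartile, the gait-phase contrast (Q2+Q3 vs Q1+Q4) used for
group inference — cancel this common term, and those are the quantities
the pipeline reports. Absolute single-condition z values at per-epoch
SNR well below 1 should not be over-interpreted.

## Permutation inference

Group inference uses the maximal-statistic sign-flip permutation test on
subject difference images: under the null the difference images are
symmetric about zero, each permutation flips subject signs, and the 95th
percentile of the permuted image-wide max |t| is the FWER threshold.
The identity relabelling is always included in the permutation set
(excluding it makes the test anticonservative; with it, the measured
family-wise error over 1000 null simulations at 12 subjects, 800 voxels
and 500 permutations is within the binomial confidence band of 5%).
When `2^subjects <= n_perm` the full sign-pattern set is enumerated and
the result is exact and deterministic; the empirical percentile uses the
order statistic (type-1 quantile) so the exhaustive and brute-force
paths agree bitwise. Per-voxel corrected p-values are returned so any
display threshold can be applied downstream.

## Connectivity constructs

The Morlet decomposition (7 cycles, unit energy, 20 log-spaced bins over
2–45 Hz by default — below the 50 Hz notch) yields one coefficient per
channel, frequency and consecutive 2-s epoch, taken at the epoch center.
PLV is the modulus of the epoch-averaged unit phasor of the phase
difference; ImCoh is the imaginary part of the normalized epoch-averaged
cross-spectrum. Their discriminating properties are tested directly:
ImCoh of any instantaneous mixture of one source is zero (volume
conduction insensitivity); PLV is exactly 1 under any constant lag.

The spherical-spline interpolation is Perrin-style: order `m = 4`,
7-term Legendre series, Tikhonov 1e-8 on the solve, with the constant
constraint, so constants are reproduced exactly and low-order fields to
~0.4%. The PLV difference (original minus interpolated targets,
computed against every channel including the other target) isolates
phase-locking the cortical scalp field cannot explain. The
target–target (O1–O2) pair carries most of the evidence: an independent
lagged oscillation confined to the occipital channels — the synthetic
stand-in for a cerebellar generator — produces a positive difference at
its frequency, while targets that are exactly interpolable (plus sensor
noise) stay within ±0.05 at 500 epochs. One behaviour worth knowing:
because interpolation averages independent sensor noise across
electrodes, at very low SNR the interpolated signals are *cleaner* than
the originals and the difference can go negative at all frequencies;
the construct is informative about locally generated signal, not a pure
zero-mean null statistic.

## Artifact handling

Filtering follows the clinical acquisition description: a zero-phase
Hamming FIR band-pass (1–200 Hz, 7500 taps at 512 Hz, applied with group
delay compensation) and a 3302-tap notch at 50 ± 2 Hz. The recording
system's two filter order descriptions are reconciled as one band-pass
of configurable order plus the notch; both orders are config keys. The
band-pass refuses orders whose Hamming transition band (≈ `3.3 rate /
order`) cannot fit below the low edge.

Infomax ICA (natural gradient, logistic nonlinearity, PCA whitening with
rank handling for common-average data) runs on continuous data before
epoching. Learning-rate annealing is twofold: a 0.9 factor when
successive weight updates turn by more than 60°, plus a slow geometric
cooling (0.99 per pass after a 10-pass burn-in) so that the stochastic
block-update noise floor, which scales with the learning rate, always
falls below the convergence tolerance. With a fixed seed the
decomposition is bit-reproducible. Components are rejected by
reproducible rules replacing visual inspection: absolute EOG correlation
above threshold, or low-frequency (< 4 Hz) to broadband power ratio
above threshold. Epoch rejection drops strides with any |sample| above
±200 µV or any channel flatlining below 0.5 µV peak-to-peak;
thresholds are configurable, and rejection can run before or after ICA
(default: ICA first, the EEGLAB-conventional order).

## The synthetic generator: what it emulates and what it does not

Defaults emulate the acquisition conditions: 512 Hz, 19 channels, ~500
strides of 1.1 s with 5% duration jitter (≈ 9 min of walking), left
heel strike at 50 ± 2% of the stride, mains at 50 Hz with
channel-specific gains (so it survives common-average referencing),
optional frontal eye-blink transients with a synchronous EOG channel,
and white sensor noise scaled to a per-epoch SNR of 0.5 — low enough
that planted sources are invisible in single strides and only epoch
averaging recovers them, which is the premise of the whole design.
Sources are gated to their active quartiles with raised-cosine ramps
(10% of quartile width) to avoid the spectral splatter of step gating.

Not emulated: biomechanical artifacts locked to heel strike (a major
confound in real gait EEG), muscle EMG, electrode motion, cortical
background with realistic 1/f spectra and spatial correlation (the
connectivity tests add band-limited cortical background explicitly), or
per-subject anatomy. Passing tests therefore demonstrate algorithmic
correctness under the stated noise model, not robustness to every
real-world artifact class.

## Epoch-count note

The source publication reports internally inconsistent epoch counts for
the same protocol (428 ± 25 in one table; 850 ± 75 before and 650 ± 80
after pruning in the narrative). Nothing here assumes an expected count;
the generator default of 500 strides sits inside the reported range.

## Problem sizes used by the shipped checks

Chosen to keep the full verification run on one CPU core in well under
half an hour: localization sweeps on the full 600-vertex space; FWER
calibration with 1000 null simulations (12 subjects, 200 vertices × 4
quartiles, 500 permutations); gait-phase recovery over 100 end-to-end
runs of 500 strides at 512 Hz on a 250-vertex space with the z-maps
evaluated on the cerebellar ROI (per-vertex estimates are independent,
so the ROI restriction reproduces the full map's values at those
vertices); connectivity nulls at 500 two-second epochs and detection
over 100 runs at 100 epochs; BH cross-validation on 10,000 random
p-vectors. The acceptance script uses the same constructions with 50
recovery runs.

## Known limitations

* The spherical head model is the one deliberate deviation from a
  template-anatomy BEM; localization claims transfer to real anatomy
  only qualitatively.
* 19 channels bound the resolvable source geometry; cerebellar findings
  rest on the posterior-channel proxy and the interpolation-difference
  construct, not on fine parcellation.
* The clinical–EEG "multiple correlation coefficient" has no published
  formula; `multiple_correlation()` implements sqrt(R²) of an OLS fit
  and is flagged experimental.
* Wilcoxon p-values with zero differences use Pratt's normal
  approximation; exact small-sample distributions apply only without
  zeros or ties.
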