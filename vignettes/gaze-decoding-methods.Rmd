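---
title: "MR-based eye tracking with gazemri: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MR-based eye tracking with gazemri}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

When the eyes rotate, the multivoxel MR pattern inside a mask covering the
eyeballs changes deterministically: lens and anterior-chamber voxels are
hypointense, and their position within the eyeball tracks the line of sight.
`gazemri` decodes on-screen gaze position — and, in a variant, the
eyes-open/closed state — from exactly this signal, one functional volume at a
time, with no temporal model and no hemodynamic component.

The decoder is a 3D convolutional regression network. Input volumes (the
eye-mask crop, normalized as below) pass through a stem convolution (kernel 3,
stride 1), dropout, a downsampling block (convolution + 2x2x2 average
pooling), and six residual blocks. Each residual block adds a convolutional
skip path to a main path of two (GroupNorm, mish, convolution) stages; two
further pooling stages sit after residual blocks 2 and 4. With the default
geometry (16x32x16 input, 60 base filters doubling per stage) the flattened
bottleneck has 2x4x2x480 = 7,680 units. The bottleneck feeds `n_sub` (default
10) *unshared* dense heads, one per sub-TR time point, each emitting an
(x, y) pair in visual degrees, plus one dense confidence head that predicts
the network's own Euclidean error (the PE), passed through softplus so it is
nonnegative.

Training minimizes, per batch,

    L = 0.1 * L_MSE + L_ED

where `L_ED` is the mean over sub-TR labels and volumes of the 2D Euclidean
distance between predicted and true gaze, and `L_MSE` is the mean squared
error between the PE and the *realized* per-volume Euclidean error. Two
detachment rules keep the confidence head honest:

* the realized error enters `L_MSE` as a constant (no gradient flows through
  the gaze pathway via the PE target), and
* the PE head reads a stop-gradient copy of the bottleneck, so optimizing the
  PE cannot move the gaze pathway at all. Without this second rule a shared
  trainable trunk would let the 0.1-weighted PE loss perturb gaze decoding;
  with it, freezing the gaze heads and training only the PE provably leaves
  `L_ED` unchanged, which the test suite asserts.

The per-volume Euclidean error is the *mean* (not the sum) over the `n_sub`
per-label distances, keeping the loss scale independent of the head count;
per-participant errors aggregate TRs by the mean (a `median` option is
exposed), and group summaries use the median across participants.

## Input normalization

Volumes are cropped to the eye-mask bounding box, voxels inside the box but
outside the mask are zeroed, and two normalization stages are applied in a
fixed order:

1. **Temporal**: per voxel, subtract the across-run median and divide by the
   median absolute deviation over time. The MAD carries no 1.4826 consistency
   factor, and a MAD of zero (constant voxel) maps the voxel to zero rather
   than NaN — constant voxels carry no information and must not poison
   training.
2. **Spatial**: per volume, z-score across mask voxels using the population
   (n) standard deviation; zero-variance volumes map to zero.

The composition is invariant to any per-voxel affine rescaling of the raw
data with positive gain, so scanner-specific intensity scaling cannot leak
into the decoder; this invariance is property-tested.

Camera eye-tracker exports are prepared by `clean_gaze_trace()` (blink
removal, pupil-size outlier rejection, polynomial detrending, 100-ms running
average, median centering — each optional, in that order) and binned by
`bin_to_subtr()` into `n_sub` equal within-TR bins with per-bin medians.
Empty bins fill from the nearest nonempty bin; a fully empty TR copies the
previous TR and is flagged in a gap report. The even-count median is the mean
of the middle two order statistics. Screen-center offsets can be estimated
from training labels (median gaze) and subtracted after decoding.

## Cross-validation, schedule, augmentation

Three fold schemes are provided: across participants (k = 5 partitions,
80%/20% train/test, every participant tested once), within participants (two
contiguous halves per participant — contiguity avoids temporal leakage between
train and test), and leave-one-dataset-out. The default schedule is Adam,
batch size 8, 1,500 steps per epoch (12,000 samples/epoch); small training
sets use the epoch rule e = 2 + N for N training participants. Batches always
mix at least two participants when the pool allows. The default learning rate
is 1e-4, the log-scale midpoint of the 1e-3..1e-5 search range; the reduced
phantom harnesses below use 1e-3, inside the same range, because the small
networks tolerate it and converge in far fewer steps.

Augmentation applies per-sample affine transforms (spatial scale, per-axis
translation, azimuth/pitch/roll rotation) with labels left unchanged — the
transforms emulate residual co-registration error, under which true gaze is
unaltered. Full-scale defaults are scale 0.9-1.1, translation +/-2 voxels,
rotation +/-10 degrees. On the reduced 8x16x8 phantom the same physical
reasoning gives proportionally smaller magnitudes (scale 0.97-1.03, +/-1
voxel, +/-1 degree, applied to 30% of samples): on a grid whose eyeballs are
2.5 voxels in radius, a 10-degree rotation would corrupt the effective gaze
label by about half the screen window.

## The synthetic eyeball phantom

The phantom renders two spherical eyeballs whose intensity deficit at a voxel
is `lobe_contrast * max(0, cos angle(voxel direction, gaze direction))` —  a
smooth, cheap stand-in for the lens/pupil hypointensity, differentiable in
gaze. Both eyes move conjugately; vergence is not simulated. Gaussian noise
(not Rician: normalized magnitude data at eyeball SNR is approximately
Gaussian) is added once per volume. Per-participant gain and offset are drawn
from configured ranges, and misalignment outliers receive an integer-voxel
translation of every volume, emulating failed co-registration.

Choices a user should know about:

* **`gaze_gain = 2`** (degrees of rotation per degree of gaze). Physical eyes
  have gain 1, but the phantom grid is far coarser than real 2-mm voxels; the
  doubled gain maps paper-scale screen windows onto a rotation range the grid
  can resolve, so that gazes one grid step apart differ by more than
  0.1 x `lobe_contrast` in at least one voxel (asserted on a 5x5 gaze grid).
  Contrast magnitudes are free parameters of the phantom; absolute decoding
  errors on the phantom are therefore not comparable to the degree-scale
  errors reported for real data.
* **Motion blur** is a weighted mean over the `n_sub` within-TR renders with
  *uniform default weights* (an arithmetic mean). A uniform mean is exactly
  reversal-symmetric, so the temporal order of within-TR gaze is provably
  unidentifiable from a single volume. In real acquisitions, slice timing
  breaks this symmetry; the phantom does not simulate slices, so the optional
  `subtr_weights` parameter (an increasing profile) emulates that
  acquisition-order asymmetry. The sub-TR resolution experiment uses it; all
  other experiments keep the uniform default.
* **Eyes closed**: closure fraction c scales the gaze lobe by (1 - c) and
  adds an anterior eyelid band proportional to c, so a fully closed eye is
  gaze-independent — the premise of eyes-open/closed classification.
* The phantom emulates gaze-dependent voxel patterns, participant gain/offset
  variation, motion blur, closure and misalignment. It does **not** emulate
  B0 distortion, susceptibility artifacts, physiological noise, slice timing,
  head anatomy, or vergence; passing phantom tests therefore demonstrates
  correctness of the pipeline's mechanics, not real-data accuracy.

## Desk-scale validation experiments

All heavy validation runs use a reduced geometry chosen to finish on a single
CPU in minutes while exercising every mechanism: an 8x16x8 voxel phantom
(eyeball radius 2.5), a reduced network (8 base filters, bottleneck 128,
dense heads of 64 units), pursuit at 4 deg/s over a 10x10-degree window with
200 TRs per participant, 10 participants, e = 2 + 8 epochs of 80 steps.
Two of the eight training participants carry 2- and 3-voxel misalignments:
real training cohorts contain poorly co-registered participants, and this
quality variation is exactly what lets the PE head learn to recognize
unreliable inputs (mirrored in how the confidence head is described as
learning "how the input looks when the error is high"). Held-out clean
participants decode at Pearson r above 0.9; decode-only cohorts with graded
0-4-voxel misalignment show a strong PE-EE rank correlation, and a single
3-voxel outlier among ten receives the highest PE.

The sub-TR experiment needs most of the gaze-path variance to live *within*
TRs: fast pursuit (16 deg/s over a 12-degree window, direction changes at
every TR boundary) makes the target sweep the screen within each volume, so
per-TR medians explain little, and the increasing blur weights make the
sweep direction identifiable. Acquisition noise is lowered to 0.02 for this
run because the decisive feature — the skew of the motion-blurred lobe — is a
second-order intensity pattern. Under these conditions decoding three labels
per TR explains visibly more upsampled-path variance than one label per TR,
mirroring the free-viewing result at 1-s TRs. The eyes-closed
experiment trains the closure variant (single head, MSE loss) on block-wise
closure series with partial-closure transition TRs and classifies the decoded
series at a 10% threshold.

## Saliency: a known limitation

The slice-shuffling saliency score permutes one randomly chosen slice's
voxels across time, re-decodes, and credits the EE increase to every voxel of
the slice (map = summed credit / participation count). Because credit is
assigned slice-wide, any background voxel sharing one axis coordinate with
the eyeballs inherits credit from eye-crossing slices. At phantom scale the
eyeballs necessarily occupy a sizeable fraction of each axis, which caps the
inside/outside saliency contrast near 2-4x regardless of training quality; a
geometry where eyes occupy under ~12% of every axis would be needed for
sharper localization, which is outside the phantom's intended desk-scale
budget. The maps do localize (eyeball mean well above background, and
zero-information slices receive essentially zero credit), and the unit suite
asserts exactly those properties.

## Nuisance regressors

Decoded per-TR median gaze yields a movement index (forward-difference path
length, final TR set to 0 as the difference leaves it undefined). Amplitudes
above the within-run 66th percentile become the "far" regressor, below the
33rd the "short" regressor; the midsection is excluded so far and short are
never both active. Percentiles interpolate linearly between order statistics
(R type 7) — membership at ties depends on this, hence it is documented and
tested. Regressors are convolved with a canonical double-gamma HRF (peak
delay 6 s, undershoot delay 16 s, unit dispersions, undershoot ratio 6,
32-s support — the conventional defaults, since the reference implementation
defers to a package default), or used raw for instantaneous-artifact models.
Percentiles are computed per run by default; a flag allows per-participant
pooling, since the original convention is unstated. Design matrices stack
far/short, optional six-column head-motion tables (BIDS-style names) and
block-diagonal run intercepts.

## Numerical notes

* Convolutions are im2col gathers plus BLAS matrix products; all backward
  passes are hand-derived and verified against central finite differences
  (worst relative error below 1e-6 on random tiny networks).
* GroupNorm uses eps = 1e-5 with population variances per (sample, group).
* The Euclidean-loss gradient at exactly zero distance is defined as zero
  (the distance is clipped at 1e-12 in the denominator).
* Weight initialization is He-normal scaled by fan-in; output layers use a
  smaller 1/fan-in scale. All randomness (initialization, batch mixing,
  augmentation, dropout, phantom rendering) flows from explicit integer
  seeds; seeded reruns reproduce loss histories to 1e-4 relative.
* FoS display truncates (floors) the integer percentage — the only convention
  consistent with all printed reference values.
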