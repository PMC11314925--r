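---
title: "Predicting ground reaction force from M-mode muscle ultrasound: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting ground reaction force from M-mode muscle ultrasound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonoforce)
```

## Overview

`sonoforce` studies whether the ground reaction force (GRF) of a maximal
isometric contraction can be predicted from M-mode ultrasound of the
contracting muscles, and whether pooling several concurrently imaged muscle
sites improves on any single site. The package is organized as a pipeline:

1. **phantom** — a generative model of the experiment (force profile, tissue
   kinematics, speckle imagery);
2. **chirp** — a physical model of the wearable frequency-sweep acquisition;
3. **mmode** — the image container, the B-mode-to-M-mode projection and all
   file I/O;
4. **features** — windowed mean-depth extraction, z-scoring, PCA;
5. **ridge** — closed-form penalized regression, smoothing, R²;
6. **evaluate** — the six-model cross-validation and held-out-test protocol;
7. **cli** — reproducible command-line runs.

This vignette records the models, the parameters that matter, and the
choices made where the design was genuinely open.

## The phantom: a stated world

The phantom emulates one subject performing repeated ~5 s maximal isometric
squats while five image streams record simultaneously: one
clinical-resolution M-mode on the vastus lateralis (VL) and four
wearable-sensor M-modes on VL, rectus femoris (RF), medial hamstring (MH)
and vastus medialis (VMO).

**Force.** Each trial's GRF is a trapezoid — a 1 s linear ramp up, a plateau
at `peak` (default 1500 N, a plausible bilateral isometric-squat maximum for
a trained adult), and a 1 s ramp down over a 5 s trial — plus additive
Gaussian noise (`force_noise_sd`, default 20 N, of the order of force-plate
noise plus physiological tremor). A trapezoid was chosen over a smoother
half-sine because its plateau value is exactly known, which makes several
tests exact. The plate samples at 1600 Hz; imaging runs at 50 Hz, and the
force is aligned to frames by **block-mean decimation** over consecutive
windows of `round(1600/50) = 32` samples — an anti-aliasing, exactly
reproducible convention, chosen because the alignment was otherwise
unspecified.

**Kinematics.** Each site has a few tissue interfaces at resting depths
within the 4 cm imaging window, and each interface displaces linearly with
the force the site transmits: `depth_j(t) = rest_j + gain_site * w_site *
F(t)`, where the contribution weights `w` are nonnegative and sum to 1
(default: equal quarters). Gains default to a fraction of a millimetre per
100 N with differing signs across sites (tissue may move toward or away
from the transducer); at the default 1500 N peak this produces interface
excursions of roughly 0.4–0.6 cm, comparable to a 25-pixel feature window.
Linearity is an *assumption of the phantom*, not a claim about muscle: it
defines the world in which a linear model should succeed, which is exactly
what makes failures of the pipeline diagnosable.

**Imagery.** A frame renders each interface as a Gaussian bright band in
depth (sd 0.06 cm ≈ a sub-millimetre interface), multiplied by unit-mean
Rayleigh multiplicative speckle (fully developed, spatially unsmoothed — the
standard worst case for an intensity-weighted estimator) and degraded by
additive white noise at a signal-to-noise ratio of 30 dB. Depth pixel `p`
(1-based) sits at `(p - 0.5) * imaging_depth / depth_px` cm — the
pixel-centre convention, stated once and used everywhere. Clinical-style
images use 256 depth pixels and wearable-style images 128, encoding the
(uncompared) resolution difference between the two systems; both are
configurable.

**What a green test establishes.** The phantom omits acoustic propagation,
attenuation, pennation geometry, out-of-plane motion, probe-pressure
artefacts and inter-subject variability. Green end-to-end tests therefore
establish that the *analysis* is correct and well-conditioned in a world
satisfying its assumptions — not that real muscles satisfy them.

## The chirp acquisition model

The wearable system transmits a 10 ms linear frequency sweep and mixes the
echo with the transmit chirp, so a reflector at depth `d` becomes a beat
tone at `f = S * 2d/c` with sweep rate `S = bandwidth / duration`: shallow
tissue is low frequency, deep tissue high frequency, everything in the kHz
band. An FFT over the sweep window recovers the A-line.

Open parameters were fixed as engineering defaults: sweep bandwidth 2 MHz
(range bin `c/(2B) ≈ 0.39 mm` over 4 cm, and kHz-band beats consistent with
down-mixing to audio-range frequencies before digitization) and baseband
sample rate 100 kHz (Nyquist-safe: the full-depth beat is ≈ 10.4 kHz). The
constructor rejects configurations whose full-depth beat would alias.
Demodulation applies a Hann window (leakage control between nearby
interfaces), zero-pads fourfold for a smooth spectrum, and linearly
interpolates the magnitude onto the pixel-centre depth grid. The carrier
phase convention `phi = 2*pi*f_c*2d/c` is fixed and documented; it cannot
affect results because only magnitudes are used.

A dedicated equivalence test confirms that M-modes acquired through this
path and M-modes rendered directly by the phantom yield mean-depth feature
series correlated at r ≥ 0.95 at 30 dB SNR: the two acquisition models
agree on kinematics, so downstream results do not depend on which path
produced the image.

## Feature extraction

Each image column is reduced by a 25-pixel moving depth window with 50%
overlap. Since 12.5 is fractional, the stride is `round(12.5) = 12` pixels
(the denser choice); only full windows are kept, giving
`floor((depth_px - 25)/12) + 1` features (20 at 256 px, 9 at 128 px).
Within a window the feature is the intensity-weighted mean depth. Depth is
measured in cm via the depth axis rather than in pixel indices; the two
differ by a fixed affine map, which z-scoring removes, so the choice is
harmless and the physical unit is more interpretable. A window whose
intensities sum to zero (possible in noise-free synthetic data) falls back
to its central depth with a warning instead of propagating NaN.

Features are z-scored and projected onto the smallest set of principal
components explaining ≥ 99% of the training variance. Two conventions make
the transform deterministic and safe: component signs are fixed by making
each component's largest-magnitude loading positive, and a zero-variance
feature gets sd 1 (becoming a constant zero). The transform is fitted **per
cross-validation fold** by default — the leakage-safe reading, since the
protocol's description leaves the alternative (one global fit before
splitting) open; `refit_transform = FALSE` provides the literal single-pass
reading for comparison. A mutation test asserts the guarantee: perturbing
test-trial data leaves every fitted transform and model bit-identical.

## Ridge regression

The model is fitted in closed form: centre `X` and `y`, solve
`(Xc'Xc + kI) b = Xc'yc` with a stable linear solve (never an explicit
inverse), and recover the intercept from the means. This centring
resolution penalizes only the slopes, satisfying simultaneously the
normal-equation form without an intercept and the penalized objective with
one; the two penalty symbols (`k`, `λ`) are treated as the same quantity.
The default `k = 5` is kept as given. Because features arrive z-scored and
PCA-projected, no further scaling happens inside the solver — rescaling
there would silently change what `k` means. At `k = 0` with collinear
columns the solver falls back to the SVD minimum-norm solution with a
warning. The independent correctness check is a numeric BFGS minimizer of
the penalized objective with analytic gradient: on random 50 x 5 problems
the two agree to < 1e-6 in prediction.

Predicted test-trial force is smoothed by a centred 25-sample moving
average whose window shrinks at the edges (keeps length, no phase lag).
Smoothing is applied only on the testing path — the literal reading of the
protocol — with an optional flag to smooth validation folds too. On a 5 s
trapezoid the smoother costs < 0.01 in R², which is why held-out R² can sit
slightly below validation R² even in a noise-free world.

## Evaluation protocol

Frames from trials 1–2 are pooled and randomly partitioned into five
near-equal folds (sizes differ by ≤ 1); each fold is held out once against
a model fitted on the rest, and the mean ± sd of fold R² is reported.
Frame-level random folds mirror the stated protocol exactly, but temporally
adjacent frames are correlated, so validation R² is optimistic relative to
held-out-trial R² — the package also provides a contiguous-segment
("blocked") fold mode as a non-default option for a sterner estimate. The
last trial never enters any fit and is scored once, after smoothing.
Unstratified fold assignment follows the protocol's literal wording. All
randomness descends from a single seed, and a rerun reproduces every
number bit-exactly.

## Numerical and degenerate-input choices

- Images are stored as 16-bit-quantized delimited text plus a JSON sidecar
  (scale, depth axis, frame rate, site, provenance, orientation): portable,
  diff-able, lossless to one step in 65535. An 8-bit PNG preview is
  optional.
- `mean_depth` accumulates left-to-right in double precision — bit-for-bit
  the definitional loop — because extended-precision accumulation (R's
  `sum()`) differs at the last ulp and the function is contractually the
  loop. The windowed extractor uses vectorized column sums and is tested
  against `mean_depth` with tolerance instead.
- Degenerate cases are errors where silence would corrupt results
  (zero-variance truth in R², trajectories leaving the imaging window,
  aliasing configurations) and guarded fallbacks where a NaN would
  otherwise propagate (all-zero windows, zero-variance features).

## Known limitations

- The force–displacement coupling is linear and instantaneous: no
  hysteresis, no electromechanical delay, no fatigue drift.
- Speckle is white in space and time; real speckle decorrelates smoothly
  with tissue motion.
- The evaluation is subject-specific by construction (one phantom = one
  subject); nothing here supports cross-subject generalization claims.
- Validation R² from frame-level folds should be read as an upper bound;
  use the blocked mode when adjacent-frame correlation matters.
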