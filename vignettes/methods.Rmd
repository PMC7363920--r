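---
title: "Estimating pedestrian shoulder-line orientation from overhead depth imagelets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating pedestrian shoulder-line orientation from overhead depth imagelets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pedorient)
```

## The measurement problem

The orientation of a walking person's shoulder line is a projective quantity:
rotating the body by half a turn leaves it unchanged. We therefore model an
orientation $\theta$ as an element of the real projective line
$\mathbf{P}^1(\mathbb{R})$, with canonical representatives in
$(-\pi/2, \pi/2]$ and $-\pi/2 \equiv \pi/2$. `wrap_p1()`, `p1_signed_diff()`
and `unwrap_p1()` implement exact arithmetic on this space.

Annotating overhead depth images with shoulder orientations by hand is both
expensive and unreliable. The package instead builds a *weakly supervised*
estimator: while walking, the velocity direction $\theta_v$ (the angle of the
instantaneous velocity to the $+y$ axis, taken with $\pi$-periodicity) is on
average orthogonal to the shoulder line, so after the conventional quarter-turn
is absorbed into the definition, $\theta = \theta_v + \epsilon$ with
$\epsilon$ a small, symmetric, zero-centered residual. Velocity direction from
existing trajectory data then supplies unlimited, individually imperfect but
centered, training labels.

## Estimator

A compact convolutional network maps a square, single-channel depth imagelet
$\mathcal{I}$ (centered on one pedestrian, depth in millimetres, smaller =
closer to the sensor) to a discrete probability distribution $h_{pred}$ over
$B$ uniform bins of $\mathbf{P}^1(\mathbb{R})$ via a softmax output layer.
The defaults use $B = 45$ bins, i.e. $4^\circ$ wide; results are insensitive
to $B$ above roughly 10 bins. The point estimate is the projective circular
average of $h_{pred}$,

$$\theta_o = \mathbb{E}_{\theta' \sim h_{pred},\,\mathbf{P}^1(\mathbb{R})}[\theta'],$$

computed with the axial-statistics double-angle construction: bin centers $c$
are mapped to unit vectors at $2c$, averaged with weights $h_{pred}$, and half
the resultant's angle is wrapped back. A resultant shorter than $10^{-8}$
(e.g. a uniform distribution) has no meaningful mean and raises an error
rather than returning an arbitrary angle.

Training labels are encoded as "two-hot" distributions $h_2(\theta)$: mass on
(at most) the two bins whose centers bracket $\theta$. We choose the two
weights as the *exact inverse* of the double-angle mean — $w \propto \sin$ of
the doubled angular distances to the neighbouring centers — so that
`circular_mean_p1(two_hot_encode(theta))` returns `theta` to machine
precision and the encoding introduces no quantization error at any bin count.
To first order in the bin width these weights coincide with the familiar
linear-interpolation coefficients (at $B = 45$ the difference is
$\sim 4\times10^{-5}$ rad), but plain linear weights would leave a small
systematic round-trip error, so the sine-corrected form is used throughout,
identically in the R reference functions and in the compiled training code.

The loss is the cross-entropy $\mathcal{H}(h_{pred}, h_2(\theta_v))$
(predictions clamped at $10^{-12}$ before the logarithm). Minimizing its
expectation drives $h_{pred}$ toward the *distribution* of labels carried by
similar imagelets; because the label noise is centered, the circular average
of that distribution is the noise-free orientation. This is the self-amending
property: the point estimate converges to the truth even though every
individual label is wrong. The package verifies it empirically (see the
acceptance tests): estimators trained with $20^\circ$ Gaussian label noise
reach aggregate biases well below $0.1^\circ$, while their error measured
*against the noisy labels themselves* saturates near $20^\circ$ — the noise
floor — and their error against ground truth keeps falling with the training
set size.

### Architecture and optimization

The network is a configuration, not a constant (`net_config()`): 3×3
stride-2 convolution blocks with ReLU, global average pooling, dense layers,
and the $B$-way softmax. Defaults: channels (16, 32, 64) with one dense layer
of 128 at 64 px input (~0.1 M parameters); the desk-scale studies shipped
with the package use 32 px imagelets with channels (8, 16, 32) and dense 64
(~11 k parameters). Optimization is Adam (learning rate $10^{-3}$, batch
128), a standard choice recorded in the configuration; epochs default to 12.
The trainer is implemented in the package's compiled code (im2col + GEMM
convolutions) with all randomness drawn from R's RNG, so a single integer
seed makes initialization, shuffling and augmentation bit-reproducible on a
single thread.

### Symmetry

Orientation is equivariant under the orthogonal group $O(2)$: rotating an
imagelet by $\alpha$ adds $\alpha$ to its orientation, mirroring about the
$y$ axis negates it ($\theta \mapsto (\theta + \alpha)\det\phi$). Two
mechanisms exploit this:

* **Training augmentation.** Every presented sample receives a fresh uniform
  rotation and a Bernoulli(0.5) flip, with the label transformed
  consistently. This spreads labels uniformly over
  $\mathbf{P}^1(\mathbb{R})$ and — because the flip also negates the label
  noise — removes any net offset the finite training sample's noise would
  otherwise imprint.
* **Group averaging at prediction** (`group_average_orientation()`). A
  strictly equivariant estimator $\tilde f$ is built by averaging
  $(f(R_\alpha\mathcal{I}) - f(JR_\alpha\mathcal{I}))/2 - \alpha$ over
  rotations. Discretely, for each sampled $\alpha_j$ (a uniform grid
  $2\pi j/k$ or i.i.d. uniform draws) the imagelet is evaluated plain and
  mirrored, giving the paired terms
  $\mathrm{wrap}(f(R_{\alpha_j}\mathcal{I}) - \alpha_j)$ and
  $\mathrm{wrap}(-f(JR_{\alpha_j}\mathcal{I}) - \alpha_j)$; the $2k$ terms
  are pooled with the projective circular mean. Averaging the wrapped paired
  terms (rather than the raw half-difference) avoids the half-turn ambiguity
  that the literal difference of two wrapped representatives can pick up,
  and reduces to the same quantity whenever the terms are coherent. Plain
  arithmetic averaging is ill-defined at the wrap point, which is why the
  circular mean is used; a constant (incoherent) estimator produces a
  degenerate term set and raises an error. Flips are always evaluated in
  pairs with their rotation, which enforces the reflection antisymmetry
  exactly — in particular any constant bias of $f$ cancels identically, so
  the construction is intended for (and warns outside of) the bias-free
  regime.

### Error protocol

With reference orientations $\theta_r$ and $M$ replicate networks trained on
independent datasets $D_k$, the systematic error is the aggregate bias
$\hat b = \sqrt{\tfrac1M \sum_k \hat b_k^2}$ with
$\hat b_k = \mathbb{E}_{\mathcal{I} \in D_k}[\theta_o - \theta_r]$, and the
total error is the ARMSE
$\tfrac1M \sum_k \sqrt{\mathbb{E}[(\theta_o - \theta_r)^2]}
= \tfrac1M \sum_k \sqrt{\hat b_k^2 + V_k}$. Residuals are taken with
`p1_signed_diff()` and so live in $(-\pi/2, \pi/2]$; the plain arithmetic
mean inside $\hat b_k$ is valid because residuals of a working estimator stay
far from the wrap point (a warning fires beyond $85^\circ$).
`learning_curve()` drives the full experiment (train $M$ networks per
training-set size on independent datasets, evaluate against both ground truth
and the noisy labels, fit $\log \mathrm{ARMSE} \sim \log N$), excluding the
smallest size from the power-law fit when its replicate spread exceeds its
mean and reporting a bootstrap CI for the exponent, since no authoritative
numeric value exists for it.

## Synthetic data

No public imagelet corpus with ground-truth orientation exists, so the
generator is first-class, tested code. A pedestrian is emulated as the
superposition of two ellipses on a flat floor: a body/shoulder ellipse whose
major axis lies along the shoulder line (hence perpendicular to $\theta$),
and a smaller head ellipse at lower depth (heads are closer to an overhead
sensor), offset along the walking direction to jitter the centroid. Defaults
(declared, as no single authoritative generation recipe exists): 64 px
imagelets at 0.02 m/px (the field of view is held at 1.28 m when the pixel
count changes); body semi-axes 0.20–0.28 m by 0.10–0.16 m (the $\ge 1.1$
axis ratio keeps orientation identifiable); head semi-axes 0.07–0.11 m,
offset up to 0.06 m; floor at 2600 mm, body 1000–1400 mm above it, head a
further 200–300 mm; Gaussian depth noise of 10 mm; 1% dropout pixels reset
to floor depth. Labels are $\theta_{gt} + \epsilon$ with
$\epsilon \sim \mathcal{N}(0, 20^\circ)$ by default, imitating
velocity-direction supervision. Ground-truth angles are i.i.d. uniform on
$\mathbf{P}^1(\mathbb{R})$.

What this emulates well: the elongated overhead silhouette, depth contrast,
sensor noise and holes, and the centered label-noise structure of
velocity-based training. What it does not: clothing, backpacks, swinging
arms, posture variety, occlusion, multi-person crops — precisely the
variability that makes real data harder. Passing tests on synthetic data
therefore validate the *estimation machinery* (encoding, training dynamics,
symmetrization, error protocol), not performance on any real sensor.

An independent classical baseline, `orientation_from_moments()` (principal
axis of the thresholded silhouette), is exact on noise-free ellipses up to
pixel discretization and exactly $O(2)$-equivariant; it serves as the oracle
against which the generator's conventions and the group-averaging machinery
are tested.

## Orientation dynamics

`velocity_direction()` turns trajectories (30 Hz positions) into unwrapped
$\theta_v(t)$ signals via central differences, flagging samples below a
0.1 m/s speed floor where direction is undefined. Continuous signals are
smoothed with a zero-phase first-order Butterworth low-pass (cutoff 2.0 Hz,
odd-reflection padding of 52 samples), applied forward and backward on the
*unwrapped* signal; DC gain is exactly 1. Note that zero-phase application
squares the magnitude response: a 0.8 Hz gait oscillation passes with gain
$1/(1 + (\tan(\pi 0.8/30)/\tan(\pi 2/30))^2) \approx 0.87$.

The velocity direction is modeled as a stochastically delayed copy of the
orientation,

$$\theta_v(t) = A\,\theta(t - d(t)), \qquad
\dot d = -\frac{d - \hat d}{\tau} + \xi_{\mathrm{eff}}\,\dot W,$$

with reference parameters $A = 1.85$, $\hat d = 0.08$ s, $\tau = 1.2$ s,
$\xi = 1.85$. Two conventions deserve note:

* **Drift sign.** The mean-reverting form above is implemented; the
  opposite sign (pushing $d$ away from $\hat d$) is divergent and
  incompatible with $\hat d$ being the average delay.
* **Amplitude convention.** $A$ multiplies the *mean-centered fluctuation*
  of $\theta$ (the mean heading is preserved). Applied to the absolute
  heading, $A = 1.85$ would force a 40° walker's velocity direction to 74°,
  contradicting the premise $\theta \approx \theta_v$.
* **Noise units.** The reference intensity $\xi = 1.85$ is dimensionless and
  its normalization is a convention. Read literally in
  $\mathrm{s\,Hz^{1/2}}$ the stationary
  delay sd would be $\xi\sqrt{\tau/2} \approx 1.4$ s — an order of magnitude
  wider than observed delay distributions, which span a few tenths of a
  second. The package therefore defaults to an intensity *relative to the
  mean delay*, $\xi_{\mathrm{eff}} = \xi\,\hat d$ (stationary sd
  $\approx 0.115$ s), which reproduces the observed delay-pdf scale and the
  property that the delay alters the spectrum only at high frequency; the
  literal reading remains available via
  `ou_params(xi_unit = "absolute")`. The mean $\hat d$ and the relaxation
  time $\tau$ — the quantities recomputed by the acceptance script — are
  unaffected by this choice.

Simulation is Euler–Maruyama at $dt = 1/30$ s (an error below $\tau$, a
warning above $\tau/10$; discretization biases at the default step are
$\sim 1.5\%$, far inside the acceptance tolerances), initialized from the
stationary law. Negative delays are allowed (the process has full support);
`synthesize_velocity_direction()` reads $\theta$ at $t - d(t)$ by linear
interpolation of the unwrapped signal and truncates (with a message) lookups
outside its span.

`estimate_delay()` measures delays by windowed normalized cross-correlation:
4 s windows, 1 s hop, lags up to ±0.5 s, parabolic sub-sample refinement of
the correlation peak, and a 0.5 peak-correlation gate — all five constants
are arguments, as no single authoritative algorithm exists. On constructed
integer-sample shifts the estimator is accurate to well under a millisecond.

`recover_amplitude()` estimates $A$ from pairs of signals after shifting by
the mean delay. Ordinary least squares is *attenuated* by the stochastic part
of the delay — the residual time-warp acts like noise in the regressor, the
classical errors-in-variables dilution — so the default is standardized
major-axis (geometric-mean) regression, $\hat A =
\mathrm{sign}(r)\,\mathrm{sd}(\theta_v)/\mathrm{sd}(\theta)$ pooled across
pairs, which is invariant to the jitter; OLS is available for comparison.

`compare_model_to_measurements()` assembles the three standard diagnostics on
a cohort of pairs: the pooled pdf of $\theta_v(t) - A\,\theta(t-\hat d)$ with
a Gaussian fit and an Anderson–Darling p-value; the delay pdf; and the
grand-average Welch PSD overlay, with the $\theta_v$ spectrum normalized by
$A^2$ so that the delay's spectral effect is isolated. One caveat is stated
openly: on *clean synthetic* signals the shifted difference is, by
construction, approximately $A\,\dot\theta\cdot(\hat d - d)$ — a Gaussian
scale mixture with positive excess kurtosis — so a formal normality test at
large $n$ rejects even though the pdf is visually Gaussian; Gaussianity of
this statistic in field data reflects the heterogeneity and measurement noise
of real signals, which the clean generator deliberately omits.

Synthetic orientation signals (`generate_orientation_signal()`) superpose a
sinusoidal sway at the stepping frequency (default 0.8 Hz, 8° amplitude,
random phase) and a slow band-limited Gaussian drift (default 10° rms in
0.1–0.3 Hz), reproducing the two spectral concentrations typical of walking
(near 0.2 Hz from path curvature, near 0.8–1 Hz from stepping).

## Problem sizes and numerical choices

The shipped studies are desk-scale by design: 32 px imagelets, an ~11 k
parameter network, training sets up to $N = 20{,}000$ with $M = 4$
replicates, a 5000-image held-out test set, $k = 8$ group averaging, OU runs
of 10 seeds × 1000 s, and 50 signal pairs of 60 s. At these sizes the
qualitative structure of the full-scale experiments (bias ≪ ARMSE, ARMSE
decreasing in both $N$ and $k$, noise-floor saturation) is already sharp.
Full-scale runs ($N \approx 5\times10^5$, $M = 32$, 64 px) are supported by
the same functions but are cluster-scale jobs, not package tests.

Other numerical decisions: canonical interval half-open at $-\pi/2$ with
$+\pi/2$ the stored wrap representative; bin $i$ covers
$[-\pi/2 + (i-1)\pi/B, -\pi/2 + i\pi/B)$ with centers at midpoints;
degenerate circular means raise (threshold $10^{-8}$) rather than guess;
cross-entropy log clamp $10^{-12}$; rotations use bilinear interpolation with
background fill about the imagelet center, and flips are exact pixel
mirrors; unwrapping precedes all filtering and correlation; imagelets are
normalized as (background − depth)/1000 before the network, making training
invariant to the sensor mounting height.

## Interchange formats

Angles are serialized in degrees (`theta_deg` columns), time in seconds,
positions in metres, depth in integer millimetres. Imagelet datasets are
written as 16-bit grayscale TIFF (lossless at 1 mm quantization) plus a
`manifest.csv`; trajectories and signals as CSV. Readers validate hard
(missing files, non-16-bit rasters, non-monotone time) and flag recoverable
issues (off-nominal sampling rates). A thin command-line wrapper over these
functions ships in `inst/cli/pedorient.R`.

## Known limitations

* Synthetic imagelets are geometric idealizations; error magnitudes on them
  are not forecasts for any real sensor.
* The group average assumes a bias-free base estimator (a warning fires when
  the recorded training bias exceeds 1°); no bias-correction variant is
  provided.
* The delay estimator needs coherent oscillatory content inside its window;
  near-constant signal stretches are gated out by the correlation threshold.
* Only $\mathbf{P}^1(\mathbb{R})$ statistics are provided; full-circle
  ($2\pi$-periodic) circular statistics are out of scope.
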