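---
title: "Simultaneous-multislice radial real-time MRI: model, pipeline and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simultaneous-multislice radial real-time MRI: model, pipeline and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Real-time MRI (rtMRI) films free, non-periodic motion - speech, swallowing,
tongue mobility - without gating. Short-TR radial FLASH acquisition yields one
k-space spoke per excitation; spokes are binned retrospectively into frames,
so the temporal resolution (spokes/frame x TR) can be chosen after the scan.
Because the TR is so short, only one slice can normally be imaged per scan.
Simultaneous multislice (SMS) excitation removes that limit: a multiband RF
pulse excites `NSli` slices at once and the slices are separated
computationally using the spatial encoding of a receive array.

`radsms` implements the full computational side of such an experiment at desk
scale, plus a digital dynamic phantom standing in for the scanner, so that
every stage - trajectory, acquisition, coil preparation, reconstruction,
evaluation - is exercisable and testable end to end.

## Acquisition model

**Trajectories.** Spoke `m` lies at angle `m * theta mod 360`. For the plain
golden-angle scheme `theta = 180 / GR` with `GR = (1 + sqrt(5))/2` (about
111.25 degrees); the SMS-adapted variant divides by the multiband factor,
`theta = 180 / (GR * NSli)`, which spreads the spokes of one CAIPIRINHA phase
cycle evenly over angle and improves the destructive interference between
slices. Each spoke is a full diameter: `points_per_spoke` samples uniformly
spanning `[-0.5, +0.5)` cycles/pixel (endpoint-exclusive, so an even sample
count hits k = 0 exactly).

**CAIPIRINHA phase cycling.** Excitation `n` applies phase
`mod(2*pi*i*n/NSli, 2*pi)` to slice `i` (slice 0 is the zero-phase
reference; any global per-slice phase is absorbed into the coil maps). Over
one period of `NSli` excitations the phase factors of distinct slices are
discretely orthogonal - the algebraic basis of slice separation, asserted
directly in the test suite.

**Signal model.** With coil sensitivities `S_ic` and slice images `x_i`, the
sample vector of excitation `n` at coil `c` is

```
y[c, n, .] = sum_i exp(1i * phase[n, i]) * F{ S_ic * x_i(t(n)) } + noise,
```

where `F` is the non-uniform Fourier transform evaluated along spoke `n` and
`t(n)` the frame active at time `n * TR`. The simulator runs exactly this
model in the generative direction with i.i.d. circular complex Gaussian
noise.

## NUFFT operators

No installed R package provides a NUFFT, so the package carries its own
Kaiser-Bessel gridding transform (C++/Armadillo): 2x oversampled FFT grid,
kernel width chosen from the requested tolerance (default `1e-6`, width 8),
Beatty's beta, and analytic deapodisation. Conventions: forward
`s(k) = sum_r x(r) exp(-2i*pi*k.r)` with pixel offsets centred on index
`N/2`; the adjoint is the exact conjugate transpose (no `1/N^2` on either
side), so `<Fx, y> = <x, F'y>` holds to rounding and all solver algebra is
exact. The brute-force DFT oracle lives in the test suite and pins both
directions to `1e-6` relative error on grids up to 32x32. Interpolation
indices and weights can be precomputed per trajectory (`nufft_plan()`), which
is what makes iterative reconstruction affordable: a transform then costs one
FFT plus a table-driven gather/scatter.

**Density compensation.** `radial_density_weights()` initialises with the
classic ramp (`w ~ |k_r|`, DC given half the first ring's weight, normalised
to sum to the sample count) and by default refines it with 10 Pipe-Menon
fixed-point iterations (`w <- w / |F F' w|`). The plain ramp leaves a
low-frequency halo of order 10% NRMSE in adjoint reconstructions because
area-based weights are not the inverse of the sampling frame operator; the
refinement reduces this to a few percent. `pipe_iterations = 0` recovers the
plain ramp, whose profile properties (proportionality to `|k_r|`,
spoke-count invariance) are asserted in the tests.

## Coil preparation

1. **PCA compression** to `n_virtual` channels from the SVD of the
   coil-by-sample matrix over the entire time series, without mean-centering
   (MR k-space is DC-dominated; centering would distort it). At
   `n_virtual = C` this is a lossless rotation. Default: all channels up to
   16, mirroring routine practice.
2. **Conjugate-phase demodulation**: multiplying spoke `n` by
   `exp(-1i*phase[n, i])` aligns slice `i` across excitations while the other
   slices keep cycling phases; aggregating all spokes then yields
   motion-averaged per-slice k-space.
3. **Density-compensated adjoint NUFFT** of all spokes gives per-coil,
   per-slice motion-averaged images.
4. **Calibration extraction**: FFT to Cartesian k-space, centred 24x24
   block (DC at block index 13).
5. **Gridding-transfer normalisation.** The Cartesian spectrum of a
   density-compensated adjoint is the object's spectrum multiplied by the
   sampling pattern's modulation transfer `W(k)` - exactly computable as the
   FFT of the weighted sampling PSF (`calibration_transfer()`). On the
   default fixture `W` varies by tens of percent across the calibration
   block and, left uncorrected, biases the sensitivity estimate by an order
   of magnitude in normalized error. The block is divided by `W` before
   ESPIRiT.
6. **ESPIRiT**: block-Hankel calibration matrix from sliding 6x6 windows,
   SVD, right-singular vectors retained at `sv_threshold = 0.01` of the
   leading singular value, image-domain pixelwise operator, leading
   eigenvector as the (single) sensitivity map, support cropped at
   eigenvalue `0.85`, per-pixel phase referenced to coil 1. The kernel size
   and thresholds are community-standard values and are config-exposed; the
   leading eigenvalue of the normalised operator never exceeds 1 (asserted
   numerically).

## Reconstruction

The estimate solves

```
argmin_x  0.5 * sum_i || phi_i F S_i x_i - y ||_2^2  +  lambda * || T x ||_1
```

frame-wise in the data term, with `T` the temporal forward difference (no
wrap; a single frame makes the penalty inert) - by ADMM with the splitting
`z = Tx`:

* x-update: inner conjugate gradient on the regularized normal equations,
  warm-started from the previous iterate;
* z-update: complex magnitude soft-thresholding at `lambda / rho`;
* scaled dual update, and residual balancing of `rho` (multiply/divide by
  `residual_balance_tau = 2` when the primal/dual residual ratio exceeds
  `residual_balance_mu = 10`).

**Normalisation.** The encoding operator is scaled to unit spectral norm
(power iteration on one frame's normal operator) and the data so that the
zero-filled adjoint has unit maximum magnitude. The solution is then O(1)
and `lambda` transfers across grid sizes, coil counts and noise levels; the
scaling is undone on output. The default `lambda = 0.04` is the method's standard
operating point, selected by the two-stage search; the coarse
(`1e-4 ... 1e-1`, logarithmic) and fine (`0.01 ... 0.1` step `0.01`) search
grids are available through `cmd_lambda_search()`.

**Stopping and diagnostics.** The outer loop stops when both relative primal
and dual residuals fall below `tolerance = 1e-5`, else after
`max_iterations` with a warning and the best iterate. The trace records
objective, residuals and `rho` per iteration. Note the objective evaluated
at ADMM iterates is not a strict Lyapunov function: with residual balancing
and inexact inner solves, late-stage oscillations of order `1e-4` relative
are normal and the test suite asserts near-monotonicity (at `1e-3`) plus an
overall decrease rather than strict descent.

**Baseline.** `cg_sense()` runs frame-independent conjugate gradient on the
data term only (the historical comparison method; 15 iterations by default).
On well-conditioned fixtures ADMM at `lambda = 0` and CG-SENSE agree to
`1e-3`, and CG-SENSE matches an explicit normal-equation solve to `1e-6`;
both checks are in the test suite. These fixtures use disc-bandlimited test
images because radial sampling only covers the k-space disc - corner
frequencies of a square grid are nearly invisible to it, and including them
would only probe the ill-conditioned null directions rather than solver
correctness.

**Post-processing.** A width-3 temporal median filter on the magnitude
(centre-frame phase retained, shrunken windows at the edges) suppresses
residual undersampling flicker. Whether the filter should act on magnitude
or complex data is an open choice; magnitude was chosen because displayed
videos are magnitude images.

## The digital phantom: what it does and does not emulate

`make_phantom()` produces, per slice: a static head ellipse carrying an
oriented sinusoidal texture (orientation rotating 60 degrees per slice), a
slice-specific set of static circular markers, a dark cavity strip, and one
bright moving "tongue" ellipse whose centroid translates sinusoidally
(protrusion/retraction analogue; amplitude 6 px, period 20 frames by
default). Three choices are deliberate and load-bearing for the tests:

* **Slices are mutually decorrelated** (masked inter-slice image correlation
  around 0.6) so that slice leakage is measurable: a reconstruction that
  mixes slices cannot correlate highly with its own ground truth while
  keeping a margin over the others. Physically adjacent slices of a real
  head are much more similar; the synthetic distinctness is a measurement
  device, not an anatomical claim.
* **The tongue's excursion (12 px) exceeds its width (about 8 px)**, so the
  per-pixel temporal median is tongue-free along the path and
  `track_moving_centroid()` recovers the centroid without bias (about 0.4 px
  on ground-truth videos).
* **The cavity strip** gives the mover high contrast against its background,
  as an actual tongue against the air-filled oral cavity.

Coil maps are periodic Gaussian lobes on a ring (radius `0.26 N`, width
`0.28 N`) with a small integer-cycle linear phase per coil: smooth under the
DFT's circular topology (out-of-band spectral energy below 1% per map,
band edge at 1/8 of the grid bandwidth) and strictly positive in
root-sum-of-squares. They are generic surrogates - the real 64-channel
head/neck array is not characterizable from published material.

Not modelled: relaxation/flip-angle contrast (images are steady-state
complex magnetization), off-resonance, intra-frame motion blur (all spokes
of a frame see one phantom state, matching the retrospective binning model),
coil noise covariance (noise is i.i.d. across channels), and the physical
phantom's mechanics. Passing tests therefore demonstrate the correctness of
the *computational* pipeline under a faithful sampling geometry, not
robustness to scanner non-idealities.

## Study conditions and problem sizes

The default configuration (`run_config()`) is the package's desk-scale study
condition: N = 64, 8 coils, NSli = 3, 40 frames of 25 spokes at TR 2.5 ms
(62.5 ms/frame), 128 points/spoke, 280 mm FOV, 5% relative complex noise,
`lambda = 0.04`. Scheme comparisons and sweeps run at N = 48 with 4 coils;
solver-oracle checks use 8x8 and 32x32 grids. Reported reconstructions use
12 outer x 6 inner ADMM iterations, where the recovery metrics (slice
correlation, leakage margin, centroid error) plateau on these fixtures; the
production defaults (50 x 10, tolerance 1e-5) are conservative. The
undersampling sweep uses a *static* phantom plus noise so that one
binning-independent ground truth exists - with a moving phantom the ground
truth itself changes with the binning (temporal blur) and the monotonicity
question would be ill-posed.

## Degenerate inputs and edge behaviour

Single-band data (`NSli = 1`) reduce every stage to plain radial imaging
(phases identically zero). A single frame makes the temporal penalty inert.
Trailing spokes that do not fill a frame are discarded so frame duration
stays uniform; fewer spokes than one frame is an explicit error at the
reconstruction entry point. Zero-valued calibration data and empty ROIs are
explicit errors; even median-filter widths are rejected.

## Container and tooling

Datasets round-trip through a versioned HDF5 container (groups `kspace/`,
`trajectory/`, `schedule/`, `truth/`, `maps/`, `recon/`, `metrics/`; complex
data as paired real/imag datasets; readers reject unknown major versions).
The `exec/radsms` script drives simulation, reconstruction, the lambda
search, parameter sweeps, metrics and PNG export from the shell with exit
codes 0/2/3 (success / configuration error / data error). Videos are
exported as per-frame PNG; animated output is left to external tools.

## Known limitations

* The adjoint-with-DCF reconstruction is a display/calibration device, not a
  quantitative inverse; even refined weights leave a few percent NRMSE.
* ESPIRiT support detection on synthetic data with near-noiseless
  calibration tends to saturate (leading eigenvalue close to 1 over much of
  the FOV); the support threshold matters mostly at realistic noise levels.
* The ROI intensity-variation comparison between sampling schemes is a soft,
  directional check on one synthetic operating point (15 spokes/frame); it
  is not a general image-quality ranking of the two trajectories.
* Five-band and higher acquisitions are accepted and simulated, but the
  default regularization weight was chosen at three bands.
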