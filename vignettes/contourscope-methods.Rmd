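---
title: "Models and methods behind contourscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind contourscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models it implements,
the parameters that matter, and the numerical and design choices made
where more than one defensible option existed. It is the place to look
before changing a default.

## 1. The imaging model

A mask-based lensless mesoscope records, for a planar fluorescent scene
$i(x, y)$ at depth $z$, a sensor frame

$$ b = \Phi i + g + \varepsilon, $$

where $\Phi$ is a linear operator built from point spread functions
(PSFs), $g$ is a slowly varying additive background (out-of-band
fluorescence, stray light, uncorrected hemodynamics) and $\varepsilon$ is
sensor noise. Two regimes of $\Phi$ are implemented:

* **Shift-invariant** (`forward_shift_invariant`): $b = p * i$, a single
  PSF convolved with the scene. Used for fast feedback and for digital
  refocusing.
* **Laterally varying** (`forward_shift_variant`): the field of view is
  covered by a grid of calibrated PSFs $p_k$ (physically, a 9 × 9 grid at
  1 mm spacing per depth, recalibrated every 20 µm of working distance),
  combined as
  $$ \Phi i = \sum_k (w_k \odot i) * p_k, $$
  with bilinear interpolation windows $w_k$. The windows form a partition
  of unity over the calibrated hull, so the model is exact at grid nodes
  and continuous in between. How the calibrated PSF grid should enter the
  forward model is genuinely open; windowed interpolation is the standard
  low-rank choice for slowly varying aberrations, and its adjoint is exact
  (both are verified against a dense matrix built by pushing unit impulses
  through the definition). Scenes extending outside the calibrated hull
  are refused rather than extrapolated.

All convolutions are zero-padded linear convolutions on a shared padded
grid (scene size + PSF size, rounded up to a 5-smooth FFT length), cropped
so that a delta scene returns the PSF centred at the delta. The forward
operator, its adjoint and the Wiener inverse share one padding plan; this
bit-compatibility is what makes the closed-form inversion exact on
interior-supported scenes.

**Assumptions.** Scalar diffraction; incoherent emission (intensities
add); a planar scene at a single depth per reconstruction; PSFs constant
within one interpolation cell; noise independent across pixels.

## 2. Mask design

The PSF pattern is a set of thin closed contours: Canny edges of a Perlin
noise field, dilated to the design stroke width. Choices:

* *Perlin flavour*: classic gradient-lattice noise with quintic fade,
  rescaled to $[-1, 1]$. Feature scale (default 24 µm here; the
  fabrication-limited design value in the instrument class is 6 µm
  pattern width on a 1 µm grid) sets the contour density.
* *Canny*: Gaussian smoothing $\sigma = 1$ px, Sobel gradients,
  four-sector non-maximum suppression, hysteresis at fractions
  (0.1, 0.3) of the maximum gradient magnitude. The fractions are
  conventional defaults; nothing in the pipeline is sensitive to them at
  the tested scales. A constant field yields an empty pattern with a
  warning, not an error.
* *Dilation* uses a square structuring element so that a 1-px edge line
  becomes a stroke of exactly `round(pattern_width / pixel_pitch)` pixels,
  including even widths.

The phase profile realizing the pattern is retrieved by error-reduction
(Gerchberg–Saxton) iterations between the mask plane (unit amplitude,
free phase) and the sensor plane (amplitude clamped to the square root of
the target), with angular-spectrum propagation in between. Evanescent
components are zeroed; a warning fires when the transfer function's phase
is undersampled at the band edge. Phase converts to resist height via
$h = \phi \lambda / (2\pi \Delta n)$ with $\Delta n = 0.55$ (typical
two-photon resist against air; configurable, as the exact resist index is
process-dependent), then quantizes to 200 nm steps clipped at 1000 nm —
the fabrication process of the physical mask. At the default
$\lambda = 530$ nm (emission-band centre of a green GCaMP filter set) the
full $2\pi$ phase range maps to 964 nm, so quantization never moves a
height by more than half a step. Design fidelity is reported as the
normalized cross-correlation between the quantized mask's propagated
intensity and the target; below `fidelity_floor` the design is flagged,
never raised as an error.

## 3. Reconstruction

**Wiener/Tikhonov (closed form).** For the shift-invariant model the
regularized least-squares estimate is
$$ \hat i = F^{-1}\!\left( \frac{\overline{F(p)} \odot F(b)}{|F(p)|^2 + \gamma} \right), $$
computed on the shared padded grid. $\gamma = 0$ is allowed only when the
PSF has no spectral zeros on that grid. The solver is checked against an
explicit-DFT per-frequency oracle and against the Fourier-domain normal
equations at every frequency.

**Joint scene + background (FISTA).** The laterally varying model solves

$$ \min_{i \ge 0,\; g \in \mathcal{S}_5} \|(\Phi i + g) - b\|_2^2 + \tfrac{\gamma}{2}\|i\|_2^2, $$

where $\mathcal{S}_5$ is the span of the 5 × 5 lowest-frequency 2-D DCT-II
basis images. Numerical choices:

* Step size $1/L$, with $L$ the largest eigenvalue of the joint Hessian
  estimated by 30 power iterations from a deterministic start. The
  operator plan and $L$ can be reused across the frames of a video
  (`op` argument), which is how stacks are reconstructed.
* Projections every iteration: clip $i$ at zero; project $g$ onto
  $\mathcal{S}_5$. $g$ is deliberately **not** clipped at zero — after
  blank subtraction low-frequency backgrounds legitimately dip negative,
  and the subspace projection is the only constraint the closed-form
  optimality conditions need.
* Momentum restart whenever the objective increases: the momentum term is
  reset and a plain proximal-gradient step is taken from the last iterate,
  which cannot increase the objective at step $1/L$; the recorded
  objective trace is therefore non-increasing, and the suite asserts it.
* Stopping: relative objective change below `tol` or `max_iter`; reaching
  `max_iter` sets `converged = FALSE` rather than erroring. A non-finite
  objective raises an error naming the step size.
* The penalty is the squared norm $\tfrac{\gamma}{2}\|i\|_2^2$ throughout.
  (The fast closed form above uses the $+\gamma$ denominator; the two
  conventions meet at `gamma_fista = 2 * gamma_wiener`, which the suite
  verifies by running the unconstrained solver to the closed form.)
* Default $\gamma = 0.01 \max |F(p_\mathrm{centre})|^2$: a fixed fraction
  of the peak spectral power makes the default scale-invariant to PSF
  normalization. It is exposed in `recon_config`.

With data of the form $b = \Phi i^\ast + g^\ast$, the split between scene
and background is identifiable only to the extent that the nonnegativity
constraint pins it: smooth nonnegative content of $i^\ast$ can migrate
into $g$. For scenes with scattered zero regions the split is sharp (the
suite plants such scenes and recovers them); for everywhere-positive
scenes the DC ends up in $g$ and only the spatial structure above the DCT
block survives in $i$ — which is exactly what the downstream
orientation analysis consumes.

**Refocusing.** Candidate depths are reconstructed with the central PSF
of each calibrated plane (fast Wiener path) and scored by the variance of
the Laplacian inside the region of interest; the sharpest depth wins and
ties break to the smallest depth (documented rule, asserted in the
suite). PSF planes between calibrated depths are linearly interpolated.

## 4. The phantoms

The phantom module defines the study conditions; its defaults are fixed
and the tests run at them.

* **Orientation map**: complex white noise filtered by a Gaussian annulus
  centred at 1.2 cycles/mm (relative bandwidth 0.25); preference is half
  the argument of the filtered field. This reproduces semi-periodic
  columns and pinwheel singularities. Pixel pitch defaults to 20 µm at
  the object plane (a 256-px map spans 5.1 mm of cortex).
* **Stimulus protocol**: 6 orientations {0, 30, …, 150}°, flashes at 4 Hz
  (100 ms ON / 150 ms OFF) for 4 cycles, 20 Hz acquisition, 10 repeats
  per condition plus 10 blanks. The recorded pre-onset baseline defaults
  to 250 ms — the blank-subtraction residual window needs 200 ms, and one
  extra frame of margin keeps the trial short. Trial lengths make 4 Hz an
  exact DFT bin at 20 Hz.
* **Responses**: cosine tuning with full modulation depth (single-pixel
  tuning curves are not constrained by mesoscale data; full depth is the
  simplest choice and the analysis is linear in it), amplitude 0.03 ΔF/F
  on a baseline of 100 counts, temporally shaped by the flash train
  convolved with a GCaMP6f-like double-exponential kernel
  ($\tau_\mathrm{rise} = 50$ ms, $\tau_\mathrm{decay} = 400$ ms, from the
  indicator literature; configurable). Note the 400 ms decay means the
  4 Hz component rides on a larger slow envelope — exactly why the
  analysis extracts the first harmonic rather than a mean response.
* **Nuisances**: a global multiplicative heartbeat sinusoid (2–3 Hz,
  random phase per trial; `heartbeat_locked` emulates heartbeat-triggered
  acquisition by phase-locking trial starts), vasculature as dark
  ridges with no tuned response, Poisson shot noise at `photon_scale`
  expected photons per count and Gaussian read noise, clipped and
  quantized to 8 bits.

What the phantom does **not** model: slow hemodynamic responses beyond
the heartbeat band, photobleaching, tissue scattering, eye-position
jitter, non-cosine tuning, and response-amplitude heterogeneity beyond
the vessel mask. Passing tests therefore demonstrate that the
*computational chain* is correct and calibrated, not that the instrument
would achieve any particular in-vivo signal quality.

* **USAF target**: three-bar elements with the chart line width
  $500 / 2^{g + (e-1)/6}$ µm and 5:1 bar geometry, laid out as a plain
  grid of elements (the spiral chart layout carries no information for
  resolution phantoms). Elements narrower than 2 px at the requested
  pitch are omitted with a warning.

## 5. The analyses

The preprocessing follows widefield calcium practice: the average blank
time course is subtracted per pixel and frame, then each trial is
re-referenced by its mean residual over the 200 ms before onset. ΔF/F
uses a per-pixel baseline window; nonpositive baselines are masked to
`NaN` and counted. Rigid registration estimates per-frame translation
from the cross-correlation peak with local upsampled-DFT refinement and
shifts frames back by Fourier phase; displacements are reported in µm.

Position tuning averages each 0.3 × 0.3 mm ROI (six of them, ~0.37 mm
apart along the field-of-view midline) over the stimulus window — onset
to onset + 1 s, i.e. the four flash cycles; the averaging window is a
package choice, as is inevitable when only the cycle count is specified —
and fits a 1-D Gaussian (amplitude, centre, width, offset) by
Levenberg–Marquardt (`minpack.lm`). Degenerate (flat) profiles and failed
fits are flagged with raw responses preserved, and the canonical stimulus
grid is −0.8° to −1.3° in 0.1° steps.

Orientation mapping computes per-pixel 4 Hz first-harmonic amplitudes
(scaled so a pure sinusoid of amplitude $A$ returns $A$), selects the ROI
where the across-condition RMS exceeds one third of its maximum, and
bandpasses the maps to 0.8–2.5 cycles/mm. The band edges are tapered by a
raised cosine of width 0.1 cycles/mm by default (`hard = TRUE` gives the
hard annulus): the taper suppresses spatial ringing at negligible cost to
the passband, and both variants are exposed because the hard mask is the
more literal reading of "removing components outside the band".

The d′ decoder weights single-trial response maps by the pixel-wise d′
map and sums over the ROI; discriminability of the resulting decision
variables is again a d′. Cross-validation is leave-one-trial-out — the
lowest-variance unbiased scheme at 10 trials per condition — with the
held-out trial excluded from its own condition's weight estimate. The
decoder's calibration is pinned by two identities verified in the suite:
on a single pixel it reduces to the per-pixel d′, and on independent
unit-variance pixels with population weights it attains the
matched-filter SNR $\sqrt{\sum_i d_i'^2}$. The per-condition SD maps are
computed across trials *after* bandpassing each trial map (bandpass and
averaging commute; computing SDs after filtering keeps the d′ map in the
same spatial band as the mean maps).

Composite maps use vector summation $z = \sum_k R_k e^{i 2\theta_k}$;
preference is $\arg(z)/2$ and strength $|z| / \sum_k |R_k|$ — one of
several normalizations in use; this one is bounded in $[0, 1]$ and
dimensionless. Isotropic pixels (vanishing $z$) get strength 0 and
preference masked to 0. Map comparison encodes each map as
$\sin 2\theta$ and correlates over the ROI.

**The shuffle null.** Orientation labels are randomly permuted, the
composite rebuilt, and compared to the reference; 1500 relabelings by
default. One subtlety is documented in `shuffle_null`: the
$\sin 2\theta$ encoding is *exactly* invariant under two relabelings —
the identity and the reflection $\theta \mapsto 90° - \theta$ (for
real-valued maps the composite field maps to $-\bar z$). A null that
includes them contains the observed value by construction, so the sampler
excludes encoding-equivalent relabelings; forced permutations (e.g. the
identity diagnostic) bypass the exclusion. The sampled null is checked
against exhaustive enumeration of all 720 label permutations.

## 6. End-to-end closure and problem sizes

The acceptance suite closes the loop at a scaled-down version of the
in-vivo protocol, chosen so the whole chain runs comfortably on one CPU:
a 256 × 256 phantom (20 µm pixels, columns at 1.2 cycles/mm, tuning
amplitude 0.03 ΔF/F), the full 6 × 10-trial + 10-blank protocol at 20 Hz
with heartbeat and shot noise (`photon_scale` 1000), a 3 × 3 grid of
32 × 32 PSFs simulated from a designed contour mask, FISTA
reconstruction, and the complete orientation-mapping analysis with the
1500-relabeling shuffle control. Two scalings keep this honest and fast:

* Measurements are averaged per condition across trials **before**
  reconstruction. The forward model is linear, so the condition-average
  measurement equals the measurement of the condition-average scene; the
  average of $n$ per-trial Poisson acquisitions is emulated exactly by a
  single draw at `photon_scale * n` (Poisson additivity) with read noise
  $\sigma/\sqrt{n}$. The composite-map analysis consumes only
  trial-averaged responses, so nothing the end-to-end check measures
  is lost; the per-trial path (d′ maps, decoder) is exercised separately
  at its own scale. Reconstructing the nonlinear estimator per trial and
  then averaging would differ at second order in the noise — a
  deliberate, documented trade.
* Each frame's FISTA run is warm-started from the previous frame and
  reuses the operator plan and step size, capped at 12 iterations — the
  regime where the harmonic analysis, which is differential, is already
  stable.

Unit-test problem sizes (8–64 px images, 2 × 2 and 3 × 3 grids, a few
thousand FISTA iterations on 12–16 px problems) were likewise chosen so
the whole suite runs in a few minutes while every oracle remains
computable by brute force.

## 7. Known limitations

* The angular-spectrum propagator warns, rather than adaptively pads,
  when the kernel is undersampled; very long propagations on small grids
  wrap around.
* The shift-variant model has no depth blending within a single
  reconstruction: one depth per frame (per-frame refocusing covers the
  calibrated range).
* `g` unconstrained in sign means pathological data can push background
  below zero where a physical background could not; this is the price of
  the closed-form projection.
* The decoder assumes two conditions (0° vs 90°); multi-class decoding is
  out of scope.
* Registration is rigid translation only, matching the instrument's
  observed sub-30 µm motion; rotation/shear are not modelled.
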