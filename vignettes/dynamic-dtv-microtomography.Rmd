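---
title: "Dynamic phase-contrast microtomography with a structure-based prior: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic phase-contrast microtomography with a structure-based prior: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtvtomo)
```

# The problem

A process such as capillary water uptake in wood evolves on a timescale of
tens of seconds.  On a laboratory micro-CT system a single well-sampled scan
takes tens of minutes, so a dynamic frame must make do with a fraction of
the photons and projection angles.  `dtvtomo` implements the combination
that makes the resulting reconstructions usable: free-space-propagation
phase contrast (more contrast per photon), single-distance phase retrieval
(trades fringes for a large noise reduction), and iterative reconstruction
regularised by a structure-based prior from a high-quality reference scan of
the same, structurally unchanged sample.

Because no public dataset of this kind exists, the package is organised
around a synthetic study: every quantitative claim the test suite makes is
evaluated on data generated by the package's own forward model under
conditions declared in this vignette.

# Imaging model

## Geometry and blur

`system_geometry()` holds the source-to-object distance `R1` (mm), the
propagation distance `R2` (mm), Gaussian width parameters `sigma_s` of the
source spot and `sigma_d` of the detector PSF (µm), the detector pitch
(µm), the effective wavelength (m) and the `delta/beta` ratio used by the
retrieval.  All lengths are converted to micrometres at construction.  The
total system PSF referred to the object plane is

$$\sigma(M) = \sqrt{(1 - 1/M)^2\,\sigma_s^2 + \sigma_d^2/M^2},
\qquad M = \frac{R_1 + R_2}{R_1}.$$

Two different optima live in this expression and are easily conflated:

* the *blur* minimiser of $\sigma(M)$ itself, which is
  $M = 1 + (\sigma_d/\sigma_s)^2$;
* the *fringe-contrast* optimum at fixed system length $L = R_1 + R_2$.
  The phase term of the near-field intensity scales with the effective
  propagation distance $R_2/M = L(M-1)/M^2$ while blur suppresses the
  fringes over a scale $\sigma(M)$, so the figure of merit is
  $(R_2/M)/\sigma^2 = L\,(M-1)/\big((M-1)^2\sigma_s^2 + \sigma_d^2\big)$,
  maximised exactly at $M_\mathrm{opt} = 1 + \sigma_d/\sigma_s$.

`optimal_magnification()` returns the second quantity — the one that
matters for propagation-based imaging — and the test suite verifies both
the closed form against a dense grid and, at the simulator level, that edge
fringe contrast grows monotonically with `R2` up to that optimum.  The
defaults (`R1 = 320`, `R2 = 140`, 70/30 µm widths, 15 µm pixels) put the
instrument at `M = 1.44`, close to `M_opt = 1.43`, with a system PSF width
of 29.8 µm and a 10.4 µm effective pixel.

Widths are treated as the Gaussian width parameters appearing in the
formula above; conversion to a full width at half maximum
(`2.3548 sigma`) happens only in the resolution analysis, where measured
edge-response widths are reported as Gaussian-equivalent FWHMs.

## Forward simulation

`contact_image()` produces Beer–Lambert transmission
`exp(-∫µ dz)` with `µ = 4πβ/λ` and the projected phase
`φ = -(2π/λ)∫δ dz` by discrete line integrals.  `tie_intensity()` applies
the near-field transport-of-intensity model
`I = (contact/M²)(1 − (R2 λ/2πM) ∇⊥²φ)` with a 5-point Laplacian stencil
(reflective boundaries) on the effective-pixel grid; intensities driven
negative by strong edges are clipped at zero with a warning.
`apply_system_blur()` convolves with the system PSF (separable sampled
Gaussian, reflective boundaries, kernel truncated at 5σ, total flux
renormalised to be conserved exactly).  `simulate_scan()` runs this chain
per projection — evaluating a time-dependent phantom at each exposure
midpoint for continuous-rotation scans — and applies Poisson counting noise
with dark and averaged flat frames; `photons_per_pixel = Inf` gives the
noiseless limit with a unit flat field.  A `supersample = 2` flag simulates
on a twice-finer grid and rebins the detector, decoupling the simulation
grid from the reconstruction grid.

The model is monochromatic at the effective wavelength (19 keV by default);
polychromatic weighting is out of scope, consistent with retrieval at a
single effective wavelength.  Motion within one exposure is represented by
the midpoint state only.

## Phase retrieval

`retrieve_phase()` implements the homogeneous-object single-distance
inversion: Fourier filter `1/((λ R2/4πM)(δ/β) k² + 1)` followed by
`φ = -(δ/β)/2 · log|·|`.  Conventions fixed here, chosen so the `R2 = 0`
and weak-object limits are exactly self-consistent with the forward model
(verified by round-trip tests):

* `(u, v)` are angular spatial frequencies, `k = 2π · fftfreq/pixel`;
* `M` divides `R2` (effective propagation distance `R2/M`) and the grid
  uses the effective pixel size at the sample plane;
* images are mirror-padded to twice their size before the FFT;
* the filtered ratio is floored at `1e-6` before the log, with a count of
  clamped pixels reported.

The retrieved phase is reported as the positive projected-phase magnitude,
so `retrieve_projections()` converts it to refractive path length
`∫δ dz = φλ/2π`, the `b` of the reconstruction problem.  For `R2 = 0` the
filter is the identity and the inversion reduces to exact Beer–Lambert.
`delta_beta` is deliberately a plain configuration scalar: for a
polychromatic source and a multi-material sample the "correct" value is
empirical, and `delta_beta_sweep()` supports the usual workflow of
rendering a sweep of candidate retrievals for visual/CNR inspection; no
automatic selection rule is invented.  Note that large `delta/beta`
strengthens the low-pass: with the default 1000 the retrieval kernel itself
contributes visibly to the point-spread of the reconstruction, which is
physically faithful but worth remembering when interpreting resolution
measurements (the resolution tests use a moderately absorbing material with
`delta/beta = 150`, where the kernel is thin).

## Tomography

`build_projector()` assembles the Joseph-type (ray-driven, linearly
interpolated) parallel-beam discrete Radon transform as a sparse matrix;
its transpose is the exact numerical adjoint (`back_project()`), which is
the load-bearing property for the convergence of the primal-dual solver and
is verified by inner-product tests on every geometry the suite constructs.
Angles are degrees externally and radians internally; rotation is
counter-clockwise about the grid centre; z is the rotation axis and the
height axis of the waterfront analysis.  Multi-slice (pseudo-3D) data are
projected and reconstructed slice by slice with one shared operator.

`fbp_reconstruct()` uses the band-limited ramp kernel constructed in the
spatial domain (so the DC response is exact), with Hann apodisation by
default (`ram-lak` available), zero-padded FFT filtering, and pixel-driven
linearly interpolated backprojection; angular coverage beyond 180° is
weighted down for redundancy.  The cone-beam geometry of a real instrument
is out of scope: the method itself is geometry-agnostic, and all study
conditions here are 2D parallel-beam slices or stacks of slices.

## dTV-regularised reconstruction

`pdhg_reconstruct()` solves

$$u = \arg\min_{u \ge 0} \tfrac12\|Au - b\|^2 + \alpha\,\mathrm{dTV}(u, v),
\qquad \mathrm{dTV}(u, v) = \sum \big\|(I - \xi\xi^\top)\nabla u\big\|_2,$$

with $\xi = \nabla v / \sqrt{\|\nabla v\|^2 + \eta^2}$.  The weight
$D_v = I - \xi\xi^\top$ is the standard orthogonal-projection form of the
directional-TV prior.  Implementation decisions:

* one shared forward-difference gradient with Neumann boundaries is used by
  `normalized_gradient()`, `dtv_functional()` and the solver's operator, in
  index units (per voxel);
* for a stack of slices the gradient acts in 3D across slices while the
  data term stays slice-wise, so the prior couples heights even though the
  projector does not;
* PDHG with θ = 1, duals initialised at zero, step sizes
  `sigma = tau = 0.99/L` with `L` from a seeded power method on the stacked
  operator, and the primal proximal step a projection onto the non-negative
  orthant;
* the two operator blocks are balanced internally: the gradient block is
  scaled by `gamma = ||A||/||grad||` (and its dual ball radius by
  `1/gamma`), a pure reparameterisation that leaves the minimised
  functional unchanged but lets both duals activate within the few
  iterations of a warm-started solve.  Without it the TV dual of a
  physically scaled operator needs thousands of iterations to saturate;
* the sinogram is normalised to unit maximum during the solve (restored on
  output), making `alpha` a scale-free relative weight.  The default
  `alpha = 1` was fixed once by inspecting CNR across a sweep on the
  synthetic calibration slice — mirroring the visual-inspection practice
  this parameter receives in real workflows — and the 10-iteration
  warm-started result is insensitive to `alpha` over more than an order of
  magnitude (the dual-growth cap, not `alpha`, limits the effective
  regularisation at this iteration count);
* `eta` defaults to 5% of the 99th percentile of `|∇v|`: reference
  boundaries saturate towards unit `ξ` while the reference noise floor
  falls back to isotropic TV;
* default 10 iterations from an FBP warm start; zero iterations return the
  clipped FBP volume; a divergence guard aborts if the objective grows
  five-fold over ten iterations.

The per-iteration objective (on the solver's normalised data scale) is
attached as a `convergence` attribute and plotted by `plot_convergence()`.

# The synthetic study

## Phantom and filling dynamics

`build_phantom()` places non-overlapping axial cylindrical vessels
(radii 25–60 µm by default, rejection-sampled) inside a wood cylinder
occupying 85% of the grid; optional joined vessel pairs share a thin
membrane below a separation height.  Default optics at the effective
wavelength: air (δ = 0), wood matrix (δ = 4.0×10⁻⁷), water
(δ = 5.1×10⁻⁷), each with `beta = delta/1000`.  These reproduce the
qualitative class ordering air < wood < water seen in regularised
reconstructions of real birch; they are configuration values, not claims
about any particular instrument.  An optional multiplicative log-normal
texture with a correlation length of ~2.5 voxels (constant along z, like
axial fibres) models the heterogeneous wood matrix; it matters wherever the
*static* structure must dominate a comparison, most of all in alignment.

Capillarity is modelled by a Lucas–Washburn-type front law
`h_i(t) = k_i √(t − t0_i)` with `k_i ∝ 1/radius_i` (narrower capillaries
rise faster); the default coefficient `k_coef = 2400 µm²·s^(-1/2)` gives
fronts that traverse a few hundred micrometres per minute, the scale of the
intended experiments.  Optional jump events `(time, height_jump, new_rate)`
emulate a joined pair separating: the front jumps and continues at the
faster single-vessel rate.  Filling is monotone by construction, and the
dry and filled states share every material boundary up to the air↔water
relabelling — precisely the situation in which the normalised gradient
directions of the two states stay perfectly correlated
(`figure1_pair()` + `gradient_direction_correlation()` demonstrate this:
the raw images decorrelate, the direction fields do not, provided every
boundary keeps its contrast sign).

## What the generator does not emulate

Real wood has thousands of cells, tortuous vessels, sub-resolution porosity
and a polychromatic spectrum; the phantom has a handful of straight
vessels, three materials and one wavelength.  Passing tests therefore
demonstrate the correctness and qualitative behaviour of the methods under
controlled conditions — not quantitative agreement with any real
instrument's numbers, which would require the (unavailable) raw data.  Two
consequences are worth naming: the synthetic sample carries far less
alignment-anchoring structure than real wood, so the alignment scenarios
use a higher photon budget (5000 counts/pixel/frame) than the dynamic CNR
scenario (1000); and absolute CNR values on the phantom differ from the
packaged reference table, while their ordering (conventional < analytical
phase-retrieved < regularised phase-retrieved) is reproduced end to end.

## Alignment

Flyscan data are aligned to the reference by grid search:
`estimate_angular_offset()` reconstructs FBP candidates with shifted angles
and minimises the l² distance between mean-subtracted, norm-scaled volumes
(hence invariance to grey-value drift); ties break towards the smallest
absolute offset, and a near-flat neighbourhood of the minimum is flagged as
a sub-grid offset.  `estimate_angular_step()` runs the same search over
per-projection angular increments (detector dead time dilates the true
step), with an optional second pass over offsets.
`split_on_discontinuity()` estimates offsets per segment so a mid-scan
detector frame skip — which silently shifts all later projection angles —
is absorbed; segments should be whole CT frames, since half-frames are
limited-angle reconstructions whose estimates bias.  The simulator injects
all three effects (`offset_deg`, `dead_time`, `frame_skip`) while recording
only nominal angles, so recovery is tested against known truth.  Volumes
are compared over the full grid; an optional mask restricts the comparison.

## Waterfront tracking

`segment_vessels()` labels near-axial air tubes in the reference volume
(Otsu-initialised threshold inside the sample interior, 2D labelling of
columns that are air over most of their height).  `classify_water()` marks
vessel voxels whose grey value exceeds the dry reference by a threshold —
canonically `halfway_threshold()` between the class means.
`thickness_ratio()` collapses masks along one in-plane ("coronal") axis,
declared per run; a per-vessel profile `R(z)` is the ratio of water to
vessel voxel counts per height.  `front_height()` scans upward from the
vessel base (the lowest segmented height) and returns the first height at
which `R` stays below 0.1 for 20 consecutive voxels (210 µm at the default
voxel size), treating the profile as zero above the vessel top; the
persistence rule makes the front robust to single-voxel air inclusions and
stray droplets, and the first qualifying height wins.
`front_uncertainty()` evaluates the rule at thresholds 0.05 and 0.15;
because the detected height is monotone non-increasing in the threshold,
the pair brackets the nominal height.  `track_vessels()` assembles
per-vessel trajectories, a cohort median ± sd summary, and a per-vessel
monotonicity flag; `fit_front_exponent()` recovers the `√t` exponent and
`detect_front_jump()` locates separation events.

The tracking tests run in the volume domain: dynamic volumes are the
phantom's δ-maps plus Gaussian noise at one sixth of the air–water class
gap (the regime of a well-regularised reconstruction, where the 3σ tail
bound keeps voxel misclassification below 0.2%).  This isolates the
tracking rules from reconstruction error; the reconstruction chain itself
is exercised by the CNR and resolution scenarios.

# Study conditions and problem sizes

The suite fixes these scenario sizes as its study conditions:

* **Dynamic slice (CNR ordering, alignment, solver behaviour):** 128²
  slice, 6 vessels (half water-filled), wood texture 0.25; reference scan
  360 × 1 s at 20 000 counts/pixel; dynamic frames 180 × 50 ms at 20°/s
  with 1000 counts/pixel (5000 for alignment scenarios).
* **Resolution stack:** 96 × 96 × 32 voxels, one 90–95 µm vessel,
  `delta/beta = 150`, front crossing mid-height at one voxel per second
  during the 9 s frame; wall edges measured above the front, the moving
  waterfront along z.  Prior-aligned walls must stay within 1.2× of the
  2.3548σ system FWHM and within one voxel of the prior's fitted edge
  centre; the waterfront must be strictly blurrier (motion plus the
  regulariser's isotropic penalty where the prior is flat).
* **Tracking volume:** 72 × 72 × 96 voxels, 6 vessels, 15 time points at
  9 s spacing, one programmed separation jump (+180 µm at t = 60 s with a
  1.8× rate increase).

# Known limitations

* 2D parallel-beam (slice-stacked) geometry only; no cone-beam weighting,
  helical trajectories or GPU projectors.
* Monochromatic forward model; retrieved δ values are non-quantitative by
  construction whenever the homogeneity assumption is violated.
* No intra-exposure motion integration (midpoint evaluation only), so very
  fast fronts alias rather than blur within a single projection.
* Vessels are straight and axis-aligned; tortuosity, embolism and
  physiological xylem behaviour are out of scope.
* The dTV prior assumes the reference and dynamic states share boundaries;
  where they do not (the moving front), resolution is deliberately
  sacrificed for CNR — the regulariser penalises any structure the
  reference does not license.
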