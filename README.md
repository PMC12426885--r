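# dtvtomo

Dynamic x-ray phase-contrast microtomography with a structure-based prior,
as an R package.

Laboratory micro-CT sources are orders of magnitude less brilliant than
synchrotrons, so imaging a process that evolves over tens of seconds — water
rising through the vessels of a piece of wood, fluid invading a pore
network — leaves each CT frame starved of photons and angles.  `dtvtomo`
implements the two ideas that make such experiments work on a bench source,
together with a full synthetic testbed:

1. **Free-space-propagation phase contrast.**  With a propagation distance
   `R2` between sample and detector, the recorded near-field intensity
   follows the transport-of-intensity equation (TIE)

   `I = (I_contact / M²) · (1 − (R2 λ / 2πM) ∇⊥² φ)`,

   where `M = (R1+R2)/R1` and `φ` is the projected phase.  Edge fringes add
   contrast at no cost in flux.  A single-distance Paganin-type Fourier
   filter, `1 / ((λ R2 / 4πM)(δ/β) k² + 1)`, inverts the TIE for a
   homogeneous object and yields high-contrast `δ`-weighted projections.

2. **Directional total-variation (dTV) regularised reconstruction.**  A
   long, well-sampled reference scan of the static sample gives a volume
   `v`.  Each undersampled dynamic frame `u(t)` is reconstructed by solving

   `u(t) = argmin_{u ≥ 0}  ½‖A u − b‖² + α · dTV(u, v)`,
   `dTV(u, v) = Σ ‖(I − ξξᵀ) ∇u‖₂`,  `ξ = ∇v / √(‖∇v‖² + η²)`,

   with the primal-dual hybrid gradient (PDHG) method.  The weight
   `D_v = I − ξξᵀ` cancels the penalty along the reference's gradient
   directions, so grey values may change freely across existing boundaries
   (air → water inside a vessel) while everything else stays smooth.  When
   structures keep their shape, the normalised gradient directions of the
   two states stay perfectly correlated even though the images decorrelate —
   that is the mutual information the prior exploits.

The package covers the full workflow: a wood-cylinder phantom whose vessels
fill with water on a capillary `√t` law, a TIE forward simulator with
source/detector blur and Poisson noise, phase retrieval, parallel-beam
projectors and FBP, the dTV-PDHG solver, angular alignment of flyscans
(start-angle offset, detector dead-time step dilation, mid-scan frame
skips), and the quantitative analyses: contrast-to-noise ratios,
edge-response resolution, and per-vessel waterfront tracking with a
persistence rule and threshold-sweep error bars.

## Worked example

```r
library(dtvtomo)

geom <- system_geometry(R1 = 320, R2 = 140, sigma_s = 70, sigma_d = 30,
                        pixel_pitch = 15, delta_beta = 1000)
geom
#> <system_geometry>
#>   R1 = 320.0 mm, R2 = 140.0 mm, M = 1.4375
#>   sigma_s = 70.0 um, sigma_d = 30.0 um, system PSF = 29.82 um
#>   pixel 15.00 um (effective 10.435 um), lambda = 6.526e-11 m, delta/beta = 1000
```

The propagation distance sits at the fringe-contrast optimum
`M_opt = 1 + σ_d/σ_s = 1.43`, and the system PSF width is essentially the
same as in contact (29.8 vs 30 µm): the fringes are free.

The canonical CNR arithmetic on the packaged class statistics (mean ± sd of
air and water voxels for each reconstruction variant):

```r
as.data.frame(birch_cnr_table())
#>   reconstruction     cnr cnr_rounded improvement
#> 1   conventional  0.4286        0.43         1.0
#> 2  analytical_pr  2.4957        2.50         5.8
#> 3 regularised_pr 12.5455       12.55        29.2
```

Phase retrieval buys a 5.8× CNR improvement over the attenuation-only
reconstruction and the dTV-regularised reconstruction 29.2×.

The same ordering emerges end-to-end on the synthetic sample — a textured
wood slice whose vessels half-filled with water, scanned as one 9 s dynamic
frame (180 × 50 ms at 20°/s) against a long dry reference scan:

```r
phantom <- build_phantom(6, c(128, 128), seed = 21, wood_texture = 0.25)
schedule <- fill_schedule(phantom$vessel_table)
schedule$t0 <- rep(c(0, 1e9), 3)            # half the vessels reached by water
wet <- fill_state(phantom, schedule, t = 1)

ref <- simulate_scan(phantom, reference_protocol(seed = 1), geom)
dyn <- simulate_scan(wet, dynamic_protocol(seed = 43), geom)

v      <- fbp_reconstruct(retrieve_projections(ref))     # structural prior
conv   <- fbp_reconstruct(attenuation_sinogram(dyn))
fbp_pr <- fbp_reconstruct(retrieve_projections(dyn))
dtv    <- pdhg_reconstruct(retrieve_projections(dyn), prior_field(v),
                           recon_config(n_iterations = 10))

masks <- phantom_masks(wet)
cnr_of <- function(vol) cnr(vol$values[masks$water], vol$values[masks$air])
sprintf("conventional %.2f | analytical PR %.2f | regularised PR %.2f",
        cnr_of(conv), cnr_of(fbp_pr), cnr_of(dtv))
#> "conventional 1.65 | analytical PR 4.86 | regularised PR 5.34"
```

Waterfront tracking operates on a timeline of reconstructed volumes:
`segment_vessels()` labels the air tubes in the reference,
`classify_water()` thresholds the voxelwise difference `u(t) − v` at the
halfway point between the class means, and `track_vessels()` collapses each
vessel to its water-to-thickness ratio profile `R(z)`, extracts the front
height with a 20-voxel persistence rule, and reports per-vessel trajectories
with error bars from a 0.05–0.15 threshold sweep (`autoplot()` renders the
cohort chart; `tidy()`/`glance()` give tabular access).

A thin command-line wrapper over the staged pipeline
(simulate → retrieve → align → reconstruct → analyse) is installed at
`inst/cli/dtvtomo`; runs are driven by a YAML configuration
(`default_run_config()`, `write_run_config()`) and emit a manifest of every
artefact with content hashes.

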