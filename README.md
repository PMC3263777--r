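# meshnpm

Forward modelling of **simultaneous EEG and fMRI BOLD** from a mean-field
neural population model (NPM) discretized on a triangulated cortical surface.

Non-invasive modalities see the same brain through very different filters:
EEG has millisecond resolution but centimetre-scale volume conduction, fMRI
BOLD localizes to millimetres but reflects slow haemodynamics. A principled
way to integrate them is a single generative model of neural activity whose
output is expressed through *both* measurement chains. `meshnpm` implements
that chain end to end for researchers building or fitting such models:

- **Mesh pruning** — curvature-preserving edge collapse (new vertex on a
  circle segment, `v = p0 + b (p3 - p0)`, `b = 1` exact for a sphere) with
  detection and removal of degenerate "tetrahedron" configurations.
- **Connectivity** — exponentially decaying background coupling
  `w ∝ area · exp(-Δ/λ)` (λ = 25 mm, cut-off λ ln 10 ≈ 57.6 mm, weights
  normalized to 1 per vertex) over surface geodesics, plus region-to-region
  *specific* connections of universal strength `W_s` (a fraction of the total
  background) with conduction delays from shortest through-volume routes
  (visibility graph + Floyd–Warshall), and homotopic mirror links.
- **Dynamics** — at every vertex, two coupled populations (excitatory,
  inhibitory): `τ_k dh_k/dt = (h_rest − h_k) + Σ_l ψ_lk(h_k) I_lk` with
  reversal-weighted alpha-kernel PSPs driven by
  `A_lk = N^α_lk S_l(h_l) + p_lk + φ_lk`, sigmoid rates
  `S(h) = S_max / (1 + exp(−√2 (h − μ)/σ))`, forward Euler at Δt = 50 µs.
  Long-range rates travel through per-vertex delay ring buffers; slow
  channels exchange only Catmull–Rom control points (up-sampling
  `u = round(0.40449 / (Δt f_cut))`), cutting traffic by exactly `u`.
  Extracortical input is band-limited spline noise with a −3 dB point at
  75 Hz.
- **EEG** — dipoles along surface normals with moments `∝ (h_e − rest) ×
  area`, through a three-compartment boundary-element volume conductor
  (0.2 / 0.03 / 0.2 S/m), verified against the analytic concentric-sphere
  series solution.
- **fMRI BOLD** — per-vertex balloon–windkessel haemodynamics driven by the
  excitatory-only input `f_e A_ee + (1 − f_e) A_ei` (`f_e = 0.85`), projected
  from vertices to voxels with an anisotropic Gaussian
  (σ_N = 2.0 mm, σ_T = 1.66 mm; FWHM ≈ 3.9 mm) and back.
- **Protocol** — a specific-connectivity strength sweep with Welch spectra of
  the vertex-averaged excitatory potential ("ECoG") and EEG/ECoG/BOLD
  snapshot export.

All inputs — hemisphere meshes, parcellations, graded connectivity matrices,
head shells, electrode caps, voxel grids — can be generated synthetically
(`make_hemispheres()`, `make_parcellation()`, `make_region_matrix()`,
`make_head_shells()`, `make_electrodes()`, `make_voxel_grid()`), so the whole
chain runs without any external data. Real surfaces are read from OFF files
with delimited-text sidecars for labels, matrices and electrodes.

See `vignettes/forward-modelling.Rmd` for the model details, parameter
conventions and numerical choices.

## Worked example

```r
library(meshnpm)

hemis  <- make_hemispheres(subdivisions = 2)      # two mirror icosphere "hemispheres"
cortex <- merge_hemispheres(hemis)
cortex$labels <- make_parcellation(cortex, n_regions = 3, seed = 1)
cortex
#> triangle_mesh: 324 vertices, 640 triangles, 960 edges
#>   Euler characteristic: 4; surface area: 1.933e+04 mm^2
#>   region labels: 3 regions

regions    <- make_region_matrix(3)               # moderate-grade triangle motif
routes     <- route_distances(cortex, hemispheres_volume(), step = 1)
connectome <- build_connectome(cortex, background_kernel(), cortex$labels,
                               regions, W_s = 0.6, routes = routes)
connectome
#> connectome: 324 vertices, 100836 connections
#>   (background: 34920, homotopic: 324, specific: 65592)

params <- npm_parameters()
sim <- run_simulation(connectome, params, duration = 2, seed = 42,
                      record_every = 200L, mean_every = 4L)
sim
#> npm_simulation: 324 vertices, 2 s at dt = 5e-05 s (seed 42)
#>   mean h_e over run: -79.081 mV (sd 0.0165)
```

The mean excitatory potential sits at the resting fixed point (≈ −79 mV for
the default parameters) with noise-driven fluctuations. Its Welch spectrum
peaks in the theta/alpha range — the damped resonance of the default
operating point:

```r
psd <- psd_welch(sim$mean_he[sim$time_mean >= 1],
                 sample_rate = 1 / (params$dt * 4), segment_s = 0.5)
#> ECoG spectral peak: 6.0 Hz
```

The same run expresses both imaging modalities:

```r
fp   <- npm_fixed_point(params, long_range_gain = 1)
bold <- simulate_bold(sim$A_ee, sim$A_ei, sim$time_fields, balloon_parameters(),
                      baseline = 0.85 * fp$A["ee"] + 0.15 * fp$A["ei"])
#> BOLD at t = 2 s: range [7.8e-03, 1.0e-02]        # positive activation everywhere

head_mod <- make_head_shells(subdivisions = 2)
transfer <- bem_transfer_matrix(head_mod, cortex$vertices, vertex_normals(cortex),
                                as.matrix(make_electrodes(16)[, c("x", "y", "z")]))
eeg <- electrode_timeseries(transfer, dipole_sources(sim$h_e, cortex, fp$h_e))
#> EEG: 16 electrodes x 200 samples (average-referenced)
```

BOLD values are dimensionless contrast (zero at rest); EEG amplitudes are in
arbitrary units because the dipole proportionality constant is not calibrated
to scalp volts. The full strength sweep — `run_sweep()` over
`W_s = 0, 0.30, …, 1.0` with identical noise per point — returns per-point
spectra in dB relative to the sweep maximum together with the accounting
check that the realized specific-to-background input ratio equals `W_s`
times the number of afferent regions.

A thin command-line front end for mesh pruning and fixture generation is in
`inst/cli/meshnpm`:

```sh
Rscript inst/cli/meshnpm prune --in mesh.off --min-edge 2.5 --b 1.0 --l 0.0 --out pruned.off
Rscript inst/cli/meshnpm fixtures --out fixtures_dir
```

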