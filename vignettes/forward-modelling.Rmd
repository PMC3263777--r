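---
title: "Forward modelling of simultaneous EEG and fMRI BOLD from a mesh-based neural population model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forward modelling of simultaneous EEG and fMRI BOLD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meshnpm)
```

# The model chain

`meshnpm` implements a complete forward chain from neural activity to detector
signal. A mean-field neural population model (NPM) with one excitatory (e) and
one inhibitory (i) population is solved at every vertex of a triangulated
cortical surface; activity propagates between vertices with explicit,
discretized conduction delays; the same simulated activity is expressed both
as scalp EEG (through a three-compartment boundary-element volume conductor)
and as fMRI BOLD contrast (through a balloon–windkessel haemodynamic model,
projected from vertices to voxels). Everything downstream of the neural model
is linear or slow, so a single simulation yields both modalities
simultaneously and self-consistently.

## The neural population model

At each vertex the state is the pair of mean soma membrane potentials
$(h_e, h_i)$ (mV) plus four second-order post-synaptic potential (PSP)
variables $I_{lk}$, one per ordered population pair $lk \in \{ee, ei, ie,
ii\}$ (source population first):

$$\tau_k \dot h_k = (h_k^{rest} - h_k) + \sum_l \frac{h^{eq}_{lk} - h_k}
{|h^{eq}_{lk} - h_k^{rest}|}\, I_{lk},$$

so each PSP is weighted by a reversal-potential factor that changes sign at
the Nernst potential $h^{eq}_{lk}$ and is normalized to one at rest. Without
input, $h_k$ relaxes to $h_k^{rest}$ with time constant $\tau_k$ (a property
the test suite checks by fitting the decay). Each $I_{lk}$ obeys a
second-order kernel which responds to a pre-synaptic Dirac pulse with an
alpha PSP $Q_{lk}\, e\, (t/\delta_{lk}) \exp(-t/\delta_{lk})$: zero at
$t = 0$, single maximum $Q_{lk}$ at the rise time $\delta_{lk}$. A decay
prolongation $\epsilon_{lk} > 0$ switches to a bi-exponential with the decay
rate divided by $1 + \epsilon_{lk}$, renormalized so the peak stays $Q_{lk}$
and continuous in $\epsilon$ at zero; the default is $\epsilon = 0$
throughout. The kernels are driven by the total pre-synaptic activation

$$A_{lk} = N^{\alpha}_{lk} S_l(h_l) + p_{lk} + \phi_{lk},$$

local firing plus extracortical input plus long-range input. Firing rates use
the sigmoid $S_k(h) = S^{max}_k / (1 + \exp(-\sqrt2 (h - \mu_k)/\sigma_k))$ —
strictly increasing, bounded, half-maximal at $\mu_k$. The exact sigmoid and
bi-exponential normalization conventions are isolated in
`sigmoid_rate()`/`psp_kernel_coefs()` so either can be swapped without
touching the integrator.

Integration is plain forward Euler at $\Delta t = 5\times10^{-5}$ s. The
first-order error this costs is measured, not assumed: the impulse response
of the discretized kernel stays within 1% of the closed form for the fastest
kernel (rise 3.3 ms) and within 0.5% for the slow one, and
`step_halving_check()` re-runs any simulation with a five-fold smaller step
against the same continuous noise input (the coarse-step control points are
reused, so the comparison isolates integration error).

### Default parameters

The source model family takes its parameter values from a companion
electrocortical model whose full table is not reproduced here; the defaults
in `npm_parameters()` are instead a documented, plausible set for this model
class, chosen once by linear stability analysis (`npm_stability()`) and then
left alone. With $\tau_e = 94$ ms, $\tau_i = 42$ ms, rest at $-70$ mV,
reversal potentials $+45$/$-90$ mV, PSP amplitudes 0.71 mV with rise times
$1/300$ s (excitatory) and $1/65$ s (inhibitory), local synapse counts
$N^\alpha = (615, 4582, 2500, 535)$, long-range counts
$N^\beta = (4000, 2000)$ and mean extracortical drive $\bar p_{ee} = 2000$
s$^{-1}$, the single-vertex system has one stable fixed point
($h_e^\ast \approx -79.3$ mV) with a damped resonance near 8 Hz, and it
remains stable when the long-range gain doubles (specific connectivity up to
roughly 1.5 times the background). Band-limited noise then produces sustained
alpha-band-like fluctuations rather than runaway oscillation. Because these
values are a stand-in rather than the published set, every dynamical test in
the package is property-based (decay constants, fixed-point agreement with an
independent Newton solver, oracle equivalence of the transmission machinery)
and no test asserts a particular spectral peak frequency or amplitude.

## Noise drive

Extracortical input is noise-like in $p_{ee}$ only. A continuous, band-limited
series is built by Catmull–Rom spline interpolation of i.i.d. Gaussian control
points sampled every $u$ steps, with
$u = \mathrm{round}(0.40449/(\Delta t\, f_{cut}))$. The constant 0.40449 is
the $-3$ dB normalized frequency of the Catmull–Rom interpolation kernel; the
package recomputes it numerically (`catmull_rom_minus3db()`) rather than
treating it as magic. At the defaults ($f_{cut} = 75$ Hz) $u = 108$.
Innovations are scaled by the reciprocal RMS of the interpolation basis
averaged over phases (`catmull_rom_variance_factor()`, $\approx \sqrt{0.814}$),
computed once numerically, so the interpolated series has the requested
standard deviation; this calibration is checked against pooled sample
statistics and the $-3$ dB point of a Welch spectrum in the tests. The default
noise SD of 500 s$^{-1}$ (25% of the mean drive) produces clearly visible but
non-saturating fluctuations.

## Connectivity and delay bookkeeping

*Background* connectivity is homogeneous, isotropic and decays exponentially
with on-surface distance: $w_{ba} \propto \mathrm{area}(b)\,
\exp(-\Delta_{ba}/\lambda)$ with $\lambda = 25$ mm, truncated at the cut-off
$\Delta_c = \lambda \ln 10 \approx 57.6$ mm (the distance at which the kernel
falls to 10% — `cutoff_distance()`), and normalized to sum to exactly one per
target vertex. The area factor makes the weights independent of mesh
resolution, which is why pruning the mesh does not change the total coupling.
Distances are graph geodesics over mesh edges (igraph Dijkstra), checked
against great-circle arcs on sphere fixtures.

*Specific* connectivity adds region-to-region weights from a graded (0–3)
connectivity matrix. Grades gate presence only; one universal strength
$W_s$ — expressed as a fraction of the total background input, which is 1 by
construction — is distributed over the source region's vertices in proportion
to their area (the matrix does not specify a vertex-level allocation, so area
weighting is used for the same resolution-independence reason as above).
Homotopic links connect every vertex to the vertex nearest its mirror image
across the midsagittal plane ($x = 0$ by default). Delays for specific and
homotopic links use the shortest *through-volume* route: a visibility graph of
straight segments entirely inside the cortical volume (tested by uniform
sampling at 0.5 mm steps; the surface edges are always included so the graph
is connected), solved by vectorized Floyd–Warshall and matched to the fine
mesh by Euclidean proximity. Routed distances are used for homotopic delays
too (the alternative, Euclidean distance, is shorter but passes outside the
volume). Velocity is 3 m/s for all long-range connections.

All delays are discretized to multiples of $\Delta t$ and served by per-vertex
ring buffers: a deposit adds a weighted source rate `delay` steps ahead of the
current-time pointer (modulo buffer length); consuming a slot adds it to
$\phi$ and resets it to zero. Channels with delays above $3u\Delta t$
($u = 5$ at the 1.6 kHz transmission cut-off, so 0.75 ms, equivalently
2.25 mm at 3 m/s) transmit only every $u$-th value — the Catmull–Rom control
points — and the receiving side reconstructs the intermediate rates, cutting
traffic by exactly a factor $u$. The buffered implementation (compiled, in
`src/`) is verified against a pure-R explicit-history reference that stores
full rate histories and evaluates $\sum_b w\, s(t - d)$ directly: the
unsplined paths agree to $10^{-14}$, and the deposit-side spline
reconstruction is bitwise identical to consumption-side interpolation.
Partitioned execution is defined to be result-invariant: deposits are always
accumulated in one canonical connection order, so the control-point streams
and state of a partitioned run are identical to a single-partition run by
construction, and the partition assignment only changes the traffic
accounting (`transmission_accounting()`).

## Signal expression

*EEG.* Each vertex carries a current dipole along its outward area-weighted
normal, with moment proportional to the deviation of $h_e$ from rest times the
vertex area. The dipole strength is only known to be roughly proportional to $h_e$, so
absolute scalp-volt calibration is out of scope: the constant `c_d` is
exposed and tests assert linearity and symmetry, not absolute amplitude. The volume conductor has three nested
closed surfaces — inside of skull 0.2 S/m, skull 0.03 S/m, scalp 0.2 S/m —
solved by collocation BEM on triangle centroids with an autosolid-angle
diagonal (row sums forced to their analytic values), deflation of the
constant-potential nullspace, and the isolated-skull substitution for the
low-conductivity skull layer. Outputs are average-referenced; the reference
convention is not dictated by the physics, which determines potentials only
up to a constant. Against the analytic concentric-three-sphere series
solution (`concentric_spheres_potential()`, an independent Legendre-expansion
oracle) the solver is within 0.8% at 1280 triangles per surface for a radial
dipole at 70% eccentricity, with monotone convergence under refinement.

*fMRI BOLD.* BOLD is driven by excitatory synaptic input only (a glutamate
proxy): $z \propto f_e A_{ee} + (1 - f_e) A_{ei}$ with $f_e = 0.85$,
baseline-subtracted at the numerically located resting point and normalized by
it (so `drive_scale` is a dimensionless sensitivity; the proportionality
constant is not stated by the physiology and is exposed as configuration).
Each vertex runs the standard four-ODE balloon–windkessel model (signal decay
0.65 s$^{-1}$, autoregulation 0.41 s$^{-1}$, transit 0.98 s, stiffness 0.32,
resting extraction 0.34, resting volume 0.02 — the canonical set of the model
this stage follows) and the three-term BOLD observation equation. The
haemodynamics are slow, so they integrate at 1 ms with the neural drive held
piecewise-constant between recorded samples; RK4 is used there because it
costs nothing at that step and puts the integration error (checked against an
adaptive `lsoda` reference at $10^{-4}$) far below the physiological
uncertainty.

*Voxel projection.* Vertex values spread to voxel centres with an anisotropic
Gaussian: the displacement is split into its component along the vertex
normal ($\sigma_N = 2.0$ mm) and the orthogonal tangential remainder
($\sigma_T = 1.66$ mm, whose FWHM $2\sqrt{2\ln 2}\,\sigma_T \approx 3.9$ mm
matches a typical pruned edge length); $|n|^2 + |t|^2 = |d|^2$ holds exactly
by construction. Weights are truncated beyond $4\max(\sigma_N, \sigma_T)$
(under 0.04% of the mass). Voxel values are weight-normalized averages,
followed by a global normalization that restores the original value range —
implemented as a linear min–max rescale to the input range (the simplest
convention consistent with that requirement) and skipped for constant fields
where it is ill-defined. The same
weights applied in transpose project voxel data back onto vertices. A
depth-weighting hook (laminar gradient) is accepted in the configuration but
is uniform by default.

## Mesh pruning

Cortical meshes from surface-extraction pipelines oversample flat regions.
`prune_mesh()` repeatedly collapses the globally shortest edge (ties broken
deterministically by lowest vertex-index pair): the two adjacent triangles are
removed and the endpoints merge into a vertex placed on a circle segment
approximating the local surface — the endpoint normals are projected into the
plane through the edge midpoint spanned by the mean normal and the edge
direction, their lines intersected, and the new vertex placed at
$v = p_0 + b\,(p_3 - p_0)$, where $b = 1$ is exact for a sphere and $b = 0$
(the midpoint) for a plane. If the projected normals are parallel the surface
is locally flat and the midpoint is used, which is then exact. Collapses that
would fold two triangles onto each other are the "tetrahedron" configuration:
a degree-3 peak vertex whose neighbours are pairwise connected while the base
triple is not itself a face. These are detected (`detect_tetrahedra()`) and
resolved by replacing the peak with the base triangle, optionally lifted
towards the peak by a factor $l$. Resolution is lazy — a tetrahedron is
handled when its base edge becomes the collapse candidate — because eager
re-scans cost quadratic time and the end state is the same. Collapses that
would flip a retained triangle's normal are rejected and the next-shortest
edge is taken, preventing local self-intersection. Each collapse changes
$(V, E, F)$ by $(-1, -3, -2)$ and tetrahedron removal by $(-1, -3, -2)$, so
the Euler characteristic is preserved; pruning a unit sphere at $b = 1$ keeps
all vertices within $10^{-2}$ of the sphere and the total area within 2%.
Defaults are $b = 1$, $l = 0$. Open (bounded) meshes are accepted: boundary
edges are simply never collapsed.

## Synthetic study conditions

Every input the chain needs is generated from a seed: two mirror-symmetric
icosphere "hemispheres" (28 mm radius, centres 70 mm apart, optional
sinusoidal folding), a contiguous 3-region parcellation grown from
farthest-point seeds, a fully connected triangle of grade-2 ("moderate")
connections between the three regions in both directions — the motif of a
small visual network (two visual areas and a frontal eye field) — plus
homotopic mirror links; three concentric head shells at 80/85/92 mm with the
standard conductivities; a Fibonacci-lattice electrode cap; an isotropic
voxel grid. The cortical volume for route finding is the union of the two
hemisphere balls and a 12 mm midline bridge ball standing in for the callosal
cross-over — without it no contralateral route exists. What the fixtures do
*not* emulate: cortical folding geometry (gyral dipole cancellation), a
realistic parcellation or graded connectome, distance-heterogeneous
conduction velocities, and the published parameter table of the source model.
Tests passing on these fixtures therefore validate the machinery — weights,
delays, buffers, solvers, projections — not the empirical spectra of any real
cortex, which is also why the connectivity-strength sweep is exercised as a
protocol (determinism, accounting, stability) rather than compared against
published spectral peak positions. `run_sweep()` accepts any user-supplied
mesh, parcellation and matrix in place of the fixtures.

## The sweep protocol

`run_sweep()` varies the universal specific strength $W_s$ over a grid
(default $0, 0.30, 0.60, 0.85, 0.90, 1.0$ — from no specific connectivity to
as strong as the background), simulating 10 s per point with identical noise
(same seed) so spectral differences are attributable to connectivity alone.
The "ECoG" is the vertex-averaged $h_e$; its Welch power spectrum (2 s Hann
segments, 50% overlap) is computed over the last 4 s to skip transients and
reported in dB relative to the largest value across the sweep. Each point
also records the realized specific-to-background input ratio per vertex,
which must equal $W_s$ times the afferent region count to $10^{-10}$ —
an accounting identity, not a statistical check. Module tests run the same
protocol desk-scaled (two icosphere hemispheres at subdivision 2, 324
vertices, 2 s per point) so the whole chain stays in the seconds range;
the durations and mesh sizes in the test suite were chosen for that purpose
and are stated in the tests themselves.

## Numerical choices and degenerate inputs

- Delays are rounded to the nearest step and floored at one step; zero-delay
  (self) connections are excluded by construction since background kernels
  exclude the target vertex itself.
- Splined channels require delays above $3u\Delta t$; shorter specific delays
  raise an error with the remediation (lower $u$, or let the channel fall
  back to per-step transmission).
- A vertex with no in-range background source (mesh coarser than the cut-off)
  is an error, not a silent zero row.
- Non-finite membrane potentials abort the integrator with the failing step;
  `run_sweep()` records such points as failed and continues.
- The BEM system is singular (potential defined up to a constant): deflation
  pins the mean, and all outputs are average-referenced anyway.
- Welch spectra refuse series shorter than one segment; the $-3$ dB locator
  works on a smoothed spectrum against the low-frequency plateau.

## Known limitations

No thalamocortical loop or sleep-cycle modulation (the extracortical input is
plain band-limited noise); volume conduction ignores anisotropy and uses
nearest-collocation electrode sampling; BOLD uses one canonical haemodynamic
parameter set everywhere; the voxel grid is axis-aligned isotropic; GIfTI
surfaces are not read (OFF and delimited sidecars are); and persistence of
distance tables and recorded series uses RDS/delimited text rather than a
hierarchical binary store.
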