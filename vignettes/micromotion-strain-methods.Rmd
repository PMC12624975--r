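---
title: "Micromotion strain modeling and recording-performance analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Micromotion strain modeling and recording-performance analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(arraystrain)
```

# The problem

Bed-of-needles ("Utah") microelectrode arrays are grids of stiff silicon
shanks bonded to a common base and implanted in cortex.  The brain moves
relative to the implant (respiration, pulsation, head movement), and
because the silicon is about eight orders of magnitude stiffer than the
tissue, that micromotion strains the tissue around each shank.  Strain
concentrations are a plausible driver of gliosis and of the spatial
pattern of recording quality across the array.  `arraystrain` implements
the full analysis chain needed to study this hypothesis at the level of
array geometry:

1. a parametric solid model of array + tissue and a conforming
   quadratic-tetrahedron mesh with tip refinement;
2. a static, nonlinear (one-term Ogden) finite-element solve of the
   micromotion boundary-value problem;
3. von Mises strain summarized over a 50 µm region of interest (ROI) at
   every electrode tip, grouped by concentric electrode rings;
4. a synthetic-recording generator whose ground truth is monotonically
   linked to a strain map;
5. the recording-to-metric pipeline (impedance screening, bandpass
   filtering, threshold-crossing snippets, PTPV, noise floor, SNR,
   envelope multi-unit activity, neighbor correlations);
6. rank-based statistics relating strain to the metrics.

Clinical and NHP recordings are not distributed with (or consumable by)
the package; the synthetic generator exists precisely so that the metric
pipeline and the correlation stage can be exercised and calibrated with
a known ground truth.

# Geometry and meshing

An `array_spec()` describes a rows × cols grid at 400 µm pitch on a base
substrate (4 mm × 4 mm × 0.2 mm for 10 × 10).  Shanks taper from a
150 µm square at the base to a 10 µm diameter circle at 1.49 mm; the tip
is a revolved quarter ellipse (major radius 10 µm along the axis, minor
radius 5 µm), total length 1.5 mm.  The taper is modeled as a
superellipse loft whose exponent interpolates from near-square at the
base to circular at the taper end; a circular frustum with matched tip
geometry is available as a fallback (`shank_profile = "frustum"`) — at
the tip, where the ROI lives, the two coincide.  The tissue block
extends 2 mm laterally from the base and 1 mm below the tips
(`tissue_spec()`).

Meshing starts from a graded tensor-product hexahedral background grid
split into tetrahedra (Freudenthal/Kuhn pattern), then refines towards
every shank tip by Maubach newest-vertex bisection until all elements
intersecting the sphere of influence at each tip have edges no longer
than `tip_max_edge`.  Maubach bisection (rather than longest-edge
bisection) is used because it is guaranteed to terminate and to produce
a conforming mesh on Kuhn-triangulated backgrounds; we observed
longest-edge closure cycling on graded grids.  Elements are tagged
tissue/array by centroid membership in the implicit array solid, so the
bonded contact is a single conforming mesh with shared interface nodes.
The interface is therefore stair-stepped at the local element size: near
the tips (refined to micrometres) the geometry is followed closely,
while the shank shaft far from the tips is resolved only at the
background cell size.  Since the ROI metrics live within 50 µm of the
tips and strain along the shaft is out of scope, this is the right place
to spend resolution.

Defaults are full fidelity — 1 µm edges inside 10 µm tip spheres — and
are what `mesh_spec()` returns.  Full-array desk-scale runs use relaxed
values (see *Problem sizes* below).

# The mechanical model

Tissue is a one-term Ogden hyperelastic solid,

$$\Psi = \frac{\mu_1}{\alpha_1}\left(\lambda_1^{-\alpha_1} +
\lambda_2^{-\alpha_1} + \lambda_3^{-\alpha_1} - 3\right) +
\frac{1}{d_1}(J-1)^2,$$

with the human-cortex parameters µ₁ = 150.5 Pa, α₁ = 19,
d₁ = 6.65 × 10⁻⁵ Pa⁻¹.  Two stretch conventions are implemented.
Applied to the raw principal stretches, the formula as written is *not*
stress-free at the reference state: because the power term is not
volumetrically projected, it carries a hydrostatic residual of −µ₁ at
λ = (1,1,1).  The default convention therefore applies the power term to
the isochoric stretches $\bar\lambda_i = J^{-1/3}\lambda_i$ — the form
used by the one-term Ogden of large-deformation commercial solvers —
which is stress-free at reference and linearizes to shear modulus
µ₀ = µ₁α₁/2 ≈ 1429.75 Pa and bulk modulus κ = 2/d₁ ≈ 30.1 kPa
(effective Poisson ratio ≈ 0.477).  The raw convention is retained
behind `ogden_material(convention = "raw")` and both are verified
against finite differences of the energy.

The array is silicon (E = 200 GPa, ν = 0.278).  With the ~10⁸ stiffness
contrast, the default "rigid" mode eliminates all array degrees of
freedom and prescribes the full driven displacement on every array-region
node; an "elastic" mode retains the silicon region (St. Venant–Kirchhoff)
for fidelity checks.  Elastic mode transmits the drive through the meshed
silicon, so it is only meaningful on meshes whose background cells are
smaller than the shank cross-section; the solver checks that the array
region is contiguous from the driven face to the tips and warns
otherwise.  Boundary conditions: tissue bottom fixed, array
driven by m·(sin θ, cos θ, 0) for magnitude m ∈ {1, 5, 10, 20, 50} µm
and in-plane angle θ ∈ {0°, 22.5°, 45°} from the Y axis.  The model is
static: micromotion has dynamic components, but a static solve gives a
first-order approximation adequate for *spatial comparisons* across the
array, which is all the downstream statistics use.

## Numerics

Displacements use 10-node (quadratic) tetrahedra with 4-point Gauss
quadrature; the consistent unit system is Pa–µm.  The Newton iteration
is load-stepped with a consistent linear predictor for each Dirichlet
increment (the constrained-column coupling is formed by a directional
finite difference of the residual), a backtracking line search on the
residual norm, and recursive bisection of steps that fail to converge.
The material tangent is formed by forward differences of the analytic
first Piola–Kirchhoff stress, which sidesteps the repeated-eigenvalue
degeneracies of the closed-form Ogden tangent; the symmetrized tangent
feeds either:

* a sparse Cholesky factorization (CHOLMOD; used up to ~100k free
  unknowns, with the symbolic analysis reused across iterations), or
* conjugate gradients preconditioned by a two-level V-cycle — damped
  Jacobi smoothing on the quadratic system plus an exact factorization
  of its Galerkin restriction to the linear (vertex) element space —
  with inexact-Newton forcing.  This backend has no factorization-fill
  memory wall and is selected automatically for larger meshes.

Convergence is declared at ‖R‖ ≤ 10⁻⁷‖R₀‖ + 10⁻⁸ (configurable through
`solver_control()`).  For pure-Y loads on mirror-symmetric geometry, a
half-domain mode (`generate_mesh(..., half_x = TRUE)`) imposes u_x = 0
on the x = 0 plane; this is exact, not an approximation, and halves the
problem.  `solve_magnitude_sweep()` runs the magnitude ladder as one
load continuation so each magnitude warm-starts the next.

Strain post-processing evaluates the deformation gradient at every node
of each tissue element from the quadratic shape functions, forms the
logarithmic (Hencky) tensor by spectral decomposition, averages tensors
over adjacent elements, and reports the von Mises equivalent strain

$$\varepsilon_{vM} = \frac{1}{1+\nu'}\sqrt{\tfrac12\left[
(\varepsilon_1-\varepsilon_2)^2 + (\varepsilon_2-\varepsilon_3)^2 +
(\varepsilon_3-\varepsilon_1)^2\right]}, \qquad \nu' = 0.5,$$

the large-deformation post-processing convention (ν′ configurable).

# ROI summarization

The ROI is a 50 µm sphere at each tip — the approximate single-unit
recording volume.  Nodal strains are averaged in half-open 2.5 µm radial
bins `[r, r + 2.5)` and the volume-weighted average weights each bin
mean by its ideal spherical-shell volume, which de-biases the summary
from local mesh density; the maximum is the largest nodal value in the
ROI.  Nodes of array-region elements are excluded; empty bins are
flagged and skipped, never counted as zeros.  Electrodes are grouped by
concentric rings (minimum grid distance to the array edge, corners as
their own group) or by distance from the array centre.

# What the synthetic generator emulates — and what it does not

`synthetic_ground_truth()` draws per-electrode spike amplitudes,
impedances and evoked gains from monotone links to the within-array
min–max normalized strain $\tilde s_e$:
$Z_e = z_0 e^{\beta_Z \tilde s_e}\eta_Z$,
$A_e = a_0 e^{\beta_A \tilde s_e}\eta_A$,
$g_e = g_0(1 + \beta_G \tilde s_e)$, with lognormal noise multipliers
and per-session lognormal variability.  Default effect sizes —
β_Z = β_A = −0.8 (σ = 0.25/0.2), β_G = 1, z₀ = 400 kΩ, a₀ = 180 µV,
noise SD 8 µV, 15 Hz firing, 5 sessions, session σ = 0.1 — were chosen
once as representative of chronic-array statistics: an e^0.8 ≈ 2.2-fold
amplitude/impedance span across the array against ~25% electrode-level
noise, spike SNR ≈ 10 at baseline.  The motor-cortex regime is negative
β_Z/β_A; the visual-cortex evoked regime is positive β_G.  Traces are
white Gaussian noise plus a fixed biphasic difference-of-Gaussians
template (1.5 ms support) at Poisson times with a 2 ms refractory gap;
an optional shared-noise block emulates insulation failure along an
array edge.  All randomness flows through R's Mersenne-Twister from a
single seed per call, so outputs are bit-reproducible across platforms.

The generator emulates the *statistical structure* the pipeline
consumes, not extracellular biophysics: no spike-shape diversity, no
LFP, no 1/f noise by default (a flag away), no drift, no electrode
interactions beyond the shared-noise block.  Passing tests therefore
demonstrate that the pipeline recovers planted structure at realistic
effect sizes — they do not validate biological claims about real
recordings.

# The metric pipeline

Per the standard chronic-array workflow: electrodes with 1 kHz impedance
strictly above 1 MΩ (SIROF) or 2 MΩ (platinum) are nonfunctional and
excluded *before* averaging and normalization.  Recordings are filtered
with a 2nd-order Butterworth bandpass (300–5000 Hz), applied zero-phase
by default (causal by flag; the choice is ours — field practice varies).
Events are negative crossings of mean − 4.5·RMS with a 1 ms lockout
(lockout rule ours); snippets span −0.5/+1 ms and clipped snippets are
discarded.  The representative PTPV is the mean of the largest
⌈0.02 N⌉ snippet peak-to-peak voltages (rounding rule ours, minimum
one); the noise floor is twice the SD of the trace with snippet windows
excised; SNR is their ratio.  eMUA is bandpass (500–5000 Hz),
rectification, 200 Hz low-pass, 1 kHz resampling — the standard envelope
recipe, fully configurable — and evoked SNR is (peak trial-averaged
stimulation eMUA − mean baseline eMUA)/SD of baseline eMUA.  Metrics are
averaged across the five sessions and then min–max normalized within the
array as (x − min)/max(x − min), which guarantees [0, 1]; undefined
metrics (empty snippet sets) propagate as missing, never as zeros.

# Statistics

Spearman rank correlation (average ranks; exact permutation p for
n ≤ 9, t approximation otherwise; two-sided throughout),
Kruskal–Wallis with tie correction plus Dunn's post-hoc z tests (raw
and Holm-adjusted — the correction choice is ours), and one-way ANOVA
with Tukey HSD for the modeled strain groups.  Missing data are deleted
pairwise per metric.  `correlate_strain_metrics()` joins a strain table
with normalized metrics, always excluding screened-out and unconnected
electrodes, and reports pooled and per-array fits.

# Problem sizes used by the tests and the acceptance script

The package defaults are full fidelity; the shipped verification studies
are deliberately desk-scale, chosen once:

* *Ring-ordering solve*: 4 × 4 grid, tip edge 3 µm in 3 µm spheres,
  300 µm background, half-domain, 10 µm Y displacement.
* *Mesh convergence*: single shank, tip edges {3, 2, 1, 0.5} µm in a
  3 µm sphere, half-domain.
* *Magnitude/angle sweeps*: half-domain continuation over
  {1, 5, 10, 20, 50} µm and full-domain off-axis runs (22.5°, 45°) on
  30 µm-tip meshes (the ring ordering is a large-scale feature and does
  not require tip-scale refinement).
* *Pipeline calibration*: 96 connected electrodes (10 × 10 with corner
  mask), shortened sessions (1–2 s instead of 30 s) at the default
  effect sizes; recovery and false-positive rates estimated over tens
  to hundreds of seeds depending on per-seed cost.

# Known limitations

* Stair-step (voxelized) array boundary: geometric fidelity is set by
  the local element size; shank shafts far above the tips are coarsely
  represented, so shaft-adjacent strain is not meaningful (and is not
  used).  A corollary is that mesh refinement changes the discrete tip
  shape along with the discretization, so ROI-average differences
  between successive refinement levels need not shrink monotonically
  even when the error against the finest mesh is small.
* Static, compressible-regularized hyperelasticity with quadratic
  displacement elements; no mixed formulation (at ν ≈ 0.477 locking is
  mild, and the patch/oracle tests bound the error), no viscoelasticity,
  no contact separation, no insertion pre-strain.
* The nodal-averaged Hencky/von Mises recovery is first-order accurate
  at material interfaces.
* The synthetic generator's scope is described above; correlations
  recovered from it validate the pipeline, not biology.
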