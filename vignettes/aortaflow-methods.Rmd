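---
title: "Aortic 4D flow analysis: models, conventions and validation phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aortic 4D flow analysis: models, conventions and validation phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What this package computes

`aortaflow` analyses time-resolved three-directional phase-contrast
("4D flow") cardiovascular MRI of the thoracic aorta. From a velocity field
$v(x, t)$ (m/s), magnitude images, an aortic segmentation, the velocity
encoding limit (venc) and the temporal resolution, it derives the
quantities used to characterise aortic valve disease and its surgical
treatment:

* per-plane **forward and net flow volumes** (mL per cardiac cycle) at nine
  standard anatomical planes P1–P9 from the left ventricular outflow tract
  to the distal descending aorta;
* **systolic 3D wall shear stress (WSS)**, the tangential viscous traction
  $\tau = \mu \, \partial v_t / \partial n$ at the wall (N/m²), summarised
  over an 18-region wall atlas, the three aortic zones, and the inner/outer
  curvature sides;
* **zone peak velocities** from a maximum-intensity projection over the
  three timeframes centred on peak systole;
* semi-quantitative **helix/vortex grades** (0–3) from pathlines traced
  through the time-interpolated velocity field;
* nonparametric **cohort statistics** (paired Wilcoxon signed-rank,
  Mann–Whitney U, Friedman with pairwise follow-ups, chi-square), with
  exact small-sample p-values.

Because clinical 4D flow studies of this kind rest on protected patient
data, the package ships a **digital aorta phantom generator** whose output
carries analytic ground truth. Every stage of the pipeline is validated
against those closed forms rather than against irreproducible patient
tables.

# Conventions

One canonical unit system is used everywhere: world coordinates in mm with
`world = (index - 1) * spacing` on the voxel grid (no affine/oblique
support; oblique inputs must be resampled by the caller), velocities in
m/s, time in ms, viscosity in Pa·s, WSS in N/m². A convenient identity is
used throughout: 1 m/s equals 1 mm/ms, so velocities integrate directly
against mm geometry and ms timing. Velocity arrays are ordered
`(x, y, z, t, component)`; readers validate shapes and refuse to guess axis
order.

The canonical on-disk container is a directory holding float64 NIfTI
volumes (`velocity.nii.gz` with the component as a fifth dimension,
`magnitude.nii.gz`) plus a JSON sidecar with spacing, dt and venc; this
round-trips to floating-point identity. Clinical NIfTI-per-component input
with a JSON sidecar is accepted as an input dialect.

# The correction chain

**Background phase (eddy currents).** Residual eddy-current phase appears
as a smooth, almost static spatial offset added to each velocity
component. Per component and timeframe we least-squares fit a spatial
polynomial (order 0–2, default 1 = planar, the standard choice for
background phase) to the velocities of *static tissue* voxels and subtract
it from the whole volume. Static tissue is identified as voxels with
temporal speed standard deviation below a threshold (default 0.05 m/s)
outside the dilated aortic mask; phantoms supply exact static masks for
testing. On noise-free polynomial offsets of the fitted order the
correction is exact to machine precision — this is asserted in the tests.
Maxwell-term (concomitant gradient) correction requires scanner gradient
calibration data that are not part of the pipeline inputs; a pass-through
hook `correct_maxwell_terms()` marks its place in the chain.

**Anti-aliasing.** True speeds beyond venc wrap by multiples of
$2\,\mathrm{venc}$. No specific published algorithm is being reproduced
here; the package uses a spatiotemporal consistency rule: a voxel whose
component differs from the median of its 3×3×3×3 space–time neighbourhood
by more than venc is shifted by the wrap multiple that minimises the
residual, iterated to convergence (max 4 passes, non-convergence is
flagged). The operation is idempotent and provably inert on fields within
±venc. It is validated only against phantoms with injected wraps (exact
inversion noise-free; ≥ 99% voxel recovery at a noise SD of 0.05·venc).
Planes that still contain neighbour jumps above venc after correction are
excluded from analysis with reason `aliasing-failure`, and, for subjects
with a prosthetic valve, planes within 2 cm above the valve are excluded
(`prosthesis-window`) because of local field distortion — in practice this
hits the sinotubular junction plane.

**Peak systole** is the timeframe with the highest mean speed inside the
segmentation; ties take the lowest frame index. The 5-frame (WSS) and
3-frame (MIP) windows centred on it wrap cyclically, since the cardiac
cycle is periodic.

# Geometry

**Centerline.** An exact Euclidean distance transform of the mask gives an
interior depth map; the two geodesic extremes of the mask (snapped onto the
medial axis) are joined by a depth-weighted shortest path (weight
$\ell / (1 + d)^3$, 26-connectivity), which hugs the medial ridge. The
path is refined by moving each sample to the centroid of its local lumen
cross-section (a one-voxel slab perpendicular to the running tangent,
radius-limited so a curved vessel cannot capture the opposite limb),
smoothed, resampled at 1 mm, and trimmed by 5 mm at each end where
one-sided slabs bias the centroid. Tangents use a ±3 mm stencil. On
phantoms this recovers a straight axis to under 0.2 voxel lateral error and
a 35 mm arch radius to within 2%.

**Planes.** Each of P1–P9 sits at a landmark given either as an arc-length
fraction (phantom use) or an explicit world point projected onto the
centerline (clinical use); landmark order is enforced. Planes are normal to
the local tangent and carry an in-plane sample grid at 0.8 mm pitch clipped
to the lumen (mask ≥ 0.5 under trilinear interpolation), with area element
pitch². Flow is the in-plane sum of through-plane velocity times area
element, integrated with the rectangle rule at step dt; forward flow keeps
only positive through-plane samples.

**Wall mesh.** The binary mask is Gaussian-smoothed (σ = 1 voxel) and the
0.5 isosurface is extracted by marching tetrahedra on the Kuhn 6-tet cube
decomposition, which is translation-consistent and therefore watertight.
Duplicate vertices are welded. Inward normals come from the gradient of the
smoothed occupancy (which increases toward the lumen) and are checked — and
flipped if needed — against the wall-to-centerline direction. A sphere's
surface area is recovered to within 5%, a cylinder's radius to half a
voxel.

**The 18-region atlas.** The analysed extent runs from P2 to P9 (the LVOT
plane P1 is excluded from wall analysis; flow there is unreliable in
practice). Zones are arc-length bands: ascending [P2, P5), arch [P5, P7),
descending [P7, P9]. The inner/outer side is the sign of the vertex offset
along the local curvature normal (the side facing the centre of curvature
is *inner*); where curvature is degenerate (straight stretches, below
10⁻³ mm⁻¹) the side falls back to the direction toward the circumcentre of
the P2/P6/P9 arch plane. Each zone×side cell is split into three
equal-arc-length thirds, giving 18 segments numbered ascending-inner 1–3
(proximal→distal), ascending-outer 4–6, arch-inner 7–9, arch-outer 10–12,
descending-inner 13–15, descending-outer 16–18. No published enumeration of
the surgical 18-region scheme exists in text form, so this construction is
the package's own, chosen to reproduce the standard aggregates (zone means,
inner/outer means, numbered segments) from one consistent rule; tests
assert it is an exact partition of the analysed wall.

# Wall shear stress

Per vertex, velocity is sampled by trilinear interpolation at two distances
$d_1 < d_2$ along the inward normal (defaults 0.5× and 1.0× the mean voxel
pitch). For each velocity component a quadratic through the no-slip wall
point $(0, 0)$ and the two samples gives the wall-normal derivative
$a = (v_1 d_2^2 - v_2 d_1^2) / (d_1 d_2 (d_2 - d_1))$; the derivative
vector is projected onto the wall-tangent plane and multiplied by the
dynamic viscosity. Blood viscosity defaults to μ = 3.2×10⁻³ Pa·s — a
conventional value for WSS mapping, recorded in every result — and is
configurable. Systolic WSS averages the WSS *vectors* over the five-frame
systolic window first and takes the norm second, so opposing directions
attenuate rather than add; regional values are unweighted vertex means, and
empty or all-invalid regions are reported missing rather than zero.

For Poiseuille pipe flow the analytic wall traction is
$2 \mu v_{max} / R$; with R = 10 mm and $v_{max}$ = 1 m/s this is
0.64 N/m². On a 1 mm phantom the vertex-mean estimate lands within 3% at
$d_1$ = 0.5 mm (the estimator is exact for a parabolic profile sampled
exactly; residual error comes from trilinear interpolation and sub-voxel
wall placement). WSS is exactly linear in the velocity field.

# Pathlines and grading

Pathlines integrate $\dot{x} = v(x, t)$ with classical RK4 through the
trilinear/linear-in-time (cyclically periodic) field; any step whose
displacement would exceed one voxel is re-taken with proportionally smaller
substeps, and particles stop at the mask or domain boundary. Seeds form a
uniform grid (≥ 100 points) across the P2 plane and are released at each of
the five systolic frames.

Helical rotation is the absolute cumulative unwrapped change of a
pathline's angular coordinate about the centerline, measured in
rotation-minimising frames and restricted to the ascending aorta
([P2, P5)). Vortical flow — revolution about a point with direction
deviating more than 90° from the physiological flow direction — is
detected when a pathline sweeps ≥ 180° about its own trajectory centroid
(in the plane of its two leading principal axes) while its mean velocity
direction makes an angle above 90° with the local centerline tangent.

The grade scale is 0 (no qualifying rotation), 1 (rotation < 360°),
2 (> 360°), 3 (> 360° with increased flow). Two boundaries are not pinned
down by common usage and are explicit package conventions, reported with
every result: the 0/1 presence floor at 90° of rotation, and "increased
flow" as ascending peak velocity above 1.5 m/s (the conventional stenotic
jet threshold), configurable as `v_thresh`. On swirl phantoms constructed
to rotate 0°/300°/540° per transit with peak velocities of 1.0/2.0 m/s the
pipeline reproduces grades 0/1/2/3 exactly, and the grade is monotone in
rotation at fixed peak velocity.

# Cohort statistics

All tests are nonparametric, matching small-cohort practice. The paired
Wilcoxon signed-rank test drops zero differences (Wilcoxon's original
convention, as in common statistical packages) and midranks ties; the
Mann–Whitney U test pools midranks. Exact p-values are computed from the
full permutation distribution (2ⁿ sign assignments, or all
$\binom{n_A+n_B}{n_A}$ labelings) via the shift algorithm on a doubled-rank
lattice so midranks stay integral; the exact path is the default whenever
n ≤ 25 (signed-rank) or total n ≤ 20 (U test), so cohorts of the size this
pipeline targets (about 20 subjects, 7 vs 13 groups) are always exact.
Beyond the thresholds tie-corrected normal approximations are used and
labelled as such. Two-sided p-values are the default and are defined
symmetrically, $P(W \le w_{min}) + P(W \ge w_{max})$, clamped at 1.

The Friedman test across the three aortic zones uses within-subject
midranks and the tie-corrected chi-square statistic (verified against
`stats::friedman.test`); an exact permutation option (full enumeration via
dynamic programming over per-subject rank orderings) is available for
k = 3 and n ≤ 8. Pairwise follow-ups are paired Wilcoxon tests reported
unadjusted — matching common clinical reporting — with an optional
Bonferroni column, off by default. The chi-square test is Pearson's without
continuity correction, with a warning when any expected count is below 5.
Under exchangeable nulls at the target cohort sizes, all four tests hold an
empirical size between 0.03 and 0.07 at α = 0.05 (2000 replicates; the
slight conservatism reflects the discreteness of exact small-sample
distributions).

# The phantom: what it emulates, and what it does not

`generate_phantom()` builds a straight tube or a U-shaped tube (two 60 mm
legs joined by a 35 mm-radius semicircular arch — an idealised thoracic
aorta) with lumen radius 10 mm, sampled at the acquisition geometry typical
of clinical aortic 4D flow: isotropic 2.5 mm voxels (an isotropic stand-in
for a 2.7×2.3×2.6 mm protocol), 40.8 ms temporal resolution, venc 1.5 m/s,
20 timeframes per cycle. The axial profile is Poiseuille,
$v(r, t) = v_{max}\, w(t) (1 - r^2/R^2)$, with a periodic waveform
$w(t) \in [0,1]$ (default: diastolic baseline 0.15 plus a Gaussian systolic
pulse of width 2.5 frames peaking at frame 5 — chosen to give a
physiologically plausible stroke volume of roughly 50 mL at
$v_{max}$ = 1 m/s). Womersley profiles are deliberately not used: the
Poiseuille closed forms make the flux and WSS oracles exact, which is the
phantom's entire purpose.

Optional features, each recorded in the emitted truth: a Gaussian jet
multiplier along the centerline (stenotic jet); core swirl
$v_\theta = \alpha r\, v_{axial}$ with α in rad/mm, which makes *every*
pathline rotate exactly α per mm of axial travel while inheriting no-slip
from the axial profile (the closed form behind the grading oracle, at the
cost of an azimuthal wall shear component
$\sqrt{1 + (\alpha R)^2}$ recorded in the WSS truth); additive Gaussian
velocity noise; polynomial background phase offsets in the same basis the
correction fits; and venc wrap injection with the exact affected-voxel set
recorded. Speeds above 3·venc are refused (double wraps are ambiguous)
unless explicitly allowed. The analytic field is divergence-free, so
agreement of net flux across all planes is a meaningful conservation test.

What the phantom does *not* emulate — and what passing tests therefore do
not establish about patient data: wall compliance and motion, supra-aortic
branch outflow (real descending-aortic flow is ~30% lower than ascending),
turbulence and Rician magnitude noise, eccentric valve jets, acquisition
blurring (k-space acceleration, view sharing), and segmentation error
(masks are inputs; the phantom's are exact). Cohort tables are drawn from
correlated bivariate Gaussians per measurement — a device for calibrating
the statistics, not a model of biological variability.

# Numerical choices and degenerate inputs

* Trilinear interpolation clamps to the grid boundary; WSS vertices whose
  normal samples exit the grid are flagged invalid and excluded from
  regional means.
* The eddy fit refuses rank-deficient static masks; unaliasing warns when
  it has not converged within its 4 passes.
* The neighbourhood median inside unaliasing is computed by vectorised
  bisection on the order statistic (exact to ~10⁻⁹ of the data range, far
  below any venc-scale comparison).
* Peak-systole ties take the lowest frame; cyclic windows are used at the
  cycle boundary.
* Atlas side labels for vertices almost on the curvature-neutral line are
  decided by the sign of a near-zero projection; this only moves vertices
  between adjacent inner/outer segments and cannot break the partition.
* Problem sizes in the test-suite and acceptance phantoms (40–100 mm tubes,
  1–2.5 mm grids, 5–20 frames, 2000-replicate null calibrations, 500
  power replicates) were chosen as the smallest sizes at which every oracle
  tolerance above is comfortably met; they are stated in each test.

# Known limitations

* Axis-aligned voxel grids only; no affine/oblique geometry.
* The 18-region boundaries are this package's reconstruction of a surgical
  atlas that has no published textual definition; absolute per-segment
  values are therefore comparable within this package only.
* The aliasing corrector is a generic spatiotemporal-median unwrapping, not
  a reimplementation of any scanner vendor's method.
* Pathline grading automates what is clinically a visual, movie-based
  reading; agreement is demonstrated on phantoms with known rotation, not
  against human readers.
* P1 (LVOT) is excluded from wall analysis and carries no atlas labels.
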