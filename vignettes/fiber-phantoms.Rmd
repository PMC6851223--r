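---
title: "Fiber phantoms and the 3D-PLI forward model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fiber phantoms and the 3D-PLI forward model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrecup)
```

`fibrecup` builds synthetic nerve-fiber models — explicit tubes with
per-point coordinates and radii — and demonstrates their use with a
Müller-matrix simulation of 3D polarized light imaging (3D-PLI). This
vignette is the package's own account of the geometry and optics: the
conventions, the tunable parameters, the numerical choices, and what the
tests do and do not show.

## The fiber model

Every model is a tidy table of fiber points. A *fiber object* is an ordered
chain of points `(x, y, z)` with a radius `r` at each point, all in
micrometres; groups collect fibers for joint transforms and for hierarchical
storage. The same representation covers an individual axon and a bundle
*envelope* — a fat tube that is later filled with thin child fibers.

Trajectories come from two sources:

* **Parametric functions.** `parametric_fiber()` evaluates four expressions
  of a parameter `t` on a uniform grid of `n_steps + 1` values. The
  expression language is a deliberate whitelist (`t`, numbers, arithmetic,
  `sin`, `cos`, `tan`, `exp`, `log`, `abs`, `sqrt`, `pi`, `e`): model files
  are data, and evaluating them must not execute arbitrary code.
* **Control points.** `spline_fiber()` interpolates coordinates *and* radii
  with the same cubic spline in a common parameter. The default parameter is
  the control-point index; chord-length parameterization
  (`parameterization = "chord"`) gives more uniform speed along unevenly
  spaced controls and is what the Fiber Cup builder uses.

**Spline end conditions.** The default boundary condition fits an exact
cubic through the four points at each end (`boundary = "cubic"`,
Forsythe–Malcolm–Moler). This makes the interpolant reproduce any global
cubic polynomial exactly — a property the test suite asserts to 1e−9 — at
the cost of slightly livelier ends than the zero-curvature alternative,
which remains available as `boundary = "natural"`. For two controls both
degenerate to the straight chord.

Rigid transforms (`translate_fibers()`, `rotate_fibers()`,
`scale_fibers()`, `duplicate_fibers()`) act on whole phantoms or selected
groups/fibers. Rotation is axis–angle through `rodrigues_rotate()`,

v' = v cos θ + (k × v) sin θ + k (k·v)(1 − cos θ),

with the pivot defaulting to the centroid of the transformed selection.
Uniform scaling multiplies radii along with coordinates, so a scaled phantom
stays geometrically similar.

## Bundle filling

`fill_bundle()` populates an envelope with parallel child fibers:

1. **Reference cross-section.** The data point with the *minimum positive*
   radius `R_ref`. Zero radii (tapered tips) are excluded — otherwise any
   envelope that pinches to a point would fill to a single axis line.
2. **Seed grid.** Children are seeded on a hexagonal (triangular) lattice in
   the reference cross-section with nearest-neighbor center distance
   `spacing`, keeping every seed whose center lies within `R_ref` of the
   axis. The lattice is anchored with the bundle axis at the *centroid of a
   lattice triangle*, i.e. there is no seed on the axis itself; the three
   nearest seeds surround it symmetrically.
3. **Frame transport.** The grid is carried along the trajectory by
   orthonormal frames: tangents are central differences (one-sided at the
   ends) and the in-plane normals of frame *i+1* are the normals of frame
   *i* rotated about `t_i × t_{i+1}` by the angle between consecutive
   tangents. This transport is torsion-minimizing: the grid never spins
   about the axis, so neighboring children cannot braid.
4. **Radius coupling.** At data point *j* the in-plane offsets are scaled by
   `R_j / R_ref`. Since `R_ref` is the minimum, the scale is always ≥ 1:
   separations only grow, which (for spacing ≥ fiber diameter) guarantees
   the children of one bundle never intersect. The suite checks this with a
   brute-force segment-distance oracle on straight, helical and conical
   envelopes.

**Grid convention and the calibration counts.** Published fiber counts pin
down conventions that prose leaves open. Two counts matter here: filling the
diagonal test object `x = y = z = r = t` (1000 points) with fiber radius 0.1
and minimum distance 0.2 must give **21** children, and the default filled
Fiber Cup must total about **10,149** fibers. A systematic scan over lattice
type, spacing rule, containment rule and lattice anchoring shows that the
seed-on-axis convention cannot produce 21 at all (hexagonal-disc counts jump
1, 7, 13, 19, 31, …), while exactly one convention reproduces both numbers:

* the *minimum distance* parameter is the surface-to-surface gap, so the
  center spacing is `d + 2 r_fiber` (0.4 for the diagonal object; 3.0 µm for
  the Fiber Cup's 1.5 µm fibers lying 1.5 µm apart);
* seeds are kept when their **centers** lie within `R_ref`;
* the lattice is anchored at a triangle centroid, not at a lattice point.

This is the package's documented convention. It yields exactly 21 children
for the diagonal object and 1,443 per Fiber Cup bundle (10,101 in total,
0.5 % below the printed reference — per-bundle grid-anchoring differences
plausibly explain a remainder that is not divisible by 7). One consequence:
when the envelope is too thin for any lattice seed (`R_ref < spacing/√3`),
the fill falls back to a single child on the axis.

**Degenerate cases.** Antiparallel consecutive tangents leave the rotation
axis undefined; an arbitrary perpendicular axis is used with a warning.
Near-parallel tangents (cross product below 1e−12) get the identity
rotation. The initial in-plane normal is taken from the first tangent turn
of the trajectory itself, which makes filling *equivariant*: filling a
rotated envelope equals rotating the filled bundle (asserted to 1e−6 µm).
Perfectly straight fibers have no intrinsic transverse direction — no
deterministic rule can be equivariant there — and fall back to the global
axis least aligned with the tangent.

## Collision detection

`detect_collisions()` treats fibers as capsule chains and reports fiber
pairs whose minimum segment–segment axis distance falls below the sum of the
local radii (linearly interpolated along each segment) minus a tolerance. A
uniform-grid broad phase over inflated segment bounding boxes prunes pairs;
the narrow phase is the exact clamped closed form. A relative epsilon of
1e−9 on the radius sum keeps exact tangency — the designed contact state of
a bundle filled at `spacing = 2 r` — from being misreported as overlap.
Collision *solving* (repositioning) is out of scope; detected overlaps are
reported, not repaired.

## The Fiber Cup phantom

`build_fibercup()` constructs seven bundle envelopes on a circular plate
(default diameter 1000 µm): a straight transverse bundle (3), a straight
diagonal bundle (2) crossing it at equal density, a C-shaped bending bundle
(1), a curved fanning bundle (7), and three bundles (4–6) that merge into a
single vertical path and cross bundle 3 at triple density. The center-line
control points are this package's versioned layout (also shipped as
`inst/extdata/fibercup_default.yaml`): they reproduce the crossing/merging
*topology* of the classic Fiber Cup design, not any particular hardware
phantom's exact coordinates, and the crossing angles are therefore nominal.
Envelopes are allowed to overlap — that is the point: overlapping fills
produce the density contrasts that make orientation recovery fail in
interesting ways.

Defaults: bundle diameter 120 µm, fiber diameter 1.5 µm, fiber gap 1.5 µm,
42 sample points per fiber (giving 424,242 data points for the filled
phantom). Filling each constant-radius envelope uses the same grid, so all
seven bundles hold identical fiber counts.

## The 3D-PLI forward model

`voxelize()` discretizes a filled phantom over a bounding box (default voxel
edge 1 µm): a voxel is tissue when its center lies inside some fiber
capsule; among overlapping fibers the nearest axis wins; the stored
orientation is the local segment direction. `simulate_measurement()` then
propagates one Stokes vector per column through the polarimeter chain for
each rotation angle ρ:

polarizer at ρ → per-voxel retarder → quarter-wave retarder at ρ − π/4 →
analyzer at ρ + π/2.

Each tissue voxel is a linear retarder with its fast axis along the fiber's
in-plane direction φ and retardance

δ = 2π · (voxel size / λ) · Δn · cos² α,

plus an intensity attenuation `exp(−µ · voxel size)`. The quarter-wave fast
axis at ρ − π/4 is the handedness for which the chain reduces, for a
homogeneous column, to the standard signal
`I(ρ) = (I_T/2)(1 + sin(2ρ − 2φ) sin δ_total)`; with the opposite choice the
modulation flips sign. `I0` is the intensity of the *polarized* beam
entering the specimen, so an empty column detects `I0/2`. Stokes
physicality (`S0 ≥ |(S1,S2,S3)|`) can be asserted at every step with
`check_stokes = TRUE`.

Defaults (`optics_params()`): λ = 525 nm, Δn = 0.001, µ = 5 mm⁻¹,
I₀ = 26,000 counts, section thickness 60 µm, nine angles 0°–160° in 20°
steps, camera pixel 20 µm, blur σ = 0.714 · pixel size. The camera model
blurs with a Gaussian (circular convolution in the Fourier domain, which
preserves the image mean to machine precision; wrap-around is negligible
for tissue away from the box edge) and block-averages down to the pixel
size, which must be an integer multiple of the voxel size. Sensor noise is
Gaussian with variance proportional to intensity (a shot-noise CCD
approximation); the default gain gives SNR ≈ 100 at I₀/2. Noise is applied
*after* blur/downsampling (sensor-level reading) and always requires an
explicit seed. The exact published CCD noise parameters are not reproduced
here; noise is therefore excluded from exact acceptance numbers.

## Orientation recovery ("rofl-lite")

`recover_orientation()` is a single-view harmonic estimator — a deliberate
simplification of full tilting-stage fitting, which needs measurements this
simulation does not produce. Per pixel, the discrete Fourier coefficients of
`I(ρ)` at frequency 2 give the direction `φ = atan2(−b_cos, b_sin)/2` mapped
to `[0, π)`, and the relative modulation gives `|sin δ_total|`. The
inclination inverts the retardance formula,
`cos² α = δ_total · λ / (2π t Δn)`, clipped to `[0, 1]`.

Two caveats are inherent and documented rather than hidden:

* The thickness `t` must be the *birefringent* path length. A filled bundle
  occupies only a packing fraction (≈ 0.9 at tangency) of each column, so
  end-to-end tests pass the measured tissue fraction × box height —
  mirroring the relative-thickness calibration real analyses need.
  Mis-calibrating `t` biases α but never φ.
* `α = acos(√·)` is ill-conditioned at α ≈ 0: sub-percent retardance bias
  (averaging `sin δ` over heterogeneous columns is slightly concave) becomes
  degrees of inclination. The suite therefore asserts the 3° inclination
  bound at a tilted orientation (α = 30°) and the 1° direction bound at both.

Pixels with modulation below `min_modulation` (vertical fibers, background)
or unphysically above the mean are masked. In a pixel where two equal
bundles cross at ±γ the estimator returns the *bisector* — retardance
vectors add at doubled angles, so symmetric contributions average. This is
the crossing-as-kissing misestimation the phantom demonstrates; the suite
asserts the recovered direction lies within 2° of the bisector for a
symmetric 60° crossing.

Color coding (`orientation_to_color()`) is antipodally symmetric: `rgb`
maps a unit direction to `(|dx|, |dy|, |dz|)`; `hsv` maps hue = φ/π,
saturation = cos α, value = 1 — the in-plane angle runs around the color
circle exactly once over 180°, so the map is continuous across φ = 0/π.

## Problem sizes, determinism, and limits

The test suite and the acceptance script run the full default Fiber Cup
fill (10,101 fibers). Simulation-stage tests use compact probe volumes
(40³–60³ voxels at 1 µm, bundles of a few hundred fibers) and property
tests use small random instances: these sizes already exercise every code
path — voxelization, the Müller chain, blur/downsampling, recovery — while
keeping a complete run in tens of seconds. All randomness is seeded;
`add_noise()` refuses to run without an explicit seed.

What passing tests show — and what they do not: the synthetic phantoms have
perfectly cylindrical, piecewise-linear fibers, homogeneous optics (single
Δn, single µ), no myelin substructure, no scattering, no tissue deformation.
Agreement with the closed-form optics and recovery bounds on these models
validates the implementation, not the biological fidelity of any particular
phantom. The Maxwell-solver (FDTD) simulation branch, scattering patterns,
tilting-stage protocols and collision resolution are outside this package's
scope.
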