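---
title: "Geodesic diffusion analysis on static curved membranes: models and methods"
author: "curvdiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geodesic diffusion analysis on static curved membranes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Lateral diffusion of lipids and membrane proteins is routinely quantified by
the mean square displacement (MSD) of their in-plane coordinates. On a curved
membrane this projection is wrong twice over: motion normal to the reference
plane is discarded (an artificial slowdown, strongest where the membrane is
steep), and the spatial structure of mobility is smeared because particles
from regions of different curvature mix as the lag time grows. The physically
meaningful displacement between two points constrained to a surface is the
*geodesic* distance — the length of the shortest path within the surface.

`curvdiff` computes spatially resolved geodesic MSD (gMSD) and
diffusion-coefficient maps on a *static* triangulated surface, together with
discrete mean (`H`) and Gaussian (`K`) curvature fields and curvature-class
statistics. The static-surface limit is appropriate whenever the membrane
shape changes much more slowly than particles diffuse across its features
(e.g. endocytic buds, cristae-like folds); fluctuating surfaces are out of
scope.

## Pipeline

1. **Meshing** (`build_heightfield_mesh`). The leaflet surface is estimated
   from scattered particle positions (typically lipid centers of mass pooled
   over frames) on a regular lateral grid: each node height is a
   Gaussian-kernel weighted mean of nearby point heights with periodic
   wrapping, and grid cells are split along a fixed diagonal so meshes are
   bit-reproducible. Nodes without support within `3 * smoothing_width` are
   an error (the surface would be unsupported there) unless an open partial
   chart is requested. Closed surfaces cannot be height fields; they enter
   as user-supplied PLY/OFF meshes, or through the radial analogues
   `build_sphere_mesh_from_points` / `build_cylinder_mesh_from_points` used
   by the validation suite.
2. **Tiling** (`tile_periodic`, `images = c(2, 2)` by default). Periodic
   displacements are evaluated on an open sheet covering four periodic
   images; each displacement's endpoint pair is translated by whole-box
   vectors so the start lies in the base-box-sized window centered in the
   tiled region and the end sits at its minimum-image position.
3. **Snapping** (`map_trajectory_to_vertices`). Particle positions are
   replaced by their nearest mesh vertex (lateral spatial index; ties break
   to the lowest index). Particles ever farther than `cutoff` (default 3 nm)
   from every vertex are excluded and counted, never interpolated.
4. **Displacement records** (`generate_displacement_records`,
   `sort_records`, `write_records`). Every (particle, start frame, lag)
   triple becomes an integer triplet `(v_lo, v_hi, lag_index)` with the
   lower vertex index first — geodesic distance is symmetric, so the
   orientation is redundant. A stable radix sort on the full key groups all
   records sharing a lower vertex into one contiguous block regardless of
   lag and makes record files byte-reproducible. The binary format is
   little-endian: magic `CURD`, version, lag table (float64 ns), record
   count, then 12-byte records.
5. **Blocked geodesic evaluation** (`evaluate_blocks`). One exact
   single-source geodesic solve per distinct lower vertex serves its whole
   block; the call count is returned and equals the number of distinct
   source vertices. Blocks are independent, so they parallelize trivially
   (`workers`), with bit-identical results for any worker count.
6. **Accumulation and maps** (`accumulate_gmsd`, `diffusion_map`). Each
   squared distance is credited to both endpoint vertices at its lag; a
   self-record contributes twice to its vertex (negligible for fine meshes,
   documented for exactness). The diffusion map is the free-diffusion
   single-lag estimate `D(v) = gMSD(v, lag) / (4 lag)` at an analysis lag of
   53 ns by default, rather than a per-vertex regression; a regression over
   a lag window can be assembled from the per-lag maps but is not the
   standard path. Internal units are nm^2/ns; `1 nm^2/ns = 1e-5 cm^2/s`.
7. **Statistics** (`classify_vertices`, `compare_classes`, `profile_field`,
   `occupancy_density`, `area_scaling_report`). Vertices are classified into
   a mean-curvature view (`Flat`, `H>0`, `H<0`) and a Gaussian-curvature
   view (`Flat`, `K>0`, `K<0`); `Flat` requires both `|H| < h_flat` and
   `|K| < k_flat`. Distributions are vertex-weighted, justified by the
   near-uniform occupancy density (which `occupancy_density` lets you
   check); occupancy weighting is available through the profile weights.
   Class pairs are compared by Welch's unequal-variance two-sample t test
   (via `stats::t.test`), with Bonferroni-adjusted p values reported
   alongside the raw ones.

## The geodesic engine

Exact polyhedral geodesics are computed by continuous-Dijkstra *window
propagation*: distance windows on mesh edges carry an unfolded planar
pseudo-source and are pushed across triangles in order of increasing
distance, splitting at face apices. Only vertices with positive angle excess
(polyhedral saddles) or boundary vertices can bend shortest paths; they act
as pseudo-sources whose emission is clipped to the *shadow cone* behind the
incoming direction (width = the angle excess, padded by 2 mrad for rounding
slack). Windows are pruned when their distance exceeds, everywhere on their
interval, the bound assembled from the current endpoint-vertex distances —
a vertex-oriented test whose interval minimum is available in closed form
because the window distance is convex and the bound is piecewise linear.
No shortest path is ever reconstructed; only distances are kept.

Numerical choices, each a named constant in the source:

* interval/coincidence tolerance `1e-12` relative to the local edge length;
* vertex-capture tolerance `1e-7` (angular): a wedge that misses a vertex by
  an angle `eps` after many splits still updates it, with the distance
  computed exactly from the unfolded pseudo-source, so the induced error is
  `O(eps^2)` — far below the pruning margin. Without this, structured meshes
  (where many geodesics pass exactly through lattice vertices) lose coverage
  to accumulated `~1e-10` rounding in the wedge boundaries;
* saddle threshold `1e-9` on the angle excess; treating flatter vertices as
  flat perturbs distances by at most `excess^2 / 8` relatively.

The second registered backend, `dijkstra`, restricts paths to mesh edges and
is therefore an upper bound everywhere; it serves as an independent oracle
in the tests and as the swap-in example for the narrow distance-backend
interface. The engine is exact on planar meshes (relative error `< 1e-12`
in practice), within 0.1% of great-circle arcs on an icosphere at
subdivision 4, and within 0.1% of the developable unrolling on cylinders.

## Discrete curvature

`H` uses the cotangent Laplace-Beltrami operator with Meyer mixed-Voronoi
vertex areas, signed by the vertex normal so that a sphere or cylinder with
outward normals is positively curved (`H = 1/R`, `H = 1/(2R)`); `K` is the
angle defect over the mixed area, orientation-independent (bowls positive,
saddles negative). Boundary vertices carry `NA` rather than a silently wrong
value. On a closed mesh the angle-defect total satisfies Gauss-Bonnet
essentially exactly. For leaflet meshes the winding convention is that
normals point from the acyl chains toward the headgroups.

Kernel bandwidths trade noise against curvature attenuation: smoothing a
sinusoid of wavenumber `k` with a Gaussian of width `w` attenuates `H` by
`exp(-k^2 w^2 / 2)`. The defaults (`smoothing_width = spacing`) favor
geometric fidelity for diffusion mapping; curvature-grade meshes in the
validation suite use wider kernels (1.5 nm on the 40 nm wave; 0.8 nm for
the 2 nm cylinder; 0.05 rad for the sphere chart), chosen once against the
closed-form curvatures of the generating surfaces.

## Synthetic ground truth

`parametric_surface` objects (plane, sphere, cylinder, sinusoidal wave
`z = A sin(2 pi y / L)`, Gaussian bud) provide closed-form normals,
curvatures, and — on plane/sphere/cylinder — geodesics.
`simulate_surface_brownian` generates surface-constrained Brownian
trajectories: an isotropic tangent-plane step with per-axis variance
`2 D0 dt`, followed by re-projection to the surface along the local normal
(radially for sphere/cylinder, Newton iteration for height fields). The step
length must satisfy `sqrt(4 D0 dt) < 0.2 / max|principal curvature|`;
violations are an error, not a warning. The scheme is validated by the flat
ensemble law `MSD = 4 D0 lag`, by isotropy of the step statistics, and by
the equilibrium saturation of the squared geodesic displacement on the unit
sphere at `(pi^2 - 4)/2` (the second moment of the arc length under the
uniform measure).

The default scene mirrors the study systems: ~40 x 40 nm boxes, mesh spacing
0.4 nm tiled over four periodic images (40,000 nodes), lag preset 2/53/453
ns, and `D0 = 0.06 nm^2/ns = 6e-7 cm^2/s`, the magnitude of flat
coarse-grained phospholipid diffusion. The generator is geometry-only: no
lipid packing, no interactions, no density-driven drift. Passing tests
therefore demonstrate the correctness of the geometric machinery — meshing,
snapping, exact distances, accumulation — not the biophysical curvature
effects themselves, which in real membranes ride on packing differences the
generator deliberately lacks.

## Validation problem sizes and estimators

The acceptance suite runs desk-scale studies chosen once:

* *Flat recovery*: 1000 particles x 10^4 frames (dt = 0.1 ns) on a 40 nm
  box, mesh spacing 1.0 nm. Nearest-vertex snapping inflates gMSD by
  `~2 E[snap^2]` (about +0.33 nm^2 here, +2.6% at 53 ns), which sets the
  spacing: fine enough that the single-lag `D` stays within 5% of the
  generator's `D0`, coarse enough that the ~4000 geodesic solves run in
  minutes.
* *Wave study*: `A = 5`, `L = 40` nm, spacing 1.25 nm, 2000 particles x
  10^4 frames. The particle count is a power choice: the reproducible
  spatial signal of the gMSD profile at the shortest lag (the
  slope-dependent snapping pattern, ~4% of the mean) must exceed the
  sampling-noise floor of the profile, which scales as `1/sqrt(n)` and does
  not shrink with lag because long-lag windows of the same trajectories
  overlap. Profile structure is estimated by the *split-half covariance*:
  particles are divided into two independent halves, profiles computed per
  half, and the reproducible variance taken as their covariance — an
  unbiased separation of signal from sampling noise. On a developable
  surface the true gMSD profile is exactly flat at every lag (the unrolling
  is an isometry), so the reproducible structure is the snapping signature,
  which dilutes as `1/gMSD`: non-increasing across 2 -> 53 -> 453 ns. At the
  two long lags the true signal is fractions of a percent, so the estimate
  sits at the split-half estimator's own resolution (a few percent-squared
  on the covariance with 20 bins); the short-lag drop is robust, while the
  53 vs 453 ns comparison is resolvable only as "both near zero".
* *Sphere equilibrium*: 400 particles x 2000 frames at `D0 = 0.5`,
  `dt = 0.01` ns on the unit sphere against an icosphere at subdivision 3,
  with a start-frame stride of 4 to bound the record count.

## Degenerate inputs and edge cases

Non-manifold or inconsistently wound meshes, degenerate faces and
zero-length edges are rejected at construction with the offending element
named. Disconnected components yield `Inf` distances rather than errors
(tiled leaflet meshes are connected in practice). Vertices never visited by
a displacement have undefined (NA) gMSD; empty profile bins are flagged, not
imputed. Ambiguously oriented lipids (head-tail vector orthogonal to every
leaflet normal within `1e-6`) are excluded from leaflet assignment and
counted. Truncated or corrupted record files fail with the byte offset.

## Known limitations

* Static surfaces only; no time-dependent meshes.
* Free-diffusion interpretation (`D = gMSD/4 lag`); no drift or
  free-energy-landscape correction, no anomalous-exponent fitting.
* Height-field meshing assumes no overhangs; closed or overhanging
  geometries must be supplied as mesh files.
* The long-time projected-vs-geodesic comparison reports the measured
  diffusion ratio next to the projected-to-true area ratio without asserting
  a functional form for the area-scaling relation.
* Binary compressed MD trajectory formats (XTC/TRR) are not parsed; a
  documented plain-text interchange format and a minimal GRO reader are
  provided, and any MD analysis stack can export to them in a few lines.
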