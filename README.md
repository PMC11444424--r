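# curvdiff

Spatially resolved **geodesic diffusion analysis on static curved
surfaces** — lipid lateral diffusion on buckled, budded, or otherwise curved
membrane leaflets, measured the way the geometry demands.

Conventional mean-square-displacement (MSD) analysis projects particle
motion onto a reference plane. On a curved membrane that projection
artificially slows apparent diffusion (most where the surface is steep) and
mixes regions of different curvature as the lag time grows. The physically
correct displacement between two points constrained to a surface is the
**geodesic distance**. `curvdiff` provides, in one package:

* **Leaflet meshing** from scattered particle positions (Gaussian-kernel
  height-field gridding with periodic tiling over four images), plus
  discrete **mean and Gaussian curvature** fields (cotangent
  Laplace–Beltrami / angle defect with mixed-Voronoi areas).
* An **exact polyhedral geodesic engine**: single-source-all-vertices
  distances by continuous-Dijkstra window propagation across unfolded
  triangles with vertex-oriented pruning — no path reconstruction, plus an
  edge-graph Dijkstra backend as an independent upper-bound oracle.
* The **sorted-triplet blocking scheme**: every displacement becomes an
  integer triplet `(v_lo, v_hi, lag_index)` with the lower vertex first;
  after a stable radix sort, one geodesic call per distinct source vertex
  evaluates a whole contiguous block, irrespective of lag. Records persist
  in a compact little-endian binary format (`CURD`).
* **gMSD and diffusion maps**: squared geodesic displacements accumulated at
  both endpoint vertices per lag; the free-diffusion map
  `D(v) = gMSD(v, Δ) / (4Δ)` at a single analysis lag (53 ns by default);
  projected-MSD comparison, spatial profiles, occupancy density,
  curvature-class decomposition with Welch tests, and the long-time
  projected-vs-geodesic area-scaling table.
* A **surface-constrained Brownian generator** on analytic surfaces (plane,
  sphere, cylinder, sinusoidal wave, Gaussian bud) with closed-form normals,
  curvatures and geodesics — ground truth with known `D0` for every stage.

The statistic at the core: for particle positions `r_i(t)` snapped to mesh
vertices,

    gMSD(v, Δ) = mean over displacements touching v of d_geo(r(t), r(t+Δ))²
    D_geo(v)   = gMSD(v, Δ) / (4 Δ)        (1 nm²/ns = 1e-5 cm²/s)

## Worked example

Simulate lipid-like Brownian motion (`D0 = 0.06 nm²/ns ≈ 6e-7 cm²/s`) on a
sinusoidal "wave" membrane, and run the full pipeline:

```r
library(curvdiff)

box  <- box_spec(40, 40)                      # nm, periodic
surf <- surface_wave(A = 5, box = box)        # z = 5 sin(2*pi*y/40)
cfg  <- run_config(surface = surf, D0 = 0.06,
                   n_particles = 300, n_frames = 4000, dt = 0.1,
                   spacing_nm = 1.25, lags_ns = c(2, 53, 203),
                   analysis_lag_ns = 53, seed = 1,
                   outdir = "wave_run")
res <- run_pipeline(cfg)
report("wave_run")
```

The run log and report print (output of this exact configuration):

```
[curvdiff] simulating 300 particles x 4000 frames on 'wave' (D0 = 0.06 nm^2/ns)
[curvdiff] mesh: 4096 vertices, 7938 faces
[curvdiff] snapped 300 particles (0 excluded), max snap distance 1.1 nm
[curvdiff] 2826000 records over 3 lags, sorted
[curvdiff] geodesic calls: 1606 (distinct source vertices)
curvdiff run summary
...
count-weighted mean D: 0.0628062 nm^2/ns = 6.28062e-07 cm^2/s

class means:
  view class       mean         sd   n
1    H  Flat 0.06281941 0.01548694 640
2    H   H>0 0.06607196 0.01588061 185
3    H   H<0 0.06565878 0.01683193 199
...
area scaling:
      D_proj      D_geo   D_ratio area_ratio discrepancy
1 0.05329677 0.06014104 0.8861964  0.8811313 0.005065128
```

Reading the output: 300 particles × (3980 + 3470 + 1970) start frames give
2.8 M displacement triplets, but only 1606 exact geodesic solves — one per
distinct lower vertex. The recovered count-weighted `D` at Δ = 53 ns is
0.0628 nm²/ns: the generator's 0.06 plus the documented nearest-vertex
snapping inflation (~+0.6 nm² on a 13 nm² gMSD at this mesh spacing, and
slightly larger on the steep slopes, which is why the curved classes sit a
couple of percent above `Flat` for this geometry-only generator). The
long-time projected-to-geodesic diffusion ratio (0.886) tracks the
projected-to-true area ratio (0.881). The output directory holds the mesh
with `H`, `K`, `gMSD_Δ`, `D` and occupancy as PLY vertex properties,
profile/class/Welch/area CSV tables, the binary record file, and a
checksummed manifest; `report()` verifies the checksums and prints the
class means — for the wave, `H>0` and `H<0` classes appear alongside
`Flat`.

A command-line wrapper mirrors the stages:

```sh
Rscript inst/cli/curvdiff.R synth --surface wave --A 5 --L 40 --particles 300 \
    --frames 4000 --dt 0.1 --seed 1 --out traj.txt
Rscript inst/cli/curvdiff.R records --traj traj.txt --dt 0.1 --lags 2,53,203 \
    --spacing 1.25 --out records.curd --write-mesh leaflet.ply
Rscript inst/cli/curvdiff.R gmsd --records records.curd --mesh leaflet.ply \
    --lag 53 --out maps/
```

## Scope

Static surfaces only, free-diffusion interpretation only; height-field
meshing (closed surfaces enter as PLY/OFF files); plain-text trajectory
interchange plus a minimal GRO reader (export from any MD stack). See the
methods vignette (`vignettes/geodesic-diffusion-methods.Rmd`) for the
models, estimators, numerical tolerances and limitations.
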