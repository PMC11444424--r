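# Shared fixtures, all generated in code.

# Closed rectangular grid sheet (includes both boundary rows/columns), so a
# 10 x 10 request really spans [0, 10]^2.
grid_mesh <- function(Lx, Ly, nx, ny, z = function(x, y) rep(0, length(x))) {
  xs <- seq(0, Lx, length.out = nx + 1)
  ys <- seq(0, Ly, length.out = ny + 1)
  g <- expand.grid(x = xs, y = ys)
  verts <- cbind(g$x, g$y, z(g$x, g$y))
  cells <- expand.grid(i = 0:(nx - 1), j = 0:(ny - 1))
  v00 <- cells$j * (nx + 1) + cells$i + 1L
  v10 <- v00 + 1L
  v01 <- v00 + nx + 1L
  v11 <- v01 + 1L
  faces <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
  triangle_mesh(verts, faces)
}

unit_square_mesh <- function() {
  triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
                rbind(c(1, 2, 3), c(1, 3, 4)))
}

# Smooth deterministic bumpy height field over a periodic box.
bumpy_mesh <- function(box_L = 15, spacing = 0.35, n_pts = 4000, seed = 11) {
  set.seed(seed)
  box <- box_spec(box_L, box_L)
  pts <- cbind(runif(n_pts, 0, box_L), runif(n_pts, 0, box_L), 0)
  pts[, 3] <- 1.5 * sin(2 * pi * pts[, 1] / box_L * 2) *
    cos(2 * pi * pts[, 2] / box_L * 1.5) + 0.5 * sin(2 * pi * pts[, 2] / box_L * 3)
  build_heightfield_mesh(pts, box, spacing = spacing, smoothing_width = 0.5)
}

# Minimal snapped-trajectory stand-in for record-level tests (no periodic
# wrapping: the mesh reference carries no grid metadata).
fake_vtraj <- function(frames, dt = 1) {
  structure(list(frames = frames, dt = dt, mesh = NULL), class = "vertex_trajectory")
}

# Restrict a vertex trajectory to a subset of particles.
subset_vtraj <- function(vt, cols) {
  for (f in c("frames", "wx", "wy", "wz", "ux", "uy"))
    if (!is.null(vt[[f]])) vt[[f]] <- vt[[f]][, cols, drop = FALSE]
  vt
}

# Sort records together with an aligned auxiliary vector.
sort_records_with_aux <- function(rec, aux) {
  ord <- order(rec$v_lo, rec$v_hi, rec$lag_index, method = "radix")
  rec$v_lo <- rec$v_lo[ord]
  rec$v_hi <- rec$v_hi[ord]
  rec$lag_index <- rec$lag_index[ord]
  rec$sorted <- TRUE
  list(records = rec, aux = aux[ord])
}

subset_records <- function(rec, idx) {
  rec$v_lo <- rec$v_lo[idx]
  rec$v_hi <- rec$v_hi[idx]
  rec$lag_index <- rec$lag_index[idx]
  rec
}

# Height-field mesh built from the wrapped positions of a trajectory.
mesh_from_trajectory <- function(traj, spacing, images = c(2L, 2L),
                                 smoothing = spacing, max_pts = 2e5) {
  L <- traj$box
  pts <- cbind(as.vector(traj$x) - L$Lx * floor(as.vector(traj$x) / L$Lx),
               as.vector(traj$y) - L$Ly * floor(as.vector(traj$y) / L$Ly),
               as.vector(traj$z))
  if (nrow(pts) > max_pts) pts <- pts[seq(1, nrow(pts), length.out = max_pts), ]
  build_heightfield_mesh(pts, L, spacing = spacing, smoothing_width = smoothing,
                         images = images)
}

# Flat tiled height-field mesh with guaranteed support everywhere.
flat_tiled_mesh <- function(box_L, spacing, z = 0, seed = 99, images = c(2L, 2L)) {
  set.seed(seed)
  box <- box_spec(box_L, box_L)
  pts <- cbind(runif(4000, 0, box_L), runif(4000, 0, box_L), z)
  build_heightfield_mesh(pts, box, spacing = spacing, images = images)
}
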