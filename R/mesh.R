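#' Orthorhombic simulation box
#'
#' Lateral box lengths used for periodic wrapping and tiling. Only
#' orthorhombic boxes are supported.
#'
#' @param Lx,Ly,Lz box edge lengths in nm (all > 0); `Lz` defaults to `Ly`.
#' @return an object of class `box_spec`.
#' @export
box_spec <- function(Lx, Ly, Lz = Ly) {
  stopifnot(is.numeric(Lx), is.numeric(Ly), is.numeric(Lz),
            Lx > 0, Ly > 0, Lz > 0)
  structure(list(Lx = Lx, Ly = Ly, Lz = Lz), class = "box_spec")
}

#' Oriented triangle mesh
#'
#' Container for a static triangulated surface: vertex positions in nm and
#' counterclockwise-wound faces (normals follow the winding). Construction
#' validates that the mesh is manifold, consistently oriented, and free of
#' degenerate faces.
#'
#' @param vertices numeric n x 3 matrix of positions (nm).
#' @param faces integer m x 3 matrix of 1-based vertex indices.
#' @param box optional [box_spec()]: lateral periodic box of the *base*
#'   (untiled) system; `NULL` for closed test surfaces.
#' @param provenance free-text tag (leaflet id / surface name).
#' @param grid optional regular-grid metadata attached by
#'   [build_heightfield_mesh()].
#' @param validate run manifold/orientation checks (default `TRUE`).
#' @return an object of class `triangle_mesh` with fields `vertices`, `faces`,
#'   `box`, `provenance`, and cached `boundary`/`angle_sum` per vertex.
#' @export
triangle_mesh <- function(vertices, faces, box = NULL, provenance = "",
                          grid = NULL, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  m <- structure(list(vertices = vertices, faces = faces, box = box,
                      provenance = provenance, grid = grid,
                      boundary = NULL, angle_sum = NULL),
                 class = "triangle_mesh")
  if (validate) {
    chk <- cpp_mesh_validate(vertices, faces)
    m$boundary <- chk$boundary
    m$angle_sum <- chk$angle_sum
  }
  m
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh '%s': %d vertices, %d faces%s%s\n",
              x$provenance, nrow(x$vertices), nrow(x$faces),
              if (!is.null(x$box)) sprintf(", box %.3g x %.3g nm", x$box$Lx, x$box$Ly) else "",
              if (!is.null(x$grid)) sprintf(", grid %dx%d", x$grid$nx, x$grid$ny) else ""))
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)

#' Scalar field on mesh vertices
#'
#' One real value per mesh vertex (curvature, gMSD, diffusion coefficient,
#' occupancy, ...). Invalid vertices (e.g. boundary vertices for curvature)
#' carry `NA`.
#'
#' @param values numeric vector, one entry per vertex.
#' @param lag optional lag time in ns the field refers to.
#' @param units free-text unit tag.
#' @return numeric vector of class `vertex_field` with `lag`/`units` attributes.
#' @export
vertex_field <- function(values, lag = NULL, units = "") {
  structure(as.numeric(values), lag = lag, units = units,
            class = "vertex_field")
}

#' Replicate points over a lattice of periodic images
#'
#' Copies each point onto an `images[1] x images[2]` lattice of box
#' translations; the default `c(2, 2)` covers four periodic images.
#'
#' @param points n x 3 matrix of positions (nm).
#' @param box a [box_spec()].
#' @param images integer pair, numbers of images along x and y (each >= 1).
#' @return the replicated `n * prod(images)` x 3 matrix.
#' @export
tile_periodic <- function(points, box, images = c(2L, 2L)) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3, length(images) == 2, all(images >= 1))
  shifts <- expand.grid(ix = seq_len(images[1]) - 1L, iy = seq_len(images[2]) - 1L)
  out <- do.call(rbind, lapply(seq_len(nrow(shifts)), function(k) {
    p <- points
    p[, 1] <- p[, 1] + shifts$ix[k] * box$Lx
    p[, 2] <- p[, 2] + shifts$iy[k] * box$Ly
    p
  }))
  out
}

#' Build a height-field mesh from scattered surface points
#'
#' Grids scattered particle positions (e.g. lipid centers of mass of one
#' leaflet) into a regular triangulated height field. Vertex heights are
#' Gaussian-kernel-weighted averages of the point z-values with bandwidth
#' `smoothing_width`, evaluated with periodic wrapping in x and y. Each grid
#' cell is split along the fixed lower-left to upper-right diagonal, so the
#' mesh is bit-reproducible; faces are wound counterclockwise seen from +z,
#' giving upward normals.
#'
#' With `images > c(1, 1)` the points are first replicated with
#' [tile_periodic()] and the grid spans the tiled region, which is how
#' periodic displacements are evaluated on an open mesh.
#'
#' @param points n x 3 matrix: a single-valued height field over (x, y).
#' @param box the *base* periodic [box_spec()].
#' @param spacing target grid spacing in nm (> 0); the actual spacing divides
#'   the box length exactly.
#' @param smoothing_width Gaussian kernel bandwidth in nm; defaults to
#'   `spacing`.
#' @param images integer pair of periodic images to tile (default no tiling).
#' @param allow_partial if `TRUE`, grid nodes with no point within
#'   `3 * smoothing_width` are dropped (open chart) instead of raising an
#'   error. Used for non-periodic partial charts such as a spherical cap.
#' @param periodic kernel wrapping; disable for partial charts.
#' @param provenance tag stored on the mesh.
#' @return a `triangle_mesh` with grid metadata.
#' @export
build_heightfield_mesh <- function(points, box, spacing,
                                   smoothing_width = spacing,
                                   images = c(1L, 1L), allow_partial = FALSE,
                                   periodic = TRUE, provenance = "heightfield") {
  points <- as.matrix(points)
  stopifnot(nrow(points) >= 3, spacing > 0, smoothing_width > 0)
  if (any(images > 1)) points <- tile_periodic(points, box, images)
  Tx <- images[1] * box$Lx
  Ty <- images[2] * box$Ly
  nx <- max(2L, as.integer(round(Tx / spacing)))
  ny <- max(2L, as.integer(round(Ty / spacing)))
  sx <- Tx / nx
  sy <- Ty / ny
  hf <- cpp_kernel_heightfield(points[, 1], points[, 2], points[, 3],
                               0, 0, sx, sy, nx, ny, smoothing_width,
                               if (periodic) Tx else -1,
                               if (periodic) Ty else -1)
  z <- hf$z
  supported <- hf$support > 0L
  if (!all(supported) && !allow_partial) {
    bad <- which(!supported)[1] - 1L
    stop(sprintf(
      "grid cell (%d, %d) has no points within 3 * smoothing_width = %.3g nm",
      bad %% nx, bad %/% nx, 3 * smoothing_width))
  }
  # vertex (i, j) -> row j*nx + i + 1, positions (i*sx, j*sy, z)
  ij <- expand.grid(i = 0:(nx - 1), j = 0:(ny - 1))
  verts <- cbind(ij$i * sx, ij$j * sy, z)
  cells <- expand.grid(i = 0:(nx - 2), j = 0:(ny - 2))
  v00 <- cells$j * nx + cells$i + 1L
  v10 <- v00 + 1L
  v01 <- v00 + nx
  v11 <- v01 + 1L
  faces <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
  if (!all(supported)) {
    keep_f <- supported[faces[, 1]] & supported[faces[, 2]] & supported[faces[, 3]]
    faces <- faces[keep_f, , drop = FALSE]
    used <- sort(unique(as.vector(faces)))
    remap <- integer(nrow(verts))
    remap[used] <- seq_along(used)
    verts <- verts[used, , drop = FALSE]
    faces <- matrix(remap[faces], ncol = 3)
    grid_meta <- NULL
  } else {
    grid_meta <- list(nx = nx, ny = ny, sx = sx, sy = sy,
                      images = as.integer(images),
                      Tx = Tx, Ty = Ty)
  }
  triangle_mesh(verts, faces, box = box, provenance = provenance,
                grid = grid_meta)
}

mesh_geometry <- function(mesh) {
  cpp_vertex_geometry(mesh$vertices, mesh$faces)
}

#' Per-vertex outward unit normals
#'
#' Area-weighted average of incident face normals; orientation follows the
#' face winding (for leaflet meshes, wind so normals point from the acyl
#' chains toward the headgroups).
#'
#' @param mesh a `triangle_mesh`.
#' @return n x 3 matrix of unit vectors.
#' @export
vertex_normals <- function(mesh) {
  mesh_geometry(mesh)$normals
}

#' Discrete mean curvature field
#'
#' Cotangent Laplace-Beltrami estimate with Meyer mixed-Voronoi vertex areas:
#' `H = 0.5 * (Laplacian of position / (2 A_mixed)) . normal`. The sign
#' convention makes a sphere or cylinder with outward normals positively
#' curved (`H = 1/R` and `H = 1/(2R)` respectively). Boundary vertices are
#' `NA`.
#'
#' @param mesh a `triangle_mesh`.
#' @return a [vertex_field()] in 1/nm.
#' @export
mean_curvature <- function(mesh) {
  vertex_field(mesh_geometry(mesh)$H, units = "1/nm")
}

#' Discrete Gaussian curvature field
#'
#' Angle-defect estimate `K(v) = (2*pi - sum of incident angles) / A_mixed(v)`.
#' The sign is independent of orientation: bowls positive, saddles negative.
#' Boundary vertices are `NA`.
#'
#' @param mesh a `triangle_mesh`.
#' @return a [vertex_field()] in 1/nm^2.
#' @export
gaussian_curvature <- function(mesh) {
  vertex_field(mesh_geometry(mesh)$K, units = "1/nm^2")
}

#' Mixed-Voronoi vertex areas
#' @param mesh a `triangle_mesh`.
#' @return numeric vector of per-vertex areas (nm^2).
#' @export
vertex_areas <- function(mesh) {
  mesh_geometry(mesh)$area_mixed
}

#' Nearest mesh vertex under the lateral minimum-image convention
#'
#' Snaps points to their closest mesh vertex (Euclidean distance, with x/y
#' wrapped by `box` when given). Ties break deterministically to the lowest
#' vertex index. A lateral spatial index makes full-trajectory snapping
#' near-linear in the number of queries.
#'
#' @param mesh a `triangle_mesh`.
#' @param points a length-3 vector or n x 3 matrix of query positions (nm).
#' @param box optional [box_spec()] for the minimum-image convention; `NULL`
#'   (default) disables wrapping.
#' @param return_distance also return snap distances.
#' @return integer vector of 1-based vertex indices, or a list
#'   `(index, distance)` when `return_distance = TRUE`.
#' @export
nearest_vertex <- function(mesh, points, box = NULL, return_distance = FALSE) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  points <- as.matrix(points)
  res <- cpp_nearest_vertex(mesh$vertices, points,
                            if (is.null(box)) -1 else box$Lx,
                            if (is.null(box)) -1 else box$Ly)
  if (return_distance) res else res$index
}

#' Total and projected surface area
#'
#' @param mesh a `triangle_mesh`.
#' @return named vector `c(A_surf, A_proj)` in nm^2: the sum of face areas and
#'   the sum of |face areas projected onto the xy-plane|; `A_proj <= A_surf`.
#' @export
surface_and_projected_area <- function(mesh) {
  cpp_mesh_areas(mesh$vertices, mesh$faces)
}

#' Vertices of the central periodic image
#'
#' For a tiled height-field mesh, the analysis window is the base-box-sized
#' region centered in the tiled extent (for 2 x 2 tiling, `[L/2, 3L/2)`);
#' statistics are taken there, away from the open outer boundary.
#'
#' @param mesh a grid `triangle_mesh` from [build_heightfield_mesh()].
#' @return logical vector marking central-window vertices.
#' @export
central_image_vertices <- function(mesh) {
  g <- mesh$grid
  if (is.null(g)) return(rep(TRUE, n_vertices(mesh)))
  offx <- (g$Tx - mesh$box$Lx) / 2
  offy <- (g$Ty - mesh$box$Ly) / 2
  x <- mesh$vertices[, 1]
  y <- mesh$vertices[, 2]
  x >= offx & x < offx + mesh$box$Lx & y >= offy & y < offy + mesh$box$Ly
}
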