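test_that("height-field gridding reproduces constant and analytic surfaces", {
  set.seed(1)
  box <- box_spec(10, 10)
  pts <- cbind(runif(500, 0, 10), runif(500, 0, 10), 5)
  m <- build_heightfield_mesh(pts, box, spacing = 0.5)
  expect_equal(nrow(m$vertices), 400)  # 20 x 20 nodes over [0, 10)
  expect_true(all(abs(m$vertices[, 3] - 5) < 1e-12))

  # dense samples of a sine sheet are recovered to well under one spacing
  n <- 20000
  ps <- cbind(runif(n, 0, 10), runif(n, 0, 10), 0)
  ps[, 3] <- sin(2 * pi * ps[, 2] / 10)
  ms <- build_heightfield_mesh(ps, box, spacing = 0.5, smoothing_width = 0.3)
  expect_lt(max(abs(ms$vertices[, 3] - sin(2 * pi * ms$vertices[, 2] / 10))), 0.5)

  # paper-scale configuration: 0.4 nm spacing, four periodic images, 40k nodes
  box40 <- box_spec(40, 40)
  pw <- sample_surface_points(surface_wave(5, box40), 40000, jitter_nm = 0.1,
                              seed = 2)
  mw <- build_heightfield_mesh(pw, box40, spacing = 0.4, images = c(2L, 2L))
  expect_equal(nrow(mw$vertices), 40000)

  # a region with no support must be reported, not silently meshed
  phalf <- ps[ps[, 2] < 5, ]
  expect_error(build_heightfield_mesh(phalf, box, spacing = 0.5,
                                      smoothing_width = 0.3),
               "no points within")
  mpart <- build_heightfield_mesh(phalf, box, spacing = 0.5,
                                  smoothing_width = 0.3, allow_partial = TRUE,
                                  periodic = FALSE)
  expect_lt(nrow(mpart$vertices), 400)
})

test_that("periodic tiling replicates points and preserves minimum-image geometry", {
  box <- box_spec(7, 9)
  p1 <- matrix(c(1, 2, 3), 1)
  t4 <- tile_periodic(p1, box, c(2L, 2L))
  expect_equal(nrow(t4), 4)
  expect_setequal(t4[, 1], c(1, 8))
  expect_setequal(t4[, 2], c(2, 11))

  p3 <- matrix(runif(9), 3)
  expect_equal(tile_periodic(p3, box, c(1L, 1L)), p3)

  set.seed(3)
  pts <- cbind(runif(100, 0, 7), runif(100, 0, 9), runif(100))
  tiled <- tile_periodic(pts, box, c(2L, 2L))
  expect_equal(nrow(tiled), 400)
  # minimum-image distance between base points equals the minimum over all
  # image copies in the tiled set
  minimg <- function(a, b) {
    d <- a - b
    d[1] <- d[1] - 7 * round(d[1] / 7)
    d[2] <- d[2] - 9 * round(d[2] / 9)
    sqrt(sum(d^2))
  }
  for (k in 1:20) {
    i <- sample(100, 1); j <- sample(100, 1)
    copies_j <- tiled[seq(j, 400, by = 100), , drop = FALSE]
    shifts <- expand.grid(sx = c(-14, -7, 0, 7, 14), sy = c(-18, -9, 0, 9, 18))
    best <- Inf
    for (s in seq_len(nrow(shifts))) {
      cj <- sweep(copies_j, 2, c(shifts$sx[s], shifts$sy[s], 0), "+")
      best <- min(best, sqrt(rowSums(sweep(cj, 2, pts[i, ])^2)))
    }
    expect_equal(best, minimg(pts[i, ], pts[j, ]), tolerance = 1e-12)
  }
})

test_that("vertex normals follow orientation and match analytic directions", {
  m <- grid_mesh(10, 10, 10, 10)
  nrm <- vertex_normals(m)
  expect_true(all(abs(nrm[, 3] - 1) < 1e-12))

  ico <- icosphere(3, 1)
  ni <- vertex_normals(ico)
  radial <- ico$vertices / sqrt(rowSums(ico$vertices^2))
  ang <- acos(pmin(1, rowSums(ni * radial))) * 180 / pi
  expect_lt(max(ang), 2)

  flipped <- triangle_mesh(ico$vertices, ico$faces[, c(1, 3, 2)])
  expect_equal(vertex_normals(flipped), -ni, tolerance = 1e-12)

  # isolated vertices have no normal
  bad <- triangle_mesh(rbind(unit_square_mesh()$vertices, c(5, 5, 5)),
                       unit_square_mesh()$faces)
  expect_error(vertex_normals(bad), "isolated")
})

test_that("discrete curvature matches plane, cylinder and sphere analytics", {
  m <- grid_mesh(10, 10, 20, 20)
  H <- mean_curvature(m)
  K <- gaussian_curvature(m)
  inner <- !is.na(H)
  expect_true(any(inner))
  expect_lt(max(abs(H[inner])), 1e-6)
  expect_lt(max(abs(K[inner])), 1e-3)

  cyl <- cylinder_mesh(2, 30, n_circ = 64, n_axial = 60)
  Hc <- mean_curvature(cyl)
  expect_lt(abs(median(Hc, na.rm = TRUE) / 0.25 - 1), 0.05)
  expect_lt(median(abs(gaussian_curvature(cyl)), na.rm = TRUE), 1e-3)

  ico <- icosphere(4, 10)
  expect_lt(abs(median(mean_curvature(ico)) / 0.1 - 1), 0.05)
  ico1 <- icosphere(4, 1)
  expect_lt(abs(median(gaussian_curvature(ico1)) - 1), 0.1)
})

test_that("Gauss-Bonnet holds and curvature converges under refinement", {
  ico <- icosphere(4, 1)
  total <- sum(gaussian_curvature(ico) * vertex_areas(ico))
  expect_lt(abs(total / (4 * pi) - 1), 0.01)

  errH <- errK <- numeric(3)
  for (s in 2:4) {
    ic <- icosphere(s, 1)
    errH[s - 1] <- median(abs(mean_curvature(ic) - 1))
    errK[s - 1] <- median(abs(gaussian_curvature(ic) - 1))
  }
  expect_true(all(diff(errH) < 0))
  expect_true(all(diff(errK) < 0))
})

test_that("curvature fields are invariant to the tiling used", {
  box <- box_spec(12, 12)
  pts <- sample_surface_points(surface_wave(2, box), 30000, jitter_nm = 0,
                               seed = 9)
  m2 <- build_heightfield_mesh(pts, box, spacing = 0.6, images = c(2L, 2L))
  m3 <- build_heightfield_mesh(pts, box, spacing = 0.6, images = c(3L, 3L))
  key <- function(m) {
    ctr <- central_image_vertices(m)
    v <- m$vertices[ctr, ]
    ord <- order(round(v[, 1] %% 12, 6), round(v[, 2] %% 12, 6))
    list(ord = which(ctr)[ord], n = sum(ctr))
  }
  k2 <- key(m2); k3 <- key(m3)
  expect_equal(k2$n, k3$n)
  H2 <- mean_curvature(m2)[k2$ord]
  H3 <- mean_curvature(m3)[k3$ord]
  expect_lt(max(abs(H2 - H3)), 1e-6)
  K2 <- gaussian_curvature(m2)[k2$ord]
  K3 <- gaussian_curvature(m3)[k3$ord]
  expect_lt(max(abs(K2 - K3)), 1e-6)
})

test_that("nearest-vertex snapping is exact against exhaustive search", {
  m <- bumpy_mesh(box_L = 8, spacing = 0.5, n_pts = 2000, seed = 4)
  V <- m$vertices
  # a query exactly on a vertex returns that vertex
  expect_equal(nearest_vertex(m, V[7, ]), 7L)
  # triangle centroid maps to its brute-force nearest corner
  f1 <- m$faces[1, ]
  cen <- colMeans(V[f1, ])
  brute <- which.min(colSums((t(V) - cen)^2))
  expect_equal(nearest_vertex(m, cen), brute)
  # 1000 random queries agree exactly with exhaustive search
  set.seed(5)
  Q <- cbind(runif(1000, -1, 9), runif(1000, -1, 9), runif(1000, -2, 2))
  got <- nearest_vertex(m, Q)
  for (i in seq_len(nrow(Q))) {
    d2 <- colSums((t(V) - Q[i, ])^2)
    expect_equal(got[i], which.min(d2))
  }
})

test_that("nearest-vertex honors the lateral minimum-image convention", {
  box <- box_spec(10, 10)
  set.seed(6)
  pts <- cbind(runif(400, 0, 10), runif(400, 0, 10), 0)
  m <- build_heightfield_mesh(pts, box, spacing = 1)
  # slightly outside the box edge: the wrapped image is closer
  q <- c(10.05, 5.0, 0)
  got <- nearest_vertex(m, q, box = box)
  V <- m$vertices
  shifts <- expand.grid(sx = c(-10, 0, 10), sy = c(-10, 0, 10))
  d2 <- rep(Inf, nrow(V))
  for (s in seq_len(nrow(shifts)))
    d2 <- pmin(d2, colSums((t(V) + c(shifts$sx[s], shifts$sy[s], 0) - q)^2))
  expect_equal(got, which.min(d2))
  expect_equal(unname(V[got, 1]), 0)  # snapped across the boundary
})

test_that("surface and projected areas match geometry", {
  flat <- grid_mesh(10, 10, 10, 10)
  a <- surface_and_projected_area(flat)
  expect_equal(unname(a), c(100, 100), tolerance = 1e-12)

  # tilt by 60 degrees about x: projected area halves
  th <- pi / 3
  Vt <- flat$vertices %*% t(rbind(c(1, 0, 0), c(0, cos(th), -sin(th)),
                                  c(0, sin(th), cos(th))))
  tilted <- triangle_mesh(Vt, flat$faces)
  at <- surface_and_projected_area(tilted)
  expect_equal(at[["A_proj"]] / at[["A_surf"]], 0.5, tolerance = 1e-12)
  expect_true(at[["A_proj"]] <= at[["A_surf"]])

  # wave sheet: area ratio matches 1-D arc-length quadrature
  wm <- grid_mesh(40, 40, 100, 100, z = function(x, y) 5 * sin(2 * pi * y / 40))
  aw <- surface_and_projected_area(wm)
  arc <- integrate(function(y) sqrt(1 + (5 * 2 * pi / 40 * cos(2 * pi * y / 40))^2),
                   0, 40)$value / 40
  expect_equal(aw[["A_surf"]] / aw[["A_proj"]], arc, tolerance = 0.01)
})

test_that("invalid meshes are rejected at construction", {
  V <- unit_square_mesh()$vertices
  # flipping one face breaks orientation consistency on the shared edge
  expect_error(triangle_mesh(V, rbind(c(1, 2, 3), c(1, 4, 3))),
               "non-manifold|oriented")
  # a repeated vertex in a face is degenerate
  expect_error(triangle_mesh(V, rbind(c(1, 2, 2))), "degenerate")
  # three faces sharing one edge are non-manifold
  V5 <- rbind(V, c(0.5, 0.5, 1))
  expect_error(triangle_mesh(V5, rbind(c(1, 2, 3), c(1, 3, 4), c(1, 2, 5), c(2, 1, 5))),
               "non-manifold|oriented")
})
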