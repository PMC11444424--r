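#' Icosphere mesh
#'
#' Recursively subdivided icosahedron projected onto the sphere, with
#' outward-oriented faces. Subdivision level s gives `10 * 4^s + 2` vertices
#' (2562 at level 4).
#'
#' @param subdivisions number of 4-to-1 face subdivisions.
#' @param R sphere radius (nm).
#' @param center sphere center.
#' @return a closed `triangle_mesh`.
#' @export
icosphere <- function(subdivisions = 3, R = 1, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    ekey <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    ukey <- unique(ekey)
    mididx <- match(ekey, ukey) + nrow(v)
    ue <- edges[!duplicated(ekey), , drop = FALSE]
    mid <- (v[ue[, 1], ] + v[ue[, 2], ]) / 2
    mid <- mid / sqrt(rowSums(mid^2))
    v <- rbind(v, mid)
    nf <- nrow(f)
    m12 <- mididx[1:nf]; m23 <- mididx[nf + 1:nf]; m31 <- mididx[2 * nf + 1:nf]
    f <- rbind(cbind(f[, 1], m12, m31), cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23), cbind(m12, m23, m31))
  }
  # enforce outward winding
  cent <- (v[f[, 1], ] + v[f[, 2], ] + v[f[, 3], ]) / 3
  e1 <- v[f[, 2], ] - v[f[, 1], ]
  e2 <- v[f[, 3], ] - v[f[, 1], ]
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  flip <- rowSums(nrm * cent) < 0
  f[flip, ] <- f[flip, c(1, 3, 2)]
  verts <- sweep(v * R, 2, center, "+")
  triangle_mesh(verts, f, provenance = sprintf("icosphere_s%d_R%g", subdivisions, R))
}

#' Open cylinder tube mesh
#'
#' Cylinder of radius `R` with axis along y, closed around the circumference
#' and open (boundary) at the two ends, outward-oriented.
#'
#' @param R radius (nm).
#' @param height axial length (nm).
#' @param n_circ,n_axial circumferential / axial resolution.
#' @return a `triangle_mesh`.
#' @export
cylinder_mesh <- function(R, height, n_circ = 64, n_axial = 64) {
  phi <- 2 * pi * (0:(n_circ - 1)) / n_circ
  yy <- height * (0:n_axial) / n_axial
  g <- expand.grid(i = seq_len(n_circ), j = seq_len(n_axial + 1))
  verts <- cbind(R * cos(phi[g$i]), yy[g$j], R * sin(phi[g$i]))
  vid <- function(i, j) (j - 1L) * n_circ + ((i - 1L) %% n_circ) + 1L
  cells <- expand.grid(i = seq_len(n_circ), j = seq_len(n_axial))
  a <- vid(cells$i, cells$j); b <- vid(cells$i + 1L, cells$j)
  cc <- vid(cells$i + 1L, cells$j + 1L); d <- vid(cells$i, cells$j + 1L)
  f <- rbind(cbind(a, b, cc), cbind(a, cc, d))
  m <- triangle_mesh(verts, f, provenance = sprintf("cylinder_R%g", R))
  # flip if winding is inward
  nrm <- vertex_normals(m)
  radial <- cbind(m$vertices[, 1], 0, m$vertices[, 3])
  radial <- radial / sqrt(rowSums(radial^2))
  if (mean(rowSums(nrm * radial)) < 0) {
    f <- f[, c(1, 3, 2)]
    m <- triangle_mesh(verts, f, provenance = m$provenance)
  }
  m
}

#' Sphere mesh from jittered surface samples
#'
#' Radial analog of the height-field gridder for closed spherical surfaces:
#' an icosphere template provides the directions, and each template vertex
#' radius is the Gaussian-kernel (in angle) weighted mean of the sample
#' radii. Used to test curvature recovery from noisy leaflet-like point
#' clouds.
#'
#' @param points n x 3 samples of a roughly spherical surface.
#' @param center sphere center.
#' @param subdivisions icosphere template resolution.
#' @param bandwidth angular kernel bandwidth in radians.
#' @return a closed `triangle_mesh`.
#' @export
build_sphere_mesh_from_points <- function(points, center = c(0, 0, 0),
                                          subdivisions = 4, bandwidth = 0.1) {
  points <- as.matrix(points)
  p <- sweep(points, 2, center)
  r <- sqrt(rowSums(p^2))
  dirs <- p / r
  tmpl <- icosphere(subdivisions, 1)
  tv <- tmpl$vertices
  rad <- numeric(nrow(tv))
  chunk <- 512L
  for (k in seq(1, nrow(tv), by = chunk)) {
    idx <- k:min(k + chunk - 1L, nrow(tv))
    cosang <- tv[idx, , drop = FALSE] %*% t(dirs)
    cosang[cosang > 1] <- 1
    cosang[cosang < -1] <- -1
    theta <- acos(cosang)
    w <- exp(-theta^2 / (2 * bandwidth^2))
    rad[idx] <- (w %*% r) / rowSums(w)
  }
  triangle_mesh(sweep(tv * rad, 2, center, "+"), tmpl$faces,
                provenance = "sphere_from_points")
}

#' Cylinder mesh from jittered surface samples
#'
#' Radial chart around the y axis: the surface is gridded in (angle, y) and
#' the radius at each node is a Gaussian-kernel weighted mean of sample
#' radii, with the kernel metric measured along the unrolled surface.
#'
#' @param points n x 3 samples of a roughly cylindrical surface (axis y).
#' @param spacing target grid spacing in nm.
#' @param smoothing kernel bandwidth in nm (default `spacing`).
#' @return a `triangle_mesh`, circumferentially closed, open at the ends.
#' @export
build_cylinder_mesh_from_points <- function(points, spacing,
                                            smoothing = spacing) {
  points <- as.matrix(points)
  r <- sqrt(points[, 1]^2 + points[, 3]^2)
  phi <- atan2(points[, 3], points[, 1])
  y <- points[, 2]
  Rhat <- mean(r)
  nphi <- max(8L, as.integer(round(2 * pi * Rhat / spacing)))
  ylo <- min(y); yhi <- max(y)
  nyy <- max(2L, as.integer(round((yhi - ylo) / spacing)))
  gphi <- 2 * pi * (0:(nphi - 1)) / nphi
  gy <- seq(ylo, yhi, length.out = nyy + 1)
  rad <- matrix(0, nphi, nyy + 1)
  for (j in seq_len(nyy + 1)) {
    dy <- y - gy[j]
    near <- abs(dy) < 3 * smoothing
    if (!any(near)) stop(sprintf("no samples near axial position y = %.3g", gy[j]))
    dphi <- outer(gphi, phi[near], "-")
    dphi <- dphi - 2 * pi * round(dphi / (2 * pi))
    d2 <- (Rhat * dphi)^2 + matrix(dy[near]^2, nphi, sum(near), byrow = TRUE)
    w <- exp(-d2 / (2 * smoothing^2))
    rad[, j] <- (w %*% r[near]) / rowSums(w)
  }
  g <- expand.grid(i = seq_len(nphi), j = seq_len(nyy + 1))
  verts <- cbind(rad[cbind(g$i, g$j)] * cos(gphi[g$i]), gy[g$j],
                 rad[cbind(g$i, g$j)] * sin(gphi[g$i]))
  vid <- function(i, j) (j - 1L) * nphi + ((i - 1L) %% nphi) + 1L
  cells <- expand.grid(i = seq_len(nphi), j = seq_len(nyy))
  a <- vid(cells$i, cells$j); b <- vid(cells$i + 1L, cells$j)
  cc <- vid(cells$i + 1L, cells$j + 1L); d <- vid(cells$i, cells$j + 1L)
  f <- rbind(cbind(a, b, cc), cbind(a, cc, d))
  m <- triangle_mesh(verts, f, provenance = "cylinder_from_points")
  nrm <- vertex_normals(m)
  radial <- cbind(m$vertices[, 1], 0, m$vertices[, 3])
  radial <- radial / pmax(1e-12, sqrt(rowSums(radial^2)))
  if (mean(rowSums(nrm * radial)) < 0)
    m <- triangle_mesh(verts, f[, c(1, 3, 2)], provenance = m$provenance)
  m
}
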