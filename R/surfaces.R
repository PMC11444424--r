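#' Analytic reference surfaces
#'
#' Parametric surfaces with closed-form normals, curvatures and (where they
#' exist) geodesics, used as ground truth for meshing, curvature and geodesic
#' tests and as substrates for surface-constrained Brownian simulation.
#'
#' Kinds:
#' * `surface_plane(z0, box)` - flat plane `z = z0` over a periodic box.
#' * `surface_sphere(R)` - sphere of radius `R` centered at the origin.
#' * `surface_cylinder(R, height)` - cylinder of radius `R` with axis along
#'   y, `y` in `[0, height]`.
#' * `surface_wave(A, box, z0)` - periodic sinusoid `z = z0 + A sin(2 pi y / Ly)`
#'   (developable: `K = 0` everywhere).
#' * `surface_bud(height, width, box, z0)` - Gaussian bump
#'   `z = z0 + height * exp(-r^2 / (2 width^2))` centered in the box
#'   (`K > 0` at the cap, `K < 0` on the flank).
#'
#' @param z0 base height in nm.
#' @param box a [box_spec()] (periodic surfaces only).
#' @param R radius in nm.
#' @param height bud height / cylinder length in nm.
#' @param A wave amplitude in nm; the wavelength is the box length `Ly`.
#' @param width bud Gaussian width in nm.
#' @return an object of class `parametric_surface`.
#' @name parametric_surface
NULL

new_surface <- function(kind, ...) {
  structure(list(kind = kind, ...), class = "parametric_surface")
}

#' @rdname parametric_surface
#' @export
surface_plane <- function(z0 = 0, box) new_surface("plane", z0 = z0, box = box)

#' @rdname parametric_surface
#' @export
surface_sphere <- function(R) new_surface("sphere", R = R)

#' @rdname parametric_surface
#' @export
surface_cylinder <- function(R, height) new_surface("cylinder", R = R, height = height)

#' @rdname parametric_surface
#' @export
surface_wave <- function(A, box, z0 = 0) new_surface("wave", A = A, box = box, z0 = z0)

#' @rdname parametric_surface
#' @export
surface_bud <- function(height, width, box, z0 = 0)
  new_surface("bud", h = height, sigma = width, box = box, z0 = z0)

is_heightfield <- function(s) s$kind %in% c("plane", "wave", "bud")

wrap_into <- function(x, L) x - L * floor(x / L)

# Height field value and derivatives at (possibly unwrapped) lateral
# coordinates; periodic surfaces are evaluated on wrapped coordinates.
hf_eval <- function(s, x, y) {
  if (!is.null(s$box)) {
    x <- wrap_into(x, s$box$Lx)
    y <- wrap_into(y, s$box$Ly)
  }
  zero <- rep(0, length(x))
  switch(s$kind,
    plane = list(z = s$z0 + zero, fx = zero, fy = zero,
                 fxx = zero, fxy = zero, fyy = zero),
    wave = {
      k <- 2 * pi / s$box$Ly
      list(z = s$z0 + s$A * sin(k * y), fx = zero,
           fy = s$A * k * cos(k * y), fxx = zero, fxy = zero,
           fyy = -s$A * k^2 * sin(k * y))
    },
    bud = {
      cx <- s$box$Lx / 2; cy <- s$box$Ly / 2
      dx <- x - cx; dy <- y - cy
      s2 <- s$sigma^2
      g <- s$h * exp(-(dx^2 + dy^2) / (2 * s2))
      list(z = s$z0 + g, fx = -dx / s2 * g, fy = -dy / s2 * g,
           fxx = (dx^2 / s2 - 1) * g / s2, fxy = dx * dy / s2^2 * g,
           fyy = (dy^2 / s2 - 1) * g / s2)
    },
    stop("not a height-field surface"))
}

#' Closed-form surface curvature
#'
#' Mean and Gaussian curvature from the first and second fundamental forms of
#' the parametrization. The sign convention matches the discrete estimators:
#' a sphere with outward normals has `H = +1/R`, a height-field crest with
#' upward normal has `H > 0`; `K` is orientation-independent.
#'
#' @param surface a [parametric_surface].
#' @param points n x 3 matrix of surface points (only x, y are used for
#'   height fields; ignored for sphere/cylinder, which are homogeneous).
#' @return list with numeric vectors `H` (1/nm) and `K` (1/nm^2).
#' @export
analytic_curvature <- function(surface, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  n <- nrow(points)
  switch(surface$kind,
    sphere = list(H = rep(1 / surface$R, n), K = rep(1 / surface$R^2, n)),
    cylinder = list(H = rep(1 / (2 * surface$R), n), K = rep(0, n)),
    {
      e <- hf_eval(surface, points[, 1], points[, 2])
      w2 <- 1 + e$fx^2 + e$fy^2
      H <- -((1 + e$fy^2) * e$fxx - 2 * e$fx * e$fy * e$fxy +
               (1 + e$fx^2) * e$fyy) / (2 * w2^1.5)
      K <- (e$fxx * e$fyy - e$fxy^2) / w2^2
      list(H = H, K = K)
    })
}

#' Closed-form surface normal (unit, outward/upward)
#' @param surface a [parametric_surface].
#' @param points n x 3 matrix of surface points.
#' @return n x 3 matrix of unit normals.
#' @export
analytic_normal <- function(surface, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  switch(surface$kind,
    sphere = points / sqrt(rowSums(points^2)),
    cylinder = {
      r <- sqrt(points[, 1]^2 + points[, 3]^2)
      cbind(points[, 1] / r, 0, points[, 3] / r)
    },
    {
      e <- hf_eval(surface, points[, 1], points[, 2])
      w <- sqrt(1 + e$fx^2 + e$fy^2)
      cbind(-e$fx / w, -e$fy / w, 1 / w)
    })
}

#' Closed-form geodesic distance on plane, sphere or cylinder
#'
#' Plane: Euclidean. Sphere: great-circle arc `R * acos(p.q / R^2)`.
#' Cylinder: `sqrt((R * dphi)^2 + dy^2)` with the angle wrapped to
#' `[-pi, pi]`. Wave and bud surfaces have no closed form; use a refined mesh
#' and the exact polyhedral engine instead.
#'
#' @param surface a [parametric_surface].
#' @param p,q length-3 surface points or n x 3 matrices.
#' @return numeric vector of distances (nm).
#' @export
analytic_geodesic <- function(surface, p, q) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3)
  if (is.null(dim(q))) q <- matrix(q, ncol = 3)
  switch(surface$kind,
    plane = sqrt(rowSums((p - q)^2)),
    sphere = {
      cosang <- rowSums(p * q) / surface$R^2
      surface$R * acos(pmin(1, pmax(-1, cosang)))
    },
    cylinder = {
      dphi <- atan2(p[, 3], p[, 1]) - atan2(q[, 3], q[, 1])
      dphi <- dphi - 2 * pi * round(dphi / (2 * pi))
      sqrt((surface$R * dphi)^2 + (p[, 2] - q[, 2])^2)
    },
    stop(sprintf("no closed-form geodesic on a '%s' surface; use a refined mesh",
                 surface$kind)))
}

# Maximum absolute principal curvature, for the Brownian step-size condition.
max_principal_curvature <- function(surface) {
  switch(surface$kind,
    plane = 0,
    sphere = 1 / surface$R,
    cylinder = 1 / surface$R,
    {
      g <- expand.grid(x = seq(0, surface$box$Lx, length.out = 101),
                       y = seq(0, surface$box$Ly, length.out = 101))
      cv <- analytic_curvature(surface, cbind(g$x, g$y, 0))
      disc <- pmax(cv$H^2 - cv$K, 0)
      max(abs(cv$H) + sqrt(disc))
    })
}

#' Area-uniform surface samples with normal jitter
#'
#' Draws `n` points uniformly by surface area and displaces each along the
#' local normal by `N(0, jitter_nm^2)` noise, mimicking the vertical spread
#' of a molecular leaflet around its midsurface.
#'
#' @param surface a [parametric_surface].
#' @param n number of points.
#' @param jitter_nm Gaussian jitter width along the normal (nm).
#' @param seed optional integer for reproducibility (the caller's RNG stream
#'   is untouched).
#' @return n x 3 matrix of positions.
#' @export
sample_surface_points <- function(surface, n, jitter_nm = 0, seed = NULL) {
  stopifnot(n > 0)
  with_seed(seed, {
    pts <- switch(surface$kind,
      sphere = {
        d <- matrix(rnorm(3 * n), ncol = 3)
        d <- d / sqrt(rowSums(d^2))
        surface$R * d
      },
      cylinder = {
        phi <- runif(n, 0, 2 * pi)
        y <- runif(n, 0, surface$height)
        cbind(surface$R * cos(phi), y, surface$R * sin(phi))
      },
      {
        # height field: rejection sampling against the area element
        box <- surface$box
        grd <- expand.grid(x = seq(0, box$Lx, length.out = 201),
                           y = seq(0, box$Ly, length.out = 201))
        eg <- hf_eval(surface, grd$x, grd$y)
        wmax <- max(sqrt(1 + eg$fx^2 + eg$fy^2)) * 1.0001
        out <- matrix(0, 0, 3)
        while (nrow(out) < n) {
          m <- ceiling((n - nrow(out)) * wmax * 1.2) + 10
          x <- runif(m, 0, box$Lx); y <- runif(m, 0, box$Ly)
          e <- hf_eval(surface, x, y)
          w <- sqrt(1 + e$fx^2 + e$fy^2)
          keep <- runif(m) < w / wmax
          out <- rbind(out, cbind(x, y, e$z)[keep, , drop = FALSE])
        }
        out[seq_len(n), , drop = FALSE]
      })
    if (jitter_nm > 0) {
      nrm <- analytic_normal(surface, pts)
      pts <- pts + nrm * rnorm(n, sd = jitter_nm)
    }
    dimnames(pts) <- NULL
    pts
  })
}

#' Surface-constrained Brownian trajectories
#'
#' Simulates `n_particles` independent Brownian walkers with lateral
#' diffusion coefficient `D0` on a static surface: each step draws an
#' isotropic tangent-plane displacement with per-axis variance `2 D0 dt` and
#' re-projects the moved point back to the surface along its normal
#' (radially for sphere/cylinder, Newton iteration for height fields).
#' Lateral coordinates are returned unwrapped; periodic surfaces are
#' evaluated on wrapped coordinates.
#'
#' The step length must satisfy `sqrt(4 D0 dt) < 0.2 / max |principal
#' curvature|`; larger steps make the tangent-step + re-projection scheme
#' inaccurate and raise an error.
#'
#' @param surface a [parametric_surface].
#' @param D0 diffusion coefficient in nm^2/ns (1 nm^2/ns = 1e-5 cm^2/s).
#' @param n_particles,n_frames trajectory dimensions.
#' @param dt frame spacing in ns.
#' @param seed optional integer seed.
#' @return a `particle_trajectory`: list with `x`, `y`, `z`
#'   (`n_frames x n_particles` matrices, nm), `dt` (ns), `box`, and the
#'   generating `surface`.
#' @export
simulate_surface_brownian <- function(surface, D0, n_particles, n_frames, dt,
                                      seed = NULL) {
  stopifnot(D0 >= 0, n_particles >= 1, n_frames >= 2, dt > 0)
  kmax <- max_principal_curvature(surface)
  if (kmax > 0 && sqrt(4 * D0 * dt) >= 0.2 / kmax)
    stop(sprintf(paste0(
      "step length sqrt(4 D0 dt) = %.3g nm violates the accuracy condition ",
      "(< 0.2 x minimal curvature radius = %.3g nm); reduce dt"),
      sqrt(4 * D0 * dt), 0.2 / kmax))
  with_seed(seed, {
    sdstep <- sqrt(2 * D0 * dt)
    np <- n_particles; nt <- n_frames
    X <- matrix(0, nt, np); Y <- matrix(0, nt, np); Z <- matrix(0, nt, np)
    start <- sample_surface_points(surface, np)
    if (surface$kind == "plane") {
      # identity projection: integrate the tangent steps directly
      X <- apply(rbind(start[, 1], matrix(rnorm((nt - 1) * np, sd = sdstep), nt - 1, np)), 2, cumsum)
      Y <- apply(rbind(start[, 2], matrix(rnorm((nt - 1) * np, sd = sdstep), nt - 1, np)), 2, cumsum)
      Z[] <- surface$z0
    } else if (surface$kind == "sphere") {
      P <- start
      R <- surface$R
      for (t in seq_len(nt)) {
        X[t, ] <- P[, 1]; Y[t, ] <- P[, 2]; Z[t, ] <- P[, 3]
        if (t == nt) break
        nrm <- P / R
        pole <- abs(nrm[, 3]) > 0.9
        ax <- cbind(as.numeric(pole), 0, as.numeric(!pole))
        e1 <- cbind(nrm[, 2] * ax[, 3] - nrm[, 3] * ax[, 2],
                    nrm[, 3] * ax[, 1] - nrm[, 1] * ax[, 3],
                    nrm[, 1] * ax[, 2] - nrm[, 2] * ax[, 1])
        e1 <- e1 / sqrt(rowSums(e1^2))
        e2 <- cbind(nrm[, 2] * e1[, 3] - nrm[, 3] * e1[, 2],
                    nrm[, 3] * e1[, 1] - nrm[, 1] * e1[, 3],
                    nrm[, 1] * e1[, 2] - nrm[, 2] * e1[, 1])
        s1 <- rnorm(np, sd = sdstep); s2 <- rnorm(np, sd = sdstep)
        P <- P + e1 * s1 + e2 * s2
        P <- P * (R / sqrt(rowSums(P^2)))
      }
    } else if (surface$kind == "cylinder") {
      P <- start
      R <- surface$R
      for (t in seq_len(nt)) {
        X[t, ] <- P[, 1]; Y[t, ] <- P[, 2]; Z[t, ] <- P[, 3]
        if (t == nt) break
        r <- sqrt(P[, 1]^2 + P[, 3]^2)
        nx <- P[, 1] / r; nz <- P[, 3] / r
        s1 <- rnorm(np, sd = sdstep)  # axial
        s2 <- rnorm(np, sd = sdstep)  # circumferential, e2 = (-nz, 0, nx)
        P[, 1] <- P[, 1] - nz * s2
        P[, 2] <- P[, 2] + s1
        P[, 3] <- P[, 3] + nx * s2
        r <- sqrt(P[, 1]^2 + P[, 3]^2)
        P[, 1] <- P[, 1] * R / r
        P[, 3] <- P[, 3] * R / r
      }
    } else {
      # height field: tangent step then re-projection along the local normal
      ux <- start[, 1]; uy <- start[, 2]
      for (t in seq_len(nt)) {
        e <- hf_eval(surface, ux, uy)
        X[t, ] <- ux; Y[t, ] <- uy; Z[t, ] <- e$z
        if (t == nt) break
        w1 <- sqrt(1 + e$fx^2)
        # orthonormal tangent frame from r_x = (1, 0, fx), r_y = (0, 1, fy)
        e1x <- 1 / w1; e1z <- e$fx / w1
        ryd <- e$fy * e1z  # r_y . e1
        t2x <- -ryd * e1x; t2y <- 1; t2z <- e$fy - ryd * e1z
        w2 <- sqrt(t2x^2 + t2y^2 + t2z^2)
        s1 <- rnorm(np, sd = sdstep); s2 <- rnorm(np, sd = sdstep)
        qx <- ux + s1 * e1x + s2 * t2x / w2
        qy <- uy + s2 * t2y / w2
        qz <- e$z + s1 * e1z + s2 * t2z / w2
        wn <- sqrt(1 + e$fx^2 + e$fy^2)
        nx <- -e$fx / wn; ny <- -e$fy / wn; nz <- 1 / wn
        ti <- rep(0, np)
        for (it in 1:3) {
          eq <- hf_eval(surface, qx + ti * nx, qy + ti * ny)
          Fv <- qz + ti * nz - eq$z
          dF <- nz - eq$fx * nx - eq$fy * ny
          ti <- ti - Fv / dF
        }
        ux <- qx + ti * nx
        uy <- qy + ti * ny
      }
    }
    structure(list(x = X, y = Y, z = Z, dt = dt,
                   box = surface$box, surface = surface,
                   leaflet = NULL),
              class = "particle_trajectory")
  })
}

#' @export
print.particle_trajectory <- function(x, ...) {
  cat(sprintf("particle_trajectory: %d particles x %d frames, dt = %g ns\n",
              ncol(x$x), nrow(x$x), x$dt))
  invisible(x)
}
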