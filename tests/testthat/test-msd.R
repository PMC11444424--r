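test_that("gMSD accumulation credits both endpoints (self-records twice)", {
  m <- unit_square_mesh()
  mk <- function(lo, hi, li) structure(
    list(v_lo = lo, v_hi = hi, lag_index = li, lags_ns = c(2, 5), sorted = TRUE),
    class = "displacement_records")
  msd <- accumulate_gmsd(mk(3L, 4L, 1L), 2, m)
  g <- gmsd_mean(msd, 2)
  expect_equal(as.numeric(g[3:4]), c(4, 4))
  expect_true(all(is.na(g[1:2])))

  # two displacements at one vertex average their squares: (1 + 9) / 2
  msd2 <- accumulate_gmsd(mk(c(1L, 1L), c(3L, 4L), c(1L, 1L)), c(1, 3), m)
  expect_equal(as.numeric(gmsd_mean(msd2, 2)[1]), 5)

  # a self-record contributes twice to its vertex
  msd3 <- accumulate_gmsd(mk(2L, 2L, 2L), 1.5, m)
  expect_equal(msd3$counts[2, 2], 2)
  expect_equal(as.numeric(gmsd_mean(msd3, 5)[2]), 2.25)
})

test_that("diffusion map is gMSD / (4 lag) with unit bookkeeping", {
  m <- unit_square_mesh()
  rec <- structure(list(v_lo = 1L, v_hi = 2L, lag_index = 1L,
                        lags_ns = 53, sorted = TRUE),
                   class = "displacement_records")
  msd <- accumulate_gmsd(rec, sqrt(12.72), m)
  D <- diffusion_map(msd, 53)
  expect_equal(as.numeric(D[1]), 0.06, tolerance = 1e-12)
  expect_equal(as.numeric(D[1]) * 1e-5, 6e-7, tolerance = 1e-12)  # cm^2/s
  expect_error(diffusion_map(msd, 10), "available")
})

test_that("curvature classification is deterministic and sign-driven", {
  H0 <- vertex_field(rep(0, 10)); K0 <- vertex_field(rep(0, 10))
  cl <- classify_vertices(H0, K0)
  expect_true(all(cl$H_class == "Flat"))
  expect_true(all(cl$K_class == "Flat"))

  # spherical cap region: positive H and K throughout
  ico <- icosphere(3, 2)
  cap <- ico$vertices[, 3] > 1
  clS <- classify_vertices(mean_curvature(ico), gaussian_curvature(ico),
                           h_flat = 0.05, k_flat = 0.005)
  expect_true(all(clS$H_class[cap] == "H>0"))
  expect_true(all(clS$K_class[cap] == "K>0"))

  # sinusoid symmetry: positive and negative H populations match within 2%
  box <- box_spec(40, 40)
  pw <- sample_surface_points(surface_wave(5, box), 60000, jitter_nm = 0,
                              seed = 20)
  mw <- build_heightfield_mesh(pw, box, spacing = 0.5, images = c(2L, 2L))
  ctr <- central_image_vertices(mw)
  clW <- classify_vertices(mean_curvature(mw), gaussian_curvature(mw),
                           h_flat = 0.01, k_flat = 0.005)
  tab <- table(clW$H_class[ctr])
  expect_lt(abs(tab[["H>0"]] / tab[["H<0"]] - 1), 0.02)
  expect_equal(clW$n_excluded, sum(is.na(mean_curvature(mw))))
})

test_that("Welch comparison reproduces closed-form statistics", {
  lab <- factor(rep(c("a", "b"), each = 3))
  cmp0 <- compare_classes(c(1, 2, 3, 1, 2, 3), lab)
  expect_equal(cmp0$tests$t, 0)
  expect_equal(cmp0$tests$p, 1)

  x <- c(2.1, 2.0, 1.9, 2.2); y <- c(1.0, 1.1, 0.9, 1.2)
  cmp <- compare_classes(c(x, y), factor(rep(c("x", "y"), each = 4)))
  # independent closed-form Welch evaluation
  vx <- var(x); vy <- var(y)
  se2 <- vx / 4 + vy / 4
  t_hand <- (mean(x) - mean(y)) / sqrt(se2)
  df_hand <- se2^2 / ((vx / 4)^2 / 3 + (vy / 4)^2 / 3)
  p_hand <- 2 * pt(-abs(t_hand), df_hand)
  expect_equal(cmp$tests$t, t_hand, tolerance = 1e-10)
  expect_equal(cmp$tests$df, df_hand, tolerance = 1e-10)
  expect_equal(cmp$tests$p, p_hand, tolerance = 1e-10)

  expect_warning(compare_classes(c(1, 2, 3), factor(c("a", "a", "b"))),
                 "fewer than 2")
})

test_that("spatial profiles bin correctly with weights and empty bins", {
  m <- grid_mesh(10, 10, 20, 20)
  const <- vertex_field(rep(3.5, nrow(m$vertices)))
  pf <- profile_field(m, const, bins = 5)
  expect_true(all(abs(pf$mean - 3.5) < 1e-12))

  fy <- vertex_field(m$vertices[, 2])
  pfy <- profile_field(m, fy, mode = "y", bins = 10)
  expect_true(all(abs(pfy$mean - pfy$mid) <= 0.5 + 1e-9))

  expect_error(profile_field(m, const, bins = 0), "positive")

  # a hole in the field flags its bins rather than inventing values
  mb <- m
  mb$box <- box_spec(10, 10)
  holey <- vertex_field(ifelse(m$vertices[, 2] < 5, NA, 1))
  ph <- profile_field(mb, holey, bins = 10)
  expect_true(any(ph$n == 0))
  expect_true(all(is.na(ph$mean[ph$n == 0])))

  # radial mode on a centered field
  r <- sqrt((m$vertices[, 1] - 5)^2 + (m$vertices[, 2] - 5)^2)
  pr <- profile_field(m, vertex_field(r), mode = "radial", bins = 6,
                      center = c(5, 5))
  expect_true(all(abs(pr$mean - pr$mid)[pr$n > 3] < 1.2))
})

test_that("projected MSD discards normal motion and respects leaflet modes", {
  # motion purely along z projects to zero
  nt <- 50
  traj <- structure(list(x = matrix(1, nt, 2), y = matrix(2, nt, 2),
                         z = matrix(seq_len(nt), nt, 2), dt = 1, box = NULL,
                         leaflet = c("up", "down")),
                    class = "particle_trajectory")
  pm <- projected_msd(traj, lag_set(5, dt = 1))
  expect_equal(unname(pm$msd), 0)

  # free 2D diffusion reproduces 4 D lag
  box <- box_spec(30, 30)
  tr <- simulate_surface_brownian(surface_plane(0, box), D0 = 0.1,
                                  n_particles = 400, n_frames = 2000,
                                  dt = 0.1, seed = 21)
  pm2 <- projected_msd(tr, lag_set(c(5, 20), dt = 0.1))
  expect_equal(unname(pm2$msd), 4 * 0.1 * c(5, 20), tolerance = 0.03)

  # a 45-degree tilt shrinks the projection below 4 D lag
  u <- tr$x; v <- tr$y
  tilted <- structure(list(x = u, y = v * cos(pi / 4), z = v * sin(pi / 4),
                           dt = 0.1, box = NULL, leaflet = NULL),
                      class = "particle_trajectory")
  pmt <- projected_msd(tilted, lag_set(20, dt = 0.1))
  expect_lt(unname(pmt$msd), 4 * 0.1 * 20 * 0.8)
  expect_gt(unname(pmt$msd), 4 * 0.1 * 20 * 0.7)  # expected factor 0.75

  # leaflet restriction
  tr$leaflet <- rep(c("upper", "lower"), each = 200)
  pml <- projected_msd(tr, lag_set(5, dt = 0.1), leaflet_mode = "upper")
  expect_equal(unname(pml$msd), 4 * 0.1 * 5, tolerance = 0.05)
  expect_error(projected_msd(tilted, lag_set(5, dt = 0.1), leaflet_mode = "upper"),
               "leaflet")
})

test_that("occupancy density conserves counts and detects uniform coverage", {
  box <- box_spec(20, 20)
  tr <- simulate_surface_brownian(surface_plane(0, box), D0 = 0.1,
                                  n_particles = 200, n_frames = 2000,
                                  dt = 0.1, seed = 22)
  mesh <- mesh_from_trajectory(tr, spacing = 1)
  vt <- map_trajectory_to_vertices(tr, mesh)
  occ <- occupancy_density(vt, mesh)
  cnt <- attr(occ, "counts")
  expect_equal(sum(cnt), 200 * 2000)

  # uniform independent sampling of the sheet gives a flat density
  set.seed(23)
  upts <- cbind(runif(4e5, 5, 35), runif(4e5, 5, 35), 0)
  uid <- nearest_vertex(mesh, upts)
  uvt <- fake_vtraj(matrix(uid, ncol = 1))
  uocc <- occupancy_density(uvt, mesh)
  ctr <- central_image_vertices(mesh)
  dens <- as.numeric(uocc)[ctr]
  expect_lt(sd(dens) / mean(dens), 0.10)

  still <- tr
  still$x[] <- 3; still$y[] <- 3; still$z[] <- 0
  vs <- map_trajectory_to_vertices(still, mesh)
  cs <- attr(occupancy_density(vs, mesh), "counts")
  expect_equal(sum(cs > 0), 1)
})

test_that("area-scaling report combines diffusion and area ratios", {
  flat <- grid_mesh(10, 10, 10, 10)
  rep0 <- area_scaling_report(flat, 0.06, 0.06)
  expect_equal(rep0$D_ratio, 1)
  expect_equal(rep0$area_ratio, 1, tolerance = 1e-12)
  expect_equal(rep0$discrepancy, 0, tolerance = 1e-12)

  th <- pi / 3
  Vt <- flat$vertices %*% t(rbind(c(1, 0, 0), c(0, cos(th), -sin(th)),
                                  c(0, sin(th), cos(th))))
  tilted <- triangle_mesh(Vt, flat$faces)
  rept <- area_scaling_report(tilted, 0.06, 0.03)
  expect_equal(rept$area_ratio, 0.5, tolerance = 1e-12)
  expect_equal(rept$D_ratio, 0.5)
})
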