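test_that("lag sets validate spacing, ordering and range", {
  expect_error(lag_set(c(2, 53.05), dt = 0.1), "integer multiple")
  expect_error(lag_set(c(5, 3), dt = 1), "diff")
  expect_error(lag_set(c(2, 500), dt = 0.1, n_frames = 4000), "shorter")
  ls <- lag_set(c(2, 53, 453), dt = 0.1)
  expect_equal(ls$k, c(20L, 530L, 4530L))
})

test_that("records are canonical (lower vertex first) and counted correctly", {
  # 3 particles, 100 frames, one 10-frame lag -> 3 * 90 = 270 records
  frames <- matrix(sample.int(50, 300, replace = TRUE), 100, 3)
  vt <- fake_vtraj(frames)
  lags <- lag_set(10, dt = 1)
  rec <- generate_displacement_records(vt, lags)
  expect_equal(length(rec$v_lo), 270)
  expect_true(all(rec$v_lo <= rec$v_hi))

  # start/end order does not matter: 5 -> 9 and 9 -> 5 give the same triplet
  vt2 <- fake_vtraj(matrix(c(5L, 9L), 2, 1))
  r12 <- generate_displacement_records(vt2, lag_set(1, dt = 1))
  vt3 <- fake_vtraj(matrix(c(9L, 5L), 2, 1))
  r21 <- generate_displacement_records(vt3, lag_set(1, dt = 1))
  expect_equal(r12$v_lo, 5L)
  expect_equal(r12$v_hi, 9L)
  expect_equal(r21$v_lo, r12$v_lo)
  expect_equal(r21$v_hi, r12$v_hi)
})

test_that("sorting produces contiguous source blocks and is idempotent", {
  rec <- structure(list(v_lo = c(9L, 2L, 2L), v_hi = c(9L, 7L, 3L),
                        lag_index = c(1L, 2L, 1L), lags_ns = c(1, 2),
                        sorted = FALSE), class = "displacement_records")
  s <- sort_records(rec)
  expect_equal(s$v_lo, c(2L, 2L, 9L))
  expect_equal(s$v_hi, c(3L, 7L, 9L))
  expect_equal(s$lag_index, c(1L, 2L, 1L))
  expect_identical(sort_records(s)[c("v_lo", "v_hi", "lag_index")],
                   s[c("v_lo", "v_hi", "lag_index")])

  set.seed(13)
  big <- structure(list(v_lo = sample.int(200, 1e5, TRUE),
                        v_hi = sample.int(200, 1e5, TRUE),
                        lag_index = sample.int(3, 1e5, TRUE),
                        lags_ns = c(1, 2, 3), sorted = FALSE),
                   class = "displacement_records")
  lo <- pmin(big$v_lo, big$v_hi); hi <- pmax(big$v_lo, big$v_hi)
  big$v_lo <- lo; big$v_hi <- hi
  sb <- sort_records(big)
  # each distinct lower vertex occupies one contiguous run
  runs <- rle(sb$v_lo)$values
  expect_false(anyDuplicated(runs) > 0)
})

test_that("record files round-trip bit-exactly and report corruption offsets", {
  tmp <- tempfile(fileext = ".curd")
  lags <- c(2, 53, 453)
  rec <- structure(list(v_lo = integer(0), v_hi = integer(0),
                        lag_index = integer(0), lags_ns = lags, sorted = TRUE),
                   class = "displacement_records")
  write_records(tmp, rec)
  expect_equal(file.size(tmp), 4 + 4 + 4 + 8 * 3 + 8)
  expect_equal(length(read_records(tmp)$v_lo), 0)

  set.seed(14)
  rec$v_lo <- sample.int(5000, 1000, TRUE)
  rec$v_hi <- pmax(rec$v_lo, sample.int(5000, 1000, TRUE))
  rec$v_lo <- pmin(rec$v_lo, rec$v_hi)
  rec$lag_index <- sample.int(3, 1000, TRUE)
  write_records(tmp, rec)
  back <- read_records(tmp)
  expect_identical(back$v_lo, rec$v_lo)
  expect_identical(back$v_hi, rec$v_hi)
  expect_identical(back$lag_index, rec$lag_index)
  expect_equal(back$lags_ns, lags)

  # truncate mid-record: the error names the byte offset of the cut
  raw <- readBin(tmp, "raw", file.size(tmp))
  writeBin(raw[1:(length(raw) - 7)], tmp)
  expect_error(read_records(tmp), "byte offset")

  con <- file(tmp, "wb")
  writeBin(c(charToRaw("NOPE"), raw(24)), con)
  close(con)
  expect_error(read_records(tmp), "magic")
})

test_that("blocked evaluation matches naive per-record distances exactly", {
  m <- bumpy_mesh(box_L = 5, spacing = 0.4, n_pts = 1200, seed = 10)
  nv <- nrow(m$vertices)
  set.seed(15)
  n <- 100
  a <- sample.int(nv, n, TRUE); b <- sample.int(nv, n, TRUE)
  rec <- structure(list(v_lo = pmin(a, b), v_hi = pmax(a, b),
                        lag_index = sample.int(2, n, TRUE),
                        lags_ns = c(1, 5), sorted = FALSE),
                   class = "displacement_records")
  expect_error(evaluate_blocks(rec, m), "sorted")
  rec <- sort_records(rec)
  ev <- evaluate_blocks(rec, m)
  expect_equal(ev$n_calls, length(unique(rec$v_lo)))
  naive <- vapply(seq_len(n), function(i)
    geodesic_distances(m, rec$v_lo[i])[rec$v_hi[i]], 0)
  expect_equal(ev$distance, naive, tolerance = 1e-12)
  # worker count never changes the numbers
  ev2 <- evaluate_blocks(rec, m, workers = 3L)
  expect_identical(ev2$distance, ev$distance)
  expect_equal(ev2$n_calls, ev$n_calls)
})

test_that("snapping is bounded and stationary particles map to one vertex", {
  box <- box_spec(10, 10)
  surf <- surface_plane(2, box)
  traj <- simulate_surface_brownian(surf, D0 = 0.05, n_particles = 20,
                                    n_frames = 200, dt = 0.1, seed = 16)
  mesh <- flat_tiled_mesh(10, 0.5, z = 2)
  vt <- map_trajectory_to_vertices(traj, mesh)
  # snapping error is bounded by the largest circumradius (flat: hyp / 2)
  expect_lt(vt$max_snap, 0.5 * sqrt(2) / 2 + 1e-9)

  # a particle resting on a central-window vertex maps to it in every frame
  vid <- which(central_image_vertices(mesh))[50]
  still <- traj
  still$x[] <- mesh$vertices[vid, 1]
  still$y[] <- mesh$vertices[vid, 2]
  still$z[] <- mesh$vertices[vid, 3]
  vs <- map_trajectory_to_vertices(still, mesh)
  expect_true(all(vs$frames == vid))
  rec <- generate_displacement_records(vs, lag_set(1, dt = 0.1))
  expect_true(all(rec$v_lo == vid & rec$v_hi == vid))
})

test_that("box-crossing displacements resolve to the minimum image", {
  box <- box_spec(10, 10)
  surf <- surface_plane(0, box)
  traj <- simulate_surface_brownian(surf, D0 = 0.2, n_particles = 50,
                                    n_frames = 400, dt = 0.1, seed = 17)
  mesh <- flat_tiled_mesh(10, 0.5)
  vt <- map_trajectory_to_vertices(traj, mesh)
  k <- 50L
  rec <- generate_displacement_records(vt, lag_set(5, dt = 0.1))
  V <- mesh$vertices
  # each record's endpoint separation on the tiled mesh equals the
  # brute-force minimum-image displacement length, up to snapping
  t0 <- seq_len(400 - k)
  dx <- as.vector(traj$x[t0 + k, ] - traj$x[t0, ])
  dy <- as.vector(traj$y[t0 + k, ] - traj$y[t0, ])
  dmi <- sqrt((dx - 10 * round(dx / 10))^2 + (dy - 10 * round(dy / 10))^2)
  # evaluate geometric separation of snapped endpoints (flat mesh: euclid)
  ii <- sample(length(rec$v_lo), 500)
  sep <- sqrt(rowSums((V[rec$v_lo[ii], 1:2] - V[rec$v_hi[ii], 1:2])^2))
  expect_lt(max(abs(sep - dmi[ii])), 2 * 0.5 * sqrt(2) / 2 + 1e-9)
})

test_that("particles far from the mesh are excluded and counted", {
  box <- box_spec(10, 10)
  surf <- surface_plane(0, box)
  traj <- simulate_surface_brownian(surf, D0 = 0.05, n_particles = 5,
                                    n_frames = 50, dt = 0.1, seed = 18)
  traj$z[, 3] <- 50  # one particle floats far above the sheet
  mesh <- flat_tiled_mesh(10, 0.5)
  expect_message(vt <- map_trajectory_to_vertices(traj, mesh, cutoff = 3),
                 "excluding 1")
  expect_equal(vt$n_excluded, 1L)
  expect_equal(ncol(vt$frames), 4)
})

test_that("leaflet assignment follows the head-tail orientation", {
  upper <- grid_mesh(10, 10, 10, 10, z = function(x, y) rep(2, length(x)))
  lowerV <- grid_mesh(10, 10, 10, 10, z = function(x, y) rep(-2, length(x)))
  lower <- triangle_mesh(lowerV$vertices, lowerV$faces[, c(1, 3, 2)])  # normals down
  meshes <- list(upper = upper, lower = lower)

  heads <- matrix(c(5, 5, 2.6), 1)
  tails <- matrix(c(5, 5, 1.6), 1)
  expect_equal(as.character(assign_leaflets(heads, tails, meshes)), "upper")
  expect_equal(as.character(assign_leaflets(tails, heads, meshes)), "lower")

  amb <- assign_leaflets(heads, heads, meshes)  # zero orientation vector
  expect_true(is.na(amb[1]))
  expect_equal(attr(amb, "n_unassigned"), 1L)

  # synthetic bilayer: 1000 lipids on known leaflets, all recovered
  set.seed(19)
  n <- 1000
  side <- rep(c("upper", "lower"), length.out = n)
  zmid <- ifelse(side == "upper", 2, -2)
  orient <- ifelse(side == "upper", 1, -1)
  mid <- cbind(runif(n, 0, 10), runif(n, 0, 10), zmid)
  heads <- mid; heads[, 3] <- heads[, 3] + 0.5 * orient
  tails <- mid; tails[, 3] <- tails[, 3] - 0.5 * orient
  got <- assign_leaflets(heads, tails, meshes)
  expect_equal(as.character(got), side)
})
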