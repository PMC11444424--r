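#' Lag-time set
#'
#' Validated set of lag times for displacement analysis. Each lag must be a
#' strictly positive integer multiple of the frame spacing and shorter than
#' the trajectory. The shipped default preset is `c(2, 53, 453)` ns.
#'
#' @param lags_ns strictly increasing lag times in ns.
#' @param dt frame spacing in ns.
#' @param n_frames optional trajectory length for range validation.
#' @return object of class `lag_set`: list with `lags_ns` and frame counts `k`.
#' @export
lag_set <- function(lags_ns = c(2, 53, 453), dt, n_frames = NULL) {
  stopifnot(length(lags_ns) >= 1, all(diff(lags_ns) > 0), dt > 0)
  k <- lags_ns / dt
  if (any(abs(k - round(k)) > 1e-9 * pmax(1, k)))
    stop("every lag must be an integer multiple of dt = ", dt, " ns")
  k <- as.integer(round(k))
  if (any(k < 1)) stop("minimum lag is one frame (dt)")
  if (!is.null(n_frames) && any(k >= n_frames))
    stop("lags must be shorter than the trajectory (", n_frames, " frames)")
  structure(list(lags_ns = lags_ns, k = k, dt = dt), class = "lag_set")
}

#' Assign lipids to leaflets by orientation
#'
#' A lipid belongs to the leaflet whose mesh normal at the nearest vertex
#' points along its head-minus-tail vector. Lipids whose orientation is
#' ambiguous (|dot| <= tol against every leaflet) are flagged `NA`, excluded
#' downstream, and counted in the `n_unassigned` attribute.
#'
#' @param head_positions,tail_positions n x 3 matrices, one row per lipid.
#' @param meshes named list of leaflet `triangle_mesh` objects.
#' @param box optional [box_spec()] for minimum-image snapping.
#' @param tol ambiguity tolerance on the orientation dot product.
#' @return character vector of leaflet names (`NA` = unassigned) with
#'   attribute `n_unassigned`.
#' @export
assign_leaflets <- function(head_positions, tail_positions, meshes,
                            box = NULL, tol = 1e-6) {
  head_positions <- as.matrix(head_positions)
  tail_positions <- as.matrix(tail_positions)
  stopifnot(nrow(head_positions) == nrow(tail_positions), length(meshes) >= 1)
  if (is.null(names(meshes))) names(meshes) <- paste0("leaflet", seq_along(meshes))
  mid <- (head_positions + tail_positions) / 2
  orient <- head_positions - tail_positions
  n <- nrow(mid)
  score <- matrix(-Inf, n, length(meshes))  # -snap distance where oriented along
  for (j in seq_along(meshes)) {
    m <- meshes[[j]]
    snap <- nearest_vertex(m, mid, box = box, return_distance = TRUE)
    nrm <- vertex_normals(m)[snap$index, , drop = FALSE]
    dp <- rowSums(nrm * orient)
    ok <- dp > tol
    score[ok, j] <- -snap$distance[ok]
  }
  best <- max.col(score, ties.method = "first")
  lab <- names(meshes)[best]
  lab[apply(score, 1, max) == -Inf] <- NA_character_
  structure(lab, n_unassigned = sum(is.na(lab)))
}

#' Snap a trajectory onto mesh vertices
#'
#' Maps every particle frame to its nearest mesh vertex. For periodic
#' (tiled height-field) meshes, positions are first wrapped into the central
#' analysis window of the tiled region, so that later displacement endpoints
#' can be placed in their minimum-image representation as close to the
#' center as possible. Unwrapped lateral coordinates are retained for
#' displacement and projected-MSD analysis.
#'
#' @param traj a `particle_trajectory` (or compatible list with `x`, `y`,
#'   `z` frame x particle matrices and `dt`).
#' @param mesh the static `triangle_mesh` of the leaflet.
#' @param cutoff particles ever farther than this from every vertex (nm) are
#'   excluded and counted.
#' @return a `vertex_trajectory`: list with `frames` (frame x particle
#'   vertex-index matrix), wrapped coordinates, unwrapped lateral
#'   coordinates, `dt`, the mesh, and exclusion bookkeeping.
#' @export
map_trajectory_to_vertices <- function(traj, mesh, cutoff = 3) {
  nt <- nrow(traj$x); np <- ncol(traj$x)
  per <- !is.null(mesh$box) && !is.null(mesh$grid)
  if (per) {
    offx <- (mesh$grid$Tx - mesh$box$Lx) / 2
    offy <- (mesh$grid$Ty - mesh$box$Ly) / 2
    wx <- offx + wrap_into(traj$x - offx, mesh$box$Lx)
    wy <- offy + wrap_into(traj$y - offy, mesh$box$Ly)
  } else {
    wx <- traj$x; wy <- traj$y
  }
  wz <- traj$z
  snap <- cpp_nearest_vertex(mesh$vertices, cbind(as.vector(wx), as.vector(wy), as.vector(wz)), -1, -1)
  idx <- matrix(snap$index, nt, np)
  dmat <- matrix(snap$distance, nt, np)
  far <- apply(dmat > cutoff, 2, any)
  keep <- which(!far)
  if (any(far))
    message(sprintf("excluding %d particle(s) farther than %.3g nm from the mesh",
                    sum(far), cutoff))
  structure(list(
    frames = idx[, keep, drop = FALSE],
    wx = wx[, keep, drop = FALSE], wy = wy[, keep, drop = FALSE],
    wz = wz[, keep, drop = FALSE],
    ux = traj$x[, keep, drop = FALSE], uy = traj$y[, keep, drop = FALSE],
    dt = traj$dt, mesh = mesh,
    leaflet = if (!is.null(traj$leaflet)) traj$leaflet[keep] else NULL,
    n_excluded = sum(far), kept = keep,
    max_snap = max(dmat[, keep, drop = FALSE])
  ), class = "vertex_trajectory")
}

#' Displacement records from a snapped trajectory
#'
#' Emits one `(v_lo, v_hi, lag_index)` integer triplet per particle, start
#' frame and lag, with the lower vertex index first (canonical order; the
#' geodesic distance is symmetric so no information is lost). For periodic
#' meshes each displacement endpoint pair is translated by whole-box vectors
#' to its minimum-image representation inside the tiled region before the
#' end point is snapped.
#'
#' @param vtraj a `vertex_trajectory`.
#' @param lags a [lag_set()].
#' @param stride start-frame stride (1 = every start frame; the record count
#'   per lag at stride 1 is `n_particles * (n_frames - k)`).
#' @return a `displacement_records` object: list with integer vectors
#'   `v_lo`, `v_hi`, `lag_index`, the lag table `lags_ns`, and `sorted` flag.
#' @export
generate_displacement_records <- function(vtraj, lags, stride = 1L) {
  stopifnot(inherits(lags, "lag_set"))
  nt <- nrow(vtraj$frames); np <- ncol(vtraj$frames)
  if (any(lags$k >= nt)) stop("lag exceeds trajectory length")
  mesh <- vtraj$mesh
  per <- !is.null(mesh$box) && !is.null(mesh$grid)
  vlo <- list(); vhi <- list(); lgi <- list()
  for (j in seq_along(lags$k)) {
    k <- lags$k[j]
    t0 <- seq(1L, nt - k, by = stride)
    vs <- vtraj$frames[t0, , drop = FALSE]
    if (per) {
      Lx <- mesh$box$Lx; Ly <- mesh$box$Ly
      dxu <- vtraj$ux[t0 + k, , drop = FALSE] - vtraj$ux[t0, , drop = FALSE]
      dyu <- vtraj$uy[t0 + k, , drop = FALSE] - vtraj$uy[t0, , drop = FALSE]
      dxu <- dxu - Lx * round(dxu / Lx)
      dyu <- dyu - Ly * round(dyu / Ly)
      ex <- vtraj$wx[t0, , drop = FALSE] + dxu
      ey <- vtraj$wy[t0, , drop = FALSE] + dyu
      ez <- vtraj$wz[t0 + k, , drop = FALSE]
      snap <- cpp_nearest_vertex(mesh$vertices,
                                 cbind(as.vector(ex), as.vector(ey), as.vector(ez)),
                                 -1, -1)
      ve <- snap$index
    } else {
      ve <- as.vector(vtraj$frames[t0 + k, , drop = FALSE])
    }
    vs <- as.vector(vs)
    vlo[[j]] <- pmin(vs, ve)
    vhi[[j]] <- pmax(vs, ve)
    lgi[[j]] <- rep.int(j, length(vs))
  }
  structure(list(v_lo = unlist(vlo), v_hi = unlist(vhi),
                 lag_index = unlist(lgi), lags_ns = lags$lags_ns,
                 sorted = FALSE),
            class = "displacement_records")
}

#' @export
print.displacement_records <- function(x, ...) {
  cat(sprintf("displacement_records: %d records, %d lags (%s ns)%s\n",
              length(x$v_lo), length(x$lags_ns),
              paste(x$lags_ns, collapse = ", "),
              if (isTRUE(x$sorted)) ", sorted" else ""))
  invisible(x)
}

#' Sort displacement records into contiguous source blocks
#'
#' Stable radix sort by `(v_lo, v_hi, lag_index)`. After sorting, all records
#' sharing a lower vertex form one contiguous block irrespective of lag, so a
#' single geodesic call per distinct `v_lo` evaluates the whole block; the
#' full sort key makes record files byte-reproducible.
#'
#' @param records a `displacement_records` object.
#' @return the sorted records.
#' @export
sort_records <- function(records) {
  ord <- order(records$v_lo, records$v_hi, records$lag_index, method = "radix")
  records$v_lo <- records$v_lo[ord]
  records$v_hi <- records$v_hi[ord]
  records$lag_index <- records$lag_index[ord]
  records$sorted <- TRUE
  records
}

CURD_MAGIC <- charToRaw("CURD")

#' Write / read the binary displacement-record file
#'
#' Little-endian layout: magic `"CURD"` (4 bytes), format version uint32 = 1,
#' `n_lags` uint32, lag times as float64 ns, `n_records` uint64, then per
#' record `v_lo` uint32, `v_hi` uint32, `lag_index` uint32 (all 0-based on
#' disk). Truncated or corrupt files raise an error naming the byte offset.
#'
#' @param path file path.
#' @param records a `displacement_records` object.
#' @return `write_records` the path, invisibly; `read_records` the records.
#' @export
write_records <- function(path, records) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(CURD_MAGIC, con)
  writeBin(1L, con, size = 4, endian = "little")
  writeBin(length(records$lags_ns), con, size = 4, endian = "little")
  writeBin(as.numeric(records$lags_ns), con, size = 8, endian = "little")
  n <- length(records$v_lo)
  writeBin(as.integer(n %% 2^32 %% 2^31), con, size = 4, endian = "little")  # low word (n < 2^31)
  writeBin(0L, con, size = 4, endian = "little")                             # high word
  if (n > 0) {
    tri <- integer(3L * n)
    tri[seq(1L, 3L * n, by = 3L)] <- records$v_lo - 1L
    tri[seq(2L, 3L * n, by = 3L)] <- records$v_hi - 1L
    tri[seq(3L, 3L * n, by = 3L)] <- records$lag_index - 1L
    writeBin(tri, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  sz <- file.size(path)
  con <- file(path, "rb")
  on.exit(close(con))
  if (sz < 12) stop("truncated record file at byte offset ", sz)
  magic <- readBin(con, "raw", 4)
  if (!identical(magic, CURD_MAGIC))
    stop("bad magic at byte offset 0: not a CURD record file")
  ver <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (ver != 1L) stop("unsupported record format version ", ver, " at byte offset 4")
  nlag <- readBin(con, "integer", 1, size = 4, endian = "little")
  hdr_end <- 12 + 8 * nlag + 8
  if (sz < hdr_end) stop("truncated record file at byte offset ", sz)
  lags <- readBin(con, "double", nlag, size = 8, endian = "little")
  nlo <- readBin(con, "integer", 1, size = 4, endian = "little")
  nhi <- readBin(con, "integer", 1, size = 4, endian = "little")
  n <- (if (nlo < 0) nlo + 2^32 else nlo) + (if (nhi < 0) nhi + 2^32 else nhi) * 2^32
  if (sz != hdr_end + 12 * n)
    stop("truncated record file: expected ", hdr_end + 12 * n,
         " bytes, got ", sz, " (corruption at byte offset ",
         hdr_end + 12 * floor((sz - hdr_end) / 12), ")")
  tri <- readBin(con, "integer", 3 * n, size = 4, endian = "little")
  structure(list(v_lo = tri[seq(1L, length.out = n, by = 3L)] + 1L,
                 v_hi = tri[seq(2L, length.out = n, by = 3L)] + 1L,
                 lag_index = tri[seq(3L, length.out = n, by = 3L)] + 1L,
                 lags_ns = lags, sorted = NA),
            class = "displacement_records")
}

#' Evaluate all record distances with one geodesic call per block
#'
#' Records must be sorted ([sort_records()]); every distinct lower vertex is
#' then solved once and all records in its contiguous block are read off the
#' resulting distance field. The number of geodesic calls equals the number
#' of distinct lower vertices and is returned for inspection.
#'
#' @param records sorted `displacement_records`.
#' @param mesh the `triangle_mesh` the vertex indices refer to.
#' @param method distance backend (see [geodesic_distances()]).
#' @param workers fork the blocks across this many processes; the result is
#'   identical for any worker count.
#' @return list with `distance` (nm, one per record) and `n_calls`.
#' @export
evaluate_blocks <- function(records, mesh, method = "vtp", workers = 1L) {
  n <- length(records$v_lo)
  if (n == 0) return(list(distance = numeric(0), n_calls = 0L))
  if (is.unsorted(records$v_lo))
    stop("records must be sorted with sort_records() before evaluation")
  if (workers > 1L && .Platform$OS.type == "unix") {
    blocks <- unique(records$v_lo)
    grp <- cut(match(records$v_lo, blocks), breaks = workers, labels = FALSE)
    pieces <- parallel::mclapply(split(seq_len(n), grp), function(ii)
      cpp_evaluate_blocks(mesh$vertices, mesh$faces,
                          records$v_lo[ii], records$v_hi[ii], method),
      mc.cores = workers)
    list(distance = unlist(lapply(pieces, `[[`, "distance"), use.names = FALSE),
         n_calls = sum(vapply(pieces, `[[`, integer(1), "n_calls")))
  } else {
    cpp_evaluate_blocks(mesh$vertices, mesh$faces, records$v_lo,
                        records$v_hi, method)
  }
}

#' Plain-text trajectory interchange format
#'
#' Whitespace-separated columns `frame particle_id x y z` (frames and ids
#' 0-based, positions in nm) preceded by a header line `#box Lx Ly Lz`.
#'
#' @param traj a `particle_trajectory`.
#' @param path file path.
#' @param dt frame spacing in ns used when reading.
#' @return `read_trajectory_txt` returns a `particle_trajectory`.
#' @export
write_trajectory_txt <- function(traj, path) {
  nt <- nrow(traj$x); np <- ncol(traj$x)
  con <- file(path, "w")
  on.exit(close(con))
  b <- traj$box
  writeLines(sprintf("#box %.17g %.17g %.17g",
                     if (is.null(b)) 0 else b$Lx,
                     if (is.null(b)) 0 else b$Ly,
                     if (is.null(b)) 0 else b$Lz), con)
  writeLines(sprintf("%d %d %.17g %.17g %.17g",
                     rep(0:(nt - 1), np), rep(0:(np - 1), each = nt),
                     as.vector(traj$x), as.vector(traj$y),
                     as.vector(traj$z)), con)
  invisible(path)
}

#' @rdname write_trajectory_txt
#' @export
read_trajectory_txt <- function(path, dt) {
  hdr <- readLines(path, 1)
  if (!startsWith(hdr, "#box")) stop("missing '#box Lx Ly Lz' header line")
  bl <- as.numeric(strsplit(trimws(hdr), "\\s+")[[1]][-1])
  box <- if (all(bl > 0)) box_spec(bl[1], bl[2], bl[3]) else NULL
  df <- read.table(path, comment.char = "#",
                   col.names = c("frame", "id", "x", "y", "z"))
  frames <- sort(unique(df$frame)); ids <- sort(unique(df$id))
  ord <- order(df$id, df$frame)
  nt <- length(frames); np <- length(ids)
  if (nrow(df) != nt * np) stop("trajectory is not rectangular")
  structure(list(x = matrix(df$x[ord], nt, np),
                 y = matrix(df$y[ord], nt, np),
                 z = matrix(df$z[ord], nt, np),
                 dt = dt, box = box, surface = NULL, leaflet = NULL),
            class = "particle_trajectory")
}

#' Minimal GRO coordinate reader
#'
#' Reads a single-frame Gromos87 coordinate file: atom names, residue ids and
#' positions in nm, plus the (orthorhombic) box from the last line. Binary
#' compressed trajectory formats are out of scope; export such trajectories
#' to the plain-text interchange format instead.
#'
#' @param path GRO file.
#' @return list with `atoms` data frame (resid, resname, name, x, y, z) and
#'   `box` ([box_spec()]).
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[2]))
  al <- lines[3:(2 + n)]
  atoms <- data.frame(
    resid = as.integer(substr(al, 1, 5)),
    resname = trimws(substr(al, 6, 10)),
    name = trimws(substr(al, 11, 15)),
    x = as.numeric(substr(al, 21, 28)),
    y = as.numeric(substr(al, 29, 36)),
    z = as.numeric(substr(al, 37, 44)))
  bl <- as.numeric(strsplit(trimws(lines[3 + n]), "\\s+")[[1]])
  list(atoms = atoms, box = box_spec(bl[1], bl[2], bl[3]))
}
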