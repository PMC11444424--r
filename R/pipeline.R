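#' Pipeline configuration
#'
#' Collects and validates everything one analysis run needs. Either an
#' in-memory `trajectory` / `mesh` or file paths may be given; a `surface`
#' plus Brownian parameters generates a synthetic trajectory instead.
#'
#' @param trajectory a `particle_trajectory`, or `NULL`.
#' @param traj_file plain-text trajectory file (see
#'   [write_trajectory_txt()]); requires `dt`.
#' @param surface a [parametric_surface] to simulate on (with `D0`,
#'   `n_particles`, `n_frames`, `dt`).
#' @param mesh a `triangle_mesh` or a PLY/OFF file path; `NULL` builds a
#'   height-field mesh from the trajectory positions.
#' @param dt frame spacing in ns.
#' @param D0,n_particles,n_frames Brownian generator parameters.
#' @param spacing_nm,smoothing_nm,images meshing parameters
#'   (see [build_heightfield_mesh()]).
#' @param lags_ns lag table in ns.
#' @param analysis_lag_ns lag for the diffusion map.
#' @param h_flat,k_flat curvature-class thresholds.
#' @param bins,profile_mode spatial profile setup.
#' @param stride start-frame stride for record generation.
#' @param snap_cutoff_nm exclusion distance for unsnappable particles.
#' @param workers process count for the geodesic stage.
#' @param seed RNG seed for the synthetic generator.
#' @param outdir output directory.
#' @return validated config list of class `run_config`.
#' @export
run_config <- function(trajectory = NULL, traj_file = NULL, surface = NULL,
                       mesh = NULL, dt = 0.1, D0 = 0.06,
                       n_particles = 1000, n_frames = 10000,
                       spacing_nm = 0.4, smoothing_nm = spacing_nm,
                       images = c(2L, 2L), lags_ns = c(2, 53, 453),
                       analysis_lag_ns = 53, h_flat = 0.05, k_flat = 0.005,
                       bins = 20, profile_mode = "y", stride = 1L,
                       snap_cutoff_nm = 3, workers = 1L, seed = 1L,
                       outdir = "curvdiff_out") {
  if (is.null(trajectory) && is.null(traj_file) && is.null(surface))
    stop("one of trajectory, traj_file or surface is required")
  if (!is.null(traj_file) && !file.exists(traj_file))
    stop("trajectory file not found: ", traj_file)
  if (is.character(mesh) && !file.exists(mesh))
    stop("mesh file not found: ", mesh)
  lag_set(lags_ns, dt)  # validates multiples before any compute
  if (!analysis_lag_ns %in% lags_ns)
    stop("analysis_lag_ns must be one of lags_ns")
  structure(as.list(environment()), class = "run_config")
}

stage_msg <- function(fmt, ...) message(sprintf(paste0("[curvdiff] ", fmt), ...))

#' Run the full geodesic-diffusion pipeline
#'
#' Executes mesh construction, vertex snapping, record generation, sorting,
#' blocked geodesic evaluation, gMSD accumulation, and map/profile/statistics
#' output, writing a manifest with checksums. Rerunning with the same config
#' and inputs reproduces identical record files and tables.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the in-memory results (mesh, records,
#'   msd map, diffusion map, tables) and the output directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()
  stage <- "setup"
  res <- tryCatch({
    stage <- "trajectory"
    traj <- config$trajectory
    if (is.null(traj) && !is.null(config$traj_file))
      traj <- read_trajectory_txt(config$traj_file, dt = config$dt)
    if (is.null(traj)) {
      stage_msg("simulating %d particles x %d frames on '%s' (D0 = %g nm^2/ns)",
                config$n_particles, config$n_frames, config$surface$kind, config$D0)
      traj <- simulate_surface_brownian(config$surface, config$D0,
                                        config$n_particles, config$n_frames,
                                        config$dt, seed = config$seed)
    }
    lags <- lag_set(config$lags_ns, traj$dt, n_frames = nrow(traj$x))

    stage <- "mesh"
    mesh <- config$mesh
    if (is.character(mesh)) {
      mesh <- if (grepl("\\.off$", mesh, ignore.case = TRUE))
        read_off(mesh, box = traj$box) else read_ply(mesh, box = traj$box)
    }
    if (is.null(mesh)) {
      pts <- cbind(wrap_into(as.vector(traj$x), traj$box$Lx),
                   wrap_into(as.vector(traj$y), traj$box$Ly),
                   as.vector(traj$z))
      if (nrow(pts) > 2e5) pts <- pts[seq(1, nrow(pts), length.out = 2e5), ]
      mesh <- build_heightfield_mesh(pts, traj$box, config$spacing_nm,
                                     config$smoothing_nm, images = config$images,
                                     provenance = "leaflet")
    }
    stage_msg("mesh: %d vertices, %d faces", nrow(mesh$vertices), nrow(mesh$faces))
    mesh_path <- file.path(config$outdir, "mesh.ply")

    stage <- "snap"
    vtraj <- map_trajectory_to_vertices(traj, mesh, cutoff = config$snap_cutoff_nm)
    stage_msg("snapped %d particles (%d excluded), max snap distance %.3g nm",
              ncol(vtraj$frames), vtraj$n_excluded, vtraj$max_snap)

    stage <- "records"
    rec <- generate_displacement_records(vtraj, lags, stride = config$stride)
    rec <- sort_records(rec)
    rec_path <- file.path(config$outdir, "records.curd")
    write_records(rec_path, rec)
    outputs <- c(outputs, rec_path)
    stage_msg("%d records over %d lags, sorted", length(rec$v_lo), length(lags$k))

    stage <- "geodesics"
    ev <- evaluate_blocks(rec, mesh, workers = config$workers)
    stage_msg("geodesic calls: %d (distinct source vertices)", ev$n_calls)

    stage <- "accumulate"
    msd <- accumulate_gmsd(rec, ev$distance, mesh)
    D <- diffusion_map(msd, config$analysis_lag_ns)

    stage <- "fields"
    H <- mean_curvature(mesh)
    K <- gaussian_curvature(mesh)
    occ <- occupancy_density(vtraj, mesh)
    fields <- list(H = as.numeric(H), K = as.numeric(K),
                   occupancy = as.numeric(attr(occ, "counts")),
                   D = as.numeric(D) )
    for (lg in lags$lags_ns)
      fields[[sprintf("gmsd_%g", lg)]] <- as.numeric(gmsd_mean(msd, lg))
    write_ply(mesh, mesh_path, fields = fields)
    outputs <- c(outputs, mesh_path)

    stage <- "statistics"
    # class statistics live on the central analysis window: occupancy is
    # uniform there, whereas sparsely visited vertices near the open tiled
    # edge are reached only by long displacements and carry biased gMSD
    cls <- classify_vertices(H, K, config$h_flat, config$k_flat)
    ctr <- central_image_vertices(mesh)
    Dctr <- as.numeric(D)
    Dctr[!ctr] <- NA_real_
    cmpH <- compare_classes(Dctr, cls$H_class)
    cmpK <- compare_classes(Dctr, cls$K_class)
    profs <- lapply(lags$lags_ns, function(lg) {
      jj <- match_lag(msd, lg)
      cbind(lag_ns = lg,
            profile_field(mesh, gmsd_mean(msd, lg), mode = config$profile_mode,
                          bins = config$bins, weights = msd$counts[, jj]))
    })
    gmsd_prof <- do.call(rbind, profs)
    pm <- projected_msd(traj, lags, bins = config$bins,
                        axis = config$profile_mode, stride = config$stride)
    Dgeo_long <- gmsd_global_mean(msd, max(lags$lags_ns)) / (4 * max(lags$lags_ns))
    Dproj_long <- unname(pm$msd[length(lags$lags_ns)]) / (4 * max(lags$lags_ns))
    area_tab <- area_scaling_report(mesh, Dgeo_long, Dproj_long)

    csv <- function(obj, name) {
      p <- file.path(config$outdir, name)
      write.csv(obj, p, row.names = FALSE)
      outputs <<- c(outputs, p)
      p
    }
    csv(gmsd_prof, "profile_gmsd.csv")
    if (!is.null(pm$profile)) csv(pm$profile, "profile_projected.csv")
    csv(rbind(cbind(view = "H", cmpH$means), cbind(view = "K", cmpK$means)),
        "class_stats.csv")
    wt <- rbind(if (!is.null(cmpH$tests)) cbind(view = "H", cmpH$tests),
                if (!is.null(cmpK$tests)) cbind(view = "K", cmpK$tests))
    if (!is.null(wt)) csv(wt, "welch_tests.csv")
    csv(area_tab, "area_scaling.csv")

    stage <- "summary"
    summ <- c(
      "curvdiff run summary",
      sprintf("seed: %d", config$seed),
      sprintf("particles kept: %d, excluded: %d", ncol(vtraj$frames), vtraj$n_excluded),
      sprintf("mesh: %d vertices, %d faces, spacing %.3g nm, images %dx%d",
              nrow(mesh$vertices), nrow(mesh$faces), config$spacing_nm,
              config$images[1], config$images[2]),
      sprintf("records: %d over lags %s ns (stride %d)", length(rec$v_lo),
              paste(lags$lags_ns, collapse = "/"), config$stride),
      sprintf("geodesic calls: %d", ev$n_calls),
      sprintf("analysis lag: %g ns", config$analysis_lag_ns),
      sprintf("curvature-class thresholds: |H| < %g 1/nm, |K| < %g 1/nm^2",
              config$h_flat, config$k_flat),
      sprintf("count-weighted mean D: %.6g nm^2/ns = %.6g cm^2/s",
              gmsd_global_mean(msd, config$analysis_lag_ns) / (4 * config$analysis_lag_ns),
              1e-5 * gmsd_global_mean(msd, config$analysis_lag_ns) / (4 * config$analysis_lag_ns)))
    sum_path <- file.path(config$outdir, "summary.txt")
    writeLines(summ, sum_path)
    outputs <- c(outputs, sum_path)

    manifest <- data.frame(file = basename(outputs),
                           md5 = unname(tools::md5sum(outputs)))
    write.csv(manifest, file.path(config$outdir, "manifest.csv"), row.names = FALSE)

    invisible(list(outdir = config$outdir, mesh = mesh, vtraj = vtraj,
                   records = rec, distances = ev$distance,
                   n_geodesic_calls = ev$n_calls, msd = msd, D = D,
                   H = H, K = K, classes = cls,
                   welch = list(H = cmpH, K = cmpK),
                   gmsd_profile = gmsd_prof, projected = pm,
                   area_scaling = area_tab, occupancy = occ,
                   manifest = manifest))
  }, error = function(e) {
    if (length(outputs)) {
      manifest <- data.frame(file = basename(outputs),
                             md5 = unname(tools::md5sum(outputs)))
      write.csv(manifest, file.path(config$outdir, "manifest_partial.csv"),
                row.names = FALSE)
    }
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  res
}

#' Summarize a finished pipeline run
#'
#' Reads the manifest of an output directory, verifies checksums, and prints
#' the run summary together with the class statistics and area-scaling
#' tables.
#'
#' @param outdir pipeline output directory.
#' @return the summary lines, invisibly.
#' @export
report <- function(outdir) {
  man_path <- file.path(outdir, "manifest.csv")
  if (!file.exists(man_path)) stop("no manifest.csv in ", outdir)
  man <- read.csv(man_path)
  for (i in seq_len(nrow(man))) {
    p <- file.path(outdir, man$file[i])
    if (!file.exists(p)) {
      warning("missing output file: ", man$file[i])
    } else if (unname(tools::md5sum(p)) != man$md5[i]) {
      warning("checksum mismatch (file modified?): ", man$file[i])
    }
  }
  lines <- readLines(file.path(outdir, "summary.txt"))
  cat(lines, sep = "\n")
  cs <- file.path(outdir, "class_stats.csv")
  if (file.exists(cs)) {
    cat("\nclass means:\n")
    print(read.csv(cs))
  }
  wt <- file.path(outdir, "welch_tests.csv")
  if (file.exists(wt)) {
    cat("\nWelch tests:\n")
    print(read.csv(wt))
  }
  as <- file.path(outdir, "area_scaling.csv")
  if (file.exists(as)) {
    cat("\narea scaling:\n")
    print(read.csv(as))
  }
  invisible(lines)
}
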