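#' Accumulate squared geodesic displacements onto mesh vertices
#'
#' Each record contributes its squared distance once to the lower and once to
#' the higher endpoint vertex at its lag (a self-record `v_lo == v_hi`
#' contributes twice to that vertex; negligible for fine meshes). Means are
#' formed lazily with [gmsd_mean()].
#'
#' @param records `displacement_records` (sorted or not).
#' @param distances per-record geodesic distances (nm), aligned with the
#'   records, e.g. from [evaluate_blocks()].
#' @param mesh the `triangle_mesh`.
#' @return an `msd_map`: list with `sums` and `counts`
#'   (n_vertices x n_lags matrices) and the lag table `lags_ns`.
#' @export
accumulate_gmsd <- function(records, distances, mesh) {
  stopifnot(length(distances) == length(records$v_lo))
  acc <- cpp_accumulate_gmsd(records$v_lo, records$v_hi, records$lag_index,
                             distances, n_vertices(mesh),
                             length(records$lags_ns))
  structure(list(sums = acc$sums, counts = acc$counts,
                 lags_ns = records$lags_ns),
            class = "msd_map")
}

#' Per-vertex mean gMSD at one lag
#' @param msd an `msd_map`.
#' @param lag_ns one of the map's lag times.
#' @return a [vertex_field()] in nm^2 (`NA` where no displacement visited).
#' @export
gmsd_mean <- function(msd, lag_ns) {
  j <- match_lag(msd, lag_ns)
  v <- msd$sums[, j] / msd$counts[, j]
  v[msd$counts[, j] == 0] <- NA_real_
  vertex_field(v, lag = lag_ns, units = "nm^2")
}

match_lag <- function(msd, lag_ns) {
  j <- which(abs(msd$lags_ns - lag_ns) < 1e-9)
  if (length(j) != 1)
    stop("lag ", lag_ns, " ns not in the map; available: ",
         paste(msd$lags_ns, collapse = ", "), " ns")
  j
}

#' Diffusion-coefficient map from a gMSD map
#'
#' Free-diffusion estimate at a single lag, `D(v) = gMSD(v, lag) / (4 lag)`,
#' instead of per-vertex regression. Internal units are nm^2/ns; multiply by
#' `1e-5` for cm^2/s.
#'
#' @param msd an `msd_map`.
#' @param lag_ns analysis lag in ns (default 53).
#' @return a [vertex_field()] in nm^2/ns.
#' @export
diffusion_map <- function(msd, lag_ns = 53) {
  g <- gmsd_mean(msd, lag_ns)
  vertex_field(as.numeric(g) / (4 * lag_ns), lag = lag_ns, units = "nm^2/ns")
}

#' Count-weighted global mean of a gMSD map at one lag
#' @param msd an `msd_map`.
#' @param lag_ns lag in ns.
#' @param subset optional logical vertex mask.
#' @return scalar mean gMSD in nm^2.
#' @export
gmsd_global_mean <- function(msd, lag_ns, subset = NULL) {
  j <- match_lag(msd, lag_ns)
  s <- msd$sums[, j]; cnt <- msd$counts[, j]
  if (!is.null(subset)) { s <- s[subset]; cnt <- cnt[subset] }
  sum(s) / sum(cnt)
}

#' Projected (conventional 2D) mean square displacement
#'
#' MSD computed after discarding the coordinate normal to the macroscopic
#' membrane plane: the mean over particles and start frames of
#' `dx^2 + dy^2` of the unwrapped lateral coordinates. Optionally binned by
#' wrapped start position. With per-particle leaflet labels, mode `"upper"` /
#' `"lower"` restricts to one leaflet and `"both"` (default) averages across
#' both.
#'
#' @param traj a `particle_trajectory`.
#' @param lags a [lag_set()].
#' @param leaflet_mode `"both"`, or a label present in `traj$leaflet`.
#' @param bins number of spatial bins (0 = no profile).
#' @param axis `"y"` (profile along y) or `"radial"` (distance from
#'   `center`).
#' @param center length-2 center for radial mode; defaults to the box center.
#' @param stride start-frame stride.
#' @return list with `msd` (per-lag scalars, nm^2) and, when `bins > 0`,
#'   `profile`: data frame (lag_ns, bin, mid, mean, se, n).
#' @export
projected_msd <- function(traj, lags, leaflet_mode = "both", bins = 0,
                          axis = c("y", "radial"), center = NULL,
                          stride = 1L) {
  axis <- match.arg(axis)
  stopifnot(inherits(lags, "lag_set"))
  nt <- nrow(traj$x)
  if (any(lags$k >= nt)) stop("lag exceeds trajectory length")
  cols <- seq_len(ncol(traj$x))
  if (!identical(leaflet_mode, "both")) {
    if (is.null(traj$leaflet)) stop("trajectory has no leaflet labels")
    cols <- which(traj$leaflet == leaflet_mode)
  }
  ux <- traj$x[, cols, drop = FALSE]
  uy <- traj$y[, cols, drop = FALSE]
  box <- traj$box
  scalars <- numeric(length(lags$k))
  prof <- list()
  for (j in seq_along(lags$k)) {
    k <- lags$k[j]
    t0 <- seq(1L, nt - k, by = stride)
    d2 <- (ux[t0 + k, , drop = FALSE] - ux[t0, , drop = FALSE])^2 +
          (uy[t0 + k, , drop = FALSE] - uy[t0, , drop = FALSE])^2
    scalars[j] <- mean(d2)
    if (bins > 0) {
      if (axis == "y") {
        pos <- uy[t0, , drop = FALSE]
        if (!is.null(box)) pos <- wrap_into(pos, box$Ly)
        rng <- if (!is.null(box)) c(0, box$Ly) else range(pos)
      } else {
        if (is.null(center)) center <- c(box$Lx / 2, box$Ly / 2)
        px <- ux[t0, , drop = FALSE]; py <- uy[t0, , drop = FALSE]
        if (!is.null(box)) { px <- wrap_into(px, box$Lx); py <- wrap_into(py, box$Ly) }
        pos <- sqrt((px - center[1])^2 + (py - center[2])^2)
        rng <- c(0, max(pos))
      }
      br <- seq(rng[1], rng[2], length.out = bins + 1)
      bi <- pmin(bins, pmax(1L, findInterval(pos, br, rightmost.closed = TRUE)))
      n <- tabulate(bi, bins)
      s <- as.vector(rowsum(as.vector(d2), as.vector(bi)))
      mids <- (br[-1] + br[-(bins + 1)]) / 2
      mu <- rep(NA_real_, bins); mu[n > 0] <- s / n[n > 0]
      ss <- as.vector(rowsum(as.vector(d2)^2, as.vector(bi)))
      se <- rep(NA_real_, bins)
      se[n > 1] <- sqrt(pmax(0, ss / n[n > 1] - mu[n > 1]^2) / (n[n > 1] - 1))
      prof[[j]] <- data.frame(lag_ns = lags$lags_ns[j], bin = seq_len(bins),
                              mid = mids, mean = mu, se = se, n = n)
    }
  }
  out <- list(msd = stats::setNames(scalars, paste0(lags$lags_ns, "ns")),
              lags_ns = lags$lags_ns)
  if (bins > 0) out$profile <- do.call(rbind, prof)
  out
}

#' Curvature-class labels for mesh vertices
#'
#' Classifies vertices into a mean-curvature view (`Flat`, `H>0`, `H<0`) and
#' a Gaussian-curvature view (`Flat`, `K>0`, `K<0`). `Flat` requires both
#' `|H| < h_flat` and `|K| < k_flat`; otherwise the sign of the respective
#' curvature decides. Vertices with invalid (NA) curvature are excluded and
#' counted.
#'
#' @param H,K curvature [vertex_field()]s on the same mesh.
#' @param h_flat,k_flat flatness thresholds (1/nm, 1/nm^2).
#' @return list with factors `H_class`, `K_class` (NA = excluded), the
#'   thresholds, and `n_excluded`.
#' @export
classify_vertices <- function(H, K, h_flat = 0.05, k_flat = 0.005) {
  stopifnot(length(H) == length(K), h_flat > 0, k_flat > 0)
  H <- as.numeric(H); K <- as.numeric(K)
  ok <- !is.na(H) & !is.na(K)
  flat <- ok & abs(H) < h_flat & abs(K) < k_flat
  hc <- ifelse(flat, "Flat", ifelse(H > 0, "H>0", "H<0"))
  kc <- ifelse(flat, "Flat", ifelse(K > 0, "K>0", "K<0"))
  hc[!ok] <- NA; kc[!ok] <- NA
  list(H_class = factor(hc, levels = c("Flat", "H>0", "H<0")),
       K_class = factor(kc, levels = c("Flat", "K>0", "K<0")),
       h_flat = h_flat, k_flat = k_flat, n_excluded = sum(!ok))
}

#' Compare diffusion between curvature classes (Welch tests)
#'
#' Pairwise two-sample t tests with unequal variances and sample sizes
#' (Welch) between the per-vertex diffusion values of each class, plus class
#' means. Raw two-sided p values are reported together with
#' Bonferroni-adjusted ones.
#'
#' @param D a diffusion [vertex_field()] (or any per-vertex values).
#' @param labels factor of class labels (NA excluded), e.g. from
#'   [classify_vertices()].
#' @return list with `means` (data frame class/mean/sd/n) and `tests`
#'   (data frame class1/class2/t/df/p/p_bonferroni).
#' @export
compare_classes <- function(D, labels) {
  D <- as.numeric(D)
  keep <- !is.na(D) & !is.na(labels)
  D <- D[keep]; labels <- droplevels(factor(labels[keep]))
  lev <- levels(labels)
  means <- data.frame(class = lev,
                      mean = vapply(lev, function(l) mean(D[labels == l]), 0),
                      sd = vapply(lev, function(l) sd(D[labels == l]), 0),
                      n = vapply(lev, function(l) sum(labels == l), 0L),
                      row.names = NULL)
  if (length(lev) < 2) return(list(means = means, tests = NULL))
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  rows <- lapply(pairs, function(p) {
    a <- D[labels == p[1]]; b <- D[labels == p[2]]
    if (length(a) < 2 || length(b) < 2) {
      warning(sprintf("class pair %s vs %s skipped: fewer than 2 members", p[1], p[2]))
      return(NULL)
    }
    tt <- t.test(a, b, var.equal = FALSE)
    data.frame(class1 = p[1], class2 = p[2],
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  })
  tests <- do.call(rbind, rows)
  if (!is.null(tests))
    tests$p_bonferroni <- pmin(1, p.adjust(tests$p, method = "bonferroni"))
  list(means = means, tests = tests)
}

#' Spatial profile of a vertex field
#'
#' Bin means of a per-vertex field along y or radially from a center, with
#' optional per-vertex weights (e.g. gMSD sample counts) and standard
#' errors. Empty bins are `NA`-flagged.
#'
#' @param mesh the `triangle_mesh`.
#' @param field a [vertex_field()] or numeric vector.
#' @param mode `"y"` or `"radial"`.
#' @param bins number of bins (> 0).
#' @param center length-2 center for radial mode.
#' @param weights optional nonnegative per-vertex weights.
#' @param subset optional logical vertex mask (default: central image for
#'   tiled meshes).
#' @return data frame (bin, mid, mean, se, n, weight).
#' @export
profile_field <- function(mesh, field, mode = c("y", "radial"), bins = 20,
                          center = NULL, weights = NULL, subset = NULL) {
  mode <- match.arg(mode)
  if (bins <= 0) stop("bins must be positive")
  v <- as.numeric(field)
  if (is.null(subset)) subset <- central_image_vertices(mesh)
  if (is.null(weights)) weights <- rep(1, length(v))
  offx <- offy <- 0
  if (!is.null(mesh$grid) && !is.null(mesh$box)) {
    offx <- (mesh$grid$Tx - mesh$box$Lx) / 2
    offy <- (mesh$grid$Ty - mesh$box$Ly) / 2
  }
  keep <- subset & !is.na(v) & weights > 0
  if (mode == "y") {
    pos <- mesh$vertices[keep, 2] - offy
    rng <- if (!is.null(mesh$box)) c(0, mesh$box$Ly) else range(pos)
  } else {
    if (is.null(center)) {
      if (is.null(mesh$box)) stop("radial mode needs a center")
      center <- c(mesh$box$Lx / 2, mesh$box$Ly / 2)
    }
    pos <- sqrt((mesh$vertices[keep, 1] - offx - center[1])^2 +
                (mesh$vertices[keep, 2] - offy - center[2])^2)
    rng <- c(0, max(pos))
  }
  v <- v[keep]; w <- weights[keep]
  br <- seq(rng[1], rng[2], length.out = bins + 1)
  bi <- pmin(bins, pmax(1L, findInterval(pos, br, rightmost.closed = TRUE)))
  n <- tabulate(bi, bins)
  wsum <- as.vector(rowsum(w, bi, reorder = TRUE))
  widx <- sort(unique(bi))
  W <- numeric(bins); W[widx] <- wsum
  S <- numeric(bins); S[widx] <- as.vector(rowsum(w * v, bi))
  S2 <- numeric(bins); S2[widx] <- as.vector(rowsum(w * v^2, bi))
  mu <- ifelse(W > 0, S / W, NA_real_)
  se <- rep(NA_real_, bins)
  ok <- n > 1 & W > 0
  se[ok] <- sqrt(pmax(0, S2[ok] / W[ok] - mu[ok]^2) / (n[ok] - 1))
  data.frame(bin = seq_len(bins), mid = (br[-1] + br[-(bins + 1)]) / 2,
             mean = mu, se = se, n = n, weight = W)
}

#' Vertex occupancy density
#'
#' Visit counts of the snapped trajectory per vertex divided by the
#' mixed-Voronoi vertex area; a near-uniform density justifies
#' vertex-weighted (rather than occupancy-weighted) diffusion statistics.
#'
#' @param vtraj a `vertex_trajectory`.
#' @param mesh the `triangle_mesh`.
#' @return a [vertex_field()] in counts/nm^2 with attribute `counts`.
#' @export
occupancy_density <- function(vtraj, mesh) {
  cnt <- tabulate(as.vector(vtraj$frames), nbins = n_vertices(mesh))
  area <- vertex_areas(mesh)
  structure(vertex_field(cnt / area, units = "1/nm^2"), counts = cnt)
}

#' Projected-versus-geodesic area-scaling comparison
#'
#' Reports the long-time ratio of projected to geodesic diffusion
#' coefficients next to the projected-to-true area ratio of the mesh. On
#' periodically repeating surfaces the long-lag projected diffusion
#' coefficient is expected to scale with the area ratio; the table reports
#' both ratios and their discrepancy without asserting a functional form.
#'
#' @param mesh the `triangle_mesh` (central image used when tiled).
#' @param D_geo_longtime,D_proj_longtime long-lag diffusion coefficients
#'   (same units).
#' @return one-row data frame: D_ratio, area_ratio, discrepancy.
#' @export
area_scaling_report <- function(mesh, D_geo_longtime, D_proj_longtime) {
  ar <- surface_and_projected_area(mesh)
  data.frame(D_proj = D_proj_longtime, D_geo = D_geo_longtime,
             D_ratio = D_proj_longtime / D_geo_longtime,
             area_ratio = ar[["A_proj"]] / ar[["A_surf"]],
             discrepancy = D_proj_longtime / D_geo_longtime -
               ar[["A_proj"]] / ar[["A_surf"]])
}
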