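#' Single-source geodesic distances on a triangle mesh
#'
#' Computes distances from one source vertex to every mesh vertex.
#'
#' The `"vtp"` backend returns exact polyhedral geodesic distances via
#' continuous-Dijkstra window propagation: distance windows are pushed across
#' unfolded triangle fans from the source (and from saddle or boundary
#' vertices acting as pseudo-sources), pruned vertex-orientedly against the
#' current per-vertex bounds, until the wavefront has covered the mesh. No
#' shortest path is ever reconstructed. The `"dijkstra"` backend restricts
#' paths to mesh edges and is therefore an upper bound everywhere; it serves
#' as an independent oracle and as a second registered distance backend.
#'
#' Vertices in disconnected components receive `Inf`.
#'
#' @param mesh a connected manifold `triangle_mesh`.
#' @param source 1-based source vertex index.
#' @param method `"vtp"` (exact, default) or `"dijkstra"` (edge graph).
#' @return numeric vector of distances (nm), `distance_field` class, with the
#'   source index and method as attributes.
#' @export
geodesic_distances <- function(mesh, source, method = c("vtp", "dijkstra")) {
  method <- match.arg(method)
  source <- as.integer(source)
  stopifnot(length(source) == 1, source >= 1, source <= n_vertices(mesh))
  d <- cpp_geodesic_single(mesh$vertices, mesh$faces, source, method)
  structure(d, source = source, method = method, class = "distance_field")
}

#' Available geodesic distance backends
#' @return character vector of backend names accepted by the `method`
#'   arguments of the distance functions.
#' @export
geodesic_backends <- function() c("vtp", "dijkstra")

#' Geodesic distances from many sources
#'
#' Independent single-source solves; `workers > 1` forks the sources across
#' processes. Results are bit-identical for any worker count and ordered as
#' the input.
#'
#' @param mesh a `triangle_mesh`.
#' @param sources integer vector of unique source vertices.
#' @param method distance backend, see [geodesic_distances()].
#' @param workers process count for parallel dispatch.
#' @return numeric `length(sources)` x n_vertices matrix; row i holds the
#'   field of `sources[i]`.
#' @export
geodesic_multi <- function(mesh, sources, method = c("vtp", "dijkstra"),
                           workers = 1L) {
  method <- match.arg(method)
  sources <- as.integer(sources)
  if (anyDuplicated(sources)) stop("sources must be unique")
  if (length(sources) == 0)
    return(matrix(numeric(0), 0, n_vertices(mesh)))
  if (workers > 1L && length(sources) > 1L &&
      .Platform$OS.type == "unix") {
    chunks <- split(sources, cut(seq_along(sources), workers, labels = FALSE))
    parts <- parallel::mclapply(chunks, function(s)
      cpp_geodesic_multi(mesh$vertices, mesh$faces, s, method),
      mc.cores = workers)
    out <- do.call(rbind, parts)
  } else {
    out <- cpp_geodesic_multi(mesh$vertices, mesh$faces, sources, method)
  }
  rownames(out) <- as.character(sources)
  out
}
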