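#' Write a mesh to PLY
#'
#' Writes ASCII or binary little-endian PLY. Scalar vertex fields (curvature,
#' gMSD, diffusion, occupancy) are stored as extra double vertex properties.
#'
#' @param mesh a `triangle_mesh`.
#' @param path output file.
#' @param fields named list of numeric per-vertex vectors to store as extra
#'   vertex properties (`NA` written as `NaN`).
#' @param binary write `binary_little_endian` instead of ASCII.
#' @export
write_ply <- function(mesh, path, fields = list(), binary = FALSE) {
  nv <- n_vertices(mesh)
  nf <- nrow(mesh$faces)
  for (f in fields) stopifnot(length(f) == nv)
  fnames <- names(fields)
  hdr <- c("ply",
           sprintf("format %s 1.0", if (binary) "binary_little_endian" else "ascii"),
           sprintf("comment %s", mesh$provenance),
           sprintf("element vertex %d", nv),
           "property double x", "property double y", "property double z",
           sprintf("property double %s", fnames),
           sprintf("element face %d", nf),
           "property list uchar int vertex_indices",
           "end_header")
  vdata <- cbind(mesh$vertices, do.call(cbind, c(fields, list(NULL))))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  if (binary) {
    writeBin(as.numeric(t(vdata)), con, size = 8, endian = "little")
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(mesh$faces[i, ] - 1L), con, size = 4, endian = "little")
    }
  } else {
    writeLines(apply(vdata, 1, function(r) paste(format(r, digits = 17, trim = TRUE), collapse = " ")), con)
    writeLines(paste(3L, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
  }
  invisible(path)
}

#' Read a PLY mesh
#'
#' Supports ASCII and binary little-endian PLY with float/double vertex
#' properties and triangular faces. Extra vertex properties are returned in
#' the `fields` attribute.
#'
#' @param path PLY file.
#' @param box,provenance passed to [triangle_mesh()].
#' @return a `triangle_mesh`; extra vertex properties in `attr(, "fields")`.
#' @export
read_ply <- function(path, box = NULL, provenance = basename(path)) {
  con <- file(path, "rb")
  on.exit(close(con))
  fmt <- NULL; nv <- 0L; nf <- 0L
  vprops <- character(); vtypes <- character()
  elem <- ""
  repeat {
    line <- readLines(con, 1)
    if (!length(line)) stop("unexpected end of PLY header")
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (tok[1] == "format") fmt <- tok[2]
    else if (tok[1] == "element") {
      elem <- tok[2]
      if (elem == "vertex") nv <- as.integer(tok[3])
      if (elem == "face") nf <- as.integer(tok[3])
    } else if (tok[1] == "property" && elem == "vertex") {
      if (tok[2] == "list") stop("list vertex properties are not supported")
      vtypes <- c(vtypes, tok[2]); vprops <- c(vprops, tok[3])
    } else if (tok[1] == "end_header") break
  }
  if (is.null(fmt) || !fmt %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format: ", fmt)
  sz <- c(float = 4L, float32 = 4L, double = 8L, float64 = 8L)
  if (!all(vtypes %in% names(sz))) stop("unsupported vertex property type")
  if (fmt == "ascii") {
    vdat <- matrix(scan(con, what = double(), n = nv * length(vprops), quiet = TRUE),
                   nrow = nv, byrow = TRUE)
    fdat <- matrix(scan(con, what = integer(), n = nf * 4L, quiet = TRUE),
                   nrow = nf, byrow = TRUE)
    if (any(fdat[, 1] != 3L)) stop("non-triangular face in PLY")
    faces <- fdat[, 2:4, drop = FALSE] + 1L
  } else {
    vdat <- matrix(0, nv, length(vprops))
    same <- length(unique(vtypes)) == 1
    if (same) {
      raw <- readBin(con, "double", n = nv * length(vprops), size = sz[[vtypes[1]]],
                     endian = "little")
      vdat <- matrix(raw, nrow = nv, byrow = TRUE)
    } else {
      for (i in seq_len(nv))
        for (j in seq_along(vprops))
          vdat[i, j] <- readBin(con, "double", 1, size = sz[[vtypes[j]]], endian = "little")
    }
    faces <- matrix(0L, nf, 3)
    for (i in seq_len(nf)) {
      cnt <- as.integer(readBin(con, "raw", 1))
      if (cnt != 3L) stop("non-triangular face in PLY")
      faces[i, ] <- readBin(con, "integer", 3, size = 4, endian = "little") + 1L
    }
  }
  colnames(vdat) <- vprops
  need <- c("x", "y", "z")
  if (!all(need %in% vprops)) stop("PLY vertex element lacks x/y/z")
  m <- triangle_mesh(vdat[, need, drop = FALSE], faces, box = box,
                     provenance = provenance)
  extra <- setdiff(vprops, need)
  attr(m, "fields") <- if (length(extra)) as.data.frame(vdat[, extra, drop = FALSE]) else NULL
  m
}

#' Write a mesh to OFF
#' @param mesh a `triangle_mesh`.
#' @param path output file.
#' @export
write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", n_vertices(mesh), nrow(mesh$faces)), con)
  writeLines(apply(mesh$vertices, 1, function(r)
    paste(format(r, digits = 17, trim = TRUE), collapse = " ")), con)
  writeLines(paste(3L, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                   mesh$faces[, 3] - 1L), con)
  invisible(path)
}

#' Read an OFF mesh
#' @param path OFF file.
#' @param box,provenance passed to [triangle_mesh()].
#' @return a `triangle_mesh`.
#' @export
read_off <- function(path, box = NULL, provenance = basename(path)) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (toupper(trimws(lines[1])) != "OFF") stop("not an OFF file")
  counts <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  vdat <- matrix(as.numeric(unlist(strsplit(trimws(lines[3:(2 + nv)]), "\\s+"))),
                 nrow = nv, byrow = TRUE)
  fl <- strsplit(trimws(lines[(3 + nv):(2 + nv + nf)]), "\\s+")
  fdat <- t(vapply(fl, function(x) as.integer(x[1:4]), integer(4)))
  if (any(fdat[, 1] != 3L)) stop("non-triangular face in OFF")
  triangle_mesh(vdat[, 1:3, drop = FALSE], fdat[, 2:4, drop = FALSE] + 1L,
                box = box, provenance = provenance)
}
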