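#' Triangle surface mesh
#'
#' Minimal triangle-mesh container for the micro-CT derived anatomy: vertices
#' in mm and 1-based triangular faces. No attributes, normals or colors are
#' kept; the package only needs geometry.
#'
#' @param vertices n x 3 numeric matrix (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @return Object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (!nrow(vertices) || !nrow(faces))
    stop("tri_mesh: empty mesh rejected")
  if (ncol(vertices) != 3L || ncol(faces) != 3L)
    stop("tri_mesh: vertices and faces must have 3 columns")
  if (!all(is.finite(vertices))) stop("tri_mesh: non-finite vertices")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("tri_mesh: face indices out of range")
  dimnames(vertices) <- list(NULL, c("x", "y", "z"))
  dimnames(faces) <- NULL
  structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("Triangle mesh: %d vertices, %d faces\n", nrow(x$vertices),
              nrow(x$faces)))
  cat(sprintf("  bbox x [%.2f, %.2f] y [%.2f, %.2f] z [%.2f, %.2f] mm\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

#' Rigidly transform a mesh
#' @param mesh a `tri_mesh`.
#' @param pose a `rigid_pose` applied to every vertex.
#' @return transformed `tri_mesh`.
#' @export
transform_mesh <- function(mesh, pose) {
  stopifnot(inherits(mesh, "tri_mesh"))
  tri_mesh(apply_pose(pose, mesh$vertices), mesh$faces)
}

#' Restrict a mesh to the faces near a point
#'
#' Keeps faces whose three vertices all lie within `radius` of `center`; used
#' to focus clearance queries on the molar or incisor region.
#' @param mesh a `tri_mesh`.
#' @param center length-3 point (mm, mesh frame).
#' @param radius inclusion radius (mm).
#' @return `tri_mesh` submesh (vertices re-indexed).
#' @export
mesh_region <- function(mesh, center, radius) {
  stopifnot(inherits(mesh, "tri_mesh"), radius > 0)
  d <- sqrt(colSums((t(mesh$vertices) - as.numeric(center))^2))
  keepv <- d <= radius
  keepf <- keepv[mesh$faces[, 1]] & keepv[mesh$faces[, 2]] & keepv[mesh$faces[, 3]]
  if (!any(keepf))
    stop("mesh_region: no faces within ", radius, " mm of the region center")
  used <- sort(unique(as.vector(mesh$faces[keepf, , drop = FALSE])))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  tri_mesh(mesh$vertices[used, , drop = FALSE],
           matrix(remap[mesh$faces[keepf, , drop = FALSE]], ncol = 3))
}

# ---- closed height-field block (used by the toy dentition generator) ----
# Builds a watertight solid from a surface z = Z[i,j] over the grid (xs, ys)
# and a flat back plane at z_back (entirely above or below the surface).
.heightfield_block <- function(xs, ys, Z, z_back) {
  nx <- length(xs); ny <- length(ys)
  stopifnot(nrow(Z) == nx, ncol(Z) == ny)
  vid <- function(i, j) (j - 1L) * nx + i
  V <- cbind(rep(xs, ny), rep(ys, each = nx), as.vector(Z))
  faces <- vector("list", 3)
  i <- rep(seq_len(nx - 1L), ny - 1L)
  j <- rep(seq_len(ny - 1L), each = nx - 1L)
  faces[[1]] <- rbind(
    cbind(vid(i, j), vid(i + 1L, j), vid(i + 1L, j + 1L)),
    cbind(vid(i, j), vid(i + 1L, j + 1L), vid(i, j + 1L)))
  # boundary ring (counter-clockwise in xy)
  ring <- c(vid(seq_len(nx), 1L),
            vid(nx, seq(2L, ny)),
            vid(seq(nx - 1L, 1L), ny),
            vid(1L, seq(ny - 1L, 2L)))
  nring <- length(ring)
  # duplicate ring at the back plane + back center
  backring <- nrow(V) + seq_len(nring)
  V <- rbind(V, cbind(V[ring, 1], V[ring, 2], z_back))
  centerid <- nrow(V) + 1L
  V <- rbind(V, c(mean(range(xs)), mean(range(ys)), z_back))
  nxt <- c(seq(2L, nring), 1L)
  faces[[2]] <- rbind(
    cbind(ring, ring[nxt], backring[nxt]),
    cbind(ring, backring[nxt], backring))
  faces[[3]] <- cbind(backring, backring[nxt], centerid)
  tri_mesh(V, do.call(rbind, faces))
}

# ---- mesh file exchange: STL and PLY, ASCII and binary ----

#' Read and write triangle meshes (STL / PLY)
#'
#' Geometry-only mesh exchange in the two formats used for segmented micro-CT
#' surfaces. The format is chosen from the file extension; ASCII and binary
#' variants of both are supported. Units are taken to be mm. STL files store
#' unconnected triangles, so reading an STL merges coincident vertices.
#'
#' @param mesh a `tri_mesh`.
#' @param path file path ending in `.stl` or `.ply`.
#' @param binary write the binary variant (default `FALSE`, ASCII).
#' @return `read_mesh` returns a `tri_mesh`; `write_mesh` returns `path`
#'   invisibly.
#' @export
write_mesh <- function(mesh, path, binary = FALSE) {
  stopifnot(inherits(mesh, "tri_mesh"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    stl = if (binary) .write_stl_bin(mesh, path) else .write_stl_ascii(mesh, path),
    ply = if (binary) .write_ply_bin(mesh, path) else .write_ply_ascii(mesh, path),
    stop("write_mesh: unsupported extension '.", ext, "' (use .stl or .ply)"))
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("read_mesh: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") return(.read_ply(path))
  if (ext == "stl") return(.read_stl(path))
  stop("read_mesh: unsupported extension '.", ext, "'")
}

.tri_corners <- function(mesh) {
  # m x 9 matrix: the three corners of every face
  cbind(mesh$vertices[mesh$faces[, 1], , drop = FALSE],
        mesh$vertices[mesh$faces[, 2], , drop = FALSE],
        mesh$vertices[mesh$faces[, 3], , drop = FALSE])
}

.write_stl_ascii <- function(mesh, path) {
  tc <- .tri_corners(mesh)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid jawtrack", con)
  body <- apply(tc, 1, function(r) paste0(
    " facet normal 0 0 0\n  outer loop\n",
    sprintf("   vertex %.9g %.9g %.9g\n", r[1], r[2], r[3]),
    sprintf("   vertex %.9g %.9g %.9g\n", r[4], r[5], r[6]),
    sprintf("   vertex %.9g %.9g %.9g\n", r[7], r[8], r[9]),
    "  endloop\n endfacet"))
  writeLines(body, con)
  writeLines("endsolid jawtrack", con)
}

.write_stl_bin <- function(mesh, path) {
  tc <- .tri_corners(mesh)
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(formatC("jawtrack binary STL", width = -80))
  writeBin(c(header, raw(80 - length(header))), con)
  writeBin(as.integer(nrow(tc)), con, size = 4, endian = "little")
  for (i in seq_len(nrow(tc))) {
    writeBin(c(0, 0, 0, tc[i, ]), con, size = 4, endian = "little")
    writeBin(as.integer(0), con, size = 2, endian = "little")
  }
}

.read_stl <- function(path) {
  con <- file(path, "rb")
  head5 <- rawToChar(readBin(con, "raw", 5))
  close(con)
  sz <- file.info(path)$size
  is_ascii <- identical(head5, "solid")
  if (is_ascii) {
    # a binary file can also start with "solid": check the size formula
    con <- file(path, "rb")
    invisible(readBin(con, "raw", 80))
    ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
    close(con)
    if (length(ntri) == 1 && !is.na(ntri) && sz == 84 + 50 * ntri)
      is_ascii <- FALSE
  }
  if (is_ascii) {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
    if (!length(vl) || length(vl) %% 3 != 0)
      stop("read_mesh: corrupt ASCII STL (vertex count not a multiple of 3)")
    nums <- lapply(strsplit(trimws(vl), "\\s+"), function(p) as.numeric(p[2:4]))
    tc <- do.call(rbind, nums)
    if (any(!is.finite(tc))) stop("read_mesh: non-numeric vertex in STL")
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    invisible(readBin(con, "raw", 80))
    ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (!length(ntri) || is.na(ntri) || ntri < 1 || sz != 84 + 50 * ntri)
      stop("read_mesh: corrupt binary STL header")
    tc <- matrix(NA_real_, ntri * 3L, 3L)
    for (i in seq_len(ntri)) {
      v <- readBin(con, "numeric", 12, size = 4, endian = "little")
      invisible(readBin(con, "integer", 1, size = 2, endian = "little"))
      tc[(i - 1L) * 3L + 1:3, ] <- matrix(v[4:12], 3, 3, byrow = TRUE)
    }
  }
  .soup_to_mesh(tc)
}

# merge coincident corners of a triangle soup into an indexed mesh
.soup_to_mesh <- function(tc) {
  key <- paste(tc[, 1], tc[, 2], tc[, 3], sep = "|")
  uid <- match(key, unique(key))
  V <- tc[!duplicated(key), , drop = FALSE]
  F <- matrix(uid, ncol = 3, byrow = TRUE)
  tri_mesh(V, F)
}

.write_ply_ascii <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0", "comment units mm",
               paste("element vertex", nrow(mesh$vertices)),
               "property double x", "property double y", "property double z",
               paste("element face", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.12g %.12g %.12g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                     mesh$faces[, 3] - 1L), con)
}

.write_ply_bin <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("ply", "format binary_little_endian 1.0", "comment units mm",
               paste("element vertex", nrow(mesh$vertices)),
               "property double x", "property double y", "property double z",
               paste("element face", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"),
             con, sep = "\n")
  writeBin(as.numeric(t(mesh$vertices)), con, size = 8, endian = "little")
  for (i in seq_len(nrow(mesh$faces))) {
    writeBin(as.raw(3), con)
    writeBin(as.integer(mesh$faces[i, ] - 1L), con, size = 4, endian = "little")
  }
}

.read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    line <- .read_bin_line(con)
    if (is.null(line)) stop("read_mesh: corrupt PLY header (no end_header)")
    header <- c(header, line)
    if (line == "end_header") break
    if (length(header) > 200) stop("read_mesh: corrupt PLY header")
  }
  if (header[1] != "ply") stop("read_mesh: not a PLY file")
  fmt <- grep("^format ", header, value = TRUE)
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", header,
                                                   value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", header,
                                                 value = TRUE)))
  if (!length(nv) || !length(nf) || is.na(nv) || is.na(nf))
    stop("read_mesh: corrupt PLY header (missing element counts)")
  vprops <- grep("^property (double|float)", header, value = TRUE)
  vsize <- ifelse(grepl("double", vprops), 8L, 4L)
  if (grepl("ascii", fmt)) {
    rest <- strsplit(rawToChar(readBin(con, "raw", file.info(path)$size)),
                     "\n", fixed = TRUE)[[1]]
    rest <- rest[nzchar(trimws(rest))]
    V <- do.call(rbind, lapply(strsplit(trimws(rest[seq_len(nv)]), "\\s+"),
                               function(p) as.numeric(p[1:3])))
    F <- do.call(rbind, lapply(strsplit(trimws(rest[nv + seq_len(nf)]), "\\s+"),
                               function(p) as.integer(p[2:4]) + 1L))
  } else {
    V <- matrix(NA_real_, nv, 3)
    for (i in seq_len(nv))
      for (k in 1:3)
        V[i, k] <- readBin(con, "numeric", 1, size = vsize[k], endian = "little")
    F <- matrix(NA_integer_, nf, 3)
    for (i in seq_len(nf)) {
      cnt <- as.integer(readBin(con, "raw", 1))
      if (cnt != 3L) stop("read_mesh: non-triangular PLY face")
      F[i, ] <- readBin(con, "integer", 3, size = 4, endian = "little") + 1L
    }
  }
  tri_mesh(V, F)
}

# read a LF-terminated text line from a binary connection
.read_bin_line <- function(con) {
  out <- raw(0)
  repeat {
    b <- readBin(con, "raw", 1)
    if (!length(b)) return(NULL)
    if (b == as.raw(10)) break
    out <- c(out, b)
  }
  sub("\r$", "", rawToChar(out))
}
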