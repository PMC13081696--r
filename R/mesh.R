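#' Triangulated surface mesh
#'
#' Light S3 container for a triangulated surface used throughout the package:
#' scalp and inner-boundary shells, folded source surfaces and candidate
#' sensor meshes. Vertices are in meters in a head-centered frame
#' (+z superior, +x right).
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates in meters.
#' @param faces integer matrix, m x 3, triangles as 1-based vertex indices.
#' @returns An object of class `surface_mesh`: a list with `vertices`,
#'   `faces` and `boundary` (logical per-vertex flag, `TRUE` on an open
#'   boundary rim; all `FALSE` for a closed surface).
#' @examples
#' m <- make_sphere_mesh(0.09, 2)
#' euler_characteristic(m)  # 2 for a closed surface
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix", call. = FALSE)
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix", call. = FALSE)
  if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range", call. = FALSE)
  if (any(!is.finite(vertices))) stop("non-finite vertex coordinates", call. = FALSE)
  areas <- triangle_areas(vertices, faces)
  if (any(areas <= 0)) stop("degenerate (zero-area) triangle in mesh", call. = FALSE)
  structure(
    list(vertices = vertices, faces = faces,
         boundary = boundary_vertex_flags(nrow(vertices), faces)),
    class = "surface_mesh"
  )
}

#' @exportS3Method base::print
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces, %s\n",
              nrow(x$vertices), nrow(x$faces),
              if (any(x$boundary)) sprintf("open (%d boundary vertices)", sum(x$boundary))
              else "closed"))
  invisible(x)
}

# Edge table with counts; boundary edges appear in exactly one face.
mesh_edges <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  list(edges = e, key = key, count = as.integer(cnt[key]))
}

boundary_vertex_flags <- function(n_vertices, faces) {
  flags <- logical(n_vertices)
  if (nrow(faces) == 0) return(flags)
  ed <- mesh_edges(faces)
  b <- ed$edges[ed$count == 1L, , drop = FALSE]
  flags[unique(as.vector(b))] <- TRUE
  flags
}

#' Euler characteristic of a mesh
#'
#' V - E + F; equals 2 for a closed genus-0 surface and 1 for a disk-like cap.
#' @param mesh a `surface_mesh`.
#' @returns integer.
#' @export
euler_characteristic <- function(mesh) {
  ed <- mesh_edges(mesh$faces)
  n_edges <- length(unique(paste(pmin(ed$edges[, 1], ed$edges[, 2]),
                                 pmax(ed$edges[, 1], ed$edges[, 2]))))
  nrow(mesh$vertices) - n_edges + nrow(mesh$faces)
}

#' Number of open boundary loops of a mesh
#'
#' @param mesh a `surface_mesh`.
#' @returns integer count of connected boundary cycles (0 for closed meshes).
#' @export
boundary_loop_count <- function(mesh) {
  ed <- mesh_edges(mesh$faces)
  b <- ed$edges[ed$count == 1L, , drop = FALSE]
  if (nrow(b) == 0) return(0L)
  g <- igraph::graph_from_edgelist(cbind(as.character(b[, 1]), as.character(b[, 2])),
                                   directed = FALSE)
  igraph::count_components(g)
}

triangle_areas <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c <- vertices[faces[, 3], , drop = FALSE]
  cr <- cross3(b - a, c - a)
  0.5 * sqrt(rowSums(cr^2))
}

face_normals <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c <- vertices[faces[, 3], , drop = FALSE]
  cr <- cross3(b - a, c - a)
  cr / sqrt(rowSums(cr^2))
}

#' Area-weighted outward vertex normals
#'
#' @param mesh a `surface_mesh` with consistently oriented faces.
#' @returns n x 3 matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  fn <- face_normals(mesh$vertices, mesh$faces)
  ar <- triangle_areas(mesh$vertices, mesh$faces)
  n <- matrix(0, nrow(mesh$vertices), 3)
  w <- fn * ar
  for (k in 1:3) {
    for (j in 1:3) {
      acc <- rowsum(w[, j], mesh$faces[, k])
      idx <- as.integer(rownames(acc))
      n[idx, j] <- n[idx, j] + acc[, 1]
    }
  }
  n / sqrt(rowSums(n^2))
}

# Row-wise cross product of two n x 3 matrices.
cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Exact distance from points to a triangulated surface
#'
#' Distance to the nearest point on any triangle (faces, edges and vertices
#' considered), not merely to the nearest mesh vertex. Used for the
#' source-exclusion rule near the inner boundary and for scalp projection,
#' where the threshold is comparable to mesh edge lengths.
#'
#' @param points numeric matrix, k x 3.
#' @param mesh a `surface_mesh`.
#' @returns list with `distance` (length k), `closest` (k x 3 closest surface
#'   points) and `face` (index of the nearest triangle).
#' @export
point_mesh_distance <- function(points, mesh) {
  points <- rbind3(points)
  k <- nrow(points)
  best_d2 <- rep(Inf, k)
  best_pt <- matrix(NA_real_, k, 3)
  best_face <- integer(k)
  V <- mesh$vertices
  F <- mesh$faces
  for (f in seq_len(nrow(F))) {
    cp <- closest_point_on_triangle(points, V[F[f, 1], ], V[F[f, 2], ], V[F[f, 3], ])
    d2 <- rowSums((points - cp)^2)
    upd <- d2 < best_d2
    if (any(upd)) {
      best_d2[upd] <- d2[upd]
      best_pt[upd, ] <- cp[upd, , drop = FALSE]
      best_face[upd] <- f
    }
  }
  list(distance = sqrt(best_d2), closest = best_pt, face = best_face)
}

# Vectorized closest point on one triangle (a, b, c) for many query points.
# Plane projection when the projection falls inside; otherwise the best of
# the three clamped edge projections.
closest_point_on_triangle <- function(p, a, b, c) {
  k <- nrow(p)
  ab <- b - a; ac <- c - a
  n <- c(ab[2] * ac[3] - ab[3] * ac[2],
         ab[3] * ac[1] - ab[1] * ac[3],
         ab[1] * ac[2] - ab[2] * ac[1])
  n2 <- sum(n^2)
  ap <- sweep(p, 2, a)
  dist_plane <- drop(ap %*% n) / sqrt(n2)
  proj <- p - outer(dist_plane, n / sqrt(n2))
  # barycentric coordinates of the projection
  d00 <- sum(ab * ab); d01 <- sum(ab * ac); d11 <- sum(ac * ac)
  vp <- sweep(proj, 2, a)
  d20 <- drop(vp %*% ab); d21 <- drop(vp %*% ac)
  den <- d00 * d11 - d01 * d01
  v <- (d11 * d20 - d01 * d21) / den
  w <- (d00 * d21 - d01 * d20) / den
  inside <- v >= 0 & w >= 0 & (v + w) <= 1
  out <- proj
  if (!all(inside)) {
    idx <- which(!inside)
    q <- p[idx, , drop = FALSE]
    e1 <- closest_point_on_segment(q, a, b)
    e2 <- closest_point_on_segment(q, b, c)
    e3 <- closest_point_on_segment(q, a, c)
    d1 <- rowSums((q - e1)^2); d2 <- rowSums((q - e2)^2); d3 <- rowSums((q - e3)^2)
    pick <- e1
    m2 <- d2 < d1
    pick[m2, ] <- e2[m2, , drop = FALSE]
    m3 <- d3 < pmin(d1, d2)
    pick[m3, ] <- e3[m3, , drop = FALSE]
    out[idx, ] <- pick
  }
  out
}

closest_point_on_segment <- function(p, a, b) {
  d <- b - a
  t <- drop(sweep(p, 2, a) %*% d) / sum(d * d)
  t <- pmin(pmax(t, 0), 1)
  sweep(outer(t, d), 2, a, `+`)
}

# Coerce a 3-vector or k x 3 matrix to matrix form.
rbind3 <- function(x) {
  if (is.null(dim(x))) {
    stopifnot(length(x) == 3L)
    matrix(as.numeric(x), 1, 3)
  } else {
    x <- as.matrix(x)
    stopifnot(ncol(x) == 3L)
    storage.mode(x) <- "double"
    x
  }
}

#' Regular grid mesh on a rectangle
#'
#' A structured triangulation of `[0, lx] x [0, ly]` in the z = 0 plane,
#' useful as a flat test surface for geodesic and Laplacian computations.
#'
#' @param nx,ny number of vertices along x and y.
#' @param lx,ly side lengths in meters.
#' @returns a `surface_mesh` with `nx * ny` vertices.
#' @export
make_grid_mesh <- function(nx, ny, lx = 1, ly = 1) {
  xs <- seq(0, lx, length.out = nx)
  ys <- seq(0, ly, length.out = ny)
  v <- cbind(rep(xs, times = ny), rep(ys, each = nx), 0)
  id <- function(i, j) (j - 1L) * nx + i
  f <- list()
  for (j in seq_len(ny - 1)) {
    i <- seq_len(nx - 1)
    f[[j]] <- rbind(cbind(id(i, j), id(i + 1, j), id(i, j + 1)),
                    cbind(id(i + 1, j), id(i + 1, j + 1), id(i, j + 1)))
  }
  surface_mesh(v, do.call(rbind, f))
}

#' Write / read a surface mesh as ASCII PLY
#'
#' Plain-text PLY with vertex and face elements; coordinates in meters.
#'
#' @param mesh a `surface_mesh`.
#' @param path file path.
#' @returns `write_ply` returns `path` invisibly; `read_ply` a `surface_mesh`.
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0",
    sprintf("element vertex %d", nrow(mesh$vertices)),
    "property double x", "property double y", "property double z",
    sprintf("element face %d", nrow(mesh$faces)),
    "property list uchar int vertex_indices", "end_header"), con)
  utils::write.table(format(mesh$vertices, digits = 17, scientific = TRUE, trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, mesh$faces - 1L), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "ply") stop("not a PLY file", call. = FALSE)
  hdr_end <- match("end_header", lines)
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)))
  vlines <- lines[(hdr_end + 1):(hdr_end + nv)]
  flines <- lines[(hdr_end + nv + 1):(hdr_end + nv + nf)]
  v <- matrix(as.numeric(unlist(strsplit(vlines, "[[:space:]]+"))), ncol = 3, byrow = TRUE)
  f <- matrix(as.integer(unlist(strsplit(flines, "[[:space:]]+"))), ncol = 4, byrow = TRUE)
  surface_mesh(v, f[, 2:4] + 1L)
}

#' Write / read a FreeSurfer binary triangle surface
#'
#' The classic FreeSurfer triangle-file format (magic 0xFFFFFE, big-endian
#' float vertices and int faces). Coordinates are written in millimeters, the
#' FreeSurfer convention, and converted back to meters on read.
#'
#' @param mesh a `surface_mesh`.
#' @param path file path.
#' @returns `write_fs_surface` returns `path` invisibly; `read_fs_surface` a
#'   `surface_mesh`.
#' @export
write_fs_surface <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0xff, 0xff, 0xfe)), con)
  writeChar("created by megarray\n\n", con, eos = NULL)
  writeBin(as.integer(nrow(mesh$vertices)), con, size = 4, endian = "big")
  writeBin(as.integer(nrow(mesh$faces)), con, size = 4, endian = "big")
  writeBin(as.numeric(t(mesh$vertices * 1000)), con, size = 4, endian = "big")
  writeBin(as.integer(t(mesh$faces - 1L)), con, size = 4, endian = "big")
  invisible(path)
}

#' @rdname write_fs_surface
#' @export
read_fs_surface <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3)
  if (!identical(as.integer(magic), c(255L, 255L, 254L)))
    stop("not a FreeSurfer triangle surface", call. = FALSE)
  # comment terminated by "\n\n"
  prev <- as.raw(0)
  repeat {
    b <- readBin(con, "raw", 1)
    if (length(b) == 0) stop("truncated FreeSurfer surface", call. = FALSE)
    if (prev == as.raw(10) && b == as.raw(10)) break
    prev <- b
  }
  nv <- readBin(con, "integer", 1, size = 4, endian = "big")
  nf <- readBin(con, "integer", 1, size = 4, endian = "big")
  v <- matrix(readBin(con, "numeric", nv * 3, size = 4, endian = "big"),
              ncol = 3, byrow = TRUE) / 1000
  f <- matrix(readBin(con, "integer", nf * 3, size = 4, endian = "big"),
              ncol = 3, byrow = TRUE) + 1L
  surface_mesh(v, f)
}
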