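# ---- 2D Delaunay (Bowyer-Watson) ----
# Incremental Delaunay triangulation of a 2D point set. Adequate for the
# few-hundred-point helmet seed sets triangulated here; no installed R
# package provides Delaunay in this environment.
delaunay2d <- function(pts) {
  n <- nrow(pts)
  if (n < 3) stop("need at least 3 points", call. = FALSE)
  rng <- apply(pts, 2, range)
  d <- max(rng[2, ] - rng[1, ])
  cx <- mean(rng[, 1]); cy <- mean(rng[, 2])
  # super-triangle
  P <- rbind(pts, c(cx - 20 * d, cy - d), c(cx + 20 * d, cy - d), c(cx, cy + 20 * d))
  sv <- n + 1:3
  tris <- list(sv)
  circum <- list(circumcircle(P[sv[1], ], P[sv[2], ], P[sv[3], ]))
  for (i in seq_len(n)) {
    p <- pts[i, ]
    bad <- which(vapply(circum, function(cc) {
      (p[1] - cc[1])^2 + (p[2] - cc[2])^2 < cc[3] * (1 + 1e-12)
    }, logical(1)))
    if (length(bad) == 0) stop("Delaunay insertion failed (degenerate input?)", call. = FALSE)
    # boundary of the cavity: edges appearing exactly once among bad triangles
    edges <- do.call(rbind, lapply(tris[bad], function(t)
      rbind(sort(t[c(1, 2)]), sort(t[c(2, 3)]), sort(t[c(1, 3)]))))
    key <- paste(edges[, 1], edges[, 2])
    keep <- key[!(key %in% key[duplicated(key)])]
    poly <- edges[match(keep, key), , drop = FALSE]
    tris[bad] <- NULL
    circum[bad] <- NULL
    for (e in seq_len(nrow(poly))) {
      t <- c(poly[e, 1], poly[e, 2], i)
      cc <- circumcircle(P[t[1], ], P[t[2], ], P[t[3], ])
      tris[[length(tris) + 1]] <- t
      circum[[length(circum) + 1]] <- cc
    }
  }
  tri <- do.call(rbind, tris)
  tri <- tri[rowSums(matrix(tri %in% sv, ncol = 3)) == 0, , drop = FALSE]
  # consistent orientation (counter-clockwise in the plane)
  a <- pts[tri[, 1], ]; b <- pts[tri[, 2], ]; c <- pts[tri[, 3], ]
  cwise <- (b[, 1] - a[, 1]) * (c[, 2] - a[, 2]) -
           (b[, 2] - a[, 2]) * (c[, 1] - a[, 1]) < 0
  tri[cwise, ] <- tri[cwise, c(1, 3, 2)]
  tri
}

circumcircle <- function(a, b, c) {
  ax <- a[1]; ay <- a[2]; bx <- b[1]; by <- b[2]; cx <- c[1]; cy <- c[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-300) return(c(Inf, Inf, Inf))
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  c(ux, uy, (ax - ux)^2 + (ay - uy)^2)
}

#' Candidate sensor mesh from helmet seed positions
#'
#' Triangulates the seed positions (2D Delaunay on a stereographic projection
#' of the cap, taken from the antipode of the mean seed direction) and
#' midpoint-subdivides until the vertex count reaches `target_vertices`.
#' When a scalp mesh is supplied, subdivided vertices are re-projected onto
#' the constant-standoff surface above the scalp.
#'
#' @param seed_positions k x 3 matrix of sensor positions (at their standoff).
#' @param target_vertices minimum vertex count after subdivision
#'   (default 5821-vertex scale of dense whole-head candidate sets).
#' @param scalp optional `surface_mesh` for standoff re-projection.
#' @param standoff standoff distance, m; default: mean scalp distance of the
#'   seed positions.
#' @returns an object of class `candidate_mesh`: a `surface_mesh` plus
#'   `embedding` (filled by [laplace_embedding()]) and `standoff`.
#' @export
build_candidate_mesh <- function(seed_positions, target_vertices = 5821,
                                 scalp = NULL, standoff = NULL) {
  pos <- rbind3(seed_positions)
  if (nrow(pos) < 4) stop("need at least 4 positions", call. = FALSE)
  ctr <- colMeans(pos / sqrt(rowSums(pos^2)))
  if (sqrt(sum(ctr^2)) < 1e-9) stop("degenerate seed directions", call. = FALSE)
  frame <- local_frame(ctr)
  loc <- pos %*% frame                    # local coords, +z towards cap center
  u <- sweep(loc, 1, sqrt(rowSums(loc^2)), `/`)
  if (any(u[, 3] <= -0.95))
    stop("seed positions wrap past the projection antipode", call. = FALSE)
  st2d <- cbind(u[, 1] / (1 + u[, 3]), u[, 2] / (1 + u[, 3]))
  sv <- svd(scale(st2d, center = TRUE, scale = FALSE), nu = 0, nv = 0)$d
  if (sv[2] < 1e-9 * max(sv[1], 1e-300))
    stop("degenerate seed positions (collinear directions)", call. = FALSE)
  tri <- delaunay2d(st2d)
  if (nrow(tri) == 0) stop("degenerate seed positions", call. = FALSE)
  v <- pos
  f <- tri
  if (!is.null(scalp) && is.null(standoff))
    standoff <- mean(point_mesh_distance(pos, scalp)$distance)
  reproject <- function(vv) {
    if (is.null(scalp)) return(vv)
    pr <- point_mesh_distance(vv, scalp)
    pr$closest + standoff * outward_normals_at(scalp, pr, vv)
  }
  while (nrow(v) < target_vertices) {
    sub <- subdivide_midpoint(v, f)
    new_idx <- (nrow(v) + 1):nrow(sub$vertices)
    sub$vertices[new_idx, ] <- reproject(sub$vertices[new_idx, , drop = FALSE])
    v <- sub$vertices
    f <- sub$faces
  }
  mesh <- surface_mesh(v, f)
  structure(c(mesh, list(embedding = NULL, eigenvalues = NULL, standoff = standoff)),
            class = c("candidate_mesh", "surface_mesh"))
}

# ---- FEM Laplacian ----

# Cotangent stiffness matrix and lumped (barycentric) mass matrix.
cotan_laplacian <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  i1 <- F[, 1]; i2 <- F[, 2]; i3 <- F[, 3]
  cot_at <- function(a, b, c) {   # cotangent of angle at vertex a
    u <- V[b, , drop = FALSE] - V[a, , drop = FALSE]
    w <- V[c, , drop = FALSE] - V[a, , drop = FALSE]
    rowSums(u * w) / sqrt(rowSums(cross3(u, w)^2))
  }
  c1 <- cot_at(i1, i2, i3); c2 <- cot_at(i2, i3, i1); c3 <- cot_at(i3, i1, i2)
  ii <- c(i2, i3, i3, i1, i1, i2)
  jj <- c(i3, i2, i1, i3, i2, i1)
  vv <- 0.5 * c(c1, c1, c2, c2, c3, c3)
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = rep(nrow(V), 2))
  K <- Matrix::Diagonal(x = Matrix::rowSums(W)) - W
  ar <- triangle_areas(V, F)
  m <- numeric(nrow(V))
  for (k in 1:3) {
    acc <- rowsum(ar / 3, F[, k])
    m[as.integer(rownames(acc))] <- m[as.integer(rownames(acc))] + acc[, 1]
  }
  list(K = K, M = m)
}

#' Smallest eigenpairs of a generalized symmetric problem
#'
#' Solves `K x = lambda diag(m) x` for the `n` smallest eigenvalues, the
#' solver behind [laplace_embedding()]. Uses dense symmetric
#' eigendecomposition for small problems and ARPACK shift-invert otherwise.
#'
#' @param K symmetric positive-definite sparse (or dense) matrix.
#' @param m positive lumped-mass vector (length = nrow(K)); use 1s for a
#'   plain graph Laplacian.
#' @param n number of eigenpairs.
#' @returns list with `values` (ascending) and `vectors` (columns,
#'   mass-orthonormal: `t(V) diag(m) V = I`).
#' @export
laplace_eigenpairs <- function(K, m, n) {
  N <- nrow(K)
  if (n >= N) stop("n must be smaller than the matrix dimension", call. = FALSE)
  s <- 1 / sqrt(m)
  A <- Matrix::Diagonal(x = s) %*% K %*% Matrix::Diagonal(x = s)
  A <- Matrix::forceSymmetric(A)
  if (N <= 600 || n > N / 3) {
    e <- eigen(as.matrix(A), symmetric = TRUE)
    idx <- order(e$values)[seq_len(n)]
    vals <- e$values[idx]
    vecs <- e$vectors[, idx, drop = FALSE]
  } else {
    ch <- Matrix::Cholesky(as(A, "CsparseMatrix"), LDL = FALSE, perm = TRUE)
    f <- function(x, extra) as.numeric(Matrix::solve(ch, x, system = "A"))
    res <- igraph::arpack(f, sym = TRUE,
                          options = list(n = N, nev = n,
                                         ncv = min(N, max(2 * n + 1, 20)),
                                         which = "LM", maxiter = 10000))
    vals <- 1 / res$values
    ord <- order(vals)
    vals <- vals[ord]
    vecs <- res$vectors[, ord, drop = FALSE]
  }
  vecs <- vecs * s   # back-transform: x = M^{-1/2} y, mass-orthonormal
  list(values = vals, vectors = vecs)
}

#' Dirichlet Laplace eigen-embedding of a candidate mesh
#'
#' First `n_basis` eigenfunctions of the mesh Laplacian (cotangent stiffness,
#' lumped mass) with zero Dirichlet values on the open boundary, each scaled
#' to unit variance over the interior vertices; eigenvalues ascending, sign
#' fixed so the largest-magnitude entry is positive. The embedding gives
#' every candidate vertex smooth, boundary-aware coordinates in which
#' Euclidean distances drive farthest-point sampling.
#'
#' @param mesh a `candidate_mesh` (or any `surface_mesh` with a boundary).
#' @param n_basis number of eigenfunctions (default 100); must be smaller
#'   than the interior vertex count.
#' @returns the mesh with `embedding` (vertices x n_basis matrix, zero rows
#'   on the boundary) and `eigenvalues` filled in.
#' @export
laplace_embedding <- function(mesh, n_basis = 100) {
  interior <- which(!mesh$boundary)
  if (length(interior) == 0) stop("mesh has no interior (Dirichlet) vertices", call. = FALSE)
  if (n_basis >= length(interior))
    stop("n_basis must be smaller than the interior vertex count", call. = FALSE)
  g <- mesh_graph(mesh)
  comp <- igraph::components(igraph::induced_subgraph(g, interior))
  if (comp$no > 1) stop("disconnected interior", call. = FALSE)
  lap <- cotan_laplacian(mesh)
  Kii <- lap$K[interior, interior]
  mii <- lap$M[interior]
  e <- laplace_eigenpairs(Kii, mii, n_basis)
  emb <- matrix(0, nrow(mesh$vertices), n_basis)
  v <- e$vectors
  # unit variance over interior vertices, deterministic sign
  v <- sweep(v, 2, sqrt(colMeans(v^2)), `/`)
  sgn <- apply(v, 2, function(col) sign(col[which.max(abs(col))]))
  v <- sweep(v, 2, sgn, `*`)
  emb[interior, ] <- v
  mesh$embedding <- emb
  mesh$eigenvalues <- e$values
  mesh
}

# Edge-weighted igraph of a mesh (weights = Euclidean edge lengths).
mesh_graph <- function(mesh) {
  ed <- mesh_edges(mesh$faces)
  e <- unique(cbind(pmin(ed$edges[, 1], ed$edges[, 2]),
                    pmax(ed$edges[, 1], ed$edges[, 2])))
  w <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                     mesh$vertices[e[, 2], , drop = FALSE])^2))
  igraph::graph_from_edgelist(e, directed = FALSE) |>
    igraph::set_edge_attr("weight", value = w)
}

#' Farthest-point sampling
#'
#' Greedy maximin selection: starting from a seed vertex, repeatedly pick the
#' vertex farthest (Euclidean distance in the embedding) from the already
#' selected set. The greedy prefix property makes samples nested: the first
#' k points of a (k+1)-sample are the k-sample.
#'
#' @param x a `candidate_mesh` with a computed embedding, or a plain numeric
#'   matrix of embedding coordinates (rows = candidates).
#' @param k number of points to select.
#' @param start_rule either an integer start index or
#'   `"max_boundary_distance"` (default; the interior vertex with maximal
#'   graph distance to the mesh boundary — requires a mesh input).
#' @returns integer vector of selected row indices, in selection order.
#' @export
farthest_point_sample <- function(x, k, start_rule = "max_boundary_distance") {
  if (inherits(x, "candidate_mesh")) {
    emb <- x$embedding
    if (is.null(emb)) stop("candidate mesh has no embedding; run laplace_embedding()",
                           call. = FALSE)
    if (identical(start_rule, "max_boundary_distance")) {
      g <- mesh_graph(x)
      b <- which(x$boundary)
      d <- igraph::distances(g, v = b, weights = NA)  # hop distance
      dmin <- apply(d, 2, min)
      start <- which.max(dmin)
    } else start <- as.integer(start_rule)
  } else {
    emb <- as.matrix(x)
    if (identical(start_rule, "max_boundary_distance"))
      stop("start_rule 'max_boundary_distance' needs a candidate mesh", call. = FALSE)
    start <- as.integer(start_rule)
  }
  n <- nrow(emb)
  if (k < 1 || k > n) stop("k must be between 1 and the number of candidates", call. = FALSE)
  sel <- integer(k)
  sel[1] <- start
  d2 <- rowSums(sweep(emb, 2, emb[start, ])^2)
  for (j in seq_len(k - 1)) {
    nxt <- which.max(d2)
    sel[j + 1] <- nxt
    d2 <- pmin(d2, rowSums(sweep(emb, 2, emb[nxt, ])^2))
  }
  sel
}

#' Uniform sensor array of arbitrary count
#'
#' Composition of [build_candidate_mesh()], [laplace_embedding()],
#' [farthest_point_sample()] and [project_to_scalp()]: selects `k`
#' quasi-uniformly spread positions from a dense candidate mesh at the
#' sensor type's standoff and turns them into a `sensor_array`.
#'
#' @param scalp scalp `surface_mesh`.
#' @param helmet_seed_positions seed positions spanning the coverage region
#'   (e.g. [helmet_seed_positions()]).
#' @param k sensor count.
#' @param sensor_type `"opm"`, `"squid_mag"` or `"squid_axial_grad"`.
#' @param channel_mode channel mode for the resulting array.
#' @param candidate optionally a precomputed embedded `candidate_mesh`
#'   (reused across counts; must match scalp/standoff).
#' @param target_vertices,n_basis candidate mesh size and embedding dimension.
#' @returns a `sensor_array` named `uniform_<type>_<k>`.
#' @export
make_uniform_array <- function(scalp, helmet_seed_positions, k,
                               sensor_type = "opm", channel_mode = "single_axis",
                               candidate = NULL, target_vertices = 5821,
                               n_basis = 100) {
  standoff <- default_standoff(sensor_type)
  if (is.null(candidate)) {
    seeds <- project_to_scalp(helmet_seed_positions, scalp, standoff = standoff)
    candidate <- build_candidate_mesh(sensor_positions(seeds), target_vertices,
                                      scalp = scalp, standoff = standoff)
    candidate <- laplace_embedding(candidate, n_basis = n_basis)
  }
  idx <- farthest_point_sample(candidate, k)
  arr <- project_to_scalp(candidate$vertices[idx, , drop = FALSE], scalp,
                          standoff = standoff, sensor_type = sensor_type,
                          channel_mode = channel_mode,
                          name = sprintf("uniform_%s_%d", sensor_type, k))
  arr
}
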