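# Independent oracles used to check the package's computations. These stay
# deliberately separate from the implementation paths they verify.

# ---- surface potential of a dipole in a homogeneous conducting sphere ----
# Legendre series solution with an insulating exterior (Neumann boundary).
# Moment is decomposed into radial and tangential parts about the dipole
# axis; P_n^1 without the Condon-Shortley phase.
legendre_p <- function(nmax, x) {
  P <- matrix(0, nmax + 1, length(x))
  P[1, ] <- 1
  if (nmax >= 1) P[2, ] <- x
  for (n in 1:(nmax - 1)) P[n + 2, ] <- ((2 * n + 1) * x * P[n + 1, ] - n * P[n, ]) / (n + 1)
  P
}

legendre_p1 <- function(nmax, x) {
  s <- sqrt(pmax(0, 1 - x^2))
  P1 <- matrix(0, nmax + 1, length(x))   # row n+1 holds P_n^1
  if (nmax >= 1) P1[2, ] <- s
  if (nmax >= 2) P1[3, ] <- 3 * x * s
  if (nmax >= 3) for (n in 2:(nmax - 1))
    P1[n + 2, ] <- ((2 * n + 1) * x * P1[n + 1, ] - (n + 1) * P1[n, ]) / n
  P1
}

# Potential at points `r` (k x 3) for a dipole (q, at r0) inside a
# homogeneous sphere radius R, conductivity sigma. `surface = TRUE` gives the
# Neumann-corrected surface potential; FALSE the infinite-medium series
# (for validating the expansion against the closed form).
sphere_potential_series <- function(r, r0, q, R, sigma = 0.3, nmax = 120,
                                    surface = TRUE) {
  b <- sqrt(sum(r0^2))
  zhat <- r0 / b
  q_r <- sum(q * zhat)
  t_vec <- q - q_r * zhat
  q_t <- sqrt(sum(t_vec^2))
  that <- if (q_t > 1e-300) t_vec / q_t else c(0, 0, 0)
  yhat <- c(zhat[2] * that[3] - zhat[3] * that[2],
            zhat[3] * that[1] - zhat[1] * that[3],
            zhat[1] * that[2] - zhat[2] * that[1])
  rn <- sqrt(rowSums(r^2))
  cg <- drop(r %*% zhat) / rn
  cphi <- drop(r %*% that) / pmax(rn * sqrt(pmax(0, 1 - cg^2)), 1e-300)
  P <- legendre_p(nmax, cg)
  P1 <- legendre_p1(nmax, cg)
  V <- numeric(nrow(r))
  for (n in 1:nmax) {
    radial_fac <- if (surface) (2 * n + 1) / (n * R^(n + 1)) else 1 / rn^(n + 1)
    V <- V + radial_fac * b^(n - 1) * (n * q_r * P[n + 1, ] + q_t * cphi * P1[n + 1, ])
  }
  V / (4 * pi * sigma)
}

# ---- Geselowitz single-layer quadrature oracle for the magnetic field ----
# B(r) = B_primary(r) - mu0 sigma / 4pi * sum_t V(c_t) n_t x (r - c_t)/|r - c_t|^3 dS_t
# over a dense spherical boundary mesh; V from the series above.
.oracle_mesh_cache <- new.env(parent = emptyenv())

oracle_field_single_layer <- function(dipole_position, dipole_moment, field_point,
                                      R = 0.09, sigma = 0.3, subdivision = 3) {
  key <- paste0("m", R, "_", subdivision)
  if (!exists(key, envir = .oracle_mesh_cache))
    assign(key, make_sphere_mesh(R, subdivision), envir = .oracle_mesh_cache)
  mesh <- get(key, envir = .oracle_mesh_cache)
  cent <- (mesh$vertices[mesh$faces[, 1], ] + mesh$vertices[mesh$faces[, 2], ] +
             mesh$vertices[mesh$faces[, 3], ]) / 3
  cent <- cent * R / sqrt(rowSums(cent^2))   # push centroids onto the sphere
  areas <- megarray:::triangle_areas(mesh$vertices, mesh$faces)
  nhat <- cent / R
  V <- sphere_potential_series(cent, dipole_position, dipole_moment, R, sigma)
  d <- sweep(-cent, 2, field_point, `+`)     # r - c_t
  d3 <- rowSums(d^2)^1.5
  integrand <- megarray:::cross3(nhat, d / d3) * (V * areas)
  B_second <- -1e-7 * sigma * colSums(integrand)
  rr <- field_point - dipole_position
  B_prim <- 1e-7 * megarray:::cross3(matrix(dipole_moment, 1, 3),
                                     matrix(rr, 1, 3))[1, ] / sum(rr^2)^1.5
  B_prim + B_second
}

# ---- principal angles via projector products ----
oracle_principal_cosines <- function(A, B) {
  qa <- qr(A); qb <- qr(B)
  Ua <- qr.Q(qa)[, seq_len(qa$rank), drop = FALSE]
  Ub <- qr.Q(qb)[, seq_len(qb$rank), drop = FALSE]
  Pa <- tcrossprod(Ua); Pb <- tcrossprod(Ub)
  ev <- eigen(Pa %*% Pb, only.values = TRUE)$values
  ev <- sort(pmax(0, pmin(1, Re(ev))), decreasing = TRUE)
  sqrt(ev[seq_len(min(qa$rank, qb$rank))])
}

# ---- plain O(n^2) Dijkstra on a mesh ----
oracle_dijkstra <- function(mesh, from) {
  ed <- megarray:::mesh_edges(mesh$faces)
  e <- unique(cbind(pmin(ed$edges[, 1], ed$edges[, 2]),
                    pmax(ed$edges[, 1], ed$edges[, 2])))
  w <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                     mesh$vertices[e[, 2], , drop = FALSE])^2))
  n <- nrow(mesh$vertices)
  adj <- vector("list", n)
  for (k in seq_len(nrow(e))) {
    adj[[e[k, 1]]] <- rbind(adj[[e[k, 1]]], c(e[k, 2], w[k]))
    adj[[e[k, 2]]] <- rbind(adj[[e[k, 2]]], c(e[k, 1], w[k]))
  }
  dist <- rep(Inf, n); dist[from] <- 0
  done <- logical(n)
  repeat {
    u <- which(!done & is.finite(dist))
    if (length(u) == 0) break
    u <- u[which.min(dist[u])]
    done[u] <- TRUE
    for (k in seq_len(NROW(adj[[u]]))) {
      v <- adj[[u]][k, 1]; wd <- dist[u] + adj[[u]][k, 2]
      if (wd < dist[v]) dist[v] <- wd
    }
  }
  dist
}

# ---- brute-force point-to-triangle distance via barycentric sampling ----
oracle_point_triangle_distance <- function(p, a, b, c, n_grid = 120) {
  u <- seq(0, 1, length.out = n_grid)
  g <- expand.grid(u = u, v = u)
  g <- g[g$u + g$v <= 1, ]
  pts <- outer(1 - g$u - g$v, a) + outer(g$u, b) + outer(g$v, c)
  min(sqrt(rowSums(sweep(pts, 2, p)^2)))
}

# ---- exhaustive maximin subset search (small cases only) ----
oracle_maximin_subset <- function(pts, k, must_include = NULL) {
  n <- nrow(pts)
  idx <- setdiff(seq_len(n), must_include)
  combs <- utils::combn(idx, k - length(must_include))
  best <- -Inf; best_set <- NULL
  D <- as.matrix(stats::dist(pts))
  for (j in seq_len(ncol(combs))) {
    s <- c(must_include, combs[, j])
    m <- min(D[s, s][upper.tri(diag(length(s)))])
    if (m > best) { best <- m; best_set <- s }
  }
  list(set = sort(best_set), min_distance = best)
}

# Random rotation matrix from a fixed seed.
random_rotation <- function(seed) {
  set.seed(seed)
  qrd <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(qrd)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
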