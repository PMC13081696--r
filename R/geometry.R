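#' @importFrom rlang .data
NULL

# Run code with a temporary RNG state seeded by `seed`, restoring the
# caller's stream afterwards so generators are pure functions of (config, seed).
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Icosphere mesh
#'
#' Closed triangulated sphere built by midpoint subdivision of an icosahedron,
#' with all vertices projected onto the sphere. Vertex count is
#' `10 * 4^level + 2` (12, 42, 162, 642, 2562, ...).
#'
#' @param radius sphere radius in meters (> 0).
#' @param subdivision_level non-negative integer; 4 gives the 2562-vertex
#'   shells used for the head compartment surfaces.
#' @returns a closed `surface_mesh` centered at the origin.
#' @export
make_sphere_mesh <- function(radius, subdivision_level = 0L) {
  if (!is.numeric(radius) || length(radius) != 1 || radius <= 0)
    stop("radius must be a positive number", call. = FALSE)
  if (subdivision_level < 0) stop("subdivision_level must be >= 0", call. = FALSE)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(subdivision_level)) {
    sub <- subdivide_midpoint(v, f)
    v <- sub$vertices / sqrt(rowSums(sub$vertices^2))
    f <- sub$faces
  }
  surface_mesh(v * radius, f)
}

# One round of midpoint (1-to-4) subdivision with shared-edge vertex reuse.
subdivide_midpoint <- function(v, f) {
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  k <- key(e[, 1], e[, 2])
  uk <- unique(k)
  mid_id <- stats::setNames(seq_along(uk) + nrow(v), uk)
  pair <- do.call(rbind, strsplit(uk, " "))
  mids <- (v[as.integer(pair[, 1]), , drop = FALSE] +
           v[as.integer(pair[, 2]), , drop = FALSE]) / 2
  m12 <- mid_id[key(f[, 1], f[, 2])]
  m23 <- mid_id[key(f[, 2], f[, 3])]
  m31 <- mid_id[key(f[, 3], f[, 1])]
  faces <- rbind(cbind(f[, 1], m12, m31),
                 cbind(f[, 2], m23, m12),
                 cbind(f[, 3], m31, m23),
                 cbind(m12, m23, m31))
  list(vertices = rbind(v, mids), faces = unname(faces))
}

# Orthonormal frame with third axis along `z` (unit 3-vector).
local_frame <- function(z) {
  z <- z / sqrt(sum(z^2))
  ref <- if (abs(z[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  x <- ref - sum(ref * z) * z
  x <- x / sqrt(sum(x^2))
  y <- c(z[2] * x[3] - z[3] * x[2], z[3] * x[1] - z[1] * x[3], z[1] * x[2] - z[2] * x[1])
  cbind(x, y, z)
}

# Triangulated spherical-cap parameter grid: concentric rings of 6*i points
# around a center vertex, polar angle up to `theta_max`. Returns the (theta,
# phi) parameters and the face table; faces are oriented so normals point
# away from the sphere center.
cap_parameter_mesh <- function(n_rings, theta_max) {
  theta <- c(0, rep(theta_max * seq_len(n_rings) / n_rings, times = 6 * seq_len(n_rings)))
  phi <- c(0, unlist(lapply(seq_len(n_rings), function(i) 2 * pi * (0:(6 * i - 1)) / (6 * i))))
  ring_of <- c(0L, rep(seq_len(n_rings), times = 6 * seq_len(n_rings)))
  first <- vapply(0:n_rings, function(i) match(i, ring_of), integer(1))
  faces <- list()
  for (i in seq_len(n_rings)) {
    m1 <- if (i == 1) 1L else 6L * (i - 1L)
    m2 <- 6L * i
    i1 <- first[i]; i2 <- first[i + 1]
    a1 <- phi[i1:(i1 + m1 - 1)]
    a2 <- phi[i2:(i2 + m2 - 1)]
    # two-pointer sweep over the annulus between ring i-1 and ring i
    p1 <- 0L; p2 <- 0L
    tri <- matrix(0L, m1 + m2, 3)
    t_i <- 0L
    while (p1 < m1 || p2 < m2) {
      adv1 <- if (p1 >= m1) FALSE
        else if (p2 >= m2) TRUE
        else {
          n1 <- if (p1 + 1 < m1) a1[p1 + 2] else a1[1] + 2 * pi
          n2 <- if (p2 + 1 < m2) a2[p2 + 2] else a2[1] + 2 * pi
          n1 <= n2
        }
      t_i <- t_i + 1L
      if (adv1) {
        tri[t_i, ] <- c(i1 + p1 %% m1, i2 + p2 %% m2, i1 + (p1 + 1) %% m1)
        p1 <- p1 + 1L
      } else {
        tri[t_i, ] <- c(i1 + p1 %% m1, i2 + p2 %% m2, i2 + (p2 + 1) %% m2)
        p2 <- p2 + 1L
      }
    }
    faces[[i]] <- tri[seq_len(t_i), , drop = FALSE]
  }
  faces <- do.call(rbind, faces)
  # drop degenerate fans at the center vertex (ring0 has m1 = 1: triangles
  # advancing p1 collapse); keep triangles with 3 distinct vertices
  ok <- faces[, 1] != faces[, 3] & faces[, 1] != faces[, 2] & faces[, 2] != faces[, 3]
  list(theta = theta, phi = phi, faces = faces[ok, , drop = FALSE],
       ring = ring_of)
}

#' Folded spherical-cap source surface
#'
#' A spherical cap perturbed radially by a seeded, band-limited pattern of
#' oriented sinusoidal modes. The perturbation frequency controls how fast
#' neighboring surface normals decorrelate, which in turn controls the field
#' cancellation that makes highly folded structures (cerebellum-like) hard to
#' measure; the amplitude controls fold depth. Dipoles are placed on interior
#' vertices, oriented along the recomputed outward mesh normals.
#'
#' @param base_radius cap sphere radius in meters.
#' @param fold_amplitude radial perturbation amplitude in meters
#'   (`0 <= fold_amplitude < base_radius / 4`); 0 gives an exact sphere cap.
#' @param fold_frequency integer >= 1, number of oscillation cycles across the
#'   cap diameter.
#' @param angular_extent polar half-angle of the cap in radians (> 0).
#' @param center_direction unit 3-vector; cap center direction from origin.
#' @param seed integer; the mode orientations and phases are drawn from this
#'   seed, so equal seeds give bit-identical surfaces.
#' @param n_rings mesh resolution (number of concentric vertex rings).
#' @param region label for the resulting source space.
#' @returns list with `mesh` (a `surface_mesh`) and `space` (a
#'   [source_space()]).
#' @export
make_folded_surface <- function(base_radius, fold_amplitude, fold_frequency,
                                angular_extent, center_direction, seed,
                                n_rings = 14L, region = "cortex") {
  if (angular_extent <= 0) stop("angular_extent must be positive", call. = FALSE)
  if (fold_amplitude < 0 || fold_amplitude >= base_radius / 4)
    stop("fold_amplitude must be in [0, base_radius/4)", call. = FALSE)
  if (fold_frequency < 1) stop("fold_frequency must be >= 1", call. = FALSE)
  par <- cap_parameter_mesh(n_rings, angular_extent)
  # azimuthal-equidistant cap coordinates, normalized to [-1, 1]
  u <- par$theta * cos(par$phi) / angular_extent
  v <- par$theta * sin(par$phi) / angular_extent
  pert <- numeric(length(u))
  if (fold_amplitude > 0) {
    n_modes <- 8L
    modes <- with_seed(seed, list(alpha = stats::runif(n_modes, 0, pi),
                                  phase = stats::runif(n_modes, 0, 2 * pi),
                                  amp = stats::runif(n_modes, 0.5, 1)))
    for (j in seq_len(n_modes)) {
      pert <- pert + modes$amp[j] *
        sin(pi * fold_frequency * (cos(modes$alpha[j]) * u + sin(modes$alpha[j]) * v) +
              modes$phase[j])
    }
    pert <- pert / max(abs(pert))
    # taper to zero at the cap rim for a clean boundary
    pert <- pert * cos(pi * par$theta / (2 * angular_extent))^2
  }
  r <- base_radius + fold_amplitude * pert
  frame <- local_frame(center_direction)
  dirs <- cbind(sin(par$theta) * cos(par$phi),
                sin(par$theta) * sin(par$phi),
                cos(par$theta)) %*% t(frame)
  mesh <- surface_mesh(dirs * r, par$faces)
  nrm <- vertex_normals(mesh)
  # enforce outward orientation (positive radial component on average)
  if (mean(rowSums(nrm * dirs)) < 0) {
    mesh$faces <- mesh$faces[, c(1, 3, 2)]
    nrm <- -nrm
  }
  # unperturbed cap: the surface is an exact sphere, so use exact radial
  # normals instead of the discretized mesh normals
  if (fold_amplitude == 0) nrm <- dirs
  interior <- which(!mesh$boundary)
  space <- source_space(positions = mesh$vertices[interior, , drop = FALSE],
                        normals = nrm[interior, , drop = FALSE],
                        region = region, vertex_ids = interior, parent_mesh = mesh)
  list(mesh = mesh, space = space)
}

#' Source space: dipoles on a surface
#'
#' @param positions k x 3 matrix of dipole positions in meters.
#' @param normals k x 3 matrix of unit dipole orientations (surface normals).
#' @param region single label, e.g. `"cortex"` or `"cerebellum"`.
#' @param vertex_ids integer vertex indices into `parent_mesh`.
#' @param parent_mesh the `surface_mesh` the dipoles sit on (optional).
#' @returns an object of class `source_space`.
#' @export
source_space <- function(positions, normals, region, vertex_ids = seq_len(nrow(positions)),
                         parent_mesh = NULL) {
  positions <- rbind3(positions)
  normals <- rbind3(normals)
  stopifnot(nrow(positions) == nrow(normals), length(vertex_ids) == nrow(positions))
  nn <- sqrt(rowSums(normals^2))
  if (nrow(normals) > 0 && any(abs(nn - 1) > 1e-9))
    normals <- normals / nn
  structure(list(positions = positions, normals = normals,
                 region = as.character(region)[1],
                 vertex_ids = as.integer(vertex_ids), parent_mesh = parent_mesh),
            class = "source_space")
}

#' @exportS3Method base::print
print.source_space <- function(x, ...) {
  cat(sprintf("<source_space> region '%s', %d dipoles\n", x$region, nrow(x$positions)))
  invisible(x)
}

#' @export
length.source_space <- function(x) nrow(x$positions)

#' Tidy view of a source space
#'
#' @param x a `source_space`.
#' @param ... unused.
#' @returns a tibble with one row per dipole: vertex id, region, position and
#'   normal components.
#' @export
as_tibble.source_space <- function(x, ...) {
  p <- x$positions
  n <- x$normals
  tibble::tibble(vertex_id = x$vertex_ids, region = x$region,
                 x = p[, 1], y = p[, 2], z = p[, 3],
                 nx = n[, 1], ny = n[, 2], nz = n[, 3])
}

# Subset a source space, preserving order.
subset_source_space <- function(space, idx) {
  source_space(space$positions[idx, , drop = FALSE],
               space$normals[idx, , drop = FALSE],
               space$region, space$vertex_ids[idx], space$parent_mesh)
}

# Concatenate source spaces (for whole-brain computations); region becomes
# a per-source attribute on the combined space.
concat_source_spaces <- function(...) {
  sps <- list(...)
  sp <- source_space(do.call(rbind, lapply(sps, `[[`, "positions")),
                     do.call(rbind, lapply(sps, `[[`, "normals")),
                     region = "combined",
                     vertex_ids = seq_len(sum(vapply(sps, length, 1L))))
  sp$source_region <- unlist(lapply(sps, function(s) rep(s$region, length(s))))
  sp
}

#' Default geometry-fixture configuration
#'
#' Adult-head-scale defaults: 9 cm scalp, 8.3 cm inner boundary, a gently
#' folded superior cortex-like cap (7.2 cm base radius, low fold frequency)
#' and a compact, highly folded posterior-inferior cerebellum-like cap
#' (5.5 cm base radius, high fold frequency).
#'
#' @param ... overrides of individual fields.
#' @returns a named list of configuration values.
#' @export
fixture_config <- function(...) {
  cfg <- list(
    scalp_radius = 0.090, scalp_subdivision = 3L,
    inner_radius = 0.083, inner_subdivision = 3L,
    cortex_radius = 0.072, cortex_fold_amplitude = 0.004,
    cortex_fold_frequency = 3L, cortex_extent = 1.25,
    cortex_center = c(0, 0, 1), cortex_rings = 16L,
    cerebellum_radius = 0.055, cerebellum_fold_amplitude = 0.004,
    cerebellum_fold_frequency = 12L, cerebellum_extent = 0.85,
    cerebellum_center = c(0, -1, -1) / sqrt(2), cerebellum_rings = 12L)
  mod <- list(...)
  cfg[names(mod)] <- mod
  cfg
}

#' Synthetic head geometry fixture
#'
#' Generates the full geometry the array-evaluation pipeline runs on: a scalp
#' shell for sensor placement, an inner conductor boundary for the 3 mm
#' source-exclusion rule, a superficial gently folded cortex-like source
#' surface, and a deep, highly folded cerebellum-like source surface in the
#' posterior-inferior direction.
#'
#' @param config list from [fixture_config()].
#' @param seed integer seed; the scalp and inner shells are deterministic,
#'   fold patterns are seeded.
#' @returns an object of class `geometry_fixture` with elements `scalp`,
#'   `inner_boundary`, `cortex_space`, `cerebellum_space`, `cortex_mesh`,
#'   `cerebellum_mesh`, `sphere_center`, `seed` and `config`.
#' @export
make_head_fixture <- function(config = fixture_config(), seed = 1L) {
  cfg <- config
  if (!(cfg$scalp_radius > cfg$inner_radius &&
        cfg$inner_radius > cfg$cortex_radius + cfg$cortex_fold_amplitude &&
        cfg$inner_radius > cfg$cerebellum_radius + cfg$cerebellum_fold_amplitude))
    stop("radius ordering violated: need scalp > inner boundary > source surfaces",
         call. = FALSE)
  scalp <- make_sphere_mesh(cfg$scalp_radius, cfg$scalp_subdivision)
  inner <- make_sphere_mesh(cfg$inner_radius, cfg$inner_subdivision)
  ctx <- make_folded_surface(cfg$cortex_radius, cfg$cortex_fold_amplitude,
                             cfg$cortex_fold_frequency, cfg$cortex_extent,
                             cfg$cortex_center, seed = seed,
                             n_rings = cfg$cortex_rings, region = "cortex")
  crb <- make_folded_surface(cfg$cerebellum_radius, cfg$cerebellum_fold_amplitude,
                             cfg$cerebellum_fold_frequency, cfg$cerebellum_extent,
                             cfg$cerebellum_center, seed = seed + 1L,
                             n_rings = cfg$cerebellum_rings, region = "cerebellum")
  structure(list(scalp = scalp, inner_boundary = inner,
                 cortex_space = ctx$space, cerebellum_space = crb$space,
                 cortex_mesh = ctx$mesh, cerebellum_mesh = crb$mesh,
                 sphere_center = c(0, 0, 0), seed = as.integer(seed), config = cfg),
            class = "geometry_fixture")
}

#' @exportS3Method base::print
print.geometry_fixture <- function(x, ...) {
  cat(sprintf(paste0("<geometry_fixture> seed %d\n  scalp r=%.3f m (%d v), inner r=%.3f m\n",
                     "  cortex: %d dipoles; cerebellum: %d dipoles\n"),
              x$seed, x$config$scalp_radius, nrow(x$scalp$vertices),
              x$config$inner_radius, length(x$cortex_space), length(x$cerebellum_space)))
  invisible(x)
}

#' Write / read a geometry fixture on disk
#'
#' Meshes as ASCII PLY, source spaces as JSON sidecars (vertex ids, region,
#' normals), configuration and seed in `fixture.json`.
#'
#' @param fixture a `geometry_fixture`.
#' @param dir output directory (created if missing).
#' @returns `write_geometry_fixture` returns `dir` invisibly;
#'   `read_geometry_fixture` a `geometry_fixture`.
#' @export
write_geometry_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ply(fixture$scalp, file.path(dir, "scalp.ply"))
  write_ply(fixture$inner_boundary, file.path(dir, "inner_boundary.ply"))
  write_ply(fixture$cortex_mesh, file.path(dir, "cortex.ply"))
  write_ply(fixture$cerebellum_mesh, file.path(dir, "cerebellum.ply"))
  for (reg in c("cortex", "cerebellum")) {
    sp <- fixture[[paste0(reg, "_space")]]
    jsonlite::write_json(
      list(region = sp$region, vertex_ids = sp$vertex_ids,
           normals = sp$normals, units = "m"),
      file.path(dir, paste0(reg, "_space.json")), digits = NA, auto_unbox = TRUE)
  }
  jsonlite::write_json(list(seed = fixture$seed, config = fixture$config),
                       file.path(dir, "fixture.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_geometry_fixture
#' @export
read_geometry_fixture <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "fixture.json"), simplifyVector = TRUE)
  fix <- list(scalp = read_ply(file.path(dir, "scalp.ply")),
              inner_boundary = read_ply(file.path(dir, "inner_boundary.ply")),
              cortex_mesh = read_ply(file.path(dir, "cortex.ply")),
              cerebellum_mesh = read_ply(file.path(dir, "cerebellum.ply")))
  for (reg in c("cortex", "cerebellum")) {
    sj <- jsonlite::read_json(file.path(dir, paste0(reg, "_space.json")),
                              simplifyVector = TRUE)
    mesh <- fix[[paste0(reg, "_mesh")]]
    fix[[paste0(reg, "_space")]] <- source_space(
      mesh$vertices[sj$vertex_ids, , drop = FALSE], sj$normals,
      region = sj$region, vertex_ids = sj$vertex_ids, parent_mesh = mesh)
  }
  fix$sphere_center <- c(0, 0, 0)
  fix$seed <- meta$seed
  fix$config <- meta$config
  class(fix) <- "geometry_fixture"
  fix
}
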