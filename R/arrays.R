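SENSOR_TYPES <- c("squid_mag", "squid_axial_grad", "opm")

# Outward surface normal at each projection result. For points strictly off
# the surface the direction from the closest surface point to the query
# point is used (this makes scalp projection exactly idempotent, including
# over edges and vertices); points on the surface fall back to the nearest
# face normal. Normals are oriented away from the mesh centroid.
outward_normals_at <- function(mesh, pr, pos) {
  fn <- face_normals(mesh$vertices, mesh$faces)[pr$face, , drop = FALSE]
  centroid <- colMeans(mesh$vertices)
  flip <- rowSums(fn * sweep(pr$closest, 2, centroid)) < 0
  fn[flip, ] <- -fn[flip, , drop = FALSE]
  dir <- pos - pr$closest
  dn <- sqrt(rowSums(dir^2))
  off <- dn > 1e-9
  if (any(off)) {
    d <- dir[off, , drop = FALSE] / dn[off]
    s <- sign(rowSums(d * fn[off, , drop = FALSE]))   # points inside flip
    fn[off, ] <- d * s
  }
  fn
}

# Physical sensor element lengths (m): SQUID pick-up loop 28 mm, OPM housing 17 mm.
physical_sensor_length <- function(sensor_type) {
  unname(c(squid_mag = 0.028, squid_axial_grad = 0.028, opm = 0.017)[sensor_type])
}

# Default sensitive-element standoff from the scalp (m).
default_standoff <- function(sensor_type) {
  unname(c(squid_mag = 0.022, squid_axial_grad = 0.022, opm = 0.005)[sensor_type])
}

# Deterministic tangential frame: tan1 = normalize(global_z x radial), with a
# global_x fallback near the poles; tan2 = radial x tan1 (right-handed).
tangent_axes <- function(radial) {
  radial <- rbind3(radial)
  gz <- matrix(rep(c(0, 0, 1), each = nrow(radial)), ncol = 3)
  t1 <- cross3(gz, radial)
  nt <- sqrt(rowSums(t1^2))
  bad <- nt < 1e-6
  if (any(bad)) {
    gx <- matrix(rep(c(1, 0, 0), each = sum(bad)), ncol = 3)
    t1[bad, ] <- cross3(gx, radial[bad, , drop = FALSE])
    nt[bad] <- sqrt(rowSums(t1[bad, , drop = FALSE]^2))
  }
  t1 <- t1 / nt
  t2 <- cross3(radial, t1)
  list(tan1 = t1, tan2 = t2 / sqrt(rowSums(t2^2)))
}

#' Sensor array
#'
#' A tibble of sensors (one row per physical sensor) with an orthonormal
#' orientation triad per sensor, plus array-level attributes. Columns:
#' `sensor_id`, position `x, y, z` (m), radial axis `rx, ry, rz`, tangential
#' axes `t1x..t1z`, `t2x..t2z`, `type` and `physical_length` (m).
#'
#' @param sensors a data frame with at least `sensor_id`, `x`, `y`, `z`,
#'   `rx`, `ry`, `rz` and `type`; tangential axes are completed
#'   deterministically if absent.
#' @param channel_mode `"single_axis"` or `"triaxial"` (triaxial only for
#'   OPM sensors, giving three orthogonal channels per sensor).
#' @param name array name.
#' @returns a `sensor_array` (tibble subclass).
#' @export
sensor_array <- function(sensors, channel_mode = c("single_axis", "triaxial"),
                         name = "array") {
  channel_mode <- match.arg(channel_mode)
  s <- tibble::as_tibble(sensors)
  stopifnot(all(c("sensor_id", "x", "y", "z", "rx", "ry", "rz", "type") %in% names(s)))
  if (anyDuplicated(s$sensor_id)) stop("duplicate sensor ids", call. = FALSE)
  if (!all(s$type %in% SENSOR_TYPES))
    stop("unknown sensor type; expected one of ", paste(SENSOR_TYPES, collapse = ", "),
         call. = FALSE)
  if (channel_mode == "triaxial" && any(s$type != "opm"))
    stop("triaxial channel mode is defined only for OPM sensors", call. = FALSE)
  rad <- as.matrix(s[, c("rx", "ry", "rz")])
  rad <- rad / sqrt(rowSums(rad^2))
  s[, c("rx", "ry", "rz")] <- rad
  if (!all(c("t1x", "t1y", "t1z", "t2x", "t2y", "t2z") %in% names(s))) {
    ta <- tangent_axes(rad)
    s$t1x <- ta$tan1[, 1]; s$t1y <- ta$tan1[, 2]; s$t1z <- ta$tan1[, 3]
    s$t2x <- ta$tan2[, 1]; s$t2y <- ta$tan2[, 2]; s$t2z <- ta$tan2[, 3]
  }
  if (!"physical_length" %in% names(s))
    s$physical_length <- physical_sensor_length(s$type)
  check_triads(s)
  structure(s, class = c("sensor_array", class(tibble::tibble()))) |>
    set_array_attrs(channel_mode = channel_mode, name = name)
}

set_array_attrs <- function(x, channel_mode, name) {
  attr(x, "channel_mode") <- channel_mode
  attr(x, "array_name") <- name
  x
}

check_triads <- function(s, tol = 1e-9) {
  r <- as.matrix(s[, c("rx", "ry", "rz")])
  t1 <- as.matrix(s[, c("t1x", "t1y", "t1z")])
  t2 <- as.matrix(s[, c("t2x", "t2y", "t2z")])
  err <- c(abs(rowSums(r * t1)), abs(rowSums(r * t2)), abs(rowSums(t1 * t2)),
           abs(rowSums(r^2) - 1), abs(rowSums(t1^2) - 1), abs(rowSums(t2^2) - 1),
           abs(rowSums(cross3(r, t1) * t2) - 1))
  if (any(err > tol)) stop("sensor orientation triads are not orthonormal", call. = FALSE)
  invisible(TRUE)
}

#' @exportS3Method base::print
print.sensor_array <- function(x, ...) {
  cat(sprintf("<sensor_array> '%s': %d sensors (%s), %s -> %d channels\n",
              attr(x, "array_name"), nrow(x),
              paste(unique(x$type), collapse = "/"), attr(x, "channel_mode"),
              n_channels(x)))
  NextMethod()
}

#' Number of channels of an array
#'
#' @param array a `sensor_array`.
#' @returns sensor count times 3 for triaxial mode, else sensor count.
#' @export
n_channels <- function(array) {
  nrow(array) * if (identical(attr(array, "channel_mode"), "triaxial")) 3L else 1L
}

sensor_positions <- function(array) as.matrix(array[, c("x", "y", "z")])

#' Project sensor positions onto a scalp surface
#'
#' Each input position is moved to its nearest point on the scalp mesh plus
#' `standoff` along the local outward normal; the sensor's radial axis is set
#' to that normal and the tangential axes completed deterministically.
#'
#' @param positions data frame with `x, y, z` columns or a k x 3 matrix, m.
#' @param scalp a `surface_mesh` (closed, or a cap covering all projections).
#' @param standoff sensor-element-to-scalp distance in meters (default 5 mm,
#'   the on-scalp OPM convention; use ~22 mm for helmet SQUIDs).
#' @param sensor_type sensor type for the resulting rows.
#' @param channel_mode passed to [sensor_array()].
#' @param name array name.
#' @returns a `sensor_array` with one sensor per input position.
#' @export
project_to_scalp <- function(positions, scalp, standoff = 0.005,
                             sensor_type = "opm",
                             channel_mode = "single_axis", name = "projected") {
  pos <- if (is.data.frame(positions)) as.matrix(positions[, c("x", "y", "z")])
         else rbind3(positions)
  pr <- point_mesh_distance(pos, scalp)
  fn <- outward_normals_at(scalp, pr, pos)
  newpos <- pr$closest + standoff * fn
  sensor_array(tibble::tibble(
    sensor_id = sprintf("S%03d", seq_len(nrow(newpos))),
    x = newpos[, 1], y = newpos[, 2], z = newpos[, 3],
    rx = fn[, 1], ry = fn[, 2], rz = fn[, 3],
    type = sensor_type), channel_mode = channel_mode, name = name)
}

#' Channel table of an array
#'
#' Expands sensors into measurement channels with integration schemes:
#' SQUID magnetometers as a 4-point square pick-up loop (edge
#' `squid_loop_edge`, default 21 mm) in the tangent plane, axial gradiometers
#' as a proximal-minus-distal point pair along the radial axis (baseline
#' default 50 mm), OPMs as a single point. In triaxial mode each OPM yields
#' radial, tan1 and tan2 channels (sensor-major ordering).
#'
#' @param array a `sensor_array`.
#' @param squid_loop_edge pick-up loop edge length, m.
#' @param gradiometer_baseline axial gradiometer baseline, m.
#' @returns tibble with `channel_id`, `sensor_id`, `axis`, `kind`,
#'   `orientation`, `points`, `weights` (the last three list-columns).
#' @export
make_channels <- function(array, squid_loop_edge = 0.021, gradiometer_baseline = 0.05) {
  mode <- attr(array, "channel_mode")
  rows <- vector("list", nrow(array))
  for (i in seq_len(nrow(array))) {
    s <- array[i, ]
    p <- c(s$x, s$y, s$z)
    rad <- c(s$rx, s$ry, s$rz); t1 <- c(s$t1x, s$t1y, s$t1z); t2 <- c(s$t2x, s$t2y, s$t2z)
    axes <- if (identical(mode, "triaxial")) c("radial", "tan1", "tan2") else "radial"
    ors <- list(radial = rad, tan1 = t1, tan2 = t2)
    ch <- lapply(axes, function(ax) {
      if (s$type == "squid_mag") {
        h <- squid_loop_edge / 2
        pts <- rbind(p + h * t1 + h * t2, p + h * t1 - h * t2,
                     p - h * t1 + h * t2, p - h * t1 - h * t2)
        w <- rep(0.25, 4)
        kind <- "magnetometer"
      } else if (s$type == "squid_axial_grad") {
        pts <- rbind(p, p + gradiometer_baseline * rad)
        w <- c(1, -1)
        kind <- "axial_gradiometer"
      } else {
        pts <- matrix(p, 1, 3)
        w <- 1
        kind <- "magnetometer"
      }
      tibble::tibble(channel_id = paste0(s$sensor_id, "_", ax),
                     sensor_id = s$sensor_id, axis = ax, kind = kind,
                     sensor_type = s$type,
                     baseline = if (s$type == "squid_axial_grad") gradiometer_baseline else NA_real_,
                     orientation = list(ors[[ax]]), points = list(pts),
                     weights = list(w))
    })
    rows[[i]] <- dplyr::bind_rows(ch)
  }
  dplyr::bind_rows(rows)
}

#' Expand an OPM array to triaxial channels
#'
#' Three channels per sensor measuring the radial and the two tangential
#' field components; errors for non-OPM sensor types.
#'
#' @param array a `sensor_array` of OPM sensors.
#' @returns a channel tibble (see [make_channels()]) with 3 x sensor rows.
#' @export
expand_triaxial <- function(array) {
  if (any(array$type != "opm"))
    stop("triaxial expansion is defined only for OPM sensors", call. = FALSE)
  make_channels(set_array_attrs(array, "triaxial", attr(array, "array_name")))
}

#' Switch the channel mode of an array
#'
#' @param array a `sensor_array`.
#' @param channel_mode `"single_axis"` or `"triaxial"`.
#' @returns the array with the new mode (validated by [sensor_array()]).
#' @export
set_channel_mode <- function(array, channel_mode) {
  sensor_array(array, channel_mode = channel_mode, name = attr(array, "array_name"))
}

#' Mean neighboring-sensor distance and overlap flag
#'
#' Mean over sensors of the distance to the nearest other sensor. The overlap
#' flag marks layouts whose mean neighbor distance is smaller than the
#' physical sensor length (28 mm SQUID, 17 mm OPM), where rigid sensors
#' would physically collide and the modeled array is optimistic.
#'
#' @param array a `sensor_array` with at least two sensors.
#' @returns list with `mean_distance` (m) and `overlap_flag`.
#' @export
mean_neighbor_distance <- function(array) {
  if (nrow(array) < 2) stop("need at least two sensors", call. = FALSE)
  p <- sensor_positions(array)
  d <- as.matrix(stats::dist(p))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  md <- mean(nn)
  list(mean_distance = md,
       overlap_flag = md < max(physical_sensor_length(array$type)))
}

#' Helmet-like seed positions on a spherical cap
#'
#' Procedurally generated quasi-uniform layout on the sphere of radius
#' `radius`, covering a cap of half-angle `coverage` around +z (extending
#' below the equator for posterior/inferior coverage when `coverage` exceeds
#' pi/2). Deterministic Fibonacci-spiral construction; stands in for
#' proprietary vendor helmet coordinates.
#'
#' @param n number of positions.
#' @param radius sphere radius, m.
#' @param coverage cap half-angle in radians (default ~118 degrees).
#' @returns n x 3 matrix of positions.
#' @export
helmet_seed_positions <- function(n, radius = 0.112, coverage = 2.06) {
  i <- seq_len(n) - 0.5
  z <- 1 - (1 - cos(coverage)) * i / n      # cos(theta) from 1 down to cos(coverage)
  golden <- pi * (3 - sqrt(5))
  phi <- golden * (seq_len(n) - 1)
  st <- sqrt(1 - z^2)
  radius * cbind(st * cos(phi), st * sin(phi), z)
}

# ---- sensor layout file I/O ----

#' Write / read a sensor layout file
#'
#' TSV with id, position, the three axis vectors and type. The reader also
#' accepts position-only files (columns `sensor_id`, `x`, `y`, `z`, `type`);
#' axes are then derived by projecting onto a supplied scalp mesh, or
#' radially from the origin when no scalp is given.
#'
#' @param array a `sensor_array`.
#' @param path file path.
#' @param scalp optional `surface_mesh` used to derive axes for
#'   position-only files.
#' @param channel_mode,name passed to [sensor_array()] on read.
#' @returns `write_sensor_layout` returns `path` invisibly;
#'   `read_sensor_layout` a `sensor_array`.
#' @export
write_sensor_layout <- function(array, path) {
  utils::write.table(as.data.frame(array), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sensor_layout
#' @export
read_sensor_layout <- function(path, scalp = NULL, channel_mode = "single_axis",
                               name = "imported") {
  s <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("sensor_id", "x", "y", "z", "type") %in% names(s)))
    stop("layout file must have sensor_id, x, y, z, type columns", call. = FALSE)
  if (!all(c("rx", "ry", "rz") %in% names(s))) {
    pos <- as.matrix(s[, c("x", "y", "z")])
    if (!is.null(scalp)) {
      pr <- point_mesh_distance(pos, scalp)
      rad <- outward_normals_at(scalp, pr, pos)
    } else {
      rad <- pos / sqrt(rowSums(pos^2))
    }
    s$rx <- rad[, 1]; s$ry <- rad[, 2]; s$rz <- rad[, 3]
  }
  sensor_array(s, channel_mode = channel_mode, name = name)
}
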