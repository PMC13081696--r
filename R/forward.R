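MU0_4PI <- 1e-7  # T m / (A m), mu0 / 4 pi

#' Magnetic field of a current dipole in a spherically symmetric conductor
#'
#' Closed-form external field (Sarvas formula). The field depends only on the
#' sphere center, not on the conductivity profile; radially oriented dipoles
#' are magnetically silent outside the conductor.
#'
#' @param dipole_position k x 3 matrix (or 3-vector) of dipole positions, m.
#' @param dipole_moment k x 3 matrix or single 3-vector, A·m.
#' @param field_point 3-vector, field evaluation point in meters; must lie
#'   strictly outside the sphere through each dipole.
#' @param sphere_center 3-vector, conductor center in meters.
#' @returns k x 3 matrix of magnetic field vectors in tesla.
#' @export
dipole_field_sphere <- function(dipole_position, dipole_moment, field_point,
                                sphere_center = c(0, 0, 0)) {
  r0 <- sweep(rbind3(dipole_position), 2, sphere_center)
  q <- rbind3(dipole_moment)
  if (nrow(q) == 1 && nrow(r0) > 1) q <- q[rep(1, nrow(r0)), , drop = FALSE]
  stopifnot(nrow(q) == nrow(r0))
  r <- as.numeric(field_point) - as.numeric(sphere_center)
  R <- sqrt(sum(r^2))
  r0n <- sqrt(rowSums(r0^2))
  if (any(r0n < 1e-12))
    stop("dipole at the sphere center: field direction undefined", call. = FALSE)
  if (any(R <= r0n))
    stop("field point inside the conductor sphere through a dipole", call. = FALSE)
  a_vec <- sweep(-r0, 2, r, `+`)          # r - r0
  a <- sqrt(rowSums(a_vec^2))
  r0_dot_r <- drop(r0 %*% r)
  F_s <- a * (R * a + R^2 - r0_dot_r)
  adotr <- drop(a_vec %*% r)
  c1 <- a^2 / R + adotr / a + 2 * a + 2 * R
  c2 <- a + 2 * R + adotr / a
  gradF <- outer(c1, r) - c2 * r0
  qxr0 <- cross3(q, r0)
  B <- MU0_4PI / F_s^2 * (F_s * qxr0 - drop(qxr0 %*% r) * gradF)
  B
}

#' Channel gain for a unit dipole
#'
#' Weighted sum over the channel's integration points of the field component
#' along the channel orientation, for a 1 A·m dipole along
#' `dipole_orientation`. A magnetometer is one or more positively weighted
#' points (weights summing to 1); an axial gradiometer is a proximal-minus-
#' distal point pair with weights (+1, -1).
#'
#' @param channel one row of a channel table (see [make_channels()]) as a
#'   list: fields `points` (p x 3), `weights` (length p), `orientation`
#'   (unit 3-vector).
#' @param dipole_position k x 3 matrix of dipole positions, m.
#' @param dipole_orientation k x 3 matrix of unit dipole orientations.
#' @param sphere_center conductor center.
#' @returns length-k vector of gains in T/(A·m).
#' @export
channel_gain <- function(channel, dipole_position, dipole_orientation,
                         sphere_center = c(0, 0, 0)) {
  pts <- rbind3(channel$points)
  w <- as.numeric(channel$weights)
  stopifnot(length(w) == nrow(pts))
  pos <- rbind3(dipole_position)
  ori <- rbind3(dipole_orientation)
  g <- numeric(nrow(pos))
  for (p in seq_len(nrow(pts))) {
    B <- dipole_field_sphere(pos, ori, pts[p, ], sphere_center)
    g <- g + w[p] * drop(B %*% as.numeric(channel$orientation))
  }
  g
}

#' Assemble a lead-field matrix
#'
#' Gain matrix over all channels of an array and all dipoles of a source
#' space, using the spherical-conductor forward model. Channels are ordered
#' by sensor id then axis (radial, tan1, tan2); sources by vertex id order of
#' the space.
#'
#' @param array a `sensor_array` (see [sensor_array()]).
#' @param space a `source_space`.
#' @param sphere_center conductor center, meters.
#' @returns an object of class `leadfield`: list with `gain` (channels x
#'   sources, T/(A·m)), `channels` (tibble), `space`, `model_tag`, `units`.
#' @export
assemble_leadfield <- function(array, space, sphere_center = c(0, 0, 0)) {
  if (length(space) == 0) stop("empty source space", call. = FALSE)
  ch <- make_channels(array)
  if (nrow(ch) == 0) stop("empty sensor array", call. = FALSE)
  gain <- matrix(0, nrow(ch), length(space))
  for (i in seq_len(nrow(ch))) {
    gain[i, ] <- channel_gain(
      list(points = ch$points[[i]], weights = ch$weights[[i]],
           orientation = ch$orientation[[i]]),
      space$positions, space$normals, sphere_center)
  }
  rownames(gain) <- ch$channel_id
  colnames(gain) <- space$vertex_ids
  new_leadfield(gain, ch, space, model_tag = "sphere")
}

new_leadfield <- function(gain, channels, space, model_tag, units = "T/(A.m)") {
  stopifnot(all(is.finite(gain)))
  structure(list(gain = gain, channels = channels, space = space,
                 model_tag = model_tag, units = units),
            class = "leadfield")
}

#' @exportS3Method base::print
print.leadfield <- function(x, ...) {
  cat(sprintf("<leadfield> %d channels x %d sources [%s, %s]\n",
              nrow(x$gain), ncol(x$gain), x$model_tag, x$units))
  invisible(x)
}

#' @export
dim.leadfield <- function(x) dim(x$gain)

# Column-bind lead fields over concatenated source spaces (same channels).
cbind_leadfields <- function(a, b) {
  stopifnot(nrow(a$gain) == nrow(b$gain))
  sp <- concat_source_spaces(a$space, b$space)
  new_leadfield(cbind(a$gain, b$gain), a$channels, sp, a$model_tag, a$units)
}

#' Exclude sources near a boundary surface
#'
#' Drops dipoles whose exact Euclidean distance to the nearest triangle of
#' `boundary` is below `min_distance` (default 3 mm), the standard guard
#' against boundary-related forward-model errors. Ordering of the surviving
#' sources is preserved.
#'
#' @param space a `source_space`.
#' @param boundary a closed `surface_mesh`.
#' @param min_distance exclusion distance in meters.
#' @returns the filtered `source_space`; warns if no sources survive.
#' @export
exclude_near_boundary <- function(space, boundary, min_distance = 0.003) {
  if (any(boundary$boundary)) stop("boundary mesh must be closed", call. = FALSE)
  d <- point_mesh_distance(space$positions, boundary)$distance
  keep <- which(d >= min_distance)
  if (length(keep) == 0) warning("all sources excluded: empty source space")
  subset_source_space(space, keep)
}

# ---- lead-field container I/O: dense TSV matrix + JSON metadata sidecar ----

#' Export / import a lead field
#'
#' Container: `<prefix>_gain.tsv` (dense channels x sources matrix) plus
#' `<prefix>_meta.json` holding units, model tag, channel metadata (id,
#' sensor, axis, kind) and source metadata (vertex ids, region). On import,
#' values are rescaled to the internal unit T/(A·m) from the declared unit
#' (e.g. fT/(nA·m) is multiplied by 1e-6).
#'
#' @param L a `leadfield`.
#' @param prefix path prefix for the two files.
#' @returns `export_leadfield` returns `prefix` invisibly; `import_leadfield`
#'   a `leadfield` with `model_tag = "imported"` (unless the container tags
#'   it otherwise).
#' @export
export_leadfield <- function(L, prefix) {
  utils::write.table(format(L$gain, digits = 17, scientific = TRUE, trim = TRUE),
                     paste0(prefix, "_gain.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  meta <- list(units = L$units, model_tag = L$model_tag,
               n_channels = nrow(L$gain), n_sources = ncol(L$gain),
               channels = list(channel_id = L$channels$channel_id,
                               sensor_id = L$channels$sensor_id,
                               axis = L$channels$axis, kind = L$channels$kind),
               sources = list(vertex_ids = L$space$vertex_ids,
                              region = L$space$region))
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(prefix)
}

#' @rdname export_leadfield
#' @param channel_meta optional channel tibble to attach (must match the
#'   stored channel count).
#' @param source_meta optional `source_space` to attach (must match the
#'   stored source count).
#' @export
import_leadfield <- function(prefix, channel_meta = NULL, source_meta = NULL) {
  meta_path <- paste0(prefix, "_meta.json")
  gain_path <- paste0(prefix, "_gain.tsv")
  if (!file.exists(meta_path) || !file.exists(gain_path))
    stop("lead-field container incomplete: missing gain or metadata file", call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  gain <- tryCatch(
    as.matrix(utils::read.table(gain_path, sep = "\t", header = FALSE,
                                colClasses = "numeric")),
    error = function(e) stop("malformed gain matrix: ", conditionMessage(e), call. = FALSE))
  dimnames(gain) <- NULL
  if (nrow(gain) != meta$n_channels || ncol(gain) != meta$n_sources)
    stop(sprintf("gain shape %d x %d does not match metadata %d x %d",
                 nrow(gain), ncol(gain), meta$n_channels, meta$n_sources), call. = FALSE)
  if (!all(is.finite(gain))) stop("non-finite entries in imported gain", call. = FALSE)
  scale <- leadfield_unit_scale(meta$units)
  if (!is.null(channel_meta) && nrow(channel_meta) != nrow(gain))
    stop("supplied channel metadata does not match gain rows", call. = FALSE)
  if (!is.null(source_meta) && length(source_meta) != ncol(gain))
    stop("supplied source metadata does not match gain columns", call. = FALSE)
  ch <- if (!is.null(channel_meta)) channel_meta else
    tibble::tibble(channel_id = as.character(meta$channels$channel_id),
                   sensor_id = meta$channels$sensor_id,
                   axis = meta$channels$axis, kind = meta$channels$kind)
  sp <- if (!is.null(source_meta)) source_meta else
    source_space(matrix(NA_real_, ncol(gain), 3), matrix(rep(c(0, 0, 1), each = ncol(gain)), ncol = 3),
                 region = meta$sources$region, vertex_ids = meta$sources$vertex_ids)
  new_leadfield(gain * scale, ch, sp, model_tag = "imported")
}

# Parse a lead-field unit string "<p>T/(<p>A.m)" into a scale factor to the
# internal T/(A.m); fT = 1e-15 T, nA.m = 1e-9 A.m, so fT/(nA.m) -> 1e-6.
leadfield_unit_scale <- function(units) {
  u <- gsub("·|⋅", ".", units)
  u <- gsub("\\s", "", u)
  m <- regmatches(u, regexec("^([fpnum]?)T/\\(([fpnum]?)A\\.?m\\)$", u))[[1]]
  if (length(m) == 0) stop("unrecognized lead-field unit: ", units, call. = FALSE)
  pref <- c("f" = 1e-15, "p" = 1e-12, "n" = 1e-9, "u" = 1e-6, "m" = 1e-3)
  num <- if (m[2] == "") 1 else pref[[m[2]]]
  den <- if (m[3] == "") 1 else pref[[m[3]]]
  num / den
}
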