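#' Geodesic patches on a source surface
#'
#' Overlapping circular patches on the mesh the source space lives on:
#' seeds are chosen greedily in ascending vertex-id order so that all seed
#' pairs are at least `spacing` apart geodesically (every source vertex then
#' lies within `spacing` of some seed); members are the source vertices
#' within geodesic `radius` of the seed (Dijkstra on the edge-length-weighted
#' mesh graph).
#'
#' @param space a `source_space` with a `parent_mesh`.
#' @param radius patch geodesic radius in meters (default 10 mm, matched to
#'   a ~100 nAm synchronously active population).
#' @param spacing seed spacing in meters (default 15 mm).
#' @returns a tibble of class `patch_set`: `seed_vertex` (mesh vertex id),
#'   `members` (list column of source-space column indices), `n_members`.
#' @export
geodesic_patches <- function(space, radius = 0.010, spacing = 0.015) {
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  if (is.null(space$parent_mesh)) stop("source space has no parent mesh", call. = FALSE)
  g <- mesh_graph(space$parent_mesh)
  vids <- space$vertex_ids
  d <- igraph::distances(g, v = vids, to = vids)  # geodesic between source vertices
  ord <- order(vids)
  seeds <- integer(0)
  for (i in ord) {
    if (length(seeds) == 0 || all(d[i, seeds] >= spacing)) seeds <- c(seeds, i)
  }
  members <- lapply(seeds, function(s) which(d[s, ] <= radius))
  out <- tibble::tibble(seed_vertex = vids[seeds],
                        members = members,
                        n_members = lengths(members))
  class(out) <- c("patch_set", class(out))
  attr(out, "radius") <- radius
  attr(out, "spacing") <- spacing
  out
}

#' Cosines of the principal angles between two lead-field subspaces
#'
#' Orthonormal bases of the two column spaces are taken from singular value
#' decompositions truncated at numerical rank; the singular values of the
#' basis cross-product are the cosines of the principal (subspace) angles,
#' equal to the canonical correlations between the spanning sets.
#'
#' @param gain_a,gain_b matrices with the same channel (row) count.
#' @returns object of class `subspace_result`: list with `cosines`
#'   (descending, clipped to `[0, 1]`), `rank_a`, `rank_b`.
#' @export
principal_angle_cosines <- function(gain_a, gain_b) {
  A <- as.matrix(gain_a); B <- as.matrix(gain_b)
  if (nrow(A) != nrow(B)) stop("channel counts differ", call. = FALSE)
  Ua <- orth_basis(A)
  Ub <- orth_basis(B)
  cosines <- svd(crossprod(Ua, Ub), nu = 0, nv = 0)$d
  cosines <- pmin(pmax(cosines, 0), 1)
  structure(list(cosines = cosines, rank_a = ncol(Ua), rank_b = ncol(Ub)),
            class = "subspace_result")
}

# Orthonormal basis of the column space, truncated at numerical rank
# (singular values > max(dim) * eps * sigma_max).
orth_basis <- function(X) {
  s <- svd(X)
  if (s$d[1] == 0) stop("zero matrix has no subspace", call. = FALSE)
  tol <- max(dim(X)) * .Machine$double.eps * s$d[1]
  r <- sum(s$d > tol)
  s$u[, seq_len(r), drop = FALSE]
}

#' @exportS3Method base::print
print.subspace_result <- function(x, ...) {
  cat(sprintf("<subspace_result> ranks %d x %d, mean cosine %.3f\n",
              x$rank_a, x$rank_b, mean(x$cosines)))
  invisible(x)
}

#' Mean subspace correlation
#'
#' Arithmetic mean of all r principal-angle cosines, collapsing a subspace
#' comparison to a single correlation value.
#'
#' @param result a `subspace_result` (or a numeric cosine vector).
#' @returns scalar in `[0, 1]`.
#' @export
mean_subspace_correlation <- function(result) {
  cosines <- if (inherits(result, "subspace_result")) result$cosines else result
  if (length(cosines) == 0) stop("empty cosine set", call. = FALSE)
  mean(cosines)
}

#' Patch-to-patch correlation map (fixed cortical seed)
#'
#' A fixed cortical patch is compared against every cerebellar patch of
#' equal size; each cerebellar patch gets the mean principal-angle cosine of
#' the two patch lead fields. Shows how correlation with one cortical site
#' distributes across the cerebellum.
#'
#' @param L_cortex `leadfield` over the cortical space.
#' @param cortical_patch one-row subset of a cortical `patch_set`.
#' @param L_cerebellum `leadfield` (same array) over the cerebellar space.
#' @param cerebellar_patches cerebellar `patch_set`.
#' @returns tibble of class `correlation_map`: `seed_vertex`, `correlation`,
#'   plus the per-patch `subspace_result`s in a list column.
#' @export
patch_to_patch_map <- function(L_cortex, cortical_patch, L_cerebellum,
                               cerebellar_patches) {
  stopifnot(nrow(cortical_patch) == 1)
  ga <- L_cortex$gain[, cortical_patch$members[[1]], drop = FALSE]
  res <- lapply(cerebellar_patches$members, function(m)
    principal_angle_cosines(ga, L_cerebellum$gain[, m, drop = FALSE]))
  out <- tibble::tibble(seed_vertex = cerebellar_patches$seed_vertex,
                        correlation = vapply(res, mean_subspace_correlation, 1),
                        result = res)
  class(out) <- c("correlation_map", class(out))
  attr(out, "location_type") <- "cerebellar_patch_seeds"
  out
}

#' Patch-to-whole-cerebellum correlation map
#'
#' Every cortical patch is compared against the full cerebellar lead field;
#' each patch gets the mean principal-angle cosine. A per-vertex cortical
#' map is formed by averaging the values of all patches containing the
#' vertex (patches overlap at the default radius/spacing).
#'
#' @param L_cortex `leadfield` over the cortical space.
#' @param cortical_patches cortical `patch_set`.
#' @param L_cerebellum `leadfield` (same array) over the cerebellar space.
#' @returns list of class `cortical_correlation_map` with `patches` (tibble:
#'   `seed_vertex`, `correlation`, `result` list column) and `vertices`
#'   (tibble: `vertex_id`, `correlation` averaged over covering patches).
#' @export
patch_to_whole_map <- function(L_cortex, cortical_patches, L_cerebellum) {
  gb <- L_cerebellum$gain
  if (all(gb == 0)) stop("zero cerebellar lead field", call. = FALSE)
  Ub <- orth_basis(gb)
  res <- lapply(cortical_patches$members, function(m) {
    Ua <- orth_basis(L_cortex$gain[, m, drop = FALSE])
    cosines <- pmin(pmax(svd(crossprod(Ua, Ub), nu = 0, nv = 0)$d, 0), 1)
    structure(list(cosines = cosines, rank_a = ncol(Ua), rank_b = ncol(Ub)),
              class = "subspace_result")
  })
  pvals <- vapply(res, mean_subspace_correlation, 1)
  patches <- tibble::tibble(seed_vertex = cortical_patches$seed_vertex,
                            correlation = pvals, result = res)
  # per-vertex averaging over covering patches
  vid <- L_cortex$space$vertex_ids
  acc <- numeric(length(vid)); cnt <- numeric(length(vid))
  for (i in seq_along(res)) {
    m <- cortical_patches$members[[i]]
    acc[m] <- acc[m] + pvals[i]
    cnt[m] <- cnt[m] + 1
  }
  covered <- cnt > 0
  vertices <- tibble::tibble(vertex_id = vid[covered],
                             correlation = acc[covered] / cnt[covered])
  structure(list(patches = patches, vertices = vertices),
            class = "cortical_correlation_map")
}

#' @exportS3Method base::print
print.cortical_correlation_map <- function(x, ...) {
  cat(sprintf("<cortical_correlation_map> %d patches, mean correlation %.3f\n",
              nrow(x$patches), mean(x$patches$correlation)))
  invisible(x)
}

#' Percentage of highly correlated subspace angles
#'
#' For each patch comparison, the percentage of principal-angle cosines
#' exceeding the threshold (default 0.5): the share of directions in the
#' patch subspace that the other region can mimic well.
#'
#' @param results list of `subspace_result`s (e.g. the `result` column of a
#'   correlation map), or a single `subspace_result`.
#' @param threshold cosine threshold.
#' @returns numeric vector of percentages (one per result).
#' @export
high_correlation_fraction <- function(results, threshold = 0.5) {
  if (inherits(results, "subspace_result")) results <- list(results)
  if (length(results) == 0) stop("no results", call. = FALSE)
  vapply(results, function(r)
    100 * sum(r$cosines > threshold) / length(r$cosines), 1)
}
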