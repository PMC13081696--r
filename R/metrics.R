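#' Sensitivity map of an array over a source space
#'
#' Per-source Euclidean norm of the source's topography (lead-field column)
#' scaled by a reference dipole moment: the field strength the array as a
#' whole sees from a dipole at that location. Default moment 100 nAm, the
#' conventional strength of a synchronously active ~1 cm patch.
#'
#' @param L a `leadfield`.
#' @param moment dipole moment in A·m (default `1e-7` = 100 nAm).
#' @returns a tibble of class `sensitivity_map` with `vertex_id`, `region`
#'   and `sensitivity` (tesla); attributes `moment`, `array_name`,
#'   `n_sensors` (NA when unknown) and `per_sensor`.
#' @export
sensitivity_map <- function(L, moment = 1e-7) {
  g <- if (inherits(L, "leadfield")) L$gain else as.matrix(L)
  stopifnot(all(is.finite(g)))
  vals <- moment * sqrt(colSums(g^2))
  region <- if (inherits(L, "leadfield")) {
    if (!is.null(L$space$source_region)) L$space$source_region else L$space$region
  } else NA_character_
  vid <- if (inherits(L, "leadfield")) L$space$vertex_ids else seq_along(vals)
  out <- tibble::tibble(vertex_id = vid, region = region, sensitivity = vals)
  class(out) <- c("sensitivity_map", class(out))
  attr(out, "moment") <- moment
  attr(out, "n_sensors") <- if (inherits(L, "leadfield"))
    length(unique(L$channels$sensor_id)) else NA_integer_
  attr(out, "per_sensor") <- FALSE
  out
}

#' Normalize a sensitivity map by sensor count
#'
#' Divides by the number of physical sensors (not channels: a triaxial array
#' of 102 sensors divides by 102, not 306), exposing per-sensor efficiency.
#'
#' @param map a `sensitivity_map`.
#' @param n_sensors positive integer; defaults to the map's recorded count.
#' @returns the normalized `sensitivity_map` (`per_sensor = TRUE`).
#' @export
normalize_per_sensor <- function(map, n_sensors = attr(map, "n_sensors")) {
  if (is.null(n_sensors) || is.na(n_sensors) || n_sensors < 1)
    stop("n_sensors must be a positive integer", call. = FALSE)
  map$sensitivity <- map$sensitivity / n_sensors
  attr(map, "per_sensor") <- TRUE
  map
}

#' Summary of a value distribution (percentiles and density peak)
#'
#' Percentiles by linear interpolation; the distribution mode as the argmax
#' of a Gaussian kernel density estimate (Silverman bandwidth, 512-point
#' grid), the way peaks are read off density plots.
#'
#' @param values nonempty numeric vector.
#' @param range_clip optional length-2 range for the density grid.
#' @returns one-row tibble: `percentile_1`, `percentile_95`, `percentile_99`,
#'   `mode_of_density`, `mean`.
#' @export
summarize_density <- function(values, range_clip = NULL) {
  values <- values[is.finite(values)]
  if (length(values) == 0) stop("no finite values", call. = FALSE)
  q <- stats::quantile(values, c(0.01, 0.95, 0.99), names = FALSE, type = 7)
  mode <- if (length(unique(values)) == 1) values[1] else {
    args <- list(x = values, bw = "nrd0", n = 512)
    if (!is.null(range_clip)) { args$from <- range_clip[1]; args$to <- range_clip[2] }
    d <- do.call(stats::density, args)
    d$x[which.max(d$y)]
  }
  tibble::tibble(percentile_1 = q[1], percentile_95 = q[2], percentile_99 = q[3],
                 mode_of_density = mode, mean = mean(values))
}

#' Ratio of mean sensitivities between two maps
#'
#' Ratio-of-means convention: `mean(map_a) / mean(map_b)` (e.g. cortex over
#' cerebellum for the same array, or the same region across two arrays).
#'
#' @param map_a,map_b `sensitivity_map` tibbles (or numeric vectors).
#' @returns scalar ratio.
#' @export
region_sensitivity_ratio <- function(map_a, map_b) {
  a <- if (is.data.frame(map_a)) map_a$sensitivity else map_a
  b <- if (is.data.frame(map_b)) map_b$sensitivity else map_b
  mb <- mean(b)
  if (mb == 0) stop("zero mean in denominator map", call. = FALSE)
  mean(a) / mb
}

#' Conservation factor of a lead field
#'
#' `C = ||sum_j L_{:,j}||_2 / sum_j ||L_{:,j}||_2`: the net field of all
#' sources active simultaneously relative to the summed fields of the
#' sources activated individually. Values near 0 indicate strong
#' cancellation from oppositely oriented dipoles (folded surfaces); 1 means
#' perfectly coherent topographies.
#'
#' @param L a `leadfield` or numeric gain matrix.
#' @returns scalar in `[0, 1]`.
#' @export
conservation_factor <- function(L) {
  g <- if (inherits(L, "leadfield")) L$gain else as.matrix(L)
  colnorms <- sqrt(colSums(g^2))
  B <- sum(colnorms)
  if (B == 0) stop("all-zero lead field", call. = FALSE)
  sqrt(sum(rowSums(g)^2)) / B
}

#' Relative error and correlation between two topographies
#'
#' Forward-error metrics between a test and a reference field pattern:
#' `RE = 100 * ||t_test - t_ref|| / ||t_ref||` (percent) and the Pearson
#' correlation coefficient across channels. The second argument is the
#' reference (the more complete model).
#'
#' @param t_test,t_ref channel vectors of equal length; `t_ref` nonzero.
#' @returns one-row tibble with `re_percent` and `cc`.
#' @export
topography_error <- function(t_test, t_ref) {
  stopifnot(length(t_test) == length(t_ref))
  nref <- sqrt(sum(t_ref^2))
  if (nref == 0) stop("zero reference topography", call. = FALSE)
  if (stats::sd(t_test) == 0 || stats::sd(t_ref) == 0)
    stop("zero-variance topography: correlation undefined", call. = FALSE)
  tibble::tibble(re_percent = 100 * sqrt(sum((t_test - t_ref)^2)) / nref,
                 cc = stats::cor(t_test, t_ref))
}
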