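#' Per-channel sensor noise model
#'
#' Homoscedastic-per-type noise: each channel gets the standard deviation of
#' its sensor type, obtained from a spectral noise density (fT/√Hz) at a
#' common measurement bandwidth. Defaults: 3 fT/√Hz for SQUID magnetometers
#' and axial gradiometers, 15 fT/√Hz for OPMs (10 fT/√Hz is the optimistic
#' OPM level).
#'
#' @param channels a channel tibble ([make_channels()]) or a `leadfield`.
#' @param opm_noise,squid_noise spectral densities in T/√Hz.
#' @param bandwidth measurement bandwidth in Hz (std = density * sqrt(bw)).
#' @returns numeric vector of per-channel noise standard deviations (tesla).
#' @export
noise_model <- function(channels, opm_noise = 15e-15, squid_noise = 3e-15,
                        bandwidth = 1) {
  ch <- if (inherits(channels, "leadfield")) channels$channels else channels
  if (!"sensor_type" %in% names(ch))
    stop("channel table lacks sensor_type", call. = FALSE)
  dens <- ifelse(ch$sensor_type == "opm", opm_noise, squid_noise)
  std <- dens * sqrt(bandwidth)
  if (any(std <= 0)) stop("noise standard deviations must be positive", call. = FALSE)
  std
}

#' Whiten a lead field by per-channel noise
#'
#' Divides each channel row by its noise standard deviation, making rows
#' unitless per A·m and channels comparable across sensor types.
#'
#' @param L a `leadfield` or gain matrix.
#' @param noise per-channel noise stds (tesla), one per channel.
#' @returns whitened gain matrix.
#' @export
whiten <- function(L, noise) {
  g <- if (inherits(L, "leadfield")) L$gain else as.matrix(L)
  if (length(noise) != nrow(g))
    stop("need one noise std per channel", call. = FALSE)
  if (any(noise <= 0)) stop("noise stds must be positive", call. = FALSE)
  g / noise
}

#' SNR spectrum of the orthogonalized channels
#'
#' Eigenvalues of `q2 * W W^T` for whitened gain `W`, in descending order
#' (negatives from round-off clipped to zero). Orthogonalization avoids
#' overestimating information from correlated sensor lead fields; the
#' spectrum keeps one entry per channel, with zero eigenvalues beyond the
#' numerical rank contributing no information.
#'
#' @param W whitened gain (channels x sources).
#' @param q2 source variance in (A·m)^2 (> 0), identical for all sources.
#' @returns numeric vector of per-orthogonal-channel SNRs, length nrow(W).
#' @export
orthogonal_snrs <- function(W, q2) {
  if (q2 <= 0) stop("q2 must be positive", call. = FALSE)
  W <- as.matrix(W)
  if (any(!is.finite(W))) stop("non-finite whitened gain", call. = FALSE)
  ev <- eigen(tcrossprod(W), symmetric = TRUE, only.values = TRUE)$values
  pmax(q2 * ev, 0)
}

#' Total Shannon information of an SNR spectrum
#'
#' `Itot = 1/2 * sum_i log2(SNR'_i + 1)` bits over the orthogonalized
#' channels.
#'
#' @param spectrum nonnegative SNR spectrum.
#' @returns total information in bits.
#' @export
total_information <- function(spectrum) {
  stopifnot(all(spectrum >= 0))
  0.5 * sum(log2(spectrum + 1))
}

#' Calibrate the source variance q2
#'
#' Per-source SNR is defined as `q2 * ||w_j||^2`, the whitened topography
#' power of source j. The returned `q2 = 1 / mean_j(||w_j||^2)` makes the
#' average SNR across sources equal 1 on the supplied reference whitened
#' gain (conventionally the largest reference array over the whole brain);
#' the same q2 is then applied to every array, sensor type and region.
#'
#' @param W_ref reference whitened gain matrix.
#' @returns scalar q2 in (A·m)^2.
#' @export
calibrate_source_variance <- function(W_ref) {
  p <- colSums(as.matrix(W_ref)^2)
  if (all(p == 0)) stop("all-zero reference gain", call. = FALSE)
  1 / mean(p)
}

#' Information capacity of one array over one source space
#'
#' Whitens, orthogonalizes, and sums Shannon information.
#'
#' @param L a `leadfield`.
#' @param noise per-channel noise stds (see [noise_model()]).
#' @param q2 calibrated source variance, (A·m)^2.
#' @param region label stored on the result.
#' @returns object of class `infocap_result`: `snr_spectrum` (descending),
#'   `itot` (bits), `n_channels`, `q2`, `region`.
#' @export
info_capacity <- function(L, noise, q2, region = NULL) {
  W <- whiten(L, noise)
  spec <- sort(orthogonal_snrs(W, q2), decreasing = TRUE)
  if (is.null(region))
    region <- if (inherits(L, "leadfield")) L$space$region else NA_character_
  structure(list(snr_spectrum = spec, itot = total_information(spec),
                 n_channels = length(spec), q2 = q2, region = region),
            class = "infocap_result")
}

#' @exportS3Method base::print
print.infocap_result <- function(x, ...) {
  cat(sprintf("<infocap_result> region '%s': %.1f bits over %d channels (q2 = %.3g)\n",
              x$region, x$itot, x$n_channels, x$q2))
  invisible(x)
}

#' Information-capacity sweep over sensor count
#'
#' Builds nested uniform arrays (farthest-point-sampling prefixes of the
#' largest layout, so arrays at smaller counts are strict subsets), computes
#' lead fields per region once at the maximum count, and evaluates Itot for
#' every (family, count, noise, region) cell. The whole-brain region is the
#' concatenated source space, not the sum of regional capacities. Each row
#' carries the mean neighboring-sensor distance and an overlap flag marking
#' counts where rigid sensors of that type would physically overlap.
#'
#' @param scalp scalp `surface_mesh`.
#' @param spaces named list of `source_space`s, e.g.
#'   `list(cortex = ..., cerebellum = ...)`; a `whole_brain` region is added
#'   automatically when both are present.
#' @param helmet_positions seed positions for the candidate meshes.
#' @param counts ascending sensor counts.
#' @param families tibble with columns `family`, `sensor_type`,
#'   `channel_mode`, `noise` (list column of spectral densities in T/√Hz);
#'   default: SQUID magnetometers at 3 fT/√Hz, single-axis and triaxial OPMs
#'   at 10 and 15 fT/√Hz.
#' @param q2_reference list naming the calibration cell: `family` and
#'   `region` (default: the largest-count array of the first family, whole
#'   brain).
#' @param sphere_center conductor center.
#' @param target_vertices,n_basis candidate-mesh controls.
#' @returns tibble of class `itot_sweep`: `family`, `sensor_type`,
#'   `channel_mode`, `count`, `noise_ft` (fT/√Hz), `region`, `n_channels`,
#'   `itot_bits`, `mean_neighbor_distance`, `overlap_flag`; the per-cell
#'   `infocap_result`s in a `result` list column.
#' @export
itot_sweep <- function(scalp, spaces, helmet_positions, counts,
                       families = default_families(),
                       q2_reference = list(family = families$family[1],
                                           region = "whole_brain"),
                       sphere_center = c(0, 0, 0),
                       target_vertices = 2000, n_basis = 60) {
  stopifnot(!is.unsorted(counts))
  if (all(c("cortex", "cerebellum") %in% names(spaces)) &&
      !"whole_brain" %in% names(spaces))
    spaces$whole_brain <- concat_source_spaces(spaces$cortex, spaces$cerebellum)
  kmax <- max(counts)
  # per sensor type: one candidate mesh, one FPS chain, one max-count lead
  # field per region; prefix arrays are row-subsets of the max-count one
  per_type <- list()
  for (ty in unique(families$sensor_type)) {
    standoff <- default_standoff(ty)
    seeds <- project_to_scalp(helmet_positions, scalp, standoff = standoff)
    cand <- build_candidate_mesh(sensor_positions(seeds), target_vertices,
                                 scalp = scalp, standoff = standoff)
    cand <- laplace_embedding(cand, n_basis = n_basis)
    arr_max <- make_uniform_array(scalp, NULL, kmax, sensor_type = ty,
                                  candidate = cand)
    per_type[[ty]] <- list(array = arr_max)
  }
  rows <- list()
  q2 <- NA_real_
  # calibration first: reference family at max count, designated region
  ref_fam <- families[families$family == q2_reference$family, ][1, ]
  ref_arrmax <- per_type[[ref_fam$sensor_type]]$array
  ref_arr <- sensor_array(ref_arrmax, channel_mode = ref_fam$channel_mode,
                          name = attr(ref_arrmax, "array_name"))
  ref_L <- assemble_leadfield(ref_arr, spaces[[q2_reference$region]], sphere_center)
  ref_noise <- noise_model(ref_L, opm_noise = ref_fam$noise[[1]][1],
                           squid_noise = ref_fam$noise[[1]][1])
  q2 <- calibrate_source_variance(whiten(ref_L, ref_noise))
  for (fi in seq_len(nrow(families))) {
    fam <- families[fi, ]
    arr_max <- per_type[[fam$sensor_type]]$array
    arr_max <- sensor_array(arr_max, channel_mode = fam$channel_mode,
                            name = attr(arr_max, "array_name"))
    L_max <- lapply(spaces, function(sp) assemble_leadfield(arr_max, sp, sphere_center))
    ch <- L_max[[1]]$channels
    for (k in counts) {
      keep_sensors <- arr_max$sensor_id[seq_len(k)]
      rowsel <- which(ch$sensor_id %in% keep_sensors)
      sub_arr <- sensor_array(arr_max[seq_len(k), ], channel_mode = fam$channel_mode,
                              name = sprintf("uniform_%s_%d", fam$sensor_type, k))
      nd <- if (k >= 2) mean_neighbor_distance(sub_arr) else
        list(mean_distance = NA_real_, overlap_flag = NA)
      for (nl in fam$noise[[1]]) {
        for (reg in names(spaces)) {
          Lk <- L_max[[reg]]
          gain <- Lk$gain[rowsel, , drop = FALSE]
          noise <- rep(nl, length(rowsel))  # families are single-type arrays
          res <- info_capacity(new_leadfield(gain, ch[rowsel, ], Lk$space,
                                             Lk$model_tag),
                               noise, q2, region = reg)
          rows[[length(rows) + 1]] <- tibble::tibble(
            family = fam$family, sensor_type = fam$sensor_type,
            channel_mode = fam$channel_mode, count = k, noise_ft = nl * 1e15,
            region = reg, n_channels = res$n_channels, itot_bits = res$itot,
            mean_neighbor_distance = nd$mean_distance,
            overlap_flag = nd$overlap_flag, result = list(res))
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("itot_sweep", class(out))
  attr(out, "q2") <- q2
  out
}

#' Default sweep families
#'
#' SQUID magnetometers at 3 fT/√Hz; single-axis and triaxial OPMs at 10 and
#' 15 fT/√Hz each.
#'
#' @returns tibble with `family`, `sensor_type`, `channel_mode`, `noise`.
#' @export
default_families <- function() {
  tibble::tibble(
    family = c("squid", "opm", "triaxial_opm"),
    sensor_type = c("squid_mag", "opm", "opm"),
    channel_mode = c("single_axis", "single_axis", "triaxial"),
    noise = list(3e-15, c(10e-15, 15e-15), c(10e-15, 15e-15)))
}
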