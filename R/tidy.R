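#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an information-capacity result
#'
#' @param x an `infocap_result`.
#' @param ... unused.
#' @returns tibble with `channel` (orthogonalized channel rank), `snr` and
#'   `bits` (that channel's information contribution).
#' @export
tidy.infocap_result <- function(x, ...) {
  tibble::tibble(channel = seq_len(x$n_channels), snr = x$snr_spectrum,
                 bits = 0.5 * log2(x$snr_spectrum + 1))
}

#' @rdname tidy.infocap_result
#' @returns `glance()`: one-row tibble with `region`, `n_channels`, `q2`,
#'   `itot_bits`.
#' @export
glance.infocap_result <- function(x, ...) {
  tibble::tibble(region = x$region, n_channels = x$n_channels, q2 = x$q2,
                 itot_bits = x$itot)
}

#' Tidy a subspace-angle result
#'
#' @param x a `subspace_result`.
#' @param ... unused.
#' @returns tibble with `angle_rank` and `cosine`.
#' @export
tidy.subspace_result <- function(x, ...) {
  tibble::tibble(angle_rank = seq_along(x$cosines), cosine = x$cosines)
}

#' @rdname tidy.subspace_result
#' @export
glance.subspace_result <- function(x, ...) {
  tibble::tibble(rank_a = x$rank_a, rank_b = x$rank_b,
                 mean_cosine = mean(x$cosines),
                 max_cosine = max(x$cosines), min_cosine = min(x$cosines))
}

#' Glance at a lead field
#'
#' @param x a `leadfield`.
#' @param ... unused.
#' @returns one-row tibble with dimensions, model tag, units and the
#'   conservation factor.
#' @export
glance.leadfield <- function(x, ...) {
  tibble::tibble(n_channels = nrow(x$gain), n_sources = ncol(x$gain),
                 model_tag = x$model_tag, units = x$units,
                 conservation_factor = conservation_factor(x))
}

#' Density plot of a sensitivity map
#'
#' One density curve per source region, on the sensitivity scale of the map
#' (tesla; shown in pT).
#'
#' @param object a `sensitivity_map`.
#' @param ... unused.
#' @returns a ggplot.
#' @export
autoplot.sensitivity_map <- function(object, ...) {
  lab <- if (isTRUE(attr(object, "per_sensor")))
    "sensitivity per sensor (pT)" else "sensitivity (pT)"
  ggplot2::ggplot(object, ggplot2::aes(x = .data$sensitivity * 1e12,
                                       fill = .data$region)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::labs(x = lab, y = "density") +
    ggplot2::theme_minimal()
}

#' Distribution of a correlation map
#'
#' @param object a `correlation_map` (patch-to-patch values).
#' @param ... unused.
#' @returns a ggplot.
#' @export
autoplot.correlation_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$correlation)) +
    ggplot2::geom_density(fill = "grey70") +
    ggplot2::geom_vline(xintercept = mean(object$correlation), linetype = 2) +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "mean subspace correlation", y = "density") +
    ggplot2::theme_minimal()
}

#' Information capacity versus sensor count
#'
#' One line per (family, noise level); overlap-flagged segments are drawn
#' with reduced alpha.
#'
#' @param object an `itot_sweep` tibble.
#' @param region region to plot (default `"cerebellum"`).
#' @param ... unused.
#' @returns a ggplot.
#' @export
autoplot.itot_sweep <- function(object, region = "cerebellum", ...) {
  d <- dplyr::filter(object, .data$region == !!region)
  d$series <- paste0(d$family, " @ ", d$noise_ft, " fT/√Hz")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$count, y = .data$itot_bits,
                                  color = .data$series,
                                  alpha = !.data$overlap_flag)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.35),
                                guide = "none") +
    ggplot2::labs(x = "sensor count", y = expression(I[tot] ~ "(bits)"),
                  title = region) +
    ggplot2::theme_minimal()
}
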