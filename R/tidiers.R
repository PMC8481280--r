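# broom-style tidiers and re-exports

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a kymograph into a long tibble
#'
#' @param x A [build_kymograph()] result.
#' @param ... Unused.
#' @return Tibble `angle_deg, t_min, value, n_domains`.
#' @export
tidy.kymograph <- function(x, ...) {
  tibble::tibble(
    angle_deg = rep(x$angles, times = length(x$times)),
    t_min = rep(x$times, each = length(x$angles)),
    value = as.vector(x$values),
    n_domains = as.vector(x$counts)
  )
}

#' One-row summary of a kymograph
#'
#' @param x A [build_kymograph()] result.
#' @param ... Unused.
#' @return Tibble with band, component, dimensions and missing fraction.
#' @export
glance.kymograph <- function(x, ...) {
  tibble::tibble(
    band = x$spec$band, component = x$spec$component,
    n_bins = length(x$angles), n_times = length(x$times),
    frac_missing = mean(!is.finite(x$values))
  )
}

#' One-row summary of a strain-map table
#'
#' @param x A [integrate_strain()] result.
#' @param ... Unused.
#' @return Tibble with node/window counts, window length and the fraction
#'   of finite component values.
#' @export
glance.strain_maps <- function(x, ...) {
  tibble::tibble(
    n_nodes = dplyr::n_distinct(x$node_id),
    n_windows = dplyr::n_distinct(x$t_min),
    window_min = attr(x, "window"),
    frac_valid = mean(is.finite(x$e_ML))
  )
}

#' Tidy a simulated embryo into its reported track table
#'
#' @param x An [simulate_embryo()] result.
#' @param ... Unused.
#' @return The reported track tibble.
#' @export
tidy.embryo_sim <- function(x, ...) x$tracks

#' One-row summary of a simulated embryo
#'
#' @param x An [simulate_embryo()] result.
#' @param ... Unused.
#' @return Tibble with cell/detection counts and key config values.
#' @export
glance.embryo_sim <- function(x, ...) {
  tibble::tibble(
    n_cells_start = x$config$n_cells,
    n_tracks = dplyr::n_distinct(x$tracks$track_id),
    n_detections = nrow(x$tracks),
    duration_min = x$config$duration,
    frame_interval_min = x$config$frame_interval,
    noise_sigma_um = x$config$noise_sigma
  )
}
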