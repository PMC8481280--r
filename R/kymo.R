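# Kymographs: angle x time matrices of one integrated strain component
# along an annular band (equatorial, or axial along the dorsal/ventral
# meridian).

#' Kymograph band specification
#'
#' @param band `"equatorial"` (the circumference bisecting the dorsal (0
#'   degrees) and ventral (+-180 degrees) meridians), `"axial_dorsal"`
#'   (along the dorsal meridian, anterior 0 to posterior 180 degrees) or
#'   `"axial_ventral"` (likewise along the ventral meridian).
#' @param component Strain component: one of `e_AP`, `e_ML`, `e_r`,
#'   `trace`, `curl_r`.
#' @param half_span Half the angular span of the band, radians; default
#'   0.19 (full span 0.38 rad).
#' @param angle_bin Angle bin width, degrees; default 5. For the
#'   equatorial band 360 must be divisible by it.
#' @return Object of class `kymograph_spec`.
#' @export
kymograph_spec <- function(band = c("equatorial", "axial_dorsal",
                                    "axial_ventral"),
                           component = c("e_ML", "e_AP", "e_r", "trace",
                                         "curl_r"),
                           half_span = 0.19, angle_bin = 5) {
  band <- match.arg(band)
  component <- match.arg(component)
  if (!(half_span > 0 && half_span < pi / 4)) {
    abort("`half_span` must be in (0, pi/4) radians.")
  }
  if (band == "equatorial" && 360 %% angle_bin != 0) {
    abort("for the equatorial band, 360 must be divisible by `angle_bin`.")
  }
  structure(list(band = band, component = component,
                 half_span = half_span, angle_bin = angle_bin),
            class = "kymograph_spec")
}

#' Select the mesh nodes of an annular band
#'
#' Equatorial band: nodes with `|theta - pi/2| <= half_span`; the band
#' angle is the signed azimuth in degrees, dorsal at 0, ventral at +-180,
#' increasing anticlockwise viewed from the anterior pole. Axial bands:
#' nodes within `half_span` of the dorsal (`|phi| <= half_span`) or
#' ventral (`|phi - pi|` wrapped) meridian; the band angle is the
#' elevation from the anterior pole, 0 to 180 degrees.
#'
#' @param mesh A [make_mesh()] mesh.
#' @param geom An [embryo_geometry()].
#' @param spec A [kymograph_spec()].
#' @return Tibble `node_id`, `band_angle` (degrees).
#' @export
select_band <- function(mesh, geom, spec) {
  stopifnot(inherits(spec, "kymograph_spec"))
  co <- to_embryo_coords(mesh_node_positions(mesh, geom), geom)
  df <- tibble::tibble(node_id = mesh$nodes$node_id,
                       theta = co$theta, phi = co$phi)
  out <- switch(spec$band,
    equatorial = df |>
      dplyr::filter(abs(.data$theta - pi / 2) <= spec$half_span) |>
      dplyr::mutate(band_angle = .data$phi * 180 / pi),
    axial_dorsal = df |>
      dplyr::filter(!is.na(.data$phi), abs(.data$phi) <= spec$half_span) |>
      dplyr::mutate(band_angle = .data$theta * 180 / pi),
    axial_ventral = df |>
      dplyr::filter(!is.na(.data$phi),
                    abs(wrap_pi(.data$phi - pi)) <= spec$half_span) |>
      dplyr::mutate(band_angle = .data$theta * 180 / pi)
  )
  if (nrow(out) == 0) {
    abort("band selection is empty; increase `half_span` or mesh resolution.")
  }
  out[, c("node_id", "band_angle")]
}

#' Build an angle x time kymograph of a strain component
#'
#' Per angle bin and window-centre time, the unweighted mean of the chosen
#' integrated strain component over the valid band nodes falling in the
#' bin. Equatorial bins are circular (the +-180-degree ventral bin wraps);
#' the dorsal 0-degree bin is centred on 0. Bins with no valid node are
#' missing, not zero.
#'
#' @param maps A [integrate_strain()] result.
#' @param band Output of [select_band()] (recomputed from `mesh`/`geom`
#'   when those are given instead).
#' @param spec A [kymograph_spec()].
#' @return Object of class `kymograph`: list with `angles` (bin centres,
#'   degrees), `times` (window centres, min), `values` (matrix bins x
#'   times), `counts` (same shape, domains per bin) and `spec`.
#' @export
build_kymograph <- function(maps, band, spec) {
  stopifnot(inherits(spec, "kymograph_spec"))
  if (!spec$component %in% names(maps)) {
    abort(paste0("component '", spec$component, "' not present in `maps`."))
  }
  bw <- spec$angle_bin
  if (spec$band == "equatorial") {
    n_bins <- as.integer(360 / bw)
    centers <- seq(-180, 180 - bw, by = bw)
    bin_of <- function(ang) {
      idx <- round(ang / bw)
      lo <- -180 / bw
      idx[idx >= 180 / bw] <- lo  # +180 wraps onto -180
      as.integer(idx - lo + 1)
    }
  } else {
    centers <- seq(0, 180, by = bw)
    n_bins <- length(centers)
    bin_of <- function(ang) as.integer(pmin(pmax(round(ang / bw), 0),
                                            180 / bw) + 1)
  }
  df <- tibble::as_tibble(maps) |>
    dplyr::inner_join(band, by = "node_id") |>
    dplyr::mutate(value = .data[[spec$component]],
                  bin = bin_of(.data$band_angle)) |>
    dplyr::filter(is.finite(.data$value))
  times <- sort(unique(maps$t_min))
  values <- matrix(NA_real_, n_bins, length(times))
  counts <- matrix(0L, n_bins, length(times))
  agg <- df |>
    dplyr::group_by(.data$bin, .data$t_min) |>
    dplyr::summarise(value = mean(.data$value), n = dplyr::n(),
                     .groups = "drop")
  ij <- cbind(agg$bin, match(agg$t_min, times))
  values[ij] <- agg$value
  counts[ij] <- agg$n
  structure(list(angles = centers, times = times, values = values,
                 counts = counts, spec = spec),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %s band, component %s: %d angle bins x %d times\n",
              x$spec$band, x$spec$component, length(x$angles),
              length(x$times)))
  invisible(x)
}

#' Write a kymograph as a delimited matrix
#'
#' Angle bin centres as row labels, window-centre times as column labels.
#'
#' @param kym A [build_kymograph()] result.
#' @param path Output file.
#' @param delim Delimiter, default tab.
#' @return `path`, invisibly.
#' @export
write_kymograph <- function(kym, path, delim = "\t") {
  stopifnot(inherits(kym, "kymograph"))
  df <- as.data.frame(kym$values)
  names(df) <- sprintf("t%g", kym$times)
  df <- cbind(angle_deg = kym$angles, df)
  readr::write_delim(tibble::as_tibble(df), path, delim = delim)
  invisible(path)
}
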