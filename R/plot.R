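# Rendering: orthographic hemisphere projections of node fields and
# kymograph rasters, with the diverging red (expansion) / blue
# (compaction) colour semantics.

VIEW_DIRS <- c("dorsal", "ventral", "left", "right", "anterior", "posterior")

# unit view direction and in-plane basis for an orthographic projection
view_basis <- function(view, geom) {
  a <- geom$anterior_axis; d <- geom$dorsal_ref; m <- geom$ml_axis
  dir <- switch(view,
    dorsal = d, ventral = -d, left = m, right = -m,
    anterior = a, posterior = -a,
    abort(paste0("unknown view '", view, "'; expected one of: ",
                 paste(VIEW_DIRS, collapse = ", "))))
  # screen "up" is anterior where possible, dorsal for the polar views
  up <- if (view %in% c("anterior", "posterior")) d else a
  up <- up - sum(up * dir) * dir
  up <- up / sqrt(sum(up^2))
  right <- cross3(up, dir)
  list(dir = dir, up = up, right = right)
}

#' Orthographic strain-map view
#'
#' Projects the node values of one strain component at one window-centre
#' time onto the viewed hemisphere (orthographic projection along the view
#' axis). Colour limits are symmetric about zero: red = expansion /
#' positive, blue = compaction / negative; nodes with missing values are
#' drawn neutral grey.
#'
#' @param maps A [integrate_strain()] result (or any tibble with
#'   `node_id`, `t_min` and the component column).
#' @param mesh,geom Mesh and geometry the maps were computed on.
#' @param view One of `"dorsal"`, `"ventral"`, `"left"`, `"right"`,
#'   `"anterior"`, `"posterior"`.
#' @param component Column to plot, default `"e_ML"`.
#' @param time Window-centre time (min); default: midmost available.
#' @param point_size Marker size.
#' @return A ggplot object.
#' @export
plot_strain_map <- function(maps, mesh, geom, view = "dorsal",
                            component = "e_ML", time = NULL,
                            point_size = 2) {
  if (!component %in% names(maps)) {
    abort(paste0("component '", component, "' not present in `maps`."))
  }
  times <- sort(unique(maps$t_min))
  if (is.null(time)) time <- times[ceiling(length(times) / 2)]
  vb <- view_basis(view, geom)
  U <- mesh_node_matrix(mesh)
  depth <- as.numeric(U %*% vb$dir)
  px <- as.numeric(U %*% vb$right)
  py <- as.numeric(U %*% vb$up)
  df <- tibble::tibble(node_id = mesh$nodes$node_id,
                       px = px, py = py, depth = depth) |>
    dplyr::filter(.data$depth > 0) |>
    dplyr::left_join(
      dplyr::filter(tibble::as_tibble(maps), .data$t_min == time)[,
        c("node_id", component)],
      by = "node_id")
  vmax <- max(abs(df[[component]]), na.rm = TRUE)
  if (!is.finite(vmax) || vmax == 0) vmax <- 1e-12
  ggplot2::ggplot(df, ggplot2::aes(x = .data$px, y = .data$py)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data[[component]]),
                        size = point_size) +
    ggplot2::scale_colour_gradient2(low = "#2166ac", mid = "white",
                                    high = "#b2182b", midpoint = 0,
                                    limits = c(-vmax, vmax),
                                    na.value = "grey80",
                                    name = component) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s view, t = %g min", view, time)) +
    ggplot2::theme_void()
}

#' Render a strain-map view to a PNG file
#'
#' Thin wrapper over [plot_strain_map()] + [ggplot2::ggsave()].
#'
#' @inheritParams plot_strain_map
#' @param path Output PNG path.
#' @param width,height,dpi Image size (inches) and resolution.
#' @return `path`, invisibly.
#' @export
render_map <- function(maps, mesh, geom, view, path, component = "e_ML",
                       time = NULL, width = 4, height = 4, dpi = 150) {
  p <- plot_strain_map(maps, mesh, geom, view = view,
                       component = component, time = time)
  ggplot2::ggsave(path, p, width = width, height = height, dpi = dpi)
  invisible(path)
}

#' Velocity field view with direction classes
#'
#' Orthographic projection of per-cell velocities at one time, coloured by
#' dominant direction class: toward-anterior (green), toward-posterior
#' (red), or medio-lateral (blue).
#'
#' @param velocities Output of [compute_velocities()].
#' @param geom An [embryo_geometry()].
#' @param view View direction, see [plot_strain_map()].
#' @param time Time (min); default: midmost sample time.
#' @param max_cells Subsample cap for plotting.
#' @return A ggplot object.
#' @export
plot_velocity_map <- function(velocities, geom, view = "dorsal",
                              time = NULL, max_cells = 3000) {
  times <- sort(unique(velocities$t_min))
  if (is.null(time)) time <- times[ceiling(length(times) / 2)]
  df <- dplyr::filter(velocities, .data$t_min == time, is.finite(.data$vx))
  if (nrow(df) > max_cells) df <- df[seq_len(max_cells), ]
  P <- as_xyz_matrix(df)
  U <- sweep(P, 2, geom$center)
  U <- U / sqrt(rowSums(U^2))
  fr <- frames_at_points(U, geom)
  V <- as.matrix(df[, c("vx", "vy", "vz")])
  v_ap <- rowSums(V * cbind(fr$ap_x, fr$ap_y, fr$ap_z))
  v_ml <- rowSums(V * cbind(fr$ml_x, fr$ml_y, fr$ml_z))
  cls <- dplyr::case_when(
    !is.finite(v_ap) | !is.finite(v_ml) ~ NA_character_,
    abs(v_ap) >= abs(v_ml) & v_ap < 0 ~ "toward-anterior",
    abs(v_ap) >= abs(v_ml) ~ "toward-posterior",
    TRUE ~ "medio-lateral")
  vb <- view_basis(view, geom)
  depth <- as.numeric(U %*% vb$dir)
  keep <- depth > 0 & !is.na(cls)
  plot_df <- tibble::tibble(px = as.numeric(U %*% vb$right)[keep],
                            py = as.numeric(U %*% vb$up)[keep],
                            class = cls[keep])
  ggplot2::ggplot(plot_df, ggplot2::aes(x = .data$px, y = .data$py,
                                        colour = .data$class)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_manual(values = c(
      "toward-anterior" = "#1b9e77", "toward-posterior" = "#d95f02",
      "medio-lateral" = "#3c6df0"), name = NULL) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s view, t = %g min", view, time)) +
    ggplot2::theme_void()
}

#' @rdname plot_strain_map
#' @param object A `strain_maps` tibble (for `autoplot`).
#' @param ... Passed to [plot_strain_map()]; must include `mesh` and
#'   `geom`.
#' @export
autoplot.strain_maps <- function(object, ...) {
  plot_strain_map(object, ...)
}

#' Kymograph raster plot
#'
#' Angle x time raster with the diverging red (expansion) / blue
#' (compaction) scale, symmetric about zero.
#'
#' @param object A [build_kymograph()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kymograph <- function(object, ...) {
  df <- tidy(object)
  vmax <- max(abs(df$value), na.rm = TRUE)
  if (!is.finite(vmax) || vmax == 0) vmax <- 1e-12
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_min, y = .data$angle_deg,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0,
                                  limits = c(-vmax, vmax),
                                  na.value = "grey85",
                                  name = object$spec$component) +
    ggplot2::labs(x = "time (min)",
                  y = sprintf("%s band angle (deg)", object$spec$band))
}
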