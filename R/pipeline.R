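# End-to-end orchestration: tracks (read or simulated) -> geometry -> mesh
# -> velocities -> strain-rate field -> windowed strain maps -> kymographs
# -> rendered views, all written to an output directory together with a
# copy of the run configuration.

#' Pipeline run configuration
#'
#' Fully serializable description of one analysis run. Either `tracks_path`
#' (a track table on disk) or `preset` (a [preset_scenario()] name to
#' simulate) must be given.
#'
#' @param tracks_path Path to a track table (see [read_tracks()]), or
#'   `NULL` to simulate.
#' @param preset Simulation preset name (see [preset_scenarios()]), or
#'   `NULL` to read tracks.
#' @param anterior_axis,dorsal_ref Anatomical axes (required for real
#'   tracks; the simulator's own axes are used for presets).
#' @param n_nodes Mesh size; default 2000.
#' @param domain_radius,window,gradient_mode,min_cells_per_domain Passed to
#'   [tectonics_config()].
#' @param kymographs List of [kymograph_spec()] (or lists of arguments for
#'   it); default: equatorial e_ML, e_AP and curl_r.
#' @param views Hemisphere views to render; default dorsal + ventral.
#' @param render_component Component for the rendered views.
#' @param seed Seed used for simulation presets.
#' @return Object of class `run_config` (a named list).
#' @export
run_config <- function(tracks_path = NULL, preset = NULL,
                       anterior_axis = c(0, 0, 1), dorsal_ref = c(1, 0, 0),
                       n_nodes = 2000, domain_radius = 110, window = 30,
                       gradient_mode = "cell_regression",
                       min_cells_per_domain = 4,
                       kymographs = list(
                         list(band = "equatorial", component = "e_ML"),
                         list(band = "equatorial", component = "e_AP"),
                         list(band = "equatorial", component = "curl_r")),
                       views = c("dorsal", "ventral"),
                       render_component = "e_ML", seed = 1) {
  if (is.null(tracks_path) && is.null(preset)) {
    abort("run_config needs either `tracks_path` or `preset`.")
  }
  structure(list(tracks_path = tracks_path, preset = preset,
                 anterior_axis = as.numeric(anterior_axis),
                 dorsal_ref = as.numeric(dorsal_ref),
                 n_nodes = n_nodes, domain_radius = domain_radius,
                 window = window, gradient_mode = gradient_mode,
                 min_cells_per_domain = min_cells_per_domain,
                 kymographs = lapply(kymographs, function(k) {
                   if (inherits(k, "kymograph_spec")) unclass(k) else k
                 }),
                 views = views, render_component = render_component,
                 seed = seed),
            class = "run_config")
}

#' Read / write a run configuration
#'
#' Plain-text YAML serialization of a [run_config()].
#'
#' @param config A [run_config()].
#' @param path File path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   a `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the full tissue-tectonics pipeline
#'
#' Executes every stage and writes the outputs into `output_dir`:
#' `tracks.tsv` (when simulated), `geometry.yaml`, `strain_maps.tsv`
#' (long-format per-node table), one `kymograph_<band>_<component>.tsv`
#' per requested kymograph, one `map_<view>.png` per requested view, and
#' `run_config.yaml` (the exact configuration of the run). Every parameter
#' that affects numerics (mesh size, domain radius, window, gradient mode,
#' seed) is echoed in messages and in the config copy.
#'
#' @param config A [run_config()] or a path to a YAML file of one.
#' @param output_dir Output directory (created if needed).
#' @return Invisibly, a named list of output paths plus the in-memory
#'   `maps` and `kymographs`.
#' @export
run_pipeline <- function(config, output_dir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  inform(sprintf(
    "run: n_nodes=%d domain_radius=%g window=%g mode=%s seed=%d",
    config$n_nodes, config$domain_radius, config$window,
    config$gradient_mode, config$seed))

  paths <- list(config = file.path(output_dir, "run_config.yaml"))
  write_run_config(config, paths$config)

  if (!is.null(config$preset)) {
    sc <- preset_scenario(config$preset, seed = config$seed)
    sim <- simulate_embryo(sc$config, sc$flow)
    tracks <- sim$tracks
    geom <- sim$geom
    paths$tracks <- file.path(output_dir, "tracks.tsv")
    write_tracks(tracks, paths$tracks)
    frame_interval <- sc$config$frame_interval
  } else {
    tracks <- read_tracks(config$tracks_path)
    frame_interval <- track_frame_interval(tracks)
    geom <- fit_embryo_geometry(tracks,
                                anterior_axis = config$anterior_axis,
                                dorsal_ref = config$dorsal_ref)
  }
  paths$geometry <- file.path(output_dir, "geometry.yaml")
  write_geometry(geom, paths$geometry)

  mesh <- make_mesh(config$n_nodes)
  tcfg <- tectonics_config(domain_radius = config$domain_radius,
                           window = config$window,
                           min_cells_per_domain = config$min_cells_per_domain,
                           gradient_mode = config$gradient_mode)
  vel <- compute_velocities(tracks, frame_interval = frame_interval)
  rates <- strain_rate_field(vel, geom, mesh, tcfg)
  maps <- integrate_strain(rates, window = config$window)

  paths$strain_maps <- file.path(output_dir, "strain_maps.tsv")
  export <- tibble::as_tibble(maps) |>
    dplyr::mutate(valid = is.finite(.data$e_ML)) |>
    dplyr::select(dplyr::all_of(c("node_id", "theta", "phi", "t_min",
                                  "e_AP", "e_ML", "e_r", "trace", "curl_r",
                                  "n_cells", "valid")))
  readr::write_tsv(export, paths$strain_maps)

  kyms <- list()
  for (ks in config$kymographs) {
    spec <- do.call(kymograph_spec, ks)
    band <- select_band(mesh, geom, spec)
    kym <- build_kymograph(maps, band, spec)
    nm <- sprintf("kymograph_%s_%s", spec$band, spec$component)
    paths[[nm]] <- file.path(output_dir, paste0(nm, ".tsv"))
    write_kymograph(kym, paths[[nm]])
    kyms[[nm]] <- kym
  }

  for (v in config$views) {
    nm <- paste0("map_", v)
    paths[[nm]] <- file.path(output_dir, paste0(nm, ".png"))
    tryCatch(render_map(maps, mesh, geom, view = v, path = paths[[nm]],
                        component = config$render_component),
             error = function(e) {
               warn(sprintf("rendering '%s' failed: %s", v,
                            conditionMessage(e)))
             })
  }
  invisible(c(paths, list(maps = maps, kymographs = kyms, geom = geom,
                          mesh = mesh)))
}
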