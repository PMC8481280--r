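# Synthetic gastrulating embryo: composable analytic surface flows with
# closed-form velocity gradients, used as ground truth for the strain
# pipeline.
#
# Each flow term is defined by its physical components in the local
# spherical frame (e_r, e_AP, e_ML) and mapped to Cartesian. The exact
# Cartesian Jacobian is assembled from the standard velocity-gradient
# formulas in spherical coordinates, so every downstream quantity has an
# oracle.

#' Analytic morphogenetic flow specification
#'
#' Superposition of the lowest-order smooth fields exhibiting the named
#' gastrulation movements on a sphere:
#' \describe{
#'   \item{epiboly}{meridional flow towards the posterior pole,
#'     `v_theta = A_ep * sin(theta)` (um/min).}
#'   \item{convergence}{azimuthal flow towards the dorsal meridian,
#'     `v_phi = -A_conv * sin(phi) * sin(theta)` (um/min).}
#'   \item{extension}{meridional divergence away from the dorsal
#'     equatorial saddle,
#'     `v_theta = A_ext * u * exp(-u^2/(2*theta_ext^2)) * exp(-phi^2/(2*sigma_ext^2))`
#'     with `u = theta - pi/2`. The Gaussian envelope in `u` localizes the
#'     term near the equator while keeping the field smooth with a
#'     closed-form gradient everywhere.}
#'   \item{rigid rotation}{`v = omega_rigid x (x - center)` (rad/min).}
#'   \item{radial expansion}{`v_r = k_rad * r` (1/min), i.e. `L = k_rad I`.}
#'   \item{translation}{constant drift `u_translate` (um/min), `L = 0`.}
#' }
#' All amplitudes zero gives the static embryo.
#'
#' @param A_ep,A_conv,A_ext Flow amplitudes, micrometres/min.
#' @param sigma_ext Azimuthal width of the extension term, radians.
#' @param theta_ext Meridional width of the extension term, radians.
#' @param omega_rigid Rigid-body angular velocity, 3-vector, rad/min.
#' @param k_rad Radial expansion rate, 1/min.
#' @param u_translate Uniform drift, 3-vector, micrometres/min.
#' @return Object of class `flow_spec`.
#' @export
flow_spec <- function(A_ep = 0, A_conv = 0, A_ext = 0,
                      sigma_ext = 0.5, theta_ext = 0.6,
                      omega_rigid = c(0, 0, 0), k_rad = 0,
                      u_translate = c(0, 0, 0)) {
  stopifnot(length(omega_rigid) == 3, length(u_translate) == 3,
            sigma_ext > 0, theta_ext > 0)
  structure(list(A_ep = A_ep, A_conv = A_conv, A_ext = A_ext,
                 sigma_ext = sigma_ext, theta_ext = theta_ext,
                 omega_rigid = as.numeric(omega_rigid), k_rad = k_rad,
                 u_translate = as.numeric(u_translate)),
            class = "flow_spec")
}

has_tangential <- function(flow) {
  flow$A_ep != 0 || flow$A_conv != 0 || flow$A_ext != 0
}

# spherical decomposition of points relative to the embryo axes; shared by
# the velocity and gradient evaluators
flow_frame <- function(points, geom) {
  P <- sweep(as_xyz_matrix(points), 2, geom$center)
  r <- sqrt(rowSums(P^2))
  if (any(r < 1e-9)) abort("flow evaluation at the embryo center.")
  U <- P / r
  a <- geom$anterior_axis; d <- geom$dorsal_ref; m <- geom$ml_axis
  ct <- pmin(1, pmax(-1, as.numeric(U %*% a)))
  st <- sqrt(pmax(0, 1 - ct^2))
  phi <- atan2(as.numeric(U %*% m), as.numeric(U %*% d))
  cp <- cos(phi); sp <- sin(phi)
  e_r <- U
  e_th <- (ct * cp) %o% d + (ct * sp) %o% m - st %o% a
  e_ph <- (-sp) %o% d + cp %o% m
  list(r = r, theta = acos(ct), phi = phi, st = st, ct = ct, cp = cp, sp = sp,
       e_r = e_r, e_th = e_th, e_ph = e_ph)
}

# tangential physical components (v_theta, v_phi) and their angular
# derivatives for the ep/conv/ext terms, as functions of theta/phi
flow_tangential <- function(fr, flow) {
  th <- fr$theta; st <- fr$st; ct <- fr$ct
  phi <- fr$phi; sp <- fr$sp; cp <- fr$cp
  u <- th - pi / 2
  g <- exp(-u^2 / (2 * flow$theta_ext^2))
  h <- exp(-phi^2 / (2 * flow$sigma_ext^2))
  v_th <- flow$A_ep * st + flow$A_ext * u * g * h
  v_ph <- -flow$A_conv * sp * st
  dvth_dth <- flow$A_ep * ct + flow$A_ext * h * g * (1 - u^2 / flow$theta_ext^2)
  dvth_dph <- flow$A_ext * u * g * h * (-phi / flow$sigma_ext^2)
  dvph_dth <- -flow$A_conv * sp * ct
  dvph_dph <- -flow$A_conv * cp * st
  list(v_th = v_th, v_ph = v_ph,
       dvth_dth = dvth_dth, dvth_dph = dvth_dph,
       dvph_dth = dvph_dth, dvph_dph = dvph_dph)
}

#' Evaluate an analytic flow and its exact velocity gradient
#'
#' `analytic_velocity()` returns the flow velocity at the given points;
#' `analytic_gradient()` returns the exact 3x3 Cartesian velocity-gradient
#' tensor `L[a,b] = dv_a/dx_b` (assembled from the closed-form spherical
#' gradient of each term, plus `skew(omega)` for the rigid part and
#' `k_rad * I` for radial expansion). The tangential flow terms are
#' undefined at the poles: evaluation there raises an error when any
#' tangential amplitude is non-zero.
#'
#' @param points Positions (um, world coordinates); matrix or data frame.
#' @param flow A [flow_spec()].
#' @param geom An [embryo_geometry()].
#' @return `analytic_velocity`: tibble `vx, vy, vz` (um/min).
#'   `analytic_gradient`: tibble `L11..L33` (1/min), row-major names
#'   (`L12` is `dv_x/dy`).
#' @export
analytic_velocity <- function(points, flow, geom) {
  P <- as_xyz_matrix(points)
  fr <- flow_frame(P, geom)
  if (has_tangential(flow) && any(fr$st < 1e-8)) {
    abort("tangential flow terms are undefined at the poles.")
  }
  tg <- flow_tangential(fr, flow)
  V <- tg$v_th * fr$e_th + tg$v_ph * fr$e_ph + (flow$k_rad * fr$r) * fr$e_r
  rel <- sweep(P, 2, geom$center)
  w <- flow$omega_rigid
  V <- V + cbind(w[2] * rel[, 3] - w[3] * rel[, 2],
                 w[3] * rel[, 1] - w[1] * rel[, 3],
                 w[1] * rel[, 2] - w[2] * rel[, 1])
  V <- sweep(V, 2, flow$u_translate, `+`)
  tibble::tibble(vx = V[, 1], vy = V[, 2], vz = V[, 3])
}

#' @rdname analytic_velocity
#' @export
analytic_gradient <- function(points, flow, geom) {
  P <- as_xyz_matrix(points)
  fr <- flow_frame(P, geom)
  if (has_tangential(flow) && any(fr$st < 1e-8)) {
    abort("tangential flow terms are undefined at the poles.")
  }
  tg <- flow_tangential(fr, flow)
  n <- nrow(P)
  r <- fr$r; st <- pmax(fr$st, 1e-300); cot <- fr$ct / st
  # spherical components of grad v, order (r, theta, phi); v_r = 0 here
  S <- array(0, c(n, 3, 3))
  S[, 1, 2] <- -tg$v_th / r                      # L_r,theta
  S[, 1, 3] <- -tg$v_ph / r                      # L_r,phi
  S[, 2, 2] <- tg$dvth_dth / r                   # L_theta,theta
  S[, 2, 3] <- tg$dvth_dph / (r * st) - tg$v_ph * cot / r
  S[, 3, 2] <- tg$dvph_dth / r
  S[, 3, 3] <- tg$dvph_dph / (r * st) + tg$v_th * cot / r
  # map to Cartesian: L = B S B^T with B = [e_r e_theta e_phi]
  L <- matrix(0, n, 9)  # row-major L11,L12,...,L33
  B <- list(fr$e_r, fr$e_th, fr$e_ph)
  for (a in 1:3) for (b in 1:3) {
    acc <- numeric(n)
    for (i in 1:3) for (j in 1:3) {
      sij <- S[, i, j]
      if (all(sij == 0)) next
      acc <- acc + B[[i]][, a] * sij * B[[j]][, b]
    }
    L[, 3 * (a - 1) + b] <- acc
  }
  # rigid rotation: L += skew(omega); radial expansion: L += k_rad * I
  w <- flow$omega_rigid
  sk <- skew3(w)
  for (a in 1:3) for (b in 1:3) {
    L[, 3 * (a - 1) + b] <- L[, 3 * (a - 1) + b] + sk[a, b] +
      (if (a == b) flow$k_rad else 0)
  }
  colnames(L) <- as.vector(t(outer(1:3, 1:3, function(a, b) paste0("L", a, b))))
  tibble::as_tibble(L)
}

#' Synthetic-embryo simulation configuration
#'
#' Acquisition-like defaults: a 350 um-radius embryo with a 30 um-thick
#' blastoderm shell imaged every 2 minutes. `noise_sigma` is observational
#' (added to reported, not dynamical, positions), so true trajectories stay
#' on the analytic flow. Identical config + seed reproduces bit-identical
#' output.
#'
#' @param n_cells Number of starting cells.
#' @param radius_R Embryo radius, um.
#' @param shell_thickness Radial thickness of the cell shell, um.
#' @param frame_interval Acquisition interval, minutes.
#' @param duration Total simulated time, minutes.
#' @param noise_sigma Isotropic Gaussian detection noise, um.
#' @param division_rate Divisions per cell per hour.
#' @param dropout_prob Probability that a detection is missing.
#' @param seed RNG seed.
#' @param init Initial placement: `"uniform"` (random on the shell) or
#'   `"fibonacci"` (low-discrepancy, guarantees a minimum inter-cell
#'   spacing; used for tracker benchmarks).
#' @return Object of class `embryo_sim_config`.
#' @export
embryo_sim_config <- function(n_cells = 2000, radius_R = 350,
                              shell_thickness = 30, frame_interval = 2,
                              duration = 240, noise_sigma = 1,
                              division_rate = 0, dropout_prob = 0,
                              seed = 1, init = c("uniform", "fibonacci")) {
  init <- match.arg(init)
  stopifnot(n_cells >= 1, radius_R > 0, shell_thickness >= 0,
            frame_interval > 0, duration >= frame_interval,
            noise_sigma >= 0, division_rate >= 0,
            dropout_prob >= 0, dropout_prob < 1)
  structure(list(n_cells = as.integer(n_cells), radius_R = radius_R,
                 shell_thickness = shell_thickness,
                 frame_interval = frame_interval, duration = duration,
                 noise_sigma = noise_sigma, division_rate = division_rate,
                 dropout_prob = dropout_prob, seed = as.integer(seed),
                 init = init),
            class = "embryo_sim_config")
}

# one classical RK4 step of the flow
rk4_step <- function(P, flow, geom, dt) {
  v <- function(X) as.matrix(analytic_velocity(X, flow, geom))
  k1 <- v(P)
  k2 <- v(P + dt / 2 * k1)
  k3 <- v(P + dt / 2 * k2)
  k4 <- v(P + dt * k3)
  P + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

#' Simulate tracked nuclei on a gastrulating embryo surface
#'
#' Cells are initialized on a spherical shell (radius in
#' `[R - thickness/2, R + thickness/2]`), advected frame-by-frame with
#' classical 4th-order Runge-Kutta integration of the analytic flow,
#' optionally dividing (daughter spawned at a 2 um tangential offset under
#' a new id) and dropping out of detection. Reported positions carry
#' Gaussian observation noise; the returned object also keeps the true
#' positions and true analytic velocities for oracle tests.
#'
#' @param config An [embryo_sim_config()].
#' @param flow A [flow_spec()].
#' @return Object of class `embryo_sim`: list with `tracks` (reported track
#'   table after noise/dropout), `truth` (tibble `track_id, t_min, x_um,
#'   y_um, z_um, vx, vy, vz` of true positions/velocities, before dropout),
#'   `geom`, `config`, `flow`.
#' @examples
#' sc <- preset_scenario("rigid", n_cells = 200, duration = 10)
#' sim <- simulate_embryo(sc$config, sc$flow)
#' head(sim$tracks)
#' @export
simulate_embryo <- function(config, flow) {
  stopifnot(inherits(config, "embryo_sim_config"), inherits(flow, "flow_spec"))
  geom <- embryo_geometry(center = c(0, 0, 0), radius = config$radius_R)
  set.seed(config$seed)
  n <- config$n_cells
  if (config$init == "fibonacci") {
    U <- fibonacci_sphere(n)
  } else {
    U <- matrix(rnorm(3 * n), n, 3)
    U <- U / sqrt(rowSums(U^2))
  }
  rad <- config$radius_R + runif(n, -0.5, 0.5) * config$shell_thickness
  P <- U * rad
  ids <- seq_len(n)
  next_id <- n + 1L
  times <- seq(0, config$duration, by = config$frame_interval)
  p_div <- config$division_rate * config$frame_interval / 60
  truth <- vector("list", length(times))
  reported <- vector("list", length(times))
  for (k in seq_along(times)) {
    t_now <- times[k]
    vel <- as.matrix(analytic_velocity(P, flow, geom))
    m <- nrow(P)
    noise <- matrix(rnorm(3 * m, sd = config$noise_sigma), m, 3)
    keep <- runif(m) >= config$dropout_prob
    truth[[k]] <- tibble::tibble(track_id = ids, t_min = t_now,
                                 x_um = P[, 1], y_um = P[, 2], z_um = P[, 3],
                                 vx = vel[, 1], vy = vel[, 2], vz = vel[, 3])
    rep_pos <- P + noise
    reported[[k]] <- tibble::tibble(track_id = ids[keep], t_min = t_now,
                                    x_um = rep_pos[keep, 1],
                                    y_um = rep_pos[keep, 2],
                                    z_um = rep_pos[keep, 3])
    if (k == length(times)) break
    # divisions: daughter at a small tangential offset, new id
    if (p_div > 0) {
      divs <- which(runif(m) < p_div)
      if (length(divs) > 0) {
        Ud <- P[divs, , drop = FALSE] /
          sqrt(rowSums(P[divs, , drop = FALSE]^2))
        rnd <- matrix(rnorm(3 * length(divs)), length(divs), 3)
        tang <- rnd - rowSums(rnd * Ud) * Ud
        tang <- tang / pmax(sqrt(rowSums(tang^2)), 1e-12)
        P <- rbind(P, P[divs, , drop = FALSE] + 2 * tang)
        new_ids <- next_id + seq_along(divs) - 1L
        next_id <- next_id + length(divs)
        ids <- c(ids, new_ids)
      }
    }
    P <- rk4_step(P, flow, geom, config$frame_interval)
  }
  structure(list(tracks = dplyr::arrange(dplyr::bind_rows(reported),
                                         .data$track_id, .data$t_min),
                 truth = dplyr::bind_rows(truth),
                 geom = geom, config = config, flow = flow),
            class = "embryo_sim")
}

#' @export
print.embryo_sim <- function(x, ...) {
  cat(sprintf("<embryo_sim> %d cells, %g min at %g-min frames, %d detections\n",
              x$config$n_cells, x$config$duration, x$config$frame_interval,
              nrow(x$tracks)))
  invisible(x)
}

# preset table; amplitudes are gastrulation-scale speeds on a 350-um embryo
.tt_presets <- list(
  static    = list(flow = list(),
                   config = list(n_cells = 2000, duration = 40,
                                 noise_sigma = 0)),
  rigid     = list(flow = list(omega_rigid = c(0, 0, 0.001)),
                   config = list(n_cells = 5000, duration = 40,
                                 noise_sigma = 0)),
  expansion = list(flow = list(k_rad = 0.001),
                   config = list(n_cells = 5000, duration = 40,
                                 noise_sigma = 0)),
  gastrula  = list(flow = list(A_ep = 1.0, A_conv = 0.8, A_ext = 2.5),
                   config = list(n_cells = 5000, duration = 120,
                                 noise_sigma = 1)),
  c59       = list(flow = list(A_ep = 1.0, A_conv = 0.8, A_ext = 0),
                   config = list(n_cells = 5000, duration = 120,
                                 noise_sigma = 1))
)

#' Named simulation scenarios
#'
#' `preset_scenarios()` lists the available scenarios; `preset_scenario()`
#' returns the flow/config pair for one of them:
#' \describe{
#'   \item{gastrula}{epiboly + convergence + extension (the full movement
#'     repertoire; 5000 cells, 1 um noise, 120 min at 2-min frames).}
#'   \item{c59}{identical to `gastrula` but with the extension amplitude
#'     set to zero, emulating Wnt-secretion inhibition, which abolishes
#'     extension while leaving convergence intact.}
#'   \item{rigid}{whole-embryo rigid rotation (noiseless).}
#'   \item{expansion}{isotropic radial expansion `v = k x` (noiseless).}
#'   \item{static}{no flow.}
#' }
#'
#' @param name Scenario name.
#' @param seed RNG seed passed to the config.
#' @param ... Overrides for [embryo_sim_config()] fields (e.g. `n_cells`,
#'   `duration`).
#' @return `preset_scenario`: list with elements `config` and `flow`.
#'   `preset_scenarios`: character vector of scenario names.
#' @export
preset_scenario <- function(name, seed = 1, ...) {
  if (!name %in% names(.tt_presets)) {
    abort(paste0("unknown preset '", name, "'; available: ",
                 paste(names(.tt_presets), collapse = ", ")))
  }
  p <- .tt_presets[[name]]
  cfg_args <- modifyList(p$config, list(seed = seed))
  cfg_args <- modifyList(cfg_args, list(...))
  list(config = do.call(embryo_sim_config, cfg_args),
       flow = do.call(flow_spec, p$flow))
}

#' @rdname preset_scenario
#' @export
preset_scenarios <- function() names(.tt_presets)

#' Ground-truth velocity gradients at mesh nodes
#'
#' Evaluates the analytic gradient of a flow at the physical node positions
#' of a mesh, as a long table for test harnesses.
#'
#' @param mesh A [make_mesh()] mesh.
#' @param geom An [embryo_geometry()].
#' @param flow A [flow_spec()].
#' @param times Times (min) to label rows with (the flows are steady; the
#'   label is for joining against pipeline output).
#' @return Tibble `node_id, t_min, L11..L33`.
#' @export
true_gradient_table <- function(mesh, geom, flow, times = 0) {
  NP <- mesh_node_positions(mesh, geom)
  Lt <- analytic_gradient(NP, flow, geom)
  purrr::map_dfr(times, function(tt) {
    dplyr::bind_cols(tibble::tibble(node_id = mesh$nodes$node_id, t_min = tt), Lt)
  })
}
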