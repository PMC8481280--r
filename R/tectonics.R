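# Core tissue-tectonics computation: overlapping spherical domains around
# mesh nodes, per-domain velocity-gradient tensors by weighted affine
# least squares, strain-rate/spin decomposition into anatomical components,
# and sliding-window time integration.

#' Tectonics analysis configuration
#'
#' @param domain_radius Radius of the overlapping spherical domains around
#'   each node, micrometres; default 110 (small enough to capture relevant
#'   spatial patterns while giving enough cells for a stable local fit).
#' @param window Integration window, minutes; default 30 (40 is used for
#'   perturbation comparisons, where the biomechanical signature needs the
#'   longer window to emerge from noise).
#' @param min_cells_per_domain Minimum member cells for a domain velocity /
#'   gradient to be computed; default 4.
#' @param ridge_epsilon Dimensionless ridge regularizer applied to the
#'   spatial block of the normal equations, relative to its mean diagonal.
#'   A failsafe against degenerate neighbourhood geometry; kept tiny
#'   (1e-9) so it never biases well-posed fits, with the condition-number
#'   cutoff doing the actual gating.
#' @param gradient_mode `"cell_regression"` (default) regresses member
#'   cells' individual velocities on their 3D positions; the radial
#'   thickness of the blastoderm shell is what makes the radial derivative
#'   identifiable. `"node_field"` regresses neighbouring nodes' domain-mean
#'   velocities (surface-only sampling: tangential components are
#'   reproduced, radial derivatives are ridge-dominated).
#' @param pole_exclusion Polar cap (radians) where anatomical frames, and
#'   hence component projections, are flagged missing; default 0.05.
#' @param cond_max Condition-number cutoff above which a gradient fit is
#'   marked invalid.
#' @param flip_curl Flip the sign convention of the radial curl. Default
#'   `FALSE`: positive curl = anticlockwise viewed from outside the embryo.
#' @return Object of class `tectonics_config`.
#' @export
tectonics_config <- function(domain_radius = 110, window = 30,
                             min_cells_per_domain = 4,
                             ridge_epsilon = 1e-9,
                             gradient_mode = c("cell_regression", "node_field"),
                             pole_exclusion = 0.05, cond_max = 1e8,
                             flip_curl = FALSE) {
  gradient_mode <- match.arg(gradient_mode)
  stopifnot(domain_radius > 0, window > 0, min_cells_per_domain >= 1,
            ridge_epsilon >= 0, pole_exclusion >= 0, cond_max > 1)
  structure(list(domain_radius = domain_radius, window = window,
                 min_cells_per_domain = min_cells_per_domain,
                 ridge_epsilon = ridge_epsilon, gradient_mode = gradient_mode,
                 pole_exclusion = pole_exclusion, cond_max = cond_max,
                 flip_curl = flip_curl),
            class = "tectonics_config")
}

# squared distances between rows of A (k x 3) and rows of B (m x 3)
cross_dist2 <- function(A, B) {
  D2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
  pmax(D2, 0)
}

#' Assign cells to overlapping spherical domains
#'
#' A cell belongs to node `i` iff its Euclidean distance to the node's
#' physical position (`center + radius_R * r_i`) is at most
#' `domain_radius`. Domains overlap by construction.
#'
#' @param cells Cell positions at one time point (data frame with
#'   `x_um`/`y_um`/`z_um`, or matrix).
#' @param mesh A [make_mesh()] mesh.
#' @param geom An [embryo_geometry()].
#' @param config A [tectonics_config()].
#' @return Tibble `node_id`, `cell` (row index into `cells`).
#' @export
assign_domains <- function(cells, mesh, geom, config = tectonics_config()) {
  NP <- mesh_node_positions(mesh, geom)
  CP <- as_xyz_matrix(cells)
  D2 <- cross_dist2(NP, CP)
  hit <- which(D2 <= config$domain_radius^2, arr.ind = TRUE)
  tibble::tibble(node_id = mesh$nodes$node_id[hit[, 1]],
                 cell = as.integer(hit[, 2])) |>
    dplyr::arrange(.data$node_id, .data$cell)
}

#' Domain-mean velocity field
#'
#' The local velocity of each domain: the arithmetic mean of the member
#' cells' velocities, reported only where the member count reaches
#' `min_cells_per_domain`.
#'
#' @param velocities Output of [compute_velocities()] (rows with `NA`
#'   velocity are ignored).
#' @param mesh,geom,config See [assign_domains()].
#' @param times Times to evaluate (default: all times present).
#' @return Tibble `node_id, t_min, vx, vy, vz, n_cells` with `NA`
#'   velocities where the domain is under-populated.
#' @export
domain_velocity <- function(velocities, mesh, geom,
                            config = tectonics_config(), times = NULL) {
  vel <- dplyr::filter(velocities, is.finite(.data$vx))
  if (is.null(times)) times <- sort(unique(vel$t_min))
  NP <- mesh_node_positions(mesh, geom)
  purrr::map_dfr(times, function(tt) {
    fr <- dplyr::filter(vel, .data$t_min == tt)
    CP <- as_xyz_matrix(fr)
    V <- as.matrix(fr[, c("vx", "vy", "vz")])
    D2 <- cross_dist2(NP, CP)
    inside <- D2 <= config$domain_radius^2
    n_i <- rowSums(inside)
    Vm <- inside %*% V / pmax(n_i, 1)
    Vm[n_i < config$min_cells_per_domain, ] <- NA_real_
    tibble::tibble(node_id = mesh$nodes$node_id, t_min = tt,
                   vx = Vm[, 1], vy = Vm[, 2], vz = Vm[, 3],
                   n_cells = as.integer(n_i))
  })
}

# Weighted affine fit of sample velocities around each query point.
# query k x 3; pos/vel m x 3. Returns list of matrices: L (k x 9,
# row-major), n_cells, cond, valid.
fit_gradients_at <- function(query, pos, vel, config) {
  k <- nrow(query)
  r2 <- config$domain_radius^2
  h2 <- (config$domain_radius / 2)^2
  D2 <- cross_dist2(query, pos)
  L <- matrix(NA_real_, k, 9)
  n_cells <- integer(k)
  cond <- rep(NA_real_, k)
  valid <- rep(FALSE, k)
  min_n <- max(config$min_cells_per_domain, 4)
  for (i in seq_len(k)) {
    idx <- which(D2[i, ] <= r2)
    n_cells[i] <- length(idx)
    if (length(idx) < min_n) next
    dx <- sweep(pos[idx, , drop = FALSE], 2, query[i, ])
    w <- exp(-D2[i, idx] / (2 * h2))
    X <- cbind(1, dx)
    A <- crossprod(X, X * w)
    b <- crossprod(X, vel[idx, , drop = FALSE] * w)
    lam <- config$ridge_epsilon * mean(diag(A)[2:4])
    A[2, 2] <- A[2, 2] + lam; A[3, 3] <- A[3, 3] + lam
    A[4, 4] <- A[4, 4] + lam
    ev <- tryCatch(eigen(A[2:4, 2:4], symmetric = TRUE,
                         only.values = TRUE)$values,
                   error = function(e) rep(NA_real_, 3))
    if (!all(is.finite(ev)) || min(ev) <= 0) next
    cond[i] <- ev[1] / ev[3]
    sol <- tryCatch(solve(A, b), error = function(e) NULL)
    if (is.null(sol) || !all(is.finite(sol))) next
    # sol rows: intercept, d/dx, d/dy, d/dz; columns: vx, vy, vz
    # L[a, b] = dv_a/dx_b  ->  row-major vector
    Lt <- t(sol[2:4, , drop = FALSE])
    L[i, ] <- as.vector(t(Lt))
    valid[i] <- cond[i] <= config$cond_max
  }
  list(L = L, n_cells = n_cells, cond = cond, valid = valid)
}

grad_colnames <- as.vector(t(outer(1:3, 1:3, function(a, b) paste0("L", a, b))))

#' Velocity-gradient tensors at arbitrary query points
#'
#' Estimates the 3x3 velocity-gradient tensor `L[a,b] = dv_a/dx_b` at each
#' query position and one time point, by weighted affine least squares over
#' the cells within `domain_radius` of the query (Gaussian distance
#' weights, bandwidth `domain_radius/2`, tiny ridge on the normal
#' equations). A globally affine velocity field is recovered to machine
#' precision whenever the sampled positions span 3D.
#'
#' @param velocities Output of [compute_velocities()].
#' @param query Query positions, matrix or data frame (um, world coords).
#' @param geom An [embryo_geometry()] (unused in the fit itself; kept so
#'   call sites mirror [strain_rate_field()]).
#' @param config A [tectonics_config()].
#' @param time The time point (min); must match a velocity sample time.
#' @return Tibble with `t_min`, `n_cells`, `cond`, `valid` and `L11..L33`
#'   (units 1/min).
#' @export
velocity_gradient <- function(velocities, query, geom,
                              config = tectonics_config(), time) {
  fr <- dplyr::filter(velocities, .data$t_min == time, is.finite(.data$vx))
  if (nrow(fr) == 0) abort(sprintf("no velocity samples at t = %g min.", time))
  Q <- as_xyz_matrix(query)
  fit <- fit_gradients_at(Q, as_xyz_matrix(fr),
                          as.matrix(fr[, c("vx", "vy", "vz")]), config)
  out <- tibble::as_tibble(setNames(as.data.frame(fit$L), grad_colnames))
  dplyr::bind_cols(tibble::tibble(t_min = time, n_cells = fit$n_cells,
                                  cond = fit$cond, valid = fit$valid), out)
}

# closed-form eigenvalues of symmetric 3x3 tensors, vectorized over rows;
# E given as columns e11, e12, e13, e22, e23, e33. Returns matrix with
# descending eigenvalues.
sym_eigenvalues <- function(e11, e12, e13, e22, e23, e33) {
  q <- (e11 + e22 + e33) / 3
  p1 <- e12^2 + e13^2 + e23^2
  p2 <- (e11 - q)^2 + (e22 - q)^2 + (e33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  b11 <- (e11 - q); b22 <- (e22 - q); b33 <- (e33 - q)
  detB <- b11 * (b22 * b33 - e23^2) - e12 * (e12 * b33 - e23 * e13) +
    e13 * (e12 * e23 - b22 * e13)
  ps <- ifelse(p > 0, p, 1)
  rr <- pmin(1, pmax(-1, detB / (2 * ps^3)))
  phi <- acos(rr) / 3
  l1 <- q + 2 * p * cos(phi)
  l3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  l2 <- 3 * q - l1 - l3
  cbind(l1, l2, l3)
}

#' Decompose velocity gradients into strain-rate and spin components
#'
#' Splits each tensor `L` into the strain-rate tensor `E = (L + L^T)/2`
#' and the spin tensor `Omega = (L - L^T)/2`, then projects onto the local
#' anatomical frame: `e_AP = e_AP^T E e_AP` (likewise `e_ML`, `e_r`),
#' `trace = tr(E)` (the local volume-change rate, i.e. the divergence of
#' the velocity field), the radial curl `curl_r = 2 * omega . e_r` (spin
#' axial vector `omega`; positive = anticlockwise viewed from outside the
#' embryo, flip with `config$flip_curl`), the spin magnitude `curl_mag`
#' (Frobenius norm of `Omega`) and the descending eigenvalues of `E`.
#' Where the node frame is missing (polar caps) the projected components
#' are `NA` while the tensor itself is retained.
#'
#' @param gradients Tibble with `node_id` and `L11..L33` columns (e.g. from
#'   [strain_rate_field()] internals or [true_gradient_table()]).
#' @param frames Node frames from [local_frames()].
#' @param config A [tectonics_config()] (for `flip_curl`).
#' @return The input with added columns `e_AP, e_ML, e_r, trace, curl_r,
#'   curl_mag, eig1, eig2, eig3`.
#' @export
decompose_gradient <- function(gradients, frames,
                               config = tectonics_config()) {
  g <- dplyr::left_join(gradients,
                        frames[, c("node_id", "theta", "phi", "valid_frame",
                                   "ap_x", "ap_y", "ap_z",
                                   "ml_x", "ml_y", "ml_z",
                                   "r_x", "r_y", "r_z")],
                        by = "node_id")
  # strain-rate tensor entries
  E11 <- g$L11; E22 <- g$L22; E33 <- g$L33
  E12 <- (g$L12 + g$L21) / 2
  E13 <- (g$L13 + g$L31) / 2
  E23 <- (g$L23 + g$L32) / 2
  # spin axial vector: omega = (O32, O13, O21)
  w1 <- (g$L32 - g$L23) / 2
  w2 <- (g$L13 - g$L31) / 2
  w3 <- (g$L21 - g$L12) / 2
  quad <- function(ux, uy, uz) {
    E11 * ux^2 + E22 * uy^2 + E33 * uz^2 +
      2 * (E12 * ux * uy + E13 * ux * uz + E23 * uy * uz)
  }
  e_AP <- quad(g$ap_x, g$ap_y, g$ap_z)
  e_ML <- quad(g$ml_x, g$ml_y, g$ml_z)
  e_r <- quad(g$r_x, g$r_y, g$r_z)
  curl_sign <- if (isTRUE(config$flip_curl)) -1 else 1
  curl_r <- curl_sign * 2 * (w1 * g$r_x + w2 * g$r_y + w3 * g$r_z)
  curl_r[!g$valid_frame] <- NA_real_
  curl_mag <- sqrt(2 * (w1^2 + w2^2 + w3^2))
  eig <- sym_eigenvalues(E11, E12, E13, E22, E23, E33)
  out <- dplyr::mutate(g,
    e_AP = e_AP, e_ML = e_ML, e_r = e_r,
    trace = E11 + E22 + E33,
    curl_r = curl_r, curl_mag = curl_mag,
    eig1 = eig[, 1], eig2 = eig[, 2], eig3 = eig[, 3])
  dplyr::select(out, -dplyr::all_of(c("ap_x", "ap_y", "ap_z",
                                      "ml_x", "ml_y", "ml_z",
                                      "r_x", "r_y", "r_z")))
}

#' Per-node, per-time strain-rate field
#'
#' The pipeline core: for every mesh node (or a subset) and time point,
#' estimates the domain velocity-gradient tensor and decomposes it into
#' anatomical strain-rate components. In the default `cell_regression`
#' mode the member cells' individual velocities are regressed on their 3D
#' positions; in `node_field` mode the domain-mean velocities of
#' neighbouring nodes are used as samples instead (see
#' [tectonics_config()]).
#'
#' @param velocities Output of [compute_velocities()].
#' @param geom An [embryo_geometry()].
#' @param mesh A [make_mesh()] mesh.
#' @param config A [tectonics_config()].
#' @param nodes Optional integer vector of node ids to evaluate (default
#'   all).
#' @param times Optional times (min) to evaluate (default all velocity
#'   sample times).
#' @return Tibble `node_id, t_min, theta, phi, valid_frame, n_cells, cond,
#'   valid, L11..L33, e_AP, e_ML, e_r, trace, curl_r, curl_mag,
#'   eig1..eig3`; rates in 1/min.
#' @export
strain_rate_field <- function(velocities, geom, mesh,
                              config = tectonics_config(),
                              nodes = NULL, times = NULL) {
  stopifnot(inherits(geom, "embryo_geometry"), inherits(mesh, "spherical_mesh"))
  vel <- dplyr::filter(velocities, is.finite(.data$vx))
  if (is.null(times)) times <- sort(unique(vel$t_min))
  if (is.null(nodes)) nodes <- mesh$nodes$node_id
  sel <- match(nodes, mesh$nodes$node_id)
  if (any(is.na(sel))) abort("unknown node ids in `nodes`.")
  NP <- mesh_node_positions(mesh, geom)[sel, , drop = FALSE]
  frames <- local_frames(mesh, geom, config$pole_exclusion)

  node_field <- identical(config$gradient_mode, "node_field")
  if (node_field) {
    dv <- domain_velocity(velocities, mesh, geom, config, times = times)
    all_np <- mesh_node_positions(mesh, geom)
  }

  res <- purrr::map_dfr(times, function(tt) {
    if (node_field) {
      fr <- dplyr::filter(dv, .data$t_min == tt, is.finite(.data$vx))
      pos <- all_np[match(fr$node_id, mesh$nodes$node_id), , drop = FALSE]
      V <- as.matrix(fr[, c("vx", "vy", "vz")])
    } else {
      fr <- dplyr::filter(vel, .data$t_min == tt)
      pos <- as_xyz_matrix(fr)
      V <- as.matrix(fr[, c("vx", "vy", "vz")])
    }
    fit <- fit_gradients_at(NP, pos, V, config)
    dplyr::bind_cols(
      tibble::tibble(node_id = nodes, t_min = tt, n_cells = fit$n_cells,
                     cond = fit$cond, valid = fit$valid),
      tibble::as_tibble(setNames(as.data.frame(fit$L), grad_colnames)))
  })
  out <- decompose_gradient(res, frames, config)
  dplyr::relocate(out, dplyr::all_of(c("node_id", "t_min", "theta", "phi",
                                       "valid_frame", "n_cells", "cond",
                                       "valid")))
}

#' Integrate strain rates over a sliding time window
#'
#' Trapezoidal integration of each projected strain-rate component over
#' windows `[t - W/2, t + W/2]` centred on the sample grid, giving the
#' dimensionless strain accumulated over the window (the quantity shown in
#' strain maps and kymographs). Components are integrated in the
#' instantaneous local frame (component-then-integrate). Windows are
#' reported where they fit entirely inside the sampled range; missing
#' samples inside a window are tolerated up to 20% of its span (the
#' integral over the covered sub-intervals is rescaled to the full window),
#' otherwise the window value is missing.
#'
#' @param rates Output of [strain_rate_field()].
#' @param window Window length W, minutes; default 30 (use 40 for
#'   perturbation comparisons).
#' @param min_coverage Minimum covered fraction of the window; default 0.8.
#' @return A `strain_maps` tibble: `node_id, theta, phi, t_min` (window
#'   centre), integrated `e_AP, e_ML, e_r, trace, curl_r`, and `n_cells`
#'   (mean member count over the window).
#' @export
integrate_strain <- function(rates, window = 30, min_coverage = 0.8) {
  comps <- c("e_AP", "e_ML", "e_r", "trace", "curl_r")
  times <- sort(unique(rates$t_min))
  if (length(times) < 2) abort("need at least 2 time points to integrate.")
  dt_min <- min(diff(times))
  if (window < 2 * dt_min) {
    abort(sprintf("window (%g min) shorter than 2 frames (%g min).",
                  window, 2 * dt_min))
  }
  nodes <- sort(unique(rates$node_id))
  node_idx <- match(rates$node_id, nodes)
  time_idx <- match(rates$t_min, times)
  mat_of <- function(col) {
    M <- matrix(NA_real_, length(nodes), length(times))
    M[cbind(node_idx, time_idx)] <- rates[[col]]
    M
  }
  mats <- lapply(comps, mat_of)
  names(mats) <- comps
  Ncells <- mat_of("n_cells")
  half <- window / 2
  centers <- times[times - half >= times[1] - 1e-9 &
                     times + half <= times[length(times)] + 1e-9]
  if (length(centers) == 0) {
    abort("no window fits inside the sampled time range; shorten `window`.")
  }
  geo <- rates |>
    dplyr::distinct(.data$node_id, .data$theta, .data$phi) |>
    dplyr::arrange(.data$node_id)
  out <- purrr::map_dfr(centers, function(tc) {
    j <- which(times >= tc - half - 1e-9 & times <= tc + half + 1e-9)
    dts <- diff(times[j])
    block <- tibble::tibble(node_id = nodes, t_min = tc)
    for (cmp in comps) {
      M <- mats[[cmp]][, j, drop = FALSE]
      Fin <- is.finite(M)
      Mz <- ifelse(Fin, M, 0)
      nj <- length(j)
      pair_ok <- Fin[, -nj, drop = FALSE] & Fin[, -1, drop = FALSE]
      contrib <- (Mz[, -nj, drop = FALSE] + Mz[, -1, drop = FALSE]) / 2
      integ <- as.numeric((contrib * pair_ok) %*% dts)
      covered <- as.numeric(pair_ok %*% dts)
      val <- ifelse(covered >= min_coverage * window & covered > 0,
                    integ * window / covered, NA_real_)
      block[[cmp]] <- val
    }
    block$n_cells <- rowMeans(Ncells[, j, drop = FALSE], na.rm = TRUE)
    block
  })
  out <- dplyr::left_join(out, geo, by = "node_id") |>
    dplyr::relocate(dplyr::all_of(c("node_id", "theta", "phi", "t_min")))
  class(out) <- c("strain_maps", class(tibble::tibble()))
  attr(out, "window") <- window
  out
}

#' Divergence (strain-trace) map
#'
#' The integrated trace field — the divergence of the velocity field, i.e.
#' the local volume change over the window — extracted as its own scalar
#' field.
#'
#' @param maps A [integrate_strain()] result.
#' @return Tibble `node_id, theta, phi, t_min, divergence`.
#' @export
divergence_map <- function(maps) {
  tibble::as_tibble(maps)[, c("node_id", "theta", "phi", "t_min", "trace")] |>
    dplyr::rename(divergence = "trace")
}
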