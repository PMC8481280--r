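#' Embryo geometry: fitted sphere plus anatomical axes
#'
#' Bundles the fitted embryo sphere (center and radius in micrometres) with
#' the anatomical reference directions used throughout the analysis: the
#' anterior axis (from the embryo center towards the anterior/animal pole)
#' and the dorsal reference (direction of the dorsal meridian at the
#' equator). The dorsal reference is orthogonalized against the anterior
#' axis. Positions are analysed on the unit sphere (normalized radius
#' `r0 = 1`); all tensor computation stays in physical units.
#'
#' The azimuth convention is `phi = 0` on the dorsal meridian, increasing
#' anticlockwise when viewed from outside the embryo above the anterior
#' pole; the elevation `theta` is measured from the anterior pole
#' (`theta = 0` anterior, `pi` posterior).
#'
#' @param center Embryo center, 3-vector, micrometres.
#' @param radius Embryo radius, micrometres (> 0).
#' @param anterior_axis Direction from center to the anterior pole
#'   (normalized internally).
#' @param dorsal_ref Direction of the dorsal meridian at the equator;
#'   orthogonalized against `anterior_axis` and normalized.
#' @return An object of class `embryo_geometry`: a list with elements
#'   `center`, `radius_R`, `r0` (always 1), `anterior_axis`, `dorsal_ref`
#'   and `ml_axis` (`anterior_axis x dorsal_ref`, completing a right-handed
#'   triad).
#' @examples
#' geom <- embryo_geometry(radius = 350)
#' geom$radius_R
#' @export
embryo_geometry <- function(center = c(0, 0, 0), radius = 350,
                            anterior_axis = c(0, 0, 1),
                            dorsal_ref = c(1, 0, 0)) {
  center <- as.numeric(center)
  if (length(center) != 3 || !all(is.finite(center))) {
    abort("`center` must be a finite 3-vector (micrometres).")
  }
  if (!is.numeric(radius) || length(radius) != 1 || !is.finite(radius) ||
      radius <= 0) {
    abort("`radius` must be a single positive number (micrometres).")
  }
  a <- normalize3(anterior_axis, "`anterior_axis`")
  d_raw <- as.numeric(dorsal_ref)
  d <- d_raw - sum(d_raw * a) * a
  if (sqrt(sum(d^2)) < 1e-10) {
    abort("`dorsal_ref` is (anti)parallel to `anterior_axis`; cannot define a dorsal meridian.")
  }
  d <- d / sqrt(sum(d^2))
  m <- cross3(a, d)
  structure(
    list(center = center, radius_R = radius, r0 = 1,
         anterior_axis = a, dorsal_ref = d, ml_axis = m),
    class = "embryo_geometry"
  )
}

#' @export
print.embryo_geometry <- function(x, ...) {
  cat("<embryo_geometry>\n")
  cat(sprintf("  center  : (%.2f, %.2f, %.2f) um\n",
              x$center[1], x$center[2], x$center[3]))
  cat(sprintf("  radius  : %.2f um (r0 = %g on the unit sphere)\n",
              x$radius_R, x$r0))
  cat(sprintf("  anterior: (%.3f, %.3f, %.3f)\n",
              x$anterior_axis[1], x$anterior_axis[2], x$anterior_axis[3]))
  cat(sprintf("  dorsal  : (%.3f, %.3f, %.3f)\n",
              x$dorsal_ref[1], x$dorsal_ref[2], x$dorsal_ref[3]))
  invisible(x)
}

#' Least-squares sphere fit
#'
#' Fits a sphere to 3D points by geometric least squares, minimizing
#' `sum((|p - c| - R)^2)`. An algebraic (linear) fit provides the starting
#' value and a few Gauss-Newton iterations refine it; for points exactly on
#' a sphere the fit is exact to numerical precision.
#'
#' @param points 3-column matrix or data frame with `x_um`/`y_um`/`z_um`
#'   (or `x`/`y`/`z`) columns, micrometres.
#' @return A list with `center` (3-vector, um), `radius` (um) and `rms`
#'   (root-mean-square radial residual, um).
#' @examples
#' th <- acos(runif(50, -1, 1)); ph <- runif(50, 0, 2 * pi)
#' p <- 350 * cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
#' fit_sphere(p)$radius
#' @export
fit_sphere <- function(points) {
  P <- as_xyz_matrix(points)
  if (nrow(P) < 4) abort("sphere fitting needs at least 4 points.")
  if (!all(is.finite(P))) abort("sphere fitting: points must be finite.")
  # algebraic fit: |p|^2 = 2 p.c + (R^2 - |c|^2)
  X <- cbind(2 * P, 1)
  y <- rowSums(P^2)
  qx <- qr(X)
  if (qx$rank < 4) {
    abort("degenerate point configuration (coplanar or coincident); cannot fit a sphere.")
  }
  beta <- qr.coef(qx, y)
  ctr <- beta[1:3]
  R <- sqrt(max(beta[4] + sum(ctr^2), 0))
  # Gauss-Newton refinement of the geometric objective
  for (it in seq_len(20)) {
    D <- sweep(P, 2, ctr)
    dist <- sqrt(rowSums(D^2))
    if (any(dist < 1e-9)) break
    res <- dist - R
    J <- cbind(-D / dist, -1)
    step <- tryCatch(qr.coef(qr(J), res), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    ctr <- ctr - step[1:3]
    R <- R - step[4]
    if (sqrt(sum(step^2)) < 1e-12 * max(R, 1)) break
  }
  D <- sweep(P, 2, ctr)
  res <- sqrt(rowSums(D^2)) - R
  list(center = as.numeric(ctr), radius = as.numeric(R),
       rms = sqrt(mean(res^2)))
}

#' Fit embryo geometry from a track table
#'
#' Fits a sphere to the cell positions of every frame and averages the
#' per-frame centers and radii into one static geometry (the embryo is
#' treated as a fixed sphere over the analysed interval). Anatomical axes
#' cannot be derived from point clouds and must be supplied.
#'
#' @param tracks Track table (`track_id`, `t_min`, `x_um`, `y_um`, `z_um`).
#' @param anterior_axis,dorsal_ref Anatomical directions, see
#'   [embryo_geometry()].
#' @param per_frame If `TRUE`, return the per-frame fits as a tibble
#'   (`t_min`, `cx`, `cy`, `cz`, `radius`, `rms`) instead of the averaged
#'   geometry.
#' @return An `embryo_geometry` (default) or a tibble of per-frame fits.
#' @export
fit_embryo_geometry <- function(tracks, anterior_axis = c(0, 0, 1),
                                dorsal_ref = c(1, 0, 0),
                                per_frame = FALSE) {
  validate_tracks(tracks)
  fits <- tracks |>
    dplyr::group_by(.data$t_min) |>
    dplyr::group_modify(function(df, key) {
      f <- fit_sphere(df)
      tibble::tibble(cx = f$center[1], cy = f$center[2], cz = f$center[3],
                     radius = f$radius, rms = f$rms)
    }) |>
    dplyr::ungroup()
  if (per_frame) return(fits)
  embryo_geometry(center = c(mean(fits$cx), mean(fits$cy), mean(fits$cz)),
                  radius = mean(fits$radius),
                  anterior_axis = anterior_axis, dorsal_ref = dorsal_ref)
}

#' Cartesian to embryo spherical coordinates
#'
#' Converts positions (micrometres, world coordinates) to embryo-centric
#' spherical coordinates: `r` is the radial distance normalized by the
#' embryo radius (so the embryo surface sits at `r = 1`), `theta` the
#' elevation from the anterior pole in `[0, pi]`, and `phi` the azimuth in
#' `(-pi, pi]` measured from the dorsal meridian, anticlockwise when viewed
#' from above the anterior pole. At the poles `phi` is undefined and
#' returned as `NA` (flagged, not an error).
#'
#' @param points Positions, matrix or data frame (see [fit_sphere()]).
#' @param geom An [embryo_geometry()].
#' @return Tibble with columns `r`, `theta`, `phi`.
#' @export
to_embryo_coords <- function(points, geom) {
  stopifnot(inherits(geom, "embryo_geometry"))
  P <- sweep(as_xyz_matrix(points), 2, geom$center)
  rr <- sqrt(rowSums(P^2))
  if (any(rr < 1e-9)) {
    abort("point at the embryo center: direction undefined.")
  }
  U <- P / rr
  ca <- as.numeric(U %*% geom$anterior_axis)
  ca <- pmin(1, pmax(-1, ca))
  theta <- acos(ca)
  pd <- as.numeric(U %*% geom$dorsal_ref)
  pm <- as.numeric(U %*% geom$ml_axis)
  phi <- atan2(pm, pd)
  sin_t <- sqrt(pmax(0, 1 - ca^2))
  phi[sin_t < 1e-12] <- NA_real_
  phi <- ifelse(is.na(phi), phi, wrap_pi(phi))
  tibble::tibble(r = rr / geom$radius_R, theta = theta, phi = phi)
}

#' Embryo spherical coordinates to Cartesian
#'
#' Inverse of [to_embryo_coords()].
#'
#' @param coords Data frame with columns `r`, `theta`, `phi` (`r` in units
#'   of the embryo radius, angles in radians).
#' @param geom An [embryo_geometry()].
#' @return Tibble with `x_um`, `y_um`, `z_um`.
#' @export
from_embryo_coords <- function(coords, geom) {
  stopifnot(inherits(geom, "embryo_geometry"))
  r <- coords$r * geom$radius_R
  st <- sin(coords$theta); ct <- cos(coords$theta)
  cp <- cos(coords$phi); sp <- sin(coords$phi)
  U <- outer(st * cp, geom$dorsal_ref) +
    outer(st * sp, geom$ml_axis) +
    outer(ct, geom$anterior_axis)
  P <- sweep(U * r, 2, geom$center, `+`)
  tibble::tibble(x_um = P[, 1], y_um = P[, 2], z_um = P[, 3])
}

# ---- mesh ------------------------------------------------------------------

# Spherical Fibonacci lattice: deterministic, near-uniform point set.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  ga <- pi * (3 - sqrt(5))
  phi <- i * ga
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(s * cos(phi), s * sin(phi), z)
}

# Incremental 3D convex hull for points in general position on a sphere
# (every input point is extreme). Returns an F x 3 matrix of vertex indices
# with outward-oriented faces.
convex_hull_triangles <- function(P) {
  n <- nrow(P)
  if (n < 4) abort("convex hull needs at least 4 points.")
  # seed tetrahedron: spread-out points
  i1 <- 1L
  d2 <- rowSums(sweep(P, 2, P[i1, ])^2)
  i2 <- which.max(d2)
  u <- P[i2, ] - P[i1, ]; u <- u / sqrt(sum(u^2))
  rel <- sweep(P, 2, P[i1, ])
  proj <- as.numeric(rel %*% u)
  i3 <- which.max(rowSums(rel^2) - proj^2)
  nrm0 <- cross3(P[i2, ] - P[i1, ], P[i3, ] - P[i1, ])
  i4 <- which.max(abs(as.numeric(rel %*% nrm0)))
  seed <- c(i1, i2, i3, i4)
  interior <- colMeans(P[seed, ])

  orient_face <- function(f) {
    nrm <- cross3(P[f[2], ] - P[f[1], ], P[f[3], ] - P[f[1], ])
    if (sum(nrm * (P[f[1], ] - interior)) < 0) f <- f[c(1, 3, 2)]
    f
  }
  faces <- t(apply(rbind(seed[c(1, 2, 3)], seed[c(1, 2, 4)],
                         seed[c(1, 3, 4)], seed[c(2, 3, 4)]),
                   1, orient_face))
  face_geom <- function(fm) {
    A <- P[fm[, 1], , drop = FALSE]
    B <- P[fm[, 2], , drop = FALSE]
    C <- P[fm[, 3], , drop = FALSE]
    e1 <- B - A; e2 <- C - A
    nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                 e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                 e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    list(normal = nrm, offset = rowSums(nrm * A))
  }
  fg <- face_geom(faces)
  tol <- 1e-12
  remaining <- setdiff(seq_len(n), seed)
  for (p_idx in remaining) {
    p <- P[p_idx, ]
    vis <- which(as.numeric(fg$normal %*% p) - fg$offset > tol)
    if (length(vis) == 0L) next  # interior (cannot happen on a sphere)
    visf <- faces[vis, , drop = FALSE]
    # directed edges of visible faces; horizon = edges whose reverse is absent
    de <- rbind(visf[, c(1, 2)], visf[, c(2, 3)], visf[, c(3, 1)])
    key <- paste(de[, 1], de[, 2])
    rkey <- paste(de[, 2], de[, 1])
    horizon <- de[!(key %in% rkey), , drop = FALSE]
    newf <- cbind(horizon, p_idx)
    faces <- rbind(faces[-vis, , drop = FALSE], newf)
    nf <- face_geom(newf)
    fg$normal <- rbind(fg$normal[-vis, , drop = FALSE], nf$normal)
    fg$offset <- c(fg$offset[-vis], nf$offset)
  }
  unname(faces)
}

#' Near-uniform spherical mesh
#'
#' Discretizes the unit sphere into `n_nodes` near-equally spaced nodes
#' using the deterministic spherical Fibonacci lattice, triangulated by the
#' convex hull of the nodes. The default 2000 nodes is the discretization
#' used for whole-embryo strain maps.
#'
#' @param n_nodes Number of nodes (>= 12); default 2000.
#' @return An object of class `spherical_mesh`: list with `nodes` (tibble
#'   `node_id`, `x`, `y`, `z`, unit vectors), `triangles` (tibble `v1`,
#'   `v2`, `v3`, outward-oriented) and `n_nodes`.
#' @examples
#' mesh <- make_mesh(500)
#' nrow(mesh$nodes)
#' @export
make_mesh <- function(n_nodes = 2000) {
  if (!is.numeric(n_nodes) || length(n_nodes) != 1 || n_nodes < 12 ||
      n_nodes != round(n_nodes)) {
    abort("`n_nodes` must be a single integer >= 12.")
  }
  n_nodes <- as.integer(n_nodes)
  key <- paste0("mesh_", n_nodes)
  if (!is.null(.tt_cache[[key]])) return(.tt_cache[[key]])
  P <- fibonacci_sphere(n_nodes)
  tri <- convex_hull_triangles(P)
  mesh <- structure(
    list(nodes = tibble::tibble(node_id = seq_len(n_nodes),
                                x = P[, 1], y = P[, 2], z = P[, 3]),
         triangles = tibble::tibble(v1 = tri[, 1], v2 = tri[, 2],
                                    v3 = tri[, 3]),
         n_nodes = n_nodes),
    class = "spherical_mesh"
  )
  .tt_cache[[key]] <- mesh
  mesh
}

#' @export
print.spherical_mesh <- function(x, ...) {
  cat(sprintf("<spherical_mesh> %d nodes, %d triangles\n",
              x$n_nodes, nrow(x$triangles)))
  invisible(x)
}

# node unit vectors as a matrix
mesh_node_matrix <- function(mesh) {
  stopifnot(inherits(mesh, "spherical_mesh"))
  unname(as.matrix(mesh$nodes[, c("x", "y", "z")]))
}

#' Physical node positions on the embryo surface
#'
#' Maps the unit-sphere mesh nodes to world coordinates:
#' `center + radius_R * r_i` (micrometres).
#'
#' @param mesh A [make_mesh()] mesh.
#' @param geom An [embryo_geometry()].
#' @return Numeric matrix, one row per node.
#' @export
mesh_node_positions <- function(mesh, geom) {
  sweep(mesh_node_matrix(mesh) * geom$radius_R, 2, geom$center, `+`)
}

#' Local anatomical frames at mesh nodes
#'
#' Builds the orthonormal right-handed triad (`e_AP`, `e_ML`, `e_r`) at
#' every mesh node: `e_AP` is the unit tangent along increasing elevation
#' (anterior to posterior), `e_ML` the unit tangent along increasing
#' azimuth (medio-lateral), and `e_r` the outward radial direction, so that
#' `e_AP x e_ML = e_r`. Within `pole_exclusion` radians of either pole the
#' tangent directions are singular and the frame is flagged missing
#' (`valid_frame = FALSE`, tangent components `NA`).
#'
#' @param mesh A [make_mesh()] mesh.
#' @param geom An [embryo_geometry()].
#' @param pole_exclusion Angular cap radius (radians) around each pole
#'   within which frames are flagged missing; default 0.05.
#' @return Tibble with `node_id`, `theta`, `phi`, `valid_frame` and frame
#'   components `ap_x..ap_z`, `ml_x..ml_z`, `r_x..r_z`.
#' @export
local_frames <- function(mesh, geom, pole_exclusion = 0.05) {
  U <- mesh_node_matrix(mesh)
  frames_at_points(U, geom, pole_exclusion) |>
    dplyr::mutate(node_id = mesh$nodes$node_id, .before = 1)
}

#' Local anatomical frames at arbitrary surface directions
#'
#' Same construction as [local_frames()], for arbitrary unit direction
#' vectors rather than mesh nodes.
#'
#' @param U Matrix of unit 3-vectors (one per row).
#' @param geom An [embryo_geometry()].
#' @param pole_exclusion See [local_frames()].
#' @return Tibble as in [local_frames()] without the `node_id` column.
#' @export
frames_at_points <- function(U, geom, pole_exclusion = 0.05) {
  a <- geom$anterior_axis; d <- geom$dorsal_ref; m <- geom$ml_axis
  ct <- as.numeric(U %*% a); ct <- pmin(1, pmax(-1, ct))
  theta <- acos(ct)
  st <- sqrt(pmax(0, 1 - ct^2))
  pd <- as.numeric(U %*% d); pm <- as.numeric(U %*% m)
  phi <- atan2(pm, pd)
  valid <- st >= sin(pole_exclusion) & pmin(theta, pi - theta) >= pole_exclusion
  cp <- cos(phi); sp <- sin(phi)
  # e_AP = cos(theta) (cos(phi) d + sin(phi) m) - sin(theta) a
  ap <- (ct * cp) %o% d + (ct * sp) %o% m - st %o% a
  # e_ML = -sin(phi) d + cos(phi) m
  ml <- (-sp) %o% d + cp %o% m
  ap[!valid, ] <- NA_real_
  ml[!valid, ] <- NA_real_
  phi[st < 1e-12] <- NA_real_
  tibble::tibble(
    theta = theta, phi = phi, valid_frame = valid,
    ap_x = ap[, 1], ap_y = ap[, 2], ap_z = ap[, 3],
    ml_x = ml[, 1], ml_y = ml[, 2], ml_z = ml[, 3],
    r_x = U[, 1], r_y = U[, 2], r_z = U[, 3]
  )
}

#' Serialize / read embryo geometry as a plain-text config
#'
#' Writes the geometry as a small YAML key-value block so that runs are
#' reproducible, and reads it back.
#'
#' @param geom An [embryo_geometry()].
#' @param path File path.
#' @return `write_geometry` returns `path` invisibly; `read_geometry`
#'   returns an `embryo_geometry`.
#' @export
write_geometry <- function(geom, path) {
  stopifnot(inherits(geom, "embryo_geometry"))
  yaml::write_yaml(list(center = as.numeric(geom$center),
                        radius_um = geom$radius_R,
                        anterior_axis = as.numeric(geom$anterior_axis),
                        dorsal_ref = as.numeric(geom$dorsal_ref)), path)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  y <- yaml::read_yaml(path)
  embryo_geometry(center = y$center, radius = y$radius_um,
                  anterior_axis = y$anterior_axis, dorsal_ref = y$dorsal_ref)
}
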