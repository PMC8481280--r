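# shared fixtures, all generated in code

# canonical test geometry: 350-um embryo, anterior = +z, dorsal = +x
tt_geom <- function(center = c(0, 0, 0)) {
  embryo_geometry(center = center, radius = 350,
                  anterior_axis = c(0, 0, 1), dorsal_ref = c(1, 0, 0))
}

# n random points on a shell around the test geometry
shell_points <- function(n, geom = tt_geom(), thickness = 30, seed = 1) {
  set.seed(seed)
  U <- matrix(rnorm(3 * n), n, 3)
  U <- U / sqrt(rowSums(U^2))
  r <- geom$radius_R + runif(n, -0.5, 0.5) * thickness
  sweep(U * r, 2, geom$center, `+`)
}

# velocity table for an affine field v(x) = v0 + A x at given positions
affine_velocity_table <- function(P, A, v0 = c(0, 0, 0), t_min = 0) {
  V <- sweep(P %*% t(A), 2, v0, `+`)
  tibble::tibble(track_id = seq_len(nrow(P)), t_min = t_min,
                 x_um = P[, 1], y_um = P[, 2], z_um = P[, 3],
                 vx = V[, 1], vy = V[, 2], vz = V[, 3])
}

# extract a 3x3 L matrix from one row of a gradient table
row_L <- function(df, i = 1) {
  matrix(as.numeric(df[i, paste0("L", c(11, 12, 13, 21, 22, 23, 31, 32, 33))]),
         3, 3, byrow = TRUE)
}

grad_cols <- paste0("L", c(11, 12, 13, 21, 22, 23, 31, 32, 33))

# small simulated embryo for integration-style tests
small_sim <- function(preset = "rigid", n_cells = 800, duration = 20,
                      seed = 1, ...) {
  sc <- preset_scenario(preset, seed = seed, n_cells = n_cells,
                        duration = duration, ...)
  simulate_embryo(sc$config, sc$flow)
}
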