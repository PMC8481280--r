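test_that("zero-amplitude flow is static and has zero gradient", {
  geom <- tt_geom()
  flow <- flow_spec()
  P <- shell_points(50, geom, seed = 31)
  expect_true(all(as.matrix(analytic_velocity(P, flow, geom)) == 0))
  expect_true(all(as.matrix(analytic_gradient(P, flow, geom)) == 0))

  sim <- small_sim("static", n_cells = 100, duration = 10, seed = 31)
  spread <- sim$tracks |>
    dplyr::group_by(track_id) |>
    dplyr::summarise(dx = max(x_um) - min(x_um), dy = max(y_um) - min(y_um))
  expect_true(all(spread$dx == 0 & spread$dy == 0))
})

test_that("rigid rotation flow has gradient skew(omega) everywhere", {
  geom <- tt_geom()
  w <- c(1e-3, -2e-3, 1.5e-3)
  flow <- flow_spec(omega_rigid = w)
  P <- shell_points(100, geom, seed = 32)
  L <- analytic_gradient(P, flow, geom)
  Aw <- matrix(c(0, -w[3], w[2], w[3], 0, -w[1], -w[2], w[1], 0),
               3, 3, byrow = TRUE)
  for (i in c(1, 50, 100)) {
    expect_equal(row_L(L, i), Aw, tolerance = 1e-14)
  }
  # and the velocity really is w x x
  V <- as.matrix(analytic_velocity(P, flow, geom))
  Vx <- t(apply(P, 1, function(p) c(w[2] * p[3] - w[3] * p[2],
                                    w[3] * p[1] - w[1] * p[3],
                                    w[1] * p[2] - w[2] * p[1])))
  expect_equal(V, Vx, tolerance = 1e-14, ignore_attr = TRUE)
})

test_that("analytic gradients match central finite differences of the velocity", {
  geom <- tt_geom()
  flow <- flow_spec(A_ep = 1, A_conv = 0.8, A_ext = 2.5,
                    omega_rigid = c(1e-3, -5e-4, 2e-3), k_rad = 1e-3,
                    u_translate = c(0.3, -0.2, 0.1))
  P <- shell_points(100, geom, seed = 33)
  La <- as.matrix(analytic_gradient(P, flow, geom))
  h <- 1e-3
  Lfd <- matrix(0, 100, 9)
  for (b in 1:3) {
    dp <- matrix(0, 100, 3); dp[, b] <- h
    D <- (as.matrix(analytic_velocity(P + dp, flow, geom)) -
            as.matrix(analytic_velocity(P - dp, flow, geom))) / (2 * h)
    for (a in 1:3) Lfd[, 3 * (a - 1) + b] <- D[, a]
  }
  expect_lt(max(abs(La - Lfd)), 1e-6)
})

test_that("tangential flows refuse evaluation at the poles", {
  geom <- tt_geom()
  pole <- matrix(geom$anterior_axis * geom$radius_R, 1, 3)
  expect_error(analytic_velocity(pole, flow_spec(A_ep = 1), geom), "pole")
  expect_error(analytic_gradient(pole, flow_spec(A_conv = 1), geom), "pole")
  # purely rigid/radial flows are fine there
  expect_silent(analytic_velocity(pole, flow_spec(k_rad = 1e-3,
                                                  omega_rigid = c(0, 0, 1e-3)),
                                  geom))
})

test_that("simulation is reproducible and honours noise/dropout/divisions", {
  sc <- preset_scenario("gastrula", seed = 42, n_cells = 200, duration = 10)
  s1 <- simulate_embryo(sc$config, sc$flow)
  s2 <- simulate_embryo(sc$config, sc$flow)
  expect_identical(s1$tracks, s2$tracks)
  expect_identical(s1$truth, s2$truth)

  # different seed, different noise realization
  sc3 <- preset_scenario("gastrula", seed = 43, n_cells = 200, duration = 10)
  s3 <- simulate_embryo(sc3$config, sc3$flow)
  expect_false(identical(s1$tracks, s3$tracks))

  # dropout removes detections but keeps ids consistent
  cfg <- embryo_sim_config(n_cells = 300, duration = 20, noise_sigma = 0,
                           dropout_prob = 0.1, seed = 44)
  sd <- simulate_embryo(cfg, flow_spec())
  expect_lt(nrow(sd$tracks), nrow(sd$truth))
  expect_true(all(sd$tracks$track_id %in% sd$truth$track_id))

  # divisions add new ids over time
  cfg2 <- embryo_sim_config(n_cells = 300, duration = 20, noise_sigma = 0,
                            division_rate = 10, seed = 45)
  sdv <- simulate_embryo(cfg2, flow_spec())
  expect_gt(dplyr::n_distinct(sdv$tracks$track_id), 300)
  # daughters appear ~2 um from their mother cell's position
  first_new <- sdv$truth |>
    dplyr::filter(track_id > 300) |>
    dplyr::slice_min(t_min, n = 1, with_ties = FALSE)
  mothers <- sdv$truth |> dplyr::filter(t_min == first_new$t_min,
                                        track_id <= 300)
  dmin <- min(sqrt((mothers$x_um - first_new$x_um)^2 +
                     (mothers$y_um - first_new$y_um)^2 +
                     (mothers$z_um - first_new$z_um)^2))
  expect_lt(dmin, 2 + 1e-9)
})

test_that("presets are defined as documented", {
  expect_setequal(preset_scenarios(),
                  c("static", "rigid", "expansion", "gastrula", "c59"))
  expect_error(preset_scenario("nope"), "static.*rigid|unknown preset")

  g <- preset_scenario("gastrula")
  c59 <- preset_scenario("c59")
  # c59 differs from gastrula only in the extension amplitude
  expect_equal(c59$flow$A_ext, 0)
  expect_gt(g$flow$A_ext, 0)
  fg <- unclass(g$flow); fc <- unclass(c59$flow)
  fg$A_ext <- fc$A_ext <- NULL
  expect_identical(fg, fc)
  expect_identical(unclass(g$config), unclass(c59$config))

  r <- preset_scenario("rigid")
  expect_true(any(r$flow$omega_rigid != 0))
  expect_equal(r$config$noise_sigma, 0)
  e <- preset_scenario("expansion")
  expect_gt(e$flow$k_rad, 0)
})

test_that("the gastrula flow has a dorsal-meridian saddle with meridional outflow", {
  geom <- tt_geom()
  flow <- preset_scenario("gastrula")$flow
  u <- seq(-1.2, 1.2, by = 0.005)
  pts <- from_embryo_coords(tibble::tibble(r = 1, theta = pi / 2 + u, phi = 0),
                            geom)
  V <- as.matrix(analytic_velocity(pts, flow, geom))
  fr <- frames_at_points(as.matrix(pts) / geom$radius_R, geom)
  v_th <- rowSums(V * cbind(fr$ap_x, fr$ap_y, fr$ap_z))
  sgn <- sign(v_th)
  roots <- which(diff(sgn) != 0)
  expect_gte(length(roots), 1)
  r1 <- roots[1]
  # outflow: meridional velocity negative (anteriorward) before the
  # stagnation point and positive (posteriorward) after it
  expect_lt(v_th[r1], 0)
  expect_gt(v_th[r1 + 1], 0)
  # azimuthal convergence toward the meridian on both sides
  off <- from_embryo_coords(tibble::tibble(r = 1, theta = pi / 2 + u[r1],
                                           phi = c(-0.3, 0.3)), geom)
  Voff <- as.matrix(analytic_velocity(off, flow, geom))
  froff <- frames_at_points(as.matrix(off) / geom$radius_R, geom)
  v_ph <- rowSums(Voff * cbind(froff$ml_x, froff$ml_y, froff$ml_z))
  expect_gt(v_ph[1], 0)  # phi < 0 side flows toward increasing phi
  expect_lt(v_ph[2], 0)
})

test_that("simulated rigid rotation yields the analytic curl field end-to-end", {
  sim <- small_sim("rigid", n_cells = 3000, duration = 12, seed = 46)
  vel <- compute_velocities(sim$tracks, frame_interval = 2)
  mesh <- make_mesh(500)
  rates <- strain_rate_field(vel, sim$geom, mesh, tectonics_config(),
                             times = 6)
  w <- preset_scenario("rigid")$flow$omega_rigid
  er <- as.matrix(mesh$nodes[, c("x", "y", "z")])
  truth <- 2 * as.numeric(er %*% w)
  i <- which(rates$valid & rates$valid_frame)
  err <- abs(rates$curl_r[i] - truth[match(rates$node_id[i],
                                           mesh$nodes$node_id)])
  expect_lt(max(err), 0.02 * 2 * sqrt(sum(w^2)))
})
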