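test_that("domain assignment matches a brute-force distance check", {
  geom <- tt_geom()
  mesh <- make_mesh(200)
  cfg <- tectonics_config()
  P <- shell_points(500, geom, seed = 21)
  memb <- assign_domains(P, mesh, geom, cfg)
  # brute force all-pairs oracle
  NP <- sweep(as.matrix(mesh$nodes[, c("x", "y", "z")]) * geom$radius_R,
              2, geom$center, `+`)
  oracle <- do.call(rbind, lapply(seq_len(nrow(NP)), function(i) {
    d <- sqrt(colSums((t(P) - NP[i, ])^2))
    j <- which(d <= cfg$domain_radius)
    if (length(j) == 0) return(NULL)
    data.frame(node_id = i, cell = j)
  }))
  expect_equal(as.data.frame(memb), oracle, ignore_attr = TRUE)

  # a cell exactly at a node's physical position belongs to that node
  memb2 <- assign_domains(NP[17, , drop = FALSE], mesh, geom, cfg)
  expect_true(any(memb2$node_id == 17 & memb2$cell == 1))
})

test_that("domain velocity is the member mean and respects the count threshold", {
  geom <- tt_geom()
  mesh <- make_mesh(200)
  cfg <- tectonics_config()
  P <- shell_points(400, geom, seed = 22)
  set.seed(23)
  V <- matrix(rnorm(1200, sd = 0.5), 400, 3)
  vel <- tibble::tibble(track_id = 1:400, t_min = 0,
                        x_um = P[, 1], y_um = P[, 2], z_um = P[, 3],
                        vx = V[, 1], vy = V[, 2], vz = V[, 3])
  dv <- domain_velocity(vel, mesh, geom, cfg)
  memb <- assign_domains(P, mesh, geom, cfg)
  for (i in c(1, 50, 120, 200)) {
    cells <- memb$cell[memb$node_id == i]
    row <- dv[dv$node_id == i, ]
    expect_equal(row$n_cells, length(cells))
    if (length(cells) >= cfg$min_cells_per_domain) {
      expect_equal(as.numeric(row[, c("vx", "vy", "vz")]),
                   colMeans(V[cells, , drop = FALSE]), tolerance = 1e-12)
    } else {
      expect_true(all(is.na(row[, c("vx", "vy", "vz")])))
    }
  }

  # constant velocity field: every populated domain reports it exactly
  velc <- dplyr::mutate(vel, vx = 0.4, vy = -0.1, vz = 0.25)
  dvc <- domain_velocity(velc, mesh, geom, cfg)
  ok <- is.finite(dvc$vx)
  expect_true(all(abs(dvc$vx[ok] - 0.4) < 1e-12))
  # under-populated domains are missing, not zero
  expect_true(all(dvc$n_cells[!ok] < cfg$min_cells_per_domain))
})

test_that("gradient estimator recovers affine fields to machine precision", {
  geom <- tt_geom()
  P <- shell_points(600, geom, seed = 24)
  q <- rbind(c(350, 0, 0), c(0, 247.49, 247.49), c(-200, 150, 250))

  # uniform translation
  vel <- affine_velocity_table(P, matrix(0, 3, 3), v0 = c(0.5, -0.2, 0.3))
  vg <- velocity_gradient(vel, q, geom, tectonics_config(), time = 0)
  expect_lt(max(abs(as.matrix(vg[, grad_cols]))), 1e-10)

  # rigid rotation v = w x x
  w <- c(2e-3, -1e-3, 3e-3)
  Aw <- matrix(c(0, -w[3], w[2], w[3], 0, -w[1], -w[2], w[1], 0),
               3, 3, byrow = TRUE)
  vg2 <- velocity_gradient(affine_velocity_table(P, Aw), q, geom,
                           tectonics_config(), time = 0)
  for (i in 1:3) expect_lt(max(abs(row_L(vg2, i) - Aw)), 1e-10)

  # arbitrary full-rank affine field
  set.seed(25)
  A <- matrix(rnorm(9, sd = 2e-3), 3, 3)
  vg3 <- velocity_gradient(affine_velocity_table(P, A, v0 = c(1, 2, 3)), q,
                           geom, tectonics_config(), time = 0)
  for (i in 1:3) expect_lt(max(abs(row_L(vg3, i) - A)), 1e-9)
  expect_true(all(vg3$valid))
})

test_that("rank-deficient neighbourhoods are flagged invalid, not fabricated", {
  geom <- tt_geom()
  # cells confined to a plane: radial derivative unidentifiable
  set.seed(26)
  P <- cbind(350, runif(50, -80, 80), runif(50, -80, 80))
  vel <- affine_velocity_table(P, matrix(0, 3, 3), v0 = c(0.1, 0, 0))
  vg <- velocity_gradient(vel, matrix(c(350, 0, 0), 1, 3), geom,
                          tectonics_config(), time = 0)
  expect_false(vg$valid[1])
})

test_that("decomposition satisfies the defining identities on random tensors", {
  geom <- tt_geom()
  mesh <- make_mesh(200)
  frames <- local_frames(mesh, geom)
  set.seed(27)
  n <- 1000
  ids <- sample(mesh$nodes$node_id[frames$valid_frame], n, replace = TRUE)
  Lmat <- matrix(rnorm(9 * n, sd = 1e-2), n, 9)
  g <- tibble::as_tibble(as.data.frame(Lmat))
  names(g) <- grad_cols
  g$node_id <- ids
  dec <- decompose_gradient(g, frames)
  # trace equals the eigenvalue sum of E
  expect_lt(max(abs(dec$trace - (dec$eig1 + dec$eig2 + dec$eig3))), 1e-10)
  # eigenvalues sorted descending
  expect_true(all(dec$eig1 >= dec$eig2 - 1e-12 & dec$eig2 >= dec$eig3 - 1e-12))
  # components are E projections, so bounded by extreme eigenvalues
  expect_true(all(dec$e_AP <= dec$eig1 + 1e-10 & dec$e_AP >= dec$eig3 - 1e-10))
  # E + Omega = L holds by construction of the projections; check through
  # an explicit matrix reconstruction on a sample of rows
  for (i in sample(n, 20)) {
    L <- matrix(Lmat[i, ], 3, 3, byrow = TRUE)
    E <- (L + t(L)) / 2; Om <- (L - t(L)) / 2
    expect_equal(E + Om, L, tolerance = 1e-15)
    expect_equal(Om, -t(Om), tolerance = 1e-15)
    expect_equal(dec$trace[i], sum(diag(E)), tolerance = 1e-12)
    ev <- sort(eigen(E, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    expect_equal(c(dec$eig1[i], dec$eig2[i], dec$eig3[i]), ev,
                 tolerance = 1e-9)
  }
})

test_that("isotropic expansion and pure spin decompose as expected", {
  geom <- tt_geom()
  mesh <- make_mesh(200)
  frames <- local_frames(mesh, geom)
  node <- mesh$nodes$node_id[frames$valid_frame][10]

  # L = k I: all components k, trace 3k, no curl
  k <- 2.5e-3
  g <- tibble::tibble(L11 = k, L12 = 0, L13 = 0, L21 = 0, L22 = k, L23 = 0,
                      L31 = 0, L32 = 0, L33 = k, node_id = node)
  d <- decompose_gradient(g, frames)
  expect_equal(d$e_AP, k, tolerance = 1e-12)
  expect_equal(d$e_ML, k, tolerance = 1e-12)
  expect_equal(d$e_r, k, tolerance = 1e-12)
  expect_equal(d$trace, 3 * k, tolerance = 1e-12)
  expect_equal(d$curl_r, 0, tolerance = 1e-15)
  expect_equal(d$curl_mag, 0, tolerance = 1e-15)

  # pure spin about the node's own radial axis: E = 0, curl_r = 2|w|,
  # positive for anticlockwise rotation viewed from outside
  er <- as.numeric(frames[frames$node_id == node, c("r_x", "r_y", "r_z")])
  wmag <- 4e-3
  w <- wmag * er
  Aw <- matrix(c(0, -w[3], w[2], w[3], 0, -w[1], -w[2], w[1], 0),
               3, 3, byrow = TRUE)
  g2 <- tibble::as_tibble(as.data.frame(matrix(as.vector(t(Aw)), 1, 9)))
  names(g2) <- grad_cols
  g2$node_id <- node
  d2 <- decompose_gradient(g2, frames)
  expect_equal(abs(d2$e_AP) + abs(d2$e_ML) + abs(d2$e_r), 0, tolerance = 1e-15)
  expect_equal(d2$curl_r, 2 * wmag, tolerance = 1e-12)
  # the flip flag reverses the sign convention
  d3 <- decompose_gradient(g2, frames, tectonics_config(flip_curl = TRUE))
  expect_equal(d3$curl_r, -2 * wmag, tolerance = 1e-12)
})

test_that("gradients are covariant under frame rotation with co-rotated axes", {
  set.seed(28)
  A <- matrix(rnorm(9, sd = 2e-3), 3, 3)
  geom <- tt_geom()
  P <- shell_points(500, geom, seed = 28)
  q <- matrix(c(0, 247.49, 247.49), 1, 3)
  vg <- velocity_gradient(affine_velocity_table(P, A), q, geom,
                          tectonics_config(), time = 0)
  # random rotation Q
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  geom_rot <- embryo_geometry(center = c(0, 0, 0), radius = 350,
                              anterior_axis = Q %*% geom$anterior_axis,
                              dorsal_ref = Q %*% geom$dorsal_ref)
  Pr <- P %*% t(Q)
  Vr <- (P %*% t(A)) %*% t(Q)
  velr <- tibble::tibble(track_id = seq_len(nrow(P)), t_min = 0,
                         x_um = Pr[, 1], y_um = Pr[, 2], z_um = Pr[, 3],
                         vx = Vr[, 1], vy = Vr[, 2], vz = Vr[, 3])
  vgr <- velocity_gradient(velr, q %*% t(Q), geom_rot, tectonics_config(),
                           time = 0)
  expect_equal(row_L(vgr, 1), Q %*% row_L(vg, 1) %*% t(Q), tolerance = 1e-9)

  # projected components are invariant when the anatomy co-rotates
  U <- q / sqrt(sum(q^2))
  fr <- frames_at_points(U, geom)
  fr$node_id <- 1L
  Ur <- U %*% t(Q)
  frr <- frames_at_points(Ur, geom_rot)
  frr$node_id <- 1L
  d <- decompose_gradient(dplyr::mutate(vg, node_id = 1L), fr)
  dr <- decompose_gradient(dplyr::mutate(vgr, node_id = 1L), frr)
  expect_equal(c(dr$e_AP, dr$e_ML, dr$e_r, dr$trace, dr$curl_r),
               c(d$e_AP, d$e_ML, d$e_r, d$trace, d$curl_r), tolerance = 1e-9)
})

test_that("mirror-symmetric data yield mirror-symmetric strain components", {
  geom <- tt_geom()
  flow <- flow_spec(A_ep = 1, A_conv = 0.8, A_ext = 2.5)
  # mirror the sample cloud about the dorsal meridian plane (phi -> -phi,
  # i.e. y -> -y for this geometry) so the data are exactly symmetric
  set.seed(29)
  half <- shell_points(800, geom, seed = 29)
  P <- rbind(half, cbind(half[, 1], -half[, 2], half[, 3]))
  V <- as.matrix(analytic_velocity(P, flow, geom))
  vel <- tibble::tibble(track_id = seq_len(nrow(P)), t_min = 0,
                        x_um = P[, 1], y_um = P[, 2], z_um = P[, 3],
                        vx = V[, 1], vy = V[, 2], vz = V[, 3])
  co <- tibble::tibble(r = 1, theta = c(1.2, 0.9, 1.7), phi = c(0.7, 1.9, 0.4))
  qa <- as.matrix(from_embryo_coords(co, geom))
  qb <- as.matrix(from_embryo_coords(dplyr::mutate(co, phi = -phi), geom))
  cfg <- tectonics_config()
  ga <- velocity_gradient(vel, qa, geom, cfg, time = 0)
  gb <- velocity_gradient(vel, qb, geom, cfg, time = 0)
  fa <- frames_at_points(qa / sqrt(rowSums(qa^2)), geom)
  fb <- frames_at_points(qb / sqrt(rowSums(qb^2)), geom)
  fa$node_id <- fb$node_id <- seq_len(3)
  da <- decompose_gradient(dplyr::mutate(ga, node_id = seq_len(3)), fa)
  db <- decompose_gradient(dplyr::mutate(gb, node_id = seq_len(3)), fb)
  expect_equal(db$e_ML, da$e_ML, tolerance = 1e-6)
  expect_equal(db$e_AP, da$e_AP, tolerance = 1e-6)
  expect_equal(db$curl_r, -da$curl_r, tolerance = 1e-6)
})

test_that("window integration: constant, analytic and gappy rate series", {
  # constant rate s integrates to s * W exactly
  s <- 3e-3
  rates <- tidyr::expand_grid(node_id = 1:5, t_min = seq(0, 60, 2)) |>
    dplyr::mutate(theta = 1.3, phi = 0.2, e_AP = s, e_ML = -s, e_r = 0,
                  trace = 0, curl_r = 0, n_cells = 10)
  maps <- integrate_strain(rates, window = 30)
  expect_lt(max(abs(maps$e_AP - s * 30)), 1e-10)
  expect_lt(max(abs(maps$e_ML + s * 30)), 1e-10)
  # window centres only where the full window fits
  expect_equal(range(maps$t_min), c(16, 44))

  # rate sin(t): trapezoid matches the closed form within its error bound
  rates2 <- dplyr::mutate(rates, e_AP = sin(t_min * 0.2))
  maps2 <- integrate_strain(rates2, window = 30)
  h <- 2 * 0.2
  for (tc in unique(maps2$t_min)) {
    # grid points span [tc-14, tc+14]; the integral is rescaled to W = 30
    exact <- (cos((tc - 14) * 0.2) - cos((tc + 14) * 0.2)) / 0.2 * 30 / 28
    got <- maps2$e_AP[maps2$t_min == tc][1]
    expect_lt(abs(got - exact), 28 / 12 * h^2)  # trapezoid bound, |f''| <= 1
  }

  # window shorter than 2 frames errors
  expect_error(integrate_strain(rates, window = 3), "2 frames")

  # missing samples: >= 80% coverage integrates (rescaled), less is missing
  gappy <- dplyr::mutate(rates, e_AP = ifelse(node_id == 1 &
    t_min == 28, NA_real_, e_AP))
  mg <- integrate_strain(gappy, window = 30)
  v1 <- mg$e_AP[mg$node_id == 1 & mg$t_min == 30]
  expect_equal(v1, s * 30, tolerance = 1e-10)  # constant rate, rescaled
  very_gappy <- dplyr::mutate(rates, e_AP = ifelse(node_id == 1 &
    t_min %in% seq(24, 36, 2), NA_real_, e_AP))
  mvg <- integrate_strain(very_gappy, window = 30)
  expect_true(is.na(mvg$e_AP[mvg$node_id == 1 & mvg$t_min == 30]))
  # untouched nodes unaffected
  expect_equal(mvg$e_AP[mvg$node_id == 2 & mvg$t_min == 30], s * 30,
               tolerance = 1e-10)
})

test_that("divergence equals the sum of the three projected components", {
  geom <- tt_geom()
  mesh <- make_mesh(300)
  flow <- flow_spec(A_ep = 0.8, A_conv = 0.6, A_ext = 1.5, k_rad = 5e-4,
                    omega_rigid = c(0, 1e-3, 0))
  frames <- local_frames(mesh, geom)
  lt <- true_gradient_table(mesh, geom, flow, times = c(0, 2, 4))
  dec <- decompose_gradient(lt, frames)
  ok <- is.finite(dec$e_AP)
  expect_lt(max(abs(dec$trace[ok] - (dec$e_AP + dec$e_ML + dec$e_r)[ok])),
            1e-8)
  dec$n_cells <- 10
  maps <- integrate_strain(dec, window = 4)
  dm <- divergence_map(maps)
  ok2 <- is.finite(maps$e_AP)
  expect_equal(dm$divergence[ok2],
               (maps$e_AP + maps$e_ML + maps$e_r)[ok2], tolerance = 1e-8)
})
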