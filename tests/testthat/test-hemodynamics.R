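test_that("steady Poiseuille flow volume matches the closed form", {
  # v_max 1 m/s, R 10 mm, cycle 20 x 40.8 ms: volume = 0.5 v_max pi R^2 T
  ph <- generate_phantom(phantom_spec(geometry = "straight",
                                      segment_length = 60, spacing = 2.5,
                                      n_timeframes = 20,
                                      waveform = steady_wave(20)))
  sp <- ph$ds$spacing
  cl <- extract_centerline(ph$lumen_mask, sp,
                           orient_point = ph$truth$centerline_points[1, ])
  cl <- place_landmarks(cl, ph$truth$landmark_fractions)
  planes <- build_planes(cl, ph$lumen_mask, sp)
  fv <- flow_volumes(ph$ds, planes$P5)
  expected <- 0.5 * 1.0 * pi * 100 * 20 * 40.8 / 1000  # 128.18 mL
  expect_lt(abs(fv$net_volume_ml / expected - 1), 0.03)
  expect_equal(fv$forward_volume_ml, fv$net_volume_ml, tolerance = 1e-9)
  # zero field
  ds0 <- ph$ds; ds0$velocity[] <- 0
  fv0 <- flow_volumes(ds0, planes$P5)
  expect_equal(fv0$forward_volume_ml, 0)
  expect_equal(fv0$net_volume_ml, 0)
  # uniform retrograde flow: forward 0, net < 0
  dsr <- ph$ds; dsr$velocity <- -dsr$velocity
  fvr <- flow_volumes(dsr, planes$P5)
  expect_equal(fvr$forward_volume_ml, 0, tolerance = 1e-9)
  expect_lt(fvr$net_volume_ml, 0)
  # excluded plane propagates qc
  pex <- planes$P5; pex$qc_flag <- "EXCLUDED"; pex$qc_reason <- "test"
  expect_equal(flow_volumes(ph$ds, pex)$qc_flag, "EXCLUDED")
})

test_that("WSS estimate matches the Poiseuille closed form and is linear", {
  ph <- generate_phantom(phantom_spec(geometry = "straight",
                                      segment_length = 40, spacing = 1,
                                      n_timeframes = 5,
                                      waveform = steady_wave(5)))
  sp <- ph$ds$spacing
  cl <- extract_centerline(ph$lumen_mask, sp,
                           orient_point = ph$truth$centerline_points[1, ])
  mesh <- extract_wall_mesh(ph$lumen_mask, sp, cl)
  interior <- mesh$vertices[, 3] > 5 & mesh$vertices[, 3] < 35
  w <- wss_vector_field(ph$ds, mesh, viscosity = 3.2e-3, t = 2,
                        d_mm = c(0.5, 1.0))
  wn <- sqrt(rowSums(w$vectors^2))
  sel <- interior & w$valid
  expect_lt(abs(mean(wn[sel]) / 0.64 - 1), 0.10)
  # zero field -> zero WSS
  ds0 <- ph$ds; ds0$velocity[] <- 0
  w0 <- wss_vector_field(ds0, mesh, 3.2e-3, t = 2)
  expect_true(all(abs(w0$vectors) < 1e-12))
  # linearity: doubling velocities doubles every WSS vector exactly
  ds2 <- ph$ds; ds2$velocity <- 2 * ds2$velocity
  w2 <- wss_vector_field(ds2, mesh, 3.2e-3, t = 2, d_mm = c(0.5, 1.0))
  expect_equal(w2$vectors, 2 * w$vectors, tolerance = 1e-12)
})

test_that("systolic WSS averages vectors before taking the norm", {
  ph <- small_straight()
  sp <- ph$ds$spacing
  cl <- extract_centerline(ph$lumen_mask, sp,
                           orient_point = ph$truth$centerline_points[1, ])
  mesh <- extract_wall_mesh(ph$lumen_mask, sp, cl)
  # time-constant field: systolic WSS equals single-frame WSS
  ds <- ph$ds
  for (t in 2:ds$n_timeframes) ds$velocity[, , , t, ] <- ds$velocity[, , , 1, ]
  pk <- list(t_peak = 3, window5 = 1:5, window3 = 2:4)
  sys <- systolic_wss(ds, mesh, 3.2e-3, pk)
  one <- wss_vector_field(ds, mesh, 3.2e-3, t = 1)
  expect_equal(sys$vectors, one$vectors, tolerance = 1e-12)
  expect_equal(sys$abs_wss, sqrt(rowSums(one$vectors^2)), tolerance = 1e-12)
  # alternating opposed fields: vector mean attenuates below mean of norms
  ds2 <- ds
  for (t in c(2, 4)) ds2$velocity[, , , t, ] <- -ds2$velocity[, , , t, ]
  sys2 <- systolic_wss(ds2, mesh, 3.2e-3, pk)
  expect_lt(mean(sys2$abs_wss), 0.5 * mean(sys$abs_wss) + 1e-9)
  # scaling by the waveform: norm scales by the window-mean of w(t)
  wvec <- c(0.2, 0.5, 1, 0.5, 0.2, rep(0.1, 5))
  ds3 <- ds
  for (t in 1:10) ds3$velocity[, , , t, ] <- wvec[t] * ds$velocity[, , , t, ]
  sys3 <- systolic_wss(ds3, mesh, 3.2e-3, pk)
  expect_equal(sys3$abs_wss, mean(wvec[1:5]) * sys$abs_wss, tolerance = 1e-9)
  expect_error(systolic_wss(velocity_field(array(0, c(4, 4, 4, 4, 3)),
                                           spacing = 1, dt = 40, venc = 1.5),
                            mesh, 3.2e-3, pk), "5 timeframes")
})

test_that("regional WSS means recover uniform and painted contrasts", {
  g <- utube_geo()
  n <- nrow(g$mesh$vertices)
  map <- structure(list(vectors = matrix(0, n, 3),
                        abs_wss = rep(0.5, n),
                        valid = rep(TRUE, n), viscosity_used = 3.2e-3),
                   class = "wss_map")
  reg <- regional_wss(map, g$atlas)
  expect_equal(reg$segments$mean_wss, rep(0.5, 18), tolerance = 1e-12)
  expect_equal(reg$zones$mean_wss, rep(0.5, 3), tolerance = 1e-12)
  # elevated WSS painted on the outer ascending wall is recovered
  sel <- g$atlas$analyzed & g$atlas$zone == "ascending" &
    g$atlas$side == "outer"
  map2 <- map
  map2$abs_wss[sel] <- 1.2
  reg2 <- regional_wss(map2, g$atlas)
  sz <- reg2$side_zones
  expect_gt(sz$mean_wss[sz$label == "outer_ascending"],
            sz$mean_wss[sz$label == "inner_ascending"])
  # an all-invalid segment is reported missing, not zero
  map3 <- map
  map3$valid[g$atlas$segment == 7 & g$atlas$analyzed] <- FALSE
  reg3 <- regional_wss(map3, g$atlas)
  expect_true(is.na(reg3$segments$mean_wss[7]))
  expect_equal(reg3$segments$n_vertices[7], 0L)
})

test_that("zone peak velocities match phantom truth and a brute-force scan", {
  ph <- cached("jet_utube", generate_phantom(
    phantom_spec(geometry = "u_tube", n_timeframes = 15, venc = 2.5,
                 jet = list(s_mm = 30, sigma_mm = 10, factor = 2))))
  sp <- ph$ds$spacing
  cl <- extract_centerline(ph$lumen_mask, sp,
                           orient_point = ph$truth$centerline_points[1, ])
  cl <- place_landmarks(cl, ph$truth$landmark_fractions)
  pk <- find_peak_systole(ph$ds, ph$lumen_mask)
  expect_equal(pk$t_peak, ph$truth$t_peak)
  zones <- voxel_zones(ph$lumen_mask, cl, sp)
  mip <- peak_velocity_mip(ph$ds, ph$lumen_mask, zones, pk)
  # brute force: exhaustive scan over zone voxels x window frames
  for (i in 1:3) {
    zn <- mip$zone[i]
    sel <- which(ph$lumen_mask & !is.na(zones) & zones == zn)
    brute <- max(vapply(pk$window3, function(t) {
      spd <- sqrt(ph$ds$velocity[, , , t, 1]^2 + ph$ds$velocity[, , , t, 2]^2 +
                  ph$ds$velocity[, , , t, 3]^2)
      max(spd[sel])
    }, numeric(1)))
    expect_identical(mip$peak_velocity[i], brute)
  }
  # truth comparison (zone membership at boundaries differs sub-voxel)
  expect_equal(mip$peak_velocity[mip$zone == "ascending"],
               unname(ph$truth$zone_peak_speed["ascending"]),
               tolerance = 0.02)
  # speeds decay downstream of the jet: ascending >= arch >= descending
  expect_true(mip$peak_velocity[1] >= mip$peak_velocity[2] - 1e-9)
  expect_true(mip$peak_velocity[2] >= mip$peak_velocity[3] - 1e-9)
  # zero field -> zero peaks
  ds0 <- ph$ds; ds0$velocity[] <- 0
  mip0 <- peak_velocity_mip(ds0, ph$lumen_mask, zones, pk)
  expect_true(all(mip0$peak_velocity == 0))
})

test_that("maximum aortic area is the diameter product in cm^2", {
  expect_equal(max_aortic_area(10, 10), 1.0)
  expect_equal(max_aortic_area(39.3, 31.8), 12.49740)
  expect_error(max_aortic_area(0, 10), "positive")
})
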