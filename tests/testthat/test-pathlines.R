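# helper: a hand-built velocity field on a small grid, constant in time
uniform_field <- function(u, dims = c(20, 20, 20), spacing = 2, nt = 4) {
  vel <- array(0, c(dims, nt, 3))
  for (c in 1:3) vel[, , , , c] <- u[c]
  velocity_field(vel, spacing = spacing, dt = 50, venc = 2.5)
}

test_that("pathlines are exact for a uniform field", {
  ds <- uniform_field(c(0.3, 0.2, 0.5))
  mask <- array(TRUE, c(20, 20, 20))
  pl <- trace_pathlines(ds, matrix(c(4, 4, 4), 1), t0_ms = 0,
                        dt_int_ms = 2, mask = mask)[[1]]
  k <- nrow(pl$positions)
  expect_gt(k, 10)
  t_el <- pl$times[k] - pl$times[1]
  expect_equal(pl$positions[k, ], c(4, 4, 4) + c(0.3, 0.2, 0.5) * t_el,
               tolerance = 1e-9)
})

test_that("solid-body rotation gives a circular pathline with period 2 pi / omega", {
  dims <- c(25, 25, 9); spacing <- 2; nt <- 4
  ctr <- c(24, 24)
  omega <- 0.02  # rad/ms
  gx <- (seq_len(dims[1]) - 1) * spacing
  vel <- array(0, c(dims, nt, 3))
  vx <- outer(gx, gx, function(x, y) -omega * (y - ctr[2]))
  vy <- outer(gx, gx, function(x, y) omega * (x - ctr[1]))
  for (t in seq_len(nt)) for (k in seq_len(dims[3])) {
    vel[, , k, t, 1] <- vx
    vel[, , k, t, 2] <- vy
  }
  ds <- velocity_field(vel, spacing = spacing, dt = 200, venc = 2.5)
  mask <- array(TRUE, dims)
  r0 <- 10
  period <- 2 * pi / omega  # 314.16 ms
  pl <- trace_pathlines(ds, matrix(c(ctr[1] + r0, ctr[2], 8), 1),
                        t0_ms = 0, dt_int_ms = 1, mask = mask,
                        max_time_ms = period)[[1]]
  k <- nrow(pl$positions)
  # radius preserved and the orbit closes after one period (within 1%)
  rr <- sqrt((pl$positions[, 1] - ctr[1])^2 + (pl$positions[, 2] - ctr[2])^2)
  expect_lt(max(abs(rr - r0)), 0.1)
  gap <- sqrt(sum((pl$positions[k, ] - pl$positions[1, ])^2))
  expect_lt(gap, 0.01 * 2 * pi * r0)
})

test_that("seeds outside the mask give empty pathlines with a warning", {
  ds <- uniform_field(c(0, 0, 0.5))
  mask <- array(FALSE, c(20, 20, 20)); mask[5:15, 5:15, ] <- TRUE
  expect_warning(
    pls <- trace_pathlines(ds, rbind(c(2, 2, 10), c(20, 20, 10)),
                           t0_ms = 0, dt_int_ms = 2, mask = mask),
    "outside")
  expect_equal(nrow(pls[[1]]$positions), 0)
  expect_gt(nrow(pls[[2]]$positions), 5)
})

test_that("helical phantom rotation matches swirl rate times transit length", {
  # 6.75 deg/mm over the central 80 mm: 540 degrees per transit
  ph <- cached("swirl540", generate_phantom(
    phantom_spec(geometry = "straight", segment_length = 100, spacing = 2.5,
                 n_timeframes = 10, venc = 2.5, waveform = steady_wave(10),
                 swirl_deg_per_mm = 6.75, swirl_extent = c(10, 90))))
  expect_equal(ph$truth$swirl_rotation_deg, 540)
  cl <- extract_centerline(ph$lumen_mask, ph$ds$spacing,
                           orient_point = ph$truth$centerline_points[1, ])
  # off-axis seeds: a particle exactly on the axis has no azimuthal angle
  seeds <- rbind(c(18, 16, 2), c(16, 13, 2), c(17.5, 17.5, 2))
  pls <- trace_pathlines(ph$ds, seeds, t0_ms = 0, dt_int_ms = 2,
                         mask = ph$lumen_mask)
  rots <- vapply(pls, function(p) rotation_angle(p, cl),
                 numeric(1))
  expect_true(all(abs(rots - 540) < 0.08 * 540))
  # reversed swirl: same magnitude
  phn <- cached("swirl540n", generate_phantom(
    phantom_spec(geometry = "straight", segment_length = 100, spacing = 2.5,
                 n_timeframes = 10, venc = 2.5, waveform = steady_wave(10),
                 swirl_deg_per_mm = -6.75, swirl_extent = c(10, 90))))
  plsn <- trace_pathlines(phn$ds, seeds, t0_ms = 0, dt_int_ms = 2,
                          mask = phn$lumen_mask)
  rotsn <- vapply(plsn, function(p) rotation_angle(p, cl),
                  numeric(1))
  expect_equal(rotsn, rots, tolerance = 0.05)
  # straight axial flow rotates by ~0
  ph0 <- small_straight()
  cl0 <- extract_centerline(ph0$lumen_mask, ph0$ds$spacing,
                            orient_point = ph0$truth$centerline_points[1, ])
  pls0 <- trace_pathlines(ph0$ds, rbind(c(18, 16, 2)), t0_ms = 0,
                          dt_int_ms = 2, mask = ph0$lumen_mask)
  expect_lt(rotation_angle(pls0[[1]], cl0), 15)
  expect_error(rotation_angle(list(positions = matrix(0, 2, 3)), cl0),
               "fewer than 3")
})

test_that("vortical flow (retrograde revolution) is distinguished from helix", {
  ph <- small_straight()
  cl <- extract_centerline(ph$lumen_mask, ph$ds$spacing,
                           orient_point = ph$truth$centerline_points[1, ])
  # recirculation bubble: revolution about a horizontal axis plus a
  # retrograde drift -> mean direction deviates > 90 deg from the tangent
  dims <- dim(ph$lumen_mask); spacing <- ph$ds$spacing
  ctr <- c(16, 16, 30)
  omega <- 0.03
  gx <- (seq_len(dims[1]) - 1) * spacing[1]
  gz <- (seq_len(dims[3]) - 1) * spacing[3]
  vel <- array(0, c(dims, 5, 3))
  vxz <- outer(gx, gz, function(x, z) -omega * (z - ctr[3]))
  vzx <- outer(gx, gz, function(x, z) omega * (x - ctr[1]))
  for (t in 1:5) for (j in seq_len(dims[2])) {
    vel[, j, , t, 1] <- vxz
    vel[, j, , t, 3] <- vzx - 0.05   # retrograde drift against +z flow
  }
  dsv <- velocity_field(vel, spacing = spacing, dt = 40.8, venc = 2.5)
  mask <- array(TRUE, dims)
  plv <- trace_pathlines(dsv, rbind(ctr + c(4, 0, 0)), t0_ms = 0,
                         dt_int_ms = 1, mask = mask)[[1]]
  expect_true(classify_vortex(plv, cl))
  # pure forward helix is NOT a vortex (helix grading handles it)
  ph540 <- cached("swirl540", generate_phantom(
    phantom_spec(geometry = "straight", segment_length = 100, spacing = 2.5,
                 n_timeframes = 10, venc = 2.5, waveform = steady_wave(10),
                 swirl_deg_per_mm = 6.75, swirl_extent = c(10, 90))))
  cl540 <- extract_centerline(ph540$lumen_mask, ph540$ds$spacing,
                              orient_point = ph540$truth$centerline_points[1, ])
  plh <- trace_pathlines(ph540$ds, rbind(c(18, 16, 2)), t0_ms = 0,
                         dt_int_ms = 2, mask = ph540$lumen_mask)[[1]]
  expect_false(classify_vortex(plh, cl540))
  # straight flow: no vortex
  pls <- trace_pathlines(ph$ds, rbind(c(18, 16, 2)), t0_ms = 0,
                         dt_int_ms = 2, mask = ph$lumen_mask)[[1]]
  expect_false(classify_vortex(pls, cl))
})

test_that("flow-pattern grades follow the 0-3 scale and are monotone", {
  expect_equal(grade_flow_pattern(10, 1.0), 0L)
  expect_equal(grade_flow_pattern(300, 1.0), 1L)
  expect_equal(grade_flow_pattern(400, 1.0, v_thresh = 1.5), 2L)
  expect_equal(grade_flow_pattern(400, 2.0, v_thresh = 1.5), 3L)
  # monotone in rotation at fixed peak velocity
  rots <- seq(0, 720, by = 30)
  for (v in c(1.0, 2.0)) {
    g <- vapply(rots, grade_flow_pattern, integer(1), peak_velocity = v)
    expect_true(all(diff(g) >= 0))
  }
})
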