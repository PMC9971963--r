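test_that("straight-tube centerline is collinear with the tube axis", {
  ph <- small_straight()
  cl <- extract_centerline(ph$lumen_mask, ph$ds$spacing,
                           orient_point = ph$truth$centerline_points[1, ])
  dev <- sqrt((cl$points[, 1] - 16)^2 + (cl$points[, 2] - 16)^2)
  expect_lt(max(dev), 0.5 * max(ph$ds$spacing))
  expect_true(all(diff(cl$arc_length) > 0))
  expect_equal(rowSums(cl$tangents^2), rep(1, nrow(cl$tangents)),
               tolerance = 1e-9)
  # oriented: starts at the z = 0 end
  expect_lt(cl$points[1, 3], cl$points[nrow(cl$points), 3])
  expect_error(extract_centerline(ph$lumen_mask & FALSE, ph$ds$spacing),
               "empty")
})

test_that("U-tube centerline recovers the arch curvature within 10%", {
  g <- utube_geo()
  truth <- g$ph$truth
  s <- g$cl$arc_length
  mid <- truth$total_length_mm / 2
  sel <- which(abs(s - mid) < 40)
  # least-squares circle through the recovered mid-arch points (x-z plane)
  P <- g$cl$points[sel, c(1, 3)]
  A <- cbind(2 * P[, 1], 2 * P[, 2], 1)
  sol <- qr.solve(A, P[, 1]^2 + P[, 2]^2)
  r_fit <- sqrt(sol[3] + sol[1]^2 + sol[2]^2)
  expect_lt(abs(r_fit / 35 - 1), 0.10)
  # and tracks the analytic centerline closely over its whole course
  ni <- aortaflow:::nearest_point_index(g$cl$points, truth$centerline_points)
  dd <- sqrt(rowSums((g$cl$points - truth$centerline_points[ni, ])^2))
  expect_lt(mean(dd), 1.0)
})

test_that("landmark placement maps fractions and projects explicit points", {
  g <- utube_geo()
  cl <- g$cl
  expect_named(cl$landmarks, paste0("P", 1:9))
  expect_true(all(diff(cl$landmarks) > 0))
  # explicit off-centerline point projects to the nearest centerline point
  idx <- which.min(abs(cl$arc_length - cl$landmarks[["P3"]])) + 3L
  target <- cl$points[idx, ] + c(0, 6, 0)   # perpendicular to the x-z plane
  spec <- lapply(cl$landmarks / max(cl$arc_length),
                 function(f) list(fraction = f))
  spec$P3 <- list(point_mm = target)
  cl2 <- place_landmarks(cl, spec)
  expect_equal(cl2$landmarks[["P3"]], cl$arc_length[idx], tolerance = 2)
  # out-of-order landmarks rejected
  bad <- spec
  bad$P5 <- list(fraction = 0.01)
  expect_error(place_landmarks(cl, bad), "out of order")
})

test_that("plane normals equal local centerline tangents on analytic geometry", {
  ph <- small_straight()
  cl <- extract_centerline(ph$lumen_mask, ph$ds$spacing,
                           orient_point = ph$truth$centerline_points[1, ])
  cl <- place_landmarks(cl, ph$truth$landmark_fractions)
  planes <- build_planes(cl, ph$lumen_mask, ph$ds$spacing)
  for (pl in planes)
    expect_gt(abs(sum(pl$normal * c(0, 0, 1))), 0.999)
  # U-tube: normals within 2 degrees of the analytic tangent away from the
  # leg/arch junctions (where the piecewise-analytic tangent is discontinuous)
  g <- utube_geo()
  spec <- phantom_spec(geometry = "u_tube", n_timeframes = 15)
  for (lb in c("P3", "P4", "P6", "P8", "P9")) {
    pl <- g$planes[[lb]]
    s_frac <- pl$arc_length / max(g$cl$arc_length)
    an <- phantom_centerline_points(spec,
                                    s_frac * g$ph$truth$total_length_mm)$tangents[1, ]
    ang <- acos(min(1, abs(sum(pl$normal * an)))) * 180 / pi
    expect_lt(ang, 2)
  }
})

test_that("plane grids cover the lumen cross-section", {
  g <- utube_geo()
  for (pl in g$planes) {
    # sampled area approximates the true lumen cross-section pi R^2
    area <- nrow(pl$grid_points) * pl$area_element
    expect_lt(abs(area / (pi * 100) - 1), 0.2)
  }
})

test_that("prosthesis window excludes only planes within 2 cm above the valve", {
  g <- utube_geo()
  lm <- g$cl$landmarks
  valve <- lm[["P3"]] - 15  # P3 sits 15 mm above the valve
  flagged <- exclude_planes_near_prosthesis(g$planes, valve)
  expect_equal(flagged$P3$qc_flag, "EXCLUDED")
  expect_equal(flagged$P3$qc_reason, "prosthesis-window")
  further <- names(lm)[lm > valve + 20]
  for (lb in further) expect_equal(flagged[[lb]]$qc_flag, "INCLUDED")
  # no prosthesis: flags untouched
  same <- exclude_planes_near_prosthesis(g$planes, NULL)
  expect_identical(vapply(same, function(p) p$qc_flag, ""),
                   vapply(g$planes, function(p) p$qc_flag, ""))
})

test_that("largest connected component extraction keeps the vessel only", {
  ph <- small_straight()
  m <- ph$lumen_mask
  m[1, 1, 1] <- TRUE  # spurious island
  out <- largest_component(m)
  expect_false(out[1, 1, 1])
  expect_equal(sum(out), sum(ph$lumen_mask))
})
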