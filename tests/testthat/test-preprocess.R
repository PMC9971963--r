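test_that("eddy-current correction recovers injected polynomial offsets exactly", {
  coeffs <- list(c(0.05, 0.001, -0.002, 0.0005),
                 c(-0.03, 0.002, 0.001, -0.001),
                 c(0.02, -0.001, 0.0015, 0.002))
  ph <- generate_phantom(phantom_spec(geometry = "straight",
                                      segment_length = 60, spacing = 2.5,
                                      n_timeframes = 5,
                                      eddy_coeffs = coeffs))
  out <- correct_eddy_currents(ph$ds, ph$static_mask, order = 1)
  for (c in 1:3)
    expect_lt(max(abs(sweep(out$coeffs[[c]], 2, coeffs[[c]]))), 1e-9)
  sidx <- which(ph$static_mask)
  for (t in 1:5) {
    for (c in 1:3) {
      v <- out$ds$velocity[, , , t, c]
      expect_lt(abs(mean(v[sidx])), 1e-6)
    }
  }
})

test_that("eddy-current correction is the identity on offset-free data and handles order 0", {
  ph <- small_straight()
  out <- correct_eddy_currents(ph$ds, ph$static_mask, order = 1)
  expect_equal(out$ds$velocity, ph$ds$velocity, tolerance = 1e-12)
  # order 0 with a constant offset shifts every voxel by -c
  ds <- ph$ds
  ds$velocity[, , , , 1] <- ds$velocity[, , , , 1] + 0.07
  out0 <- correct_eddy_currents(ds, ph$static_mask, order = 0)
  expect_equal(out0$ds$velocity, ph$ds$velocity, tolerance = 1e-9)
  expect_error(correct_eddy_currents(ph$ds, ph$static_mask & FALSE),
               "empty")
})

test_that("unaliasing inverts injected wraps and is idempotent", {
  spec_args <- list(geometry = "straight", segment_length = 60,
                    spacing = 2.5, n_timeframes = 10, v_max = 1.8,
                    venc = 1.5)
  ph_w <- generate_phantom(do.call(phantom_spec,
                                   c(spec_args, wrap_injection = TRUE)))
  ph_0 <- generate_phantom(do.call(phantom_spec, spec_args))
  expect_gt(sum(lengths(ph_w$truth$wrapped_voxels)), 0)
  ua <- unalias_velocity(ph_w$ds)
  expect_true(ua$converged)
  # exactly the injected voxels, none else, recovered exactly
  expect_identical(ua$corrected_idx,
                   lapply(ph_w$truth$wrapped_voxels, sort))
  expect_equal(ua$ds$velocity, ph_0$ds$velocity, tolerance = 1e-12)
  # idempotent
  ua2 <- unalias_velocity(ua$ds)
  expect_identical(ua2$correction_count, c(0L, 0L, 0L))
  expect_identical(ua2$ds$velocity, ua$ds$velocity)
  # a field within +/-venc is never altered
  ua3 <- unalias_velocity(ph_0$ds)
  expect_identical(ua3$correction_count, c(0L, 0L, 0L))
})

test_that("PC-MRA is nonnegative, linear in magnitude, and peaks in the lumen", {
  ph <- small_straight()
  p <- compute_pcmra(ph$ds)
  expect_true(all(p >= 0))
  expect_true(ph$lumen_mask[which.max(p)])
  ds2 <- ph$ds
  ds2$magnitude <- 3 * ds2$magnitude
  expect_equal(compute_pcmra(ds2), 3 * p, tolerance = 1e-12)
  ds0 <- ph$ds
  ds0$velocity[] <- 0
  expect_true(all(compute_pcmra(ds0) == 0))
})

test_that("peak systole matches the waveform argmax, ties break low, windows wrap", {
  ph <- small_straight()
  pk <- find_peak_systole(ph$ds, ph$lumen_mask)
  expect_equal(pk$t_peak, ph$truth$t_peak)
  expect_equal(pk$window5, ((pk$t_peak - 3):(pk$t_peak + 1)) %% 10 + 1)
  # time-constant flow: tie -> lowest frame
  ds <- ph$ds
  for (t in 2:ds$n_timeframes) {
    ds$velocity[, , , t, ] <- ds$velocity[, , , 1, ]
  }
  expect_equal(find_peak_systole(ds, ph$lumen_mask)$t_peak, 1)
  # cyclic wrap when the peak sits at the first frame
  w <- steady_wave(20, peak = 1)
  w[2:20] <- seq(0.9, 0.2, length.out = 19)
  ph2 <- generate_phantom(phantom_spec(geometry = "straight",
                                       segment_length = 40, spacing = 2.5,
                                       n_timeframes = 20, waveform = w))
  pk2 <- find_peak_systole(ph2$ds, ph2$lumen_mask)
  expect_equal(pk2$t_peak, 1)
  expect_equal(pk2$window5, c(19, 20, 1, 2, 3))
  expect_equal(pk2$window3, c(20, 1, 2))
})

test_that("static-tissue identification selects quiet voxels outside the vessel", {
  ph <- small_straight()
  st <- identify_static_tissue(ph$ds, ph$lumen_mask)
  expect_gt(sum(st), 0)
  expect_false(any(st & ph$lumen_mask))
  # the bulk of the detected voxels lie in the truly static region
  expect_gt(mean(ph$static_mask[st]), 0.5)
})

test_that("planes crossing residual wraps are excluded, clean planes kept", {
  g <- utube_geo()
  ph <- g$ph
  planes <- g$planes
  flagged <- flag_failed_unaliasing(ph$ds, planes)
  expect_true(all(vapply(flagged, function(p) p$qc_flag, "") == "INCLUDED"))
  # corrupt the P4 cross-section with an uncorrected wrap-like jump
  ds_bad <- ph$ds
  o <- planes$P4$origin
  ci <- round(o / ds_bad$spacing) + 1
  ds_bad$velocity[ci[1], ci[2], ci[3], , 3] <-
    ds_bad$velocity[ci[1], ci[2], ci[3], , 3] - 2 * ds_bad$venc[3]
  flagged2 <- flag_failed_unaliasing(ds_bad, planes)
  expect_equal(flagged2$P4$qc_flag, "EXCLUDED")
  expect_equal(flagged2$P4$qc_reason, "aliasing-failure")
  expect_equal(flagged2$P6$qc_flag, "INCLUDED")
})
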