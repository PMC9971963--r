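# Pathline tracing through the time-resolved velocity field and the
# semi-quantitative helix/vortex grading of ascending-aortic flow patterns.

#' Interpolate the velocity field in space and time
#'
#' Trilinear in space, linear in time, cyclic over the cardiac cycle.
#'
#' @param ds a [velocity_field()]
#' @param pts n x 3 world points, mm
#' @param t_ms time within the cycle, ms (frame 1 is t = 0)
#' @return n x 3 velocity matrix, m/s
#' @export
interp_velocity <- function(ds, pts, t_ms) {
  nt <- ds$n_timeframes
  f <- (t_ms / ds$dt) %% nt          # 0-based continuous frame
  f0 <- floor(f)
  fr <- f - f0
  i0 <- as.integer(f0) %% nt + 1L
  i1 <- i0 %% nt + 1L
  out <- matrix(0, nrow(pts), 3)
  for (c in 1:3) {
    v0 <- interp3(ds$velocity[, , , i0, c], pts, ds$spacing)
    v1 <- interp3(ds$velocity[, , , i1, c], pts, ds$spacing)
    out[, c] <- (1 - fr) * v0 + fr * v1
  }
  out
}

#' Trace pathlines through the velocity field
#'
#' 4th-order Runge-Kutta integration through the space- and time-interpolated
#' field from seed release at `t0_ms` until the particle leaves the mask or
#' the cardiac cycle ends. Steps whose displacement would exceed one voxel
#' are re-taken with proportionally smaller substeps. Velocities in m/s equal
#' mm/ms numerically, so positions (mm) integrate directly against ms.
#'
#' @param ds a [velocity_field()]
#' @param seeds n x 3 seed points, mm
#' @param t0_ms release time, ms
#' @param dt_int_ms integration step, ms (default 2)
#' @param mask 3D logical array bounding the traced domain
#' @param max_time_ms tracing horizon (default one cycle)
#' @return list of pathlines; each is a list with `times` (ms), `positions`
#'   (k x 3, mm) and `speeds` (m/s). Seeds released outside the mask yield
#'   empty pathlines with a warning.
#' @export
trace_pathlines <- function(ds, seeds, t0_ms = 0, dt_int_ms = 2, mask,
                            max_time_ms = NULL) {
  cycle <- ds$n_timeframes * ds$dt
  if (is.null(max_time_ms)) max_time_ms <- cycle
  maskd <- array(as.numeric(mask), dim(mask))
  lim <- (dim(mask) - 1) * ds$spacing
  inside <- function(p) {
    interp3(maskd, p, ds$spacing) >= 0.5 &
      p[, 1] > 0 & p[, 1] < lim[1] & p[, 2] > 0 & p[, 2] < lim[2] &
      p[, 3] > 0 & p[, 3] < lim[3]
  }
  n <- nrow(seeds)
  ok0 <- inside(seeds)
  if (!all(ok0)) warning(sum(!ok0), " seed(s) outside the mask; empty pathlines")
  nstep <- ceiling(max_time_ms / dt_int_ms)
  vmin <- min(ds$spacing)
  pos <- vector("list", n)
  for (i in seq_len(n)) pos[[i]] <- if (ok0[i]) seeds[i, , drop = FALSE] else
    matrix(0, 0, 3)
  times <- vector("list", n)
  for (i in seq_len(n)) times[[i]] <- if (ok0[i]) t0_ms else numeric(0)
  active <- ok0
  p <- seeds
  t <- t0_ms
  rk4 <- function(p, t, h) {
    k1 <- interp_velocity(ds, p, t)
    k2 <- interp_velocity(ds, p + h / 2 * k1, t + h / 2)
    k3 <- interp_velocity(ds, p + h / 2 * k2, t + h / 2)
    k4 <- interp_velocity(ds, p + h * k3, t + h)
    (k1 + 2 * k2 + 2 * k3 + k4) / 6
  }
  for (s in seq_len(nstep)) {
    if (!any(active)) break
    ia <- which(active)
    pa <- p[ia, , drop = FALSE]
    vbar <- rk4(pa, t, dt_int_ms)
    disp <- vbar * dt_int_ms
    dmax <- apply(abs(disp), 1, max)
    too_big <- dmax > vmin
    if (any(too_big)) {
      # substep rejected moves so each substep stays below one voxel
      for (j in which(too_big)) {
        nsub <- ceiling(dmax[j] / vmin)
        pj <- pa[j, , drop = FALSE]
        tj <- t
        h <- dt_int_ms / nsub
        for (u in seq_len(nsub)) {
          pj <- pj + rk4(pj, tj, h) * h
          tj <- tj + h
        }
        disp[j, ] <- pj - pa[j, , drop = FALSE]
      }
    }
    pnew <- pa + disp
    alive <- inside(pnew)
    for (k in seq_along(ia)) {
      i <- ia[k]
      if (alive[k]) {
        pos[[i]] <- rbind(pos[[i]], pnew[k, ])
        times[[i]] <- c(times[[i]], t + dt_int_ms)
        p[i, ] <- pnew[k, ]
      } else {
        active[i] <- FALSE
      }
    }
    t <- t + dt_int_ms
  }
  lapply(seq_len(n), function(i) {
    pp <- pos[[i]]
    sp <- if (nrow(pp) > 1)
      c(sqrt(rowSums(diff(pp)^2)) / diff(times[[i]]), NA) else
        rep(NA_real_, nrow(pp))
    structure(list(times = times[[i]], positions = pp, speeds = sp),
              class = "pathline")
  })
}

# rotation-minimizing frames (normal, binormal) along a centerline
centerline_frames <- function(cl) {
  n <- nrow(cl$points)
  t1 <- cl$tangents[1, ]
  ref <- if (abs(t1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  nv <- ref - sum(ref * t1) * t1
  nv <- nv / sqrt(sum(nv^2))
  N <- matrix(0, n, 3)
  N[1, ] <- nv
  for (i in 2:n) {
    ti <- cl$tangents[i, ]
    v <- N[i - 1, ] - sum(N[i - 1, ] * ti) * ti
    nn <- sqrt(sum(v^2))
    N[i, ] <- if (nn > 1e-9) v / nn else N[i - 1, ]
  }
  B <- cross_rows(cl$tangents, N)
  list(normal = N, binormal = B)
}

#' Cumulative rotation of a pathline about the centerline
#'
#' Each pathline position is projected into the plane normal to the local
#' centerline tangent (using rotation-minimizing frames so the angular
#' coordinate is continuous along the vessel); the absolute cumulative
#' unwrapped change of the angle about the centerline is returned in degrees.
#'
#' @param pl a `pathline`
#' @param cl a `centerline`
#' @param s_range optional arc-length window `c(lo, hi)` (mm) restricting the
#'   measurement, e.g. the ascending aorta
#' @return rotation, degrees (absolute value)
#' @export
rotation_angle <- function(pl, cl, s_range = NULL) {
  pp <- pl$positions
  if (nrow(pp) < 3L) stop("pathline has fewer than 3 samples")
  ni <- nearest_point_index(pp, cl$points)
  if (!is.null(s_range)) {
    keep <- cl$arc_length[ni] >= s_range[1] & cl$arc_length[ni] <= s_range[2]
    if (sum(keep) < 3L) return(0)
    pp <- pp[keep, , drop = FALSE]
    ni <- ni[keep]
  }
  fr <- centerline_frames(cl)
  d <- pp - cl$points[ni, , drop = FALSE]
  a <- rowSums(d * fr$normal[ni, , drop = FALSE])
  b <- rowSums(d * fr$binormal[ni, , drop = FALSE])
  theta <- atan2(b, a)
  dth <- diff(theta)
  dth <- (dth + pi) %% (2 * pi) - pi
  abs(sum(dth)) * 180 / pi
}

#' Classify a pathline as vortical flow
#'
#' Vortical flow is revolving motion about a local centre whose direction
#' deviates by more than 90 degrees from the main (centerline-parallel)
#' physiological flow direction — as opposed to helical flow, which corkscrews
#' about an axis parallel to the bulk motion. The pathline qualifies when
#' (a) it sweeps at least 180 degrees about the centroid of its own
#' trajectory (in the plane of its two leading principal axes) and (b) its
#' mean velocity direction makes an angle above 90 degrees with the local
#' centerline tangent.
#'
#' @param pl a `pathline`
#' @param cl a `centerline`
#' @return logical
#' @export
classify_vortex <- function(pl, cl) {
  pp <- pl$positions
  if (nrow(pp) < 4L) return(FALSE)
  ni <- nearest_point_index(pp, cl$points)
  tg <- normalize_rows(matrix(colMeans(cl$tangents[ni, , drop = FALSE]), 1))
  vel <- diff(pp) / diff(pl$times)
  mdir <- colMeans(normalize_rows(vel))
  nm <- sqrt(sum(mdir^2))
  if (nm < 1e-9) return(FALSE)
  deviates <- sum(mdir / nm * tg) < 0   # angle to tangent > 90 degrees
  if (!deviates) return(FALSE)
  ctr <- colMeans(pp)
  X <- sweep(pp, 2, ctr)
  ev <- eigen(crossprod(X), symmetric = TRUE)$vectors
  a <- X %*% ev[, 1]; b <- X %*% ev[, 2]
  theta <- atan2(b, a)
  dth <- diff(theta)
  dth <- (dth + pi) %% (2 * pi) - pi
  abs(sum(dth)) * 180 / pi >= 180
}

#' Semi-quantitative flow-pattern grade
#'
#' Grading scale: 0 — no qualifying rotation (below 90 degrees); 1 — flow
#' rotations below 360 degrees; 2 — rotations above 360 degrees; 3 — above
#' 360 degrees with increased flow (ascending peak velocity above
#' `v_thresh`). The 90-degree presence floor and the 1.5 m/s "increased
#' flow" threshold are configurable conventions.
#'
#' @param max_rotation_deg maximum pathline rotation, degrees
#' @param peak_velocity ascending peak velocity, m/s
#' @param v_thresh increased-flow threshold, m/s (default 1.5)
#' @return integer grade 0..3
#' @export
grade_flow_pattern <- function(max_rotation_deg, peak_velocity,
                               v_thresh = 1.5) {
  if (max_rotation_deg < 90) 0L
  else if (max_rotation_deg < 360) 1L
  else if (peak_velocity <= v_thresh) 2L
  else 3L
}

#' Assess helix/vortex flow patterns in the ascending aorta
#'
#' Seeds a uniform grid across the proximal (P2) plane, releases pathlines at
#' every systolic frame, measures each pathline's rotation about the
#' centerline within the ascending aorta, classifies vortical trajectories,
#' and grades both patterns.
#'
#' @param ds unaliased [velocity_field()]
#' @param cl `centerline` with landmarks
#' @param plane_p2 the P2 `quant_plane` (seed surface)
#' @param aorta 3D logical mask
#' @param peak result of [find_peak_systole()]
#' @param ascending_peak_velocity m/s, from [peak_velocity_mip()]
#' @param v_thresh increased-flow threshold, m/s
#' @param n_seeds target seed count (default 100)
#' @param dt_int_ms integration step, ms
#' @return a `flow_grade`: `helix_grade`, `vortex_grade`, `max_rotation_deg`,
#'   `n_pathlines`, `v_thresh`
#' @export
assess_flow_patterns <- function(ds, cl, plane_p2, aorta, peak,
                                 ascending_peak_velocity, v_thresh = 1.5,
                                 n_seeds = 100, dt_int_ms = 2) {
  gp <- plane_p2$grid_points
  stride <- max(1L, floor(nrow(gp) / n_seeds))
  seeds <- gp[seq(1L, nrow(gp), by = stride), , drop = FALSE]
  s_asc <- c(cl$landmarks[["P2"]], cl$landmarks[["P5"]])
  rot <- numeric(0)
  any_vortex_rot <- numeric(0)
  n_valid <- 0L
  for (t0 in peak$window5) {
    pls <- trace_pathlines(ds, seeds, t0_ms = (t0 - 1) * ds$dt,
                           dt_int_ms = dt_int_ms, mask = aorta)
    for (pl in pls) {
      if (nrow(pl$positions) < 3L) next
      n_valid <- n_valid + 1L
      r <- rotation_angle(pl, cl, s_range = s_asc)
      if (classify_vortex(pl, cl)) any_vortex_rot <- c(any_vortex_rot, r)
      else rot <- c(rot, r)
    }
  }
  if (n_valid == 0L) stop("no valid pathlines")
  max_rot <- if (length(rot)) max(rot) else 0
  max_vrot <- if (length(any_vortex_rot)) max(any_vortex_rot) else 0
  structure(list(
    helix_grade = grade_flow_pattern(max_rot, ascending_peak_velocity,
                                     v_thresh),
    vortex_grade = grade_flow_pattern(max_vrot, ascending_peak_velocity,
                                      v_thresh),
    max_rotation_deg = max(max_rot, max_vrot),
    n_pathlines = n_valid, v_thresh = v_thresh),
    class = "flow_grade")
}
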