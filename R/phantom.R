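# Digital aorta phantom: a thoracic-aorta-like curved (or straight) tube with
# pulsatile Poiseuille flow, optional core swirl, jets, velocity noise,
# background phase offsets and injectable venc wraps — with analytic ground
# truth emitted alongside every dataset.

#' Specification of a digital 4D flow aorta phantom
#'
#' Defaults mirror a clinical thoracic-aorta 4D flow acquisition: isotropic
#' 2.5 mm voxels (approximating a 2.7 x 2.3 x 2.6 mm protocol), 40.8 ms
#' temporal resolution, venc 1.5 m/s, 20 cardiac timeframes.
#'
#' @param geometry `"straight"` (tube along z) or `"u_tube"` (ascending leg,
#'   semicircular arch, descending leg in the x-z plane)
#' @param radius lumen radius R, mm
#' @param centerline_radius arch radius of curvature R_c, mm (u_tube only;
#'   must exceed `radius`)
#' @param segment_length straight-leg length, mm (u_tube) or tube length
#'   (straight)
#' @param spacing voxel spacing, mm (scalar or length 3)
#' @param dt temporal resolution, ms
#' @param n_timeframes cardiac timeframes per cycle
#' @param venc velocity encoding, m/s (scalar or length 3)
#' @param v_max centerline peak velocity at the waveform maximum, m/s
#' @param waveform either `NULL` (default raised-Gaussian systolic pulse with
#'   diastolic baseline 0.15 and width 2.5 frames) or a numeric vector of
#'   length `n_timeframes` in `[0, 1]` with a unique maximum
#' @param peak_frame 1-based frame of the default waveform's maximum
#' @param swirl_deg_per_mm helical rotation rate: degrees of rotation about
#'   the centerline per mm of axial travel (rigid-body core, no-slip rolloff
#'   inherited from the Poiseuille axial profile)
#' @param swirl_extent arc-length range `c(s0, s1)` (mm) over which swirl is
#'   active; `NULL` = whole centerline
#' @param jet optional `list(s_mm =, sigma_mm =, factor =)`: Gaussian
#'   velocity multiplier bump along the centerline (a stenotic jet)
#' @param noise_sd additive Gaussian velocity noise SD, m/s
#' @param eddy_coeffs optional list of 3 numeric vectors (one per velocity
#'   component) of polynomial background-phase coefficients in the basis of
#'   [eddy_design_matrix()] (centered world mm coordinates), m/s
#' @param wrap_injection wrap out-of-venc components into `[-venc, venc]`
#'   (recording the affected voxels in the truth)
#' @param allow_extreme_speeds permit `|v| > 3 venc` (ambiguous double wraps)
#' @param seed integer RNG seed; the phantom is a pure function of the spec
#' @return a `phantom_spec` list
#' @export
phantom_spec <- function(geometry = c("u_tube", "straight"),
                         radius = 10, centerline_radius = 35,
                         segment_length = 60,
                         spacing = 2.5, dt = 40.8, n_timeframes = 20,
                         venc = 1.5, v_max = 1.0,
                         waveform = NULL, peak_frame = 5,
                         swirl_deg_per_mm = 0, swirl_extent = NULL,
                         jet = NULL, noise_sd = 0, eddy_coeffs = NULL,
                         wrap_injection = FALSE,
                         allow_extreme_speeds = FALSE, seed = 1L) {
  geometry <- match.arg(geometry)
  spacing <- rep_len(as.numeric(spacing), 3L)
  venc <- rep_len(as.numeric(venc), 3L)
  if (geometry == "u_tube" && radius >= centerline_radius)
    stop("lumen radius must be smaller than the centerline radius")
  if (!is.null(waveform)) {
    if (length(waveform) != n_timeframes)
      stop("waveform length must equal n_timeframes")
    if (sum(waveform == max(waveform)) != 1L)
      stop("waveform must have a unique maximum")
    if (any(waveform < 0 | waveform > 1)) stop("waveform must lie in [0, 1]")
  }
  structure(list(
    geometry = geometry, radius = radius,
    centerline_radius = centerline_radius,
    segment_length = segment_length, spacing = spacing, dt = dt,
    n_timeframes = n_timeframes, venc = venc, v_max = v_max,
    waveform = waveform, peak_frame = peak_frame,
    swirl_deg_per_mm = swirl_deg_per_mm, swirl_extent = swirl_extent,
    jet = jet, noise_sd = noise_sd, eddy_coeffs = eddy_coeffs,
    wrap_injection = wrap_injection,
    allow_extreme_speeds = allow_extreme_speeds, seed = as.integer(seed)),
    class = "phantom_spec")
}

phantom_waveform <- function(spec) {
  if (!is.null(spec$waveform)) return(spec$waveform)
  f <- seq_len(spec$n_timeframes)
  base <- 0.15
  base + (1 - base) * exp(-0.5 * ((f - spec$peak_frame) / 2.5)^2)
}

# Closed-form nearest-centerline geometry for every query point:
# returns arc length s, radial distance r, unit tangent, unit radial vector.
phantom_centerline_geometry <- function(spec, pts) {
  R <- spec$radius
  if (spec$geometry == "straight") {
    L <- spec$segment_length
    x0 <- R + 6; y0 <- R + 6
    s <- pmin(pmax(pts[, 3], 0), L)
    dx <- pts[, 1] - x0; dy <- pts[, 2] - y0
    r <- sqrt(dx^2 + dy^2 + (pts[, 3] - s)^2)
    tang <- matrix(rep(c(0, 0, 1), each = nrow(pts)), ncol = 3)
    rad <- normalize_rows(cbind(dx, dy, 0))
    list(s = s, r = r, tangent = tang, radial = rad, total_length = L)
  } else {
    Rc <- spec$centerline_radius; L <- spec$segment_length
    x0 <- R + 6; y0 <- R + 6
    cz <- L                      # legs run z in [0, L]; arch centre at z = L
    cx <- x0 + Rc
    total <- 2 * L + pi * Rc
    x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
    # candidate 1: inlet (ascending) leg at x = x0, z in [0, L], tangent +z
    s1 <- pmin(pmax(z, 0), L)
    d1 <- sqrt((x - x0)^2 + (y - y0)^2 + (z - s1)^2)
    # candidate 2: arch, semicircle in plane y = y0, angle phi in [0, pi]
    dxc <- x - cx; dzc <- z - cz
    phi <- atan2(dzc, dxc)
    phi <- pmin(pmax(phi, 0), pi)
    ax <- cx + Rc * cos(phi); az <- cz + Rc * sin(phi)
    d2 <- sqrt((x - ax)^2 + (y - y0)^2 + (z - az)^2)
    s2 <- L + (pi - phi) * Rc
    # candidate 3: outlet (descending) leg at x = x0 + 2 Rc, tangent -z
    x1 <- x0 + 2 * Rc
    zz <- pmin(pmax(z, 0), L)
    d3 <- sqrt((x - x1)^2 + (y - y0)^2 + (z - zz)^2)
    s3 <- L + pi * Rc + (L - zz)
    dmat <- cbind(d1, d2, d3)
    best <- max.col(-dmat, ties.method = "first")
    n <- nrow(pts)
    s <- numeric(n); r <- numeric(n)
    tang <- matrix(0, n, 3); cpt <- matrix(0, n, 3)
    i1 <- best == 1L; i2 <- best == 2L; i3 <- best == 3L
    s[i1] <- s1[i1]; r[i1] <- d1[i1]
    tang[i1, ] <- rep(c(0, 0, 1), each = sum(i1))
    cpt[i1, ] <- cbind(rep(x0, sum(i1)), rep(y0, sum(i1)), s1[i1])
    s[i2] <- s2[i2]; r[i2] <- d2[i2]
    tang[i2, ] <- cbind(sin(phi[i2]), 0, -cos(phi[i2]))
    cpt[i2, ] <- cbind(ax[i2], rep(y0, sum(i2)), az[i2])
    s[i3] <- s3[i3]; r[i3] <- d3[i3]
    tang[i3, ] <- rep(c(0, 0, -1), each = sum(i3))
    cpt[i3, ] <- cbind(rep(x1, sum(i3)), rep(y0, sum(i3)), zz[i3])
    rad <- normalize_rows(pts - cpt)
    list(s = s, r = r, tangent = tang, radial = rad, total_length = total)
  }
}

phantom_grid <- function(spec) {
  R <- spec$radius; sp <- spec$spacing
  margin <- 6
  if (spec$geometry == "straight") {
    ext <- c(2 * (R + margin), 2 * (R + margin), spec$segment_length)
  } else {
    Rc <- spec$centerline_radius
    ext <- c(2 * R + 2 * margin + 2 * Rc, 2 * (R + margin),
             spec$segment_length + Rc + R + margin)
  }
  dims <- pmax(ceiling(ext / sp) + 1L, 4L)
  dims
}

#' Analytic arc-length fractions of the nine quantification landmarks
#'
#' For the U-tube, P5 and P7 sit exactly at the leg/arch junctions so the
#' ascending/arch/descending zones coincide with the geometric segments; the
#' remaining landmarks are spread over the legs. For the straight tube the
#' landmarks are evenly spaced.
#'
#' @param spec a [phantom_spec()]
#' @return named numeric vector of fractions for P1..P9
#' @export
phantom_landmark_fractions <- function(spec) {
  if (spec$geometry == "u_tube") {
    L <- spec$segment_length; Rc <- spec$centerline_radius
    total <- 2 * L + pi * Rc
    f5 <- L / total; f7 <- (L + pi * Rc) / total
    f <- c(P1 = 0.02, P2 = 0.05,
           P3 = 0.05 + 0.25 * (f5 - 0.05), P4 = 0.05 + 0.6 * (f5 - 0.05),
           P5 = f5, P6 = (f5 + f7) / 2, P7 = f7,
           P8 = f7 + 0.45 * (0.97 - f7), P9 = 0.97)
  } else {
    f <- stats::setNames(seq(0.02, 0.97, length.out = 9), paste0("P", 1:9))
  }
  f
}

#' Generate a digital 4D flow aorta phantom with ground truth
#'
#' The axial velocity profile is Poiseuille,
#' `v(r, t) = v_max w(t) (1 - r^2/R^2)` along the local centerline tangent;
#' swirl adds an azimuthal component `v_theta = alpha r v_axial` (alpha in
#' rad/mm), which makes every pathline rotate by exactly `alpha` radians per
#' mm of axial travel while preserving no-slip. The analytic field is
#' divergence-free, so cross-plane flux comparisons are meaningful. Noise,
#' background phase offsets and venc wrapping are applied in that order,
#' after the truth has been recorded.
#'
#' @param spec a [phantom_spec()]
#' @return list with elements `ds` (a [velocity_field()]), `lumen_mask`,
#'   `static_mask` (3D logical arrays) and `truth` (analytic ground truth:
#'   per-frame flux in mL/s, stroke volume in mL, peak-systole frame, wall
#'   shear stress magnitude at peak systole for the default viscosity,
#'   grid-evaluated zone peak speeds, swirl rotation per transit, wrapped
#'   voxel indices, injected background coefficients, analytic centerline)
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  dims <- phantom_grid(spec)
  sp <- spec$spacing
  nt <- spec$n_timeframes
  R <- spec$radius
  w <- phantom_waveform(spec)
  t_peak <- which.max(w)

  # voxel-centre world coordinates
  gx <- (seq_len(dims[1]) - 1) * sp[1]
  gy <- (seq_len(dims[2]) - 1) * sp[2]
  gz <- (seq_len(dims[3]) - 1) * sp[3]
  pts <- cbind(rep(gx, times = dims[2] * dims[3]),
               rep(rep(gy, each = dims[1]), times = dims[3]),
               rep(gz, each = dims[1] * dims[2]))
  geo <- phantom_centerline_geometry(spec, pts)
  lumen <- geo$r <= R
  static <- geo$r > R + 5
  lumen_mask <- array(lumen, dims)
  static_mask <- array(static, dims)

  # spatial (time-independent) velocity pattern at w = 1, m/s
  prof <- ifelse(lumen, spec$v_max * (1 - (geo$r / R)^2), 0)
  if (!is.null(spec$jet)) {
    j <- spec$jet
    prof <- prof * (1 + (j$factor - 1) * exp(-0.5 * ((geo$s - j$s_mm) / j$sigma_mm)^2))
  }
  vpat <- geo$tangent * prof
  if (spec$swirl_deg_per_mm != 0) {
    alpha <- spec$swirl_deg_per_mm * pi / 180  # rad per mm of axial travel
    ext <- spec$swirl_extent %||% c(0, geo$total_length)
    on <- lumen & geo$s >= ext[1] & geo$s <= ext[2]
    etheta <- cross_rows(geo$tangent, geo$radial)
    vpat <- vpat + etheta * ifelse(on, alpha * geo$r * prof, 0)
  }
  spd_pat <- sqrt(rowSums(vpat^2))
  max_speed <- max(spd_pat) * max(w)
  if (max_speed > 3 * min(spec$venc) && !spec$allow_extreme_speeds)
    stop("peak speed ", round(max_speed, 2), " m/s exceeds 3*venc; ",
         "double wraps would be ambiguous (set allow_extreme_speeds = TRUE to override)")

  nvox <- prod(dims)
  vel <- array(0, c(dims, nt, 3L))
  for (t in seq_len(nt)) {
    for (c in 1:3) {
      vel[, , , t, c] <- array(vpat[, c] * w[t], dims)
    }
  }

  # truth (before artifacts)
  frac <- phantom_landmark_fractions(spec)
  s_lm <- frac * geo$total_length
  zone_of_s <- function(s) {
    z <- rep(NA_character_, length(s))
    z[s >= s_lm["P2"] & s < s_lm["P5"]] <- "ascending"
    z[s >= s_lm["P5"] & s < s_lm["P7"]] <- "arch"
    z[s >= s_lm["P7"] & s <= s_lm["P9"]] <- "descending"
    z
  }
  vzone <- zone_of_s(geo$s)
  win3 <- cyclic_window(t_peak, 3L, nt)
  zone_peak <- vapply(c("ascending", "arch", "descending"), function(zn) {
    sel <- lumen & !is.na(vzone) & vzone == zn
    if (!any(sel)) return(NA_real_)
    max(spd_pat[sel]) * max(w[win3])
  }, numeric(1))
  mu_default <- 3.2e-3
  alpha_rad <- spec$swirl_deg_per_mm * pi / 180
  wss_peak <- 2 * mu_default * spec$v_max * max(w) / (R / 1000) *
    sqrt(1 + (alpha_rad * R)^2)
  flux <- 0.5 * spec$v_max * w * pi * R^2        # mm^3/ms == mL/s
  s_grid <- seq(0, geo$total_length, by = 1)
  cl_geo <- phantom_centerline_points(spec, s_grid)
  ext <- spec$swirl_extent %||% c(0, geo$total_length)
  truth <- list(
    waveform = w, t_peak = t_peak,
    flux_ml_per_s = flux,
    stroke_volume_ml = sum(flux * spec$dt) / 1000,
    wss_peak_nm2 = wss_peak, viscosity_used = mu_default,
    peak_speed = max(spd_pat) * max(w),
    zone_peak_speed = zone_peak,
    swirl_rotation_deg = spec$swirl_deg_per_mm * (ext[2] - ext[1]),
    landmark_fractions = frac, landmark_arc_mm = s_lm,
    total_length_mm = geo$total_length,
    centerline_points = cl_geo$points, centerline_tangents = cl_geo$tangents,
    eddy_coeffs = spec$eddy_coeffs,
    wrapped_voxels = NULL)

  # artifacts: noise -> background phase -> venc wrap
  if (spec$noise_sd > 0)
    vel <- vel + array(stats::rnorm(length(vel), 0, spec$noise_sd), dim(vel))
  if (!is.null(spec$eddy_coeffs)) {
    X <- eddy_design_matrix(pts, dims, sp,
                            order = eddy_order_of(spec$eddy_coeffs))
    for (c in 1:3) {
      off <- array(as.vector(X %*% spec$eddy_coeffs[[c]]), dims)
      for (t in seq_len(nt)) vel[, , , t, c] <- vel[, , , t, c] + off
    }
  }
  mag <- array(rep(ifelse(lumen, 1, 0.2), times = nt), c(dims, nt))
  ds <- velocity_field(vel, mag, spacing = sp, dt = spec$dt, venc = spec$venc)
  if (spec$wrap_injection) {
    wrapped <- inject_wraps(ds, spec$venc)
    ds <- wrapped$ds
    truth$wrapped_voxels <- wrapped$wrapped
  }
  list(ds = ds, lumen_mask = lumen_mask, static_mask = static_mask,
       truth = truth)
}

#' Analytic centerline points and tangents of a phantom at given arc lengths
#' @param spec a [phantom_spec()]
#' @param s_mm arc-length positions, mm
#' @return list with `points` (n x 3, mm) and `tangents` (n x 3, unit)
#' @export
phantom_centerline_points <- function(spec, s_mm) {
  R <- spec$radius
  x0 <- R + 6; y0 <- R + 6
  if (spec$geometry == "straight") {
    pts <- cbind(x0, y0, s_mm)
    tg <- matrix(rep(c(0, 0, 1), each = length(s_mm)), ncol = 3)
    return(list(points = pts, tangents = tg))
  }
  Rc <- spec$centerline_radius; L <- spec$segment_length
  cx <- x0 + Rc; cz <- L
  pts <- matrix(0, length(s_mm), 3); tg <- matrix(0, length(s_mm), 3)
  for (i in seq_along(s_mm)) {
    s <- s_mm[i]
    if (s <= L) {
      pts[i, ] <- c(x0, y0, s); tg[i, ] <- c(0, 0, 1)
    } else if (s <= L + pi * Rc) {
      phi <- pi - (s - L) / Rc
      pts[i, ] <- c(cx + Rc * cos(phi), y0, cz + Rc * sin(phi))
      tg[i, ] <- c(sin(phi), 0, -cos(phi))
    } else {
      z <- L - (s - L - pi * Rc)
      pts[i, ] <- c(x0 + 2 * Rc, y0, z); tg[i, ] <- c(0, 0, -1)
    }
  }
  list(points = pts, tangents = tg)
}

#' Wrap out-of-venc velocity components into the encodable range
#'
#' Each component value outside `[-venc, venc]` is shifted by the multiple of
#' `2 venc` that brings it into range, emulating phase aliasing; the affected
#' 5-D array indices are recorded per component.
#'
#' @param ds a [velocity_field()]
#' @param venc velocity encoding, m/s (scalar or length 3)
#' @return list with `ds` (wrapped dataset) and `wrapped` (list of 3 integer
#'   vectors of linear indices into the per-component 4-D array)
#' @export
inject_wraps <- function(ds, venc = ds$venc) {
  venc <- rep_len(as.numeric(venc), 3L)
  wrapped <- vector("list", 3L)
  for (c in 1:3) {
    vc <- ds$velocity[, , , , c]
    out <- which(abs(vc) > venc[c])
    # shift by the wrap multiple that lands inside [-venc, venc]
    k <- ceiling((abs(vc) - venc[c]) / (2 * venc[c])) * sign(vc)
    vc[out] <- vc[out] - 2 * venc[c] * k[out]
    ds$velocity[, , , , c] <- vc
    wrapped[[c]] <- out
  }
  list(ds = ds, wrapped = wrapped)
}

eddy_order_of <- function(coeffs) {
  n <- length(coeffs[[1]])
  if (n == 1) 0L else if (n == 4) 1L else if (n == 10) 2L
  else stop("eddy coefficient vectors must have length 1, 4 or 10")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
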