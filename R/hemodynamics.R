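# Quantification: per-plane flow volumes, systolic 3D wall shear stress
# (per vertex and per atlas region), and zone peak velocities by
# maximum-intensity projection over the systolic window.

#' Through-plane velocity samples of one timeframe
#'
#' Trilinearly samples the three velocity components at a plane's in-plane
#' grid points and projects onto the plane normal.
#'
#' @param ds a [velocity_field()]
#' @param plane a `quant_plane`
#' @param t timeframe (1-based)
#' @return numeric vector, m/s (positive = along the plane normal)
#' @export
through_plane_velocity <- function(ds, plane, t) {
  p <- plane$grid_points
  vx <- interp3(ds$velocity[, , , t, 1], p, ds$spacing)
  vy <- interp3(ds$velocity[, , , t, 2], p, ds$spacing)
  vz <- interp3(ds$velocity[, , , t, 3], p, ds$spacing)
  vx * plane$normal[1] + vy * plane$normal[2] + vz * plane$normal[3]
}

#' Forward and net flow volume through a quantification plane
#'
#' Instantaneous flow is the in-plane sum of through-plane velocity times
#' area element (velocity in m/s equals mm/ms numerically, so
#' `v * dA` is mm^3/ms, i.e. mL/s); volumes integrate over one cardiac cycle
#' with the rectangle rule at step `dt` and are reported in mL. Forward flow
#' counts only positive (normal-direction) samples.
#'
#' @param ds a [velocity_field()]
#' @param plane a `quant_plane` (must be INCLUDED, else result is flagged)
#' @return list: `plane_label`, `forward_volume_ml`, `net_volume_ml`,
#'   `flux_ml_per_s` (per-frame net flow), `qc_flag`
#' @export
flow_volumes <- function(ds, plane) {
  if (plane$qc_flag == "EXCLUDED") {
    return(list(plane_label = plane$label, forward_volume_ml = NA_real_,
                net_volume_ml = NA_real_, flux_ml_per_s = NULL,
                qc_flag = "EXCLUDED", qc_reason = plane$qc_reason))
  }
  nt <- ds$n_timeframes
  fw <- 0; net <- 0
  flux <- numeric(nt)
  for (t in seq_len(nt)) {
    vperp <- through_plane_velocity(ds, plane, t)
    flux[t] <- sum(vperp) * plane$area_element           # mm^3/ms = mL/s
    fw <- fw + sum(pmax(vperp, 0)) * plane$area_element * ds$dt
    net <- net + flux[t] * ds$dt
  }
  list(plane_label = plane$label,
       forward_volume_ml = fw / 1000, net_volume_ml = net / 1000,
       flux_ml_per_s = flux, qc_flag = "INCLUDED", qc_reason = NA_character_)
}

#' Wall shear stress vectors at one timeframe
#'
#' Per vertex, velocity is sampled at two distances along the inward normal;
#' a quadratic through the wall no-slip point (0, 0) and the two samples is
#' fit per component, its wall derivative is projected onto the wall-tangent
#' plane, and the WSS vector is viscosity times that tangential gradient.
#' Vertices whose sample points leave the velocity grid are flagged invalid.
#'
#' @param ds a [velocity_field()]
#' @param mesh a `wall_mesh`
#' @param viscosity dynamic viscosity, Pa s (default 3.2e-3 for blood)
#' @param t timeframe
#' @param d_mm the two sampling distances, mm; default 0.5 and 1.0 times the
#'   mean voxel pitch
#' @return list: `vectors` (n x 3, N/m^2), `valid` (logical)
#' @export
wss_vector_field <- function(ds, mesh, viscosity = 3.2e-3, t,
                             d_mm = NULL) {
  if (is.null(d_mm)) d_mm <- mean(ds$spacing) * c(0.5, 1.0)
  stopifnot(length(d_mm) == 2L, d_mm[1] > 0, d_mm[2] > d_mm[1])
  v <- mesh$vertices
  n <- mesh$inward_normals
  p1 <- v + d_mm[1] * n
  p2 <- v + d_mm[2] * n
  dims <- dim(ds$velocity)[1:3]
  lim <- (dims - 1) * ds$spacing
  inb <- function(p) p[, 1] >= 0 & p[, 1] <= lim[1] &
    p[, 2] >= 0 & p[, 2] <= lim[2] & p[, 3] >= 0 & p[, 3] <= lim[3]
  valid <- inb(p1) & inb(p2)
  d1 <- d_mm[1]; d2 <- d_mm[2]
  grad <- matrix(0, nrow(v), 3)
  for (c in 1:3) {
    arr <- ds$velocity[, , , t, c]
    v1 <- interp3(arr, p1, ds$spacing)
    v2 <- interp3(arr, p2, ds$spacing)
    # v(d) = a d + b d^2 through (0,0): wall-gradient a, per mm
    grad[, c] <- (v1 * d2^2 - v2 * d1^2) / (d1 * d2 * (d2 - d1))
  }
  # project out the wall-normal part, keep the tangential gradient
  gn <- rowSums(grad * n)
  gt <- grad - n * gn
  # (m/s per mm) * 1000 = 1/s; times Pa s = N/m^2
  list(vectors = gt * 1000 * viscosity, valid = valid)
}

#' Systolic wall shear stress map
#'
#' WSS vectors of the five timeframes centred on peak systole are averaged
#' component-wise, then the norm is taken (vector mean first, norm second),
#' yielding per-vertex systolic WSS vectors and magnitudes.
#'
#' @param ds a [velocity_field()]
#' @param mesh a `wall_mesh`
#' @param viscosity dynamic viscosity, Pa s
#' @param peak result of [find_peak_systole()]
#' @param d_mm sampling distances passed to [wss_vector_field()]
#' @return a `wss_map`: `vectors` (n x 3), `abs_wss` (norms, N/m^2),
#'   `valid`, `viscosity_used`
#' @export
systolic_wss <- function(ds, mesh, viscosity = 3.2e-3, peak, d_mm = NULL) {
  if (ds$n_timeframes < 5L)
    stop("systolic WSS needs at least 5 timeframes")
  acc <- matrix(0, nrow(mesh$vertices), 3)
  valid <- rep(TRUE, nrow(mesh$vertices))
  for (t in peak$window5) {
    w <- wss_vector_field(ds, mesh, viscosity, t, d_mm)
    acc <- acc + w$vectors
    valid <- valid & w$valid
  }
  vec <- acc / length(peak$window5)
  structure(list(vectors = vec, abs_wss = sqrt(rowSums(vec^2)),
                 valid = valid, viscosity_used = viscosity),
            class = "wss_map")
}

#' Regional WSS means over the 18-segment / zone / side-by-zone atlas
#'
#' Unweighted vertex means of absolute systolic WSS per label; empty or
#' all-invalid regions are reported as missing (`NA`), never as zero.
#'
#' @param map a `wss_map` from [systolic_wss()]
#' @param atlas a `region_atlas`
#' @return list of data.frames `segments` (segment, mean_wss, n_vertices),
#'   `zones`, and `side_zones` (e.g. `outer_ascending`)
#' @export
regional_wss <- function(map, atlas) {
  ok <- map$valid & atlas$analyzed
  seg_df <- data.frame(segment = 1:18, mean_wss = NA_real_, n_vertices = 0L)
  for (s in 1:18) {
    sel <- ok & !is.na(atlas$segment) & atlas$segment == s
    seg_df$n_vertices[s] <- sum(sel)
    if (any(sel)) seg_df$mean_wss[s] <- mean(map$abs_wss[sel])
  }
  zones <- c("ascending", "arch", "descending")
  zone_df <- data.frame(zone = zones, mean_wss = NA_real_, n_vertices = 0L)
  for (i in seq_along(zones)) {
    sel <- ok & !is.na(atlas$zone) & atlas$zone == zones[i]
    zone_df$n_vertices[i] <- sum(sel)
    if (any(sel)) zone_df$mean_wss[i] <- mean(map$abs_wss[sel])
  }
  sz <- expand.grid(side = c("inner", "outer"), zone = zones,
                    stringsAsFactors = FALSE)
  sz$label <- paste(sz$side, sz$zone, sep = "_")
  sz$mean_wss <- NA_real_; sz$n_vertices <- 0L
  for (i in seq_len(nrow(sz))) {
    sel <- ok & !is.na(atlas$zone) & atlas$zone == sz$zone[i] &
      atlas$side == sz$side[i]
    sz$n_vertices[i] <- sum(sel)
    if (any(sel)) sz$mean_wss[i] <- mean(map$abs_wss[sel])
  }
  list(segments = seg_df, zones = zone_df,
       side_zones = sz[c("label", "mean_wss", "n_vertices")])
}

#' Zone peak velocities by maximum-intensity projection
#'
#' Per zone, the peak velocity is the maximum voxel speed over the three
#' timeframes centred on peak systole — by construction equal to the maximum
#' over the per-view (sagittal/coronal/axial) MIP images.
#'
#' @param ds a [velocity_field()]
#' @param aorta 3D logical mask
#' @param zones 3D character zone array from [voxel_zones()]
#' @param peak result of [find_peak_systole()]
#' @return data.frame: `zone`, `peak_velocity` (m/s), `voxel` (linear index
#'   of the maximizing voxel)
#' @export
peak_velocity_mip <- function(ds, aorta, zones, peak) {
  zl <- c("ascending", "arch", "descending")
  d <- dim(ds$velocity)
  best <- stats::setNames(rep(NA_real_, 3), zl)
  bvox <- stats::setNames(rep(NA_integer_, 3), zl)
  for (t in peak$window3) {
    spd <- sqrt(ds$velocity[, , , t, 1]^2 + ds$velocity[, , , t, 2]^2 +
                ds$velocity[, , , t, 3]^2)
    for (z in zl) {
      sel <- which(aorta & !is.na(zones) & zones == z)
      if (!length(sel)) next
      m <- max(spd[sel])
      if (is.na(best[z]) || m > best[z]) {
        best[z] <- m
        bvox[z] <- sel[which.max(spd[sel])]
      }
    }
  }
  if (anyNA(best)) stop("empty zone: ", paste(zl[is.na(best)], collapse = ", "))
  data.frame(zone = zl, peak_velocity = as.numeric(best),
             voxel = as.integer(bvox))
}

#' Maximum aortic cross-sectional area from two orthogonal diameters
#'
#' Defined as the product of the two orthogonal aortic diameter
#' measurements, converted from mm^2 to cm^2.
#'
#' @param d1,d2 orthogonal diameters, mm
#' @return area, cm^2
#' @export
max_aortic_area <- function(d1, d2) {
  if (any(d1 <= 0) || any(d2 <= 0)) stop("diameters must be positive")
  d1 * d2 / 100
}
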