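# Shared numerical helpers: world<->voxel coordinate mapping, trilinear
# interpolation, separable Gaussian smoothing, array shifting.
#
# Conventions used throughout the package:
#   * voxel [i, j, k] (1-based) sits at world position (i-1, j-1, k-1) * spacing [mm]
#   * velocities are stored in m/s; numerically 1 m/s == 1 mm/ms, so velocity
#     values can be used directly as mm/ms against mm geometry and ms timing.

#' Convert world coordinates (mm) to continuous 1-based voxel indices
#' @param pts n x 3 matrix of world points in mm
#' @param spacing length-3 voxel spacing in mm
#' @return n x 3 matrix of continuous indices
#' @keywords internal
world_to_index <- function(pts, spacing) {
  sweep(pts, 2, spacing, "/") + 1
}

#' Convert 1-based voxel indices to world coordinates (mm)
#' @keywords internal
index_to_world <- function(idx, spacing) {
  sweep(idx - 1, 2, spacing, "*")
}

#' Trilinear interpolation of a 3D array at world points
#'
#' Points outside the grid are clamped to the boundary voxel centres.
#'
#' @param arr 3D numeric array
#' @param pts n x 3 matrix of world points (mm)
#' @param spacing length-3 mm spacing
#' @return numeric vector of length n
#' @keywords internal
interp3 <- function(arr, pts, spacing) {
  d <- dim(arr)
  ci <- world_to_index(pts, spacing)
  # clamp into [1, d]
  for (a in 1:3) ci[, a] <- pmin(pmax(ci[, a], 1), d[a])
  i0 <- pmin(floor(ci), matrix(rep(d - 1L, each = nrow(ci)), ncol = 3))
  i0 <- pmax(i0, 1)
  f <- ci - i0
  i1 <- i0 + 1
  # gather the 8 corners with linear indexing
  lin <- function(ix, iy, iz) arr[cbind(ix, iy, iz)]
  v000 <- lin(i0[, 1], i0[, 2], i0[, 3]); v100 <- lin(i1[, 1], i0[, 2], i0[, 3])
  v010 <- lin(i0[, 1], i1[, 2], i0[, 3]); v110 <- lin(i1[, 1], i1[, 2], i0[, 3])
  v001 <- lin(i0[, 1], i0[, 2], i1[, 3]); v101 <- lin(i1[, 1], i0[, 2], i1[, 3])
  v011 <- lin(i0[, 1], i1[, 2], i1[, 3]); v111 <- lin(i1[, 1], i1[, 2], i1[, 3])
  fx <- f[, 1]; fy <- f[, 2]; fz <- f[, 3]
  c00 <- v000 * (1 - fx) + v100 * fx
  c10 <- v010 * (1 - fx) + v110 * fx
  c01 <- v001 * (1 - fx) + v101 * fx
  c11 <- v011 * (1 - fx) + v111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  c0 * (1 - fz) + c1 * fz
}

#' Shift a 3D array by integer offsets with edge replication
#' @keywords internal
shift3 <- function(arr, dx, dy, dz) {
  d <- dim(arr)
  ix <- pmin(pmax(seq_len(d[1]) + dx, 1), d[1])
  iy <- pmin(pmax(seq_len(d[2]) + dy, 1), d[2])
  iz <- pmin(pmax(seq_len(d[3]) + dz, 1), d[3])
  arr[ix, iy, iz, drop = FALSE]
}

#' Separable Gaussian smoothing of a 3D array (sigma in voxels)
#' @keywords internal
gauss_smooth3 <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-r):r / sigma)^2)
  k <- k / sum(k)
  d <- dim(arr)
  conv_axis <- function(a, axis) {
    out <- array(0, dim(a))
    for (off in (-r):r) {
      w <- k[off + r + 1]
      sh <- switch(axis,
        shift3(a, off, 0L, 0L),
        shift3(a, 0L, off, 0L),
        shift3(a, 0L, 0L, off))
      out <- out + w * sh
    }
    out
  }
  arr <- conv_axis(arr, 1L)
  arr <- conv_axis(arr, 2L)
  conv_axis(arr, 3L)
}

#' Normalize rows of a matrix to unit length
#' @keywords internal
normalize_rows <- function(m, eps = 1e-12) {
  n <- sqrt(rowSums(m^2))
  m / pmax(n, eps)
}

#' Row-wise cross product of two n x 3 matrices
#' @keywords internal
cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' For each query point, index of the nearest point in a reference set
#'
#' Chunked brute force; reference sets here are ~10^2-10^3 centerline points.
#' @keywords internal
nearest_point_index <- function(query, ref, chunk = 4096L) {
  n <- nrow(query)
  out <- integer(n)
  rx <- ref[, 1]; ry <- ref[, 2]; rz <- ref[, 3]
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    q <- query[s:e, , drop = FALSE]
    d2 <- outer(q[, 1], rx, "-")^2 + outer(q[, 2], ry, "-")^2 +
      outer(q[, 3], rz, "-")^2
    out[s:e] <- max.col(-d2, ties.method = "first")
  }
  out
}

#' Cyclic timeframe window of given width centred on a frame
#' @keywords internal
cyclic_window <- function(center, width, n) {
  h <- (width - 1L) %/% 2L
  ((center - h - 1L):(center + h - 1L)) %% n + 1L
}
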