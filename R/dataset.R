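# The central data container: a time-resolved three-directional velocity
# field plus magnitude images and acquisition metadata.

#' Construct a 4D flow velocity dataset
#'
#' Bundles the three-directional velocity field, the magnitude images and the
#' acquisition metadata (voxel spacing, temporal resolution, velocity
#' encoding) into a single validated object. Axis order is fixed as
#' `(x, y, z, t, component)` for velocity and `(x, y, z, t)` for magnitude;
#' world coordinates are `(index - 1) * spacing` millimetres, velocities are
#' metres per second.
#'
#' @param velocity 5-D numeric array `(x, y, z, t, 3)`, m/s
#' @param magnitude 4-D numeric array `(x, y, z, t)`, arbitrary units; if
#'   `NULL` a unit magnitude is assumed
#' @param spacing length-3 numeric, mm per voxel along x, y, z
#' @param dt scalar, ms per cardiac timeframe
#' @param venc length-3 numeric (or scalar, recycled), m/s per encoding
#'   direction
#' @param check_venc_range if `TRUE`, assert that every stored velocity
#'   component lies within `[-venc, venc]` (raw, pre-unaliasing data);
#'   unaliased fields may legitimately exceed venc
#' @return an object of class `velocity_field_4d`
#' @export
velocity_field <- function(velocity, magnitude = NULL, spacing, dt, venc,
                           check_venc_range = FALSE) {
  if (length(dim(velocity)) != 5L || dim(velocity)[5] != 3L)
    stop("velocity must be a 5-D array (x, y, z, t, 3)")
  dims <- dim(velocity)
  if (dims[4] < 3L) stop("at least 3 timeframes are required")
  if (is.null(magnitude)) magnitude <- array(1, dims[1:4])
  if (!identical(dim(magnitude), dims[1:4]))
    stop("magnitude dimensions must equal the velocity spatial/temporal dimensions")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(is.na(spacing)) || any(spacing <= 0))
    stop("spacing must be positive (mm)")
  if (length(dt) != 1L || is.na(dt) || dt <= 0) stop("dt must be a positive scalar (ms)")
  venc <- rep_len(as.numeric(venc), 3L)
  if (any(is.na(venc)) || any(venc <= 0)) stop("venc must be positive (m/s)")
  if (check_venc_range) {
    for (c in 1:3) {
      vc <- velocity[, , , , c]
      if (any(abs(vc[is.finite(vc)]) > venc[c] + 1e-9))
        stop("raw velocity component ", c, " exceeds venc; data are not phase-wrapped raw values")
    }
  }
  structure(
    list(velocity = velocity, magnitude = magnitude,
         spacing = spacing, dt = dt, venc = venc,
         n_timeframes = dims[4]),
    class = "velocity_field_4d")
}

#' @export
print.velocity_field_4d <- function(x, ...) {
  d <- dim(x$velocity)
  cat(sprintf("4D flow dataset: %d x %d x %d voxels, %d timeframes\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  spacing: %s mm, dt: %.1f ms, venc: %s m/s\n",
              paste(format(x$spacing), collapse = " x "), x$dt,
              paste(format(x$venc), collapse = "/")))
  invisible(x)
}

#' Validate an aortic segmentation mask against a dataset
#'
#' @param mask 3D logical array aligned to the dataset's spatial grid
#' @param ds a `velocity_field_4d`
#' @return the mask, invisibly validated
#' @export
validate_mask <- function(mask, ds) {
  if (!identical(dim(mask), dim(ds$velocity)[1:3]))
    stop("mask spatial dimensions do not match the dataset")
  if (!any(mask)) stop("mask is empty")
  mask
}

#' Largest 6-connected component of a 3D logical mask
#'
#' @param mask 3D logical array
#' @return 3D logical array keeping only the largest connected component
#' @export
largest_component <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  idx <- which(mask)
  if (length(idx) == 0L) stop("mask is empty")
  cur <- 0L
  nxyz <- d[1] * d[2]
  neigh_off <- c(-1L, 1L, -d[1], d[1], -nxyz, nxyz)
  for (seed in idx) {
    if (lab[seed] != 0L) next
    cur <- cur + 1L
    frontier <- seed
    lab[seed] <- cur
    while (length(frontier)) {
      # expand with boundary guards per axis
      ai <- arrayInd(frontier, d)
      cand <- integer(0)
      for (k in seq_along(neigh_off)) {
        ok <- switch(k,
          ai[, 1] > 1, ai[, 1] < d[1],
          ai[, 2] > 1, ai[, 2] < d[2],
          ai[, 3] > 1, ai[, 3] < d[3])
        cand <- c(cand, frontier[ok] + neigh_off[k])
      }
      cand <- unique(cand)
      cand <- cand[mask[cand] & lab[cand] == 0L]
      lab[cand] <- cur
      frontier <- cand
    }
  }
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}
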