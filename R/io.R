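# Readers and writers: NIfTI per-component input dialect, the canonical
# container (a directory with float64 NIfTI volumes + JSON metadata sidecar),
# result tables (CSV), landmark definitions (JSON) and wall meshes (ASCII PLY).

VALID_LOCATION_LABELS <- c(
  paste0("P", 1:9),
  paste0("segment_", 1:18),
  "ascending", "arch", "descending",
  paste0("inner_", c("ascending", "arch", "descending")),
  paste0("outer_", c("ascending", "arch", "descending")))

VALID_UNITS <- c("mL", "N/m^2", "m/s", "grade")

#' Read a 4D flow dataset
#'
#' Two dialects are accepted. (1) Canonical container: a directory written by
#' [write_dataset()] holding `velocity.nii.gz` (5-D, component last),
#' `magnitude.nii.gz` and `meta.json` with `spacing`, `dt` and `venc`.
#' (2) Clinical NIfTI-per-component: `paths` is a list with elements `vx`,
#' `vy`, `vz` (each a 4-D NIfTI path), optional `magnitude`, and `metadata`
#' must supply `venc` (m/s) and `dt` (ms) — typically parsed from a JSON
#' sidecar via [read_metadata_sidecar()].
#'
#' The reader validates shapes and metadata and fails loudly rather than
#' reordering axes.
#'
#' @param paths directory path (canonical) or named list of file paths
#' @param metadata named list with `venc`, `dt` and optionally `spacing`
#'   (mm); required for the per-component dialect
#' @return a [velocity_field()] object
#' @export
read_dataset <- function(paths, metadata = NULL) {
  if (is.character(paths) && length(paths) == 1L && dir.exists(paths)) {
    meta_path <- file.path(paths, "meta.json")
    if (!file.exists(meta_path)) stop("missing meta.json in container: ", paths)
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    vel <- array(as.numeric(RNifti::readNifti(file.path(paths, "velocity.nii.gz"))),
                 dim = unlist(meta$dims))
    mag <- array(as.numeric(RNifti::readNifti(file.path(paths, "magnitude.nii.gz"))),
                 dim = unlist(meta$dims)[1:4])
    return(velocity_field(vel, mag, spacing = meta$spacing, dt = meta$dt,
                          venc = meta$venc))
  }
  if (!is.list(paths) || !all(c("vx", "vy", "vz") %in% names(paths)))
    stop("paths must be a container directory or a list with vx/vy/vz")
  comp <- lapply(paths[c("vx", "vy", "vz")], function(p) {
    if (!file.exists(p)) stop("file not found: ", p)
    img <- RNifti::readNifti(p)
    array(as.numeric(img), dim = dim(img))
  })
  shapes <- vapply(comp, function(a) paste(dim(a), collapse = "x"), "")
  if (length(unique(shapes)) != 1L)
    stop("velocity component grids have unequal shapes: ",
         paste(shapes, collapse = " vs "))
  if (length(dim(comp[[1]])) != 4L)
    stop("velocity components must be 4-D (x, y, z, t)")
  if (is.null(metadata) || is.null(metadata$venc) || is.null(metadata$dt))
    stop("metadata with venc and dt is required for per-component input")
  d <- dim(comp[[1]])
  vel <- array(0, c(d, 3L))
  for (c in 1:3) vel[, , , , c] <- comp[[c]]
  mag <- NULL
  if (!is.null(paths$magnitude)) {
    img <- RNifti::readNifti(paths$magnitude)
    mag <- array(as.numeric(img), dim = dim(img))
    if (!identical(dim(mag), d))
      stop("magnitude shape does not match the velocity components")
  }
  spacing <- metadata$spacing
  if (is.null(spacing)) {
    spacing <- RNifti::pixdim(RNifti::readNifti(paths$vx))[1:3]
  }
  velocity_field(vel, mag, spacing = spacing, dt = metadata$dt,
                 venc = metadata$venc)
}

#' Read a JSON metadata sidecar (venc, dt, spacing)
#' @param path JSON file path
#' @return named list
#' @export
read_metadata_sidecar <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a 4D flow dataset to the canonical container
#'
#' Writes a directory holding float64 NIfTI volumes and a JSON metadata
#' sidecar; [read_dataset()] on the result reproduces the dataset to
#' floating-point identity (NaN voxels included).
#'
#' @param ds a [velocity_field()] object
#' @param path directory to create/overwrite
#' @return `path`, invisibly
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "velocity_field_4d"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create container directory: ", path)
  RNifti::writeNifti(RNifti::asNifti(ds$velocity), file.path(path, "velocity.nii.gz"),
                     datatype = "double")
  RNifti::writeNifti(RNifti::asNifti(ds$magnitude), file.path(path, "magnitude.nii.gz"),
                     datatype = "double")
  jsonlite::write_json(
    list(dims = dim(ds$velocity), spacing = ds$spacing, dt = ds$dt,
         venc = ds$venc),
    file.path(path, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Assemble rows of a result table
#'
#' @param subject_id,timepoint,group,measurement_name,location_label,value,units,qc_flag
#'   vectors, recycled to a common length
#' @return a `data.frame` with the fixed column order
#' @export
result_rows <- function(subject_id, timepoint, group, measurement_name,
                        location_label, value, units, qc_flag = "INCLUDED") {
  df <- data.frame(subject_id = subject_id, timepoint = timepoint,
                   group = group, measurement_name = measurement_name,
                   location_label = location_label, value = value,
                   units = units, qc_flag = qc_flag,
                   stringsAsFactors = FALSE)
  validate_result_table(df)
}

#' Validate a result table
#' @param df data.frame of result rows
#' @return the validated data.frame
#' @export
validate_result_table <- function(df) {
  need <- c("subject_id", "timepoint", "group", "measurement_name",
            "location_label", "value", "units", "qc_flag")
  if (!all(need %in% names(df))) stop("result table missing columns: ",
                                      paste(setdiff(need, names(df)), collapse = ", "))
  bad <- setdiff(unique(df$location_label), VALID_LOCATION_LABELS)
  if (length(bad)) stop("unknown location_label: ", paste(bad, collapse = ", "))
  badu <- setdiff(unique(df$units), VALID_UNITS)
  if (length(badu)) stop("unknown units: ", paste(badu, collapse = ", "))
  if (nrow(df) && !all(df$timepoint %in% c("B", "FU")))
    stop("timepoint must be B or FU")
  df[need]
}

#' Write a result table as CSV with deterministic row order
#'
#' Rows are ordered by subject, timepoint, then location (P-planes first in
#' numeric order, then segments, then zones/sides), so repeated runs produce
#' byte-identical files.
#'
#' @param df result table data.frame
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_result_table <- function(df, path) {
  df <- validate_result_table(df)
  loc_rank <- match(df$location_label, VALID_LOCATION_LABELS)
  ord <- order(df$subject_id, df$timepoint, loc_rank, df$measurement_name)
  df <- df[ord, , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read landmark definitions from JSON
#'
#' Format: `{"P2": {"fraction": 0.08}, "P3": {"point_mm": [x,y,z]}, ...}` —
#' each landmark either an arc-length fraction of the centerline or an
#' explicit world point (projected onto the centerline).
#'
#' @param path JSON file
#' @return named list of landmark specs
#' @export
read_landmark_spec <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Export a wall mesh (with optional per-vertex atlas labels) as ASCII PLY
#'
#' @param mesh a wall mesh as returned by [extract_wall_mesh()]
#' @param path output `.ply` path
#' @param atlas optional region atlas from [build_region_atlas()]; adds
#'   per-vertex `zone_id`, `side_id` and `segment` properties
#' @param scalars optional named list of per-vertex numeric vectors to embed
#' @return `path`, invisibly
#' @export
write_mesh_ply <- function(mesh, path, atlas = NULL, scalars = NULL) {
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  props <- c("property float x", "property float y", "property float z",
             "property float nx", "property float ny", "property float nz")
  vert_cols <- cbind(mesh$vertices, mesh$inward_normals)
  if (!is.null(atlas)) {
    props <- c(props, "property int zone_id", "property int side_id",
               "property int segment")
    zone_id <- match(atlas$zone, c("ascending", "arch", "descending"))
    side_id <- match(atlas$side, c("inner", "outer"))
    vert_cols <- cbind(vert_cols, zone_id, side_id, atlas$segment)
  }
  for (nm in names(scalars)) {
    props <- c(props, paste("property float", nm))
    vert_cols <- cbind(vert_cols, scalars[[nm]])
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nv), props,
               paste("element face", nf),
               "property list uchar int vertex_indices",
               "end_header"), con)
  utils::write.table(format(vert_cols, trim = TRUE, digits = 7), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, mesh$faces - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
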