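#' Grey-value micro-CT volume
#'
#' A 3D intensity volume in the 16-bit unsigned range with an isotropic
#' voxel size and free-form provenance metadata. Axis 1 is the stacking
#' (scaffold) axis, i.e. the vertical direction of the tomographic scans.
#'
#' @param data 3D numeric/integer array with values in `[0, 65535]`.
#' @param voxel_size Isotropic voxel edge length in micrometres.
#' @param metadata Named list of provenance annotations (e.g. the
#'   beamline phase-retrieval "Paganin length"; carried along, never used).
#'
#' @return An object of class `grey_volume`: a list with elements
#'   `data` (integer array), `voxel_size` (um) and `metadata`.
#' @examples
#' v <- grey_volume(array(0L, c(4, 4, 4)), voxel_size = 3.07)
#' dim(v$data)
#' @export
grey_volume <- function(data, voxel_size, metadata = list()) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (!is.numeric(voxel_size) || length(voxel_size) != 1 || voxel_size <= 0) {
    stop("voxel_size must be a single positive number (micrometres)")
  }
  if (anyNA(data)) stop("grey volume contains NA values")
  rng <- range(data)
  if (rng[1] < 0 || rng[2] > 65535) {
    stop("grey values must lie in [0, 65535] (16-bit unsigned range)")
  }
  storage.mode(data) <- "integer"
  structure(
    list(data = data, voxel_size = as.numeric(voxel_size), metadata = metadata),
    class = "grey_volume"
  )
}

#' Corrosion-phase label volume
#'
#' A 3D map of corrosion phases co-registered with a grey volume:
#' label 0 background/soft tissue, 1 metallic Mg, 2 degraded Mg
#' (conversion layer), 3 severely degraded Mg.
#'
#' @param data 3D array of integers in `{0, 1, 2, 3}`.
#' @param voxel_size Isotropic voxel edge length in micrometres.
#' @param axis_hint Optional unit 3-vector giving the nominal scaffold axis
#'   in voxel coordinates (default: axis 1, the stacking direction).
#'
#' @return An object of class `label_volume`.
#' @examples
#' lv <- label_volume(array(0L, c(4, 4, 4)), voxel_size = 3.07)
#' table(lv$data)
#' @export
label_volume <- function(data, voxel_size, axis_hint = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (!is.numeric(voxel_size) || length(voxel_size) != 1 || voxel_size <= 0) {
    stop("voxel_size must be a single positive number (micrometres)")
  }
  if (anyNA(data)) stop("label volume contains NA values")
  u <- unique(as.vector(data))
  if (!all(u %in% 0:3)) {
    stop("label values must be in {0, 1, 2, 3}; found: ",
         paste(setdiff(u, 0:3), collapse = ", "))
  }
  if (!is.null(axis_hint)) {
    stopifnot(is.numeric(axis_hint), length(axis_hint) == 3)
    n <- sqrt(sum(axis_hint^2))
    if (n == 0) stop("axis_hint must be a non-zero vector")
    axis_hint <- axis_hint / n
  }
  storage.mode(data) <- "integer"
  structure(
    list(data = data, voxel_size = as.numeric(voxel_size),
         axis_hint = axis_hint),
    class = "label_volume"
  )
}

#' @export
print.grey_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<grey_volume> %d x %d x %d voxels @ %.3g um, range [%d, %d]\n",
              d[1], d[2], d[3], x$voxel_size, min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$data)
  tab <- tabulate(as.vector(x$data) + 1L, nbins = 4L)
  cat(sprintf("<label_volume> %d x %d x %d voxels @ %.3g um\n",
              d[1], d[2], d[3], x$voxel_size))
  cat(sprintf("  labels: 0 (background) %d | 1 (metallic) %d | 2 (degraded) %d | 3 (severe) %d\n",
              tab[1], tab[2], tab[3], tab[4]))
  invisible(x)
}

is_grey_volume <- function(x) inherits(x, "grey_volume")
is_label_volume <- function(x) inherits(x, "label_volume")

# Per-phase voxel counts, labels 0..3
label_counts <- function(labels) {
  tabulate(as.vector(labels$data) + 1L, nbins = 4L)
}

# Voxel volume in mm^3 for a given voxel edge in um
voxel_volume_mm3 <- function(voxel_size_um) (voxel_size_um * 1e-3)^3

#' Field of view of a scan in millimetres
#'
#' @param n_voxels Extent in voxels (e.g. 2048 for a full detector width).
#' @param voxel_size_um Isotropic voxel edge in micrometres.
#' @return Physical extent in mm.
#' @examples
#' field_of_view_mm(2048, 3.07) # about 6.3 mm
#' @export
field_of_view_mm <- function(n_voxels, voxel_size_um) {
  stopifnot(n_voxels > 0, voxel_size_um > 0)
  n_voxels * voxel_size_um / 1000
}
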