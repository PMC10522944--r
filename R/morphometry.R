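#' Per-phase volumes and degraded fraction
#'
#' Volume of phase k is `count(label == k) * voxel_size^3`, reported in
#' mm^3. The degraded fraction is `(V2 + V3) / (V1 + V2 + V3)`, i.e.
#' degraded plus severely degraded material over the total solid scaffold
#' volume. An all-background volume reports zero volumes and a flagged
#' undefined fraction (returned as 0 with `fraction_defined = FALSE`).
#'
#' @param labels A [label_volume()].
#' @return A `morphometry_report` list with `volume_metallic`,
#'   `volume_degraded`, `volume_severe` (mm^3), `fraction_degraded` and
#'   `fraction_defined`.
#' @export
phase_volumes <- function(labels) {
  stopifnot(is_label_volume(labels))
  counts <- label_counts(labels)
  vv <- voxel_volume_mm3(labels$voxel_size)
  v <- counts * vv
  solid <- v[2] + v[3] + v[4]
  structure(
    list(volume_metallic = v[2], volume_degraded = v[3], volume_severe = v[4],
         fraction_degraded = if (solid > 0) (v[3] + v[4]) / solid else 0,
         fraction_defined = solid > 0,
         surface_area = NA_real_, regional_volumes = NULL,
         luminal_abluminal_ratio = NA_real_,
         voxel_size = labels$voxel_size, source = "labels"),
    class = "morphometry_report")
}

#' @export
print.morphometry_report <- function(x, ...) {
  cat("<morphometry_report>\n")
  cat(sprintf("  metallic  %.6g mm^3\n", x$volume_metallic))
  cat(sprintf("  degraded  %.6g mm^3\n", x$volume_degraded))
  cat(sprintf("  severe    %.6g mm^3\n", x$volume_severe))
  cat(sprintf("  degraded fraction %.4f%s\n", x$fraction_degraded,
              if (!x$fraction_defined) " (undefined: empty scaffold)" else ""))
  if (!is.na(x$surface_area))
    cat(sprintf("  surface area %.6g mm^2\n", x$surface_area))
  if (!is.null(x$regional_volumes)) {
    rv <- x$regional_volumes
    cat(sprintf("  regional (label 2): luminal %.6g | lateral %.6g | abluminal %.6g mm^3\n",
                rv[["luminal"]], rv[["lateral"]], rv[["abluminal"]]))
    cat(sprintf("  luminal:abluminal ratio %.3f\n", x$luminal_abluminal_ratio))
  }
  invisible(x)
}

# triangle mesh of the 0.5-isosurface of a phase union, voxel coordinates.
# The binary mask is anti-aliased with a small Gaussian (smooth_sigma,
# voxels) before extraction: the raw binary level set is a staircase whose
# area is biased high; sub-voxel smoothing puts the interpolated vertices
# on the underlying smooth boundary. smooth_sigma = 0 gives the raw mask.
isosurface_mesh <- function(labels, phase_set, smooth_sigma = 1) {
  d <- dim(labels$data)
  mask <- array(as.numeric(labels$data %in% phase_set), dim = d)
  if (smooth_sigma > 0) {
    mask <- cpp_gaussian_blur3(mask, d, smooth_sigma)
  }
  cpp_isosurface(as.numeric(mask), d, 0.5)
}

mesh_area <- function(mesh) {
  V <- mesh$vertices
  F_ <- mesh$faces
  if (nrow(F_) == 0) return(0)
  a <- V[F_[, 2], , drop = FALSE] - V[F_[, 1], , drop = FALSE]
  b <- V[F_[, 3], , drop = FALSE] - V[F_[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Surface area of a phase union
#'
#' Extracts the boundary isosurface of the union of the given phases at
#' iso-level 0.5 (triangulated per grid cell) and sums the triangle
#' areas, scaled by the voxel size. The binary mask is anti-aliased with
#' a one-voxel Gaussian before extraction so the level set follows the
#' underlying boundary rather than the voxel staircase; set
#' `smooth_sigma = 0` for the raw binary level set. Structures thinner
#' than about two voxels may be missed with smoothing on.
#'
#' @param labels A [label_volume()].
#' @param phase_set Labels treated as solid (default all scaffold phases).
#' @param smooth_sigma Mask anti-aliasing sigma in voxels.
#' @return Surface area in mm^2 (0 for an empty mask).
#' @export
surface_area <- function(labels, phase_set = 1:3, smooth_sigma = 1) {
  stopifnot(is_label_volume(labels))
  if (!any(labels$data %in% phase_set)) return(0)
  mesh <- isosurface_mesh(labels, phase_set, smooth_sigma)
  mesh_area(mesh) * (labels$voxel_size * 1e-3)^2
}

#' Estimate the scaffold axis
#'
#' Principal direction (largest-variance axis) of the non-background voxel
#' coordinates, through their centroid.
#'
#' @param labels A [label_volume()] with at least 100 non-background voxels.
#' @return A `scaffold_axis`: list with `point` (centroid, voxel
#'   coordinates) and `direction` (unit vector).
#' @export
estimate_axis <- function(labels) {
  stopifnot(is_label_volume(labels))
  idx <- which(labels$data != 0L)
  if (length(idx) < 100) stop("need at least 100 non-background voxels")
  co <- arrayInd(idx, dim(labels$data))
  if (length(idx) > 2e5) {
    keep <- as.integer(seq(1, length(idx), length.out = 2e5))
    co <- co[keep, , drop = FALSE]
  }
  ctr <- colMeans(co)
  pc <- stats::prcomp(co, center = TRUE, scale. = FALSE)
  dirv <- pc$rotation[, 1]
  nz <- which(abs(dirv) > 1e-12)[1]
  if (dirv[nz] < 0) dirv <- -dirv
  structure(list(point = ctr, direction = dirv / sqrt(sum(dirv^2))),
            class = "scaffold_axis")
}

#' Partition degraded material into luminal, lateral and abluminal volumes
#'
#' For every degraded (label 2) voxel the escape direction is the
#' direction toward its nearest background: estimated as the gradient of
#' a lightly smoothed background-indicator field, which at voxel
#' distances is far less direction-quantized than the literal
#' voxel-to-nearest-background vector (that vector is used as a fallback
#' where the gradient degenerates deep inside thick struts). With the
#' outward radial unit vector r-hat (perpendicular from the scaffold axis
#' through the voxel), the voxel is classified abluminal if the escape
#' direction lies within `cone_half_angle` of r-hat, luminal if within
#' `cone_half_angle` of -r-hat, and lateral otherwise (the lateral class
#' collects both circumferential side faces). Severely degraded voxels
#' (label 3) are excluded from the analysis entirely.
#'
#' @param labels A [label_volume()] containing label-2 voxels.
#' @param axis A `scaffold_axis`. By default the volume's `axis_hint` is
#'   used when present (through the non-background centroid), otherwise
#'   the axis is estimated by [estimate_axis()]; the PCA estimate needs a
#'   scaffold clearly longer than its diameter.
#' @param cone_half_angle Cone half-angle in degrees (default 45, an equal
#'   angular budget for each radial class; escape directions at exactly
#'   the cone boundary count as radial).
#' @return Named numeric vector (mm^3) with components `luminal`,
#'   `lateral`, `abluminal`; their sum equals the total label-2 volume.
#' @export
partition_strut_regions <- function(labels, axis = NULL, cone_half_angle = 45) {
  stopifnot(is_label_volume(labels))
  if (is.null(axis)) {
    if (!is.null(labels$axis_hint)) {
      idx <- which(labels$data != 0L)
      ctr <- colMeans(arrayInd(idx, dim(labels$data)))
      axis <- structure(list(point = ctr, direction = labels$axis_hint),
                        class = "scaffold_axis")
    } else {
      axis <- estimate_axis(labels)
    }
  }
  stopifnot(inherits(axis, "scaffold_axis"))
  dvec <- axis$direction
  if (abs(sqrt(sum(dvec^2)) - 1) > 1e-6) stop("degenerate axis direction")
  idx2 <- which(labels$data == 2L)
  if (length(idx2) == 0) stop("no degraded (label 2) voxels to partition")
  dims <- dim(labels$data)
  co <- arrayInd(idx2, dims)

  # escape direction: gradient of the smoothed background indicator
  bgind <- array(as.numeric(labels$data == 0L), dim = dims)
  sm <- cpp_gaussian_blur3(bgind, dims, 1.5)
  dim(sm) <- dims
  esc <- vapply(1:3, function(ax) {
    up <- co; up[, ax] <- pmin(up[, ax] + 1L, dims[ax])
    dn <- co; dn[, ax] <- pmax(dn[, ax] - 1L, 1L)
    (sm[up] - sm[dn]) / 2
  }, numeric(nrow(co)))
  if (nrow(co) == 1L) esc <- matrix(esc, nrow = 1L)
  esc_n <- sqrt(rowSums(esc^2))
  flat <- esc_n < 1e-9
  if (any(flat)) {
    # deep-interior voxels: fall back to the vector to the literal
    # nearest background voxel from the exact feature transform
    edt <- cpp_edt_feature(as.integer(labels$data != 0L), dims)
    nb <- arrayInd(edt$feature[idx2[flat]], dims)
    esc[flat, ] <- nb - co[flat, , drop = FALSE]
    esc_n <- sqrt(rowSums(esc^2))
  }
  ok <- esc_n > 0
  esc <- esc[ok, , drop = FALSE] / esc_n[ok]
  co <- co[ok, , drop = FALSE]

  rel <- sweep(co, 2, axis$point)
  axial <- as.vector(rel %*% dvec)
  radial <- rel - outer(axial, dvec)
  rn <- sqrt(rowSums(radial^2))
  on_axis <- rn < 1e-9
  radial[!on_axis, ] <- radial[!on_axis, , drop = FALSE] / rn[!on_axis]

  cosang <- rowSums(esc * radial)
  cosang[on_axis] <- 0 # undefined radial direction -> lateral
  # small slack so grid-diagonal escapes at exactly 45 degrees count radial
  cth <- cos(cone_half_angle * pi / 180) - 1e-6
  cls <- ifelse(cosang >= cth, "abluminal",
                ifelse(cosang <= -cth, "luminal", "lateral"))
  vv <- voxel_volume_mm3(labels$voxel_size)
  out <- c(luminal = sum(cls == "luminal") * vv,
           lateral = sum(cls == "lateral") * vv,
           abluminal = sum(cls == "abluminal") * vv)
  # voxels fully enclosed by scaffold (no direction) count as lateral
  out["lateral"] <- out["lateral"] + sum(!ok) * vv
  out
}

#' Ratio of luminal to abluminal degraded volume
#'
#' @param regional_volumes Output of [partition_strut_regions()].
#' @return The ratio `luminal / abluminal`; `NA` with an `undefined`
#'   attribute when the abluminal volume is zero.
#' @export
luminal_abluminal_ratio <- function(regional_volumes) {
  stopifnot(all(c("luminal", "abluminal") %in% names(regional_volumes)))
  if (regional_volumes[["abluminal"]] <= 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  unname(regional_volumes[["luminal"]] / regional_volumes[["abluminal"]])
}

#' Full morphometry report for a label volume
#'
#' Combines [phase_volumes()], [surface_area()] and (when label-2 voxels
#' are present) [partition_strut_regions()] into one report.
#'
#' @param labels A [label_volume()].
#' @param cone_half_angle Cone half-angle for the regional partition.
#' @return A `morphometry_report`.
#' @export
morphometry_report <- function(labels, cone_half_angle = 45) {
  rep_ <- phase_volumes(labels)
  rep_$surface_area <- surface_area(labels, 1:3)
  if (any(labels$data == 2L) && sum(labels$data != 0L) >= 100) {
    rv <- partition_strut_regions(labels, cone_half_angle = cone_half_angle)
    rep_$regional_volumes <- rv
    rep_$luminal_abluminal_ratio <- luminal_abluminal_ratio(rv)
  }
  rep_
}

#' Export a phase-union mesh to STL and/or PLY
#'
#' Writes the 0.5-isosurface mesh of the given phases in physical units
#' (mm). Binary STL and ASCII PLY are supported, chosen by file extension.
#'
#' @param labels A [label_volume()].
#' @param path Output path ending in `.stl` or `.ply`.
#' @param phase_set Labels treated as solid.
#' @param smooth_sigma Mask anti-aliasing sigma in voxels (matches
#'   [surface_area()], so the exported mesh area equals the reported one).
#' @return Invisibly, the mesh (list of `vertices` in mm and `faces`).
#' @export
export_mesh <- function(labels, path, phase_set = 1:3, smooth_sigma = 1) {
  stopifnot(is_label_volume(labels))
  if (!any(labels$data %in% phase_set)) stop("empty mask: nothing to mesh")
  mesh <- isosurface_mesh(labels, phase_set, smooth_sigma)
  mesh$vertices <- mesh$vertices * (labels$voxel_size * 1e-3) # mm
  ext <- tolower(tools::file_ext(path))
  if (ext == "stl") {
    write_stl_binary(mesh, path)
  } else if (ext == "ply") {
    write_ply_ascii(mesh, path)
  } else {
    stop("unsupported mesh format: .", ext, " (use .stl or .ply)")
  }
  invisible(mesh)
}

write_stl_binary <- function(mesh, path) {
  V <- mesh$vertices
  F_ <- mesh$faces
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80), con)
  writeBin(as.integer(nrow(F_)), con, size = 4, endian = "little")
  for (i in seq_len(nrow(F_))) {
    p1 <- V[F_[i, 1], ]; p2 <- V[F_[i, 2], ]; p3 <- V[F_[i, 3], ]
    u <- p2 - p1; v <- p3 - p1
    n <- c(u[2] * v[3] - u[3] * v[2],
           u[3] * v[1] - u[1] * v[3],
           u[1] * v[2] - u[2] * v[1])
    nn <- sqrt(sum(n^2))
    if (nn > 0) n <- n / nn
    writeBin(as.numeric(c(n, p1, p2, p3)), con, size = 4, endian = "little")
    writeBin(raw(2), con)
  }
  invisible(path)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  nt <- readBin(con, "integer", 1, size = 4, endian = "little")
  tri <- matrix(0, nt, 9)
  for (i in seq_len(nt)) {
    rec <- readBin(con, "numeric", 12, size = 4, endian = "little")
    readBin(con, "raw", 2)
    tri[i, ] <- rec[4:12]
  }
  tri
}

write_ply_ascii <- function(mesh, path) {
  V <- mesh$vertices
  F_ <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(V)),
               "property float x", "property float y", "property float z",
               paste("element face", nrow(F_)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  utils::write.table(format(V, scientific = FALSE, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, F_ - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

# V - E + F of a triangle mesh with exactly deduplicated vertices
mesh_euler_characteristic <- function(mesh) {
  F_ <- mesh$faces
  edges <- rbind(F_[, c(1, 2)], F_[, c(2, 3)], F_[, c(1, 3)])
  edges <- t(apply(edges, 1, sort))
  ne <- nrow(unique(edges))
  nrow(mesh$vertices) - ne + nrow(F_)
}
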