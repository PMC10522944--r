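#' Write a volume to disk (multi-page TIFF or raw binary + JSON sidecar)
#'
#' Grey volumes are written as 16-bit multi-page TIFF (one page per slice
#' along the stacking axis) or raw little-endian 16-bit binary; label
#' volumes as 8-bit. A JSON sidecar `<path>.json` records the volume type,
#' dimensions, voxel size, data type and metadata, making the round trip
#' through [read_volume()] lossless.
#'
#' @param volume A [grey_volume()] or [label_volume()].
#' @param path Output path; `.tif`/`.tiff` for TIFF, `.raw` for raw binary.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(volume, path) {
  is_grey <- is_grey_volume(volume)
  if (!is_grey && !is_label_volume(volume)) stop("not a volume object")
  ext <- tolower(tools::file_ext(path))
  d <- dim(volume$data)
  if (ext %in% c("tif", "tiff")) {
    denom <- if (is_grey) 65535 else 255
    pages <- lapply(seq_len(d[1]), function(i) volume$data[i, , ] / denom)
    tiff::writeTIFF(pages, path, bits.per.sample = if (is_grey) 16L else 8L,
                    compression = "none")
  } else if (ext == "raw") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.integer(volume$data), con, size = if (is_grey) 2L else 1L,
             endian = "little")
  } else {
    stop("unsupported volume format: .", ext, " (use .tif/.tiff or .raw)")
  }
  sidecar <- list(
    type = if (is_grey) "grey" else "label",
    dims = d,
    voxel_size_um = volume$voxel_size,
    dtype = if (is_grey) "uint16" else "uint8",
    axis_order = "x(axial) y z",
    metadata = if (is_grey) volume$metadata else NULL,
    axis_hint = if (!is_grey) volume$axis_hint else NULL)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a volume written by [write_volume()]
#'
#' Reads TIFF stacks or raw binary with their JSON sidecar; the sidecar
#' supplies type, shape and voxel size. Label files are validated to the
#' 4-label scheme; a value outside `{0..3}` is an error.
#'
#' @param path Volume file path (the sidecar `<path>.json` must exist,
#'   unless `voxel_size` and `type` are supplied for a TIFF).
#' @param voxel_size Voxel size in um, overriding/replacing the sidecar.
#' @param type `"grey"` or `"label"`, if no sidecar is present.
#' @return A [grey_volume()] or [label_volume()].
#' @export
read_volume <- function(path, voxel_size = NULL, type = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  side_path <- paste0(path, ".json")
  side <- NULL
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    if (is.null(voxel_size)) voxel_size <- side$voxel_size_um
    if (is.null(type)) type <- side$type
  }
  if (is.null(voxel_size))
    stop("voxel size unknown: no sidecar found and none supplied")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    if (is.null(type)) stop("volume type unknown: supply type=")
    denom <- if (type == "grey") 65535 else 255
    d1 <- length(pages)
    dlat <- dim(pages[[1]])
    arr <- array(0L, dim = c(d1, dlat[1], dlat[2]))
    for (i in seq_len(d1)) arr[i, , ] <- as.integer(round(pages[[i]] * denom))
  } else if (ext == "raw") {
    if (is.null(side)) stop("raw volumes require the JSON sidecar")
    d <- as.integer(side$dims)
    sz <- if (side$dtype == "uint16") 2L else 1L
    con <- file(path, "rb")
    on.exit(close(con))
    vals <- readBin(con, "integer", prod(d), size = sz, signed = sz > 2,
                    endian = "little")
    vals[vals < 0] <- vals[vals < 0] + if (sz == 2L) 65536L else 256L
    arr <- array(as.integer(vals), dim = d)
  } else {
    stop("unsupported volume format: .", ext)
  }
  if (type == "grey") {
    md <- if (!is.null(side$metadata)) side$metadata else list()
    grey_volume(arr, voxel_size, md)
  } else {
    bad <- setdiff(unique(as.vector(arr)), 0:3)
    if (length(bad))
      stop("label file contains invalid value(s): ", paste(bad, collapse = ", "))
    ah <- if (!is.null(side$axis_hint)) as.numeric(side$axis_hint) else NULL
    label_volume(arr, voxel_size, axis_hint = ah)
  }
}

#' Write a morphometry report to CSV/JSON
#'
#' @param report A `morphometry_report` (or list of them, one per sample).
#' @param path Output path ending in `.csv` or `.json`.
#' @param sample_ids Optional sample identifiers.
#' @return Invisibly, the report data frame.
#' @export
write_report <- function(report, path, sample_ids = NULL) {
  if (inherits(report, "morphometry_report")) report <- list(report)
  df <- do.call(rbind, lapply(seq_along(report), function(i) {
    r <- report[[i]]
    rv <- r$regional_volumes
    data.frame(
      sample_id = if (is.null(sample_ids)) sprintf("S%02d", i) else sample_ids[i],
      volume_metallic_mm3 = r$volume_metallic,
      volume_degraded_mm3 = r$volume_degraded,
      volume_severe_mm3 = r$volume_severe,
      fraction_degraded = r$fraction_degraded,
      surface_area_mm2 = r$surface_area,
      luminal_mm3 = if (is.null(rv)) NA_real_ else rv[["luminal"]],
      lateral_mm3 = if (is.null(rv)) NA_real_ else rv[["lateral"]],
      abluminal_mm3 = if (is.null(rv)) NA_real_ else rv[["abluminal"]],
      luminal_abluminal_ratio = as.numeric(r$luminal_abluminal_ratio))
  }))
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.csv(df, path, row.names = FALSE)
  } else if (ext == "json") {
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA)
  } else stop("unsupported report format: .", ext)
  invisible(df)
}
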