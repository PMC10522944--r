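#' Merge vertically overlapping scans into a single volume
#'
#' Concatenates a bottom-to-top series of scans along the stacking axis.
#' Adjacent scans share a nominal overlap; the overlap region is filled by
#' a linear blend, which reduces seams under slight intensity drift and is
#' exactly the identity when the overlapping data agree. With
#' `refine = TRUE` the per-pair overlap is adjusted by maximizing the
#' normalized cross-correlation over +/- `search` slices around the
#' nominal value (computed on a central lateral crop); if no candidate
#' reaches correlation 0.5 a warning is raised and the nominal overlap is
#' used.
#'
#' @param series A `scan_series` (see [split_scans()]), or a plain list of
#'   [grey_volume()]s (then `overlap` must be given).
#' @param refine Refine each pair overlap by cross-correlation.
#' @param overlap Nominal overlap in um (only needed for a plain list).
#' @param search Half-width of the refinement search window, in slices.
#' @return A single [grey_volume()] of height
#'   `sum(heights) - (n - 1) * overlap_slices` (with per-pair refined
#'   overlaps when requested).
#' @export
stitch_scans <- function(series, refine = FALSE, overlap = NULL, search = 10L) {
  if (inherits(series, "scan_series")) {
    scans <- series$scans
    overlap <- series$nominal_overlap
  } else {
    scans <- series
    if (is.null(overlap)) stop("overlap (um) required for a plain scan list")
  }
  stopifnot(length(scans) >= 1, all(vapply(scans, is_grey_volume, TRUE)))
  if (length(scans) == 1L) return(scans[[1]])
  vs <- scans[[1]]$voxel_size
  lat <- dim(scans[[1]]$data)[2:3]
  for (s in scans) {
    if (s$voxel_size != vs) stop("scans must share voxel_size")
    if (!identical(dim(s$data)[2:3], lat)) stop("scans must share lateral dimensions")
    if (dim(s$data)[1] <= round(overlap / vs))
      stop("nominal overlap is not smaller than every scan height")
  }
  ov_nom <- as.integer(round(overlap / vs))

  out <- scans[[1]]$data
  for (i in 2:length(scans)) {
    nxt <- scans[[i]]$data
    ov <- ov_nom
    if (refine && ov_nom > 0L) {
      ov <- refine_overlap(out, nxt, ov_nom, search)
    }
    if (ov > 0L) {
      ha <- dim(out)[1]
      a <- out[(ha - ov + 1L):ha, , , drop = FALSE]
      b <- nxt[1:ov, , , drop = FALSE]
      w <- if (ov == 1L) 0.5 else (seq_len(ov) - 1) / (ov - 1)
      blend <- a * (1 - w) + b * w   # w recycles along axis 1
      out[(ha - ov + 1L):ha, , ] <- as.integer(round(blend))
      out <- abind_axis1(out, nxt[(ov + 1L):dim(nxt)[1], , , drop = FALSE])
    } else {
      out <- abind_axis1(out, nxt)
    }
  }
  grey_volume(out, vs, scans[[1]]$metadata)
}

# concatenate two 3D arrays along axis 1
abind_axis1 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0L, dim = c(da[1] + db[1], da[2], da[3]))
  out[seq_len(da[1]), , ] <- a
  out[da[1] + seq_len(db[1]), , ] <- b
  out
}

# best overlap (slices) between the top of `bottom` and the base of `top`
# by normalized cross-correlation on a central lateral crop
refine_overlap <- function(bottom, top, ov_nom, search) {
  hb <- dim(bottom)[1]; ht <- dim(top)[1]
  lat <- dim(bottom)[2:3]
  cy <- seq.int(floor(lat[1] / 4) + 1L, floor(3 * lat[1] / 4))
  cz <- seq.int(floor(lat[2] / 4) + 1L, floor(3 * lat[2] / 4))
  best_ov <- ov_nom
  best_cc <- -Inf
  for (s in -search:search) {
    ov <- ov_nom + s
    if (ov < 1L || ov >= hb || ov >= ht) next
    a <- as.vector(bottom[(hb - ov + 1L):hb, cy, cz])
    b <- as.vector(top[1:ov, cy, cz])
    if (stats::sd(a) == 0 || stats::sd(b) == 0) next
    cc <- stats::cor(a, b)
    if (cc > best_cc) { best_cc <- cc; best_ov <- ov }
  }
  if (!is.finite(best_cc) || best_cc < 0.5) {
    warning("overlap refinement found no correlation above 0.5; ",
            "falling back to the nominal overlap")
    return(ov_nom)
  }
  as.integer(best_ov)
}

#' Rescale a volume to the full 16-bit range
#'
#' Linear rescale of the intensity window `[P_low, P_high]` (percentiles)
#' to `[0, 65535]`, clipping outside the window. With clips `(0, 100)` on
#' data already spanning the full 16-bit range this is the identity. The
#' mapping is monotone within the clipped range. A constant-valued volume
#' maps to all zeros with a warning.
#'
#' @param volume A [grey_volume()] or a plain numeric 3D array.
#' @param clip_low,clip_high Percentiles in `[0, 100]`, `clip_low < clip_high`.
#'   Defaults `(0.1, 99.9)` are robust to hot pixels.
#' @param voxel_size Voxel size in um (only needed for a plain array).
#' @return A [grey_volume()].
#' @export
to_uint16 <- function(volume, clip_low = 0.1, clip_high = 99.9,
                      voxel_size = NULL) {
  if (is_grey_volume(volume)) {
    data <- volume$data
    voxel_size <- volume$voxel_size
    md <- volume$metadata
  } else {
    stopifnot(is.array(volume), length(dim(volume)) == 3,
              !is.null(voxel_size))
    data <- volume
    md <- list()
  }
  if (!(clip_low >= 0 && clip_high <= 100 && clip_low < clip_high))
    stop("clips must satisfy 0 <= clip_low < clip_high <= 100")
  p <- stats::quantile(data, c(clip_low, clip_high) / 100, names = FALSE)
  if (p[1] == p[2]) {
    warning("constant-valued volume: mapping to zero")
    out <- array(0L, dim = dim(data))
    return(grey_volume(out, voxel_size, md))
  }
  scaled <- (pmin(pmax(as.numeric(data), p[1]), p[2]) - p[1]) /
    (p[2] - p[1]) * 65535
  out <- as.integer(round(scaled))
  dim(out) <- dim(data)
  grey_volume(out, voxel_size, md)
}
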