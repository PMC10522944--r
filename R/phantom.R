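#' Parametric scaffold phantom specification
#'
#' Describes a synthetic crown-and-link magnesium scaffold, its degradation
#' state and the imaging model used to render it. Defaults follow the
#' geometry of a laser-cut coronary scaffold expanded in a vessel:
#' 15 mm long, 8 crowns per ring, 12 axial links, 130 um wall thickness,
#' imaged at an isotropic voxel size of 3.07 um. The degradation defaults
#' emulate the morphology seen in explants after four weeks: slight
#' (conversion-layer) degradation growing from the strut surface inward and
#' concentrated at crown bends, plus a few randomly placed severely
#' degraded regions that swell beyond the original strut envelope and
#' crack open.
#'
#' @param scaffold_length Scaffold length in mm.
#' @param outer_diameter Outer diameter of the (expanded) scaffold in mm.
#' @param wall_thickness Strut wall thickness in um (radial extent).
#' @param strut_width Strut width in um (in the shell surface).
#' @param n_crowns Sinusoid peaks per ring.
#' @param n_links Number of axial links around the circumference.
#' @param voxel_size Isotropic voxel edge in um.
#' @param slight_degradation_fraction Fraction of the solid scaffold volume
#'   converted to the degraded phase (label 2), in `[0, 1]`.
#' @param curvature_bias Non-negative weight concentrating slight
#'   degradation at the highly bent crown regions; 0 = uniform.
#' @param n_severe_blobs Number of severely degraded regions (label 3).
#' @param severe_blob_radius Radius of each severe region in um.
#' @param phase_grey_means Named numeric vector of mean 16-bit intensities
#'   for phases `background`, `metallic`, `degraded`, `severe`. Metallic Mg
#'   is the brightest phase; values must be pairwise distinct.
#' @param noise_sd Gaussian noise standard deviation (intensity units).
#' @param psf_sigma Gaussian point-spread sigma in um.
#' @param crack_texture Carve thin cracks through severe regions so the
#'   rendered blobs look broken up.
#' @param seed Integer seed; all stochastic phantom operations are
#'   reproducible given the spec.
#'
#' @return A validated object of class `phantom_spec`.
#' @examples
#' spec <- phantom_spec(scaffold_length = 0.4, outer_diameter = 0.3,
#'                      wall_thickness = 60, strut_width = 50,
#'                      n_crowns = 3, n_links = 3)
#' spec$voxel_size
#' @export
phantom_spec <- function(scaffold_length = 15,
                         outer_diameter = 3.0,
                         wall_thickness = 130,
                         strut_width = 130,
                         n_crowns = 8,
                         n_links = 12,
                         voxel_size = 3.07,
                         slight_degradation_fraction = 0.4,
                         curvature_bias = 4,
                         n_severe_blobs = 2,
                         severe_blob_radius = 120,
                         phase_grey_means = c(background = 12000,
                                              severe = 28000,
                                              degraded = 40000,
                                              metallic = 52000),
                         noise_sd = 800,
                         psf_sigma = 3,
                         crack_texture = TRUE,
                         seed = 1L) {
  spec <- structure(
    list(scaffold_length = scaffold_length,
         outer_diameter = outer_diameter,
         wall_thickness = wall_thickness,
         strut_width = strut_width,
         n_crowns = as.integer(n_crowns),
         n_links = as.integer(n_links),
         voxel_size = voxel_size,
         slight_degradation_fraction = slight_degradation_fraction,
         curvature_bias = curvature_bias,
         n_severe_blobs = as.integer(n_severe_blobs),
         severe_blob_radius = severe_blob_radius,
         phase_grey_means = phase_grey_means,
         noise_sd = noise_sd,
         psf_sigma = psf_sigma,
         crack_texture = isTRUE(crack_texture),
         seed = as.integer(seed)),
    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (!is.numeric(scaffold_length) || scaffold_length <= 0)
      stop("scaffold_length must be positive (mm)")
    if (outer_diameter <= 0) stop("outer_diameter must be positive (mm)")
    if (voxel_size <= 0) stop("voxel_size must be positive (um)")
    if (wall_thickness >= outer_diameter / 2 * 1000)
      stop("wall_thickness must be smaller than the outer radius")
    if (wall_thickness / voxel_size < 2 || strut_width / voxel_size < 2)
      stop("strut cross-section below 2 voxels: undersampled geometry; ",
           "reduce voxel_size or enlarge the struts")
    if (n_crowns < 1 || n_links < 0) stop("n_crowns >= 1 and n_links >= 0 required")
    if (slight_degradation_fraction < 0 || slight_degradation_fraction > 1)
      stop("slight_degradation_fraction must be in [0, 1]")
    if (curvature_bias < 0) stop("curvature_bias must be >= 0")
    if (n_severe_blobs < 0 || severe_blob_radius < 0)
      stop("n_severe_blobs and severe_blob_radius must be >= 0")
    req <- c("background", "metallic", "degraded", "severe")
    if (!all(req %in% names(phase_grey_means)))
      stop("phase_grey_means must name: ", paste(req, collapse = ", "))
    pg <- phase_grey_means[req]
    if (any(pg < 0) || any(pg > 65535)) stop("grey means must be in [0, 65535]")
    if (anyDuplicated(pg)) stop("phase grey means must be pairwise distinct")
    if (noise_sd < 0 || psf_sigma < 0)
      stop("noise_sd and psf_sigma must be >= 0")
  })
  invisible(spec)
}

# run code with a private, restorable RNG stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Lateral (in-plane) coordinate maps shared by geometry and degradation:
# radius (um), angle, and the normalized bend-curvature of the sinusoidal
# rings |sin(n_crowns * theta)| (1 at crown apices, 0 on straight segments).
phantom_lateral_maps <- function(spec, ny, nz) {
  cy <- (ny + 1) / 2
  cz <- (nz + 1) / 2
  y <- (seq_len(ny) - cy) * spec$voxel_size
  z <- (seq_len(nz) - cz) * spec$voxel_size
  r <- sqrt(outer(y^2, z^2, "+"))
  theta <- atan2(rep(z, each = ny), rep(y, times = nz))
  dim(theta) <- c(ny, nz)
  list(r = r, theta = theta,
       curvature = abs(sin(spec$n_crowns * theta)))
}

phantom_dims <- function(spec) {
  nx <- max(1L, as.integer(round(spec$scaffold_length * 1000 / spec$voxel_size)))
  r_out_vox <- ceiling(spec$outer_diameter / 2 * 1000 / spec$voxel_size)
  lat <- as.integer(2 * r_out_vox + 9)
  c(nx, lat, lat)
}

# number of crown rings: one ring per ~1.2 mm of scaffold length, at
# least two so that links always have two rings to connect
phantom_n_rings <- function(spec) {
  max(2L, as.integer(round(spec$scaffold_length / 1.2)))
}

#' Build the metallic scaffold geometry
#'
#' Voxelizes a crown-and-link scaffold: sinusoidal rings (`n_crowns` peaks
#' per ring) living on a cylindrical shell of the given wall thickness,
#' connected by `n_links` axial bridges. The scaffold axis is array axis 1
#' (the stacking direction). Deterministic for a given spec.
#'
#' @param spec A [phantom_spec()].
#' @return A [label_volume()] containing labels 0 (background) and
#'   1 (metallic Mg) only.
#' @examples
#' spec <- phantom_spec(scaffold_length = 0.25, outer_diameter = 0.28,
#'                      wall_thickness = 60, strut_width = 50,
#'                      n_crowns = 3, n_links = 3, n_severe_blobs = 0)
#' geo <- build_scaffold_geometry(spec)
#' table(geo$data)
#' @export
build_scaffold_geometry <- function(spec) {
  validate_phantom_spec(spec)
  d <- phantom_dims(spec)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  maps <- phantom_lateral_maps(spec, ny, nz)

  r_out <- spec$outer_diameter / 2 * 1000       # um
  r_in <- r_out - spec$wall_thickness
  r_mid <- (r_out + r_in) / 2
  shell <- maps$r >= r_in & maps$r <= r_out

  n_rings <- phantom_n_rings(spec)
  length_um <- spec$scaffold_length * 1000
  pitch <- length_um / n_rings
  amp <- pitch / 2                               # ring-to-ring half-pitch
  x1 <- pitch / 2                                # first ring centre (um)

  # sinusoidal ring offset and slope-corrected half-width, per lateral pixel
  offs <- amp * sin(spec$n_crowns * maps$theta)
  slope <- amp * spec$n_crowns * cos(spec$n_crowns * maps$theta) / r_mid
  halfw <- (spec$strut_width / 2) * sqrt(1 + slope^2)

  # link bands: axial bars at n_links angular positions
  link_band <- matrix(FALSE, ny, nz)
  if (spec$n_links > 0) {
    half_ang <- (spec$strut_width / 2) / r_mid
    th_links <- -pi + (seq_len(spec$n_links) - 0.5) * 2 * pi / spec$n_links
    for (tl in th_links) {
      dth <- abs(((maps$theta - tl + pi) %% (2 * pi)) - pi)
      link_band <- link_band | (dth <= half_ang)
    }
  }
  link_lo <- -spec$strut_width / 2
  link_hi <- (n_rings - 1) * pitch + spec$strut_width / 2

  arr <- array(0L, dim = c(nx, ny, nz))
  x_um <- (seq_len(nx) - 0.5) * spec$voxel_size
  for (ix in seq_len(nx)) {
    u <- x_um[ix] - offs - x1                    # axial dist to ring 1 curve
    j <- pmin(pmax(round(u / pitch), 0), n_rings - 1)
    dring <- abs(u - j * pitch)
    on_ring <- dring <= halfw
    on_link <- link_band & u >= link_lo & u <= link_hi
    slice <- shell & (on_ring | on_link)
    arr[ix, , ] <- as.integer(slice)
  }
  if (sum(arr) == 0L) stop("spec produced an empty scaffold geometry")
  label_volume(arr, spec$voxel_size, axis_hint = c(1, 0, 0))
}

#' Apply slight and severe degradation to a scaffold geometry
#'
#' Converts a curvature-biased, surface-inward subset of metallic voxels to
#' the degraded phase (label 2) and places seeded spherical severely
#' degraded regions (label 3) that dilate beyond the original strut
#' envelope and, optionally, crack open. Slight degradation grows from the
#' strut surface inward: a voxel is converted when its depth below the
#' strut surface falls under a bend-weighted threshold, so label 2 always
#' forms layers between background and remaining metal. The label-2 volume
#' fraction of the solid scaffold matches `slight_degradation_fraction`
#' up to label ties.
#'
#' @param geometry A [label_volume()] containing labels 0/1 only.
#' @param spec The [phantom_spec()] that generated it.
#' @return A [label_volume()] with labels in `{0, 1, 2, 3}`.
#' @export
apply_degradation <- function(geometry, spec) {
  stopifnot(is_label_volume(geometry))
  validate_phantom_spec(spec)
  lab <- geometry$data
  if (!all(unique(as.vector(lab)) %in% c(0L, 1L)))
    stop("geometry must contain labels {0, 1} only")
  if (sum(lab == 1L) == 0L) stop("geometry has no metallic (label 1) voxels")
  if (spec$slight_degradation_fraction == 0 && spec$n_severe_blobs == 0L)
    return(geometry)

  dims <- dim(lab)
  strut_mask <- lab == 1L

  # depth below the strut surface, on the original geometry
  edt <- cpp_edt_feature(as.integer(strut_mask), dims)
  depth <- edt$dist
  dim(depth) <- dims

  with_seed(spec$seed + 101L, {
    # severe blobs first: spheres centred on strut voxels, overwriting
    # everything inside (dilation beyond the strut envelope), then cracked
    if (spec$n_severe_blobs > 0L && spec$severe_blob_radius > 0) {
      rad <- spec$severe_blob_radius / spec$voxel_size
      idx1 <- which(strut_mask)
      centers <- idx1[sample.int(length(idx1), min(spec$n_severe_blobs, length(idx1)))]
      for (ci in centers) {
        cc <- arrayInd(ci, dims)
        rg <- lapply(1:3, function(a) {
          max(1L, floor(cc[a] - rad)):min(dims[a], ceiling(cc[a] + rad))
        })
        dx <- rg[[1]] - cc[1]; dy <- rg[[2]] - cc[2]; dz <- rg[[3]] - cc[3]
        d2 <- outer(outer(dx^2, dy^2, "+"), dz^2, "+")
        inside <- d2 <= rad^2
        sub <- lab[rg[[1]], rg[[2]], rg[[3]], drop = FALSE]
        sub[inside] <- 3L
        if (spec$crack_texture) {
          for (k in 1:2) {
            nrm <- stats::rnorm(3)
            nrm <- nrm / sqrt(sum(nrm^2))
            pd <- outer(outer(dx * nrm[1], dy * nrm[2], "+"), dz * nrm[3], "+")
            crack <- inside & abs(pd) <= 0.6
            sub[crack] <- 0L
          }
        }
        lab[rg[[1]], rg[[2]], rg[[3]]] <- sub
      }
    }

    # slight degradation: convert label-1 voxels with smallest
    # depth / (bend weight * jitter) until the target fraction is reached
    f <- spec$slight_degradation_fraction
    if (f > 0) {
      maps <- phantom_lateral_maps(spec, dims[2], dims[3])
      w_lat <- 1 + spec$curvature_bias * maps$curvature
      # piecewise-constant seeded jitter over (axial, angular) sectors,
      # constant along each radial column so layers stay surface-inward
      n_ax <- 12L; n_ang <- 16L
      jit <- matrix(stats::runif(n_ax * n_ang, 0.85, 1.15), n_ax, n_ang)
      ang_bin_lat <- pmin(n_ang, 1L + floor((maps$theta + pi) / (2 * pi) * n_ang))
      cand <- which(lab == 1L)
      ai <- arrayInd(cand, dims)
      ax_bin <- pmin(n_ax, 1L + floor((ai[, 1] - 1) / dims[1] * n_ax))
      lat_lin <- ai[, 2] + dims[2] * (ai[, 3] - 1)
      wgt <- w_lat[lat_lin] * jit[cbind(ax_bin, ang_bin_lat[lat_lin])]
      rho <- depth[cand] / wgt
      solid <- sum(lab != 0L)
      target <- min(length(cand), round(f * solid))
      if (target > 0) {
        thr <- sort(rho, partial = target)[target]
        lab[cand[rho <= thr]] <- 2L
      }
    }
  })
  label_volume(lab, geometry$voxel_size, axis_hint = geometry$axis_hint)
}

#' Render a label volume to grey values
#'
#' Emulates the appearance of a reconstructed phase-contrast slice: each
#' phase is mapped to its mean intensity, convolved with an isotropic
#' Gaussian point-spread function, and corrupted with seeded Gaussian
#' noise, then clipped and quantized to the 16-bit range.
#'
#' @param labels A [label_volume()].
#' @param spec The [phantom_spec()] providing grey means, PSF and noise.
#' @return A [grey_volume()].
#' @export
render_grey <- function(labels, spec) {
  stopifnot(is_label_volume(labels))
  validate_phantom_spec(spec)
  means <- spec$phase_grey_means[c("background", "metallic", "degraded", "severe")]
  img <- means[labels$data + 1L]
  dims <- dim(labels$data)
  dim(img) <- dims
  if (spec$psf_sigma > 0) {
    img <- cpp_gaussian_blur3(img, dims, spec$psf_sigma / spec$voxel_size)
    dim(img) <- dims
  }
  if (spec$noise_sd > 0) {
    img <- img + with_seed(spec$seed + 202L,
                           stats::rnorm(length(img), 0, spec$noise_sd))
    dim(img) <- dims
  }
  img <- round(pmin(pmax(img, 0), 65535))
  grey_volume(img, labels$voxel_size,
              metadata = list(phantom_seed = spec$seed,
                              psf_sigma_um = spec$psf_sigma,
                              noise_sd = spec$noise_sd))
}

#' Generate a complete phantom (geometry, degradation, rendering)
#'
#' Convenience wrapper chaining [build_scaffold_geometry()],
#' [apply_degradation()] and [render_grey()].
#'
#' @param spec A [phantom_spec()].
#' @return List with elements `labels` (ground truth [label_volume()]) and
#'   `grey` (rendered [grey_volume()]).
#' @export
make_phantom <- function(spec) {
  geo <- build_scaffold_geometry(spec)
  labels <- apply_degradation(geo, spec)
  list(labels = labels, grey = render_grey(labels, spec))
}

#' Split a volume into vertically overlapping scans
#'
#' Cuts a volume into `n_scans` vertical blocks along the stacking axis,
#' adjacent blocks sharing `overlap` micrometres (rounded to whole slices),
#' emulating the multi-scan acquisition of a tall sample. The inverse of
#' [stitch_scans()]: stitching the output reproduces the input bit-exactly.
#'
#' @param volume A [grey_volume()].
#' @param n_scans Number of blocks (>= 1).
#' @param overlap Nominal overlap between adjacent blocks in um.
#' @return A `scan_series`: list with `scans` (bottom-to-top list of
#'   [grey_volume()]) and `nominal_overlap` (um).
#' @export
split_scans <- function(volume, n_scans, overlap = 750) {
  stopifnot(is_grey_volume(volume), n_scans >= 1, overlap >= 0)
  n_scans <- as.integer(n_scans)
  H <- dim(volume$data)[1]
  ov <- as.integer(round(overlap / volume$voxel_size))
  if (n_scans == 1L) {
    return(structure(list(scans = list(volume), nominal_overlap = overlap),
                     class = "scan_series"))
  }
  total <- H + (n_scans - 1L) * ov
  base <- total %/% n_scans
  rem <- total %% n_scans
  heights <- rep(base, n_scans) + c(rep(1L, rem), rep(0L, n_scans - rem))
  if (any(heights <= ov))
    stop("overlap too large for the requested number of scans")
  starts <- cumsum(c(1L, heights[-n_scans] - ov))
  scans <- vector("list", n_scans)
  for (i in seq_len(n_scans)) {
    block <- volume$data[starts[i]:(starts[i] + heights[i] - 1L), , , drop = FALSE]
    md <- volume$metadata
    md$scan_index <- i
    md$overlap_slices <- ov
    scans[[i]] <- grey_volume(block, volume$voxel_size, md)
  }
  structure(list(scans = scans, nominal_overlap = overlap),
            class = "scan_series")
}

#' Exact morphometry of a ground-truth label volume
#'
#' Per-phase voxel counting times the voxel volume; the reference against
#' which segmentation-based morphometry is compared. Implemented by direct
#' counting, independently of [phase_volumes()].
#'
#' @param labels A [label_volume()].
#' @return A `morphometry_report` with per-phase volumes (mm^3) and the
#'   degraded fraction.
#' @export
ground_truth_report <- function(labels) {
  stopifnot(is_label_volume(labels))
  vv <- voxel_volume_mm3(labels$voxel_size)
  lab <- labels$data
  v1 <- sum(lab == 1L) * vv
  v2 <- sum(lab == 2L) * vv
  v3 <- sum(lab == 3L) * vv
  solid <- v1 + v2 + v3
  structure(
    list(volume_metallic = v1, volume_degraded = v2, volume_severe = v3,
         fraction_degraded = if (solid > 0) (v2 + v3) / solid else 0,
         fraction_defined = solid > 0,
         surface_area = NA_real_, regional_volumes = NULL,
         luminal_abluminal_ratio = NA_real_,
         voxel_size = labels$voxel_size, source = "ground_truth"),
    class = "morphometry_report")
}
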