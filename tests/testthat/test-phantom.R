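test_that("scaffold geometry has the expected strut radial extent", {
  # 130 um wall at 3.07 um voxels -> radial extent ~ 42 voxels
  spec <- phantom_spec(scaffold_length = 0.1, outer_diameter = 0.4,
                       wall_thickness = 130, strut_width = 110,
                       n_crowns = 3, n_links = 3)
  geo <- build_scaffold_geometry(spec)
  idx <- which(geo$data == 1L)
  expect_gt(length(idx), 0)
  co <- arrayInd(idx, dim(geo$data))
  ctr <- (dim(geo$data)[2:3] + 1) / 2
  r <- sqrt((co[, 2] - ctr[1])^2 + (co[, 3] - ctr[2])^2)
  extent <- (max(r) - min(r)) + 1
  expect_equal(extent, 130 / 3.07, tolerance = 2 / 42)
})

test_that("degenerate or undersampled specs are rejected", {
  expect_error(phantom_spec(scaffold_length = 0), "positive")
  expect_error(phantom_spec(wall_thickness = 5, voxel_size = 3.07),
               "undersampled")
  expect_error(phantom_spec(wall_thickness = 2000, outer_diameter = 3),
               "outer radius")
  expect_error(phantom_spec(phase_grey_means = c(background = 1, metallic = 1,
                                                 degraded = 2, severe = 3)),
               "distinct")
})

test_that("geometry generation is deterministic", {
  spec <- small_phantom_spec(seed = 3)
  expect_identical(build_scaffold_geometry(spec)$data,
                   build_scaffold_geometry(spec)$data)
})

test_that("degradation without slight fraction or blobs is the identity", {
  spec <- small_phantom_spec(slight_degradation_fraction = 0,
                             n_severe_blobs = 0)
  geo <- build_scaffold_geometry(spec)
  expect_identical(apply_degradation(geo, spec)$data, geo$data)
})

test_that("degradation is seeded and bit-reproducible", {
  spec <- small_phantom_spec(seed = 11)
  geo <- build_scaffold_geometry(spec)
  expect_identical(apply_degradation(geo, spec)$data,
                   apply_degradation(geo, spec)$data)
})

test_that("degraded volume fraction tracks the requested fraction", {
  spec <- small_phantom_spec(slight_degradation_fraction = 0.4,
                             n_severe_blobs = 0, seed = 7)
  lab <- apply_degradation(build_scaffold_geometry(spec), spec)
  counts <- tabulate(lab$data + 1L, 4L)
  frac <- counts[3] / sum(counts[2:4])
  expect_gte(frac, 0.36)
  expect_lte(frac, 0.44)
})

test_that("degradation never converts background to metal or degraded", {
  spec <- small_phantom_spec(seed = 5)
  geo <- build_scaffold_geometry(spec)
  lab <- apply_degradation(geo, spec)
  was_bg <- geo$data == 0L
  expect_false(any(lab$data[was_bg] %in% c(1L, 2L)))
  # label 3 may expand into background (blob dilation), nothing else may
  expect_true(all(lab$data[was_bg] %in% c(0L, 3L)))
})

test_that("slight degradation is layered surface-inward along radial rays", {
  spec <- small_phantom_spec(n_severe_blobs = 0, seed = 5)
  lab <- apply_degradation(build_scaffold_geometry(spec), spec)
  d <- dim(lab$data)
  ctr <- (d[2:3] + 1) / 2
  viol <- 0L; runs <- 0L
  for (ix in seq.int(2L, d[1] - 1L, by = 5L)) {
    for (ang in seq(0, 2 * pi, length.out = 25)[-25]) {
      rr <- seq(1, d[2] / 2 - 1, by = 0.5)
      iy <- round(ctr[1] + rr * cos(ang))
      iz <- round(ctr[2] + rr * sin(ang))
      ok <- iy >= 1 & iy <= d[2] & iz >= 1 & iz <= d[3]
      v <- lab$data[cbind(ix, iy[ok], iz[ok])]
      solid <- which(v %in% c(1L, 2L))
      if (!length(solid)) next
      grp <- split(solid, cumsum(c(1, diff(solid) != 1)))
      outer_run <- grp[[length(grp)]]
      if (any(v[outer_run] == 2L)) {
        runs <- runs + 1L
        # entering from the background, label 2 must come before label 1
        if (v[outer_run[length(outer_run)]] == 1L) viol <- viol + 1L
      }
    }
  }
  expect_gt(runs, 50)
  expect_identical(viol, 0L)
})

test_that("degradation rejects invalid geometry", {
  spec <- small_phantom_spec()
  empty <- label_volume(array(0L, c(8, 8, 8)), spec$voxel_size)
  expect_error(apply_degradation(empty, spec), "no metallic")
  with2 <- label_volume(array(2L, c(4, 4, 4)), spec$voxel_size)
  expect_error(apply_degradation(with2, spec), "labels \\{0, 1\\}")
})

test_that("noise-free, blur-free rendering reproduces the phase mean map", {
  spec <- small_phantom_spec(noise = FALSE, seed = 2)
  lab <- apply_degradation(build_scaffold_geometry(spec), spec)
  g <- render_grey(lab, spec)
  means <- spec$phase_grey_means[c("background", "metallic", "degraded", "severe")]
  expected <- array(as.integer(means[lab$data + 1L]), dim = dim(lab$data))
  expect_identical(g$data, expected)
})

test_that("rendering is seeded and bit-reproducible", {
  spec <- small_phantom_spec(seed = 4)
  lab <- apply_degradation(build_scaffold_geometry(spec), spec)
  expect_identical(render_grey(lab, spec)$data, render_grey(lab, spec)$data)
})

test_that("phase intensity histograms separate cleanly at low noise", {
  # mean separation 10000 with noise sd 100: nearest-mean classification
  # of the rendered intensities must misassign fewer than 0.1% of voxels
  spec <- small_phantom_spec(
    noise_sd = 100, psf_sigma = 0, seed = 6,
    phase_grey_means = c(background = 10000, severe = 20000,
                         degraded = 30000, metallic = 40000))
  lab <- apply_degradation(build_scaffold_geometry(spec), spec)
  g <- render_grey(lab, spec)
  means <- c(10000, 40000, 30000, 20000) # by label 0..3
  nearest <- apply(abs(outer(as.vector(g$data), means, "-")), 1, which.min) - 1L
  overlap <- mean(nearest != as.vector(lab$data))
  expect_lt(overlap, 0.001)
})

test_that("split_scans produces the documented block arithmetic", {
  # one scan: identity
  v <- grey_volume(array(7L, c(10, 3, 3)), 3.07)
  s1 <- split_scans(v, 1, 750)
  expect_identical(s1$scans[[1]]$data, v$data)
  # 3852 slices, 2 scans, 750 um at 3.07 um (= 244 slices): 2048 + 2048
  tall <- grey_volume(array(0L, c(3852, 2, 2)), 3.07)
  s2 <- split_scans(tall, 2, 750)
  heights <- vapply(s2$scans, function(s) dim(s$data)[1], 1L)
  expect_identical(heights, c(2048L, 2048L))
  expect_identical(sum(heights) - 244L, 3852L)
  # overlap too large: 10 slices into 4 scans sharing 8 slices each
  expect_error(split_scans(grey_volume(array(0L, c(10, 2, 2)), 1), 4,
                           overlap = 8), "overlap too large")
})

test_that("split then stitch is a bit-exact round trip", {
  set.seed(42)
  arr <- array(sample.int(65536, 60 * 5 * 4, replace = TRUE) - 1L,
               c(60, 5, 4))
  v <- grey_volume(arr, 3.07)
  for (n in c(2, 3)) {
    series <- split_scans(v, n, overlap = 10 * 3.07)
    expect_identical(stitch_scans(series)$data, v$data)
  }
})

test_that("ground-truth morphometry counts voxels exactly", {
  empty <- label_volume(array(0L, c(5, 5, 5)), 3.07)
  r0 <- ground_truth_report(empty)
  expect_identical(r0$volume_metallic, 0)
  expect_identical(r0$volume_degraded, 0)
  expect_identical(r0$volume_severe, 0)
  expect_false(r0$fraction_defined)

  # 10^6 metallic voxels at 3.07 um -> 2.8934e-2 mm^3
  big <- label_volume(array(1L, c(100, 100, 100)), 3.07)
  r1 <- ground_truth_report(big)
  expect_equal(r1$volume_metallic, (3.07e-3)^3 * 1e6, tolerance = 1e-12)
  expect_equal(round(r1$volume_metallic, 4), 0.0289)

  # conservation: volumes sum to nonzero voxel count x voxel volume
  spec <- small_phantom_spec(seed = 8)
  lab <- apply_degradation(build_scaffold_geometry(spec), spec)
  r2 <- ground_truth_report(lab)
  vv <- (3.07e-3)^3
  expect_equal(r2$volume_metallic + r2$volume_degraded + r2$volume_severe,
               sum(lab$data != 0L) * vv, tolerance = 1e-12)
})
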