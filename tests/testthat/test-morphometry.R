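test_that("phase volumes count voxels exactly and match the phantom oracle", {
  # 10^6 degraded voxels at 3.07 um -> 2.894e-2 mm^3
  big <- label_volume(array(2L, c(100, 100, 100)), 3.07)
  r <- phase_volumes(big)
  expect_equal(r$volume_degraded, (3.07e-3)^3 * 1e6, tolerance = 1e-12)
  expect_equal(r$fraction_degraded, 1)

  empty <- label_volume(array(0L, c(4, 4, 4)), 3.07)
  r0 <- phase_volumes(empty)
  expect_identical(r0$volume_metallic, 0)
  expect_false(r0$fraction_defined)
  expect_identical(r0$fraction_degraded, 0)

  spec <- small_phantom_spec(seed = 9)
  lab <- apply_degradation(build_scaffold_geometry(spec), spec)
  a <- phase_volumes(lab)
  b <- ground_truth_report(lab)
  for (f in c("volume_metallic", "volume_degraded", "volume_severe",
              "fraction_degraded")) {
    expect_identical(a[[f]], b[[f]])
  }
})

test_that("cylinder surface area matches the closed form within 5%", {
  cyl <- cylinder_labels(radius = 50, height = 200, voxel = 1000)
  a <- surface_area(cyl, 1)           # 1 mm voxels: mm^2 == voxel^2
  analytic <- 2 * pi * 50 * 200 + 2 * pi * 50^2
  expect_equal(a, analytic, tolerance = 0.05)
})

test_that("surface area scales with the voxel size squared", {
  cyl <- cylinder_labels(radius = 12, height = 30, voxel = 3.07)
  a1 <- surface_area(cyl, 1)
  cyl2 <- label_volume(cyl$data, 2 * 3.07)
  expect_equal(surface_area(cyl2, 1), 4 * a1, tolerance = 1e-12)
})

test_that("empty masks have zero area and cannot be meshed", {
  empty <- label_volume(array(0L, c(4, 4, 4)), 1)
  expect_identical(surface_area(empty), 0)
  expect_error(export_mesh(empty, tempfile(fileext = ".stl")), "empty mask")
})

test_that("the scaffold axis is recovered within one degree", {
  cyl <- cylinder_labels(radius = 15, height = 80, voxel = 1)
  ax <- estimate_axis(cyl)
  ang <- acos(abs(sum(ax$direction * c(1, 0, 0)))) * 180 / pi
  expect_lt(ang, 1)

  # same cylinder rotated 30 degrees in the xy-plane, built analytically
  th <- 30 * pi / 180
  n <- 96
  ctr <- (n + 1) / 2
  arr <- array(0L, c(n, n, n))
  co <- as.matrix(expand.grid(x = 1:n, y = 1:n, z = 1:n)) - ctr
  u <- c(cos(th), sin(th), 0)
  proj <- co %*% u
  rad2 <- rowSums(co^2) - proj^2
  inside <- abs(proj) <= 40 & rad2 <= 15^2
  arr[inside] <- 1L
  rot <- label_volume(arr, 1)
  ax2 <- estimate_axis(rot)
  ang2 <- acos(abs(sum(ax2$direction * u))) * 180 / pi
  expect_lt(ang2, 1)

  expect_error(estimate_axis(label_volume(array(0L, c(5, 5, 5)), 1)),
               "at least 100")
})

test_that("outer-surface degradation is classified abluminal", {
  sh <- shell_labels(r_out = 30, thickness = 10, height = 60, outer_skin = 2)
  rv <- partition_strut_regions(sh, axis = structure(
    list(point = (dim(sh$data) + 1) / 2, direction = c(1, 0, 0)),
    class = "scaffold_axis"))
  expect_gte(rv[["abluminal"]] / sum(rv), 0.9)
  # regional volumes sum exactly to the label-2 volume
  expect_equal(sum(rv), sum(sh$data == 2L) * (3.07e-3)^3, tolerance = 1e-12)
})

test_that("inner-surface degradation is classified luminal", {
  sh <- shell_labels(r_out = 30, thickness = 10, height = 60, inner_skin = 2)
  rv <- partition_strut_regions(sh)
  expect_gte(rv[["luminal"]] / sum(rv), 0.9)
})

test_that("symmetric degradation gives a luminal:abluminal ratio near one", {
  # thin shell: luminal and abluminal faces have comparable areas
  sh <- shell_labels(r_out = 60, thickness = 6, height = 40,
                     outer_skin = 2, inner_skin = 2)
  rv <- partition_strut_regions(sh)
  ratio <- luminal_abluminal_ratio(rv)
  expect_gte(ratio, 0.9)
  expect_lte(ratio, 1.1)
})

test_that("the regional partition is invariant under rotation about the axis", {
  spec <- small_phantom_spec(seed = 13, n_severe_blobs = 0)
  lab <- apply_degradation(build_scaffold_geometry(spec), spec)
  rv <- partition_strut_regions(lab)
  # quarter-turn about the scaffold axis maps the voxel grid onto itself
  rot <- label_volume(aperm(lab$data[, , rev(seq_len(dim(lab$data)[3]))],
                            c(1, 3, 2)), lab$voxel_size)
  rv_rot <- partition_strut_regions(rot)
  for (f in names(rv)) {
    expect_equal(rv_rot[[f]], rv[[f]], tolerance = 0.02)
  }
})

test_that("the luminal:abluminal ratio follows its definition", {
  expect_equal(luminal_abluminal_ratio(c(luminal = 1, lateral = 0,
                                         abluminal = 1)), 1)
  expect_equal(luminal_abluminal_ratio(c(luminal = 2, lateral = 5,
                                         abluminal = 1)), 2)
  expect_equal(luminal_abluminal_ratio(c(luminal = 0.7, lateral = 0,
                                         abluminal = 0.3)), 7 / 3,
               tolerance = 1e-12)
  und <- luminal_abluminal_ratio(c(luminal = 1, lateral = 0, abluminal = 0))
  expect_true(is.na(und))
  expect_true(attr(und, "undefined"))
})

test_that("severely degraded voxels are excluded from the regional analysis", {
  sh <- shell_labels(r_out = 20, thickness = 8, height = 30, outer_skin = 2)
  with3 <- sh$data
  sl <- with3[15, , ]
  sl[sl == 1L] <- 3L
  with3[15, , ] <- sl
  v3 <- label_volume(with3, sh$voxel_size)
  rv <- partition_strut_regions(v3)
  expect_equal(sum(rv), sum(v3$data == 2L) * (3.07e-3)^3, tolerance = 1e-12)
})

test_that("mesh export writes a watertight mesh matching the reported area", {
  cube <- array(0L, c(10, 10, 10))
  cube[3:8, 3:8, 3:8] <- 1L
  lv <- label_volume(cube, 2)
  stl <- tempfile(fileext = ".stl")
  ply <- tempfile(fileext = ".ply")
  mesh <- export_mesh(lv, stl, phase_set = 1)
  export_mesh(lv, ply, phase_set = 1)
  # ball topology: Euler characteristic 2
  expect_identical(mgscaffold:::mesh_euler_characteristic(
    mgscaffold:::isosurface_mesh(lv, 1)), 2L)
  # exported mesh area equals surface_area (same mesh, mm^2)
  area_mesh <- mgscaffold:::mesh_area(mesh)
  expect_equal(area_mesh, surface_area(lv, 1), tolerance = 1e-9)
  # STL round trip preserves the triangle count and total area
  tri <- mgscaffold:::read_stl_binary(stl)
  expect_identical(nrow(tri), nrow(mesh$faces))
  a <- tri[, 4:6] - tri[, 1:3]
  b <- tri[, 7:9] - tri[, 1:3]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  expect_equal(sum(sqrt(rowSums(cr^2))) / 2, area_mesh, tolerance = 1e-5)
  # PLY header declares the right element counts
  hdr <- readLines(ply, n = 8)
  expect_true(any(grepl(paste("element vertex", nrow(mesh$vertices)), hdr)))
  expect_true(any(grepl(paste("element face", nrow(mesh$faces)), hdr)))
})

test_that("end-to-end segmentation recovers ground-truth degraded volume", {
  for (s in 0:2) {
    res <- e2e_result(s, noise = TRUE)
    expect_gt(res$ref$volume_degraded, 0)
    expect_equal(res$est$volume_degraded, res$ref$volume_degraded,
                 tolerance = 0.10,
                 info = sprintf("seed %d", s))
  }
})
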