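# brute-force tiling enumerator, independent of the package's start-grid
brute_tiles_1d <- function(n, p, ov) {
  starts <- integer(0)
  s <- 1L
  repeat {
    if (s + p - 1L >= n) { starts <- c(starts, n - p + 1L); break }
    starts <- c(starts, s)
    s <- s + (p - ov)
  }
  unique(starts)
}

test_that("orthogonal-plane patch counts match the printed arithmetic", {
  expect_identical(count_patch_pairs(c(800, 800, 800), 800), 2400L)
  expect_identical(6L * count_patch_pairs(c(800, 800, 800), 800), 14400L)
  expect_identical(count_patch_pairs(c(1, 1, 1), 1), 3L)
  expect_identical(count_patch_pairs(c(64, 64, 64), 64), 192L)
})

test_that("actual patch extraction agrees with the closed-form count", {
  set.seed(3)
  g <- grey_volume(array(sample.int(100, 64^3, TRUE), c(64, 64, 64)), 3.07)
  l <- label_volume(array(0L, c(64, 64, 64)), 3.07)
  ps <- extract_patches(g, l, 64)
  expect_identical(length(ps$grey), 192L)
  expect_identical(length(ps$grey), count_patch_pairs(c(64, 64, 64), 64))
  expect_setequal(unique(ps$plane), c("xy", "yz", "xz"))
  # grey and label patches stay congruent
  expect_true(all(mapply(function(a, b) identical(dim(a), dim(b)),
                         ps$grey, ps$label)))
})

test_that("patch counting matches brute-force enumeration with overlaps", {
  set.seed(11)
  for (rep in 1:6) {
    d <- sample(5:17, 3, replace = TRUE)
    p <- sample.int(min(d), 1)
    ov <- sample.int(p, 1) - 1L
    brute <- 0L
    for (ax in 1:3) {
      inplane <- setdiff(1:3, ax)
      brute <- brute + d[ax] *
        length(brute_tiles_1d(d[inplane[1]], p, ov)) *
        length(brute_tiles_1d(d[inplane[2]], p, ov))
    }
    expect_identical(count_patch_pairs(d, p, ov), brute)
    g <- grey_volume(array(0L, d), 1)
    l <- label_volume(array(0L, d), 1)
    expect_identical(length(extract_patches(g, l, p, ov)$grey), brute)
  }
})

test_that("oversized patches and incongruent volumes are rejected", {
  g <- grey_volume(array(0L, c(8, 8, 8)), 1)
  l <- label_volume(array(0L, c(8, 8, 8)), 1)
  expect_error(extract_patches(g, l, 9), "exceeds")
  l2 <- label_volume(array(0L, c(8, 8, 7)), 1)
  expect_error(extract_patches(g, l2, 4), "congruent")
})

test_that("analytic parameter count matches hand-derived layer sums", {
  # tiniest net (1 stage, 1 conv, 2 features, 4-class head):
  # enc 3x3 1->2: 20; bottleneck 3x3 2->4: 76; upconv 2x2 4->2: 34;
  # dec 3x3 4->2: 74; head 1x1 2->4: 12  => 216
  expect_identical(count_parameters(unet_spec(1, 1, 2, 3)), 216L)
  # default architecture (3 stages, 2 convs, 16 base, 4-class head),
  # summed layer by layer by hand: 481,796
  expect_identical(count_parameters(unet_spec()), 481796L)
  # single-layer sanity: 1x1 conv 16->1 with bias is 17 parameters,
  # 3x3 conv 1->16 with bias is 160
  conv_params <- function(k, cin, cout) k^2 * cin * cout + cout
  expect_identical(conv_params(1, 16, 1), 17)
  expect_identical(conv_params(3, 1, 16), 160)
})

test_that("the built network allocates exactly the analytic parameter count", {
  set.seed(21)
  for (rep in 1:5) {
    spec <- unet_spec(n_encoding_stages = sample(1:3, 1),
                      convs_per_stage = sample(1:2, 1),
                      base_features = sample(c(2, 3, 4, 8), 1),
                      kernel_size = sample(c(3, 5), 1))
    for (oc in c(1L, 4L)) {
      arch <- mgscaffold:::unet_arch(spec, oc)
      expect_identical(as.integer(mgscaffold:::cpp_unet_param_count(arch)),
                       count_parameters(spec, oc))
      expect_identical(length(mgscaffold:::cpp_unet_init(arch, 1L)),
                       count_parameters(spec, oc))
    }
  }
})

test_that("backpropagation matches finite-difference gradients", {
  arch <- list(n_encoding_stages = 2L, convs_per_stage = 2L,
               base_features = 3L, kernel_size = 3L, out_channels = 4L)
  set.seed(1)
  p <- mgscaffold:::cpp_unet_init(arch, 42L)
  g <- matrix(rnorm(64), 8, 8)
  l <- matrix(sample(0:3, 64, TRUE), 8, 8)
  storage.mode(l) <- "integer"
  w <- c(1, 2, 1.5, 0.5)
  ana <- mgscaffold:::cpp_unet_loss_grad(p, g, l, arch, w)
  eps <- 1e-6
  idx <- sample(length(p), 25)
  for (i in idx) {
    p1 <- p; p1[i] <- p1[i] + eps
    p2 <- p; p2[i] <- p2[i] - eps
    num <- (mgscaffold:::cpp_unet_loss_grad(p1, g, l, arch, w)$loss -
            mgscaffold:::cpp_unet_loss_grad(p2, g, l, arch, w)$loss) / (2 * eps)
    expect_equal(ana$grad[i], num, tolerance = 1e-4)
  }
})

test_that("training is deterministic for a fixed seed and reduces the loss", {
  set.seed(5)
  mk_patch <- function() {
    l <- matrix(sample(0:3, 64, TRUE), 8, 8)
    storage.mode(l) <- "integer"
    list(g = matrix(10000 * l + rnorm(64, sd = 200), 8, 8), l = l)
  }
  ps <- replicate(6, mk_patch(), simplify = FALSE)
  patches <- structure(list(grey = lapply(ps, `[[`, "g"),
                            label = lapply(ps, `[[`, "l"),
                            plane = rep("xy", 6), slice = 1:6,
                            patch_size = 8L, overlap = 0L),
                       class = "training_patch_set")
  spec <- small_unet_spec(epochs = 8, base_features = 4)
  m1 <- train_unet(patches, spec)
  m2 <- train_unet(patches, spec)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$loss, m2$loss)
  expect_lt(utils::tail(m1$loss[[1]], 1), m1$loss[[1]][1])
})

test_that("a class missing from the training labels triggers a warning", {
  l <- matrix(sample(0:1, 64, TRUE), 8, 8)
  storage.mode(l) <- "integer"
  patches <- structure(list(grey = list(matrix(rnorm(64), 8, 8)),
                            label = list(l), plane = "xy", slice = 1L,
                            patch_size = 8L, overlap = 0L),
                       class = "training_patch_set")
  expect_warning(train_unet(patches, small_unet_spec(epochs = 1,
                                                     base_features = 2)),
                 "absent")
})

test_that("patch dimensions must match the network stride", {
  l <- matrix(0L, 6, 6)
  patches <- structure(list(grey = list(matrix(rnorm(36), 6, 6)),
                            label = list(l), plane = "xy", slice = 1L,
                            patch_size = 6L, overlap = 0L),
                       class = "training_patch_set")
  expect_error(train_unet(patches, small_unet_spec()), "divisible")
})

test_that("stratified subsampling keeps rare classes represented", {
  set.seed(2)
  mk <- function(has3) {
    l <- matrix(sample(0:1, 16, TRUE), 4, 4)
    if (has3) l[1, 1] <- 3L
    storage.mode(l) <- "integer"
    l
  }
  labs <- c(lapply(1:2, function(i) mk(TRUE)),
            lapply(1:40, function(i) mk(FALSE)))
  patches <- structure(list(grey = lapply(labs, function(l) l * 1.0),
                            label = labs, plane = rep("xy", 42),
                            slice = seq_len(42), patch_size = 4L,
                            overlap = 0L),
                       class = "training_patch_set")
  sub <- subsample_patches(patches, 10, seed = 1)
  expect_identical(length(sub$grey), 10L)
  expect_true(any(vapply(sub$label, function(l) any(l == 3L), TRUE)))
})

test_that("dice and IoU follow their set-arithmetic definitions", {
  base <- array(0L, c(4, 4, 4))
  a <- base; a[1:2, , ] <- 1L
  b <- base; b[2:3, , ] <- 1L
  va <- label_volume(a, 1); vb <- label_volume(b, 1)
  same <- evaluate_segmentation(va, va)
  expect_equal(same$dice, rep(1, 4))
  # half-overlapping equal-size masks -> dice 0.5, iou 1/3
  half <- evaluate_segmentation(va, vb)
  expect_equal(half$dice[half$class == 1], 0.5)
  expect_equal(half$iou[half$class == 1], 1 / 3)
  # disjoint masks -> dice 0
  c_ <- base; c_[4, , ] <- 1L
  expect_equal(evaluate_segmentation(va, label_volume(c_, 1))$dice[2], 0)
  # class absent from both scores 1 by convention
  expect_equal(half$dice[half$class == 3], 1)
  expect_error(evaluate_segmentation(va, label_volume(array(0L, c(3, 3, 3)), 1)),
               "shape")
})

test_that("noiseless separable phantoms are segmented near-perfectly", {
  res <- e2e_result(3, noise = FALSE)
  expect_true(all(res$dice$dice >= 0.99))
})

test_that("default noisy phantoms reach high held-out Dice on all classes", {
  for (s in 0:2) {
    res <- e2e_result(s, noise = TRUE)
    expect_true(all(res$dice$dice >= 0.85),
                info = sprintf("seed %d: dice %s", s,
                               paste(round(res$dice$dice, 3), collapse = " ")))
  }
})

test_that("prediction is deterministic and labels a background volume as such", {
  res <- e2e_result(0, noise = TRUE)
  spec <- small_phantom_spec(seed = 30)
  set.seed(77)
  vals <- round(spec$phase_grey_means[["background"]] +
                  stats::rnorm(32^3, 0, spec$noise_sd))
  bg <- grey_volume(array(as.integer(pmax(pmin(vals, 65535), 0)),
                          c(32, 32, 32)), spec$voxel_size)
  p1 <- predict_volume(res$model, bg)
  p2 <- predict_volume(res$model, bg)
  expect_identical(p1$data, p2$data)
  expect_gte(mean(p1$data == 0L), 0.99)
})

test_that("the binary-per-class head trains and fuses to a 4-label volume", {
  spec <- small_phantom_spec(seed = 15, noise = FALSE)
  ph <- cropped_phantom(spec)
  patches <- subsample_patches(extract_patches(ph$grey, ph$labels, 32),
                               100, seed = 4)
  us <- small_unet_spec(epochs = 20, base_features = 4,
                        head_mode = "binary_per_class")
  m <- train_unet(patches, us)
  expect_identical(length(m$params), 3L)
  pred <- predict_volume(m, ph$grey)
  expect_true(all(pred$data %in% 0:3))
  ev <- evaluate_segmentation(pred, ph$labels)
  expect_gt(mean(ev$dice), 0.7)
})
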