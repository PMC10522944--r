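# Desk-scale study conditions shared across the suite: a short
# crown-and-link scaffold at the native 3.07 um voxel size, small enough
# to train and segment in seconds but with all morphological features
# (bent crowns, links, surface-inward degradation, severe blobs, blur,
# noise) present.

small_phantom_spec <- function(seed = 1L, noise = TRUE, ...) {
  args <- list(scaffold_length = 0.2, outer_diameter = 0.22,
               wall_thickness = 45, strut_width = 40,
               n_crowns = 3, n_links = 3,
               n_severe_blobs = 2, severe_blob_radius = 35,
               seed = as.integer(seed))
  if (!noise) {
    args$noise_sd <- 0
    args$psf_sigma <- 0
  }
  do.call(phantom_spec, utils::modifyList(args, list(...)))
}

small_unet_spec <- function(epochs = 50, ...) {
  do.call(unet_spec,
          utils::modifyList(list(n_encoding_stages = 2, base_features = 8,
                                 epochs = epochs, seed = 2L),
                            list(...)))
}

# phantom cropped so every dimension is divisible by the network stride
cropped_phantom <- function(spec, div = 4L) {
  ph <- make_phantom(spec)
  d <- dim(ph$grey$data)
  crop <- lapply(d, function(n) seq_len(n - n %% div))
  list(grey = grey_volume(ph$grey$data[crop[[1]], crop[[2]], crop[[3]]],
                          ph$grey$voxel_size),
       labels = label_volume(ph$labels$data[crop[[1]], crop[[2]], crop[[3]]],
                             ph$labels$voxel_size))
}

# Memoized end-to-end runs (phantom -> render -> train -> predict),
# shared between the segmentation tests and the acceptance suite.
# Training and held-out evaluation use different phantom seeds (split by
# whole volume, never by patch).
.e2e_cache <- new.env(parent = emptyenv())

e2e_result <- function(seed, noise = TRUE) {
  key <- paste0("s", seed, if (noise) "_noisy" else "_clean")
  if (!is.null(.e2e_cache[[key]])) return(.e2e_cache[[key]])
  train <- cropped_phantom(small_phantom_spec(seed = seed, noise = noise))
  heldout <- cropped_phantom(small_phantom_spec(seed = seed + 10L, noise = noise))
  patches <- subsample_patches(extract_patches(train$grey, train$labels, 32),
                               260, seed = 9L)
  model <- train_unet(patches, small_unet_spec(epochs = 60))
  pred <- predict_volume(model, heldout$grey)
  res <- list(model = model,
              pred = pred,
              truth = heldout$labels,
              dice = evaluate_segmentation(pred, heldout$labels),
              est = phase_volumes(pred),
              ref = ground_truth_report(heldout$labels))
  .e2e_cache[[key]] <- res
  res
}

# solid voxelized cylinder along axis 1 (radius/height in voxels)
cylinder_labels <- function(radius = 50, height = 200, margin = 2,
                            label = 1L, voxel = 1000) {
  ny <- nz <- 2L * (radius + margin)
  nx <- height + 2L * margin
  y <- seq_len(ny) - (ny + 1) / 2
  z <- seq_len(nz) - (nz + 1) / 2
  lat <- outer(y^2, z^2, "+") <= radius^2
  arr <- array(0L, c(nx, ny, nz))
  for (i in (margin + 1L):(margin + height)) arr[i, , ] <- as.integer(lat) * label
  label_volume(arr, voxel)
}

# cylindrical shell (tube) with optional degraded skins on the outer
# and/or inner surface, used for the regional-partition constructions
shell_labels <- function(r_out = 30, thickness = 10, height = 60,
                         outer_skin = 0L, inner_skin = 0L, voxel = 3.07) {
  ny <- nz <- 2L * (r_out + 3L)
  nx <- height
  y <- seq_len(ny) - (ny + 1) / 2
  z <- seq_len(nz) - (nz + 1) / 2
  r <- sqrt(outer(y^2, z^2, "+"))
  r_in <- r_out - thickness
  solid <- r <= r_out & r >= r_in
  lab2 <- (outer_skin > 0 & solid & r > r_out - outer_skin) |
          (inner_skin > 0 & solid & r < r_in + inner_skin)
  slice <- ifelse(lab2, 2L, ifelse(solid, 1L, 0L))
  arr <- array(0L, c(nx, ny, nz))
  for (i in seq_len(nx)) arr[i, , ] <- slice
  label_volume(arr, voxel, axis_hint = c(1, 0, 0))
}
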