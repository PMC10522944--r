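#' U-Net architecture specification
#'
#' A compact 2D U-Net: `n_encoding_stages` encoder stages of
#' `convs_per_stage` same-padding convolutions + ReLU each, feature maps
#' starting at `base_features` and doubling after every stage, 2x2
#' max-pooling, a bottleneck at `base_features * 2^n_encoding_stages`
#' features, a mirrored decoder using 2x2 stride-2 up-convolutions and
#' skip concatenations, and a 1x1 output head.
#'
#' Two head modes are available: `multiclass_4` (default) ends in a
#' 4-channel softmax trained with class-weighted cross-entropy;
#' `binary_per_class` reproduces a single-output-channel design as three
#' independent binary (sigmoid) networks, one per material phase, whose
#' predictions are combined by highest probability with background
#' elsewhere.
#'
#' @param n_encoding_stages Encoder stages (>= 1).
#' @param convs_per_stage Convolutions per stage.
#' @param base_features Feature maps in the first stage (doubled per stage).
#' @param kernel_size Convolution kernel edge (odd).
#' @param head_mode `"multiclass_4"` or `"binary_per_class"`.
#' @param loss_name Loss identifier (informational; cross-entropy / BCE).
#' @param learning_rate Adam learning rate.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size (patches).
#' @param class_weights `"sqrt_inverse_frequency"` (default; square-root
#'   tempered inverse class frequency, which counteracts the volumetric
#'   dominance of the background without over-segmenting minority phases
#'   at blurred boundaries), `"inverse_frequency"`, or a numeric vector of
#'   per-class weights.
#' @param seed Integer seed for initialization and shuffling.
#' @return An object of class `unet_spec`.
#' @examples
#' spec <- unet_spec(n_encoding_stages = 2, base_features = 8)
#' count_parameters(spec)
#' @export
unet_spec <- function(n_encoding_stages = 3,
                      convs_per_stage = 2,
                      base_features = 16,
                      kernel_size = 3,
                      head_mode = c("multiclass_4", "binary_per_class"),
                      loss_name = "weighted_cross_entropy",
                      learning_rate = 1e-3,
                      epochs = 20,
                      batch_size = 8,
                      class_weights = "sqrt_inverse_frequency",
                      seed = 1L) {
  head_mode <- match.arg(head_mode)
  spec <- structure(
    list(n_encoding_stages = as.integer(n_encoding_stages),
         convs_per_stage = as.integer(convs_per_stage),
         base_features = as.integer(base_features),
         kernel_size = as.integer(kernel_size),
         head_mode = head_mode,
         loss_name = loss_name,
         learning_rate = learning_rate,
         epochs = as.integer(epochs),
         batch_size = as.integer(batch_size),
         class_weights = class_weights,
         seed = as.integer(seed)),
    class = "unet_spec")
  validate_unet_spec(spec)
  spec
}

validate_unet_spec <- function(spec) {
  with(spec, {
    if (n_encoding_stages < 1) stop("n_encoding_stages must be >= 1")
    if (convs_per_stage < 1) stop("convs_per_stage must be >= 1")
    if (base_features < 1) stop("base_features must be >= 1")
    if (kernel_size %% 2 != 1) stop("kernel_size must be odd")
    if (learning_rate <= 0) stop("learning_rate must be positive")
    if (batch_size < 1) stop("batch_size must be >= 1")
  })
  invisible(spec)
}

# architecture list handed to the C++ side
unet_arch <- function(spec, out_channels) {
  list(n_encoding_stages = spec$n_encoding_stages,
       convs_per_stage = spec$convs_per_stage,
       base_features = spec$base_features,
       kernel_size = spec$kernel_size,
       out_channels = as.integer(out_channels))
}

unet_out_channels <- function(spec) {
  if (spec$head_mode == "multiclass_4") 4L else 1L
}

#' Analytic trainable-parameter count of a U-Net spec
#'
#' Sums, layer by layer, `k^2 * c_in * c_out + c_out` for convolutions
#' (with bias), `2^2 * c_in * c_out + c_out` for the 2x2 up-convolutions
#' and `c_in * c_out + c_out` for the final 1x1 head. The built model's
#' allocated parameter vector has exactly this length (checked in tests
#' against the independent count reported by the network code).
#'
#' @param spec A [unet_spec()].
#' @param out_channels Output channels of the head (default: 4 for the
#'   multiclass head, 1 per network for `binary_per_class`).
#' @return Integer parameter count.
#' @export
count_parameters <- function(spec, out_channels = unet_out_channels(spec)) {
  validate_unet_spec(spec)
  S <- spec$n_encoding_stages
  C <- spec$convs_per_stage
  Fb <- spec$base_features
  k <- spec$kernel_size
  n <- 0
  conv <- function(kk, cin, cout) kk^2 * cin * cout + cout
  ch <- 1
  for (s in seq_len(S)) {
    f <- Fb * 2^(s - 1)
    n <- n + conv(k, ch, f)
    ch <- f
    if (C > 1) n <- n + (C - 1) * conv(k, f, f)
  }
  fb <- Fb * 2^S
  n <- n + conv(k, ch, fb)
  if (C > 1) n <- n + (C - 1) * conv(k, fb, fb)
  ch <- fb
  for (s in seq.int(S, 1)) {
    f <- Fb * 2^(s - 1)
    n <- n + conv(2, ch, f)            # up-convolution
    n <- n + conv(k, 2 * f, f)         # first conv after concatenation
    if (C > 1) n <- n + (C - 1) * conv(k, f, f)
    ch <- f
  }
  n <- n + conv(1, ch, out_channels)   # 1x1 head
  as.integer(n)
}

#' Extract orthogonal-plane training patches
#'
#' Tiles every slice of the three orthogonal plane families of a
#' grey/label volume pair into congruent 2D patches. Partial tiles are
#' taken flush to the volume edge (no padding), so for a cubic volume of
#' side `s` with `patch_size = s` and zero overlap the pair count is
#' `3 * s`.
#'
#' @param grey A [grey_volume()].
#' @param labels A congruent [label_volume()].
#' @param patch_size Patch edge length in voxels.
#' @param overlap Patch overlap in voxels (0 = non-overlapping tiling).
#' @return A `training_patch_set`: list with parallel lists `grey`
#'   (numeric matrices), `label` (integer matrices), and vectors `plane`
#'   (`"xy"`, `"yz"`, `"xz"`) and `slice`.
#' @export
extract_patches <- function(grey, labels, patch_size, overlap = 0) {
  stopifnot(is_grey_volume(grey), is_label_volume(labels))
  if (!identical(dim(grey$data), dim(labels$data)))
    stop("grey and label volumes must be congruent")
  d <- dim(grey$data)
  patch_size <- as.integer(patch_size)
  overlap <- as.integer(overlap)
  if (any(patch_size > d)) stop("patch_size exceeds a volume dimension")
  if (overlap >= patch_size) stop("overlap must be smaller than patch_size")

  g_list <- list(); l_list <- list()
  plane <- character(0); slice <- integer(0)
  # families named by the in-plane axes; slices run along the third axis
  fams <- list(yz = 1L, xz = 2L, xy = 3L)
  for (fam in names(fams)) {
    ax <- fams[[fam]]
    inplane <- setdiff(1:3, ax)
    s1 <- patch_starts(d[inplane[1]], patch_size, overlap)
    s2 <- patch_starts(d[inplane[2]], patch_size, overlap)
    for (k in seq_len(d[ax])) {
      gs <- slice_array(grey$data, ax, k)
      ls <- slice_array(labels$data, ax, k)
      for (a in s1) for (b in s2) {
        ri <- a:(a + patch_size - 1L)
        ci <- b:(b + patch_size - 1L)
        g_list[[length(g_list) + 1L]] <- gs[ri, ci, drop = FALSE]
        l_list[[length(l_list) + 1L]] <- ls[ri, ci, drop = FALSE]
        plane <- c(plane, fam)
        slice <- c(slice, k)
      }
    }
  }
  structure(list(grey = g_list, label = l_list, plane = plane, slice = slice,
                 patch_size = patch_size, overlap = overlap),
            class = "training_patch_set")
}

# flush-to-edge tiling start positions (1-based)
patch_starts <- function(n, p, overlap = 0L) {
  if (p >= n) return(1L)
  step <- p - overlap
  s <- seq.int(1L, n - p + 1L, by = step)
  if (s[length(s)] != n - p + 1L) s <- c(s, n - p + 1L)
  as.integer(s)
}

# 2D slice of a 3D array along axis `ax`
slice_array <- function(arr, ax, k) {
  switch(ax,
         `1` = arr[k, , , drop = TRUE],
         `2` = arr[, k, , drop = TRUE],
         `3` = arr[, , k, drop = TRUE])
}

#' Closed-form orthogonal-plane patch-pair count
#'
#' For a volume of dimensions `(a, b, c)`, patch size `p` and zero
#' overlap, the count is
#' `a * ceil(b/p) * ceil(c/p) + b * ceil(a/p) * ceil(c/p) + c * ceil(a/p) * ceil(b/p)`;
#' general overlaps use the flush-to-edge tiling rule. An 800^3 volume at
#' patch 800 and zero overlap gives 2400 pairs.
#'
#' @param dims Integer vector of volume dimensions (length 3).
#' @param patch_size Patch edge length.
#' @param overlap Patch overlap in voxels.
#' @return Integer pair count.
#' @export
count_patch_pairs <- function(dims, patch_size, overlap = 0) {
  stopifnot(length(dims) == 3)
  if (any(patch_size > dims)) stop("patch_size exceeds a volume dimension")
  tiles <- vapply(dims, function(n) length(patch_starts(n, patch_size,
                                                        as.integer(overlap))), 1L)
  as.integer(dims[1] * tiles[2] * tiles[3] +
             dims[2] * tiles[1] * tiles[3] +
             dims[3] * tiles[1] * tiles[2])
}

#' Seeded subsample of a training patch set
#'
#' Reduces a patch set to at most `n` patches. With
#' `stratify = TRUE` (default) patches containing the rarest classes are
#' kept preferentially, so minority phases (notably the severely degraded
#' blobs, which occupy a tiny volume fraction) stay represented in small
#' training sets; the remainder is filled by a seeded uniform draw.
#'
#' @param patches A `training_patch_set`.
#' @param n Maximum number of patches to keep.
#' @param stratify Prefer patches containing rare classes.
#' @param seed Integer seed for the random fill.
#' @return A `training_patch_set` with at most `n` patches.
#' @export
subsample_patches <- function(patches, n, stratify = TRUE, seed = 1L) {
  stopifnot(inherits(patches, "training_patch_set"))
  np <- length(patches$grey)
  if (np <= n) return(patches)
  keep <- with_seed(seed, {
    if (stratify) {
      counts <- vapply(patches$label,
                       function(l) tabulate(as.vector(l) + 1L, 4L),
                       numeric(4))
      class_tot <- rowSums(counts)
      rare <- order(class_tot)           # rarest class first
      chosen <- integer(0)
      quota <- ceiling(n / 2)
      for (cls in rare) {
        if (class_tot[cls] == 0) next
        has <- setdiff(which(counts[cls, ] > 0), chosen)
        if (!length(has)) next
        take <- min(length(has), max(0, quota - length(chosen)))
        if (take > 0) chosen <- c(chosen, sample(has, take))
      }
      rest <- setdiff(seq_len(np), chosen)
      c(chosen, sample(rest, min(length(rest), n - length(chosen))))
    } else {
      sample.int(np, n)
    }
  })
  for (f in c("grey", "label", "plane", "slice")) patches[[f]] <- patches[[f]][keep]
  patches
}

# normalization + per-class weights from a patch set
patchset_stats <- function(patches, n_classes = 4L) {
  all_g <- unlist(patches$grey)
  mu <- mean(all_g)
  sd_ <- stats::sd(all_g)
  if (sd_ == 0) sd_ <- 1
  counts <- rep(0, n_classes)
  for (l in patches$label) {
    tb <- tabulate(as.vector(l) + 1L, nbins = n_classes)
    counts <- counts + tb
  }
  list(mean = mu, sd = sd_, class_counts = counts)
}

#' Train a U-Net on an orthogonal-plane patch set
#'
#' Patches are z-scored with training-set statistics (stored in the
#' model), classes are weighted by inverse frequency unless explicit
#' weights are given, and optimization uses Adam. Training is
#' single-threaded and fully seeded, so repeated runs with the same spec,
#' data and seed produce identical parameter states.
#'
#' @param patches A `training_patch_set` from [extract_patches()].
#' @param spec A [unet_spec()]. Patch sizes must be divisible by
#'   `2^n_encoding_stages`.
#' @return A `segmentation_model`: architecture echo, learned parameters
#'   (one vector per network), normalization statistics, class weights and
#'   the per-epoch loss history.
#' @export
train_unet <- function(patches, spec) {
  stopifnot(inherits(patches, "training_patch_set"))
  validate_unet_spec(spec)
  div <- 2^spec$n_encoding_stages
  for (g in patches$grey) {
    if (any(dim(g) %% div != 0))
      stop("patch dimensions must be divisible by 2^n_encoding_stages (= ",
           div, ")")
  }
  st <- patchset_stats(patches)
  present <- st$class_counts > 0
  if (!all(present)) {
    warning("class(es) absent from training labels: ",
            paste(which(!present) - 1L, collapse = ", "),
            "; their weights are set to 0")
  }
  greys <- lapply(patches$grey, function(g) (g - st$mean) / st$sd)

  if (spec$head_mode == "multiclass_4") {
    if (is.character(spec$class_weights)) {
      w <- ifelse(st$class_counts > 0,
                  sum(st$class_counts) / pmax(st$class_counts, 1), 0)
      if (identical(spec$class_weights, "sqrt_inverse_frequency")) w <- sqrt(w)
      else if (!identical(spec$class_weights, "inverse_frequency"))
        stop("unknown class_weights rule: ", spec$class_weights)
      w <- w / sum(w[present]) * sum(present)
    } else {
      w <- as.numeric(spec$class_weights)
    }
    labs <- lapply(patches$label, function(l) {
      storage.mode(l) <- "integer"; l
    })
    arch <- unet_arch(spec, 4L)
    params <- cpp_unet_init(arch, spec$seed)
    fit <- cpp_unet_train(params, greys, labs, arch, w, spec$learning_rate,
                          spec$epochs, spec$batch_size, spec$seed + 1L)
    nets <- list(fit)
    arches <- list(arch)
  } else {
    # one binary sigmoid network per material phase (1, 2, 3)
    nets <- list(); arches <- list()
    for (cls in 1:3) {
      labs <- lapply(patches$label, function(l) {
        b <- (l == cls) + 0L
        storage.mode(b) <- "integer"; dim(b) <- dim(l); b
      })
      pos <- sum(st$class_counts[cls + 1L])
      neg <- sum(st$class_counts) - pos
      # sqrt-tempered positive weight, matching the multiclass default
      w <- c(1, if (pos > 0) sqrt(neg / pos) else 0)
      arch <- unet_arch(spec, 1L)
      params <- cpp_unet_init(arch, spec$seed + cls)
      nets[[cls]] <- cpp_unet_train(params, greys, labs, arch, w,
                                    spec$learning_rate, spec$epochs,
                                    spec$batch_size, spec$seed + 100L + cls)
      arches[[cls]] <- arch
    }
  }
  structure(
    list(spec = spec,
         arch = arches,
         params = lapply(nets, `[[`, "params"),
         loss = lapply(nets, `[[`, "loss"),
         norm = list(mean = st$mean, sd = st$sd),
         class_counts = st$class_counts),
    class = "segmentation_model")
}

#' Number of parameters actually allocated by a trained model
#'
#' @param model A `segmentation_model`.
#' @return Total length of the model's parameter vectors (per network for
#'   the binary head mode this is the per-network count times 3).
#' @export
model_parameter_count <- function(model) {
  stopifnot(inherits(model, "segmentation_model"))
  sum(vapply(model$params, length, 1L))
}

#' Segment a grey volume with a trained model
#'
#' Runs 2D inference over every slice of the three orthogonal plane
#' families, averages the three per-voxel class-probability fields and
#' takes the argmax. For the binary head mode the three per-class
#' probability fields are combined by highest probability, with background
#' where no class reaches 0.5.
#'
#' @param model A `segmentation_model` from [train_unet()].
#' @param grey A [grey_volume()]; all dimensions must be divisible by
#'   `2^n_encoding_stages`.
#' @return A [label_volume()] congruent with the input.
#' @export
predict_volume <- function(model, grey) {
  stopifnot(inherits(model, "segmentation_model"), is_grey_volume(grey))
  d <- dim(grey$data)
  div <- 2^model$spec$n_encoding_stages
  if (any(d %% div != 0))
    stop("volume dimensions must be divisible by 2^n_encoding_stages (= ",
         div, "); pad or crop the volume")
  if (any(d < div)) stop("volume smaller than the network's minimum tile")
  norm <- model$norm
  vol <- (grey$data - norm$mean) / norm$sd

  if (model$spec$head_mode == "multiclass_4") {
    probs <- fused_probs(model$params[[1]], model$arch[[1]], vol, 4L)
    lab <- max.col(matrix(probs, ncol = 4L), ties.method = "first") - 1L
  } else {
    pc <- vapply(1:3, function(cls) {
      fused_probs(model$params[[cls]], model$arch[[cls]], vol, 1L)
    }, numeric(prod(d)))
    best <- max.col(pc, ties.method = "first")
    lab <- ifelse(pc[cbind(seq_len(nrow(pc)), best)] >= 0.5, best, 0L)
  }
  lab <- as.integer(lab)
  dim(lab) <- d
  label_volume(lab, grey$voxel_size)
}

# average class probabilities over the three orthogonal plane families;
# returns a (prod(d) * n_classes) numeric vector (array layout d x C)
fused_probs <- function(params, arch, vol, n_classes) {
  d <- dim(vol)
  acc <- array(0, dim = c(d, n_classes))
  for (ax in 1:3) {
    for (k in seq_len(d[ax])) {
      sl <- slice_array(vol, ax, k)
      pr <- cpp_unet_predict(params, sl, arch) # H x W x C
      for (cls in seq_len(n_classes)) {
        switch(ax,
               `1` = { acc[k, , , cls] <- acc[k, , , cls] + pr[, , cls] },
               `2` = { acc[, k, , cls] <- acc[, k, , cls] + pr[, , cls] },
               `3` = { acc[, , k, cls] <- acc[, , k, cls] + pr[, , cls] })
      }
    }
  }
  as.vector(acc / 3)
}

#' Per-class overlap scores between predicted and true labels
#'
#' Dice `2|A n B| / (|A| + |B|)` and IoU per class; a class absent from
#' both volumes scores 1 by convention.
#'
#' @param pred,truth Congruent [label_volume()]s.
#' @return A data frame with columns `class`, `dice`, `iou`.
#' @export
evaluate_segmentation <- function(pred, truth) {
  stopifnot(is_label_volume(pred), is_label_volume(truth))
  if (!identical(dim(pred$data), dim(truth$data)))
    stop("prediction and truth volumes differ in shape")
  p <- as.vector(pred$data)
  t_ <- as.vector(truth$data)
  res <- lapply(0:3, function(cls) {
    a <- p == cls
    b <- t_ == cls
    na <- sum(a); nb <- sum(b)
    inter <- sum(a & b)
    if (na + nb == 0) {
      c(dice = 1, iou = 1)
    } else {
      c(dice = 2 * inter / (na + nb),
        iou = inter / (na + nb - inter))
    }
  })
  data.frame(class = 0:3,
             dice = vapply(res, `[[`, 1, "dice"),
             iou = vapply(res, `[[`, 1, "iou"))
}
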