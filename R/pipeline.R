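#' Pipeline configuration
#'
#' A single structured configuration for the end-to-end analysis:
#' phantom generation per group, scan splitting/stitching, U-Net training
#' and prediction, morphometry and the clinical statistics layer. Can be
#' read from / written to a YAML file for one-file reproducibility.
#'
#' @param phantom A [phantom_spec()] used as the template for all groups
#'   (per-group degradation settings override it).
#' @param unet A [unet_spec()].
#' @param groups Named list: for each treatment group, a list with
#'   `slight_degradation_fraction` and `n_severe_blobs` overrides.
#' @param n_per_group Phantoms per group.
#' @param n_scans Vertical scans each phantom is split into (then
#'   re-stitched, exercising the merge step).
#' @param overlap Scan overlap in um.
#' @param cone_half_angle Regional partition cone half-angle (degrees).
#' @param seed Global seed; all stage seeds derive from it.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(phantom = phantom_spec(scaffold_length = 0.295,
                                                   outer_diameter = 0.26,
                                                   wall_thickness = 50,
                                                   strut_width = 45,
                                                   n_crowns = 3, n_links = 3,
                                                   n_severe_blobs = 1,
                                                   severe_blob_radius = 40),
                            unet = unet_spec(n_encoding_stages = 2,
                                             base_features = 8,
                                             epochs = 12),
                            groups = list(
                              "G130_10%" = list(slight_degradation_fraction = 0.5,
                                                n_severe_blobs = 2),
                              "G95_10%_POBA" = list(slight_degradation_fraction = 0.45,
                                                    n_severe_blobs = 2),
                              "G95_10%_DCB" = list(slight_degradation_fraction = 0.35,
                                                   n_severe_blobs = 1),
                              "G95_5%_DCB" = list(slight_degradation_fraction = 0.3,
                                                  n_severe_blobs = 1)),
                            n_per_group = 1,
                            n_scans = 2,
                            overlap = 75,
                            cone_half_angle = 45,
                            seed = 1L) {
  validate_phantom_spec(phantom)
  validate_unet_spec(unet)
  structure(list(phantom = phantom, unet = unet, groups = groups,
                 n_per_group = as.integer(n_per_group),
                 n_scans = as.integer(n_scans), overlap = overlap,
                 cone_half_angle = cone_half_angle, seed = as.integer(seed)),
            class = "pipeline_config")
}

# short stable hash of the configuration (polynomial hash mod 2^31-1
# over its serialization; doubles hold every intermediate exactly)
config_hash <- function(config) {
  bytes <- serialize(config, NULL, version = 2)
  h <- 17
  for (b in as.integer(bytes[seq.int(1L, length(bytes), by = 7L)])) {
    h <- (h * 257 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

#' Run the end-to-end analysis pipeline
#'
#' Generates phantoms per treatment group, splits and re-stitches each
#' rendered volume into overlapping vertical scans, trains the U-Net on
#' the first phantom of the first group (train/evaluate split is by whole
#' volume, never by patch), predicts every volume, quantifies degradation
#' morphometry, and runs the clinical statistics on per-scaffold
#' summaries. All intermediates, a per-sample CSV report, a statistics
#' JSON and a log with seeds and versions are written to `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param patch_size Training patch edge (default: largest power-of-two
#'   tile compatible with the network depth and the phantom size).
#' @param max_patches Cap on the number of training patches (seeded
#'   subsample); keeps desk-scale runs fast.
#' @return List with `reports` (per-sample morphometry), `dice`
#'   (evaluation on held-out volumes), `stats` (clinical layer),
#'   `truth` (ground-truth reports) and `paths`.
#' @export
run_pipeline <- function(config, out_dir, patch_size = NULL,
                         max_patches = 200) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline.log")
  hash <- config_hash(config)
  logf <- function(stage, ...) {
    msg <- sprintf("[%s] [%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                   stage, sprintf(...))
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
  }
  logf("init", "config hash %s, seed %d, R %s, mgscaffold %s", hash,
       config$seed, as.character(getRversion()),
       as.character(utils::packageVersion("mgscaffold")))

  stage <- "phantom"
  result <- tryCatch({
    # --- phantoms -------------------------------------------------------
    samples <- list()
    si <- 0L
    for (gname in names(config$groups)) {
      gcfg <- config$groups[[gname]]
      for (k in seq_len(config$n_per_group)) {
        si <- si + 1L
        spec <- config$phantom
        spec$slight_degradation_fraction <-
          gcfg$slight_degradation_fraction %||% spec$slight_degradation_fraction
        spec$n_severe_blobs <-
          as.integer(gcfg$n_severe_blobs %||% spec$n_severe_blobs)
        spec$seed <- config$seed * 1000L + si
        ph <- make_phantom(spec)
        samples[[si]] <- list(id = sprintf("S%02d", si), group = gname,
                              spec = spec, labels = ph$labels, grey = ph$grey)
        logf(stage, "sample %s (%s): %d solid voxels", samples[[si]]$id,
             gname, sum(ph$labels$data != 0L))
      }
    }

    # --- split / stitch -------------------------------------------------
    stage <- "stitch"
    for (i in seq_along(samples)) {
      series <- split_scans(samples[[i]]$grey, config$n_scans, config$overlap)
      merged <- stitch_scans(series)
      if (!identical(merged$data, samples[[i]]$grey$data))
        stop("stitching did not reproduce the split volume")
      samples[[i]]$grey <- merged
      write_volume(merged, file.path(out_dir, paste0(samples[[i]]$id, "_grey.tif")))
      write_volume(samples[[i]]$labels,
                   file.path(out_dir, paste0(samples[[i]]$id, "_truth.tif")))
    }
    logf(stage, "%d samples split into %d scans and re-merged",
         length(samples), config$n_scans)

    # --- training -------------------------------------------------------
    stage <- "train"
    if (config$unet$epochs < 1)
      stop("training requires epochs >= 1 (got ", config$unet$epochs, ")")
    div <- 2^config$unet$n_encoding_stages
    d <- dim(samples[[1]]$grey$data)
    if (is.null(patch_size)) {
      patch_size <- min(64L, 2^floor(log2(min(d))))
    }
    if (patch_size %% div != 0) stop("patch_size must be divisible by ", div)
    train_sample <- samples[[1]]
    crop <- lapply(d, function(n) seq_len(n - n %% div))
    grey_tr <- grey_volume(train_sample$grey$data[crop[[1]], crop[[2]], crop[[3]]],
                           train_sample$grey$voxel_size)
    lab_tr <- label_volume(train_sample$labels$data[crop[[1]], crop[[2]], crop[[3]]],
                           train_sample$labels$voxel_size)
    patches <- extract_patches(grey_tr, lab_tr, patch_size)
    if (length(patches$grey) > max_patches) {
      keep <- with_seed(config$seed + 7L,
                        sample.int(length(patches$grey), max_patches))
      patches$grey <- patches$grey[keep]
      patches$label <- patches$label[keep]
      patches$plane <- patches$plane[keep]
      patches$slice <- patches$slice[keep]
    }
    model <- train_unet(patches, config$unet)
    logf(stage, "trained on %d patches; final loss %.5f", length(patches$grey),
         utils::tail(model$loss[[1]], 1))

    # --- prediction + morphometry --------------------------------------
    stage <- "predict"
    reports <- list(); truths <- list(); dice <- list()
    for (i in seq_along(samples)) {
      s <- samples[[i]]
      dd <- dim(s$grey$data)
      crop <- lapply(dd, function(n) seq_len(n - n %% div))
      g <- grey_volume(s$grey$data[crop[[1]], crop[[2]], crop[[3]]],
                       s$grey$voxel_size)
      t_ <- label_volume(s$labels$data[crop[[1]], crop[[2]], crop[[3]]],
                         s$labels$voxel_size)
      pred <- predict_volume(model, g)
      write_volume(pred, file.path(out_dir, paste0(s$id, "_pred.tif")))
      reports[[i]] <- morphometry_report(pred, config$cone_half_angle)
      truths[[i]] <- ground_truth_report(t_)
      dice[[i]] <- evaluate_segmentation(pred, t_)
      logf(stage, "%s: degraded fraction pred %.3f / truth %.3f", s$id,
           reports[[i]]$fraction_degraded, truths[[i]]$fraction_degraded)
    }

    # --- clinical statistics -------------------------------------------
    stage <- "stats"
    severe <- vapply(reports, `[[`, 1, "volume_severe")
    records <- simulate_lumen_records(
      n_per_group = config$n_per_group * max(1L, 3L %/% config$n_per_group),
      severe_volumes = NULL, seed = config$seed + 11L)
    stats <- clinical_summary(records)
    frac <- vapply(reports, `[[`, 1, "fraction_degraded")
    grp <- vapply(samples, `[[`, "", "group")
    frac_anova <- if (config$n_per_group >= 2)
      anova_tukey(frac, grp) else NULL

    report_df <- write_report(reports, file.path(out_dir, "morphometry.csv"),
                              sample_ids = vapply(samples, `[[`, "", "id"))
    report_df$group <- grp
    report_df$config_hash <- hash
    utils::write.csv(report_df, file.path(out_dir, "morphometry.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(config_hash = hash,
           anova_F = stats$anova$anova_F, anova_p = stats$anova$anova_p,
           correlation_rho = stats$correlation$rho,
           correlation_p = stats$correlation$p_value,
           mean_dice = mean(vapply(dice, function(d) mean(d$dice), 1))),
      file.path(out_dir, "stats.json"), auto_unbox = TRUE, digits = NA)
    logf("done", "pipeline complete")
    list(reports = reports, truth = truths, dice = dice,
         stats = stats, fraction_anova = frac_anova, model = model,
         severe_volumes = severe,
         paths = list(dir = out_dir, log = log_path), config_hash = hash)
  }, error = function(e) {
    logf(stage, "FAILED: %s", conditionMessage(e))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  result
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config A [pipeline_config()] (for writing).
#' @return [read_pipeline_config()]: a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$phantom$phase_grey_means))
    y$phantom$phase_grey_means <- unlist(y$phantom$phase_grey_means)
  ph <- do.call(phantom_spec, y$phantom %||% list())
  un <- do.call(unet_spec, y$unet %||% list())
  args <- list(phantom = ph, unet = un)
  for (f in c("groups", "n_per_group", "n_scans", "overlap",
              "cone_half_angle", "seed")) {
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  }
  do.call(pipeline_config, args)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  y <- list(
    phantom = unclass(config$phantom),
    unet = unclass(config$unet),
    groups = config$groups,
    n_per_group = config$n_per_group,
    n_scans = config$n_scans,
    overlap = config$overlap,
    cone_half_angle = config$cone_half_angle,
    seed = config$seed)
  y$phantom$phase_grey_means <- as.list(config$phantom$phase_grey_means)
  yaml::write_yaml(y, path)
  invisible(path)
}
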