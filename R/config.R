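#' Default pipeline configuration
#'
#' All fields default to the reference protocol: 256-px tiles, 20/5-px DEM
#' filter windows, learning rate 0.001, 100 epochs, batch size 4, patience
#' 10, hold-out fraction 0.2, IoU acceptance threshold 50%, and the survey
#' resolution of 0.01532703 m/pixel.
#'
#' @return nested list of settings (class `run_config`).
#' @export
default_config <- function() {
  structure(list(
    combo = "RGB-CHM",
    resolution = 0.01532703,
    tile_size = 256L,
    augment = TRUE,
    min_window = 20L,
    mean_window = 5L,
    normalization = list(max_height = 5),
    model = list(base_width = 64L, encoder_depth = 4L, blocks_per_stage = 1L,
                 learning_rate = 0.001, max_epochs = 100L, batch_size = 4L,
                 patience = 10L, val_fraction = 0.2),
    metrics = list(iou_threshold = 50, min_crown_pixels = 50L),
    synthetic = list(n_crowns = 20L, size = 1024L, noise_sd = 8,
                     height_max = 3.0, cw_range = c(1.16, 3.47)),
    seed = 42L), class = "run_config")
}

merge_config <- function(base, override, path = "") {
  for (nm in names(override)) {
    full <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(base))
      stop("unknown configuration key: ", full)
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      if (!is.list(override[[nm]]))
        stop("configuration key ", full, " must be a mapping")
      base[[nm]] <- merge_config(base[[nm]], override[[nm]], full)
    } else {
      val <- override[[nm]]
      if (is.list(val)) val <- unlist(val)
      if (is.numeric(base[[nm]]) && !is.numeric(val))
        stop("configuration key ", full, " must be numeric")
      base[[nm]] <- if (is.integer(base[[nm]])) as.integer(val) else val
    }
  }
  base
}

#' Load a YAML pipeline configuration
#'
#' Reads a YAML file and merges it over [default_config()]. Unknown keys are
#' rejected (with the offending key named) so typos never silently fall back
#' to a default.
#'
#' @param path YAML file; an empty file yields the defaults.
#' @return a `run_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  if (length(user)) cfg <- merge_config(cfg, user)
  # resolve the combination early so bad names fail here
  invisible(band_combination(cfg$combo))
  cfg
}

# single user seed fans out to fixed per-stage seeds (kept below 2^31)
stage_seed <- function(seed, stage) {
  offsets <- c(scene = 0L, model = 101L, split = 211L)
  (as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the synthetic end-to-end pipeline
#'
#' Generates a seeded scene, prepares band tiles for the configured
#' combination, trains the segmentation model, predicts the scene mask,
#' measures crowns, and evaluates against scene truth. Artifacts (rasters,
#' truth table, training log, report JSON and the resolved configuration
#' snapshot) are written under `out_dir` when given.
#'
#' @param config a `run_config` (see [default_config()], [load_config()]).
#' @param out_dir optional artifact directory, created if missing.
#' @param verbose print stage progress lines.
#' @return list with `report` (a `crown_report`), `training` (log etc.),
#'   `scene`, `pred_mask`, and `config`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- proc.time()[3]

  say("[scene] generating %d crowns on a %d px grid (seed %d)",
      config$synthetic$n_crowns, config$synthetic$size, config$seed)
  scene <- gen_scene(config$synthetic$n_crowns, config$synthetic$size,
                     resolution = config$resolution,
                     cw_range = config$synthetic$cw_range,
                     height_max = config$synthetic$height_max,
                     noise_sd = config$synthetic$noise_sd,
                     seed = stage_seed(config$seed, "scene"))

  combo <- band_combination(config$combo)
  say("[prep] combo %s (%d layer(s)), tile %d px", combo$name, combo$layers,
      config$tile_size)
  tiles <- scene_to_tiles(scene, combo = combo,
                          tile_size = config$tile_size,
                          augment = isTRUE(config$augment),
                          min_window = config$min_window,
                          mean_window = config$mean_window,
                          max_height = config$normalization$max_height)
  say("[prep] %d training tile(s)", length(tiles))

  mc <- config$model
  mcfg <- resunet_config(in_layers = combo$layers,
                         base_width = mc$base_width,
                         encoder_depth = mc$encoder_depth,
                         blocks_per_stage = mc$blocks_per_stage,
                         learning_rate = mc$learning_rate,
                         max_epochs = mc$max_epochs,
                         batch_size = mc$batch_size, patience = mc$patience,
                         val_fraction = mc$val_fraction,
                         seed = stage_seed(config$seed, "model"))
  model <- build_resunet(mcfg)
  say("[train] model: %d input layer(s), base width %d, depth %d",
      mcfg$in_layers, mcfg$base_width, mcfg$encoder_depth)
  tr <- train_resunet(model, tiles, verbose = verbose)
  say("[train] best epoch %d (val mIoU %.4f)%s", tr$best_epoch,
      max(tr$log$val_miou), if (tr$stopped_early) ", stopped early" else "")

  # the model input for inference: same bands/normalisation as training
  stack <- scene$stack
  if ("chm" %in% combo$bands && !has_band(stack, "chm")) {
    dsm <- get_band(stack, "dsm")
    stack <- set_band(stack, "chm",
                      compute_chm(dsm, derive_dem(dsm, config$min_window,
                                                  config$mean_window)))
  }
  grid <- stack_bands(stack, combo, normalize = TRUE,
                      max_height = config$normalization$max_height)
  say("[segment] predicting the %d px scene mask", config$synthetic$size)
  pred <- predict_mask(tr$model, grid, tile_size = config$tile_size)

  say("[measure+evaluate] IoU threshold %g%%, min component %d px",
      config$metrics$iou_threshold, config$metrics$min_crown_pixels)
  ref <- truth_to_reference(scene$truth)
  chm <- if (has_band(stack, "chm")) get_band(stack, "chm") else NULL
  report <- evaluate_run(pred, ref, config$resolution, chm = chm,
                         iou_threshold = config$metrics$iou_threshold,
                         min_crown_pixels = config$metrics$min_crown_pixels)
  say("[done] %.1f s elapsed; TP %d FP %d FN %d", proc.time()[3] - t0,
      report$counts$tp, report$counts$fp, report$counts$fn)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    px <- scene$stack$pixels
    write_raster(px[, , 1:3] / 255 * 255, file.path(out_dir, "ortho.tif"),
                 uint8 = TRUE)
    write_raster(get_band(scene$stack, "dsm"), file.path(out_dir, "dsm.tif"))
    write_mask(scene$truth$mask, file.path(out_dir, "mask.tif"))
    write_mask(pred, file.path(out_dir, "pred_mask.tif"))
    utils::write.csv(scene$truth$crowns, file.path(out_dir, "truth.csv"),
                     row.names = FALSE)
    utils::write.csv(tr$log, file.path(out_dir, "training_log.csv"),
                     row.names = FALSE)
    write_report(report, file.path(out_dir, "report.json"))
    yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
  }
  list(report = report, training = tr, scene = scene, pred_mask = pred,
       config = config)
}

#' Reference instances from scene truth
#'
#' Extracts instances from the truth mask and overwrites their measured
#' attributes with the analytic truth (crown width from the planted axes,
#' CPA from the rendered pixel count, height from the dome peak), matched by
#' the component label under each crown center.
#'
#' @param truth a `scene_truth`.
#' @return a `crown_instances` carrying truth metrics.
#' @export
truth_to_reference <- function(truth) {
  stopifnot(inherits(truth, "scene_truth"))
  inst <- extract_crown_instances(truth$mask, truth$resolution,
                                  min_crown_pixels = 1L)
  if (!is.null(truth$crowns) && nrow(truth$crowns)) {
    lab_at <- inst$labels[cbind(round(truth$crowns$center_row),
                                round(truth$crowns$center_col))]
    m <- match(inst$table$label, lab_at)
    hit <- !is.na(m)
    inst$table$cw_mean_m[hit] <- truth$crowns$cw_mean_m[m[hit]]
    inst$table$cpa_m2[hit] <- truth$crowns$cpa_m2[m[hit]]
    inst$table$height_m[hit] <- truth$crowns$height_m[m[hit]]
  }
  inst
}

#' Desk-scale end-to-end demo
#'
#' Runs the full pipeline on a synthetic scene with a miniature model
#' (8-channel stem, two residual stages) sized for a single CPU: 20 crowns
#' on a 1024-px grid, at most 15 training epochs.
#'
#' @param seed integer seed for the whole run.
#' @param out_dir optional artifact directory.
#' @param combo band combination name (default `"RGB-CHM"`).
#' @param verbose print progress.
#' @return see [run_pipeline()].
#' @export
run_demo <- function(seed = 42L, out_dir = NULL, combo = "RGB-CHM",
                     verbose = FALSE) {
  cfg <- default_config()
  cfg$combo <- combo
  cfg$seed <- as.integer(seed)
  cfg$augment <- FALSE
  cfg$model$base_width <- 8L
  cfg$model$encoder_depth <- 2L
  cfg$model$max_epochs <- 15L
  cfg$model$patience <- 6L
  run_pipeline(cfg, out_dir = out_dir, verbose = verbose)
}
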