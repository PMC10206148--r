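# Config-driven orchestration of the full workflow with seeded
# reproducibility. Each stage reads the previous stage's artifacts from the
# configured output directory, writes its own, and records a manifest
# (config hash, stage seed, input/output checksums) so every number is
# traceable to a configuration.

PIPELINE_STAGES <- c("simulate", "segment", "train-vae", "features",
                     "train-iforest", "score", "filter", "annotate",
                     "evaluate", "ecology")

default_pipeline_config <- function() {
  list(
    seed = 1,
    paths = list(out_dir = "pipeline_out"),
    scene = list(image_width = 256, image_height = 256,
                 nodule_density = 150, fauna_rate = 2, laser_rate = 0.5,
                 dark_patch_rate = 0.2, noise_sigma = 0.02),
    survey = list(n_images = 20, start_lon = -117.5, start_lat = 11.85,
                  heading_deg = 90, speed_ms = 0.26, interval_s = 10,
                  fix_interval_s = 5, fauna_density_m2 = NULL),
    segmentation = list(scale = 100, sigma = 1.0, min_size = 50,
                        max_area_fraction = 0.25, patch_size = 64),
    vae = list(latent_dim = 32, epochs = 20, batch_size = 64,
               learning_rate = 1e-3, hidden_dim = 128, input_side = 16,
               max_patches = 4000),
    iforest = list(n_trees = 100, subsample_size = 256,
                   contamination = 0.4),
    filter = list(method = "classifier", percentile = 75,
                  prob_cutoff = 0.5, max_positives = 512,
                  classifier_epochs = 150),
    annotate = list(train_fraction = 0.9, min_iou = 0.1,
                    add_missed = TRUE),
    evaluate = list(miss_rate = 0.1, fp_rate = 0.5, jitter_px = 2),
    ecology = list(cell_size_m = 200, fov_x_deg = 64, fov_y_deg = 64,
                   max_gap_s = 60))
}

merge_config <- function(defaults, user, path = character(0)) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ",
         paste(paste(c(path, ""), collapse = "."), unknown,
               sep = "", collapse = ", "), call. = FALSE)
  }
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      if (!is.list(user[[nm]])) {
        stop("configuration section `", nm, "` must be a mapping",
             call. = FALSE)
      }
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]],
                                     c(path, nm))
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Pipeline configuration
#'
#' Builds and validates the nested configuration driving [run_stage()]:
#' one section per workflow stage plus a global seed and output paths.
#' Unknown keys are rejected before any computation runs (fail fast), so
#' a typo cannot silently fall back to a default.
#'
#' @param config `NULL` (all defaults), a nested list overriding
#'   defaults, or the path of a YAML file with such overrides.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = NULL) {
  if (inherits(config, "pipeline_config")) return(config)
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(default_pipeline_config(), config %||% list())
  cfg$seed <- check_count(cfg$seed, "seed", min = 0)
  if (!cfg$filter$method %in% c("classifier", "threshold")) {
    stop("filter.method must be 'classifier' or 'threshold'",
         call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp)
  md5_file(tmp)
}

stage_seed <- function(cfg, stage) derive_seed(cfg$seed, paste0("stage_", stage))

pipeline_log <- function(cfg, stage, level, msg) {
  line <- sprintf("%s\t%s\t%s", stage, level, msg)
  message(line)
  cat(line, "\n", sep = "",
      file = file.path(cfg$paths$out_dir, "pipeline.log"), append = TRUE)
}

require_artifact <- function(path, produced_by) {
  if (!file.exists(path)) {
    stop(sprintf("missing upstream artifact `%s`; run stage '%s' first",
                 path, produced_by), call. = FALSE)
  }
  path
}

write_stage_manifest <- function(cfg, stage, inputs, outputs) {
  describe <- function(files) {
    files <- files[file.exists(files)]
    data.frame(file = basename(files),
               md5 = vapply(files, md5_file, character(1)),
               row.names = NULL)
  }
  manifest <- list(stage = stage, seed = stage_seed(cfg, stage),
                   config_md5 = config_hash(cfg),
                   inputs = describe(inputs), outputs = describe(outputs))
  jsonlite::write_json(
    manifest, file.path(cfg$paths$out_dir,
                        paste0("manifest_", stage, ".json")),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

out_path <- function(cfg, ...) file.path(cfg$paths$out_dir, ...)

#' Run one pipeline stage (or all of them)
#'
#' Stages, in workflow order: `simulate` (synthetic survey to disk),
#' `segment` (superpixels and patches), `train-vae`, `features`,
#' `train-iforest`, `score` (anomaly scores + contamination flags),
#' `filter` (weak annotations via classifier or percentile threshold),
#' `annotate` (semantic labels from the synthetic ground truth, playing
#' the expert annotator, plus the train/validation split), `evaluate`
#' (noisy oracle detector vs ground truth, COCO-style summary) and
#' `ecology` (abundance, diversity, gridded density). `all` chains them.
#' Each stage derives its own seed from the global one, writes versioned
#' outputs plus a manifest with config hash and checksums, and never
#' mutates upstream artifacts. Rerunning with an identical config and
#' seed reproduces outputs bit for bit.
#'
#' @param stage one of the stage names above or `"all"`.
#' @param config a [pipeline_config()], override list, or YAML path.
#' @return invisibly, the paths of the stage's primary outputs.
#' @export
run_stage <- function(stage = "all", config = NULL) {
  cfg <- pipeline_config(config)
  if (!stage %in% c(PIPELINE_STAGES, "all")) {
    stop("unknown stage '", stage, "'; expected one of: ",
         paste(c(PIPELINE_STAGES, "all"), collapse = ", "), call. = FALSE)
  }
  dir.create(cfg$paths$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (stage == "all") {
    out <- lapply(PIPELINE_STAGES, run_stage, config = cfg)
    return(invisible(unlist(out)))
  }
  fn <- switch(stage,
               "simulate" = stage_simulate, "segment" = stage_segment,
               "train-vae" = stage_train_vae, "features" = stage_features,
               "train-iforest" = stage_train_iforest,
               "score" = stage_score, "filter" = stage_filter,
               "annotate" = stage_annotate, "evaluate" = stage_evaluate,
               "ecology" = stage_ecology)
  pipeline_log(cfg, stage, "INFO", "starting")
  out <- fn(cfg)
  pipeline_log(cfg, stage, "INFO",
               paste("wrote", paste(basename(out), collapse = ", ")))
  invisible(out)
}

stage_simulate <- function(cfg) {
  sc <- scene_config(
    image_size = c(cfg$scene$image_width, cfg$scene$image_height),
    nodule_density = cfg$scene$nodule_density,
    fauna_rate = cfg$scene$fauna_rate, laser_rate = cfg$scene$laser_rate,
    dark_patch_rate = cfg$scene$dark_patch_rate,
    noise_sigma = cfg$scene$noise_sigma,
    seed = stage_seed(cfg, "simulate"))
  track <- survey_track(
    start_lon = cfg$survey$start_lon, start_lat = cfg$survey$start_lat,
    heading_deg = cfg$survey$heading_deg, speed_ms = cfg$survey$speed_ms,
    interval_s = cfg$survey$interval_s,
    fix_interval_s = cfg$survey$fix_interval_s)
  survey <- generate_survey(sc, cfg$survey$n_images, track,
                            fauna_density_m2 = cfg$survey$fauna_density_m2)
  manifest <- write_survey(survey$scenes, survey$track, cfg$paths$out_dir)
  write_stage_manifest(cfg, "simulate", character(0), manifest)
  manifest
}

load_scene_images <- function(cfg) {
  coco <- read_coco(require_artifact(out_path(cfg, "ground_truth.json"),
                                     "simulate"))
  imgs <- coco$images
  imgs$path <- out_path(cfg, imgs$file_name)
  imgs
}

stage_segment <- function(cfg) {
  imgs <- load_scene_images(cfg)
  params <- segmentation_params(
    scale = cfg$segmentation$scale, sigma = cfg$segmentation$sigma,
    min_size = cfg$segmentation$min_size,
    max_area_fraction = cfg$segmentation$max_area_fraction)
  patches <- vector("list", nrow(imgs))
  for (i in seq_len(nrow(imgs))) {
    img <- png::readPNG(imgs$path[i])
    labels <- segment_image(img, params)
    patches[[i]] <- extract_patches(img, labels, params,
                                    patch_size = cfg$segmentation$patch_size,
                                    parent_id = imgs$scene_id[i])
  }
  patches <- dplyr::bind_rows(patches)
  rds <- out_path(cfg, "patches.rds")
  saveRDS(patches, rds)
  csv <- out_path(cfg, "patches.csv")
  utils::write.csv(patches[, setdiff(names(patches), "patch")], csv,
                   row.names = FALSE)
  write_stage_manifest(cfg, "segment", imgs$path, c(rds, csv))
  c(rds, csv)
}

stage_train_vae <- function(cfg) {
  rds <- require_artifact(out_path(cfg, "patches.rds"), "segment")
  patches <- readRDS(rds)
  seed <- stage_seed(cfg, "train-vae")
  if (nrow(patches) > cfg$vae$max_patches) {
    keep <- with_seed(derive_seed(seed, "subsample"),
                      sample.int(nrow(patches), cfg$vae$max_patches))
    patches <- patches[sort(keep), ]
  }
  vc <- vae_config(latent_dim = cfg$vae$latent_dim,
                   patch_size = cfg$segmentation$patch_size,
                   epochs = cfg$vae$epochs, batch_size = cfg$vae$batch_size,
                   learning_rate = cfg$vae$learning_rate,
                   hidden_dim = cfg$vae$hidden_dim,
                   input_side = cfg$vae$input_side, seed = seed)
  vae <- train_vae(patches, vc)
  out_rds <- out_path(cfg, "vae.rds")
  saveRDS(vae, out_rds)
  loss_csv <- out_path(cfg, "vae_loss.csv")
  utils::write.csv(vae$loss_history, loss_csv, row.names = FALSE)
  write_stage_manifest(cfg, "train-vae", rds, c(out_rds, loss_csv))
  c(out_rds, loss_csv)
}

stage_features <- function(cfg) {
  patches <- readRDS(require_artifact(out_path(cfg, "patches.rds"),
                                      "segment"))
  vae <- readRDS(require_artifact(out_path(cfg, "vae.rds"), "train-vae"))
  features <- encode_patches(vae, patches)
  rds <- out_path(cfg, "features.rds")
  saveRDS(features, rds)
  write_stage_manifest(cfg, "features",
                       out_path(cfg, c("patches.rds", "vae.rds")), rds)
  rds
}

stage_train_iforest <- function(cfg) {
  features <- readRDS(require_artifact(out_path(cfg, "features.rds"),
                                       "features"))
  fc <- forest_config(n_trees = cfg$iforest$n_trees,
                      subsample_size = cfg$iforest$subsample_size,
                      contamination = cfg$iforest$contamination,
                      seed = stage_seed(cfg, "train-iforest"))
  forest <- fit_iforest(features, fc)
  rds <- out_path(cfg, "iforest.rds")
  saveRDS(forest, rds)
  write_stage_manifest(cfg, "train-iforest", out_path(cfg, "features.rds"),
                       rds)
  rds
}

stage_score <- function(cfg) {
  features <- readRDS(require_artifact(out_path(cfg, "features.rds"),
                                       "features"))
  forest <- readRDS(require_artifact(out_path(cfg, "iforest.rds"),
                                     "train-iforest"))
  patches <- readRDS(require_artifact(out_path(cfg, "patches.rds"),
                                      "segment"))
  scores <- score_iforest(forest, features) |>
    flag_by_contamination(cfg$iforest$contamination) |>
    dplyr::left_join(patches[, c("patch_id", "parent_id", "x_min", "y_min",
                                 "x_max", "y_max", "area")],
                     by = "patch_id")
  csv <- out_path(cfg, "scores.csv")
  utils::write.csv(scores, csv, row.names = FALSE)
  write_stage_manifest(cfg, "score",
                       out_path(cfg, c("features.rds", "iforest.rds")), csv)
  csv
}

# Label flagged patches against the synthetic ground truth (IoU > 0 with
# any planted fauna box), standing in for the expert who picks classifier
# training examples from the score-sorted review queue.
label_flagged_by_truth <- function(flagged, truth) {
  overlaps <- logical(nrow(flagged))
  for (sc in unique(flagged$parent_id)) {
    fi <- which(flagged$parent_id == sc)
    ti <- which(truth$scene_id == sc)
    if (!length(ti)) next
    M <- iou_matrix(flagged[fi, ], truth[ti, ])
    overlaps[fi] <- apply(M, 1, max) > 0
  }
  overlaps
}

stage_filter <- function(cfg) {
  scores <- tibble::as_tibble(utils::read.csv(
    require_artifact(out_path(cfg, "scores.csv"), "score"),
    stringsAsFactors = FALSE))
  patches <- readRDS(require_artifact(out_path(cfg, "patches.rds"),
                                      "segment"))
  flagged <- scores[scores$flagged, ]
  flagged <- dplyr::left_join(flagged,
                              patches[, c("patch_id", "patch")],
                              by = "patch_id")

  if (cfg$filter$method == "threshold") {
    retained <- threshold_filter(flagged, cfg$filter$percentile)
    rows <- flagged[flagged$patch_id %in% retained, ]
    weak <- tibble::tibble(
      scene_id = rows$parent_id, x_min = rows$x_min, y_min = rows$y_min,
      x_max = rows$x_max, y_max = rows$y_max, label = UNLABELED,
      source = "weak", anomaly_score = rows$score)
  } else {
    truth <- read_ground_truth_csv(require_artifact(
      out_path(cfg, "ground_truth.csv"), "simulate"))
    is_pos <- label_flagged_by_truth(flagged, truth)
    ord <- order(-flagged$score, flagged$patch_id)
    # positives capped from the top of the review queue; every remaining
    # flagged patch serves as a negative so the classifier sees the full
    # false-positive population (lasers, dark patches, odd nodules)
    pos_rows <- ord[is_pos[ord]][seq_len(min(cfg$filter$max_positives,
                                             sum(is_pos)))]
    neg_rows <- ord[!is_pos[ord]]
    classifier <- train_patch_classifier(
      flagged[pos_rows, ], flagged[neg_rows, ],
      epochs = cfg$filter$classifier_epochs,
      seed = stage_seed(cfg, "filter"))
    weak <- classifier_filter(classifier, flagged,
                              prob_cutoff = cfg$filter$prob_cutoff)
    weak <- weak[, c("scene_id", "x_min", "y_min", "x_max", "y_max",
                     "label", "source", "anomaly_score")]
  }
  csv <- out_path(cfg, "weak_annotations.csv")
  write_annotations_csv(weak, csv)
  write_stage_manifest(cfg, "filter",
                       out_path(cfg, c("scores.csv", "patches.rds")), csv)
  csv
}

stage_annotate <- function(cfg) {
  weak <- read_annotations_csv(require_artifact(
    out_path(cfg, "weak_annotations.csv"), "filter"))
  truth <- read_ground_truth_csv(require_artifact(
    out_path(cfg, "ground_truth.csv"), "simulate"))
  # emulated expert: each weak box takes the morphotype of the best-
  # overlapping planted fauna; boxes overlapping nothing are discarded.
  labelled <- list()
  covered <- rep(FALSE, nrow(truth))
  for (sc in unique(weak$scene_id)) {
    wi <- which(weak$scene_id == sc)
    ti <- which(truth$scene_id == sc)
    if (!length(ti)) next
    M <- iou_matrix(weak[wi, ], truth[ti, ])
    best <- apply(M, 1, which.max)
    best_iou <- M[cbind(seq_along(wi), best)]
    keep <- best_iou >= cfg$annotate$min_iou
    covered[ti[unique(best[keep])]] <- TRUE
    if (any(keep)) {
      rows <- weak[wi[keep], ]
      rows$label <- truth$label[ti[best[keep]]]
      labelled[[length(labelled) + 1]] <- rows
    }
  }
  labelled <- dplyr::bind_rows(c(list(empty_annotations()), labelled))
  if (isTRUE(cfg$annotate$add_missed) && any(!covered)) {
    manual <- truth[!covered, ]
    manual$source <- "manual"
    manual$anomaly_score <- NA_real_
    labelled <- dplyr::bind_rows(labelled, manual)
  }
  ann_csv <- out_path(cfg, "annotations.csv")
  write_annotations_csv(labelled, ann_csv)
  split <- split_annotations(labelled,
                             train_fraction = cfg$annotate$train_fraction,
                             seed = stage_seed(cfg, "annotate"))
  train_csv <- out_path(cfg, "annotations_train.csv")
  val_csv <- out_path(cfg, "annotations_val.csv")
  write_annotations_csv(split$train, train_csv)
  write_annotations_csv(split$validation, val_csv)
  coco <- read_coco(out_path(cfg, "ground_truth.json"))
  coco_json <- out_path(cfg, "annotations_coco.json")
  write_coco(labelled, coco$images, coco_json,
             categories = default_label_set())
  write_stage_manifest(
    cfg, "annotate",
    out_path(cfg, c("weak_annotations.csv", "ground_truth.csv")),
    c(ann_csv, train_csv, val_csv, coco_json))
  c(ann_csv, train_csv, val_csv, coco_json)
}

stage_evaluate <- function(cfg) {
  truth <- read_ground_truth_csv(require_artifact(
    out_path(cfg, "ground_truth.csv"), "simulate"))
  coco <- read_coco(require_artifact(out_path(cfg, "ground_truth.json"),
                                     "simulate"))
  dets <- oracle_detector(
    truth, miss_rate = cfg$evaluate$miss_rate,
    fp_rate = cfg$evaluate$fp_rate, jitter_px = cfg$evaluate$jitter_px,
    seed = stage_seed(cfg, "evaluate"),
    image_size = c(cfg$scene$image_width, cfg$scene$image_height),
    scene_ids = coco$images$scene_id)
  dets <- greedy_nms(dets, 0.5)
  det_csv <- out_path(cfg, "detections.csv")
  utils::write.csv(dets, det_csv, row.names = FALSE)
  ev <- evaluate_detections(dets, truth)
  summary_json <- out_path(cfg, "eval_summary.json")
  jsonlite::write_json(
    list(metrics = as.list(ev$metrics), per_class = ev$per_class),
    summary_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cm <- confusion_matrix(dets, truth)
  cm_csv <- out_path(cfg, "confusion_matrix.csv")
  utils::write.csv(as.data.frame(cm), cm_csv)
  write_stage_manifest(cfg, "evaluate", out_path(cfg, "ground_truth.csv"),
                       c(det_csv, summary_json, cm_csv))
  c(det_csv, summary_json, cm_csv)
}

stage_ecology <- function(cfg) {
  coco <- read_coco(require_artifact(out_path(cfg, "ground_truth.json"),
                                     "simulate"))
  track <- read_navigation_csv(require_artifact(
    out_path(cfg, "navigation.csv"), "simulate"))
  dets <- tibble::as_tibble(utils::read.csv(
    require_artifact(out_path(cfg, "detections.csv"), "evaluate"),
    stringsAsFactors = FALSE))
  geo <- georeference(coco$images, track,
                      max_gap_s = cfg$ecology$max_gap_s)
  geo$footprint_m2 <- ifelse(
    geo$resolved,
    image_footprint(geo$altitude_m, cfg$ecology$fov_x_deg,
                    cfg$ecology$fov_y_deg), NA_real_)
  images <- geo[geo$resolved, ]
  gdet <- dplyr::inner_join(
    dets, images[, c("scene_id", "lon", "lat", "altitude_m",
                     "footprint_m2")], by = "scene_id")
  ab <- abundance(gdet, images)
  ab_csv <- out_path(cfg, "ecology_abundance.csv")
  utils::write.csv(ab, ab_csv, row.names = FALSE)
  counts <- table(gdet$label)
  xy_img <- lonlat_to_local(images$lon, images$lat)
  xy_det <- lonlat_to_local(gdet$lon, gdet$lat,
                            lon0 = mean(images$lon),
                            lat0 = mean(images$lat))
  grid <- grid_density(
    cbind(gdet, xy_det), cbind(images, xy_img),
    cell_size = cfg$ecology$cell_size_m)
  grid_csv <- out_path(cfg, "grid_density.csv")
  utils::write.csv(grid, grid_csv, row.names = FALSE)
  summary_json <- out_path(cfg, "ecology_summary.json")
  jsonlite::write_json(
    list(n_detections = nrow(gdet),
         n_images = nrow(images),
         total_footprint_m2 = sum(images$footprint_m2),
         abundance_ind_m2 = ab$abundance_ind_m2[1],
         shannon_effective = shannon_effective(as.numeric(counts)),
         unresolved_images = sum(!geo$resolved)),
    summary_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_stage_manifest(
    cfg, "ecology",
    out_path(cfg, c("ground_truth.json", "navigation.csv",
                    "detections.csv")),
    c(ab_csv, grid_csv, summary_json))
  c(ab_csv, grid_csv, summary_json)
}
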