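# Staged pipeline tying the modules together over an on-disk project:
#
#   simulate -> frames -> flow -> features -> split -> reduce -> train
#            -> predict -> confidence -> review -> evaluate -> export
#
# Each stage reads the artifacts of its upstream stages from the project
# directory, writes its own, and records a digest of (config, seed) so that
# re-running a completed stage with an unchanged configuration is a no-op.
# Frames and flow images are stored as one PNG per frame in a per-video
# directory (a plain-files frame store); arrays are serialized per clip
# with deterministic filenames.

pipeline_stages <- c("simulate", "frames", "flow", "features", "split",
                     "reduce", "train", "predict", "confidence", "review",
                     "evaluate", "export")

stage_deps <- list(
  simulate = character(), frames = "simulate", flow = "frames",
  features = "flow", split = "frames", reduce = c("features", "split"),
  train = "reduce", predict = "train", confidence = "predict",
  review = "confidence", evaluate = "confidence", export = "predict"
)

default_config <- function() {
  list(
    project_dir = ".",
    behaviors = c("rest", "walk", "groom"),
    background = NULL,
    clip_seconds = 60,
    prop_labeled = 0.3,
    prop_validate = 0.2,
    seed = 1L,
    input_size = 64L,
    stack_size = 11L,
    backbone_seed = 0L,
    flow = list(tau = 0.25, lambda = 0.15, theta = 0.3, n_warps = 5,
                n_scales = 5, zoom = 0.5, max_iter = 50, epsilon = 0.01),
    rica = list(d_out = 512L, lambda = 1, n_iter = 100L,
                fit_on = "labeled"),
    classifier = list(hidden_units = 128L, dropout = 0.5, max_epochs = 16L,
                      validation_patience = 2L, initial_lr = 1e-3,
                      lr_drop_period = 4L, lr_drop_factor = 0.1,
                      minibatch_size = 8L, sequence_seconds = 15),
    confidence_method = "temperature",
    review = list(n_permutations = 100L),
    synthetic = list(n_videos = 2L, video_frames = 240L, fps = 4,
                     frame_size = 64L, p_stay = 0.9,
                     weights = NULL, delta = 6, sigma = 1)
  )
}

merge_config <- function(base, user, path = "") {
  for (nm in names(user)) {
    if (!nm %in% names(base))
      abort_invalid("unknown configuration key: %s%s", path, nm)
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      if (!is.list(user[[nm]]))
        abort_invalid("configuration key %s%s must be a mapping", path, nm)
      base[[nm]] <- merge_config(base[[nm]], user[[nm]],
                                 paste0(path, nm, "."))
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML configuration, fills unspecified keys with package
#' defaults, and rejects unknown keys. See [default_config_yaml()] for a
#' template.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param overrides Optional named list applied after the file.
#' @return Validated configuration list of class `pipeline_config`.
#' @export
read_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- merge_config(cfg, user)
  }
  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides)
  check_scalar_number(cfg$clip_seconds, "clip_seconds", 0, strict_lower = TRUE)
  check_scalar_number(cfg$prop_labeled, "prop_labeled", 0, 1,
                      strict_lower = TRUE, strict_upper = TRUE)
  check_scalar_number(cfg$prop_validate, "prop_validate", 0, 1,
                      strict_lower = TRUE, strict_upper = TRUE)
  if (!cfg$confidence_method %in% c("softmax", "temperature"))
    abort_invalid("confidence_method must be 'softmax' or 'temperature'")
  structure(cfg, class = "pipeline_config")
}

#' Write a template configuration file
#'
#' @param path Destination YAML path.
#' @return `path`, invisibly.
#' @export
default_config_yaml <- function(path) {
  yaml::write_yaml(default_config(), path)
  invisible(path)
}

proj_path <- function(cfg, ...) file.path(cfg$project_dir, ...)

stage_digest <- function(cfg, stage) {
  relevant <- cfg[setdiff(names(cfg), "project_dir")]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(c(stage, utils::capture.output(utils::str(relevant,
                                                       digits.d = 12))), tmp)
  unname(tools::md5sum(tmp))
}

stage_done_file <- function(cfg, stage) proj_path(cfg, paste0(".", stage, ".done"))

stage_is_done <- function(cfg, stage) {
  f <- stage_done_file(cfg, stage)
  file.exists(f) && identical(readLines(f, n = 1L), stage_digest(cfg, stage))
}

mark_stage_done <- function(cfg, stage) {
  writeLines(stage_digest(cfg, stage), stage_done_file(cfg, stage))
}

pipe_log <- function(cfg, stage, fmt, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(fmt, ...)))
}

#' Run one pipeline stage
#'
#' Checks that the stage's upstream artifacts exist (error naming the stage
#' to run first otherwise), re-uses the existing result when the stage has
#' already run with an identical configuration and seed, and otherwise
#' executes the stage and records its digest.
#'
#' @param stage One of `simulate`, `frames`, `flow`, `features`, `split`,
#'   `reduce`, `train`, `predict`, `confidence`, `review`, `evaluate`,
#'   `export`.
#' @param config A [read_config()] configuration.
#' @return Invisibly, `TRUE` if the stage executed, `FALSE` for a digest-
#'   matched no-op.
#' @export
run_stage <- function(stage, config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- match.arg(stage, pipeline_stages)
  for (dep in stage_deps[[stage]]) {
    if (!stage_is_done(config, dep))
      abort_invalid("stage '%s' requires stage '%s'; run that stage first",
                    stage, dep)
  }
  if (stage_is_done(config, stage)) {
    pipe_log(config, stage, "up to date (digest match), skipping")
    return(invisible(FALSE))
  }
  dir.create(config$project_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  switch(stage,
         simulate = stage_simulate(config),
         frames = stage_frames(config),
         flow = stage_flow(config),
         features = stage_features(config),
         split = stage_split(config),
         reduce = stage_reduce(config),
         train = stage_train(config),
         predict = stage_predict(config),
         confidence = stage_confidence(config),
         review = stage_review(config),
         evaluate = stage_evaluate(config),
         export = stage_export(config))
  mark_stage_done(config, stage)
  # freeze the configuration actually used next to the artifacts
  yaml::write_yaml(unclass(config), proj_path(config, "config_frozen.yaml"))
  pipe_log(config, stage, "done in %.1f s",
           as.numeric(Sys.time() - t0, units = "secs"))
  invisible(TRUE)
}

#' Run several pipeline stages in order
#'
#' @param config A [read_config()] configuration.
#' @param stages Stages to run (default: all, in pipeline order).
#' @return Invisibly, the configuration.
#' @export
run_pipeline <- function(config, stages = pipeline_stages) {
  for (s in stages) run_stage(s, config)
  invisible(config)
}

# ---- stage implementations -------------------------------------------------

write_gray_png <- function(mat, path) {
  png::writePNG(pmin(pmax(mat, 0), 1), path)
}

stage_simulate <- function(cfg) {
  sy <- cfg$synthetic
  bset <- behavior_set(cfg$behaviors, cfg$background)
  spec <- synthetic_behavior_spec(
    bset, p_stay = sy$p_stay,
    weights = if (is.null(sy$weights)) 1 else sy$weights,
    fps = sy$fps, frame_size = sy$frame_size
  )
  ann <- NULL
  videos <- list()
  for (v in seq_len(sy$n_videos)) {
    vid <- sprintf("video%02d", v)
    out <- generate_video(spec, sy$video_frames,
                          seed = substream_seed(cfg$seed, paste0("video", v)))
    d <- proj_path(cfg, "frames", vid, "cam1")
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    for (t in seq_along(out$frames))
      write_gray_png(out$frames[[t]], file.path(d, sprintf("f%05d.png", t)))
    ann <- rbind(ann, data.frame(video_id = vid,
                                 frame = seq_along(out$labels) - 1L,
                                 label = out$labels))
    videos[[v]] <- list(video_id = vid, n_frames = sy$video_frames,
                        fps = sy$fps, cameras = 1L)
  }
  write_annotation_csv(ann, proj_path(cfg, "annotations.csv"))
  yaml::write_yaml(list(videos = videos, behaviors = cfg$behaviors),
                   proj_path(cfg, "manifest.yaml"))
  pipe_log(cfg, "simulate", "%d videos x %d frames", sy$n_videos,
           sy$video_frames)
}

read_manifest <- function(cfg) {
  mf <- yaml::read_yaml(proj_path(cfg, "manifest.yaml"))
  mf$videos <- lapply(mf$videos, function(v)
    video_record(v$video_id, v$n_frames, v$fps, v$cameras))
  mf
}

project_clips <- function(cfg) {
  mf <- read_manifest(cfg)
  clips <- do.call(c, lapply(mf$videos, split_video_into_clips,
                             clip_seconds = cfg$clip_seconds))
  ann_path <- proj_path(cfg, "annotations.csv")
  if (file.exists(ann_path)) {
    clips <- attach_labels(clips, read_annotation_csv(ann_path),
                           behavior_set(cfg$behaviors, cfg$background))
  }
  clips
}

video_frame_files <- function(cfg, video_id, camera = 1L, kind = "frames") {
  d <- proj_path(cfg, kind, video_id, paste0("cam", camera))
  sort(list.files(d, pattern = "\\.png$", full.names = TRUE))
}

stage_frames <- function(cfg) {
  mf <- read_manifest(cfg)
  for (v in mf$videos) {
    for (cam in seq_len(v$cameras)) {
      files <- video_frame_files(cfg, v$video_id, cam)
      if (length(files) != v$n_frames)
        abort_invalid("video %s cam%d: found %d frames, manifest says %d",
                      v$video_id, cam, length(files), v$n_frames)
    }
  }
  pipe_log(cfg, "frames", "verified frame store for %d videos",
           length(mf$videos))
}

stage_flow <- function(cfg) {
  mf <- read_manifest(cfg)
  fp <- do.call(tvl1_params, cfg$flow)
  for (v in mf$videos) {
    for (cam in seq_len(v$cameras)) {
      files <- video_frame_files(cfg, v$video_id, cam)
      frames <- lapply(files, function(f) as_gray(png::readPNG(f)))
      flows <- vector("list", length(frames))
      for (t in seq_len(length(frames) - 1L))
        flows[[t]] <- compute_tvl1_flow(frames[[t]], frames[[t + 1L]], fp)
      flows[[length(frames)]] <- flows[[length(frames) - 1L]]  # reuse last
      mm <- flow_norm_constant(flows[seq_len(length(frames) - 1L)])
      d <- proj_path(cfg, "flow", v$video_id, paste0("cam", cam))
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      for (t in seq_along(flows)) {
        img <- flow_to_image(flows[[t]], mm)
        png::writePNG(img / 255, file.path(d, sprintf("f%05d.png", t)))
      }
    }
  }
  pipe_log(cfg, "flow", "TV-L1 flow images written")
}

stage_features <- function(cfg) {
  mf <- read_manifest(cfg)
  bb <- backbone_resnet18(seed = cfg$backbone_seed)
  fbb <- make_flow_backbone(bb, cfg$stack_size)
  clips <- project_clips(cfg)
  dir.create(proj_path(cfg, "features"), showWarnings = FALSE)
  for (v in mf$videos) {
    v_clips <- Filter(function(cl) cl$video_id == v$video_id, clips)
    for (cl in v_clips) {
      per_cam <- list()
      for (cam in seq_len(v$cameras)) {
        idx <- (cl$start + 1L):cl$end
        sp_files <- video_frame_files(cfg, v$video_id, cam)[idx]
        sp <- preprocess_frames(lapply(sp_files, png::readPNG),
                                cfg$input_size)
        f_sp <- extract_stream_features(sp, bb, "spatial", cam)
        fl_files <- video_frame_files(cfg, v$video_id, cam, "flow")[idx]
        fl <- preprocess_frames(lapply(fl_files, png::readPNG),
                                cfg$input_size)
        stacks <- build_flow_stacks(fl, cfg$stack_size)
        f_tm <- extract_stream_features(stacks, fbb, "temporal", cam)
        per_cam[[length(per_cam) + 1L]] <- f_sp
        per_cam[[length(per_cam) + 1L]] <- f_tm
      }
      concat <- concat_features(per_cam)
      saveRDS(concat, proj_path(cfg, "features",
                                paste0(cl$clip_id, "_concat.rds")))
    }
  }
  pipe_log(cfg, "features", "spatiotemporal features for %d clips",
           length(clips))
}

stage_split <- function(cfg) {
  clips <- project_clips(cfg)
  split <- select_labeled_clips(clips, cfg$prop_labeled, cfg$seed)
  tv <- split_train_validate(split$D_labeled, cfg$prop_validate, cfg$seed)
  out <- list(D_labeled = split$D_labeled, D_unlabeled = split$D_unlabeled,
              D_train = tv$D_train, D_validate = tv$D_validate,
              D_test = split$D_unlabeled)
  yaml::write_yaml(out, proj_path(cfg, "split.yaml"))
  pipe_log(cfg, "split", "%d labeled (%d train / %d validate), %d unlabeled",
           length(out$D_labeled), length(out$D_train),
           length(out$D_validate), length(out$D_unlabeled))
}

read_split <- function(cfg) yaml::read_yaml(proj_path(cfg, "split.yaml"))

clip_concat_features <- function(cfg, clip_id) {
  readRDS(proj_path(cfg, "features", paste0(clip_id, "_concat.rds")))
}

stage_reduce <- function(cfg) {
  sp <- read_split(cfg)
  fit_ids <- if (identical(cfg$rica$fit_on, "all"))
    c(sp$D_labeled, sp$D_unlabeled) else sp$D_labeled
  X <- do.call(rbind, lapply(fit_ids, clip_concat_features, cfg = cfg))
  d_out <- min(cfg$rica$d_out, ncol(X), nrow(X))
  rt <- fit_rica(X, d_out = d_out, lambda = cfg$rica$lambda,
                 n_iter = cfg$rica$n_iter, seed = cfg$seed)
  saveRDS(rt, proj_path(cfg, "rica.rds"))
  dir.create(proj_path(cfg, "reduced"), showWarnings = FALSE)
  for (cid in c(sp$D_labeled, sp$D_unlabeled)) {
    saveRDS(apply_rica(rt, clip_concat_features(cfg, cid)),
            proj_path(cfg, "reduced", paste0(cid, ".rds")))
  }
  pipe_log(cfg, "reduce", "RICA %d -> %d fitted on %d rows", ncol(X), d_out,
           nrow(X))
}

clip_reduced_features <- function(cfg, clip_id) {
  readRDS(proj_path(cfg, "reduced", paste0(clip_id, ".rds")))
}

clips_by_id <- function(cfg) {
  clips <- project_clips(cfg)
  names(clips) <- clip_ids(clips)
  clips
}

clip_sequences <- function(cfg, ids, clips, hp) {
  mf <- read_manifest(cfg)
  fps <- mf$videos[[1L]]$fps
  do.call(c, lapply(ids, function(cid) {
    split_into_sequences(clip_reduced_features(cfg, cid),
                         clips[[cid]]$labels, fps, hp$sequence_seconds)
  }))
}

pipeline_hp <- function(cfg) {
  cc <- cfg$classifier
  default_hyperparameters(
    max_epochs = cc$max_epochs, validation_patience = cc$validation_patience,
    initial_lr = cc$initial_lr, lr_drop_period = cc$lr_drop_period,
    lr_drop_factor = cc$lr_drop_factor, minibatch_size = cc$minibatch_size,
    dropout = cc$dropout, hidden_units = cc$hidden_units,
    sequence_seconds = cc$sequence_seconds
  )
}

stage_train <- function(cfg) {
  sp <- read_split(cfg)
  clips <- clips_by_id(cfg)
  hp <- pipeline_hp(cfg)
  bset <- behavior_set(cfg$behaviors, cfg$background)
  d_in <- ncol(clip_reduced_features(cfg, sp$D_train[[1L]]))
  net <- build_network(bset$K, d_in = d_in, hidden_units = hp$hidden_units,
                       dropout = hp$dropout, seed = cfg$seed,
                       behaviors = bset)
  model <- train_network(net, clip_sequences(cfg, sp$D_train, clips, hp),
                         clip_sequences(cfg, sp$D_validate, clips, hp),
                         hp, seed = cfg$seed)
  saveRDS(model, proj_path(cfg, "model.rds"))
  utils::write.csv(model$log, proj_path(cfg, "training_log.csv"),
                   row.names = FALSE)
  pipe_log(cfg, "train", "%d epochs (%s), best epoch %d", nrow(model$log),
           model$stopping_reason, model$best_epoch)
}

stage_predict <- function(cfg) {
  sp <- read_split(cfg)
  model <- readRDS(proj_path(cfg, "model.rds"))
  mf <- read_manifest(cfg)
  fps <- mf$videos[[1L]]$fps
  dir.create(proj_path(cfg, "predictions"), showWarnings = FALSE)
  for (cid in c(sp$D_unlabeled, sp$D_validate)) {
    pr <- predict_frames(model, clip_reduced_features(cfg, cid), fps)
    saveRDS(pr, proj_path(cfg, "predictions", paste0(cid, ".rds")))
  }
  pipe_log(cfg, "predict", "predictions for %d clips",
           length(sp$D_unlabeled) + length(sp$D_validate))
}

clip_prediction <- function(cfg, clip_id) {
  readRDS(proj_path(cfg, "predictions", paste0(clip_id, ".rds")))
}

stage_confidence <- function(cfg) {
  sp <- read_split(cfg)
  clips <- clips_by_id(cfg)
  bset <- behavior_set(cfg$behaviors, cfg$background)
  val_logits <- do.call(rbind, lapply(sp$D_validate, function(cid)
    clip_prediction(cfg, cid)$logits))
  val_labels <- unlist(lapply(sp$D_validate, function(cid)
    clips[[cid]]$labels))
  tm <- tryCatch(
    fit_temperature(val_logits, val_labels, bset),
    error = function(e) {
      # single-class validation labels: calibration is undefined, keep raw
      # softmax scores (T = 1) rather than failing the pipeline
      pipe_log(cfg, "confidence",
               "temperature fit degenerate (%s); using T = 1",
               conditionMessage(e))
      structure(list(T = 1, nll = NA_real_, nll_1 = NA_real_,
                     n = nrow(val_logits)),
                class = "temperature_model")
    })
  rows <- lapply(sp$D_unlabeled, function(cid) {
    pr <- clip_prediction(cfg, cid)
    data.frame(
      clip_id = cid, n_frames = pr$n,
      conf_softmax = clip_confidence(softmax_confidence(pr$logits)),
      conf_temperature = clip_confidence(scaled_confidence(pr$logits, tm$T)),
      acc = if (is.null(clips[[cid]]$labels)) NA_real_ else
        clip_accuracy(pr$labels, clips[[cid]]$labels),
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, proj_path(cfg, "confidence.csv"), row.names = FALSE)
  saveRDS(tm, proj_path(cfg, "temperature.rds"))
  pipe_log(cfg, "confidence", "T = %.3f; dataset conf = %.3f", tm$T,
           dataset_confidence(df$conf_temperature, df$n_frames))
}

confidence_column <- function(cfg) {
  if (cfg$confidence_method == "temperature") "conf_temperature"
  else "conf_softmax"
}

stage_review <- function(cfg) {
  df <- utils::read.csv(proj_path(cfg, "confidence.csv"),
                        stringsAsFactors = FALSE)
  conf <- df[[confidence_column(cfg)]]
  ord <- confidence_ordering(conf, df$clip_id)
  utils::write.csv(
    data.frame(clip_id = df$clip_id[ord], confidence = conf[ord],
               rank = seq_along(ord)),
    proj_path(cfg, "review_order.csv"), row.names = FALSE)
  if (!anyNA(df$acc)) {
    rs <- evaluate_review(conf, df$acc, df$n_frames,
                          n_permutations = cfg$review$n_permutations,
                          seed = cfg$seed, ids = df$clip_id)
    curves <- data.frame(k = rs$curve_conf$k,
                         acc_confidence = rs$curve_conf$acc_k,
                         acc_optimal = rs$curve_opt$acc_k,
                         acc_random = rs$curve_rand$acc_k)
    utils::write.csv(curves, proj_path(cfg, "review_curves.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(mean_IOR_conf = rs$IOR_conf$mean_IOR,
           mean_IOR_opt = rs$IOR_opt$mean_IOR,
           review_efficiency = as.numeric(rs$efficiency)),
      proj_path(cfg, "review_summary.json"), auto_unbox = TRUE, digits = NA)
    pipe_log(cfg, "review", "review efficiency = %.3f",
             as.numeric(rs$efficiency))
  } else {
    pipe_log(cfg, "review", "review order written (no ground truth)")
  }
}

stage_evaluate <- function(cfg) {
  sp <- read_split(cfg)
  clips <- clips_by_id(cfg)
  bset <- behavior_set(cfg$behaviors, cfg$background)
  pred <- unlist(lapply(sp$D_test, function(cid)
    clip_prediction(cfg, cid)$labels))
  true <- unlist(lapply(sp$D_test, function(cid) clips[[cid]]$labels))
  if (is.null(true) || anyNA(true))
    abort_invalid("evaluation requires ground-truth labels for the test clips")
  prf <- per_class_prf(pred, true, bset)
  cm <- confusion_matrix(pred, true, bset)
  df <- utils::read.csv(proj_path(cfg, "confidence.csv"),
                        stringsAsFactors = FALSE)
  cal <- calibration_errors(df[[confidence_column(cfg)]], df$acc,
                            df$n_frames)
  out <- list(
    accuracy = accuracy(pred, true),
    F1_all = prf$F1_all,
    per_class = prf$per_class,
    MAE = cal$MAE, MSD = cal$MSD,
    dataset_confidence = dataset_confidence(df[[confidence_column(cfg)]],
                                            df$n_frames),
    dataset_accuracy = dataset_confidence(df$acc, df$n_frames)
  )
  jsonlite::write_json(out, proj_path(cfg, "metrics.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  utils::write.csv(as.data.frame(cm), proj_path(cfg, "confusion.csv"))
  pipe_log(cfg, "evaluate", "test accuracy = %.3f, F1_all = %.3f",
           out$accuracy, out$F1_all)
}

#' Export annotations for all clips
#'
#' Writes the project's final ethogram: a per-frame CSV and a bout-interval
#' CSV covering every clip, with human labels for labeled clips
#' (`source = "human"`) and classifier predictions for the rest
#' (`source = "classifier"`, with a confidence column when requested).
#'
#' @param cfg A `pipeline_config`.
#' @param include_confidence Add the clip confidence score to predicted rows
#'   (default TRUE).
#' @param partial Allow clips that have neither labels nor predictions to be
#'   skipped instead of erroring (default FALSE).
#' @return Paths of the two files, invisibly.
#' @export
export_annotations <- function(cfg, include_confidence = TRUE,
                               partial = FALSE) {
  sp <- read_split(cfg)
  clips <- clips_by_id(cfg)
  conf_df <- tryCatch(utils::read.csv(proj_path(cfg, "confidence.csv"),
                                      stringsAsFactors = FALSE),
                      error = function(e) NULL)
  frame_rows <- list()
  bout_rows <- list()
  for (cid in names(clips)) {
    cl <- clips[[cid]]
    labeled <- cid %in% sp$D_labeled
    if (labeled) {
      labs <- cl$labels
      src <- "human"
      conf <- NA_real_
    } else if (file.exists(proj_path(cfg, "predictions",
                                     paste0(cid, ".rds")))) {
      pr <- clip_prediction(cfg, cid)
      labs <- pr$labels
      src <- "classifier"
      conf <- if (!is.null(conf_df) && cid %in% conf_df$clip_id)
        conf_df[[confidence_column(cfg)]][match(cid, conf_df$clip_id)]
      else NA_real_
    } else if (partial) {
      next
    } else {
      abort_invalid("clip %s has neither labels nor predictions; %s", cid,
                    "run `predict` or export with partial = TRUE")
    }
    fr <- data.frame(video_id = cl$video_id,
                     frame = cl$start + seq_len(cl$size) - 1L,
                     label = labs, source = src, stringsAsFactors = FALSE)
    bt <- labels_to_bouts(labs, cl$video_id, offset = cl$start)
    bt$source <- src
    if (include_confidence) {
      fr$confidence <- conf
      bt$confidence <- conf
    }
    frame_rows[[cid]] <- fr
    bout_rows[[cid]] <- bt
  }
  fr_all <- do.call(rbind, frame_rows)
  bt_all <- do.call(rbind, bout_rows)
  fr_all <- fr_all[order(fr_all$video_id, fr_all$frame), ]
  p1 <- proj_path(cfg, "export_frames.csv")
  p2 <- proj_path(cfg, "export_bouts.csv")
  write_annotation_csv(fr_all, p1)
  write_annotation_csv(bt_all, p2)
  invisible(c(frames = p1, bouts = p2))
}

stage_export <- function(cfg) {
  paths <- export_annotations(cfg, include_confidence = TRUE, partial = FALSE)
  pipe_log(cfg, "export", "wrote %s and %s", basename(paths[1L]),
           basename(paths[2L]))
}
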