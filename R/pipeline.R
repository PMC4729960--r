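#' Read and validate a pipeline run configuration
#'
#' The configuration is a YAML file with the replicate inputs, the marker /
#' annotation files, per-stage parameter blocks and one global seed that
#' governs every stochastic stage. Referenced files are checked at
#' validation time, before any compute.
#'
#' Recognized keys (defaults in parentheses):
#' ```yaml
#' replicates:            # one or more PSM tables
#'   - psm: exp1.tsv
#'   - psm: exp2.tsv
#' channels: [TMT126, ...]   # optional, default TMT 10-plex
#' markers: markers.tsv
#' annotation: annotation.tsv   # optional; enables FDR gating
#' max_missing: 4
#' discovery:             # optional block; presence enables discovery
#'   n_iterations: 200
#'   outlier_level: 0.05
#'   min_group_size: 20
#' classifier:
#'   n_repeats: 100
#'   n_folds: 5
#' threshold:
#'   target_fdr: 0.05
#'   min_annotated: 10
#' seed: 1
#' output_dir: out/
#' ```
#' @param path YAML file.
#' @return a validated `RunConfig` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$replicates) || length(cfg$replicates) < 1)
    stop("config must declare at least one replicate PSM table")
  for (r in cfg$replicates) {
    if (is.null(r$psm)) stop("each replicate needs a 'psm' path")
    if (!file.exists(r$psm)) stop("replicate PSM file not found: ", r$psm)
  }
  if (is.null(cfg$markers)) stop("config must declare a marker file")
  if (!file.exists(cfg$markers)) stop("marker file not found: ", cfg$markers)
  if (!is.null(cfg$annotation) && !file.exists(cfg$annotation))
    stop("annotation file not found: ", cfg$annotation)
  cfg$channels <- if (is.null(cfg$channels)) tmt10_channels()
                  else as.character(cfg$channels)
  cfg$max_missing <- if (is.null(cfg$max_missing)) 4L
                     else as.integer(cfg$max_missing)
  cfg$seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  cfg$output_dir <- if (is.null(cfg$output_dir)) "spatialmap_out"
                    else cfg$output_dir
  cfg$version <- "1"
  structure(cfg, class = "RunConfig")
}

.stage_log <- function(con, stage, ...) {
  rec <- c(list(stage = stage, time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
           list(...))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
}

#' Run the end-to-end localization pipeline
#'
#' Stages, in order: read + missing-filter + aggregate + normalize each
#' replicate; fuse replicates (skipped for a single replicate); load
#' markers; optional phenotype discovery; SVM training; scoring; FDR
#' threshold calibration (when an annotation file is configured, otherwise
#' every prediction is reported ungated with threshold 0); assignment; QC
#' (replicate concordance when >= 2 replicates); PCA map. Every stage's
#' parameters and outputs are appended to a JSON-lines run log; rerunning
#' the same config reproduces identical outputs.
#'
#' @param config a [read_run_config()] object (or path to one).
#' @return invisible list with the main artifacts (`result`, `model`,
#'   `thresholds`, `projection`, `qc`, paths).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$output_dir, "run_log.jsonl")
  con <- file(log_path, open = "wt")
  on.exit(close(con), add = TRUE)
  .stage_log(con, "config", config = unclass(config))

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      .stage_log(con, stage, error = conditionMessage(e))
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  mats <- run_stage("normalize", {
    lapply(seq_along(config$replicates), function(i) {
      psms <- read_psm_table(config$replicates[[i]]$psm,
                             channels = config$channels)
      psms <- filter_missing(psms, max_missing = config$max_missing)
      m <- normalize_sum_to_one(aggregate_psms_to_proteins(psms))
      .stage_log(con, "normalize", replicate = i,
                 n_psms = nrow(psms), n_proteins = nrow(m))
      m
    })
  })
  fused <- run_stage("fuse", {
    if (length(mats) >= 2) {
      f <- fuse_replicates(mats)
      .stage_log(con, "fuse", n_rows = nrow(f), n_channels = ncol(f))
      f
    } else mats[[1]]
  })
  markers <- run_stage("markers", load_markers(config$markers))

  if (!is.null(config$discovery)) {
    disc <- run_stage("discovery", {
      dp <- do.call(discovery_params,
                    c(config$discovery, list(seed = config$seed)))
      phenodisco(fused, markers, dp)
    })
    markers <- disc$augmented_markers
    write_markers(markers, file.path(config$output_dir,
                                     "markers_augmented.tsv"))
    .stage_log(con, "discovery", new_classes = disc$new_classes,
               rounds = disc$rounds_run)
  }

  clf <- run_stage("train", {
    cp <- do.call(classifier_params,
                  c(config$classifier, list(seed = config$seed)))
    train_svm(fused, markers, cp)
  })
  .stage_log(con, "train", sigma = clf$sigma, cost = clf$cost,
             outer_f1 = mean(clf$outer_f1))
  model_path <- file.path(config$output_dir, "model.json")
  write_model(clf, model_path)

  parts <- attach_markers(fused, markers)
  scores <- run_stage("score", score_proteins(clf, parts$unlabelled))
  thresholds <- run_stage("calibrate", {
    if (!is.null(config$annotation)) {
      ann <- load_annotation(config$annotation, vocabulary = clf$classes)
      tp <- do.call(threshold_params,
                    if (is.null(config$threshold)) list() else config$threshold)
      calibrate_thresholds(scores, ann, tp)
    } else stats::setNames(rep(0, length(clf$classes)), clf$classes)
  })
  .stage_log(con, "calibrate", thresholds = as.list(thresholds))
  result <- run_stage("assign", assign_classes(scores, thresholds, markers))
  result_path <- file.path(config$output_dir, "result.tsv")
  utils::write.table(result, result_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  .stage_log(con, "assign", n_assigned = sum(result$final_label != "UNASSIGNED"),
             n_total = nrow(result))

  qc <- run_stage("qc", {
    medians <- class_median_profiles(fused, markers)
    dist_own <- distance_to_medians(parts$labelled, medians)
    list(class_medians = medians, marker_distances = dist_own)
  })
  proj <- run_stage("project", project_pca(fused, k = 2L))
  write_projection(proj, file.path(config$output_dir, "pca.tsv"))
  run_stage("plot", render_map(proj, result,
                               file = file.path(config$output_dir, "map.png")))
  .stage_log(con, "done", outputs = c("result.tsv", "model.json", "pca.tsv",
                                      "map.png", "run_log.jsonl"))
  invisible(list(result = result, model = clf, thresholds = thresholds,
                 projection = proj, qc = qc,
                 paths = list(result = result_path, model = model_path,
                              log = log_path)))
}

#' Serialize the trained classifier's metadata as JSON
#'
#' Stores the searched grids, the winning hyperparameters, class weights and
#' the cross-validation F1 table (the fitted kernel machine itself is a
#' binary in-memory object; retrain from the profiles and the stored
#' parameters to reproduce it exactly).
#' @export
write_model <- function(clf, path) {
  stopifnot(inherits(clf, "TrainedClassifier"))
  jsonlite::write_json(
    list(kernel = "rbf (exp(-sigma * ||x - y||^2))",
         sigma = clf$sigma, cost = clf$cost,
         class_weights = as.list(clf$class_weights),
         classes = clf$classes, channels = clf$channels,
         outer_f1 = clf$outer_f1, cv_f1 = clf$cv_f1),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
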