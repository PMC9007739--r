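#' Pipeline configuration with documented defaults
#'
#' Collects every named hyperparameter of the pipeline with its default:
#' score-map smoothing `sigma` (1 grid cell), peak `min_confidence` (0.01)
#' and `nms_radius` (2 cells), PAF `n_samples` (10) and `paf_threshold`
#' (0.1), temporal coherence `gamma` (0.01), tracker `iou_threshold` (0.6),
#' `min_hits` (1), `max_age` (1), stitching `residual_min_length` (5 frames)
#' and `max_gap` (NULL = automatic 1.5-tau rule), equal affinity weights,
#' `appearance_strength` (0.5), evaluation `pck_fraction` (1/3) and `oks_sd`
#' (0.1). Unknown keys are rejected; every value is validated against its
#' domain.
#'
#' @param ... overrides of the defaults.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    sigma = 1, min_confidence = 0.01, nms_radius = 2L,
    n_samples = 10L, paf_method = "projection", paf_threshold = 0.1,
    gamma = 0.01, temporal_window = 0L,
    tracker = "ellipse", iou_threshold = 0.6, min_hits = 1L, max_age = 1L,
    box_margin = 0,
    residual_min_length = 5L, max_gap = NULL,
    affinity_weights = c(motion = 1, proximity = 1, shape = 1, dynamics = 1),
    appearance_strength = 0.5, id_weight = 0,
    n_animals = NULL,
    pck_fraction = 1 / 3, oks_sd = 0.1,
    mot_match_threshold = NULL,
    seed = 1L
  )
  over <- list(...)
  if (length(over) == 1 && is.list(over[[1]]) && is.null(names(over))) {
    over <- over[[1]]
  }
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, over)
  validate_pipeline_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_pipeline_config <- function(cfg) {
  stopifnot(
    cfg$sigma >= 0,
    cfg$min_confidence > 0, cfg$min_confidence < 1,
    cfg$nms_radius >= 1,
    cfg$n_samples >= 2,
    cfg$paf_method %in% c("projection", "norm"),
    cfg$gamma >= 0,
    cfg$tracker %in% c("ellipse", "box"),
    cfg$iou_threshold >= 0, cfg$iou_threshold <= 1,
    cfg$min_hits >= 1, cfg$max_age >= 1,
    cfg$residual_min_length >= 1,
    is.null(cfg$max_gap) || cfg$max_gap >= 1,
    all(cfg$affinity_weights >= 0),
    cfg$appearance_strength >= 0, cfg$appearance_strength <= 1,
    cfg$id_weight >= 0, cfg$id_weight < 1,
    cfg$pck_fraction > 0,
    cfg$oks_sd > 0
  )
  invisible(cfg)
}

#' Write / read a pipeline configuration as YAML
#'
#' `read_config(write_config(cfg))` reproduces the canonical form; unknown
#' keys in the file are rejected by [pipeline_config()].
#'
#' @param cfg a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$affinity_weights <- as.list(out$affinity_weights)
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw <- raw[!vapply(raw, is.null, logical(1))] # nulls mean "use default"
  if (!is.null(raw$affinity_weights)) {
    raw$affinity_weights <- unlist(raw$affinity_weights)
  }
  do.call(pipeline_config, raw)
}

#' Ground-truth per-frame centroid table of a scene
#'
#' @param scene a `gt_scene`.
#' @param visible_only drop frames where the animal is occluded.
#' @return data.frame `id`, `frame`, `x`, `y`.
#' @export
scene_gt_centroids <- function(scene, visible_only = TRUE) {
  n_frames <- dim(scene$coords)[1]
  n_animals <- dim(scene$coords)[2]
  rows <- list()
  for (a in seq_len(n_animals)) {
    for (f in seq_len(n_frames)) {
      vis <- scene$visible[f, a, ]
      if (visible_only && !any(vis)) next
      co <- scene$coords[f, a, , , drop = FALSE]
      dim(co) <- dim(scene$coords)[3:4]
      rows[[length(rows) + 1]] <- data.frame(
        id = a, frame = f, x = mean(co[, 1]), y = mean(co[, 2]))
    }
  }
  do.call(rbind, rows)
}

#' Run the full pipeline on a synthetic scene
#'
#' Executes detection (either decoding rendered target tensors or corrupting
#' ground truth into noisy detection tables), per-frame assembly with PAF
#' affinities from the rendered fields, local tracking, tracklet stitching
#' and CLEAR-MOT evaluation against the scene's ground truth.
#'
#' @param scene a `gt_scene`.
#' @param config a `pipeline_config`.
#' @param detection_source "corrupt" (noisy detection tables, default) or
#'   "decode" (decode rendered tensors; noiseless).
#' @param graph part affinity graph; defaults to the scene skeleton.
#' @param embeddings optional per-tracklet appearance embeddings (matrix or
#'   function(tracklets) returning one).
#' @return list with `detections`, `assemblies`, `tracklets`, `tracks`,
#'   `track_table`, `mot` (stitched evaluation), `mot_tracklets` (naive
#'   tracklet baseline evaluation), and a `log` of per-stage counts.
#' @export
run_pipeline <- function(scene, config = pipeline_config(),
                         detection_source = c("corrupt", "decode"),
                         graph = NULL, embeddings = NULL) {
  detection_source <- match.arg(detection_source)
  cfg <- config
  scfg <- scene$config
  if (is.null(graph)) graph <- paf_graph(scfg$skeleton_template)
  k <- cfg$n_animals %||% scfg$n_animals
  n_frames <- dim(scene$coords)[1]
  log <- list(config = cfg, seed = cfg$seed)

  # stage 1: detections + per-frame PAF tensors
  targets <- lapply(seq_len(n_frames), function(f) {
    render_targets(scene, f, scfg)
  })
  detections <- if (detection_source == "corrupt") {
    corrupt_detections(scene, scfg, seed = cfg$seed + 1L)
  } else {
    do.call(rbind, lapply(seq_len(n_frames), function(f) {
      det <- decode_detections(targets[[f]], cfg$sigma, cfg$min_confidence,
                               cfg$nms_radius)
      if (nrow(det) > 0) cbind(frame = f, det) else NULL
    }))
  }
  log$n_detections <- nrow(detections)

  # stage 2: assembly
  assemblies <- assemble_video(
    detections, function(f) targets[[f]]$pafs, graph, scfg$stride,
    options = list(paf_threshold = cfg$paf_threshold,
                   temporal_window = cfg$temporal_window,
                   gamma = cfg$gamma,
                   n_samples = cfg$n_samples, method = cfg$paf_method,
                   paf_edges = scfg$skeleton_template))
  log$n_assemblies <- sum(vapply(assemblies, function(a) {
    length(a$assemblies)
  }, integer(1)))

  # stage 3: local tracking
  frames_for_tracking <- lapply(assemblies, `[[`, "assemblies")
  names(frames_for_tracking) <- names(assemblies)
  tracklets <- track_video(
    frames_for_tracking, method = cfg$tracker,
    min_hits = cfg$min_hits, max_age = cfg$max_age,
    iou_threshold = cfg$iou_threshold, margin = cfg$box_margin,
    id_weight = cfg$id_weight)
  log$n_tracklets <- length(tracklets)

  # stage 4: stitching
  emb <- if (is.function(embeddings)) embeddings(tracklets) else embeddings
  stitched <- stitch_tracklets(
    tracklets, k, min_length = cfg$residual_min_length,
    max_gap = cfg$max_gap, weights = cfg$affinity_weights,
    embeddings = emb, appearance_strength = cfg$appearance_strength)
  log$n_tracks <- length(stitched$tracks)

  # stage 5: evaluation
  gt <- scene_gt_centroids(scene)
  thr <- cfg$mot_match_threshold %||%
    (0.5 * sqrt(scfg$body_length^2 + scfg$body_width^2))
  mot <- mot_evaluate(tracks_to_centroids(stitched$tracks), gt, thr)
  mot_tl <- mot_evaluate(tracklets_to_centroids(tracklets), gt, thr)

  list(detections = detections, assemblies = assemblies,
       tracklets = tracklets, tracks = stitched$tracks,
       track_table = tracks_to_table(stitched$tracks),
       residual_report = stitched$residual_report,
       mot = mot, mot_tracklets = mot_tl, log = log)
}
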