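#' Write / read the detection interchange table
#'
#' One tabular file per video: comma-separated with header, columns `frame`,
#' `bodypart`, `x`, `y`, `confidence`, optional `gt_animal` and
#' `id_prob_1..id_prob_n`. Round trips exactly.
#'
#' @param detections detection data.frame.
#' @param path file path.
#' @export
write_detections <- function(detections, path) {
  utils::write.csv(detections, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_detections
#' @return `read_detections`: the detection data.frame; malformed rows raise
#'   an error naming the row.
#' @export
read_detections <- function(path) {
  det <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("frame", "bodypart", "x", "y", "confidence")
  missing_cols <- setdiff(required, names(det))
  if (length(missing_cols)) {
    stop(sprintf("detection table %s lacks column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  for (cn in c("frame", "bodypart", "x", "y", "confidence")) {
    v <- det[[cn]]
    bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))
    if (length(bad)) {
      stop(sprintf("malformed value in column '%s' at data row %d of %s",
                   cn, bad[1], path), call. = FALSE)
    }
  }
  det
}

#' Write / read the track table
#'
#' Columns `track_id`, `frame`, `bodypart`, `x`, `y`, `confidence`.
#'
#' @param tracks track table ([tracks_to_table()]).
#' @param path file path.
#' @export
write_tracks <- function(tracks, path) {
  utils::write.csv(tracks, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("track_id", "frame", "bodypart", "x", "y")
  missing_cols <- setdiff(required, names(tr))
  if (length(missing_cols)) {
    stop(sprintf("track table %s lacks column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  tr
}

#' Write a scene's ground truth as COCO-keypoints JSON
#'
#' Standard COCO layout: `images` (one per frame), `annotations` with
#' `keypoints` triplets (x, y, v) — v = 2 visible, 0 not labelled — plus
#' `bbox`, `area`, and a `categories` entry carrying the bodypart names and
#' skeleton.
#'
#' @param scene a `gt_scene`.
#' @param path output JSON path.
#' @export
write_coco_json <- function(scene, path) {
  cfg <- scene$config
  n_frames <- dim(scene$coords)[1]
  n_animals <- dim(scene$coords)[2]
  K <- dim(scene$coords)[3]
  images <- lapply(seq_len(n_frames), function(f) {
    list(id = f, width = cfg$image_size[2], height = cfg$image_size[1],
         file_name = sprintf("frame%05d.png", f))
  })
  annotations <- list()
  aid <- 0L
  for (f in seq_len(n_frames)) {
    for (a in seq_len(n_animals)) {
      vis <- scene$visible[f, a, ]
      if (!any(vis)) next
      kpts <- numeric(3 * K)
      for (k in seq_len(K)) {
        if (vis[k]) {
          kpts[3 * k - 2] <- scene$coords[f, a, k, 1]
          kpts[3 * k - 1] <- scene$coords[f, a, k, 2]
          kpts[3 * k] <- 2
        }
      }
      co <- scene$coords[f, a, vis, , drop = FALSE]
      dim(co) <- c(sum(vis), 2)
      bb <- bbox_from_keypoints(co)
      aid <- aid + 1L
      annotations[[aid]] <- list(
        id = aid, image_id = f, category_id = 1L,
        keypoints = kpts, num_keypoints = sum(vis),
        bbox = c(bb[1], bb[2], bb[3] - bb[1], bb[4] - bb[2]),
        area = (bb[3] - bb[1]) * (bb[4] - bb[2]),
        track_id = a, iscrowd = 0L
      )
    }
  }
  obj <- list(
    images = images,
    annotations = annotations,
    categories = list(list(
      id = 1L, name = "animal",
      keypoints = scene$bodyparts,
      skeleton = apply(cfg$skeleton_template, 1, identity, simplify = FALSE)
    ))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read COCO-keypoints JSON
#'
#' @param path JSON path.
#' @return data.frame `frame`, `gt_animal` (track id or annotation id),
#'   `bodypart`, `x`, `y`; keypoints with visibility 0 are absent.
#' @export
read_coco_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- list()
  for (ann in obj$annotations) {
    kp <- unlist(ann$keypoints)
    K <- length(kp) %/% 3
    for (k in seq_len(K)) {
      v <- kp[3 * k]
      if (v > 0) {
        rows[[length(rows) + 1]] <- data.frame(
          frame = ann$image_id,
          gt_animal = ann$track_id %||% ann$id,
          bodypart = k, x = kp[3 * k - 2], y = kp[3 * k - 1]
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(frame = integer(), gt_animal = integer(),
                      bodypart = integer(), x = numeric(), y = numeric())
  }
  out
}

#' Serialize / load a part affinity graph
#'
#' Plain-text edge list (two bodypart indices per line) plus an optional
#' per-edge auROC column.
#'
#' @param graph a `paf_graph`.
#' @param path file path.
#' @export
write_graph <- function(graph, path) {
  df <- data.frame(i = graph$edges[, 1], j = graph$edges[, 2])
  if (!is.null(graph$auroc)) df$auroc <- graph$auroc
  utils::write.table(df, path, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname write_graph
#' @export
read_graph <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  paf_graph(cbind(df$i, df$j), auroc = df$auroc)
}

#' Write / read per-tracklet appearance embeddings
#'
#' Plain numeric table keyed by tracklet id: first column `tracklet_id`,
#' remaining columns the embedding dimensions.
#'
#' @param embeddings matrix (tracklets x dims) with tracklet ids as rownames
#'   (or 1..n).
#' @param path file path.
#' @export
write_embeddings <- function(embeddings, path) {
  df <- data.frame(tracklet_id = rownames(embeddings) %||%
                     seq_len(nrow(embeddings)), embeddings)
  utils::write.table(df, path, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$tracklet_id
  m
}
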