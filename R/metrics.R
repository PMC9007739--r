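#' Keypoint detection error (distance to nearest prediction)
#'
#' For every ground-truth keypoint, the Euclidean distance to the closest
#' predicted keypoint of the same bodypart; aggregated as root-mean-square
#' (default), mean or median.
#'
#' @param pred,gt data.frames with `bodypart`, `x`, `y` (and optionally
#'   `frame`, matched when present in both).
#' @param aggregate "rms", "mean" or "median".
#' @return aggregated error in px (`NA` if no gt keypoint has a prediction).
#' @export
rmse <- function(pred, gt, aggregate = c("rms", "mean", "median")) {
  aggregate <- match.arg(aggregate)
  stopifnot(nrow(gt) >= 1)
  d <- nearest_errors(pred, gt)
  d <- d[!is.na(d)]
  if (length(d) == 0) return(NA_real_)
  switch(aggregate,
         rms = sqrt(mean(d^2)),
         mean = mean(d),
         median = stats::median(d))
}

nearest_errors <- function(pred, gt) {
  use_frame <- "frame" %in% names(pred) && "frame" %in% names(gt)
  vapply(seq_len(nrow(gt)), function(r) {
    sel <- pred$bodypart == gt$bodypart[r]
    if (use_frame) sel <- sel & pred$frame == gt$frame[r]
    if (!any(sel)) return(NA_real_)
    min(sqrt((pred$x[sel] - gt$x[r])^2 + (pred$y[sel] - gt$y[r])^2))
  }, numeric(1))
}

#' Percentage of correct keypoints (PCK)
#'
#' Fraction of ground-truth keypoints whose nearest same-bodypart prediction
#' falls within `fraction` times a per-frame reference distance (e.g. a third
#' of the left-right ear distance). Frames whose reference distance is zero
#' are skipped with a warning.
#'
#' @param pred,gt data.frames with `frame`, `bodypart`, `x`, `y`; `gt`
#'   additionally needs `gt_animal` for the reference pair lookup.
#' @param reference_pair length-2 bodypart indices defining the reference
#'   distance (measured per frame and animal, then averaged per frame).
#' @param fraction threshold as a fraction of the reference distance
#'   (default 1/3).
#' @return fraction of correct keypoints in [0, 1].
#' @export
pck <- function(pred, gt, reference_pair, fraction = 1 / 3) {
  stopifnot(length(reference_pair) == 2)
  frames <- unique(gt$frame)
  correct <- 0L
  total <- 0L
  for (f in frames) {
    g <- gt[gt$frame == f, , drop = FALSE]
    refs <- numeric(0)
    for (a in unique(g$gt_animal)) {
      p1 <- g[g$gt_animal == a & g$bodypart == reference_pair[1], ,
              drop = FALSE]
      p2 <- g[g$gt_animal == a & g$bodypart == reference_pair[2], ,
              drop = FALSE]
      if (nrow(p1) == 1 && nrow(p2) == 1) {
        refs <- c(refs, euclid(c(p1$x, p1$y), c(p2$x, p2$y)))
      }
    }
    ref <- mean(refs)
    if (!length(refs) || !is.finite(ref) || ref <= 0) {
      warning(sprintf("frame %s skipped: zero reference distance", f))
      next
    }
    d <- nearest_errors(pred[pred$frame == f, , drop = FALSE], g)
    d <- d[!is.na(d)] # undetected keypoints are handled by rmse/mAP, not PCK
    correct <- correct + sum(d <= fraction * ref)
    total <- total + length(d)
  }
  if (total == 0) return(NA_real_)
  correct / total
}

oks_similarity <- function(pred_coords, gt_coords, gt_vis, area, kpt_sd,
                           swap_pairs = NULL) {
  kappa2 <- (2 * kpt_sd)^2
  term <- function(pc) {
    d2 <- rowSums((pc - gt_coords)^2)
    e <- exp(-d2 / (2 * max(area, 1) * kappa2))
    e[!gt_vis | !stats::complete.cases(pc)] <- NA
    e
  }
  e <- term(pred_coords)
  if (!is.null(swap_pairs)) {
    for (r in seq_len(nrow(swap_pairs))) {
      a <- swap_pairs[r, 1]
      b <- swap_pairs[r, 2]
      pc <- pred_coords
      pc[c(a, b), ] <- pred_coords[c(b, a), ]
      ef <- term(pc)
      orig <- sum(e[c(a, b)], na.rm = TRUE)
      flip <- sum(ef[c(a, b)], na.rm = TRUE)
      if (flip > orig) e[c(a, b)] <- ef[c(a, b)]
    }
  }
  vis_n <- sum(gt_vis)
  if (vis_n == 0) return(NA_real_)
  sum(e[gt_vis], na.rm = TRUE) / vis_n
}

#' Mean average precision over OKS thresholds
#'
#' COCO-style evaluation of assemblies: per frame, predictions (sorted by
#' score) greedily match the ground-truth animal of highest object keypoint
#' similarity (OKS) above the threshold; average precision is computed from
#' the pooled ranked detections and averaged over thresholds 0.50 to 0.95 in
#' steps of 0.05. OKS uses the ground-truth bounding-box area and keypoint
#' standard deviation `kpt_sd` (kappa = 2 * kpt_sd); configured symmetric
#' keypoint pairs are evaluated under the best flip.
#'
#' @param frames list; each element has `pred` (list of assemblies: `coords`
#'   K x 2 with NA for missing, `score`) and `gt` (list of animals: `coords`
#'   K x 2, `visible` logical K).
#' @param kpt_sd keypoint standard deviation (default 0.1).
#' @param thresholds OKS thresholds (default `seq(0.5, 0.95, 0.05)`).
#' @param swap_pairs optional matrix of symmetric bodypart index pairs.
#' @return list with `map` and per-threshold `ap`.
#' @export
oks_map <- function(frames, kpt_sd = 0.1, thresholds = seq(0.5, 0.95, 0.05),
                    swap_pairs = NULL) {
  # precompute OKS matrices per frame
  pre <- lapply(frames, function(fr) {
    np <- length(fr$pred)
    ng <- length(fr$gt)
    M <- matrix(NA_real_, np, ng)
    for (gi in seq_len(ng)) {
      g <- fr$gt[[gi]]
      vis <- g$visible & stats::complete.cases(g$coords)
      if (!any(vis)) next
      bb <- bbox_from_keypoints(g$coords[vis, , drop = FALSE])
      area <- max((bb[3] - bb[1]) * (bb[4] - bb[2]), 1)
      for (pi in seq_len(np)) {
        M[pi, gi] <- oks_similarity(fr$pred[[pi]]$coords, g$coords, vis,
                                    area, kpt_sd, swap_pairs)
      }
    }
    scores <- vapply(fr$pred, function(p) p$score %||% 0, numeric(1))
    list(M = M, scores = scores,
         n_gt = sum(vapply(fr$gt, function(g) any(g$visible), logical(1))))
  })
  total_gt <- sum(vapply(pre, `[[`, numeric(1), "n_gt"))
  ap <- vapply(thresholds, function(thr) {
    scores <- numeric(0)
    matched <- logical(0)
    for (fr in pre) {
      np <- nrow(fr$M)
      if (np == 0) next
      taken <- logical(ncol(fr$M))
      ord <- order(-fr$scores)
      hit <- logical(np)
      for (pi in ord) {
        oks <- fr$M[pi, ]
        oks[taken] <- NA
        if (all(is.na(oks))) next
        best <- which.max(oks)
        if (!is.na(oks[best]) && oks[best] >= thr) {
          taken[best] <- TRUE
          hit[pi] <- TRUE
        }
      }
      scores <- c(scores, fr$scores)
      matched <- c(matched, hit)
    }
    if (total_gt == 0 || length(scores) == 0) return(0)
    ord <- order(-scores)
    tp <- cumsum(matched[ord])
    fp <- cumsum(!matched[ord])
    recall <- tp / total_gt
    precision <- tp / (tp + fp)
    # interpolated AP: precision envelope integrated over recall steps
    penv <- rev(cummax(rev(precision)))
    sum(diff(c(0, recall)) * penv)
  }, numeric(1))
  list(map = mean(ap), ap = stats::setNames(ap, thresholds))
}

#' Assembly purity and unconnected fraction
#'
#' Purity: accuracy of assigning each assembly's keypoints to its most
#' frequent ground-truth animal (keypoint-weighted over assemblies).
#' Unconnected fraction: detected true keypoints left in no assembly over all
#' detected true keypoints (clutter detections, with `NA` labels, are
#' excluded from both).
#'
#' @param assemblies list of assemblies (with `members` detection indices).
#' @param gt_labels per-detection ground-truth animal labels (`NA` =
#'   clutter).
#' @param n_detections total number of detections in the frame.
#' @return list with `purity` and `unconnected_fraction` (either may be `NA`
#'   when undefined).
#' @export
assembly_quality <- function(assemblies, gt_labels, n_detections =
                               length(gt_labels)) {
  assigned <- unlist(lapply(assemblies, `[[`, "members"))
  correct <- 0L
  total <- 0L
  for (a in assemblies) {
    lab <- gt_labels[a$members]
    lab <- lab[!is.na(lab)]
    if (length(lab) == 0) next
    correct <- correct + max(table(lab))
    total <- total + length(lab)
  }
  purity <- if (total > 0) correct / total else NA_real_
  true_dets <- which(!is.na(gt_labels))
  unconnected <- if (length(true_dets) > 0) {
    sum(!(true_dets %in% assigned)) / length(true_dets)
  } else NA_real_
  list(purity = purity, unconnected_fraction = unconnected)
}

#' CLEAR-MOT evaluation
#'
#' Frame-by-frame distance-thresholded matching with match persistence (an
#' existing ground-truth-to-hypothesis match is kept while both are present
#' and within the threshold; remaining objects are matched by minimal total
#' distance). MOTA is one minus the normalized sum of misses, false positives
#' and identity switches; fragments count tracking interruptions and
#' mostly-tracked the ground-truth objects matched in at least 80% of their
#' frames.
#'
#' @param tracks data.frame `id`, `frame`, `x`, `y` (hypotheses, one row per
#'   track and frame, e.g. [tracks_to_centroids()]).
#' @param gt_tracks data.frame `id`, `frame`, `x`, `y` (ground truth).
#' @param match_threshold maximal gt-to-hypothesis centroid distance.
#' @return a `mot_report` list: `mota`, `misses`, `false_positives`,
#'   `switches`, `fragments`, `mostly_tracked`, `n_gt`, and `rates` (events
#'   per animal per 100 frames).
#' @export
mot_evaluate <- function(tracks, gt_tracks, match_threshold) {
  frames <- sort(unique(gt_tracks$frame))
  gt_ids <- unique(gt_tracks$id)
  last_match <- stats::setNames(rep(NA, length(gt_ids)), gt_ids) # persistent
  prev_matched <- stats::setNames(rep(FALSE, length(gt_ids)), gt_ids)
  ever_matched <- stats::setNames(rep(FALSE, length(gt_ids)), gt_ids)
  matched_count <- stats::setNames(rep(0L, length(gt_ids)), gt_ids)
  present_count <- stats::setNames(rep(0L, length(gt_ids)), gt_ids)
  misses <- fps <- switches <- fragments <- 0L
  total <- 0L
  for (f in frames) {
    g <- gt_tracks[gt_tracks$frame == f, , drop = FALSE]
    h <- tracks[tracks$frame == f, , drop = FALSE]
    total <- total + nrow(g)
    present_count[as.character(g$id)] <-
      present_count[as.character(g$id)] + 1L
    cur <- stats::setNames(rep(NA, nrow(g)), g$id)
    free_h <- rep(TRUE, nrow(h))
    # persistence: keep previous pairs still valid
    for (r in seq_len(nrow(g))) {
      lm <- last_match[as.character(g$id[r])]
      if (!is.na(lm)) {
        hi <- which(h$id == lm & free_h)
        if (length(hi) == 1) {
          d <- euclid(c(g$x[r], g$y[r]), c(h$x[hi], h$y[hi]))
          if (d <= match_threshold) {
            cur[r] <- lm
            free_h[hi] <- FALSE
          }
        }
      }
    }
    # Hungarian on the rest
    gr <- which(is.na(cur))
    hr <- which(free_h)
    if (length(gr) > 0 && length(hr) > 0) {
      D <- outer(gr, hr, Vectorize(function(i, j) {
        euclid(c(g$x[i], g$y[i]), c(h$x[j], h$y[j]))
      }))
      D[D > match_threshold] <- Inf
      sel <- solve_assignment(matrix(D, length(gr), length(hr)))
      for (ii in seq_along(gr)) {
        if (!is.na(sel[ii])) {
          cur[gr[ii]] <- h$id[hr[sel[ii]]]
          free_h[hr[sel[ii]]] <- FALSE
        }
      }
    }
    for (r in seq_len(nrow(g))) {
      key <- as.character(g$id[r])
      if (is.na(cur[r])) {
        misses <- misses + 1L
        prev_matched[key] <- FALSE
      } else {
        lm <- last_match[key]
        if (!is.na(lm) && lm != cur[r]) switches <- switches + 1L
        if (!prev_matched[key] && ever_matched[key]) {
          fragments <- fragments + 1L
        }
        last_match[key] <- cur[r]
        prev_matched[key] <- TRUE
        ever_matched[key] <- TRUE
        matched_count[key] <- matched_count[key] + 1L
      }
    }
    fps <- fps + sum(free_h)
  }
  mota <- 1 - (misses + fps + switches) / max(total, 1L)
  n_frames <- length(frames)
  n_animals <- length(gt_ids)
  rate <- function(x) 100 * x / max(n_animals * n_frames, 1L)
  structure(list(
    mota = mota, misses = misses, false_positives = fps,
    switches = switches, fragments = fragments,
    mostly_tracked = sum(matched_count / pmax(present_count, 1L) >= 0.8),
    n_gt = total,
    rates = list(misses = rate(misses),
                 false_positives = rate(fps),
                 switches = rate(switches))
  ), class = "mot_report")
}

#' @export
print.mot_report <- function(x, ...) {
  cat(sprintf(
    "MOTA %.3f | misses %d, FP %d, switches %d, fragments %d, MT %d (of %d gt)\n",
    x$mota, x$misses, x$false_positives, x$switches, x$fragments,
    x$mostly_tracked, x$n_gt))
  invisible(x)
}

#' Flag potential identity swaps between track pairs
#'
#' Flags frames at which the x and y coordinates of a pair of tracks
#' simultaneously intersect (both coordinate orderings strictly invert
#' between consecutive frames) — the signature of a swap during a close
#' crossing.
#'
#' @param tracks data.frame `id`, `frame`, `x`, `y`.
#' @return data.frame `frame`, `id1`, `id2` (possibly empty).
#' @export
flag_swaps <- function(tracks) {
  ids <- sort(unique(tracks$id))
  out <- list()
  if (length(ids) >= 2) {
    combos <- utils::combn(ids, 2)
    for (ci in seq_len(ncol(combos))) {
      a <- tracks[tracks$id == combos[1, ci], , drop = FALSE]
      b <- tracks[tracks$id == combos[2, ci], , drop = FALSE]
      common <- sort(intersect(a$frame, b$frame))
      if (length(common) < 2) next
      ia <- match(common, a$frame)
      ib <- match(common, b$frame)
      dx <- a$x[ia] - b$x[ib]
      dy <- a$y[ia] - b$y[ib]
      consec <- diff(common) == 1
      crossx <- dx[-length(dx)] * dx[-1] < 0
      crossy <- dy[-length(dy)] * dy[-1] < 0
      hit <- which(consec & crossx & crossy)
      for (hh in hit) {
        out[[length(out) + 1]] <- data.frame(
          frame = common[hh + 1], id1 = combos[1, ci], id2 = combos[2, ci])
      }
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(frame = integer(), id1 = integer(), id2 = integer())
  }
  res
}

#' Proximity Index of animals in a frame
#'
#' For each animal, the disk centred on its centroid with the smallest radius
#' inscribing all of its keypoints; the index is the ratio of other animals'
#' keypoints inside that disk to the animal's own keypoint count.
#'
#' @param frame_animals list of keypoint coordinate matrices (one per
#'   animal).
#' @return numeric vector of per-animal indices.
#' @export
proximity_index <- function(frame_animals) {
  stopifnot(length(frame_animals) >= 1)
  vapply(seq_along(frame_animals), function(ai) {
    own <- frame_animals[[ai]]
    own <- own[stats::complete.cases(own), , drop = FALSE]
    if (nrow(own) == 0) return(NA_real_)
    ctr <- colMeans(own)
    radius <- max(sqrt(rowSums(sweep(own, 2, ctr)^2)))
    others <- do.call(rbind, frame_animals[-ai])
    if (is.null(others) || nrow(others) == 0) return(0)
    others <- others[stats::complete.cases(others), , drop = FALSE]
    inside <- sum(sqrt(rowSums(sweep(others, 2, ctr)^2)) <= radius)
    inside / nrow(own)
  }, numeric(1))
}
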