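# Fixture builders shared across tests (all generated in code).

# detections + affinity tables for one frame of a scene, using the scene's
# rendered (noiseless) PAFs; jitter only, no dropout/clutter by default
frame_fixture <- function(scene, frame, jitter_sd = 0.5, seed = 1,
                          graph = paf_graph(scene$config$skeleton_template)) {
  cfg <- scene$config
  cfg$jitter_sd <- jitter_sd
  cfg$dropout <- 0
  cfg$clutter_rate <- 0
  det <- corrupt_detections(scene, cfg, seed = seed)
  det <- det[det$frame == frame, , drop = FALSE]
  rownames(det) <- NULL
  tg <- render_targets(scene, frame, scene$config)
  tables <- build_affinity_tables(det, tg$pafs, graph, cfg$stride,
                                  paf_edges = scene$config$skeleton_template)
  list(detections = det, tables = tables, targets = tg, graph = graph)
}

# a tracklet built from a deterministic centroid path; keypoints are the
# centroid plus a fixed offset pattern
make_tracklet <- function(id, frames, xy, offsets = NULL) {
  xy <- matrix(xy, ncol = 2)
  if (is.null(offsets)) {
    offsets <- rbind(c(-3, 0), c(0, 0), c(3, 0))
  }
  assemblies <- lapply(seq_along(frames), function(i) {
    co <- sweep(offsets, 2, xy[i, ], "+")
    rownames(co) <- seq_len(nrow(offsets))
    list(members = stats::setNames(seq_len(nrow(offsets)),
                                   seq_len(nrow(offsets))),
         score = 1, coords = co)
  })
  new_tracklet(id, frames, assemblies)
}

# two elongated animals crossing at the centre of the arena; assemblies fed
# straight to the trackers, with occasional outlier keypoints borrowed from
# the other animal while the two are close (the failure mode box trackers
# are sensitive to)
crossing_assemblies <- function(n_frames = 60, outlier_prob = 0.3,
                                seed = 1) {
  set.seed(seed)
  template <- cbind(seq(-12, 12, length.out = 5), rep(0, 5))
  frames <- vector("list", n_frames)
  gt <- list()
  for (f in seq_len(n_frames)) {
    t <- (f - 1) / (n_frames - 1)
    c1 <- c(20 + 160 * t, 100) # left -> right
    c2 <- c(100, 20 + 160 * t) # top -> bottom
    k1 <- sweep(template, 2, c1, "+")
    k2 <- sweep(template %*% t(matrix(c(0, 1, -1, 0), 2, 2)), 2, c2, "+")
    close <- sqrt(sum((c1 - c2)^2)) < 40
    if (close && stats::runif(1) < outlier_prob) {
      k1[5, ] <- k2[3, ] # outlier keypoint from the other animal
    }
    rownames(k1) <- rownames(k2) <- 1:5
    frames[[f]] <- list(
      list(members = stats::setNames(1:5, 1:5), score = 1, coords = k1),
      list(members = stats::setNames(1:5, 1:5), score = 1, coords = k2)
    )
    gt[[length(gt) + 1]] <- data.frame(
      id = c(1, 2), frame = f,
      x = c(mean(k1[, 1]), mean(k2[, 1])),
      y = c(mean(k1[, 2]), mean(k2[, 2])))
  }
  names(frames) <- seq_len(n_frames)
  list(frames = frames, gt = do.call(rbind, gt))
}

# random ground truth + hypothesis tracks for CLEAR-MOT cross-checks
random_mot_scenario <- function(seed, n_frames = 25, n_animals = 3) {
  set.seed(seed)
  gt <- list()
  hyp <- list()
  next_id <- n_animals
  cur_id <- seq_len(n_animals)
  pos <- matrix(stats::runif(2 * n_animals, 20, 180), n_animals, 2)
  for (f in seq_len(n_frames)) {
    pos <- pos + matrix(stats::rnorm(2 * n_animals, 0, 4), n_animals, 2)
    for (a in seq_len(n_animals)) {
      gt[[length(gt) + 1]] <- data.frame(
        id = a, frame = f, x = pos[a, 1], y = pos[a, 2])
      # hypothesis: mostly present, sometimes missing, noisy, id can change
      if (stats::runif(1) < 0.9) {
        if (stats::runif(1) < 0.07) {
          next_id <- next_id + 1L
          cur_id[a] <- next_id
        }
        hyp[[length(hyp) + 1]] <- data.frame(
          id = cur_id[a], frame = f,
          x = pos[a, 1] + stats::rnorm(1, 0, 2),
          y = pos[a, 2] + stats::rnorm(1, 0, 2))
      }
    }
    # spurious detection
    if (stats::runif(1) < 0.15) {
      hyp[[length(hyp) + 1]] <- data.frame(
        id = 999, frame = f,
        x = stats::runif(1, 0, 200), y = stats::runif(1, 0, 200))
    }
  }
  list(gt = do.call(rbind, gt), hyp = do.call(rbind, hyp))
}
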