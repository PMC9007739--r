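#' Partition tracklets into graph tracklets and residuals
#'
#' Tracklets shorter than `min_length` frames are flagged as residuals: they
#' do not contribute to the stitching graph and are reinserted only after
#' stitching.
#'
#' @param tracklets list of `tracklet`s.
#' @param min_length minimal tracklet length in frames (default 5); a
#'   tracklet of exactly `min_length` frames is kept in the graph.
#' @return list with `graph_tracklets` and `residuals`.
#' @export
split_residuals <- function(tracklets, min_length = 5L) {
  stopifnot(min_length >= 1)
  len <- vapply(tracklets, function(t) length(t$frames), integer(1))
  list(graph_tracklets = tracklets[len >= min_length],
       residuals = tracklets[len < min_length])
}

#' Automatic maximal stitching gap
#'
#' `tau` is the smallest temporal gap guaranteeing that all pairs of
#' consecutive tracklets are connected: every tracklet can reach its nearest
#' following tracklet, and every tracklet can be reached from its nearest
#' preceding one. The threshold is `ceiling(1.5 * tau)`, unless overridden.
#'
#' @param tracklets list of `tracklet`s.
#' @param override user-specified gap taking precedence (or `NULL`).
#' @return integer maximal gap in frames.
#' @export
compute_max_gap <- function(tracklets, override = NULL) {
  if (!is.null(override)) return(as.integer(override))
  if (length(tracklets) < 2) return(0L)
  ends <- vapply(tracklets, function(t) t$end, numeric(1))
  starts <- vapply(tracklets, function(t) t$start, numeric(1))
  gaps <- numeric(0)
  for (i in seq_along(tracklets)) {
    after <- starts[starts > ends[i]]
    if (length(after)) gaps <- c(gaps, min(after - ends[i]))
    before <- ends[ends < starts[i]]
    if (length(before)) gaps <- c(gaps, starts[i] - max(before))
  }
  if (length(gaps) == 0) return(0L)
  as.integer(ceiling(1.5 * max(gaps)))
}

tl_velocity <- function(centroids, head = TRUE, n_pts = 3L) {
  n <- nrow(centroids)
  if (n < 2) return(c(0, 0))
  pts <- if (head) centroids[seq_len(min(n_pts, n)), , drop = FALSE] else
    centroids[seq(max(1, n - n_pts + 1), n), , drop = FALSE]
  colMeans(diff(pts))
}

#' Motion affinity between two tracklets
#'
#' Assuming uniform rectilinear motion, the first tracklet's centroid is
#' extrapolated forward (tail velocity, averaged over its three last points)
#' to the start frame of the second, and the second's backward (head
#' velocity) to the end frame of the first; the affinity is the mean of the
#' two prediction errors in pixels. Single-frame tracklets use zero velocity.
#'
#' @param t1,t2 `tracklet`s with `t1$end < t2$start`.
#' @return mean prediction error (px).
#' @export
motion_affinity <- function(t1, t2) {
  stopifnot(t1$end < t2$start)
  dt <- t2$start - t1$end
  v_tail <- tl_velocity(t1$centroids, head = FALSE)
  v_head <- tl_velocity(t2$centroids, head = TRUE)
  c1 <- t1$centroids[nrow(t1$centroids), ]
  c2 <- t2$centroids[1, ]
  d_f <- euclid(c1 + v_tail * dt, c2)
  d_b <- euclid(c2 - v_head * dt, c1)
  (d_f + d_b) / 2
}

#' Spatial proximity between two tracklets
#'
#' Time-overlapping tracklets: mean Euclidean distance between their
#' centroids over the overlapping frames. Disjoint tracklets: distance
#' between the earlier tracklet's tail centroid and the later one's head.
#'
#' @param t1,t2 `tracklet`s.
#' @return distance in pixels.
#' @export
spatial_proximity <- function(t1, t2) {
  common <- intersect(t1$frames, t2$frames)
  if (length(common) > 0) {
    i1 <- match(common, t1$frames)
    i2 <- match(common, t2$frames)
    return(mean(sqrt(rowSums(
      (t1$centroids[i1, , drop = FALSE] -
         t2$centroids[i2, , drop = FALSE])^2))))
  }
  if (t1$end < t2$start) {
    euclid(t1$centroids[nrow(t1$centroids), ], t2$centroids[1, ])
  } else {
    euclid(t2$centroids[nrow(t2$centroids), ], t1$centroids[1, ])
  }
}

tl_keypoints <- function(t, head = TRUE) {
  a <- if (head) t$assemblies[[1]] else t$assemblies[[length(t$assemblies)]]
  m <- a$coords[stats::complete.cases(a$coords), , drop = FALSE]
  m
}

#' Shape similarity between two tracklets
#'
#' Undirected Hausdorff distance between the keypoint set at the tail of the
#' earlier tracklet and the head of the later one; defined for keypoint sets
#' of unequal size. An empty set yields `Inf` (edge disfavoured, not
#' dropped).
#'
#' @param t1,t2 `tracklet`s (t1 earlier).
#' @return Hausdorff distance in pixels.
#' @export
shape_similarity <- function(t1, t2) {
  P <- tl_keypoints(t1, head = FALSE)
  Q <- tl_keypoints(t2, head = TRUE)
  if (nrow(P) == 0 || nrow(Q) == 0) return(Inf)
  pracma::hausdorff_dist(P, Q)
}

# Hankel matrix of a centroid sequence: per coordinate a square-as-possible
# Hankel block, blocks stacked row-wise. Rank via singular values: smallest r
# such that all following singular values are below 1% of the largest.
hankel_rank <- function(centroids, L = NULL, rel_tol = 0.01) {
  n <- nrow(centroids)
  if (is.null(L)) L <- floor(n / 2) + 1
  L <- min(L, n)
  ncols <- n - L + 1
  blocks <- lapply(1:2, function(cc) {
    v <- centroids[, cc]
    H <- matrix(0, L, ncols)
    for (i in seq_len(L)) H[i, ] <- v[i:(i + ncols - 1)]
    H
  })
  H <- do.call(rbind, blocks)
  d <- svd(H, nu = 0, nv = 0)$d
  d <- d[d > 1e-9 * max(d, 1e-12)]
  if (length(d) == 0) return(0L)
  sum(d >= rel_tol * d[1])
}

#' Dynamic similarity between two tracklets
#'
#' Effective ranks of the centroid Hankel matrices of each tracklet and of
#' their column-wise concatenation (a shared low-order regressor explains
#' both when they originate from one dynamical system). Returns
#' `r_joint / (r1 + r2)`: 0.5 means identical dynamics, larger values more
#' dissimilar. Tracklets shorter than `min_length` yield `NA` (affinity
#' unavailable).
#'
#' @param t1,t2 `tracklet`s.
#' @param min_length minimal tracklet length for a defined rank (default 4).
#' @return rank ratio, or `NA`.
#' @export
dynamic_similarity <- function(t1, t2, min_length = 4L) {
  n1 <- nrow(t1$centroids)
  n2 <- nrow(t2$centroids)
  if (n1 < min_length || n2 < min_length) return(NA_real_)
  L <- min(floor(n1 / 2) + 1, floor(n2 / 2) + 1)
  r1 <- hankel_rank(t1$centroids, L)
  r2 <- hankel_rank(t2$centroids, L)
  mk <- function(tc) {
    n <- nrow(tc)
    ncols <- n - L + 1
    do.call(rbind, lapply(1:2, function(cc) {
      H <- matrix(0, L, ncols)
      for (i in seq_len(L)) H[i, ] <- tc[i:(i + ncols - 1), cc]
      H
    }))
  }
  HJ <- cbind(mk(t1$centroids), mk(t2$centroids))
  d <- svd(HJ, nu = 0, nv = 0)$d
  d <- d[d > 1e-9 * max(d, 1e-12)]
  r_joint <- if (length(d) == 0) 0L else sum(d >= 0.01 * d[1])
  r_joint / (r1 + r2)
}

#' Stitch tracklets into k full tracks
#'
#' The complete stitching pipeline: residual splitting, automatic gap
#' computation, graph construction, min-cost flow solution, and greedy
#' residual reinsertion.
#'
#' @param tracklets list of `tracklet`s.
#' @param k number of tracks to form (number of animals).
#' @param min_length residual threshold (default 5 frames).
#' @param max_gap maximal linking gap; `NULL` for the automatic 1.5-tau rule.
#' @param weights affinity weights (see [build_stitch_graph()]).
#' @param embeddings optional per-tracklet appearance embedding matrix (rows
#'   follow the order of non-residual tracklets).
#' @param appearance_strength appearance down-weighting strength.
#' @return list with `tracks` (each: list with `pieces`, a temporally sorted
#'   list of tracklets), `residual_report` (placed/unplaced counts), `graph`
#'   and `cost`.
#' @export
stitch_tracklets <- function(tracklets, k, min_length = 5L, max_gap = NULL,
                             weights = c(motion = 1, proximity = 1,
                                         shape = 1, dynamics = 1),
                             embeddings = NULL, appearance_strength = 0.5) {
  parts <- split_residuals(tracklets, min_length)
  gt <- parts$graph_tracklets
  if (length(gt) == 0) {
    # residual-only reconstruction: chain residuals greedily
    tracks <- residual_only_tracks(parts$residuals, k)
    return(list(tracks = tracks, residual_report = list(
      placed = sum(vapply(tracks, function(t) length(t$pieces), integer(1))),
      unplaced = length(parts$residuals) -
        sum(vapply(tracks, function(t) length(t$pieces), integer(1)))),
      graph = NULL, cost = NA_real_))
  }
  mg <- compute_max_gap(gt, override = max_gap)
  if (!is.null(embeddings)) {
    stopifnot(nrow(embeddings) == length(tracklets))
    keep_len <- vapply(tracklets, function(t) length(t$frames), integer(1))
    embeddings <- embeddings[keep_len >= min_length, , drop = FALSE]
  }
  residuals <- parts$residuals
  # demote tracklets until a k-path node-disjoint cover exists: the flow
  # formulation requires every graph tracklet visited exactly once, which
  # spurious or isolated tracklets can make infeasible
  repeat {
    graph <- build_stitch_graph(gt, mg, weights, embeddings,
                                appearance_strength)
    kmin <- min_path_cover_size(graph)
    if (kmin <= k || length(gt) <= k) break
    # first resolve small boundary overlaps (tracker hand-off artifacts)
    # by trimming a few frames, which preserves most observations
    trimmed <- trim_small_overlaps(gt)
    if (!is.null(trimmed)) {
      gt <- trimmed
      next
    }
    drop <- pick_demotion(graph, gt)
    residuals <- c(residuals, gt[drop])
    gt <- gt[-drop]
    if (!is.null(embeddings)) {
      embeddings <- embeddings[-drop, , drop = FALSE]
    }
  }
  paths <- solve_flow(graph, k)
  tracks <- lapply(seq_along(paths), function(ti) {
    list(id = ti, pieces = gt[paths[[ti]]])
  })
  res <- reinsert_residuals(tracks, residuals, max_gap = max(mg, 1L))
  res$graph <- graph
  res$cost <- attr(paths, "cost")
  res
}

# Minimal number of node-disjoint paths covering the stitch DAG:
# n - maximum bipartite matching of the successor relation.
min_path_cover_size <- function(graph) {
  n <- graph$n
  if (nrow(graph$edges) == 0) return(n)
  C <- matrix(Inf, n, n)
  C[cbind(graph$edges$from, graph$edges$to)] <- -1
  C[!is.finite(C)] <- 0
  sel <- solve_assignment(C)
  matched <- sum(vapply(seq_len(n), function(i) {
    !is.na(sel[i]) && C[i, sel[i]] < 0
  }, logical(1)))
  n - matched
}

# Trim small temporal overlaps between tracklet pairs: the later-starting
# tracklet loses its overlapping leading frames (at most max_trim of them).
# These overlaps are tracker hand-off artifacts that block graph edges and
# can render the k-path cover infeasible. Returns the updated list, or NULL
# when nothing was trimmed.
trim_small_overlaps <- function(tracklets, max_trim = 3L) {
  changed <- FALSE
  n <- length(tracklets)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      ti <- tracklets[[i]]
      tj <- tracklets[[j]]
      if (tj$start <= ti$start || tj$start > ti$end) next
      ov <- sum(tj$frames <= ti$end)
      if (ov < 1 || ov > max_trim || ov >= length(tj$frames)) next
      tracklets[[j]] <- tl_slice(tj, (ov + 1):length(tj$frames))
      changed <- TRUE
    }
  }
  if (changed) tracklets else NULL
}

# Choose a tracklet to demote to residual status when the cover is
# infeasible. Preference order: (1) the shorter member of a pair of
# time-overlapping, spatially coincident tracklets — a duplicate fragment of
# one animal produced by a split assembly; (2) the shortest tracklet with
# neither predecessor nor successor in the graph; (3) the shortest overall.
pick_demotion <- function(graph, tracklets) {
  n <- graph$n
  len <- vapply(tracklets, function(t) length(t$frames), integer(1))
  best <- NA_integer_
  best_len <- Inf
  for (i in seq_len(n)) {
    ti <- tracklets[[i]]
    # body extent of this tracklet: scale for "same animal" closeness
    ext <- max(vapply(ti$assemblies, function(a) {
      co <- a$coords[stats::complete.cases(a$coords), , drop = FALSE]
      if (nrow(co) < 1) return(0)
      max(sqrt(rowSums(sweep(co, 2, colMeans(co))^2)))
    }, numeric(1)), 1)
    for (j in seq_len(n)) {
      if (i == j) next
      common <- intersect(ti$frames, tracklets[[j]]$frames)
      if (length(common) < max(1, 0.5 * len[i])) next
      i1 <- match(common, ti$frames)
      i2 <- match(common, tracklets[[j]]$frames)
      d <- mean(sqrt(rowSums((ti$centroids[i1, , drop = FALSE] -
                              tracklets[[j]]$centroids[i2, ,
                                                       drop = FALSE])^2)))
      # duplicate fragments of one animal hold complementary bodyparts;
      # two genuinely interacting animals each carry (nearly) all of them
      bp_overlap <- mean(vapply(seq_along(common), function(ci) {
        b1 <- rownames(ti$assemblies[[i1[ci]]]$coords)
        b2 <- rownames(tracklets[[j]]$assemblies[[i2[ci]]]$coords)
        length(intersect(b1, b2)) / max(min(length(b1), length(b2)), 1)
      }, numeric(1)))
      if (d <= 2 * ext && bp_overlap < 0.5 &&
          len[i] <= len[j] && len[i] < best_len) {
        best <- i
        best_len <- len[i]
      }
    }
  }
  if (!is.na(best)) return(best)
  has_out <- rep(FALSE, n)
  has_in <- rep(FALSE, n)
  if (nrow(graph$edges) > 0) {
    has_out[unique(graph$edges$from)] <- TRUE
    has_in[unique(graph$edges$to)] <- TRUE
  }
  isolated <- which(!has_out & !has_in)
  pool <- if (length(isolated) > 0) isolated else seq_len(n)
  pool[which.min(len[pool])]
}

# Degenerate path: no tracklet long enough for the graph. Greedily chain
# residuals into k tracks by temporal order and spatial proximity.
residual_only_tracks <- function(residuals, k) {
  if (length(residuals) == 0) {
    return(lapply(seq_len(k), function(i) list(id = i, pieces = list())))
  }
  ord <- order(vapply(residuals, function(t) t$start, numeric(1)))
  residuals <- residuals[ord]
  tracks <- lapply(seq_len(k), function(i) list(id = i, pieces = list()))
  for (tl in residuals) {
    best <- NA_integer_
    best_d <- Inf
    for (ti in seq_len(k)) {
      pieces <- tracks[[ti]]$pieces
      if (length(pieces) == 0) {
        d <- 0 # empty track accepts anything
        if (is.na(best)) {
          best <- ti
          best_d <- d
        }
        next
      }
      last <- pieces[[length(pieces)]]
      if (last$end >= tl$start) next
      d <- euclid(last$centroids[nrow(last$centroids), ], tl$centroids[1, ])
      if (d < best_d) {
        best <- ti
        best_d <- d
      }
    }
    if (!is.na(best)) {
      tracks[[best]]$pieces <- c(tracks[[best]]$pieces, list(tl))
    }
  }
  tracks
}

#' Reinsert residual tracklets into stitched tracks
#'
#' Residuals are first chained into longer composites along weighted longest
#' paths of a small DAG (edges between temporally compatible residuals,
#' scored by spatial closeness), then greedily placed into temporal gaps of
#' the stitched tracks, choosing the placement minimizing the distance to the
#' neighbouring tracklets. Residuals that fit nowhere are reported, not
#' forced.
#'
#' @param tracks list of stitched tracks (each with `pieces`).
#' @param residuals list of residual `tracklet`s.
#' @param max_gap maximal temporal gap for residual chaining.
#' @return list with updated `tracks` and `residual_report` (counts and the
#'   unplaced tracklets).
#' @export
reinsert_residuals <- function(tracks, residuals, max_gap = 5L) {
  if (length(residuals) == 0) {
    return(list(tracks = tracks,
                residual_report = list(placed = 0L, unplaced = 0L,
                                       unplaced_tracklets = list())))
  }
  composites <- chain_residuals(residuals, max_gap)
  placed <- 0L
  unplaced <- list()
  # speed scale for plausibility gating of placements
  all_steps <- unlist(lapply(c(unlist(lapply(tracks, `[[`, "pieces"),
                                      recursive = FALSE), residuals),
                             function(t) {
    if (nrow(t$centroids) < 2) return(NULL)
    sqrt(rowSums(diff(t$centroids)^2))
  }))
  v_ref <- if (length(all_steps) > 0) max(stats::median(all_steps), 1) else 5
  # longest composites first: most evidence, least ambiguity
  ord <- order(-vapply(composites, function(ch) {
    sum(vapply(ch, function(t) length(t$frames), integer(1)))
  }, numeric(1)))
  queue <- composites[ord]
  while (length(queue) > 0) {
    ch <- queue[[1]]
    queue <- queue[-1]
    span <- c(ch[[1]]$start, ch[[length(ch)]]$end)
    best_track <- NA_integer_
    best_d <- Inf
    for (ti in seq_along(tracks)) {
      pieces <- tracks[[ti]]$pieces
      occupied <- unlist(lapply(pieces, function(p) p$frames))
      if (length(occupied) > 0 &&
          any(occupied >= span[1] & occupied <= span[2])) next
      # temporal continuity: span must fall strictly between neighbours
      prevs <- Filter(function(p) p$end < span[1], pieces)
      nexts <- Filter(function(p) p$start > span[2], pieces)
      ds <- numeric(0)
      plausible <- TRUE
      if (length(prevs) > 0) {
        pe <- prevs[[which.max(vapply(prevs, function(p) p$end, numeric(1)))]]
        d0 <- euclid(pe$centroids[nrow(pe$centroids), ],
                     ch[[1]]$centroids[1, ])
        gap0 <- span[1] - pe$end
        if (d0 > 3 * v_ref * gap0 + v_ref) plausible <- FALSE
        ds <- c(ds, d0)
      }
      if (length(nexts) > 0) {
        nx <- nexts[[which.min(vapply(nexts, function(p) p$start,
                                      numeric(1)))]]
        last <- ch[[length(ch)]]
        d1 <- euclid(last$centroids[nrow(last$centroids), ],
                     nx$centroids[1, ])
        gap1 <- nx$start - span[2]
        if (d1 > 3 * v_ref * gap1 + v_ref) plausible <- FALSE
        ds <- c(ds, d1)
      }
      if (!plausible) next
      d <- if (length(ds) > 0) mean(ds) else 0
      if (d < best_d) {
        best_d <- d
        best_track <- ti
      }
    }
    if (is.na(best_track)) {
      if (length(ch) > 1) {
        # a composite that fits nowhere is split and retried piecewise
        queue <- c(queue, lapply(ch, list))
      } else {
        # partially overlapping residual: trim to the free portion of the
        # best gap, when one exists
        trimmed <- trim_to_gap(ch[[1]], tracks, v_ref)
        if (!is.null(trimmed)) {
          tracks <- trimmed$tracks
          placed <- placed + 1L
        } else {
          unplaced <- c(unplaced, ch)
        }
      }
    } else {
      pieces <- c(tracks[[best_track]]$pieces, ch)
      starts <- vapply(pieces, function(p) p$start, numeric(1))
      tracks[[best_track]]$pieces <- pieces[order(starts)]
      placed <- placed + length(ch)
    }
  }
  list(tracks = tracks,
       residual_report = list(placed = placed,
                              unplaced = length(unplaced),
                              unplaced_tracklets = unplaced))
}

# Insert the longest free contiguous slice of a residual tracklet into a
# track gap, subject to the same speed-plausibility gate as whole placements.
# Returns updated tracks, or NULL when no admissible slice exists.
trim_to_gap <- function(tl, tracks, v_ref) {
  best <- NULL
  for (ti in seq_along(tracks)) {
    pieces <- tracks[[ti]]$pieces
    occupied <- unlist(lapply(pieces, function(p) p$frames))
    free <- !(tl$frames %in% occupied)
    if (!any(free)) next
    runs <- rle(free)
    ends <- cumsum(runs$lengths)
    starts_r <- ends - runs$lengths + 1
    for (ri in which(runs$values)) {
      idx <- starts_r[ri]:ends[ri]
      f0 <- tl$frames[idx[1]]
      f1 <- tl$frames[idx[length(idx)]]
      # the slice must sit inside one temporal gap of the track
      if (length(occupied) > 0 && any(occupied >= f0 & occupied <= f1)) next
      prevs <- Filter(function(p) p$end < f0, pieces)
      nexts <- Filter(function(p) p$start > f1, pieces)
      ok <- TRUE
      ds <- numeric(0)
      if (length(prevs) > 0) {
        pe <- prevs[[which.max(vapply(prevs, function(p) p$end,
                                      numeric(1)))]]
        d0 <- euclid(pe$centroids[nrow(pe$centroids), ],
                     tl$centroids[idx[1], ])
        if (d0 > 3 * v_ref * (f0 - pe$end) + v_ref) ok <- FALSE
        ds <- c(ds, d0)
      }
      if (length(nexts) > 0) {
        nx <- nexts[[which.min(vapply(nexts, function(p) p$start,
                                      numeric(1)))]]
        d1 <- euclid(tl$centroids[idx[length(idx)], ], nx$centroids[1, ])
        if (d1 > 3 * v_ref * (nx$start - f1) + v_ref) ok <- FALSE
        ds <- c(ds, d1)
      }
      if (!ok) next
      score <- length(idx) - mean(c(ds, 0)) / (100 * v_ref) # longest first
      if (is.null(best) || score > best$score) {
        best <- list(track = ti, idx = idx, score = score)
      }
    }
  }
  if (is.null(best)) return(NULL)
  piece <- tl_slice(tl, best$idx)
  pieces <- c(tracks[[best$track]]$pieces, list(piece))
  starts <- vapply(pieces, function(p) p$start, numeric(1))
  tracks[[best$track]]$pieces <- pieces[order(starts)]
  list(tracks = tracks)
}

# Chain temporally close residuals along weighted longest DAG paths
# (weights favour spatial closeness); returns a list of chains (lists of
# tracklets in temporal order). Edges additionally require a plausible
# implied speed (relative to the residuals' own per-frame displacements) so
# that chains do not jump between distant animals.
chain_residuals <- function(residuals, max_gap) {
  n <- length(residuals)
  if (n <= 1) return(lapply(residuals, list))
  starts <- vapply(residuals, function(t) t$start, numeric(1))
  ends <- vapply(residuals, function(t) t$end, numeric(1))
  steps <- unlist(lapply(residuals, function(t) {
    if (nrow(t$centroids) < 2) return(NULL)
    sqrt(rowSums(diff(t$centroids)^2))
  }))
  v_ref <- if (length(steps) > 0) max(stats::median(steps), 1) else 5
  edges <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      gap <- starts[j] - ends[i]
      if (gap >= 1 && gap <= max_gap) {
        d <- euclid(residuals[[i]]$centroids[nrow(residuals[[i]]$centroids), ],
                    residuals[[j]]$centroids[1, ])
        if (d > 3 * v_ref * gap + v_ref) next # implausible jump
        edges[[length(edges) + 1]] <- c(i, j, 1 / (1 + d))
      }
    }
  }
  chains <- list()
  remaining <- rep(TRUE, n)
  if (length(edges) > 0) {
    E <- do.call(rbind, edges)
    repeat {
      # longest (max total weight) path over remaining nodes, DP in
      # topological (start-frame) order
      ord <- order(starts)
      score <- rep(0, n)
      pred <- rep(NA_integer_, n)
      score[!remaining] <- -Inf
      for (v in ord) {
        if (!remaining[v]) next
        inc <- E[E[, 2] == v & remaining[E[, 1]], , drop = FALSE]
        if (nrow(inc) > 0) {
          cand <- score[inc[, 1]] + inc[, 3]
          b <- which.max(cand)
          if (cand[b] > score[v]) {
            score[v] <- cand[b]
            pred[v] <- inc[b, 1]
          }
        }
      }
      v <- which.max(ifelse(remaining, score, -Inf))
      if (length(v) == 0 || !remaining[v]) break
      path <- v
      while (!is.na(pred[path[1]])) path <- c(pred[path[1]], path)
      chains[[length(chains) + 1]] <- residuals[path]
      remaining[path] <- FALSE
      if (!any(remaining)) break
      if (score[v] <= 0 && length(path) == 1 && sum(remaining) > 0) {
        # no connectable structure left: emit singles
        for (s in which(remaining)) {
          chains[[length(chains) + 1]] <- residuals[s]
        }
        remaining[] <- FALSE
        break
      }
    }
  } else {
    for (s in which(remaining)) chains[[length(chains) + 1]] <- residuals[s]
    remaining[] <- FALSE
  }
  chains
}

#' Flatten stitched tracks to a coordinate table
#'
#' @param tracks list of tracks (with `pieces`).
#' @return data.frame `track_id`, `frame`, `bodypart`, `x`, `y`,
#'   `confidence`.
#' @export
tracks_to_table <- function(tracks) {
  rows <- list()
  for (tr in tracks) {
    for (p in tr$pieces) {
      for (fi in seq_along(p$frames)) {
        co <- p$assemblies[[fi]]$coords
        rows[[length(rows) + 1]] <- data.frame(
          track_id = tr$id, frame = p$frames[fi],
          bodypart = as.integer(rownames(co)),
          x = co[, 1], y = co[, 2],
          confidence = p$assemblies[[fi]]$score %||% NA_real_
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(track_id = integer(), frame = integer(),
                      bodypart = integer(), x = numeric(), y = numeric(),
                      confidence = numeric())
  }
  rownames(out) <- NULL
  out
}

#' Per-frame track centroids
#'
#' @param tracks stitched tracks.
#' @return data.frame `id`, `frame`, `x`, `y` (one row per track and frame).
#' @export
tracks_to_centroids <- function(tracks) {
  rows <- list()
  for (tr in tracks) {
    for (p in tr$pieces) {
      rows[[length(rows) + 1]] <- data.frame(
        id = tr$id, frame = p$frames,
        x = p$centroids[, 1], y = p$centroids[, 2]
      )
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(id = integer(), frame = integer(), x = numeric(),
                      y = numeric())
  }
  rownames(out) <- NULL
  out
}

#' Tracklets as naive tracks (identity = tracker id)
#'
#' Baseline against which stitching is compared: each tracklet becomes its
#' own track piece under its local id.
#'
#' @param tracklets list of `tracklet`s.
#' @return data.frame like [tracks_to_centroids()].
#' @export
tracklets_to_centroids <- function(tracklets) {
  rows <- lapply(tracklets, function(t) {
    data.frame(id = t$id, frame = t$frames,
               x = t$centroids[, 1], y = t$centroids[, 2])
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(id = integer(), frame = integer(), x = numeric(),
                      y = numeric())
  }
  rownames(out) <- NULL
  out
}
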