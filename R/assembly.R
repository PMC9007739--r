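#' Pick optimal keypoint pairs for one edge
#'
#' One-to-one matching of the proposals of the two endpoint bodyparts that
#' maximizes total affinity cost among pairs with cost at least
#' `paf_threshold` (bipartite assignment; pairs below the threshold are never
#' selected).
#'
#' @param table one per-edge affinity table from [build_affinity_tables()].
#' @param paf_threshold minimum affinity cost for a usable connection.
#' @return data.frame of matched pairs: `i`, `j` (detection row indices),
#'   `bodypart_i`, `bodypart_j`, `cost`.
#' @export
pick_optimal_pairs <- function(table, paf_threshold = 0.1) {
  empty <- data.frame(i = integer(), j = integer(),
                      bodypart_i = integer(), bodypart_j = integer(),
                      cost = numeric())
  ni <- length(table$det_i)
  nj <- length(table$det_j)
  if (ni == 0 || nj == 0) return(empty)
  gain <- table$cost
  gain[gain < paf_threshold] <- NA
  if (all(is.na(gain))) return(empty)
  k <- max(ni, nj)
  G <- matrix(0, k, k)
  G[seq_len(ni), seq_len(nj)] <- ifelse(is.na(gain), 0, gain)
  sel <- solve_assignment(-G)
  rows <- which(!is.na(sel) & sel <= nj)
  rows <- rows[rows <= ni]
  ok <- rows[!is.na(gain[cbind(rows, sel[rows])])]
  if (length(ok) == 0) return(empty)
  data.frame(
    i = table$det_i[ok], j = table$det_j[sel[ok]],
    bodypart_i = table$edge[1], bodypart_j = table$edge[2],
    cost = table$cost[cbind(ok, sel[ok])]
  )
}

#' Connected components of matched keypoint pairs
#'
#' Maximal groups of detections mutually reachable through matched pairs
#' (pure graph connectivity; redundant connections are handled naturally).
#'
#' @param pairs data.frame with columns `i`, `j` of detection indices.
#' @return list of integer vectors (sorted detection indices per group).
#' @export
connected_components <- function(pairs) {
  if (nrow(pairs) == 0) return(list())
  verts <- sort(unique(c(pairs$i, pairs$j)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = match(pairs$i, verts), to = match(pairs$j, verts)),
    directed = FALSE, vertices = data.frame(name = seq_along(verts)))
  comp <- igraph::components(g)
  lapply(seq_len(comp$no), function(ci) sort(verts[comp$membership == ci]))
}

# Internal grouping state used by greedy linking. Groups are grown by
# applying connections in descending cost order under the conflict rule: a
# connection is skipped if it would give any group two detections of one
# bodypart. With an optional pose prior, growth is additionally gated on the
# Mahalanobis criterion.
link_connections <- function(connections, detections, state = NULL,
                             prior = NULL) {
  n <- nrow(detections)
  if (is.null(state)) {
    state <- list(group_of = rep(0L, n), groups = list(),
                  applied = logical(0))
  }
  group_of <- state$group_of
  groups <- state$groups # each: list(members = named det ids by bodypart)
  applied <- logical(nrow(connections))
  if (nrow(connections) > 0) {
    ord <- order(-connections$cost)
    for (ci in ord) {
      i <- connections$i[ci]
      j <- connections$j[ci]
      bi <- as.character(connections$bodypart_i[ci])
      bj <- as.character(connections$bodypart_j[ci])
      gi <- group_of[i]
      gj <- group_of[j]
      if (gi > 0 && gi == gj) next # redundant connection inside one group
      if (gi > 0 && gj > 0) {
        if (length(intersect(names(groups[[gi]]), names(groups[[gj]])))) next
        merged <- c(groups[[gi]], groups[[gj]])
        if (!gate_ok(groups[[gi]], merged, detections, prior) ||
            !gate_ok(groups[[gj]], merged, detections, prior)) next
        groups[[gi]] <- merged
        group_of[group_of == gj] <- gi
        groups[gj] <- list(NULL)
      } else if (gi > 0) {
        if (bj %in% names(groups[[gi]])) next
        cand <- c(groups[[gi]], stats::setNames(j, bj))
        if (!gate_ok(groups[[gi]], cand, detections, prior)) next
        groups[[gi]] <- cand
        group_of[j] <- gi
      } else if (gj > 0) {
        if (bi %in% names(groups[[gj]])) next
        cand <- c(groups[[gj]], stats::setNames(i, bi))
        if (!gate_ok(groups[[gj]], cand, detections, prior)) next
        groups[[gj]] <- cand
        group_of[i] <- gj
      } else {
        groups[[length(groups) + 1]] <- stats::setNames(c(i, j), c(bi, bj))
        group_of[c(i, j)] <- length(groups)
      }
      applied[ci] <- TRUE
    }
  }
  list(group_of = group_of, groups = groups, applied = applied)
}

gate_ok <- function(members_before, members_after, detections, prior) {
  if (is.null(prior)) return(TRUE)
  coords_of <- function(members) {
    m <- cbind(detections$x[members], detections$y[members])
    rownames(m) <- names(members)
    m
  }
  mahalanobis_gate(coords_of(members_before), coords_of(members_after), prior)
}

#' Greedily link remaining connections into groups
#'
#' Iterates connections in descending affinity cost; a connection is applied
#' unless it would merge two groups sharing a bodypart or give a group two
#' detections of one bodypart. With a pose prior, a group only grows if the
#' candidate connection does not increase the (per-coordinate) Mahalanobis
#' distance between the configuration and the prior.
#'
#' @param connections data.frame (`i`, `j`, `bodypart_i`, `bodypart_j`,
#'   `cost`).
#' @param groups starting groups: list of named detection-index vectors
#'   (names = bodyparts), e.g. from [connected_components()] pairs.
#' @param detections detection data.frame (for coordinates and bodyparts).
#' @param prior optional [fit_pose_prior()] result.
#' @return list of named detection-index vectors (final groups).
#' @export
greedy_link <- function(connections, groups, detections, prior = NULL) {
  n <- nrow(detections)
  group_of <- rep(0L, n)
  for (gi in seq_along(groups)) group_of[groups[[gi]]] <- gi
  state <- list(group_of = group_of, groups = groups)
  state <- link_connections(connections, detections, state, prior)
  Filter(Negate(is.null), state$groups)
}

#' Fit a multivariate normal pose prior over pairwise keypoint distances
#'
#' The prior of an animal's pose is a Gaussian over the vector of distances
#' between all pairs of keypoints; mean and covariance come from labelled
#' poses via Gaussian kernel density estimation with bandwidth chosen by
#' Scott's rule (the mixture covariance is the sample covariance inflated by
#' `1 + n^(-2/(d+4))`). A singular covariance is regularized by adding
#' `1e-8 * trace / dim` to the diagonal.
#'
#' @param poses either an `n x K x 2` array or a list of `K x 2` matrices of
#'   labelled poses (complete, >= 2 poses, >= 2 bodyparts).
#' @return a `pose_prior`: list with `mean`, `cov`, `pairs` (the `D x 2`
#'   bodypart index pairs defining distance coordinates), `n_bodyparts`.
#' @export
fit_pose_prior <- function(poses) {
  if (is.list(poses)) {
    poses <- simplify2array(poses) # K x 2 x n
    poses <- aperm(poses, c(3, 1, 2))
  }
  n <- dim(poses)[1]
  K <- dim(poses)[2]
  stopifnot(n >= 2, K >= 2)
  pairs <- t(utils::combn(K, 2))
  D <- nrow(pairs)
  X <- matrix(0, n, D)
  for (d in seq_len(D)) {
    X[, d] <- sqrt((poses[, pairs[d, 1], 1] - poses[, pairs[d, 2], 1])^2 +
                   (poses[, pairs[d, 1], 2] - poses[, pairs[d, 2], 2])^2)
  }
  mu <- colMeans(X)
  S <- stats::cov(X)
  S <- S * (1 + n^(-2 / (D + 4))) # Scott bandwidth inflation
  eps <- 1e-8 * max(sum(diag(S)) / D, 1e-12)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < eps) S <- S + diag(eps, D)
  structure(list(mean = mu, cov = S, pairs = pairs, n_bodyparts = K),
            class = "pose_prior")
}

prior_coord_index <- function(prior, bp_a, bp_b) {
  a <- pmin(bp_a, bp_b)
  b <- pmax(bp_a, bp_b)
  match(paste(a, b), paste(prior$pairs[, 1], prior$pairs[, 2]))
}

# mean squared Mahalanobis distance per observed distance coordinate,
# restricted to the sub-block of the prior (Gaussian marginalization).
partial_mahalanobis <- function(coords, prior) {
  bps <- as.integer(rownames(coords))
  if (length(bps) < 2) return(NA_real_)
  pr <- t(utils::combn(length(bps), 2))
  idx <- prior_coord_index(prior, bps[pr[, 1]], bps[pr[, 2]])
  d <- sqrt(rowSums((coords[pr[, 1], , drop = FALSE] -
                     coords[pr[, 2], , drop = FALSE])^2))
  mu <- prior$mean[idx]
  S <- prior$cov[idx, idx, drop = FALSE]
  as.numeric(stats::mahalanobis(matrix(d, 1), mu, S)) / length(idx)
}

#' Mahalanobis gate for skeleton growth
#'
#' Accepts a candidate connection if the Mahalanobis distance between the
#' resulting configuration and the pose prior — computed on the observed
#' pairwise-distance coordinates and normalized per coordinate so that
#' configurations of different sizes are comparable — does not increase.
#' When the gate is inapplicable (fewer than two keypoints before growth),
#' the connection is accepted.
#'
#' @param coords_before,coords_after keypoint coordinate matrices with
#'   bodypart indices as rownames.
#' @param prior a `pose_prior`.
#' @return `TRUE` (accept) or `FALSE` (reject).
#' @export
mahalanobis_gate <- function(coords_before, coords_after, prior) {
  before <- partial_mahalanobis(coords_before, prior)
  if (is.na(before)) return(TRUE)
  after <- partial_mahalanobis(coords_after, prior)
  if (is.na(after)) return(TRUE)
  after <= before + 1e-12
}

#' Temporal coherence weight of a candidate connection
#'
#' Average exponential kernel `mean(exp(-gamma * dt * ||c - c_n||^2))` over
#' the `j` most recent past frames, where `c_n` is the closest matching
#' connection (same edge) in each past frame and `dt` the frame gap. The
#' affinity cost is multiplied by `1 + weight` before greedy sorting.
#'
#' @param connection numeric length-4 vector `(x_i, y_i, x_j, y_j)`.
#' @param past_frames list of past frames, each a list with `dt` (temporal
#'   gap, frames) and `connections` (matrix with 4 columns, one row per
#'   applied connection of the same edge; may have 0 rows).
#' @param gamma kernel decay, default 0.01.
#' @return weight in [0, 1]; 0 if there are no past frames.
#' @export
temporal_coherence_weight <- function(connection, past_frames, gamma = 0.01) {
  if (length(past_frames) == 0) return(0)
  terms <- vapply(past_frames, function(pf) {
    if (is.null(pf$connections) || nrow(pf$connections) == 0) return(0)
    d2 <- rowSums(sweep(pf$connections, 2, connection)^2)
    exp(-gamma * pf$dt * min(d2))
  }, numeric(1))
  mean(terms)
}

#' Assemble one frame's detections into individual animals
#'
#' The full per-frame grouping procedure: per-edge optimal pairing, connected
#' components of the strong pairs, then greedy linking of the remaining
#' above-threshold connections (optionally gated by a pose prior and weighted
#' by temporal coherence). Detections left in no multi-member group are
#' returned as unconnected. With `identity_mode = TRUE` grouping bypasses
#' PAFs entirely and uses the argmax of per-detection identity probabilities
#' (columns `id_prob_1..id_prob_n` of `detections`).
#'
#' @param detections detection data.frame for one frame.
#' @param tables per-edge affinity tables aligned with `graph$edges`.
#' @param graph the part affinity graph.
#' @param options list: `paf_threshold` (0.1), `prior` (NULL),
#'   `past_frames` (NULL), `gamma` (0.01), `identity_mode` (FALSE).
#' @return list with `assemblies` (each: `members` named detection indices,
#'   `score`, `coords`), `unconnected` (detection indices), and `connections`
#'   (the applied connections, for temporal coherence bookkeeping).
#' @export
assemble_frame <- function(detections, tables, graph, options = list()) {
  opt <- utils::modifyList(list(paf_threshold = 0.1, prior = NULL,
                                past_frames = NULL, gamma = 0.01,
                                identity_mode = FALSE), options)
  mk_assembly <- function(members, score) {
    list(members = members, score = score,
         coords = {
           m <- cbind(detections$x[members], detections$y[members])
           rownames(m) <- names(members)
           m
         })
  }
  empty <- list(assemblies = list(), unconnected = integer(),
                connections = matrix(numeric(0), 0, 4))
  if (nrow(detections) == 0) return(empty)

  if (isTRUE(opt$identity_mode)) {
    idcols <- grep("^id_prob_", names(detections))
    stopifnot(length(idcols) > 0)
    probs <- as.matrix(detections[, idcols, drop = FALSE])
    label <- max.col(probs, ties.method = "first")
    groups <- split(seq_len(nrow(detections)), label)
    assemblies <- lapply(groups, function(g) {
      # keep at most one detection per bodypart (highest confidence)
      ord <- g[order(-detections$confidence[g])]
      keep <- ord[!duplicated(detections$bodypart[ord])]
      members <- stats::setNames(keep, detections$bodypart[keep])
      mk_assembly(members, mean(probs[cbind(keep, label[keep])]))
    })
    assigned <- unlist(lapply(assemblies, `[[`, "members"))
    return(list(assemblies = unname(assemblies),
                unconnected = setdiff(seq_len(nrow(detections)), assigned),
                connections = matrix(numeric(0), 0, 4)))
  }

  # phase 1: strong connections (per-edge optimal pairs)
  pairs <- do.call(rbind, lapply(tables, pick_optimal_pairs,
                                 paf_threshold = opt$paf_threshold))
  if (is.null(pairs)) pairs <- data.frame(i = integer(), j = integer(),
                                          bodypart_i = integer(),
                                          bodypart_j = integer(),
                                          cost = numeric())
  state <- link_connections(pairs, detections, prior = opt$prior)

  # phase 2: remaining above-threshold connections, greedily linked
  used <- paste(pairs$i, pairs$j)
  remaining <- do.call(rbind, lapply(tables, function(tab) {
    if (length(tab$det_i) == 0 || length(tab$det_j) == 0) return(NULL)
    idx <- which(tab$cost >= opt$paf_threshold, arr.ind = TRUE)
    if (nrow(idx) == 0) return(NULL)
    out <- data.frame(i = tab$det_i[idx[, 1]], j = tab$det_j[idx[, 2]],
                      bodypart_i = tab$edge[1], bodypart_j = tab$edge[2],
                      cost = tab$cost[idx])
    out[!(paste(out$i, out$j) %in% used), , drop = FALSE]
  }))
  if (!is.null(remaining) && nrow(remaining) > 0) {
    if (!is.null(opt$past_frames) && length(opt$past_frames) > 0) {
      w <- vapply(seq_len(nrow(remaining)), function(r) {
        conn <- c(detections$x[remaining$i[r]], detections$y[remaining$i[r]],
                  detections$x[remaining$j[r]], detections$y[remaining$j[r]])
        temporal_coherence_weight(conn, opt$past_frames, opt$gamma)
      }, numeric(1))
      remaining$cost <- remaining$cost * (1 + w)
    }
    state <- link_connections(remaining, detections, state, opt$prior)
  }

  groups <- Filter(Negate(is.null), state$groups)
  multi <- vapply(groups, length, integer(1)) >= 2 |
    max(detections$bodypart) == 1
  assemblies <- lapply(groups[multi], function(members) {
    mk_assembly(members, NA_real_)
  })
  # assembly score: mean cost of internal connections
  all_conns <- rbind(pairs, remaining)
  if (length(assemblies) > 0 && !is.null(all_conns) && nrow(all_conns) > 0) {
    for (ai in seq_along(assemblies)) {
      mem <- assemblies[[ai]]$members
      inside <- all_conns$i %in% mem & all_conns$j %in% mem
      assemblies[[ai]]$score <- if (any(inside)) {
        mean(all_conns$cost[inside])
      } else 0
    }
  } else {
    for (ai in seq_along(assemblies)) assemblies[[ai]]$score <- 0
  }
  assigned <- unlist(lapply(assemblies, `[[`, "members"))
  applied4 <- if (nrow(all_conns) > 0) {
    ap <- all_conns[all_conns$i %in% assigned & all_conns$j %in% assigned, ,
                    drop = FALSE]
    cbind(detections$x[ap$i], detections$y[ap$i],
          detections$x[ap$j], detections$y[ap$j])
  } else matrix(numeric(0), 0, 4)
  list(assemblies = assemblies,
       unconnected = setdiff(seq_len(nrow(detections)), assigned),
       connections = applied4)
}

#' Assemble a whole video of detection frames
#'
#' Applies [assemble_frame()] per frame, maintaining the rolling window of
#' past applied connections for the temporal coherence weight.
#'
#' @param detections detection data.frame with a `frame` column.
#' @param pafs_by_frame function(frame) returning the PAF array for a frame,
#'   or a list indexed by frame.
#' @param graph part affinity graph.
#' @param stride overall stride.
#' @param options assembly options; `temporal_window` (default 0 = off) sets
#'   the number of past frames used for temporal coherence.
#' @return list per frame of [assemble_frame()] results.
#' @export
assemble_video <- function(detections, pafs_by_frame, graph, stride,
                           options = list()) {
  opt <- utils::modifyList(list(temporal_window = 0L, n_samples = 10L,
                                method = "projection", paf_edges = NULL),
                           options)
  frames <- sort(unique(detections$frame))
  out <- vector("list", length(frames))
  past <- list()
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    det_f <- detections[detections$frame == f, , drop = FALSE]
    rownames(det_f) <- NULL
    pafs <- if (is.function(pafs_by_frame)) pafs_by_frame(f) else
      pafs_by_frame[[f]]
    tabs <- build_affinity_tables(det_f, pafs, graph, stride,
                                  n_samples = opt$n_samples,
                                  method = opt$method,
                                  paf_edges = opt$paf_edges)
    fopt <- opt
    fopt$past_frames <- if (opt$temporal_window > 0) past else NULL
    res <- assemble_frame(det_f, tabs, graph, fopt)
    res$frame <- f
    res$detections <- det_f
    out[[fi]] <- res
    if (opt$temporal_window > 0) {
      past <- c(list(list(dt = 1, connections = res$connections)),
                lapply(past, function(p) {
                  p$dt <- p$dt + 1
                  p
                }))
      past <- past[seq_len(min(length(past), opt$temporal_window))]
    }
  }
  names(out) <- frames
  out
}
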