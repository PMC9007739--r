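# Minimum-cost maximum-flow via successive shortest augmenting paths
# (Bellman-Ford on the residual graph; capacities are small integers here).
# Edges are given as a data.frame (from, to, cap, cost); returns per-edge
# flow and the total cost of the maximum flow from s to t.
min_cost_max_flow <- function(n_nodes, edges, s, t) {
  m <- nrow(edges)
  # residual arc arrays: forward arcs 1..m, backward arcs m+1..2m
  from <- c(edges$from, edges$to)
  to <- c(edges$to, edges$from)
  cap <- c(edges$cap, rep(0, m))
  cost <- c(edges$cost, -edges$cost)
  flow <- rep(0, 2 * m)
  out_arcs <- split(seq_len(2 * m), from)
  total_flow <- 0
  total_cost <- 0
  repeat {
    # Bellman-Ford shortest path s -> t on residual arcs
    dist <- rep(Inf, n_nodes)
    dist[s] <- 0
    prev_arc <- rep(NA_integer_, n_nodes)
    repeat {
      improved <- FALSE
      for (a in seq_len(2 * m)) {
        if (cap[a] - flow[a] > 1e-9 && is.finite(dist[from[a]])) {
          nd <- dist[from[a]] + cost[a]
          if (nd < dist[to[a]] - 1e-9) {
            dist[to[a]] <- nd
            prev_arc[to[a]] <- a
            improved <- TRUE
          }
        }
      }
      if (!improved) break
    }
    if (!is.finite(dist[t])) break
    # bottleneck along path
    path <- integer(0)
    v <- t
    while (v != s) {
      a <- prev_arc[v]
      path <- c(path, a)
      v <- from[a]
    }
    aug <- min(cap[path] - flow[path])
    rev_of <- function(a) ifelse(a > m, a - m, a + m)
    flow[path] <- flow[path] + aug
    flow[rev_of(path)] <- flow[rev_of(path)] - aug
    total_flow <- total_flow + aug
    total_cost <- total_cost + aug * dist[t]
  }
  list(flow = flow[seq_len(m)], total_flow = total_flow,
       total_cost = total_cost)
}

#' Build the tracklet stitching graph
#'
#' Directed acyclic graph over non-residual tracklets: an edge connects two
#' tracklets when they do not overlap in time and are separated by at most
#' `max_gap` frames. Edge weights combine the motion, proximity, shape and
#' dynamic affinities (min-max normalized over the candidate edge set,
#' weighted sum), optionally down-weighted by appearance similarity.
#'
#' @param tracklets list of `tracklet`s (graph nodes, in order).
#' @param max_gap maximal temporal gap (frames) between linked tracklets.
#' @param weights named affinity weights (`motion`, `proximity`, `shape`,
#'   `dynamics`), default equal.
#' @param embeddings optional matrix of per-tracklet appearance embeddings
#'   (rows aligned with `tracklets`).
#' @param appearance_strength multiplicative down-weighting strength s in
#'   [0, 1]: `w <- w * (1 - s * cosine)`.
#' @return a `stitch_graph`: list with `n`, `edges` (data.frame `from`, `to`,
#'   `w` plus the per-affinity breakdown).
#' @export
build_stitch_graph <- function(tracklets, max_gap,
                               weights = c(motion = 1, proximity = 1,
                                           shape = 1, dynamics = 1),
                               embeddings = NULL,
                               appearance_strength = 0.5) {
  n <- length(tracklets)
  cand <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      gap <- tracklets[[j]]$start - tracklets[[i]]$end
      if (gap >= 1 && gap <= max_gap) cand[[length(cand) + 1]] <- c(i, j)
    }
  }
  if (length(cand) == 0) {
    return(structure(list(n = n, edges = data.frame(
      from = integer(), to = integer(), w = numeric())),
      class = "stitch_graph"))
  }
  cand <- do.call(rbind, cand)
  aff <- data.frame(
    motion = numeric(nrow(cand)), proximity = numeric(nrow(cand)),
    shape = numeric(nrow(cand)), dynamics = numeric(nrow(cand)),
    appearance = NA_real_
  )
  for (r in seq_len(nrow(cand))) {
    t1 <- tracklets[[cand[r, 1]]]
    t2 <- tracklets[[cand[r, 2]]]
    aff$motion[r] <- motion_affinity(t1, t2)
    aff$proximity[r] <- spatial_proximity(t1, t2)
    aff$shape[r] <- shape_similarity(t1, t2)
    aff$dynamics[r] <- dynamic_similarity(t1, t2)
    if (!is.null(embeddings)) {
      aff$appearance[r] <- tracklet_cosine(embeddings[cand[r, 1], ],
                                           embeddings[cand[r, 2], ])
    }
  }
  w <- combine_costs(aff[, c("motion", "proximity", "shape", "dynamics")],
                     weights,
                     appearance = if (is.null(embeddings)) NULL else
                       aff$appearance,
                     appearance_strength = appearance_strength)
  keep <- !is.na(w)
  edges <- data.frame(from = cand[keep, 1], to = cand[keep, 2], w = w[keep])
  edges <- cbind(edges, aff[keep, , drop = FALSE])
  structure(list(n = n, edges = edges), class = "stitch_graph")
}

#' Combine tracklet affinities into edge weights
#'
#' Each available affinity column is min-max normalized over the candidate
#' edge set (infinite costs map to 1); the edge weight is the weighted sum of
#' the normalized costs, with weights renormalized per edge over the
#' affinities available there. If appearance cosine similarities are
#' supplied, weights are multiplied by `1 - s * cosine`.
#'
#' @param affinities data.frame of raw affinity costs (NA = unavailable).
#' @param weights named weight vector matching the affinity columns.
#' @param appearance optional cosine similarity vector.
#' @param appearance_strength s in [0, 1].
#' @return numeric edge weights (NA where no affinity was available).
#' @export
combine_costs <- function(affinities, weights, appearance = NULL,
                          appearance_strength = 0.5) {
  affinities <- as.data.frame(affinities)
  cols <- names(affinities)
  wts <- weights[cols]
  wts[is.na(wts)] <- 0
  norm <- affinities
  for (cn in cols) {
    v <- affinities[[cn]]
    fin <- is.finite(v)
    if (any(fin)) {
      lo <- min(v[fin])
      hi <- max(v[fin])
      nv <- if (hi > lo) (v - lo) / (hi - lo) else rep(0, length(v))
      nv[!fin & !is.na(v)] <- 1 # +Inf: maximally disfavoured
      norm[[cn]] <- nv
    } else {
      norm[[cn]] <- ifelse(is.na(v), NA_real_, 1)
    }
  }
  w <- numeric(nrow(norm))
  for (r in seq_len(nrow(norm))) {
    avail <- !is.na(unlist(norm[r, ]))
    if (!any(avail & wts > 0)) {
      w[r] <- NA_real_
      next
    }
    wr <- wts[avail]
    w[r] <- sum(wr * unlist(norm[r, avail])) / sum(wr)
  }
  if (!is.null(appearance)) {
    fac <- ifelse(is.na(appearance), 1,
                  1 - appearance_strength * appearance)
    w <- w * fac
  }
  w
}

#' Solve the stitching problem as a min-cost network flow
#'
#' Covers the tracklet DAG with `k` node-disjoint source-to-sink paths of
#' minimal total weight; every tracklet is visited exactly once (unit node
#' demand/supply). Weights are scaled by 1e4 and rounded to integers for the
#' flow solver.
#'
#' @param graph a `stitch_graph`.
#' @param k number of tracks (animals).
#' @return list of integer vectors: the tracklet indices of each track, in
#'   temporal order; attribute `cost` holds the total unscaled cost.
#' @export
solve_flow <- function(graph, k) {
  n <- graph$n
  stopifnot(k >= 1)
  if (n == 0) return(list())
  if (k > n) stop("cannot form more tracks than tracklets", call. = FALSE)
  # nodes: 1 = SS, 2 = TT, 3 = S, 4 = T, in_i = 4 + i, out_i = 4 + n + i
  SS <- 1L; TT <- 2L; S <- 3L; T_ <- 4L
  in_id <- function(i) 4L + i
  out_id <- function(i) 4L + n + i
  e <- list(
    data.frame(from = SS, to = S, cap = k, cost = 0),
    data.frame(from = T_, to = TT, cap = k, cost = 0),
    data.frame(from = SS, to = out_id(seq_len(n)), cap = 1, cost = 0),
    data.frame(from = in_id(seq_len(n)), to = TT, cap = 1, cost = 0),
    data.frame(from = S, to = in_id(seq_len(n)), cap = 1, cost = 0),
    data.frame(from = out_id(seq_len(n)), to = T_, cap = 1, cost = 0)
  )
  if (nrow(graph$edges) > 0) {
    e[[length(e) + 1]] <- data.frame(
      from = out_id(graph$edges$from), to = in_id(graph$edges$to),
      cap = 1, cost = round(graph$edges$w * 1e4)
    )
  }
  edges <- do.call(rbind, e)
  res <- min_cost_max_flow(4L + 2L * n, edges, SS, TT)
  if (res$total_flow < n + k) {
    covered <- edges$from == S & res$flow > 0.5
    uncovered <- setdiff(seq_len(n), edges$to[covered] - 4L)
    stop(sprintf(
      "stitching infeasible for k = %d: no path cover (bottleneck around tracklet(s) %s)",
      k, paste(uncovered, collapse = ", ")), call. = FALSE)
  }
  # successor map from flow on inter-tracklet arcs
  succ <- rep(NA_integer_, n)
  starts <- integer(0)
  for (a in which(res$flow > 0.5)) {
    fr <- edges$from[a]
    to <- edges$to[a]
    if (fr == S && to > 4L && to <= 4L + n) starts <- c(starts, to - 4L)
    if (fr > 4L + n && to > 4L && to <= 4L + n) {
      succ[fr - 4L - n] <- to - 4L
    }
  }
  tracks <- lapply(sort(starts), function(s0) {
    path <- s0
    while (!is.na(succ[path[length(path)]])) {
      path <- c(path, succ[path[length(path)]])
    }
    path
  })
  used <- if (nrow(graph$edges) > 0) {
    sum(edges$cost[res$flow > 0.5] * res$flow[res$flow > 0.5])
  } else 0
  attr(tracks, "cost") <- used / 1e4
  tracks
}
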