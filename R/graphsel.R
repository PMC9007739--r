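#' Complete part affinity graph over bodyparts
#'
#' @param n_bodyparts number of bodyparts.
#' @return a `paf_graph` with all unordered bodypart pairs.
#' @export
full_graph <- function(n_bodyparts) {
  edges <- t(utils::combn(n_bodyparts, 2))
  paf_graph(edges)
}

#' Construct a part affinity graph
#'
#' @param edges matrix (L x 2) of bodypart indices, no duplicates.
#' @param auroc optional per-edge discriminability (auROC).
#' @return a `paf_graph` list with `edges` and `auroc`.
#' @export
paf_graph <- function(edges, auroc = NULL) {
  edges <- matrix(as.integer(edges), ncol = 2)
  edges <- t(apply(edges, 1, sort)) # canonical orientation i < j
  if (nrow(edges) != nrow(unique(edges))) stop("duplicate edges")
  structure(list(edges = edges, auroc = auroc), class = "paf_graph")
}

#' @export
print.paf_graph <- function(x, ...) {
  cat(sprintf("paf_graph with %d edges over %d bodyparts\n",
              nrow(x$edges), length(unique(c(x$edges)))))
  invisible(x)
}

edge_key <- function(edges) paste(pmin(edges[, 1], edges[, 2]),
                                  pmax(edges[, 1], edges[, 2]), sep = "-")

#' Within- and between-animal affinity cost distributions
#'
#' Accumulates, for each edge of the graph, histograms (bin width 0.01) of
#' affinity costs of same-animal detection pairs (within) and
#' different-animal pairs (between), using the hidden ground-truth animal
#' membership of each detection. Edges with no same-animal examples are
#' flagged invalid and excluded from ranking.
#'
#' @param labelled_frames list of frames; each frame is a list with
#'   `detections` (data.frame with a `gt_animal` column) and `tables`
#'   (affinity tables from [build_affinity_tables()] over the same graph).
#' @param graph the `paf_graph` the tables were built over.
#' @return an `edge_cost_distributions` object: per edge, `within` and
#'   `between` counts over common breaks (`breaks`, bin width 0.01,
#'   left-closed), plus a `valid` flag.
#' @export
edge_cost_distributions <- function(labelled_frames, graph) {
  L <- nrow(graph$edges)
  lo <- -1
  hi <- 1
  breaks <- seq(lo, hi + 0.01, by = 0.01)
  nb <- length(breaks) - 1L
  within <- matrix(0L, L, nb)
  between <- matrix(0L, L, nb)
  bin_of <- function(x) {
    pmin(pmax(findInterval(x, breaks, left.open = FALSE), 1L), nb)
  }
  for (fr in labelled_frames) {
    lab <- fr$detections$gt_animal
    for (l in seq_len(L)) {
      tab <- fr$tables[[l]]
      if (length(tab$det_i) == 0 || length(tab$det_j) == 0) next
      li <- lab[tab$det_i]
      lj <- lab[tab$det_j]
      for (ii in seq_along(tab$det_i)) {
        if (is.na(li[ii])) next
        for (jj in seq_along(tab$det_j)) {
          if (is.na(lj[jj])) next
          b <- bin_of(tab$cost[ii, jj])
          if (li[ii] == lj[jj]) {
            within[l, b] <- within[l, b] + 1L
          } else {
            between[l, b] <- between[l, b] + 1L
          }
        }
      }
    }
  }
  structure(list(edges = graph$edges, breaks = breaks,
                 within = within, between = between,
                 valid = rowSums(within) > 0),
            class = "edge_cost_distributions")
}

#' auROC of a pair of binned distributions
#'
#' Probability that a draw from the positive (within-animal) histogram
#' exceeds a draw from the negative (between-animal) histogram, ties within a
#' bin counting one half — the area under the ROC curve of the binned costs.
#'
#' @param within,between nonnegative count vectors over identical bins.
#' @return auROC in [0, 1].
#' @export
auroc_binned <- function(within, between) {
  W <- sum(within)
  B <- sum(between)
  if (W == 0 || B == 0) return(NA_real_)
  below <- cumsum(between) - between # strictly lower bins
  sum(within * (below + 0.5 * between)) / (W * B)
}

#' Rank graph edges by affinity discriminability
#'
#' @param dists an `edge_cost_distributions` object.
#' @return data.frame (`i`, `j`, `auroc`) sorted by decreasing auROC
#'   (stable), containing only valid edges with both histograms nonempty.
#' @export
rank_edges_auroc <- function(dists) {
  L <- nrow(dists$edges)
  auroc <- vapply(seq_len(L), function(l) {
    auroc_binned(dists$within[l, ], dists$between[l, ])
  }, numeric(1))
  out <- data.frame(i = dists$edges[, 1], j = dists$edges[, 2],
                    auroc = auroc)
  out <- out[dists$valid & !is.na(auroc), , drop = FALSE]
  out <- out[order(-out$auroc), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Maximum spanning tree of ranked edges
#'
#' The smallest data-driven skeleton: a tree over all bodyparts with the
#' largest possible total edge discriminability (auROC as the weight).
#'
#' @param ranked_edges data.frame (`i`, `j`, `auroc`), e.g. from
#'   [rank_edges_auroc()].
#' @param n_bodyparts total number of bodyparts the tree must span.
#' @return a `paf_graph` with `n_bodyparts - 1` edges.
#' @export
maximum_spanning_tree <- function(ranked_edges, n_bodyparts) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = ranked_edges$i, to = ranked_edges$j),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n_bodyparts))
  )
  comp <- igraph::components(g)
  if (comp$no > 1) {
    orphan <- which(comp$membership != comp$membership[1])
    stop(sprintf("edge set does not span all bodyparts; unreachable: %s",
                 paste(orphan, collapse = ", ")), call. = FALSE)
  }
  mst <- igraph::mst(g, weights = -ranked_edges$auroc)
  el <- igraph::as_edgelist(mst)
  edges <- cbind(as.integer(el[, 1]), as.integer(el[, 2]))
  key <- edge_key(edges)
  rkey <- edge_key(as.matrix(ranked_edges[, c("i", "j")]))
  paf_graph(edges, auroc = ranked_edges$auroc[match(key, rkey)])
}

#' Candidate graph sequence from minimal to complete
#'
#' Builds up to `n_candidates` increasingly redundant graphs: the first is
#' the maximum spanning tree, the following ones add the next best-ranked
#' non-tree edges in (approximately) equal increments up to the full ranked
#' set. With `from = "baseline"` the sequence instead grows a user-supplied
#' skeleton by adding the remaining edges from least to most discriminative.
#'
#' @param mst `paf_graph`, the maximum spanning tree (ignored for baseline).
#' @param ranked_edges ranked edge data.frame (decreasing auROC).
#' @param n_candidates number of graphs (default 9).
#' @param from "mst" or "baseline".
#' @param skeleton baseline user skeleton (`paf_graph` or edge matrix),
#'   required for `from = "baseline"`.
#' @return list of `paf_graph`s with strictly increasing edge counts, each
#'   containing its predecessor.
#' @export
candidate_graphs <- function(mst, ranked_edges, n_candidates = 9L,
                             from = c("mst", "baseline"), skeleton = NULL) {
  from <- match.arg(from)
  rkey <- edge_key(as.matrix(ranked_edges[, c("i", "j")]))
  if (from == "mst") {
    base_edges <- mst$edges
    pool_order <- seq_len(nrow(ranked_edges)) # best first
  } else {
    stopifnot(!is.null(skeleton))
    base_edges <- if (inherits(skeleton, "paf_graph")) skeleton$edges else
      matrix(as.integer(skeleton), ncol = 2)
    base_edges <- t(apply(base_edges, 1, sort))
    pool_order <- rev(seq_len(nrow(ranked_edges))) # worst first
  }
  bkey <- edge_key(base_edges)
  pool <- pool_order[!(rkey[pool_order] %in% bkey)]
  n0 <- nrow(base_edges)
  n_full <- n0 + length(pool)
  sizes <- unique(round(seq(n0, n_full, length.out = max(1L, n_candidates))))
  lapply(sizes, function(sz) {
    extra <- pool[seq_len(sz - n0)]
    edges <- rbind(base_edges, as.matrix(ranked_edges[extra, c("i", "j")]))
    key <- edge_key(edges)
    paf_graph(edges, auroc = ranked_edges$auroc[match(key, rkey)])
  })
}

#' Select the part affinity graph maximizing assembly quality
#'
#' Runs assembly on labelled evaluation frames for every candidate graph and
#' retains the one jointly maximizing purity and the fraction of connected
#' keypoints (unweighted mean of the two; ties broken towards the smaller
#' graph, then the earlier candidate).
#'
#' @param candidates list of `paf_graph`s.
#' @param eval_frames list of frames, each a list with `detections`
#'   (including `gt_animal`) and `tables` built over the full graph used to
#'   produce the candidates (tables are subset per candidate).
#' @param full_graph the graph the tables were built over.
#' @param options assembly options (see [assemble_frame()]).
#' @return list with `graph` (the selected `paf_graph`), `scores`
#'   (data.frame of per-candidate purity, connected fraction and mean).
#' @export
select_graph <- function(candidates, eval_frames, full_graph,
                         options = list()) {
  fkey <- edge_key(full_graph$edges)
  scores <- data.frame(size = integer(), purity = numeric(),
                       connected = numeric(), score = numeric())
  for (ci in seq_along(candidates)) {
    cand <- candidates[[ci]]
    idx <- match(edge_key(cand$edges), fkey)
    if (anyNA(idx)) stop("candidate edge missing from full-graph tables")
    pur <- conn <- numeric(0)
    for (fr in eval_frames) {
      tabs <- fr$tables[idx]
      res <- assemble_frame(fr$detections, tabs, cand, options)
      q <- assembly_quality(res$assemblies, fr$detections$gt_animal,
                           n_detections = nrow(fr$detections))
      pur <- c(pur, q$purity)
      conn <- c(conn, 1 - q$unconnected_fraction)
    }
    scores <- rbind(scores, data.frame(
      size = nrow(cand$edges),
      purity = mean(pur, na.rm = TRUE),
      connected = mean(conn, na.rm = TRUE),
      score = mean(c(mean(pur, na.rm = TRUE), mean(conn, na.rm = TRUE)))
    ))
  }
  # argmax score; ties -> smaller graph, then first in order
  best <- order(-scores$score, scores$size, seq_len(nrow(scores)))[1]
  list(graph = candidates[[best]], scores = scores, best = best)
}

#' Random connected subgraph of a given size
#'
#' Uniformly samples the requested fraction of edges, then forces
#' connectivity by swapping spanning-tree edges in for sampled edges lying on
#' cycles.
#'
#' @param full_graph `paf_graph` (must be connected).
#' @param fraction fraction of edges to keep, in (0, 1].
#' @param seed RNG seed.
#' @return a connected `paf_graph` with `round(fraction * L)` edges.
#' @export
prune_random_subgraph <- function(full_graph, fraction, seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1)
  L <- nrow(full_graph$edges)
  m <- max(1L, round(fraction * L))
  if (m >= L) return(full_graph)
  verts <- sort(unique(c(full_graph$edges)))
  n <- length(verts)
  if (m < n - 1) stop("fraction too small to stay connected")
  with_seed(seed, {
    keep <- sort(sample.int(L, m))
    mk_graph <- function(rows) {
      igraph::graph_from_data_frame(
        data.frame(from = full_graph$edges[rows, 1],
                   to = full_graph$edges[rows, 2]),
        directed = FALSE, vertices = data.frame(name = verts))
    }
    g_full <- mk_graph(seq_len(L))
    tree <- igraph::mst(g_full)
    tree_el <- igraph::as_edgelist(tree)
    tree_rows <- match(edge_key(cbind(as.integer(tree_el[, 1]),
                                      as.integer(tree_el[, 2]))),
                       edge_key(full_graph$edges))
    repeat {
      g <- mk_graph(keep)
      comp <- igraph::components(g)
      if (comp$no == 1) break
      # swap in a spanning-tree edge that bridges two components
      missing_tree <- setdiff(tree_rows, keep)
      bridged <- missing_tree[vapply(missing_tree, function(r) {
        comp$membership[full_graph$edges[r, 1]] !=
          comp$membership[full_graph$edges[r, 2]]
      }, logical(1))]
      add <- bridged[1]
      # remove a kept edge that lies on a cycle (not an articulation edge)
      g2 <- mk_graph(c(keep, add))
      drop_pool <- setdiff(keep, tree_rows)
      dropped <- FALSE
      for (r in sample(drop_pool)) {
        g3 <- mk_graph(setdiff(c(keep, add), r))
        if (igraph::components(g3)$no == comp$no - 1) {
          keep <- sort(setdiff(c(keep, add), r))
          dropped <- TRUE
          break
        }
      }
      if (!dropped) keep <- sort(c(keep, add)) # give up size, keep connected
    }
    key <- edge_key(full_graph$edges)
    paf_graph(full_graph$edges[keep, , drop = FALSE],
              auroc = full_graph$auroc[keep])
  })
}
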