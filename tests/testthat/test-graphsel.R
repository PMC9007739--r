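make_dists <- function(within_costs, between_costs, edges = rbind(c(1, 2))) {
  frames <- list()
  # build a synthetic distributions object directly through the public API:
  # one detection pair per cost value
  breaks <- seq(-1, 1.01, by = 0.01)
  nb <- length(breaks) - 1
  hist_of <- function(x) {
    b <- pmin(pmax(findInterval(x, breaks), 1), nb)
    tabulate(b, nb)
  }
  structure(list(
    edges = edges, breaks = breaks,
    within = matrix(hist_of(within_costs), 1),
    between = matrix(hist_of(between_costs), 1),
    valid = TRUE
  ), class = "edge_cost_distributions")
}

test_that("cost distributions separate within from between animals", {
  cfg <- scene_config(n_animals = 2, n_bodyparts = 3,
                      skeleton_template = rbind(c(1, 2), c(2, 3), c(1, 3)),
                      n_frames = 4, image_size = c(128, 128), stride = 4,
                      occlusion_rate = 0, seed = 17)
  sc <- generate_scene(cfg)
  fg <- full_graph(3)
  frames <- lapply(1:4, function(f) {
    fx <- frame_fixture(sc, f, jitter_sd = 0, graph = fg)
    list(detections = fx$detections, tables = fx$tables)
  })
  dists <- edge_cost_distributions(frames, fg)
  expect_true(all(dists$valid))
  mids <- (dists$breaks[-1] + dists$breaks[-length(dists$breaks)]) / 2
  for (l in seq_len(nrow(fg$edges))) {
    w_mean <- sum(dists$within[l, ] * mids) / sum(dists$within[l, ])
    b_mean <- sum(dists$between[l, ] * mids) / sum(dists$between[l, ])
    expect_gt(w_mean, b_mean)
  }

  # single animal: between histograms all empty
  cfg1 <- scene_config(n_animals = 1, n_bodyparts = 3,
                       skeleton_template = full_graph(3)$edges,
                       n_frames = 2, occlusion_rate = 0, seed = 3)
  sc1 <- generate_scene(cfg1)
  frames1 <- lapply(1:2, function(f) {
    fx <- frame_fixture(sc1, f, jitter_sd = 0, graph = fg)
    list(detections = fx$detections, tables = fx$tables)
  })
  d1 <- edge_cost_distributions(frames1, fg)
  expect_equal(sum(d1$between), 0)

  # binning arithmetic: cost 0.005 falls in bin [0.00, 0.01)
  d <- make_dists(0.005, -0.5)
  bin_low <- which(abs(d$breaks - 0) < 1e-9)
  expect_equal(d$within[1, bin_low], 1)
  expect_equal(sum(d$within), 1)
})

test_that("binned auROC matches its trivial anchors and the O(n^2) oracle", {
  # disjoint distributions: auROC 1
  expect_equal(auroc_binned(make_dists(c(0.8, 0.9), c(-0.1, 0))$within[1, ],
                            make_dists(c(0.8, 0.9), c(-0.1, 0))$between[1, ]),
               1)
  # identical distributions: 0.5
  d <- make_dists(c(0.1, 0.5, 0.9), c(0.1, 0.5, 0.9))
  expect_equal(auroc_binned(d$within[1, ], d$between[1, ]), 0.5)
  # random samples: binned auROC close to the pairwise comparison oracle
  set.seed(123)
  for (rep in 1:50) {
    # values at bin centres: the binned statistic is exactly the pairwise one
    w <- round(stats::runif(60, -1, 0.99), 2) + 0.005
    b <- round(stats::runif(50, -1, 0.99), 2) + 0.005
    d <- make_dists(w, b)
    expect_equal(auroc_binned(d$within[1, ], d$between[1, ]),
                 oracle_auroc(w, b), tolerance = 1e-9)
  }
})

test_that("maximum spanning tree maximizes total discriminability", {
  ranked <- data.frame(i = c(1, 2, 1), j = c(2, 3, 3),
                       auroc = c(0.9, 0.8, 0.2))
  mst <- maximum_spanning_tree(ranked, 3)
  expect_equal(nrow(mst$edges), 2)
  expect_setequal(paste(mst$edges[, 1], mst$edges[, 2]), c("1 2", "2 3"))

  # random 6-node weights: total weight equals exhaustive enumeration
  set.seed(5)
  for (rep in 1:10) {
    fg <- full_graph(6)
    w <- stats::runif(nrow(fg$edges))
    ranked <- data.frame(i = fg$edges[, 1], j = fg$edges[, 2], auroc = w)
    ranked <- ranked[order(-ranked$auroc), ]
    mst <- maximum_spanning_tree(ranked, 6)
    expect_equal(sum(mst$auroc),
                 oracle_mst_weight(fg$edges, w, 6), tolerance = 1e-12)
  }

  # disconnected input names the unreachable bodyparts
  expect_error(
    maximum_spanning_tree(data.frame(i = 1, j = 2, auroc = 0.9), 3),
    "unreachable")
})

test_that("candidate graphs grow monotonically from the spanning tree", {
  set.seed(11)
  fg <- full_graph(6)
  ranked <- data.frame(i = fg$edges[, 1], j = fg$edges[, 2],
                       auroc = stats::runif(nrow(fg$edges), 0.5, 1))
  ranked <- ranked[order(-ranked$auroc), ]
  mst <- maximum_spanning_tree(ranked, 6)
  cands <- candidate_graphs(mst, ranked, 9)
  sizes <- vapply(cands, function(g) nrow(g$edges), integer(1))
  expect_equal(sizes[1], 5) # the MST itself
  expect_equal(sizes[length(sizes)], nrow(fg$edges)) # the full graph
  expect_true(all(diff(sizes) > 0))
  for (ci in 2:length(cands)) {
    expect_true(all(edge_key(cands[[ci - 1]]$edges) %in%
                    edge_key(cands[[ci]]$edges)))
  }
  # every candidate is connected over all bodyparts
  for (g in cands) {
    ig <- igraph::graph_from_edgelist(g$edges, directed = FALSE)
    expect_equal(igraph::components(ig)$no, 1)
  }
  # n_candidates 1: only the MST
  just_mst <- candidate_graphs(mst, ranked, 1)
  expect_equal(length(just_mst), 1)
  expect_equal(nrow(just_mst[[1]]$edges), 5)
  # baseline growth: least discriminative edges first
  base <- candidate_graphs(mst, ranked, 3, from = "baseline",
                           skeleton = mst$edges)
  expect_equal(nrow(base[[1]]$edges), 5)
  added <- setdiff(edge_key(base[[2]]$edges), edge_key(base[[1]]$edges))
  worst <- edge_key(as.matrix(ranked[nrow(ranked), c("i", "j")]))
  expect_true(worst %in% added)
})

test_that("graph selection retains the jointly best candidate", {
  cfg <- scene_config(n_animals = 2, n_bodyparts = 4,
                      skeleton_template = rbind(c(1, 2), c(2, 3), c(3, 4)),
                      n_frames = 3, image_size = c(128, 128),
                      occlusion_rate = 0, seed = 19)
  sc <- generate_scene(cfg)
  fg <- full_graph(4)
  # evaluation frames need tables over the full graph, but the scene renders
  # PAFs only for its skeleton; rebuild a scene whose skeleton IS the full
  # graph so every channel exists
  cfg_full <- cfg
  cfg_full$skeleton_template <- fg$edges
  sc_full <- generate_scene(cfg_full)
  frames <- lapply(1:3, function(f) {
    fx <- frame_fixture(sc_full, f, jitter_sd = 0.3, seed = f, graph = fg)
    list(detections = fx$detections, tables = fx$tables)
  })
  dists <- edge_cost_distributions(frames, fg)
  ranked <- rank_edges_auroc(dists)
  mst <- maximum_spanning_tree(ranked, 4)
  cands <- candidate_graphs(mst, ranked, 3)
  sel <- select_graph(cands, frames, fg)
  expect_s3_class(sel$graph, "paf_graph")
  expect_equal(nrow(sel$scores), length(cands))
  # single candidate: returned unconditionally
  one <- select_graph(cands[1], frames, fg)
  expect_identical(one$graph, cands[[1]])
  # tie: first (smaller) candidate wins
  two <- select_graph(list(cands[[1]], cands[[1]]), frames, fg)
  expect_equal(two$best, 1)
})

test_that("random pruning keeps the requested size and connectivity", {
  fg <- full_graph(12)
  expect_equal(nrow(fg$edges), 66)
  pruned <- prune_random_subgraph(fg, 0.5, seed = 2)
  expect_equal(nrow(pruned$edges), 33)
  ig <- igraph::graph_from_edgelist(pruned$edges, directed = FALSE)
  expect_equal(igraph::components(ig)$no, 1)
  # determinism
  pruned2 <- prune_random_subgraph(fg, 0.5, seed = 2)
  expect_identical(pruned$edges, pruned2$edges)
  # fraction 1: the full graph
  expect_identical(prune_random_subgraph(fg, 1, seed = 1)$edges, fg$edges)
})
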