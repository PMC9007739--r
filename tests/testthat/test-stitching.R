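test_that("residual splitting respects the length threshold", {
  tls <- list(make_tracklet(1, 1:3, cbind(1:3, 1)),
              make_tracklet(2, 10:14, cbind(10:14, 1)),
              make_tracklet(3, 20:26, cbind(20:26, 1)))
  parts <- split_residuals(tls, 5)
  expect_equal(vapply(parts$residuals, function(t) t$id, integer(1)), 1)
  expect_equal(sort(vapply(parts$graph_tracklets, function(t) t$id,
                           integer(1))), c(2, 3)) # 5 frames is not residual
  # min 1: nothing is residual
  expect_equal(length(split_residuals(tls, 1)$residuals), 0)
})

test_that("the automatic gap rule follows 1.5 tau", {
  t1 <- make_tracklet(1, 1:5, cbind(1:5, 1))
  t2 <- make_tracklet(2, 8:12, cbind(8:12, 1)) # gap 3
  t3 <- make_tracklet(3, 17:20, cbind(17:20, 1)) # gap 5
  # tau = max over tracklets of the nearest following start gap
  expect_equal(compute_max_gap(list(t1, t2, t3)), ceiling(1.5 * 5))
  # contiguous tracklets: gap 1 everywhere
  c1 <- make_tracklet(1, 1:5, cbind(1:5, 1))
  c2 <- make_tracklet(2, 6:9, cbind(6:9, 1))
  expect_equal(compute_max_gap(list(c1, c2)), ceiling(1.5))
  # user override takes precedence
  expect_equal(compute_max_gap(list(t1, t2, t3), override = 10), 10)
  expect_equal(compute_max_gap(list(t1)), 0)
})

test_that("motion affinity extrapolates uniform rectilinear motion", {
  path <- cbind(10 + 2 * (0:19), 5 + 1 * (0:19))
  t1 <- make_tracklet(1, 1:10, path[1:10, ])
  t2 <- make_tracklet(2, 14:20, path[14:20, ])
  expect_equal(motion_affinity(t1, t2), 0, tolerance = 1e-9)
  # displacement (3, 4) off the extrapolation in both directions: error 5
  off <- path
  off[14:20, ] <- sweep(path[14:20, ], 2, c(3, 4), "+")
  t2b <- make_tracklet(2, 14:20, off[14:20, ])
  expect_equal(motion_affinity(t1, t2b), 5, tolerance = 1e-9)
  # two stationary tracklets at distance D: affinity D
  s1 <- make_tracklet(1, 1:5, cbind(rep(0, 5), 0))
  s2 <- make_tracklet(2, 8:12, cbind(rep(6, 5), 8))
  expect_equal(motion_affinity(s1, s2), 10)
})

test_that("spatial proximity handles overlapping and disjoint tracklets", {
  a <- make_tracklet(1, 1:5, cbind(1:5, 1))
  expect_equal(spatial_proximity(a, a), 0)
  b <- make_tracklet(2, 8:10, cbind(c(7, 8, 9), 9))
  # disjoint: tail (5, 1) to head (7, 9) -> sqrt(4 + 64)... use 3-4-5 case
  t1 <- make_tracklet(1, 1:3, cbind(c(0, 0, 0), 0))
  t2 <- make_tracklet(2, 5:7, cbind(c(6, 6, 6), 8))
  expect_equal(spatial_proximity(t1, t2), 10)
  # overlapping with constant offset (0, 2): averaged distance 2
  o1 <- make_tracklet(1, 1:6, cbind(1:6, 0))
  o2 <- make_tracklet(2, 3:8, cbind(3:8, 2))
  expect_equal(spatial_proximity(o1, o2), 2)
})

test_that("shape similarity is the undirected Hausdorff distance", {
  t1 <- make_tracklet(1, 1:3, cbind(c(0, 0, 0), 0),
                      offsets = rbind(c(0, 0)))
  t2 <- make_tracklet(2, 5:7, cbind(c(3, 3, 3), 4),
                      offsets = rbind(c(0, 0)))
  expect_equal(shape_similarity(t1, t1), 0)
  expect_equal(shape_similarity(t1, t2), 5)
  # undirectedness forces the max of the two directed distances
  t3 <- make_tracklet(3, 1:3, cbind(c(0, 0, 0), 0),
                      offsets = rbind(c(0, 0), c(10, 0)))
  t4 <- make_tracklet(4, 5:7, cbind(c(0, 0, 0), 0),
                      offsets = rbind(c(0, 0)))
  expect_equal(shape_similarity(t3, t4), 10)
})

test_that("Hankel ranks discriminate shared from different dynamics", {
  # uniform rectilinear motion: rank exactly 2
  path <- cbind(5 + 3 * (0:29), 40 - 2 * (0:29))
  expect_equal(poselink:::hankel_rank(path), 2)
  # two segments of one trajectory: ratio 0.5
  t1 <- make_tracklet(1, 1:12, path[1:12, ])
  t2 <- make_tracklet(2, 16:28, path[16:28, ])
  expect_equal(dynamic_similarity(t1, t2), 0.5)
  # genuinely different dynamics (curved vs straight): ratio > 0.5.
  # note a time-reversed straight line is still affine in time and spans the
  # same Hankel column space, so only a change of dynamical order shows up
  curve <- cbind(5 + 3 * (16:28) + 15 * sin((16:28) / 2),
                 40 - 2 * (16:28) + 15 * cos((16:28) / 2))
  t3 <- make_tracklet(3, 16:28, curve)
  expect_gt(dynamic_similarity(t1, t3), 0.5)
  # too short: affinity unavailable
  t4 <- make_tracklet(4, 1:2, path[1:2, ])
  expect_true(is.na(dynamic_similarity(t4, t2)))
})

test_that("cost combination normalizes, weights and applies appearance", {
  aff <- data.frame(motion = c(2, 10), proximity = c(NA, NA),
                    shape = c(NA, NA), dynamics = c(NA, NA))
  w <- combine_costs(aff, c(motion = 1, proximity = 1, shape = 1,
                            dynamics = 1))
  expect_equal(w, c(0, 1)) # single affinity: its min-max normalized value
  # identical affinities on two edges: identical weights
  aff2 <- data.frame(motion = c(5, 5), proximity = c(1, 1),
                     shape = c(2, 2), dynamics = c(0.5, 0.5))
  w2 <- combine_costs(aff2, c(motion = 1, proximity = 1, shape = 1,
                              dynamics = 1))
  expect_equal(w2[1], w2[2])
  # appearance: cosine 1 at strength 1 zeroes the weight
  w3 <- combine_costs(aff, c(motion = 1, proximity = 1, shape = 1,
                             dynamics = 1),
                      appearance = c(1, 1), appearance_strength = 1)
  expect_equal(w3, c(0, 0))
  # infinite shape cost maps to the maximal normalized cost
  aff4 <- data.frame(motion = c(1, 2), proximity = c(1, 2),
                     shape = c(Inf, 3), dynamics = c(NA, NA))
  w4 <- combine_costs(aff4, c(motion = 1, proximity = 1, shape = 1,
                              dynamics = 1))
  expect_true(all(is.finite(w4)))
  expect_gt(w4[1], w4[2] - 1)
})

test_that("min-cost flow covers the DAG with k optimal disjoint paths", {
  # forced chain, k = 1
  chain <- structure(list(n = 3, edges = data.frame(
    from = c(1, 2), to = c(2, 3), w = c(0.1, 0.2))), class = "stitch_graph")
  p1 <- solve_flow(chain, 1)
  expect_equal(p1, list(1:3), ignore_attr = TRUE)
  # two parallel chains, k = 2
  par2 <- structure(list(n = 4, edges = data.frame(
    from = c(1, 2), to = c(3, 4), w = c(0.1, 0.2))), class = "stitch_graph")
  p2 <- solve_flow(par2, 2)
  expect_equal(length(p2), 2)
  expect_setequal(vapply(p2, paste, character(1), collapse = "-"),
                  c("1-3", "2-4"))
  # random DAGs: optimal cost equals brute-force path-cover enumeration
  set.seed(91)
  for (rep in 1:30) {
    n <- sample(5:9, 1)
    k <- sample(1:3, 1)
    # random temporal layout guarantees acyclicity
    starts <- sort(sample(1:50, n)) * 10
    edges <- list()
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        if (stats::runif(1) < 0.5) {
          edges[[length(edges) + 1]] <- data.frame(
            from = i, to = j, w = round(stats::runif(1), 4))
        }
      }
    }
    if (length(edges) == 0) next
    E <- do.call(rbind, edges)
    want <- oracle_path_cover(n, E, k)
    g <- structure(list(n = n, edges = E), class = "stitch_graph")
    if (is.na(want)) {
      expect_error(solve_flow(g, k), "infeasible")
    } else {
      got <- solve_flow(g, k)
      expect_equal(attr(got, "cost"), want, tolerance = 1e-6)
      expect_equal(length(got), k)
      expect_setequal(unlist(got), 1:n) # every tracklet visited once
    }
  }
})

test_that("residual reinsertion preserves continuity and prefers proximity", {
  # a track with a gap; a residual exactly bridging it is inserted
  t1 <- make_tracklet(1, 1:6, cbind(1:6, 0))
  t2 <- make_tracklet(2, 10:15, cbind(10:15, 0))
  tracks <- list(list(id = 1, pieces = list(t1, t2)))
  res <- make_tracklet(3, 7:9, cbind(7:9, 0))
  out <- reinsert_residuals(tracks, list(res))
  expect_equal(out$residual_report$placed, 1)
  expect_equal(length(out$tracks[[1]]$pieces), 3)
  # a residual entirely overlapping occupied frames of every track stays
  # unplaced (continuity guarantee)
  res2 <- make_tracklet(4, 4:6, cbind(4:6, 0))
  out2 <- reinsert_residuals(tracks, list(res2))
  expect_equal(out2$residual_report$unplaced, 1)
  # two candidate tracks: the closer one wins
  ta <- list(id = 1, pieces = list(make_tracklet(1, 1:6, cbind(1:6, 0)),
                                   make_tracklet(2, 10:15, cbind(10:15, 0))))
  tb <- list(id = 2, pieces = list(make_tracklet(3, 1:6, cbind(1:6, 50)),
                                   make_tracklet(4, 10:15, cbind(10:15, 50))))
  resm <- make_tracklet(5, 7:9, cbind(7:9, 49))
  out3 <- reinsert_residuals(list(ta, tb), list(resm))
  expect_equal(length(out3$tracks[[2]]$pieces), 3)
  expect_equal(length(out3$tracks[[1]]$pieces), 2)
})

test_that("stitched tracks are temporally consistent", {
  cfg <- scene_config(n_animals = 3, n_frames = 80, seed = 41)
  sc <- generate_scene(cfg)
  res <- run_pipeline(sc, pipeline_config(seed = 41))
  for (tr in res$tracks) {
    frames <- unlist(lapply(tr$pieces, function(p) p$frames))
    expect_equal(anyDuplicated(frames), 0) # never two assemblies per frame
    starts <- vapply(tr$pieces, function(p) p$start, numeric(1))
    expect_true(all(diff(starts) > 0)) # strictly temporal piece order
  }
})
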