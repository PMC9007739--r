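mk_table <- function(cost, edge = c(1, 2), det_i = NULL, det_j = NULL) {
  list(edge = edge, paf_index = 1L,
       det_i = det_i %||% seq_len(nrow(cost)),
       det_j = det_j %||% (nrow(cost) + seq_len(ncol(cost))),
       cost = cost)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("per-edge optimal pairing maximizes total affinity", {
  tab <- mk_table(rbind(c(0.9, 0.1), c(0.2, 0.8)))
  pairs <- pick_optimal_pairs(tab, 0.1)
  expect_equal(pairs$i[order(pairs$i)], c(1, 2))
  expect_equal(pairs$j[order(pairs$i)], c(3, 4))
  # all below threshold: no pairs
  expect_equal(nrow(pick_optimal_pairs(mk_table(matrix(0.05, 2, 2)), 0.1)), 0)
  # random 5x5 tables: total equals brute force over all 5! assignments
  set.seed(44)
  for (rep in 1:20) {
    C <- matrix(stats::runif(25), 5, 5)
    got <- pick_optimal_pairs(mk_table(C), paf_threshold = 0)
    gain <- C
    gain[gain < 0] <- 0
    expect_equal(sum(got$cost), oracle_max_matching(gain), tolerance = 1e-9)
  }
})

test_that("connected components equal a union-find oracle", {
  pairs <- data.frame(i = c(1, 2), j = c(2, 3))
  expect_equal(connected_components(pairs), list(c(1, 2, 3)))
  pairs2 <- data.frame(i = c(1, 3), j = c(2, 4))
  expect_equal(connected_components(pairs2), list(c(1, 2), c(3, 4)))
  set.seed(12)
  for (rep in 1:30) {
    n <- sample(4:12, 1)
    m <- sample(2:10, 1)
    pr <- data.frame(i = sample(n, m, replace = TRUE),
                     j = sample(n, m, replace = TRUE))
    pr <- pr[pr$i != pr$j, , drop = FALSE]
    if (nrow(pr) == 0) next
    got <- connected_components(pr)
    want <- oracle_components(pr)
    norm <- function(l) l[order(vapply(l, `[`, numeric(1), 1))]
    expect_equal(norm(got), norm(want))
  }
})

test_that("greedy linking respects the bodypart conflict rule", {
  det <- data.frame(bodypart = c(1, 2, 2), x = c(0, 1, 50), y = c(0, 0, 0),
                    confidence = 1)
  # two singleton groups, one valid connection: merged
  conns <- data.frame(i = 1, j = 2, bodypart_i = 1, bodypart_j = 2,
                      cost = 0.9)
  groups <- greedy_link(conns, list(), det)
  expect_equal(length(groups), 1)
  expect_setequal(unname(groups[[1]]), c(1, 2))
  # a connection that would duplicate a bodypart is skipped
  conns2 <- rbind(conns, data.frame(i = 1, j = 3, bodypart_i = 1,
                                    bodypart_j = 2, cost = 0.5))
  groups2 <- greedy_link(conns2, list(), det)
  expect_equal(length(groups2), 1)
  expect_setequal(unname(groups2[[1]]), c(1, 2))
})

test_that("pose prior estimation recovers distance statistics", {
  # identical poses: mean is that pose's distance vector, covariance floor
  pose <- rbind(c(0, 0), c(3, 0), c(3, 4))
  prior <- fit_pose_prior(list(pose, pose, pose))
  expect_equal(unname(prior$mean), c(3, 5, 4))
  expect_true(all(abs(prior$cov[upper.tri(prior$cov)]) < 1e-10))
  expect_true(all(diag(prior$cov) > 0)) # regularization floor

  # two bodyparts: a single distance coordinate
  p2 <- fit_pose_prior(list(rbind(c(0, 0), c(1, 0)),
                            rbind(c(0, 0), c(2, 0))))
  expect_equal(length(p2$mean), 1)

  # poses from a known Gaussian over distances: mean recovered within 3 s.e.
  set.seed(15)
  n <- 500
  d_true <- 10
  sd_true <- 1
  poses <- lapply(seq_len(n), function(i) {
    len <- stats::rnorm(1, d_true, sd_true)
    rbind(c(0, 0), c(len, 0))
  })
  pr <- fit_pose_prior(poses)
  expect_lt(abs(pr$mean[1] - d_true), 3 * sd_true / sqrt(n))
})

test_that("the Mahalanobis gate accepts prior-consistent growth only", {
  set.seed(8)
  # prior around an equilateral triangle of side 10, s.d. 1
  poses <- lapply(1:200, function(i) {
    s <- 10 + stats::rnorm(1)
    rbind(c(0, 0), c(s, 0), c(s / 2, s * sqrt(3) / 2))
  })
  prior <- fit_pose_prior(poses)
  base <- rbind(c(0, 0), c(10, 0))
  rownames(base) <- c(1, 2)
  # candidate at the prior mean distance: accepted
  good <- rbind(base, c(5, 10 * sqrt(3) / 2))
  rownames(good) <- c(1, 2, 3)
  expect_true(mahalanobis_gate(base, good, prior))
  # candidate at ten times the prior mean distance: rejected
  bad <- rbind(base, c(100, 80))
  rownames(bad) <- c(1, 2, 3)
  expect_false(mahalanobis_gate(base, bad, prior))
  # fewer than two keypoints before growth: gate inapplicable, accept
  single <- base[1, , drop = FALSE]
  expect_true(mahalanobis_gate(single, base, prior))
})

test_that("temporal coherence weight follows the exponential kernel", {
  conn <- c(0, 0, 10, 0)
  # all past connections identical: weight 1
  past <- list(list(dt = 1, connections = rbind(conn)))
  expect_equal(temporal_coherence_weight(conn, past), 1)
  # distant connections: weight tends to 0
  far <- list(list(dt = 1, connections = rbind(conn + 1e4)))
  expect_lt(temporal_coherence_weight(conn, far), 1e-10)
  # j = 2, gamma 0.01, dt 1, distances 0 and 10: (1 + exp(-1)) / 2
  past2 <- list(list(dt = 1, connections = rbind(conn)),
                list(dt = 1, connections = rbind(conn + c(10, 0, 0, 0))))
  expect_equal(temporal_coherence_weight(conn, past2, gamma = 0.01),
               (1 + exp(-1)) / 2)
  # no past frames: weight 0
  expect_equal(temporal_coherence_weight(conn, list()), 0)
})

test_that("frame assembly groups clean detections into pure animals", {
  cfg <- scene_config(n_animals = 1, n_bodyparts = 4,
                      n_frames = 1, occlusion_rate = 0, seed = 23)
  sc <- generate_scene(cfg)
  fx <- frame_fixture(sc, 1, jitter_sd = 0)
  res <- assemble_frame(fx$detections, fx$tables, fx$graph)
  expect_equal(length(res$assemblies), 1)
  expect_equal(length(res$assemblies[[1]]$members), 4)
  expect_equal(length(res$unconnected), 0)

  # two well-separated animals: two pure assemblies
  cfg2 <- scene_config(n_animals = 2, n_bodyparts = 4, n_frames = 1,
                       image_size = c(256, 256), occlusion_rate = 0,
                       seed = 29)
  sc2 <- generate_scene(cfg2)
  fx2 <- frame_fixture(sc2, 1, jitter_sd = 0)
  res2 <- assemble_frame(fx2$detections, fx2$tables, fx2$graph)
  q <- assembly_quality(res2$assemblies, fx2$detections$gt_animal,
                        nrow(fx2$detections))
  expect_equal(q$purity, 1)
  expect_equal(q$unconnected_fraction, 0)

  # empty frame: empty output
  res0 <- assemble_frame(fx2$detections[0, ], fx2$tables, fx2$graph)
  expect_equal(length(res0$assemblies), 0)
})

test_that("identity-mode grouping follows the argmax of identity scores", {
  det <- data.frame(bodypart = c(1, 2, 1, 2), x = c(0, 1, 50, 51),
                    y = 0, confidence = 1,
                    id_prob_1 = c(0.9, 0.8, 0.1, 0.2),
                    id_prob_2 = c(0.1, 0.2, 0.9, 0.8))
  res <- assemble_frame(det, list(), paf_graph(rbind(c(1, 2))),
                        options = list(identity_mode = TRUE))
  expect_equal(length(res$assemblies), 2)
  members <- lapply(res$assemblies, function(a) sort(unname(a$members)))
  expect_setequal(members, list(1:2, 3:4))
})

test_that("no detection is ever assigned twice within a frame", {
  set.seed(77)
  for (rep in 1:20) {
    cfg <- scene_config(n_animals = 3, n_bodyparts = 5, n_frames = 1,
                        occlusion_rate = 0, seed = rep)
    sc <- generate_scene(cfg)
    fx <- frame_fixture(sc, 1, jitter_sd = 1, seed = rep + 100)
    res <- assemble_frame(fx$detections, fx$tables, fx$graph)
    all_members <- unlist(lapply(res$assemblies, `[[`, "members"))
    expect_equal(anyDuplicated(all_members), 0)
    for (a in res$assemblies) {
      expect_equal(anyDuplicated(names(a$members)), 0)
    }
    expect_equal(sort(unname(c(all_members, res$unconnected))),
                 seq_len(nrow(fx$detections)))
  }
})

test_that("greedy assembly matches the exhaustive partition oracle", {
  hits <- 0
  n_frames <- 40
  for (rep in seq_len(n_frames)) {
    cfg <- scene_config(n_animals = 3, n_bodyparts = 4, n_frames = 1,
                        image_size = c(192, 192), occlusion_rate = 0,
                        seed = 1000 + rep)
    sc <- generate_scene(cfg)
    fx <- frame_fixture(sc, 1, jitter_sd = 0.5, seed = rep)
    res <- assemble_frame(fx$detections, fx$tables, fx$graph)
    got <- canonical_partition(assembly_labels(res, nrow(fx$detections)))
    want <- oracle_best_partition(fx$detections, fx$tables, 3)
    want_p <- canonical_partition(want$assignment)
    if (identical(got, want_p)) hits <- hits + 1
  }
  expect_gte(hits / n_frames, 0.95)
})
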