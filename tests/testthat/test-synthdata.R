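test_that("scene generation is deterministic and honours the motion model", {
  cfg <- scene_config(n_animals = 2, n_frames = 20, seed = 11)
  s1 <- generate_scene(cfg)
  s2 <- generate_scene(cfg)
  expect_identical(s1$coords, s2$coords)
  expect_identical(s1$visible, s2$visible)

  # zero motion: every frame identical to frame 0
  cfg0 <- scene_config(n_animals = 1, n_frames = 5, speed = 0,
                       articulation_sd = 0, turn_sd = 0, seed = 2)
  s0 <- generate_scene(cfg0)
  for (f in 2:5) {
    expect_equal(s0$coords[f, , , ], s0$coords[1, , , ])
  }

  # occlusion rate 0: every animal visible in every frame (exhaustive scan)
  cfg3 <- scene_config(n_animals = 3, n_frames = 100, occlusion_rate = 0,
                       seed = 5)
  s3 <- generate_scene(cfg3)
  expect_true(all(s3$visible))
  expect_true(all(s3$coords[, , , 1] >= 0 &
                  s3$coords[, , , 1] < cfg3$image_size[2]))
  expect_true(all(s3$coords[, , , 2] >= 0 &
                  s3$coords[, , , 2] < cfg3$image_size[1]))
})

test_that("invalid scene configurations are rejected", {
  expect_error(scene_config(stride = 3), "stride")
  expect_error(scene_config(image_size = c(190, 192), stride = 4),
               "divisible")
  expect_error(scene_config(dropout = 1.4), "probabilities")
  expect_error(scene_config(n_bodyparts = 3,
                            skeleton_template = rbind(c(1, 4))),
               "unknown bodypart")
})

test_that("occlusion events hide whole animals for the configured duration", {
  cfg <- scene_config(n_animals = 1, n_frames = 300, occlusion_rate = 0.03,
                      occlusion_duration = 4, seed = 9)
  sc <- generate_scene(cfg)
  vis_any <- apply(sc$visible[, 1, ], 1, any)
  vis_all <- apply(sc$visible[, 1, ], 1, all)
  # whole-animal occlusion: a frame is either fully visible or fully hidden
  expect_identical(vis_any, vis_all)
  runs <- rle(!vis_any)
  expect_true(any(!vis_any)) # events do occur at this rate
  hid <- which(runs$values)
  # every hidden run is a whole number of 4-frame events (the last run may
  # be truncated by the end of the video)
  ends_at_eof <- cumsum(runs$lengths)[hid] == length(vis_any)
  expect_true(all(runs$lengths[hid] %% 4 == 0 | ends_at_eof))
})

test_that("score map and locref rendering follow the target rule", {
  cfg <- scene_config(n_animals = 1, n_bodyparts = 2, n_frames = 1,
                      image_size = c(64, 64), stride = 4, target_radius = 1.9,
                      seed = 1)
  sc <- generate_scene(cfg)
  # keypoint exactly at a cell centre, r < stride/2: one positive cell,
  # zero offset
  sc$coords[1, 1, 1, ] <- c(4 * 3 + 2, 4 * 5 + 2) # cell p=3, q=5
  sc$coords[1, 1, 2, ] <- c(4 * 3 + 2, 4 * 5 + 2) # coincident, other channel
  tg <- render_targets(sc, 1)
  expect_equal(sum(tg$score_maps[, , 1]), 1)
  expect_equal(tg$score_maps[5 + 1, 3 + 1, 1], 1)
  expect_equal(tg$locref[5 + 1, 3 + 1, 1, ], c(0, 0))
  # coincident keypoints of different bodyparts: identical channels
  expect_equal(tg$score_maps[, , 1], tg$score_maps[, , 2])
  # binary score maps, PAF norms bounded by 1
  expect_true(all(tg$score_maps %in% c(0, 1)))
})

test_that("PAF band matches direct geometric enumeration", {
  K <- 2
  cfg <- scene_config(n_animals = 1, n_bodyparts = K,
                      skeleton_template = rbind(c(1, 2)),
                      n_frames = 1, image_size = c(64, 64), stride = 4,
                      pafwidth = 3, seed = 1)
  sc <- generate_scene(cfg)
  y <- 30.5
  sc$coords[1, 1, 1, ] <- c(10, y)
  sc$coords[1, 1, 2, ] <- c(50, y)
  tg <- render_targets(sc, 1)
  px <- tg$pafs[, , 1]
  py <- tg$pafs[, , 2]
  nz <- which(px != 0 | py != 0)
  # horizontal limb: unit vector (1, 0) everywhere on the band
  expect_true(all(px[nz] == 1))
  expect_true(all(py[nz] == 0))
  # enumerate cells within pafwidth of the segment directly
  cx <- (0:15) * 4 + 2
  cy <- (0:15) * 4 + 2
  cnt <- 0
  for (q in 1:16) {
    for (p in 1:16) {
      along <- cx[p] - 10
      perp <- abs(cy[q] - y)
      if (along >= 0 && along <= 40 && perp <= 3) cnt <- cnt + 1
    }
  }
  expect_equal(length(nz), cnt)
  # PAF channel pairs = skeleton edges; score channels = bodyparts
  expect_equal(dim(tg$pafs)[3], 2 * nrow(cfg$skeleton_template))
  expect_equal(dim(tg$score_maps)[3], K)
})

test_that("detection corruption behaves at its boundary settings", {
  cfg <- scene_config(n_animals = 2, n_frames = 10, seed = 21,
                      jitter_sd = 0, dropout = 0, clutter_rate = 0,
                      occlusion_rate = 0)
  sc <- generate_scene(cfg)
  det <- corrupt_detections(sc)
  # identity: detections equal ground truth
  expect_equal(nrow(det), 10 * 2 * 5)
  for (r in sample(nrow(det), 20)) {
    expect_equal(det$x[r],
                 sc$coords[det$frame[r], det$gt_animal[r], det$bodypart[r], 1])
  }
  # dropout 1: empty tables
  cfg1 <- cfg
  cfg1$dropout <- 1
  expect_equal(nrow(corrupt_detections(sc, cfg1)), 0)
  # dropout 0.2 on 1000 keypoints: survivors within binomial 99% interval
  cfgb <- scene_config(n_animals = 2, n_frames = 100, seed = 3,
                       jitter_sd = 0, dropout = 0.2, clutter_rate = 0,
                       occlusion_rate = 0)
  scb <- generate_scene(cfgb)
  detb <- corrupt_detections(scb)
  n_total <- 100 * 2 * 5
  bounds <- qbinom(c(0.005, 0.995), n_total, 0.8)
  expect_gte(nrow(detb), bounds[1])
  expect_lte(nrow(detb), bounds[2])
})

test_that("crop centres follow the two sampling strategies", {
  # single keypoint, density strategy: all centres within the 40% shift box
  kp <- matrix(c(50, 60), 1, 2)
  ctr <- sample_crop_centers(kp, c(200, 200), 50, crop_size = 100, seed = 4,
                             strategy = "density")
  expect_true(all(abs(ctr[, 1] - 50) <= 40 + 1e-9))
  expect_true(all(abs(ctr[, 2] - 60) <= 40 + 1e-9))

  # uniform strategy: chi-square uniformity over a coarse histogram
  ctr2 <- sample_crop_centers(NULL, c(100, 100), 1e4, crop_size = 1,
                              seed = 8, strategy = "uniform")
  # shifts move centres at most 0.4 px; bin the central region
  xs <- ctr2[, 1]
  keep <- xs >= 0 & xs <= 100
  h <- table(cut(xs[keep], seq(0, 100, by = 20)))
  expect_gt(stats::chisq.test(h)$p.value, 0.01)

  # two clusters, 9 vs 1 keypoints: density picks in proportion to
  # neighbour-count weights
  cl9 <- cbind(stats::runif(9, 10, 14), stats::runif(9, 10, 14))
  cl1 <- matrix(c(180, 180), 1, 2)
  kps <- rbind(cl9, cl1)
  # direct neighbour counting: each cluster point has 8 neighbours within
  # radius 20 (10% of 200), the singleton none
  w <- c(rep(1 + 8, 9), 1)
  expected_frac <- sum(w[1:9]) / sum(w)
  ctr3 <- sample_crop_centers(kps, c(200, 200), 4000, crop_size = 10,
                              seed = 6, strategy = "density")
  frac9 <- mean(ctr3[, 1] < 100)
  expect_lt(abs(frac9 - expected_frac), 0.03)
})

test_that("decoding noiseless rendered targets recovers keypoints", {
  # render/decode round trip within 0.5 px at worst; locref makes it exact
  cfg <- scene_config(n_animals = 1, n_bodyparts = 1,
                      skeleton_template = matrix(integer(0), 0, 2),
                      n_frames = 1, image_size = c(64, 64), stride = 8,
                      target_radius = 6, seed = 1)
  sc <- generate_scene(cfg)
  set.seed(42)
  for (i in 1:20) {
    sc$coords[1, 1, 1, ] <- stats::runif(2, 5, 59)
    tg <- render_targets(sc, 1)
    det <- decode_detections(tg)
    expect_equal(nrow(det), 1)
    expect_lt(abs(det$x - sc$coords[1, 1, 1, 1]), 1e-9)
    expect_lt(abs(det$y - sc$coords[1, 1, 1, 2]), 1e-9)
  }
})
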