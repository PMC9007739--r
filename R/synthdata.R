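#' Scene configuration for the synthetic multi-animal generator
#'
#' Bundles every knob of the scene simulator: number of animals and bodyparts,
#' skeleton template, image geometry, rendering stride and target parameters,
#' a simple motion model (rigid translation of a body template plus small
#' per-keypoint articulation noise), whole-animal occlusion events, and the
#' detection-noise model used by [corrupt_detections()].
#'
#' Coordinates are 0-based pixels, x rightward, y downward; keypoints are
#' continuous subpixel positions. The rendering grid cell `(p, q)` (0-based)
#' corresponds to the full-image point `(p * stride + stride / 2,
#' q * stride + stride / 2)`, which makes target rendering the exact inverse
#' of peak decoding.
#'
#' @param n_animals number of animals (>= 1).
#' @param n_bodyparts keypoints per animal.
#' @param skeleton_template integer matrix (edges x 2) of bodypart indices;
#'   default is the chain 1-2, 2-3, ...
#' @param image_size `c(H, W)` in pixels; both must be multiples of `stride`.
#' @param n_frames number of frames.
#' @param stride rendering stride (lambda), one of 2, 4, 8.
#' @param target_radius score-map target radius r in pixels.
#' @param pafwidth half-width of the part affinity field band in pixels.
#' @param speed translation speed in px/frame.
#' @param turn_sd s.d. of the per-frame heading change (radians).
#' @param articulation_sd s.d. of per-keypoint articulation noise (px).
#' @param body_length,body_width body template extent in pixels.
#' @param occlusion_rate per-frame probability that an occlusion event starts
#'   for an animal.
#' @param occlusion_duration duration of an occlusion event in frames.
#' @param jitter_sd detection jitter s.d. (px).
#' @param dropout detection dropout probability.
#' @param clutter_rate expected number of clutter detections per frame
#'   (Poisson).
#' @param seed integer seed making the generator deterministic.
#' @return a `scene_config` list, validated.
#' @export
scene_config <- function(n_animals = 3L,
                         n_bodyparts = 5L,
                         skeleton_template = NULL,
                         image_size = c(192L, 192L),
                         n_frames = 100L,
                         stride = 4L,
                         target_radius = 3,
                         pafwidth = 3,
                         speed = 2,
                         turn_sd = 0.3,
                         articulation_sd = 0.5,
                         body_length = 28,
                         body_width = 8,
                         occlusion_rate = 0.02,
                         occlusion_duration = 8L,
                         jitter_sd = 0.5,
                         dropout = 0.05,
                         clutter_rate = 0.5,
                         seed = 1L) {
  if (is.null(skeleton_template)) {
    # chain along the body plus skip-one edges: a realistically redundant
    # limb set, so one dropped keypoint does not disconnect an animal
    chain <- if (n_bodyparts >= 2) {
      cbind(seq_len(n_bodyparts - 1L), seq_len(n_bodyparts - 1L) + 1L)
    } else {
      matrix(integer(0), 0, 2)
    }
    skips <- if (n_bodyparts >= 3) {
      cbind(seq_len(n_bodyparts - 2L), seq_len(n_bodyparts - 2L) + 2L)
    } else {
      matrix(integer(0), 0, 2)
    }
    skeleton_template <- rbind(chain, skips)
  }
  skeleton_template <- matrix(as.integer(skeleton_template), ncol = 2)
  cfg <- list(
    n_animals = as.integer(n_animals), n_bodyparts = as.integer(n_bodyparts),
    skeleton_template = skeleton_template,
    image_size = as.integer(image_size), n_frames = as.integer(n_frames),
    stride = as.integer(stride), target_radius = target_radius,
    pafwidth = pafwidth, speed = speed, turn_sd = turn_sd,
    articulation_sd = articulation_sd, body_length = body_length,
    body_width = body_width, occlusion_rate = occlusion_rate,
    occlusion_duration = as.integer(occlusion_duration),
    jitter_sd = jitter_sd, dropout = dropout, clutter_rate = clutter_rate,
    seed = as.integer(seed)
  )
  validate_scene_config(cfg)
  class(cfg) <- "scene_config"
  cfg
}

validate_scene_config <- function(cfg) {
  stopifnot(cfg$n_animals >= 1L, cfg$n_bodyparts >= 1L, cfg$n_frames >= 1L)
  if (!cfg$stride %in% c(2L, 4L, 8L)) {
    stop("stride must be one of 2, 4, 8", call. = FALSE)
  }
  if (any(cfg$image_size %% cfg$stride != 0L)) {
    stop("image_size must be divisible by stride", call. = FALSE)
  }
  probs <- c(cfg$occlusion_rate, cfg$dropout)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  edges <- cfg$skeleton_template
  if (nrow(edges) > 0 &&
      (any(edges < 1L) || any(edges > cfg$n_bodyparts) ||
       any(edges[, 1] == edges[, 2]))) {
    stop("skeleton edge references unknown bodypart", call. = FALSE)
  }
  invisible(cfg)
}

# Body template: keypoints along the body axis with alternating lateral
# offsets so poses have 2D spread (needed by the ellipse tracker).
body_template <- function(cfg) {
  k <- cfg$n_bodyparts
  if (k == 1L) return(matrix(0, 1, 2))
  ax <- cfg$body_length * (0.5 - (seq_len(k) - 1) / (k - 1))
  lat <- rep(c(1, -1), length.out = k) * cfg$body_width / 2
  lat[c(1, k)] <- 0 # head and tail on the axis
  cbind(ax, lat)
}

rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

#' Generate a synthetic multi-animal ground-truth scene
#'
#' Animals follow a smooth random walk (constant speed, Gaussian heading
#' changes, reflection at the image borders); the body is a rigid template
#' rotated to the heading plus per-keypoint articulation noise. Occlusion
#' events hide a whole animal for a configured duration. Deterministic for a
#' fixed config (the seed is part of the config).
#'
#' @param config a [scene_config()].
#' @return a `gt_scene`: list with `coords` (`n_frames x n_animals x
#'   n_bodyparts x 2` array of (x, y)), `visible` (logical array,
#'   frame x animal x bodypart), `bodyparts`, `animals`, and `config`.
#' @export
generate_scene <- function(config) {
  validate_scene_config(config)
  cfg <- config
  with_seed(cfg$seed, {
    H <- cfg$image_size[1]
    W <- cfg$image_size[2]
    K <- cfg$n_bodyparts
    tmpl <- body_template(cfg)
    margin <- max(cfg$body_length / 2 + cfg$body_width, 4)
    coords <- array(NA_real_, c(cfg$n_frames, cfg$n_animals, K, 2))
    visible <- array(TRUE, c(cfg$n_frames, cfg$n_animals, K))
    for (a in seq_len(cfg$n_animals)) {
      pos <- c(stats::runif(1, margin, W - margin),
               stats::runif(1, margin, H - margin))
      heading <- stats::runif(1, 0, 2 * pi)
      occl_left <- 0L
      for (f in seq_len(cfg$n_frames)) {
        if (f > 1) {
          heading <- heading + stats::rnorm(1, 0, cfg$turn_sd)
          step <- cfg$speed * c(cos(heading), sin(heading))
          pos <- pos + step
          # reflect off walls
          if (pos[1] < margin || pos[1] > W - margin) {
            heading <- pi - heading
            pos[1] <- min(max(pos[1], margin), W - margin)
          }
          if (pos[2] < margin || pos[2] > H - margin) {
            heading <- -heading
            pos[2] <- min(max(pos[2], margin), H - margin)
          }
        }
        kp <- tmpl %*% t(rot2(heading))
        kp <- sweep(kp, 2, pos, "+")
        if (cfg$articulation_sd > 0 && cfg$speed > 0) {
          kp <- kp + matrix(stats::rnorm(2 * K, 0, cfg$articulation_sd), K, 2)
        }
        kp[, 1] <- pmin(pmax(kp[, 1], 0), W - 1e-6)
        kp[, 2] <- pmin(pmax(kp[, 2], 0), H - 1e-6)
        coords[f, a, , ] <- kp
        if (occl_left > 0L) {
          visible[f, a, ] <- FALSE
          occl_left <- occl_left - 1L
        } else if (cfg$occlusion_rate > 0 &&
                   stats::runif(1) < cfg$occlusion_rate) {
          visible[f, a, ] <- FALSE
          occl_left <- cfg$occlusion_duration - 1L
        }
      }
    }
    structure(list(
      coords = coords, visible = visible,
      bodyparts = paste0("bp", seq_len(K)),
      animals = paste0("animal", seq_len(cfg$n_animals)),
      config = cfg
    ), class = "gt_scene")
  })
}

#' @export
print.gt_scene <- function(x, ...) {
  cat(sprintf(
    "gt_scene: %d frames, %d animals, %d bodyparts, %dx%d px (stride %d)\n",
    x$config$n_frames, x$config$n_animals, x$config$n_bodyparts,
    x$config$image_size[1], x$config$image_size[2], x$config$stride
  ))
  invisible(x)
}

#' Render training-target tensors for one scene frame
#'
#' Produces the three target tensors used by bottom-up pose models:
#' binary score maps (1 on grid cells whose full-image centre lies closer
#' than `target_radius` to a keypoint), location refinement fields storing
#' the subpixel offset `(x_true - cell_centre)` of the nearest keypoint, and
#' part affinity fields holding the limb's unit direction vector on cells
#' within `pafwidth` of the limb segment (averaged where limbs overlap).
#'
#' @param scene a `gt_scene`.
#' @param frame frame index (1-based).
#' @param config scene configuration; defaults to the scene's own.
#' @return list with `score_maps` (`nq x np x K`), `locref`
#'   (`nq x np x K x 2`), `pafs` (`nq x np x 2L` with channels `2l-1, 2l`
#'   holding the x and y components of edge `l`), `stride` and `edges`.
#'   Array rows index the y grid cell (q), columns the x grid cell (p).
#' @export
render_targets <- function(scene, frame, config = scene$config) {
  cfg <- config
  lam <- cfg$stride
  H <- cfg$image_size[1]
  W <- cfg$image_size[2]
  np <- W %/% lam
  nq <- H %/% lam
  K <- cfg$n_bodyparts
  edges <- cfg$skeleton_template
  L <- nrow(edges)
  cx <- (seq_len(np) - 1) * lam + lam / 2
  cy <- (seq_len(nq) - 1) * lam + lam / 2

  score <- array(0, c(nq, np, K))
  locref <- array(0, c(nq, np, K, 2))
  pafs <- array(0, c(nq, np, 2 * L))

  kp_all <- scene$coords[frame, , , , drop = FALSE]
  vis <- scene$visible[frame, , , drop = FALSE]
  dim(kp_all) <- c(dim(scene$coords)[2], K, 2)
  dim(vis) <- c(dim(scene$coords)[2], K)

  for (k in seq_len(K)) {
    # nearest-keypoint distance field for this bodypart
    best_d2 <- matrix(Inf, nq, np)
    for (a in seq_len(nrow(vis))) {
      if (!vis[a, k]) next
      x <- kp_all[a, k, 1]
      y <- kp_all[a, k, 2]
      if (x < 0 || x > W || y < 0 || y > H || !is.finite(x) || !is.finite(y)) {
        warning(sprintf("keypoint outside image excluded (frame %d)", frame))
        next
      }
      d2 <- outer((cy - y)^2, (cx - x)^2, "+")
      hit <- d2 < cfg$target_radius^2
      upd <- hit & (d2 < best_d2)
      if (any(hit)) {
        sc <- score[, , k]; sc[hit] <- 1; score[, , k] <- sc
        lx <- matrix(x, nq, np) - matrix(cx, nq, np, byrow = TRUE)
        ly <- matrix(y, nq, np) - matrix(cy, nq, np)
        tmp <- locref[, , k, 1]; tmp[upd] <- lx[upd]; locref[, , k, 1] <- tmp
        tmp <- locref[, , k, 2]; tmp[upd] <- ly[upd]; locref[, , k, 2] <- tmp
        best_d2[upd] <- d2[upd]
      }
    }
  }

  if (L > 0) {
    gx <- matrix(cx, nq, np, byrow = TRUE)
    gy <- matrix(cy, nq, np)
    for (l in seq_len(L)) {
      accx <- matrix(0, nq, np)
      accy <- matrix(0, nq, np)
      cnt <- matrix(0L, nq, np)
      for (a in seq_len(nrow(vis))) {
        i <- edges[l, 1]; j <- edges[l, 2]
        if (!vis[a, i] || !vis[a, j]) next
        p1 <- kp_all[a, i, ]
        p2 <- kp_all[a, j, ]
        seg <- p2 - p1
        len <- sqrt(sum(seg^2))
        if (len < 1e-12) next
        u <- seg / len
        dx <- gx - p1[1]
        dy <- gy - p1[2]
        along <- dx * u[1] + dy * u[2]
        perp <- abs(dx * u[2] - dy * u[1])
        band <- along >= 0 & along <= len & perp <= cfg$pafwidth
        accx[band] <- accx[band] + u[1]
        accy[band] <- accy[band] + u[2]
        cnt[band] <- cnt[band] + 1L
      }
      nz <- cnt > 0L
      px <- matrix(0, nq, np); py <- matrix(0, nq, np)
      px[nz] <- accx[nz] / cnt[nz]
      py[nz] <- accy[nz] / cnt[nz]
      pafs[, , 2 * l - 1] <- px
      pafs[, , 2 * l] <- py
    }
  }

  list(score_maps = score, locref = locref, pafs = pafs,
       stride = lam, edges = edges)
}

#' Corrupt ground-truth keypoints into noisy detection tables
#'
#' Adds Gaussian position jitter, drops detections with probability
#' `dropout`, and injects uniform clutter detections (Poisson count per
#' frame, confidence drawn from U(0.1, 0.6) so confidence thresholds are
#' exercisable). The ground-truth animal of each true detection is retained
#' in the hidden `gt_animal` column for evaluation; clutter rows carry `NA`.
#'
#' @param scene a `gt_scene`.
#' @param config scene config (noise parameters); defaults to the scene's.
#' @param seed RNG seed; defaults to `config$seed + 1`.
#' @return data.frame with columns `frame`, `bodypart` (index), `x`, `y`,
#'   `confidence`, `gt_animal`.
#' @export
corrupt_detections <- function(scene, config = scene$config,
                               seed = config$seed + 1L) {
  cfg <- config
  with_seed(seed, {
    n_frames <- dim(scene$coords)[1]
    n_animals <- dim(scene$coords)[2]
    K <- dim(scene$coords)[3]
    rows <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      vis <- scene$visible[f, , , drop = FALSE]
      dim(vis) <- c(n_animals, K)
      idx <- which(vis, arr.ind = TRUE)
      out <- NULL
      if (nrow(idx) > 0) {
        keep <- stats::runif(nrow(idx)) >= cfg$dropout
        idx <- idx[keep, , drop = FALSE]
        if (nrow(idx) > 0) {
          xs <- scene$coords[cbind(f, idx[, 1], idx[, 2], 1)] +
            stats::rnorm(nrow(idx), 0, cfg$jitter_sd)
          ys <- scene$coords[cbind(f, idx[, 1], idx[, 2], 2)] +
            stats::rnorm(nrow(idx), 0, cfg$jitter_sd)
          out <- data.frame(
            frame = f, bodypart = idx[, 2],
            x = pmin(pmax(xs, 0), cfg$image_size[2] - 1e-6),
            y = pmin(pmax(ys, 0), cfg$image_size[1] - 1e-6),
            confidence = stats::runif(nrow(idx), 0.75, 1),
            gt_animal = idx[, 1]
          )
        }
      }
      n_clut <- if (cfg$clutter_rate > 0) stats::rpois(1, cfg$clutter_rate) else 0L
      if (n_clut > 0) {
        clut <- data.frame(
          frame = f,
          bodypart = sample.int(K, n_clut, replace = TRUE),
          x = stats::runif(n_clut, 0, cfg$image_size[2]),
          y = stats::runif(n_clut, 0, cfg$image_size[1]),
          confidence = stats::runif(n_clut, 0.1, 0.6),
          gt_animal = NA_integer_
        )
        out <- rbind(out, clut)
      }
      rows[[f]] <- out
    }
    det <- do.call(rbind, rows)
    if (is.null(det)) {
      det <- data.frame(frame = integer(), bodypart = integer(),
                        x = numeric(), y = numeric(),
                        confidence = numeric(), gt_animal = integer())
    }
    rownames(det) <- NULL
    det
  })
}

#' Sample keypoint-aware crop centres
#'
#' Each centre is drawn by one of two strategies: uniform over the image, or
#' density-proportional, where a labelled keypoint is picked with probability
#' proportional to one plus its number of neighbours within a radius equal to
#' 10% of the smallest image side. The centre is then shifted along both axes
#' by a uniform random amount no greater than 40% of the crop size.
#'
#' @param keypoints matrix of (x, y) keypoint positions (possibly empty).
#' @param image_size `c(H, W)`.
#' @param n number of centres.
#' @param crop_size crop side length in pixels.
#' @param seed RNG seed.
#' @param strategy "mixed" (choose per sample at random), "uniform" or
#'   "density". With no keypoints, density falls back to uniform.
#' @return n x 2 matrix of (x, y) centres.
#' @export
sample_crop_centers <- function(keypoints, image_size, n, crop_size,
                                seed = 1L,
                                strategy = c("mixed", "uniform", "density")) {
  strategy <- match.arg(strategy)
  stopifnot(n >= 1)
  H <- image_size[1]; W <- image_size[2]
  keypoints <- if (is.null(keypoints)) matrix(numeric(0), 0, 2) else
    matrix(as.numeric(keypoints), ncol = 2)
  with_seed(seed, {
    radius <- 0.1 * min(H, W)
    wts <- NULL
    if (nrow(keypoints) > 0) {
      d <- as.matrix(stats::dist(keypoints))
      wts <- 1 + rowSums(d <= radius) - 1 # neighbours exclude self
    }
    centres <- matrix(0, n, 2)
    for (i in seq_len(n)) {
      use_density <- switch(strategy,
        uniform = FALSE,
        density = TRUE,
        mixed = stats::runif(1) < 0.5
      )
      if (use_density && nrow(keypoints) > 0) {
        pick <- sample.int(nrow(keypoints), 1, prob = wts)
        ctr <- keypoints[pick, ]
      } else {
        ctr <- c(stats::runif(1, 0, W), stats::runif(1, 0, H))
      }
      shift <- stats::runif(2, -0.4, 0.4) * crop_size
      centres[i, ] <- ctr + shift
    }
    colnames(centres) <- c("x", "y")
    centres
  })
}
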