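#' Bounding box around an assembly's keypoints
#'
#' @param coords keypoint coordinate matrix (n x 2).
#' @param margin expansion margin in pixels (default 0).
#' @return numeric `c(xmin, ymin, xmax, ymax)`.
#' @export
bbox_from_keypoints <- function(coords, margin = 0) {
  stopifnot(nrow(coords) >= 1)
  c(min(coords[, 1]) - margin, min(coords[, 2]) - margin,
    max(coords[, 1]) + margin, max(coords[, 2]) + margin)
}

#' Intersection over union of two boxes
#'
#' @param b1,b2 boxes as `c(xmin, ymin, xmax, ymax)`.
#' @return IoU in [0, 1].
#' @export
iou <- function(b1, b2) {
  ix <- max(0, min(b1[3], b2[3]) - max(b1[1], b2[1]))
  iy <- max(0, min(b1[4], b2[4]) - max(b1[2], b2[2]))
  inter <- ix * iy
  a1 <- (b1[3] - b1[1]) * (b1[4] - b1[2])
  a2 <- (b2[3] - b2[1]) * (b2[4] - b2[2])
  denom <- a1 + a2 - inter
  if (denom <= 0) return(0)
  inter / denom
}

#' Fit a 2-sigma covariance error ellipse to keypoints
#'
#' Centre is the keypoint mean; semi-axes are twice the square roots of the
#' covariance eigenvalues; the inclination is the angle of the leading
#' eigenvector, mapped to (-pi/2, pi/2] (0 when the point cloud is isotropic).
#' With fewer than two distinct points, a fallback circle of
#' `min_radius` is returned.
#'
#' @param coords keypoint coordinate matrix (n x 2).
#' @param min_radius fallback circle radius (px).
#' @return list `(x, y, h, w, theta)` with `h >= w`.
#' @export
fit_ellipse <- function(coords, min_radius = 1) {
  coords <- coords[stats::complete.cases(coords), , drop = FALSE]
  distinct <- unique(round(coords, 9))
  if (nrow(distinct) < 2) {
    ctr <- if (nrow(coords) >= 1) colMeans(coords) else c(NA_real_, NA_real_)
    return(list(x = ctr[1], y = ctr[2], h = min_radius, w = min_radius,
                theta = 0))
  }
  ctr <- colMeans(coords)
  S <- stats::cov(coords)
  eig <- eigen(S, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  h <- 2 * sqrt(vals[1])
  w <- 2 * sqrt(vals[2])
  if (abs(vals[1] - vals[2]) < 1e-12) {
    theta <- 0 # isotropic: orientation undefined, tie rule
  } else {
    v <- eig$vectors[, 1]
    theta <- atan2(v[2], v[1])
    if (theta <= -pi / 2) theta <- theta + pi
    if (theta > pi / 2) theta <- theta - pi
  }
  list(x = ctr[1], y = ctr[2], h = h, w = w, theta = theta)
}

#' Similarity between two ellipses
#'
#' `c = 0.8 (1 - d) + 0.2 (1 - d) cos(theta_d - theta_p)` where `d` is the
#' centroid distance normalized by the longest semi-axis of the pair, clamped
#' to [0, 1] so that `c` stays in [0, 1]; the angle difference is wrapped to
#' (-pi/2, pi/2] (ellipse orientation has period pi).
#'
#' @param e1,e2 ellipses from [fit_ellipse()].
#' @return similarity in [0, 1].
#' @export
ellipse_similarity <- function(e1, e2) {
  maxax <- max(e1$h, e2$h)
  cd <- euclid(c(e1$x, e1$y), c(e2$x, e2$y))
  d <- if (maxax <= 0) {
    if (cd < 1e-12) 0 else 1
  } else {
    min(cd / maxax, 1)
  }
  dth <- e1$theta - e2$theta
  dth <- ((dth + pi / 2) %% pi) - pi / 2
  0.8 * (1 - d) + 0.2 * (1 - d) * cos(dth)
}

# --- Kalman filtering (constant velocity, SORT-style noise conventions) ---

kalman_matrices <- function(dim_obs) {
  n <- 2 * dim_obs
  F <- diag(n)
  F[cbind(seq_len(dim_obs), dim_obs + seq_len(dim_obs))] <- 1
  H <- cbind(diag(dim_obs), matrix(0, dim_obs, dim_obs))
  list(F = F, H = H)
}

#' Create a Kalman tracker state from a first observation
#'
#' All unobservable velocities are initialized to zero, with large initial
#' velocity uncertainty and modest process noise (SORT conventions).
#'
#' @param z first observation: box `c(x, y, A, r)` or ellipse
#'   `c(x, y, h, w, theta)`.
#' @param noise optional list overriding `P0`, `Q`, `R` diagonal vectors.
#' @return a `kalman_state` list.
#' @export
kalman_create <- function(z, noise = list()) {
  d <- length(z)
  mats <- kalman_matrices(d)
  P0 <- noise$P0 %||% c(rep(10, d), rep(1e4, d))
  Q <- noise$Q %||% c(rep(1, d), rep(0.01, d))
  R <- noise$R %||% c(rep(1, 2), rep(10, d - 2))
  structure(list(
    x = c(z, rep(0, d)), P = diag(P0, 2 * d),
    F = mats$F, H = mats$H,
    Q = diag(Q, 2 * d), R = diag(R, d), d = d
  ), class = "kalman_state")
}

#' One Kalman predict/update step
#'
#' Constant-velocity prediction followed by a linear update when an
#' observation is supplied; non-finite observations are rejected
#' (predict-only).
#'
#' @param kf a `kalman_state`.
#' @param z observation vector or `NULL`.
#' @return the updated `kalman_state`, with `$predicted` holding the
#'   predicted observation (before update).
#' @export
kalman_step <- function(kf, z = NULL) {
  kf$x <- as.numeric(kf$F %*% kf$x)
  kf$P <- kf$F %*% kf$P %*% t(kf$F) + kf$Q
  kf$predicted <- as.numeric(kf$H %*% kf$x)
  if (!is.null(z) && all(is.finite(z))) {
    if (kf$d == 5) {
      # ellipse state: unwrap observed theta towards the predicted one
      z[5] <- kf$predicted[5] +
        (((z[5] - kf$predicted[5] + pi / 2) %% pi) - pi / 2)
    }
    y <- z - kf$predicted
    S <- kf$H %*% kf$P %*% t(kf$H) + kf$R
    K <- kf$P %*% t(kf$H) %*% solve(S)
    kf$x <- kf$x + as.numeric(K %*% y)
    kf$P <- (diag(2 * kf$d) - K %*% kf$H) %*% kf$P
  }
  kf
}

obs_box <- function(coords, margin = 0) {
  b <- bbox_from_keypoints(coords, margin)
  w <- max(b[3] - b[1], 1e-6)
  h <- max(b[4] - b[2], 1e-6)
  c((b[1] + b[3]) / 2, (b[2] + b[4]) / 2, w * h, w / h)
}

box_from_obs <- function(z) {
  w <- sqrt(max(z[3], 1e-12) * max(z[4], 1e-12))
  h <- max(z[3], 1e-12) / w
  c(z[1] - w / 2, z[2] - h / 2, z[1] + w / 2, z[2] + h / 2)
}

obs_ellipse <- function(coords, min_radius = 1) {
  e <- fit_ellipse(coords, min_radius)
  c(e$x, e$y, e$h, e$w, e$theta)
}

ellipse_from_obs <- function(z) {
  list(x = z[1], y = z[2], h = max(z[3], 1e-6), w = max(min(z[4], z[3]), 0),
       theta = z[5])
}

#' Associate trackers with assemblies
#'
#' One-to-one maximum-similarity matching (Hungarian on `1 - similarity`);
#' matches whose similarity falls below the threshold are dissolved into
#' unmatched.
#'
#' @param sim similarity matrix (trackers x assemblies) in [0, 1].
#' @param threshold minimum similarity for a valid match.
#' @return list with `matches` (two-column matrix tracker/assembly),
#'   `unmatched_trackers`, `unmatched_assemblies`.
#' @export
associate <- function(sim, threshold = 0.6) {
  nt <- nrow(sim)
  na <- ncol(sim)
  if (nt == 0 || na == 0) {
    return(list(matches = matrix(integer(0), 0, 2),
                unmatched_trackers = seq_len(nt),
                unmatched_assemblies = seq_len(na)))
  }
  sel <- solve_assignment(1 - sim)
  m <- cbind(seq_len(nt), sel)
  m <- m[!is.na(sel), , drop = FALSE]
  ok <- sim[m] >= threshold
  m <- m[ok, , drop = FALSE]
  list(matches = m,
       unmatched_trackers = setdiff(seq_len(nt), m[, 1]),
       unmatched_assemblies = setdiff(seq_len(na), m[, 2]))
}

# identity agreement between a tracker's accumulated vote profile and an
# assembly's soft vote (mean probability overlap).
id_agreement <- function(tracker_profile, assembly_probs) {
  if (is.null(tracker_profile) || is.null(assembly_probs)) return(NA_real_)
  sum(tracker_profile * assembly_probs) /
    max(sqrt(sum(tracker_profile^2)) * sqrt(sum(assembly_probs^2)), 1e-12)
}

#' Track assemblies across frames into tracklets
#'
#' SORT-style tracking-by-detection: per frame, Kalman predict, Hungarian
#' association with IoU (box tracker) or ellipse similarity (ellipse
#' tracker), then update matched trackers, create trackers for unmatched
#' assemblies (velocities zero) and terminate trackers undetected for
#' `max_age` consecutive frames. Runs shorter than `min_hits` consecutive
#' matched frames are discarded. Output tracklets contain observed frames
#' only, split into temporally contiguous runs.
#'
#' @param frames list of per-frame assembly lists; element `f` is a list of
#'   assemblies (each with `coords` and optionally `id_probs`). Frame numbers
#'   are taken from `names(frames)` when present.
#' @param method "ellipse" or "box".
#' @param min_hits minimum consecutive matched frames (default 1).
#' @param max_age consecutive undetected frames before termination (default
#'   1: any miss terminates).
#' @param iou_threshold minimum similarity for a valid association.
#' @param margin box expansion margin (box tracker).
#' @param id_weight blending weight in [0, 1) for identity-vote agreement in
#'   the similarity (0 = off; requires per-assembly `id_probs`).
#' @param noise optional Kalman noise overrides (see [kalman_create()]).
#' @return list of `tracklet` objects: `id`, `frames`, `assemblies`,
#'   `centroids` (matrix), `start`, `end`.
#' @export
track_video <- function(frames, method = c("ellipse", "box"),
                        min_hits = 1L, max_age = 1L, iou_threshold = 0.6,
                        margin = 0, id_weight = 0, noise = list()) {
  method <- match.arg(method)
  stopifnot(min_hits >= 1, max_age >= 1)
  frame_ids <- if (!is.null(names(frames))) as.integer(names(frames)) else
    seq_along(frames)
  observe <- if (method == "box") {
    function(coords) obs_box(coords, margin)
  } else {
    obs_ellipse
  }
  similarity <- if (method == "box") {
    function(zp, zo) iou(box_from_obs(zp), box_from_obs(zo))
  } else {
    function(zp, zo) ellipse_similarity(ellipse_from_obs(zp),
                                        ellipse_from_obs(zo))
  }
  trackers <- list()
  finished <- list()
  for (fi in seq_along(frames)) {
    f <- frame_ids[fi]
    assemblies <- frames[[fi]]
    zs <- lapply(assemblies, function(a) observe(a$coords))
    # predict
    for (ti in seq_along(trackers)) {
      trackers[[ti]]$kf <- kalman_step(trackers[[ti]]$kf, NULL)
    }
    sim <- matrix(0, length(trackers), length(assemblies))
    if (length(trackers) && length(assemblies)) {
      for (ti in seq_along(trackers)) {
        zp <- trackers[[ti]]$kf$predicted
        for (ai in seq_along(assemblies)) {
          s <- similarity(zp, zs[[ai]])
          if (id_weight > 0 && !is.null(assemblies[[ai]]$id_probs)) {
            agr <- id_agreement(trackers[[ti]]$id_profile,
                                assemblies[[ai]]$id_probs)
            if (!is.na(agr)) s <- (1 - id_weight) * s + id_weight * agr
          }
          sim[ti, ai] <- s
        }
      }
    }
    asc <- associate(sim, iou_threshold)
    if (nrow(asc$matches)) {
      for (r in seq_len(nrow(asc$matches))) {
        ti <- asc$matches[r, 1]
        ai <- asc$matches[r, 2]
        tr <- trackers[[ti]]
        tr$kf <- kalman_step_update_only(tr$kf, zs[[ai]])
        tr$frames <- c(tr$frames, f)
        tr$assemblies <- c(tr$assemblies, assemblies[ai])
        tr$streak <- tr$streak + 1L
        tr$max_streak <- max(tr$max_streak, tr$streak)
        tr$tsu <- 0L
        if (!is.null(assemblies[[ai]]$id_probs)) {
          n <- length(tr$frames)
          tr$id_profile <- if (is.null(tr$id_profile)) {
            assemblies[[ai]]$id_probs
          } else {
            ((n - 1) * tr$id_profile + assemblies[[ai]]$id_probs) / n
          }
        }
        trackers[[ti]] <- tr
      }
    }
    for (ti in asc$unmatched_trackers) {
      trackers[[ti]]$tsu <- trackers[[ti]]$tsu + 1L
      trackers[[ti]]$streak <- 0L
    }
    for (ai in asc$unmatched_assemblies) {
      trackers[[length(trackers) + 1]] <- list(
        kf = kalman_create(zs[[ai]], noise),
        frames = f, assemblies = assemblies[ai],
        streak = 1L, max_streak = 1L, tsu = 0L,
        id_profile = assemblies[[ai]]$id_probs
      )
    }
    dead <- vapply(trackers, function(tr) tr$tsu >= max_age, logical(1))
    finished <- c(finished, trackers[dead])
    trackers <- trackers[!dead]
  }
  finished <- c(finished, trackers)
  emit_tracklets(finished, min_hits)
}

# update-only step (prediction already applied this frame)
kalman_step_update_only <- function(kf, z) {
  if (kf$d == 5) {
    z[5] <- kf$predicted[5] +
      (((z[5] - kf$predicted[5] + pi / 2) %% pi) - pi / 2)
  }
  y <- z - as.numeric(kf$H %*% kf$x)
  S <- kf$H %*% kf$P %*% t(kf$H) + kf$R
  K <- kf$P %*% t(kf$H) %*% solve(S)
  kf$x <- kf$x + as.numeric(K %*% y)
  kf$P <- (diag(2 * kf$d) - K %*% kf$H) %*% kf$P
  kf
}

emit_tracklets <- function(trackers, min_hits) {
  out <- list()
  for (tr in trackers) {
    if (length(tr$frames) == 0) next
    # split observed frames into contiguous runs
    runs <- cumsum(c(1L, diff(tr$frames) != 1L))
    for (rg in split(seq_along(tr$frames), runs)) {
      if (length(rg) < min_hits) next
      out[[length(out) + 1]] <- new_tracklet(
        id = length(out) + 1L,
        frames = tr$frames[rg],
        assemblies = tr$assemblies[rg]
      )
    }
  }
  out
}

#' Construct a tracklet
#'
#' @param id tracklet identifier.
#' @param frames strictly increasing, contiguous frame indices.
#' @param assemblies list of assemblies (one per frame, each with `coords`).
#' @return a `tracklet` with precomputed `centroids`.
#' @export
new_tracklet <- function(id, frames, assemblies) {
  id <- as.integer(id)
  frames <- as.integer(frames)
  stopifnot(length(frames) == length(assemblies),
            all(diff(frames) >= 1))
  centroids <- t(vapply(assemblies, function(a) {
    colMeans(a$coords[stats::complete.cases(a$coords), , drop = FALSE])
  }, numeric(2)))
  structure(list(id = id, frames = frames, assemblies = assemblies,
                 centroids = centroids,
                 start = frames[1], end = frames[length(frames)]),
            class = "tracklet")
}

#' Slice a tracklet to a subset of its observed frames
#'
#' @param t a `tracklet`.
#' @param idx indices into `t$frames` (must stay contiguous).
#' @return the sliced `tracklet`.
#' @export
tl_slice <- function(t, idx) {
  new_tracklet(t$id, t$frames[idx], t$assemblies[idx])
}

#' @export
print.tracklet <- function(x, ...) {
  cat(sprintf("tracklet %d: frames %d-%d (%d observed)\n",
              x$id, x$start, x$end, length(x$frames)))
  invisible(x)
}
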