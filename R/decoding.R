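#' Smooth score maps with a Gaussian kernel
#'
#' Per-channel 2D Gaussian convolution (separable, kernel truncated at four
#' sigma, border-renormalized so flat maps stay flat). `sigma = 0` is the
#' identity. The default spread of 1 grid cell makes peaks more salient
#' before non-maximum suppression.
#'
#' @param score_maps `nq x np x K` array.
#' @param sigma Gaussian spread in grid cells (>= 0).
#' @return array of the same shape.
#' @export
smooth_scoremaps <- function(score_maps, sigma = 1) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(score_maps)
  out <- score_maps
  for (k in seq_len(dim(score_maps)[3])) {
    out[, , k] <- gauss_smooth2d(score_maps[, , k], sigma)
  }
  out
}

#' Find score-map peaks by non-maximum suppression
#'
#' A grid cell is a peak when its value equals the maximum of its
#' `(2 * nms_radius + 1)^2` window and exceeds `min_confidence`. Plateaus of
#' equal values within a window keep a single representative: the cell with
#' the lowest `(p, q)` order (p = x cell, then q).
#'
#' @param score_maps `nq x np x K` array.
#' @param min_confidence detection threshold in (0, 1).
#' @param nms_radius window radius in grid cells.
#' @return data.frame with columns `bodypart`, `p`, `q` (0-based grid cell)
#'   and `value`.
#' @export
find_peaks <- function(score_maps, min_confidence = 0.01, nms_radius = 2L) {
  stopifnot(min_confidence > 0, min_confidence < 1, nms_radius >= 1)
  nq <- dim(score_maps)[1]
  np <- dim(score_maps)[2]
  K <- dim(score_maps)[3]
  res <- vector("list", K)
  for (k in seq_len(K)) {
    M <- score_maps[, , k]
    wmax <- window_max(M, nms_radius)
    cand <- which(M >= wmax - 1e-12 & M > min_confidence, arr.ind = TRUE)
    if (nrow(cand) == 0) next
    # plateau tie-break: drop a candidate if an equal-valued candidate with
    # lower (p, then q) order lies within its window
    p0 <- cand[, 2] - 1L
    q0 <- cand[, 1] - 1L
    ord <- p0 * nq + q0
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      near <- abs(p0 - p0[i]) <= nms_radius & abs(q0 - q0[i]) <= nms_radius
      tied <- near & abs(M[cand] - M[cand[i, , drop = FALSE]]) < 1e-12
      keep[i] <- ord[i] == min(ord[tied])
    }
    cand <- cand[keep, , drop = FALSE]
    res[[k]] <- data.frame(
      bodypart = k, p = cand[, 2] - 1L, q = cand[, 1] - 1L,
      value = M[cand]
    )
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(bodypart = integer(), p = integer(), q = integer(),
                      value = numeric())
  }
  rownames(out) <- NULL
  out
}

# Max filter with a (2r+1)^2 window (separable shift-max), replicate border.
window_max <- function(M, r) {
  shift_max_rows <- function(X, r) {
    n <- nrow(X)
    out <- X
    for (s in seq_len(r)) {
      up <- X[pmin(seq_len(n) + s, n), , drop = FALSE]
      dn <- X[pmax(seq_len(n) - s, 1), , drop = FALSE]
      out <- pmax(out, up, dn)
    }
    out
  }
  t(shift_max_rows(t(shift_max_rows(M, r)), r))
}

#' Refine peak cells to subpixel keypoint detections
#'
#' Applies the decoding rule `x = p * stride + stride / 2 + Lx(p, q)` (and
#' likewise for y), the exact inverse of target rendering.
#'
#' @param peaks data.frame from [find_peaks()].
#' @param locref `nq x np x K x 2` location refinement array.
#' @param stride overall stride (lambda).
#' @return data.frame of keypoint detections: `bodypart`, `x`, `y`,
#'   `confidence`, `p`, `q`.
#' @export
refine_locations <- function(peaks, locref, stride) {
  if (nrow(peaks) == 0) {
    return(data.frame(bodypart = integer(), x = numeric(), y = numeric(),
                      confidence = numeric(), p = integer(), q = integer()))
  }
  lx <- locref[cbind(peaks$q + 1L, peaks$p + 1L, peaks$bodypart, 1L)]
  ly <- locref[cbind(peaks$q + 1L, peaks$p + 1L, peaks$bodypart, 2L)]
  data.frame(
    bodypart = peaks$bodypart,
    x = peaks$p * stride + stride / 2 + lx,
    y = peaks$q * stride + stride / 2 + ly,
    confidence = peaks$value,
    p = peaks$p, q = peaks$q
  )
}

#' Decode target tensors into keypoint detections
#'
#' Convenience wrapper: smooth, find peaks, refine locations.
#'
#' @param targets list with `score_maps`, `locref`, `stride` (as returned by
#'   [render_targets()]).
#' @param sigma smoothing spread (grid cells).
#' @param min_confidence,nms_radius peak detection parameters.
#' @return detection data.frame (see [refine_locations()]).
#' @export
decode_detections <- function(targets, sigma = 1, min_confidence = 0.01,
                              nms_radius = 2L) {
  sm <- smooth_scoremaps(targets$score_maps, sigma)
  peaks <- find_peaks(sm, min_confidence, nms_radius)
  refine_locations(peaks, targets$locref, targets$stride)
}

#' Part affinity cost along the line between two detections
#'
#' Samples `n_samples` equally spaced points (endpoints included) on the
#' segment between two keypoint proposals, reads the PAF at the enclosing
#' grid cell (nearest-cell lookup), and averages. `method = "projection"`
#' (default) projects the field onto the unit vector from `a` to `b`, which
#' yields direction-discriminative costs in [-1, 1]; `method = "norm"`
#' averages the field magnitude.
#'
#' @param pafs `nq x np x 2L` PAF array.
#' @param edge_index edge (limb) index l; channels `2l-1, 2l` are used.
#' @param a,b numeric (x, y) positions of the two proposals.
#' @param stride overall stride.
#' @param n_samples number of sample points (>= 2, or a zero-length segment).
#' @param method "projection" or "norm".
#' @return scalar affinity cost.
#' @export
paf_line_cost <- function(pafs, edge_index, a, b, stride, n_samples = 10L,
                          method = c("projection", "norm")) {
  method <- match.arg(method)
  nq <- dim(pafs)[1]
  np <- dim(pafs)[2]
  seg <- b - a
  len <- sqrt(sum(seg^2))
  if (len < 1e-12) {
    # degenerate: field magnitude at the single point
    p0 <- min(max(floor(a[1] / stride), 0), np - 1)
    q0 <- min(max(floor(a[2] / stride), 0), nq - 1)
    v <- c(pafs[q0 + 1, p0 + 1, 2 * edge_index - 1],
           pafs[q0 + 1, p0 + 1, 2 * edge_index])
    return(sqrt(sum(v^2)))
  }
  stopifnot(n_samples >= 2)
  t <- seq(0, 1, length.out = n_samples)
  xs <- a[1] + t * seg[1]
  ys <- a[2] + t * seg[2]
  p0 <- pmin(pmax(floor(xs / stride), 0), np - 1)
  q0 <- pmin(pmax(floor(ys / stride), 0), nq - 1)
  vx <- pafs[cbind(q0 + 1, p0 + 1, 2 * edge_index - 1)]
  vy <- pafs[cbind(q0 + 1, p0 + 1, 2 * edge_index)]
  if (method == "projection") {
    u <- seg / len
    mean(vx * u[1] + vy * u[2])
  } else {
    mean(sqrt(vx^2 + vy^2))
  }
}

#' Build per-edge affinity cost tables
#'
#' For every edge of the part affinity graph, computes the dense table of
#' [paf_line_cost()] values over all cross pairs of proposals of the two
#' endpoint bodyparts.
#'
#' @param detections detection data.frame (needs `bodypart`, `x`, `y`).
#' @param pafs PAF array whose channel pair `2l-1, 2l` corresponds to edge
#'   `l` of `paf_edges`.
#' @param graph a part affinity graph (list with an `edges` matrix) or an
#'   edges matrix.
#' @param stride overall stride.
#' @param n_samples,method passed to [paf_line_cost()].
#' @param paf_edges the edge list the PAF channels were rendered for;
#'   defaults to `graph` itself. Graph edges are matched to channels by
#'   bodypart pair, so `graph` may be any subset or reordering of
#'   `paf_edges`.
#' @return list of per-edge tables: `edge` (bodypart pair), `det_i`, `det_j`
#'   (row indices into `detections`), `cost` (matrix `length(det_i) x
#'   length(det_j)`).
#' @export
build_affinity_tables <- function(detections, pafs, graph, stride,
                                  n_samples = 10L,
                                  method = c("projection", "norm"),
                                  paf_edges = NULL) {
  method <- match.arg(method)
  get_edges <- function(g) {
    e <- if (is.list(g) && !is.null(g$edges)) g$edges else g
    matrix(as.integer(e), ncol = 2)
  }
  edges <- get_edges(graph)
  pedges <- if (is.null(paf_edges)) edges else get_edges(paf_edges)
  chan <- match(edge_key(edges), edge_key(pedges))
  if (anyNA(chan)) {
    stop("graph edge without a rendered PAF channel", call. = FALSE)
  }
  if (2 * max(chan, 0) > dim(pafs)[3]) {
    stop("PAF array has fewer channels than edges", call. = FALSE)
  }
  tables <- vector("list", nrow(edges))
  for (l in seq_len(nrow(edges))) {
    di <- which(detections$bodypart == edges[l, 1])
    dj <- which(detections$bodypart == edges[l, 2])
    cost <- matrix(numeric(0), length(di), length(dj))
    if (length(di) > 0 && length(dj) > 0) {
      cost <- matrix(0, length(di), length(dj))
      for (ii in seq_along(di)) {
        a <- c(detections$x[di[ii]], detections$y[di[ii]])
        for (jj in seq_along(dj)) {
          b <- c(detections$x[dj[jj]], detections$y[dj[jj]])
          cost[ii, jj] <- paf_line_cost(pafs, chan[l], a, b, stride,
                                        n_samples, method)
        }
      }
    }
    tables[[l]] <- list(edge = edges[l, ], paf_index = chan[l],
                        det_i = di, det_j = dj, cost = cost)
  }
  tables
}
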