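# Independent oracles used to cross-check the package's algorithms.
# These deliberately use different algorithmic routes (enumeration,
# union-find, explicit loops) from the implementations they verify.

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1]] <- append(p, n, after = pos)
    }
  }
  out
}

# brute-force maximum-gain one-to-one matching of a gain matrix
# (rows to columns, unmatched allowed, gain 0 for unmatched)
oracle_max_matching <- function(gain) {
  n <- nrow(gain)
  m <- ncol(gain)
  k <- max(n, m)
  G <- matrix(0, k, k)
  G[seq_len(n), seq_len(m)] <- gain
  best <- -Inf
  for (p in all_perms(k)) {
    tot <- sum(G[cbind(seq_len(k), p)])
    if (tot > best) best <- tot
  }
  best
}

# brute-force minimum-cost complete assignment of a square cost matrix
oracle_min_assignment <- function(cost) {
  n <- nrow(cost)
  best <- Inf
  for (p in all_perms(n)) {
    tot <- sum(cost[cbind(seq_len(n), p)])
    if (tot < best) best <- tot
  }
  best
}

# union-find connected components over detection pairs
oracle_components <- function(pairs) {
  verts <- sort(unique(c(pairs$i, pairs$j)))
  parent <- stats::setNames(verts, verts)
  find <- function(x) {
    while (parent[as.character(x)] != x) x <- parent[as.character(x)]
    x
  }
  for (r in seq_len(nrow(pairs))) {
    ri <- find(pairs$i[r])
    rj <- find(pairs$j[r])
    if (ri != rj) parent[as.character(ri)] <- rj
  }
  roots <- vapply(verts, find, numeric(1))
  unname(lapply(split(verts, roots), sort))
}

# O(n^2) pairwise-comparison auROC from raw samples
oracle_auroc <- function(within, between) {
  wins <- 0
  for (w in within) {
    wins <- wins + sum(w > between) + 0.5 * sum(w == between)
  }
  wins / (length(within) * length(between))
}

# exhaustive maximum-weight spanning tree by subset enumeration
oracle_mst_weight <- function(edges, weights, n) {
  idx <- utils::combn(nrow(edges), n - 1)
  connected <- function(rows) {
    adj <- lapply(seq_len(n), function(i) integer(0))
    for (r in rows) {
      adj[[edges[r, 1]]] <- c(adj[[edges[r, 1]]], edges[r, 2])
      adj[[edges[r, 2]]] <- c(adj[[edges[r, 2]]], edges[r, 1])
    }
    seen <- logical(n)
    stack <- 1L
    seen[1] <- TRUE
    while (length(stack)) {
      v <- stack[1]
      stack <- stack[-1]
      for (u in adj[[v]]) {
        if (!seen[u]) {
          seen[u] <- TRUE
          stack <- c(stack, u)
        }
      }
    }
    all(seen)
  }
  best <- -Inf
  for (ci in seq_len(ncol(idx))) {
    rows <- idx[, ci]
    if (connected(rows)) best <- max(best, sum(weights[rows]))
  }
  best
}

# brute-force minimum-cost cover of a DAG by exactly k node-disjoint paths:
# choose n - k edges forming a successor matching (in/out degree <= 1)
oracle_path_cover <- function(n, edges, k) {
  m <- nrow(edges)
  need <- n - k
  if (need == 0) return(0)
  if (m < need) return(NA_real_)
  best <- Inf
  combos <- utils::combn(m, need)
  for (ci in seq_len(ncol(combos))) {
    rows <- combos[, ci]
    if (anyDuplicated(edges$from[rows]) || anyDuplicated(edges$to[rows])) {
      next
    }
    best <- min(best, sum(edges$w[rows]))
  }
  if (is.infinite(best)) NA_real_ else best
}

# Independent CLEAR-MOT reference: explicit per-frame loops, brute-force
# (permutation) minimal-distance matching of the leftovers after persistence.
oracle_clearmot <- function(tracks, gt_tracks, threshold) {
  frames <- sort(unique(gt_tracks$frame))
  gt_ids <- unique(gt_tracks$id)
  M <- list() # gt id (character) -> hyp id
  misses <- 0L
  fps <- 0L
  switches <- 0L
  total <- 0L
  for (f in frames) {
    g <- gt_tracks[gt_tracks$frame == f, , drop = FALSE]
    h <- tracks[tracks$frame == f, , drop = FALSE]
    total <- total + nrow(g)
    pair <- rep(NA, nrow(g))
    used <- rep(FALSE, nrow(h))
    for (r in seq_len(nrow(g))) {
      prev <- M[[as.character(g$id[r])]]
      if (!is.null(prev)) {
        hi <- which(h$id == prev & !used)
        if (length(hi) == 1 &&
            sqrt((g$x[r] - h$x[hi])^2 + (g$y[r] - h$y[hi])^2) <= threshold) {
          pair[r] <- prev
          used[hi] <- TRUE
        }
      }
    }
    gr <- which(is.na(pair))
    hr <- which(!used)
    if (length(gr) && length(hr)) {
      # brute force over all injections of the smaller side
      ng <- length(gr)
      nh <- length(hr)
      D <- matrix(Inf, ng, nh)
      for (a in seq_len(ng)) {
        for (b in seq_len(nh)) {
          dd <- sqrt((g$x[gr[a]] - h$x[hr[b]])^2 +
                     (g$y[gr[a]] - h$y[hr[b]])^2)
          if (dd <= threshold) D[a, b] <- dd
        }
      }
      kk <- max(ng, nh)
      DD <- matrix(0, kk, kk)
      DD[seq_len(ng), seq_len(nh)] <- ifelse(is.finite(D), D, 1e7)
      bestp <- NULL
      bestc <- Inf
      for (p in all_perms(kk)) {
        tot <- sum(DD[cbind(seq_len(kk), p)])
        if (tot < bestc) {
          bestc <- tot
          bestp <- p
        }
      }
      for (a in seq_len(ng)) {
        b <- bestp[a]
        if (b <= nh && is.finite(D[a, b])) {
          pair[gr[a]] <- h$id[hr[b]]
          used[hr[b]] <- TRUE
        }
      }
    }
    for (r in seq_len(nrow(g))) {
      key <- as.character(g$id[r])
      if (is.na(pair[r])) {
        misses <- misses + 1L
      } else {
        if (!is.null(M[[key]]) && M[[key]] != pair[r]) {
          switches <- switches + 1L
        }
        M[[key]] <- pair[r]
      }
    }
    fps <- fps + sum(!used)
  }
  list(mota = 1 - (misses + fps + switches) / total,
       misses = misses, false_positives = fps, switches = switches)
}

# exhaustive best partition of per-bodypart detections into animal slots,
# maximizing total within-group affinity over all graph edges
oracle_best_partition <- function(detections, tables, n_slots) {
  bps <- sort(unique(detections$bodypart))
  # detections per bodypart, padded with NA slots
  slots <- lapply(bps, function(b) {
    ids <- which(detections$bodypart == b)
    length(ids) <- n_slots # pad with NA
    ids
  })
  perms <- all_perms(n_slots)
  np <- length(perms)
  combo_idx <- do.call(expand.grid, rep(list(seq_len(np)), length(bps)))
  total <- numeric(nrow(combo_idx))
  for (tab in tables) {
    bi <- match(tab$edge[1], bps)
    bj <- match(tab$edge[2], bps)
    # contribution matrix over (perm of bi, perm of bj)
    C <- matrix(0, np, np)
    for (a in seq_len(np)) {
      for (b in seq_len(np)) {
        s <- 0
        for (slot in seq_len(n_slots)) {
          di <- slots[[bi]][perms[[a]][slot]]
          dj <- slots[[bj]][perms[[b]][slot]]
          if (!is.na(di) && !is.na(dj)) {
            ii <- match(di, tab$det_i)
            jj <- match(dj, tab$det_j)
            s <- s + tab$cost[ii, jj]
          }
        }
        C[a, b] <- s
      }
    }
    total <- total + C[cbind(combo_idx[[bi]], combo_idx[[bj]])]
  }
  best <- which.max(total)
  assignment <- integer(nrow(detections))
  for (bidx in seq_along(bps)) {
    perm <- perms[[combo_idx[best, bidx]]]
    for (slot in seq_len(n_slots)) {
      det <- slots[[bidx]][perm[slot]]
      if (!is.na(det)) assignment[det] <- slot
    }
  }
  list(assignment = assignment, total = max(total))
}

# canonical form of a partition given per-detection group labels
canonical_partition <- function(labels) {
  groups <- split(seq_along(labels), labels)
  groups <- lapply(groups, sort)
  groups <- groups[order(vapply(groups, `[`, integer(1), 1))]
  unname(groups)
}

# partition labels from assemble_frame output (singletons = own group)
assembly_labels <- function(res, n_detections) {
  lab <- rep(NA_integer_, n_detections)
  for (ai in seq_along(res$assemblies)) {
    lab[res$assemblies[[ai]]$members] <- ai
  }
  nxt <- length(res$assemblies)
  for (d in which(is.na(lab))) {
    nxt <- nxt + 1L
    lab[d] <- nxt
  }
  lab
}
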