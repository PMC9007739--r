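#' @keywords internal
"_PACKAGE"

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (!is.null(old)) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

#' Solve the linear sum assignment problem
#'
#' Minimum-cost one-to-one assignment of rows to columns (Kuhn-Munkres with
#' dual potentials, O(n^3)). Rectangular matrices are padded internally; a
#' padded (dummy) partner means the row/column is left unassigned.
#'
#' @param cost numeric matrix of assignment costs; `Inf` forbids a pairing.
#' @return integer vector of length `nrow(cost)`: for each row the assigned
#'   column index, or `NA` if the row is unassigned (rectangular case or
#'   forbidden everywhere).
#' @export
solve_assignment <- function(cost) {
  if (!is.matrix(cost)) cost <- as.matrix(cost)
  n <- nrow(cost)
  m <- ncol(cost)
  if (n == 0L || m == 0L) return(rep(NA_integer_, n))
  k <- max(n, m)
  finite <- cost[is.finite(cost)]
  big <- if (length(finite)) sum(abs(finite)) + max(abs(finite)) + 1 else 1
  a <- matrix(0, k, k)
  a[seq_len(n), seq_len(m)] <- 0
  a[seq_len(n), seq_len(m)] <- ifelse(is.finite(cost), cost, big)
  # rows/cols beyond the real matrix cost 0 (dummy partners)

  INF <- .Machine$double.xmax / 4
  # e-maxx Hungarian; arrays indexed 1..k+1 where slot 1 is the virtual col 0
  u <- numeric(k + 1)
  v <- numeric(k + 1)
  p <- integer(k + 1) # p[j+1] = row matched to column j (0 = none)
  way <- integer(k + 1)
  for (i in seq_len(k)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(INF, k + 1)
    used <- rep(FALSE, k + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- INF
      j1 <- 0L
      for (j in seq_len(k)) {
        if (!used[j + 1]) {
          cur <- a[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) {
            minv[j + 1] <- cur
            way[j + 1] <- j0
          }
          if (minv[j + 1] < delta) {
            delta <- minv[j + 1]
            j1 <- j
          }
        }
      }
      for (j in 0:k) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign_row <- rep(NA_integer_, n)
  for (j in seq_len(k)) {
    r <- p[j + 1]
    if (r >= 1 && r <= n && j <= m) {
      if (is.finite(cost[r, j])) assign_row[r] <- j
    }
  }
  assign_row
}

# 1D Gaussian convolution band matrix (truncated at 4 sigma, renormalized
# at the borders so constant signals stay constant).
gauss_band <- function(n, sigma) {
  h <- max(1L, ceiling(4 * sigma))
  g <- stats::dnorm(-h:h, sd = sigma)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- max(1, i - h):min(n, i + h)
    A[i, j] <- g[j - i + h + 1]
  }
  sweep(A, 1, rowSums(A), "/")
}

# Gaussian smooth a matrix (separable), identity for sigma = 0.
gauss_smooth2d <- function(M, sigma) {
  if (sigma <= 0) return(M)
  Ar <- gauss_band(nrow(M), sigma)
  Ac <- gauss_band(ncol(M), sigma)
  Ar %*% M %*% t(Ac)
}

euclid <- function(a, b) sqrt(sum((a - b)^2))

`%||%` <- function(a, b) if (is.null(a)) b else a
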