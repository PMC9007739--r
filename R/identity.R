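#' Soft-vote an assembly's identity from per-keypoint probabilities
#'
#' Body parts act as individual classifiers: the assembly label is the argmax
#' of the mean identity probability vector over its members (ties broken by
#' individual order), with the mean probability as confidence.
#'
#' @param id_probs matrix of identity probabilities (members x individuals);
#'   rows with all-NA are ignored.
#' @return list with `label` (column index, `NA` if no scores) and
#'   `confidence`.
#' @export
soft_vote <- function(id_probs) {
  if (is.null(id_probs) || length(id_probs) == 0) {
    return(list(label = NA_integer_, confidence = 0))
  }
  id_probs <- matrix(id_probs, ncol = NCOL(id_probs))
  ok <- rowSums(!is.na(id_probs)) > 0
  if (!any(ok)) return(list(label = NA_integer_, confidence = 0))
  mp <- colMeans(id_probs[ok, , drop = FALSE], na.rm = TRUE)
  lab <- which.max(mp) # first maximum: deterministic order tie-break
  list(label = as.integer(lab), confidence = unname(mp[lab]))
}

#' Cosine similarity between two embedding vectors
#'
#' @param e1,e2 numeric vectors of equal length and nonzero norm.
#' @return cosine similarity in [-1, 1].
#' @export
tracklet_cosine <- function(e1, e2) {
  stopifnot(length(e1) == length(e2))
  n1 <- sqrt(sum(e1^2))
  n2 <- sqrt(sum(e2^2))
  if (n1 == 0 || n2 == 0) stop("zero embedding vector", call. = FALSE)
  sum(e1 * e2) / (n1 * n2)
}

#' Triplet accuracy of appearance embeddings
#'
#' Fraction of (anchor, positive, negative) triplets for which the anchor is
#' closer (by cosine similarity) to the positive than to the negative; ties
#' count as failures.
#'
#' @param embeddings matrix, one embedding per row.
#' @param triplets integer matrix (n x 3) of row indices
#'   (anchor, positive, negative).
#' @return fraction in [0, 1].
#' @export
triplet_accuracy <- function(embeddings, triplets) {
  triplets <- matrix(as.integer(triplets), ncol = 3)
  if (nrow(triplets) == 0) return(NA_real_)
  hits <- vapply(seq_len(nrow(triplets)), function(r) {
    a <- embeddings[triplets[r, 1], ]
    p <- embeddings[triplets[r, 2], ]
    n <- embeddings[triplets[r, 3], ]
    tracklet_cosine(a, p) > tracklet_cosine(a, n)
  }, logical(1))
  mean(hits)
}
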