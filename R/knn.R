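#' Exact Euclidean nearest-neighbor index
#'
#' A brute-force exact index over a representation matrix.  Neighbors are
#' returned by ascending Euclidean distance; exact ties are broken by
#' ascending protein id for determinism.
#'
#' @param m a non-empty [representation_matrix].
#' @return a `knn_index`.
#' @export
build_knn_index <- function(m) {
  stopifnot(inherits(m, "representation_matrix"))
  if (nrow(m$values) == 0) psp_abort("cannot index an empty matrix", "psp_empty")
  structure(list(ids = m$ids, x = m$values,
                 sq = rowSums(m$values^2)),
            class = "knn_index")
}

#' Query nearest neighbors
#'
#' @param index a `knn_index`.
#' @param query numeric vector (single query) or matrix (one query per row).
#' @param n number of neighbors, at most the index size.
#' @param exclude_ids optional protein ids to drop from results (e.g. the
#'   query itself); `n` neighbors must remain after exclusion.
#' @return for a single query, a list with `ids` and `distances`; for a
#'   matrix query, a list with `ids` (character matrix, queries x n) and
#'   `distances` (numeric matrix).
#' @export
knn_query <- function(index, query, n, exclude_ids = NULL) {
  stopifnot(inherits(index, "knn_index"))
  single <- is.null(dim(query))
  q <- if (single) matrix(query, nrow = 1) else as.matrix(query)
  keep <- if (is.null(exclude_ids)) seq_along(index$ids) else
    which(!(index$ids %in% exclude_ids))
  if (n > length(keep)) {
    psp_abort(sprintf("requested %d neighbors from an index of size %d",
                      n, length(keep)), "psp_too_many_neighbors")
  }
  x <- index$x[keep, , drop = FALSE]
  ids <- index$ids[keep]
  sq <- index$sq[keep]
  # squared cross distances: ||x||^2 - 2 x.q + ||q||^2
  d2 <- outer(rep(1, length(keep)), rowSums(q^2)) + sq - 2 * (x %*% t(q))
  d2[d2 < 0] <- 0
  out_ids <- matrix("", nrow(q), n)
  out_d <- matrix(0, nrow(q), n)
  for (j in seq_len(nrow(q))) {
    ord <- order(d2[, j], ids)[seq_len(n)]
    out_ids[j, ] <- ids[ord]
    out_d[j, ] <- sqrt(d2[ord, j])
  }
  if (single) list(ids = out_ids[1, ], distances = out_d[1, ])
  else list(ids = out_ids, distances = out_d)
}

#' Aggregate neighbor labels into a prediction
#'
#' Voting rules over the label sets of the first `k` neighbors:
#' \describe{
#'   \item{majority (default)}{a label is predicted iff it occurs in more
#'     than `k/2` of the neighbors; if no label reaches a majority the
#'     prediction falls back to the nearest neighbor's label set, so
#'     predictions are never empty.}
#'   \item{union}{all labels of all `k` neighbors.}
#'   \item{plurality}{the label(s) with the highest vote count.}
#' }
#'
#' @param neighbor_ids character vector of neighbor ids, nearest first
#'   (length >= k); each neighbor must be labeled in `ontology`.
#' @param k neighborhood size to use.
#' @param annotations an [annotation_table].
#' @param ontology ontology name.
#' @param aggregation voting rule.
#' @return predicted label set (character vector, never empty).
#' @export
predict_labels <- function(neighbor_ids, k, annotations, ontology,
                           aggregation = c("majority", "union", "plurality")) {
  aggregation <- match.arg(aggregation)
  stopifnot(length(neighbor_ids) >= k, k >= 1)
  sets <- lapply(neighbor_ids[seq_len(k)], labels_for,
                 tab = annotations, ontology = ontology)
  if (any(lengths(sets) == 0)) {
    psp_abort("a neighbor carries no label in this ontology", "psp_unlabeled_neighbor")
  }
  votes <- table(unlist(sets))
  pred <- switch(aggregation,
    union = names(votes),
    plurality = names(votes)[votes == max(votes)],
    majority = names(votes)[votes > k / 2])
  if (length(pred) == 0) pred <- sets[[1]]  # nearest-neighbor fallback
  sort(unname(pred))
}
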