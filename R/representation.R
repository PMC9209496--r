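#' Representation matrices
#'
#' The common currency of the toolkit: a dense numeric matrix with one row
#' per protein, rownames carrying the protein ids, and a provenance tag
#' recording which method produced it (`lm-mean`, `kmer-tfidf`, `aa-freq`,
#' or `pca-reduced`).
#'
#' @param ids ordered character vector of protein ids (unique).
#' @param values numeric matrix, one row per id; all values finite.
#' @param method provenance tag.
#' @return an object of class `representation_matrix`.
#' @export
representation_matrix <- function(ids, values, method) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  ids <- as.character(ids)
  if (nrow(values) != length(ids)) {
    psp_abort("row count must equal id count", "psp_shape_mismatch")
  }
  if (anyDuplicated(ids)) psp_abort("duplicate ids", "psp_duplicate_id")
  if (!all(is.finite(values))) {
    psp_abort("representation matrix must contain finite values only",
              "psp_nonfinite")
  }
  stopifnot(is.character(method), length(method) == 1, nzchar(method))
  rownames(values) <- ids
  structure(list(ids = ids, values = values, method = method),
            class = "representation_matrix")
}

#' @export
print.representation_matrix <- function(x, ...) {
  cat(sprintf("<representation_matrix> %d proteins x %d dims (method: %s)\n",
              nrow(x$values), ncol(x$values), x$method))
  invisible(x)
}

#' @export
dim.representation_matrix <- function(x) dim(x$values)

#' Subset a representation matrix by protein id
#' @param m a `representation_matrix`.
#' @param ids ids to keep, in the given order.
#' @return a `representation_matrix` restricted to `ids`.
#' @export
subset_matrix <- function(m, ids) {
  stopifnot(inherits(m, "representation_matrix"))
  missing <- setdiff(ids, m$ids)
  if (length(missing) > 0) {
    psp_abort(paste0("unknown ids: ", paste(head(missing, 5), collapse = ", ")),
              "psp_unknown_id")
  }
  representation_matrix(ids, m$values[ids, , drop = FALSE], m$method)
}
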