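#' Projection configuration
#'
#' Defaults follow the analysis pipeline: PCA to 50 dimensions for all
#' downstream work, UMAP with 50 neighbors and minimum distance 0.3 for 2-D
#' visualization (remaining UMAP parameters at the projection library's
#' defaults).
#'
#' @param pca_components number of principal components to keep.
#' @param umap_neighbors UMAP `n_neighbors`.
#' @param umap_min_dist UMAP `min_dist`, in \[0, 1\].
#' @param seed integer seed for UMAP reproducibility.
#' @return a `projection_config` list.
#' @export
projection_config <- function(pca_components = 50L, umap_neighbors = 50L,
                              umap_min_dist = 0.3, seed = 0L) {
  stopifnot(pca_components >= 1, umap_neighbors >= 1,
            umap_min_dist >= 0, umap_min_dist <= 1)
  structure(list(pca_components = as.integer(pca_components),
                 umap_neighbors = as.integer(umap_neighbors),
                 umap_min_dist = umap_min_dist, seed = as.integer(seed)),
            class = "projection_config")
}

#' PCA reduction of a representation matrix
#'
#' Columns are mean-centered and projected onto the leading principal
#' components via exact SVD.  Component signs are canonicalized (the
#' largest-magnitude loading of each component is made positive) so results
#' are deterministic across BLAS implementations.
#'
#' @param m a [representation_matrix] with at least 2 rows.
#' @param config a [projection_config]; `pca_components` must not exceed
#'   `min(nrow, ncol)` of the input.
#' @return list with `matrix` (a [representation_matrix], method
#'   `"pca-reduced"`) and `explained_variance` (per-component ratios of total
#'   variance, nonincreasing).
#' @export
pca_reduce <- function(m, config = projection_config()) {
  stopifnot(inherits(m, "representation_matrix"))
  x <- m$values
  if (nrow(x) < 2) psp_abort("PCA needs at least 2 rows", "psp_too_few_rows")
  ncomp <- config$pca_components
  if (ncomp > min(dim(x))) {
    psp_abort(sprintf("pca_components = %d exceeds min(rows, cols) = %d",
                      ncomp, min(dim(x))), "psp_bad_components")
  }
  p <- prcomp(x, center = TRUE, scale. = FALSE, rank. = ncomp)
  scores <- p$x[, seq_len(ncomp), drop = FALSE]
  rot <- p$rotation[, seq_len(ncomp), drop = FALSE]
  for (j in seq_len(ncomp)) {
    lead <- which.max(abs(rot[, j]))
    if (rot[lead, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  evr <- p$sdev^2 / sum(p$sdev^2)
  list(matrix = representation_matrix(m$ids, scores, "pca-reduced"),
       explained_variance = evr[seq_len(ncomp)])
}

#' 2-D UMAP projection
#'
#' Runs Uniform Manifold Approximation and Projection on a representation
#' matrix (typically PCA-reduced) through the environment's Python
#' `umap-learn`, with a fixed `random_state` for seed-reproducible output.
#' Orientation of the layout is arbitrary; only reproducibility under a
#' fixed seed is promised.
#'
#' @param m a [representation_matrix] with more rows than `umap_neighbors`.
#' @param config a [projection_config].
#' @param python path of the python interpreter to use.
#' @return tibble with columns `id`, `x`, `y`.
#' @export
umap_project <- function(m, config = projection_config(),
                         python = Sys.which("python")) {
  stopifnot(inherits(m, "representation_matrix"))
  if (nrow(m$values) < config$umap_neighbors + 1) {
    psp_abort(sprintf(paste0("only %d rows for umap_neighbors = %d; ",
                             "use a smaller umap_neighbors"),
                      nrow(m$values), config$umap_neighbors), "psp_too_few_rows")
  }
  if (!nzchar(python)) psp_abort("no python interpreter found", "psp_no_python")
  script <- system.file("python", "umap_project.py", package = "protspace")
  tmp_in <- tempfile(fileext = ".tsv")
  tmp_out <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(tmp_in, tmp_out)))
  write.table(m$values, tmp_in, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  status <- system2(python, c(script, tmp_in, tmp_out,
                              config$umap_neighbors, config$umap_min_dist,
                              config$seed),
                    stdout = FALSE, stderr = "")
  if (status != 0 || !file.exists(tmp_out)) {
    psp_abort("UMAP projection subprocess failed", "psp_umap")
  }
  xy <- as.matrix(read.delim(tmp_out, header = FALSE))
  tibble::tibble(id = m$ids, x = xy[, 1], y = xy[, 2])
}
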