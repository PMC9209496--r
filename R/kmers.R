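#' Bag-of-k-mers specification
#'
#' Columns are all `20^k` k-mers over the canonical alphabet in alphabetical
#' order (k = 2 -> 400, k = 3 -> 8,000, k = 4 -> 160,000 dimensions).
#'
#' @param k k-mer length (1 to 4; larger k makes the dense contract
#'   combinatorially impractical).
#' @return a `kmer_spec` list with fields `k`, `alphabet`, `dim`.
#' @export
kmer_spec <- function(k = 3L) {
  stopifnot(is.numeric(k), k >= 1, k <= 4)
  structure(list(k = as.integer(k), alphabet = PSP_CANONICAL,
                 dim = length(PSP_CANONICAL)^as.integer(k)),
            class = "kmer_spec")
}

#' All k-mers of a spec in alphabetical (column) order
#' @param spec a [kmer_spec].
#' @return character vector of length `20^k`.
#' @export
kmer_names <- function(spec) {
  grids <- rev(lapply(seq_len(spec$k), function(i) spec$alphabet))
  do.call(paste0, rev(expand.grid(grids, stringsAsFactors = FALSE)))
}

# integer-encode a sequence's overlapping k-mer windows into 1-based column
# indices of the alphabetical ordering; windows touching ambiguity letters
# give NA.
psp_kmer_indices <- function(sequence, spec) {
  k <- spec$k
  a <- match(strsplit(sequence, "")[[1]], spec$alphabet)  # NA for ambiguity
  L <- length(a)
  if (L < k) return(integer(0))
  idx <- rep(0, L - k + 1)
  ok <- rep(TRUE, L - k + 1)
  for (j in seq_len(k)) {
    digit <- a[j:(L - k + j)]
    ok <- ok & !is.na(digit)
    idx <- idx * length(spec$alphabet) + ifelse(is.na(digit), 0, digit - 1)
  }
  out <- idx + 1
  out[!ok] <- NA_integer_
  as.integer(out)
}

#' Overlapping k-mer counts of one protein
#'
#' Entry j counts occurrences of the j-th alphabetical k-mer; windows that
#' contain ambiguity letters contribute no count.  A sequence shorter than k
#' yields the zero vector (with a logged warning), not an error.
#'
#' @param sequence amino-acid sequence string.
#' @param spec a [kmer_spec].
#' @return numeric count vector of length `20^k`, named by k-mer when
#'   `k <= 3`.
#' @export
kmer_counts <- function(sequence, spec = kmer_spec()) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  idx <- psp_kmer_indices(toupper(sequence), spec)
  if (length(idx) == 0) {
    psp_log(sprintf("sequence of length %d is shorter than k = %d; zero vector",
                    nchar(sequence), spec$k), level = "WARN")
  }
  counts <- tabulate(idx[!is.na(idx)], nbins = spec$dim)
  v <- as.numeric(counts)
  if (spec$k <= 3) names(v) <- kmer_names(spec)
  v
}

#' Sparse k-mer count matrix for a protein set
#'
#' @param proteins a [protein_set].
#' @param spec a [kmer_spec].
#' @return a `dgCMatrix` (proteins x `20^k`), rownames = protein ids.
#' @export
kmer_count_matrix <- function(proteins, spec = kmer_spec()) {
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (r in seq_len(nrow(proteins))) {
    idx <- psp_kmer_indices(proteins$sequence[r], spec)
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0) next
    tb <- table(idx)
    jj <- c(jj, as.integer(names(tb)))
    ii <- c(ii, rep(r, length(tb)))
    xx <- c(xx, as.numeric(tb))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(nrow(proteins), spec$dim),
                       dimnames = list(proteins$id, NULL))
}

#' Fit a smoothed-TFIDF model on a reference count corpus
#'
#' Standard smoothed inverse document frequency,
#' `idf(t) = ln((1 + n) / (1 + df(t))) + 1`, with transformed rows
#' L2-normalized — the convention of the widely used TfidfTransformer
#' default, which accentuates rare k-mers.
#'
#' @param counts nonnegative count matrix (dense or sparse), documents in
#'   rows.
#' @return a `tfidf_model` holding the per-column idf weights.
#' @export
fit_tfidf <- function(counts) {
  if (any(counts < 0)) psp_abort("counts must be nonnegative", "psp_bad_counts")
  n <- nrow(counts)
  df <- Matrix::colSums(counts > 0)
  idf <- log((1 + n) / (1 + df)) + 1
  structure(list(idf = as.numeric(idf), n_docs = n), class = "tfidf_model")
}

#' Apply a fitted TFIDF model
#'
#' @param model a `tfidf_model` from [fit_tfidf()].
#' @param counts count matrix with the same number of columns as the fitting
#'   corpus.
#' @return dense matrix of L2-normalized tf-idf rows (all-zero rows stay
#'   zero).
#' @export
transform_tfidf <- function(model, counts) {
  if (!inherits(model, "tfidf_model")) {
    psp_abort("transform_tfidf called before fit_tfidf", "psp_usage")
  }
  if (ncol(counts) != length(model$idf)) {
    psp_abort("column count differs from the fitted corpus", "psp_shape_mismatch")
  }
  x <- as.matrix(counts)
  w <- sweep(x, 2, model$idf, "*")
  nrm <- sqrt(rowSums(w^2))
  nrm[nrm == 0] <- 1
  w / nrm
}

#' Amino-acid frequency vector of one protein
#'
#' Counts of each canonical residue divided by the number of canonical
#' residues; entries sum to 1.  Ambiguity letters are ignored.
#'
#' @param sequence amino-acid sequence containing at least one canonical
#'   residue.
#' @return named 20-dimensional frequency vector.
#' @export
aa_frequencies <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  chars <- strsplit(toupper(sequence), "")[[1]]
  counts <- table(factor(chars, levels = PSP_CANONICAL))
  total <- sum(counts)
  if (total == 0) {
    psp_abort("sequence contains no canonical residues", "psp_no_canonical")
  }
  setNames(as.numeric(counts) / total, PSP_CANONICAL)
}

#' Build a baseline representation matrix
#'
#' The two non-deep baselines: alphabetically sorted bag-of-k-mers with
#' TFIDF weighting (`kmer-tfidf`; the TFIDF model is fitted on `proteins`
#' itself unless a fitted model is supplied), and amino-acid frequency
#' vectors (`aa-freq`).
#'
#' @param proteins a [protein_set].
#' @param method `"kmer-tfidf"` or `"aa-freq"`.
#' @param k k-mer length for `"kmer-tfidf"`.
#' @param tfidf optional pre-fitted `tfidf_model` (fitting corpus is then
#'   external).
#' @return a [representation_matrix].
#' @export
baseline_representation <- function(proteins, method = c("kmer-tfidf", "aa-freq"),
                                    k = 3L, tfidf = NULL) {
  method <- match.arg(method)
  if (method == "aa-freq") {
    vals <- t(vapply(proteins$sequence, aa_frequencies,
                     numeric(length(PSP_CANONICAL))))
    return(representation_matrix(proteins$id, vals, "aa-freq"))
  }
  spec <- kmer_spec(k)
  counts <- kmer_count_matrix(proteins, spec)
  if (is.null(tfidf)) tfidf <- fit_tfidf(counts)
  representation_matrix(proteins$id, transform_tfidf(tfidf, counts), "kmer-tfidf")
}
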