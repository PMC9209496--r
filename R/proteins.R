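#' Protein sequence sets
#'
#' A `protein_set` is the package's atomic input container: a tibble with
#' columns `id` (unique, whitespace-free) and `sequence` (upper-case amino
#' acids over the 20 canonical letters plus the ambiguity letters
#' B, J, O, U, X, Z).
#'
#' @param id character vector of unique identifiers.
#' @param sequence character vector of amino-acid sequences (same length).
#' @return a tibble of class `protein_set`.
#' @examples
#' protein_set(c("p1", "p2"), c("MKV", "GG"))
#' @export
protein_set <- function(id, sequence) {
  stopifnot(length(id) == length(sequence))
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (any(!nzchar(id)) || any(grepl("\\s", id))) {
    psp_abort("protein ids must be non-empty and contain no whitespace",
              "psp_invalid_id")
  }
  if (anyDuplicated(id)) {
    dups <- unique(id[duplicated(id)])
    psp_abort(paste0("duplicate protein ids: ", paste(dups, collapse = ", ")),
              "psp_duplicate_id")
  }
  if (any(nchar(sequence) < 1)) {
    psp_abort("all sequences must have length >= 1", "psp_empty_sequence")
  }
  bad <- !grepl(paste0("^[", paste(c(PSP_CANONICAL, PSP_AMBIGUITY), collapse = ""), "]+$"),
                sequence)
  if (any(bad)) {
    psp_abort(paste0("sequence for id '", id[which(bad)[1]],
                     "' contains characters outside the amino-acid alphabet"),
              "psp_bad_alphabet")
  }
  out <- tibble::tibble(id = id, sequence = sequence)
  class(out) <- c("protein_set", class(out))
  out
}

#' @export
print.protein_set <- function(x, ...) {
  cat(sprintf("<protein_set> %d proteins, lengths %d-%d\n",
              nrow(x), min(nchar(x$sequence)), max(nchar(x$sequence))))
  NextMethod()
}
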