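#' Read a protein FASTA file
#'
#' Wrap-agnostic FASTA reader.  The header token before the first whitespace
#' becomes the protein id; sequences are upper-cased; entry order is
#' preserved.
#'
#' @param path path to a FASTA file.
#' @return a [protein_set].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) psp_abort(paste0("no such file: ", path), "psp_io")
  lines <- readLines(path)
  ids <- character(0)
  seqs <- character(0)
  cur <- NULL
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln))) next
    if (startsWith(ln, ">")) {
      if (!is.null(cur)) seqs <- c(seqs, cur)
      ids <- c(ids, strsplit(trimws(substring(ln, 2)), "\\s+")[[1]][1])
      cur <- ""
    } else {
      if (is.null(cur)) {
        psp_abort(sprintf("malformed FASTA: sequence line before any header at line %d", i),
                  "psp_fasta_parse")
      }
      cur <- paste0(cur, gsub("\\s", "", ln))
    }
  }
  if (!is.null(cur)) seqs <- c(seqs, cur)
  if (length(ids) == 0) {
    out <- tibble::tibble(id = character(0), sequence = character(0))
    class(out) <- c("protein_set", class(out))
    return(out)
  }
  if (anyDuplicated(ids)) {
    dups <- unique(ids[duplicated(ids)])
    psp_abort(paste0("duplicate ids in FASTA: ", paste(dups, collapse = ", ")),
              "psp_duplicate_id")
  }
  protein_set(ids, seqs)
}

#' Write a protein set to FASTA
#'
#' Sequences are wrapped at 60 columns.
#'
#' @param proteins a [protein_set].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(proteins))) {
    writeLines(paste0(">", proteins$id[i]), con)
    s <- proteins$sequence[i]
    starts <- seq(1, nchar(s), by = 60)
    writeLines(substring(s, starts, pmin(starts + 59, nchar(s))), con)
  }
  invisible(path)
}

#' Read a multi-label annotation TSV
#'
#' The toolkit's annotation exchange format: tab-separated columns
#' `protein_id`, `ontology`, `label`, one row per label, optional header.
#'
#' @param path path to the TSV file.
#' @return an [annotation_table].
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) psp_abort(paste0("no such file: ", path), "psp_io")
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(annotation_table(data.frame(protein_id = character(0),
                                       ontology = character(0),
                                       label = character(0))))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield < 3)) {
    psp_abort(sprintf("annotation TSV row with fewer than 3 columns at line %d",
                      which(nfield < 3)[1]), "psp_tsv_parse")
  }
  df <- data.frame(protein_id = vapply(parts, `[[`, "", 1),
                   ontology = vapply(parts, `[[`, "", 2),
                   label = vapply(parts, `[[`, "", 3),
                   stringsAsFactors = FALSE)
  # tolerate a header row
  if (nrow(df) > 0 && identical(tolower(df$protein_id[1]), "protein_id")) {
    df <- df[-1, , drop = FALSE]
  }
  annotation_table(df)
}

#' Write an annotation table to TSV
#' @param tab an [annotation_table].
#' @param path output path.
#' @param header write a header row (default TRUE).
#' @return `path`, invisibly.
#' @export
write_annotations <- function(tab, path, header = TRUE) {
  stopifnot(inherits(tab, "annotation_table"))
  write.table(tab$long, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = header)
  invisible(path)
}

#' Persist a representation matrix
#'
#' Matrices are stored as a raw little-endian double stream (`<path>`) with a
#' JSON sidecar (`<path>.json`) carrying ids, method, dimension and row
#' count, so a round trip is bit-exact and the store is self-describing.
#'
#' @param m a [representation_matrix].
#' @param path output path for the binary value stream.
#' @return `path`, invisibly.
#' @export
save_matrix <- function(m, path) {
  stopifnot(inherits(m, "representation_matrix"))
  meta <- list(ids = m$ids, method = m$method,
               dim = ncol(m$values), n = nrow(m$values),
               storage = "float64-little-endian-row-major")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(t(m$values)), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname save_matrix
#' @export
load_matrix <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(sidecar)) {
    psp_abort(paste0("matrix store incomplete at ", path), "psp_io")
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  n <- as.integer(meta$n)
  d <- as.integer(meta$dim)
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, "double", n = n * d + 1, size = 8, endian = "little")
  if (length(vals) != n * d) {
    psp_abort(sprintf("matrix store corrupt: expected %d values, found %d",
                      n * d, length(vals)), "psp_integrity")
  }
  if (length(meta$ids) != n) {
    psp_abort("matrix store corrupt: id count does not match row count",
              "psp_integrity")
  }
  representation_matrix(meta$ids, matrix(vals, nrow = n, byrow = TRUE),
                        meta$method)
}
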