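#' Multi-label protein annotation tables
#'
#' An `annotation_table` maps protein id -> ontology name -> set of labels.
#' Label sets are true sets (sorted, duplicate-free character vectors); a
#' protein may be absent from an ontology, in which case it is unlabeled
#' there.  Ontology names are free strings (e.g. Pfam, KO, EC, GO, or the
#' synthetic generator's "function"/"domain"/"taxonomy").
#'
#' @param df data frame with columns `protein_id`, `ontology`, `label`
#'   (one row per label; duplicate rows collapse silently).
#' @return an object of class `annotation_table`.
#' @export
annotation_table <- function(df) {
  stopifnot(all(c("protein_id", "ontology", "label") %in% names(df)))
  df <- unique(data.frame(protein_id = as.character(df$protein_id),
                          ontology = as.character(df$ontology),
                          label = as.character(df$label),
                          stringsAsFactors = FALSE))
  df <- df[order(df$protein_id, df$ontology, df$label), , drop = FALSE]
  rownames(df) <- NULL
  entries <- list()
  if (nrow(df) > 0) {
    by_prot <- split(df[c("ontology", "label")], df$protein_id)
    entries <- lapply(by_prot, function(d) {
      lapply(split(d$label, d$ontology), function(l) sort(unique(l)))
    })
  }
  structure(list(entries = entries, long = df), class = "annotation_table")
}

#' @export
print.annotation_table <- function(x, ...) {
  cat(sprintf("<annotation_table> %d proteins, ontologies: %s\n",
              length(x$entries),
              paste(ontologies(x), collapse = ", ")))
  invisible(x)
}

#' Ontology names present in an annotation table
#' @param tab an `annotation_table`.
#' @return character vector of ontology names.
#' @export
ontologies <- function(tab) {
  stopifnot(inherits(tab, "annotation_table"))
  sort(unique(tab$long$ontology))
}

#' Label set for one protein in one ontology
#'
#' @param tab an `annotation_table`.
#' @param protein_id protein identifier.
#' @param ontology ontology name.
#' @return sorted character vector of labels; `character(0)` if unlabeled.
#' @export
labels_for <- function(tab, protein_id, ontology) {
  stopifnot(inherits(tab, "annotation_table"))
  ent <- tab$entries[[protein_id]]
  if (is.null(ent)) return(character(0))
  lab <- ent[[ontology]]
  if (is.null(lab)) character(0) else lab
}

#' Proteins carrying at least one label in an ontology
#' @inheritParams labels_for
#' @return character vector of protein ids (sorted).
#' @export
labeled_proteins <- function(tab, ontology) {
  stopifnot(inherits(tab, "annotation_table"))
  sort(unique(tab$long$protein_id[tab$long$ontology == ontology]))
}

#' @export
as.data.frame.annotation_table <- function(x, ...) x$long

#' Test equality of two annotation tables
#' @param a,b annotation tables.
#' @return logical scalar.
#' @export
annotations_equal <- function(a, b) {
  identical(a$long, b$long)
}
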