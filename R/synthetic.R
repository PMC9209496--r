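#' Specification of a synthetic motif-family corpus
#'
#' The generator emulates the structure the embedding approach exploits in
#' real protein catalogs: families defined by conserved sequence motifs
#' embedded in neutral random background, function-like labels determined by
#' motif content, and taxonomy-like labels assigned independently of the
#' sequence.  Every member sequence has length
#' `background_length + motifs_per_family * motif_length`.
#'
#' @param n_families number of families.
#' @param members_per_family members generated per family.
#' @param motif_length residues per conserved motif.
#' @param motifs_per_family conserved motifs defining each family.
#' @param background_length residues of i.i.d. background per member.
#' @param substitution_rate per-position substitution probability applied
#'   independently to every motif copy, in \[0, 1\].
#' @param residue_distribution probability vector over the 20 canonical
#'   residues (default uniform).
#' @param n_taxa number of random taxonomy labels.
#' @param seed integer seed; generation is fully reproducible.
#' @return a `family_spec` list.
#' @export
family_spec <- function(n_families = 5L, members_per_family = 40L,
                        motif_length = 12L, motifs_per_family = 2L,
                        background_length = 60L, substitution_rate = 0.1,
                        residue_distribution = rep(1 / 20, 20),
                        n_taxa = 4L, seed = 0L) {
  stopifnot(n_families >= 1, members_per_family >= 1, motif_length >= 1,
            motifs_per_family >= 1, background_length >= 1,
            substitution_rate >= 0, substitution_rate <= 1,
            length(residue_distribution) == 20,
            all(residue_distribution >= 0), n_taxa >= 1)
  residue_distribution <- residue_distribution / sum(residue_distribution)
  structure(list(n_families = as.integer(n_families),
                 members_per_family = as.integer(members_per_family),
                 motif_length = as.integer(motif_length),
                 motifs_per_family = as.integer(motifs_per_family),
                 background_length = as.integer(background_length),
                 substitution_rate = substitution_rate,
                 residue_distribution = residue_distribution,
                 n_taxa = as.integer(n_taxa), seed = as.integer(seed)),
            class = "family_spec")
}

psp_random_residues <- function(n, dist) {
  sample(PSP_CANONICAL, n, replace = TRUE, prob = dist)
}

psp_mutate_motif <- function(motif_chars, rate, dist) {
  hit <- runif(length(motif_chars)) < rate
  if (any(hit)) motif_chars[hit] <- psp_random_residues(sum(hit), dist)
  motif_chars
}

# insert motif copies into a background character vector at random cut
# points, never splitting a previously inserted motif; returns list(chars,
# starts) with 1-based motif start positions in the final sequence.
psp_insert_motifs <- function(background, motif_list, rate, dist) {
  chars <- background
  spans <- list()  # c(start, end) of motifs already placed
  for (mi in seq_along(motif_list)) {
    copy <- psp_mutate_motif(motif_list[[mi]], rate, dist)
    blocked <- unlist(lapply(spans, function(se) se[1]:(se[2] - 1)))
    allowed <- setdiff(0:length(chars), blocked)
    cut <- allowed[sample.int(length(allowed), 1)]
    chars <- append(chars, copy, after = cut)
    spans <- lapply(spans, function(se) if (se[1] > cut) se + length(copy) else se)
    spans[[mi]] <- c(cut + 1, cut + length(copy))
  }
  list(chars = chars, starts = vapply(spans, function(s) as.integer(s[1]), 0L))
}

#' Generate a synthetic motif-family corpus
#'
#' Each family draws `motifs_per_family` distinct motifs; each member is an
#' i.i.d. background sequence with one independently mutated copy of every
#' family motif inserted at a random position.  Annotations: ontology
#' `"function"` carries the family label (a deterministic function of motif
#' content; shared motifs added by [inject_shared_motif()] make it
#' multi-label-capable via the `"domain"` ontology), `"domain"` one label
#' per motif present, `"taxonomy"` a random label drawn independently of the
#' sequence.
#'
#' @param spec a [family_spec].
#' @return a `synthetic_corpus`: list with `proteins` (a [protein_set]),
#'   `annotations` (an [annotation_table]), `truth` (tibble: id, family and
#'   a list-column of motif start positions) and `spec`.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  with_seed(spec$seed, {
    # distinct motif sets per family
    motifs <- list()
    seen <- character(0)
    for (fam in seq_len(spec$n_families)) {
      fam_motifs <- list()
      for (mi in seq_len(spec$motifs_per_family)) {
        repeat {
          cand <- psp_random_residues(spec$motif_length, spec$residue_distribution)
          key <- paste(cand, collapse = "")
          if (!(key %in% seen)) { seen <- c(seen, key); break }
        }
        fam_motifs[[mi]] <- cand
      }
      motifs[[fam]] <- fam_motifs
    }
    ids <- character(0); seqs <- character(0)
    ann <- list(); truth_rows <- list()
    for (fam in seq_len(spec$n_families)) {
      fam_lab <- sprintf("F%02d", fam)
      for (mem in seq_len(spec$members_per_family)) {
        pid <- sprintf("%s_m%03d", fam_lab, mem)
        bg <- psp_random_residues(spec$background_length, spec$residue_distribution)
        ins <- psp_insert_motifs(bg, motifs[[fam]], spec$substitution_rate,
                                 spec$residue_distribution)
        ids <- c(ids, pid)
        seqs <- c(seqs, paste(ins$chars, collapse = ""))
        ann[[length(ann) + 1]] <- data.frame(
          protein_id = pid,
          ontology = c("function",
                       rep("domain", spec$motifs_per_family),
                       "taxonomy"),
          label = c(fam_lab,
                    sprintf("%s_M%d", fam_lab, seq_len(spec$motifs_per_family)),
                    sprintf("T%02d", sample.int(spec$n_taxa, 1))))
        truth_rows[[length(truth_rows) + 1]] <-
          tibble::tibble(id = pid, family = fam_lab,
                         motif_starts = list(ins$starts))
      }
    }
    structure(list(proteins = protein_set(ids, seqs),
                   annotations = annotation_table(do.call(rbind, ann)),
                   truth = do.call(rbind, truth_rows),
                   spec = spec),
              class = "synthetic_corpus")
  })
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(sprintf("<synthetic_corpus> %d proteins, %d families, seed %d\n",
              nrow(x$proteins), x$spec$n_families, x$spec$seed))
  invisible(x)
}

#' Inject a motif shared across families
#'
#' Adds one common motif (an independently mutated copy per member, at the
#' corpus substitution rate) to all members of the listed families, plus a
#' shared `"domain"` label — modelling cross-family similarity such as
#' enzymes that can share substrates.  Returns a new corpus; the input is
#' unchanged.
#'
#' @param corpus a `synthetic_corpus`.
#' @param family_ids family labels (e.g. `"F01"`) receiving the motif.
#' @param motif motif sequence string (canonical residues; at most
#'   `background_length` long).
#' @param seed seed for the insertion positions and mutations (default:
#'   derived from the corpus seed).
#' @return a `synthetic_corpus`.
#' @export
inject_shared_motif <- function(corpus, family_ids, motif,
                                seed = fork_seed(corpus$spec$seed, 7919L)) {
  stopifnot(inherits(corpus, "synthetic_corpus"))
  if (length(family_ids) == 0) return(corpus)
  known <- unique(corpus$truth$family)
  bad <- setdiff(family_ids, known)
  if (length(bad) > 0) {
    psp_abort(paste0("unknown family id(s): ", paste(bad, collapse = ", ")),
              "psp_unknown_family")
  }
  if (nchar(motif) > corpus$spec$background_length) {
    psp_abort("shared motif longer than the background length", "psp_motif_too_long")
  }
  motif_chars <- strsplit(toupper(motif), "")[[1]]
  if (!all(motif_chars %in% PSP_CANONICAL)) {
    psp_abort("shared motif must use canonical residues", "psp_bad_alphabet")
  }
  shared_label <- paste0("SHARED_", substr(motif, 1, 6))
  proteins <- corpus$proteins
  ann_long <- as.data.frame(corpus$annotations)
  with_seed(seed, {
    for (i in seq_len(nrow(proteins))) {
      fam <- corpus$truth$family[corpus$truth$id == proteins$id[i]]
      if (!(fam %in% family_ids)) next
      chars <- strsplit(proteins$sequence[i], "")[[1]]
      copy <- psp_mutate_motif(motif_chars, corpus$spec$substitution_rate,
                               corpus$spec$residue_distribution)
      cut <- sample.int(length(chars) + 1, 1) - 1
      proteins$sequence[i] <- paste(append(chars, copy, after = cut),
                                    collapse = "")
      ann_long <- rbind(ann_long,
                        data.frame(protein_id = proteins$id[i],
                                   ontology = "domain", label = shared_label))
    }
    structure(list(proteins = protein_set(proteins$id, proteins$sequence),
                   annotations = annotation_table(ann_long),
                   truth = corpus$truth, spec = corpus$spec),
              class = "synthetic_corpus")
  })
}
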