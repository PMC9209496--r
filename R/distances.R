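#' Pairwise Euclidean distances between two id sets
#'
#' @param m a [representation_matrix].
#' @param ids_a,ids_b protein ids present in `m`.
#' @return numeric matrix `length(ids_a)` x `length(ids_b)`; symmetric with
#'   zero diagonal when `ids_a == ids_b`.
#' @export
euclidean_distances <- function(m, ids_a, ids_b = ids_a) {
  a <- subset_matrix(m, ids_a)$values
  b <- subset_matrix(m, ids_b)$values
  # direct differences (not the expanded-square shortcut) so that identical
  # vectors give exactly zero
  d <- matrix(0, nrow(a), nrow(b), dimnames = list(ids_a, ids_b))
  for (i in seq_len(nrow(a))) {
    d[i, ] <- sqrt(colSums((t(b) - a[i, ])^2))
  }
  d
}

#' Global-alignment percent identity between two sequences
#'
#' Needleman-Wunsch global alignment with BLOSUM62 scoring and affine gaps
#' (open -10, extend -0.5), identity counted on aligned columns:
#' `100 * identical columns / alignment length`, the alignment length
#' including gap columns.  Symmetric; 100 for identical sequences.
#'
#' @param seq_a,seq_b non-empty amino-acid sequences.
#' @return percent identity in \[0, 100\].
#' @export
percent_identity <- function(seq_a, seq_b) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) {
    psp_abort("percent identity of an empty sequence is undefined", "psp_empty_sequence")
  }
  psp_pid_vec(seq_a, seq_b)
}

# vectorized core: percent identity of each pattern sequence against one
# subject, from a single batched global alignment call
psp_pid_vec <- function(patterns, subject) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(patterns), Biostrings::AAString(subject),
    substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5, type = "global")
  100 * Biostrings::nmatch(al) /
    Biostrings::width(Biostrings::alignedPattern(al))
}

#' Percent-identity matrix for a set of proteins
#' @param proteins a [protein_set].
#' @param ids_a,ids_b ids to compare (defaults: all vs all).
#' @return matrix of percent identities.
#' @export
identity_matrix <- function(proteins, ids_a = proteins$id, ids_b = ids_a) {
  seqs <- setNames(proteins$sequence, proteins$id)
  out <- matrix(NA_real_, length(ids_a), length(ids_b),
                dimnames = list(ids_a, ids_b))
  for (j in seq_along(ids_b)) {
    sym <- match(ids_b[j], ids_a)  # fill symmetric entries only once
    todo <- if (!is.na(sym)) which(is.na(out[, j])) else seq_along(ids_a)
    todo <- todo[ids_a[todo] != ids_b[j]]
    if (length(todo) > 0) {
      out[todo, j] <- psp_pid_vec(unname(seqs[ids_a[todo]]), seqs[[ids_b[j]]])
    }
    if (ids_b[j] %in% ids_a) out[match(ids_b[j], ids_a), j] <- 100
    if (!is.na(sym)) {
      back <- match(ids_a, ids_b)
      ok <- !is.na(back)
      out[sym, back[ok]] <- out[ok, j]
    }
  }
  out
}

#' Group assignment for distance analysis
#'
#' @param groups tibble/data frame with columns `protein_id`, `group`.
#' @param background character vector of background protein ids (disjoint
#'   from the groups).
#' @return a `group_assignment`.
#' @export
group_assignment <- function(groups, background = character(0)) {
  stopifnot(all(c("protein_id", "group") %in% names(groups)))
  if (length(intersect(groups$protein_id, background)) > 0) {
    psp_abort("background overlaps the groups", "psp_group_overlap")
  }
  structure(list(groups = tibble::as_tibble(groups[c("protein_id", "group")]),
                 background = as.character(background)),
            class = "group_assignment")
}

psp_mean_cross <- function(d) mean(d)

psp_mean_within <- function(d) {
  # mean over unordered distinct pairs of a symmetric matrix
  mean(d[upper.tri(d)])
}

#' Within-, between- and background mean distances per group
#'
#' For each group: (i) the mean pairwise distance over its unordered
#' distinct member pairs, (ii) the mean cross distance to every other group,
#' (iii) the mean cross distance to a random background set — computed for
#' the embedding metric (Euclidean on the representation matrix, typically
#' 50 PCA components) and for the sequence metric (100 - percent identity).
#' Singleton groups are excluded from within-group means with a log message.
#'
#' @param assignment a [group_assignment]; if its background is empty,
#'   `background_size` ids are drawn from the remaining proteins of `m`
#'   under `seed`.
#' @param m a [representation_matrix] covering all ids.
#' @param proteins a [protein_set] with the sequences (for the identity
#'   metric); pass `NULL` to skip the sequence metric.
#' @param background_size number of background proteins to draw when the
#'   assignment does not fix them.
#' @param seed integer seed for the background draw.
#' @return a `distance_report` tibble with columns `metric`
#'   (`embedding` / `identity`), `group_a`, `group_b` (another group name,
#'   `WITHIN`, or `BACKGROUND`), `mean_distance`, `n_pairs`.
#' @export
distance_report <- function(assignment, m, proteins = NULL,
                            background_size = 500L, seed = 0L) {
  stopifnot(inherits(assignment, "group_assignment"),
            inherits(m, "representation_matrix"))
  ga <- assignment$groups
  group_names <- sort(unique(ga$group))
  members <- split(ga$protein_id, ga$group)
  background <- assignment$background
  if (length(background) == 0) {
    pool <- setdiff(m$ids, ga$protein_id)
    if (length(pool) == 0) psp_abort("no proteins left for the background", "psp_empty")
    background <- with_seed(seed, sort(sample(pool, min(background_size, length(pool)))))
  }
  metrics <- list(embedding = function(a, b) euclidean_distances(m, a, b))
  if (!is.null(proteins)) {
    metrics$identity <- function(a, b) 100 - identity_matrix(proteins, a, b)
  }
  rows <- list()
  add <- function(metric, a, b, d, n) {
    rows[[length(rows) + 1]] <<- data.frame(metric = metric, group_a = a,
                                            group_b = b, mean_distance = d,
                                            n_pairs = n)
  }
  for (mt in names(metrics)) {
    fn <- metrics[[mt]]
    for (g in group_names) {
      ids <- members[[g]]
      if (length(ids) < 2) {
        psp_log(sprintf("group '%s' is a singleton; no within-group mean", g),
                level = "WARN")
      } else {
        d <- fn(ids, ids)
        add(mt, g, "WITHIN", psp_mean_within(d), choose(length(ids), 2))
      }
      d <- fn(ids, background)
      add(mt, g, "BACKGROUND", psp_mean_cross(d), length(ids) * length(background))
    }
    for (i in seq_along(group_names)) {
      for (j in seq_along(group_names)) {
        if (j <= i) next
        a <- members[[group_names[i]]]; b <- members[[group_names[j]]]
        d <- fn(a, b)
        add(mt, group_names[i], group_names[j], psp_mean_cross(d),
            length(a) * length(b))
      }
    }
  }
  out <- tibble::as_tibble(do.call(rbind, rows))
  attr(out, "background") <- background
  class(out) <- c("distance_report", class(out))
  out
}
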