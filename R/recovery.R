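#' Configuration of the label-recovery benchmark
#'
#' Defaults follow the evaluation protocol: fivefold cross-validation
#' (each held-out fold is 20% of the labeled proteins), neighborhoods up to
#' N = 51, the whole procedure repeated 5 times per k with derived seeds.
#'
#' @param n_folds number of cross-validation folds (>= 2).
#' @param max_neighbors largest neighborhood ever queried.
#' @param k_values ascending neighborhood sizes to evaluate, each
#'   `<= max_neighbors`.
#' @param aggregation label-voting rule (see [predict_labels()]).
#' @param n_repeats repetitions of the whole CV procedure.
#' @param seed integer seed; repeat r uses the derived seed
#'   `fork_seed(seed, r)`.
#' @return a `recovery_config` list.
#' @export
recovery_config <- function(n_folds = 5L, max_neighbors = 51L,
                            k_values = c(1L, 3L, 11L, 51L),
                            aggregation = "majority",
                            n_repeats = 5L, seed = 0L) {
  k_values <- as.integer(k_values)
  stopifnot(n_folds >= 2, length(k_values) >= 1, !is.unsorted(k_values),
            all(k_values <= max_neighbors), n_repeats >= 1)
  structure(list(n_folds = as.integer(n_folds),
                 max_neighbors = as.integer(max_neighbors),
                 k_values = k_values, aggregation = aggregation,
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed)),
            class = "recovery_config")
}

#' Cross-validated multi-label kNN label recovery
#'
#' For each ontology, the evaluation restricts to proteins carrying at least
#' one label there, splits them into `n_folds` equal parts under a derived
#' seed, builds an exact kNN index on the remaining folds, queries each
#' held-out protein's nearest neighbors, aggregates neighbor labels into a
#' prediction for every `k` in `k_values`, and scores it against the ground
#' truth with IoU, Precision, Recall and F1.  The procedure is repeated
#' `n_repeats` times with distinct derived seeds.
#'
#' @param m a [representation_matrix] (typically PCA-reduced).
#' @param annotations an [annotation_table].
#' @param ontology_names ontologies to evaluate (must exist in
#'   `annotations`).
#' @param config a [recovery_config].
#' @return a `recovery_report`: list with `per_protein` (tibble: protein_id,
#'   ontology, k, repeat, iou, precision, recall, f1), `aggregates` (tibble:
#'   ontology, k, metric means and sds across proteins and repeats) and
#'   `rer` (tibble: protein_id, rer).
#' @export
evaluate_recovery <- function(m, annotations, ontology_names,
                              config = recovery_config()) {
  stopifnot(inherits(m, "representation_matrix"),
            inherits(annotations, "annotation_table"))
  avail <- ontologies(annotations)
  missing <- setdiff(ontology_names, avail)
  if (length(missing) > 0) {
    psp_abort(paste0("ontology not annotated: ", paste(missing, collapse = ", "),
                     "; available: ", paste(avail, collapse = ", ")),
              "psp_unknown_ontology")
  }
  rows <- vector("list", 0)
  for (ont in ontology_names) {
    prot <- intersect(labeled_proteins(annotations, ont), m$ids)
    if (length(prot) < config$n_folds) {
      psp_abort(sprintf("ontology '%s' has %d labeled proteins; need >= %d",
                        ont, length(prot), config$n_folds), "psp_too_few_labeled")
    }
    truth_sets <- lapply(prot, labels_for, tab = annotations, ontology = ont)
    names(truth_sets) <- prot
    sub <- subset_matrix(m, prot)
    n_query <- min(max(config$k_values), length(prot) - 1)
    for (rep_i in seq_len(config$n_repeats)) {
      fold_of <- with_seed(fork_seed(config$seed, rep_i), {
        sample(rep_len(seq_len(config$n_folds), length(prot)))
      })
      for (fold in seq_len(config$n_folds)) {
        test_ids <- prot[fold_of == fold]
        train_ids <- prot[fold_of != fold]
        if (length(test_ids) == 0) next
        idx <- build_knn_index(subset_matrix(sub, train_ids))
        nq <- min(n_query, length(train_ids))
        res <- knn_query(idx, sub$values[test_ids, , drop = FALSE], nq,
                         exclude_ids = test_ids)
        for (ti in seq_along(test_ids)) {
          pid <- test_ids[ti]
          truth <- truth_sets[[pid]]
          nb <- res$ids[ti, ]
          for (k in config$k_values) {
            kk <- min(k, nq)
            pred <- predict_labels(nb, kk, annotations, ont,
                                   aggregation = config$aggregation)
            rows[[length(rows) + 1]] <- list(
              protein_id = pid, ontology = ont, k = k, rep = rep_i,
              iou = set_iou(pred, truth),
              precision = set_precision(pred, truth),
              recall = set_recall(pred, truth),
              f1 = set_f1(pred, truth))
          }
        }
      }
    }
  }
  per <- tibble::as_tibble(do.call(rbind, lapply(rows, as.data.frame)))
  names(per)[names(per) == "rep"] <- "repeat"
  agg <- do.call(rbind, lapply(split(per, list(per$ontology, per$k), drop = TRUE),
    function(d) data.frame(ontology = d$ontology[1], k = d$k[1],
                           iou_mean = mean(d$iou), iou_sd = sd(d$iou),
                           precision_mean = mean(d$precision),
                           recall_mean = mean(d$recall),
                           f1_mean = mean(d$f1))))
  agg <- tibble::as_tibble(agg[order(agg$ontology, agg$k), ])
  report <- structure(list(per_protein = per, aggregates = agg,
                           config = config),
                      class = "recovery_report")
  report$rer <- recovery_error_rate(report)
  report
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %d scored predictions, %d proteins\n",
              nrow(x$per_protein), nrow(x$rer)))
  print(x$aggregates)
  invisible(x)
}

#' Per-protein Recovery Error Rate
#'
#' `RER(p) = 1 - mean(IoU)` over every IoU value recorded for protein `p`
#' across all evaluated ontologies, neighborhood sizes and repeats (pooled
#' mean).  High RER marks proteins whose labels are hard to recover from
#' their neighborhood.
#'
#' @param report a `recovery_report`.
#' @return tibble with columns `protein_id`, `rer` (each in \[0, 1\]).
#' @export
recovery_error_rate <- function(report) {
  per <- if (inherits(report, "recovery_report")) report$per_protein else report
  stopifnot(all(c("protein_id", "iou") %in% names(per)))
  mean_iou <- tapply(per$iou, per$protein_id, mean)
  tibble::tibble(protein_id = names(mean_iou),
                 rer = 1 - as.numeric(mean_iou))
}
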