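test_that("set metrics follow their definitions on direct examples", {
  expect_equal(set_iou(c("A", "B"), c("B", "C")), 1 / 3)
  expect_equal(set_iou("A", "A"), 1)
  expect_equal(set_iou(character(0), "A"), 0)
  expect_equal(set_precision(c("A", "B"), c("B", "C")), 1 / 2)
  expect_equal(set_recall(c("A", "B"), c("B", "C")), 1 / 2)
  expect_equal(set_f1(c("A", "B"), c("B", "C")), 1 / 2)
  expect_equal(set_recall(c("A", "B", "C"), "A"), 1)
  expect_equal(set_precision(c("A", "B", "C"), "A"), 1 / 3)
  expect_equal(set_precision(character(0), "A"), 0)
  for (f in list(set_iou, set_precision, set_recall, set_f1)) {
    expect_error(f("A", character(0)), class = "psp_empty_truth")
  }
})

test_that("metric algebra holds over all subset pairs of a 4-label universe", {
  universe <- c("a", "b", "c", "d")
  subsets <- all_subsets(universe)
  for (truth in subsets) {
    if (length(truth) == 0) next
    for (pred in subsets) {
      iou <- set_iou(pred, truth)
      p <- set_precision(pred, truth)
      r <- set_recall(pred, truth)
      f1 <- set_f1(pred, truth)
      # independent arithmetic from the set definitions
      ni <- length(intersect(pred, truth))
      nu <- length(union(pred, truth))
      expect_equal(iou, ni / nu)
      if (length(pred) > 0) expect_equal(p, ni / length(pred))
      expect_equal(r, ni / length(truth))
      expect_true(all(c(iou, p, r, f1) >= 0 & c(iou, p, r, f1) <= 1))
      expect_lte(iou, p + 1e-12)
      expect_lte(iou, r + 1e-12)
      expect_lte(iou, f1 + 1e-12)
      # single-label collapse to 0/1 accuracy
      if (length(pred) == 1 && length(truth) == 1) {
        acc <- as.numeric(identical(sort(pred), sort(truth)))
        expect_equal(iou, acc)
        expect_equal(f1, acc)
      }
    }
  }
})

test_that("kNN queries are exact and tie-break by ascending id", {
  set.seed(3)
  x <- matrix(rnorm(200 * 5), 200, 5)
  ids <- sprintf("p%03d", 1:200)
  index <- build_knn_index(representation_matrix(ids, x, "aa-freq"))
  # membership query returns itself at distance zero
  hit <- knn_query(index, x[17, ], 1)
  expect_equal(hit$ids, "p017")
  expect_equal(hit$distances, 0)
  # agreement with a brute-force oracle
  q <- matrix(rnorm(3 * 5), 3, 5)
  res <- knn_query(index, q, 10)
  oracle_d <- oracle_pairwise_dist(q, x)
  for (j in 1:3) {
    ord <- order(oracle_d[j, ], ids)[1:10]
    expect_equal(res$ids[j, ], ids[ord])
    expect_equal(res$distances[j, ], oracle_d[j, ord], tolerance = 1e-10)
  }
  # exact ties resolved by ascending protein id
  dup <- representation_matrix(c("z9", "a1", "m5"), matrix(0, 3, 2), "aa-freq")
  tie <- knn_query(build_knn_index(dup), c(0, 0), 3)
  expect_equal(tie$ids, c("a1", "m5", "z9"))
  expect_error(knn_query(index, x[1, ], 201), class = "psp_too_many_neighbors")
})

test_that("label aggregation implements majority with nearest-neighbor fallback", {
  ann <- annotation_table(data.frame(
    protein_id = c("n1", "n2", "n3"), ontology = "Pfam",
    label = c("X", "X", "Y")))
  expect_equal(predict_labels(c("n1", "n2", "n3"), 1, ann, "Pfam"), "X")
  expect_equal(predict_labels(c("n1", "n2", "n3"), 3, ann, "Pfam"), "X")
  # 1-1 split: no majority, fall back to the nearest neighbor
  expect_equal(predict_labels(c("n1", "n3"), 2, ann, "Pfam"), "X")
  expect_equal(predict_labels(c("n3", "n1"), 2, ann, "Pfam"), "Y")
  # union and plurality
  expect_equal(predict_labels(c("n1", "n3"), 2, ann, "Pfam", "union"),
               c("X", "Y"))
  expect_equal(predict_labels(c("n1", "n2", "n3"), 3, ann, "Pfam", "plurality"),
               "X")
  # all aggregations agree at k = 1
  for (agg in c("majority", "union", "plurality")) {
    expect_equal(predict_labels("n3", 1, ann, "Pfam", agg), "Y")
  }
})

test_that("a perfectly separable representation recovers every label", {
  # coordinates are a one-hot encoding of the true label
  labs <- rep(c("L1", "L2", "L3"), each = 10)
  ids <- sprintf("p%02d", 1:30)
  x <- model.matrix(~ 0 + factor(labs)) * 10
  m <- representation_matrix(ids, x, "aa-freq")
  ann <- annotation_table(data.frame(protein_id = ids, ontology = "fn",
                                     label = labs))
  cfg <- recovery_config(n_folds = 5, max_neighbors = 5, k_values = c(1L, 3L, 5L),
                         n_repeats = 1, seed = 4)
  rep1 <- evaluate_recovery(m, ann, "fn", cfg)
  expect_equal(rep1$aggregates$iou_mean, rep(1, 3))
  expect_equal(rep1$rer$rer, rep(0, 30))
})

test_that("evaluate_recovery is deterministic, partitions folds, and validates input", {
  corpus <- generate_corpus(family_spec(n_families = 3, members_per_family = 10,
                                        seed = 6))
  m <- pca_reduce(baseline_representation(corpus$proteins, "kmer-tfidf", k = 2),
                  projection_config(pca_components = 10))$matrix
  cfg <- recovery_config(n_folds = 5, max_neighbors = 5, k_values = c(1L, 3L),
                         n_repeats = 2, seed = 8)
  r1 <- evaluate_recovery(m, corpus$annotations, c("function", "taxonomy"), cfg)
  r2 <- evaluate_recovery(m, corpus$annotations, c("function", "taxonomy"), cfg)
  expect_identical(r1$per_protein, r2$per_protein)
  expect_identical(r1$aggregates, r2$aggregates)
  # every labeled protein scored exactly once per (ontology, k, repeat)
  counts <- table(r1$per_protein$protein_id, r1$per_protein$ontology,
                  r1$per_protein$k, r1$per_protein$`repeat`)
  expect_true(all(counts == 1))
  expect_true(all(r1$per_protein$iou >= 0 & r1$per_protein$iou <= 1))
  expect_error(evaluate_recovery(m, corpus$annotations, "Pfam", cfg),
               "available", class = "psp_unknown_ontology")
})

test_that("recovery error rate is one minus the pooled mean IoU", {
  fake <- tibble::tibble(protein_id = c("a", "a", "a", "b"),
                         iou = c(1, 0.5, 0, 1))
  rer <- recovery_error_rate(fake)
  expect_equal(rer$rer[rer$protein_id == "a"], 0.5)
  expect_equal(rer$rer[rer$protein_id == "b"], 0)
})
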