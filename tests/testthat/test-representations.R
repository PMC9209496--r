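test_that("k-mer vectors have dimension 20^k with alphabetical columns", {
  expect_length(kmer_counts("ACDEF", kmer_spec(2)), 400)
  expect_length(kmer_counts("ACDEF", kmer_spec(3)), 8000)
  nm <- kmer_names(kmer_spec(2))
  expect_equal(nm[1:3], c("AA", "AC", "AD"))
  expect_equal(nm[400], "YY")
})

test_that("k-mer counting enumerates overlapping windows", {
  v <- kmer_counts("ACACA", kmer_spec(3))
  expect_equal(unname(v["ACA"]), 2)
  expect_equal(unname(v["CAC"]), 1)
  expect_equal(sum(v), 3)  # L - k + 1

  # windows touching ambiguity letters contribute nothing
  vx <- kmer_counts("ACXCA", kmer_spec(3))
  expect_equal(sum(vx), 0)
  vy <- kmer_counts("ACACAX", kmer_spec(3))
  expect_equal(sum(vy), 3)

  # shorter than k: zero vector with a warning log, not an error
  expect_message(vs <- kmer_counts("AC", kmer_spec(3)), "shorter than k")
  expect_equal(sum(vs), 0)
})

test_that("concatenation telescopes k-mer count sums", {
  k <- 3
  for (pair in list(c("MKVLAHGKKE", "GGWWCPNDYT"), c("ACDEF", "GHIKL"))) {
    v1 <- kmer_counts(pair[1], kmer_spec(k))
    v2 <- kmer_counts(pair[2], kmer_spec(k))
    vc <- kmer_counts(paste0(pair[1], pair[2]), kmer_spec(k))
    expect_equal(sum(vc), sum(v1) + sum(v2) + (k - 1))
    expect_true(all(vc >= pmax(v1, v2) - (k - 1)))  # interior k-mers never lost
  }
})

test_that("TFIDF follows the smoothed-idf + L2 convention", {
  # 3-document toy corpus, hand-computed smoothed idf
  counts <- rbind(c(2, 1, 0), c(0, 1, 0), c(1, 1, 1))
  model <- fit_tfidf(counts)
  idf_expected <- log((1 + 3) / (1 + c(2, 3, 1))) + 1
  expect_equal(model$idf, idf_expected, tolerance = 1e-12)
  w <- transform_tfidf(model, counts)
  raw <- sweep(counts, 2, idf_expected, "*")
  expect_equal(w, raw / sqrt(rowSums(raw^2)), tolerance = 1e-12)

  # identical documents: one shared idf for present terms, unit rows
  same <- rbind(c(1, 2, 0), c(1, 2, 0), c(1, 2, 0))
  ms <- fit_tfidf(same)
  expect_equal(ms$idf[1], ms$idf[2])
  expect_equal(sqrt(rowSums(transform_tfidf(ms, same)^2)), rep(1, 3))

  # single-document corpus: transform proportional to L2-normalized counts
  one <- matrix(c(3, 4, 0), 1)
  w1 <- transform_tfidf(fit_tfidf(one), one)
  expect_equal(as.numeric(w1), c(3, 4, 0) / 5, tolerance = 1e-12)

  expect_error(transform_tfidf(list(), counts), class = "psp_usage")
})

test_that("TFIDF preserves the zero pattern of the counts", {
  ps <- generate_corpus(family_spec(n_families = 3, members_per_family = 5,
                                    seed = 4))$proteins
  counts <- kmer_count_matrix(ps, kmer_spec(2))
  w <- transform_tfidf(fit_tfidf(counts), counts)
  expect_identical(w == 0, as.matrix(counts) == 0)
})

test_that("amino-acid frequencies normalize and ignore sequence order", {
  expect_equal(aa_frequencies("AAAA")[["A"]], 1)
  f <- aa_frequencies("ACAC")
  expect_equal(unname(f[c("A", "C")]), c(0.5, 0.5))
  expect_equal(sum(aa_frequencies("MKVLAHGKKEWW")), 1, tolerance = 1e-12)
  shuf <- paste(rev(strsplit("MKVLAHGKKEWW", "")[[1]]), collapse = "")
  expect_equal(aa_frequencies("MKVLAHGKKEWW"), aa_frequencies(shuf))
  # ambiguity ignored in the denominator
  expect_equal(unname(aa_frequencies("AXA")[["A"]]), 1)
  expect_error(aa_frequencies("XXX"), class = "psp_no_canonical")
})

test_that("baseline_representation builds tagged matrices", {
  ps <- tiny_proteins()
  mk <- baseline_representation(ps, "kmer-tfidf", k = 2)
  expect_equal(mk$method, "kmer-tfidf")
  expect_equal(dim(mk$values), c(4, 400))
  expect_equal(mk$ids, ps$id)
  ma <- baseline_representation(ps, "aa-freq")
  expect_equal(ma$method, "aa-freq")
  expect_equal(dim(ma$values), c(4, 20))
  expect_equal(rowSums(ma$values), setNames(rep(1, 4), ps$id), tolerance = 1e-12)
})
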