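test_that("corpus generation is reproducible and structurally correct", {
  spec <- family_spec(n_families = 3, members_per_family = 6, seed = 20)
  c1 <- generate_corpus(spec)
  c2 <- generate_corpus(spec)
  expect_identical(c1$proteins, c2$proteins)
  expect_true(annotations_equal(c1$annotations, c2$annotations))
  expect_equal(nrow(c1$proteins), 18)
  # fixed total length: background + motifs
  exp_len <- spec$background_length + spec$motifs_per_family * spec$motif_length
  expect_true(all(nchar(c1$proteins$sequence) == exp_len))
  # one function label per member, equal to the truth family
  fn <- vapply(c1$proteins$id, function(p)
    labels_for(c1$annotations, p, "function"), "")
  expect_equal(unname(fn), c1$truth$family)
  expect_setequal(ontologies(c1$annotations),
                  c("function", "domain", "taxonomy"))
})

test_that("zero substitution rate leaves family motifs verbatim in every member", {
  spec <- family_spec(n_families = 2, members_per_family = 5,
                      substitution_rate = 0, seed = 23)
  corpus <- generate_corpus(spec)
  # recover each family's motifs from the recorded start positions
  for (i in seq_len(nrow(corpus$proteins))) {
    starts <- corpus$truth$motif_starts[[i]]
    seqs <- corpus$proteins$sequence[i]
    fam_members <- which(corpus$truth$family == corpus$truth$family[i])
    # every member of a family carries identical motif substrings
    motif_i <- sort(substring(seqs, starts, starts + spec$motif_length - 1))
    j <- fam_members[1]
    motif_j <- sort(substring(corpus$proteins$sequence[j],
                              corpus$truth$motif_starts[[j]],
                              corpus$truth$motif_starts[[j]] + spec$motif_length - 1))
    expect_equal(motif_i, motif_j)
  }
})

test_that("taxonomy labels are independent of family; function labels are not", {
  corpus <- generate_corpus(family_spec(n_families = 4, members_per_family = 30,
                                        n_taxa = 3, seed = 29))
  fam <- corpus$truth$family
  tax <- vapply(corpus$truth$id, function(p)
    labels_for(corpus$annotations, p, "taxonomy"), "")
  chi <- suppressWarnings(stats::chisq.test(table(fam, tax)))
  expect_gt(chi$p.value, 0.01)
  # sequences carry the family signal: motif 3-mers distinguish families
  m <- baseline_representation(corpus$proteins, "kmer-tfidf", k = 3)
  d <- euclidean_distances(m, m$ids)
  same <- outer(fam, fam, "==") & upper.tri(d)
  diff_f <- outer(fam, fam, "!=") & upper.tri(d)
  expect_lt(mean(d[same]), mean(d[diff_f]))
})

test_that("generated sequences survive a FASTA round trip untouched", {
  corpus <- generate_corpus(family_spec(n_families = 2, members_per_family = 4,
                                        seed = 31))
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(corpus$proteins, f)
  back <- read_fasta(f)
  expect_equal(back$id, corpus$proteins$id)
  expect_equal(back$sequence, corpus$proteins$sequence)
})

test_that("shared-motif injection draws the listed families together", {
  spec <- family_spec(n_families = 3, members_per_family = 10,
                      substitution_rate = 0.05, seed = 37)
  corpus <- generate_corpus(spec)
  motif <- "WWHHCCPPYYKK"
  injected <- inject_shared_motif(corpus, c("F01", "F02"), motif)
  # untouched family unchanged
  f3 <- corpus$truth$id[corpus$truth$family == "F03"]
  expect_equal(injected$proteins$sequence[match(f3, injected$proteins$id)],
               corpus$proteins$sequence[match(f3, corpus$proteins$id)])
  # shared domain label on all injected members
  f1 <- corpus$truth$id[corpus$truth$family == "F01"][1]
  expect_true(any(grepl("SHARED", labels_for(injected$annotations, f1, "domain"))))
  # between-family k-mer distance drops after injection
  mean_between <- function(cp) {
    m <- baseline_representation(cp$proteins, "kmer-tfidf", k = 2)
    fam <- cp$truth$family
    a <- cp$truth$id[fam == "F01"]; b <- cp$truth$id[fam == "F02"]
    mean(euclidean_distances(m, a, b))
  }
  expect_lt(mean_between(injected), mean_between(corpus))

  expect_identical(inject_shared_motif(corpus, character(0), motif), corpus)
  expect_error(inject_shared_motif(corpus, "F09", motif),
               class = "psp_unknown_family")
  long_motif <- paste(rep("A", spec$background_length + 1), collapse = "")
  expect_error(inject_shared_motif(corpus, "F01", long_motif),
               class = "psp_motif_too_long")
})
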