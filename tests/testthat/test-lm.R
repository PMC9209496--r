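tiny_cfg <- function(...) {
  lm_config(num_layers = 2, hidden_units = 8, embedding_dim = 8,
            batch_size = 4, warmup_steps = 10, seed = 1, ...)
}

test_that("tokenize maps residues, clips long sequences, accepts ambiguity", {
  cfg <- tiny_cfg()
  expect_length(tokenize("MKV", cfg), 3)
  long <- paste(rep("A", 1600), collapse = "")
  expect_length(tokenize(long, lm_config(seed = 1)), 1500)
  tk <- tokenize("MXV", cfg)
  expect_equal(cfg$vocabulary[tk[2]], "X")
  expect_error(tokenize("M1V", cfg), "'1' at position 2", class = "psp_tokenize")
})

test_that("ECE of a uniform model is the alphabet size; a confident predictor approaches 1", {
  cfg <- tiny_cfg()
  ps <- protein_set(c("a", "b"), c("MKVLAHG", "AAAAAAAA"))
  expect_equal(ece(lm_uniform(cfg), ps), 20, tolerance = 1e-12)

  # bias-only head locked onto A scores ~1 on an all-A sequence
  m <- lm_uniform(cfg)
  m$params$fwd.ob[1] <- 60  # class A
  m$params$bwd.ob[1] <- 60
  only_a <- protein_set("a", paste(rep("A", 30), collapse = ""))
  expect_equal(ece(m, only_a), 1, tolerance = 1e-9)
})

test_that("ECE matches a hand-computed cross-entropy for fixed output distributions", {
  # with zero output weights and a fixed bias vector, every position gets the
  # same softmax distribution; the expected ECE follows by direct arithmetic
  cfg <- tiny_cfg()
  m <- lm_uniform(cfg)
  bias <- c(2, 1, rep(0, 18))
  m$params$fwd.ob <- bias
  m$params$bwd.ob <- bias
  ps <- protein_set(c("s1", "s2"), c("ACA", "CC"))
  p <- exp(bias) / sum(exp(bias))  # class order = alphabetical residues
  # forward targets: s1 -> C, A ; s2 -> C.  backward targets: s1 -> A, C ; s2 -> C
  ce <- -c(log(p[2]), log(p[1]), log(p[2]), log(p[1]), log(p[2]), log(p[2]))
  expect_equal(ece(m, ps), exp(mean(ce)), tolerance = 1e-12)
})

test_that("ECE is permutation invariant and >= 1 for untrained models", {
  cfg <- tiny_cfg()
  ps <- generate_corpus(family_spec(n_families = 2, members_per_family = 6,
                                    seed = 9))$proteins
  m <- lm_init(cfg)
  e1 <- ece(m, ps)
  shuffled <- ps[rev(seq_len(nrow(ps))), ]
  class(shuffled) <- class(ps)
  expect_equal(ece(m, shuffled), e1, tolerance = 1e-10)
  expect_gt(e1, 1)
  expect_lt(abs(e1 - 20), 2)  # random init stays near the alphabet size
})

test_that("ECE errors when no sequence yields prediction targets", {
  cfg <- tiny_cfg()
  singles <- protein_set(c("a", "b"), c("M", "K"))
  expect_error(ece(lm_uniform(cfg), singles), class = "psp_no_targets")
})

test_that("embeddings have dimension 2 x hidden_units and ignore batch padding", {
  cfg <- tiny_cfg()
  m <- lm_init(cfg)
  ps <- protein_set(c("short", "long", "mid"),
                    c("MK", "MKVLAHGKKEWWPHE", "ACDEF"))
  emb <- embed_proteins(m, ps)
  expect_equal(dim(emb$values), c(3, 16))
  expect_equal(emb$method, "lm-mean")
  # alone vs padded within a batch: identical vectors
  solo <- embed_proteins(m, protein_set("short", "MK"))
  expect_equal(unname(emb$values["short", ]), unname(solo$values[1, ]),
               tolerance = 1e-12)
  # length-1 sequence: embedding equals its single position vector
  one <- embed_proteins(m, protein_set("one", "W"))
  expect_equal(dim(one$values), c(1, 16))
  # determinism
  again <- embed_proteins(m, ps)
  expect_identical(emb$values, again$values)
})

test_that("training is deterministic, rejects bad inputs, and reduces the loss", {
  cfg <- tiny_cfg()
  ps <- generate_corpus(family_spec(n_families = 2, members_per_family = 10,
                                    background_length = 20, motif_length = 6,
                                    seed = 21))$proteins
  expect_error(train_lm(ps, cfg, steps = 0), class = "psp_bad_steps")
  empty <- protein_set(character(0), character(0))
  expect_error(train_lm(empty, cfg, steps = 1), class = "psp_empty_corpus")
  expect_error(train_lm(protein_set("a", "M"), cfg, steps = 1),
               class = "psp_no_targets")

  m1 <- train_lm(ps, cfg, steps = 30)
  m2 <- train_lm(ps, cfg, steps = 30)
  expect_identical(m1$training_log, m2$training_log)
  expect_lt(mean(tail(m1$training_log, 5)), mean(head(m1$training_log, 5)))
})

test_that("checkpoint save/load round trips weights, config and vocabulary", {
  cfg <- tiny_cfg()
  ps <- protein_set(c("a", "b"), c("MKVLAHG", "GGWWCPN"))
  m <- train_lm(ps, cfg, steps = 5)
  dir <- withr::local_tempdir()
  save_lm(m, dir)
  back <- load_lm(dir)
  expect_identical(back$params, m$params)
  expect_identical(back$training_log, m$training_log)
  expect_identical(back$config$vocabulary, m$config$vocabulary)
  expect_equal(ece(back, ps), ece(m, ps), tolerance = 1e-12)
})
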