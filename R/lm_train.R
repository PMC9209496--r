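#' Train the bidirectional protein language model
#'
#' Optimizes the sum of the forward-direction (next residue) and
#' backward-direction (previous residue) mean cross-entropies with AdamW,
#' using a linear learning-rate warmup over `warmup_steps` followed by a
#' constant rate, and global gradient-norm clipping.  Identical seed, config
#' and corpus give bit-identical training logs.
#'
#' @param corpus a [protein_set] (non-empty; at least one sequence of
#'   length >= 2).
#' @param config an [lm_config].
#' @param steps number of optimizer steps (>= 1).
#' @param verbose log the loss every 50 steps.
#' @return a `trained_lm`: list with `config`, `params`, `training_log`
#'   (per-step loss).
#' @export
train_lm <- function(corpus, config, steps, verbose = FALSE) {
  stopifnot(inherits(config, "lm_config"))
  if (nrow(corpus) == 0) psp_abort("training corpus is empty", "psp_empty_corpus")
  if (!is.numeric(steps) || steps < 1) {
    psp_abort("steps must be >= 1", "psp_bad_steps")
  }
  toks_all <- lapply(corpus$sequence, tokenize, config = config)
  if (all(lengths(toks_all) < 2)) {
    psp_abort("all sequences are shorter than 2 residues; no prediction targets",
              "psp_no_targets")
  }
  model <- with_seed(config$seed, {
    params <- psp_init_params(config)
    mstate <- lapply(params, function(p) p * 0)
    vstate <- lapply(params, function(p) p * 0)
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    log_loss <- numeric(steps)
    n <- length(toks_all)
    for (step in seq_len(steps)) {
      sel <- sample.int(n, min(config$batch_size, n))
      pass <- psp_lm_pass(params, config, toks_all[sel], want_grads = TRUE)
      loss <- sum(ifelse(pass$n > 0, pass$ce_sum / pmax(pass$n, 1L), 0))
      log_loss[step] <- loss
      g <- pass$grads
      # global-norm clip
      gn <- sqrt(sum(vapply(g, function(x) sum(x^2), 0)))
      if (is.finite(gn) && gn > config$clip_norm) {
        g <- lapply(g, function(x) x * (config$clip_norm / gn))
      }
      lr <- config$learning_rate *
        if (config$warmup_steps > 0) min(1, step / config$warmup_steps) else 1
      for (nm in names(params)) {
        mstate[[nm]] <- beta1 * mstate[[nm]] + (1 - beta1) * g[[nm]]
        vstate[[nm]] <- beta2 * vstate[[nm]] + (1 - beta2) * g[[nm]]^2
        mhat <- mstate[[nm]] / (1 - beta1^step)
        vhat <- vstate[[nm]] / (1 - beta2^step)
        params[[nm]] <- params[[nm]] - lr * (mhat / (sqrt(vhat) + eps) +
                                               config$weight_decay * params[[nm]])
      }
      if (verbose && step %% 50 == 0) {
        psp_log(sprintf("step %d/%d loss %.4f", step, steps, loss))
      }
    }
    list(params = params, training_log = log_loss)
  })
  structure(list(config = config, params = model$params,
                 training_log = model$training_log),
            class = "trained_lm")
}

#' Initialize an untrained language model
#'
#' Random initialization under the config seed; useful as the before-training
#' reference in ECE comparisons.
#'
#' @param config an [lm_config].
#' @return a `trained_lm` with empty training log.
#' @export
lm_init <- function(config) {
  stopifnot(inherits(config, "lm_config"))
  params <- with_seed(config$seed, psp_init_params(config))
  structure(list(config = config, params = params, training_log = numeric(0)),
            class = "trained_lm")
}

#' A model that emits the uniform distribution over canonical residues
#'
#' Both direction heads are zeroed, so every position receives probability
#' 1/20 for each canonical residue and [ece()] returns exactly 20.
#'
#' @param config an [lm_config].
#' @return a `trained_lm`.
#' @export
lm_uniform <- function(config) {
  m <- lm_init(config)
  for (d in c("fwd", "bwd")) {
    m$params[[paste0(d, ".oW")]][] <- 0
    m$params[[paste0(d, ".ob")]][] <- 0
  }
  m
}

#' @export
print.trained_lm <- function(x, ...) {
  cat(sprintf("<trained_lm> %d layers x %d units/direction, %d training steps logged\n",
              x$config$num_layers, x$config$hidden_units, length(x$training_log)))
  invisible(x)
}

#' Exponential cross-entropy (perplexity) of a language model
#'
#' Returns `exp` of the mean per-position cross-entropy in natural-log
#' units, pooled over both directions and all prediction targets of all
#' sequences.  First residues contribute no backward target and last
#' residues no forward target; ambiguity residues are excluded as targets.
#' A uniform predictor over the 20-residue output alphabet scores exactly
#' 20; a perfect predictor scores 1.
#'
#' @param model a `trained_lm`.
#' @param eval_set a [protein_set].
#' @param batch_size sequences per evaluation batch.
#' @return ECE, a real >= 1.
#' @export
ece <- function(model, eval_set, batch_size = 64L) {
  stopifnot(inherits(model, "trained_lm"))
  if (nrow(eval_set) == 0) psp_abort("evaluation set is empty", "psp_empty_corpus")
  toks <- lapply(eval_set$sequence, tokenize, config = model$config)
  total_ce <- 0; total_n <- 0L
  for (start in seq(1, length(toks), by = batch_size)) {
    chunk <- toks[start:min(start + batch_size - 1, length(toks))]
    pass <- psp_lm_pass(model$params, model$config, chunk)
    total_ce <- total_ce + sum(pass$ce_sum)
    total_n <- total_n + sum(pass$n)
  }
  if (total_n == 0) {
    psp_abort("no prediction targets in evaluation set (all sequences length 1?)",
              "psp_no_targets")
  }
  exp(total_ce / total_n)
}

#' Mean-pooled bidirectional embeddings
#'
#' For each protein the final recurrent layer's forward and backward hidden
#' states are concatenated at every residue position and averaged over
#' positions, yielding a `2 * hidden_units`-dimensional vector (2,048 at the
#' full-scale configuration).  Padding within a batch does not affect the
#' result.
#'
#' @param model a `trained_lm`.
#' @param proteins a [protein_set].
#' @param batch_size sequences per forward batch.
#' @return a [representation_matrix] with method `"lm-mean"`.
#' @export
embed_proteins <- function(model, proteins, batch_size = 64L) {
  stopifnot(inherits(model, "trained_lm"))
  H <- model$config$hidden_units
  out <- matrix(0, nrow(proteins), 2 * H)
  toks <- lapply(proteins$sequence, tokenize, config = model$config)
  for (start in seq(1, length(toks), by = batch_size)) {
    idx <- start:min(start + batch_size - 1, length(toks))
    pass <- psp_lm_pass(model$params, model$config, toks[idx],
                        want_states = TRUE)
    for (j in seq_along(idx)) {
      L <- length(toks[[idx[j]]])
      acc <- numeric(2 * H)
      for (t in seq_len(L)) {
        acc <- acc + c(pass$states$fwd[[t]][j, ], pass$states$bwd[[t]][j, ])
      }
      out[idx[j], ] <- acc / L
    }
  }
  representation_matrix(proteins$id, out, "lm-mean")
}

#' Save / load a language-model checkpoint
#'
#' A checkpoint is a directory holding `config.json`, `vocabulary.txt` (one
#' token per line, order significant), `weights.bin` (little-endian float64
#' stream) and `weights.json` (parameter names and shapes, plus the training
#' log).  Round trips are bit-exact.
#'
#' @param model a `trained_lm`.
#' @param dir checkpoint directory (created if absent).
#' @return `dir` (for `save_lm`) or a `trained_lm` (for `load_lm`).
#' @export
save_lm <- function(model, dir) {
  stopifnot(inherits(model, "trained_lm"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- model$config
  cfg_json <- cfg[setdiff(names(cfg), "vocabulary")]
  jsonlite::write_json(cfg_json, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(cfg$vocabulary, file.path(dir, "vocabulary.txt"))
  shapes <- lapply(model$params, function(p) if (is.matrix(p)) dim(p) else length(p))
  jsonlite::write_json(list(shapes = shapes,
                            n_log = length(model$training_log)),
                       file.path(dir, "weights.json"), digits = NA)
  con <- file(file.path(dir, "weights.bin"), "wb")
  on.exit(close(con))
  for (nm in names(model$params)) {
    writeBin(as.vector(model$params[[nm]]), con, size = 8, endian = "little")
  }
  writeBin(model$training_log, con, size = 8, endian = "little")
  invisible(dir)
}

#' @rdname save_lm
#' @export
load_lm <- function(dir) {
  cfg_json <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  config <- lm_config(num_layers = cfg_json$num_layers,
                      hidden_units = cfg_json$hidden_units,
                      embedding_dim = cfg_json$embedding_dim,
                      max_sequence_length = cfg_json$max_sequence_length,
                      learning_rate = cfg_json$learning_rate,
                      warmup_steps = cfg_json$warmup_steps,
                      batch_size = cfg_json$batch_size,
                      weight_decay = cfg_json$weight_decay,
                      clip_norm = cfg_json$clip_norm,
                      seed = cfg_json$seed)
  config$vocabulary <- readLines(file.path(dir, "vocabulary.txt"))
  meta <- jsonlite::read_json(file.path(dir, "weights.json"), simplifyVector = TRUE)
  con <- file(file.path(dir, "weights.bin"), "rb")
  on.exit(close(con))
  params <- list()
  for (nm in names(meta$shapes)) {
    sh <- meta$shapes[[nm]]
    n <- prod(sh)
    vals <- readBin(con, "double", n = n, size = 8, endian = "little")
    if (length(vals) != n) psp_abort("checkpoint truncated", "psp_integrity")
    params[[nm]] <- if (length(sh) == 2) matrix(vals, sh[1], sh[2]) else vals
  }
  n_log <- as.integer(meta$n_log)
  training_log <- readBin(con, "double", n = n_log, size = 8, endian = "little")
  if (length(training_log) != n_log) psp_abort("checkpoint truncated", "psp_integrity")
  structure(list(config = config, params = params,
                 training_log = training_log),
            class = "trained_lm")
}
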