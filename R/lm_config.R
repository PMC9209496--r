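#' Vocabulary of the protein language model
#'
#' Ordered token list: padding / start / stop specials, the 20 canonical
#' residues in alphabetical order, then the six ambiguity letters
#' (B, J, O, U, X, Z).  Ambiguity tokens participate as model inputs but are
#' never prediction targets; the softmax output layer covers exactly the 20
#' canonical residues.
#'
#' @return character vector of tokens (order significant).
#' @export
lm_vocabulary <- function() {
  c("<pad>", "<s>", "</s>", PSP_CANONICAL, PSP_AMBIGUITY)
}

# index of first canonical token within the vocabulary
PSP_VOCAB_OFFSET <- 3L

#' Configuration of the bidirectional recurrent language model
#'
#' Defaults mirror the full-scale training setup (3 BiLSTM layers of 1024
#' hidden units per direction, 1,500-residue clipping, AdamW at learning
#' rate 1e-3 with an 8,000-step linear warmup, mini-batches of 1024).
#' Tests and desk-scale runs pass much smaller values; the architecture is
#' the same at every scale.  The embedding produced downstream has dimension
#' `2 * hidden_units` (forward and backward states concatenated).
#'
#' @param num_layers number of stacked recurrent layers per direction.
#' @param hidden_units LSTM state size per direction.
#' @param embedding_dim input token-embedding size (defaults to
#'   `hidden_units`).
#' @param max_sequence_length clip length in residues.
#' @param learning_rate AdamW learning rate after warmup.
#' @param warmup_steps linear warmup length in optimizer steps.
#' @param batch_size sequences per optimizer step.
#' @param weight_decay decoupled AdamW weight decay.
#' @param clip_norm global gradient-norm clip.
#' @param seed integer seed controlling initialization and batch sampling.
#' @return a `lm_config` list.
#' @export
lm_config <- function(num_layers = 3L, hidden_units = 1024L,
                      embedding_dim = hidden_units,
                      max_sequence_length = 1500L,
                      learning_rate = 1e-3, warmup_steps = 8000L,
                      batch_size = 1024L, weight_decay = 0.01,
                      clip_norm = 1.0, seed = 0L) {
  stopifnot(num_layers >= 1, hidden_units >= 1, embedding_dim >= 1,
            max_sequence_length >= 1, learning_rate > 0, warmup_steps >= 0,
            batch_size >= 1)
  structure(list(num_layers = as.integer(num_layers),
                 hidden_units = as.integer(hidden_units),
                 embedding_dim = as.integer(embedding_dim),
                 max_sequence_length = as.integer(max_sequence_length),
                 learning_rate = learning_rate,
                 warmup_steps = as.integer(warmup_steps),
                 batch_size = as.integer(batch_size),
                 weight_decay = weight_decay,
                 clip_norm = clip_norm,
                 vocabulary = lm_vocabulary(),
                 seed = as.integer(seed)),
            class = "lm_config")
}

#' Tokenize a protein sequence
#'
#' Residues map to vocabulary indices; sequences longer than the configured
#' clip length are truncated to their first `max_sequence_length` residues.
#' Ambiguity letters map to their dedicated tokens.
#'
#' @param sequence a single amino-acid sequence string.
#' @param config an [lm_config].
#' @return integer vector of vocabulary indices.
#' @export
tokenize <- function(sequence, config) {
  stopifnot(is.character(sequence), length(sequence) == 1, nchar(sequence) >= 1)
  chars <- strsplit(toupper(sequence), "")[[1]]
  idx <- match(chars, config$vocabulary)
  if (anyNA(idx)) {
    p <- which(is.na(idx))[1]
    psp_abort(sprintf("cannot tokenize character '%s' at position %d", chars[p], p),
              "psp_tokenize")
  }
  if (length(idx) > config$max_sequence_length) {
    idx <- idx[seq_len(config$max_sequence_length)]
  }
  as.integer(idx)
}
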