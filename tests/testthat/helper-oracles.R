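# Shared fixtures and independent oracles used across test files.

tiny_proteins <- function() {
  protein_set(c("p1", "p2", "p3", "p4"),
              c("MKVLAHGKKE", "MKVLAHGQKE", "GGWWCPNDYT", "ACDEFGHIKL"))
}

# Independent affine-gap global aligner (Gotoh), used as the oracle for
# percent_identity().  Scoring: BLOSUM62, a gap of length L costs
# open + L * ext.  Returns percent identity over the full alignment length
# (gap columns included).
oracle_percent_identity <- function(a, b, open = 10, ext = 0.5) {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  sm <- e$BLOSUM62
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)  # ends in match/mismatch
  X <- matrix(NEG, n + 1, m + 1)  # ends in gap in b (A aligned to '-')
  Y <- matrix(NEG, n + 1, m + 1)  # ends in gap in a
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -open - ext * (i - 1)
  for (j in 2:(m + 1)) Y[1, j] <- -open - ext * (j - 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- sm[A[i - 1], B[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
    }
  }
  # traceback from the best final state, counting identities and columns
  state <- which.max(c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1]))
  i <- n + 1; j <- m + 1
  ident <- 0L; cols <- 0L
  tol <- 1e-9
  while (i > 1 || j > 1) {
    cols <- cols + 1L
    if (state == 1) {
      s <- sm[A[i - 1], B[j - 1]]
      if (A[i - 1] == B[j - 1]) ident <- ident + 1L
      prev <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      state <- which(prev >= max(prev) - tol)[1]
      i <- i - 1; j <- j - 1
    } else if (state == 2) {
      cand_m <- M[i - 1, j] - open - ext
      cand_x <- X[i - 1, j] - ext
      state <- if (cand_m >= cand_x - tol) 1 else 2
      i <- i - 1
    } else {
      cand_m <- M[i, j - 1] - open - ext
      cand_y <- Y[i, j - 1] - ext
      state <- if (cand_m >= cand_y - tol) 1 else 3
      j <- j - 1
    }
    if (i == 1 && j > 1 && state != 3) state <- 3
    if (j == 1 && i > 1 && state != 2) state <- 2
  }
  list(score = max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1]),
       pid = 100 * ident / cols, alen = cols)
}

# oracle score only (no traceback ambiguity): optimal global affine score
oracle_alignment_score <- function(a, b, open = 10, ext = 0.5) {
  oracle_percent_identity(a, b, open, ext)$score
}

# brute-force per-pair Euclidean distances
oracle_pairwise_dist <- function(a, b) {
  out <- matrix(0, nrow(a), nrow(b))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      out[i, j] <- sqrt(sum((a[i, ] - b[j, ])^2))
    }
  }
  out
}

# all subsets of a character universe (including the empty set)
all_subsets <- function(universe) {
  n <- length(universe)
  lapply(seq_len(2^n) - 1, function(mask) {
    universe[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
  })
}
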