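#' @keywords internal
"_PACKAGE"

#' @importFrom tibble tibble as_tibble
#' @importFrom stats prcomp rnorm runif sd setNames
#' @importFrom utils head read.delim write.table
NULL

# Canonical residue alphabet, alphabetical; ambiguity letters handled per module.
PSP_CANONICAL <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
PSP_AMBIGUITY <- c("B", "J", "O", "U", "X", "Z")

psp_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "protspace_error")))
}

#' Derive a child seed from a global seed
#'
#' All multi-stage pipelines fork one user-supplied seed into per-stage seeds
#' so that stages are individually reproducible.  The fork is a fixed affine
#' map kept inside 32-bit integer range.
#'
#' @param seed integer scalar.
#' @param index nonnegative integer identifying the stage or repeat.
#' @return an integer seed.
#' @export
fork_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(index))
  as.integer((abs(seed) * 1009L + 99991L * (index + 1L)) %% .Machine$integer.max)
}

# Evaluate `expr` under a local RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

psp_log <- function(..., level = "INFO") {
  message(sprintf("[protspace %s] %s", level, paste0(...)))
}
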