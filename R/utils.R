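# Internal helpers shared across modules.

#' @importFrom stats runif rnorm rbinom dist prcomp predict setNames binomial glm
#' @importFrom utils write.csv read.csv head
NULL

# The 20 standard amino acids in alphabetical one-letter order; this order
# fixes the composition block of every feature vector and all CSV layouts.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# stream. `seed = NULL` means: use the current stream as-is.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Derive a sub-seed from a base seed, kept within 32-bit integer range.
deriveSeed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}

stopIfNot <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
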