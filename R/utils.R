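#' @importFrom stats rpois rbinom rmultinom runif optim setNames
#' @importFrom utils read.delim write.table packageVersion
NULL

BASES <- c("A", "C", "G", "T")

# three-letter amino-acid codes for HGVS protein names; "*" is the stop symbol
AA3 <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
  E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
  Y = "Tyr", V = "Val", `*` = "Ter"
)
AA1 <- setNames(names(AA3), AA3)

# Derive a reproducible substream seed from a master seed and a stage key.
# Keeps the result in the 32-bit signed range expected by set.seed().
derive_seed <- function(seed, key) {
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647L)
}

# Evaluate expr under a derived seed, restoring the caller's RNG state after.
with_substream <- function(seed, key, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(seed, key))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
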