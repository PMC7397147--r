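#' @keywords internal
"_PACKAGE"

#' @importFrom methods is
#' @importFrom stats runif rbinom setNames
#' @importFrom utils read.delim write.table head
NULL

DNA_BASES <- c("A", "C", "G", "T")

# random DNA string of length n using the current RNG stream
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# reverse complement of a plain character vector of sequences
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

complement_base <- function(b) {
  c(A = "T", C = "G", G = "C", T = "A", N = "N")[[toupper(b)]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# run `expr` with the RNG seeded to `seed`, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
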