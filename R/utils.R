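# Internal helpers shared across modules.

.rhdtyper_cache <- new.env(parent = emptyenv())

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores the global RNG state so that package internals
#' (notably the fixed-seed locus builder) never perturb user randomness.
#' @noRd
withSeed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' @noRd
randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## deterministic base swap used to derive RHCE diagnostic bases and
## spike-in alternates; always yields a different base
.BASE_SWAP <- c(A = "G", G = "A", C = "T", T = "C")

#' @noRd
swapBase <- function(b) unname(.BASE_SWAP[b])

#' Reverse complement of a plain character sequence
#' @noRd
revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' All start positions of an exact substring match (fixed, no regex)
#' @noRd
findExact <- function(pattern, subject) {
  if (nchar(subject) < nchar(pattern) || nchar(pattern) == 0L) return(integer(0))
  hits <- gregexpr(pattern, subject, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) integer(0) else as.integer(hits)
}

#' Positions at which two equal-length sequences differ
#' @noRd
mismatchPositions <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  which(charToRaw(a) != charToRaw(b))
}

#' @noRd
substrReplace <- function(x, pos, value) {
  substr(x, pos, pos + nchar(value) - 1L) <- value
  x
}
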