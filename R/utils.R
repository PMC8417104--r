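## Internal helpers: deterministic sub-seeding, CDR3 translation, misc.

#' Derive a reproducible sub-seed from a master seed and string labels
#'
#' Polynomial rolling hash over the UTF-8 bytes of the labels, folded into
#' the master seed modulo the Mersenne prime 2^31 - 1, so every derived
#' seed is a valid positive 32-bit R integer. Used throughout the pipeline
#' to give each (sample, analysis) its own reproducible RNG stream.
#'
#' @param seed master seed (single integer-like value)
#' @param ... character or numeric labels mixed into the hash
#' @return a single integer in [1, 2^31 - 2]
#' @export
deriveSeed <- function(seed, ...) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  mod <- 2147483647
  h <- as.numeric(seed) %% mod
  for (lab in list(...)) {
    for (ch in utf8ToInt(paste(as.character(lab), collapse = "\r"))) {
      h <- (h * 131 + ch) %% mod
    }
    h <- (h * 131 + 7) %% mod
  }
  as.integer(h %% (mod - 2) + 1)
}

## Run `expr` under a local RNG seeded with `seed`; global RNG untouched.
## `seed = NULL` means: use the current RNG stream as-is.
withSeed <- function(seed, expr) {
  if (is.null(seed)) expr
  else withr::with_seed(as.integer(seed), expr)
}

## Codon -> amino-acid lookup from the standard genetic code (Biostrings).
.codonTable <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

#' Translate CDR3 nucleotide sequences
#'
#' Frame-0 translation with the standard genetic code. Sequences whose
#' length is not a multiple of 3 translate to the frameshift marker
#' \code{"_"}; stop codons translate to \code{"*"} within the product.
#'
#' @param nt character vector of A/C/G/T strings
#' @return character vector of amino-acid strings
#' @export
translateCdr3 <- function(nt) {
  out <- character(length(nt))
  len <- nchar(nt)
  bad <- len %% 3L != 0L | len == 0L
  out[bad] <- "_"
  ok <- which(!bad)
  if (length(ok)) {
    aa <- Biostrings::translate(Biostrings::DNAStringSet(nt[ok]),
                                no.init.codon = TRUE)
    out[ok] <- as.character(aa)
  }
  out
}

## Strip allele suffix ("*01"), composite hit lists ("TRBV9*00(123),TRBV5..")
## and score parentheses from MiXCR/AIRR segment calls.
normalizeSegment <- function(x) {
  x <- sub(",.*$", "", x)
  x <- sub("\\(.*$", "", x)
  sub("\\*.*$", "", x)
}

## Longest common prefix length of two strings (vectorized over x).
.lcpLength <- function(x, ref) {
  nref <- nchar(ref)
  vapply(x, function(s) {
    m <- min(nchar(s), nref)
    if (m == 0L) return(0L)
    a <- utf8ToInt(substr(s, 1L, m))
    b <- utf8ToInt(substr(ref, 1L, m))
    neq <- which(a != b)
    if (length(neq)) neq[1L] - 1L else m
  }, integer(1), USE.NAMES = FALSE)
}

.reverseString <- function(x) {
  vapply(strsplit(x, NULL), function(ch) paste(rev(ch), collapse = ""),
         character(1), USE.NAMES = FALSE)
}

## Largest-remainder apportionment of `total` integer units proportional to
## weights w, every part >= 1. Conserves the total exactly.
largestRemainder <- function(w, total) {
  n <- length(w)
  stopifnot(n >= 1L, total >= n, all(w > 0))
  t <- w / sum(w) * total
  base <- floor(t)
  rem <- total - sum(base)
  if (rem > 0) {
    give <- order(t - base, decreasing = TRUE)[seq_len(rem)]
    base[give] <- base[give] + 1
  }
  ## enforce the >= 1 floor, taking units back from the largest parts
  zero <- which(base == 0)
  for (i in zero) {
    donor <- which.max(base)
    base[donor] <- base[donor] - 1
    base[i] <- 1
  }
  as.integer(base)
}
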