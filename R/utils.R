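#' @include AllClasses.R
NULL

# Small deterministic linear congruential generator used by the fixture
# builders so they never touch (or disturb) R's global RNG stream.
# Constants are the classic Numerical Recipes LCG modulo 2^32.
lcgNew <- function(seed) {
    env <- new.env(parent = emptyenv())
    env$state <- as.numeric(seed) %% 2^32
    env
}

lcgNext <- function(rng) {
    rng$state <- (1664525 * rng$state + 1013904223) %% 2^32
    rng$state
}

# integer in 1..n
lcgInt <- function(rng, n) {
    as.integer(lcgNext(rng) %% n) + 1L
}

# deterministic nucleotide string over the given alphabet
lcgSeq <- function(rng, n, alphabet = c("A", "C", "G")) {
    paste(alphabet[vapply(seq_len(n), function(i) lcgInt(rng, length(alphabet)),
                          integer(1))], collapse = "")
}

# split a string into a character vector of single letters
strChars <- function(s) strsplit(as.character(s), "", fixed = TRUE)[[1]]

charsToStr <- function(ch) paste(ch, collapse = "")

degapStr <- function(s) gsub("-", "", as.character(s), fixed = TRUE)

revComp <- function(s) as.character(reverseComplement(DNAString(as.character(s))))

# exon start/end offsets (1-based, within the CDS) from exon lengths
exonOffsets <- function(exonLengths) {
    ends <- cumsum(exonLengths)
    cbind(start = c(1L, head(ends, -1L) + 1L), end = ends)
}

stopCodons <- function() c("TAA", "TAG", "TGA")

# first in-frame stop at or after `from` (1-based), frame anchored at `from`;
# returns start position of the stop codon or NA
firstInFrameStop <- function(seq, from = 1L) {
    s <- as.character(seq)
    n <- nchar(s)
    i <- from
    while (i + 2L <= n) {
        if (substr(s, i, i + 2L) %in% stopCodons()) return(i)
        i <- i + 3L
    }
    NA_integer_
}
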