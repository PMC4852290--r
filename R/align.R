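#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Default nucleotide alignment scoring scheme
#'
#' Match +2, mismatch -3, gap open -5, gap extend -2 (a gap of length L
#' scores open + L * extend).  These follow common nucleotide-alignment
#' practice; every entry point that aligns accepts an explicit scheme.
#'
#' @return named list with match, mismatch, gapOpen, gapExtend.
#' @export
alignDefaults <- function() {
    list(match = 2, mismatch = -3, gapOpen = -5, gapExtend = -2)
}

# scheme used for the >95%-identity CDS deduplication rule: match 1,
# mismatch 0, affine gap open -10 extend -0.5, global mode
identityScheme <- function() {
    list(match = 1, mismatch = 0, gapOpen = -10, gapExtend = -0.5)
}

#' Pairwise alignment with a deterministic affine-gap DP
#'
#' Optimal pairwise alignment under an affine gap scheme with a fixed
#' tie-break order (diagonal, then up, then left), so results are
#' reproducible to the byte.  Semiglobal mode leaves leading/trailing gaps
#' unpenalised in both sequences; local mode is Smith-Waterman.
#'
#' @param query,target nucleotide strings (or \code{DNAString}).
#' @param mode \code{"global"}, \code{"semiglobal"} or \code{"local"}.
#' @param scheme scoring scheme, see \code{\link{alignDefaults}}.
#' @param queryId,targetId identifiers carried into the result.
#' @return a \code{PairwiseAlignment}.
#' @examples
#' pa <- alignPair("ACGTACGTACGT", "ACGTACGTACGT", mode = "semiglobal")
#' pa@score      # 24 under the default scheme
#' @export
alignPair <- function(query, target,
                      mode = c("global", "semiglobal", "local"),
                      scheme = alignDefaults(),
                      queryId = "query", targetId = "target") {
    mode <- match.arg(mode)
    q <- toupper(as.character(query)); t <- toupper(as.character(target))
    if (!nzchar(q) || !nzchar(t))
        stop("alignPair: empty query or target")
    res <- cpp_align_pair(q, t, scheme$match, scheme$mismatch,
                          scheme$gapOpen, scheme$gapExtend,
                          match(mode, c("global", "semiglobal", "local")) - 1L)
    pa <- new("PairwiseAlignment", queryId = queryId, targetId = targetId,
              alignedQuery = res$a, alignedTarget = res$b,
              score = res$score, mode = mode, identity = NA_real_,
              params = scheme,
              range = as.integer(c(res$start_a, res$end_a,
                                   res$start_b, res$end_b)))
    pa@identity <- alignmentIdentity(pa)
    pa
}

#' Identity of a pairwise alignment
#'
#' Matches divided by aligned columns; terminal gap columns (leading or
#' trailing gap runs in either sequence) are excluded, interior gap columns
#' count as non-matching columns.
#'
#' @param pa a \code{PairwiseAlignment}.
#' @param excludeTerminalGaps drop leading/trailing gap columns first.
#' @return fraction in [0, 1] (NaN for an empty alignment).
#' @export
alignmentIdentity <- function(pa, excludeTerminalGaps = TRUE) {
    a <- strChars(pa@alignedQuery); b <- strChars(pa@alignedTarget)
    keep <- rep(TRUE, length(a))
    if (excludeTerminalGaps && length(a)) {
        gapcol <- a == "-" | b == "-"
        lead <- cumsum(!gapcol) == 0
        trail <- rev(cumsum(rev(!gapcol)) == 0)
        term <- (lead | trail) & gapcol
        keep <- !term
    }
    a <- a[keep]; b <- b[keep]
    if (!length(a)) return(NaN)
    sum(a == b & a != "-") / length(a)
}

#' CDS identity used by the same-species deduplication rule
#'
#' Global alignment with match 1 / mismatch 0 and affine gaps (open 10,
#' extend 0.5, as penalties); identity = matches / non-terminal-gap columns.
#'
#' @param a,b CDS strings.
#' @return fraction in [0, 1].
#' @export
cdsIdentity <- function(a, b) {
    pa <- alignPair(a, b, mode = "global", scheme = identityScheme())
    alignmentIdentity(pa, excludeTerminalGaps = TRUE)
}

#' Alignability of a segment against a (non)coding partner
#'
#' A segment is alignable iff it spans at least \code{minCols} bp and at
#' least a fraction \code{minIdentity} of its positions are matched in the
#' best local alignment to the partner.  Anchoring the identity on the
#' query keeps short segments robust to end trimming while stopping
#' spurious short local hits in unrelated sequence from qualifying.  Used
#' to separate exonization/pseudoexonization (alignable to noncoding
#' sequence) from exon gain/loss (alignable nowhere).
#'
#' @param query segment to test.
#' @param target partner sequence (intron, UTR, intergenic).
#' @param minIdentity minimum matched fraction of the query (default 0.5).
#' @param minCols minimum query span in bp (default 15).
#' @param scheme scoring scheme for the local DP.
#' @return TRUE/FALSE with attribute \code{"alignment"} (the
#'   \code{PairwiseAlignment}) when TRUE.
#' @export
isAlignable <- function(query, target, minIdentity = 0.5, minCols = 15L,
                        scheme = alignDefaults()) {
    q <- as.character(query); t <- as.character(target)
    if (!nzchar(q) || !nzchar(t) || nchar(q) < minCols) return(FALSE)
    pa <- alignPair(q, t, mode = "local", scheme = scheme)
    a <- strChars(pa@alignedQuery); b <- strChars(pa@alignedTarget)
    matches <- sum(a == b & a != "-")
    ok <- is.finite(pa@score) && matches / nchar(q) >= minIdentity
    if (ok) attr(ok, "alignment") <- pa
    ok
}

#' Best local hit of an exon inside a long noncoding region
#'
#' Scans up to \code{maxSpan} bp of noncoding sequence (truncating with a
#' warning beyond that) for a local alignment to the exon that meets the
#' alignability threshold.
#'
#' @param exonSeq exon sequence.
#' @param noncodingSeq noncoding sequence, e.g. a downstream intergenic
#'   region.
#' @param maxSpan maximum scanned span in bp (default 200000).
#' @param minIdentity,minCols alignability threshold.
#' @return \code{NULL} when nothing meets the threshold, otherwise a list
#'   with \code{offset} (1-based start of the hit in the noncoding
#'   sequence), \code{identity}, \code{score} and \code{alignment}.
#' @export
scanNoncodingForHomolog <- function(exonSeq, noncodingSeq, maxSpan = 200000L,
                                    minIdentity = 0.5, minCols = 15L) {
    q <- as.character(exonSeq); t <- as.character(noncodingSeq)
    if (!nzchar(q) || !nzchar(t)) return(NULL)
    if (nchar(t) > maxSpan) {
        warning(sprintf("noncoding sequence truncated to %d bp", maxSpan))
        t <- substr(t, 1L, maxSpan)
    }
    pa <- alignPair(q, t, mode = "local")
    a <- strChars(pa@alignedQuery); b <- strChars(pa@alignedTarget)
    matches <- sum(a == b & a != "-")
    if (nchar(q) < minCols || matches / nchar(q) < minIdentity)
        return(NULL)
    list(offset = pa@range[3], identity = pa@identity, score = pa@score,
         alignment = pa)
}

setMethod("show", "PairwiseAlignment", function(object) {
    cat(sprintf("PairwiseAlignment (%s) %s vs %s: score %.1f, identity %.3f\n",
                object@mode, object@queryId, object@targetId,
                object@score, object@identity))
})

# sum-of-pairs score of a block (character matrix); per row pair the induced
# pairwise alignment is scored under the scheme with affine gap runs,
# both-gap columns skipped
spScore <- function(block, scheme = alignDefaults()) {
    nr <- nrow(block)
    if (nr < 2L) return(0)
    total <- 0
    for (i in seq_len(nr - 1L)) {
        for (j in seq(i + 1L, nr)) {
            a <- block[i, ]; b <- block[j, ]
            keep <- !(a == "-" & b == "-")
            a <- a[keep]; b <- b[keep]
            if (!length(a)) next
            agap <- a == "-"; bgap <- b == "-"
            both <- !agap & !bgap
            total <- total + sum(a[both] == b[both]) * scheme$match +
                sum(a[both] != b[both]) * scheme$mismatch
            for (g in list(agap, bgap)) {
                if (!any(g)) next
                runs <- rle(g)
                nrun <- sum(runs$values)
                total <- total + nrun * scheme$gapOpen +
                    sum(runs$lengths[runs$values]) * scheme$gapExtend
            }
        }
    }
    total
}
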