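#' @include AllClasses.R AllGenerics.R align.R
NULL

# build a CodonAlignment from a character matrix of single letters
newCodonAlignment <- function(mat, codonProjected = FALSE) {
    stopifnot(!is.null(rownames(mat)))
    colMap <- lapply(seq_len(nrow(mat)), function(i) {
        row <- mat[i, ]
        cm <- cumsum(row != "-")
        cm[row == "-"] <- NA_integer_
        as.integer(cm)
    })
    names(colMap) <- rownames(mat)
    new("CodonAlignment", mat = mat, colMap = colMap,
        boundaryCols = setNames(rep(list(integer()), nrow(mat)), rownames(mat)),
        annotatedRows = setNames(rep(FALSE, nrow(mat)), rownames(mat)),
        mask = rep(FALSE, ncol(mat)),
        maskReason = rep(NA_character_, ncol(mat)),
        codonProjected = codonProjected)
}

#' @export
setMethod("alignmentMatrix", "CodonAlignment", function(x) x@mat)

#' @export
setMethod("columnMap", "CodonAlignment", function(x) x@colMap)

#' @export
setMethod("boundaryColumns", "CodonAlignment", function(x) x@boundaryCols)

#' @export
setMethod("columnMask", "CodonAlignment", function(x) x@mask)

#' @export
setMethod("maskReasons", "CodonAlignment", function(x) x@maskReason)

#' @export
setMethod("dim", "CodonAlignment", function(x) dim(x@mat))

setMethod("show", "CodonAlignment", function(object) {
    cat(sprintf("CodonAlignment: %d row(s) x %d column(s)%s, %d masked column(s)\n",
                nrow(object@mat), ncol(object@mat),
                if (object@codonProjected) " (codon-projected)" else "",
                sum(object@mask)))
})

#' Ungapped row sequences of an alignment
#'
#' @param x a \code{CodonAlignment}.
#' @return named character vector of de-gapped row sequences.
#' @export
degappedRows <- function(x) {
    vapply(seq_len(nrow(x@mat)),
           function(i) paste(x@mat[i, x@mat[i, ] != "-"], collapse = ""),
           character(1)) |> setNames(rownames(x@mat))
}

#' Project a protein guide alignment onto coding sequences
#'
#' Expands each aligned amino-acid column into its source codon triple
#' (protein gaps become \code{---}).  Each row must translate from its CDS
#' under the standard genetic code; a terminal stop codon in the CDS is
#' tolerated and appended ungapped after the projected body.
#'
#' @param proteinAln aligned proteins: an \code{AAStringSet} or named
#'   character vector, equal widths, gaps as \code{-}.
#' @param cdsById named character vector / \code{DNAStringSet} /
#'   \code{FamilySet} supplying each row's CDS.
#' @return a codon-projected \code{CodonAlignment}.
#' @export
projectProteinAlignment <- function(proteinAln, cdsById) {
    prot <- if (is(proteinAln, "XStringSet"))
        setNames(as.character(proteinAln), names(proteinAln))
    else unlist(proteinAln)
    if (is.null(names(prot)) || any(!nzchar(names(prot))))
        stop("protein alignment rows must be named")
    widths <- nchar(prot)
    if (length(unique(widths)) != 1L)
        stop("protein alignment rows have unequal lengths; not a valid guide")
    if (is(cdsById, "FamilySet"))
        cdsById <- vapply(models(cdsById),
                          function(m) as.character(cdsSeq(m)), character(1))
    if (is(cdsById, "XStringSet"))
        cdsById <- setNames(as.character(cdsById), names(cdsById))
    missing <- setdiff(names(prot), names(cdsById))
    if (length(missing))
        stop("no CDS for row(s): ", paste(missing, collapse = ", "))

    code <- Biostrings::GENETIC_CODE
    rows <- list(); stops <- list(); hasStop <- logical(0)
    for (id in names(prot)) {
        res <- strChars(prot[[id]])
        cds <- toupper(as.character(cdsById[[id]]))
        nres <- sum(res != "-")
        extra <- nchar(cds) - 3L * nres
        if (!extra %in% c(0L, 3L))
            stop(sprintf("row %s: CDS length %d does not fit %d residues",
                         id, nchar(cds), nres))
        stopCodon <- if (extra == 3L) substr(cds, nchar(cds) - 2L, nchar(cds))
                     else ""
        if (nzchar(stopCodon) && !stopCodon %in% stopCodons())
            stop(sprintf("row %s: trailing codon %s is not a stop codon",
                         id, stopCodon))
        out <- character(length(res)); k <- 0L
        for (p in seq_along(res)) {
            if (res[p] == "-") { out[p] <- "---"; next }
            codon <- substr(cds, 3L * k + 1L, 3L * k + 3L)
            aa <- code[[codon]]
            if (is.null(aa)) aa <- "X"
            if (aa != res[p] && res[p] != "X")
                stop(sprintf(
                    "row %s: residue %d is '%s' but codon %s translates to '%s'",
                    id, p - nchar(gsub("[^-]", "", substr(prot[[id]], 1, p))),
                    res[p], codon, aa))
            out[p] <- codon
            k <- k + 1L
        }
        rows[[id]] <- out
        stops[[id]] <- stopCodon
        hasStop <- c(hasStop, nzchar(stopCodon))
    }
    ncol3 <- length(strChars(prot[[1]]))
    mat <- matrix("-", nrow = length(rows), ncol = 3L * ncol3 +
                      if (any(hasStop)) 3L else 0L,
                  dimnames = list(names(rows), NULL))
    for (i in seq_along(rows)) {
        body <- strChars(paste(rows[[i]], collapse = ""))
        mat[i, seq_along(body)] <- body
        if (nzchar(stops[[i]]))
            mat[i, (3L * ncol3 + 1L):(3L * ncol3 + 3L)] <- strChars(stops[[i]])
    }
    newCodonAlignment(mat, codonProjected = TRUE)
}

#' Mark exon-intron boundaries in alignment coordinates
#'
#' For each row whose gene model carries a structural annotation, maps the
#' cumulative exon lengths through the row's column map and records the
#' alignment columns at which each exon (except the last) ends.  Rows
#' without annotation keep an empty boundary list and are flagged.
#'
#' @param aln a \code{CodonAlignment}.
#' @param fs the \code{FamilySet} providing exon lengths.
#' @return the alignment with boundary columns filled in.
#' @export
markExonBoundaries <- function(aln, fs) {
    for (id in rownames(aln@mat)) {
        gm <- if (id %in% names(fs)) fs[[id]] else NULL
        if (is.null(gm) || !isAnnotated(gm)) {
            aln@annotatedRows[[id]] <- FALSE
            aln@boundaryCols[[id]] <- integer()
            next
        }
        ends <- cumsum(exonLengths(gm))
        ends <- head(ends, -1L)
        cm <- aln@colMap[[id]]
        cols <- vapply(ends, function(e) {
            hit <- which(cm == e)
            if (!length(hit))
                stop(sprintf("row %s: CDS position %d not present in alignment",
                             id, e))
            hit[1]
        }, integer(1))
        aln@boundaryCols[[id]] <- as.integer(cols)
        aln@annotatedRows[[id]] <- TRUE
    }
    validObject(aln)
    aln
}

#' Consensus exon boundary columns across annotated rows
#'
#' Per-row boundary columns within \code{tolerance} of each other are
#' clustered as one exon junction; each cluster supported by at least half
#' of the annotated rows contributes its modal column (smallest at ties)
#' to the consensus.  Rows hit by boundary-shifting events (exonization,
#' intron loss) deviate singly and do not disturb the consensus.
#'
#' @param aln a boundary-marked \code{CodonAlignment}.
#' @param tolerance columns within this distance cluster together
#'   (default 12).
#' @return sorted integer vector of consensus boundary columns.
#' @export
consensusBoundaries <- function(aln, tolerance = 12L) {
    ann <- names(which(aln@annotatedRows))
    if (!length(ann)) return(integer())
    all <- unlist(aln@boundaryCols[ann], use.names = FALSE)
    if (!length(all)) return(integer())
    all <- sort(all)
    cl <- cumsum(c(1L, diff(all) > tolerance))
    out <- integer()
    for (g in unique(cl)) {
        cols <- all[cl == g]
        if (length(cols) < length(ann) / 2) next
        tab <- table(cols)
        out <- c(out, as.integer(names(tab)[which.max(tab)]))
    }
    sort(out)
}

# block spans (start, end columns) delimited by consensus boundaries
blockSpans <- function(aln, boundaries = consensusBoundaries(aln)) {
    nc <- ncol(aln@mat)
    starts <- c(1L, boundaries + 1L)
    ends <- c(boundaries, nc)
    keep <- starts <= ends
    cbind(start = starts[keep], end = ends[keep])
}

# score of one row against all other rows of a block (affine per pair)
rowBlockScore <- function(block, i, scheme = alignDefaults()) {
    a <- block[i, ]
    total <- 0
    for (j in setdiff(seq_len(nrow(block)), i)) {
        b <- block[j, ]
        keep <- !(a == "-" & b == "-")
        aa <- a[keep]; bb <- b[keep]
        if (!length(aa)) next
        both <- aa != "-" & bb != "-"
        total <- total + sum(aa[both] == bb[both]) * scheme$match +
            sum(aa[both] != bb[both]) * scheme$mismatch
        for (g in list(aa == "-", bb == "-")) {
            if (!any(g)) next
            runs <- rle(g)
            total <- total + sum(runs$values) * scheme$gapOpen +
                sum(runs$lengths[runs$values]) * scheme$gapExtend
        }
    }
    total
}

#' Refine gap placement exon by exon
#'
#' Relocates gap runs -- without changing any row's sequence -- to the
#' placement that maximises the sum-of-pairs score around each run.  Among
#' score-equivalent placements, placements that do not straddle an exon
#' boundary of any other annotated row are preferred (a gap run straddling
#' a boundary is retained, and flagged, only when it scores strictly
#' better than every non-straddling placement); remaining ties are
#' resolved by left-aligning the run.  The sum-of-pairs score never
#' decreases.  Blocks whose per-row ungapped lengths differ are flagged as
#' candidates for event detection.
#'
#' @param aln a boundary-marked \code{CodonAlignment}.
#' @param fs the \code{FamilySet} (used to re-mark boundaries afterwards).
#' @param scheme scoring scheme for sum-of-pairs evaluation.
#' @param maxPasses sweeps over the rows (placement usually stabilises
#'   after one).
#' @param maxShift how far (columns) a run may be relocated per pass.
#' @return the refined alignment, boundaries re-marked; attributes
#'   \code{straddleFlagged} (data.frame of retained straddling runs) and
#'   \code{divergentBlocks} (integer block indices) summarise the flags.
#' @export
refineExonByExon <- function(aln, fs, scheme = alignDefaults(),
                             maxPasses = 3L, maxShift = 30L) {
    mat <- aln@mat
    flagged <- list()
    for (pass in seq_len(maxPasses)) {
        changed <- FALSE
        # boundary columns of every annotated row under the current gaps
        cur <- markExonBoundaries(newCodonAlignment(mat), fs)
        # rows sharing a byte-identical gap run move as one group, so that
        # shared (clade-wide) gaps can relocate without transient penalties
        runKey <- list()
        for (i in seq_len(nrow(mat))) {
            runs <- gapRuns(mat[i, ])
            if (!nrow(runs)) next
            for (r in seq_len(nrow(runs))) {
                key <- paste(runs[r, "start"], runs[r, "end"])
                runKey[[key]] <- c(runKey[[key]], i)
            }
        }
        for (key in names(runKey)) {
            se <- as.integer(strsplit(key, " ")[[1]])
            rows <- runKey[[key]]
            # the run may have moved in an earlier iteration of this pass
            ok <- vapply(rows, function(i)
                all(mat[i, se[1]:se[2]] == "-"), logical(1))
            rows <- rows[ok]
            if (!length(rows)) next
            annOut <- setdiff(which(cur@annotatedRows), rows)
            otherB <- sort(unique(unlist(cur@boundaryCols[annOut])))
            res <- bestRunPlacement(mat, rows, se[1], se[2], otherB,
                                    scheme, maxShift)
            if (!is.null(res$mat)) {
                mat <- res$mat
                changed <- TRUE
            }
            if (isTRUE(res$straddled))
                flagged[[length(flagged) + 1L]] <- data.frame(
                    rows = paste(rownames(mat)[rows], collapse = ","),
                    start = se[1], end = se[2], stringsAsFactors = FALSE)
        }
        if (!changed) break
    }
    out <- newCodonAlignment(mat, codonProjected = aln@codonProjected)
    out <- markExonBoundaries(out, fs)
    attr(out, "straddleFlagged") <- if (length(flagged))
        unique(do.call(rbind, flagged)) else NULL
    spans <- blockSpans(out)
    divergent <- which(vapply(seq_len(nrow(spans)), function(k) {
        cols <- spans[k, "start"]:spans[k, "end"]
        lens <- rowSums(out@mat[, cols, drop = FALSE] != "-")
        length(unique(lens[lens > 0L])) > 1L
    }, logical(1)))
    attr(out, "divergentBlocks") <- divergent
    out
}

# maximal gap runs of a row: matrix with columns start, end (block-local)
gapRuns <- function(row) {
    r <- rle(row == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    cbind(start = starts[keep], end = ends[keep])
}

# evaluate all placements of one (possibly shared) gap run within its free
# corridor (bounded by neighbouring gaps of the moved rows and the matrix
# edges, limited to maxShift columns of relocation); returns
# list(mat = modified matrix or NULL, straddled = TRUE when the kept
# placement straddles a boundary of another row although a worse-scoring
# non-straddling placement exists)
bestRunPlacement <- function(mat, rows, rs, re, otherBoundaries, scheme,
                             maxShift = 30L) {
    L <- re - rs + 1L
    nc <- ncol(mat)
    lo <- 1L; hi <- nc
    for (i in rows) {
        row <- mat[i, ]
        left <- rs - 1L
        while (left >= 1L && row[left] != "-") left <- left - 1L
        right <- re + 1L
        while (right <= nc && row[right] != "-") right <- right + 1L
        lo <- max(lo, left + 1L); hi <- min(hi, right - 1L)
    }
    if (hi - lo + 1L <= L) return(list(mat = NULL, straddled = FALSE))
    starts <- max(lo, rs - maxShift):min(hi - L + 1L, rs + maxShift)
    if (length(starts) < 2L) return(list(mat = NULL, straddled = FALSE))
    # scoring window: corridor plus a small margin so run merging at the
    # corridor edges is scored consistently across candidates
    wlo <- max(1L, lo - L - 5L); whi <- min(nc, hi + L + 5L)
    placeRun <- function(row, st) {
        chars <- row[lo:hi]; chars <- chars[chars != "-"]
        seg <- rep("-", hi - lo + 1L)
        npre <- st - lo
        if (npre > 0L) seg[seq_len(npre)] <- chars[seq_len(npre)]
        if (npre < length(chars))
            seg[(npre + L + 1L):(hi - lo + 1L)] <-
                chars[(npre + 1L):length(chars)]
        row[lo:hi] <- seg
        row
    }
    unmoved <- setdiff(seq_len(nrow(mat)), rows)
    scoreCand <- function(st) {
        tmp <- mat[, wlo:whi, drop = FALSE]
        for (i in rows) tmp[i, ] <- placeRun(mat[i, ], st)[wlo:whi]
        total <- 0
        for (i in seq_along(rows))
            total <- total + rowPairsScore(tmp, rows[i], unmoved, scheme)
        total
    }
    scores <- vapply(starts, scoreCand, numeric(1))
    straddles <- vapply(starts, function(st) {
        en <- st + L - 1L
        any(otherBoundaries >= st & otherBoundaries < en)
    }, logical(1))
    best <- max(scores)
    cand <- which(scores == best)
    straddledKept <- FALSE
    if (any(!straddles[cand])) {
        cand <- cand[!straddles[cand]]
    } else if (any(!straddles)) {
        straddledKept <- TRUE   # straddling strictly outscores; retain, flag
    }
    # gaps born at exon junctions belong flush against the boundary: among
    # remaining ties prefer a placement whose run edge touches a boundary
    flush <- vapply(starts, function(st)
        any(otherBoundaries == st - 1L | otherBoundaries == st + L - 1L),
        logical(1))
    if (any(flush[cand])) cand <- cand[flush[cand]]
    bestStart <- starts[cand[1]]
    curIdx <- match(rs, starts)
    current <- scores[curIdx]
    curStraddle <- straddles[curIdx]
    curFlush <- flush[curIdx]
    bestIdx <- match(bestStart, starts)
    better <- best > current ||
        (best == current && (
            (curStraddle && !straddles[bestIdx]) ||
            (identical(curStraddle, straddles[bestIdx]) &&
             !curFlush && flush[bestIdx]) ||
            (identical(curStraddle, straddles[bestIdx]) &&
             identical(curFlush, flush[bestIdx]) && bestStart < rs)))
    if (better) {
        for (i in rows) mat[i, ] <- placeRun(mat[i, ], bestStart)
        return(list(mat = mat, straddled = straddledKept))
    }
    list(mat = NULL, straddled = straddledKept)
}

# score of row i against the given other rows over a window matrix
rowPairsScore <- function(block, i, others, scheme) {
    a <- block[i, ]
    total <- 0
    for (j in others) {
        b <- block[j, ]
        keep <- !(a == "-" & b == "-")
        aa <- a[keep]; bb <- b[keep]
        if (!length(aa)) next
        both <- aa != "-" & bb != "-"
        total <- total + sum(aa[both] == bb[both]) * scheme$match +
            sum(aa[both] != bb[both]) * scheme$mismatch
        for (g in list(aa == "-", bb == "-")) {
            if (!any(g)) next
            runs <- rle(g)
            total <- total + sum(runs$values) * scheme$gapOpen +
                sum(runs$lengths[runs$values]) * scheme$gapExtend
        }
    }
    total
}

#' Progressive alignment of family CDSs along a guide tree
#'
#' Profile-profile progressive alignment under the package's affine DP
#' scheme, with the input phylogeny as the guide tree.  This exists so that
#' synthetic families can be aligned without an external aligner; real
#' analyses normally start from a curated protein guide alignment via
#' \code{\link{projectProteinAlignment}}.
#'
#' @param fs a \code{FamilySet}.
#' @param tree rooted \code{phylo} whose tip labels are the gene ids.
#' @param scheme scoring scheme.
#' @return a \code{CodonAlignment} (not codon-projected).
#' @export
progressiveAlign <- function(fs, tree, scheme = alignDefaults()) {
    stopifnot(inherits(tree, "phylo"))
    tips <- tree$tip.label
    missing <- setdiff(tips, names(fs))
    if (length(missing))
        stop("tree tips without gene models: ", paste(missing, collapse = ", "))
    lookup <- c("A" = 1L, "C" = 2L, "G" = 3L, "T" = 4L, "-" = 5L, "N" = 5L)
    profileOf <- function(mat) {
        p <- matrix(0, nrow = 5L, ncol = ncol(mat))
        for (i in seq_len(nrow(mat))) {
            idx <- lookup[mat[i, ]]
            p[cbind(idx, seq_len(ncol(mat)))] <-
                p[cbind(idx, seq_len(ncol(mat)))] + 1
        }
        sweep(p, 2, colSums(p), "/")
    }
    mergeMats <- function(A, B) {
        path <- cpp_align_profiles(profileOf(A), profileOf(B),
                                   scheme$match, scheme$mismatch,
                                   scheme$gapOpen, scheme$gapExtend)
        n <- length(path)
        out <- matrix("-", nrow = nrow(A) + nrow(B), ncol = n,
                      dimnames = list(c(rownames(A), rownames(B)), NULL))
        ia <- 0L; ib <- 0L
        colA <- integer(0); posA <- integer(0)
        for (k in seq_len(n)) {
            if (path[k] != 2L) { ia <- ia + 1L; out[seq_len(nrow(A)), k] <- A[, ia] }
            if (path[k] != 1L) { ib <- ib + 1L;
                out[nrow(A) + seq_len(nrow(B)), k] <- B[, ib] }
        }
        out
    }
    alignNode <- function(node) {
        ntip <- length(tips)
        if (node <= ntip) {
            id <- tips[node]
            s <- strChars(as.character(cdsSeq(fs[[id]])))
            return(matrix(s, nrow = 1, dimnames = list(id, NULL)))
        }
        children <- tree$edge[tree$edge[, 1] == node, 2]
        mats <- lapply(children, alignNode)
        out <- mats[[1]]
        for (k in seq_along(mats)[-1]) out <- mergeMats(out, mats[[k]])
        out
    }
    root <- length(tips) + 1L
    mat <- alignNode(root)
    # keep row order of the family set for reproducibility
    mat <- mat[intersect(names(fs), rownames(mat)), , drop = FALSE]
    newCodonAlignment(mat)
}

#' Mask non-homologous alignment columns
#'
#' Masks (1) columns downstream of an unrepaired frameshift within the
#' affected rows' span, (2) columns where independent events of different
#' origin overlap, and (3) columns whose gap fraction exceeds
#' \code{maxGapFraction}.  Masked columns carry a reason and are excluded
#' from exported matrices; event classification never consumes them.
#'
#' @param aln a \code{CodonAlignment}.
#' @param events list of \code{StructuralEvent} (possibly empty).
#' @param maxGapFraction columns with a strictly greater gap fraction are
#'   masked (default 0.8).
#' @return the alignment with its mask filled in.
#' @export
maskNonhomologousColumns <- function(aln, events = list(),
                                     maxGapFraction = 0.8) {
    nc <- ncol(aln@mat)
    mask <- aln@mask; reason <- aln@maskReason
    # (1) frameshifts: cumulative non-triplet length per event chain, masked
    # from the first frame-violating event until frame restoration (or the
    # end of the affected rows' span)
    fsEvents <- Filter(function(e) !e@framePreserving &&
                           !e@mechanism %in% c("intron_gain", "intron_loss"),
                       events)
    if (length(fsEvents)) {
        ord <- order(vapply(fsEvents, function(e) e@columnSpan[1], integer(1)))
        fsEvents <- fsEvents[ord]
        shift <- 0L
        from <- NA_integer_
        for (e in fsEvents) {
            prev <- shift
            shift <- (shift + e@lengthBp) %% 3L
            if (prev == 0L && shift != 0L) {
                from <- e@columnSpan[2] + 1L
            }
            if (prev != 0L && shift == 0L && !is.na(from)) {
                if (from <= e@columnSpan[1] - 1L) {
                    idx <- from:(e@columnSpan[1] - 1L)
                    mask[idx] <- TRUE
                    reason[idx] <- "frameshift_downstream"
                }
                from <- NA_integer_
            }
        }
        if (shift != 0L && !is.na(from) && from <= nc) {
            rows <- unique(unlist(lapply(fsEvents, function(e)
                c(e@carrierGenes, e@gapRows))))
            rows <- intersect(rows, rownames(aln@mat))
            spanEnd <- if (length(rows)) {
                max(vapply(rows, function(r)
                    max(which(aln@mat[r, ] != "-")), integer(1)))
            } else nc
            if (from <= spanEnd) {
                idx <- from:spanEnd
                mask[idx] <- TRUE
                reason[idx] <- "frameshift_downstream"
            }
        }
    }
    # (2) overlapping independent events
    if (length(events) > 1L) {
        for (i in seq_len(length(events) - 1L)) {
            for (j in seq(i + 1L, length(events))) {
                a <- events[[i]]@columnSpan; b <- events[[j]]@columnSpan
                lo <- max(a[1], b[1]); hi <- min(a[2], b[2])
                if (lo <= hi &&
                    !setequal(events[[i]]@carrierGenes,
                              events[[j]]@carrierGenes)) {
                    mask[lo:hi] <- TRUE
                    reason[lo:hi] <- "independent_events"
                }
            }
        }
    }
    # (3) gappy columns
    gapFrac <- colMeans(aln@mat == "-")
    gappy <- gapFrac > maxGapFraction
    reason[gappy & !mask] <- "gap_fraction"
    mask[gappy] <- TRUE
    aln@mask <- mask
    aln@maskReason <- reason
    aln
}
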