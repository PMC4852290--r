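#' @include AllClasses.R AllGenerics.R align.R codon-align.R
NULL

#' @export
setMethod("eventId", "StructuralEvent", function(x) x@eventId)

#' @export
setMethod("mechanism", "StructuralEvent", function(x) x@mechanism)

#' @export
setMethod("exonIndex", "StructuralEvent", function(x) x@exonIndex)

#' @export
setMethod("lengthBp", "StructuralEvent", function(x) x@lengthBp)

#' @export
setMethod("carrierGenes", "StructuralEvent", function(x) x@carrierGenes)

#' @export
setMethod("framePreserving", "StructuralEvent", function(x) x@framePreserving)

#' @export
setMethod("evidence", "StructuralEvent", function(x) x@evidence)

setMethod("show", "StructuralEvent", function(object) {
    cat(sprintf("StructuralEvent %s: %s, exon %d, %d bp%s, carriers: %s [%s]\n",
                object@eventId, object@mechanism, object@exonIndex,
                object@lengthBp,
                if (object@framePreserving) "" else " (frame-violating)",
                paste(object@carrierGenes, collapse = ","), object@evidence))
})

newEvent <- function(eventId, mechanism, exonIndex, lengthBp, columnSpan,
                     carrierGenes, gapRows = character(), evidence,
                     detail = list()) {
    new("StructuralEvent", eventId = eventId, mechanism = mechanism,
        exonIndex = as.integer(exonIndex), lengthBp = as.integer(lengthBp),
        columnSpan = as.integer(columnSpan),
        carrierGenes = carrierGenes, gapRows = gapRows,
        framePreserving = as.integer(lengthBp) %% 3L == 0L,
        evidence = evidence, detail = detail)
}

#' Event table
#'
#' Flattens a list of \code{StructuralEvent} (or \code{EventPlacement}) into
#' a data.frame suitable for TSV export.
#' @param events list of events.
#' @return data.frame with one row per event.
#' @export
eventTable <- function(events) {
    if (!length(events))
        return(data.frame(event_id = character(), mechanism = character(),
                          exon_index = integer(), length_bp = integer(),
                          frame_preserving = logical(), carriers = character(),
                          evidence = character(), column_start = integer(),
                          column_end = integer(), stringsAsFactors = FALSE))
    do.call(rbind, lapply(events, function(e) data.frame(
        event_id = e@eventId, mechanism = e@mechanism,
        exon_index = e@exonIndex, length_bp = e@lengthBp,
        frame_preserving = e@framePreserving,
        carriers = paste(sort(e@carrierGenes), collapse = ","),
        evidence = e@evidence,
        column_start = e@columnSpan[1], column_end = e@columnSpan[2],
        stringsAsFactors = FALSE)))
}

# rows of a block partitioned by gap signature: for every column with >= 1
# gap among informative rows, the signature is the sorted set of gapped
# rows; maximal runs of a constant signature are candidate events
gapSignatureRuns <- function(mat, cols, rows) {
    sub <- mat[rows, cols, drop = FALSE]
    isgap <- sub == "-"
    anyGap <- colSums(isgap) > 0 & colSums(!isgap) > 0
    if (!any(anyGap)) return(list())
    sig <- apply(isgap, 2, function(g) paste(rows[g], collapse = ";"))
    sig[!anyGap] <- ""
    r <- rle(sig)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    keep <- r$values != ""
    out <- list()
    for (k in which(keep)) {
        out[[length(out) + 1L]] <- list(
            start = cols[starts[k]], end = cols[ends[k]],
            gapRows = strsplit(r$values[k], ";", fixed = TRUE)[[1]])
    }
    out
}

# noncoding sequence of `row` adjacent to a gap run that starts at column
# `runStart` in block `k` (of nBlocks): the row's intron following its last
# exon ending before the run, or a flank at the alignment ends.  Indexing
# from the run itself (not the consensus column) stays correct when the
# row's own boundary was shifted by the event under classification.
rowNoncodingAt <- function(aln, fs, row, k, side, runStart, nBlocks) {
    if (!row %in% names(fs)) return(NULL)
    gm <- fs[[row]]
    if (!isAnnotated(gm)) return(NULL)
    if (side == 5L && k == 1L) {
        s <- as.character(flank5(gm))
        return(if (nzchar(s)) s else NULL)
    }
    if (side == 3L && k == nBlocks) {
        s <- as.character(flank3(gm))
        return(if (nzchar(s)) s else NULL)
    }
    if (!length(intronSeqs(gm))) return(NULL)
    bc <- aln@boundaryCols[[row]]
    idx <- sum(bc <= runStart + 2L)
    if (idx < 1L || idx > length(intronSeqs(gm))) return(NULL)
    s <- as.character(intronSeqs(gm)[[idx]])
    if (nzchar(s)) s else NULL
}

#' Classify a gap run abutting an exon boundary
#'
#' Decides between the exonization/pseudoexonization class (the extra exonic
#' sequence of the longer rows is alignable to noncoding sequence of a
#' shorter row), a whole-exon change (the entire exon of one side is
#' unalignable to any region of the other, refined to exon gain/loss by
#' parsimony), and an indeterminate indel (noncoding sequence unavailable,
#' or the segment is too short to establish noncoding homology).  Polarity
#' is always left to parsimony mapping.
#'
#' @param aln boundary-marked \code{CodonAlignment}.
#' @param fs the \code{FamilySet}.
#' @param run list with \code{start}, \code{end}, \code{gapRows} (a gap run
#'   whose columns abut a consensus boundary).
#' @param k block (exon) index the run belongs to.
#' @param side 5 or 3: which edge of the block the run abuts.
#' @param eventId identifier for the resulting event.
#' @param minIdentity,minCols alignability threshold.
#' @return a \code{StructuralEvent}.
#' @export
classifyBoundaryGap <- function(aln, fs, run, k, side, eventId = "ev",
                                minIdentity = 0.5, minCols = 15L) {
    cols <- run$start:run$end
    if (!length(cols) || run$end < run$start)
        stop("not a boundary gap: zero-length gap run")
    boundaries <- consensusBoundaries(aln)
    spans <- blockSpans(aln, boundaries)
    if (k > nrow(spans)) stop("block index out of range")
    atEdge <- (side == 5L && run$start == spans[k, "start"]) ||
              (side == 3L && run$end == spans[k, "end"])
    if (!atEdge)
        stop("not a boundary gap: run does not abut the block edge")
    seqRows <- setdiff(rownames(aln@mat), run$gapRows)
    # rows fully gapped in the run columns are the short state; use the
    # majority sequence of the long state as the focal extra segment
    extra <- vapply(seqRows, function(r)
        paste(aln@mat[r, cols][aln@mat[r, cols] != "-"], collapse = ""),
        character(1))
    extra <- extra[nzchar(extra)]
    if (!length(extra))
        stop("not a boundary gap: no row carries sequence in the run")
    focal <- extra[[which.max(nchar(extra))]]
    L <- length(cols)
    wholeExon <- run$start == spans[k, "start"] && run$end == spans[k, "end"]
    if (!wholeExon) {
        # a sequence-bearing row whose own annotation brackets the run as a
        # separate exon marks a whole-exon (gain-type) change
        wholeExon <- any(vapply(names(extra), function(r) {
            bc <- aln@boundaryCols[[r]]
            length(bc) &&
                any(bc >= run$start - 1L & bc < run$start) &&
                any(bc == run$end)
        }, logical(1)))
    }
    # try the noncoding sequence of each gap row adjacent to the boundary
    nc <- NULL
    for (r in run$gapRows) {
        nc <- rowNoncodingAt(aln, fs, r, k, side, run$start, nrow(spans))
        if (!is.null(nc)) break
    }
    if (wholeExon) {
        # geometry of the extra exon within the consensus block, needed to
        # present ancestral structures on the exon-bearing side correctly
        focalRow <- names(extra)[which.max(nchar(extra))]
        leftPart <- if (run$start > spans[k, "start"])
            sum(aln@mat[focalRow,
                        spans[k, "start"]:(run$start - 1L)] != "-") else 0L
        rightPart <- if (run$end < spans[k, "end"])
            sum(aln@mat[focalRow,
                        (run$end + 1L):spans[k, "end"]] != "-") else 0L
        wholeBlock <- run$start == spans[k, "start"] &&
            run$end == spans[k, "end"]
        geom <- list(wholeBlock = wholeBlock,
                     subBlockParts = c(leftPart, nchar(focal), rightPart))
        # whole-exon change: alignable to noncoding -> exonization class;
        # unalignable anywhere (coding or noncoding) -> exon gain/loss
        ok <- !is.null(nc) && isTRUE(isAlignable(focal, nc, minIdentity,
                                                 minCols))
        if (!ok && !is.null(nc <- wholeExonPartner(aln, fs, run, k,
                                                   nrow(spans))))
            ok <- isTRUE(isAlignable(focal, nc, minIdentity, minCols))
        if (ok)
            return(newEvent(eventId, "exonization", k, L,
                            c(run$start, run$end), names(extra), run$gapRows,
                            "boundary_gap_noncoding_alignable",
                            detail = c(list(polarityResolved = FALSE,
                                            wholeExon = TRUE), geom)))
        return(newEvent(eventId, "indeterminate_exon_change", k, L,
                        c(run$start, run$end), names(extra), run$gapRows,
                        "whole_exon_unalignable",
                        detail = c(list(polarityResolved = FALSE), geom)))
    }
    # which ancestral exon the boundary segment belongs to: decided by the
    # sequence-bearing rows' own boundary at the run edge (e.g. a run at
    # the start of block k whose bearing rows place an exon end at the run
    # end is the 3' tail of exon k-1, not the head of exon k)
    target <- k
    bearingB <- unlist(aln@boundaryCols[names(extra)])
    if (side == 5L && run$start == spans[k, "start"] &&
        any(bearingB == run$end)) target <- k - 1L
    if (side == 3L && run$end == spans[k, "end"] &&
        any(bearingB == run$start - 1L)) target <- k + 1L
    if (is.null(nc))
        return(newEvent(eventId, "indeterminate_indel", k, L,
                        c(run$start, run$end), run$gapRows,
                        gapRows = run$gapRows, evidence = "internal_gap",
                        detail = list(polarityResolved = FALSE,
                                      note = "no noncoding sequence available",
                                      boundary = TRUE, side = side,
                                      lengthTargetBlock = target)))
    if (nchar(focal) >= minCols &&
        isTRUE(isAlignable(focal, nc, minIdentity, minCols)))
        return(newEvent(eventId, "exonization", k, L,
                        c(run$start, run$end), names(extra), run$gapRows,
                        "boundary_gap_noncoding_alignable",
                        detail = list(polarityResolved = FALSE, side = side,
                                      lengthTargetBlock = target)))
    newEvent(eventId, "indeterminate_indel", k, L,
             c(run$start, run$end), run$gapRows, gapRows = run$gapRows,
             evidence = "internal_gap",
             detail = list(polarityResolved = FALSE,
                           note = if (nchar(focal) < minCols)
                               "segment below alignability span"
                           else "not alignable to adjacent noncoding",
                           boundary = TRUE, side = side,
                           lengthTargetBlock = target))
}

# classify a whole-exon bracket (see the whole-exon pass in detectEvents):
# alignable to the gap rows' noncoding sequence -> exonization class,
# otherwise an indeterminate exon gain/loss refined by parsimony.  The
# event length is the bearing row's exon length, independent of how the
# aligner fragmented the gaps.
classifyWholeExon <- function(aln, fs, run, k, spans, eventId,
                              minIdentity = 0.5, minCols = 15L) {
    cols <- run$start:run$end
    seqRows <- setdiff(rownames(aln@mat), run$gapRows)
    extra <- vapply(seqRows, function(r)
        paste(aln@mat[r, cols][aln@mat[r, cols] != "-"], collapse = ""),
        character(1))
    extra <- extra[nzchar(extra)]
    if (!length(extra)) stop("no row carries sequence in the bracket")
    focalRow <- names(extra)[which.max(nchar(extra))]
    focal <- extra[[focalRow]]
    L <- nchar(focal)
    leftPart <- if (run$start > spans[k, "start"])
        sum(aln@mat[focalRow,
                    spans[k, "start"]:(run$start - 1L)] != "-") else 0L
    rightPart <- if (run$end < spans[k, "end"])
        sum(aln@mat[focalRow, (run$end + 1L):spans[k, "end"]] != "-")
        else 0L
    wholeBlock <- run$start <= spans[k, "start"] &&
        run$end >= spans[k, "end"]
    geom <- list(wholeExon = TRUE, wholeBlock = wholeBlock,
                 subBlockParts = c(leftPart, L, rightPart))
    nc <- NULL
    for (r in run$gapRows) {
        nc <- rowNoncodingAt(aln, fs, r, k, 5L, run$start, nrow(spans))
        if (!is.null(nc)) break
    }
    ok <- !is.null(nc) && isTRUE(isAlignable(focal, nc, minIdentity, minCols))
    if (!ok && !is.null(nc <- wholeExonPartner(aln, fs, run, k,
                                               nrow(spans))))
        ok <- isTRUE(isAlignable(focal, nc, minIdentity, minCols))
    if (ok)
        return(newEvent(eventId, "exonization", k, L,
                        c(run$start, run$end), names(extra), run$gapRows,
                        "boundary_gap_noncoding_alignable",
                        detail = c(list(polarityResolved = FALSE), geom)))
    newEvent(eventId, "indeterminate_exon_change", k, L,
             c(run$start, run$end), names(extra), run$gapRows,
             "whole_exon_unalignable",
             detail = c(list(polarityResolved = FALSE), geom))
}

# concatenated noncoding context of the gap rows around a missing exon
# (both adjacent introns plus flanks where applicable)
wholeExonPartner <- function(aln, fs, run, k, nBlocks) {
    for (r in run$gapRows) {
        l5 <- rowNoncodingAt(aln, fs, r, k, 5L, run$start, nBlocks)
        l3 <- rowNoncodingAt(aln, fs, r, k, 3L, run$end, nBlocks)
        if (!is.null(l5) || !is.null(l3))
            return(paste0(if (is.null(l5)) "" else l5,
                          if (is.null(l3)) "" else l3))
    }
    NULL
}

#' Detect intraexonic insertions/deletions in an exon block
#'
#' Gaps strictly interior to an exon are attributed to intraexonic
#' insertion/deletion.  Columns are partitioned by their gap signature (the
#' set of rows gapped there); each maximal run of a constant signature
#' becomes one event whose carrier grouping is exactly the rows sharing the
#' identical gap run.  Polarity (insertion vs deletion) is left
#' indeterminate and resolved by parsimony mapping.
#'
#' @param aln boundary-marked \code{CodonAlignment}.
#' @param blockIndex which consensus exon block to scan (default: all).
#' @param hotspotMax when a contiguous gapped region carries more than this
#'   many distinct signatures it is flagged as an indel hotspot and handed
#'   to masking instead of being force-classified.
#' @return list with \code{events} (list of \code{StructuralEvent}) and
#'   \code{hotspots} (list of column ranges).
#' @export
detectInternalIndels <- function(aln, blockIndex = NULL, hotspotMax = 2L) {
    spans <- blockSpans(aln)
    blocks <- if (is.null(blockIndex)) seq_len(nrow(spans)) else blockIndex
    events <- list(); hotspots <- list()
    eid <- 0L
    for (k in blocks) {
        cols <- spans[k, "start"]:spans[k, "end"]
        rows <- rownames(aln@mat)
        # rows fully gapped across the block carry no information here
        informative <- rows[vapply(rows, function(r)
            any(aln@mat[r, cols] != "-"), logical(1))]
        if (length(informative) < 2L) next
        runs <- gapSignatureRuns(aln@mat, cols, informative)
        if (!length(runs)) next
        # interior only
        runs <- Filter(function(r) r$start > spans[k, "start"] &&
                           r$end < spans[k, "end"], runs)
        if (!length(runs)) next
        # hotspot flagging: distinct signatures within one contiguous gapped
        # region (runs touching each other)
        grp <- cumsum(c(TRUE, vapply(seq_along(runs)[-1], function(i)
            runs[[i]]$start > runs[[i - 1L]]$end + 1L, logical(1))))
        for (g in unique(grp)) {
            members <- runs[grp == g]
            if (length(members) > hotspotMax) {
                hotspots[[length(hotspots) + 1L]] <- list(
                    start = members[[1]]$start,
                    end = members[[length(members)]]$end, block = k)
                next
            }
            for (r in members) {
                eid <- eid + 1L
                events[[length(events) + 1L]] <- newEvent(
                    sprintf("indel_b%d_%d", k, eid), "indeterminate_indel",
                    k, r$end - r$start + 1L, c(r$start, r$end),
                    carrierGenes = r$gapRows, gapRows = r$gapRows,
                    evidence = "internal_gap",
                    detail = list(polarityResolved = FALSE))
            }
        }
    }
    list(events = events, hotspots = hotspots)
}

#' Detect intron gain/loss between two annotated gene models
#'
#' An intron change is called when one exon of one gene aligns perfectly
#' (identity >= \code{minIdentity} on each sub-segment) to the concatenation
#' of two neighbouring exons of the other gene, with the junction within
#' \code{junctionTolerance} bp of the partner's exon boundary.  No gaps are
#' involved; only the exon numbers differ.  The loss-vs-gain polarity is
#' resolved by parsimony mapping; the reported event carries the merged
#' exon's length in its detail and \code{lengthBp} 0.
#'
#' @param gmA,gmB annotated \code{GeneModel}s.
#' @param minIdentity per-sub-segment identity for a "perfect" alignment
#'   (default 0.9).
#' @param junctionTolerance allowed offset (bp) between the alignment
#'   junction and the partner's boundary (default 3).
#' @return list of \code{StructuralEvent} (possibly empty).
#' @examples
#' fx <- emitFixture("brassicaceae_intron_loss")
#' ev <- detectIntronChange(models(fx$family)[[1]], models(fx$family)[[2]])
#' ev[[1]]@detail$mergedExonLength   # 84
#' @export
detectIntronChange <- function(gmA, gmB, minIdentity = 0.9,
                               junctionTolerance = 3L) {
    if (!isAnnotated(gmA) || !isAnnotated(gmB))
        stop("structural annotation required for both genes")
    # orient: S has fewer exons (candidate merged), M more
    swap <- length(exonLengths(gmA)) > length(exonLengths(gmB))
    S <- if (swap) gmB else gmA
    M <- if (swap) gmA else gmB
    if (length(exonLengths(S)) == length(exonLengths(M))) return(list())
    exS <- as.character(exonSeqs(S)); exM <- as.character(exonSeqs(M))
    events <- list()
    for (i in seq_along(exS)) {
        for (j in seq_len(length(exM) - 1L)) {
            merged <- paste0(exM[j], exM[j + 1L])
            if (abs(nchar(exS[i]) - nchar(merged)) > junctionTolerance)
                next
            pa <- alignPair(exS[i], merged, mode = "global")
            # split the alignment at the partner's junction
            tpos <- cumsum(strChars(pa@alignedTarget) != "-")
            junctionCol <- which(tpos == nchar(exM[j]))[1]
            if (is.na(junctionCol)) next
            idSeg <- function(colsel) {
                a <- strChars(pa@alignedQuery)[colsel]
                b <- strChars(pa@alignedTarget)[colsel]
                keep <- !(a == "-" & b == "-")
                a <- a[keep]; b <- b[keep]
                if (!length(a)) return(0)
                sum(a == b & a != "-") / length(a)
            }
            ncols <- nchar(pa@alignedQuery)
            id1 <- idSeg(seq_len(junctionCol))
            id2 <- idSeg(seq(junctionCol + 1L, ncols))
            # no gaps may be required at the junction region
            qchars <- strChars(pa@alignedQuery)
            jwin <- max(1L, junctionCol - junctionTolerance):
                    min(ncols, junctionCol + junctionTolerance)
            if (any(qchars[jwin] == "-")) next
            if (id1 >= minIdentity && id2 >= minIdentity) {
                events[[length(events) + 1L]] <- newEvent(
                    sprintf("intron_%s_%d", geneId(S), i),
                    "intron_loss", j, 0L, c(NA_integer_, NA_integer_),
                    carrierGenes = geneId(S), gapRows = geneId(M),
                    evidence = "exon_merge",
                    detail = list(polarityResolved = FALSE,
                                  mergedExonLength = nchar(exS[i]),
                                  mergedExonIndex = i,
                                  splitLengths = c(nchar(exM[j]),
                                                   nchar(exM[j + 1L])),
                                  identities = c(id1, id2)))
            }
        }
    }
    events
}

#' Detect stop-codon-driven terminal-exon events between two genes
#'
#' Covers the two classic scenarios.  Readthrough exonization: one gene's
#' terminal coding region extends beyond the other's stop codon, the stop
#' codon columns are substituted (not gapped), and the extension aligns to
#' the shorter gene's 3' UTR.  Frameshift pseudoexonization: a non-triplet
#' indel inside the terminal exon creates a premature in-frame stop, turning
#' the reference-coding tail beyond the new stop into noncoding sequence;
#' the emitted pseudoexonization is linked to its causal indel.
#'
#' @param gmA,gmB gene models with terminal exons; \code{gmB} acts as the
#'   reference when lengths differ.
#' @param flank3B optional override of \code{gmB}'s 3' flanking sequence.
#' @param flankWindow bp of 3' flank used for alignment and the stop search
#'   (default 200).
#' @param minIdentity,minCols alignability threshold for the UTR test.
#' @return list of \code{StructuralEvent} (possibly empty).
#' @export
detectStopCodonEvents <- function(gmA, gmB, flank3B = NULL,
                                  flankWindow = 200L,
                                  minIdentity = 0.5, minCols = 15L) {
    exA <- as.character(exonSeqs(gmA)); exB <- as.character(exonSeqs(gmB))
    termA <- exA[length(exA)]; termB <- exB[length(exB)]
    fA <- substr(as.character(flank3(gmA)), 1L, flankWindow)
    fB <- if (is.null(flank3B)) as.character(flank3(gmB))
          else as.character(flank3B)
    fB <- substr(fB, 1L, flankWindow)
    # unterminated ORF guard: a stop must exist in some frame within the
    # terminal exon plus the flank window
    for (nm in c("A", "B")) {
        s <- if (nm == "A") paste0(termA, fA) else paste0(termB, fB)
        found <- any(!is.na(vapply(1:3, function(f)
            firstInFrameStop(s, f), integer(1))))
        if (!found)
            stop(sprintf("unterminated ORF: gene %s",
                         if (nm == "A") geneId(gmA) else geneId(gmB)))
    }
    regA <- paste0(termA, fA); regB <- paste0(termB, fB)
    pa <- alignPair(regA, regB, mode = "global")
    a <- strChars(pa@alignedQuery); b <- strChars(pa@alignedTarget)
    posA <- cumsum(a != "-"); posA[a == "-"] <- NA
    posB <- cumsum(b != "-"); posB[b == "-"] <- NA
    codEndA <- nchar(termA); codEndB <- nchar(termB)
    colA <- which(!is.na(posA) & posA == codEndA)[1]
    colB <- which(!is.na(posB) & posB == codEndB)[1]
    events <- list()
    # interior indels within the overlap of both coding spans
    lastCod <- min(colA, colB)
    runsA <- gapRuns(a); runsB <- gapRuns(b)
    indelEvents <- list()
    collect <- function(runs, inWhom) {
        for (r in seq_len(nrow(runs))) {
            rs <- runs[r, "start"]; re <- runs[r, "end"]
            if (rs <= 1L || re >= lastCod) next
            L <- re - rs + 1L
            indelEvents[[length(indelEvents) + 1L]] <<- newEvent(
                sprintf("term_indel_%d", length(indelEvents) + 1L),
                "indeterminate_indel",
                length(exB), L, c(rs, re),
                carrierGenes = if (inWhom == "A") geneId(gmA) else geneId(gmB),
                gapRows = if (inWhom == "A") geneId(gmA) else geneId(gmB),
                evidence = "internal_gap",
                detail = list(polarityResolved = FALSE, terminalExon = TRUE))
        }
    }
    if (nrow(runsA)) collect(runsA, "A")
    if (nrow(runsB)) collect(runsB, "B")
    events <- c(events, indelEvents)
    if (!is.na(colA) && !is.na(colB) && colA != colB) {
        long <- if (colA > colB) "A" else "B"
        colShort <- min(colA, colB); colLong <- max(colA, colB)
        longChars <- if (long == "A") a else b
        shortChars <- if (long == "A") b else a
        gmLong <- if (long == "A") gmA else gmB
        gmShort <- if (long == "A") gmB else gmA
        flankShort <- if (long == "A") fB else fA
        # extension: coding characters of the long gene beyond the short
        # gene's coding end column
        extCols <- seq(colShort + 1L, colLong)
        ext <- longChars[extCols]; ext <- paste(ext[ext != "-"], collapse = "")
        # stop codon columns of the short gene (its last three coding bases)
        stopCols <- which(!is.na(if (long == "A") posB else posA) &
                          (if (long == "A") posB else posA) >= codEndShort(gmShort))
        stopCols <- stopCols[seq_len(min(3L, length(stopCols)))]
        stopSubstituted <- length(stopCols) == 3L &&
            all(longChars[stopCols] != "-") &&
            any(longChars[stopCols] != shortChars[stopCols])
        aligned <- all(shortChars[extCols] != "-") ||
            isTRUE(isAlignable(ext, flankShort, minIdentity,
                               min(minCols, nchar(ext))))
        if (stopSubstituted && aligned && nchar(ext) > 0L) {
            # readthrough: the long gene exonized the short gene's UTR
            events[[length(events) + 1L]] <- newEvent(
                "term_exonization", "exonization", length(exB), nchar(ext),
                c(colShort + 1L, colLong),
                carrierGenes = geneId(gmLong), gapRows = geneId(gmShort),
                evidence = "stop_codon_change",
                detail = list(polarityResolved = FALSE, terminalExon = TRUE))
        } else if (nchar(ext) > 0L) {
            # premature stop in the short gene: reference-coding tail beyond
            # its stop is pseudoexonized; link the causal frameshift indel
            causal <- Filter(function(e) !e@framePreserving, indelEvents)
            pseudoLen <- nchar(ext)
            events[[length(events) + 1L]] <- newEvent(
                "term_pseudoexonization", "pseudoexonization", length(exB),
                pseudoLen, c(colShort + 1L, colLong),
                carrierGenes = geneId(gmShort), gapRows = geneId(gmShort),
                evidence = "stop_codon_change",
                detail = list(polarityResolved = TRUE, terminalExon = TRUE,
                              linkedIndel = if (length(causal))
                                  causal[[1]]@eventId else NA_character_))
        }
    }
    events
}

codEndShort <- function(gm) {
    ex <- exonLengths(gm)
    ex[length(ex)] - 2L
}

# A single char of one row occasionally gets matched inside an indel
# region, splitting what is biologically one event into a long run and a
# sliver.  Runs with identical gap signatures separated by <= maxSep
# columns are coalesced back into one event and re-classified against the
# flanking noncoding sequence when they touch a consensus boundary.
coalesceSliverEvents <- function(events, aln, fs, boundaries, spans,
                                 minIdentity, minCols, maxSep = 2L) {
    if (length(events) < 2L) return(events)
    repeat {
        mergedAny <- FALSE
        for (i in seq_along(events)) {
            for (j in seq_along(events)) {
                if (j <= i) next
                e1 <- events[[i]]; e2 <- events[[j]]
                if (e1@mechanism != "indeterminate_indel" ||
                    e2@mechanism != "indeterminate_indel") next
                if (!setequal(e1@gapRows, e2@gapRows)) next
                s1 <- e1@columnSpan; s2 <- e2@columnSpan
                if (anyNA(c(s1, s2))) next
                sep <- max(s1[1], s2[1]) - min(s1[2], s2[2]) - 1L
                if (sep < 0L || sep > maxSep) next
                span <- c(min(s1[1], s2[1]), max(s1[2], s2[2]))
                gapRows <- e1@gapRows
                informative <- union(e1@detail$informativeRows,
                                     e2@detail$informativeRows)
                seqRows <- setdiff(informative, gapRows)
                L <- e1@lengthBp + e2@lengthBp
                big <- if (e1@lengthBp >= e2@lengthBp) e1 else e2
                newE <- NULL
                b <- boundaries[boundaries >= span[1] - 1L &
                                boundaries <= span[2] + 1L]
                if (length(b) && length(seqRows)) {
                    k <- match(b[1], boundaries) + 1L
                    cols <- span[1]:span[2]
                    gmask <- aln@mat[gapRows[1], cols] == "-"
                    fchars <- aln@mat[seqRows[1], cols]
                    focal <- paste(fchars[gmask & fchars != "-"],
                                   collapse = "")
                    nc <- NULL
                    for (r in gapRows) {
                        nc <- rowNoncodingAt(aln, fs, r, k, 5L, b[1] + 1L,
                                             nrow(spans))
                        if (!is.null(nc)) break
                    }
                    if (!is.null(nc) && nchar(focal) >= minCols &&
                        isTRUE(isAlignable(focal, nc, minIdentity, minCols)))
                        newE <- newEvent(paste0(big@eventId, "m"),
                                         "exonization", k, L, span, seqRows,
                                         gapRows,
                                         "boundary_gap_noncoding_alignable",
                                         detail = list(
                                             polarityResolved = FALSE,
                                             coalesced = TRUE,
                                             informativeRows = informative))
                }
                if (is.null(newE))
                    newE <- newEvent(paste0(big@eventId, "m"),
                                     "indeterminate_indel", big@exonIndex,
                                     L, span, gapRows, gapRows,
                                     "internal_gap",
                                     detail = list(polarityResolved = FALSE,
                                                   coalesced = TRUE,
                                                   informativeRows =
                                                       informative))
                events[[i]] <- newE
                events[[j]] <- NULL
                mergedAny <- TRUE
                break
            }
            if (mergedAny) break
        }
        if (!mergedAny) break
    }
    events
}

#' Detect structural events across a boundary-marked family alignment
#'
#' Walks the consensus exon blocks of the alignment and attributes every
#' gap column to an event (or to an indel hotspot handed to masking):
#' interior gap-signature runs become intraexonic indel candidates, runs
#' abutting consensus boundaries are classified against the flanking
#' noncoding sequence (exonization class, whole-exon change, or
#' indeterminate indel), rows lacking a consensus boundary are tested for
#' intron gain/loss, and coding-length differences at the 3' terminus are
#' classified with stop-codon awareness.  All polarity decisions are left
#' to \code{\link{mapEvent}}.
#'
#' @param aln refined, boundary-marked \code{CodonAlignment}.
#' @param fs the \code{FamilySet}.
#' @param hotspotMax see \code{\link{detectInternalIndels}}.
#' @param minIdentity,minCols alignability threshold.
#' @param perfectIdentity per-sub-segment identity for intron-change calls.
#' @param junctionTolerance junction offset tolerance (bp) for intron
#'   changes.
#' @return list with \code{events} and \code{hotspots}.
#' @export
detectEvents <- function(aln, fs, hotspotMax = 2L, minIdentity = 0.5,
                         minCols = 15L, perfectIdentity = 0.9,
                         junctionTolerance = 3L) {
    boundaries <- consensusBoundaries(aln)
    spans <- blockSpans(aln, boundaries)
    rows <- rownames(aln@mat)
    events <- list(); hotspots <- list()
    eid <- 0L
    nextId <- function(prefix) {
        eid <<- eid + 1L
        sprintf("%s_%03d", prefix, eid)
    }
    # whole-exon pass: an exon bracketed by one row's own boundaries in
    # which the other rows are predominantly gapped marks an exon
    # gain/loss-type event.  Anchoring on the annotation makes the call
    # (and the event length) robust to gap fragmentation when a unique
    # exon has no homologous counterpart to align against.
    brackets <- list()
    for (r in rows) {
        if (!isTRUE(aln@annotatedRows[[r]])) next
        bc <- aln@boundaryCols[[r]]
        edges <- c(0L, bc, ncol(aln@mat))
        rowStart <- which(aln@mat[r, ] != "-")[1]
        rowEnd <- max(which(aln@mat[r, ] != "-"))
        for (i in seq_len(length(edges) - 1L)) {
            bs <- max(edges[i] + 1L, rowStart); be <- min(edges[i + 1L], rowEnd)
            if (be - bs + 1L < 15L) next
            sub <- aln@mat[, bs:be, drop = FALSE]
            gf <- rowMeans(sub == "-")
            gapRows <- rows[gf >= 0.7]
            seqRows <- rows[gf <= 0.5]
            if (!length(gapRows) || !(r %in% seqRows)) next
            dup <- any(vapply(brackets, function(b)
                min(b$end, be) - max(b$start, bs) + 1L >
                    0.5 * (be - bs + 1L), logical(1)))
            if (dup) next
            brackets[[length(brackets) + 1L]] <-
                list(start = bs, end = be, gapRows = gapRows,
                     seqRows = seqRows, row = r)
        }
    }
    for (b in brackets) {
        k <- which(spans[, "start"] <= (b$start + b$end) %/% 2L &
                   spans[, "end"] >= (b$start + b$end) %/% 2L)[1]
        run <- list(start = b$start, end = b$end, gapRows = b$gapRows)
        e <- tryCatch(
            classifyWholeExon(aln, fs, run, k, spans, nextId("exon"),
                              minIdentity, minCols),
            error = function(err) NULL)
        if (is.null(e)) next
        e@detail$informativeRows <- union(b$seqRows, b$gapRows)
        events[[length(events) + 1L]] <- e
    }
    inBracket <- function(run) {
        for (b in brackets) {
            if (run$start >= b$start - 2L && run$end <= b$end + 2L &&
                all(run$gapRows %in% b$gapRows)) return(TRUE)
        }
        FALSE
    }
    for (k in seq_len(nrow(spans))) {
        cols <- spans[k, "start"]:spans[k, "end"]
        informative <- rows[vapply(rows, function(r)
            any(aln@mat[r, cols] != "-"), logical(1))]
        if (length(informative) < 2L) next
        runs <- gapSignatureRuns(aln@mat, cols, informative)
        if (!length(runs)) next
        grp <- cumsum(c(TRUE, vapply(seq_along(runs)[-1], function(i)
            runs[[i]]$start > runs[[i - 1L]]$end + 1L, logical(1))))
        for (g in unique(grp)) {
            members <- runs[grp == g]
            if (length(members) > hotspotMax) {
                hotspots[[length(hotspots) + 1L]] <- list(
                    start = members[[1]]$start,
                    end = members[[length(members)]]$end, block = k)
                next
            }
            for (r in members) {
                if (r$start == spans[k, "start"] && r$end == spans[k, "end"])
                    next  # whole-block absence handled by the bracket pass
                if (inBracket(r)) next
                e <- if (r$start == spans[k, "start"]) {
                    classifyBoundaryGap(aln, fs, r, k, 5L, nextId("bnd"),
                                        minIdentity, minCols)
                } else if (r$end == spans[k, "end"]) {
                    classifyBoundaryGap(aln, fs, r, k, 3L, nextId("bnd"),
                                        minIdentity, minCols)
                } else {
                    newEvent(nextId("indel"), "indeterminate_indel", k,
                             r$end - r$start + 1L, c(r$start, r$end),
                             carrierGenes = r$gapRows, gapRows = r$gapRows,
                             evidence = "internal_gap",
                             detail = list(polarityResolved = FALSE))
                }
                e@detail$informativeRows <- informative
                events[[length(events) + 1L]] <- e
            }
        }
    }
    events <- coalesceSliverEvents(events, aln, fs, boundaries, spans,
                                   minIdentity, minCols)
    # intron gain by a minority clade: boundary clusters supported by fewer
    # than half of the annotated rows, away from any consensus junction,
    # mark exons split by a novel intron; the unsplit (merged-state)
    # majority must align perfectly across the candidate junction
    annRows <- rownames(aln@mat)[vapply(rownames(aln@mat), function(r)
        isTRUE(aln@annotatedRows[[r]]), logical(1))]
    if (length(annRows) >= 2L) {
        pairs <- do.call(rbind, lapply(annRows, function(r) {
            bc <- aln@boundaryCols[[r]]
            if (!length(bc)) return(NULL)
            data.frame(row = r, col = bc, stringsAsFactors = FALSE)
        }))
        if (!is.null(pairs) && nrow(pairs)) {
            pairs <- pairs[order(pairs$col), , drop = FALSE]
            cl <- cumsum(c(1L, diff(pairs$col) > 12L))
            for (g in unique(cl)) {
                sub <- pairs[cl == g, , drop = FALSE]
                splitRows <- unique(sub$row)
                if (length(splitRows) >= length(annRows) / 2) next
                tabc <- table(sub$col)
                col <- as.integer(names(tabc)[which.max(tabc)])
                if (length(boundaries) && min(abs(boundaries - col)) <= 12L)
                    next
                k <- which(spans[, "start"] <= col & spans[, "end"] > col)
                if (!length(k)) next
                mergedRows <- setdiff(annRows, splitRows)
                confirmed <- character(); mergedLen <- NA_integer_
                splitLens <- NULL
                for (r in splitRows) {
                    jwin <- max(spans[k, "start"], col - junctionTolerance):
                            min(spans[k, "end"], col + junctionTolerance)
                    if (any(aln@mat[r, jwin] == "-")) next
                    for (p in mergedRows) {
                        idSeg <- function(colsel) {
                            x <- aln@mat[r, colsel]; y <- aln@mat[p, colsel]
                            keep <- !(x == "-" & y == "-")
                            x <- x[keep]; y <- y[keep]
                            if (!length(x)) return(0)
                            sum(x == y & x != "-") / length(x)
                        }
                        if (idSeg(spans[k, "start"]:col) >= perfectIdentity &&
                            idSeg((col + 1L):spans[k, "end"]) >=
                                perfectIdentity) {
                            confirmed <- c(confirmed, r)
                            mergedLen <- sum(aln@mat[p,
                                spans[k, "start"]:spans[k, "end"]] != "-")
                            splitLens <- c(
                                sum(aln@mat[r, spans[k, "start"]:col] != "-"),
                                sum(aln@mat[r, (col + 1L):spans[k, "end"]]
                                    != "-"))
                            break
                        }
                    }
                }
                if (length(confirmed)) {
                    events[[length(events) + 1L]] <- newEvent(
                        nextId("intron"), "intron_loss", k, 0L,
                        c(spans[k, "start"], spans[k, "end"]),
                        carrierGenes = mergedRows, gapRows = confirmed,
                        evidence = "exon_merge",
                        detail = list(polarityResolved = FALSE,
                                      mergedExonLength = mergedLen,
                                      boundaryColumn = col,
                                      referenceSplit = FALSE,
                                      splitLengths = splitLens,
                                      informativeRows = union(confirmed,
                                                              mergedRows)))
                }
            }
        }
    }
    # intron gain/loss: annotated rows lacking a consensus boundary
    for (bi in seq_along(boundaries)) {
        col <- boundaries[bi]
        haveB <- character(); lackB <- character()
        for (r in rows) {
            if (!aln@annotatedRows[[r]]) next
            bc <- aln@boundaryCols[[r]]
            if (any(abs(bc - col) <= junctionTolerance))
                haveB <- c(haveB, r)
            else lackB <- c(lackB, r)
        }
        if (!length(lackB) || !length(haveB)) next
        # the merged row must be gapless around the junction and align
        # "perfectly" to a boundary-bearing row on both sides
        spanL <- spans[bi, ]; spanR <- spans[bi + 1L, ]
        confirmed <- character()
        mergedLen <- NA_integer_
        for (r in lackB) {
            # skip rows that simply lack the exon
            rc <- aln@mat[r, c(spanL["start"]:spanL["end"],
                               spanR["start"]:spanR["end"])]
            if (all(rc == "-")) next
            jwin <- max(spanL["start"], col - junctionTolerance):
                    min(spanR["end"], col + junctionTolerance)
            if (any(aln@mat[r, jwin] == "-")) next
            ok <- FALSE
            for (p in haveB) {
                idSeg <- function(colsel) {
                    x <- aln@mat[r, colsel]; y <- aln@mat[p, colsel]
                    keep <- !(x == "-" & y == "-")
                    x <- x[keep]; y <- y[keep]
                    if (!length(x)) return(0)
                    sum(x == y & x != "-") / length(x)
                }
                if (idSeg(spanL["start"]:spanL["end"]) >= perfectIdentity &&
                    idSeg(spanR["start"]:spanR["end"]) >= perfectIdentity) {
                    ok <- TRUE; break
                }
            }
            if (ok) {
                confirmed <- c(confirmed, r)
                rc2 <- aln@mat[r, c(spanL["start"]:spanL["end"],
                                    spanR["start"]:spanR["end"])]
                mergedLen <- sum(rc2 != "-")
            }
        }
        if (length(confirmed)) {
            events[[length(events) + 1L]] <- newEvent(
                nextId("intron"), "intron_loss", bi, 0L,
                c(spans[bi, "start"], spans[bi + 1L, "end"]),
                carrierGenes = confirmed, gapRows = setdiff(haveB, confirmed),
                evidence = "exon_merge",
                detail = list(polarityResolved = FALSE,
                              mergedExonLength = mergedLen,
                              boundaryColumn = col,
                              referenceSplit = TRUE,
                              informativeRows = union(confirmed, haveB)))
        }
    }
    list(events = events, hotspots = hotspots)
}
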