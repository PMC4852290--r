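#' @include AllClasses.R gene-models.R align.R events.R
NULL

#' Filter gene models by CDS length and same-species redundancy
#'
#' Applies the two quantitative retention rules: coding sequences shorter
#' than \code{minCds} bp are excluded as uninformative, and among multiple
#' highly similar sequences from the same species (pairwise CDS identity
#' above \code{dedupeIdentity}, treated as alleles of one gene) exactly one
#' representative is kept -- the longest CDS, ties broken by gene id.
#' Identity is computed on a global CDS alignment (match 1 / mismatch 0,
#' affine gaps), matches over non-terminal-gap columns.  Every removal is
#' logged in the provenance slot; the operation is idempotent.
#'
#' @param fs a \code{FamilySet}.
#' @param minCds minimum retained CDS length in bp (default 400).
#' @param dedupeIdentity same-species identity above which only one of a
#'   pair survives (default 0.95).
#' @return the filtered \code{FamilySet}.
#' @export
filterModels <- function(fs, minCds = 400L, dedupeIdentity = 0.95) {
    keep <- names(fs)
    # length rule
    short <- keep[vapply(keep, function(id)
        length(cdsSeq(fs[[id]])) < minCds, logical(1))]
    for (id in short)
        fs <- addProvenance(fs, id, "removed",
                            sprintf("CDS shorter than %d bp (%d bp)",
                                    minCds, length(cdsSeq(fs[[id]]))))
    keep <- setdiff(keep, short)
    # same-species near-identity rule
    sp <- vapply(keep, function(id) speciesId(fs[[id]]), character(1))
    removed <- character()
    for (s in unique(sp[!is.na(sp)])) {
        ids <- keep[!is.na(sp) & sp == s]
        if (length(ids) < 2L) next
        # connected components of the >identity graph
        comp <- seq_along(ids)
        pairsId <- list()
        for (i in seq_len(length(ids) - 1L)) {
            for (j in seq(i + 1L, length(ids))) {
                idty <- cdsIdentity(as.character(cdsSeq(fs[[ids[i]]])),
                                    as.character(cdsSeq(fs[[ids[j]]])))
                if (!is.nan(idty) && idty > dedupeIdentity) {
                    comp[comp == comp[j]] <- comp[i]
                    pairsId[[paste(i, j)]] <- idty
                }
            }
        }
        for (cl in unique(comp)) {
            members <- ids[comp == cl]
            if (length(members) < 2L) next
            lens <- vapply(members, function(id)
                length(cdsSeq(fs[[id]])), integer(1))
            o <- order(-lens, members)
            winner <- members[o][1]
            losers <- setdiff(members, winner)
            for (id in losers)
                fs <- addProvenance(fs, id, "removed",
                    sprintf("redundant with %s (same species, CDS identity > %.2f)",
                            winner, dedupeIdentity))
            removed <- c(removed, losers)
        }
    }
    keep <- setdiff(keep, removed)
    if (!length(keep))
        warning("filterModels removed every gene model")
    fs@models <- fs@models[keep]
    fs@subfamilyLabels <- fs@subfamilyLabels[
        names(fs@subfamilyLabels) %in% keep]
    fs@outgroup <- intersect(fs@outgroup, keep)
    validObject(fs)
    fs
}

#' Count structural differences between two gene models
#'
#' Pairwise structural-event count used as the divergence score for
#' transcript selection: the two CDSs are globally aligned, exon
#' boundaries marked where annotated, gap runs attributed to events, and
#' intron changes added when the exon counts differ.
#'
#' @param gmA,gmB gene models.
#' @return list with \code{nEvents} and \code{totalLength} (bp).
#' @export
pairwiseStructuralDivergence <- function(gmA, gmB) {
    pa <- alignPair(as.character(cdsSeq(gmA)), as.character(cdsSeq(gmB)),
                    mode = "global")
    mat <- rbind(strChars(pa@alignedQuery), strChars(pa@alignedTarget))
    rownames(mat) <- c(geneId(gmA), geneId(gmB))
    aln <- newCodonAlignment(mat)
    fs <- FamilySet(list(gmA, gmB))
    aln <- markExonBoundaries(aln, fs)
    det <- detectEvents(aln, fs)
    ev <- det$events
    n <- length(ev)
    total <- sum(vapply(ev, function(e) e@lengthBp, integer(1)))
    if (isAnnotated(gmA) && isAnnotated(gmB) &&
        length(exonLengths(gmA)) != length(exonLengths(gmB))) {
        ic <- detectIntronChange(gmA, gmB)
        # intron changes already visible as merged boundaries carry no gaps,
        # so they are counted in addition to gap-based events
        n <- n + length(ic)
    }
    list(nEvents = n, totalLength = total)
}

#' Select the transcript with the least structural divergence
#'
#' Among alternative transcripts of one locus, returns the isoform with
#' the smallest structural-divergence score against its nearest reference
#' (the reference with the highest CDS identity): fewest detected events,
#' ties broken by smaller total event length, then by transcript id.
#'
#' @param isoforms list of \code{GeneModel} sharing a locus.
#' @param references a non-empty \code{FamilySet} of homologs.
#' @return the selected \code{GeneModel}.
#' @export
selectTranscript <- function(isoforms, references) {
    stopifnot(length(isoforms) >= 1L, length(references) >= 1L)
    if (length(isoforms) == 1L) return(isoforms[[1]])
    scores <- lapply(isoforms, function(iso) {
        ids <- vapply(names(references), function(rid)
            cdsIdentity(as.character(cdsSeq(iso)),
                        as.character(cdsSeq(references[[rid]]))),
            numeric(1))
        if (all(is.nan(ids)) ||
            !isTRUE(isAlignable(as.character(cdsSeq(iso)),
                                as.character(cdsSeq(
                                    references[[names(which.max(ids))]])))))
            return(NULL)
        ref <- references[[names(which.max(ids))]]
        div <- pairwiseStructuralDivergence(iso, ref)
        list(n = div$nEvents, len = div$totalLength, id = geneId(iso))
    })
    ok <- !vapply(scores, is.null, logical(1))
    if (!any(ok))
        stop("unclassifiable locus: no isoform alignable to any reference")
    scores <- scores[ok]; isoforms <- isoforms[ok]
    o <- order(vapply(scores, `[[`, numeric(1), "n"),
               vapply(scores, `[[`, numeric(1), "len"),
               vapply(scores, `[[`, character(1), "id"))
    isoforms[[o[1]]]
}
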