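#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a GeneModel
#'
#' @param geneId gene identifier.
#' @param cds coding sequence (string or \code{DNAString}).
#' @param exonLengths integer vector of exon lengths summing to the CDS
#'   length; \code{NULL} marks the gene as structurally unannotated (a single
#'   placeholder exon spanning the CDS is recorded).
#' @param speciesId species tag.
#' @param strand \code{"+"} or \code{"-"}.
#' @param introns optional \code{DNAStringSet}/character of intron sequences.
#' @param flank5,flank3 optional flanking noncoding sequence.
#' @param exons optional \code{GRanges} of genomic exon coordinates.
#' @param annotationSource free-text provenance of the annotation.
#' @return a validated \code{GeneModel}.
#' @examples
#' gm <- GeneModel("toy", "ATGAAACCCGGGTAA", exonLengths = c(9, 6))
#' exonLengths(gm)
#' @export
GeneModel <- function(geneId, cds, exonLengths = NULL, speciesId = NA_character_,
                      strand = "+", introns = NULL, flank5 = "", flank3 = "",
                      exons = GRanges(), annotationSource = "constructed") {
    cds <- DNAString(as.character(cds))
    annotated <- !is.null(exonLengths)
    if (is.null(exonLengths))
        exonLengths <- length(cds)
    if (is.null(introns)) introns <- DNAStringSet()
    if (is.character(introns)) introns <- DNAStringSet(introns)
    new("GeneModel", geneId = as.character(geneId),
        speciesId = as.character(speciesId), strand = strand,
        exonLengths = as.integer(exonLengths), exons = exons, cds = cds,
        introns = introns, flank5 = DNAString(as.character(flank5)),
        flank3 = DNAString(as.character(flank3)),
        annotationSource = annotationSource, annotated = annotated)
}

#' @describeIn GeneModel gene identifier
#' @param x a \code{GeneModel}
#' @export
setMethod("geneId", "GeneModel", function(x) x@geneId)

#' @export
setMethod("speciesId", "GeneModel", function(x) x@speciesId)

#' @export
setMethod("cdsSeq", "GeneModel", function(x) x@cds)

#' @export
setMethod("exonLengths", "GeneModel", function(x) x@exonLengths)

#' @export
setMethod("intronSeqs", "GeneModel", function(x) x@introns)

#' @export
setMethod("flank5", "GeneModel", function(x) x@flank5)

#' @export
setMethod("flank3", "GeneModel", function(x) x@flank3)

#' @export
setMethod("isAnnotated", "GeneModel", function(x) x@annotated)

#' Exon sequences of a gene model
#'
#' Slices the CDS at the cumulative exon lengths; by construction their
#' concatenation equals the CDS.
#' @param x a \code{GeneModel}.
#' @return \code{DNAStringSet}, one entry per exon in transcript order.
#' @export
setMethod("exonSeqs", "GeneModel", function(x) {
    ends <- cumsum(x@exonLengths)
    starts <- c(1L, head(ends, -1L) + 1L)
    DNAStringSet(mapply(function(s, e) as.character(subseq(x@cds, s, e)),
                        starts, ends))
})

setMethod("show", "GeneModel", function(object) {
    cat(sprintf("GeneModel %s (%s, %s strand): %d bp CDS, %d exon(s)%s\n",
                object@geneId,
                ifelse(is.na(object@speciesId), "species NA", object@speciesId),
                object@strand, length(object@cds),
                length(object@exonLengths),
                if (object@annotated)
                    paste0(" [", paste(object@exonLengths, collapse = ","), "]")
                else " (unannotated)"))
})

#' Construct a FamilySet
#'
#' @param models list of \code{GeneModel}.
#' @param subfamilyLabels optional named character vector (gene id -> label).
#' @param outgroup optional character vector of outgroup gene ids.
#' @return a validated \code{FamilySet}.
#' @export
FamilySet <- function(models = list(), subfamilyLabels = character(),
                      outgroup = character()) {
    names(models) <- vapply(models, geneId, character(1))
    new("FamilySet", models = models, subfamilyLabels = subfamilyLabels,
        outgroup = outgroup)
}

#' @export
setMethod("models", "FamilySet", function(x) x@models)

#' @export
setMethod("provenance", "FamilySet", function(x) x@provenance)

#' @export
setMethod("subfamilyLabels", "FamilySet", function(x) x@subfamilyLabels)

#' @export
setMethod("outgroup", "FamilySet", function(x) x@outgroup)

#' @export
setReplaceMethod("outgroup", "FamilySet", function(x, value) {
    x@outgroup <- value
    validObject(x)
    x
})

#' @export
setMethod("length", "FamilySet", function(x) length(x@models))

#' @export
setMethod("names", "FamilySet", function(x) names(x@models))

#' @export
setMethod("[[", "FamilySet", function(x, i) x@models[[i]])

setMethod("show", "FamilySet", function(object) {
    cat(sprintf("FamilySet with %d gene model(s)", length(object@models)))
    if (length(object@outgroup))
        cat(sprintf(", outgroup: %s",
                    paste(object@outgroup, collapse = ", ")))
    cat("\n")
    if (nrow(object@provenance))
        cat(sprintf("  provenance log: %d record(s)\n", nrow(object@provenance)))
})

addProvenance <- function(fs, geneIds, action, reason) {
    if (!length(geneIds)) return(fs)
    fs@provenance <- rbind(fs@provenance,
        data.frame(gene_id = geneIds, action = action, reason = reason,
                   stringsAsFactors = FALSE))
    fs
}
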