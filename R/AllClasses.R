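#' @import methods
#' @importFrom Biostrings DNAString DNAStringSet AAStringSet readDNAStringSet
#'   readAAStringSet writeXStringSet reverseComplement translate subseq
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols DataFrame
#' @importFrom BiocGenerics strand start end width
#' @importFrom stats rpois runif rgeom setNames
#' @importFrom utils write.table read.table head tail
#' @useDynLib exonEvo, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

VALID_MECHANISMS <- c("exonization", "pseudoexonization", "exon_gain",
                      "exon_loss", "intron_gain", "intron_loss",
                      "intraexonic_insertion", "intraexonic_deletion",
                      "indeterminate_indel", "indeterminate_exon_change")

VALID_EVIDENCE <- c("boundary_gap_noncoding_alignable", "whole_exon_unalignable",
                    "internal_gap", "exon_merge", "stop_codon_change", "scan_hit")

#' GeneModel: one gene's exon-intron structure and sequences
#'
#' A \code{GeneModel} holds a single gene's coding sequence, its ordered exon
#' lengths (5' to 3' in transcript orientation), and, when genomic sequence is
#' available, the intron sequences and flanking noncoding sequence on each
#' side.  The concatenation of the exon sequences equals the CDS exactly; the
#' CDS length need not be a multiple of three, so frameshifted descendants are
#' legal inputs.
#'
#' @slot geneId single gene identifier.
#' @slot speciesId species tag used by the same-species deduplication rule.
#' @slot strand \code{"+"} or \code{"-"} (genomic orientation of the model).
#' @slot exonLengths integer vector of exon lengths in bp, transcript order.
#' @slot exons optional \code{GRanges} of genomic exon coordinates in
#'   transcript order (0-based half-open externally; \code{GRanges} is 1-based
#'   internally as usual).
#' @slot cds the coding sequence (a \code{DNAString}).
#' @slot introns \code{DNAStringSet} of intron sequences in transcript order
#'   (empty when no genomic sequence was supplied).
#' @slot flank5,flank3 flanking noncoding sequence (may be empty).
#' @slot annotationSource free-text origin of the structural annotation.
#' @slot annotated \code{TRUE} when exon lengths come from a structural
#'   annotation rather than being a single-exon placeholder.
#' @export
setClass("GeneModel",
    representation(geneId = "character", speciesId = "character",
                   strand = "character", exonLengths = "integer",
                   exons = "GRanges", cds = "DNAString",
                   introns = "DNAStringSet", flank5 = "DNAString",
                   flank3 = "DNAString", annotationSource = "character",
                   annotated = "logical"),
    prototype(speciesId = NA_character_, strand = "+",
              annotationSource = "constructed", annotated = FALSE))

setValidity("GeneModel", function(object) {
    msg <- character()
    if (length(object@geneId) != 1L || is.na(object@geneId) ||
        !nzchar(object@geneId))
        msg <- c(msg, "geneId must be a single non-empty string")
    if (!object@strand %in% c("+", "-"))
        msg <- c(msg, "strand must be '+' or '-'")
    if (length(object@exonLengths)) {
        if (any(object@exonLengths <= 0L))
            msg <- c(msg, "every exon length must be > 0")
        if (sum(object@exonLengths) != length(object@cds))
            msg <- c(msg, sprintf(
                "sum(exonLengths) == %d but CDS length is %d",
                sum(object@exonLengths), length(object@cds)))
    }
    if (length(object@introns) &&
        length(object@introns) != max(0L, length(object@exonLengths) - 1L))
        msg <- c(msg, "introns must number one fewer than exons (or be empty)")
    if (length(msg)) msg else TRUE
})

#' FamilySet: a collection of gene models with provenance
#'
#' Container for the gene models of one (sub)family, the optional subfamily
#' labels, a provenance log recording every filtering decision, and the
#' identifiers of designated outgroup genes (used to polarise events during
#' parsimony mapping).
#'
#' @slot models named list of \code{GeneModel} (names are the gene ids).
#' @slot subfamilyLabels named character vector, gene id to label.
#' @slot provenance data.frame with columns gene_id, action, reason.
#' @slot outgroup character vector of gene ids designated as outgroup.
#' @export
setClass("FamilySet",
    representation(models = "list", subfamilyLabels = "character",
                   provenance = "data.frame", outgroup = "character"),
    prototype(subfamilyLabels = character(),
              provenance = data.frame(gene_id = character(),
                                      action = character(),
                                      reason = character(),
                                      stringsAsFactors = FALSE),
              outgroup = character()))

setValidity("FamilySet", function(object) {
    msg <- character()
    ids <- vapply(object@models, function(m) m@geneId, character(1))
    if (anyDuplicated(ids))
        msg <- c(msg, "gene ids must be unique")
    if (length(object@models) && !identical(unname(ids), names(object@models)))
        msg <- c(msg, "models must be named by their gene ids")
    bad <- setdiff(names(object@subfamilyLabels), ids)
    if (length(bad))
        msg <- c(msg, paste("subfamily labels refer to unknown gene ids:",
                            paste(bad, collapse = ", ")))
    badog <- setdiff(object@outgroup, ids)
    if (length(badog))
        msg <- c(msg, paste("outgroup refers to unknown gene ids:",
                            paste(badog, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' CodonAlignment: exon-boundary-aware multiple alignment
#'
#' A nucleotide multiple alignment stored as a character matrix over
#' \code{A,C,G,T,-,N}, together with a per-row map from alignment column to
#' CDS position, per-row exon-boundary columns, and a per-column homology
#' mask.  De-gapping any row reproduces that row's CDS byte for byte at every
#' pipeline stage.
#'
#' @slot mat character matrix, rows named by gene id, one character per cell.
#' @slot colMap list (per row) of integer vectors, alignment column to CDS
#'   position, \code{NA} at gaps.
#' @slot boundaryCols list (per row) of strictly increasing alignment columns
#'   at which exons 1..(n-1) end; empty for rows without annotation.
#' @slot annotatedRows logical per row: does the row carry exon boundaries.
#' @slot mask logical per column, \code{TRUE} = masked (non-homologous).
#' @slot maskReason character per column (\code{NA} where unmasked).
#' @slot codonProjected was the alignment built by protein projection.
#' @export
setClass("CodonAlignment",
    representation(mat = "matrix", colMap = "list", boundaryCols = "list",
                   annotatedRows = "logical", mask = "logical",
                   maskReason = "character", codonProjected = "logical"),
    prototype(codonProjected = FALSE))

setValidity("CodonAlignment", function(object) {
    msg <- character()
    nr <- nrow(object@mat); nc <- ncol(object@mat)
    if (is.null(rownames(object@mat)))
        msg <- c(msg, "alignment rows must be named by gene id")
    if (length(object@colMap) != nr || length(object@boundaryCols) != nr ||
        length(object@annotatedRows) != nr)
        msg <- c(msg, "per-row slots must match the number of rows")
    if (length(object@mask) != nc || length(object@maskReason) != nc)
        msg <- c(msg, "per-column slots must match the number of columns")
    for (b in object@boundaryCols)
        if (length(b) > 1L && any(diff(b) <= 0L)) {
            msg <- c(msg, "exon boundary columns must be strictly increasing")
            break
        }
    if (length(msg)) msg else TRUE
})

#' PairwiseAlignment: one pairwise DP alignment
#'
#' @slot queryId,targetId sequence identifiers.
#' @slot alignedQuery,alignedTarget gapped strings of equal length.
#' @slot score alignment score under the recorded scheme.
#' @slot mode \code{"global"}, \code{"semiglobal"} or \code{"local"}.
#' @slot identity matches / aligned (non-terminal-gap) columns.
#' @slot params scoring scheme used (match, mismatch, gapOpen, gapExtend).
#' @slot range integer vector (startQuery, endQuery, startTarget, endTarget)
#'   of the aligned block in sequence coordinates (relevant for local mode).
#' @export
setClass("PairwiseAlignment",
    representation(queryId = "character", targetId = "character",
                   alignedQuery = "character", alignedTarget = "character",
                   score = "numeric", mode = "character",
                   identity = "numeric", params = "list",
                   range = "integer"))

setValidity("PairwiseAlignment", function(object) {
    if (nchar(object@alignedQuery) != nchar(object@alignedTarget))
        return("aligned strings must have equal length")
    TRUE
})

#' StructuralEvent: one classified exon-intron structural change
#'
#' @slot eventId unique event identifier.
#' @slot mechanism one of the ten mechanism labels (see
#'   \code{exonEvo:::VALID_MECHANISMS}); indeterminate labels are refined by
#'   parsimony mapping.
#' @slot exonIndex 1-based exon index in the reference numbering.
#' @slot lengthBp event length in bp (0 only for intron gain/loss).
#' @slot columnSpan first and last alignment column affected.
#' @slot carrierGenes genes exhibiting the derived state (non-empty).
#' @slot gapRows rows showing the gap (shorter) state, kept for polarisation.
#' @slot framePreserving TRUE iff lengthBp is a multiple of three.
#' @slot evidence evidence class behind the call.
#' @slot detail free-form list (merged lengths, linked events, notes).
#' @export
setClass("StructuralEvent",
    representation(eventId = "character", mechanism = "character",
                   exonIndex = "integer", lengthBp = "integer",
                   columnSpan = "integer", carrierGenes = "character",
                   gapRows = "character", framePreserving = "logical",
                   evidence = "character", detail = "list"),
    prototype(detail = list(), gapRows = character()))

setValidity("StructuralEvent", function(object) {
    msg <- character()
    if (!object@mechanism %in% VALID_MECHANISMS)
        msg <- c(msg, paste("unknown mechanism:", object@mechanism))
    if (!object@evidence %in% VALID_EVIDENCE)
        msg <- c(msg, paste("unknown evidence class:", object@evidence))
    if (object@lengthBp < 0L)
        msg <- c(msg, "lengthBp must be >= 0")
    if (object@lengthBp == 0L &&
        !object@mechanism %in% c("intron_gain", "intron_loss"))
        msg <- c(msg, "lengthBp 0 is permitted only for intron gain/loss")
    if (!identical(object@framePreserving, object@lengthBp %% 3L == 0L))
        msg <- c(msg, "framePreserving must equal lengthBp %% 3 == 0")
    if (!length(object@carrierGenes))
        msg <- c(msg, "carrierGenes must be non-empty")
    ismerge <- object@mechanism %in% c("intron_gain", "intron_loss")
    if (ismerge != identical(object@evidence, "exon_merge"))
        msg <- c(msg, "intron gain/loss iff evidence is exon_merge")
    if (length(msg)) msg else TRUE
})

#' EventPlacement: parsimony branch assignment of one event
#'
#' @slot eventId the placed event.
#' @slot branches child-node labels of the branches on which the (polarised)
#'   event is inferred to have occurred.
#' @slot lossBranches child-node labels of reversal branches under the chosen
#'   scenario (empty for simple single-origin placements).
#' @slot mechanism polarised mechanism.
#' @slot cost parsimony cost (number of state changes).
#' @slot alternatives list of equally parsimonious scenarios (each a list
#'   with elements \code{branches} and \code{lossBranches}), not chosen.
#' @slot signedLength signed bp effect on the affected exon (+ gain of
#'   sequence in carriers, - loss), 0 for intron gain/loss.
#' @slot exonIndex reference exon index the event affects.
#' @slot detail free-form list.
#' @export
setClass("EventPlacement",
    representation(eventId = "character", branches = "character",
                   lossBranches = "character", mechanism = "character",
                   cost = "numeric", alternatives = "list",
                   signedLength = "integer", exonIndex = "integer",
                   detail = "list"),
    prototype(alternatives = list(), detail = list(),
              lossBranches = character()))

#' AncestralStructure: exon-intron structure at one internal node
#'
#' @slot nodeId internal node label.
#' @slot exonCount number of exons at the node.
#' @slot exonLengths inferred exon lengths (bp).
#' @slot support per-exon flag, \code{"unambiguous"} or \code{"ambiguous"}.
#' @export
setClass("AncestralStructure",
    representation(nodeId = "character", exonCount = "integer",
                   exonLengths = "integer", support = "character"))

setValidity("AncestralStructure", function(object) {
    msg <- character()
    if (object@exonCount != length(object@exonLengths))
        msg <- c(msg, "exonCount must equal length(exonLengths)")
    if (any(object@exonLengths <= 0L))
        msg <- c(msg, "all exon lengths must be > 0")
    if (length(msg)) msg else TRUE
})

#' SimConfig: parameters of the gene-family simulator
#'
#' @slot tree optional fixed rooted tree (class \code{phylo}); when NULL a
#'   random topology with \code{nLeaves} ingroup leaves plus one outgroup is
#'   drawn from the seed.
#' @slot nLeaves ingroup leaf count for random topologies.
#' @slot seed integer seed; identical config + seed gives byte-identical
#'   output.
#' @slot ancestralExonLengths exon lengths of the ancestral gene (bp).
#' @slot intronLength intron length of the ancestral gene (bp).
#' @slot flankLength flanking noncoding length on each side (bp).
#' @slot substRate substitutions per site per unit branch length
#'   (Jukes-Cantor).
#' @slot eventRates named per-mechanism rates per unit branch length.
#' @slot pFrame probability that an intraexonic indel length is a multiple
#'   of three.
#' @slot indelMeanCodons mean of the geometric codon-count distribution for
#'   intraexonic indels.
#' @export
setClass("SimConfig",
    representation(tree = "ANY", nLeaves = "integer", seed = "integer",
                   ancestralExonLengths = "integer", intronLength = "integer",
                   flankLength = "integer", substRate = "numeric",
                   eventRates = "numeric", pFrame = "numeric",
                   indelMeanCodons = "numeric"))

setValidity("SimConfig", function(object) {
    msg <- character()
    if (any(object@eventRates < 0)) msg <- c(msg, "event rates must be >= 0")
    if (object@pFrame < 0 || object@pFrame > 1)
        msg <- c(msg, "pFrame must be in [0, 1]")
    if (any(object@ancestralExonLengths <= 0L))
        msg <- c(msg, "ancestral exon lengths must be > 0")
    if (object@substRate < 0) msg <- c(msg, "substRate must be >= 0")
    if (length(msg)) msg else TRUE
})

#' TrueHistory: the simulator's event ledger and node snapshots
#'
#' Replaying the ledger from the ancestral snapshot reproduces every leaf
#' GeneModel exactly (see \code{\link{replayHistory}}).
#'
#' @slot ledger data.frame with columns event_id, branch (child node label),
#'   mechanism, exon_index, length_bp, position.
#' @slot snapshots named list of \code{GeneModel}, one per tree node.
#' @slot tree the rooted \code{phylo} the family evolved on.
#' @slot ancestorId node label of the root snapshot.
#' @export
setClass("TrueHistory",
    representation(ledger = "data.frame", snapshots = "list",
                   tree = "ANY", ancestorId = "character"))
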