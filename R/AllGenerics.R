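#' @include AllClasses.R
NULL

#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))

#' @export
setGeneric("speciesId", function(x) standardGeneric("speciesId"))

#' @export
setGeneric("cdsSeq", function(x) standardGeneric("cdsSeq"))

#' @export
setGeneric("exonLengths", function(x) standardGeneric("exonLengths"))

#' @export
setGeneric("exonSeqs", function(x) standardGeneric("exonSeqs"))

#' @export
setGeneric("intronSeqs", function(x) standardGeneric("intronSeqs"))

#' @export
setGeneric("flank5", function(x) standardGeneric("flank5"))

#' @export
setGeneric("flank3", function(x) standardGeneric("flank3"))

#' @export
setGeneric("isAnnotated", function(x) standardGeneric("isAnnotated"))

#' @export
setGeneric("models", function(x) standardGeneric("models"))

#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @export
setGeneric("subfamilyLabels", function(x) standardGeneric("subfamilyLabels"))

#' @export
setGeneric("outgroup", function(x) standardGeneric("outgroup"))

#' @export
setGeneric("outgroup<-", function(x, value) standardGeneric("outgroup<-"))

#' @export
setGeneric("alignmentMatrix", function(x) standardGeneric("alignmentMatrix"))

#' @export
setGeneric("columnMap", function(x) standardGeneric("columnMap"))

#' @export
setGeneric("boundaryColumns", function(x) standardGeneric("boundaryColumns"))

#' @export
setGeneric("columnMask", function(x) standardGeneric("columnMask"))

#' @export
setGeneric("maskReasons", function(x) standardGeneric("maskReasons"))

#' @export
setGeneric("mechanism", function(x) standardGeneric("mechanism"))

#' @export
setGeneric("exonIndex", function(x) standardGeneric("exonIndex"))

#' @export
setGeneric("lengthBp", function(x) standardGeneric("lengthBp"))

#' @export
setGeneric("carrierGenes", function(x) standardGeneric("carrierGenes"))

#' @export
setGeneric("framePreserving", function(x) standardGeneric("framePreserving"))

#' @export
setGeneric("evidence", function(x) standardGeneric("evidence"))

#' @export
setGeneric("eventId", function(x) standardGeneric("eventId"))

#' @export
setGeneric("branches", function(x) standardGeneric("branches"))

#' @export
setGeneric("ledger", function(x) standardGeneric("ledger"))

#' @export
setGeneric("snapshots", function(x) standardGeneric("snapshots"))
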