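#' @include AllClasses.R gene-models.R
NULL

# pull a per-feature gene id out of a GFF3/BED GRanges
featureGeneIds <- function(gr) {
    mc <- S4Vectors::mcols(gr)
    if (!is.null(mc$Parent) && any(lengths(mc$Parent) > 0)) {
        par <- vapply(as.list(mc$Parent), function(p)
            if (length(p)) p[[1]] else NA_character_, character(1))
        if (!anyNA(par)) return(par)
    }
    for (field in c("gene_id", "ID", "Name", "name")) {
        if (!is.null(mc[[field]]) && !anyNA(mc[[field]]))
            return(as.character(mc[[field]]))
    }
    stop("annotation features carry no usable gene identifier ",
         "(need Parent, gene_id, ID or Name)")
}

#' Load gene models from FASTA + annotation
#'
#' Builds a \code{FamilySet} from a CDS FASTA, an optional exon annotation
#' (GFF3 with CDS/exon features, or BED), and an optional genomic FASTA.
#' With genomic sequence available, each gene's exon concatenation
#' (reverse-complemented for minus-strand genes) is checked against its
#' CDS; genes failing the concordance check are retained as unannotated
#' models and reported in the provenance log, never silently dropped.
#' An annotated gene with no sequence in the FASTA is a hard error.
#'
#' Coordinates are 1-based inclusive on disk (GFF3 convention) and
#' half-open internally via \code{IRanges}.
#'
#' @param cdsFasta path to the CDS FASTA (record names = gene ids).
#' @param annotation optional path to a GFF3 (\code{.gff/.gff3}) or BED
#'   file of exon/CDS features.
#' @param genomicFasta optional path to genomic FASTA; sequence names must
#'   match the annotation's sequence names.
#' @param flankLength bp of flanking noncoding sequence extracted on each
#'   side of the gene (default 300).
#' @param species optional named character vector gene id -> species tag.
#' @return a \code{FamilySet}.
#' @export
loadGeneModels <- function(cdsFasta, annotation = NULL, genomicFasta = NULL,
                           flankLength = 300L, species = NULL) {
    cds <- readDNAStringSet(cdsFasta)
    names(cds) <- sub("\\s.*$", "", names(cds))
    genomic <- if (!is.null(genomicFasta)) {
        g <- readDNAStringSet(genomicFasta)
        names(g) <- sub("\\s.*$", "", names(g))
        g
    } else NULL
    prov <- list()
    models <- list()
    ann <- NULL
    if (!is.null(annotation)) {
        fmt <- if (grepl("\\.bed$", annotation, ignore.case = TRUE)) "bed"
               else "gff3"
        gr <- rtracklayer::import(annotation, format = fmt)
        if (fmt == "gff3") {
            keep <- if (any(gr$type == "CDS")) gr$type == "CDS"
                    else gr$type == "exon"
            gr <- gr[keep]
        }
        ids <- featureGeneIds(gr)
        ann <- split(gr, ids)
    }
    spOf <- function(id) {
        if (!is.null(species) && id %in% names(species)) species[[id]]
        else NA_character_
    }
    annIds <- if (is.null(ann)) character() else names(ann)
    for (id in union(names(cds), annIds)) {
        if (!id %in% names(cds))
            stop("annotated gene without CDS sequence: ", id)
        cdsSeq <- as.character(cds[[id]])
        if (is.null(ann) || !id %in% names(ann)) {
            models[[id]] <- GeneModel(id, cdsSeq, speciesId = spOf(id),
                                      annotationSource = "cds_only")
            next
        }
        feats <- ann[[id]]
        strand <- as.character(BiocGenerics::strand(feats))[1]
        if (!strand %in% c("+", "-")) strand <- "+"
        o <- order(BiocGenerics::start(feats),
                   decreasing = (strand == "-"))
        feats <- feats[o]
        widths <- BiocGenerics::width(feats)
        if (is.null(genomic)) {
            if (sum(widths) != nchar(cdsSeq)) {
                prov[[length(prov) + 1L]] <- data.frame(
                    gene_id = id, action = "annotation_rejected",
                    reason = sprintf(
                        "exon lengths sum to %d but CDS is %d bp",
                        sum(widths), nchar(cdsSeq)),
                    stringsAsFactors = FALSE)
                models[[id]] <- GeneModel(id, cdsSeq, speciesId = spOf(id),
                                          annotationSource = "cds_only")
            } else {
                models[[id]] <- GeneModel(id, cdsSeq,
                                          exonLengths = widths,
                                          speciesId = spOf(id),
                                          strand = strand,
                                          exons = GRanges(feats),
                                          annotationSource = basename(annotation))
            }
            next
        }
        chrom <- as.character(GenomicRanges::seqnames(feats))[1]
        if (!chrom %in% names(genomic))
            stop("missing genomic sequence for annotated gene: ", id,
                 " (sequence ", chrom, ")")
        gseq <- genomic[[chrom]]
        slice <- function(s, e) as.character(subseq(gseq, s, e))
        exonSeqs <- mapply(slice, BiocGenerics::start(feats),
                           BiocGenerics::end(feats))
        if (strand == "-") exonSeqs <- vapply(exonSeqs, revComp, character(1))
        concat <- paste(exonSeqs, collapse = "")
        if (!identical(toupper(concat), toupper(cdsSeq))) {
            prov[[length(prov) + 1L]] <- data.frame(
                gene_id = id, action = "annotation_rejected",
                reason = "CDS mismatch: exon concatenation differs from CDS",
                stringsAsFactors = FALSE)
            models[[id]] <- GeneModel(id, cdsSeq, speciesId = spOf(id),
                                      annotationSource = "cds_only")
            next
        }
        # introns between genomically adjacent exons, flanks beyond the ends
        gs <- BiocGenerics::start(feats); ge <- BiocGenerics::end(feats)
        n <- length(feats)
        introns <- character(0)
        if (n > 1L) {
            introns <- vapply(seq_len(n - 1L), function(i) {
                s <- ge[i] + 1L; e <- gs[i + 1L] - 1L
                if (strand == "-") { s <- ge[i + 1L] + 1L; e <- gs[i] - 1L }
                if (e < s) return("")
                out <- slice(s, e)
                if (strand == "-") revComp(out) else out
            }, character(1))
        }
        glen <- length(gseq)
        if (strand == "+") {
            f5s <- max(1L, gs[1] - flankLength); f5e <- gs[1] - 1L
            f3s <- ge[n] + 1L; f3e <- min(glen, ge[n] + flankLength)
            flank5 <- if (f5e >= f5s) slice(f5s, f5e) else ""
            flank3 <- if (f3e >= f3s) slice(f3s, f3e) else ""
        } else {
            f5s <- min(glen, ge[1] + flankLength); f5e <- ge[1] + 1L
            flank5 <- if (f5s >= f5e) revComp(slice(f5e, f5s)) else ""
            f3e <- gs[n] - 1L; f3s <- max(1L, gs[n] - flankLength)
            flank3 <- if (f3e >= f3s) revComp(slice(f3s, f3e)) else ""
        }
        models[[id]] <- GeneModel(id, cdsSeq, exonLengths = widths,
                                  speciesId = spOf(id), strand = strand,
                                  exons = GRanges(feats), introns = introns,
                                  flank5 = flank5, flank3 = flank3,
                                  annotationSource = basename(annotation))
    }
    fs <- FamilySet(models)
    if (length(prov)) fs@provenance <- do.call(rbind, prov)
    fs
}

#' Write a FamilySet as FASTA + GFF3
#'
#' Writes the CDS FASTA, a reconstructed genomic FASTA (flank5 + exon1 +
#' intron1 + ... + flank3 per gene, one sequence per gene named
#' \code{<gene_id>_region}), a GFF3 of CDS features, and the provenance
#' log as TSV.  Reloading the written files reproduces the same gene
#' models.
#'
#' @param fs a \code{FamilySet}.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix (default "family").
#' @return invisibly, the named vector of written paths.
#' @export
writeFamilySet <- function(fs, dir, prefix = "family") {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(cds = file.path(dir, paste0(prefix, "_cds.fasta")),
               genomic = file.path(dir, paste0(prefix, "_genomic.fasta")),
               gff = file.path(dir, paste0(prefix, ".gff3")),
               provenance = file.path(dir, paste0(prefix, "_provenance.tsv")))
    cds <- DNAStringSet(vapply(models(fs), function(m)
        as.character(cdsSeq(m)), character(1)))
    writeXStringSet(cds, paths["cds"])
    gen <- character(); feats <- list()
    for (m in models(fs)) {
        introns <- as.character(intronSeqs(m))
        ex <- as.character(exonSeqs(m))
        pieces <- character(2L * length(ex) - 1L)
        pieces[seq(1L, length(pieces), by = 2L)] <- ex
        if (length(introns))
            pieces[seq(2L, length(pieces), by = 2L)] <- introns
        f5 <- as.character(flank5(m)); f3 <- as.character(flank3(m))
        region <- paste0(f5, paste(pieces, collapse = ""), f3)
        chrom <- paste0(geneId(m), "_region")
        gen[chrom] <- region
        # exon coordinates within the reconstructed region (plus strand);
        # GFF3 phase = bases to trim to reach the next codon boundary
        pos <- nchar(f5); cum <- 0L
        for (i in seq_along(ex)) {
            s <- pos + 1L; e <- pos + nchar(ex[i])
            feats[[length(feats) + 1L]] <- data.frame(
                chrom = chrom, start = s, end = e, gene = geneId(m),
                exon = i, phase = (3L - cum %% 3L) %% 3L,
                stringsAsFactors = FALSE)
            cum <- cum + nchar(ex[i])
            pos <- e + (if (i <= length(introns)) nchar(introns[i]) else 0L)
        }
    }
    writeXStringSet(DNAStringSet(gen), paths["genomic"])
    fdf <- do.call(rbind, feats)
    gr <- GRanges(fdf$chrom, IRanges(fdf$start, fdf$end), strand = "+")
    S4Vectors::mcols(gr)$type <- "CDS"
    S4Vectors::mcols(gr)$ID <- paste0(fdf$gene, ".cds", fdf$exon)
    S4Vectors::mcols(gr)$Parent <- fdf$gene
    S4Vectors::mcols(gr)$phase <- fdf$phase
    rtracklayer::export(gr, paths["gff"], format = "gff3")
    write.table(provenance(fs), paths["provenance"], sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(paths)
}

#' Export boundary map, event and mask tables
#'
#' @param aln a \code{CodonAlignment}.
#' @param path output TSV path.
#' @return invisibly, the path.
#' @export
writeBoundaryMap <- function(aln, path) {
    rows <- list()
    for (id in rownames(aln@mat)) {
        bc <- aln@boundaryCols[[id]]
        if (!length(bc)) next
        rows[[id]] <- data.frame(gene_id = id, exon_index = seq_along(bc),
                                 end_column = bc, stringsAsFactors = FALSE)
    }
    out <- if (length(rows)) do.call(rbind, rows)
           else data.frame(gene_id = character(), exon_index = integer(),
                           end_column = integer())
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write an alignment (optionally masked) as aligned FASTA
#'
#' @param aln a \code{CodonAlignment}.
#' @param path output path.
#' @param dropMasked exclude masked columns from the output matrix.
#' @return invisibly, the path.
#' @export
writeAlignment <- function(aln, path, dropMasked = FALSE) {
    mat <- aln@mat
    if (dropMasked && any(aln@mask)) mat <- mat[, !aln@mask, drop = FALSE]
    seqs <- apply(mat, 1L, paste, collapse = "")
    writeLines(paste0(">", names(seqs), "\n", seqs), path)
    invisible(path)
}

#' Write the column mask as a BED-like TSV over alignment columns
#' @param aln a \code{CodonAlignment}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeMask <- function(aln, path) {
    idx <- which(aln@mask)
    if (!length(idx)) {
        write.table(data.frame(start = integer(), end = integer(),
                               reason = character()),
                    path, sep = "\t", quote = FALSE, row.names = FALSE)
        return(invisible(path))
    }
    r <- rle(paste0(aln@mask, "|", aln@maskReason))
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    keep <- grepl("^TRUE", r$values)
    out <- data.frame(start = starts[keep] - 1L, end = ends[keep],
                      reason = sub("^TRUE\\|", "", r$values[keep]),
                      stringsAsFactors = FALSE)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
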