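#' @include AllClasses.R io.R filter.R codon-align.R events.R parsimony.R
#'   simulate.R fixtures.R
NULL

#' Pipeline configuration
#'
#' One flat configuration object for the end-to-end analysis.  Exactly one
#' input source is used: a packaged fixture name, a \code{SimConfig}, or
#' file paths.  Every analysis-facing threshold appears here with its default
#' and is echoed into the report header for reproducibility.
#'
#' @param fixture name of a packaged fixture (see \code{\link{emitFixture}}).
#' @param simulate a \code{SimConfig} for a simulated family.
#' @param cdsFasta,annotation,genomicFasta,treeFile,guideProteinFasta input
#'   file paths (tree required; guide protein alignment optional -- without
#'   it the built-in progressive aligner is used).
#' @param outDir output directory; \code{NULL} skips file output.
#' @param seed integer seed forwarded to stochastic steps.
#' @param minCds,dedupeIdentity retention rules of
#'   \code{\link{filterModels}} (applied only to file inputs).
#' @param minIdentity,minCols alignability threshold.
#' @param perfectIdentity,junctionTolerance intron-change calling.
#' @param maxGapFraction,hotspotMax masking thresholds.
#' @param nonTripletPenalty weight of frame-violating events in the
#'   divergence ranking.
#' @param divergenceThresholds retention cutoffs for nested subsets.
#' @return a validated configuration list of class \code{exonEvoConfig}.
#' @export
pipelineConfig <- function(fixture = NULL, simulate = NULL, cdsFasta = NULL,
                           annotation = NULL, genomicFasta = NULL,
                           treeFile = NULL, guideProteinFasta = NULL,
                           outDir = NULL, seed = 1L,
                           minCds = 400L, dedupeIdentity = 0.95,
                           minIdentity = 0.5, minCols = 15L,
                           perfectIdentity = 0.9, junctionTolerance = 3L,
                           maxGapFraction = 0.8, hotspotMax = 2L,
                           nonTripletPenalty = 2,
                           divergenceThresholds = numeric()) {
    nInput <- (!is.null(fixture)) + (!is.null(simulate)) +
        (!is.null(cdsFasta))
    if (nInput != 1L)
        stop("exactly one of fixture, simulate, cdsFasta must be given")
    if (!is.null(cdsFasta) && is.null(treeFile))
        stop("file input requires a Newick tree (treeFile)")
    cfg <- list(fixture = fixture, simulate = simulate, cdsFasta = cdsFasta,
                annotation = annotation, genomicFasta = genomicFasta,
                treeFile = treeFile, guideProteinFasta = guideProteinFasta,
                outDir = outDir, seed = as.integer(seed), minCds = minCds,
                dedupeIdentity = dedupeIdentity, minIdentity = minIdentity,
                minCols = minCols, perfectIdentity = perfectIdentity,
                junctionTolerance = junctionTolerance,
                maxGapFraction = maxGapFraction, hotspotMax = hotspotMax,
                nonTripletPenalty = nonTripletPenalty,
                divergenceThresholds = divergenceThresholds)
    for (p in c("fixture", "cdsFasta", "annotation", "genomicFasta",
                "treeFile", "guideProteinFasta")) {
        if (!is.null(cfg[[p]]) && p != "fixture" && !file.exists(cfg[[p]]))
            stop("input path does not exist: ", cfg[[p]])
    }
    class(cfg) <- "exonEvoConfig"
    cfg
}

#' Run the structural-change analysis end to end
#'
#' Executes load/filter, align/project/mark/refine, event detection,
#' parsimony mapping with ancestral-structure reconstruction, masking and
#' divergence ranking, and (when \code{outDir} is set) writes the report
#' bundle: event table, placements, ancestral structures, divergence
#' ranking, boundary map, full and masked alignments, mask table,
#' annotated tree, provenance log, a configuration echo and a
#' human-readable summary (event counts per mechanism and per exon
#' index).  All outputs are deterministic for a given configuration and
#' seed.
#'
#' @param cfg an \code{exonEvoConfig} from \code{\link{pipelineConfig}}.
#' @return invisibly, a list with the family, tree, alignment, events,
#'   hotspots, placements, ancestral structures, ranking and (for
#'   generated inputs) the true history.
#' @examples
#' res <- runPipeline(pipelineConfig(fixture = "flc_exon3"))
#' ancestralTable(res$ancestral)
#' @export
runPipeline <- function(cfg) {
    stopifnot(inherits(cfg, "exonEvoConfig"))
    history <- NULL
    if (!is.null(cfg$fixture)) {
        fx <- emitFixture(cfg$fixture)
        fs <- fx$family; tree <- fx$tree; history <- fx$history
    } else if (!is.null(cfg$simulate)) {
        sim <- simulateFamily(cfg$simulate)
        fs <- sim$family; tree <- sim$tree; history <- sim$history
    } else {
        fs <- loadGeneModels(cfg$cdsFasta, cfg$annotation, cfg$genomicFasta)
        fs <- filterModels(fs, cfg$minCds, cfg$dedupeIdentity)
        tree <- ape::read.tree(cfg$treeFile)
        drop <- setdiff(tree$tip.label, names(fs))
        if (length(drop)) tree <- ape::drop.tip(tree, drop)
    }
    tree <- ensureNodeLabels(tree)
    aln <- if (!is.null(cfg$guideProteinFasta)) {
        prot <- readAAStringSet(cfg$guideProteinFasta)
        projectProteinAlignment(prot, fs)
    } else {
        progressiveAlign(fs, tree)
    }
    aln <- markExonBoundaries(aln, fs)
    aln <- refineExonByExon(aln, fs)
    det <- detectEvents(aln, fs, hotspotMax = cfg$hotspotMax,
                        minIdentity = cfg$minIdentity,
                        minCols = cfg$minCols,
                        perfectIdentity = cfg$perfectIdentity,
                        junctionTolerance = cfg$junctionTolerance)
    placements <- mapEvents(tree, det$events, outgroup(fs))
    ancestral <- tryCatch(
        reconstructAncestralStructure(tree, fs, placements, aln,
                                      strict = FALSE,
                                      outgroup = outgroup(fs)),
        error = function(e) {
            warning("ancestral reconstruction failed: ",
                    conditionMessage(e))
            list()
        })
    aln <- maskNonhomologousColumns(aln, det$events, cfg$maxGapFraction)
    for (h in det$hotspots) {
        aln@mask[h$start:h$end] <- TRUE
        aln@maskReason[h$start:h$end] <- "indel_hotspot"
    }
    ranking <- rankStructuralDivergence(fs, placements, tree,
                                        cfg$divergenceThresholds,
                                        cfg$nonTripletPenalty)
    res <- list(family = fs, tree = tree, alignment = aln,
                events = det$events, hotspots = det$hotspots,
                placements = placements, ancestral = ancestral,
                ranking = ranking, history = history, config = cfg)
    if (!is.null(cfg$outDir)) writeReportBundle(res, cfg$outDir)
    invisible(res)
}

# deterministic report bundle (no timestamps, fixed column order)
writeReportBundle <- function(res, outDir) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    cfg <- res$config
    echo <- cfg[!vapply(cfg, is.null, logical(1))]
    echo <- echo[!names(echo) %in% c("simulate", "outDir")]
    lines <- c("# exonEvo pipeline configuration",
               vapply(names(echo), function(n)
                   sprintf("%s\t%s", n, paste(format(echo[[n]]),
                                              collapse = ",")),
                   character(1)))
    writeLines(lines, file.path(outDir, "config.tsv"))
    write.table(eventTable(res$events), file.path(outDir, "events.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(placementTable(res$placements),
                file.path(outDir, "placements.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(ancestralTable(res$ancestral),
                file.path(outDir, "ancestral_structures.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(res$ranking$ranking, file.path(outDir, "divergence.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(provenance(res$family), file.path(outDir, "provenance.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeBoundaryMap(res$alignment, file.path(outDir, "boundaries.tsv"))
    writeAlignment(res$alignment, file.path(outDir, "alignment.fasta"))
    writeAlignment(res$alignment, file.path(outDir, "masked_alignment.fasta"),
                   dropMasked = TRUE)
    writeMask(res$alignment, file.path(outDir, "mask.tsv"))
    writeLines(annotatedNewick(res$tree, res$placements),
               file.path(outDir, "tree_annotated.nwk"))
    writeLines(pipelineSummary(res), file.path(outDir, "summary.txt"))
    invisible(outDir)
}

# Newick with per-branch event lists as NHX-style comments
annotatedNewick <- function(tree, placements) {
    byBranch <- list()
    for (p in placements) {
        for (b in p@branches)
            byBranch[[b]] <- c(byBranch[[b]],
                               paste0(p@eventId, ":", p@mechanism))
        for (b in p@lossBranches)
            byBranch[[b]] <- c(byBranch[[b]], paste0(p@eventId, ":reversal"))
    }
    n <- ape::Ntip(tree)
    rec <- function(node) {
        lab <- nodeLabel(tree, node)
        core <- if (node <= n) lab
                else paste0("(", paste(vapply(childrenOf(tree, node), rec,
                                              character(1)),
                                       collapse = ","), ")", lab)
        e <- which(tree$edge[, 2] == node)
        br <- if (length(e) && !is.null(tree$edge.length))
                  sprintf(":%g", tree$edge.length[e]) else ""
        nhx <- if (!is.null(byBranch[[lab]]))
                   sprintf("[&&NHX:events=%s]",
                           paste(sort(byBranch[[lab]]), collapse = "|"))
               else ""
        paste0(core, br, nhx)
    }
    paste0(rec(rootNode(tree)), ";")
}

pipelineSummary <- function(res) {
    ev <- res$events
    lines <- c("exonEvo structural-change summary",
               sprintf("genes: %d", length(res$family)),
               sprintf("alignment: %d columns, %d masked",
                       ncol(res$alignment@mat), sum(res$alignment@mask)),
               sprintf("events detected: %d", length(ev)), "")
    if (length(res$placements)) {
        mech <- table(vapply(res$placements, function(p) p@mechanism,
                             character(1)))
        lines <- c(lines, "events per mechanism (after polarisation):",
                   sprintf("  %s\t%d", names(mech), as.integer(mech)), "")
        exn <- table(vapply(res$placements, function(p) p@exonIndex,
                            integer(1)))
        lines <- c(lines, "events per exon index:",
                   sprintf("  exon %s\t%d", names(exn), as.integer(exn)))
    }
    lines
}
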