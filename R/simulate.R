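#' @include AllClasses.R AllGenerics.R gene-models.R parsimony.R
NULL

#' @export
setMethod("ledger", "TrueHistory", function(x) x@ledger)

#' @export
setMethod("snapshots", "TrueHistory", function(x) x@snapshots)

setMethod("show", "TrueHistory", function(object) {
    st <- structuralLedger(object@ledger)
    cat(sprintf("TrueHistory: %d structural event(s), %d substitution(s), %d node snapshot(s)\n",
                nrow(st), sum(object@ledger$mechanism == "substitution"),
                length(object@snapshots)))
})

#' Structural rows of a simulation ledger
#'
#' Drops point-substitution bookkeeping rows, leaving the structural
#' change events.
#' @param ledger the \code{TrueHistory} ledger data.frame.
#' @return the structural subset.
#' @export
structuralLedger <- function(ledger) {
    ledger[ledger$mechanism != "substitution", , drop = FALSE]
}

#' Simulator configuration
#'
#' Defaults describe a MADS-box-like family: an 8-exon ancestor with a
#' conserved core (MADS/K-encoding exons of near-fixed length) and variable
#' terminal exons, shallow (within-family) sequence divergence, and
#' structural events dominated by codon-multiple intraexonic indels with
#' rarer boundary recruitment, intron gain/loss and whole-exon gain/loss.
#'
#' @param tree optional fixed rooted \code{phylo}; otherwise a random
#'   ingroup topology plus one outgroup leaf is generated per family.
#' @param nLeaves ingroup leaves for random topologies (default 5).
#' @param seed RNG seed (default 1).
#' @param ancestralExonLengths ancestral exon lengths (default the 8-exon
#'   template 185, 79, 62, 100, 42, 42, 137, 85 bp; the sum must be a
#'   multiple of three).
#' @param intronLength ancestral intron length (default 200 bp).
#' @param flankLength flanking noncoding length per side (default 300 bp).
#' @param substRate substitutions per site per unit branch length
#'   (default 1; branch lengths are in substitutions/site).
#' @param eventRates named per-mechanism rates per unit branch length.
#' @param pFrame probability an indel length is a codon multiple
#'   (default 0.9).
#' @param indelMeanCodons mean codons per indel (geometric, default 2).
#' @return a validated \code{SimConfig}.
#' @export
simConfig <- function(tree = NULL, nLeaves = 5L, seed = 1L,
                      ancestralExonLengths = c(185L, 79L, 62L, 100L, 42L,
                                               42L, 137L, 85L),
                      intronLength = 200L, flankLength = 300L,
                      substRate = 1,
                      eventRates = c(intraexonic_indel = 20, exonization = 4,
                                     pseudoexonization = 4, intron_loss = 3,
                                     intron_gain = 1.5, exon_gain = 1,
                                     exon_loss = 1),
                      pFrame = 0.9, indelMeanCodons = 2) {
    if (sum(ancestralExonLengths) %% 3L != 0L)
        stop("ancestral exon lengths must sum to a multiple of three")
    new("SimConfig", tree = tree, nLeaves = as.integer(nLeaves),
        seed = as.integer(seed),
        ancestralExonLengths = as.integer(ancestralExonLengths),
        intronLength = as.integer(intronLength),
        flankLength = as.integer(flankLength), substRate = substRate,
        eventRates = eventRates, pFrame = pFrame,
        indelMeanCodons = indelMeanCodons)
}

# ---------------------------------------------------------------------------
# gene state: a mutable representation of one gene during simulation.
# Per-position "tags" name the ancestral (root) segment and position of
# every base, NA for material inserted after the root; they drive the
# non-overlap bookkeeping of the stochastic generator.

tagVec <- function(prefix, n) {
    if (n > 0L) paste0(prefix, ":", seq_len(n)) else character()
}

newStateFromSeqs <- function(exonSeqs, intronSeqs, flank5, flank3) {
    n <- length(exonSeqs)
    list(exonIds = paste0("E", seq_len(n)),
         exonSeqs = exonSeqs,
         intronSeqs = intronSeqs,
         flank5 = flank5, flank3 = flank3,
         exonTags = lapply(seq_len(n), function(i)
             tagVec(paste0("E", i), nchar(exonSeqs[i]))),
         intronTags = lapply(seq_along(intronSeqs), function(i)
             tagVec(paste0("I", i), nchar(intronSeqs[i]))),
         flank5Tags = tagVec("F5", nchar(flank5)),
         flank3Tags = tagVec("F3", nchar(flank3)),
         frameIntact = TRUE,
         gainCounter = 0L)
}

# random ancestral gene: stop-free codons, ATG start, TGA terminal stop
ancestralState <- function(exonLengths, intronLength, flankLength) {
    total <- sum(exonLengths)
    codons <- setdiff(names(Biostrings::GENETIC_CODE),
                      stopCodons())
    ncod <- total %/% 3L
    cds <- paste(sample(codons, ncod, replace = TRUE), collapse = "")
    substr(cds, 1L, 3L) <- "ATG"
    substr(cds, total - 2L, total) <- "TGA"
    off <- exonOffsets(exonLengths)
    exonSeqs <- vapply(seq_along(exonLengths), function(i)
        substr(cds, off[i, "start"], off[i, "end"]), character(1))
    rseq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")
    intronSeqs <- vapply(seq_len(length(exonLengths) - 1L),
                         function(i) rseq(intronLength), character(1))
    newStateFromSeqs(exonSeqs, intronSeqs, rseq(flankLength),
                     rseq(flankLength))
}

stateToModel <- function(geneId, state, speciesId = NA_character_,
                         annotationSource = "simulated") {
    GeneModel(geneId, paste(state$exonSeqs, collapse = ""),
              exonLengths = nchar(state$exonSeqs),
              speciesId = speciesId,
              introns = state$intronSeqs, flank5 = state$flank5,
              flank3 = state$flank3, annotationSource = annotationSource)
}

stateCds <- function(state) paste(state$exonSeqs, collapse = "")

rootIndexOf <- function(exonId) {
    m <- regmatches(exonId, regexpr("[0-9]+", exonId))
    if (!length(m)) NA_integer_ else as.integer(m)
}

pick1 <- function(v) if (length(v) == 1L) v else sample(v, 1L)

strIns <- function(s, pos, ins) paste0(substr(s, 1L, pos), ins,
                                       substr(s, pos + 1L, nchar(s)))
strDel <- function(s, pos, len) paste0(substr(s, 1L, pos - 1L),
                                       substr(s, pos + len, nchar(s)))
vecIns <- function(v, pos, ins) append(v, ins, after = pos)
vecDel <- function(v, pos, len) if (len > 0L) v[-(pos:(pos + len - 1L))] else v

# apply one ledger operation to a state; op is a one-row list with fields
# mechanism, seg_type, seg_index, side, position, length_bp, payload
applyOp <- function(state, op) {
    m <- op$mechanism
    i <- op$seg_index
    p <- op$position
    L <- op$length_bp
    if (m == "substitution") {
        if (op$seg_type == "exon")
            substr(state$exonSeqs[i], p, p) <- op$payload
        else if (op$seg_type == "intron")
            substr(state$intronSeqs[i], p, p) <- op$payload
        else if (op$seg_type == "flank5")
            substr(state$flank5, p, p) <- op$payload
        else substr(state$flank3, p, p) <- op$payload
        return(state)
    }
    if (m == "intraexonic_insertion") {
        state$exonSeqs[i] <- strIns(state$exonSeqs[i], p, op$payload)
        state$exonTags[[i]] <- vecIns(state$exonTags[[i]], p,
                                      rep(NA_character_, L))
    } else if (m == "intraexonic_deletion") {
        state$exonSeqs[i] <- strDel(state$exonSeqs[i], p, L)
        state$exonTags[[i]] <- vecDel(state$exonTags[[i]], p, L)
    } else if (m == "exonization") {
        n <- length(state$exonSeqs)
        if (op$side == 5L) {
            if (i == 1L) {
                src <- state$flank5; tg <- state$flank5Tags
                take <- substr(src, nchar(src) - L + 1L, nchar(src))
                state$flank5 <- substr(src, 1L, nchar(src) - L)
                mv <- tail(tg, L); state$flank5Tags <- head(tg, -L)
            } else {
                src <- state$intronSeqs[i - 1L]; tg <- state$intronTags[[i - 1L]]
                take <- substr(src, nchar(src) - L + 1L, nchar(src))
                state$intronSeqs[i - 1L] <- substr(src, 1L, nchar(src) - L)
                mv <- tail(tg, L); state$intronTags[[i - 1L]] <- head(tg, -L)
            }
            state$exonSeqs[i] <- paste0(take, state$exonSeqs[i])
            state$exonTags[[i]] <- c(mv, state$exonTags[[i]])
        } else {
            if (i == n) {
                src <- state$flank3; tg <- state$flank3Tags
                take <- substr(src, 1L, L)
                state$flank3 <- substr(src, L + 1L, nchar(src))
                mv <- head(tg, L); state$flank3Tags <- tail(tg, -L)
            } else {
                src <- state$intronSeqs[i]; tg <- state$intronTags[[i]]
                take <- substr(src, 1L, L)
                state$intronSeqs[i] <- substr(src, L + 1L, nchar(src))
                mv <- head(tg, L); state$intronTags[[i]] <- tail(tg, -L)
            }
            state$exonSeqs[i] <- paste0(state$exonSeqs[i], take)
            state$exonTags[[i]] <- c(state$exonTags[[i]], mv)
        }
    } else if (m == "pseudoexonization") {
        n <- length(state$exonSeqs)
        ex <- state$exonSeqs[i]; tg <- state$exonTags[[i]]
        if (op$side == 3L) {
            take <- substr(ex, nchar(ex) - L + 1L, nchar(ex))
            state$exonSeqs[i] <- substr(ex, 1L, nchar(ex) - L)
            mv <- tail(tg, L); state$exonTags[[i]] <- head(tg, -L)
            if (i == n) {
                state$flank3 <- paste0(take, state$flank3)
                state$flank3Tags <- c(mv, state$flank3Tags)
            } else {
                state$intronSeqs[i] <- paste0(take, state$intronSeqs[i])
                state$intronTags[[i]] <- c(mv, state$intronTags[[i]])
            }
        } else {
            take <- substr(ex, 1L, L)
            state$exonSeqs[i] <- substr(ex, L + 1L, nchar(ex))
            mv <- head(tg, L); state$exonTags[[i]] <- tail(tg, -L)
            if (i == 1L) {
                state$flank5 <- paste0(state$flank5, take)
                state$flank5Tags <- c(state$flank5Tags, mv)
            } else {
                state$intronSeqs[i - 1L] <- paste0(state$intronSeqs[i - 1L],
                                                   take)
                state$intronTags[[i - 1L]] <- c(state$intronTags[[i - 1L]], mv)
            }
        }
    } else if (m == "intron_loss") {
        # intron i excised; exons i and i+1 merge
        state$exonSeqs[i] <- paste0(state$exonSeqs[i], state$exonSeqs[i + 1L])
        state$exonTags[[i]] <- c(state$exonTags[[i]], state$exonTags[[i + 1L]])
        state$exonIds[i] <- paste0(state$exonIds[i], "+",
                                   state$exonIds[i + 1L])
        state$exonSeqs <- state$exonSeqs[-(i + 1L)]
        state$exonTags[[i + 1L]] <- NULL
        state$exonIds <- state$exonIds[-(i + 1L)]
        state$intronSeqs <- state$intronSeqs[-i]
        state$intronTags[[i]] <- NULL
    } else if (m == "intron_gain") {
        # exon i splits after position p; the payload is the novel intron
        ex <- state$exonSeqs[i]; tg <- state$exonTags[[i]]
        left <- substr(ex, 1L, p); right <- substr(ex, p + 1L, nchar(ex))
        id <- state$exonIds[i]
        state$exonSeqs <- append(state$exonSeqs[-i], c(left, right),
                                 after = i - 1L)
        state$exonIds <- append(state$exonIds[-i],
                                paste0(id, c("a", "b")), after = i - 1L)
        tgs <- state$exonTags; tgs[[i]] <- NULL
        tgs <- append(tgs, list(head(tg, p), tail(tg, -p)), after = i - 1L)
        state$exonTags <- tgs
        state$intronSeqs <- append(state$intronSeqs, op$payload,
                                   after = i - 1L)
        itg <- state$intronTags
        itg <- append(itg, list(rep(NA_character_, nchar(op$payload))),
                      after = i - 1L)
        state$intronTags <- itg
    } else if (m == "exon_gain") {
        # novel exon inserted inside intron i at position p
        state$gainCounter <- state$gainCounter + 1L
        gid <- paste0("G", state$gainCounter)
        intr <- state$intronSeqs[i]; itg <- state$intronTags[[i]]
        left <- substr(intr, 1L, p); right <- substr(intr, p + 1L, nchar(intr))
        state$intronSeqs <- append(state$intronSeqs[-i], c(left, right),
                                   after = i - 1L)
        tgs <- state$intronTags; tgs[[i]] <- NULL
        tgs <- append(tgs, list(head(itg, p), tail(itg, -p)), after = i - 1L)
        state$intronTags <- tgs
        state$exonSeqs <- append(state$exonSeqs, op$payload, after = i)
        state$exonIds <- append(state$exonIds, gid, after = i)
        etg <- state$exonTags
        etg <- append(etg, list(rep(NA_character_, nchar(op$payload))),
                      after = i)
        state$exonTags <- etg
    } else if (m == "exon_loss") {
        n <- length(state$exonSeqs)
        if (i == 1L) {
            state$flank5 <- paste0(state$flank5, state$intronSeqs[1L])
            state$flank5Tags <- c(state$flank5Tags, state$intronTags[[1L]])
            state$intronSeqs <- state$intronSeqs[-1L]
            state$intronTags[[1L]] <- NULL
        } else if (i == n) {
            state$flank3 <- paste0(state$intronSeqs[n - 1L], state$flank3)
            state$flank3Tags <- c(state$intronTags[[n - 1L]],
                                  state$flank3Tags)
            state$intronSeqs <- state$intronSeqs[-(n - 1L)]
            state$intronTags[[n - 1L]] <- NULL
        } else {
            state$intronSeqs[i - 1L] <- paste0(state$intronSeqs[i - 1L],
                                               state$intronSeqs[i])
            state$intronTags[[i - 1L]] <- c(state$intronTags[[i - 1L]],
                                            state$intronTags[[i]])
            state$intronSeqs <- state$intronSeqs[-i]
            state$intronTags[[i]] <- NULL
        }
        state$exonSeqs <- state$exonSeqs[-i]
        state$exonIds <- state$exonIds[-i]
        state$exonTags[[i]] <- NULL
    } else {
        stop("unknown ledger mechanism: ", m)
    }
    if (m %in% c("intraexonic_insertion", "intraexonic_deletion",
                 "exonization", "pseudoexonization", "exon_gain",
                 "exon_loss") && L %% 3L != 0L)
        state$frameIntact <- FALSE
    state
}

applyOps <- function(state, ops) {
    if (is.null(ops) || !nrow(ops)) return(state)
    for (r in seq_len(nrow(ops))) state <- applyOp(state, as.list(ops[r, ]))
    state
}

emptyLedger <- function() {
    data.frame(event_id = character(), branch = character(),
               mechanism = character(), seg_type = character(),
               seg_index = integer(), exon_index = integer(),
               side = integer(), position = integer(),
               length_bp = integer(), payload = character(),
               stringsAsFactors = FALSE)
}

ledgerRow <- function(event_id, branch, mechanism, seg_type, seg_index,
                      exon_index, side, position, length_bp, payload) {
    data.frame(event_id = event_id, branch = branch, mechanism = mechanism,
               seg_type = seg_type, seg_index = as.integer(seg_index),
               exon_index = as.integer(exon_index), side = as.integer(side),
               position = as.integer(position),
               length_bp = as.integer(length_bp), payload = payload,
               stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# stochastic generation

# random ingroup topology + one outgroup leaf; branch lengths in
# substitutions/site, shallow (within-family) divergence
randomFamilyTree <- function(nLeaves) {
    ing <- ape::rtree(nLeaves, rooted = TRUE, tip.label = paste0("g", seq_len(nLeaves)))
    ing$edge.length <- runif(nrow(ing$edge), 0.005, 0.02)
    txt <- ape::write.tree(ing)
    txt <- sub(";$", "", txt)
    full <- ape::read.tree(text = sprintf("(outgroup:0.0125,%s:0.0125);", txt))
    full
}

# claim helper: returns TRUE (and registers) when the root-coordinate tags
# of the affected interval are all known and unclaimed
tryClaim <- function(registry, tags, buffer = 12L) {
    if (!length(tags)) return(FALSE)
    if (anyNA(tags)) return(FALSE)
    plain <- tags[!grepl(":", tags, fixed = TRUE)]
    tags <- setdiff(tags, plain)
    expand <- plain
    if (length(tags)) {
        parts <- strsplit(tags, ":", fixed = TRUE)
        segs <- vapply(parts, `[`, character(1), 1L)
        pos <- as.integer(vapply(parts, `[`, character(1), 2L))
        for (s in unique(segs)) {
            p <- pos[segs == s]
            expand <- c(expand, paste0(s, ":",
                                       seq(min(p) - buffer, max(p) + buffer)))
        }
    }
    if (any(vapply(expand, function(t) !is.null(registry[[t]]),
                   logical(1))))
        return(FALSE)
    for (t in expand) registry[[t]] <- TRUE
    TRUE
}

# junction token of an intron/flank segment: any two structural events
# touching the same inter-exon junction collide in alignment space even
# when their genomic footprints are disjoint (e.g. recruitment from the
# head and the tail of one intron), so each junction is claimable once
juncToken <- function(tags) {
    real <- tags[!is.na(tags)]
    if (!length(real)) return(NA_character_)
    paste0("JUNC_", sub(":.*$", "", real[1]))
}

# tags touched by a proposed op, used for the overlap check; boundary and
# segment-level events additionally claim the junction token(s) and a
# buffer into the adjacent segments
opTags <- function(state, m, i, side, p, L) {
    n <- length(state$exonSeqs)
    edge <- 12L
    if (m %in% c("intraexonic_insertion", "intron_gain")) {
        tg <- state$exonTags[[i]]
        idx <- max(1L, p):min(length(tg), p + 1L)
        return(tg[idx])
    }
    if (m == "intraexonic_deletion") {
        tg <- state$exonTags[[i]]
        return(tg[p:(p + L - 1L)])
    }
    if (m %in% c("exonization", "pseudoexonization")) {
        nc <- if (side == 5L) {
            if (i == 1L) state$flank5Tags else state$intronTags[[i - 1L]]
        } else {
            if (i == n) state$flank3Tags else state$intronTags[[i]]
        }
        ex <- state$exonTags[[i]]
        part <- if (m == "exonization") {
            if (side == 5L) tail(nc, L) else head(nc, L)
        } else {
            if (side == 5L) head(ex, L) else tail(ex, L)
        }
        exEdge <- if (side == 5L) head(ex, edge) else tail(ex, edge)
        ncEdge <- if (side == 5L) tail(nc, edge) else head(nc, edge)
        return(c(part, exEdge, ncEdge, juncToken(nc)))
    }
    if (m == "intron_loss") {
        nc <- state$intronTags[[i]]
        return(c(nc, tail(state$exonTags[[i]], edge),
                 head(state$exonTags[[i + 1L]], edge), juncToken(nc)))
    }
    if (m == "exon_gain") {
        tg <- state$intronTags[[i]]
        idx <- max(1L, p):min(length(tg), p + 1L)
        return(c(tg[idx], juncToken(tg)))
    }
    if (m == "exon_loss") {
        left <- if (i == 1L) state$flank5Tags else state$intronTags[[i - 1L]]
        right <- if (i == n) state$flank3Tags else state$intronTags[[i]]
        return(c(state$exonTags[[i]], tail(left, edge), head(right, edge),
                 juncToken(left), juncToken(right)))
    }
    character()
}

# does the CDS of `state` contain a premature in-frame stop (frame of the
# current CDS start)?  Only meaningful while the frame is intact.
hasPrematureStop <- function(state) {
    cds <- stateCds(state)
    n <- nchar(cds)
    s <- firstInFrameStop(cds, 1L)
    !is.na(s) && s < n - 2L
}

#' Simulate one gene family with a known event history
#'
#' Evolves a MADS-box-like ancestral gene along a rooted tree by
#' Jukes-Cantor point substitution plus structural events drawn per branch
#' (Poisson with mean rate x branch length).  Boundary-recruitment events
#' exchange sequence with the adjacent intron so exonized material remains
#' detectable in the partner's noncoding sequence.  Event positions are
#' rejected (and redrawn) when they would overlap a previous event's
#' footprint, keeping histories overlap-free at default rates; the
#' designated outgroup branch stays event-free so it anchors ancestral
#' states.  Substitutions never create a premature in-frame stop and never
#' touch the terminal stop codon; only structural events may break these.
#'
#' @param cfg a \code{SimConfig}.
#' @return list with \code{family} (\code{FamilySet}, outgroup designated),
#'   \code{tree} (labelled rooted \code{phylo}) and \code{history}
#'   (\code{TrueHistory}).
#' @examples
#' sim <- simulateFamily(simConfig(seed = 7))
#' nrow(structuralLedger(ledger(sim$history)))
#' @export
simulateFamily <- function(cfg) {
    stopifnot(is(cfg, "SimConfig"))
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(cfg@seed)
    tree <- if (is.null(cfg@tree)) randomFamilyTree(cfg@nLeaves)
            else cfg@tree
    tree <- ensureNodeLabels(tree)
    n <- ape::Ntip(tree)
    rootLab <- nodeLabel(tree, rootNode(tree))
    anc <- ancestralState(cfg@ancestralExonLengths, cfg@intronLength,
                          cfg@flankLength)
    registry <- new.env(parent = emptyenv())
    ledgerRows <- list()
    snapshots <- list()
    counters <- new.env(parent = emptyenv())
    counters$ev <- 0L; counters$sub <- 0L
    counters$attempts <- 0L; counters$rejected <- 0L
    counters$drawn <- 0L; counters$dropped <- 0L
    snapshots[[rootLab]] <- stateToModel(rootLab, anc)
    states <- list(); states[[rootLab]] <- anc

    evolveEdge <- function(parentState, childLab, len, allowEvents) {
        state <- parentState
        # --- substitutions
        p <- cfg@substRate * len
        segments <- c(lapply(seq_along(state$exonSeqs), function(i)
                          list(type = "exon", i = i)),
                      lapply(seq_along(state$intronSeqs), function(i)
                          list(type = "intron", i = i)),
                      list(list(type = "flank5", i = 1L),
                           list(type = "flank3", i = 1L)))
        for (seg in segments) {
            s <- switch(seg$type, exon = state$exonSeqs[seg$i],
                        intron = state$intronSeqs[seg$i],
                        flank5 = state$flank5, flank3 = state$flank3)
            lenS <- nchar(s)
            if (!lenS) next
            hits <- which(runif(lenS) < p)
            for (pos in hits) {
                cur <- substr(s, pos, pos)
                newb <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
                if (seg$type == "exon") {
                    # protect terminal stop; avoid creating premature stops
                    nEx <- length(state$exonSeqs)
                    if (seg$i == nEx && pos > nchar(s) - 3L && state$frameIntact)
                        next
                    cand <- state
                    substr(cand$exonSeqs[seg$i], pos, pos) <- newb
                    if (cand$frameIntact && hasPrematureStop(cand)) next
                    state <- cand
                } else if (seg$type == "intron") {
                    substr(state$intronSeqs[seg$i], pos, pos) <- newb
                } else if (seg$type == "flank5") {
                    substr(state$flank5, pos, pos) <- newb
                } else {
                    substr(state$flank3, pos, pos) <- newb
                }
                s <- switch(seg$type, exon = state$exonSeqs[seg$i],
                            intron = state$intronSeqs[seg$i],
                            flank5 = state$flank5, flank3 = state$flank3)
                counters$sub <- counters$sub + 1L
                ledgerRows[[length(ledgerRows) + 1L]] <<- ledgerRow(
                    sprintf("S%04d", counters$sub), childLab, "substitution",
                    seg$type, seg$i, NA_integer_, NA_integer_, pos, 1L, newb)
            }
        }
        # --- structural events
        if (allowEvents) {
            for (m in names(cfg@eventRates)) {
                lambda <- cfg@eventRates[[m]] * len
                nEv <- rpois(1L, lambda)
                for (k in seq_len(nEv)) {
                    counters$drawn <- counters$drawn + 1L
                    res <- drawEvent(state, m, cfg, registry, counters)
                    if (is.null(res)) {
                        counters$dropped <- counters$dropped + 1L
                        next
                    }
                    state <- applyOp(state, res$op)
                    counters$ev <- counters$ev + 1L
                    ledgerRows[[length(ledgerRows) + 1L]] <<- ledgerRow(
                        sprintf("V%04d", counters$ev), childLab,
                        res$op$mechanism, res$op$seg_type, res$op$seg_index,
                        res$exonIndex, res$op$side, res$op$position,
                        res$op$length_bp, res$op$payload)
                }
            }
        }
        state
    }

    walk <- function(node) {
        for (child in childrenOf(tree, node)) {
            lab <- nodeLabel(tree, child)
            len <- tree$edge.length[which(tree$edge[, 2] == child)]
            allow <- !(child <= n && lab == "outgroup")
            st <- evolveEdge(states[[nodeLabel(tree, node)]], lab, len, allow)
            states[[lab]] <<- st
            snapshots[[lab]] <<- stateToModel(lab, st)
            if (child > n) walk(child)
        }
    }
    walk(rootNode(tree))

    if (counters$drawn >= 10L && counters$dropped / counters$drawn > 0.5)
        stop("event rates too high: more than half of the drawn events ",
             "could not be placed without overlapping existing events; ",
             "lower the per-branch event rates")

    ledger <- if (length(ledgerRows)) do.call(rbind, ledgerRows)
              else emptyLedger()
    leafModels <- lapply(tree$tip.label, function(t) {
        gm <- snapshots[[t]]
        gm@speciesId <- t
        gm
    })
    fam <- FamilySet(leafModels,
                     outgroup = intersect("outgroup", tree$tip.label))
    history <- new("TrueHistory", ledger = ledger, snapshots = snapshots,
                   tree = tree, ancestorId = rootLab)
    list(family = fam, tree = tree, history = history)
}

# draw one event of mechanism class m; returns NULL when no eligible site
# was found (every rejection is counted)
drawEvent <- function(state, m, cfg, registry, counters, maxTry = 20L) {
    nEx <- length(state$exonSeqs)
    nonStopCodons <- setdiff(names(Biostrings::GENETIC_CODE), stopCodons())
    for (attempt in seq_len(maxTry)) {
        counters$attempts <- counters$attempts + 1L
        op <- NULL
        if (m == "intraexonic_indel") {
            Lc <- 1L + rgeom(1L, 1 / cfg@indelMeanCodons)
            L <- 3L * Lc
            if (runif(1) > cfg@pFrame)
                L <- max(1L, L + sample(c(-1L, 1L), 1L))
            ins <- runif(1) < 0.5
            elig <- which(nchar(state$exonSeqs) >= (if (ins) 20L else L + 20L))
            if (!length(elig)) { counters$rejected <- counters$rejected + 1L; next }
            e <- pick1(elig)
            lenE <- nchar(state$exonSeqs[e])
            if (ins) {
                p <- pick1(seq(5L, lenE - 5L))
                payload <- paste(sample(c("A", "C", "G", "T"), L,
                                        replace = TRUE), collapse = "")
                op <- list(mechanism = "intraexonic_insertion",
                           seg_type = "exon", seg_index = e, side = NA_integer_,
                           position = p, length_bp = L, payload = payload)
            } else {
                p <- pick1(seq(3L, lenE - L - 2L))
                op <- list(mechanism = "intraexonic_deletion",
                           seg_type = "exon", seg_index = e, side = NA_integer_,
                           position = p, length_bp = L,
                           payload = NA_character_)
            }
        } else if (m %in% c("exonization", "pseudoexonization")) {
            L <- 15L + 3L * rgeom(1L, 1 / 3)
            # internal boundaries only (side 5 of exons 2..n, side 3 of 1..n-1)
            opts <- rbind(cbind(e = 2:nEx, side = 5L),
                          cbind(e = 1:(nEx - 1L), side = 3L))
            ok <- apply(opts, 1L, function(o) {
                intr <- if (o["side"] == 5L) o["e"] - 1L else o["e"]
                if (m == "exonization")
                    nchar(state$intronSeqs[intr]) >= L + 40L
                else nchar(state$exonSeqs[o["e"]]) >= L + 30L &&
                     !(o["e"] == nEx && o["side"] == 3L) &&
                     !(o["e"] == 1L && o["side"] == 5L)
            })
            opts <- opts[ok, , drop = FALSE]
            if (!nrow(opts)) { counters$rejected <- counters$rejected + 1L; next }
            pick <- opts[sample(nrow(opts), 1L), ]
            op <- list(mechanism = m, seg_type = "exon",
                       seg_index = unname(pick["e"]),
                       side = unname(pick["side"]),
                       position = NA_integer_, length_bp = L,
                       payload = NA_character_)
        } else if (m == "intron_loss") {
            if (length(state$intronSeqs) < 1L) {
                counters$rejected <- counters$rejected + 1L; next }
            i <- sample(length(state$intronSeqs), 1L)
            op <- list(mechanism = "intron_loss", seg_type = "intron",
                       seg_index = i, side = NA_integer_,
                       position = NA_integer_, length_bp = 0L,
                       payload = NA_character_)
        } else if (m == "intron_gain") {
            elig <- which(nchar(state$exonSeqs) >= 60L)
            if (!length(elig)) { counters$rejected <- counters$rejected + 1L; next }
            e <- pick1(elig)
            lenE <- nchar(state$exonSeqs[e])
            p <- pick1(seq(20L, lenE - 20L))
            payload <- paste(sample(c("A", "C", "G", "T"), cfg@intronLength,
                                    replace = TRUE), collapse = "")
            op <- list(mechanism = "intron_gain", seg_type = "exon",
                       seg_index = e, side = NA_integer_, position = p,
                       length_bp = 0L, payload = payload)
        } else if (m == "exon_gain") {
            if (length(state$intronSeqs) < 1L) {
                counters$rejected <- counters$rejected + 1L; next }
            i <- sample(length(state$intronSeqs), 1L)
            lenI <- nchar(state$intronSeqs[i])
            if (lenI < 80L) { counters$rejected <- counters$rejected + 1L; next }
            p <- pick1(seq(30L, lenI - 30L))
            L <- 3L * (15L + rgeom(1L, 1 / 5))
            payload <- paste(sample(nonStopCodons, L %/% 3L, replace = TRUE),
                             collapse = "")
            op <- list(mechanism = "exon_gain", seg_type = "intron",
                       seg_index = i, side = NA_integer_, position = p,
                       length_bp = L, payload = payload)
        } else if (m == "exon_loss") {
            if (nEx < 4L) { counters$rejected <- counters$rejected + 1L; next }
            e <- pick1(2:(nEx - 1L))
            op <- list(mechanism = "exon_loss", seg_type = "exon",
                       seg_index = e, side = NA_integer_,
                       position = NA_integer_,
                       length_bp = nchar(state$exonSeqs[e]),
                       payload = NA_character_)
        }
        if (is.null(op)) return(NULL)
        tags <- opTags(state, op$mechanism, op$seg_index, op$side,
                       op$position, op$length_bp)
        if (!tryClaim(registry, tags)) {
            counters$rejected <- counters$rejected + 1L
            next
        }
        # frame-preserving events must not create a premature stop
        cand <- applyOp(state, op)
        if (state$frameIntact && cand$frameIntact && hasPrematureStop(cand)) {
            counters$rejected <- counters$rejected + 1L
            next
        }
        exonIndex <- if (op$seg_type == "exon")
            rootIndexOf(state$exonIds[op$seg_index])
        else if (op$mechanism %in% c("intron_loss", "exon_gain"))
            rootIndexOf(state$exonIds[op$seg_index])
        else NA_integer_
        return(list(op = op, exonIndex = exonIndex))
    }
    NULL
}

#' Replay a TrueHistory from its ancestral snapshot
#'
#' Re-applies every ledger operation (substitutions and structural events)
#' along the tree, starting from the root snapshot; the resulting leaf gene
#' models must reproduce the recorded leaves byte for byte.
#'
#' @param history a \code{TrueHistory}.
#' @return named list of reconstructed leaf \code{GeneModel}s.
#' @export
replayHistory <- function(history) {
    tree <- history@tree
    n <- ape::Ntip(tree)
    root <- rootNode(tree)
    anc <- history@snapshots[[history@ancestorId]]
    state0 <- newStateFromSeqs(as.character(exonSeqs(anc)),
                               as.character(intronSeqs(anc)),
                               as.character(flank5(anc)),
                               as.character(flank3(anc)))
    out <- list()
    walk <- function(node, state) {
        for (child in childrenOf(tree, node)) {
            lab <- nodeLabel(tree, child)
            ops <- history@ledger[history@ledger$branch == lab, , drop = FALSE]
            st <- applyOps(state, ops)
            if (child <= n) out[[lab]] <<- stateToModel(lab, st)
            else walk(child, st)
        }
    }
    walk(root, state0)
    out
}
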