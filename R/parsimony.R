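#' @include AllClasses.R AllGenerics.R events.R
NULL

#' @export
setMethod("branches", "EventPlacement", function(x) x@branches)

setMethod("show", "EventPlacement", function(object) {
    cat(sprintf("EventPlacement %s: %s on branch(es) %s (cost %d%s)\n",
                object@eventId, object@mechanism,
                paste(object@branches, collapse = ","),
                as.integer(object@cost),
                if (length(object@alternatives))
                    sprintf(", %d alternative scenario(s)",
                            length(object@alternatives)) else ""))
})

# label every node of a rooted phylo; internal nodes without labels get
# node<N>; returns the tree with tip+node labels guaranteed unique
ensureNodeLabels <- function(tree) {
    stopifnot(inherits(tree, "phylo"))
    n <- ape::Ntip(tree)
    if (is.null(tree$node.label) || !length(tree$node.label))
        tree$node.label <- rep("", tree$Nnode)
    empty <- !nzchar(tree$node.label) | is.na(tree$node.label)
    tree$node.label[empty] <- paste0("node", which(empty) + n)
    tree
}

nodeLabel <- function(tree, node) {
    n <- ape::Ntip(tree)
    if (node <= n) tree$tip.label[node] else tree$node.label[node - n]
}

nodeNumber <- function(tree, label) {
    n <- ape::Ntip(tree)
    i <- match(label, tree$tip.label)
    if (!is.na(i)) return(i)
    j <- match(label, tree$node.label)
    if (is.na(j)) stop("unknown node label: ", label)
    j + n
}

childrenOf <- function(tree, node) tree$edge[tree$edge[, 1] == node, 2]

rootNode <- function(tree) ape::Ntip(tree) + 1L

# binary Sankoff: states is a named logical vector over tips (TRUE =
# derived), NA = missing.  Returns matrix [node, state(1=absent,2=present)]
# of minimal change counts in the subtree below each node.
sankoffBinary <- function(tree, states) {
    n <- ape::Ntip(tree)
    nn <- n + tree$Nnode
    cost <- matrix(Inf, nrow = nn, ncol = 2)
    for (i in seq_len(n)) {
        s <- states[[tree$tip.label[i]]]
        if (is.na(s)) cost[i, ] <- c(0, 0)
        else if (s) cost[i, ] <- c(Inf, 0)
        else cost[i, ] <- c(0, Inf)
    }
    po <- ape::reorder.phylo(tree, "postorder")
    for (e in seq_len(nrow(po$edge))) {
        parent <- po$edge[e, 1]
        if (is.finite(cost[parent, 1]) || is.finite(cost[parent, 2])) next
        # fill when all children done; postorder guarantees children first
        kids <- childrenOf(tree, parent)
        c0 <- 0; c1 <- 0
        for (k in kids) {
            c0 <- c0 + min(cost[k, 1], cost[k, 2] + 1)
            c1 <- c1 + min(cost[k, 2], cost[k, 1] + 1)
        }
        cost[parent, ] <- c(c0, c1)
    }
    # any internal nodes left (e.g. root when marked): fill via recursion
    fill <- function(node) {
        if (node <= n) return(invisible())
        if (is.finite(cost[node, 1]) || is.finite(cost[node, 2]))
            return(invisible())
        kids <- childrenOf(tree, node)
        for (k in kids) fill(k)
        c0 <- 0; c1 <- 0
        for (k in kids) {
            c0 <- c0 + min(cost[k, 1], cost[k, 2] + 1)
            c1 <- c1 + min(cost[k, 2], cost[k, 1] + 1)
        }
        cost[node, ] <- c(c0, c1)
        invisible()
    }
    fill(rootNode(tree))
    cost
}

# minimal-change state assignment given a fixed root state; at ties the
# derived state is preferred so gains sit as close to the root as possible
extractScenario <- function(tree, cost, rootState) {
    n <- ape::Ntip(tree)
    nn <- n + tree$Nnode
    derived <- 1L - rootState
    state <- rep(NA_integer_, nn)
    state[rootNode(tree)] <- rootState
    assign <- function(node) {
        for (k in childrenOf(tree, node)) {
            s <- state[node]
            stay <- cost[k, s + 1]
            switchc <- cost[k, (1 - s) + 1] + 1
            state[k] <<- if (switchc < stay) 1L - s
                         else if (stay < switchc) s
                         else derived   # tie: prefer derived (root-most gain)
            if (k > n) assign(k)
        }
    }
    assign(rootNode(tree))
    state
}

mrcaOf <- function(tree, tips) {
    n <- ape::Ntip(tree)
    idx <- match(tips, tree$tip.label)
    if (length(idx) == 1L) return(idx)
    ape::getMRCA(tree, idx)
}

descendantTips <- function(tree, node) {
    n <- ape::Ntip(tree)
    if (node <= n) return(tree$tip.label[node])
    kids <- childrenOf(tree, node)
    unlist(lapply(kids, descendantTips, tree = tree))
}

# Dollo scenario for derived set D: single gain on the stem of MRCA(D),
# losses on the maximal subtrees inside that clade with no derived tip.
# Tips with NA state are treated as compatible with either state.
dolloScenario <- function(tree, derivedTips, missingTips = character()) {
    m <- mrcaOf(tree, derivedTips)
    losses <- integer()
    walk <- function(node) {
        tips <- descendantTips(tree, node)
        informative <- setdiff(tips, missingTips)
        if (!length(informative)) return(invisible())
        if (!any(informative %in% derivedTips)) {
            losses <<- c(losses, node)
            return(invisible())
        }
        if (all(informative %in% derivedTips)) return(invisible())
        for (k in childrenOf(tree, node)) walk(k)
        invisible()
    }
    if (m > ape::Ntip(tree)) for (k in childrenOf(tree, m)) walk(k)
    list(gain = m, losses = losses, cost = 1L + length(losses))
}

#' Place one structural event on a rooted phylogeny by maximum parsimony
#'
#' Minimises the number of state changes of the binary presence/absence
#' character defined by the event's derived rows.  Among equally
#' parsimonious scenarios the single-origin (Dollo-like) scenario is
#' preferred, then the scenario whose gains sit closest to the root;
#' alternatives are listed, not chosen.  The root (ancestral) state is
#' fixed by designated outgroup rows when available, otherwise by the
#' cheaper root state, with remaining ties resolved toward the state of
#' the root-adjacent subtrees' majority and flagged.
#'
#' Polarisation happens here: indeterminate mechanisms are resolved from
#' the reconstructed ancestral state (e.g. an indeterminate indel whose
#' ancestral state is "sequence present" becomes an intraexonic deletion
#' carried by the gap rows).
#'
#' @param tree rooted \code{phylo}, tips = gene ids (internal labels kept).
#' @param event a \code{StructuralEvent}.
#' @param outgroup character vector of outgroup gene ids (may be empty).
#' @return an \code{EventPlacement}.
#' @export
mapEvent <- function(tree, event, outgroup = character()) {
    tree <- ensureNodeLabels(tree)
    tips <- tree$tip.label
    seqRows <- setdiff(tips, event@gapRows)
    known <- union(intersect(event@carrierGenes, tips),
                   intersect(event@gapRows, tips))
    miss <- setdiff(event@carrierGenes, tips)
    if (length(miss) && !length(intersect(event@carrierGenes, tips)))
        stop("carriers not on tree: ", paste(miss, collapse = ", "))
    # the binary character: TRUE = "long" state (sequence present); rows
    # with no information in the event's block (recorded by the detector)
    # stay NA (missing data)
    isMerge <- event@mechanism %in% c("intron_gain", "intron_loss")
    informative <- event@detail$informativeRows
    if (is.null(informative)) informative <- tips
    longRows <- if (isMerge) event@carrierGenes   # TRUE = merged
                else setdiff(intersect(informative, tips), event@gapRows)
    shortRows <- if (isMerge) event@gapRows else intersect(event@gapRows, tips)
    states <- setNames(rep(NA, length(tips)), tips)
    states[intersect(longRows, tips)] <- TRUE
    states[intersect(shortRows, tips)] <- FALSE
    cost <- sankoffBinary(tree, states)
    root <- rootNode(tree)
    # root (ancestral) state
    rootFlag <- "unambiguous"
    og <- intersect(outgroup, tips)
    og <- og[!is.na(states[og])]
    if (length(og)) {
        rootState <- as.integer(mean(states[og]) >= 0.5)
    } else if (cost[root, 1] != cost[root, 2]) {
        rootState <- which.min(cost[root, ]) - 1L
    } else {
        kidStates <- vapply(childrenOf(tree, root), function(k)
            which.min(cost[k, ]) - 1L, integer(1))
        if (length(unique(kidStates)) == 1L) rootState <- kidStates[1]
        else { rootState <- 0L; rootFlag <- "ambiguous" }
    }
    minCost <- cost[root, rootState + 1]
    derivedState <- 1L - rootState   # 0/1 in the long/short coding
    # derived tips (those whose observed state differs from the root state)
    derivedTips <- names(states)[!is.na(states) & states == (derivedState == 1L)]
    missingTips <- names(states)[is.na(states)]
    if (!length(derivedTips))
        stop("event has no derived tips after polarisation")
    # resolve mechanism
    mech <- polarisedMechanism(event, rootStateLong = (rootState == 1L))
    signed <- signedLengthFor(mech, event)
    # scenario
    dollo <- dolloScenario(tree, derivedTips, missingTips)
    scen <- NULL
    if (dollo$cost <= minCost) {
        scen <- dollo
        minCost <- dollo$cost
    } else {
        st <- extractScenario(tree, cost, rootState)
        gains <- integer(); losses <- integer()
        for (e in seq_len(nrow(tree$edge))) {
            p <- tree$edge[e, 1]; k <- tree$edge[e, 2]
            if (st[p] == rootState && st[k] != rootState)
                gains <- c(gains, k)
            if (st[p] != rootState && st[k] == rootState)
                losses <- c(losses, k)
        }
        scen <- list(gain = gains, losses = losses, cost = minCost)
    }
    alternatives <- enumerateAltScenarios(tree, cost, rootState, minCost,
                                          chosenGain = scen$gain, cap = 8L)
    new("EventPlacement", eventId = event@eventId,
        branches = vapply(scen$gain, function(x) nodeLabel(tree, x),
                          character(1)),
        lossBranches = vapply(scen$losses, function(x) nodeLabel(tree, x),
                              character(1)),
        mechanism = mech, cost = as.numeric(minCost),
        alternatives = alternatives,
        signedLength = signed, exonIndex = event@exonIndex,
        detail = list(rootFlag = rootFlag, derivedTips = derivedTips,
                      sourceEvent = event))
}

# resolved mechanism once the ancestral ("root") state of the long/merged
# character is known
polarisedMechanism <- function(event, rootStateLong) {
    m <- event@mechanism
    if (m %in% c("intron_gain", "intron_loss")) {
        # character TRUE = merged; ancestral merged => split rows gained an
        # intron; ancestral split => merged rows lost one
        return(if (rootStateLong) "intron_gain" else "intron_loss")
    }
    if (isTRUE(event@detail$polarityResolved)) return(m)
    if (m == "exonization")
        return(if (rootStateLong) "pseudoexonization" else "exonization")
    if (m == "indeterminate_exon_change")
        return(if (rootStateLong) "exon_loss" else "exon_gain")
    if (m == "indeterminate_indel")
        return(if (rootStateLong) "intraexonic_deletion"
               else "intraexonic_insertion")
    m
}

# signed bp effect of the polarised event on its exon, derived-lineage view
signedLengthFor <- function(mech, event) {
    L <- event@lengthBp
    switch(mech,
           intraexonic_insertion = L,
           exonization = L,
           exon_gain = L,
           intraexonic_deletion = -L,
           pseudoexonization = -L,
           exon_loss = -L,
           0L) |> as.integer()
}

# equally parsimonious alternative scenarios, enumerated by backtracking
# over tied child-state choices (capped); reported as branch-label lists
enumerateAltScenarios <- function(tree, cost, rootState, minCost,
                                  chosenGain, cap = 8L) {
    n <- ape::Ntip(tree)
    results <- list()
    recurse <- function(stateMap, frontier) {
        if (length(results) >= cap) return(invisible())
        if (!length(frontier)) {
            gains <- integer(); losses <- integer()
            for (e in seq_len(nrow(tree$edge))) {
                p <- tree$edge[e, 1]; k <- tree$edge[e, 2]
                if (stateMap[p] == rootState && stateMap[k] != rootState)
                    gains <- c(gains, k)
                if (stateMap[p] != rootState && stateMap[k] == rootState)
                    losses <- c(losses, k)
            }
            results[[length(results) + 1L]] <<-
                list(branches = vapply(gains, function(x)
                         nodeLabel(tree, x), character(1)),
                     lossBranches = vapply(losses, function(x)
                         nodeLabel(tree, x), character(1)))
            return(invisible())
        }
        node <- frontier[1]; rest <- frontier[-1]
        parent <- tree$edge[tree$edge[, 2] == node, 1]
        s <- stateMap[parent]
        stay <- cost[node, s + 1]
        switchc <- cost[node, (1 - s) + 1] + 1
        opts <- c()
        if (stay <= switchc) opts <- c(opts, s)
        if (switchc <= stay) opts <- c(opts, 1 - s)
        for (o in opts) {
            sm <- stateMap
            sm[node] <- o
            kids <- if (node > n) childrenOf(tree, node) else integer()
            recurse(sm, c(rest, kids))
        }
        invisible()
    }
    nn <- n + tree$Nnode
    stateMap <- rep(NA_integer_, nn)
    stateMap[rootNode(tree)] <- rootState
    recurse(stateMap, childrenOf(tree, rootNode(tree)))
    # drop the chosen scenario itself
    chosenLabels <- sort(vapply(chosenGain, function(x) nodeLabel(tree, x),
                                character(1)))
    Filter(function(alt) !identical(sort(alt$branches), chosenLabels),
           results)
}

#' Map a list of events and polarise them
#'
#' @param tree rooted \code{phylo}.
#' @param events list of \code{StructuralEvent}.
#' @param outgroup outgroup gene ids.
#' @return list of \code{EventPlacement}.
#' @export
mapEvents <- function(tree, events, outgroup = character()) {
    lapply(events, function(e) mapEvent(tree, e, outgroup))
}

#' Placements table
#' @param placements list of \code{EventPlacement}.
#' @return data.frame, one row per placement.
#' @export
placementTable <- function(placements) {
    if (!length(placements))
        return(data.frame(event_id = character(), mechanism = character(),
                          exon_index = integer(), signed_length = integer(),
                          branches = character(), loss_branches = character(),
                          cost = numeric(), n_alternatives = integer(),
                          stringsAsFactors = FALSE))
    do.call(rbind, lapply(placements, function(p) data.frame(
        event_id = p@eventId, mechanism = p@mechanism,
        exon_index = p@exonIndex, signed_length = p@signedLength,
        branches = paste(sort(p@branches), collapse = ","),
        loss_branches = paste(sort(p@lossBranches), collapse = ","),
        cost = p@cost, n_alternatives = length(p@alternatives),
        stringsAsFactors = FALSE)))
}

# labels of nodes on the path root -> node (excluding root, including node)
pathFromRoot <- function(tree, node) {
    path <- integer()
    cur <- node
    root <- rootNode(tree)
    while (cur != root) {
        path <- c(cur, path)
        cur <- tree$edge[tree$edge[, 2] == cur, 1]
    }
    path
}

#' Reconstruct ancestral exon-intron structures
#'
#' Computes per-exon ancestral lengths at every internal node from the leaf
#' lengths and the polarised event placements: for every root-to-leaf path,
#' leaf length = node length + the signed sum of event lengths on the path
#' below the node.  Root lengths are anchored on designated outgroup rows
#' when available (they carry the ancestral state by construction),
#' otherwise on the modal estimate across leaves; a dissenting leaf makes
#' the exon ambiguous (or raises an error naming the offending path when
#' \code{strict = TRUE}).  Exon counts adjust at branches carrying exon
#' gain/loss or intron gain/loss placements, on whichever side of the
#' branch holds the split or exon-bearing state.
#'
#' @param tree rooted labelled \code{phylo}.
#' @param fs the \code{FamilySet}.
#' @param placements list of \code{EventPlacement}.
#' @param aln the refined \code{CodonAlignment} (defines the reference exon
#'   blocks and per-leaf block lengths).
#' @param strict error on an inconsistent path instead of flagging.
#' @param outgroup outgroup gene ids used to anchor the root estimate.
#' @return named list of \code{AncestralStructure}, one per internal node.
#' @export
reconstructAncestralStructure <- function(tree, fs, placements, aln,
                                          strict = TRUE,
                                          outgroup = character()) {
    tree <- ensureNodeLabels(tree)
    n <- ape::Ntip(tree)
    spans <- blockSpans(aln)
    nExon <- nrow(spans)
    tips <- tree$tip.label
    # leaf lengths per reference exon = ungapped length within the block
    leafLen <- matrix(0L, nrow = length(tips), ncol = nExon,
                      dimnames = list(tips, NULL))
    for (r in tips) {
        for (k in seq_len(nExon)) {
            cols <- spans[k, "start"]:spans[k, "end"]
            leafLen[r, k] <- sum(aln@mat[r, cols] != "-")
        }
    }
    internal <- (n + 1L):(n + tree$Nnode)
    allNodes <- seq_len(n + tree$Nnode)
    branchEffect <- matrix(0L, nrow = length(allNodes), ncol = nExon)
    # presentation ops: per node, blocks to merge with their right
    # neighbour, and per-block segmentations replacing the single length
    mergeOps <- lapply(allNodes, function(i) integer())
    splitOps <- lapply(allNodes, function(i) list())
    transferEffect <- matrix(0L, nrow = length(allNodes), ncol = nExon)
    nodesBelow <- function(b) {
        kids <- childrenOf(tree, b)
        c(b, unlist(lapply(kids, nodesBelow)))
    }
    for (p in placements) {
        k <- p@exonIndex
        if (is.na(k) || k < 1L || k > nExon) next
        gainNodes <- vapply(p@branches, function(b) nodeNumber(tree, b),
                            integer(1))
        lossNodes <- vapply(p@lossBranches, function(b) nodeNumber(tree, b),
                            integer(1))
        derived <- setdiff(unique(unlist(lapply(gainNodes, nodesBelow))),
                           unique(unlist(lapply(lossNodes, nodesBelow))))
        src <- p@detail$sourceEvent
        d <- if (!is.null(src)) src@detail else list()
        if (p@mechanism %in% c("intron_gain", "intron_loss")) {
            refSplit <- isTRUE(d$referenceSplit)
            mergedNodes <- if (p@mechanism == "intron_loss") derived
                           else setdiff(allNodes, derived)
            splitNodes <- setdiff(allNodes, mergedNodes)
            if (refSplit) {
                if (k < nExon)
                    for (nd in mergedNodes)
                        mergeOps[[nd]] <- union(mergeOps[[nd]], k)
            } else if (!is.null(d$splitLengths)) {
                for (nd in splitNodes)
                    splitOps[[nd]][[as.character(k)]] <- d$splitLengths
            }
            next
        }
        # length-affecting events
        for (nd in gainNodes)
            branchEffect[nd, k] <- branchEffect[nd, k] + p@signedLength
        for (nd in lossNodes)
            branchEffect[nd, k] <- branchEffect[nd, k] - p@signedLength
        # a boundary segment that the consensus partition put into the
        # wrong block is re-attributed at sequence-bearing nodes
        tgt <- d$lengthTargetBlock
        if (!is.null(tgt) && !is.na(tgt) && tgt != k && tgt >= 1L &&
            tgt <= nExon) {
            bearing <- if (p@signedLength > 0L) derived
                       else setdiff(allNodes, derived)
            Labs <- abs(p@signedLength)
            for (nd in bearing) {
                transferEffect[nd, k] <- transferEffect[nd, k] - Labs
                transferEffect[nd, tgt] <- transferEffect[nd, tgt] + Labs
            }
        }
        # whole-exon events that live inside a larger consensus block need
        # the exon-bearing side presented as separate exons
        isExonEvent <- p@mechanism %in% c("exon_gain", "exon_loss") ||
            isTRUE(d$wholeExon)
        if (isExonEvent && !isTRUE(d$wholeBlock) &&
            !is.null(d$subBlockParts)) {
            bearing <- if (p@signedLength > 0L) derived
                       else setdiff(allNodes, derived)
            parts <- d$subBlockParts
            for (nd in bearing)
                splitOps[[nd]][[as.character(k)]] <- parts[parts > 0L]
        }
    }
    # root lengths per block: anchored on outgroup leaves when designated
    ogTips <- intersect(outgroup, tips)
    rootLen <- integer(nExon); support <- rep("unambiguous", nExon)
    estAll <- matrix(0L, nrow = length(tips), ncol = nExon,
                     dimnames = list(tips, NULL))
    for (r in tips) {
        node <- match(r, tips)
        path <- pathFromRoot(tree, node)
        estAll[r, ] <- leafLen[r, ] -
            colSums(branchEffect[path, , drop = FALSE])
    }
    for (k in seq_len(nExon)) {
        est <- estAll[, k]
        anchor <- if (length(ogTips)) est[ogTips] else est
        tab <- sort(table(anchor), decreasing = TRUE)
        rootLen[k] <- as.integer(names(tab)[1])
        if (length(unique(est)) > 1L) {
            bad <- tips[est != rootLen[k]]
            if (strict)
                stop(sprintf(
                    "exon %d: root length implied by leaf %s (%d) disagrees with the anchor estimate (%d)",
                    k, bad[1], est[bad[1]], rootLen[k]))
            support[k] <- "ambiguous"
        }
    }
    out <- list()
    for (nd in internal) {
        path <- pathFromRoot(tree, nd)
        lens <- rootLen + colSums(branchEffect[path, , drop = FALSE]) +
            transferEffect[nd, ]
        segs <- lapply(seq_len(nExon), function(k) lens[k])
        segSupport <- lapply(seq_len(nExon), function(k) support[k])
        for (k in names(splitOps[[nd]])) {
            ki <- as.integer(k)
            parts <- splitOps[[nd]][[k]]
            # keep path conservation exact: absorb any residual in the
            # largest part
            diffv <- lens[ki] - sum(parts)
            if (diffv != 0L) {
                w <- which.max(parts)
                parts[w] <- parts[w] + diffv
                segSupport[[ki]] <- rep("ambiguous", length(parts))
            } else {
                segSupport[[ki]] <- rep(support[ki], length(parts))
            }
            segs[[ki]] <- parts
        }
        # merges combine a block with its right neighbour
        for (k in sort(mergeOps[[nd]], decreasing = TRUE)) {
            if (k + 1L > nExon) next
            segs[[k]] <- sum(segs[[k]], segs[[k + 1L]])
            segSupport[[k]] <- if (any(c(segSupport[[k]][1],
                                         segSupport[[k + 1L]][1]) ==
                                      "ambiguous")) "ambiguous"
                               else "unambiguous"
            segs[[k + 1L]] <- numeric()
            segSupport[[k + 1L]] <- character()
        }
        lensOut <- as.integer(unlist(segs))
        supOut <- unlist(segSupport)
        keep <- lensOut > 0L
        lab <- nodeLabel(tree, nd)
        out[[lab]] <- new("AncestralStructure", nodeId = lab,
                          exonCount = sum(keep),
                          exonLengths = lensOut[keep],
                          support = supOut[keep])
    }
    out
}

#' Ancestral structure table
#' @param structures named list of \code{AncestralStructure}.
#' @return data.frame with node_id, exon_count, lengths, support.
#' @export
ancestralTable <- function(structures) {
    if (!length(structures))
        return(data.frame(node_id = character(), exon_count = integer(),
                          exon_lengths = character(), support = character(),
                          stringsAsFactors = FALSE))
    do.call(rbind, lapply(structures, function(s) data.frame(
        node_id = s@nodeId, exon_count = s@exonCount,
        exon_lengths = paste(s@exonLengths, collapse = ","),
        support = paste(s@support, collapse = ","),
        stringsAsFactors = FALSE)))
}

#' Rank genes by structural divergence and emit nested subsets
#'
#' The per-gene divergence score sums, over all events placed on the gene's
#' root-to-leaf path, a unit weight inflated by \code{nonTripletPenalty}
#' for frame-violating events.  Genes are ordered (score, then id);
#' caller-supplied retention thresholds produce nested subsets in the
#' spirit of progressively excluding structurally diverged lineages.
#'
#' @param fs the \code{FamilySet}.
#' @param placements list of \code{EventPlacement}.
#' @param tree rooted labelled \code{phylo}.
#' @param thresholds numeric vector of score cutoffs (a gene is retained
#'   when its score is <= the cutoff).
#' @param nonTripletPenalty extra weight for frame-violating events
#'   (default 2).
#' @return list with \code{ranking} (data.frame gene_id, score) and
#'   \code{subsets} (list of gene id vectors, one per threshold).
#' @export
rankStructuralDivergence <- function(fs, placements, tree,
                                     thresholds = numeric(),
                                     nonTripletPenalty = 2) {
    tree <- ensureNodeLabels(tree)
    tips <- tree$tip.label
    score <- setNames(numeric(length(tips)), tips)
    for (p in placements) {
        w <- 1 + nonTripletPenalty * (p@signedLength %% 3L != 0L)
        affected <- unique(unlist(lapply(
            c(p@branches, p@lossBranches), function(b)
                descendantTips(tree, nodeNumber(tree, b)))))
        score[affected] <- score[affected] + w
    }
    ranking <- data.frame(gene_id = tips, score = as.numeric(score),
                          stringsAsFactors = FALSE)
    ranking <- ranking[order(ranking$score, ranking$gene_id), ]
    rownames(ranking) <- NULL
    subsets <- lapply(thresholds, function(t)
        ranking$gene_id[ranking$score <= t])
    names(subsets) <- as.character(thresholds)
    list(ranking = ranking, subsets = subsets)
}
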