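# Independent reference implementations used as oracles.  These are
# deliberately written from scratch (different structure, plain R) so they
# share no code with the package internals they check.

# plain three-state affine DP, no pruning; returns the optimal score
oracleAlignScore <- function(a, b, match = 2, mismatch = -3,
                             gapOpen = -5, gapExtend = -2,
                             mode = c("global", "semiglobal", "local")) {
    mode <- match.arg(mode)
    A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
    n <- length(A); m <- length(B)
    NEG <- -1e18
    M <- matrix(NEG, n + 1, m + 1)
    X <- matrix(NEG, n + 1, m + 1)   # gap in b
    Y <- matrix(NEG, n + 1, m + 1)   # gap in a
    free <- mode != "global"
    M[1, 1] <- 0
    for (i in 2:(n + 1)) {
        X[i, 1] <- if (free) 0 else gapOpen + (i - 1) * gapExtend
        if (mode == "local") M[i, 1] <- 0
    }
    for (j in 2:(m + 1)) {
        Y[1, j] <- if (free) 0 else gapOpen + (j - 1) * gapExtend
        if (mode == "local") M[1, j] <- 0
    }
    for (i in 2:(n + 1)) {
        for (j in 2:(m + 1)) {
            s <- if (A[i - 1] == B[j - 1]) match else mismatch
            M[i, j] <- s + max(M[i - 1, j - 1], X[i - 1, j - 1],
                               Y[i - 1, j - 1])
            if (mode == "local") M[i, j] <- max(M[i, j], 0)
            X[i, j] <- max(M[i - 1, j] + gapOpen + gapExtend,
                           X[i - 1, j] + gapExtend,
                           Y[i - 1, j] + gapOpen + gapExtend)
            Y[i, j] <- max(M[i, j - 1] + gapOpen + gapExtend,
                           X[i, j - 1] + gapOpen + gapExtend,
                           Y[i, j - 1] + gapExtend)
        }
    }
    if (mode == "global")
        return(max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1]))
    if (mode == "local")
        return(max(M, 0))
    best <- -Inf
    for (i in 1:(n + 1))
        best <- max(best, M[i, m + 1], X[i, m + 1], Y[i, m + 1])
    for (j in 1:(m + 1))
        best <- max(best, M[n + 1, j], X[n + 1, j], Y[n + 1, j])
    best
}

# re-score a returned pairwise alignment under the scheme it was made with
# (both-gap columns impossible in pairwise output)
rescoreAlignment <- function(pa) {
    s <- pa@params
    a <- strsplit(pa@alignedQuery, "")[[1]]
    b <- strsplit(pa@alignedTarget, "")[[1]]
    if (pa@mode != "global") {
        # trim free terminal gap columns
        gapcol <- a == "-" | b == "-"
        lead <- cumsum(!gapcol) == 0
        trail <- rev(cumsum(rev(!gapcol)) == 0)
        keep <- !(gapcol & (lead | trail))
        a <- a[keep]; b <- b[keep]
    }
    total <- 0
    both <- a != "-" & b != "-"
    total <- total + sum(a[both] == b[both]) * s$match +
        sum(a[both] != b[both]) * s$mismatch
    for (g in list(a == "-", b == "-")) {
        if (!any(g)) next
        r <- rle(g)
        total <- total + sum(r$values) * s$gapOpen +
            sum(r$lengths[r$values]) * s$gapExtend
    }
    total
}

randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# exhaustive minimum-change count for a binary character on a rooted tree;
# NA leaf states are unconstrained
bruteForceParsimony <- function(tree, states) {
    n <- ape::Ntip(tree)
    m <- tree$Nnode
    leafState <- states[tree$tip.label]
    freeLeaves <- which(is.na(leafState))
    best <- Inf
    for (mask in 0:(2^m - 1)) {
        internalState <- as.integer(intToBits(mask))[seq_len(m)]
        for (leafMask in 0:(2^length(freeLeaves) - 1)) {
            ls <- as.integer(leafState)
            if (length(freeLeaves))
                ls[freeLeaves] <-
                    as.integer(intToBits(leafMask))[seq_along(freeLeaves)]
            full <- c(ls, internalState)
            cost <- 0
            for (e in seq_len(nrow(tree$edge))) {
                p <- tree$edge[e, 1]; k <- tree$edge[e, 2]
                cost <- cost + (full[p] != full[k])
            }
            if (cost < best) best <- cost
            if (!length(freeLeaves)) break
        }
    }
    best
}

# exhaustive Sankoff over observed length states with unit cost per change
bruteForceSankoffLengths <- function(tree, leafLengths) {
    n <- ape::Ntip(tree)
    m <- tree$Nnode
    statesPool <- sort(unique(leafLengths))
    leaf <- leafLengths[tree$tip.label]
    grid <- expand.grid(rep(list(statesPool), m))
    best <- Inf; bestRoot <- NA
    for (g in seq_len(nrow(grid))) {
        full <- c(leaf, as.numeric(grid[g, ]))
        cost <- 0
        for (e in seq_len(nrow(tree$edge))) {
            p <- tree$edge[e, 1]; k <- tree$edge[e, 2]
            cost <- cost + (full[p] != full[k])
        }
        if (cost < best) { best <- cost; bestRoot <- full[n + 1] }
    }
    list(cost = best, root = bestRoot)
}

# mechanism classes as used throughout: intraexonic indel, boundary
# recruitment (exonization/pseudoexonization), whole-exon change, intron
# change
mechClass <- function(m) {
    if (m %in% c("intraexonic_insertion", "intraexonic_deletion",
                 "indeterminate_indel")) return("indel")
    if (m %in% c("exonization", "pseudoexonization")) return("recruit")
    if (m %in% c("exon_gain", "exon_loss", "indeterminate_exon_change"))
        return("exon")
    "intron"
}

# match simulated (true) events against detected placements, preferring
# exact exon index and branch agreement; returns per-true-event indices
matchEvents <- function(truth, det) {
    nT <- nrow(truth); nD <- nrow(det)
    usedD <- rep(FALSE, nD); match_j <- rep(NA_integer_, nT)
    tlen <- ifelse(truth$mechanism %in% c("intron_loss", "intron_gain"),
                   0L, truth$length_bp)
    crit <- list(
        function(i, j) det$exon_index[j] == truth$exon_index[i] &&
            det$branches[j] == truth$branch[i],
        function(i, j) abs(det$exon_index[j] - truth$exon_index[i]) <= 1 &&
            det$branches[j] == truth$branch[i],
        function(i, j) det$exon_index[j] == truth$exon_index[i],
        function(i, j) abs(det$exon_index[j] - truth$exon_index[i]) <= 2)
    for (cr in crit) {
        for (i in seq_len(nT)) {
            if (!is.na(match_j[i])) next
            for (j in seq_len(nD)) {
                if (usedD[j] || abs(det$signed_length[j]) != tlen[i]) next
                if (!cr(i, j)) next
                usedD[j] <- TRUE; match_j[i] <- j
                break
            }
        }
    }
    list(match_j = match_j, usedD = usedD, tlen = tlen)
}

# leaf-lengths-vs-root conservation: every leaf's per-block exon lengths
# equal the reconstructed root lengths plus the signed placed lengths on
# its root-to-leaf path
checkPathConservation <- function(res) {
    aln <- res$alignment; tree <- res$tree
    spans <- blockSpans(aln)
    det <- placementTable(res$placements)
    rootLab <- tree$node.label[1]
    root <- res$ancestral[[rootLab]]
    # root lengths in reference-block terms: recompute from block geometry
    for (leaf in tree$tip.label) {
        node <- match(leaf, tree$tip.label)
        # labels on the path root -> leaf
        path <- character()
        cur <- node
        while (cur != ape::Ntip(tree) + 1L) {
            path <- c(path, if (cur <= ape::Ntip(tree))
                tree$tip.label[cur] else tree$node.label[cur - ape::Ntip(tree)])
            cur <- tree$edge[tree$edge[, 2] == cur, 1]
        }
        for (k in seq_len(nrow(spans))) {
            cols <- spans[k, "start"]:spans[k, "end"]
            leafLen <- sum(alignmentMatrix(aln)[leaf, cols] != "-")
            eff <- 0L
            for (p in res$placements) {
                if (p@exonIndex != k) next
                if (p@mechanism %in% c("intron_gain", "intron_loss")) next
                if (any(p@branches %in% path)) eff <- eff + p@signedLength
                if (any(p@lossBranches %in% path)) eff <- eff - p@signedLength
            }
            rootBlockLen <- rootBlockLengths(res)[k]
            expect_equal(leafLen, rootBlockLen + eff,
                         info = sprintf("leaf %s exon block %d", leaf, k))
        }
    }
}

# reconstructed root lengths expressed per reference block (undoing the
# presentation-level splits/merges)
rootBlockLengths <- function(res) {
    aln <- res$alignment; tree <- res$tree
    spans <- blockSpans(aln)
    og <- outgroup(res$family)
    anchor <- if (length(og)) og[1] else tree$tip.label[1]
    node <- match(anchor, tree$tip.label)
    path <- character()
    cur <- node
    while (cur != ape::Ntip(tree) + 1L) {
        path <- c(path, if (cur <= ape::Ntip(tree)) tree$tip.label[cur]
                  else tree$node.label[cur - ape::Ntip(tree)])
        cur <- tree$edge[tree$edge[, 2] == cur, 1]
    }
    vapply(seq_len(nrow(spans)), function(k) {
        cols <- spans[k, "start"]:spans[k, "end"]
        leafLen <- sum(alignmentMatrix(aln)[anchor, cols] != "-")
        eff <- 0L
        for (p in res$placements) {
            if (p@exonIndex != k) next
            if (p@mechanism %in% c("intron_gain", "intron_loss")) next
            if (any(p@branches %in% path)) eff <- eff + p@signedLength
            if (any(p@lossBranches %in% path)) eff <- eff - p@signedLength
        }
        leafLen - eff
    }, integer(1))
}
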