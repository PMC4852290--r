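mkEvent <- function(carriers, gapRows, mechanism = "indeterminate_indel",
                    len = 3L, informative = NULL) {
    d <- list(polarityResolved = FALSE)
    if (!is.null(informative)) d$informativeRows <- informative
    exonEvo:::newEvent("ev", mechanism, 1L, len, c(1L, len),
                       carrierGenes = carriers, gapRows = gapRows,
                       evidence = "internal_gap", detail = d)
}

test_that("a clade-wide derived state maps to the stem branch", {
    tree <- ape::read.tree(
        text = "(outgroup:1,(Capsella:1,(Brassica:1,Arabidopsis:1)BA:1)ingroup:1)root;")
    ev <- mkEvent(carriers = "outgroup",
                  gapRows = "outgroup")   # gap in outgroup = insertion in clade
    pl <- mapEvent(tree, ev, outgroup = "outgroup")
    expect_identical(branches(pl), "ingroup")
    expect_identical(pl@mechanism, "intraexonic_insertion")
    expect_equal(pl@cost, 1)
    expect_setequal(pl@detail$derivedTips,
                    c("Capsella", "Brassica", "Arabidopsis"))
})

test_that("a single-leaf derived state maps to its terminal branch", {
    tree <- ape::read.tree(text = "(o:1,(a:1,(b:1,c:1)x:1)y:1)root;")
    ev <- mkEvent(carriers = "b", gapRows = "b")
    pl <- mapEvent(tree, ev, outgroup = "o")
    expect_identical(branches(pl), "b")
    expect_identical(pl@mechanism, "intraexonic_deletion")
})

test_that("disjoint carrier clades separated by non-carriers need two origins", {
    tree <- ape::read.tree(
        text = "((a:1,b:1)ab:1,((c:1,d:1)cd:1,(e:1,f:1)ef:1)x:1)root;")
    ev <- mkEvent(carriers = c("a", "e"), gapRows = c("a", "e"))
    pl <- mapEvent(tree, ev)
    expect_equal(pl@cost, 2)
    expect_setequal(branches(pl), c("a", "e"))
    # brute force agrees on the minimum
    states <- setNames(tree$tip.label %in% c("a", "e"), tree$tip.label)
    expect_equal(pl@cost, bruteForceParsimony(tree, states))
})

test_that("parsimony cost equals the exhaustive minimum on random trees", {
    set.seed(77)
    for (trial in 1:150) {
        n <- sample(6:8, 1)
        tree <- exonEvo:::ensureNodeLabels(ape::rtree(n))
        k <- sample(1:(n - 1), 1)
        carriers <- sample(tree$tip.label, k)
        ev <- mkEvent(carriers = carriers, gapRows = carriers)
        pl <- mapEvent(tree, ev)
        states <- setNames(tree$tip.label %in% carriers, tree$tip.label)
        oracleMin <- bruteForceParsimony(tree, states)
        expect_equal(pl@cost, oracleMin,
                     info = sprintf("trial %d", trial))
        # the derived set is the carriers or, when the carrier state is
        # reconstructed as ancestral, their complement
        other <- setdiff(tree$tip.label, carriers)
        expect_true(setequal(pl@detail$derivedTips, carriers) ||
                    setequal(pl@detail$derivedTips, other))
    }
})

test_that("carriers missing from the tree are an error", {
    tree <- ape::read.tree(text = "(a:1,b:1)r;")
    ev <- mkEvent(carriers = "zz", gapRows = "zz")
    expect_error(mapEvent(tree, ev), "zz")
})

test_that("adding a duplicate of a non-carrier leaf changes no placement", {
    tree <- ape::read.tree(text = "(o:1,(a:1,(b:1,c:1)x:1)y:1)r;")
    ev <- mkEvent(carriers = c("b", "c"), gapRows = c("b", "c"))
    before <- mapEvent(tree, ev, outgroup = "o")
    tree2 <- ape::read.tree(text = "(o:1,((a:1,a2:1)aa:1,(b:1,c:1)x:1)y:1)r;")
    after <- mapEvent(tree2, ev, outgroup = "o")
    expect_identical(branches(before), branches(after))
    expect_equal(before@cost, after@cost)
    expect_identical(before@mechanism, after@mechanism)
})

test_that("ancestral lengths are uniform when no events are placed", {
    fx <- emitFixture("capsella_nested_insertions")
    res <- runPipeline(pipelineConfig(fixture = "capsella_nested_insertions"))
    anc <- res$ancestral
    # exon 1 saw no events anywhere: identical at every internal node
    e1 <- vapply(anc, function(s) s@exonLengths[1], integer(1))
    expect_true(all(e1 == 185L))
})

test_that("a terminal-branch insertion leaves the root at the outgroup state", {
    # 4 leaves, one 3-bp insertion on terminal branch d; Sankoff oracle on
    # the observed lengths gives the same root length
    tree <- ape::read.tree(text = "((a:1,b:1)ab:1,(c:1,d:1)cd:1)root;")
    anc <- exonEvo:::fixtureAncestralState(c(30L, 30L), exonEvo:::lcgNew(5),
                                           intronLength = 50L,
                                           flankLength = 40L)
    ops <- exonEvo:::fixtureOp("V1", "d", "intraexonic_insertion", "exon",
                               2L, 2L, position = 10L, length_bp = 3L,
                               payload = "GCA")
    fx <- exonEvo:::buildFixture(anc, "((a:1,b:1)ab:1,(c:1,d:1)cd:1)root;",
                                 ops, outgroup = "a")
    aln <- markExonBoundaries(progressiveAlign(fx$family, fx$tree),
                              fx$family)
    aln <- refineExonByExon(aln, fx$family)
    det <- detectEvents(aln, fx$family)
    pl <- mapEvents(fx$tree, det$events, outgroup(fx$family))
    recon <- reconstructAncestralStructure(fx$tree, fx$family, pl, aln,
                                           outgroup = "a")
    expect_identical(recon[["root"]]@exonLengths, c(30L, 30L))
    expect_identical(recon[["cd"]]@exonLengths, c(30L, 30L))
    leafLens <- setNames(vapply(names(fx$family), function(id)
        exonLengths(fx$family[[id]])[2], integer(1)), names(fx$family))
    oracle <- bruteForceSankoffLengths(fx$tree, leafLens)
    expect_equal(recon[["root"]]@exonLengths[2], unname(oracle$root))
})

test_that("inconsistent placements raise an error naming the offending path", {
    tree <- exonEvo:::ensureNodeLabels(
        ape::read.tree(text = "(a:1,b:1)root;"))
    mat <- rbind(a = strsplit("AAACCC", "")[[1]],
                 b = strsplit("AAACCC", "")[[1]])
    fs <- FamilySet(list(GeneModel("a", "AAACCC"), GeneModel("b", "AAACCC")))
    aln <- markExonBoundaries(exonEvo:::newCodonAlignment(mat), fs)
    ghost <- new("EventPlacement",
        eventId = "ghost", branches = "a", lossBranches = character(),
        mechanism = "intraexonic_insertion", cost = 1, alternatives = list(),
        signedLength = 3L, exonIndex = 1L, detail = list())
    expect_error(
        reconstructAncestralStructure(tree, fs, list(ghost), aln,
                                      strict = TRUE),
        "disagrees")
})

test_that("divergence ranking weights frame-violating events and nests subsets", {
    tree <- exonEvo:::ensureNodeLabels(
        ape::read.tree(text = "((a:1,b:1)ab:1,(c:1,d:1)cd:1)root;"))
    fs <- FamilySet(lapply(c("a", "b", "c", "d"), function(i)
        GeneModel(i, "ATGTAA")))
    mk <- function(id, br, len, mech) new("EventPlacement", eventId = id,
        branches = br, lossBranches = character(), mechanism = mech,
        cost = 1, alternatives = list(),
        signedLength = len, exonIndex = 1L, detail = list())
    pl <- list(mk("p1", "a", 4L, "intraexonic_insertion"),     # frame-violating
               mk("p2", "c", 3L, "intraexonic_insertion"))     # frame-preserving
    rk <- rankStructuralDivergence(fs, pl, tree, thresholds = c(0, 1, 10))
    ranking <- rk$ranking
    expect_equal(ranking$score[ranking$gene_id == "a"], 3)  # 1 + 2 penalty
    expect_equal(ranking$score[ranking$gene_id == "c"], 1)
    expect_equal(ranking$score[ranking$gene_id == "b"], 0)
    # zero-event genes rank first and survive every threshold
    expect_setequal(rk$subsets[["0"]], c("b", "d"))
    expect_setequal(rk$subsets[["1"]], c("b", "d", "c"))
    expect_setequal(rk$subsets[["10"]], c("a", "b", "c", "d"))
    # subsets are nested
    expect_true(all(rk$subsets[["0"]] %in% rk$subsets[["1"]]))
    expect_true(all(rk$subsets[["1"]] %in% rk$subsets[["10"]]))
})
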