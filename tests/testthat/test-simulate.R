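test_that("identical configuration and seed give byte-identical families", {
    a <- simulateFamily(simConfig(seed = 9))
    b <- simulateFamily(simConfig(seed = 9))
    expect_identical(ledger(a$history), ledger(b$history))
    expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
    for (id in names(a$family)) {
        expect_identical(as.character(cdsSeq(a$family[[id]])),
                         as.character(cdsSeq(b$family[[id]])))
        expect_identical(as.character(flank3(a$family[[id]])),
                         as.character(flank3(b$family[[id]])))
    }
    c <- simulateFamily(simConfig(seed = 10))
    expect_false(identical(as.character(cdsSeq(a$family[[1]])),
                           as.character(cdsSeq(c$family[[1]]))))
})

test_that("zero event rates leave every leaf with the ancestral structure", {
    cfg <- simConfig(seed = 4, eventRates = c(intraexonic_indel = 0,
                                              exonization = 0,
                                              pseudoexonization = 0,
                                              intron_loss = 0,
                                              intron_gain = 0,
                                              exon_gain = 0, exon_loss = 0))
    sim <- simulateFamily(cfg)
    expect_equal(nrow(structuralLedger(ledger(sim$history))), 0)
    for (id in names(sim$family))
        expect_identical(exonLengths(sim$family[[id]]),
                         cfg@ancestralExonLengths)
})

test_that("a forced insertion lengthens exactly its target exon", {
    anc <- exonEvo:::ancestralState(c(30L, 60L, 30L), 50L, 40L)
    op <- list(mechanism = "intraexonic_insertion", seg_type = "exon",
               seg_index = 2L, side = NA_integer_, position = 10L,
               length_bp = 3L, payload = "GCA")
    after <- exonEvo:::applyOp(anc, op)
    expect_equal(nchar(after$exonSeqs), c(30L, 63L, 30L))
    expect_equal(nchar(exonEvo:::stateCds(after)), 123L)
})

test_that("ledger replay reproduces every leaf byte for byte", {
    for (seed in c(13, 14)) {
        sim <- simulateFamily(simConfig(seed = seed))
        leaves <- replayHistory(sim$history)
        for (id in names(sim$family)) {
            expect_identical(as.character(cdsSeq(leaves[[id]])),
                             as.character(cdsSeq(sim$family[[id]])),
                             info = sprintf("seed %d %s", seed, id))
            expect_identical(as.character(intronSeqs(leaves[[id]])),
                             as.character(intronSeqs(sim$family[[id]])))
            expect_identical(exonLengths(leaves[[id]]),
                             exonLengths(sim$family[[id]]))
        }
    }
})

test_that("leaf exon lengths equal ancestral lengths plus signed path events", {
    for (seed in c(15, 16, 17)) {
        sim <- simulateFamily(simConfig(seed = seed))
        led <- structuralLedger(ledger(sim$history))
        tree <- sim$tree
        anc <- exonLengths(snapshots(sim$history)[[sim$history@ancestorId]])
        for (leaf in tree$tip.label) {
            # node labels on the root -> leaf path
            path <- character(); cur <- match(leaf, tree$tip.label)
            while (cur != ape::Ntip(tree) + 1L) {
                path <- c(path, if (cur <= ape::Ntip(tree))
                    tree$tip.label[cur]
                    else tree$node.label[cur - ape::Ntip(tree)])
                cur <- tree$edge[tree$edge[, 2] == cur, 1]
            }
            sub <- led[led$branch %in% path, , drop = FALSE]
            expected <- sum(anc)
            for (i in seq_len(nrow(sub))) {
                m <- sub$mechanism[i]; L <- sub$length_bp[i]
                expected <- expected + switch(m,
                    intraexonic_insertion = L, exonization = L,
                    exon_gain = L,
                    intraexonic_deletion = -L, pseudoexonization = -L,
                    exon_loss = -L, 0L)
            }
            expect_equal(sum(exonLengths(sim$family[[leaf]])), expected,
                         info = sprintf("seed %d leaf %s", seed, leaf))
        }
    }
})

test_that("the non-triplet indel fraction converges to 1 - pFrame", {
    lens <- integer()
    for (seed in 101:130) {
        sim <- simulateFamily(simConfig(seed = seed))
        led <- structuralLedger(ledger(sim$history))
        lens <- c(lens, led$length_bp[led$mechanism %in%
            c("intraexonic_insertion", "intraexonic_deletion")])
    }
    n <- length(lens)
    expect_gt(n, 30)
    obs <- mean(lens %% 3L != 0L)
    p <- 0.1
    expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("the simulated event count tracks the branch-length-weighted expectation", {
    counts <- integer(); expects <- numeric()
    rates <- simConfig()@eventRates
    for (seed in 201:240) {
        sim <- simulateFamily(simConfig(seed = seed))
        counts <- c(counts, nrow(structuralLedger(ledger(sim$history))))
        tree <- sim$tree
        og <- match("outgroup", tree$tip.label)
        keep <- tree$edge[, 2] != og
        expects <- c(expects, sum(tree$edge.length[keep]) * sum(rates))
    }
    lambda <- mean(expects)
    se <- sqrt(lambda / length(counts))
    expect_lt(abs(mean(counts) - lambda), 3 * se + 0.25 * lambda * 0.2)
})

test_that("excessive event rates abort with guidance", {
    cfg <- simConfig(seed = 2,
                     eventRates = c(intraexonic_indel = 0,
                                    exonization = 4000,
                                    pseudoexonization = 4000,
                                    intron_loss = 2000, intron_gain = 0,
                                    exon_gain = 0, exon_loss = 0))
    expect_error(simulateFamily(cfg), "lower the per-branch event rates")
})

test_that("fixtures are deterministic, well-formed, and replayable", {
    valid <- c("brassicaceae_intron_loss", "paleoAP1_stop_loss",
               "euAP1_frameshift", "capsella_nested_insertions",
               "flc_exon3", "flc_exon_loss")
    expect_error(emitFixture("nope"), "brassicaceae_intron_loss")
    for (name in valid) {
        fx1 <- emitFixture(name); fx2 <- emitFixture(name)
        for (id in names(fx1$family))
            expect_identical(as.character(cdsSeq(fx1$family[[id]])),
                             as.character(cdsSeq(fx2$family[[id]])),
                             info = name)
        leaves <- replayHistory(fx1$history)
        for (id in names(fx1$family)) {
            expect_identical(as.character(cdsSeq(leaves[[id]])),
                             as.character(cdsSeq(fx1$family[[id]])),
                             info = paste(name, id))
            expect_identical(exonLengths(leaves[[id]]),
                             exonLengths(fx1$family[[id]]))
        }
    }
    # the intron-loss fixture pairs an 8-exon gene with a 7-exon twin CDS
    fx <- emitFixture("brassicaceae_intron_loss")
    counts <- sort(vapply(models(fx$family), function(m)
        length(exonLengths(m)), integer(1)))
    expect_identical(unname(counts), c(7L, 8L))
    cds <- vapply(models(fx$family), function(m)
        as.character(cdsSeq(m)), character(1))
    expect_identical(unname(cds[1]), unname(cds[2]))
    # the nested-insertion fixture stacks 33 + 66 bp in exon 7
    fx2 <- emitFixture("capsella_nested_insertions")
    e7 <- vapply(models(fx2$family), function(m) exonLengths(m)[7],
                 integer(1))
    expect_equal(unname(sort(e7)), c(137L, 170L, 170L, 236L))
})
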