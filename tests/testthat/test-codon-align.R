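test_that("protein projection expands residues to codons and appends the stop", {
    # forced gap expansion
    aln <- projectProteinAlignment(c(r1 = "MK-", r2 = "M-K"),
                                   c(r1 = "ATGAAA", r2 = "ATGAAG"))
    rows <- degappedRows(aln)
    mat <- alignmentMatrix(aln)
    expect_identical(paste(mat["r1", ], collapse = ""), "ATGAAA---")
    expect_identical(paste(mat["r2", ], collapse = ""), "ATG---AAG")
    expect_equal(dim(aln)[2] %% 3, 0)
    # trailing stop codon is tolerated and appended ungapped
    cds <- "ATGAAACCCGGGACGTAA"   # 5 codons + TAA
    aln2 <- projectProteinAlignment(c(a = "MKPGT", b = "MKPGT"),
                                    c(a = cds, b = substr(cds, 1, 15)))
    expect_identical(degappedRows(aln2)[["a"]], cds)
    expect_equal(ncol(alignmentMatrix(aln2)), 18)
})

test_that("projection rejects malformed guides and translation mismatches", {
    expect_error(projectProteinAlignment(c(r1 = "MK", r2 = "M-K"),
                                         c(r1 = "ATGAAA", r2 = "ATGAAA")),
                 "unequal")
    expect_error(projectProteinAlignment(c(r1 = "MQ"),
                                         c(r1 = "ATGAAA")),
                 "translates")
})

test_that("exon boundaries map through the column map", {
    gm1 <- GeneModel("single", "ATGAAACCCTAA")
    gm0 <- GeneModel("two", "ATGAAACCCGGGTAA", exonLengths = c(9, 6))
    fs <- FamilySet(list(gm0, gm1))
    # ungapped: boundary after column 9
    mat <- rbind(two = strsplit("ATGAAACCCGGGTAA", "")[[1]])
    aln <- exonEvo:::newCodonAlignment(mat)
    aln <- markExonBoundaries(aln, fs)
    expect_identical(boundaryColumns(aln)[["two"]], 9L)
    # a 3-column gap before CDS position 9 shifts the boundary to column 12
    mat2 <- rbind(two = strsplit("ATGAA---ACCCGGGTAA", "")[[1]])
    aln2 <- markExonBoundaries(exonEvo:::newCodonAlignment(mat2), fs)
    expect_identical(boundaryColumns(aln2)[["two"]], 12L)
    # single-exon and unannotated rows carry empty boundary lists
    mat3 <- rbind(single = strsplit("ATGAAACCCTAA", "")[[1]])
    aln3 <- markExonBoundaries(exonEvo:::newCodonAlignment(mat3), fs)
    expect_length(boundaryColumns(aln3)[["single"]], 0)
})

test_that("de-gapping any row reproduces the CDS at every pipeline stage", {
    sim <- simulateFamily(simConfig(seed = 31))
    fs <- sim$family
    aln <- progressiveAlign(fs, sim$tree)
    for (stage in 1:3) {
        rows <- degappedRows(aln)
        for (id in names(fs))
            expect_identical(rows[[id]], as.character(cdsSeq(fs[[id]])),
                             info = sprintf("stage %d row %s", stage, id))
        if (stage == 1) aln <- markExonBoundaries(aln, fs)
        if (stage == 2) aln <- refineExonByExon(aln, fs)
    }
})

test_that("refinement left-aligns tied gap runs and never lowers the score", {
    # a 3-column gap scores equally at either end of the homopolymer run
    mat <- rbind(a = strsplit("CCAAAAAATT", "")[[1]],
                 b = strsplit("CC---AAATT", "")[[1]])
    gmA <- GeneModel("a", "CCAAAAAATT")
    gmB <- GeneModel("b", "CCAAATT")
    fs <- FamilySet(list(gmA, gmB))
    aln <- markExonBoundaries(exonEvo:::newCodonAlignment(mat), fs)
    before <- exonEvo:::spScore(alignmentMatrix(aln))
    out <- refineExonByExon(aln, fs)
    expect_identical(paste(alignmentMatrix(out)["b", ], collapse = ""),
                     "CC---AAATT")
    expect_gte(exonEvo:::spScore(alignmentMatrix(out)), before)
    # identical rows stay untouched
    mat2 <- rbind(a = strsplit("ACGTACGT", "")[[1]],
                  b = strsplit("ACGTACGT", "")[[1]])
    fs2 <- FamilySet(list(GeneModel("a", "ACGTACGT"),
                          GeneModel("b", "ACGTACGT")))
    out2 <- refineExonByExon(
        markExonBoundaries(exonEvo:::newCodonAlignment(mat2), fs2), fs2)
    expect_identical(alignmentMatrix(out2), mat2)
})

test_that("refinement is a non-decreasing sum-of-pairs operation on families", {
    for (seed in c(41, 42)) {
        sim <- simulateFamily(simConfig(seed = seed))
        aln <- markExonBoundaries(progressiveAlign(sim$family, sim$tree),
                                  sim$family)
        before <- exonEvo:::spScore(alignmentMatrix(aln))
        after <- exonEvo:::spScore(alignmentMatrix(
            refineExonByExon(aln, sim$family)))
        expect_gte(after, before)
    }
})

test_that("masking covers gappy columns, frameshift tails and overlapping events", {
    mat <- do.call(rbind, c(
        lapply(1:9, function(i) strsplit("ACG-ACGT", "")[[1]]),
        list(strsplit("ACGTACGT", "")[[1]])))
    rownames(mat) <- paste0("r", 1:10)
    aln <- exonEvo:::newCodonAlignment(mat)
    out <- maskNonhomologousColumns(aln, list())
    expect_true(columnMask(out)[4])
    expect_identical(maskReasons(out)[4], "gap_fraction")
    expect_equal(sum(columnMask(out)), 1)
    # no events, no gappy columns -> nothing masked
    clean <- exonEvo:::newCodonAlignment(
        rbind(a = strsplit("ACGT", "")[[1]], b = strsplit("ACGT", "")[[1]]))
    expect_equal(sum(columnMask(maskNonhomologousColumns(clean, list()))), 0)
    # overlapping events of different origin mask their shared columns
    ev1 <- exonEvo:::newEvent("e1", "exonization", 1L, 6L, c(10L, 15L),
                              carrierGenes = "a", evidence = "boundary_gap_noncoding_alignable")
    ev2 <- exonEvo:::newEvent("e2", "exonization", 1L, 6L, c(13L, 18L),
                              carrierGenes = "b", evidence = "boundary_gap_noncoding_alignable")
    wide <- exonEvo:::newCodonAlignment(
        rbind(a = rep("A", 30), b = rep("A", 30)))
    out2 <- maskNonhomologousColumns(wide, list(ev1, ev2))
    expect_true(all(columnMask(out2)[13:15]))
    expect_identical(unique(maskReasons(out2)[13:15]), "independent_events")
    # an unrepaired frameshift masks downstream columns of the carrier span
    fsEv <- exonEvo:::newEvent("e3", "intraexonic_deletion", 1L, 1L,
                               c(5L, 5L), carrierGenes = "a",
                               evidence = "internal_gap")
    out3 <- maskNonhomologousColumns(wide, list(fsEv))
    expect_true(all(columnMask(out3)[6:30]))
    expect_identical(unique(maskReasons(out3)[6:30]), "frameshift_downstream")
})
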