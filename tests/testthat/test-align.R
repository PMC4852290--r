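test_that("pairwise DP matches the reference affine-gap oracle exactly on short sequences", {
    set.seed(101)
    schemes <- list(alignDefaults(),
                    list(match = 1, mismatch = 0, gapOpen = -10,
                         gapExtend = -0.5))
    for (trial in 1:120) {
        a <- randomSeq(sample(1:20, 1))
        b <- randomSeq(sample(1:20, 1))
        sch <- schemes[[1 + trial %% 2]]
        for (mode in c("global", "semiglobal", "local")) {
            pa <- alignPair(a, b, mode = mode, scheme = sch)
            expect_identical(pa@score,
                             oracleAlignScore(a, b, sch$match, sch$mismatch,
                                              sch$gapOpen, sch$gapExtend,
                                              mode),
                             info = sprintf("%s: %s vs %s", mode, a, b))
            # the reported alignment is valid and reproduces its own score
            if (mode == "local") {
                # local alignments return the optimal block only
                expect_true(grepl(gsub("-", "", pa@alignedQuery), a,
                                  fixed = TRUE))
                expect_true(grepl(gsub("-", "", pa@alignedTarget), b,
                                  fixed = TRUE))
            } else {
                expect_identical(gsub("-", "", pa@alignedQuery), a)
                expect_identical(gsub("-", "", pa@alignedTarget), b)
                expect_equal(rescoreAlignment(pa), pa@score)
            }
        }
    }
})

test_that("global DP score agrees with Biostrings pairwiseAlignment", {
    set.seed(7)
    submat <- matrix(-3, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                               c("A", "C", "G", "T")))
    diag(submat) <- 2
    for (i in 1:25) {
        a <- randomSeq(sample(5:40, 1)); b <- randomSeq(sample(5:40, 1))
        mine <- alignPair(a, b, mode = "global")@score
        ref <- Biostrings::pairwiseAlignment(
            a, b, type = "global", substitutionMatrix = submat,
            gapOpening = 5, gapExtension = 2, scoreOnly = TRUE)
        expect_equal(mine, ref, info = paste(a, b))
    }
})

test_that("identical sequences align gap-free with full identity", {
    pa <- alignPair("ACGTACGTACGT", "ACGTACGTACGT", mode = "semiglobal")
    expect_equal(pa@score, 24)
    expect_equal(pa@identity, 1)
    expect_false(grepl("-", pa@alignedQuery, fixed = TRUE))
})

test_that("local mode recovers a perfect sub-block", {
    pa <- alignPair("ACGTACGT", "ACGTTTTTACGT", mode = "local")
    expect_gte(nchar(pa@alignedQuery), 4)
    expect_equal(pa@identity, 1)
})

test_that("empty input is rejected", {
    expect_error(alignPair("", "ACGT"), "empty")
})

test_that("identity excludes terminal gap columns but counts interior gaps", {
    pa <- alignPair("AAAATTTT", "TTTT", mode = "semiglobal")
    # leading gap columns excluded; the aligned TTTT block matches fully
    expect_equal(pa@identity, 1)
    pa2 <- alignPair("AAAGGTTT", "AAATTT", mode = "global")
    # interior 2-gap counts as non-matching columns: 6 matches / 8 columns
    expect_equal(pa2@identity, 6 / 8)
})

test_that("deduplication identity equals the oracle-scored optimum on short CDSs", {
    set.seed(33)
    sch <- list(match = 1, mismatch = 0, gapOpen = -10, gapExtend = -0.5)
    for (i in 1:40) {
        a <- randomSeq(sample(5:30, 1)); b <- randomSeq(sample(5:30, 1))
        pa <- alignPair(a, b, mode = "global", scheme = sch)
        expect_identical(pa@score,
                         oracleAlignScore(a, b, 1, 0, -10, -0.5, "global"))
        idty <- cdsIdentity(a, b)
        expect_true(is.nan(idty) || (idty >= 0 && idty <= 1))
    }
})

test_that("a sequence with no shared k-mers is not alignable", {
    set.seed(5)
    q <- randomSeq(40)
    expect_true(isTRUE(isAlignable(q, paste0(randomSeq(60), q, randomSeq(60)))))
    # an A/C-only query against its reverse complement (G/T-only) shares
    # no k-mer of any length
    q2 <- paste(sample(c("A", "C"), 30, replace = TRUE), collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(q2)))
    expect_false(isTRUE(isAlignable(q2, rc)))
})

test_that("noncoding scan recovers a planted exon and ignores noise", {
    set.seed(11)
    exon <- randomSeq(100)
    background <- paste0(randomSeq(50000), exon, randomSeq(10000))
    hit <- scanNoncodingForHomolog(exon, background)
    expect_false(is.null(hit))
    expect_equal(hit$offset, 50001)
    expect_equal(hit$identity, 1)
    expect_null(scanNoncodingForHomolog(randomSeq(100), randomSeq(10000)))
    expect_null(scanNoncodingForHomolog(randomSeq(100), ""))
    expect_warning(
        scanNoncodingForHomolog(exon, paste0(randomSeq(2000), exon),
                                maxSpan = 1000L),
        "truncated")
})
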