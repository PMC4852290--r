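# small handmade alignments exercising the classifiers directly

mkAln <- function(rows, fs = NULL) {
    mat <- do.call(rbind, lapply(rows, function(s) strsplit(s, "")[[1]]))
    rownames(mat) <- names(rows)
    aln <- exonEvo:::newCodonAlignment(mat)
    if (!is.null(fs)) aln <- markExonBoundaries(aln, fs)
    aln
}

test_that("interior gap runs become one indel event per signature group", {
    rows <- c(a = "ACGTACGTACGTACGTACGTACGT",
              b = "ACGTACGT---TACGTACGTACGT",
              c = "ACGTACGTACGTACGTACGTACGT",
              d = "ACGTACGTACGTACGTACGTACGT",
              e = "ACGTACGTACGTACGTACGTACGT")
    det <- detectInternalIndels(mkAln(rows))
    expect_length(det$events, 1)
    ev <- det$events[[1]]
    expect_equal(lengthBp(ev), 3L)
    expect_true(framePreserving(ev))
    expect_identical(carrierGenes(ev), "b")
    # two rows sharing an identical run group into one event with 2 carriers
    rows2 <- c(a = "ACGTACGTACGTACGTACGTACGT",
               b = "ACGTAC------GTACGTACGTAC",
               c = "ACGTAC------GTACGTACGTAC",
               d = "ACGTACGTACGTACGTACGTACGT")
    det2 <- detectInternalIndels(mkAln(rows2))
    expect_length(det2$events, 1)
    expect_setequal(carrierGenes(det2$events[[1]]), c("b", "c"))
    expect_equal(lengthBp(det2$events[[1]]), 6L)
    # a 4-column run is frame-violating
    rows3 <- c(a = "ACGTACGTACGTACGTACGT",
               b = "ACGTACG----TACGTACGT")
    det3 <- detectInternalIndels(mkAln(rows3))
    expect_false(framePreserving(det3$events[[1]]))
})

test_that("nested gap signatures resolve into separate stacked events", {
    # b,c,d share a 6-bp insertion relative to a; d carries a second,
    # adjacent 6-bp insertion of its own -> two stacked signature runs
    rows <- c(a = "AAACCC------------ACGTACGTAAA",
              b = "AAACCCGGGCGG------ACGTACGTAAA",
              c = "AAACCCGGGCGG------ACGTACGTAAA",
              d = "AAACCCGGGCGGTTTCTGACGTACGTAAA")
    det <- detectInternalIndels(mkAln(rows))
    expect_length(det$events, 2)
    lens <- vapply(det$events, lengthBp, integer(1))
    expect_identical(sort(lens), c(6L, 6L))
    gaps <- lapply(det$events, function(e) sort(e@gapRows))
    expect_true(any(vapply(gaps, identical, logical(1), "a")))
    expect_true(any(vapply(gaps, identical, logical(1), c("a", "b", "c"))))
})

test_that("more than hotspotMax interleaved signatures flag an indel hotspot", {
    rows <- c(a = "AAAA---CCC---GGG---TTTTAAAACCCC",
              b = "AAAACCC---GGG------TTTTAAAACCCC",
              c = "AAAA------GGGCCCTTTTTTTAAAACCCC",
              d = "AAAACCCCCCGGGCCCTTTTTTTAAAACCCC")
    det <- detectInternalIndels(mkAln(rows), hotspotMax = 2L)
    expect_gte(length(det$hotspots), 1)
})

test_that("intron change calls require a perfect two-exon match at the junction", {
    fx <- emitFixture("brassicaceae_intron_loss")
    A <- fx$family[["SEP1_other"]]; B <- fx$family[["SEP12_brassicaceae"]]
    ev <- detectIntronChange(A, B)
    expect_length(ev, 1)
    expect_identical(mechanism(ev[[1]]), "intron_loss")
    expect_equal(exonIndex(ev[[1]]), 5L)
    expect_equal(lengthBp(ev[[1]]), 0L)
    expect_equal(ev[[1]]@detail$mergedExonLength, 84L)
    expect_identical(evidence(ev[[1]]), "exon_merge")
    # symmetric in the argument order, with mirrored polarity bookkeeping
    ev2 <- detectIntronChange(B, A)
    expect_equal(ev2[[1]]@detail$mergedExonLength, 84L)
    expect_equal(exonIndex(ev2[[1]]), 5L)
    # identical structures yield no events
    expect_length(detectIntronChange(A, A), 0)
    # clustered mismatches in one half defeat the per-segment threshold
    Bm <- B
    cds <- as.character(cdsSeq(B))
    off <- cumsum(exonLengths(B))
    # corrupt 10 bases inside the first half of the merged exon (exon 5)
    s <- off[4] + 2L
    for (p in s:(s + 9L)) {
        cur <- substr(cds, p, p)
        substr(cds, p, p) <- setdiff(c("A", "C", "G", "T"), cur)[1]
    }
    Bm@cds <- Biostrings::DNAString(cds)
    expect_length(detectIntronChange(A, Bm), 0)
    # both genes need structural annotation
    expect_error(detectIntronChange(GeneModel("x", "ATGTAA"), B),
                 "annotation required")
})

test_that("stop-codon readthrough is classified as terminal exonization", {
    fx <- emitFixture("paleoAP1_stop_loss")
    ev <- detectStopCodonEvents(fx$family[["paleoAP1_gene"]],
                                fx$family[["ancestral_like"]])
    expect_length(ev, 1)
    expect_identical(mechanism(ev[[1]]), "exonization")
    expect_equal(lengthBp(ev[[1]]), 15L)
    expect_identical(evidence(ev[[1]]), "stop_codon_change")
    # identical terminal exons produce nothing
    none <- detectStopCodonEvents(fx$family[["ancestral_like"]],
                                  fx$family[["ancestral_like"]])
    expect_length(none, 0)
})

test_that("a frameshifting deletion links to the pseudoexonized tail", {
    fx <- emitFixture("euAP1_frameshift")
    ev <- detectStopCodonEvents(fx$family[["euAP1_gene"]],
                                fx$family[["ancestral_like"]])
    mech <- vapply(ev, mechanism, character(1))
    expect_setequal(mech, c("indeterminate_indel", "pseudoexonization"))
    indel <- ev[[which(mech == "indeterminate_indel")]]
    pseudo <- ev[[which(mech == "pseudoexonization")]]
    expect_equal(lengthBp(indel), 1L)
    expect_false(framePreserving(indel))
    expect_equal(lengthBp(pseudo), 8L)
    expect_identical(pseudo@detail$linkedIndel, eventId(indel))
})

test_that("an unterminated ORF is a hard error", {
    gm <- GeneModel("noStop", strrep("GCA", 40), exonLengths = c(60L, 60L),
                    flank3 = strrep("GCA", 70))
    expect_error(detectStopCodonEvents(gm, gm), "unterminated ORF")
})

test_that("every gap column is attributed to an event, hotspot or mask", {
    for (seed in c(51, 52, 53)) {
        res <- runPipeline(pipelineConfig(simulate = simConfig(seed = seed)))
        aln <- res$alignment
        mat <- alignmentMatrix(aln)
        gapCols <- which(colSums(mat == "-") > 0 & colSums(mat != "-") > 0)
        covered <- rep(FALSE, ncol(mat))
        for (e in res$events) {
            sp <- e@columnSpan
            if (!anyNA(sp)) covered[sp[1]:sp[2]] <- TRUE
        }
        for (h in res$hotspots) covered[h$start:h$end] <- TRUE
        covered[columnMask(aln)] <- TRUE
        expect_true(all(covered[gapCols]),
                    info = sprintf("seed %d: unattributed gap columns", seed))
    }
})

test_that("emitted events satisfy the frame-flag invariant", {
    for (seed in c(51, 52)) {
        res <- runPipeline(pipelineConfig(simulate = simConfig(seed = seed)))
        for (e in res$events)
            expect_identical(framePreserving(e), lengthBp(e) %% 3L == 0L)
    }
})
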