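test_that("a consistent two-exon gene model validates by construction", {
    gm <- GeneModel("toy", "ATGAAACCCGGGTAA", exonLengths = c(9, 6))
    expect_s4_class(gm, "GeneModel")
    expect_identical(exonLengths(gm), c(9L, 6L))
    expect_identical(as.character(exonSeqs(gm)),
                     c("ATGAAACCC", "GGGTAA"))
})

test_that("exon lengths must sum to the CDS length", {
    expect_error(GeneModel("bad", "ATGAAACCCGGGTAA", exonLengths = c(9, 5)),
                 "sum\\(exonLengths\\)")
})

test_that("family sets round-trip through FASTA + GFF3 byte for byte", {
    set.seed(21)
    sim <- simulateFamily(simConfig(seed = 21))
    fs <- sim$family
    dir <- tempfile()
    writeFamilySet(fs, dir, prefix = "rt")
    fs2 <- loadGeneModels(file.path(dir, "rt_cds.fasta"),
                          annotation = file.path(dir, "rt.gff3"),
                          genomicFasta = file.path(dir, "rt_genomic.fasta"))
    expect_setequal(names(fs2), names(fs))
    for (id in names(fs)) {
        expect_identical(as.character(cdsSeq(fs2[[id]])),
                         as.character(cdsSeq(fs[[id]])), info = id)
        expect_identical(exonLengths(fs2[[id]]), exonLengths(fs[[id]]),
                         info = id)
        expect_identical(as.character(intronSeqs(fs2[[id]])),
                         as.character(intronSeqs(fs[[id]])), info = id)
        expect_identical(as.character(flank3(fs2[[id]])),
                         as.character(flank3(fs[[id]])), info = id)
    }
})

test_that("minus-strand exon extraction agrees with a reverse-complement oracle", {
    set.seed(3)
    ex1 <- randomSeq(9); ex2 <- randomSeq(6); intron <- randomSeq(20)
    # plus-strand layout of the minus-strand gene: revcomp everything
    rc <- function(s) as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(s)))
    genomic <- paste0(randomSeq(10), rc(ex2), rc(intron), rc(ex1),
                      randomSeq(10))
    # exon1 (transcript order) sits at plus coords 37..45, exon2 at 11..16
    gff <- c("##gff-version 3",
             sprintf("chr1\ttest\tCDS\t%d\t%d\t.\t-\t.\tID=g.c1;Parent=g", 37, 45),
             sprintf("chr1\ttest\tCDS\t%d\t%d\t.\t-\t.\tID=g.c2;Parent=g", 11, 16))
    gffPath <- tempfile(fileext = ".gff3")
    writeLines(gff, gffPath)
    fa <- tempfile(fileext = ".fa"); cdsPath <- tempfile(fileext = ".fa")
    writeLines(c(">chr1", genomic), fa)
    writeLines(c(">g", paste0(ex1, ex2)), cdsPath)
    fs <- loadGeneModels(cdsPath, gffPath, fa, flankLength = 5L)
    gm <- fs[["g"]]
    expect_true(isAnnotated(gm))
    expect_identical(exonLengths(gm), c(9L, 6L))
    expect_identical(as.character(intronSeqs(gm))[[1]], intron)
})

test_that("a CDS/exon mismatch is reported, never silently dropped", {
    dir <- tempfile(); dir.create(dir)
    genomic <- paste0("AAAA", "ATGAAACCC", "GGGG", "GGGTAA", "TTTT")
    writeLines(c(">chr1", genomic), file.path(dir, "g.fa"))
    writeLines(c("##gff-version 3",
                 "chr1\tt\tCDS\t5\t13\t.\t+\t.\tParent=g1",
                 "chr1\tt\tCDS\t18\t23\t.\t+\t.\tParent=g1"),
               file.path(dir, "a.gff3"))
    writeLines(c(">g1", "ATGAAACCCGGGTAC"), file.path(dir, "cds.fa"))
    fs <- loadGeneModels(file.path(dir, "cds.fa"), file.path(dir, "a.gff3"),
                         file.path(dir, "g.fa"))
    expect_true("g1" %in% names(fs))
    expect_false(isAnnotated(fs[["g1"]]))
    expect_true(any(grepl("CDS mismatch", provenance(fs)$reason)))
})

test_that("an annotated gene without sequence is a hard error naming the id", {
    dir <- tempfile(); dir.create(dir)
    writeLines(c(">chrX", "ACGTACGTACGT"), file.path(dir, "g.fa"))
    writeLines(c("##gff-version 3",
                 "chr1\tt\tCDS\t1\t6\t.\t+\t.\tParent=lost"),
               file.path(dir, "a.gff3"))
    writeLines(c(">lost", "ACGTAA"), file.path(dir, "cds.fa"))
    expect_error(loadGeneModels(file.path(dir, "cds.fa"),
                                file.path(dir, "a.gff3"),
                                file.path(dir, "g.fa")),
                 "lost")
})

test_that("short CDSs are excluded and same-species near-duplicates collapse to one", {
    set.seed(17)
    base <- randomSeq(500)
    mutate <- function(s, n) {
        pos <- sample(nchar(s), n)
        for (p in pos) substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                                         substr(s, p, p)), 1)
        s
    }
    fs <- FamilySet(list(
        GeneModel("shorty", randomSeq(399), speciesId = "spA"),
        GeneModel("a1", base, speciesId = "spA"),
        GeneModel("a2", mutate(base, 15), speciesId = "spA"),   # ~97% identical
        GeneModel("b1", mutate(base, 15), speciesId = "spB"),
        GeneModel("c1", mutate(base, 150), speciesId = "spA"))) # ~70% identical
    out <- filterModels(fs)
    expect_false("shorty" %in% names(out))
    # exactly one of the spA near-identical pair survives
    expect_equal(sum(c("a1", "a2") %in% names(out)), 1L)
    # a different-species near-duplicate and a diverged same-species gene stay
    expect_true(all(c("b1", "c1") %in% names(out)))
    expect_true(any(grepl("redundant", provenance(out)$reason)))
    # idempotence
    again <- filterModels(out)
    expect_setequal(names(again), names(out))
    # removing everything warns rather than errors
    tiny <- FamilySet(list(GeneModel("t", randomSeq(100))))
    expect_warning(filterModels(tiny), "every gene model")
})

test_that("transcript selection minimises structural divergence with documented tie-breaks", {
    fx <- emitFixture("brassicaceae_intron_loss")
    ref <- FamilySet(list(fx$family[["SEP1_other"]]))
    isoA <- fx$family[["SEP1_other"]]        # structurally identical
    isoB <- fx$family[["SEP12_brassicaceae"]] # one intron-change event
    isoA@geneId <- "isoA"; isoB@geneId <- "isoB"
    expect_identical(geneId(selectTranscript(list(isoA, isoB), ref)), "isoA")
    # single isoform returns itself
    expect_identical(geneId(selectTranscript(list(isoB), ref)), "isoB")
    # tie on event count broken by smaller total event length
    anc <- as.character(cdsSeq(fx$family[["SEP1_other"]]))
    del <- function(s, at, n) paste0(substr(s, 1, at - 1),
                                     substr(s, at + n, nchar(s)))
    lens <- exonLengths(fx$family[["SEP1_other"]])
    iso3 <- GeneModel("iso3", del(anc, 300, 3),
                      exonLengths = replace(lens, 3, lens[3] - 3L))
    iso21 <- GeneModel("iso21", del(anc, 300, 21),
                       exonLengths = replace(lens, 3, lens[3] - 21L))
    expect_identical(geneId(selectTranscript(list(iso21, iso3), ref)), "iso3")
    # nothing alignable -> unclassifiable locus (no shared alphabet at all)
    refG <- FamilySet(list(GeneModel("refG", strrep("G", 450))))
    junkA <- GeneModel("junkA", strrep("C", 450))
    junkB <- GeneModel("junkB", strrep("C", 444))
    expect_error(selectTranscript(list(junkA, junkB), refG),
                 "unclassifiable")
})
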