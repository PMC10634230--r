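test_that("FASTA reading normalizes case and alphabet and preserves order", {
    f <- withr::local_tempfile(fileext = ".fa")
    writeLines(c(">G1|tx1", "acgt", ">G2|tx2", "UUGG", "AA"), f)
    ts <- readTranscriptome(f)
    expect_s4_class(ts, "TranscriptSet")
    expect_identical(as.character(ts), c(tx1 = "ACGU", tx2 = "UUGGAA"))
    expect_identical(geneSymbols(ts), c("G1", "G2"))
    expect_identical(width(ts), c(4L, 6L))
})

test_that("invalid records and headers are rejected with names", {
    f <- withr::local_tempfile(fileext = ".fa")
    writeLines(c(">G1|tx1", "ACXU"), f)
    expect_error(readTranscriptome(f), "tx1")
    writeLines(c(">G1|tx1", ""), f)
    expect_error(readTranscriptome(f), "tx1")
    expect_error(readTranscriptome(withr::local_tempfile()), "not found")
})

test_that("N is retained but never forms a UU or motif match", {
    ts <- TranscriptSet("UNUNNGUCCUUCAA", "tx1", "G1")
    s <- as.character(ts)[[1]]
    expect_identical(countUU(s), 1L)
    expect_identical(findMotif(s), 6L)
    expect_identical(findMotif("GNCCUUCAA"), integer(0))
})

test_that("longest variant is kept per gene, ties broken by smallest id", {
    ts <- TranscriptSet(
        c(strrep("A", 100), strrep("A", 250), "ACGU", "GGCC", "GGCC"),
        c("v1", "v2", "tx", "NR_2", "NR_1"),
        c("GA", "GA", "GB", "GC", "GC"))
    sel <- selectLongestVariant(ts)
    expect_identical(geneSymbols(sel), c("GA", "GB", "GC"))
    expect_identical(unname(width(sel)[1]), 250L)
    expect_identical(transcriptIds(sel)[3], "NR_1")
    ## single-variant genes pass through unchanged
    expect_identical(as.character(sel)[["tx"]], "ACGU")
})

test_that("UU counting follows the printed-oligo and definition cases", {
    expect_identical(countUU(oligoSeq("polyA")), 0L)
    expect_identical(countUU(oligoSeq("XIST1.1")), 2L)
    expect_identical(countUU(oligoSeq("XIST1.1"), "overlapping"), 2L)
    expect_identical(countUU("UUU"), 1L)
    expect_identical(countUU("UUU", "overlapping"), 2L)
    ## vectorized over a set
    expect_identical(countUU(c("UU", "AA", "UUUU")), c(1L, 0L, 2L))
})

test_that("counting modes satisfy the bracketing invariant on random RNA", {
    set.seed(42)
    for (i in 1:30) {
        s <- randomRNA(sample(10:400, 1), uFrac = runif(1, 0.1, 0.9))
        ov <- countUU(s, "overlapping")
        no <- countUU(s, "nonoverlapping")
        expect_identical(no, bruteCountUU(s))
        expect_identical(ov, bruteCountUU(s, "overlapping"))
        expect_gte(ov, no)
        expect_gte(no, as.integer(ceiling(ov / 2)))
    }
})

test_that("A-padding leaves UU counts unchanged", {
    set.seed(7)
    s <- randomRNA(200, 0.5)
    expect_identical(countUU(paste0("AAA", s, "AA")), countUU(s))
    expect_identical(countUU(paste0("AAA", s, "AA"), "overlapping"),
                     countUU(s, "overlapping"))
})

test_that("windowed maximum matches the brute-force oracle", {
    set.seed(11)
    for (i in 1:8) {
        w <- sample(c(10, 25, 60), 1)
        s <- randomRNA(sample(80:600, 1), uFrac = runif(1, 0.2, 0.8))
        for (mode in c("nonoverlapping", "overlapping")) {
            got <- maxWindowUU(s, window = w, mode = mode)
            want <- bruteMaxWindowUU(s, w, mode)
            expect_identical(got$count, want$count)
            expect_identical(got$start, want$start)
        }
    }
})

test_that("short sequences collapse to a single window", {
    s <- randomRNA(40, 0.5)
    got <- maxWindowUU(s, window = 500)
    expect_identical(got$count, countUU(s))
    expect_identical(got$start, 1L)
    expect_error(maxWindowUU(s, window = 1), ">= 2")
})

test_that("the maximal window of a U-run lies fully inside the run", {
    s <- paste0("AA", strrep("UU", 10), "AA")
    got <- maxWindowUU(s, window = 10)
    expect_identical(got$count, 5L)
    expect_gte(got$start, 3L)
    expect_lte(got$start + 10L - 1L, 22L)
})

test_that("uuProfile agrees with per-window counts and maxWindowUU", {
    expect_error(uuProfile(randomRNA(100), window = 500), "shorter")
    prof <- uuProfile(strrep("U", 600), window = 500)
    expect_true(all(prof$uu_count == prof$uu_count[1]))
    expect_identical(nrow(prof), 101L)
    set.seed(3)
    s <- randomRNA(700, 0.5)
    prof <- uuProfile(s, window = 500)
    expect_identical(max(prof$uu_count), maxWindowUU(s, 500)$count)
    expect_identical(prof$uu_count[1], countUU(substr(s, 1, 500)))
})

test_that("motif matching reports every overlapping exact hit", {
    expect_identical(findMotif(oligoSeq("RNA9.2s")), 11L)
    expect_identical(findMotif(oligoSeq("XIST1.1")), 11L)
    expect_identical(findMotif(oligoSeq("polyA")), integer(0))
    expect_error(findMotif("ACGU", motif = "GTC"), "A/C/G/U")
    set.seed(5)
    s <- paste0(randomRNA(50), "GUCCUUCAA", randomRNA(20), "GUCCUUCAA")
    hits <- findMotif(s)
    for (p in hits)
        expect_identical(substr(s, p, p + 8), "GUCCUUCAA")
    expect_identical(hits, c(51L, 80L))
    ## overlapping self-matches
    expect_identical(findMotif("UUUU", motif = "UU"), 1:3)
})

test_that("transcript profiles collect all sequence metrics consistently", {
    ts <- TranscriptSet(c(oligoSeq("XIST1.1"), oligoSeq("polyA")),
                        c("t1", "t2"), c("XIST1.1", "polyA"))
    prof <- profileTranscripts(ts, window = 10)
    expect_identical(prof$uu_count, c(2L, 0L))
    expect_identical(prof$motif_hits, c("11", ""))
    expect_identical(prof$has_motif, c(TRUE, FALSE))
    expect_true(all(prof$max_window_uu <= prof$uu_count))
})

test_that("coordinates are 1-based and inclusive at both ends", {
    expect_identical(intervalLength(105, 851), 747L)
    expect_identical(intervalLength(1, 1), 1L)
})

test_that("FASTA round-trips through write and read", {
    set.seed(8)
    ts <- TranscriptSet(replicate(3, randomRNA(150)),
                        c("t1", "t2", "t3"), c("G1", "G2", "G3"))
    f <- withr::local_tempfile(fileext = ".fa")
    writeTranscriptomeFASTA(ts, f)
    back <- readTranscriptome(f)
    expect_identical(as.character(back), as.character(ts))
    expect_identical(geneSymbols(back), geneSymbols(ts))
})
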