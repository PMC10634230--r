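test_that("transcriptome generation is deterministic and self-consistent", {
    a <- simulateTranscriptome(nGenes = 40, seed = 5)
    b <- simulateTranscriptome(nGenes = 40, seed = 5)
    expect_identical(as.character(a$transcripts), as.character(b$transcripts))
    expect_identical(a$truth, b$truth)
    ## and FASTA bytes are identical too
    fa <- withr::local_tempfile(); fb <- withr::local_tempfile()
    writeTranscriptomeFASTA(a$transcripts, fa)
    writeTranscriptomeFASTA(b$transcripts, fb)
    expect_identical(readLines(fa), readLines(fb))
    ## a different seed changes the sequences
    c <- simulateTranscriptome(nGenes = 40, seed = 6)
    expect_false(identical(as.character(a$transcripts),
                           as.character(c$transcripts)))
})

test_that("the planted transcript carries its recorded motif and U-block", {
    sim <- simulateTranscriptome(nGenes = 30, seed = 11)
    planted <- selectLongestVariant(sim$transcripts)
    seqP <- as.character(planted)[[
        which(geneSymbols(planted) == sim$truth$planted_gene)]]
    expect_true(all(sim$truth$motif_positions %in% findMotif(seqP)))
    block <- substr(seqP, sim$truth$block_start,
                    sim$truth$block_start + sim$truth$block_length - 1)
    uFrac <- mean(strsplit(block, "")[[1]] == "U")
    expect_gt(uFrac, sim$truth$block_u_density - 0.1)
})

test_that("the planted U-block dominates max-window richness", {
    wins <- vapply(1:10, function(s) {
        sim <- simulateTranscriptome(nGenes = 60, seed = 200 + s)
        prof <- profileTranscripts(selectLongestVariant(sim$transcripts))
        planted <- prof$max_window_uu[prof$gene_symbol ==
                                          sim$truth$planted_gene]
        planted > max(prof$max_window_uu[prof$gene_symbol !=
                                             sim$truth$planted_gene])
    }, logical(1))
    expect_gte(sum(wins), 9)
})

test_that("multi-variant genes are emitted and resolved by variant selection", {
    sim <- simulateTranscriptome(nGenes = 50, nMultiVariant = 10, seed = 3)
    expect_identical(sum(duplicated(geneSymbols(sim$transcripts))), 10L)
    sel <- selectLongestVariant(sim$transcripts)
    expect_identical(anyDuplicated(geneSymbols(sel)), 0L)
    expect_identical(length(sel), 51L)
})

test_that("count simulation is deterministic with NB counts and varied depth", {
    tx <- simulateTranscriptome(nGenes = 60, seed = 7)
    a <- simulateCounts(tx$transcripts, tx$truth, nTissues = 2,
                        nPerSex = 5, seed = 7)
    b <- simulateCounts(tx$transcripts, tx$truth, nTissues = 2,
                        nPerSex = 5, seed = 7)
    expect_identical(a$counts, b$counts)
    expect_identical(a$sampleMeta, b$sampleMeta)
    expect_true(all(a$counts >= 0))
    expect_true(all(a$counts == round(a$counts)))
    ## library sizes vary severalfold
    depth <- colSums(a$counts)
    expect_gt(max(depth) / min(depth), 1.5)
    expect_error(simulateCounts(tx$transcripts, tx$truth, dispersion = 0),
                 "positive")
})

test_that("the planted sex effect is recovered by the TPM fold-change", {
    tx <- simulateTranscriptome(seed = 13)
    bulk <- simulateCounts(tx$transcripts, tx$truth, nTissues = 1,
                           nPerSex = 20, seed = 13)
    keep <- filterLowCounts(bulk$counts)
    expect_true(tx$truth$planted_gene %in% keep)
    tpm <- computeTPM(bulk$counts[keep, ], bulk$geneLengths[keep])
    fc <- log2fcSex(tpm, bulk$sampleMeta$sex)
    expect_equal(unname(fc[tx$truth$planted_gene]), log2(472),
                 tolerance = 0.5 / log2(472))
})

test_that("single-cell simulation is deterministic with one small patient", {
    a <- simulateSingleCell(nGenes = 50, nPatients = 5,
                            cellsPerPatient = 15, seed = 4)
    b <- simulateSingleCell(nGenes = 50, nPatients = 5,
                            cellsPerPatient = 15, seed = 4)
    expect_identical(a$expr, b$expr)
    tabs <- table(a$cellMeta$patient_id)
    expect_identical(sum(tabs < 10), 1L)
    expect_identical(unname(tabs[a$truth$small_patient]), 9L)
    expect_false(a$truth$tracking_gene %in% a$geneSet)
    expect_error(simulateSingleCell(nPatients = 3), ">= 4")
})

test_that("truth files round-trip losslessly", {
    truth <- list(planted_gene = "XISTL", block_start = 181,
                  motif_positions = c(2500, 2609),
                  sex_beta = c(G1 = 0, G2 = 1.5, XISTL = log2(472)))
    f <- withr::local_tempfile()
    writeTruth(truth, f)
    back <- readTruth(f)
    expect_identical(names(back), names(truth))
    expect_equal(back$sex_beta, truth$sex_beta)
    expect_identical(back$planted_gene, "XISTL")
    expect_equal(back$motif_positions, truth$motif_positions)
})

test_that("stage seeds are deterministic, distinct and below 2^31", {
    s <- vapply(1:5, function(k) stageSeed(123, k), integer(1))
    expect_identical(s, vapply(1:5, function(k) stageSeed(123, k),
                               integer(1)))
    expect_identical(anyDuplicated(s), 0L)
    expect_true(all(s >= 0 & s < 2^31))
})
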