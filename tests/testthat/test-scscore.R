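makeScMatrix <- function(nGenes, nCells, seed = 1) {
    set.seed(seed)
    base <- runif(nGenes, 0, 3)
    matrix(pmax(rnorm(nGenes * nCells, base, 0.5), 0), nGenes, nCells,
           dimnames = list(sprintf("g%04d", seq_len(nGenes)),
                           sprintf("c%03d", seq_len(nCells))))
}

test_that("module score is zero under self-control and uniform expression", {
    ## single-gene universe: the control pool can only be the gene itself
    m <- matrix(runif(5), 1, 5, dimnames = list("g1", paste0("c", 1:5)))
    expect_equal(unname(moduleScore(m, "g1", seed = 3)), rep(0, 5))
    ## uniform matrix: any control pool has the gene-set mean
    u <- matrix(2, 50, 10, dimnames = list(sprintf("g%02d", 1:50),
                                           paste0("c", 1:10)))
    expect_equal(unname(moduleScore(u, c("g01", "g07"), seed = 1)),
                 rep(0, 10))
})

test_that("module score validates its gene set", {
    m <- makeScMatrix(30, 8)
    expect_error(moduleScore(m, character(0)), "empty")
    expect_error(moduleScore(m, c("g0001", "nope")), "nope")
})

test_that("module score is invariant to cell-constant offsets", {
    m <- makeScMatrix(100, 20, seed = 5)
    gs <- c("g0001", "g0002", "g0003")
    base <- moduleScore(m, gs, seed = 11)
    off <- sweep(m, 2, runif(20, -2, 2), "+")
    expect_equal(moduleScore(off, gs, seed = 11), base)
})

test_that("scores are bit-reproducible under a fixed seed", {
    m <- makeScMatrix(200, 30, seed = 6)
    gs <- sprintf("g%04d", 1:10)
    expect_identical(moduleScore(m, gs, seed = 42),
                     moduleScore(m, gs, seed = 42))
    ## and the global RNG state is left untouched
    set.seed(99); before <- .Random.seed
    invisible(moduleScore(m, gs, seed = 42))
    expect_identical(.Random.seed, before)
})

test_that("an up-shift of the gene set in marked cells is recovered", {
    set.seed(71)
    delta <- 1.5
    m <- makeScMatrix(2000, 60, seed = 7)
    gs <- sprintf("g%04d", 1:15)
    marked <- 1:30
    m[gs, marked] <- m[gs, marked] + delta
    sc <- moduleScore(m, gs, seed = 2)
    expect_equal(mean(sc[marked]) - mean(sc[-marked]), delta,
                 tolerance = 0.15)
})

test_that("patient screen excludes small patients and needs 3 patients", {
    sim <- simulateSingleCell(nGenes = 120, nPatients = 6,
                              cellsPerPatient = 30, ifnSetSize = 10,
                              seed = 4)
    sc <- moduleScore(sim$expr, sim$geneSet, seed = 8)
    out <- patientScreen(sim$expr, sc, sim$cellMeta)
    expect_false(sim$truth$small_patient %in% out$per_patient$patient_id)
    expect_identical(nrow(out$per_patient), 5L)
    expect_true(all(out$per_patient$n_cells >= 10))
    expect_true(all(abs(out$screen$r) <= 1, na.rm = TRUE))
    expect_error(patientScreen(sim$expr, sc, sim$cellMeta, minCells = 1000),
                 "fewer than 3")
    expect_error(patientScreen(sim$expr, sc, sim$cellMeta[-1, ]),
                 "without patient")
})

test_that("a gene tracking the score correlates perfectly; unrelated do not", {
    sim <- simulateSingleCell(nGenes = 150, nPatients = 8,
                              cellsPerPatient = 40, ifnSetSize = 10,
                              effectSize = 1.2, seed = 9)
    sc <- moduleScore(sim$expr, sim$geneSet, seed = 3)
    ## plant a gene exactly equal to the score
    expr2 <- rbind(sim$expr, SCORECOPY = sc)
    out <- patientScreen(expr2, sc, sim$cellMeta)
    expect_equal(out$screen$r[out$screen$gene_symbol == "SCORECOPY"], 1,
                 tolerance = 1e-8)
    trk <- out$screen[out$screen$gene_symbol == sim$truth$tracking_gene, ]
    expect_gt(trk$r, 0.5)
    expect_identical(trk$direction, "positive")
})

test_that("null data yield small correlations and roughly uniform p-values", {
    set.seed(81)
    ps <- unlist(lapply(1:5, function(i) {
        sim <- simulateSingleCell(nGenes = 80, nPatients = 10,
                                  cellsPerPatient = 25, ifnSetSize = 8,
                                  effectSize = 0, seed = 100 + i)
        sc <- moduleScore(sim$expr, sim$geneSet, seed = i)
        out <- patientScreen(sim$expr, sc, sim$cellMeta,
                             genes = setdiff(rownames(sim$expr),
                                             c(sim$geneSet, "TRACK1")))
        out$screen$p_value
    }))
    expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
    expect_lt(mean(ps < 0.05), 0.10)
})

test_that("MTX and dense expression readers round-trip a matrix", {
    m <- makeScMatrix(12, 5, seed = 10)
    d <- withr::local_tempdir()
    Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE),
                    file.path(d, "m.mtx"))
    writeLines(rownames(m), file.path(d, "genes.txt"))
    writeLines(colnames(m), file.path(d, "cells.txt"))
    back <- readMTXExpression(file.path(d, "m.mtx"),
                              file.path(d, "genes.txt"),
                              file.path(d, "cells.txt"))
    expect_equal(back, m)
    writeCountsTSV(m, file.path(d, "dense.tsv"))
    expect_equal(readDenseExpression(file.path(d, "dense.tsv")), m)
    writeLines(c("g001", "", "g002 "), file.path(d, "gs.txt"))
    expect_identical(readGeneSet(file.path(d, "gs.txt")), c("g001", "g002"))
})
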