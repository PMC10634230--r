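#' Derive a stage seed from a master seed
#'
#' Every generator draws from its own stage seed so that stages can be
#' regenerated independently while a single master seed fixes the whole
#' dataset. The scheme is \code{(seed * 101 + stage * 7919) mod (2^31 - 1)}.
#'
#' @param seed master seed (integer).
#' @param stage small integer stage index.
#' @return Integer seed below 2^31.
#' @export
stageSeed <- function(seed, stage) {
    as.integer((as.numeric(seed) * 101 + as.numeric(stage) * 7919) %%
                   2147483647)
}

#' Simulate a transcript pool with a planted XIST-like transcript
#'
#' Background transcripts are drawn i.i.d. from the given base composition
#' with heterogeneous lengths. One planted transcript mimics the features
#' that make XIST stand out: a contiguous U-dense block (emulating the
#' A-repeat region of short repeats joined by U-rich linkers) and an
#' embedded copy of the TLR7-stimulatory motif at a recorded position. A
#' subset of background genes is emitted with a second, shorter variant to
#' exercise longest-variant selection. Output is a pure function of the
#' configuration and seed.
#'
#' @param nGenes number of background genes (>= 2).
#' @param lengthRange integer range of background transcript lengths (nt).
#' @param baseFreq named base frequencies for A/C/G/U (default uniform).
#' @param plantedGene symbol of the planted transcript.
#' @param plantedLength length of the planted transcript (nt).
#' @param blockStart,blockLength 1-based start and length of the U-dense
#'   block (defaults mimic an A-repeat-like 5' region at nt 181 onward).
#' @param blockUDensity probability of U inside the block (default 0.8).
#' @param motif motif embedded in the planted transcript.
#' @param motifStart 1-based position at which the motif is written.
#' @param nMultiVariant background genes emitted with a second variant.
#' @param seed master seed.
#' @return List with \code{transcripts} (a \code{\link{TranscriptSet}}) and
#'   \code{truth} (planted gene, block coordinates and density, motif
#'   positions, seed).
#' @export
simulateTranscriptome <- function(nGenes = 500L,
                                  lengthRange = c(500L, 4000L),
                                  baseFreq = c(A = 0.25, C = 0.25,
                                               G = 0.25, U = 0.25),
                                  plantedGene = "XISTL",
                                  plantedLength = 3000L,
                                  blockStart = 181L,
                                  blockLength = 800L,
                                  blockUDensity = 0.8,
                                  motif = "GUCCUUCAA",
                                  motifStart = 2500L,
                                  nMultiVariant = 20L,
                                  seed = 1L) {
    stopifnot(nGenes >= 2L, blockUDensity > 0, blockUDensity <= 1)
    if (blockStart + blockLength - 1L > plantedLength)
        stop("U-dense block extends beyond the planted transcript")
    if (motifStart + nchar(motif) - 1L > plantedLength)
        stop("motif extends beyond the planted transcript")
    old <- .saveSeed(); on.exit(.restoreSeed(old), add = TRUE)
    set.seed(stageSeed(seed, 1L))
    bases <- c("A", "C", "G", "U")
    freq <- baseFreq[bases]
    lens <- sample(lengthRange[1]:lengthRange[2], nGenes, replace = TRUE)
    seqs <- vapply(lens, function(L)
        paste(sample(bases, L, replace = TRUE, prob = freq), collapse = ""),
        character(1))
    genes <- sprintf("G%04d", seq_len(nGenes))
    ids <- sprintf("T%04d_1", seq_len(nGenes))
    ## planted transcript: background composition, then overwrite the block
    ## and the motif
    pl <- sample(bases, plantedLength, replace = TRUE, prob = freq)
    nonU <- (1 - blockUDensity) / 3
    blk <- sample(bases, blockLength, replace = TRUE,
                  prob = c(nonU, nonU, nonU, blockUDensity))
    pl[blockStart:(blockStart + blockLength - 1L)] <- blk
    pl[motifStart:(motifStart + nchar(motif) - 1L)] <-
        strsplit(motif, "")[[1L]]
    seqs <- c(seqs, paste(pl, collapse = ""))
    genes <- c(genes, plantedGene)
    ids <- c(ids, paste0(plantedGene, "_1"))
    ## extra shorter variants for a subset of background genes
    nMV <- min(nMultiVariant, nGenes)
    if (nMV > 0L) {
        mv <- sample.int(nGenes, nMV)
        seqs <- c(seqs, substr(seqs[mv], 1L, pmax(2L, floor(lens[mv] * 0.6))))
        genes <- c(genes, sprintf("G%04d", mv))
        ids <- c(ids, sprintf("T%04d_2", mv))
    }
    ts <- TranscriptSet(seqs, transcriptIds = ids, geneSymbols = genes)
    truth <- list(planted_gene = plantedGene,
                  block_start = blockStart,
                  block_length = blockLength,
                  block_u_density = blockUDensity,
                  motif = motif,
                  motif_positions = findMotif(seqs[nGenes + 1L], motif),
                  seed = seed)
    list(transcripts = ts, truth = truth)
}

#' Simulate sex-stratified negative-binomial counts across tissues
#'
#' Per tissue, baseline means are drawn log-normally per gene; each sample's
#' counts are negative binomial around the baseline scaled by a symmetric
#' sex multiplier \code{2^(+-beta/2)} and a log-uniform library-size factor
#' spanning a 3-fold range either way (exercising TPM normalization). The
#' planted gene carries an extreme female bias (default female:male ratio
#' 472) and a high baseline so its female TPM sits in the top expression
#' decile; a small fraction of background genes receives random sex effects.
#'
#' @param transcripts \code{TranscriptSet} from
#'   \code{\link{simulateTranscriptome}} (variants are resolved internally).
#' @param truth truth list from \code{\link{simulateTranscriptome}}.
#' @param nTissues number of tissues.
#' @param nPerSex samples per sex per tissue.
#' @param dispersion negative-binomial dispersion (> 0); variance is
#'   \code{mu + dispersion * mu^2}.
#' @param sexFoldChange planted gene's female:male mean ratio (default 472);
#'   set to 1 for a null dataset.
#' @param plantedMaleMu planted gene's male-side mean count (default 120).
#'   Anchoring the male side keeps the planted gene clear of the 25-read
#'   low-count filter at simulation depth while the female side carries the
#'   full fold-change, emulating an abundant transcript sequenced deeply
#'   enough to be detected in both sexes.
#' @param sexEffectFrac fraction of background genes with a random sex
#'   effect; their \code{beta ~ N(0, sexEffectSd)}.
#' @param sexEffectSd SD of background sex effects (log2 scale).
#' @param seed master seed.
#' @return List with \code{counts} (integer matrix), \code{sampleMeta}
#'   (sample_id, sex, tissue), \code{geneLengths} (named, from the longest
#'   variant) and \code{truth} extended with per-gene \code{sex_beta}.
#' @export
simulateCounts <- function(transcripts, truth, nTissues = 3L, nPerSex = 20L,
                           dispersion = 0.1, sexFoldChange = 472,
                           sexEffectFrac = 0.05, sexEffectSd = 1,
                           plantedMaleMu = 120, seed = 1L) {
    if (dispersion <= 0) stop("'dispersion' must be positive")
    longest <- selectLongestVariant(transcripts)
    genes <- geneSymbols(longest)
    lens <- stats::setNames(width(longest), genes)
    nGenes <- length(genes)
    planted <- truth$planted_gene
    old <- .saveSeed(); on.exit(.restoreSeed(old), add = TRUE)
    set.seed(stageSeed(seed, 2L))
    beta <- stats::setNames(numeric(nGenes), genes)
    nEff <- round(sexEffectFrac * nGenes)
    if (nEff > 0) {
        eff <- sample(setdiff(genes, planted), nEff)
        beta[eff] <- stats::rnorm(nEff, 0, sexEffectSd)
    }
    beta[planted] <- log2(sexFoldChange)
    tissues <- sprintf("tissue%d", seq_len(nTissues))
    counts <- NULL; meta <- NULL
    for (t in tissues) {
        baseMu <- stats::setNames(
            stats::rlnorm(nGenes, meanlog = log(100), sdlog = 1.2), genes)
        ## planted baseline anchored on the male side: with the symmetric
        ## 2^(+-beta/2) split, male mean = plantedMaleMu and female mean =
        ## plantedMaleMu * sexFoldChange
        baseMu[planted] <- plantedMaleMu * sqrt(sexFoldChange)
        sex <- rep(c("female", "male"), each = nPerSex)
        sf <- exp(stats::runif(2 * nPerSex, log(1 / 3), log(3)))
        mu <- (baseMu %o% rep(1, length(sex))) *
            2^(beta %o% ifelse(sex == "female", 0.5, -0.5))
        mu <- sweep(mu, 2L, sf, "*")
        cts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                     size = 1 / dispersion),
                      nrow = nGenes,
                      dimnames = list(genes, NULL))
        ids <- sprintf("%s_%s%02d", t, ifelse(sex == "female", "F", "M"),
                       c(seq_len(nPerSex), seq_len(nPerSex)))
        colnames(cts) <- ids
        counts <- cbind(counts, cts)
        meta <- rbind(meta, data.frame(sample_id = ids, sex = sex,
                                       tissue = t))
    }
    truth$sex_beta <- beta
    truth$dispersion <- dispersion
    truth$sex_fold_change <- sexFoldChange
    list(counts = counts, sampleMeta = meta, geneLengths = lens,
         truth = truth)
}

#' Simulate a multi-patient single-cell expression matrix
#'
#' Per-patient interferon-program intensities are drawn Uniform(0, 1); the
#' expression of the interferon gene set and of one non-member "tracking"
#' gene is up-shifted by \code{effectSize * intensity} in every cell of the
#' patient, on top of Gaussian noise around per-gene baselines (truncated at
#' zero, emulating a log-normalized matrix). With the default 16 patients,
#' 15 survive the 10-cell filter. One patient contributes fewer
#' than 10 cells to exercise the per-patient cell filter.
#'
#' @param nGenes number of genes.
#' @param nPatients number of patients (>= 4).
#' @param cellsPerPatient cells per (full-sized) patient.
#' @param ifnSetSize number of interferon-module genes.
#' @param effectSize shift per unit program intensity (log-expression
#'   units); 0 gives a null dataset.
#' @param smallPatientCells cell count of the deliberately small patient
#'   (default 9, below the screen's 10-cell filter).
#' @param noiseSd per-cell Gaussian noise SD.
#' @param seed master seed.
#' @return List with \code{expr} (genes x cells), \code{cellMeta}
#'   (cell_id, patient_id), \code{geneSet} (interferon module symbols) and
#'   \code{truth} (per-patient intensity, tracking gene, small patient).
#' @export
simulateSingleCell <- function(nGenes = 1000L, nPatients = 16L,
                               cellsPerPatient = 80L, ifnSetSize = 20L,
                               effectSize = 1, smallPatientCells = 9L,
                               noiseSd = 0.5, seed = 1L) {
    if (nPatients < 4L) stop("'nPatients' must be >= 4")
    nCellsTotal <- (nPatients - 1L) * cellsPerPatient + smallPatientCells
    if (nCellsTotal < nPatients) stop("fewer cells than patients")
    old <- .saveSeed(); on.exit(.restoreSeed(old), add = TRUE)
    set.seed(stageSeed(seed, 3L))
    genes <- sprintf("SG%04d", seq_len(nGenes))
    ifnSet <- sprintf("IFN%03d", seq_len(ifnSetSize))
    tracking <- "TRACK1"
    genes[seq_len(ifnSetSize)] <- ifnSet
    genes[ifnSetSize + 1L] <- tracking
    patients <- sprintf("P%02d", seq_len(nPatients))
    cellsOf <- rep(cellsPerPatient, nPatients)
    cellsOf[nPatients] <- smallPatientCells
    patOfCell <- rep(patients, times = cellsOf)
    cellIds <- sprintf("cell%05d", seq_along(patOfCell))
    intensity <- stats::setNames(stats::runif(nPatients), patients)
    base <- stats::runif(nGenes, 0.1, 2)
    expr <- matrix(pmax(stats::rnorm(nGenes * length(cellIds), mean = base,
                                     sd = noiseSd), 0),
                   nrow = nGenes, dimnames = list(genes, cellIds))
    shifted <- c(ifnSet, tracking)
    shift <- effectSize * intensity[patOfCell]
    expr[shifted, ] <- sweep(expr[shifted, , drop = FALSE], 2L, shift, "+")
    list(expr = expr,
         cellMeta = data.frame(cell_id = cellIds, patient_id = patOfCell),
         geneSet = ifnSet,
         truth = list(intensity = intensity, tracking_gene = tracking,
                      ifn_set = ifnSet, effect_size = effectSize,
                      small_patient = patients[nPatients],
                      small_patient_cells = smallPatientCells,
                      seed = seed))
}

#' Write a counts matrix as TSV (gene_symbol first column)
#'
#' @param counts genes x samples matrix with dimnames.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCountsTSV <- function(counts, path) {
    df <- data.frame(gene_symbol = rownames(counts), counts,
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeCountsTSV
#' @param meta sample-metadata data.frame.
#' @export
writeSampleMetaTSV <- function(meta, path) {
    utils::write.table(meta, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write a ground-truth list as flat key-value text
#'
#' Scalars and (named) vectors are written as
#' \code{key<TAB>type<TAB>comma-joined values[<TAB>comma-joined names]} so
#' the file round-trips losslessly through \code{\link{readTruth}}.
#'
#' @param truth named list of character/numeric scalars or vectors.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeTruth <- function(truth, path) {
    lines <- vapply(names(truth), function(k) {
        v <- truth[[k]]
        type <- if (is.character(v)) "chr" else "num"
        val <- paste(if (is.numeric(v)) format(v, digits = 17) else v,
                     collapse = ",")
        nm <- if (!is.null(names(v))) paste(names(v), collapse = ",") else ""
        paste(k, type, val, nm, sep = "\t")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

#' @rdname writeTruth
#' @return \code{readTruth}: the reconstructed list.
#' @export
readTruth <- function(path) {
    lines <- readLines(path)
    out <- list()
    for (ln in lines) {
        f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
        v <- strsplit(f[3L], ",", fixed = TRUE)[[1L]]
        if (f[2L] == "num") v <- as.numeric(v)
        if (length(f) >= 4L && nzchar(f[4L]))
            names(v) <- strsplit(f[4L], ",", fixed = TRUE)[[1L]]
        out[[f[1L]]] <- v
    }
    out
}
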