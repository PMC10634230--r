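#' Configuration for the ligation-score pipeline
#'
#' All defaults are the screen's published operating point: 500-nt window,
#' motif \code{GUCCUUCAA}, low-count filter at 25 reads in 10\% of samples,
#' fold-change pseudocount 0.01 TPM, the 8 sex-specific tissues excluded,
#' and alpha 0.05 for the Benjamini-Yekutieli-adjusted differential
#' expression call.
#'
#' @param fasta,counts,meta,outDir input file paths and output directory.
#' @param motif,window,mode sequence-metric settings
#'   (\code{\link{profileTranscripts}}).
#' @param threshold,fraction low-count filter
#'   (\code{\link{filterLowCounts}}).
#' @param pseudocount TPM pseudocount for fold-change and log expression.
#' @param excludeTissues tissues dropped before analysis.
#' @param alpha significance level for the DE call.
#' @param expressionCriterion \code{"female"} (mean female TPM, the
#'   default) or \code{"all"} (all-sample mean) as the expression ranking
#'   criterion.
#' @return A \code{RunConfig} list.
#' @export
scoreConfig <- function(fasta, counts, meta, outDir,
                        motif = "GUCCUUCAA", window = 500L,
                        mode = "nonoverlapping",
                        threshold = 25, fraction = 0.10,
                        pseudocount = 0.01,
                        excludeTissues = sexSpecificTissues(),
                        alpha = 0.05,
                        expressionCriterion = c("female", "all")) {
    list(fasta = fasta, counts = counts, meta = meta, outDir = outDir,
         motif = motif, window = as.integer(window), mode = mode,
         threshold = threshold, fraction = fraction,
         pseudocount = pseudocount, excludeTissues = excludeTissues,
         alpha = alpha,
         expressionCriterion = match.arg(expressionCriterion))
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop("[stage: ", name, "] ", conditionMessage(e), call. = FALSE))
}

#' Run the full transcript-prioritization pipeline
#'
#' Orchestrates sequence profiling, per-tissue expression summaries,
#' moderated differential-expression testing and rank-sum ligation scoring,
#' writing one TSV per product plus a run manifest with input checksums.
#' Reruns with identical config and inputs are byte-identical.
#'
#' Products written to \code{config$outDir}: \code{profile.tsv},
#' \code{score_<tissue>.tsv} and \code{de_<tissue>.tsv} per tissue,
#' \code{combined_scores.tsv} (cross-tissue normalized average) and
#' \code{manifest.txt}.
#'
#' @param config a \code{\link{scoreConfig}} list.
#' @return Invisibly, a list with \code{profile}, \code{perTissue} (list of
#'   score tables), \code{de} (list of DE tables), \code{combined}, and
#'   \code{files}.
#' @export
runScorePipeline <- function(config) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    ts <- .stage("seqio", {
        readTranscriptome(config$fasta)
    })
    ts <- selectLongestVariant(ts)
    profile <- .stage("profile",
        profileTranscripts(ts, motif = config$motif,
                           window = config$window, mode = config$mode))
    lens <- stats::setNames(profile$length, profile$gene_symbol)
    se <- .stage("expression", {
        cts <- readCountsMatrix(config$counts)
        meta <- readSampleMeta(config$meta)
        shared <- intersect(rownames(cts), profile$gene_symbol)
        if (length(shared) == 0L)
            stop("no genes shared between counts matrix and transcriptome")
        SexExpressionSet(cts[shared, , drop = FALSE], meta,
                         geneLengths = lens[shared])
    })
    se <- excludeSexSpecificTissues(se, config$excludeTissues)
    tissues <- unique(SummarizedExperiment::colData(se)$tissue)
    perTissue <- list(); deTabs <- list()
    for (t in tissues) {
        seT <- se[, SummarizedExperiment::colData(se)$tissue == t]
        sexT <- SummarizedExperiment::colData(seT)$sex
        if (sum(sexT == "female") < 2L || sum(sexT == "male") < 2L) next
        seT <- .stage(paste0("expression:", t), {
            seT <- filterLowCounts(seT, config$threshold, config$fraction)
            computeTPM(seT)
        })
        bias <- sexBiasTable(seT, pseudocount = config$pseudocount)
        deTabs[[t]] <- .stage(paste0("diffexpr:", t), {
            lg <- log2(SummarizedExperiment::assay(seT, "tpm") +
                           config$pseudocount)
            moderatedSexTest(lg, sexT, alpha = config$alpha)
        })
        exprCrit <- if (config$expressionCriterion == "female")
            stats::setNames(bias$mean_tpm_female, bias$gene_symbol)
        else stats::setNames(
            rowMeans(SummarizedExperiment::assay(seT, "tpm")),
            bias$gene_symbol)
        profT <- profile[profile$gene_symbol %in% bias$gene_symbol, ]
        perTissue[[t]] <- .stage(paste0("ranking:", t),
            ligationScore(profT,
                          exprCrit[profT$gene_symbol],
                          stats::setNames(bias$log2fc_sex,
                                          bias$gene_symbol)[profT$gene_symbol]))
    }
    if (length(perTissue) == 0L)
        stop("[stage: ranking] no tissue with >= 2 samples per sex")
    combined <- normalizeAndAverage(perTissue)
    files <- c(profile = file.path(config$outDir, "profile.tsv"),
               combined = file.path(config$outDir, "combined_scores.tsv"))
    .writeTSV(profile, files["profile"])
    .writeTSV(combined, files["combined"])
    for (t in names(perTissue)) {
        f <- file.path(config$outDir, paste0("score_", t, ".tsv"))
        .writeTSV(perTissue[[t]], f)
        files[paste0("score_", t)] <- f
        f <- file.path(config$outDir, paste0("de_", t, ".tsv"))
        .writeTSV(as.data.frame(deTabs[[t]]), f)
        files[paste0("de_", t)] <- f
    }
    manifest <- file.path(config$outDir, "manifest.txt")
    .writeManifest(config, files, manifest)
    files["manifest"] <- manifest
    invisible(list(profile = profile, perTissue = perTissue, de = deTabs,
                   combined = combined, files = files))
}

.writeTSV <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
}

.writeManifest <- function(config, files, path) {
    opts <- vapply(setdiff(names(config), "outDir"), function(k)
        paste0("config.", k, "=",
               paste(format(config[[k]]), collapse = ",")),
        character(1))
    sums <- c(
        vapply(c(config$fasta, config$counts, config$meta), function(f)
            paste0("input.", basename(f), ".md5=",
                   unname(tools::md5sum(f))), character(1)),
        vapply(unname(files), function(f)
            paste0("output.", basename(f), ".md5=",
                   unname(tools::md5sum(f))), character(1)))
    writeLines(c(paste0("tlr7scan.version=",
                        as.character(utils::packageVersion("tlr7scan"))),
                 opts, sums), path)
}
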