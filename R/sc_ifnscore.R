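#' Read a sparse genes-by-cells expression matrix (MTX triplet)
#'
#' @param matrixPath MatrixMarket file.
#' @param genesPath one gene symbol per line (rows of the matrix).
#' @param barcodesPath one cell identifier per line (columns).
#' @return A dense genes x cells matrix with dimnames.
#' @export
readMTXExpression <- function(matrixPath, genesPath, barcodesPath) {
    m <- as.matrix(Matrix::readMM(matrixPath))
    rownames(m) <- readLines(genesPath)
    colnames(m) <- readLines(barcodesPath)
    m
}

#' Read a dense genes-by-cells expression TSV
#'
#' First column gene symbols, remaining columns one per cell.
#'
#' @param path TSV file path.
#' @return Numeric matrix with dimnames.
#' @export
readDenseExpression <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "numeric"
    rownames(m) <- df[[1L]]
    m
}

#' Read a gene set (one symbol per line)
#'
#' @param path text file path; blank lines are ignored.
#' @return Character vector of gene symbols.
#' @export
readGeneSet <- function(path) {
    x <- trimws(readLines(path))
    x[nzchar(x)]
}

#' Per-cell gene-set module score with bin-matched control genes
#'
#' For every cell, the mean expression of the gene set minus the mean
#' expression of a control gene pool matched on average expression: all
#' genes are split into \code{nBins} equal-frequency bins by their average
#' expression across cells (ties broken by a seeded shuffle), \code{nCtrl}
#' control genes are drawn uniformly with replacement from the bin of each
#' gene-set gene, and the draws are pooled as a unique set before
#' averaging. Expression is assumed log-normalized. With a fixed seed the
#' scores are bit-reproducible.
#'
#' @param expr genes x cells numeric matrix (log-normalized).
#' @param geneSet character vector of gene symbols; must be non-empty and
#'   present in \code{rownames(expr)}.
#' @param nBins number of expression bins (capped at the number of genes).
#' @param nCtrl control genes drawn per gene-set gene.
#' @param seed integer seed for binning tie-breaks and control sampling.
#' @return Named numeric vector of per-cell scores.
#' @export
moduleScore <- function(expr, geneSet, nBins = 24L, nCtrl = 100L, seed = 1L) {
    expr <- as.matrix(expr)
    if (length(geneSet) == 0L) stop("gene set is empty")
    missing <- setdiff(geneSet, rownames(expr))
    if (length(missing))
        stop("gene set gene(s) absent from the matrix: ",
             paste(missing, collapse = ", "))
    nGenes <- nrow(expr)
    nBins <- max(1L, min(as.integer(nBins), nGenes))
    avg <- rowMeans(expr)
    old <- .saveSeed()
    on.exit(.restoreSeed(old), add = TRUE)
    set.seed(as.integer(seed))
    ord <- order(avg, sample.int(nGenes), method = "radix")
    binOf <- integer(nGenes)
    binOf[ord] <- ceiling(seq_len(nGenes) * nBins / nGenes)
    names(binOf) <- rownames(expr)
    ctrl <- unlist(lapply(geneSet, function(g) {
        pool <- rownames(expr)[binOf == binOf[g]]
        pool[sample.int(length(pool), nCtrl, replace = TRUE)]
    }), use.names = FALSE)
    ctrl <- unique(ctrl)
    colMeans(expr[geneSet, , drop = FALSE]) -
        colMeans(expr[ctrl, , drop = FALSE])
}

.saveSeed <- function() {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
}

.restoreSeed <- function(old) {
    if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
}

#' Per-patient aggregation and gene-wise correlation screen
#'
#' Aggregates per-cell module scores and gene expression to patient means
#' (patients contributing fewer than \code{minCells} cells are excluded),
#' then correlates each gene's per-patient mean expression with the
#' per-patient mean score (Pearson, two-sided).
#'
#' @param expr genes x cells matrix (log-normalized).
#' @param scores named per-cell score vector from \code{\link{moduleScore}}.
#' @param cellMeta data.frame with columns \code{cell_id}, \code{patient_id}
#'   covering every cell in \code{expr}.
#' @param minCells minimum cells per patient (default 10).
#' @param genes genes to screen; default all rows of \code{expr}.
#' @return List with \code{per_patient} (patient_id, n_cells, mean_score)
#'   and \code{screen} (gene_symbol, r, p_value, direction,
#'   positive_hit = r > 0 & p < 0.05). Genes constant across patients get
#'   \code{NA} correlation.
#' @export
patientScreen <- function(expr, scores, cellMeta, minCells = 10L,
                          genes = rownames(expr)) {
    expr <- as.matrix(expr)
    req <- c("cell_id", "patient_id")
    if (!all(req %in% colnames(cellMeta)))
        stop("cellMeta must have columns: ", paste(req, collapse = ", "))
    unmapped <- setdiff(colnames(expr), cellMeta$cell_id)
    if (length(unmapped))
        stop("cells without patient mapping: ",
             paste(utils::head(unmapped, 5), collapse = ", "))
    pat <- cellMeta$patient_id[match(colnames(expr), cellMeta$cell_id)]
    tab <- table(pat)
    keepPat <- names(tab)[tab >= minCells]
    if (length(keepPat) < 3L)
        stop("fewer than 3 patients with >= ", minCells,
             " cells; correlation undefined")
    keep <- pat %in% keepPat
    expr <- expr[, keep, drop = FALSE]
    scores <- scores[keep]
    pat <- factor(pat[keep], levels = keepPat)
    meanScore <- tapply(scores, pat, mean)
    nCells <- as.integer(table(pat))
    patMeans <- t(apply(expr[genes, , drop = FALSE], 1L, function(x)
        tapply(x, pat, mean)))
    screen <- do.call(rbind, lapply(seq_along(genes), function(i) {
        x <- patMeans[i, ]
        if (stats::sd(x) == 0 || stats::sd(meanScore) == 0)
            return(data.frame(gene_symbol = genes[i], r = NA_real_,
                              p_value = NA_real_))
        ct <- stats::cor.test(x, as.numeric(meanScore), method = "pearson")
        data.frame(gene_symbol = genes[i], r = unname(ct$estimate),
                   p_value = ct$p.value)
    }))
    screen$direction <- ifelse(is.na(screen$r), NA_character_,
                               ifelse(screen$r > 0, "positive", "negative"))
    screen$positive_hit <- !is.na(screen$r) & screen$r > 0 &
        screen$p_value < 0.05
    list(per_patient = data.frame(patient_id = keepPat, n_cells = nCells,
                                  mean_score = as.numeric(meanScore),
                                  row.names = NULL),
         screen = screen)
}
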