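#' @importFrom SummarizedExperiment assay assay<- assayNames colData rowData
NULL

#' Read a gene-level counts matrix from TSV
#'
#' First column \code{gene_symbol}, remaining columns one per sample.
#'
#' @param path TSV file path.
#' @return Integer matrix with gene rownames and sample colnames.
#' @export
readCountsMatrix <- function(path) {
    if (!file.exists(path)) stop("counts file not found: ", path)
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (nrow(df) == 0L || ncol(df) < 2L)
        stop("counts file has no genes or no samples: ", path)
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "numeric"
    rownames(m) <- df[[1L]]
    m
}

#' Read sample metadata from TSV
#'
#' @param path TSV with header \code{sample_id}, \code{sex}, \code{tissue}.
#' @return A data.frame.
#' @export
readSampleMeta <- function(path) {
    if (!file.exists(path)) stop("metadata file not found: ", path)
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    req <- c("sample_id", "sex", "tissue")
    if (!all(req %in% colnames(df)))
        stop("metadata must have columns: ", paste(req, collapse = ", "))
    df
}

#' Sex-specific tissues excluded from the screen
#'
#' The default exclusion list: tissues present in only one sex, for which a
#' female/male expression contrast is undefined.
#'
#' @return Character vector of 8 tissue names (lowercase).
#' @export
sexSpecificTissues <- function() {
    c("uterus", "vagina", "breast", "ovary", "cervix/uteri",
      "fallopian tube", "prostate", "testis")
}

#' Drop samples from sex-specific tissues
#'
#' Tissue names are compared case-insensitively against the exclusion list.
#'
#' @param x a \code{SexExpressionSet} or a sample-metadata data.frame with a
#'   \code{tissue} column.
#' @param exclusions character vector of tissue names to drop; default
#'   \code{\link{sexSpecificTissues}()}.
#' @return Object of the same class with the listed tissues' samples removed.
#' @export
excludeSexSpecificTissues <- function(x, exclusions = sexSpecificTissues()) {
    if (is(x, "SexExpressionSet")) {
        keep <- !(tolower(colData(x)$tissue) %in% tolower(exclusions))
        return(x[, keep])
    }
    x[!(tolower(x$tissue) %in% tolower(exclusions)), , drop = FALSE]
}

#' Low-count gene filter
#'
#' A gene is excluded when the fraction of samples with fewer than
#' \code{threshold} reads is \code{fraction} or more (the boundary is
#' inclusive on the fraction: 1 sample below threshold out of 10 already
#' excludes at the default 10\%). The filter is idempotent.
#'
#' @param x counts matrix (genes x samples) or a \code{SexExpressionSet}.
#' @param threshold read-count threshold; counts strictly below it are "low".
#' @param fraction proportion of samples at which a gene is excluded.
#' @return For a matrix, the character vector of retained gene names; for a
#'   \code{SexExpressionSet}, the object subset to retained genes.
#' @export
filterLowCounts <- function(x, threshold = 25, fraction = 0.10) {
    cts <- if (is(x, "SexExpressionSet")) assay(x, "counts") else as.matrix(x)
    if (nrow(cts) == 0L || ncol(cts) == 0L)
        stop("empty counts matrix")
    lowFrac <- rowMeans(cts < threshold)
    keep <- lowFrac < fraction
    if (is(x, "SexExpressionSet")) x[keep, ] else rownames(cts)[keep]
}

#' Transcripts-per-million from counts and transcript lengths
#'
#' Per sample: length-normalized rates \code{count / (length/1000)} are
#' rescaled to sum to 1e6. Columns of the result therefore sum to 1e6
#' exactly (up to floating-point error). When applied to a
#' \code{SexExpressionSet} the TPM is computed on the current (post-filter)
#' gene set, keeping values comparable across the analyzed universe, and is
#' stored as a \code{tpm} assay.
#'
#' @param x counts matrix or a \code{SexExpressionSet} whose rowData carries
#'   \code{gene_length}.
#' @param geneLengths numeric vector of transcript lengths (nt), recycled
#'   against matrix rows; ignored for a \code{SexExpressionSet}.
#' @return TPM matrix, or the \code{SexExpressionSet} with a \code{tpm}
#'   assay added.
#' @export
computeTPM <- function(x, geneLengths = NULL) {
    if (is(x, "SexExpressionSet")) {
        gl <- rowData(x)$gene_length
        if (is.null(gl))
            stop("rowData(x)$gene_length is required to compute TPM")
        assay(x, "tpm") <- computeTPM(assay(x, "counts"), gl)
        return(x)
    }
    cts <- as.matrix(x)
    if (is.null(geneLengths)) stop("'geneLengths' is required")
    if (any(geneLengths <= 0)) stop("gene lengths must be positive")
    rate <- cts / (geneLengths / 1000)
    tot <- colSums(rate)
    if (any(tot == 0))
        stop("all-zero counts in sample(s): ",
             paste(colnames(cts)[tot == 0], collapse = ", "))
    sweep(rate, 2L, tot, "/") * 1e6
}

#' Per-gene log2 female/male expression fold-change
#'
#' \code{log2((mean female TPM + pseudocount) / (mean male TPM +
#' pseudocount))}. The pseudocount (default 0.01 TPM) bounds the statistic
#' for genes expressed in one sex only while perturbing strong ratios by
#' under 1 percent.
#'
#' @param tpm TPM matrix (genes x samples).
#' @param sex character vector, one of \code{"female"}/\code{"male"} per
#'   column of \code{tpm}.
#' @param pseudocount TPM offset added to both means.
#' @return Named numeric vector of log2 fold-changes (female over male).
#' @export
log2fcSex <- function(tpm, sex, pseudocount = 0.01) {
    stopifnot(ncol(tpm) == length(sex))
    isF <- sex == "female"
    isM <- sex == "male"
    if (!any(isF) || !any(isM))
        stop("both sexes must be present (sex-specific tissues should have ",
             "been excluded upstream)")
    mF <- rowMeans(tpm[, isF, drop = FALSE])
    mM <- rowMeans(tpm[, isM, drop = FALSE])
    log2((mF + pseudocount) / (mM + pseudocount))
}

#' Per-tissue sex expression summary
#'
#' Mean TPM by sex and the log2 female/male fold-change for every gene of
#' one tissue's samples.
#'
#' @param se a \code{SexExpressionSet} with a \code{tpm} assay, restricted
#'   to a single tissue.
#' @inheritParams log2fcSex
#' @return data.frame with \code{gene_symbol}, \code{mean_tpm_female},
#'   \code{mean_tpm_male}, \code{log2fc_sex}.
#' @export
sexBiasTable <- function(se, pseudocount = 0.01) {
    if (!"tpm" %in% assayNames(se))
        stop("run computeTPM() first")
    tpm <- assay(se, "tpm")
    sex <- colData(se)$sex
    isF <- sex == "female"; isM <- sex == "male"
    if (!any(isF) || !any(isM))
        stop("both sexes must be present in the tissue")
    data.frame(
        gene_symbol = rownames(se),
        mean_tpm_female = rowMeans(tpm[, isF, drop = FALSE]),
        mean_tpm_male = rowMeans(tpm[, isM, drop = FALSE]),
        log2fc_sex = log2fcSex(tpm, sex, pseudocount),
        row.names = NULL)
}
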