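#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame metadata metadata<-
#' @importFrom Biostrings RNAStringSet width
NULL

#' Set of transcript variants with gene annotation
#'
#' A \code{TranscriptSet} is an \linkS4class{RNAStringSet} whose elements are
#' normalized transcript sequences (uppercase, \code{T} mapped to \code{U},
#' alphabet restricted to \code{A/C/G/U/N}), named by transcript identifier
#' and carrying a \code{gene_symbol} metadata column. It is the container all
#' sequence-level ligand metrics operate on.
#'
#' @slot .Data inherited from \code{RNAStringSet}.
#' @seealso \code{\link{readTranscriptome}}, \code{\link{profileTranscripts}}
#' @exportClass TranscriptSet
setClass("TranscriptSet", contains = "RNAStringSet")

setValidity("TranscriptSet", function(object) {
    msg <- character()
    if (length(object) == 0L)
        msg <- c(msg, "TranscriptSet must contain at least one transcript")
    ids <- names(object)
    if (is.null(ids) || anyNA(ids) || any(!nzchar(ids)))
        msg <- c(msg, "every transcript must have a non-empty identifier")
    else if (anyDuplicated(ids))
        msg <- c(msg, "transcript identifiers must be unique")
    gs <- mcols(object)$gene_symbol
    if (is.null(gs) || !is.character(gs) || anyNA(gs) || any(!nzchar(gs)))
        msg <- c(msg, "mcols() must carry a non-empty character 'gene_symbol'")
    if (length(object) && any(width(object) < 1L))
        msg <- c(msg, "all sequences must have length >= 1")
    if (length(object)) {
        freq <- Biostrings::alphabetFrequency(object)
        allowed <- c("A", "C", "G", "U", "N")
        bad <- rowSums(freq[, !(colnames(freq) %in% allowed), drop = FALSE])
        if (any(bad > 0))
            msg <- c(msg, paste0("sequences restricted to A/C/G/U/N; offending: ",
                                 paste(utils::head(ids[bad > 0], 5), collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
})

#' Construct a TranscriptSet
#'
#' Normalizes input sequences (uppercasing, DNA \code{T} to RNA \code{U}) and
#' attaches transcript identifiers and gene symbols. Records containing any
#' character outside \code{A/C/G/U/T/N} after uppercasing are rejected with an
#' error naming the record; \code{N} is retained and treated as a
#' non-\code{U}, non-matching base by all downstream metrics.
#'
#' @param sequences character vector of sequences, or an \code{RNAStringSet}.
#' @param transcriptIds character vector of unique transcript identifiers.
#' @param geneSymbols character vector of gene symbols, one per transcript.
#' @return A \code{TranscriptSet}.
#' @examples
#' ts <- TranscriptSet(c("acgt", "UUGG"), c("tx1", "tx2"), c("G1", "G2"))
#' as.character(ts[["tx1"]])  # "ACGU"
#' @export
TranscriptSet <- function(sequences, transcriptIds = names(sequences),
                          geneSymbols) {
    if (is(sequences, "XStringSet"))
        sequences <- as.character(sequences)
    if (!is.character(sequences))
        stop("'sequences' must be a character vector or XStringSet")
    if (is.null(transcriptIds))
        stop("transcript identifiers are required")
    if (any(!nzchar(sequences)))
        stop("empty sequence for record(s): ",
             paste(transcriptIds[!nzchar(sequences)], collapse = ", "))
    seqs <- chartr("Tt", "Uu", toupper(sequences))
    bad <- grepl("[^ACGUN]", seqs)
    if (any(bad))
        stop("invalid characters (outside A/C/G/U/T/N) in record(s): ",
             paste(transcriptIds[bad], collapse = ", "))
    set <- RNAStringSet(seqs)
    names(set) <- as.character(transcriptIds)
    mcols(set) <- DataFrame(gene_symbol = as.character(geneSymbols))
    new("TranscriptSet", set)
}

#' @describeIn TranscriptSet transcript identifiers.
#' @param x a \code{TranscriptSet}.
#' @export
transcriptIds <- function(x) names(x)

#' @describeIn TranscriptSet gene symbols, one per transcript.
#' @export
geneSymbols <- function(x) mcols(x)$gene_symbol

setMethod("show", "TranscriptSet", function(object) {
    cat("TranscriptSet with", length(object), "transcripts covering",
        length(unique(geneSymbols(object))), "genes\n")
    callNextMethod()
})

#' Sex-annotated expression experiment
#'
#' A \code{SexExpressionSet} extends
#' \linkS4class{SummarizedExperiment}: the \code{counts} assay holds
#' non-negative integer read counts (genes x samples), \code{colData}
#' carries \code{sex} (\code{"female"}/\code{"male"}) and \code{tissue} for
#' every sample, and \code{rowData} may carry \code{gene_length} (nt of the
#' selected transcript variant) used for TPM. A \code{tpm} assay is added by
#' \code{\link{computeTPM}}.
#'
#' @seealso \code{\link{filterLowCounts}}, \code{\link{computeTPM}},
#'   \code{\link{log2fcSex}}
#' @exportClass SexExpressionSet
setClass("SexExpressionSet", contains = "SummarizedExperiment")

setValidity("SexExpressionSet", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "a 'counts' assay is required")
    else {
        cts <- SummarizedExperiment::assay(object, "counts")
        if (any(cts < 0, na.rm = TRUE))
            msg <- c(msg, "counts must be non-negative")
    }
    cd <- SummarizedExperiment::colData(object)
    for (col in c("sex", "tissue"))
        if (!col %in% colnames(cd))
            msg <- c(msg, paste0("colData must contain '", col, "'"))
    if ("sex" %in% colnames(cd) &&
        !all(cd$sex %in% c("female", "male")))
        msg <- c(msg, "sex must be 'female' or 'male' for every sample")
    gl <- SummarizedExperiment::rowData(object)$gene_length
    if (!is.null(gl) && any(!is.na(gl) & gl <= 0))
        msg <- c(msg, "gene_length must be positive")
    if (length(msg)) msg else TRUE
})

#' Construct a SexExpressionSet
#'
#' @param counts integer matrix of read counts, genes in rows (rownames are
#'   gene symbols), samples in columns.
#' @param sampleMeta data.frame with columns \code{sample_id}, \code{sex}
#'   (\code{"female"}/\code{"male"}) and \code{tissue}; must cover every
#'   column of \code{counts}.
#' @param geneLengths optional named numeric vector of transcript lengths in
#'   nucleotides (names = gene symbols); required later for TPM.
#' @return A \code{SexExpressionSet}.
#' @export
SexExpressionSet <- function(counts, sampleMeta, geneLengths = NULL) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)) || is.null(colnames(counts)))
        stop("'counts' must have gene rownames and sample colnames")
    req <- c("sample_id", "sex", "tissue")
    if (!all(req %in% colnames(sampleMeta)))
        stop("sampleMeta must contain columns: ", paste(req, collapse = ", "))
    missing <- setdiff(colnames(counts), sampleMeta$sample_id)
    if (length(missing))
        stop("sampleMeta does not cover sample(s): ",
             paste(missing, collapse = ", "))
    sampleMeta <- sampleMeta[match(colnames(counts), sampleMeta$sample_id), ]
    cd <- S4Vectors::DataFrame(sex = as.character(sampleMeta$sex),
                               tissue = as.character(sampleMeta$tissue),
                               row.names = colnames(counts))
    rd <- S4Vectors::DataFrame(row.names = rownames(counts))
    if (!is.null(geneLengths)) {
        gl <- geneLengths[rownames(counts)]
        if (anyNA(gl))
            stop("geneLengths missing for gene(s): ",
                 paste(utils::head(rownames(counts)[is.na(gl)], 5),
                       collapse = ", "))
        rd$gene_length <- as.numeric(gl)
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), colData = cd, rowData = rd)
    new("SexExpressionSet", se)
}

setMethod("show", "SexExpressionSet", function(object) {
    cd <- SummarizedExperiment::colData(object)
    cat("SexExpressionSet:", nrow(object), "genes x", ncol(object),
        "samples;", sum(cd$sex == "female"), "female /",
        sum(cd$sex == "male"), "male;",
        length(unique(cd$tissue)), "tissue(s)\n")
})
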