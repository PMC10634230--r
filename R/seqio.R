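#' Header parsing rule for transcriptome FASTA files
#'
#' FASTA headers are split on \code{delim}; \code{geneField} selects the gene
#' symbol and \code{idField} the transcript identifier. With the defaults a
#' header \code{">G1|tx1"} yields gene \code{G1} and transcript \code{tx1}.
#' A header with a single field supplies both the symbol and the identifier.
#'
#' @param delim single-character field delimiter (default \code{"|"}).
#' @param geneField 1-based index of the gene-symbol field.
#' @param idField 1-based index of the transcript-identifier field.
#' @return A list used as the \code{headerRule} of
#'   \code{\link{readTranscriptome}}.
#' @export
headerRule <- function(delim = "|", geneField = 1L, idField = 2L) {
    stopifnot(nchar(delim) == 1L, geneField >= 1L, idField >= 1L)
    list(delim = delim, geneField = as.integer(geneField),
         idField = as.integer(idField))
}

#' Read a transcriptome FASTA into a TranscriptSet
#'
#' Sequences are uppercased and DNA \code{T} is mapped to RNA \code{U}, so
#' DNA- and RNA-alphabet FASTA files are both accepted. Records containing
#' characters outside \code{A/C/G/U/T/N} are rejected with an error naming
#' the record; \code{N} is retained (it never forms a UU or motif match).
#'
#' @param fastaPath path to a (multi-record, wrapped or unwrapped) FASTA file.
#' @param rule header parsing rule from \code{\link{headerRule}}.
#' @return A \code{\link{TranscriptSet}} in file order.
#' @export
readTranscriptome <- function(fastaPath, rule = headerRule()) {
    if (!file.exists(fastaPath))
        stop("FASTA file not found: ", fastaPath)
    raw <- Biostrings::readBStringSet(fastaPath)
    if (length(raw) == 0L)
        stop("no FASTA records in ", fastaPath)
    headers <- sub("\\s.*$", "", names(raw))
    fields <- strsplit(headers, rule$delim, fixed = TRUE)
    gene <- vapply(fields, function(f) {
        if (length(f) < rule$geneField || !nzchar(f[rule$geneField]))
            NA_character_ else f[rule$geneField]
    }, character(1))
    txid <- vapply(fields, function(f) {
        if (length(f) >= rule$idField && nzchar(f[rule$idField]))
            f[rule$idField]
        else if (length(f) == 1L) f[1L]
        else NA_character_
    }, character(1))
    bad <- is.na(gene) | is.na(txid)
    if (any(bad))
        stop("unparseable FASTA header(s): ",
             paste(utils::head(headers[bad], 5), collapse = ", "))
    TranscriptSet(as.character(raw), transcriptIds = txid, geneSymbols = gene)
}

#' Write a TranscriptSet as FASTA
#'
#' Headers are \code{gene_symbol|transcript_id}, matching the default
#' \code{\link{headerRule}} so the file round-trips through
#' \code{\link{readTranscriptome}}.
#'
#' @param ts a \code{TranscriptSet}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeTranscriptomeFASTA <- function(ts, path) {
    out <- RNAStringSet(as.character(ts))
    names(out) <- paste0(geneSymbols(ts), "|", transcriptIds(ts))
    Biostrings::writeXStringSet(out, path, width = 70L)
    invisible(path)
}

#' Keep one transcript variant per gene: the longest
#'
#' For genes listed with multiple sequence variants only the longest variant
#' is retained; length ties are broken by the lexicographically smallest
#' transcript identifier (C-locale ordering), making the selection
#' deterministic.
#'
#' @param ts a \code{TranscriptSet}.
#' @return A \code{TranscriptSet} with exactly one record per gene symbol,
#'   in first-appearance gene order.
#' @export
selectLongestVariant <- function(ts) {
    gene <- geneSymbols(ts)
    len <- width(ts)
    ids <- transcriptIds(ts)
    ord <- order(match(gene, unique(gene)), -len, ids, method = "radix")
    keep <- ord[!duplicated(gene[ord])]
    ts[sort(keep)]
}

## U-run decomposition of one sequence: start positions and lengths of
## maximal runs of 'U'. All UU statistics derive from it.
.uRuns <- function(chars) {
    r <- rle(chars == "U")
    ends <- cumsum(r$lengths)
    keep <- r$values & r$lengths >= 1L
    list(start = (ends - r$lengths + 1L)[keep], len = r$lengths[keep])
}

.asSeqChars <- function(sequence) {
    if (is(sequence, "XStringSet")) sequence <- as.character(sequence)
    if (is(sequence, "XString")) sequence <- as.character(sequence)
    if (!is.character(sequence))
        stop("'sequence' must be character or a Biostrings object")
    sequence
}

#' Count UU dinucleotides in transcript sequences
#'
#' In \code{"nonoverlapping"} mode (the default) matches of \code{UU} are
#' counted greedily left to right without reuse of a base, so a run of k
#' consecutive U contributes floor(k/2). In \code{"overlapping"} mode every
#' position i with U at both i and i+1 is counted, so the same run
#' contributes k-1.
#'
#' @param sequence character vector of normalized RNA sequences, or a
#'   \code{TranscriptSet}/\code{RNAStringSet}.
#' @param mode counting convention, \code{"nonoverlapping"} or
#'   \code{"overlapping"}.
#' @return Integer vector of UU counts, one per sequence.
#' @examples
#' countUU("GUUGUCAAUGGUCCUUCAA")           # 2
#' countUU("UUU")                            # 1
#' countUU("UUU", mode = "overlapping")      # 2
#' @export
countUU <- function(sequence, mode = c("nonoverlapping", "overlapping")) {
    mode <- match.arg(mode)
    sequence <- .asSeqChars(sequence)
    vapply(strsplit(sequence, "", fixed = TRUE), function(chars) {
        runs <- .uRuns(chars)
        if (mode == "nonoverlapping") sum(runs$len %/% 2L)
        else sum(pmax(runs$len - 1L, 0L))
    }, integer(1))
}

## UU count for every window of length `window` (step 1), positions
## 1..L-window+1. A UU is attributed to a window only when both bases lie
## inside it; nonoverlapping counting restarts greedily at the window edge.
.windowUUCounts <- function(chars, window, mode) {
    L <- length(chars)
    nwin <- L - window + 1L
    runs <- .uRuns(chars)
    counts <- integer(nwin)
    for (k in seq_along(runs$start)) {
        a <- runs$start[k]; b <- a + runs$len[k] - 1L
        if (runs$len[k] < 2L) next
        jlo <- max(1L, a - window + 2L)   # need >= 2 overlapping bases
        jhi <- min(nwin, b - 1L)
        if (jlo > jhi) next
        js <- jlo:jhi
        m <- pmin(b, js + window - 1L) - pmax(a, js) + 1L
        counts[js] <- counts[js] +
            if (mode == "nonoverlapping") m %/% 2L else pmax(m - 1L, 0L)
    }
    counts
}

#' Maximum local UU richness of a transcript
#'
#' Slides a fixed-length window (default 500 nt) one nucleotide at a time
#' over the sequence and reports the largest UU count observed in any window
#' lying fully inside the sequence, together with the (smallest) 1-based
#' start position achieving it. Both bases of a counted UU must lie inside
#' the window. Sequences shorter than the window are treated as a single
#' window: the count is \code{countUU(sequence)} and the start is 1.
#'
#' @param sequence a single RNA sequence (character or Biostrings object).
#' @param window window width in nucleotides (>= 2).
#' @inheritParams countUU
#' @return A list with elements \code{count} and \code{start}.
#' @export
maxWindowUU <- function(sequence, window = 500L,
                        mode = c("nonoverlapping", "overlapping")) {
    mode <- match.arg(mode)
    sequence <- .asSeqChars(sequence)
    stopifnot(length(sequence) == 1L)
    if (window < 2L) stop("'window' must be >= 2")
    chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
    if (length(chars) < window)
        return(list(count = countUU(sequence, mode), start = 1L))
    counts <- .windowUUCounts(chars, as.integer(window), mode)
    list(count = max(counts), start = which.max(counts))
}

#' Windowed UU-richness profile along a transcript
#'
#' The UU count of the fixed-length window starting at every nucleotide
#' position, i.e. the curve whose maximum is \code{\link{maxWindowUU}}. Used
#' to localize UU-dense regions such as the XIST A-repeat region.
#'
#' @inheritParams maxWindowUU
#' @return A data.frame with columns \code{start} (1-based window start) and
#'   \code{uu_count}, one row per start position 1..length-window+1.
#' @export
uuProfile <- function(sequence, window = 500L,
                      mode = c("nonoverlapping", "overlapping")) {
    mode <- match.arg(mode)
    sequence <- .asSeqChars(sequence)
    stopifnot(length(sequence) == 1L)
    if (window < 2L) stop("'window' must be >= 2")
    chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
    if (length(chars) < window)
        stop("sequence (", length(chars), " nt) shorter than window ", window)
    counts <- .windowUUCounts(chars, as.integer(window), mode)
    data.frame(start = seq_along(counts), uu_count = counts)
}

#' Exact-match positions of an RNA motif
#'
#' All (possibly overlapping) exact matches of \code{motif} in the sequence,
#' as ascending 1-based start positions. \code{N} in the sequence never
#' matches.
#'
#' @param sequence a single RNA sequence (character or Biostrings object).
#' @param motif RNA motif over \code{A/C/G/U}; default is the TLR7
#'   stimulatory 9-mer \code{GUCCUUCAA}.
#' @return Integer vector of start positions (possibly empty).
#' @examples
#' findMotif("AGCUUAACCUGUCCUUCAA")  # 11
#' @export
findMotif <- function(sequence, motif = "GUCCUUCAA") {
    sequence <- .asSeqChars(sequence)
    stopifnot(length(sequence) == 1L)
    if (!nzchar(motif) || grepl("[^ACGU]", motif))
        stop("'motif' must be a non-empty string over A/C/G/U")
    hits <- Biostrings::matchPattern(Biostrings::RNAString(motif),
                                     Biostrings::RNAString(sequence))
    sort(BiocGenerics::start(hits))
}

#' Per-gene sequence-level ligand profile
#'
#' Computes, for every transcript in the set, the total UU count, the
#' maximum-window UU richness with its location, and the motif hit
#' positions. Typically run after \code{\link{selectLongestVariant}} so each
#' gene is represented once.
#'
#' @param ts a \code{TranscriptSet}.
#' @param motif motif passed to \code{\link{findMotif}}.
#' @param window window width for \code{\link{maxWindowUU}}.
#' @inheritParams countUU
#' @return A data.frame with columns \code{gene_symbol},
#'   \code{transcript_id}, \code{length}, \code{uu_count},
#'   \code{max_window_uu}, \code{max_window_start}, \code{motif_hits}
#'   (comma-joined positions, \code{""} if none) and \code{has_motif}.
#' @export
profileTranscripts <- function(ts, motif = "GUCCUUCAA", window = 500L,
                               mode = c("nonoverlapping", "overlapping")) {
    mode <- match.arg(mode)
    seqs <- as.character(ts)
    prof <- lapply(seqs, function(s) {
        mw <- maxWindowUU(s, window = window, mode = mode)
        hits <- findMotif(s, motif = motif)
        list(uu = countUU(s, mode = mode), mw = mw, hits = hits)
    })
    data.frame(
        gene_symbol = geneSymbols(ts),
        transcript_id = transcriptIds(ts),
        length = width(ts),
        uu_count = vapply(prof, function(p) p$uu, integer(1)),
        max_window_uu = vapply(prof, function(p) p$mw$count, integer(1)),
        max_window_start = vapply(prof, function(p) as.integer(p$mw$start),
                                  integer(1)),
        motif_hits = vapply(prof, function(p) paste(p$hits, collapse = ","),
                            character(1)),
        has_motif = vapply(prof, function(p) length(p$hits) > 0L, logical(1)),
        row.names = NULL)
}

#' Length of a 1-based, both-ends-inclusive nucleotide interval
#'
#' The coordinate convention used throughout the package: the interval
#' 105..851 spans 747 nt.
#'
#' @param start,end 1-based positions, \code{end >= start}.
#' @return Integer interval length \code{end - start + 1}.
#' @export
intervalLength <- function(start, end) {
    stopifnot(all(end >= start), all(start >= 1))
    as.integer(end - start + 1)
}
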