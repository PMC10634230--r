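#' Ascending ranks with average ties
#'
#' Smallest value gets rank 1; tied values receive the average of the ranks
#' they span, which preserves the rank-sum total.
#'
#' @param values numeric vector without missing values.
#' @return Numeric vector of ranks.
#' @examples
#' rankAscending(c(5, 1, 3))   # 3 1 2
#' rankAscending(c(2, 2, 7))   # 1.5 1.5 3
#' @export
rankAscending <- function(values) {
    if (anyNA(values)) stop("missing values are not allowed in ranking")
    rank(values, ties.method = "average")
}

#' Percentile position of a rank, rounded half-up to two decimals
#'
#' \code{100 * position / n} for a 1-based position in a descending-score
#' ordering, rounded half-up to two decimals: position 4 of 15,003 reports
#' as the top 0.03\%.
#'
#' @param position 1-based rank position (1 = highest score).
#' @param n number of ranked items.
#' @return Numeric percentile(s), two decimals.
#' @export
topPercent <- function(position, n) {
    stopifnot(all(position >= 1), all(position <= n))
    floor(100 * position / n * 100 + 0.5) / 100
}

#' Per-tissue TLR7 ligation score
#'
#' Each gene is ranked in ascending order on four criteria: total UU count,
#' maximum-window UU richness, sex bias (strongest male bias ranked 1,
#' strongest female bias ranked N) and expression level. The ligation score
#' is the sum of the four ranks; a higher score marks a stronger candidate
#' source of TLR7 ligands. Scores are also reported normalized by the
#' tissue's maximum score.
#'
#' @param profile data.frame from \code{\link{profileTranscripts}} (columns
#'   \code{gene_symbol}, \code{uu_count}, \code{max_window_uu}).
#' @param expression named numeric vector of the expression criterion per
#'   gene (by default the mean TPM in female samples of the tissue).
#' @param sexbias named numeric vector of log2 female/male fold-changes.
#' @return data.frame sorted by descending score with columns
#'   \code{gene_symbol}, \code{rank_uu}, \code{rank_maxrichness},
#'   \code{rank_sexbias}, \code{rank_expression}, \code{ligation_score},
#'   \code{normalized_score} and \code{top_percent} (percentile of the
#'   descending-score position, ties taking the best position).
#' @export
ligationScore <- function(profile, expression, sexbias) {
    genes <- profile$gene_symbol
    mism <- c(setdiff(genes, names(expression)),
              setdiff(names(expression), genes),
              setdiff(genes, names(sexbias)),
              setdiff(names(sexbias), genes))
    if (length(mism))
        stop("gene universes differ; symmetric difference: ",
             paste(unique(mism), collapse = ", "))
    expression <- expression[genes]
    sexbias <- sexbias[genes]
    out <- data.frame(
        gene_symbol = genes,
        rank_uu = rankAscending(profile$uu_count),
        rank_maxrichness = rankAscending(profile$max_window_uu),
        rank_sexbias = rankAscending(sexbias),
        rank_expression = rankAscending(expression),
        row.names = NULL)
    out$ligation_score <- out$rank_uu + out$rank_maxrichness +
        out$rank_sexbias + out$rank_expression
    out$normalized_score <- out$ligation_score / max(out$ligation_score)
    pos <- rank(-out$ligation_score, ties.method = "min")
    out$top_percent <- topPercent(pos, nrow(out))
    out[order(-out$ligation_score, out$gene_symbol, method = "radix"), ,
        drop = FALSE]
}

#' Cross-tissue normalized ligation score average
#'
#' Per gene, the mean of the tissue-normalized ligation scores over the
#' tissues in which the gene was analyzed (genes absent from a tissue,
#' e.g. filtered there, are averaged over the tissues where they are
#' present, recorded via \code{n_tissues}).
#'
#' @param tissueTables named list of per-tissue tables from
#'   \code{\link{ligationScore}}.
#' @return data.frame sorted by descending \code{mean_normalized_score} with
#'   columns \code{gene_symbol}, \code{mean_normalized_score},
#'   \code{n_tissues} and \code{top_percent}.
#' @export
normalizeAndAverage <- function(tissueTables) {
    if (length(tissueTables) == 0L) stop("no tissue tables supplied")
    all <- do.call(rbind, lapply(tissueTables, function(tb)
        tb[, c("gene_symbol", "normalized_score")]))
    agg <- stats::aggregate(normalized_score ~ gene_symbol, data = all,
                            FUN = mean)
    ntis <- stats::aggregate(normalized_score ~ gene_symbol, data = all,
                             FUN = length)
    out <- data.frame(gene_symbol = agg$gene_symbol,
                      mean_normalized_score = agg$normalized_score,
                      n_tissues = ntis$normalized_score)
    pos <- rank(-out$mean_normalized_score, ties.method = "min")
    out$top_percent <- topPercent(pos, nrow(out))
    out[order(-out$mean_normalized_score, out$gene_symbol, method = "radix"),
        , drop = FALSE]
}
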