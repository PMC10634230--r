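#' qPCR relative expression by the delta-delta-Ct method
#'
#' Fold change of the target gene in a test sample relative to a calibrator
#' sample, each normalized to a reference gene:
#' 2^-ddCt with ddCt = (Ct_target,test - Ct_ref,test) -
#' (Ct_target,cal - Ct_ref,cal).
#'
#' @param ctTargetTest,ctRefTest Ct of target and reference gene, test
#'   sample.
#' @param ctTargetCal,ctRefCal Ct of target and reference gene, calibrator
#'   sample.
#' @return Fold change (1 when test equals calibrator).
#' @examples
#' ddctFold(20, 18, 24, 18)  # 16
#' @export
ddctFold <- function(ctTargetTest, ctRefTest, ctTargetCal, ctRefCal) {
    stopifnot(is.finite(ctTargetTest), is.finite(ctRefTest),
              is.finite(ctTargetCal), is.finite(ctRefCal))
    ddct <- (ctTargetTest - ctRefTest) - (ctTargetCal - ctRefCal)
    2^(-ddct)
}

#' Relative quantity of transcript released
#'
#' \code{2^(Ct_ref - Ct_target) * R}, where R is the RNA-yield ratio of
#' treated (e.g. UV-irradiated) over live cells. The exponent is oriented so
#' that a more abundant target (lower target Ct) gives a larger output; the
#' result scales linearly in R.
#'
#' @param ctTarget,ctRef cycle thresholds of the target and reference gene.
#' @param R RNA-yield ratio, must be positive.
#' @return Relative quantity released.
#' @examples
#' relativeQuantityReleased(15, 18, 2)  # 2^3 * 2 = 16
#' @export
relativeQuantityReleased <- function(ctTarget, ctRef, R) {
    if (any(R <= 0)) stop("'R' must be positive")
    2^(ctRef - ctTarget) * R
}

#' SEAP reporter fold induction
#'
#' \code{(A_treated - A_untreated) / (A_comparator - A_untreated)}: the
#' absorbance gain of the treated well over background, relative to the gain
#' of a comparator (mock transfection or polyA) well. Returns \code{NaN}
#' when the comparator delta is zero (fold induction undefined).
#'
#' @param absorbanceTreated,absorbanceComparator,absorbanceUntreated optical
#'   densities of the treated, comparator and untreated wells.
#' @return Fold induction (1 when treated equals comparator, 0 when treated
#'   equals untreated).
#' @examples
#' foldInduction(0.9, 0.5, 0.3)  # 3
#' @export
foldInduction <- function(absorbanceTreated, absorbanceComparator,
                          absorbanceUntreated) {
    d0 <- absorbanceComparator - absorbanceUntreated
    dA <- absorbanceTreated - absorbanceUntreated
    ifelse(d0 == 0, NaN, dA / d0)
}
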