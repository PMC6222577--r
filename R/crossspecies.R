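#' Map mouse gene symbols to human symbols
#'
#' Default rule: uppercase the mouse symbol (Gpnmb -> GPNMB), the usual
#' mouse-to-human naming convention. A two-column ortholog table
#' (\code{mouse}, \code{human}) overrides the default per symbol, for
#' genes whose human ortholog carries a different name (e.g. Dtr ->
#' HBEGF).
#'
#' @param symbols character vector of mouse symbols.
#' @param ortholog_table optional data.frame with columns mouse, human.
#' @return named character vector, mouse symbol -> human symbol.
#' @export
mapSymbols <- function(symbols, ortholog_table = NULL) {
    out <- stats::setNames(toupper(symbols), symbols)
    if (!is.null(ortholog_table)) {
        if (!all(c("mouse", "human") %in% colnames(ortholog_table)))
            stop("ortholog table must have columns mouse, human",
                 call. = FALSE)
        if (anyDuplicated(ortholog_table$mouse))
            stop("duplicate mouse symbol in ortholog table", call. = FALSE)
        hit <- match(symbols, ortholog_table$mouse)
        out[!is.na(hit)] <- ortholog_table$human[hit[!is.na(hit)]]
    }
    out
}

#' Cross-species concordance of candidate genes
#'
#' Looks each candidate up in a human differential-expression summary
#' table (symbol, logFC, p_value) after symbol mapping, and classifies:
#' \itemize{
#'   \item \code{concordant}: human p < alpha and the human logFC has the
#'     same sign as the mouse logFC;
#'   \item \code{discordant}: human p < alpha, opposite sign;
#'   \item \code{not_significant}: present in the human table with
#'     p >= alpha;
#'   \item \code{absent}: unmapped or missing from the human table.
#' }
#' Candidates are never dropped. \code{human_fc_linear = TRUE} declares
#' the human fold-change column to be on the linear scale and log2 is
#' taken before comparing signs.
#'
#' @param candidates data.frame from \code{\link{overlayCandidates}}
#'   (columns symbol, logFC).
#' @param human data.frame with columns symbol, logFC, p_value.
#' @param alpha significance level in (0, 1), default 0.05.
#' @param ortholog_table optional override table for
#'   \code{\link{mapSymbols}}.
#' @param human_fc_linear human fold changes are linear, not log2.
#' @return data.frame with columns symbol, human_symbol, human_logFC,
#'   human_p, status, alpha; one row per candidate.
#' @export
concordance <- function(candidates, human, alpha = 0.05,
                        ortholog_table = NULL, human_fc_linear = FALSE) {
    if (!(alpha > 0 && alpha < 1))
        stop("alpha must lie in (0, 1)", call. = FALSE)
    hsym <- mapSymbols(candidates$symbol, ortholog_table)
    hit <- match(hsym, human$symbol)
    hfc <- human$logFC[hit]
    if (human_fc_linear) hfc <- log2(hfc)
    hp <- human$p_value[hit]
    status <- rep("absent", nrow(candidates))
    present <- !is.na(hit)
    sig <- present & !is.na(hp) & hp < alpha & !is.na(hfc)
    same <- !is.na(hfc) & sign(hfc) == sign(candidates$logFC)
    status[present & !sig] <- "not_significant"
    status[sig & same] <- "concordant"
    status[sig & !same] <- "discordant"
    data.frame(symbol = candidates$symbol,
               human_symbol = unname(hsym),
               human_logFC = hfc,
               human_p = hp,
               status = status,
               alpha = alpha,
               row.names = NULL)
}
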