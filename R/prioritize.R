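## Candidate nomination: collapse probe-level top lists to gene symbols
## and intersect the differential-expression and trait-correlation lists.
## Known markers are flagged, never removed.

#' Default known circulating-marker symbols
#'
#' Established heart-failure plasma markers used to flag (not filter)
#' non-novel candidates: natriuretic peptide B, TIMP metallopeptidase
#' inhibitor 1, galectin-3 and osteopontin.
#' @export
knownMarkersDefault <- c("Nppb", "Timp1", "Lgals3", "Spp1")

collapseToSymbols <- function(tab, stat_col, collapse = c("extreme", "mean")) {
    collapse <- match.arg(collapse)
    tab <- tab[!is.na(tab$symbol) & tab$symbol != "", , drop = FALSE]
    if (nrow(tab) == 0L) return(tab)
    if (collapse == "extreme") {
        ord <- order(-abs(tab[[stat_col]]))
        tab <- tab[ord, , drop = FALSE]
        tab <- tab[!duplicated(tab$symbol), , drop = FALSE]
    } else {
        agg <- stats::aggregate(tab[[stat_col]], list(symbol = tab$symbol),
                                mean)
        ord <- order(-abs(tab[[stat_col]]))
        first <- tab[ord, , drop = FALSE]
        first <- first[!duplicated(first$symbol), , drop = FALSE]
        first[[stat_col]] <- agg$x[match(first$symbol, agg$symbol)]
        tab <- first
    }
    rownames(tab) <- NULL
    tab
}

#' Symbol-level top differentially expressed list
#'
#' Filters a DE table by absolute logFC and/or adjusted p, or truncates to
#' the strongest \code{top_k} probes, then collapses probes to symbols
#' keeping the probe with the largest |logFC| (or the symbol-mean logFC
#' with \code{collapse = "mean"}).
#'
#' @param de_table data.frame from \code{\link{runDE}} (or the packaged
#'   reference table); needs columns symbol, logFC and (if \code{max_p}
#'   is used) p_adj or p_value.
#' @param min_abs_logfc minimum |logFC| to retain.
#' @param top_k alternatively, keep the k largest |logFC| probes.
#' @param max_p maximum adjusted p (column p_adj, falling back to
#'   p_value when p_adj is absent or all-NA).
#' @param collapse probe-to-symbol rule.
#' @return symbol-level data.frame sorted by |logFC| descending.
#' @export
topDE <- function(de_table, min_abs_logfc = NULL, top_k = NULL,
                  max_p = NULL, collapse = c("extreme", "mean")) {
    if (is.null(min_abs_logfc) && is.null(top_k))
        stop("set at least one of 'min_abs_logfc' or 'top_k'",
             call. = FALSE)
    tab <- de_table
    if (!is.null(max_p)) {
        pcol <- if ("p_adj" %in% names(tab) && !all(is.na(tab$p_adj)))
            tab$p_adj else tab$p_value
        tab <- tab[!is.na(pcol) & pcol <= max_p, , drop = FALSE]
    }
    if (!is.null(min_abs_logfc))
        tab <- tab[abs(tab$logFC) >= min_abs_logfc, , drop = FALSE]
    if (!is.null(top_k)) {
        tab <- tab[order(-abs(tab$logFC)), , drop = FALSE]
        tab <- utils::head(tab, top_k)
    }
    tab <- collapseToSymbols(tab, "logFC", match.arg(collapse))
    tab[order(-abs(tab$logFC)), , drop = FALSE]
}

#' Symbol-level top trait-correlated list
#'
#' Analogous to \code{\link{topDE}}: filter by correlation p and/or
#' truncate to the k largest |r|, collapse probes to symbols keeping the
#' probe with the largest |r|.
#'
#' @param corr_table data.frame from \code{\link{correlateTrait}} (or the
#'   packaged reference table); needs columns symbol, cor, p_value.
#' @param max_p maximum correlation p-value.
#' @param top_k alternatively, keep the k largest |r| probes.
#' @param collapse probe-to-symbol rule.
#' @return symbol-level data.frame sorted by |cor| descending.
#' @export
topCorr <- function(corr_table, max_p = NULL, top_k = NULL,
                    collapse = c("extreme", "mean")) {
    if (is.null(max_p) && is.null(top_k))
        stop("set at least one of 'max_p' or 'top_k'", call. = FALSE)
    tab <- corr_table
    if (!is.null(max_p))
        tab <- tab[!is.na(tab$p_value) & tab$p_value <= max_p, ,
                   drop = FALSE]
    if (!is.null(top_k)) {
        tab <- tab[order(-abs(tab$cor)), , drop = FALSE]
        tab <- utils::head(tab, top_k)
    }
    tab <- collapseToSymbols(tab, "cor", match.arg(collapse))
    tab[order(-abs(tab$cor)), , drop = FALSE]
}

#' Overlay top DE and top correlated lists into candidate records
#'
#' The candidate set is the symbol intersection of the two lists. Each
#' record carries the best (largest-|statistic|) logFC and correlation
#' with their directions, and a novelty flag: symbols in
#' \code{known_markers} are flagged \code{novel = FALSE} but retained.
#' Records are ordered by |cor| descending.
#'
#' @param top_de_list symbol-level data.frame from \code{\link{topDE}}.
#' @param top_corr_list symbol-level data.frame from \code{\link{topCorr}}.
#' @param known_markers character vector of established marker symbols.
#' @return data.frame with columns symbol, de_probe, corr_probe, logFC,
#'   cor, de_direction (up/down), corr_direction (pos/neg), novel.
#' @export
overlayCandidates <- function(top_de_list, top_corr_list,
                              known_markers = knownMarkersDefault) {
    syms <- intersect(top_de_list$symbol, top_corr_list$symbol)
    de <- top_de_list[match(syms, top_de_list$symbol), , drop = FALSE]
    co <- top_corr_list[match(syms, top_corr_list$symbol), , drop = FALSE]
    de_probe <- if ("probe_id" %in% names(de)) de$probe_id
        else rep(NA_character_, length(syms))
    corr_probe <- if ("probe_id" %in% names(co)) co$probe_id
        else rep(NA_character_, length(syms))
    out <- data.frame(symbol = syms,
                      de_probe = de_probe,
                      corr_probe = corr_probe,
                      logFC = de$logFC,
                      cor = co$cor,
                      de_direction = ifelse(de$logFC >= 0, "up", "down"),
                      corr_direction = ifelse(co$cor >= 0, "pos", "neg"),
                      novel = !(syms %in% known_markers),
                      row.names = NULL)
    out <- out[order(-abs(out$cor)), , drop = FALSE]
    rownames(out) <- NULL
    out
}
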