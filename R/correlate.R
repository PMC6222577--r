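#' Strain-level expression summaries
#'
#' Arithmetic mean over replicates, per strain, within one treatment arm.
#' Strains with no samples in the requested arm are omitted.
#'
#' @param panel an \linkS4class{ExpressionPanel}.
#' @param arm \code{"treated"} (default; endpoint expression) or
#'   \code{"control"}.
#' @return strain x probe numeric matrix of means.
#' @export
strainSummarize <- function(panel, arm = c("treated", "control")) {
    arm <- match.arg(arm)
    meta <- sampleMeta(panel)
    keep <- meta$treatment == arm
    if (!any(keep))
        stop("arm '", arm, "' has no samples", call. = FALSE)
    v <- exprValues(panel)[, keep, drop = FALSE]
    strain <- meta$strain[keep]
    g <- factor(strain, levels = unique(strain))
    ## rowsum sums columns within strain; divide by replicate counts
    sums <- rowsum(t(v), g)
    sums / as.vector(table(g))
}

#' Correlate strain-level expression with a quantitative trait
#'
#' Joins the strain x probe summary matrix with the per-strain trait on
#' strain id (pairwise-complete: strains with a missing trait are
#' dropped), then computes per-probe Pearson (default) or Spearman
#' correlation. The two-sided p-value uses the t transform
#' \code{t = r * sqrt((n - 2) / (1 - r^2))} on n - 2 degrees of freedom;
#' Spearman is Pearson on midranks with the same transform. Zero-variance
#' probes get r = 0, p = 1 and a \code{degenerate} flag. Rows are sorted
#' by p ascending.
#'
#' @param strain_expr strain x probe matrix from
#'   \code{\link{strainSummarize}}.
#' @param trait data.frame with columns strain, trait_delta.
#' @param method \code{"pearson"} or \code{"spearman"}.
#' @param annotation optional probe annotation (probe_id, symbol).
#' @return data.frame with columns probe_id, symbol, cor, p_value, n,
#'   degenerate.
#' @export
correlateTrait <- function(strain_expr, trait,
                           method = c("pearson", "spearman"),
                           annotation = NULL) {
    method <- match.arg(method)
    trait <- trait[is.finite(trait$trait_delta), , drop = FALSE]
    common <- intersect(rownames(strain_expr), trait$strain)
    if (length(common) < 3L)
        stop("fewer than 3 strains common to expression and trait",
             call. = FALSE)
    x <- strain_expr[common, , drop = FALSE]
    y <- trait$trait_delta[match(common, trait$strain)]
    n <- length(common)
    if (method == "spearman") {
        x <- apply(x, 2L, rank)
        y <- rank(y)
    }
    xc <- sweep(x, 2L, colMeans(x))
    yc <- y - mean(y)
    sx <- sqrt(colSums(xc^2))
    sy <- sqrt(sum(yc^2))
    degenerate <- sx == 0 | sy == 0
    r <- numeric(ncol(x))
    r[!degenerate] <- as.numeric(crossprod(xc[, !degenerate, drop = FALSE],
                                           yc)) / (sx[!degenerate] * sy)
    r <- pmin(1, pmax(-1, r))
    p <- rep(1, ncol(x))
    ok <- !degenerate & abs(r) < 1
    tstat <- r[ok] * sqrt((n - 2) / (1 - r[ok]^2))
    p[ok] <- 2 * stats::pt(-abs(tstat), df = n - 2)
    p[!degenerate & abs(r) == 1] <- 0
    sym <- rep(NA_character_, ncol(x))
    if (!is.null(annotation))
        sym <- annotation$symbol[match(colnames(x), annotation$probe_id)]
    out <- data.frame(probe_id = colnames(x), symbol = sym, cor = r,
                      p_value = p, n = n, degenerate = degenerate,
                      row.names = NULL)
    out <- out[order(out$p_value, -abs(out$cor), out$probe_id), ]
    rownames(out) <- NULL
    out
}
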