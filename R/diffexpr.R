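## Two-group differential expression with empirical-Bayes moderated
## t-statistics. The per-probe residual variances are shrunk toward a
## common prior (d0, s0^2) estimated by closed-form moment matching of
## log s_g^2 against a scaled-F distribution; the moderated t is
##   t_g = logFC_g / (s_tilde_g * u),  s_tilde_g^2 = (d0 s0^2 + d_g s_g^2)
##                                                  / (d0 + d_g)
## with u the design scale sqrt(1/n1 + 1/n2) and d0 + d_g degrees of
## freedom. d0 = 0 reduces to the ordinary t-test; d0 = Inf pools all
## probes to the common variance s0^2.

#' Log2 fold change of one probe
#'
#' Treated-arm mean minus control-arm mean on the log2 scale.
#'
#' @param panel an \linkS4class{ExpressionPanel}.
#' @param probe probe id.
#' @return numeric log2 ratio.
#' @export
logFoldChange <- function(panel, probe) {
    v <- exprValues(panel)
    if (!probe %in% rownames(v))
        stop("unknown probe: ", probe, call. = FALSE)
    arm <- sampleMeta(panel)$treatment
    if (!all(c("control", "treated") %in% arm))
        stop("both arms must have at least one sample", call. = FALSE)
    mean(v[probe, arm == "treated"]) - mean(v[probe, arm == "control"])
}

#' Inverse of the trigamma function
#'
#' Newton iteration on 1/trigamma, used by the variance-prior moment
#' equations. Monotone decreasing; accurate to ~1e-8.
#'
#' @param x positive numeric vector.
#' @return y with trigamma(y) = x.
#' @export
trigammaInverse <- function(x) {
    vapply(x, function(xi) {
        if (!is.finite(xi)) return(NaN)
        if (xi > 1e7) return(1 / sqrt(xi))
        if (xi < 1e-6) return(1 / xi)
        y <- 0.5 + 1 / xi
        for (i in 1:50) {
            tri <- trigamma(y)
            dif <- tri * (1 - tri / xi) / psigamma(y, 2L)
            y <- y + dif
            if (-dif / y < 1e-8) break
        }
        y
    }, numeric(1))
}

#' Estimate the variance prior (d0, s0^2) by moment matching
#'
#' Fits a scaled-F distribution to the per-probe sample variances: with
#' z_g = log s_g^2, e_g = z_g - digamma(d_g/2) + log(d_g/2) has mean
#' log s0^2 + digamma(d0/2) - log(d0/2) and variance trigamma(d_g/2) +
#' trigamma(d0/2). Solving the excess-variance equation for d0 gives the
#' prior degrees of freedom. When the excess variance is <= 0 the
#' variances are under-dispersed relative to any finite prior and the
#' limit d0 = Inf (complete pooling) is returned.
#'
#' @param s2 per-probe residual variances (length >= 2).
#' @param df residual degrees of freedom (recycled).
#' @return list(d0, s0) with s0 the prior variance s0^2.
#' @export
estimateVariancePrior <- function(s2, df) {
    if (length(s2) < 2L)
        stop("need at least 2 probes to estimate a variance prior",
             call. = FALSE)
    df <- rep_len(df, length(s2))
    if (any(df < 1))
        stop("all residual df must be >= 1", call. = FALSE)
    if (all(s2 == 0))
        stop("all residual variances are zero: degenerate data",
             call. = FALSE)
    ok <- s2 > 0
    z <- log(s2[ok])
    e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
    emean <- mean(e)
    n <- length(e)
    evar <- mean((e - emean)^2) * n / (n - 1) - mean(trigamma(df[ok] / 2))
    if (is.finite(evar) && evar > 0) {
        d0 <- 2 * trigammaInverse(evar)
        s0 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
        d0 <- Inf
        s0 <- exp(emean)
    }
    list(d0 = d0, s0 = s0)
}

#' Moderated t-statistics from per-probe variances
#'
#' @param logfc per-probe log2 fold changes.
#' @param s2 per-probe residual variances.
#' @param df per-probe residual degrees of freedom (recycled).
#' @param u design scale: the standard error of logFC is s_g * u (for a
#'   two-group comparison, sqrt(1/n1 + 1/n2)).
#' @param d0,s0 variance prior; estimated from the data when NULL. Forcing
#'   \code{d0 = 0} yields the ordinary t-test.
#' @return data.frame with t_mod, p_raw, df_total, s2_post and the prior
#'   used (attributes d0, s0).
#' @export
moderatedT <- function(logfc, s2, df, u, d0 = NULL, s0 = NULL) {
    df <- rep_len(df, length(s2))
    if (is.null(d0) || is.null(s0)) {
        prior <- estimateVariancePrior(s2, df)
        if (is.null(d0)) d0 <- prior$d0
        if (is.null(s0)) s0 <- prior$s0
    }
    if (is.infinite(d0)) {
        s2_post <- rep_len(s0, length(s2))
        df_total <- rep_len(Inf, length(s2))
    } else if (d0 == 0) {
        s2_post <- s2
        df_total <- df
    } else {
        s2_post <- (d0 * s0 + df * s2) / (d0 + df)
        df_total <- d0 + df
    }
    t_mod <- logfc / (sqrt(s2_post) * u)
    p_raw <- 2 * stats::pt(-abs(t_mod), df = df_total)
    out <- data.frame(t_mod = t_mod, p_raw = p_raw, df_total = df_total,
                      s2_post = s2_post)
    attr(out, "d0") <- d0
    attr(out, "s0") <- s0
    out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement: the i-th smallest
#' p becomes min over j >= i of p_(j) * m / j, capped at 1. Order
#' preserving and elementwise >= the input.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values in the original order.
#' @export
bhAdjust <- function(p) {
    if (length(p) == 0L) return(numeric(0))
    if (any(!is.finite(p)) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1]", call. = FALSE)
    m <- length(p)
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

#' Panel-wide differential expression
#'
#' Computes per-probe logFC (treated minus control), AveExpr (the plain
#' arithmetic mean of the probe's log2 values over all samples), the
#' empirical-Bayes moderated t, raw and BH-adjusted p-values. Rows are
#' sorted by |logFC| descending (ties by raw p ascending, then probe id),
#' mirroring how top tables are usually reported; \code{sort_by = "p"}
#' sorts by raw p instead.
#'
#' @param panel an \linkS4class{ExpressionPanel} with both arms.
#' @param annotation optional probe annotation data.frame (probe_id,
#'   symbol); unannotated probes keep an NA symbol.
#' @param d0 optional forced prior df (0 = ordinary t-test).
#' @param sort_by \code{"logFC"} (default) or \code{"p"}.
#' @return data.frame with columns probe_id, symbol, logFC, AveExpr,
#'   t_mod, p_raw, p_adj, df_total; attributes d0/s0 carry the estimated
#'   variance prior.
#' @export
runDE <- function(panel, annotation = NULL, d0 = NULL,
                  sort_by = c("logFC", "p")) {
    sort_by <- match.arg(sort_by)
    v <- exprValues(panel)
    arm <- sampleMeta(panel)$treatment
    n1 <- sum(arm == "control"); n2 <- sum(arm == "treated")
    if (n1 < 1L || n2 < 1L)
        stop("both arms must have at least one sample", call. = FALSE)
    if (n1 + n2 < 3L)
        stop("need at least 3 samples for residual variance", call. = FALSE)
    mc <- rowMeans(v[, arm == "control", drop = FALSE])
    mt <- rowMeans(v[, arm == "treated", drop = FALSE])
    logfc <- mt - mc
    ave <- rowMeans(v)
    ## pooled two-group residual variance per probe
    ssc <- rowSums((v[, arm == "control", drop = FALSE] - mc)^2)
    sst <- rowSums((v[, arm == "treated", drop = FALSE] - mt)^2)
    df <- n1 + n2 - 2L
    s2 <- (ssc + sst) / df
    u <- sqrt(1 / n1 + 1 / n2)
    s0 <- NULL
    if (!is.null(d0) && d0 == 0) s0 <- 0   # any value; unused at d0 = 0
    mt_res <- moderatedT(logfc, s2, df, u, d0 = d0, s0 = s0)
    sym <- rep(NA_character_, nrow(v))
    if (!is.null(annotation))
        sym <- annotation$symbol[match(rownames(v), annotation$probe_id)]
    out <- data.frame(probe_id = rownames(v), symbol = sym,
                      logFC = logfc, AveExpr = ave,
                      t_mod = mt_res$t_mod, p_raw = mt_res$p_raw,
                      p_adj = bhAdjust(mt_res$p_raw),
                      df_total = mt_res$df_total,
                      row.names = NULL)
    ord <- if (sort_by == "logFC")
        order(-abs(out$logFC), out$p_raw, out$probe_id)
    else order(out$p_raw, -abs(out$logFC), out$probe_id)
    out <- out[ord, ]
    rownames(out) <- NULL
    attr(out, "d0") <- attr(mt_res, "d0")
    attr(out, "s0") <- attr(mt_res, "s0")
    out
}
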