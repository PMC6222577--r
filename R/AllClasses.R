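#' ExpressionPanel: log2 expression across a strain panel
#'
#' An \code{ExpressionPanel} holds a probe-by-sample matrix of log2
#' intensities together with per-sample metadata (inbred strain, treatment
#' arm, replicate index). It extends
#' \link[SummarizedExperiment]{SummarizedExperiment}, so all the usual
#' subsetting and accessor machinery applies; the single assay is named
#' \code{"log2expr"}.
#'
#' Validity requires finite values, unique probe ids, and a treatment arm
#' of \code{"control"} or \code{"treated"} for every sample.
#'
#' @slot .. see \link[SummarizedExperiment]{SummarizedExperiment}
#' @aliases ExpressionPanel-class
#' @exportClass ExpressionPanel
setClass("ExpressionPanel", contains = "SummarizedExperiment")

setValidity("ExpressionPanel", function(object) {
    msg <- character()
    if (!"log2expr" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'log2expr' is required")
    else {
        v <- SummarizedExperiment::assay(object, "log2expr")
        if (!is.numeric(v) || any(!is.finite(v)))
            msg <- c(msg, "all log2 expression values must be finite numbers")
    }
    rn <- rownames(object)
    if (is.null(rn) || anyDuplicated(rn))
        msg <- c(msg, "probe ids (rownames) must be present and unique")
    cd <- SummarizedExperiment::colData(object)
    need <- c("strain", "treatment", "replicate")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        msg <- c(msg, paste0("sample metadata lacks column(s): ",
                             paste(miss, collapse = ", ")))
    else if (!all(cd$treatment %in% c("control", "treated")))
        msg <- c(msg, "treatment must be 'control' or 'treated'")
    if (length(msg)) msg else TRUE
})

#' Construct an ExpressionPanel
#'
#' @param values numeric matrix of log2 intensities, probes in rows (rownames
#'   are probe ids), samples in columns (colnames are sample ids).
#' @param strain character vector, one strain id per sample.
#' @param treatment character vector, \code{"control"} or \code{"treated"}.
#' @param replicate integer replicate index within strain and arm; derived
#'   automatically when omitted.
#' @return an \linkS4class{ExpressionPanel}.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("probe", 1:3), paste0("s", 1:4)))
#' ExpressionPanel(m, strain = c("A", "A", "B", "B"),
#'                 treatment = c("control", "treated", "control", "treated"))
#' @export
ExpressionPanel <- function(values, strain, treatment, replicate = NULL) {
    values <- as.matrix(values)
    if (is.null(colnames(values)))
        colnames(values) <- paste0("sample", seq_len(ncol(values)))
    if (length(strain) != ncol(values) || length(treatment) != ncol(values))
        stop("strain and treatment must have one entry per sample column",
             call. = FALSE)
    strain <- as.character(strain)
    treatment <- as.character(treatment)
    if (is.null(replicate)) {
        replicate <- stats::ave(seq_along(strain),
                                paste(strain, treatment),
                                FUN = seq_along)
    }
    cd <- S4Vectors::DataFrame(sample_id = colnames(values),
                               strain = strain,
                               treatment = treatment,
                               replicate = as.integer(replicate),
                               row.names = colnames(values))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(log2expr = values), colData = cd)
    methods::new("ExpressionPanel", se)
}

#' LogisticFit: IRLS logistic-regression result
#'
#' Per-term log-odds coefficients with standard errors, Wald odds ratios and
#' 95\% confidence intervals, together with convergence diagnostics: the
#' iteration count, the log-likelihood trace across iterations, the maximum
#' absolute score (gradient) at the final iterate, and flags for
#' non-convergence and (quasi-)separation.
#'
#' @slot coefTable data.frame with columns term, estimate, se, or, ci_lo,
#'   ci_hi, z, p_value.
#' @slot converged logical, max |score| below tolerance at exit.
#' @slot iterations integer number of Newton/IRLS iterations performed.
#' @slot logLik numeric final Bernoulli log-likelihood.
#' @slot llTrace numeric log-likelihood after each iteration.
#' @slot maxScore numeric max absolute gradient component at exit.
#' @slot separation logical, fitted probabilities pinned at 0/1 with
#'   diverging coefficients.
#' @slot n integer number of observations.
#' @exportClass LogisticFit
setClass("LogisticFit",
    representation(coefTable = "data.frame",
                   converged = "logical",
                   iterations = "integer",
                   logLik = "numeric",
                   llTrace = "numeric",
                   maxScore = "numeric",
                   separation = "logical",
                   n = "integer"))

#' @importMethodsFrom methods show
setMethod("show", "ExpressionPanel", function(object) {
    cd <- SummarizedExperiment::colData(object)
    cat("ExpressionPanel:", nrow(object), "probes x", ncol(object),
        "samples\n")
    cat("  strains:", length(unique(cd$strain)),
        " arms:", paste(sort(unique(cd$treatment)), collapse = "/"), "\n")
    invisible(object)
})

setMethod("show", "LogisticFit", function(object) {
    cat("Logistic regression (IRLS), n =", object@n, "\n")
    cat(sprintf("  converged: %s after %d iterations (max |score| %.3g)\n",
                object@converged, object@iterations, object@maxScore))
    if (object@separation)
        cat("  WARNING: (quasi-)separation detected; estimates unreliable\n")
    tab <- object@coefTable
    tab$or <- sprintf("%.3f (%.3f-%.3f)", tab$or, tab$ci_lo, tab$ci_hi)
    print(tab[, c("term", "estimate", "se", "or", "p_value")],
          row.names = FALSE, digits = 4)
    invisible(object)
})
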