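#' Accessors for ExpressionPanel objects
#'
#' \code{exprValues} returns the log2 intensity matrix; \code{sampleMeta}
#' the per-sample metadata as a plain data.frame; \code{panelStrains} the
#' unique strain ids; \code{panelArms} the treatment arms present.
#'
#' @param x an \linkS4class{ExpressionPanel}.
#' @return matrix, data.frame or character vector as described.
#' @name panel-accessors
NULL

#' @rdname panel-accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname panel-accessors
#' @export
setGeneric("sampleMeta", function(x) standardGeneric("sampleMeta"))

#' @rdname panel-accessors
#' @export
setGeneric("panelStrains", function(x) standardGeneric("panelStrains"))

#' @rdname panel-accessors
#' @export
setGeneric("panelArms", function(x) standardGeneric("panelArms"))

#' @rdname panel-accessors
setMethod("exprValues", "ExpressionPanel", function(x)
    SummarizedExperiment::assay(x, "log2expr"))

#' @rdname panel-accessors
setMethod("sampleMeta", "ExpressionPanel", function(x)
    as.data.frame(SummarizedExperiment::colData(x)))

#' @rdname panel-accessors
setMethod("panelStrains", "ExpressionPanel", function(x)
    unique(as.character(SummarizedExperiment::colData(x)$strain)))

#' @rdname panel-accessors
setMethod("panelArms", "ExpressionPanel", function(x)
    sort(unique(as.character(SummarizedExperiment::colData(x)$treatment))))

#' Coefficient table of a logistic fit
#'
#' @param x a \linkS4class{LogisticFit}.
#' @return data.frame with columns term, estimate, se, or, ci_lo, ci_hi,
#'   z, p_value.
#' @export
setGeneric("coefTable", function(x) standardGeneric("coefTable"))

#' @rdname coefTable
setMethod("coefTable", "LogisticFit", function(x) x@coefTable)
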