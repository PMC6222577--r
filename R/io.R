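## Tabular I/O. All text formats are TSV/CSV with a header row, UTF-8,
## '.' decimal; gene symbols are stored case-preserving. Missing trait
## values are empty cells and are dropped pairwise downstream.

#' Read a strain-panel expression matrix and its sample metadata
#'
#' The expression file is TSV with probe ids in the first column and one
#' column per sample; the metadata file is TSV with columns
#' \code{sample_id}, \code{strain}, \code{treatment} (and optionally
#' \code{replicate}). Column order of the matrix is preserved. Every sample
#' column must have a metadata row.
#'
#' @param path path to the expression TSV.
#' @param meta_path path to the sample-metadata TSV.
#' @return an \linkS4class{ExpressionPanel}.
#' @export
readExpression <- function(path, meta_path) {
    stopifnot(file.exists(path), file.exists(meta_path))
    tab <- utils::read.delim(path, check.names = FALSE,
                             colClasses = "character")
    probes <- tab[[1L]]
    m <- as.matrix(tab[, -1L, drop = FALSE])
    suppressWarnings(storage <- matrix(as.numeric(m), nrow(m), ncol(m),
                                       dimnames = list(probes, colnames(m))))
    if (anyNA(storage)) {
        bad <- which(is.na(storage), arr.ind = TRUE)[1L, ]
        stop(sprintf("non-numeric expression value at probe '%s', sample '%s'",
                     probes[bad[1L]], colnames(m)[bad[2L]]), call. = FALSE)
    }
    meta <- utils::read.delim(meta_path, colClasses = "character")
    if (!all(c("sample_id", "strain", "treatment") %in% colnames(meta)))
        stop("metadata must have columns sample_id, strain, treatment",
             call. = FALSE)
    missing <- setdiff(colnames(storage), meta$sample_id)
    if (length(missing))
        stop("samples present in matrix but absent from metadata: ",
             paste(missing, collapse = ", "), call. = FALSE)
    meta <- meta[match(colnames(storage), meta$sample_id), ]
    rep <- if ("replicate" %in% colnames(meta))
        as.integer(meta$replicate) else NULL
    ExpressionPanel(storage, strain = meta$strain,
                    treatment = meta$treatment, replicate = rep)
}

#' Write an ExpressionPanel to expression + metadata TSV files
#'
#' @param panel an \linkS4class{ExpressionPanel}.
#' @param path,meta_path output file paths.
#' @return invisibly, the panel.
#' @export
writeExpression <- function(panel, path, meta_path) {
    v <- exprValues(panel)
    df <- data.frame(probe_id = rownames(v), v, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(sampleMeta(panel), meta_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(panel)
}

#' Read or write a per-strain trait table
#'
#' TSV with columns \code{strain} and \code{trait_delta} (e.g. the change
#' in left ventricular internal dimension, mm). Empty trait cells become
#' \code{NA} and are dropped pairwise by downstream correlation.
#'
#' @param path file path.
#' @return data.frame with columns strain, trait_delta.
#' @export
readTrait <- function(path) {
    tab <- utils::read.delim(path, colClasses = c("character", "numeric"))
    if (!all(c("strain", "trait_delta") %in% colnames(tab)))
        stop("trait table must have columns strain, trait_delta",
             call. = FALSE)
    if (anyDuplicated(tab$strain))
        stop("trait table has duplicated strain ids", call. = FALSE)
    tab
}

#' @rdname readTrait
#' @param trait data.frame with columns strain, trait_delta.
#' @export
writeTrait <- function(trait, path) {
    utils::write.table(trait, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(trait)
}

#' Read or write a probe annotation table
#'
#' TSV with columns \code{probe_id}, \code{symbol}, \code{species}.
#' Probe ids must be unique; a symbol may map to several probes.
#'
#' @param path file path.
#' @return data.frame with columns probe_id, symbol, species.
#' @export
readAnnotation <- function(path) {
    tab <- utils::read.delim(path, colClasses = "character")
    if (!all(c("probe_id", "symbol") %in% colnames(tab)))
        stop("annotation must have columns probe_id, symbol", call. = FALSE)
    if (anyDuplicated(tab$probe_id))
        stop("annotation has duplicated probe ids", call. = FALSE)
    if (!"species" %in% colnames(tab)) tab$species <- NA_character_
    tab
}

#' @rdname readAnnotation
#' @param annot annotation data.frame.
#' @export
writeAnnotation <- function(annot, path) {
    utils::write.table(annot, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(annot)
}

#' Read or write a case-control cohort table
#'
#' CSV with columns \code{subject_id}, \code{biomarker_ng_ml},
#' \code{age_yr}, \code{bmi_kg_m2}, \code{htn}, \code{dm}, \code{egfr},
#' \code{ldl_mg_dl}, \code{hf_status} and optionally \code{probnp}.
#' Biomarker values must be strictly positive and binary fields 0/1.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readCohort <- function(path) {
    tab <- utils::read.csv(path)
    need <- c("subject_id", "biomarker_ng_ml", "hf_status")
    if (!all(need %in% colnames(tab)))
        stop("cohort table must have columns ",
             paste(need, collapse = ", "), call. = FALSE)
    if (anyDuplicated(tab$subject_id))
        stop("cohort table has duplicated subject ids", call. = FALSE)
    if (any(tab$biomarker_ng_ml <= 0))
        stop("biomarker values must be strictly positive", call. = FALSE)
    if (!all(tab$hf_status %in% c(0L, 1L)))
        stop("hf_status must be 0/1", call. = FALSE)
    tab
}

#' @rdname readCohort
#' @param cohort cohort data.frame.
#' @export
writeCohort <- function(cohort, path) {
    utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
    invisible(cohort)
}

#' Read a human differential-expression summary table
#'
#' TSV with columns \code{symbol}, \code{logFC}, \code{p_value}. An empty
#' logFC cell (fold change not reported for a non-significant gene) becomes
#' \code{NA}.
#'
#' @param path file path.
#' @return data.frame with columns symbol, logFC, p_value.
#' @export
readHumanDE <- function(path) {
    tab <- utils::read.delim(path,
        colClasses = c("character", "numeric", "numeric"))
    if (!all(c("symbol", "logFC", "p_value") %in% colnames(tab)))
        stop("human DE table must have columns symbol, logFC, p_value",
             call. = FALSE)
    if (any(stats::na.omit(tab$p_value) < 0 | stats::na.omit(tab$p_value) > 1))
        stop("p_value outside [0,1]", call. = FALSE)
    tab
}

#' Read the expression block of a GEO series-matrix file
#'
#' Parses the table between the \code{!series_matrix_table_begin} and
#' \code{!series_matrix_table_end} markers of a GEO series-matrix text
#' file. Intended for replication runs against deposited accessions; no
#' download is performed.
#'
#' @param path path to a series-matrix text file.
#' @return numeric matrix, probes in rows, GSM samples in columns.
#' @export
readSeriesMatrix <- function(path) {
    lines <- readLines(path)
    beg <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L)
        stop("no series-matrix table block found", call. = FALSE)
    block <- lines[(beg + 1L):(end - 1L)]
    tab <- utils::read.delim(text = block, check.names = FALSE)
    probes <- as.character(tab[[1L]])
    m <- as.matrix(tab[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- probes
    m
}

fixturePath <- function(name)
    system.file("extdata", name, package = "panelmark", mustWork = TRUE)

#' Bundled reference tables
#'
#' \code{loadTopDETable} returns the packaged table of top differentially
#' expressed probes from the chronic-isoproterenol mouse strain panel (22
#' probes; columns PROBE_ID, SYMBOL, logFC, AveExpr, p_value, and an empty
#' p_adj column since the published table does not disambiguate raw from
#' adjusted p). \code{loadTopCorrTable} returns the table of the 47 probes
#' most correlated with isoproterenol-induced left ventricular dilation
#' (ilmn_id, symbol, cor, p_value). \code{loadHumanDETable} returns the
#' four-gene human heart-failure differential-expression summary used by
#' the concordance demonstration (GPNMB, TIMP1, LGALS3, NPPB).
#'
#' @return data.frame; see Details.
#' @name fixtures
NULL

#' @rdname fixtures
#' @export
loadTopDETable <- function() {
    tab <- utils::read.delim(fixturePath("iso_top_de.tsv"),
        colClasses = c("character", "character", "numeric", "numeric",
                       "numeric", "numeric"))
    names(tab) <- c("probe_id", "symbol", "logFC", "AveExpr", "p_value",
                    "p_adj")
    tab
}

#' @rdname fixtures
#' @export
loadTopCorrTable <- function() {
    utils::read.delim(fixturePath("lvidd_top_corr.tsv"),
        colClasses = c("character", "character", "numeric", "numeric"))
}

#' @rdname fixtures
#' @export
loadHumanDETable <- function() readHumanDE(fixturePath("human_hf_de.tsv"))
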