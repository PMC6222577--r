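## End-to-end orchestration: differential expression -> trait correlation
## -> overlay -> cross-species concordance -> cohort statistics, driven by
## a single configuration list, with a run manifest for reproducibility.

#' Build a pipeline configuration
#'
#' Paths may be NULL; stages whose inputs are absent are skipped (and
#' logged). Thresholds default to the values that reproduce the packaged
#' reference tables' contents: |logFC| >= 1 with adjusted p < 0.05 for
#' the DE list and correlation p < 1e-3 for the trait list.
#'
#' @param expr,meta,trait,annot,human,cohort input file paths (TSV/CSV;
#'   see the data I/O readers) or NULL.
#' @param min_abs_logfc,de_max_p DE top-list thresholds.
#' @param corr_max_p trait-correlation top-list threshold.
#' @param alpha concordance significance level.
#' @param known_markers established marker symbols to flag.
#' @param biomarker_scale scale for the biomarker in logistic models.
#' @param out_dir output directory.
#' @param seed integer seed recorded in the manifest.
#' @return list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(expr = NULL, meta = NULL, trait = NULL,
                           annot = NULL, human = NULL, cohort = NULL,
                           min_abs_logfc = 1.0, de_max_p = 0.05,
                           corr_max_p = 1e-3, alpha = 0.05,
                           known_markers = knownMarkersDefault,
                           biomarker_scale = "raw",
                           out_dir = tempfile("panelmark_run_"),
                           seed = 1L) {
    cfg <- list(expr = expr, meta = meta, trait = trait, annot = annot,
                human = human, cohort = cohort,
                min_abs_logfc = min_abs_logfc, de_max_p = de_max_p,
                corr_max_p = corr_max_p, alpha = alpha,
                known_markers = known_markers,
                biomarker_scale = biomarker_scale,
                out_dir = out_dir, seed = as.integer(seed))
    for (f in c("expr", "meta", "trait", "annot", "human", "cohort"))
        if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
            stop("configured input does not exist: ", f, " = ", cfg[[f]],
                 call. = FALSE)
    if (!(cfg$alpha > 0 && cfg$alpha < 1) || cfg$corr_max_p <= 0 ||
        cfg$de_max_p <= 0)
        stop("thresholds out of range", call. = FALSE)
    structure(cfg, class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match \code{\link{pipelineConfig}}
#'   arguments.
#' @return list of class \code{PipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
    vals <- yaml::read_yaml(path)
    do.call(pipelineConfig, vals)
}

#' Run the full biomarker-discovery pipeline
#'
#' Executes, in order: differential expression, trait correlation,
#' overlay, cross-species concordance, cohort statistics — skipping any
#' stage whose inputs are not configured. Writes \code{de.tsv},
#' \code{corr.tsv}, \code{candidates.tsv}, \code{concordance.tsv},
#' \code{cohort_univariate.tsv}, \code{cohort_multivariate.tsv} and a
#' \code{manifest.yaml} (package version, seed, config hash, stage log)
#' under \code{config$out_dir}.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
runAll <- function(config, quiet = FALSE) {
    stopifnot(inherits(config, "PipelineConfig"))
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    log <- character(0)
    note <- function(...) {
        msg <- paste0(...)
        log <<- c(log, msg)
        if (!quiet) message(msg)
    }
    res <- list()

    if (!is.null(config$expr) && !is.null(config$meta)) {
        panel <- readExpression(config$expr, config$meta)
        annot <- if (!is.null(config$annot)) readAnnotation(config$annot)
                 else NULL
        note("stage de: ", nrow(panel), " probes, ", ncol(panel),
             " samples")
        res$de <- runDE(panel, annot)
        utils::write.table(res$de, file.path(config$out_dir, "de.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        if (!is.null(config$trait)) {
            tr <- readTrait(config$trait)
            note("stage correlate: ", nrow(tr), " strains with trait")
            sm <- strainSummarize(panel, arm = "treated")
            res$corr <- correlateTrait(sm, tr, annotation = annot)
            utils::write.table(res$corr,
                               file.path(config$out_dir, "corr.tsv"),
                               sep = "\t", quote = FALSE,
                               row.names = FALSE)
        } else note("stage correlate: skipped (no trait table)")
    } else note("stage de: skipped (no expression input)")

    if (!is.null(res$de) && !is.null(res$corr)) {
        tde <- topDE(res$de, min_abs_logfc = config$min_abs_logfc,
                     max_p = config$de_max_p)
        tco <- topCorr(res$corr, max_p = config$corr_max_p)
        res$candidates <- overlayCandidates(tde, tco,
                                            config$known_markers)
        note("stage overlay: ", nrow(res$candidates), " candidate(s)")
        utils::write.table(res$candidates,
                           file.path(config$out_dir, "candidates.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    } else note("stage overlay: skipped (missing DE or correlation)")

    if (!is.null(res$candidates) && !is.null(config$human)) {
        human <- readHumanDE(config$human)
        res$concordance <- concordance(res$candidates, human,
                                       alpha = config$alpha)
        note("stage concord: ",
             sum(res$concordance$status == "concordant"), " concordant")
        utils::write.table(res$concordance,
                           file.path(config$out_dir, "concordance.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    } else note("stage concord: skipped")

    if (!is.null(config$cohort)) {
        co <- readCohort(config$cohort)
        note("stage cohort: ", nrow(co), " subjects")
        res$cohort <- runCohortAnalysis(
            co, biomarker_scale = config$biomarker_scale)
        utils::write.table(res$cohort$univariate,
            file.path(config$out_dir, "cohort_univariate.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(res$cohort$multivariate,
            file.path(config$out_dir, "cohort_multivariate.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
    } else note("stage cohort: skipped (no cohort table)")

    manifest <- list(
        package = "panelmark",
        version = as.character(utils::packageVersion("panelmark")),
        seed = config$seed,
        config_hash = configHash(config),
        stages = log,
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
    res$manifest <- manifest
    invisible(res)
}

#' Hash of a pipeline configuration
#'
#' MD5 of the canonical YAML serialization of the configuration plus the
#' MD5 of every configured input file, so the hash changes iff the
#' configuration or any input changes.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return character MD5 hex string.
#' @export
configHash <- function(config) {
    files <- Filter(Negate(is.null),
                    config[c("expr", "meta", "trait", "annot", "human",
                             "cohort")])
    fh <- if (length(files))
        unname(tools::md5sum(unlist(files))) else character(0)
    cfg <- config
    cfg$out_dir <- NULL   # output location does not affect results
    tmp <- tempfile()
    on.exit(unlink(tmp))
    yaml::write_yaml(c(cfg[order(names(cfg))], list(inputs = fh)), tmp)
    unname(tools::md5sum(tmp))
}

#' Demonstration run on the packaged reference tables
#'
#' Overlays the packaged top-DE and top-correlation tables (default
#' thresholds), flags the default known markers, and checks cross-species
#' concordance against the packaged human heart-failure DE table. Prints
#' the candidate set and concordance statuses.
#'
#' @param out_dir optional directory for candidates.tsv and
#'   concordance.tsv.
#' @param quiet suppress printing.
#' @return list with candidates and concordance data.frames.
#' @export
runDemo <- function(out_dir = NULL, quiet = FALSE) {
    de <- loadTopDETable()
    co <- loadTopCorrTable()
    names(co)[names(co) == "ilmn_id"] <- "probe_id"
    tde <- topDE(de, min_abs_logfc = 1.0, max_p = 0.05)
    tco <- topCorr(co, max_p = 1e-3)
    cand <- overlayCandidates(tde, tco)
    conc <- concordance(cand, loadHumanDETable(), alpha = 0.05)
    ## the established markers are also checked against the human table
    ## mouse logFC is NA for markers outside the top-DE table (e.g. the
    ## natriuretic peptide, unchanged by the treatment); the sign is only
    ## needed where the human gene is significant
    markers <- data.frame(symbol = knownMarkersDefault,
                          logFC = de$logFC[match(knownMarkersDefault,
                                                 de$symbol)])
    marker_conc <- concordance(markers, loadHumanDETable(), alpha = 0.05)
    if (!quiet) {
        cat("Candidates (DE x trait-correlation overlay):\n")
        print(cand, row.names = FALSE)
        cat("\nNovel candidates:",
            paste(sort(cand$symbol[cand$novel]), collapse = ", "), "\n")
        cat("\nConcordance vs human heart-failure DE:\n")
        print(conc, row.names = FALSE)
    }
    if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        utils::write.table(cand, file.path(out_dir, "candidates.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(conc, file.path(out_dir, "concordance.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    invisible(list(candidates = cand, concordance = conc,
                   marker_concordance = marker_conc))
}
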