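## Synthetic-data generators. The panel generator emulates a paired
## control/treated inbred-strain expression study with planted log2 fold
## changes and a quantitative remodeling trait built as a noisy linear
## function of selected transcripts; the cohort generator emulates a
## case-control plasma-biomarker study with planted covariate effects.
## Ground truth is returned alongside the data so every downstream stage
## can be tested for parameter recovery.

#' Derive a sub-generator seed from a global seed
#'
#' Deterministic Lehmer-style split so that one global seed drives the
#' panel and cohort generators independently. Result is in [1, 2^31-2].
#'
#' @param seed integer global seed.
#' @param index integer sub-generator index (0, 1, 2, ...).
#' @return integer seed.
#' @export
splitSeed <- function(seed, index = 0L) {
    s <- (as.double(seed) %% 2147483647) + 1
    for (i in seq_len(index + 1L)) s <- (s * 48271) %% 2147483647
    as.integer(s)
}

#' Configuration for the strain-panel generator
#'
#' Defaults describe the study conditions the package emulates: 91 inbred
#' strains, paired control/treated arms with 2 replicates each, Gaussian
#' log2-scale noise of 0.5, planted treatment effects of 1 to 2 log2 units
#' (mixed signs), and trait-linked transcripts whose planted population
#' correlations with the trait lie in 0.30-0.45. The trait is a noisy
#' linear function of the strain-mean treated-arm expression of the
#' trait-linked probes; weights are solved from the requested correlations
#' and the trait noise (0.5 mm) unless \code{trait_weights} is given
#' explicitly.
#'
#' @param n_strains number of inbred strains (>= 4).
#' @param n_probes number of probes on the simulated array.
#' @param replicates_per_arm replicate mice per strain and arm.
#' @param n_de number of probes with a planted treatment effect.
#' @param n_trait number of trait-linked probes.
#' @param n_overlap number of probes planted in both sets (candidates).
#' @param logfc_range absolute planted log2 fold-change range.
#' @param target_r_range absolute planted trait-correlation range; the
#'   squared targets must sum to < 1.
#' @param noise_sd_expr residual SD of log2 expression.
#' @param strain_sd_expr SD of an optional per-strain random baseline
#'   shift (0 disables it).
#' @param noise_sd_trait residual SD of the trait (mm).
#' @param trait_intercept mean trait change (mm).
#' @param trait_weights optional explicit named weight vector (probe id ->
#'   weight), bypassing the target-correlation scaling.
#' @param seed integer random seed; fixed seed gives bit-identical output.
#' @return a validated list of class \code{PanelSimConfig}.
#' @export
panelSimConfig <- function(n_strains = 91L, n_probes = 1000L,
                           replicates_per_arm = 2L,
                           n_de = 20L, n_trait = 6L, n_overlap = 3L,
                           logfc_range = c(1.0, 2.0),
                           target_r_range = c(0.30, 0.38),
                           noise_sd_expr = 0.5,
                           strain_sd_expr = 0,
                           noise_sd_trait = 0.5,
                           trait_intercept = 0.8,
                           trait_weights = NULL,
                           seed = 1L) {
    cfg <- list(n_strains = as.integer(n_strains),
                n_probes = as.integer(n_probes),
                replicates_per_arm = as.integer(replicates_per_arm),
                n_de = as.integer(n_de), n_trait = as.integer(n_trait),
                n_overlap = as.integer(n_overlap),
                logfc_range = as.numeric(logfc_range),
                target_r_range = as.numeric(target_r_range),
                noise_sd_expr = noise_sd_expr,
                strain_sd_expr = strain_sd_expr,
                noise_sd_trait = noise_sd_trait,
                trait_intercept = trait_intercept,
                trait_weights = trait_weights,
                seed = as.integer(seed))
    for (f in c("n_strains", "n_probes", "replicates_per_arm"))
        if (is.na(cfg[[f]]) || cfg[[f]] < 1L)
            stop("invalid configuration: '", f, "' must be >= 1",
                 call. = FALSE)
    if (cfg$n_strains < 4L)
        stop("invalid configuration: 'n_strains' must be >= 4 ",
             "for correlation stages", call. = FALSE)
    if (cfg$noise_sd_expr <= 0)
        stop("invalid configuration: 'noise_sd_expr' must be > 0",
             call. = FALSE)
    if (cfg$noise_sd_trait < 0 || cfg$strain_sd_expr < 0)
        stop("invalid configuration: noise SDs must be >= 0", call. = FALSE)
    if (cfg$n_de + cfg$n_trait - cfg$n_overlap > cfg$n_probes)
        stop("invalid configuration: planted probes exceed 'n_probes'",
             call. = FALSE)
    if (cfg$n_overlap > min(cfg$n_de, cfg$n_trait))
        stop("invalid configuration: 'n_overlap' exceeds planted set sizes",
             call. = FALSE)
    if (is.null(cfg$trait_weights) && cfg$n_trait > 0 &&
        cfg$n_trait * max(cfg$target_r_range)^2 >= 1)
        stop("invalid configuration: 'target_r_range' too large for ",
             "'n_trait' (sum of squared correlations must be < 1)",
             call. = FALSE)
    structure(cfg, class = "PanelSimConfig")
}

#' Simulate a paired control/treated strain-panel expression study
#'
#' Generates an \linkS4class{ExpressionPanel} (both arms for every strain),
#' a probe annotation, a per-strain trait table, and the full ground truth.
#' Treated-arm values of planted DE probes are shifted by their planted
#' log2 fold change; the trait is
#' \code{intercept + sum(w_j * (m_j - E[m_j])) + N(0, noise_sd_trait)}
#' where \code{m_j} is the strain-mean treated expression of trait probe j.
#'
#' @param config a \code{\link{panelSimConfig}}.
#' @return list with elements \code{panel}, \code{annotation},
#'   \code{trait}, \code{truth}. \code{truth} has the planted probe sets,
#'   the full planted logFC vector (exactly zero off the planted set), the
#'   trait weights and target correlations, and the noise SDs.
#' @examples
#' sim <- simulatePanel(panelSimConfig(n_strains = 8, n_probes = 50,
#'                                     seed = 42))
#' sim$panel
#' @export
simulatePanel <- function(config = panelSimConfig()) {
    if (!inherits(config, "PanelSimConfig"))
        stop("config must come from panelSimConfig()", call. = FALSE)
    set.seed(splitSeed(config$seed, 0L))
    np <- config$n_probes; ns <- config$n_strains
    reps <- config$replicates_per_arm
    probes <- sprintf("ILMN_SIM_%06d", seq_len(np))
    symbols <- sprintf("Gene%04d", seq_len(np))
    strains <- sprintf("STRAIN_%03d", seq_len(ns))

    ## planted sets: overlap probes first, then DE-only, then trait-only
    n_ov <- config$n_overlap
    idx_ov <- seq_len(n_ov)
    idx_de <- seq_len(config$n_de)
    idx_tr <- c(idx_ov, config$n_de + seq_len(config$n_trait - n_ov))
    planted_logfc <- stats::setNames(numeric(np), probes)
    if (config$n_de > 0) {
        mag <- stats::runif(config$n_de, config$logfc_range[1L],
                            config$logfc_range[2L])
        sgn <- sample(c(-1, 1), config$n_de, replace = TRUE)
        planted_logfc[idx_de] <- mag * sgn
    }

    ## trait weights: explicit, or solved so that the planted population
    ## correlation of probe j with the trait equals its target r_j given
    ## strain-mean variance v and trait noise:
    ##   r_j = w_j sqrt(v) / sd(trait),  sd(trait)^2 = sum(w^2) v + s_t^2
    ##   => w_j = r_j s_t / (sqrt(v) sqrt(1 - sum r^2))
    v <- config$strain_sd_expr^2 + config$noise_sd_expr^2 / reps
    target_r <- numeric(0)
    if (!is.null(config$trait_weights)) {
        w <- config$trait_weights
        if (is.null(names(w)) || !all(names(w) %in% probes))
            stop("trait_weights must be named by generated probe ids",
                 call. = FALSE)
        weights <- stats::setNames(numeric(np), probes)
        weights[names(w)] <- w
        idx_tr <- which(weights != 0)
    } else {
        weights <- stats::setNames(numeric(np), probes)
        if (config$n_trait > 0) {
            rmag <- stats::runif(config$n_trait, config$target_r_range[1L],
                                 config$target_r_range[2L])
            rsgn <- sample(c(-1, 1), config$n_trait, replace = TRUE)
            target_r <- rmag * rsgn
            if (config$noise_sd_trait > 0) {
                weights[idx_tr] <- target_r * config$noise_sd_trait /
                    (sqrt(v) * sqrt(1 - sum(target_r^2)))
            } else weights[idx_tr] <- target_r  # degenerate: direction only
            target_r <- stats::setNames(target_r, probes[idx_tr])
        }
    }

    mu <- stats::runif(np, 5, 12)
    n_samp <- ns * 2L * reps
    strain_v <- rep(strains, each = 2L * reps)
    arm_v <- rep(rep(c("control", "treated"), each = reps), ns)
    rep_v <- rep(rep(seq_len(reps), 2L), ns)
    sample_id <- paste(strain_v, ifelse(arm_v == "control", "CON", "TRT"),
                       rep_v, sep = "_")
    strain_fx <- if (config$strain_sd_expr > 0)
        matrix(stats::rnorm(np * ns, 0, config$strain_sd_expr), np, ns,
               dimnames = list(probes, strains))
    else NULL
    vals <- matrix(stats::rnorm(np * n_samp, 0, config$noise_sd_expr),
                   np, n_samp, dimnames = list(probes, sample_id))
    vals <- vals + mu
    trt <- arm_v == "treated"
    vals[, trt] <- vals[, trt] + planted_logfc
    if (!is.null(strain_fx))
        vals <- vals + strain_fx[, match(strain_v, strains)]
    panel <- ExpressionPanel(vals, strain = strain_v, treatment = arm_v,
                             replicate = rep_v)

    ## trait from strain-mean treated expression of the trait probes
    m <- strainSummarize(panel, arm = "treated")
    active <- which(weights != 0)
    center <- mu + planted_logfc
    signal <- if (length(active))
        as.numeric(m[, active, drop = FALSE] %*% weights[active]) -
            sum(center[active] * weights[active])
    else rep(0, ns)
    trait_delta <- config$trait_intercept + signal +
        stats::rnorm(ns, 0, config$noise_sd_trait)
    trait <- data.frame(strain = strains, trait_delta = trait_delta)

    annotation <- data.frame(probe_id = probes, symbol = symbols,
                             species = "mouse")
    truth <- structure(list(
        de_genes = probes[idx_de],
        trait_genes = probes[idx_tr],
        overlap_genes = probes[idx_ov[seq_len(min(n_ov, config$n_de))]],
        planted_logfc = planted_logfc,
        planted_weights = weights,
        target_r = target_r,
        noise_sd_expr = config$noise_sd_expr,
        noise_sd_trait = config$noise_sd_trait,
        trait_intercept = config$trait_intercept), class = "PanelTruth")
    list(panel = panel, annotation = annotation, trait = trait,
         truth = truth)
}

#' Configuration for the case-control cohort generator
#'
#' Defaults emulate a plasma-biomarker case-control study nested in a male
#' population cohort: 119 heart-failure cases and 270 controls; a
#' lognormal biomarker that is lower in cases (natural-scale mean 1.20
#' ng/mL, SD 0.26 in controls vs 0.74, SD 0.40 in cases); cases older,
#' heavier, more hypertensive and diabetic, with lower eGFR and lower
#' LDL-C. Two sampling modes are supported: \code{"case-control"} fixes
#' the case/control labels first and draws biomarker and covariates
#' conditionally on group (retrospective ascertainment); in
#' \code{"prospective"} mode covariates are drawn from a population and
#' case status follows the logistic model with the planted coefficients
#' \code{beta}, so the planted odds ratios are exactly the true logistic
#' parameters.
#'
#' @param n_cases,n_controls group sizes (case-control mode; each >= 2).
#' @param biomarker_control,biomarker_case natural-scale (mean, sd) of the
#'   lognormal biomarker per group.
#' @param covariates list per covariate: for Gaussian covariates
#'   \code{list(control = c(mean, sd), case = c(mean, sd))}; for binary
#'   covariates \code{list(control = prev, case = prev)}.
#' @param include_probnp include an independent lognormal proBNP column.
#' @param mode \code{"case-control"} or \code{"prospective"}.
#' @param n total subjects (prospective mode).
#' @param beta named log-odds coefficients including \code{intercept}
#'   (prospective mode); remaining names must match generated covariates
#'   or \code{biomarker_ng_ml}.
#' @param biomarker_meanlog,biomarker_sdlog population lognormal
#'   parameters of the biomarker (prospective mode).
#' @param seed integer random seed.
#' @return a validated list of class \code{CohortSimConfig}.
#' @export
cohortSimConfig <- function(n_cases = 119L, n_controls = 270L,
                            biomarker_control = c(mean = 1.20, sd = 0.26),
                            biomarker_case = c(mean = 0.74, sd = 0.40),
                            covariates = list(
                                age_yr     = list(control = c(57, 6),
                                                  case = c(63, 6)),
                                bmi_kg_m2  = list(control = c(27, 4),
                                                  case = c(29.5, 4)),
                                htn        = list(control = 0.30,
                                                  case = 0.72),
                                dm         = list(control = 0.08,
                                                  case = 0.45),
                                egfr       = list(control = c(90, 15),
                                                  case = c(80, 15)),
                                ldl_mg_dl  = list(control = c(135, 30),
                                                  case = c(112, 30))),
                            include_probnp = FALSE,
                            mode = c("case-control", "prospective"),
                            n = 2000L,
                            beta = c(intercept = -1, biomarker_ng_ml = -0.139),
                            biomarker_meanlog = 0, biomarker_sdlog = 0.4,
                            seed = 1L) {
    mode <- match.arg(mode)
    cfg <- list(n_cases = as.integer(n_cases),
                n_controls = as.integer(n_controls),
                biomarker_control = biomarker_control,
                biomarker_case = biomarker_case,
                covariates = covariates,
                include_probnp = isTRUE(include_probnp),
                mode = mode, n = as.integer(n), beta = beta,
                biomarker_meanlog = biomarker_meanlog,
                biomarker_sdlog = biomarker_sdlog,
                seed = as.integer(seed))
    if (mode == "case-control" && (cfg$n_cases < 2L || cfg$n_controls < 2L))
        stop("invalid configuration: case/control counts must be >= 2",
             call. = FALSE)
    for (bm in list(biomarker_control, biomarker_case))
        if (any(bm <= 0))
            stop("invalid configuration: biomarker mean/sd must be > 0",
                 call. = FALSE)
    if (mode == "prospective" && cfg$biomarker_sdlog <= 0)
        stop("invalid configuration: 'biomarker_sdlog' must be > 0",
             call. = FALSE)
    for (nm in names(covariates)) {
        cv <- covariates[[nm]]
        if (length(cv$control) == 2L && (cv$control[2L] <= 0 ||
                                         cv$case[2L] <= 0))
            stop("invalid configuration: covariate '", nm,
                 "' has nonpositive sd", call. = FALSE)
        if (length(cv$control) == 1L &&
            any(c(cv$control, cv$case) < 0 | c(cv$control, cv$case) > 1))
            stop("invalid configuration: covariate '", nm,
                 "' prevalence outside [0,1]", call. = FALSE)
    }
    structure(cfg, class = "CohortSimConfig")
}

rlnorm_ms <- function(n, mean, sd) {
    sdlog2 <- log(1 + (sd / mean)^2)
    stats::rlnorm(n, meanlog = log(mean) - sdlog2 / 2,
                  sdlog = sqrt(sdlog2))
}

#' Simulate a case-control biomarker cohort
#'
#' @param config a \code{\link{cohortSimConfig}}.
#' @return list with \code{cohort} (data.frame with subject_id,
#'   biomarker_ng_ml, covariates, hf_status) and \code{truth}: planted or
#'   implied log-odds coefficients (for case-control mode the implied
#'   coefficient of a Gaussian covariate is the discriminant identity
#'   \code{(mu_case - mu_control)/sigma^2}, of a binary covariate the log
#'   odds ratio of its prevalences, and of the biomarker the log-scale
#'   discriminant coefficient, recorded with \code{biomarker_scale =
#'   "log"}), the group means and sizes, and the sampling mode.
#' @export
simulateCohort <- function(config = cohortSimConfig()) {
    if (!inherits(config, "CohortSimConfig"))
        stop("config must come from cohortSimConfig()", call. = FALSE)
    set.seed(splitSeed(config$seed, 1L))
    if (config$mode == "case-control") {
        n1 <- config$n_cases; n0 <- config$n_controls
        hf <- c(rep(1L, n1), rep(0L, n0))
        bm <- numeric(n1 + n0)
        bm[hf == 1L] <- rlnorm_ms(n1, config$biomarker_case["mean"],
                                  config$biomarker_case["sd"])
        bm[hf == 0L] <- rlnorm_ms(n0, config$biomarker_control["mean"],
                                  config$biomarker_control["sd"])
        cov_df <- list()
        beta <- c()
        for (nm in names(config$covariates)) {
            cv <- config$covariates[[nm]]
            x <- numeric(n1 + n0)
            if (length(cv$control) == 2L) {
                x[hf == 1L] <- stats::rnorm(n1, cv$case[1L], cv$case[2L])
                x[hf == 0L] <- stats::rnorm(n0, cv$control[1L],
                                            cv$control[2L])
                s2 <- (cv$case[2L]^2 + cv$control[2L]^2) / 2
                beta[nm] <- (cv$case[1L] - cv$control[1L]) / s2
            } else {
                x[hf == 1L] <- stats::rbinom(n1, 1L, cv$case)
                x[hf == 0L] <- stats::rbinom(n0, 1L, cv$control)
                beta[nm] <- log(cv$case / (1 - cv$case)) -
                    log(cv$control / (1 - cv$control))
            }
            cov_df[[nm]] <- x
        }
        ## implied log-scale biomarker coefficient (Gaussian discriminant
        ## on log biomarker, pooled variance)
        lp <- function(m, s) {
            sl2 <- log(1 + (s / m)^2); c(log(m) - sl2 / 2, sl2)
        }
        p1 <- lp(config$biomarker_case["mean"], config$biomarker_case["sd"])
        p0 <- lp(config$biomarker_control["mean"],
                 config$biomarker_control["sd"])
        beta <- c(biomarker_ng_ml = unname((p1[1L] - p0[1L]) /
                                           ((p1[2L] + p0[2L]) / 2)), beta)
        cohort <- data.frame(
            subject_id = sprintf("SUBJ%04d", seq_len(n1 + n0)),
            biomarker_ng_ml = bm,
            as.data.frame(cov_df),
            hf_status = hf)
        if (config$include_probnp)
            cohort$probnp <- stats::rlnorm(n1 + n0, 5, 1)
        truth <- list(beta = beta, biomarker_scale = "log",
                      case_mean = unname(config$biomarker_case["mean"]),
                      control_mean = unname(config$biomarker_control["mean"]),
                      case_n = n1, control_n = n0, mode = config$mode)
    } else {
        n <- config$n
        bm <- stats::rlnorm(n, config$biomarker_meanlog,
                            config$biomarker_sdlog)
        X <- data.frame(biomarker_ng_ml = bm)
        for (nm in names(config$beta)) {
            if (nm %in% c("intercept", "biomarker_ng_ml")) next
            X[[nm]] <- stats::rnorm(n)  # standardized extra covariates
        }
        eta <- config$beta[["intercept"]] +
            as.matrix(X[, setdiff(names(config$beta), "intercept"),
                        drop = FALSE]) %*%
            config$beta[setdiff(names(config$beta), "intercept")]
        hf <- stats::rbinom(n, 1L, stats::plogis(as.numeric(eta)))
        cohort <- data.frame(subject_id = sprintf("SUBJ%04d", seq_len(n)),
                             X, hf_status = hf)
        truth <- list(beta = config$beta, biomarker_scale = "raw",
                      case_mean = mean(bm[hf == 1L]),
                      control_mean = mean(bm[hf == 0L]),
                      case_n = sum(hf == 1L),
                      control_n = sum(hf == 0L), mode = config$mode)
    }
    list(cohort = cohort, truth = structure(truth, class = "CohortTruth"))
}

#' Write a simulated panel or cohort bundle to disk
#'
#' \code{writePanelSim} writes expr.tsv, meta.tsv, trait.tsv, annot.tsv
#' and truth.yaml; \code{writeCohortSim} writes cohort.csv and
#' truth.yaml.
#'
#' @param sim result of \code{\link{simulatePanel}} or
#'   \code{\link{simulateCohort}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
writePanelSim <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeExpression(sim$panel, file.path(dir, "expr.tsv"),
                    file.path(dir, "meta.tsv"))
    writeTrait(sim$trait, file.path(dir, "trait.tsv"))
    writeAnnotation(sim$annotation, file.path(dir, "annot.tsv"))
    tr <- sim$truth
    yaml::write_yaml(list(
        de_genes = tr$de_genes, trait_genes = tr$trait_genes,
        planted_logfc = as.list(tr$planted_logfc[tr$planted_logfc != 0]),
        planted_weights = as.list(tr$planted_weights[tr$planted_weights != 0]),
        noise_sd_expr = tr$noise_sd_expr,
        noise_sd_trait = tr$noise_sd_trait),
        file.path(dir, "truth.yaml"))
    invisible(file.path(dir, c("expr.tsv", "meta.tsv", "trait.tsv",
                               "annot.tsv", "truth.yaml")))
}

#' @rdname writePanelSim
#' @export
writeCohortSim <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeCohort(sim$cohort, file.path(dir, "cohort.csv"))
    yaml::write_yaml(list(beta = as.list(sim$truth$beta),
                          biomarker_scale = sim$truth$biomarker_scale,
                          case_n = sim$truth$case_n,
                          control_n = sim$truth$control_n,
                          mode = sim$truth$mode),
                     file.path(dir, "truth.yaml"))
    invisible(file.path(dir, c("cohort.csv", "truth.yaml")))
}
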