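## Case-control validation statistics: two-sample t-tests (raw data or
## published group summaries), Fisher exact tests, Spearman rank
## correlation, and Newton/IRLS logistic regression with Wald odds-ratio
## intervals.

#' Two-sample t-test from group summaries
#'
#' Pooled (Student) or Welch t-test computed from (mean, sd, n) per
#' group, as needed when only published summaries are available. The
#' difference is \code{mean_a - mean_b}. Identical in formula to
#' \code{\link{tTestRaw}}; the two agree exactly when the summaries come
#' from the same raw data.
#'
#' @param mean_a,sd_a,n_a group A summary (sd >= 0, n >= 2).
#' @param mean_b,sd_b,n_b group B summary.
#' @param method \code{"pooled"} (df = n_a + n_b - 2) or \code{"welch"}
#'   (Welch-Satterthwaite df).
#' @return list of class \code{TTestResult}: t, df, p_value, method,
#'   estimate (the mean difference).
#' @export
tTestSummary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                         method = c("pooled", "welch")) {
    method <- match.arg(method)
    if (n_a < 2 || n_b < 2)
        stop("each group needs n >= 2", call. = FALSE)
    if (sd_a < 0 || sd_b < 0)
        stop("standard deviations must be >= 0", call. = FALSE)
    if (sd_a == 0 && sd_b == 0 && mean_a == mean_b)
        stop("degenerate data: both variances zero and means equal",
             call. = FALSE)
    if (method == "pooled") {
        sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2)
        se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
        df <- n_a + n_b - 2
    } else {
        va <- sd_a^2 / n_a; vb <- sd_b^2 / n_b
        se <- sqrt(va + vb)
        df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
    }
    tstat <- (mean_a - mean_b) / se
    structure(list(t = tstat, df = df,
                   p_value = 2 * stats::pt(-abs(tstat), df),
                   method = method, estimate = mean_a - mean_b),
              class = "TTestResult")
}

#' Two-sample t-test on raw values
#'
#' @param a,b numeric vectors (each length >= 2; positive variance in at
#'   least one group).
#' @param method \code{"pooled"} or \code{"welch"}.
#' @return list of class \code{TTestResult}; see
#'   \code{\link{tTestSummary}}.
#' @export
tTestRaw <- function(a, b, method = c("pooled", "welch")) {
    tTestSummary(mean(a), stats::sd(a), length(a),
                 mean(b), stats::sd(b), length(b), method = method)
}

#' @export
print.TTestResult <- function(x, ...) {
    cat(sprintf("Two-sample t-test (%s): t = %.4g, df = %.4g, p = %.4g\n",
                x$method, x$t, x$df, x$p_value))
    invisible(x)
}

#' Fisher exact test for a 2x2 table
#'
#' Exact hypergeometric test conditioning on the margins. The default
#' two-sided rule is the probability-mass method: the p-value sums the
#' probabilities of all tables (with the observed margins) whose
#' probability does not exceed that of the observed table, with a small
#' relative tolerance against floating-point ties.
#' \code{alternative = "double"} doubles the smaller one-sided tail
#' (capped at 1) instead. The reported odds ratio is the sample
#' cross-product ratio ad/bc (Inf when bc = 0 with ad > 0).
#'
#' @param tab 2x2 matrix of nonnegative integer counts
#'   \code{rbind(c(a, b), c(c, d))}.
#' @param alternative \code{"prob"} (probability-mass) or
#'   \code{"double"}.
#' @return list: p_value, odds_ratio, method.
#' @export
fisherExact <- function(tab, alternative = c("prob", "double")) {
    alternative <- match.arg(alternative)
    tab <- as.matrix(tab)
    if (!all(dim(tab) == c(2L, 2L)) || any(tab < 0) ||
        any(tab != round(tab)))
        stop("need a 2x2 table of nonnegative integers", call. = FALSE)
    a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
    m <- a + cc; nn <- b + d; k <- a + b
    lo <- max(0, k - nn); hi <- min(k, m)
    support <- lo:hi
    dens <- stats::dhyper(support, m, nn, k)
    pobs <- stats::dhyper(a, m, nn, k)
    if (alternative == "prob") {
        p <- sum(dens[dens <= pobs * (1 + 1e-7)])
    } else {
        lower <- sum(dens[support <= a])
        upper <- sum(dens[support >= a])
        p <- min(1, 2 * min(lower, upper))
    }
    or <- if (b * cc == 0) {
        if (a * d == 0) NaN else Inf
    } else (a * d) / (b * cc)
    list(p_value = min(1, p), odds_ratio = or, method = alternative)
}

#' Spearman rank correlation with t-transform p-value
#'
#' Pearson correlation on midranks; two-sided p from
#' \code{t = rho * sqrt((n - 2)/(1 - rho^2))} on n - 2 df. Constant input
#' yields rho = 0, p = 1 and a degenerate flag.
#'
#' @param x,y paired numeric vectors, length >= 3.
#' @return list: rho, p_value, n, degenerate.
#' @export
spearmanCor <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
    rx <- rank(x); ry <- rank(y)
    if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
        return(list(rho = 0, p_value = 1, n = n, degenerate = TRUE))
    rho <- stats::cor(rx, ry)
    if (abs(rho) >= 1)
        return(list(rho = sign(rho), p_value = 0, n = n,
                    degenerate = FALSE))
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    list(rho = rho, p_value = 2 * stats::pt(-abs(tstat), n - 2), n = n,
         degenerate = FALSE)
}

#' Logistic regression by Newton/IRLS
#'
#' Maximizes the Bernoulli log-likelihood by iteratively reweighted least
#' squares. Standard errors come from the inverse observed information at
#' the optimum; Wald 95\% intervals are \code{exp(beta +/- 1.959964 se)}.
#' A step-halving line search keeps the log-likelihood non-decreasing.
#' Quasi-separation (fitted probabilities pinned at 0/1 alongside
#' diverging coefficients) is flagged and the fit marked non-converged,
#' never silently ignored.
#'
#' @param X design matrix including an intercept column.
#' @param y binary outcome vector (0/1).
#' @param tol convergence tolerance on the maximum absolute score
#'   component (default 1e-8).
#' @param max_iter maximum Newton iterations (default 50).
#' @return a \linkS4class{LogisticFit}.
#' @export
logisticFit <- function(X, y, tol = 1e-8, max_iter = 50L) {
    X <- as.matrix(X)
    if (is.null(colnames(X)))
        colnames(X) <- c("intercept",
                         paste0("x", seq_len(ncol(X) - 1L)))[seq_len(ncol(X))]
    if (!all(y %in% c(0, 1)))
        stop("outcome must be 0/1", call. = FALSE)
    if (nrow(X) != length(y))
        stop("X and y dimensions differ", call. = FALSE)
    sds <- apply(X, 2L, stats::sd)
    if (any(sds == 0 & colMeans(X) == 0))
        stop("constant zero predictor column", call. = FALSE)
    beta <- numeric(ncol(X))
    ll <- function(b) {
        eta <- as.numeric(X %*% b)
        ## numerically stable log(1 + exp(eta))
        lse <- ifelse(eta > 30, eta, log1p(exp(pmin(eta, 30))))
        sum(y * eta - lse)
    }
    ll_old <- ll(beta)
    trace <- numeric(0)
    iter <- 0L
    max_score <- Inf
    separation <- FALSE
    repeat {
        iter <- iter + 1L
        eta <- as.numeric(X %*% beta)
        p <- stats::plogis(eta)
        w <- p * (1 - p)
        score <- as.numeric(crossprod(X, y - p))
        info <- crossprod(X * w, X)
        step <- tryCatch(solve(info, score), error = function(e) NULL)
        if (is.null(step)) { separation <- TRUE; break }
        ## step halving: never decrease the log-likelihood
        stepsize <- 1
        repeat {
            cand <- beta + stepsize * step
            ll_new <- ll(cand)
            if (is.finite(ll_new) && ll_new >= ll_old - 1e-12) break
            stepsize <- stepsize / 2
            if (stepsize < 1e-10) { cand <- beta; ll_new <- ll_old; break }
        }
        beta <- cand
        ll_old <- ll_new
        trace <- c(trace, ll_new)
        max_score <- max(abs(as.numeric(crossprod(X, y -
            stats::plogis(as.numeric(X %*% beta))))))
        pinned <- mean(p > 1 - 1e-8 | p < 1e-8)
        if (pinned > 0 && max(abs(beta)) > 15) { separation <- TRUE; break }
        if (max_score < tol || iter >= max_iter) break
    }
    eta <- as.numeric(X %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-12)
    info <- crossprod(X * w, X)
    cov <- tryCatch(solve(info), error = function(e)
        matrix(NA_real_, ncol(X), ncol(X)))
    se <- sqrt(diag(cov))
    zq <- 1.959964
    z <- beta / se
    tab <- data.frame(term = colnames(X), estimate = beta, se = se,
                      or = exp(beta), ci_lo = exp(beta - zq * se),
                      ci_hi = exp(beta + zq * se), z = z,
                      p_value = 2 * stats::pnorm(-abs(z)),
                      row.names = NULL)
    converged <- is.finite(max_score) && max_score < tol && !separation
    if (separation)
        warning("(quasi-)separation detected: estimates are unreliable",
                call. = FALSE)
    methods::new("LogisticFit", coefTable = tab, converged = converged,
                 iterations = iter, logLik = ll_old, llTrace = trace,
                 maxScore = max_score, separation = separation,
                 n = length(y))
}

#' Full case-control validation report
#'
#' Given a cohort table, produces: a baseline comparison of every
#' variable between cases and controls (t-test for continuous, Fisher
#' exact for binary); univariate logistic fits per variable; a
#' multivariate fit with the biomarker plus all covariates; a sensitivity
#' fit (biomarker + age only, when age is among the covariates); and,
#' when a \code{probnp} column is present, the Spearman correlation of
#' the biomarker with proBNP among cases. The biomarker enters the
#' logistic models on the scale named by \code{biomarker_scale}
#' (\code{"raw"} ng/mL or \code{"log"}), which is recorded in the report.
#'
#' @param cohort data.frame as returned by \code{\link{readCohort}} or
#'   \code{\link{simulateCohort}}.
#' @param biomarker name of the biomarker column.
#' @param covariates character vector of covariate column names.
#' @param biomarker_scale \code{"raw"} or \code{"log"}.
#' @return list of class \code{CohortReport}: baseline, univariate
#'   (data.frame in odds-ratio table layout), multivariate, sensitivity,
#'   probnp_cor (NULL when unavailable), biomarker_scale, fits.
#' @export
runCohortAnalysis <- function(cohort, biomarker = "biomarker_ng_ml",
                              covariates = c("age_yr", "bmi_kg_m2", "htn",
                                             "dm", "egfr", "ldl_mg_dl"),
                              biomarker_scale = c("raw", "log")) {
    biomarker_scale <- match.arg(biomarker_scale)
    covariates <- intersect(covariates, names(cohort))
    y <- cohort$hf_status
    bm <- cohort[[biomarker]]
    if (biomarker_scale == "log") bm <- log(bm)
    vars <- c(stats::setNames(list(bm), biomarker),
              lapply(cohort[covariates], identity))

    baseline <- do.call(rbind, lapply(names(vars), function(nm) {
        x <- vars[[nm]]
        binary <- all(x %in% c(0, 1))
        if (binary) {
            tab <- rbind(c(sum(x[y == 1]), sum(1 - x[y == 1])),
                         c(sum(x[y == 0]), sum(1 - x[y == 0])))
            fe <- fisherExact(tab)
            data.frame(variable = nm, type = "binary",
                       case_stat = mean(x[y == 1]),
                       control_stat = mean(x[y == 0]),
                       p_value = fe$p_value)
        } else {
            tt <- tTestRaw(x[y == 1], x[y == 0], method = "welch")
            data.frame(variable = nm, type = "continuous",
                       case_stat = mean(x[y == 1]),
                       control_stat = mean(x[y == 0]),
                       p_value = tt$p_value)
        }
    }))

    uniFit <- function(nm) {
        X <- cbind(intercept = rep(1, length(y)), vars[[nm]])
        colnames(X) <- c("intercept", nm)
        logisticFit(X, y)
    }
    fits_uni <- lapply(names(vars), uniFit)
    names(fits_uni) <- names(vars)
    univariate <- do.call(rbind, lapply(names(vars), function(nm) {
        ct <- coefTable(fits_uni[[nm]])
        ct <- ct[ct$term == nm, , drop = FALSE]
        data.frame(variable = nm, or = ct$or, ci_lo = ct$ci_lo,
                   ci_hi = ct$ci_hi, p_value = ct$p_value)
    }))

    Xm <- cbind(intercept = 1, as.matrix(as.data.frame(vars)))
    colnames(Xm) <- c("intercept", names(vars))
    fit_multi <- logisticFit(Xm, y)
    ctm <- coefTable(fit_multi)
    multivariate <- data.frame(variable = ctm$term[-1L],
                               or = ctm$or[-1L], ci_lo = ctm$ci_lo[-1L],
                               ci_hi = ctm$ci_hi[-1L],
                               p_value = ctm$p_value[-1L])

    sensitivity <- NULL
    if ("age_yr" %in% covariates) {
        Xs <- cbind(intercept = 1, bm = vars[[biomarker]],
                    age_yr = vars[["age_yr"]])
        colnames(Xs) <- c("intercept", biomarker, "age_yr")
        fs <- coefTable(logisticFit(Xs, y))
        sensitivity <- data.frame(variable = fs$term[-1L],
                                  or = fs$or[-1L], ci_lo = fs$ci_lo[-1L],
                                  ci_hi = fs$ci_hi[-1L],
                                  p_value = fs$p_value[-1L])
    }

    probnp_cor <- NULL
    if ("probnp" %in% names(cohort)) {
        sub <- cohort[y == 1 & is.finite(cohort$probnp), ]
        if (nrow(sub) >= 3L)
            probnp_cor <- spearmanCor(sub[[biomarker]], sub$probnp)
    }

    structure(list(baseline = baseline, univariate = univariate,
                   multivariate = multivariate, sensitivity = sensitivity,
                   probnp_cor = probnp_cor,
                   biomarker_scale = biomarker_scale,
                   fits = c(fits_uni, list(multivariate = fit_multi))),
              class = "CohortReport")
}

#' @export
print.CohortReport <- function(x, ...) {
    fmt <- function(tab) {
        data.frame(variable = tab$variable,
                   `OR (95% CI)` = sprintf("%.3f (%.3f-%.3f)", tab$or,
                                           tab$ci_lo, tab$ci_hi),
                   p = signif(tab$p_value, 3), check.names = FALSE)
    }
    cat("Cohort analysis (biomarker scale:", x$biomarker_scale, ")\n")
    cat("\nUnivariate logistic models:\n")
    print(fmt(x$univariate), row.names = FALSE)
    cat("\nMultivariate model:\n")
    print(fmt(x$multivariate), row.names = FALSE)
    if (!is.null(x$probnp_cor))
        cat(sprintf("\nproBNP correlation (cases): rho = %.3f, p = %.3f\n",
                    x$probnp_cor$rho, x$probnp_cor$p_value))
    invisible(x)
}
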