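test_that("t-tests satisfy limit cases and match stats::t.test", {
    a <- c(1, 2, 3, 4)
    tt <- tTestRaw(a, a)
    expect_equal(tt$t, 0)
    expect_equal(tt$p_value, 1)
    # separation limit: huge shift, tiny variance
    far <- tTestRaw(a, a + 1000)
    expect_lt(far$p_value, 1e-10)
    set.seed(3)
    x <- rnorm(7); y <- rnorm(9, 0.5)
    for (m in c("pooled", "welch")) {
        mine <- tTestRaw(x, y, method = m)
        ref <- t.test(x, y, var.equal = (m == "pooled"))
        expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
        expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-12)
        expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
    }
    expect_error(tTestRaw(c(1, 1), c(1, 1)), "degenerate")
    expect_error(tTestSummary(1, 1, 1, 2, 1, 5), "n >= 2")
})

test_that("summary-statistic t-test is identical to the raw-data t-test", {
    set.seed(14)
    a <- rnorm(11, 5, 2); b <- rnorm(8, 4, 1.5)
    for (m in c("pooled", "welch")) {
        raw <- tTestRaw(a, b, method = m)
        sm <- tTestSummary(mean(a), sd(a), length(a),
                           mean(b), sd(b), length(b), method = m)
        expect_equal(sm$t, raw$t, tolerance = 1e-12)
        expect_equal(sm$df, raw$df, tolerance = 1e-12)
        expect_equal(sm$p_value, raw$p_value, tolerance = 1e-12)
    }
})

test_that("published group summaries reproduce the reported p-values", {
    # chronic beta-agonist infusion vs control plasma biomarker, assuming
    # 10 animals per arm (control n unprinted)
    iso <- tTestSummary(5.96, 2.66, 10, 3.18, 1.08, 10, method = "pooled")
    expect_equal(iso$p_value, 0.007, tolerance = 0.05)
    # pressure-overload vs sham, n = 6 per arm
    tac <- tTestSummary(4.19, 2.33, 6, 2.22, 1.80, 6, method = "pooled")
    expect_equal(tac$p_value, 0.13, tolerance = 0.05)
    # human case-control comparison: far below the reported < 0.0001
    # bound on either scale convention
    hum <- tTestSummary(1.20, 0.26, 270, 0.74, 0.40, 119,
                        method = "welch")
    expect_lt(hum$p_value, 1e-20)
})

test_that("pooled t p-value sits within Monte-Carlo reach of a permutation null", {
    set.seed(7)
    a <- round(rnorm(6, 5, 1), 3)
    b <- round(rnorm(6, 5.8, 1), 3)
    tt <- tTestRaw(a, b, method = "pooled")
    pool <- c(a, b)
    obs <- abs(mean(a) - mean(b))
    set.seed(1)
    perm <- mean(replicate(20000, {
        i <- sample(12, 6)
        abs(mean(pool[i]) - mean(pool[-i]))
    }) >= obs - 1e-12)
    expect_lt(abs(tt$p_value - perm), 0.01)
})

test_that("fisherExact equals full enumeration and handles degenerate margins", {
    expect_equal(fisherExact(rbind(c(1, 1), c(1, 1)))$p_value, 1)
    # a zero margin leaves a single possible table
    expect_equal(fisherExact(rbind(c(0, 0), c(3, 5)))$p_value, 1)
    res <- fisherExact(rbind(c(8, 2), c(1, 5)))
    expect_equal(res$p_value, enumFisher(8, 2, 1, 5), tolerance = 1e-12)
    expect_equal(res$odds_ratio, 20)
    expect_true(is.infinite(fisherExact(rbind(c(3, 0),
                                              c(1, 4)))$odds_ratio))
    expect_error(fisherExact(rbind(c(-1, 1), c(1, 1))), "nonnegative")
    # double-one-sided alternative is bounded by 1 and >= one tail
    d <- fisherExact(rbind(c(8, 2), c(1, 5)), alternative = "double")
    expect_lte(d$p_value, 1)
})

test_that("spearmanCor handles monotone, reversed and tied data", {
    x <- c(1, 2, 3, 4, 5)
    expect_equal(spearmanCor(x, x^3)$rho, 1)
    expect_equal(spearmanCor(x, -exp(x))$rho, -1)
    # midrank ties: compare against rank-then-pearson done by hand
    xt <- c(1, 2, 2, 3, 4, 5, 5, 5, 6, 7)
    yt <- c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9)
    mine <- spearmanCor(xt, yt)
    hand <- cor(rank(xt), rank(yt))
    expect_equal(mine$rho, hand, tolerance = 1e-12)
    expect_equal(mine$rho,
                 suppressWarnings(cor.test(xt, yt,
                                           method = "spearman")$estimate),
                 tolerance = 1e-12, ignore_attr = TRUE)
    const <- spearmanCor(rep(1, 5), 1:5)
    expect_identical(const$rho, 0)
    expect_identical(const$p_value, 1)
    expect_true(const$degenerate)
    expect_error(spearmanCor(1:2, 1:2), "at least 3")
})

test_that("logistic IRLS matches closed forms and the glm oracle", {
    # 2x2 closed form: exposed-case table [[10,20],[30,40]]
    x <- c(rep(1, 30), rep(0, 70))
    y <- c(rep(1, 10), rep(0, 20), rep(1, 30), rep(0, 40))
    fit <- logisticFit(cbind(intercept = 1, exposed = x), y)
    or <- coefTable(fit)$or[2L]
    expect_equal(or, (10 * 40) / (20 * 30), tolerance = 1e-8)
    # all-intercept model on 30% positives
    y2 <- c(rep(1, 30), rep(0, 70))
    fit2 <- logisticFit(matrix(1, 100, 1,
                               dimnames = list(NULL, "intercept")), y2)
    expect_equal(coefTable(fit2)$estimate, log(0.3 / 0.7),
                 tolerance = 1e-8)
    # random design vs glm: coefficients and Wald SEs
    set.seed(23)
    X <- cbind(intercept = 1, a = rnorm(300), b = rbinom(300, 1, 0.4))
    eta <- -0.3 + 0.8 * X[, "a"] - 0.5 * X[, "b"]
    yy <- rbinom(300, 1, plogis(eta))
    mine <- logisticFit(X, yy)
    ref <- glm(yy ~ X[, "a"] + X[, "b"], family = binomial())
    expect_equal(coefTable(mine)$estimate, unname(coef(ref)),
                 tolerance = 1e-6)
    expect_equal(coefTable(mine)$se,
                 unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
    expect_true(mine@converged)
    expect_lt(mine@maxScore, 1e-8)
    # log-likelihood is non-decreasing across iterations
    expect_true(all(diff(mine@llTrace) >= -1e-10))
    # CI contains the OR
    ct <- coefTable(mine)
    expect_true(all(ct$ci_lo <= ct$or & ct$or <= ct$ci_hi))
})

test_that("2x2 logistic OR equals the Fisher sample odds ratio exactly", {
    set.seed(29)
    for (i in 1:10) {
        tab <- matrix(rpois(4, 15) + 1, 2)
        x <- c(rep(1, tab[1, 1] + tab[1, 2]), rep(0, tab[2, 1] + tab[2, 2]))
        y <- c(rep(1, tab[1, 1]), rep(0, tab[1, 2]),
               rep(1, tab[2, 1]), rep(0, tab[2, 2]))
        fit <- logisticFit(cbind(intercept = 1, x = x), y)
        expect_equal(coefTable(fit)$or[2L],
                     fisherExact(tab)$odds_ratio, tolerance = 1e-8)
    }
})

test_that("separation is detected and flagged, not silently reported", {
    x <- c(rep(0, 10), rep(1, 10))
    y <- x
    expect_warning(fit <- logisticFit(cbind(intercept = 1, x = x), y),
                   "separation")
    expect_true(fit@separation)
    expect_false(fit@converged)
    expect_error(logisticFit(cbind(intercept = 1, z = rep(0, 10)),
                             rep(c(0, 1), 5)), "constant zero")
})

test_that("cohort report has the full published layout and optional pieces", {
    sim <- simulateCohort(cohortSimConfig(include_probnp = TRUE,
                                          seed = 31L))
    rep <- runCohortAnalysis(sim$cohort)
    expect_setequal(rep$univariate$variable,
                    c("biomarker_ng_ml", "age_yr", "bmi_kg_m2", "htn",
                      "dm", "egfr", "ldl_mg_dl"))
    expect_identical(rep$multivariate$variable, rep$univariate$variable)
    expect_identical(rep$sensitivity$variable,
                     c("biomarker_ng_ml", "age_yr"))
    expect_false(is.null(rep$probnp_cor))
    expect_identical(rep$biomarker_scale, "raw")
    # planted directions: protective biomarker and eGFR/LDL, harmful rest
    uv <- setNames(rep$univariate$or, rep$univariate$variable)
    expect_lt(uv[["biomarker_ng_ml"]], 1)
    expect_gt(uv[["age_yr"]], 1)
    expect_gt(uv[["dm"]], 1)
    expect_lt(uv[["egfr"]], 1)
    # without a proBNP column the correlation section is simply absent
    sim2 <- simulateCohort(cohortSimConfig(seed = 32L))
    rep2 <- runCohortAnalysis(sim2$cohort, biomarker_scale = "log")
    expect_null(rep2$probnp_cor)
    expect_identical(rep2$biomarker_scale, "log")
})
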