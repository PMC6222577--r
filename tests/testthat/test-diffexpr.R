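test_that("logFC is the treated-minus-control mean difference", {
    p <- toyPanel()
    # identical arms -> 0
    m <- matrix(c(1, 1, 2, 2), 1, dimnames = list("p1", paste0("s", 1:4)))
    same <- ExpressionPanel(m, strain = c("X", "X", "Y", "Y"),
                            treatment = c("control", "treated",
                                          "control", "treated"))
    expect_equal(logFoldChange(same, "p1"), 0)
    # exact unit shift
    m2 <- rbind(p1 = c(3, 4, 4, 5))
    colnames(m2) <- paste0("s", 1:4)
    shift <- ExpressionPanel(m2, strain = c("X", "Y", "X", "Y"),
                             treatment = c("control", "control",
                                           "treated", "treated"))
    expect_equal(logFoldChange(shift, "p1"), 1)
    # random 6-sample fixture vs one-line oracle
    set.seed(31)
    v <- matrix(rnorm(6), 1, dimnames = list("pX", paste0("s", 1:6)))
    arm <- c("control", "control", "control", "treated", "treated",
             "treated")
    pan <- ExpressionPanel(v, strain = rep(c("A", "B", "C"), 2),
                           treatment = arm)
    expect_equal(logFoldChange(pan, "pX"),
                 mean(v[1, 4:6]) - mean(v[1, 1:3]), tolerance = 1e-15)
    expect_error(logFoldChange(pan, "nope"), "unknown probe")
})

test_that("moderated t reduces to the ordinary t-test at d0 = 0", {
    set.seed(5)
    np <- 30; n <- 5
    v <- matrix(rnorm(np * 2 * n, 8, 0.7), np,
                dimnames = list(sprintf("p%02d", 1:np),
                                sprintf("s%02d", 1:(2 * n))))
    pan <- ExpressionPanel(v, strain = rep(paste0("st", 1:n), 2),
                           treatment = rep(c("control", "treated"),
                                           each = n))
    de <- runDE(pan, d0 = 0)
    for (i in c(1L, 7L, 30L)) {
        pid <- de$probe_id[i]
        tt <- t.test(v[pid, (n + 1):(2 * n)], v[pid, 1:n],
                     var.equal = TRUE)
        expect_equal(de$t_mod[i], unname(tt$statistic), tolerance = 1e-12)
        expect_equal(de$p_raw[i], tt$p.value, tolerance = 1e-12)
    }
})

test_that("shared residual variance is a fixed point of shrinkage", {
    s2 <- rep(0.25, 20)
    res <- moderatedT(logfc = rnorm(20), s2 = s2, df = 6, u = sqrt(0.5),
                      d0 = 4, s0 = 0.25)
    expect_equal(res$s2_post, s2)
    res2 <- moderatedT(logfc = rnorm(20), s2 = s2, df = 6, u = sqrt(0.5),
                       d0 = 50, s0 = 0.25)
    expect_equal(res2$s2_post, s2)
})

test_that("variance-prior estimation recovers generating (d0, s0^2)", {
    d0 <- 4; s02 <- 0.04; dfr <- 6L; np <- 50L
    skip_if_not_installed("limma")
    est <- t(vapply(seq_len(200L), function(i) {
        set.seed(200L + i)
        sigma2 <- s02 * d0 / rchisq(np, d0)
        s2 <- sigma2 * rchisq(np, dfr) / dfr
        pr <- estimateVariancePrior(s2, dfr)
        ff <- limma::fitFDist(s2, dfr)
        c(pr$d0, pr$s0, ff$df2, ff$scale)
    }, numeric(4)))
    # per-repeat equality with the independent closed-form implementation
    fin <- is.finite(est[, 1]) & is.finite(est[, 3])
    expect_gt(mean(fin), 0.95)
    expect_lt(max(abs(est[fin, 1] - est[fin, 3]) / est[fin, 3]), 1e-6)
    expect_lt(max(abs(est[, 2] - est[, 4]) / est[, 4]), 1e-6)
    # Monte-Carlo recovery: the d0 sampling distribution at 50 probes is
    # right-skewed, so the median is the stable location summary
    expect_gt(median(est[fin, 1]), 2.5)
    expect_lt(median(est[fin, 1]), 6)
    expect_lt(abs(mean(log(est[, 2])) - log(s02)), 0.15)
})

test_that("degenerate variance input is rejected", {
    expect_error(estimateVariancePrior(numeric(1), 4), "at least 2")
    expect_error(estimateVariancePrior(c(0, 0, 0), 4), "degenerate")
    expect_error(estimateVariancePrior(c(0.1, 0.2), 0.5), "df")
})

test_that("BH adjustment matches hand enumeration and oracles", {
    expect_equal(bhAdjust(0.03), 0.03)
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
    set.seed(77)
    for (i in 1:1000) {
        m <- sample(1:40, 1)
        p <- round(runif(m), 3)
        adj <- bhAdjust(p)
        expect_equal(adj, bruteBH(p), tolerance = 1e-12)
        expect_equal(adj, p.adjust(p, "BH"), tolerance = 1e-14)
        expect_true(all(adj >= p - 1e-15))
        expect_true(all(adj <= 1))
        # order preservation
        o <- order(p)
        expect_true(all(diff(adj[o]) >= -1e-15))
    }
})

test_that("whole DE stage agrees with the limma oracle", {
    skip_if_not_installed("limma")
    set.seed(17)
    np <- 120; n <- 4
    sigma2 <- 0.05 * 5 / rchisq(np, 5)
    v <- matrix(rnorm(np * 2 * n, 0, rep(sqrt(sigma2), 2 * n)), np,
                dimnames = list(sprintf("p%03d", 1:np),
                                sprintf("s%02d", 1:(2 * n)))) + 7
    v[1:6, (n + 1):(2 * n)] <- v[1:6, (n + 1):(2 * n)] + 1.2
    pan <- ExpressionPanel(v, strain = rep(paste0("st", 1:n), 2),
                           treatment = rep(c("control", "treated"),
                                           each = n))
    de <- runDE(pan)
    fit <- limma::eBayes(limma::lmFit(v, cbind(1, rep(0:1, each = n))))
    i <- match(de$probe_id, rownames(v))
    expect_equal(attr(de, "d0"), fit$df.prior, tolerance = 1e-8)
    expect_equal(attr(de, "s0"), fit$s2.prior, tolerance = 1e-8)
    expect_equal(de$t_mod, unname(fit$t[i, 2]), tolerance = 1e-10)
    expect_equal(de$p_raw, unname(fit$p.value[i, 2]), tolerance = 1e-10)
    expect_equal(de$logFC, unname(fit$coefficients[i, 2]),
                 tolerance = 1e-12)
    # AveExpr is the plain mean over all arrays
    expect_equal(de$AveExpr, unname(rowMeans(v)[i]), tolerance = 1e-12)
})

test_that("DE output contracts hold: ordering, signs, p ranges", {
    sim <- simulatePanel(panelSimConfig(n_strains = 12, n_probes = 150,
                                        n_de = 8, n_trait = 0,
                                        n_overlap = 0, seed = 21L))
    de <- runDE(sim$panel, sim$annotation)
    expect_true(all(de$p_raw >= 0 & de$p_raw <= 1))
    expect_true(all(de$p_adj >= de$p_raw - 1e-15))
    expect_true(all(sign(de$t_mod) == sign(de$logFC) | de$logFC == 0))
    expect_true(all(diff(abs(de$logFC)) <= 1e-12))
    desorted <- runDE(sim$panel, sim$annotation, sort_by = "p")
    expect_true(all(diff(desorted$p_raw) >= -1e-15))
})

test_that("a planted strong effect ranks first and duplicates sit together", {
    set.seed(13)
    np <- 80; n <- 6
    v <- matrix(rnorm(np * 2 * n, 7, 0.3), np,
                dimnames = list(sprintf("p%03d", 1:np),
                                sprintf("s%02d", 1:(2 * n))))
    v[1, (n + 1):(2 * n)] <- v[1, (n + 1):(2 * n)] + 2
    # Timp1-style duplicate probes: same symbol, same planted effect
    v[2, (n + 1):(2 * n)] <- v[2, (n + 1):(2 * n)] + 1.4
    v[3, (n + 1):(2 * n)] <- v[3, (n + 1):(2 * n)] + 1.4
    annot <- data.frame(probe_id = rownames(v),
                        symbol = c("Big", "Dup", "Dup",
                                   sprintf("G%03d", 4:np)),
                        species = "mouse")
    pan <- ExpressionPanel(v, strain = rep(paste0("st", 1:n), 2),
                           treatment = rep(c("control", "treated"),
                                           each = n))
    de <- runDE(pan, annot)
    expect_identical(de$probe_id[1L], "p001")
    dup_rows <- which(de$symbol == "Dup")
    expect_identical(diff(dup_rows), 1L)
    expect_lt(abs(de$logFC[dup_rows[1]] - de$logFC[dup_rows[2]]), 0.5)
})

test_that("planted signs are recovered for effects >= 3x noise sd", {
    hits <- vapply(seq_len(50L), function(i) {
        sim <- simulatePanel(panelSimConfig(
            n_strains = 10, n_probes = 60, n_de = 5, n_trait = 0,
            n_overlap = 0, logfc_range = c(1.5, 1.5),
            noise_sd_expr = 0.5, seed = 3000L + i))
        de <- runDE(sim$panel)
        planted <- sim$truth$planted_logfc[sim$truth$de_genes]
        est <- de$logFC[match(names(planted), de$probe_id)]
        all(sign(est) == sign(planted))
    }, logical(1))
    expect_gte(mean(hits), 0.99)
})
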