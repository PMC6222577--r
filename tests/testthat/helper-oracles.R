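# Independent oracles used across test files. These deliberately avoid
# the package's own code paths.

# tiny deterministic panel with explicit values
toyPanel <- function() {
    m <- matrix(c(1.0, 2.0, 3.0, 4.0,
                  5.0, 5.5, 6.0, 6.5,
                  9.0, 8.0, 7.0, 6.0), nrow = 3, byrow = TRUE,
                dimnames = list(c("pA", "pB", "pC"),
                                c("s1", "s2", "s3", "s4")))
    ExpressionPanel(m, strain = c("X", "X", "Y", "Y"),
                    treatment = c("control", "treated",
                                  "control", "treated"))
}

# brute-force BH step-up: sort, walk from the largest rank down
bruteBH <- function(p) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    adj <- numeric(m)
    prev <- 1
    for (i in m:1) {
        prev <- min(prev, ps[i] * m / i)
        adj[i] <- prev
    }
    out <- numeric(m)
    out[o] <- adj
    out
}

# full-enumeration Fisher probability-mass p, via log factorials only
enumFisher <- function(a, b, cc, d) {
    r1 <- a + b; r2 <- cc + d; c1 <- a + cc; n <- r1 + r2
    lp <- function(x) lchoose(r1, x) + lchoose(r2, c1 - x) -
        lchoose(n, c1)
    supp <- max(0, c1 - r2):min(r1, c1)
    probs <- exp(lp(supp))
    pobs <- exp(lp(a))
    min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

# group-by mean via split/sapply, independent of rowsum
groupMeanOracle <- function(v, strain) {
    t(sapply(split(seq_along(strain), strain)[unique(strain)],
             function(i) rowMeans(v[, i, drop = FALSE])))
}
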