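# Shared fixture builders: everything is generated in code at test time.

# small random gene x sample matrix with dimnames
randomMatrix <- function(nGenes, nSamples, seed = 1, mean = 5, sd = 1) {
    set.seed(seed)
    matrix(rnorm(nGenes * nSamples, mean = mean, sd = sd), nGenes, nSamples,
           dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                           sprintf("s%02d", seq_len(nSamples))))
}

# a tiny timecourse from an explicit genes x 14 matrix
timecourseFromMatrix <- function(m) {
    if (is.null(rownames(m))) rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
    colnames(m) <- paste0(rep(c("5X", "10X"), each = 7), "_d",
                          sprintf("%02d", rep(cultureDays(), 2)))
    FollicleTimecourse(m, condition = rep(c("5X", "10X"), each = 7),
                       day = rep(cultureDays(), 2))
}

# independent least-squares PVE oracle via lm()
pveOracle <- function(y, x = codedTime()) {
    fit <- lm(y ~ x + I(x^2) + I(x^3))
    summary(fit)$r.squared
}

# exhaustive-enumeration cohesion oracle over all 21 unordered pairs
cohesionOracle <- function(y) {
    ssdA <- 0; ssdNA <- 0
    for (i in 1:6) for (j in (i + 1):7) {
        d2 <- (y[i] - y[j])^2
        if (j - i == 1) ssdA <- ssdA + d2 else ssdNA <- ssdNA + d2
    }
    list(ssdA = ssdA, ssdNA = ssdNA, C = ssdA / ssdNA)
}

# brute-force quantile normalization oracle (mean of tied ranks)
quantileNormOracle <- function(m) {
    ranks <- apply(m, 2, rank, ties.method = "average")
    sorted <- apply(m, 2, sort)
    target <- rowMeans(sorted)
    out <- m
    for (j in seq_len(ncol(m)))
        out[, j] <- approx(seq_len(nrow(m)), target, xout = ranks[, j])$y
    out
}
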