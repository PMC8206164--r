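test_that("two-group fit computes textbook means and pooled variances", {
    m <- rbind(g1 = c(2, 2, 4, 4), g2 = c(1, 3, 6, 2))
    colnames(m) <- c("a1", "a2", "b1", "b2")
    fit <- fitTwoGroup(m, c("a1", "a2"), c("b1", "b2"))
    expect_equal(fit["g1", "logFC"], 2)
    expect_equal(fit["g1", "s2"], 0)
    expect_equal(fit["g1", "df"], 2)
    # antisymmetry under relabeling
    rev <- fitTwoGroup(m, c("b1", "b2"), c("a1", "a2"))
    expect_equal(rev$logFC, -fit$logFC)
    expect_equal(rev$s2, fit$s2)
    # brute-force oracle on random data
    mm <- randomMatrix(50, 8, seed = 1)
    A <- colnames(mm)[1:3]; B <- colnames(mm)[4:8]
    f <- fitTwoGroup(mm, A, B)
    for (i in c(1, 17, 50)) {
        a <- mm[i, A]; b <- mm[i, B]
        expect_equal(f$logFC[i], mean(b) - mean(a))
        expect_equal(f$s2[i],
                     (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / 6)
    }
    expect_error(fitTwoGroup(mm, A, c(A[1], B)), "overlap")
    expect_error(fitTwoGroup(mm, "nope", B), "unknown sample")
    expect_error(fitTwoGroup(mm, A[1], B[1]), "nA \\+ nB")
})

test_that("moderation reduces to no-op when variances are homogeneous", {
    s2 <- rep(0.5, 100)
    mod <- ebayesModerate(s2, df = 4)
    expect_true(all(abs(mod@postVar - 0.5) < 1e-8))
    m <- randomMatrix(100, 8, seed = 2)
    fit <- fitTwoGroup(m, colnames(m)[1:4], colnames(m)[5:8])
    modI <- ebayesModerate(fit$s2, fit$df, d0 = Inf)
    expect_true(all(modI@postVar == modI@s0sq))
    expect_error(ebayesModerate(rep(0, 20), df = 4), "zero")
})

test_that("hyperparameters are recovered from a known variance prior", {
    set.seed(3)
    d0 <- 4; s0sq <- 0.09; df <- 10; n <- 5000
    sigma2 <- s0sq * d0 / rchisq(n, d0)
    s2 <- sigma2 * rchisq(n, df) / df
    mod <- ebayesModerate(s2, df)
    expect_lt(abs(mod@d0 - d0) / d0, 0.15)
    expect_lt(abs(mod@s0sq - s0sq) / s0sq, 0.15)
    # posterior variances lie between the observation and the prior
    expect_true(all(mod@postVar >= pmin(s2, mod@s0sq) - 1e-12))
    expect_true(all(mod@postVar <= pmax(s2, mod@s0sq) + 1e-12))
})

test_that("moderated t agrees with limma on identical inputs", {
    m <- randomMatrix(300, 10, seed = 4)
    A <- colnames(m)[1:5]; B <- colnames(m)[6:10]
    de <- runDE(m, A, B)
    design <- cbind(1, rep(c(0, 1), each = 5))
    lf <- limma::eBayes(limma::lmFit(m, design))
    expect_equal(unname(de$logFC), unname(lf$coefficients[, 2]),
                 tolerance = 1e-10)
    expect_equal(unname(de$tModerated), unname(lf$t[, 2]), tolerance = 1e-6)
    expect_equal(unname(de$pValue), unname(lf$p.value[, 2]), tolerance = 1e-6)
})

test_that("moderated t handles null, scaling and classical limits", {
    m <- randomMatrix(60, 8, seed = 5)
    fit <- fitTwoGroup(m, colnames(m)[1:4], colnames(m)[5:8])
    fit$logFC[1] <- 0
    mod <- ebayesModerate(fit$s2, fit$df)
    tt <- moderatedT(fit, mod)
    expect_equal(tt$tModerated[1], 0)
    expect_equal(tt$pValue[1], 1)
    # doubling logFC doubles t at fixed variance
    fit2 <- fit; fit2$logFC <- 2 * fit$logFC
    tt2 <- moderatedT(fit2, mod)
    expect_equal(tt2$tModerated, 2 * tt$tModerated)
    # the ordinary t matches the classical pooled two-sample statistic
    i <- 7
    a <- m[i, 1:4]; b <- m[i, 5:8]
    sp <- sqrt(((3 * var(a) + 3 * var(b)) / 6) * (1/4 + 1/4))
    expect_equal(tt$tOrdinary[i], (mean(b) - mean(a)) / sp, tolerance = 1e-10)
    # swapping groups negates every t (on an unmodified fit)
    fit0 <- fitTwoGroup(m, colnames(m)[1:4], colnames(m)[5:8])
    tt0 <- moderatedT(fit0, ebayesModerate(fit0$s2, fit0$df))
    fitR <- fitTwoGroup(m, colnames(m)[5:8], colnames(m)[1:4])
    ttR <- moderatedT(fitR, ebayesModerate(fitR$s2, fitR$df))
    expect_equal(ttR$tModerated, -tt0$tModerated, tolerance = 1e-12)
})

test_that("logFC ranking sorts with the documented tie rules", {
    de <- S4Vectors::DataFrame(logFC = c(3, 1, 2),
                               tModerated = c(1, 1, 1),
                               row.names = c("g1", "g2", "g3"))
    expect_identical(rankByLogFC(de), c("g1", "g3", "g2"))
    tie <- S4Vectors::DataFrame(logFC = c(1, 1, 1),
                                tModerated = c(-2, 3, 1),
                                row.names = c("gb", "ga", "gc"))
    expect_identical(rankByLogFC(tie), c("ga", "gb", "gc"))
    # random input against an independent sort oracle
    set.seed(6)
    rnd <- S4Vectors::DataFrame(logFC = sample(rep(1:5, 4)),
                                tModerated = rnorm(20),
                                row.names = sprintf("g%02d", 1:20))
    ids <- rownames(rnd)
    oracle <- ids[order(-rnd$logFC, -abs(rnd$tModerated), ids)]
    expect_identical(rankByLogFC(rnd), oracle)
})

test_that("hypergeometric enrichment matches closed forms and enumeration", {
    universe <- paste0("g", 1:20)
    sets <- list(all5 = universe[1:5])
    res <- hypergeometricEnrichment(universe[1:5], universe, sets)
    expect_equal(res$pValue, 1 / choose(20, 5), tolerance = 1e-12)
    # zero overlap: p is a probability and hits the upper boundary
    res0 <- hypergeometricEnrichment(universe[6:8], universe, sets)
    expect_lte(res0$pValue, 1)
    expect_equal(res0$pValue, 1, tolerance = 1e-12)
    # exhaustive enumeration oracle on a small instance
    hits <- universe[1:6]; s <- universe[c(1, 2, 3, 10, 11)]
    obs <- length(intersect(s, hits))
    prob <- 0
    for (k in obs:length(s))
        prob <- prob + choose(6, k) * choose(14, 5 - k) / choose(20, 5)
    res2 <- hypergeometricEnrichment(hits, universe, list(s = s))
    expect_equal(res2$pValue, prob, tolerance = 1e-12)
    # size cap and validation
    expect_equal(nrow(hypergeometricEnrichment(hits, universe, sets,
                                               maxSetSize = 4)), 0)
    expect_error(hypergeometricEnrichment(hits, character(0), sets), "universe")
    expect_error(hypergeometricEnrichment("nope", universe, sets), "subset")
})

test_that("GMT collections round-trip", {
    d <- withr::local_tempdir()
    sets <- list(setA = c("g1", "g2", "g3"), setB = c("g4", "g5"))
    writeGMT(sets, file.path(d, "x.gmt"))
    back <- readGMT(file.path(d, "x.gmt"))
    expect_equal(back[order(names(back))], sets[order(names(sets))])
})
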