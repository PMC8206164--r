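test_that("condition collapsing averages the 5X and 10X columns", {
    m <- matrix(0, 4, 14); m[, 8:14] <- 2
    tc <- timecourseFromMatrix(m)
    coll <- collapseConditions(tc)
    expect_equal(dim(coll), c(4L, 7L))
    expect_true(all(coll == 1))
    tc2 <- simulateTimecourse(list(archetypeSpec("late_activator", 6)),
                              seed = 1)
    mm <- exprValues(tc2)
    expect_equal(unname(collapseConditions(tc2)),
                 unname((mm[, 1:7] + mm[, 8:14]) / 2))
})

test_that("harmonization intersects genes and equalizes distributions", {
    a <- randomMatrix(30, 4, seed = 2)
    b <- randomMatrix(40, 5, seed = 3)[11:40, ]
    rownames(b) <- rownames(a)[c(11:30, 1:10)]   # shared but reordered
    h <- harmonizeDatasets(a, b)
    expect_identical(rownames(h$a), rownames(h$b))
    joint <- cbind(h$a, h$b)
    sorted <- apply(joint, 2, sort)
    expect_true(all(abs(sorted - sorted[, 1]) < 1e-10))
    # disjoint gene sets are an error
    b2 <- b; rownames(b2) <- paste0("x", seq_len(nrow(b2)))
    expect_error(harmonizeDatasets(a, b2), "shared")
    # identical inputs harmonize to identical outputs
    h2 <- harmonizeDatasets(a, a)
    expect_equal(h2$a, h2$b)
    # idempotence: harmonizing harmonized inputs changes nothing
    h3 <- harmonizeDatasets(h$a, h$b)
    expect_equal(h3$a, h$a, tolerance = 1e-10)
})

test_that("transition t-scores carry the direction of the mean change", {
    m <- randomMatrix(50, 6, seed = 4)
    shifted <- cbind(m, m + 1)
    colnames(shifted) <- c(colnames(m), paste0("t", 1:6))
    tUp <- transitionTScores(shifted, from = colnames(m),
                             to = paste0("t", 1:6))
    expect_true(all(tUp > 0))
    # swapping groups negates the t vector
    tDown <- transitionTScores(shifted, from = paste0("t", 1:6),
                               to = colnames(m))
    expect_equal(tDown, -tUp, tolerance = 1e-12)
    # signs match a brute-force mean comparison on random groups
    t2 <- transitionTScores(m, from = colnames(m)[1:3], to = colnames(m)[4:6])
    delta <- rowMeans(m[, 4:6]) - rowMeans(m[, 1:3])
    nz <- delta != 0
    expect_equal(sign(t2[nz]), sign(delta[nz]))
})

test_that("t-score concordance handles identity, negation and validation", {
    set.seed(5)
    t1 <- setNames(rnorm(100), sprintf("g%03d", 1:100))
    same <- tscoreConcordance(t1, t1)
    expect_equal(same$r, 1)
    expect_setequal(same$agreement, names(t1)[t1 != 0])
    neg <- tscoreConcordance(t1, -t1)
    expect_equal(neg$r, -1)
    expect_setequal(neg$disagreement, names(t1)[t1 != 0])
    expect_length(neg$agreement, 0)
    # Fisher machinery: z = atanh(r), p from z * sqrt(n-3)
    t2 <- t1 + rnorm(100)
    res <- tscoreConcordance(t1, t2)
    expect_equal(res$z, atanh(res$r))
    expect_equal(res$p, 2 * pnorm(-abs(atanh(res$r)) * sqrt(97)))
    expect_equal(length(res$agreement) + length(res$disagreement) +
                 length(res$zeros), res$n)
    expect_error(tscoreConcordance(t1, rep(0, 100)), "variance")
    expect_error(tscoreConcordance(t1[1:3], t1[1:3]), "at least 4")
})

test_that("transition signs are consistent on noiseless monotone genes", {
    tc <- simulateTimecourse(
        list(archetypeSpec("delayed_activator", 30, noiseSd = 0),
             archetypeSpec("early_activator", 30, noiseSd = 0)),
        seed = 6)
    coll <- collapseConditions(tc)
    # shrinkage needs variance heterogeneity; use ordinary group means here
    days <- cultureDays()
    em <- rowMeans(coll[, days %in% c(4, 6, 7, 8)]) - coll[, days == 2]
    el <- rowMeans(coll[, days %in% c(10, 12)]) - coll[, days == 2]
    nz <- em != 0 & el != 0
    expect_true(all(sign(em[nz]) == sign(el[nz])))
})

test_that("end-to-end concordance recovers planted sign sharing", {
    tc <- simulateTimecourse(defaultArchetypeMix(40), seed = 7)
    ss1 <- simulateStageSeries(tc, sharedSignFraction = 1, noiseSd = 0.1,
                               seed = 8)
    ss0 <- simulateStageSeries(tc, sharedSignFraction = 0, noiseSd = 0.1,
                               seed = 9)
    co1 <- concordanceAnalysis(tc, ss1)
    co0 <- concordanceAnalysis(tc, ss0)
    r1 <- mean(sapply(co1@transitions, `[[`, "r"))
    r0 <- mean(sapply(co0@transitions, `[[`, "r"))
    expect_gt(r1, 0.8)
    expect_lt(abs(r0), 0.25)
    expect_gt(r1, r0)
    expect_equal(co1@nGenes, nrow(tc))
})
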