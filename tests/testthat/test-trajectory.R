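test_that("sample PCA reproduces the covariance eigenstructure", {
    m <- randomMatrix(200, 14, seed = 1)
    res <- pcaSamples(m, nComponents = 5)
    # oracle: eigendecomposition of the sample covariance of gene-centred data
    cm <- t(m - rowMeans(m))
    ev <- eigen(cov(cm), symmetric = TRUE)
    expect_equal(res$varianceFraction,
                 (ev$values / sum(ev$values))[1:5], tolerance = 1e-8)
    scoreOracle <- scale(cm, center = TRUE, scale = FALSE) %*% ev$vectors[, 1:5]
    for (j in 1:5)
        expect_equal(abs(unname(res$scores[, j])),
                     abs(unname(scoreOracle[, j])), tolerance = 1e-6)
    expect_true(all(diff(res$varianceFraction) <= 1e-12))
    expect_lte(sum(res$varianceFraction), 1 + 1e-12)
})

test_that("PCA degenerate cases: rank-1 data and duplicated samples", {
    v <- rnorm(14)
    m <- outer(rnorm(50), v)
    dimnames(m) <- list(paste0("g", 1:50), paste0("s", 1:14))
    res <- pcaSamples(m, nComponents = 3)
    expect_equal(res$varianceFraction[1], 1, tolerance = 1e-10)
    m2 <- randomMatrix(40, 6, seed = 2)
    m2[, 6] <- m2[, 5]
    res2 <- pcaSamples(m2, nComponents = 3)
    expect_equal(res2$scores[5, ], res2$scores[6, ], tolerance = 1e-10)
    expect_error(pcaSamples(m2, nComponents = 6), "exceeds")
})

test_that("consensus profiles are the elementwise condition means", {
    m <- matrix(0, 3, 14)
    m[, 8:14] <- 2
    tc <- timecourseFromMatrix(m)
    traj <- consensusProfiles(tc)
    expect_true(all(traj@consensus == 1))
    # random input: elementwise mean oracle
    tc2 <- simulateTimecourse(list(archetypeSpec("oscillatory", 10)), seed = 3)
    tr2 <- consensusProfiles(tc2)
    mm <- exprValues(tc2)
    expect_equal(unname(tr2@consensus),
                 unname((mm[, 1:7] + mm[, 8:14]) / 2))
    # identical conditions: consensus equals either
    m3 <- cbind(randomMatrix(4, 7, seed = 4), randomMatrix(4, 7, seed = 4))
    tc3 <- timecourseFromMatrix(m3)
    expect_equal(unname(consensusProfiles(tc3)@consensus), unname(m3[, 1:7]))
    # missing condition-day cell is named
    expect_error(consensusProfiles(tc[, -3]), "5X/day6")
})

test_that("consensus averaging commutes with row mean-centering", {
    tc <- simulateTimecourse(list(archetypeSpec("early_activator", 15)),
                             seed = 5)
    a <- consensusProfiles(meanCenterRows(tc))@consensus
    b <- consensusProfiles(tc)@consensus
    expect_equal(unname(a), unname(b - rowMeans(exprValues(tc))),
                 tolerance = 1e-12)
})

test_that("k-means recovers well-separated planted profiles exactly", {
    specs <- list(archetypeSpec("early_activator", 50, noiseSd = 0),
                  archetypeSpec("transient_mid", 50, noiseSd = 0),
                  archetypeSpec("late_activator", 50, noiseSd = 0))
    tc <- simulateTimecourse(specs, seed = 6, baseline = 0)
    traj <- consensusProfiles(tc)
    km <- kmeansProfiles(traj, k = 3, seed = 1)
    truth <- syntheticTruth(tc)$archetype
    # partition equals archetype groups up to label permutation
    expect_equal(length(unique(paste(truth, assignments(km)))), 3)
    # determinism
    km2 <- kmeansProfiles(traj, k = 3, seed = 1)
    expect_identical(assignments(km), assignments(km2))
})

test_that("k-means degenerate and error cases behave", {
    tc <- simulateTimecourse(list(archetypeSpec("delayed_activator", 30)),
                             seed = 7)
    traj <- consensusProfiles(standardizeRows(tc))
    km1 <- kmeansProfiles(traj, k = 1, seed = 1)
    expect_equal(unname(km1@centroids[1, ]),
                 unname(colMeans(traj@consensus)), tolerance = 1e-10)
    zero <- simulateTimecourse(list(archetypeSpec("flat", 5, noiseSd = 0)),
                               seed = 8, baseline = 0)
    expect_error(kmeansProfiles(consensusProfiles(zero), k = 3), "distinct")
})

test_that("contrast definitions translate day sets into sample groups", {
    tc <- simulateTimecourse(list(archetypeSpec("transient_mid", 5)), seed = 9)
    grp <- defineContrasts(tc, list(`1` = list(high = c(4, 6, 7, 8, 10),
                                               low = c(2, 12))))[[1]]
    # middle five time points in both conditions = 10 samples; ends = 4
    expect_length(grp$high, 10)
    expect_length(grp$low, 4)
    # recount oracle against metadata
    expect_setequal(grp$high,
                    colnames(tc)[cultureDay(tc) %in% c(4, 6, 7, 8, 10)])
    expect_length(intersect(grp$high, grp$low), 0)
    # skip flag, overlap and empty-group validation
    sk <- defineContrasts(tc, list(`1` = list(skip = TRUE)))[[1]]
    expect_true(sk$skip)
    expect_error(defineContrasts(tc, list(`1` = list(high = 2, low = 2))),
                 "overlap")
    expect_error(defineContrasts(tc, list(`1` = list(high = 4,
                                                     low = numeric(0)))),
                 "nonempty")
    expect_error(defineContrasts(tc, list(`1` = list(high = 5, low = 2))),
                 "absent")
})
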