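test_that("PVE is exactly 1 on trajectories inside the cubic span", {
    x <- codedTime()
    expect_equal(cubicPVE(x^3)$pve, 1, tolerance = 1e-10)
    expect_equal(cubicPVE(0:6)$pve, 1, tolerance = 1e-10)
    expect_equal(cubicPVE(2 - 0.5 * x + 0.1 * x^2)$pve, 1, tolerance = 1e-10)
})

test_that("PVE matches the independent least-squares oracle", {
    y <- c(0, 1, 0, 1, 0, 1, 0)
    expect_equal(cubicPVE(y)$pve, pveOracle(y), tolerance = 1e-10)
    set.seed(1)
    for (i in 1:20) {
        yr <- rnorm(7)
        expect_equal(cubicPVE(yr)$pve, pveOracle(yr), tolerance = 1e-10)
    }
})

test_that("PVE handles the constant-trajectory sentinel and affine invariance", {
    res <- cubicPVE(rep(3, 7))
    expect_true(is.na(res$pve))
    set.seed(2)
    y <- rnorm(7)
    expect_equal(cubicPVE(5 + 2 * y)$pve, cubicPVE(y)$pve, tolerance = 1e-10)
    expect_equal(meanPVE(codedTime()^3, c(0, 1, 0, 1, 0, 1, 0)),
                 (1 + pveOracle(c(0, 1, 0, 1, 0, 1, 0))) / 2,
                 tolerance = 1e-10)
    expect_true(is.na(meanPVE(rep(1, 7), codedTime())))
})

test_that("cohesion matches exhaustive enumeration over all 21 pairs", {
    ramp <- cohesion(0:6)
    expect_equal(ramp$ssdA, 6)
    expect_equal(ramp$ssdNA, 190)
    expect_equal(ramp$C, 6 / 190)
    alt <- cohesion(c(0, 1, 0, 1, 0, 1, 0))
    expect_equal(alt$C, 1)
    expect_equal(alt$ssdA, 6); expect_equal(alt$ssdNA, 6)
    set.seed(3)
    for (i in 1:20) {
        y <- rnorm(7)
        o <- cohesionOracle(y)
        got <- cohesion(y)
        expect_equal(got$ssdA, o$ssdA, tolerance = 1e-12)
        expect_equal(got$ssdNA, o$ssdNA, tolerance = 1e-12)
        expect_equal(got$C, o$C, tolerance = 1e-12)
        # 21-pair accounting and shift/scale invariance
        expect_equal(cohesion(10 + 3 * y)$C, got$C, tolerance = 1e-10)
    }
    expect_true(is.na(cohesion(rep(2, 7))$C))
})

test_that("two-factor ANOVA decomposes sums of squares exactly", {
    set.seed(4)
    for (i in 1:100) {
        y5 <- rnorm(7); y10 <- rnorm(7)
        res <- twofactorAnova(y5, y10)
        expect_lt(abs(res$SS[["total"]] - res$SS[["group"]] -
                      res$SS[["time"]] - res$SS[["interaction"]]), 1e-10)
    }
    # oracle: aov on the long-format 2x7 table
    y5 <- rnorm(7); y10 <- rnorm(7)
    d <- data.frame(y = c(y5, y10),
                    g = factor(rep(c("5X", "10X"), each = 7)),
                    t = factor(rep(1:7, 2)))
    ss <- summary(aov(y ~ g + t, data = d))[[1]][, "Sum Sq"]
    res <- twofactorAnova(y5, y10)
    expect_equal(res$SS[["group"]], ss[1], tolerance = 1e-10)
    expect_equal(res$SS[["time"]], ss[2], tolerance = 1e-10)
    expect_equal(res$SS[["interaction"]], ss[3], tolerance = 1e-10)
})

test_that("additive and identical condition series give zero interaction", {
    set.seed(5)
    y5 <- rnorm(7)
    res <- twofactorAnova(y5, y5 + 1.7)
    expect_equal(res$SS[["interaction"]], 0, tolerance = 1e-12)
    expect_equal(res$F[["interaction"]], 0, tolerance = 1e-10)
    same <- twofactorAnova(y5, y5)
    expect_equal(same$F[["group"]], 0, tolerance = 1e-12)
    expect_equal(same$F[["interaction"]], 0, tolerance = 1e-12)
    # cubic series leave zero error mean square: sentinel
    x <- codedTime()
    res2 <- twofactorAnova(x^2, x^3)
    expect_true(all(is.na(res2$F)))
})

test_that("the combined filter applies strict thresholds and sentinels", {
    mkScores <- function(pve, c, f) S4Vectors::DataFrame(
        pveMean = pve, cMean = c, fInt = f,
        pass = !is.na(pve) & !is.na(c) & !is.na(f) &
            pve > 0.6 & c < 0.35 & f > 2,
        row.names = sprintf("g%d", seq_along(pve)))
    sc <- mkScores(c(0.9, 0.9, 0.5, NA), c(0.1, 0.5, 0.1, 0.1),
                   c(5, 5, 5, 5))
    res <- applySmoothnessFilter(sc, filterThresholds())
    expect_identical(res$retained, "g1")
    # vacuous thresholds retain every non-sentinel gene
    resAll <- applySmoothnessFilter(sc, filterThresholds(0, Inf, 0))
    expect_setequal(resAll$retained, c("g1", "g2", "g3"))
})

test_that("smoothness scores separate planted smooth genes from noise", {
    specs <- list(archetypeSpec("u_shape_5x_vs_rise_10x", 100),
                  archetypeSpec("fall_5x_vs_rise_10x", 100),
                  archetypeSpec("flat", 200))
    tc <- simulateTimecourse(specs, seed = 6)
    sc <- smoothnessScores(tc)
    truth <- syntheticTruth(tc)
    expect_gt(mean(sc$pass[truth$divergent]), 0.9)
    expect_lt(mean(sc$pass[!truth$divergent]), 0.05)
    # scores table is complete and within range
    expect_true(all(sc$pveMean >= 0 & sc$pveMean <= 1, na.rm = TRUE))
    expect_true(all(sc$cMean >= 0, na.rm = TRUE))
    expect_true(all(sc$fInt >= 0, na.rm = TRUE))
})

test_that("added noise does not increase expected PVE of a smooth curve", {
    base <- archetypeCurve("delayed_activator", "5X")
    set.seed(7)
    clean <- cubicPVE(base)$pve
    noisy <- mean(replicate(200, cubicPVE(base + rnorm(7, sd = 0.5))$pve))
    expect_lt(noisy, clean + 1e-6)
})
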