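## Trajectory-quality statistics and the combined gene filter.
##
## Three per-gene statistics grade a 7-point trajectory:
##  * PVE  — fraction of trajectory variance explained by a least-squares
##           cubic in coded time; high PVE = smooth, trend-like.
##  * C    — lag cohesion: sum of squared adjacent-pair differences over the
##           sum of squared non-adjacent-pair differences (6 vs 15 of the 21
##           pairs); low C = adjacent points agree, no stochastic spikes.
##  * F    — two-factor (condition x time) ANOVA F statistics from the
##           unreplicated 2x7 layout; a large interaction F flags genes whose
##           temporal shape differs between 5X and 10X.
## The default filter keeps genes with PVE > 0.6, C < 0.35 and F_int > 2.

#' Least-squares cubic fit and percent variance explained
#'
#' Fits \eqn{y = a x^3 + b x^2 + c x + d} on the coded time grid and returns
#' the fraction of the trajectory's variance captured by the fit,
#' \eqn{PVE = V_C / V_T}. A constant trajectory (zero total variance) has no
#' defined PVE and returns \code{NA} (the gene then fails the filter).
#'
#' @param y numeric trajectory, one value per time point.
#' @param x coded time grid (default \code{codedTime()}).
#' @return List: \code{coefficients} (a, b, c, d), \code{fitted},
#'   \code{rss}, \code{vC}, \code{vT}, \code{pve}.
#' @examples
#' cubicPVE(codedTime()^3)$pve   # exactly 1: the curve lies in the span
#' @export
cubicPVE <- function(y, x = codedTime()) {
    stopifnot(length(y) == length(x), length(y) >= 5L)
    if (!all(is.finite(y))) stop("trajectory contains non-finite values")
    vT <- var(y)
    if (vT == 0)
        return(list(coefficients = c(a = NA_real_, b = NA_real_,
                                     c = NA_real_, d = NA_real_),
                    fitted = rep(mean(y), length(y)), rss = 0,
                    vC = 0, vT = 0, pve = NA_real_))
    X <- cbind(x^3, x^2, x, 1)
    beta <- qr.coef(qr(X), y)
    fitted <- drop(X %*% beta)
    rss <- sum((y - fitted)^2)
    vC <- var(fitted)
    pve <- min(1, max(0, vC / vT))
    list(coefficients = setNames(beta, c("a", "b", "c", "d")),
         fitted = fitted, rss = rss, vC = vC, vT = vT, pve = pve)
}

#' Average PVE of the two condition series
#'
#' @param y5x,y10x 7-point trajectories for the 5X and 10X series.
#' @param x coded time grid.
#' @return Mean of the two PVEs; \code{NA} if either is undefined.
#' @export
meanPVE <- function(y5x, y10x, x = codedTime()) {
    p5 <- cubicPVE(y5x, x)$pve
    p10 <- cubicPVE(y10x, x)$pve
    (p5 + p10) / 2
}

#' Lag cohesion of a trajectory
#'
#' From the 7-by-7 matrix of absolute pairwise differences,
#' \eqn{C = SSD_A / SSD_{N-A}}: the sum of squares of the 6 adjacent
#' differences over the sum of squares of the 15 non-adjacent differences.
#' Smooth trajectories have small C; spiky ones approach or exceed 1.
#'
#' @param y numeric 7-point trajectory.
#' @return List: \code{C} (\code{NA} if the non-adjacent sum is zero),
#'   \code{ssdA}, \code{ssdNA}.
#' @examples
#' cohesion(0:6)$C          # 6/190, a perfectly smooth ramp
#' cohesion(c(0,1,0,1,0,1,0))$C  # 1, maximally spiky
#' @export
cohesion <- function(y) {
    stopifnot(length(y) == 7L)
    if (!all(is.finite(y))) stop("trajectory contains non-finite values")
    d <- abs(outer(y, y, "-"))
    lag <- abs(outer(seq_len(7L), seq_len(7L), "-"))
    ssdA <- sum(d[lag == 1L]^2) / 2      # each unordered pair counted once
    ssdNA <- sum(d[lag >= 2L]^2) / 2
    C <- if (ssdNA == 0) NA_real_ else ssdA / ssdNA
    list(C = C, ssdA = ssdA, ssdNA = ssdNA)
}

#' Two-factor ANOVA of the unreplicated 2 x 7 design
#'
#' Decomposes the 14 values of one gene (condition x time, one observation
#' per cell) into condition, time and interaction sums of squares. With one
#' observation per cell the saturated model leaves no residual degrees of
#' freedom, so the error mean square is estimated from the pooled residuals
#' of the per-series cubic fits (3 df each, 6 df total) by default, or by an
#' extra-sum-of-squares test of the group-by-cubic interaction
#' (\code{errorMethod = "polyInteraction"}).
#'
#' @param y5x,y10x 7-point series for the two conditions.
#' @param x coded time grid.
#' @param errorMethod "cubicResidual" (default) or "polyInteraction".
#' @return List: \code{F} (named: group, time, interaction), \code{SS}
#'   (group, time, interaction, total), \code{msError}, \code{dfError}. F
#'   values are \code{NA} when the error mean square is zero.
#' @export
twofactorAnova <- function(y5x, y10x, x = codedTime(),
                           errorMethod = c("cubicResidual",
                                           "polyInteraction")) {
    errorMethod <- match.arg(errorMethod)
    stopifnot(length(y5x) == 7L, length(y10x) == 7L)
    y <- rbind(y5x, y10x)
    grand <- mean(y)
    ssGroup <- 7 * sum((rowMeans(y) - grand)^2)
    ssTime <- 2 * sum((colMeans(y) - grand)^2)
    ssTotal <- sum((y - grand)^2)
    ssInt <- ssTotal - ssGroup - ssTime
    ssInt <- max(ssInt, 0)   # guard tiny negative rounding

    rss5 <- cubicPVE(y5x, x)$rss
    rss10 <- cubicPVE(y10x, x)$rss
    ## residuals that are pure floating-point dust count as a zero error term
    msZero <- 1e-10 * (ssTotal / 13 + .Machine$double.xmin)
    if (errorMethod == "cubicResidual") {
        dfError <- 6
        msError <- (rss5 + rss10) / dfError
        msInt <- ssInt / 6
        if (msError <= msZero) {
            msError <- 0
            f <- c(group = NA_real_, time = NA_real_, interaction = NA_real_)
        } else {
            f <- c(group = ssGroup / 1 / msError,
                   time = ssTime / 6 / msError,
                   interaction = msInt / msError)
        }
    } else {
        ## reduced model: common cubic + group offset; full: separate cubics
        X <- cbind(x^3, x^2, x, 1)
        yAll <- c(y5x, y10x)
        Xred <- rbind(cbind(X, 0), cbind(X, 1))
        rssRed <- sum(qr.resid(qr(Xred), yAll)^2)
        rssFull <- rss5 + rss10
        dfError <- 6
        msError <- rssFull / dfError
        if (msError <= msZero) {
            msError <- 0
            f <- c(group = NA_real_, time = NA_real_, interaction = NA_real_)
        } else {
            f <- c(group = ssGroup / 1 / msError,
                   time = ssTime / 6 / msError,
                   interaction = ((rssRed - rssFull) / 3) / msError)
        }
    }
    list(F = f,
         SS = c(group = ssGroup, time = ssTime, interaction = ssInt,
                total = ssTotal),
         msError = msError, dfError = dfError)
}

#' Default smoothness-filter thresholds
#'
#' @param pve minimum mean PVE (strict), default 0.6.
#' @param c maximum mean cohesion (strict), default 0.35.
#' @param f minimum interaction F (strict), default 2.
#' @return Named list of thresholds.
#' @export
filterThresholds <- function(pve = 0.6, c = 0.35, f = 2) {
    stopifnot(is.numeric(pve), is.numeric(c), is.numeric(f),
              pve >= 0, pve <= 1)
    list(pve = pve, c = c, f = f)
}

#' Per-gene smoothness, cohesion and ANOVA scores
#'
#' Computes, for every gene of a 14-sample time course, the per-condition
#' and averaged cubic-fit PVE and cohesion, the two-factor ANOVA F
#' statistics, and the combined pass verdict under the given thresholds.
#'
#' With the default \code{errorMethod = "moderatedCubicResidual"}, each
#' gene's error mean square (pooled per-series cubic residuals, 6 df) is
#' shrunk across genes by the same empirical-Bayes machinery used for the
#' moderated t before forming the F ratios. With only 6 error df per gene,
#' the raw per-gene error estimate is unstable and strongly anticorrelated
#' with the gene's own incidental smoothness, which would let white-noise
#' genes that happen to look smooth pass the F criterion; cross-gene
#' moderation stabilises the denominator and restores the filter's
#' discrimination. \code{"cubicResidual"} uses each gene's own error mean
#' square unmoderated.
#'
#' @param tc a \code{FollicleTimecourse}.
#' @param thresholds see \code{\link{filterThresholds}}.
#' @param fStatistic which F must exceed the threshold: "interaction"
#'   (default) or "max" (largest of the three).
#' @param errorMethod "moderatedCubicResidual" (default), "cubicResidual"
#'   or "polyInteraction" (see \code{\link{twofactorAnova}} for the latter
#'   two).
#' @return \code{DataFrame}, one row per gene: pve5x, pve10x, pveMean, c5x,
#'   c10x, cMean, fGroup, fTime, fInt, pass. Undefined (sentinel) statistics
#'   are \code{NA} and fail the filter.
#' @export
smoothnessScores <- function(tc, thresholds = filterThresholds(),
                             fStatistic = c("interaction", "max"),
                             errorMethod = c("moderatedCubicResidual",
                                             "cubicResidual",
                                             "polyInteraction")) {
    fStatistic <- match.arg(fStatistic)
    errorMethod <- match.arg(errorMethod)
    traj <- consensusProfiles(tc)
    n <- nrow(traj@consensus)
    x <- traj@x
    out <- matrix(NA_real_, n, 9L)
    colnames(out) <- c("pve5x", "pve10x", "pveMean", "c5x", "c10x", "cMean",
                       "fGroup", "fTime", "fInt")
    moderated <- errorMethod == "moderatedCubicResidual"
    perGeneMethod <- if (moderated) "cubicResidual" else errorMethod
    errorMS <- ssInt <- ssGroup <- ssTime <- rep(NA_real_, n)
    for (i in seq_len(n)) {
        y5 <- traj@profile5x[i, ]
        y10 <- traj@profile10x[i, ]
        p5 <- cubicPVE(y5, x)$pve
        p10 <- cubicPVE(y10, x)$pve
        c5 <- cohesion(y5)$C
        c10 <- cohesion(y10)$C
        av <- twofactorAnova(y5, y10, x, errorMethod = perGeneMethod)
        errorMS[i] <- av$msError
        ssGroup[i] <- av$SS[["group"]]
        ssTime[i] <- av$SS[["time"]]
        ssInt[i] <- av$SS[["interaction"]]
        out[i, ] <- c(p5, p10, (p5 + p10) / 2, c5, c10, (c5 + c10) / 2,
                      av$F[["group"]], av$F[["time"]], av$F[["interaction"]])
    }
    if (moderated && sum(errorMS > 0, na.rm = TRUE) >= 10L) {
        mod <- ebayesModerate(errorMS, df = 6)
        denom <- mod@postVar
        out[, "fGroup"] <- ifelse(denom > 0, ssGroup / 1 / denom, NA_real_)
        out[, "fTime"] <- ifelse(denom > 0, ssTime / 6 / denom, NA_real_)
        out[, "fInt"] <- ifelse(denom > 0, ssInt / 6 / denom, NA_real_)
    }
    fUsed <- if (fStatistic == "interaction") out[, "fInt"]
             else pmax(out[, "fGroup"], out[, "fTime"], out[, "fInt"])
    pass <- !is.na(out[, "pveMean"]) & !is.na(out[, "cMean"]) & !is.na(fUsed) &
        out[, "pveMean"] > thresholds$pve &
        out[, "cMean"] < thresholds$c &
        fUsed > thresholds$f
    res <- DataFrame(out, pass = pass, row.names = rownames(traj@consensus))
    metadata(res) <- list(thresholds = thresholds, fStatistic = fStatistic,
                          errorMethod = errorMethod)
    res
}

#' Apply the smoothness filter
#'
#' @param scores result of \code{\link{smoothnessScores}}.
#' @param thresholds optional thresholds overriding those stored with the
#'   scores (re-evaluates the verdict).
#' @return List: \code{retained} gene identifiers, and per-criterion pass
#'   counts (\code{nPve}, \code{nCohesion}, \code{nF}, \code{nRetained}).
#' @export
applySmoothnessFilter <- function(scores, thresholds = NULL) {
    if (is.null(thresholds)) {
        pass <- scores$pass
        thresholds <- metadata(scores)$thresholds
    } else {
        pass <- !is.na(scores$pveMean) & !is.na(scores$cMean) &
            !is.na(scores$fInt) &
            scores$pveMean > thresholds$pve &
            scores$cMean < thresholds$c &
            scores$fInt > thresholds$f
    }
    list(retained = rownames(scores)[pass],
         nPve = sum(scores$pveMean > thresholds$pve, na.rm = TRUE),
         nCohesion = sum(scores$cMean < thresholds$c, na.rm = TRUE),
         nF = sum(scores$fInt > thresholds$f, na.rm = TRUE),
         nRetained = sum(pass))
}
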