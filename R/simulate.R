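## Synthetic-data generator. Every gene is a noisy realisation of a known
## archetype base curve, and the ground truth (archetype, divergence flag,
## amplitude, baseline, per-gene noise SD) is carried in rowData so that
## downstream recovery can be scored exactly.

.sampleIds <- function() {
    paste0(rep(c("5X", "10X"), each = 7), "_d",
           sprintf("%02d", rep(cultureDays(), 2)))
}

#' Simulate a two-condition follicle-culture time course
#'
#' Generates the 14-sample design (2 conditions x 7 culture days, one sample
#' per cell) from a list of archetype specifications. Each gene's value is
#' baseline + archetype base curve + N(0, noiseSd^2) noise. With
#' \code{geneNoise = "invchisq"}, per-gene noise variances are drawn from a
#' scaled inverse-chi-square distribution (prior df \code{invChisqDf}, scale
#' \code{noiseSd^2}), the variance model the moderated-t machinery assumes.
#'
#' @param specs list of \code{\link{archetypeSpec}} objects; total gene
#'   count must be at least 1.
#' @param seed integer seed; fixed seed reproduces the matrix exactly.
#' @param baseline per-gene mean log-expression: a range \code{c(lo, hi)}
#'   sampled uniformly per gene (default 4--10, a realistic log-intensity
#'   spread that keeps genes above a typical intensity filter), or a single
#'   value for a constant baseline.
#' @param geneNoise "constant" (each gene uses its spec's noiseSd) or
#'   "invchisq" (per-gene SDs drawn around the spec's noiseSd).
#' @param invChisqDf prior degrees of freedom for "invchisq" noise.
#' @return A \code{\link{FollicleTimecourse}} whose \code{rowData} holds the
#'   synthetic truth (archetype, divergent, amplitude, baseline, noiseSd).
#' @examples
#' tc <- simulateTimecourse(list(archetypeSpec("late_activator", 5)), seed = 1)
#' dim(tc)
#' @export
simulateTimecourse <- function(specs, seed, baseline = c(4, 10),
                               geneNoise = c("constant", "invchisq"),
                               invChisqDf = 4) {
    geneNoise <- match.arg(geneNoise)
    if (inherits(specs, "ArchetypeSpec")) specs <- list(specs)
    if (length(specs) == 0L) stop("empty archetype spec list")
    if (!all(vapply(specs, inherits, TRUE, "ArchetypeSpec")))
        stop("specs must be a list of ArchetypeSpec objects")
    nTotal <- sum(vapply(specs, `[[`, 1L, "nGenes"))
    if (nTotal < 1L) stop("total gene count must be at least 1")

    set.seed(as.integer(seed))
    x <- codedTime()
    archetype <- unlist(lapply(specs, function(s) rep(s$name, s$nGenes)))
    amplitude <- unlist(lapply(specs, function(s) rep(s$amplitude, s$nGenes)))
    specSd    <- unlist(lapply(specs, function(s) rep(s$noiseSd, s$nGenes)))
    geneIds <- sprintf("gene_%05d", seq_len(nTotal))

    base <- if (length(baseline) == 2L)
        stats::runif(nTotal, baseline[1], baseline[2]) else rep(baseline[1], nTotal)
    noiseSd <- if (geneNoise == "invchisq")
        sqrt(specSd^2 * invChisqDf / rchisq(nTotal, df = invChisqDf))
    else specSd

    vals <- matrix(NA_real_, nTotal, 14L,
                   dimnames = list(geneIds, .sampleIds()))
    curves5 <- curves10 <- matrix(NA_real_, nTotal, 7L)
    for (a in unique(archetype)) {
        idx <- which(archetype == a)
        for (amp in unique(amplitude[idx])) {
            j <- idx[amplitude[idx] == amp]
            curves5[j, ]  <- matrix(archetypeCurve(a, "5X",  x, amp),
                                    length(j), 7L, byrow = TRUE)
            curves10[j, ] <- matrix(archetypeCurve(a, "10X", x, amp),
                                    length(j), 7L, byrow = TRUE)
        }
    }
    vals[, 1:7]  <- base + curves5  + rnorm(nTotal * 7L) * noiseSd
    vals[, 8:14] <- base + curves10 + rnorm(nTotal * 7L) * noiseSd

    rd <- DataFrame(archetype = archetype,
                    divergent = isDivergentArchetype(archetype),
                    amplitude = amplitude,
                    baseline = base,
                    noiseSd = noiseSd,
                    row.names = geneIds)
    tc <- FollicleTimecourse(vals,
                             condition = rep(c("5X", "10X"), each = 7),
                             day = rep(cultureDays(), 2),
                             rowData = rd)
    metadata(tc)$seed <- as.integer(seed)
    metadata(tc)$synthetic <- TRUE
    tc
}

#' Ground-truth table of a synthetic time course
#'
#' @param tc a synthetic \code{FollicleTimecourse}.
#' @return \code{DataFrame} with one row per gene: archetype, divergence
#'   flag, amplitude, baseline and noise SD.
#' @export
syntheticTruth <- function(tc) {
    rd <- rowData(tc)
    if (!all(c("archetype", "divergent") %in% colnames(rd)))
        stop("object carries no synthetic truth (was it simulated?)")
    rd
}

#' Recompute the noiseless base trajectories of a synthetic time course
#'
#' Re-evaluates each gene's archetype curve, demonstrating that the truth
#' ledger is sufficient to reconstruct the signal exactly.
#'
#' @param tc a synthetic \code{FollicleTimecourse}.
#' @param condition "5X" or "10X".
#' @return genes x 7 matrix of baseline + base curve values.
#' @export
baseTrajectories <- function(tc, condition = c("5X", "10X")) {
    condition <- match.arg(condition)
    tr <- syntheticTruth(tc)
    out <- matrix(NA_real_, nrow(tr), 7L,
                  dimnames = list(rownames(tr), NULL))
    for (i in seq_len(nrow(tr)))
        out[i, ] <- tr$baseline[i] +
            archetypeCurve(tr$archetype[i], condition,
                           amplitude = tr$amplitude[i])
    out
}

#' Simulate a stage-labelled comparator dataset sharing transition signs
#'
#' Builds a freshly-isolated-follicle style comparator (3 stages x
#' \code{repsPerStage} replicates) on the same genes as a synthetic time
#' course. For a random \code{sharedSignFraction} of genes the stage-to-stage
#' mean changes (Early to Middle, Middle to Late) carry the same sign as the
#' corresponding in vitro consensus transitions; for the rest, signs are
#' randomised independently. This controls the expected cross-dataset
#' t-score concordance from full agreement down to none.
#'
#' Each gene's stage-to-stage mean shift has the magnitude of its in vitro
#' consensus transition (so the counterpart emulates the same developmental
#' program, not just its directions), scaled by \code{effect}; only the
#' signs are controlled by \code{sharedSignFraction}. Replicates within a
#' stage are placed at different positions along the developmental
#' trajectory (they sample the base curve at the stage's mapped culture
#' days), mirroring the within-stage heterogeneity of freshly isolated
#' follicles; with full sign sharing and low noise the counterpart then
#' reproduces the in vitro transition t-scores.
#'
#' @param tc synthetic \code{FollicleTimecourse} carrying its truth.
#' @param sharedSignFraction proportion in [0, 1] of genes whose transition
#'   signs copy the in vitro truth.
#' @param repsPerStage replicates per stage (>= 2).
#' @param noiseSd additive Gaussian noise SD.
#' @param seed integer seed.
#' @param effect multiplier on the mirrored transition magnitudes.
#' @param stages stage labels, Early/Middle/Late order.
#' @return A \code{\link{StageSeries}}; \code{rowData} records each gene's
#'   planted transition signs and whether it was a sign-sharing gene.
#' @export
simulateStageSeries <- function(tc, sharedSignFraction = 1, repsPerStage = 3,
                                noiseSd = 0.3, seed = 1, effect = 1,
                                stages = c("Primary", "MultilayerSecondary",
                                           "Antral")) {
    stopifnot(sharedSignFraction >= 0, sharedSignFraction <= 1,
              repsPerStage >= 2, noiseSd >= 0)
    tr <- syntheticTruth(tc)
    n <- nrow(tr)
    set.seed(as.integer(seed))

    ## in vitro consensus stage means and transition signs from the
    ## noiseless base curves
    days <- cultureDays()
    dayMap <- stageMapping()$invitro
    cons <- (baseTrajectories(tc, "5X") + baseTrajectories(tc, "10X")) / 2
    stageMean <- sapply(dayMap, function(d)
        rowMeans(cons[, days %in% d, drop = FALSE]))
    dEM <- stageMean[, "Middle"] - stageMean[, "Early"]
    dML <- stageMean[, "Late"] - stageMean[, "Middle"]
    sEM <- sign(dEM); sML <- sign(dML)

    randSign <- function(n) sample(c(-1, 1), n, replace = TRUE)
    shared <- rep(FALSE, n)
    shared[sample.int(n, round(sharedSignFraction * n))] <- TRUE
    ## zero in vitro signs carry no direction to share; randomise them
    s1 <- ifelse(shared & sEM != 0, sEM, randSign(n))
    s2 <- ifelse(shared & sML != 0, sML, randSign(n))

    nSamp <- 3L * repsPerStage
    stageOf <- rep(stages, each = repsPerStage)
    ids <- paste0(stageOf, "_r", rep(seq_len(repsPerStage), times = 3))
    shift1 <- s1 * abs(dEM) * effect
    shift2 <- s2 * abs(dML) * effect
    nu <- cbind(stageMean[, "Early"], stageMean[, "Early"] + shift1,
                stageMean[, "Early"] + shift1 + shift2)
    ## within-stage developmental spread: replicate j of a stage sits at one
    ## of the stage's mapped culture days along the base trajectory
    vals <- matrix(NA_real_, n, nSamp, dimnames = list(rownames(tr), ids))
    col <- 0L
    for (s in 1:3) {
        ds <- dayMap[[s]]
        pick <- ds[round(seq(1, length(ds), length.out = repsPerStage))]
        dev <- sapply(pick, function(d) cons[, days == d] - stageMean[, s])
        dev <- dev - rowMeans(dev)   # spread must not shift the stage mean
        for (j in seq_len(repsPerStage)) {
            col <- col + 1L
            vals[, col] <- nu[, s] + dev[, j] * effect +
                rnorm(n, sd = noiseSd)
        }
    }

    rd <- DataFrame(sharedSign = shared, signEM = s1, signML = s2,
                    row.names = rownames(tr))
    ss <- StageSeries(vals, stage = stageOf,
                      replicate = rep(seq_len(repsPerStage), times = 3),
                      rowData = rd)
    metadata(ss)$seed <- as.integer(seed)
    metadata(ss)$sharedSignFraction <- sharedSignFraction
    ss
}
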