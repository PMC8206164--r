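## Trajectory analysis: sample-space PCA, consensus 7-point profiles,
## temporal k-means clustering, and cluster-specific High/Low contrast
## definitions for the downstream DE step.

#' Principal component analysis of samples
#'
#' Gene-centred PCA of the samples (samples are observations, genes are
#' variables). Component signs are fixed so the largest-magnitude gene
#' loading on each component is positive, making orientations reproducible.
#'
#' @param x matrix or expression container (genes x samples).
#' @param nComponents number of components to retain; at most
#'   \code{nSamples - 1}.
#' @return List with \code{scores} (samples x components),
#'   \code{varianceFraction} (per retained component, of total variance),
#'   \code{sdev} and \code{loadings}.
#' @export
pcaSamples <- function(x, nComponents = NULL) {
    m <- .getMatrix(x)
    ns <- ncol(m)
    if (ns < 2L) stop("need at least 2 samples")
    if (is.null(nComponents)) nComponents <- ns - 1L
    if (nComponents > ns - 1L)
        stop("nComponents exceeds the number of samples minus one")
    pc <- prcomp(t(m), center = TRUE, scale. = FALSE)
    k <- min(nComponents, ncol(pc$rotation))
    scores <- pc$x[, seq_len(k), drop = FALSE]
    loadings <- pc$rotation[, seq_len(k), drop = FALSE]
    for (j in seq_len(k)) {
        i <- which.max(abs(loadings[, j]))
        if (loadings[i, j] < 0) {
            loadings[, j] <- -loadings[, j]
            scores[, j] <- -scores[, j]
        }
    }
    varFrac <- pc$sdev^2 / sum(pc$sdev^2)
    list(scores = scores,
         varianceFraction = varFrac[seq_len(k)],
         sdev = pc$sdev[seq_len(k)],
         loadings = loadings)
}

#' Per-condition and consensus 7-point trajectory profiles
#'
#' Reshapes a 14-sample time course into per-gene ordered 7-point profiles
#' for each condition and their consensus (the elementwise mean of the 5X
#' and 10X series at each day).
#'
#' @param tc a \code{FollicleTimecourse} with both conditions at all 7 days.
#' @return A \linkS4class{TrajectoryProfiles} object.
#' @export
consensusProfiles <- function(tc) {
    m <- .getMatrix(tc)
    cond <- condition(tc); day <- cultureDay(tc)
    days <- cultureDays()
    missing <- character(0)
    idx5 <- idx10 <- integer(7)
    for (j in seq_along(days)) {
        i5 <- which(cond == "5X" & day == days[j])
        i10 <- which(cond == "10X" & day == days[j])
        if (length(i5) != 1L) missing <- c(missing, paste0("5X/day", days[j]))
        if (length(i10) != 1L) missing <- c(missing, paste0("10X/day", days[j]))
        idx5[j] <- i5[1]; idx10[j] <- i10[1]
    }
    if (length(missing))
        stop("missing or duplicated condition-day cell(s): ",
             paste(missing, collapse = ", "))
    p5 <- m[, idx5, drop = FALSE]
    p10 <- m[, idx10, drop = FALSE]
    colnames(p5) <- colnames(p10) <- paste0("day", days)
    new("TrajectoryProfiles", x = as.numeric(codedTime()),
        profile5x = p5, profile10x = p10, consensus = (p5 + p10) / 2)
}

#' k-means clustering of temporal profiles
#'
#' Groups genes by their temporal expression shape. By default clustering
#' runs on the consensus 7-point profiles (computed from standardized
#' genes); \code{features = "full"} clusters the concatenated 14-point
#' two-condition vectors instead.
#'
#' @param traj a \code{TrajectoryProfiles} object (profiles of standardized
#'   genes).
#' @param k number of clusters (default 6).
#' @param seed integer seed; fixed seed gives identical partitions.
#' @param nRestarts number of random restarts; the best (lowest
#'   within-cluster sum of squares) solution is kept.
#' @param features "consensus" (7-point) or "full" (14-point).
#' @return A \linkS4class{ClusterResult}.
#' @export
kmeansProfiles <- function(traj, k = 6, seed = 1, nRestarts = 25,
                           features = c("consensus", "full")) {
    features <- match.arg(features)
    stopifnot(is(traj, "TrajectoryProfiles"), k >= 1)
    data <- if (features == "consensus") traj@consensus
            else cbind(traj@profile5x, traj@profile10x)
    nDistinct <- nrow(unique(data))
    if (k > nDistinct)
        stop("k exceeds the number of distinct profiles (", nDistinct, ")")
    set.seed(as.integer(seed))
    km <- kmeans(data, centers = k, nstart = nRestarts, iter.max = 100L)
    new("ClusterResult", k = as.integer(k),
        assignments = setNames(as.integer(km$cluster), rownames(data)),
        centroids = km$centers,
        inertia = km$tot.withinss,
        seed = as.integer(seed),
        features = features)
}

#' Cluster assignments accessor
#' @param object a \code{ClusterResult} or \code{SOMModel}.
#' @return Named integer vector, gene id to cluster/node label.
#' @export
setGeneric("assignments", function(object) standardGeneric("assignments"))

#' @rdname assignments
#' @export
setMethod("assignments", "ClusterResult", function(object) object@assignments)

#' @rdname assignments
#' @export
setMethod("assignments", "SOMModel", function(object) object@assignments)

#' Define High/Low sample groups per temporal cluster
#'
#' Translates per-cluster contrast specifications (sets of culture days for
#' the High and Low groups; both conditions' samples at those days are
#' included) into sample-identifier lists for differential expression. A
#' cluster may be flagged \code{skip} (e.g. oscillatory clusters with no
#' coherent direction).
#'
#' @param tc the \code{FollicleTimecourse} providing sample metadata.
#' @param contrasts named list, one element per cluster label, each a list
#'   with numeric \code{high} and \code{low} day sets and optional logical
#'   \code{skip}.
#' @return Named list per cluster: \code{high}/\code{low} sample id vectors
#'   and the \code{skip} flag.
#' @examples
#' tc <- simulateTimecourse(list(archetypeSpec("transient_mid", 5)), seed = 1)
#' defineContrasts(tc, list(`1` = list(high = c(4,6,7,8,10), low = c(2,12))))
#' @export
defineContrasts <- function(tc, contrasts) {
    day <- cultureDay(tc)
    ids <- colnames(tc)
    lapply(contrasts, function(spec) {
        skip <- isTRUE(spec$skip)
        if (skip)
            return(list(high = character(0), low = character(0), skip = TRUE))
        if (length(spec$high) == 0L || length(spec$low) == 0L)
            stop("High and Low day sets must be nonempty")
        if (length(intersect(spec$high, spec$low)))
            stop("High and Low day sets overlap")
        unknown <- setdiff(c(spec$high, spec$low), day)
        if (length(unknown))
            stop("day(s) absent from metadata: ",
                 paste(unknown, collapse = ", "))
        list(high = ids[day %in% spec$high],
             low = ids[day %in% spec$low],
             skip = FALSE)
    })
}

#' Default mid-culture contrast applied to every cluster
#'
#' High = the middle five time points (days 4--10), Low = the first and last
#' days combined (2 and 12); the canonical contrast for clusters that rise
#' mid-culture.
#'
#' @param k number of clusters.
#' @param skip optional integer labels of clusters to skip (no DE).
#' @return Named contrast list suitable for \code{\link{defineContrasts}}.
#' @export
defaultContrasts <- function(k = 6, skip = integer(0)) {
    out <- lapply(seq_len(k), function(i) {
        if (i %in% skip) list(skip = TRUE)
        else list(high = c(4, 6, 7, 8, 10), low = c(2, 12))
    })
    names(out) <- as.character(seq_len(k))
    out
}
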