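## Preprocessing: intensity/variability gene filtering, row standardisation
## and mean-centering, and joint quantile normalisation. All functions accept
## either a bare matrix or a SummarizedExperiment-derived container and
## return the same kind of object.

.getMatrix <- function(x) {
    if (is(x, "SummarizedExperiment")) assay(x, "exprs") else as.matrix(x)
}

.setMatrix <- function(x, m) {
    if (is(x, "SummarizedExperiment")) { assay(x, "exprs") <- m; x } else m
}

.subsetRows <- function(x, keep) {
    x[keep, , drop = FALSE]
}

#' Filter genes on intensity and variability
#'
#' Retains genes whose summary normalized intensity exceeds
#' \code{intensityThreshold} \emph{and} whose across-sample standard
#' deviation exceeds \code{sdThreshold}; the defaults (3 and 0.3 on the log
#' scale) reduce a full microarray gene set to its expressed, variable core.
#'
#' @param x matrix or \code{FollicleTimecourse}/\code{StageSeries}.
#' @param intensityThreshold minimum summary intensity (strict).
#' @param sdThreshold minimum across-sample SD (strict).
#' @param intensitySummary per-gene summary used for the intensity rule:
#'   mean (default) or max across samples.
#' @return List with elements \code{matrix} (the filtered object, same class
#'   as the input) and \code{report}: counts \code{nInput},
#'   \code{nPassedIntensity}, \code{nPassedSd}, \code{nRetained} and the
#'   per-gene logical pass flags.
#' @examples
#' m <- matrix(rnorm(42, mean = 5), 3, 14,
#'             dimnames = list(c("g1","g2","g3"), paste0("s", 1:14)))
#' filterGenes(m)$report$nRetained
#' @export
filterGenes <- function(x, intensityThreshold = 3, sdThreshold = 0.3,
                        intensitySummary = c("mean", "max")) {
    intensitySummary <- match.arg(intensitySummary)
    m <- .getMatrix(x)
    if (nrow(m) == 0L) stop("empty expression matrix")
    stopifnot(is.finite(intensityThreshold) || intensityThreshold == -Inf,
              is.finite(sdThreshold) || sdThreshold == -Inf)
    intensity <- if (intensitySummary == "mean") rowMeans(m)
                 else apply(m, 1L, max)
    sds <- apply(m, 1L, sd)
    passIntensity <- intensity > intensityThreshold
    passSd <- sds > sdThreshold
    pass <- passIntensity & passSd
    if (!any(pass))
        warning("no genes pass the intensity/SD filter")
    report <- list(nInput = nrow(m),
                   nPassedIntensity = sum(passIntensity),
                   nPassedSd = sum(passSd),
                   nRetained = sum(pass),
                   passIntensity = setNames(passIntensity, rownames(m)),
                   passSd = setNames(passSd, rownames(m)),
                   pass = setNames(pass, rownames(m)))
    list(matrix = .subsetRows(x, pass), report = report)
}

#' Standardize each gene to mean 0, SD 1
#'
#' @param x matrix or expression container.
#' @return Object of the same class with each row scaled to zero mean and
#'   unit standard deviation.
#' @export
standardizeRows <- function(x) {
    m <- .getMatrix(x)
    mu <- rowMeans(m)
    sds <- apply(m, 1L, sd)
    zero <- sds == 0
    if (any(zero))
        stop("zero-SD gene(s) cannot be standardized: ",
             paste(head(rownames(m)[zero], 5), collapse = ", "))
    .setMatrix(x, (m - mu) / sds)
}

#' Mean-center each gene
#'
#' @param x matrix or expression container.
#' @return Object of the same class with each row shifted to zero mean;
#'   row variances are unchanged.
#' @export
meanCenterRows <- function(x) {
    m <- .getMatrix(x)
    if (nrow(m) == 0L) stop("empty expression matrix")
    .setMatrix(x, m - rowMeans(m))
}

#' Joint quantile normalization of one or more expression matrices
#'
#' Column-binds all inputs (which must share an identical gene set and
#' ordering), forces every sample onto the common distribution of per-rank
#' means (ties replaced by the mean of tied ranks), and splits back into the
#' input shapes.
#'
#' @param ... one or more matrices or expression containers over the same
#'   genes.
#' @return A single normalized object if one input was given, otherwise a
#'   list of normalized objects in input order.
#' @export
quantileNormalize <- function(...) {
    inputs <- list(...)
    if (length(inputs) == 1L && is.list(inputs[[1]]) &&
        !is.matrix(inputs[[1]]) && !is(inputs[[1]], "SummarizedExperiment"))
        inputs <- inputs[[1]]
    if (length(inputs) == 0L) stop("no input matrices")
    mats <- lapply(inputs, .getMatrix)
    genes <- rownames(mats[[1]])
    for (m in mats[-1])
        if (!identical(rownames(m), genes))
            stop("gene identifier sets/order differ between inputs")
    joint <- do.call(cbind, mats)
    normed <- limma::normalizeQuantiles(joint, ties = TRUE)
    dimnames(normed) <- dimnames(joint)
    offsets <- cumsum(c(0L, vapply(mats, ncol, 1L)))
    out <- vector("list", length(mats))
    for (i in seq_along(mats)) {
        cols <- (offsets[i] + 1L):offsets[i + 1L]
        out[[i]] <- .setMatrix(inputs[[i]], normed[, cols, drop = FALSE])
    }
    if (length(out) == 1L) out[[1]] else out
}
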