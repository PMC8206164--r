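## Central data containers. Expression data live in SummarizedExperiment
## subclasses whose validity pins down the sample design the analysis
## assumes; derived results get lightweight S4 classes with show methods.

#' @importClassesFrom SummarizedExperiment SummarizedExperiment
setClass("FollicleTimecourse", contains = "SummarizedExperiment")

setClass("StageSeries", contains = "SummarizedExperiment")

setValidity("FollicleTimecourse", function(object) {
    cd <- colData(object)
    msg <- character(0)
    if (!all(c("condition", "day") %in% colnames(cd)))
        msg <- c(msg, "colData must contain 'condition' and 'day'")
    else {
        if (!all(cd$condition %in% cocultureConditions()))
            msg <- c(msg, "condition must be one of '5X', '10X'")
        if (!is.numeric(cd$day))
            msg <- c(msg, "day must be numeric")
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate gene identifiers")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate sample identifiers")
    if (length(msg)) msg else TRUE
})

setValidity("StageSeries", function(object) {
    cd <- colData(object)
    msg <- character(0)
    if (!all(c("stage", "replicate") %in% colnames(cd)))
        msg <- c(msg, "colData must contain 'stage' and 'replicate'")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate gene identifiers")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate sample identifiers")
    if (length(msg)) msg else TRUE
})

#' Container for a two-condition follicle culture time course
#'
#' A \linkS4class{SummarizedExperiment} holding a genes-by-samples log-scale
#' expression matrix for the 5X/10X co-culture design: two conditions, one
#' sample per condition per culture day. Sample metadata (condition, day)
#' live in \code{colData}; any synthetic ground truth lives in \code{rowData}.
#'
#' @param values numeric matrix, genes in rows, samples in columns; rownames
#'   are gene identifiers, colnames sample identifiers.
#' @param condition character/factor of length \code{ncol(values)}, values
#'   "5X" or "10X".
#' @param day numeric culture day per sample.
#' @param rowData optional \code{DataFrame} of per-gene annotation.
#'
#' @return A \code{FollicleTimecourse} object.
#' @examples
#' m <- matrix(rnorm(4 * 14), 4, 14,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:14)))
#' tc <- FollicleTimecourse(m,
#'   condition = rep(c("5X", "10X"), each = 7),
#'   day = rep(cultureDays(), 2))
#' @export
FollicleTimecourse <- function(values, condition, day, rowData = NULL) {
    values <- as.matrix(values)
    if (is.null(rownames(values)) || is.null(colnames(values)))
        stop("expression matrix must have gene rownames and sample colnames")
    if (!all(is.finite(values)))
        stop("expression values must be finite")
    cd <- DataFrame(condition = as.character(condition), day = as.numeric(day),
                    row.names = colnames(values))
    se <- SummarizedExperiment(assays = list(exprs = values), colData = cd)
    if (!is.null(rowData)) rowData(se) <- rowData
    new("FollicleTimecourse", se)
}

#' Container for a stage-labelled replicate expression series
#'
#' Holds a comparator dataset with developmental stage labels (e.g. Primary,
#' MultilayerSecondary, Antral follicles, three replicates each) on the same
#' gene identifier space as the in vitro time course.
#'
#' @param values numeric genes-by-samples matrix with dimnames.
#' @param stage character stage label per sample.
#' @param replicate replicate index per sample.
#' @param rowData optional per-gene annotation.
#' @return A \code{StageSeries} object.
#' @export
StageSeries <- function(values, stage, replicate, rowData = NULL) {
    values <- as.matrix(values)
    if (is.null(rownames(values)) || is.null(colnames(values)))
        stop("expression matrix must have gene rownames and sample colnames")
    cd <- DataFrame(stage = as.character(stage),
                    replicate = as.integer(replicate),
                    row.names = colnames(values))
    se <- SummarizedExperiment(assays = list(exprs = values), colData = cd)
    if (!is.null(rowData)) rowData(se) <- rowData
    new("StageSeries", se)
}

## ---- derived-result classes -------------------------------------------

setClass("TrajectoryProfiles", representation(
    x = "numeric",
    profile5x = "matrix",
    profile10x = "matrix",
    consensus = "matrix"))

setValidity("TrajectoryProfiles", function(object) {
    ok <- length(object@x) == 7L &&
        ncol(object@profile5x) == 7L && ncol(object@profile10x) == 7L &&
        ncol(object@consensus) == 7L &&
        nrow(object@profile5x) == nrow(object@consensus) &&
        nrow(object@profile10x) == nrow(object@consensus)
    if (ok) TRUE else "profile matrices must share genes and have 7 columns"
})

setClass("ClusterResult", representation(
    k = "integer",
    assignments = "integer",
    centroids = "matrix",
    inertia = "numeric",
    seed = "integer",
    features = "character"))

setClass("SOMModel", representation(
    gridRows = "integer",
    gridCols = "integer",
    gridCoords = "matrix",
    codebooks = "matrix",
    assignments = "integer",
    qerror = "numeric",
    qerrorFine = "numeric",
    seed = "integer"))

setClass("ModeratedModel", representation(
    d0 = "numeric",
    s0sq = "numeric",
    postVar = "numeric",
    df = "numeric",
    s2 = "numeric"))

setClass("ConcordanceResult", representation(
    transitions = "list",
    nGenes = "integer"))

## ---- accessors & show --------------------------------------------------

#' Condition labels of a time course
#' @param x a \code{FollicleTimecourse}.
#' @return Character vector of per-sample conditions.
#' @export
setGeneric("condition", function(x) standardGeneric("condition"))

#' @rdname condition
#' @export
setMethod("condition", "FollicleTimecourse",
          function(x) colData(x)$condition)

#' Culture day of each sample
#' @param x a \code{FollicleTimecourse}.
#' @return Numeric vector of per-sample culture days.
#' @export
setGeneric("cultureDay", function(x) standardGeneric("cultureDay"))

#' @rdname cultureDay
#' @export
setMethod("cultureDay", "FollicleTimecourse",
          function(x) colData(x)$day)

#' Expression values of a container
#' @param x a \code{FollicleTimecourse} or \code{StageSeries}.
#' @return The genes-by-samples numeric matrix.
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname exprValues
#' @export
setMethod("exprValues", "SummarizedExperiment", function(x) assay(x, "exprs"))

#' Developmental stage of each comparator sample
#' @param x a \code{StageSeries}.
#' @return Character vector of stage labels.
#' @export
setGeneric("stageLabel", function(x) standardGeneric("stageLabel"))

#' @rdname stageLabel
#' @export
setMethod("stageLabel", "StageSeries", function(x) colData(x)$stage)

setMethod("show", "TrajectoryProfiles", function(object) {
    cat("TrajectoryProfiles:", nrow(object@consensus), "genes,",
        "coded time", paste(range(object@x), collapse = ".."), "\n")
})

setMethod("show", "ClusterResult", function(object) {
    cat("ClusterResult: k =", object@k, "on", length(object@assignments),
        "genes (", object@features, "features ), inertia",
        format(object@inertia, digits = 6), "\n")
    print(table(cluster = object@assignments))
})

setMethod("show", "SOMModel", function(object) {
    cat("SOMModel:", object@gridRows, "x", object@gridCols, "grid,",
        length(object@assignments), "genes\n")
    sizes <- tabulate(object@assignments, nbins = nrow(object@codebooks))
    cat("node sizes:", paste(sizes, collapse = " "),
        if (any(sizes == 0)) "(empty nodes present)" else "", "\n")
})

setMethod("show", "ModeratedModel", function(object) {
    cat("ModeratedModel: d0 =", format(object@d0, digits = 4),
        ", s0^2 =", format(object@s0sq, digits = 4),
        ",", length(object@postVar), "genes\n")
})

setMethod("show", "ConcordanceResult", function(object) {
    cat("ConcordanceResult over", object@nGenes, "shared genes\n")
    for (nm in names(object@transitions)) {
        tr <- object@transitions[[nm]]
        cat(sprintf("  %-14s r = %6.3f  z = %6.3f  p = %.3g  (agree %d / disagree %d)\n",
                    nm, tr$r, tr$z, tr$p,
                    length(tr$agreement), length(tr$disagreement)))
    }
})
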