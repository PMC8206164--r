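## Batch self-organizing map on a small rectangular lattice. Codebooks are
## initialised on the grid spanned by the first two principal components
## (deterministic), trained with a shrinking Gaussian neighborhood
## (ordering phase) and then polished with a zero-neighborhood phase that is
## exactly Lloyd's algorithm, whose quantization error is provably
## nonincreasing.

.somGridCoords <- function(rows, cols) {
    cbind(row = rep(seq_len(rows), times = cols),
          col = rep(seq_len(cols), each = rows))
}

.nearestCodebook <- function(data, codebooks) {
    ## squared Euclidean distances, n x k
    cross <- data %*% t(codebooks)
    d2 <- outer(rowSums(data^2), rowSums(codebooks^2), "+") - 2 * cross
    list(bmu = max.col(-d2, ties.method = "first"),
         d2 = pmax(d2[cbind(seq_len(nrow(data)),
                            max.col(-d2, ties.method = "first"))], 0))
}

#' Train a batch self-organizing map on gene profiles
#'
#' Clusters standardized gene vectors (typically the concatenated
#' 14-sample two-condition profiles) onto a small node lattice, default
#' 3 x 3, yielding nine trajectory subsets. Training is fully deterministic:
#' codebooks start on the grid spanned by the first two principal
#' components, an ordering phase shrinks a Gaussian neighborhood from
#' \code{radius0} to near zero, and a fine-tuning phase runs
#' zero-neighborhood (Lloyd) updates to convergence of the quantization
#' error.
#'
#' @param data numeric matrix, genes x features, standardized per gene.
#' @param gridRows,gridCols lattice dimensions (default 3 x 3).
#' @param seed integer seed (kept for the API; training is deterministic).
#' @param orderEpochs neighborhood-shrinking epochs.
#' @param fineEpochs zero-neighborhood polishing epochs.
#' @param radius0 initial neighborhood radius in grid units; default half
#'   the grid diagonal.
#' @return A \linkS4class{SOMModel}: codebooks, nearest-codebook
#'   assignments, per-epoch quantization errors (mean squared distance to
#'   the best-matching unit), and the grid geometry.
#' @export
trainSOM <- function(data, gridRows = 3, gridCols = 3, seed = 1,
                     orderEpochs = 15, fineEpochs = 15, radius0 = NULL) {
    data <- as.matrix(data)
    stopifnot(nrow(data) >= 1L, orderEpochs >= 0, fineEpochs >= 1)
    k <- gridRows * gridCols
    if (nrow(unique(data)) < k)
        warning("fewer distinct profiles than nodes; some nodes will be empty")
    set.seed(as.integer(seed))
    coords <- .somGridCoords(gridRows, gridCols)
    gridD2 <- as.matrix(stats::dist(coords))^2

    ## PCA-spanned initialisation
    center <- colMeans(data)
    codebooks <- matrix(rep(center, each = k), k, ncol(data))
    if (k > 1L) {
        pc <- prcomp(data, center = TRUE, scale. = FALSE, rank. = 2)
        u <- if (gridRows > 1) (coords[, 1] - mean(coords[, 1])) /
                 max(1, (gridRows - 1) / 2) else rep(0, k)
        v <- if (gridCols > 1) (coords[, 2] - mean(coords[, 2])) /
                 max(1, (gridCols - 1) / 2) else rep(0, k)
        ncomp <- ncol(pc$rotation)
        codebooks <- codebooks + outer(u, pc$sdev[1] * pc$rotation[, 1])
        if (ncomp >= 2)
            codebooks <- codebooks + outer(v, pc$sdev[2] * pc$rotation[, 2])
    }

    if (is.null(radius0))
        radius0 <- max(1, sqrt((gridRows - 1)^2 + (gridCols - 1)^2) / 2)
    qerr <- numeric(0)
    if (orderEpochs > 0) {
        radii <- seq(radius0, 0.2, length.out = orderEpochs)
        for (e in seq_len(orderEpochs)) {
            nb <- .nearestCodebook(data, codebooks)
            qerr <- c(qerr, mean(nb$d2))
            h <- exp(-gridD2 / (2 * radii[e]^2))     # k x k neighborhood
            w <- h[, nb$bmu, drop = FALSE]           # k x n weights
            denom <- rowSums(w)
            upd <- (w %*% data) / denom
            nz <- denom > 1e-12
            codebooks[nz, ] <- upd[nz, ]
        }
    }
    qerrFine <- numeric(0)
    nDistinct <- nrow(unique(data))
    for (e in seq_len(fineEpochs)) {
        nb <- .nearestCodebook(data, codebooks)
        qerrFine <- c(qerrFine, mean(nb$d2))
        for (j in seq_len(k)) {
            members <- nb$bmu == j
            if (any(members))
                codebooks[j, ] <- colMeans(data[members, , drop = FALSE])
        }
        ## empty-node repair (only when enough distinct profiles exist):
        ## park the codebook on the worst-quantized point, which strictly
        ## lowers the quantization error
        empties <- setdiff(seq_len(k), unique(nb$bmu))
        if (length(empties) && nDistinct >= k) {
            far <- order(nb$d2, decreasing = TRUE)
            for (i in seq_along(empties))
                codebooks[empties[i], ] <- data[far[i], ]
        }
    }
    nb <- .nearestCodebook(data, codebooks)
    qerrFine <- c(qerrFine, mean(nb$d2))
    rownames(codebooks) <- paste0("node_", coords[, 1], "_", coords[, 2])
    new("SOMModel", gridRows = as.integer(gridRows),
        gridCols = as.integer(gridCols),
        gridCoords = coords,
        codebooks = codebooks,
        assignments = setNames(as.integer(nb$bmu), rownames(data)),
        qerror = qerr, qerrorFine = qerrFine,
        seed = as.integer(seed))
}

#' Merge SOM nodes with near-identical mean profiles
#'
#' Computes each nonempty node's mean member profile, links nodes whose
#' profiles exceed a Pearson correlation threshold, and unions linked nodes
#' by transitive closure. The merged subsets partition the assigned genes.
#'
#' @param model a trained \linkS4class{SOMModel}.
#' @param data the matrix the model was trained on (for member profiles).
#' @param corThreshold merge when correlation is strictly above this
#'   (default 0.95).
#' @return List: \code{subsets} (list of gene-id vectors per merged subset),
#'   \code{membership} (gene id to merged subset index), \code{nodeGroups}
#'   (node index to merged subset index).
#' @export
mergeSimilarNodes <- function(model, data, corThreshold = 0.95) {
    stopifnot(is(model, "SOMModel"))
    data <- as.matrix(data)
    k <- nrow(model@codebooks)
    asg <- model@assignments
    means <- model@codebooks
    nonempty <- sort(unique(asg))
    for (j in nonempty)
        means[j, ] <- colMeans(data[asg == j, , drop = FALSE])
    ## union-find over nodes correlated above threshold
    parent <- seq_len(k)
    findRoot <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    if (length(nonempty) > 1L) {
        for (a in seq_along(nonempty)) for (b in seq_len(a - 1L)) {
            i <- nonempty[a]; j <- nonempty[b]
            if (sd(means[i, ]) > 0 && sd(means[j, ]) > 0 &&
                cor(means[i, ], means[j, ]) > corThreshold) {
                ri <- findRoot(i); rj <- findRoot(j)
                if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
            }
        }
    }
    roots <- vapply(seq_len(k), findRoot, 1L)
    groupIds <- match(roots, sort(unique(roots)))
    membership <- setNames(groupIds[asg], names(asg))
    subsets <- split(names(asg), membership)
    list(subsets = subsets, membership = membership, nodeGroups = groupIds)
}
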