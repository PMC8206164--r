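## Plain-text I/O: TSV expression matrices with a gene_id column, sample
## metadata tables, GMT gene-set collections and JSON truth ledgers.

#' Write an expression matrix as TSV
#'
#' Genes as rows with a leading \code{gene_id} column, sample identifiers
#' as the header.
#'
#' @param x matrix or expression container.
#' @param path output file.
#' @export
writeExpressionTSV <- function(x, path) {
    m <- .getMatrix(x)
    df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read an expression matrix written by \code{writeExpressionTSV}
#'
#' @param path TSV file with a \code{gene_id} first column.
#' @return Numeric matrix with gene rownames.
#' @export
readExpressionTSV <- function(path) {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    storage.mode(m) <- "double"
    m
}

#' Write sample metadata as TSV
#'
#' @param x a \code{FollicleTimecourse} or \code{StageSeries}.
#' @param path output file.
#' @export
writeSampleMetaTSV <- function(x, path) {
    cd <- as.data.frame(colData(x))
    df <- data.frame(sample_id = rownames(cd), cd, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read sample metadata written by \code{writeSampleMetaTSV}
#'
#' @param path TSV file with a \code{sample_id} first column.
#' @return data.frame with sample_id rownames.
#' @export
readSampleMetaTSV <- function(path) {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    rownames(df) <- df$sample_id
    df
}

#' Assemble a FollicleTimecourse from matrix + metadata files
#'
#' @param exprPath expression TSV (see \code{\link{readExpressionTSV}}).
#' @param metaPath metadata TSV with \code{sample_id}, \code{condition},
#'   \code{day} columns.
#' @return A \code{FollicleTimecourse}.
#' @export
readFollicleTimecourse <- function(exprPath, metaPath) {
    m <- readExpressionTSV(exprPath)
    meta <- readSampleMetaTSV(metaPath)
    meta <- meta[colnames(m), , drop = FALSE]
    FollicleTimecourse(m, condition = meta$condition, day = meta$day)
}

#' Read a GMT gene-set collection
#'
#' @param path GMT file (set name, description, tab-separated members).
#' @return Named list of character vectors.
#' @export
readGMT <- function(path) {
    fgsea::gmtPathways(path)
}

#' Write a GMT gene-set collection
#'
#' @param sets named list of character vectors.
#' @param path output file.
#' @param descriptions optional per-set description column (defaults to the
#'   set names).
#' @export
writeGMT <- function(sets, path, descriptions = names(sets)) {
    lines <- vapply(seq_along(sets), function(i) {
        paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Write the synthetic-truth ledger as JSON
#'
#' @param tc synthetic \code{FollicleTimecourse}.
#' @param path output JSON file.
#' @export
writeTruthJSON <- function(tc, path) {
    tr <- as.data.frame(syntheticTruth(tc))
    obj <- lapply(seq_len(nrow(tr)), function(i) as.list(tr[i, ]))
    names(obj) <- rownames(tr)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
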