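## Two-group differential expression with empirical-Bayes variance
## moderation. The moderated t follows the standard hierarchical model:
## per-gene residual variances s2_g ~ s2_true * chisq(df)/df with
## s2_true ~ scaled-inv-chisq(d0, s0^2); hyperparameters (d0, s0^2) are
## estimated by method of moments on log variances, posterior variances are
## the df-weighted blend, and t-statistics gain d0 extra degrees of freedom.

#' Fit per-gene two-group means and pooled variances
#'
#' Computes, for every gene, the log-fold change \code{mean(B) - mean(A)},
#' the pooled residual variance and its degrees of freedom
#' \code{nA + nB - 2}. Groups of size one are allowed (they contribute a
#' mean but no variance); at least one group must have two or more samples.
#'
#' @param x matrix or expression container.
#' @param groupA,groupB disjoint sample identifier vectors.
#' @return \code{DataFrame} with columns \code{logFC}, \code{s2}, \code{df};
#'   group sizes are kept in \code{metadata()}.
#' @export
fitTwoGroup <- function(x, groupA, groupB) {
    m <- .getMatrix(x)
    if (length(intersect(groupA, groupB)))
        stop("groups overlap")
    unknown <- setdiff(c(groupA, groupB), colnames(m))
    if (length(unknown))
        stop("unknown sample identifier(s): ", paste(unknown, collapse = ", "))
    nA <- length(groupA); nB <- length(groupB)
    if (nA < 1L || nB < 1L || nA + nB < 3L)
        stop("need nA >= 1, nB >= 1 and nA + nB >= 3")
    a <- m[, groupA, drop = FALSE]
    b <- m[, groupB, drop = FALSE]
    meanA <- rowMeans(a); meanB <- rowMeans(b)
    ssA <- rowSums((a - meanA)^2)
    ssB <- rowSums((b - meanB)^2)
    df <- nA + nB - 2L
    out <- DataFrame(logFC = unname(meanB - meanA),
                     s2 = unname((ssA + ssB) / df),
                     df = rep(as.numeric(df), nrow(m)),
                     row.names = rownames(m))
    metadata(out) <- list(nA = nA, nB = nB,
                          groupA = groupA, groupB = groupB)
    out
}

## Invert the trigamma function by Newton iteration (monotone decreasing on
## (0, Inf)); used to solve the method-of-moments equation for d0/2.
.trigammaInverse <- function(y) {
    out <- y
    pos <- which(is.finite(y) & y > 0)
    for (i in pos) {
        yi <- y[i]
        if (yi > 1e7) { out[i] <- 1 / sqrt(yi); next }
        if (yi < 1e-6) { out[i] <- 1 / yi; next }
        x <- 0.5 + 1 / yi
        for (iter in 1:50) {
            tri <- trigamma(x)
            dif <- tri * (1 - tri / yi) / psigamma(x, 2L)
            x <- x + dif
            if (abs(dif) / x < 1e-10) break
        }
        out[i] <- x
    }
    out[!is.finite(y)] <- NA_real_
    out
}

#' Empirical-Bayes moderation of per-gene variances
#'
#' Estimates the prior degrees of freedom \code{d0} and prior variance
#' \code{s0^2} of the scaled inverse-chi-square variance prior by method of
#' moments on \code{log(s2)}: after correcting each log variance for the
#' chi-square sampling bias, the excess spread beyond the sampling
#' distribution determines \code{d0} (via the inverse trigamma), and the
#' corrected mean determines \code{s0^2}. When the observed spread does not
#' exceed the sampling spread, \code{d0 = Inf} and every posterior variance
#' equals \code{s0^2}.
#'
#' @param s2 per-gene residual variances (>= 0; zeros are excluded from
#'   hyperparameter estimation).
#' @param df residual degrees of freedom (scalar or per-gene, >= 1).
#' @param d0 optional override of the prior degrees of freedom (e.g.
#'   \code{Inf} for complete pooling).
#' @return A \linkS4class{ModeratedModel} with the hyperparameters and the
#'   per-gene posterior variances \code{(d0 s0^2 + df s2) / (d0 + df)}.
#' @export
ebayesModerate <- function(s2, df, d0 = NULL) {
    stopifnot(all(s2 >= 0), all(df >= 1))
    if (all(s2 == 0)) stop("all variances are zero; moderation is degenerate")
    df <- rep_len(as.numeric(df), length(s2))
    use <- s2 > 0
    if (sum(use) < 10L && is.null(d0))
        warning("fewer than 10 positive variances; hyperparameter estimates ",
                "may be unstable")
    z <- log(s2[use])
    e <- z - digamma(df[use] / 2) + log(df[use] / 2)
    ebar <- mean(e)
    if (is.null(d0)) {
        evar <- var(e) - mean(trigamma(df[use] / 2))
        if (is.finite(evar) && evar > 0) {
            d0 <- 2 * .trigammaInverse(evar)
            s0sq <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
        } else {
            d0 <- Inf
            s0sq <- mean(s2[use])
        }
    } else {
        s0sq <- if (is.infinite(d0)) mean(s2[use])
                else exp(ebar + digamma(d0 / 2) - log(d0 / 2))
    }
    postVar <- if (is.infinite(d0)) rep_len(s0sq, length(s2))
               else (d0 * s0sq + df * s2) / (d0 + df)
    names(postVar) <- names(s2)
    new("ModeratedModel", d0 = d0, s0sq = s0sq, postVar = postVar,
        df = df, s2 = as.numeric(s2))
}

#' Moderated t-statistics and p-values
#'
#' @param fit result of \code{\link{fitTwoGroup}} (provides logFC and group
#'   sizes).
#' @param model a \linkS4class{ModeratedModel} over the same genes.
#' @return \code{DataFrame} with \code{tModerated} and two-sided
#'   \code{pValue} from a t distribution on \code{df + d0} degrees of
#'   freedom (capped at the pooled residual df across genes), plus the
#'   ordinary \code{tOrdinary}.
#' @export
moderatedT <- function(fit, model) {
    stopifnot(is(model, "ModeratedModel"),
              nrow(fit) == length(model@postVar))
    if (any(model@postVar == 0))
        stop("zero posterior variance")
    nA <- metadata(fit)$nA; nB <- metadata(fit)$nB
    seFactor <- 1 / nA + 1 / nB
    tmod <- fit$logFC / sqrt(model@postVar * seFactor)
    tord <- ifelse(model@s2 > 0,
                   fit$logFC / sqrt(model@s2 * seFactor),
                   ifelse(fit$logFC == 0, 0, sign(fit$logFC) * Inf))
    ## total df capped at the pooled residual df across genes
    dfTotal <- pmin(fit$df + model@d0, sum(fit$df))
    p <- 2 * pt(-abs(tmod), df = dfTotal)
    DataFrame(tModerated = unname(tmod), tOrdinary = unname(tord),
              pValue = unname(p), row.names = rownames(fit))
}

#' Two-group moderated differential expression in one call
#'
#' Convenience wrapper chaining \code{\link{fitTwoGroup}},
#' \code{\link{ebayesModerate}} and \code{\link{moderatedT}}, with
#' Benjamini-Hochberg adjusted p-values.
#'
#' @inheritParams fitTwoGroup
#' @param d0 optional prior degrees-of-freedom override.
#' @return \code{DataFrame}: \code{logFC}, \code{s2}, \code{df},
#'   \code{tOrdinary}, \code{tModerated}, \code{pValue}, \code{adjP}; the
#'   fitted \code{ModeratedModel} is in \code{metadata()$model}.
#' @export
runDE <- function(x, groupA, groupB, d0 = NULL) {
    fit <- fitTwoGroup(x, groupA, groupB)
    model <- ebayesModerate(fit$s2, fit$df, d0 = d0)
    tt <- moderatedT(fit, model)
    out <- DataFrame(logFC = fit$logFC, s2 = fit$s2, df = fit$df,
                     tOrdinary = tt$tOrdinary, tModerated = tt$tModerated,
                     pValue = tt$pValue,
                     adjP = p.adjust(tt$pValue, method = "BH"),
                     row.names = rownames(fit))
    metadata(out) <- c(metadata(fit), list(model = model))
    out
}

#' Rank genes by log-fold change
#'
#' Descending by logFC; ties broken by decreasing |moderated t|, then by
#' gene identifier (stable).
#'
#' @param de a DE table with \code{logFC} and \code{tModerated} columns and
#'   gene rownames.
#' @return Character vector of gene identifiers in rank order.
#' @export
rankByLogFC <- function(de) {
    if (nrow(de) == 0L) stop("empty DE table")
    ids <- rownames(de)
    ord <- order(-de$logFC, -abs(de$tModerated), ids, method = "radix")
    ids[ord]
}

#' Hypergeometric gene-set enrichment over a GMT collection
#'
#' Upper-tail hypergeometric test of each gene set's overlap with a hit
#' list, after intersecting sets with the universe and discarding sets
#' larger than \code{maxSetSize}; Benjamini-Hochberg adjusted p-values.
#'
#' @param hits character vector of hit genes (subset of \code{universe}).
#' @param universe background gene identifiers.
#' @param collection named list of gene sets (e.g. from
#'   \code{\link{readGMT}}).
#' @param maxSetSize largest post-intersection set size tested (default 500).
#' @param minSetSize smallest set size tested.
#' @return data.frame: set, setSize, overlap, pValue, adjP.
#' @export
hypergeometricEnrichment <- function(hits, universe, collection,
                                     maxSetSize = 500, minSetSize = 1) {
    if (length(universe) == 0L) stop("empty universe")
    if (length(setdiff(hits, universe)))
        stop("hits must be a subset of the universe")
    universe <- unique(universe); hits <- unique(hits)
    N <- length(universe); nHits <- length(hits)
    rows <- lapply(names(collection), function(nm) {
        s <- intersect(collection[[nm]], universe)
        if (length(s) > maxSetSize || length(s) < minSetSize) return(NULL)
        k <- length(intersect(s, hits))
        p <- phyper(k - 1, length(s), N - length(s), nHits,
                    lower.tail = FALSE)
        data.frame(set = nm, setSize = length(s), overlap = k, pValue = p)
    })
    rows <- rows[!vapply(rows, is.null, TRUE)]
    out <- if (length(rows)) do.call(rbind, rows)
           else data.frame(set = character(0), setSize = integer(0),
                           overlap = integer(0), pValue = numeric(0))
    out$adjP <- p.adjust(out$pValue, method = "BH")
    out
}
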