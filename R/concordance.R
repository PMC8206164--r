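## Cross-dataset developmental-transition concordance. The in vitro time
## course is collapsed to one column per day (mean of 5X and 10X), mapped
## onto Early/Middle/Late stages, and each stage transition is scored by
## moderated t per gene in both datasets; agreement is quantified by the
## Pearson correlation of the two t-score vectors with a Fisher-z test.

#' Default Early/Middle/Late stage mapping
#'
#' In vitro: Early = day 2, Middle = days 4-8, Late = days 10 and 12.
#' Comparator: Early = Primary, Middle = MultilayerSecondary, Late = Antral
#' follicle stages.
#'
#' @return Nested list with \code{invitro} (day sets) and \code{comparator}
#'   (stage labels) per developmental stage.
#' @export
stageMapping <- function() {
    list(invitro = list(Early = 2, Middle = c(4, 6, 7, 8), Late = c(10, 12)),
         comparator = list(Early = "Primary", Middle = "MultilayerSecondary",
                           Late = "Antral"))
}

#' Average the 5X and 10X columns at each day
#'
#' @param tc a \code{FollicleTimecourse} with both conditions at every day.
#' @return genes x 7 matrix, one column per culture day (named
#'   \code{day<d>}).
#' @export
collapseConditions <- function(tc) {
    traj <- consensusProfiles(tc)   # validates the condition-day layout
    out <- traj@consensus
    colnames(out) <- paste0("day", cultureDays())
    out
}

#' Harmonize two expression datasets onto their shared genes
#'
#' Intersects the gene sets (keeping the first input's order), then applies
#' joint quantile normalization across all columns of both datasets so that
#' every sample shares one value distribution.
#'
#' @param a,b matrices or expression containers.
#' @return List of the two harmonized objects restricted to shared genes.
#' @export
harmonizeDatasets <- function(a, b) {
    ma <- .getMatrix(a); mb <- .getMatrix(b)
    shared <- intersect(rownames(ma), rownames(mb))
    if (length(shared) == 0L) stop("no shared gene identifiers")
    a2 <- .subsetRows(a, match(shared, rownames(ma)))
    b2 <- .subsetRows(b, match(shared, rownames(mb)))
    out <- quantileNormalize(a2, b2)
    names(out) <- c("a", "b")
    out
}

#' Per-gene moderated t-scores for one developmental transition
#'
#' Positive t means the gene rises from the "from" group to the "to" group.
#' Single-observation groups are allowed; their variance information comes
#' entirely from the empirical-Bayes pooling across genes.
#'
#' @param x matrix or expression container.
#' @param from,to column identifier vectors for the two groups.
#' @param d0 optional prior degrees-of-freedom override for the moderation.
#' @return Named numeric vector of moderated t-scores.
#' @export
transitionTScores <- function(x, from, to, d0 = NULL) {
    fit <- fitTwoGroup(x, groupA = from, groupB = to)
    model <- ebayesModerate(fit$s2, fit$df, d0 = d0)
    tt <- moderatedT(fit, model)
    setNames(tt$tModerated, rownames(tt))
}

#' Concordance of two t-score vectors
#'
#' Pearson correlation of paired per-gene t-scores, Fisher transformation
#' \eqn{z = \mathrm{atanh}(r)} with two-sided p-value from
#' \eqn{z\sqrt{n-3}} against the standard normal, and sign-agreement gene
#' lists. Genes with a zero t-score in either vector are reported
#' separately (their sign is undefined).
#'
#' @param t1,t2 equal-length named t-score vectors over the same genes.
#' @return List: \code{r}, \code{z}, \code{p}, \code{n}, \code{agreement},
#'   \code{disagreement}, \code{zeros} (gene id vectors).
#' @export
tscoreConcordance <- function(t1, t2) {
    stopifnot(length(t1) == length(t2))
    n <- length(t1)
    if (n < 4L) stop("need at least 4 genes")
    if (!is.null(names(t1)) && !is.null(names(t2)) &&
        !identical(names(t1), names(t2)))
        stop("t-score vectors are over different genes")
    if (sd(t1) == 0 || sd(t2) == 0)
        stop("zero variance in a t-score vector")
    r <- cor(t1, t2)
    z <- atanh(r)
    p <- 2 * pnorm(-abs(z) * sqrt(n - 3))
    ids <- if (is.null(names(t1))) as.character(seq_len(n)) else names(t1)
    s1 <- sign(t1); s2 <- sign(t2)
    zeros <- ids[s1 == 0 | s2 == 0]
    agree <- ids[s1 != 0 & s1 == s2]
    disagree <- ids[s1 != 0 & s2 != 0 & s1 != s2]
    list(r = r, z = z, p = p, n = n,
         agreement = agree, disagreement = disagree, zeros = zeros)
}

#' Full in vitro vs comparator transition-concordance analysis
#'
#' Collapses the in vitro conditions, harmonizes both datasets on shared
#' genes with joint quantile normalization, computes moderated t-scores for
#' the Early-to-Middle, Middle-to-Late and Early-to-Late transitions in each
#' dataset, and correlates them per transition.
#'
#' @param tc in vitro \code{FollicleTimecourse}.
#' @param comparator a \code{StageSeries} (or matrix with stage-labelled
#'   columns plus a \code{stages} factor argument).
#' @param mapping stage mapping, see \code{\link{stageMapping}}.
#' @param d0 optional prior degrees-of-freedom override.
#' @return A \linkS4class{ConcordanceResult}.
#' @export
concordanceAnalysis <- function(tc, comparator, mapping = stageMapping(),
                                d0 = NULL) {
    collapsed <- collapseConditions(tc)
    harm <- harmonizeDatasets(collapsed, comparator)
    invitro <- .getMatrix(harm$a)
    invivo <- .getMatrix(harm$b)
    stageOf <- if (is(comparator, "StageSeries")) stageLabel(comparator)
               else stop("comparator must be a StageSeries")

    dayCols <- function(days) paste0("day", days)
    stageCols <- function(stg) colnames(invivo)[stageOf %in% stg]
    transitions <- list(
        EarlyToMiddle = c("Early", "Middle"),
        MiddleToLate = c("Middle", "Late"),
        EarlyToLate = c("Early", "Late"))
    res <- lapply(transitions, function(tr) {
        tIn <- transitionTScores(invitro,
                                 from = dayCols(mapping$invitro[[tr[1]]]),
                                 to = dayCols(mapping$invitro[[tr[2]]]),
                                 d0 = d0)
        tOut <- transitionTScores(invivo,
                                  from = stageCols(mapping$comparator[[tr[1]]]),
                                  to = stageCols(mapping$comparator[[tr[2]]]),
                                  d0 = d0)
        out <- tscoreConcordance(tIn, tOut)
        out$tInvitro <- tIn
        out$tInvivo <- tOut
        out
    })
    new("ConcordanceResult", transitions = res,
        nGenes = nrow(invitro))
}
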