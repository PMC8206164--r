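## Trajectory archetypes: closed-form base curves on the coded 7-point grid.
## Six shared-shape archetypes (identical in 5X and 10X) and three
## condition-divergent archetypes whose 5X and 10X curves differ. Shapes are
## deliberate caricatures of the temporal classes seen in follicle co-culture
## somatic cells: early activators that decay, a transient mid-culture bump,
## delayed and late activators, flat housekeeping genes, oscillatory genes
## with no coherent trajectory, and U-shape/monotone divergence between the
## suboptimal (5X) and optimal (10X) group sizes.

.sharedArchetypes <- c("early_activator", "transient_mid", "delayed_activator",
                       "late_activator", "flat", "oscillatory")
.divergentArchetypes <- c("u_shape_5x_vs_rise_10x", "inverse_u_5x_vs_fall_10x",
                          "fall_5x_vs_rise_10x")

#' Names of the built-in trajectory archetypes
#'
#' @return Character vector of the nine archetype names; the last three are
#'   condition-divergent (different base curve in 5X and 10X).
#' @export
archetypeNames <- function() c(.sharedArchetypes, .divergentArchetypes)

#' Is an archetype condition-divergent?
#'
#' @param name archetype name(s).
#' @return Logical vector; \code{TRUE} where the 5X and 10X base curves
#'   differ.
#' @export
isDivergentArchetype <- function(name) {
    bad <- setdiff(name, archetypeNames())
    if (length(bad))
        stop("unknown archetype name(s): ", paste(bad, collapse = ", "))
    name %in% .divergentArchetypes
}

#' Evaluate an archetype base curve
#'
#' Returns the deterministic, noiseless base trajectory of an archetype at
#' the coded time points, for one culture condition. Non-divergent archetypes
#' return the same curve for both conditions.
#'
#' Functional forms (amplitude \eqn{A}, coded time \eqn{x}):
#' \describe{
#'   \item{early_activator}{falling logistic \eqn{A/(1+e^{1.2(x+1)})}}
#'   \item{transient_mid}{Gaussian bump \eqn{A e^{-x^2/2}}}
#'   \item{delayed_activator}{rising logistic \eqn{A/(1+e^{-1.5x})}}
#'   \item{late_activator}{rising logistic \eqn{A/(1+e^{-1.5(x-1.5)})}}
#'   \item{flat}{constant 0}
#'   \item{oscillatory}{\eqn{0.75A\cos(\pi x)}, alternating on the grid}
#'   \item{u_shape_5x_vs_rise_10x}{5X: \eqn{A x^2/9} (interior minimum);
#'     10X: linear rise \eqn{A(x+3)/6}}
#'   \item{inverse_u_5x_vs_fall_10x}{5X: \eqn{A(1-x^2/9)} (interior maximum);
#'     10X: linear fall \eqn{A(3-x)/6}}
#'   \item{fall_5x_vs_rise_10x}{5X: linear fall; 10X: linear rise}
#' }
#'
#' @param name one of \code{archetypeNames()}.
#' @param condition "5X" or "10X".
#' @param x coded time vector (default the standard 7-point grid).
#' @param amplitude peak-to-trough scale of the curve, log-expression units.
#' @return Numeric vector the length of \code{x}.
#' @examples
#' archetypeCurve("late_activator", "10X")
#' archetypeCurve("u_shape_5x_vs_rise_10x", "5X")
#' @export
archetypeCurve <- function(name, condition = c("5X", "10X"), x = codedTime(),
                           amplitude = 2) {
    condition <- match.arg(condition)
    if (length(name) != 1L || !name %in% archetypeNames())
        stop("unknown archetype name: ", paste(name, collapse = ", "))
    stopifnot(is.numeric(x), is.finite(amplitude))
    A <- amplitude
    switch(name,
        early_activator   = A / (1 + exp(1.2 * (x + 1))),
        transient_mid     = A * exp(-x^2 / 2),
        delayed_activator = A / (1 + exp(-1.5 * x)),
        late_activator    = A / (1 + exp(-1.5 * (x - 1.5))),
        flat              = rep(0, length(x)),
        oscillatory       = 0.75 * A * cos(pi * x),
        u_shape_5x_vs_rise_10x =
            if (condition == "5X") A * x^2 / 9 else A * (x + 3) / 6,
        inverse_u_5x_vs_fall_10x =
            if (condition == "5X") A * (1 - x^2 / 9) else A * (3 - x) / 6,
        fall_5x_vs_rise_10x =
            if (condition == "5X") A * (3 - x) / 6 else A * (x + 3) / 6)
}

#' Specify a block of genes drawn from one archetype
#'
#' @param name archetype name (see \code{archetypeNames()}).
#' @param nGenes number of genes to draw from this archetype.
#' @param amplitude curve amplitude in log-expression units.
#' @param noiseSd standard deviation of the additive Gaussian noise.
#' @return A list of class \code{"ArchetypeSpec"}.
#' @export
archetypeSpec <- function(name, nGenes, amplitude = 2, noiseSd = 0.3) {
    if (!name %in% archetypeNames())
        stop("unknown archetype name: ", name)
    stopifnot(nGenes >= 0, noiseSd >= 0, is.finite(amplitude))
    structure(list(name = name, nGenes = as.integer(nGenes),
                   amplitude = amplitude, noiseSd = noiseSd),
              class = "ArchetypeSpec")
}

#' Default archetype mix spanning all nine trajectory classes
#'
#' @param nPerArchetype genes per archetype.
#' @param amplitude curve amplitude.
#' @param noiseSd noise standard deviation.
#' @return List of \code{ArchetypeSpec}, one per archetype.
#' @export
defaultArchetypeMix <- function(nPerArchetype = 100, amplitude = 2,
                                noiseSd = 0.3) {
    lapply(archetypeNames(), archetypeSpec, nGenes = nPerArchetype,
           amplitude = amplitude, noiseSd = noiseSd)
}
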