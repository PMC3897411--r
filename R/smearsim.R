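#' Components of a simulated dissociating lane
#'
#' Output of [simulateLane()]: per-position densities of the free-DNA
#' contribution (initial free DNA plus everything that dissociated during
#' the run), the surviving complex, the dissociation smear alone, and their
#' total.
#'
#' @slot grid migration positions.
#' @slot dna free-DNA density, including the smear.
#' @slot complex surviving-complex density.
#' @slot smear the dissociation smear alone (part of `dna`).
#' @slot params the [SmearSimParams-class] used.
#' @seealso [simulateLane()], [correctDivisionLine()]
#' @export
setClass("SmearComponents",
         representation(grid = "numeric", dna = "numeric",
                        complex = "numeric", smear = "numeric",
                        params = "SmearSimParams"))

setMethod("show", "SmearComponents", function(object) {
    p <- object@params
    dx <- diff(object@grid)
    tot <- sum((object@dna + object@complex)[-1] * dx +
               diff(object@dna + object@complex) * dx / 2)
    cat(sprintf(
        "SmearComponents: %d grid points, kOff*T = %.3g, total mass %.6g\n",
        length(object@grid), p@kOff * p@Tend, tot))
})

# Eq.-26/27-style kinematics of a complex dissociating at time t: it moves
# with the complex velocity until t and with the DNA velocity afterwards,
# and accumulates each state's diffusion over the time spent in it.
.smearMean <- function(t, p) p@vPrD * t + p@vD * (p@Tend - t)
.smearSD <- function(t, p) sqrt(2 * p@dPrD * t + 2 * p@dD * (p@Tend - t))

.trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

#' Simulate a lane with complex dissociation
#'
#' One-dimensional electrophoresis of a mixture of free DNA and protein-DNA
#' complex, with first-order complex dissociation during the run and no
#' re-association.  The initial free DNA and the surviving complex
#' (`c0PrD * exp(-kOff*T)`) are Gaussians centred at their terminal
#' positions with variances `2*D*T`; a complex dissociating at time t lands
#' in a Gaussian whose mean interpolates between the two band positions and
#' whose variance mixes the two diffusion coefficients by the time spent in
#' each state.  The smear is the integral of these Gaussians against the
#' exponential dissociation-time density, evaluated by composite Simpson
#' quadrature (512 intervals by default).  Dissociated molecules run as DNA
#' afterwards, so the smear is accounted to the DNA component; total mass
#' is `c0D + c0PrD`.
#'
#' @param params a [SmearSimParams-class].
#' @param nQuad number of Simpson intervals over `[0, T]` (even).
#' @return a [SmearComponents-class].
#' @export
simulateLane <- function(params, nQuad = 512L) {
    stopifnot(is(params, "SmearSimParams"))
    validObject(params)
    p <- params
    x <- p@grid
    muC <- .smearMean(p@Tend, p); sdC <- .smearSD(p@Tend, p)
    muD <- .smearMean(0, p); sdD <- .smearSD(0, p)
    if (min(x) > min(muC - 4 * sdC, muD - 4 * sdD) ||
        max(x) < max(muC + 4 * sdC, muD + 4 * sdD))
        warning("grid does not cover +/- 4 std of both bands; ",
                "profiles are truncated")
    complex <- p@c0PrD * exp(-p@kOff * p@Tend) * stats::dnorm(x, muC, sdC)
    dnaPure <- p@c0D * stats::dnorm(x, muD, sdD)
    smear <- numeric(length(x))
    if (p@kOff > 0 && p@c0PrD > 0) {
        if (nQuad %% 2L) nQuad <- nQuad + 1L
        tt <- seq(0, p@Tend, length.out = nQuad + 1L)
        h <- p@Tend / nQuad
        wts <- c(1, rep(c(4, 2), length.out = nQuad - 1L), 1) * h / 3
        dens <- p@kOff * p@c0PrD * exp(-p@kOff * tt)
        mu <- .smearMean(tt, p); sd <- .smearSD(tt, p)
        # positions x times quadrature nodes t
        G <- stats::dnorm(outer(x, mu, "-") /
                          rep(sd, each = length(x))) /
            rep(sd, each = length(x))
        smear <- as.vector(G %*% (wts * dens))
    }
    new("SmearComponents", grid = x, dna = dnaPure + smear,
        complex = complex, smear = smear, params = p)
}

#' Correct division line between the DNA and complex bands
#'
#' The position at which splitting the total profile reproduces the
#' equilibrium amounts: the integral of the total on the DNA side of the
#' line equals the initial free-DNA amount, and the other side the initial
#' complex amount.  Complexes that dissociated during the run (the smear)
#' were complexes at equilibrium, so they count toward the complex side;
#' this is the line the upper/lower bound construction of [findBound()]
#' brackets.  Found by inverting the cumulative integral with linear
#' interpolation; when the two bands do not overlap the cumulative is flat
#' across the gap and the gap midpoint is returned.
#'
#' @param components a [SmearComponents-class].
#' @return migration position of the correct division line.
#' @export
correctDivisionLine <- function(components) {
    stopifnot(is(components, "SmearComponents"))
    x <- components@grid
    tot <- components@dna + components@complex
    p <- components@params
    dnaMass <- .trapz(x, components@dna - components@smear)
    # which side of the axis the DNA band is on
    muD <- .smearMean(0, p); muC <- .smearMean(p@Tend, p)
    cum <- c(0, cumsum(diff(x) * (tot[-1] + tot[-length(tot)]) / 2))
    target <- if (muD < muC) dnaMass else cum[length(cum)] - dnaMass
    # leftmost and rightmost crossings; midpoint is robust to flat gaps
    lo <- suppressWarnings(max(which(cum <= target)))
    hi <- suppressWarnings(min(which(cum >= target)))
    interp <- function(i) {
        if (i >= length(cum)) return(x[length(x)])
        d <- cum[i + 1L] - cum[i]
        if (d <= 0) x[i] else x[i] + (target - cum[i]) / d * (x[i + 1L] - x[i])
    }
    xlo <- interp(max(lo, 1L))
    # last index where cum < target strictly, to find the right edge of a
    # flat plateau at the target level
    plateau <- which(abs(cum - target) <= 1e-12 * max(cum))
    if (length(plateau) > 1L)
        (x[min(plateau)] + x[max(plateau)]) / 2
    else
        xlo
}

#' Check that the smear decreases toward the complex band
#'
#' The amount of complex dissociating per unit time is proportional to the
#' amount left, so the smear density laid down between the bands decreases
#' toward the complex band.  Evaluated on the region between the band
#' cores, excluding `nSigma` standard deviations around each band centre so
#' the pure-band Gaussian tails do not dominate.  Returns NA when the bands
#' are closer than twice their combined widths (check skipped).
#'
#' @param components a [SmearComponents-class].
#' @param nSigma tail exclusion half-width in band standard deviations.
#' @return TRUE/FALSE, or NA when the bands are too close (or no smear).
#' @export
smearDecreasingTowardComplex <- function(components, nSigma = 2) {
    stopifnot(is(components, "SmearComponents"))
    p <- components@params
    if (p@kOff == 0) return(TRUE)    # vacuous: no smear
    muD <- .smearMean(0, p); sdD <- .smearSD(0, p)
    muC <- .smearMean(p@Tend, p); sdC <- .smearSD(p@Tend, p)
    if (abs(muD - muC) < 2 * (sdD + sdC)) return(NA)
    x <- components@grid
    if (muD < muC) {
        keep <- x > muD + nSigma * sdD & x < muC - nSigma * sdC
        towardComplex <- TRUE       # increasing x moves toward the complex
    } else {
        keep <- x < muD - nSigma * sdD & x > muC + nSigma * sdC
        towardComplex <- FALSE
    }
    s <- components@smear[keep]
    if (length(s) < 3L) return(NA)
    # the convolved density still rises on the DNA-band side of its own
    # maximum; the claim is about the decay toward the complex band
    if (!towardComplex) s <- rev(s)
    s <- s[which.max(s):length(s)]
    if (length(s) < 3L) return(NA)
    all(diff(s) <= 1e-12 * max(s))
}
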