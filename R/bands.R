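# Profiles are piecewise-constant over pixels: pixel p covers [p-1, p) on
# the continuous migration axis, so the cumulative integral is piecewise
# linear and boundaries resolve to sub-pixel positions by linear
# interpolation.

# cumulative integral of v at (possibly fractional) position x in [0, n]
.cumAt <- function(v, x) {
    n <- length(v)
    x <- pmin(pmax(x, 0), n)
    k <- pmin(floor(x), n - 1)
    cs <- c(0, cumsum(v))
    cs[k + 1] + (x - k) * v[k + 1]
}

#' Integrate a lane profile over an interval
#'
#' Treats the profile as piecewise-constant over pixels (pixel p covers
#' `[p-1, p)`); fractional limits contribute proportionally.
#'
#' @param values numeric vector, one lane's profile.
#' @param a,b integration limits on the migration axis (a <= b).
#' @return the integral (intensity x position units).
#' @export
profileIntegral <- function(values, a, b) {
    stopifnot(a <= b)
    .cumAt(values, b) - .cumAt(values, a)
}

#' Construct a band-boundary bound by area matching
#'
#' The user picks a point `p1 = (x1, y1)` on the profile inside the smear
#' near the flanking band, and `p2 = (x2, y2)` with `x2` at that band's peak
#' and `y2` an estimate of the single-stranded-DNA smear level (zero when
#' none).  The rectangle spanned by the two points, `|x2 - x1| * (y1 - y2)`,
#' estimates the dissociation smear beyond `x1`; the returned division line
#' `x*` sits between `x1` and the peak such that the profile area between
#' `x*` and `x1` equals that rectangle, found by inverting the cumulative
#' integral with sub-pixel linear interpolation.  With `y1` an
#' under-estimate of the smear the result is an upper bound of the correct
#' division line; with an over-estimate (and `x2` slightly off-peak) a lower
#' bound.  `y1 = y2` (all smear attributed to ssDNA) returns `x1` itself,
#' which is also the manual-selection mode.
#'
#' @param values numeric vector, one lane's profile (background-subtracted).
#' @param p1 numeric `c(x1, y1)`: point on the curve within the smear.
#' @param p2 numeric `c(x2, y2)`: peak position and ssDNA smear estimate.
#' @return the division-line position `x*`.
#' @export
findBound <- function(values, p1, p2) {
    stopifnot(length(p1) == 2L, length(p2) == 2L)
    n <- length(values)
    x1 <- p1[1L]; y1 <- p1[2L]; x2 <- p2[1L]; y2 <- p2[2L]
    if (x1 < 0 || x1 > n || x2 < 0 || x2 > n)
        stop("invalid selection: points outside the profile")
    if (x1 == x2) stop("invalid selection: p1 and p2 coincide")
    A <- abs(x2 - x1) * (y1 - y2)
    if (A <= 0) return(x1)
    avail <- abs(profileIntegral(values, min(x1, x2), max(x1, x2)))
    if (A >= avail) {
        warning("target area exceeds profile area before the band peak; ",
                "returning the peak position")
        return(x2)
    }
    dir <- sign(x2 - x1)
    f <- function(x) abs(.cumAt(values, x1) - .cumAt(values, x)) - A
    # cumulative is monotone non-decreasing, so f is monotone along dir
    stats::uniroot(f, sort(c(x1, x2)), tol = 1e-12)$root
}

.checkPairs <- function(pairs, outer) {
    if (length(pairs) == 0L) stop("need at least one boundary pair")
    lows <- vapply(pairs, function(p) p@lower, numeric(1))
    ups <- vapply(pairs, function(p) p@upper, numeric(1))
    ord <- order(lows)
    lows <- lows[ord]; ups <- ups[ord]
    if (any(lows < outer[1L]) || any(ups > outer[2L]))
        stop("invalid selection: boundary pair outside the outer lines")
    if (length(lows) > 1L && any(lows[-1L] < ups[-length(ups)]))
        stop("invalid selection: overlapping boundary pairs")
    list(lower = lows, upper = ups)
}

#' Integrate band intensities with half-smear assignment
#'
#' Band j integrates the profile from the upper bound of interface j-1 to
#' the lower bound of interface j; the smear inside each boundary pair
#' (where the division line is uncertain) is split half-and-half between the
#' two adjacent bands.  The outer background lines close the first and last
#' band, so the band total equals the full profile integral between the
#' outer lines.
#'
#' @param values numeric vector, one lane's background-subtracted profile.
#' @param pairs list of [BoundaryPair-class], ordered and disjoint.
#' @param outer numeric(2), the outer integration limits.
#' @return list with `intensity` (length pairs+1), `smear` (length pairs).
#' @export
assignBands <- function(values, pairs, outer) {
    pp <- .checkPairs(pairs, outer)
    m <- length(pp$lower)
    edgeLo <- c(outer[1L], pp$upper)       # start of band j
    edgeHi <- c(pp$lower, outer[2L])       # end of band j
    core <- vapply(seq_len(m + 1L), function(j)
        profileIntegral(values, edgeLo[j], edgeHi[j]), numeric(1))
    smear <- vapply(seq_len(m), function(k)
        profileIntegral(values, pp$lower[k], pp$upper[k]), numeric(1))
    half <- c(0, smear / 2) + c(smear / 2, 0)
    list(intensity = core + half, smear = smear)
}

#' Build the band table for all lanes
#'
#' Applies one set of boundary pairs (selected on a representative lane and
#' transferred to all lanes) to every lane profile.  Nominal band extents,
#' used for background-error integration, run between interface midpoints.
#'
#' @param profiles a background-subtracted [LaneProfileSet-class] with
#'   outer limits set.
#' @param pairs list of [BoundaryPair-class]; optionally a list of such
#'   lists, one per lane, for per-lane overrides.
#' @return a [BandTable-class].
#' @export
bandTable <- function(profiles, pairs) {
    stopifnot(is(profiles, "LaneProfileSet"))
    if (length(profiles@outer) != 2L)
        stop("profiles need outer limits (run subtractBackground first)")
    outer <- profiles@outer
    nl <- ncol(profiles@values)
    perLane <- length(pairs) && is(pairs[[1L]], "list")
    getPairs <- function(lane) if (perLane) pairs[[lane]] else pairs
    p1 <- getPairs(1L)
    m <- length(p1)
    intensity <- matrix(NA_real_, nl, m + 1L)
    smear <- matrix(NA_real_, nl, m)
    for (lane in seq_len(nl)) {
        a <- assignBands(profiles@values[, lane], getPairs(lane), outer)
        intensity[lane, ] <- a$intensity
        smear[lane, ] <- a$smear
    }
    # bookkeeping extents/interfaces: per-lane pairs are averaged so band
    # extents (used for background-error integration) are shared
    pp <- .checkPairs(p1, outer)
    if (perLane) {
        allP <- lapply(seq_len(nl), function(lane)
            .checkPairs(getPairs(lane), outer))
        lows <- matrix(vapply(allP, `[[`, numeric(m), "lower"), nrow = m)
        ups <- matrix(vapply(allP, `[[`, numeric(m), "upper"), nrow = m)
        pp <- list(lower = rowMeans(lows), upper = rowMeans(ups))
    }
    mids <- (pp$lower + pp$upper) / 2
    extents <- cbind(c(outer[1L], mids), c(mids, outer[2L]))
    laneSums <- vapply(seq_len(nl), function(lane)
        profileIntegral(profiles@values[, lane], outer[1L], outer[2L]),
        numeric(1))
    new("BandTable", intensity = intensity, smear = smear,
        extents = extents, interfaces = cbind(pp$lower, pp$upper),
        laneSums = laneSums)
}

#' @describeIn BandTable-class lanes x bands intensity matrix.
#' @param x a `BandTable`.
#' @export
setGeneric("bandIntensities", function(x) standardGeneric("bandIntensities"))

#' @rdname BandTable-class
#' @export
setMethod("bandIntensities", "BandTable", function(x) x@intensity)

#' @describeIn BandTable-class lanes x interfaces smear matrix.
#' @export
setGeneric("smearAmounts", function(x) standardGeneric("smearAmounts"))

#' @rdname BandTable-class
#' @export
setMethod("smearAmounts", "BandTable", function(x) x@smear)

#' @describeIn BandTable-class per-lane totals between the outer lines.
#' @export
setGeneric("laneSums", function(x) standardGeneric("laneSums"))

#' @rdname BandTable-class
#' @export
setMethod("laneSums", "BandTable", function(x) x@laneSums)

setMethod("show", "BandTable", function(object) {
    cat(sprintf("BandTable: %d lanes x %d bands\n",
                nrow(object@intensity), ncol(object@intensity)))
    print(signif(object@intensity, 5))
})

#' Subtract a constant ssDNA (or contaminant) band from all lanes
#'
#' Single-stranded DNA forms before electrophoresis and its band intensity
#' is protein-independent, so it can be measured once -- in the lane where
#' it is best resolved, usually the no-protein lane -- and subtracted from
#' the band (or interface smear) it sits in, in every lane.
#'
#' @param table a [BandTable-class].
#' @param profiles the [LaneProfileSet-class] the table was built from.
#' @param referenceLane lane in which the ssDNA band is measured.
#' @param region numeric `c(a, b)`: migration interval of the ssDNA band.
#' @param target list `list(type = "band"|"interface", index = j)`: where
#'   the ssDNA band sits.  Subtracting from an interface also removes the
#'   half-smear shares the two adjacent bands received from it.
#' @return the corrected [BandTable-class].
#' @export
subtractSsDNA <- function(table, profiles, referenceLane, region, target) {
    stopifnot(is(table, "BandTable"), is(profiles, "LaneProfileSet"))
    q <- profileIntegral(profiles@values[, referenceLane],
                         region[1L], region[2L])
    ext <- table@extents
    j <- target$index
    if (target$type == "band") {
        if (region[1L] < ext[j, 1L] - 1e-9 || region[2L] > ext[j, 2L] + 1e-9)
            stop("invalid selection: region outside the target band")
        table@intensity[, j] <- table@intensity[, j] - q
    } else if (target$type == "interface") {
        itf <- table@interfaces
        if (region[1L] < itf[j, 1L] - 1e-9 || region[2L] > itf[j, 2L] + 1e-9)
            stop("invalid selection: region outside the target interface")
        table@smear[, j] <- table@smear[, j] - q
        table@intensity[, j] <- table@intensity[, j] - q / 2
        table@intensity[, j + 1L] <- table@intensity[, j + 1L] - q / 2
    } else stop("target$type must be 'band' or 'interface'")
    if (any(table@intensity < 0))
        message("ssDNA subtraction produced negative band intensities")
    table@laneSums <- table@laneSums - q
    table
}

#' Zero out a contaminant region in every lane
#'
#' Literal removal of a contaminating or ssDNA band that does not overlap
#' any band of interest: profile values in `[a, b)` are set to zero in all
#' lanes before integration.  Idempotent.
#'
#' @param profiles a [LaneProfileSet-class].
#' @param region numeric `c(a, b)` on the migration axis.
#' @param cores optional list of band core intervals; a warning is issued if
#'   the region intersects one.
#' @return the modified [LaneProfileSet-class].
#' @export
zeroRegion <- function(profiles, region, cores = NULL) {
    stopifnot(is(profiles, "LaneProfileSet"))
    if (region[2L] <= region[1L]) return(profiles)
    if (!is.null(cores)) {
        for (core in cores)
            if (region[1L] < core[2L] && region[2L] > core[1L]) {
                warning("zeroed region intersects a band core interval")
                break
            }
    }
    nr <- nrow(profiles@values)
    pos <- seq_len(nr) - 0.5
    rows <- which(pos >= region[1L] & pos < region[2L])
    profiles@values[rows, ] <- 0
    profiles
}

# linear interpolation of a profile at fractional position (pixel centers)
.profAt <- function(values, x) {
    pos <- seq_along(values) - 0.5
    stats::approx(pos, values, xout = x, rule = 2)$y
}

#' Select boundary pairs by the upper/lower-bound recipe
#'
#' Automates the interactive construction: for each interface between
#' adjacent band peaks, the upper bound uses a point `p1` on the profile in
#' the smear close to the lower band (at `fracUpper` of the gap) with `p2`
#' at the band peak and the ssDNA smear over-estimate; the lower bound uses
#' a `p1` where the profile reaches an over-estimate of the smear level
#' (by `overFactor`) and a `p2` slightly left of the peak (by `offset`
#' pixels, compensating the peak shift that smear causes) at the ssDNA
#' under-estimate.  Pairs are selected on one representative lane and
#' applied to all lanes by [bandTable()].
#'
#' @param values one lane's background-subtracted profile.
#' @param peaks increasing migration positions of the band peaks.
#' @param ssdnaOver,ssdnaUnder over-/under-estimate of the ssDNA smear level
#'   (0 when there is none).
#' @param offset left shift of the lower-bound `p2` in pixels (default 2).
#' @param fracUpper position of the upper-bound `p1` within the gap.
#' @param overFactor smear over-estimation factor for the lower bound.
#' @return list of [BoundaryPair-class], one per interface.
#' @export
selectBoundaryPairs <- function(values, peaks, ssdnaOver = 0,
                                ssdnaUnder = 0, offset = 2,
                                fracUpper = 0.45, overFactor = 1.5) {
    stopifnot(length(peaks) >= 2L, all(diff(peaks) > 0))
    out <- vector("list", length(peaks) - 1L)
    for (j in seq_len(length(peaks) - 1L)) {
        lo <- peaks[j]; hi <- peaks[j + 1L]
        gap <- hi - lo
        # p1 must sit on the smear, past the visible flank of the lower
        # band: estimate the band width from its half-maximum point
        vPk <- .profAt(values, lo)
        xs0 <- seq(lo, hi, by = 0.25)
        half <- which(.profAt(values, xs0) <= vPk / 2)
        sigmaHat <- if (length(half))
            (xs0[min(half)] - lo) / 1.1774 else gap / 8
        x1 <- lo + min(max(fracUpper * gap, 4.5 * sigmaHat), 0.8 * gap)
        y1 <- .profAt(values, x1)
        upper <- findBound(values, c(x1, y1), c(lo, ssdnaOver))
        # lower-bound p1: where the profile first descends to an
        # over-estimate of the smear level, scanning from the peak
        yTarget <- overFactor * max(y1, 0)
        xs <- seq(lo, x1, by = 0.25)
        vs <- .profAt(values, xs)
        idx <- which(vs <= yTarget)
        x1l <- if (length(idx)) xs[min(idx)] else x1
        y1l <- .profAt(values, x1l)
        lower <- findBound(values, c(x1l, y1l), c(lo - offset, ssdnaUnder))
        if (lower > upper) {
            warning("interface ", j, ": bound recipe inverted the pair; ",
                    "bounds swapped")
            tmp <- lower; lower <- upper; upper <- tmp
        }
        out[[j]] <- BoundaryPair(lower, upper)
    }
    out
}

#' Detect band peaks from lane profiles
#'
#' Sums the background-subtracted profiles over lanes, smooths with a
#' running mean, and returns the positions of the `nBands` highest local
#' maxima (sorted).  Intended as the automatic starting point for
#' [selectBoundaryPairs()]; explicit peak positions always take precedence.
#'
#' @param profiles a [LaneProfileSet-class].
#' @param nBands number of bands expected.
#' @param smoothWidth running-mean width in pixels.
#' @return increasing peak positions.
#' @export
detectBandPeaks <- function(profiles, nBands, smoothWidth = 5L) {
    stopifnot(is(profiles, "LaneProfileSet"))
    s <- .runMean(rowSums(profiles@values), smoothWidth)
    n <- length(s)
    cand <- which(diff(sign(diff(s))) < 0) + 1L
    cand <- cand[cand > 1L & cand < n]
    if (length(cand) < nBands)
        stop("found ", length(cand), " profile maxima for ", nBands,
             " bands; specify band peaks manually")
    cand <- cand[order(s[cand], decreasing = TRUE)][seq_len(nBands)]
    sort(cand - 0.5)
}
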