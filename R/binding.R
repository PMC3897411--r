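#' Protein concentration in a lane
#'
#' Dilution arithmetic for the binding reaction: a volume of protein stock
#' diluted into the total sample volume.  Mass-concentration stocks (g/L;
#' mg/mL is numerically identical) are converted to molar via the molar
#' weight.  The free protein concentration at equilibrium is taken equal to
#' the added concentration, valid when the protein is in large excess over
#' the DNA (DNA around 0.1 nM, protein in the nM-uM range).
#'
#' @param stockConcentration stock concentration, molar or g/L.
#' @param volume protein volume added to the lane (any volume unit, shared
#'   with `totalVolume`).
#' @param totalVolume total sample volume.
#' @param molarWeight g/mol; required for mass-based stocks.
#' @param stockUnit "molar" or "mass_per_volume".
#' @return molar concentration.
#' @examples
#' proteinConcentration(200e-9, 1, 20)                      # 10 nM
#' proteinConcentration(0.5, 2, 20, molarWeight = 50000,
#'                      stockUnit = "mass_per_volume")      # 1 uM
#' @export
proteinConcentration <- function(stockConcentration, volume, totalVolume,
                                 molarWeight = NULL,
                                 stockUnit = c("molar", "mass_per_volume")) {
    stockUnit <- match.arg(stockUnit)
    if (totalVolume <= 0) stop("total volume must be positive")
    if (volume < 0) stop("protein volume must be non-negative")
    molar <- if (stockUnit == "molar") stockConcentration else {
        if (is.null(molarWeight) || !is.finite(molarWeight) ||
            molarWeight <= 0)
            stop("mass-based stock concentration requires a molar weight")
        stockConcentration / molarWeight
    }
    molar * volume / totalVolume
}

#' Per-lane stepwise equilibrium constant
#'
#' The stepwise association constant for adding the j-th protein,
#' `K_j = I(band j+1) / I(band j) / [Pr]`, the ratio of the two band
#' intensities flanking interface j divided by the protein concentration.
#' Being a ratio it is invariant to any global intensity scaling of the
#' image.
#'
#' @param table a [BandTable-class].
#' @param lane lane index.
#' @param interface interface index j (between bands j and j+1); the
#'   user-selectable K index.
#' @param pr protein concentration in the lane (molar).
#' @return a [LaneKEstimate-class] with the K value (error slots NA).  A
#'   lane with `pr = 0` or a non-positive denominator band yields `k = NA`
#'   (the lane is excluded from averaging), with a warning in the latter
#'   case.
#' @export
stepwiseK <- function(table, lane, interface, pr) {
    stopifnot(is(table, "BandTable"))
    iLo <- table@intensity[lane, interface]
    iHi <- table@intensity[lane, interface + 1L]
    k <- NA_real_; ratio <- NA_real_
    if (pr > 0) {
        if (iLo <= 0) {
            warning("lane ", lane, ": denominator band intensity <= 0; ",
                    "K undefined")
        } else {
            ratio <- iHi / iLo
            k <- max(ratio, 0) / pr
        }
    }
    new("LaneKEstimate", lane = as.integer(lane), k = k, ratio = ratio,
        pr = as.numeric(pr), sigmaBg = NA_real_, sigmaSmear = NA_real_)
}

# perturb-and-recompute relative K error when the two band intensities
# change by (dLo, dHi); exact rather than first-order
.relKShift <- function(iLo, iHi, dLo, dHi) {
    k0 <- iHi / iLo
    k1 <- (iHi + dHi) / (iLo + dLo)
    abs(k1 - k0) / abs(k0)
}

#' Background non-uniformity error of a lane K value
#'
#' The baseline subtracted in a lane cannot be checked inside its own bands;
#' the difference between the lane's baseline and each neighbouring lane's
#' baseline, integrated over each band's extent, proxies the non-uniformity.
#' For each available neighbour the two band perturbations are applied to
#' the measured intensities and K is recomputed; the largest absolute
#' relative shift is the maximum error E_max.  Treating the true error as
#' uniformly distributed on (-E_max, +E_max) gives the standard deviation
#' `sigma = E_max / sqrt(3)`.
#'
#' @param profiles the background-subtracted [LaneProfileSet-class].
#' @param table the [BandTable-class].
#' @param lane,interface as in [stepwiseK()].
#' @return the relative standard deviation (dimensionless); multiply by |K|
#'   for the absolute value.  NA with a message when the lane has no
#'   neighbour.
#' @export
backgroundError <- function(profiles, table, lane, interface) {
    stopifnot(is(profiles, "LaneProfileSet"), is(table, "BandTable"))
    nl <- ncol(profiles@values)
    neigh <- intersect(c(lane - 1L, lane + 1L), seq_len(nl))
    if (length(neigh) == 0L) {
        message("single lane: background error undefined")
        return(NA_real_)
    }
    extLo <- table@extents[interface, ]
    extHi <- table@extents[interface + 1L, ]
    iLo <- table@intensity[lane, interface]
    iHi <- table@intensity[lane, interface + 1L]
    bgLane <- profiles@background[, lane]
    est <- vapply(neigh, function(nb) {
        dB <- profiles@background[, nb] - bgLane
        dLo <- profileIntegral(dB, extLo[1L], extLo[2L])
        dHi <- profileIntegral(dB, extHi[1L], extHi[2L])
        .relKShift(iLo, iHi, -dLo, -dHi)
    }, numeric(1))
    max(abs(est)) / sqrt(3)
}

#' Smear error of a lane K value
#'
#' Half the smear inside each boundary pair was assigned to each adjacent
#' band; the true division could have sent it all to one side.  The maximum
#' error is found by recomputing K with the half-smear of the interface
#' moved fully to one band and then fully to the other.  With more than one
#' binding site the smear in front of the lower band (interface j-1) and
#' behind the upper band (interface j+1) perturb one band each in the same
#' way; the per-interval standard deviations `E_max / sqrt(3)` are combined
#' as the square root of the sum of variances.
#'
#' @param table a [BandTable-class].
#' @param lane,interface as in [stepwiseK()].
#' @param nSites number of binding sites on the DNA fragment.
#' @return the relative standard deviation (dimensionless).
#' @export
smearError <- function(table, lane, interface, nSites = 1L) {
    stopifnot(is(table, "BandTable"))
    iLo <- table@intensity[lane, interface]
    iHi <- table@intensity[lane, interface + 1L]
    m <- ncol(table@smear)
    eMaxOf <- function(dLo1, dHi1, dLo2, dHi2)
        max(.relKShift(iLo, iHi, dLo1, dHi1),
            .relKShift(iLo, iHi, dLo2, dHi2))
    s <- table@smear[lane, interface]
    sigmas <- eMaxOf(-s / 2, s / 2, s / 2, -s / 2) / sqrt(3)
    if (nSites > 1L) {
        if (interface - 1L >= 1L) {
            sb <- table@smear[lane, interface - 1L]
            sigmas <- c(sigmas, eMaxOf(-sb / 2, 0, sb / 2, 0) / sqrt(3))
        }
        if (interface + 1L <= m) {
            sa <- table@smear[lane, interface + 1L]
            sigmas <- c(sigmas, eMaxOf(0, -sa / 2, 0, sa / 2) / sqrt(3))
        }
    }
    sqrt(sum(sigmas^2))
}

#' Estimate a lane's K value with its full error budget
#'
#' Convenience wrapper: [stepwiseK()] plus [backgroundError()] and
#' [smearError()], with the relative errors converted to the K scale.
#'
#' @inheritParams backgroundError
#' @inheritParams smearError
#' @param pr protein concentration in the lane (molar).
#' @return a completed [LaneKEstimate-class].
#' @export
laneKEstimate <- function(profiles, table, lane, interface, pr,
                          nSites = 1L) {
    est <- stepwiseK(table, lane, interface, pr)
    if (is.finite(est@k)) {
        est@sigmaBg <- backgroundError(profiles, table, lane, interface) *
            abs(est@k)
        est@sigmaSmear <- smearError(table, lane, interface, nSites) *
            abs(est@k)
    }
    est
}

setMethod("show", "LaneKEstimate", function(object) {
    cat(sprintf(
        "LaneKEstimate lane %d: K = %.4g (ratio %.4g, [Pr] = %.4g), %s\n",
        object@lane, object@k, object@ratio, object@pr,
        sprintf("sigma_bg = %.3g, sigma_smear = %.3g",
                object@sigmaBg, object@sigmaSmear)))
})

#' Average K over selected lanes with error decomposition
#'
#' Background and technical errors are random over lanes, so they average
#' down and are measured by the standard error of the mean; smear errors
#' are assumed fully correlated over lanes (the same boundary pairs are
#' applied everywhere), so they are systematic and do not average down:
#' \itemize{
#'   \item `sem = sd(K) / sqrt(n)` (the measured random error),
#'   \item `sigmaBgAvg = sqrt(sum sigmaBg_i^2) / n` (independent),
#'   \item `sigmaSmearAvg = sum(sigmaSmear_i) / n` (correlated),
#'   \item `sigmaTotal = sqrt(sem^2 + sigmaSmearAvg^2)`,
#'   \item `sigmaTech = sqrt(max(0, sem^2 - sigmaBgAvg^2))`, the technical
#'     remainder, floored at zero since the background contribution may be
#'     overestimated.
#' }
#' With a reference summary, `normalizedK = meanK / meanK_ref` and the
#' relative variances of the two totals add.
#'
#' @param estimates list of [LaneKEstimate-class].
#' @param selectedLanes lanes to average; fewer than 2 is an error and fewer
#'   than 3 draws a warning (too few lanes underestimate the spread).
#' @param reference optional [KSummary-class] of a reference sequence
#'   measured in parallel, for normalization.
#' @return a [KSummary-class].
#' @export
summarizeK <- function(estimates, selectedLanes = NULL, reference = NULL) {
    lanes <- vapply(estimates, function(e) e@lane, integer(1))
    if (is.null(selectedLanes))
        selectedLanes <- lanes[vapply(estimates,
                                      function(e) is.finite(e@k), logical(1))]
    sel <- estimates[match(selectedLanes, lanes)]
    if (anyNA(match(selectedLanes, lanes)))
        stop("selected lane without an estimate")
    ks <- vapply(sel, function(e) e@k, numeric(1))
    if (any(!is.finite(ks)))
        stop("selected lanes include an undefined K value")
    n <- length(ks)
    if (n < 2L) stop("need at least 2 lanes to summarize")
    if (n < 3L)
        warning("select at least 3 lanes for the calculation of an ",
                "average equilibrium constant")
    meanK <- mean(ks)
    sem <- stats::sd(ks) / sqrt(n)
    sBg <- vapply(sel, function(e) e@sigmaBg, numeric(1))
    sSm <- vapply(sel, function(e) e@sigmaSmear, numeric(1))
    sigmaBgAvg <- if (all(is.finite(sBg))) sqrt(sum(sBg^2)) / n else NA_real_
    sigmaSmearAvg <- if (all(is.finite(sSm))) sum(sSm) / n else NA_real_
    sigmaTotal <- sqrt(sem^2 + ifelse(is.finite(sigmaSmearAvg),
                                      sigmaSmearAvg^2, 0))
    sigmaTech <- if (is.finite(sigmaBgAvg)) {
        if (sem < sigmaBgAvg)
            message("background error exceeds the measured spread; ",
                    "technical contribution floored at 0")
        sqrt(max(0, sem^2 - sigmaBgAvg^2))
    } else NA_real_
    normalizedK <- NA_real_; normalizedStd <- NA_real_
    if (!is.null(reference)) {
        stopifnot(is(reference, "KSummary"))
        normalizedK <- meanK / reference@meanK
        relVar <- (sigmaTotal / meanK)^2 +
            (reference@sigmaTotal / reference@meanK)^2
        normalizedStd <- abs(normalizedK) * sqrt(relVar)
    }
    new("KSummary", meanK = meanK, sem = sem, sigmaBgAvg = sigmaBgAvg,
        sigmaSmearAvg = sigmaSmearAvg, sigmaTech = sigmaTech,
        sigmaTotal = sigmaTotal,
        selectedLanes = as.integer(selectedLanes),
        normalizedK = normalizedK, normalizedStd = normalizedStd)
}

setMethod("show", "KSummary", function(object) {
    cat(sprintf("KSummary over lanes %s:\n",
                paste(object@selectedLanes, collapse = ", ")))
    cat(sprintf("  mean K      = %.4g +/- %.3g (total)\n",
                object@meanK, object@sigmaTotal))
    cat(sprintf("  sem %.3g | sigma_bg %.3g | sigma_smear %.3g | tech %.3g\n",
                object@sem, object@sigmaBgAvg, object@sigmaSmearAvg,
                object@sigmaTech))
    if (is.finite(object@normalizedK))
        cat(sprintf("  normalized K = %.4g +/- %.3g\n",
                    object@normalizedK, object@normalizedStd))
})

#' Select the best lanes for averaging
#'
#' Lanes with a nearly invisible band -- typically the extremes of a
#' titration -- carry outsized background and smear error estimates and a
#' biased intensity ratio; averaging them in degrades the result.  The
#' default selection keeps every lane with a defined K whose estimated
#' relative error, `sqrt((sigmaBg/K)^2 + (sigmaSmear/K)^2)`, is within
#' `maxFactor` times the median over the candidate lanes; at least
#' `minLanes` lanes (those with the smallest estimated error) are always
#' retained.
#'
#' @param estimates list of [LaneKEstimate-class].
#' @param maxFactor outlier threshold relative to the median (default 3).
#' @param minLanes minimum number of lanes kept (default 3).
#' @return integer vector of selected lane indices.
#' @export
bestLanes <- function(estimates, maxFactor = 3, minLanes = 3L) {
    lanes <- vapply(estimates, function(e) e@lane, integer(1))
    ok <- vapply(estimates, function(e) is.finite(e@k) && e@k > 0,
                 logical(1))
    cand <- which(ok)
    relE <- vapply(estimates[cand], function(e) {
        comp <- c(e@sigmaBg, e@sigmaSmear) / e@k
        sqrt(sum(comp[is.finite(comp)]^2))
    }, numeric(1))
    if (!any(is.finite(relE))) return(lanes[cand])
    keep <- relE <= maxFactor * stats::median(relE, na.rm = TRUE)
    if (sum(keep) < min(minLanes, length(cand)))
        keep <- rank(relE, ties.method = "first") <=
            min(minLanes, length(cand))
    sort(lanes[cand[keep]])
}
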