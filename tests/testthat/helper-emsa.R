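# shared fixtures, all generated in code

# run the standard quantification on a generated EMSA, returning the
# analyzeScan() result
analyzeTruth <- function(tr, ...) {
    gen <- generateEMSA(tr)
    tablet <- NULL; film <- NULL
    if (tr@sourceKind == "autoradiograph") {
        tablet <- tabletFromImage(gen$tabletImage, gen$tabletRects,
                                  gen$tabletOD)
        film <- tr@film
    }
    res <- suppressMessages(suppressWarnings(analyzeScan(
        gen$scan, tr@sourceKind, tablet = tablet, film = film,
        nLanes = length(tr@prLane), laneBoundaries = gen$laneBoundaries,
        bgLeft = gen$bgLeft, bgRight = gen$bgRight,
        nBands = length(tr@bandCenters), bandPeaks = tr@bandCenters,
        prLane = tr@prLane, kIndex = 1L, ...)))
    res$gen <- gen
    res
}

# a LaneProfileSet built directly from a matrix of profile values
profilesFrom <- function(values, background = NULL, outer = NULL) {
    if (is.null(background)) background <- matrix(0, nrow(values),
                                                  ncol(values))
    if (is.null(outer)) outer <- c(0, nrow(values))
    new("LaneProfileSet", values = values, background = background,
        outer = as.numeric(outer))
}

# a CalibratedImage from a plain matrix
imageFrom <- function(m, mask = NULL, kind = "phosphorimage") {
    if (is.null(mask)) mask <- matrix(TRUE, nrow(m), ncol(m))
    new("CalibratedImage", intensities = m, mask = mask, sourceKind = kind)
}

# dissociation simulation on a unit-spaced grid in lane-profile
# orientation (DNA band at low positions)
smearCase <- function(kOffT, sep, dRatio, sigmaD = 8, muD = 60,
                      c0D = 1, c0PrD = 1, n = NULL) {
    if (is.null(n)) n <- ceiling(muD + sep + 8 * sigmaD)
    dD <- sigmaD^2 / 2
    simulateLane(SmearSimParams(dD = dD, dPrD = dD / dRatio, vD = muD,
                                vPrD = muD + sep, Tend = 1, kOff = kOffT,
                                c0D = c0D, c0PrD = c0PrD,
                                grid = seq(0.5, n - 0.5, by = 1)))
}
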