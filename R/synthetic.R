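#' Equilibrium species fractions for sequential binding
#'
#' For a DNA fragment binding up to m proteins with stepwise association
#' constants K_1..K_m, the species with j proteins bound has statistical
#' weight `prod(K_i * pr, i <= j)` relative to free DNA.  This partition
#' function is also the brute-force oracle behind the K-recovery and
#' cooperativity tests.
#'
#' @param ks stepwise association constants (1/molar), length m.
#' @param pr free protein concentration (molar).
#' @return fractions of the m + 1 species (free DNA first), summing to 1.
#' @examples
#' equilibriumFractions(0.1, 10)        # one site, K*pr = 1: 0.5 / 0.5
#' @export
equilibriumFractions <- function(ks, pr) {
    stopifnot(all(ks > 0), pr >= 0)
    w <- c(1, cumprod(ks * pr))
    w / sum(w)
}

#' Ground truth for a synthetic EMSA
#'
#' Fully determines a generated scan given the seed.  The defaults mirror a
#' typical EMSA titration: 7 lanes, free DNA at the image bottom, protein
#' concentration 0 in lane 1 and a geometric series across the remaining
#' lanes spanning K*Pr from 0.1 to 10, constant DNA mass per lane,
#' mild complex dissociation during the run (kOff*T = 0.1, DNA
#' diffusing 1.5x faster than the complex), an affine background, Kodak
#' Biomax MR film response (OD 0.06-1.6) and scanner noise at a
#' signal-to-noise ratio of about 30.
#'
#' @slot trueK stepwise constants (1/nM), one per interface.
#' @slot prLane per-lane protein concentration (nM).
#' @slot dnaMass total DNA mass per lane (arbitrary units).
#' @slot laneWidth,height geometry in pixels.
#' @slot bandCenters migration positions of the band centres (from bottom).
#' @slot bandSigma,laneSigma Gaussian band width (migration) and lane width
#'   (horizontal) in pixels.
#' @slot bgCoef affine background `c(a, bx, by)` in intensity units.
#' @slot ssdnaMass,ssdnaCenter constant ssDNA band (mass 0 = none).
#' @slot kOffT dissociation extent over the run (0 = no smear).
#' @slot diffRatio D_DNA / D_complex.
#' @slot film the [FilmModel-class] applied in forward direction.
#' @slot odTarget peak OD the exposure is scaled to.
#' @slot gain fixed exposure gain (gray per unit mass density); NA (the
#'   default) auto-exposes each image to `odTarget`.
#' @slot snr peak-signal to noise-sd ratio of the scanner, gray domain.
#' @slot sourceKind "autoradiograph" or "phosphorimage".
#' @slot seed RNG seed.
#' @seealso [syntheticTruth()], [generateEMSA()]
#' @export
setClass("SyntheticTruth",
         representation(trueK = "numeric", prLane = "numeric",
                        dnaMass = "numeric", laneWidth = "numeric",
                        height = "numeric", bandCenters = "numeric",
                        bandSigma = "numeric", laneSigma = "numeric",
                        bgCoef = "numeric", ssdnaMass = "numeric",
                        ssdnaCenter = "numeric", kOffT = "numeric",
                        diffRatio = "numeric", film = "FilmModel",
                        odTarget = "numeric", gain = "numeric",
                        snr = "numeric",
                        sourceKind = "character", seed = "integer"))

setValidity("SyntheticTruth", function(object) {
    if (any(object@trueK <= 0)) return("trueK must be positive")
    if (length(object@bandCenters) != length(object@trueK) + 1L)
        return("need one band centre per species")
    if (any(diff(object@bandCenters) <= 0))
        return("band centres must increase with migration position")
    if (any(object@prLane < 0)) return("prLane must be non-negative")
    if (!object@sourceKind %in% c("autoradiograph", "phosphorimage"))
        return("sourceKind must be autoradiograph or phosphorimage")
    TRUE
})

#' @rdname SyntheticTruth-class
#' @param trueK,prLane,dnaMass,laneWidth,height,bandCenters,bandSigma
#'   see slot documentation.
#' @param laneSigma,bgCoef,ssdnaMass,ssdnaCenter,kOffT,diffRatio,film
#'   see slot documentation.
#' @param odTarget,snr,sourceKind,seed see slot documentation.
#' @export
syntheticTruth <- function(trueK = 0.05,
                           prLane = c(0, (0.1 / trueK[1L]) *
                                          100^(0:5 / 5)),
                           dnaMass = 1000,
                           laneWidth = 30,
                           height = 180 + 140 * length(trueK),
                           bandCenters = 90 + 140 * seq(0, length(trueK)),
                           bandSigma = 8, laneSigma = laneWidth / 5,
                           bgCoef = c(0.3, 5e-4, 1.5e-3),
                           ssdnaMass = 0, ssdnaCenter = 160,
                           kOffT = 0.1, diffRatio = 1.5,
                           film = FilmModel(0.06, 1.6), odTarget = 1.4,
                           gain = NA_real_, snr = 30,
                           sourceKind = "autoradiograph", seed = 1L) {
    new("SyntheticTruth", trueK = trueK, prLane = prLane,
        dnaMass = dnaMass, laneWidth = laneWidth, height = height,
        bandCenters = bandCenters, bandSigma = bandSigma,
        laneSigma = laneSigma, bgCoef = bgCoef, ssdnaMass = ssdnaMass,
        ssdnaCenter = ssdnaCenter, kOffT = kOffT, diffRatio = diffRatio,
        film = film, odTarget = odTarget, gain = as.numeric(gain),
        snr = snr, sourceKind = sourceKind, seed = as.integer(seed))
}

setMethod("show", "SyntheticTruth", function(object) {
    cat(sprintf(
        "SyntheticTruth: %d lanes x %d bands, K = %s 1/nM, kOff*T = %g, %s\n",
        length(object@prLane), length(object@bandCenters),
        paste(signif(object@trueK, 4), collapse = ", "), object@kOffT,
        object@sourceKind))
})

# noiseless per-lane density along the migration axis (mass per px)
.laneDensity <- function(truth, masses, yPos) {
    ctr <- truth@bandCenters
    sigD <- truth@bandSigma
    dens <- masses[1L] * stats::dnorm(yPos, ctr[1L], sigD)
    dD <- sigD^2 / 2
    for (j in seq_along(truth@trueK)) {       # species j: j proteins bound
        if (masses[j + 1L] <= 0) next
        if (truth@kOffT > 0) {
            par <- SmearSimParams(dD = dD, dPrD = dD / truth@diffRatio,
                                  vD = ctr[j], vPrD = ctr[j + 1L],
                                  Tend = 1, kOff = truth@kOffT,
                                  c0D = 0, c0PrD = masses[j + 1L],
                                  grid = yPos)
            comp <- suppressWarnings(simulateLane(par, nQuad = 128L))
            dens <- dens + comp@dna + comp@complex
        } else {
            dens <- dens + masses[j + 1L] *
                stats::dnorm(yPos, ctr[j + 1L], sigD / sqrt(truth@diffRatio))
        }
    }
    if (truth@ssdnaMass > 0)
        dens <- dens + truth@ssdnaMass *
            stats::dnorm(yPos, truth@ssdnaCenter, sigD)
    dens
}

#' Generate a synthetic EMSA scan with ground truth
#'
#' Renders per-lane equilibrium band masses (from [equilibriumFractions()])
#' as separable Gaussians, adds the dissociation smear via [simulateLane()],
#' an optional constant ssDNA band, and an affine background; applies the
#' saturating film law in the forward direction, converts optical density to
#' 16-bit scanner gray values through the inverse of a linear step tablet
#' (darker = lower gray), adds Gaussian scanner noise in gray space where
#' real noise enters, and quantizes.  Deterministic given `truth@seed`.
#'
#' @param truth a [SyntheticTruth-class].
#' @return list with `scan` (integer gray matrix, row 1 at image top),
#'   `tabletImage` (step-tablet strip image), `tabletOD` (certified step
#'   ODs), `tabletRects` (step rectangles for [tabletFromImage()]),
#'   `laneBoundaries`, `bgLeft`/`bgRight` (flat-zone positions),
#'   `trueMasses` (lanes x species equilibrium masses) and `truth`.
#' @export
generateEMSA <- function(truth) {
    stopifnot(is(truth, "SyntheticTruth"))
    validObject(truth)
    set.seed(truth@seed)
    nl <- length(truth@prLane)
    W <- nl * truth@laneWidth
    H <- truth@height
    yPos <- seq_len(H) - 0.5                # bottom-based
    xPos <- seq_len(W) - 0.5
    cr <- matrix(0, H, W)                   # bottom-based rows
    trueMasses <- matrix(0, nl, length(truth@bandCenters))
    for (lane in seq_len(nl)) {
        fr <- equilibriumFractions(truth@trueK, truth@prLane[lane])
        masses <- truth@dnaMass * fr
        trueMasses[lane, ] <- masses
        dens <- .laneDensity(truth, masses, yPos)
        ctrX <- (lane - 0.5) * truth@laneWidth
        gx <- stats::dnorm(xPos, ctrX, truth@laneSigma)
        # wells are narrower than the lane pitch: keep a 3 px margin so
        # neighbouring tracks never touch
        cols <- which(xPos >= (lane - 1) * truth@laneWidth + 3 &
                      xPos < lane * truth@laneWidth - 3)
        cr[, cols] <- cr[, cols] + outer(dens, gx[cols])
    }
    bg <- truth@bgCoef[1L] +
        outer(truth@bgCoef[3L] * yPos, truth@bgCoef[2L] * xPos, "+")
    cr <- cr + bg
    cr <- cr[H:1, , drop = FALSE]           # to scanner orientation (top row 1)

    film <- truth@film
    dOD <- film@odMax - film@odMin
    if (truth@sourceKind == "autoradiograph") {
        gain <- if (is.finite(truth@gain)) truth@gain else
            -log(1 - (truth@odTarget - film@odMin) / dOD) / max(cr)
        od <- film@odMin + dOD * (1 - exp(-gain * pmin(cr, 5 / gain)))
        gray <- 62000 - 28000 * od
    } else {
        gain <- if (is.finite(truth@gain)) truth@gain else 30000 / max(cr)
        gray <- cr * gain
    }
    sigma <- (max(gray) - min(gray)) / truth@snr
    scan <- round(gray + stats::rnorm(length(gray), 0, sigma))
    scan <- matrix(pmin(pmax(scan, 0), 65535), nrow(gray), ncol(gray))

    # step-tablet strip: 9 steps, OD 0 to 2
    tabletOD <- seq(0, 2, by = 0.25)
    stepW <- 24L; tabH <- 40L
    tabletGray <- 62000 - 28000 * tabletOD
    tab <- matrix(rep(tabletGray, each = tabH * stepW),
                  tabH, stepW * length(tabletOD))
    tab <- round(tab + stats::rnorm(length(tab), 0, sigma))
    tab <- matrix(pmin(pmax(tab, 0), 65535), nrow(tab), ncol(tab))
    tabletRects <- lapply(seq_along(tabletOD), function(i)
        c((i - 1L) * stepW + 3, 4, i * stepW - 3, tabH - 4))

    ctr <- truth@bandCenters
    list(scan = scan, tabletImage = tab, tabletOD = tabletOD,
         tabletRects = tabletRects,
         laneBoundaries = seq(0, W, by = truth@laneWidth),
         bgLeft = ctr[1L] - 4 * truth@bandSigma - 5,
         bgRight = ctr[length(ctr)] + 4 * truth@bandSigma + 5,
         trueMasses = trueMasses, truth = truth)
}

#' Measure a step tablet from its scanned image
#'
#' Each step's gray value is the mean over a user-supplied rectangle inside
#' the step (same corner-pair syntax as artifact masks), paired with the
#' certified OD list.
#'
#' @param img numeric gray matrix of the scanned tablet strip.
#' @param rects list of `c(x0, y0, x1, y1)` rectangles, one per step.
#' @param od certified optical densities, one per step.
#' @return a [StepTablet-class].
#' @export
tabletFromImage <- function(img, rects, od) {
    stopifnot(length(rects) == length(od))
    gray <- vapply(rects, function(rect) {
        cells <- .rectCells(rect, nrow(img), ncol(img))
        mean(img[cells$rows, cells$cols])
    }, numeric(1))
    StepTablet(gray, od)
}
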