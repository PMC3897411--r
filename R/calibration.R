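#' Map scanner gray values to optical densities
#'
#' Piecewise-linear interpolation through the step-tablet (gray, OD) pairs.
#' Gray values outside the tablet range are extrapolated linearly from the
#' nearest segment and the result is then clamped to the tablet's OD range,
#' so a slightly over- or under-exposed pixel never acquires an OD the
#' tablet cannot certify.
#'
#' @param gray numeric vector or matrix of raw gray values.
#' @param tablet a [StepTablet-class].
#' @return optical densities, same shape as `gray`.
#' @examples
#' tab <- StepTablet(c(0, 100), c(0, 1))
#' grayToOD(c(0, 50, 100), tab)
#' @export
grayToOD <- function(gray, tablet) {
    stopifnot(is(tablet, "StepTablet"))
    validObject(tablet)
    g <- tablet@gray
    o <- tablet@od
    x <- as.numeric(gray)
    if (anyNA(x) || any(!is.finite(x)))
        stop("gray values must be finite")
    od <- stats::approx(g, o, xout = x, rule = 2)$y
    # rule = 2 clamps; replace the clamped ends by linear extrapolation,
    # then clamp to the tablet's OD range
    n <- length(g)
    lo <- x < g[1L]
    if (any(lo)) {
        s <- (o[2L] - o[1L]) / (g[2L] - g[1L])
        od[lo] <- o[1L] + s * (x[lo] - g[1L])
    }
    hi <- x > g[n]
    if (any(hi)) {
        s <- (o[n] - o[n - 1L]) / (g[n] - g[n - 1L])
        od[hi] <- o[n] + s * (x[hi] - g[n])
    }
    od <- pmin(pmax(od, min(o)), max(o))
    if (is.matrix(gray)) dim(od) <- dim(gray)
    od
}

#' Forward film law: relative concentration to optical density
#'
#' The developed density of an autoradiographic film saturates with
#' exposure: OD(E) = odMin + (odMax - odMin) * (1 - exp(-E)), with E the
#' exposure in units absorbing the film speed.  This is the forward model
#' whose inversion underlies [odToRelativeConcentration()]; it is exported
#' for simulation and round-trip testing.
#'
#' @param cr relative concentration (exposure), >= 0.
#' @param film a [FilmModel-class].
#' @return optical densities in [odMin, odMax).
#' @export
relativeConcentrationToOD <- function(cr, film) {
    stopifnot(is(film, "FilmModel"))
    validObject(film)
    film@odMin + (film@odMax - film@odMin) * (1 - exp(-cr))
}

#' Invert the film saturation law
#'
#' Maps optical densities to relative concentrations of radioactive
#' material: CR = -ln((odMax - OD) / (odMax - odMin)).  The result is 0 at
#' odMin, strictly increasing, and diverges as OD approaches odMax.  ODs
#' below odMin (background fluctuations on unexposed film) clamp to odMin;
#' ODs within `eps` of odMax (saturated pixels) clamp to odMax - eps with a
#' warning, keeping the pipeline running on overexposed regions.
#'
#' @param od numeric vector or matrix of optical densities.
#' @param film a [FilmModel-class].
#' @param eps saturation guard below odMax (default 1e-3 OD).
#' @return relative concentrations, same shape as `od`.
#' @examples
#' film <- FilmModel(0.06, 1.6)
#' odToRelativeConcentration(c(0.06, 0.2, 0.8, 1.5), film)
#' @export
odToRelativeConcentration <- function(od, film, eps = 1e-3) {
    stopifnot(is(film, "FilmModel"))
    validObject(film)
    x <- as.numeric(od)
    if (anyNA(x) || any(!is.finite(x)))
        stop("optical densities must be finite")
    lo <- film@odMin
    hi <- film@odMax
    sat <- x >= hi - eps
    if (any(sat)) {
        warning(sprintf("%d OD value(s) within %g of saturation (%g); clamped",
                        sum(sat), eps, hi))
        x[sat] <- hi - eps
    }
    x[x < lo] <- lo
    cr <- -log((hi - x) / (hi - lo))
    if (is.matrix(od)) dim(cr) <- dim(od)
    cr
}

#' Calibrate a raw scan to relative concentrations
#'
#' An autoradiograph is mapped gray -> OD (step tablet) -> relative
#' concentration (film inversion); a stained gel stops at ODs, which are
#' linear in amount for gels; a phosphorimage stores counts that already are
#' relative concentrations.  Both scanner polarities are accepted: whether a
#' darker (denser) region is stored as a low or a high gray value is read off
#' the sign of the tablet's gray-to-OD slope.  For phosphorimages, counts
#' pass through unchanged.
#'
#' @param raw numeric matrix of raw gray values (or counts).
#' @param sourceKind "autoradiograph", "gel" or "phosphorimage".
#' @param tablet a [StepTablet-class]; required for autoradiograph and gel.
#' @param film a [FilmModel-class]; required for autoradiograph.
#' @param eps saturation guard passed to [odToRelativeConcentration()].
#' @return A [CalibratedImage-class] with an all-TRUE mask.
#' @examples
#' raw <- matrix(runif(100, 0, 1000), 10, 10)
#' calibrateImage(raw, "phosphorimage")
#' @export
calibrateImage <- function(raw, sourceKind = c("autoradiograph", "gel",
                                               "phosphorimage"),
                           tablet = NULL, film = NULL, eps = 1e-3) {
    sourceKind <- match.arg(sourceKind)
    if (!is.matrix(raw) || !is.numeric(raw))
        stop("raw must be a numeric matrix")
    if (sourceKind %in% c("autoradiograph", "gel") && is.null(tablet))
        stop("sourceKind '", sourceKind, "' requires a step tablet")
    if (sourceKind == "autoradiograph" && is.null(film))
        stop("an autoradiograph requires a film model")
    intens <- switch(sourceKind,
        phosphorimage = raw,
        gel = grayToOD(raw, tablet),
        autoradiograph = odToRelativeConcentration(grayToOD(raw, tablet),
                                                   film, eps = eps))
    intens <- pmax(intens, 0)
    dim(intens) <- dim(raw)
    new("CalibratedImage", intensities = intens,
        mask = matrix(TRUE, nrow(raw), ncol(raw)), sourceKind = sourceKind)
}

#' @describeIn CalibratedImage-class intensity matrix accessor.
#' @param object,x a `CalibratedImage`.
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname CalibratedImage-class
#' @export
setMethod("intensities", "CalibratedImage", function(x) x@intensities)

#' @describeIn CalibratedImage-class validity-mask accessor.
#' @export
setGeneric("pixelMask", function(x) standardGeneric("pixelMask"))

#' @rdname CalibratedImage-class
#' @export
setMethod("pixelMask", "CalibratedImage", function(x) x@mask)

setMethod("show", "CalibratedImage", function(object) {
    d <- dim(object@intensities)
    cat(sprintf("CalibratedImage (%s): %d x %d px, %d masked\n",
                object@sourceKind, d[1L], d[2L], sum(!object@mask)))
    v <- object@intensities[object@mask]
    if (length(v))
        cat(sprintf("  intensity range [%.4g, %.4g]\n", min(v), max(v)))
})

setMethod("show", "StepTablet", function(object) {
    cat(sprintf("StepTablet: %d steps, gray [%g, %g] -> OD [%g, %g]\n",
                length(object@gray), min(object@gray), max(object@gray),
                min(object@od), max(object@od)))
})

setMethod("show", "FilmModel", function(object) {
    cat(sprintf("FilmModel: odMin = %g, odMax = %g\n",
                object@odMin, object@odMax))
})
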