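#' @import methods
NULL

#' Step-tablet calibration curve
#'
#' Holds the measured mean gray value and the certified optical density (OD)
#' of each step of a calibrated step tablet scanned alongside the film or
#' gel.  The pairs define the piecewise-linear gray-to-OD map used during
#' calibration.  Gray values may run in either direction (some scanners store
#' darker pixels as lower gray values, some as higher); polarity is inferred
#' from the sign of the gray-to-OD slope.
#'
#' @slot gray numeric vector of mean scanner gray values, one per step.
#' @slot od numeric vector of optical densities, one per step.
#'
#' @seealso [StepTablet()], [grayToOD()]
#' @export
setClass("StepTablet", representation(gray = "numeric", od = "numeric"))

setValidity("StepTablet", function(object) {
    g <- object@gray; o <- object@od
    if (length(g) != length(o))
        return("gray and od must have equal length")
    if (length(g) < 2L)
        return("a step tablet needs at least 2 steps")
    if (anyNA(g) || anyNA(o) || any(!is.finite(g)) || any(!is.finite(o)))
        return("gray and od must be finite")
    if (anyDuplicated(g))
        return("duplicate gray values in step tablet")
    ord <- order(g)
    d <- diff(o[ord])
    if (!(all(d > 0) || all(d < 0)))
        return("od must be strictly monotone in gray")
    TRUE
})

#' Construct a step tablet
#'
#' @param gray numeric, mean gray value of each step.
#' @param od numeric, certified optical density of each step.
#' @return A [StepTablet-class] object with steps sorted by gray value.
#' @examples
#' tab <- StepTablet(gray = c(0, 100), od = c(0, 1))
#' grayToOD(50, tab)
#' @export
StepTablet <- function(gray, od) {
    ord <- order(gray)
    new("StepTablet", gray = as.numeric(gray)[ord], od = as.numeric(od)[ord])
}

#' Autoradiographic film response model
#'
#' The developed film has a minimum attainable optical density (fog level of
#' an unexposed film) and a maximum attainable density (film exposed to broad
#' daylight).  Between the two the response to exposure saturates
#' exponentially, which is what makes raw autoradiograph densities non-linear
#' in the amount of radioactive material.
#'
#' @slot odMin numeric(1), OD of the unexposed developed film.
#' @slot odMax numeric(1), OD at full saturation.
#' @seealso [FilmModel()], [odToRelativeConcentration()]
#' @export
setClass("FilmModel", representation(odMin = "numeric", odMax = "numeric"))

setValidity("FilmModel", function(object) {
    if (length(object@odMin) != 1L || length(object@odMax) != 1L)
        return("odMin and odMax must be scalars")
    if (!is.finite(object@odMin) || !is.finite(object@odMax))
        return("odMin and odMax must be finite")
    if (!(object@odMin >= 0 && object@odMin < object@odMax))
        return("need 0 <= odMin < odMax")
    TRUE
})

#' Construct a film model
#'
#' Defaults correspond to Kodak Biomax MR film.
#'
#' @param odMin minimum attainable optical density (default 0.06).
#' @param odMax maximum attainable optical density (default 1.6).
#' @return A [FilmModel-class] object.
#' @export
FilmModel <- function(odMin = 0.06, odMax = 1.6) {
    new("FilmModel", odMin = as.numeric(odMin), odMax = as.numeric(odMax))
}

#' Calibrated image
#'
#' A scanned image after conversion of raw gray values to relative
#' concentrations (quantities proportional to the local amount of labelled
#' material), together with a per-pixel validity mask used to exclude
#' artifacts from all downstream averages and integrals.
#'
#' Matrix rows run top to bottom as scanned; lane profiles are reported
#' bottom-to-top because the free-DNA band sits at the image bottom.
#'
#' @slot intensities numeric matrix of relative concentrations.
#' @slot mask logical matrix, TRUE where the pixel is valid.
#' @slot sourceKind one of "autoradiograph", "gel", "phosphorimage".
#' @seealso [calibrateImage()], [smoothImage()], [maskArtifacts()]
#' @export
setClass("CalibratedImage",
         representation(intensities = "matrix", mask = "matrix",
                        sourceKind = "character"))

setValidity("CalibratedImage", function(object) {
    if (!identical(dim(object@intensities), dim(object@mask)))
        return("intensities and mask must have identical dimensions")
    if (!is.logical(object@mask))
        return("mask must be logical")
    if (!object@sourceKind %in% c("autoradiograph", "gel", "phosphorimage"))
        return("sourceKind must be autoradiograph, gel or phosphorimage")
    v <- object@intensities[object@mask]
    if (length(v) && (anyNA(v) || any(!is.finite(v))))
        return("unmasked intensities must be finite")
    TRUE
})

#' Lane layout
#'
#' Vertical boundaries that partition the image width into migration lanes.
#' Boundary i and i+1 delimit lane i as the half-open column interval
#' [b_i, b_{i+1}) in 0-based continuous x coordinates (pixel column j covers
#' [j-1, j)).
#'
#' @slot boundaries strictly increasing numeric vector, length nLanes + 1.
#' @seealso [detectLanes()], [laneProfiles()]
#' @export
setClass("LaneLayout", representation(boundaries = "numeric"))

setValidity("LaneLayout", function(object) {
    b <- object@boundaries
    if (length(b) < 2L) return("need at least 2 boundaries (1 lane)")
    if (any(diff(b) <= 0)) return("boundaries must be strictly increasing")
    if (any(!is.finite(b))) return("boundaries must be finite")
    TRUE
})

#' @rdname LaneLayout-class
#' @param boundaries numeric vector of lane boundaries.
#' @export
LaneLayout <- function(boundaries) new("LaneLayout",
                                       boundaries = as.numeric(boundaries))

#' Per-lane average intensity profiles
#'
#' One column per lane; row r is the mean unmasked intensity of the lane at
#' migration position r, with row 1 the image BOTTOM (free-DNA side).  The
#' continuous migration coordinate x is 0-based: row r covers [r-1, r).
#' After background subtraction the subtracted baseline is kept in
#' `background` so the operation is invertible, and the two outer background
#' lines (which double as the outer integration limits of the first and last
#' band) are stored in `outer`.
#'
#' @slot values numeric matrix, positions x lanes.
#' @slot background numeric matrix, same shape, the subtracted baseline.
#' @slot outer numeric(2) or numeric(0): outer integration limits.
#' @seealso [laneProfiles()], [subtractBackground()]
#' @export
setClass("LaneProfileSet",
         representation(values = "matrix", background = "matrix",
                        outer = "numeric"))

setValidity("LaneProfileSet", function(object) {
    if (!identical(dim(object@values), dim(object@background)))
        return("values and background must have identical dimensions")
    if (!length(object@outer) %in% c(0L, 2L))
        return("outer must be empty or length 2")
    if (length(object@outer) == 2L && diff(object@outer) <= 0)
        return("outer limits must be increasing")
    TRUE
})

#' Band boundary uncertainty interval
#'
#' The division line between two adjacent bands cannot be placed exactly in
#' the presence of smear; it is bracketed by a lower and an upper bound.
#' Half of the smear integrated between the bounds is assigned to each
#' adjacent band, and the half-smear is the handle for the smear error.
#'
#' @slot lower numeric(1), migration position of the lower bound.
#' @slot upper numeric(1), migration position of the upper bound
#'   (lower <= upper).
#' @seealso [findBound()], [assignBands()]
#' @export
setClass("BoundaryPair", representation(lower = "numeric", upper = "numeric"))

setValidity("BoundaryPair", function(object) {
    if (!is.finite(object@lower) || !is.finite(object@upper))
        return("bounds must be finite")
    if (object@lower > object@upper)
        return("lower bound must not exceed upper bound")
    TRUE
})

#' @rdname BoundaryPair-class
#' @param lower,upper migration positions bracketing the division line.
#' @export
BoundaryPair <- function(lower, upper)
    new("BoundaryPair", lower = as.numeric(lower), upper = as.numeric(upper))

#' Band intensity table
#'
#' Integrated band intensities per lane and band, the smear integrated inside
#' each boundary-pair interval, and the band extents used for background
#' error estimation.  Band j of a lane integrates the profile from the upper
#' bound of interface j-1 to the lower bound of interface j, plus half the
#' smear of each flanking interface; the outer background lines close the
#' first and last band.
#'
#' @slot intensity numeric matrix, lanes x bands.
#' @slot smear numeric matrix, lanes x interfaces (bands - 1 columns).
#' @slot extents numeric matrix, (bands x 2): nominal band start/end along the
#'   migration axis (interface midpoints; shared across lanes).
#' @slot interfaces numeric matrix, (interfaces x 2): the lower/upper bounds
#'   of each boundary pair.
#' @slot laneSums numeric vector of per-lane totals between the outer lines.
#' @seealso [bandTable()], [assignBands()], [stepwiseK()]
#' @export
setClass("BandTable",
         representation(intensity = "matrix", smear = "matrix",
                        extents = "matrix", interfaces = "matrix",
                        laneSums = "numeric"))

setValidity("BandTable", function(object) {
    nb <- ncol(object@intensity)
    if (ncol(object@smear) != max(nb - 1L, 0L))
        return("smear must have bands - 1 columns")
    if (nrow(object@smear) != nrow(object@intensity))
        return("intensity and smear must have equal lane counts")
    if (nrow(object@extents) != nb || ncol(object@extents) != 2L)
        return("extents must be bands x 2")
    if (length(object@laneSums) != nrow(object@intensity))
        return("laneSums must have one entry per lane")
    TRUE
})

#' Per-lane stepwise equilibrium constant estimate
#'
#' @slot lane integer lane index (1-based).
#' @slot k numeric(1), stepwise association constant (1/molar units of `pr`).
#' @slot ratio numeric(1), band intensity ratio I(band j+1)/I(band j).
#' @slot pr numeric(1), protein concentration in the lane (molar).
#' @slot sigmaBg numeric(1), std of the non-uniform-background error (same
#'   units as k; NA when no neighbour lane exists).
#' @slot sigmaSmear numeric(1), std of the smear error (same units as k).
#' @seealso [stepwiseK()], [backgroundError()], [smearError()], [summarizeK()]
#' @export
setClass("LaneKEstimate",
         representation(lane = "integer", k = "numeric", ratio = "numeric",
                        pr = "numeric", sigmaBg = "numeric",
                        sigmaSmear = "numeric"))

#' Averaged equilibrium constant with error decomposition
#'
#' Averages per-lane stepwise constants over user-selected lanes and
#' decomposes the uncertainty: the standard error of the mean measures the
#' random part (background non-uniformity plus technical error); smear errors
#' are treated as correlated over lanes, hence systematic, and add in
#' quadrature to the SEM.
#'
#' @slot meanK mean stepwise constant over the selected lanes.
#' @slot sem standard error of the mean (sample std / sqrt(n)).
#' @slot sigmaBgAvg averaged background error, sqrt(sum sigmaBg_i^2)/n.
#' @slot sigmaSmearAvg averaged smear error, (sum sigmaSmear_i)/n (correlated).
#' @slot sigmaTech technical contribution, sqrt(max(0, sem^2 - sigmaBgAvg^2)).
#' @slot sigmaTotal total std, sqrt(sem^2 + sigmaSmearAvg^2).
#' @slot selectedLanes integer vector of lanes used.
#' @slot normalizedK meanK / reference meanK (NA without a reference).
#' @slot normalizedStd std of normalizedK by relative-variance addition.
#' @seealso [summarizeK()]
#' @export
setClass("KSummary",
         representation(meanK = "numeric", sem = "numeric",
                        sigmaBgAvg = "numeric", sigmaSmearAvg = "numeric",
                        sigmaTech = "numeric", sigmaTotal = "numeric",
                        selectedLanes = "integer",
                        normalizedK = "numeric", normalizedStd = "numeric"))

#' Dissociation-smear simulation parameters
#'
#' Physical parameters of the one-dimensional electrophoresis model used to
#' simulate the lane profile of a dissociating protein-DNA complex.  A
#' complex that dissociates at time t has migrated with the complex velocity
#' until t and with the (faster) free-DNA velocity afterwards, and has
#' accumulated the diffusion of each state over the time spent in it;
#' re-association during the run is neglected.  Units are arbitrary but must
#' be mutually consistent.
#'
#' @slot dD,dPrD diffusion coefficients of DNA and complex (length^2/time).
#' @slot vD,vPrD electrophoretic velocities of DNA and complex (length/time).
#' @slot Tend run duration.
#' @slot kOff dissociation rate constant (1/time).
#' @slot c0D,c0PrD initial amounts of free DNA and complex.
#' @slot grid migration positions at which profiles are evaluated.
#' @seealso [SmearSimParams()], [simulateLane()]
#' @export
setClass("SmearSimParams",
         representation(dD = "numeric", dPrD = "numeric", vD = "numeric",
                        vPrD = "numeric", Tend = "numeric", kOff = "numeric",
                        c0D = "numeric", c0PrD = "numeric", grid = "numeric"))

setValidity("SmearSimParams", function(object) {
    if (object@dD <= 0 || object@dPrD <= 0)
        return("diffusion coefficients must be positive")
    if (object@Tend <= 0) return("run duration must be positive")
    if (object@kOff < 0) return("kOff must be non-negative")
    if (object@c0D < 0 || object@c0PrD < 0)
        return("initial amounts must be non-negative")
    if (object@vD == object@vPrD)
        return("vD and vPrD must differ (distinct bands)")
    if (length(object@grid) < 2L || any(diff(object@grid) <= 0))
        return("grid must be increasing with >= 2 points")
    TRUE
})

#' @rdname SmearSimParams-class
#' @param dD,dPrD,vD,vPrD,Tend,kOff,c0D,c0PrD,grid see slot documentation.
#' @export
SmearSimParams <- function(dD, dPrD, vD, vPrD, Tend, kOff,
                           c0D = 1, c0PrD = 1, grid) {
    new("SmearSimParams", dD = as.numeric(dD), dPrD = as.numeric(dPrD),
        vD = as.numeric(vD), vPrD = as.numeric(vPrD), Tend = as.numeric(Tend),
        kOff = as.numeric(kOff), c0D = as.numeric(c0D),
        c0PrD = as.numeric(c0PrD), grid = as.numeric(grid))
}
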