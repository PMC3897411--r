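# Summed-area-table box sums; window of half-width r, shrunk at borders.
.boxSum <- function(m, r) {
    nr <- nrow(m); nc <- ncol(m)
    S <- rbind(0, apply(m, 2L, cumsum))
    S <- cbind(0, t(apply(S, 1L, cumsum)))
    i1 <- pmax(seq_len(nr) - r, 1L); i2 <- pmin(seq_len(nr) + r, nr)
    j1 <- pmax(seq_len(nc) - r, 1L); j2 <- pmin(seq_len(nc) + r, nc)
    out <- S[cbind(rep(i2 + 1L, nc), rep(j2 + 1L, each = nr))] -
        S[cbind(rep(i1, nc), rep(j2 + 1L, each = nr))] -
        S[cbind(rep(i2 + 1L, nc), rep(j1, each = nr))] +
        S[cbind(rep(i1, nc), rep(j1, each = nr))]
    matrix(out, nr, nc)
}

#' Smooth a calibrated image with a 5 x 5 running-average filter
#'
#' Reduces film grain and scanner noise before profiling.  Each valid pixel
#' is replaced by the mean of the valid pixels in its 5 x 5 neighbourhood;
#' at the borders the window shrinks to its in-image part, and masked pixels
#' are excluded from the mean (the window renormalizes) rather than treated
#' as zero, so integrals are not biased near artifacts.
#'
#' @param img a [CalibratedImage-class] (or a bare numeric matrix of raw
#'   gray values, smoothed before calibration as scans usually are), at
#'   least 5 x 5.
#' @return the smoothed image, same type as the input; the mask is
#'   unchanged.
#' @export
smoothImage <- function(img) {
    if (is.matrix(img) && is.numeric(img)) {
        if (nrow(img) < 5L || ncol(img) < 5L)
            stop("image must be at least 5 x 5 for the running-average filter")
        return(.boxSum(img, 2L) /
               .boxSum(matrix(1, nrow(img), ncol(img)), 2L))
    }
    stopifnot(is(img, "CalibratedImage"))
    v <- img@intensities; msk <- img@mask
    if (nrow(v) < 5L || ncol(v) < 5L)
        stop("image must be at least 5 x 5 for the running-average filter")
    vm <- v; vm[!msk] <- 0
    num <- .boxSum(vm, 2L)
    den <- .boxSum(msk + 0, 2L)
    out <- v
    ok <- msk & den > 0
    out[ok] <- num[ok] / den[ok]
    new("CalibratedImage", intensities = out, mask = msk,
        sourceKind = img@sourceKind)
}

# rectangles: list of c(x0, y0, x1, y1) corner pairs, x = column, y = row,
# continuous 0-based coordinates (pixel column j covers [j-1, j)).
.rectCells <- function(rect, nr, nc) {
    x <- sort(c(rect[1L], rect[3L])); y <- sort(c(rect[2L], rect[4L]))
    cols <- which(seq_len(nc) - 0.5 >= x[1L] & seq_len(nc) - 0.5 <= x[2L])
    rows <- which(seq_len(nr) - 0.5 >= y[1L] & seq_len(nr) - 0.5 <= y[2L])
    list(rows = rows, cols = cols)
}

#' Mask artifact rectangles
#'
#' Flags every pixel inside the given rectangles (scratches, development
#' spots) as invalid; masked pixels are excluded from all downstream
#' averages and integrals.  Each rectangle is given by two opposite corners
#' in image coordinates (x = column, y = row, matrix row 1 at top).
#'
#' @param img a [CalibratedImage-class].
#' @param rectangles list of numeric `c(x0, y0, x1, y1)` corner pairs.
#' @return the image with an updated mask.
#' @export
maskArtifacts <- function(img, rectangles) {
    stopifnot(is(img, "CalibratedImage"))
    if (length(rectangles) == 0L) return(img)
    msk <- img@mask
    nr <- nrow(msk); nc <- ncol(msk)
    for (rect in rectangles) {
        if (length(rect) != 4L || any(!is.finite(rect)))
            stop("each rectangle must be c(x0, y0, x1, y1)")
        if (abs(rect[1L] - rect[3L]) == 0 || abs(rect[2L] - rect[4L]) == 0) {
            warning("zero-area artifact rectangle ignored")
            next
        }
        if (min(rect[c(1L, 3L)]) < 0 || max(rect[c(1L, 3L)]) > nc ||
            min(rect[c(2L, 4L)]) < 0 || max(rect[c(2L, 4L)]) > nr)
            stop("artifact rectangle outside the image")
        cells <- .rectCells(rect, nr, nc)
        msk[cells$rows, cells$cols] <- FALSE
    }
    new("CalibratedImage", intensities = img@intensities, mask = msk,
        sourceKind = img@sourceKind)
}

# running mean of width w (shrinking at the ends)
.runMean <- function(x, w) {
    if (w <= 1L) return(x)
    r <- (w - 1L) %/% 2L
    cs <- c(0, cumsum(x))
    n <- length(x)
    i1 <- pmax(seq_len(n) - r, 1L); i2 <- pmin(seq_len(n) + r, n)
    (cs[i2 + 1L] - cs[i1]) / (i2 - i1 + 1L)
}

#' Detect lane boundaries
#'
#' Lanes are separated by the gaps between migration tracks, which show up
#' as local minima of the column-sum intensity profile.  The column sums
#' (over valid pixels) are smoothed with a running mean of width
#' `width / (4 * nLanes)`, and the `nLanes - 1` deepest local minima at
#' least `width / (2 * nLanes)` apart become the inner boundaries; the outer
#' boundaries sit at the image edges.  Detection is invariant to global
#' intensity scaling.  An explicit `boundaries` vector overrides detection.
#'
#' @param img a [CalibratedImage-class].
#' @param nLanes number of lanes (>= 1).
#' @param boundaries optional explicit boundary positions (manual override);
#'   outer edges are added if absent.
#' @return a [LaneLayout-class].
#' @export
detectLanes <- function(img, nLanes, boundaries = NULL) {
    stopifnot(is(img, "CalibratedImage"), nLanes >= 1)
    nc <- ncol(img@intensities)
    if (!is.null(boundaries)) {
        b <- sort(as.numeric(boundaries))
        if (length(b) == nLanes - 1L) b <- c(0, b, nc)
        if (length(b) != nLanes + 1L)
            stop("boundaries must have nLanes - 1 or nLanes + 1 entries")
        return(LaneLayout(b))
    }
    if (nLanes == 1L) return(LaneLayout(c(0, nc)))
    v <- img@intensities; v[!img@mask] <- 0
    colsum <- colSums(v)
    w <- max(1L, round(nc / (4 * nLanes)))
    s <- .runMean(colsum, w)
    n <- length(s)
    cand <- which(diff(sign(diff(s))) > 0) + 1L       # strict local minima
    cand <- cand[cand > 1L & cand < n]
    if (length(cand) == 0L)
        stop("lane detection failed: no column-profile minima; ",
             "specify lane boundaries manually")
    cand <- cand[order(s[cand])]                       # deepest first
    minSep <- nc / (2 * nLanes)
    chosen <- numeric(0)
    for (j in cand) {
        if (all(abs(j - chosen) >= minSep)) chosen <- c(chosen, j)
        if (length(chosen) == nLanes - 1L) break
    }
    if (length(chosen) < nLanes - 1L)
        stop("lane detection failed: found ", length(chosen),
             " usable minima for ", nLanes - 1L,
             " boundaries; specify lane boundaries manually")
    LaneLayout(c(0, sort(chosen) - 0.5, nc))
}

#' @describeIn LaneLayout-class number of lanes.
#' @param x a `LaneLayout`.
#' @export
setGeneric("nLanes", function(x) standardGeneric("nLanes"))

#' @rdname LaneLayout-class
#' @export
setMethod("nLanes", "LaneLayout", function(x) length(x@boundaries) - 1L)

#' @describeIn LaneLayout-class boundary positions.
#' @export
setGeneric("laneBoundaries", function(x) standardGeneric("laneBoundaries"))

#' @rdname LaneLayout-class
#' @export
setMethod("laneBoundaries", "LaneLayout", function(x) x@boundaries)

setMethod("show", "LaneLayout", function(object) {
    cat(sprintf("LaneLayout: %d lanes, boundaries %s\n", nLanes(object),
                paste(signif(object@boundaries, 5), collapse = ", ")))
})

.laneCols <- function(layout, lane, nc) {
    b <- layout@boundaries
    centers <- seq_len(nc) - 0.5
    which(centers >= b[lane] & centers < b[lane + 1L])
}

#' Average lane intensity profiles
#'
#' For each lane, the mean valid intensity of every image row, reported
#' bottom-to-top (profile row 1 = image bottom, the free-DNA side).  Rows in
#' which every lane pixel is masked are filled by linear interpolation from
#' the neighbouring rows.
#'
#' @param img a [CalibratedImage-class] (typically smoothed).
#' @param layout a [LaneLayout-class].
#' @return a [LaneProfileSet-class] with a zero background model.
#' @export
laneProfiles <- function(img, layout) {
    stopifnot(is(img, "CalibratedImage"), is(layout, "LaneLayout"))
    v <- img@intensities; msk <- img@mask
    nr <- nrow(v); nc <- ncol(v)
    nl <- nLanes(layout)
    if (max(layout@boundaries) > nc + 1e-9)
        stop("lane layout exceeds image width")
    prof <- matrix(NA_real_, nr, nl)
    for (lane in seq_len(nl)) {
        cols <- .laneCols(layout, lane, nc)
        if (length(cols) == 0L) stop("lane ", lane, " contains no columns")
        sub <- v[, cols, drop = FALSE]
        m <- msk[, cols, drop = FALSE]
        cnt <- rowSums(m)
        if (all(cnt == 0)) stop("lane ", lane, " is fully masked")
        sub[!m] <- 0
        p <- rowSums(sub) / ifelse(cnt > 0, cnt, NA)
        if (anyNA(p)) {
            ok <- which(!is.na(p))
            p <- stats::approx(ok, p[ok], xout = seq_len(nr), rule = 2)$y
        }
        prof[, lane] <- rev(p)     # bottom-to-top
    }
    new("LaneProfileSet", values = prof,
        background = matrix(0, nr, nl), outer = numeric(0))
}

#' @describeIn LaneProfileSet-class profile value matrix (positions x lanes).
#' @param x a `LaneProfileSet`.
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))

#' @rdname LaneProfileSet-class
#' @export
setMethod("profileValues", "LaneProfileSet", function(x) x@values)

#' @describeIn LaneProfileSet-class subtracted baseline matrix.
#' @export
setGeneric("backgroundModel", function(x) standardGeneric("backgroundModel"))

#' @rdname LaneProfileSet-class
#' @export
setMethod("backgroundModel", "LaneProfileSet", function(x) x@background)

#' @describeIn LaneProfileSet-class outer integration limits.
#' @export
setGeneric("outerLimits", function(x) standardGeneric("outerLimits"))

#' @rdname LaneProfileSet-class
#' @export
setMethod("outerLimits", "LaneProfileSet", function(x) x@outer)

setMethod("show", "LaneProfileSet", function(object) {
    cat(sprintf("LaneProfileSet: %d positions x %d lanes%s\n",
                nrow(object@values), ncol(object@values),
                if (length(object@outer))
                    sprintf(", outer limits [%g, %g]", object@outer[1L],
                            object@outer[2L]) else ""))
})

#' Subtract the lane background
#'
#' Three estimators of the per-lane baseline:
#' \describe{
#'   \item{double_sided}{the user marks a flat zone at the far bottom
#'     (positions below `left`) and the far top (positions above `right`) of
#'     the profiles; per lane, the baseline is the straight line through the
#'     two zone means, evaluated at every position.  Exact for any baseline
#'     affine in position.  `left` and `right` also become the outer
#'     integration limits of the first and last band.}
#'   \item{single_sided}{a constant baseline, the mean of one flat zone
#'     (below `left` or above `right`).}
#'   \item{region}{a constant baseline shared by all lanes: the mean valid
#'     intensity of an image region (for gels whose lanes never reach the
#'     background level).}
#' }
#' Negative values after subtraction are retained; clipping would bias
#' low-signal bands.
#'
#' @param profiles a [LaneProfileSet-class].
#' @param method one of "double_sided", "single_sided", "region".
#' @param left end of the bottom flat zone (migration position).
#' @param right start of the top flat zone.
#' @param img,region for `method = "region"`: the [CalibratedImage-class]
#'   and a rectangle `c(x0, y0, x1, y1)` in image coordinates.
#' @param outer optional explicit outer integration limits; defaults to
#'   `c(left, right)` for double_sided and the full profile otherwise.
#' @return a [LaneProfileSet-class] with the baseline subtracted and stored.
#' @export
subtractBackground <- function(profiles,
                               method = c("double_sided", "single_sided",
                                          "region"),
                               left = NULL, right = NULL,
                               img = NULL, region = NULL, outer = NULL) {
    stopifnot(is(profiles, "LaneProfileSet"))
    method <- match.arg(method)
    v <- profiles@values
    nr <- nrow(v); nl <- ncol(v)
    pos <- seq_len(nr) - 0.5
    bg <- matrix(0, nr, nl)
    if (method == "double_sided") {
        if (is.null(left) || is.null(right) || left >= right)
            stop("double_sided needs positions left < right")
        zl <- which(pos < left); zr <- which(pos > right)
        if (length(zl) == 0L || length(zr) == 0L)
            stop("flat zone of zero width")
        for (lane in seq_len(nl)) {
            x1 <- mean(pos[zl]); y1 <- mean(v[zl, lane])
            x2 <- mean(pos[zr]); y2 <- mean(v[zr, lane])
            slope <- (y2 - y1) / (x2 - x1)
            bg[, lane] <- y1 + slope * (pos - x1)
        }
        if (is.null(outer)) outer <- c(left, right)
    } else if (method == "single_sided") {
        if (!is.null(left) && !is.null(right))
            stop("single_sided takes exactly one of left or right")
        if (!is.null(left)) {
            z <- which(pos < left)
            if (is.null(outer)) outer <- c(left, nr)
        } else if (!is.null(right)) {
            z <- which(pos > right)
            if (is.null(outer)) outer <- c(0, right)
        } else stop("single_sided needs left or right")
        if (length(z) == 0L) stop("flat zone of zero width")
        for (lane in seq_len(nl)) bg[, lane] <- mean(v[z, lane])
    } else {
        if (is.null(img) || is.null(region))
            stop("region method needs img and region")
        cells <- .rectCells(region, nrow(img@intensities),
                            ncol(img@intensities))
        if (length(cells$rows) == 0L || length(cells$cols) == 0L)
            stop("flat zone of zero width")
        sub <- img@intensities[cells$rows, cells$cols, drop = FALSE]
        m <- img@mask[cells$rows, cells$cols, drop = FALSE]
        if (!any(m)) stop("background region fully masked")
        bg[] <- mean(sub[m])
        if (is.null(outer)) outer <- c(0, nr)
    }
    new("LaneProfileSet", values = v - bg,
        background = profiles@background + bg, outer = as.numeric(outer))
}
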