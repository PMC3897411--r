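test_that("5x5 running average: constants, impulse response, size guard", {
    cimg <- imageFrom(matrix(3.7, 20, 20))
    expect_equal(intensities(smoothImage(cimg)), matrix(3.7, 20, 20))
    imp <- matrix(0, 21, 21); imp[11, 11] <- 25
    sm <- intensities(smoothImage(imageFrom(imp)))
    expect_equal(sm[9:13, 9:13], matrix(1, 5, 5))
    expect_equal(sum(sm != 0), 25)
    expect_error(smoothImage(imageFrom(matrix(1, 4, 9))), "5 x 5")
})

test_that("masked smoothing matches a brute-force double loop", {
    set.seed(11)
    v <- matrix(rnorm(2500), 50, 50)
    msk <- matrix(runif(2500) > 0.15, 50, 50)
    sm <- smoothImage(imageFrom(v, msk))
    oracle <- v
    for (i in 1:50) for (j in 1:50) {
        if (!msk[i, j]) next
        ri <- max(1, i - 2):min(50, i + 2)
        rj <- max(1, j - 2):min(50, j + 2)
        w <- msk[ri, rj]
        oracle[i, j] <- sum(v[ri, rj][w]) / sum(w)
    }
    expect_equal(intensities(sm)[msk], oracle[msk], tolerance = 1e-12)
})

test_that("artifact rectangles mask pixels; degenerate rectangles warn", {
    img <- imageFrom(matrix(1, 30, 30))
    expect_identical(pixelMask(maskArtifacts(img, list())),
                     pixelMask(img))
    m1 <- maskArtifacts(img, list(c(5, 5, 10, 10)))
    expect_false(any(pixelMask(m1)[6:10, 6:10]))
    expect_true(all(pixelMask(m1)[1:4, ]))
    expect_warning(m2 <- maskArtifacts(img, list(c(5, 5, 5, 12))),
                   "zero-area")
    expect_identical(pixelMask(m2), pixelMask(img))
    # fully masked image: downstream averaging must refuse
    allm <- maskArtifacts(img, list(c(0, 0, 30, 30)))
    expect_error(laneProfiles(allm, LaneLayout(c(0, 30))), "masked")
})

test_that("a masked scratch leaves the lane profile near the clean one", {
    tr <- syntheticTruth(seed = 3L, prLane = rep(20, 3), snr = 1e5)
    gen <- generateEMSA(tr)
    scratch <- gen$scan
    rows <- 30:34                        # background region above the bands
    scratch[rows, 10:50] <- 65535                     # bright scratch
    tab <- tabletFromImage(gen$tabletImage, gen$tabletRects, gen$tabletOD)
    mk <- function(raw, rects) {
        img <- calibrateImage(smoothImage(raw), "autoradiograph",
                              tablet = tab, film = tr@film)
        img <- maskArtifacts(img, rects)
        laneProfiles(img, LaneLayout(gen$laneBoundaries))
    }
    clean <- profileValues(mk(gen$scan, list()))
    fixed <- profileValues(mk(scratch, list(c(6, 26, 54, 38))))
    expect_lt(max(abs(fixed - clean)), 0.05 * max(clean))
})

test_that("lane detection finds gaps, honours overrides, and fails loudly", {
    # 5 well-separated Gaussian lanes
    x <- seq_len(250) - 0.5
    g <- rowSums(vapply(seq(25, 225, by = 50), function(c)
        exp(-(x - c)^2 / (2 * 6^2)), numeric(250)))
    img <- imageFrom(matrix(rep(g, each = 100), 100, 250, byrow = FALSE) * 0 +
                     outer(rep(1, 100), g))
    lay <- detectLanes(img, 5)
    expect_equal(nLanes(lay), 5L)
    inner <- laneBoundaries(lay)[2:5]
    expect_true(all(abs(inner - c(50, 100, 150, 200)) <= 2))
    # scaling invariance
    lay2 <- detectLanes(imageFrom(intensities(img) * 1e3), 5)
    expect_identical(laneBoundaries(lay2), laneBoundaries(lay))
    # single lane and manual override
    expect_equal(laneBoundaries(detectLanes(img, 1)), c(0, 250))
    expect_equal(laneBoundaries(detectLanes(img, 2, boundaries = 130)),
                 c(0, 130, 250))
    # uniform image has no minima
    expect_error(detectLanes(imageFrom(matrix(1, 60, 60)), 3),
                 "manual")
})

test_that("lane profiles average rows bottom-to-top with mask handling", {
    m <- matrix(2.5, 40, 10)
    lay <- LaneLayout(c(0, 10))
    expect_equal(profileValues(laneProfiles(imageFrom(m), lay))[, 1],
                 rep(2.5, 40))
    # a horizontal bar maps to the right (bottom-based) profile rows
    m2 <- matrix(0, 40, 10); m2[5:8, ] <- 7       # image rows 5..8 from top
    p <- profileValues(laneProfiles(imageFrom(m2), lay))[, 1]
    expect_equal(which(p == 7), 40 - (8:5) + 1)
    expect_equal(sum(p != 0), 4L)
    # masked vertical strip: brute-force masked row means
    set.seed(5)
    v <- matrix(rnorm(400), 40, 10)
    msk <- matrix(TRUE, 40, 10); msk[, 3:5] <- FALSE
    p2 <- profileValues(laneProfiles(imageFrom(v, msk), lay))[, 1]
    expect_equal(p2, rev(rowMeans(v[, -(3:5)])), tolerance = 1e-12)
})

test_that("double-sided subtraction is exact for affine backgrounds", {
    pos <- seq_len(200) - 0.5
    v <- cbind(0.03 * pos + 2, -0.01 * pos + 5)
    prof <- subtractBackground(profilesFrom(v), "double_sided",
                               left = 40, right = 160)
    expect_lt(max(abs(profileValues(prof))), 1e-10)
    expect_equal(backgroundModel(prof), v, tolerance = 1e-12)
    expect_equal(outerLimits(prof), c(40, 160))
})

test_that("single-sided and region subtraction remove a constant baseline", {
    pos <- seq_len(200) - 0.5
    peak <- 5 * exp(-(pos - 100)^2 / 50)
    prof <- subtractBackground(profilesFrom(cbind(peak + 3)),
                               "single_sided", left = 40)
    expect_equal(profileValues(prof)[, 1], peak, tolerance = 1e-10)
    img <- imageFrom(matrix(3, 50, 20))
    prof2 <- subtractBackground(profilesFrom(cbind(peak[1:50] + 3)),
                                "region", img = img,
                                region = c(0, 0, 20, 10))
    expect_equal(profileValues(prof2)[, 1], peak[1:50], tolerance = 1e-10)
    expect_error(subtractBackground(profilesFrom(cbind(peak)),
                                    "double_sided", left = 0, right = 0.2),
                 "zero width|left < right")
    expect_error(subtractBackground(profilesFrom(cbind(peak)),
                                    "single_sided"), "left or right")
})

test_that("lane-weighted profile means conserve total image intensity", {
    set.seed(9)
    v <- matrix(runif(80 * 60), 80, 60)
    img <- imageFrom(v)
    lay <- detectLanes(img, 3, boundaries = c(0, 17.5, 41.5, 60))
    prof <- profileValues(laneProfiles(img, lay))
    widths <- vapply(1:3, function(l)
        length(emsaquant:::.laneCols(lay, l, 60)), numeric(1))
    total <- sum(vapply(1:3, function(l)
        widths[l] * sum(prof[, l]), numeric(1)))
    expect_equal(total, sum(v), tolerance = 1e-9)
})

test_that("tilted background plus bands: band integrals within 1 percent", {
    tr <- syntheticTruth(seed = 13L, snr = 1e6, kOffT = 0,
                         bgCoef = c(1, 2e-3, 4e-3),
                         sourceKind = "phosphorimage")
    res <- analyzeTruth(tr)
    I <- bandIntensities(res$table)
    frac <- t(vapply(tr@prLane, function(p)
        equilibriumFractions(tr@trueK, p), numeric(2)))
    meas <- I / rowSums(I)
    expect_lt(max(abs(meas - frac)), 0.01)
})
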