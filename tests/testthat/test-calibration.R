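test_that("gray-to-OD interpolation is exact on knots and linear between", {
    tab <- StepTablet(gray = c(0, 100), od = c(0, 1))
    expect_equal(grayToOD(50, tab), 0.5)
    expect_equal(grayToOD(0, tab), 0)
    expect_equal(grayToOD(100, tab), 1)
    # knot exactness and monotonicity on a multi-step tablet
    g <- seq(1000, 60000, length.out = 11)
    o <- 2 * ((g - 1000) / 59000)^3 + 0.05 * (g - 1000) / 59000
    tab2 <- StepTablet(g, o)
    expect_equal(grayToOD(g, tab2), o)
    x <- seq(1000, 60000, length.out = 500)
    expect_true(all(diff(grayToOD(x, tab2)) >= 0))
})

test_that("interpolation matches a per-segment linear oracle", {
    set.seed(42)
    g <- sort(runif(11, 0, 65535))
    o <- sort(runif(11, 0, 2.2))
    tab <- StepTablet(g, o)
    q <- runif(1000, min(g), max(g))
    oracle <- vapply(q, function(x) {
        i <- max(which(g <= x))
        if (i == length(g)) return(o[i])
        o[i] + (o[i + 1] - o[i]) * (x - g[i]) / (g[i + 1] - g[i])
    }, numeric(1))
    expect_equal(grayToOD(q, tab), oracle, tolerance = 1e-12)
})

test_that("out-of-range grays extrapolate linearly then clamp to tablet ODs", {
    tab <- StepTablet(c(100, 200, 300), c(0.5, 1.0, 2.0))
    # extrapolation below the range lands below min od and clamps back
    expect_equal(grayToOD(90, tab), 0.5)
    expect_equal(grayToOD(310, tab), 2)      # clamped at max od
    expect_equal(grayToOD(-1000, tab), 0.5)  # clamped at min od
})

test_that("invalid tablets are rejected", {
    expect_error(StepTablet(1, 0.5), "at least 2")
    expect_error(StepTablet(c(1, 1), c(0, 1)), "duplicate")
    expect_error(StepTablet(c(1, 2, 3), c(0, 1, 0.5)), "monotone")
})

test_that("film inversion anchors at odMin, increases, and clamps", {
    film <- FilmModel(0.06, 1.6)
    expect_equal(odToRelativeConcentration(0.06, film), 0)
    out <- odToRelativeConcentration(c(0.2, 0.8, 1.5), film)
    expect_true(all(diff(out) > 0))
    # below odMin clamps to zero exposure
    expect_equal(odToRelativeConcentration(0.01, film), 0)
    # saturated pixels clamp with a warning
    expect_warning(sat <- odToRelativeConcentration(1.6, film),
                   "saturation")
    expect_equal(sat, suppressWarnings(
        odToRelativeConcentration(1.6 - 1e-3, film)))
    expect_error(odToRelativeConcentration(NaN, film), "finite")
    expect_error(FilmModel(1.6, 0.06))
})

test_that("film round trip recovers exposure over three decades", {
    film <- FilmModel(0.06, 1.6)
    E <- 10^seq(-2.5, 0.5, length.out = 400)   # below the saturation guard
    od <- relativeConcentrationToOD(E, film)
    back <- odToRelativeConcentration(od, film)
    expect_lt(max(abs(back - E) / E), 1e-9)
})

test_that("calibrateImage dispatches on source kind with required inputs", {
    raw <- matrix(runif(100, 100, 1000), 10, 10)
    # phosphorimage: counts pass through
    img <- calibrateImage(raw, "phosphorimage")
    expect_equal(intensities(img), raw)
    expect_identical(dim(pixelMask(img)), dim(raw))
    # gel: interpolated ODs are the intensities
    tab <- StepTablet(c(0, 65535), c(0, 2))
    gel <- calibrateImage(raw, "gel", tablet = tab)
    expect_equal(intensities(gel), grayToOD(raw, tab))
    # missing requirements
    expect_error(calibrateImage(raw, "gel"), "tablet")
    expect_error(calibrateImage(raw, "autoradiograph", tablet = tab),
                 "film")
})

test_that("full autoradiograph path is linear in simulated radioactivity", {
    set.seed(7)
    film <- FilmModel(0.06, 1.6)
    E <- matrix(10^runif(2500, -2.5, 0.5), 50, 50)    # 3 decades
    od <- relativeConcentrationToOD(E, film)
    gray <- 62000 - 28000 * od                        # darker = lower gray
    tab <- StepTablet(62000 - 28000 * seq(0, 2, 0.25), seq(0, 2, 0.25))
    img <- calibrateImage(gray, "autoradiograph", tablet = tab,
                          film = film)
    expect_gt(cor(as.vector(intensities(img)), as.vector(E)), 0.9999)
    expect_false(any(!is.finite(intensities(img))))
    expect_true(all(intensities(img) >= 0))
})

test_that("gray polarity is auto-detected from the tablet slope", {
    film <- FilmModel(0.06, 1.6)
    E <- matrix(10^seq(-1, 0.8, length.out = 100), 10, 10)
    od <- relativeConcentrationToOD(E, film)
    odSteps <- seq(0, 2, 0.25)
    up <- calibrateImage(1000 + 30000 * od, "autoradiograph",
                         tablet = StepTablet(1000 + 30000 * odSteps,
                                             odSteps), film = film)
    down <- calibrateImage(62000 - 28000 * od, "autoradiograph",
                           tablet = StepTablet(62000 - 28000 * odSteps,
                                               odSteps), film = film)
    expect_equal(intensities(up), intensities(down), tolerance = 1e-9)
})
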