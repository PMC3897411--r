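test_that("findBound matches the closed form on a constant profile", {
    v <- rep(2, 100)                      # constant c = 2
    # peak at 20, p1 at 60 with height h = 1.5, width w = 40, no ssDNA:
    # x* = x1 - h*w/c
    x <- findBound(v, p1 = c(60, 1.5), p2 = c(20, 0))
    expect_equal(x, 60 - 1.5 * 40 / 2, tolerance = 1e-9)
    # all smear attributed to ssDNA: A = 0, manual mode
    expect_equal(findBound(v, c(60, 1.5), c(20, 1.5)), 60)
    expect_equal(findBound(v, c(60, 1.0), c(20, 1.5)), 60)  # floored at 0
    # area exceeding what is available returns the peak with a warning
    expect_warning(xp <- findBound(rep(0.01, 100), c(60, 5), c(20, 0)),
                   "peak")
    expect_equal(xp, 20)
    expect_error(findBound(v, c(60, 1), c(60, 0)), "coincide")
    expect_error(findBound(v, c(200, 1), c(20, 0)), "outside")
})

test_that("assignBands splits in-pair smear half and half", {
    # two separated triangles, zero-width pair between them
    x <- seq_len(120) - 0.5
    tri <- function(c, w, h) pmax(0, h * (1 - abs(x - c) / w))
    v <- tri(30, 10, 2) + tri(90, 10, 3)
    a <- assignBands(v, list(BoundaryPair(60, 60)), c(0, 120))
    expect_equal(a$intensity, c(sum(tri(30, 10, 2)), sum(tri(90, 10, 3))),
                 tolerance = 1e-9)
    expect_equal(a$smear, 0)
    # uniform u over a pair of width w: each band gains u*w/2
    u <- 0.8; v2 <- rep(u, 100)
    a2 <- assignBands(v2, list(BoundaryPair(40, 50)), c(0, 100))
    expect_equal(a2$smear, u * 10)
    expect_equal(a2$intensity, c(40 * u + u * 5, 50 * u + u * 5))
    expect_error(assignBands(v2, list(BoundaryPair(40, 60),
                                      BoundaryPair(50, 70)), c(0, 100)),
                 "overlap")
    expect_error(assignBands(v2, list(BoundaryPair(-5, 10)), c(0, 100)),
                 "outside")
})

test_that("band totals conserve the profile integral on random fixtures", {
    set.seed(21)
    for (rep in 1:20) {
        v <- abs(rnorm(150, 1, 2)) + runif(1, 0, 3)
        outer <- sort(runif(2, 0, 150))
        while (diff(outer) < 30) outer <- sort(runif(2, 0, 150))
        cuts <- sort(runif(4, outer[1], outer[2]))
        pairs <- list(BoundaryPair(cuts[1], cuts[2]),
                      BoundaryPair(cuts[3], cuts[4]))
        a <- assignBands(v, pairs, outer)
        expect_equal(sum(a$intensity),
                     profileIntegral(v, outer[1], outer[2]),
                     tolerance = 1e-9)
    }
})

test_that("ssDNA subtraction is exact, invertible, and conserving", {
    v <- matrix(1, 100, 3)
    prof <- profilesFrom(v, outer = c(0, 100))
    tab <- bandTable(prof, list(BoundaryPair(50, 52)))
    # empty region: unchanged
    t0 <- subtractSsDNA(tab, prof, 1, c(60, 60),
                        list(type = "band", index = 2))
    expect_equal(bandIntensities(t0), bandIntensities(tab))
    # subtract then re-add equals the original
    t1 <- subtractSsDNA(tab, prof, 1, c(60, 70),
                        list(type = "band", index = 2))
    expect_equal(bandIntensities(t1)[, 2], bandIntensities(tab)[, 2] - 10)
    neg <- profilesFrom(-v, outer = c(0, 100))   # re-add via negative q
    t2 <- subtractSsDNA(t1, neg, 1, c(60, 70),
                        list(type = "band", index = 2))
    expect_equal(bandIntensities(t2), bandIntensities(tab),
                 tolerance = 1e-12)
    expect_equal(laneSums(t2), laneSums(tab), tolerance = 1e-12)
    # interface target: smear and both half-shares drop
    t3 <- subtractSsDNA(tab, prof, 1, c(50.5, 51.5),
                        list(type = "interface", index = 1))
    expect_equal(smearAmounts(t3)[, 1], smearAmounts(tab)[, 1] - 1)
    expect_equal(bandIntensities(t3), bandIntensities(tab) - 0.5)
    expect_error(subtractSsDNA(tab, prof, 1, c(10, 80),
                               list(type = "band", index = 2)),
                 "outside")
})

test_that("subtracting a constant injected ssDNA band restores truth", {
    base <- syntheticTruth(seed = 31L, sourceKind = "phosphorimage")
    with <- syntheticTruth(seed = 31L, sourceKind = "phosphorimage",
                           ssdnaMass = 120, ssdnaCenter = 160)
    # identical seeds: same noise stream order differs, so compare via
    # the noiseless structure at high SNR
    base@snr <- 1e6; with@snr <- 1e6
    r0 <- analyzeTruth(base)
    r1 <- analyzeTruth(with, pairs = r0$pairs)   # paired band accounting
    # the ssDNA band (centre 160) falls inside band 2's extent
    t2 <- subtractSsDNA(r1$table, r1$profiles, 1, c(135, 185),
                        list(type = "band", index = 2))
    k0 <- bandIntensities(r0$table)[, 2] / bandIntensities(r0$table)[, 1]
    k2 <- bandIntensities(t2)[, 2] / bandIntensities(t2)[, 1]
    expect_lt(max(abs(k2[-1] - k0[-1]) / k0[-1]), 0.05)
})

test_that("zeroRegion is idempotent and removes a contaminant", {
    v <- matrix(runif(300), 100, 3)
    prof <- profilesFrom(v)
    expect_equal(profileValues(zeroRegion(prof, c(40, 40))), v)
    z1 <- zeroRegion(prof, c(40, 60))
    expect_true(all(profileValues(z1)[41:60, ] == 0))
    expect_equal(profileValues(zeroRegion(z1, c(40, 60))),
                 profileValues(z1))
    expect_warning(zeroRegion(prof, c(40, 60),
                              cores = list(c(55, 80))), "core")
})

test_that("recipe bounds sandwich the oracle division line", {
    for (kOffT in c(0.1, 0.3, 0.5)) {
        for (sep in c(80, 120)) {
            comp <- smearCase(kOffT, sep, 1.5)
            xc <- correctDivisionLine(comp)
            v <- comp@dna + comp@complex
            pr <- suppressWarnings(
                selectBoundaryPairs(v, c(60, 60 + sep)))[[1]]
            expect_lte(pr@lower, xc)
            expect_gte(pr@upper, xc)
            expect_gt(xc, 60); expect_lt(xc, 60 + sep)
        }
    }
})

test_that("detectBandPeaks finds the band positions", {
    tr <- syntheticTruth(seed = 17L)
    res <- analyzeTruth(tr)
    peaks <- detectBandPeaks(res$profiles, 2)
    expect_equal(peaks, tr@bandCenters, tolerance = 4)
})
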