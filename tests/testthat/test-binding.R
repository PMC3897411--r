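test_that("protein concentration follows dilution arithmetic", {
    expect_equal(proteinConcentration(200e-9, 1, 20), 10e-9)
    expect_equal(proteinConcentration(200e-9, 0, 20), 0)
    # 2 uL of 0.5 mg/mL (= 0.5 g/L) stock, MW 50 kg/mol, in 20 uL -> 1 uM
    expect_equal(proteinConcentration(0.5, 2, 20, molarWeight = 5e4,
                                      stockUnit = "mass_per_volume"),
                 1e-6)
    expect_error(proteinConcentration(0.5, 2, 20,
                                      stockUnit = "mass_per_volume"),
                 "molar weight")
    expect_error(proteinConcentration(1, 1, 0), "positive")
})

simpleTable <- function(iLo, iHi, smear = 0) {
    new("BandTable",
        intensity = matrix(c(iLo, iHi), 1, 2),
        smear = matrix(smear, 1, 1),
        extents = matrix(c(0, 50, 50, 100), 2, 2, byrow = TRUE),
        interfaces = matrix(c(49, 51), 1, 2),
        laneSums = iLo + iHi)
}

test_that("stepwise K is the band ratio over the concentration", {
    tab <- simpleTable(4, 4)
    est <- stepwiseK(tab, 1, 1, 10e-9)
    expect_equal(est@k, 0.1e9)                 # ratio 1 at 10 nM
    expect_equal(stepwiseK(simpleTable(4, 0), 1, 1, 1e-8)@k, 0)
    expect_warning(bad <- stepwiseK(simpleTable(0, 4), 1, 1, 1e-8),
                   "denominator")
    expect_true(is.na(bad@k))
    expect_true(is.na(stepwiseK(tab, 1, 1, 0)@k))   # no protein: no K
})

test_that("K is invariant to global intensity rescaling", {
    set.seed(2)
    v <- abs(rnorm(2))
    for (s in c(1e-3, 1, 1e4)) {
        k <- stepwiseK(simpleTable(s * v[1], s * v[2]), 1, 1, 5e-9)@k
        expect_equal(k, v[2] / v[1] / 5e-9, tolerance = 1e-12)
    }
})

twoLaneProfiles <- function(delta, len = 100) {
    # lane 1 flat-zero baseline; lane 2 baseline differs by delta inside
    # the upper band extent only
    bg <- matrix(0, len, 2)
    bg[61:80, 2] <- delta
    profilesFrom(matrix(1, len, 2), background = bg, outer = c(0, len))
}

test_that("background error reduces the maximum estimate by sqrt(3)", {
    # neighbour baseline differs by delta over the upper band extent
    prof <- twoLaneProfiles(0.02)
    pairs <- list(BoundaryPair(50, 50))
    tab <- bandTable(prof, pairs)
    iLo <- bandIntensities(tab)[1, 1]; iHi <- bandIntensities(tab)[1, 2]
    dHi <- 0.02 * 20                     # integral of the difference
    eMax <- abs((iHi - dHi) / iLo - iHi / iLo) / (iHi / iLo)
    expect_equal(backgroundError(prof, tab, 1, 1), eMax / sqrt(3),
                 tolerance = 1e-9)
    # identical baselines give zero error
    expect_equal(backgroundError(twoLaneProfiles(0), tab, 1, 1), 0)
})

test_that("exact recomputation meets the first-order form as errors shrink", {
    pairs <- list(BoundaryPair(50, 50))
    for (delta in c(0.05, 0.005, 5e-4)) {
        prof <- twoLaneProfiles(delta)
        tab <- bandTable(prof, pairs)
        iHi <- bandIntensities(tab)[1, 2]
        got <- backgroundError(prof, tab, 1, 1) * sqrt(3)
        firstOrder <- (delta * 20) / iHi          # dB_hi/I_hi - 0
        expect_equal(got, firstOrder, tolerance = 2.5 * delta)
    }
})

test_that("single lane has no background error estimate", {
    prof <- profilesFrom(matrix(1, 100, 1), outer = c(0, 100))
    tab <- bandTable(prof, list(BoundaryPair(50, 50)))
    expect_message(e <- backgroundError(prof, tab, 1, 1), "single lane")
    expect_true(is.na(e))
})

test_that("smear error follows the brute-force reassignment oracle", {
    i1 <- 6; i2 <- 3; s <- 1.2
    tab <- simpleTable(i1, i2, smear = s)
    k <- i2 / i1
    eMax <- max(abs((i2 + s / 2) / (i1 - s / 2) - k),
                abs((i2 - s / 2) / (i1 + s / 2) - k)) / k
    expect_equal(smearError(tab, 1, 1), eMax / sqrt(3), tolerance = 1e-12)
    expect_equal(smearError(simpleTable(6, 3, 0), 1, 1), 0)
    # scale invariance of the relative error
    expect_equal(smearError(simpleTable(12, 6, 2.4), 1, 1),
                 smearError(tab, 1, 1), tolerance = 1e-12)
})

test_that("multi-site smear error adds flanking variances in quadrature", {
    tab <- new("BandTable",
               intensity = matrix(c(5, 4, 3), 1, 3),
               smear = matrix(c(0.6, 0.4), 1, 2),
               extents = matrix(c(0, 40, 40, 70, 70, 100), 3, 2,
                               byrow = TRUE),
               interfaces = matrix(c(39, 41, 69, 71), 2, 2, byrow = TRUE),
               laneSums = 12)
    # K at interface 2 (bands 2 and 3): contributions from interface 2
    # plus interface 1 (perturbs the lower band only)
    single <- smearError(tab, 1, 2, nSites = 1)
    multi <- smearError(tab, 1, 2, nSites = 2)
    k <- 3 / 4
    eBefore <- max(abs(3 / (4 - 0.3) - k), abs(3 / (4 + 0.3) - k)) / k
    expect_equal(multi, sqrt(single^2 + (eBefore / sqrt(3))^2),
                 tolerance = 1e-12)
    expect_gt(multi, single)
})

mkEst <- function(lane, k, sBg = 0, sSm = 0)
    new("LaneKEstimate", lane = as.integer(lane), k = k, ratio = k,
        pr = 1, sigmaBg = sBg, sigmaSmear = sSm)

test_that("summarizeK decomposes random and systematic errors", {
    # identical K, zero sigmas: all zero spread
    s0 <- summarizeK(list(mkEst(1, 2), mkEst(2, 2), mkEst(3, 2)))
    expect_equal(s0@sem, 0); expect_equal(s0@sigmaTotal, 0)
    # textbook case: K = 1, 2, 3
    s1 <- summarizeK(list(mkEst(1, 1), mkEst(2, 2), mkEst(3, 3)))
    expect_equal(s1@meanK, 2)
    expect_equal(s1@sem, 1 / sqrt(3), tolerance = 1e-12)
    expect_equal(s1@sigmaTotal, s1@sem)
    # independent background errors: sqrt-sum over n; correlated smear:
    # plain mean; technical floor at zero
    est <- list(mkEst(1, 1, 0.3, 0.1), mkEst(2, 2, 0.4, 0.2),
                mkEst(3, 3, 0.5, 0.3))
    s2 <- suppressMessages(summarizeK(est))
    expect_equal(s2@sigmaBgAvg, sqrt(0.3^2 + 0.4^2 + 0.5^2) / 3)
    expect_equal(s2@sigmaSmearAvg, 0.2)
    expect_equal(s2@sigmaTotal, sqrt(s2@sem^2 + 0.2^2))
    expect_equal(s2@sigmaTech,
                 sqrt(max(0, s2@sem^2 - s2@sigmaBgAvg^2)))
    expect_error(summarizeK(list(mkEst(1, 1))), "at least 2")
    expect_warning(summarizeK(list(mkEst(1, 1), mkEst(2, 2))),
                   "at least 3")
})

test_that("normalization divides by the reference with added variances", {
    a <- summarizeK(list(mkEst(1, 1), mkEst(2, 2), mkEst(3, 3)))
    ref <- summarizeK(list(mkEst(1, 4), mkEst(2, 4), mkEst(3, 4)))
    n <- summarizeK(list(mkEst(1, 1), mkEst(2, 2), mkEst(3, 3)),
                    reference = ref)
    expect_equal(n@normalizedK, 0.5)
    relVar <- (a@sigmaTotal / a@meanK)^2 + 0
    expect_equal(n@normalizedStd, 0.5 * sqrt(relVar))
})

test_that("per-lane error components are scale-free in intensities", {
    tr <- syntheticTruth(seed = 23L, sourceKind = "phosphorimage")
    res <- analyzeTruth(tr)
    # doubling every intensity (a rescan at twice the gain) leaves the
    # relative error components untouched
    prof2 <- res$profiles
    prof2@values <- prof2@values * 2
    prof2@background <- prof2@background * 2
    tab2 <- res$table
    tab2@intensity <- tab2@intensity * 2
    tab2@smear <- tab2@smear * 2
    expect_equal(backgroundError(prof2, tab2, 4, 1),
                 backgroundError(res$profiles, res$table, 4, 1),
                 tolerance = 1e-12)
    expect_equal(smearError(tab2, 4, 1), smearError(res$table, 4, 1),
                 tolerance = 1e-12)
})
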