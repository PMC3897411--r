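#' Two-site equilibrium occupancy (brute-force oracle)
#'
#' Species fractions for a DNA fragment with two non-overlapping sites of
#' intrinsic affinities k1 and k2 and cooperativity factor `w`, at free
#' protein concentration `pr`.  Statistical weights relative to free DNA:
#' free 1, bound at site 1 `k1*pr`, bound at site 2 `k2*pr`, doubly bound
#' `k1*k2*w*pr^2`.  The two singly-bound species co-migrate in an EMSA, so
#' the reported fractions are (free, singly bound, doubly bound).
#'
#' @param k1,k2 intrinsic site affinities (1/molar).
#' @param w cooperative binding constant (dimensionless).
#' @param pr free protein concentration (molar).
#' @return numeric(3): fractions of free, singly and doubly bound DNA.
#' @export
twoSiteFractions <- function(k1, k2, w, pr) {
    stopifnot(k1 > 0, k2 > 0, w > 0, pr >= 0)
    weights <- c(1, (k1 + k2) * pr, k1 * k2 * w * pr^2)
    weights / sum(weights)
}

#' Expected first stepwise constant of a two-box construct
#'
#' The first shifted band of the two-box fragment contains DNA bound at
#' either site, so its stepwise constant is the sum of the intrinsic
#' affinities, `K1 = k1 + k2`.
#'
#' @param k1,k2 intrinsic site affinities (1/molar), from single-box EMSAs.
#' @return `k1 + k2`.
#' @export
expectedK1 <- function(k1, k2) {
    stopifnot(k1 >= 0, k2 >= 0)
    k1 + k2
}

#' Cooperative binding constant from stepwise constants
#'
#' For homotypic binding at two non-overlapping boxes, the product of the
#' two stepwise constants of the two-box construct equals
#' `K1 * K2 = k1 * k2 * omega`, so
#' `omega = K1 * K2 / (k1 * k2)`.
#' Unlike the classical single-lane approach, K1 and K2 may be averages
#' from different lanes or even different gels, so all three bands need
#' never be present simultaneously.  The expression is homogeneous of
#' degree 0, so reference-normalized (relative) constants give a relative
#' cooperativity measure: `omega = 1` means independent binding.
#'
#' @param K1,K2 stepwise constants of the two-box construct (1/molar, or
#'   normalized).
#' @param k1,k2 intrinsic single-box affinities (same units).
#' @return the cooperativity factor omega (dimensionless).
#' @examples
#' omega(K1 = 2, K2 = 2, k1 = 1, k2 = 1)   # 4: cooperative
#' omega(K1 = 2, K2 = 0.5, k1 = 1, k2 = 1) # 1: independent
#' @export
omega <- function(K1, K2, k1, k2) {
    if (any(c(K1, K2, k1, k2) <= 0))
        stop("all binding constants must be positive")
    K1 * K2 / (k1 * k2)
}

#' First-order standard deviation of omega
#'
#' Taylor propagation through `omega = K1*K2/(k1*k2)` with the four inputs
#' independent (they come from different EMSAs): the relative variances
#' add,
#' `(sigma_w/w)^2 = (sK1/K1)^2 + (sK2/K2)^2 + (sk1/k1)^2 + (sk2/k2)^2`.
#' When K1 and K2 derive from the same gel this underestimates their
#' correlation; see the package vignette.
#'
#' @inheritParams omega
#' @param sK1,sK2,sk1,sk2 standard deviations of the four inputs (>= 0).
#' @return the standard deviation of omega.
#' @export
omegaStd <- function(K1, K2, k1, k2, sK1 = 0, sK2 = 0, sk1 = 0, sk2 = 0) {
    if (any(c(sK1, sK2, sk1, sk2) < 0))
        stop("standard deviations must be non-negative")
    w <- omega(K1, K2, k1, k2)
    w * sqrt((sK1 / K1)^2 + (sK2 / K2)^2 + (sk1 / k1)^2 + (sk2 / k2)^2)
}

#' Cooperativity with propagated uncertainty
#'
#' @inheritParams omegaStd
#' @param mode "absolute" for molar constants, "relative" for constants
#'   normalized by a common reference (preferred when the active protein
#'   fraction is uncertain; omega is unchanged by common normalization).
#' @return list with `omega`, `std` and `mode`.
#' @export
cooperativity <- function(K1, K2, k1, k2, sK1 = 0, sK2 = 0, sk1 = 0,
                          sk2 = 0, mode = c("relative", "absolute")) {
    mode <- match.arg(mode)
    list(omega = omega(K1, K2, k1, k2),
         std = omegaStd(K1, K2, k1, k2, sK1, sK2, sk1, sk2),
         mode = mode)
}
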