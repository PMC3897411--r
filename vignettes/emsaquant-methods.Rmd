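---
title: "Quantifying EMSAs: the model, the error budget, and the design choices"
author: "emsaquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying EMSAs: the model, the error budget, and the design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emsaquant)
```

# The measurement problem

An electrophoretic mobility shift assay (EMSA) separates free DNA from its
protein complexes on a native gel; the intensity of each band is
proportional to the abundance of the corresponding species at the moment
the sample entered the gel.  For a titration in which lane $i$ received
protein at concentration $[\mathrm{Pr}]_i$ (in large excess over the DNA,
so the free concentration equals the added one), the stepwise association
constant for adding the $j$-th protein is estimated per lane as

$$K_j = \frac{I_{j+1}}{I_j}\cdot\frac{1}{[\mathrm{Pr}]},$$

the ratio of the intensities of the bands with $j+1$ and $j$ proteins
bound.  Being a ratio, $K_j$ is invariant to the overall intensity scale,
but it inherits every error made in measuring the two band integrals.
This package implements the complete chain from a raw 16-bit scan to an
averaged $K$ with a decomposed error bar, plus cooperative binding
constants for two-site constructs.

# From gray values to relative concentrations

Autoradiographic film responds non-linearly: the developed optical density
saturates with exposure,

$$\mathrm{OD}(E) = \mathrm{OD}_{\min} +
  (\mathrm{OD}_{\max}-\mathrm{OD}_{\min})\,(1 - e^{-cE}),$$

where $\mathrm{OD}_{\min}$ is the fog density of unexposed film and
$\mathrm{OD}_{\max}$ the density of film exposed to daylight (0.06 and 1.6
for the Kodak Biomax MR film the defaults describe).  Quantifying an
autoradiograph therefore needs two maps: scanner gray values to optical
densities -- piecewise-linear interpolation through a calibrated step
tablet scanned with the film -- and optical densities to relative
concentrations by inverting the saturation law:

$$\mathrm{CR}(\mathrm{OD}) = -\ln\!\left(
 \frac{\mathrm{OD}_{\max}-\mathrm{OD}}
      {\mathrm{OD}_{\max}-\mathrm{OD}_{\min}}\right).$$

`odToRelativeConcentration()` is zero at $\mathrm{OD}_{\min}$, strictly
increasing, and diverges at $\mathrm{OD}_{\max}$; the composition with the
forward law recovers exposure to better than $10^{-9}$ relative over three
decades (this is asserted in the test suite).  Numerical guards:

* ODs below $\mathrm{OD}_{\min}$ (background fluctuation on unexposed
  film) clamp to zero exposure;
* ODs within $\varepsilon = 10^{-3}$ of $\mathrm{OD}_{\max}$ clamp to
  $\mathrm{OD}_{\max}-\varepsilon$ with a warning -- the inversion
  diverges there, and an overexposed pixel should not abort a pipeline;
* gray values outside the tablet's range clamp to the tablet's OD range
  (for a monotone tablet, linear extrapolation beyond the end segments
  always leaves the certified range, so the clamp is what remains of it);
* scanner polarity (whether darker film is stored as a low or a high gray
  value) is read off the sign of the tablet's gray-to-OD slope, so both
  conventions work unmodified.

Stained-gel scans stop at the OD map (staining density is taken linear in
amount), and phosphorimager counts are used directly.  Scans are smoothed
with a 5 x 5 running average *in gray space* before calibration, which is
where film grain and scanner noise live; masked pixels are excluded from
the window mean (renormalised, never zero-filled) so artifact masks do not
bias integrals.

# Lanes, profiles, and background

Lane boundaries are the minima of the smoothed column-sum profile (the
gaps between migration tracks); the automatic detector takes the
`nLanes - 1` deepest local minima at least `width/(2 nLanes)` apart, and an
explicit boundary list always overrides it.  The per-lane profile is the
mean valid intensity of each image row, reported bottom-to-top because the
free DNA band sits at the image bottom (band 1).  On the continuous
migration axis, pixel $p$ covers $[p-1, p)$; profiles are treated as
piecewise-constant over pixels, so cumulative integrals are piecewise
linear and all boundary positions resolve to sub-pixel precision.

Background is estimated per lane from flat zones the user designates:
`double_sided` fits the straight line through the mean of a bottom zone
and the mean of a top zone (exact for any baseline affine in position --
a property the tests check to $10^{-10}$), `single_sided` uses one zone as
a constant, and `region` uses the mean of an image region shared by all
lanes.  Negative values after subtraction are retained; clipping would
bias faint bands upward.  The two double-sided positions double as the
outer integration limits closing the first and last band.

# Division lines under smear

Complexes that dissociate during the run leave a smear between the
complex and the DNA band.  Those molecules were complexes at equilibrium,
so the *correct* division line is the position at which the area on the
DNA side equals the initial free-DNA amount.  With the components unknown
in a real lane, the line is bracketed instead:

* **Upper bound** -- pick $p_1=(x_1,y_1)$ on the profile in the smear
  close to the DNA band and $p_2=(x_2,y_2)$ at the DNA peak with $y_2$ an
  over-estimate of any single-stranded-DNA smear.  The rectangle
  $|x_2-x_1|\,(y_1-y_2)$ under-estimates the dissociation smear on the
  DNA side of $x_1$ (the smear density decreases toward the complex band,
  because the amount dissociating is proportional to the amount left), so
  sliding the line from $x_1$ toward the peak until the removed area
  equals the rectangle stops at or beyond the correct line.
* **Lower bound** -- the same construction with $y_1$ at an over-estimate
  of the smear level and $x_2$ slightly (2 px by default) before the
  peak, compensating the apparent peak shift the smear causes.

`findBound()` performs the area inversion; `selectBoundaryPairs()`
automates the recipe, estimating the band width from its half-maximum
point so that $p_1$ sits past 4.5 estimated band sigma -- on the smear,
not on the band flank.  The smear integrated between the two bounds is
split half-and-half between the adjacent bands, so by construction the
intensity error from misassignment is at most half the in-pair smear;
that bound is exactly what the smear error term uses.

Two conditions limit the recipe, and the package treats both explicitly:
bands closer than roughly ten band-widths have no clean smear zone
(the constructions contaminate each other's flanks), which is the regime
where division lines should be placed manually; and the correct line
moves from lane to lane with the lane's smear-to-DNA balance, so a pair
selected on one lane does not bracket the others.  The default therefore
runs the recipe *per lane* (each lane's pair brackets its own line,
keeping the half-smear bound valid everywhere); passing `selectLane`
restores the classical single-lane selection transferred to all lanes.

An ssDNA or contaminant band -- recognisable by its protein-independent
intensity -- is removed either by measuring its integral in one reference
lane and subtracting it from the target band in every lane
(`subtractSsDNA()`, which also keeps the lane totals consistent), or by
zeroing its region outright (`zeroRegion()`) when it overlaps nothing.

# The error budget

Three error sources act on each lane's $K$:

* **Non-uniform background** (`backgroundError()`): the baseline inside a
  lane's bands cannot be checked directly, so the difference between the
  lane's fitted baseline and each neighbour's, integrated over each
  band's extent, proxies it.  The perturbed intensities are plugged back
  into the ratio (exact recomputation rather than the first-order
  expansion -- the two agree as the perturbation vanishes, which is a
  test, and recomputation stays sensible for large errors).  The largest
  absolute estimate is the maximum error $E_{\max}$, and treating the
  true error as uniform on $(-E_{\max}, E_{\max})$ gives
  $\sigma = E_{\max}/\sqrt3$.
* **Smear** (`smearError()`): the half-smear of the interface is moved
  fully to one band and then the other; the larger relative shift is
  $E_{\max}$ and $\sigma = E_{\max}/\sqrt3$ again.  With more than one
  binding site the smear before the lower and after the upper band each
  perturb one band; the three interval variances add.
* **Technical errors** (pipetting, dilution) are not estimated per lane;
  they surface in the spread of $K$ over lanes.

Averaging over the selected lanes (`summarizeK()`) treats background and
technical errors as random -- they average down, and the standard error
of the mean *measures* them -- while smear errors are assumed fully
correlated over lanes (the same division ambiguity repeats), hence
systematic:

$$\sigma_{\mathrm{bg}} = \frac{\sqrt{\sum_i \sigma_{\mathrm{bg},i}^2}}{n},
\qquad
\sigma_{\mathrm{smear}} = \frac{\sum_i \sigma_{\mathrm{smear},i}}{n},
\qquad
\sigma_{\mathrm{tot}} = \sqrt{\mathrm{sem}^2 + \sigma_{\mathrm{smear}}^2},
\qquad
\sigma_{\mathrm{tech}} = \sqrt{\max(0, \mathrm{sem}^2 -
\sigma_{\mathrm{bg}}^2)}.$$

$\sigma_{\mathrm{tech}}$ is floored at zero because the background term
can be over-estimated.  Lanes whose own error estimates are outliers --
typically the titration extremes, where one band is nearly invisible and
the intensity ratio is both noisy and biased -- degrade the average;
`bestLanes()` implements the selection a practitioner makes from the
diagnostic plots: keep lanes whose relative error estimate is within 3x
the candidate median, never fewer than three lanes (averages over fewer
lanes underestimate the spread).  An explicit lane list always wins.

Experiments run on different days see different active-protein fractions;
dividing by the constant of a reference sequence measured in parallel
cancels this, and the relative variances of the two totals add.

# Cooperativity

For homotypic binding at two non-overlapping boxes with intrinsic
affinities $k_1, k_2$ (from single-box EMSAs), the two-box construct's
first shifted band contains DNA bound at either box, so $K_1 = k_1+k_2$,
and the product of the two stepwise constants satisfies
$K_1 K_2 = k_1 k_2\,\omega$.  Hence

$$\omega = \frac{K_1 K_2}{k_1 k_2},$$

with $\omega = 1$ for independent binding.  Because $K_1$ and $K_2$ are
averages, the three bands never need to coexist in one lane, and because
the expression is homogeneous of degree zero, reference-normalised
constants give a relative cooperativity measure -- the preferred mode
when the absolute active-protein concentration is unreliable.  The
standard deviation propagates to first order as the root sum of the four
relative variances, with the inputs taken independent (they come from
different gels; when $K_1$ and $K_2$ share a gel this understates their
correlation -- a known limitation).  A $10^5$-draw Monte-Carlo at 5 %
input noise agrees with the Taylor value within 10 % (tested), and the
ratio tends to 1 as the noise shrinks.

# Simulating dissociation smear

`simulateLane()` implements the one-dimensional transport model used to
validate the division-line construction.  A complex dissociating at time
$t$ of a run of length $T$ migrates with the complex velocity until $t$
and with the DNA velocity afterwards, and diffuses with each state's
coefficient while in it, landing in a Gaussian with

$$\mu(t) = v_{\mathrm{PrD}}\,t + v_{\mathrm{D}}\,(T-t), \qquad
\sigma^2(t) = 2 D_{\mathrm{PrD}}\,t + 2 D_{\mathrm{D}}\,(T-t).$$

The smear is the integral of these Gaussians against the
exponential dissociation-time density $k_{\mathrm{off}}
e^{-k_{\mathrm{off}}t}$, evaluated by composite Simpson quadrature with
512 intervals (deterministic and refinable); re-association during the
run is neglected (the molecules lack proximity and buffer).  Mass is
conserved to $10^{-6}$ relative, the components are linear in the loaded
amounts, and as the diffusion coefficients vanish the smear tends to the
kinematic density $k_{\mathrm{off}} e^{-k_{\mathrm{off}}t(x)} |dt/dx|$ --
all tested.  `correctDivisionLine()` inverts the cumulative total to the
initial-amount split and returns the gap midpoint when the bands do not
overlap.

# The synthetic generator

`generateEMSA()` renders a complete scan from a `SyntheticTruth`: per-lane
equilibrium masses from the binding polynomial, Gaussian bands (migration
x lane width, with a 3 px well margin so neighbouring tracks never
touch), dissociation smear through the simulator above, an optional
constant ssDNA band, an affine background, the forward film law, a linear
step tablet (darker = lower gray), Gaussian scanner noise added in gray
space -- where real noise enters -- and 16-bit quantisation.  The
defaults describe one titration: 7 lanes of 30 px, no protein in lane 1
and a geometric series spanning $K[\mathrm{Pr}]$ from 0.1 to 10 across
lanes 2-7, constant DNA mass, band centres 140 px apart with
$\sigma = 8$ px (a well-resolved 600 dpi scan; about 1 mm bands),
$k_{\mathrm{off}}T = 0.1$ (mild dissociation, consistent with smear being
a 10-20 % -scale error source), DNA diffusing 1.5x faster than the
complex, film OD 0.06-1.6 exposed to a peak OD of 1.4, and a
signal-to-noise ratio of 30.

What the generator does *not* emulate: lane curvature ("smiling"), comb
distortion, spatially correlated film grain, depth-dependent blur, or
irreproducible staining response.  Passing tests therefore demonstrate
the correctness of the calibration, accounting, and error algebra under
the stated physics -- not robustness to every artifact of real gels,
which is what the artifact masks and manual overrides are for.

Calibration of the error bar is checked end to end: over 200 generated
titrations, the averaged $K$ lies within $1\sigma_{\mathrm{tot}}$ of the
truth in 60-75 % of runs and within $2\sigma_{\mathrm{tot}}$ in over
92 % -- the slight over-coverage relative to a normal interval reflects
the deliberately conservative, systematic treatment of the smear term.

# Problem sizes and reproducibility

The test suite and the acceptance script use scans of roughly
320 x 210 px, 200-seed recovery studies, a 75-point
(dissociation x separation x diffusion-ratio) grid for the
division-line property, $10^5$-$10^6$ Monte-Carlo draws, and 50-seed
paired designs; the full suite runs in well under a minute on one core.
Every random quantity is seeded, generation is bit-reproducible given the
seed, and a pipeline run is fully determined by (workbook, images,
config).

Two packaging conventions are worth noting.  Lane and band indices are
1-based everywhere (band 1 = free DNA); the continuous migration
coordinate starts at 0 with pixel $p$ covering $[p-1,p)$.  And the
metadata workbook is plain text: a directory holding a `Data.csv` sheet
(one row per experiment; the `Results.csv` sheet is written beside it),
with `.xlsx` workbooks carrying a 'Data' sheet read transparently when
readxl is installed.

# Known limitations

* The free protein concentration is taken equal to the added
  concentration; titrations where the DNA is not in large deficit need an
  external correction (out of scope by design).
* Binding isotherm fitting is deliberately absent: the per-lane ratio
  route yields a standard deviation, a fit does not.
* The smear error assumes the true division line lies between the
  selected bounds; grossly misplaced bounds invalidate it.
* Strongly overlapping bands (separation below ~10 band sigma) are
  outside the recipe's regime -- use manual division lines.
* $\sigma_{\mathrm{tech}}$ is only a remainder and can be floored to
  zero when the background term is over-estimated.
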