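# emsaquant

Densitometric quantification of electrophoretic mobility shift assays
(EMSAs), and of electrophoretic band intensities in general, from scanned
autoradiographs, stained gels and phosphorimages.

Most densitometry software treats the gray values of a scanned
autoradiograph as if they were proportional to the amount of labelled
material.  They are not: film density saturates with exposure between the
film's minimum density OD_min (fog) and its maximum OD_max, so raw
autoradiograph quantification is systematically non-linear.  emsaquant
corrects this by calibrating the scan in two steps — gray values to
optical densities through a step tablet scanned with the film, then
optical densities to relative concentrations by inverting the saturating
film law

    OD(E) = OD_min + (OD_max − OD_min) · (1 − e^(−cE)),
    CR(OD) = −ln[(OD_max − OD) / (OD_max − OD_min)]

— and then quantifies protein–DNA binding from the corrected image.  For a
titration with protein concentration [Pr] per lane, the stepwise
association constant at band interface *j* is estimated per lane as

    K_j = I(band j+1) / I(band j) / [Pr]

and averaged over the best lanes with a full error budget: background
non-uniformity and technical errors are random (measured by the standard
error of the mean), dissociation-smear errors are treated as systematic
(correlated over lanes), and the total is
σ_tot = sqrt(sem² + σ_smear²).  Cooperative binding constants for
two-site constructs follow as ω = K1·K2/(k1·k2) with first-order error
propagation.  A physical simulator of dissociation smear and a synthetic
EMSA generator with ground truth make every stage testable without a real
scan.

Intended users: molecular biologists quantifying EMSAs or band
intensities, and anyone needing equilibrium constants with defensible
error bars from gel images.

## Worked example

Generate a synthetic 7-lane titration (true K = 0.05 nM⁻¹, film response
OD 0.06–1.6, scanner noise at SNR ≈ 30, mild dissociation smear), write it
to disk as a scan + step tablet + metadata workbook, and run the full
pipeline on the files:

```r
library(emsaquant)

truth <- syntheticTruth(trueK = 0.05, seed = 42L)   # 1/nM
dir <- file.path(tempdir(), "demo")
writeSyntheticEMSA(truth, dir)

res <- runPipeline(dir, syntheticConfig(truth), "synthetic1")
res$summary
#> KSummary over lanes 3, 4, 5, 6, 7:
#>   mean K      = 0.05199 +/- 0.00102 (total)
#>   sem 0.000743 | sigma_bg 0.00278 | sigma_smear 0.000692 | tech 0

round(bandIntensities(res$table), 3)
#>        [,1]   [,2]
#> [1,] 15.507  0.135
#> [2,] 14.009  1.542
#> [3,] 12.491  3.222
#> [4,]  9.647  6.143
#> [5,]  5.956  9.779
#> [6,]  3.075 12.608
#> [7,]  1.285 14.087
```

Reading the output: column 1 is the free-DNA band (band 1, image bottom),
column 2 the complex band; the free DNA shifts into the complex as [Pr]
rises from 0 (lane 1) to 200 nM (lane 7).  The averaged constant,
0.0520 ± 0.0010 nM⁻¹, covers the true 0.05 nM⁻¹ within 2σ; lanes 1–2 were
excluded automatically — lane 1 has no protein (no K defined) and lane 2's
nearly invisible complex band carries an outlier error estimate.  The
`Results.csv` sheet written beside the workbook's `Data.csv` holds the
same numbers at full precision, including per-lane K values and error
components.

Individual stages are exported (`calibrateImage()`, `smoothImage()`,
`detectLanes()`, `laneProfiles()`, `subtractBackground()`, `findBound()`,
`bandTable()`, `subtractSsDNA()`, `stepwiseK()`, `summarizeK()`,
`omega()`, `simulateLane()`, …), and a thin command-line wrapper lives at
`inst/scripts/emsaquant.R`:

```sh
Rscript inst/scripts/emsaquant.R synth --seed 42 --out demo --template
Rscript inst/scripts/emsaquant.R kvalue --workbook demo --config demo/config.yaml
Rscript inst/scripts/emsaquant.R cooperativity --k1 1,0.05 --k2 1,0.05 --K1 2,0.1 --K2 2,0.1
```

See the vignette (`vignettes/emsaquant-methods.Rmd`) for the model, the
division-line construction under smear, the error algebra, and the design
decisions.

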