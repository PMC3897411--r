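# internal: pick the lane on which boundary pairs are selected -- the lane
# whose adjacent band regions are most balanced (division lines are easiest
# to place where neither band dominates)
.chooseSelectLane <- function(profiles, peaks) {
    v <- profiles@values
    outer <- profiles@outer
    edges <- c(outer[1L], (peaks[-1L] + peaks[-length(peaks)]) / 2,
               outer[2L])
    score <- vapply(seq_len(ncol(v)), function(lane) {
        ints <- vapply(seq_len(length(edges) - 1L), function(j)
            profileIntegral(v[, lane], edges[j], edges[j + 1L]), numeric(1))
        if (any(ints <= 0)) return(0)
        min(vapply(seq_len(length(ints) - 1L), function(j)
            min(ints[j], ints[j + 1L]) / max(ints[j], ints[j + 1L]),
            numeric(1)))
    }, numeric(1))
    which.max(score)
}

# recipe bounds applied lane by lane: each lane's pair brackets its own
# division line (the line moves with the lane's smear/DNA balance), which
# keeps the half-smear misassignment bound valid in every lane; lanes where
# the recipe fails inherit the most balanced lane's pairs
.perLanePairs <- function(profiles, peaks) {
    v <- profiles@values
    fallbackLane <- .chooseSelectLane(profiles, peaks)
    fallback <- selectBoundaryPairs(v[, fallbackLane], peaks)
    lapply(seq_len(ncol(v)), function(lane)
        tryCatch(selectBoundaryPairs(v[, lane], peaks),
                 error = function(e) fallback))
}

#' Quantify an EMSA scan in memory
#'
#' The full quantification chain on in-memory objects: smooth the raw scan,
#' calibrate, mask artifacts, locate lanes, build background-subtracted
#' lane profiles, place band-boundary pairs (explicit, or by the
#' upper/lower-bound recipe on a representative lane), integrate the band
#' table, apply ssDNA removal, and -- when protein concentrations are given
#' -- estimate the chosen stepwise constant per lane with its error budget
#' and average it.  [runPipeline()] wraps this with file and workbook I/O.
#'
#' @param raw numeric matrix of raw gray values (row 1 = image top).
#' @param sourceKind "autoradiograph", "gel" or "phosphorimage".
#' @param tablet [StepTablet-class] (autoradiograph/gel).
#' @param film [FilmModel-class] (autoradiograph).
#' @param nLanes number of lanes.
#' @param laneBoundaries optional explicit boundaries (else auto-detected).
#' @param artifacts list of artifact rectangles `c(x0, y0, x1, y1)`.
#' @param bgMethod,bgLeft,bgRight,bgRegion background subtraction; see
#'   [subtractBackground()].
#' @param nBands number of bands.
#' @param bandPeaks optional band peak positions (else auto-detected).
#' @param pairs optional list of [BoundaryPair-class] (else selected by
#'   [selectBoundaryPairs()] on `selectLane`).
#' @param selectLane lane for pair selection (default: most balanced lane).
#' @param ssdna optional list:
#'   `list(mode = "subtract", lane =, region =, target = list(type=, index=))`
#'   or `list(mode = "zero", region =)`.
#' @param prLane per-lane protein concentrations (molar); NULL for
#'   intensity-only mode.
#' @param kIndex interface index of the K value to estimate.
#' @param selectedLanes lanes averaged by [summarizeK()] (default: all
#'   lanes with a defined K).
#' @param nSites number of binding sites (widens the smear error).
#' @param reference optional reference [KSummary-class] for normalization.
#' @return list with `profiles`, `table`, `pairs`, `estimates`, `summary`
#'   (NULL in intensity-only mode), `layout` and `image`.
#' @export
analyzeScan <- function(raw, sourceKind, tablet = NULL, film = NULL,
                        nLanes, laneBoundaries = NULL, artifacts = list(),
                        bgMethod = "double_sided", bgLeft = NULL,
                        bgRight = NULL, bgRegion = NULL,
                        nBands, bandPeaks = NULL, pairs = NULL,
                        selectLane = NULL, ssdna = NULL,
                        prLane = NULL, kIndex = 1L, selectedLanes = NULL,
                        nSites = 1L, reference = NULL) {
    smoothRaw <- smoothImage(raw)
    img <- calibrateImage(smoothRaw, sourceKind, tablet = tablet,
                          film = film)
    if (length(artifacts)) img <- maskArtifacts(img, artifacts)
    layout <- detectLanes(img, nLanes, boundaries = laneBoundaries)
    profiles <- laneProfiles(img, layout)
    profiles <- subtractBackground(profiles, method = bgMethod,
                                   left = bgLeft, right = bgRight,
                                   img = img, region = bgRegion)
    if (!is.null(ssdna) && identical(ssdna$mode, "zero"))
        profiles <- zeroRegion(profiles, ssdna$region)
    if (is.null(pairs)) {
        if (nBands < 2L) stop("need at least 2 bands to place boundaries")
        if (is.null(bandPeaks))
            bandPeaks <- detectBandPeaks(profiles, nBands)
        if (!is.null(selectLane)) {
            pairs <- selectBoundaryPairs(profiles@values[, selectLane],
                                         bandPeaks)
        } else {
            pairs <- .perLanePairs(profiles, bandPeaks)
        }
    }
    table <- bandTable(profiles, pairs)
    if (!is.null(ssdna) && identical(ssdna$mode, "subtract"))
        table <- subtractSsDNA(table, profiles, ssdna$lane, ssdna$region,
                               ssdna$target)
    estimates <- NULL; summary <- NULL
    if (!is.null(prLane)) {
        if (length(prLane) != nLanes(layout))
            stop("prLane must have one concentration per lane")
        estimates <- lapply(seq_along(prLane), function(lane)
            laneKEstimate(profiles, table, lane, kIndex, prLane[lane],
                          nSites = nSites))
        if (is.null(selectedLanes))
            selectedLanes <- bestLanes(estimates)
        summary <- summarizeK(estimates, selectedLanes = selectedLanes,
                              reference = reference)
    }
    list(profiles = profiles, table = table, pairs = pairs,
         estimates = estimates, summary = summary, layout = layout,
         image = img)
}

.asPairs <- function(spec) {
    lapply(spec, function(p) {
        if (is(p, "BoundaryPair")) p
        else BoundaryPair(p$lower, p$upper)
    })
}

#' Run the pipeline for one experiment of a workbook
#'
#' Loads the experiment record from the workbook's 'Data' sheet, reads the
#' scan and step-tablet images, derives per-lane protein concentrations,
#' runs [analyzeScan()] under the selection config, and appends the result
#' to the 'Results' sheet.  Every formerly interactive choice is a config
#' field, so a run is fully reproducible from (workbook, images, config).
#'
#' @param workbook workbook directory (or Data.csv / .xlsx path).
#' @param config selection config: a YAML file path or an equivalent nested
#'   list with optional entries `lanes` (`boundaries`), `artifacts`,
#'   `background` (`method`, `left`, `right`, `region`), `bands` (`peaks`,
#'   `interfaces` as lower/upper lists, `select_lane`), `tablet`
#'   (`rectangles`), `ssdna`, `k` (`index`, `lanes`, `n_sites`),
#'   `intensity_only`.
#' @param experimentId row to analyze (default: the first).
#' @param reference optional [KSummary-class] for normalization.
#' @param writeSheet write the 'Results' sheet (default TRUE).
#' @return the [analyzeScan()] result list, invisibly.
#' @export
runPipeline <- function(workbook, config = list(), experimentId = NULL,
                        reference = NULL, writeSheet = TRUE) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    records <- loadDataSheet(workbook)
    if (is.null(experimentId)) experimentId <- names(records)[1L]
    rec <- records[[experimentId]]
    if (is.null(rec)) stop("no experiment '", experimentId, "' in workbook")
    base <- if (dir.exists(workbook)) workbook else dirname(workbook)
    resolve <- function(p) if (file.exists(p)) p else file.path(base, p)

    raw <- readGrayImage(resolve(rec$image))
    tablet <- NULL; film <- NULL
    if (rec$kind %in% c("autoradiograph", "gel")) {
        tabImg <- readGrayImage(resolve(rec$tabletImage))
        rects <- config$tablet$rectangles
        if (is.null(rects)) {           # equal step widths with margins
            ns <- length(rec$tabletOD)
            stepW <- ncol(tabImg) / ns
            rects <- lapply(seq_len(ns), function(i)
                c((i - 1) * stepW + stepW / 8, nrow(tabImg) / 10,
                  i * stepW - stepW / 8, nrow(tabImg) * 9 / 10))
        }
        tablet <- tabletFromImage(tabImg, rects, rec$tabletOD)
    }
    if (rec$kind == "autoradiograph")
        film <- FilmModel(rec$odMin, rec$odMax)

    prLane <- NULL
    intensityOnly <- isTRUE(config$intensity_only) ||
        length(rec$proteinVolumes) == 0L
    if (!intensityOnly)
        prLane <- vapply(rec$proteinVolumes, function(v)
            proteinConcentration(rec$stockConcentration, v,
                                 rec$totalVolume,
                                 molarWeight = rec$molarWeight,
                                 stockUnit = rec$stockUnit), numeric(1))

    bg <- config$background
    pairs <- if (!is.null(config$bands$interfaces))
        .asPairs(config$bands$interfaces) else NULL
    res <- analyzeScan(raw, rec$kind, tablet = tablet, film = film,
                       nLanes = rec$nLanes,
                       laneBoundaries = config$lanes$boundaries,
                       artifacts = config$artifacts %||% list(),
                       bgMethod = bg$method %||% "double_sided",
                       bgLeft = bg$left, bgRight = bg$right,
                       bgRegion = bg$region,
                       nBands = rec$nBands,
                       bandPeaks = config$bands$peaks,
                       pairs = pairs,
                       selectLane = config$bands$select_lane,
                       ssdna = config$ssdna,
                       prLane = prLane,
                       kIndex = config$k$index %||% 1L,
                       selectedLanes = config$k$lanes,
                       nSites = config$k$n_sites %||% 1L,
                       reference = reference)
    if (writeSheet) {
        if (is.null(res$summary))
            writeBandIntensities(workbook, res$table)
        else
            writeResults(workbook, stats::setNames(list(list(
                summary = res$summary, estimates = res$estimates,
                kIndex = config$k$index %||% 1L)), experimentId))
    }
    invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a synthetic EMSA to disk as a ready-to-run workbook
#'
#' Emits `scan.tif`, `tablet.tif`, a `Data.csv` sheet describing them and a
#' `truth.json` ground-truth record into a directory, so the full
#' file-based pipeline can be exercised end to end.  The protein volumes
#' are written such that the per-lane concentrations (in nM) equal the
#' truth's `prLane` with a 20 uL total volume and a 1 uM stock.
#'
#' @param truth a [SyntheticTruth-class].
#' @param dir output directory (created).
#' @return the directory, invisibly; side effect: four files.
#' @export
writeSyntheticEMSA <- function(truth, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    gen <- generateEMSA(truth)
    writeGrayImage(gen$scan, file.path(dir, "scan.tif"))
    writeGrayImage(gen$tabletImage, file.path(dir, "tablet.tif"))
    rec <- list(experimentId = "synthetic1", image = "scan.tif",
                kind = truth@sourceKind,
                nBands = length(truth@bandCenters),
                nLanes = length(truth@prLane),
                odMin = truth@film@odMin, odMax = truth@film@odMax,
                tabletImage = "tablet.tif", tabletOD = gen$tabletOD,
                molarWeight = NA_real_,
                stockConcentration = 1000,      # nM
                stockUnit = "molar",
                proteinVolumes = truth@prLane * 20 / 1000,
                totalVolume = 20)
    if (truth@sourceKind == "phosphorimage") {
        rec$odMin <- NA_real_; rec$odMax <- NA_real_
        rec$tabletImage <- NA_character_; rec$tabletOD <- numeric(0)
    }
    writeDataSheet(list(rec), dir)
    truthList <- list(trueK = truth@trueK, prLane = truth@prLane,
                      dnaMass = truth@dnaMass,
                      bandCenters = truth@bandCenters,
                      kOffT = truth@kOffT, snr = truth@snr,
                      seed = truth@seed,
                      laneBoundaries = gen$laneBoundaries,
                      bgLeft = gen$bgLeft, bgRight = gen$bgRight)
    jsonlite::write_json(truthList, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(dir)
}

#' Default selection config for a synthetic EMSA
#'
#' The config [runPipeline()] needs to analyze a [writeSyntheticEMSA()]
#' directory: true lane boundaries, the background flat-zone positions and
#' the band peak positions implied by the truth.
#'
#' @param truth the [SyntheticTruth-class].
#' @return a config list.
#' @export
syntheticConfig <- function(truth) {
    ctr <- truth@bandCenters
    list(lanes = list(boundaries = seq(0, length(truth@prLane) *
                                           truth@laneWidth,
                                       by = truth@laneWidth)),
         background = list(method = "double_sided",
                           left = ctr[1L] - 4 * truth@bandSigma - 5,
                           right = ctr[length(ctr)] +
                               4 * truth@bandSigma + 5),
         bands = list(peaks = ctr),
         k = list(index = 1L, n_sites = length(truth@trueK)))
}
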