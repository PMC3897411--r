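#' Read a grayscale scan
#'
#' Reads an 8- or 16-bit single-channel TIFF or PNG as a numeric matrix of
#' raw gray values (TIFF via native integer values; PNG values are scaled
#' to the 16-bit range; note PNG files written by [writeGrayImage()] carry
#' 8-bit precision).  Multi-channel images use the first channel with a
#' warning.
#'
#' @param path image file (.tif/.tiff/.png).
#' @return numeric matrix, row 1 = image top.
#' @export
readGrayImage <- function(path) {
    if (!file.exists(path)) stop("image not found: ", path)
    ext <- tolower(tools::file_ext(path))
    img <- switch(ext,
        tif = , tiff = tiff::readTIFF(path, as.is = TRUE),
        png = png::readPNG(path) * 65535,
        stop("unsupported image format: .", ext))
    if (length(dim(img)) == 3L) {
        warning("multi-channel image; using the first channel")
        img <- img[, , 1L]
    }
    img
}

#' Write a grayscale scan
#'
#' Writes a numeric matrix of 16-bit gray values as a single-channel TIFF
#' or PNG.
#'
#' @param img numeric matrix, values in 0..65535.
#' @param path output file (.tif/.tiff/.png).
#' @export
writeGrayImage <- function(img, path) {
    ext <- tolower(tools::file_ext(path))
    norm <- pmin(pmax(img / 65535, 0), 1)
    switch(ext,
        tif = , tiff = tiff::writeTIFF(norm, path, bits.per.sample = 16L),
        png = png::writePNG(norm, path),
        stop("unsupported image format: .", ext))
    invisible(path)
}

.dataColumns <- c("experiment_id", "image", "kind", "n_bands", "n_lanes",
                  "od_min", "od_max", "tablet_image", "tablet_od",
                  "molar_weight", "stock_concentration", "stock_unit",
                  "protein_volumes", "total_volume")

.splitNum <- function(x) {
    if (is.na(x) || !nzchar(x)) return(numeric(0))
    as.numeric(strsplit(as.character(x), ";")[[1L]])
}

.dataSheetPath <- function(workbook) {
    if (dir.exists(workbook)) return(file.path(workbook, "Data.csv"))
    workbook
}

#' Load the experiment metadata sheet
#'
#' The metadata workbook is a directory holding a `Data.csv` sheet (and
#' receiving a `Results.csv` sheet); a bare `.csv` file or an `.xlsx`
#' workbook with a sheet named 'Data' (read via readxl, if installed) is
#' also accepted.  Fixed column layout, one row per experiment:
#' `experiment_id`, `image`, `kind` (autoradiograph/gel/phosphorimage),
#' `n_bands`, `n_lanes`, `od_min`, `od_max` (autoradiograph),
#' `tablet_image`, `tablet_od` (semicolon-separated ODs; autoradiograph and
#' gel), `molar_weight`, `stock_concentration`, `stock_unit` ("molar" or
#' "mass_per_volume"), `protein_volumes` (semicolon-separated, one per
#' lane), `total_volume`.  Binding fields may be empty for intensity-only
#' experiments with `n_lanes` given.
#'
#' @param workbook directory, .csv or .xlsx path.
#' @return list of experiment records (named lists), named by id.
#' @export
loadDataSheet <- function(workbook) {
    path <- .dataSheetPath(workbook)
    if (!file.exists(path)) stop("no 'Data' sheet found at ", path)
    df <- if (tolower(tools::file_ext(path)) == "xlsx") {
        if (!requireNamespace("readxl", quietly = TRUE))
            stop("reading .xlsx requires the readxl package")
        as.data.frame(readxl::read_excel(path, sheet = "Data"))
    } else {
        utils::read.csv(path, stringsAsFactors = FALSE)
    }
    missingCols <- setdiff(.dataColumns, names(df))
    if (length(missingCols))
        stop("'Data' sheet is missing column(s): ",
             paste(missingCols, collapse = ", "))
    records <- lapply(seq_len(nrow(df)), function(i) {
        row <- df[i, ]
        cell <- function(col) sprintf("row %d, column '%s'", i, col)
        need <- function(col) {
            v <- row[[col]]
            if (is.na(v) || (is.character(v) && !nzchar(v)))
                stop("'Data' validation: missing value at ", cell(col))
            v
        }
        kind <- match.arg(need("kind"),
                          c("autoradiograph", "gel", "phosphorimage"))
        rec <- list(experimentId = as.character(need("experiment_id")),
                    image = as.character(need("image")),
                    kind = kind,
                    nBands = as.integer(need("n_bands")),
                    nLanes = if (!is.na(row$n_lanes))
                        as.integer(row$n_lanes) else NA_integer_,
                    odMin = NA_real_, odMax = NA_real_,
                    tabletImage = NA_character_, tabletOD = numeric(0),
                    molarWeight = suppressWarnings(
                        as.numeric(row$molar_weight)),
                    stockConcentration = suppressWarnings(
                        as.numeric(row$stock_concentration)),
                    stockUnit = if (!is.na(row$stock_unit) &&
                                    nzchar(row$stock_unit))
                        as.character(row$stock_unit) else "molar",
                    proteinVolumes = .splitNum(row$protein_volumes),
                    totalVolume = suppressWarnings(
                        as.numeric(row$total_volume)))
        if (kind == "autoradiograph") {
            rec$odMin <- as.numeric(need("od_min"))
            rec$odMax <- as.numeric(need("od_max"))
        }
        if (kind %in% c("autoradiograph", "gel")) {
            rec$tabletImage <- as.character(need("tablet_image"))
            rec$tabletOD <- .splitNum(need("tablet_od"))
        }
        hasBinding <- length(rec$proteinVolumes) > 0
        if (hasBinding) {
            if (is.na(rec$totalVolume))
                stop("'Data' validation: missing value at ",
                     cell("total_volume"))
            if (is.na(rec$stockConcentration))
                stop("'Data' validation: missing value at ",
                     cell("stock_concentration"))
            if (rec$stockUnit == "mass_per_volume" && is.na(rec$molarWeight))
                stop("'Data' validation: mass-based stock without ",
                     cell("molar_weight"))
            if (!is.na(rec$nLanes) &&
                length(rec$proteinVolumes) != rec$nLanes)
                stop("'Data' validation: protein_volumes length != n_lanes ",
                     "at ", cell("protein_volumes"))
            if (is.na(rec$nLanes))
                rec$nLanes <- length(rec$proteinVolumes)
        } else if (is.na(rec$nLanes)) {
            stop("'Data' validation: intensity-only experiments need ",
                 cell("n_lanes"))
        }
        rec
    })
    names(records) <- vapply(records, `[[`, character(1), "experimentId")
    records
}

#' Write experiment records to a 'Data' sheet
#'
#' Inverse of [loadDataSheet()]; used by the synthetic generator to emit a
#' ready-to-run workbook.
#'
#' @param records list of experiment records.
#' @param workbook directory (receives `Data.csv`) or .csv path.
#' @return the sheet path, invisibly.
#' @export
writeDataSheet <- function(records, workbook) {
    if (!grepl("[.]csv$", workbook))
        dir.create(workbook, showWarnings = FALSE, recursive = TRUE)
    path <- .dataSheetPath(workbook)
    join <- function(v) paste(v, collapse = ";")
    df <- do.call(rbind, lapply(records, function(r) data.frame(
        experiment_id = r$experimentId, image = r$image, kind = r$kind,
        n_bands = r$nBands, n_lanes = r$nLanes,
        od_min = r$odMin, od_max = r$odMax,
        tablet_image = r$tabletImage, tablet_od = join(r$tabletOD),
        molar_weight = r$molarWeight,
        stock_concentration = r$stockConcentration,
        stock_unit = r$stockUnit,
        protein_volumes = join(r$proteinVolumes),
        total_volume = r$totalVolume, stringsAsFactors = FALSE)))
    utils::write.csv(df, path, row.names = FALSE)
    invisible(path)
}

.resultsPath <- function(workbook) {
    if (dir.exists(workbook)) return(file.path(workbook, "Results.csv"))
    sub("Data[.]csv$", "Results.csv", workbook)
}

#' Write K summaries to the 'Results' sheet
#'
#' One row per experiment: the chosen K index, per-lane K values and error
#' components (semicolon-separated), the selected lanes, the averaged K
#' with its error decomposition, and the normalized value with its standard
#' deviation.  All numbers are written at full precision.
#'
#' @param workbook directory or Data.csv path (Results.csv lands beside it).
#' @param results named list (by experiment id); each element a list with
#'   `summary` (a [KSummary-class]), `estimates` (list of
#'   [LaneKEstimate-class]) and `kIndex`.
#' @return the sheet path, invisibly.
#' @export
writeResults <- function(workbook, results) {
    path <- .resultsPath(workbook)
    join <- function(v) paste(format(v, digits = 17, trim = TRUE),
                              collapse = ";")
    rows <- lapply(names(results), function(id) {
        res <- results[[id]]
        s <- res$summary
        ks <- vapply(res$estimates, function(e) e@k, numeric(1))
        data.frame(experiment_id = id, k_index = res$kIndex,
                   lane_k = join(ks),
                   lane_sigma_bg = join(vapply(res$estimates,
                                               function(e) e@sigmaBg,
                                               numeric(1))),
                   lane_sigma_smear = join(vapply(res$estimates,
                                                  function(e) e@sigmaSmear,
                                                  numeric(1))),
                   selected_lanes = join(s@selectedLanes),
                   mean_k = s@meanK, sem = s@sem,
                   sigma_bg_avg = s@sigmaBgAvg,
                   sigma_smear_avg = s@sigmaSmearAvg,
                   sigma_tech = s@sigmaTech, sigma_total = s@sigmaTotal,
                   normalized_k = s@normalizedK,
                   normalized_std = s@normalizedStd,
                   stringsAsFactors = FALSE)
    })
    fmt <- function(df) {                      # full precision in the CSV
        for (nm in names(df))
            if (is.numeric(df[[nm]]))
                df[[nm]] <- sprintf("%.17g", df[[nm]])
        df
    }
    rows <- lapply(rows, fmt)
    df <- if (length(rows)) do.call(rbind, rows) else
        stats::setNames(as.data.frame(matrix(nrow = 0, ncol = 14)),
                        c("experiment_id", "k_index", "lane_k",
                          "lane_sigma_bg", "lane_sigma_smear",
                          "selected_lanes", "mean_k", "sem", "sigma_bg_avg",
                          "sigma_smear_avg", "sigma_tech", "sigma_total",
                          "normalized_k", "normalized_std"))
    utils::write.csv(df, path, row.names = FALSE)
    invisible(path)
}

#' Write a band-intensity table to the 'Results' sheet
#'
#' Intensity-only mode (for example for stained protein gels, whose
#' staining response is not reliably invertible to amounts): band and smear
#' integrals per lane, no binding constants.
#'
#' @param workbook directory or Data.csv path.
#' @param table a [BandTable-class].
#' @return the sheet path, invisibly.
#' @export
writeBandIntensities <- function(workbook, table) {
    stopifnot(is(table, "BandTable"))
    path <- .resultsPath(workbook)
    nb <- ncol(table@intensity)
    df <- data.frame(lane = seq_len(nrow(table@intensity)))
    for (b in seq_len(nb)) df[[paste0("band_", b)]] <- table@intensity[, b]
    for (k in seq_len(ncol(table@smear)))
        df[[paste0("smear_", k)]] <- table@smear[, k]
    df$lane_sum <- table@laneSums
    utils::write.csv(df, path, row.names = FALSE)
    invisible(path)
}
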