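#' @include AllGenerics.R
NULL

#' Read a binary left-ventricle mask from a grayscale image
#'
#' Any nonzero pixel becomes foreground.  The file must decode to a
#' single-channel (grayscale) image; an image with no foreground pixel
#' is rejected, since every geometry operation requires a non-empty
#' mask.
#'
#' @param path path to an 8-bit grayscale PNG.
#' @param spacingMmPerPx pixel spacing, mm per pixel (EchoNet-style
#'   exports carry no calibration, so this is explicit configuration;
#'   default 1).
#' @param phase cardiac phase, `"ED"` or `"ES"`.
#' @param caseID case identifier (default: file name without extension).
#' @return an [LVMask-class].
#' @seealso [writeMask()]
#' @export
readMask <- function(path, spacingMmPerPx = 1, phase = "ED",
                     caseID = sub("\\.[^.]*$", "", basename(path))) {
    if (!file.exists(path))
        stop("mask file not found: ", path)
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) {
        if (dim(img)[3] > 1L)
            stop("multi-channel image is not a valid mask: ", path)
        img <- img[, , 1]
    }
    fg <- img > 0
    if (!any(fg))
        stop("mask has no foreground pixels: ", path)
    new("LVMask", pixels = fg, spacingMmPerPx = spacingMmPerPx,
        phase = phase, caseID = caseID)
}

#' Write a binary mask as an 8-bit grayscale PNG
#'
#' Foreground pixels are written as 255, background as 0, so
#' [readMask()] round-trips pixel-identically.
#'
#' @param mask an [LVMask-class].
#' @param path output path.
#' @return (invisibly) `path`.
#' @export
writeMask <- function(mask, path) {
    stopifnot(is(mask, "LVMask"))
    png::writePNG(ifelse(mask@pixels, 1, 0), path)
    invisible(path)
}

#' Read an EchoNet-dialect file list with per-case ground truth
#'
#' Expects a CSV whose header contains at least `FileName`, `EF`, `ESV`
#' and `EDV`; extra columns are ignored.  Case identifiers are the file
#' names without extension.
#'
#' @param path CSV path.
#' @return data frame with columns `case_id`, `ef_pct`, `edv_ml`,
#'   `esv_ml`, one row per input row in file order.
#' @export
readFileList <- function(path) {
    if (!file.exists(path))
        stop("file list not found: ", path)
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
    need <- c("FileName", "EF", "ESV", "EDV")
    missing <- setdiff(need, names(df))
    if (length(missing))
        stop("file list is missing required column(s): ",
             paste(missing, collapse = ", "))
    out <- data.frame(
        case_id = sub("\\.[^.]*$", "", df$FileName),
        ef_pct = as.numeric(df$EF),
        edv_ml = as.numeric(df$EDV),
        esv_ml = as.numeric(df$ESV),
        stringsAsFactors = FALSE)
    bad <- !is.finite(out$ef_pct) | !is.finite(out$edv_ml) |
        !is.finite(out$esv_ml)
    if (any(bad))
        stop("non-numeric EF/EDV/ESV in row(s): ",
             paste(which(bad), collapse = ", "))
    if (any(out$ef_pct < 0 | out$ef_pct > 100))
        stop("EF outside [0, 100] in row(s): ",
             paste(which(out$ef_pct < 0 | out$ef_pct > 100), collapse = ", "))
    if (any(out$edv_ml <= 0))
        stop("non-positive EDV in row(s): ",
             paste(which(out$edv_ml <= 0), collapse = ", "))
    out
}

#' Read an EchoNet-dialect volume-tracings table
#'
#' Expects a CSV with columns `FileName, X1, Y1, X2, Y2, Frame`: one
#' endocardial-border chord per row, grouped by case and frame, input
#' order preserved.  Extra columns are ignored.
#'
#' @param path CSV path.
#' @return data frame with columns `case_id`, `frame_index`, `x1`, `y1`,
#'   `x2`, `y2`.
#' @export
readTracings <- function(path) {
    if (!file.exists(path))
        stop("tracings table not found: ", path)
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
    need <- c("FileName", "X1", "Y1", "X2", "Y2", "Frame")
    missing <- setdiff(need, names(df))
    if (length(missing))
        stop("tracings table is missing required column(s): ",
             paste(missing, collapse = ", "))
    coord <- lapply(df[c("X1", "Y1", "X2", "Y2")],
                    function(v) suppressWarnings(as.numeric(v)))
    bad <- Reduce(`|`, lapply(coord, function(v) !is.finite(v)))
    if (any(bad))
        stop("non-numeric coordinate in row(s): ",
             paste(which(bad), collapse = ", "))
    out <- data.frame(
        case_id = sub("\\.[^.]*$", "", df$FileName),
        frame_index = as.integer(df$Frame),
        x1 = coord$X1, y1 = coord$Y1, x2 = coord$X2, y2 = coord$Y2,
        stringsAsFactors = FALSE)
    degenerate <- out$x1 == out$x2 & out$y1 == out$y2
    if (any(degenerate))
        stop("degenerate chord (identical endpoints) in row(s): ",
             paste(which(degenerate), collapse = ", "))
    out
}

#' Write a feature table to CSV
#'
#' Writes a regression feature table (see [assembleFeatures()] for the
#' column layout) with a deterministic column order and fixed 10
#' significant-digit formatting, so the file round-trips losslessly and
#' re-runs are byte-identical.
#'
#' @param rows data frame of feature rows (may be empty).
#' @param path output CSV path.
#' @return (invisibly) `path`.
#' @seealso [readFeatureTable()]
#' @export
writeFeatureTable <- function(rows, path) {
    stopifnot(is.data.frame(rows))
    out <- rows
    for (cc in names(out))
        if (is.numeric(out[[cc]]))
            out[[cc]] <- sprintf("%.10g", out[[cc]])
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read a feature table written by [writeFeatureTable()]
#'
#' @param path CSV path.
#' @return data frame with numeric feature columns.
#' @export
readFeatureTable <- function(path) {
    if (!file.exists(path))
        stop("feature table not found: ", path)
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
    for (cc in setdiff(names(df), "case_id"))
        df[[cc]] <- as.numeric(df[[cc]])
    df
}

#' Default run configuration
#'
#' The configuration consumed by the command-line entry points:
#' calibration, number of disks, regressor choice with its
#' hyperparameter grid, and seeds.
#'
#' @return named list of defaults.
#' @seealso [readRunConfig()], [defaultGrid()]
#' @export
defaultRunConfig <- function() {
    list(
        spacing_mm_per_px = 1.0,
        n_disks = 20L,
        seed = 1L,
        regressor = list(kind = "LR", cv_folds = 5L, grid = NULL),
        plots = FALSE
    )
}

#' Read a YAML run configuration, merged over the defaults
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides named list applied on top of the file values
#'   (command-line overrides).
#' @return named list with the same structure as [defaultRunConfig()].
#' @export
readRunConfig <- function(path = NULL, overrides = list()) {
    cfg <- defaultRunConfig()
    mergeList <- function(base, extra) {
        for (nm in names(extra)) {
            if (is.list(base[[nm]]) && is.list(extra[[nm]]))
                base[[nm]] <- mergeList(base[[nm]], extra[[nm]])
            else base[[nm]] <- extra[[nm]]
        }
        base
    }
    if (!is.null(path)) {
        if (!file.exists(path)) stop("config file not found: ", path)
        cfg <- mergeList(cfg, yaml::read_yaml(path))
    }
    cfg <- mergeList(cfg, overrides)
    if (!is.numeric(cfg$spacing_mm_per_px) || cfg$spacing_mm_per_px <= 0)
        stop("spacing_mm_per_px must be positive")
    if (!is.numeric(cfg$n_disks) || cfg$n_disks < 1)
        stop("n_disks must be >= 1")
    cfg$n_disks <- as.integer(cfg$n_disks)
    cfg$seed <- as.integer(cfg$seed)
    cfg
}

# Timestamped progress line on stderr (per-case logging for cohort runs).
logMsg <- function(fmt, ...) {
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%OS2"),
                    sprintf(fmt, ...)))
}
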