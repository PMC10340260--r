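#' @include AllClasses.R
NULL

#' Accessors for package classes
#'
#' Small accessor generics for the package's S4 classes, so user code
#' never touches slots directly.
#'
#' @param object an object of one of the package classes.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("maskPixels", function(object) standardGeneric("maskPixels"))
#' @rdname accessors
#' @export
setGeneric("spacingMmPerPx", function(object) standardGeneric("spacingMmPerPx"))
#' @rdname accessors
#' @export
setGeneric("cardiacPhase", function(object) standardGeneric("cardiacPhase"))
#' @rdname accessors
#' @export
setGeneric("caseID", function(object) standardGeneric("caseID"))
#' @rdname accessors
#' @export
setGeneric("diameters", function(object) standardGeneric("diameters"))
#' @rdname accessors
#' @export
setGeneric("diskHeight", function(object) standardGeneric("diskHeight"))
#' @rdname accessors
#' @export
setGeneric("axisLength", function(object) standardGeneric("axisLength"))
#' @rdname accessors
#' @export
setGeneric("nDisks", function(object) standardGeneric("nDisks"))
#' @rdname accessors
#' @export
setGeneric("edv", function(object) standardGeneric("edv"))
#' @rdname accessors
#' @export
setGeneric("esv", function(object) standardGeneric("esv"))
#' @rdname accessors
#' @export
setGeneric("lvef", function(object) standardGeneric("lvef"))
#' @rdname accessors
#' @export
setGeneric("apexPoint", function(object) standardGeneric("apexPoint"))
#' @rdname accessors
#' @export
setGeneric("mitralMidPoint", function(object) standardGeneric("mitralMidPoint"))
#' @rdname accessors
#' @export
setGeneric("axisUnit", function(object) standardGeneric("axisUnit"))

#' @rdname accessors
#' @export
setMethod("maskPixels", "LVMask", function(object) object@pixels)
#' @rdname accessors
#' @export
setMethod("spacingMmPerPx", "LVMask", function(object) object@spacingMmPerPx)
#' @rdname accessors
#' @export
setMethod("cardiacPhase", "LVMask", function(object) object@phase)
#' @rdname accessors
#' @export
setMethod("caseID", "LVMask", function(object) object@caseID)
#' @rdname accessors
#' @export
setMethod("caseID", "SyntheticCase", function(object) object@caseID)

#' @rdname accessors
#' @export
setMethod("diameters", "DiskProfile", function(object) object@diametersMm)
#' @rdname accessors
#' @export
setMethod("diskHeight", "DiskProfile", function(object) object@diskHeightMm)
#' @rdname accessors
#' @export
setMethod("axisLength", "DiskProfile", function(object) object@axisLengthMm)
#' @rdname accessors
#' @export
setMethod("axisLength", "LVShape", function(object) object@axisLengthMm)
#' @rdname accessors
#' @export
setMethod("axisLength", "Landmarks", function(object) object@axisLengthPx)
#' @rdname accessors
#' @export
setMethod("nDisks", "DiskProfile", function(object) object@nDisks)

#' @rdname accessors
#' @export
setMethod("edv", "VolumeEstimate", function(object) object@edvMl)
#' @rdname accessors
#' @export
setMethod("esv", "VolumeEstimate", function(object) object@esvMl)
#' @rdname accessors
#' @export
setMethod("lvef", "VolumeEstimate", function(object) object@lvefPct)
#' @rdname accessors
#' @export
setMethod("edv", "SyntheticCase", function(object) object@trueEdvMl)
#' @rdname accessors
#' @export
setMethod("esv", "SyntheticCase", function(object) object@trueEsvMl)
#' @rdname accessors
#' @export
setMethod("lvef", "SyntheticCase", function(object) object@trueEfPct)

#' @rdname accessors
#' @export
setMethod("apexPoint", "Landmarks", function(object) object@apex)
#' @rdname accessors
#' @export
setMethod("mitralMidPoint", "Landmarks", function(object) object@mitralMid)
#' @rdname accessors
#' @export
setMethod("axisUnit", "Landmarks", function(object) object@axisUnit)

setMethod("show", "LVShape", function(object) {
    cat(sprintf(
        "LVShape: L = %.2f mm, basal r = %.2f mm, p = %.3g, taper = %.3g\n",
        object@axisLengthMm, object@basalRadiusMm,
        object@profileExponent, object@apexTaper))
    invisible(NULL)
})

setMethod("show", "LVMask", function(object) {
    d <- dim(object@pixels)
    cat(sprintf(
        "LVMask '%s' [%s]: %d x %d px, %.3g mm/px, %d foreground px\n",
        object@caseID, object@phase, d[2], d[1],
        object@spacingMmPerPx, sum(object@pixels)))
    invisible(NULL)
})

setMethod("show", "Landmarks", function(object) {
    cat(sprintf(
        "Landmarks: apex (%.1f, %.1f), mitral mid (%.1f, %.1f), L = %.1f px\n",
        object@apex[1], object@apex[2],
        object@mitralMid[1], object@mitralMid[2], object@axisLengthPx))
    invisible(NULL)
})

setMethod("show", "DiskProfile", function(object) {
    cat(sprintf(
        "DiskProfile: %d disks, L = %.2f mm, l = %.3f mm\n",
        object@nDisks, object@axisLengthMm, object@diskHeightMm))
    cat("  diameters (base -> apex, mm): ",
        paste(sprintf("%.1f", object@diametersMm), collapse = " "), "\n")
    invisible(NULL)
})

setMethod("show", "VolumeEstimate", function(object) {
    cat(sprintf("VolumeEstimate: EDV %.2f mL, ESV %.2f mL, LVEF %.2f%%\n",
        object@edvMl, object@esvMl, object@lvefPct))
    invisible(NULL)
})

setMethod("show", "AgreementReport", function(object) {
    cat(sprintf(
        paste0("AgreementReport (n = %d):\n",
               "  MAE %.4g  RMSE %.4g  Corr %.4g\n",
               "  bias %.4g  LoA [%.4g, %.4g]\n"),
        object@n, object@mae, object@rmse, object@corr,
        object@bias, object@loaLow, object@loaHigh))
    invisible(NULL)
})

setMethod("show", "SyntheticCase", function(object) {
    cat(sprintf(
        paste0("SyntheticCase '%s': EDV %.2f mL, ESV %.2f mL, EF %.2f%%\n",
               "  %.3g mm/px, %d x %d px, rot %.1f deg, seed %d\n"),
        object@caseID, object@trueEdvMl, object@trueEsvMl, object@trueEfPct,
        object@spacingMmPerPx, object@imageSizePx[1], object@imageSizePx[2],
        object@rotationDeg, object@seed))
    invisible(NULL)
})
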