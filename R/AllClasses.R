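#' @import methods
NULL

#' Parametric left-ventricle shape
#'
#' A solid of revolution standing in for the left ventricle.  The radius
#' profile along the long axis is \eqn{\rho(x) = r (1 - (x/L)^2)^{p/2}}
#' with \eqn{x} the distance from the mitral (basal) plane, so the shape
#' is widest at the base and tapers to a point at the apex.  \eqn{p = 1}
#' gives a half prolate spheroid whose volume has the closed form
#' \eqn{(2/3)\pi r^2 L}; other exponents give blunter (\eqn{p < 1}) or
#' more bullet-like (\eqn{p > 1}) chambers.
#'
#' @slot axisLengthMm positive length \eqn{L} of the long (major) axis, mm.
#' @slot basalRadiusMm positive radius \eqn{r} at the mitral plane, mm.
#' @slot profileExponent positive exponent \eqn{p} of the radius profile.
#' @slot apexTaper asymmetry factor in \eqn{[0, 1]}: the lateral radius on
#'   one side of the axis is multiplied by \eqn{1 - \mathrm{taper}\cdot x/L},
#'   so 0 keeps the silhouette symmetric.  Asymmetric shapes have no
#'   closed-form revolved volume and are only used for rendering.
#'
#' @seealso [lvShape()], [analyticVolume()], [renderMask()]
#' @export
setClass("LVShape",
    representation(
        axisLengthMm    = "numeric",
        basalRadiusMm   = "numeric",
        profileExponent = "numeric",
        apexTaper       = "numeric"
    ),
    prototype(profileExponent = 1, apexTaper = 0)
)

setValidity("LVShape", function(object) {
    msg <- character()
    if (length(object@axisLengthMm) != 1L || !is.finite(object@axisLengthMm) ||
        object@axisLengthMm <= 0)
        msg <- c(msg, "axisLengthMm must be a single positive number")
    if (length(object@basalRadiusMm) != 1L || !is.finite(object@basalRadiusMm) ||
        object@basalRadiusMm <= 0)
        msg <- c(msg, "basalRadiusMm must be a single positive number")
    if (length(object@profileExponent) != 1L || !is.finite(object@profileExponent) ||
        object@profileExponent <= 0)
        msg <- c(msg, "profileExponent must be a single positive number")
    if (length(object@apexTaper) != 1L || !is.finite(object@apexTaper) ||
        object@apexTaper < 0 || object@apexTaper > 1)
        msg <- c(msg, "apexTaper must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Binary left-ventricle segmentation mask
#'
#' A binary pixel grid with physical calibration and cardiac phase.
#' Pixels are stored as a logical matrix indexed `[row, col]`; the
#' package-wide coordinate convention is x = column index, y = row index,
#' both 0-based, with pixel centers at integer coordinates and the y axis
#' pointing down (image convention).
#'
#' @slot pixels logical matrix, `TRUE` = left-ventricle foreground.
#' @slot spacingMmPerPx positive pixel spacing, mm per pixel.
#' @slot phase cardiac phase, `"ED"` (end-diastole) or `"ES"` (end-systole).
#' @slot caseID case identifier.
#'
#' @seealso [readMask()], [renderMask()], [extractContour()]
#' @export
setClass("LVMask",
    representation(
        pixels         = "matrix",
        spacingMmPerPx = "numeric",
        phase          = "character",
        caseID         = "character"
    ),
    prototype(spacingMmPerPx = 1, phase = "ED", caseID = "")
)

setValidity("LVMask", function(object) {
    msg <- character()
    if (!is.logical(object@pixels))
        msg <- c(msg, "pixels must be a logical matrix")
    if (length(object@spacingMmPerPx) != 1L || !is.finite(object@spacingMmPerPx) ||
        object@spacingMmPerPx <= 0)
        msg <- c(msg, "spacingMmPerPx must be a single positive number")
    if (length(object@phase) != 1L || !(object@phase %in% c("ED", "ES")))
        msg <- c(msg, "phase must be \"ED\" or \"ES\"")
    if (length(msg)) msg else TRUE
})

#' Left-ventricle landmarks
#'
#' Apex and mitral-valve midpoint located on a mask contour, and the
#' major axis they define.  Coordinates follow the package pixel
#' convention (x = column, y = row, 0-based).
#'
#' @slot apex numeric length-2, (x, y) of the apical landmark, pixels.
#' @slot mitralMid numeric length-2, (x, y) of the mitral-plane midpoint.
#' @slot axisLengthPx positive Euclidean distance apex to mitral midpoint.
#' @slot axisUnit numeric length-2 unit vector pointing apex -> base.
#'
#' @seealso [localizeLandmarks()], [placeDisks()], [measureDiameters()]
#' @export
setClass("Landmarks",
    representation(
        apex         = "numeric",
        mitralMid    = "numeric",
        axisLengthPx = "numeric",
        axisUnit     = "numeric"
    )
)

setValidity("Landmarks", function(object) {
    msg <- character()
    if (length(object@apex) != 2L || !all(is.finite(object@apex)))
        msg <- c(msg, "apex must be a finite (x, y) pair")
    if (length(object@mitralMid) != 2L || !all(is.finite(object@mitralMid)))
        msg <- c(msg, "mitralMid must be a finite (x, y) pair")
    if (length(object@axisLengthPx) != 1L || !is.finite(object@axisLengthPx) ||
        object@axisLengthPx <= 0)
        msg <- c(msg, "axisLengthPx must be a single positive number")
    d <- sqrt(sum((object@apex - object@mitralMid)^2))
    if (length(msg) == 0L && abs(d - object@axisLengthPx) > 1e-6 * max(1, d))
        msg <- c(msg, "axisLengthPx must equal distance(apex, mitralMid)")
    if (length(object@axisUnit) != 2L ||
        abs(sqrt(sum(object@axisUnit^2)) - 1) > 1e-6)
        msg <- c(msg, "axisUnit must be a unit vector")
    if (length(msg)) msg else TRUE
})

#' Method-of-disks diameter profile
#'
#' The per-disk diameters measured perpendicular to the left-ventricular
#' major axis, ordered from the mitral base toward the apex, together
#' with the disk height \eqn{l = L/n} and the axis length \eqn{L}.
#'
#' @slot diametersMm numeric vector of n disk diameters \eqn{a_i \ge 0}, mm,
#'   ordered base -> apex.
#' @slot diskHeightMm disk height \eqn{l = L/n}, mm.
#' @slot axisLengthMm major-axis length \eqn{L}, mm.
#' @slot nDisks number of disks (clinical default 20).
#'
#' @seealso [measureDiameters()], [simpsonVolume()]
#' @export
setClass("DiskProfile",
    representation(
        diametersMm  = "numeric",
        diskHeightMm = "numeric",
        axisLengthMm = "numeric",
        nDisks       = "integer"
    )
)

setValidity("DiskProfile", function(object) {
    msg <- character()
    if (length(object@nDisks) != 1L || object@nDisks < 1L)
        msg <- c(msg, "nDisks must be a single integer >= 1")
    if (length(object@diametersMm) != object@nDisks)
        msg <- c(msg, "length(diametersMm) must equal nDisks")
    if (any(!is.finite(object@diametersMm)) || any(object@diametersMm < 0))
        msg <- c(msg, "diametersMm must be finite and >= 0")
    if (length(object@axisLengthMm) != 1L || object@axisLengthMm <= 0)
        msg <- c(msg, "axisLengthMm must be positive")
    if (length(msg) == 0L &&
        abs(object@diskHeightMm * object@nDisks - object@axisLengthMm) >
            1e-9 * object@axisLengthMm)
        msg <- c(msg, "diskHeightMm * nDisks must equal axisLengthMm")
    if (length(msg)) msg else TRUE
})

#' Left-ventricular volumes and ejection fraction
#'
#' @slot edvMl end-diastolic volume, mL.
#' @slot esvMl end-systolic volume, mL.
#' @slot lvefPct ejection fraction, percent:
#'   \eqn{\mathrm{LVEF} = (\mathrm{EDV} - \mathrm{ESV}) / \mathrm{EDV} \times 100}.
#'
#' @seealso [simpsonEFFromMasks()], [ejectionFraction()]
#' @export
setClass("VolumeEstimate",
    representation(
        edvMl   = "numeric",
        esvMl   = "numeric",
        lvefPct = "numeric"
    )
)

setValidity("VolumeEstimate", function(object) {
    msg <- character()
    if (length(object@edvMl) != 1L || !is.finite(object@edvMl) || object@edvMl < 0)
        msg <- c(msg, "edvMl must be a single number >= 0")
    if (length(object@esvMl) != 1L || !is.finite(object@esvMl) || object@esvMl < 0)
        msg <- c(msg, "esvMl must be a single number >= 0")
    if (length(msg) == 0L && object@edvMl > 0) {
        ef <- (object@edvMl - object@esvMl) / object@edvMl * 100
        if (abs(ef - object@lvefPct) > 1e-6)
            msg <- c(msg, "lvefPct inconsistent with (EDV - ESV)/EDV * 100")
    }
    if (length(msg)) msg else TRUE
})

#' Agreement statistics between predicted and reference series
#'
#' Cohort-level agreement between predicted and ground-truth values:
#' mean absolute error, root mean squared error, Pearson correlation,
#' and Bland-Altman bias with limits of agreement at
#' \eqn{\pm 1.96} standard deviations of the paired differences.
#'
#' @slot mae mean absolute error.
#' @slot rmse root mean squared error.
#' @slot corr Pearson correlation (NA for constant series).
#' @slot bias mean difference, predicted minus truth.
#' @slot loaLow,loaHigh Bland-Altman limits of agreement,
#'   \eqn{\mathrm{bias} \mp 1.96\,\mathrm{SD}} of the differences
#'   (sample SD, \eqn{n - 1} denominator).
#' @slot n number of paired observations.
#'
#' @seealso [regressionMetrics()], [blandAltmanPlot()]
#' @export
setClass("AgreementReport",
    representation(
        mae     = "numeric",
        rmse    = "numeric",
        corr    = "numeric",
        bias    = "numeric",
        loaLow  = "numeric",
        loaHigh = "numeric",
        n       = "integer"
    )
)

setValidity("AgreementReport", function(object) {
    msg <- character()
    if (object@rmse < object@mae - 1e-9)
        msg <- c(msg, "rmse must be >= mae")
    if (object@mae < 0)
        msg <- c(msg, "mae must be >= 0")
    if (!is.na(object@corr) && (object@corr < -1 - 1e-9 || object@corr > 1 + 1e-9))
        msg <- c(msg, "corr must lie in [-1, 1]")
    if (object@loaLow > object@bias + 1e-9 || object@loaHigh < object@bias - 1e-9)
        msg <- c(msg, "limits of agreement must bracket the bias")
    if (length(msg)) msg else TRUE
})

#' Synthetic left-ventricle case with exact ground truth
#'
#' An end-diastolic / end-systolic shape pair with analytically known
#' volumes and ejection fraction, plus the pose and calibration used to
#' rasterize the pair into masks.
#'
#' @slot caseID case identifier.
#' @slot edShape,esShape [LVShape-class] at end-diastole / end-systole.
#' @slot trueEdvMl,trueEsvMl analytic volumes, mL.
#' @slot trueEfPct analytic ejection fraction, percent.
#' @slot rotationDeg in-plane rotation applied at rendering, degrees.
#' @slot translationPx (x, y) translation applied at rendering, pixels.
#' @slot spacingMmPerPx pixel spacing, mm per pixel.
#' @slot imageSizePx (width, height) of the rendered canvas, pixels.
#' @slot seed per-case random seed.
#'
#' @seealso [makeCase()], [makeDataset()], [renderCase()]
#' @export
setClass("SyntheticCase",
    representation(
        caseID         = "character",
        edShape        = "LVShape",
        esShape        = "LVShape",
        trueEdvMl      = "numeric",
        trueEsvMl      = "numeric",
        trueEfPct      = "numeric",
        rotationDeg    = "numeric",
        translationPx  = "numeric",
        spacingMmPerPx = "numeric",
        imageSizePx    = "integer",
        seed           = "integer"
    )
)

setValidity("SyntheticCase", function(object) {
    msg <- character()
    if (object@trueEdvMl <= 0)
        msg <- c(msg, "trueEdvMl must be positive")
    if (object@trueEsvMl >= object@trueEdvMl)
        msg <- c(msg, "trueEsvMl must be smaller than trueEdvMl")
    ef <- (object@trueEdvMl - object@trueEsvMl) / object@trueEdvMl * 100
    if (abs(ef - object@trueEfPct) > 1e-9)
        msg <- c(msg, "trueEfPct inconsistent with (EDV - ESV)/EDV * 100")
    if (object@trueEfPct < 0 || object@trueEfPct > 100)
        msg <- c(msg, "trueEfPct must lie in [0, 100]")
    if (length(object@imageSizePx) != 2L || any(object@imageSizePx < 1L))
        msg <- c(msg, "imageSizePx must be two positive integers")
    if (object@spacingMmPerPx <= 0)
        msg <- c(msg, "spacingMmPerPx must be positive")
    if (length(msg)) msg else TRUE
})
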