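#' @include AllGenerics.R
NULL

#' Volume of a single elliptical disk
#'
#' Method-of-disks element: an elliptical slab with full diameters
#' \eqn{a_i} (apical four-chamber view) and \eqn{b_i} (apical
#' two-chamber view) and height \eqn{l} has volume
#' \eqn{\pi a_i b_i l / 4} (the ellipse area is
#' \eqn{\pi (a/2)(b/2) = \pi a b / 4}).
#'
#' @param aMm,bMm full disk diameters in the two orthogonal views, mm.
#' @param lMm disk height, mm.
#' @return disk volume in mm^3.
#' @examples
#' diskVolume(2, 2, 1)  # pi
#' @export
diskVolume <- function(aMm, bMm, lMm) {
    if (any(aMm < 0) || any(bMm < 0) || any(lMm < 0))
        stop("diameters and height must be non-negative")
    pi * aMm * bMm * lMm / 4
}

#' Simpson's method-of-disks chamber volume
#'
#' Sums the elliptical disk volumes over a diameter profile.  The
#' biplane form uses diameters from two orthogonal apical views,
#' \eqn{V = \sum_i \pi a_i b_i l / 4}; when only the four-chamber view
#' is available the monoplane form assumes circular disks
#' (\eqn{b_i = a_i}), \eqn{V = \sum_i \pi a_i^2 l / 4}.
#'
#' @param profile a [DiskProfile-class] (apical four-chamber).
#' @param mode `"monoplane"` (default) or `"biplane"`.
#' @param profileB second-view [DiskProfile-class] for biplane mode;
#'   must have the same number of disks and an axis length within 5 %.
#' @return chamber volume in mL (1000 mm^3 = 1 mL).
#' @examples
#' # cylinder of diameter 30 mm, length 80 mm
#' p <- new("DiskProfile", diametersMm = rep(30, 20), diskHeightMm = 4,
#'          axisLengthMm = 80, nDisks = 20L)
#' simpsonVolume(p)  # pi * 30^2 * 80 / 4 / 1000
#' @export
simpsonVolume <- function(profile, mode = c("monoplane", "biplane"),
                          profileB = NULL) {
    stopifnot(is(profile, "DiskProfile"))
    mode <- match.arg(mode)
    a <- profile@diametersMm
    l <- profile@diskHeightMm
    if (mode == "monoplane") {
        b <- a
    } else {
        if (is.null(profileB) || !is(profileB, "DiskProfile"))
            stop("biplane mode requires a second DiskProfile")
        if (profileB@nDisks != profile@nDisks)
            stop("biplane profiles must have the same number of disks")
        if (abs(profileB@axisLengthMm - profile@axisLengthMm) >
            0.05 * profile@axisLengthMm)
            stop("biplane axis lengths differ by more than 5%")
        b <- profileB@diametersMm
    }
    sum(diskVolume(a, b, l)) / 1000
}

#' Ejection fraction from end-diastolic and end-systolic volumes
#'
#' \eqn{\mathrm{LVEF} = (\mathrm{EDV} - \mathrm{ESV})/\mathrm{EDV}
#' \times 100}.  A negative result (ESV exceeding EDV, e.g. from a
#' mislabeled frame pair) is returned with a warning rather than an
#' error.
#'
#' @param edvMl end-diastolic volume, mL (> 0).
#' @param esvMl end-systolic volume, mL (>= 0).
#' @return ejection fraction, percent.
#' @examples
#' ejectionFraction(100, 40)  # 60
#' @export
ejectionFraction <- function(edvMl, esvMl) {
    if (!is.finite(edvMl) || edvMl <= 0)
        stop("edvMl must be positive")
    if (!is.finite(esvMl) || esvMl < 0)
        stop("esvMl must be non-negative")
    ef <- (edvMl - esvMl) / edvMl * 100
    if (ef < 0)
        warning("negative ejection fraction: ESV exceeds EDV")
    ef
}

#' Direct Simpson's-method LVEF from a mask pair
#'
#' The clinical monoplane workflow on segmented frames: contour
#' extraction, apex / mitral-midpoint localization, per-disk diameter
#' measurement and monoplane method-of-disks volumes for each frame,
#' then the ejection fraction.  Each frame uses its own major-axis
#' length and disk height.
#'
#' @param edMask end-diastolic [LVMask-class].
#' @param esMask end-systolic [LVMask-class].
#' @param nDisks number of disks (clinical default 20).
#' @return a [VolumeEstimate-class].
#' @export
simpsonEFFromMasks <- function(edMask, esMask, nDisks = 20L) {
    stopifnot(is(edMask, "LVMask"), is(esMask, "LVMask"))
    if (edMask@spacingMmPerPx != esMask@spacingMmPerPx)
        stop("ED and ES masks must share the same pixel spacing")
    vol1 <- function(mask) {
        lm <- localizeLandmarks(extractContour(mask))
        simpsonVolume(measureDiameters(mask, lm, nDisks))
    }
    edv <- vol1(edMask)
    esv <- vol1(esMask)
    new("VolumeEstimate", edvMl = edv, esvMl = esv,
        lvefPct = (edv - esv) / edv * 100)
}
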