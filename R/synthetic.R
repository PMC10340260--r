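#' @include AllGenerics.R
NULL

# Run expr with a fixed seed, restoring the caller's RNG state afterwards.
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

#' Construct a parametric left-ventricle shape
#'
#' @param axisLengthMm long-axis length L, mm.
#' @param basalRadiusMm radius r at the mitral (basal) plane, mm.
#' @param profileExponent radius-profile exponent p;
#'   `p = 1` is a half prolate spheroid (closed-form volume).
#' @param apexTaper one-sided asymmetry factor in \eqn{[0, 1]} (0 = symmetric).
#' @return an [LVShape-class] object.
#' @examples
#' lvShape(80, 20)
#' @export
lvShape <- function(axisLengthMm, basalRadiusMm, profileExponent = 1,
                    apexTaper = 0) {
    new("LVShape",
        axisLengthMm = as.numeric(axisLengthMm),
        basalRadiusMm = as.numeric(basalRadiusMm),
        profileExponent = as.numeric(profileExponent),
        apexTaper = as.numeric(apexTaper))
}

# Radius of the revolved profile at distance x (mm) from the basal plane.
radiusProfileMm <- function(shape, xFromBaseMm) {
    L <- shape@axisLengthMm
    u <- pmin(pmax(xFromBaseMm / L, 0), 1)
    shape@basalRadiusMm * (1 - u^2)^(shape@profileExponent / 2)
}

#' Analytic volume of a left-ventricle shape
#'
#' Volume of the solid of revolution defined by the shape's radius
#' profile.  For `profileExponent = 1` the closed form
#' \eqn{V = (2/3)\pi r^2 L} is used; otherwise the revolution integral
#' \eqn{\int_0^L \pi \rho(x)^2 dx} is evaluated with a high-resolution
#' midpoint rule.
#'
#' @param shape an [LVShape-class].
#' @param nSlices number of midpoint-rule slices for non-spheroidal
#'   exponents (default 20000).
#' @return volume in mL.
#' @examples
#' analyticVolume(lvShape(80, 20))  # (2/3) * pi * 400 * 80 / 1000 ~= 67 mL
#' @export
analyticVolume <- function(shape, nSlices = 20000L) {
    stopifnot(is(shape, "LVShape"))
    validObject(shape)
    if (shape@apexTaper != 0)
        stop("analytic volume is defined for symmetric shapes (apexTaper = 0)")
    L <- shape@axisLengthMm
    r <- shape@basalRadiusMm
    if (shape@profileExponent == 1)
        return((2 / 3) * pi * r^2 * L / 1000)
    x <- (seq_len(nSlices) - 0.5) / nSlices * L
    sum(pi * radiusProfileMm(shape, x)^2) * (L / nSlices) / 1000
}

# Analytic area of the 2-D silhouette (mm^2); pi*r*L/2 for p = 1.
silhouetteAreaMm2 <- function(shape, nSlices = 20000L) {
    L <- shape@axisLengthMm
    x <- (seq_len(nSlices) - 0.5) / nSlices * L
    rho <- radiusProfileMm(shape, x)
    taperMult <- 1 - shape@apexTaper * (x / L)
    sum(rho + rho * taperMult) * (L / nSlices)
}

#' Rasterize a left-ventricle shape into a binary mask
#'
#' Renders the 2-D silhouette of the shape onto a pixel canvas.  The
#' canonical pose is apex-up (apical four-chamber display convention)
#' with the shape centered on the canvas; `rotationDeg` rotates the
#' silhouette about the canvas center in the pixel frame and
#' `translationPx` shifts it.  Optional Gaussian radial jitter of the
#' contour (standard deviation `jitterSdMm`, sampled at 64 axial knots
#' and linearly interpolated) emulates imperfect segmentations; the
#' default is noiseless.
#'
#' @param shape an [LVShape-class].
#' @param rotationDeg in-plane rotation, degrees.
#' @param translationPx numeric length-2 (x, y) shift in pixels.
#' @param spacingMmPerPx pixel spacing, mm per pixel.
#' @param imageSizePx integer length-2 (width, height) of the canvas.
#' @param jitterSdMm standard deviation of contour jitter, mm (0 = off).
#' @param seed seed for the jitter noise (required when `jitterSdMm > 0`).
#' @param phase cardiac phase tag for the resulting mask.
#' @param caseID case identifier tag.
#' @return an [LVMask-class].
#' @examples
#' m <- renderMask(lvShape(40, 12), spacingMmPerPx = 0.5)
#' sum(maskPixels(m))
#' @export
renderMask <- function(shape, rotationDeg = 0, translationPx = c(0, 0),
                       spacingMmPerPx = 1, imageSizePx = c(112L, 112L),
                       jitterSdMm = 0, seed = NULL,
                       phase = "ED", caseID = "") {
    stopifnot(is(shape, "LVShape"))
    validObject(shape)
    W <- as.integer(imageSizePx[1]); H <- as.integer(imageSizePx[2])
    Lpx <- shape@axisLengthMm / spacingMmPerPx
    rpx <- shape@basalRadiusMm / spacingMmPerPx
    cx <- (W - 1) / 2 + translationPx[1]
    cy <- (H - 1) / 2 + translationPx[2]
    th <- rotationDeg * pi / 180

    # shape-frame bounding box corners after pose; all must land on canvas
    corners <- rbind(c(-rpx, -Lpx / 2), c(rpx, -Lpx / 2),
                     c(-rpx,  Lpx / 2), c(rpx,  Lpx / 2))
    rot <- cbind(corners[, 1] * cos(th) - corners[, 2] * sin(th),
                 corners[, 1] * sin(th) + corners[, 2] * cos(th))
    px <- rot[, 1] + cx; py <- rot[, 2] + cy
    if (any(px < 0) || any(px > W - 1) || any(py < 0) || any(py > H - 1)) {
        need <- 2 * (max(abs(rot)) + max(abs(translationPx)) + 2)
        stop(sprintf(
            "shape does not fit inside a %d x %d canvas; needs about %d x %d px",
            W, H, ceiling(need), ceiling(need)))
    }

    # inverse pose: pixel centers -> shape frame
    X <- matrix(rep(0:(W - 1), each = H), nrow = H)
    Y <- matrix(rep(0:(H - 1), times = W), nrow = H)
    dx <- X - cx; dy <- Y - cy
    qx <- cos(th) * dx + sin(th) * dy
    qy <- -sin(th) * dx + cos(th) * dy

    dApex <- qy + Lpx / 2            # 0 at apex, Lpx at base
    xb <- Lpx - dApex                # axial distance from base, px
    inAxis <- dApex >= 0 & dApex <= Lpx
    xbc <- pmin(pmax(xb, 0), Lpx)
    rho <- rpx * pmax(1 - (xbc / Lpx)^2, 0)^(shape@profileExponent / 2)
    if (jitterSdMm > 0) {
        if (is.null(seed))
            stop("seed must be given when jitterSdMm > 0")
        nKnots <- 64L
        delta <- withSeed(seed, stats::rnorm(nKnots, 0, jitterSdMm)) /
            spacingMmPerPx
        knotX <- seq(0, Lpx, length.out = nKnots)
        rho <- pmax(rho + stats::approx(knotX, delta, xout = as.vector(xbc),
                                        rule = 2)$y, 0)
        rho <- matrix(rho, nrow = H)
    }
    lim <- rho
    if (shape@apexTaper > 0) {
        limRight <- rho * (1 - shape@apexTaper * xbc / Lpx)
        fg <- inAxis & ((qx <= 0 & -qx <= lim) | (qx > 0 & qx <= limRight))
    } else {
        fg <- inAxis & abs(qx) <= lim
    }
    if (jitterSdMm > 0 && any(fg))   # jitter can pinch the silhouette apart
        fg <- cleanPixelGrid(fg)
    new("LVMask", pixels = fg, spacingMmPerPx = spacingMmPerPx,
        phase = phase, caseID = caseID)
}

#' Build a synthetic case meeting volume and ejection-fraction targets
#'
#' Solves for an end-diastolic / end-systolic half-spheroid pair
#' (`profileExponent = 1`) whose analytic volumes meet the requested
#' end-diastolic volume and ejection fraction exactly.  The end-systolic
#' shape is a radially contracted version of the end-diastolic one with
#' a randomly drawn 3--10 % long-axis shortening, mimicking systolic
#' contraction.  The long-axis length, pose rotation and translation are
#' drawn deterministically from `seed`.
#'
#' @param targetEdvMl target end-diastolic volume, mL.
#' @param targetEfPct target ejection fraction, percent, in (0, 100).
#' @param seed per-case seed; the case is a pure function of its arguments.
#' @param poseJitterDeg half-range of the uniform rotation jitter, degrees.
#' @param spacingMmPerPx pixel spacing used when the case is rendered.
#' @param imageSizePx canvas size used when the case is rendered.
#' @param caseID case identifier (default derived from the seed).
#' @return a [SyntheticCase-class].
#' @examples
#' cs <- makeCase(100, 60, seed = 1)
#' c(edv(cs), esv(cs), lvef(cs))
#' @export
makeCase <- function(targetEdvMl, targetEfPct, seed, poseJitterDeg = 10,
                     spacingMmPerPx = 0.5, imageSizePx = c(256L, 256L),
                     caseID = sprintf("case_%06d", as.integer(seed))) {
    if (!is.finite(targetEdvMl) || targetEdvMl <= 0)
        stop("targetEdvMl must be positive")
    if (!is.finite(targetEfPct) || targetEfPct <= 0 || targetEfPct >= 100)
        stop("targetEfPct must lie strictly between 0 and 100")
    draws <- withSeed(seed, list(
        L = stats::runif(1, 70, 95),
        shorten = stats::runif(1, 0.03, 0.10),
        rot = stats::runif(1, -poseJitterDeg, poseJitterDeg),
        trans = stats::runif(2, -8, 8)))
    Led <- draws$L
    # invert V = (2/3) pi r^2 L for the basal radius (volumes in mm^3)
    red <- sqrt(3 * targetEdvMl * 1000 / (2 * pi * Led))
    esv <- targetEdvMl * (1 - targetEfPct / 100)
    Les <- Led * (1 - draws$shorten)
    res <- sqrt(3 * esv * 1000 / (2 * pi * Les))
    edShape <- lvShape(Led, red)
    esShape <- lvShape(Les, res)
    new("SyntheticCase",
        caseID = caseID,
        edShape = edShape, esShape = esShape,
        trueEdvMl = analyticVolume(edShape),
        trueEsvMl = analyticVolume(esShape),
        trueEfPct = (targetEdvMl - esv) / targetEdvMl * 100,
        rotationDeg = draws$rot,
        translationPx = round(draws$trans),
        spacingMmPerPx = spacingMmPerPx,
        imageSizePx = as.integer(imageSizePx),
        seed = as.integer(seed))
}

#' Render both frames of a synthetic case
#'
#' @param case a [SyntheticCase-class].
#' @param jitterSdMm contour jitter passed to [renderMask()] (default 0).
#' @return list with elements `ed` and `es`, each an [LVMask-class].
#' @export
renderCase <- function(case, jitterSdMm = 0) {
    stopifnot(is(case, "SyntheticCase"))
    ed <- renderMask(case@edShape, case@rotationDeg, case@translationPx,
                     case@spacingMmPerPx, case@imageSizePx,
                     jitterSdMm = jitterSdMm, seed = case@seed * 2L + 1L,
                     phase = "ED", caseID = case@caseID)
    es <- renderMask(case@esShape, case@rotationDeg, case@translationPx,
                     case@spacingMmPerPx, case@imageSizePx,
                     jitterSdMm = jitterSdMm, seed = case@seed * 2L + 2L,
                     phase = "ES", caseID = case@caseID)
    list(ed = ed, es = es)
}

# True pose geometry of a rendered case: apex/base pixel coordinates of
# the given frame, straight from the generator parameters (independent of
# any landmark detection).
casePoseGeometry <- function(case, phase = c("ED", "ES")) {
    phase <- match.arg(phase)
    shape <- if (phase == "ED") case@edShape else case@esShape
    Lpx <- shape@axisLengthMm / case@spacingMmPerPx
    W <- case@imageSizePx[1]; H <- case@imageSizePx[2]
    cx <- (W - 1) / 2 + case@translationPx[1]
    cy <- (H - 1) / 2 + case@translationPx[2]
    th <- case@rotationDeg * pi / 180
    pose <- function(q) c(cos(th) * q[1] - sin(th) * q[2] + cx,
                          sin(th) * q[1] + cos(th) * q[2] + cy)
    list(apex = pose(c(0, -Lpx / 2)), base = pose(c(0, Lpx / 2)),
         axisLengthPx = Lpx, shape = shape)
}

# Ground-truth tracing chords for one rendered frame: the major axis
# followed by n chords (base -> apex), endpoints snapped to mask pixels.
caseTracingChords <- function(case, mask, phase, n = 20L) {
    geo <- casePoseGeometry(case, phase)
    pts <- foregroundPoints(maskPixels(mask))
    u <- (geo$apex - geo$base); u <- u / sqrt(sum(u^2))   # base -> apex
    w <- c(-u[2], u[1])
    t <- (pts[, 1] - geo$base[1]) * u[1] + (pts[, 2] - geo$base[2]) * u[2]
    s <- (pts[, 1] - geo$base[1]) * w[1] + (pts[, 2] - geo$base[2]) * w[2]
    chords <- matrix(NA_real_, nrow = n, ncol = 4)
    for (k in seq_len(n)) {
        tk <- (k - 0.5) / n * geo$axisLengthPx
        sel <- abs(t - tk) <= 0.5
        if (!any(sel)) next
        i1 <- which(sel)[which.min(s[sel])]
        i2 <- which(sel)[which.max(s[sel])]
        chords[k, ] <- c(pts[i1, 1], pts[i1, 2], pts[i2, 1], pts[i2, 2])
    }
    rbind(c(geo$apex[1], geo$apex[2], geo$base[1], geo$base[2]),
          chords[stats::complete.cases(chords), , drop = FALSE])
}

#' Write a synthetic dataset with exact ground truth to disk
#'
#' Generates `nCases` synthetic end-diastolic / end-systolic mask pairs
#' and writes them as 8-bit grayscale PNGs together with three CSV
#' tables: a file list (`FileList.csv`, EchoNet-Dynamic dialect with
#' `FileName`, `EF`, `ESV`, `EDV` columns), a chord table
#' (`VolumeTracings.csv`, columns `FileName, X1, Y1, X2, Y2, Frame` with
#' frame 0 = ED and frame 1 = ES), and a ground-truth manifest
#' (`manifest.csv`).  Ejection-fraction targets are drawn uniformly from
#' `efRange` and end-diastolic volumes from `edvRange`; per-case seeds
#' are `seed + case index`.  Re-running with the same arguments
#' reproduces every file byte-for-byte.
#'
#' @param nCases number of cases (>= 1).
#' @param seed dataset seed.
#' @param outDir output directory (created if missing).
#' @param jitterSdMm contour jitter passed to the renderer (default 0).
#' @param spacingMmPerPx pixel spacing, mm per pixel.
#' @param imageSizePx canvas size, pixels.
#' @param poseJitterDeg half-range of rotation jitter, degrees.
#' @param efRange range of ejection-fraction targets, percent.
#' @param edvRange range of end-diastolic volume targets, mL.
#' @return (invisibly) the manifest data frame.
#' @export
makeDataset <- function(nCases, seed, outDir, jitterSdMm = 0,
                        spacingMmPerPx = 0.5, imageSizePx = c(256L, 256L),
                        poseJitterDeg = 10, efRange = c(20, 75),
                        edvRange = c(70, 180)) {
    if (!is.numeric(nCases) || nCases < 1)
        stop("nCases must be >= 1")
    nCases <- as.integer(nCases)
    dir.create(file.path(outDir, "masks"), recursive = TRUE,
               showWarnings = FALSE)
    if (!dir.exists(outDir))
        stop("cannot create output directory: ", outDir)
    targets <- withSeed(seed, list(
        ef = stats::runif(nCases, efRange[1], efRange[2]),
        edv = stats::runif(nCases, edvRange[1], edvRange[2])))
    manifest <- data.frame(
        case_id = sprintf("case_%04d", seq_len(nCases)),
        true_edv_ml = NA_real_, true_esv_ml = NA_real_,
        true_ef_pct = NA_real_,
        spacing_mm_per_px = spacingMmPerPx,
        seed = seed + seq_len(nCases), stringsAsFactors = FALSE)
    tracings <- vector("list", nCases)
    for (i in seq_len(nCases)) {
        cs <- makeCase(targets$edv[i], targets$ef[i], seed = seed + i,
                       poseJitterDeg = poseJitterDeg,
                       spacingMmPerPx = spacingMmPerPx,
                       imageSizePx = imageSizePx,
                       caseID = manifest$case_id[i])
        frames <- renderCase(cs, jitterSdMm = jitterSdMm)
        writeMask(frames$ed,
                  file.path(outDir, "masks",
                            paste0(cs@caseID, "_ED.png")))
        writeMask(frames$es,
                  file.path(outDir, "masks",
                            paste0(cs@caseID, "_ES.png")))
        manifest$true_edv_ml[i] <- cs@trueEdvMl
        manifest$true_esv_ml[i] <- cs@trueEsvMl
        manifest$true_ef_pct[i] <- cs@trueEfPct
        chEd <- caseTracingChords(cs, frames$ed, "ED")
        chEs <- caseTracingChords(cs, frames$es, "ES")
        tracings[[i]] <- data.frame(
            FileName = paste0(cs@caseID, ".avi"),
            X1 = c(chEd[, 1], chEs[, 1]), Y1 = c(chEd[, 2], chEs[, 2]),
            X2 = c(chEd[, 3], chEs[, 3]), Y2 = c(chEd[, 4], chEs[, 4]),
            Frame = rep(c(0L, 1L), c(nrow(chEd), nrow(chEs))),
            stringsAsFactors = FALSE)
    }
    fileList <- data.frame(
        FileName = paste0(manifest$case_id, ".avi"),
        EF = sprintf("%.6f", manifest$true_ef_pct),
        ESV = sprintf("%.6f", manifest$true_esv_ml),
        EDV = sprintf("%.6f", manifest$true_edv_ml),
        FrameWidth = imageSizePx[1], FrameHeight = imageSizePx[2],
        Split = "TRAIN", stringsAsFactors = FALSE)
    tr <- do.call(rbind, tracings)
    for (cc in c("X1", "Y1", "X2", "Y2")) tr[[cc]] <- sprintf("%.4f", tr[[cc]])
    mf <- manifest
    for (cc in c("true_edv_ml", "true_esv_ml", "true_ef_pct",
                 "spacing_mm_per_px"))
        mf[[cc]] <- sprintf("%.6f", manifest[[cc]])
    utils::write.csv(fileList, file.path(outDir, "FileList.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(tr, file.path(outDir, "VolumeTracings.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(mf, file.path(outDir, "manifest.csv"),
                     row.names = FALSE, quote = FALSE)
    invisible(manifest)
}
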