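#' @include AllGenerics.R
NULL

# Largest connected component with holes filled.  Segmentation masks may
# carry satellites or interior holes; every geometry operation works on
# the cleaned grid.  Ties between equally sized components resolve to
# the first label in raster-scan order (deterministic).
cleanPixelGrid <- function(fg) {
    lab <- EBImage::bwlabel(EBImage::Image(fg * 1))
    labv <- as.integer(EBImage::imageData(lab))
    if (max(labv) > 1L) {
        sizes <- tabulate(labv[labv > 0L])
        keep <- which(sizes == max(sizes))[1]
        comp <- EBImage::imageData(lab) == keep
    } else {
        comp <- fg
    }
    filled <- EBImage::fillHull(EBImage::Image(comp * 1))
    matrix(as.integer(EBImage::imageData(filled)) > 0L,
           nrow = nrow(fg))
}

# Foreground pixel centers as an n x 2 matrix of (x, y), 0-based.
foregroundPoints <- function(fg) {
    idx <- which(fg, arr.ind = TRUE)
    cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
}

# Moore-neighbor boundary trace of a cleaned (single component,
# hole-free) grid.  Returns ordered (x, y) boundary pixel centers.
mooreTrace <- function(fg) {
    idx <- which(fg, arr.ind = TRUE)
    if (nrow(idx) == 1L)
        return(cbind(x = idx[1, 2] - 1, y = idx[1, 1] - 1))
    o <- order(idx[, 1], idx[, 2])          # smallest (row, col) start
    s <- idx[o[1], ]
    H <- nrow(fg); W <- ncol(fg)
    # clockwise from north: N NE E SE S SW W NW, as (drow, dcol)
    dr <- c(-1, -1, 0, 1, 1, 1, 0, -1)
    dc <- c(0, 1, 1, 1, 0, -1, -1, -1)
    isFg <- function(r, c) r >= 1 && r <= H && c >= 1 && c <= W && fg[r, c]
    cur <- s
    backDir <- 1L                           # came from the north (background)
    pts <- matrix(NA_integer_, nrow = 8L * nrow(idx) + 8L, ncol = 2)
    pts[1, ] <- cur
    np <- 1L
    # the walk is periodic in the (pixel, backtrack) state; trace until
    # a state repeats, then return the cycle
    seen <- new.env(hash = TRUE, parent = emptyenv())
    assign(paste(cur[1], cur[2], backDir), 1L, envir = seen)
    firstIdx <- 1L
    repeat {
        found <- FALSE
        for (step in 1:8) {
            d <- ((backDir - 1L + step - 1L) %% 8L) + 1L
            r <- cur[1] + dr[d]; c <- cur[2] + dc[d]
            if (isFg(r, c)) {
                # new backtrack: the background neighbor examined just
                # before this pixel, as seen from this pixel
                pd <- ((d - 2L) %% 8L) + 1L
                pr <- cur[1] + dr[pd]; pc <- cur[2] + dc[pd]
                cur <- c(r, c)
                backDir <- which(dr == pr - r & dc == pc - c)
                found <- TRUE
                break
            }
        }
        if (!found) break                   # isolated pixel (cannot happen here)
        key <- paste(cur[1], cur[2], backDir)
        prev <- mget(key, envir = seen, ifnotfound = list(NULL))[[1]]
        if (!is.null(prev)) { firstIdx <- prev; break }
        np <- np + 1L
        if (np > nrow(pts)) break           # safety
        pts[np, ] <- cur
        assign(key, np, envir = seen)
    }
    pts <- pts[firstIdx:np, , drop = FALSE]
    pts <- startAtLexMin(cbind(x = pts[, 2] - 1, y = pts[, 1] - 1))
    colnames(pts) <- c("x", "y")
    pts
}

#' Extract the ordered boundary contour of a mask
#'
#' Boundary of the largest connected component after hole filling,
#' traced once as a closed polygon.  Points are returned
#' counter-clockwise (positive shoelace area in the package's
#' x-right / y-down pixel coordinates), starting at the boundary pixel
#' with the lexicographically smallest (y, x), with no consecutive
#' duplicates.  Every returned point is a foreground pixel with at
#' least one background 8-neighbor.
#'
#' @param mask an [LVMask-class] with at least one foreground pixel.
#' @return an n x 2 matrix with columns `x`, `y` (0-based pixel centers).
#' @export
extractContour <- function(mask) {
    stopifnot(is(mask, "LVMask"))
    if (!any(mask@pixels))
        stop("empty mask: no foreground pixels")
    fg <- cleanPixelGrid(mask@pixels)
    pts <- mooreTrace(fg)
    if (nrow(pts) <= 2L) return(pts)
    # drop consecutive duplicates (can arise at single-pixel necks)
    keep <- c(TRUE, rowSums(abs(diff(pts))) > 0)
    pts <- pts[keep, , drop = FALSE]
    if (nrow(pts) >= 3L) {
        xs <- pts[, 1]; ys <- pts[, 2]
        area2 <- sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)
        if (area2 < 0) pts <- pts[c(1, rev(seq_len(nrow(pts))[-1])), ,
                                  drop = FALSE]
    }
    pts
}

# Rotate a closed point cycle so it starts at the smallest (y, x).
startAtLexMin <- function(pts) {
    i <- order(pts[, 2], pts[, 1])[1]
    if (i == 1L) pts
    else pts[c(i:nrow(pts), 1:(i - 1L)), , drop = FALSE]
}

#' Locate the apex and mitral-valve midpoint on a contour
#'
#' The principal axis of the contour (from the second moments of the
#' boundary points) gives the long-axis direction.  The two axis-extreme
#' ends of the contour are the landmark candidates; each candidate point
#' is the centroid of the boundary points within a one-pixel band of the
#' extreme projection, so a flat mitral plane yields its midpoint.  The
#' apex is the end with the smaller local width, measured as the maximal
#' perpendicular spread of boundary points within the 10 % of the axis
#' length nearest that end -- anatomically the apex is pointed and the
#' mitral base broad.  If the two widths differ by less than 1 % the end
#' nearer the image top is taken as apex (apical-view display
#' convention) with a warning.
#'
#' @param contour n x 2 matrix from [extractContour()], n >= 8.
#' @return a [Landmarks-class].
#' @export
localizeLandmarks <- function(contour) {
    if (!is.matrix(contour) || ncol(contour) != 2L)
        stop("contour must be an n x 2 matrix")
    if (nrow(contour) < 8L)
        stop("contour must have at least 8 points")
    m <- colMeans(contour)
    P <- sweep(contour, 2, m)
    ev <- eigen(crossprod(P) / nrow(P), symmetric = TRUE)
    v <- ev$vectors[, 1]
    vperp <- c(-v[2], v[1])
    t <- P %*% v
    w <- P %*% vperp
    if (max(w) - min(w) < 1)
        stop("degenerate contour: all points collinear within 1 px")
    tmin <- min(t); tmax <- max(t); trange <- tmax - tmin
    dEnd <- max(1, 0.005 * trange)
    bandHi <- t >= tmax - dEnd
    bandLo <- t <= tmin + dEnd
    candHi <- colMeans(contour[bandHi, , drop = FALSE])
    candLo <- colMeans(contour[bandLo, , drop = FALSE])
    d10 <- 0.1 * trange
    widthHi <- {
        sel <- t >= tmax - d10
        max(w[sel]) - min(w[sel])
    }
    widthLo <- {
        sel <- t <= tmin + d10
        max(w[sel]) - min(w[sel])
    }
    if (abs(widthHi - widthLo) < 0.01 * max(widthHi, widthLo)) {
        warning("end widths nearly equal; taking the upper end as apex ",
                "(apex-up convention)")
        if (candHi[2] <= candLo[2]) {
            apex <- candHi; base <- candLo
        } else {
            apex <- candLo; base <- candHi
        }
    } else if (widthHi < widthLo) {
        apex <- candHi; base <- candLo
    } else {
        apex <- candLo; base <- candHi
    }
    L <- sqrt(sum((apex - base)^2))
    new("Landmarks", apex = as.numeric(apex), mitralMid = as.numeric(base),
        axisLengthPx = L, axisUnit = as.numeric((base - apex) / L))
}

#' Disk center positions along the major axis
#'
#' Divides the apex--mitral axis into `nDisks` equal parts and returns
#' the midpoint of each part, ordered from the mitral base toward the
#' apex: center_k = base + (k - 0.5)/n * (apex - base).
#'
#' @param landmarks a [Landmarks-class].
#' @param nDisks number of disks (>= 1).
#' @return nDisks x 2 matrix of (x, y) centers, base -> apex.
#' @export
placeDisks <- function(landmarks, nDisks = 20L) {
    stopifnot(is(landmarks, "Landmarks"))
    if (!is.numeric(nDisks) || nDisks < 1)
        stop("nDisks must be >= 1")
    nDisks <- as.integer(nDisks)
    base <- landmarks@mitralMid
    apex <- landmarks@apex
    f <- (seq_len(nDisks) - 0.5) / nDisks
    cbind(x = base[1] + f * (apex[1] - base[1]),
          y = base[2] + f * (apex[2] - base[2]))
}

# Exact maximum pairwise distance of a point set: all pairs on the
# convex hull (identical to all-pairs on the full set, much cheaper).
maxPairwiseDistance <- function(pts) {
    n <- nrow(pts)
    if (n <= 1L) return(0)
    if (n > 3L) {
        h <- tryCatch(grDevices::chull(pts[, 1], pts[, 2]),
                      error = function(e) seq_len(n))
        if (length(h) >= 2L) pts <- pts[h, , drop = FALSE]
    }
    dx <- outer(pts[, 1], pts[, 1], "-")
    dy <- outer(pts[, 2], pts[, 2], "-")
    sqrt(max(dx * dx + dy * dy))
}

#' Measure per-disk diameters from a mask
#'
#' For each of the `nDisks` positions along the major axis the region of
#' interest is the perpendicular slab of thickness \eqn{l = L/n}
#' centered at that position: the foreground pixels whose signed
#' projection onto the axis lies within \eqn{\pm l/2} of the position's
#' projection.  The slabs partition the chamber, matching the
#' method-of-disks volume decomposition.  The disk diameter \eqn{a_i} is
#' the maximum Euclidean distance between any two pixels of the region
#' (computed exactly on the region's convex hull); an empty region
#' yields 0.  A circular region (radius \eqn{l/2} around the disk
#' center) is available via `roi = "circle"`.
#'
#' @param mask an [LVMask-class].
#' @param landmarks a [Landmarks-class] for the same mask.
#' @param nDisks number of disks (clinical default 20).
#' @param roi region-of-interest shape, `"slab"` (default) or `"circle"`.
#' @return a [DiskProfile-class] with diameters in mm, ordered
#'   base -> apex.
#' @export
measureDiameters <- function(mask, landmarks, nDisks = 20L,
                             roi = c("slab", "circle")) {
    stopifnot(is(mask, "LVMask"), is(landmarks, "Landmarks"))
    roi <- match.arg(roi)
    if (!is.numeric(nDisks) || nDisks < 1)
        stop("nDisks must be >= 1")
    nDisks <- as.integer(nDisks)
    pts <- foregroundPoints(cleanPixelGrid(mask@pixels))
    base <- landmarks@mitralMid
    u <- landmarks@axisUnit * -1            # base -> apex
    L <- landmarks@axisLengthPx
    l <- L / nDisks
    t <- (pts[, 1] - base[1]) * u[1] + (pts[, 2] - base[2]) * u[2]
    centers <- placeDisks(landmarks, nDisks)
    a <- numeric(nDisks)
    for (k in seq_len(nDisks)) {
        tk <- (k - 0.5) * l
        if (roi == "slab") {
            sel <- abs(t - tk) <= l / 2
        } else {
            d2 <- (pts[, 1] - centers[k, 1])^2 + (pts[, 2] - centers[k, 2])^2
            sel <- d2 <= (l / 2)^2
        }
        a[k] <- maxPairwiseDistance(pts[sel, , drop = FALSE])
    }
    sp <- mask@spacingMmPerPx
    new("DiskProfile", diametersMm = a * sp, diskHeightMm = l * sp,
        axisLengthMm = L * sp, nDisks = nDisks)
}

# Extreme pixel pair per disk slab (for the debug overlay).
diskExtremePairs <- function(mask, landmarks, nDisks = 20L) {
    pts <- foregroundPoints(cleanPixelGrid(mask@pixels))
    base <- landmarks@mitralMid
    u <- -landmarks@axisUnit
    L <- landmarks@axisLengthPx; l <- L / nDisks
    t <- (pts[, 1] - base[1]) * u[1] + (pts[, 2] - base[2]) * u[2]
    out <- vector("list", nDisks)
    for (k in seq_len(nDisks)) {
        sel <- which(abs(t - (k - 0.5) * l) <= l / 2)
        if (length(sel) < 2L) next
        sub <- pts[sel, , drop = FALSE]
        h <- if (nrow(sub) > 3L) grDevices::chull(sub) else seq_len(nrow(sub))
        hp <- sub[h, , drop = FALSE]
        dx <- outer(hp[, 1], hp[, 1], "-"); dy <- outer(hp[, 2], hp[, 2], "-")
        ij <- which(dx * dx + dy * dy == max(dx * dx + dy * dy),
                    arr.ind = TRUE)[1, ]
        out[[k]] <- rbind(hp[ij[1], ], hp[ij[2], ])
    }
    out
}

#' Contour points of a mask as a physical point set
#'
#' Convenience wrapper: extracts the boundary contour and scales it to
#' millimeters, for Hausdorff / contour-error comparisons against
#' reference tracings.
#'
#' @param mask an [LVMask-class].
#' @param units `"mm"` (default) or `"px"`.
#' @return n x 2 matrix of contour points.
#' @export
maskContourPoints <- function(mask, units = c("mm", "px")) {
    units <- match.arg(units)
    pts <- extractContour(mask)
    if (units == "mm") pts <- pts * mask@spacingMmPerPx
    pts
}

#' Write a debug overlay of the extracted geometry
#'
#' Renders the mask with its contour, major axis and per-disk diameter
#' chords into a PNG, mirroring the usual diameter-tracing figures.
#'
#' @param mask an [LVMask-class].
#' @param file output PNG path.
#' @param nDisks number of disks to draw.
#' @return (invisibly) `file`.
#' @export
drawOverlay <- function(mask, file, nDisks = 20L) {
    ct <- extractContour(mask)
    lm <- localizeLandmarks(ct)
    pairs <- diskExtremePairs(mask, lm, nDisks)
    d <- dim(mask@pixels)
    grDevices::png(file, width = d[2], height = d[1])
    op <- graphics::par(mar = c(0, 0, 0, 0))
    on.exit({ graphics::par(op); grDevices::dev.off() })
    graphics::image(t(mask@pixels)[, d[1]:1], col = c("black", "grey40"),
                    axes = FALSE, useRaster = TRUE)
    sc <- function(p) cbind(p[, 1] / (d[2] - 1), 1 - p[, 2] / (d[1] - 1))
    graphics::lines(sc(rbind(ct, ct[1, , drop = FALSE])), col = "yellow")
    ab <- rbind(lm@apex, lm@mitralMid)
    graphics::lines(sc(ab), col = "red", lwd = 2)
    for (p in pairs)
        if (!is.null(p)) graphics::lines(sc(p), col = "cyan")
    invisible(file)
}
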