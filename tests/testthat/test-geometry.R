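test_that("contour of a raster square is its 36-pixel perimeter", {
    px <- matrix(FALSE, 20, 20); px[6:15, 6:15] <- TRUE
    ct <- extractContour(newMask(px))
    expect_equal(nrow(ct), 36)
    # starts at the lexicographically smallest (y, x)
    expect_equal(unname(ct[1, ]), c(5, 5))
    # counter-clockwise: positive shoelace area in x-right/y-down coords
    area2 <- sum(ct[, 1] * c(ct[-1, 2], ct[1, 2]) -
                 c(ct[-1, 1], ct[1, 1]) * ct[, 2])
    expect_gt(area2, 0)
    # every contour point is foreground with a background 8-neighbor
    for (i in seq_len(nrow(ct))) {
        x <- ct[i, 1]; y <- ct[i, 2]
        expect_true(px[y + 1, x + 1])
        nb <- expand.grid(dx = -1:1, dy = -1:1)
        nb <- nb[!(nb$dx == 0 & nb$dy == 0), ]
        hasBg <- any(mapply(function(dx, dy) {
            xx <- x + dx; yy <- y + dy
            xx < 0 || yy < 0 || xx >= 20 || yy >= 20 || !px[yy + 1, xx + 1]
        }, nb$dx, nb$dy))
        expect_true(hasBg)
    }
    # no consecutive duplicates
    expect_true(all(rowSums(abs(diff(ct))) > 0))
})

test_that("contour handles degenerate and holed masks", {
    px1 <- matrix(FALSE, 5, 5); px1[3, 3] <- TRUE
    expect_equal(nrow(extractContour(newMask(px1))), 1)
    # interior holes are filled before tracing
    px <- matrix(FALSE, 20, 20); px[6:15, 6:15] <- TRUE
    pxh <- px; pxh[10:11, 10:11] <- FALSE
    expect_identical(extractContour(newMask(pxh)),
                     extractContour(newMask(px)))
    # only the largest component is traced
    pxs <- px; pxs[2, 2] <- TRUE
    expect_identical(extractContour(newMask(pxs)),
                     extractContour(newMask(px)))
    empty <- newMask(matrix(FALSE, 5, 5))
    expect_error(extractContour(empty), "empty mask")
})

test_that("landmarks localize the apex and mitral midpoint of a spheroid", {
    m <- renderMask(lvShape(80, 20), spacingMmPerPx = 0.5,
                    imageSizePx = c(256, 256))
    lm <- localizeLandmarks(extractContour(m))
    # apex-up render: apex at (127.5, 127.5 - 80), base at (127.5, 207.5)
    expect_lt(sqrt(sum((apexPoint(lm) - c(127.5, 47.5))^2)), 2)
    expect_lt(sqrt(sum((mitralMidPoint(lm) - c(127.5, 207.5))^2)), 2)
    expect_lt(abs(axisLength(lm) - 160) / 160, 0.02)
    # axis unit points apex -> base
    expect_gt(axisUnit(lm)[2], 0.99)
})

test_that("landmarks are equivariant under rotation", {
    m90 <- renderMask(lvShape(80, 20), rotationDeg = 90,
                      spacingMmPerPx = 0.5, imageSizePx = c(256, 256))
    lm90 <- localizeLandmarks(extractContour(m90))
    # apex (0, -L/2) rotated by 90 deg lands at (127.5 + 80, 127.5)
    expect_lt(sqrt(sum((apexPoint(lm90) - c(207.5, 127.5))^2)), 2)
})

test_that("ambiguous and degenerate contours are handled as documented", {
    expect_warning(localizeLandmarks(extractContour(circleMask(15))),
                   "apex-up")
    pxl <- matrix(FALSE, 10, 50); pxl[5, 3:45] <- TRUE
    expect_error(localizeLandmarks(extractContour(newMask(pxl))),
                 "degenerate")
    expect_error(localizeLandmarks(matrix(0, 4, 2)), "at least 8")
})

test_that("disk centers divide the axis into equal parts", {
    lm <- manualLandmarks(apex = c(0, 0), base = c(0, 100))
    ctr <- placeDisks(lm, 20)
    expect_equal(unname(ctr[1, ]), c(0, 97.5))
    expect_equal(unname(ctr[20, ]), c(0, 2.5))
    gaps <- sqrt(rowSums(diff(ctr)^2))
    expect_equal(gaps, rep(5, 19), tolerance = 1e-12)
    expect_equal(unname(placeDisks(lm, 1)), matrix(c(0, 50), 1))
    expect_error(placeDisks(lm, 0), "nDisks")
})

test_that("slab diameters of a rectangle match the slab diagonal", {
    # 40 px wide, 200 px tall; landmarks set on the midline
    m <- rectMask(10, 49, 10, 209)
    lm <- manualLandmarks(apex = c(29.5, 10), base = c(29.5, 209))
    prof <- measureDiameters(m, lm, 20)
    l <- axisLength(lm) / 20
    expected <- sqrt(40^2 + l^2)   # exact max pairwise distance in a w x l slab
    a <- diameters(prof)
    for (k in 3:18)
        expect_lt(abs(a[k] - expected) / expected, 0.05)
    expect_equal(diskHeight(prof) * nDisks(prof), axisLength(prof),
                 tolerance = 1e-9)
})

test_that("spheroid diameters decrease monotonically base to apex", {
    m <- renderMask(lvShape(80, 20), spacingMmPerPx = 0.5,
                    imageSizePx = c(256, 256))
    prof <- measureDiameters(m, localizeLandmarks(extractContour(m)), 20)
    a <- diameters(prof)
    # no increase beyond rasterization tolerance (2 px equivalent)
    expect_true(all(diff(a) < 2 * 0.5))
})

test_that("central diameters match the analytic chord profile", {
    r <- 20; L <- 80
    m <- renderMask(lvShape(L, r), spacingMmPerPx = 0.5,
                    imageSizePx = c(256, 256))
    prof <- measureDiameters(m, localizeLandmarks(extractContour(m)), 20)
    a <- diameters(prof)
    x <- (seq_len(20) - 0.5) / 20 * L
    chord <- 2 * r * sqrt(1 - (x / L)^2)
    # the slab maximum tracks the midpoint chord only where the chord
    # varies slowly; near the apex it exceeds it by construction
    for (k in 1:13)
        expect_lt(abs(a[k] - chord[k]) / chord[k], 0.03)
})

test_that("single-pixel masks give one zero-diameter disk", {
    px <- matrix(FALSE, 9, 9); px[5, 5] <- TRUE
    lm <- manualLandmarks(apex = c(4, 0), base = c(4, 8))
    prof <- measureDiameters(newMask(px), lm, 20)
    expect_equal(sum(diameters(prof) > 0), 0)
    expect_length(diameters(prof), 20)
})

test_that("diameter profiles are translation-invariant and rotation-stable", {
    s <- lvShape(80, 20)
    base <- renderMask(s, 0, c(0, 0), 0.5, c(256, 256))
    lmB <- localizeLandmarks(extractContour(base))
    dB <- diameters(measureDiameters(base, lmB, 20))
    shifted <- renderMask(s, 0, c(7, -5), 0.5, c(256, 256))
    dS <- diameters(measureDiameters(
        shifted, localizeLandmarks(extractContour(shifted)), 20))
    expect_equal(dS, dB, tolerance = 1e-9)
    rot <- renderMask(s, 90, c(0, 0), 0.5, c(256, 256))
    dR <- diameters(measureDiameters(
        rot, localizeLandmarks(extractContour(rot)), 20))
    expect_lt(max(abs(dR - dB)), 2 * 0.5)
})

test_that("diameters are consistent across rendering resolutions", {
    s <- lvShape(80, 20)
    mCoarse <- renderMask(s, 0, c(0, 0), 0.5, c(256, 256))
    mFine <- renderMask(s, 0, c(0, 0), 0.25, c(512, 512))
    dC <- diameters(measureDiameters(
        mCoarse, localizeLandmarks(extractContour(mCoarse)), 20))
    dF <- diameters(measureDiameters(
        mFine, localizeLandmarks(extractContour(mFine)), 20))
    # every diameter within two coarse pixels (quantization bound) and
    # the summed volume within 2 %
    expect_lt(max(abs(dC - dF)), 2 * 0.5)
    vC <- simpsonVolume(measureDiameters(
        mCoarse, localizeLandmarks(extractContour(mCoarse)), 20))
    vF <- simpsonVolume(measureDiameters(
        mFine, localizeLandmarks(extractContour(mFine)), 20))
    expect_lt(abs(vC - vF) / vF, 0.02)
})

test_that("circular-ROI variant measures within the slab value", {
    m <- renderMask(lvShape(80, 20), spacingMmPerPx = 0.5,
                    imageSizePx = c(256, 256))
    lm <- localizeLandmarks(extractContour(m))
    slab <- diameters(measureDiameters(m, lm, 20, roi = "slab"))
    circ <- diameters(measureDiameters(m, lm, 20, roi = "circle"))
    # the circular ROI is a subset of the slab, so diameters cannot exceed it
    expect_true(all(circ <= slab + 1e-9))
})

test_that("debug overlay writes a PNG", {
    d <- tmpDir()
    on.exit(unlink(d, recursive = TRUE))
    m <- renderMask(lvShape(60, 18), spacingMmPerPx = 0.5,
                    imageSizePx = c(160, 160))
    f <- drawOverlay(m, file.path(d, "overlay.png"))
    expect_true(file.exists(f))
    expect_gt(file.info(f)$size, 0)
})
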