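test_that("analytic volume matches the closed form for half prolate spheroids", {
    expect_equal(analyticVolume(lvShape(80, 20)), (2 / 3) * pi * 400 * 80 / 1000,
                 tolerance = 1e-12)
    # degenerate limit: vanishing basal radius gives vanishing volume
    expect_lt(analyticVolume(lvShape(80, 1e-4)), 1e-8)
    expect_error(lvShape(80, -1), "basalRadiusMm")
    expect_error(lvShape(0, 20), "axisLengthMm")
})

test_that("numerical revolution integral is stable and agrees with the closed form", {
    # general exponent: doubling the slice count moves the value by < 1e-4 rel.
    v1 <- analyticVolume(lvShape(60, 25, profileExponent = 1.5),
                         nSlices = 20000L)
    v2 <- analyticVolume(lvShape(60, 25, profileExponent = 1.5),
                         nSlices = 40000L)
    expect_lt(abs(v1 - v2) / v2, 5e-5)
    # independent midpoint-rule oracle written here from the profile formula
    L <- 80; r <- 20; n <- 20000
    x <- (seq_len(n) - 0.5) / n * L
    oracle <- sum(pi * (r * sqrt(1 - (x / L)^2))^2) * L / n / 1000
    expect_lt(abs(analyticVolume(lvShape(L, r)) - oracle) / oracle, 1e-4)
})

test_that("rendered silhouette area matches the analytic area", {
    s <- lvShape(80, 20)
    m <- renderMask(s, spacingMmPerPx = 0.5, imageSizePx = c(512, 512))
    areaPx <- sum(maskPixels(m))
    analyticPx <- (pi * 20 * 80 / 2) / 0.25        # pi*r*L/2 mm^2 -> px
    expect_lt(abs(areaPx - analyticPx) / analyticPx, 0.01)
    # rotation preserves area
    m180 <- renderMask(s, 180, spacingMmPerPx = 0.5, imageSizePx = c(512, 512))
    expect_lt(abs(sum(maskPixels(m180)) - areaPx) / areaPx, 0.01)
    # doubling the basal radius doubles the silhouette area
    mHalf <- renderMask(lvShape(80, 10), spacingMmPerPx = 0.5,
                        imageSizePx = c(512, 512))
    expect_lt(abs(areaPx / sum(maskPixels(mHalf)) - 2), 0.02)
})

test_that("render refuses shapes that do not fit and reports the needed canvas", {
    expect_error(renderMask(lvShape(80, 20), spacingMmPerPx = 0.5,
                            imageSizePx = c(112, 112)),
                 "canvas")
})

test_that("makeCase hits its volume and EF targets exactly", {
    cs <- makeCase(100, 60, seed = 11)
    expect_equal(edv(cs), 100, tolerance = 1e-3)
    expect_equal(esv(cs), 40, tolerance = 1e-3)
    expect_equal(lvef(cs), 60, tolerance = 1e-9)
    expect_error(makeCase(100, 100, seed = 1), "between 0 and 100")
    expect_error(makeCase(-5, 50, seed = 1), "positive")
})

test_that("makeCase is deterministic and internally consistent", {
    expect_identical(makeCase(120, 45, seed = 7), makeCase(120, 45, seed = 7))
    tg <- cohortTargets(15, targetSeed = 99)
    for (i in seq_len(15)) {
        cs <- makeCase(tg$edv[i], tg$ef[i], seed = i - 1)
        expect_equal(lvef(cs), (edv(cs) - esv(cs)) / edv(cs) * 100,
                     tolerance = 1e-9)
        expect_lt(esv(cs), edv(cs))
    }
})

test_that("makeDataset writes masks and CSVs reproducibly", {
    d1 <- tmpDir(); d2 <- tmpDir()
    on.exit(unlink(c(d1, d2), recursive = TRUE))
    mf <- makeDataset(5, seed = 7, outDir = d1)
    expect_equal(nrow(mf), 5)
    expect_length(list.files(file.path(d1, "masks"), pattern = "png$"), 10)
    expect_true(all(file.exists(file.path(d1, c("FileList.csv",
                                                "VolumeTracings.csv",
                                                "manifest.csv")))))
    makeDataset(5, seed = 7, outDir = d2)
    for (f in c("FileList.csv", "VolumeTracings.csv", "manifest.csv"))
        expect_identical(unname(tools::md5sum(file.path(d1, f))),
                         unname(tools::md5sum(file.path(d2, f))))
    m1 <- list.files(file.path(d1, "masks"), full.names = TRUE)
    m2 <- list.files(file.path(d2, "masks"), full.names = TRUE)
    expect_identical(unname(tools::md5sum(m1)), unname(tools::md5sum(m2)))
    expect_error(makeDataset(0, seed = 1, outDir = tempdir()), "nCases")
})

test_that("generated tracing chords lie on the rendered contour", {
    d <- tmpDir()
    on.exit(unlink(d, recursive = TRUE))
    makeDataset(1, seed = 3, outDir = d)
    tr <- readTracings(file.path(d, "VolumeTracings.csv"))
    ed <- readMask(file.path(d, "masks", "case_0001_ED.png"),
                   spacingMmPerPx = 0.5)
    ct <- extractContour(ed)
    frame0 <- tr[tr$frame_index == 0L, ]
    # first row per frame is the major axis (analytic endpoints);
    # the remaining rows are diameter chords snapped to mask pixels
    chords <- frame0[-1, ]
    ends <- rbind(as.matrix(chords[c("x1", "y1")]),
                  as.matrix(chords[c("x2", "y2")]))
    dmin <- apply(ends, 1, function(p)
        sqrt(min((ct[, 1] - p[1])^2 + (ct[, 2] - p[2])^2)))
    expect_lt(max(dmin), 0.5)
    # axis endpoints are analytic, so only rasterization-accurate
    axisEnds <- rbind(as.numeric(frame0[1, c("x1", "y1")]),
                      as.numeric(frame0[1, c("x2", "y2")]))
    dAxis <- apply(axisEnds, 1, function(p)
        sqrt(min((ct[, 1] - p[1])^2 + (ct[, 2] - p[2])^2)))
    expect_lt(max(dAxis), 1.5)
})

test_that("contour jitter produces a valid but different mask", {
    s <- lvShape(80, 20)
    m0 <- renderMask(s, spacingMmPerPx = 0.5, imageSizePx = c(256, 256))
    mj <- renderMask(s, spacingMmPerPx = 0.5, imageSizePx = c(256, 256),
                     jitterSdMm = 1.5, seed = 5)
    expect_false(identical(maskPixels(m0), maskPixels(mj)))
    # still one clean component: contour extraction succeeds
    expect_gt(nrow(extractContour(mj)), 8)
    # same seed reproduces the jitter
    mj2 <- renderMask(s, spacingMmPerPx = 0.5, imageSizePx = c(256, 256),
                      jitterSdMm = 1.5, seed = 5)
    expect_identical(maskPixels(mj), maskPixels(mj2))
})
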