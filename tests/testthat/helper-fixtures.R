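# Fixtures are built in code: small raster masks with known geometry,
# and synthetic cohorts with analytic ground truth.

newMask <- function(px, spacing = 1, phase = "ED", caseID = "fixture") {
    new("LVMask", pixels = px, spacingMmPerPx = spacing, phase = phase,
        caseID = caseID)
}

# axis-aligned filled rectangle, pixel-index corners inclusive (0-based)
rectMask <- function(x0, x1, y0, y1, W = 60, H = 240, spacing = 1) {
    px <- matrix(FALSE, H, W)
    px[(y0:y1) + 1, (x0:x1) + 1] <- TRUE
    newMask(px, spacing)
}

# filled digital circle of radius R centred on the canvas
circleMask <- function(R, W = 2 * R + 11, spacing = 1) {
    c0 <- (W - 1) / 2
    px <- outer(0:(W - 1), 0:(W - 1),
                function(y, x) (x - c0)^2 + (y - c0)^2 <= R^2)
    newMask(px, spacing)
}

manualLandmarks <- function(apex, base) {
    L <- sqrt(sum((apex - base)^2))
    new("Landmarks", apex = apex, mitralMid = base, axisLengthPx = L,
        axisUnit = (base - apex) / L)
}

# analytic half-spheroid diameter profile sampled at disk midpoints
spheroidProfile <- function(n, r = 20, L = 80) {
    x <- (seq_len(n) - 0.5) / n * L
    new("DiskProfile", diametersMm = 2 * r * sqrt(1 - (x / L)^2),
        diskHeightMm = L / n, axisLengthMm = L, nDisks = as.integer(n))
}

# cohort of synthetic cases: EF/EDV targets drawn from their own stream,
# case shapes and poses from per-case seeds (streams kept separate so no
# target information leaks into shape parameters)
cohortTargets <- function(n, targetSeed) {
    set.seed(targetSeed)
    list(ef = runif(n, 20, 75), edv = runif(n, 70, 180))
}

# features + direct-Simpson estimates + truth for a vector of case seeds
buildCohort <- function(caseSeeds, targetSeed, nDisks = 20L) {
    tg <- cohortTargets(length(caseSeeds), targetSeed)
    rows <- vector("list", length(caseSeeds))
    simpson <- truth <- numeric(length(caseSeeds))
    for (i in seq_along(caseSeeds)) {
        cs <- makeCase(tg$edv[i], tg$ef[i], seed = caseSeeds[i])
        fr <- renderCase(cs)
        pEd <- measureDiameters(fr$ed,
                                localizeLandmarks(extractContour(fr$ed)),
                                nDisks)
        pEs <- measureDiameters(fr$es,
                                localizeLandmarks(extractContour(fr$es)),
                                nDisks)
        rows[[i]] <- assembleFeatures(pEd, pEs, label = lvef(cs),
                                      nDisks = nDisks)
        simpson[i] <- lvef(simpsonEFFromMasks(fr$ed, fr$es, nDisks))
        truth[i] <- lvef(cs)
    }
    list(features = do.call(rbind, rows), simpson = simpson, truth = truth)
}

# random feature table in the package layout (no imaging involved)
randomFeatureTable <- function(n, seed, nDisks = 20L) {
    set.seed(seed)
    p <- 2L * (nDisks + 1L)
    X <- matrix(runif(n * p, 5, 60), n, p,
                dimnames = list(NULL, featureNames(nDisks)))
    df <- as.data.frame(X)
    df$ef <- NA_real_
    df
}

tmpDir <- function() {
    d <- tempfile("echoSimpson-test-")
    dir.create(d)
    d
}
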