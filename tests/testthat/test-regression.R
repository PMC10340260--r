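test_that("feature assembly follows the documented order", {
    expect_length(featureNames(20), 42)
    pEd <- spheroidProfile(20)
    pEs <- spheroidProfile(20, r = 14, L = 72)
    fv <- assembleFeatures(pEd, pEs, label = 58.5, caseID = "c1")
    expect_equal(ncol(fv), 44)   # case_id + 42 features + ef
    expect_equal(as.numeric(fv[sprintf("ed_diam_%02d", 1:20)]),
                 diameters(pEd))
    expect_equal(fv$ed_length, 80)
    expect_equal(fv$es_length, 72)
    expect_equal(fv$ef, 58.5)
    same <- assembleFeatures(pEd, pEd)
    expect_equal(as.numeric(same[sprintf("ed_diam_%02d", 1:20)]),
                 as.numeric(same[sprintf("es_diam_%02d", 1:20)]))
    expect_error(assembleFeatures(pEd, spheroidProfile(10)), "disks")
})

test_that("native OLS recovers exact linear labels and matches lm", {
    df <- randomFeatureTable(100, seed = 1)
    beta <- seq(0.1, 4.2, by = 0.1)
    df$ef <- 7 + as.matrix(df[featureNames(20)]) %*% beta
    m <- fitLinearEF(df)
    expect_false(m$fit$ridge)
    expect_lt(max(abs(m$fit$coefficients[-1] - beta)), 1e-6)
    expect_lt(mean(abs(predictEF(m, df) - df$ef)), 1e-8)
    # independent route: stats::lm on the same design
    lmFit <- lm(ef ~ ., data = df)
    expect_equal(unname(m$fit$coefficients), unname(coef(lmFit)),
                 tolerance = 1e-8)
})

test_that("constant labels give a pure intercept", {
    df <- randomFeatureTable(80, seed = 2)
    df$ef <- 42
    m <- fitLinearEF(df)
    expect_equal(unname(m$fit$coefficients[1]), 42, tolerance = 1e-8)
    expect_lt(max(abs(m$fit$coefficients[-1])), 1e-8)
    dfNo <- randomFeatureTable(10, seed = 3)
    expect_error(fitLinearEF(dfNo), "label")
})

test_that("rank-deficient designs fall back to ridge", {
    df <- randomFeatureTable(30, seed = 4)   # fewer rows than 43 parameters
    df$ef <- 50 + 0.3 * df$ed_length
    m <- fitLinearEF(df)
    expect_true(m$fit$ridge)
    expect_lt(mean(abs(predictEF(m, df) - df$ef)), 1e-3)
})

test_that("OLS coefficients land within three standard errors at n = 500", {
    set.seed(6)
    n <- 500
    X <- matrix(rnorm(n * 6), n, 6,
                dimnames = list(NULL, paste0("f", 1:6)))
    beta <- c(2, -1, 0.5, 3, 0, -2)
    y <- 30 + X %*% beta + rnorm(n, 0, 5)
    df <- data.frame(X); df$ef <- as.numeric(y)
    m <- fitLinearEF(df)
    se <- summary(lm(ef ~ ., data = df))$coefficients[-1, "Std. Error"]
    expect_true(all(abs(m$fit$coefficients[-1] - beta) < 3 * se))
})

test_that("grid search is deterministic and honours single-point grids", {
    df <- randomFeatureTable(60, seed = 7)
    df$ef <- 20 + 0.5 * df$ed_length - 0.3 * df$es_length
    spec <- regressorSpec("DT", grid = list(max_depth = 4L), seed = 3)
    m <- fitRegressor(spec, df)
    expect_equal(nrow(m$cvTable), 1)
    expect_equal(m$params$max_depth, 4L)
    m2 <- fitRegressor(spec, df)
    expect_identical(m$cvTable, m2$cvTable)
    expect_identical(echoSimpson:::foldAssignment(60, 5, 3),
                     echoSimpson:::foldAssignment(60, 5, 3))
    expect_error(regressorSpec("DT", grid = list(max_depth = integer(0))),
                 "empty candidate")
})

test_that("linear regression has vanishing CV error on noiseless linear data", {
    df <- randomFeatureTable(80, seed = 8)
    df$ef <- 5 + as.matrix(df[featureNames(20)]) %*% rep(0.2, 42)
    m <- fitRegressor(regressorSpec("LR", seed = 1), df)
    expect_lt(m$cvTable$cv_mse, 1e-10)
})

test_that("grid selection never loses to the worst grid point", {
    # depth-3 step function of one feature
    set.seed(101)
    n <- 400
    df <- data.frame(f1 = runif(n), f2 = runif(n), f3 = runif(n))
    df$ef <- 10 * floor(df$f1 * 8)
    tr <- 1:300; te <- 301:400
    grid <- 5:10
    sel <- fitRegressor(regressorSpec("DT", grid = list(max_depth = grid),
                                      seed = 5), df[tr, ])
    maeSel <- mean(abs(predictEF(sel, df[te, ]) - df$ef[te]))
    maes <- vapply(grid, function(d) {
        m <- fitRegressor(regressorSpec("DT", grid = list(max_depth = d),
                                        seed = 5), df[tr, ])
        mean(abs(predictEF(m, df[te, ]) - df$ef[te]))
    }, numeric(1))
    expect_lte(maeSel, max(maes) + 1e-9)
})

test_that("delegated learners honour the grid contract", {
    df <- randomFeatureTable(60, seed = 9)
    df$ef <- 25 + 0.4 * df$ed_length - 0.2 * df$es_length
    svr <- fitRegressor(regressorSpec(
        "SVR", grid = list(kernel = "linear", C = c(1, 10), epsilon = 0.1),
        seed = 2), df)
    expect_equal(nrow(svr$cvTable), 2)
    expect_lt(mean(abs(predictEF(svr, df) - df$ef)), 2)
    rf <- fitRegressor(regressorSpec(
        "RF", grid = list(n_estimators = 50L, max_depth = NA,
                          max_features = "sqrt"), seed = 2), df)
    expect_true(all(is.finite(predictEF(rf, df))))
    # same seed, same forest
    rf2 <- fitRegressor(regressorSpec(
        "RF", grid = list(n_estimators = 50L, max_depth = NA,
                          max_features = "sqrt"), seed = 2), df)
    expect_equal(predictEF(rf, df), predictEF(rf2, df), tolerance = 1e-12)
})

test_that("predictions are row-wise and validate dimensionality", {
    df <- randomFeatureTable(50, seed = 10)
    df$ef <- 15 + 0.3 * df$ed_length
    m <- fitLinearEF(df)
    expect_lt(max(abs(predictEF(m, df) - df$ef)), 1e-6)
    dup <- rbind(df[3, ], df[3, ])
    p <- predictEF(m, dup)
    expect_equal(p[1], p[2])
    bad <- df; names(bad)[1] <- "renamed"
    expect_error(predictEF(m, bad), "feature columns")
})

test_that("sequence layout is a lossless two-step reshape", {
    v <- as.numeric(1:42)
    m <- sequenceLayout(v)
    expect_equal(dim(m), c(2, 21))
    expect_equal(as.numeric(t(m)), v)
    expect_equal(unname(m[1, ]), v[1:21])       # step 1 = ED block
    expect_equal(unname(m[2, ]), v[22:42])      # step 2 = ES block
    m10 <- sequenceLayout(as.numeric(1:22), nDisks = 10)
    expect_equal(dim(m10), c(2, 11))
    expect_error(sequenceLayout(1:40), "expected 42")
})

test_that("standardization is exactly invertible", {
    set.seed(11)
    X <- matrix(rnorm(200), 20, 10)
    std <- echoSimpson:::fitStandardizer(X)
    Z <- echoSimpson:::applyStandardizer(std, X)
    expect_equal(colMeans(Z), rep(0, 10), tolerance = 1e-12)
    expect_equal(echoSimpson:::invertStandardizer(std, Z), X,
                 tolerance = 1e-12)
    # constant column keeps scale 1
    X[, 3] <- 5
    std2 <- echoSimpson:::fitStandardizer(X)
    expect_equal(std2$scale[3], 1)
})
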