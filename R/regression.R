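#' @include AllGenerics.R
NULL

#' Feature-column names for the regression layout
#'
#' The fixed, documented feature order: the end-diastolic disk diameters
#' (base -> apex), the end-diastolic axis length, then the end-systolic
#' disk diameters and axis length.  The label column is `ef`.
#'
#' @param nDisks number of disks per frame (default 20, giving 42
#'   features).
#' @return character vector of feature-column names.
#' @export
featureNames <- function(nDisks = 20L) {
    c(sprintf("ed_diam_%02d", seq_len(nDisks)), "ed_length",
      sprintf("es_diam_%02d", seq_len(nDisks)), "es_length")
}

#' Assemble a regression feature vector from two disk profiles
#'
#' Concatenates the end-diastolic and end-systolic disk diameters and
#' major-axis lengths in the fixed order of [featureNames()], with the
#' reference ejection fraction attached as label when available.
#'
#' @param edProfile,esProfile [DiskProfile-class] objects for the two
#'   frames; both must have `nDisks` disks.
#' @param label reference LVEF in percent, or `NA` when unknown.
#' @param nDisks expected number of disks (default 20; other values are
#'   allowed but must match a correspondingly configured model).
#' @param caseID optional case identifier column.
#' @return one-row data frame: `2 * nDisks + 2` feature columns plus
#'   `ef` (and `case_id` when given).
#' @export
assembleFeatures <- function(edProfile, esProfile, label = NA_real_,
                             nDisks = 20L, caseID = NULL) {
    stopifnot(is(edProfile, "DiskProfile"), is(esProfile, "DiskProfile"))
    if (edProfile@nDisks != nDisks || esProfile@nDisks != nDisks)
        stop(sprintf("profiles must have %d disks (got %d ED, %d ES)",
                     nDisks, edProfile@nDisks, esProfile@nDisks))
    vals <- c(edProfile@diametersMm, edProfile@axisLengthMm,
              esProfile@diametersMm, esProfile@axisLengthMm)
    if (any(!is.finite(vals)) || any(vals < 0))
        stop("features must be finite and non-negative")
    row <- as.data.frame(as.list(stats::setNames(vals, featureNames(nDisks))))
    row$ef <- as.numeric(label)
    if (!is.null(caseID)) row <- cbind(case_id = caseID, row)
    row
}

# Feature matrix / label vector from a feature table.
featureMatrix <- function(data) {
    cols <- setdiff(names(data), c("ef", "case_id"))
    X <- as.matrix(data[cols])
    storage.mode(X) <- "double"
    list(X = X, y = data$ef, names = cols)
}

# z-score standardization from training statistics; constant columns
# keep scale 1 so the transform stays exactly invertible.
fitStandardizer <- function(X) {
    mu <- colMeans(X)
    sd <- apply(X, 2, stats::sd)
    sd[!is.finite(sd) | sd == 0] <- 1
    list(center = mu, scale = sd)
}

applyStandardizer <- function(std, X) {
    sweep(sweep(X, 2, std$center), 2, std$scale, "/")
}

invertStandardizer <- function(std, Z) {
    sweep(sweep(Z, 2, std$scale, "*"), 2, std$center, "+")
}

# Native ordinary least squares via QR, with a small ridge fallback
# (lambda = 1e-8) when the design is rank-deficient or has fewer rows
# than parameters.
olsFit <- function(X, y, lambda = 1e-8) {
    Xd <- cbind(`(Intercept)` = 1, X)
    qrX <- qr(Xd)
    if (qrX$rank == ncol(Xd) && nrow(Xd) >= ncol(Xd)) {
        beta <- qr.coef(qrX, y)
        ridge <- FALSE
    } else {
        beta <- solve(crossprod(Xd) + lambda * diag(ncol(Xd)),
                      crossprod(Xd, y))[, 1]
        ridge <- TRUE
    }
    list(coefficients = stats::setNames(as.numeric(beta), colnames(Xd)),
         ridge = ridge)
}

olsPredict <- function(fit, X) {
    as.numeric(cbind(1, X) %*% fit$coefficients)
}

#' Fit a native linear LVEF model
#'
#' Ordinary least squares on the disk-diameter features, solved by QR
#' factorization of the design matrix.  When the design is
#' rank-deficient (collinear diameters) or has fewer rows than
#' parameters, a ridge fallback with \eqn{\lambda = 10^{-8}} is used.
#'
#' @param data feature table with a non-`NA` `ef` label column (layout
#'   of [assembleFeatures()]).
#' @return a fitted model usable with [predictEF()]; the component
#'   `fit$coefficients` holds intercept and feature coefficients.
#' @export
fitLinearEF <- function(data) {
    fm <- featureMatrix(data)
    if (is.null(fm$y) || all(is.na(fm$y)))
        stop("no labels: the ef column is missing or all NA")
    keep <- !is.na(fm$y)
    model <- list(kind = "LR",
                  params = list(),
                  fit = olsFit(fm$X[keep, , drop = FALSE], fm$y[keep]),
                  standardize = NULL,
                  featureNames = fm$names,
                  nDisks = (length(fm$names) - 2L) %/% 2L)
    class(model) <- "efModel"
    model
}

#' Hyperparameter grid search specification
#'
#' Describes a regressor family, its hyperparameter grid and the
#' cross-validation settings used by [fitRegressor()].  The default
#' grids follow the published search ranges for each family; grid keys
#' use the familiar names (`C`, `epsilon`, `gamma`, `n_estimators`,
#' `max_depth`, `max_features`, `min_samples_leaf`, `min_samples_split`,
#' `units`, `learning_rate`, `batch_size`, `epochs`, `optimizer`).
#'
#' @param kind one of `"LR"`, `"SVR"`, `"DT"`, `"RF"`, `"RNN"`, `"LSTM"`.
#' @param grid named list of candidate values per hyperparameter;
#'   `NULL` uses [defaultGrid()] for the family.
#' @param cvFolds number of cross-validation folds (default 5).
#' @param seed seed controlling fold assignment and stochastic learners.
#' @return an object of class `RegressorSpec`.
#' @export
regressorSpec <- function(kind = c("LR", "SVR", "DT", "RF", "RNN", "LSTM"),
                          grid = NULL, cvFolds = 5L, seed = 1L) {
    kind <- match.arg(kind)
    if (is.null(grid)) grid <- defaultGrid(kind)
    if (!is.list(grid))
        stop("grid must be a named list of candidate values")
    if (length(grid) && any(lengths(grid) == 0L))
        stop("empty candidate list in grid for: ",
             paste(names(grid)[lengths(grid) == 0L], collapse = ", "))
    if (cvFolds < 2L) stop("cvFolds must be >= 2")
    structure(list(kind = kind, grid = grid, cvFolds = as.integer(cvFolds),
                   seed = as.integer(seed)),
              class = "RegressorSpec")
}

#' Default hyperparameter grids per regressor family
#'
#' @param kind regressor family, as in [regressorSpec()].
#' @return named list of candidate values.
#' @export
defaultGrid <- function(kind = c("LR", "SVR", "DT", "RF", "RNN", "LSTM")) {
    kind <- match.arg(kind)
    switch(kind,
        LR = list(),
        SVR = list(
            kernel = c("linear", "rbf"),
            degree = 2:6,
            gamma = c(0.001, 0.01, 0.1, 1),
            C = c(0.1, 1, 10),
            epsilon = c(0.1, 0.01, 0.001)),
        DT = list(
            max_depth = 5:10,
            min_samples_leaf = seq(5L, 20L, 2L),
            min_samples_split = seq(5L, 20L, 2L)),
        RF = list(
            n_estimators = seq(100L, 500L, 100L),
            max_depth = c(NA, 5L, 10L),
            max_features = c("auto", "sqrt", "log2")),
        RNN = list(
            units = list(c(128L, 32L, 16L)),
            learning_rate = 0.001,
            batch_size = 32L,
            epochs = 70L,
            optimizer = "adam"),
        LSTM = list(
            units = list(c(64L, 32L, 16L)),
            learning_rate = 0.001,
            batch_size = 32L,
            epochs = 100L,
            optimizer = "sgd"))
}

# Deterministic k-fold assignment: a pure function of (n, k, seed).
foldAssignment <- function(n, k, seed) {
    withSeed(seed, sample(rep_len(seq_len(k), n)))
}

standardizedKinds <- c("SVR", "RNN", "LSTM")

# Train one learner at one grid point.  The linear model is native;
# kernel, tree and forest learners are delegated to the standard
# implementations behind this fixed contract.
trainOne <- function(kind, params, X, y, nDisks, seed) {
    std <- NULL
    stdY <- NULL
    if (kind %in% standardizedKinds) {
        std <- fitStandardizer(X)
        X <- applyStandardizer(std, X)
    }
    fit <- switch(kind,
        LR = olsFit(X, y),
        SVR = e1071::svm(
            x = X, y = y, type = "eps-regression", scale = FALSE,
            kernel = if (identical(params$kernel, "rbf")) "radial"
                     else "linear",
            degree = if (!is.null(params$degree)) params$degree else 3,
            gamma = if (!is.null(params$gamma)) params$gamma else 1 / ncol(X),
            cost = if (!is.null(params$C)) params$C else 1,
            epsilon = if (!is.null(params$epsilon)) params$epsilon else 0.1),
        DT = {
            df <- data.frame(X, ef = y, check.names = FALSE)
            rpart::rpart(ef ~ ., data = df, method = "anova",
                control = rpart::rpart.control(
                    maxdepth = if (!is.null(params$max_depth))
                        params$max_depth else 30,
                    minbucket = if (!is.null(params$min_samples_leaf))
                        params$min_samples_leaf else 7,
                    minsplit = if (!is.null(params$min_samples_split))
                        params$min_samples_split else 20,
                    cp = 0, xval = 0))
        },
        RF = withSeed(seed, {
            p <- ncol(X)
            mtry <- if (is.null(params$max_features) ||
                        params$max_features == "auto") p
                    else if (params$max_features == "sqrt")
                        max(1L, floor(sqrt(p)))
                    else max(1L, floor(log2(p)))
            maxnodes <- if (is.null(params$max_depth) ||
                            is.na(params$max_depth)) NULL
                        else 2L^as.integer(params$max_depth)
            randomForest::randomForest(
                x = X, y = y,
                ntree = if (!is.null(params$n_estimators))
                    params$n_estimators else 500,
                mtry = mtry, maxnodes = maxnodes)
        }),
        RNN = ,
        LSTM = {
            stdY <- fitStandardizer(matrix(y, ncol = 1))
            ys <- (y - stdY$center) / stdY$scale
            trainRecurrent(
                featureSequenceArray(X, nDisks), ys,
                kind = tolower(kind),
                units = if (!is.null(params$units)) unlist(params$units)
                        else c(32L, 16L),
                lr = if (!is.null(params$learning_rate))
                    params$learning_rate else 0.001,
                epochs = if (!is.null(params$epochs)) params$epochs else 70L,
                batchSize = if (!is.null(params$batch_size))
                    params$batch_size else 32L,
                optimizer = if (!is.null(params$optimizer))
                    params$optimizer else "adam",
                seed = seed)
        })
    list(kind = kind, params = params, fit = fit,
         standardize = std, standardizeY = stdY)
}

predictOne <- function(model, X, nDisks) {
    if (!is.null(model$standardize))
        X <- applyStandardizer(model$standardize, X)
    out <- switch(model$kind,
        LR = olsPredict(model$fit, X),
        SVR = as.numeric(stats::predict(model$fit, X)),
        DT = as.numeric(stats::predict(
            model$fit, data.frame(X, check.names = FALSE))),
        RF = as.numeric(stats::predict(model$fit, X)),
        RNN = ,
        LSTM = as.numeric(predictRecurrent(
            model$fit, featureSequenceArray(X, nDisks))))
    if (!is.null(model$standardizeY))
        out <- out * model$standardizeY$scale + model$standardizeY$center
    out
}

#' Grid-search a regressor with k-fold cross-validation
#'
#' Exhaustively evaluates every grid point by k-fold cross-validation
#' (mean squared error criterion, matching the training loss of the
#' network configurations), refits the best point on the full training
#' data, and returns the fitted model together with the complete CV
#' score table for audit.  Fold assignment is a pure function of the
#' number of rows, the fold count and the seed.  Feature
#' standardization (z-score on training statistics) is applied for the
#' kernel and sequence learners; tree learners see raw features.
#'
#' @param spec a `RegressorSpec` from [regressorSpec()].
#' @param data feature table with non-`NA` `ef` labels.
#' @return an `efModel` with components `kind`, `params` (selected
#'   hyperparameters), `fit`, `cvTable` and `cvFolds`.
#' @export
fitRegressor <- function(spec, data) {
    stopifnot(inherits(spec, "RegressorSpec"))
    fm <- featureMatrix(data)
    keep <- which(!is.na(fm$y))
    if (length(keep) < spec$cvFolds)
        stop("need at least cvFolds labeled rows")
    X <- fm$X[keep, , drop = FALSE]
    y <- fm$y[keep]
    nDisks <- (length(fm$names) - 2L) %/% 2L
    combos <- if (length(spec$grid) == 0L) {
        data.frame(row.names = 1)
    } else {
        do.call(expand.grid, c(lapply(spec$grid, function(v)
            if (is.list(v)) I(v) else v),
            stringsAsFactors = FALSE))
    }
    folds <- foldAssignment(length(y), spec$cvFolds, spec$seed)
    cvMse <- numeric(nrow(combos))
    for (i in seq_len(nrow(combos))) {
        params <- lapply(combos[i, , drop = FALSE], function(v)
            if (is.list(v)) v[[1]] else v)
        se <- 0
        for (f in seq_len(spec$cvFolds)) {
            tr <- folds != f
            m <- trainOne(spec$kind, params, X[tr, , drop = FALSE], y[tr],
                          nDisks, spec$seed + f)
            pred <- predictOne(m, X[!tr, , drop = FALSE], nDisks)
            se <- se + sum((pred - y[!tr])^2)
        }
        cvMse[i] <- se / length(y)
    }
    best <- which.min(cvMse)
    bestParams <- lapply(combos[best, , drop = FALSE], function(v)
        if (is.list(v)) v[[1]] else v)
    final <- trainOne(spec$kind, bestParams, X, y, nDisks, spec$seed)
    cvTable <- cbind(combos, cv_mse = cvMse)
    model <- c(final,
               list(featureNames = fm$names, nDisks = nDisks,
                    cvTable = cvTable, cvFolds = spec$cvFolds,
                    seed = spec$seed))
    class(model) <- "efModel"
    model
}

#' Predict LVEF for a feature table
#'
#' @param model a fitted `efModel` from [fitLinearEF()] or
#'   [fitRegressor()].
#' @param data feature table with the same feature columns the model
#'   was trained on (a label column, if present, is ignored).
#' @return numeric vector of LVEF predictions, percent, one per row.
#' @export
predictEF <- function(model, data) {
    stopifnot(inherits(model, "efModel"))
    fm <- featureMatrix(data)
    if (!identical(fm$names, model$featureNames))
        stop("feature columns do not match the fitted model")
    predictOne(model, fm$X, model$nDisks)
}

#' Reshape a feature vector into the two-step frame sequence
#'
#' The sequence learners consume the features as a 2-step sequence:
#' step 1 is the end-diastolic block (diameters plus axis length),
#' step 2 the end-systolic block.  The reshape is lossless:
#' `as.numeric(t(m))` recovers the original vector.
#'
#' @param features numeric feature vector of length `2 * (nDisks + 1)`
#'   in [featureNames()] order, or a one-row feature data frame.
#' @param nDisks number of disks per frame.
#' @return a `2 x (nDisks + 1)` matrix, one row per time step.
#' @export
sequenceLayout <- function(features, nDisks = 20L) {
    if (is.data.frame(features)) {
        if (nrow(features) != 1L)
            stop("features must be a single row or a numeric vector")
        features <- as.numeric(features[featureNames(nDisks)])
    }
    p <- nDisks + 1L
    if (length(features) != 2L * p)
        stop(sprintf("expected %d features, got %d", 2L * p,
                     length(features)))
    m <- rbind(ED = features[seq_len(p)], ES = features[p + seq_len(p)])
    colnames(m) <- c(sprintf("diam_%02d", seq_len(nDisks)), "length")
    m
}

# Feature matrix -> n x 2 x (nDisks + 1) sequence array.
featureSequenceArray <- function(X, nDisks) {
    p <- nDisks + 1L
    arr <- array(0, dim = c(nrow(X), 2L, p))
    arr[, 1L, ] <- X[, seq_len(p), drop = FALSE]
    arr[, 2L, ] <- X[, p + seq_len(p), drop = FALSE]
    arr
}
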