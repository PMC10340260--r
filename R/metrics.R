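#' @include AllGenerics.R
NULL

#' Dice similarity coefficient between two masks
#'
#' \eqn{\mathrm{DSC} = 2|A \cap B| / (|A| + |B|)}, ranging from 0 (no
#' overlap) to 1 (identical masks).  Two empty masks are defined as
#' perfectly agreeing (DSC 1) with a warning.
#'
#' @param maskA,maskB [LVMask-class] objects on the same pixel grid.
#' @return DSC in \eqn{[0, 1]}.
#' @export
diceCoefficient <- function(maskA, maskB) {
    stopifnot(is(maskA, "LVMask"), is(maskB, "LVMask"))
    if (!identical(dim(maskA@pixels), dim(maskB@pixels)))
        stop("masks must have identical dimensions")
    na <- sum(maskA@pixels); nb <- sum(maskB@pixels)
    if (na + nb == 0L) {
        warning("both masks empty; Dice defined as 1")
        return(1)
    }
    2 * sum(maskA@pixels & maskB@pixels) / (na + nb)
}

# All min distances from each row of u to the set v (chunked to bound
# the distance-matrix size).
minDistances <- function(u, v) {
    n <- nrow(u)
    out <- numeric(n)
    chunk <- max(1L, floor(4e6 / nrow(v)))
    for (s in seq(1L, n, by = chunk)) {
        e <- min(s + chunk - 1L, n)
        dx <- outer(u[s:e, 1], v[, 1], "-")
        dy <- outer(u[s:e, 2], v[, 2], "-")
        out[s:e] <- sqrt(apply(dx * dx + dy * dy, 1, min))
    }
    out
}

asPointSet <- function(p, what) {
    p <- as.matrix(p)
    if (ncol(p) != 2L || nrow(p) == 0L || any(!is.finite(p)))
        stop(what, " must be a non-empty n x 2 matrix of finite coordinates")
    p
}

#' Hausdorff distance between two point sets
#'
#' \eqn{H(U, V) = \max\{\max_{u} \min_{v} \|u - v\|,
#' \max_{v} \min_{u} \|u - v\|\}}: the worst-case boundary
#' disagreement, symmetric by construction.  Units follow the inputs
#' (mm for contours from [maskContourPoints()]).
#'
#' @param u,v non-empty n x 2 point matrices.
#' @return the Hausdorff distance.
#' @examples
#' hausdorffDistance(cbind(0, 0), cbind(3, 4))  # 5
#' @export
hausdorffDistance <- function(u, v) {
    u <- asPointSet(u, "u"); v <- asPointSet(v, "v")
    max(max(minDistances(u, v)), max(minDistances(v, u)))
}

#' Mean absolute contour error between two point sets
#'
#' Symmetric mean nearest-neighbor distance: the average of (i) the
#' mean distance from each point of `u` to its nearest point of `v` and
#' (ii) the converse.  Pairing-free, symmetric, and exactly 0 for
#' identical sets.
#'
#' @param u,v non-empty n x 2 point matrices.
#' @return the mean contour error, same units as the inputs.
#' @export
contourMAE <- function(u, v) {
    u <- asPointSet(u, "u"); v <- asPointSet(v, "v")
    (mean(minDistances(u, v)) + mean(minDistances(v, u))) / 2
}

#' Agreement statistics for predicted vs. reference values
#'
#' Computes the cohort metrics used to judge an LVEF estimator: mean
#' absolute error, root mean squared error, Pearson correlation, and
#' the Bland-Altman bias with limits of agreement at \eqn{\pm 1.96}
#' sample standard deviations of the paired differences.
#'
#' @param predicted,truth equal-length numeric vectors, n >= 2.
#' @return an [AgreementReport-class].  For a constant series the
#'   correlation is undefined and reported as `NA` with a warning.
#' @examples
#' regressionMetrics(c(2, 4), c(1, 2))
#' @export
regressionMetrics <- function(predicted, truth) {
    if (length(predicted) != length(truth))
        stop("predicted and truth must have equal length")
    if (length(predicted) < 2L)
        stop("at least 2 paired observations are required")
    if (any(!is.finite(predicted)) || any(!is.finite(truth)))
        stop("non-finite values in the paired series")
    d <- predicted - truth
    corr <- if (stats::sd(predicted) == 0 || stats::sd(truth) == 0) {
        warning("constant series; correlation undefined (NA)")
        NA_real_
    } else {
        stats::cor(predicted, truth)
    }
    bias <- mean(d)
    sdd <- stats::sd(d)                    # n - 1 denominator
    new("AgreementReport",
        mae = mean(abs(d)),
        rmse = sqrt(mean(d^2)),
        corr = corr,
        bias = bias,
        loaLow = bias - 1.96 * sdd,
        loaHigh = bias + 1.96 * sdd,
        n = length(d))
}

#' Coerce an agreement report to a one-row data frame
#'
#' @param report an [AgreementReport-class].
#' @return data frame with columns mae, rmse, corr, bias, loa_low,
#'   loa_high, n.
#' @export
agreementAsDataFrame <- function(report) {
    stopifnot(is(report, "AgreementReport"))
    data.frame(mae = report@mae, rmse = report@rmse, corr = report@corr,
               bias = report@bias, loa_low = report@loaLow,
               loa_high = report@loaHigh, n = report@n)
}

#' Bland-Altman plot of predicted vs. reference values
#'
#' Differences against pair means, with the bias line and the
#' \eqn{\pm 1.96} SD limits of agreement.
#'
#' @param predicted,truth equal-length numeric vectors.
#' @param file optional PNG path; when given the plot is written there.
#' @param label axis label for the quantity (default LVEF in percent).
#' @return (invisibly) the [AgreementReport-class].
#' @export
blandAltmanPlot <- function(predicted, truth, file = NULL,
                            label = "LVEF (%)") {
    rep <- regressionMetrics(predicted, truth)
    if (!is.null(file)) {
        grDevices::png(file, width = 640, height = 480)
        on.exit(grDevices::dev.off())
    }
    avg <- (predicted + truth) / 2
    dif <- predicted - truth
    graphics::plot(avg, dif, pch = 19, col = "grey30",
                   xlab = paste("Mean of estimate and reference,", label),
                   ylab = paste("Estimate - reference,", label),
                   main = "Bland-Altman agreement",
                   ylim = range(c(dif, rep@loaLow, rep@loaHigh)))
    graphics::abline(h = rep@bias, col = "blue", lwd = 2)
    graphics::abline(h = c(rep@loaLow, rep@loaHigh), col = "red", lty = 2)
    invisible(rep)
}

#' Correlation scatter plot of predicted vs. reference values
#'
#' @inheritParams blandAltmanPlot
#' @return (invisibly) the [AgreementReport-class].
#' @export
correlationPlot <- function(predicted, truth, file = NULL,
                            label = "LVEF (%)") {
    rep <- regressionMetrics(predicted, truth)
    if (!is.null(file)) {
        grDevices::png(file, width = 640, height = 480)
        on.exit(grDevices::dev.off())
    }
    graphics::plot(truth, predicted, pch = 19, col = "grey30",
                   xlab = paste("Reference", label),
                   ylab = paste("Estimated", label),
                   main = sprintf("Corr = %.3f", rep@corr))
    graphics::abline(0, 1, col = "blue", lwd = 2)
    invisible(rep)
}
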