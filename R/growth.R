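#' @include AllClasses.R AllGenerics.R
NULL

#' Fit a Richards growth curve
#'
#' Nonlinear least-squares fit of the generalized-logistic (Richards) form
#' \deqn{y(t) = A (1 + \nu e^{1+\nu} e^{(\mu/A)(1+\nu)^{1+1/\nu}(\lambda - t)})^{-1/\nu}}
#' where \code{A} is the asymptotic OD, \code{mu} the maximum slope (OD/min),
#' \code{lambda} the lag (intercept of the inflection tangent with the
#' baseline, min) and \code{nu} the shape (1 = logistic).  Initialization:
#' \code{A} = max OD, \code{mu} = max finite-difference slope, \code{lambda} =
#' first time OD exceeds baseline + 5% of range; multi-start over
#' \code{nu} in {0.5, 1, 2}, best residual sum of squares kept.
#'
#' @param time strictly increasing time points (min), length >= 8.
#' @param od OD values (>= 0), same length.
#' @return list of class \code{"GrowthParams"}: \code{A}, \code{mu},
#'   \code{lambda}, \code{nu}, \code{rms} (fit residual RMS), \code{converged}.
#' @export
fitRichards <- function(time, od) {
    if (is.data.frame(time)) { od <- time$od; time <- time$time_min }
    if (length(time) < 8L) stop("need >= 8 time points for a Richards fit")
    if (any(diff(time) <= 0)) stop("time points must be strictly increasing")
    if (any(od < 0)) stop("OD values must be non-negative")
    rng <- diff(range(od))
    if (rng <= 0) stop("constant OD curve: zero range, nothing to fit")

    A0 <- max(od)
    mu0 <- max(diff(od) / diff(time))
    if (mu0 <= 0) mu0 <- rng / diff(range(time))
    lam0 <- time[which(od > min(od) + 0.05 * rng)[1L]]
    if (is.na(lam0)) lam0 <- time[1L]

    best <- NULL
    for (nu0 in c(0.5, 1, 2)) {
        fit <- tryCatch(
            minpack.lm::nlsLM(
                od ~ richardsCurve(time, A, mu, lambda, nu),
                start = list(A = A0, mu = mu0, lambda = lam0, nu = nu0),
                lower = c(A = 1e-8, mu = 1e-8, lambda = 0, nu = 1e-3),
                control = minpack.lm::nls.lm.control(maxiter = 200)),
            error = function(e) NULL)
        if (is.null(fit)) next
        rss <- sum(stats::residuals(fit)^2)
        if (is.null(best) || rss < best$rss)
            best <- list(fit = fit, rss = rss)
    }
    if (is.null(best))
        stop("Richards fit did not converge from any start (A0=", signif(A0, 3),
             ", mu0=", signif(mu0, 3), ", lambda0=", signif(lam0, 3), ")")
    p <- as.list(stats::coef(best$fit))
    structure(list(A = p$A, mu = p$mu, lambda = p$lambda, nu = p$nu,
                   rms = sqrt(best$rss / length(od)), converged = TRUE),
              class = "GrowthParams")
}

#' @export
print.GrowthParams <- function(x, ...) {
    cat(sprintf("Richards fit: A=%.4g, mu=%.4g OD/min, lambda=%.4g min, nu=%.3g (RMS %.3g)\n",
                x$A, x$mu, x$lambda, x$nu, x$rms))
    invisible(x)
}

#' Heat-induced lag
#'
#' Difference in fitted lag duration between the heat-stressed and the
#' mock-treated culture of one strain; negative values (faster recovery than
#' mock) are meaningful and returned as-is.
#'
#' @param hs,mock \code{"GrowthParams"} fits of the heat-stressed and mock
#'   curves.
#' @return lag difference in minutes.
#' @export
heatInducedLag <- function(hs, mock) {
    stopifnot(inherits(hs, "GrowthParams"), inherits(mock, "GrowthParams"))
    hs$lambda - mock$lambda
}

#' Aggregate replicate heat-induced lags
#'
#' @param lags numeric vector of replicate lag differences for one strain.
#' @return list: \code{mean}, \code{sd}, \code{n}.
#' @export
aggregateLagReplicates <- function(lags) {
    list(mean = mean(lags), sd = stats::sd(lags), n = length(lags))
}

#' Batch-correct plate trait measurements
#'
#' Subtracts the batch mean from every measurement, then iteratively removes
#' over-dispersed batches: while any batch variance exceeds \code{varRatio}
#' times the mean batch variance, the highest-variance batch is removed and
#' variances are recomputed.
#'
#' @param values numeric trait values.
#' @param batch batch labels, same length.
#' @param varRatio removal threshold on the batch-variance ratio.
#' @return list: \code{corrected} (named by original index, dropped batches
#'   excluded), \code{removedBatches}.
#' @export
batchCorrect <- function(values, batch, varRatio = 2.5) {
    stopifnot(length(values) == length(batch), length(values) >= 1L)
    batch <- as.character(batch)
    centered <- values - stats::ave(values, batch)
    keep <- unique(batch)
    removed <- character(0)
    repeat {
        vs <- vapply(keep, function(b) {
            x <- centered[batch == b]
            if (length(x) < 2L) 0 else stats::var(x)
        }, numeric(1))
        if (length(keep) <= 1L || !any(vs > varRatio * mean(vs))) break
        worst <- keep[which.max(vs)]
        removed <- c(removed, worst)
        keep <- setdiff(keep, worst)
    }
    if (length(keep) == 0L) stop("all batches removed by the variance filter")
    sel <- batch %in% keep
    out <- centered[sel]
    names(out) <- which(sel)
    list(corrected = out, removedBatches = removed)
}

#' Growth efficiency
#'
#' Final minus initial OD of a growth curve.
#'
#' @param time time points (min), strictly increasing.
#' @param od OD values.
#' @return OD difference.
#' @export
growthEfficiency <- function(time, od) {
    if (is.data.frame(time)) { od <- time$od; time <- time$time_min }
    if (any(diff(time) <= 0)) stop("time points must be strictly increasing")
    od[length(od)] - od[1L]
}
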