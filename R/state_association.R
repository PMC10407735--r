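#' @include AllClasses.R AllGenerics.R
NULL

#' Per-feature linear models on the state score
#'
#' OLS of every (standardized) feature on the state score over the shared
#' strains: slope sign, adjusted R-squared, two-sided p and BH q (adjusted
#' within the matrix's layer).  Constant features are skipped with a log
#' entry.
#'
#' @param abund an [AbundanceMatrix-class].
#' @param scores a \code{"StateScoreVector"} (or named numeric).
#' @param minStrains minimum shared strains.
#' @return data.frame of class \code{"FeatureModelTable"}: \code{feature},
#'   \code{slope}, \code{slopeSign}, \code{adjR2}, \code{p}, \code{q},
#'   \code{n}, \code{layer}; attribute \code{"skipped"} lists constant
#'   features.
#' @export
featureStateModels <- function(abund, scores, minStrains = 20L) {
    stopifnot(is(abund, "AbundanceMatrix"))
    v <- abundanceValues(standardizeFeatures(abund))
    strains <- intersect(colnames(v), names(scores)[!is.na(scores)])
    if (length(strains) < minStrains)
        stop("need >= ", minStrains, " shared strains")
    s <- as.numeric(scores[strains])
    v <- v[, strains, drop = FALSE]
    # pairwise-complete per-feature correlation with the score
    r <- suppressWarnings(as.numeric(
        stats::cor(t(v), s, use = "pairwise.complete.obs")))
    n <- rowSums(!is.na(v))
    skipped <- rownames(v)[is.na(r) | n < 3L]
    ok <- !(rownames(v) %in% skipped)
    r2 <- r^2
    adjR2 <- 1 - (1 - r2) * (n - 1) / (n - 2)
    tstat <- r * sqrt((n - 2) / pmax(1 - r2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
    out <- data.frame(feature = rownames(v), slope = r, slopeSign = sign(r),
                      adjR2 = adjR2, p = p, q = NA_real_, n = n,
                      layer = layerTag(abund), stringsAsFactors = FALSE)
    out <- out[ok, , drop = FALSE]
    out$q <- stats::p.adjust(out$p, "BH")
    rownames(out) <- NULL
    attr(out, "skipped") <- skipped
    class(out) <- c("FeatureModelTable", "data.frame")
    out
}

#' Summarize state-score fits per GO term
#'
#' Intersects each term's membership with the measured features and reports
#' the proportion significant at \code{qMax} and the mean signed accuracy
#' (mean over members of sign(slope) x adjusted R-squared).  Terms with
#' fewer than \code{minSize} measured members are excluded.  For
#' phosphopeptide layers, reduce to one best peptide per protein first (see
#' [selectBestPeptide()]) and pass a protein-level model table.
#'
#' @param models a \code{"FeatureModelTable"} from [featureStateModels()].
#' @param goMap data.frame with columns \code{feature} and \code{term}.
#' @param minSize minimum measured members per term.
#' @param qMax significance threshold.
#' @return data.frame of class \code{"GoSummary"}: \code{term}, \code{n},
#'   \code{propSignificant}, \code{signedAccuracy}.
#' @export
goTermSummary <- function(models, goMap, minSize = 3L, qMax = 0.05) {
    stopifnot(all(c("feature", "term") %in% colnames(goMap)))
    if (nrow(goMap) == 0L) stop("empty GO map")
    goMap <- goMap[goMap$feature %in% models$feature, , drop = FALSE]
    ix <- match(goMap$feature, models$feature)
    rows <- lapply(split(ix, goMap$term), function(members) {
        if (length(members) < minSize) return(NULL)
        m <- models[members, ]
        data.frame(n = nrow(m),
                   propSignificant = mean(m$q <= qMax),
                   signedAccuracy = mean(m$slopeSign * m$adjR2))
    })
    keep <- !vapply(rows, is.null, logical(1))
    out <- cbind(data.frame(term = names(rows)[keep],
                            stringsAsFactors = FALSE),
                 do.call(rbind, rows[keep]))
    rownames(out) <- NULL
    class(out) <- c("GoSummary", "data.frame")
    out
}

#' PCA of strains with per-component state-score regression
#'
#' PCA over strains (observations) x standardized features; missing values
#' are mean-imputed (i.e. set to 0 on the standardized scale) for the PCA
#' only.  Each principal component's strain scores are regressed on the
#' state score.
#'
#' @param abund an [AbundanceMatrix-class].
#' @param scores a \code{"StateScoreVector"} (or named numeric).
#' @param nComponents number of components to keep.
#' @return list of class \code{"PCAStateResult"}: \code{scores} (strains x
#'   PCs), \code{varianceFraction}, \code{adjR2} (per PC), \code{nImputed}.
#' @export
pcaStateCorrelation <- function(abund, scores, nComponents = 5L) {
    stopifnot(is(abund, "AbundanceMatrix"))
    z <- abundanceValues(standardizeFeatures(abund))
    strains <- intersect(colnames(z), names(scores)[!is.na(scores)])
    if (nComponents > length(strains))
        stop("more components than strains")
    z <- z[, strains, drop = FALSE]
    nImputed <- sum(is.na(z))
    z[is.na(z)] <- 0
    keep <- apply(z, 1L, stats::sd) > 0
    pc <- stats::prcomp(t(z[keep, , drop = FALSE]), center = TRUE,
                        scale. = FALSE)
    k <- min(nComponents, ncol(pc$x))
    varFrac <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
    s <- as.numeric(scores[strains])
    adjR2 <- vapply(seq_len(k), function(i)
        summary(stats::lm(pc$x[, i] ~ s))$adj.r.squared, numeric(1))
    structure(list(scores = pc$x[, seq_len(k), drop = FALSE],
                   varianceFraction = varFrac, adjR2 = adjR2,
                   nImputed = nImputed),
              class = "PCAStateResult")
}

#' @export
print.PCAStateResult <- function(x, ...) {
    k <- length(x$varianceFraction)
    cat(sprintf("PCA: %d components; variance fractions %s\n", k,
                paste(sprintf("%.2f", x$varianceFraction), collapse = ", ")))
    cat(sprintf("State-score adj R2 per PC: %s\n",
                paste(sprintf("%.2f", x$adjR2), collapse = ", ")))
    invisible(x)
}

#' Partial correlation of a trait with the state score given covariate loci
#'
#' Residualizes both the trait and the score on the allele codes of the
#' covariate markers by OLS, then correlates the residuals; the p-value uses
#' the t-distribution at n - #covariates - 2 degrees of freedom.  Collinear
#' covariates are deduplicated with a warning.
#'
#' @param trait named numeric vector.
#' @param scores named numeric vector (state score).
#' @param genotypes a [GenotypeMatrix-class]; omit \code{covariates} for a
#'   plain correlation.
#' @param covariates marker IDs to partial out.
#' @return list: \code{r}, \code{p}, \code{n}, \code{nCovariates}.
#' @export
partialCorrelation <- function(trait, scores, genotypes = NULL,
                               covariates = character(0)) {
    strains <- intersect(names(trait)[!is.na(trait)],
                         names(scores)[!is.na(scores)])
    y <- as.numeric(trait[strains])
    s <- as.numeric(scores[strains])
    k <- 0L
    if (length(covariates)) {
        stopifnot(is(genotypes, "GenotypeMatrix"))
        X <- alleleMatrix(genotypes)[strains, covariates, drop = FALSE]
        if (ncol(X) > 1L) {
            cc <- suppressWarnings(stats::cor(X))
            drop <- logical(ncol(X))
            for (i in seq_len(ncol(X) - 1L))
                for (j in (i + 1L):ncol(X))
                    if (!drop[i] && !is.na(cc[i, j]) && abs(cc[i, j]) == 1)
                        drop[j] <- TRUE
            if (any(drop)) {
                warning("dropping collinear covariate(s): ",
                        paste(colnames(X)[drop], collapse = ", "))
                X <- X[, !drop, drop = FALSE]
            }
        }
        k <- ncol(X)
        if (length(strains) < k + 10L)
            stop("need >= #covariates + 10 strains")
        y <- stats::residuals(stats::lm(y ~ X))
        s <- stats::residuals(stats::lm(s ~ X))
    }
    r <- stats::cor(y, s)
    df <- length(strains) - k - 2L
    tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
    list(r = r, p = 2 * stats::pt(-abs(tstat), df), n = length(strains),
         nCovariates = k)
}
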