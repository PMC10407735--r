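#' @include AllClasses.R AllGenerics.R
NULL

#' Draw an abundance-matched random feature set
#'
#' Features are binned into \code{nBins} quantile bins of mean (raw)
#' abundance; a random set is drawn without replacement, excluding the
#' reference set, matching the reference set's per-bin counts.  When a bin
#' lacks enough non-reference features, sampling relaxes to adjacent bins
#' with a warning.
#'
#' @param abund an [AbundanceMatrix-class] on the raw (unstandardized) scale;
#'   standardized input is rejected because matching needs mean abundances.
#' @param referenceSet character vector of feature IDs to match.
#' @param nBins number of quantile bins.
#' @param seed optional integer seed.
#' @return character vector of sampled feature IDs (same size as the mapped
#'   reference set, disjoint from it).
#' @export
abundanceMatchedSample <- function(abund, referenceSet, nBins = 10L,
                                   seed = NULL) {
    stopifnot(is(abund, "AbundanceMatrix"))
    if (isStandardized(abund))
        stop("abundance matching needs raw (unstandardized) mean abundances")
    if (!is.null(seed)) set.seed(seed)
    mu <- rowMeans(abundanceValues(abund), na.rm = TRUE)
    referenceSet <- intersect(referenceSet, names(mu))
    if (length(referenceSet) == 0L) stop("reference set has no measured features")
    br <- stats::quantile(mu, probs = seq(0, 1, length.out = nBins + 1L),
                          names = FALSE)
    br[1L] <- -Inf; br[length(br)] <- Inf
    bin <- findInterval(mu, br, rightmost.closed = TRUE)
    names(bin) <- names(mu)
    pool <- setdiff(names(mu), referenceSet)
    picked <- character(0)
    for (b in sort(unique(bin[referenceSet]))) {
        need <- sum(bin[referenceSet] == b)
        avail <- setdiff(pool[bin[pool] == b], picked)
        if (length(avail) < need) {
            warning(sprintf("bin %d short of features (%d < %d); relaxing to adjacent bins",
                            b, length(avail), need))
            widen <- 1L
            while (length(avail) < need && widen <= nBins) {
                extra <- pool[abs(bin[pool] - b) <= widen]
                avail <- setdiff(extra, picked)
                widen <- widen + 1L
            }
            if (length(avail) < need)
                stop("not enough non-reference features to match bin ", b)
        }
        picked <- c(picked,
                    if (length(avail) == need) avail
                    else sample(avail, need))
    }
    picked
}

# mean pairwise squared Pearson correlation of a feature set over a strain
# subset (pairwise-complete)
.meanPairR2 <- function(values, features, strains) {
    m <- t(values[features, strains, drop = FALSE])
    cc <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
    mean(cc[upper.tri(cc)]^2, na.rm = TRUE)
}

#' Coordination of a hotspot's targets after stratifying out its allele
#'
#' Within each allele stratum at \code{stratifyMarker} separately, computes
#' the mean over all target pairs of the squared Pearson correlation, and
#' compares it against the same statistic for \code{nRandom}
#' abundance-matched random sets (empirical p with a pseudo-count).  Removing
#' the stratifying allele removes that locus' own effect; coordination that
#' survives indicates shared control by further loci.
#'
#' @param abund an [AbundanceMatrix-class] (raw scale; correlations are
#'   scale-invariant, matching needs raw means).
#' @param targetSet character vector of target feature IDs.
#' @param genotypes a [GenotypeMatrix-class].
#' @param stratifyMarker marker ID to stratify on.
#' @param nRandom number of abundance-matched null sets.
#' @param nBins quantile bins for abundance matching.
#' @param seed integer seed.
#' @return list of class \code{"CoordinationResult"}: per-stratum observed
#'   mean R2, null distributions, per-stratum and pooled empirical p,
#'   \code{nTargets}, \code{nRandom}.
#' @export
coordinationTest <- function(abund, targetSet, genotypes, stratifyMarker,
                             nRandom = 1000L, nBins = 10L, seed = 1L) {
    stopifnot(is(abund, "AbundanceMatrix"), is(genotypes, "GenotypeMatrix"))
    v <- abundanceValues(abund)
    targetSet <- intersect(targetSet, rownames(v))
    if (length(targetSet) < 2L) stop("need >= 2 measured target features")
    g <- alleleMatrix(genotypes)[, stratifyMarker]
    strains <- intersect(colnames(v), names(g)[!is.na(g)])
    strata <- split(strains, g[strains])
    if (length(strata) < 2L || any(lengths(strata) < 10L))
        stop("both allele strata need >= 10 strains; sizes: ",
             paste(lengths(strata), collapse = "/"))
    set.seed(seed)
    obs <- vapply(strata, function(s) .meanPairR2(v, targetSet, s), numeric(1))
    nulls <- matrix(NA_real_, nRandom, length(strata),
                    dimnames = list(NULL, names(strata)))
    for (k in seq_len(nRandom)) {
        rs <- abundanceMatchedSample(abund, targetSet, nBins = nBins)
        nulls[k, ] <- vapply(strata, function(s) .meanPairR2(v, rs, s),
                             numeric(1))
    }
    pStrat <- vapply(names(strata), function(a)
        (1 + sum(nulls[, a] >= obs[a])) / (1 + nRandom), numeric(1))
    pooledObs <- mean(obs)
    pooledNull <- rowMeans(nulls)
    pPooled <- (1 + sum(pooledNull >= pooledObs)) / (1 + nRandom)
    structure(list(observed = obs, null = nulls, pStratum = pStrat,
                   pooledObserved = pooledObs, pPooled = pPooled,
                   nTargets = length(targetSet), nRandom = nRandom),
              class = "CoordinationResult")
}

#' @export
print.CoordinationResult <- function(x, ...) {
    cat(sprintf("Coordination test: %d targets, %d matched null sets\n",
                x$nTargets, x$nRandom))
    for (a in names(x$observed))
        cat(sprintf("  allele %s: mean pair R2 = %.3f (null mean %.3f), empirical p = %.3g\n",
                    a, x$observed[a], mean(x$null[, a]), x$pStratum[a]))
    cat(sprintf("  pooled: mean R2 = %.3f, empirical p = %.3g\n",
                x$pooledObserved, x$pPooled))
    invisible(x)
}
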