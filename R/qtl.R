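#' @include AllClasses.R AllGenerics.R
NULL

#' Genotype quality control for an RNA-seq-called cross
#'
#' Applies the marker filters used for sequencing-based genotype calls in a
#' haploid cross: markers with a missing parental call, with segregant
#' missingness above \code{missMax}, or with minor allele frequency below
#' \code{mafMin} are dropped.  Per strain, a call that differs from both its
#' nearest called neighbors is set missing when those neighbors agree and both
#' lie within \code{window} bp (an apparent double-crossover singleton is far
#' more likely a genotyping error).  Finally, missing calls are imputed from
#' the two flanking markers when those flanks show identical segregation
#' patterns, lie within \code{window} bp, and agree for the strain in
#' question.
#'
#' @param raw a [GenotypeMatrix-class], possibly with missing calls.
#' @param parents matrix of parental calls, markers x 2 (rownames = marker
#'   IDs; NA = uncallable).
#' @param mafMin minimum minor allele frequency.
#' @param missMax maximum fraction of missing segregant calls per marker.
#' @param window neighborhood in bp for the singleton and imputation rules.
#' @return a filtered [GenotypeMatrix-class]; attribute \code{"qcReport"}
#'   lists counts of markers dropped per rule and of masked/imputed calls.
#' @export
genotypeQC <- function(raw, parents, mafMin = 0.10, missMax = 0.50,
                       window = 50000L) {
    stopifnot(is(raw, "GenotypeMatrix"))
    a <- assay(raw, "alleles")
    mi <- markerInfo(raw)
    parents <- as.matrix(parents)
    if (is.null(rownames(parents)) || !all(rownames(a) %in% rownames(parents)))
        stop("parents must be a markers x 2 matrix covering all markers")
    parents <- parents[rownames(a), , drop = FALSE]

    parentOK <- rowSums(is.na(parents)) == 0L
    missFrac <- rowMeans(is.na(a))
    af <- rowMeans(a, na.rm = TRUE)
    maf <- pmin(af, 1 - af)
    maf[is.nan(maf)] <- 0
    keep <- parentOK & missFrac <= missMax & maf >= mafMin
    report <- c(droppedParentMissing = sum(!parentOK),
                droppedMissingness = sum(parentOK & missFrac > missMax),
                droppedMAF = sum(parentOK & missFrac <= missMax & maf < mafMin))
    if (!any(keep)) stop("no markers survive genotype QC")
    a <- a[keep, , drop = FALSE]
    mi <- mi[keep, , drop = FALSE]

    # singleton masking, per chromosome / per strain
    nMasked <- 0L
    for (chr in unique(mi$chromosome)) {
        ix <- which(mi$chromosome == chr)
        if (length(ix) < 3L) next
        pos <- mi$position[ix]
        for (j in seq_len(ncol(a))) {
            x <- a[ix, j]
            called <- which(!is.na(x))
            if (length(called) < 3L) next
            for (k in 2:(length(called) - 1L)) {
                m <- called[k]; up <- called[k - 1L]; dn <- called[k + 1L]
                if (x[up] == x[dn] && x[m] != x[up] &&
                    abs(pos[m] - pos[up]) <= window &&
                    abs(pos[dn] - pos[m]) <= window) {
                    a[ix[m], j] <- NA_integer_
                    nMasked <- nMasked + 1L
                }
            }
        }
    }

    # imputation from identically-segregating flanks
    nImputed <- 0L
    for (chr in unique(mi$chromosome)) {
        ix <- which(mi$chromosome == chr)
        if (length(ix) < 3L) next
        pos <- mi$position[ix]
        for (k in 2:(length(ix) - 1L)) {
            m <- ix[k]
            miss <- which(is.na(a[m, ]))
            if (length(miss) == 0L) next
            up <- ix[k - 1L]; dn <- ix[k + 1L]
            if (abs(pos[k] - pos[k - 1L]) > window ||
                abs(pos[k + 1L] - pos[k]) > window) next
            bothCalled <- !is.na(a[up, ]) & !is.na(a[dn, ])
            if (!any(bothCalled) || !all(a[up, bothCalled] == a[dn, bothCalled]))
                next  # flanks must segregate identically
            fix <- miss[bothCalled[miss]]
            if (length(fix)) {
                a[m, fix] <- a[up, fix]
                nImputed <- nImputed + length(fix)
            }
        }
    }

    out <- GenotypeMatrix(a, mi$chromosome, mi$position)
    attr(out, "qcReport") <- c(report, maskedSingletons = nMasked,
                               imputedCalls = nImputed,
                               markersKept = nrow(a))
    out
}

# Shared Random-Forest permutation-FDR machinery.  Returns per-predictor
# importance, empirical p (pooled or per-predictor nulls) and BH q.
.rfPermutationMap <- function(X, y, nTrees, nPerm, seed, pooledNull = TRUE,
                              mtry = NULL) {
    p <- ncol(X)
    if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
    df <- data.frame(..y = y, X, check.names = FALSE)
    fitOne <- function(yy, s) {
        df$..y <- yy
        ranger::ranger(dependent.variable.name = "..y", data = df,
                       num.trees = nTrees, mtry = mtry,
                       importance = "permutation", seed = s,
                       num.threads = 1L, verbose = FALSE)$variable.importance
    }
    obs <- fitOne(y, seed)
    set.seed(seed)
    nulls <- matrix(NA_real_, nPerm, p)
    for (k in seq_len(nPerm))
        nulls[k, ] <- fitOne(sample(y), seed + k)
    if (pooledNull) {
        pooled <- sort(as.numeric(nulls))
        n0 <- length(pooled)
        exceed <- n0 - findInterval(obs, pooled)  # #{null >= obs}
        pval <- (1 + exceed) / (1 + n0)
    } else {
        pval <- vapply(seq_len(p), function(m)
            (1 + sum(nulls[, m] >= obs[m])) / (1 + nPerm), numeric(1))
    }
    data.frame(predictor = colnames(X), importance = unname(obs),
               p = unname(pval), q = stats::p.adjust(pval, "BH"),
               stringsAsFactors = FALSE)
}

#' Map QTL by Random-Forest importance with permutation FDR
#'
#' Fits a Random-Forest regression of the trait on all markers (permutation
#' importance, out-of-bag), builds a null importance distribution by
#' refitting on \code{nPerm} permutations of the trait, converts importances
#' to empirical p-values and applies Benjamini-Hochberg across markers.
#' Contiguous runs of significant markers are collapsed into peaks at the
#' marker of maximum importance.  By default null importances are pooled
#' across markers within permutation rounds, which gives p-value resolution
#' of about 1/(nPerm x nMarkers) instead of 1/nPerm.
#'
#' @param genotypes a [GenotypeMatrix-class] (missing calls are imputed to the
#'   marker's major allele for the forest fit).
#' @param trait named numeric vector (strain -> value); needs >= 20 strains
#'   with non-missing values and nonzero variance.
#' @param nTrees,nPerm forest size and number of trait permutations.
#' @param fdr BH threshold declaring markers significant.
#' @param seed integer seed (forest and permutations).
#' @param pooledNull pool null importances across markers (default TRUE).
#' @return list of class \code{"QTLResult"}: \code{table} (marker,
#'   chromosome, position, importance, p, q, significant), \code{peaks}
#'   (chromosome, peak marker, flanking significant range, allele effect and
#'   its sign), \code{fdr}, \code{nPerm}.
#' @export
mapQTLrf <- function(genotypes, trait, nTrees = 1000L, nPerm = 100L,
                     fdr = 0.15, seed = 1L, pooledNull = TRUE) {
    stopifnot(is(genotypes, "GenotypeMatrix"))
    X <- alleleMatrix(genotypes)
    trait <- trait[names(trait) %in% rownames(X)]
    y <- as.numeric(trait[!is.na(trait)])
    strains <- names(trait)[!is.na(trait)]
    if (length(strains) < 20L) stop("need >= 20 strains with trait values")
    if (length(strains) < 0.8 * length(trait))
        warning("more than 20% of trait values are missing")
    if (stats::var(y) == 0) stop("trait is constant; nothing to map")
    if (nPerm < 20L) warning("nPerm < 20 gives poor p-value resolution")
    X <- X[strains, , drop = FALSE]
    if (anyNA(X)) {  # major-allele imputation for the forest fit only
        for (m in which(colSums(is.na(X)) > 0L)) {
            fill <- as.integer(round(mean(X[, m], na.rm = TRUE)))
            X[is.na(X[, m]), m] <- fill
        }
    }
    res <- .rfPermutationMap(X, y, nTrees, nPerm, seed, pooledNull)
    mi <- markerInfo(genotypes)
    tab <- data.frame(marker = res$predictor,
                      chromosome = mi$chromosome[match(res$predictor, mi$marker)],
                      position = mi$position[match(res$predictor, mi$marker)],
                      importance = res$importance, p = res$p, q = res$q,
                      significant = res$q <= fdr, stringsAsFactors = FALSE)
    peaks <- .collapsePeaks(tab, genotypes, trait)
    structure(list(table = tab, peaks = peaks, fdr = fdr, nPerm = nPerm),
              class = "QTLResult")
}

.collapsePeaks <- function(tab, genotypes, trait) {
    sig <- which(tab$significant)
    if (length(sig) == 0L)
        return(data.frame(chromosome = character(0), peakMarker = character(0),
                          startMarker = character(0), endMarker = character(0),
                          importance = numeric(0), effect = numeric(0),
                          effectSign = integer(0)))
    runs <- split(sig, cumsum(c(1L, diff(sig) != 1L |
                                tab$chromosome[sig][-1L] !=
                                tab$chromosome[sig][-length(sig)])))
    do.call(rbind, lapply(runs, function(ix) {
        peak <- ix[which.max(tab$importance[ix])]
        eff <- tryCatch(
            alleleEffect(genotypes, tab$marker[peak], trait)$difference,
            error = function(e) NA_real_)
        data.frame(chromosome = tab$chromosome[peak],
                   peakMarker = tab$marker[peak],
                   startMarker = tab$marker[ix[1L]],
                   endMarker = tab$marker[ix[length(ix)]],
                   importance = tab$importance[peak],
                   effect = eff, effectSign = sign(eff),
                   stringsAsFactors = FALSE)
    }))
}

#' @export
print.QTLResult <- function(x, ...) {
    cat(sprintf("QTL mapping: %d markers, %d significant at FDR %.2g (%d permutations)\n",
                nrow(x$table), sum(x$table$significant), x$fdr, x$nPerm))
    if (nrow(x$peaks)) {
        cat("Peaks:\n")
        print(x$peaks, row.names = FALSE)
    }
    invisible(x)
}

#' Map a trait to molecular features by Random-Forest importance
#'
#' Same forest-plus-permutation machinery as [mapQTLrf()] but with
#' standardized feature abundances as continuous predictors; returns the
#' features predictive of the trait at the given FDR together with the sign
#' of their trait correlation.
#'
#' @param features an [AbundanceMatrix-class].
#' @param trait named numeric vector (strain -> value).
#' @param nTrees,nPerm,seed,pooledNull as in [mapQTLrf()].
#' @param fdr BH threshold.
#' @return list of class \code{"FeaturePredictorResult"}: \code{table} (all
#'   features with importance, p, q, correlation sign), \code{predictive}
#'   (subset with q <= fdr), \code{fdr}, \code{nPerm}.
#' @export
mapTraitToFeatures <- function(features, trait, nPerm = 100L, fdr = 0.20,
                               nTrees = 1000L, seed = 1L, pooledNull = TRUE) {
    stopifnot(is(features, "AbundanceMatrix"))
    z <- abundanceValues(standardizeFeatures(features))
    shared <- intersect(colnames(z), names(trait)[!is.na(trait)])
    if (length(shared) < 20L) stop("need >= 20 strains with trait values")
    y <- as.numeric(trait[shared])
    if (stats::var(y) == 0) stop("trait is constant; nothing to map")
    X <- t(z[, shared, drop = FALSE])
    X[is.na(X)] <- 0  # standardized scale: mean imputation
    res <- .rfPermutationMap(X, y, nTrees, nPerm, seed, pooledNull)
    rs <- suppressWarnings(as.numeric(stats::cor(X, y)))
    tab <- data.frame(feature = res$predictor, importance = res$importance,
                      p = res$p, q = res$q, corSign = sign(rs),
                      stringsAsFactors = FALSE)
    tab <- tab[order(tab$p, -tab$importance), ]
    structure(list(table = tab, predictive = tab[tab$q <= fdr, ],
                   fdr = fdr, nPerm = nPerm),
              class = "FeaturePredictorResult")
}

#' Allele effect at one marker
#'
#' Signed mean difference (allele 1 minus allele 0; positive means the second
#' parent's allele raises the value) with a Welch t-test.
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param marker marker ID or index.
#' @param values named numeric vector (strain -> trait or feature value).
#' @return list: \code{difference}, \code{p}, \code{n0}, \code{n1}.
#' @export
alleleEffect <- function(genotypes, marker, values) {
    g <- alleleMatrix(genotypes)[, marker]
    shared <- intersect(names(values)[!is.na(values)], names(g)[!is.na(g)])
    v <- values[shared]; gg <- g[shared]
    v0 <- v[gg == 0L]; v1 <- v[gg == 1L]
    if (length(v0) < 3L || length(v1) < 3L)
        stop(sprintf("need >= 3 strains per allele group (got %d / %d)",
                     length(v0), length(v1)))
    d <- mean(v1) - mean(v0)
    p <- if (stats::sd(v0) == 0 && stats::sd(v1) == 0) {
        if (d == 0) 1 else 0
    } else stats::t.test(v1, v0)$p.value
    list(difference = d, p = p, n0 = length(v0), n1 = length(v1))
}

#' Per-marker feature effects (pQTL links) at selected markers
#'
#' Vectorized allele-effect scan: for each requested marker, the signed mean
#' abundance difference (allele 1 minus allele 0) and a Welch t-test per
#' feature, with BH adjustment across all computed (marker, feature) pairs.
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param abund an [AbundanceMatrix-class].
#' @param markers marker IDs to scan (default: all).
#' @param fdr BH threshold for a significant link.
#' @return list of class \code{"PQTLMap"}: \code{links} (marker, feature,
#'   effect, p, q for links with q <= fdr), \code{targetCounts} (named by
#'   marker), \code{fdr}, \code{tested}.
#' @export
mapPQTL <- function(genotypes, abund, markers = NULL, fdr = 0.10) {
    stopifnot(is(genotypes, "GenotypeMatrix"), is(abund, "AbundanceMatrix"))
    G <- alleleMatrix(genotypes)
    V <- abundanceValues(abund)
    shared <- intersect(rownames(G), colnames(V))
    if (length(shared) < 6L) stop("need >= 6 shared strains")
    G <- G[shared, , drop = FALSE]
    V <- V[, shared, drop = FALSE]
    if (is.null(markers)) markers <- colnames(G)
    res <- vector("list", length(markers))
    for (i in seq_along(markers)) {
        g <- G[, markers[i]]
        ok <- !is.na(g)
        i1 <- which(ok & g == 1L); i0 <- which(ok & g == 0L)
        if (length(i0) < 3L || length(i1) < 3L) next
        m1 <- rowMeans(V[, i1, drop = FALSE], na.rm = TRUE)
        m0 <- rowMeans(V[, i0, drop = FALSE], na.rm = TRUE)
        v1 <- apply(V[, i1, drop = FALSE], 1L, stats::var, na.rm = TRUE)
        v0 <- apply(V[, i0, drop = FALSE], 1L, stats::var, na.rm = TRUE)
        n1 <- length(i1); n0 <- length(i0)
        se2 <- v1 / n1 + v0 / n0
        tstat <- (m1 - m0) / sqrt(se2)
        df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
        p <- 2 * stats::pt(-abs(tstat), df)
        res[[i]] <- data.frame(marker = markers[i], feature = rownames(V),
                               effect = m1 - m0, p = p,
                               stringsAsFactors = FALSE)
    }
    all <- do.call(rbind, res)
    if (is.null(all) || nrow(all) == 0L) stop("no marker had both allele groups")
    all <- all[is.finite(all$p), ]
    all$q <- stats::p.adjust(all$p, "BH")
    links <- all[all$q <= fdr, c("marker", "feature", "effect", "p", "q")]
    rownames(links) <- NULL
    counts <- table(factor(links$marker, levels = markers))
    structure(list(links = links,
                   targetCounts = stats::setNames(as.integer(counts),
                                                  names(counts)),
                   fdr = fdr, tested = nrow(all)),
              class = "PQTLMap")
}

#' @export
print.PQTLMap <- function(x, ...) {
    cat(sprintf("PQTLMap: %d significant links at FDR %.2g (%d tests, %d markers with targets)\n",
                nrow(x$links), x$fdr, x$tested, sum(x$targetCounts > 0)))
    invisible(x)
}

#' Joint (conditional) allele effects of several loci on every feature
#'
#' Multiple regression of each feature on the allele codes of all listed
#' markers simultaneously: each locus' coefficient is its effect conditional
#' on the other loci, which removes the spurious marginal associations a
#' single marker inherits by chance correlation with a strong trans-acting
#' axis.  BH adjustment is applied per locus across features.
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param abund an [AbundanceMatrix-class].
#' @param markers marker IDs (the loci analyzed jointly).
#' @return list: \code{effects}, \code{p}, \code{q} (features x markers
#'   matrices), \code{n} (strains used).
#' @export
jointAlleleEffects <- function(genotypes, abund, markers) {
    stopifnot(is(genotypes, "GenotypeMatrix"), is(abund, "AbundanceMatrix"))
    G <- alleleMatrix(genotypes)[, markers, drop = FALSE]
    V <- abundanceValues(abund)
    strains <- intersect(rownames(G)[rowSums(is.na(G)) == 0L], colnames(V))
    m <- length(markers)
    if (length(strains) < m + 10L) stop("need >= #loci + 10 fully typed strains")
    G <- G[strains, , drop = FALSE]
    V <- V[, strains, drop = FALSE]
    if (anyNA(V)) {  # mean-impute for this vectorized scan
        mu <- rowMeans(V, na.rm = TRUE)
        V[is.na(V)] <- mu[row(V)[is.na(V)]]
    }
    X <- cbind(1, G)
    XtXinv <- solve(crossprod(X))
    B <- V %*% X %*% XtXinv                     # features x (m+1)
    resid <- V - B %*% t(X)
    df <- length(strains) - m - 1L
    s2 <- rowSums(resid^2) / df
    se <- sqrt(outer(s2, diag(XtXinv)[-1L]))
    eff <- B[, -1L, drop = FALSE]
    tstat <- eff / se
    p <- 2 * stats::pt(-abs(tstat), df)
    q <- apply(p, 2L, stats::p.adjust, method = "BH")
    dimnames(eff) <- dimnames(p) <- dimnames(q) <- list(rownames(V), markers)
    list(effects = eff, p = p, q = q, n = length(strains))
}

#' Adjusted R-squared of an additive multi-locus model
#'
#' Ordinary least squares of the trait on the allele codes of the listed
#' markers; markers in complete LD (identical or complementary allele
#' columns) are deduplicated with a warning.
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param markers marker IDs.
#' @param trait named numeric vector.
#' @return adjusted R-squared.
#' @export
additiveModelR2 <- function(genotypes, markers, trait) {
    X <- alleleMatrix(genotypes)[, markers, drop = FALSE]
    shared <- intersect(rownames(X), names(trait)[!is.na(trait)])
    X <- X[shared, , drop = FALSE]
    y <- as.numeric(trait[shared])
    if (length(y) <= ncol(X) + 1L)
        stop("need more strains than markers + 1")
    if (ncol(X) > 1L) {
        cc <- suppressWarnings(stats::cor(X))
        drop <- logical(ncol(X))
        for (i in seq_len(ncol(X) - 1L))
            for (j in (i + 1L):ncol(X))
                if (!drop[i] && !is.na(cc[i, j]) && abs(cc[i, j]) == 1)
                    drop[j] <- TRUE
        if (any(drop)) {
            warning("dropping marker(s) in complete LD: ",
                    paste(colnames(X)[drop], collapse = ", "))
            X <- X[, !drop, drop = FALSE]
        }
    }
    summary(stats::lm(y ~ X))$adj.r.squared
}

#' Broad-sense heritability from replicated measurements
#'
#' Adjusted R-squared of a strain-identity regression: the share of total
#' variance that lies between strains rather than between replicates.
#'
#' @param values numeric measurements.
#' @param strain strain labels, same length.
#' @return adjusted R-squared.
#' @export
heritabilityFromReplicates <- function(values, strain) {
    strain <- as.character(strain)
    reps <- table(strain)
    if (sum(reps >= 2L) < 2L)
        stop("need >= 2 strains with >= 2 replicates each")
    summary(stats::lm(values ~ factor(strain)))$adj.r.squared
}

#' Test for epistasis between two loci
#'
#' OLS of the trait on gA + gB + gA:gB.  Reports the interaction coefficient
#' and p-value plus the conditional effect of each locus within the other's
#' allele backgrounds (the "+1.10 vs +0.21" presentation).
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param markerA,markerB marker IDs.
#' @param trait named numeric vector (trait or state score).
#' @return list: \code{interaction}, \code{p}, \code{coefficients},
#'   \code{conditionalA} (effect of A in B = 0 / B = 1), \code{conditionalB},
#'   \code{classCounts}.
#' @export
interactionTest <- function(genotypes, markerA, markerB, trait) {
    G <- alleleMatrix(genotypes)
    shared <- intersect(rownames(G), names(trait)[!is.na(trait)])
    gA <- G[shared, markerA]; gB <- G[shared, markerB]
    y <- as.numeric(trait[shared])
    ok <- !is.na(gA) & !is.na(gB)
    gA <- gA[ok]; gB <- gB[ok]; y <- y[ok]
    cls <- table(factor(gA, levels = 0:1), factor(gB, levels = 0:1))
    if (any(cls < 3L))
        stop("all four genotype classes need >= 3 strains; counts: ",
             paste(as.integer(cls), collapse = "/"))
    fit <- stats::lm(y ~ gA * gB)
    sm <- summary(fit)$coefficients
    b <- stats::coef(fit)
    list(interaction = unname(b["gA:gB"]),
         p = unname(sm["gA:gB", "Pr(>|t|)"]),
         coefficients = b,
         conditionalA = c(B0 = unname(b["gA"]),
                          B1 = unname(b["gA"] + b["gA:gB"])),
         conditionalB = c(A0 = unname(b["gB"]),
                          A1 = unname(b["gB"] + b["gA:gB"])),
         classCounts = cls)
}
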