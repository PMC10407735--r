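#' @include AllClasses.R AllGenerics.R
NULL

#' Derive induced/repressed marker sets from an inhibition profile
#'
#' Per treatment, effects are z-scored against the cross-feature SD of that
#' treatment.  A feature becomes an induced candidate if its z reaches
#' \code{kSD} in at least one treatment, a repressed candidate if it reaches
#' \code{-kSD}.  Candidates whose effect has the strictly opposite sign in any
#' treatment (beyond a dead zone of |z| < 0.1, which is treated as zero) are
#' excluded: a consistent signature must move the same way under every
#' treatment.
#'
#' With \code{direction = "inhibition"} (the default, matching an inhibition
#' experiment as input) the induced set collects features whose abundance
#' consistently \emph{falls} under treatment — pathway-induced genes are the
#' ones the pathway's inhibition reduces.  \code{direction = "activity"}
#' applies the thresholds to the effect matrix as given (use it when the
#' effects are already oriented as pathway-activity responses).
#'
#' @param profile an \code{"InhibitionProfile"}.
#' @param kSD z-score threshold in SD units.
#' @param direction \code{"inhibition"} (default) or \code{"activity"}; see
#'   Details.
#' @return a [MarkerSetPair-class]; attribute \code{"exclusionLog"} is a
#'   data.frame of candidates removed by the sign-consistency rule, attribute
#'   \code{"candidates"} records the pre-filter counts.
#' @export
deriveMarkerSets <- function(profile, kSD = 2,
                             direction = c("inhibition", "activity")) {
    stopifnot(inherits(profile, "InhibitionProfile"))
    direction <- match.arg(direction)
    E <- profile$effects
    if (direction == "inhibition") E <- -E
    z <- sweep(E, 2L, apply(E, 2L, stats::sd), `/`)
    zDead <- z
    zDead[abs(zDead) < 0.1] <- 0

    indCand <- rownames(z)[apply(z >= kSD, 1L, any)]
    repCand <- rownames(z)[apply(z <= -kSD, 1L, any)]
    indKeep <- indCand[!apply(zDead[indCand, , drop = FALSE] < 0, 1L, any)]
    repKeep <- repCand[!apply(zDead[repCand, , drop = FALSE] > 0, 1L, any)]
    # a feature crossing both thresholds is by construction sign-inconsistent
    both <- intersect(indKeep, repKeep)
    indKeep <- setdiff(indKeep, both)
    repKeep <- setdiff(repKeep, both)

    if (length(indKeep) == 0L || length(repKeep) == 0L)
        stop("empty marker set after filtering (induced: ", length(indKeep),
             ", repressed: ", length(repKeep), "); consider a lower kSD")
    excl <- data.frame(
        feature = c(setdiff(indCand, indKeep), setdiff(repCand, repKeep)),
        candidateSet = rep(c("induced", "repressed"),
                           c(length(setdiff(indCand, indKeep)),
                             length(setdiff(repCand, repKeep)))),
        stringsAsFactors = FALSE)
    out <- MarkerSetPair(indKeep, repKeep,
                         provenance = sprintf(
                             "derived at %g SD from %d treatments (%d/%d and %d/%d candidates retained)",
                             kSD, ncol(E), length(indKeep), length(indCand),
                             length(repKeep), length(repCand)))
    attr(out, "exclusionLog") <- excl
    attr(out, "candidates") <- c(induced = length(indCand),
                                 repressed = length(repCand))
    out
}

#' Compute a median-difference state score
#'
#' For every strain, the score is the median standardized abundance of the
#' measured induced markers minus the median of the measured repressed
#' markers.  Abundances are feature-standardized first (z-scores across
#' strains) if the matrix is not already standardized; missing values are
#' ignored inside each median.
#'
#' @param abund an [AbundanceMatrix-class].
#' @param markers a [MarkerSetPair-class].
#' @param minPerSet minimum overlap of each marker set with the measured
#'   features.
#' @return a named numeric vector of class \code{"StateScoreVector"} with
#'   attributes \code{nInducedUsed} and \code{nRepressedUsed}.
#' @export
computeStateScore <- function(abund, markers, minPerSet = 3) {
    stopifnot(is(abund, "AbundanceMatrix"), is(markers, "MarkerSetPair"))
    z <- abundanceValues(standardizeFeatures(abund))
    ind <- intersect(inducedMarkers(markers), rownames(z))
    rep_ <- intersect(repressedMarkers(markers), rownames(z))
    if (length(ind) < minPerSet || length(rep_) < minPerSet)
        stop(sprintf(
            "marker overlap with measured features below %d (induced: %d, repressed: %d)",
            minPerSet, length(ind), length(rep_)))
    colMed <- function(m) apply(m, 2L, stats::median, na.rm = TRUE)
    score <- colMed(z[ind, , drop = FALSE]) - colMed(z[rep_, , drop = FALSE])
    structure(score, nInducedUsed = length(ind), nRepressedUsed = length(rep_),
              class = "StateScoreVector")
}

#' @export
print.StateScoreVector <- function(x, ...) {
    cat(sprintf("State scores for %d strains (markers used: %d induced, %d repressed)\n",
                length(x), attr(x, "nInducedUsed"), attr(x, "nRepressedUsed")))
    print(stats::setNames(as.numeric(x), names(x)), ...)
    invisible(x)
}

#' Map a marker-set pair to another species via an ortholog table
#'
#' Unmapped markers are dropped and logged; one-to-many mappings expand to all
#' targets.  If a target gene ends up in both sets, the mapping is rejected.
#'
#' @param markers a [MarkerSetPair-class] in the source namespace.
#' @param orthologTable data.frame with columns \code{source}, \code{target}
#'   (one row per mapping; one-to-many allowed).
#' @return a [MarkerSetPair-class] in the target namespace; attribute
#'   \code{"unmapped"} lists dropped source IDs per set.
#' @export
mapOrthologs <- function(markers, orthologTable) {
    stopifnot(is(markers, "MarkerSetPair"),
              all(c("source", "target") %in% colnames(orthologTable)))
    mapSet <- function(ids) {
        hit <- orthologTable$source %in% ids
        list(mapped = unique(orthologTable$target[hit]),
             unmapped = setdiff(ids, orthologTable$source))
    }
    ind <- mapSet(inducedMarkers(markers))
    rep_ <- mapSet(repressedMarkers(markers))
    clash <- intersect(ind$mapped, rep_$mapped)
    if (length(clash))
        stop("ortholog mapping sends gene(s) into both sets: ",
             paste(clash, collapse = ", "))
    out <- MarkerSetPair(ind$mapped, rep_$mapped,
                         provenance = paste("ortholog-mapped from:",
                                            markers@provenance))
    attr(out, "unmapped") <- list(induced = ind$unmapped,
                                  repressed = rep_$unmapped)
    out
}

#' Correlate an effect vector with a signature's inhibition profile
#'
#' Pearson correlation between a per-feature signed effect vector (e.g. the
#' allele effect of a locus on each protein) and the mean inhibition effect
#' across treatments, over the shared features.
#'
#' @param effectVector named numeric vector of signed effects.
#' @param profile an \code{"InhibitionProfile"}.
#' @return list: \code{r}, \code{p}, \code{nShared}.
#' @export
effectVsSignature <- function(effectVector, profile) {
    stopifnot(inherits(profile, "InhibitionProfile"))
    meanEff <- rowMeans(profile$effects)
    shared <- intersect(names(effectVector), names(meanEff))
    if (length(shared) < 10L)
        stop("need >= 10 shared features (got ", length(shared), ")")
    ct <- stats::cor.test(effectVector[shared], meanEff[shared])
    list(r = unname(ct$estimate), p = ct$p.value, nShared = length(shared))
}
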