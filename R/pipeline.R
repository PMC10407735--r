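#' @include AllClasses.R AllGenerics.R
NULL

#' Evidence and classification for a set of loci
#'
#' For each locus (marker), gathers the evidence the spread classification
#' needs: significant molecular targets (joint conditional allele effects
#' over all analyzed loci, BH per locus at \code{pqtlFdr} — see
#' [jointAlleleEffects()]), the state-score shift and its p-value, the
#' pairwise network distances of the graph-mapped targets, and the
#' random-sample envelope position — then applies [classifySpread()].
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param abund an [AbundanceMatrix-class] (protein layer).
#' @param scores a \code{"StateScoreVector"}.
#' @param graph an [InteractionGraph-class].
#' @param loci named character vector of marker IDs (names = locus labels).
#' @param pqtlFdr BH threshold for significant targets.
#' @param envelopeSamples random subsets per envelope size.
#' @param localMax,alpha classification thresholds (see [classifySpread()]).
#' @param seed integer seed for the envelope.
#' @return list of class \code{"LocusEvidence"} with one entry per locus:
#'   the \code{"SpreadClassification"} plus \code{targets},
#'   \code{alleleEffects} and the \code{"DistanceDistribution"}.
#' @export
analyzeLoci <- function(genotypes, abund, scores, graph, loci,
                        pqtlFdr = 0.10, envelopeSamples = 1000L,
                        localMax = 5L, alpha = 0.05, seed = 1L) {
    if (is.null(names(loci))) names(loci) <- loci
    jt <- jointAlleleEffects(genotypes, abund, unname(loci))
    g <- interactionGraph(graph)
    # one envelope pass over the distinct mapped-target sizes
    sizes <- integer(0)
    perLocus <- list()
    for (lab in names(loci)) {
        m <- loci[[lab]]
        sig <- jt$q[, m] <= pqtlFdr
        targets <- rownames(jt$q)[sig]
        mapped <- intersect(targets, igraph::V(g)$name)
        perLocus[[lab]] <- list(
            effects = stats::setNames(jt$effects[sig, m], targets),
            targets = targets, mapped = mapped)
        if (length(mapped) >= 2L) sizes <- c(sizes, length(mapped))
    }
    envelope <- if (length(sizes))
        distanceNullEnvelope(graph, sort(unique(sizes)),
                             nSamples = envelopeSamples, seed = seed)
    else NULL
    out <- list()
    for (lab in names(loci)) {
        info <- perLocus[[lab]]
        shift <- alleleEffect(genotypes, loci[[lab]], scores)
        dist <- if (length(info$mapped) >= 2L)
            pairwiseDistances(graph, info$mapped, label = lab) else NULL
        cls <- classifySpread(lab, nTargets = length(info$targets),
                              dist = dist, envelope = envelope,
                              stateShiftP = shift$p,
                              stateShift = shift$difference,
                              localMax = localMax, alpha = alpha)
        out[[lab]] <- list(classification = cls, targets = info$targets,
                           alleleEffects = info$effects,
                           distances = dist, stateShift = shift)
    }
    structure(out, class = "LocusEvidence", envelope = envelope)
}

#' Run the full synthetic study end to end
#'
#' Simulates the cross, network, omics layers and inhibition profiles;
#' derives the induced/repressed marker sets from the inhibition profile;
#' scores every strain; optionally maps state-score QTL by Random Forest with
#' permutation FDR; and classifies each planted locus from its molecular
#' evidence.
#'
#' @param cfg a [simConfig()] object.
#' @param mapState run the Random-Forest state-score QTL scan.
#' @param nTrees,nPerm,stateFdr Random-Forest mapping parameters.
#' @param pqtlFdr BH threshold for per-locus molecular targets.
#' @param envelopeSamples random subsets per envelope size.
#' @param growth simulate and analyze the growth panel.
#' @return list of class \code{"SyntheticStudyResult"}: the simulated
#'   \code{study}, \code{markers}, \code{scores},
#'   \code{scoreLatentCorrelation}, \code{stateQTL} (a \code{"QTLResult"} or
#'   NULL), \code{locusEvidence}, \code{labels} (planted vs assigned).
#' @export
runSyntheticStudy <- function(cfg = simConfig(), mapState = TRUE,
                              nTrees = 1000L, nPerm = 100L, stateFdr = 0.15,
                              pqtlFdr = 0.10, envelopeSamples = 1000L,
                              growth = FALSE) {
    study <- simulateStudy(cfg, growth = growth)
    markers <- deriveMarkerSets(study$inhibition)
    scores <- computeStateScore(study$layers$protein, markers)
    latentCor <- stats::cor(as.numeric(scores),
                            study$truth$latentState[names(scores)])
    stateQTL <- if (mapState)
        mapQTLrf(study$genotypes, stats::setNames(as.numeric(scores),
                                                  names(scores)),
                 nTrees = nTrees, nPerm = nPerm, fdr = stateFdr,
                 seed = cfg$seed)
    else NULL
    loci <- stats::setNames(study$truth$qtl$marker,
                            paste0(study$truth$qtl$type, "_",
                                   study$truth$qtl$marker))
    evidence <- analyzeLoci(study$genotypes, study$layers$protein, scores,
                            study$network$graph, loci, pqtlFdr = pqtlFdr,
                            envelopeSamples = envelopeSamples,
                            seed = cfg$seed)
    labels <- data.frame(
        locus = names(loci), marker = unname(loci),
        planted = study$truth$qtl$type,
        assigned = vapply(evidence, function(e) e$classification$label,
                          character(1)),
        nTargets = vapply(evidence, function(e)
            e$classification$evidence$nTargets, numeric(1)),
        stateShiftP = vapply(evidence, function(e)
            e$classification$evidence$stateShiftP, numeric(1)),
        stringsAsFactors = FALSE)
    rownames(labels) <- NULL
    structure(list(study = study, markers = markers, scores = scores,
                   scoreLatentCorrelation = latentCor, stateQTL = stateQTL,
                   locusEvidence = evidence, labels = labels, cfg = cfg),
              class = "SyntheticStudyResult")
}

#' @export
print.SyntheticStudyResult <- function(x, ...) {
    cat("Synthetic study result\n")
    cat(sprintf("  state score vs latent axis: r = %.3f\n",
                x$scoreLatentCorrelation))
    if (!is.null(x$stateQTL))
        cat(sprintf("  state-score QTL peaks: %d (FDR %.2g)\n",
                    nrow(x$stateQTL$peaks), x$stateQTL$fdr))
    cat("  planted-locus classification:\n")
    print(x$labels[, c("locus", "planted", "assigned", "nTargets")],
          row.names = FALSE)
    invisible(x)
}
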