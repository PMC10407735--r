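#' @include AllClasses.R AllGenerics.R
NULL

#' Build a thresholded interaction graph from a weighted edge list
#'
#' Keeps edges with confidence strictly above \code{scoreMin} (0.400 is the
#' STRING "medium confidence" convention), drops self-loops, and collapses
#' duplicate and multi-edges into a simple undirected graph.
#'
#' @param edges an \code{"EdgeList"} data.frame (see [readEdgeList()]).
#' @param scoreMin confidence threshold (strict inequality).
#' @return an [InteractionGraph-class].
#' @export
buildGraph <- function(edges, scoreMin = 0.400) {
    stopifnot(all(c("proteinA", "proteinB", "score") %in% colnames(edges)))
    keep <- edges$score > scoreMin
    nBelow <- sum(!keep)
    e <- edges[keep, , drop = FALSE]
    self <- e$proteinA == e$proteinB
    nSelf <- sum(self)
    e <- e[!self, , drop = FALSE]
    if (nrow(e) == 0L) stop("no edges remain above score ", scoreMin)
    g <- igraph::graph_from_edgelist(cbind(e$proteinA, e$proteinB),
                                     directed = FALSE)
    nMulti <- igraph::ecount(g)
    g <- igraph::simplify(g)
    nMulti <- nMulti - igraph::ecount(g)
    new("InteractionGraph", graph = g, scoreMin = scoreMin,
        dropped = c(belowThreshold = nBelow, selfLoops = nSelf,
                    multiEdges = as.integer(nMulti)))
}

#' Pairwise shortest-path distances within a node set
#'
#' Unweighted shortest-path length for every unordered pair of the mapped
#' nodes.  Pairs with no connecting path are assigned the maximum finite
#' distance observed among the other pairs of the same set (the imputation
#' the distance-spread statistics use); their count is reported.
#'
#' @param graph an [InteractionGraph-class] or igraph object.
#' @param nodeSet character vector of node IDs; unmapped IDs are dropped and
#'   logged.
#' @param label set label carried into the result.
#' @return list of class \code{"DistanceDistribution"}: \code{distances}
#'   (after imputation), \code{mean}, \code{nPairs}, \code{nUnreachable},
#'   \code{imputedDistance}, \code{nodes}, \code{unmapped}, \code{label}.
#' @export
pairwiseDistances <- function(graph, nodeSet, label = "set") {
    g <- if (is(graph, "InteractionGraph")) interactionGraph(graph) else graph
    nodeSet <- unique(as.character(nodeSet))
    mapped <- intersect(nodeSet, igraph::V(g)$name)
    unmapped <- setdiff(nodeSet, mapped)
    if (length(mapped) < 2L)
        stop("fewer than 2 set members map to the graph")
    D <- igraph::distances(g, v = mapped, to = mapped)
    d <- D[upper.tri(D)]
    nUnreach <- sum(is.infinite(d))
    imputed <- NA_real_
    if (nUnreach > 0L) {
        finite <- d[is.finite(d)]
        if (length(finite) == 0L)
            stop("no pair in the set is connected; distances undefined")
        imputed <- max(finite)
        d[is.infinite(d)] <- imputed
    }
    structure(list(distances = d, mean = mean(d),
                   nPairs = length(d), nUnreachable = nUnreach,
                   imputedDistance = imputed, nodes = mapped,
                   unmapped = unmapped, label = label),
              class = "DistanceDistribution")
}

#' @export
print.DistanceDistribution <- function(x, ...) {
    cat(sprintf("Distances [%s]: %d nodes, %d pairs, mean %.3f (%d unreachable imputed at %s)\n",
                x$label, length(x$nodes), x$nPairs, x$mean, x$nUnreachable,
                format(x$imputedDistance)))
    invisible(x)
}

#' Null envelope of mean pair distance for random node samples
#'
#' For each sample size, draws \code{nSamples} uniform random node subsets,
#' computes each subset's mean pair distance (same unreachable-pair
#' imputation as [pairwiseDistances()]) and records the 0.05 / 0.5 / 0.95
#' percentiles.
#'
#' @param graph an [InteractionGraph-class] or igraph object.
#' @param sampleSizes integer vector of subset sizes (each >= 2, <= #nodes).
#' @param nSamples random subsets per size.
#' @param seed integer seed.
#' @return list of class \code{"NullEnvelope"}: \code{percentiles} (matrix
#'   sizes x c(p05, p50, p95)), \code{samples} (list of the raw mean
#'   distances per size), \code{nSamples}, \code{seed}.
#' @export
distanceNullEnvelope <- function(graph, sampleSizes, nSamples = 10000L,
                                 seed = 1L) {
    g <- if (is(graph, "InteractionGraph")) interactionGraph(graph) else graph
    n <- igraph::vcount(g)
    sampleSizes <- as.integer(sampleSizes)
    if (any(sampleSizes < 2L) || any(sampleSizes > n))
        stop("sample sizes must lie in [2, #nodes]")
    D <- igraph::distances(g)
    set.seed(seed)
    samples <- list()
    perc <- matrix(NA_real_, length(sampleSizes), 3L,
                   dimnames = list(as.character(sampleSizes),
                                   c("p05", "p50", "p95")))
    for (i in seq_along(sampleSizes)) {
        k <- sampleSizes[i]
        means <- vapply(seq_len(nSamples), function(.) {
            ix <- sample.int(n, k)
            d <- D[ix, ix][upper.tri(matrix(0, k, k))]
            if (any(is.infinite(d))) {
                finite <- d[is.finite(d)]
                if (length(finite) == 0L) return(NA_real_)
                d[is.infinite(d)] <- max(finite)
            }
            mean(d)
        }, numeric(1))
        samples[[as.character(k)]] <- means
        perc[i, ] <- stats::quantile(means, c(0.05, 0.5, 0.95), na.rm = TRUE,
                                     names = FALSE)
    }
    if (any(perc[, "p05"] > perc[, "p50"] | perc[, "p50"] > perc[, "p95"],
            na.rm = TRUE))
        stop("envelope percentile ordering violated")  # defensive
    structure(list(percentiles = perc, samples = samples,
                   nSamples = nSamples, seed = seed),
              class = "NullEnvelope")
}

# envelope row for a given set size: exact match or nearest available size
.envelopeRow <- function(envelope, size) {
    sizes <- as.integer(rownames(envelope$percentiles))
    i <- which.min(abs(sizes - size))
    envelope$percentiles[i, ]
}

#' Compare two distance distributions with an exact Poisson rate test
#'
#' Models the total path length of each set as Poisson with exposure equal to
#' its pair count, and tests rate equality with the exact conditional
#' binomial: given the combined total, the first set's total is binomial with
#' probability exposure1 / (exposure1 + exposure2).
#'
#' @param d1,d2 \code{"DistanceDistribution"} objects.
#' @return list: \code{rateRatio} (mean1/mean2), \code{p} (two-sided),
#'   \code{totals}, \code{exposures}.
#' @export
compareDistancePoisson <- function(d1, d2) {
    stopifnot(inherits(d1, "DistanceDistribution"),
              inherits(d2, "DistanceDistribution"))
    t1 <- sum(d1$distances); t2 <- sum(d2$distances)
    if (t1 == 0 || t2 == 0) stop("zero total path length; rates undefined")
    n1 <- d1$nPairs; n2 <- d2$nPairs
    p <- stats::binom.test(round(t1), round(t1 + t2),
                           p = n1 / (n1 + n2))$p.value
    list(rateRatio = d1$mean / d2$mean, p = p,
         totals = c(t1, t2), exposures = c(n1, n2))
}

#' Mean network distance among the top-N most affected proteins
#'
#' For each N in \code{nList}, takes the N features with the largest absolute
#' effect (ties broken by feature ID order), computes their pairwise distance
#' distribution and positions its mean within the null envelope.
#'
#' @param graph an [InteractionGraph-class] or igraph object.
#' @param effectVector named numeric vector (feature -> signed or absolute
#'   effect); absolute values are ranked.
#' @param nList integer vector of top-N sizes.
#' @param envelope optional \code{"NullEnvelope"}; when missing, one is built
#'   at the needed sizes with \code{nSamples} draws.
#' @param nSamples,seed envelope parameters when it is built here.
#' @return data.frame: N, meanDistance, nUnreachable, p05, p50, p95,
#'   position (below_p05 / within / above_p95); attribute
#'   \code{"distributions"} holds the per-N distance objects.
#' @export
topNDistance <- function(graph, effectVector, nList = c(50L, 100L, 200L, 320L),
                         envelope = NULL, nSamples = 1000L, seed = 1L) {
    g <- if (is(graph, "InteractionGraph")) interactionGraph(graph) else graph
    mappable <- intersect(names(effectVector), igraph::V(g)$name)
    if (length(mappable) < max(nList))
        stop(sprintf("only %d features map to the graph; max N is %d",
                     length(mappable), max(nList)))
    eff <- abs(effectVector[mappable])
    ord <- mappable[order(-eff, mappable)]
    if (is.null(envelope))
        envelope <- distanceNullEnvelope(graph, nList, nSamples = nSamples,
                                         seed = seed)
    dists <- list()
    rows <- lapply(nList, function(N) {
        dd <- pairwiseDistances(g, ord[seq_len(N)], label = paste0("top", N))
        dists[[as.character(N)]] <<- dd
        env <- .envelopeRow(envelope, N)
        pos <- if (dd$mean < env["p05"]) "below_p05"
               else if (dd$mean > env["p95"]) "above_p95" else "within"
        data.frame(N = N, meanDistance = dd$mean,
                   nUnreachable = dd$nUnreachable,
                   p05 = env["p05"], p50 = env["p50"], p95 = env["p95"],
                   position = pos, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "distributions") <- dists
    out
}

#' Split a locus' targets into state-consistent and state-inconsistent sets
#'
#' A target is consistent when the sign of its allele effect equals the sign
#' of the locus' state-score shift times the sign of the feature's
#' association with the state score; targets whose effect runs against that
#' expectation are inconsistent (candidates for a primary regional effect
#' with a secondary global response).
#'
#' @param alleleEffects named numeric vector (feature -> signed allele
#'   effect).
#' @param stateShift signed state-score shift of the locus (nonzero).
#' @param stateAssociation named numeric vector (feature -> signed
#'   association with the state score, e.g. correlation or slope).
#' @return list: \code{consistent}, \code{inconsistent} (feature IDs);
#'   features with a zero effect or no association entry are dropped and
#'   listed under \code{skipped}.
#' @export
consistencySplit <- function(alleleEffects, stateShift, stateAssociation) {
    if (is.na(stateShift) || stateShift == 0)
        stop("state-score shift is zero; the split is undefined")
    shared <- intersect(names(alleleEffects), names(stateAssociation))
    skipped <- setdiff(names(alleleEffects), shared)
    eff <- alleleEffects[shared]
    assoc <- stateAssociation[shared]
    usable <- eff != 0 & !is.na(assoc) & assoc != 0
    skipped <- c(skipped, shared[!usable])
    shared <- shared[usable]
    expected <- sign(stateShift) * sign(assoc[shared])
    consistent <- shared[sign(eff[shared]) == expected]
    list(consistent = consistent,
         inconsistent = setdiff(shared, consistent),
         skipped = skipped)
}

#' Classify a locus' network effect as local, regional or global
#'
#' Decision rule over the locus evidence: fewer than \code{localMax}
#' significant targets is a local effect; targets closer than the null-median
#' distance without a state-score shift is regional; targets at or beyond the
#' null median together with a significant state shift — or beyond the 0.95
#' percentile outright — is global; anything else is regional with a
#' \code{"mixed"} note.  All thresholds are exposed.
#'
#' @param locus locus ID (character).
#' @param nTargets number of significant molecular targets.
#' @param dist \code{"DistanceDistribution"} of the targets (NULL when
#'   nTargets < 2).
#' @param envelope \code{"NullEnvelope"} covering the target-set size.
#' @param stateShiftP p-value of the locus' state-score shift.
#' @param stateShift signed state-score shift (evidence only).
#' @param effectSignatureR optional correlation of the locus' effect vector
#'   with the inhibition signature (evidence only).
#' @param localMax,alpha classification thresholds.
#' @return list of class \code{"SpreadClassification"}: \code{locus},
#'   \code{label}, \code{note}, \code{evidence}.
#' @export
classifySpread <- function(locus, nTargets, dist, envelope, stateShiftP,
                           stateShift = NA_real_,
                           effectSignatureR = NA_real_,
                           localMax = 5L, alpha = 0.05) {
    if (missing(nTargets) || missing(stateShiftP))
        stop("nTargets and stateShiftP evidence is required")
    note <- ""
    if (nTargets < localMax) {
        label <- "local"
        meanD <- if (!is.null(dist)) dist$mean else NA_real_
        env <- c(p05 = NA_real_, p50 = NA_real_, p95 = NA_real_)
    } else {
        if (is.null(dist) || is.null(envelope))
            stop("distance distribution and envelope are required for >= ",
                 localMax, " targets")
        meanD <- dist$mean
        env <- .envelopeRow(envelope, length(dist$nodes))
        if (meanD > env["p95"]) {
            label <- "global"
        } else if (meanD >= env["p50"] && stateShiftP < alpha) {
            label <- "global"
        } else if (meanD < env["p50"] && stateShiftP >= alpha) {
            label <- "regional"
        } else {
            label <- "regional"; note <- "mixed"
        }
    }
    structure(list(locus = locus, label = label, note = note,
                   evidence = list(nTargets = nTargets, meanDistance = meanD,
                                   envelope = env, stateShiftP = stateShiftP,
                                   stateShift = stateShift,
                                   effectSignatureR = effectSignatureR)),
              class = "SpreadClassification")
}

#' @export
print.SpreadClassification <- function(x, ...) {
    ev <- x$evidence
    cat(sprintf("%s: %s%s (targets=%d, mean distance=%.3g, p50=%.3g, state-shift p=%.3g)\n",
                x$locus, x$label,
                if (nzchar(x$note)) paste0(" [", x$note, "]") else "",
                ev$nTargets, ev$meanDistance, ev$envelope["p50"],
                ev$stateShiftP))
    invisible(x)
}

#' State association of correlated protein pairs across network distance
#'
#' Takes every feature pair with |pairwise r| above \code{rMin}, computes each
#' member's correlation with the state score (for anti-correlated pairs one
#' coefficient is sign-inverted), and uses the absolute mean of the two
#' sign-corrected correlations as the pair's state-association statistic.
#' Pairs are binned by graph distance (bins above \code{collapseBin}
#' collapsed); per bin the counts of correlated vs anti-correlated pairs and
#' the fraction with association above \code{assocMin} are reported, and a
#' Fisher exact test contrasts that fraction between bins 1-3 pooled and
#' bins >= 4 pooled.
#'
#' @param abund an [AbundanceMatrix-class].
#' @param scores a \code{"StateScoreVector"} (or named numeric) over the same
#'   strains.
#' @param graph an [InteractionGraph-class] or igraph object.
#' @param rMin pairwise correlation threshold.
#' @param assocMin state-association threshold.
#' @param collapseBin distances above this collapse into it.
#' @return list of class \code{"PairStateAssociation"}: \code{binTable},
#'   \code{fisherP}, \code{fisherTable}, \code{nPairs},
#'   \code{nUnreachablePairs}.
#' @export
pairStateAssociation <- function(abund, scores, graph, rMin = 0.5,
                                 assocMin = 0.5, collapseBin = 6L) {
    stopifnot(is(abund, "AbundanceMatrix"))
    g <- if (is(graph, "InteractionGraph")) interactionGraph(graph) else graph
    v <- abundanceValues(abund)
    strains <- intersect(colnames(v), names(scores))
    if (length(strains) < 10L) stop("need >= 10 shared strains")
    feats <- intersect(rownames(v), igraph::V(g)$name)
    if (length(feats) < 3L) stop("fewer than 3 features map to the graph")
    m <- t(v[feats, strains, drop = FALSE])
    cc <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
    sc <- suppressWarnings(as.numeric(
        stats::cor(m, as.numeric(scores[strains]),
                   use = "pairwise.complete.obs")))
    names(sc) <- feats
    ut <- which(upper.tri(cc) & abs(cc) > rMin & !is.na(cc), arr.ind = TRUE)
    if (nrow(ut) == 0L) stop("no feature pair passes |r| > ", rMin)
    D <- igraph::distances(g, v = feats, to = feats)
    pairR <- cc[ut]
    s1 <- sc[ut[, 1L]]; s2 <- sc[ut[, 2L]]
    s2[pairR < 0] <- -s2[pairR < 0]  # sign correction for anti-correlated pairs
    assoc <- abs((s1 + s2) / 2)
    d <- D[ut]
    reachable <- is.finite(d)
    nUnreach <- sum(!reachable)
    d <- d[reachable]; assoc <- assoc[reachable]; pairR <- pairR[reachable]
    bin <- pmin(pmax(d, 1), collapseBin)
    binF <- factor(bin, levels = seq_len(collapseBin))
    binTable <- data.frame(
        bin = seq_len(collapseBin),
        nPairs = as.integer(table(binF)),
        nCorrelated = as.integer(table(binF[pairR > 0])),
        nAntiCorrelated = as.integer(table(binF[pairR < 0])),
        nAssociated = as.integer(table(binF[assoc > assocMin])),
        fracAssociated = as.numeric(table(binF[assoc > assocMin]) /
                                    pmax(table(binF), 1L)))
    low <- bin <= 3; high <- bin >= 4
    ft <- matrix(c(sum(assoc[low] > assocMin), sum(assoc[low] <= assocMin),
                   sum(assoc[high] > assocMin), sum(assoc[high] <= assocMin)),
                 nrow = 2L,
                 dimnames = list(c("associated", "notAssociated"),
                                 c("bins1to3", "bins4plus")))
    fp <- if (any(colSums(ft) == 0)) NA_real_ else stats::fisher.test(ft)$p.value
    structure(list(binTable = binTable, fisherP = fp, fisherTable = ft,
                   nPairs = length(d), nUnreachablePairs = nUnreach),
              class = "PairStateAssociation")
}

#' @export
print.PairStateAssociation <- function(x, ...) {
    cat(sprintf("Pair-state association: %d pairs (%d unreachable dropped), Fisher p = %.3g\n",
                x$nPairs, x$nUnreachablePairs, x$fisherP))
    print(x$binTable, row.names = FALSE)
    invisible(x)
}
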