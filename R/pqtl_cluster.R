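#' @include AllClasses.R AllGenerics.R
NULL

#' Linkage disequilibrium between two markers
#'
#' Squared Pearson correlation of allele codes over the jointly called
#' strains — the standard biallelic LD metric, symmetric under allele
#' relabeling (complementary columns give LD 1).
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param markerA,markerB marker IDs or indices.
#' @return r-squared in [0, 1]; NA with a warning when either marker is
#'   monomorphic among the shared strains.
#' @export
computeLD <- function(genotypes, markerA, markerB) {
    G <- alleleMatrix(genotypes)
    a <- G[, markerA]; b <- G[, markerB]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 10L) stop("need >= 10 strains with both markers called")
    if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) {
        warning("monomorphic marker among shared strains; LD undefined")
        return(NA_real_)
    }
    stats::cor(a[ok], b[ok])^2
}

# pairwise LD matrix for a set of markers (columns of the allele matrix)
.ldMatrix <- function(G, markers) {
    cc <- suppressWarnings(stats::cor(G[, markers, drop = FALSE],
                                      use = "pairwise.complete.obs"))
    cc^2
}

#' Adjacency-restricted LD clustering of pQTL markers
#'
#' Groups pQTL markers into genome-contiguous clusters: within each
#' chromosome, adjacent clusters are merged agglomeratively (complete
#' linkage on pairwise LD, merges restricted to genomic neighbors) for as
#' long as every merged cluster keeps its minimum within-cluster pairwise LD
#' at or above \code{ldMin} — i.e. the smallest number of clusters compatible
#' with the LD criterion.  Each cluster's lead marker is the member with the
#' most pQTL targets (ties resolved to the lower genomic position); adjacent
#' clusters whose lead markers have LD above \code{ldMin} are then merged,
#' iterated to a fixed point.  A lead-marker merge is applied only when the
#' merged cluster still satisfies the within-cluster LD floor, so the floor
#' is an invariant of every returned cluster.  A cluster's target set is the
#' union of its members' targets.
#'
#' @param pqtl a \code{"PQTLMap"} from [mapPQTL()] (or any list with a
#'   \code{links} data.frame of marker/feature rows).
#' @param genotypes a [GenotypeMatrix-class] containing every pQTL marker.
#' @param ldMin minimum within-cluster pairwise LD (0.9 by default; 0.8
#'   reproduces the relaxed linkage-grouping variant).
#' @return list of class \code{"ClusterSet"}: \code{clusters} (data.frame:
#'   cluster, chromosome, startMarker, endMarker, nMarkers, leadMarker,
#'   nTargets, minLD), \code{targets} (list of per-cluster target ID
#'   vectors), \code{members} (list of per-cluster marker IDs),
#'   \code{mergeLog}, \code{ldMin}.
#' @export
clusterPQTL <- function(pqtl, genotypes, ldMin = 0.9) {
    stopifnot(is(genotypes, "GenotypeMatrix"))
    links <- pqtl$links
    if (is.null(links) || nrow(links) == 0L) stop("no pQTL markers to cluster")
    mi <- markerInfo(genotypes)
    markers <- unique(links$marker)
    if (!all(markers %in% mi$marker))
        stop("pQTL markers missing from the genotype matrix")
    markers <- mi$marker[mi$marker %in% markers]  # genome order
    G <- alleleMatrix(genotypes)
    targetsOf <- split(links$feature, links$marker)

    clusters <- list()   # each: list(chromosome, members)
    for (chr in unique(mi$chromosome[match(markers, mi$marker)])) {
        chrMarkers <- markers[mi$chromosome[match(markers, mi$marker)] == chr]
        ld <- .ldMatrix(G, chrMarkers)
        groups <- as.list(chrMarkers)  # start from singletons, genome order
        repeat {
            if (length(groups) < 2L) break
            best <- NULL; bestLD <- -Inf
            for (i in seq_len(length(groups) - 1L)) {
                merged <- c(groups[[i]], groups[[i + 1L]])
                sub <- ld[merged, merged]
                minLD <- min(sub[upper.tri(sub)], na.rm = TRUE)
                if (minLD > bestLD) { bestLD <- minLD; best <- i }
            }
            if (bestLD < ldMin) break
            groups[[best]] <- c(groups[[best]], groups[[best + 1L]])
            groups[[best + 1L]] <- NULL
        }
        clusters <- c(clusters,
                      lapply(groups, function(m) list(chromosome = chr,
                                                      members = m)))
    }

    leadOf <- function(members) {
        nt <- vapply(members, function(m)
            length(unique(targetsOf[[m]])), integer(1))
        pos <- mi$position[match(members, mi$marker)]
        members[order(-nt, pos)][1L]
    }

    # lead-marker merging of adjacent clusters, iterated to a fixed point
    mergeLog <- character(0)
    repeat {
        mergedAny <- FALSE
        i <- 1L
        while (i < length(clusters)) {
            a <- clusters[[i]]; b <- clusters[[i + 1L]]
            if (a$chromosome == b$chromosome) {
                ldLead <- computeLD(genotypes, leadOf(a$members),
                                    leadOf(b$members))
                mergedMembers <- c(a$members, b$members)
                sub <- .ldMatrix(G, mergedMembers)
                floorOK <- min(sub[upper.tri(sub)], na.rm = TRUE) >= ldMin
                if (!is.na(ldLead) && ldLead > ldMin && floorOK) {
                    mergeLog <- c(mergeLog, sprintf(
                        "merged adjacent clusters on %s (lead LD %.3f): %s + %s",
                        a$chromosome, ldLead, leadOf(a$members),
                        leadOf(b$members)))
                    clusters[[i]]$members <- c(a$members, b$members)
                    clusters[[i + 1L]] <- NULL
                    mergedAny <- TRUE
                    next
                }
            }
            i <- i + 1L
        }
        if (!mergedAny) break
    }

    rows <- lapply(seq_along(clusters), function(k) {
        cl <- clusters[[k]]
        m <- cl$members
        minLD <- if (length(m) > 1L) {
            sub <- .ldMatrix(G, m)
            min(sub[upper.tri(sub)], na.rm = TRUE)
        } else 1
        tg <- unique(unlist(targetsOf[m], use.names = FALSE))
        data.frame(cluster = k, chromosome = cl$chromosome,
                   startMarker = m[1L], endMarker = m[length(m)],
                   nMarkers = length(m), leadMarker = leadOf(m),
                   nTargets = length(tg), minLD = minLD,
                   stringsAsFactors = FALSE)
    })
    structure(list(clusters = do.call(rbind, rows),
                   targets = lapply(clusters, function(cl)
                       unique(unlist(targetsOf[cl$members], use.names = FALSE))),
                   members = lapply(clusters, `[[`, "members"),
                   mergeLog = mergeLog, ldMin = ldMin),
              class = "ClusterSet")
}

#' @export
print.ClusterSet <- function(x, ...) {
    cat(sprintf("ClusterSet: %d clusters of %d markers (LD >= %.2g; %d lead-marker merges)\n",
                nrow(x$clusters), sum(x$clusters$nMarkers), x$ldMin,
                length(x$mergeLog)))
    print(utils::head(x$clusters, 10L), row.names = FALSE)
    invisible(x)
}
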