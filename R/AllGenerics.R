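#' @include AllClasses.R
NULL

#' Allele matrix of a cross
#'
#' Returns the allele calls as a strains x markers matrix (the orientation the
#' mapping statistics use).
#'
#' @param x a [GenotypeMatrix-class].
#' @return integer matrix, strains x markers.
#' @export
setGeneric("alleleMatrix", function(x) standardGeneric("alleleMatrix"))

#' @rdname alleleMatrix
#' @export
setMethod("alleleMatrix", "GenotypeMatrix", function(x) {
    t(assay(x, "alleles"))
})

#' Marker annotation of a cross
#'
#' @param x a [GenotypeMatrix-class].
#' @return data.frame with columns \code{marker}, \code{chromosome},
#'   \code{position}, in genome order.
#' @export
setGeneric("markerInfo", function(x) standardGeneric("markerInfo"))

#' @rdname markerInfo
#' @export
setMethod("markerInfo", "GenotypeMatrix", function(x) {
    rd <- rowData(x)
    data.frame(marker = rownames(x),
               chromosome = as.character(rd$chromosome),
               position = as.integer(rd$position),
               row.names = NULL)
})

#' Abundance values
#'
#' @param x an [AbundanceMatrix-class].
#' @return numeric matrix, features x strains.
#' @export
setGeneric("abundanceValues", function(x) standardGeneric("abundanceValues"))

#' @rdname abundanceValues
#' @export
setMethod("abundanceValues", "AbundanceMatrix", function(x) assay(x, "values"))

#' Layer tag of an abundance matrix
#'
#' @param x an [AbundanceMatrix-class].
#' @return character scalar: the omics layer.
#' @export
setGeneric("layerTag", function(x) standardGeneric("layerTag"))

#' @rdname layerTag
#' @export
setMethod("layerTag", "AbundanceMatrix", function(x) metadata(x)$layer)

#' Is an abundance matrix feature-standardized?
#'
#' @param x an [AbundanceMatrix-class].
#' @return logical scalar.
#' @export
setGeneric("isStandardized", function(x) standardGeneric("isStandardized"))

#' @rdname isStandardized
#' @export
setMethod("isStandardized", "AbundanceMatrix", function(x) isTRUE(metadata(x)$standardized))

#' Standardize features (row z-scores)
#'
#' Centers and scales every feature row to mean 0, SD 1 over its non-missing
#' strains.  Rows with zero variance are left at 0 (centered only).
#'
#' @param x an [AbundanceMatrix-class].
#' @return an [AbundanceMatrix-class] with the standardized flag set.
#' @export
setGeneric("standardizeFeatures", function(x) standardGeneric("standardizeFeatures"))

#' @rdname standardizeFeatures
#' @export
setMethod("standardizeFeatures", "AbundanceMatrix", function(x) {
    if (isStandardized(x)) return(x)
    v <- assay(x, "values")
    mu <- rowMeans(v, na.rm = TRUE)
    sdv <- apply(v, 1L, stats::sd, na.rm = TRUE)
    sdv[is.na(sdv) | sdv == 0] <- Inf  # zero-variance rows collapse to 0
    z <- (v - mu) / sdv
    AbundanceMatrix(z, layer = layerTag(x), standardized = TRUE)
})

#' Induced / repressed members of a signature
#'
#' @param x a [MarkerSetPair-class].
#' @return character vector of feature IDs.
#' @export
setGeneric("inducedMarkers", function(x) standardGeneric("inducedMarkers"))

#' @rdname inducedMarkers
#' @export
setMethod("inducedMarkers", "MarkerSetPair", function(x) x@induced)

#' @rdname inducedMarkers
#' @export
setGeneric("repressedMarkers", function(x) standardGeneric("repressedMarkers"))

#' @rdname inducedMarkers
#' @export
setMethod("repressedMarkers", "MarkerSetPair", function(x) x@repressed)

#' Underlying igraph object of an InteractionGraph
#'
#' @param x an [InteractionGraph-class].
#' @return an \pkg{igraph} graph.
#' @export
setGeneric("interactionGraph", function(x) standardGeneric("interactionGraph"))

#' @rdname interactionGraph
#' @export
setMethod("interactionGraph", "InteractionGraph", function(x) x@graph)

# ---------------------------------------------------------------------------
# show methods
# ---------------------------------------------------------------------------

setMethod("show", "GenotypeMatrix", function(object) {
    mi <- markerInfo(object)
    cat(sprintf("GenotypeMatrix: %d strains x %d markers on %d chromosome(s)\n",
                ncol(object), nrow(object), length(unique(mi$chromosome))))
    a <- assay(object, "alleles")
    cat(sprintf("  missing calls: %.2f%%\n", 100 * mean(is.na(a))))
})

setMethod("show", "AbundanceMatrix", function(object) {
    cat(sprintf("AbundanceMatrix [%s]: %d features x %d strains%s\n",
                layerTag(object), nrow(object), ncol(object),
                if (isStandardized(object)) " (standardized)" else ""))
})

setMethod("show", "MarkerSetPair", function(object) {
    cat(sprintf("MarkerSetPair: %d induced / %d repressed (%s)\n",
                length(object@induced), length(object@repressed),
                object@provenance))
})

setMethod("show", "InteractionGraph", function(object) {
    g <- object@graph
    cat(sprintf("InteractionGraph: %d nodes, %d edges (score > %s)\n",
                igraph::vcount(g), igraph::ecount(g),
                format(object@scoreMin)))
    if (length(object@dropped))
        cat("  dropped:", paste(names(object@dropped), object@dropped,
                                sep = "=", collapse = ", "), "\n")
})
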