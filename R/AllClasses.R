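#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames rowData colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

# ---------------------------------------------------------------------------
# GenotypeMatrix: markers x strains allele calls from a haploid biallelic cross
# ---------------------------------------------------------------------------

#' GenotypeMatrix: haploid biallelic genotypes of a segregant cross
#'
#' Stores allele calls (0 = first parent, 1 = second parent, NA = missing) for
#' genome-ordered markers (rows) across strains (columns), together with the
#' chromosome and base-pair position of every marker.  Extends
#' \linkS4class{SummarizedExperiment}; the single assay is named
#' \code{"alleles"}.
#'
#' @slot ... see \linkS4class{SummarizedExperiment}
#' @seealso [GenotypeMatrix()], [alleleMatrix()], [markerInfo()]
#' @export
setClass("GenotypeMatrix", contains = "SummarizedExperiment")

.validGenotypeMatrix <- function(object) {
    msg <- character()
    if (!"alleles" %in% assayNames(object))
        return("assay 'alleles' is required")
    a <- assay(object, "alleles")
    if (!all(a[!is.na(a)] %in% c(0L, 1L)))
        msg <- c(msg, "allele calls must be 0, 1 or NA")
    rd <- rowData(object)
    if (!all(c("chromosome", "position") %in% colnames(rd))) {
        msg <- c(msg, "rowData must contain 'chromosome' and 'position'")
    } else {
        chrom <- as.character(rd$chromosome)
        pos <- rd$position
        r <- rle(chrom)
        if (anyDuplicated(r$values))
            msg <- c(msg, "markers of one chromosome must be contiguous")
        if (length(chrom) > 1L) {
            same <- chrom[-1L] == chrom[-length(chrom)]
            if (any(same & diff(pos) <= 0))
                msg <- c(msg, "positions must be strictly increasing within chromosomes")
        }
    }
    if (ncol(object) < 2L)
        msg <- c(msg, "at least 2 strains are required")
    if (nrow(object) < 1L)
        msg <- c(msg, "at least 1 marker is required")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "strain IDs must be unique")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "marker IDs must be unique")
    if (length(msg)) msg else TRUE
}
setValidity("GenotypeMatrix", .validGenotypeMatrix)

#' Construct a GenotypeMatrix
#'
#' @param alleles integer matrix (markers x strains) with entries 0, 1 or NA.
#'   Row and column names give marker and strain IDs.
#' @param chromosome character vector of chromosome names, one per marker.
#' @param position integer vector of 1-based base-pair positions, one per marker.
#'
#' Markers supplied out of genomic order are sorted by (chromosome, position)
#' with a warning; chromosome order follows first appearance.
#'
#' @return a [GenotypeMatrix-class] object.
#' @export
GenotypeMatrix <- function(alleles, chromosome, position) {
    alleles <- as.matrix(alleles)
    storage.mode(alleles) <- "integer"
    chromosome <- as.character(chromosome)
    position <- as.integer(position)
    stopifnot(length(chromosome) == nrow(alleles),
              length(position) == nrow(alleles))
    ord <- order(match(chromosome, unique(chromosome)), position)
    if (!identical(ord, seq_len(nrow(alleles)))) {
        warning("markers were not in genomic order; sorting by (chromosome, position)")
        alleles <- alleles[ord, , drop = FALSE]
        chromosome <- chromosome[ord]
        position <- position[ord]
    }
    if (is.null(rownames(alleles)))
        rownames(alleles) <- sprintf("m%05d", seq_len(nrow(alleles)))
    se <- SummarizedExperiment(
        assays = list(alleles = alleles),
        rowData = DataFrame(chromosome = chromosome, position = position))
    new("GenotypeMatrix", se)
}

# ---------------------------------------------------------------------------
# AbundanceMatrix: omics features x strains
# ---------------------------------------------------------------------------

.ABUNDANCE_LAYERS <- c("transcript", "protein", "phosphopeptide", "phospho_residual")

#' AbundanceMatrix: omics feature abundances across strains
#'
#' Features (transcripts, proteins, phosphopeptides or phospho-residuals) in
#' rows, strains in columns.  Extends \linkS4class{SummarizedExperiment}; the
#' single assay is named \code{"values"}.  The layer tag and the standardized
#' flag live in \code{metadata()}; the per-feature missing fraction is kept in
#' \code{rowData()$missing_frac}.
#'
#' @seealso [AbundanceMatrix()], [standardizeFeatures()], [layerTag()]
#' @export
setClass("AbundanceMatrix", contains = "SummarizedExperiment")

.validAbundanceMatrix <- function(object) {
    msg <- character()
    if (!"values" %in% assayNames(object))
        return("assay 'values' is required")
    md <- metadata(object)
    if (is.null(md$layer) || !md$layer %in% .ABUNDANCE_LAYERS)
        msg <- c(msg, sprintf("metadata layer must be one of: %s",
                              paste(.ABUNDANCE_LAYERS, collapse = ", ")))
    if (!is.logical(md$standardized) || length(md$standardized) != 1L)
        msg <- c(msg, "metadata standardized flag must be a single logical")
    else if (isTRUE(md$standardized)) {
        v <- assay(object, "values")
        mu <- rowMeans(v, na.rm = TRUE)
        sdv <- apply(v, 1L, stats::sd, na.rm = TRUE)
        ok <- is.na(mu) | (abs(mu) < 1e-8 & (is.na(sdv) | abs(sdv - 1) < 1e-8 | sdv == 0))
        if (!all(ok))
            msg <- c(msg, "standardized flag set but rows are not mean 0 / SD 1")
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "feature IDs must be unique")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "strain IDs must be unique")
    if (length(msg)) msg else TRUE
}
setValidity("AbundanceMatrix", .validAbundanceMatrix)

#' Construct an AbundanceMatrix
#'
#' @param values numeric matrix, features x strains; NA marks missing values.
#' @param layer one of \code{"transcript"}, \code{"protein"},
#'   \code{"phosphopeptide"}, \code{"phospho_residual"}.
#' @param standardized logical; set only when each row already has mean 0 and
#'   SD 1 over non-missing strains.
#' @return an [AbundanceMatrix-class] object.
#' @export
AbundanceMatrix <- function(values, layer, standardized = FALSE) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    layer <- match.arg(layer, .ABUNDANCE_LAYERS)
    se <- SummarizedExperiment(
        assays = list(values = values),
        rowData = DataFrame(missing_frac = rowMeans(is.na(values))),
        metadata = list(layer = layer, standardized = isTRUE(standardized)))
    new("AbundanceMatrix", se)
}

# ---------------------------------------------------------------------------
# MarkerSetPair: induced / repressed signature gene sets
# ---------------------------------------------------------------------------

#' MarkerSetPair: an induced/repressed state-signature pair
#'
#' Two disjoint, non-empty feature-ID sets defining a network-state signature
#' (e.g. the PKA/TOR-responsive marker sets used for state scoring).
#'
#' @slot induced character vector of induced feature IDs.
#' @slot repressed character vector of repressed feature IDs.
#' @slot provenance free-text note on how the sets were derived.
#' @seealso [deriveMarkerSets()], [computeStateScore()]
#' @export
setClass("MarkerSetPair",
         representation(induced = "character",
                        repressed = "character",
                        provenance = "character"))

setValidity("MarkerSetPair", function(object) {
    msg <- character()
    if (length(object@induced) == 0L) msg <- c(msg, "induced set is empty")
    if (length(object@repressed) == 0L) msg <- c(msg, "repressed set is empty")
    if (length(intersect(object@induced, object@repressed)))
        msg <- c(msg, "induced and repressed sets must be disjoint")
    if (anyDuplicated(object@induced) || anyDuplicated(object@repressed))
        msg <- c(msg, "marker sets must not contain duplicates")
    if (length(msg)) msg else TRUE
})

#' Construct a MarkerSetPair
#'
#' @param induced,repressed character vectors of feature IDs (disjoint,
#'   non-empty).
#' @param provenance free-text provenance note.
#' @return a [MarkerSetPair-class] object.
#' @export
MarkerSetPair <- function(induced, repressed, provenance = "user-supplied") {
    new("MarkerSetPair",
        induced = as.character(induced),
        repressed = as.character(repressed),
        provenance = as.character(provenance)[1L])
}

# ---------------------------------------------------------------------------
# InteractionGraph: simple undirected protein-interaction graph
# ---------------------------------------------------------------------------

#' InteractionGraph: thresholded protein-interaction graph
#'
#' A simple undirected graph over protein IDs, built from a weighted edge list
#' by confidence thresholding, self-loop removal and multi-edge collapsing.
#' Construction metadata records the threshold and the numbers of dropped
#' edges.
#'
#' @slot graph an \pkg{igraph} graph object (simple, undirected).
#' @slot scoreMin numeric confidence threshold used (strict inequality); NA for
#'   simulated graphs.
#' @slot dropped named integer vector: edges dropped below threshold, self
#'   loops removed, multi edges collapsed.
#' @seealso [buildGraph()], [pairwiseDistances()]
#' @export
setClass("InteractionGraph",
         representation(graph = "ANY",
                        scoreMin = "numeric",
                        dropped = "integer"))

setValidity("InteractionGraph", function(object) {
    g <- object@graph
    if (!igraph::is_igraph(g)) return("graph slot must hold an igraph object")
    msg <- character()
    if (igraph::is_directed(g)) msg <- c(msg, "graph must be undirected")
    if (!igraph::is_simple(g)) msg <- c(msg, "graph must be simple (no loops / multi-edges)")
    if (is.null(igraph::V(g)$name)) msg <- c(msg, "graph vertices must be named")
    if (length(msg)) msg else TRUE
})
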