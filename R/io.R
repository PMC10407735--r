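#' @include AllClasses.R AllGenerics.R
NULL

.NA_TOKENS <- c("NA", "NaN", "")  # fixed, case-sensitive

#' Read a genotype table
#'
#' Marker-row dialect: columns \code{marker}, \code{chromosome},
#' \code{position}, then one column per strain.  Strain-row dialect
#' (\code{dialect = "strains"}): first column strain ID, remaining columns are
#' markers, with chromosome/position supplied separately via
#' \code{markerInfo}.  Allele symbols are mapped through \code{symbolMap}
#' (default BY/RM and 0/1); unmapped symbols are a parse error naming the
#' offending row and column.  Markers out of genomic order are sorted with a
#' warning.
#'
#' @param path TSV file path.
#' @param dialect \code{"markers"} (default) or \code{"strains"}.
#' @param symbolMap named integer vector mapping allele symbols to 0/1.
#' @param markerInfo for the strain-row dialect: data.frame with columns
#'   \code{marker}, \code{chromosome}, \code{position}.
#' @return a [GenotypeMatrix-class].
#' @export
readGenotypes <- function(path, dialect = c("markers", "strains"),
                          symbolMap = c(BY = 0L, RM = 1L, "0" = 0L, "1" = 1L),
                          markerInfo = NULL) {
    dialect <- match.arg(dialect)
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             colClasses = "character", check.names = FALSE,
                             comment.char = "#", na.strings = character(0))
    if (dialect == "strains") {
        if (is.null(markerInfo))
            stop("strain-row dialect requires a markerInfo table")
        strains <- tab[[1L]]
        sym <- t(as.matrix(tab[, -1L, drop = FALSE]))
        colnames(sym) <- strains
        mi <- markerInfo[match(rownames(sym), markerInfo$marker), ]
    } else {
        if (ncol(tab) < 4L)
            stop("marker-row genotype tables need marker, chromosome, position + >= 1 strain")
        if (anyDuplicated(tab[[1L]]))
            stop("duplicate marker ID: ",
                 paste(unique(tab[[1L]][duplicated(tab[[1L]])]), collapse = ", "))
        sym <- as.matrix(tab[, -(1:3), drop = FALSE])
        rownames(sym) <- tab[[1L]]
        mi <- data.frame(marker = tab[[1L]], chromosome = tab[[2L]],
                         position = as.integer(tab[[3L]]))
    }
    alleles <- matrix(NA_integer_, nrow(sym), ncol(sym), dimnames = dimnames(sym))
    isNA <- matrix(sym %in% .NA_TOKENS, nrow(sym))
    known <- matrix(sym %in% names(symbolMap), nrow(sym))
    if (any(!isNA & !known)) {
        bad <- which(!isNA & !known, arr.ind = TRUE)[1L, ]
        stop(sprintf("unknown allele symbol '%s' at marker '%s', strain '%s'",
                     sym[bad[1L], bad[2L]], rownames(sym)[bad[1L]],
                     colnames(sym)[bad[2L]]))
    }
    alleles[known] <- symbolMap[sym[known]]
    GenotypeMatrix(alleles, mi$chromosome, mi$position)
}

#' Write a genotype table (marker-row dialect)
#'
#' @param x a [GenotypeMatrix-class].
#' @param path output TSV path.
#' @param comment optional header comment line (version/seed provenance).
#' @return invisibly, the path.
#' @export
writeGenotypes <- function(x, path, comment = NULL) {
    mi <- markerInfo(x)
    a <- assay(x, "alleles")
    out <- data.frame(marker = mi$marker, chromosome = mi$chromosome,
                      position = mi$position, a, check.names = FALSE)
    .writeTSV(out, path, comment)
}

.writeTSV <- function(df, path, comment = NULL) {
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(comment)) writeLines(paste0("# ", comment), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
    invisible(path)
}

#' Read an abundance table
#'
#' TSV with features in rows (first column feature ID) and strains in columns.
#' Blank, \code{NA} and \code{NaN} cells become missing; any other non-numeric
#' cell is a parse error.  No imputation is performed at load time.
#'
#' @param path TSV file path.
#' @param layer omics layer tag (see [AbundanceMatrix()]).
#' @return an [AbundanceMatrix-class] (standardized flag unset).
#' @export
readAbundance <- function(path, layer) {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             colClasses = "character", check.names = FALSE,
                             comment.char = "#", na.strings = character(0))
    ids <- tab[[1L]]
    cells <- as.matrix(tab[, -1L, drop = FALSE])
    vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells),
                                   dimnames = list(ids, colnames(cells))))
    bad <- is.na(vals) & !matrix(cells %in% .NA_TOKENS, nrow(cells))
    if (any(bad)) {
        w <- which(bad, arr.ind = TRUE)[1L, ]
        stop(sprintf("non-numeric cell '%s' at feature '%s', strain '%s'",
                     cells[w[1L], w[2L]], ids[w[1L]], colnames(cells)[w[2L]]))
    }
    AbundanceMatrix(vals, layer = layer)
}

#' Write an abundance table
#'
#' @param x an [AbundanceMatrix-class].
#' @param path output TSV path.
#' @param comment optional header comment line.
#' @return invisibly, the path.
#' @export
writeAbundance <- function(x, path, comment = NULL) {
    v <- abundanceValues(x)
    out <- data.frame(feature = rownames(v),
                      format(v, digits = 15, trim = TRUE, scientific = FALSE),
                      check.names = FALSE)
    out[-1L][is.na(v)] <- "NA"
    .writeTSV(out, path, comment)
}

#' Read a STRING-style weighted edge list
#'
#' Whitespace- or tab-delimited, optional header, columns (protein A, protein
#' B, combined score).  Scores on the 0-1000 scale (any value > 1) are
#' rescaled to 0-1 (400 becomes 0.400).  Self-edges are kept but flagged.
#'
#' @param path file path.
#' @return data.frame of class \code{"EdgeList"}: \code{proteinA},
#'   \code{proteinB}, \code{score}, \code{selfEdge}; attribute
#'   \code{"rescaled"} records whether the 0-1000 rule fired.
#' @export
readEdgeList <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
    fields <- strsplit(trimws(lines), "[[:space:]]+")
    nf <- lengths(fields)
    if (any(nf < 3L))
        stop("edge list lines must have at least 3 columns (A, B, score)")
    a <- vapply(fields, `[[`, character(1), 1L)
    b <- vapply(fields, `[[`, character(1), 2L)
    sc <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
    if (is.na(sc[1L]) && length(sc) > 1L) {  # header line
        a <- a[-1L]; b <- b[-1L]; sc <- sc[-1L]
    }
    if (anyNA(sc)) stop("non-numeric score in edge list")
    if (any(sc < 0)) stop("scores must be non-negative")
    rescaled <- any(sc > 1)
    if (rescaled) sc <- sc / 1000
    structure(data.frame(proteinA = a, proteinB = b, score = sc,
                         selfEdge = a == b, stringsAsFactors = FALSE),
              class = c("EdgeList", "data.frame"), rescaled = rescaled)
}

#' Write an edge list
#'
#' @param edges an \code{"EdgeList"} data.frame.
#' @param path output path.
#' @param scale1000 write scores on the STRING 0-1000 integer scale.
#' @return invisibly, the path.
#' @export
writeEdgeList <- function(edges, path, scale1000 = FALSE) {
    sc <- if (scale1000) round(edges$score * 1000) else edges$score
    .writeTSV(data.frame(protein1 = edges$proteinA, protein2 = edges$proteinB,
                         combined_score = sc), path)
}

#' Read / write marker-set pairs (two-column TSV: set, feature_id)
#'
#' @param path TSV path with columns \code{set} (induced/repressed) and
#'   \code{feature_id}.
#' @return a [MarkerSetPair-class].
#' @export
readMarkerSets <- function(path) {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             colClasses = "character", comment.char = "#")
    if (!all(c("set", "feature_id") %in% colnames(tab)))
        stop("marker-set table needs columns 'set' and 'feature_id'")
    MarkerSetPair(induced = tab$feature_id[tab$set == "induced"],
                  repressed = tab$feature_id[tab$set == "repressed"],
                  provenance = paste("read from", basename(path)))
}

#' @rdname readMarkerSets
#' @param markers a [MarkerSetPair-class] to write.
#' @param comment optional header comment line.
#' @export
writeMarkerSets <- function(markers, path, comment = NULL) {
    out <- data.frame(
        set = rep(c("induced", "repressed"),
                  c(length(inducedMarkers(markers)),
                    length(repressedMarkers(markers)))),
        feature_id = c(inducedMarkers(markers), repressedMarkers(markers)))
    .writeTSV(out, path, comment)
}

#' Quantile-based library-size correction of a count matrix
#'
#' Genes detected (non-zero) in fewer than half of the samples are dropped.
#' For each sample the median of counts lying between that sample's 20% and
#' 80% quantiles is computed; sample counts are multiplied by the ratio of the
#' mean of these medians to the sample's own median, which equalizes the
#' inter-quantile medians across samples.  Replicate samples are averaged on
#' the corrected scale when a replicate map is supplied.
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @param replicateMap optional named character vector mapping sample ->
#'   replicate-group label; groups are averaged after scaling.
#' @return an [AbundanceMatrix-class] (layer \code{"transcript"}) of corrected
#'   values; attributes \code{"scaleFactors"} and \code{"dropped"} record the
#'   per-sample factors and discarded genes.
#' @export
normalizeCounts <- function(counts, replicateMap = NULL) {
    counts <- as.matrix(counts)
    if (ncol(counts) < 2L) stop("need >= 2 samples")
    if (any(counts < 0)) stop("counts must be non-negative")
    zeroSample <- colSums(counts) == 0
    if (any(zeroSample))
        stop("sample(s) with all-zero counts: ",
             paste(colnames(counts)[zeroSample], collapse = ", "))
    detected <- rowMeans(counts > 0) >= 0.5
    dropped <- rownames(counts)[!detected]
    counts <- counts[detected, , drop = FALSE]
    M <- vapply(seq_len(ncol(counts)), function(i) {
        x <- counts[, i]
        q <- stats::quantile(x, c(0.2, 0.8), names = FALSE)
        stats::median(x[x >= q[1L] & x <= q[2L]])
    }, numeric(1))
    if (any(M == 0))
        stop("inter-quantile median is zero for sample(s): ",
             paste(colnames(counts)[M == 0], collapse = ", "))
    f <- mean(M) / M
    corrected <- sweep(counts, 2L, f, `*`)
    if (!is.null(replicateMap)) {
        grp <- replicateMap[colnames(corrected)]
        if (anyNA(grp)) stop("replicateMap must cover every sample")
        corrected <- vapply(split(seq_along(grp), grp), function(ix)
            rowMeans(corrected[, ix, drop = FALSE]),
            numeric(nrow(corrected)))
    }
    out <- AbundanceMatrix(corrected, layer = "transcript")
    attr(out, "scaleFactors") <- stats::setNames(f, colnames(counts))
    attr(out, "dropped") <- dropped
    out
}

#' Write state scores as TSV
#'
#' @param scores a \code{"StateScoreVector"} from [computeStateScore()].
#' @param path output path.
#' @param comment optional header comment.
#' @return invisibly, the path.
#' @export
writeStateScores <- function(scores, path, comment = NULL) {
    .writeTSV(data.frame(strain = names(scores), score = as.numeric(scores),
                         n_induced_used = attr(scores, "nInducedUsed"),
                         n_repressed_used = attr(scores, "nRepressedUsed")),
              path, comment)
}
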