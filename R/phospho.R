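#' @include AllClasses.R AllGenerics.R
NULL

#' Protein-abundance-corrected phosphorylation residuals
#'
#' Per phosphopeptide with a measured host protein, regresses the peptide's
#' standardized abundance on the host protein's standardized abundance across
#' strains (OLS with intercept) and keeps the residuals — a raw peptide mixes
#' host-protein abundance change with phosphorylation-rate change, the
#' residual isolates the latter.  Peptides whose host protein is unmeasured
#' pass through unchanged with a flag; peptides sharing fewer than
#' \code{minShared} strains with their host are dropped and logged.
#'
#' @param peptides an [AbundanceMatrix-class] (layer phosphopeptide).
#' @param proteins an [AbundanceMatrix-class] (layer protein).
#' @param peptideMap named character vector: peptide ID -> host protein ID
#'   (exactly one host per peptide).
#' @param minShared minimum jointly measured strains for the regression.
#' @return an [AbundanceMatrix-class] with layer \code{"phospho_residual"};
#'   rowData columns \code{hostProtein}, \code{hostMeasured}, \code{slope};
#'   attribute \code{"droppedPeptides"} lists peptides below
#'   \code{minShared}.
#' @export
phosphoResiduals <- function(peptides, proteins, peptideMap, minShared = 10L) {
    stopifnot(is(peptides, "AbundanceMatrix"), is(proteins, "AbundanceMatrix"))
    if (anyDuplicated(names(peptideMap)))
        stop("peptideMap must map every peptide to exactly one host protein")
    zp <- abundanceValues(standardizeFeatures(peptides))
    zh <- abundanceValues(standardizeFeatures(proteins))
    strains <- intersect(colnames(zp), colnames(zh))
    zp <- zp[, strains, drop = FALSE]
    out <- zp
    host <- peptideMap[rownames(zp)]
    hostMeasured <- !is.na(host) & host %in% rownames(zh)
    slope <- rep(NA_real_, nrow(zp))
    dropped <- character(0)
    for (i in which(hostMeasured)) {
        y <- zp[i, ]
        x <- zh[host[i], strains]
        ok <- !is.na(y) & !is.na(x)
        if (sum(ok) < minShared) {
            out[i, ] <- NA_real_
            dropped <- c(dropped, rownames(zp)[i])
            next
        }
        fit <- stats::lm.fit(cbind(1, x[ok]), y[ok])
        out[i, ok] <- fit$residuals
        out[i, !ok] <- NA_real_
        slope[i] <- fit$coefficients[2L]
    }
    res <- AbundanceMatrix(out, layer = "phospho_residual")
    rowData(res)$hostProtein <- unname(host)
    rowData(res)$hostMeasured <- hostMeasured
    rowData(res)$slope <- slope
    attr(res, "droppedPeptides") <- dropped
    res
}

#' Select the best state-predicted peptide per protein
#'
#' Among each protein's phosphopeptides, picks the peptide with the highest
#' adjusted R-squared against the state score (ties resolved to the
#' lexicographically first peptide ID).  The number of candidate peptides is
#' always reported because this selection favors proteins with many measured
#' peptides.
#'
#' @param fits data.frame with columns \code{peptide} and \code{adjR2} (e.g.
#'   from [featureStateModels()] on the peptide layer).
#' @param peptideMap named character vector: peptide ID -> host protein ID.
#' @return data.frame: \code{protein}, \code{peptide} (selected),
#'   \code{adjR2}, \code{nCandidates}; attribute \code{"candidates"} keeps
#'   the full per-protein candidate table.
#' @export
selectBestPeptide <- function(fits, peptideMap) {
    stopifnot(all(c("peptide", "adjR2") %in% colnames(fits)))
    fits$protein <- peptideMap[fits$peptide]
    fits <- fits[!is.na(fits$protein), , drop = FALSE]
    if (nrow(fits) == 0L) stop("no peptide maps to a host protein")
    picked <- do.call(rbind, lapply(split(fits, fits$protein), function(d) {
        d <- d[order(-d$adjR2, d$peptide), ]
        data.frame(protein = d$protein[1L], peptide = d$peptide[1L],
                   adjR2 = d$adjR2[1L], nCandidates = nrow(d),
                   stringsAsFactors = FALSE)
    }))
    rownames(picked) <- NULL
    attr(picked, "candidates") <- fits
    picked
}

#' Audit cross-peptide consistency of state predictions
#'
#' Among proteins with at least two peptides significant at the given FDR, a
#' protein is inconsistent when its significant peptides disagree in the sign
#' of their state-score coefficient.  The audit is repeated at a second,
#' laxer FDR.
#'
#' @param fits data.frame with columns \code{peptide}, \code{beta} (signed
#'   state-score coefficient) and \code{q}.
#' @param peptideMap named character vector: peptide ID -> host protein ID.
#' @param fdr primary significance threshold.
#' @param fdr2 secondary threshold for the repeat audit.
#' @return list of class \code{"ConsistencyAudit"} with one entry per
#'   threshold: \code{nTested} (proteins with >= 2 significant peptides),
#'   \code{nInconsistent}, \code{fraction}, \code{inconsistent} (protein
#'   IDs).
#' @export
consistencyAudit <- function(fits, peptideMap, fdr = 0.05, fdr2 = 0.25) {
    stopifnot(all(c("peptide", "beta", "q") %in% colnames(fits)))
    auditAt <- function(th) {
        sig <- fits[fits$q <= th, , drop = FALSE]
        sig$protein <- peptideMap[sig$peptide]
        sig <- sig[!is.na(sig$protein), , drop = FALSE]
        byProt <- split(sig$beta, sig$protein)
        multi <- byProt[lengths(byProt) >= 2L]
        bad <- names(multi)[vapply(multi, function(b)
            length(unique(sign(b))) > 1L, logical(1))]
        list(fdr = th, nTested = length(multi), nInconsistent = length(bad),
             fraction = if (length(multi)) length(bad) / length(multi)
                        else NA_real_,
             inconsistent = bad)
    }
    structure(stats::setNames(list(auditAt(fdr), auditAt(fdr2)),
                              paste0("fdr", c(fdr, fdr2))),
              class = "ConsistencyAudit")
}

#' @export
print.ConsistencyAudit <- function(x, ...) {
    for (a in x)
        cat(sprintf("FDR <= %.2g: %d/%d proteins with inconsistent peptide signs (%.1f%%)\n",
                    a$fdr, a$nInconsistent, a$nTested, 100 * a$fraction))
    invisible(x)
}
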