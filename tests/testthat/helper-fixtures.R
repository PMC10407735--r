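# Shared desk-scale fixtures, built in code and memoized per test run.

smallCfg <- function(seed = 5L, ...) {
    simConfig(
        nStrains = 60L,
        chromosomes = data.frame(name = sprintf("chr%02d", 1:4),
                                 nMarkers = 40L, recomb = 0.05),
        nFeatures = c(transcript = 60L, protein = 120L, phosphopeptide = 40L),
        network = list(nNodes = 60L, nModules = 3L, pWithin = 0.4,
                       pBetween = 0.02),
        seed = seed, ...)
}

.fixtureEnv <- new.env(parent = emptyenv())

smallStudy <- function(seed = 5L) {
    key <- paste0("study", seed)
    if (is.null(.fixtureEnv[[key]]))
        .fixtureEnv[[key]] <- simulateStudy(smallCfg(seed), growth = FALSE)
    .fixtureEnv[[key]]
}

# tiny genotype matrix built by hand
tinyGenotypes <- function() {
    a <- rbind(m1 = c(0L, 1L, 0L, 1L, 0L, 1L),
               m2 = c(0L, 1L, 0L, 1L, 1L, 0L),
               m3 = c(1L, 1L, 0L, 0L, 1L, 0L))
    colnames(a) <- paste0("S", 1:6)
    GenotypeMatrix(a, chromosome = c("chr01", "chr01", "chr02"),
                   position = c(1000L, 2000L, 500L))
}
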