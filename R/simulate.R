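#' @include AllClasses.R AllGenerics.R
NULL

# Seed offsets so that one config seed drives every generator stage while the
# stages draw from distinct streams.
.SEED_CROSS <- 0L
.SEED_NETWORK <- 11L
.SEED_OMICS <- 23L
.SEED_INHIBITION <- 37L
.SEED_GROWTH <- 53L

#' Planted QTL specification
#'
#' Describes one causal variant for the synthetic cross: a global variant acts
#' on the latent state axis, a regional variant on one network module, a local
#' variant on a single feature.  An optional epistatic partner adds a product
#' term (genotype_a * genotype_b * interaction) on the latent axis.
#'
#' @param marker integer marker index (genome order).
#' @param type one of \code{"global"}, \code{"regional"}, \code{"local"}.
#' @param effect effect size in standardized units.
#' @param target for regional: module ID (integer); for local: protein feature
#'   ID (character); must be NA for global.
#' @param partner optional marker index of an epistatic partner (global only).
#' @param interaction interaction coefficient for the product term.
#' @param lagEffect additive effect (minutes) of allele 1 on the heat-induced
#'   lag, on top of any effect routed through the latent state.
#' @return a list of class \code{"PlantedQTL"}.
#' @export
plantedQTL <- function(marker, type = c("global", "regional", "local"),
                       effect, target = NA, partner = NA_integer_,
                       interaction = NA_real_, lagEffect = 0) {
    type <- match.arg(type)
    if (type == "global" && !is.na(target))
        stop("a global variant targets the latent axis only; target must be NA")
    if (type == "local" && (length(target) != 1L || is.na(target)))
        stop("a local variant must target exactly one feature")
    if (type == "regional" && (length(target) != 1L || is.na(target)))
        stop("a regional variant must target one module")
    if (type != "global" && !is.na(partner))
        stop("epistatic partners are modeled on the latent axis (global only)")
    structure(list(marker = as.integer(marker), type = type,
                   effect = as.numeric(effect), target = target,
                   partner = as.integer(partner),
                   interaction = as.numeric(interaction),
                   lagEffect = as.numeric(lagEffect)),
              class = "PlantedQTL")
}

.defaultChromosomes <- function() {
    n <- c(rep(63L, 8L), rep(62L, 8L))  # 1,000 markers over 16 chromosomes
    data.frame(name = sprintf("chr%02d", 1:16), nMarkers = n, recomb = 0.02)
}

.markerOffsets <- function(chromosomes) {
    c(0L, cumsum(chromosomes$nMarkers))
}

.defaultPlantedQTL <- function(chromosomes, nProteins, nNodes, nModules) {
    off <- .markerOffsets(chromosomes)
    nChr <- nrow(chromosomes)
    # five loci spread over the genome; distinct chromosomes when available,
    # distinct within-chromosome positions otherwise
    chrPick <- round(seq(1, nChr, length.out = 5L))
    at <- integer(5L)
    for (i in seq_len(5L)) {
        chr <- chrPick[i]
        frac <- (sum(chrPick[seq_len(i)] == chr) * 2 - 1) /
            (2 * sum(chrPick == chr))
        at[i] <- off[chr] + max(1L, ceiling(frac * chromosomes$nMarkers[chr]))
    }
    localTarget <- sprintf("P%04d", if (nProteins > nNodes)
        nNodes + ceiling(0.75 * (nProteins - nNodes)) else nProteins)
    # Three latent-axis variants mirroring the reported PT-score architecture:
    # direct effects +0.21 / +1.14 / -1.41 with product terms +0.89 and -0.90
    # on the strongest locus, reproducing conditional effects of ~+1.10 vs
    # +0.21 and +1.14 vs +0.24 depending on the third locus' allele.
    list(
        plantedQTL(at[3L], "global", effect = 0.21,
                   partner = at[5L], interaction = 0.89),
        plantedQTL(at[4L], "global", effect = 1.14,
                   partner = at[5L], interaction = -0.90),
        plantedQTL(at[5L], "global", effect = -1.41),
        plantedQTL(at[2L], "regional", effect = 1.0,
                   target = min(2L, nModules)),
        plantedQTL(at[1L], "local", effect = 1.5, target = localTarget,
                   lagEffect = 25)
    )
}

#' Configuration of the synthetic segregant study
#'
#' Bundles every parameter of the synthetic multi-omics cross: genome layout,
#' planted causal variants, latent-state and feature noise, the
#' planted-partition interaction network, kinase-inhibition profiles, and
#' Richards-shaped growth curves.  Defaults describe a desk-scale haploid
#' cross of 100 strains, 1,000 markers on 16 chromosomes, 2,000 protein
#' features and a 300-node network.
#'
#' @param nStrains number of segregant strains.
#' @param chromosomes data.frame with columns \code{name}, \code{nMarkers},
#'   \code{recomb} (per-interval switch probability in (0, 0.5]).
#' @param nFeatures named counts per layer (transcript, protein,
#'   phosphopeptide).
#' @param plantedQTL list of [plantedQTL()] specifications.
#' @param latentNoiseSD SD of the non-genetic component of the latent state.
#' @param featureNoiseSD SD of per-feature measurement noise.
#' @param baselineSD SD of per-feature baseline abundance offsets
#'   (log-intensity units); real proteome intensities differ far more
#'   between proteins than between strains, and abundance matching relies on
#'   that spread.
#' @param moduleActivitySD SD of the shared per-module activity component
#'   (drives state-independent co-expression within modules).
#' @param fracGlobal fraction of features per layer loading on the latent axis.
#' @param loadingScale absolute loading of axis-responsive features.
#' @param peripheralBias if TRUE, axis-responsive network proteins are sampled
#'   with inverse-degree weights (state programs sit at the network periphery,
#'   so their targets lie farther apart than uniform random samples).
#' @param network list: \code{nNodes}, \code{nModules}, \code{pWithin},
#'   \code{pBetween}.
#' @param inhibition list: treatment labels, per-treatment scales, effect
#'   noise SD, decoy fraction (sign-inconsistent injected features).
#' @param phospho list: \code{frac} of peptides with a state-driven
#'   phosphorylation component and its \code{loading}.
#' @param growth list of growth-curve parameters (Richards A, mu, nu, mock
#'   lag, baseline heat-induced lag, latent coefficient, noise SDs, time grid,
#'   replicate count).
#' @param missingRate fraction of abundance cells set missing uniformly.
#' @param seed integer seed driving all stages.
#' @return a validated list of class \code{"SimConfig"}.
#' @export
simConfig <- function(nStrains = 100L,
                      chromosomes = .defaultChromosomes(),
                      nFeatures = c(transcript = 1000L, protein = 2000L,
                                    phosphopeptide = 500L),
                      plantedQTL = NULL,
                      latentNoiseSD = 0.5,
                      featureNoiseSD = 0.5,
                      baselineSD = 2,
                      moduleActivitySD = 0.7,
                      fracGlobal = 0.25,
                      loadingScale = 1,
                      peripheralBias = TRUE,
                      network = list(nNodes = 300L, nModules = 6L,
                                     pWithin = 0.2, pBetween = 0.01),
                      inhibition = list(
                          treatments = c("PKA_20", "PKA_150", "TOR_20", "TOR_150"),
                          scales = c(1, 0.8, 0.9, 0.7),
                          noiseSD = 0.2, decoyFrac = 0.02),
                      phospho = list(frac = 0.3, loading = 0.8),
                      growth = list(lambdaMock = 60, lagBase = 40,
                                    lagStateCoef = 12, lagNoiseSD = 6,
                                    odNoiseSD = 0.005, A = 1.2, mu = 0.008,
                                    nu = 1, times = seq(0, 1800, by = 15),
                                    nReplicates = 1L),
                      missingRate = 0,
                      seed = 1L) {
    if (is.null(plantedQTL))
        plantedQTL <- .defaultPlantedQTL(chromosomes,
                                         nFeatures[["protein"]],
                                         network$nNodes, network$nModules)
    cfg <- structure(as.list(environment()), class = "SimConfig")
    validateSimConfig(cfg)
    cfg
}

#' Validate a SimConfig
#'
#' @param cfg a \code{"SimConfig"} list.
#' @return invisibly TRUE; stops with a configuration error otherwise.
#' @export
validateSimConfig <- function(cfg) {
    stopifnot(inherits(cfg, "SimConfig"))
    ch <- cfg$chromosomes
    if (!all(c("name", "nMarkers", "recomb") %in% names(ch)))
        stop("chromosomes must have columns name, nMarkers, recomb")
    if (any(ch$recomb <= 0 | ch$recomb > 0.5))
        stop("recombination probabilities must lie in (0, 0.5]")
    if (any(ch$nMarkers < 1L) || cfg$nStrains < 2L || any(cfg$nFeatures < 1L))
        stop("all counts must be positive (>= 2 strains)")
    nw <- cfg$network
    if (nw$nModules < 1L)
        stop("n_modules must be >= 1")
    if (any(c(nw$pWithin, nw$pBetween) < 0) || any(c(nw$pWithin, nw$pBetween) > 1))
        stop("edge probabilities must lie in [0, 1]")
    nTotal <- sum(ch$nMarkers)
    for (q in cfg$plantedQTL) {
        if (q$marker < 1L || q$marker > nTotal)
            stop("planted QTL marker index out of range")
        if (!is.na(q$partner) && (q$partner < 1L || q$partner > nTotal))
            stop("epistatic partner marker index out of range")
        if (q$type == "regional" && (q$target < 1L || q$target > nw$nModules))
            stop("regional target module out of range")
    }
    if (cfg$missingRate < 0 || cfg$missingRate >= 1)
        stop("missingRate must lie in [0, 1)")
    invisible(TRUE)
}

.strainIDs <- function(n) sprintf("S%03d", seq_len(n))
.proteinIDs <- function(n) sprintf("P%04d", seq_len(n))
.transcriptIDs <- function(n) sprintf("T%04d", seq_len(n))
.peptideIDs <- function(n) sprintf("pp%04d", seq_len(n))

#' Simulate a haploid biallelic cross
#'
#' Generates genome-ordered allele calls as a per-chromosome two-state Markov
#' chain: the first marker of each chromosome is Bernoulli(1/2) and every
#' subsequent marker switches parent with the chromosome's recombination
#' probability, producing the block linkage-disequilibrium structure of a
#' meiotic cross.
#'
#' @param cfg a [simConfig()] object.
#' @param seed integer; defaults to the config seed.
#' @return a [GenotypeMatrix-class] (no missing calls).
#' @export
simulateCross <- function(cfg, seed = cfg$seed) {
    validateSimConfig(cfg)
    set.seed(seed + .SEED_CROSS)
    n <- cfg$nStrains
    ch <- cfg$chromosomes
    blocks <- vector("list", nrow(ch))
    for (i in seq_len(nrow(ch))) {
        m <- ch$nMarkers[i]
        r <- ch$recomb[i]
        x <- matrix(NA_integer_, nrow = m, ncol = n)
        x[1L, ] <- stats::rbinom(n, 1L, 0.5)
        if (m > 1L) {
            sw <- matrix(stats::runif((m - 1L) * n) < r, nrow = m - 1L)
            for (k in 2:m)
                x[k, ] <- ifelse(sw[k - 1L, ], 1L - x[k - 1L, ], x[k - 1L, ])
        }
        rownames(x) <- sprintf("%s_m%03d", ch$name[i], seq_len(m))
        blocks[[i]] <- x
    }
    alleles <- do.call(rbind, blocks)
    colnames(alleles) <- .strainIDs(n)
    chromosome <- rep(ch$name, ch$nMarkers)
    position <- unlist(lapply(ch$nMarkers, function(m) seq_len(m) * 12000L),
                       use.names = FALSE)
    GenotypeMatrix(alleles, chromosome, position)
}

#' Simulate a modular protein-interaction network
#'
#' Planted-partition model: nodes are split into contiguous modules; each pair
#' of nodes is linked independently with the within- or between-module edge
#' probability.  Node IDs coincide with the first protein feature IDs so that
#' network analyses map directly onto the simulated proteome.
#'
#' @param cfg a [simConfig()] object.
#' @param seed integer; defaults to the config seed.
#' @return list with elements \code{graph} (an [InteractionGraph-class]) and
#'   \code{moduleAssignment} (named integer vector, node -> module).
#' @export
simulateNetwork <- function(cfg, seed = cfg$seed) {
    validateSimConfig(cfg)
    set.seed(seed + .SEED_NETWORK)
    nw <- cfg$network
    n <- nw$nNodes
    ids <- .proteinIDs(n)
    module <- rep(seq_len(nw$nModules),
                  each = ceiling(n / nw$nModules))[seq_len(n)]
    names(module) <- ids
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    same <- module[idx[, 1L]] == module[idx[, 2L]]
    p <- ifelse(same, nw$pWithin, nw$pBetween)
    keep <- stats::runif(nrow(idx)) < p
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    igraph::V(g)$name <- ids
    if (any(keep))
        g <- igraph::add_edges(g, rbind(idx[keep, 1L], idx[keep, 2L]))
    g <- igraph::simplify(g)
    graph <- new("InteractionGraph", graph = g, scoreMin = NA_real_,
                 dropped = integer(0))
    list(graph = graph, moduleAssignment = module)
}

#' Simulate multi-omics abundance layers with planted ground truth
#'
#' The latent state of strain i is the genetic sum over planted global
#' variants (plus epistatic product terms) and Gaussian noise.  Feature f of
#' strain i is \code{loading_f * state_i + moduleActivity + regional and local
#' genotype effects + noise}.  Phosphopeptides are generated as their host
#' protein's value plus an independent state-driven phosphorylation component,
#' so protein-corrected residuals retain signal.
#'
#' @param genotypes a [GenotypeMatrix-class] from [simulateCross()].
#' @param networkModules named integer vector (node -> module) from
#'   [simulateNetwork()], or a list with a \code{moduleAssignment} element.
#' @param cfg a [simConfig()] object.
#' @param seed integer; defaults to the config seed.
#' @return list with \code{layers} (named list of [AbundanceMatrix-class]:
#'   transcript, protein, phosphopeptide) and \code{truth} (class
#'   \code{"SimTruth"}): latent state, per-feature loadings, module
#'   assignment, realized planted-QTL table, peptide-host map, phospho
#'   loadings.
#' @export
simulateOmics <- function(genotypes, networkModules, cfg, seed = cfg$seed) {
    validateSimConfig(cfg)
    if (is.list(networkModules) && !is.null(networkModules$moduleAssignment)) {
        graphObj <- networkModules$graph
        networkModules <- networkModules$moduleAssignment
    } else graphObj <- NULL
    set.seed(seed + .SEED_OMICS)
    g <- alleleMatrix(genotypes)
    n <- nrow(g)
    nTotal <- ncol(g)
    strains <- rownames(g)

    for (q in cfg$plantedQTL)
        if (q$marker > nTotal) stop("planted QTL marker index out of range")

    # latent state
    s <- stats::rnorm(n, 0, cfg$latentNoiseSD)
    for (q in cfg$plantedQTL) {
        if (q$type != "global") next
        s <- s + q$effect * g[, q$marker]
        if (!is.na(q$partner))
            s <- s + q$interaction * g[, q$marker] * g[, q$partner]
    }
    names(s) <- strains

    nProt <- cfg$nFeatures[["protein"]]
    prot <- .proteinIDs(nProt)
    moduleOf <- rep(NA_integer_, nProt)
    names(moduleOf) <- prot
    inNet <- intersect(prot, names(networkModules))
    moduleOf[inNet] <- networkModules[inNet]

    localTargets <- vapply(
        Filter(function(q) q$type == "local", cfg$plantedQTL),
        function(q) as.character(q$target), character(1))
    if (!all(localTargets %in% prot))
        stop("local planted-QTL targets must be protein feature IDs")

    # axis-responsive ("global") features, peripheral-biased inside the network
    pool <- setdiff(prot, localTargets)
    w <- rep(1, length(pool))
    if (isTRUE(cfg$peripheralBias) && !is.null(graphObj)) {
        deg <- igraph::degree(interactionGraph(graphObj))
        net <- pool %in% names(deg)
        wNet <- 1 / (1 + deg[pool[net]])^2
        w[net] <- wNet / mean(wNet)
    }
    nGlobal <- round(cfg$fracGlobal * nProt)
    globalFeatures <- sample(pool, nGlobal, prob = w)
    loadings <- stats::setNames(rep(0, nProt), prot)
    signs <- rep(c(1, -1), length.out = nGlobal)[sample.int(nGlobal)]
    loadings[globalFeatures] <- signs * cfg$loadingScale

    nMod <- cfg$network$nModules
    modAct <- matrix(stats::rnorm(nMod * n, 0, cfg$moduleActivitySD),
                     nrow = nMod)

    X <- outer(loadings, s)
    hasMod <- !is.na(moduleOf)
    X[hasMod, ] <- X[hasMod, ] + modAct[moduleOf[hasMod], , drop = FALSE]
    for (q in cfg$plantedQTL) {
        if (q$type == "regional") {
            members <- names(moduleOf)[!is.na(moduleOf) & moduleOf == q$target]
            X[members, ] <- X[members, ] +
                matrix(q$effect * g[, q$marker], nrow = length(members),
                       ncol = n, byrow = TRUE)
        } else if (q$type == "local") {
            X[as.character(q$target), ] <-
                X[as.character(q$target), ] + q$effect * g[, q$marker]
        }
    }
    X <- X + matrix(stats::rnorm(nProt * n, 0, cfg$featureNoiseSD), nrow = nProt)
    X <- X + stats::rnorm(nProt, 0, cfg$baselineSD)  # per-protein baseline
    colnames(X) <- strains

    # transcript layer: its own axis-responsive subset, no network structure
    nTx <- cfg$nFeatures[["transcript"]]
    tx <- .transcriptIDs(nTx)
    txGlobal <- sample(tx, round(cfg$fracGlobal * nTx))
    txLoad <- stats::setNames(rep(0, nTx), tx)
    txLoad[txGlobal] <- rep(c(1, -1), length.out = length(txGlobal)) *
        cfg$loadingScale
    Tx <- outer(txLoad, s) +
        matrix(stats::rnorm(nTx * n, 0, cfg$featureNoiseSD), nrow = nTx) +
        stats::rnorm(nTx, 0, cfg$baselineSD)
    colnames(Tx) <- strains

    # phosphopeptide layer: host protein value + independent phospho component
    nPep <- cfg$nFeatures[["phosphopeptide"]]
    pep <- .peptideIDs(nPep)
    host <- stats::setNames(sample(prot, nPep, replace = TRUE), pep)
    phosLoad <- stats::setNames(rep(0, nPep), pep)
    nPhos <- round(cfg$phospho$frac * nPep)
    phosIdx <- sample(pep, nPhos)
    phosLoad[phosIdx] <- rep(c(1, -1), length.out = nPhos) * cfg$phospho$loading
    Pep <- X[host, , drop = FALSE] + outer(phosLoad, s) +
        matrix(stats::rnorm(nPep * n, 0, cfg$featureNoiseSD), nrow = nPep)
    rownames(Pep) <- pep

    layers <- list(
        transcript = .injectMissing(Tx, cfg$missingRate),
        protein = .injectMissing(X, cfg$missingRate),
        phosphopeptide = .injectMissing(Pep, cfg$missingRate))
    layers <- Map(function(v, l) AbundanceMatrix(v, layer = l),
                  layers, names(layers))

    mi <- markerInfo(genotypes)
    qtlTab <- do.call(rbind, lapply(cfg$plantedQTL, function(q) {
        data.frame(marker = mi$marker[q$marker], markerIndex = q$marker,
                   chromosome = mi$chromosome[q$marker], type = q$type,
                   effect = q$effect, target = as.character(q$target),
                   partner = if (is.na(q$partner)) NA_character_ else
                       mi$marker[q$partner],
                   interaction = q$interaction, lagEffect = q$lagEffect,
                   stringsAsFactors = FALSE)
    }))

    truth <- structure(list(
        latentState = s,
        featureLoadings = loadings,
        transcriptLoadings = txLoad,
        moduleAssignment = moduleOf,
        globalFeatures = globalFeatures,
        qtl = qtlTab,
        peptideHost = host,
        phosphoLoadings = phosLoad), class = "SimTruth")
    list(layers = layers, truth = truth)
}

.injectMissing <- function(x, rate) {
    if (rate <= 0) return(x)
    x[sample(length(x), round(rate * length(x)))] <- NA_real_
    x
}

#' Simulate kinase-inhibition effect profiles
#'
#' Produces a feature x treatment effect matrix for two pathways at two time
#' points.  Inhibition reverses the state program: the effect of every
#' treatment on feature f is proportional to minus its latent-axis loading,
#' plus noise; features with zero loading receive pure noise.  A configurable
#' fraction of sign-inconsistent decoy features (strong effects with opposite
#' sign in one treatment) is injected and recorded.
#'
#' @param truth a \code{"SimTruth"} object from [simulateOmics()].
#' @param cfg a [simConfig()] object.
#' @param seed integer; defaults to the config seed.
#' @return list of class \code{"InhibitionProfile"}: \code{effects} (matrix),
#'   \code{treatments}, \code{decoys} (injected inconsistent feature IDs).
#' @export
simulateInhibitionProfiles <- function(truth, cfg, seed = cfg$seed) {
    stopifnot(inherits(truth, "SimTruth"))
    set.seed(seed + .SEED_INHIBITION)
    inh <- cfg$inhibition
    load <- truth$featureLoadings
    E <- -outer(load, inh$scales) +
        matrix(stats::rnorm(length(load) * length(inh$scales), 0, inh$noiseSD),
               nrow = length(load))
    dimnames(E) <- list(names(load), inh$treatments)
    zeroLoad <- names(load)[load == 0]
    nDecoy <- round(inh$decoyFrac * length(zeroLoad))
    decoys <- if (nDecoy > 0) sample(zeroLoad, nDecoy) else character(0)
    if (nDecoy > 0) {
        colSD <- apply(E, 2L, stats::sd)
        k <- ncol(E)
        E[decoys, seq_len(k - 1L)] <-
            matrix(3 * colSD[seq_len(k - 1L)], nrow = nDecoy, ncol = k - 1L,
                   byrow = TRUE)
        E[decoys, k] <- -3 * colSD[k]
    }
    structure(list(effects = E, treatments = inh$treatments, decoys = decoys),
              class = "InhibitionProfile")
}

#' Wrap a user effect matrix as an InhibitionProfile
#'
#' @param effects numeric matrix, features x treatments, with dimnames.
#' @return an \code{"InhibitionProfile"} list.
#' @export
inhibitionProfile <- function(effects) {
    effects <- as.matrix(effects)
    if (is.null(colnames(effects)) || ncol(effects) < 1L)
        stop("effects must have >= 1 named treatment column")
    if (any(!is.finite(effects)))
        stop("effects must be finite")
    structure(list(effects = effects, treatments = colnames(effects),
                   decoys = character(0)),
              class = "InhibitionProfile")
}

#' Richards growth curve
#'
#' Generalized-logistic form with asymptote \code{A}, maximum slope \code{mu},
#' lag \code{lambda} (intercept of the inflection tangent with the baseline)
#' and shape \code{nu}.
#'
#' @param t time (minutes).
#' @param A asymptotic OD.
#' @param mu maximum slope (OD/min).
#' @param lambda lag time (min).
#' @param nu shape parameter (1 = logistic).
#' @return OD values.
#' @export
richardsCurve <- function(t, A, mu, lambda, nu) {
    A * (1 + nu * exp(1 + nu) *
             exp((mu / A) * (1 + nu)^(1 + 1 / nu) * (lambda - t)))^(-1 / nu)
}

#' Simulate growth-curve panels with a genotype- and state-dependent lag
#'
#' Heat-stressed and mock-treated Richards curves per strain.  The true
#' heat-induced lag of a strain is \code{lagBase + sum(lagEffect_q * g) +
#' lagStateCoef * latentState}; replicate curves add lag noise
#' (\code{lagNoiseSD}) and OD noise.
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param truth a \code{"SimTruth"} object.
#' @param cfg a [simConfig()] object.
#' @param seed integer; defaults to the config seed.
#' @return list: \code{curves} (long data.frame strain / condition /
#'   replicate / time_min / od), \code{trueLag} (named numeric, minutes),
#'   \code{lambdaMock}, \code{lambdaHS}.
#' @export
simulateGrowth <- function(genotypes, truth, cfg, seed = cfg$seed) {
    stopifnot(inherits(truth, "SimTruth"))
    set.seed(seed + .SEED_GROWTH)
    gp <- cfg$growth
    g <- alleleMatrix(genotypes)
    strains <- rownames(g)
    hilag <- rep(gp$lagBase, length(strains))
    for (q in cfg$plantedQTL)
        if (q$lagEffect != 0) hilag <- hilag + q$lagEffect * g[, q$marker]
    hilag <- hilag + gp$lagStateCoef * truth$latentState[strains]
    names(hilag) <- strains
    lambdaMock <- stats::setNames(rep(gp$lambdaMock, length(strains)), strains)
    lambdaHS <- lambdaMock + hilag

    nrep <- gp$nReplicates
    grid <- expand.grid(strain = strains, condition = c("mock", "heat"),
                        replicate = seq_len(nrep), stringsAsFactors = FALSE)
    rows <- vector("list", nrow(grid))
    for (i in seq_len(nrow(grid))) {
        st <- grid$strain[i]
        lam <- if (grid$condition[i] == "heat") lambdaHS[st] else lambdaMock[st]
        lam <- max(0, lam + stats::rnorm(1, 0, gp$lagNoiseSD))
        od <- richardsCurve(gp$times, gp$A, gp$mu, lam, gp$nu) +
            stats::rnorm(length(gp$times), 0, gp$odNoiseSD)
        rows[[i]] <- data.frame(strain = st, condition = grid$condition[i],
                                replicate = grid$replicate[i],
                                time_min = gp$times, od = pmax(od, 0))
    }
    list(curves = do.call(rbind, rows), trueLag = hilag,
         lambdaMock = lambdaMock, lambdaHS = lambdaHS)
}

#' Run every generator stage from one config
#'
#' @param cfg a [simConfig()] object.
#' @param growth if FALSE, skip the growth-curve panel (the slowest stage).
#' @return list: genotypes, network, layers, truth, inhibition, growth.
#' @export
simulateStudy <- function(cfg, growth = TRUE) {
    genotypes <- simulateCross(cfg)
    net <- simulateNetwork(cfg)
    om <- simulateOmics(genotypes, net, cfg)
    inh <- simulateInhibitionProfiles(om$truth, cfg)
    gr <- if (growth) simulateGrowth(genotypes, om$truth, cfg) else NULL
    list(genotypes = genotypes, network = net, layers = om$layers,
         truth = om$truth, inhibition = inh, growth = gr)
}
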