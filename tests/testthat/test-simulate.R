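test_that("configuration errors are caught", {
    expect_error(simConfig(chromosomes = data.frame(name = "c1",
                                                    nMarkers = 10L,
                                                    recomb = 0.6)),
                 "recombination")
    expect_error(simConfig(network = list(nNodes = 10L, nModules = 0L,
                                          pWithin = 0.5, pBetween = 0)),
                 "n_modules")
    expect_error(simConfig(network = list(nNodes = 10L, nModules = 2L,
                                          pWithin = 1.5, pBetween = 0)),
                 "edge probabilities")
    cfg <- smallCfg()
    bad <- cfg
    bad$plantedQTL[[1]]$marker <- 10000L
    expect_error(validateSimConfig(bad), "out of range")
})

test_that("simulated cross is deterministic and Markov-LD structured", {
    cfg <- smallCfg(seed = 11L)
    g1 <- simulateCross(cfg)
    g2 <- simulateCross(cfg)
    expect_identical(alleleMatrix(g1), alleleMatrix(g2))  # bit-identical

    # free recombination: adjacent-marker LD vanishes
    cfgFree <- simConfig(
        nStrains = 10000L,
        chromosomes = data.frame(name = "chr01", nMarkers = 12L, recomb = 0.5),
        nFeatures = c(transcript = 5L, protein = 20L, phosphopeptide = 5L),
        network = list(nNodes = 10L, nModules = 1L, pWithin = 1, pBetween = 0),
        plantedQTL = list(plantedQTL(1L, "global", 1)), seed = 2L)
    a <- alleleMatrix(simulateCross(cfgFree))
    ld <- sapply(2:12, function(i) cor(a[, i - 1], a[, i])^2)
    expect_lt(mean(ld), 0.01)

    # tight linkage: LD decays with marker distance (Markov correlation decay)
    cfgTight <- cfgFree
    cfgTight$chromosomes$recomb <- 0.01
    cfgTight$nStrains <- 1000L
    b <- alleleMatrix(simulateCross(cfgTight))
    ldAdj <- mean(sapply(2:12, function(i) cor(b[, i - 1], b[, i])^2))
    ld10 <- mean(sapply(11:12, function(i) cor(b[, i - 10], b[, i])^2))
    expect_gt(ldAdj, ld10)
    # theoretical adjacent correlation is (1 - 2r)
    expect_equal(ldAdj, (1 - 2 * 0.01)^2, tolerance = 0.05)

    # allele-frequency binomial bound holds for >= 99% of markers
    st <- smallStudy()
    af <- colMeans(alleleMatrix(st$genotypes))
    n <- nrow(alleleMatrix(st$genotypes))
    expect_gte(mean(abs(af - 0.5) <= 3 * sqrt(0.25 / n)), 0.99)
})

test_that("planted-partition network matches its module structure", {
    netCfg <- function(nw) simConfig(
        nStrains = 20L,
        chromosomes = data.frame(name = "chr01", nMarkers = 10L,
                                 recomb = 0.1),
        nFeatures = c(transcript = 10L, protein = 30L, phosphopeptide = 5L),
        network = nw, plantedQTL = list(plantedQTL(1L, "global", 1)),
        seed = 5L)
    cfg <- netCfg(list(nNodes = 20L, nModules = 4L, pWithin = 1,
                       pBetween = 0))
    net <- simulateNetwork(cfg)
    g <- interactionGraph(net$graph)
    expect_equal(igraph::count_components(g), 4L)
    expect_true(all(igraph::degree(g) == 4L))  # 5-cliques

    net2 <- simulateNetwork(netCfg(list(nNodes = 200L, nModules = 5L,
                                        pWithin = 0.5, pBetween = 0.01)))
    D <- igraph::distances(interactionGraph(net2$graph))
    mod <- net2$moduleAssignment
    same <- outer(mod, mod, `==`)
    ut <- upper.tri(D)
    expect_lt(mean(D[ut & same][is.finite(D[ut & same])]),
              mean(D[ut & !same][is.finite(D[ut & !same])]))

    net3 <- simulateNetwork(netCfg(list(nNodes = 10L, nModules = 1L,
                                        pWithin = 1, pBetween = 0)))
    D3 <- igraph::distances(interactionGraph(net3$graph))
    expect_true(all(D3[upper.tri(D3)] == 1))
})

test_that("omics generator realizes the planted effect structure", {
    # all effects and noises zero -> all features exactly 0
    cfg0 <- smallCfg()
    cfg0$latentNoiseSD <- 0; cfg0$featureNoiseSD <- 0
    cfg0$moduleActivitySD <- 0; cfg0$fracGlobal <- 0
    cfg0$phospho$frac <- 0; cfg0$baselineSD <- 0
    cfg0$plantedQTL <- list(plantedQTL(1L, "global", 0))
    om0 <- simulateOmics(simulateCross(cfg0), simulateNetwork(cfg0), cfg0)
    expect_true(all(abundanceValues(om0$layers$protein) == 0))
    expect_true(all(om0$truth$latentState == 0))

    # one strong global QTL: genotype-latent correlation is high
    cfg1 <- smallCfg(seed = 3L)
    cfg1$nStrains <- 100L
    cfg1$latentNoiseSD <- 0.1; cfg1$featureNoiseSD <- 0.1
    cfg1$plantedQTL <- list(plantedQTL(10L, "global", 2))
    om1 <- simulateOmics(simulateCross(cfg1), simulateNetwork(cfg1), cfg1)
    gg <- alleleMatrix(simulateCross(cfg1))[, 10L]
    expect_gt(cor(om1$truth$latentState, gg), 0.9)

    # local QTL touches only its target among unloaded, module-free features
    st <- smallStudy()
    truth <- st$truth
    localRow <- truth$qtl[truth$qtl$type == "local", ]
    g <- alleleMatrix(st$genotypes)[, localRow$marker]
    v <- abundanceValues(st$layers$protein)
    plain <- names(truth$featureLoadings)[
        truth$featureLoadings == 0 & is.na(truth$moduleAssignment)]
    rs <- abs(as.numeric(cor(t(v[plain, , drop = FALSE]), g)))
    names(rs) <- plain
    expect_gt(rs[localRow$target], 0.5)
    expect_true(all(rs[setdiff(plain, localRow$target)] <= 0.5))

    # zero-effect features stay uncorrelated with markers (null bound)
    G <- alleleMatrix(st$genotypes)
    others <- setdiff(plain, localRow$target)
    cc <- abs(cor(t(v[others, , drop = FALSE]), G[, seq(1, 160, by = 8)]))
    expect_lt(mean(cc > 3 / sqrt(nrow(G))), 0.05)
})

test_that("inhibition profiles follow the sign convention and log decoys", {
    st <- smallStudy()
    cfg <- smallCfg()
    E <- st$inhibition$effects
    load <- st$truth$featureLoadings
    induced <- names(load)[load > 0]
    # inhibition reduces induced features: effects mostly negative
    expect_gt(mean(E[induced, ] < 0), 0.95)

    # zero loadings + zero decoys -> pure noise, ~95% within 2 z-units
    cfgN <- smallCfg(seed = 8L)
    cfgN$fracGlobal <- 0
    cfgN$inhibition$decoyFrac <- 0
    omN <- simulateOmics(simulateCross(cfgN), simulateNetwork(cfgN), cfgN)
    ipN <- simulateInhibitionProfiles(omN$truth, cfgN)
    z <- sweep(ipN$effects, 2, apply(ipN$effects, 2, sd), `/`)
    expect_equal(mean(abs(z) < 2), 0.95, tolerance = 0.03)

    # noiseless profile: all treatment effects strictly negative for loading +1
    cfg0 <- smallCfg(seed = 9L)
    cfg0$inhibition$noiseSD <- 0
    cfg0$inhibition$decoyFrac <- 0
    om0 <- simulateOmics(simulateCross(cfg0), simulateNetwork(cfg0), cfg0)
    ip0 <- simulateInhibitionProfiles(om0$truth, cfg0)
    pos <- names(om0$truth$featureLoadings)[om0$truth$featureLoadings > 0]
    expect_true(all(ip0$effects[pos, ] < 0))

    # injected decoys are recorded and sign-inconsistent
    expect_true(length(st$inhibition$decoys) > 0)
    dz <- E[st$inhibition$decoys, , drop = FALSE]
    expect_true(all(apply(sign(dz), 1, function(s) length(unique(s)) > 1)))
})

test_that("growth panel encodes the planted lag structure", {
    cfg <- smallCfg(seed = 4L)
    cfg$growth$lagNoiseSD <- 0
    cfg$growth$odNoiseSD <- 0
    cfg$growth$lagStateCoef <- 0
    st <- simulateStudy(cfg, growth = TRUE)
    qtl <- st$truth$qtl
    localMarker <- qtl$marker[qtl$type == "local"]
    g <- alleleMatrix(st$genotypes)[, localMarker]
    lag <- st$growth$trueLag
    # the planted 25-min lag allele shifts group means by exactly 25
    expect_equal(mean(lag[g == 1]) - mean(lag[g == 0]), 25, tolerance = 1e-9)

    # all effects zero -> identical lag everywhere
    cfg0 <- cfg
    cfg0$plantedQTL <- list(plantedQTL(1L, "global", 0))
    st0 <- simulateStudy(cfg0, growth = TRUE)
    expect_equal(diff(range(st0$growth$trueLag)), 0)

    # curves approach the asymptote A
    late <- subset(st$growth$curves, time_min == max(time_min))
    expect_true(all(abs(late$od - cfg$growth$A) < 0.02))
})

test_that("the whole study is bit-identical under a fixed seed", {
    cfg <- smallCfg(seed = 21L)
    s1 <- simulateStudy(cfg, growth = TRUE)
    s2 <- simulateStudy(cfg, growth = TRUE)
    expect_identical(alleleMatrix(s1$genotypes), alleleMatrix(s2$genotypes))
    expect_identical(abundanceValues(s1$layers$protein),
                     abundanceValues(s2$layers$protein))
    expect_identical(s1$inhibition$effects, s2$inhibition$effects)
    expect_identical(s1$growth$curves$od, s2$growth$curves$od)
    expect_identical(s1$truth$latentState, s2$truth$latentState)
})
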