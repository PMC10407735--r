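edgeList <- function(a, b, s) {
    structure(data.frame(proteinA = a, proteinB = b, score = s,
                         selfEdge = a == b, stringsAsFactors = FALSE),
              class = c("EdgeList", "data.frame"))
}

test_that("graph construction thresholds strictly and simplifies", {
    e <- edgeList(c("A", "A", "B", "A", "C"), c("B", "B", "A", "A", "D"),
                  c(0.5, 0.7, 0.9, 0.9, 0.400))
    g <- buildGraph(e, scoreMin = 0.400)
    gg <- interactionGraph(g)
    # duplicate/multi A-B edges collapse to one; self-edge removed;
    # the exactly-0.400 edge is dropped (strict inequality)
    expect_equal(igraph::ecount(gg), 1L)
    expect_setequal(igraph::V(gg)$name, c("A", "B"))
    expect_gte(g@dropped["selfLoops"], 1)
    expect_gte(g@dropped["belowThreshold"], 1)
    expect_error(buildGraph(edgeList("A", "B", 0.1)), "no edges")
})

test_that("pairwise distances match hand cases and impute unreachable pairs", {
    tri <- buildGraph(edgeList(c("A", "B", "C"), c("B", "C", "A"),
                               rep(0.9, 3)))
    d <- pairwiseDistances(tri, c("A", "B", "C"))
    expect_equal(d$distances, c(1, 1, 1))
    expect_equal(d$mean, 1)

    path <- buildGraph(edgeList(c("A", "B", "C"), c("B", "C", "D"),
                                rep(0.9, 3)))
    expect_equal(pairwiseDistances(path, c("A", "D"))$distances, 3)

    # isolated node: pairs imputed at the set's max finite distance
    iso <- buildGraph(edgeList(c("A", "B", "C", "X"), c("B", "C", "D", "Y"),
                               rep(0.9, 4)))
    d2 <- pairwiseDistances(iso, c("A", "B", "C", "D", "X"))
    expect_equal(d2$nUnreachable, 4L)       # X vs each of A,B,C,D
    expect_equal(d2$imputedDistance, 3)     # max finite = d(A,D)
    expect_equal(sum(d2$distances == 3), 1 + 4)
    expect_true(all(d2$distances >= 1))

    expect_error(pairwiseDistances(tri, c("A", "zz")), "fewer than 2")
})

test_that("shortest paths agree exactly with a Floyd-Warshall oracle", {
    for (k in 1:100) {
        rg <- randomIgraph(n = 10L + (k %% 21L), p = 0.15, seed = 1000L + k)
        D <- igraph::distances(rg$graph)
        expect_identical(unname(D), unname(fwDistances(rg$adj)))
    }
})

test_that("null envelopes are ordered, degenerate where expected, and match
           a same-seed brute-force oracle", {
    k5 <- t(combn(LETTERS[1:5], 2))
    comp <- buildGraph(edgeList(k5[, 1], k5[, 2], rep(0.9, nrow(k5))))
    env <- distanceNullEnvelope(comp, c(2L, 3L, 5L), nSamples = 50L, seed = 1L)
    expect_true(all(env$percentiles == 1))  # complete graph

    rg <- randomIgraph(30L, 0.12, seed = 77L)
    env2 <- distanceNullEnvelope(rg$graph, c(5L, 10L, 30L), nSamples = 200L,
                                 seed = 9L)
    p <- env2$percentiles
    expect_true(all(p[, "p05"] <= p[, "p50"] & p[, "p50"] <= p[, "p95"]))
    # full-size samples are all identical: degenerate envelope
    expect_equal(p["30", "p05"], p["30", "p95"])

    # oracle: replay the same seed stream with brute-force distances
    Dfw <- fwDistances(rg$adj)
    set.seed(9L)
    for (k in c(5L, 10L, 30L)) {
        means <- vapply(seq_len(200L), function(.)
            meanPairDistOracle(Dfw, sample.int(30L, k)), numeric(1))
        expect_equal(unname(env2$percentiles[as.character(k), ]),
                     unname(quantile(means, c(0.05, 0.5, 0.95))),
                     tolerance = 1e-12)
    }
})

test_that("the Poisson rate comparison equals the exact binomial tail", {
    mkDist <- function(d) structure(list(distances = d, mean = mean(d),
                                         nPairs = length(d),
                                         nUnreachable = 0L,
                                         imputedDistance = NA_real_,
                                         nodes = as.character(seq_along(d)),
                                         unmapped = character(0),
                                         label = "x"),
                                    class = "DistanceDistribution")
    v1 <- rep(3, 100); v1[1] <- 5                      # total 302
    v2 <- rep(3, 100); v2[1:24] <- 4; v2[25] <- 25     # total 346
    d1 <- mkDist(v1); d2 <- mkDist(v2)
    expect_equal(sum(d2$distances), 346)
    res <- compareDistancePoisson(d1, d2)
    expect_equal(res$p, binomOracle(302L, 648L, 0.5), tolerance = 1e-12)
    expect_equal(res$rateRatio, 3.02 / 3.46)

    same <- compareDistancePoisson(d1, d1)
    expect_equal(same$rateRatio, 1)
    expect_equal(same$p, 1)

    # doubling multiplicities: same ratio, smaller p
    d1b <- mkDist(rep(v1, 2)); d2b <- mkDist(rep(v2, 2))
    res2 <- compareDistancePoisson(d1b, d2b)
    expect_equal(res2$rateRatio, res$rateRatio)
    expect_lt(res2$p, res$p)
})

test_that("top-N distances find planted cliques and behave under null effects", {
    # one 10-clique plus background
    cl <- t(combn(paste0("C", 1:10), 2))
    bg <- cbind(paste0("B", 1:40), paste0("B", c(2:40, 1)))
    link <- cbind(paste0("B", 1:10), paste0("C", 1:10))
    e <- edgeList(c(cl[, 1], bg[, 1], link[, 1]),
                  c(cl[, 2], bg[, 2], link[, 2]),
                  rep(0.9, nrow(cl) + nrow(bg) + nrow(link)))
    g <- buildGraph(e)
    eff <- setNames(c(rep(10, 10), runif(40, 0, 1)),
                    c(paste0("C", 1:10), paste0("B", 1:40)))
    res <- topNDistance(g, eff, nList = c(10L, 20L), nSamples = 200L,
                        seed = 3L)
    expect_equal(res$meanDistance[res$N == 10], 1)   # the clique
    expect_identical(res$position[res$N == 10], "below_p05")

    # uniform random effects stay inside the envelope most of the time
    set.seed(11)
    inEnv <- replicate(20, {
        effN <- setNames(runif(50), c(paste0("C", 1:10), paste0("B", 1:40)))
        r <- topNDistance(g, effN, nList = 15L, nSamples = 200L, seed = 3L)
        r$position == "within"
    })
    expect_gte(mean(inEnv), 0.7)

    # N = 2 with the two top features adjacent
    eff2 <- setNames(c(5, 4, runif(48)), c("C1", "C2", paste0("B", 1:40),
                                           paste0("C", 3:10)))
    r2 <- topNDistance(g, eff2, nList = 2L, nSamples = 50L, seed = 3L)
    expect_equal(r2$meanDistance, 1)

    expect_error(topNDistance(g, eff[1:5], nList = 10L), "map")
})

test_that("consistency split follows the sign algebra", {
    eff <- c(f1 = 1, f2 = -1, f3 = 0.5, f4 = -2)
    assoc <- c(f1 = 0.8, f2 = 0.8, f3 = -0.6, f4 = -0.6)
    sp <- consistencySplit(eff, stateShift = 1, stateAssociation = assoc)
    # expected sign = sign(shift) * sign(assoc)
    expect_setequal(sp$consistent, c("f1", "f4"))
    expect_setequal(sp$inconsistent, c("f2", "f3"))
    sp2 <- consistencySplit(eff, stateShift = -1, stateAssociation = assoc)
    expect_setequal(sp2$consistent, c("f2", "f3"))
    expect_error(consistencySplit(eff, 0, assoc), "zero")
})

test_that("planted composite loci put inconsistent targets closer together", {
    # A regional+global composite locus: its primary effect raises one
    # module against that module's state expectation (negative loading,
    # positive allele effect), while a weaker secondary response moves the
    # dispersed state program with the state shift.  The state-inconsistent
    # targets are then the module (short mutual distances); the consistent
    # targets span the rest of the network.
    hits <- 0L
    for (k in 1:5) {
        cfg <- smallCfg(seed = 400L + k)
        net <- simulateNetwork(cfg)
        mods <- net$moduleAssignment
        g <- interactionGraph(net$graph)
        nodes <- names(mods)
        set.seed(500L + k)
        n <- 100L
        gA <- rbinom(n, 1, 0.5)                 # the composite locus
        s <- rnorm(n) + 0.3 * gA                # state, nudged by the locus
        strains <- paste0("X", seq_len(n))
        loading <- ifelse(mods == 3, -1,        # module 3: respiration-like
                          sample(c(1, -1), length(mods), replace = TRUE))
        names(loading) <- nodes
        v <- outer(loading, s) + matrix(rnorm(length(mods) * n, 0, 0.4),
                                        nrow = length(mods))
        # primary regional effect: +1.5 on module 3 (against its loading)
        v[mods == 3, ] <- v[mods == 3, ] +
            matrix(1.5 * gA, sum(mods == 3), n, byrow = TRUE)
        # secondary global response: weak state-consistent effect elsewhere
        v[mods != 3, ] <- v[mods != 3, ] +
            outer(0.4 * loading[mods != 3], gA)
        colnames(v) <- strains
        scores <- setNames(s, strains)
        eff <- setNames(as.numeric(v %*% (gA - mean(gA))) /
                        sum((gA - mean(gA))^2), nodes)
        sp <- consistencySplit(eff, stateShift = 0.3,
                               stateAssociation = loading)
        cs <- intersect(sp$consistent, nodes)
        ic <- intersect(sp$inconsistent, nodes)
        if (length(cs) < 2 || length(ic) < 2) next
        di <- pairwiseDistances(g, ic)$mean
        dc <- pairwiseDistances(g, cs)$mean
        hits <- hits + (di < dc)
    }
    expect_gte(hits, 4L)
})

test_that("spread classification follows its decision thresholds", {
    rg <- randomIgraph(40L, 0.2, seed = 5L)
    env <- distanceNullEnvelope(rg$graph, c(5L, 10L), nSamples = 200L,
                                seed = 2L)
    mkDist <- function(nodes, mean) structure(
        list(distances = rep(mean, 10), mean = mean, nPairs = 10,
             nUnreachable = 0L, imputedDistance = NA_real_, nodes = nodes,
             unmapped = character(0), label = "t"),
        class = "DistanceDistribution")
    p50 <- env$percentiles["10", "p50"]
    p95 <- env$percentiles["10", "p95"]

    expect_identical(classifySpread("L", nTargets = 2, dist = NULL,
                                    envelope = env, stateShiftP = 1)$label,
                     "local")
    nodes <- igraph::V(rg$graph)$name[1:10]
    expect_identical(classifySpread("R", 50, mkDist(nodes, p50 - 0.3), env,
                                    stateShiftP = 0.5)$label, "regional")
    expect_identical(classifySpread("G", 50, mkDist(nodes, p50 + 0.01), env,
                                    stateShiftP = 0.001)$label, "global")
    expect_identical(classifySpread("G2", 50, mkDist(nodes, p95 + 0.1), env,
                                    stateShiftP = 0.9)$label, "global")
    mixed <- classifySpread("M", 50, mkDist(nodes, p50 - 0.3), env,
                            stateShiftP = 0.001)
    expect_identical(mixed$label, "regional")
    expect_identical(mixed$note, "mixed")
    expect_error(classifySpread("X", nTargets = 50, dist = NULL,
                                envelope = env, stateShiftP = 0.5),
                 "required")
})

test_that("pair-state association matches the Fisher oracle and hand cases", {
    st <- smallStudy()
    sc <- computeStateScore(st$layers$protein,
                            deriveMarkerSets(st$inhibition))
    psa <- pairStateAssociation(st$layers$protein, sc, st$network$graph)
    # identical-feature logic: a pair of score-equal features has assoc 1
    expect_true(all(psa$binTable$fracAssociated >= 0 &
                    psa$binTable$fracAssociated <= 1))
    expect_equal(sum(psa$binTable$nPairs), psa$nPairs)
    expect_equal(psa$fisherP,
                 fisherOracle(psa$fisherTable), tolerance = 1e-10)

    # oracle equivalence on random 2x2 tables
    set.seed(12)
    for (k in 1:50) {
        tab <- matrix(rpois(4, 30) + 1L, 2)
        expect_equal(fisher.test(tab)$p.value, fisherOracle(tab),
                     tolerance = 1e-10)
    }

    # features equal to +/- the score give association exactly 1
    s <- as.numeric(sc)
    v <- rbind(A = s, B = s, C = -s)
    colnames(v) <- names(sc)
    g <- buildGraph(edgeList(c("A", "B"), c("B", "C"), c(0.9, 0.9)))
    psa2 <- pairStateAssociation(AbundanceMatrix(v, layer = "protein"), sc, g,
                                 rMin = 0.5)
    expect_equal(psa2$binTable$nAssociated[1], 2L)  # A-B and B-C at distance 1
    expect_equal(psa2$binTable$fracAssociated[1], 1)
})
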