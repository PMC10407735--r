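test_that("genotype QC drops, masks and imputes by the stated rules", {
    # 5 markers on one chromosome, 12 kb apart; 10 strains
    a <- matrix(rep(c(0L, 1L), each = 5 * 5), nrow = 5)
    colnames(a) <- paste0("S", 1:10)
    rownames(a) <- paste0("m", 1:5)
    # marker 4: minor allele in 1/10 strains -> MAF 0.1 kept at threshold;
    # make marker 5 MAF 0 -> dropped
    a[5, ] <- 0L
    # strain S1: singleton double-crossover at m2 (flanks agree)
    a[, "S1"] <- c(0L, 1L, 0L, 0L, 0L)
    # strain S2: missing call at m3, flanks m2/m4 identical patterns
    a[2, "S2"] <- a[4, "S2"] <- 1L
    a[3, "S2"] <- NA
    a[2, ] <- a[4, ]  # identical segregation of the flanks
    a[2, "S1"] <- 1L  # keep the singleton
    g <- GenotypeMatrix(a, rep("chr01", 5), (1:5) * 12000L)
    parents <- cbind(p0 = rep(0L, 5), p1 = rep(1L, 5))
    rownames(parents) <- rownames(a)
    qc <- genotypeQC(g, parents, mafMin = 0.10, missMax = 0.5,
                     window = 50000L)
    rep_ <- attr(qc, "qcReport")
    expect_gte(rep_["droppedMAF"], 1)           # monomorphic marker dropped
    expect_gte(rep_["maskedSingletons"], 1)     # S1 singleton masked
    aq <- t(alleleMatrix(qc))
    # the masked singleton is subsequently re-imputed from its agreeing
    # flanks: the final call is the flank allele, not the original 1
    expect_identical(aq["m2", "S1"], 0L)
    # the missing S2 call was imputed from the identical flanks
    expect_identical(aq["m3", "S2"], 1L)

    # parental-missing markers are dropped
    parents2 <- parents; parents2[1, 1] <- NA
    qc2 <- genotypeQC(g, parents2)
    expect_false("m1" %in% rownames(t(alleleMatrix(qc2))))
})

test_that("allele effects carry the second-parent sign convention", {
    g <- tinyGenotypes()
    v <- setNames(c(1, 2, 1, 2, 1, 2), paste0("S", 1:6))
    ae <- alleleEffect(g, "m1", v)  # allele 1 strains have value 2
    expect_equal(ae$difference, 1)
    expect_lt(ae$p, 0.05)

    v2 <- setNames(rep(1, 6), paste0("S", 1:6))
    ae2 <- alleleEffect(g, "m1", v2)
    expect_equal(ae2$difference, 0)
    expect_equal(ae2$p, 1)

    expect_error(alleleEffect(g, "m1", v[1:4]), ">= 3 strains")

    # sampling distribution of the estimate: Normal(0.5, sqrt(2/50))
    st <- smallStudy()
    G <- alleleMatrix(st$genotypes)
    set.seed(4)
    devs <- replicate(20, {
        gg <- rep(0:1, each = 50)
        y <- setNames(0.5 * gg + rnorm(100), paste0("X", 1:100))
        gm <- GenotypeMatrix(matrix(c(gg, 1L - gg), nrow = 2, byrow = TRUE,
                                    dimnames = list(c("ma", "mb"),
                                                    names(y))),
                             c("c1", "c1"), c(1L, 2L))
        alleleEffect(gm, "ma", y)$difference - 0.5
    })
    # 95% interval of the estimator is +/- 1.96 * 0.2 = 0.39
    expect_gte(mean(abs(devs) < 0.39), 0.8)
    expect_lt(abs(mean(devs)), 0.15)
})

test_that("RF mapping finds a planted QTL and nothing under the null", {
    cfg <- smallCfg(seed = 17L)
    g <- simulateCross(cfg)
    G <- alleleMatrix(g)
    y <- setNames(G[, "chr02_m020"] + rnorm(nrow(G), 0, 0.1), rownames(G))
    res <- mapQTLrf(g, y, nTrees = 300L, nPerm = 50L, fdr = 0.05, seed = 1L)
    expect_gt(nrow(res$peaks), 0)
    top <- res$peaks$peakMarker[which.max(res$peaks$importance)]
    expect_gt(computeLD(g, top, "chr02_m020"), 0.9)
    expect_equal(res$peaks$effectSign[which.max(res$peaks$importance)], 1)
    # q >= p everywhere; determinism under the seed
    expect_true(all(res$table$q >= res$table$p))
    res2 <- mapQTLrf(g, y, nTrees = 300L, nPerm = 50L, fdr = 0.05, seed = 1L)
    expect_identical(res$table, res2$table)

    expect_error(mapQTLrf(g, setNames(rep(1, nrow(G)), rownames(G))),
                 "constant")
    expect_warning(mapQTLrf(g, y, nTrees = 100L, nPerm = 10L, seed = 1L),
                   "resolution")
})

test_that("feature-predictor mapping ranks the causal features first", {
    st <- smallStudy()
    v <- abundanceValues(st$layers$protein)
    y <- setNames(v["P0100", ], colnames(v))
    res <- mapTraitToFeatures(st$layers$protein, y, nPerm = 30L,
                              nTrees = 300L, fdr = 0.2, seed = 2L)
    expect_identical(res$table$feature[1], "P0100")
    expect_true("P0100" %in% res$predictive$feature)

    # trait = F1 - F2 + noise: both recovered with opposite signs
    set.seed(5)
    y2 <- setNames(v["P0100", ] - v["P0101", ] + rnorm(ncol(v), 0, 0.2),
                   colnames(v))
    res2 <- mapTraitToFeatures(st$layers$protein, y2, nPerm = 30L,
                               nTrees = 300L, fdr = 0.2, seed = 2L)
    top <- res2$table[res2$table$feature %in% c("P0100", "P0101"), ]
    expect_true(all(top$q <= 0.2))
    expect_identical(sort(top$corSign), c(-1, 1))
})

test_that("joint allele effects remove marginal trans confounding", {
    st <- smallStudy()
    truth <- st$truth
    jt <- jointAlleleEffects(st$genotypes, st$layers$protein,
                             truth$qtl$marker)
    localRow <- truth$qtl[truth$qtl$type == "local", ]
    # the local target is significant only at its own locus
    qs <- jt$q[localRow$target, ]
    expect_lt(qs[localRow$marker], 1e-6)
    expect_true(all(qs[setdiff(names(qs), localRow$marker)] > 0.05))
    expect_equal(unname(jt$effects[localRow$target, localRow$marker]),
                 localRow$effect, tolerance = 0.35)
})

test_that("additive model and heritability estimators behave", {
    g <- smallStudy()$genotypes
    G <- alleleMatrix(g)
    y <- setNames(G[, 5] + G[, 90], rownames(G))
    expect_equal(additiveModelR2(g, colnames(G)[c(5, 90)], y), 1)

    set.seed(6)
    r2null <- replicate(20, {
        yn <- setNames(rnorm(nrow(G)), rownames(G))
        additiveModelR2(g, colnames(G)[c(5, 90)], yn)
    })
    expect_gte(mean(r2null <= 0.05), 0.9)

    # planted 50% residual variance: beta = 1 on two markers, noise var
    # matched to the genetic variance
    set.seed(7)
    r2p <- replicate(20, {
        gg <- G[, c(5, 90)]
        gen <- gg[, 1] + gg[, 2]
        yp <- setNames(gen + rnorm(nrow(G), 0, sd(gen)), rownames(G))
        additiveModelR2(g, colnames(G)[c(5, 90)], yp)
    })
    expect_lt(abs(mean(r2p) - 0.5), 0.1)

    # collinear markers deduplicated
    dup <- cbind(G[, 5, drop = FALSE], dupM = G[, 5], G[, 90, drop = FALSE])
    gd <- GenotypeMatrix(t(dup), rep("chr01", 3), c(1L, 2L, 3L))
    expect_warning(additiveModelR2(gd, colnames(dup), y), "complete LD")

    # heritability: replicates identical within strain -> ~1; iid -> ~0
    strains <- rep(paste0("s", 1:20), each = 3)
    expect_gt(heritabilityFromReplicates(rep(rnorm(20), each = 3), strains),
              0.99)
    set.seed(8)
    h0 <- replicate(20, heritabilityFromReplicates(rnorm(60), strains))
    expect_lt(abs(mean(h0)), 0.1)
    expect_error(heritabilityFromReplicates(rnorm(5), paste0("s", 1:5)),
                 "replicates")
})

test_that("interaction test isolates product-term epistasis", {
    set.seed(9)
    n <- 100
    gA <- rep(0:1, each = n / 2)
    gB <- rep(rep(0:1, each = n / 4), 2)
    ids <- paste0("S", seq_len(n))
    gm <- GenotypeMatrix(matrix(c(gA, gB), nrow = 2, byrow = TRUE,
                                dimnames = list(c("mA", "mB"), ids)),
                         c("c1", "c1"), c(1L, 2L))
    # exact product trait
    y <- setNames(gA * gB, ids)
    it <- interactionTest(gm, "mA", "mB", y)
    expect_equal(it$interaction, 1, tolerance = 1e-10)
    expect_equal(unname(it$coefficients["gA"]), 0, tolerance = 1e-10)
    expect_equal(it$conditionalA, c(B0 = 0, B1 = 1), tolerance = 1e-10)

    # additive trait: interaction coefficient near zero, null p well-behaved
    ps <- replicate(50, {
        ya <- setNames(gA + gB + rnorm(n), ids)
        interactionTest(gm, "mA", "mB", ya)$p
    })
    expect_gt(ks.test(ps, "punif")$p.value, 0.01)

    # power at the planted settings
    det <- replicate(20, {
        yp <- setNames(gA + gB + 0.9 * gA * gB + rnorm(n, 0, 0.5), ids)
        interactionTest(gm, "mA", "mB", yp)$p < 0.05
    })
    expect_gte(mean(det), 0.8)

    expect_error(interactionTest(gm, "mA", "mA", y), ">= 3 strains")
})
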