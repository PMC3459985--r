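test_that("configuration validation names the offending field", {
    expect_error(simConfig(chromLength = -5), "chromLength")
    expect_error(simConfig(isizeClassWeights = c(0.5, 0.2, 0.2)),
                 "isizeClassWeights")
    expect_error(simConfig(cenCoreWidth = 400, nucleosomeSpacing = 165),
                 "cenCoreWidth")
    expect_error(simConfig(deFraction = 1.5), "deFraction")
})

test_that("configuration files round-trip through the flat key-value format", {
    cfg <- simConfig(seed = 42L, mutantCenSubset = c(1L, 3L),
                     isizeClassWeights = c(0.5, 0.3, 0.2))
    tf <- tempfile(fileext = ".txt")
    writeSimConfig(cfg, tf)
    cfg2 <- readSimConfig(tf)
    for (nm in slotNames(cfg))
        expect_equal(slot(cfg2, nm), slot(cfg, nm), info = nm)
})

test_that("genome generation places one centromere per chromosome", {
    g <- makeGenome(simConfig(nChromosomes = 2L, chromLength = 60000L,
                              seed = 3L))
    cens <- truthCens(g$truth)
    expect_length(cens, 2L)
    expect_equal(unname(BiocGenerics::width(cens)), c(125L, 125L))
    ## genome sequence and annotation cover the configured geometry
    expect_equal(unname(Biostrings::width(g$sequence)), c(60000L, 60000L))
    expect_equal(sum(g$annotation$type == "ORF"), 40L)
})

test_that("a fixed seed reproduces the truth set and read streams exactly", {
    cfg <- smallConfig()
    g1 <- makeGenome(cfg)
    g2 <- makeGenome(cfg)
    expect_identical(truthDyads(g1$truth), truthDyads(g2$truth))
    expect_identical(as.character(g1$sequence), as.character(g2$sequence))
    expect_identical(simulateMnasePairs(g1$truth, cfg, "wt"),
                     simulateMnasePairs(g2$truth, cfg, "wt"))
    tg1 <- simulateChipTags(g1$truth, cfg, "Fun30-like", "wt")
    tg2 <- simulateChipTags(g2$truth, cfg, "Fun30-like", "wt")
    expect_identical(tg1, tg2)
    expect_identical(simulateExpression(g1$truth, cfg),
                     simulateExpression(g2$truth, cfg))
})

test_that("mutant truth differs from wild type only at centromere flanks", {
    cfg <- smallConfig(mutantFlankShift = 30L, mutantCoreHeightFactor = 1)
    g <- makeGenome(cfg)
    wt <- truthDyads(g$truth, "wt")
    mut <- truthDyads(g$truth, "mutant")
    moved <- setdiff(wt$pos, mut$pos)
    gained <- setdiff(mut$pos, wt$pos)
    expect_length(moved, 2L)     # one flanking dyad each side of the CEN
    expect_equal(sort(gained), sort(moved + 30L))
    cen <- truthCens(g$truth)
    expect_true(all(abs(moved - BiocGenerics::start(cen)) < 400 |
                        abs(moved - BiocGenerics::end(cen)) < 400))
})

test_that("neutral perturbation parameters give identical genotypes", {
    cfg <- smallConfig(mutantFlankShift = 0L, mutantCoreHeightFactor = 1)
    g <- makeGenome(cfg)
    wt <- truthDyads(g$truth, "wt")
    mut <- truthDyads(g$truth, "mutant")
    expect_identical(wt[, c("chrom", "pos", "occupancy", "is_core")],
                     mut[, c("chrom", "pos", "occupancy", "is_core")])
})

test_that("every centromere interval holds exactly one core-particle dyad", {
    g <- smallGenome()
    dy <- truthDyads(g$truth, "wt")
    cen <- truthCens(g$truth)
    inside <- dy$pos >= BiocGenerics::start(cen) - 1L &
        dy$pos < BiocGenerics::end(cen)
    expect_equal(sum(dy$is_core[inside]), 1L)
    expect_equal(sum(dy$is_core), 1L)
})

test_that("degenerate noise settings emit pairs centered exactly on the dyad", {
    cfg <- smallConfig(dyadJitter = 0L, isizeClassWeights = c(1, 0, 0))
    tr <- pointTruth(cfg)
    pairs <- simulateMnasePairs(tr, cfg, "wt")
    expect_gt(nrow(pairs), 0L)
    expect_true(all(dyadPositions(pairs)$pos == 5000L))
})

test_that("pair counts follow the occupancy-weighted sampling scheme", {
    cfg <- smallConfig()
    tr <- pointTruth(cfg, n.dyads = 10L)
    pairs <- simulateMnasePairs(tr, cfg, "wt")
    expected <- 10 * 195
    expect_lt(abs(nrow(pairs) - expected), 3 * sqrt(expected))
})

test_that("emitted size-class fractions match the configured mixture", {
    cfg <- smallConfig(isizeClassWeights = c(0.6, 0.25, 0.15))
    g <- makeGenome(cfg)
    pairs <- simulateMnasePairs(g$truth, cfg, "wt")
    ## classify emitted pairs by nearest class mean
    cls <- apply(abs(outer(pairs$isize, cfg@isizeMeans, "-")), 1L,
                 which.min)
    n <- nrow(pairs)
    frac <- tabulate(cls, 3L) / n
    ## core and edge dyads fall back to the mono class, so allow that
    ## excess on top of 3 multinomial SDs
    for (k in 2:3) {
        tol <- 3 * sqrt(cfg@isizeClassWeights[k] *
                            (1 - cfg@isizeClassWeights[k]) / n)
        expect_lt(frac[k], cfg@isizeClassWeights[k] + tol + 0.001)
        expect_gt(frac[k], cfg@isizeClassWeights[k] - tol - 0.02)
    }
})

test_that("unknown genotypes and targets are rejected", {
    g <- smallGenome()
    expect_error(simulateMnasePairs(g$truth, genotype = "het"))
    expect_error(simulateChipTags(g$truth, target = "nonesuch"),
                 "nonesuch")
})

test_that("null enrichment gives statistically indistinguishable libraries", {
    null.folds <- list("Fun30-like" = list(
        wt = c(CEN = 1, promoter = 1, gene_body = 1),
        mutant = c(CEN = 1, promoter = 1, gene_body = 1)))
    cfg <- smallConfig(chipEnrichment = null.folds,
                       chipTagCount = 20000L, inputTagCount = 20000L)
    g <- makeGenome(cfg)
    tg <- simulateChipTags(g$truth, cfg, "Fun30-like", "wt")
    ## compare tag rates falling left of the chromosome midpoint
    mid <- g$seqlengths[[1]] / 2
    tt <- prop.test(c(sum(tg$chip$pos5 < mid), sum(tg$input$pos5 < mid)),
                    c(nrow(tg$chip), nrow(tg$input)))
    expect_gt(tt$p.value, 0.01)
})

test_that("expression truth plants exactly the configured fraction of changes", {
    g <- smallGenome()   # 4 genes, deFraction 0.1 -> floor = 0
    expect_equal(nrow(truthDeGenes(g$truth)), 0L)
    cfg <- simConfig(nChromosomes = 2L, nGenesPerChrom = 20L,
                     deFraction = 0.1, seed = 5L)
    g2 <- makeGenome(cfg)
    expect_equal(nrow(truthDeGenes(g2$truth)), 4L)
    expect_true(all(truthDeGenes(g2$truth)$true_ratio >= 1.5 |
                        truthDeGenes(g2$truth)$true_ratio <= 1 / 1.5))
    ## deFraction 0: all true ratios are exactly 1
    g0 <- makeGenome(smallConfig(deFraction = 0))
    expect_true(all(truthExpr(g0$truth)$true_ratio == 1))
})

test_that("deep counts recover a planted two-fold expression change", {
    cfg <- smallConfig(deFraction = 0.5, deRatioUp = 2, deRatioDown = 0.5,
                       exprMeanLog = log(50000), exprDispersion = 1e-4)
    g <- makeGenome(cfg)
    counts <- simulateExpression(g$truth, cfg)
    truth <- truthExpr(g$truth)
    est <- counts$mutant_count / counts$wt_count
    expect_equal(est, truth$true_ratio, tolerance = 0.05)
})
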