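test_that("the insert-size spectrum is an exact unbinned histogram", {
    p <- data.frame(chrom = "c", left5 = 0L,
                    isize = c(150L, 150L, 300L))
    sp <- isizeSpectrum(p)
    expect_equal(sp$isize, c(150L, 300L))
    expect_equal(sp$count, c(2L, 1L))
    empty <- isizeSpectrum(p[0, ])
    expect_equal(nrow(empty), 0L)
})

test_that("size-class selection keeps the inclusive window around the target", {
    p <- data.frame(chrom = "c", left5 = 0L, isize = 100:200)
    kept <- sizeClassFilter(p, target = 150, windowFraction = 0.2)
    expect_equal(range(kept$isize), c(120L, 180L))
    expect_equal(nrow(kept), 61L)
    expect_equal(nrow(sizeClassFilter(p[0, ])), 0L)
    ## idempotence
    expect_equal(sizeClassFilter(kept), kept)
})

test_that("size-class selection agrees with a brute-force filter", {
    p <- randomPairs(10000L, seed = 2L)
    kept <- sizeClassFilter(p, 150, 0.2)
    manual <- p[vapply(p$isize, function(s) s >= 120 && s <= 180,
                       logical(1)), ]
    expect_equal(kept, manual, ignore_attr = TRUE)
})

test_that("pair centers implement the floor rule and preserve order", {
    p <- data.frame(chrom = c("chrI", "chrI"), left5 = c(1000L, 0L),
                    isize = c(150L, 151L))
    d <- dyadPositions(p)
    expect_equal(d$pos, c(1075L, 75L))
})

test_that("with zero jitter the mapped dyads equal the emitting truth dyads", {
    cfg <- smallConfig(dyadJitter = 0L, isizeClassWeights = c(1, 0, 0))
    g <- makeGenome(cfg)
    pairs <- simulateMnasePairs(g$truth, cfg, "wt")
    mapped <- dyadPositions(pairs)$pos
    expect_equal(mapped, attr(pairs, "truth_dyad"))
    ## multiset equality against occupancy-weighted truth
    expect_setequal(unique(mapped), truthDyads(g$truth, "wt")$pos)
})

test_that("dyad binning counts by floor(pos / width) and conserves totals", {
    d <- data.frame(chrom = "c", pos = c(0L, 7L, 14L))
    tr <- binDyads(d, 15L, seqlengths = c(c = 60L))
    expect_equal(trackValues(tr)$c, c(3, 0, 0, 0))
    tr2 <- binDyads(data.frame(chrom = "c", pos = 1075L), 15L,
                    seqlengths = c(c = 1200L))
    expect_equal(which(trackValues(tr2)$c == 1) - 1L, 71L)
    ## conservation on random input
    d3 <- data.frame(chrom = "c", pos = sample.int(1000L, 500L,
                                                   replace = TRUE))
    tr3 <- binDyads(d3, 15L, seqlengths = c(c = 1000L))
    expect_equal(sum(trackValues(tr3)$c), 500)
    ## out-of-range positions land in the terminal bin with a warning
    expect_warning(
        tr4 <- binDyads(data.frame(chrom = "c", pos = 120L), 15L,
                        seqlengths = c(c = 60L)),
        "terminal")
    expect_equal(sum(trackValues(tr4)$c), 1)
    expect_equal(trackValues(tr4)$c[4], 1)
})

test_that("3-bin smoothing follows the edge-shrink moving-average rule", {
    expect_equal(trackValues(smooth3(BinnedTrack(list(c = c(2, 2, 2, 2)),
                                                 15L)))$c,
                 c(2, 2, 2, 2))
    expect_equal(trackValues(smooth3(BinnedTrack(list(c = c(0, 3, 0)),
                                                 15L)))$c,
                 c(1.5, 1, 1.5))
    ## direct-evaluation oracle on random tracks
    set.seed(4)
    for (i in 1:25) {
        v <- runif(sample(3:40, 1L))
        sm <- trackValues(smooth3(BinnedTrack(list(c = v), 10L)))$c
        n <- length(v)
        oracle <- vapply(seq_len(n), function(j)
            mean(v[max(1L, j - 1L):min(n, j + 1L)]), numeric(1))
        expect_equal(sm, oracle)
    }
    ## zero-padded tracks conserve total mass under smoothing
    v <- c(0, 0, runif(20), 0, 0)
    sm <- trackValues(smooth3(BinnedTrack(list(c = v), 10L)))$c
    expect_equal(sum(sm), sum(v))
})

test_that("particle mapping equals the composition of its four steps", {
    g <- smallGenome()
    pairs <- simulateMnasePairs(g$truth, genotype = "wt")
    composed <- smooth3(binDyads(dyadPositions(
        sizeClassFilter(pairs, 150, 0.2)), 15L,
        seqlengths = g$seqlengths))
    direct <- mapParticles(pairs, seqlengths = g$seqlengths)
    expect_equal(trackValues(direct), trackValues(composed))
    ## no pairs -> all-zero track
    zero <- mapParticles(pairs[0, ], seqlengths = g$seqlengths)
    expect_true(all(unlist(trackValues(zero)) == 0))
})

test_that("unsmoothed mapping is additive over pair sets", {
    g <- smallGenome()
    pairs <- simulateMnasePairs(g$truth, genotype = "wt")
    half <- seq_len(nrow(pairs)) %% 2L == 0L
    t.all <- mapParticles(pairs, seqlengths = g$seqlengths, smooth = FALSE)
    t.a <- mapParticles(pairs[half, ], seqlengths = g$seqlengths,
                        smooth = FALSE)
    t.b <- mapParticles(pairs[!half, ], seqlengths = g$seqlengths,
                        smooth = FALSE)
    for (chr in seqnames(t.all))
        expect_equal(trackValues(t.all)[[chr]],
                     trackValues(t.a)[[chr]] + trackValues(t.b)[[chr]])
})

test_that("peak calling reports plateaus at their leftmost bin", {
    tr <- BinnedTrack(list(c = c(0, 1, 3, 3, 1, 0, 2, 0)), 10L)
    pk <- callPeaks(tr)
    expect_equal(pk$bin, c(2L, 6L))
    expect_equal(pk$height, c(3, 2))
    ## monotone tracks have no interior peak
    expect_equal(nrow(callPeaks(BinnedTrack(list(c = 1:5), 10L))), 0L)
})

test_that("the di-nucleosome class peaks midway between adjacent dyads", {
    cfg <- smallConfig()
    g <- makeGenome(cfg)
    pairs <- simulateMnasePairs(g$truth, cfg, "wt")
    tr300 <- mapParticles(pairs, target = 300, seqlengths = g$seqlengths)
    pk <- callPeaks(tr300, minHeight = max(unlist(trackValues(tr300))) / 5)
    dy <- truthDyads(g$truth, "wt")
    dy <- dy[!dy$is_core, ]
    ## interior array dyads one spacing apart
    adj <- which(diff(dy$pos) == cfg@nucleosomeSpacing)
    mids <- (dy$pos[adj] + dy$pos[adj + 1L]) / 2
    hit <- vapply(mids, function(m) any(abs(pk$pos - m) <= 15 + 7.5),
                  logical(1))
    expect_gt(mean(hit), 0.9)
})

test_that("dyad recovery meets the coverage-scaled expectations", {
    g <- smallGenome()
    pairs <- simulateMnasePairs(g$truth, genotype = "wt")
    tr <- mapParticles(pairs, seqlengths = g$seqlengths)
    pk <- callPeaks(tr)
    td <- truthDyads(g$truth, "wt")
    rec <- vapply(seq_len(nrow(td)), function(i) {
        p <- pk[pk$chrom == td$chrom[i], ]
        any(abs(p$bin - td$pos[i] %/% 15L) <= 1L)
    }, logical(1))
    expect_gte(mean(rec), 0.9)
})
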