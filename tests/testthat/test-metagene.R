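## minimal gene-table constructor for profile tests
mkTab <- function(chrom, strand, tss, tts = tss, id = "g1",
                  orf_start = tss, orf_end = tts + 1L) {
    data.frame(id = id, chrom = chrom, strand = strand,
               orf_start = orf_start, orf_end = orf_end,
               tss = tss, tts = tts, stringsAsFactors = FALSE)
}

test_that("an indicator track anchors at offset zero for a plus-strand gene", {
    v <- numeric(200)
    v[2001 %/% 25 + 1] <- 1          # bin holding the TSS at 2001
    tr <- BinnedTrack(list(c = v), 25L)
    tab <- mkTab("c", "+", 2000L)    # TSS at a bin boundary
    v[] <- 0; v[2000 %/% 25 + 1] <- 1
    tr <- BinnedTrack(list(c = v), 25L)
    prof <- anchoredProfile(tr, tab, "tss5", upstream = 500L,
                            downstream = 500L, probe = 25L)
    expect_equal(prof$mean[prof$offset == 0], 1)
    expect_true(all(prof$mean[prof$offset != 0] == 0))
})

test_that("profiles are invariant under strand mirroring", {
    L <- 5000L
    set.seed(3)
    v <- runif(L / 25L)
    tr <- BinnedTrack(list(c = v), 25L)
    tab <- mkTab("c", "+", 2000L)
    p1 <- anchoredProfile(tr, tab, "tss5", 500L, 500L, 25L)
    ## mirrored: reverse bins, gene on minus strand at the mirrored TSS
    trm <- BinnedTrack(list(c = rev(v)), 25L)
    tabm <- mkTab("c", "-", L - 1L - 2000L)
    p2 <- anchoredProfile(trm, tabm, "tss5", 500L, 500L, 25L)
    expect_equal(p1$mean, p2$mean)
})

test_that("anchored profiles equal an independent per-gene loop", {
    g <- smallGenome()
    tr <- mapParticles(simulateMnasePairs(g$truth, genotype = "wt"),
                       seqlengths = g$seqlengths)
    tab <- geneTable(truthGenes(g$truth))
    up <- 500L; down <- 1000L; probe <- 25L
    prof <- anchoredProfile(tr, tab, "tss5", up, down, probe)
    ## brute-force oracle: loop genes, loop probes, loop bases
    n.win <- (up + down) %/% probe
    acc <- matrix(NA_real_, nrow(tab), n.win)
    bw <- binWidth(tr)
    for (i in seq_len(nrow(tab))) {
        v <- trackValues(tr)[[tab$chrom[i]]]
        L <- seqlengths(tr)[[tab$chrom[i]]]
        dir <- if (tab$strand[i] == "+") 1L else -1L
        for (w in seq_len(n.win)) {
            o <- -up + (w - 1L) * probe
            vals <- numeric(probe)
            ok <- TRUE
            for (b in 0:(probe - 1L)) {
                pos <- tab$tss[i] + dir * (o + b)
                if (pos < 0 || pos >= L) { ok <- FALSE; break }
                vals[b + 1L] <- v[pos %/% bw + 1L]
            }
            if (ok) acc[i, w] <- mean(vals)
        }
    }
    oracle <- colMeans(acc, na.rm = TRUE)
    expect_lt(max(abs(prof$mean - oracle)), 1e-9)
    expect_equal(prof$n, colSums(!is.na(acc)), ignore_attr = TRUE)
})

test_that("planted enrichment surfaces at the planted offsets", {
    set.seed(8)
    L <- 20000L
    n.genes <- 50L
    v <- rep(1, L / 25L)
    tss <- sample(3000:15000, n.genes)
    tab <- do.call(rbind, lapply(seq_len(n.genes), function(i)
        mkTab("c", "+", tss[i], id = paste0("g", i))))
    ## plant signal at +200..+400 downstream of every TSS
    for (t in tss) {
        bins <- ((t + 200L) %/% 25L):((t + 400L) %/% 25L) + 1L
        v[bins] <- v[bins] + 5
    }
    tr <- BinnedTrack(list(c = v), 25L)
    prof <- anchoredProfile(tr, tab, "tss5", 1000L, 1000L, 25L)
    peak.offset <- prof$offset[which.max(prof$mean)]
    expect_gte(peak.offset, 200L)
    expect_lte(peak.offset, 400L)
})

test_that("strata report their gene counts and partition the cohort", {
    g <- smallGenome()
    tr <- mapParticles(simulateMnasePairs(g$truth, genotype = "wt"),
                       seqlengths = g$seqlengths)
    tab <- geneTable(truthGenes(g$truth))
    strata <- structure(rep(c("A", "B"), length.out = nrow(tab)),
                        names = tab$id)
    prof <- anchoredProfile(tr, tab, "tss5", 250L, 250L, 25L,
                            strata = strata)
    per.offset <- tapply(prof$n, prof$offset, sum)
    expect_true(all(per.offset <= nrow(tab)))
    expect_setequal(unique(prof$stratum), c("A", "B"))
})

test_that("scaled profiles resample bodies exactly", {
    ## constant track -> constant profile
    tr <- BinnedTrack(list(c = rep(2, 400)), 10L)
    tab <- mkTab("c", "+", 2000L, orf_start = 2000L, orf_end = 2400L)
    prof <- scaledProfile(tr, tab, bodyBins = 40L, flank = 250L,
                          flankFragment = 25L)
    expect_true(all(prof$mean == 2))
    ## a gene of exactly bodyBins bases has identity resampling
    tr1 <- BinnedTrack(list(c = as.numeric(1:4000)), 1L)
    tab1 <- mkTab("c", "+", 1000L, orf_start = 1000L, orf_end = 1040L)
    p1 <- scaledProfile(tr1, tab1, bodyBins = 40L, flank = 100L,
                        flankFragment = 25L)
    expect_equal(p1$mean[p1$segment == "body"], as.numeric(1001:1040))
    ## genes of lengths 400 and 4000 with the same relative shape give
    ## near-identical scaled bodies
    shape <- function(n) sin(seq(0, 3 * pi, length.out = n))
    v <- c(rep(0, 500), shape(400), rep(0, 500), shape(4000),
           rep(0, 500))
    trs <- BinnedTrack(list(c = v), 1L)
    tabs <- rbind(
        mkTab("c", "+", 500L, orf_start = 500L, orf_end = 900L,
              id = "short"),
        mkTab("c", "+", 1400L, orf_start = 1400L, orf_end = 5400L,
              id = "long"))
    p.each <- lapply(1:2, function(i)
        scaledProfile(trs, tabs[i, ], bodyBins = 40L, flank = 100L,
                      flankFragment = 25L))
    b1 <- p.each[[1]]$mean[p.each[[1]]$segment == "body"]
    b2 <- p.each[[2]]$mean[p.each[[2]]$segment == "body"]
    expect_lt(max(abs(b1 - b2)), 0.05)
    ## too-short genes are excluded with a warning
    tab.mix <- rbind(tabs[2, ],
                     mkTab("c", "+", 100L, orf_start = 100L,
                           orf_end = 120L, id = "tiny"))
    expect_warning(pm <- scaledProfile(trs, tab.mix, bodyBins = 40L,
                                       flank = 100L, flankFragment = 25L),
                   "excluded")
    expect_true(all(pm$n <= 1L))
})

test_that("vector resampling matches a brute-force overlap computation", {
    set.seed(5)
    for (i in 1:20) {
        n <- sample(5:200, 1L)
        k <- sample(2:50, 1L)
        x <- runif(n)
        got <- resampleVector(x, k)
        ## oracle: refine the step function so every output-bin boundary
        ## falls on the fine grid, then average contiguous chunks
        fine <- rep(x, each = k * 50L)
        oracle <- colMeans(matrix(fine, ncol = k))
        expect_equal(got, oracle, tolerance = 1e-12)
    }
    expect_equal(resampleVector(1:5, 5L), as.numeric(1:5))
})

test_that("occupancy normalization puts random occupancy at one", {
    expect_equal(normalizeOccupancy(c(2, 4, 6)), c(0.5, 1, 1.5))
    x <- runif(100) + 0.5
    nx <- normalizeOccupancy(x)
    expect_equal(mean(nx), 1, tolerance = 1e-12)
    expect_equal(normalizeOccupancy(nx), nx)   # idempotence
    expect_error(normalizeOccupancy(rep(0, 5)), "positive")
})

test_that("moving-average ratio curves have the documented geometry", {
    wt <- structure(seq(1, 300), names = paste0("g", 1:300))
    mut <- wt
    flat <- movingAverageRatio(wt, mut, window = 150L)
    expect_equal(nrow(flat), 151L)             # n - window + 1
    expect_true(all(abs(flat$y - 1) < 1e-12))
    ## window = n collapses to the global mean ratio
    one <- movingAverageRatio(wt, mut, window = 300L)
    expect_equal(nrow(one), 1L)
    expect_equal(one$y, mean((mut + 1) / (wt + 1)))
    ## elevated ratios at weakly expressed genes lift the low end only
    mut2 <- ifelse(wt <= 75, wt * 2, wt)
    curve <- movingAverageRatio(structure(wt, names = names(wt)),
                                structure(mut2, names = names(wt)),
                                window = 50L)
    expect_gt(curve$y[1], 1.5)
    expect_lt(abs(curve$y[nrow(curve)] - 1), 0.05)
})
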