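## Shared fixtures, built once per test run and memoized.

.fixture.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
    if (!exists(key, envir = .fixture.cache))
        assign(key, force(expr), envir = .fixture.cache)
    get(key, envir = .fixture.cache)
}

## small one-chromosome study for fast unit tests
smallConfig <- function(seed = 11L, ...) {
    simConfig(nChromosomes = 1L, chromLength = 20000L, nGenesPerChrom = 4L,
              seed = seed, ...)
}

smallGenome <- function() memo("smallGenome", makeGenome(smallConfig()))

## the default two-chromosome study (the documented study conditions)
defaultGenome <- function() memo("defaultGenome", makeGenome(simConfig(seed = 7L)))

defaultPairsWt <- function() memo("defaultPairsWt", {
    g <- defaultGenome()
    simulateMnasePairs(g$truth, genotype = "wt")
})

## hand-built single-dyad truth for degenerate-noise tests
pointTruth <- function(config, pos = 5000L, n.dyads = 1L,
                       chromLength = 20000L) {
    pos <- as.integer(pos + (seq_len(n.dyads) - 1L) * 400L)
    dy <- do.call(rbind, lapply(c("wt", "mutant"), function(gt)
        data.frame(genotype = gt, chrom = "chrT", pos = pos,
                   occupancy = 1, is_core = FALSE)))
    empty.gr <- GenomicRanges::GRanges()
    new("TruthSet", dyads = dy, cens = empty.gr, genes = empty.gr,
        features = empty.gr, enrichment = list(),
        deGenes = data.frame(gene_id = character(),
                             true_ratio = numeric()),
        exprTruth = data.frame(gene_id = character(),
                               true_mean = numeric(),
                               true_ratio = numeric()),
        seqlengths = c(chrT = as.integer(chromLength)), config = config)
}

randomPairs <- function(n, seed = 1L, chroms = "chrR", maxPos = 50000L) {
    set.seed(seed)
    data.frame(chrom = sample(chroms, n, replace = TRUE),
               left5 = sample.int(maxPos, n, replace = TRUE) - 1L,
               isize = sample(50:600, n, replace = TRUE),
               stringsAsFactors = FALSE)
}
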