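mkGenes <- function(...) {
    ## rows: list(chrom, start0, end0, strand, id, u5, u3)
    rows <- list(...)
    df <- do.call(rbind, lapply(rows, function(r)
        data.frame(chrom = r[[1]], s0 = r[[2]], e0 = r[[3]],
                   strand = r[[4]], id = r[[5]],
                   u5 = if (length(r) > 5) r[[6]] else NA,
                   u3 = if (length(r) > 6) r[[7]] else NA)))
    GenomicRanges::GRanges(df$chrom,
                           IRanges::IRanges(df$s0 + 1L, df$e0),
                           strand = df$strand, type = "ORF", ID = df$id,
                           utr5_len = as.integer(df$u5),
                           utr3_len = as.integer(df$u3))
}

test_that("transcript anchors derive from ORF boundaries and UTR lengths", {
    g <- mkGenes(list("c", 1000L, 2000L, "+", "a", 50L, 100L),
                 list("c", 3000L, 4000L, "-", "b", 50L, 100L))
    tab <- geneTable(g)
    expect_equal(tab$tss[tab$id == "a"], 950L)
    expect_equal(tab$tts[tab$id == "a"], 2099L)
    ## minus strand mirrors: TSS right of the ORF, TTS left
    expect_equal(tab$tss[tab$id == "b"], 4049L)
    expect_equal(tab$tts[tab$id == "b"], 2900L)
})

test_that("intergenic regions comprise the UTR plus a 150-base extension", {
    g <- mkGenes(list("c", 1000L, 2000L, "+", "a", 50L, 100L))
    tab <- assignIgrs(geneTable(g))
    expect_equal(tab$igr5_start, 800L)   # 50 UTR + 150 extension
    expect_equal(tab$igr5_end, 1000L)
    expect_equal(tab$igr3_start, 2000L)
    expect_equal(tab$igr3_end, 2250L)    # 100 UTR + 150 extension
})

test_that("genes without UTR annotation fall back to the bare extension", {
    g <- mkGenes(list("c", 1000L, 2000L, "+", "a"))
    tab <- assignIgrs(geneTable(g))
    expect_equal(tab$igr5_start, 850L)
    expect_equal(tab$igr3_end, 2150L)
})

test_that("intergenic regions clip at chromosome ends and neighbour ORFs", {
    g <- mkGenes(list("c", 100L, 900L, "+", "a"))
    tab <- assignIgrs(geneTable(g), seqlengths = c(c = 1000L))
    expect_equal(tab$igr5_start, 0L)     # clipped at the chromosome start
    expect_equal(tab$igr3_end, 1000L)

    ## two plus-strand genes 100 bases apart: downstream 5'IGR truncates
    g2 <- mkGenes(list("c", 1000L, 2000L, "+", "a", 50L, 100L),
                  list("c", 2100L, 3000L, "+", "b", 50L, 100L))
    tab2 <- assignIgrs(geneTable(g2))
    expect_equal(tab2$igr5_start[tab2$id == "b"], 2000L)
    expect_equal(tab2$igr5_end[tab2$id == "b"], 2100L)
})

test_that("overlapping neighbours produce zero-length regions with a warning", {
    g <- mkGenes(list("c", 1000L, 2000L, "+", "a"),
                 list("c", 1900L, 2800L, "+", "b"))
    expect_warning(tab <- assignIgrs(geneTable(g)), "zero-length")
    expect_equal(tab$igr3_start[tab$id == "a"],
                 tab$igr3_end[tab$id == "a"])
})

test_that("intergenic regions never invade any ORF on simulated annotation", {
    g <- smallGenome()
    tab <- assignIgrs(geneTable(truthGenes(g$truth)),
                      neighbors = g$annotation,
                      seqlengths = g$truth@seqlengths)
    orfs <- tab[, c("chrom", "orf_start", "orf_end")]
    overlaps <- function(s, e, chr)
        any(orfs$chrom == chr & orfs$orf_start < e & orfs$orf_end > s)
    for (i in seq_len(nrow(tab))) {
        expect_false(overlaps(tab$igr5_start[i], tab$igr5_end[i],
                              tab$chrom[i]))
        expect_false(overlaps(tab$igr3_start[i], tab$igr3_end[i],
                              tab$chrom[i]))
        ## the gene's own two IGRs are disjoint
        expect_true(tab$igr5_end[i] <= tab$igr3_start[i] ||
                        tab$igr3_end[i] <= tab$igr5_start[i])
    }
})

test_that("adjacent gene pairs classify as convergent or divergent", {
    ## heads facing: (-) then (+)
    g <- mkGenes(list("c", 1000L, 2000L, "-", "a"),
                 list("c", 3000L, 4000L, "+", "b"))
    tab <- classifyOrientation(geneTable(g))
    expect_equal(tab$promoter_context, c("divergent", "divergent"))
    ## tails facing: (+) then (-)
    g2 <- mkGenes(list("c", 1000L, 2000L, "+", "a"),
                  list("c", 3000L, 4000L, "-", "b"))
    tab2 <- classifyOrientation(geneTable(g2))
    expect_equal(tab2$terminator_context, c("convergent", "convergent"))
    ## chromosome-terminal sides stay tandem and are flagged
    expect_true(all(tab2$terminal))
})

test_that("orientation labels match an exhaustive pairwise-scan oracle", {
    set.seed(9)
    n <- 20L
    starts <- sort(sample.int(50000L, n)) * 2L
    g <- do.call(mkGenes, lapply(seq_len(n), function(i)
        list("c", starts[i], starts[i] + 800L,
             sample(c("+", "-"), 1L), paste0("g", i))))
    tab <- classifyOrientation(geneTable(g))
    ## oracle: direct scan over all other genes
    for (i in seq_len(n)) {
        others <- tab[-i, ]
        left <- others[others$orf_end <= tab$orf_start[i], ]
        right <- others[others$orf_start >= tab$orf_end[i], ]
        nl <- if (nrow(left)) left[which.max(left$orf_end), ] else NULL
        nr <- if (nrow(right)) right[which.min(right$orf_start), ] else NULL
        up <- if (tab$strand[i] == "+") nl else nr
        down <- if (tab$strand[i] == "+") nr else nl
        expect_equal(tab$promoter_context[i],
                     if (!is.null(up) && up$strand != tab$strand[i])
                         "divergent" else "tandem")
        expect_equal(tab$terminator_context[i],
                     if (!is.null(down) && down$strand != tab$strand[i])
                         "convergent" else "tandem")
    }
})

test_that("strand-mirroring the genome mirrors the orientation labels", {
    set.seed(10)
    n <- 12L
    L <- 100000L
    starts <- sort(sample.int(90000L, n))
    strands <- sample(c("+", "-"), n, replace = TRUE)
    g <- do.call(mkGenes, lapply(seq_len(n), function(i)
        list("c", starts[i], starts[i] + 500L, strands[i],
             paste0("g", i))))
    tab <- classifyOrientation(geneTable(g))
    ## mirrored genome: coordinates reflected, strands flipped
    gm <- do.call(mkGenes, lapply(seq_len(n), function(i)
        list("c", L - (starts[i] + 500L), L - starts[i],
             if (strands[i] == "+") "-" else "+", paste0("g", i))))
    tabm <- classifyOrientation(geneTable(gm))
    tabm <- tabm[match(tab$id, tabm$id), ]
    expect_equal(tab$promoter_context, tabm$promoter_context)
    expect_equal(tab$terminator_context, tabm$terminator_context)
})

test_that("expression categories form near-equal tertiles with fixed ties", {
    v <- structure(c(10, 500, 3, 80, 900, 45, 2, 160, 7),
                   names = paste0("g", 1:9))
    cats <- expressionCategories(v)
    expect_equal(unname(table(cats)[c("high", "medium", "low")]),
                 rep(3L, 3L), ignore_attr = TRUE)
    expect_equal(as.character(cats[order(-v)[1:3]]), rep("high", 3))
    ## all-equal values fill classes by gene-id order
    ve <- structure(rep(5, 9), names = paste0("g", 1:9))
    ce <- expressionCategories(ve)
    expect_equal(as.character(ce[paste0("g", 1:3)]), rep("high", 3))
    expect_equal(unname(table(ce)), rep(3L, 3L), ignore_attr = TRUE)
    ## sizes differ by at most one for any n
    for (n in c(10L, 100L, 4560L)) {
        sizes <- table(expressionCategories(
            structure(runif(n), names = sprintf("x%05d", seq_len(n)))))
        expect_lte(diff(range(sizes)), 1L)
    }
})
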