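#' Generate the synthetic mini-genome, annotation and ground truth
#'
#' Builds a random mini-genome with the chromatin and annotation structure
#' the pipeline assumes: per chromosome, a regularly spaced nucleosome array
#' interrupted by promoter nucleosome-depleted regions, one centromere with
#' a single low-occupancy core particle flanked by well-positioned
#' nucleosomes, telomeric repeats at both ends, a set of protein-coding
#' genes with strands and (for most genes) UTR annotation, and scattered
#' noncoding features (tRNA, snoRNA, snRNA, ARS, LTR).  Ground truth for
#' both genotypes -- nucleosome dyads with occupancy weights, enrichment
#' folds, and planted expression ratios -- is returned as a
#' [TruthSet-class].
#'
#' In the mutant genotype, for every perturbed centromere the two
#' immediately flanking nucleosome dyads are displaced by
#' `mutantFlankShift` bases and the core-particle occupancy is multiplied
#' by `mutantCoreHeightFactor`; all dyads away from perturbed centromeres
#' are identical between genotypes.
#'
#' @param config a [SimConfig-class] from [simConfig()].
#'
#' @return A list with elements:
#' \describe{
#'   \item{sequence}{[Biostrings::DNAStringSet] of chromosome sequences.}
#'   \item{annotation}{[GenomicRanges::GRanges] of all feature intervals
#'     (classes ORF, CEN, tRNA, snoRNA, snRNA, ARS, LTR, telomere in the
#'     `type` metadata column).}
#'   \item{genes}{`GRanges` of gene ORFs with `ID`, `utr5_len`, `utr3_len`.}
#'   \item{truth}{the [TruthSet-class].}
#'   \item{seqlengths}{named integer vector of chromosome lengths.}
#' }
#' @examples
#' g <- makeGenome(simConfig(nChromosomes = 1L, chromLength = 20000L,
#'                           nGenesPerChrom = 5L, seed = 3))
#' g$truth
#' @export
makeGenome <- function(config) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    .setStreamSeed(config, "genome")

    L <- config@chromLength
    chroms <- paste0("chrS", seq_len(config@nChromosomes))
    seqlens <- structure(rep(L, config@nChromosomes), names = chroms)

    seqs <- Biostrings::DNAStringSet(vapply(chroms, function(chr)
        paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                     prob = c(0.31, 0.19, 0.19, 0.31)), collapse = ""),
        character(1)))

    feat <- list(); gene.rows <- list()
    wt.dyads <- list(); mut.dyads <- list()

    for (ci in seq_along(chroms)) {
        chr <- chroms[ci]
        lay <- .layoutChromosome(chr, ci, L, config)
        feat[[chr]] <- lay$features
        gene.rows[[chr]] <- lay$genes
        perturbed <- length(config@mutantCenSubset) == 0L ||
            ci %in% config@mutantCenSubset
        dy <- .layoutDyads(chr, L, lay, config, perturbed)
        wt.dyads[[chr]] <- dy$wt
        mut.dyads[[chr]] <- dy$mutant
    }

    ## combining per-chromosome GRanges warns about disjoint seqlevels
    genes <- suppressWarnings(do.call(c, unname(gene.rows)))
    features <- suppressWarnings(do.call(c, unname(feat)))
    GenomeInfoDb::seqlengths(genes) <- seqlens[GenomeInfoDb::seqlevels(genes)]
    GenomeInfoDb::seqlengths(features) <-
        seqlens[GenomeInfoDb::seqlevels(features)]
    cens <- features[features$type == "CEN"]

    expr <- .planExpression(genes$ID, config)

    dyads <- rbind(
        cbind(genotype = "wt", do.call(rbind, unname(wt.dyads))),
        cbind(genotype = "mutant", do.call(rbind, unname(mut.dyads))))
    rownames(dyads) <- NULL

    truth <- new("TruthSet",
        dyads = dyads, cens = cens, genes = genes, features = features,
        enrichment = config@chipEnrichment,
        deGenes = expr$deGenes, exprTruth = expr$table,
        seqlengths = seqlens, config = config)
    validObject(truth)

    list(sequence = seqs, annotation = features, genes = genes,
         truth = truth, seqlengths = seqlens)
}

## Place genes, centromere, telomeres and noncoding features on one
## chromosome.  All GRanges coordinates are 1-based inclusive (Bioconductor
## convention); dyad/pair coordinates elsewhere are 0-based.
.layoutChromosome <- function(chr, ci, L, config) {
    cw <- config@cenCoreWidth
    cen.start0 <- L %/% 2L - cw %/% 2L
    cen <- GRanges(chr, IRanges(cen.start0 + 1L, cen.start0 + cw),
                   strand = "*", type = "CEN", ID = paste0("CEN", ci),
                   utr5_len = NA_integer_, utr3_len = NA_integer_)
    telo <- GRanges(chr, IRanges(c(1L, L - 499L), c(500L, L)), strand = "*",
                    type = "telomere",
                    ID = paste0("TEL", ci, c("L", "R")),
                    utr5_len = NA_integer_, utr3_len = NA_integer_)

    ## gene slots: even spacing, skipping a guard zone around the CEN
    nG <- config@nGenesPerChrom
    lo <- 800L; hi <- L - 800L
    guard <- c(cen.start0 - 700L, cen.start0 + cw + 700L)
    n.slots <- nG + 4L
    sw <- (hi - lo) %/% n.slots
    if (sw < 1400L)
        stop("chromLength too small for nGenesPerChrom (slot width ",
             sw, " < 1400)")
    slot.starts <- lo + (seq_len(n.slots) - 1L) * sw
    ok <- !(slot.starts < guard[2] & (slot.starts + sw) > guard[1])
    slot.starts <- slot.starts[ok]
    if (length(slot.starts) < nG)
        stop("could not place ", nG, " genes on ", chr)
    slot.starts <- slot.starts[seq_len(nG)]

    orf.len <- sample(900:min(1500L, sw - 400L), nG, replace = TRUE)
    offs <- vapply(sw - orf.len - 300L, function(m)
        sample.int(m, 1L), integer(1))
    orf.start0 <- slot.starts + offs
    strands <- sample(c("+", "-"), nG, replace = TRUE)
    has.utr <- runif(nG) >= config@utrMissingFraction
    utr5 <- ifelse(has.utr, sample(30:90, nG, replace = TRUE), NA_integer_)
    utr3 <- ifelse(has.utr, sample(60:150, nG, replace = TRUE), NA_integer_)

    genes <- GRanges(chr, IRanges(orf.start0 + 1L, orf.start0 + orf.len),
                     strand = strands, type = "ORF",
                     ID = sprintf("gene_%d_%02d", ci, seq_len(nG)),
                     utr5_len = as.integer(utr5),
                     utr3_len = as.integer(utr3))

    ## noncoding features dropped into sufficiently large inter-ORF gaps
    nc.classes <- c(tRNA = 75L, snoRNA = 100L, snRNA = 120L, ARS = 150L,
                    LTR = 300L)
    occupied <- sort(c(orf.start0, orf.start0 + orf.len))
    gap.start <- c(600L, orf.start0 + orf.len + 80L)
    gap.end <- c(orf.start0 - 80L, L - 600L)
    o <- order(gap.start)
    gap.start <- gap.start[o]; gap.end <- gap.end[o]
    nc.list <- list()
    gi <- 1L
    for (k in seq_along(nc.classes)) {
        wk <- nc.classes[[k]]
        while (gi <= length(gap.start) &&
               (gap.end[gi] - gap.start[gi] < wk + 40L ||
                (gap.start[gi] < cen.start0 + cw + 700L &&
                 gap.end[gi] > cen.start0 - 700L))) gi <- gi + 1L
        if (gi > length(gap.start)) break
        s0 <- gap.start[gi] + 20L
        nc.list[[k]] <- GRanges(chr, IRanges(s0 + 1L, s0 + wk),
                                strand = sample(c("+", "-"), 1L),
                                type = names(nc.classes)[k],
                                ID = sprintf("%s_%d_%d",
                                             names(nc.classes)[k], ci, k),
                                utr5_len = NA_integer_,
                                utr3_len = NA_integer_)
        gi <- gi + 1L
    }

    all.feat <- c(list(genes, cen, telo), nc.list)
    list(features = sort(do.call(c, all.feat)), genes = sort(genes),
         cen.start0 = cen.start0, cen.end0 = cen.start0 + cw)
}

## Ground-truth dyads for one chromosome, both genotypes.
.layoutDyads <- function(chr, L, lay, config, perturbed) {
    sp <- config@nucleosomeSpacing
    phase <- sample.int(sp, 1L) - 1L
    pos <- seq.int(600L + phase, L - 600L, by = sp)

    ## promoter NDRs: remove array dyads immediately upstream of each TSS
    g <- lay$genes
    plus <- as.character(strand(g)) == "+"
    u5 <- ifelse(is.na(g$utr5_len), 0L, g$utr5_len)
    tss0 <- ifelse(plus, start(g) - 1L - u5, end(g) + u5)
    ndr.lo <- ifelse(plus, tss0 - config@ndrWidth, tss0 + 1L)
    ndr.hi <- ndr.lo + config@ndrWidth
    in.ndr <- rep(FALSE, length(pos))
    for (i in seq_along(ndr.lo))
        in.ndr <- in.ndr | (pos >= ndr.lo[i] & pos < ndr.hi[i])
    pos <- pos[!in.ndr]

    ## centromere: clear the array locally, then place core + flanks
    cs0 <- lay$cen.start0; ce0 <- lay$cen.end0
    pos <- pos[pos < cs0 - 240L | pos >= ce0 + 240L]
    core <- (cs0 + ce0) %/% 2L
    flankL <- cs0 - 95L
    flankR <- ce0 + 94L

    wt <- data.frame(
        chrom = chr,
        pos = as.integer(c(pos, flankL, core, flankR)),
        occupancy = c(rep(1, length(pos)), 1, config@cenCoreOccupancy, 1),
        is_core = c(rep(FALSE, length(pos)), FALSE, TRUE, FALSE))
    wt <- wt[order(wt$pos), , drop = FALSE]

    mut <- wt
    if (perturbed) {
        sh <- config@mutantFlankShift
        mut$pos[mut$pos %in% c(flankL, flankR)] <-
            as.integer(c(flankL, flankR) + sh)
        mut$occupancy[mut$is_core] <-
            mut$occupancy[mut$is_core] * config@mutantCoreHeightFactor
        mut <- mut[order(mut$pos), , drop = FALSE]
    }
    list(wt = wt, mutant = mut)
}

## Per-gene true mean expression and mutant/wild-type ratio.  Genes with a
## true ratio at or beyond the 1.5-fold cutoff constitute the deGenes set.
.planExpression <- function(gene.ids, config) {
    n <- length(gene.ids)
    mu <- rlnorm(n, config@exprMeanLog, config@exprSdLog)
    ratio <- rep(1, n)
    n.de <- floor(config@deFraction * n)
    if (n.de > 0) {
        de.idx <- sample.int(n, n.de)
        n.up <- ceiling(n.de / 2)
        ratio[de.idx[seq_len(n.up)]] <- config@deRatioUp
        if (n.de > n.up)
            ratio[de.idx[(n.up + 1L):n.de]] <- config@deRatioDown
    }
    if (config@lowExprElevation != 1) {
        q <- quantile(mu, 0.25)
        low <- which(mu <= q & ratio == 1)
        ratio[low] <- config@lowExprElevation
    }
    tab <- data.frame(gene_id = gene.ids, true_mean = mu, true_ratio = ratio,
                      stringsAsFactors = FALSE)
    de <- tab[tab$true_ratio >= 1.5 | tab$true_ratio <= 1 / 1.5,
              c("gene_id", "true_ratio")]
    rownames(de) <- NULL
    list(table = tab, deGenes = de)
}

#' @rdname makeGenome
#' @param object a `TruthSet`.
#' @export
setMethod("show", "TruthSet", function(object) {
    nd <- table(object@dyads$genotype)
    cat(sprintf(
        "TruthSet: %d chromosome(s), %d CEN(s), %d gene(s)\n",
        length(object@seqlengths), length(object@cens),
        length(object@genes)))
    cat(sprintf("  dyads: %s\n",
                paste(sprintf("%s=%d", names(nd), nd), collapse = ", ")))
    cat(sprintf("  planted expression changes: %d gene(s)\n",
                nrow(object@deGenes)))
    invisible(NULL)
})

#' Accessors for TruthSet components
#'
#' @param x a [TruthSet-class].
#' @param genotype optional `"wt"` or `"mutant"` to subset the dyad table.
#' @return `truthDyads` a data.frame of ground-truth dyads; `truthCens` a
#'   `GRanges` of centromeres; `truthGenes` a `GRanges` of gene ORFs;
#'   `truthDeGenes` the planted fold-change table; `truthExpr` the per-gene
#'   expression truth.
#' @export
truthDyads <- function(x, genotype = NULL) {
    stopifnot(is(x, "TruthSet"))
    d <- x@dyads
    if (!is.null(genotype)) {
        if (!genotype %in% c("wt", "mutant"))
            stop("unknown genotype: ", genotype)
        d <- d[d$genotype == genotype, , drop = FALSE]
        rownames(d) <- NULL
    }
    d
}

#' @rdname truthDyads
#' @export
truthCens <- function(x) { stopifnot(is(x, "TruthSet")); x@cens }

#' @rdname truthDyads
#' @export
truthGenes <- function(x) { stopifnot(is(x, "TruthSet")); x@genes }

#' @rdname truthDyads
#' @export
truthDeGenes <- function(x) { stopifnot(is(x, "TruthSet")); x@deGenes }

#' @rdname truthDyads
#' @export
truthExpr <- function(x) { stopifnot(is(x, "TruthSet")); x@exprTruth }
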