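#' Simulate paired-end MNase-seq alignments from ground-truth dyads
#'
#' Every ground-truth dyad emits a Poisson number of read pairs with mean
#' `pairsPerNucleosome * occupancy`.  Each pair is assigned a particle size
#' class from the configured mixture: a mono-nucleosome pair is centered on
#' the emitting dyad, a di-nucleosome pair on the midpoint of the dyad and
#' its next array neighbour, a tri-nucleosome pair on the midpoint of the
#' dyad and the neighbour two positions over (pairs lacking the required
#' neighbour fall back to the mono class, as does the isolated centromeric
#' core particle).  Insert sizes are drawn from a truncated normal around
#' the class mean; observed centers carry uniform integer jitter of up to
#' `dyadJitter` bases.  The emitted leftmost coordinate satisfies
#' `left5 + floor(isize / 2) == observed center` exactly, so center-point
#' dyad mapping recovers the jittered center without rounding loss.
#'
#' @param truth a [TruthSet-class].
#' @param config the [SimConfig-class] (defaults to the one stored in
#'   `truth`).
#' @param genotype `"wt"` or `"mutant"`.
#'
#' @return data.frame of aligned pairs with columns `chrom`, `left5`
#'   (0-based leftmost 5' coordinate) and `isize` (end-to-end distance,
#'   bases), plus a `"truth_dyad"` attribute giving the emitting ground
#'   truth dyad of every pair.
#' @examples
#' g <- makeGenome(simConfig(nChromosomes = 1L, chromLength = 20000L,
#'                           nGenesPerChrom = 5L, seed = 3))
#' pairs <- simulateMnasePairs(g$truth, genotype = "wt")
#' head(pairs)
#' @export
simulateMnasePairs <- function(truth, config = truth@config,
                               genotype = c("wt", "mutant")) {
    stopifnot(is(truth, "TruthSet"), is(config, "SimConfig"))
    genotype <- match.arg(genotype)
    .setStreamSeed(config, paste0("pairs.", genotype))

    dy <- truth@dyads[truth@dyads$genotype == genotype, , drop = FALSE]
    out <- vector("list", length(unique(dy$chrom)))
    names(out) <- unique(dy$chrom)

    for (chr in unique(dy$chrom)) {
        d <- dy[dy$chrom == chr, , drop = FALSE]
        d <- d[order(d$pos), , drop = FALSE]
        L <- truth@seqlengths[[chr]]
        n.per <- rpois(nrow(d), config@pairsPerNucleosome * d$occupancy)
        idx <- rep(seq_len(nrow(d)), n.per)
        n <- length(idx)
        if (n == 0L) next

        k <- sample.int(length(config@isizeClassWeights), n, replace = TRUE,
                        prob = config@isizeClassWeights)
        ## particles spanning k nucleosomes need k - 1 downstream
        ## neighbours at array spacing; otherwise fall back to mono
        partner <- idx + (k - 1L)
        bad <- partner > nrow(d) | d$is_core[idx] |
            d$is_core[pmin(partner, nrow(d))] |
            (d$pos[pmin(partner, nrow(d))] - d$pos[idx]) >
                (k - 1L) * config@nucleosomeSpacing + 30L
        k[bad] <- 1L
        partner <- idx + (k - 1L)

        center <- (d$pos[idx] + d$pos[partner]) %/% 2L
        isize <- .rtruncnormInt(n, config@isizeMeans[k], config@isizeSd)
        jit <- if (config@dyadJitter > 0L)
            sample.int(2L * config@dyadJitter + 1L, n, replace = TRUE) -
                config@dyadJitter - 1L
        else integer(n)
        obs <- center + jit
        left5 <- obs - isize %/% 2L
        keep <- left5 >= 0L & (left5 + isize) <= L
        out[[chr]] <- data.frame(chrom = chr, left5 = left5[keep],
                                 isize = isize[keep],
                                 truth_dyad = d$pos[idx][keep],
                                 stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    if (is.null(res))
        res <- data.frame(chrom = character(), left5 = integer(),
                          isize = integer(), truth_dyad = integer())
    rownames(res) <- NULL
    td <- res$truth_dyad
    res$truth_dyad <- NULL
    attr(res, "truth_dyad") <- td
    res
}

## integer truncated normal on [mean - 3 sd, mean + 3 sd] via the
## inverse-CDF method (vectorized over per-draw means)
.rtruncnormInt <- function(n, mean, sd) {
    lo <- pnorm(mean - 3 * sd, mean, sd)
    hi <- pnorm(mean + 3 * sd, mean, sd)
    u <- runif(n, lo, hi)
    pmax(1L, as.integer(round(qnorm(u, mean, sd))))
}

#' Simulate ChIP and input tag libraries
#'
#' Input tags are sampled uniformly over the genome.  ChIP tags are sampled
#' with per-base density proportional to the enrichment fold of the feature
#' class covering each base (background fold 1).  Feature classes are taken
#' from the truth annotation; in addition, `promoter` intervals (150 bases
#' upstream of each TSS through 50 bases downstream), `gene_body` (the
#' ORF), and `igr3` (150 bases downstream of each TTS) are derived from the
#' gene models.  When overlapping, the later class in the priority order
#' CEN > tRNA > snoRNA > snRNA > ARS > LTR > telomere > promoter > igr3 >
#' gene_body wins.
#'
#' @param truth a [TruthSet-class].
#' @param config the [SimConfig-class].
#' @param target ChIP target; must name an entry of the configured
#'   enrichment map (defaults: `"Fun30-like"`, `"Htz1-like"`,
#'   `"H3-like"`).
#' @param genotype `"wt"` or `"mutant"`.
#'
#' @return list with elements `chip` and `input`, each a data.frame of
#'   tags with columns `chrom`, `pos5` (0-based 5' coordinate), `strand`.
#' @export
simulateChipTags <- function(truth, config = truth@config,
                             target = "Fun30-like",
                             genotype = c("wt", "mutant")) {
    stopifnot(is(truth, "TruthSet"), is(config, "SimConfig"))
    genotype <- match.arg(genotype)
    if (!target %in% names(config@chipEnrichment))
        stop("no enrichment folds configured for target '", target, "'")
    folds <- config@chipEnrichment[[target]][[genotype]]
    if (is.null(folds))
        stop("no enrichment folds configured for target '", target,
             "', genotype '", genotype, "'")
    ti <- match(target, names(config@chipEnrichment))
    gi <- match(genotype, c("wt", "mutant"))
    .setStreamSeed(config, "chip", extra = 10L * ti + gi)

    dens <- .foldDensity(truth, folds)
    tot.w <- vapply(dens, sum, numeric(1))
    n.chip <- .splitCount(config@chipTagCount, tot.w)
    lens <- truth@seqlengths[names(dens)]
    n.input <- .splitCount(config@inputTagCount, lens)

    samp <- function(chr, n, w = NULL) {
        if (n == 0L)
            return(data.frame(chrom = character(), pos5 = integer(),
                              strand = character()))
        pos <- if (is.null(w)) sample.int(lens[[chr]], n, replace = TRUE)
               else sample.int(lens[[chr]], n, replace = TRUE, prob = w)
        data.frame(chrom = chr, pos5 = pos - 1L,
                   strand = sample(c("+", "-"), n, replace = TRUE),
                   stringsAsFactors = FALSE)
    }
    chip <- do.call(rbind, lapply(names(dens), function(chr)
        samp(chr, n.chip[[chr]], dens[[chr]])))
    input <- do.call(rbind, lapply(names(dens), function(chr)
        samp(chr, n.input[[chr]])))
    rownames(chip) <- rownames(input) <- NULL
    list(chip = chip, input = input)
}

## per-base enrichment fold vectors, one per chromosome
.foldDensity <- function(truth, folds) {
    gr <- truth@features
    genes <- truth@genes
    plus <- as.character(strand(genes)) == "+"
    u5 <- ifelse(is.na(genes$utr5_len), 0L, genes$utr5_len)
    u3 <- ifelse(is.na(genes$utr3_len), 0L, genes$utr3_len)
    tss0 <- ifelse(plus, start(genes) - 1L - u5, end(genes) + u5)
    tts0 <- ifelse(plus, end(genes) + u3, start(genes) - 1L - u3)

    ## class intervals in increasing priority (later assignments win)
    iv <- list(
        gene_body = data.frame(chrom = as.character(seqnames(genes)),
                               s0 = start(genes) - 1L, e0 = end(genes)),
        igr3 = data.frame(chrom = as.character(seqnames(genes)),
                          s0 = ifelse(plus, tts0, tts0 - 150L),
                          e0 = ifelse(plus, tts0 + 150L, tts0)),
        promoter = data.frame(chrom = as.character(seqnames(genes)),
                              s0 = ifelse(plus, tss0 - 150L, tss0 - 50L),
                              e0 = ifelse(plus, tss0 + 50L, tss0 + 150L)))
    for (cl in c("telomere", "LTR", "ARS", "snRNA", "snoRNA", "tRNA",
                 "CEN")) {
        sel <- gr[gr$type == cl]
        if (length(sel))
            iv[[cl]] <- data.frame(chrom = as.character(seqnames(sel)),
                                   s0 = start(sel) - 1L, e0 = end(sel))
    }
    dens <- lapply(truth@seqlengths, function(L) rep(1, L))
    for (cl in names(iv)) {
        if (!cl %in% names(folds)) next
        f <- folds[[cl]]
        if (is.na(f)) next
        tab <- iv[[cl]]
        for (i in seq_len(nrow(tab))) {
            chr <- tab$chrom[i]
            s <- max(0L, tab$s0[i]); e <- min(truth@seqlengths[[chr]],
                                              tab$e0[i])
            if (e > s) dens[[chr]][(s + 1L):e] <- f
        }
    }
    dens
}

## deterministic largest-remainder apportionment of n among weights
.splitCount <- function(n, w) {
    n <- as.numeric(n); w <- stats::setNames(as.numeric(w), names(w))
    if (sum(w) == 0) return(structure(rep(0L, length(w)), names = names(w)))
    exact <- n * w / sum(w)
    base <- floor(exact)
    rem <- n - sum(base)
    if (rem > 0) {
        o <- order(exact - base, decreasing = TRUE)
        base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1
    }
    structure(as.integer(base), names = names(w))
}

#' Simulate per-gene expression counts for both genotypes
#'
#' Counts are drawn from a negative binomial around the per-gene true
#' means planned in the [TruthSet-class]: wild-type counts around
#' `true_mean`, mutant counts around `true_mean * true_ratio`, both with
#' the configured overdispersion (`variance = mu + dispersion * mu^2`).
#'
#' @param truth a [TruthSet-class].
#' @param config the [SimConfig-class].
#' @return data.frame with columns `gene_id`, `wt_count`, `mutant_count`.
#' @export
simulateExpression <- function(truth, config = truth@config) {
    stopifnot(is(truth, "TruthSet"), is(config, "SimConfig"))
    .setStreamSeed(config, "expression")
    tab <- truth@exprTruth
    size <- 1 / config@exprDispersion
    data.frame(
        gene_id = tab$gene_id,
        wt_count = rnbinom(nrow(tab), mu = tab$true_mean, size = size),
        mutant_count = rnbinom(nrow(tab), mu = tab$true_mean *
                                   tab$true_ratio, size = size),
        stringsAsFactors = FALSE)
}
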