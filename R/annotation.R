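#' Build the augmented gene table
#'
#' Converts gene ORF annotation into the package's gene-context table:
#' 0-based half-open ORF coordinates, UTR lengths (NA when unannotated),
#' and derived transcript anchors.  `tss` is the 0-based coordinate of the
#' first transcribed base and `tts` of the last, both strand-aware: on the
#' plus strand `tss = orf_start - utr5_len` and
#' `tts = orf_end + utr3_len - 1`; mirrored on the minus strand.  Genes
#' without UTR annotation anchor at the ORF boundary.
#'
#' @param genes a [GenomicRanges::GRanges] with `ID`, `utr5_len`,
#'   `utr3_len` metadata (as produced by [makeGenome()] or
#'   [readAnnotationGff()]).
#' @return data.frame with one row per gene, sorted by chromosome and
#'   position.
#' @export
geneTable <- function(genes) {
    stopifnot(is(genes, "GRanges"))
    genes <- sort(genes)
    plus <- as.character(strand(genes)) == "+"
    u5 <- ifelse(is.na(genes$utr5_len), 0L, genes$utr5_len)
    u3 <- ifelse(is.na(genes$utr3_len), 0L, genes$utr3_len)
    s0 <- start(genes) - 1L
    e0 <- end(genes)
    t.lo <- s0 - ifelse(plus, u5, u3)
    t.hi <- e0 + ifelse(plus, u3, u5)
    data.frame(
        id = genes$ID,
        chrom = as.character(seqnames(genes)),
        strand = as.character(strand(genes)),
        orf_start = s0, orf_end = e0,
        utr5_len = genes$utr5_len, utr3_len = genes$utr3_len,
        tss = ifelse(plus, t.lo, t.hi - 1L),
        tts = ifelse(plus, t.hi - 1L, t.lo),
        stringsAsFactors = FALSE)
}

#' Assign 5' and 3' intergenic regions to genes
#'
#' The 5'IGR comprises the annotated 5'UTR plus an `extension` of 150
#' bases outward, integrating the promoter; the 3'IGR is the 3'UTR plus
#' the same extension, integrating the terminator.  Genes lacking UTR
#' annotation fall back to the bare extension outward from the ORF
#' boundary.  IGRs are truncated at the nearest neighbouring feature
#' boundary (neighbours default to the genes themselves; pass the full
#' annotation to also respect noncoding genes) and clipped at chromosome
#' ends; a gene squeezed against an overlapping neighbour gets a
#' zero-length IGR with a warning.
#'
#' @param genes a gene table from [geneTable()] (or a `GRanges`, converted
#'   internally).
#' @param extension outward extension in bases (default 150).
#' @param neighbors optional `GRanges` of intervals that IGRs must not
#'   invade.
#' @param seqlengths named chromosome lengths for end clipping.
#' @return the gene table with added 0-based half-open columns
#'   `igr5_start`, `igr5_end`, `igr3_start`, `igr3_end`.
#' @export
assignIgrs <- function(genes, extension = 150L, neighbors = NULL,
                       seqlengths = NULL) {
    tab <- if (is(genes, "GRanges")) geneTable(genes) else genes
    if (is.null(neighbors)) {
        nb <- data.frame(chrom = tab$chrom, s0 = tab$orf_start,
                         e0 = tab$orf_end)
    } else {
        nb <- data.frame(chrom = as.character(seqnames(neighbors)),
                         s0 = start(neighbors) - 1L, e0 = end(neighbors))
    }
    plus <- tab$strand == "+"
    u5 <- ifelse(is.na(tab$utr5_len), 0L, tab$utr5_len)
    u3 <- ifelse(is.na(tab$utr3_len), 0L, tab$utr3_len)
    ext5 <- u5 + extension
    ext3 <- u3 + extension

    ## raw intervals outward from the ORF boundary, strand-aware
    igr5.s <- ifelse(plus, tab$orf_start - ext5, tab$orf_end)
    igr5.e <- ifelse(plus, tab$orf_start, tab$orf_end + ext5)
    igr3.s <- ifelse(plus, tab$orf_end, tab$orf_start - ext3)
    igr3.e <- ifelse(plus, tab$orf_end + ext3, tab$orf_start)

    clip <- function(s, e, i, side) {
        chr <- tab$chrom[i]
        L <- if (!is.null(seqlengths)) seqlengths[[chr]] else Inf
        s <- max(0L, s); e <- min(L, e)
        ## truncate at the nearest neighbouring feature boundary
        others <- nb$chrom == chr &
            !(nb$s0 == tab$orf_start[i] & nb$e0 == tab$orf_end[i])
        if (any(others)) {
            os <- nb$s0[others]; oe <- nb$e0[others]
            if (side == "left") {
                ## interval abuts the ORF at its right end `e`
                lim <- suppressWarnings(max(oe[oe <= e]))
                if (is.finite(lim)) s <- max(s, lim)
                if (any(os < e & oe > e)) s <- e  # neighbour overlaps ORF
            } else {
                lim <- suppressWarnings(min(os[os >= s]))
                if (is.finite(lim)) e <- min(e, lim)
                if (any(os < s & oe > s)) e <- s
            }
        }
        c(max(s, 0), max(e, s))
    }
    n <- nrow(tab)
    res5 <- matrix(0L, n, 2L); res3 <- matrix(0L, n, 2L)
    for (i in seq_len(n)) {
        side5 <- if (plus[i]) "left" else "right"
        side3 <- if (plus[i]) "right" else "left"
        res5[i, ] <- clip(igr5.s[i], igr5.e[i], i, side5)
        res3[i, ] <- clip(igr3.s[i], igr3.e[i], i, side3)
    }
    zero <- res5[, 1] >= res5[, 2] | res3[, 1] >= res3[, 2]
    if (any(zero))
        warning(sum(zero), " gene(s) received a zero-length IGR ",
                "(overlapping or abutting neighbours)")
    tab$igr5_start <- as.integer(res5[, 1]); tab$igr5_end <- as.integer(res5[, 2])
    tab$igr3_start <- as.integer(res3[, 1]); tab$igr3_end <- as.integer(res3[, 2])
    tab
}

#' Classify promoter and terminator orientation context
#'
#' For each gene, the promoter side is `divergent` when the nearest
#' neighbour on the gene's 5' side lies on the opposite strand (head to
#' head), else `tandem`; the terminator side is `convergent` when the
#' nearest neighbour on the 3' side lies on the opposite strand (tail to
#' tail), else `tandem`.  Strand-bearing noncoding genes (tRNA, snoRNA,
#' snRNA) count as neighbours when supplied.  Genes with no neighbour on a
#' side keep the `tandem` label and are flagged `terminal`.
#'
#' @param genes a gene table from [geneTable()] / [assignIgrs()].
#' @param neighbors optional `GRanges` of additional orientation-bearing
#'   features (entries with strand `*` are ignored).
#' @return the gene table with added columns `promoter_context`
#'   (`divergent`/`tandem`), `terminator_context` (`convergent`/`tandem`)
#'   and logical `terminal`.
#' @export
classifyOrientation <- function(genes, neighbors = NULL) {
    tab <- if (is(genes, "GRanges")) geneTable(genes) else genes
    nb <- data.frame(chrom = tab$chrom, s0 = tab$orf_start,
                     e0 = tab$orf_end, strand = tab$strand,
                     stringsAsFactors = FALSE)
    if (!is.null(neighbors)) {
        st <- as.character(strand(neighbors))
        keep <- st %in% c("+", "-")
        if (any(keep))
            nb <- rbind(nb, data.frame(
                chrom = as.character(seqnames(neighbors))[keep],
                s0 = start(neighbors)[keep] - 1L,
                e0 = end(neighbors)[keep],
                strand = st[keep], stringsAsFactors = FALSE))
    }
    n <- nrow(tab)
    prom <- rep("tandem", n); term <- rep("tandem", n)
    terminal <- rep(FALSE, n)
    for (i in seq_len(n)) {
        same <- nb$chrom == tab$chrom[i] &
            !(nb$s0 == tab$orf_start[i] & nb$e0 == tab$orf_end[i] &
                  nb$strand == tab$strand[i])
        left <- same & nb$e0 <= tab$orf_start[i]
        right <- same & nb$s0 >= tab$orf_end[i]
        nearL <- if (any(left)) which(left)[which.max(nb$e0[left])] else NA
        nearR <- if (any(right)) which(right)[which.min(nb$s0[right])] else NA
        if (tab$strand[i] == "+") {
            up <- nearL; down <- nearR
        } else {
            up <- nearR; down <- nearL
        }
        if (is.na(up) || is.na(down)) terminal[i] <- TRUE
        if (!is.na(up) && nb$strand[up] != tab$strand[i])
            prom[i] <- "divergent"
        if (!is.na(down) && nb$strand[down] != tab$strand[i])
            term[i] <- "convergent"
    }
    tab$promoter_context <- prom
    tab$terminator_context <- term
    tab$terminal <- terminal
    tab
}

#' Assign expression categories by ranked log2 intensity
#'
#' Genes are ranked by `log2(value + pseudocount)` and split into
#' `nClasses` groups of as-equal-as-possible size (default tertiles:
#' `high`, `medium`, `low`).  Ties across a class boundary are broken by
#' gene identifier order.
#'
#' @param values numeric expression values (>= 0), named by gene id.
#' @param nClasses number of categories (default 3).
#' @param pseudocount added before the log (default 1).
#' @return factor of categories (levels `high`, `medium`, `low` for three
#'   classes), named like `values`.
#' @examples
#' expressionCategories(c(a = 10, b = 100, c = 1000))
#' @export
expressionCategories <- function(values, nClasses = 3L, pseudocount = 1) {
    if (any(values < 0)) stop("expression values must be >= 0")
    n <- length(values)
    ids <- if (is.null(names(values))) as.character(seq_len(n))
           else names(values)
    score <- log2(values + pseudocount)
    o <- order(-score, ids)
    grp <- ((seq_len(n) - 1L) * nClasses) %/% n + 1L  # 1 = highest class
    lev <- if (nClasses == 3L) c("high", "medium", "low")
           else paste0("class", seq_len(nClasses))
    cat.by.rank <- lev[grp]
    out <- character(n)
    out[o] <- cat.by.rank
    factor(structure(out, names = ids), levels = lev)
}
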