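#' Anchored average-gene profile
#'
#' Extracts, for every gene, the track signal in tiled probes of `probe`
#' bases laid out in gene orientation around an anchor -- the 5'
#' transcription start site (`tss5`, default window -1000..+2000) or the
#' 3' transcription termination site (`tts3`, default window
#' -2000..+1000) -- and averages each probe offset across genes, within
#' expression strata when supplied.  Minus-strand genes are reversed so
#' that positive offsets always point in the direction of transcription.
#' A probe that extends beyond the chromosome is missing for that gene
#' and excluded from that offset's mean.  The 95% confidence interval is
#' `mean +/- 1.96 * SE`.
#'
#' @param track a [BinnedTrack-class].
#' @param genes a gene table (see [geneTable()]) with `tss`/`tts` columns.
#' @param anchor `"tss5"` or `"tts3"`.
#' @param upstream,downstream window extent in bases (anchor-relative,
#'   gene-oriented).  Defaults depend on the anchor.
#' @param probe probe width in bases (default 25).
#' @param strata optional factor/character of stratum labels, named by (or
#'   ordered like) gene id.
#' @return data.frame with columns `offset` (probe start relative to the
#'   anchor), `stratum`, `n`, `mean`, `ci_low`, `ci_high`.
#' @export
anchoredProfile <- function(track, genes, anchor = c("tss5", "tts3"),
                            upstream = NULL, downstream = NULL,
                            probe = 25L, strata = NULL) {
    stopifnot(is(track, "BinnedTrack"))
    anchor <- match.arg(anchor)
    if (is.null(upstream)) upstream <- if (anchor == "tss5") 1000L else 2000L
    if (is.null(downstream)) downstream <- if (anchor == "tss5") 2000L else 1000L
    span <- upstream + downstream
    if (span %% probe != 0L)
        stop("upstream + downstream must be a multiple of probe")
    n.win <- span %/% probe
    offsets <- -upstream + (seq_len(n.win) - 1L) * probe

    mat <- .geneProbeMatrix(track, genes, anchor, upstream, downstream,
                            probe)
    strata <- .resolveStrata(strata, genes$id, nrow(mat))
    rows <- lapply(split(seq_len(nrow(mat)), strata), function(idx) {
        sub <- mat[idx, , drop = FALSE]
        n.ok <- colSums(!is.na(sub))
        mu <- colMeans(sub, na.rm = TRUE)
        se <- apply(sub, 2L, function(col) {
            col <- col[!is.na(col)]
            if (length(col) > 1L) sd(col) / sqrt(length(col)) else NA_real_
        })
        data.frame(offset = offsets, stratum = as.character(strata[idx[1L]]),
                   n = n.ok, mean = mu, ci_low = mu - 1.96 * se,
                   ci_high = mu + 1.96 * se, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

## per-gene x per-probe signal matrix, gene-oriented; NA where a probe
## leaves the chromosome
.geneProbeMatrix <- function(track, genes, anchor, upstream, downstream,
                             probe) {
    span <- upstream + downstream
    n.win <- span %/% probe
    bw <- track@binWidth
    a.col <- if (anchor == "tss5") genes$tss else genes$tts
    mat <- matrix(NA_real_, nrow(genes), n.win)
    rel <- -upstream:(downstream - 1L)          # gene-oriented base offsets
    win.of <- rep(seq_len(n.win), each = probe)
    for (i in seq_len(nrow(genes))) {
        v <- track@values[[genes$chrom[i]]]
        if (is.null(v)) next
        L <- track@seqlengths[[genes$chrom[i]]]
        dir <- if (genes$strand[i] == "+") 1L else -1L
        pos <- a.col[i] + dir * rel
        val <- rep(NA_real_, span)
        inside <- pos >= 0L & pos < L
        val[inside] <- v[pos[inside] %/% bw + 1L]
        pm <- tapply(val, win.of, function(x)
            if (anyNA(x)) NA_real_ else mean(x))
        mat[i, ] <- as.numeric(pm)
    }
    rownames(mat) <- genes$id
    mat
}

.resolveStrata <- function(strata, ids, n) {
    if (is.null(strata)) return(factor(rep("all", n)))
    if (!is.null(names(strata))) strata <- strata[ids]
    if (length(strata) != n)
        stop("strata must match the gene table (by name or order)")
    factor(as.character(strata))
}

#' Length-scaled average-gene profile
#'
#' Each gene body (ORF) is resampled to `bodyBins` equal bins (mean of
#' the overlapping source signal, weighted by overlap length); the 5' and
#' 3' flanking regions of `flank` bases are split into
#' `flank / flankFragment` fragments of `flankFragment` bases each.  The
#' concatenated flank5 + body + flank3 vectors, oriented 5' to 3', are
#' averaged across genes.  Genes shorter than `bodyBins` bases are
#' excluded with a warning.
#'
#' @param track a [BinnedTrack-class].
#' @param genes a gene table.
#' @param bodyBins number of body bins (default 40).
#' @param flank flank extent in bases (default 1250).
#' @param flankFragment flank fragment width in bases (default 25).
#' @param strata optional stratum labels as in [anchoredProfile()].
#' @return data.frame with columns `position` (1-based index along the
#'   concatenated profile), `segment` (`flank5`/`body`/`flank3`),
#'   `stratum`, `n`, `mean`, `ci_low`, `ci_high`.
#' @export
scaledProfile <- function(track, genes, bodyBins = 40L, flank = 1250L,
                          flankFragment = 25L, strata = NULL) {
    stopifnot(is(track, "BinnedTrack"))
    if (flank %% flankFragment != 0L)
        stop("flank must be a multiple of flankFragment")
    n.frag <- flank %/% flankFragment
    bw <- track@binWidth

    short <- (genes$orf_end - genes$orf_start) < bodyBins
    if (any(short)) {
        warning(sum(short), " gene(s) shorter than ", bodyBins,
                " bases excluded from the scaled profile")
        genes <- genes[!short, , drop = FALSE]
    }
    total <- 2L * n.frag + bodyBins
    mat <- matrix(NA_real_, nrow(genes), total)
    for (i in seq_len(nrow(genes))) {
        v <- track@values[[genes$chrom[i]]]
        if (is.null(v)) next
        L <- track@seqlengths[[genes$chrom[i]]]
        baseVal <- function(pos) {
            out <- rep(NA_real_, length(pos))
            inside <- pos >= 0L & pos < L
            out[inside] <- v[pos[inside] %/% bw + 1L]
            out
        }
        s0 <- genes$orf_start[i]; e0 <- genes$orf_end[i]
        if (genes$strand[i] == "+") {
            f5 <- baseVal((s0 - flank):(s0 - 1L))
            body <- baseVal(s0:(e0 - 1L))
            f3 <- baseVal(e0:(e0 + flank - 1L))
        } else {
            f5 <- baseVal(rev(e0:(e0 + flank - 1L)))
            body <- baseVal(rev(s0:(e0 - 1L)))
            f3 <- baseVal(rev((s0 - flank):(s0 - 1L)))
        }
        frag <- function(x) colMeans(matrix(x, nrow = flankFragment))
        mat[i, ] <- c(frag(f5), resampleVector(body, bodyBins), frag(f3))
    }
    segment <- c(rep("flank5", n.frag), rep("body", bodyBins),
                 rep("flank3", n.frag))
    strata <- .resolveStrata(strata, genes$id, nrow(mat))
    rows <- lapply(split(seq_len(nrow(mat)), strata), function(idx) {
        sub <- mat[idx, , drop = FALSE]
        n.ok <- colSums(!is.na(sub))
        mu <- colMeans(sub, na.rm = TRUE)
        se <- apply(sub, 2L, function(col) {
            col <- col[!is.na(col)]
            if (length(col) > 1L) sd(col) / sqrt(length(col)) else NA_real_
        })
        data.frame(position = seq_len(total), segment = segment,
                   stratum = as.character(strata[idx[1L]]), n = n.ok,
                   mean = mu, ci_low = mu - 1.96 * se,
                   ci_high = mu + 1.96 * se, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Resample a vector to a fixed number of equal bins
#'
#' Treats `x` as a step function on `[0, length(x))` and returns the mean
#' of each of `nbins` equal-width intervals, weighting source elements by
#' their overlap with the interval.  Exact for any bin count; the identity
#' when `nbins == length(x)`.
#'
#' @param x numeric vector.
#' @param nbins number of output bins.
#' @return numeric vector of length `nbins`.
#' @export
resampleVector <- function(x, nbins) {
    n <- length(x)
    stopifnot(nbins >= 1L, n >= 1L)
    if (nbins == n) return(as.numeric(x))
    b <- seq(0, n, length.out = nbins + 1L)
    cs <- c(0, cumsum(x))
    integ <- function(t) {
        f <- pmin(floor(t), n - 1)
        cs[f + 1L] + (t - f) * x[f + 1L]
    }
    (integ(b[-1L]) - integ(b[-(nbins + 1L)])) / diff(b)
}

#' Place random occupancy at 1 within a feature window
#'
#' Divides every value of a profile window by the window mean, so that a
#' "random" (uniform) dyad frequency sits at exactly 1; the output mean is
#' 1 by construction.
#'
#' @param x numeric vector (a profile window); must have a positive mean.
#' @return the normalized vector.
#' @examples
#' normalizeOccupancy(c(2, 4, 6))
#' @export
normalizeOccupancy <- function(x) {
    m <- mean(x, na.rm = TRUE)
    if (!is.finite(m) || m <= 0)
        stop("window mean must be positive to normalize occupancy")
    x / m
}

#' Moving-average expression-ratio profile
#'
#' Genes are sorted by wild-type expression; a sliding window of `window`
#' genes advancing by `step` yields one point per window with x = mean
#' wild-type expression and y = mean mutant/wild-type ratio (pseudocount
#' added to both sides for stability at silent genes).
#'
#' @param wt,mut numeric expression vectors over the same genes (same
#'   names or order).
#' @param window window size in genes (default 150).
#' @param step step size in genes (default 1).
#' @param pseudocount added to numerator and denominator of each ratio.
#' @return data.frame with columns `x` (mean wild-type expression) and
#'   `y` (mean ratio); `nrow = floor((n - window) / step) + 1`.
#' @export
movingAverageRatio <- function(wt, mut, window = 150L, step = 1L,
                               pseudocount = 1) {
    if (length(wt) != length(mut))
        stop("wt and mut must cover the same genes")
    if (!is.null(names(wt)) && !is.null(names(mut))) {
        if (!setequal(names(wt), names(mut)))
            stop("wt and mut must cover the same genes")
        mut <- mut[names(wt)]
    }
    n <- length(wt)
    if (window > n) stop("window exceeds the number of genes")
    o <- order(wt)
    wt <- wt[o]; mut <- mut[o]
    ratio <- (mut + pseudocount) / (wt + pseudocount)
    starts <- seq.int(1L, n - window + 1L, by = step)
    cw <- c(0, cumsum(wt)); cr <- c(0, cumsum(ratio))
    data.frame(
        x = (cw[starts + window] - cw[starts]) / window,
        y = (cr[starts + window] - cr[starts]) / window)
}
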