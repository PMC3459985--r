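#' Insert-size spectrum of aligned pairs
#'
#' Exact integer counts of pairs per insert size, with no binning.  On
#' MNase-digested chromatin the spectrum is expected to show local maxima
#' near 150, 300 and 450 bp, reflecting the mono-, di- and tri-nucleosome
#' DNA fractions of the digest.
#'
#' @param pairs data.frame with columns `chrom`, `left5`, `isize`.
#' @return data.frame with columns `isize` (ascending) and `count`.
#' @examples
#' p <- data.frame(chrom = "c", left5 = 0L, isize = c(150L, 150L, 300L))
#' isizeSpectrum(p)
#' @export
isizeSpectrum <- function(pairs) {
    if (!nrow(pairs))
        return(data.frame(isize = integer(), count = integer()))
    tab <- table(pairs$isize)
    data.frame(isize = as.integer(names(tab)),
               count = as.integer(tab))
}

#' Select pairs of one particle size class
#'
#' Keeps exactly the pairs whose insert size lies in the inclusive window
#' `[target * (1 - windowFraction), target * (1 + windowFraction)]`.  The
#' nucleosome class is the default: 150 bp +/- 20%, i.e. 150 +/- 30 bp.
#'
#' @param pairs aligned-pair data.frame.
#' @param target nominal particle size (bases), > 0.
#' @param windowFraction half-width of the acceptance window as a fraction
#'   of `target`, in (0, 1).
#' @return the filtered pair data.frame.
#' @examples
#' p <- data.frame(chrom = "c", left5 = 0L, isize = c(119L, 120L, 180L, 181L))
#' sizeClassFilter(p)$isize  # 120 and 180 kept, bounds inclusive
#' @export
sizeClassFilter <- function(pairs, target = 150, windowFraction = 0.2) {
    stopifnot(target > 0, windowFraction > 0, windowFraction < 1)
    lo <- target * (1 - windowFraction)
    hi <- target * (1 + windowFraction)
    out <- pairs[pairs$isize >= lo & pairs$isize <= hi, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Pair center points as putative particle dyad positions
#'
#' The center of each read pair, `left5 + floor(isize / 2)`, estimates the
#' map position of the particle dyad (for the nucleosome size class, the
#' nucleosome dyad).  Input order is preserved.
#'
#' @param pairs aligned-pair data.frame.
#' @return data.frame with columns `chrom`, `pos` (0-based dyad position).
#' @examples
#' dyadPositions(data.frame(chrom = "chrI", left5 = 1000L, isize = 150L))
#' @export
dyadPositions <- function(pairs) {
    data.frame(chrom = pairs$chrom,
               pos = pairs$left5 + pairs$isize %/% 2L,
               stringsAsFactors = FALSE)
}

#' Bin dyad positions into a genome-wide frequency track
#'
#' Dyads are counted into fixed-width bins anchored at coordinate 0: a
#' dyad at position `p` falls in bin `floor(p / binWidth)`.  The total
#' over all bins equals the number of input dyads; positions beyond the
#' chromosome end are counted in the terminal bin with a warning.
#'
#' @param dyads data.frame with columns `chrom`, `pos`.
#' @param binWidth bin width (bases), default 15.
#' @param seqlengths named chromosome lengths; inferred from the largest
#'   position when omitted.
#' @return a [BinnedTrack-class] of dyad frequencies.
#' @export
binDyads <- function(dyads, binWidth = 15L, seqlengths = NULL) {
    stopifnot(binWidth > 0)
    binWidth <- as.integer(binWidth)
    if (is.null(seqlengths)) {
        if (!nrow(dyads)) stop("cannot infer seqlengths from empty input")
        seqlengths <- vapply(split(dyads$pos, dyads$chrom), max,
                             numeric(1)) + 1
    }
    vals <- lapply(names(seqlengths), function(chr) {
        n.bins <- as.integer(ceiling(seqlengths[[chr]] / binWidth))
        p <- dyads$pos[dyads$chrom == chr]
        idx <- p %/% binWidth + 1L
        if (any(idx > n.bins)) {
            warning(sum(idx > n.bins), " dyad(s) beyond the end of ", chr,
                    " counted in the terminal bin")
            idx[idx > n.bins] <- n.bins
        }
        as.numeric(tabulate(idx, nbins = n.bins))
    })
    names(vals) <- names(seqlengths)
    BinnedTrack(vals, binWidth = binWidth, seqlengths = seqlengths,
                valueType = "frequency")
}

#' Bin single-end tag 5' positions into a track
#'
#' Identical arithmetic to [binDyads()] applied to the `pos5` column of a
#' tag data.frame; the conventional bin width for enrichment tracks is
#' 10 bp.
#'
#' @param tags data.frame with columns `chrom`, `pos5`, `strand`.
#' @param binWidth bin width (bases).
#' @param seqlengths named chromosome lengths.
#' @return a [BinnedTrack-class] of tag counts.
#' @export
binTags <- function(tags, binWidth = 10L, seqlengths = NULL) {
    binDyads(data.frame(chrom = tags$chrom, pos = tags$pos5,
                        stringsAsFactors = FALSE),
             binWidth = binWidth, seqlengths = seqlengths)
}

#' Three-bin moving average
#'
#' Interior bins are replaced by the mean of themselves and their two
#' neighbours; terminal bins use the mean over the two available bins
#' (edge-shrink policy, so constant tracks are fixed points).
#'
#' @param track a [BinnedTrack-class].
#' @return the smoothed [BinnedTrack-class].
#' @examples
#' smooth3(BinnedTrack(list(c = c(0, 3, 0)), 15))  # 1.5, 1, 1.5
#' @export
smooth3 <- function(track) {
    stopifnot(is(track, "BinnedTrack"))
    .mapTrack(track, .smooth3vec)
}

.smooth3vec <- function(v) {
    n <- length(v)
    if (n <= 1L) return(v)
    if (n == 2L) return(rep(mean(v), 2L))
    out <- v
    out[1L] <- (v[1L] + v[2L]) / 2
    out[n] <- (v[n - 1L] + v[n]) / 2
    mid <- 2L:(n - 1L)
    out[mid] <- (v[mid - 1L] + v[mid] + v[mid + 1L]) / 3
    out
}

#' Size-class particle dyad mapping
#'
#' The composed core computation: select pairs of the target size class,
#' take pair centers as dyad positions, bin them genome-wide, and smooth
#' with a 3-bin moving average.  With the defaults (150 bp +/- 20%, 15 bp
#' bins) the result is the nucleosome dyad frequency track.
#'
#' @param pairs aligned-pair data.frame.
#' @param target,windowFraction size-class selection (see
#'   [sizeClassFilter()]).
#' @param binWidth bin width (bases).
#' @param seqlengths named chromosome lengths.
#' @param smooth apply the 3-bin moving average (default `TRUE`).
#' @return a [BinnedTrack-class] of (smoothed) dyad frequencies.
#' @export
mapParticles <- function(pairs, target = 150, windowFraction = 0.2,
                         binWidth = 15L, seqlengths = NULL, smooth = TRUE) {
    sel <- sizeClassFilter(pairs, target, windowFraction)
    track <- binDyads(dyadPositions(sel), binWidth = binWidth,
                      seqlengths = seqlengths)
    if (smooth) smooth3(track) else track
}

#' Local maxima of a binned track
#'
#' A peak is a bin whose value is strictly greater than the values of the
#' neighbouring runs on both sides; a plateau of equal values reports its
#' leftmost bin.  Track ends are not peaks.
#'
#' @param track a [BinnedTrack-class].
#' @param minHeight discard peaks below this value.
#' @return data.frame with columns `chrom`, `bin` (0-based bin index),
#'   `pos` (bin center coordinate, bases), `height`.
#' @export
callPeaks <- function(track, minHeight = 0) {
    stopifnot(is(track, "BinnedTrack"))
    bw <- track@binWidth
    res <- lapply(names(track@values), function(chr) {
        v <- track@values[[chr]]
        r <- rle(v)
        k <- length(r$values)
        if (k < 3L)
            return(data.frame(chrom = character(), bin = integer(),
                              pos = numeric(), height = numeric()))
        is.peak <- c(FALSE, r$values[2:(k - 1)] > r$values[1:(k - 2)] &
                         r$values[2:(k - 1)] > r$values[3:k], FALSE)
        first.bin <- cumsum(c(0L, r$lengths[-k]))  # 0-based run starts
        sel <- which(is.peak & r$values > minHeight)
        data.frame(chrom = rep(chr, length(sel)), bin = first.bin[sel],
                   pos = first.bin[sel] * bw + (bw - 1) / 2,
                   height = r$values[sel], stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}
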